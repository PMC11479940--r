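#' Binarize per-read methylation calls by log-likelihood ratio
#'
#' Nanopore methylation callers emit a per-read, per-site log-likelihood
#' ratio (positive favours 5mC). Calls with `LLR >= threshold` are
#' methylated, calls with `LLR <= -threshold` unmethylated, and calls in
#' the symmetric dead zone `|LLR| < threshold` are discarded and counted.
#' The default threshold of 2 is common nanopolish practice.
#'
#' @param calls data.frame with a `log_lik_ratio` column (see
#'   [read_methylation_calls()]).
#' @param llr_threshold Positive dead-zone half-width; default 2.
#' @return list with `calls` (retained rows plus a logical `methylated`
#'   column) and `n_discarded` (dead-zone call count).
#' @export
binarize_calls <- function(calls, llr_threshold = 2) {
  stopifnot(llr_threshold > 0)
  keep <- abs(calls$log_lik_ratio) >= llr_threshold
  out <- calls[keep, , drop = FALSE]
  out$methylated <- out$log_lik_ratio > 0
  list(calls = out, n_discarded = sum(!keep))
}

# 5'-anchored quarter index (1-4) for 0-based positions within an element.
.quarter_of <- function(pos, start, end, strand) {
  q_len <- (end - start) / 4
  q <- pmin(4L, as.integer(floor((pos - start) / q_len)) + 1L)
  if (identical(strand, "-")) q <- 5L - q
  q
}

#' Per-element methylation summary with strand-aware quarters
#'
#' Aggregates binarized calls falling inside one element into a read-level
#' methylation fraction (methylated calls / retained calls), plus the same
#' fraction over four equal sub-intervals ordered from the element's 5'
#' end. For minus-strand elements the genomic quarters are reversed, so
#' "first quarter" always means the quarter containing the element's own
#' TSS. The call-weighted average of the quarter means equals the
#' full-element mean.
#'
#' @param calls Binarized calls (`$calls` from [binarize_calls()]), with
#'   `chromosome`, `start` (0-based site) and `methylated` columns.
#' @param element One-row BED data.frame with `chrom`, `start`, `end`,
#'   `name`, `strand` (`+` or `-`).
#' @return list with `element_id`, `n_sites`, `n_calls`,
#'   `mean_methylation`, `quarter_means` (length 4, 5' to 3') and
#'   `quarter_calls`. With zero retained calls the means are `NA` and the
#'   count fields 0.
#' @export
element_methylation <- function(calls, element) {
  stopifnot(nrow(element) == 1L, element$strand %in% c("+", "-"))
  inside <- calls$chromosome == element$chrom &
    calls$start >= element$start & calls$start < element$end
  sub <- calls[inside, , drop = FALSE]
  id <- if (!is.null(element$name)) element$name else
    sprintf("%s:%d-%d", element$chrom, element$start, element$end)
  if (nrow(sub) == 0L) {
    return(list(element_id = id, n_sites = 0L, n_calls = 0L,
                mean_methylation = NA_real_,
                quarter_means = rep(NA_real_, 4L),
                quarter_calls = rep(0L, 4L)))
  }
  q <- .quarter_of(sub$start, element$start, element$end, element$strand)
  qn <- tabulate(q, 4L)
  qm <- vapply(1:4, function(k) {
    if (qn[k] == 0L) NA_real_ else mean(sub$methylated[q == k])
  }, numeric(1))
  list(element_id = id,
       n_sites = length(unique(sub$start)),
       n_calls = nrow(sub),
       mean_methylation = mean(sub$methylated),
       quarter_means = qm,
       quarter_calls = qn)
}

#' Summarize methylation for many elements
#'
#' @param calls Binarized calls (see [element_methylation()]).
#' @param elements BED data.frame of elements.
#' @return data.frame with one row per element: `element_id`, `n_sites`,
#'   `n_calls`, `mean_methylation`, `q1`..`q4` (5'-anchored quarter
#'   means).
#' @export
methylation_by_element <- function(calls, elements) {
  rows <- lapply(seq_len(nrow(elements)), function(i) {
    em <- element_methylation(calls, elements[i, , drop = FALSE])
    data.frame(element_id = em$element_id, n_sites = em$n_sites,
               n_calls = em$n_calls,
               mean_methylation = em$mean_methylation,
               q1 = em$quarter_means[1L], q2 = em$quarter_means[2L],
               q3 = em$quarter_means[3L], q4 = em$quarter_means[4L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare element methylation between two groups
#'
#' Takes two groups of per-element summaries (e.g. a methylated control
#' condition versus a demethylated knockdown) and compares either the
#' full-element means or the 5'-anchored first-quarter means with a
#' two-sided two-sample Student's t-test.
#'
#' @param group_a,group_b data.frames from [methylation_by_element()].
#' @param region `"full"` (uses `mean_methylation`) or `"first_quarter"`
#'   (uses `q1`).
#' @return list with `region`, per-group `n` and means, `difference`
#'   (a - b), `t_statistic`, `p_value` and `test` (`"student_t"`, or
#'   `"not_applicable"` when either group has fewer than 2 usable
#'   values, in which case the statistic and p-value are `NA`).
#' @export
compare_methylation <- function(group_a, group_b,
                                region = c("full", "first_quarter")) {
  region <- match.arg(region)
  col <- if (region == "full") "mean_methylation" else "q1"
  a <- group_a[[col]][!is.na(group_a[[col]])]
  b <- group_b[[col]][!is.na(group_b[[col]])]
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  out <- list(region = region, n_a = length(a), n_b = length(b),
              mean_a = mean(a), mean_b = mean(b),
              difference = mean(a) - mean(b))
  if (length(a) < 2L || length(b) < 2L ||
      (stats::var(a) == 0 && stats::var(b) == 0)) {
    if (length(a) >= 2L && length(b) >= 2L && mean(a) == mean(b)) {
      # degenerate equal constant groups: no evidence of difference
      out$t_statistic <- 0
      out$p_value <- 1
      out$test <- "student_t"
    } else {
      out$t_statistic <- NA_real_
      out$p_value <- NA_real_
      out$test <- "not_applicable"
    }
    return(out)
  }
  tt <- t.test(a, b, var.equal = TRUE)
  out$t_statistic <- unname(tt$statistic)
  out$p_value <- tt$p.value
  out$test <- "student_t"
  out
}
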