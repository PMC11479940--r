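#' Cohort descriptive statistics for one field
#'
#' Mean and sample standard deviation (n - 1 denominator) of a numeric
#' field over cohort records; records missing the field are excluded and
#' counted. Display rounding is half-up to one decimal; full-precision
#' values are always returned.
#'
#' @param records data.frame of cohort records (e.g. columns
#'   `participant`, `status`, `age_at_onset`, `age_at_collection`,
#'   `hexamer_copies`).
#' @param field Column name to summarize.
#' @return list with `field`, `n`, `n_missing`, `mean`, `sd` (`NA` with
#'   n = 1), and `display` (e.g. `"42.7 +/- 13.6"`).
#' @export
cohort_summary <- function(records, field) {
  if (!field %in% names(records)) stop("unknown field: ", field)
  v <- records[[field]]
  n_missing <- sum(is.na(v))
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no record carries a value for '", field, "'")
  m <- mean(v)
  s <- if (length(v) >= 2L) sd(v) else NA_real_
  half_up <- function(x, d) floor(x * 10^d + 0.5) / 10^d
  disp <- if (is.na(s)) sprintf("%.1f (n = 1)", half_up(m, 1L)) else
    sprintf("%.1f +/- %.1f", half_up(m, 1L), half_up(s, 1L))
  list(field = field, n = length(v), n_missing = n_missing,
       mean = m, sd = s, display = disp)
}

#' On-target read statistics for targeted sequencing
#'
#' Per-sample on-target proportions (on-target primary reads over total
#' reads) and their summary across samples. The headline is the unweighted
#' mean of the per-sample proportions; the pooled proportion (summed
#' on-target over summed totals) is also computed. A user-supplied total
#' differing from the per-sample sum is reported verbatim alongside the
#' sum, never silently reconciled.
#'
#' @param total_reads Integer vector of per-sample total read counts (all
#'   > 0).
#' @param on_target_reads Integer vector of per-sample on-target primary
#'   read counts; each must not exceed its total.
#' @param sample_ids Optional sample names.
#' @param stated_total Optional externally stated grand total to report
#'   next to `sum(total_reads)`.
#' @return list with `per_sample` (data.frame of totals, on-target counts
#'   and proportions), `mean_proportion` (unweighted), `pooled_proportion`,
#'   `total_reads_sum` and `stated_total` (`NA` when not given).
#' @export
on_target_stats <- function(total_reads, on_target_reads,
                            sample_ids = NULL, stated_total = NULL) {
  if (length(total_reads) != length(on_target_reads)) {
    stop("total_reads and on_target_reads must have equal length")
  }
  if (any(total_reads <= 0)) stop("all totals must be positive")
  if (any(on_target_reads < 0 | on_target_reads > total_reads)) {
    stop("on-target counts must lie in [0, total] for every sample")
  }
  if (is.null(sample_ids)) {
    sample_ids <- paste0("sample", seq_along(total_reads))
  }
  prop <- on_target_reads / total_reads
  list(per_sample = data.frame(sample = sample_ids,
                               total_reads = total_reads,
                               on_target_reads = on_target_reads,
                               proportion = prop,
                               stringsAsFactors = FALSE),
       mean_proportion = mean(prop),
       pooled_proportion = sum(on_target_reads) / sum(total_reads),
       total_reads_sum = sum(total_reads),
       stated_total = if (is.null(stated_total)) NA_real_ else stated_total)
}
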