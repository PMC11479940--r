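#' Filter alignment records for unique, low-mismatch hits
#'
#' Mirrors the read-filtering used for repeat-element quantification:
#' secondary/supplementary records are dropped, multimapping records are
#' dropped when `unique_only`, and records whose per-base mismatch rate
#' exceeds `max_mismatch_rate` are dropped. The rate comparison is
#' inclusive (`mismatches / aligned_length <= max_mismatch_rate`), matching
#' a "maximum allowed" semantics, so a 100-base read with exactly 3
#' mismatches survives the default 0.03 cut.
#'
#' @param records data.frame of alignment records (see
#'   [read_sam_minimal()]).
#' @param max_mismatch_rate Maximum mismatches per aligned base; default
#'   0.03.
#' @param unique_only Drop records with `number_of_hits > 1`; default TRUE.
#' @return The surviving subset of `records`, order preserved.
#' @export
filter_alignments <- function(records, max_mismatch_rate = 0.03,
                              unique_only = TRUE) {
  stopifnot(all(records$aligned_length > 0))
  keep <- records$is_primary &
    (!unique_only | records$number_of_hits == 1L) &
    records$mismatches / records$aligned_length <= max_mismatch_rate
  records[keep, , drop = FALSE]
}

#' Spike-in scaling factor from aligned exogenous reads
#'
#' CUT&RUN libraries carry exogenous (yeast) spike-in DNA; coverage is made
#' comparable across samples by scaling with `1e4 / aligned spike-in
#' reads`.
#'
#' @param aligned_spikein_reads Number of reads aligned to the spike-in
#'   genome; must be positive.
#' @return list with `aligned_reads` and `scale_factor`.
#' @export
spikein_scale_factor <- function(aligned_spikein_reads) {
  n <- as.numeric(aligned_spikein_reads)
  if (length(n) != 1L || is.na(n) || n < 0) {
    stop("aligned_spikein_reads must be a single non-negative number")
  }
  if (n == 0) {
    stop("no aligned spike-in reads: cannot compute a scaling factor")
  }
  list(aligned_reads = n, scale_factor = 1e4 / n)
}

#' @rdname spikein_scale_factor
#' @param track Coverage track data.frame (`chrom`, `start`, `end`,
#'   `value`).
#' @param factor Multiplicative factor, e.g.
#'   `spikein_scale_factor(n)$scale_factor`.
#' @export
scale_track <- function(track, factor) {
  track$value <- track$value * factor
  track
}

# Mean track value over [from, to) in one chromosome, length-weighted over
# the overlapping track intervals; uncovered bases count as 0. `from`/`to`
# may be fractional (scaled body bins cut the track at non-integer points).
.track_mean <- function(starts, ends, values, from, to) {
  if (to <= from) return(NA_real_)
  ov <- pmin(ends, to) - pmax(starts, from)
  ov[ov < 0] <- 0
  sum(ov * values) / (to - from)
}

#' Scale-regions profile matrix over elements
#'
#' Builds a deepTools-style scale-regions matrix: each qualifying element's
#' body is rescaled to `body / bin` bins by length-weighted averaging of
#' the track, and fixed-width `flank` regions on both sides are averaged in
#' raw `bin`-sized windows. Rows for minus-strand elements are reversed so
#' that columns always run 5' to 3' of the element. Only elements with
#' `end - start > min_element_length` get a row. Flank bins that extend
#' beyond a chromosome end (when `chrom_lengths` is supplied) are set to
#' `NA` and excluded from column means.
#'
#' @param track Coverage track data.frame (`chrom`, `start`, `end`,
#'   `value`), intervals sorted and non-overlapping; uncovered bases are 0.
#' @param elements BED data.frame (`chrom`, `start`, `end`, `name`,
#'   `strand`).
#' @param body Rescaled body width in bases (default 1000).
#' @param flank Flank width in bases on each side (default 10000).
#' @param bin Bin width in bases (default 50); must divide `body` and
#'   `flank`.
#' @param min_element_length Strict length cutoff in bases (default 1000).
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   off-end flank detection.
#' @return A `profile_matrix`: numeric matrix (elements x bins) with
#'   attributes `body`, `flank`, `bin`.
#' @export
scale_regions_matrix <- function(track, elements, body = 1000L,
                                 flank = 10000L, bin = 50L,
                                 min_element_length = 1000L,
                                 chrom_lengths = NULL) {
  if (body %% bin != 0L || flank %% bin != 0L) {
    stop("body and flank must be multiples of bin")
  }
  keep <- (elements$end - elements$start) > min_element_length
  elements <- elements[keep, , drop = FALSE]
  nb_body <- body %/% bin
  nb_flank <- flank %/% bin
  ncol_total <- 2L * nb_flank + nb_body
  mat <- matrix(NA_real_, nrow(elements), ncol_total)
  rn <- if (!is.null(elements$name) && !anyDuplicated(elements$name)) {
    elements$name
  } else {
    sprintf("%s:%d-%d", elements$chrom, elements$start, elements$end)
  }
  rownames(mat) <- rn
  by_chrom <- split(track, track$chrom)
  for (i in seq_len(nrow(elements))) {
    chrom <- elements$chrom[i]
    tc <- by_chrom[[chrom]]
    st <- if (is.null(tc)) numeric() else tc$start
    en <- if (is.null(tc)) numeric() else tc$end
    va <- if (is.null(tc)) numeric() else tc$value
    s <- elements$start[i]
    e <- elements$end[i]
    # bin edges in genomic coordinates: upstream flank, scaled body, downstream
    up_edges <- seq(s - flank, s, by = bin)
    body_edges <- seq(s, e, length.out = nb_body + 1L)
    down_edges <- seq(e, e + flank, by = bin)
    edges <- list(up_edges, body_edges, down_edges)
    row <- unlist(lapply(edges, function(ed) {
      vapply(seq_len(length(ed) - 1L), function(j) {
        .track_mean(st, en, va, ed[j], ed[j + 1L])
      }, numeric(1))
    }))
    # off-chromosome bins become NA (missing), never fabricated zeros
    lo <- c(head(up_edges, -1L), head(body_edges, -1L),
            head(down_edges, -1L))
    hi <- c(up_edges[-1L], body_edges[-1L], down_edges[-1L])
    row[lo < 0] <- NA_real_
    if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths)) {
      row[hi > chrom_lengths[[chrom]]] <- NA_real_
    }
    if (identical(elements$strand[i], "-")) row <- rev(row)
    mat[i, ] <- row
  }
  structure(mat, body = body, flank = flank, bin = bin,
            class = c("profile_matrix", "matrix", "array"))
}

#' Write/read a profile matrix as TSV with a JSON header line
#'
#' The first line is a `#` comment carrying the body/flank/bin geometry as
#' JSON; the rest is a plain TSV (rows = elements, columns = bins).
#'
#' @param mat A `profile_matrix`.
#' @param path File path.
#' @export
write_profile_matrix <- function(mat, path) {
  hdr <- paste0("#", jsonlite::toJSON(list(body = attr(mat, "body"),
                                           flank = attr(mat, "flank"),
                                           bin = attr(mat, "bin")),
                                      auto_unbox = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(unclass(mat), con, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(path)
}

#' @rdname write_profile_matrix
#' @export
read_profile_matrix <- function(path) {
  hdr <- jsonlite::fromJSON(sub("^#", "", readLines(path, n = 1L)))
  df <- read.delim(path, comment.char = "#", row.names = 1L,
                   check.names = FALSE)
  m <- as.matrix(df)
  colnames(m) <- NULL
  structure(m, body = hdr$body, flank = hdr$flank, bin = hdr$bin,
            class = c("profile_matrix", "matrix", "array"))
}

#' Boundary-enrichment ratio per element
#'
#' For each row of a scale-regions matrix, the mean signal over the bins
#' within `window` of each body edge -- the outermost body bins plus the
#' innermost flank bins on both sides -- is divided by the mean over the
#' most distal flank bins (the same `window` at the far ends of both
#' flanks). The flank-side bins are in raw genomic units, so a boundary
#' peak is captured undiluted even when a long body is scaled down.
#' Elements with zero distal-flank signal return `NA`, never infinity.
#'
#' @param mat A `profile_matrix` from [scale_regions_matrix()].
#' @param window Width in bases of the boundary/distal windows; must be a
#'   multiple of the matrix bin size and at most the flank width. Default
#'   1000.
#' @return Named numeric vector of ratios, one per element row.
#' @export
boundary_enrichment <- function(mat, window = 1000L) {
  bin <- attr(mat, "bin")
  flank <- attr(mat, "flank")
  body <- attr(mat, "body")
  if (window %% bin != 0L) stop("window must be a multiple of the bin size")
  if (window > flank) stop("window must not exceed the flank width")
  w <- window %/% bin
  nf <- flank %/% bin
  nb <- body %/% bin
  body_cols <- unique(c(nf + seq_len(min(w, nb)),          # outer body
                        nf + nb - seq_len(min(w, nb)) + 1L,
                        nf - seq_len(w) + 1L,              # inner flanks
                        nf + nb + seq_len(w)))
  distal_cols <- c(seq_len(w), ncol(mat) - seq_len(w) + 1L)
  ratio <- vapply(seq_len(nrow(mat)), function(i) {
    b <- mean(mat[i, body_cols], na.rm = TRUE)
    d <- mean(mat[i, distal_cols], na.rm = TRUE)
    if (!is.finite(d) || d == 0) return(NA_real_)
    b / d
  }, numeric(1))
  setNames(ratio, rownames(mat))
}
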