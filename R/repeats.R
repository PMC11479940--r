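#' Reverse-complement a nucleotide string
#'
#' @param x Character vector of sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Column-majority consensus of aligned reads
#'
#' Computes a per-column plurality consensus from a multiple alignment of
#' reads spanning one locus, including insertions and deletions: a column
#' whose plurality symbol is the gap character is deleted from the
#' consensus, and columns with informative depth below `min_depth` emit
#' `N`. Ties are broken in the fixed order A < C < G < T < gap.
#'
#' @param alignment Character vector of equal-length gapped read strings
#'   over A/C/G/T/N/-; `N` marks a read not covering the column and does
#'   not count towards depth.
#' @param min_depth Minimum informative depth per column; default 1.
#' @return The consensus sequence (character scalar).
#' @export
column_consensus <- function(alignment, min_depth = 1L) {
  stopifnot(min_depth >= 1L)
  if (length(alignment) == 0L) stop("empty alignment")
  alignment <- toupper(alignment)
  w <- unique(nchar(alignment))
  if (length(w) != 1L) stop("aligned reads must have equal length")
  if (w == 0L) stop("empty alignment")
  m <- do.call(rbind, strsplit(alignment, ""))
  symbols <- c("A", "C", "G", "T", "-")
  out <- vapply(seq_len(w), function(j) {
    col <- m[, j]
    counts <- vapply(symbols, function(s) sum(col == s), integer(1))
    if (sum(counts) < min_depth) return("N")
    symbols[which.max(counts)]  # which.max honours the A<C<G<T<- tie order
  }, character(1))
  paste(out[out != "-"], collapse = "")
}

#' Find noise-tolerant tandem-motif runs
#'
#' Locates maximal segments of `sequence` alignable to a tandem
#' concatenation of `motif` with an edit-noise fraction (substitutions +
#' insertions + deletions over aligned columns) below `max_noise`, using
#' local wraparound dynamic programming with unit edit costs. Matching is
#' phase-agnostic: a run may start and end mid-motif, and terminal partial
#' copies contribute fractionally to the copy estimate. Runs are reported
#' 5' to 3', non-overlapping, extracted best-scoring first; a segment must
#' span at least two motif copies to count as a tandem run, so isolated
#' chance matches in random sequence are not reported.
#'
#' @param sequence Nucleotide string.
#' @param motif Short motif string (e.g. `"CCCTCT"` for the SVA hexamer
#'   head).
#' @param max_noise Maximum edit-noise fraction in [0, 0.5); default 0.2.
#' @param min_length Minimum run length in bases; shorter runs are
#'   discarded. Default 0.
#' @return data.frame with one row per run: `start`, `end` (0-based
#'   half-open on `sequence`), `motif`, `copy_estimate` (aligned motif
#'   copies, real-valued), `matches`, `mismatches_plus_indels`,
#'   `identity`. Zero rows when no run is found.
#' @examples
#' find_motif_run(strrep("CCCTCT", 40), "CCCTCT")
#' @export
find_motif_run <- function(sequence, motif, max_noise = 0.2,
                           min_length = 0L) {
  stopifnot(nchar(motif) >= 1L, max_noise >= 0, max_noise < 0.5)
  sequence <- toupper(sequence)
  motif <- toupper(motif)
  runs <- .motif_runs_recursive(strsplit(sequence, "")[[1]],
                                strsplit(motif, "")[[1]],
                                max_noise, 0L)
  if (length(runs) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), copy_estimate = numeric(),
                      matches = integer(),
                      mismatches_plus_indels = integer(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(runs, as.data.frame))
  df$motif <- motif
  df <- df[df$end - df$start >= min_length, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("start", "end", "motif", "copy_estimate", "matches",
         "mismatches_plus_indels", "identity")]
}

# Best-run-then-recurse extraction of non-overlapping runs. A segment only
# counts as tandem when it spans at least two motif copies; a best hit
# below that also prunes the recursion (chance single-copy matches in
# random sequence never nest a stronger multi-copy run).
.motif_runs_recursive <- function(s, m, max_noise, offset) {
  if (length(s) < 2L * length(m)) return(list())
  best <- .wraparound_dp(s, m, max_noise)
  if (is.null(best) || best$consumed < 2L * length(m)) return(list())
  run <- list(start = offset + best$start,
              end = offset + best$end,
              copy_estimate = best$consumed / length(m),
              matches = best$matches,
              mismatches_plus_indels = best$errors,
              identity = best$matches / (best$matches + best$errors))
  left <- if (best$start >= length(m)) {
    .motif_runs_recursive(s[seq_len(best$start)], m, max_noise, offset)
  } else list()
  right <- if (length(s) - best$end >= length(m)) {
    .motif_runs_recursive(s[(best$end + 1L):length(s)], m, max_noise,
                          offset + best$end)
  } else list()
  c(left, list(run), right)
}

# Local alignment of s against an unbounded tandem repeat of motif m.
# Match scores +1; each edit costs (1 - max_noise)/max_noise, so any
# positive-scoring segment has edit noise strictly below max_noise.
# Cell state: for each motif phase j (next motif char to align is m[j+1]),
# the best local alignment ending at the current sequence position with
# that phase, carrying its start, match/error counts and motif chars
# consumed. Deletion chains within a row are relaxed with two passes over
# the cyclic phases (a full-motif deletion chain is never beneficial).
.wraparound_dp <- function(s, m, max_noise) {
  n <- length(s)
  k <- length(m)
  ep <- if (max_noise == 0) Inf else (1 - max_noise) / max_noise
  neg <- -Inf
  score <- rep(0, k); start <- rep(0L, k)
  mat <- rep(0L, k); err <- rep(0L, k); cons <- rep(0L, k)
  best <- list(score = 0)
  for (i in seq_len(n)) {
    ns <- rep(neg, k); nstart <- integer(k)
    nmat <- integer(k); nerr <- integer(k); ncons <- integer(k)
    for (j in seq_len(k)) {
      pj <- if (j == 1L) k else j - 1L
      # diagonal: align s[i] with m[pj] -> arrive at phase j
      dscore <- if (s[i] == m[pj]) score[pj] + 1 else score[pj] - ep
      dmatch <- s[i] == m[pj]
      # fresh start: first aligned char is s[i] vs m[pj]
      fscore <- if (dmatch) 1 else -ep
      if (fscore > dscore) {
        ns[j] <- fscore; nstart[j] <- i - 1L
        nmat[j] <- as.integer(dmatch); nerr[j] <- as.integer(!dmatch)
        ncons[j] <- 1L
      } else {
        ns[j] <- dscore; nstart[j] <- start[pj]
        nmat[j] <- mat[pj] + as.integer(dmatch)
        nerr[j] <- err[pj] + as.integer(!dmatch)
        ncons[j] <- cons[pj] + 1L
      }
      # insertion in s (extra sequence char, phase unchanged)
      iscore <- score[j] - ep
      if (iscore > ns[j]) {
        ns[j] <- iscore; nstart[j] <- start[j]
        nmat[j] <- mat[j]; nerr[j] <- err[j] + 1L; ncons[j] <- cons[j]
      }
    }
    if (is.finite(ep)) {
      for (pass in 1:2) {
        for (j in seq_len(k)) {
          pj <- if (j == 1L) k else j - 1L
          dscore <- ns[pj] - ep  # deletion: skip m[pj], consume no s char
          if (dscore > ns[j]) {
            ns[j] <- dscore; nstart[j] <- nstart[pj]
            nmat[j] <- nmat[pj]; nerr[j] <- nerr[pj] + 1L
            ncons[j] <- ncons[pj] + 1L
          }
        }
      }
    }
    jbest <- which.max(ns)
    if (ns[jbest] > best$score) {
      best <- list(score = ns[jbest], start = nstart[jbest], end = i,
                   matches = nmat[jbest], errors = nerr[jbest],
                   consumed = ncons[jbest])
    }
    score <- ns; start <- nstart; mat <- nmat; err <- nerr; cons <- ncons
  }
  if (best$score <= 0) NULL else best
}

#' Hexamer copy-number report from an aligned read set
#'
#' Pipeline composition of [column_consensus()] and [find_motif_run()]:
#' builds the consensus of the aligned reads, locates tandem runs of the
#' motif, and reports the copy number of the longest run (ties broken
#' 5'-most), rounded half-up to an integer -- the headline hexamer length
#' of an SVA.
#'
#' @param alignment Character vector of equal-length gapped reads.
#' @param motif Motif string; default the SVA hexamer `"CCCTCT"`.
#' @param max_noise,min_length Passed to [find_motif_run()].
#' @param min_depth Passed to [column_consensus()].
#' @return list with `consensus`, `runs` (the [find_motif_run()] table)
#'   and `copies` (integer, or `NA` when no run was found -- never a
#'   fabricated 0).
#' @export
hexamer_report <- function(alignment, motif = "CCCTCT", max_noise = 0.2,
                           min_length = 0L, min_depth = 1L) {
  consensus <- column_consensus(alignment, min_depth = min_depth)
  runs <- find_motif_run(consensus, motif, max_noise = max_noise,
                         min_length = min_length)
  copies <- if (nrow(runs) == 0L) {
    NA_integer_
  } else {
    span <- runs$end - runs$start
    top <- which(span == max(span))
    top <- top[which.min(runs$start[top])]
    as.integer(floor(runs$copy_estimate[top] + 0.5))  # half-up
  }
  list(consensus = consensus, runs = runs, copies = copies)
}
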