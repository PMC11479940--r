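#' Default TLDR-style quality-filter thresholds
#'
#' Insertion calls are retained when the fraction of the inserted sequence
#' covered by TE sequence (UnmapCover) is at least 80%, similarity to the TE
#' consensus (TEMatch) is at least 80%, at least three reads span the
#' insertion, and the inserted sequence is longer than 1 kbp. Subfamily
#' restriction is off by default (empty set = allow all).
#'
#' @param min_unmap_cover,min_te_match Minimum quality fractions in [0, 1].
#' @param min_span_reads Minimum supporting read count (inclusive).
#' @param min_length Length threshold in bases; the comparison is strict
#'   (`length > min_length`).
#' @param allowed_subfamilies Character vector of subfamily labels; empty
#'   means no restriction.
#' @return A list of thresholds for [filter_insertions()].
#' @export
insertion_thresholds <- function(min_unmap_cover = 0.80,
                                 min_te_match = 0.80,
                                 min_span_reads = 3L,
                                 min_length = 1000L,
                                 allowed_subfamilies = character()) {
  stopifnot(min_unmap_cover >= 0, min_te_match >= 0,
            min_span_reads >= 0, min_length >= 0)
  list(min_unmap_cover = min_unmap_cover, min_te_match = min_te_match,
       min_span_reads = as.integer(min_span_reads),
       min_length = as.integer(min_length),
       allowed_subfamilies = allowed_subfamilies)
}

# Header aliases: TLDR and close variants -> canonical column names.
.insertion_aliases <- list(
  chrom = c("chrom", "chromosome", "chr", "Chrom", "Chromosome", "Chr"),
  start = c("start", "Start"),
  end = c("end", "End"),
  subfamily = c("subfamily", "Subfamily", "family", "Family"),
  consensus = c("consensus", "Consensus", "TEConsensus", "ins_seq"),
  unmap_cover = c("unmap_cover", "UnmapCover", "UnmapCoverage"),
  te_match = c("te_match", "TEMatch", "Match"),
  span_reads = c("span_reads", "SpanReads", "span-reads", "span.reads",
                 "SpanReadCount"),
  sample_ids = c("sample_ids", "SampleReads", "Samples", "sample", "samples")
)

#' Read a TLDR-style non-reference insertion table
#'
#' Parses a tab-separated table of non-reference TE insertion calls into a
#' validated data frame. Column headers are resolved through a configurable
#' alias table (TLDR spells the quality fields `UnmapCover`, `TEMatch`,
#' `SpanReads`). Percentage-scaled quality columns (values in 0-100) are
#' detected per column and normalized to fractions.
#'
#' @param path Path to a tab-separated file with a header row naming at
#'   least the chromosome, start, end, subfamily, consensus and the three
#'   quality columns.
#' @param aliases Named list mapping canonical field names to accepted
#'   header spellings; defaults cover TLDR's headers.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `subfamily`, `consensus`, `length`, `unmap_cover`,
#'   `te_match` (fractions), `span_reads`, `sample_ids`
#'   (comma-separated text).
#' @export
read_insertion_table <- function(path, aliases = .insertion_aliases) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  resolve <- function(field) {
    hit <- intersect(aliases[[field]], names(raw))
    if (length(hit) == 0L && field != "sample_ids") {
      stop("insertion table is missing a column for '", field,
           "' (accepted headers: ", paste(aliases[[field]], collapse = ", "),
           ")")
    }
    if (length(hit)) hit[1L] else NA_character_
  }
  cols <- vapply(names(aliases), resolve, character(1))
  out <- data.frame(
    chrom = as.character(raw[[cols["chrom"]]]),
    start = as.integer(raw[[cols["start"]]]),
    end = as.integer(raw[[cols["end"]]]),
    subfamily = as.character(raw[[cols["subfamily"]]]),
    consensus = toupper(as.character(raw[[cols["consensus"]]])),
    stringsAsFactors = FALSE
  )
  num_col <- function(field) {
    v <- raw[[cols[field]]]
    n <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(n) & !is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                   v[bad[1L]], cols[field], bad[1L]))
    }
    n
  }
  for (field in c("unmap_cover", "te_match")) {
    v <- num_col(field)
    # columns printed as percentages (0-100) are normalized to fractions
    if (any(v > 1, na.rm = TRUE)) v <- v / 100
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      stop("column '", cols[field], "' is not a fraction or percentage")
    }
    out[[field]] <- v
  }
  out$span_reads <- as.integer(num_col("span_reads"))
  out$sample_ids <- if (!is.na(cols["sample_ids"])) {
    as.character(raw[[cols["sample_ids"]]])
  } else rep("", nrow(out))
  out$length <- nchar(out$consensus)
  if (nrow(out)) {
    if (any(out$start > out$end)) stop("insertion with start > end")
    if (any(out$length == 0L)) stop("insertion with empty consensus")
    if (any(out$span_reads < 0L)) stop("negative span_reads")
  }
  out[, c("chrom", "start", "end", "subfamily", "consensus", "length",
          "unmap_cover", "te_match", "span_reads", "sample_ids")]
}

#' @rdname read_insertion_table
#' @param calls Validated insertion-call data.frame.
#' @export
write_insertion_table <- function(calls, path) {
  write.table(calls[, setdiff(names(calls), "length")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quality-filter insertion calls
#'
#' Keeps calls satisfying all thresholds: `unmap_cover >= min_unmap_cover`,
#' `te_match >= min_te_match`, `span_reads >= min_span_reads`, `length >
#' min_length` (strict, so a 1,000-bp call fails the default 1-kbp cut) and,
#' when `allowed_subfamilies` is non-empty, subfamily membership. Input
#' order is preserved; an empty result is valid.
#'
#' @param calls data.frame from [read_insertion_table()].
#' @param thresholds List from [insertion_thresholds()].
#' @return The surviving subset of `calls`.
#' @export
filter_insertions <- function(calls, thresholds = insertion_thresholds()) {
  keep <- calls$unmap_cover >= thresholds$min_unmap_cover &
    calls$te_match >= thresholds$min_te_match &
    calls$span_reads >= thresholds$min_span_reads &
    calls$length > thresholds$min_length
  if (length(thresholds$allowed_subfamilies)) {
    keep <- keep & calls$subfamily %in% thresholds$allowed_subfamilies
  }
  calls[keep, , drop = FALSE]
}

#' Export insertion calls as BED
#'
#' Writes calls as 0-based half-open BED records with the subfamily in the
#' name field and span-read support as the score.
#'
#' @param calls Insertion-call data.frame.
#' @param path Output path.
#' @export
insertions_to_bed <- function(calls, path) {
  write_bed(data.frame(chrom = calls$chrom, start = calls$start,
                       end = calls$end, name = calls$subfamily,
                       score = calls$span_reads, strand = "."), path)
}

#' Partition insertion events into shared and private sets
#'
#' Calls from different samples are treated as the same insertion event when
#' they lie on the same chromosome, carry the same subfamily label, and
#' their start positions differ by at most `tolerance` bases (single-linkage
#' within a sorted sweep, accommodating long-read breakpoint jitter). Events
#' observed in more than one sample are "shared"; the rest are "private".
#'
#' @param calls_by_sample Named list: sample id -> insertion-call
#'   data.frame.
#' @param tolerance Maximum start-position difference (bases) for two calls
#'   to be merged; default 50.
#' @return A list with data.frames `shared` and `private` (event-level, one
#'   row per event with the member samples collapsed) and `events`, the
#'   per-call table with an `event_id` column covering every call exactly
#'   once.
#' @export
shared_and_private <- function(calls_by_sample, tolerance = 50L) {
  stopifnot(tolerance >= 0)
  if (is.null(names(calls_by_sample))) {
    stop("calls_by_sample must be a named list (sample -> calls)")
  }
  all <- do.call(rbind, lapply(names(calls_by_sample), function(s) {
    df <- calls_by_sample[[s]]
    if (nrow(df) == 0L) return(NULL)
    data.frame(sample = s, chrom = df$chrom, start = df$start,
               subfamily = df$subfamily, stringsAsFactors = FALSE)
  }))
  if (is.null(all)) {
    empty <- data.frame(chrom = character(), start = integer(),
                        subfamily = character(), samples = character(),
                        n_samples = integer())
    return(list(shared = empty, private = empty, events = data.frame()))
  }
  ord <- order(all$chrom, all$subfamily, all$start)
  all <- all[ord, , drop = FALSE]
  grp_key <- paste(all$chrom, all$subfamily)
  event <- integer(nrow(all))
  eid <- 0L
  for (i in seq_len(nrow(all))) {
    new_event <- i == 1L || grp_key[i] != grp_key[i - 1L] ||
      all$start[i] - all$start[i - 1L] > tolerance
    if (new_event) eid <- eid + 1L
    event[i] <- eid
  }
  all$event_id <- event
  ev <- do.call(rbind, lapply(split(all, all$event_id), function(g) {
    data.frame(chrom = g$chrom[1L], start = min(g$start),
               subfamily = g$subfamily[1L],
               samples = paste(sort(unique(g$sample)), collapse = ","),
               n_samples = length(unique(g$sample)),
               stringsAsFactors = FALSE)
  }))
  rownames(ev) <- NULL
  list(shared = ev[ev$n_samples > 1L, , drop = FALSE],
       private = ev[ev$n_samples == 1L, , drop = FALSE],
       events = all)
}
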