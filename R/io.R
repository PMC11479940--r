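#' Read and write FASTA genomes
#'
#' Thin wrappers around Biostrings returning/accepting a named character
#' vector (one element per chromosome), the genome container used throughout
#' the package.
#'
#' @param path File path.
#' @return `read_fasta()` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' @rdname read_fasta
#' @param genome Named character vector of chromosome sequences.
#' @export
write_fasta <- function(genome, path) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read and write BED interval files
#'
#' BED records are held as data frames with 0-based half-open `start`/`end`
#' plus `name`, `score` and `strand` columns. Import/export goes through
#' rtracklayer.
#'
#' @param path File path.
#' @return `read_bed()` returns a data.frame with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else ".",
    score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  df$strand[df$strand == "*"] <- "."
  df
}

#' @rdname read_bed
#' @param bed data.frame as returned by `read_bed()` (`name`, `score`,
#'   `strand` optional).
#' @export
write_bed <- function(bed, path) {
  bed <- as.data.frame(bed)
  n <- nrow(bed)
  out <- data.frame(
    chrom = bed$chrom,
    start = format(bed$start, scientific = FALSE, trim = TRUE),
    end = format(bed$end, scientific = FALSE, trim = TRUE),
    name = if (!is.null(bed$name)) bed$name else rep(".", n),
    score = if (!is.null(bed$score)) bed$score else rep(0, n),
    strand = if (!is.null(bed$strand)) bed$strand else rep(".", n)
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write bedGraph coverage tracks
#'
#' A coverage track is a data.frame of sorted, non-overlapping 0-based
#' half-open intervals with a numeric `value` column.
#'
#' @param path File path.
#' @return `read_bedgraph()` returns a data.frame with columns `chrom`,
#'   `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = as.numeric(gr$score),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_bedgraph
#' @param track data.frame with `chrom`, `start`, `end`, `value`.
#' @export
write_bedgraph <- function(track, path) {
  out <- data.frame(
    chrom = track$chrom,
    start = format(track$start, scientific = FALSE, trim = TRUE),
    end = format(track$end, scientific = FALSE, trim = TRUE),
    value = track$value
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write GTF annotation
#'
#' Annotation records are data frames in GTF convention (1-based inclusive
#' `start`/`end`) with columns `chrom`, `source`, `feature`, `start`, `end`,
#' `score`, `strand`, `frame`, `attributes` (raw attribute text) plus parsed
#' `gene_id` and `transcript_id` convenience columns on read.
#'
#' @param path File path.
#' @return `read_gtf()` returns a data.frame of annotation records.
#' @export
read_gtf <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE,
                   col.names = c("chrom", "source", "feature", "start", "end",
                                 "score", "strand", "frame", "attributes"))
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$gene_id <- gtf_attr(df$attributes, "gene_id")
  df$transcript_id <- gtf_attr(df$attributes, "transcript_id")
  df
}

gtf_attr <- function(attributes, key) {
  pat <- paste0(key, "[ =]+\"([^\"]*)\"")
  m <- regexec(pat, attributes)
  vapply(regmatches(attributes, m), function(x) {
    if (length(x) == 2L) x[2L] else NA_character_
  }, character(1))
}

#' @rdname read_gtf
#' @param gtf data.frame of annotation records (attribute text in
#'   `attributes`).
#' @export
write_gtf <- function(gtf, path) {
  out <- data.frame(
    chrom = gtf$chrom, source = gtf$source, feature = gtf$feature,
    start = gtf$start, end = gtf$end,
    score = if (!is.null(gtf$score)) gtf$score else ".",
    strand = gtf$strand,
    frame = if (!is.null(gtf$frame)) gtf$frame else ".",
    attributes = gtf$attributes
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read minimal single-end SAM records
#'
#' Parses the subset of SAM needed for alignment filtering: position, flag,
#' CIGAR-derived aligned length, and the `NH` (number of hits) and `NM`
#' (mismatches) tags. Records with missing tags default to `NH=1`, `NM=0`.
#' Unmapped records (flag 0x4) are dropped.
#'
#' @param path Path to a SAM text file.
#' @return data.frame with columns `read_id`, `chrom`, `start` (0-based),
#'   `aligned_length`, `number_of_hits`, `mismatches`, `is_primary`,
#'   `strand`.
#' @export
read_sam_minimal <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(data.frame(read_id = character(), chrom = character(),
                      start = integer(), aligned_length = integer(),
                      number_of_hits = integer(), mismatches = integer(),
                      is_primary = logical(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(fields, function(f) as.integer(f[2L]), integer(1))
  keep <- bitwAnd(flag, 4L) == 0L
  fields <- fields[keep]; flag <- flag[keep]
  tag_int <- function(f, tag, default) {
    hit <- grep(paste0("^", tag, ":i:"), f[-(1:11)], value = TRUE)
    if (length(hit)) as.integer(sub("^..:i:", "", hit[1L])) else default
  }
  data.frame(
    read_id = vapply(fields, `[`, character(1), 1L),
    chrom = vapply(fields, `[`, character(1), 3L),
    start = vapply(fields, function(f) as.integer(f[4L]) - 1L, integer(1)),
    aligned_length = vapply(fields, function(f) cigar_query_length(f[6L]),
                            integer(1)),
    number_of_hits = vapply(fields, tag_int, integer(1), "NH", 1L),
    mismatches = vapply(fields, tag_int, integer(1), "NM", 0L),
    is_primary = bitwAnd(flag, 0x900L) == 0L,
    strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
    stringsAsFactors = FALSE
  )
}

# Query bases consumed by alignment operations (M/=/X/I); soft clips excluded.
cigar_query_length <- function(cigar) {
  if (cigar == "*") return(0L)
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub(".$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  as.integer(sum(len[op %in% c("M", "=", "X", "I")]))
}

#' @rdname read_sam_minimal
#' @param records data.frame of alignment records (as produced by
#'   [read_sam_minimal()] or the simulator) to serialize.
#' @param chrom_lengths Named integer vector for the `@SQ` header lines.
#' @export
write_sam_minimal <- function(records, chrom_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  flag <- ifelse(records$strand == "-", 16L, 0L) +
    ifelse(records$is_primary, 0L, 256L)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*\tNH:i:%d\tNM:i:%d",
                  records$read_id, flag, records$chrom,
                  records$start + 1L, ifelse(records$is_primary, 60L, 0L),
                  records$aligned_length, records$number_of_hits,
                  records$mismatches)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read and write nanopore-style per-read methylation call tables
#'
#' Tab-separated tables with one row per (read, CpG site) call:
#' `chromosome`, `strand`, `start` (0-based CpG position), `read_name`,
#' `log_lik_ratio` (positive favours methylated), `sample`, `condition`.
#'
#' @param path File path.
#' @return `read_methylation_calls()` returns the calls data.frame.
#' @export
read_methylation_calls <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chromosome", "strand", "start", "read_name", "log_lik_ratio")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("methylation call table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  df
}

#' @rdname read_methylation_calls
#' @param calls Calls data.frame.
#' @export
write_methylation_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
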