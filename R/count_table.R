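#' Feature count table with lengths, kinds and sample groups
#'
#' A light S3 container for a features-by-samples matrix of non-negative
#' integer counts, together with per-feature lengths (bases), per-feature
#' kinds (`gene`, `intron`, `exon` or `TE`) and per-sample group labels.
#'
#' @param counts Integer matrix, features in rows, samples in columns; both
#'   dimensions must be named.
#' @param lengths Named numeric vector of feature lengths (bases), one per
#'   row of `counts`.
#' @param kinds Named character vector of feature kinds; defaults to "gene".
#' @param groups Named character vector of per-sample group labels; defaults
#'   to a single group "all".
#' @return An object of class `count_table`.
#' @examples
#' m <- matrix(c(10L, 20L, 30L, 60L), 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' ct <- count_table(m, lengths = c(g1 = 1000, g2 = 2000))
#' tpm(ct)
#' @export
count_table <- function(counts, lengths, kinds = NULL, groups = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have row (feature) and column (sample) names")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  lengths <- lengths[rownames(counts)]
  if (anyNA(lengths) || any(lengths <= 0)) {
    stop("every feature needs a positive length")
  }
  if (is.null(kinds)) {
    kinds <- setNames(rep("gene", nrow(counts)), rownames(counts))
  }
  kinds <- kinds[rownames(counts)]
  if (is.null(groups)) {
    groups <- setNames(rep("all", ncol(counts)), colnames(counts))
  }
  groups <- groups[colnames(counts)]
  structure(list(counts = counts, lengths = lengths,
                 kinds = kinds, groups = groups),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("kinds:", paste(names(table(x$kinds)), table(x$kinds),
                      sep = "=", collapse = " "), "\n")
  cat("groups:", paste(names(table(x$groups)), table(x$groups),
                       sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @rdname count_table
#' @param path File path for the serialized table. The on-disk layout is a
#'   TSV with `feature`, `length`, `kind` columns followed by one count
#'   column per sample; sample groups are recorded in a `#groups:` comment
#'   on the first line.
#' @export
write_count_table <- function(counts, path) {
  stopifnot(inherits(counts, "count_table"))
  hdr <- paste0("#groups: ",
                paste(colnames(counts$counts), counts$groups,
                      sep = "=", collapse = ","))
  df <- data.frame(feature = rownames(counts$counts),
                   length = counts$lengths, kind = counts$kinds,
                   counts$counts, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname count_table
#' @export
read_count_table <- function(path) {
  first <- readLines(path, n = 1L)
  groups <- NULL
  if (startsWith(first, "#groups:")) {
    kv <- strsplit(strsplit(sub("^#groups:\\s*", "", first), ",")[[1]], "=")
    groups <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  }
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("feature", "length", "kind")),
                    drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$feature
  count_table(m, lengths = setNames(df$length, df$feature),
              kinds = setNames(df$kind, df$feature), groups = groups)
}
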