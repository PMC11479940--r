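#' Transcripts-per-million normalization
#'
#' Length-normalized rates `count / (length/1000)` are rescaled per sample
#' to sum to one million. Samples with all-zero counts return all-zero TPM
#' rather than dividing by zero. This is the "approximate TPM" used for
#' per-feature bar plots: the effective length is the annotated feature
#' length, with no fragment-length correction.
#'
#' @param table A [count_table()].
#' @return Numeric matrix of TPM values, same dimensions as the counts.
#' @export
tpm <- function(table) {
  stopifnot(inherits(table, "count_table"))
  rate <- table$counts / (table$lengths / 1000)
  denom <- colSums(rate)
  out <- sweep(rate, 2L, ifelse(denom == 0, 1, denom), "/") * 1e6
  out[, denom == 0] <- 0
  out
}

#' Median-of-ratios size factors
#'
#' The DESeq-style normalization: per feature, the reference is the
#' geometric mean of its counts across samples (features with any zero
#' count are excluded); each sample's size factor is the median across
#' features of `count / reference`.
#'
#' @param table A [count_table()] or a plain counts matrix.
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors_median_ratios <- function(table) {
  counts <- if (inherits(table, "count_table")) table$counts else
    as.matrix(table)
  usable <- rowSums(counts == 0) == 0L
  if (!any(usable)) {
    stop("no feature has nonzero counts in every sample; ",
         "size factors are undefined")
  }
  cu <- counts[usable, , drop = FALSE]
  ref <- exp(rowMeans(log(cu)))  # geometric mean across samples
  apply(cu / ref, 2L, median)
}

#' Intron-retention summary between two sample groups
#'
#' Quantifies retention of a target intron and expression of a downstream
#' exon: per-group mean TPM for both features and the between-group ratios
#' (group b over group a). Direction flags are set when the ratios cross 1
#' in opposite directions (intron up while the downstream exon is down),
#' the signature of retention with reduced downstream expression.
#'
#' @param table A [count_table()] whose `groups` contains both labels.
#' @param intron_id,exon_id Feature ids; both must be present.
#' @param groups Character vector of two group labels `(reference,
#'   perturbed)`, e.g. `c("control", "double_kd")`.
#' @return list with `intron`/`exon` sublists (per-group mean TPM and
#'   `ratio` = perturbed/reference; ratio is `NA` when the reference mean
#'   is 0), and flags `intron_up`, `exon_down`.
#' @export
intron_retention <- function(table, intron_id, exon_id, groups) {
  stopifnot(inherits(table, "count_table"), length(groups) == 2L)
  for (id in c(intron_id, exon_id)) {
    if (!id %in% rownames(table$counts)) {
      stop("feature '", id, "' is absent from the count table")
    }
  }
  missing_groups <- setdiff(groups, table$groups)
  if (length(missing_groups)) {
    stop("group(s) not present: ", paste(missing_groups, collapse = ", "))
  }
  x <- tpm(table)
  summarize <- function(id) {
    m <- vapply(groups, function(g) {
      mean(x[id, table$groups == g])
    }, numeric(1))
    ratio <- if (m[1L] == 0) NA_real_ else unname(m[2L] / m[1L])
    list(mean_reference = unname(m[1L]), mean_perturbed = unname(m[2L]),
         ratio = ratio)
  }
  intron <- summarize(intron_id)
  exon <- summarize(exon_id)
  both_defined <- !is.na(intron$ratio) && !is.na(exon$ratio)
  list(intron = intron, exon = exon,
       intron_up = both_defined && intron$ratio > 1 && exon$ratio < 1,
       exon_down = both_defined && exon$ratio < 1 && intron$ratio > 1)
}

#' Link elements to nearby gene TSSs
#'
#' Emits one link per (element, gene) pair whose distance from the nearest
#' element edge to the gene's TSS lies within `[min_distance,
#' max_distance]` -- the window used to ask whether an element exerts
#' cis-regulatory effects on neighbouring promoters. The TSS is the gene
#' start on the + strand and the gene end on the - strand; a TSS inside
#' the element has distance 0.
#'
#' @param elements BED data.frame (`chrom`, `start`, `end`, `name`,
#'   `strand`).
#' @param annotation GTF data.frame; rows with `feature == "gene"` are
#'   used.
#' @param min_distance,max_distance Distance window in bases (default
#'   2,000-50,000).
#' @return data.frame sorted by distance with columns `element_id`,
#'   `gene_id`, `distance`, `side` (`upstream`/`downstream` of the TSS in
#'   gene orientation; `inside` for distance 0), `same_strand`.
#' @export
link_elements_to_genes <- function(elements, annotation,
                                   min_distance = 2000L,
                                   max_distance = 50000L) {
  stopifnot(min_distance <= max_distance)
  genes <- annotation[annotation$feature == "gene", , drop = FALSE]
  if (is.null(genes$gene_id)) genes$gene_id <- gtf_attr(genes$attributes,
                                                        "gene_id")
  if (nrow(genes) == 0L || nrow(elements) == 0L) {
    return(data.frame(element_id = character(), gene_id = character(),
                      distance = numeric(), side = character(),
                      same_strand = logical(), stringsAsFactors = FALSE))
  }
  # TSS as 0-based position: gene start (+) or gene end (-)
  tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start - 1L)
  rows <- list()
  for (i in seq_len(nrow(elements))) {
    on_chrom <- genes$chrom == elements$chrom[i]
    if (!any(on_chrom)) next
    g <- genes[on_chrom, , drop = FALSE]
    gt <- tss[on_chrom]
    d <- ifelse(gt < elements$start[i], elements$start[i] - gt,
                ifelse(gt >= elements$end[i],
                       gt - (elements$end[i] - 1L), 0L))
    keep <- d >= min_distance & d <= max_distance
    if (!any(keep)) next
    # side of the element relative to the TSS, in gene orientation
    elem_left <- (elements$end[i] - 1L) < gt[keep]
    side <- ifelse(d[keep] == 0L, "inside",
                   ifelse(xor(elem_left, g$strand[keep] == "-"),
                          "upstream", "downstream"))
    rows[[length(rows) + 1L]] <- data.frame(
      element_id = elements$name[i], gene_id = g$gene_id[keep],
      distance = d[keep], side = side,
      same_strand = elements$strand[i] == g$strand[keep],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(element_id = character(), gene_id = character(),
               distance = numeric(), side = character(),
               same_strand = logical(), stringsAsFactors = FALSE)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Contiguous covered extent on one strand track walking outward from
# `boundary` in direction `dir` (+1 rightward, -1 leftward); gaps of up to
# max_gap uncovered bases are bridged.
.covered_extent <- function(track, chrom, boundary, dir, min_coverage,
                            max_gap) {
  tc <- track[track$chrom == chrom & track$value >= min_coverage, ,
              drop = FALSE]
  if (nrow(tc) == 0L) return(0)
  if (dir > 0) {
    tc <- tc[tc$end > boundary, , drop = FALSE]
    tc <- tc[order(tc$start), , drop = FALSE]
    pos <- boundary
    for (r in seq_len(nrow(tc))) {
      if (tc$start[r] - pos > max_gap) break
      pos <- max(pos, tc$end[r])
    }
    pos - boundary
  } else {
    tc <- tc[tc$start < boundary, , drop = FALSE]
    tc <- tc[order(-tc$end), , drop = FALSE]
    pos <- boundary
    for (r in seq_len(nrow(tc))) {
      if (pos - tc$end[r] > max_gap) break
      pos <- min(pos, tc$start[r])
    }
    boundary - pos
  }
}

#' Detect readthrough transcription beyond an element
#'
#' Measures, on each strand, the contiguous transcribed extent starting at
#' the element boundary and continuing outward (+ strand rightward from
#' the element end, - strand leftward from the element start), bridging
#' uncovered gaps of at most `max_gap` bases. The longer extent is
#' reported and labelled `antisense` when its strand is opposite to the
#' overlapped (or nearest) gene's strand -- the signature of an element
#' driving an antisense readthrough transcript into a neighbouring gene.
#'
#' @param track_plus,track_minus Stranded coverage tracks (`chrom`,
#'   `start`, `end`, `value`).
#' @param element One-row BED data.frame.
#' @param annotation GTF data.frame (rows with `feature == "gene"` are
#'   consulted for direction labelling).
#' @param min_coverage Minimum track value counting as transcribed;
#'   default 1.
#' @param max_gap Maximum bridged gap in bases; default 200.
#' @return list with `element_id`, `direction` (`sense`/`antisense`),
#'   `strand` (of the readthrough), `extent` (bases), `mean_coverage`
#'   over the extent, and `gene_id` of the reference gene (`NA` when no
#'   gene is on the chromosome, in which case direction is `sense`).
#' @export
detect_readthrough <- function(track_plus, track_minus, element, annotation,
                               min_coverage = 1, max_gap = 200L) {
  stopifnot(nrow(element) == 1L)
  ext_plus <- .covered_extent(track_plus, element$chrom, element$end, +1,
                              min_coverage, max_gap)
  ext_minus <- .covered_extent(track_minus, element$chrom, element$start,
                               -1, min_coverage, max_gap)
  if (ext_plus >= ext_minus) {
    strand <- "+"; extent <- ext_plus
    span <- c(element$end, element$end + ext_plus)
    track <- track_plus
  } else {
    strand <- "-"; extent <- ext_minus
    span <- c(element$start - ext_minus, element$start)
    track <- track_minus
  }
  mean_cov <- if (extent > 0) {
    tc <- track[track$chrom == element$chrom, , drop = FALSE]
    .track_mean(tc$start, tc$end, tc$value, span[1L], span[2L])
  } else 0
  genes <- annotation[annotation$feature == "gene" &
                        annotation$chrom == element$chrom, , drop = FALSE]
  if (is.null(genes$gene_id)) genes$gene_id <- gtf_attr(genes$attributes,
                                                        "gene_id")
  gene_id <- NA_character_
  direction <- "sense"
  if (nrow(genes) > 0L) {
    mid <- (element$start + element$end) / 2
    overlap <- genes$start - 1L <= element$end & genes$end >= element$start
    pick <- if (any(overlap)) which(overlap)[1L] else
      which.min(pmin(abs(genes$start - 1L - mid), abs(genes$end - mid)))
    gene_id <- genes$gene_id[pick]
    direction <- if (strand == genes$strand[pick]) "sense" else "antisense"
  }
  list(element_id = if (!is.null(element$name)) element$name else
         sprintf("%s:%d-%d", element$chrom, element$start, element$end),
       direction = direction, strand = strand, extent = extent,
       mean_coverage = mean_cov, gene_id = gene_id)
}
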