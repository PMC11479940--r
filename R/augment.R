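#' Coordinate map between a reference and its insertion-augmented genome
#'
#' A `coord_map` records, per chromosome, the sorted insertion breakpoints
#' (0-based insert-before reference positions), each inserted length, and
#' the cumulative offset accumulated *after* each insertion. It makes the
#' splice performed by [augment_genome()] exactly reversible.
#'
#' @param plan data.frame with columns `chrom`, `position` (0-based
#'   insert-before point), `length` (or `sequence`, from which lengths are
#'   taken) and `label`.
#' @param chrom_lengths Optional named vector of reference chromosome
#'   lengths used to validate positions and support length arithmetic
#'   without sequences.
#' @return A `coord_map`: data.frame with columns `chrom`,
#'   `ref_breakpoint`, `ins_length`, `cum_offset`, `label`, sorted by
#'   chromosome and breakpoint, with `chrom_lengths` attached as an
#'   attribute when supplied.
#' @export
coord_map <- function(plan, chrom_lengths = NULL) {
  if (is.null(plan$length)) plan$length <- nchar(plan$sequence)
  if (is.null(plan$label)) {
    plan$label <- sprintf("ins_%s_%d", plan$chrom, plan$position)
  }
  m <- data.frame(chrom = as.character(plan$chrom),
                  ref_breakpoint = as.numeric(plan$position),
                  ins_length = as.numeric(plan$length),
                  label = as.character(plan$label),
                  stringsAsFactors = FALSE)
  m <- m[order(m$chrom, m$ref_breakpoint), , drop = FALSE]
  dup <- duplicated(m[, c("chrom", "ref_breakpoint")])
  if (any(dup)) {
    stop("conflicting insertions at the same position: ",
         paste(m$label[dup], collapse = ", "))
  }
  if (!is.null(chrom_lengths)) {
    bad <- m$ref_breakpoint < 0 |
      m$ref_breakpoint > chrom_lengths[m$chrom] |
      is.na(chrom_lengths[m$chrom])
    if (any(bad)) {
      stop("insertion out of chromosome bounds: ",
           paste(m$label[bad], collapse = ", "))
    }
  }
  m$cum_offset <- stats::ave(m$ins_length, m$chrom, FUN = cumsum)
  rownames(m) <- NULL
  structure(m[, c("chrom", "ref_breakpoint", "ins_length", "cum_offset",
                  "label")],
            chrom_lengths = chrom_lengths,
            class = c("coord_map", "data.frame"))
}

#' @rdname coord_map
#' @param map A `coord_map`.
#' @export
augmented_seqlengths <- function(map, chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) chrom_lengths <- attr(map, "chrom_lengths")
  if (is.null(chrom_lengths)) stop("chromosome lengths are required")
  added <- tapply(map$ins_length, map$chrom, sum)
  out <- chrom_lengths
  out[names(added)] <- out[names(added)] + added
  out
}

#' Serialize and load coordinate maps
#'
#' The on-disk form is a chain-like tab-separated file with one row per
#' insertion: chromosome, reference breakpoint, cumulative offset, inserted
#' length, label.
#'
#' @param map A `coord_map`.
#' @param path File path.
#' @export
write_coord_map <- function(map, path) {
  write.table(map[, c("chrom", "ref_breakpoint", "cum_offset", "ins_length",
                      "label")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coord_map
#' @export
read_coord_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  coord_map(data.frame(chrom = df$chrom, position = df$ref_breakpoint,
                       length = df$ins_length, label = df$label))
}

#' Build an insertion-augmented genome
#'
#' Splices each planned insertion into its chromosome before the stated
#' 0-based position. Insertions are applied from the end of each chromosome
#' towards its start, so earlier positions are unaffected by later splices;
#' the result is identical to any application order with recomputed
#' offsets. Inserted length is conserved exactly:
#' `nchar(augmented) == nchar(reference) + sum(inserted lengths)` per
#' chromosome.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param plan data.frame with `chrom`, `position` (0-based insert-before
#'   point), `sequence` and optional `label` columns. Two insertions at one
#'   (chromosome, position) are rejected.
#' @return list with `genome` (augmented sequences) and `map` (the
#'   [coord_map()] describing every splice).
#' @examples
#' res <- augment_genome(c(chr1 = "ACGTACGTAC"),
#'                       data.frame(chrom = "chr1", position = 5,
#'                                  sequence = "TTT", label = "demo"))
#' res$genome  # "ACGTATTTCGTAC"
#' @export
augment_genome <- function(genome, plan) {
  chrom_lengths <- setNames(nchar(genome), names(genome))
  if (nrow(plan) == 0L) {
    return(list(genome = genome,
                map = coord_map(data.frame(chrom = character(),
                                           position = numeric(),
                                           length = numeric(),
                                           label = character()),
                                chrom_lengths = chrom_lengths)))
  }
  missing_chrom <- setdiff(unique(plan$chrom), names(genome))
  if (length(missing_chrom)) {
    stop("plan references unknown chromosome(s): ",
         paste(missing_chrom, collapse = ", "))
  }
  map <- coord_map(plan, chrom_lengths = chrom_lengths)
  out <- genome
  for (chrom in unique(map$chrom)) {
    mc <- map[map$chrom == chrom, , drop = FALSE]
    seqs <- if (!is.null(plan$sequence)) {
      ord <- order(plan$chrom, plan$position)
      plan$sequence[ord][plan$chrom[ord] == chrom]
    } else {
      stop("plan must carry insertion sequences to augment a genome")
    }
    # split the chromosome at all breakpoints, then interleave inserts;
    # one paste0 avoids the per-insertion rewrite of the naive approach
    s <- genome[[chrom]]
    cuts <- c(0, mc$ref_breakpoint, nchar(s))
    pieces <- substring(s, head(cuts, -1L) + 1L, tail(cuts, -1L))
    interleaved <- character(2L * length(seqs) + 1L)
    interleaved[seq(1L, by = 2L, length.out = length(pieces))] <- pieces
    interleaved[seq(2L, by = 2L, length.out = length(seqs))] <- seqs
    out[[chrom]] <- paste0(interleaved, collapse = "")
  }
  list(genome = out, map = map)
}

#' Stitch an insert into a chromosome at a 1-based breakpoint
#'
#' Concatenates `genome[chrom][1..breakpoint]`, the insert, and
#' `genome[chrom][(breakpoint+1)..end]` -- the three-segment splice used to
#' place an SVA consensus into chrX at the base after which the element
#' integrated. Equivalent to [augment_genome()] with a single insertion at
#' 0-based position `breakpoint`.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param chrom Chromosome name.
#' @param breakpoint 1-based position of the last base of the left segment;
#'   must satisfy `1 <= breakpoint < nchar(chromosome)`.
#' @param insert Sequence to stitch in (may be empty).
#' @param label Label recorded in the coordinate map.
#' @return list with `genome` and `map`, as for [augment_genome()].
#' @export
stitch_at_breakpoint <- function(genome, chrom, breakpoint, insert,
                                 label = "stitched_insert") {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  L <- nchar(genome[[chrom]])
  if (breakpoint < 1 || breakpoint >= L) {
    stop(sprintf("breakpoint %d out of range [1, %d)", breakpoint, L))
  }
  augment_genome(genome, data.frame(chrom = chrom, position = breakpoint,
                                    sequence = insert, label = label,
                                    stringsAsFactors = FALSE))
}

# Offset accumulated strictly before 0-based reference position pos:
# sum of lengths of insertions with ref_breakpoint < pos (vectorized).
.offset_before <- function(map, chrom, pos) {
  mc <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(mc) == 0L) return(rep(0, length(pos)))
  idx <- findInterval(pos, mc$ref_breakpoint, left.open = TRUE)
  c(0, mc$cum_offset)[idx + 1L]
}

#' Lift a reference position into augmented coordinates
#'
#' @param map A [coord_map()].
#' @param chrom Chromosome name.
#' @param position 0-based reference position(s), vectorized.
#' @return Augmented 0-based position(s): `position + ` total length of
#'   insertions at breakpoints `<= position` (an insertion *at* the queried
#'   position is placed before it, so the original base shifts right).
#' @export
lift_position <- function(map, chrom, position) {
  mc <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(mc) == 0L) return(position)
  idx <- findInterval(position, mc$ref_breakpoint)  # breakpoints <= position
  position + c(0, mc$cum_offset)[idx + 1L]
}

#' Project an augmented-genome position back to the reference
#'
#' The inverse of the splice: positions outside inserted segments map to a
#' unique reference coordinate; positions inside an inserted segment map to
#' the insertion point, flagged `inside_insertion` with the insertion's
#' label.
#'
#' @param map A [coord_map()].
#' @param chrom Chromosome name.
#' @param position 0-based augmented position(s), vectorized.
#' @return data.frame with columns `position` (reference 0-based), `status`
#'   (`unique` or `inside_insertion`) and `label` (insertion label or NA).
#' @export
project_to_reference <- function(map, chrom, position) {
  if (any(position < 0)) stop("position out of range")
  cl <- attr(map, "chrom_lengths")
  if (!is.null(cl) && chrom %in% names(cl)) {
    aug_len <- augmented_seqlengths(map)[chrom]
    if (any(position >= aug_len)) {
      stop("position beyond augmented chromosome end")
    }
  }
  mc <- map[map$chrom == chrom, , drop = FALSE]
  out <- data.frame(position = as.numeric(position),
                    status = rep("unique", length(position)),
                    label = rep(NA_character_, length(position)),
                    stringsAsFactors = FALSE)
  if (nrow(mc) == 0L) return(out)
  ins_start <- mc$ref_breakpoint + c(0, head(mc$cum_offset, -1L))
  ins_end <- ins_start + mc$ins_length  # augmented span of each insertion
  for (k in seq_len(nrow(mc))) {
    inside <- position >= ins_start[k] & position < ins_end[k]
    out$position[inside] <- mc$ref_breakpoint[k]
    out$status[inside] <- "inside_insertion"
    out$label[inside] <- mc$label[k]
  }
  after <- findInterval(position, ins_end)  # insertions fully left of pos
  uniq <- out$status == "unique"
  out$position[uniq] <- position[uniq] -
    c(0, mc$cum_offset)[after[uniq] + 1L]
  out
}

#' Lift annotation records onto the insertion-augmented genome
#'
#' Features wholly upstream of every insertion are unchanged; features
#' wholly downstream of k inserted bases shift by k; features whose
#' interval contains an insertion point keep their (shifted) start and gain
#' the internal insertion's length in their end, so the insertion lies
#' inside the lifted feature (an intronic insertion stretches the intron,
#' it never splits it).
#'
#' @param records GTF-convention data.frame (1-based inclusive `start`,
#'   `end`; see [read_gtf()]).
#' @param map A [coord_map()].
#' @return The lifted records, same shape as the input. Records on
#'   chromosomes absent from the map pass through unchanged with one
#'   warning.
#' @export
lift_annotation <- function(records, map) {
  out <- records
  mapped <- unique(map$chrom)
  off_chrom <- setdiff(unique(records$chrom), mapped)
  # an empty map legitimately leaves everything untouched
  if (length(off_chrom) && nrow(map) > 0L) {
    warning("no insertions mapped on chromosome(s): ",
            paste(off_chrom, collapse = ", "),
            "; records passed through unchanged")
  }
  for (chrom in intersect(mapped, unique(records$chrom))) {
    i <- which(records$chrom == chrom)
    s1 <- records$start[i]
    e1 <- records$end[i]
    # 1-based feature [s1, e1]; 0-based insert-before p shifts the start
    # iff p < s1 and the end iff p < e1 (p in [s1-1, e1-1] is internal)
    out$start[i] <- s1 + .offset_before(map, chrom, s1)
    out$end[i] <- e1 + .offset_before(map, chrom, e1)
  }
  out
}
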