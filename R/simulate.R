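# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Uniform integer draw from an inclusive (min, max) range; immune to the
# sample()-on-a-scalar expansion when min == max.
.pick_int <- function(rng) {
  if (rng[1L] == rng[2L]) return(rng[1L])
  sample(seq(rng[1L], rng[2L]), 1L)
}

.rand_bases <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulation configuration for the synthetic truth-set generator
#'
#' Parameters describing the synthetic study system: a small
#' multi-chromosome genome carrying planted SVA-like elements (a (CCCTCT)n
#' hexamer head followed by a GC-rich VNTR-like body), a truth set of
#' non-reference insertions with TLDR-style quality fields,
#' boundary-enriched repressive-mark coverage with spike-in read counts,
#' per-CpG methylation calls under a methylated control versus a
#' demethylated knockdown, and count tables with a planted
#' intron-retention effect.
#'
#' @param seed Integer RNG seed; identical configurations reproduce
#'   byte-identical outputs.
#' @param n_chromosomes,chrom_length Genome shape; `chrom_length` must
#'   exceed the maximum element length plus twice the 10-kbp profiling
#'   flank.
#' @param n_fixed_elements Elements planted in the reference (total across
#'   chromosomes).
#' @param n_polymorphic_insertions Non-reference insertion events in the
#'   truth set (at least one per chromosome lands inside a gene's intron).
#' @param element_length_range Min/max element length in bases (> 1000, so
#'   every planted element passes the 1-kbp analysis cutoff).
#' @param hexamer_copies_range Min/max (CCCTCT) copies in the element head.
#' @param vntr_gc_fraction P(G or C) per body base; SVA bodies are GC-rich.
#' @param boundary_enrichment Fold-change of boundary windows over genomic
#'   background in the repressive-mark track (>= 1).
#' @param methylation_high,methylation_low Per-call methylation
#'   probabilities for methylated and demethylated elements.
#' @param noise_rate Uniform substitution rate used for simulated read
#'   mismatches, in [0, 0.2].
#' @param spikein_reads Aligned spike-in read count to report.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 3L, chrom_length = 100000L,
                       n_fixed_elements = 6L, n_polymorphic_insertions = 6L,
                       element_length_range = c(1500L, 3000L),
                       hexamer_copies_range = c(30L, 50L),
                       vntr_gc_fraction = 0.7, boundary_enrichment = 5,
                       methylation_high = 0.9, methylation_low = 0.1,
                       noise_rate = 0.02, spikein_reads = 10000L) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              n_fixed_elements = as.integer(n_fixed_elements),
              n_polymorphic_insertions = as.integer(n_polymorphic_insertions),
              element_length_range = as.integer(element_length_range),
              hexamer_copies_range = as.integer(hexamer_copies_range),
              vntr_gc_fraction = vntr_gc_fraction,
              boundary_enrichment = boundary_enrichment,
              methylation_high = methylation_high,
              methylation_low = methylation_low,
              noise_rate = noise_rate,
              spikein_reads = as.integer(spikein_reads))
  frac <- c(cfg$vntr_gc_fraction, cfg$methylation_high, cfg$methylation_low)
  if (any(frac < 0 | frac > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$noise_rate < 0 || cfg$noise_rate > 0.2) {
    stop("noise_rate must lie in [0, 0.2]")
  }
  if (cfg$boundary_enrichment < 1) stop("boundary_enrichment must be >= 1")
  if (length(cfg$element_length_range) != 2L ||
      cfg$element_length_range[1L] <= 1000L ||
      diff(cfg$element_length_range) < 0L) {
    stop("element_length_range must be (min, max) with min > 1000")
  }
  if (6L * cfg$hexamer_copies_range[2L] + 100L > cfg$element_length_range[1L]) {
    stop("hexamer head cannot exceed the minimum element length")
  }
  if (cfg$chrom_length <= cfg$element_length_range[2L] + 2L * 10000L) {
    stop("chrom_length must exceed max element length + 2 x 10 kbp flank")
  }
  if (cfg$n_chromosomes < 1L) stop("need at least one chromosome")
  structure(cfg, class = c("sim_config", "list"))
}

# One SVA-like element sequence (5'->3'): (CCCTCT)^copies head, a short
# A-rich spacer (mirroring the non-repetitive junction before the Alu-like
# region, and pinning the hexamer run to exactly the planted copy number),
# then a GC-rich body with 20 CG dyads forced at evenly spaced offsets so
# every element has enough CpG sites for methylation aggregation.
.element_sequence <- function(total_length, copies, gc) {
  head_seq <- strrep("CCCTCT", copies)
  body_len <- total_length - nchar(head_seq)
  body <- strsplit(.rand_bases(body_len, gc), "")[[1]]
  body[1:6] <- c("A", "A", "A", "T", "A", "A")
  at <- as.integer(seq(8L, body_len - 1L, length.out = 20L))
  body[at] <- "C"
  body[at + 1L] <- "G"
  paste0(head_seq, paste(body, collapse = ""))
}

#' Simulate a genome with planted SVA-like elements and annotation
#'
#' Generates `n_chromosomes` random chromosomes; plants fixed elements
#' (present in the reference) at evenly spaced, flank-clear positions with
#' alternating strands; draws a truth set of non-reference polymorphic
#' insertions with TLDR-style quality fields (a deterministic mix of calls
#' passing and failing the default filters, with at least one passing call
#' placed inside a gene intron per chromosome); and writes a multi-exon
#' gene annotation per chromosome, plus one extra gene with its TSS 2-50
#' kbp from an element for cis-linkage analysis.
#'
#' @param config A [sim_config()].
#' @return list with `genome` (named character vector), `elements` (BED
#'   data.frame with planted hexamer copies in the truth), `annotation`
#'   (GTF data.frame) and `truth` (planted insertions, per-element hexamer
#'   copies and sequences, enriched/demethylated element ids, nearby-gene
#'   table and the designated readthrough element).
#' @export
simulate_genome_with_elements <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    genome <- setNames(vapply(chroms, function(ch) {
      .rand_bases(config$chrom_length, 0.4)
    }, character(1)), chroms)

    # fixed elements: round-robin over chromosomes, evenly spaced slots
    n_el <- config$n_fixed_elements
    margin <- 10000L + 2000L
    el <- NULL
    truth_elements <- NULL
    if (n_el > 0L) {
      chrom_of <- chroms[(seq_len(n_el) - 1L) %% length(chroms) + 1L]
      per_chrom <- table(factor(chrom_of, levels = chroms))
      rows <- list()
      for (ch in chroms) {
        k <- per_chrom[[ch]]
        if (k == 0L) next
        # keep the last 16 kbp before the end margin element-free: the
        # multi-exon host gene lives there
        usable <- config$chrom_length - 2L * margin - 16000L
        slot <- usable %/% max(k, 1L)
        if (slot < config$element_length_range[2L] + 13000L) {
          stop("chromosome too short for ", k, " elements with clear ",
               "10-kbp flanks between neighbours")
        }
        for (i in seq_len(k)) {
          len <- .pick_int(config$element_length_range)
          copies <- .pick_int(config$hexamer_copies_range)
          # jitter bounded so consecutive elements stay >= 12 kbp apart:
          # a distal profiling flank must never touch a neighbour's
          # enriched boundary window
          start <- margin + (i - 1L) * slot +
            sample.int(max(slot - len - 12000L, 1L), 1L)
          strand <- if ((length(rows) %% 2L) == 0L) "+" else "-"
          seq5p <- .element_sequence(len, copies, config$vntr_gc_fraction)
          placed <- if (strand == "+") seq5p else revcomp(seq5p)
          substr(genome[[ch]], start + 1L, start + len) <- placed
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = ch, start = start, end = start + len,
            name = sprintf("sva_%02d", length(rows) + 1L), score = 0,
            strand = strand, hexamer_copies = copies,
            sequence_5p = seq5p, genomic_sequence = placed,
            stringsAsFactors = FALSE)
        }
      }
      truth_elements <- do.call(rbind, rows)
      el <- truth_elements[, c("chrom", "start", "end", "name", "score",
                               "strand")]
    } else {
      el <- data.frame(chrom = character(), start = integer(),
                       end = integer(), name = character(),
                       score = numeric(), strand = character(),
                       stringsAsFactors = FALSE)
    }

    # one multi-exon host gene per chromosome in the element-free tail;
    # insertions will land inside its first intron
    gene_rows <- list()
    nearby_rows <- list()
    host <- list()
    for (ci in seq_along(chroms)) {
      ch <- chroms[ci]
      g_start0 <- config$chrom_length - margin - 8000L
      g_end0 <- g_start0 + 6000L
      gid <- sprintf("gene_host_%s", ch)
      exon_bounds <- list(c(g_start0, g_start0 + 500L),
                          c(g_start0 + 2500L, g_start0 + 3000L),
                          c(g_end0 - 500L, g_end0))
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        chrom = ch, source = "polySVA_sim",
        feature = c("gene", "exon", "exon", "exon"),
        start = c(g_start0, vapply(exon_bounds, `[`, 0, 1L)) + 1L,
        end = c(g_end0, vapply(exon_bounds, `[`, 0, 2L)),
        score = ".", strand = "+", frame = ".",
        attributes = sprintf("gene_id \"%s\"; transcript_id \"%s.1\";",
                             gid, gid),
        stringsAsFactors = FALSE)
      host[[ch]] <- list(gene_id = gid,
                         intron0 = c(g_start0 + 500L, g_start0 + 2500L))
      # nearby gene: TSS ~10 kbp downstream of the first element on ch
      el_ch <- el[el$chrom == ch, , drop = FALSE]
      if (nrow(el_ch)) {
        tss0 <- el_ch$end[1L] + 10000L
        ngid <- sprintf("gene_near_%s", ch)
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          chrom = ch, source = "polySVA_sim",
          feature = c("gene", "exon", "exon"),
          start = c(tss0, tss0, tss0 + 2000L) + 1L,
          end = c(tss0 + 3000L, tss0 + 400L, tss0 + 3000L),
          score = ".", strand = "+", frame = ".",
          attributes = sprintf("gene_id \"%s\"; transcript_id \"%s.1\";",
                               ngid, ngid),
          stringsAsFactors = FALSE)
        nearby_rows[[length(nearby_rows) + 1L]] <- data.frame(
          gene_id = ngid, chrom = ch, start0 = tss0, end0 = tss0 + 3000L,
          strand = "+", linked_element = el_ch$name[1L],
          stringsAsFactors = FALSE)
      }
    }
    annotation <- do.call(rbind, gene_rows)
    nearby_genes <- if (length(nearby_rows)) do.call(rbind, nearby_rows) else
      data.frame()

    # polymorphic (non-reference) insertions with TLDR-style quality fields:
    # ~60% pass the default filters; the rest each break one criterion
    n_ins <- config$n_polymorphic_insertions
    ins <- NULL
    if (n_ins > 0L) {
      n_pass <- max(1L, ceiling(0.6 * n_ins))
      subfams <- paste0("SVA_", c("A", "B", "C", "D", "E", "F"))
      rows <- list()
      for (i in seq_len(n_ins)) {
        ch <- chroms[(i - 1L) %% length(chroms) + 1L]
        len <- .pick_int(config$element_length_range)
        copies <- .pick_int(config$hexamer_copies_range)
        consensus <- .element_sequence(len, copies, config$vntr_gc_fraction)
        passes <- i <= n_pass
        if (i <= length(chroms)) {
          # inside the host gene's first intron
          pos <- sample(seq(host[[ch]]$intron0[1L] + 100L,
                            host[[ch]]$intron0[2L] - 100L), 1L)
        } else {
          pos <- sample(seq(margin, config$chrom_length - margin), 1L)
        }
        unmap <- runif(1L, 0.85, 0.99)
        tem <- runif(1L, 0.85, 0.99)
        span <- sample(3:10, 1L)
        if (!passes) {
          fail_mode <- (i %% 3L) + 1L
          if (fail_mode == 1L) unmap <- runif(1L, 0.5, 0.79)
          if (fail_mode == 2L) tem <- runif(1L, 0.5, 0.79)
          if (fail_mode == 3L) span <- sample(1:2, 1L)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("ins_%02d", i), chrom = ch, start = pos, end = pos,
          subfamily = sample(subfams, 1L), consensus = consensus,
          length = nchar(consensus), unmap_cover = unmap, te_match = tem,
          span_reads = span, passes_filter = passes,
          hexamer_copies = copies, stringsAsFactors = FALSE)
      }
      ins <- do.call(rbind, rows)
    } else {
      ins <- data.frame(id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        subfamily = character(), consensus = character(),
                        length = integer(), unmap_cover = numeric(),
                        te_match = numeric(), span_reads = integer(),
                        passes_filter = logical(),
                        hexamer_copies = integer(), stringsAsFactors = FALSE)
    }

    # epigenetic truth: ~2/3 of elements boundary-enriched, half of those
    # demethylated in the knockdown; readthrough from the first element
    # with a nearby (+) gene, antisense on the minus strand
    enriched <- if (nrow(el)) {
      el$name[seq_len(max(1L, ceiling(2 / 3 * nrow(el))))]
    } else character()
    demeth <- if (nrow(el)) {
      el$name[seq(1L, nrow(el), by = 2L)]
    } else character()
    readthrough <- NULL
    if (nrow(nearby_genes) && nrow(el)) {
      rt_el <- nearby_genes$linked_element[1L]
      readthrough <- list(element_id = rt_el, strand = "-", extent = 2000L,
                          gene_id = nearby_genes$gene_id[1L])
    }
    truth <- list(elements = truth_elements, planted_insertions = ins,
                  enriched_element_ids = enriched,
                  demethylated_element_ids = demeth,
                  nearby_genes = nearby_genes, readthrough = readthrough)
    list(genome = genome, elements = el, annotation = annotation,
         truth = truth)
  })
}

#' Simulate repressive-mark coverage, alignments and spike-in counts
#'
#' Builds a bedGraph-style coverage track in 100-bp windows with a flat
#' genomic background (mild multiplicative noise) and
#' `config$boundary_enrichment`-fold signal over +/- 1 kbp windows at both
#' boundaries of every enriched element; a set of minimal single-end
#' alignment records carrying hit-count and mismatch tags for filter
#' exercises; stranded expression tracks with the planted antisense
#' readthrough; and the aligned spike-in read count (a passthrough of
#' `config$spikein_reads`).
#'
#' @param config A [sim_config()].
#' @param elements BED data.frame from [simulate_genome_with_elements()].
#' @param truth Matching truth list.
#' @return list with `track` (coverage data.frame), `sam` (alignment-record
#'   data.frame), `spikein_aligned`, and stranded `rna_plus` / `rna_minus`
#'   tracks.
#' @export
simulate_signal_and_alignments <- function(config, elements, truth) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed + 1000L, {
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    bin <- 100L
    tracks <- lapply(chroms, function(ch) {
      starts <- seq(0L, config$chrom_length - bin, by = bin)
      value <- exp(rnorm(length(starts), 0, 0.05))
      enr <- elements[elements$chrom == ch &
                        elements$name %in% truth$enriched_element_ids, ,
                      drop = FALSE]
      if (nrow(enr)) {
        # union of all boundary windows, enriched exactly once even where
        # the start and end windows of a short element overlap
        hit <- rep(FALSE, length(starts))
        for (i in seq_len(nrow(enr))) {
          for (b in c(enr$start[i], enr$end[i])) {
            hit <- hit | (starts >= b - 1000L & starts < b + 1000L)
          }
        }
        value[hit] <- value[hit] * config$boundary_enrichment
      }
      data.frame(chrom = ch, start = starts, end = starts + bin,
                 value = value, stringsAsFactors = FALSE)
    })
    track <- do.call(rbind, tracks)

    n_reads <- 200L
    read_len <- 100L
    chrom <- sample(chroms, n_reads, replace = TRUE)
    start <- sample.int(config$chrom_length - read_len, n_reads)
    hits <- sample(c(1L, 2L, 3L), n_reads, replace = TRUE,
                   prob = c(0.85, 0.10, 0.05))
    sam <- data.frame(
      read_id = sprintf("read_%04d", seq_len(n_reads)),
      chrom = chrom, start = start, aligned_length = read_len,
      number_of_hits = hits,
      mismatches = rbinom(n_reads, read_len,
                          pmax(config$noise_rate, 0.015)),
      is_primary = runif(n_reads) > 0.1,
      strand = sample(c("+", "-"), n_reads, replace = TRUE),
      stringsAsFactors = FALSE)

    # stranded expression: sense coverage over nearby genes on (+); the
    # planted readthrough walks leftward from its element start on (-)
    rna_plus <- if (nrow(truth$nearby_genes)) {
      data.frame(chrom = truth$nearby_genes$chrom,
                 start = truth$nearby_genes$start0,
                 end = truth$nearby_genes$end0,
                 value = 3, stringsAsFactors = FALSE)
    } else data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric())
    rna_minus <- data.frame(chrom = character(), start = integer(),
                            end = integer(), value = numeric())
    if (!is.null(truth$readthrough)) {
      rt <- truth$readthrough
      e <- elements[elements$name == rt$element_id, , drop = FALSE]
      rna_minus <- data.frame(chrom = e$chrom,
                              start = e$start - rt$extent, end = e$start,
                              value = 5, stringsAsFactors = FALSE)
    }
    list(track = track, sam = sam,
         spikein_aligned = config$spikein_reads,
         rna_plus = rna_plus, rna_minus = rna_minus)
  })
}

#' Simulate methylation calls and a count table with planted effects
#'
#' Per-CpG, per-read methylation calls for a methylated `control` and a
#' `knockdown` condition in which the truth's demethylated elements drop
#' to `methylation_low` (10 reads per site; log-likelihood ratios drawn
#' with |LLR| >= 2 so binarization is unambiguous), and a features-by-
#' samples count table (host and nearby genes, a background gene set,
#' element TE features, and a target intron/exon pair) with a planted
#' 3-fold intron-retention increase and 0.5-fold downstream-exon decrease
#' in the `double_kd` group.
#'
#' @param config A [sim_config()].
#' @param elements BED data.frame of elements.
#' @param truth Matching truth list (CpG sites are taken from the planted
#'   element sequences).
#' @return list with `calls` (methylation-call data.frame) and `counts`
#'   (a [count_table()]).
#' @export
simulate_methylation_and_counts <- function(config, elements, truth) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed + 2000L, {
    reads_per_site <- 10L
    call_rows <- list()
    for (i in seq_len(nrow(elements))) {
      e <- elements[i, ]
      gseq <- truth$elements$genomic_sequence[truth$elements$name == e$name]
      cpg0 <- e$start +
        as.integer(gregexpr("CG", gseq, fixed = TRUE)[[1]]) - 1L
      cpg0 <- cpg0[cpg0 >= e$start]
      for (cond in c("control", "knockdown")) {
        p <- if (cond == "knockdown" &&
                 e$name %in% truth$demethylated_element_ids) {
          config$methylation_low
        } else config$methylation_high
        n <- length(cpg0) * reads_per_site
        meth <- rbinom(n, 1L, p) == 1L
        llr <- ifelse(meth, 1, -1) * runif(n, 2, 10)
        call_rows[[length(call_rows) + 1L]] <- data.frame(
          chromosome = e$chrom, strand = "+",
          start = rep(cpg0, each = reads_per_site),
          read_name = sprintf("%s_%s_r%03d", e$name, cond,
                              rep(seq_len(reads_per_site),
                                  times = length(cpg0))),
          log_lik_ratio = round(llr, 3L),
          sample = if (cond == "control") "ctrl_1" else "kd_1",
          condition = cond, stringsAsFactors = FALSE)
      }
    }
    calls <- do.call(rbind, call_rows)

    genes <- truth$nearby_genes
    gene_ids <- c(sprintf("gene_host_chr%d", seq_len(config$n_chromosomes)),
                  if (nrow(genes)) genes$gene_id else character())
    bg_ids <- sprintf("gene_bg_%02d", 1:20)
    te_ids <- elements$name
    feature_ids <- c(gene_ids, bg_ids, "target_intron", "target_exon",
                     te_ids)
    lengths <- setNames(c(rep(3000, length(gene_ids)),
                          rep(2000, length(bg_ids)), 2000, 300,
                          if (length(te_ids)) {
                            elements$end - elements$start
                          } else numeric()),
                        feature_ids)
    kinds <- setNames(c(rep("gene", length(gene_ids) + length(bg_ids)),
                        "intron", "exon", rep("TE", length(te_ids))),
                      feature_ids)
    samples <- c(paste0("control_", 1:3), paste0("double_kd_", 1:3))
    groups <- setNames(rep(c("control", "double_kd"), each = 3L), samples)
    base_mu <- setNames(c(rep(300, length(gene_ids)),
                          rep(500, length(bg_ids)), 400, 150,
                          rep(40, length(te_ids))),
                        feature_ids)
    counts <- matrix(0L, length(feature_ids), length(samples),
                     dimnames = list(feature_ids, samples))
    for (s in samples) {
      mu <- base_mu
      if (groups[[s]] == "double_kd") {
        mu["target_intron"] <- mu["target_intron"] * 3
        mu["target_exon"] <- mu["target_exon"] * 0.5
        mu[te_ids] <- mu[te_ids] * 2  # repeat derepression
      }
      counts[, s] <- rpois(length(mu), mu)
    }
    list(calls = calls,
         counts = count_table(counts, lengths = lengths, kinds = kinds,
                              groups = groups))
  })
}

#' Write a complete synthetic fixture directory
#'
#' Runs the three generators and serializes every pipeline input under
#' `dir`: `genome.fa`, `elements.bed`, `annotation.gtf`, `insertions.tsv`
#' (TLDR-style headers), `signal.bedGraph`, `rna_plus.bedGraph`,
#' `rna_minus.bedGraph`, `alignments.sam`, `methylation.tsv`,
#' `counts.tsv` and `truth.json`. Identical configurations produce
#' byte-identical trees.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths plus the in-memory
#'   objects (`genome`, `elements`, `annotation`, `truth`, `signal`,
#'   `methylation`).
#' @export
write_fixture_dir <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- simulate_genome_with_elements(config)
  sig <- simulate_signal_and_alignments(config, gen$elements, gen$truth)
  met <- simulate_methylation_and_counts(config, gen$elements, gen$truth)
  p <- function(f) file.path(dir, f)
  write_fasta(gen$genome, p("genome.fa"))
  write_bed(gen$elements, p("elements.bed"))
  write_gtf(gen$annotation, p("annotation.gtf"))
  ins <- gen$truth$planted_insertions
  tldr <- data.frame(Chrom = ins$chrom, Start = ins$start, End = ins$end,
                     Subfamily = ins$subfamily,
                     UnmapCover = round(ins$unmap_cover * 100, 2L),
                     TEMatch = round(ins$te_match * 100, 2L),
                     SpanReads = ins$span_reads, Consensus = ins$consensus,
                     stringsAsFactors = FALSE)
  write.table(tldr, p("insertions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_bedgraph(sig$track, p("signal.bedGraph"))
  write_bedgraph(sig$rna_plus, p("rna_plus.bedGraph"))
  write_bedgraph(sig$rna_minus, p("rna_minus.bedGraph"))
  chrom_lengths <- setNames(nchar(gen$genome), names(gen$genome))
  write_sam_minimal(sig$sam, chrom_lengths, p("alignments.sam"))
  write_methylation_calls(met$calls, p("methylation.tsv"))
  write_count_table(met$counts, p("counts.tsv"))
  jsonlite::write_json(gen$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(dir = dir, genome = gen$genome, elements = gen$elements,
                 annotation = gen$annotation, truth = gen$truth,
                 signal = sig, methylation = met,
                 paths = setNames(file.path(dir, c(
                   "genome.fa", "elements.bed", "annotation.gtf",
                   "insertions.tsv", "signal.bedGraph", "rna_plus.bedGraph",
                   "rna_minus.bedGraph", "alignments.sam",
                   "methylation.tsv", "counts.tsv", "truth.json")),
                   c("genome", "elements", "annotation", "insertions",
                     "signal", "rna_plus", "rna_minus", "alignments",
                     "methylation", "counts", "truth"))))
}
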