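#' Run the full analysis pipeline on a synthetic fixture
#'
#' End-to-end orchestration over the generated truth set: fixture
#' generation, insertion-call filtering, genome augmentation with
#' annotation liftover, boundary profiling with spike-in scaling,
#' methylation aggregation and group comparison, hexamer copy-number
#' estimation, and expression summaries (TPM, size factors, intron
#' retention, cis links, readthrough). Each stage writes its tabular
#' output under `outdir` together with a JSON summary and a structured
#' log; identical config + seed reproduces identical outputs.
#'
#' @param config A [sim_config()], or a list with elements `sim` (a
#'   `sim_config` or arguments for one) and optional `thresholds`
#'   ([insertion_thresholds()]) and `inputs` (named list of pre-existing
#'   input paths; every named path must exist -- checked before any stage
#'   runs). A path to a JSON file with those fields is also accepted.
#' @param outdir Report directory (created if needed).
#' @return Invisibly, the summary list (also written as
#'   `summary.json`/`report.md` in `outdir`), including per-stage truth
#'   recovery: filtered insertion count versus planted, recovered
#'   enriched/demethylated element ids, hexamer copies versus planted,
#'   intron-retention ratios and the readthrough call.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::fromJSON(config)
  }
  if (inherits(config, "sim_config")) config <- list(sim = config)
  if (!is.null(config$inputs)) {
    missing <- unlist(config$inputs)[!file.exists(unlist(config$inputs))]
    if (length(missing)) {
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
    }
  }
  sim <- if (inherits(config$sim, "sim_config")) config$sim else
    do.call(sim_config, as.list(config$sim))
  thresholds <- if (!is.null(config$thresholds)) {
    do.call(insertion_thresholds, as.list(config$thresholds))
  } else insertion_thresholds()

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  note <- function(stage, msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, msg))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # stage 1: fixture
  fx <- run_stage("fixture", write_fixture_dir(sim, file.path(outdir,
                                                              "fixture")))
  truth <- fx$truth
  note("fixture", sprintf("generated %d chromosomes, %d elements, %d insertions",
                          sim$n_chromosomes, nrow(fx$elements),
                          nrow(truth$planted_insertions)))

  # stage 2: insertion catalog (through the on-disk TLDR-style table)
  calls <- run_stage("catalog", read_insertion_table(fx$paths["insertions"]))
  kept <- run_stage("catalog", filter_insertions(calls, thresholds))
  write_insertion_table(kept, file.path(outdir, "filtered_insertions.tsv"))
  insertions_to_bed(kept, file.path(outdir, "filtered_insertions.bed"))
  note("catalog", sprintf("%d/%d calls pass filters", nrow(kept),
                          nrow(calls)))

  # stage 3: genome augmentation + liftover
  plan <- data.frame(chrom = kept$chrom, position = kept$start,
                     sequence = kept$consensus,
                     label = sprintf("ins_%s_%d", kept$chrom, kept$start),
                     stringsAsFactors = FALSE)
  aug <- run_stage("augment", augment_genome(fx$genome, plan))
  lifted <- run_stage("augment", lift_annotation(fx$annotation, aug$map))
  write_fasta(aug$genome, file.path(outdir, "augmented_genome.fa"))
  write_gtf(lifted, file.path(outdir, "augmented_annotation.gtf"))
  write_coord_map(aug$map, file.path(outdir, "coordinate_map.tsv"))
  note("augment", sprintf("added %d bases over %d insertions",
                          sum(aug$map$ins_length), nrow(aug$map)))

  # stage 4: coverage profiling with spike-in scaling
  track <- read_bedgraph(fx$paths["signal"])
  spike <- run_stage("profile", spikein_scale_factor(fx$signal$spikein_aligned))
  scaled <- scale_track(track, spike$scale_factor)
  chrom_lengths <- setNames(nchar(fx$genome), names(fx$genome))
  mat <- run_stage("profile",
                   scale_regions_matrix(scaled, fx$elements,
                                        chrom_lengths = chrom_lengths))
  ratios <- boundary_enrichment(mat, window = 1000L)
  write_profile_matrix(mat, file.path(outdir, "profile_matrix.tsv"))
  enriched_called <- names(ratios)[!is.na(ratios) &
                                     ratios >= (1 + sim$boundary_enrichment) / 2]
  note("profile", sprintf("%d elements boundary-enriched (factor %.3g/read)",
                          length(enriched_called), spike$scale_factor))

  # stage 5: methylation aggregation and comparison
  raw_calls <- read_methylation_calls(fx$paths["methylation"])
  bin <- run_stage("methylation", binarize_calls(raw_calls))
  by_cond <- split(bin$calls, bin$calls$condition)
  meth_ctrl <- methylation_by_element(by_cond$control, fx$elements)
  meth_kd <- methylation_by_element(by_cond$knockdown, fx$elements)
  cmp <- compare_methylation(meth_ctrl, meth_kd, region = "full")
  write.table(cbind(condition = "control", meth_ctrl),
              file.path(outdir, "methylation_control.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cbind(condition = "knockdown", meth_kd),
              file.path(outdir, "methylation_knockdown.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  midpoint <- (sim$methylation_high + sim$methylation_low) / 2
  demeth_called <- meth_kd$element_id[!is.na(meth_kd$mean_methylation) &
                                        meth_kd$mean_methylation < midpoint]
  note("methylation", sprintf("%d elements demethylated in knockdown",
                              length(demeth_called)))

  # stage 6: hexamer characterization of each planted element (element
  # 5'->3' orientation, three identical pseudo-reads as the alignment)
  hex_rows <- lapply(seq_len(nrow(fx$elements)), function(i) {
    e <- fx$elements[i, ]
    seq5p <- truth$elements$sequence_5p[truth$elements$name == e$name]
    rep_out <- hexamer_report(rep(seq5p, 3L))
    data.frame(element_id = e$name, copies = rep_out$copies,
               planted = truth$elements$hexamer_copies[
                 truth$elements$name == e$name],
               stringsAsFactors = FALSE)
  })
  hexamers <- do.call(rbind, hex_rows)
  write.table(hexamers, file.path(outdir, "hexamer_copies.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  note("repeats", sprintf("%d/%d hexamer copy numbers recovered exactly",
                          sum(hexamers$copies == hexamers$planted),
                          nrow(hexamers)))

  # stage 7: expression
  counts <- read_count_table(fx$paths["counts"])
  tpm_mat <- tpm(counts)
  sfs <- size_factors_median_ratios(counts)
  ir <- run_stage("expression",
                  intron_retention(counts, "target_intron", "target_exon",
                                   c("control", "double_kd")))
  links <- link_elements_to_genes(fx$elements, fx$annotation)
  rna_plus <- read_bedgraph(fx$paths["rna_plus"])
  rna_minus <- if (file.size(fx$paths["rna_minus"]) > 0L) {
    read_bedgraph(fx$paths["rna_minus"])
  } else data.frame(chrom = character(), start = integer(),
                    end = integer(), value = numeric())
  rt_calls <- lapply(seq_len(nrow(fx$elements)), function(i) {
    detect_readthrough(rna_plus, rna_minus, fx$elements[i, , drop = FALSE],
                       fx$annotation)
  })
  rt_df <- do.call(rbind, lapply(rt_calls, function(x) {
    data.frame(element_id = x$element_id, direction = x$direction,
               strand = x$strand, extent = x$extent,
               mean_coverage = x$mean_coverage, gene_id = x$gene_id,
               stringsAsFactors = FALSE)
  }))
  write.table(round(tpm_mat, 4L), file.path(outdir, "tpm.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  write.table(data.frame(sample = names(sfs), size_factor = sfs),
              file.path(outdir, "size_factors.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(links, file.path(outdir, "gene_links.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(rt_df, file.path(outdir, "readthrough.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  note("expression", sprintf("intron ratio %.2f, exon ratio %.2f",
                             ir$intron$ratio, ir$exon$ratio))

  summary <- list(
    seed = sim$seed,
    insertions = list(planted = nrow(truth$planted_insertions),
                      truth_passing = sum(truth$planted_insertions$passes_filter),
                      recovered = nrow(kept)),
    augmentation = list(inserted_bases = sum(aug$map$ins_length),
                        length_conserved = all(
                          nchar(aug$genome) - nchar(fx$genome) ==
                            vapply(names(fx$genome), function(ch) {
                              sum(aug$map$ins_length[aug$map$chrom == ch])
                            }, numeric(1)))),
    boundary = list(truth = truth$enriched_element_ids,
                    called = enriched_called,
                    ratios = as.list(round(ratios, 3L))),
    methylation = list(truth = truth$demethylated_element_ids,
                       called = demeth_called,
                       comparison = cmp[c("mean_a", "mean_b", "difference",
                                          "p_value")]),
    hexamers = list(recovered_exactly = sum(hexamers$copies ==
                                              hexamers$planted),
                    total = nrow(hexamers)),
    expression = list(intron_ratio = ir$intron$ratio,
                      exon_ratio = ir$exon$ratio,
                      intron_up = ir$intron_up, exon_down = ir$exon_down,
                      n_links = nrow(links)),
    readthrough = if (!is.null(truth$readthrough)) {
      called <- rt_df[rt_df$element_id == truth$readthrough$element_id, ]
      list(truth_element = truth$readthrough$element_id,
           truth_extent = truth$readthrough$extent,
           called_extent = called$extent,
           called_direction = called$direction)
    } else NULL)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  writeLines(log_lines, file.path(outdir, "pipeline.log"))
  report <- c("# polySVA pipeline report", "",
              sprintf("- seed: %d", sim$seed),
              sprintf("- insertion calls passing filters: %d of %d planted (truth: %d)",
                      nrow(kept), nrow(truth$planted_insertions),
                      sum(truth$planted_insertions$passes_filter)),
              sprintf("- bases added to the genome: %d",
                      sum(aug$map$ins_length)),
              sprintf("- boundary-enriched elements called: %s",
                      paste(enriched_called, collapse = ", ")),
              sprintf("- demethylated elements called: %s",
                      paste(demeth_called, collapse = ", ")),
              sprintf("- hexamer copies recovered exactly: %d/%d",
                      summary$hexamers$recovered_exactly,
                      summary$hexamers$total),
              sprintf("- intron-retention ratio (double KD / control): %.2f",
                      ir$intron$ratio),
              sprintf("- downstream-exon ratio: %.2f", ir$exon$ratio))
  writeLines(report, file.path(outdir, "report.md"))
  invisible(summary)
}
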