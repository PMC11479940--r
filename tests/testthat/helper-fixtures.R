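# Shared builders for small in-code fixtures.

# A coverage track that is constant over each supplied interval.
toy_track <- function(chrom, starts, ends, values) {
  data.frame(chrom = chrom, start = starts, end = ends, value = values,
             stringsAsFactors = FALSE)
}

# Flat unit-coverage track over [0, len) on one chromosome.
flat_track <- function(chrom = "chr1", len = 50000L, value = 1) {
  toy_track(chrom, 0L, len, value)
}

one_element <- function(chrom = "chr1", start = 20000L, end = 22000L,
                        name = "el1", strand = "+") {
  data.frame(chrom = chrom, start = start, end = end, name = name,
             score = 0, strand = strand, stringsAsFactors = FALSE)
}

# Brute-force per-base mean of a track over [from, to): the oracle for all
# interval-averaging code. Positions without track coverage count as 0.
per_base_mean <- function(track, chrom, from, to) {
  pos <- seq(from, to - 1L)
  vals <- numeric(length(pos))
  tc <- track[track$chrom == chrom, , drop = FALSE]
  for (r in seq_len(nrow(tc))) {
    hit <- pos >= tc$start[r] & pos < tc$end[r]
    vals[hit] <- vals[hit] + tc$value[r]
  }
  mean(vals)
}

# Brute-force scale-regions matrix via per-base averaging (integer-aligned
# bins only, which all tests respect for the body by choosing element
# lengths divisible by the bin count).
brute_matrix <- function(track, elements, body, flank, bin) {
  nb <- body %/% bin
  nf <- flank %/% bin
  out <- matrix(NA_real_, nrow(elements), 2L * nf + nb)
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    len <- e$end - e$start
    stopifnot(len %% nb == 0L)  # keep body bins integer-aligned
    bounds <- c(seq(e$start - flank, e$start, by = bin),
                seq(e$start, e$end, by = len %/% nb)[-1L],
                seq(e$end + bin, e$end + flank, by = bin))
    stopifnot(length(bounds) == 2L * nf + nb + 1L)
    row <- vapply(seq_len(length(bounds) - 1L), function(j) {
      per_base_mean(track, e$chrom, bounds[j], bounds[j + 1L])
    }, numeric(1))
    if (identical(e$strand, "-")) row <- rev(row)
    out[i, ] <- row
  }
  rownames(out) <- elements$name
  out
}

# Methylation calls with given methylated flags at given positions.
toy_calls <- function(chrom, positions, methylated,
                      read = paste0("r", seq_along(positions))) {
  data.frame(chromosome = chrom, strand = "+", start = positions,
             read_name = read,
             log_lik_ratio = ifelse(methylated, 5, -5),
             methylated = methylated, stringsAsFactors = FALSE)
}

# Tiny deterministic insertion-call table (as read_insertion_table output).
toy_insertions <- function(n = 5L) {
  data.frame(
    chrom = rep("chr1", n),
    start = seq(1000L, by = 5000L, length.out = n),
    end = seq(1000L, by = 5000L, length.out = n),
    subfamily = rep(c("SVA_E", "SVA_F"), length.out = n),
    consensus = strrep("ACGT", seq(200L, by = 150L, length.out = n)),
    length = 4L * seq(200L, by = 150L, length.out = n),
    unmap_cover = seq(0.70, 0.98, length.out = n),
    te_match = rep(0.9, n),
    span_reads = seq_len(n) + 1L,
    sample_ids = "s1",
    stringsAsFactors = FALSE
  )
}

small_sim <- function(seed = 11L, ...) {
  args <- list(seed = seed, n_chromosomes = 2L, chrom_length = 60000L,
               n_fixed_elements = 2L, n_polymorphic_insertions = 4L)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}
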