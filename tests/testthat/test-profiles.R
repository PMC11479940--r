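test_that("alignment filtering applies uniqueness and mismatch-rate rules", {
  rec <- function(hits, mm, len = 100L, primary = TRUE) {
    data.frame(read_id = "r", chrom = "chr1", start = 0L,
               aligned_length = len, number_of_hits = hits,
               mismatches = mm, is_primary = primary, strand = "+",
               stringsAsFactors = FALSE)
  }
  # multimapper removed under unique_only
  expect_equal(nrow(filter_alignments(rec(2L, 0L))), 0L)
  expect_equal(nrow(filter_alignments(rec(2L, 0L), unique_only = FALSE)), 1L)
  # 3 mismatches in 100 bases pass the inclusive 0.03 cut; 4 fail
  expect_equal(nrow(filter_alignments(rec(1L, 3L))), 1L)
  expect_equal(nrow(filter_alignments(rec(1L, 4L))), 0L)
  # secondary records always removed
  expect_equal(nrow(filter_alignments(rec(1L, 0L, primary = FALSE))), 0L)
  # brute-force predicate agreement on a random table
  set.seed(5)
  tab <- do.call(rbind, lapply(1:50, function(i) {
    rec(sample(1:3, 1L), sample(0:6, 1L), 100L, runif(1) > 0.2)
  }))
  got <- filter_alignments(tab)
  keep <- tab$is_primary & tab$number_of_hits == 1L & tab$mismatches <= 3L
  expect_equal(got, tab[keep, , drop = FALSE])
})

test_that("spike-in factors follow 1e4 per aligned read and scale linearly", {
  expect_equal(spikein_scale_factor(10000L)$scale_factor, 1)
  expect_equal(spikein_scale_factor(1000L)$scale_factor, 10)
  # doubling the count halves the factor exactly
  expect_equal(spikein_scale_factor(4000L)$scale_factor,
               spikein_scale_factor(2000L)$scale_factor / 2)
  expect_error(spikein_scale_factor(0L), "spike-in")
  tr <- flat_track(value = 2.5)
  scaled <- scale_track(tr, spikein_scale_factor(2000L)$scale_factor)
  expect_equal(scaled$value, 12.5)
})

test_that("constant tracks give constant matrices at any geometry", {
  el <- rbind(one_element(start = 20000L, end = 22000L),
              one_element(start = 30000L, end = 33000L, name = "el2",
                          strand = "-"))
  tr <- flat_track(len = 60000L, value = 4)
  for (geom in list(c(1000L, 10000L, 50L), c(500L, 2000L, 100L),
                    c(1000L, 5000L, 250L))) {
    m <- scale_regions_matrix(tr, el, body = geom[1L], flank = geom[2L],
                              bin = geom[3L])
    expect_equal(dim(m), c(2L, (2L * geom[2L] + geom[1L]) / geom[3L]),
                 ignore_attr = TRUE)
    expect_true(all(abs(m - 4) < 1e-12))
  }
})

test_that("body/flank separation matches the interval-average oracle exactly", {
  el <- rbind(one_element(start = 20000L, end = 22000L),
              one_element(start = 40000L, end = 42500L, name = "el2",
                          strand = "-"))
  # value 2 over element bodies, 0 elsewhere; elements far enough apart
  # that neither body intrudes into the other's flanks
  tr <- toy_track("chr1", c(20000L, 40000L), c(22000L, 42500L), c(2, 2))
  m <- scale_regions_matrix(tr, el, body = 1000L, flank = 10000L, bin = 50L)
  nf <- 200L
  nb <- 20L
  expect_true(all(m[, nf + seq_len(nb)] == 2))
  expect_true(all(m[, c(seq_len(nf), nf + nb + seq_len(nf))] == 0))
  # full equality with the brute-force per-base oracle
  set.seed(41)
  bumpy <- toy_track("chr1", seq(0L, 59900L, by = 100L),
                     seq(100L, 60000L, by = 100L),
                     round(runif(600L, 0, 5), 3L))
  m2 <- scale_regions_matrix(bumpy, el, body = 1000L, flank = 2000L,
                             bin = 100L)
  oracle <- brute_matrix(bumpy, el, body = 1000L, flank = 2000L,
                         bin = 100L)
  expect_equal(unclass(m2), oracle, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("short elements are excluded and off-end flanks go missing", {
  el <- rbind(one_element(start = 2000L, end = 4000L),        # off-start flank
              one_element(start = 10000L, end = 10800L, name = "short"))
  m <- scale_regions_matrix(flat_track(len = 20000L), el, body = 1000L,
                            flank = 5000L, bin = 100L,
                            min_element_length = 1000L,
                            chrom_lengths = c(chr1 = 20000L))
  expect_equal(nrow(m), 1L)  # the 800-bp element is dropped
  # upstream flank extends to -3000: those bins are NA
  expect_true(all(is.na(m[1L, 1:30])))
  expect_true(all(!is.na(m[1L, 31:80])))
})

test_that("minus-strand rows are reversed so columns run 5' to 3'", {
  el_plus <- one_element(start = 20000L, end = 21200L)
  el_minus <- one_element(start = 20000L, end = 21200L, strand = "-")
  # asymmetric track: high just upstream of the genomic start
  tr <- rbind(flat_track(len = 50000L, value = 1),
              toy_track("chr1", 19000L, 20000L, 9))
  mp <- scale_regions_matrix(tr, el_plus, body = 1000L, flank = 2000L,
                             bin = 100L)
  mm <- scale_regions_matrix(tr, el_minus, body = 1000L, flank = 2000L,
                             bin = 100L)
  expect_equal(unname(mm[1L, ]), rev(unname(mp[1L, ])))
  # strand-balanced column means are palindromic
  both <- rbind(el_plus, within(el_minus, name <- "el1m"))
  mb <- scale_regions_matrix(tr, both, body = 1000L, flank = 2000L,
                             bin = 100L)
  cm <- colMeans(mb)
  expect_equal(unname(cm), rev(unname(cm)))
})

test_that("boundary enrichment recovers planted fold changes", {
  # flat matrix -> all ratios 1
  el <- one_element(start = 20000L, end = 22000L)
  m1 <- scale_regions_matrix(flat_track(), el)
  expect_equal(unname(boundary_enrichment(m1)), 1)
  # planted 5-fold boundary windows
  tr <- rbind(flat_track(len = 50000L, value = 1),
              toy_track("chr1", c(19000L, 21000L), c(21000L, 23000L),
                        c(4, 4)))
  m5 <- scale_regions_matrix(tr, el)
  r <- unname(boundary_enrichment(m5, window = 1000L))
  expect_gte(r, 4)
  expect_lte(r, 6)
  # zero distal signal -> NA, not infinity
  tr0 <- toy_track("chr1", c(19000L, 21000L), c(21000L, 23000L), c(5, 5))
  m0 <- scale_regions_matrix(tr0, el)
  expect_true(is.na(boundary_enrichment(m0)))
  # column-mean profile peaks at the body-edge columns
  cm <- colMeans(m5)
  nf <- attr(m5, "flank") %/% attr(m5, "bin")
  nb <- attr(m5, "body") %/% attr(m5, "bin")
  top2 <- order(cm, decreasing = TRUE)[1:2]
  expect_true(all(top2 %in% c(nf + 1L, nf + nb)) ||
                all(cm[c(nf + 1L, nf + nb)] == max(cm)))
})

test_that("profile matrices round-trip through the TSV serialization", {
  el <- one_element(start = 20000L, end = 22000L)
  m <- scale_regions_matrix(flat_track(value = 3.25), el, body = 1000L,
                            flank = 2000L, bin = 500L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_matrix(m, path)
  back <- read_profile_matrix(path)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12)
  expect_equal(attr(back, "bin"), attr(m, "bin"))
})

test_that("SAM round trip preserves the fields the filter consumes", {
  recs <- data.frame(read_id = c("a", "b"), chrom = "chr1",
                     start = c(10L, 99L), aligned_length = c(100L, 80L),
                     number_of_hits = c(1L, 2L), mismatches = c(3L, 0L),
                     is_primary = c(TRUE, FALSE), strand = c("+", "-"),
                     stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam_minimal(recs, c(chr1 = 1000L), path)
  back <- read_sam_minimal(path)
  expect_equal(back, recs)
})
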