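toy_counts <- function(counts, lengths, groups = NULL) {
  count_table(counts, lengths = lengths, groups = groups)
}

test_that("TPM normalizes by length and sums to one million per sample", {
  # single feature: any positive count -> 1e6
  m1 <- matrix(5L, 1L, 1L, dimnames = list("g", "s"))
  expect_equal(unname(tpm(toy_counts(m1, c(g = 1234)))[1L, 1L]), 1e6)
  # hand-computed two-feature case
  m2 <- matrix(c(10L, 10L), 2L, 1L, dimnames = list(c("a", "b"), "s"))
  x <- tpm(toy_counts(m2, c(a = 1000, b = 2000)))
  expect_equal(unname(x[, 1L]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  # all-zero sample: all zero, no division error
  m3 <- matrix(c(4L, 6L, 0L, 0L), 2L,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  x3 <- tpm(toy_counts(m3, c(a = 500, b = 1500)))
  expect_equal(unname(x3[, "s2"]), c(0, 0))
  # column sums at 1e6 for random tables
  set.seed(3)
  m4 <- matrix(rpois(60L, 50L), 10L,
               dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  x4 <- tpm(toy_counts(m4, setNames(sample(200:5000, 10L), rownames(m4))))
  expect_equal(unname(colSums(x4)), rep(1e6, 6L), tolerance = 1e-6)
})

test_that("median-of-ratios matches the closed form and the brute force", {
  # identical samples -> unit factors
  m <- matrix(rep(c(10L, 20L, 40L), 2L), 3L,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(unname(size_factors_median_ratios(
    toy_counts(m, c(a = 1, b = 1, c = 1)))), c(1, 1))
  # sample B = 2 x sample A -> factors (1/sqrt(2), sqrt(2))
  m2 <- m
  m2[, 2L] <- m2[, 1L] * 2L
  sf <- size_factors_median_ratios(toy_counts(m2, c(a = 1, b = 1, c = 1)))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(unname(sf[2L] / sf[1L]), 2, tolerance = 1e-12)
  # scaling one sample's counts by c scales its factor relative to every
  # other sample by c (the geometric-mean reference absorbs a common
  # c^(1/S), so only relative factors are equivariant)
  set.seed(11)
  m3 <- matrix(rpois(50L * 6L, 100L) + 1L, 50L,
               dimnames = list(paste0("f", 1:50), paste0("s", 1:6)))
  sf3 <- size_factors_median_ratios(m3)
  m3c <- m3
  m3c[, 3L] <- m3c[, 3L] * 3L
  sf3c <- size_factors_median_ratios(m3c)
  expect_equal(unname((sf3c[3L] / sf3c[-3L]) / (sf3[3L] / sf3[-3L])),
               rep(3, 5L), tolerance = 1e-12)
  # brute-force definition, feature by feature
  ref <- apply(m3, 1L, function(r) exp(mean(log(r))))
  brute <- apply(m3 / ref, 2L, median)
  expect_equal(size_factors_median_ratios(m3), brute, tolerance = 1e-12)
  # all-zero-containing features unusable -> error
  zz <- matrix(c(0L, 5L, 3L, 0L), 2L,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors_median_ratios(zz), "nonzero")
})

test_that("median-of-ratios agrees with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(19)
  # odd feature count: the exact median coincides for ratios and
  # log-ratios, so the two routes must agree to machine precision
  m <- matrix(rpois(41L * 5L, 80L) + 1L, 41L,
              dimnames = list(paste0("f", 1:41), paste0("s", 1:5)))
  expect_equal(unname(size_factors_median_ratios(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("intron retention reports group ratios and direction flags", {
  groups <- setNames(rep(c("control", "double_kd"), each = 2L),
                     c("c1", "c2", "k1", "k2"))
  # a block of unchanged background genes keeps the TPM denominator
  # stable so the planted fold changes survive normalization
  bg <- matrix(2000L, 5L, 4L,
               dimnames = list(paste0("bg", 1:5), names(groups)))
  base <- rbind(matrix(c(1000L, 100L, 200L,
                         1000L, 100L, 200L,
                         1000L, 300L, 100L,
                         1000L, 300L, 100L), 3L,
                       dimnames = list(c("gene", "intron", "exon"),
                                       names(groups))),
                bg)
  lens <- c(gene = 3000, intron = 2000, exon = 300,
            setNames(rep(2000, 5L), rownames(bg)))
  ct <- count_table(base, lengths = lens,
                    kinds = setNames(c("gene", "intron", "exon",
                                       rep("gene", 5L)), rownames(base)),
                    groups = groups)
  ir <- intron_retention(ct, "intron", "exon", c("control", "double_kd"))
  # ratios carry the planted 3x / 0.5x effect (TPM denominators shift a
  # little because the same library hosts both changes)
  expect_gt(ir$intron$ratio, 2.5)
  expect_lt(ir$intron$ratio, 3.5)
  expect_gt(ir$exon$ratio, 0.4)
  expect_lt(ir$exon$ratio, 0.6)
  expect_true(ir$intron_up)
  expect_true(ir$exon_down)
  # equal groups -> unit ratios, no flags
  base_eq <- base
  base_eq[, 3:4] <- base[, 1:2]
  eq <- count_table(base_eq, lengths = ct$lengths, groups = groups)
  ir_eq <- intron_retention(eq, "intron", "exon",
                            c("control", "double_kd"))
  expect_equal(ir_eq$intron$ratio, 1)
  expect_false(ir_eq$intron_up)
  # zero intron counts in both groups -> NA ratio, not 0/0
  z <- base
  z["intron", ] <- 0L
  ir_z <- intron_retention(count_table(z, lengths = ct$lengths,
                                       groups = groups),
                           "intron", "exon", c("control", "double_kd"))
  expect_true(is.na(ir_z$intron$ratio))
  # absent feature named in the error
  expect_error(intron_retention(ct, "intron99", "exon",
                                c("control", "double_kd")), "intron99")
})

test_that("element-gene links respect the distance window and TSS strandness", {
  el <- one_element(start = 100000L, end = 102000L)
  gene <- function(id, start1, end1, strand) {
    data.frame(chrom = "chr1", source = "t", feature = "gene",
               start = start1, end = end1, score = ".", strand = strand,
               frame = ".",
               attributes = sprintf("gene_id \"%s\";", id),
               gene_id = id, stringsAsFactors = FALSE)
  }
  ann <- rbind(gene("g10k", 112000L, 115000L, "+"),   # TSS 10 kbp right
               gene("g1k", 103000L, 106000L, "+"),    # TSS 1 kbp: too close
               gene("g60k", 162000L, 165000L, "+"),   # TSS 60 kbp: too far
               gene("gminus", 50000L, 70000L, "-"))   # TSS = end, 30 kbp left
  links <- link_elements_to_genes(el, ann, 2000L, 50000L)
  expect_setequal(links$gene_id, c("g10k", "gminus"))
  expect_equal(links$distance[links$gene_id == "g10k"], 10000L)
  expect_equal(links$distance[links$gene_id == "gminus"],
               100000L - (70000L - 1L))
  expect_true(!is.unsorted(links$distance))
  # translation invariance
  el2 <- el
  el2$start <- el$start + 7000L
  el2$end <- el$end + 7000L
  ann2 <- ann
  ann2$start <- ann$start + 7000L
  ann2$end <- ann$end + 7000L
  links2 <- link_elements_to_genes(el2, ann2, 2000L, 50000L)
  expect_equal(links2$distance, links$distance)
  expect_equal(links2$gene_id, links$gene_id)
})

test_that("readthrough extent walks outward, bridges gaps and labels direction", {
  el <- one_element(start = 50000L, end = 52000L, strand = "+")
  gene <- data.frame(chrom = "chr1", source = "t", feature = "gene",
                     start = 40001L, end = 49000L, score = ".",
                     strand = "-", frame = ".",
                     attributes = "gene_id \"gm\";", gene_id = "gm",
                     stringsAsFactors = FALSE)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric())
  # zero coverage beyond the element -> extent 0
  rt0 <- detect_readthrough(empty, empty, el, gene)
  expect_equal(rt0$extent, 0)
  # planted 2-kb readthrough leftward on the minus strand, into a
  # minus-strand gene -> sense; into a plus-strand gene -> antisense
  minus_track <- toy_track("chr1", 48000L, 50000L, 5)
  rt <- detect_readthrough(empty, minus_track, el, gene)
  expect_equal(rt$extent, 2000L)
  expect_equal(rt$strand, "-")
  expect_equal(rt$direction, "sense")
  gene_plus <- within(gene, strand <- "+")
  rt_as <- detect_readthrough(empty, minus_track, el, gene_plus)
  expect_equal(rt_as$direction, "antisense")
  expect_gte(rt_as$extent, 1800L)
  expect_lte(rt_as$extent, 2200L)
  # a 100-base hole under max_gap 200 is bridged; under max_gap 50 not
  gappy <- toy_track("chr1", c(48000L, 49100L), c(49000L, 50000L), c(5, 5))
  rt_g <- detect_readthrough(empty, gappy, el, gene, max_gap = 200L)
  expect_equal(rt_g$extent, 2000L)
  rt_s <- detect_readthrough(empty, gappy, el, gene, max_gap = 50L)
  expect_equal(rt_s$extent, 900L)
  # extent monotone: non-increasing in min_coverage, non-decreasing in max_gap
  ext <- function(minc, gap) {
    detect_readthrough(empty, gappy, el, gene, min_coverage = minc,
                       max_gap = gap)$extent
  }
  expect_true(ext(1, 200L) >= ext(6, 200L))
  expect_true(ext(1, 50L) <= ext(1, 200L))
})
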