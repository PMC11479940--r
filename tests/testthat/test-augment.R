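test_that("single-insertion splice matches the manual string oracle", {
  res <- augment_genome(c(chr1 = "ACGTACGTAC"),
                        data.frame(chrom = "chr1", position = 5L,
                                   sequence = "TTT", label = "x"))
  expect_identical(res$genome[["chr1"]], "ACGTATTTCGTAC")
  expect_equal(nchar(res$genome[["chr1"]]), 13L)
  expect_equal(res$map$cum_offset, 3)
})

test_that("empty plan is the identity with an empty map", {
  g <- c(chr1 = "ACGTACGT", chr2 = "GGGGCCCC")
  res <- augment_genome(g, data.frame(chrom = character(),
                                      position = integer(),
                                      sequence = character()))
  expect_identical(res$genome, g)
  expect_equal(nrow(res$map), 0L)
  expect_identical(lift_annotation(
    data.frame(chrom = "chr1", source = "s", feature = "gene",
               start = 2L, end = 6L, score = ".", strand = "+",
               frame = ".", attributes = "gene_id \"g\";"), res$map)$start,
    2L)
})

test_that("application order does not change the augmented sequence", {
  g <- c(chr1 = paste(rep("ACGTTGCA", 50L), collapse = ""))
  plan <- data.frame(chrom = "chr1", position = c(300L, 40L, 170L),
                     sequence = c("TTTT", "GG", "CCCCCC"),
                     label = c("a", "b", "c"), stringsAsFactors = FALSE)
  res <- augment_genome(g, plan)
  # brute-force splice applied end-to-start
  s <- g[["chr1"]]
  for (i in order(-plan$position)) {
    s <- paste0(substr(s, 1L, plan$position[i]), plan$sequence[i],
                substr(s, plan$position[i] + 1L, nchar(s)))
  }
  expect_identical(res$genome[["chr1"]], s)
  # and start-to-end application with recomputed offsets agrees
  s2 <- g[["chr1"]]
  off <- 0L
  for (i in order(plan$position)) {
    p <- plan$position[i] + off
    s2 <- paste0(substr(s2, 1L, p), plan$sequence[i],
                 substr(s2, p + 1L, nchar(s2)))
    off <- off + nchar(plan$sequence[i])
  }
  expect_identical(res$genome[["chr1"]], s2)
  # length conservation
  expect_equal(nchar(res$genome[["chr1"]]),
               nchar(g[["chr1"]]) + sum(nchar(plan$sequence)))
})

test_that("invalid plans are rejected with informative errors", {
  g <- c(chr1 = "ACGTACGT")
  expect_error(augment_genome(g, data.frame(chrom = "chr1", position = 9L,
                                            sequence = "T", label = "far")),
               "far")
  expect_error(augment_genome(g, data.frame(chrom = "chr1",
                                            position = c(4L, 4L),
                                            sequence = c("A", "C"),
                                            label = c("p", "q"))),
               "conflict|same position")
  expect_error(augment_genome(g, data.frame(chrom = "chrX", position = 1L,
                                            sequence = "T", label = "x")),
               "chrX")
})

test_that("breakpoint stitching equals the two-segment concatenation", {
  g <- c(toy = "AAAAGGGG")
  res <- stitch_at_breakpoint(g, "toy", breakpoint = 4L, insert = "CC")
  expect_identical(res$genome[["toy"]], "AAAACCGGGG")
  # zero-length insert is the identity
  res0 <- stitch_at_breakpoint(g, "toy", breakpoint = 4L, insert = "")
  expect_identical(res0$genome[["toy"]], g[["toy"]])
  expect_error(stitch_at_breakpoint(g, "toy", breakpoint = 8L, insert = "C"),
               "out of range")
  # equivalence with augment_genome at 0-based position = breakpoint
  res2 <- augment_genome(g, data.frame(chrom = "toy", position = 4L,
                                       sequence = "CC", label = "s"))
  expect_identical(res$genome, res2$genome)
})

test_that("stitch length arithmetic reproduces the chrX augmentation", {
  # coordinate-map arithmetic at the real scale, no sequence materialized
  map <- coord_map(data.frame(chrom = "chrX", position = 71440502,
                              length = 2638, label = "sva"),
                   chrom_lengths = c(chrX = 156040895))
  expect_equal(unname(augmented_seqlengths(map)["chrX"]), 156043533)
})

test_that("annotation liftover shifts, stretches and preserves features", {
  map <- coord_map(data.frame(chrom = "chr1", position = 500L,
                              length = 50L, label = "ins"))
  rec <- function(s, e) data.frame(chrom = "chr1", source = "t",
                                   feature = "gene", start = s, end = e,
                                   score = ".", strand = "+", frame = ".",
                                   attributes = "gene_id \"g\";",
                                   stringsAsFactors = FALSE)
  # wholly upstream feature unchanged
  up <- lift_annotation(rec(100L, 200L), map)
  expect_equal(c(up$start, up$end), c(100L, 200L))
  # wholly downstream feature shifts by the inserted length
  down <- lift_annotation(rec(600L, 700L), map)
  expect_equal(c(down$start, down$end), c(650L, 750L))
  # containing feature stretches by the internal insertion
  intron <- lift_annotation(rec(400L, 800L), map)
  expect_equal(c(intron$start, intron$end), c(400L, 850L))
  expect_equal(intron$end - intron$start, (800L - 400L) + 50L)
  # unmapped chromosome passes through with a warning
  other <- rec(10L, 20L)
  other$chrom <- "chr9"
  expect_warning(lifted <- lift_annotation(other, map), "chr9")
  expect_equal(c(lifted$start, lifted$end), c(10L, 20L))
})

test_that("projection inverts lifting everywhere off the insertions", {
  g <- c(chr1 = "ACGTACGTAC")
  res <- augment_genome(g, data.frame(chrom = "chr1", position = 5L,
                                      sequence = "TTT", label = "ins1"))
  # identity map: projection is the identity
  id_map <- augment_genome(g, data.frame(chrom = character(),
                                         position = integer(),
                                         sequence = character()))$map
  pr <- project_to_reference(id_map, "chr1", 0:9)
  expect_equal(pr$position, 0:9)
  expect_true(all(pr$status == "unique"))
  # inside the planted insertion -> insertion point, labelled
  ins <- project_to_reference(res$map, "chr1", 5:7)
  expect_true(all(ins$status == "inside_insertion"))
  expect_true(all(ins$position == 5))
  expect_true(all(ins$label == "ins1"))
  expect_error(project_to_reference(res$map, "chr1", 13), "beyond")
})

test_that("lift/project round trips on random positions across chromosomes", {
  set.seed(17)
  chroms <- paste0("chr", 1:10)
  chrom_lengths <- setNames(rep(100000L, 10L), chroms)
  plan <- data.frame(
    chrom = rep(chroms, each = 3L),
    position = as.integer(replicate(10L, sort(sample.int(99000L, 3L)))),
    length = sample(50:500, 30L, TRUE))
  plan$sequence <- strrep("A", plan$length)
  plan$label <- sprintf("ins%02d", seq_len(30L))
  map <- coord_map(plan, chrom_lengths = chrom_lengths)
  for (ch in chroms) {
    pos <- sample.int(100000L, 100L) - 1L
    lifted <- lift_position(map, ch, pos)
    back <- project_to_reference(map, ch, lifted)
    expect_equal(back$position, pos)
    expect_true(all(back$status == "unique"))
  }
})

test_that("insertion-free features keep identical sequence after lifting", {
  set.seed(23)
  g <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 2000L, TRUE),
                      collapse = ""))
  plan <- data.frame(chrom = "chr1", position = c(500L, 1500L),
                     sequence = c(strrep("GATTACA", 10L), strrep("TT", 30L)),
                     label = c("i1", "i2"), stringsAsFactors = FALSE)
  res <- augment_genome(g, plan)
  # feature [700, 1400] 0-based lies strictly between the insertions
  lifted_start <- lift_position(res$map, "chr1", 700L)
  expect_identical(substr(res$genome[["chr1"]], lifted_start + 1L,
                          lifted_start + 700L),
                   substr(g[["chr1"]], 701L, 1400L))
})

test_that("coordinate maps survive a write/read round trip", {
  plan <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     position = c(100L, 900L, 50L),
                     length = c(10L, 20L, 30L),
                     label = c("a", "b", "c"))
  map <- coord_map(plan)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_coord_map(map, path)
  back <- read_coord_map(path)
  expect_equal(as.data.frame(back), as.data.frame(map))
})
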