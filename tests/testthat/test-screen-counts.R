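guides4 <- c(gA = "ACTTATTAATTTATTATTTA",
             gB = "ACTTATTAATTTATTATTTC",
             gC = "TTTTATTAATTTATTATTTA",
             gD = "GGGGGGGGGGGGGGGGGGGG")

test_that("reads match exactly, at Hamming-1, or stay unassigned", {
  reads <- c(guides4[["gA"]],                       # perfect
             guides4[["gA"]],                       # perfect again
             sub("^AC", "AG", guides4[["gA"]]),     # 1 mismatch from gA
             chartr("G", "T", guides4[["gD"]]),     # 20 mismatches
             "ACGT",                                # wrong length
             guides4[["gC"]])
  res <- matchReads(reads, guides4)
  expect_identical(res$perfect,
                   c(gA = 2L, gB = 0L, gC = 1L, gD = 0L))
  expect_equal(nrow(res$mismatches), 1L)
  expect_identical(res$mismatches$parent_guide_id, "gA")
  expect_identical(res$mismatches$position, 2L)
  expect_identical(res$mismatches$observed_base, "G")
  expect_identical(res$mismatches$reads, 1L)
  expect_equal(res$unassigned, 2L)
  # conservation: every input read lands in exactly one bucket
  expect_equal(sum(res$perfect) + sum(res$mismatches$reads) +
                 res$unassigned, length(reads))
  # a read 1 mismatch from two guides is ambiguous -> unassigned
  amb <- sub("A$", "G", guides4[["gA"]])  # 1 from gA and 1 from gB
  res2 <- matchReads(amb, guides4)
  expect_equal(res2$unassigned, 1L)
  expect_equal(nrow(res2$mismatches), 0L)
})

test_that("the synthesis-error ratio rule is strict at its boundary", {
  # 80 / 1000 = 0.08 > 0.075 -> synthesis error
  res <- se_fixture(80, 1000)
  expect_equal(nrow(res$se_set), 1L)
  expect_false(res$se_set$abundant)
  expect_true("gA_v1" %in% rownames(countMatrix(res$corrected)))
  expect_true(isSeGuide(res$corrected)[match("gA_v1",
                                             rownames(res$corrected))])
  # SE reads are removed from the parent, not folded in
  expect_equal(unname(countMatrix(res$corrected)["gA", 1]), 500L)

  # 75 / 1000 = 0.075 exactly: retained as sequencing error
  res2 <- se_fixture(75, 1000)
  expect_equal(nrow(res2$se_set), 0L)
  # non-SE mismatch reads are credited to the parent
  expect_equal(unname(countMatrix(res2$corrected)["gA", 1]),
               500L + 37L)

  # abundant null control above 1000 total reads
  res3 <- se_fixture(1200, 10000)
  expect_true(res3$se_set$abundant)

  # zero perfect reads with mismatch reads: SE by convention
  perfect0 <- ScreenCounts(
    matrix(c(0L, 0L), nrow = 1, dimnames = list("gA", NULL)),
    timepoint = c("T0_mutagenesis", "T_end"), replicate = c("A", "A"))
  res4 <- detectSynthesisErrors(
    matrix(c(5L, 5L), nrow = 1, dimnames = list("gA_v1", NULL)),
    data.frame(variant_id = "gA_v1", parent_guide_id = "gA"), perfect0)
  expect_equal(nrow(res4$se_set), 1L)
  expect_identical(res4$se_set$ratio, Inf)
})

test_that("read totals are conserved through SE correction", {
  res <- se_fixture(80, 1000)
  expect_equal(sum(countMatrix(res$corrected)), 1000L + 100L + 80L)
  res2 <- se_fixture(75, 1000)
  expect_equal(sum(countMatrix(res2$corrected)), 1000L + 100L + 74L)
})

test_that("presence filtering uses a strict majority of zero samples", {
  m <- matrix(1L, nrow = 3, ncol = 12,
              dimnames = list(c("g7", "g6", "g0"), NULL))
  m["g7", 1:7] <- 0L
  m["g6", 1:6] <- 0L
  sc <- ScreenCounts(m, timepoint = rep(c("T0_mutagenesis", "T_end"),
                                        each = 6),
                     replicate = rep(as.character(1:6), 2))
  kept <- rownames(filterPresence(sc))
  expect_identical(kept, c("g6", "g0"))
})

test_that("the minimal read threshold is inclusive and per-replicate", {
  m <- matrix(c(54L, 60L, 10L, 10L,
                53L, 500L, 10L, 10L,
                0L, 0L, 10L, 10L), nrow = 3, byrow = TRUE,
              dimnames = list(c("ok", "low", "zero"), NULL))
  sc <- ScreenCounts(m, timepoint = c("T0_mutagenesis", "T0_mutagenesis",
                                      "T_end", "T_end"),
                     replicate = c("A", "B", "A", "B"))
  expect_identical(filterMinReads(sc), "ok")
  sc2 <- sc[, 1:2]
  expect_error(filterMinReads(sc2, timepoint = "T_end"), "missing")
})

test_that("count tables round-trip through TSV", {
  m <- matrix(1:8, nrow = 2,
              dimnames = list(c("g1", "g2"), NULL))
  sc <- ScreenCounts(m, timepoint = rep(c("T0_mutagenesis", "T_end"),
                                        each = 2),
                     replicate = rep(c("A", "B"), 2),
                     is_se = c(FALSE, TRUE))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCountTable(sc, f)
  sc2 <- readCountTable(f)
  expect_equal(unname(countMatrix(sc2)), unname(countMatrix(sc)))
  expect_identical(unname(isSeGuide(sc2)), c(FALSE, TRUE))
  expect_identical(SummarizedExperiment::colData(sc2)$timepoint,
                   SummarizedExperiment::colData(sc)$timepoint)
})

test_that("ScreenCounts validity rejects malformed containers", {
  expect_error(ScreenCounts(matrix(-1L, 1, 2, dimnames = list("g", NULL)),
                            c("T0_mutagenesis", "T_end"), c("A", "A")),
               "negative")
  expect_error(ScreenCounts(matrix(1L, 1, 2, dimnames = list("g", NULL)),
                            c("bad_tp", "T_end"), c("A", "A")),
               "timepoint")
})
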