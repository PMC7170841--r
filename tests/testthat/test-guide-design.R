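test_that("editable cytosines use the PAM-relative window convention", {
  # C at string index 2 is 19 bases 5' of the PAM
  p <- "ACTTATTAATTTATTATTTA"
  expect_identical(editableCytosines(p),
                   list(extended = -19L, high = -19L))
  expect_identical(editableCytosines(strrep("A", 20)),
                   list(extended = integer(0), high = integer(0)))
  # Cs at -16 and -14 sit outside the high-activity window
  p2 <- "AAAACACATTTTATTATTTA"
  expect_identical(editableCytosines(p2),
                   list(extended = c(-16L, -14L), high = integer(0)))
  expect_error(editableCytosines("ACGT"), "20 nt")
})

test_that("a single-PAM toy gene yields exactly one indexed candidate", {
  fx <- toy_single_site()
  cand <- enumerateCandidates(fx$ref)
  expect_equal(nrow(cand), 1L)
  expect_identical(cand$protospacer, fx$proto)
  expect_identical(cand$protospacer_start, fx$start)
  expect_identical(cand$protospacer_strand, "+")
  expect_identical(cand$strand_class, "coding")
  expect_identical(cand$c_positions[[1]], -19L)
  expect_identical(cand$pam, "AGG")

  # and the intended edit lands at CDS position 6 of 60
  frac <- cdsPositionFraction(cand[1, ], refGenes(fx$ref)[1, ])
  expect_equal(frac, 6 / 60)

  # no PAM, no candidates
  ref0 <- ReferenceSet(
    c(c1 = strrep("AT", 30)),
    data.frame(gene_id = "g", chrom = "c1", strand = "+", starts = 0,
               ends = 60, target_class = "essential",
               fitness_score = NA_real_))
  expect_equal(nrow(enumerateCandidates(ref0)), 0L)
})

test_that("minus-strand candidates carry reverse-complement protospacers", {
  fx <- ggc_gene()
  cand <- enumerateCandidates(fx$ref)
  hit <- cand[cand$protospacer_strand == "-" &
                cand$protospacer_start == fx$proto_start, ]
  expect_equal(nrow(hit), 1L)
  expect_identical(hit$protospacer, fx$proto)
  expect_identical(hit$strand_class, "noncoding")
  # window Cs pair the GGC glycine codon guanines
  expect_identical(sort(hit$c_positions[[1]]), c(-19L, -18L))
})

test_that("each planted zoo cassette fails for exactly its reason", {
  ref <- zoo_reference()
  cand <- enumerateCandidates(ref)
  z <- zoo_cassettes()
  reasons_of <- function(proto) {
    rows <- which(cand$protospacer == proto)
    expect_true(length(rows) >= 1L, label = paste("cassette found:", proto))
    lapply(rows, function(i)
      applyDesignFilters(cand[i, ], ref)$reasons)
  }
  expect_identical(sort(reasons_of(z$z_all3)[[1]]),
                   c("all_three_high", "pair_18_17"))
  expect_identical(reasons_of(z$z_pair)[[1]], "pair_18_17")
  expect_identical(reasons_of(z$z_bsai)[[1]], "bsai")
  for (r in reasons_of(z$z_dup)) expect_identical(r, "not_unique")
  expect_identical(reasons_of(z$z_nag)[[1]], "nag_site")
  expect_identical(reasons_of(z$z_low)[[1]], "cds_fraction_low")
  expect_identical(reasons_of(z$z_high)[[1]], "cds_fraction_high")
  ok <- applyDesignFilters(cand[which(cand$protospacer == z$z_ok), ], ref)
  expect_true(ok$pass)
  expect_identical(ok$reasons, character(0))
})

test_that("risk categories follow the pattern table and weight fallback", {
  # unambiguous anchor pattern: single C in the high-activity window
  expect_identical(assignRiskCategory("ACGATAA"), "very_low")
  expect_identical(assignRiskCategory("TCAATTA"), "very_low")
  # one high-window C plus no secondary C anywhere
  expect_identical(assignRiskCategory("AACTTAA"), "very_low")
  # two high-activity Cs
  expect_identical(assignRiskCategory("ACACTTA"), "high")
  # CC dinucleotide
  expect_identical(assignRiskCategory("ACCTTAA"), "high")
  # secondary C at the mid-weight -16 position
  expect_identical(assignRiskCategory("AACACTA"), "moderate")
  # secondary C only at a weight <= 0.1 position (-20)
  expect_identical(assignRiskCategory("CACTATA"), "low")
  expect_error(assignRiskCategory("ACGT"), "7")
  # a configured pattern wins over the fallback
  cfg <- designConfig(risk_patterns = data.frame(
    pattern = c("NCDCNNN", "NCDDDNN"),
    category = c("moderate", "very_low")))
  expect_identical(assignRiskCategory("ACACTTA", cfg), "moderate")
})

test_that("built libraries are valid, categorized, and deterministic", {
  ref <- generateReference(n_genes = 3, length_range = c(400, 600),
                           gc = 0.4, seed = 3)
  lib <- buildLibrary(ref)
  expect_gt(nrow(lib), 0)
  # every guide has a high-window C and exactly one risk category
  expect_true(all(lengths(lib$high_c) >= 1))
  expect_true(all(lib$risk_category %in%
                    c("very_low", "low", "moderate", "high")))
  expect_true(all(lib$cds_fraction >= 0.005 & lib$cds_fraction <= 0.75))
  # no kept guide violates any individually re-checked filter
  for (i in seq_len(nrow(lib)))
    expect_true(applyDesignFilters(lib[i, ], ref)$pass)
  # report tallies are consistent
  rep_ <- attr(lib, "report")
  expect_equal(rep_$n_kept, nrow(lib))
  expect_equal(sum(unlist(rep_$per_target_class)), nrow(lib))

  # byte-identical output on repeated runs
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeGuideLibrary(buildLibrary(ref), f1)
  writeGuideLibrary(buildLibrary(ref), f2)
  expect_identical(readLines(f1), readLines(f2))
  # round trip preserves content
  lib2 <- readGuideLibrary(f1)
  expect_identical(lib2$protospacer, lib$protospacer)
  expect_identical(lib2$c_positions, lib$c_positions)
})

test_that("impossible configuration bounds are rejected", {
  expect_error(designConfig(cds_fraction_bounds = c(0.9, 0.2)),
               "increasing")
  expect_error(designConfig(cds_fraction_bounds = c(-0.1, 0.5)))
  expect_error(designConfig(high_window = -25:-23), "contained")
})
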