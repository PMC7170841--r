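test_that("position ranking follows activity weights with PAM-ward ties", {
  expect_identical(rankPositions(-19L), -19L)
  expect_identical(rankPositions(c(-18L, -14L)), c(-18L, -14L))
  expect_identical(rankPositions(c(-19L, -17L)), c(-17L, -19L))
  # -20 and -15 share weight 0.1; the tie breaks toward the PAM
  expect_identical(rankPositions(c(-20L, -15L)), c(-15L, -20L))
  expect_identical(rankPositions(integer(0)), integer(0))
  expect_error(activityProfile(c(`-18` = 0.2, `-16` = 0.5)), "exceed")
})

test_that("the glycine codon example yields Arg/Ser at the top rank", {
  fx <- ggc_gene()
  cand <- enumerateCandidates(fx$ref)
  guide <- cand[cand$protospacer_strand == "-" &
                  cand$protospacer_start == fx$proto_start, ]
  gene <- refGenes(fx$ref)[1, ]
  out <- predictOutcomes(guide, gene, fx$ref)
  expect_equal(nrow(out), 4L)
  r1 <- out[out$rank == 1, ]
  # template-strand C>G appears as G>C on the sense strand: GGC -> CGC (Arg)
  expect_identical(r1$ref_codon, c("GGC", "GGC"))
  expect_identical(r1$alt_codon[r1$alt == "G"], "CGC")
  expect_identical(r1$alt_aa[r1$alt == "G"], "R")
  # template-strand C>T appears as G>A: GGC -> AGC (Ser)
  expect_identical(r1$alt_codon[r1$alt == "T"], "AGC")
  expect_identical(r1$alt_aa[r1$alt == "T"], "S")
  expect_identical(unique(r1$ref_aa), "G")
  expect_identical(unique(r1$consequence), "missense")
  expect_identical(unique(out$consequence[out$rank == 2]), "missense")
  expect_identical(patternKey(out), "G>R/S")
  # the guide is not stop-generating
  expect_null(classifySgg(guide, gene, fx$ref))
})

test_that("model sets hold 2 genotypes per ranked position, never C-to-A", {
  fx <- toy_single_site()
  cand <- enumerateCandidates(fx$ref)
  out <- predictOutcomes(cand[1, ], refGenes(fx$ref)[1, ], fx$ref)
  expect_equal(nrow(out), 2L)           # single editable C
  expect_true(all(out$alt %in% c("G", "T")))
  expect_true(all(out$rank == 1L))
  expect_identical(unique(out$sense_ref), "C")  # coding-strand guide
  # a silent target: GTC valine codon edited at its third base
  fx2 <- codon_guide_ref("GTC", 2, "coding")
  out2 <- predictOutcomes(fx2$guide, fx2$gene, fx2$ref)
  expect_identical(unique(out2$consequence), "silent")
  expect_identical(patternKey(out2), "V>V/V")
  # guides without high-window cytosines are rejected
  bad <- cand[1, ]
  bad$c_positions <- list(-15L); bad$high_c <- list(integer(0))
  expect_error(predictOutcomes(bad, refGenes(fx$ref)[1, ], fx$ref),
               "high-activity")
})

test_that("SGG classification agrees with codon-table brute force", {
  codons <- apply(expand.grid(b1 = c("A", "C", "G", "T"),
                              b2 = c("A", "C", "G", "T"),
                              b3 = c("A", "C", "G", "T")), 1, paste,
                  collapse = "")
  n_checked <- 0L
  hits <- character(0)
  for (codon in codons) {
    for (offset in 0:2) {
      for (mode in c("coding", "template")) {
        fx <- codon_guide_ref(codon, offset, mode)
        if (is.null(fx)) next
        n_checked <- n_checked + 1L
        alts <- oracle_codon_alts(codon, offset, mode)
        ref_aa <- Biostrings::GENETIC_CODE[codon]
        expect_stop <- any(Biostrings::GENETIC_CODE[alts] == "*") &&
          ref_aa != "*"
        sgg <- classifySgg(fx$guide, fx$gene, fx$ref)
        expect_identical(!is.null(sgg), unname(expect_stop),
                         info = paste("SGG status", codon, offset, mode))
        if (!is.null(sgg)) {
          hits <- c(hits, codon)
          expect_identical(sgg$codon, codon)
          via <- names(alts)[Biostrings::GENETIC_CODE[alts] == "*"][1]
          expect_identical(sgg$stop_via, paste0("C>", via))
          expect_identical(sgg$on_noncoding_strand, mode == "template")
        }
      }
    }
  }
  expect_gte(n_checked, 45)
  # single-C/single-G enumeration recovers the stop-reachable codons
  expect_setequal(unique(hits), c("TCA", "TAC", "CAA", "CAG", "CGA"))
  # TGG (two guanines) is reached through the template strand, where the
  # protospacer shows the CC dinucleotide pairing the tryptophan codon
  fx <- codon_guide_ref_tgg()
  sgg <- classifySgg(fx$guide, fx$gene, fx$ref)
  expect_identical(sgg$codon, "TGG")
  expect_identical(sgg$stop_via, "C>T")
  expect_true(sgg$on_noncoding_strand)
})

test_that("duplex melting temperature matches a hand-summed oracle", {
  # frozen oracle values from an independent nearest-neighbor summation
  # over the RNA/DNA parameter set (25/25 nM strands, 50 mM Na+)
  expect_equal(duplexTm("ACGTACGTACGTACGTACGT"), 47.71346224764068,
               tolerance = 1e-10)
  expect_equal(duplexTm("ACGTACGTACGTACGTACGT", salt_correction = FALSE),
               60.20904864552921, tolerance = 1e-10)
  # explicit two-step hand computation for a short duplex
  s <- "ACGT"
  dH <- 1.9 + (-5.9) + (-16.3) + (-7.8)
  dS <- -3.9 + (-12.3) + (-47.1) + (-21.6) + 0.368 * 3 * log(0.05)
  expect_equal(duplexTm(s),
               1000 * dH / (dS + 1.987 * log(12.5e-9)) - 273.15)
  expect_gt(duplexTm(strrep("GC", 10)), duplexTm(strrep("AT", 10)))
  expect_error(duplexTm("ACGN"), "outside")
})

test_that("guide features report base fractions in [0,1]", {
  f <- guideFeatures(paste0(strrep("G", 10), strrep("C", 10)))
  expect_equal(f$gc_fraction, 1.0)
  expect_equal(f$g_fraction, 0.5)
  expect_equal(f$c_fraction, 0.5)
  expect_error(guideFeatures("ACGT"), "20 nt")
})

test_that("model coverage is the model-set read share", {
  obs <- c(CGC = 60, AGC = 30, other = 10)
  expect_equal(modelCoverage(obs, c("CGC", "AGC")), 0.9)
  expect_equal(modelCoverage(obs, names(obs)), 1.0)
  expect_error(modelCoverage(numeric(0), "x"), "undefined")
})

test_that("combination percentiles agree between enumeration and sampling", {
  obs <- c(a = 500, b = 200, c = 150, d = 90, e = 40, f = 20)
  exact <- randomCombinationPercentile(obs, k = 3, q = 0.9)
  sampled <- randomCombinationPercentile(obs, k = 3, q = 0.9,
                                         n_samples = 4000, seed = 5,
                                         exhaustive_cap = 1)
  expect_lt(abs(exact - sampled), 0.05)
  # concentrated mass bounds any subset containing the dominant genotype
  obs2 <- c(x = 990, y = 4, z = 3, w = 2, v = 1)
  expect_gte(randomCombinationPercentile(obs2, k = 4, q = 0.99), 0.99)
  expect_error(randomCombinationPercentile(obs, k = 10), "exceeds")
  # seeded sampling is reproducible
  s1 <- randomCombinationPercentile(obs, 3, 0.9, 500, seed = 2,
                                    exhaustive_cap = 1)
  s2 <- randomCombinationPercentile(obs, 3, 0.9, 500, seed = 2,
                                    exhaustive_cap = 1)
  expect_identical(s1, s2)
})

test_that("rank-agreement permutation test behaves at its limits", {
  # perfect agreement over 6 guides x 3 sites sits near the p floor
  pred <- replicate(6, sample(1:3), simplify = FALSE)
  res <- rankAgreementTest(pred, pred, n_perm = 2000, seed = 1)
  expect_equal(res$statistic, 18)
  expect_lt(res$p_value, 0.01)
  # a single two-site guide has only two permutations
  res2 <- rankAgreementTest(list(1:2), list(1:2), n_perm = 4000, seed = 2)
  expect_lt(abs(res2$p_value - 0.5), 0.05)
  # independent predictions give a roughly uniform p-value
  set.seed(3)
  ps <- replicate(40, {
    pred <- replicate(5, sample(1:3), simplify = FALSE)
    obs <- replicate(5, sample(1:3), simplify = FALSE)
    rankAgreementTest(pred, obs, n_perm = 200)$p_value
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.8)
  expect_error(rankAgreementTest(list(1:2), list(1:3)), "shape")
})
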