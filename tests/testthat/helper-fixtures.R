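# Fixtures and independent oracles shared across the test files. All
# fixtures are built in code; oracles deliberately avoid the package's own
# code paths (plain string surgery, GENETIC_CODE lookups, choose()-based
# probabilities).

oracle_revcomp <- function(s)
  vapply(s, function(x) paste(rev(strsplit(chartr("ACGTN", "TGCAN", x),
                                           "")[[1]]), collapse = ""),
         "", USE.NAMES = FALSE)

oracle_translate <- function(s) {
  n <- nchar(s) %/% 3
  paste(Biostrings::GENETIC_CODE[substring(s, 3 * seq_len(n) - 2,
                                           3 * seq_len(n))],
        collapse = "")
}

# --- minimal single-candidate gene -----------------------------------------
# 60-nt plus-strand gene holding exactly one NGG PAM genome-wide (no GG/CC
# elsewhere on either strand); protospacer starts at 0-based position 4 and
# carries window cytosines only at string index 2 (PAM-relative -19).
toy_single_site <- function() {
  proto <- "ACTTATTAATCTATTATTTA"
  chrom <- paste0("ATAT", proto, "AGG", strrep("TA", 16), "T")
  stopifnot(nchar(chrom) == 60)
  ref <- ReferenceSet(
    c(chr1 = chrom),
    data.frame(gene_id = "tg1", chrom = "chr1", strand = "+",
               starts = 0, ends = 60, target_class = "essential",
               fitness_score = NA_real_))
  list(ref = ref, proto = proto, start = 4L)
}

# --- glycine-codon gene targeted on the template strand --------------------
# Plus-strand gene whose codon 11 is GGC; the naturally occurring CCA at
# gene positions 10..12 provides a minus-strand PAM so that a template
# (noncoding-strand) guide with protospacer start 13 (gene-relative) edits
# the first G of the GGC codon at its top-ranked position (-18).
ggc_gene <- function(pad = 10) {
  gene <- "ATGAAATTAACCAATTTAATTACTATTAATGGCTAA"
  stopifnot(substr(gene, 31, 33) == "GGC")
  chrom <- paste0(strrep("T", pad), gene, strrep("T", pad))
  ref <- ReferenceSet(
    c(chr1 = chrom),
    data.frame(gene_id = "gGGC", chrom = "chr1", strand = "+",
               starts = pad, ends = pad + 36, target_class = "essential",
               fitness_score = NA_real_))
  list(ref = ref, proto_start = pad + 13L,
       proto = oracle_revcomp(substr(chrom, pad + 14, pad + 33)))
}

# --- single-codon guide construction for the SGG oracle --------------------
# Embeds ATG AAA <codon> AAA TAA in an A/T chromosome and plants a PAM so
# that a guide's top-ranked editable C sits on the requested codon base:
# 'coding' guides edit a codon C directly; 'template' guides edit the C
# pairing a codon G. Returns NULL when the construction would put extra
# cytosines in the editing window (codons with more than one C resp. G).
codon_guide_ref <- function(codon, offset, mode = c("coding", "template")) {
  mode <- match.arg(mode)
  base <- substr(codon, offset + 1, offset + 1)
  if (mode == "coding" && base != "C") return(NULL)
  if (mode == "template" && base != "G") return(NULL)
  n_target <- sum(strsplit(codon, "")[[1]] ==
                    if (mode == "coding") "C" else "G")
  if (n_target != 1L) return(NULL)
  g0 <- if (mode == "coding") 10L else 30L
  gene <- paste0("ATGAAA", codon, "AAATAA")
  chrom <- paste0(strrep("A", g0), gene,
                  strrep("A", if (mode == "coding") 40 else 30))
  p <- g0 + 6L + offset                      # 0-based target base
  if (mode == "coding") {
    s <- p - 2L                              # target at -18 on + strand
    substr(chrom, s + 21L, s + 23L) <- "AGG"
    strand <- "+"
  } else {
    s <- p - 17L                             # target at -18 on - strand
    substr(chrom, s - 2L, s) <- "CCA"
    strand <- "-"
  }
  ref <- ReferenceSet(
    c(chr1 = chrom),
    data.frame(gene_id = "gz", chrom = "chr1", strand = "+",
               starts = g0, ends = g0 + 15L, target_class = "essential",
               fitness_score = NA_real_))
  cand <- enumerateCandidates(ref)
  hit <- cand[cand$protospacer_start == s &
                cand$protospacer_strand == strand, ]
  if (nrow(hit) != 1L) return(NULL)
  if (!identical(hit$c_positions[[1]], -18L)) return(NULL)
  list(ref = ref, guide = hit, gene = refGenes(ref)[1, ])
}

# Template-strand guide against a TGG tryptophan codon (two guanines, so
# the protospacer shows a CC dinucleotide); top-ranked C pairs the middle G.
codon_guide_ref_tgg <- function() {
  g0 <- 30L
  gene <- "ATGAAATGGAAATAA"
  chrom <- paste0(strrep("A", g0), gene, strrep("A", 30))
  p <- g0 + 7L                               # middle G of TGG
  s <- p - 17L
  substr(chrom, s - 2L, s) <- "CCA"
  ref <- ReferenceSet(
    c(chr1 = chrom),
    data.frame(gene_id = "gz", chrom = "chr1", strand = "+",
               starts = g0, ends = g0 + 15L, target_class = "essential",
               fitness_score = NA_real_))
  cand <- enumerateCandidates(ref)
  hit <- cand[cand$protospacer_start == s &
                cand$protospacer_strand == "-", ]
  stopifnot(nrow(hit) == 1L,
            identical(sort(hit$c_positions[[1]]), c(-19L, -18L)))
  list(ref = ref, guide = hit, gene = refGenes(ref)[1, ])
}

# Expected single-edit outcome codons, computed by string surgery: 'coding'
# edits replace the codon C by G/T; 'template' edits appear as G->C / G->A.
oracle_codon_alts <- function(codon, offset, mode) {
  alts <- if (mode == "coding") c(G = "G", T = "T") else c(G = "C", T = "A")
  vapply(alts, function(b) {
    x <- codon
    substr(x, offset + 1, offset + 1) <- b
    x
  }, "")
}

# --- engineered "filter zoo" gene ------------------------------------------
# One 1200-nt essential gene carrying planted protospacer cassettes, each
# exercising a specific rejection rule. Cassette target C positions sit
# between 0.5% and 75% of the CDS except where the position rule itself is
# under test.
zoo_cassettes <- function() list(
  z_low  = "ACTTTAATTATTAATTATAT",  # C at CDS position 5 of 1200 (< 0.5%)
  z_all3 = "ACCCTTATTAATTTATTAAT",  # C at -19,-18,-17
  z_pair = "ATCCTTATTAATTTATTAAT",  # C at -18,-17
  z_bsai = "ACTTATTAAGGTCTCTTAAT",  # BsaI site in the protospacer
  z_dup  = "ACATTATTAATTATTATTAT",  # planted twice -> not unique
  z_nag  = "ACTAATTATTAATTATTTAT",  # second copy followed by AAG
  z_ok   = "ACTATTAATTATTAATTTAT", # passes every rule
  z_high = "ACTTAATTAATTATTATTAT") # target C past 75% of the CDS

zoo_reference <- function() {
  z <- zoo_cassettes()
  cas <- function(p) paste0(p, "AGG")
  sp <- "TTTT"
  head_part <- paste0("ATG", cas(z$z_low), sp, cas(z$z_all3), sp,
                      cas(z$z_pair), sp, cas(z$z_bsai), sp, cas(z$z_dup),
                      sp, cas(z$z_dup), sp, cas(z$z_nag), sp, cas(z$z_ok),
                      sp, paste0(z$z_nag, "AAG"), sp)
  fill1 <- strrep("AT", (1060 - nchar(head_part)) %/% 2)
  body <- paste0(head_part, fill1, cas(z$z_high))
  tail_len <- 1200 - nchar(body) - 3
  gene <- paste0(body, strrep("TA", tail_len %/% 2),
                 strrep("T", tail_len %% 2), "TAA")
  stopifnot(nchar(gene) == 1200)
  chrom <- paste0("TATATATATA", gene, "TATATATATA")
  ReferenceSet(
    c(chrZ = chrom),
    data.frame(gene_id = "zoo", chrom = "chrZ", strand = "+",
               starts = 10, ends = 1210, target_class = "essential",
               fitness_score = NA_real_))
}

# --- independent brute-force design oracle ---------------------------------
# Re-derives the full candidate list and every filter decision with plain
# string operations; single-interval genes only (all fixtures comply).
oracle_design <- function(ref, lower = 0.005, upper = 0.75) {
  seqs <- as.character(refSequences(ref))
  genes <- refGenes(ref)
  prio <- c(-18, -17, -19, -16, -15, -20, -14)
  occ20 <- character(0); occ3 <- character(0)
  for (cs in seqs) for (s in c(cs, oracle_revcomp(cs))) {
    L <- nchar(s)
    if (L < 23) next
    i <- seq_len(L - 22)
    occ20 <- c(occ20, substring(s, i, i + 19))
    occ3 <- c(occ3, substring(s, i + 21, i + 22))
  }
  out <- list()
  for (chrom in names(seqs)) {
    cs <- seqs[[chrom]]
    L <- nchar(cs)
    for (strand in c("+", "-")) {
      s0 <- if (strand == "+") cs else oracle_revcomp(cs)
      if (L < 23) next
      for (i in seq_len(L - 22)) {
        if (substring(s0, i + 21, i + 22) != "GG") next
        proto <- substring(s0, i, i + 19)
        gstart <- if (strand == "+") i - 1L else L - 20L - (i - 1L)
        for (gi in seq_len(nrow(genes))) {
          g <- genes[gi, ]
          if (g$chrom != chrom) next
          g_s <- g$starts[[1]][1]; g_e <- g$ends[[1]][1]
          if (!(gstart < g_e && gstart + 20L > g_s)) next
          win <- strsplit(substr(proto, 1, 7), "")[[1]]
          cpos <- which(win == "C") - 21L
          high <- cpos[cpos >= -19 & cpos <= -17]
          reasons <- character(0)
          if (!length(high)) reasons <- c(reasons, "no_high_c")
          if (all(c(-19, -18, -17) %in% cpos))
            reasons <- c(reasons, "all_three_high")
          if (all(c(-18, -17) %in% cpos))
            reasons <- c(reasons, "pair_18_17")
          if (grepl("GGTCTC", proto) || grepl("GAGACC", proto))
            reasons <- c(reasons, "bsai")
          hitme <- occ20 == proto
          if (sum(hitme & occ3 == "GG") != 1L)
            reasons <- c(reasons, "not_unique")
          if (sum(hitme & occ3 == "AG") > 0L)
            reasons <- c(reasons, "nag_site")
          if (length(cpos)) {
            top <- prio[prio %in% cpos][1]
            k <- -top
            gp <- if (strand == "+") gstart + 20L - k else gstart + k - 1L
            if (gp < g_s || gp >= g_e) {
              reasons <- c(reasons, "target_outside_cds")
            } else {
              cdspos <- if (g$strand == "+") gp - g_s + 1L else g_e - gp
              frac <- cdspos / (g_e - g_s)
              if (frac < lower) reasons <- c(reasons, "cds_fraction_low")
              if (frac > upper) reasons <- c(reasons, "cds_fraction_high")
            }
          }
          out[[length(out) + 1L]] <- data.frame(
            key = paste(chrom, gstart, strand, g$gene_id, sep = ":"),
            proto = proto, pass = length(reasons) == 0L,
            reasons = paste(sort(reasons), collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}

# two-sample count fixture feeding the synthesis-error detector: one
# mismatch variant of guide gA with the given aggregate read totals
se_fixture <- function(mm_total, perfect_total) {
  perfect <- ScreenCounts(
    matrix(as.integer(c(perfect_total / 2, perfect_total / 2, 50, 50)),
           nrow = 2, byrow = TRUE,
           dimnames = list(c("gA", "gB"), NULL)),
    timepoint = c("T0_mutagenesis", "T_end"), replicate = c("A", "A"))
  mm <- matrix(as.integer(c(mm_total / 2, mm_total / 2)), nrow = 1,
               dimnames = list("gA_v1", NULL))
  meta <- data.frame(variant_id = "gA_v1", parent_guide_id = "gA")
  detectSynthesisErrors(mm, meta, perfect)
}

# choose()-based exhaustive two-sided Fisher oracle for fixed margins.
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  support <- max(0, k - n):min(k, m)
  lp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p <- exp(lp)
  p_obs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# candidate key used to align package output with the oracle
cand_key <- function(cand)
  paste(cand$chrom, cand$protospacer_start, cand$protospacer_strand,
        cand$gene_id, sep = ":")
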