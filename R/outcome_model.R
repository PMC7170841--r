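#' Editing activity profile of the base editor
#'
#' Relative editing activity per PAM-relative window position. Only the rank
#' order of the weights is used by the outcome model; the default ordering
#' places the high-activity window (-19..-17) above all flanking positions,
#' with -18 highest. Weights are editable data, not measured constants.
#'
#' @param weights Named non-negative numeric vector; names are PAM-relative
#'   positions.
#' @param high_window Positions whose weights must strictly exceed all
#'   others (validity check).
#' @return An `ActivityProfile` object.
#' @export
activityProfile <- function(weights = c(`-18` = 1.0, `-17` = 0.9,
                                        `-19` = 0.8, `-16` = 0.3,
                                        `-15` = 0.1, `-20` = 0.1,
                                        `-14` = 0.05),
                            high_window = -19:-17) {
  if (any(weights < 0)) stop("activity weights must be non-negative")
  pos <- as.integer(names(weights))
  hi <- weights[pos %in% high_window]
  lo <- weights[!pos %in% high_window]
  if (length(hi) && length(lo) && min(hi) <= max(lo))
    stop("high-window weights must strictly exceed all other weights")
  structure(list(weights = weights), class = "ActivityProfile")
}

profileWeights <- function(profile, positions) {
  w <- profile$weights[as.character(positions)]
  w[is.na(w)] <- 0
  unname(w)
}

#' Rank editable positions by editing activity
#'
#' Orders PAM-relative cytosine positions by descending activity weight;
#' ties break toward the PAM (the less negative position first).
#'
#' @param c_positions Integer vector of PAM-relative positions.
#' @param profile An [activityProfile()].
#' @return Integer vector, highest-activity position first.
#' @export
rankPositions <- function(c_positions, profile = activityProfile()) {
  if (!length(c_positions)) return(integer(0))
  w <- profileWeights(profile, c_positions)
  c_positions[order(-w, -c_positions)]
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Annotate the protein consequence of coding-strand edits
#'
#' @param edits data.frame with columns `genomic_pos` (0-based) and
#'   `sense_alt` (substituted base on the gene's mRNA-sense strand).
#' @param gene Gene row from [refGenes()].
#' @param reference A [ReferenceSet-class].
#' @return List with `consequence` (`silent`, `missense`, `nonsense`,
#'   `multi` or `intron`) and a data.frame `aa_changes` of
#'   (`residue`, `ref_aa`, `alt_aa`).
#' @export
annotateConsequence <- function(edits, gene, reference) {
  if (gene$target_class %in% c("intron", "putative_peptide") ||
      !gene$target_class %in% CDS_CLASSES)
    return(list(consequence = "intron",
                aa_changes = data.frame(residue = integer(0),
                                        ref_aa = character(0),
                                        alt_aa = character(0))))
  cds <- cdsSequence(reference, gene$gene_id)
  cdspos <- genomicToCds(gene, edits$genomic_pos)
  if (anyNA(cdspos))
    stop("edit at genomic position ",
         paste(edits$genomic_pos[is.na(cdspos)], collapse = ","),
         " lies outside the CDS of ", gene$gene_id)
  mut <- strsplit(cds, "")[[1]]
  ref_bases <- mut[cdspos]
  mut[cdspos] <- edits$sense_alt
  ref_aa_all <- translateCds(cds)
  alt_aa_all <- translateCds(paste(mut, collapse = ""))
  residues <- which(strsplit(ref_aa_all, "")[[1]] !=
                      strsplit(alt_aa_all, "")[[1]])
  aa <- if (length(residues))
    data.frame(residue = residues,
               ref_aa = substring(ref_aa_all, residues, residues),
               alt_aa = substring(alt_aa_all, residues, residues))
  else data.frame(residue = integer(0), ref_aa = character(0),
                  alt_aa = character(0))
  consequence <- if (nrow(aa) == 0L) "silent"
    else if (nrow(aa) >= 2L) "multi"
    else if (aa$alt_aa == "*") "nonsense"
    else "missense"
  list(consequence = consequence, aa_changes = aa, sense_ref = ref_bases)
}

#' Predict the ranked mutational outcome set of a guide
#'
#' The model set holds the C-to-G and C-to-T outcomes at the highest-ranked
#' editable position, plus both outcomes at the second-ranked position when
#' one exists (at most four genotypes). C-to-A products are treated as
#' negligible and never enter the model set. Edits are expressed on the
#' protospacer strand; the coding-strand change (complemented for guides on
#' the template strand) and the protein consequence are annotated per
#' genotype.
#'
#' @param guide One guide row from [buildLibrary()].
#' @param gene The matching gene row.
#' @param reference A [ReferenceSet-class].
#' @param profile An [activityProfile()].
#' @return data.frame, one row per model-set genotype.
#' @export
predictOutcomes <- function(guide, gene, reference,
                            profile = activityProfile()) {
  if (!length(guide$high_c[[1]]))
    stop("guide ", guide$guide_id, " has no high-activity-window cytosine")
  ranked <- rankPositions(guide$c_positions[[1]], profile)
  ranked <- utils::head(ranked, 2L)
  coding <- guide$strand_class == "coding"
  rows <- list()
  is_cds_gene <- gene$target_class %in% CDS_CLASSES
  for (r in seq_along(ranked)) {
    pos <- ranked[r]
    gpos <- guideWindowGenomicPos(guide$protospacer_start,
                                  guide$protospacer_strand, pos)
    stopifnot(substr(guide$protospacer, posToProtoIndex(pos),
                     posToProtoIndex(pos)) == "C")
    # secondary positions can fall outside the CDS near gene edges; such
    # genotypes carry no codon consequence and are left out of the model set
    if (is_cds_gene && is.na(genomicToCds(gene, gpos))) next
    for (alt in c("G", "T")) {
      sense_alt <- if (coding) alt else unname(COMPLEMENT[alt])
      ann <- annotateConsequence(
        data.frame(genomic_pos = gpos, sense_alt = sense_alt),
        gene, reference)
      cdspos <- if (ann$consequence == "intron") NA_integer_
        else genomicToCds(gene, gpos)
      ci <- if (is.na(cdspos)) NA_integer_ else (cdspos - 1L) %/% 3L + 1L
      ref_codon <- alt_codon <- NA_character_
      if (!is.na(ci)) {
        cds <- cdsSequence(reference, gene$gene_id)
        ref_codon <- substr(cds, 3L * ci - 2L, 3L * ci)
        alt_codon <- ref_codon
        off <- cdspos - (3L * ci - 3L)
        substr(alt_codon, off, off) <- sense_alt
      }
      aa <- ann$aa_changes
      rows[[length(rows) + 1L]] <- data.frame(
        guide_id = guide$guide_id, rank = r, position = pos,
        alt = alt, genotype = sprintf("%dC>%s", pos, alt),
        genomic_pos = gpos,
        sense_ref = if (coding) "C" else "G", sense_alt = sense_alt,
        cds_pos = cdspos, codon_index = ci,
        ref_codon = ref_codon, alt_codon = alt_codon,
        ref_aa = if (nrow(aa)) aa$ref_aa[1] else NA_character_,
        alt_aa = if (nrow(aa)) aa$alt_aa[1] else NA_character_,
        consequence = ann$consequence,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Classify a stop-codon-generating guide (SGG)
#'
#' A guide is an SGG when any model-set genotype is a nonsense change. The
#' affected codon is reported on the coding strand; TGG (Trp) is the only
#' codon reached through the template strand (the protospacer then reads
#' CCA over the codon).
#'
#' @inheritParams predictOutcomes
#' @return `NULL` for non-SGG guides, else a list with `codon`, `stop_via`
#'   (`"C>G"` or `"C>T"` on the protospacer strand), `position`, and
#'   `on_noncoding_strand`.
#' @export
classifySgg <- function(guide, gene, reference,
                        profile = activityProfile()) {
  out <- predictOutcomes(guide, gene, reference, profile)
  ns <- out[out$consequence == "nonsense", , drop = FALSE]
  if (nrow(ns) == 0L) return(NULL)
  ns <- ns[1L, ]
  list(codon = ns$ref_codon,
       stop_via = paste0("C>", ns$alt),
       position = ns$position,
       on_noncoding_strand = guide$strand_class == "noncoding")
}

# RNA/DNA hybrid nearest-neighbor parameters (Sugimoto et al. 1995):
# dH kcal/mol, dS cal/(mol K); keyed by the RNA strand 5'->3' written in
# DNA letters (T for U). Initiation: dH 1.9, dS -3.9.
.RNA_DNA_NN <- list(
  dH = c(AA = -7.8, AC = -5.9, AG = -9.1, AT = -8.3,
         CA = -9.0, CC = -9.3, CG = -16.3, CT = -7.0,
         GA = -5.5, GC = -8.0, GG = -12.8, GT = -7.8,
         TA = -7.8, TC = -8.6, TG = -10.4, TT = -11.5),
  dS = c(AA = -21.9, AC = -12.3, AG = -23.5, AT = -23.9,
         CA = -26.1, CC = -23.2, CG = -47.1, CT = -19.7,
         GA = -13.5, GC = -17.1, GG = -31.9, GT = -21.6,
         TA = -23.2, TC = -22.9, TG = -28.4, TT = -36.4),
  init_dH = 1.9, init_dS = -3.9)

#' RNA:DNA duplex melting temperature
#'
#' Nearest-neighbor melting temperature of the guide RNA hybridized to its
#' genomic DNA target, using the published RNA/DNA hybrid parameter set
#' (shipped as data via `nn_table`, overridable). Entropy is optionally
#' salt-corrected (`0.368 * (N-1) * ln[Na+]`), and the two-state Tm uses
#' `CT = dnac1 - dnac2/2` nM for non-self-complementary duplexes.
#'
#' @param seq Nucleotide string (the protospacer, DNA letters).
#' @param dnac1,dnac2 Strand concentrations in nM (defaults 25/25).
#' @param na_mM Monovalent cation concentration in mM (default 50).
#' @param salt_correction Apply the entropic salt correction (default TRUE).
#' @param nn_table Parameter list with elements `dH`, `dS`, `init_dH`,
#'   `init_dS`.
#' @return Melting temperature in degrees Celsius.
#' @export
duplexTm <- function(seq, dnac1 = 25, dnac2 = 25, na_mM = 50,
                     salt_correction = TRUE, nn_table = .RNA_DNA_NN) {
  if (grepl("[^ACGT]", seq))
    stop("duplexTm: bases outside {A,C,G,T}")
  n <- nchar(seq)
  if (n < 2L) stop("sequence too short for nearest-neighbor model")
  di <- substring(seq, 1:(n - 1L), 2:n)
  dH <- nn_table$init_dH + sum(nn_table$dH[di])
  dS <- nn_table$init_dS + sum(nn_table$dS[di])
  if (salt_correction)
    dS <- dS + 0.368 * (n - 1L) * log(na_mM / 1000)
  k <- (dnac1 - dnac2 / 2) * 1e-9
  1000 * dH / (dS + 1.987 * log(k)) - 273.15
}

#' Physical features of a guide
#'
#' @param protospacer 20-nt protospacer string.
#' @param ... Passed to [duplexTm()].
#' @return List with `duplex_tm` (deg C), `gc_fraction`, `c_fraction`,
#'   `g_fraction`.
#' @export
guideFeatures <- function(protospacer, ...) {
  if (nchar(protospacer) != 20L)
    stop("protospacer must be 20 nt")
  ch <- strsplit(protospacer, "")[[1]]
  if (any(!ch %in% c("A", "C", "G", "T")))
    stop("guideFeatures: bases outside {A,C,G,T}")
  list(duplex_tm = duplexTm(protospacer, ...),
       gc_fraction = mean(ch %in% c("G", "C")),
       c_fraction = mean(ch == "C"),
       g_fraction = mean(ch == "G"))
}

#' Model coverage of observed edited genotypes
#'
#' Fraction of edited reads carrying a genotype in the model set.
#'
#' @param observed Named numeric vector: edited genotype -> read count.
#' @param model_set Character vector of model-set genotype names.
#' @return Fraction in `[0, 1]`.
#' @export
modelCoverage <- function(observed, model_set) {
  total <- sum(observed)
  if (!length(observed) || total <= 0)
    stop("model coverage undefined: no edited reads")
  sum(observed[names(observed) %in% model_set]) / total
}

#' Coverage percentile of random genotype combinations
#'
#' Coverage achieved by the q-th percentile of all k-genotype subsets of the
#' observed genotypes; exhaustively enumerated when the number of subsets is
#' at most `exhaustive_cap`, otherwise estimated from `n_samples` seeded
#' random subsets.
#'
#' @param observed Named numeric vector of genotype read counts.
#' @param k Subset size.
#' @param q Percentile in `[0, 1]` (default 0.99).
#' @param n_samples Number of random subsets when sampling.
#' @param seed Optional integer seed for the sampling path.
#' @param exhaustive_cap Maximum number of subsets enumerated exhaustively.
#' @return Coverage threshold (numeric scalar).
#' @export
randomCombinationPercentile <- function(observed, k, q = 0.99,
                                        n_samples = 10000, seed = NULL,
                                        exhaustive_cap = 100000) {
  n <- length(observed)
  if (k > n)
    stop("k = ", k, " exceeds the number of genotypes (", n, ")")
  total <- sum(observed)
  if (total <= 0) stop("no reads in observed genotypes")
  if (choose(n, k) <= exhaustive_cap) {
    cov <- utils::combn(n, k, function(i) sum(observed[i])) / total
  } else {
    if (!is.null(seed)) set.seed(seed)
    cov <- vapply(seq_len(n_samples),
                  function(i) sum(observed[sample.int(n, k)]),
                  numeric(1)) / total
  }
  unname(stats::quantile(cov, q))
}

#' Permutation test of predicted vs observed editing-rank agreement
#'
#' The statistic is the number of sites whose predicted activity rank equals
#' the observed editing-frequency rank; observed ranks are permuted within
#' each guide, and the p-value is `(1 + #{perm >= obs}) / (n_perm + 1)`.
#'
#' @param predicted,observed Lists of per-guide integer rank vectors of
#'   matching lengths.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return List with `statistic`, `p_value`, `n_perm`.
#' @export
rankAgreementTest <- function(predicted, observed, n_perm = 10000,
                              seed = NULL) {
  if (length(predicted) != length(observed) ||
      any(lengths(predicted) != lengths(observed)))
    stop("predicted and observed rank lists must match in shape")
  if (!is.null(seed)) set.seed(seed)
  obs_stat <- sum(mapply(function(p, o) sum(p == o), predicted, observed))
  perm <- vapply(seq_len(n_perm), function(i) {
    sum(mapply(function(p, o) sum(p == sample(o)), predicted, observed))
  }, numeric(1))
  list(statistic = obs_stat,
       p_value = (1 + sum(perm >= obs_stat)) / (n_perm + 1),
       n_perm = n_perm)
}
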