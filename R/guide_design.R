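#' Guide library design configuration
#'
#' Encodes the library-design rules for a Target-AID style cytidine base
#' editor: the extended editing window (PAM-relative positions -20..-14), the
#' high-activity window (-19..-17), the allowed span of the intended edit
#' along the coding sequence, forbidden restriction motifs, and the
#' co-editing risk pattern table.
#'
#' @param extended_window Integer vector of PAM-relative positions scanned
#'   for editable cytosines. Position `-k` is `k` bases 5' of the first PAM
#'   base.
#' @param high_window High-activity positions; every library guide must have
#'   at least one cytosine here.
#' @param cds_fraction_bounds Length-2 numeric; the intended edit must fall
#'   between these fractions of the coding sequence (defaults 0.005 and
#'   0.75, i.e. the 0.5th to 75th percentile of CDS length).
#' @param forbidden_sites Motifs disallowed in the protospacer (default BsaI
#'   GGTCTC and its reverse complement, to protect Golden Gate cloning).
#' @param nag_excluded Discard guides whose protospacer also matches a
#'   genomic site followed by an NAG PAM.
#' @param risk_patterns data.frame with columns `pattern` (7-character
#'   strings over the IUPAC-like alphabet `N` = any, `D` = A/G/T, literal
#'   bases otherwise, spanning positions -20..-14) and `category`. Patterns
#'   are tried in order before the algorithmic fallback of
#'   [assignRiskCategory()].
#' @return A `DesignConfig` list.
#' @export
designConfig <- function(extended_window = -20:-14,
                         high_window = -19:-17,
                         cds_fraction_bounds = c(0.005, 0.75),
                         forbidden_sites = c("GGTCTC", "GAGACC"),
                         nag_excluded = TRUE,
                         risk_patterns = data.frame(
                           pattern = "NCDDDNN",
                           category = "very_low",
                           stringsAsFactors = FALSE)) {
  if (length(cds_fraction_bounds) != 2L ||
      any(cds_fraction_bounds < 0) || any(cds_fraction_bounds > 1) ||
      cds_fraction_bounds[1] >= cds_fraction_bounds[2])
    stop("cds_fraction_bounds must be increasing and within [0, 1]")
  if (!all(high_window %in% extended_window))
    stop("high_window must be contained in extended_window")
  structure(list(extended_window = sort(extended_window),
                 high_window = sort(high_window),
                 cds_fraction_bounds = cds_fraction_bounds,
                 forbidden_sites = toupper(forbidden_sites),
                 nag_excluded = isTRUE(nag_excluded),
                 risk_patterns = risk_patterns),
            class = "DesignConfig")
}

# PAM-relative position of 1-based protospacer string index i: i - 21
# (index 20 abuts the PAM at -1; index 1 is the 5' end at -20).
protoIndexToPos <- function(i) i - 21L
posToProtoIndex <- function(pos) pos + 21L

#' Editable cytosines of a protospacer
#'
#' Reports the PAM-relative positions of cytosines inside the extended
#' editing window and, separately, inside the high-activity window.
#' Position `-1` abuts the PAM; `-20` is the protospacer 5' end.
#'
#' @param protospacer A 20-nt string.
#' @param config A [designConfig()].
#' @return List with integer vectors `extended` and `high`.
#' @export
editableCytosines <- function(protospacer, config = designConfig()) {
  if (nchar(protospacer) != 20L)
    stop("protospacer must be 20 nt, got ", nchar(protospacer))
  idx <- which(strsplit(protospacer, "")[[1]] == "C")
  pos <- protoIndexToPos(idx)
  ext <- pos[pos %in% config$extended_window]
  list(extended = ext, high = ext[ext %in% config$high_window])
}

# All protospacer+PAM candidate sites of one chromosome, both strands.
# Returns 0-based genomic protospacer starts in plus-strand coordinates:
# plus-strand guides have the PAM at [start+20, start+23); minus-strand
# guides at [start-3, start).
scanPamSites <- function(chromseq) {
  L <- nchar(chromseq)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") chromseq else revComp(chromseq)
    if (L < 23L) next
    starts <- seq_len(L - 22L)                      # 1-based in s
    pam <- substring(s, starts + 20L, starts + 22L)
    keep <- substring(pam, 2L, 3L) == "GG"
    if (!any(keep)) next
    st <- starts[keep]
    proto <- substring(s, st, st + 19L)
    gstart <- if (strand == "+") st - 1L else L - 20L - (st - 1L)
    res[[strand]] <- data.frame(protospacer_start = gstart,
                                protospacer_strand = strand,
                                protospacer = proto, pam = pam[keep],
                                stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

# Genomic 0-based coordinate of PAM-relative position -k for a guide.
guideWindowGenomicPos <- function(protospacer_start, strand, pos) {
  k <- -pos
  if (strand == "+") protospacer_start + 20L - k
  else protospacer_start + k - 1L
}

#' Enumerate unfiltered guide candidates
#'
#' Scans the reference for 20-mers adjacent to an NGG PAM on either strand
#' whose protospacer overlaps a gene's footprint, and annotates PAM-relative
#' cytosine positions (computed on the protospacer strand).
#'
#' @param reference A [ReferenceSet-class].
#' @param config A [designConfig()].
#' @return data.frame of candidates, one row per (site, gene); list columns
#'   `c_positions` and `high_c` carry PAM-relative cytosine positions.
#' @export
enumerateCandidates <- function(reference, config = designConfig()) {
  genes <- refGenes(reference)
  out <- list()
  for (chrom in names(refSequences(reference))) {
    gsub_ <- genes[genes$chrom == chrom, , drop = FALSE]
    if (nrow(gsub_) == 0L) next
    sites <- scanPamSites(as.character(refSequences(reference)[[chrom]]))
    if (is.null(sites) || nrow(sites) == 0L) next
    for (gi in seq_len(nrow(gsub_))) {
      g <- gsub_[gi, ]
      st <- g$starts[[1]]; en <- g$ends[[1]]
      ov <- rep(FALSE, nrow(sites))
      for (k in seq_along(st))
        ov <- ov | (sites$protospacer_start < en[k] &
                    sites$protospacer_start + 20L > st[k])
      if (!any(ov)) next
      cand <- sites[ov, , drop = FALSE]
      cand$chrom <- chrom
      cand$gene_id <- g$gene_id
      cand$target_class <- g$target_class
      cand$strand_class <- ifelse(cand$protospacer_strand == g$strand,
                                  "coding", "noncoding")
      cp <- lapply(cand$protospacer, function(p)
        editableCytosines(p, config))
      cand$c_positions <- lapply(cp, `[[`, "extended")
      cand$high_c <- lapply(cp, `[[`, "high")
      out[[length(out) + 1L]] <- cand
    }
  }
  if (!length(out))
    return(data.frame())
  cand <- do.call(rbind, out)
  cand$guide_id <- sprintf("%s_%d%s_%s", cand$chrom,
                           cand$protospacer_start,
                           ifelse(cand$protospacer_strand == "+", "p", "m"),
                           cand$gene_id)
  rownames(cand) <- NULL
  cand[, c("guide_id", "gene_id", "target_class", "chrom",
           "protospacer_start", "protospacer_strand", "strand_class",
           "protospacer", "pam", "c_positions", "high_c")]
}

# Occurrence counts of a protospacer followed by NGG / NAG PAMs across the
# genome, both strands (brute-force exact matching).
genomeMatchCounts <- function(reference, protospacer) {
  ngg <- 0L; nag <- 0L
  for (chrom in as.character(refSequences(reference))) {
    for (s in c(chrom, revComp(chrom))) {
      L <- nchar(s)
      if (L < 23L) next
      starts <- seq_len(L - 22L)
      hits <- substring(s, starts, starts + 19L) == protospacer
      if (!any(hits)) next
      nxt <- substring(s, starts[hits] + 21L, starts[hits] + 22L)
      ngg <- ngg + sum(nxt == "GG")
      nag <- nag + sum(nxt == "AG")
    }
  }
  list(ngg = ngg, nag = nag)
}

#' CDS position fraction of a guide's intended edit
#'
#' Returns the 1-based coordinate of the highest-activity-ranked editable
#' cytosine along the spliced coding sequence, divided by the CDS length.
#' The edit site, not the guide body, determines where a truncation or
#' substitution lands, so the fraction is anchored there.
#'
#' @param candidate One candidate row (from [enumerateCandidates()]).
#' @param gene The matching gene row from [refGenes()].
#' @param profile An [activityProfile()] used to rank editable cytosines.
#' @return Numeric fraction in `[0, 1]`, or `NA` if the ranked cytosine
#'   falls outside the CDS.
#' @export
cdsPositionFraction <- function(candidate, gene,
                                profile = activityProfile()) {
  pos <- rankPositions(candidate$c_positions[[1]], profile)
  if (!length(pos)) stop("candidate has no editable cytosine")
  g <- guideWindowGenomicPos(candidate$protospacer_start,
                             candidate$protospacer_strand, pos[1])
  cdspos <- genomicToCds(gene, g)
  if (is.na(cdspos)) return(NA_real_)
  cdspos / cdsLength(gene)
}

#' Co-editing risk category of an editing-window sequence
#'
#' Categorizes the 7-nt window spanning PAM-relative positions -20..-14 by
#' the risk that a secondary cytosine is co-edited along with the intended
#' target. The configured pattern table is consulted first (`N` = any base,
#' `D` = A/G/T); windows matching no pattern fall back to an activity-weight
#' rule: the primary cytosine is the highest-weight C, and the category
#' grows with the weight of the remaining (secondary) Cs - `very_low` with
#' none, `high` with a secondary C in the high-activity window or a CC
#' dinucleotide, `moderate` with a secondary C at a mid-weight position,
#' `low` otherwise.
#'
#' @param window7 7-character string over positions -20..-14 (the first 7
#'   protospacer bases).
#' @param config A [designConfig()].
#' @param profile An [activityProfile()].
#' @return One of `"very_low"`, `"low"`, `"moderate"`, `"high"`.
#' @export
assignRiskCategory <- function(window7, config = designConfig(),
                               profile = activityProfile()) {
  if (nchar(window7) != 7L)
    stop("risk window must be 7 nt, got ", nchar(window7))
  pats <- config$risk_patterns
  for (i in seq_len(nrow(pats))) {
    if (matchesRiskPattern(window7, pats$pattern[i]))
      return(pats$category[i])
  }
  chars <- strsplit(window7, "")[[1]]
  cpos <- protoIndexToPos(which(chars == "C"))
  cpos <- cpos[cpos %in% config$extended_window]
  if (!length(cpos)) return("very_low")
  w <- profileWeights(profile, cpos)
  primary <- cpos[which.max(w)]
  secondary <- setdiff(cpos, primary)
  if (!length(secondary)) return("very_low")
  has_cc <- grepl("CC", window7, fixed = TRUE)
  if (any(secondary %in% config$high_window) || has_cc) return("high")
  if (any(profileWeights(profile, secondary) > 0.1)) return("moderate")
  "low"
}

matchesRiskPattern <- function(window7, pattern) {
  if (nchar(pattern) != 7L) stop("risk pattern must be 7 characters")
  w <- strsplit(window7, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  all(ifelse(p == "N", TRUE,
             ifelse(p == "D", w %in% c("A", "G", "T"), w == p)))
}

riskLevel <- function(category) {
  match(category, c("very_low", "low", "moderate", "high"))
}

#' Apply the library design filters to one candidate
#'
#' A candidate passes when all of the following hold: at least one cytosine
#' in the high-activity window; not all three of positions -19/-18/-17 are
#' cytosines; positions -18 and -17 are not both cytosines; no forbidden
#' motif in the protospacer; the protospacer+PAM matches the genome exactly
#' once (and, optionally, never with an NAG PAM); and, for CDS target
#' classes, the intended edit lies within the configured CDS fraction
#' bounds. Reason codes enumerate every failed rule.
#'
#' @param candidate One row from [enumerateCandidates()].
#' @param reference The [ReferenceSet-class] scanned.
#' @param config A [designConfig()].
#' @param profile An [activityProfile()].
#' @return List with `pass` (flag), `reasons` (character vector) and
#'   `cds_fraction`.
#' @export
applyDesignFilters <- function(candidate, reference,
                               config = designConfig(),
                               profile = activityProfile()) {
  reasons <- character()
  high <- candidate$high_c[[1]]
  if (!length(high)) reasons <- c(reasons, "no_high_c")
  if (all(c(-19L, -18L, -17L) %in% high))
    reasons <- c(reasons, "all_three_high")
  if (all(c(-18L, -17L) %in% high))
    reasons <- c(reasons, "pair_18_17")
  if (length(high) >= 3L && !("all_three_high" %in% reasons))
    reasons <- c(reasons, "three_in_high")
  for (motif in config$forbidden_sites)
    if (grepl(motif, candidate$protospacer, fixed = TRUE)) {
      reasons <- c(reasons, "bsai")
      break
    }
  mc <- genomeMatchCounts(reference, candidate$protospacer)
  if (mc$ngg != 1L) reasons <- c(reasons, "not_unique")
  if (config$nag_excluded && mc$nag > 0L)
    reasons <- c(reasons, "nag_site")
  frac <- NA_real_
  if (candidate$target_class %in% CDS_CLASSES &&
      length(candidate$c_positions[[1]])) {
    gene <- geneRow(reference, candidate$gene_id)
    frac <- cdsPositionFraction(candidate, gene, profile)
    if (is.na(frac)) reasons <- c(reasons, "target_outside_cds")
    else {
      if (frac < config$cds_fraction_bounds[1])
        reasons <- c(reasons, "cds_fraction_low")
      if (frac > config$cds_fraction_bounds[2])
        reasons <- c(reasons, "cds_fraction_high")
    }
  }
  list(pass = length(reasons) == 0L, reasons = reasons, cds_fraction = frac)
}

#' Build an annotated guide library
#'
#' Runs candidate enumeration and all design filters over a reference and
#' returns the passing guides with co-editing risk categories and CDS
#' fractions. The attached `report` attribute tallies guides per target
#' class, risk category and editable-C count, plus rejections per reason.
#'
#' @param reference A [ReferenceSet-class].
#' @param config A [designConfig()].
#' @param profile An [activityProfile()].
#' @return data.frame of passing guides with attribute `report`.
#' @export
buildLibrary <- function(reference, config = designConfig(),
                         profile = activityProfile()) {
  stopifnot(inherits(config, "DesignConfig"))
  cand <- enumerateCandidates(reference, config)
  if (nrow(cand) == 0L) {
    lib <- cand
    attr(lib, "report") <- list(n_candidates = 0L, n_kept = 0L)
    return(lib)
  }
  res <- lapply(seq_len(nrow(cand)), function(i)
    applyDesignFilters(cand[i, ], reference, config, profile))
  pass <- vapply(res, `[[`, logical(1), "pass")
  cand$cds_fraction <- vapply(res, `[[`, numeric(1), "cds_fraction")
  reject <- table(unlist(lapply(res[!pass], `[[`, "reasons")))
  lib <- cand[pass, , drop = FALSE]
  if (nrow(lib)) {
    lib$risk_category <- vapply(substr(lib$protospacer, 1L, 7L),
                                assignRiskCategory, "", config = config,
                                profile = profile, USE.NAMES = FALSE)
    lib$risk_level <- riskLevel(lib$risk_category)
  }
  rownames(lib) <- NULL
  attr(lib, "report") <- list(
    n_candidates = nrow(cand),
    n_kept = nrow(lib),
    rejections = as.list(reject),
    per_target_class = as.list(table(lib$target_class)),
    per_risk_category = as.list(table(lib$risk_category)),
    per_c_count = as.list(table(lengths(lib$c_positions))))
  lib
}

#' Write / read a guide library as TSV
#'
#' List columns are serialized as comma-separated PAM-relative positions.
#'
#' @param library Guide library data.frame from [buildLibrary()].
#' @param path File path.
#' @return `path` (write) or the library data.frame (read).
#' @export
writeGuideLibrary <- function(library, path) {
  out <- library
  out$c_positions <- vapply(out$c_positions, paste, "", collapse = ",")
  out$high_c <- vapply(out$high_c, paste, "", collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGuideLibrary
#' @export
readGuideLibrary <- function(path) {
  lib <- utils::read.delim(path, stringsAsFactors = FALSE)
  lib$c_positions <- lapply(strsplit(as.character(lib$c_positions), ","),
                            as.integer)
  lib$high_c <- lapply(strsplit(as.character(lib$high_c), ","), as.integer)
  lib
}
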