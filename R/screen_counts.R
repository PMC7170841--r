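#' Match sequencing reads to a guide library
#'
#' Reads (pre-trimmed to the 20-nt variable region) are matched exactly
#' first; reads at Hamming distance 1 from exactly one library guide become
#' mismatch records (candidate synthesis or sequencing errors); everything
#' else is unassigned. Assigned + unassigned always equals the input count.
#'
#' @param reads Character vector of read sequences.
#' @param guides Named character vector `guide_id -> 20-nt protospacer`, or
#'   a guide library data.frame with `guide_id` and `protospacer` columns.
#' @return List with `perfect` (named integer counts per guide),
#'   `mismatches` (data.frame: `parent_guide_id`, `variant_sequence`,
#'   `position`, `observed_base`, `reads`), and `unassigned` (integer).
#' @export
matchReads <- function(reads, guides) {
  if (is.data.frame(guides))
    guides <- stats::setNames(guides$protospacer, guides$guide_id)
  perfect <- stats::setNames(integer(length(guides)), names(guides))
  tab <- table(reads)
  useq <- names(tab)
  ucnt <- as.integer(tab)
  hit <- match(useq, guides)
  exact <- !is.na(hit)
  agg <- tapply(ucnt[exact], names(guides)[hit[exact]], sum)
  perfect[names(agg)] <- as.integer(agg)
  unassigned <- 0L
  mm <- list()
  for (i in which(!exact)) {
    r <- useq[i]
    if (nchar(r) != 20L) {
      unassigned <- unassigned + ucnt[i]
      next
    }
    cand <- hamming1Hits(r, guides)
    if (length(cand$guide) == 1L) {
      mm[[length(mm) + 1L]] <- data.frame(
        parent_guide_id = cand$guide, variant_sequence = r,
        position = cand$position, observed_base = cand$base,
        reads = ucnt[i], stringsAsFactors = FALSE)
    } else {
      unassigned <- unassigned + ucnt[i]
    }
  }
  mismatches <- if (length(mm)) do.call(rbind, mm) else
    data.frame(parent_guide_id = character(0),
               variant_sequence = character(0), position = integer(0),
               observed_base = character(0), reads = integer(0))
  list(perfect = perfect, mismatches = mismatches, unassigned = unassigned)
}

# Guides at Hamming distance exactly 1 from read r (20 nt).
hamming1Hits <- function(r, guides) {
  hits <- character(0); pos <- integer(0); base <- character(0)
  for (p in 1:20) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(r, p, p))) {
      v <- r
      substr(v, p, p) <- b
      j <- match(v, guides)
      if (!is.na(j)) {
        hits <- c(hits, names(guides)[j])
        pos <- c(pos, p)
        base <- c(base, substr(r, p, p))
      }
    }
  }
  list(guide = unique(hits),
       position = if (length(unique(hits)) == 1L) pos[1] else integer(0),
       base = if (length(unique(hits)) == 1L) base[1] else character(0))
}

#' Detect synthesis-error (SE) guides among mismatch variants
#'
#' A mismatch variant whose read total, aggregated across all samples,
#' exceeds `ratio_threshold` times the parent guide's perfect-match total is
#' called a synthesis error rather than a recurring sequencing error. SE
#' variant reads are removed from the parent and kept as separate SE guide
#' rows (null controls); non-SE mismatch reads are credited to the parent.
#' Variants with mismatch reads but zero perfect parent reads are SE by
#' convention (infinite ratio).
#'
#' @param mismatch_counts Integer matrix, variants x samples; rownames are
#'   variant ids.
#' @param variant_meta data.frame with columns `variant_id`,
#'   `parent_guide_id` (and optionally `variant_sequence`, `position`,
#'   `observed_base`), one row per row of `mismatch_counts`.
#' @param perfect A [ScreenCounts-class] of perfect-match counts.
#' @param ratio_threshold SE ratio rule (default 0.075; strictly greater
#'   flags SE).
#' @param abundant_threshold Total-read rule for the abundant-SE null
#'   controls (default 1000; strictly greater flags abundant).
#' @return List with `se_set` (data.frame: variant, parent, ratio, totals,
#'   `abundant` flag) and `corrected` (a [ScreenCounts-class] with non-SE
#'   mismatch reads folded into parents and SE variants appended as rows
#'   flagged `is_se`).
#' @export
detectSynthesisErrors <- function(mismatch_counts, variant_meta, perfect,
                                  ratio_threshold = 0.075,
                                  abundant_threshold = 1000) {
  m <- as.matrix(mismatch_counts)
  stopifnot(nrow(m) == nrow(variant_meta))
  pm <- countMatrix(perfect)
  if (!all(variant_meta$parent_guide_id %in% rownames(pm)))
    stop("mismatch variants reference unknown parent guides")
  parent_tot <- rowSums(pm)[variant_meta$parent_guide_id]
  var_tot <- rowSums(m)
  ratio <- ifelse(parent_tot > 0, var_tot / parent_tot, Inf)
  is_se <- ratio > ratio_threshold
  se_set <- data.frame(
    variant_id = variant_meta$variant_id[is_se],
    parent_guide_id = variant_meta$parent_guide_id[is_se],
    ratio = ratio[is_se], total_reads = var_tot[is_se],
    abundant = var_tot[is_se] > abundant_threshold,
    stringsAsFactors = FALSE)
  corrected <- pm
  keep <- which(!is_se)
  for (i in keep) {
    p <- variant_meta$parent_guide_id[i]
    corrected[p, ] <- corrected[p, ] + m[i, ]
  }
  se_rows <- m[is_se, , drop = FALSE]
  rownames(se_rows) <- variant_meta$variant_id[is_se]
  out <- rbind(corrected, se_rows)
  cd <- SummarizedExperiment::colData(perfect)
  list(se_set = se_set,
       corrected = ScreenCounts(out, cd$timepoint, cd$replicate,
                                is_se = c(isSeGuide(perfect),
                                          rep(TRUE, nrow(se_rows)))))
}

#' Drop guides absent from more than half of the samples
#'
#' A guide with zero reads in strictly more than half of the samples is
#' removed before abundance calculations.
#'
#' @param counts A [ScreenCounts-class].
#' @return The filtered [ScreenCounts-class].
#' @export
filterPresence <- function(counts) {
  m <- countMatrix(counts)
  if (ncol(m) < 2L) stop("presence filter needs at least 2 samples")
  keep <- rowSums(m == 0L) <= ncol(m) / 2
  counts[keep, ]
}

#' Guides passing the minimal read threshold at a time point
#'
#' A guide is eligible for fitness analysis when its count is at least
#' `threshold` (inclusive) in every replicate at the stated time point.
#' The default of 54 reads at the mutagenesis step trades the number of
#' analyzable guides against inter-replicate reproducibility.
#'
#' @param counts A [ScreenCounts-class].
#' @param timepoint Time point at which the threshold applies.
#' @param threshold Minimal read count (inclusive).
#' @return Character vector of eligible guide ids.
#' @export
filterMinReads <- function(counts, timepoint = "T0_mutagenesis",
                           threshold = 54) {
  cd <- SummarizedExperiment::colData(counts)
  reps <- unique(cd$replicate)
  cols <- lapply(reps, function(r) which(cd$timepoint == timepoint &
                                           cd$replicate == r))
  if (any(lengths(cols) == 0L))
    stop("time point ", timepoint, " missing in replicate ",
         paste(reps[lengths(cols) == 0L], collapse = ", "))
  m <- countMatrix(counts)
  ok <- Reduce(`&`, lapply(cols, function(j)
    apply(m[, j, drop = FALSE] >= threshold, 1, all)))
  rownames(m)[ok]
}

#' Write / read a ScreenCounts table as TSV
#'
#' Sample columns are named `<timepoint>.<replicate>`.
#'
#' @param counts A [ScreenCounts-class] (write) or file path (read).
#' @param path File path.
#' @return `path` (write) or a [ScreenCounts-class] (read).
#' @export
writeCountTable <- function(counts, path) {
  m <- countMatrix(counts)
  cd <- SummarizedExperiment::colData(counts)
  out <- data.frame(guide_id = rownames(m), is_se = isSeGuide(counts), m,
                    check.names = FALSE)
  colnames(out)[-(1:2)] <- paste(cd$timepoint, cd$replicate, sep = ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountTable
#' @export
readCountTable <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(m) <- tab$guide_id
  parts <- strsplit(colnames(m), ".", fixed = TRUE)
  ScreenCounts(m, timepoint = vapply(parts, `[`, "", 1),
               replicate = vapply(parts, `[`, "", 2),
               is_se = as.logical(tab$is_se))
}
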