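#' Log2 change in relative guide abundance
#'
#' `delta_log2 = log2(count_t1 / total_t1) - log2(count_t0 / total_t0)`,
#' comparing the relative abundance of a guide barcode at the end of the
#' bulk competition (`t1`) with its abundance after mutagenesis (`t0`). A
#' zero count at `t1` (and only there) is replaced by 0.5 before the ratio;
#' nonzero counts are never perturbed.
#'
#' @param count_t1,count_t0 Guide read counts (vectorized).
#' @param total_t1,total_t0 Per-sample total read counts.
#' @return Numeric vector of log2 abundance changes.
#' @export
deltaLog2 <- function(count_t1, total_t1, count_t0, total_t0) {
  if (any(total_t1 <= 0) || any(total_t0 <= 0))
    stop("sample totals must be positive")
  if (any(count_t0 <= 0))
    stop("zero count at t0; guides must pass the minimal read threshold")
  c1 <- ifelse(count_t1 == 0, 0.5, count_t1)
  log2(c1 / total_t1) - log2(count_t0 / total_t0)
}

#' Within-replicate z-scores of abundance changes
#'
#' Standardizes each replicate's delta-log2 distribution over all eligible
#' guides (synthesis-error guides included) using the sample mean and
#' standard deviation, then averages z-scores across replicates.
#'
#' @param deltas Numeric matrix, guides x replicates, of [deltaLog2()]
#'   values.
#' @return List with `z` (matrix, same shape) and `z_avg` (named vector).
#' @export
zscoreReplicates <- function(deltas) {
  deltas <- as.matrix(deltas)
  if (nrow(deltas) < 3L)
    stop("need at least 3 guides per replicate to standardize")
  z <- apply(deltas, 2, function(d) {
    s <- stats::sd(d)
    if (!is.finite(s) || s == 0)
      stop("degenerate delta-log2 distribution (sd = 0)")
    (d - mean(d)) / s
  })
  rownames(z) <- rownames(deltas)
  list(z = z, z_avg = rowMeans(z))
}

#' Fit the synthesis-error null distribution
#'
#' Maximum-likelihood Gaussian fit (mean and population standard deviation)
#' to the averaged z-scores of abundant synthesis-error guides, which carry
#' no editing activity and therefore trace abundance variation with no
#' fitness effect.
#'
#' @param z_avg_se Averaged z-scores of abundant SE guides.
#' @param min_n Minimum number of SE guides required (default 10).
#' @return An `SeNullModel` list with `mu`, `sigma`, `n`.
#' @export
fitSeNull <- function(z_avg_se, min_n = 10) {
  z_avg_se <- z_avg_se[is.finite(z_avg_se)]
  if (length(z_avg_se) < min_n)
    stop("need at least ", min_n, " abundant SE guides, got ",
         length(z_avg_se))
  mu <- mean(z_avg_se)
  sigma <- sqrt(mean((z_avg_se - mu)^2))
  if (sigma == 0) stop("SE z-scores are all identical; cannot fit null")
  structure(list(mu = mu, sigma = sigma, n = length(z_avg_se)),
            class = "SeNullModel")
}

#' False-positive and false-discovery rates at a z threshold
#'
#' Under the SE null `N(mu, sigma)`, the false positive rate at threshold
#' `t` is `Phi((t - mu) / sigma)`; the expected number of false positives
#' is `fpr * n_tested`, and the FDR divides it by the number of observed
#' hits at or below `t` (`Inf` with no hits).
#'
#' @param t Numeric vector of z-score thresholds.
#' @param null An [fitSeNull()] model.
#' @param z_avg_tested Averaged z-scores of the tested (non-SE) guides.
#' @return data.frame with columns `t`, `fpr`, `expected_fp`, `n_hits`,
#'   `fdr`.
#' @export
fdrAtThreshold <- function(t, null, z_avg_tested) {
  fpr <- stats::pnorm((t - null$mu) / null$sigma)
  expected_fp <- fpr * length(z_avg_tested)
  n_hits <- vapply(t, function(ti) sum(z_avg_tested <= ti), numeric(1))
  data.frame(t = t, fpr = fpr, expected_fp = expected_fp, n_hits = n_hits,
             fdr = ifelse(n_hits > 0, expected_fp / n_hits, Inf))
}

#' Call guides with significant negative fitness effects (GNEs)
#'
#' Sets the z-score threshold to the largest observed averaged z-score whose
#' estimated FDR is at or below `fdr_target`, then calls every non-SE guide
#' at or below the threshold a GNE (guide with negative effect); all other
#' guides are NSGs. Synthesis-error guides are controls and never receive
#' GNE calls.
#'
#' @param z_avg Named numeric vector of averaged z-scores (all guides,
#'   SE included).
#' @param is_se Logical vector marking SE guides.
#' @param null An [fitSeNull()] model.
#' @param fdr_target Target false discovery rate (default 0.10).
#' @return List with `calls` (data.frame: `guide_id`, `z_avg`, `is_se`,
#'   `call`), `z_threshold`, `fdr_at_threshold`, `fdr_target`, `n_tested`.
#' @export
callGnes <- function(z_avg, is_se, null, fdr_target = 0.10) {
  tested <- z_avg[!is_se]
  cand <- sort(unique(tested))
  fdr <- fdrAtThreshold(cand, null, tested)
  ok <- fdr$t[fdr$fdr <= fdr_target]
  if (!length(ok)) {
    warning("no threshold achieves FDR <= ", fdr_target, "; zero GNEs")
    thr <- -Inf
    fdr_thr <- NA_real_
  } else {
    thr <- max(ok)
    fdr_thr <- fdr$fdr[match(thr, fdr$t)]
  }
  calls <- data.frame(
    guide_id = names(z_avg), z_avg = unname(z_avg), is_se = is_se,
    call = ifelse(!is_se & z_avg <= thr, "GNE", "NSG"),
    stringsAsFactors = FALSE)
  list(calls = calls, z_threshold = thr, fdr_at_threshold = fdr_thr,
       fdr_target = fdr_target, n_tested = length(tested))
}

#' Full fitness analysis of a screen count table
#'
#' Convenience wrapper chaining presence filtering, the minimal read
#' threshold, per-replicate [deltaLog2()] and [zscoreReplicates()], the
#' abundant-SE null fit and [callGnes()].
#'
#' @param counts A [ScreenCounts-class] with `T0_mutagenesis` and `T_end`
#'   samples in each replicate.
#' @param min_reads Minimal T0 read count per replicate (default 54).
#' @param fdr_target Target FDR (default 0.10).
#' @param abundant_threshold SE guides with more total reads than this are
#'   used for the null fit (default 1000).
#' @return The [callGnes()] result, augmented with `delta_log2` and `z`
#'   matrices, the `null` model, and `eligible` guide ids.
#' @export
fitnessAnalysis <- function(counts, min_reads = 54, fdr_target = 0.10,
                            abundant_threshold = 1000) {
  counts <- filterPresence(counts)
  eligible <- filterMinReads(counts, threshold = min_reads)
  if (!length(eligible)) stop("no guides pass the minimal read threshold")
  counts <- counts[rownames(counts) %in% eligible, ]
  m <- countMatrix(counts)
  cd <- SummarizedExperiment::colData(counts)
  totals <- colSums(m)
  reps <- sort(unique(cd$replicate))
  deltas <- vapply(reps, function(r) {
    j0 <- which(cd$timepoint == "T0_mutagenesis" & cd$replicate == r)
    j1 <- which(cd$timepoint == "T_end" & cd$replicate == r)
    if (length(j0) != 1L || length(j1) != 1L)
      stop("replicate ", r, " must have exactly one T0_mutagenesis and ",
           "one T_end sample")
    deltaLog2(m[, j1], totals[j1], m[, j0], totals[j0])
  }, numeric(nrow(m)))
  zs <- zscoreReplicates(deltas)
  is_se <- isSeGuide(counts)
  abundant_se <- is_se & rowSums(m) > abundant_threshold
  null <- fitSeNull(zs$z_avg[abundant_se])
  res <- callGnes(zs$z_avg, is_se, null, fdr_target)
  res$delta_log2 <- deltas
  res$z <- zs$z
  res$null <- null
  res$eligible <- rownames(m)
  res$n_abundant_se <- sum(abundant_se)
  res
}

#' Write a fitness call table as TSV
#'
#' @param result A [fitnessAnalysis()] (or [callGnes()]) result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFitnessCalls <- function(result, path) {
  out <- result$calls
  if (!is.null(result$delta_log2)) {
    colnames(result$delta_log2) <- paste0("delta_log2_",
                                          colnames(result$delta_log2))
    colnames(result$z) <- paste0("z_", colnames(result$z))
    out <- cbind(out, result$delta_log2[out$guide_id, , drop = FALSE],
                 result$z[out$guide_id, , drop = FALSE])
  }
  out$z_threshold <- result$z_threshold
  out$fdr_target <- result$fdr_target
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
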