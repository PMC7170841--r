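#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric two-sided p-value (the sum of probabilities of all
#' tables with the observed margins whose point probability does not exceed
#' that of the observed table) and the sample odds ratio `ad / bc` (`Inf`
#' when `bc = 0`).
#'
#' @param table 2x2 matrix (or length-4 vector `a, b, c, d` filled by row):
#'   rows are groups (e.g. GNE / NSG), columns property presence.
#' @return List with `odds_ratio` and `p_value`.
#' @examples
#' fisher2x2(matrix(c(12, 696, 251, 15795), 2, 2, byrow = TRUE))
#' @export
fisher2x2 <- function(table) {
  x <- as.vector(t(as.matrix(table)))
  if (length(x) != 4L) stop("fisher2x2 expects a 2x2 table")
  if (any(x < 0) || any(x != round(x)))
    stop("fisher2x2: entries must be non-negative integers")
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  list(odds_ratio = or, p_value = min(1, p))
}

#' Holm-Bonferroni step-down rejections
#'
#' Standard step-down familywise-error control: p-values are sorted
#' ascending and rejected while `p(i) <= alpha / (m - i + 1)`, stopping at
#' the first failure.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha Familywise error level (default 0.05).
#' @param method `"holm"` (default) or `"BH"` for a Benjamini-Hochberg
#'   false-discovery-rate alternative.
#' @return Logical rejection flags, same length and order as `p_values`.
#' @export
holmBonferroni <- function(p_values, alpha = 0.05, method = c("holm", "BH")) {
  method <- match.arg(method)
  if (!length(p_values)) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = method) <= alpha
}

#' Mutational pattern key of a guide
#'
#' The paired C-to-G / C-to-T outcome notation (e.g. `"G>R/S"` for a glycine
#' codon whose first-ranked edit yields arginine via C-to-G and serine via
#' C-to-T; `*` marks stops). Guides targeting introns or putative peptides
#' map to their target class.
#'
#' @param outcomes A [predictOutcomes()] data.frame for one guide.
#' @param target_class The guide's target class.
#' @return Single pattern key string.
#' @export
patternKey <- function(outcomes, target_class = "essential") {
  if (target_class %in% c("intron", "putative_peptide"))
    return(target_class)
  r1 <- outcomes[outcomes$rank == 1L, ]
  aaOf <- function(alt) {
    row <- r1[r1$alt == alt, ]
    if (!nrow(row)) return("?")
    if (row$consequence[1] == "silent" || is.na(row$alt_aa[1]))
      translateCds(row$ref_codon[1])
    else row$alt_aa[1]
  }
  ref <- translateCds(r1$ref_codon[1])
  sprintf("%s>%s/%s", ref, aaOf("G"), aaOf("T"))
}

#' Substitution-pattern enrichment of GNEs versus NSGs
#'
#' For every pattern key, builds the 2x2 table (pattern vs not, GNE vs NSG),
#' computes the fold change of pattern share among GNEs over NSGs and the
#' two-sided Fisher p-value, and applies Holm-Bonferroni across all
#' patterns.
#'
#' @param gne_keys,nsg_keys Character vectors of [patternKey()] values, one
#'   per guide.
#' @param alpha Familywise error level for the step-down correction.
#' @return data.frame with `pattern`, counts, `fold`, `p_value`,
#'   `rejected`.
#' @export
patternEnrichment <- function(gne_keys, nsg_keys, alpha = 0.05) {
  if (!length(gne_keys) || !length(nsg_keys))
    stop("both GNE and NSG sets must be non-empty")
  pats <- sort(unique(c(gne_keys, nsg_keys)))
  n_g <- length(gne_keys); n_n <- length(nsg_keys)
  rows <- lapply(pats, function(p) {
    a <- sum(gne_keys == p); c_ <- sum(nsg_keys == p)
    ft <- fisher2x2(matrix(c(a, n_g - a, c_, n_n - c_), 2, 2, byrow = TRUE))
    share_g <- a / n_g; share_n <- c_ / n_n
    data.frame(pattern = p, gne_count = a, nsg_count = c_,
               fold = if (share_n > 0) share_g / share_n else Inf,
               p_value = ft$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rejected <- holmBonferroni(out$p_value, alpha)
  out
}

#' Annotation (binding site / PTM) enrichment around target residues
#'
#' Splits guides into on-site (edited residue annotated), near-site (within
#' `window_aa` residues of an annotation but not on it) and off-annotation
#' classes, and tests on-site and near-site GNE ratios against the
#' off-annotation guides with two-sided Fisher's exact tests.
#'
#' @param guides data.frame with columns `gene_id`, `residue` (1-based
#'   target residue index) and `call` (`"GNE"`/`"NSG"`).
#' @param site_annotations data.frame with columns `gene_id`, `residue`
#'   (and optionally `kind`). Annotations for genes absent from `guides`
#'   are skipped with a warning.
#' @param window_aa Near-site half-window in residues (default 2,
#'   inclusive).
#' @return List with per-class counts/ratios and the `on` and `near` test
#'   results.
#' @export
annotationEnrichment <- function(guides, site_annotations, window_aa = 2) {
  unknown <- setdiff(site_annotations$gene_id, guides$gene_id)
  if (length(unknown)) {
    warning("annotations for unknown gene(s) skipped: ",
            paste(unknown, collapse = ", "))
    site_annotations <- site_annotations[
      !site_annotations$gene_id %in% unknown, , drop = FALSE]
  }
  class_of <- vapply(seq_len(nrow(guides)), function(i) {
    ann <- site_annotations$residue[
      site_annotations$gene_id == guides$gene_id[i]]
    if (!length(ann)) return("off")
    d <- abs(ann - guides$residue[i])
    if (any(d == 0)) "on"
    else if (any(d <= window_aa) && window_aa > 0) "near"
    else "off"
  }, character(1))
  is_gne <- guides$call == "GNE"
  cnt <- function(cl) c(gne = sum(is_gne & class_of == cl),
                        nsg = sum(!is_gne & class_of == cl))
  on <- cnt("on"); near <- cnt("near"); off <- cnt("off")
  test <- function(x) {
    tab <- matrix(c(x["gne"], off["gne"], x["nsg"], off["nsg"]),
                  2, 2, byrow = TRUE)
    c(list(table = tab), fisher2x2(tab))
  }
  list(classes = class_of,
       counts = list(on = on, near = near, off = off),
       ratios = list(on = unname(on["gne"] / sum(on)),
                     near = unname(near["gne"] / sum(near)),
                     off = unname(off["gne"] / sum(off))),
       on = test(on), near = test(near))
}

#' Welch comparison of a guide feature between GNEs and NSGs
#'
#' @param gne_values,nsg_values Numeric vectors (at least 2 values each).
#' @return List with `t`, `p_value`, `means`, `medians`.
#' @export
featureComparison <- function(gne_values, nsg_values) {
  if (length(gne_values) < 2L || length(nsg_values) < 2L)
    stop("need at least 2 values per group")
  if (stats::var(gne_values) == 0 && stats::var(nsg_values) == 0)
    stop("degenerate (zero-variance) feature in both groups")
  tt <- stats::t.test(gne_values, nsg_values, var.equal = FALSE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       means = c(gne = mean(gne_values), nsg = mean(nsg_values)),
       medians = c(gne = stats::median(gne_values),
                   nsg = stats::median(nsg_values)))
}

#' Per-bin GNE enrichment along a guide feature
#'
#' Bins guides by a feature (e.g. duplex melting temperature) and reports
#' each bin's GNE ratio divided by the overall GNE ratio.
#'
#' @param values Numeric feature per guide.
#' @param is_gne Logical per guide.
#' @param breaks Bin edges covering the feature range (passed to [cut()]).
#' @return data.frame with per-bin counts, GNE ratio and enrichment.
#' @export
gneRatioByBin <- function(values, is_gne, breaks) {
  bins <- cut(values, breaks, include.lowest = TRUE)
  if (anyNA(bins)) stop("breaks do not cover the feature range")
  overall <- mean(is_gne)
  agg <- data.frame(bin = levels(bins))
  agg$n <- as.integer(table(bins))
  agg$gne <- as.integer(tapply(is_gne, bins, sum, default = 0L))
  agg$ratio <- ifelse(agg$n > 0, agg$gne / agg$n, NA_real_)
  agg$enrichment <- agg$ratio / overall
  agg
}

#' Spearman rank correlation between a feature and counts
#'
#' @param x,y Numeric vectors.
#' @return List with `rho` and `p_value`.
#' @export
featureCorrelation <- function(x, y) {
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
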