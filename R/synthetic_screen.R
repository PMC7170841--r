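#' Generate a random reference genome with gene models
#'
#' Builds random coding sequences (start codon, no internal stops, stop
#' codon) at a target GC content, places them on a single chromosome with
#' random intergenic spacers and alternating strands, and labels a fraction
#' essential (remaining genes are `no_effect` with fitness 1.0).
#'
#' @param n_genes Number of genes.
#' @param length_range CDS length range in nt (rounded to codons).
#' @param gc Target GC fraction.
#' @param essential_fraction Fraction of genes labeled essential.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param spacer_length Intergenic spacer length in nt.
#' @return A [ReferenceSet-class].
#' @export
generateReference <- function(n_genes = 3, length_range = c(300, 600),
                              gc = 0.4, essential_fraction = 0.8, seed = 1,
                              spacer_length = 60) {
  if (n_genes < 1 || any(length_range < 9) ||
      length_range[1] > length_range[2] || gc <= 0 || gc >= 1 ||
      essential_fraction < 0 || essential_fraction > 1)
    stop("invalid reference generation parameters")
  set.seed(seed)
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  rbases <- function(n) sample(names(base_p), n, replace = TRUE,
                               prob = base_p)
  stops <- c("TAA", "TAG", "TGA")
  randCds <- function(len_nt) {
    n_codon <- max(3L, round(len_nt / 3))
    mid <- character(n_codon - 2L)
    for (i in seq_along(mid)) {
      repeat {
        cod <- paste(rbases(3), collapse = "")
        if (!cod %in% stops) break
      }
      mid[i] <- cod
    }
    paste0("ATG", paste(mid, collapse = ""), sample(stops, 1))
  }
  lens <- sample(seq(length_range[1], length_range[2]), n_genes,
                 replace = TRUE)
  cds <- vapply(lens, randCds, "")
  strands <- rep(c("+", "-"), length.out = n_genes)
  chrom <- paste(rbases(spacer_length), collapse = "")
  starts <- integer(n_genes); ends <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    insert <- if (strands[i] == "+") cds[i] else revComp(cds[i])
    starts[i] <- nchar(chrom)
    chrom <- paste0(chrom, insert, paste(rbases(spacer_length),
                                         collapse = ""))
    ends[i] <- starts[i] + nchar(insert)
  }
  n_ess <- round(n_genes * essential_fraction)
  classes <- c(rep("essential", n_ess),
               rep("no_effect", n_genes - n_ess))
  scores <- c(rep(NA_real_, n_ess), rep(1.0, n_genes - n_ess))
  ReferenceSet(
    c(chr1 = chrom),
    data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)),
               chrom = "chr1", strand = strands,
               starts = I(as.list(starts)), ends = I(as.list(ends)),
               target_class = classes, fitness_score = scores,
               stringsAsFactors = FALSE))
}

#' Ground-truth parameters for a simulated screen
#'
#' Assigns each guide an editing rate and a selection coefficient `s`
#' (relative growth-rate deficit of the edited subpopulation; 1 = lethal),
#' and fixes the outcome spectrum, synthesis-error fraction, sequencing
#' depth and number of generations. Defaults mirror the regime the screen
#' design targets: editing rates centered on 0.5-0.9, ~3% synthesis-error
#' guides, depth of a few hundred reads per guide, 10 generations of bulk
#' competition and two replicates.
#'
#' @param guide_ids Character vector of guide identifiers.
#' @param seed Integer seed; all downstream simulation randomness derives
#'   from it.
#' @param lethal_fraction Fraction of guides whose edited outcome is lethal
#'   (`s = 1`).
#' @param moderate_fraction Fraction with a moderate deficit `moderate_s`.
#' @param moderate_s Selection coefficient of the moderate class.
#' @param editing_rate_range Editing rates are drawn uniformly from this
#'   range.
#' @param spectrum Outcome spectrum weights `(cg, ct, ca, multi)`, summing
#'   to 1.
#' @param se_fraction Fraction of guides receiving an injected
#'   synthesis-error variant (editing-inactive).
#' @param depth_per_guide Expected sequencing depth per guide per sample.
#' @param generations Generations of growth between T0 and T_end.
#' @return A `SimTruth` list.
#' @export
simTruth <- function(guide_ids, seed = 1, lethal_fraction = 0.05,
                     moderate_fraction = 0, moderate_s = 0.3,
                     editing_rate_range = c(0.5, 0.9),
                     spectrum = c(cg = 0.45, ct = 0.45, ca = 0.05,
                                  multi = 0.05),
                     se_fraction = 0.03, depth_per_guide = 300,
                     generations = 10) {
  if (abs(sum(spectrum) - 1) > 1e-8)
    stop("spectrum weights must sum to 1")
  if (depth_per_guide <= 0) stop("depth must be positive")
  set.seed(seed)
  n <- length(guide_ids)
  s <- rep(0, n)
  n_lethal <- round(n * lethal_fraction)
  n_mod <- round(n * moderate_fraction)
  idx <- sample.int(n, n_lethal + n_mod)
  s[idx[seq_len(n_lethal)]] <- 1
  if (n_mod > 0) s[idx[n_lethal + seq_len(n_mod)]] <- moderate_s
  structure(list(
    guides = data.frame(
      guide_id = guide_ids,
      editing_rate = stats::runif(n, editing_rate_range[1],
                                  editing_rate_range[2]),
      s = s, stringsAsFactors = FALSE),
    spectrum = spectrum, se_fraction = se_fraction,
    depth_per_guide = depth_per_guide, generations = generations,
    seed = seed), class = "SimTruth")
}

#' Simulate a pooled base-editing competition screen
#'
#' Each guide's cell subpopulation is a mixture of unedited cells (relative
#' fitness 1) and edited cells (fitness `1 - s`) at the guide's editing
#' rate. Subpopulations grow deterministically and exponentially over the
#' configured generations; sequencing reads are drawn multinomially at each
#' sample's depth for two time points and two replicates. Synthesis-error
#' variants (Hamming-1 neighbors with editing rate 0) are injected at the
#' truth's `se_fraction`, at abundances comparable to their parents.
#'
#' @param library Guide library data.frame (needs `guide_id`; `protospacer`
#'   used for SE variant sequences when present) or a character vector of
#'   guide ids.
#' @param truth A [simTruth()] object for the library's guides.
#' @return List with `counts` (a [ScreenCounts-class] including SE guide
#'   rows), `se_guides` (data.frame of injected variants) and `truth`.
#' @export
simulateScreen <- function(library, truth) {
  ids <- if (is.data.frame(library)) library$guide_id else library
  if (!length(ids)) stop("library is empty")
  stopifnot(identical(ids, truth$guides$guide_id))
  set.seed(truth$seed)
  n <- length(ids)
  # post-cloning abundance heterogeneity; kept modest (cv ~ 25%) so that
  # multinomial sampling noise stays near-homogeneous across guides and the
  # abundant-SE null remains representative of the tested population
  a0 <- stats::rlnorm(n, meanlog = 0, sdlog = 0.25)
  n_se <- round(n * truth$se_fraction)
  se_parent <- if (n_se > 0) sample.int(n, n_se) else integer(0)
  se_ids <- character(0); se_seq <- rep(NA_character_, n_se)
  if (n_se > 0) {
    se_ids <- paste0(ids[se_parent], "_se")
    if (is.data.frame(library) && "protospacer" %in% names(library)) {
      se_seq <- vapply(library$protospacer[se_parent], function(p) {
        pos <- sample.int(20, 1)
        b <- sample(setdiff(c("A", "C", "G", "T"),
                            substr(p, pos, pos)), 1)
        substr(p, pos, pos) <- b
        p
      }, "", USE.NAMES = FALSE)
    }
    a0 <- c(a0, a0[se_parent] * stats::runif(n_se, 0.8, 1.2))
  }
  e <- c(truth$guides$editing_rate, rep(0, n_se))
  s <- c(truth$guides$s, rep(0, n_se))
  # relative growth of the edited/unedited mixture over g generations
  w <- (1 - e) + e * 2^(-s * truth$generations)
  all_ids <- c(ids, se_ids)
  depth <- round(truth$depth_per_guide * length(all_ids))
  samples <- expand.grid(replicate = c("A", "B"),
                         timepoint = c("T0_mutagenesis", "T_end"),
                         stringsAsFactors = FALSE)
  m <- matrix(0L, nrow = length(all_ids), ncol = nrow(samples),
              dimnames = list(all_ids, paste(samples$timepoint,
                                             samples$replicate,
                                             sep = "_")))
  for (j in seq_len(nrow(samples))) {
    p <- if (samples$timepoint[j] == "T0_mutagenesis") a0 else a0 * w
    m[, j] <- as.integer(stats::rmultinom(1, depth, p / sum(p)))
  }
  counts <- ScreenCounts(m, samples$timepoint, samples$replicate,
                         is_se = c(rep(FALSE, n), rep(TRUE, n_se)))
  list(counts = counts,
       se_guides = data.frame(variant_id = se_ids,
                              parent_guide_id = ids[se_parent],
                              variant_sequence = se_seq,
                              stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate per-genotype amplicon read counts for one guide
#'
#' Draws edited reads across single- and multi-edit genotypes according to
#' the truth's outcome spectrum and the activity-weighted position ranks,
#' emulating deep sequencing of the edited locus.
#'
#' @param guide One guide row from [buildLibrary()] (needs `c_positions`),
#'   or an integer vector of editable PAM-relative positions.
#' @param truth A [simTruth()] object (spectrum weights used); the guide's
#'   editing rate is looked up by id when present, else `editing_rate`.
#' @param n_reads Total reads sequenced.
#' @param editing_rate Editing rate override.
#' @param profile An [activityProfile()].
#' @param seed Optional integer seed.
#' @return Named integer vector: genotype label -> read count (edited
#'   genotypes only; empty when nothing is edited).
#' @export
simulateAmpliconGenotypes <- function(guide, truth, n_reads = 10000,
                                      editing_rate = NULL,
                                      profile = activityProfile(),
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- if (is.numeric(guide)) as.integer(guide)
    else guide$c_positions[[1]]
  if (!length(pos)) stop("guide has no editable cytosine")
  if (is.null(editing_rate)) {
    editing_rate <- if (!is.numeric(guide) &&
                        guide$guide_id %in% truth$guides$guide_id)
      truth$guides$editing_rate[match(guide$guide_id,
                                      truth$guides$guide_id)]
    else stop("editing_rate not found in truth; supply it explicitly")
  }
  n_edit <- stats::rbinom(1, n_reads, editing_rate)
  if (n_edit == 0) return(stats::setNames(integer(0), character(0)))
  sp <- truth$spectrum
  multi_ok <- length(pos) >= 2L
  p_multi <- if (multi_ok) sp[["multi"]] else 0
  w <- profileWeights(profile, pos)
  if (all(w == 0)) w <- rep(1, length(pos))
  alt_p <- c(G = sp[["cg"]], T = sp[["ct"]], A = sp[["ca"]])
  alt_p <- alt_p / sum(alt_p)
  labels <- character(n_edit)
  is_multi <- stats::runif(n_edit) < p_multi
  for (i in seq_len(n_edit)) {
    k <- if (is_multi[i]) 2L else 1L
    at <- sort(pos[sample.int(length(pos), k, prob = w)])
    alts <- sample(names(alt_p), k, replace = TRUE, prob = alt_p)
    labels[i] <- paste(sprintf("%dC>%s", at, alts), collapse = ",")
  }
  tab <- table(labels)
  stats::setNames(as.integer(tab), names(tab))
}

#' Write / read simulation ground truth as JSON
#'
#' The round trip is lossless.
#'
#' @param truth A [simTruth()] object (write) or file path (read).
#' @param path File path.
#' @return `path` (write) or a `SimTruth` (read).
#' @export
writeSimTruth <- function(truth, path) {
  x <- unclass(truth)
  x$spectrum <- as.list(x$spectrum)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSimTruth
#' @export
readSimTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$guides <- as.data.frame(x$guides, stringsAsFactors = FALSE)
  x$spectrum <- unlist(x$spectrum)
  for (f in c("se_fraction", "depth_per_guide", "generations", "seed"))
    x[[f]] <- as.numeric(x[[f]])
  structure(x, class = "SimTruth")
}
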