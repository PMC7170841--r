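#' Run the screen pipeline from a single configuration
#'
#' Chains the analysis stages in dependency order - guide design, screen
#' simulation (or count-table loading), fitness statistics, and pattern
#' enrichment - writing each stage's artifacts (TSV/JSON) to the output
#' directory together with run metadata (seed, configuration hash, package
#' version). All randomness flows from the single configuration seed, so
#' two runs with the same configuration produce identical artifacts.
#'
#' The configuration is a named list (or path to a YAML file) with fields:
#' \describe{
#'   \item{seed}{Integer seed (required).}
#'   \item{outdir}{Output directory (required; created if missing).}
#'   \item{stages}{Subset of `design`, `simulate`, `fitness`, `enrich`
#'     (default all). `counts` may replace `simulate` with
#'     `counts_table` pointing at a TSV from [writeCountTable()].}
#'   \item{reference}{Either `generate: <args for [generateReference()]>`
#'     or `fasta:`/`genes:` paths.}
#'   \item{design}{Arguments for [designConfig()].}
#'   \item{simulate}{Arguments for [simTruth()].}
#'   \item{fitness}{`min_reads`, `fdr_target`.}
#' }
#'
#' @param config Named list or path to a YAML configuration file.
#' @param outdir,seed Optional overrides of the configuration fields.
#' @return Invisibly, a list of stage results and artifact paths.
#' @export
runPipeline <- function(config, outdir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config) || !length(config))
    stop("config: must be a non-empty named list or YAML file")
  if (!is.null(outdir)) config$outdir <- outdir
  if (!is.null(seed)) config$seed <- seed
  for (field in c("seed", "outdir"))
    if (is.null(config[[field]]))
      stop("config: required field '", field, "' is missing")
  config$seed <- as.integer(config$seed)
  stages <- config$stages %||% c("design", "simulate", "fitness", "enrich")
  bad <- setdiff(stages, c("design", "simulate", "counts", "fitness",
                           "enrich"))
  if (length(bad))
    stop("config: unknown stage(s) in 'stages': ",
         paste(bad, collapse = ", "))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  res <- list(config = config)
  logmsg <- function(...) message("[pipeline] ", ...)

  if ("design" %in% stages || "simulate" %in% stages) {
    refcfg <- config$reference %||% list(generate = list())
    if (!is.null(refcfg$generate)) {
      args <- refcfg$generate
      args$seed <- args$seed %||% config$seed
      res$reference <- do.call(generateReference, args)
    } else {
      for (f in c("fasta", "genes"))
        if (is.null(refcfg[[f]]))
          stop("config: reference needs 'generate' or both 'fasta' and ",
               "'genes'; missing '", f, "'")
      res$reference <- loadGeneTable(refcfg$genes,
                                     readFastaRef(refcfg$fasta))
    }
    logmsg("reference: ", nrow(refGenes(res$reference)), " genes")
  }

  if ("design" %in% stages) {
    dcfg <- do.call(designConfig, config$design %||% list())
    res$library <- buildLibrary(res$reference, dcfg)
    paths$library <- file.path(config$outdir, "guide_library.tsv")
    writeGuideLibrary(res$library, paths$library)
    report <- attr(res$library, "report")
    paths$design_report <- file.path(config$outdir, "design_report.json")
    jsonlite::write_json(report, paths$design_report, auto_unbox = TRUE)
    logmsg("design: ", nrow(res$library), " guides kept of ",
           report$n_candidates, " candidates")
  }

  if ("simulate" %in% stages) {
    if (is.null(res$library)) stop("simulate stage requires design stage")
    args <- config$simulate %||% list()
    args$guide_ids <- res$library$guide_id
    args$seed <- args$seed %||% config$seed
    truth <- do.call(simTruth, args)
    sim <- simulateScreen(res$library, truth)
    res$counts <- sim$counts
    res$truth <- truth
    paths$counts <- file.path(config$outdir, "counts.tsv")
    writeCountTable(sim$counts, paths$counts)
    paths$truth <- file.path(config$outdir, "truth.json")
    writeSimTruth(truth, paths$truth)
    logmsg("simulate: ", nrow(res$counts), " guide rows (",
           sum(isSeGuide(res$counts)), " SE)")
  } else if ("counts" %in% stages) {
    if (is.null(config$counts_table))
      stop("config: counts stage requires 'counts_table'")
    if (!file.exists(config$counts_table))
      stop("missing upstream artifact: ", config$counts_table)
    res$counts <- readCountTable(config$counts_table)
  }

  if ("fitness" %in% stages) {
    if (is.null(res$counts))
      stop("fitness stage requires counts (simulate or counts stage)")
    fcfg <- config$fitness %||% list()
    res$fitness <- fitnessAnalysis(
      res$counts, min_reads = fcfg$min_reads %||% 54,
      fdr_target = fcfg$fdr_target %||% 0.10)
    paths$fitness <- file.path(config$outdir, "fitness_calls.tsv")
    writeFitnessCalls(res$fitness, paths$fitness)
    n_gne <- sum(res$fitness$calls$call == "GNE")
    logmsg("fitness: ", n_gne, " GNEs at z <= ",
           signif(res$fitness$z_threshold, 4))
    if (!is.null(res$truth)) {
      truth_s <- res$truth$guides$s[match(res$fitness$calls$guide_id,
                                          res$truth$guides$guide_id)]
      called <- res$fitness$calls$call == "GNE"
      planted <- !is.na(truth_s) & truth_s > 0
      res$truth_comparison <- list(
        sensitivity = if (any(planted)) mean(called[planted]) else NA,
        realized_fdr = if (any(called))
          mean(!planted[called]) else NA,
        n_planted_eligible = sum(planted), n_called = sum(called))
      paths$truth_comparison <- file.path(config$outdir,
                                          "truth_comparison.json")
      jsonlite::write_json(res$truth_comparison, paths$truth_comparison,
                           auto_unbox = TRUE, digits = NA)
    }
  }

  if ("enrich" %in% stages) {
    if (is.null(res$fitness) || is.null(res$library))
      stop("enrich stage requires design and fitness stages")
    keys <- guidePatternKeys(res$library, res$reference)
    calls <- res$fitness$calls
    calls <- calls[!calls$is_se & calls$guide_id %in% names(keys), ]
    gne <- keys[calls$guide_id[calls$call == "GNE"]]
    nsg <- keys[calls$guide_id[calls$call == "NSG"]]
    if (length(gne) && length(nsg)) {
      res$enrichment <- patternEnrichment(gne, nsg)
      paths$enrichment <- file.path(config$outdir,
                                    "pattern_enrichment.tsv")
      utils::write.table(res$enrichment, paths$enrichment, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      logmsg("enrich: ", sum(res$enrichment$rejected),
             " pattern(s) significant")
    } else logmsg("enrich: skipped (empty GNE or NSG set)")
  }

  meta <- list(seed = config$seed,
               config_hash = rlang::hash(config),
               package_version = as.character(utils::packageVersion(
                 "baseEditScreen")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               stages = stages)
  paths$metadata <- file.path(config$outdir, "run_metadata.json")
  jsonlite::write_json(meta, paths$metadata, auto_unbox = TRUE)
  res$paths <- paths
  invisible(res)
}

#' Pattern keys for every guide of a library
#'
#' @param library Guide library data.frame.
#' @param reference The matching [ReferenceSet-class].
#' @param profile An [activityProfile()].
#' @return Named character vector guide_id -> pattern key.
#' @export
guidePatternKeys <- function(library, reference,
                             profile = activityProfile()) {
  keys <- vapply(seq_len(nrow(library)), function(i) {
    g <- library[i, ]
    if (g$target_class %in% c("intron", "putative_peptide"))
      return(g$target_class)
    out <- tryCatch(
      predictOutcomes(g, geneRow(reference, g$gene_id), reference,
                      profile),
      error = function(e) NULL)
    if (is.null(out) || !nrow(out)) return(NA_character_)
    patternKey(out, g$target_class)
  }, character(1))
  names(keys) <- library$guide_id
  keys[!is.na(keys)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
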