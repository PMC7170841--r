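#' @import methods
#' @importFrom Biostrings DNAStringSet
NULL

CDS_CLASSES <- c("essential", "high_effect", "no_effect")
TARGET_CLASSES <- c(CDS_CLASSES, "intron", "putative_peptide")

#' Reference sequences plus gene models
#'
#' A `ReferenceSet` bundles chromosome sequences with a table of gene models.
#' Gene coordinates are 0-based half-open internally; human-readable exports
#' use 1-based inclusive coordinates.
#'
#' The `genes` data.frame carries one row per gene with columns `gene_id`,
#' `chrom`, `strand` (`"+"`/`"-"`), `starts`/`ends` (list columns of integer
#' vectors, ascending genomic order), `target_class` (one of `essential`,
#' `high_effect`, `no_effect`, `intron`, `putative_peptide`) and
#' `fitness_score` (relative deletion fitness in `[0, 1.1]`, `NA` allowed).
#'
#' @slot sequences A [Biostrings::DNAStringSet] of chromosome sequences.
#' @slot genes A data.frame of gene models (see Details).
#'
#' @export
setClass("ReferenceSet",
  representation(sequences = "DNAStringSet", genes = "data.frame"))

validReferenceSet <- function(object) {
  msg <- character()
  seqs <- object@sequences
  genes <- object@genes
  if (length(seqs) == 0L)
    msg <- c(msg, "no sequences")
  if (anyDuplicated(names(seqs)))
    msg <- c(msg, "duplicate sequence identifiers")
  letters_ok <- vapply(as.character(seqs), function(s)
    !grepl("[^ACGTN]", s), logical(1))
  if (!all(letters_ok))
    msg <- c(msg, "sequences contain bases outside {A,C,G,T,N}")
  need <- c("gene_id", "chrom", "strand", "starts", "ends", "target_class",
            "fitness_score")
  if (!all(need %in% names(genes))) {
    msg <- c(msg, paste("genes table missing columns:",
                        paste(setdiff(need, names(genes)), collapse = ", ")))
  } else if (nrow(genes) > 0L) {
    if (anyDuplicated(genes$gene_id))
      msg <- c(msg, "duplicate gene_id")
    if (!all(genes$strand %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-'")
    if (!all(genes$target_class %in% TARGET_CLASSES))
      msg <- c(msg, paste("target_class must be one of:",
                          paste(TARGET_CLASSES, collapse = ", ")))
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      st <- g$starts[[1]]; en <- g$ends[[1]]
      if (length(st) != length(en) || any(en <= st)) {
        msg <- c(msg, sprintf("gene %s: malformed intervals", g$gene_id))
        next
      }
      if (is.unsorted(st) || (length(st) > 1L && any(st[-1] < en[-length(en)])))
        msg <- c(msg, sprintf(
          "gene %s: intervals must be sorted and non-overlapping", g$gene_id))
      if (!g$chrom %in% names(seqs)) {
        msg <- c(msg, sprintf("gene %s: unknown chromosome %s",
                              g$gene_id, g$chrom))
        next
      }
      clen <- Biostrings::width(seqs[g$chrom])
      if (min(st) < 0L || max(en) > clen)
        msg <- c(msg, sprintf(
          "gene %s: interval [%d,%d) outside chromosome %s (length %d)",
          g$gene_id, min(st), max(en), g$chrom, clen))
      if (g$target_class %in% CDS_CLASSES && sum(en - st) %% 3L != 0L)
        msg <- c(msg, sprintf(
          "gene %s: CDS length %d not a multiple of 3", g$gene_id,
          sum(en - st)))
      fs <- g$fitness_score
      if (!is.na(fs)) {
        if (fs < 0 || fs > 1.1)
          msg <- c(msg, sprintf("gene %s: fitness_score outside [0,1.1]",
                                g$gene_id))
        if (fs < 0.75 && g$target_class %in% CDS_CLASSES &&
            g$target_class != "high_effect")
          msg <- c(msg, sprintf(
            "gene %s: fitness_score %.3f < 0.75 requires target_class high_effect",
            g$gene_id, fs))
        if (fs >= 0.999 && fs <= 1.001 && g$target_class %in% CDS_CLASSES &&
            g$target_class != "no_effect")
          msg <- c(msg, sprintf(
            "gene %s: fitness_score %.3f in [0.999,1.001] requires target_class no_effect",
            g$gene_id, fs))
      }
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("ReferenceSet", validReferenceSet)

#' Construct a ReferenceSet
#'
#' @param sequences Named character vector or [Biostrings::DNAStringSet] of
#'   chromosome sequences.
#' @param genes Gene model data.frame (see [ReferenceSet-class]). `starts`
#'   and `ends` may be plain integers (single-interval genes) or list columns.
#' @return A validated [ReferenceSet-class] object.
#' @examples
#' ref <- ReferenceSet(
#'   c(chr1 = "ATGGCTTGGTAA"),
#'   data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
#'              starts = 0, ends = 12, target_class = "essential",
#'              fitness_score = NA))
#' @export
ReferenceSet <- function(sequences, genes) {
  if (!is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  if (!is.list(genes$starts)) genes$starts <- as.list(as.integer(genes$starts))
  if (!is.list(genes$ends)) genes$ends <- as.list(as.integer(genes$ends))
  genes$starts <- lapply(genes$starts, as.integer)
  genes$ends <- lapply(genes$ends, as.integer)
  if (is.null(genes$fitness_score)) genes$fitness_score <- NA_real_
  rownames(genes) <- genes$gene_id
  new("ReferenceSet", sequences = sequences, genes = genes)
}

#' @describeIn ReferenceSet Accessor for the chromosome sequences.
#' @param x,object A `ReferenceSet`.
#' @export
refSequences <- function(x) x@sequences

#' @describeIn ReferenceSet Accessor for the gene table.
#' @export
refGenes <- function(x) x@genes

setMethod("show", "ReferenceSet", function(object) {
  cat("ReferenceSet with", length(object@sequences), "sequence(s) and",
      nrow(object@genes), "gene(s)\n")
  cat("  chromosomes:",
      paste(utils::head(names(object@sequences), 5), collapse = ", "), "\n")
  if (nrow(object@genes))
    cat("  target classes:",
        paste(names(table(object@genes$target_class)), collapse = ", "), "\n")
})

#' Guide-count container for a pooled screen
#'
#' `ScreenCounts` is a [SummarizedExperiment::SummarizedExperiment] with a
#' single integer `counts` assay (guides x samples), required `colData`
#' columns `timepoint` (one of `T0_mutagenesis`, `T_end`) and `replicate`,
#' and a logical `rowData` column `is_se` flagging synthesis-error guides.
#'
#' @export
setClass("ScreenCounts", contains = "SummarizedExperiment")

setValidity("ScreenCounts", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("missing 'counts' assay")
  m <- SummarizedExperiment::assay(object, "counts")
  if (any(m < 0)) msg <- c(msg, "negative counts")
  if (any(m != round(m))) msg <- c(msg, "non-integer counts")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("timepoint", "replicate") %in% names(cd)))
    msg <- c(msg, "colData must contain 'timepoint' and 'replicate'")
  else if (!all(cd$timepoint %in% c("T0_mutagenesis", "T_end")))
    msg <- c(msg, "timepoint must be 'T0_mutagenesis' or 'T_end'")
  if (!"is_se" %in% names(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must contain logical 'is_se'")
  if (length(msg)) msg else TRUE
})

#' Construct a ScreenCounts object
#'
#' @param counts Integer matrix, guides in rows (rownames = guide ids),
#'   samples in columns.
#' @param timepoint Character vector per sample, `"T0_mutagenesis"` or
#'   `"T_end"`.
#' @param replicate Character vector per sample (e.g. `"A"`, `"B"`).
#' @param is_se Logical per guide; `TRUE` marks synthesis-error guides kept
#'   as null controls. Default all `FALSE`.
#' @return A [ScreenCounts-class] object.
#' @export
ScreenCounts <- function(counts, timepoint, replicate,
                         is_se = rep(FALSE, nrow(counts))) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(colnames(counts)))
    colnames(counts) <- paste(timepoint, replicate, sep = "_")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(timepoint = timepoint,
                                   replicate = replicate,
                                   row.names = colnames(counts)),
    rowData = S4Vectors::DataFrame(is_se = is_se,
                                   row.names = rownames(counts)))
  new("ScreenCounts", se)
}

#' @describeIn ScreenCounts The guide x sample count matrix.
#' @param x A `ScreenCounts`.
#' @export
countMatrix <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn ScreenCounts Per-sample total read counts (column sums).
#' @export
sampleTotals <- function(x) colSums(countMatrix(x))

#' @describeIn ScreenCounts Logical vector flagging synthesis-error guides.
#' @export
isSeGuide <- function(x) SummarizedExperiment::rowData(x)$is_se

setMethod("show", "ScreenCounts", function(object) {
  cat("ScreenCounts:", nrow(object), "guides x", ncol(object), "samples\n")
  cd <- SummarizedExperiment::colData(object)
  cat("  samples:", paste(paste(cd$timepoint, cd$replicate, sep = "/"),
                          collapse = ", "), "\n")
  cat("  synthesis-error guides:", sum(isSeGuide(object)), "\n")
})
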