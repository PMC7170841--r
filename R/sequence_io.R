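#' Read reference sequences from a FASTA file
#'
#' Sequences are uppercased; `N` is allowed. Duplicate record identifiers and
#' empty files are hard errors.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
readFastaRef <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- toupper(as.character(seqs))
  names(out) <- ids
  bad <- grepl("[^ACGTN]", out)
  if (any(bad))
    stop("sequence(s) with bases outside {A,C,G,T,N}: ",
         paste(ids[bad], collapse = ", "))
  out
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector or DNAStringSet.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFastaRef <- function(sequences, path) {
  if (!is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' Derive a fitness target class from a deletion fitness score
#'
#' Genes with a (media/replicate-averaged) deletion fitness score below 0.75
#' are classed `high_effect`; scores between 0.999 and 1.001 are
#' `no_effect`. Scores outside those ranges carry no defined class and
#' require an explicit `target_class`.
#'
#' @param fitness_score Numeric vector of fitness scores in `[0, 1.1]`.
#' @return Character vector of target classes.
#' @export
deriveTargetClass <- function(fitness_score) {
  out <- rep(NA_character_, length(fitness_score))
  out[!is.na(fitness_score) & fitness_score < 0.75] <- "high_effect"
  out[!is.na(fitness_score) & fitness_score >= 0.999 &
        fitness_score <= 1.001] <- "no_effect"
  if (anyNA(out))
    stop("fitness score(s) outside the classifiable ranges ",
         "(< 0.75 or [0.999, 1.001]); supply target_class explicitly")
  out
}

#' Load a gene annotation table
#'
#' Reads a tab-separated table with header columns `gene_id`, `chrom`,
#' `strand`, `starts`, `ends` (0-based half-open, comma-separated for
#' multi-interval CDSs), and optionally `target_class` and `fitness_score`.
#' When `target_class` is absent it is derived from `fitness_score` via
#' [deriveTargetClass()].
#'
#' @param path Path to the TSV file.
#' @param sequences Named character vector (or DNAStringSet) of chromosome
#'   sequences used to validate gene bounds.
#' @return A validated [ReferenceSet-class] object.
#' @export
loadGeneTable <- function(path, sequences) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("gene_id", "chrom", "strand", "starts", "ends")
  if (!all(need %in% names(tab)))
    stop("gene table missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  genes <- data.frame(gene_id = tab$gene_id, chrom = tab$chrom,
                      strand = tab$strand, stringsAsFactors = FALSE)
  genes$starts <- lapply(strsplit(tab$starts, ","), as.integer)
  genes$ends <- lapply(strsplit(tab$ends, ","), as.integer)
  genes$fitness_score <- if ("fitness_score" %in% names(tab))
    suppressWarnings(as.numeric(tab$fitness_score)) else NA_real_
  genes$target_class <- if ("target_class" %in% names(tab) &&
                            !all(tab$target_class == ""))
    tab$target_class else deriveTargetClass(genes$fitness_score)
  ReferenceSet(sequences, genes)
}

#' Write the gene table of a ReferenceSet to TSV
#'
#' @param ref A [ReferenceSet-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(ref, path) {
  g <- refGenes(ref)
  out <- data.frame(
    gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
    starts = vapply(g$starts, paste, "", collapse = ","),
    ends = vapply(g$ends, paste, "", collapse = ","),
    target_class = g$target_class, fitness_score = g$fitness_score)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reverse complement
#'
#' Vectorized reverse complement over the `{A,C,G,T,N}` alphabet.
#'
#' @param seq Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @examples
#' revComp("ACC")  # "GGT"
#' @export
revComp <- function(seq) {
  if (any(grepl("[^ACGTN]", seq)))
    stop("revComp: bases outside {A,C,G,T,N}")
  out <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seq)))
  names(out) <- names(seq)
  out
}

#' Translate a coding sequence with the standard genetic code
#'
#' Stop codons are rendered as `*`. The input length must be a multiple of
#' three; ambiguous bases are an error.
#'
#' @param cds_seq A nucleotide string over `{A,C,G,T}`.
#' @return Amino-acid string.
#' @examples
#' translateCds("ATGTGGTAA")  # "MW*"
#' @export
translateCds <- function(cds_seq) {
  if (nchar(cds_seq) %% 3L != 0L)
    stop("CDS length ", nchar(cds_seq), " is not a multiple of 3")
  if (grepl("[^ACGT]", cds_seq))
    stop("translateCds: ambiguous or invalid base in CDS")
  as.character(Biostrings::translate(Biostrings::DNAString(cds_seq),
                                     no.init.codon = TRUE))
}

#' Spliced coding sequence of a gene
#'
#' Concatenates the gene's intervals and reverse-complements for minus-strand
#' genes, yielding the mRNA-sense coding sequence.
#'
#' @param ref A [ReferenceSet-class].
#' @param gene_id Gene identifier.
#' @return Nucleotide string.
#' @export
cdsSequence <- function(ref, gene_id) {
  g <- geneRow(ref, gene_id)
  chrom <- as.character(refSequences(ref)[[g$chrom]])
  parts <- mapply(function(s, e) substr(chrom, s + 1L, e),
                  g$starts[[1]], g$ends[[1]])
  s <- paste(parts, collapse = "")
  if (g$strand == "-") revComp(s) else s
}

geneRow <- function(ref, gene_id) {
  g <- refGenes(ref)
  i <- match(gene_id, g$gene_id)
  if (is.na(i)) stop("unknown gene: ", gene_id)
  g[i, ]
}

cdsLength <- function(gene) sum(gene$ends[[1]] - gene$starts[[1]])

# Map a 0-based genomic position to a 1-based coordinate along the spliced
# CDS (transcription order); NA when the position is not inside the gene.
genomicToCds <- function(gene, gpos) {
  st <- gene$starts[[1]]; en <- gene$ends[[1]]
  offs <- cumsum(c(0L, (en - st)[-length(st)]))
  out <- rep(NA_integer_, length(gpos))
  for (k in seq_along(st)) {
    hit <- gpos >= st[k] & gpos < en[k]
    out[hit] <- offs[k] + (gpos[hit] - st[k]) + 1L
  }
  if (gene$strand == "-") {
    total <- sum(en - st)
    out <- ifelse(is.na(out), NA_integer_, total - out + 1L)
  }
  out
}
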