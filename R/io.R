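#' Read coding sequences from FASTA
#'
#' Records are canonicalized on read: bases uppercased and RNA `U` converted
#' to DNA `T` (sense-strand convention, `T` standing for `U` in reported
#' skews). Duplicate ids are an error; an empty file yields an empty set.
#'
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet] named by the first whitespace-token
#'   of each header.
#' @export
readCds <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(Biostrings::DNAStringSet())
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- chartr("uU", "TT", toupper(as.character(raw)))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param records a [Biostrings::DNAStringSet] (or coercible named character
#'   vector).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCds <- function(records, path) {
  if (!methods::is(records, "XStringSet"))
    records <- Biostrings::DNAStringSet(records)
  Biostrings::writeXStringSet(records, path)
  invisible(path)
}

#' Extract coding sequences from contigs using GFF3 features
#'
#' Pulls CDS features out of assembled contigs: minus-strand features are
#' reverse-complemented, the GFF3 `phase` offset is trimmed from the coding
#' 5' end, and any resulting sequence whose length is not a multiple of 3
#' (a partial gene call at a contig edge, typically) is excluded and
#' counted rather than silently dropped.
#'
#' @param contigs a [Biostrings::DNAStringSet] or FASTA path.
#' @param features GFF3 path or a [GenomicRanges::GRanges] with an `ID` (or
#'   `Name`) metadata column; coordinates 1-based inclusive.
#' @param type feature type to keep (default "CDS"; use NULL to keep all).
#' @return A [Biostrings::DNAStringSet] of in-frame CDS named by feature id,
#'   with attribute `"n_excluded"` giving the count of length-excluded
#'   features.
#' @export
extractCds <- function(contigs, features, type = "CDS") {
  if (is.character(contigs)) contigs <- readCds(contigs)
  if (is.character(features))
    features <- rtracklayer::import(features, format = "gff3")
  if (!is.null(type) && "type" %in% names(S4Vectors::mcols(features))) {
    keep <- as.character(features$type) %in% type
    if (any(keep)) features <- features[keep]
  }
  ids <- S4Vectors::mcols(features)$ID
  if (is.null(ids)) ids <- S4Vectors::mcols(features)$Name
  if (is.null(ids)) ids <- paste0("feature_", seq_along(features))
  ids <- as.character(ids)

  ctg_len <- setNames(Biostrings::width(contigs), names(contigs))
  seqn <- as.character(GenomicRanges::seqnames(features))
  st <- GenomicRanges::start(features)
  en <- GenomicRanges::end(features)
  strand <- as.character(GenomicRanges::strand(features))
  unknown <- !(seqn %in% names(contigs))
  if (any(unknown))
    stop("feature(s) on unknown contig: ",
         paste(ids[unknown], collapse = ", "))
  oob <- st < 1L | en > ctg_len[seqn]
  if (any(oob))
    stop("feature(s) beyond contig bounds: ",
         paste(ids[oob], collapse = ", "))
  if (any(!strand %in% c("+", "-")))
    stop("feature(s) without strand: ",
         paste(ids[!strand %in% c("+", "-")], collapse = ", "))

  phase <- S4Vectors::mcols(features)$phase
  if (is.null(phase)) phase <- rep(0L, length(features))
  phase <- as.integer(phase)
  phase[is.na(phase)] <- 0L

  seqs <- character(length(features))
  for (i in seq_along(features)) {
    s <- Biostrings::subseq(contigs[[seqn[i]]], st[i], en[i])
    if (strand[i] == "-") s <- Biostrings::reverseComplement(s)
    if (phase[i] > 0L) s <- Biostrings::subseq(s, phase[i] + 1L)
    seqs[i] <- as.character(s)
  }
  in_frame <- nchar(seqs) %% 3L == 0L & nchar(seqs) > 0L
  out <- Biostrings::DNAStringSet(seqs[in_frame])
  names(out) <- ids[in_frame]
  if (anyDuplicated(names(out)))
    stop("duplicate feature ids after extraction")
  attr(out, "n_excluded") <- sum(!in_frame)
  out
}

#' Read the gene annotation table
#'
#' Tab-separated with header and columns `gene_id`, `taxon_id`, `ko_id`,
#' `pathway_tags` (semicolon-separated tags; empty allowed). Optional extra
#' columns (e.g. `phylum`) are carried through.
#'
#' @param path TSV path.
#' @return data.frame keyed by `gene_id`, with `pathway_tags` as a list
#'   column of character vectors.
#' @export
readAnnotations <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "taxon_id", "ko_id", "pathway_tags")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("annotation table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene_id in annotation table")
  tab$pathway_tags <- lapply(strsplit(as.character(tab$pathway_tags), ";",
                                      fixed = TRUE),
                             function(x) x[nzchar(x)])
  rownames(tab) <- tab$gene_id
  tab
}

#' Read per-gene read depths
#'
#' @param path TSV with header columns `gene_id`, `depth` (mean per-base
#'   coverage, nonnegative).
#' @return named numeric vector of depths.
#' @export
readDepths <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "depth") %in% names(tab)))
    stop("depth table must have columns gene_id, depth")
  d <- as.numeric(tab$depth)
  if (anyNA(d)) stop("non-numeric depth value(s)")
  if (any(d < 0)) stop("negative depth value(s)")
  setNames(d, tab$gene_id)
}

#' Read a transcript count matrix with its sample design
#'
#' The counts TSV has a `gene_id` column plus one integer column per sample;
#' the design TSV has columns `sample_id`, `treatment`, `replicate`. Every
#' count column must have exactly one design row.
#'
#' @param path counts TSV path.
#' @param design_path design TSV path (or a data.frame).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"counts"` and colData columns `treatment`, `replicate`.
#' @export
readCounts <- function(path, design_path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(tab))
    stop("counts table must have a gene_id column")
  m <- as.matrix(tab[, setdiff(names(tab), "gene_id"), drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- tab$gene_id
  design <- if (is.data.frame(design_path)) design_path
            else read.delim(design_path, stringsAsFactors = FALSE)
  makeCountMatrix(m, design)
}

#' Assemble a count SummarizedExperiment from a matrix and design table
#'
#' Validates that counts are nonnegative integers and that every sample
#' column has a design row.
#'
#' @param counts numeric matrix, genes x samples, with dimnames.
#' @param design data.frame with `sample_id`, `treatment`, `replicate`.
#' @return A [SummarizedExperiment::SummarizedExperiment].
#' @export
makeCountMatrix <- function(counts, design) {
  if (anyNA(counts)) stop("missing values in counts")
  if (any(counts < 0)) stop("negative counts")
  if (any(counts != round(counts))) stop("non-integer counts")
  need <- c("sample_id", "treatment", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design missing column(s): ", paste(miss, collapse = ", "))
  idx <- match(colnames(counts), design$sample_id)
  if (anyNA(idx))
    stop("sample(s) without design row: ",
         paste(colnames(counts)[is.na(idx)], collapse = ", "))
  cd <- S4Vectors::DataFrame(
    treatment = as.character(design$treatment[idx]),
    replicate = as.integer(design$replicate[idx]),
    row.names = colnames(counts))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = round(counts)), colData = cd)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
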