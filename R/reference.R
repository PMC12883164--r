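#' CodonCountTable class
#'
#' Per-taxon accumulations of (optionally depth-weighted) codon counts from a
#' metagenome gene set: the "genomic background" observations from which
#' reference codon frequencies are built. Sense codons are tabulated per
#' taxon; stop codons and ambiguous (non-ACGT) codons are tallied separately
#' and never enter frequencies or index calculations.
#'
#' @slot counts numeric matrix, taxa x 61 sense codons (depth-weighted counts
#'   when accumulated with weighting).
#' @slot stops numeric vector, per-taxon stop-codon tally.
#' @slot skipped numeric vector, per-taxon ambiguous-codon tally.
#' @slot code the [GeneticCode-class] used.
#'
#' @seealso [accumulateCounts()], [filterTaxa()], [aggregateRank()],
#'   [buildReference()]
#' @export
setClass("CodonCountTable",
  representation(counts = "matrix", stops = "numeric",
                 skipped = "numeric", code = "GeneticCode"))

setValidity("CodonCountTable", function(object) {
  msg <- character()
  sense <- senseCodons(object@code)
  if (!identical(colnames(object@counts), sense))
    msg <- c(msg, "count columns must be the sense codons of the code")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
  if (length(object@stops) != nrow(object@counts) ||
      length(object@skipped) != nrow(object@counts))
    msg <- c(msg, "stops/skipped must have one entry per taxon")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CodonCountTable", function(object) {
  cat("CodonCountTable: ", nrow(object@counts), " taxa, ",
      ncol(object@counts), " sense codons\n", sep = "")
  tot <- totalCodons(object)
  if (length(tot))
    cat("  total codon counts: ",
        paste(format(range(tot), big.mark = ","), collapse = " .. "),
        "\n", sep = "")
})

#' @rdname CodonCountTable-class
#' @param x a CodonCountTable.
#' @return `totalCodons()`: named numeric vector of per-taxon totals (sum of
#'   sense-codon counts); `taxonIds()`: character vector of taxon names;
#'   `codonCounts()`: the taxa x codon matrix.
#' @export
totalCodons <- function(x) rowSums(x@counts)

#' @rdname CodonCountTable-class
#' @export
taxonIds <- function(x) rownames(x@counts)

#' @rdname CodonCountTable-class
#' @export
codonCounts <- function(x) x@counts

# genes -> per-gene codon count matrix over the 64 codons, via
# non-overlapping trinucleotide windows; ambiguous codons fall outside the
# 64 columns and are recovered as width/3 - rowSums
geneCodonMatrix <- function(genes) {
  if (!methods::is(genes, "DNAStringSet"))
    genes <- Biostrings::DNAStringSet(genes)
  if (any(Biostrings::width(genes) %% 3L != 0L))
    stop("sequence length(s) not divisible by 3")
  Biostrings::oligonucleotideFrequency(genes, width = 3L, step = 3L)
}

#' Accumulate per-taxon codon counts from a gene set
#'
#' Each codon occurrence contributes the gene's read depth (when
#' `depth_weighted`) or 1 to its taxon's table. Genes without a taxon label
#' are routed to an `"unclassified"` bucket, which [buildReference()]
#' excludes. Ambiguous codons (containing non-ACGT characters) are skipped
#' and tallied; stop codons are tallied separately.
#'
#' @param genes [Biostrings::DNAStringSet] of in-frame CDS.
#' @param taxa character vector of taxon labels, one per gene (defaults to
#'   `mcols(genes)$taxon_id`).
#' @param depths numeric per-gene depths (defaults to `mcols(genes)$depth`;
#'   required when `depth_weighted`).
#' @param depth_weighted logical; weight codon occurrences by depth.
#' @param code a [GeneticCode-class].
#' @return A [CodonCountTable-class].
#' @export
accumulateCounts <- function(genes, taxa = NULL, depths = NULL,
                             depth_weighted = TRUE, code = geneticCode()) {
  mc <- if (methods::is(genes, "DNAStringSet")) S4Vectors::mcols(genes)
        else NULL
  if (is.null(taxa)) taxa <- mc$taxon_id
  if (is.null(taxa)) stop("taxon labels required (taxa= or mcols taxon_id)")
  taxa <- as.character(taxa)
  taxa[is.na(taxa) | !nzchar(taxa)] <- "unclassified"
  if (depth_weighted) {
    if (is.null(depths)) depths <- mc$depth
    if (is.null(depths))
      stop("depths required for depth-weighted accumulation")
    if (any(depths < 0)) stop("negative depth(s)")
    w <- as.numeric(depths)
  } else {
    w <- rep(1, length(genes))
  }
  m64 <- geneCodonMatrix(genes)
  n_cod <- if (methods::is(genes, "DNAStringSet"))
             Biostrings::width(genes) / 3L else nchar(genes) / 3L
  skipped_gene <- n_cod - rowSums(m64)
  mw <- m64 * w
  agg <- rowsum(mw, group = taxa)
  sense <- senseCodons(code)
  stops <- stopCodons(code)
  stops_t <- rowsum(rowSums(m64[, stops, drop = FALSE]) * w,
                    group = taxa)[, 1]
  skipped_t <- rowsum(skipped_gene * w, group = taxa)[, 1]
  counts <- agg[, sense, drop = FALSE]
  new("CodonCountTable", counts = counts,
      stops = stops_t[rownames(counts)],
      skipped = skipped_t[rownames(counts)], code = code)
}

#' Filter taxa by total depth-adjusted codon count
#'
#' Removes taxa whose total sense-codon count falls below `min_total`
#' (default 750,000); the boundary itself is retained.
#'
#' @param x a [CodonCountTable-class].
#' @param min_total minimum retained total.
#' @return A filtered [CodonCountTable-class].
#' @export
filterTaxa <- function(x, min_total = 750000) {
  keep <- totalCodons(x) >= min_total
  new("CodonCountTable", counts = x@counts[keep, , drop = FALSE],
      stops = x@stops[keep], skipped = x@skipped[keep], code = x@code)
}

#' Aggregate taxon count tables to a coarser rank
#'
#' Sums member-taxon count rows into group rows (e.g. species to phylum).
#' Taxa absent from `group_map` are excluded; their number is attached as
#' attribute `"n_unmapped"` and a warning is raised.
#'
#' @param x a [CodonCountTable-class].
#' @param group_map named character vector mapping taxon id to group id.
#' @return A [CodonCountTable-class] at group level.
#' @export
aggregateRank <- function(x, group_map) {
  tx <- taxonIds(x)
  grp <- unname(group_map[tx])
  unmapped <- is.na(grp)
  if (any(unmapped))
    warning(sum(unmapped), " taxa without group mapping were excluded")
  keep <- !unmapped
  counts <- rowsum(x@counts[keep, , drop = FALSE], group = grp[keep])
  stops <- rowsum(x@stops[keep], group = grp[keep])[, 1]
  skipped <- rowsum(x@skipped[keep], group = grp[keep])[, 1]
  out <- new("CodonCountTable", counts = counts,
             stops = stops[rownames(counts)],
             skipped = skipped[rownames(counts)], code = x@code)
  attr(out, "n_unmapped") <- sum(unmapped)
  out
}

#' ReferenceFrequencies class
#'
#' Per-taxon reference codon statistics derived from genomic background
#' counts: within-family codon frequencies `f_c` (also used as the expected
#' frequencies `g_c` of the MILC and ENC' null), CAI weights
#' `w_c = f_c / max(f of synonymous codons)`, and the optimal-codon set
#' (per-family argmax; ties all marked optimal).
#'
#' @slot freq numeric matrix, taxa x 61: within-family frequencies.
#' @slot weights numeric matrix, taxa x 61: CAI weights in (0, 1].
#' @slot optimal logical matrix, taxa x 61: optimal-codon indicators.
#' @slot pseudocount the pseudocount used.
#' @slot code the [GeneticCode-class] used.
#'
#' @seealso [buildReference()], [codonWeights()], [optimalCodons()]
#' @export
setClass("ReferenceFrequencies",
  representation(freq = "matrix", weights = "matrix", optimal = "matrix",
                 pseudocount = "numeric", code = "GeneticCode"))

setValidity("ReferenceFrequencies", function(object) {
  msg <- character()
  sense <- senseCodons(object@code)
  if (!identical(colnames(object@freq), sense) ||
      !identical(colnames(object@weights), sense) ||
      !identical(colnames(object@optimal), sense))
    msg <- c(msg, "matrix columns must be the sense codons of the code")
  if (nrow(object@freq)) {
    aa <- translateCodon(sense, object@code)
    for (fam in split(sense, aa)) {
      fs <- rowSums(object@freq[, fam, drop = FALSE])
      if (any(abs(fs - 1) > 1e-8))
        msg <- c(msg, "within-family frequencies must sum to 1")
      wmax <- apply(object@weights[, fam, drop = FALSE], 1, max)
      if (any(abs(wmax - 1) > 1e-8))
        msg <- c(msg, "max weight per family must be 1")
    }
  }
  if (length(msg)) unique(msg) else TRUE
})

setMethod("show", "ReferenceFrequencies", function(object) {
  cat("ReferenceFrequencies: ", nrow(object@freq), " taxa, ",
      ncol(object@freq), " sense codons (pseudocount ",
      object@pseudocount, ")\n", sep = "")
})

#' Build reference frequencies and CAI weights from codon counts
#'
#' Within each synonymous family of each taxon, frequencies are
#' `f_c = count_c / family total` and weights `w_c = f_c / max(family f)`.
#' The pseudocount is added per codon within a family only when at least one
#' family member is unobserved (keeping observed worked examples exact while
#' preventing zero weights, which would collapse CAI to 0). The
#' `"unclassified"` bucket is excluded.
#'
#' @param x a [CodonCountTable-class].
#' @param pseudocount nonnegative real (default 0.5).
#' @return A [ReferenceFrequencies-class].
#' @export
buildReference <- function(x, pseudocount = 0.5) {
  keep <- taxonIds(x) != "unclassified"
  counts <- x@counts[keep, , drop = FALSE]
  sense <- senseCodons(x@code)
  aa <- translateCodon(sense, x@code)
  freq <- weights <- matrix(NA_real_, nrow(counts), ncol(counts),
                            dimnames = dimnames(counts))
  optimal <- matrix(FALSE, nrow(counts), ncol(counts),
                    dimnames = dimnames(counts))
  for (fam in split(sense, aa)) {
    sub <- counts[, fam, drop = FALSE]
    zero_fam <- apply(sub, 1, function(v) any(v == 0))
    if (pseudocount > 0)
      sub[zero_fam, ] <- sub[zero_fam, , drop = FALSE] + pseudocount
    tot <- rowSums(sub)
    if (any(tot == 0))
      stop("empty synonymous family (", paste(fam, collapse = "/"),
           ") for taxon ", paste(rownames(sub)[tot == 0], collapse = ", "),
           " with pseudocount 0: weights undefined")
    f <- sub / tot
    w <- f / apply(f, 1, max)
    freq[, fam] <- f
    weights[, fam] <- w
    optimal[, fam] <- abs(w - 1) < 1e-12
  }
  new("ReferenceFrequencies", freq = freq, weights = weights,
      optimal = optimal, pseudocount = pseudocount, code = x@code)
}

#' Accessors for ReferenceFrequencies
#'
#' @param ref a [ReferenceFrequencies-class].
#' @param taxon taxon id (row name).
#' @return `codonWeights()`: named numeric vector of CAI weights;
#'   `expectedFrequencies()`: named vector of within-family frequencies
#'   (the `g_c` null of MILC/ENC'); `optimalCodons()`: character vector of
#'   optimal codons (for ties, all tied codons, lexicographically sorted).
#' @export
codonWeights <- function(ref, taxon) {
  if (!taxon %in% rownames(ref@weights)) stop("no reference for: ", taxon)
  ref@weights[taxon, ]
}

#' @rdname codonWeights
#' @export
expectedFrequencies <- function(ref, taxon) {
  if (!taxon %in% rownames(ref@freq)) stop("no reference for: ", taxon)
  ref@freq[taxon, ]
}

#' @rdname codonWeights
#' @export
optimalCodons <- function(ref, taxon) {
  if (!taxon %in% rownames(ref@optimal)) stop("no reference for: ", taxon)
  sort(colnames(ref@optimal)[ref@optimal[taxon, ]])
}

#' Serialize a reference to TSV
#'
#' Long-format table (taxon_id, codon, amino_acid, count, f_c, w_c,
#' is_optimal) for inspection or downstream ordination of codon-frequency
#' profiles.
#'
#' @param ref a [ReferenceFrequencies-class].
#' @param path output TSV path.
#' @param counts optional [CodonCountTable-class] supplying raw counts.
#' @return `path`, invisibly.
#' @export
writeReferenceTsv <- function(ref, path, counts = NULL) {
  sense <- senseCodons(ref@code)
  taxa <- rownames(ref@freq)
  df <- data.frame(
    taxon_id = rep(taxa, each = length(sense)),
    codon = rep(sense, times = length(taxa)),
    amino_acid = rep(translateCodon(sense, ref@code), times = length(taxa)),
    count = if (is.null(counts)) NA_real_
            else as.vector(t(counts@counts[taxa, sense, drop = FALSE])),
    f_c = as.vector(t(ref@freq)),
    w_c = as.vector(t(ref@weights)),
    is_optimal = as.vector(t(ref@optimal)),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
}
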