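#' Codon profile of a transcript
#'
#' Tabulates sense-codon counts `O_c` and the codon length `L` of a
#' transcript. Stop codons and ambiguous codons (any non-ACGT character) are
#' excluded from both `O_c` and `L` and tallied separately — never silently
#' dropped.
#'
#' @param sequence character, [Biostrings::DNAString] or RNA string (U is
#'   converted to T); length must be divisible by 3.
#' @param code a [GeneticCode-class].
#' @return list with `O` (named numeric over the 61 sense codons), `L`
#'   (counted codons), `n_stops`, `n_skipped`.
#' @examples
#' codonProfile("GAAGAAGAG")$O[c("GAA", "GAG")]
#' @export
codonProfile <- function(sequence, code = geneticCode()) {
  s <- chartr("uU", "TT", toupper(as.character(sequence)))
  if (nchar(s) == 0L) stop("empty sequence")
  if (nchar(s) %% 3L != 0L)
    stop("sequence length not divisible by 3")
  codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  sense <- senseCodons(code)
  O <- setNames(numeric(length(sense)), sense)
  tab <- table(codons)
  hit <- intersect(names(tab), sense)
  O[hit] <- as.numeric(tab[hit])
  n_stops <- sum(as.numeric(tab[intersect(names(tab), stopCodons(code))]))
  list(O = O, L = sum(O), n_stops = n_stops,
       n_skipped = length(codons) - sum(O) - n_stops)
}

as_profile <- function(x, code) {
  if (is.list(x) && !is.null(x$O)) x else codonProfile(x, code)
}

#' Codon Adaptation Index
#'
#' Geometric mean of per-codon reference weights `w_c` over the counted
#' codons of a transcript: `CAI = (prod w_c)^(1/L)`. Values near 1 indicate
#' usage dominated by each family's preferred codon. Single-codon families
#' (Met, Trp under the bacterial code) carry weight 1 and are included by
#' default; `exclude_singletons = TRUE` applies the classical convention of
#' dropping them from both numerator and `L`.
#'
#' @param x a [codonProfile()] list, or a sequence (profiled on the fly).
#' @param ref a [ReferenceFrequencies-class].
#' @param taxon reference row to use.
#' @param exclude_singletons drop single-codon families from the mean.
#' @param code a [GeneticCode-class] (used only when profiling a raw
#'   sequence).
#' @return CAI in (0, 1], or `NA` when no codons are counted.
#' @export
cai <- function(x, ref, taxon, exclude_singletons = FALSE,
                code = ref@code) {
  p <- as_profile(x, code)
  w <- codonWeights(ref, taxon)
  O <- p$O
  if (exclude_singletons) {
    sense <- names(O)
    aa <- translateCodon(sense, ref@code)
    fam_size <- table(aa)
    O[fam_size[aa] == 1L] <- 0
  }
  used <- O > 0
  L <- sum(O)
  if (L == 0) return(NA_real_)
  if (any(w[used] <= 0))
    stop("zero reference weight for observed codon(s) ",
         paste(names(O)[used & w <= 0], collapse = ", "),
         "; rebuild the reference with a positive pseudocount")
  exp(sum(O[used] * log(w[used])) / L)
}

#' Frequency of Optimized Codons
#'
#' Fraction of a transcript's counted codons that belong to the reference's
#' optimal-codon set (the per-family maximum-frequency codons; ties all
#' count as optimal).
#'
#' @inheritParams cai
#' @return FOP in \[0, 1\], or `NA` when no codons are counted.
#' @export
fop <- function(x, ref, taxon, code = ref@code) {
  p <- as_profile(x, code)
  if (p$L == 0) return(NA_real_)
  opt <- ref@optimal[taxon, names(p$O)]
  sum(p$O[opt]) / p$L
}

#' MILC: Measure Independent of Length and Composition
#'
#' Per-amino-acid codon bias against expected frequencies,
#' `M_a = sum_c O_c ln(f_c / g_c)` with `f_c` the observed within-family
#' frequency in the transcript and `g_c` the expected (reference background)
#' frequency, combined as `MILC = sum_a M_a / L - C` with the
#' short-sequence correction `C = sum_a (r_a - 1) / L - 0.5` taken over
#' amino acids present in the transcript. Values near 0 indicate usage
#' matching the reference.
#'
#' @inheritParams cai
#' @return MILC (nonnegative up to the sign of `-C`), or `NA` when no codons
#'   are counted.
#' @export
milc <- function(x, ref, taxon, code = ref@code) {
  p <- as_profile(x, code)
  if (p$L == 0) return(NA_real_)
  g <- expectedFrequencies(ref, taxon)
  sense <- names(p$O)
  aa <- translateCodon(sense, ref@code)
  M_sum <- 0
  corr_sum <- 0
  for (fam in split(sense, aa)) {
    O_fam <- p$O[fam]
    n_a <- sum(O_fam)
    if (n_a == 0) next
    used <- O_fam > 0
    if (any(g[fam][used] <= 0))
      stop("zero expected frequency g_c for observed codon(s) ",
           paste(fam[used & g[fam] <= 0], collapse = ", "),
           "; rebuild the reference with a positive pseudocount")
    f_obs <- O_fam / n_a
    M_sum <- M_sum + sum(O_fam[used] * log(f_obs[used] / g[fam][used]))
    corr_sum <- corr_sum + (length(fam) - 1L)
  }
  C <- corr_sum / p$L - 0.5
  M_sum / p$L - C
}

#' ENC': background-corrected effective number of codons
#'
#' Effective number of codons with codon usage judged against expected
#' (reference background) frequencies rather than uniform usage. For each
#' amino acid with at least `min_family_count` counted codons, a chi-square
#' deviation from the expected frequencies gives a corrected homozygosity
#' `F'_a = (chi2_a + n_a - r_a) / (r_a (n_a - 1))`; class averages over
#' family sizes then combine as in the classical effective-number formula
#' (for the bacterial code, `ENC' = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`). Ranges
#' from about 20 (extreme bias) to 61 (usage at background); clamped to
#' \[1, 61\].
#'
#' @inheritParams cai
#' @param min_family_count minimum counted codons for a family to enter its
#'   class average (at least 2).
#' @return ENC' in \[1, 61\], or `NA` when too few families are observed.
#' @export
encPrime <- function(x, ref, taxon, min_family_count = 2L,
                     code = ref@code) {
  p <- as_profile(x, code)
  if (p$L == 0) return(NA_real_)
  g <- expectedFrequencies(ref, taxon)
  sense <- names(p$O)
  aa <- translateCodon(sense, ref@code)
  fams <- split(sense, aa)
  r_of <- vapply(fams, length, integer(1))
  min_family_count <- max(2L, as.integer(min_family_count))

  Fp <- rep(NA_real_, length(fams))
  names(Fp) <- names(fams)
  for (a in names(fams)) {
    fam <- fams[[a]]
    r_a <- length(fam)
    if (r_a < 2L) next
    O_fam <- p$O[fam]
    n_a <- sum(O_fam)
    if (n_a < min_family_count) next
    e <- g[fam]
    f_obs <- O_fam / n_a
    chi2 <- n_a * sum((f_obs - e)^2 / e)
    Fp[a] <- (chi2 + n_a - r_a) / (r_a * (n_a - 1))
  }

  sizes <- sort(unique(r_of[r_of >= 2L]))
  n_singles <- sum(r_of == 1L)
  Fbar <- setNames(rep(NA_real_, length(sizes)), sizes)
  for (r in sizes) {
    vals <- Fp[r_of == r]
    vals <- vals[!is.na(vals)]
    if (length(vals)) Fbar[as.character(r)] <- mean(vals)
  }
  # classical fallback: an unobserved threefold class (Ile) borrows the mean
  # of the two- and fourfold class averages
  if (is.na(Fbar["3"]) && !is.na(Fbar["2"]) && !is.na(Fbar["4"]))
    Fbar["3"] <- (Fbar["2"] + Fbar["4"]) / 2
  if (anyNA(Fbar) || any(Fbar < 1e-8)) return(NA_real_)
  enc <- n_singles +
    sum(vapply(sizes, function(r)
      sum(r_of == r) / Fbar[as.character(r)], numeric(1)))
  min(max(enc, 1), 61)
}

# per-code nucleotide-by-site-class contribution matrices: for each codon,
# how many of its positions of a given class carry each nucleotide
siteNucleotideMatrix <- function(code, site_class) {
  cls <- siteClassTable(code)
  sense <- senseCodons(code)
  nts <- c("A", "C", "G", "T")
  m <- matrix(0L, length(sense), 4L, dimnames = list(sense, nts))
  for (cd in sense) {
    for (pos in 1:3) {
      if (isTRUE(unname(cls[cd, pos]) == site_class)) {
        nt <- substr(cd, pos, pos)
        m[cd, nt] <- m[cd, nt] + 1L
      }
    }
  }
  m
}

site_nt_counts <- function(sequence, site_filter, code) {
  s <- chartr("uU", "TT", toupper(as.character(sequence)))
  nts <- c("A", "C", "G", "T")
  if (identical(site_filter, "all")) {
    chars <- strsplit(s, "")[[1]]
    tab <- table(factor(chars, levels = nts))
    return(as.numeric(tab))
  }
  if (!site_filter %in% c(SITE_FOURFOLD, SITE_NONSYNONYMOUS, SITE_MIXED))
    stop("site_filter must be 'all', SITE_FOURFOLD, SITE_NONSYNONYMOUS or SITE_MIXED")
  p <- codonProfile(s, code)
  m <- siteNucleotideMatrix(code, site_filter)
  as.numeric(p$O %*% m)
}

#' GC content, optionally restricted to a site class
#'
#' `(G + C) / (A + C + G + T)` over all positions (`site_filter = "all"`),
#' or over fourfold-degenerate ("synonymous") or strictly nonsynonymous
#' codon positions.
#'
#' @param sequence DNA/RNA string; must be codon-divisible for site-filtered
#'   variants.
#' @param site_filter `"all"`, [SITE_FOURFOLD], [SITE_NONSYNONYMOUS] or
#'   [SITE_MIXED].
#' @param code a [GeneticCode-class].
#' @return value in \[0, 1\], or `NA` when the selected site pool is empty.
#' @export
gcContent <- function(sequence, site_filter = "all", code = geneticCode()) {
  n <- site_nt_counts(sequence, site_filter, code)
  tot <- sum(n)
  if (tot == 0) return(NA_real_)
  (n[2] + n[3]) / tot
}

#' GC skew and AT skew, optionally restricted to a site class
#'
#' `GC skew = (G - C) / (G + C)` and `AT skew = (A - T) / (A + T)` on the
#' sense strand (T standing for U); lower values favor the energetically
#' cheaper nucleotide (C over G, T/U over A). Computed over all positions or
#' a site-class pool as in [gcContent()].
#'
#' @inheritParams gcContent
#' @return value in \[-1, 1\], or `NA` when the denominator pool is empty.
#' @export
gcSkew <- function(sequence, site_filter = "all", code = geneticCode()) {
  n <- site_nt_counts(sequence, site_filter, code)
  if (n[3] + n[2] == 0) return(NA_real_)
  (n[3] - n[2]) / (n[3] + n[2])
}

#' @rdname gcSkew
#' @export
atSkew <- function(sequence, site_filter = "all", code = geneticCode()) {
  n <- site_nt_counts(sequence, site_filter, code)
  if (n[1] + n[4] == 0) return(NA_real_)
  (n[1] - n[4]) / (n[1] + n[4])
}

#' Amino acid cost and composition tables
#'
#' Loads the residue synthesis-cost table (high-energy phosphate bonds per
#' residue) and the elemental-composition table (atom counts of the free
#' amino acids). Packaged defaults ship as editable TSVs under
#' `inst/extdata/` (`aa_cost.tsv`, `aa_composition.tsv`); pass paths to
#' substitute your own.
#'
#' @param cost_path TSV with columns `residue`, `cost` (defaults to the
#'   packaged table).
#' @param composition_path TSV with columns `residue`, `C`, `H`, `N`, `O`,
#'   `S`.
#' @return list with `cost` (named numeric, 20 residues) and `composition`
#'   (20 x 5 integer matrix).
#' @export
aminoAcidTables <- function(cost_path = NULL, composition_path = NULL) {
  if (is.null(cost_path))
    cost_path <- system.file("extdata", "aa_cost.tsv",
                             package = "codonTraits", mustWork = TRUE)
  if (is.null(composition_path))
    composition_path <- system.file("extdata", "aa_composition.tsv",
                                    package = "codonTraits", mustWork = TRUE)
  ct <- read.delim(cost_path, stringsAsFactors = FALSE)
  cost <- setNames(as.numeric(ct$cost), ct$residue)
  if (length(cost) != 20L || any(is.na(cost)) || any(cost <= 0))
    stop("cost table must give a positive cost for each of the 20 residues")
  cm <- read.delim(composition_path, stringsAsFactors = FALSE)
  comp <- as.matrix(cm[, c("C", "H", "N", "O", "S")])
  rownames(comp) <- cm$residue
  if (nrow(comp) != 20L || anyNA(comp))
    stop("composition table must give atom counts for each of the 20 residues")
  list(cost = cost, composition = comp)
}

#' Mean synthesis cost and C:N stoichiometry of encoded residues
#'
#' `mean_cost` is the average number of high-energy phosphate bonds required
#' to synthesize one residue of the protein; `cn_ratio` is the molar carbon
#' to nitrogen ratio of the summed residue formulas.
#'
#' @param protein one-letter residue string, or a nucleotide CDS when
#'   `translate = TRUE` (stops and ambiguous codons skipped).
#' @param tables from [aminoAcidTables()].
#' @param translate treat `protein` as a CDS and translate first.
#' @param strict error (rather than skip-and-tally) on unknown residues.
#' @param code a [GeneticCode-class] for translation.
#' @return list with `mean_cost`, `cn_ratio`, `n_residues`, `n_skipped`.
#' @export
aminoAcidTraits <- function(protein, tables = aminoAcidTables(),
                            translate = FALSE, strict = FALSE,
                            code = geneticCode()) {
  if (translate) {
    p <- codonProfile(protein, code)
    aa_codon <- translateCodon(names(p$O), code)
    res <- rep(aa_codon, times = p$O)
  } else {
    res <- strsplit(toupper(as.character(protein)), "")[[1]]
  }
  known <- res %in% names(tables$cost)
  if (strict && any(!known))
    stop("unknown residue(s): ", paste(unique(res[!known]), collapse = ", "))
  res <- res[known]
  if (!length(res))
    return(list(mean_cost = NA_real_, cn_ratio = NA_real_,
                n_residues = 0L, n_skipped = sum(!known)))
  tab <- table(factor(res, levels = names(tables$cost)))
  n <- as.numeric(tab)
  list(mean_cost = sum(n * tables$cost) / sum(n),
       cn_ratio = sum(n * tables$composition[names(tables$cost), "C"]) /
                  sum(n * tables$composition[names(tables$cost), "N"]),
       n_residues = length(res), n_skipped = sum(!known))
}

#' Discard genes shorter than a codon-length threshold
#'
#' Genes with fewer than `min_codons` codons are discarded to limit
#' small-sample bias in frequency-based indices; the boundary value is
#' retained.
#'
#' @param genes [Biostrings::DNAStringSet] (mcols preserved) or character
#'   vector of CDS.
#' @param min_codons minimum retained length in codons (default 80).
#' @return the retained subset, with attribute `"n_discarded"`.
#' @export
lengthFilter <- function(genes, min_codons = 80L) {
  w <- if (methods::is(genes, "XStringSet")) Biostrings::width(genes)
       else nchar(genes)
  keep <- (w %/% 3L) >= min_codons
  out <- genes[keep]
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Compute the full per-transcript trait table
#'
#' One row per gene: codon-optimization indices against the gene's taxon
#' reference (CAI, FOP, MILC, ENC'), GC content overall and by site class,
#' GC/AT skew at fourfold-degenerate sites, and amino acid cost and C:N.
#' Genes whose taxon has no reference row get `NA` for the reference-based
#' indices (flagged via `has_reference`); traits with an empty site pool are
#' `NA`, never 0.
#'
#' @param genes [Biostrings::DNAStringSet] with `mcols` columns `taxon_id`
#'   (and optionally `ko_id`, `depth`, `pathway_tags`), or a named character
#'   vector plus `taxa`.
#' @param ref a [ReferenceFrequencies-class].
#' @param taxa optional character vector of per-gene taxon labels.
#' @param min_codons length filter applied first (default 80; 0 disables).
#' @param aa_tables from [aminoAcidTables()].
#' @param compute_enc include ENC' (the costliest index).
#' @return data.frame with one row per retained gene.
#' @export
computeGeneTraits <- function(genes, ref, taxa = NULL, min_codons = 80L,
                              aa_tables = aminoAcidTables(),
                              compute_enc = TRUE) {
  if (!methods::is(genes, "DNAStringSet"))
    genes <- Biostrings::DNAStringSet(genes)
  mc <- S4Vectors::mcols(genes)
  if (is.null(taxa)) taxa <- mc$taxon_id
  if (is.null(taxa)) stop("taxon labels required (taxa= or mcols taxon_id)")
  taxa <- as.character(taxa)
  keep <- (Biostrings::width(genes) %/% 3L) >= min_codons
  n_discarded <- sum(!keep)
  genes <- genes[keep]
  taxa <- taxa[keep]
  n <- length(genes)
  ids <- names(genes)
  if (is.null(ids)) ids <- paste0("gene_", seq_len(n))

  code <- ref@code
  has_ref <- taxa %in% rownames(ref@freq)
  out <- data.frame(
    gene_id = ids, taxon_id = taxa,
    n_codons = as.integer(Biostrings::width(genes) %/% 3L),
    has_reference = has_ref,
    cai = NA_real_, fop = NA_real_, milc = NA_real_, enc_prime = NA_real_,
    gc_total = NA_real_, gc_fourfold = NA_real_, gc_nonsyn = NA_real_,
    gc_skew_fourfold = NA_real_, at_skew_fourfold = NA_real_,
    aa_mean_cost = NA_real_, aa_cn = NA_real_,
    n_skipped_codons = NA_integer_,
    stringsAsFactors = FALSE)

  m64 <- geneCodonMatrix(genes)
  sense <- senseCodons(code)
  m_sense <- m64[, sense, drop = FALSE]
  L <- rowSums(m_sense)
  n_stop <- rowSums(m64[, stopCodons(code), drop = FALSE])
  out$n_skipped_codons <- as.integer(round(
    Biostrings::width(genes) / 3 - L - n_stop))

  nt_4f <- siteNucleotideMatrix(code, SITE_FOURFOLD)
  nt_ns <- siteNucleotideMatrix(code, SITE_NONSYNONYMOUS)
  p4 <- m_sense %*% nt_4f
  pn <- m_sense %*% nt_ns
  all_nt <- Biostrings::alphabetFrequency(genes)[, c("A", "C", "G", "T"),
                                                drop = FALSE]
  tot_all <- rowSums(all_nt)
  out$gc_total <- ifelse(tot_all > 0,
                         (all_nt[, "G"] + all_nt[, "C"]) / tot_all, NA)
  t4 <- rowSums(p4)
  out$gc_fourfold <- ifelse(t4 > 0, (p4[, "G"] + p4[, "C"]) / t4, NA)
  tn <- rowSums(pn)
  out$gc_nonsyn <- ifelse(tn > 0, (pn[, "G"] + pn[, "C"]) / tn, NA)
  gcd <- p4[, "G"] + p4[, "C"]
  out$gc_skew_fourfold <- ifelse(gcd > 0, (p4[, "G"] - p4[, "C"]) / gcd, NA)
  atd <- p4[, "A"] + p4[, "T"]
  out$at_skew_fourfold <- ifelse(atd > 0, (p4[, "A"] - p4[, "T"]) / atd, NA)

  for (i in seq_len(n)) {
    prof <- list(O = m_sense[i, ], L = L[i])
    at <- aminoAcidTraits(
      paste(rep(translateCodon(sense, code), times = m_sense[i, ]),
            collapse = ""), tables = aa_tables)
    out$aa_mean_cost[i] <- at$mean_cost
    out$aa_cn[i] <- at$cn_ratio
    if (!has_ref[i] || L[i] == 0) next
    tx <- taxa[i]
    out$cai[i] <- cai(prof, ref, tx)
    out$fop[i] <- fop(prof, ref, tx)
    out$milc[i] <- milc(prof, ref, tx)
    if (compute_enc) out$enc_prime[i] <- encPrime(prof, ref, tx)
  }
  for (col in c("ko_id", "depth"))
    if (!is.null(mc[[col]])) out[[col]] <- mc[[col]][keep]
  if (!is.null(mc$pathway_tags))
    out$pathway_tags <- vapply(mc$pathway_tags[keep],
                               paste, character(1), collapse = ";")
  attr(out, "n_discarded") <- n_discarded
  out
}
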