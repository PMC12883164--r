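DEFAULT_TRAIT_COLS <- c("cai", "fop", "milc", "enc_prime", "gc_total",
                        "gc_fourfold", "gc_nonsyn", "gc_skew_fourfold",
                        "at_skew_fourfold", "aa_mean_cost", "aa_cn")

#' Depth-weighted trait summaries by grouping keys
#'
#' `mean_t = sum(trait_g * weight_g) / sum(weight_g)` over the genes of each
#' group, skipping genes with undefined (`NA`) traits with weight
#' renormalization. Weights are read depths (DNA reference summaries) or
#' transcript abundances (RNA pool summaries) depending on what the caller
#' supplies.
#'
#' @param traits trait table from [computeGeneTraits()] (or any data.frame
#'   with the trait columns and the grouping columns).
#' @param weights numeric per-gene weights; defaults to `traits$depth`.
#' @param by character vector of grouping column names (e.g. `"ko_id"`,
#'   `c("ko_id", "taxon_id")`); empty for one overall summary.
#' @param trait_cols trait columns to summarize.
#' @return data.frame: grouping keys, `n_genes`, `total_weight`, one
#'   weighted-mean column per trait (`NA` when a group has no defined
#'   values or zero weight).
#' @export
weightedSummary <- function(traits, weights = NULL, by = "ko_id",
                            trait_cols = intersect(DEFAULT_TRAIT_COLS,
                                                   names(traits))) {
  if (is.null(weights)) weights <- traits$depth
  if (is.null(weights)) stop("weights required (weights= or traits$depth)")
  if (length(weights) != nrow(traits))
    stop("one weight per trait row required")
  if (any(weights < 0, na.rm = TRUE)) stop("weights must be nonnegative")
  key <- if (length(by)) interaction(traits[by], drop = TRUE, sep = "\r")
         else factor(rep("all", nrow(traits)))
  groups <- levels(key)
  out <- if (length(by)) {
    kd <- do.call(rbind, strsplit(groups, "\r", fixed = TRUE))
    stats::setNames(as.data.frame(kd, stringsAsFactors = FALSE), by)
  } else data.frame(group = groups, stringsAsFactors = FALSE)
  out$n_genes <- as.integer(table(key)[groups])
  out$total_weight <- as.numeric(tapply(weights, key, sum)[groups])
  for (tc in trait_cols) {
    v <- traits[[tc]]
    out[[tc]] <- as.numeric(tapply(seq_along(v), key, function(i) {
      ok <- !is.na(v[i]) & !is.na(weights[i]) & weights[i] > 0
      if (!any(ok)) return(NA_real_)
      sum(v[i][ok] * weights[i][ok]) / sum(weights[i][ok])
    })[groups])
  }
  out
}

#' Per-sample transcript-pool trait means
#'
#' The community-level view: for each sample, the mean of each gene trait
#' weighted by that gene's normalized transcript count in the sample
#' (`weighting = "counts"`, the metatranscriptome default) or by DNA read
#' depth (`weighting = "depth"`, constant across samples).
#'
#' @param traits trait table from [computeGeneTraits()], keyed by `gene_id`.
#' @param se counts [SummarizedExperiment::SummarizedExperiment] with rows
#'   matching `traits$gene_id`.
#' @param weighting `"counts"` or `"depth"`.
#' @param trait_cols trait columns to summarize.
#' @return data.frame: `sample_id`, `treatment`, `replicate`, one column per
#'   trait.
#' @export
transcriptPoolMeans <- function(traits, se, weighting = c("counts", "depth"),
                                trait_cols = intersect(DEFAULT_TRAIT_COLS,
                                                       names(traits))) {
  weighting <- match.arg(weighting)
  counts <- SummarizedExperiment::assay(se, "counts")
  idx <- match(rownames(counts), traits$gene_id)
  if (all(is.na(idx))) stop("no overlap between counts rows and trait genes")
  cd <- SummarizedExperiment::colData(se)
  sf <- computeSizeFactors(counts, pseudo_reference = TRUE)
  norm <- sweep(counts, 2, sf, "/")
  out <- data.frame(sample_id = colnames(counts),
                    treatment = cd$treatment, replicate = cd$replicate,
                    stringsAsFactors = FALSE)
  for (tc in trait_cols) {
    v <- traits[[tc]][idx]
    out[[tc]] <- vapply(seq_len(ncol(norm)), function(j) {
      w <- if (weighting == "counts") norm[, j] else traits$depth[idx]
      ok <- !is.na(v) & !is.na(w) & w > 0
      if (!any(ok)) return(NA_real_)
      sum(v[ok] * w[ok]) / sum(w[ok])
    }, numeric(1))
  }
  out
}

#' ANOVA and Tukey HSD comparisons of trait means across treatments
#'
#' One-way analysis of variance per trait over a grouping factor (treatment
#' or timepoint), with Tukey honest significant difference pairwise
#' comparisons.
#'
#' @param summaries data.frame of per-sample trait values (e.g. from
#'   [transcriptPoolMeans()]).
#' @param factor_col name of the grouping column.
#' @param trait_cols trait columns to test.
#' @return list with `omnibus` (data.frame: trait, F, df, p_value) and
#'   `pairwise` (data.frame: trait, comparison, diff, lwr, upr, p_adj).
#' @export
compareGroups <- function(summaries, factor_col = "treatment",
                          trait_cols = intersect(DEFAULT_TRAIT_COLS,
                                                 names(summaries))) {
  g <- factor(summaries[[factor_col]])
  if (nlevels(g) < 2L) stop("need at least two groups")
  if (any(table(g) < 2L))
    warning("group(s) with a single replicate: ",
            paste(names(table(g))[table(g) < 2L], collapse = ", "),
            "; pairwise comparisons involving them are unreliable")
  omni <- NULL
  pw <- NULL
  for (tc in trait_cols) {
    v <- summaries[[tc]]
    ok <- !is.na(v)
    if (sum(ok) < nlevels(g) + 1L || length(unique(g[ok])) < 2L) next
    fit <- aov(v[ok] ~ g[ok])
    an <- summary(fit)[[1]]
    omni <- rbind(omni, data.frame(
      trait = tc, F = an$`F value`[1],
      df1 = an$Df[1], df2 = an$Df[2], p_value = an$`Pr(>F)`[1],
      stringsAsFactors = FALSE))
    tk <- TukeyHSD(fit)[[1]]
    pw <- rbind(pw, data.frame(
      trait = tc, comparison = rownames(tk),
      diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
      p_adj = tk[, "p adj"], row.names = NULL, stringsAsFactors = FALSE))
  }
  list(omnibus = omni, pairwise = pw)
}

ols_fit <- function(df, response, predictors) {
  X <- stats::model.matrix(
    stats::as.formula(paste(response, "~", paste(predictors, collapse = "+"))),
    data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear predictor(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- lm(stats::as.formula(
    paste(response, "~", paste(predictors, collapse = "+"))), data = df)
  sm <- summary(fit)
  list(coefficients = data.frame(
         term = rownames(sm$coefficients),
         estimate = sm$coefficients[, 1], se = sm$coefficients[, 2],
         p_value = sm$coefficients[, 4], row.names = NULL,
         stringsAsFactors = FALSE),
       r_squared = sm$r.squared,
       n_points = nrow(fit$model),
       confint = confint(fit),
       fit = fit)
}

#' Multiple linear regression of log2-fold change on gene traits
#'
#' Ordinary least squares of per-feature LFC on one or more trait
#' predictors, with analytic coefficient standard errors. Features are
#' matched between the DE table and the trait table on id.
#'
#' @param de DE table from [estimateDE()].
#' @param traits trait table (gene- or summary-level).
#' @param predictors character vector of trait column names.
#' @param de_key,trait_key id columns used for matching.
#' @return list with `coefficients` (term, estimate, se, p_value),
#'   `r_squared`, `n_points`, `confint` and the underlying `lm` fit.
#' @export
regressLfcOnTraits <- function(de, traits, predictors = "fop",
                               de_key = "feature_id", trait_key = "gene_id") {
  df <- merge(de[, c(de_key, "lfc")], traits,
              by.x = de_key, by.y = trait_key)
  df <- df[complete.cases(df[, c("lfc", predictors), drop = FALSE]), ]
  if (nrow(df) < length(predictors) + 2L)
    stop("too few matched features for regression (", nrow(df), ")")
  ols_fit(df, "lfc", predictors)
}

#' Pathway-level trait-expression relation across MAGs
#'
#' For each MAG (taxon), averages a codon-optimization trait and the
#' estimated LFC over that MAG's genes carrying a pathway tag, giving one
#' point per MAG, then fits mean LFC on mean trait by OLS. Reported with and
#' without an explicit exclusion list (never automatic outlier deletion),
#' plus leave-one-out slopes so single influential MAGs — the situation
#' where one lineage dominates a fit — are visible.
#'
#' @param traits gene-level trait table with `taxon_id` and `pathway_tags`
#'   (semicolon-separated string or list column).
#' @param de gene-level DE table from [estimateDE()].
#' @param pathway_tag tag selecting the pathway's genes.
#' @param trait trait column to average (default `"fop"`).
#' @param exclusions taxon ids excluded from the secondary fit.
#' @param min_points minimum MAGs required to fit (default 3); with fewer,
#'   the fit is refused but points are still returned.
#' @return list with `points` (taxon_id, x, y, n_genes), `fit`,
#'   `fit_excluded` (NULL when nothing excluded), `loo` (data.frame of
#'   leave-one-out slopes with `influence` = slope change), and
#'   `max_influence` (taxon whose removal moves the slope most).
#' @export
pathwayLevelRelation <- function(traits, de, pathway_tag, trait = "fop",
                                 exclusions = character(),
                                 min_points = 3L) {
  tags <- traits$pathway_tags
  if (is.list(tags)) {
    has_tag <- vapply(tags, function(x) pathway_tag %in% x, logical(1))
  } else {
    has_tag <- vapply(strsplit(as.character(tags), ";", fixed = TRUE),
                      function(x) pathway_tag %in% x, logical(1))
  }
  sub <- traits[has_tag, , drop = FALSE]
  if (!nrow(sub)) stop("no genes carry pathway tag: ", pathway_tag)
  m <- merge(sub, de[, c("feature_id", "lfc")],
             by.x = "gene_id", by.y = "feature_id")
  m <- m[!is.na(m[[trait]]) & !is.na(m$lfc), , drop = FALSE]
  pts <- do.call(rbind, lapply(split(m, m$taxon_id), function(d)
    data.frame(taxon_id = d$taxon_id[1], x = mean(d[[trait]]),
               y = mean(d$lfc), n_genes = nrow(d),
               stringsAsFactors = FALSE)))
  rownames(pts) <- NULL
  out <- list(points = pts, trait = trait, pathway_tag = pathway_tag,
              fit = NULL, fit_excluded = NULL, loo = NULL,
              max_influence = NA_character_)
  if (is.null(pts) || nrow(pts) < min_points) {
    out$refused <- paste0("fewer than ", min_points,
                          " MAGs with pathway genes; fit refused")
    return(out)
  }
  out$fit <- ols_fit(pts, "y", "x")
  if (length(exclusions)) {
    keep <- !pts$taxon_id %in% exclusions
    if (sum(keep) >= min_points)
      out$fit_excluded <- ols_fit(pts[keep, , drop = FALSE], "y", "x")
  }
  slope <- out$fit$coefficients$estimate[2]
  loo <- do.call(rbind, lapply(seq_len(nrow(pts)), function(i) {
    if (nrow(pts) - 1L < 2L) return(NULL)
    f <- ols_fit(pts[-i, , drop = FALSE], "y", "x")
    data.frame(taxon_id = pts$taxon_id[i],
               slope_without = f$coefficients$estimate[2],
               influence = abs(f$coefficients$estimate[2] - slope),
               stringsAsFactors = FALSE)
  }))
  out$loo <- loo
  if (!is.null(loo) && nrow(loo))
    out$max_influence <- loo$taxon_id[which.max(loo$influence)]
  out
}

#' Export a per-taxon codon-frequency matrix for a pathway
#'
#' Rows are taxa/MAGs, columns the 61 sense codons; entries are within-
#' synonymous-family frequencies computed over the taxon's genes carrying
#' the pathway tag (each family block of a row sums to 1). This is the
#' matrix an ordination of pathway codon usage (e.g. NMDS) consumes.
#'
#' @param genes [Biostrings::DNAStringSet] with mcols `taxon_id` and
#'   `pathway_tags`.
#' @param pathway_tag tag selecting genes; NULL for all genes.
#' @param path optional TSV output path.
#' @param code a [GeneticCode-class].
#' @return the frequency matrix (0 rows, 61 columns when no gene matches).
#' @export
exportCodonMatrix <- function(genes, pathway_tag = NULL, path = NULL,
                              code = geneticCode()) {
  mc <- S4Vectors::mcols(genes)
  if (!is.null(pathway_tag)) {
    tags <- mc$pathway_tags
    has_tag <- if (is.list(tags))
      vapply(tags, function(x) pathway_tag %in% x, logical(1))
    else vapply(strsplit(as.character(tags), ";", fixed = TRUE),
                function(x) pathway_tag %in% x, logical(1))
    genes <- genes[has_tag]
  }
  sense <- senseCodons(code)
  if (!length(genes)) {
    m <- matrix(numeric(0), 0, length(sense),
                dimnames = list(NULL, sense))
  } else {
    cct <- accumulateCounts(genes, depth_weighted = FALSE, code = code)
    ref <- buildReference(cct, pseudocount = 0.5)
    m <- ref@freq
  }
  if (!is.null(path))
    write_tsv(cbind(data.frame(taxon_id = rownames(m)), as.data.frame(m)),
              path)
  m
}
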