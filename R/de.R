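#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the median across features of the
#' ratio of a sample's count to the feature's geometric mean across samples,
#' computed over features with nonzero counts in every sample, then scaled
#' to geometric mean 1.
#'
#' @param counts nonnegative integer matrix (features x samples) or a
#'   [SummarizedExperiment::SummarizedExperiment] with a `"counts"` assay.
#' @param pseudo_reference when no feature is nonzero in all samples, fall
#'   back to geometric means over positive counts only instead of erroring.
#' @return named positive numeric vector, one factor per sample.
#' @export
computeSizeFactors <- function(counts, pseudo_reference = FALSE) {
  if (methods::is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  lc <- log(counts)
  all_pos <- rowSums(is.finite(lc)) == ncol(counts)
  if (!any(all_pos)) {
    if (!pseudo_reference)
      stop("no feature has nonzero counts in all samples; ",
           "set pseudo_reference = TRUE to use a positive-count reference")
    geo <- apply(lc, 1, function(v) mean(v[is.finite(v)]))
    use <- is.finite(geo)
    med <- apply(lc[use, , drop = FALSE] - geo[use], 2,
                 function(v) median(v[is.finite(v)]))
  } else {
    geo <- rowMeans(lc[all_pos, , drop = FALSE])
    med <- apply(lc[all_pos, , drop = FALSE] - geo, 2, median)
  }
  sf <- exp(med - mean(med))
  setNames(sf, colnames(counts))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment. Thin validated wrapper over
#' `p.adjust(..., method = "BH")`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as `p`.
#' @export
bhFdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Aggregate gene counts to KO-level features
#'
#' Sums count rows of genes sharing a KO identifier (community-scale
#' analyses work at KO level; MAG-scale analyses at gene level). Genes
#' without a KO are dropped.
#'
#' @param se counts [SummarizedExperiment::SummarizedExperiment].
#' @param ko character vector of per-gene KO ids (defaults to
#'   `rowData(se)$ko_id`).
#' @return a KO-level SummarizedExperiment with the same colData.
#' @export
aggregateByKO <- function(se, ko = NULL) {
  if (is.null(ko)) ko <- SummarizedExperiment::rowData(se)$ko_id
  if (is.null(ko)) stop("KO ids required (ko= or rowData ko_id)")
  ko <- as.character(ko)
  keep <- !is.na(ko) & nzchar(ko)
  m <- rowsum(SummarizedExperiment::assay(se, "counts")[keep, , drop = FALSE],
              group = ko[keep])
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    colData = SummarizedExperiment::colData(se))
}

#' Simplified negative-binomial Wald test for differential expression
#'
#' A deliberately simple treatment-vs-control contrast: median-of-ratios
#' normalization, per-feature method-of-moments dispersion moderated toward
#' the across-feature trend, and a Wald z-test on
#' `lfc = log2(mean normalized treatment / mean normalized control)`.
#' No dispersion or LFC shrinkage beyond the moderation, no outlier
#' refitting — the contract is calibration, unbiasedness and the FDR < 0.1
#' significance rule, not bit-reproduction of any particular DE tool.
#'
#' When either arm mean is zero, an offset of 0.5 normalized counts is added
#' to both arm means for that feature (flagged in the output).
#'
#' @param se counts [SummarizedExperiment::SummarizedExperiment] with
#'   colData `treatment`.
#' @param control,treatment levels of `treatment` to contrast.
#' @param fdr significance threshold on the BH-adjusted p-value
#'   (default 0.1).
#' @param prior_df weight (in pseudo-degrees-of-freedom) of the dispersion
#'   trend in the moderated per-feature estimate.
#' @param dispersion_floor lower bound on the dispersion.
#' @param pseudo_reference passed to [computeSizeFactors()].
#' @return data.frame with `feature_id`, `base_mean`, `lfc`, `se`,
#'   `p_value`, `fdr`, `significant`, `zero_arm`, `dispersion`.
#' @export
estimateDE <- function(se, control, treatment, fdr = 0.1,
                       prior_df = 10, dispersion_floor = 1e-8,
                       pseudo_reference = FALSE) {
  counts <- SummarizedExperiment::assay(se, "counts")
  trt <- SummarizedExperiment::colData(se)$treatment
  idx_c <- which(trt == control)
  idx_t <- which(trt == treatment)
  if (length(idx_c) < 2L || length(idx_t) < 2L)
    stop("at least two replicates per arm required")
  sf <- computeSizeFactors(counts[, c(idx_c, idx_t), drop = FALSE],
                           pseudo_reference = pseudo_reference)
  norm <- sweep(counts[, c(idx_c, idx_t), drop = FALSE], 2, sf, "/")
  n_c <- length(idx_c); n_t <- length(idx_t)
  nc <- norm[, seq_len(n_c), drop = FALSE]
  nt <- norm[, n_c + seq_len(n_t), drop = FALSE]
  mu_c <- rowMeans(nc); mu_t <- rowMeans(nt)
  var_c <- apply(nc, 1, var); var_t <- apply(nt, 1, var)

  # per-feature method-of-moments dispersion, pooled across arms and
  # moderated toward the across-feature mean (per-feature estimates at a
  # handful of replicates are far too noisy to use raw)
  disp_arm <- function(v, mu) ifelse(mu > 0, (v - mu) / mu^2, NA)
  d_c <- disp_arm(var_c, mu_c); d_t <- disp_arm(var_t, mu_t)
  w_c <- ifelse(is.na(d_c), 0, n_c - 1); w_t <- ifelse(is.na(d_t), 0, n_t - 1)
  d_feat <- ifelse(w_c + w_t > 0,
                   (ifelse(is.na(d_c), 0, d_c) * w_c +
                    ifelse(is.na(d_t), 0, d_t) * w_t) / (w_c + w_t), NA)
  d_feat_f <- pmax(d_feat, 0)
  trend <- mean(d_feat_f, na.rm = TRUE)
  if (!is.finite(trend)) trend <- dispersion_floor
  df_feat <- w_c + w_t
  disp <- (prior_df * trend + df_feat * ifelse(is.na(d_feat_f), 0, d_feat_f)) /
    (prior_df + df_feat)
  disp <- pmax(disp, dispersion_floor)

  zero_arm <- mu_c == 0 | mu_t == 0
  off <- ifelse(zero_arm, 0.5, 0)
  mc <- mu_c + off; mt <- mu_t + off
  lfc <- log2(mt / mc)
  se_lfc <- sqrt(((1 / mc + disp) / n_c + (1 / mt + disp) / n_t)) / log(2)
  z <- lfc / se_lfc
  p <- 2 * pnorm(-abs(z))
  q <- bhFdr(p)
  data.frame(feature_id = rownames(counts), base_mean = rowMeans(norm),
             lfc = lfc, se = se_lfc, p_value = p, fdr = q,
             significant = q < fdr, zero_arm = zero_arm,
             dispersion = disp, row.names = NULL,
             stringsAsFactors = FALSE)
}
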