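#' Configuration for the synthetic community generator
#'
#' Defines the simulated study: a community of taxa with distinct synonymous
#' codon preference profiles, genes spanning a range of codon optimization
#' relative to their taxon's profile, per-gene read depths, and
#' negative-binomial transcript counts whose treatment log2-fold change is
#' coupled to a gene's true optimization for "growth" pathways and flat for
#' "stress" and "background" pathways.
#'
#' @param n_taxa number of taxa.
#' @param genes_per_taxon genes generated per taxon.
#' @param bias_strength concentration of synonymous preference; 0 gives
#'   exactly uniform family profiles, larger values give spikier (more
#'   biased) profiles.
#' @param optimization_range range of the per-gene mixing coefficient in
#'   \[0, 1\] between the taxon preference profile and uniform usage.
#' @param length_range_codons per-gene length range in codons (uniform).
#' @param depth_meanlog,depth_sdlog log-normal parameters of per-gene depth.
#' @param count_meanlog,count_sdlog log-normal parameters of the control-arm
#'   mean count per gene.
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + mu^2 * dispersion); must be positive.
#' @param lfc_noise_sd Gaussian sd of gene-level noise on the true LFC.
#' @param effect_model named list of `c(alpha, beta)` per pathway class:
#'   true LFC = alpha + beta * true_optimization + noise ("growth"), or
#'   alpha + noise (beta is 0 for "stress"/"background" by default).
#' @param pathway_proportions proportions of genes (by KO slot) assigned to
#'   each class; must sum to 1.
#' @param treatments two treatment levels, control first.
#' @param replicates replicates per treatment arm.
#' @param seed integer master seed; all stages derive substreams from it.
#' @return validated config list of class `"communityConfig"`.
#' @export
communityConfig <- function(n_taxa = 30L, genes_per_taxon = 50L,
                            bias_strength = 5,
                            optimization_range = c(0, 1),
                            length_range_codons = c(100L, 400L),
                            depth_meanlog = log(20), depth_sdlog = 1,
                            count_meanlog = log(50), count_sdlog = 1,
                            dispersion = 0.1,
                            lfc_noise_sd = 0.25,
                            effect_model = list(
                              growth = c(alpha = 0, beta = 2),
                              stress = c(alpha = 0, beta = 0),
                              background = c(alpha = 0, beta = 0)),
                            pathway_proportions = c(growth = 0.2,
                                                    stress = 0.2,
                                                    background = 0.6),
                            treatments = c("control", "treatment"),
                            replicates = 4L,
                            seed = 1L) {
  cfg <- list(n_taxa = as.integer(n_taxa),
              genes_per_taxon = as.integer(genes_per_taxon),
              bias_strength = bias_strength,
              optimization_range = optimization_range,
              length_range_codons = as.integer(length_range_codons),
              depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
              count_meanlog = count_meanlog, count_sdlog = count_sdlog,
              dispersion = dispersion, lfc_noise_sd = lfc_noise_sd,
              effect_model = effect_model,
              pathway_proportions = pathway_proportions,
              treatments = as.character(treatments),
              replicates = as.integer(replicates),
              seed = as.integer(seed))
  if (cfg$n_taxa < 0L) stop("n_taxa must be nonnegative")
  if (cfg$bias_strength < 0) stop("bias_strength must be >= 0")
  if (any(cfg$optimization_range < 0) || any(cfg$optimization_range > 1))
    stop("optimization_range must lie in [0, 1]")
  if (cfg$dispersion <= 0) stop("dispersion must be positive")
  if (cfg$lfc_noise_sd < 0) stop("lfc_noise_sd must be nonnegative")
  if (abs(sum(cfg$pathway_proportions) - 1) > 1e-8)
    stop("pathway_proportions must sum to 1")
  miss <- setdiff(names(cfg$pathway_proportions), names(cfg$effect_model))
  if (length(miss))
    stop("effect_model missing class(es): ", paste(miss, collapse = ", "))
  if (length(cfg$treatments) != 2L) stop("exactly two treatments required")
  if (cfg$replicates < 1L) stop("at least one replicate per arm required")
  class(cfg) <- "communityConfig"
  cfg
}

# substream seeds (kept below 2^31) so stages regenerate independently
substream_seed <- function(seed, stage, unit = 0L)
  as.integer((as.double(seed) * 97 + stage * 1e6 + unit) %% 2147483629)

#' Generate per-taxon synonymous codon preference profiles
#'
#' For each taxon and each synonymous family, a probability vector over the
#' family's codons, drawn from a symmetric Dirichlet whose concentration is
#' the inverse of `bias_strength` (0 gives exactly uniform vectors).
#' Deterministic given the config seed.
#'
#' @param config a [communityConfig()].
#' @param code a [GeneticCode-class].
#' @return numeric matrix taxa x 61 sense codons of within-family
#'   probabilities.
#' @export
generateReferenceProfiles <- function(config, code = geneticCode()) {
  set.seed(substream_seed(config$seed, 1L))
  sense <- senseCodons(code)
  aa <- translateCodon(sense, code)
  taxa <- sprintf("taxon_%02d", seq_len(config$n_taxa))
  prof <- matrix(NA_real_, config$n_taxa, length(sense),
                 dimnames = list(taxa, sense))
  if (config$n_taxa == 0L) return(prof)
  for (fam in split(sense, aa)) {
    r <- length(fam)
    if (config$bias_strength == 0) {
      prof[, fam] <- matrix(1 / r, config$n_taxa, r)
    } else {
      g <- matrix(rgamma(config$n_taxa * r,
                         shape = 1 / config$bias_strength, rate = 1),
                  config$n_taxa, r)
      # guard against all-zero gamma draws at extreme concentrations
      g[rowSums(g) == 0, ] <- 1
      prof[, fam] <- g / rowSums(g)
    }
  }
  prof
}

#' Generate coding sequences with known optimization ground truth
#'
#' Each gene's codons are drawn family-by-family from the mixture
#' `t * taxon preference + (1 - t) * uniform`, where `t` is the gene's true
#' optimization level (uniform over `optimization_range`). Amino acids are
#' drawn uniformly; no stop codons occur in frame. KO slots are shared
#' across taxa (gene j of every taxon carries the same KO) and pathway
#' classes are assigned per KO slot by the configured proportions.
#'
#' @param config a [communityConfig()].
#' @param profiles from [generateReferenceProfiles()].
#' @param code a [GeneticCode-class].
#' @return list with `genes` (a [Biostrings::DNAStringSet] with mcols
#'   `taxon_id`, `ko_id`, `pathway_tags`, `depth`) and `truth` (data.frame
#'   with `gene_id`, `taxon_id`, `ko_id`, `pathway_class`,
#'   `true_optimization`, `true_lfc`, `depth`).
#' @export
generateGenes <- function(config, profiles, code = geneticCode()) {
  sense <- senseCodons(code)
  aa <- translateCodon(sense, code)
  fams <- split(sense, aa)
  aas <- names(fams)
  g <- config$genes_per_taxon
  n_ko <- g
  classes <- names(config$pathway_proportions)
  n_per <- floor(config$pathway_proportions * n_ko)
  n_per[length(n_per)] <- n_ko - sum(n_per[-length(n_per)])
  ko_class <- rep(classes, times = n_per)
  taxa <- rownames(profiles)

  seq_list <- character(0)
  truth <- vector("list", config$n_taxa)
  for (i in seq_along(taxa)) {
    set.seed(substream_seed(config$seed, 2L, i))
    tx <- taxa[i]
    L <- sample(seq(config$length_range_codons[1],
                    config$length_range_codons[2]), g, replace = TRUE)
    t_opt <- runif(g, config$optimization_range[1],
                   config$optimization_range[2])
    depth <- rlnorm(g, config$depth_meanlog, config$depth_sdlog)
    noise <- rnorm(g, 0, config$lfc_noise_sd)
    eff <- do.call(rbind, config$effect_model[ko_class])
    true_lfc <- eff[, "alpha"] +
      ifelse(ko_class == "growth", eff[, "beta"] * t_opt, 0) + noise
    seqs <- character(g)
    for (j in seq_len(g)) {
      aa_seq <- sample(aas, L[j], replace = TRUE)
      cod <- character(L[j])
      for (a in unique(aa_seq)) {
        fam <- fams[[a]]
        p <- t_opt[j] * profiles[tx, fam] +
          (1 - t_opt[j]) / length(fam)
        idx <- which(aa_seq == a)
        cod[idx] <- sample(fam, length(idx), replace = TRUE, prob = p)
      }
      seqs[j] <- paste(cod, collapse = "")
    }
    ids <- sprintf("%s_g%03d", tx, seq_len(g))
    names(seqs) <- ids
    seq_list <- c(seq_list, seqs)
    truth[[i]] <- data.frame(
      gene_id = ids, taxon_id = tx,
      ko_id = sprintf("K%05d", seq_len(g)),
      pathway_class = ko_class,
      true_optimization = t_opt, true_lfc = true_lfc, depth = depth,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  genes <- Biostrings::DNAStringSet(seq_list)
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    taxon_id = truth$taxon_id, ko_id = truth$ko_id,
    pathway_tags = I(as.list(truth$pathway_class)),
    depth = truth$depth)
  list(genes = genes, truth = truth)
}

#' Generate a negative-binomial transcript count matrix from ground truth
#'
#' Control-arm means are log-normal per gene; treatment-arm means are
#' `control mean * 2^true_lfc`; counts are negative binomial with the
#' configured dispersion. Deterministic given the config seed.
#'
#' @param config a [communityConfig()].
#' @param truth the truth table from [generateGenes()].
#' @return A [SummarizedExperiment::SummarizedExperiment] (assay
#'   `"counts"`, colData `treatment`/`replicate`).
#' @export
generateCounts <- function(config, truth) {
  if (config$dispersion <= 0) stop("dispersion must be positive")
  set.seed(substream_seed(config$seed, 3L))
  n <- nrow(truth)
  reps <- config$replicates
  trt <- config$treatments
  mu0 <- rlnorm(n, config$count_meanlog, config$count_sdlog)
  mu1 <- mu0 * 2^truth$true_lfc
  size <- 1 / config$dispersion
  cols <- c(paste0(trt[1], "_", seq_len(reps)),
            paste0(trt[2], "_", seq_len(reps)))
  counts <- matrix(0L, n, 2L * reps, dimnames = list(truth$gene_id, cols))
  for (r in seq_len(reps)) {
    counts[, r] <- rnbinom(n, mu = mu0, size = size)
    counts[, reps + r] <- rnbinom(n, mu = mu1, size = size)
  }
  design <- data.frame(sample_id = cols,
                       treatment = rep(trt, each = reps),
                       replicate = rep(seq_len(reps), times = 2L),
                       stringsAsFactors = FALSE)
  makeCountMatrix(counts, design)
}

#' Simulate a full synthetic community
#'
#' Runs profile, gene and count generation and returns everything needed by
#' the downstream pipeline together with the generator ground truth.
#'
#' @param config a [communityConfig()].
#' @param code a [GeneticCode-class].
#' @return list with `genes`, `truth`, `counts`, `profiles`, `config`.
#' @export
simulateCommunity <- function(config = communityConfig(),
                              code = geneticCode()) {
  profiles <- generateReferenceProfiles(config, code)
  gg <- generateGenes(config, profiles, code)
  counts <- generateCounts(config, gg$truth)
  list(genes = gg$genes, truth = gg$truth, counts = counts,
       profiles = profiles, config = config)
}

#' Write a simulated community to a directory of standard files
#'
#' Emits `cds.fasta`, `annotations.tsv`, `depths.tsv`, `counts.tsv`,
#' `design.tsv` and `truth.tsv` so the file-based pipeline entry points can
#' be exercised on synthetic data.
#'
#' @param sim from [simulateCommunity()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeCommunity <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCds(sim$genes, file.path(dir, "cds.fasta"))
  tr <- sim$truth
  write_tsv(data.frame(gene_id = tr$gene_id, taxon_id = tr$taxon_id,
                       ko_id = tr$ko_id, pathway_tags = tr$pathway_class,
                       stringsAsFactors = FALSE),
            file.path(dir, "annotations.tsv"))
  write_tsv(data.frame(gene_id = tr$gene_id, depth = tr$depth),
            file.path(dir, "depths.tsv"))
  cm <- SummarizedExperiment::assay(sim$counts, "counts")
  write_tsv(cbind(data.frame(gene_id = rownames(cm)), as.data.frame(cm)),
            file.path(dir, "counts.tsv"))
  cd <- SummarizedExperiment::colData(sim$counts)
  write_tsv(data.frame(sample_id = rownames(cd),
                       treatment = cd$treatment,
                       replicate = cd$replicate),
            file.path(dir, "design.tsv"))
  write_tsv(tr, file.path(dir, "truth.tsv"))
  invisible(dir)
}
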