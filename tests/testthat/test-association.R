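test_that("weighted summaries implement depth-weighted means with NA skipping", {
  tr <- data.frame(gene_id = c("a", "b"), ko_id = c("K1", "K1"),
                   fop = c(1, 3))
  s <- weightedSummary(tr, weights = c(1, 1), by = "ko_id",
                       trait_cols = "fop")
  expect_equal(s$fop, 2)
  s2 <- weightedSummary(tr, weights = c(3, 1), by = "ko_id",
                        trait_cols = "fop")
  expect_equal(s2$fop, 1.5)
  # single gene: identity
  s3 <- weightedSummary(tr[1, ], weights = 5, by = "ko_id",
                        trait_cols = "fop")
  expect_equal(s3$fop, 1)
  # undefined trait skipped with weight renormalization
  tr$fop[2] <- NA
  s4 <- weightedSummary(tr, weights = c(3, 1), by = "ko_id",
                        trait_cols = "fop")
  expect_equal(s4$fop, 1)
  # all-NA group is NA, not 0
  tr$fop <- NA_real_
  expect_true(is.na(weightedSummary(tr, weights = c(1, 1), by = "ko_id",
                                    trait_cols = "fop")$fop))
})

test_that("weighted summaries are scale invariant and bounded by members", {
  set.seed(13)
  tr <- data.frame(gene_id = paste0("g", 1:40),
                   ko_id = sample(c("K1", "K2", "K3"), 40, replace = TRUE),
                   fop = runif(40), cai = runif(40))
  w <- rlnorm(40)
  s1 <- weightedSummary(tr, weights = w, by = "ko_id",
                        trait_cols = c("fop", "cai"))
  s2 <- weightedSummary(tr, weights = 2 * w, by = "ko_id",
                        trait_cols = c("fop", "cai"))
  expect_equal(s1$fop, s2$fop, tolerance = 1e-12)
  seq_w <- weightedSummary(tr, weights = rep(1, 40), by = "ko_id",
                           trait_cols = "fop")
  for (k in seq_w$ko_id) {
    members <- tr$fop[tr$ko_id == k]
    v <- seq_w$fop[seq_w$ko_id == k]
    expect_equal(v, mean(members), tolerance = 1e-12)
    expect_true(v >= min(members) - 1e-12 && v <= max(members) + 1e-12)
  }
})

test_that("group comparison reduces to the two-sample t-test for two groups", {
  set.seed(19)
  df <- data.frame(treatment = rep(c("a", "b"), each = 6),
                   fop = c(rnorm(6, 0.5, 0.05), rnorm(6, 0.6, 0.05)))
  out <- compareGroups(df, "treatment", trait_cols = "fop")
  tt <- t.test(fop ~ treatment, data = df, var.equal = TRUE)
  expect_equal(out$omnibus$F[1], unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(out$omnibus$p_value[1], tt$p.value, tolerance = 1e-9)
  expect_equal(nrow(out$pairwise), 1L)
  expect_error(compareGroups(df[df$treatment == "a", ], "treatment"),
               "two groups")
  expect_warning(compareGroups(rbind(df, data.frame(treatment = "c",
                                                    fop = 0.5)),
                               "treatment"), "single replicate")
})

test_that("a five-sd group shift is detected at n = 4 per group", {
  set.seed(23)
  df <- data.frame(treatment = rep(c("a", "b", "c"), each = 4),
                   fop = c(rnorm(4, 0, 1), rnorm(4, 0, 1), rnorm(4, 5, 1)))
  out <- compareGroups(df, "treatment", trait_cols = "fop")
  expect_lt(out$omnibus$p_value[1], 0.001)
  pc <- out$pairwise[out$pairwise$comparison == "c-a", ]
  expect_lt(pc$p_adj, 0.01)
})

test_that("LFC-on-trait regression matches closed-form OLS and flags collinearity", {
  de <- data.frame(feature_id = paste0("g", 1:10), lfc = 2 * (1:10))
  tr <- data.frame(gene_id = paste0("g", 1:10), fop = 1:10)
  fit <- suppressWarnings(regressLfcOnTraits(de, tr, "fop"))  # exact fit
  expect_equal(fit$coefficients$estimate[2], 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # random fixture against the normal equations
  set.seed(29)
  tr2 <- data.frame(gene_id = paste0("g", 1:50), fop = runif(50),
                    cai = runif(50))
  de2 <- data.frame(feature_id = paste0("g", 1:50),
                    lfc = 1 + 0.5 * tr2$fop - 2 * tr2$cai + rnorm(50, 0, 0.3))
  fit2 <- regressLfcOnTraits(de2, tr2, c("fop", "cai"))
  X <- cbind(1, tr2$fop, tr2$cai)
  beta <- oracle_ols(X, de2$lfc)
  expect_equal(fit2$coefficients$estimate, as.numeric(beta),
               tolerance = 1e-10)
  # collinear predictors error by name
  tr2$fop2 <- 2 * tr2$fop
  expect_error(regressLfcOnTraits(de2, tr2, c("fop", "fop2")),
               "collinear.*fop2")
})

test_that("slope confidence intervals cover zero at the nominal rate", {
  set.seed(37)
  cover <- 0
  for (i in 1:200) {
    x <- runif(20)
    y <- rnorm(20)
    de <- data.frame(feature_id = paste0("g", 1:20), lfc = y)
    tr <- data.frame(gene_id = paste0("g", 1:20), fop = x)
    ci <- regressLfcOnTraits(de, tr, "fop")$confint["fop", ]
    if (ci[1] <= 0 && ci[2] >= 0) cover <- cover + 1
  }
  expect_gt(cover / 200, 0.90)
  expect_lt(cover / 200, 0.99)
})

test_that("pathway-level relation refuses tiny fits but emits points", {
  tr <- data.frame(gene_id = c("a", "b"), taxon_id = c("m1", "m2"),
                   pathway_tags = c("growth", "growth"), fop = c(0.3, 0.6))
  de <- data.frame(feature_id = c("a", "b"), lfc = c(0.1, 1.2))
  out <- pathwayLevelRelation(tr, de, "growth")
  expect_null(out$fit)
  expect_match(out$refused, "refused")
  expect_equal(nrow(out$points), 2L)
  expect_error(pathwayLevelRelation(tr, de, "no_such_tag"), "no genes")
})

test_that("an extreme synthetic outlier is the max leave-one-out influence", {
  set.seed(43)
  n <- 12
  tr <- data.frame(gene_id = paste0("g", 1:n),
                   taxon_id = paste0("m", 1:n),
                   pathway_tags = rep("growth", n),
                   fop = seq(0.2, 0.8, length.out = n))
  de <- data.frame(feature_id = paste0("g", 1:n),
                   lfc = 2 * tr$fop + rnorm(n, 0, 0.05))
  de$lfc[n] <- 25   # one wildly over-expressed lineage
  out <- pathwayLevelRelation(tr, de, "growth")
  expect_equal(out$max_influence, "m12")
  out_ex <- pathwayLevelRelation(tr, de, "growth", exclusions = "m12")
  expect_equal(out_ex$fit_excluded$coefficients$estimate[2], 2,
               tolerance = 0.2)
})

test_that("codon matrix export normalizes family blocks per taxon", {
  set.seed(47)
  genes <- Biostrings::DNAStringSet(
    setNames(replicate(6, random_gene(100)), paste0("g", 1:6)))
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    taxon_id = rep(c("m1", "m2", "m3"), each = 2),
    pathway_tags = rep("growth", 6))
  m <- exportCodonMatrix(genes, "growth")
  expect_equal(dim(m), c(3L, 61L))
  code <- geneticCode()
  for (fam in synonymousFamilies(code))
    expect_equal(unname(rowSums(m[, fam$codons, drop = FALSE])),
                 rep(1, 3), tolerance = 1e-12)
  # empty pathway: empty matrix with codon header
  m0 <- exportCodonMatrix(genes, "absent_tag")
  expect_equal(dim(m0), c(0L, 61L))
  expect_equal(colnames(m0), senseCodons(code))
  # single-gene taxon: fully observed families equal the gene's composition
  g1 <- genes[1]
  m1 <- exportCodonMatrix(g1, "growth")
  p <- codonProfile(as.character(genes[[1]]))
  for (fam in synonymousFamilies(code)) {
    O <- p$O[fam$codons]
    if (all(O > 0))
      expect_equal(unname(m1[1, fam$codons]), unname(O / sum(O)),
                   tolerance = 1e-12)
  }
})

test_that("transcript-pool means shift with count weighting", {
  # two genes, trait 0 and 1; sample A expresses gene1, sample B gene2
  tr <- data.frame(gene_id = c("g1", "g2"), fop = c(0, 1),
                   depth = c(1, 1))
  m <- rbind(g1 = c(90, 10), g2 = c(10, 90))
  colnames(m) <- c("A", "B")
  design <- data.frame(sample_id = c("A", "B"),
                       treatment = c("control", "treatment"),
                       replicate = c(1L, 1L))
  se <- makeCountMatrix(m, design)
  pool <- transcriptPoolMeans(tr, se, weighting = "counts",
                              trait_cols = "fop")
  expect_equal(pool$fop, c(0.1, 0.9), tolerance = 1e-9)
  pool_d <- transcriptPoolMeans(tr, se, weighting = "depth",
                                trait_cols = "fop")
  expect_equal(pool_d$fop, c(0.5, 0.5), tolerance = 1e-12)
})
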