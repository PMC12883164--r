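# Independent brute-force oracles and small fixture builders. The oracles
# deliberately share no code with the package implementations: plain loops
# over codons/sites, evaluated termwise.

std_code <- geneticCode()

split_codons <- function(s) {
  s <- toupper(s)
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

# a CodonCountTable with one taxon; `overrides` is a named vector of counts,
# all other sense codons get `fill`
make_cct <- function(overrides = NULL, fill = 1, taxon = "tax",
                     code = std_code) {
  sense <- senseCodons(code)
  counts <- matrix(fill, 1, length(sense), dimnames = list(taxon, sense))
  if (!is.null(overrides)) counts[, names(overrides)] <- overrides
  new("CodonCountTable", counts = counts, stops = 0, skipped = 0,
      code = code)
}

# multi-taxon variant from a taxa x codon matrix
make_cct_multi <- function(counts, code = std_code) {
  new("CodonCountTable", counts = counts,
      stops = rep(0, nrow(counts)), skipped = rep(0, nrow(counts)),
      code = code)
}

random_gene <- function(n_codons, code = std_code) {
  paste(sample(senseCodons(code), n_codons, replace = TRUE), collapse = "")
}

# random reference: Dirichlet-ish positive counts for every codon
random_ref <- function(code = std_code) {
  sense <- senseCodons(code)
  counts <- matrix(rgamma(length(sense), 2, 1) * 100 + 1, 1,
                   length(sense), dimnames = list("tax", sense))
  buildReference(make_cct_multi(counts, code), pseudocount = 0)
}

oracle_cai <- function(seq, w, code = std_code) {
  logs <- c()
  for (cd in split_codons(seq)) {
    aa <- translateCodon(cd, code)
    if (is.na(aa) || aa == "*") next
    logs <- c(logs, log(w[[cd]]))
  }
  exp(mean(logs))
}

oracle_fop <- function(seq, optimal, code = std_code) {
  n_opt <- 0; n_tot <- 0
  for (cd in split_codons(seq)) {
    aa <- translateCodon(cd, code)
    if (is.na(aa) || aa == "*") next
    n_tot <- n_tot + 1
    if (cd %in% optimal) n_opt <- n_opt + 1
  }
  n_opt / n_tot
}

# termwise evaluation: M_a = sum O_c ln(f_c/g_c); MILC = sum M_a / L - C;
# C = sum (r_a - 1)/L - 0.5 over amino acids present
oracle_milc <- function(seq, g, code = std_code) {
  cods <- split_codons(seq)
  aas <- sapply(cods, function(cd) translateCodon(cd, code))
  keep <- !is.na(aas) & aas != "*"
  cods <- cods[keep]; aas <- aas[keep]
  L <- length(cods)
  M_total <- 0; corr <- 0
  for (a in unique(aas)) {
    fam_codons <- cods[aas == a]
    fam_all <- synonymousFamily(a, code)$codons
    n_a <- length(fam_codons)
    M_a <- 0
    for (cd in unique(fam_codons)) {
      O_c <- sum(fam_codons == cd)
      f_c <- O_c / n_a
      M_a <- M_a + O_c * log(f_c / g[[cd]])
    }
    M_total <- M_total + M_a
    corr <- corr + (length(fam_all) - 1)
  }
  M_total / L - (corr / L - 0.5)
}

# second, loop-style evaluation of the background-corrected effective
# number of codons
oracle_encprime <- function(seq, g, code = std_code, min_n = 2) {
  cods <- split_codons(seq)
  aas <- sapply(cods, function(cd) translateCodon(cd, code))
  keep <- !is.na(aas) & aas != "*"
  cods <- cods[keep]; aas <- aas[keep]
  fams <- synonymousFamilies(code)
  Fp <- list()
  for (a in names(fams)) {
    r_a <- fams[[a]]$r_a
    if (r_a < 2) next
    fam_codons <- cods[aas == a]
    n_a <- length(fam_codons)
    if (n_a < min_n) next
    chi2 <- 0
    for (cd in fams[[a]]$codons) {
      f_obs <- sum(fam_codons == cd) / n_a
      e <- g[[cd]]
      chi2 <- chi2 + (f_obs - e)^2 / e
    }
    chi2 <- chi2 * n_a
    Fp[[a]] <- list(r = r_a, F = (chi2 + n_a - r_a) / (r_a * (n_a - 1)))
  }
  r_all <- sapply(fams, function(f) f$r_a)
  sizes <- sort(unique(r_all[r_all >= 2]))
  Fbar <- sapply(sizes, function(r) {
    vals <- sapply(Fp[sapply(Fp, function(x) x$r == r)], function(x) x$F)
    if (length(vals) == 0) NA_real_ else mean(unlist(vals))
  })
  names(Fbar) <- sizes
  if (is.na(Fbar["3"]) && !is.na(Fbar["2"]) && !is.na(Fbar["4"]))
    Fbar["3"] <- (Fbar["2"] + Fbar["4"]) / 2
  if (any(is.na(Fbar)) || any(Fbar < 1e-8)) return(NA_real_)
  enc <- sum(r_all == 1)
  for (r in sizes)
    enc <- enc + sum(r_all == r) / Fbar[as.character(r)]
  min(max(enc, 1), 61)
}

# per-site loop with exhaustive substitution done inline (independent of
# classifySite)
oracle_site_nt <- function(seq, want_class, code = std_code) {
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  nts <- c("A", "C", "G", "T")
  for (cd in split_codons(seq)) {
    aa <- translateCodon(cd, code)
    if (is.na(aa) || aa == "*") next
    for (pos in 1:3) {
      same <- logical(0)
      for (nt in setdiff(nts, substr(cd, pos, pos))) {
        mut <- cd
        substr(mut, pos, pos) <- nt
        same <- c(same, identical(translateCodon(mut, code), aa))
      }
      cls <- if (all(same)) "fourfold"
             else if (!any(same)) "nonsynonymous" else "mixed"
      if (cls == want_class) {
        nt0 <- substr(cd, pos, pos)
        counts[nt0] <- counts[nt0] + 1
      }
    }
  }
  counts
}

oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  # step-up: q_(i) = min_{j >= i} p_(j) * m / j
  sorted <- p[ord]
  run_min <- Inf
  for (i in m:1) {
    run_min <- min(run_min, sorted[i] * m / i)
    q[ord[i]] <- min(run_min, 1)
  }
  q
}

oracle_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# shared default-scenario simulation (memoized): the study conditions of the
# end-to-end recovery checks
.shared <- new.env()
shared_sim <- function() {
  if (is.null(.shared$sim)) .shared$sim <-
    simulateCommunity(communityConfig(seed = 42L))
  .shared$sim
}
shared_traits <- function() {
  if (is.null(.shared$traits)) {
    sim <- shared_sim()
    ref <- buildReference(filterTaxa(accumulateCounts(sim$genes),
                                     min_total = 0))
    .shared$ref <- ref
    .shared$traits <- computeGeneTraits(sim$genes, ref)
  }
  .shared$traits
}
shared_ref <- function() { shared_traits(); .shared$ref }
shared_de <- function() {
  if (is.null(.shared$de))
    .shared$de <- estimateDE(shared_sim()$counts, "control", "treatment")
  .shared$de
}
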