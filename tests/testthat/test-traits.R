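test_that("codon profiles count sense codons and tally the rest", {
  p <- codonProfile("GAAGAAGAG")
  expect_equal(p$O[["GAA"]], 2)
  expect_equal(p$O[["GAG"]], 1)
  expect_equal(p$L, 3)
  p2 <- codonProfile("ATG")
  expect_equal(p2$O[["ATG"]], 1)
  expect_equal(p2$L, 1)
  p3 <- codonProfile("GAANNNGAG")
  expect_equal(p3$L, 2)
  expect_equal(p3$n_skipped, 1)
  p4 <- codonProfile("GAATAA")
  expect_equal(p4$L, 1)
  expect_equal(p4$n_stops, 1)
  expect_error(codonProfile(""), "empty")
  expect_error(codonProfile("GAAG"), "divisible")
})

test_that("CAI reproduces the three-codon worked example and its limits", {
  ref <- buildReference(make_cct(c(GAA = 20, GAG = 80)), pseudocount = 0)
  v <- cai("GAAGAAGAG", ref, "tax")
  expect_equal(v, (0.25 * 0.25 * 1)^(1 / 3), tolerance = 1e-12)
  expect_equal(round(v, 2), 0.40)
  expect_equal(cai("GAGGAGGAG", ref, "tax"), 1)
  # zero-weight codon without pseudocount errors with advice
  ref0 <- buildReference(make_cct(c(GAA = 0, GAG = 100)), pseudocount = 0)
  expect_error(cai("GAAGAG", ref0, "tax"), "pseudocount")
})

test_that("FOP counts optimal codons; ties make every codon optimal", {
  ref <- buildReference(make_cct(c(GAA = 20, GAG = 80)), pseudocount = 0)
  expect_equal(fop("GAAGAAGAG", ref, "tax"), 1 / 3)
  expect_equal(fop("GAGGAGGAG", ref, "tax"), 1)
  ref_u <- buildReference(make_cct(), pseudocount = 0)  # uniform counts
  expect_equal(fop(random_gene(30), ref_u, "tax"), 1)
})

test_that("MILC equals -C when observed family frequencies match the null", {
  # 100 Glu codons at 50/50 against g = {0.5, 0.5}: M_a = 0, C = 1/100 - 0.5
  ref <- buildReference(make_cct(c(GAA = 50, GAG = 50)), pseudocount = 0)
  s <- paste(rep(c("GAA", "GAG"), each = 50), collapse = "")
  expect_equal(milc(s, ref, "tax"), 0.49, tolerance = 1e-12)
  # a multi-family transcript matching g exactly also gives -C
  code <- geneticCode()
  fams <- synonymousFamilies(code)
  s2 <- paste(unlist(lapply(fams, function(f) rep(f$codons, 12))),
              collapse = "")
  ref_u <- buildReference(make_cct(), pseudocount = 0)  # uniform g
  L <- 61 * 12
  C <- sum(vapply(fams, function(f) f$r_a - 1, numeric(1))) / L - 0.5
  expect_equal(milc(s2, ref_u, "tax"), -C, tolerance = 1e-12)
  # divergence from g at fixed L increases MILC
  s3 <- paste(rep(vapply(fams, function(f) f$codons[1], ""),
                  each = 12), collapse = "")
  expect_gt(milc(s3, ref_u, "tax"), milc(s2, ref_u, "tax"))
})

test_that("ENC' hits its classical limits", {
  code <- geneticCode()
  fams <- synonymousFamilies(code)
  ref_u <- buildReference(make_cct(), pseudocount = 0)
  # usage exactly at (uniform) background, long transcript: ~61
  s_bg <- paste(unlist(lapply(fams, function(f) rep(f$codons, 20))),
                collapse = "")
  expect_equal(encPrime(s_bg, ref_u, "tax"), 61, tolerance = 1e-9)
  # one codon per family against uniform background: the 20-residue bound
  s_one <- paste(rep(vapply(fams, function(f) f$codons[1], ""),
                     each = 60), collapse = "")
  expect_equal(encPrime(s_one, ref_u, "tax"), 20, tolerance = 1e-9)
  # too little data is flagged undefined, not zero
  expect_true(is.na(encPrime("GAAGAA", ref_u, "tax")))
})

test_that("all indices agree with independent brute-force oracles", {
  set.seed(1234)
  ref <- random_ref()
  w <- codonWeights(ref, "tax")
  g <- expectedFrequencies(ref, "tax")
  opt <- optimalCodons(ref, "tax")
  for (i in 1:100) {
    s <- random_gene(sample(80:200, 1))
    expect_equal(cai(s, ref, "tax"), oracle_cai(s, w), tolerance = 1e-12)
    expect_equal(fop(s, ref, "tax"), oracle_fop(s, opt), tolerance = 1e-12)
    expect_equal(milc(s, ref, "tax"), oracle_milc(s, g), tolerance = 1e-12)
    e1 <- encPrime(s, ref, "tax")
    e2 <- oracle_encprime(s, g)
    expect_equal(e1, e2, tolerance = 1e-9)
  }
})

test_that("site-filtered GC and skews agree with the per-site oracle", {
  set.seed(99)
  for (i in 1:40) {
    s <- random_gene(sample(30:80, 1))
    for (cls in c(SITE_FOURFOLD, SITE_NONSYNONYMOUS)) {
      n <- oracle_site_nt(s, cls)
      gc_o <- if (sum(n) == 0) NA_real_ else (n[["G"]] + n[["C"]]) / sum(n)
      expect_equal(gcContent(s, cls), gc_o, tolerance = 1e-12)
      gs_o <- if (n[["G"]] + n[["C"]] == 0) NA_real_ else
        (n[["G"]] - n[["C"]]) / (n[["G"]] + n[["C"]])
      expect_equal(gcSkew(s, cls), gs_o, tolerance = 1e-12)
      as_o <- if (n[["A"]] + n[["T"]] == 0) NA_real_ else
        (n[["A"]] - n[["T"]]) / (n[["A"]] + n[["T"]])
      expect_equal(atSkew(s, cls), as_o, tolerance = 1e-12)
    }
  }
})

test_that("GC and skew handle textbook compositions and extremes", {
  expect_equal(gcContent("GGCC"), 1)
  expect_equal(gcContent("GCTGCG", SITE_FOURFOLD), 0.5)  # Ala-Ala thirds T, G
  expect_equal(atSkew("AATT"), 0)
  expect_equal(gcSkew("GGCC"), 0)
  expect_equal(gcSkew("GGGGGG"), 1)
  expect_equal(gcSkew("CCCCCC"), -1)
  expect_true(is.na(gcSkew("AATTAA")))    # empty G+C pool
  expect_true(is.na(gcContent("ATGATG", SITE_FOURFOLD)))  # no fourfold site
})

test_that("amino acid traits follow residue composition only", {
  tables <- aminoAcidTables()
  hg <- aminoAcidTraits(strrep("G", 25), tables)
  expect_equal(hg$cn_ratio, 2.0)
  expect_equal(hg$mean_cost, tables$cost[["G"]])
  hr <- aminoAcidTraits(strrep("R", 10), tables)
  expect_equal(hr$cn_ratio, 1.5)
  # any homopolymer's mean cost is that residue's cost
  for (r in names(tables$cost))
    expect_equal(aminoAcidTraits(strrep(r, 7), tables)$mean_cost,
                 tables$cost[[r]])
  # synonymous recoding leaves amino-acid traits unchanged
  a1 <- aminoAcidTraits("GAAGAAGAA", tables, translate = TRUE)
  a2 <- aminoAcidTraits("GAGGAGGAG", tables, translate = TRUE)
  expect_equal(a1$mean_cost, a2$mean_cost)
  expect_equal(a1$cn_ratio, a2$cn_ratio)
  # unknown residues: skipped with tally, or strict error
  ax <- aminoAcidTraits("GGX", tables)
  expect_equal(ax$n_skipped, 1L)
  expect_equal(ax$mean_cost, tables$cost[["G"]])
  expect_error(aminoAcidTraits("GGX", tables, strict = TRUE), "unknown")
})

test_that("length filter discards below 80 codons and keeps the boundary", {
  genes <- Biostrings::DNAStringSet(c(
    short = random_gene(79), edge = random_gene(80), long = random_gene(120)))
  kept <- lengthFilter(genes)
  expect_setequal(names(kept), c("edge", "long"))
  expect_equal(attr(kept, "n_discarded"), 1L)
  all_kept <- lengthFilter(genes, min_codons = 0L)
  expect_equal(length(all_kept), 3L)
})

test_that("traits are invariant under codon order permutation", {
  set.seed(21)
  ref <- random_ref()
  s <- random_gene(120)
  cods <- split_codons(s)
  s_perm <- paste(sample(cods), collapse = "")
  expect_equal(cai(s, ref, "tax"), cai(s_perm, ref, "tax"), tolerance = 1e-12)
  expect_equal(fop(s, ref, "tax"), fop(s_perm, ref, "tax"), tolerance = 1e-12)
  expect_equal(milc(s, ref, "tax"), milc(s_perm, ref, "tax"),
               tolerance = 1e-12)
  expect_equal(encPrime(s, ref, "tax"), encPrime(s_perm, ref, "tax"),
               tolerance = 1e-12)
  expect_equal(gcContent(s, SITE_FOURFOLD), gcContent(s_perm, SITE_FOURFOLD),
               tolerance = 1e-12)
})

test_that("swapping a codon to the family optimum never lowers CAI or FOP", {
  set.seed(31)
  ref <- random_ref()
  w <- codonWeights(ref, "tax")
  code <- geneticCode()
  for (i in 1:25) {
    cods <- split_codons(random_gene(100))
    j <- sample(100, 1)
    fam <- synonymousFamily(translateCodon(cods[j], code), code)$codons
    best <- fam[which.max(w[fam])]
    swapped <- cods
    swapped[j] <- best
    s0 <- paste(cods, collapse = ""); s1 <- paste(swapped, collapse = "")
    expect_gte(cai(s1, ref, "tax") - cai(s0, ref, "tax"), -1e-12)
    expect_gte(fop(s1, ref, "tax") - fop(s0, ref, "tax"), -1e-12)
  }
})

test_that("trait values stay in their defined ranges on fuzzed input", {
  set.seed(77)
  ref <- random_ref()
  for (i in 1:30) {
    s <- random_gene(sample(80:300, 1))
    expect_true(cai(s, ref, "tax") > 0 && cai(s, ref, "tax") <= 1)
    f <- fop(s, ref, "tax")
    expect_true(f >= 0 && f <= 1)
    g4 <- gcContent(s, SITE_FOURFOLD)
    expect_true(is.na(g4) || (g4 >= 0 && g4 <= 1))
    sk <- gcSkew(s, SITE_FOURFOLD)
    expect_true(is.na(sk) || (sk >= -1 && sk <= 1))
    e <- encPrime(s, ref, "tax")
    expect_true(is.na(e) || (e >= 1 && e <= 61))
  }
})

test_that("the full trait table flags missing references and empty pools as NA", {
  set.seed(41)
  ref <- random_ref()
  genes <- Biostrings::DNAStringSet(c(a = random_gene(100),
                                      b = random_gene(90)))
  tr <- computeGeneTraits(genes, ref, taxa = c("tax", "other_taxon"))
  expect_true(tr$has_reference[1])
  expect_false(tr$has_reference[2])
  expect_true(is.na(tr$cai[2]))
  expect_false(is.na(tr$gc_total[2]))  # sequence-only traits still computed
  expect_equal(tr$cai[1], cai(as.character(genes[[1]]), ref, "tax"),
               tolerance = 1e-12)
  expect_equal(tr$aa_mean_cost[1],
               aminoAcidTraits(as.character(genes[[1]]),
                               translate = TRUE)$mean_cost,
               tolerance = 1e-12)
})
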