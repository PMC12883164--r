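---
title: "Methods: codon usage, nucleotide and amino acid traits of metatranscriptomes"
author: "codonTraits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage, nucleotide and amino acid traits of metatranscriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonTraits)
```

## The problem

In a soil (or any community) metatranscriptome, the transcript pool mixes
thousands of taxa whose genomes differ in synonymous codon preference,
nucleotide economy and amino acid economy. A recurring question is whether
genes whose composition is "cheap and optimized" — codon usage aligned with
the taxon's preferred codons, energetically cheaper nucleotides at
synonymous sites, cheaper amino acids — are the genes that get transcribed
hardest when conditions change (for example after a labile-carbon pulse).
`codonTraits` provides the full chain needed to ask that question from
standard inputs: per-taxon reference codon frequencies built from
metagenome gene sets, per-transcript optimization and composition traits,
a simple differential-expression stage, and the statistics linking traits
to expression. A synthetic community generator with known ground truth
makes the whole chain testable without any external sequencing data.

## Reference codon frequencies

The natural reference for codon optimization is the tRNA pool, but tRNA
annotation is too sparse across community taxa to be usable; the package
therefore uses each taxon's *genomic background* codon frequencies as the
reference, the same single reference serving every index. Counts are
accumulated per taxon over all its genes, each codon occurrence weighted by
the gene's read depth (so abundant genomes dominate their taxon's profile
the way they dominate its reads). Two filters keep the estimates stable:

* taxa whose total depth-adjusted codon count falls **below 750,000** are
  removed (the boundary value is kept);
* genes with **fewer than 80 codons** are discarded before trait
  computation (80 is kept).

Within each synonymous family the frequency of codon $c$ is
$f_c = n_c / \sum_{c'} n_{c'}$ and the CAI weight is
$w_c = f_c / \max f_{\text{synonymous}}$. A pseudocount (default 0.5) is
added per codon *only in families with at least one unobserved member*:
this prevents zero weights (which would collapse CAI to 0) while leaving
fully observed families untouched, so small worked examples are exact.
References can be held at species/MAG level or aggregated to phylum by
summing member count tables; aggregation commutes with frequency building.

## Per-transcript traits

With $O_c$ the count of codon $c$ in a transcript and $L = \sum O_c$ the
counted codon length (stop codons and ambiguous codons are excluded from
both and tallied separately, never silently dropped):

* **CAI** $= \left(\prod_c w_c^{O_c}\right)^{1/L}$, the geometric mean of
  the reference weights. Single-codon families (Met, Trp) are included by
  default with weight 1 — they cannot lower the product but do enter $L$;
  a switch (`exclude_singletons`) applies the classical convention instead.
* **FOP** = (codons in the reference's per-family argmax set) / $L$. Tied
  maxima all count as optimal, so a uniform reference gives FOP = 1.
* **MILC** $= \sum_a M_a / L - C$ with
  $M_a = \sum_c O_c \ln(f_c / g_c)$, where $f_c$ is the observed
  within-family frequency in the transcript and $g_c$ the expected
  (reference) frequency, and $C = \sum_a (r_a - 1)/L - 0.5$. The correction
  sum runs over amino acids present in the transcript ($r_a$ = family
  size), following the index's original definition. A transcript whose
  family frequencies match $g$ exactly has $M_a \equiv 0$ and
  MILC $= -C$.
* **ENC′**, the background-corrected effective number of codons: per
  family, a chi-square deviation of observed from expected frequencies
  gives $F'_a = (\chi^2_a + n_a - r_a)/(r_a(n_a - 1))$; class averages over
  family sizes combine as
  $ENC' = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$ under the
  bacterial code. Families with fewer than 2 counted codons are excluded
  from their class average; an unobserved threefold class borrows
  $(\bar F_2 + \bar F_4)/2$; the value is clamped to $[1, 61]$ and is `NA`
  (undefined, never 0) when classes are missing. Usage exactly at
  background gives $\approx 61$; one codon per family against a uniform
  background gives 20.
* **Site-classified composition.** A codon position is *fourfold
  degenerate* when all three substitutions preserve the residue (the
  "synonymous site" pool), *strictly nonsynonymous* when all three change
  it, and *mixed* otherwise; mixed sites count toward whole-gene GC but
  toward neither pool. GC content is $(G+C)/(A+C+G+T)$ over the selected
  pool; GC skew $=(G-C)/(G+C)$ and AT skew $=(A-T)/(A+T)$ on the sense
  strand (T standing for U), lower values favoring the energetically
  cheaper nucleotide.
* **Amino acid economy.** Mean synthesis cost per residue (high-energy
  phosphate bonds, from the packaged cost table) and the molar C:N of the
  summed residue formulas. Both depend only on the translated residue
  sequence, so synonymous recoding leaves them unchanged. The cost and
  elemental-composition tables ship as editable TSVs
  (`inst/extdata/aa_cost.tsv`, `aa_composition.tsv`); no cost value is
  hard-coded.

The genetic code defaults to NCBI translation table 11 (bacterial), whose
sense/stop assignments match the standard table; other tables can be
selected by id or loaded from a plain-text file. RNA input (`U`) is
converted to DNA sense-strand `T` on read.

## Differential expression

The DE stage is a deliberately simple negative-binomial contrast, not a
reimplementation of any particular tool: median-of-ratios size factors
(normalized to geometric mean 1), per-feature method-of-moments dispersion
pooled across arms and moderated toward the across-feature mean (weight
`prior_df = 10` against the per-feature residual degrees of freedom — raw
per-feature estimates at 4 replicates are far too noisy), and a two-sided
Wald z-test on $\log_2(\bar\mu_T / \bar\mu_C)$. When either arm mean is
zero, 0.5 normalized counts are added to both means and the feature is
flagged. Benjamini–Hochberg adjustment with **FDR < 0.1** defines
significance. There is no LFC shrinkage and no outlier refitting; the
contract verified by the tests is calibration (null rejection rate at the
nominal level), unbiasedness on balanced synthetic truth, sign accuracy
for strong effects, and directional agreement with an established NB fit
(DESeq2) used purely as a cross-check. Counts can be contrasted per gene
(MAG-scale) or after summing genes per KO (community scale).

## Trait summaries and associations

Summaries are depth-weighted means: trait $\times$ weight over genes with a
defined trait value, renormalizing the weights when traits are undefined
(`NA` propagates as missing, never as 0). Two weightings are exposed
because "adjusted for read depth" is genuinely ambiguous: DNA coverage
(constant per gene — reference-pool view) and normalized transcript counts
per sample (transcript-pool view, the default for metatranscriptome-level
comparisons). Treatment effects on per-sample trait means use one-way
ANOVA with Tukey HSD pairwise comparisons (base R `aov`/`TukeyHSD`, i.e.
the studentized-range distribution). LFC-on-trait regression is ordinary
least squares with analytic standard errors; rank-deficient designs error
naming the collinear predictors.

The pathway-level relation mirrors the analysis where the signal actually
lives: per MAG, average a trait (FOP by default) and the per-gene LFC over
the MAG's genes in a pathway, one point per MAG, then regress. Fits are
refused below 3 points (points still returned). Exclusion lists are
explicit configuration — never automatic outlier deletion — and
leave-one-out slopes are always reported so a single dominant lineage is
visible. A per-taxon codon-frequency matrix over a pathway's genes can be
exported for ordination; the ordination itself is out of scope.

## The synthetic community generator

The generator emulates exactly the statistical structure the pipeline is
meant to detect: (a) taxa with distinct synonymous preference profiles
(symmetric Dirichlet per family, concentration $1/\text{bias\_strength}$;
0 gives uniform); (b) genes drawn codon-by-codon from the mixture
$t \cdot \text{preference} + (1-t) \cdot \text{uniform}$, where the
per-gene optimization $t \sim U(0,1)$ is recorded as ground truth;
(c) log-normal per-gene depths; (d) negative-binomial counts whose true
LFC is $\alpha + \beta\,t + \varepsilon$ for "growth"-class KOs and
$\alpha + \varepsilon$ for "stress"/"background" ($\varepsilon$ Gaussian,
sd 0.25; dispersion 0.1 with variance $\mu + \mu^2\,\text{disp}$). Defaults
are 30 taxa × 50 genes, bias strength 5, gene lengths uniform in
[100, 400] codons (above the 80-codon filter, so the filter is exercised
by explicit short-gene fixtures in tests rather than by accident), 2
treatments × 4 replicates, $\beta_{\text{growth}} = 2$,
$\beta_{\text{stress}} = 0$. A single master seed drives per-stage,
per-taxon substreams, so regeneration is deterministic and partial. Amino
acids are drawn uniformly over the 20 residues — a neutral choice that
keeps every family represented.

What the generator does *not* emulate: real amino acid usage, GC
heterogeneity along genes, assembly/binning artifacts, chimeric genes,
multi-factor or time-course designs, and genome-wide correlation between
GC content and optimization. Passing recovery tests therefore shows the
estimators are correct and the chain is wired correctly — not that every
biological signal in real soil data will be detectable.

Desk-scale note: at these community sizes per-taxon codon totals are
orders of magnitude below a real metagenome's, so the recovery analyses
build references with the taxon filter threshold set to 0; the 750,000
boundary itself is verified on constructed fixtures.

## Validation design

Every index is checked three ways: printed worked examples (the two-codon
glutamate family at frequencies 0.2/0.8 gives weights 0.25/1 and CAI 0.40
for `GAA GAA GAG`; the 100-codon 50/50 construction gives MILC 0.49),
hand-derivable limit cases (all-optimal transcripts, usage exactly at
background, skew extremes), and equivalence with independent brute-force
oracles on ≥100 random genes (tolerance 1e−12; 1e−9 for ENC′, which is
validated against a second, independently written implementation of the
published definition). Statistical stages are validated by Monte-Carlo
calibration (null NB simulation at 2,000 features: p < 0.05 fraction in
[0.03, 0.07]), exact agreement of BH with a brute-force step-up, OLS
against the normal equations (1e−10), and end-to-end parameter recovery on
the default synthetic scenario: positive, significant growth-pathway slope
of mean LFC on mean FOP; stress-pathway slope CI covering 0; and a higher
transcript-pool mean FOP in the coupled arm. Problem sizes (30 × 50 genes,
4 replicates/arm, 2,000 null features) were chosen once as the smallest
sizes at which these effects are unambiguous.

## Known limitations

* The DE stage is intentionally minimal; for publication-grade DE on real
  data use a dedicated tool and feed its LFCs into the association layer.
* ENC′ requires most degeneracy classes to be observed; very short or
  compositionally extreme genes return `NA`.
* The amino-acid cost table is organism-context dependent (aerobic
  heterotrophy assumed by the packaged defaults); swap in your own TSV for
  other contexts.
* Phylum-level references inherit whatever taxonomic annotation the input
  provides; mis-binned genes blur the reference toward the community mean.
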