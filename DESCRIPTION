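Package: codonTraits
Title: Codon Usage, Nucleotide and Amino Acid Traits of Metatranscriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes per-transcript gene traits for community
    metatranscriptomes: codon optimization indices (CAI, FOP, MILC and the
    background-corrected effective number of codons ENC') against
    taxon-specific genomic reference codon frequencies, nucleotide
    composition and GC/AT skew at fourfold-degenerate and nonsynonymous
    sites, and amino acid synthesis cost and C:N stoichiometry. Includes
    depth-weighted reference construction from metagenome gene sets, a
    simplified negative-binomial differential-expression stage, depth- or
    count-weighted trait summaries, trait-versus-expression regression at
    the pathway level, and a synthetic community generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
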