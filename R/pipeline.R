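#' Pipeline configuration
#'
#' Collects every path and parameter of an end-to-end run. Defaults match
#' the analysis conventions used throughout the package: 80-codon minimum
#' gene length, 750,000 minimum depth-adjusted codon total per taxon,
#' pseudocount 0.5, FDR threshold 0.1, transcript-count weighting for pool
#' summaries.
#'
#' @param out_dir output directory.
#' @param cds_fasta CDS FASTA path (alternatively `contigs_fasta` + `gff`).
#' @param contigs_fasta,gff contig FASTA and GFF3 feature paths for CDS
#'   extraction.
#' @param annotations,depths,counts,design input TSV paths.
#' @param simulate optional [communityConfig()]; when given, inputs are
#'   generated into `out_dir/sim` and the path arguments are ignored.
#' @param reference_rank `"species"` (taxon_id as-is, the MAG case) or
#'   `"phylum"` (aggregate via the annotation table's `phylum` column).
#' @param pseudocount reference pseudocount.
#' @param min_codons gene length filter (codons).
#' @param min_taxon_codons taxon total-codon filter.
#' @param fdr significance threshold.
#' @param weighting `"counts"` or `"depth"` for pool summaries.
#' @param de_level `"ko"` (community) or `"gene"` (MAG-level).
#' @param control,treatment treatment levels contrasted by the DE stage.
#' @param seed integer seed recorded in the manifest (and driving
#'   simulation when `simulate` is set).
#' @return validated config list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(out_dir,
                           cds_fasta = NULL, contigs_fasta = NULL,
                           gff = NULL, annotations = NULL, depths = NULL,
                           counts = NULL, design = NULL,
                           simulate = NULL,
                           reference_rank = c("species", "phylum"),
                           pseudocount = 0.5, min_codons = 80L,
                           min_taxon_codons = 750000, fdr = 0.1,
                           weighting = c("counts", "depth"),
                           de_level = c("ko", "gene"),
                           control = "control", treatment = "treatment",
                           seed = 1L) {
  cfg <- list(out_dir = out_dir, cds_fasta = cds_fasta,
              contigs_fasta = contigs_fasta, gff = gff,
              annotations = annotations, depths = depths,
              counts = counts, design = design, simulate = simulate,
              reference_rank = match.arg(reference_rank),
              pseudocount = pseudocount,
              min_codons = as.integer(min_codons),
              min_taxon_codons = min_taxon_codons, fdr = fdr,
              weighting = match.arg(weighting),
              de_level = match.arg(de_level),
              control = control, treatment = treatment,
              seed = as.integer(seed))
  if (is.null(cfg$simulate)) {
    if (is.null(cfg$cds_fasta) && (is.null(cfg$contigs_fasta) ||
                                   is.null(cfg$gff)))
      stop("config error: provide cds_fasta or contigs_fasta + gff, ",
           "or a simulate block")
    for (f in c("annotations", "depths", "counts", "design"))
      if (is.null(cfg[[f]]))
        stop("config error: missing input path: ", f)
  }
  if (cfg$pseudocount < 0) stop("config error: pseudocount must be >= 0")
  if (cfg$fdr <= 0 || cfg$fdr >= 1)
    stop("config error: fdr must be in (0, 1)")
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipelineConfig()]; a `simulate:` mapping is
#' passed to [communityConfig()].
#'
#' @param path YAML file path.
#' @return a `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulate))
    raw$simulate <- do.call(communityConfig, raw$simulate)
  do.call(pipelineConfig, raw)
}

stage_msg <- function(stage, ...) message("[", stage, "] ", ...)

#' Run the full analysis pipeline
#'
#' Stages: optional simulation; reference construction (depth-weighted
#' codon accumulation, taxon filter, frequency/weight build); per-gene
#' traits; differential expression; trait summaries; pathway-level
#' trait-expression associations. Every stage logs its record counts (genes
#' read, genes discarded at the length filter, taxa removed by the codon
#' total filter, ...) so the filters are auditable, and a manifest with
#' input hashes, seed and package version is written alongside the outputs.
#'
#' @param config a [pipelineConfig()] or path to its YAML file.
#' @return invisibly, a list of output file paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()

  if (!is.null(config$simulate)) {
    stage_msg("simulate", "generating synthetic community (seed ",
              config$simulate$seed, ")")
    sim <- simulateCommunity(config$simulate)
    sim_dir <- file.path(out_dir, "sim")
    writeCommunity(sim, sim_dir)
    config$cds_fasta <- file.path(sim_dir, "cds.fasta")
    config$annotations <- file.path(sim_dir, "annotations.tsv")
    config$depths <- file.path(sim_dir, "depths.tsv")
    config$counts <- file.path(sim_dir, "counts.tsv")
    config$design <- file.path(sim_dir, "design.tsv")
    outputs$sim <- sim_dir
  }

  for (f in c("annotations", "depths", "counts", "design"))
    if (!file.exists(config[[f]]))
      stop("input stage: missing ", f, " file: ", config[[f]])

  genes <- if (!is.null(config$cds_fasta)) readCds(config$cds_fasta)
           else extractCds(config$contigs_fasta, config$gff)
  ann <- readAnnotations(config$annotations)
  dep <- readDepths(config$depths)
  stage_msg("input", length(genes), " genes read; ",
            nrow(ann), " annotation rows; ", length(dep), " depths")
  idx <- match(names(genes), ann$gene_id)
  taxa <- ann$taxon_id[idx]
  if (config$reference_rank == "phylum") {
    if (is.null(ann$phylum))
      stop("reference stage: phylum rank requested but annotation table ",
           "has no phylum column")
    taxa <- ann$phylum[idx]
  }
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    taxon_id = taxa, ko_id = ann$ko_id[idx],
    pathway_tags = I(ann$pathway_tags[idx]),
    depth = unname(dep[names(genes)]))

  cct <- accumulateCounts(genes, depth_weighted = TRUE)
  kept <- filterTaxa(cct, config$min_taxon_codons)
  stage_msg("reference", nrow(codonCounts(cct)), " taxa accumulated; ",
            nrow(codonCounts(cct)) - nrow(codonCounts(kept)),
            " removed below ", config$min_taxon_codons, " codons")
  ref <- buildReference(kept, config$pseudocount)
  outputs$reference <- file.path(out_dir, "reference.tsv")
  writeReferenceTsv(ref, outputs$reference, counts = kept)

  traits <- computeGeneTraits(genes, ref, min_codons = config$min_codons)
  stage_msg("traits", nrow(traits), " genes profiled; ",
            attr(traits, "n_discarded"), " discarded below ",
            config$min_codons, " codons")
  outputs$traits <- file.path(out_dir, "traits.tsv")
  write_tsv(traits, outputs$traits)

  se <- readCounts(config$counts, config$design)
  ko <- ann$ko_id[match(rownames(se), ann$gene_id)]
  de_se <- if (config$de_level == "ko") aggregateByKO(se, ko) else se
  de <- estimateDE(de_se, config$control, config$treatment,
                   fdr = config$fdr)
  stage_msg("de", nrow(de), " features tested at level ", config$de_level,
            "; ", sum(de$significant), " significant at FDR < ", config$fdr)
  outputs$de <- file.path(out_dir, "de.tsv")
  write_tsv(de, outputs$de)

  summ <- weightedSummary(traits, by = "ko_id")
  outputs$summary_ko <- file.path(out_dir, "summary_ko.tsv")
  write_tsv(summ, outputs$summary_ko)
  pool <- transcriptPoolMeans(traits, se, weighting = config$weighting)
  outputs$pool_means <- file.path(out_dir, "pool_means.tsv")
  write_tsv(pool, outputs$pool_means)

  de_gene <- if (config$de_level == "gene") de
             else estimateDE(se, config$control, config$treatment,
                             fdr = config$fdr)
  tags <- unique(unlist(traits$pathway_tags))
  if (is.character(traits$pathway_tags))
    tags <- unique(unlist(strsplit(traits$pathway_tags, ";", fixed = TRUE)))
  tags <- tags[!is.na(tags) & nzchar(tags)]
  assoc <- NULL
  for (tg in tags) {
    rel <- pathwayLevelRelation(traits, de_gene, tg)
    if (is.null(rel$fit)) {
      stage_msg("associate", "pathway ", tg, ": ", rel$refused)
      next
    }
    co <- rel$fit$coefficients
    assoc <- rbind(assoc, data.frame(
      pathway = tg, trait = rel$trait,
      slope = co$estimate[2], se = co$se[2], p_value = co$p_value[2],
      r_squared = rel$fit$r_squared, n_points = rel$fit$n_points,
      max_influence = rel$max_influence, stringsAsFactors = FALSE))
  }
  if (!is.null(assoc)) {
    outputs$associations <- file.path(out_dir, "associations.tsv")
    write_tsv(assoc, outputs$associations)
    stage_msg("associate", nrow(assoc), " pathway fits written")
  }

  resolved <- config
  resolved$simulate <- if (is.null(config$simulate)) NULL
                       else unclass(config$simulate)
  yaml::write_yaml(lapply(unclass(resolved), function(x)
    if (is.null(x)) NA else x), file.path(out_dir, "config_resolved.yaml"))
  inputs <- unlist(config[c("cds_fasta", "contigs_fasta", "gff",
                            "annotations", "depths", "counts", "design")])
  inputs <- inputs[!is.na(inputs) & file.exists(inputs)]
  manifest <- list(package = "codonTraits",
                   version = as.character(packageVersion("codonTraits")),
                   seed = config$seed,
                   input_md5 = as.list(tools::md5sum(inputs)),
                   outputs = lapply(outputs, as.character),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  outputs$manifest <- file.path(out_dir, "manifest.json")
  invisible(outputs)
}
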