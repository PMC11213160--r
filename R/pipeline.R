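# End-to-end orchestration: integrate -> genotype-qc -> annotate ->
# match-catalog -> classify -> report, with a structured config carrying
# every tunable at its reference default.

#' Pipeline configuration
#'
#' All tunables with their reference defaults: 200 bp concordance and
#' catalog windows, PASS_ratio >= 0.5, GQ >= 20 for breakend-derived
#' genotypes, per-group missingness <= 0.2, MAF tiers at 1% / 5%, 1 kb
#' promoters, 1 Mb breakpoint-only span, score thresholds
#' (StrVCTVRE 0.37, CADD-SV 10, POSTRE 0.8, PhenoSV 0.5), 2-of-4 score
#' consensus, 2-of-3 gene-set support, catalog AF cutoff 0.01, and the
#' ISUP grade-group aggressiveness cut of 3.
#'
#' @param ... overrides of the defaults
#' @return a named list of class `pipeline_config`
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    concordance_window = 200,
    min_pass_ratio = 0.5,
    min_gq = 20,
    max_missing = 0.2,
    maf_rare = 0.01,
    maf_common = 0.05,
    promoter_size = 1000,
    max_span = 1e6,
    score_thresholds = as.list(DEFAULT_SCORE_THRESHOLDS),
    consensus_k = 2,
    geneset_k = 2,
    catalog_window = 200,
    catalog_max_af = 0.01,
    gg_cut = 3)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    abort("unknown config field(s): %s", paste(unknown, collapse = ","))
  cfg[names(over)] <- over
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read / write a pipeline config (JSON)
#'
#' Configs round-trip through serialization.
#'
#' @param path JSON file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the discovery pipeline on a bundle directory
#'
#' Stages, in fixed order: (1) integrate — per-sample Manta/GRIDSS
#' concordance, keeping the Manta representation; (2) genotype-qc — restrict
#' the genotyped multi-sample set to concordance survivors, then site
#' filters, call masking, per-group missingness, fixed-site removal and
#' allele frequencies; (3) annotate — gene-impact categories against the
#' canonical transcript models; (4) match-catalog; (5) classify — the
#' consensus pathogenicity cascade; (6) report. Intermediate artifacts are
#' written under `out_dir`; the returned funnel records per-stage counts.
#'
#' @param config a [pipeline_config()]
#' @param input_dir bundle directory (layout of [write_sv_bundle()])
#' @param out_dir output directory
#' @param stages run only the first stages of
#'   `c("integrate","genotype-qc","annotate","match-catalog","classify",
#'   "report")` (default: all)
#' @param verbose log per-stage counts (default FALSE)
#' @return list with `funnel`, `concordance`, `gmatrix`, `freqs`, `impacts`,
#'   `catalog_anns`, `calls`, `report`
#' @export
run_pipeline <- function(config, input_dir, out_dir,
                         stages = c("integrate", "genotype-qc", "annotate",
                                    "match-catalog", "classify", "report"),
                         verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  funnel <- list()
  clinical <- read_clinical_table(file.path(input_dir, "clinical.tsv"))
  res <- list(funnel = funnel)

  # --- integrate ------------------------------------------------------
  prov <- list(); kept_ids <- character()
  for (s in clinical$patient_id) {
    mp <- file.path(input_dir, "calls", paste0(s, ".manta.vcf"))
    gp <- file.path(input_dir, "calls", paste0(s, ".gridss.vcf"))
    if (!file.exists(mp) || !file.exists(gp))
      abort("stage integrate: missing caller VCFs for sample %s", s)
    manta <- read_sv_vcf(mp, "manta")
    gridss <- suppressWarnings(read_sv_vcf(gp, "gridss"))
    m <- match_callsets(manta, gridss, config$concordance_window)
    if (nrow(m) > 0) {
      prov[[s]] <- cbind(sample = s,
                         m[, c("manta_id", "gridss_id", "svtype",
                               "bp1_dist", "bp2_dist", "manta_pass",
                               "gridss_pass")])
      kept_ids <- union(kept_ids, m$manta_id)
    }
  }
  prov <- if (length(prov)) do.call(rbind, c(prov, list(
    make.row.names = FALSE))) else data.frame()
  write_tsv_file(prov, file.path(out_dir, "concordance.tsv"))
  res$concordance <- prov
  funnel$concordant_sites <- length(kept_ids)
  pipeline_log(verbose, "integrate: %d concordant site ids", length(kept_ids))
  if (!"genotype-qc" %in% stages) {
    res$funnel <- funnel
    return(invisible(res))
  }

  # --- genotype-qc ----------------------------------------------------
  gmatrix <- read_sv_vcf(file.path(input_dir, "genotypes.vcf"), "genotyped")
  gmatrix <- set_sample_groups(
    gmatrix, stats::setNames(clinical$group, clinical$patient_id))
  funnel$genotyped_sites <- nrow(gmatrix$sites)
  gmatrix <- subset_sites(gmatrix, gmatrix$sites$id %in% kept_ids)
  funnel$after_concordance <- nrow(gmatrix$sites)
  gmatrix <- apply_site_filters(gmatrix, config$min_pass_ratio)
  funnel$after_site_filters <- nrow(gmatrix$sites)
  gmatrix <- mask_low_quality_genotypes(gmatrix, config$min_gq)
  gmatrix <- filter_missingness(gmatrix, config$max_missing)
  funnel$after_missingness <- nrow(gmatrix$sites)
  gmatrix <- drop_fixed_sites(gmatrix)
  funnel$after_fixed_removal <- nrow(gmatrix$sites)
  freqs <- compute_frequencies(gmatrix)
  write_tsv_file(freqs, file.path(out_dir, "frequencies.tsv"))
  res$gmatrix <- gmatrix; res$freqs <- freqs
  pipeline_log(verbose, "genotype-qc: %d sites survive QC",
               nrow(gmatrix$sites))
  if (!"annotate" %in% stages) { res$funnel <- funnel; return(invisible(res)) }

  # --- annotate -------------------------------------------------------
  models <- read_gene_models(file.path(input_dir, "annotation.gtf"))
  enh_path <- file.path(input_dir, "enhancers.bed")
  enhancers <- if (file.exists(enh_path)) read_enhancer_bed(enh_path)
               else NULL
  impacts <- annotate_impacts(gmatrix$sites, models, enhancers,
                              config$max_span, config$promoter_size)
  write_tsv_file(impacts, file.path(out_dir, "impacts.tsv"))
  res$impacts <- impacts
  funnel$gene_disruptive <- length(unique(
    impacts$sv_id[impacts$category %in% GENE_DISRUPTIVE]))
  pipeline_log(verbose, "annotate: %d gene-disruptive SVs",
               funnel$gene_disruptive)
  if (!"match-catalog" %in% stages) {
    res$funnel <- funnel
    return(invisible(res))
  }

  # --- match-catalog --------------------------------------------------
  catalog <- read_sv_catalog(file.path(input_dir, "catalog.tsv"))
  catalog_anns <- annotate_catalog(gmatrix$sites, catalog,
                                   config$catalog_window,
                                   config$catalog_max_af)
  write_tsv_file(catalog_anns, file.path(out_dir, "catalog_matches.tsv"))
  res$catalog_anns <- catalog_anns
  funnel$in_catalog <- sum(!catalog_anns$novel)
  funnel$novel <- sum(catalog_anns$novel)
  if (!"classify" %in% stages) { res$funnel <- funnel; return(invisible(res)) }

  # --- classify -------------------------------------------------------
  panels <- read_score_panel(file.path(input_dir, "scores.tsv"))
  gs_dir <- file.path(input_dir, "genesets")
  gs_files <- list.files(gs_dir, full.names = TRUE)
  genesets <- read_gene_sets(stats::setNames(
    gs_files, sub("\\.[^.]*$", "", basename(gs_files))))
  curation <- read_gene_curation(file.path(input_dir, "curation.tsv"))
  calls <- classify_cohort(
    gmatrix$sites$id, impacts, freqs, catalog_anns, panels, genesets,
    curation,
    thresholds = unlist(config$score_thresholds),
    consensus_k = config$consensus_k, geneset_k = config$geneset_k,
    maf_common = config$maf_common, maf_rare = config$maf_rare,
    catalog_max_af = config$catalog_max_af)
  write_tsv_file(calls, file.path(out_dir, "pathogenicity_calls.tsv"))
  res$calls <- calls
  tier_tab <- table(calls$tier)
  funnel$tiers <- as.list(tier_tab)
  pipeline_log(verbose, "classify: %s",
               paste(names(tier_tab), tier_tab, sep = "=", collapse = " "))
  if (!"report" %in% stages) { res$funnel <- funnel; return(invisible(res)) }

  # --- report ---------------------------------------------------------
  res$report <- render_tables(calls, impacts, freqs, catalog_anns, gmatrix,
                              clinical, out_dir)
  res$funnel <- funnel
  jsonlite::write_json(funnel, file.path(out_dir, "funnel.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
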