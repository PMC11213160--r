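# Synthetic cohort generator. Produces an internally consistent bundle —
# annotation, per-sample dual-caller VCFs, a genotyped multi-sample VCF,
# score tables, an SV catalog, cancer gene sets, a curation table and a
# clinical table — from a roster of planted SVs whose impact category,
# frequencies, scores and expected pathogenicity tier are known, so every
# pipeline stage can be checked against planted truth without controlled-
# access data.

# run expr with a private RNG state, fully determined by seed
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulation plan
#'
#' Defaults mirror the cohort the workflow was designed around: 113 African
#' and 57 European patients, and a planted-SV roster covering every impact
#' category and every pathogenicity tier. Noise dials default to zero (the
#' noiseless bundle is the reference condition); [perturb()] and non-default
#' dial values degrade it in controlled ways.
#'
#' @param seed integer; fully determines all outputs
#' @param n_african,n_european sample counts per ancestry group
#' @param n_chroms,chrom_length,n_genes annotation size
#' @param shared_caller_fraction probability a planted SV appears in both
#'   callsets (default 1)
#' @param breakpoint_jitter_sd sd in bases of the second caller's breakpoint
#'   jitter, clipped at 2 sd (default 0)
#' @param genotype_error_rate,missingness_rate per-call noise probabilities
#'   (default 0)
#' @param specs planted-SV roster (default [default_planted_specs()])
#' @return object of class `simulation_plan`
#' @export
simulation_plan <- function(seed = 1, n_african = 113, n_european = 57,
                            n_chroms = 4, chrom_length = 3e6, n_genes = 44,
                            shared_caller_fraction = 1,
                            breakpoint_jitter_sd = 0,
                            genotype_error_rate = 0, missingness_rate = 0,
                            specs = default_planted_specs()) {
  probs <- c(shared_caller_fraction, genotype_error_rate, missingness_rate)
  if (any(probs < 0 | probs > 1)) abort("plan probabilities must be in [0,1]")
  structure(list(seed = as.integer(seed), n_african = n_african,
                 n_european = n_european, n_chroms = n_chroms,
                 chrom_length = chrom_length, n_genes = n_genes,
                 shared_caller_fraction = shared_caller_fraction,
                 breakpoint_jitter_sd = breakpoint_jitter_sd,
                 genotype_error_rate = genotype_error_rate,
                 missingness_rate = missingness_rate, specs = specs),
            class = "simulation_plan")
}

#' Default planted-SV roster
#'
#' One row per planted SV: target impact category, curated gene role(s),
#' score pass/fail template, frequency class, ClinVar label, catalog status
#' and the pathogenicity tier the full cascade is expected to assign. The
#' roster covers all eleven impact categories and all eleven tiers.
#'
#' @return data.frame roster
#' @export
default_planted_specs <- function() {
  s <- function(name, svtype, impact, role, role2, template, freq, clinvar,
                in_catalog, catalog_af, n_genesets, expected_tier)
    data.frame(name = name, svtype = svtype, impact = impact, role = role,
               role2 = role2, template = template, freq = freq,
               clinvar = clinvar, in_catalog = in_catalog,
               catalog_af = catalog_af, n_genesets = n_genesets,
               expected_tier = expected_tier, stringsAsFactors = FALSE)
  rbind(
    # ClinVar-verified tiers (scores and gene sets are short-circuited)
    s("clv_path_del", "DEL", "pLoF_DEL", "tumour_suppressor", NA, "2of4",
      "rare_afr1", "pathogenic", TRUE, 1.3e-4, 2, "clinvar_pathogenic"),
    s("clv_lp_del", "DEL", "pLoF_DEL", "tumour_suppressor", NA, "2of4",
      "rare_afr1", "likely_pathogenic", TRUE, 1.5e-3, 2,
      "clinvar_likely_pathogenic"),
    s("clv_lp_ied", "DUP", "IED", "oncogene", NA, "2of4", "rare_afr2",
      "likely_pathogenic", TRUE, 7.5e-3, 2, "clinvar_likely_pathogenic"),
    s("clv_benign_del", "DEL", "pLoF_DEL", "tumour_suppressor", NA, "1of4",
      "rare_afr1", "benign", TRUE, 1e-4, 2, "excluded_benign"),
    s("clv_uncertain_del", "DEL", "pLoF_DEL", "tumour_suppressor", NA,
      "2of4", "rare_afr1", "uncertain", TRUE, 1e-4, 2, "pp_sv"),
    # predicted PP-SVs
    s("pp_del_afr", "DEL", "pLoF_DEL", "tumour_suppressor", NA, "2of4",
      "rare_afr2", "none", TRUE, 1e-4, 2, "pp_sv"),
    s("pp_del_eur", "DEL", "pLoF_DEL", "tumour_suppressor", NA, "2of4",
      "rare_eur1", "none", FALSE, NA, 2, "pp_sv"),
    s("pp_del_4of4", "DEL", "pLoF_DEL", "tumour_suppressor", NA, "4of4",
      "rare_afr1", "none", FALSE, NA, 3, "pp_sv"),
    s("pp_dup_exonic", "DUP", "pLoF_DUP", "tumour_suppressor", NA, "2of4",
      "rare_afr1", "none", FALSE, NA, 2, "pp_sv"),
    s("pp_cg_onco", "DUP", "CG", "oncogene", NA, "2of4", "rare_afr1",
      "none", TRUE, 1.3e-4, 2, "pp_sv"),
    s("pp_ied_onco", "DUP", "IED", "oncogene", NA, "2of4", "rare_eur1",
      "none", TRUE, 7.3e-4, 2, "pp_sv"),
    s("pp_inv_ts", "INV", "pLoF_INV", "tumour_suppressor", NA, "2of4",
      "rare_afr1", "none", TRUE, 9.6e-5, 2, "pp_sv"),
    s("pp_tra_single", "TRA", "pLoF_TRA", "tumour_suppressor", NA, "2of4",
      "rare_eur1", "none", FALSE, NA, 2, "pp_sv"),
    s("pp_tra_fusion_ts", "TRA", "pLoF_TRA_fusion", "tumour_suppressor",
      "tumour_suppressor", "2of4", "rare_eur1", "none", FALSE, NA, 2,
      "pp_sv"),
    s("pp_ins_cds", "INS", "pLoF_INS", "tumour_suppressor", NA, "2of4",
      "rare_afr1", "none", FALSE, NA, 2, "pp_sv"),
    # unlikely: mechanism inconsistent with curated role
    s("unl_del_onco", "DEL", "pLoF_DEL", "oncogene", NA, "2of4",
      "rare_afr1", "none", FALSE, NA, 2, "unlikely"),
    s("unl_inv_onco", "INV", "pLoF_INV", "oncogene", NA, "2of4",
      "rare_afr1", "none", TRUE, 1e-4, 2, "unlikely"),
    s("unl_cg_ts", "DUP", "CG", "tumour_suppressor", NA, "2of4",
      "rare_afr1", "none", FALSE, NA, 2, "unlikely"),
    s("unl_tra_onco", "TRA", "pLoF_TRA", "oncogene", NA, "2of4",
      "rare_afr1", "none", FALSE, NA, 2, "unlikely"),
    # cautionary: mixed or unclear roles
    s("cau_fusion_ts_onco", "TRA", "pLoF_TRA_fusion", "tumour_suppressor",
      "oncogene", "2of4", "rare_afr1", "none", FALSE, NA, 2,
      "cautionary_pp_sv"),
    s("cau_fusion_ts_uncl", "TRA", "pLoF_TRA_fusion", "tumour_suppressor",
      "unclear", "2of4", "rare_afr2", "none", FALSE, NA, 2,
      "cautionary_pp_sv"),
    s("cau_tra_unclear", "TRA", "pLoF_TRA", "unclear", NA, "2of4",
      "rare_afr1", "none", FALSE, NA, 2, "cautionary_pp_sv"),
    # frequency and catalog exclusions
    s("exc_common_del", "DEL", "pLoF_DEL", "tumour_suppressor", NA, "2of4",
      "common", "none", FALSE, NA, 2, "excluded_common"),
    s("exc_lowfreq_del", "DEL", "pLoF_DEL", "tumour_suppressor", NA, "2of4",
      "low_afr", "none", FALSE, NA, 2, "excluded_common"),
    s("exc_catalog_af", "DEL", "pLoF_DEL", "tumour_suppressor", NA, "2of4",
      "rare_afr1", "none", TRUE, 0.03, 2, "excluded_catalog_af"),
    # consensus / gene-set failures
    s("exc_1of4", "DEL", "pLoF_DEL", "tumour_suppressor", NA, "1of4",
      "rare_afr1", "none", FALSE, NA, 2, "excluded_no_consensus"),
    s("exc_0of4", "DEL", "pLoF_DEL", "tumour_suppressor", NA, "0of4",
      "rare_afr1", "none", FALSE, NA, 2, "excluded_no_consensus"),
    s("exc_1geneset", "DEL", "pLoF_DEL", "tumour_suppressor", NA, "2of4",
      "rare_afr1", "none", FALSE, NA, 1, "excluded_no_cancer_support"),
    # non-disruptive impact categories
    s("nd_partial_gene_dup", "DUP", "partial_gene_DUP", "none", NA, "2of4",
      "rare_afr1", "none", FALSE, NA, 0, "not_gene_disruptive"),
    s("nd_partial_exon_dup", "DUP", "partial_exon_DUP", "none", NA, "2of4",
      "rare_afr1", "none", FALSE, NA, 0, "not_gene_disruptive"),
    s("nd_whole_gene_inv", "INV", "whole_gene_INV", "none", NA, "2of4",
      "rare_afr1", "none", FALSE, NA, 0, "not_gene_disruptive"),
    s("nd_utr_del", "DEL", "UTR", "none", NA, "0of4", "rare_afr1", "none",
      FALSE, NA, 0, "not_gene_disruptive"),
    s("nd_promoter_del", "DEL", "promoter", "none", NA, "0of4", "rare_afr1",
      "none", FALSE, NA, 0, "not_gene_disruptive"),
    s("nd_intronic_del", "DEL", "intronic", "none", NA, "0of4", "rare_afr2",
      "none", FALSE, NA, 0, "not_gene_disruptive"),
    s("nd_enhancer_del", "DEL", "enhancer", "none", NA, "0of4", "rare_afr1",
      "none", FALSE, NA, 0, "not_gene_disruptive"),
    s("nd_intergenic_del", "DEL", "intergenic", "none", NA, "0of4",
      "rare_eur1", "none", FALSE, NA, 0, "not_gene_disruptive")
  )
}

# genes consumed by a spec: 2 for fusions, 0 for intergenic, else 1
genes_needed <- function(specs) {
  ifelse(specs$impact == "pLoF_TRA_fusion", 2L,
         ifelse(specs$impact == "intergenic", 0L, 1L))
}

#' Simulate a gene annotation
#'
#' Non-overlapping genes laid out on a fixed grid (one 60 kb slot per gene,
#' genes interleaved across chromosomes so consecutive genes sit on
#' different chromosomes), alternating strands. Planted-target genes have a
#' fixed 5-exon structure (150 bp exons, 1 kb introns; exons 2-4 coding,
#' exons 1 and 5 UTR); filler genes get 3-12 exons. One intergenic enhancer
#' per gene, 10 kb upstream of the gene start, targets that gene.
#'
#' @param plan a [simulation_plan]
#' @return list with `models` ([transcript_models]) and `enhancers`
#' @export
simulate_annotation <- function(plan) {
  with_seed(derive_seed(plan$seed, "annotation"), {
    n <- plan$n_genes
    slot <- 60000
    per_chrom <- ceiling(n / plan$n_chroms)
    if (per_chrom * slot > plan$chrom_length - 1e5)
      abort("infeasible packing: %d genes on %d chroms of %g bp",
            n, plan$n_chroms, plan$chrom_length)
    genes <- list(); exons <- list(); cds <- list(); enh <- list()
    n_spec <- sum(genes_needed(plan$specs))
    for (k in seq_len(n)) {
      chrom <- paste0("chr", (k - 1) %% plan$n_chroms + 1)
      slot_i <- (k - 1) %/% plan$n_chroms
      start <- slot_i * slot + 25000
      gid <- sprintf("G%03d", k)
      gname <- sprintf("GENE%03d", k)
      if (k <= n_spec) {
        n_ex <- 5L; ex_w <- 150L; intron <- 1000L
      } else {
        n_ex <- sample(3:12, 1); ex_w <- sample(120:200, 1)
        intron <- sample(500:1500, 1)
      }
      ex_start <- start + (seq_len(n_ex) - 1L) * (ex_w + intron)
      ex_end <- ex_start + ex_w - 1L
      end <- ex_end[n_ex]
      strand <- if (k %% 2 == 1) "+" else "-"
      genes[[k]] <- data.frame(gene_id = gid, gene_name = gname,
                               chrom = chrom, strand = strand,
                               start = start, end = end,
                               stringsAsFactors = FALSE)
      exons[[k]] <- data.frame(gene_id = gid, start = ex_start, end = ex_end,
                               stringsAsFactors = FALSE)
      coding <- if (n_ex >= 3) 2:(n_ex - 1) else seq_len(n_ex)
      cds[[k]] <- data.frame(gene_id = gid, start = ex_start[coding],
                             end = ex_end[coding], stringsAsFactors = FALSE)
      enh[[k]] <- data.frame(chrom = chrom, start = start - 10000L,
                             end = start - 9501L, gene_id = gid,
                             stringsAsFactors = FALSE)
    }
    if (n == 0)
      return(list(models = transcript_models(
        data.frame(gene_id = character(), gene_name = character(),
                   chrom = character(), strand = character(),
                   start = integer(), end = integer()),
        data.frame(gene_id = character(), start = integer(),
                   end = integer()),
        data.frame(gene_id = character(), start = integer(),
                   end = integer())),
        enhancers = data.frame(chrom = character(), start = integer(),
                               end = integer(), gene_id = character())))
    list(models = transcript_models(do.call(rbind, genes),
                                    do.call(rbind, exons),
                                    do.call(rbind, cds)),
         enhancers = do.call(rbind, enh))
  })
}

#' Write transcript models as GTF
#'
#' Emits gene, transcript (tagged `Ensembl_canonical`), exon and CDS
#' features readable by [read_gene_models()].
#'
#' @param models a [transcript_models] object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_annotation_gtf <- function(models, path) {
  lines <- character()
  gtf_line <- function(chrom, feature, start, end, strand, attrs) {
    sprintf("%s\tsvpath\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, feature,
            start, end, strand, attrs)
  }
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i, ]
    tid <- paste0(g$gene_id, "_t1")
    base <- sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$gene_name)
    txa <- sprintf('%s transcript_id "%s"; tag "Ensembl_canonical";',
                   base, tid)
    lines <- c(lines,
               gtf_line(g$chrom, "gene", g$start, g$end, g$strand, base),
               gtf_line(g$chrom, "transcript", g$start, g$end, g$strand, txa))
    ex <- models$exons[models$exons$gene_id == g$gene_id, ]
    cd <- models$cds[models$cds$gene_id == g$gene_id, ]
    for (j in seq_len(nrow(ex)))
      lines <- c(lines, gtf_line(g$chrom, "exon", ex$start[j], ex$end[j],
                                 g$strand, txa))
    for (j in seq_len(nrow(cd)))
      lines <- c(lines, gtf_line(g$chrom, "CDS", cd$start[j], cd$end[j],
                                 g$strand, txa))
  }
  writeLines(lines, path)
  invisible(path)
}

# breakpoint recipe for one spec against its assigned gene(s); returns a
# one-row data.frame of sv_set columns
place_spec_sv <- function(spec, g1, ex1, g2, plan, idx) {
  E <- function(i) c(ex1$start[i], ex1$end[i])
  id <- spec$name
  mk <- function(chrom1, pos1, chrom2 = chrom1, pos2 = pos1,
                 insertion_seq = NA_character_) {
    or <- orient_for_type(spec$svtype)
    data.frame(id = id, chrom1 = chrom1, pos1 = as.integer(pos1),
               orient1 = or[1], chrom2 = chrom2, pos2 = as.integer(pos2),
               orient2 = or[2], svtype = spec$svtype, caller = "truth",
               filter_pass = TRUE, mate_id = NA_character_,
               insertion_seq = insertion_seq, stringsAsFactors = FALSE)
  }
  switch(spec$impact,
    pLoF_DEL = mk(g1$chrom, E(3)[1] - 200L, , E(3)[2] + 200L),
    UTR = mk(g1$chrom, E(1)[1] + 20L, , E(1)[1] + 80L),
    intronic = mk(g1$chrom, E(2)[2] + 100L, , E(2)[2] + 400L),
    promoter = if (g1$strand == "+")
      mk(g1$chrom, g1$start - 600L, , g1$start - 501L)
      else mk(g1$chrom, g1$end + 501L, , g1$end + 600L),
    enhancer = mk(g1$chrom, g1$start - 9900L, , g1$start - 9800L),
    intergenic = mk("chr1", plan$chrom_length - 50000L + idx * 500L, ,
                    plan$chrom_length - 50000L + idx * 500L + 300L),
    pLoF_DUP = mk(g1$chrom, E(2)[1] + 50L, , E(3)[1] + 50L),
    IED = mk(g1$chrom, E(2)[2] + 300L, , E(3)[2] + 300L),
    partial_exon_DUP = mk(g1$chrom, E(2)[2] + 100L, , E(3)[1] + 50L),
    partial_gene_DUP = mk(g1$chrom, g1$start - 3000L, , E(2)[2] + 150L),
    CG = mk(g1$chrom, g1$start - 2500L, , g1$end + 2500L),
    whole_gene_INV = mk(g1$chrom, g1$start - 2500L, , g1$end + 2500L),
    pLoF_INV = mk(g1$chrom, E(2)[2] + 200L, , g1$end + 5000L),
    pLoF_TRA = mk(g1$chrom, E(2)[2] + 250L,
                  setdiff(paste0("chr", seq_len(plan$n_chroms)),
                          g1$chrom)[1],
                  plan$chrom_length - 100000L + idx * 700L),
    pLoF_TRA_fusion = mk(g1$chrom, E(2)[2] + 250L, g2$chrom,
                         g2$start + 2000L),
    pLoF_INS = mk(g1$chrom, E(3)[1] + 60L, , E(3)[1] + 60L,
                  insertion_seq = paste(sample(c("A", "C", "G", "T"), 80,
                                               TRUE), collapse = "")),
    abort("no placement recipe for impact %s", spec$impact)
  )
}

# heterozygous-carrier counts per frequency class, scaled to (and capped
# at) the group sizes; at the default 113 + 57 cohort this gives 1/2/1
# rare carriers, 5 low-frequency and 31 + 15 common carriers
carrier_plan <- function(freq, n_afr, n_eur) {
  cap <- function(x, n) min(max(x, if (n > 0) 1 else 0), n)
  switch(freq,
         rare_afr1 = list(afr = cap(1, n_afr), eur = 0),
         rare_afr2 = list(afr = cap(2, n_afr), eur = 0),
         rare_eur1 = list(afr = 0, eur = cap(1, n_eur)),
         low_afr = list(afr = cap(round(0.044 * n_afr), n_afr), eur = 0),
         common = list(afr = cap(round(0.27 * n_afr), n_afr),
                       eur = cap(round(0.26 * n_eur), n_eur)),
         abort("unknown frequency class %s", freq))
}

# score templates: pass the first k covered tools (tool order strvctvre,
# cadd_sv, postre, phenosv), fail the remaining covered tools, NA elsewhere
PASS_SCORES <- c(strvctvre = 0.6, cadd_sv = 15, postre = 0.9, phenosv = 0.7)
FAIL_SCORES <- c(strvctvre = 0.1, cadd_sv = 5, postre = 0.3, phenosv = 0.2)

tool_coverage <- function(svtype, impact) {
  exonic <- impact %in% c("pLoF_DEL", "pLoF_DUP", "CG", "IED",
                          "partial_exon_DUP", "UTR")
  c(strvctvre = svtype %in% c("DEL", "DUP") && exonic,
    cadd_sv = svtype %in% c("DEL", "DUP", "INS"),
    postre = svtype %in% c("DEL", "DUP", "INV", "TRA"),
    phenosv = TRUE)
}

score_panel_row <- function(spec) {
  cov <- tool_coverage(spec$svtype, spec$impact)
  k <- switch(spec$template, "0of4" = 0L, "1of4" = 1L, "2of4" = 2L,
              "4of4" = 4L, abort("unknown template %s", spec$template))
  covered <- names(cov)[cov]
  pass <- covered[seq_len(min(k, length(covered)))]
  row <- as.list(rep(NA_real_, 4))
  names(row) <- names(cov)
  for (tool in covered)
    row[[tool]] <- if (tool %in% pass) PASS_SCORES[[tool]]
                   else FAIL_SCORES[[tool]]
  as.data.frame(c(list(sv_id = spec$name), row), stringsAsFactors = FALSE)
}

#' Simulate a full cohort bundle
#'
#' @param plan a [simulation_plan]
#' @param annotation optional precomputed [simulate_annotation()] result
#' @return an `sv_bundle`: list with `plan`, `models`, `enhancers`, `svs`
#'   (planted [sv_set]), `manta`/`gridss` (named lists of per-sample
#'   [sv_set]s), `gmatrix` (`sv_genotype_matrix`), `scores`, `catalog`,
#'   `genesets`, `curation`, `clinical`, `truth`
#' @export
simulate_cohort <- function(plan, annotation = simulate_annotation(plan)) {
  with_seed(derive_seed(plan$seed, "cohort"), {
    specs <- plan$specs
    models <- annotation$models
    enhancers <- annotation$enhancers
    need <- genes_needed(specs)
    if (sum(need) > nrow(models$genes))
      abort("roster needs %d genes but annotation has %d", sum(need),
            nrow(models$genes))
    gene_cursor <- cumsum(need)
    afr_ids <- sprintf("AFR%03d", seq_len(plan$n_african))
    eur_ids <- sprintf("EUR%03d", seq_len(plan$n_european))
    samples <- c(afr_ids, eur_ids)

    svs <- list(); truth <- list(); scores <- list(); catalog <- list()
    curation <- list(); geneset_members <- list(hallmark = character(),
                                                oncogenic = character(),
                                                cosmic_cgc = character())
    carriers_by_sv <- list()
    for (i in seq_len(nrow(specs))) {
      spec <- specs[i, ]
      gidx <- if (need[i] > 0) gene_cursor[i] - need[i] + 1 else NA
      g1 <- if (!is.na(gidx)) models$genes[gidx, ] else NULL
      ex1 <- if (!is.na(gidx))
        models$exons[models$exons$gene_id == g1$gene_id, ] else NULL
      g2 <- if (need[i] == 2) models$genes[gidx + 1, ] else NULL
      sv <- place_spec_sv(spec, g1, ex1, g2, plan, i)
      svs[[i]] <- sv

      cp <- carrier_plan(spec$freq, plan$n_african, plan$n_european)
      carr <- c(if (cp$afr > 0) sample(afr_ids, cp$afr),
                if (cp$eur > 0) sample(eur_ids, cp$eur))
      carriers_by_sv[[spec$name]] <- carr
      af_afr <- cp$afr / (2 * plan$n_african)
      af_eur <- cp$eur / (2 * plan$n_european)

      scores[[i]] <- score_panel_row(spec)

      genes_hit <- c(if (!is.null(g1) && spec$impact != "enhancer" &&
                          spec$impact != "promoter" &&
                          spec$impact != "intergenic") g1$gene_name,
                     if (!is.null(g2)) g2$gene_name)
      fusion <- if (spec$impact == "pLoF_TRA_fusion")
        paste0(g1$gene_name, "-", g2$gene_name) else NA_character_

      # gene-set membership: single gene in the first n sets; fusion
      # partners split across sets (union-over-genes semantics)
      if (spec$n_genesets > 0 && length(genes_hit) > 0) {
        if (length(genes_hit) == 2 && spec$n_genesets >= 2) {
          geneset_members$hallmark <- c(geneset_members$hallmark,
                                        genes_hit[1])
          geneset_members$cosmic_cgc <- c(geneset_members$cosmic_cgc,
                                          genes_hit[2])
        } else {
          for (si in seq_len(spec$n_genesets))
            geneset_members[[si]] <- c(geneset_members[[si]], genes_hit[1])
        }
      }
      # curation roles for disruptive genes
      roles <- c(spec$role, spec$role2)[seq_along(genes_hit)]
      for (j in seq_along(genes_hit))
        if (!is.na(roles[j]) && roles[j] != "none")
          curation[[length(curation) + 1]] <- data.frame(
            gene_id = genes_hit[j], role = roles[j], note = spec$name,
            stringsAsFactors = FALSE)

      if (spec$in_catalog) {
        off <- sample(-150:150, 2, replace = TRUE) # stays within 200 bp
        catalog[[length(catalog) + 1]] <- data.frame(
          catalog_id = paste0("cat_", spec$name),
          chrom1 = sv$chrom1, pos1 = sv$pos1 + off[1],
          chrom2 = sv$chrom2,
          pos2 = if (sv$svtype == "INS") sv$pos2 + off[1]
                 else sv$pos2 + off[2],
          svtype = sv$svtype, significance = spec$clinvar,
          population_af = if (is.na(spec$catalog_af)) "" else
            sprintf("African:%g;European:%g", spec$catalog_af,
                    spec$catalog_af / 10),
          stringsAsFactors = FALSE)
      }

      truth[[i]] <- data.frame(
        sv_id = spec$name, svtype = sv$svtype, chrom1 = sv$chrom1,
        pos1 = sv$pos1, chrom2 = sv$chrom2, pos2 = sv$pos2,
        impact = spec$impact, genes = paste(genes_hit, collapse = ","),
        af_african = af_afr, af_european = af_eur,
        clinvar = spec$clinvar, novel = !spec$in_catalog,
        expected_tier = spec$expected_tier, fusion = fusion,
        template = spec$template,
        carriers = paste(carr, collapse = ","), stringsAsFactors = FALSE)
    }
    svs <- canonicalize_svs(as_sv_set(do.call(rbind, svs)))
    truth <- do.call(rbind, truth)
    scores <- do.call(rbind, scores)
    catalog <- if (length(catalog)) do.call(rbind, catalog) else
      data.frame(catalog_id = character(), chrom1 = character(),
                 pos1 = integer(), chrom2 = character(), pos2 = integer(),
                 svtype = character(), significance = character(),
                 population_af = character(), stringsAsFactors = FALSE)
    # decoy catalog entries in the gene desert: must match nothing
    catalog <- rbind(catalog, data.frame(
      catalog_id = paste0("decoy_", 1:3), chrom1 = "chr2",
      pos1 = as.integer(plan$chrom_length - c(30000, 25000, 20000)),
      chrom2 = "chr2",
      pos2 = as.integer(plan$chrom_length - c(28000, 23000, 18000)),
      svtype = c("DEL", "DUP", "INV"), significance = "none",
      population_af = "African:0.2;European:0.1", stringsAsFactors = FALSE))
    curation <- unique(do.call(rbind, curation))
    # pad gene sets with filler genes so sets are not trivially tiny
    filler <- setdiff(models$genes$gene_name, unlist(geneset_members))
    geneset_members$hallmark <- unique(c(geneset_members$hallmark,
                                         utils::head(filler, 2)))
    geneset_members$oncogenic <- unique(c(geneset_members$oncogenic,
                                          utils::head(rev(filler), 2)))
    geneset_members$cosmic_cgc <- unique(geneset_members$cosmic_cgc)

    # clinical table: grade-group distribution fixed per group
    gg_afr <- c(rep(5L, 50), rep(4L, 31), rep(3L, 12), rep(2L, 10),
                rep(1L, 8), rep(NA_integer_, 2))
    gg_eur <- c(rep(5L, 25), rep(4L, 24), rep(2L, 5), rep(1L, 3))
    gg_afr <- sample(rep_len(gg_afr, plan$n_african))
    gg_eur <- sample(rep_len(gg_eur, plan$n_european))
    clinical <- data.frame(
      patient_id = samples,
      group = c(rep("African", plan$n_african),
                rep("European", plan$n_european)),
      age = sample(50:80, length(samples), replace = TRUE),
      psa = round_half_up(exp(stats::rnorm(length(samples),
                                           log(20), 1)), 1),
      isup_gg = c(gg_afr, gg_eur),
      family_history = "", stringsAsFactors = FALSE)

    # genotype matrix (graphtyper-aggregate emulation over the merged set)
    n_sv <- nrow(svs)
    gt <- matrix(0L, n_sv, length(samples),
                 dimnames = list(svs$id, samples))
    for (id in names(carriers_by_sv)) gt[id, carriers_by_sv[[id]]] <- 1L
    ft <- matrix("PASS", n_sv, length(samples),
                 dimnames = dimnames(gt))
    gq <- matrix(99, n_sv, length(samples), dimnames = dimnames(gt))
    if (plan$missingness_rate > 0) {
      mask <- matrix(stats::runif(length(gt)) < plan$missingness_rate,
                     n_sv, length(samples))
      ft[mask] <- "FAIL"
      gq[mask] <- 5
    }
    if (plan$genotype_error_rate > 0) {
      err <- matrix(stats::runif(length(gt)) < plan$genotype_error_rate,
                    n_sv, length(samples))
      gt[err] <- (gt[err] + 1L) %% 3L
    }
    sites <- as.data.frame(svs)
    sites$site_filter <- "PASS"
    sites$pass_ratio <- rowMeans(ft == "PASS")
    gmatrix <- sv_genotype_matrix(as_sv_set(sites), gt, ft, gq,
                                  groups = stats::setNames(clinical$group,
                                                           clinical$patient_id))

    # per-sample caller VCF pairs with controlled concordance
    manta <- list(); gridss <- list()
    sdv <- plan$breakpoint_jitter_sd
    for (s in samples) {
      carried <- svs[vapply(svs$id, function(id)
        s %in% carriers_by_sv[[id]], TRUE), , drop = FALSE]
      m <- carried
      if (nrow(m) > 0) m$caller <- "manta"
      shared <- if (nrow(carried) > 0)
        stats::runif(nrow(carried)) <= plan$shared_caller_fraction
        else logical()
      gsub_ <- carried[shared, , drop = FALSE]
      if (nrow(gsub_) > 0) {
        gsub_$caller <- "gridss"
        gsub_$id <- paste0(gsub_$id, "_g")
        if (sdv > 0) {
          j1 <- pmin(pmax(round(stats::rnorm(nrow(gsub_), 0, sdv)),
                          -2 * sdv), 2 * sdv)
          j2 <- pmin(pmax(round(stats::rnorm(nrow(gsub_), 0, sdv)),
                          -2 * sdv), 2 * sdv)
          gsub_$pos1 <- pmax(1L, as.integer(gsub_$pos1 + j1))
          gsub_$pos2 <- pmax(1L, as.integer(gsub_$pos2 + j2))
          ins <- gsub_$svtype == "INS"
          gsub_$pos2[ins] <- gsub_$pos1[ins]
        }
      }
      manta[[s]] <- as_sv_set(as.data.frame(m))
      gridss[[s]] <- canonicalize_svs(as_sv_set(as.data.frame(gsub_)))
    }

    structure(list(plan = plan, models = models, enhancers = enhancers,
                   svs = svs, manta = manta, gridss = gridss,
                   gmatrix = gmatrix, scores = scores, catalog = catalog,
                   genesets = geneset_members, curation = curation,
                   clinical = clinical, truth = truth),
              class = "sv_bundle")
  })
}

#' @export
print.sv_bundle <- function(x, ...) {
  cat(sprintf(
    "<sv_bundle> %d planted SVs, %d samples, %d genes (seed %d)\n",
    nrow(x$svs), ncol(x$gmatrix$gt), nrow(x$models$genes), x$plan$seed))
  invisible(x)
}

#' Write a simulated bundle to disk
#'
#' Lays out the file bundle the pipeline consumes: `annotation.gtf`,
#' `enhancers.bed`, `calls/<sample>.{manta,gridss}.vcf`, `genotypes.vcf`,
#' `scores.tsv`, `catalog.tsv`, `genesets/*.txt`, `curation.tsv`,
#' `clinical.tsv`, `truth.tsv`.
#'
#' @param bundle an `sv_bundle`
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_sv_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "calls"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "genesets"), showWarnings = FALSE)
  write_annotation_gtf(bundle$models, file.path(dir, "annotation.gtf"))
  write_enhancer_bed(bundle$enhancers, file.path(dir, "enhancers.bed"))
  for (s in names(bundle$manta)) {
    write_sv_vcf(bundle$manta[[s]],
                 file.path(dir, "calls", paste0(s, ".manta.vcf")), "manta")
    write_sv_vcf(bundle$gridss[[s]],
                 file.path(dir, "calls", paste0(s, ".gridss.vcf")), "gridss")
  }
  write_genotyped_vcf(bundle$gmatrix, file.path(dir, "genotypes.vcf"))
  write_tsv_file(bundle$scores, file.path(dir, "scores.tsv"))
  write_sv_catalog(bundle$catalog, file.path(dir, "catalog.tsv"))
  for (nm in names(bundle$genesets))
    writeLines(bundle$genesets[[nm]],
               file.path(dir, "genesets", paste0(nm, ".txt")))
  write_tsv_file(bundle$curation, file.path(dir, "curation.tsv"))
  write_tsv_file(bundle$clinical, file.path(dir, "clinical.tsv"))
  write_tsv_file(bundle$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Degrade a bundle in controlled ways
#'
#' @param bundle an `sv_bundle`
#' @param jitter named integer vector: add this many bases to both gridss
#'   breakpoints of the named SV in every sample (e.g. 300 pushes it past
#'   the 200 bp concordance window)
#' @param mask_african named numeric vector: fraction of African samples
#'   whose genotype call at the named SV is flagged low-quality (FT FAIL and
#'   GQ 5)
#' @param site_fail character vector of site ids whose FILTER is set FAIL
#' @param low_pass_ratio named numeric vector: override PASS_ratio of sites
#' @param orphan_bnds number of orphan breakend records appended to the
#'   first sample's gridss callset
#' @return the degraded bundle
#' @export
perturb <- function(bundle, jitter = NULL, mask_african = NULL,
                    site_fail = NULL, low_pass_ratio = NULL,
                    orphan_bnds = 0) {
  for (id in names(jitter)) {
    for (s in names(bundle$gridss)) {
      g <- bundle$gridss[[s]]
      hit <- g$id == paste0(id, "_g")
      if (any(hit)) {
        g$pos1[hit] <- g$pos1[hit] + jitter[[id]]
        g$pos2[hit] <- g$pos2[hit] + jitter[[id]]
        bundle$gridss[[s]] <- g
      }
    }
  }
  if (!is.null(mask_african)) {
    grp <- bundle$gmatrix$groups
    afr <- names(grp)[grp == "African"]
    for (id in names(mask_african)) {
      k <- ceiling(mask_african[[id]] * length(afr))
      victims <- afr[seq_len(k)]
      bundle$gmatrix$ft[id, victims] <- "FAIL"
      bundle$gmatrix$gq[id, victims] <- 5
    }
    bundle$gmatrix$sites$pass_ratio <- rowMeans(bundle$gmatrix$ft == "PASS")
  }
  if (!is.null(site_fail))
    bundle$gmatrix$sites$site_filter[
      bundle$gmatrix$sites$id %in% site_fail] <- "FAIL"
  for (id in names(low_pass_ratio))
    bundle$gmatrix$sites$pass_ratio[
      bundle$gmatrix$sites$id == id] <- low_pass_ratio[[id]]
  if (orphan_bnds > 0) {
    s <- names(bundle$gridss)[1]
    orph <- sv_set(id = sprintf("orphan%d", seq_len(orphan_bnds)),
                   chrom1 = "chr1", pos1 = 1000 + seq_len(orphan_bnds) * 10,
                   orient1 = "+", chrom2 = "chr2",
                   pos2 = 5000 + seq_len(orphan_bnds) * 10, orient2 = "-",
                   svtype = "BND", caller = "gridss", filter_pass = TRUE,
                   mate_id = sprintf("nonexistent%d",
                                     seq_len(orphan_bnds)))
    bundle$gridss[[s]] <- as_sv_set(rbind(as.data.frame(bundle$gridss[[s]]),
                                          as.data.frame(orph)))
  }
  bundle
}
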