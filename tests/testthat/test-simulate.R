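test_that("annotation generation is deterministic and strand-correct", {
  plan <- simulation_plan(seed = 1)
  d1 <- withr::local_tempfile(fileext = ".gtf")
  d2 <- withr::local_tempfile(fileext = ".gtf")
  write_annotation_gtf(simulate_annotation(plan)$models, d1)
  write_annotation_gtf(simulate_annotation(plan)$models, d2)
  expect_identical(readLines(d1), readLines(d2))  # byte-identical
  ann <- simulate_annotation(plan)
  g <- ann$models$genes
  pw <- promoter_windows(ann$models)
  # promoter strictly upstream of the TSS on the transcribed strand
  plus <- g$strand == "+"
  expect_true(all(pw$end[plus] < g$start[plus]))
  expect_true(all(pw$start[!plus] > g$end[!plus]))
  # exons sorted, non-overlapping; cds within exons
  expect_s3_class(ann$models, "transcript_models")
  # n_genes = 0 gives an empty annotation
  specs0 <- default_planted_specs()[0, ]
  empty <- simulate_annotation(simulation_plan(n_genes = 0, specs = specs0))
  expect_equal(nrow(empty$models$genes), 0)
})

test_that("infeasible packing and oversubscribed rosters raise errors", {
  expect_error(simulate_annotation(simulation_plan(n_genes = 500,
                                                   chrom_length = 1e6)),
               "infeasible")
  plan_small <- simulation_plan(n_genes = 4)
  expect_error(simulate_cohort(plan_small), "roster needs")
  expect_error(simulation_plan(shared_caller_fraction = 1.2), "\\[0,1\\]")
})

test_that("bundle generation is deterministic under a fixed seed", {
  b1 <- simulate_cohort(simulation_plan(seed = 11, n_african = 10,
                                        n_european = 5))
  b2 <- simulate_cohort(simulation_plan(seed = 11, n_african = 10,
                                        n_european = 5))
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$gmatrix$gt, b2$gmatrix$gt)
  expect_identical(b1$clinical, b2$clinical)
  b3 <- simulate_cohort(simulation_plan(seed = 12, n_african = 10,
                                        n_european = 5))
  expect_identical(names(b3$truth), names(b1$truth))   # same schema
  expect_false(identical(b1$truth$carriers, b3$truth$carriers))
})

test_that("generated files are parseable with zero warnings at zero noise", {
  dir <- ref_bundle_dir()
  expect_no_warning({
    models <- read_gene_models(file.path(dir, "annotation.gtf"))
    enh <- read_enhancer_bed(file.path(dir, "enhancers.bed"))
    gm <- read_sv_vcf(file.path(dir, "genotypes.vcf"), "genotyped")
    cat <- read_sv_catalog(file.path(dir, "catalog.tsv"))
    sc <- read_score_panel(file.path(dir, "scores.tsv"))
    cur <- read_gene_curation(file.path(dir, "curation.tsv"))
    cli <- read_clinical_table(file.path(dir, "clinical.tsv"))
    s <- cli$patient_id[1]
    m <- read_sv_vcf(file.path(dir, "calls", paste0(s, ".manta.vcf")),
                     "manta")
    g <- read_sv_vcf(file.path(dir, "calls", paste0(s, ".gridss.vcf")),
                     "gridss")
  })
  expect_equal(nrow(models$genes), ref_bundle()$plan$n_genes)
  expect_gt(nrow(gm$sites), 30)
})

test_that("enhancer BED round-trips through the 0-based conversion", {
  enh <- ref_bundle()$enhancers
  tmp <- withr::local_tempfile(fileext = ".bed")
  write_enhancer_bed(enh, tmp)
  back <- read_enhancer_bed(tmp)
  expect_equal(back$start, enh$start)
  expect_equal(back$end, enh$end)
  expect_equal(back$gene_id, enh$gene_id)
})

test_that("perturb: zero perturbation leaves the bundle unchanged", {
  b <- simulate_cohort(simulation_plan(seed = 3, n_african = 8,
                                       n_european = 4))
  expect_identical(perturb(b), b)
})

test_that("perturb: jitter past the window removes the SV downstream", {
  b <- simulate_cohort(simulation_plan(seed = 3, n_african = 8,
                                       n_european = 4))
  b2 <- perturb(b, jitter = c(pp_del_afr = 300))
  carr <- strsplit(b$truth$carriers[b$truth$sv_id == "pp_del_afr"],
                   ",")[[1]][1]
  cf <- concordant_fraction(b2$manta[[carr]], b2$gridss[[carr]])
  expect_equal(cf$matched, nrow(b2$manta[[carr]]) - 1)
  dir <- withr::local_tempdir()
  write_sv_bundle(b2, dir)
  res <- run_pipeline(pipeline_config(), dir, withr::local_tempdir())
  expect_false("pp_del_afr" %in% res$calls$sv_id)
})

test_that("perturb: masking above the missingness gate drops the site", {
  b <- simulate_cohort(simulation_plan(seed = 3, n_african = 20,
                                       n_european = 10))
  b2 <- perturb(b, mask_african = c(pp_del_afr = 0.25))
  gm <- mask_low_quality_genotypes(b2$gmatrix)
  gm <- filter_missingness(gm)
  expect_false("pp_del_afr" %in% gm$sites$id)
  expect_true("pp_del_eur" %in% gm$sites$id)
})

test_that("perturb: site failures and orphan breakends behave as planned", {
  b <- simulate_cohort(simulation_plan(seed = 3, n_african = 8,
                                       n_european = 4))
  b2 <- perturb(b, site_fail = "pp_del_afr",
                low_pass_ratio = c(pp_del_eur = 0.4),
                orphan_bnds = 2)
  out <- apply_site_filters(b2$gmatrix)
  expect_false("pp_del_afr" %in% out$sites$id)
  expect_false("pp_del_eur" %in% out$sites$id)
  # orphan breakends survive writing and reading with a warning
  s <- names(b2$gridss)[1]
  dir <- withr::local_tempdir()
  write_sv_bundle(b2, dir)
  w <- capture_warnings(
    g <- read_sv_vcf(file.path(dir, "calls", paste0(s, ".gridss.vcf")),
                     "gridss"))
  expect_length(w, 2)
  expect_match(w, "orphan", all = TRUE)
  expect_equal(sum(g$svtype == "BND"), 2)
})

test_that("planted singleton frequency lands on the printed 0.004", {
  freqs <- compute_frequencies(ref_bundle()$gmatrix)
  f <- freqs[freqs$id == "clv_path_del", ]
  expect_equal(f$maf_display_african, 0.004)   # 1 het / 226 alleles
})

test_that("score tables honor each tool's SV-type coverage", {
  b <- ref_bundle()
  sc <- b$scores
  tra <- sc[sc$sv_id %in% b$truth$sv_id[b$truth$svtype == "TRA"], ]
  expect_true(all(is.na(tra$strvctvre)) && all(is.na(tra$cadd_sv)))
  inv <- sc[sc$sv_id %in% b$truth$sv_id[b$truth$svtype == "INV"], ]
  expect_true(all(is.na(inv$cadd_sv)))
  ins <- sc[sc$sv_id %in% b$truth$sv_id[b$truth$svtype == "INS"], ]
  expect_true(all(is.na(ins$postre)) && all(is.na(ins$strvctvre)))
})
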