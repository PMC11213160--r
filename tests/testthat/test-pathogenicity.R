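panel <- function(strvctvre = NA, cadd_sv = NA, postre = NA, phenosv = NA)
  data.frame(sv_id = "x", strvctvre = strvctvre, cadd_sv = cadd_sv,
             postre = postre, phenosv = phenosv)

toy_genesets <- function() list(
  hallmark = c("TP53", "MLH1", "BIRC6", "PHC3", "KCTD3"),
  oncogenic = c("TP53", "MLH1", "NSD3"),
  cosmic_cgc = c("TP53", "LTBP1", "NSD3", "PRKACA", "DST"))

toy_curation <- function() data.frame(
  gene_id = c("MLH1", "NSD3", "PHC3", "PRKACA", "KCTD3", "DST", "TP53"),
  role = c("tumour_suppressor", "oncogene", "tumour_suppressor", "oncogene",
           "unclear", "tumour_suppressor", "tumour_suppressor"),
  note = "", stringsAsFactors = FALSE)

imp_row <- function(gene, category, fusion = NA_character_)
  data.frame(sv_id = "x", gene_id = gene, gene_name = gene,
             category = category, fusion_partner = fusion, evidence = "",
             stringsAsFactors = FALSE)

freq_row <- function(maf_afr = 0.004, maf_eur = 0) data.frame(
  id = "x", maf_african = maf_afr, maf_european = maf_eur)

cat_row <- function(significance = "none", max_af = NA_real_,
                    af_excluded = FALSE, novel = TRUE)
  data.frame(sv_id = "x", matched_ids = "", significance = significance,
             max_af = max_af, af_excluded = af_excluded, novel = novel,
             stringsAsFactors = FALSE)

classify1 <- function(impacts, freq = freq_row(), catalog = cat_row(),
                      pan = panel(postre = 0.9, phenosv = 0.7),
                      genesets = toy_genesets(), curation = toy_curation())
  classify_pathogenicity("x", impacts, freq, catalog, pan, genesets,
                         curation)

test_that("tools_passed applies per-tool thresholds to present scores", {
  expect_equal(tools_passed(panel()), character())
  expect_equal(tools_passed(panel(strvctvre = 0.37)), "strvctvre")  # >=
  expect_equal(tools_passed(panel(0.5, 9, NA, 0.6)),
               c("strvctvre", "phenosv"))
  expect_equal(tools_passed(panel(0.3699, 10, 0.8, 0.4999)),
               c("cadd_sv", "postre"))
})

test_that("is_candidate needs two passing tools, coverage-constrained", {
  expect_false(is_candidate(panel(strvctvre = 0.9)))
  expect_true(is_candidate(panel(postre = 0.85, phenosv = 0.55)))  # TRA-like
  expect_true(is_candidate(panel(0.9, 20, 0.9, 0.9)))
})

test_that("cancer gene-set support uses union-over-genes semantics", {
  gs <- toy_genesets()
  expect_equal(cancer_gene_support("TP53", gs)$n_sets, 3)
  expect_true(cancer_gene_support("TP53", gs)$supported)
  expect_false(cancer_gene_support("LTBP1", gs)$supported)  # one set only
  # fusion partners each hit a different set
  expect_true(cancer_gene_support(c("BIRC6", "LTBP1"), gs)$supported)
  expect_false(cancer_gene_support("NOTHERE", gs)$supported)
})

test_that("cascade recovers the worked tier assignments", {
  # pLoF INV on a tumour suppressor, rare, 2 tools, 2 sets -> PP-SV
  expect_equal(classify1(imp_row("MLH1", "pLoF"))$tier, "pp_sv")
  # pLoF on an oncogene -> unlikely
  expect_equal(classify1(imp_row("NSD3", "pLoF"))$tier, "unlikely")
  # fusion with tumour suppressor + oncogene partners -> cautionary
  fus <- rbind(imp_row("PHC3", "pLoF", "PHC3-PRKACA"),
               imp_row("PRKACA", "pLoF", "PHC3-PRKACA"))
  expect_equal(classify1(fus)$tier, "cautionary_pp_sv")
  # tumour suppressor + unclear partner -> cautionary
  fus2 <- rbind(imp_row("KCTD3", "pLoF"), imp_row("DST", "pLoF"))
  expect_equal(classify1(fus2)$tier, "cautionary_pp_sv")
  # ClinVar likely-pathogenic short-circuits the panel entirely
  expect_equal(classify1(imp_row("MLH1", "IED"),
                         catalog = cat_row("likely_pathogenic", 1e-4,
                                           FALSE, FALSE),
                         pan = panel())$tier, "clinvar_likely_pathogenic")
  expect_equal(classify1(imp_row("MLH1", "pLoF"),
                         catalog = cat_row("benign"))$tier,
               "excluded_benign")
  # uncertain significance falls through to the score cascade
  expect_equal(classify1(imp_row("MLH1", "pLoF"),
                         catalog = cat_row("uncertain"))$tier, "pp_sv")
})

test_that("cascade exclusion gates fire in order", {
  expect_equal(classify1(imp_row("MLH1", "intronic"))$tier,
               "not_gene_disruptive")
  expect_equal(classify1(imp_row("MLH1", "pLoF"),
                         freq = freq_row(0.13, 0.1))$tier,
               "excluded_common")
  expect_equal(classify1(imp_row("MLH1", "pLoF"),
                         pan = panel(phenosv = 0.9))$tier,
               "excluded_no_consensus")
  expect_equal(classify1(imp_row("LTBP1", "pLoF"))$tier,
               "excluded_no_cancer_support")
  # low-frequency (1-5%) in one group
  expect_equal(classify1(imp_row("MLH1", "pLoF"),
                         freq = freq_row(0.02, 0))$tier, "excluded_common")
  expect_equal(classify1(imp_row("MLH1", "pLoF"),
                         catalog = cat_row("none", 0.03, TRUE, FALSE))$tier,
               "excluded_catalog_af")
  # copy gain of an oncogene is pathogenic; of a tumour suppressor not
  expect_equal(classify1(imp_row("NSD3", "CG"))$tier, "pp_sv")
  expect_equal(classify1(imp_row("MLH1", "CG"))$tier, "unlikely")
})

test_that("genes missing from the curation table become unclear + warning", {
  expect_warning(res <- classify1(imp_row("UNKNOWNGENE", "pLoF"),
                                  genesets = list(a = "UNKNOWNGENE",
                                                  b = "UNKNOWNGENE",
                                                  c = "other")),
                 "curation")
  expect_equal(res$tier, "cautionary_pp_sv")
})

test_that("raising any single score never demotes a candidate", {
  set.seed(4)
  thresholds <- svpath:::DEFAULT_SCORE_THRESHOLDS
  for (i in 1:50) {
    base <- panel(runif(1), runif(1, 0, 20), runif(1), runif(1))
    before <- is_candidate(base)
    tool <- sample(names(thresholds), 1)
    bumped <- base
    bumped[[tool]] <- bumped[[tool]] + runif(1, 0, 10)
    if (before) expect_true(is_candidate(bumped))
  }
})

test_that("a 4-of-4 rule strictly shrinks candidates under partial coverage", {
  panels <- rbind(
    panel(0.9, 20, 0.9, 0.9),                 # full pass
    panel(NA, NA, 0.9, 0.9),                  # TRA-like coverage, 2 tools
    panel(0.9, 20, 0.2, 0.9))                 # 3 of 4
  n2 <- sum(vapply(seq_len(3), function(i)
    is_candidate(panels[i, ], k = 2), TRUE))
  n4 <- sum(vapply(seq_len(3), function(i)
    is_candidate(panels[i, ], k = 4), TRUE))
  expect_equal(n2, 3)
  expect_equal(n4, 1)
  expect_lt(n4, n2)
})

test_that("gene sets read from plain files and GMT lines", {
  d <- withr::local_tempdir()
  writeLines(c("TP53", "MLH1"), file.path(d, "plain.txt"))
  writeLines("MY_SET\tdesc\tBRCA1\tBRCA2", file.path(d, "sets.gmt"))
  gs <- read_gene_sets(c(plain = file.path(d, "plain.txt"),
                         gmt = file.path(d, "sets.gmt")))
  expect_equal(gs$plain, c("TP53", "MLH1"))
  expect_equal(gs$MY_SET, c("BRCA1", "BRCA2"))
})
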