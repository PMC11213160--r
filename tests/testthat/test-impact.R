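# toy gene geometry (toy_gene): exons at start + 0/1150/2300/3450/4600,
# each 150 bp; exons 2-4 coding, exons 1 and 5 UTR

test_that("DEL decision table: CDS -> pLoF, UTR-only, intronic", {
  g <- toy_gene("OCA2")
  models <- toy_models(g)
  ex <- g$exons
  del_cds <- sv1("d1", "DEL", "chr1", ex$start[3] - 200L, ex$end[3] + 200L)
  expect_equal(classify_impact(del_cds, "OCA2", models), "pLoF")
  del_utr <- sv1("d2", "DEL", "chr1", ex$start[1] + 20L, ex$start[1] + 80L)
  expect_equal(classify_impact(del_utr, "OCA2", models), "UTR")
  del_int <- sv1("d3", "DEL", "chr1", ex$end[2] + 100L, ex$end[2] + 400L)
  expect_equal(classify_impact(del_int, "OCA2", models), "intronic")
})

test_that("DUP decision table: CG, exon-breakpoint pLoF, IED, partials", {
  g <- toy_gene("SLC3A1")
  models <- toy_models(g)
  ex <- g$exons; gr <- g$gene
  expect_equal(classify_impact(
    sv1("cg", "DUP", "chr1", gr$start - 2500L, gr$end + 2500L),
    "SLC3A1", models), "CG")
  expect_equal(classify_impact(
    sv1("plof", "DUP", "chr1", ex$start[2] + 50L, ex$start[3] + 50L),
    "SLC3A1", models), "pLoF")
  # both breakpoints intronic, exon 3 fully contained -> IED
  expect_equal(classify_impact(
    sv1("ied", "DUP", "chr1", ex$end[2] + 300L, ex$end[3] + 300L),
    "SLC3A1", models), "IED")
  expect_equal(classify_impact(
    sv1("pe", "DUP", "chr1", ex$end[2] + 100L, ex$start[3] + 50L),
    "SLC3A1", models), "partial_exon_DUP")
  expect_equal(classify_impact(
    sv1("pg", "DUP", "chr1", gr$start - 3000L, ex$end[2] + 150L),
    "SLC3A1", models), "partial_gene_DUP")
})

test_that("INV decision table: whole-gene vs breakpoint pLoF", {
  g <- toy_gene("MLH1")
  models <- toy_models(g)
  gr <- g$gene
  expect_equal(classify_impact(
    sv1("wg", "INV", "chr1", gr$start - 2500L, gr$end + 2500L),
    "MLH1", models), "whole_gene_INV")
  expect_equal(classify_impact(
    sv1("bp", "INV", "chr1", g$exons$end[2] + 200L, gr$end + 5000L),
    "MLH1", models), "pLoF")
})

test_that("TRA breakpoints in gene bodies give pLoF and fusion names", {
  a <- toy_gene("GA", gene_name = "AK8", chrom = "chr9", start = 20000L)
  b <- toy_gene("GB", gene_name = "DST", chrom = "chr6", start = 30000L)
  models <- toy_models(a, b)
  tra <- sv1("t", "TRA", "chr9", 21500L, 31500L, "chr6")
  expect_equal(classify_impact(tra, "GA", models), "pLoF")
  expect_equal(annotate_fusion(tra, models), "AK8-DST")   # order preserved
  # breakpoint 2 intergenic: pLoF on one gene, no fusion
  tra2 <- sv1("t2", "TRA", "chr9", 21500L, 500L, "chr6")
  expect_true(is.na(annotate_fusion(tra2, models)))
  imp <- annotate_impacts(tra2, models)
  expect_equal(imp$category, "pLoF")
  expect_true(is.na(imp$fusion_partner))
})

test_that("promoter windows are strand-aware and never overlap the gene", {
  plus <- toy_gene("P", strand = "+", start = 50000L)
  minus <- toy_gene("M", strand = "-", chrom = "chr2", start = 50000L)
  models <- toy_models(plus, minus)
  pw <- promoter_windows(models)
  expect_equal(pw$start[pw$gene_id == "P"], 49000)
  expect_equal(pw$end[pw$gene_id == "P"], 49999)
  expect_equal(pw$start[pw$gene_id == "M"], minus$gene$end + 1)
  # mirror: never overlapping own gene body
  g <- models$genes
  expect_true(all(pw$end < g$start | pw$start > g$end))
  # DEL in the upstream window is a promoter SV on each strand
  expect_equal(classify_impact(sv1("p1", "DEL", "chr1", 49400L, 49500L),
                               "P", models), "promoter")
  expect_equal(classify_impact(
    sv1("p2", "DEL", "chr2", minus$gene$end + 400L, minus$gene$end + 500L),
    "M", models), "promoter")
})

test_that("enhancer and intergenic fallbacks", {
  g <- toy_gene("E1", start = 50000L)
  models <- toy_models(g)
  enh <- data.frame(chrom = "chr1", start = 40000L, end = 40500L,
                    gene_id = "E1", stringsAsFactors = FALSE)
  expect_equal(classify_impact(sv1("e", "DEL", "chr1", 40100L, 40200L),
                               "E1", models, enhancers = enh), "enhancer")
  imp <- annotate_impacts(sv1("i", "DEL", "chr1", 5000L, 5100L), models, enh)
  expect_equal(imp$category, "intergenic")
  expect_true(is.na(imp$gene_id))
})

test_that("SVs above the span cutoff are annotated via breakpoints only", {
  hit <- toy_gene("FOXP1", chrom = "chr3", start = 20000L)
  inside <- toy_gene("IN1", chrom = "chr3", start = 500000L)
  models <- toy_models(hit, inside)
  big <- sv1("inv", "INV", "chr3", 21500L, 1500000L)   # 1.48 Mb span
  cands <- candidate_genes(big, models, max_span = 1e6)
  expect_equal(cands, "FOXP1")                         # IN1 skipped
  cands_small_cutoff <- candidate_genes(big, models, max_span = 2e6)
  expect_setequal(cands_small_cutoff, c("FOXP1", "IN1"))
})

test_that("exactly one category per (sv, gene); oracle equivalence", {
  for (seed in 1:15) {
    inst <- random_impact_instance(seed)
    imp <- annotate_impacts(inst$svs, inst$models)
    expect_equal(anyDuplicated(imp[, c("sv_id", "gene_id")]), 0)
    # gene-body categories agree with the per-base oracle
    for (i in seq_len(nrow(inst$svs))) {
      sv <- inst$svs[i, ]
      for (gid in candidate_genes(sv, inst$models)) {
        got <- imp$category[imp$sv_id == sv$id & !is.na(imp$gene_id) &
                              imp$gene_id == gid]
        want <- oracle_gene_body(sv, gid, inst$models)
        if (is.na(want)) {
          expect_true(length(got) == 0 ||
                        got %in% c("promoter", "enhancer"),
                      info = sprintf("seed %d sv %s gene %s", seed, sv$id,
                                     gid))
        } else {
          expect_equal(got, want, info = sprintf("seed %d sv %s gene %s",
                                                 seed, sv$id, gid))
        }
      }
    }
  }
})

test_that("depth ratio recovers heterozygous DEL and DUP signatures", {
  del <- sv1("d", "DEL", "chr1", 20001L, 30000L)
  track <- list(chr1 = c(rep(30, 20000), rep(15, 10000), rep(30, 10000)))
  expect_equal(depth_ratio(del, track), 0.5)
  dup <- sv1("u", "DUP", "chr1", 20001L, 30000L)
  track$chr1[20001:30000] <- 45
  expect_equal(depth_ratio(dup, track), 1.5)
  # noisy heterozygous DEL: 44-51% depth reduction
  set.seed(9)
  base <- rpois(40000, 30)
  reduction <- runif(10000, 0.44, 0.51)
  noisy <- base
  noisy[20001:30000] <- rpois(10000, 30 * (1 - mean(reduction)))
  r <- depth_ratio(del, list(chr1 = noisy))
  expect_gt(r, 0.49); expect_lt(r, 0.56)
  # flank truncation at the contig edge warns
  del_edge <- sv1("e", "DEL", "chr1", 5001L, 15000L)
  expect_warning(depth_ratio(del_edge, list(chr1 = base)), "truncated")
  expect_error(depth_ratio(sv1("t", "INS", "chr1", 10L), list(chr1 = base)),
               "DEL/DUP")
})
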