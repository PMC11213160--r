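test_that("header-only VCF yields an empty record set", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(sv_set(), tmp, "manta")
  out <- read_sv_vcf(tmp, "manta")
  expect_s3_class(out, "sv_set")
  expect_equal(nrow(out), 0)
})

test_that("a symbolic DEL line parses with the documented length convention", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"),
    paste(c("chr15", "28017719", "del1", "N", "<DEL>", ".", "PASS",
            "SVTYPE=DEL;END=28020677;SVLEN=-2958"), collapse = "\t")), tmp)
  out <- read_sv_vcf(tmp, "manta")
  expect_equal(out$svtype, "DEL")
  expect_equal(out$pos1, 28017719L)
  expect_equal(out$pos2, 28020677L)
  expect_equal(sv_length(out), 2958L)
  expect_true(out$filter_pass)
})

test_that("FILTER mapping: PASS and '.' pass, anything else fails", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO"), collapse = "\t"))
  line <- function(id, filt) paste(c("chr1", "100", id, "N", "<DEL>", ".",
                                     filt, "SVTYPE=DEL;END=500"),
                                   collapse = "\t")
  writeLines(c(hdr, line("a", "PASS"), line("b", "."),
               line("c", "LowQual")), tmp)
  out <- read_sv_vcf(tmp, "manta")
  expect_equal(out$filter_pass, c(TRUE, TRUE, FALSE))
})

test_that("BND bracket forms map to the orientation/type table", {
  # one junction per bracket form; position order (lo, hi) drives the type
  tmp <- withr::local_tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO"), collapse = "\t"))
  bl <- function(id, pos, alt, mate)
    paste(c("chr1", pos, id, "N", alt, ".", "PASS",
            sprintf("SVTYPE=BND;MATEID=%s", mate)), collapse = "\t")
  writeLines(c(hdr,
    # (+,-) -> DEL of length 400
    bl("d_bnd1", 100, "N[chr1:500[", "d_bnd2"),
    bl("d_bnd2", 500, "]chr1:100]N", "d_bnd1"),
    # (-,+) -> DUP
    bl("u_bnd1", 1000, "]chr1:1400]N", "u_bnd2"),
    bl("u_bnd2", 1400, "N[chr1:1000[", "u_bnd1"),
    # (+,+) -> INV
    bl("v_bnd1", 2000, "N]chr1:2400]", "v_bnd2"),
    bl("v_bnd2", 2400, "N]chr1:2000]", "v_bnd1"),
    # (-,-) -> INV
    bl("w_bnd1", 3000, "[chr1:3400[N", "w_bnd2"),
    bl("w_bnd2", 3400, "[chr1:3000[N", "w_bnd1"),
    # different chromosomes -> TRA
    bl("t_bnd1", 138903881, "N[chr19:21614900[", "t_bnd2")), tmp)
  writeLines(c(readLines(tmp),
    paste(c("chr19", 21614900, "t_bnd2", "N", "]chr5:138903881]N", ".",
            "PASS", "SVTYPE=BND;MATEID=t_bnd1"), collapse = "\t")), tmp)
  # fix chrom of the TRA first mate: rewrite with chr5
  lines <- readLines(tmp)
  lines[grepl("^chr1\t138903881", lines)] <-
    sub("^chr1", "chr5", lines[grepl("^chr1\t138903881", lines)])
  writeLines(lines, tmp)
  out <- read_sv_vcf(tmp, "gridss")
  out <- out[order(out$id), ]
  expect_equal(stats::setNames(out$svtype, out$id),
               c(d = "DEL", t = "TRA", u = "DUP", v = "INV", w = "INV"))
  expect_equal(out$length[out$id == "d"], 400L)
  tra <- out[out$id == "t", ]
  expect_equal(c(tra$chrom1, tra$chrom2), c("chr5", "chr19"))
})

test_that("orphan breakends are retained with a warning; counts add up", {
  raw <- bind_svs(
    sv1("p_bnd1", "TRA", "chr1", 100L, 900L, "chr2"),
    sv1("p_bnd2", "TRA", "chr2", 900L, 100L, "chr1"),
    sv1("orph", "TRA", "chr1", 5000L, 7000L, "chr2"))
  raw$svtype <- "BND"
  raw$mate_id <- c("p_bnd2", "p_bnd1", "missing")
  expect_warning(res <- resolve_bnd_pairs(raw), "orphan")
  # (3 BND lines - 1 orphan)/2 + 1 orphan = 2 records
  expect_equal(nrow(res), 2)
  expect_setequal(res$svtype, c("TRA", "BND"))
})

test_that("inconsistent mate coordinates raise an error", {
  raw <- bind_svs(sv1("a", "TRA", "chr1", 100L, 900L, "chr2"),
                  sv1("b", "TRA", "chr2", 950L, 100L, "chr1"))
  raw$svtype <- "BND"
  raw$mate_id <- c("b", "a")
  expect_error(resolve_bnd_pairs(raw), "inconsistent mate")
})

test_that("malformed bracket ALT errors with the line number", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO"), collapse = "\t"),
               paste(c("chr1", "100", "x", "N", "N[chr1:500", ".", "PASS",
                       "SVTYPE=BND"), collapse = "\t")), tmp)
  expect_error(read_sv_vcf(tmp, "gridss"), "line 1")
})

test_that("canonicalize orders intra-chromosomal breakpoints, preserves TRA", {
  rec <- bind_svs(sv1("x", "DEL", "chr1", 200L, 100L),
                  sv1("t", "TRA", "chr9", 132876361L, 56896165L, "chr6"))
  # force the reversed DEL through the raw constructor path
  canon <- canonicalize_svs(rec)
  expect_equal(canon$pos1[1], 100L)
  expect_equal(canon$pos2[1], 200L)
  expect_equal(canon$chrom1[2], "chr9")   # reported order preserved
  expect_identical(canonicalize_svs(canon), canon)  # idempotent
  expect_equal(sv_length(canon)[1], sv_length(rec)[1])  # length invariant
})

test_that("sv_length follows the type conventions", {
  svs <- bind_svs(
    sv1("pign", "DEL", "chr18", 62152637L, 62157701L),
    sv1("slc3a1", "DUP", "chr2", 44281377L, 44281612L),
    sv1("tra", "TRA", "chr1", 100L, 200L, "chr2"),
    sv1("ins", "INS", "chr1", 500L, insertion_seq = "ACGTACGT"))
  expect_equal(sv_length(svs), c(5064L, 235L, NA, 8L))
  expect_true(all(sv_length(svs) >= 0, na.rm = TRUE))
})

test_that("write/read round-trips are identities for both caller dialects", {
  cols <- c("id", "chrom1", "pos1", "orient1", "chrom2", "pos2", "orient2",
            "svtype", "filter_pass", "insertion_seq", "length")
  for (seed in 1:5) {
    svs <- random_sv_set(12, seed)
    for (dialect in c("manta", "gridss")) {
      tmp <- withr::local_tempfile(fileext = ".vcf")
      write_sv_vcf(svs, tmp, dialect)
      back <- read_sv_vcf(tmp, dialect)
      back <- back[order(match(back$id, svs$id)), ]
      rownames(back) <- NULL
      expect_equal(as.data.frame(back)[, cols],
                   as.data.frame(svs)[, cols],
                   ignore_attr = TRUE,
                   info = sprintf("seed %d dialect %s", seed, dialect))
    }
  }
})

test_that("genotyped dialect round-trips sites, genotypes and QC fields", {
  gm <- single_site_matrix(4, 3, afr_het = 1)
  gm$gt[1, 2] <- NA
  gm$ft[1, 2] <- "FAIL"
  gm$sites$pass_ratio <- 6 / 7
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_genotyped_vcf(gm, tmp)
  back <- read_sv_vcf(tmp, "genotyped")
  expect_s3_class(back, "sv_genotype_matrix")
  expect_equal(back$gt, gm$gt)
  expect_equal(back$ft, gm$ft)
  expect_equal(back$sites$pass_ratio, gm$sites$pass_ratio, tolerance = 1e-6)
  expect_equal(back$sites$svtype, gm$sites$svtype)
})
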