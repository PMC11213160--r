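# Shared fixtures and independent oracles.

# ---- toy annotation --------------------------------------------------

# a 5-exon gene mirroring the generator geometry: 150 bp exons, 1 kb
# introns, exons 2-4 coding
toy_gene <- function(gene_id, gene_name = gene_id, chrom = "chr1",
                     start = 10000L, strand = "+") {
  ex_start <- start + (0:4) * 1150L
  ex_end <- ex_start + 149L
  list(gene = data.frame(gene_id = gene_id, gene_name = gene_name,
                         chrom = chrom, strand = strand, start = start,
                         end = ex_end[5], stringsAsFactors = FALSE),
       exons = data.frame(gene_id = gene_id, start = ex_start, end = ex_end,
                          stringsAsFactors = FALSE),
       cds = data.frame(gene_id = gene_id, start = ex_start[2:4],
                        end = ex_end[2:4], stringsAsFactors = FALSE))
}

toy_models <- function(...) {
  gs <- list(...)
  transcript_models(do.call(rbind, lapply(gs, `[[`, "gene")),
                    do.call(rbind, lapply(gs, `[[`, "exons")),
                    do.call(rbind, lapply(gs, `[[`, "cds")))
}

sv1 <- function(id, svtype, chrom1, pos1, pos2 = pos1, chrom2 = chrom1,
                filter_pass = TRUE, insertion_seq = NA_character_,
                caller = "manta") {
  or <- switch(svtype, DEL = c("+", "-"), DUP = c("-", "+"),
               INV = c("+", "+"), INS = c("+", "-"), TRA = c("+", "-"))
  sv_set(id = id, chrom1 = chrom1, pos1 = pos1, orient1 = or[1],
         chrom2 = chrom2, pos2 = pos2, orient2 = or[2], svtype = svtype,
         caller = caller, filter_pass = filter_pass,
         insertion_seq = insertion_seq)
}

bind_svs <- function(...) {
  svpath:::as_sv_set(do.call(rbind, lapply(list(...), as.data.frame)))
}

# random sv_set for round-trip / matcher properties
random_sv_set <- function(n, seed, chroms = c("chrA", "chrB"),
                          pass_prob = 0.8, prefix = "sv") {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    svtype <- sample(c("DEL", "DUP", "INV", "INS", "TRA"), 1)
    c1 <- sample(chroms, 1)
    p1 <- sample(1000:100000, 1)
    if (svtype == "TRA") {
      c2 <- sample(setdiff(chroms, c1), 1)
      p2 <- sample(1000:100000, 1)
    } else {
      c2 <- c1
      p2 <- if (svtype == "INS") p1 else p1 + sample(50:5000, 1)
    }
    as.data.frame(sv1(sprintf("%s%03d", prefix, i), svtype, c1, p1, p2, c2,
                      filter_pass = runif(1) < pass_prob,
                      insertion_seq = if (svtype == "INS")
                        paste(sample(c("A", "C", "G", "T"),
                                     sample(5:50, 1), TRUE), collapse = "")
                      else NA_character_))
  })
  canonicalize_svs(svpath:::as_sv_set(do.call(rbind, rows)))
}

# ---- genotype matrix builder -----------------------------------------

make_gmatrix <- function(svs, gt, groups, ft = NULL, gq = NULL,
                         site_filter = "PASS", pass_ratio = 1) {
  sites <- as.data.frame(svs)
  sites$site_filter <- rep_len(site_filter, nrow(sites))
  sites$pass_ratio <- rep_len(pass_ratio, nrow(sites))
  if (is.null(ft)) ft <- matrix("PASS", nrow(gt), ncol(gt),
                                dimnames = dimnames(gt))
  if (is.null(gq)) gq <- matrix(99, nrow(gt), ncol(gt),
                                dimnames = dimnames(gt))
  sv_genotype_matrix(svpath:::as_sv_set(sites), gt, ft, gq, groups = groups)
}

# diploid cohort with `carriers` heterozygous at a single DEL site
single_site_matrix <- function(n_african, n_european, afr_het = 0,
                               eur_het = 0) {
  samples <- c(sprintf("AFR%03d", seq_len(n_african)),
               sprintf("EUR%03d", seq_len(n_european)))
  groups <- stats::setNames(c(rep("African", n_african),
                              rep("European", n_european)), samples)
  gt <- matrix(0L, 1, length(samples), dimnames = list("s1", samples))
  if (afr_het > 0) gt[1, seq_len(afr_het)] <- 1L
  if (eur_het > 0) gt[1, n_african + seq_len(eur_het)] <- 1L
  make_gmatrix(sv1("s1", "DEL", "chr1", 1000L, 2000L), gt, groups)
}

# ---- independent oracles ---------------------------------------------

# brute-force all-pairs concordance matcher (nested loops, then greedy
# smallest-total-distance one-to-one assignment with id tie-breaks)
oracle_match_callsets <- function(manta, gridss, window) {
  cand <- list()
  for (i in seq_len(nrow(manta))) {
    for (j in seq_len(nrow(gridss))) {
      a <- manta[i, ]; b <- gridss[j, ]
      if (a$svtype != b$svtype) next
      if (!(a$filter_pass || b$filter_pass)) next
      d <- NULL
      if (a$svtype == "TRA") {
        if (a$chrom1 == b$chrom1 && a$chrom2 == b$chrom2) {
          dd <- c(abs(a$pos1 - b$pos1), abs(a$pos2 - b$pos2))
          if (all(dd <= window)) d <- dd
        }
        if (a$chrom1 == b$chrom2 && a$chrom2 == b$chrom1) {
          dd <- c(abs(a$pos1 - b$pos2), abs(a$pos2 - b$pos1))
          if (all(dd <= window) && (is.null(d) || sum(dd) < sum(d))) d <- dd
        }
      } else if (a$svtype == "INS") {
        if (a$chrom1 == b$chrom1 && abs(a$pos1 - b$pos1) <= window)
          d <- rep(abs(a$pos1 - b$pos1), 2)
      } else {
        if (a$chrom1 == b$chrom1) {
          dd <- c(abs(a$pos1 - b$pos1), abs(a$pos2 - b$pos2))
          if (all(dd <= window)) d <- dd
        }
      }
      if (!is.null(d))
        cand[[length(cand) + 1]] <- data.frame(
          mi = i, gi = j, manta_id = a$id, gridss_id = b$id,
          total = sum(d), stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(data.frame(manta_id = character(),
                                       gridss_id = character()))
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$total, cand$manta_id, cand$gridss_id), ]
  used_m <- used_g <- character()
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (cand$manta_id[k] %in% used_m || cand$gridss_id[k] %in% used_g) next
    keep[k] <- TRUE
    used_m <- c(used_m, cand$manta_id[k])
    used_g <- c(used_g, cand$gridss_id[k])
  }
  out <- cand[keep, c("manta_id", "gridss_id")]
  out[order(out$manta_id), , drop = FALSE]
}

# brute-force catalog scan
oracle_match_catalog <- function(sv, catalog, window) {
  hits <- logical(nrow(catalog))
  for (k in seq_len(nrow(catalog))) {
    e <- catalog[k, ]
    if (e$svtype != sv$svtype) next
    ok <- FALSE
    if (sv$svtype == "TRA") {
      ok <- (e$chrom1 == sv$chrom1 && e$chrom2 == sv$chrom2 &&
               abs(e$pos1 - sv$pos1) <= window &&
               abs(e$pos2 - sv$pos2) <= window) ||
        (e$chrom1 == sv$chrom2 && e$chrom2 == sv$chrom1 &&
           abs(e$pos1 - sv$pos2) <= window &&
           abs(e$pos2 - sv$pos1) <= window)
    } else if (sv$svtype == "INS") {
      ok <- e$chrom1 == sv$chrom1 && abs(e$pos1 - sv$pos1) <= window
    } else {
      ok <- e$chrom1 == sv$chrom1 && abs(e$pos1 - sv$pos1) <= window &&
        abs(e$pos2 - sv$pos2) <= window
    }
    hits[k] <- ok
  }
  catalog$catalog_id[hits]
}

# per-base gene-body impact oracle for one (sv, gene) pair; NA when no
# gene-body rule fires
oracle_gene_body <- function(sv, gene_id, models) {
  g <- models$genes[models$genes$gene_id == gene_id, ]
  ex <- models$exons[models$exons$gene_id == gene_id, , drop = FALSE]
  cd <- models$cds[models$cds$gene_id == gene_id, , drop = FALSE]
  gb <- g$start:g$end
  exb <- unlist(mapply(seq, ex$start, ex$end, SIMPLIFY = FALSE))
  cdb <- if (nrow(cd)) unlist(mapply(seq, cd$start, cd$end,
                                     SIMPLIFY = FALSE)) else integer()
  in1 <- sv$chrom1 == g$chrom && sv$pos1 %in% gb
  in2 <- sv$chrom2 == g$chrom && sv$pos2 %in% gb
  if (sv$svtype %in% c("TRA", "BND"))
    return(if (in1 || in2) "pLoF" else NA_character_)
  if (sv$chrom1 != g$chrom) return(NA_character_)
  span <- sv$pos1:sv$pos2
  if (sv$svtype == "DEL") {
    if (length(intersect(span, cdb)) > 0) return("pLoF")
    if (length(intersect(span, exb)) > 0) return("UTR")
    if (all(span %in% setdiff(gb, exb))) return("intronic")
    return(NA_character_)
  }
  if (sv$svtype == "DUP") {
    if (!in1 && !in2 && all(gb %in% span)) return("CG")
    if (in1 && in2) {
      if (sv$pos1 %in% exb && sv$pos2 %in% exb) return("pLoF")
      inner <- setdiff(span, c(sv$pos1, sv$pos2))
      for (k in seq_len(nrow(ex)))
        if (all(seq(ex$start[k], ex$end[k]) %in% inner)) return("IED")
      return("partial_exon_DUP")
    }
    if (in1 || in2) return("partial_gene_DUP")
    return(NA_character_)
  }
  if (sv$svtype == "INV") {
    if (!in1 && !in2 && all(gb %in% span)) return("whole_gene_INV")
    if (in1 || in2) return("pLoF")
    return(NA_character_)
  }
  if (sv$svtype == "INS") {
    if (!in1) return(NA_character_)
    if (sv$pos1 %in% cdb) return("pLoF")
    if (sv$pos1 %in% exb) return("UTR")
    return("intronic")
  }
  NA_character_
}

# random toy annotation + SVs around it, for impact-oracle equivalence
random_impact_instance <- function(seed, n_genes = 6, n_svs = 15) {
  set.seed(seed)
  gs <- lapply(seq_len(n_genes), function(k) {
    toy_gene(sprintf("G%02d", k), chrom = paste0("chr", (k %% 2) + 1),
             start = 20000L + (k %/% 2) * 40000L,
             strand = if (k %% 2 == 0) "-" else "+")
  })
  models <- do.call(toy_models, gs)
  svs <- lapply(seq_len(n_svs), function(i) {
    svtype <- sample(c("DEL", "DUP", "INV", "INS", "TRA"), 1)
    g <- models$genes[sample(nrow(models$genes), 1), ]
    p1 <- g$start + sample(-6000:6000, 1)
    if (svtype == "TRA") {
      g2 <- models$genes[sample(nrow(models$genes), 1), ]
      while (g2$chrom == g$chrom) g2 <- models$genes[
        sample(nrow(models$genes), 1), ]
      p2 <- g2$start + sample(-6000:6000, 1)
      c2 <- g2$chrom
    } else if (svtype == "INS") {
      p2 <- p1; c2 <- g$chrom
    } else {
      p2 <- p1 + sample(10:9000, 1); c2 <- g$chrom
    }
    as.data.frame(sv1(sprintf("rsv%03d", i), svtype, g$chrom,
                      max(1L, p1), max(1L, p2), c2,
                      insertion_seq = if (svtype == "INS") "ACGTACGTAC"
                      else NA_character_))
  })
  list(models = models,
       svs = canonicalize_svs(svpath:::as_sv_set(do.call(rbind, svs))))
}

# ---- cohort clinical fixture -----------------------------------------
# A published-style candidate-carrier table: 20 reportable SVs, their
# carriers with grade groups, embedded in a 113 + 57 cohort whose grade
# distribution gives 81/113 GG>=4, 93/113 GG>=3 (African) and 49/57 GG>=4
# (European).
cohort_fixture <- function() {
  carrier_rows <- list(
    # gene, tier, carriers (id=GG, NA = unknown), group
    list("SLC3A1", "clinvar_likely_pathogenic",
         c(N0001 = 4, SMU094 = 4), "African"),
    list("OCA2", "clinvar_likely_pathogenic", c(N0059 = 5), "African"),
    list("PIGN", "clinvar_pathogenic", c(SMU083 = 3), "African"),
    list("SLC7A2", "pp_sv", c(UP2035 = 5, KAL0054 = 5), "African"),
    list("DNAJC15", "pp_sv", c(`17135` = 5), "European"),
    list("BCL2L11", "pp_sv", c(KAL0101 = 5), "African"),
    list("BARD1", "pp_sv", c(N0073 = NA), "African"),
    list("COL4A2", "pp_sv", c(UP2039 = 4), "African"),
    list("SLC2A5", "pp_sv", c(`11099` = 5), "European"),
    list("FOXP1", "pp_sv", c(UP2101 = 5, N0084 = 4), "African"),
    list("WASF1", "pp_sv", c(N0048 = 5), "African"),
    list("MLH1", "pp_sv", c(SMU080 = 4), "African"),
    list("RB1", "pp_sv", c(SMU064 = 3), "African"),
    list("CTNNA1", "pp_sv", c(`13179` = 5), "European"),
    list("AK8-DST", "pp_sv", c(`11452` = 1), "European"),
    list("LTBP1", "cautionary_pp_sv", c(`5287` = 5), "European"),
    list("PHC3-PRKACA", "cautionary_pp_sv", c(SMU061 = 3), "African"),
    list("KCTD3-DST", "cautionary_pp_sv", c(UP2039 = 4, SMU101 = 3),
         "African"),
    list("PKHD1", "cautionary_pp_sv", c(N0056 = 5, SMU196 = 1), "African"))
  carrier_ids <- unique(unlist(lapply(carrier_rows, function(r)
    names(r[[3]]))))
  carrier_gg <- unlist(lapply(carrier_rows, function(r) r[[3]]))
  carrier_gg <- carrier_gg[!duplicated(names(carrier_gg))]
  carrier_grp <- unlist(lapply(carrier_rows, function(r)
    stats::setNames(rep(r[[4]], length(r[[3]])), names(r[[3]]))))
  carrier_grp <- carrier_grp[!duplicated(names(carrier_grp))]

  # filler patients completing the grade-group distribution
  afr_carriers <- names(carrier_grp)[carrier_grp == "African"]   # 18
  eur_carriers <- names(carrier_grp)[carrier_grp == "European"]  # 5
  # African carriers: 7x GG5, 5x GG4, 4x GG3, 1x GG1, 1 unknown
  afr_fill_gg <- c(rep(5L, 40), rep(4L, 29), rep(3L, 8),
                   rep(2L, 10), rep(1L, 7), NA)   # 95 fillers
  # European carriers: 4x GG5, 1x GG1
  eur_fill_gg <- c(rep(5L, 20), rep(4L, 25), rep(2L, 4), rep(1L, 3)) # 52
  afr_fill <- sprintf("AFILL%03d", seq_along(afr_fill_gg))
  eur_fill <- sprintf("EFILL%03d", seq_along(eur_fill_gg))
  patients <- data.frame(
    patient_id = c(afr_carriers, afr_fill, eur_carriers, eur_fill),
    group = c(rep("African", length(afr_carriers) + length(afr_fill)),
              rep("European", length(eur_carriers) + length(eur_fill))),
    age = 65, psa = 20,
    isup_gg = c(unname(carrier_gg[afr_carriers]), afr_fill_gg,
                unname(carrier_gg[eur_carriers]), eur_fill_gg),
    family_history = "", stringsAsFactors = FALSE)

  calls <- data.frame(
    sv_id = vapply(carrier_rows, `[[`, "", 1),
    tier = vapply(carrier_rows, `[[`, "", 2),
    fusion = NA_character_, stringsAsFactors = FALSE)

  gt <- matrix(0L, length(carrier_rows), nrow(patients),
               dimnames = list(calls$sv_id, patients$patient_id))
  for (r in carrier_rows) gt[r[[1]], names(r[[3]])] <- 1L
  svs <- do.call(bind_svs, lapply(seq_along(carrier_rows), function(i)
    sv1(carrier_rows[[i]][[1]], "DEL", "chr1", 1000L + i * 10000L,
        2000L + i * 10000L)))
  gmatrix <- make_gmatrix(svs, gt,
                          stats::setNames(patients$group,
                                          patients$patient_id))
  list(patients = patients, calls = calls, gmatrix = gmatrix)
}

read_sv_catalog_empty <- function() {
  data.frame(catalog_id = character(), chrom1 = character(),
             pos1 = integer(), chrom2 = character(), pos2 = integer(),
             svtype = character(), significance = character(),
             population_af = character(), stringsAsFactors = FALSE)
}

# ---- shared reference bundle (built once per test run) ----------------

.ref_cache <- new.env(parent = emptyenv())

ref_bundle <- function() {
  if (is.null(.ref_cache$bundle))
    .ref_cache$bundle <- simulate_cohort(simulation_plan(seed = 42))
  .ref_cache$bundle
}

ref_pipeline <- function() {
  if (is.null(.ref_cache$pipeline)) {
    dir <- file.path(tempdir(), "svpath_ref_bundle")
    if (!dir.exists(dir)) write_sv_bundle(ref_bundle(), dir)
    .ref_cache$pipeline <- run_pipeline(
      pipeline_config(), dir, file.path(tempdir(), "svpath_ref_out"))
    .ref_cache$bundle_dir <- dir
  }
  .ref_cache$pipeline
}

ref_bundle_dir <- function() {
  invisible(ref_pipeline())
  .ref_cache$bundle_dir
}
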