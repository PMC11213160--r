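# Population-level genotype QC and ancestry-stratified allele frequencies.
#
# The QC order is fixed: site filters (FILTER = PASS and PASS_ratio >= 0.5)
# -> per-call masking (FT for simple types; GQ for breakend-derived INV/TRA)
# -> per-group missingness gate (<= 20% in BOTH groups) -> removal of fixed
# sites (overall AF = 1) -> allele frequencies from the surviving calls only.

#' Construct an SV genotype matrix
#'
#' @param sites an [sv_set] with additional columns `site_filter` (character,
#'   VCF FILTER) and `pass_ratio` (fraction of genotype calls flagged PASS)
#' @param gt integer matrix (sites x samples) of alternate-allele counts
#'   (0/1/2), NA = missing
#' @param ft character matrix of per-sample genotype filter tags
#' @param gq numeric matrix of genotype qualities
#' @param groups named character vector mapping sample -> ancestry group
#'   (e.g. "African"/"European"); may be set later with [set_sample_groups()]
#' @return an object of class `sv_genotype_matrix`
#' @export
sv_genotype_matrix <- function(sites, gt, ft, gq, groups = NULL) {
  stopifnot(nrow(gt) == nrow(sites),
            all(dim(gt) == dim(ft)), all(dim(gt) == dim(gq)))
  if (is.null(rownames(gt))) rownames(gt) <- sites$id
  rownames(ft) <- rownames(gq) <- rownames(gt)
  if (!is.null(groups)) {
    missing_grp <- setdiff(colnames(gt), names(groups))
    if (length(missing_grp))
      abort("samples without group label: %s",
            paste(missing_grp, collapse = ","))
  }
  structure(list(sites = sites, gt = gt, ft = ft, gq = gq,
                 groups = groups),
            class = "sv_genotype_matrix")
}

#' @export
print.sv_genotype_matrix <- function(x, ...) {
  cat(sprintf("<sv_genotype_matrix> %d sites x %d samples\n",
              nrow(x$gt), ncol(x$gt)))
  if (!is.null(x$groups))
    print(table(x$groups))
  invisible(x)
}

#' Attach ancestry group labels to samples
#'
#' @param matrix an `sv_genotype_matrix`
#' @param groups named character vector, sample id -> group
#' @return the matrix with groups set
#' @export
set_sample_groups <- function(matrix, groups) {
  sv_genotype_matrix(matrix$sites, matrix$gt, matrix$ft, matrix$gq,
                     groups = groups[colnames(matrix$gt)])
}

parse_gt_field <- function(gt) {
  alt <- ifelse(gt %in% c("0/0", "0|0"), 0L,
         ifelse(gt %in% c("0/1", "1/0", "0|1", "1|0"), 1L,
         ifelse(gt %in% c("1/1", "1|1"), 2L, NA_integer_)))
  alt
}

parse_genotyped_body <- function(body, samples, path) {
  n <- length(body)
  sites <- vector("list", n)
  gt <- matrix(NA_integer_, n, length(samples),
               dimnames = list(NULL, samples))
  ft <- matrix(NA_character_, n, length(samples),
               dimnames = list(NULL, samples))
  gq <- matrix(NA_real_, n, length(samples), dimnames = list(NULL, samples))
  for (i in seq_len(n)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    info <- parse_info(f[8])
    svtype <- info$SVTYPE %||% abort("%s line %d: missing SVTYPE", path, i)
    or <- orient_for_type(svtype)
    pos <- as.integer(f[2])
    sites[[i]] <- data.frame(
      id = f[3], chrom1 = f[1], pos1 = pos, orient1 = or[1],
      chrom2 = info$CHR2 %||% f[1],
      pos2 = if (svtype == "TRA") as.integer(info$END2)
             else if (svtype == "INS") pos else as.integer(info$END %||% pos),
      orient2 = or[2], svtype = svtype, caller = "genotyped",
      filter_pass = f[7] %in% c("PASS", "."), mate_id = NA_character_,
      insertion_seq = info$SVINSSEQ %||% NA_character_,
      site_filter = f[7],
      pass_ratio = if (is.null(info$PASS_ratio)) NA_real_
                   else as.numeric(info$PASS_ratio),
      stringsAsFactors = FALSE)
    if (length(samples) > 0) {
      keys <- strsplit(f[9], ":", fixed = TRUE)[[1]]
      for (s in seq_along(samples)) {
        vals <- strsplit(f[9 + s], ":", fixed = TRUE)[[1]]
        names(vals) <- keys[seq_along(vals)]
        gt[i, s] <- parse_gt_field(vals["GT"])
        ft[i, s] <- if ("FT" %in% names(vals)) vals[["FT"]] else NA_character_
        gq[i, s] <- if ("GQ" %in% names(vals)) suppressWarnings(
          as.numeric(vals[["GQ"]])) else NA_real_
      }
    }
  }
  sites <- as_sv_set(do.call(rbind, sites))
  rownames(gt) <- rownames(ft) <- rownames(gq) <- sites$id
  sv_genotype_matrix(sites, gt, ft, gq)
}

gt_string <- function(alt) {
  ifelse(is.na(alt), "./.", c("0/0", "0/1", "1/1")[alt + 1L])
}

#' Write a genotyped multi-sample SV VCF
#'
#' @param matrix an `sv_genotype_matrix`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_genotyped_vcf <- function(matrix, path) {
  samples <- colnames(matrix$gt)
  lines <- vcf_header_lines("genotyped", samples)
  for (i in seq_len(nrow(matrix$sites))) {
    r <- matrix$sites[i, ]
    alt <- paste0("<", r$svtype, ">")
    info <- format_info(
      SVTYPE = r$svtype,
      END = if (r$svtype %in% c("DEL", "DUP", "INV")) r$pos2 else NULL,
      CHR2 = if (r$svtype == "TRA") r$chrom2 else NULL,
      END2 = if (r$svtype == "TRA") r$pos2 else NULL,
      SVINSSEQ = r$insertion_seq,
      PASS_ratio = r$pass_ratio)
    geno <- sprintf("%s:%s:%d", gt_string(matrix$gt[i, ]),
                    ifelse(is.na(matrix$ft[i, ]), ".", matrix$ft[i, ]),
                    as.integer(ifelse(is.na(matrix$gq[i, ]), 0,
                                      matrix$gq[i, ])))
    lines <- c(lines, paste(c(r$chrom1, r$pos1, r$id, "N", alt, ".",
                              r$site_filter %||% "PASS", info, "GT:FT:GQ",
                              geno), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

subset_sites <- function(matrix, keep) {
  sv_genotype_matrix(matrix$sites[keep, , drop = FALSE],
                     matrix$gt[keep, , drop = FALSE],
                     matrix$ft[keep, , drop = FALSE],
                     matrix$gq[keep, , drop = FALSE],
                     matrix$groups)
}

#' Site-level QC filter
#'
#' Retains sites whose FILTER is PASS and whose `PASS_ratio` (fraction of
#' per-sample genotype calls flagged PASS) is at least `min_pass_ratio`.
#' Sites with no `pass_ratio` are dropped with a warning.
#'
#' @param matrix an `sv_genotype_matrix`
#' @param min_pass_ratio minimum PASS fraction (default 0.5)
#' @return the filtered matrix
#' @export
apply_site_filters <- function(matrix, min_pass_ratio = 0.5) {
  pr <- matrix$sites$pass_ratio
  if (any(is.na(pr)))
    warnf("%d site(s) without PASS_ratio dropped", sum(is.na(pr)))
  keep <- !is.na(pr) & pr >= min_pass_ratio &
    matrix$sites$site_filter %in% c("PASS", ".")
  subset_sites(matrix, keep)
}

#' Mask low-quality genotype calls
#'
#' For DEL/DUP/INS sites a call is set missing when its per-sample filter tag
#' (FT) is not PASS. Breakend-derived sites (INV and TRA, genotyped without an
#' FT tag) instead mask calls with genotype quality GQ < `min_gq`.
#'
#' @param matrix an `sv_genotype_matrix`
#' @param min_gq GQ threshold for breakend-derived sites (default 20)
#' @return the matrix with masked calls set to NA
#' @export
mask_low_quality_genotypes <- function(matrix, min_gq = 20) {
  bnd_derived <- matrix$sites$svtype %in% c("INV", "TRA")
  gt <- matrix$gt
  for (i in seq_len(nrow(gt))) {
    if (bnd_derived[i]) {
      bad <- is.na(matrix$gq[i, ]) | matrix$gq[i, ] < min_gq
    } else {
      bad <- is.na(matrix$ft[i, ]) | matrix$ft[i, ] != "PASS"
    }
    gt[i, bad] <- NA_integer_
  }
  sv_genotype_matrix(matrix$sites, gt, matrix$ft, matrix$gq, matrix$groups)
}

group_missingness <- function(matrix) {
  grp <- matrix$groups
  if (is.null(grp)) abort("sample groups not set; see set_sample_groups()")
  vapply(unique(grp), function(g) {
    cols <- names(grp)[grp == g]
    rowMeans(is.na(matrix$gt[, cols, drop = FALSE]))
  }, numeric(nrow(matrix$gt)))
}

#' Per-group missingness filter
#'
#' Drops sites whose genotype missingness exceeds `max_missing` in EITHER
#' ancestry group (a site must be well genotyped in both).
#'
#' @param matrix an `sv_genotype_matrix` with groups set, masking applied
#' @param max_missing maximum tolerated missingness per group (default 0.2)
#' @return the filtered matrix
#' @export
filter_missingness <- function(matrix, max_missing = 0.2) {
  miss <- group_missingness(matrix)
  if (nrow(matrix$gt) == 0) return(matrix)
  keep <- apply(miss <= max_missing, 1, all)
  subset_sites(matrix, keep)
}

#' Remove fixed sites
#'
#' Sites at overall alternate allele frequency 1 reflect divergence of the
#' cohort from the reference genome, not variation within the cohort.
#'
#' @param matrix an `sv_genotype_matrix`
#' @return the filtered matrix
#' @export
drop_fixed_sites <- function(matrix) {
  if (nrow(matrix$gt) == 0) return(matrix)
  ac <- rowSums(matrix$gt, na.rm = TRUE)
  an <- 2 * rowSums(!is.na(matrix$gt))
  keep <- !(an > 0 & ac == an)
  subset_sites(matrix, keep)
}

#' Ancestry-stratified allele frequencies
#'
#' AC/AN/AF/MAF per group plus overall, computed from non-missing calls only
#' (AN = 2 x non-missing calls; ploidy fixed at 2). MAF = min(AF, 1 - AF).
#' Frequencies are kept unrounded; `maf_display` columns give the 3-decimal
#' presentation used in reports.
#'
#' @param matrix an `sv_genotype_matrix` with all QC applied and groups set
#' @return data.frame with one row per site: per-group `ac_*`, `an_*`, `af_*`,
#'   `maf_*`, `tier_*` columns and overall `af`/`maf`/`tier`
#' @export
compute_frequencies <- function(matrix) {
  grp <- matrix$groups
  if (is.null(grp)) abort("sample groups not set; see set_sample_groups()")
  groups <- sort(unique(grp))
  out <- data.frame(id = matrix$sites$id, svtype = matrix$sites$svtype,
                    stringsAsFactors = FALSE)
  for (g in groups) {
    cols <- names(grp)[grp == g]
    sub <- matrix$gt[, cols, drop = FALSE]
    ac <- rowSums(sub, na.rm = TRUE)
    an <- 2 * rowSums(!is.na(sub))
    af <- ifelse(an > 0, ac / an, NA_real_)
    maf <- pmin(af, 1 - af)
    key <- tolower(g)
    out[[paste0("ac_", key)]] <- ac
    out[[paste0("an_", key)]] <- an
    out[[paste0("af_", key)]] <- af
    out[[paste0("maf_", key)]] <- maf
    out[[paste0("maf_display_", key)]] <- round_half_up(maf, 3)
    out[[paste0("tier_", key)]] <- frequency_tier(maf)
  }
  ac <- rowSums(matrix$gt, na.rm = TRUE)
  an <- 2 * rowSums(!is.na(matrix$gt))
  out$af <- ifelse(an > 0, ac / an, NA_real_)
  out$maf <- pmin(out$af, 1 - out$af)
  out$tier <- frequency_tier(out$maf)
  out
}

#' Frequency tier of a minor allele frequency
#'
#' rare: MAF < 1%; low_frequency: 1% <= MAF <= 5%; common: MAF > 5%. The
#' boundaries are closed into low_frequency because rare and common are
#' defined by strict inequalities.
#'
#' @param maf numeric vector of MAFs in `[0, 0.5]`
#' @return character vector of tiers
#' @export
frequency_tier <- function(maf) {
  ifelse(is.na(maf), NA_character_,
         ifelse(maf < 0.01, "rare",
                ifelse(maf <= 0.05, "low_frequency", "common")))
}
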