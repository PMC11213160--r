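# Cohort-level reporting: distinct-carrier summaries per pathogenicity tier
# and ancestry group, aggressiveness fractions (ISUP grade group >= 3), and
# germline-testing eligibility arithmetic.

REPORTABLE_TIERS <- list(
  clinvar = c("clinvar_pathogenic", "clinvar_likely_pathogenic"),
  pp_sv = "pp_sv",
  cautionary_pp_sv = "cautionary_pp_sv")

# summary rows: the three reportable tiers, the ClinVar-or-predicted union
# (the headline "patients presenting with a potentially pathogenic SV"),
# and the union of all three
summary_tiersets <- function() {
  c(REPORTABLE_TIERS,
    list(clinvar_or_pp = c(REPORTABLE_TIERS$clinvar, REPORTABLE_TIERS$pp_sv),
         any = unlist(REPORTABLE_TIERS, use.names = FALSE)))
}

#' Read a patient clinical table
#'
#' @param path TSV with columns `patient_id`, `group`, `age`, `psa`,
#'   `isup_gg` (1-5 or NA = unknown), `family_history`
#' @return data.frame
#' @export
read_clinical_table <- function(path) {
  df <- read_tsv_file(path)
  df$isup_gg <- suppressWarnings(as.integer(df$isup_gg))
  df
}

# sample ids carrying >= 1 alternate allele at any of the given sites
carriers_of <- function(gt, sv_ids) {
  sv_ids <- intersect(sv_ids, rownames(gt))
  if (length(sv_ids) == 0) return(character())
  sub <- gt[sv_ids, , drop = FALSE]
  colnames(sub)[colSums(sub >= 1, na.rm = TRUE) > 0]
}

tier_group_of <- function(tiers) {
  out <- rep(NA_character_, length(tiers))
  for (nm in names(REPORTABLE_TIERS))
    out[tiers %in% REPORTABLE_TIERS[[nm]]] <- nm
  out
}

#' Distinct-carrier summary per tier and ancestry group
#'
#' Counts distinct patients carrying at least one SV of each reportable tier
#' (ClinVar-verified, predicted PP-SV, cautionary PP-SV) plus the union of
#' all three (`any`), per ancestry group, with percentages of group size
#' (half-up, 1 decimal).
#'
#' @param calls pathogenicity call table ([classify_cohort()])
#' @param gmatrix post-QC `sv_genotype_matrix` (carriers are read from its
#'   genotypes)
#' @param patients clinical table ([read_clinical_table()])
#' @return data.frame: `tier`, `group`, `carriers`, `cohort`, `pct`
#' @export
carrier_summary <- function(calls, gmatrix, patients) {
  calls$tier_group <- tier_group_of(calls$tier)
  groups <- sort(unique(patients$group))
  unknown <- setdiff(colnames(gmatrix$gt), patients$patient_id)
  if (length(unknown))
    warnf("genotyped samples absent from clinical table: %s",
          paste(unknown, collapse = ","))
  tiersets <- summary_tiersets()
  rows <- list()
  for (nm in names(tiersets)) {
    ids <- calls$sv_id[calls$tier %in% tiersets[[nm]]]
    carr <- carriers_of(gmatrix$gt, ids)
    for (g in groups) {
      members <- patients$patient_id[patients$group == g]
      n <- length(intersect(carr, members))
      rows[[length(rows) + 1]] <- data.frame(
        tier = nm, group = g, carriers = n, cohort = length(members),
        pct = round_half_up(100 * n / max(1, length(members)), 1),
        stringsAsFactors = FALSE)
    }
  }
  rbind_rows(rows)
}

#' Aggressive-disease fraction among tier carriers
#'
#' High-risk or aggressive disease is defined as ISUP grade group >=
#' `gg_cut` (default 3). Carriers with unknown grade are excluded from the
#' default denominator and reported separately; `pct_all` gives the
#' alternative convention with all carriers in the denominator.
#'
#' @inheritParams carrier_summary
#' @param gg_cut grade-group cut for "aggressive" (default 3)
#' @return data.frame per tier: `n_carriers`, `n_known`, `n_aggressive`,
#'   `n_unknown`, `pct` (known-grade denominator), `pct_all`
#' @export
aggressive_fraction <- function(calls, gmatrix, patients, gg_cut = 3) {
  tiersets <- summary_tiersets()
  rows <- list()
  for (nm in names(tiersets)) {
    ids <- calls$sv_id[calls$tier %in% tiersets[[nm]]]
    carr <- carriers_of(gmatrix$gt, ids)
    gg <- patients$isup_gg[match(carr, patients$patient_id)]
    known <- !is.na(gg)
    n_agg <- sum(gg[known] >= gg_cut)
    rows[[length(rows) + 1]] <- data.frame(
      tier = nm, n_carriers = length(carr), n_known = sum(known),
      n_aggressive = n_agg, n_unknown = sum(!known),
      pct = if (sum(known) > 0)
        round_half_up(100 * n_agg / sum(known), 1) else NA_real_,
      pct_all = if (length(carr) > 0)
        round_half_up(100 * n_agg / length(carr), 1) else NA_real_,
      stringsAsFactors = FALSE)
  }
  rbind_rows(rows)
}

#' Germline-testing eligibility counts
#'
#' Eligibility by ISUP grade group under the standard rule (GG >= 4,
#' high-risk localized disease) and an extended rule (GG >= 3) proposed for
#' cohorts with elevated aggressive presentation. Percentages are rounded
#' half-up to the nearest integer.
#'
#' @param patients clinical table
#' @param rules named integer vector of GG cuts
#'   (default `c(standard = 4, extended = 3)`)
#' @return data.frame: `rule`, `group`, `eligible`, `total`, `pct`
#' @export
nccn_eligibility <- function(patients, rules = c(standard = 4, extended = 3)) {
  groups <- sort(unique(patients$group))
  rows <- list()
  for (r in names(rules)) {
    for (g in groups) {
      gg <- patients$isup_gg[patients$group == g]
      n <- sum(!is.na(gg) & gg >= rules[[r]])
      rows[[length(rows) + 1]] <- data.frame(
        rule = r, group = g, eligible = n, total = length(gg),
        pct = round_half_up(100 * n / max(1, length(gg)), 0),
        stringsAsFactors = FALSE)
    }
  }
  rbind_rows(rows)
}

#' Render cohort report tables
#'
#' Writes a candidate-SV table (gene, impact, coordinates, type, catalog
#' concordance, per-group MAFs), a per-carrier clinical table, and a
#' machine-readable JSON summary whose percentages are recomputed from their
#' own counts. Output is deterministic: rows are sorted on stable keys.
#'
#' @param calls pathogenicity call table
#' @param impacts impact annotation table
#' @param freqs frequency table
#' @param catalog_anns catalog annotation table
#' @param gmatrix post-QC `sv_genotype_matrix`
#' @param patients clinical table
#' @param dir output directory (created if needed)
#' @return named list of the three tables, invisibly; files
#'   `candidates.tsv`, `carriers.tsv`, `summary.json` under `dir`
#' @export
render_tables <- function(calls, impacts, freqs, catalog_anns, gmatrix,
                          patients, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  calls$tier_group <- tier_group_of(calls$tier)
  rep_calls <- calls[!is.na(calls$tier_group), , drop = FALSE]
  rep_calls <- rep_calls[order(match(rep_calls$tier, PATHOGENICITY_TIERS),
                               rep_calls$sv_id), , drop = FALSE]
  sites <- gmatrix$sites
  maf_cols <- grep("^maf_display_", names(freqs), value = TRUE)
  t1 <- lapply(seq_len(nrow(rep_calls)), function(i) {
    id <- rep_calls$sv_id[i]
    s <- sites[sites$id == id, , drop = FALSE]
    f <- freqs[freqs$id == id, , drop = FALSE]
    ca <- catalog_anns[catalog_anns$sv_id == id, , drop = FALSE]
    imp <- impacts[impacts$sv_id == id & impacts$category %in%
                     GENE_DISRUPTIVE, , drop = FALSE]
    row <- data.frame(
      genes = if (!is.na(rep_calls$fusion[i])) rep_calls$fusion[i]
              else paste(sort(unique(imp$gene_name)), collapse = "/"),
      impact = paste(sort(unique(imp$category)), collapse = "/"),
      chrom1 = s$chrom1, pos1 = s$pos1, chrom2 = s$chrom2, pos2 = s$pos2,
      svtype = s$svtype, tier = rep_calls$tier[i],
      catalog = if (nrow(ca) == 0 || ca$novel) "novel"
                else if (ca$significance != "none") ca$significance
                else "in_catalog",
      catalog_max_af = if (nrow(ca)) ca$max_af else NA_real_,
      stringsAsFactors = FALSE)
    for (mc in maf_cols) row[[sub("_display", "", mc)]] <- f[[mc]]
    row
  })
  t1 <- if (length(t1)) do.call(rbind, c(t1, list(make.row.names = FALSE)))
        else data.frame()

  t2 <- lapply(seq_len(nrow(rep_calls)), function(i) {
    id <- rep_calls$sv_id[i]
    carr <- sort(carriers_of(gmatrix$gt, id))
    if (length(carr) == 0) return(NULL)
    p <- patients[match(carr, patients$patient_id), , drop = FALSE]
    imp <- impacts[impacts$sv_id == id & impacts$category %in%
                     GENE_DISRUPTIVE, , drop = FALSE]
    s <- sites[sites$id == id, , drop = FALSE]
    data.frame(
      gene = if (!is.na(rep_calls$fusion[i])) rep_calls$fusion[i]
             else paste(sort(unique(imp$gene_name)), collapse = "/"),
      tier = rep_calls$tier[i], svtype = s$svtype, sv_id = id,
      patient_id = carr, group = p$group, age = p$age, psa = p$psa,
      isup_gg = p$isup_gg, stringsAsFactors = FALSE)
  })
  t2 <- t2[!vapply(t2, is.null, TRUE)]
  t2 <- if (length(t2)) do.call(rbind, c(t2, list(make.row.names = FALSE)))
        else data.frame()

  summary <- list(
    carriers = carrier_summary(calls, gmatrix, patients),
    aggressive = aggressive_fraction(calls, gmatrix, patients),
    eligibility = nccn_eligibility(patients),
    tier_counts = as.list(table(calls$tier)))
  # internal consistency: every printed percentage recomputes from counts
  stopifnot(all(summary$carriers$pct ==
                  round_half_up(100 * summary$carriers$carriers /
                                  pmax(1, summary$carriers$cohort), 1)))
  write_tsv_file(t1, file.path(dir, "candidates.tsv"))
  write_tsv_file(t2, file.path(dir, "carriers.tsv"))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  invisible(list(candidates = t1, carriers = t2, summary = summary))
}
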