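# Consensus pathogenicity cascade. A gene-disruptive SV (pLoF/CG/IED) is a
# pathogenicity candidate when at least two of four impact-prediction tools
# score it at or above their thresholds (StrVCTVRE >= 0.37, CADD-SV >= 10,
# POSTRE >= 0.8, PhenoSV >= 0.5), with disrupted genes required in at least
# two of three cancer gene sets. ClinVar pathogenic/likely-pathogenic (or
# benign) catalog matches short-circuit the score consensus; rarity gates and
# a curated gene-role gate decide the final tier.

DEFAULT_SCORE_THRESHOLDS <- c(strvctvre = 0.37, cadd_sv = 10,
                              postre = 0.8, phenosv = 0.5)

PATHOGENICITY_TIERS <- c("clinvar_pathogenic", "clinvar_likely_pathogenic",
                         "pp_sv", "cautionary_pp_sv", "unlikely",
                         "excluded_benign", "excluded_common",
                         "excluded_catalog_af", "excluded_no_consensus",
                         "excluded_no_cancer_support", "not_gene_disruptive")

#' Read per-SV pathogenicity score panels
#'
#' Absent scores are legal and reflect each tool's SV-type coverage:
#' StrVCTVRE scores only exon-overlapping DEL/DUP, CADD-SV scores DEL/DUP/INS,
#' POSTRE scores DEL/DUP/INV/TRA, PhenoSV scores all five types.
#'
#' @param path TSV with columns `sv_id`, `strvctvre`, `cadd_sv`, `postre`,
#'   `phenosv` (NA = not scored)
#' @return data.frame of score panels
#' @export
read_score_panel <- function(path) {
  df <- read_tsv_file(path)
  for (col in names(DEFAULT_SCORE_THRESHOLDS))
    df[[col]] <- as.numeric(df[[col]])
  df
}

#' Tools whose score passes its threshold
#'
#' A tool passes iff its score is present and `>=` its threshold; absent
#' scores never pass (they are not imputed).
#'
#' @param panel one-row data.frame (or named list) of scores
#' @param thresholds named numeric vector of per-tool thresholds
#' @return character vector of passing tool names
#' @export
tools_passed <- function(panel, thresholds = DEFAULT_SCORE_THRESHOLDS) {
  passed <- character()
  for (tool in names(thresholds)) {
    s <- panel[[tool]]
    if (!is.null(s) && length(s) == 1 && !is.na(s) && s >= thresholds[[tool]])
      passed <- c(passed, tool)
  }
  passed
}

#' Consensus candidacy: at least `k` of the four tools pass
#'
#' @inheritParams tools_passed
#' @param k minimum number of passing tools (default 2)
#' @return logical
#' @export
is_candidate <- function(panel, thresholds = DEFAULT_SCORE_THRESHOLDS,
                         k = 2) {
  length(tools_passed(panel, thresholds)) >= k
}

#' Read cancer gene sets
#'
#' Accepts either one-gene-per-line set files (named by file) or GMT lines
#' (set name, description, genes, tab-separated).
#'
#' @param paths named character vector of file paths; names become set names
#' @return named list of character vectors
#' @export
read_gene_sets <- function(paths) {
  out <- list()
  for (nm in names(paths)) {
    lines <- readLines(paths[[nm]])
    lines <- lines[nzchar(lines)]
    if (any(grepl("\t", lines))) { # GMT
      for (l in lines) {
        f <- strsplit(l, "\t", fixed = TRUE)[[1]]
        out[[f[1]]] <- f[-(1:2)]
      }
    } else {
      out[[nm]] <- lines
    }
  }
  out
}

#' Cancer gene-set support for an SV's disrupted genes
#'
#' A set is hit when ANY disrupted gene (fusion partners included) is a
#' member; support requires hits in at least `k` sets.
#'
#' @param genes character vector of disrupted gene names/ids
#' @param genesets named list of gene sets (hallmark, oncogenic signatures,
#'   COSMIC CGC)
#' @param k minimum number of sets (default 2)
#' @return list with `n_sets` hit count, `sets` names hit, and `supported`
#' @export
cancer_gene_support <- function(genes, genesets, k = 2) {
  hit <- vapply(genesets, function(s) any(genes %in% s), TRUE)
  list(n_sets = sum(hit), sets = names(genesets)[hit],
       supported = sum(hit) >= k)
}

#' Read a gene-role curation table
#'
#' @param path TSV with columns `gene_id`, `role` (tumour_suppressor,
#'   oncogene, conflicting, unclear) and optional `note`
#' @return data.frame
#' @export
read_gene_curation <- function(path) {
  read_tsv_file(path)
}

# role lookup with missing genes treated as unclear (warning)
curated_roles <- function(genes, curation) {
  roles <- curation$role[match(genes, curation$gene_id)]
  if (any(is.na(roles))) {
    warnf("gene(s) missing from curation table treated as unclear: %s",
          paste(genes[is.na(roles)], collapse = ","))
    roles[is.na(roles)] <- "unclear"
  }
  stats::setNames(roles, genes)
}

# Curation gate over the disruptive (category, gene-role) pairs of one SV.
# Mixed tumour_suppressor + oncogene involvement, or any unclear/conflicting
# role, yields a cautionary call; otherwise a consistent pathogenic
# mechanism (pLoF of a tumour suppressor, dosage gain of an oncogene) gives
# pp_sv and the opposite mechanism gives unlikely.
curation_gate <- function(categories, roles) {
  stopifnot(length(categories) == length(roles))
  if ("tumour_suppressor" %in% roles && "oncogene" %in% roles)
    return("cautionary_pp_sv")
  if (any(roles %in% c("unclear", "conflicting")))
    return("cautionary_pp_sv")
  pp <- (categories == "pLoF" & roles == "tumour_suppressor") |
    (categories %in% c("CG", "IED") & roles == "oncogene")
  if (any(pp)) "pp_sv" else "unlikely"
}

#' Classify one SV through the pathogenicity cascade
#'
#' First rule wins: (1) not gene-disruptive; (2) common (MAF > 5% in a
#' group); (3) ClinVar tiering (pathogenic/likely-pathogenic accepted,
#' benign/likely-benign excluded; uncertain falls through); (4) score
#' consensus; (5) cancer gene-set support; (6) rarity (MAF >= 1% in either
#' group) and catalog AF exclusion; (7) curated gene-role gate.
#'
#' @param sv_id SV identifier
#' @param impacts impact annotations for this SV (rows of
#'   [annotate_impacts()] output)
#' @param freq one row of [compute_frequencies()] output (or NULL)
#' @param catalog_ann one row of [annotate_catalog()] output (or NULL =
#'   novel)
#' @param panel one-row score panel (or NULL = unscored)
#' @param genesets named list of cancer gene sets
#' @param curation gene-role curation table
#' @param thresholds per-tool score thresholds
#' @param consensus_k tools required (default 2)
#' @param geneset_k gene sets required (default 2)
#' @param maf_common common-SV cutoff (default 0.05)
#' @param maf_rare rare-SV cutoff (default 0.01)
#' @param catalog_max_af catalog AF exclusion threshold (default 0.01)
#' @return one-row data.frame: `sv_id`, `tier`, and the evidence trail
#'   (`tools_passed`, `n_tools`, `genesets_hit`, `n_genesets`, per-group
#'   MAFs, catalog significance and AF, disrupted genes, roles, fusion)
#' @export
classify_pathogenicity <- function(sv_id, impacts, freq, catalog_ann, panel,
                                   genesets, curation,
                                   thresholds = DEFAULT_SCORE_THRESHOLDS,
                                   consensus_k = 2, geneset_k = 2,
                                   maf_common = 0.05, maf_rare = 0.01,
                                   catalog_max_af = 0.01) {
  disruptive <- impacts[!is.na(impacts$category) &
                          impacts$category %in% GENE_DISRUPTIVE, ,
                        drop = FALSE]
  fusion <- NA_character_
  if (nrow(disruptive) > 0) {
    fp <- disruptive$fusion_partner[!is.na(disruptive$fusion_partner)]
    if (length(fp)) fusion <- fp[1]
  }
  genes <- unique(disruptive$gene_name)
  mafs <- if (is.null(freq)) numeric() else
    unlist(freq[grepl("^maf_[^d]", names(freq))])
  mafs <- mafs[!is.na(mafs)]
  tools <- tools_passed(panel %||% list(), thresholds)
  support <- cancer_gene_support(genes, genesets, geneset_k)
  sig <- if (is.null(catalog_ann)) "none" else catalog_ann$significance
  evidence <- data.frame(
    sv_id = sv_id, tier = NA_character_,
    tools_passed = paste(tools, collapse = ","), n_tools = length(tools),
    genesets_hit = paste(support$sets, collapse = ","),
    n_genesets = support$n_sets,
    maf_max_group = if (length(mafs)) max(mafs) else NA_real_,
    catalog_significance = sig,
    catalog_max_af = if (is.null(catalog_ann)) NA_real_ else
      catalog_ann$max_af,
    genes = paste(genes, collapse = ","),
    roles = "", fusion = fusion, stringsAsFactors = FALSE)
  finish <- function(tier) { evidence$tier <- tier; evidence }

  if (nrow(disruptive) == 0) return(finish("not_gene_disruptive"))
  if (length(mafs) && any(mafs > maf_common)) return(finish("excluded_common"))
  if (sig %in% c("pathogenic", "likely_pathogenic"))
    return(finish(paste0("clinvar_", sig)))
  if (sig %in% c("benign", "likely_benign"))
    return(finish("excluded_benign"))
  if (length(tools) < consensus_k) return(finish("excluded_no_consensus"))
  if (!support$supported) return(finish("excluded_no_cancer_support"))
  if (length(mafs) && any(mafs >= maf_rare)) return(finish("excluded_common"))
  if (!is.null(catalog_ann) && isTRUE(catalog_ann$af_excluded))
    return(finish("excluded_catalog_af"))
  roles <- curated_roles(disruptive$gene_name, curation)
  evidence$roles <- paste(sprintf("%s=%s", names(roles), roles),
                          collapse = ",")
  finish(curation_gate(disruptive$category, roles))
}

#' Classify every SV of a cohort
#'
#' @param sv_ids character vector of SV ids to classify
#' @param impacts full impact annotation table
#' @param freqs full frequency table ([compute_frequencies()])
#' @param catalog_anns full catalog annotation table ([annotate_catalog()])
#' @param panels score panel table
#' @param genesets named list of cancer gene sets
#' @param curation gene-role curation table
#' @param ... tuning parameters passed to [classify_pathogenicity()]
#' @return data.frame of pathogenicity calls, one row per SV
#' @export
classify_cohort <- function(sv_ids, impacts, freqs, catalog_anns, panels,
                            genesets, curation, ...) {
  if (length(sv_ids) == 0)
    return(data.frame(sv_id = character(), tier = character(),
                      tools_passed = character(), n_tools = integer(),
                      genesets_hit = character(), n_genesets = integer(),
                      maf_max_group = numeric(),
                      catalog_significance = character(),
                      catalog_max_af = numeric(), genes = character(),
                      roles = character(), fusion = character(),
                      stringsAsFactors = FALSE))
  out <- lapply(sv_ids, function(id) {
    classify_pathogenicity(
      id,
      impacts = impacts[impacts$sv_id == id, , drop = FALSE],
      freq = if (id %in% freqs$id) freqs[freqs$id == id, , drop = FALSE]
             else NULL,
      catalog_ann = if (id %in% catalog_anns$sv_id)
        catalog_anns[catalog_anns$sv_id == id, , drop = FALSE] else NULL,
      panel = if (id %in% panels$sv_id)
        panels[panels$sv_id == id, , drop = FALSE] else NULL,
      genesets = genesets, curation = curation, ...)
  })
  rbind_rows(out)
}
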