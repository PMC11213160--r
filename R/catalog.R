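# Matching against a dbVar/ClinVar-style SV catalog. A cohort SV matches a
# catalog entry when type and chromosome pair agree and both breakpoints lie
# within 200 bases of the catalog breakpoints; unmatched SVs are novel.

CLINVAR_SEVERITY <- c("pathogenic", "likely_pathogenic", "uncertain",
                      "likely_benign", "benign")

#' Read an SV catalog table
#'
#' @param path TSV with columns `catalog_id`, `chrom1`, `pos1`, `chrom2`,
#'   `pos2`, `svtype`, `significance` (one of pathogenic, likely_pathogenic,
#'   uncertain, likely_benign, benign, none) and `population_af`
#'   (semicolon-separated `population:af` pairs, or empty)
#' @return data.frame of catalog entries
#' @export
read_sv_catalog <- function(path) {
  df <- read_tsv_file(path)
  df$pos1 <- as.integer(df$pos1)
  df$pos2 <- as.integer(df$pos2)
  df$significance[is.na(df$significance)] <- "none"
  df
}

#' Write an SV catalog table
#' @param catalog data.frame as in [read_sv_catalog()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sv_catalog <- function(catalog, path) {
  write_tsv_file(catalog, path)
}

parse_population_af <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric())
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  stats::setNames(vapply(kv, function(p) as.numeric(p[2]), 0),
                  vapply(kv, `[`, "", 1))
}

#' Match one SV against the catalog
#'
#' @param sv a one-row canonical [sv_set]
#' @param catalog catalog data.frame
#' @param window per-breakpoint distance bound in bases (default 200)
#' @return the matching catalog rows (zero rows = novel)
#' @export
match_catalog <- function(sv, catalog, window = 200) {
  same <- catalog$svtype == sv$svtype
  if (sv$svtype == "TRA") {
    fwd <- same & catalog$chrom1 == sv$chrom1 & catalog$chrom2 == sv$chrom2 &
      abs(catalog$pos1 - sv$pos1) <= window &
      abs(catalog$pos2 - sv$pos2) <= window
    rev <- same & catalog$chrom1 == sv$chrom2 & catalog$chrom2 == sv$chrom1 &
      abs(catalog$pos1 - sv$pos2) <= window &
      abs(catalog$pos2 - sv$pos1) <= window
    hit <- fwd | rev
  } else if (sv$svtype == "INS") {
    hit <- same & catalog$chrom1 == sv$chrom1 &
      abs(catalog$pos1 - sv$pos1) <= window
  } else {
    hit <- same & catalog$chrom1 == sv$chrom1 &
      abs(catalog$pos1 - sv$pos1) <= window &
      abs(catalog$pos2 - sv$pos2) <= window
  }
  catalog[hit, , drop = FALSE]
}

#' Most severe ClinVar significance among catalog matches
#'
#' Severity order: pathogenic > likely_pathogenic > uncertain >
#' likely_benign > benign. Returns `"none"` for novel or unannotated SVs.
#'
#' @param matches catalog rows from [match_catalog()]
#' @return a single significance string
#' @export
clinvar_tier <- function(matches) {
  sig <- matches$significance[matches$significance %in% CLINVAR_SEVERITY]
  if (length(sig) == 0) return("none")
  CLINVAR_SEVERITY[min(match(sig, CLINVAR_SEVERITY))]
}

#' Catalog frequency exclusion
#'
#' TRUE when any reported population AF among the matches reaches `max_af`
#' (default 0.01): an SV already seen at such frequencies in population
#' catalogs is not a rare pathogenic candidate.
#'
#' @param matches catalog rows from [match_catalog()]
#' @param max_af exclusion threshold (default 0.01)
#' @return logical
#' @export
catalog_frequency_exclusion <- function(matches, max_af = 0.01) {
  afs <- unlist(lapply(matches$population_af, parse_population_af))
  length(afs) > 0 && any(afs >= max_af)
}

#' Annotate a set of SVs against the catalog
#'
#' @param svs an [sv_set]
#' @param catalog catalog data.frame
#' @param window matching window (default 200)
#' @param max_af catalog AF exclusion threshold (default 0.01)
#' @return data.frame: `sv_id`, `matched_ids`, `significance`, `max_af`
#'   (NA when no AFs reported), `af_excluded`, `novel`
#' @export
annotate_catalog <- function(svs, catalog, window = 200, max_af = 0.01) {
  if (nrow(svs) == 0)
    return(data.frame(sv_id = character(), matched_ids = character(),
                      significance = character(), max_af = numeric(),
                      af_excluded = logical(), novel = logical(),
                      stringsAsFactors = FALSE))
  out <- lapply(seq_len(nrow(svs)), function(i) {
    m <- match_catalog(svs[i, ], catalog, window)
    afs <- unlist(lapply(m$population_af, parse_population_af))
    data.frame(sv_id = svs$id[i],
               matched_ids = paste(m$catalog_id, collapse = ","),
               significance = clinvar_tier(m),
               max_af = if (length(afs)) max(afs) else NA_real_,
               af_excluded = catalog_frequency_exclusion(m, max_af),
               novel = nrow(m) == 0,
               stringsAsFactors = FALSE)
  })
  rbind_rows(out)
}
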