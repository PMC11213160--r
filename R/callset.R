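# Dual-caller callset integration. Two calls are concordant when they have
# the same SV type, the same chromosome pair, both breakpoints within the
# matching window (default 200 bp) of each other, and at least one of the two
# records passed its caller's filters. Matching is one-to-one: among the
# candidates satisfying the rule, the pair with the smallest total breakpoint
# distance wins, ties broken by record id order.

# Candidate pair table for two sv_sets. INS records are matched on their
# single locus (bp1) only. TRA records must share the ordered chromosome
# pair; a reciprocal (swapped-mate) comparison is also tried so both caller
# representations of the same junction can match.
candidate_pairs <- function(manta, gridss, window) {
  out <- list()
  for (i in seq_len(nrow(manta))) {
    a <- manta[i, ]
    same_type <- gridss$svtype == a$svtype
    if (!any(same_type)) next
    for (j in which(same_type)) {
      b <- gridss[j, ]
      if (!(a$filter_pass || b$filter_pass)) next
      if (a$svtype == "TRA") {
        d_fwd <- if (a$chrom1 == b$chrom1 && a$chrom2 == b$chrom2)
          c(abs(a$pos1 - b$pos1), abs(a$pos2 - b$pos2)) else NULL
        d_rev <- if (a$chrom1 == b$chrom2 && a$chrom2 == b$chrom1)
          c(abs(a$pos1 - b$pos2), abs(a$pos2 - b$pos1)) else NULL
        d <- NULL
        for (cand in list(d_fwd, d_rev))
          if (!is.null(cand) && all(cand <= window) &&
              (is.null(d) || sum(cand) < sum(d))) d <- cand
        if (is.null(d)) next
      } else if (a$svtype == "INS") {
        if (a$chrom1 != b$chrom1) next
        d1 <- abs(a$pos1 - b$pos1)
        if (d1 > window) next
        d <- c(d1, d1)
      } else {
        if (a$chrom1 != b$chrom1) next
        d <- c(abs(a$pos1 - b$pos1), abs(a$pos2 - b$pos2))
        if (any(d > window)) next
      }
      out[[length(out) + 1]] <- data.frame(
        mi = i, gi = j, manta_id = a$id, gridss_id = b$id,
        svtype = a$svtype, bp1_dist = d[1], bp2_dist = d[2],
        manta_pass = a$filter_pass, gridss_pass = b$filter_pass,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_concordance())
  do.call(rbind, out)
}

empty_concordance <- function() {
  data.frame(mi = integer(), gi = integer(), manta_id = character(),
             gridss_id = character(), svtype = character(),
             bp1_dist = integer(), bp2_dist = integer(),
             manta_pass = logical(), gridss_pass = logical(),
             stringsAsFactors = FALSE)
}

#' Match two SV callsets under the breakpoint concordance rule
#'
#' @param manta,gridss canonicalized [sv_set]s from the two callers
#' @param window maximum per-breakpoint distance in bases (default 200)
#' @return data.frame of concordant calls (`manta_id`, `gridss_id`, `svtype`,
#'   `bp1_dist`, `bp2_dist`, per-caller PASS flags); attribute
#'   `"manta_records"` carries the matched Manta-side records (the
#'   representation forwarded to genotyping)
#' @export
match_callsets <- function(manta, gridss, window = 200) {
  cand <- candidate_pairs(manta, gridss, window)
  # greedy one-to-one assignment: smallest total distance first
  ord <- order(cand$bp1_dist + cand$bp2_dist, cand$manta_id, cand$gridss_id)
  cand <- cand[ord, , drop = FALSE]
  used_m <- logical(nrow(manta)); used_g <- logical(nrow(gridss))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (used_m[cand$mi[k]] || used_g[cand$gi[k]]) next
    keep[k] <- TRUE
    used_m[cand$mi[k]] <- TRUE
    used_g[cand$gi[k]] <- TRUE
  }
  res <- cand[keep, , drop = FALSE]
  res <- res[order(res$mi), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "manta_records") <- manta[res$mi, , drop = FALSE]
  res
}

#' Concordance summary counts
#'
#' @inheritParams match_callsets
#' @return list with `matched`, `manta_only`, `gridss_only` counts (so that
#'   `matched + manta_only == nrow(manta)` and likewise for gridss)
#' @export
concordant_fraction <- function(manta, gridss, window = 200) {
  m <- match_callsets(manta, gridss, window)
  list(matched = nrow(m),
       manta_only = nrow(manta) - nrow(m),
       gridss_only = nrow(gridss) - nrow(m))
}

#' High-confidence per-sample SV set
#'
#' The Manta-side representation of each concordant call (exact breakpoint
#' sequence detail is needed downstream by the population genotyper).
#'
#' @inheritParams match_callsets
#' @return an [sv_set]
#' @export
concordant_svs <- function(manta, gridss, window = 200) {
  m <- match_callsets(manta, gridss, window)
  recs <- attr(m, "manta_records")
  rownames(recs) <- NULL
  as_sv_set(recs)
}
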