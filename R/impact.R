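# Gene-impact classification. Each retained SV is classified against every
# candidate gene into one category of the taxonomy used by gnomAD-style SV
# annotation: pLoF, CG (copy gain), IED (intragenic exon duplication),
# partial_gene_DUP, partial_exon_DUP, whole_gene_INV, UTR, promoter,
# intronic, enhancer, intergenic. Gene-body rules take precedence over
# regulatory rules, which take precedence over intergenic.

GENE_DISRUPTIVE <- c("pLoF", "CG", "IED")

# total overlap (in bases) between [p1,p2] and a set of intervals
interval_overlap_bases <- function(p1, p2, starts, ends) {
  if (length(starts) == 0) return(0L)
  o <- pmin(p2, ends) - pmax(p1, starts) + 1L
  sum(pmax(0L, o))
}

point_in <- function(p, starts, ends) {
  any(p >= starts & p <= ends)
}

#' Candidate genes for an SV
#'
#' For SVs with a defined span up to `max_span`, every gene whose body
#' intersects the span is a candidate. For larger SVs — where short-read
#' evidence only supports the breakpoints — and for translocations, only
#' genes containing a breakpoint are considered.
#'
#' @param sv a one-row [sv_set]
#' @param models a [transcript_models] object
#' @param max_span span cutoff in bases (default 1e6)
#' @return character vector of gene ids
#' @export
candidate_genes <- function(sv, models, max_span = 1e6) {
  g <- models$genes
  bp_genes <- unique(c(
    g$gene_id[g$chrom == sv$chrom1 & g$start <= sv$pos1 & sv$pos1 <= g$end],
    g$gene_id[g$chrom == sv$chrom2 & g$start <= sv$pos2 & sv$pos2 <= g$end]))
  if (sv$svtype == "TRA") return(bp_genes)
  if (sv$svtype == "INS")
    return(g$gene_id[g$chrom == sv$chrom1 & g$start <= sv$pos1 &
                       sv$pos1 <= g$end])
  span <- sv$pos2 - sv$pos1
  if (span > max_span) return(bp_genes)
  g$gene_id[g$chrom == sv$chrom1 & g$start <= sv$pos2 & g$end >= sv$pos1]
}

# Gene-body category for one (sv, gene) pair, or NA if no gene-body rule
# fires. Returns list(category, evidence).
gene_body_category <- function(sv, gene_id, models) {
  g <- models$genes[models$genes$gene_id == gene_id, ]
  ex <- models$exons[models$exons$gene_id == gene_id, , drop = FALSE]
  cd <- models$cds[models$cds$gene_id == gene_id, , drop = FALSE]
  none <- list(category = NA_character_, evidence = NA_character_)
  in1 <- sv$chrom1 == g$chrom && g$start <= sv$pos1 && sv$pos1 <= g$end
  in2 <- sv$chrom2 == g$chrom && g$start <= sv$pos2 && sv$pos2 <= g$end
  if (sv$svtype %in% c("TRA", "BND")) {
    if (in1 || in2)
      return(list(category = "pLoF", evidence = "breakpoint in gene body"))
    return(none)
  }
  if (sv$chrom1 != g$chrom) return(none)
  p1 <- sv$pos1; p2 <- sv$pos2
  if (sv$svtype == "DEL") {
    cds_bases <- interval_overlap_bases(p1, p2, cd$start, cd$end)
    if (cds_bases > 0)
      return(list(category = "pLoF",
                  evidence = sprintf("removes %d CDS bases", cds_bases)))
    utr_bases <- interval_overlap_bases(p1, p2, ex$start, ex$end)
    if (utr_bases > 0)
      return(list(category = "UTR",
                  evidence = sprintf("removes %d UTR exon bases", utr_bases)))
    if (nrow(ex) > 1) {
      intron_start <- ex$end[-nrow(ex)] + 1L
      intron_end <- ex$start[-1] - 1L
      inside <- p1 >= intron_start & p2 <= intron_end
      if (any(inside))
        return(list(category = "intronic",
                    evidence = "fully inside one intron"))
    }
    return(none)
  }
  if (sv$svtype == "DUP") {
    gene_inside <- p1 < g$start && g$end < p2
    if (!in1 && !in2 && gene_inside)
      return(list(category = "CG", evidence = "gene fully duplicated"))
    if (in1 && in2) {
      if (point_in(p1, ex$start, ex$end) && point_in(p2, ex$start, ex$end))
        return(list(category = "pLoF",
                    evidence = "both breakpoints inside exons"))
      whole_exon <- any(ex$start > p1 & ex$end < p2)
      if (whole_exon)
        return(list(category = "IED",
                    evidence = "whole exon(s) fully duplicated within gene"))
      return(list(category = "partial_exon_DUP",
                  evidence = "intragenic, no whole exon duplicated"))
    }
    if (in1 || in2)
      return(list(category = "partial_gene_DUP",
                  evidence = "one breakpoint inside gene"))
    return(none)
  }
  if (sv$svtype == "INV") {
    gene_inside <- p1 < g$start && g$end < p2
    if (!in1 && !in2 && gene_inside)
      return(list(category = "whole_gene_INV",
                  evidence = "gene fully inverted, breakpoints outside"))
    if (in1 || in2)
      return(list(category = "pLoF", evidence = "breakpoint in gene body"))
    return(none)
  }
  if (sv$svtype == "INS") {
    if (!in1) return(none)
    if (point_in(p1, cd$start, cd$end))
      return(list(category = "pLoF", evidence = "insertion inside CDS"))
    if (point_in(p1, ex$start, ex$end))
      return(list(category = "UTR", evidence = "insertion inside UTR exon"))
    return(list(category = "intronic", evidence = "insertion inside intron"))
  }
  none
}

#' Classify the impact of one SV on one gene
#'
#' Applies the gene-body decision table first; if no gene-body rule fires,
#' falls back to promoter, then enhancer, then intergenic.
#'
#' @param sv a one-row [sv_set]
#' @param gene_id gene to classify against
#' @param models a [transcript_models] object
#' @param enhancers optional enhancer data.frame (see [read_enhancer_bed()])
#' @param promoter_size promoter window width (default 1000)
#' @return character category
#' @export
classify_impact <- function(sv, gene_id, models, enhancers = NULL,
                            promoter_size = 1000) {
  gb <- gene_body_category(sv, gene_id, models)
  if (!is.na(gb$category)) return(gb$category)
  prom <- promoter_windows(models, promoter_size)
  pr <- prom[prom$gene_id == gene_id, ]
  bp_hits <- function(tbl) {
    any(tbl$chrom == sv$chrom1 & tbl$start <= sv$pos1 & sv$pos1 <= tbl$end) ||
      any(tbl$chrom == sv$chrom2 & tbl$start <= sv$pos2 & sv$pos2 <= tbl$end)
  }
  if (nrow(pr) > 0 && bp_hits(pr)) return("promoter")
  if (!is.null(enhancers)) {
    en <- enhancers[enhancers$gene_id == gene_id, , drop = FALSE]
    if (nrow(en) > 0 && bp_hits(en)) return("enhancer")
  }
  "intergenic"
}

#' Annotate a set of SVs against transcript models
#'
#' One annotation per (SV, gene): gene-body categories for all candidate
#' genes; for SVs (and genes) without a gene-body hit, promoter and enhancer
#' annotations keyed on breakpoint containment; SVs hitting nothing get a
#' single intergenic row. Translocation pLoF annotations carry the fusion
#' partner when both breakpoints land in (distinct) genes.
#'
#' @param svs an [sv_set]
#' @param models a [transcript_models] object
#' @param enhancers optional enhancer table
#' @param max_span breakpoint-only restriction threshold (default 1e6)
#' @param promoter_size promoter window width (default 1000)
#' @return data.frame: `sv_id`, `gene_id`, `gene_name`, `category`,
#'   `fusion_partner`, `evidence`
#' @export
annotate_impacts <- function(svs, models, enhancers = NULL, max_span = 1e6,
                             promoter_size = 1000) {
  prom <- promoter_windows(models, promoter_size)
  gname <- stats::setNames(models$genes$gene_name, models$genes$gene_id)
  rows <- list()
  add <- function(sv_id, gene_id, category, evidence,
                  fusion = NA_character_) {
    rows[[length(rows) + 1]] <<- data.frame(
      sv_id = sv_id, gene_id = gene_id,
      gene_name = if (is.na(gene_id)) NA_character_ else
        unname(gname[gene_id]),
      category = category, fusion_partner = fusion, evidence = evidence,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(svs))) {
    sv <- svs[i, ]
    cands <- candidate_genes(sv, models, max_span)
    fusion <- if (sv$svtype == "TRA") annotate_fusion(sv, models)
              else NA_character_
    annotated <- character()
    for (gid in cands) {
      gb <- gene_body_category(sv, gid, models)
      if (!is.na(gb$category)) {
        add(sv$id, gid, gb$category, gb$evidence,
            fusion = if (gb$category == "pLoF") fusion else NA_character_)
        annotated <- c(annotated, gid)
      }
    }
    # regulatory fallbacks for genes without a gene-body annotation
    bp_in <- function(tbl) {
      hit1 <- tbl$chrom == sv$chrom1 & tbl$start <= sv$pos1 &
        sv$pos1 <= tbl$end
      hit2 <- tbl$chrom == sv$chrom2 & tbl$start <= sv$pos2 &
        sv$pos2 <= tbl$end
      unique(tbl$gene_id[hit1 | hit2])
    }
    for (gid in setdiff(bp_in(prom), annotated)) {
      add(sv$id, gid, "promoter", "breakpoint in promoter window")
      annotated <- c(annotated, gid)
    }
    if (!is.null(enhancers)) {
      for (gid in setdiff(bp_in(enhancers), annotated)) {
        add(sv$id, gid, "enhancer", "breakpoint in enhancer element")
        annotated <- c(annotated, gid)
      }
    }
    if (length(annotated) == 0)
      add(sv$id, NA_character_, "intergenic", "no gene, promoter or enhancer hit")
  }
  if (!length(rows))
    return(data.frame(sv_id = character(), gene_id = character(),
                      gene_name = character(), category = character(),
                      fusion_partner = character(), evidence = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Name a gene fusion from a translocation
#'
#' @param tra a one-row [sv_set] with svtype TRA
#' @param models a [transcript_models] object
#' @return `"GENE1-GENE2"` (breakpoint order as reported) or NA when fewer
#'   than two distinct genes are hit
#' @export
annotate_fusion <- function(tra, models) {
  g <- models$genes
  g1 <- g$gene_name[g$chrom == tra$chrom1 & g$start <= tra$pos1 &
                      tra$pos1 <= g$end]
  g2 <- g$gene_name[g$chrom == tra$chrom2 & g$start <= tra$pos2 &
                      tra$pos2 <= g$end]
  if (length(g1) == 0 || length(g2) == 0) return(NA_character_)
  if (identical(g1[1], g2[1])) return(NA_character_)
  paste0(g1[1], "-", g2[1])
}

#' Read-depth ratio of a DEL/DUP region against its flanks
#'
#' Mean per-base depth inside the SV divided by the mean depth of the two
#' flanking regions combined. A heterozygous deletion is expected near 0.5, a
#' heterozygous tandem duplication near 1.5.
#'
#' @param sv a one-row [sv_set] with svtype DEL or DUP
#' @param depth named list, chromosome -> numeric per-base depth vector
#'   (1-based)
#' @param flank flank width in bases (default 10000)
#' @return numeric ratio
#' @export
depth_ratio <- function(sv, depth, flank = 10000) {
  if (!sv$svtype %in% c("DEL", "DUP"))
    abort("depth_ratio applies to DEL/DUP only")
  d <- depth[[sv$chrom1]]
  if (is.null(d)) abort("no depth track for %s", sv$chrom1)
  lo <- sv$pos1; hi <- sv$pos2
  fl_start <- lo - flank; fr_end <- hi + flank
  if (fl_start < 1 || fr_end > length(d)) {
    warnf("flank truncated at contig boundary")
    fl_start <- max(1, fl_start); fr_end <- min(length(d), fr_end)
  }
  inside <- d[lo:hi]
  flanks <- c(if (fl_start <= lo - 1) d[fl_start:(lo - 1)],
              if (hi + 1 <= fr_end) d[(hi + 1):fr_end])
  mean(inside) / mean(flanks)
}
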