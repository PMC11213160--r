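# SV VCF input/output in three dialects:
#   manta     - symbolic ALT (<DEL>, <DUP:TANDEM>, <INS>, <INV>) with INFO
#               END/SVLEN/SVTYPE; translocations as paired BND lines
#   gridss    - every junction as paired BND bracket-notation lines
#   genotyped - multi-sample symbolic dialect with INFO PASS_ratio and
#               FORMAT GT:FT:GQ (graphtyper-aggregate style)
#
# The files are small, line-oriented and dialect-specific (BND bracket ALT,
# PASS_ratio, FT), so parsing is done directly rather than through a generic
# VCF container.

vcf_header_lines <- function(dialect, samples = character()) {
  h <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=svpath-%s", dialect),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Difference in length between REF and ALT alleles\">",
    "##INFO=<ID=SVINSSEQ,Number=1,Type=String,Description=\"Insertion sequence\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of mate breakend\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Chromosome of second breakpoint\">",
    "##INFO=<ID=END2,Number=1,Type=Integer,Description=\"Position of second breakpoint\">",
    "##INFO=<ID=PASS_ratio,Number=1,Type=Float,Description=\"Fraction of genotype calls flagged PASS at this site\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=FT,Number=1,Type=String,Description=\"Per-sample genotype filter\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FILTER=<ID=FAIL,Description=\"Failed caller filters\">"
  )
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(samples) > 0) cols <- c(cols, "FORMAT", samples)
  c(h, paste(cols, collapse = "\t"))
}

parse_info <- function(s) {
  if (is.na(s) || s == "." || s == "") return(list())
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  out <- lapply(kv, function(p) if (length(p) > 1) p[2] else TRUE)
  names(out) <- vapply(kv, `[`, "", 1)
  out
}

format_info <- function(...) {
  kv <- list(...)
  kv <- kv[!vapply(kv, function(x) is.null(x) || (length(x) == 1 && is.na(x)),
                   TRUE)]
  paste(sprintf("%s=%s", names(kv), vapply(kv, as.character, "")),
        collapse = ";")
}

# Parse a BND bracket ALT. Returns list(local_orient, mate_chrom, mate_pos,
# mate_orient, insertion_seq) or calls abort() naming the offending line.
parse_bnd_alt <- function(alt, line = NA_integer_) {
  m <- regmatches(alt, regexec(
    "^([A-Za-z.]*)(\\[|\\])([^:]+):([0-9]+)(\\[|\\])([A-Za-z.]*)$", alt))[[1]]
  if (length(m) == 0 || m[3] != m[6])
    abort("malformed BND ALT '%s' at line %s", alt, line)
  before <- m[2]; after <- m[7]
  if (nzchar(before) == nzchar(after))
    abort("malformed BND ALT '%s' at line %s (need bases on exactly one side)",
          alt, line)
  local_orient <- if (nzchar(before)) "+" else "-"
  mate_orient <- if (m[3] == "]") "+" else "-"
  ins <- if (nzchar(before)) substring(before, 2) else
    substring(after, 1, nchar(after) - 1)
  list(local_orient = local_orient, mate_chrom = m[4],
       mate_pos = as.integer(m[5]), mate_orient = mate_orient,
       insertion_seq = if (nzchar(ins)) ins else NA_character_)
}

format_bnd_alt <- function(local_orient, mate_chrom, mate_pos, mate_orient,
                           insertion_seq = NA_character_) {
  br <- if (mate_orient == "+") "]" else "["
  mate <- sprintf("%s%s:%d%s", br, mate_chrom, mate_pos, br)
  ins <- if (is.na(insertion_seq)) "" else insertion_seq
  if (local_orient == "+") paste0("N", ins, mate) else paste0(mate, ins, "N")
}

orient_for_type <- function(svtype) {
  switch(svtype,
         DEL = c("+", "-"), DUP = c("-", "+"), INV = c("+", "+"),
         INS = c("+", "-"), TRA = c("+", "-"),
         abort("no default orientation for svtype %s", svtype))
}

#' Read an SV VCF
#'
#' Parses a VCF 4.2 file in one of the supported caller dialects. BND lines
#' yield one raw breakend row each and are resolved into simple SV records
#' via [resolve_bnd_pairs()]. FILTER values of `PASS` or `.` map to
#' `filter_pass = TRUE`.
#'
#' @param path file path
#' @param dialect one of `"manta"`, `"gridss"`, `"genotyped"`
#' @return an [sv_set] for `manta`/`gridss`; an `sv_genotype_matrix` (sites +
#'   per-sample GT/FT/GQ payload) for `genotyped`
#' @export
read_sv_vcf <- function(path, dialect = c("manta", "gridss", "genotyped")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  chrom_line <- lines[grepl("^#CHROM", lines)]
  if (length(chrom_line) != 1) abort("%s: missing #CHROM header line", path)
  cols <- strsplit(chrom_line, "\t", fixed = TRUE)[[1]]
  samples <- if (length(cols) > 9) cols[-(1:9)] else character()
  body <- lines[!hdr & nzchar(lines)]
  if (dialect == "genotyped")
    return(parse_genotyped_body(body, samples, path))
  recs <- parse_sv_body(body, caller = dialect)
  canonicalize_svs(recs$simple_and_resolved)
}

# Shared body parser for manta/gridss dialects: symbolic lines become records
# directly, BND lines are collected and resolved into simple SVs.
parse_sv_body <- function(body, caller) {
  simple <- list(); bnd <- list()
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) abort("truncated VCF data line %d", i)
    info <- parse_info(f[8])
    fp <- f[7] %in% c("PASS", ".")
    alt <- f[5]
    if (grepl("^<", alt)) {
      svtype <- info$SVTYPE %||% gsub("[<>]|:.*", "", alt)
      or <- orient_for_type(svtype)
      pos <- as.integer(f[2])
      end <- if (!is.null(info$END)) as.integer(info$END) else pos
      if (svtype == "INS") end <- pos
      simple[[length(simple) + 1]] <- data.frame(
        id = f[3], chrom1 = f[1], pos1 = pos, orient1 = or[1],
        chrom2 = info$CHR2 %||% f[1],
        pos2 = if (svtype == "TRA") as.integer(info$END2) else end,
        orient2 = or[2], svtype = svtype, caller = caller,
        filter_pass = fp, mate_id = NA_character_,
        insertion_seq = info$SVINSSEQ %||% NA_character_,
        stringsAsFactors = FALSE)
    } else {
      b <- parse_bnd_alt(alt, line = i)
      bnd[[length(bnd) + 1]] <- data.frame(
        id = f[3], chrom1 = f[1], pos1 = as.integer(f[2]),
        orient1 = b$local_orient, chrom2 = b$mate_chrom, pos2 = b$mate_pos,
        orient2 = b$mate_orient, svtype = "BND", caller = caller,
        filter_pass = fp, mate_id = info$MATEID %||% NA_character_,
        insertion_seq = b$insertion_seq, stringsAsFactors = FALSE)
    }
  }
  parts <- list()
  if (length(simple)) parts$simple <- do.call(rbind, simple)
  if (length(bnd)) {
    resolved <- resolve_bnd_pairs(as_sv_set(do.call(rbind, bnd)))
    resolved <- as.data.frame(resolved)
    resolved$length <- NULL
    parts$resolved <- resolved
  }
  out <- if (length(parts)) do.call(rbind, parts) else as.data.frame(sv_set())
  out$length <- NULL
  rownames(out) <- NULL
  list(simple_and_resolved = as_sv_set(out))
}

#' Resolve paired breakends into simple SV records
#'
#' Mate pairs (linked by MATEID) are deduplicated to one record. For
#' same-chromosome junctions the orientation pair, taken in genomic position
#' order, determines the type: `(+,-)` deletion, `(-,+)` tandem duplication,
#' `(+,+)` or `(-,-)` inversion; adjacent breakends carrying an insertion
#' sequence become INS. Different chromosomes give TRA, with breakpoint order
#' preserved as reported (fusion naming depends on it). Orphan breakends are
#' retained as single-junction `BND` records with a warning.
#'
#' @param records an `sv_set` of raw breakend rows (svtype `BND`; `chrom2`,
#'   `pos2`, `orient2` describe the mate as parsed from the bracket ALT)
#' @return an `sv_set` of resolved records
#' @export
resolve_bnd_pairs <- function(records) {
  if (nrow(records) == 0) return(records)
  out <- list(); seen <- character()
  idx <- stats::setNames(seq_len(nrow(records)), records$id)
  for (i in seq_len(nrow(records))) {
    a <- records[i, ]
    if (a$id %in% seen) next
    j <- if (!is.na(a$mate_id)) idx[a$mate_id] else NA_integer_
    if (is.na(j)) {
      warnf("orphan breakend %s retained unpaired", a$id)
      orow <- as.data.frame(a)
      orow$length <- NULL
      out[[length(out) + 1]] <- orow
      seen <- c(seen, a$id)
      next
    }
    b <- records[j, ]
    if (b$chrom1 != a$chrom2 || b$pos1 != a$pos2 ||
        a$chrom1 != b$chrom2 || a$pos1 != b$pos2)
      abort("inconsistent mate coordinates for breakends %s / %s", a$id, b$id)
    seen <- c(seen, a$id, b$id)
    base_id <- sub("_bnd[12]$", "", a$id)
    fp <- a$filter_pass && b$filter_pass
    ins <- if (!is.na(a$insertion_seq)) a$insertion_seq else b$insertion_seq
    if (a$chrom1 != b$chrom1) {
      rec <- data.frame(id = base_id, chrom1 = a$chrom1, pos1 = a$pos1,
                        orient1 = a$orient1, chrom2 = b$chrom1, pos2 = b$pos1,
                        orient2 = b$orient1, svtype = "TRA",
                        caller = a$caller, filter_pass = fp,
                        mate_id = NA_character_, insertion_seq = NA_character_,
                        stringsAsFactors = FALSE)
    } else {
      lo <- if (a$pos1 <= b$pos1) a else b
      hi <- if (a$pos1 <= b$pos1) b else a
      opair <- paste0(lo$orient1, hi$orient1)
      if (!is.na(ins) && hi$pos1 - lo$pos1 <= 1 && opair == "+-") {
        svtype <- "INS"
      } else {
        svtype <- switch(opair, "+-" = "DEL", "-+" = "DUP", "INV")
      }
      p2 <- if (svtype == "INS") lo$pos1 else hi$pos1
      rec <- data.frame(id = base_id, chrom1 = lo$chrom1, pos1 = lo$pos1,
                        orient1 = lo$orient1, chrom2 = hi$chrom1, pos2 = p2,
                        orient2 = hi$orient1, svtype = svtype,
                        caller = a$caller, filter_pass = fp,
                        mate_id = NA_character_,
                        insertion_seq = if (svtype == "INS") ins
                                        else NA_character_,
                        stringsAsFactors = FALSE)
    }
    out[[length(out) + 1]] <- as.data.frame(rec)
  }
  as_sv_set(do.call(rbind, out))
}

sv_vcf_data_lines <- function(records, dialect) {
  lines <- character()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (dialect == "manta" && r$svtype != "TRA" ||
        dialect == "genotyped" && r$svtype != "TRA") {
      alt <- switch(r$svtype, DEL = "<DEL>", DUP = "<DUP:TANDEM>",
                    INS = "<INS>", INV = "<INV>")
      svlen <- switch(r$svtype, DEL = -r$length, r$length)
      info <- format_info(SVTYPE = r$svtype,
                          END = if (r$svtype == "INS") r$pos1 else r$pos2,
                          SVLEN = svlen, SVINSSEQ = r$insertion_seq)
      lines <- c(lines, paste(r$chrom1, r$pos1, r$id, "N", alt, ".",
                              if (r$filter_pass) "PASS" else "FAIL", info,
                              sep = "\t"))
    } else if (dialect == "genotyped" && r$svtype == "TRA") {
      info <- format_info(SVTYPE = "TRA", CHR2 = r$chrom2, END2 = r$pos2)
      lines <- c(lines, paste(r$chrom1, r$pos1, r$id, "N", "<TRA>", ".",
                              if (r$filter_pass) "PASS" else "FAIL", info,
                              sep = "\t"))
    } else if (r$svtype == "BND") {
      # unresolved single breakend (e.g. an orphan): one line, MATEID kept
      alt <- format_bnd_alt(r$orient1, r$chrom2, r$pos2, r$orient2,
                            r$insertion_seq)
      lines <- c(lines, paste(r$chrom1, r$pos1, r$id, "N", alt, ".",
                              if (r$filter_pass) "PASS" else "FAIL",
                              format_info(SVTYPE = "BND",
                                          MATEID = r$mate_id), sep = "\t"))
    } else {
      # breakend pair (gridss dialect, or manta TRA)
      ids <- paste0(r$id, c("_bnd1", "_bnd2"))
      filt <- if (r$filter_pass) "PASS" else "FAIL"
      ins <- r$insertion_seq
      gr_pos2 <- r$pos2
      gr_or <- c(r$orient1, r$orient2)
      if (r$svtype == "INS") { # adjacent breakends carrying the inserted seq
        gr_pos2 <- r$pos1 + 1L
        gr_or <- c("+", "-")
      }
      alt1 <- format_bnd_alt(gr_or[1], r$chrom2, gr_pos2, gr_or[2], ins)
      alt2 <- format_bnd_alt(gr_or[2], r$chrom1, r$pos1, gr_or[1], ins)
      lines <- c(lines,
        paste(r$chrom1, r$pos1, ids[1], "N", alt1, ".", filt,
              format_info(SVTYPE = "BND", MATEID = ids[2]), sep = "\t"),
        paste(r$chrom2, gr_pos2, ids[2], "N", alt2, ".", filt,
              format_info(SVTYPE = "BND", MATEID = ids[1]), sep = "\t"))
    }
  }
  lines
}

#' Write an SV VCF
#'
#' Inverse of [read_sv_vcf()]: `read_sv_vcf(write_sv_vcf(x, p, d), d)` equals
#' `canonicalize_svs(x)` up to provenance columns.
#'
#' @param records an `sv_set` (canonical)
#' @param path output path
#' @param dialect `"manta"` (symbolic; TRA as BND pairs) or `"gridss"` (all
#'   records as BND pairs)
#' @return `path`, invisibly
#' @export
write_sv_vcf <- function(records, path, dialect = c("manta", "gridss")) {
  dialect <- match.arg(dialect)
  lines <- c(vcf_header_lines(dialect), sv_vcf_data_lines(records, dialect))
  writeLines(lines, path)
  invisible(path)
}
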