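#' SV record sets
#'
#' An `sv_set` is a data.frame with one row per structural variant and two
#' breakpoints per record (VCF convention, 1-based). Orientation flags follow
#' breakend semantics: `+` means the joined segment extends to the LEFT of the
#' breakpoint position, `-` means it extends to the RIGHT. Simple types map to
#' fixed orientation pairs: DEL is (+,-), tandem DUP is (-,+), INV is (+,+) or
#' (-,-), INS is a single-locus event, TRA joins two chromosomes.
#'
#' @param id character record identifiers
#' @param chrom1,pos1,orient1 first breakpoint (chromosome, 1-based position,
#'   orientation in `+`/`-`)
#' @param chrom2,pos2,orient2 second breakpoint
#' @param svtype one of DEL, DUP, INS, INV, TRA
#' @param caller source label (e.g. "manta", "gridss")
#' @param filter_pass logical; VCF FILTER was PASS or "."
#' @param mate_id optional BND partner id
#' @param insertion_seq optional inserted sequence (INS records)
#' @return a data.frame of class `sv_set` with an additional `length` column
#'   (`pos2 - pos1` for intra-chromosomal DEL/DUP/INV, inserted length for INS,
#'   NA for TRA)
#' @export
sv_set <- function(id = character(), chrom1 = character(), pos1 = integer(),
                   orient1 = character(), chrom2 = character(),
                   pos2 = integer(), orient2 = character(),
                   svtype = character(), caller = NA_character_,
                   filter_pass = TRUE, mate_id = NA_character_,
                   insertion_seq = NA_character_) {
  n <- length(id)
  df <- data.frame(
    id = as.character(id),
    chrom1 = as.character(chrom1), pos1 = as.integer(pos1),
    orient1 = as.character(orient1),
    chrom2 = as.character(chrom2), pos2 = as.integer(pos2),
    orient2 = as.character(orient2),
    svtype = as.character(svtype),
    caller = rep_len(as.character(caller), n),
    filter_pass = rep_len(as.logical(filter_pass), n),
    mate_id = rep_len(as.character(mate_id), n),
    insertion_seq = rep_len(as.character(insertion_seq), n),
    stringsAsFactors = FALSE
  )
  validate_sv_set(df)
  df$length <- sv_length_vec(df)
  class(df) <- c("sv_set", "data.frame")
  df
}

validate_sv_set <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$pos1)) || any(df$pos1 < 1) || any(df$pos2 < 1, na.rm = TRUE))
    abort("breakpoint positions must be >= 1")
  if (any(!nzchar(df$chrom1)))
    abort("empty chromosome name")
  bad <- !df$svtype %in% c("DEL", "DUP", "INS", "INV", "TRA", "BND")
  if (any(bad))
    abort("unknown svtype: %s", paste(unique(df$svtype[bad]), collapse = ","))
  ok_or <- c("+", "-")
  if (any(!df$orient1 %in% ok_or) || any(!df$orient2 %in% ok_or))
    abort("orientation flags must be '+' or '-'")
  tra <- df$svtype == "TRA"
  if (any(tra & df$chrom1 == df$chrom2))
    abort("TRA records must join two different chromosomes")
  if (any(!tra & df$svtype != "BND" & df$chrom1 != df$chrom2))
    abort("non-TRA records must be intra-chromosomal")
  invisible(df)
}

#' @export
print.sv_set <- function(x, ...) {
  cat(sprintf("<sv_set> %d records (%s)\n", nrow(x),
              paste(sprintf("%s:%d", names(table(x$svtype)),
                            as.integer(table(x$svtype))), collapse = ", ")))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

as_sv_set <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$length <- sv_length_vec(df)
  class(df) <- c("sv_set", "data.frame")
  df
}

sv_length_vec <- function(df) {
  if (nrow(df) == 0) return(integer())
  len <- ifelse(df$svtype %in% c("DEL", "DUP", "INV"),
                abs(df$pos2 - df$pos1),
                NA_integer_)
  ins <- df$svtype == "INS"
  len[ins] <- ifelse(is.na(df$insertion_seq[ins]), NA_integer_,
                     nchar(df$insertion_seq[ins]))
  as.integer(len)
}

#' SV length
#'
#' Length convention: `pos2 - pos1` for intra-chromosomal DEL/DUP/INV (no +1;
#' breakpoints delimit the rearranged segment), inserted-sequence length for
#' INS, and undefined (NA) for inter-chromosomal translocations.
#'
#' @param records an `sv_set`
#' @return integer vector, NA where undefined
#' @export
sv_length <- function(records) {
  sv_length_vec(records)
}

#' Canonicalize SV records
#'
#' Orders breakpoints so that `pos1 <= pos2` for intra-chromosomal records
#' (orientations travel with their breakpoints). Inter-chromosomal records are
#' left in caller-reported order so that fusion naming (gene at breakpoint 1
#' first) is preserved. Idempotent.
#'
#' @param records an `sv_set`
#' @return the canonicalized `sv_set`
#' @export
canonicalize_svs <- function(records) {
  if (nrow(records) == 0) return(records)
  swap <- records$chrom1 == records$chrom2 & records$pos1 > records$pos2 &
    records$svtype != "INS"
  swap[is.na(swap)] <- FALSE
  if (any(swap)) {
    tmp <- records[swap, c("pos1", "orient1")]
    records$pos1[swap] <- records$pos2[swap]
    records$orient1[swap] <- records$orient2[swap]
    records$pos2[swap] <- tmp$pos1
    records$orient2[swap] <- tmp$orient1
  }
  records$length <- sv_length_vec(records)
  records
}
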