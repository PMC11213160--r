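# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; cohort percentages are reported
#' with conventional half-up rounding (e.g. 12.35 -> 12.4).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# stop() with sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# read a TSV with headers as plain character-safe data.frame
read_tsv_file <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""), ...)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rbind a list of one-row data.frames; empty list gives the zero-row proto
rbind_rows <- function(rows, proto = data.frame()) {
  if (!length(rows)) return(proto)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# deterministic sub-seed derivation: keep below 2^31
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}
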