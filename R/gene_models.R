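# Canonical transcript models. One representative transcript per gene:
# gene span, ordered non-overlapping exons, the CDS sub-segments, UTR = exon
# minus CDS, and a strand-aware transcription start site (span start on '+',
# span end on '-').

#' Construct transcript models
#'
#' @param genes data.frame: `gene_id`, `gene_name`, `chrom`, `strand`
#'   (`+`/`-`), `start`, `end` (1-based inclusive)
#' @param exons data.frame: `gene_id`, `start`, `end`
#' @param cds data.frame: `gene_id`, `start`, `end` (sub-intervals of exons;
#'   genes absent from `cds` are non-coding)
#' @return object of class `transcript_models` with a computed `tss` column
#' @export
transcript_models <- function(genes, exons, cds) {
  stopifnot(all(c("gene_id", "gene_name", "chrom", "strand", "start", "end")
                %in% names(genes)))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  # exons must be sorted and non-overlapping within a gene
  for (g in unique(exons$gene_id)) {
    e <- exons[exons$gene_id == g, ]
    if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)]))
      abort("overlapping exons in gene %s", g)
  }
  structure(list(genes = genes, exons = exons, cds = cds),
            class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat(sprintf("<transcript_models> %d genes, %d exons, %d CDS segments\n",
              nrow(x$genes), nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

#' Read canonical transcript models from GTF
#'
#' Uses the `gene`, `exon` and `CDS` features of the transcript tagged
#' `Ensembl_canonical` (all transcripts if no tag attribute is present).
#'
#' @param path GTF/GFF2 file
#' @return a [transcript_models] object
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  gene_rows <- df[df$type == "gene", ]
  genes <- data.frame(gene_id = gene_rows$gene_id,
                      gene_name = gene_rows$gene_name %||% gene_rows$gene_id,
                      chrom = gene_rows$seqnames, strand = gene_rows$strand,
                      start = gene_rows$start, end = gene_rows$end,
                      stringsAsFactors = FALSE)
  tx <- df[df$type == "transcript", ]
  if (!is.null(tx$tag)) {
    canon <- tx$transcript_id[!is.na(tx$tag) & tx$tag == "Ensembl_canonical"]
    if (length(canon) == 0) canon <- tx$transcript_id
  } else canon <- tx$transcript_id
  ex <- df[df$type == "exon" & df$transcript_id %in% canon, ]
  cd <- df[df$type == "CDS" & df$transcript_id %in% canon, ]
  transcript_models(
    genes,
    exons = data.frame(gene_id = ex$gene_id, start = ex$start, end = ex$end,
                       stringsAsFactors = FALSE),
    cds = data.frame(gene_id = cd$gene_id, start = cd$start, end = cd$end,
                     stringsAsFactors = FALSE))
}

#' Promoter windows
#'
#' A promoter is the 1 kb window immediately upstream of the transcription
#' start site on the transcribed strand: `[start - size, start - 1]` for `+`
#' genes, `[end + 1, end + size]` for `-` genes. Windows never overlap their
#' own gene body.
#'
#' @param models a [transcript_models] object
#' @param size window width in bases (default 1000)
#' @return data.frame: `gene_id`, `chrom`, `start`, `end`
#' @export
promoter_windows <- function(models, size = 1000) {
  g <- models$genes
  data.frame(gene_id = g$gene_id, chrom = g$chrom,
             start = ifelse(g$strand == "+", pmax(1, g$start - size),
                            g$end + 1),
             end = ifelse(g$strand == "+", g$start - 1, g$end + size),
             stringsAsFactors = FALSE)
}

#' Read enhancer elements from BED
#'
#' BED half-open 0-based intervals are converted to 1-based inclusive on
#' read. The BED name column carries the target gene id.
#'
#' @param path BED file (chrom, start, end, target gene id)
#' @return data.frame: `chrom`, `start`, `end`, `gene_id`
#' @export
read_enhancer_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  data.frame(chrom = as.character(df$seqnames), start = df$start,
             end = df$end, gene_id = df$name, stringsAsFactors = FALSE)
}

#' Write enhancer elements to BED
#'
#' @param enhancers data.frame as returned by [read_enhancer_bed()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_enhancer_bed <- function(enhancers, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", enhancers$chrom,
                   as.integer(enhancers$start - 1L),
                   as.integer(enhancers$end), enhancers$gene_id)
  writeLines(lines, path)
  invisible(path)
}
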