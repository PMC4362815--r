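# Gene models: strand-aware TSS/TTS with exon blocks, refFlat-like I/O.

#' Construct a gene set
#'
#' @param genes data.frame with `gene_id`, `chrom`, `strand` (+/-), `tx_start`,
#'   `tx_end` (0-based half-open transcript span) and optional list columns
#'   `exon_starts`, `exon_ends` (numeric vectors per gene).
#' @return a `GeneSet`: data.frame with derived `tss` and `tts` columns.
#'   On the + strand `tss = tx_start`, `tts = tx_end`; on the - strand
#'   `tss = tx_end`, `tts = tx_start` (so the TSS is always the 5' end).
#' @export
gene_set <- function(genes) {
  df <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end")
  if (!all(need %in% names(df)))
    stop("gene_set: need columns ", paste(need, collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("gene_set: strand must be + or -")
  if (any(df$tx_start >= df$tx_end))
    stop("gene_set: tx_start must be < tx_end")
  if (anyDuplicated(df$gene_id))
    stop("gene_set: duplicate gene_id")
  if (!"exon_starts" %in% names(df)) {
    df$exon_starts <- as.list(df$tx_start)
    df$exon_ends <- as.list(df$tx_end)
  }
  for (i in seq_len(nrow(df))) {
    es <- df$exon_starts[[i]]; ee <- df$exon_ends[[i]]
    if (length(es) != length(ee) || any(es >= ee))
      stop("gene_set: malformed exons for ", df$gene_id[i])
    o <- order(es)
    es <- es[o]; ee <- ee[o]
    if (any(ee[-length(ee)] > es[-1]))
      stop("gene_set: overlapping exons for ", df$gene_id[i])
    if (es[1] < df$tx_start[i] || ee[length(ee)] > df$tx_end[i])
      stop("gene_set: exons outside transcript for ", df$gene_id[i])
    df$exon_starts[[i]] <- es; df$exon_ends[[i]] <- ee
  }
  df$tss <- ifelse(df$strand == "+", df$tx_start, df$tx_end)
  df$tts <- ifelse(df$strand == "+", df$tx_end, df$tx_start)
  o <- order(df$chrom, df$tx_start, df$tx_end, df$gene_id, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("GeneSet", "data.frame")
  df
}

#' Read a refFlat-like gene table
#'
#' Tab-separated columns: gene_id, chrom, strand, txStart, txEnd, exonStarts,
#' exonEnds; the last two are comma-separated block lists (trailing comma
#' tolerated). Coordinates 0-based half-open.
#'
#' @param path file path
#' @return `GeneSet`
#' @export
read_genes <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "txStart", "txEnd")
  if (!all(need %in% names(df)))
    stop("read_genes: need header columns ", paste(need, collapse = ", "))
  parse_blocks <- function(x) lapply(strsplit(as.character(x), ","),
                                     function(v) as.numeric(v[nzchar(v)]))
  g <- data.frame(gene_id = df$gene_id, chrom = df$chrom, strand = df$strand,
                  tx_start = as.numeric(df$txStart),
                  tx_end = as.numeric(df$txEnd), stringsAsFactors = FALSE)
  if ("exonStarts" %in% names(df)) {
    g$exon_starts <- parse_blocks(df$exonStarts)
    g$exon_ends <- parse_blocks(df$exonEnds)
  }
  gene_set(g)
}

#' Write a gene set in the refFlat-like dialect read by [read_genes()]
#' @param genes `GeneSet`
#' @param path output path
#' @export
write_genes <- function(genes, path) {
  fmt <- function(v) paste0(paste(format(v, scientific = FALSE, trim = TRUE),
                                  collapse = ","), ",")
  out <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    txStart = format(genes$tx_start, scientific = FALSE, trim = TRUE),
    txEnd = format(genes$tx_end, scientific = FALSE, trim = TRUE),
    exonStarts = vapply(genes$exon_starts, fmt, character(1)),
    exonEnds = vapply(genes$exon_ends, fmt, character(1)),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
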