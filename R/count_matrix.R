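# Region x sample count container shared by the FAIRE and ChIP analyses.

#' Construct a region count matrix
#'
#' @param regions `RegionSet` (rows).
#' @param samples data.frame of sample metadata; must contain `sample_id` and
#'   `library_size`, and for time-course scoring `time_point` and `replicate`.
#' @param counts integer matrix, regions x samples, non-negative; columns in
#'   `samples$sample_id` order.
#' @return a `RegionCountMatrix`.
#' @export
region_count_matrix <- function(regions, samples, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != length(regions))
    stop("region_count_matrix: counts rows must match regions")
  if (ncol(counts) != nrow(samples))
    stop("region_count_matrix: counts columns must match samples")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("region_count_matrix: counts must be non-negative integers")
  if (!all(c("sample_id", "library_size") %in% names(samples)))
    stop("region_count_matrix: samples need sample_id and library_size")
  if (any(samples$library_size <= 0))
    stop("region_count_matrix: library sizes must be > 0")
  if (!is.null(colnames(counts)) &&
      !identical(colnames(counts), as.character(samples$sample_id)))
    stop("region_count_matrix: counts column names disagree with sample_id")
  colnames(counts) <- samples$sample_id
  structure(list(regions = regions, samples = samples, counts = counts),
            class = "RegionCountMatrix")
}

#' Library-size normalized counts (reads per million)
#' @param m `RegionCountMatrix`
#' @return numeric matrix of counts / library_size * 1e6.
#' @export
normalized_counts <- function(m) {
  t(t(m$counts) / m$samples$library_size) * 1e6
}

#' @export
print.RegionCountMatrix <- function(x, ...) {
  cat(sprintf("RegionCountMatrix: %d regions x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Write a count matrix and its sample metadata sidecar
#'
#' The main TSV has a `region_id` column then one column per sample; the
#' sidecar carries sample_id, assay, time_point, replicate, library_size.
#'
#' @param m `RegionCountMatrix`
#' @param path counts TSV path
#' @param samples_path sidecar TSV path (default `<path>.samples.tsv`)
#' @export
write_count_matrix <- function(m, path,
                               samples_path = paste0(path, ".samples.tsv")) {
  df <- m$regions$intervals
  region_id <- ifelse(is.na(df$name),
                      sprintf("%s:%s-%s", df$chrom,
                              format(df$start, scientific = FALSE, trim = TRUE),
                              format(df$end, scientific = FALSE, trim = TRUE)),
                      df$name)
  out <- data.frame(region_id = region_id, m$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(m$samples, samples_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param path counts TSV
#' @param regions `RegionSet` giving row coordinates (row order must match)
#' @param samples_path sidecar TSV
#' @return `RegionCountMatrix`
#' @export
read_count_matrix <- function(path, regions,
                              samples_path = paste0(path, ".samples.tsv")) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  samples <- read.delim(samples_path, header = TRUE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  region_count_matrix(regions, samples, counts)
}
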