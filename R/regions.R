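#' @importFrom stats quantile sd rnorm rbinom runif cor pt pbinom dnorm rnbinom
#' @importFrom utils read.delim write.table head tail
NULL

# Internal coordinate convention: 0-based half-open [start, end), BED style.
# IRanges (1-based closed) is used as the overlap engine; conversion happens
# only inside these helpers.

.region_cols <- c("chrom", "start", "end", "name", "score", "strand", "summit")

.empty_intervals <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             name = character(0), score = numeric(0), strand = character(0),
             summit = numeric(0), stringsAsFactors = FALSE)
}

#' Chromosome sizes
#'
#' A named numeric vector mapping chromosome name to length in bp.
#'
#' @param lengths numeric vector of chromosome lengths, named by chromosome.
#' @return a validated `ChromSizes` object (named numeric vector).
#' @export
chrom_sizes <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chrom_sizes: all lengths must be named by chromosome")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chrom_sizes: all lengths must be finite and > 0")
  structure(as.numeric(lengths), names = names(lengths), class = "ChromSizes")
}

#' Read a two-column chrom.sizes file
#' @param path file path (TSV: chrom, length).
#' @return `ChromSizes`
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("chrom.sizes file must have two columns")
  chrom_sizes(structure(as.numeric(df[[2]]), names = as.character(df[[1]])))
}

#' Write chromosome sizes
#' @param genome `ChromSizes`
#' @param path output path
#' @export
write_chrom_sizes <- function(genome, path) {
  write.table(data.frame(names(genome), as.numeric(genome)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a region set
#'
#' A `RegionSet` is a sorted collection of genomic intervals in 0-based
#' half-open coordinates, optionally carrying a strand, a score (conventionally
#' a -log10 p-value or a fold change) and a summit coordinate (the absolute
#' position of the local signal maximum inside the interval).
#'
#' @param intervals data.frame with at least `chrom`, `start`, `end`; optional
#'   `name`, `score`, `strand`, `summit`.
#' @param genome optional `ChromSizes`; when given, intervals are validated
#'   against chromosome bounds.
#' @param name label for the set.
#' @return a `RegionSet`.
#' @export
region_set <- function(intervals, genome = NULL, name = "regions") {
  df <- as.data.frame(intervals, stringsAsFactors = FALSE)
  if (nrow(df) == 0) df <- .empty_intervals()
  if (!all(c("chrom", "start", "end") %in% names(df)))
    stop("region_set: intervals need chrom, start, end columns")
  if (!"name" %in% names(df)) df$name <- rep(NA_character_, nrow(df))
  if (!"score" %in% names(df)) df$score <- rep(NA_real_, nrow(df))
  if (!"strand" %in% names(df)) df$strand <- rep("*", nrow(df))
  if (!"summit" %in% names(df)) df$summit <- rep(NA_real_, nrow(df))
  df <- df[, .region_cols]
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df$name <- as.character(df$name)
  df$strand <- as.character(df$strand)
  obj <- structure(list(name = name, intervals = df, genome = genome),
                   class = "RegionSet")
  validate_region_set(sort_regions(obj))
}

#' Validate a region set
#' @param x `RegionSet`
#' @return `x`, invisibly on success; errors otherwise.
#' @export
validate_region_set <- function(x) {
  df <- x$intervals
  if (any(df$start < 0)) stop("RegionSet: negative start coordinate")
  if (any(df$start >= df$end)) stop("RegionSet: start >= end")
  if (!all(df$strand %in% c("+", "-", "*")))
    stop("RegionSet: strand must be one of +, -, *")
  bad <- !is.na(df$summit) & (df$summit < df$start | df$summit >= df$end)
  if (any(bad)) stop("RegionSet: summit outside [start, end)")
  if (!is.null(x$genome)) {
    g <- x$genome
    unknown <- setdiff(unique(df$chrom), names(g))
    if (length(unknown))
      stop("RegionSet: unknown chromosome(s): ", paste(unknown, collapse = ", "))
    if (any(df$end > g[df$chrom]))
      stop("RegionSet: interval end exceeds chromosome length")
  }
  x
}

sort_regions <- function(x) {
  df <- x$intervals
  o <- order(df$chrom, df$start, df$end, df$name, method = "radix")
  x$intervals <- df[o, , drop = FALSE]
  rownames(x$intervals) <- NULL
  x
}

#' @export
print.RegionSet <- function(x, ...) {
  cat(sprintf("RegionSet '%s': %d intervals on %d chromosome(s)\n",
              x$name, nrow(x$intervals), length(unique(x$intervals$chrom))))
  print(head(x$intervals))
  invisible(x)
}

#' @export
length.RegionSet <- function(x) nrow(x$intervals)

#' Subset a region set by interval index
#' @param x `RegionSet`
#' @param i index vector
#' @param ... ignored
#' @return `RegionSet`
#' @export
`[.RegionSet` <- function(x, i, ...) {
  x$intervals <- x$intervals[i, , drop = FALSE]
  rownames(x$intervals) <- NULL
  x
}

# split intervals by chromosome into IRanges, remembering row indices
.by_chrom_iranges <- function(df) {
  idx <- split(seq_len(nrow(df)), df$chrom)
  lapply(idx, function(i)
    list(idx = i,
         ir = IRanges::IRanges(start = df$start[i] + 1L, end = df$end[i])))
}

#' Read a BED file
#'
#' Accepts BED3 or BED6 with an optional seventh column holding an absolute
#' summit coordinate. Coordinates are 0-based half-open per the BED standard.
#'
#' @param path file path.
#' @param genome optional `ChromSizes`; unknown chromosomes are rejected.
#' @param name label for the returned set (default: file basename).
#' @return sorted `RegionSet`.
#' @export
read_bed <- function(path, genome = NULL, name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (is.null(name)) name <- basename(path)
  if (length(lines) == 0)
    return(region_set(.empty_intervals(), genome = genome, name = name))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- which(nf < 3)[1]
    stop(sprintf("read_bed: malformed line %d in %s (fewer than 3 fields)",
                 bad, path))
  }
  k <- min(nf)
  m <- t(vapply(fields, function(f) f[seq_len(k)], character(k)))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  if (any(is.na(start)) || any(is.na(end))) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop(sprintf("read_bed: malformed line %d in %s (non-numeric coordinate)",
                 bad, path))
  }
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop(sprintf("read_bed: invalid interval at line %d in %s (start >= end)",
                 bad, path))
  }
  df <- data.frame(chrom = m[, 1], start = start, end = end,
                   stringsAsFactors = FALSE)
  if (k >= 4) df$name <- ifelse(m[, 4] == ".", NA_character_, m[, 4])
  if (k >= 5) df$score <- suppressWarnings(as.numeric(ifelse(m[, 5] == ".",
                                                             NA, m[, 5])))
  if (k >= 6) df$strand <- ifelse(m[, 6] %in% c("+", "-"), m[, 6], "*")
  if (k >= 7) df$summit <- suppressWarnings(as.numeric(ifelse(m[, 7] == ".",
                                                              NA, m[, 7])))
  region_set(df, genome = genome, name = name)
}

#' Write a region set as BED
#'
#' Emits BED6 plus a seventh summit column when any summit is present; the
#' round trip `read_bed(write_bed(x))` preserves coordinates exactly.
#'
#' @param x `RegionSet`
#' @param path output path
#' @export
write_bed <- function(x, path) {
  df <- x$intervals
  out <- data.frame(
    chrom = df$chrom,
    start = format(df$start, scientific = FALSE, trim = TRUE),
    end = format(df$end, scientific = FALSE, trim = TRUE),
    name = ifelse(is.na(df$name), ".", df$name),
    score = ifelse(is.na(df$score), ".",
                   format(df$score, scientific = FALSE, trim = TRUE, digits = 15)),
    strand = ifelse(df$strand == "*", ".", df$strand),
    stringsAsFactors = FALSE)
  if (any(!is.na(df$summit)))
    out$summit <- ifelse(is.na(df$summit), ".",
                         format(df$summit, scientific = FALSE, trim = TRUE))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge overlapping intervals
#'
#' Intervals sharing at least one base pair are merged; book-ended intervals
#' (e.g. `[0,10)` and `[10,20)`) are kept separate. Scores, names and summits
#' are dropped (a merged interval has no single summit).
#'
#' @param x `RegionSet`
#' @return `RegionSet` of pairwise-disjoint intervals covering the same bases.
#' @export
merge_regions <- function(x) {
  df <- x$intervals
  if (nrow(df) == 0) return(x)
  parts <- .by_chrom_iranges(df)
  out <- lapply(names(parts), function(ch) {
    red <- IRanges::reduce(parts[[ch]]$ir, min.gapwidth = 0L)
    data.frame(chrom = ch, start = IRanges::start(red) - 1,
               end = IRanges::end(red), stringsAsFactors = FALSE)
  })
  region_set(do.call(rbind, out), genome = x$genome,
             name = paste0(x$name, ".merged"))
}

#' Flag intervals of one set that overlap another
#'
#' "Overlap" means sharing at least one base pair; half-open adjacency does
#' not count. Both sets must be built on the same genome when genomes are set.
#'
#' @param a,b `RegionSet`s
#' @return list with `flags` (logical per interval of `a`) and `fraction`
#'   (mean of flags; `NaN` for an empty `a`).
#' @export
region_overlaps <- function(a, b) {
  if (!is.null(a$genome) && !is.null(b$genome) &&
      !identical(unclass(a$genome), unclass(b$genome)))
    stop("region_overlaps: region sets built on different genomes")
  da <- a$intervals
  db <- b$intervals
  flags <- logical(nrow(da))
  if (nrow(da) > 0 && nrow(db) > 0) {
    pa <- .by_chrom_iranges(da)
    pb <- .by_chrom_iranges(db)
    for (ch in intersect(names(pa), names(pb))) {
      hit <- IRanges::overlapsAny(pa[[ch]]$ir, pb[[ch]]$ir, minoverlap = 1L)
      flags[pa[[ch]]$idx] <- hit
    }
  }
  list(flags = flags, fraction = mean(flags))
}

#' Count 5' read positions per region
#'
#' Each read is a (chrom, position) pair giving its 5' end; a read is counted
#' in a region when its position lies in `[start, end)`. Counting is by read
#' position, not fragment span, so a read overlapping two regions is counted
#' where its 5' end falls.
#'
#' @param regions `RegionSet`
#' @param tags named list (one element per sample) of data.frames with columns
#'   `chrom` and `pos` (0-based 5' positions).
#' @param samples optional sample metadata data.frame (`sample_id`,
#'   `time_point`, `replicate`, ...); default derives ids from `names(tags)`.
#' @return a `RegionCountMatrix`: list with `regions`, `samples`
#'   (incl. `library_size` = total reads per sample) and integer `counts`.
#' @export
count_reads <- function(regions, tags, samples = NULL) {
  if (is.null(names(tags)) || any(!nzchar(names(tags))))
    stop("count_reads: tags must be a named list (one element per sample)")
  nreads <- vapply(tags, nrow, integer(1))
  if (any(nreads == 0))
    stop("count_reads: sample(s) with zero reads: ",
         paste(names(tags)[nreads == 0], collapse = ", "))
  df <- regions$intervals
  counts <- matrix(0L, nrow = nrow(df), ncol = length(tags),
                   dimnames = list(NULL, names(tags)))
  if (nrow(df) > 0) {
    parts <- .by_chrom_iranges(df)
    for (j in seq_along(tags)) {
      td <- tags[[j]]
      for (ch in intersect(names(parts), unique(td$chrom))) {
        pos <- td$pos[td$chrom == ch]
        pr <- IRanges::IRanges(start = pos + 1L, width = 1L)
        counts[parts[[ch]]$idx, j] <-
          counts[parts[[ch]]$idx, j] + IRanges::countOverlaps(parts[[ch]]$ir, pr)
      }
    }
  }
  if (is.null(samples))
    samples <- data.frame(sample_id = names(tags), stringsAsFactors = FALSE)
  samples$library_size <- as.numeric(nreads[samples$sample_id])
  region_count_matrix(regions, samples, counts)
}
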