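# Pairwise overlap statistics between binding-site sets, input-normalized
# signal correlation at open-chromatin sites, and average-linkage clustering
# of datasets.

#' Directional overlap summary between two region sets
#'
#' Fraction of `a` intervals sharing >= 1 bp with `b`, optionally restricted
#' to the `a` intervals that overlap a stratum (e.g. open chromatin). Overlap
#' fractions are directional; compute both directions by swapping arguments.
#'
#' @param a,b `RegionSet`s
#' @param stratum optional `RegionSet`; when given, only `a` intervals
#'   overlapping it enter the numerator and denominator.
#' @return data.frame row: set_a, set_b, stratum, n_a, n_a_overlapping_b,
#'   fraction.
#' @export
overlap_summary <- function(a, b, stratum = NULL) {
  if (length(a) == 0) stop("overlap_summary: empty query set")
  keep <- rep(TRUE, length(a))
  sname <- "all"
  if (!is.null(stratum)) {
    keep <- region_overlaps(a, stratum)$flags
    sname <- stratum$name
  }
  a_sub <- a[which(keep)]
  if (length(a_sub) == 0)
    return(data.frame(set_a = a$name, set_b = b$name, stratum = sname,
                      n_a = 0, n_a_overlapping_b = 0, fraction = NaN))
  fl <- region_overlaps(a_sub, b)$flags
  data.frame(set_a = a$name, set_b = b$name, stratum = sname,
             n_a = length(a_sub), n_a_overlapping_b = sum(fl),
             fraction = mean(fl), stringsAsFactors = FALSE)
}

#' Input-normalized signal correlation matrix
#'
#' Per dataset and site, signal = RPM(count + 1) / RPM(input + 1); the matrix
#' is the Pearson correlation of these ratios (optionally log2) across sites,
#' for every dataset pair. Zero-variance datasets yield `NA` rows/columns and
#' are flagged.
#'
#' @param counts sites x datasets matrix of ChIP read counts.
#' @param input_counts sites x 1 (vector) or sites x datasets matrix of input
#'   read counts.
#' @param lib_sizes named numeric, mapped reads per dataset.
#' @param input_lib_sizes numeric, mapped reads of the input(s).
#' @param log2_ratio correlate log2 ratios instead of linear (default FALSE).
#' @return a `SignalCorrelationMatrix`: list with `cor` (symmetric matrix),
#'   `excluded` (zero-variance dataset names) and `ratios`.
#' @export
signal_correlation <- function(counts, input_counts, lib_sizes,
                               input_lib_sizes, log2_ratio = FALSE) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("signal_correlation: need >= 2 datasets")
  if (nrow(counts) < 3) stop("signal_correlation: need >= 3 sites")
  if (is.vector(input_counts))
    input_counts <- matrix(input_counts, nrow = nrow(counts),
                           ncol = ncol(counts))
  if (length(input_lib_sizes) == 1)
    input_lib_sizes <- rep(input_lib_sizes, ncol(counts))
  chip_rpm <- sweep(counts + 1, 2, lib_sizes / 1e6, "/")
  input_rpm <- sweep(as.matrix(input_counts) + 1, 2, input_lib_sizes / 1e6,
                     "/")
  ratios <- chip_rpm / input_rpm
  if (log2_ratio) ratios <- log2(ratios)
  vars <- apply(ratios, 2, stats::var)
  excluded <- colnames(counts)[vars == 0]
  cm <- suppressWarnings(cor(ratios, method = "pearson"))
  structure(list(cor = cm, excluded = excluded, ratios = ratios),
            class = "SignalCorrelationMatrix")
}

#' Average-linkage clustering of datasets from a correlation matrix
#'
#' Agglomerative average linkage (UPGMA) on dissimilarity `1 - r`. Ties in
#' the minimum inter-cluster distance are broken by the lexically smallest
#' member pair, so the merge order is deterministic and invariant to input
#' order. Datasets flagged as zero-variance are excluded.
#'
#' @param scm `SignalCorrelationMatrix` (or a plain correlation matrix).
#' @return list with `merges` (data.frame: step, a, b, height — a, b are
#'   cluster labels, leaves named by dataset), `order` (leaf order) and
#'   `newick` (tree text with branch lengths = merge heights).
#' @export
cluster_datasets <- function(scm) {
  cm <- if (inherits(scm, "SignalCorrelationMatrix")) scm$cor else as.matrix(scm)
  if (inherits(scm, "SignalCorrelationMatrix") && length(scm$excluded)) {
    keep <- setdiff(colnames(cm), scm$excluded)
    cm <- cm[keep, keep, drop = FALSE]
  }
  n <- ncol(cm)
  if (n < 2) stop("cluster_datasets: need >= 2 datasets")
  if (anyNA(cm)) stop("cluster_datasets: missing correlations")
  d <- 1 - cm
  # active clusters: list of member index vectors, labelled
  labels <- colnames(cm)
  clusters <- as.list(seq_len(n))
  names(clusters) <- labels
  newick <- labels
  heights <- rep(0, n)
  merges <- data.frame(step = integer(0), a = character(0), b = character(0),
                       height = numeric(0), stringsAsFactors = FALSE)
  step <- 0
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- NULL
    for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      key <- sort(c(names(clusters)[i], names(clusters)[j]))
      if (is.null(best) || dij < best$d - 1e-12 ||
          (abs(dij - best$d) <= 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(i = i, j = j, d = dij, key = key)
      }
    }
    step <- step + 1
    i <- best$i; j <- best$j
    la <- names(clusters)[i]; lb <- names(clusters)[j]
    merges <- rbind(merges, data.frame(step = step, a = la, b = lb,
                                       height = best$d,
                                       stringsAsFactors = FALSE))
    new_members <- c(clusters[[i]], clusters[[j]])
    bl_a <- best$d - heights[i]
    bl_b <- best$d - heights[j]
    new_newick <- sprintf("(%s:%.6g,%s:%.6g)", newick[i], bl_a,
                          newick[j], bl_b)
    keep <- setdiff(seq_len(k), c(i, j))
    clusters <- c(clusters[keep], list(new_members))
    names(clusters)[length(clusters)] <-
      paste0("(", best$key[1], "+", best$key[2], ")")
    newick <- c(newick[keep], new_newick)
    heights <- c(heights[keep], best$d)
  }
  ord_idx <- clusters[[1]]
  list(merges = merges, order = labels[ord_idx],
       newick = paste0(newick[1], ";"))
}
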