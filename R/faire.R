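# Differential open-chromatin calling over a replicate time course.
#
# For each region and time point the statistic is
#   |mean(normalized, reps of t) - mean(normalized, all other samples)|
#     / (sd_t + sd_rest)
# with sample (n-1) standard deviations on RPM-normalized counts. The null is
# built by permuting the sample -> time-point assignment jointly across all
# samples and recomputing every score.

row_sd <- function(x) {
  # sample sd per row of a matrix with >= 2 columns
  n <- ncol(x)
  mu <- rowMeans(x)
  sqrt(rowSums((x - mu)^2) / (n - 1))
}

.score_one_labeling <- function(norm, time_labels) {
  tps <- sort(unique(time_labels))
  out <- vector("list", length(tps))
  for (k in seq_along(tps)) {
    idx <- which(time_labels == tps[k])
    rest <- which(time_labels != tps[k])
    x_t <- norm[, idx, drop = FALSE]
    x_r <- norm[, rest, drop = FALSE]
    mean_t <- rowMeans(x_t)
    mean_rest <- rowMeans(x_r)
    sd_t <- row_sd(x_t)
    sd_rest <- row_sd(x_r)
    denom <- sd_t + sd_rest
    diff <- mean_t - mean_rest
    score <- abs(diff) / denom
    score[denom == 0 & diff == 0] <- 0
    score[denom == 0 & diff != 0] <- Inf
    out[[k]] <- data.frame(region = seq_len(nrow(norm)), time_point = tps[k],
                           mean_t = mean_t, mean_rest = mean_rest,
                           sd_t = sd_t, sd_rest = sd_rest, score = score,
                           direction = ifelse(diff >= 0, "up", "down"),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.check_design <- function(samples) {
  if (!"time_point" %in% names(samples))
    stop("score_regions: samples need a time_point column")
  tab <- table(samples$time_point)
  if (length(tab) < 2)
    stop("score_regions: need >= 2 time points (rest group otherwise empty)")
  if (any(tab < 2))
    stop("score_regions: every time point needs >= 2 replicates")
}

#' Score regions for differential accessibility
#'
#' One score per region x time point: the absolute difference between the
#' mean normalized signal of that time point's replicates and the mean over
#' all remaining samples, divided by the sum of the two groups' sample
#' standard deviations. A zero denominator yields score 0 when the means are
#' equal and `Inf` (flagged downstream) when they are not.
#'
#' @param m `RegionCountMatrix` with `time_point` metadata, >= 2 time points
#'   and >= 2 replicates per time point.
#' @return data.frame with columns region (row index), time_point, mean_t,
#'   mean_rest, sd_t, sd_rest, score, direction.
#' @export
score_regions <- function(m) {
  .check_design(m$samples)
  norm <- normalized_counts(m)
  .score_one_labeling(norm, as.character(m$samples$time_point))
}

# cap infinite scores at (max finite + 1) so quantiles and ranks are defined
cap_scores <- function(s) {
  inf <- is.infinite(s)
  if (any(inf)) {
    fin <- s[!inf]
    s[inf] <- if (length(fin)) max(fin) + 1 else 1
  }
  s
}

#' Build a replicate-permutation null for the differential score
#'
#' Sample-to-time-point labels are shuffled uniformly over all samples
#' (full exchangeability) `n_permutations` times; all region x time scores
#' are recomputed each time. Two empirical thresholds are retained: the
#' (1-alpha) quantile of all pooled permuted scores (`score_threshold`), and
#' the (1-alpha) quantile of the per-region maximum permuted score
#' (`threshold`), which is the one used for calling so that a fraction alpha
#' of null regions is called.
#'
#' @param m `RegionCountMatrix`
#' @param n_permutations integer >= 1 (default 1000)
#' @param alpha upper-tail level in (0,1) (default 0.05)
#' @param seed integer RNG seed (mandatory: the null must be reproducible)
#' @return a `PermutationNull`: list with `n_permutations`, `alpha`, `seed`,
#'   `threshold`, `score_threshold`, and `permuted_scores` /
#'   `permuted_max_scores` summaries.
#' @export
build_null <- function(m, n_permutations = 1000, alpha = 0.05, seed) {
  if (missing(seed)) stop("build_null: seed is mandatory")
  if (!(alpha > 0 && alpha < 1)) stop("build_null: alpha must be in (0,1)")
  if (n_permutations < 1) stop("build_null: n_permutations must be >= 1")
  .check_design(m$samples)
  norm <- normalized_counts(m)
  labels <- as.character(m$samples$time_point)
  nr <- nrow(norm)
  set.seed(seed)
  pooled <- vector("list", n_permutations)
  pooled_max <- vector("list", n_permutations)
  for (p in seq_len(n_permutations)) {
    perm <- sample(labels)
    sc <- .score_one_labeling(norm, perm)
    s <- cap_scores(sc$score)
    pooled[[p]] <- s
    pooled_max[[p]] <- tapply(s, sc$region, max)
  }
  pooled <- unlist(pooled, use.names = FALSE)
  pooled_max <- as.numeric(unlist(pooled_max, use.names = FALSE))
  structure(list(
    n_permutations = n_permutations, alpha = alpha, seed = seed,
    threshold = as.numeric(quantile(pooled_max, 1 - alpha, names = FALSE)),
    score_threshold = as.numeric(quantile(pooled, 1 - alpha, names = FALSE)),
    permuted_scores = pooled, permuted_max_scores = pooled_max),
    class = "PermutationNull")
}

#' @export
print.PermutationNull <- function(x, ...) {
  cat(sprintf(paste0("PermutationNull: %d permutations, alpha = %g,\n",
                     "  call threshold (max statistic) = %.4g,",
                     " per-score threshold = %.4g\n"),
              x$n_permutations, x$alpha, x$threshold, x$score_threshold))
  invisible(x)
}

#' Call differential regions against a permutation null
#'
#' A region is called differential when the maximum over time points of its
#' (infinity-capped) score exceeds the null's calling threshold.
#'
#' @param scores data.frame from [score_regions()]
#' @param null `PermutationNull` built from the same matrix
#' @param regions `RegionSet` the scores refer to
#' @return list with `regions` (called subset, score column = max score),
#'   `report` (per region: max_score, time_point of the maximum, direction,
#'   called, any_infinite) and `threshold`.
#' @export
call_differential <- function(scores, null, regions) {
  s <- scores
  s$capped <- cap_scores(s$score)
  ord <- order(s$region, -s$capped, s$time_point, method = "radix")
  s <- s[ord, , drop = FALSE]
  first <- !duplicated(s$region)
  rep_df <- data.frame(
    region = s$region[first],
    max_score = s$capped[first],
    time_point = s$time_point[first],
    direction = s$direction[first],
    any_infinite = as.logical(tapply(is.infinite(scores$score), scores$region,
                                     any)[as.character(s$region[first])]),
    stringsAsFactors = FALSE)
  rep_df <- rep_df[order(rep_df$region), , drop = FALSE]
  rep_df$called <- rep_df$max_score > null$threshold
  called <- regions[rep_df$region[rep_df$called]]
  called$intervals$score <- rep_df$max_score[rep_df$called]
  called$name <- paste0(regions$name, ".differential")
  list(regions = called, report = rep_df, threshold = null$threshold)
}

#' Presence/absence pattern of a region across time points
#'
#' Descriptive companion to the amplitude score: a region is "present" at a
#' time point when its mean normalized signal there exceeds `min_rpm`.
#'
#' @param m `RegionCountMatrix`
#' @param min_rpm presence cutoff in RPM units (default 1)
#' @return data.frame region x time_point with logical `present`.
#' @export
presence_pattern <- function(m, min_rpm = 1) {
  norm <- normalized_counts(m)
  tps <- sort(unique(as.character(m$samples$time_point)))
  out <- lapply(tps, function(tp) {
    idx <- which(m$samples$time_point == tp)
    data.frame(region = seq_len(nrow(norm)), time_point = tp,
               present = rowMeans(norm[, idx, drop = FALSE]) > min_rpm,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
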