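# Transformation-specific ("differential") TF binding-site calling:
# treated subpeaks that (i) do not touch any control subpeak and (ii) have a
# smoothed RPM fold change above mean + k_sd * sd of all treated subpeaks.

#' Smoothed fold change between treated and control signal
#'
#' `FC = ((count_treated + smoothing) / lib_treated) /
#'       ((count_control + smoothing) / lib_control)`.
#' The pseudocount is added to the raw counts before library scaling; the
#' per-million factors cancel.
#'
#' @param count_treated,count_control raw read counts (>= 0), vectorized
#' @param lib_treated,lib_control mapped-read totals (> 0)
#' @param smoothing pseudocount added to both counts (default 10)
#' @return numeric fold change(s), always finite and > 0.
#' @export
fold_change <- function(count_treated, lib_treated, count_control, lib_control,
                        smoothing = 10) {
  if (any(lib_treated <= 0) || any(lib_control <= 0))
    stop("fold_change: library sizes must be > 0")
  if (any(count_treated < 0) || any(count_control < 0))
    stop("fold_change: counts must be >= 0")
  if (any(smoothing <= 0)) stop("fold_change: smoothing must be > 0")
  ((count_treated + smoothing) / lib_treated) /
    ((count_control + smoothing) / lib_control)
}

#' Configuration for differential subpeak calling
#'
#' @param peak_p_threshold minimum -log10 p for input subpeaks (default 9,
#'   i.e. p <= 1e-9); subpeaks below it are dropped before calling.
#' @param smoothing fold-change pseudocount (default 10)
#' @param k_sd multiplier on the fold-change standard deviation (default 1)
#' @param min_fold_change optional extra floor on the fold change (e.g. 5);
#'   `NULL` (default) disables it.
#' @return a `DifferentialCallConfig` list.
#' @export
differential_call_config <- function(peak_p_threshold = 9, smoothing = 10,
                                     k_sd = 1, min_fold_change = NULL) {
  if (peak_p_threshold <= 0 || smoothing <= 0 || k_sd <= 0)
    stop("differential_call_config: all parameters must be > 0")
  structure(list(peak_p_threshold = peak_p_threshold, smoothing = smoothing,
                 k_sd = k_sd, min_fold_change = min_fold_change),
            class = "DifferentialCallConfig")
}

#' Call differential (treatment-specific) subpeaks
#'
#' A treated subpeak is called differential iff it shares no base pair with
#' any control subpeak AND its smoothed fold change exceeds
#' `mean(FC) + k_sd * sd(FC)` computed over ALL treated subpeaks of the same
#' population (sample/time point). Both sets are first filtered to the
#' configured -log10 p threshold (score column).
#'
#' @param treated `RegionSet` of treated subpeaks; `score` = -log10 p.
#' @param control `RegionSet` of control subpeaks, same convention.
#' @param fc data.frame covering every treated subpeak after filtering, with
#'   columns `count_treated`, `count_control`, `lib_treated`, `lib_control`
#'   (row order = filtered treated order), or a precomputed numeric vector of
#'   fold changes.
#' @param cfg `DifferentialCallConfig`
#' @return list with `regions` (called `RegionSet`, score column = fold
#'   change) and `report` (per treated subpeak: fold_change, overlaps_control,
#'   fc_cutoff, called, exclusion_reason).
#' @export
call_differential_peaks <- function(treated, control, fc,
                                    cfg = differential_call_config()) {
  keep_t <- !is.na(treated$intervals$score) &
    treated$intervals$score >= cfg$peak_p_threshold
  keep_c <- !is.na(control$intervals$score) &
    control$intervals$score >= cfg$peak_p_threshold
  treated_f <- treated[which(keep_t)]
  control_f <- control[which(keep_c)]
  n <- length(treated_f)
  if (n < 2)
    stop("call_differential_peaks: need >= 2 treated subpeaks after ",
         "filtering (population sd undefined)")
  if (is.data.frame(fc)) {
    if (nrow(fc) != n)
      stop("call_differential_peaks: fc must cover every filtered treated ",
           "subpeak")
    fcv <- fold_change(fc$count_treated, fc$lib_treated,
                       fc$count_control, fc$lib_control, cfg$smoothing)
  } else {
    fcv <- as.numeric(fc)
    if (length(fcv) != n)
      stop("call_differential_peaks: fc must cover every filtered treated ",
           "subpeak")
  }
  cutoff <- mean(fcv) + cfg$k_sd * sd(fcv)
  ov <- region_overlaps(treated_f, control_f)$flags
  pass_fc <- fcv > cutoff
  if (!is.null(cfg$min_fold_change))
    pass_fc <- pass_fc & (fcv > cfg$min_fold_change)
  called <- !ov & pass_fc
  reason <- rep("", n)
  reason[ov] <- "overlaps_control"
  reason[!ov & !pass_fc] <- "below_fc_cutoff"
  out <- treated_f[which(called)]
  out$intervals$score <- fcv[called]
  out$name <- paste0(treated$name, ".differential")
  list(regions = out,
       report = data.frame(treated_f$intervals[, c("chrom", "start", "end")],
                           fold_change = fcv, overlaps_control = ov,
                           fc_cutoff = cutoff, called = called,
                           exclusion_reason = reason,
                           stringsAsFactors = FALSE))
}
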