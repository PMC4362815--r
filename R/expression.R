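# Differential expression across the 2x2 treatment x siRNA design, STAT3-
# dependence classification, and differential-peak density per ranked gene.

#' Construct an expression matrix with its design table
#'
#' @param values numeric genes x samples matrix of log2 expression; rownames
#'   = gene ids.
#' @param design data.frame with one row per sample: `sample_id`, `treatment`
#'   (e.g. EtOH/TAM), `sirna` (e.g. siSCM/siSTAT3), `time`, `replicate`.
#' @return an `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, design) {
  values <- as.matrix(values)
  need <- c("sample_id", "treatment", "sirna", "time", "replicate")
  if (!all(need %in% names(design)))
    stop("expression_matrix: design needs ", paste(need, collapse = ", "))
  if (ncol(values) != nrow(design))
    stop("expression_matrix: values columns must match design rows")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("gene_%d", seq_len(nrow(values)))
  colnames(values) <- design$sample_id
  structure(list(values = values, design = design),
            class = "ExpressionMatrix")
}

# Vectorized Welch two-sample t-test on rows of two matrices.
welch_rows <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(-abs(t), df)
  p[se2 == 0 & (mx == my)] <- 1
  p[se2 == 0 & (mx != my)] <- 0
  data.frame(log2fc = mx - my, t = t, df = df, p = p)
}

.expr_group <- function(expr, treatment, sirna, time) {
  d <- expr$design
  idx <- which(d$treatment == treatment & d$sirna == sirna & d$time == time)
  expr$values[, idx, drop = FALSE]
}

#' Call transformation-differential genes at one time point
#'
#' Welch two-sample t-test of TAM vs EtOH on log2 values under the control
#' siRNA; a gene is differential iff `p < p_threshold` AND
#' `|log2fc| > lfc_threshold` (a pure conjunction; no multiple-testing
#' correction by default, matching the raw-threshold rule).
#'
#' @param expr `ExpressionMatrix`
#' @param time time point label present in the design.
#' @param treatment_levels `c(control, treated)` labels
#'   (default `c("EtOH","TAM")`); log2fc = mean(treated) - mean(control).
#' @param sirna control siRNA label (default "siSCM").
#' @param p_threshold raw p cutoff (default 1e-4).
#' @param lfc_threshold absolute log2 fold-change cutoff (default 0.5).
#' @param fdr apply Benjamini-Hochberg to the p-values first (default FALSE).
#' @return data.frame: gene_id, time, log2fc, p, differential, direction.
#' @export
call_differential_genes <- function(expr, time,
                                    treatment_levels = c("EtOH", "TAM"),
                                    sirna = "siSCM", p_threshold = 1e-4,
                                    lfc_threshold = 0.5, fdr = FALSE) {
  x <- .expr_group(expr, treatment_levels[2], sirna, time)
  y <- .expr_group(expr, treatment_levels[1], sirna, time)
  if (ncol(x) < 2 || ncol(y) < 2)
    stop("call_differential_genes: need >= 2 replicates per treatment group")
  w <- welch_rows(x, y)
  p <- if (fdr) stats::p.adjust(w$p, "BH") else w$p
  data.frame(gene_id = rownames(expr$values), time = time,
             log2fc = w$log2fc, p = p,
             differential = p < p_threshold & abs(w$log2fc) > lfc_threshold,
             direction = ifelse(w$log2fc >= 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Classify knockdown dependence of differential genes
#'
#' For each gene differential under the control siRNA, the TAM-vs-EtOH
#' contrast is re-evaluated under the knockdown siRNA:
#' \itemize{
#'   \item dependent — the effect disappears: non-significant
#'     (`p >= p_threshold`) AND `|log2fc| < lfc_threshold` under knockdown;
#'   \item independent — the effect persists: significant AND
#'     `|log2fc| > lfc_threshold` under knockdown (the stated
#'     "independent" rule);
#'   \item ambiguous — anything in between.
#' }
#' Genes not differential under the control siRNA get status `NA`.
#'
#' @param expr `ExpressionMatrix`
#' @param de_calls data.frame from [call_differential_genes()]
#' @param knockdown_sirna knockdown label (default "siSTAT3")
#' @param treatment_levels,p_threshold,lfc_threshold as in
#'   [call_differential_genes()]
#' @return data.frame: gene_id, time, status, log2fc_control, log2fc_knockdown,
#'   p_knockdown.
#' @export
classify_stat3_dependence <- function(expr, de_calls,
                                      knockdown_sirna = "siSTAT3",
                                      treatment_levels = c("EtOH", "TAM"),
                                      p_threshold = 1e-4,
                                      lfc_threshold = 0.5) {
  time <- unique(de_calls$time)
  if (length(time) != 1)
    stop("classify_stat3_dependence: de_calls must be from a single time")
  x <- .expr_group(expr, treatment_levels[2], knockdown_sirna, time)
  y <- .expr_group(expr, treatment_levels[1], knockdown_sirna, time)
  if (ncol(x) < 2 || ncol(y) < 2)
    stop("classify_stat3_dependence: need >= 2 replicates per group under ",
         knockdown_sirna)
  w <- welch_rows(x, y)
  sig <- w$p < p_threshold
  big <- abs(w$log2fc) > lfc_threshold
  small <- abs(w$log2fc) < lfc_threshold
  status <- rep(NA_character_, nrow(de_calls))
  de <- de_calls$differential
  status[de & !sig & small] <- "dependent"
  status[de & sig & big] <- "independent"
  status[de & is.na(status)] <- "ambiguous"
  data.frame(gene_id = de_calls$gene_id, time = time, status = status,
             log2fc_control = de_calls$log2fc, log2fc_knockdown = w$log2fc,
             p_knockdown = w$p, stringsAsFactors = FALSE)
}

#' Rolling mean with a centered, edge-truncated window
#' @param x numeric series
#' @param window window size in elements (default 1000)
#' @return numeric vector, same length; each element averages the window
#'   centered on it, truncated at the series edges.
#' @export
rolling_mean <- function(x, window = 1000) {
  if (window < 1) stop("rolling_mean: window must be >= 1")
  n <- length(x)
  half_lo <- floor((window - 1) / 2)
  half_hi <- ceiling((window - 1) / 2)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1)
  hi <- pmin(i + half_hi, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Differential-peak density per gene, with rolling means over ranked genes
#'
#' For each gene, counts differential-peak summits in a strand-aware promoter
#' window and in flanking windows (+/- `flank_bp` of the TSS, excluding the
#' promoter), normalizes to peaks per kbp of window, ranks genes by
#' descending log2 fold change and smooths each density with a rolling mean.
#'
#' @param de_calls data.frame with `gene_id` and `log2fc` (ranking key); when
#'   several rows share a gene_id the lowest-p row is kept (needs a `p`
#'   column).
#' @param genes `GeneSet`
#' @param diff_peaks `RegionSet` of differential peaks (summits used;
#'   midpoints when absent).
#' @param promoter_window `c(upstream, downstream)` bp (default
#'   `c(2500, 500)`).
#' @param flank_bp flank half-width (default 50000).
#' @param rolling rolling-mean window in genes (default 1000).
#' @return data.frame ranked by log2fc: rank, gene_id, log2fc,
#'   promoter_density, flank_density (peaks per kbp), rolling_promoter,
#'   rolling_flank.
#' @export
peak_density_profile <- function(de_calls, genes, diff_peaks,
                                 promoter_window = c(2500, 500),
                                 flank_bp = 50000, rolling = 1000) {
  dc <- de_calls
  if (anyDuplicated(dc$gene_id)) {
    if (!"p" %in% names(dc))
      stop("peak_density_profile: duplicate gene ids need a p column")
    dc <- dc[order(dc$gene_id, dc$p), ]
    dc <- dc[!duplicated(dc$gene_id), ]
  }
  dc <- dc[dc$gene_id %in% genes$gene_id, , drop = FALSE]
  dc <- dc[order(-dc$log2fc, dc$gene_id), , drop = FALSE]
  sm <- .summits_of(diff_peaks)
  g <- genes[match(dc$gene_id, genes$gene_id), , drop = FALSE]
  prom_len_kb <- sum(promoter_window) / 1000
  n <- nrow(dc)
  prom_d <- numeric(n)
  flank_d <- numeric(n)
  for (i in seq_len(n)) {
    plus <- g$strand[i] == "+"
    tss <- g$tss[i]
    pr <- if (plus) c(tss - promoter_window[1], tss + promoter_window[2])
          else c(tss - promoter_window[2], tss + promoter_window[1])
    fl <- c(tss - flank_bp, tss + flank_bp)
    on_chr <- sm$chrom == g$chrom[i]
    inp <- on_chr & sm$pos >= pr[1] & sm$pos < pr[2]
    infl <- on_chr & sm$pos >= fl[1] & sm$pos < fl[2] & !inp
    prom_d[i] <- sum(inp) / prom_len_kb
    flank_d[i] <- sum(infl) / ((2 * flank_bp - sum(promoter_window)) / 1000)
  }
  data.frame(rank = seq_len(n), gene_id = dc$gene_id, log2fc = dc$log2fc,
             promoter_density = prom_d, flank_density = flank_d,
             rolling_promoter = rolling_mean(prom_d, rolling),
             rolling_flank = rolling_mean(flank_d, rolling),
             stringsAsFactors = FALSE)
}
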