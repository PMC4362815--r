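# Shared fixtures and independent oracles. Oracles are deliberately naive
# (per-base arrays, all-pairs scans, exhaustive enumeration) and never share
# code with the implementation paths they check.

random_intervals <- function(n, chrom_len = 1e5, chroms = "c1",
                             max_width = 500) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- floor(runif(n, 0, chrom_len - max_width - 1))
  width <- pmax(1, floor(runif(n, 1, max_width)))
  data.frame(chrom = chrom, start = start, end = start + width,
             name = sprintf("iv%04d", seq_len(n)), stringsAsFactors = FALSE)
}

# per-base boolean coverage of a set of intervals on one toy chromosome
coverage_oracle <- function(df, chrom_len) {
  covered <- logical(chrom_len)
  for (i in seq_len(nrow(df)))
    covered[(df$start[i] + 1):df$end[i]] <- TRUE
  covered
}

# all-pairs overlap flags of a against b (>= 1 shared bp, half-open)
overlap_oracle <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

# exhaustive PWM tail probability over all 4^W W-mers, on the same rounded
# score grid the DP uses
enumeration_pvalue <- function(p, score, precision = 1e-3) {
  L <- chromdiff::score_matrix(p)
  I <- matrix(as.integer(round(L / precision)), nrow = nrow(L))
  W <- nrow(I)
  grid <- expand.grid(rep(list(1:4), W))
  tot <- as.integer(as.matrix(grid) %*% rep(1L, W) * 0L) # init zeros
  pr <- rep(1, nrow(grid))
  for (w in seq_len(W)) {
    tot <- tot + I[w, grid[[w]]]
    pr <- pr * p$background[grid[[w]]]
  }
  k <- as.integer(round(score / precision))
  sum(pr[tot >= k])
}

# naive O(n^3) average-linkage merge heights on a dissimilarity matrix
naive_average_linkage <- function(d) {
  n <- ncol(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- Inf; bi <- bj <- 0
    for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < best) { best <- dij; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    merged <- c(clusters[[bi]], clusters[[bj]])
    clusters <- c(clusters[-c(bi, bj)], list(merged))
  }
  heights
}

toy_genes <- function() {
  gene_set(data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("c1", "c1", "c2"),
    strand = c("+", "-", "+"),
    tx_start = c(100000, 300000, 50000),
    tx_end = c(120000, 320000, 70000),
    stringsAsFactors = FALSE))
}

# expression fixture with groups set to exact values (3 reps per cell)
fixed_expression <- function(etoh_scm, tam_scm, etoh_kd, tam_kd,
                             time = "4h") {
  ng <- nrow(etoh_scm)
  design <- expand.grid(replicate = 1:3,
                        treatment = c("EtOH", "TAM"),
                        sirna = c("siSCM", "siSTAT3"),
                        time = time, stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_%s_%s_r%d", design$treatment, design$sirna,
                              design$time, design$replicate)
  values <- matrix(NA_real_, nrow = ng, ncol = nrow(design))
  rownames(values) <- sprintf("g%03d", seq_len(ng))
  put <- function(block, treatment, sirna) {
    idx <- which(design$treatment == treatment & design$sirna == sirna)
    values[, idx] <<- block
  }
  put(etoh_scm, "EtOH", "siSCM"); put(tam_scm, "TAM", "siSCM")
  put(etoh_kd, "EtOH", "siSTAT3"); put(tam_kd, "TAM", "siSTAT3")
  expression_matrix(values, design)
}
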