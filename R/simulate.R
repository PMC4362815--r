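# Synthetic data with known ground truth for every pipeline stage: a toy
# genome with genes, negative-binomial FAIRE count matrices with planted
# amplitude changes, motif instances with a logistic binding model stratified
# by open chromatin, and a 2x2 treatment x siRNA expression design with
# planted knockdown-dependent effects.
#
# All randomness flows through set.seed(cfg$seed + stage offset); offsets:
# genome +1, faire +2, chip +3, expression +4. Draw order inside each stage
# is fixed and documented inline, so outputs are bit-identical per seed.

#' Simulation configuration
#'
#' Defaults state the simulated world: a 10-Mb toy chromosome; ~17% of open
#' chromatin sites given a 3x amplitude change at one time point of a
#' 4 time point x 3 replicate negative-binomial design (mean 100, size 25,
#' i.e. replicate CV ~22%); motif binding probability logistic in motif score
#' inside open chromatin and damped 10x outside; and a 2x2 EtOH/TAM x
#' siSCM/siSTAT3 expression design with effect 1.5 log2 units and residual
#' sd 0.2.
#'
#' @param seed integer seed (mandatory).
#' @param chrom_lengths named vector (default `c(chrS = 1e7)`).
#' @param base_composition A/C/G/T probabilities of the background sequence.
#' @param n_genes genes to place (default 200).
#' @param gene_length_range transcript length range, bp.
#' @param n_faire_sites open-chromatin regions (default 2000).
#' @param site_width_range FAIRE site width range, bp.
#' @param fraction_differential planted differential fraction (default 0.17).
#' @param n_time_points,n_replicates design shape (default 4 x 3).
#' @param nb_mean,nb_dispersion negative-binomial mean and size of site
#'   counts at the reference library size.
#' @param effect_multiplier amplitude multiplier at the affected time point
#'   (default 3).
#' @param library_size reference mapped reads per sample (default 2e7);
#'   per-sample sizes jittered +/-10%.
#' @param n_motif_instances planted motif instances (default 20000).
#' @param frac_instances_open fraction planted inside open chromatin (0.5).
#' @param motif_emit_prob probability an instance sequence is emitted from
#'   the PWM rather than the background (0.5; spreads scores over the range).
#' @param binding_slope,binding_intercept logistic binding model on motif
#'   score (bits): `P(bound | open) = plogis(intercept + slope * score)`.
#' @param closed_factor multiplier on the binding probability outside open
#'   chromatin (default 0.1).
#' @param peak_halfwidth subpeak half-width, bp (default 150).
#' @param control_bound_frac fraction of bound instances also bound in the
#'   non-transformed control (default 0.3).
#' @param chip_mu_bound,chip_mu_unbound NB means of treated/control counts at
#'   bound and unbound sites.
#' @param n_expr_genes,frac_dependent,frac_independent expression generator
#'   shape (default 1000 genes, 20% dependent, 20% independent).
#' @param expr_effect,expr_sd planted log2 effect and residual sd
#'   (default 1.5, 0.2).
#' @param expr_baseline_mean,expr_baseline_sd per-gene baseline distribution.
#' @param expr_times time labels (default `c("4h", "24h")`).
#' @return a `SimulationConfig` list.
#' @export
sim_config <- function(seed,
                       chrom_lengths = c(chrS = 1e7),
                       base_composition = rep(0.25, 4),
                       n_genes = 200,
                       gene_length_range = c(2000, 20000),
                       n_faire_sites = 2000,
                       site_width_range = c(200, 1000),
                       fraction_differential = 0.17,
                       n_time_points = 4,
                       n_replicates = 3,
                       nb_mean = 100,
                       nb_dispersion = 25,
                       effect_multiplier = 3,
                       library_size = 2e7,
                       n_motif_instances = 20000,
                       frac_instances_open = 0.5,
                       motif_emit_prob = 0.5,
                       binding_slope = 0.6,
                       binding_intercept = -5.5,
                       closed_factor = 0.1,
                       peak_halfwidth = 150,
                       control_bound_frac = 0.3,
                       chip_mu_bound = 200,
                       chip_mu_unbound = 20,
                       n_expr_genes = 1000,
                       frac_dependent = 0.2,
                       frac_independent = 0.2,
                       expr_effect = 1.5,
                       expr_sd = 0.2,
                       expr_baseline_mean = 8,
                       expr_baseline_sd = 1.5,
                       expr_times = c("4h", "24h")) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  cfg <- as.list(environment())
  rates <- c(cfg$fraction_differential, cfg$frac_instances_open,
             cfg$motif_emit_prob, cfg$closed_factor, cfg$control_bound_frac,
             cfg$frac_dependent, cfg$frac_independent)
  if (any(rates < 0 | rates > 1)) stop("sim_config: rates must be in [0,1]")
  if (cfg$frac_dependent + cfg$frac_independent > 1)
    stop("sim_config: dependent + independent fractions exceed 1")
  if (cfg$n_genes < 0) stop("sim_config: n_genes must be >= 0")
  counts <- c(cfg$n_faire_sites, cfg$n_time_points,
              cfg$n_replicates, cfg$nb_mean, cfg$nb_dispersion,
              cfg$library_size, cfg$n_motif_instances, cfg$n_expr_genes)
  if (any(counts <= 0)) stop("sim_config: counts and scales must be > 0")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' The default synthetic motif (a STAT-like palindromic 10-mer)
#' @param informativeness probability mass on the consensus base per
#'   informative position (default 0.85).
#' @return `PWM`
#' @export
default_sim_pwm <- function(informativeness = 0.85) {
  consensus <- c("T", "T", "C", "C", "C", "G", "G", "G", "A", "A")
  W <- length(consensus)
  m <- matrix((1 - informativeness) / 3, nrow = W, ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_len(W), match(consensus, colnames(m)))] <- informativeness
  pwm(m, motif_id = "synthetic_stat_like")
}

#' Simulate the toy genome: chromosome sizes, sequence and gene models
#'
#' Background sequence is i.i.d. at the configured base composition. Genes
#' are placed in equal slots along each chromosome (so basal regulatory
#' domains never overlap), with random strand and 2-5 exons.
#'
#' Draw order: per chromosome sequence; then per gene (strand, length,
#' offset, exon count, exon boundaries).
#'
#' @param cfg `SimulationConfig`
#' @return list with `genome` (`ChromSizes`), `sequences` (named character),
#'   `genes` (`GeneSet`).
#' @export
simulate_genome <- function(cfg) {
  set.seed(cfg$seed + 1)
  genome <- chrom_sizes(cfg$chrom_lengths)
  sequences <- vapply(names(genome), function(ch) {
    paste(sample(c("A", "C", "G", "T"), genome[[ch]], replace = TRUE,
                 prob = cfg$base_composition), collapse = "")
  }, character(1))
  genes <- list()
  if (cfg$n_genes > 0) {
    per_chrom <- table(rep(names(genome), length.out = cfg$n_genes))
    gid <- 0
    for (ch in names(genome)) {
      ng <- as.integer(per_chrom[ch])
      if (is.na(ng) || ng == 0) next
      slot <- floor(genome[[ch]] / ng)
      margin <- 6000 # basal domain: 5 kb up + 1 kb down
      if (slot < max(cfg$gene_length_range) + 2 * margin)
        stop("simulate_genome: cannot place genes at requested density")
      for (k in seq_len(ng)) {
        gid <- gid + 1
        strand <- sample(c("+", "-"), 1)
        len <- round(runif(1, cfg$gene_length_range[1],
                           cfg$gene_length_range[2]))
        lo <- (k - 1) * slot + margin
        hi <- k * slot - margin - len
        tx_start <- round(runif(1, lo, hi))
        tx_end <- tx_start + len
        n_ex <- sample(2:5, 1)
        inner <- sort(sample(seq(tx_start + 100, tx_end - 100),
                             2 * (n_ex - 1)))
        bounds <- c(tx_start, inner, tx_end)
        es <- bounds[seq(1, length(bounds), by = 2)]
        ee <- bounds[seq(2, length(bounds), by = 2)]
        genes[[gid]] <- data.frame(
          gene_id = sprintf("gene_%04d", gid), chrom = ch, strand = strand,
          tx_start = tx_start, tx_end = tx_end, stringsAsFactors = FALSE)
        genes[[gid]]$exon_starts <- list(es)
        genes[[gid]]$exon_ends <- list(ee)
      }
    }
  }
  gs <- if (length(genes)) gene_set(do.call(rbind, genes)) else
    gene_set(data.frame(gene_id = character(0), chrom = character(0),
                        strand = character(0), tx_start = numeric(0),
                        tx_end = numeric(0))[FALSE, ])
  list(genome = genome, sequences = sequences, genes = gs)
}

#' Simulate FAIRE site counts with planted amplitude changes
#'
#' Non-overlapping sites are placed uniformly; counts are negative binomial
#' with mean proportional to the per-sample library size. A planted fraction
#' of sites has its mean multiplied by `effect_multiplier` at one uniformly
#' chosen time point.
#'
#' Draw order: library sizes; site widths; site gaps; differential flags
#' (first `round(fraction * n)` sites after a permutation); affected time
#' points; counts column by column.
#'
#' @param cfg `SimulationConfig`
#' @param genome list from [simulate_genome()] (only `genome` used).
#' @return list with `matrix` (`RegionCountMatrix`) and `truth` (data.frame:
#'   region, differential, time_point).
#' @export
simulate_faire_counts <- function(cfg, genome) {
  set.seed(cfg$seed + 2)
  g <- genome$genome
  n <- cfg$n_faire_sites
  tps <- sprintf("t%d", seq_len(cfg$n_time_points))
  samples <- data.frame(
    sample_id = sprintf("faire_%s_r%d",
                        rep(tps, each = cfg$n_replicates),
                        rep(seq_len(cfg$n_replicates), cfg$n_time_points)),
    assay = "FAIRE",
    time_point = rep(tps, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), cfg$n_time_points),
    stringsAsFactors = FALSE)
  ns <- nrow(samples)
  samples$library_size <- round(cfg$library_size * runif(ns, 0.9, 1.1))
  # distribute sites over chromosomes proportionally to length
  per_chrom <- round(n * as.numeric(g) / sum(as.numeric(g)))
  per_chrom[length(per_chrom)] <- n - sum(per_chrom[-length(per_chrom)])
  names(per_chrom) <- names(g)
  sites <- list()
  for (ch in names(g)) {
    k <- per_chrom[[ch]]
    if (k <= 0) next
    w <- round(runif(k, cfg$site_width_range[1], cfg$site_width_range[2]))
    free <- g[[ch]] - sum(w)
    if (free <= k) stop("simulate_faire_counts: sites do not fit")
    gaps <- floor(free * diff(c(0, sort(runif(k)))))
    starts <- cumsum(gaps) + cumsum(c(0, w[-k]))
    sites[[ch]] <- data.frame(chrom = ch, start = starts, end = starts + w,
                              stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, sites)
  sites$name <- sprintf("faire_%05d", seq_len(nrow(sites)))
  regions <- region_set(sites, genome = g, name = "faire_union")
  # planted truth (indices refer to sorted region order)
  n_diff <- round(cfg$fraction_differential * n)
  diff_idx <- sample(n, n_diff)
  differential <- seq_len(n) %in% diff_idx
  affected <- rep(NA_character_, n)
  affected[differential] <- sample(tps, n_diff, replace = TRUE)
  mu_base <- cfg$nb_mean * samples$library_size / cfg$library_size
  counts <- matrix(0L, nrow = n, ncol = ns,
                   dimnames = list(NULL, samples$sample_id))
  for (j in seq_len(ns)) {
    mu <- rep(mu_base[j], n)
    hit <- differential & affected == samples$time_point[j]
    mu[hit] <- mu[hit] * cfg$effect_multiplier
    counts[, j] <- rnbinom(n, mu = mu, size = cfg$nb_dispersion)
  }
  truth <- data.frame(region = seq_len(n), name = regions$intervals$name,
                      differential = differential, time_point = affected,
                      stringsAsFactors = FALSE)
  list(matrix = region_count_matrix(regions, samples, counts), truth = truth)
}

#' Simulate motif instances, TF binding and ChIP subpeaks
#'
#' Motif instances are planted inside open chromatin (fraction
#' `frac_instances_open`) and outside it; each instance sequence is emitted
#' from the PWM with probability `motif_emit_prob`, else from the background,
#' and scored. Binding is Bernoulli with
#' `P = plogis(intercept + slope * score)` inside open chromatin and
#' `closed_factor` times that outside. Bound instances emit treated subpeaks
#' (summit at the instance center); a fraction is also bound in the control.
#' Instance sequences are implanted into the genome sequence so scanning the
#' emitted FASTA recovers them.
#'
#' Draw order: instance open flags; positions; emission flags; sequences;
#' binding draws; control-bound draws; subpeak -log10 p scores; treated,
#' control then input counts; library sizes.
#'
#' @param cfg `SimulationConfig`
#' @param genome list from [simulate_genome()]
#' @param faire `RegionSet` of open chromatin (e.g. simulated FAIRE regions).
#' @param pwm_obj `PWM` (default [default_sim_pwm()]).
#' @return list with `instances` (truth table: chrom, start, end, strand,
#'   score, in_open_chromatin, bound, control_bound, p_bound), `treated` and
#'   `control` subpeak `RegionSet`s, `chip_counts` (data.frame with
#'   count_treated/count_control per treated subpeak), `lib_treated`,
#'   `lib_control`, and `sequences` (genome sequences with instances
#'   implanted).
#' @export
simulate_chip <- function(cfg, genome, faire, pwm_obj = default_sim_pwm()) {
  set.seed(cfg$seed + 3)
  g <- genome$genome
  W <- pwm_obj$width
  n <- cfg$n_motif_instances
  fdf <- faire$intervals
  fdf <- fdf[(fdf$end - fdf$start) >= W, , drop = FALSE]
  if (!nrow(fdf)) stop("simulate_chip: no open region can hold the motif")
  open <- runif(n) < cfg$frac_instances_open
  chrom <- character(n)
  start <- numeric(n)
  # open instances: uniform over FAIRE intervals wide enough
  oi <- which(open)
  if (length(oi)) {
    pick <- sample(nrow(fdf), length(oi), replace = TRUE)
    chrom[oi] <- fdf$chrom[pick]
    start[oi] <- floor(fdf$start[pick] +
                         runif(length(oi)) * (fdf$end[pick] - fdf$start[pick] - W))
  }
  # closed instances: rejection-sample positions clear of open chromatin
  ci <- which(!open)
  if (length(ci)) {
    lens <- as.numeric(g)
    todo <- ci
    while (length(todo)) {
      ch_i <- sample(length(g), length(todo), replace = TRUE,
                     prob = lens / sum(lens))
      pos <- floor(runif(length(todo)) * (lens[ch_i] - W))
      cand <- region_set(data.frame(chrom = names(g)[ch_i], start = pos,
                                    end = pos + W,
                                    name = as.character(seq_along(todo))),
                         name = "cand")
      bad_sorted <- region_overlaps(cand, faire)$flags
      bad <- logical(length(todo))
      bad[as.integer(cand$intervals$name)] <- bad_sorted
      ok <- !bad
      chrom[todo[ok]] <- names(g)[ch_i[ok]]
      start[todo[ok]] <- pos[ok]
      todo <- todo[!ok]
    }
  }
  emit <- runif(n) < cfg$motif_emit_prob
  seqs <- character(n)
  for (i in seq_len(n)) {
    probs <- if (emit[i]) pwm_obj$freq else
      matrix(pwm_obj$background, nrow = W, ncol = 4, byrow = TRUE)
    seqs[i] <- paste(vapply(seq_len(W), function(w)
      sample(c("A", "C", "G", "T"), 1, prob = probs[w, ]), character(1)),
      collapse = "")
  }
  score <- score_site(pwm_obj, seqs)
  p_open <- stats::plogis(cfg$binding_intercept + cfg$binding_slope * score)
  p_bound <- ifelse(open, p_open, cfg$closed_factor * p_open)
  bound <- runif(n) < p_bound
  control_bound <- bound & (runif(n) < cfg$control_bound_frac)
  center <- floor(start + W / 2)
  hw <- cfg$peak_halfwidth
  mk_peaks <- function(sel, label) {
    if (!any(sel)) return(region_set(.empty_intervals(), genome = g,
                                     name = label))
    s <- pmax(center[sel] - hw, 0)
    e <- pmin(center[sel] + hw, g[chrom[sel]])
    region_set(data.frame(chrom = chrom[sel], start = s, end = e,
                          name = sprintf("%s_%05d", label, which(sel)),
                          score = 10 + round(stats::rexp(sum(sel), 0.1), 3),
                          strand = "*", summit = center[sel],
                          stringsAsFactors = FALSE),
               genome = g, name = label)
  }
  treated <- mk_peaks(bound, "treated")
  control <- mk_peaks(control_bound, "control")
  # counts follow the sorted order of the treated RegionSet; peak names carry
  # the originating instance index
  b_idx <- as.integer(sub(".*_", "", treated$intervals$name))
  nt <- length(b_idx)
  count_treated <- rnbinom(nt, mu = cfg$chip_mu_bound,
                           size = cfg$nb_dispersion)
  mu_ctrl <- ifelse(control_bound[b_idx], cfg$chip_mu_bound,
                    cfg$chip_mu_unbound)
  count_control <- rnbinom(nt, mu = mu_ctrl, size = cfg$nb_dispersion)
  count_input <- rnbinom(nt, mu = cfg$chip_mu_unbound,
                         size = cfg$nb_dispersion)
  libs <- round(cfg$library_size * runif(3, 0.9, 1.1))
  # implant instance sequences into the genome (vectorized: split the
  # chromosome once, overwrite instance windows, paste once); skipped when
  # the genome carries no sequences (sizes-only simulations)
  sequences <- genome$sequences
  if (!is.null(sequences)) for (ch in unique(chrom)) {
    v <- strsplit(sequences[[ch]], "")[[1]]
    ii <- which(chrom == ch)
    idx <- unlist(lapply(ii, function(i) start[i] + seq_len(W)))
    v[idx] <- unlist(strsplit(seqs[ii], ""))
    sequences[[ch]] <- paste(v, collapse = "")
  }
  instances <- data.frame(chrom = chrom, start = start, end = start + W,
                          strand = "+", sequence = seqs, score = score,
                          in_open_chromatin = open, bound = bound,
                          control_bound = control_bound, p_bound = p_bound,
                          stringsAsFactors = FALSE)
  list(instances = instances, treated = treated, control = control,
       chip_counts = data.frame(count_treated = count_treated,
                                count_control = count_control,
                                count_input = count_input,
                                lib_treated = libs[1], lib_control = libs[2],
                                lib_input = libs[3]),
       lib_treated = libs[1], lib_control = libs[2], sequences = sequences)
}

#' Simulate the 2x2 expression design with planted dependence structure
#'
#' Gene value = baseline + treatment effect + Normal(0, sd) noise, in log2
#' units. Dependent genes carry the effect only under the control siRNA;
#' independent genes under both siRNAs; the rest have no effect. Effect signs
#' are random per gene; effects apply at every time point.
#'
#' Draw order: baselines; status permutation; effect signs; noise
#' (genes x samples).
#'
#' @param cfg `SimulationConfig`
#' @return list with `expr` (`ExpressionMatrix`) and `truth` (gene_id,
#'   status, effect).
#' @export
simulate_expression <- function(cfg) {
  set.seed(cfg$seed + 4)
  ng <- cfg$n_expr_genes
  design <- expand.grid(replicate = seq_len(3),
                        treatment = c("EtOH", "TAM"),
                        sirna = c("siSCM", "siSTAT3"),
                        time = cfg$expr_times,
                        stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_%s_%s_r%d", design$treatment, design$sirna,
                              design$time, design$replicate)
  baseline <- rnorm(ng, cfg$expr_baseline_mean, cfg$expr_baseline_sd)
  nd <- round(cfg$frac_dependent * ng)
  ni <- round(cfg$frac_independent * ng)
  status <- rep("null", ng)
  lab_idx <- sample(ng, nd + ni)
  status[lab_idx[seq_len(nd)]] <- "dependent"
  status[lab_idx[nd + seq_len(ni)]] <- "independent"
  sign_ <- sample(c(-1, 1), ng, replace = TRUE)
  effect <- ifelse(status == "null", 0, sign_ * cfg$expr_effect)
  values <- matrix(baseline, nrow = ng, ncol = nrow(design))
  tam <- design$treatment == "TAM"
  scm <- design$sirna == "siSCM"
  for (j in seq_len(nrow(design))) {
    if (tam[j]) {
      add <- ifelse(status == "independent" | (status == "dependent" & scm[j]),
                    effect, 0)
      values[, j] <- values[, j] + add
    }
  }
  values <- values + matrix(rnorm(ng * nrow(design), 0, cfg$expr_sd),
                            nrow = ng)
  rownames(values) <- sprintf("gene_%05d", seq_len(ng))
  truth <- data.frame(gene_id = rownames(values), status = status,
                      effect = effect, stringsAsFactors = FALSE)
  list(expr = expression_matrix(values, design), truth = truth)
}

#' Write sequences as FASTA
#' @param sequences named character vector
#' @param path output path
#' @export
write_fasta <- function(sequences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(sequences)) {
    writeLines(paste0(">", ch), con)
    s <- sequences[[ch]]
    starts <- seq(1, nchar(s), by = 70)
    writeLines(substring(s, starts, pmin(starts + 69, nchar(s))), con)
  }
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path file path
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  structure(as.character(x), names = sub("\\s.*", "", names(x)))
}
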