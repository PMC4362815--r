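# Stage-based pipeline driver. Stages form a small DAG:
#   simulate -> {faire_diff, chip_diff, motif_scan} -> occupancy
#   simulate -> {annotate (also needs chip_diff), cooccupancy, expression}
# Each stage reads only files named in the manifest conventions below, so any
# stage can equally run on user-supplied files laid out the same way.

.STAGES <- c("simulate", "faire_diff", "chip_diff", "motif_scan", "occupancy",
             "annotate", "cooccupancy", "expression")

.STAGE_DEPS <- list(
  simulate = character(0),
  faire_diff = "simulate",
  chip_diff = "simulate",
  motif_scan = "simulate",
  occupancy = c("motif_scan", "simulate"),
  annotate = c("chip_diff", "simulate"),
  cooccupancy = "simulate",
  expression = c("simulate", "chip_diff"))

#' Pipeline configuration
#'
#' @param seed integer seed driving every stochastic stage.
#' @param outdir output directory (created if missing).
#' @param sim `SimulationConfig` (default `sim_config(seed)` with a smaller
#'   1-Mb chromosome, 500 sites and 2,000 motif instances so a full run stays
#'   fast; pass your own for larger worlds).
#' @param alpha,n_permutations differential-FAIRE null parameters.
#' @param chip `DifferentialCallConfig`.
#' @param motif_p_threshold scanning p-value cutoff (default 1e-4).
#' @param force overwrite existing outputs (default FALSE).
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(seed, outdir,
                            sim = NULL,
                            alpha = 0.05, n_permutations = 200,
                            chip = differential_call_config(),
                            motif_p_threshold = 1e-4,
                            force = FALSE) {
  if (missing(seed)) stop("pipeline_config: seed is mandatory")
  if (missing(outdir)) stop("pipeline_config: outdir is mandatory")
  if (is.null(sim))
    sim <- sim_config(seed, chrom_lengths = c(chrS = 1e6), n_genes = 20,
                      n_faire_sites = 500, n_motif_instances = 2000,
                      n_expr_genes = 500)
  structure(list(seed = seed, outdir = outdir, sim = sim, alpha = alpha,
                 n_permutations = n_permutations, chip = chip,
                 motif_p_threshold = motif_p_threshold, force = force),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from a JSON file
#'
#' Flat JSON with required `seed` and `outdir`; optional blocks `sim`, `chip`
#' and scalar fields override the defaults of [pipeline_config()].
#'
#' @param path JSON file
#' @return `PipelineConfig`
#' @export
read_pipeline_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(js$seed) || is.null(js$outdir))
    stop("pipeline config: required fields missing: ",
         paste(setdiff(c("seed", "outdir"), names(js)), collapse = ", "))
  sim <- NULL
  if (!is.null(js$sim)) {
    sim_args <- js$sim
    if (!is.null(sim_args$chrom_lengths))
      sim_args$chrom_lengths <- unlist(sim_args$chrom_lengths)
    sim <- do.call(sim_config, c(list(seed = js$seed), sim_args))
  }
  chip <- if (!is.null(js$chip)) do.call(differential_call_config, js$chip)
          else differential_call_config()
  args <- list(seed = js$seed, outdir = js$outdir, sim = sim, chip = chip)
  for (f in c("alpha", "n_permutations", "motif_p_threshold", "force"))
    if (!is.null(js[[f]])) args[[f]] <- js[[f]]
  do.call(pipeline_config, args)
}

.stage_outputs <- function(cfg) {
  o <- function(...) file.path(cfg$outdir, ...)
  list(
    simulate = c(o("genome.chrom.sizes"), o("genome.fa"), o("genes.tsv"),
                 o("faire.bed"), o("faire_counts.tsv"),
                 o("faire_counts.tsv.samples.tsv"), o("faire_truth.tsv"),
                 o("chip_treated.bed"), o("chip_control.bed"),
                 o("chip_counts.tsv"), o("motif_instances.tsv"),
                 o("motif.tsv"), o("expression.tsv"), o("expr_design.tsv"),
                 o("expr_truth.tsv")),
    faire_diff = c(o("differential_faire.bed"), o("faire_report.tsv")),
    chip_diff = c(o("differential_chip.bed"), o("chip_report.tsv")),
    motif_scan = o("motif_hits.tsv"),
    occupancy = o("occupancy.tsv"),
    annotate = c(o("tss_annotation.tsv"), o("regulatory_domains.tsv"),
                 o("gene_associations.tsv")),
    cooccupancy = c(o("overlap_summary.tsv"), o("signal_correlation.tsv"),
                    o("dataset_clustering.newick")),
    expression = c(o("de_calls.tsv"), o("stat3_dependence.tsv"),
                   o("peak_density_profile.tsv")))
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.check_deps <- function(stage, cfg) {
  outs <- .stage_outputs(cfg)
  for (dep in .STAGE_DEPS[[stage]]) {
    missing <- outs[[dep]][!file.exists(outs[[dep]])]
    if (length(missing))
      stop(sprintf(
        "run_stage('%s'): missing input %s - run stage '%s' first",
        stage, basename(missing[1]), dep))
  }
}

.run_simulate <- function(cfg) {
  o <- function(...) file.path(cfg$outdir, ...)
  gen <- simulate_genome(cfg$sim)
  fa <- simulate_faire_counts(cfg$sim, gen)
  pw <- default_sim_pwm()
  ch <- simulate_chip(cfg$sim, gen, fa$matrix$regions, pw)
  ex <- simulate_expression(cfg$sim)
  write_chrom_sizes(gen$genome, o("genome.chrom.sizes"))
  write_fasta(ch$sequences, o("genome.fa"))
  write_genes(gen$genes, o("genes.tsv"))
  write_bed(fa$matrix$regions, o("faire.bed"))
  write_count_matrix(fa$matrix, o("faire_counts.tsv"))
  .write_tsv(fa$truth, o("faire_truth.tsv"))
  write_bed(ch$treated, o("chip_treated.bed"))
  write_bed(ch$control, o("chip_control.bed"))
  .write_tsv(ch$chip_counts, o("chip_counts.tsv"))
  .write_tsv(ch$instances, o("motif_instances.tsv"))
  .write_tsv(as.data.frame(pw$freq), o("motif.tsv"))
  ev <- data.frame(gene_id = rownames(ex$expr$values), ex$expr$values,
                   check.names = FALSE)
  .write_tsv(ev, o("expression.tsv"))
  .write_tsv(ex$expr$design, o("expr_design.tsv"))
  .write_tsv(ex$truth, o("expr_truth.tsv"))
}

.run_faire_diff <- function(cfg) {
  o <- function(...) file.path(cfg$outdir, ...)
  genome <- read_chrom_sizes(o("genome.chrom.sizes"))
  regions <- read_bed(o("faire.bed"), genome, name = "faire_union")
  m <- read_count_matrix(o("faire_counts.tsv"), regions)
  scores <- score_regions(m)
  null <- build_null(m, n_permutations = cfg$n_permutations,
                     alpha = cfg$alpha, seed = cfg$seed + 10)
  res <- call_differential(scores, null, regions)
  write_bed(res$regions, o("differential_faire.bed"))
  .write_tsv(res$report, o("faire_report.tsv"))
}

.run_chip_diff <- function(cfg) {
  o <- function(...) file.path(cfg$outdir, ...)
  genome <- read_chrom_sizes(o("genome.chrom.sizes"))
  treated <- read_bed(o("chip_treated.bed"), genome, name = "treated")
  control <- read_bed(o("chip_control.bed"), genome, name = "control")
  fc <- read.delim(o("chip_counts.tsv"), stringsAsFactors = FALSE)
  res <- call_differential_peaks(treated, control, fc, cfg$chip)
  write_bed(res$regions, o("differential_chip.bed"))
  .write_tsv(res$report, o("chip_report.tsv"))
}

.run_motif_scan <- function(cfg) {
  o <- function(...) file.path(cfg$outdir, ...)
  genome <- read_chrom_sizes(o("genome.chrom.sizes"))
  pw <- read_pwm_tsv(o("motif.tsv"), motif_id = "motif")
  seqs <- read_fasta(o("genome.fa"))
  hits <- scan_sequences(pw, seqs, p_threshold = cfg$motif_p_threshold,
                         genome = genome)
  .write_tsv(hits, o("motif_hits.tsv"))
}

.run_occupancy <- function(cfg) {
  o <- function(...) file.path(cfg$outdir, ...)
  genome <- read_chrom_sizes(o("genome.chrom.sizes"))
  hits <- read.delim(o("motif_hits.tsv"), stringsAsFactors = FALSE)
  peaks <- read_bed(o("chip_treated.bed"), genome, name = "treated")
  open_r <- read_bed(o("faire.bed"), genome, name = "faire_union")
  ann <- annotate_hits(hits, peaks, open_r)
  .write_tsv(occupancy_curve(ann), o("occupancy.tsv"))
}

.run_annotate <- function(cfg) {
  o <- function(...) file.path(cfg$outdir, ...)
  genome <- read_chrom_sizes(o("genome.chrom.sizes"))
  genes <- read_genes(o("genes.tsv"))
  peaks <- read_bed(o("differential_chip.bed"), genome, name = "diff_chip")
  ann <- nearest_tss(peaks, genes)
  ann$feature_class <- classify_feature(peaks, genes)
  .write_tsv(ann, o("tss_annotation.tsv"))
  dom <- regulatory_domains(genes, genome)
  .write_tsv(dom, o("regulatory_domains.tsv"))
  assoc <- associate_regions(peaks, dom)
  .write_tsv(assoc$associations, o("gene_associations.tsv"))
}

.run_cooccupancy <- function(cfg) {
  o <- function(...) file.path(cfg$outdir, ...)
  genome <- read_chrom_sizes(o("genome.chrom.sizes"))
  treated <- read_bed(o("chip_treated.bed"), genome, name = "treated")
  control <- read_bed(o("chip_control.bed"), genome, name = "control")
  open_r <- read_bed(o("faire.bed"), genome, name = "faire_union")
  ov <- rbind(overlap_summary(treated, control),
              overlap_summary(control, treated),
              overlap_summary(treated, control, stratum = open_r),
              overlap_summary(treated, open_r))
  .write_tsv(ov, o("overlap_summary.tsv"))
  fc <- read.delim(o("chip_counts.tsv"), stringsAsFactors = FALSE)
  counts <- cbind(treated = fc$count_treated, control = fc$count_control)
  if (nrow(counts) >= 3) {
    scm <- signal_correlation(counts, fc$count_input,
                              lib_sizes = c(treated = fc$lib_treated[1],
                                            control = fc$lib_control[1]),
                              input_lib_sizes = fc$lib_input[1])
    cm <- data.frame(dataset = rownames(scm$cor), scm$cor,
                     check.names = FALSE)
    .write_tsv(cm, o("signal_correlation.tsv"))
    cl <- cluster_datasets(scm)
    writeLines(cl$newick, o("dataset_clustering.newick"))
  } else {
    .write_tsv(data.frame(), o("signal_correlation.tsv"))
    writeLines(";", o("dataset_clustering.newick"))
  }
}

.run_expression <- function(cfg) {
  o <- function(...) file.path(cfg$outdir, ...)
  ev <- read.delim(o("expression.tsv"), check.names = FALSE,
                   stringsAsFactors = FALSE)
  design <- read.delim(o("expr_design.tsv"), stringsAsFactors = FALSE)
  values <- as.matrix(ev[, -1])
  rownames(values) <- ev$gene_id
  expr <- expression_matrix(values, design)
  genome <- read_chrom_sizes(o("genome.chrom.sizes"))
  genes <- read_genes(o("genes.tsv"))
  peaks <- read_bed(o("differential_chip.bed"), genome, name = "diff_chip")
  de_all <- list()
  dep_all <- list()
  for (tm in unique(design$time)) {
    de <- call_differential_genes(expr, tm)
    de_all[[tm]] <- de
    dep_all[[tm]] <- classify_stat3_dependence(expr, de)
  }
  de <- do.call(rbind, de_all)
  dep <- do.call(rbind, dep_all)
  .write_tsv(de, o("de_calls.tsv"))
  .write_tsv(dep, o("stat3_dependence.tsv"))
  # density profile needs genes present in the gene model; map the first
  # n_genes expression genes onto gene-model ids by rank for the synthetic
  # world (real runs supply their own mapping)
  first_t <- de_all[[1]]
  k <- min(nrow(genes), nrow(first_t))
  prof_calls <- first_t[seq_len(k), ]
  prof_calls$gene_id <- genes$gene_id[seq_len(k)]
  prof <- peak_density_profile(prof_calls, genes, peaks,
                               rolling = max(1, min(100, k)))
  .write_tsv(prof, o("peak_density_profile.tsv"))
}

#' Run one pipeline stage
#'
#' Checks stage dependencies, refuses to overwrite existing outputs unless
#' `cfg$force`, executes the stage, and appends an entry (parameters, seed,
#' output MD5 hashes) to `manifest.json` in the output directory.
#'
#' @param name one of `simulate`, `faire_diff`, `chip_diff`, `motif_scan`,
#'   `occupancy`, `annotate`, `cooccupancy`, `expression`.
#' @param cfg `PipelineConfig`
#' @return invisibly, the stage's output paths.
#' @export
run_stage <- function(name, cfg) {
  name <- match.arg(name, .STAGES)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  .check_deps(name, cfg)
  outs <- .stage_outputs(cfg)[[name]]
  if (!cfg$force && any(file.exists(outs)))
    stop(sprintf("run_stage('%s'): outputs exist; use force = TRUE", name))
  switch(name,
         simulate = .run_simulate(cfg),
         faire_diff = .run_faire_diff(cfg),
         chip_diff = .run_chip_diff(cfg),
         motif_scan = .run_motif_scan(cfg),
         occupancy = .run_occupancy(cfg),
         annotate = .run_annotate(cfg),
         cooccupancy = .run_cooccupancy(cfg),
         expression = .run_expression(cfg))
  .update_manifest(name, cfg, outs)
  invisible(outs)
}

.update_manifest <- function(name, cfg, outs) {
  mpath <- file.path(cfg$outdir, "manifest.json")
  manifest <- if (file.exists(mpath))
    jsonlite::read_json(mpath, simplifyVector = FALSE) else list()
  manifest[[name]] <- list(
    stage = name, seed = cfg$seed,
    parameters = list(alpha = cfg$alpha,
                      n_permutations = cfg$n_permutations,
                      motif_p_threshold = cfg$motif_p_threshold),
    outputs = as.list(structure(unname(tools::md5sum(outs)),
                                names = basename(outs))))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}

#' Run the whole pipeline
#'
#' Executes every stage in dependency order and writes `summary.txt` with the
#' headline numbers (differential FAIRE fraction and recovery against truth,
#' differential peak count, occupancy at the top score bin, overlap
#' fractions, dependence counts).
#'
#' @param cfg `PipelineConfig`
#' @return the summary as a named list, invisibly; `summary.txt` and
#'   `manifest.json` land in `cfg$outdir`.
#' @export
run_all <- function(cfg) {
  for (s in .STAGES) run_stage(s, cfg)
  o <- function(...) file.path(cfg$outdir, ...)
  rep_f <- read.delim(o("faire_report.tsv"), stringsAsFactors = FALSE)
  truth <- read.delim(o("faire_truth.tsv"), stringsAsFactors = FALSE)
  called <- rep_f$called
  sens <- mean(called[truth$differential])
  fpr <- mean(called[!truth$differential])
  chip_rep <- read.delim(o("chip_report.tsv"), stringsAsFactors = FALSE)
  occ <- read.delim(o("occupancy.tsv"), stringsAsFactors = FALSE)
  top <- occ[!is.na(occ$frac_bound_in_open) & occ$n_in_open >= 20, ]
  top <- if (nrow(top)) top[which.max(top$bin_lo), ] else
    data.frame(bin_lo = NA, frac_bound_in_open = NA, frac_bound_outside = NA)
  ov <- read.delim(o("overlap_summary.tsv"), stringsAsFactors = FALSE)
  dep <- read.delim(o("stat3_dependence.tsv"), stringsAsFactors = FALSE)
  summary <- list(
    n_faire_sites = nrow(rep_f),
    differential_faire_fraction = mean(called),
    planted_differential_fraction = mean(truth$differential),
    faire_sensitivity = sens,
    faire_fpr = fpr,
    n_differential_chip = sum(chip_rep$called),
    occupancy_top_bin = top$bin_lo,
    occupancy_in_open_at_top = top$frac_bound_in_open,
    occupancy_outside_at_top = top$frac_bound_outside,
    treated_in_control_fraction = ov$fraction[1],
    dependence_counts = as.list(table(dep$status)))
  lines <- c("pipeline summary",
             sprintf("%s\t%s", names(unlist(summary)),
                     vapply(unlist(summary), format, character(1))))
  writeLines(lines, o("summary.txt"))
  invisible(summary)
}
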