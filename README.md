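# chromdiff

Tools for analysing how open chromatin and transcription-factor binding
change across a cellular state transition, built around the kind of
time-course FAIRE-seq + ChIP-seq + expression experiment used to study
inducible oncogenic transformation. Everything is exercisable on synthetic
data with known ground truth, so each stage is testable without any external
download.

## What it computes

**Differential open chromatin.** Given replicate read counts over a union
set of open-chromatin regions (time points *t* = 1..T, replicates *r* =
1..R), each region × time point gets the amplitude statistic

```
S(i, t) = | mean_t(x_i) - mean_rest(x_i) | / ( sd_t(x_i) + sd_rest(x_i) )
```

on RPM-normalized counts, with sample (n−1) standard deviations. The null is
built by permuting the sample → time-point assignment jointly across all
samples and recomputing every score; a region is called differential when its
maximum score over time points exceeds the empirical (1−α) quantile of the
permuted per-region maxima (α = 0.05 by default), which makes the site-level
false-positive rate equal α on null data.

**Differential TF binding.** A treated subpeak (MACS/PeakSplitter-style BED
with −log10 p and summit) is transformation-specific iff it shares no base
pair with any control subpeak and its smoothed fold change

```
FC = ((n_treated + 10) / N_treated) / ((n_control + 10) / N_control)
```

exceeds `mean(FC) + 1·sd(FC)` over all treated subpeaks.

**Motif quality and occupancy.** PWMs score W-mers as log2-odds in bits
against a 0-order background; score p-values are exact (dynamic programming
over a 1/1000-bit grid, validated against exhaustive enumeration for W ≤ 8).
Scanning reports both strands at p ≤ 1e−4 by default. Occupancy curves bin
hits by score and report the bound fraction inside vs outside open chromatin.

**Annotation.** Strand-aware nearest-TSS distances, feature classes
(promoter −2,500..+500 > exon > intron > upstream ≤10 kb > downstream ≤10 kb
> distal intergenic), Gaussian-smoothed TSS-distance densities, one-sided
binomial feature enrichment, GREAT-style regulatory domains (basal 5 kb
up / 1 kb down, extended to the nearest basal, capped at 1 Mb) and
summit-in-domain gene association.

**Co-occupancy and expression.** Directional overlap fractions (optionally
stratified by open chromatin), input-normalized Pearson correlation matrices
with deterministic average-linkage clustering, Welch-test differential
expression (p < 1e−4 AND |log2FC| > 0.5), and knockdown-dependence
classification (dependent / independent / ambiguous).

## Worked example

```r
library(chromdiff)
cfg <- pipeline_config(seed = 42, outdir = "demo_out")
summary <- run_all(cfg)
str(summary)
```

prints (seed 42, default synthetic world: 1-Mb chromosome, 500 open-chromatin
sites, 17% planted 3× amplitude changes, 2,000 motif instances, 500 genes):

```
 $ n_faire_sites                : int 500
 $ differential_faire_fraction  : num 0.22
 $ planted_differential_fraction: num 0.17
 $ faire_sensitivity            : num 1
 $ faire_fpr                    : num 0.0602
 $ n_differential_chip          : int 43
 $ occupancy_top_bin            : int 17
 $ occupancy_in_open_at_top     : num 1
 $ occupancy_outside_at_top     : num 0.108
 $ treated_in_control_fraction  : num 0.424
 $ dependence_counts            :List of 2
  ..$ ambiguous: int 9
  ..$ dependent: int 11
```

Reading: all 85 planted differential sites are recovered (sensitivity 1.0)
with a 6% false-positive rate, so 22% of sites are called against 17%
planted — the α = 0.05 null contributes the difference. At the top motif
score bin (17 bits, near-consensus) every motif inside open chromatin is
bound versus 11% outside, reproducing the strong open-chromatin dependence
of binding that the generator plants. Outputs (BED/TSV/newick files, a
`manifest.json` with seed, parameters and MD5s, and `summary.txt`) land in
`demo_out/`; rerunning with the same seed is byte-identical.

Each stage is also callable alone — `run_stage("faire_diff", cfg)` — or from
the shell via `inst/cli/chromdiff.R`:

```sh
Rscript inst/cli/chromdiff.R run-all --seed 42 --outdir demo_out --force
```

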