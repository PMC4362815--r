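---
title: "chromdiff: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromdiff: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements,
the knobs that matter, what the synthetic-data generator does and does not
emulate, and the places where the design was genuinely open and a choice had
to be made.

# Coordinate and overlap conventions

All intervals are 0-based half-open (`[start, end)`, BED convention)
everywhere inside the package; 1-based formats are converted at the I/O
boundary. "Overlap" always means sharing at least one base pair: book-ended
intervals (`[0,10)` and `[10,20)`) neither overlap nor merge. Sorting ties
break by `(end, name)` so every operation is order-deterministic. The
interval engine is IRanges (`reduce` with `min.gapwidth = 0`,
`overlapsAny`, `countOverlaps`) behind these conventions; the test suite
checks it against per-base and all-pairs brute-force oracles rather than
trusting the engine.

Reads are counted by their 5' position, not a fragment span: a read is in a
region iff its position lies in `[start, end)`. On overlapping regions a
read can therefore count twice; column sums are bounded by library sizes
only after merging.

# Differential open chromatin

## The score

For region $i$ and time point $t$, with RPM-normalized counts
($x = 10^6 \cdot \text{count}/\text{library size}$):

$$ S(i,t) = \frac{\left| \bar x_{i,t} - \bar x_{i,\text{rest}} \right|}
                 {s_{i,t} + s_{i,\text{rest}}} $$

where the "rest" group pools all samples of the other time points and both
standard deviations use the sample ($n-1$) denominator — with three
replicates per time point, the conventional estimator. The denominator is
the *sum* of the two group SDs (a literal two-group contrast), not a pooled
SD. The score is scale-invariant (numerator and denominator are both linear
in the data), so the $10^6$ RPM factor is cosmetic.

Degenerate cases: zero SD sum with equal means scores 0; zero SD sum with
unequal means is $+\infty$, capped at (max finite score + 1) for ranking and
quantiles and flagged in the report (`any_infinite`), so NaNs never
propagate.

## The permutation null and why calling uses the max statistic

The null shuffles the sample-to-time-point assignment uniformly over *all*
samples (full exchangeability — replicates are not kept within their time
point) and recomputes every score, `n_permutations` times (default 1,000;
a seed is mandatory). Two pooled empirical quantiles are kept:

* `score_threshold` — the $(1-\alpha)$ quantile of all permuted
  region × time scores;
* `threshold` — the $(1-\alpha)$ quantile of the permuted *per-region
  maximum* score. **Calling uses this one.**

A region's calling statistic is its maximum score over time points. Had the
max been compared against the per-score quantile, the site-level
false-positive rate on null data would be roughly $4\alpha$ (four highly
dependent chances to exceed a marginal quantile). Comparing the max against
the null distribution of the max makes the fraction of null sites called
equal $\alpha$ exactly in expectation, by exchangeability — this is the
single 0.05 criterion the method advertises. Both thresholds are single
global quantiles pooled over regions and permutations; nothing is fit per
region. The acceptance suite checks both calibrations on a 10,000-site null
matrix.

Occurrence (presence/absence across time points) is reported descriptively
by `presence_pattern()` (mean RPM above a cutoff, default 1 RPM); the
amplitude score is the primary caller.

# Differential TF binding

Inputs are subpeak BEDs (score column = $-\log_{10} p$, optional summit
column) pre-filtered — and re-filtered by the package — at
$p \le 10^{-9}$ (`peak_p_threshold = 9`). The fold change adds a
pseudocount of 10 to the raw counts *before* per-million scaling:

$$ FC = \frac{(n_T + 10)/N_T}{(n_C + 10)/N_C} $$

so it is always finite and positive. A treated subpeak is called iff it
overlaps no control subpeak (exclusion dominates, whatever the fold change)
and $FC > \overline{FC} + k\,\widehat{sd}(FC)$ with $k = 1$ over all treated
subpeaks of the population passed in — per-time-point populations are the
caller's slicing. An optional `min_fold_change` floor (e.g. 5) exists but is
off by default: a reported "greater than 5-fold" property of called sites is
treated as a consequence of the mean + 1 SD rule, not an extra filter.
Fewer than two usable treated subpeaks is an error (the SD is undefined).

# Motif model

"Motif quality score" is defined in this package as the log2-odds score in
bits against the 0-order background, binned at 1 bit for occupancy curves.
The scale of the original figure axis is not recoverable from the source
description; bits are a declared convention, chosen so that a near-perfect
match to a 10-bp, 85%-informative motif scores ≈ 17.7 bits.

Exact p-values ($P(\text{score} \ge s)$ under the 0-order background) come
from dynamic programming over a discretized score grid, step $10^{-3}$ bits
by default. Per-position scores are rounded to the grid, so the DP
distribution is exact for the rounded scores; the tests require equality
with exhaustive enumeration over all $4^W$ W-mers (same rounding) to
1e−12 for every width ≤ 8. A higher-order background may be used as
discovery context, but p-values are always 0-order — exact DP is only
defined there. Scanning inverts the p-value threshold into the smallest grid
score with tail ≤ p (default p ≤ 1e−4), scans both strands (reverse strand
via the reverse-complemented score matrix), skips windows containing
non-ACGT characters, keeps overlapping hits, and counts opposite-strand hits
at one position as distinct — occupancy denominators are therefore
unambiguous. Note a coarse motif may not attain a small p at all (tails of a
2-bp motif are multiples of 1/16); the threshold is then $+\infty$ and no
hit is reported.

Occupancy curves report, per score bin and separately inside/outside open
chromatin, the number of hits and the bound fraction; empty bins are `NA`,
never 0%.

**Measurement caveat.** Annotating instances as "bound" by ≥ 1 bp overlap
with subpeaks is the realistic measurement, but inside open regions that
hold several instances a ±150 bp subpeak around one bound instance also
covers its unbound neighbours. On dense synthetic data this spatial
contamination inflates apparent occupancy at low-score bins. The planted
logistic binding model is therefore validated on the instances' own bound
flags; the peak-overlap route is exercised separately. A green occupancy
test establishes that the curve machinery recovers a known binding model —
not that peak-overlap annotation is contamination-free on dense regions.

# Annotation

* Nearest TSS: minimal $|$summit − TSS$|$, ties by lexical gene id, sign on
  the gene's strand (negative = upstream). Summit-less regions use their
  midpoint.
* Feature classes, precedence: promoter > exon > intron > upstream ≤ 10 kb >
  downstream ≤ 10 kb of TTS > distal intergenic. The promoter window is
  −2,500..+500 bp by default; the upstream-only variant (−2,500..0) is a
  preset (`promoter_window = c(2500, 0)`) because both definitions appear in
  this literature. Promoter-first matches presenting a single class per
  site.
* TSS-distance densities: 500-bp bins over ±10 kb; the Gaussian KDE
  bandwidth defaults to one bin (500 bp) — the minimal-smoothing convention,
  since "bandwidth equal to the kernel's SD" is circular — and the density
  is renormalized to integrate to 1 over the window (trapezoid rule), so
  edge leakage does not break normalization.
* Enrichment: one-sided binomial tail $P(X \ge k)$, $X \sim B(n, f)$ with
  $f$ the genome fraction of the class, computed from the supplied gene
  model and chromosome sizes (`feature_genome_fraction()`, stride-sampled),
  never hard-coded — published fractions are tied to an annotation snapshot.
* Regulatory domains (basal-plus-extension): basal = TSS − 5 kb to
  TSS + 1 kb (strand-aware); each side extends to the nearest other gene's
  basal edge, at most 1 Mb, clipped to the chromosome. A foreign basal
  overlapping the gene's own basal blocks extension on that side (the domain
  always contains its basal). Formally the invariant is: the *extension
  zones* never intersect a foreign basal with positive length — with
  overlapping basals a stronger statement is impossible. Summits are
  associated to every domain containing them; overlapping domains yield
  multiple associations by design.

# Expression

Differential calling is a Welch two-sample t-test on log2 values (treated vs
control under the control siRNA), gated conjunctively: $p < 10^{-4}$ AND
$|\log_2 FC| > 0.5$, no multiple-testing correction by default (a raw
threshold is the stated rule; BH-FDR is an option). The test statistic
itself was an open choice — only the thresholds are stated — and Welch is
the minimal-assumption two-group test; it is frozen here for determinism.

Dependence classification re-evaluates the contrast under knockdown:
*independent* = the effect persists (significant and $|\log_2 FC| > 0.5$
under knockdown — the stated rule); *dependent* = the effect disappears
(non-significant and $|\log_2 FC| < 0.5$) — the inversion of that rule;
anything between is *ambiguous*, matching the acknowledgement that many
genes cannot be unambiguously assigned. With three replicates the
$p < 10^{-4}$ gate is severe (a 7.5-SD shift gives $p \approx 8\times
10^{-4}$ at df ≈ 4), so on realistic noise most planted genes land in
`NA`/ambiguous; the recovery criterion is correctness among the unambiguous,
which is what a green test establishes. Duplicate probes keep the lowest-p
row ("discarding the probe set with the highest P value" read as keeping the
most significant probe).

Peak-density profiles count differential-peak summits in the strand-aware
promoter window (−2,500..+500, 3 kb) and in ±50 kb flanks excluding the
promoter, normalize to peaks per kbp of window, rank genes by descending
log2 fold change and smooth with a centered, edge-truncated 1,000-gene
rolling mean.

# The synthetic world

The generator's defaults state the simulated world once:

| knob | default | why |
|---|---|---|
| chromosome | one 10 Mb toy | room for 1 Mb domain caps to bind; minutes-fast |
| FAIRE design | 4 time points × 3 replicates | the experiment's shape |
| counts | NB(mean 100, size 25) | replicate CV ≈ 22%, typical for FAIRE replicates; overdispersed, Poisson reachable via the size knob |
| differential fraction | 0.17 | the reported minority of changing sites |
| effect | 3× at one uniformly chosen time point | an unambiguous amplitude change |
| library sizes | 2×10⁷ ± 10% | realistic depth jitter |
| binding | $P = \mathrm{logis}(-5.5 + 0.6\,s)$, ×0.1 outside open chromatin | ≈ 95% occupancy at a near-perfect motif inside open chromatin, ≈ 10% outside — the qualitative separation the curves must reproduce |
| expression | 2×2 design, effect 1.5 log2 units, sd 0.2, 20% dependent + 20% independent | the stated recovery regime |

Every generator is a pure function of `(cfg, seed)` (one `set.seed` per
stage with a fixed offset and documented draw order), so outputs are
byte-identical per seed. What the generator does **not** emulate: read-level
data (FASTQ), fragment-size and GC effects, mapability, correlated
replicates, batch structure, annotation-driven motif clustering. Green tests
therefore establish statistical correctness of the methods on an idealized
world, not robustness to those artefacts.

# Pipeline

Stages form a DAG (`simulate` → `faire_diff`/`chip_diff`/`motif_scan` →
`occupancy`/`annotate`/`cooccupancy`/`expression`); a missing upstream file
is an error naming the producing stage; existing outputs are never
overwritten without `force`. The per-stage manifest records seed, parameters
and output MD5s — and deliberately no timestamps, so reruns are
byte-identical. The config file is JSON (the runtime environment ships no
YAML parser); command-line flags override file values.

# Numerical choices, in one place

* sample (n−1) SDs everywhere; infinite scores capped at max finite + 1.
* quantiles: `stats::quantile` type 7 on pooled permuted scores.
* score grid 1/1000 bit; hit calling compares grid-rounded scores.
* correlation ratios: (count + 1)/(input + 1), each RPM-scaled; linear by
  default, log2 optional (the original scale is unstated).
* clustering: average linkage on 1 − r, ties broken by the lexically
  smallest member pair; composite labels are sorted so the tree is invariant
  to input order.
* rolling means: centered window, truncated at the edges.
* promoter presets: `c(2500, 500)` (default) and `c(2500, 0)`.

# Known limitations

Feature-class genome fractions are stride-sampled (default 1 kb), not exact
base counts. The nearest-TSS and feature classifiers are quadratic per
chromosome — fine at annotation scale, not engineered for tens of millions
of summits. Upstream peak calling and enrichment calling (the window-level
mixture models of the original tools) are out of scope: the package consumes
their outputs or synthetic equivalents.
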