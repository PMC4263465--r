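---
title: "Methods: enrichment tracks, bound-region calling and repeat analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment tracks, bound-region calling and repeat analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mslchip)
```

# Scope and model

`mslchip` implements the computational core of a ChIP-seq analysis of
MSL-complex targeting in *Drosophila*, where the male-specific lethal
complex normally coats the male X chromosome and, in *roX1 roX2* double
mutants, relocates to pericentromeric heterochromatin, the 4th chromosome
and repeat-rich autosomal sites.  The pipeline consumes stepped coverage
tracks (not reads) and interval/count annotations, and produces four
results:

1. a log2 ChIP/input enrichment-ratio track at 10 bp resolution,
   median-smoothed with data-poor windows discarded;
2. MSL-bound regions called by a top-percentile threshold with gap
   merging and length/unit filters, scored by the best five consecutive
   ratio values;
3. the distribution of nearest distances between bound regions and
   high-affinity sites (HAS), binned against a seeded random-position
   control;
4. repeat-content statistics: the repeat-masked fraction profile around
   TSSs of bound vs unbound expressed genes, and per-repeat-class RPKM
   enrichment ratios.

A synthetic-data generator plants all the structure these analyses assume
(HAS, noise, gradients, repeat-density contrasts, class folds) with known
ground truth, so every stage is testable end to end without any external
download.

# The enrichment-ratio track

Coverage tracks live on a fixed step grid (default 10 bp; the last step of
a chromosome may be partial).  The published analysis cites an external
procedure for the ratio itself without reproducing it, so the package
declares a minimal standard form: both tracks are scaled to equal
genome-wide totals (each multiplied so its total over jointly covered
steps equals the mean of the two totals), then

$$ r_i = \log_2 \frac{c_i s_c + p}{x_i s_x + p} $$

with an additive pseudocount $p$ (default 0.5, configurable) that damps
ratios where coverage is low.  Steps missing in either input are missing
in the output.  `normalize = FALSE` disables the scaling for callers that
have already normalized.

## Median smoothing

`median_smooth()` replaces each step with the median of the non-missing
raw values in a window of 500 bp or 2000 bp centred on it; windows
retaining fewer than 25 (resp. 100) values are discarded.  Two numerical
choices matter:

* **Window membership.** A 500 bp window spans an even number (50) of
  10 bp steps, so a perfectly symmetric window does not exist at step
  granularity; step *i*'s window is steps $[i - w/2,\; i + w/2 - 1]$.
* **Tie rule.** Even-count windows take the *lower* of the two central
  order statistics.  This keeps the smoother's output an observed value
  and makes it monotone: raising any raw value never lowers any smoothed
  value.  Windows truncate at chromosome ends, where the minimum-point
  rule still applies, so edge steps are usually discarded.

The smoother is validated against a brute-force per-window median on
random tracks (up to 5000 steps) in the test suite.

# Bound-region calling

Given a smoothed track, the cutoff is the nearest-rank top-1.5%
value: the $r$-th largest non-missing value with
$r = \lceil 0.015\,n \rceil$; ties at the cutoff all count as crossing.
By default one cutoff is computed over all analysed chromosomes
(per-chromosome scope is available; the original description does not say
which was used).  Steps at or above the cutoff are *data units*.  Units
spaced at most 200 bp apart — gap measured from the end of one unit's
step to the start of the next — chain into candidate regions spanning
first-unit start to last-unit end.  Candidates shorter than 200 bp or
with fewer than five units are discarded.

Each region's score is the mean of its best five *consecutive* steps,
computed on smoothed values whether or not each individual step crosses
the cutoff (the original text does not state whether sub-cutoff values
may enter this window; this choice is declared and kept).  The peak
centre is the genomic centre of the maximizing window, leftmost on ties;
ties are common on median-smoothed data, so the implementation computes
exact window means rather than running sums to keep the tie-break
deterministic.  Windows containing missing steps are skipped; in the
degenerate case where a region has no complete window (possible only
with missing data between units), the five best consecutive non-missing
values are used instead.

Note one consequence of scoring with sub-cutoff steps admitted: on
adversarial (unsmoothed) tracks a region's score can fall below the
cutoff, so the package does not promise `score >= cutoff` as an
invariant, although it holds on smoothed data in practice.

# HAS distance profiles

Distance is the interval-to-interval gap: zero when a bound region
overlaps or abuts a HAS (overlap *is* the first bin's meaning), otherwise
the count of intervening bases.  Distances are binned into eight 5 kb
bins, the last open-ended (">35 kb"), and reported as fractions that sum
to one.  The control draws 10,000 uniform positions on the chromosome
(the original count is unstated; the value is configurable and seeded),
treats each as a zero-length site, and bins identically.  Whether the
original measured from region edge, centre or midpoint is not stated;
the package measures from region edges, consistent with "overlap" being
bin one.

# TSS repeat landscape

`repeat_fraction_track()` computes, at every step, the fraction of
repeat-masked bases in a 200 bp window centred on it (truncated windows
use the truncated width, so values stay in [0, 1] and total masked bp is
conserved up to one window per chromosome end).
`tss_repeat_profile()` then averages this track in twenty 1 kb bins of
distance from each gene's TSS.  Distance is unsigned by default, pooling
upstream and downstream (the source figure axis does not carry a sign);
strand-oriented signed profiling is available via `signed = TRUE`.
Genes are the independent units: per-gene bin means are averaged within
each group and the 95% interval is the normal approximation
$\bar x \pm 1.96\,\mathrm{SE}$ over genes — the original's CI unit is
not stated, and gene-level resampling is the conservative choice.  Genes
whose window crosses a chromosome end are retained with the available
bins and flagged.

Wild-type MSL2 groups are derived with
`select_wildtype_bound_genes()`: an expressed gene is bound when any
step of its span reaches the top-5% cutoff of the smoothed MSL2 track.
On a constant track every gene ties at the cutoff and all are bound —
degenerate but documented behaviour of the ≥ rule.

# Repeat-class enrichment

For each Repbase-style class, RPKM = count / ((length/1000) ×
(mapped/10^6)), where *mapped* is the library's genome-mapped total (not
the repeat-mapped total).  The enrichment ratio is ChIP RPKM over input
RPKM; classes with zero input RPKM get an undefined ratio rather than an
infinity.  Because counting retains all multi-mapped alignments, a read
matching several classes contributes to each — documented over-counting
of shared k-mers.  The 95% interval is a percentile bootstrap over reads:
each library's repeat-mapped reads are resampled across classes
(multinomial, B = 1000, seeded); the original's CI construction is not
stated.  `rank_enriched_classes()` orders classes by mutant/wild-type
relative enrichment (or mutant ratio alone) and flags those above a
2-fold report threshold.

# The synthetic generator

`simulation_config()` fixes the validation conditions:

| parameter | default | role |
|---|---|---|
| chrX length / HAS | 1 Mb, 50 sites of 500 bp | dense region-calling testbed |
| HAS fold | 4 (linear) | log2 ratio 2 inside sites |
| noise sd | 0.3 | Gaussian log2-ratio noise per step |
| gradient | off (max fold 1) | optional exponential pericentromeric rise |
| chr2L length / genes | 17 Mb, 400 genes (200 per group) | TSS profile testbed |
| repeat densities | 24% near bound, 8% near unbound TSSs | planted 3× contrast |
| class folds | 5, 3, 2 for PROTOP_B, PROTOP_A, NTS_DM | planted class enrichment |
| repeat reads | 10^5 per library | Poisson counting depth |

Noise is Gaussian on the log2 ratio (standard for coverage ratios; split
evenly in variance between the two tracks).  HAS are uniform
non-overlapping boxcar enrichments — no fragment-length smearing, since
the pipeline consumes tracks, not reads.  The pericentromeric gradient,
when enabled, multiplies ChIP coverage by
$1 + (f_{max}-1)e^{-(L-x)/\lambda}$ towards the right chromosome end.
Genes sit on a 42 kb grid with ±1 kb TSS jitter; the spacing is chosen so
that each gene's ±20 kb planted repeat zone cannot leak into a
neighbour's twenty 1 kb profile bins.  Repeats occupy one slot per 1 kb
cell at a random offset — 240 bp wide near bound TSSs, 80 bp elsewhere —
so the planted bound:unbound masked-density ratio is exactly 3 by
construction.  Expression flags are assigned by configuration, not
simulated.  Everything is byte-reproducible under a fixed seed.

What the generator does *not* emulate: mappability and GC structure,
fragment-length autocorrelation in raw coverage, polytene copy-number
variation, overlapping gene models, and the clustered spatial
distribution of real HAS.  Passing tests therefore demonstrate
correctness of the computations under the declared statistical model,
not robustness to every artefact of real ChIP-seq data.

## A note on validation scales

Two HAS densities appear in the checks.  The dense testbed (50 sites on
1 Mb, 4× the real X-chromosomal density of roughly 263 sites per 22 Mb)
stresses the caller, but at that density a 5 kb-binned random control is
within 5 kb of *some* site about 40% of the time, so the
observed-vs-control first-bin contrast is structurally capped near 2.4.
At the realistic density (12 sites per Mb) the control's first bin drops
to about 0.12 and the observed profile exceeds it several-fold — the
qualitative result the distance analysis is designed to show.  Both
figures are computed by `scripts/acceptance.R`.  At realistic density
the fixed 1.5% unit budget also exceeds the planted site steps, so a
fraction of called regions are noise clusters; precision is reported at
the dense scale where the budget is saturated.

Problem sizes used throughout the checks (1–3 Mb chromosomes, 10^5
repeat reads, 100 replicate draws) are the package's validation
defaults; all scale linearly if larger scenarios are wanted.

# Known limitations

* The enrichment-ratio formula is a declared stand-in for the cited
  external procedure; absolute region counts on real data depend on it.
* Multi-mapping reads are counted once per class they hit, inflating
  classes that share sequence.
* The caller has no FDR control or input-aware local background — by
  design, mirroring the percentile procedure it implements.
* `run_has_analysis()` computes distances on the chromosomes carrying
  HAS; regions elsewhere are still reported in the BED output.
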