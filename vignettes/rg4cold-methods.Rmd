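---
title: "Methods: quantifying cold-responsive RNA G-quadruplex folding and its consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cold-responsive RNA G-quadruplex folding and its consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rg4cold)
library(dplyr)
```

## Scope

`rg4cold` implements an analysis chain for studying RNA G-quadruplexes
(RG4s) as a cold-adaptation feature of plant transcriptomes. It covers
four linked questions:

1. Does transcriptome nucleotide / RG4 composition covary with the
   climate of a species' habitat?
2. How folded are individual RG4s in living cells, measured from
   SHALiPE-seq reverse-transcription stop counts?
3. Does cold (4 °C vs 22 °C) shift that folding?
4. Do cold-responsive RG4s change mRNA decay or translation efficiency?

All inputs start at processed tables (sequences, per-position stop
counts, per-occurrence climate values, abundance time courses); read
alignment, raster extraction and all wet-lab steps are upstream and out
of scope. A seeded synthetic-data module generates every input format
with planted ground truth, so each stage is testable without external
downloads.

## RG4 motif grammar

An RG4 motif is four G-tracts separated by three loops:
`Gx N(1-7) Gx N(1-7) Gx N(1-7) Gx`, with `x = 3` (G3, three stacked
quartets) or `x = 2` (G2). The scanner (`scan_rg4()`) runs the G3 pass
first and then a G2 pass on sequence not already covered; within a pass
matches are leftmost and non-overlapping with minimal (non-greedy)
loop extension. Tract/loop bounds are all arguments.

Deterministic details that the grammar alone does not fix, and how we
resolved them:

* Candidate tracts are *maximal* G runs of length at least `x`, clipped
  to the class length from the 5′ end; leftover guanines of a longer
  run fall into the adjacent loop. Loops may therefore contain G (e.g.
  a 2-G run inside a G3 loop) but never `N` — an unknown base cannot
  support a quartet, so any `N` in a candidate span vetoes the match.
* A run used by a G3 motif cannot seed a G2 motif, and G2 spans may not
  overlap G3 spans; this prevents double counting of the same tract.
* "Leftmost with minimal extension" is implemented as depth-first
  chaining that always tries the nearest eligible run first; the test
  suite proves it equivalent to exhaustive enumeration of every
  (start, tract, loop) placement followed by the same resolution rule.

Motifs are binned by *total* loop length (bins 2/4/6/8/10 nt with upper
edges 3/5/7/9; both are arguments) and assigned to the genic region —
5′-UTR, CDS, 3′-UTR from transcript-relative, 0-based half-open
boundaries — containing the larger part of the span, ties going
downstream. Per-loop or mean-loop binning can be emulated by passing a
different `total_loop_length` column; total length is the default
because the alternative metrics are not better constrained by the data
we emulate.

RG4 density (`rg4_density()`) is the motif count per 1000 nt of
transcriptome; per-region denominators are emitted alongside the
whole-transcriptome one since either normalization is defensible.

## Composition and climate association

`nucleotide_frequency()` pools A/C/G/U counts over all (region slices
of) transcripts — a transcriptome-level fraction — with `N` excluded
from numerator and denominator; a per-transcript-mean variant is
exposed as a flag because pooling versus averaging is a genuine
free choice for assembled transcriptomes.

The climate module takes species feature vectors (e.g. G frequency, RG4
density) and occurrence-level values of the 19 bioclimatic variables
(BIO1–BIO11 temperature, BIO12–BIO19 precipitation, units as supplied).
Species need strictly more than 100 occurrences to enter
(`filter_species()`). Per species × variable, occurrence values are
summarized at the 10/25/50/75/90 quantile points using the standard
linear-interpolation estimator (R type 7; the estimator is fixed and
documented for reproducibility rather than prescribed by the emulated
study design). Each feature is Pearson-correlated with each quantile
column; p values come from the t transform on n − 2 degrees of
freedom; Benjamini–Hochberg adjustment is applied within the five
quantiles of one variable (a flag widens the family to all variables ×
quantiles), and the minimum-FDR quantile row represents the variable,
ties broken by larger |PCC|, then lower quantile. Significance counts
(`count_significant()`) default to raw p < 0.01, with the FDR
alternative recorded in the output's `criterion` column, because both
conventions occur in practice and outputs should state which was used.

## Gini index and folding score

SHALiPE-seq stops concentrate on the 3′-most G of each tract when an
RG4 is folded and spread evenly when it is unfolded. For the `n` tract
guanines of a site (`gtract_g_positions()`; loop Gs excluded, all tract
Gs included by default — a last-G-only analysis can be run by
subsetting positions), dispersion is the population Gini index

$$\mathrm{Gini} = \frac{\sum_{i=1}^{n}\sum_{j=1}^{n}|r_i - r_j|}{2 n^2 \bar r},$$

with \(r_i\) the stop count at position \(i\). Both indices \(i,j\) run
over all \(n\) positions (ordered pairs), i.e. the population — not the
sample-corrected — definition, for fidelity to the formula as printed
in the SHALiPE literature. The implementation uses the sorted-weights
identity \(\sum_{i,j}|r_i-r_j| = 2\sum_i (2i-n-1) r_{(i)}\) and is
tested against the literal double sum to 1e-12. Replicate libraries
are summed position-wise before the Gini calculation.

In vitro probing under K⁺ (stabilizing) and Li⁺ (destabilizing) gives
folded/unfolded benchmarks. A site is eligible when
Gini(K⁺)/Gini(Li⁺) ≥ 1.1 *and* every contributing condition has mean
reads ≥ 10 (the reads filter is enforced per condition — the strictest
reading — so no score divides an unreliable profile). The boundary
comparison carries a 1e-9 absolute tolerance on the ratio so that sites
exactly at the printed threshold (0.22/0.20) are eligible despite
floating-point division. For eligible sites the folding score is

$$\mathrm{FS} = \frac{\mathrm{Gini}(\text{in vivo}) - \mathrm{Gini}(\text{in vitro Li}^+)}
{\mathrm{Gini}(\text{in vitro K}^+) - \mathrm{Gini}(\text{in vitro Li}^+)},$$

0 at the unfolded and 1 at the folded benchmark, reported raw (it can
fall outside [0, 1]; a clamp flag exists for plotting). The cold
response of a site is `delta_score = FS(4 °C) − FS(22 °C)`, and a site
is called *cold-responsive* when eligible and `delta_score` exceeds a
threshold that defaults to 0 — the class has no published numeric
cutoff, so the threshold is an explicit parameter and 0 ("any
cold-directed shift") is the documented assumption.
`stratify_and_compare()` summarizes `delta_score` by quartet class,
loop bin or region and runs pairwise Student's t tests (one-sided
`greater` by default, matching directional comparisons such as G3 > G2).

## Decay rates and translation efficiency

Transcription-arrest (cordycepin) time courses at 0/15/30/60/120/240
min are normalized per (transcript, condition, replicate) to the t = 0
point (optionally divided by an internal reference transcript).
Because the assay stops synthesis, abundance is modelled as
single-exponential decay; `fit_decay_rate()` does ordinary least
squares of \(\ln a(t) = -k t\) with no intercept (the series is
anchored at 1 by construction), pooled over replicates. The model
choice is an assumption documented here: first-order decay is the
standard model for transcription-arrest assays, is exactly recoverable
on noiseless data (tested to 1e-10), and scales exactly with the time
unit. A nonlinear raw-scale fit is deliberately not the default: on
lognormal noise, log-scale OLS is the maximum-likelihood estimator.
Negative fitted rates are kept (flagged `stabilized`), not truncated,
so cold-minus-control rate differences `delta_k = k(4C) − k(22C)`
remain unbiased. Half-life is \(\ln 2 / k\) (infinite for k ≤ 0).

Translation efficiency is polysome abundance divided by total
abundance after per-million scaling of each column (the upstream
normalization is unspecified in the emulated study, so per-million is
the default and can be disabled). The condition comparison reports the
Pearson correlation of TE(4 °C) against TE(22 °C) and the mean
relative difference. Steady-state 4 °C/22 °C abundance ratios are
summarized per RG4 category (nonRG4 / 5′-UTR / CDS / 3′-UTR, assigned
from scanner + cold-responsive calls; a transcript with RG4s in
several regions belongs to each) with t tests against the nonRG4
baseline.

## Synthetic-data generators

Each generator is a pure function of its seed; a single global seed
expands to per-component child seeds through `child_seed(seed, stream)`
with fixed stream ids, so adding a generator never perturbs existing
outputs.

* **Transcriptomes** — i.i.d. background with plant-like composition
  (A 0.31, C 0.20, G 0.19, U 0.30), lengths 900–2400 nt, boundaries at
  12% / 75% of length. With `background_clean = TRUE` every background
  G run of ≥ 2 is broken by substitution and planted motifs (loops
  drawn from A/C/U, flanks forced non-G) are the only scannable RG4s,
  recovered with exact spans — the regime used for round-trip tests.
* **Species × climate** — species-level G frequency and BIO1 follow a
  bivariate normal with a target correlation (−0.6 by default, n = 200
  species, matching the planted-signal recovery condition); BIO2–BIO19
  are independent with plausible means/spreads; per-occurrence values
  jitter around the species value (temperature ≈ 1 °C, precipitation
  tens of mm — small against the ≈ 6 °C between-species spread, as for
  real within-range climate variation); occurrence counts are 110–180
  with a configurable fraction below the >100 filter.
* **Stop counts** — `depth` stops multinomially distributed over the
  tract Gs with weights
  `folded_fraction · last_G_profile + (1 − folded_fraction) · uniform`,
  where the last-G profile puts λ = 0.85 on the four 3′-most Gs (split
  evenly) and the remainder evenly elsewhere. λ = 0.85 keeps folded and
  unfolded profiles clearly separable at depth 1000 without making the
  folded profile a degenerate point mass. The default in vivo folded
  fractions are 0.3 (22 °C) and 0.8 (4 °C) — a cold-enhanced folding
  scenario — with K⁺ = 1 and Li⁺ = 0 as benchmarks.
* **Decay / TE** — `a(t) = A0 · e^{−kt} · e^{N(0, σ)}` per replicate
  (σ = 0.1 by default, 3 replicates), with per-category rates planting
  the cold-stabilization ordering: 0.010 min⁻¹ at 22 °C everywhere and
  4 °C rates of 0.009 (nonRG4), 0.006 (5′-UTR, CDS) and 0.002
  (3′-UTR), i.e. Δk = −0.008 min⁻¹ for the 3′-UTR class. TE(4 °C) is
  TE(22 °C) times `1 + N(0, 0.02)`, a ~2% relative perturbation.

What the generators do *not* emulate: read-level sequencing artifacts
(ligation bias, drop-off gradients along the transcript), phylogenetic
covariance among species, spatial autocorrelation of occurrences,
transcript-abundance-dependent coverage, and non-exponential decay.
Passing tests therefore demonstrate correctness of the computations
and recoverability of planted effects under idealized noise — not
robustness to every failure mode of real libraries.

## Problem sizes and numerical choices

The routine verification built into the test suite and
`scripts/acceptance.R` uses: 1000 random profiles (n ≤ 50) for the
Gini oracle; 500 random 2-kb sequences plus 100 planted transcriptomes
(6 transcripts, 12 motifs each) for scanner/oracle equivalence; 60 and
200 sites at depth 1000 for folding-state separation and the cold
shift; a decay grid of k ∈ {0.001, 0.005, 0.02} min⁻¹ × σ ∈
{0.05, 0.2} with 200 series per cell plus 100 eight-transcript-
per-category cohorts for the Δk ordering; and 100 planted plus
40–60 null seeds of the 200-species climate panel. These sizes give
stable verdicts at interactive runtimes.

One measurement limit is worth stating explicitly: at k = 0.001 min⁻¹
(half-life ≈ 11.5 h) observed through a 240-min window with σ = 0.2
noise, the sampling sd of any log-linear estimator is ≈ 8 × 10⁻⁴
min⁻¹, so per-series relative errors of tens of percent are intrinsic
to that corner of the grid, not an estimator defect; the grid-wide
median relative error (≈ 4–5%) is the meaningful accuracy summary, and
the better-identified cells (k ≥ 0.005) individually achieve median
errors well under 15%.

Other numerical conventions: coordinates are 0-based half-open
internally; all-zero stop-count profiles yield `NA` Gini with a
warning rather than an error; constant vectors make a Pearson pair
`NA` (recorded, not fatal) inside the climate driver but are an error
when `pearson_with_p()` is called directly; BH inputs must lie in
(0, 1].

## Worked example

```{r example}
sim <- simulate_transcriptome(seed = 7)
motifs <- scan_transcripts(sim$transcripts)
count(motifs, quartet_class, region)

ex <- simulate_shalipe_experiment(n_sites = 40, seed = 7)
scores <- compute_folding_scores(ex$stop_counts, ex$sites)
summarise(scores, eligible = sum(eligible),
          mean_fs_22C = mean(score_22C, na.rm = TRUE),
          mean_fs_4C = mean(score_4C, na.rm = TRUE))

dec <- simulate_decay_and_te(seed = 7)
fits <- fit_decay_rates(normalize_timecourse(dec$timecourse))
decay_rate_difference(fits, dec$categories)$by_category
```

## Known limitations

* The scanner's grammar excludes bulged tracts, two-quartet irregular
  topologies and thermodynamic scoring (G4Hunter/cGcC); it is a motif
  counter, not a stability predictor.
* Cross-species correlations are not phylogenetically corrected;
  shared ancestry can inflate apparent composition–climate
  associations.
* The "cold-responsive" call depends on a threshold the field has not
  standardized; downstream category analyses inherit that choice.
* Folding scores compare one in vivo state against in vitro
  benchmarks measured on naked RNA; protein occupancy that mimics
  protection is indistinguishable from folding in this assay design.
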