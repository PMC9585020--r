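# rg4cold

Plants growing in cold climates carry transcriptomes enriched in
guanine and in RNA G-quadruplexes (RG4s) — four-stranded structures
formed by four G-tracts on one transcript — and cold itself promotes
RG4 folding in living cells, with consequences for mRNA stability.
`rg4cold` is an R package implementing the computational chain behind
that line of analysis:

* **Composition & motifs** — per-region (5′-UTR / CDS / 3′-UTR)
  nucleotide frequencies of a transcriptome, and a deterministic RG4
  scanner for two- and three-quartet motifs
  (`Gx N(1-7) Gx N(1-7) Gx N(1-7) Gx`, x = 2 or 3; G3 pass first,
  leftmost non-overlapping, non-greedy loops), with loop-length bins,
  genic-region assignment and per-kb densities.
* **Climate association** — Pearson correlation of per-species
  features against the 10/25/50/75/90-quantile profiles of the 19
  bioclimatic variables (BIO1–BIO11 temperature, BIO12–BIO19
  precipitation), Benjamini–Hochberg adjustment within each variable's
  quantiles, minimum-FDR representative selection, and signed
  significance counts per variable family. Species require more than
  100 occurrence records.
* **In vivo RG4 folding from SHALiPE-seq** — stop-count dispersion
  over tract guanines as the Gini index

  Gini = Σᵢ Σⱼ |rᵢ − rⱼ| / (2 n² r̄),

  benchmark eligibility (Gini(K⁺)/Gini(Li⁺) ≥ 1.1, mean reads ≥ 10
  per condition), and the folding score

  FS = (Gini(in vivo) − Gini(Li⁺)) / (Gini(K⁺) − Gini(Li⁺)),

  0 at the unfolded and 1 at the folded benchmark, plus
  cold-minus-control differences FS(4 °C) − FS(22 °C) stratified by
  quartet class, loop bin and region.
* **Expression dynamics** — first-order decay rates from
  transcription-arrest time courses (OLS on log abundance, t = 0
  anchored), half-lives, Δk = k(4 °C) − k(22 °C) by RG4 category,
  relative-abundance curves, translation efficiency
  (polysome / total) and steady-state abundance ratios.
* **Synthetic data** — fully seeded generators for every input format
  with planted ground truth (motif spans, feature–climate correlation,
  folded fractions, decay rates), used throughout the test suite.

See `vignettes/rg4cold-methods.Rmd` for the model details, parameter
defaults and known limitations.

## Worked example

Simulate a transcriptome with planted motifs, scan it, quantify
folding in a simulated SHALiPE experiment, and estimate cold effects on
decay:

```r
library(rg4cold)
library(dplyr)

sim <- simulate_transcriptome(seed = 7)
motifs <- scan_transcripts(sim$transcripts)
count(motifs, quartet_class, region)
#>   quartet_class region        n
#> 1 G2            CDS           2
#> 2 G2            FIVE_UTR      2
#> 3 G2            THREE_UTR     2
#> 4 G3            CDS           2
#> 5 G3            FIVE_UTR      2
#> 6 G3            THREE_UTR     2
```

The scanner recovers exactly the 12 planted motifs (2 per class and
region). SHALiPE folding scores, with in vivo folded fractions of 0.3
(22 °C) and 0.8 (4 °C) planted by the generator:

```r
ex <- simulate_shalipe_experiment(n_sites = 40, seed = 7)
scores <- compute_folding_scores(ex$stop_counts, ex$sites)
summarise(scores, eligible = sum(eligible),
          mean_fs_22C = mean(score_22C, na.rm = TRUE),
          mean_fs_4C  = mean(score_4C,  na.rm = TRUE))
#>   eligible mean_fs_22C mean_fs_4C
#> 1       40       0.257      0.795
```

Mean folding scores track the planted folded fractions, and every site
passes the benchmark filters at depth 1000. Decay-rate differences by
RG4 category (the generator plants Δk = −0.008 min⁻¹ for the 3′-UTR
class):

```r
dec <- simulate_decay_and_te(seed = 7)
fits <- fit_decay_rates(normalize_timecourse(dec$timecourse))
decay_rate_difference(fits, dec$categories)$by_category
#>   category      n mean_delta_k        se
#> 1 CDS          30    -0.00396  0.0000828
#> 2 FIVE_UTR     30    -0.00421  0.0000888
#> 3 THREE_UTR    30    -0.00791  0.0000858
#> 4 nonRG4       30    -0.000989 0.000134
```

Transcripts with 3′-UTR RG4s come out most stabilized in the cold
(most negative Δk), recovering the planted ordering.

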