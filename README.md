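# dielcycle

Tools for analysing **paired mRNA–protein expression dynamics over a
synchronized 24-hour light–dark cycle** — the situation of a phototroph
culture sampled every 2 h over 26 h, with transcript abundances from
strand-specific RNA-seq coverage and protein abundances from
isotope-ratio (e.g. ¹⁵N metabolic labelling) mass spectrometry.

The package is aimed at researchers who want to ask, per gene: *does the
transcript oscillate with the diel cycle? does the protein? and when both
do, how much is the protein oscillation damped and how long does its peak
lag the transcript's?*

## What it does

1. **Proteome rollup** (`quantify_proteome()`): peptide peak-ratio tables →
   protein log2 timecourses. CV-percentile quality filter, per-timepoint
   median normalization of the isotope mixing ratio, a scale-invariant
   inconsistency filter within protein–timepoint groups (cutoff 1.81),
   lognormal maximum-likelihood ratio estimates with small-sample
   (Gurland-corrected) 95% CIs, the 4/3/2/1-peaks-over-≥8-timepoints
   timecourse rule, and a 4.15× nearest-neighbour timepoint outlier rule.
   Every run emits an audit in which
   `peaks_in = retained + cv_filtered + iir_flagged + rejected` holds.
2. **Transcript quantification** (`quantify_transcripts()`): strand-specific
   per-base coverage (bedGraph) + gene models (GFF3) → per-gene sense and
   antisense abundances (coverage sum / gene length / total aligned bp)
   and antisense detection statistics.
3. **Rhythm detection** (`detect_cycling()`): for every log2 timecourse, an
   OLS cosinor fit with 24-h period,
   `y = m + a·cos(2πt/24) + b·sin(2πt/24)`, half-amplitude
   `H = √(a²+b²)` (fold change `2^(2H)`), phase = time of fitted maximum;
   significance from 1000 simulated AR(1) null series per gene (fit by a
   projection-corrected moment estimator, moderated across the
   collection, compared on a variance-studentized score), with
   polynomial-π₀ robust q-values and a sensitivity/specificity-corrected
   cycling proportion.
4. **mRNA–protein comparison** (`pair_cycling()`): per-gene lag on the
   (−2, 22] h convention, amplitude ratios in both log2-unit and
   fold-change form, phase classes (in-phase ±2 h / lagged 2–8 h /
   antiphase 11–13 h / other), transcriptional-control calls, peak-window
   lag summaries, cohort report.
5. **Synthetic data** (`sim_config()`, `simulate_dataset()`): a
   ground-truthed generator for all of the above (sinusoidal signals with
   gene-specific phase/amplitude/lag/damping, AR(1) noise, heteroscedastic
   peptide peak scatter, mixing biases, injected outliers, sense/antisense
   coverage), used by the test suite for end-to-end validation.

See the methods vignette (`vignettes/diel-expression-methods.Rmd`) for the
statistical model, defaults, and numerical decisions.

## Worked example

Simulate a 150-gene experiment and run the whole chain:

```r
library(dielcycle)

cfg <- run_config(sim = sim_config(n_genes = 150, seed = 42), n_sims = 500)
res <- run_pipeline(cfg, "demo_out")
#> [dielcycle] simulate: 150 genes, 14 timepoints, 16837 peaks
#> [dielcycle] quant-protein: 16837 peaks in, 12608 retained (74.9%), 150 proteins resolvable
#> [dielcycle] quant-transcript: 150 genes x 14 timepoints; antisense detected 70.7%
#> [dielcycle] detect-cycling: mRNA 118/150 significant; protein 42/150
#> [dielcycle] compare: 40 paired cycling genes

res$proteome
#> <proteome_quant>
#>   peaks: 16837 in; 12608 retained (74.9%), 3368 CV-filtered, 861 IIR-flagged, 0 rejected
#>   realized CV threshold: 0.407
#>   proteins: 150 detected, 150 resolvable timecourses

res$pairing
#> <diel_pairing>
#>   40 paired genes; classes: in_phase=6, lagged_2_8=28, antiphase=0, other=6; 3 transcriptional-control

summarize_cohort(res$pairing)$medians
#> # A tibble: 1 × 3
#>   median_amp_ratio_log median_amp_ratio_fold median_lag
#>                  <dbl>                 <dbl>      <dbl>
#> 1                 1.84                  1.59       4.41
```

Reading the output: 74.9% of simulated peptide peaks survive quality
filtering (the realized CV threshold, 40.7%, is logged so the
percentile↔CV correspondence is auditable); of the 40 genes cycling
significantly at both levels, most protein peaks lag their transcript by
2–8 h (median 4.4 h) and 31/40 are damped at the protein level (median
mRNA:protein half-amplitude ratio 1.84 in log2 units, or 1.59-fold in
fold-change terms).

Single series work the same way, tidyverse-style:

```r
t <- seq(0, 26, by = 2)
f <- fit_sinusoid_24h(t, 2 + 0.8 * cos(2 * pi * (t - 5.5) / 24) + rnorm(14, 0, 0.2))
f
#> <sinusoid_fit> period 24 h | mesor 1.857 | half-amplitude 0.868 log2 (3.33-fold) | phase 5.70 h
glance(f)          # one-row tibble; tidy(f) for per-term estimates
autoplot(f)        # data + fitted curve
```

`plot_phase_comparison()`, `plot_amplitude_comparison()` and
`plot_lag_histogram()` draw the standard cohort figures from a
`pair_cycling()` result. A thin command-line wrapper with `simulate`,
`quant-protein`, `quant-transcript`, `detect-cycling`, `compare` and `run`
subcommands lives at `inst/cli/dielcycle.R`.

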