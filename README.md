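# accelmix

External physical load profiling from wearable accelerometry via Gaussian
mixture modelling.

## What problem this solves

Trunk-mounted inertial sensors give coaches and sports scientists hour-long
tri-axial acceleration recordings of training and matches. The habitual
summary — the mean acceleration magnitude over the session — assumes a
unimodal intensity distribution. In stop-and-go sports the distribution of
active play is bimodal: a low-intensity mode (walking-level movement,
waiting between strokes) and a high-intensity mode (chasing, sprinting,
striking). A single mean blurs the two and is insensitive to exactly the
high-intensity exposure that drives fatigue and injury risk.

`accelmix` converts raw acceleration into an **acceleration index**,
segments play from rest, and models the in-play intensity distribution with
a two-component Gaussian mixture:

```
p(x) = (1 - w_high) N(x | mu_low, sigma_low^2) + w_high N(x | mu_high, sigma_high^2)
```

fitted by maximum likelihood (EM). The five parameters (mu_low, sigma_low,
mu_high, sigma_high, w_high) are the load features; the high-intensity
pair (mu_high, sigma_high) is the headline summary. The package also
computes the conventional raw-norm mean (mu_total) and a comparison layer
(standardization, Euclidean group distances over feature subsets, two-class
LDA) for contrasting the two approaches on a cohort.

The processing chain: second-order Butterworth band-pass 0.5–20 Hz (zero
phase, per axis) → vector norm → 1-s moving average (the acceleration
index) → rest detection (5-s smoothed detector < 0.3 G for ≥ 5 s) → pooled
in-play samples → EM mixture fit.

Because recordings of this kind are rarely shareable, the package includes
a synthetic match generator with exact ground truth (bout boundaries and
mixture parameters) at realistic defaults, so every stage is testable end
to end.

## Worked example

```r
library(accelmix)
cfg <- run_config()

# simulate a 10-minute match and run the full pipeline
rec <- simulate_match(synth_match_config(seed = 16))
res <- process_recording(rec$trace, cfg)
res$fit
#> <mixture_fit> two-component Gaussian mixture (EM)
#>   low : mu = 0.2667 G, sigma = 0.1029 G (w = 0.185)
#>   high: mu = 0.8769 G, sigma = 0.2532 G (w = 0.815)
#>   logLik -18075.02 after 204 iteration(s) on 70647 samples (converged)
```

The low mode recovered near 0.26 G and the high mode near 0.88 G match the
generator's truth (0.25 G and 0.90 G within the rendering tolerance); the
recording pooled 70,647 in-play index samples after rest removal.

```r
# a two-group cohort differing only in high-intensity behaviour
co <- simulate_cohort(synth_cohort_config(seed = 1))
rows <- lapply(co$recordings, function(r)
  as.data.frame(process_recording(r$trace, cfg, r$group)$features))
std <- standardize(feature_table(do.call(rbind, rows)))

distance_matrix(std)$best_pair
#> [1] "mu_high"    "sigma_high"
compare_methods(std)
#> proposed     {mu_high, sigma_high}: distance 1.682, LDA accuracy 95.0%
#> conventional {mu_total}: distance 1.256, LDA accuracy 85.0%
```

The feature pair separating the groups most is the high-intensity mean and
spread, and the mixture features classify the two groups more accurately
than the conventional overall mean — the central claim the pipeline is
built to support.

Command-line use (thin wrapper over the same functions):

```sh
Rscript inst/cli/accelmix.R simulate --out data/ --seed 1
Rscript inst/cli/accelmix.R process  --out run/ --groups A data/A_01.csv
Rscript inst/cli/accelmix.R compare  --out cmp/ run/features.csv
```

## Package layout

- `R/` — pipeline stages (`preprocess`, `segmentation`, `mixture`,
  `features`), IO (`trace`, `config`), generator (`synth`), commands
  (`cli`, `pipeline`)
- `src/` — EM core and zero-phase IIR inner loop (Rcpp)
- `vignettes/load-profiling.Rmd` — the model, its assumptions, numerical
  choices, and what the generator does and does not emulate
- `tests/testthat/` — unit, property and end-to-end suites
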