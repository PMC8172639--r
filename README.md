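# brass

Bias and Resolvability Attribution using Split Samples: an R package for
benchmarking single-cell and single-transcript measurement methods that were
run **in parallel on splits of the same culture**, so that biological and
experimental variability is shared between the methods being compared.

## The problem and who this is for

Single-cell methods (flow cytometry, microscopy, smFISH, HCR) measure the
same biology with different preparations, detections and measurands, and
their performance is hard to compare across experiments because
replicate-to-replicate variability confounds method differences. In a
split-sample design, every culture is divided at each step of the
measurement process, so a difference between two methods measured on the
same split cannot be a replicate effect. `brass` implements the analysis
side of that design for anyone benchmarking a new method (e.g. a new RNA
labeling chemistry) against an established one:

* **Resolvability** — the ability to distinguish the single-cell
  distributions at two stimulus levels, quantified by the area under the ROC
  curve between them:
  `AUC = P(signal_high > signal_low) + 1/2 P(tie)`,
  computed by rank sums (Mann–Whitney). 0.5 means complete overlap, 1
  complete resolution in the expected direction, 0 in the unexpected
  direction. Over an ordered stimulus series the adjacent-pair AUCs form an
  *AUC profile*, summarized by the average AUC.
* **Dose–response bias** — each distribution is reduced to its median (with
  1000-iteration bootstrap uncertainty), optionally normalized to relative
  promoter units, `RPU = (S_test − S_neg) / (S_pos − S_neg)`, and fit to the
  Hill equation `S = offset + A·xⁿ/(K₁/₂ⁿ + xⁿ)` by weighted nonlinear least
  squares, with inverse-variance weights clamped within a factor of 10 of
  their geometric mean.
* **Attribution** — pairs of methods differing in exactly one step
  (preparation, detection, measurand) are compared cell-by-cell across the
  (replicate × adjacent pair) grid with exact two-sided sign tests, and
  method-to-method vs replicate-to-replicate bias in Hill parameters is
  tested with tie-corrected Friedman tests (exact permutation option
  included).
* **Transcriptional bursting** — RNA-count distributions are fit with a
  negative binomial `P(n) = C(n+r−1, n) pʳ(1−p)ⁿ`; burst frequency
  `f = r/τ_RNA` (τ_RNA = 2.8 min by default) and burst size `b = (1−p)/p`.
* **Hybridization efficiency** — under binomial thinning with detection
  probability `p_m`, `E(Y) = μp_m` and `Fano(Y) − 1 = p_m(σ²/μ − 1)`, so for
  two methods differing only in efficiency both the mean ratio and the
  (Fano−1) ratio estimate `p_A/p_B`. The pooled median across both statistic
  types, all samples and replicates, times the reference efficiency, gives
  the absolute efficiency of the new method, and burst sizes are corrected
  as `b/ε` (frequency is unaffected).

A seeded generator (`simulate_experiment()`) produces a complete synthetic
split-sample experiment — shared latent negative-binomial RNA counts,
binomial thinning per labeling method, Hill-shaped protein response with
lognormal noise, per-replicate stimulus-potency shifts, DAPI stainability —
so the entire pipeline is testable without external data.

## Worked example

```r
library(brass)
set.seed(1)

# resolvability between two stimulus levels
lo <- rnbinom(500, size = 2, mu = 4); hi <- rnbinom(500, size = 2, mu = 9)
compute_auc(lo, hi)
#> [1] 0.76289

# Hill fit on a noisy dose-response
x <- stimulus_series()                       # 0 ... 1000 umol/L IPTG
y <- hill_function(x, 0.05, 1, 30, 1.8) * (1 + rnorm(8, 0, 0.01))
fit_hill(x, y)
#> <Hill fit> (raw) status: converged
#>          offset      A  K_half      n
#> estimate 0.0511 0.9921 29.2198 1.8704
#> se       0.0071 0.0102  0.5562 0.0599

# hybridization efficiency of HCR relative to FISH by binomial thinning
lat  <- lapply(1:6, function(i) rnbinom(400, size = 1.5, mu = 4 * i))
fish <- lapply(lat, thin_counts, efficiency = 0.95)
hcr  <- lapply(lat, thin_counts, efficiency = 0.341)
names(fish) <- names(hcr) <- paste0("s", 1:6)
efficiency_ratio(hcr, fish, n_boot = 1000, seed = 2)
#> <efficiency ratio> overall median 0.361 (95% boot CI 0.336-0.388)
#> absolute efficiency = 0.361 x 0.950 = 0.343 (34.3%)

# burst kinetics from one RNA-count table
f <- fit_negative_binomial(fish$s3)
burst_parameters(f$r, f$p_nb, tau_min = 2.8, efficiency = 0.95)
#> <burst> f = 0.4642 /min, b = 8.693 (corrected 9.15 at efficiency 0.95)
```

The AUC of 0.76 says a cell at the higher stimulus outranks a cell at the
lower one 76% of the time; the Hill fit recovers the planted parameters
(K₁/₂ ≈ 29 vs 30 true); the pooled-median estimator recovers the true
thinning ratio 0.341/0.95 ≈ 0.359 from the count distributions alone; and
the corrected burst size rescales the fitted `b` by the labeling efficiency
while leaving the burst frequency untouched.

The full pipeline runs from one configuration:

```r
res <- run_pipeline(pipeline_config(simulation = sim_config(), seed = 1))
```

and writes `auc_profiles.csv`, `hill_fits.csv`, `friedman.csv`,
`pairwise.csv`, `burst_fits.csv`, `efficiency.csv` plus a JSON manifest when
`out_dir` is set. A command-line wrapper with `simulate`, `analyze` and
`report` subcommands lives at `inst/scripts/brass.R`.

## Documentation

The methods vignette (`vignettes/brass-methods.Rmd`) describes the models,
the synthetic-data generator and its limits, the numerical choices inside
the fitters, and known limitations.
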