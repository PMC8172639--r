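---
title: "Methods behind brass: resolvability, bias attribution, and burst inference on split samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind brass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brass)
```

# The split-sample design

`brass` analyzes experiments in which one culture is divided at each step of
the measurement process — sample preparation (live-cell antibiotic
treatment with kanamycin or chloramphenicol, or RNA labeling by FISH or
HCR), signal detection (flow cytometry or microscopy), and measurand
(whole-cell protein fluorescence, whole-cell RNA fluorescence, or estimated
RNA count per cell). Because methods derived from one culture share its
biology, differences between them cannot be replicate effects. The default
design is ten cultures per replicate — an inducible construct at eight IPTG
concentrations (0, 5, 10, 20, 40, 100, 400, 1000 µmol/L), a constitutive
positive control used as the living reference for RPU normalization, and a
negative control — in biological triplicate, measured by twelve methods.
The twelve methods are data, not code: `method_validity()` reads a table
that users can replace to adapt the analysis to other designs.

# Resolvability: AUC between single-cell distributions

For two stimulus levels the resolvability of a method is the area under the
ROC curve between the two measured distributions,

$$\mathrm{AUC} = \Pr(Y_{high} > Y_{low}) + \tfrac12 \Pr(Y_{high} = Y_{low}),$$

computed via rank sums in $O(n\log n)$; the $O(n^2)$ pairwise count is kept
in the test suite as an independent oracle. Three conventions matter:

* **Ties count one half** (midrank convention). RNA counts are small
  integers with many ties, and the half-weight keeps the probabilistic
  interpretation above exact.
* **Direction is fixed by the stimulus**: the sample at the larger stimulus
  is always the positive class. AUC below 0.5 (resolution in the unexpected
  direction) is reported as-is, never folded, because it is diagnostic.
* **Profiles and averages**: over an ordered series the adjacent-pair AUCs
  form the AUC profile (seven values for the canonical eight-level series);
  the summary is their *unweighted* arithmetic mean. If a level is missing,
  the pairs touching the gap are dropped — never bridged, since an AUC
  across a wider stimulus gap is systematically larger and would bias the
  average — and the mean runs over the remaining pairs with a warning.

# Dose–response: medians, RPU, and the Hill fit

Each distribution is reduced to its median (robust to the heavy right
tails of fluorescence data). Uncertainty on the median is the variance over
1000 bootstrap resamples (`n_boot`, tunable). RPU normalization maps a
median $S$ to $(S - S_{neg})/(S_{pos} - S_{neg})$ using the same-replicate
controls measured by the same method; its variance follows by the
first-order delta method. A denominator below a relative tolerance of
$10^{-8}$ is reported as a degenerate-reference error rather than a huge
ratio.

The Hill equation

$$S(x) = \mathrm{offset} + A\,\frac{x^n}{K_{1/2}^n + x^n}$$

is fit by weighted nonlinear least squares. The weights are inverse
bootstrap variances, *clamped within a factor of 10 of the geometric mean*
of the available inverse variances within a replicate (computed from the
inducible samples only): bootstrapping underestimates the scatter around
the fitted curve, so unclamped weights would let one tight sample dominate.
Zero bootstrap variance (a constant sample) maps to the upper clamp.

Numerical choices:

* Bounds $A \ge 0$, $K_{1/2} > 0$, $n \in (0, 10]$, offset free. $x = 0$ is
  used as-is ($x^n$ defined as 0 there); there is no log-x transform.
* Multi-start Levenberg–Marquardt (`minpack.lm::nlsLM`) over
  $K_0 \in \{0.25, 1, 4\} \times$ the geometric mid-range of the positive
  stimuli and $n_0 \in \{0.5, 1, 2, 4\}$, with offset$_0 = \min y$ and
  $A_0 = \max y - \min y$; Hill least squares is multimodal in $(K, n)$ and
  a single start is not reliable. Best weighted RSS wins.
* Degenerate designs (for example a flat response) make the LM Jacobian
  singular at every start; the fit then falls back to bounded L-BFGS-B on
  the same objective and reports NA standard errors where the linearized
  covariance is singular. Only if every start of both optimizers fails is
  the fit flagged `status = "failed"` (a result, not an exception).
* Confidence intervals are Gaussian, estimate ± 1.96 SE, from the
  linearized covariance at the solution. With eight points and four
  parameters a $t_{4}$ interval would also be defensible; the z-interval is
  the documented choice, and coverage is verified empirically in the test
  suite (19–20 of 20 seeded fits cover $K_{1/2}$ and $n$).

# Attribution: sign tests and Friedman tests

Method pairs differing in exactly one step are enumerated by
`attribution_pairs()`. For the measurand step the default comparison is
protein versus whole-cell RNA fluorescence — the two measurands available
on both detections, which is what makes the four pairwise panels of the
benchmark design; `values = NULL` enumerates all eight measurand pairs
including RNA count. Matched (replicate × adjacent pair) AUC cells are
compared; ties are excluded (standard sign-test convention) and reported.
The sign test is the exact binomial two-sided p,
$p = \min(1,\, 2\min(P(X \le k_{min}), P(X \ge k_{max})))$ with
$X \sim \mathrm{Bin}(N, 1/2)$, and $p = 1$ when no cell breaks the tie.

Bias in Hill parameters is tested with the tie-corrected Friedman statistic,
once with method as primary factor and replicate as block, and once
transposed. Blocks with missing cells are dropped listwise, never imputed.
The p-value defaults to the $\chi^2_{k-1}$ approximation; with only three
blocks that approximation is rough, so an exact permutation null
(enumerating all $k!^n$ within-block rank assignments) is available behind
`exact = TRUE` and is used in the tests. For the fully concordant
$k = 3, n = 3$ case the statistic is 6, the chi-square p is 0.0498 and the
exact p is $6/216 \approx 0.0278$ — a gap of 0.022 that is inherent to the
approximation at this size, which is why conclusions should not hang on
p-value thresholds at $n = 3$ blocks.

# Burst inference and hybridization efficiency

RNA-count distributions are fit with an unmodified negative binomial
$P(n) = \binom{n+r-1}{n} p^r (1-p)^n$ with continuous $r$. Cells with zero
counts are retained: they pass the stainability QC and may be genuine
biology. The MLE profiles the likelihood over $\log r$ (the MLE of the mean
equals the sample mean for every $r$), initialized at the moment estimate
$r_0 = m^2/(v-m)$. Underdispersed samples ($v \le m$) return a boundary
result flagged `poisson_boundary` with $r$ capped at $10^4$. Burst
frequency is $f = r/\tau_{RNA}$ with $\tau_{RNA} = 2.8$ min by default, and
burst size $b = (1-p)/p$.

Binomial thinning with detection probability $\varepsilon$ maps
$\mathrm{NB}(r, p)$ to $\mathrm{NB}(r, p')$ with
$(1-p')/p' = \varepsilon\,(1-p)/p$: the size parameter $r$ — hence the
burst frequency — is invariant, while the apparent burst size scales by
$\varepsilon$. The efficiency-corrected burst size is therefore
$b/\varepsilon$, and frequency is never modified.

The relative efficiency of two labeling methods follows from the thinning
moments $E(Y) = \mu p$ and $\mathrm{Fano}(Y) - 1 = p(\sigma^2/\mu - 1)$:
both the mean ratio and the (Fano−1) ratio estimate $p_A/p_B$ sample by
sample. Samples where either Fano factor is ≤ 1 contribute no Fano-based
ratio (the ratio would be undefined or sign-flipped) but still contribute
their mean ratio. Ratios are computed in log space and exponentiated; the
pooled estimate is the median across both statistic types, all samples and
replicates (median is monotone-invariant, so the log-space choice changes
nothing). Confidence intervals come from 1000 bootstrap iterations
resampling cells within each table; the same bootstrap drives the interval
on the pooled median. Multiplying by the assumed absolute efficiency of the
reference method converts the ratio into an absolute efficiency.

Spot-level data can be cleaned with `spot_intensity_mixture()`: EM on the
log scale for a two-component lognormal mixture whose component log-medians
are constrained on either side of a user-supplied threshold (how to choose
the threshold is deliberately left to the user; it is a property of the
imaging setup). All data on one side of the threshold yields a degenerate
single-component result rather than a forced fit.

# The synthetic experiment generator

`simulate_experiment()` draws, per culture, a latent pool of cells with
negative-binomial RNA counts (burst frequency and size each Hill-shaped in
the effective stimulus) and lognormal protein levels around the protein
Hill curve; every method derived from that culture subsamples the same
pool. The split-sample contract is enforced by construction: each labeling
preparation's thinning outcome is drawn once per culture and shared between
flow and microscopy detection, and the measurands of one
(preparation, detection) route observe the same cells. Replicate effects
enter only as a stimulus-potency multiplier $\rho_r$ on $x$, which shifts
$K_{1/2}$ by $1/\rho_r$ without moving offset, cooperativity, or normalized
amplitude — the signature the Friedman replicate test is designed to
detect. Randomness is organized as one global seed plus per-table
substreams derived by stable key hashing, so adding methods never perturbs
existing tables and two runs with one seed are bit-identical.

Defaults follow the study design where it is explicit: the eight-level IPTG
series, three replicates, 20000 cells per flow sample and 500 per
microscopy sample, $\tau_{RNA} = 2.8$ min, hybridization efficiencies 0.95
(FISH) and 0.341 (HCR, ratio 0.359). Where no value is stated the defaults
are chosen once at magnitudes typical of bacterial reporter experiments:
protein amplitude 2×10⁴ a.u. over an offset of 200 with 35% cell-to-cell
CV, potency multipliers (1, 0.7, 1.4), per-transcript brightness 120 a.u.
with 25% CV, detection noise 5% (flow) and 15% (microscopy), and 5% poorly
permeabilized cells whose DAPI and labeling are suppressed five-fold.

What the generator does *not* emulate: optics (PSF, focus drift,
segmentation errors), spot-detection and brightness-to-count calibration,
cell-cycle and growth effects, RNA–protein per-cell correlation (a
`couple_rna_protein` flag exists for future use but is off by default, as
no generative model for that correlation is assumed), and instrument-
specific gating. Passing tests on synthetic data therefore demonstrate that
the estimators recover the parameters of this generative model under the
split-sample structure — not that real microscopy artifacts are handled.

# Quality control

Cells whose DAPI signal is below half the arithmetic mean of their sample
are excluded before analysis (poor permeabilization). The threshold uses
the *pre-exclusion* mean — the rule is single-pass, and re-applying it with
a recomputed mean can exclude more cells, which the tests assert against.
Ties at exactly half the mean are retained. The filter applies only where a
DAPI column exists (microscopy tables); flow event tables carry no DAPI.

# Problem sizes used in the tests

The shipped tests run the generator at 300 flow / 150 microscopy cells with
100-iteration bootstraps for the integration tests, 5000 counts for the
negative-binomial recovery and thinning-invariance checks, $10^5$ draws for
moment closed-form checks, and 1000-iteration bootstraps at
8 levels × 3 replicates × 500 cells for the efficiency-ratio recovery;
these sizes give stable Monte-Carlo behavior while keeping the suite quick.
Null calibration of the tests uses $k = 5$ treatments over 20 blocks
(Friedman) and 400 non-tied cells (sign test): at very small $k, n$ the
exact tests are too discrete for any implementation to produce uniform
p-values, so calibration is checked at sizes where the null distribution is
near-continuous.

# Known limitations

* Wald intervals on Hill and NB parameters are first-order; at three
  replicates and eight doses their coverage is approximate, which is one
  reason the attribution layer is rank-based.
* The bootstrap of the median is known to underestimate curve-level
  variability; the factor-of-10 weight clamp mitigates but does not remove
  this.
* The efficiency-ratio identity assumes the two labeling methods differ
  *only* in detection probability; preparation-specific losses that change
  the latent distribution violate it.
* The exact Friedman option enumerates $k!^n$ assignments and is intended
  for small designs (its guard refuses beyond $10^7$).
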