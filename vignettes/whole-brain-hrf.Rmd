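---
title: "Estimating a whole-brain HRF from block-design BOLD fMRI"
author: "hrfkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating a whole-brain HRF from block-design BOLD fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Task fMRI detects activation by regressing each voxel's BOLD time course on
the convolution of a hemodynamic response function (HRF) with the stimulus
paradigm. The HRF, however, differs between species, and using a mismatched
(for example human) HRF on rodent data degrades both detection and the
interpretation of response kinetics. `hrfkit` implements the complete
workflow for measuring a species-specific HRF from block-design data and for
quantifying how much the choice of HRF matters.

The response model is the two-gamma form

$$\mathrm{HRF}(t) \;=\; A\,e^{-bt}\left(\frac{b^{p_1}}{\Gamma(p_1)}\,t^{p_1-1}
  \;-\; \frac{b^{p_2}}{V\,\Gamma(p_2)}\,t^{p_2-1}\right),$$

where the first gamma term produces the positive BOLD peak and the second the
post-stimulus undershoot. The five parameters are the amplitude $A$
(absorbed by normalization in most uses), the dispersion/rate $b$ (s$^{-1}$),
the peak and undershoot shape parameters $p_1$ and $p_2$ (with $p_2 > p_1 >
1$, which guarantees $\mathrm{HRF}(0) = 0$), and the peak-to-undershoot
ratio $V > 0$. Two presets ship with the package: the whole-brain mouse HRF
($b = 0.9$, $p_1 = 4.5$, $p_2 = 7.9$, $V = 1.8$) and the standard human
canonical set expressed in this parameterization ($b = 1$, $p_1 = 6$,
$p_2 = 16$, $V = 6$; its full width at half maximum evaluates to 5.3 s).
Rat-derived parameters are not hard-coded; they enter through a JSON
parameter file via `read_hrf_params()`.

## The estimation workflow

The chain mirrors how such an HRF is measured in practice:

1. **Detection** (`detect_activation()`): voxelwise ordinary least squares
   on either an order-9 finite-impulse-response (FIR) basis — nine
   contiguous boxcar bins tiling one 30 s block cycle — or a canonical basis
   of order 1 (HRF-convolved regressor) or 3 (plus temporal and dispersion
   derivatives). Activation is thresholded at uncorrected $p < 0.05$ with
   connected components of more than 5 voxels retained (6-neighbourhood).
   FIR detection is the default for HRF *measurement* because it does not
   presuppose the response shape being estimated.
2. **Extraction** (`extract_voxel_timecourses()`, `epoch_average()`):
   activated voxels are grouped by atlas structure; each voxel's analyzed
   series is folded over the 20 paradigm cycles into one 30 s epoch that
   starts 10 s before stimulus onset and is converted to % signal change
   against the mean of that 10 s pre-onset baseline.
3. **Polarity classification** (`classify_polarity()`): a curve counts as a
   positive response when its peak reaches 0.6% signal change *and* the
   signal decays by at least 40% of the peak afterwards; the inverted
   criteria define negative responses. Classification operates on curves
   smoothed by a 5 s moving average; by default the *unsmoothed* epoch
   average is what is subsequently fitted (`smooth_before_fit` flips this —
   the order of these two operations is a genuine free choice, and fitting
   the raw average avoids biasing the fitted kinetics by the smoother).
4. **Structure curves and fitting** (`structure_mean_curve()`,
   `fit_hrf()`): structures contribute only when more than four voxels are
   positive. The fit minimizes $\lVert y - A\,(\mathrm{HRF}(\theta) \otimes
   \text{paradigm})\rVert^2$ where the forward model reproduces the data
   path exactly: convolution over the full acquisition (so the analyzed
   window is in convolution steady state), sampling at TR, folding into one
   epoch, baseline subtraction. Fits are excluded when the normalized MSE
   (residual mean square over the variance of the measured curve) exceeds
   0.1 or when the fitted response rises — first crossing of 10% of its
   peak — before the 10 s stimulation onset.
5. **Aggregation** (`aggregate_whole_brain()`): included HRFs are evaluated,
   peak-normalized, averaged pointwise, and a single parameter set is
   obtained by refitting the two-gamma form to the mean curve. Parameter
   vectors are deliberately *not* averaged: the two-gamma family is not
   closed under parameter averaging, so the refit is the shape-faithful
   summary.
6. **Comparison** (`max_t_permutation_test()`, `compare_groups()`): two
   samples of curves are compared by the maximum over time of the pointwise
   Welch-type statistic
   $t(\tau) = |\bar{x}(\tau) - \bar{y}(\tau)| / \sqrt{s_x^2(\tau)/n_x +
   s_y^2(\tau)/n_y}$, calibrated by relabeling permutations. The p-value is
   the plain ratio $N/B$ of permutations whose max-$t$ strictly exceeds the
   observed one (the $(N{+}1)/(B{+}1)$ correction is available behind
   `plus_one`, off by default). Families of comparisons use a Bonferroni
   threshold $\alpha/m$ from the realized number of comparisons; groups
   enter testing only at $n \ge 6$.

## Numerical choices

* **Grids.** HRFs are evaluated at $dt = 0.05$ s over one 30 s cycle for
  convolution and fitting; curve characterization (FWHM by linear
  interpolation of half-maximum crossings) uses $dt = 0.01$ s.
* **Derivative basis.** The temporal derivative uses a 0.1 s onset-shift
  finite difference, the dispersion derivative a 1% relative perturbation
  of $b$ — the conventional finite-difference construction of the 3rd-order
  canonical set.
* **Optimizer.** Bounded Levenberg–Marquardt (`minpack.lm`) with 8
  multi-starts drawn log-uniformly (±50%) around $(b{=}1, p_1{=}5,
  p_2{=}10, V{=}2)$ under a fixed seed; bounds $b \in [0.1, 5]$,
  $p_1 \in [1.5, 15]$, $p_2 \in [p_1 + 0.5, 30]$, $V \in [0.2, 20]$. The
  constraint $p_2 > p_1$ is enforced by fitting the gap $p_2 - p_1$ as a
  box-bounded parameter. Convolutions inside the objective are FFT-based
  with power-of-two padding and a cached stimulus transform.
* **Degenerate inputs.** Exactly-fitted voxels (zero residual variance)
  report $p = 1$ when the task effect is also zero and $p = 0$ otherwise,
  so noise-free data yield perfect detection rather than 0/0. Time points
  where both the mean difference and the pooled variance vanish contribute
  $t = 0$; elsewhere a variance floor of $10^{-12}$ of the squared sample
  scale guards the denominator. An observed max-$t$ of exactly 0 (identical
  samples) reports $p = 1$: under the strict-exceedance rule the ratio
  $N/B$ would otherwise declare identical samples maximally significant.
  Ties in the permutation distribution count as non-exceeding.
* **Thresholds.** "More than four voxels" and "cluster size > 5" are strict
  inequalities; $p < 0.05$ is strict. Bonferroni thresholds are carried at
  full precision and displayed rounded to 4 decimals (0.05/210 → 0.0002,
  0.05/6 → 0.0083).

## The synthetic-data generator

`generate_dataset()` emulates the acquisition the workflow targets: TR 1 s,
620 volumes with the first 20 discarded as pre-steady-state, a 20-block
paradigm of 10 s stimulation / 20 s rest (1 Hz pulses of 0.5 s are modeled
as a block envelope by default — pulse substructure lies far above the HRF's
bandwidth, and a pulse-resolved stimulus sits behind `pulse_level`), an
ellipsoidal brain of 30 region-grown atlas structures of at least 10 voxels,
a baseline level of 100 so raw values read as $100 + \%$ signal change,
responders at a fraction 0.0836 of in-brain voxels with amplitudes of
$0.838 \pm 0.1$% signal change, and white Gaussian noise (0.2% by default;
an AR-free choice because it is the testable one). Responder counts are
drawn binomially at the configured fraction; responders are placed as
contiguous region-grown patches (mean 15 voxels, never below 6) because
real activation is spatially coherent — scattered single-voxel responders
would be erased by the cluster-extent rule the pipeline itself applies.
Optional knobs add linear drift, inverted (negative) responders and
group-specific responder fractions for sex/modality contrasts.

What the generator does *not* emulate: spatially correlated or
physiological noise, motion, slice-timing effects, coil sensitivity
profiles, or k-space physics. Tests passing on this generator therefore
demonstrate the correctness of the estimation machinery under the stated
noise model, not robustness to every artifact of real acquisitions.
A measured BOLD peak about 7 s after stimulus onset emerges from the
mouse-preset convolution; it is a consequence of the model, not an enforced
target.

## Design choices in open territory

* The epoch window (30 s, onset at 10 s) follows from the quality-control
  rule that a fitted response rising before 10 s "started prior to the
  stimulation": the baseline must span the 10 s before onset.
* The FIR window is one block cycle (30 s) in nine bins of 10/3 s — the
  unique choice that tiles the inter-onset interval exactly.
* Onset is the 10%-of-peak crossing of the fitted curve on a fine (0.05 s)
  steady-state cycle.
* NMSE is normalized by the variance of the measured curve, making "fit no
  better than the mean" score exactly 1.
* Permutations resample group assignments uniformly (with replacement
  across permutations); exhaustive enumeration replaces sampling
  automatically when at most 10,000 distinct splits exist.
* Activation-probability maps are compared after binarizing at
  probability > 0 by default; the cut is configurable since any other
  choice is equally defensible.

## Problem sizes used in the checks

The packaged tests and the acceptance script run desk-scale versions of the
study conditions: synthetic volumes of $16 \times 16 \times 8$ to
$24 \times 24 \times 12$ voxels with 8–30 structures (the full 620-volume,
20-block acquisition is always kept), 50-curve recovery experiments, and
200-replicate null calibrations at 1,000 permutations. These sizes were
chosen so every property that matters — exact noise-free recovery,
calibration of the permutation test, perfect detection under the cluster
rule — is exercised by the same code paths a full-size analysis would use.

## Known limitations

* With 10 s blocks sampled at TR 1 s, the undershoot parameters $p_2$ and
  $V$ are only weakly identified at realistic noise: the fit surface has a
  flat ridge along which the optimizer legitimately finds solutions with
  residuals below those of the generating parameters. Median recovery
  errors for $b$ and $p_1$ stay within 15% under study-scale noise, while
  $p_2$ and $V$ wander further (about 20%) without harming the fitted
  curve's shape. Whole-brain aggregation averages much of this out.
* The baseline window of each epoch overlaps the previous block's
  undershoot, so measured epoch amplitudes sit a few percent above the
  generating amplitude. This is a property of baseline-normalized block
  designs, not an artifact of the implementation.
* Functional testing treats curves as exchangeable under the null; it does
  not model within-animal correlation across structures.
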