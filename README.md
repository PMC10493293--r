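# hrfkit

Whole-brain hemodynamic response function (HRF) estimation and comparison
from block-design BOLD fMRI.

GLM-based analysis of task fMRI detects activation by regressing voxel time
courses on the convolution of an HRF with the stimulus paradigm — and the
HRF differs markedly between species. `hrfkit` is for researchers analyzing
rodent (or other non-human) task fMRI who need to *measure* the HRF of
their preparation rather than assume the human canonical one: it simulates
ground-truth block-design BOLD data, detects activation without assuming a
response shape, extracts and quality-controls structure-wise responses,
fits a species-specific two-gamma HRF, and tests HRF samples against each
other with a functional permutation test.

## The model

The response shape is the two-gamma HRF

```
HRF(t) = A e^(-bt) [ b^p1/Γ(p1) t^(p1-1)  -  b^p2/(V Γ(p2)) t^(p2-1) ]
```

with dispersion `b` (1/s), peak shape `p1`, undershoot shape `p2 > p1`, and
peak-to-undershoot ratio `V`. Presets: `hrf_preset("mouse")` — the
whole-brain mouse HRF (b = 0.9, p1 = 4.5, p2 = 7.9, V = 1.8) — and
`hrf_preset("human")` — the standard canonical set (b = 1, p1 = 6,
p2 = 16, V = 6). The estimation chain is: FIR (or canonical) GLM detection
with uncorrected-p + cluster-extent thresholding → structure-wise epoch
averaging and baseline normalization → polarity criteria (peak ≥ 0.6%,
post-peak decay ≥ 40%) → bounded multi-start nonlinear least-squares fit of
the paradigm-convolved HRF → NMSE ≤ 0.1 and onset ≥ stimulation-onset QC →
peak-normalized averaging and refit into one whole-brain HRF → functional
max-t permutation tests (Bonferroni-corrected, groups of n ≥ 6) between
structures, sexes, modalities or species.

## Worked example

Simulate a labeled dataset that emulates a rodent somatosensory block
design (TR 1 s, 620 volumes, 20 blocks of 10 s stimulation / 20 s rest,
~8.4% responding voxels at ~0.84% amplitude) and run the full analysis:

```r
library(hrfkit)

mouse <- hrf_preset("mouse")
characterize_hrf(evaluate_hrf(mouse, hrf_time_grid(30, 0.01)))
#> HRF kinetics: peak 0.17 at 3.55 s, FWHM 3.84 s, undershoot -0.0366 at 9.92 s

spec <- synthetic_spec(dims = c(16, 16, 8), n_structures = 8,
                       noise_sd = 0.2, seed = 3)
ds   <- generate_dataset(spec)
res  <- analyze_run(ds, run_config(spec = spec, basis = "fir9", seed = 2))
#> scan 1: 67 voxels survive p<0.05 & cluster>5 thresholding
#> scan 1: 59 positive voxels; 3 structures above 4 positive voxels; 3 fits
#> fits: 3 total, 3 included after NMSE <= 0.1 and onset >= 10 s QC (0.00% excluded)

res$whole_brain$params
#> Two-gamma HRF parameters:
#>   A = 4.82835, b = 1.07558 1/s, p1 = 4.9351, p2 = 10.1696, V = 2.17429
```

The log mirrors the pipeline's attrition: voxels surviving detection, the
positive-polarity subset, structures with more than four positive voxels,
and fits surviving quality control. At 0.2% noise the recovered dispersion
(b ≈ 1.08) and peak shape (p1 ≈ 4.9) sit near the generating mouse preset;
with `noise_sd = 0` the recovery is exact to optimizer precision. Fitted
parameters can be exported for use in external GLM software with
`write_hrf_params(res$whole_brain$params, "mouse_hrf.json")`.

Two samples of HRFs are compared with the functional max-t permutation
test:

```r
x <- sample_hrf_curves(10, hrf_preset("mouse"), seed = 1)
y <- sample_hrf_curves(10, hrf_preset("human"), seed = 2)
max_t_permutation_test(x, y, n_permutations = 10000, seed = 3)
#> Functional max-t test: t_max = 8.831, p = 0 (monte-carlo, 10000 permutations; n = 10 vs 10)
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/hrfkit.R` (subcommands `simulate`, `analyze`, `compare-basis`,
`ftest`, `export-hrf`).

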