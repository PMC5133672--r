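# defcyto

Deformability cytometry measures the mechanical phenotype of single cells
at high throughput: cells in suspension are driven through a microfluidic
extensional-flow junction where opposing flows stretch each cell within a
few microseconds while a high-speed camera records a short frame sequence
per cell. Cell mechanics is a label-free marker of cell state — for
example, pluripotent stem cells are smaller and more deformable than their
differentiated progeny — so the resulting per-cell profiles support
clustering, classification, purity gating and spike-in impurity detection
without antibodies.

`defcyto` implements the computational core of this assay for R:

- **Feature extraction** — segmentation (Otsu or fixed threshold,
  largest-component, hole filling), sub-pixel iso-contours, radial
  boundary traces by polar transformation about the area centroid, and the
  fifteen canonical biophysical parameters
  `A, C1, D1–D4, T1, T2, S1, S2, M1–M4, AR1`: initial equivalent diameter
  (μm) and circularity; deformability, the major/minor axis ratio
  `D = a/b` of the moment-equivalent ellipse, at junction arrival, on
  average, at maximum (`D3`) and at the final frame; time to maximum
  deformability `T1` (μs) and maximum strain rate `T2` (1/μs); maximum and
  residual strain `S = (L − A)/A`; boundary roughness and
  trace/moving-average intersection counts before and during stretch; and
  the area ratio.
- **Multiparameter statistics** — z-scoring with stored transforms;
  expectation–maximization Gaussian-mixture (EMGM) clustering initialized
  by k-means, scored by the within/between clustering error
  `E = [Σ‖xᵢ−m_C1‖² + Σ‖xⱼ−m_C2‖²] / (n‖m_C1−m_C2‖²)`; hierarchical
  backward feature elimination in clustering and SVM modes; SVM training
  (linear/Gaussian kernels) with stratified seeded 5-fold
  cross-validation, ROC/AUC, and JSON-serializable classifier bundles;
  size (`A < 15` μm), diagonal (`D3 > 1.4` and `A < 15` μm) and fitted
  75%-containment Mahalanobis quantile gates; spike-in mixture
  deconvolution, spike-response slope and limit of detection
  `LOD = sd_max / slope`; similarity matrices, PCA/LDA projections, the
  median `D3/A` stiffness summary; and bead-based stiffness calibration
  `log₁₀E = α + βD` (kPa).
- **Synthetic events** — a ground-truthed simulator: incompressible
  viscoelastic ellipses with creep strain `ε(t) = ε_max(1 − e^(−t/τ))`
  (so `D = (1+ε)²` analytically), Fourier boundary modes, rasterization to
  noisy multi-frame stacks, plus truncated-Gaussian feature-space
  populations and exact largest-remainder spiked mixtures — so every stage
  is testable without instrument data.
- **Workbench I/O** — canonical feature-table CSVs, multi-page TIFF event
  stacks with JSON sidecars, YAML run configurations, a manifest-writing
  `run_pipeline()`, density plots with gate overlays, and a CLI
  (`inst/cli/defcyto.R`) chaining
  `simulate | extract | cluster | train | classify | gate | lod | calibrate | plot | run`.

## Worked example

```r
library(defcyto)
set.seed(1)

## one cell: simulate a stretch event, then recover its profile from pixels
spec <- viscoelastic_cell_spec(initial_diameter = 15, max_strain = 0.5,
                               creep_time = 2,
                               boundary_modes = list(c(6, 0.03)))
ev <- simulate_event(spec, render_spec(noise_sd = 0.01), event_id = "demo")
round(extract_profile(ev), 3)
#>      A     C1     D1     D2     D3     D4     T1     T2     S1     S2
#> 15.016  0.983  1.001  1.705  2.116  1.599  5.000  0.194  0.457  0.266
#>     M1     M2     M3     M4    AR1
#>  0.008 12.000  0.022  6.000  1.002
```

The cell entered at 15.016 μm (true diameter 15 μm), reached its maximum
deformability `D3 = 2.116` five microseconds after junction arrival
(`T1 = 5`), at a maximum strain `S1 = 0.457` — the creep law saturates at
`ε_max(1 − e^(−5/2)) ≈ 0.459`, and `D3` tracks the analytic
`(1 + ε)² ≈ 2.13`. The mode-6 boundary perturbation shows up as twelve
trace/moving-average crossings before stretch (`M2 = 12`).

```r
## populations: train a classifier, gate, deconvolve a spiked mixture
specs <- benchmark_population_specs(n_classes = 2L, n_cells = 500L,
                                    separation = 3, seed = 1L)
train <- do.call(rbind, lapply(specs, generate_feature_population))
bundle <- train_svm(train, train$label, kernel = "gaussian", seed = 1L)
bundle$cv_accuracy
#> [1] 1

mix <- generate_spiked_mixture(specs, c(0.25, 0.75), 1000L, seed = 2L)
round(predict_fractions(bundle, mix), 3)
#> class1 class2
#>   0.25   0.75

gate <- fit_quantile_gate(train[train$label == "class1", ])
apply_gate(train[train$label == "class1", ], gate)$fraction
#> [1] 0.75

deformability_size_ratio(train)
#> [1] 0.1103
```

With two classes separated by three pooled SDs in six of fifteen
parameters, cross-validated accuracy is 1, a 25/75 spiked mixture is
deconvolved to the exact composition (largest-remainder allocation makes
the truth exact by construction), and the fitted day-0-style quantile gate
contains exactly 75% of its reference population.

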