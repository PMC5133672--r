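---
title: "Models and methods behind defcyto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind defcyto}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defcyto)
```

# The measurement this package models

In extensional-flow deformability cytometry, single cells in suspension are
carried at high speed into a microfluidic cross-junction where two opposing
flows stretch each cell along the outlet axis. A high-speed camera records a
short frame sequence per cell; stretch timescales are of order a few
microseconds, so a handful of frames spans the whole deformation and
relaxation. From each frame sequence the analysis extracts fifteen
biophysical parameters (`DC_PARAMETERS`): initial size `A` and circularity
`C1`, deformability `D1`–`D4` (the major/minor axis ratio of the
moment-equivalent ellipse at junction arrival, its mean and maximum over
junction residence, and at the final frame), timing parameters `T1` (time
from arrival to maximum deformability, μs) and `T2` (maximum strain rate,
1/μs), strains `S1` (maximum) and `S2` (residual), boundary-morphology
metrics `M1`–`M4` (roughness and trace/moving-average intersection counts,
before and during stretch), and the area ratio `AR1`.

Downstream, populations of such profiles are compared with a statistical
stack: z-scoring, expectation–maximization Gaussian-mixture (EMGM)
clustering scored by a within/between clustering error, hierarchical
backward feature elimination, SVM classification with stratified 5-fold
cross-validation and ROC analysis, flow-cytometry-style gating, spike-in
mixture deconvolution with a limit of detection, similarity matrices,
PCA/LDA projections, the median `D3/A` stiffness summary, and a bead-based
calibration mapping deformability to an effective elastic modulus in kPa.

Because no public instrument data accompany this problem, the package ships
a first-class synthetic event simulator; every stage is exercised and
tested on ground-truthed synthetic inputs.

# The synthetic cell model

## Creep law

A cell is an incompressible ellipse undergoing Kelvin–Voigt-type creep.
During junction residence the major-axis strain grows as

$$\epsilon(t) = \epsilon_{max}\,(1 - e^{-t/\tau}),$$

with time measured from junction arrival, and after exit it relaxes as

$$\epsilon(t) = \epsilon_{exit}\,[(1-\rho) + \rho\, e^{-t/\tau_r}],$$

where $\rho$ is the recoverable fraction. The single-time-constant creep
form is a modeling choice: the underlying deformation-versus-time response
of real cells is not specified by a published functional form, and this is
the simplest viscoelastic law that produces the observed phenomenology — a
monotone rise to a maximum (defining `T1`, `S1`, `T2`) and a partial
recovery (defining `S2`, `D4`). Ground truth for simulated events is
defined relative to this law.

Area is conserved during deformation (incompressibility): with initial
diameter `A` the semi-axes are $a = (A/2)(1+\epsilon)$ and
$b = (A/2)/(1+\epsilon)$, which links strain and deformability analytically
as $D = a/b = (1+\epsilon)^2$. This identity is what makes the
feature-recovery tests sharp: a rendered event with saturated creep at
$\epsilon_{max}=0.5$ must yield $D3 \approx 2.25$.

Boundary texture is added as static low-order Fourier modes on the radial
function, $r(\theta) = r_{ellipse}(\theta)\,(1 + \sum_k a_k \sin k\theta)$,
with amplitudes below 0.3 so the boundary stays simple and star-convex. A
$k$-lobed mode crosses its own moving average $2k$ times per revolution,
giving direct analytic control of the `M` metrics.

## Rendering

Frames are brightfield-like: a dark cell (fixed contrast 0.6) on a bright
background, rasterized with 2×2 subpixel coverage sampling, blurred with a
Gaussian PSF and given additive Gaussian noise. Defaults: 0.4 μm/px (a
15 μm cell is ~38 px across; the constructor refuses specs that would leave
the cell under 10 px), 1 μs frame interval, 3 pre-junction + 6 junction +
3 post-junction frames, 96×96 px. The event's ground-truth profile is
computed from the continuous noise-free shapes by dense polygon quadrature
(2048 vertices), not from pixels, so extraction accuracy is measured
against an independent analytic reference.

What the simulator does *not* emulate: optical cell-to-cell variation
beyond additive noise, internal structure (nuclei, granularity),
illumination gradients, motion blur, cell translation across the field,
out-of-focus effects, and the fluid dynamics of the junction itself.
Passing tests therefore demonstrate correctness of the *operators* under
controlled conditions, not instrument-level performance on real cells.

## Feature-space populations

Population-level experiments draw 15-dimensional truncated Gaussians per
class (`population_spec`), with physical bounds (`A > 0`, `D* ≥ 1`,
`T1 ≥ 0`, counts ≥ 0) enforced by rejection sampling. Spiked mixtures use
exact largest-remainder allocation rather than multinomial draws, so the
true composition of a mixture is exact by construction and
fraction-recovery tests compare against sharp targets.
`benchmark_population_specs()` provides the standard well-separated
multi-class layout: six informative parameters (`A`, `D2`, `D3`, `T1`,
`S1`, `M1`) separated by a chosen number of pooled SDs per adjacent class
pair, nine parameters identically distributed across classes.

# Feature extraction

Segmentation thresholds each frame (Otsu by default on the dark-cell
convention), keeps the largest connected component, fills holes, and takes
the *sub-pixel* closed iso-intensity contour at the threshold level
(`grDevices::contourLines`, a marching-squares construction with linear
interpolation). Sub-pixel boundaries matter: at ~38 px cell diameter a
±1 px boundary error is a ~5% area error, outside the 2% recovery target.

Shape statistics come from exact polygon moments (Green's theorem) of the
contour: area, perimeter, centroid, and the second-central-moment tensor
whose eigenvalues give the moment-equivalent ellipse. Deformability is the
major/minor axis-length ratio of that ellipse — rotation invariant by
construction and far more noise-robust than a bounding box. The radial
boundary trace r(θ) is sampled at 360 uniform angles by ray casting from
the area centroid with exact ray–edge intersection; shapes whose centroid
is not star-visible are signalled as degenerate rather than silently
mis-traced.

Morphology metrics compare the trace with its circular (wrap-around)
moving average, default window 31 of 360 samples — wide enough to smooth
pixelation, narrow enough to keep mode-6 lobes in the residual. Roughness
is `SD(residual)/mean(r)`; the intersection count is the number of sign
changes of the residual around the closed trace, counting a transition
through exact zero once. The moving average (not the raw border) is the
crossing reference; both metrics are invariant to the starting angle.

Conventions worth stating once: frame indices are 0-based;
`junction_arrival_index` comes from the event metadata (the simulator knows
it; for foreign data the fallback detects the first frame whose strain
exceeds 0.05). Events carry an optional `junction_exit_index`: without it,
junction residence is taken to end at the deformability peak, since the
mean junction deformability `D2` is otherwise undefined on relaxing
events. `T1` is defined as arrival-to-*maximum-deformability* time; the
alternative reading (total time including relaxation) is not used. Of the
fifteen parameters, `A`, `D3`, `D4`, `T1`, `T2`, `S1`, `M1`, `M3`, `M4`
follow their established meanings; `C1`, `D1`, `D2`, `S2`, `M2`, `AR1`
complete the family symmetrically (circularity, arrival/mean
deformability, residual strain, pre-stretch crossing count, area ratio) so
the full 15-dimensional profile is self-consistent.

# The statistical stack

**Standardization.** Features are z-scored; the training transform is
stored and reapplied to held-out data (never that data's own moments).
Zero-variance features are excluded with a warning.

**EMGM.** k-means (seeded, 5 restarts) initializes EM for a full-covariance
Gaussian mixture. The E step works in log space; the M step uses
maximum-likelihood (1/n) covariances with a permanent 1e-6 diagonal ridge;
convergence is declared at a relative log-likelihood improvement below
1e-6 (default cap 500 iterations, returning the best solution with a
warning if hit). The log-likelihood trace is non-decreasing — a property
the tests check on 100 random instances. Shared-covariance variants were
deliberately not used; full covariances are the least-assumption default
when the component shapes are unknown.

**Clustering error.** For two classes,
$$E = \frac{\sum_{x_i \in C_1}\|x_i - m_{C_1}\|^2 +
            \sum_{x_j \in C_2}\|x_j - m_{C_2}\|^2}
           {n\,\|m_{C_1} - m_{C_2}\|^2}.$$
The denominator's $n\,\|m_{C_1}-m_{C_2}\|^2$ normalization is a design
choice: it makes the statistic intensive (sample-size-free) and invariant
to global scaling and rotation, properties the tests verify. A
consequence worth knowing: under this definition, parameters that carry no
class signal strictly *increase* the error (they add within-class scatter
and no between-class separation), so backward elimination drives the error
*down* while noise parameters are being removed. On real data where all
parameters carry some signal the trajectory can run the other way; both
behaviors are consistent with the same statistic.

**Backward elimination.** Greedy worst-first: every remaining feature is
tentatively removed, the criterion (clustering error after an EMGM refit,
or 5-fold CV misclassification after an SVM refit) is recomputed, and the
best removal is committed. In SVM mode, criterion ties are resolved by the
classic SVM-RFE ranking — the tied feature with the smallest squared
weight in the linear decision function is removed. This matters in
practice: on strongly separable data the CV error ties at zero for nearly
every candidate removal, and a naive positional tie-break would discard
informative features by accident of column order. The final tie-break
everywhere is the lowest feature index, and all randomized steps take
explicit seeds.

**SVM.** `e1071::svm` (libsvm) with cost fixed at 1; the Gaussian kernel
width uses the median heuristic on pairwise distances
($\gamma = 1/(2\,\mathrm{med}^2)$, computed on a ≤1000-row subsample).
Cross-validation is stratified and seeded; accuracy is the fraction of
points classified correctly; multiclass is one-vs-one. Bundles serialize
to a single JSON file (transform statistics, kernel spec, support vectors
and dual coefficients, feature list, seed); a reloaded bundle predicts
through the package's own one-vs-one decision function and the tests
require exact agreement with the in-memory model.

**ROC.** Thresholds sweep all distinct score values with ties grouped;
AUC by trapezoid equals the tie-corrected Mann–Whitney statistic (checked
exactly against a pairwise oracle).

**Gating.** Size gate: `A < 15` μm, strict. Diagonal gate: `D3 > 1.4` and
`A < 15` μm, strict. The quantile ("day-0"-style) gate is a Mahalanobis
ellipse fitted on a reference population: center at the feature means,
shape from the covariance, radius at the empirical `containment` quantile
of the reference Mahalanobis distances, so exactly
`ceiling(containment * n)` reference points fall inside or on the
boundary — the 75% default containment holds by construction, not by
asymptotics. The ellipse (rather than a box or a kernel contour) is the
natural two-moment gate; a singular covariance falls back to an
axis-aligned quantile box with a warning.

**Mixtures, spike response, LOD.** Predicted composition is the fraction
of rows assigned to each class. The spike response is the OLS line of
predicted versus spiked fraction across a dilution series (slope 1 ideal);
the analytical sensitivity is that slope divided by the maximum replicate
SD across mixing ratios, and the limit of detection is its inverse,
`sd_max / slope` — the caption-literal reading in which only the maximum
SD normalizes the slope, with no additional axis rescaling. Fractions are
kept in [0, 1] internally; the CLI reports percent.

**Projections and summaries.** The similarity matrix is plain pairwise
Euclidean distance on standardized rows, ordered by class so block
structure is visible. PCA (on standardized data) fixes signs so each
component's largest-magnitude loading is positive. LDA solves the
generalized eigenproblem $S_b v = \lambda S_w v$ directly, adding a 1e-6
ridge to a singular within-class scatter — implemented in-package so that
ridge behavior is an explicit contract. `deformability_size_ratio` is the
population median of `D3/A`, compensating the size-dependence of applied
hydrodynamic stress.

**Stiffness calibration.** Bead calibration fits
$\log_{10} E = \alpha + \beta D$ over ≥3 beads (the intended span is
roughly 0.2–40 kPa agarose beads). The log-linear form reflects that
moduli span two orders of magnitude while deformability varies over a
unit-scale range; mapping outside the fitted deformability range is
flagged as extrapolation, and a fit with $R^2 < 0.5$ warns.

# Reproducibility and problem sizes

Every randomized operation takes an explicit seed; the pipeline derives
per-stage seeds from a single global seed and the stage name, and its
manifest records configuration and MD5 checksums so a re-run is verifiably
bit-identical. The test suite sizes were chosen to make each claim
statistically sharp at desk scale: 5000-point references for gate
containment, 500 rendered events for feature recovery (9 frames each,
creep time 0.8 μs so the deformability peak stays localized in time while
creep saturates to within 1%), 2000-point training sets for classifier
nulls, 100 random instances for EM monotonicity, and 10 seeds for the
3-informative/12-noise elimination recovery in both modes.

# Known limitations

- The creep/recovery law and the completed parameter definitions are the
  package's reference model; real instruments may define `T1`'s endpoint
  or deformability differently, and profiles extracted here are comparable
  across this package, not across instruments.
- Segmentation assumes one dark cell per frame on a bright background;
  bright-cell or multi-cell fields need preprocessing.
- The boundary trace assumes star-convexity about the centroid — adequate
  for near-elliptical cells, wrong for strongly concave shapes (these are
  signalled, not silently traced).
- The clustering-error statistic compares exactly two classes; multi-class
  clustering quality is not defined here.
- Classification accuracy, AUC and LOD values obtained on synthetic
  populations characterize the operators, not any real cell system.
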