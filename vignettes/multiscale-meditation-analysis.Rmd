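---
title: "Multiscale analysis of ordered meditative states: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale analysis of ordered meditative states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medstates)
```

## The analysis problem

Advanced concentration-absorption meditation of the jhana type (ACAM-J)
progresses through eight ordered states (J1–J8), typically bracketed in
the scanner by non-meditative control tasks (silent counting, episodic
memory recall). `medstates` implements a complete analysis chain for
such designs, at three spatial scales plus brain–behavior coupling:

1. **Local synchrony (ReHo).** Kendall's coefficient of concordance
   \(W\) over each voxel and its neighbors' time-course ranks,
   standardized, smoothed, and parcel-averaged.
2. **Macroscale hierarchy (connectivity gradients).** Diffusion-map
   embedding of a sparsified, cosine-similarity affinity built from the
   parcel-wise functional connectivity matrix, aligned across segments
   by orthogonal Procrustes rotation to a template; the principal
   gradient (G1) spans the unimodal-to-transmodal axis and its range
   quantifies hierarchy differentiation.
3. **Global dynamics (geometric eigenmodes).** Laplace–Beltrami
   eigenmodes \(\psi_k\) (eigenvalues \(\lambda_k\)) of a cortical
   surface mesh; vertex time series are projected to mode coefficients
   \(\omega_k(t)\), summarized as power \(|\omega_k(t)|\) and energy
   \(|\omega_k(t)|^2\lambda_k^2\).
4. **State-trajectory inference.** Random-intercept linear mixed models
   with orthogonal polynomial contrasts (linear, quadratic, cubic) over
   the ordered state index, iterative degree reduction, categorical
   state-versus-control contrasts, and Benjamini–Hochberg FDR.
5. **Brain–behavior coupling.** Partial least squares correlation
   (PLSC) of brain metrics against phenomenology, trait, or cognition
   tables, with permutation inference on singular values, bootstrap
   salience stability, Kaiser retention, and latent Pearson
   correlations; chained-equation imputation with predictive mean
   matching handles missing behavior entries.
6. **Contextual decoding and robustness.** Correlation decoding of
   unthresholded state-minus-control delta maps against a
   psychobehavioral term-map library, and subgroup spatial-similarity
   checks with permutation inference and a linear similarity trend over
   states.

Because no public dataset accompanies this design, the package ships a
first-class synthetic-data module that plants known effects at every
scale; all validation is parameter recovery against that ground truth.

## The local synchrony model

For a neighborhood of \(m\) series over \(T\) time points with rank sums
\(R_t\),

\[
W \;=\; \frac{12\sum_t (R_t-\bar R)^2}{m^2(T^3-T) - m\sum_i C_i},
\qquad C_i = \sum_g (t_g^3-t_g),
\]

with mid-ranks for ties and the standard tie correction \(C_i\) (the
common choice in neuroimaging implementations; it keeps \(W \le 1\)).
The stencil is configurable as 7 (faces), 19 (faces+edges), or the
default 27 (full cube). Voxels at mask boundaries are scored on their
shrunken in-mask neighborhood rather than dropped, down to a minimum of
4 neighbors; this preserves cortex edges on small grids and is
configurable. Standardization (z-scoring across the mask, \(n-1\)
denominator) precedes smoothing; smoothing is a separable Gaussian with
\(\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})\) per axis in voxel units,
truncated at \(4\sigma\) (truncation error below \(10^{-4}\) of kernel
mass) and renormalized by the smoothed mask so that out-of-mask voxels
neither bleed in nor attenuate edge values. A consequence of mask
renormalization is that total map mass is conserved only away from the
boundary band.

## The gradient pipeline and its conventions

Connectivity is the Pearson correlation between parcel time series.
Sparsification is **row-wise**: each row keeps its top \(1-s\) fraction
of off-diagonal entries by value (default sparsity \(s=0.9\)), ties at
the cutoff all kept (deterministic), negatives among the kept entries
clipped. Cosine similarity between the sparsified rows gives the
affinity, negatives clipped to zero. The embedding uses anisotropic
normalization \(W' = D^{-\alpha} W D^{-\alpha}\) with \(\alpha = 0.5\)
and Markov normalization, followed by eigendecomposition; coordinates
are the nontrivial eigenvectors scaled by \(\lambda/(1-\lambda)\)
(diffusion time 0). Row-wise thresholding, \(\alpha\), and the
diffusion-time convention follow the dominant gradient-mapping toolbox
conventions; all are exposed in the configuration. Disconnected
sparsified graphs are refused with the block sizes named rather than
silently embedded, and repeated-eigenvalue (rotationally degenerate)
embeddings are flagged.

Procrustes alignment is orthogonal only — rotation/reflection after
column centering, **no isotropic scaling** — because scaling would erase
exactly the dispersion differences (hierarchy flattening) the analysis
measures. Alignment is re-estimated for the configured 10 iterations;
with a fixed template the update converges immediately, and the
iterations matter only for evolving references.

## The eigenmode stage

The Laplace–Beltrami operator uses cotangent stiffness weights and a
**lumped (diagonal) mass matrix** (one third of incident triangle area
per vertex). Lumping makes projection a closed-form mass-weighted inner
product \(\omega = \psi^\top M y\) for mass-orthonormal modes and is
standard in surface eigenmode work; a general least-squares path is used
whenever a vertex mask excludes rows (e.g. a medial wall), and a plain
pseudoinverse projection is available as an alternative. Eigenpairs come
from the dense symmetric conjugate \(D^{-1/2} S D^{-1/2}\); signs follow
a deterministic convention (first non-negligible entry positive).

Summaries average power/energy over time **before** the log transform
(log base 10, floor \(10^{-12}\), floored values flagged); the
alternative order is a configuration switch. Eigengroups default to
spherical-harmonic multiplicities (sizes 1, 3, 5, ...), the natural
partition for near-spherical meshes, with custom partitions accepted.

On a subdivision-4 unit icosphere the spectrum reproduces the analytic
sphere: groups at \(l(l+1) \in \{2, 6, 12\}\) within 3% with
multiplicities \(\{3, 5, 7\}\), and the package's tests assert exactly
that, together with projection orthonormality, complete-basis
reconstruction, and the Parseval identity at \(K = V\).

## Trend models

For each metric the package fits
\(y = \beta_0 + \sum_{d\le D}\beta_d P_d(\text{state}) + u_{\text{participant}} + \varepsilon\)
by restricted maximum likelihood, where \(P_d\) are orthonormal
(centered, zero-sum) polynomial codes. Fitting uses an internal profiled
REML solver specialized to the random-intercept structure: the single
variance ratio is optimized in one dimension with closed-form per-group
(Woodbury) solves, which makes massively univariate fitting (hundreds of
parcels, thousands of null simulations) run at about a millisecond per
model; unit tests verify agreement of fixed effects and variance
components with `lmerTest` on unbalanced data. Fixed-effect tests are t
statistics on residual degrees of freedom
\(N_{\text{obs}} - N_{\text{participants}} - D\); Satterthwaite-type
corrections are deliberately not used, and the reduction tests use the
coefficient p-value under REML (likelihood-ratio reduction under ML
would be the natural alternative; the choice is declared in the output
metadata). Iterative reduction drops only the single highest degree per
step and never removes the linear term; the full-degree fit is retained
for audit. Contrast analyses model condition categorically against the
composite control (mean of counting and memory per participant), with
estimated marginal means, FDR within each model's eight contrasts, and a
second FDR across metrics; the FDR family definitions (trends: across
metrics per modality; contrasts: two-level) are fixed and recorded.

## PLSC conventions

The cross-block matrix is computed on z-scored columns
(correlation-scale PLSC): behavioral domains mix 1–10 ratings with task
scores, so scale invariance is required. Permutation inference permutes
rows of the behavior block only and compares sorted singular values
index-wise, with add-one smoothing (minimum attainable p is
\(1/(n_{\text{perm}}+1)\)); a Procrustes-corrected permutation scheme is
a recognized alternative and deliberately not the default. Bootstrap
saliences are sign-aligned per latent variable to the original by inner
product before computing percentile intervals and bootstrap ratios
(|ratio| ≥ 1.96 flags stability); degenerate resamples are redrawn and
counted. The number of components equals the number of behavioral
variables, capped at the rank of the cross-block matrix. Multiple
imputations are averaged into one completed table before PLSC — a
declared simplification; full multiple-imputation pooling of PLSC
outputs is out of scope. The imputer itself assumes missing-at-random;
the generator plants missing-completely-at-random entries, a strict
subset of that assumption, to keep ground truth simple.

## What the synthetic generators emulate

The generators are pure functions of (spec, seed); a single master seed
drives a hierarchical stream per participant × condition so any subset
regenerates identically.

* **Local synchrony.** Each voxel mixes a parcel-shared signal with
  i.i.d. noise, \(y = \sqrt{w}\,s + \sqrt{1-w}\,\varepsilon\), with
  \(\mathrm{logit}(w)\) following planted linear/quadratic/cubic
  coefficients over the eight ordered states. Region groups (anterior,
  midline, posterior) are thirds along the first axis — deterministic
  and resolution-independent. The default plants the
  anterior-negative / posterior-positive linear pattern
  (anterior-to-posterior reorganization); controls use the base weight.
* **Gradients.** Parcels occupy latent coordinates \(g_i \in [-1, 1]\)
  with exponential-kernel signal correlation
  \(\exp(-|g_i-g_j|/\ell)\), \(\ell = 0.5\). Segments are sampled as
  \(c \cdot \mathrm{SNR} \cdot \text{signal} + \text{noise}\): the
  condition's compression factor \(c\) scales the hierarchy amplitude
  against sampling noise, which is how flattening manifests in real
  segment-level connectivity (weaker profile differentiation against a
  fixed noise floor). With the default calibration (SNR 2.4 at 40
  parcels and 60 volumes, fixed at design time) the segment-averaged
  principal-gradient range tracks \(c\) approximately proportionally,
  so the default \(c = 0.5\) in states versus 1 in controls yields a
  range ratio near 0.5. Per-segment ranges are noisy near the spectral
  transition, so the ratio is defined over segment averages; rarely, a
  sparsified segment graph disconnects and is skipped and counted.
  A noiseless kernel matrix is included in the ground truth for
  ordering-recovery checks.
* **Eigenmodes.** Per-state amplitudes on a planted mode group
  (default: U-shaped 2, 1.5, 1, 0.8, 0.7, 0.9, 1.3, 1.8 across J1–J8 on
  modes 2–10, giving the negative-linear-plus-positive-quadratic
  log-power trajectory) with unit-variance innovations and vertex
  noise.
* **Behavior.** A latent score projected from the brain summary matrix
  drives each behavioral domain through random unit saliences at latent
  correlation \(\rho\) (default 0.7); phenomenology is clipped to
  integer 1–10 ratings, and missing entries are inserted completely at
  random (default rate 0.1) in the phenomenology and trait tables.
  Rating and trait distributions beyond their scale bounds are not
  modeled (uniform-normal bases within bounds).
* **Term library.** 123 synthetic term maps; the planted term is an
  exact-correlation blend of the z-scored target with an orthogonalized
  noise map, so its sample correlation equals the target correlation by
  construction.

What these generators do **not** emulate: hemodynamic response shapes,
physiological (cardiac/respiratory) noise, head motion, spatial
autocorrelation of real BOLD fields, realistic parcel geometry, or
questionnaire response styles. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated statistical
structure, not robustness to every artifact of real 7T data. In
particular, the naive location-shuffling null in the subgroup
similarity permutation assumes exchangeable locations; real maps are
spatially autocorrelated, and a variogram-preserving (spin-style) null
would be more conservative there.

## Numerical choices and degenerate inputs

* Kendall's W returns missing when the tie-corrected denominator is not
  positive (all-constant neighborhoods).
* Zero-variance parcels and behavior columns are dropped with a warning
  naming them; all-zero affinity rows likewise.
* The REML optimizer profiles the variance ratio on a log grid and
  compares against the zero-variance boundary; on failure the trend fit
  falls back to OLS on participant-demeaned values and is flagged.
* Permutation p-values use add-one smoothing and never reach zero.
* Eigenvalues are clamped at zero from below; mode signs and PLSC
  salience signs follow deterministic conventions so repeated runs are
  byte-identical.
* Segments shorter than 20 volumes are refused; shorter than 60
  produces a warning (roughly the 3-minute mark at typical repetition
  times).

## Problem sizes used in the shipped validation

The packaged tests and the acceptance script run at desk scale, chosen
as the package's own validation conditions: oracle equivalence on
6×6×6×30 images; icosphere subdivisions 2–4 (up to 2562 vertices);
40-parcel gradient datasets with 8 segments per condition; 500-metric
null calibrations with 10–20 replicates; PLSC calibration over 200
replicate null datasets at 500 permutations; and an end-to-end run with
12 participants, 8 states plus 2 controls on a 10×10×10 grid at 60
volumes per segment. Resampling depths default to 10,000 in the
configuration and are scaled down in the end-to-end runner
(`resampling_scale`).

## Known limitations

* One participant missing late-state transition marks in a real dataset
  must be handled upstream: the package requires explicit segment rows
  and treats absent rows as missing data.
* The proportional compression-to-range response of the gradient
  generator is a calibrated approximation valid near the default
  regime, not an analytic identity; far from that regime the response
  saturates (ratio → 1 as noise vanishes, → 0 deep in the noise-dominated
  phase).
* Covariance-explained percentages use the \(\sigma_i^2/\sum\sigma^2\)
  convention throughout; no distinction is drawn between "shared
  covariance" and "shared variance" phrasings.
* PLSC rows may be participant×state segments or participant-level
  aggregates; the row-key contract accepts either, and the caller owns
  the exchangeability implications for permutation inference.
* The term-map interface is a local library (matrix + names); building
  a library from a public meta-analytic database is possible upstream
  but intentionally outside the tested surface.
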