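# medstates

Multiscale brain mapping of ordered meditative absorption states.

Advanced concentration-absorption meditation (jhana type, "ACAM-J")
moves through eight ordered states (J1–J8), scanned alongside
non-meditative control tasks (counting, memory). `medstates` implements
the complete analysis chain such designs call for, for neuroimaging
researchers studying altered states or any design with an ordered
within-participant condition factor:

- **Local synchrony (ReHo):** Kendall's coefficient of concordance
  over each voxel's neighborhood time-course ranks,
  W = 12 Σ_t (R_t − R̄)² / (m²(T³−T) − m Σ C_i), with mid-rank tie
  correction; z-scoring, mask-aware Gaussian smoothing, parcel
  averaging.
- **Connectivity gradients:** Pearson functional connectivity →
  row-wise sparsification (90%) → cosine affinity → diffusion-map
  embedding (α = 0.5, coordinates scaled λ/(1−λ)) → orthogonal
  Procrustes alignment to a template → principal-gradient (G1)
  range/SD summaries of hierarchy flattening.
- **Geometric eigenmodes:** cotangent Laplace–Beltrami operator with
  lumped mass on a triangle mesh, the K lowest eigenmodes ψ_k, mode
  coefficients ω_k(t) = ψᵀM y(t), power |ω_k(t)| and energy
  |ω_k(t)|²λ_k², log-scale segment summaries and eigengroup means.
- **State trends:** random-intercept mixed models with orthonormal
  polynomial contrasts up to cubic, iterative degree reduction,
  state-vs-composite-control contrasts with estimated marginal means,
  and Benjamini–Hochberg FDR (two-level for contrasts).
- **Brain–behavior coupling:** partial least squares correlation (SVD
  of the z-scored cross-block matrix), permutation inference on
  singular values, bootstrap salience stability, Kaiser retention,
  latent Pearson correlations; chained-equation imputation with
  predictive mean matching for missing behavior entries.
- **Decoding and robustness:** correlation decoding of unthresholded
  state-minus-control delta maps against a psychobehavioral term-map
  library (top-10 lists), subgroup spatial-similarity permutation
  tests, and a linear similarity trend across states.
- **Synthetic data:** seeded generators that plant known trend
  coefficients, gradient compression, U-shaped eigenmode power
  schedules, latent brain–behavior coupling, and a planted decoder
  term — every downstream stage is validated by parameter recovery.

## Worked example

A three-rater concordance check, an eigenmode basis, and the full
pipeline on a seeded synthetic dataset:

```r
library(medstates)

# Kendall's W for ranks (1,2,3), (1,2,3), (3,2,1): rank sums 5, 6, 7
kendalls_w(rbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1)))
#> [1] 0.1111111

# Laplace-Beltrami eigenmodes of a unit sphere mesh
m <- icosphere(3)
lbo <- assemble_lbo(m)
basis <- solve_eigenmodes(lbo$stiffness, lbo$mass, K = 16)
basis
#> <eigenmode_basis> 16 modes on 642 vertices; lambda in [5.68e-14, 11.8]
round(basis$eigenvalues[1:9], 3)
#> [1] 0.000 2.000 2.000 2.000 5.966 5.966 5.966 5.966 5.966
```

The eigenvalues reproduce the analytic sphere spectrum l(l+1) with
multiplicities 2l+1: the constant mode at 0, the l = 1 triplet at 2,
the l = 2 quintet near 6.

```r
spec <- simulation_spec(n_participants = 12, grid = c(10, 10, 10),
                        T_per_segment = 60, seed = 7)
res <- run_pipeline(spec, verbose = FALSE)
round(res$summary, 3)
#>  trend_sign_recovery       g1_range_ratio  mode_quadratic_beta
#>                1.000                0.535                0.431
#>           plsc_lv1_r     plsc_lv1_cov_pct           plsc_lv1_q
#>                0.553               90.654                0.014
#> plsc_salience_cosine    planted_term_rank       planted_term_r
#>                0.978                1.000                0.900
#>       subgroup_min_r
#>                0.996
```

Reading the summary: every parcel generated with a nonzero linear
local-synchrony trend is recovered with the planted sign
(`trend_sign_recovery` = 1); the principal-gradient range in meditation
states is about half the control range (`g1_range_ratio` ≈ 0.5,
matching the planted compression factor 0.5); the U-shaped eigenmode
amplitude schedule yields a positive quadratic log-power trend; the
first PLSC latent variable is significant (permutation q = 0.014) with
its behavior salience nearly parallel to the planted one (cosine 0.978);
the planted term ranks first in the 123-term decoder at its target
correlation 0.9; and the subgroup similarity maps agree at r > 0.99.

A command-line front end wrapping these functions (subcommands
`simulate`, `reho`, `gradients`, `eigenmodes`, `trends`, `plsc`,
`decode`, `robustness`, `run`) is installed at `inst/cli/medstates.R`:

```sh
Rscript inst/cli/medstates.R run --seed 7 --out summary.json
```

## Documentation

The methods vignette
(`vignettes/multiscale-meditation-analysis.Rmd`) documents the models
and their assumptions, every tunable parameter with its default and
rationale, what the synthetic generators do and do not emulate, and the
package's numerical conventions and limitations.
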