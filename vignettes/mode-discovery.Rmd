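---
title: "Discovering brain-behaviour modes with ccamodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering brain-behaviour modes with ccamodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccamodes)
```

## The model

`ccamodes` estimates *modes of covariation* between two participant-aligned
data blocks: an imaging block $X$ (participants $\times$ brain features,
e.g. FreeSurfer-style morphometry over a Desikan-Killiany parcellation) and
a behavioural block $Y$ (symptom scores, cognitive tests,
socio-environmental measures). A mode is a pair of weight vectors
$(a_k, b_k)$ whose participant scores $X a_k$ and $Y b_k$ are highly
correlated across participants — a latent dimension linking a weighted
brain pattern to a weighted behavioural profile.

The estimation pipeline is PCA $\to$ CCA $\to$ ICA:

1. **PCA** reduces each block to its leading components. This avoids the
   rank deficiency and noise fitting that plague CCA when the variable
   count approaches the sample size.
2. **CCA** between the two score matrices finds successive weight pairs
   maximizing $\mathrm{corr}(Xa_k, Yb_k)$ subject to within-block
   orthogonality. It is computed by the QR/SVD route (QR of each centered
   score matrix, SVD of $Q_x^\top Q_y$); no covariance matrix is ever
   inverted, so the solution is stable even near rank deficiency. The
   brute-force generalized-eigenproblem solver appears in the test suite as
   an independent oracle, never in the fitting path.
3. **ICA** rotates the canonical variates into *independent* modes. CCA
   only identifies the correlated subspace: when two modes have similar
   canonical correlations, any rotation of their variates is an equally
   good CCA solution, and the individual variates are dense, hard-to-read
   mixtures. A fixed-point ICA (log-cosh contrast, symmetric decorrelation,
   whitened input) estimates one $K \times K$ unmixing matrix from the
   vertically stacked canonical scores $[U; V]$ and applies it to both
   sides. Fitting a *single* rotation on the stack — rather than separate
   rotations per side — is what guarantees that an imaging-only weight
   matrix exists afterwards, which out-of-sample projection requires.

Because ICA leaves sign and order unidentified, the package fixes both
deterministically: modes are ordered by descending cross-side correlation,
and each mode is oriented so the behavioural variable with the largest
absolute loading loads positively. Flipping a mode's sign is always a
legitimate presentation choice.

Modes are interpreted through **variable loadings**: the Pearson
correlation of each original (de-confounded) variable with its side's
participant mode loadings, optionally as partial correlations controlling a
covariate such as age.

## Preprocessing

`preprocessBlock()` applies four steps in a fixed order:

1. **Cleaning** (`cleanBlock`): cells with robust z-score (median/MAD)
   beyond `zExtreme` are blanked, then variables and finally participants
   with more than `maxVarMissing` / `maxParticipantMissing` missingness are
   dropped. Defaults are $|z| > 4$ and 50 %; both are tunable because no
   universal threshold exists — the 8-SD contamination the synthetic
   generator plants is far outside any sensible choice, which keeps the
   stage testable without tuning.
2. **Imputation** (`knnImpute`): nearest-neighbour imputation over
   *variables as rows* — a missing entry is filled with the unweighted mean
   of the `k` nearest variables (Euclidean distance over mutually observed
   participants) observed for that participant. `k = 1` by default,
   matching the classic nearest-neighbour semantics of the MATLAB-style
   `knnimpute` tools.
3. **Residualisation** (`residualise`): per-variable OLS against dummy-coded
   categorical confounds (scanner site, scan sequence) with an intercept;
   volumetric features are additionally residualised for a global-volume
   covariate (eTIV), which may itself stay in the analysis as a variable.
   Residualisation is idempotent and leaves exactly zero column means —
   which is also why the composed projection matrices behave as purely
   linear maps downstream.
4. **Rank-based inverse normal transform** (`rankInverseNormal`):
   $z = \Phi^{-1}\!\big((r - c)/(n - 2c + 1)\big)$ with average ranks for
   ties. The Blom offset $c = 3/8$ is the default; Tukey, van der Waerden
   and rankit variants are selectable since published pipelines differ and
   rarely say which they used.

## Dimensionality, inference, validation

**Split-half reliability** (`selectDimensionality`): for each candidate
(PCA-brain, PCA-behaviour, K) triple, participants are repeatedly split in
half (stratified by site when available), the pipeline is fit independently
per half, modes are matched across halves by maximizing total |correlation|
of behaviour-side variable-loading vectors over all assignments (exact
exhaustive search, equivalent to optimal assignment for the $K \le 8$ used
here), and each candidate is scored by its *least* reliable mode, averaged
over splits. The candidate maximizing that worst-case reliability wins;
ties break toward fewer dimensions. Ten splits by default. A candidate
whose ICA rotation fails to converge even at a relaxed tolerance scores
zero for that split: an unstable rotation is the definition of unreliable.

**Permutation inference** (`permutationTestModes`, `permutationTestCCA`):
participant rows of the behaviour block are permuted (1000 times by
default), breaking the brain-behaviour link while preserving each block's
internal structure. The null statistic is the *maximum* mode (or canonical)
correlation per permutation, and
$p_k = \big(1 + \#\{\max\text{-null} \ge r_k\}\big)/(1 + n_{perm})$, which
controls the family-wise error across components and can never be zero.
Because a block's PCA basis is invariant to permuting the *other* block's
rows, and a row permutation of a centered matrix permutes its Q factor
while leaving R unchanged, each permutation costs one cross-product and a
small SVD — an exact reformulation, not an approximation. Whether the ICA
rotation should be refit inside each permutation is genuinely open; the
package refits by default (`icaInNull = TRUE`, single restart) so the null
reflects the full pipeline, with the cheaper canonical-correlation null
available as a flag (it bounds the mode statistic from above, hence is
conservative).

**Out-of-sample projection** (`projectOutOfSample`): the composed imaging
projection $P = B_{pca} A_{cca} T_{ica}$ maps de-confounded brain variables
of a *new* cohort straight to mode loadings, matching variables by name
(alias table supported, absent variables are a hard error — never silent
zero-fill). Replication is then assessed by (i) correlating the training
and new-cohort spatial loading maps with a **spin-permutation** null and
(ii) **bootstrap** 95 % percentile CIs for correlations between projected
brain loadings and phenotypes, optionally age-partialled.

The spin null preserves spatial autocorrelation: each spin draws a uniform
random rotation of the sphere (QR of a Gaussian matrix, sign-fixed,
determinant +1), applies it to left-hemisphere parcel centroids and its
midsagittal mirror to the right, and reassigns parcels to rotated
positions. The package defaults to one-to-one greedy nearest-centroid
matching, so every spin is a *permutation* of the map values (the value
multiset is preserved exactly); plain nearest-centroid reassignment, which
may duplicate source parcels, is available via `oneToOne = FALSE` with
duplicate counts recorded. Features without spherical coordinates
(subcortical volumes, global summaries) are freely permuted among
themselves within each spin — they have no geometry to rotate. The spin p
is two-sided on $|r|$.

**Post-hoc association** (`diagnosisContrasts`, `comorbidityTrend`,
`robustnessReruns`): mode loadings are regressed on diagnosis category plus
age, centered-age$^2$ and sex; estimated marginal means are evaluated at
covariate sample means and each category is contrasted against the
reference ("no diagnosis"), with Tukey studentized-range adjustment
$p = P\!\big(q_{k,df} \ge |t|\sqrt{2}\big)$ — with two groups this is
exactly the pooled t-test. Whether the published convention adjusts across
all pairs or only reference contrasts is ambiguous; both are provided
(`allPairwise`). Centering age before squaring decorrelates the linear and
quadratic terms. Robustness re-runs report the concordance (Pearson r of
variable-loading vectors) between the original fit and sex-residualised
refits, covariate-partialled loadings, or leave-one-diagnosis-out
projections.

## The synthetic study

`generateLinkedBlocks()` defines the study conditions every test runs
under. Each planted mode $k$ gives both sides the latent
$z_{side} = \sqrt{\rho_k}\, z_{shared} + \sqrt{1-\rho_k}\, z_{unique}$, so
the two sides correlate at exactly $\rho_k$ in expectation and the target
canonical correlations are controlled analytically. Observed variables are
random Gaussian mixtures of the side latents plus i.i.d. noise
(`noiseSd = 1`). Latent factors are standardized **Laplace** draws by
default: a rotation recovered by ICA is only identifiable for non-Gaussian
sources, and heavy-tailed composite scores are also what real
rank-normalised questionnaire data deliver at the latent level; a Gaussian
option exists for null studies. Confound structure (site offsets, age
trends), MCAR missingness, $\ge 8$-SD extreme cells, and diagnosis labels
whose probability is monotone in one latent mode are added by
`injectConfoundsAndNoise()` and `assignDiagnoses()`.

Desk-scale defaults are n = 500 with 120 imaging and 200 behavioural
variables — roughly a quarter of the motivating cohort's 1732 × (447, 793)
scale, which remains available behind the `paper_scale` config flag. Test
problem sizes (n = 200–2000, 199–1000 permutations/spins, 100–1000
bootstraps, 20-run selection studies) were chosen so the full suite
exercises every stage at meaningful power on a single CPU.

What the generator does *not* emulate: realistic FreeSurfer covariance
structure, ordinal questionnaire marginals, site-by-variable interactions,
or longitudinal structure. Passing tests therefore demonstrate the
*estimator's* correctness and calibration under known truth, not that any
particular real dataset satisfies its assumptions.

## Numerical choices and degenerate inputs

- ICA: log-cosh contrast ($a = 1$), tolerance $10^{-7}$, 500 iterations
  maximum, 5 random restarts keeping the highest negentropy sum;
  non-convergence after all restarts is an error reporting the final
  tolerance (inside permutation nulls, a failed single-restart refit falls
  back to the conservative canonical-correlation bound).
- CCA clamps canonical correlations to [0, 1] against floating-point
  overshoot; attainable rank is checked and reported.
- Constant variables: an error in the inverse-normal transform (or
  pass-through as zeros behind a flag), an `NA` loading (never a fake zero)
  in variable-loading tables, an excluded-and-counted draw in bootstrap
  resamples, a hard error in spin maps.
- Ties in ranks get average ranks; assignment ties in mode matching break
  by enumeration order, selection ties toward smaller dimensionality.
- All randomness flows from explicit integer seeds; identical seeds
  reproduce every artifact byte-for-byte (manifest hashes in
  `runPipeline()` make this checkable).

## A worked example

```{r example, eval = FALSE}
sim <- generateLinkedBlocks(n = 500, pBrain = 120, pBehav = 200, kTrue = 2,
                            crossBlockCorr = c(0.9, 0.7), seed = 1)
conf <- generateConfoundTable(sim$imaging, seed = 2)
raw <- injectConfoundsAndNoise(sim$imaging, conf,
                               effects = list(site = c(siteB = 0.5)),
                               missingRate = 0.02, extremeRate = 0.005,
                               seed = 3)
prX <- preprocessBlock(raw, conf, confoundSpec = c("site", "sequence"))
prY <- preprocessBlock(sim$behaviour, conf,
                       confoundSpec = c("site", "sequence"))
modes <- runFullDecomposition(prX$block, prY$block, K = 2, seed = 4)
modeCorrs(modes)
permutationTestModes(prX$block, prY$block, K = 2, nPerm = 1000, seed = 5)
```

## Known limitations

- No sparse or regularized CCA: with very many variables relative to n the
  PCA step is the only regularizer.
- Mode matching is exact only up to $K = 8$ (exhaustive assignment).
- The spin null operates on parcel centroids, not surface vertices, and
  treats non-surface features by free permutation.
- The bootstrap resamples participants of the projection cohort only; the
  training-fit uncertainty is not propagated.
- Diagnosis contrasts assume homoscedastic residuals across categories
  (ordinary least squares with a pooled error term).
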