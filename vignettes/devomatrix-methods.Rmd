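---
title: "Estimating and comparing developmental, genetic and phenotypic covariance matrices from bilateral landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing developmental, genetic and phenotypic covariance matrices from bilateral landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

devomatrix quantifies *developmental variability* in a bilateral
morphological trait and asks whether it predicts standing genetic
variation and environmentally induced shape change. The data model is a
classic common-garden quantitative-genetic design: full-sib families from
several source populations are reared at two temperatures, and a paired
left/right structure is landmarked twice per side so that measurement
error is separable from biological asymmetry.

## The decomposition of shape variance

Each record is a configuration of $k$ 2D landmarks ($p = 2k$ shape
variables). After generalized Procrustes superimposition (the designated
side mirrored first — *matching symmetry*), a record's shape is modeled
as

$$
y_{isr} = \mu + a\,\log CS_i + \beta_T x_i + \beta_L \ell_i +
\delta\,[s = \text{right}] + g_{f(i)} + e_i + d_{is} + \varepsilon_{isr},
$$

with $g \sim N(0, \mathbf{G})$ the family (broad-sense genetic) deviation,
$e \sim N(0, \mathbf{E})$ the individual-environment deviation,
$d \sim N(0, \mathbf{D})$ the side-specific developmental deviation
(fluctuating asymmetry), and $\varepsilon$ heteroscedastic digitizing
error. The quantities of interest are the covariance matrices:

* $\mathbf{D}$ — the *developmental* covariance, from the
  individual-by-side component. Because left and right share a genome and
  an environment, their random divergence isolates developmental noise.
* $\mathbf{P} = \mathbf{G} + \mathbf{E}$ — the among-individual
  ("static") covariance after fixed-effect adjustment.
* $\mathbf{G}$ — the between-family component (full-sib, so broad sense),
  pooled within populations.

`symmetry_anova()` performs the Goodall-style bilateral Procrustes ANOVA
(SS summed over shape variables; individual, side, individual×side and
error terms), testing the FA term against measurement error and
supplementing the F statistic with a permutation test that shuffles side
labels within individuals.

## Why everything is fitted in a reduced shape space

Superimposition removes translation (2), rotation (1) and scale (1), so
aligned covariance matrices have rank at most $2k - 4$: sample
mean-square matrices in the raw variable frame are *exactly singular* and
Wishart likelihoods are degenerate there. All variance-component fitting
therefore happens in the $(2k-4)$-dimensional tangent basis $T$ computed
at the consensus, and estimates are mapped back as $T \hat\Theta T'$.

The same projection applies to digitizing error. Raw noise that is
independent per coordinate loses its four similarity components during
alignment, so the aligned error covariance is $T' \mathrm{diag}(\sigma^2) T$
— *not* diagonal. The residual model keeps one free variance per shape
variable (heteroscedastic, as the landmarking process warrants) but
propagates it through the projection. Early versions modeled the aligned
error as diagonal; the misspecified off-diagonal error structure was then
absorbed by spurious extra factor dimensions and inflated AIC-selected
ranks, which is why the projected form is used throughout.

## Estimators

With $r$ replicates per side, the signed right-minus-left contrast of
replicate means has covariance $2\mathbf{D} + (2/r)\,\Sigma_\varepsilon$.
The moment estimator residualizes the contrasts on the directional
asymmetry (intercept), mean log centroid size and cohort, and subtracts
the projected error covariance:

$$
\hat{\mathbf{D}} = \tfrac12\left(\mathrm{Cov}(\text{contrasts}) -
\tfrac{2}{r}\, T\,\mathrm{diag}(\hat\sigma^2)\,T'\right),
$$

with $\hat\sigma^2$ estimated once from the within-(individual, side)
replicate residuals by restricted maximum likelihood. $\hat{\mathbf{P}}$
subtracts the FA and error noise carried by individual means
($\mathbf{D}/2 + \Sigma_\varepsilon/(sr)$) after adjusting size,
temperature and population; $\hat{\mathbf{G}}$ is the between-family
component $S_B - S_W/n_0$ of fixed-effect-adjusted individual means. The
`method = "reml"` path maximizes the joint two-stratum restricted
likelihood numerically (quasi-Newton on the same strata, analytic
gradients); on balanced designs the optimum coincides with the moment
estimator, which the tests verify to $10^{-6}$ relative Frobenius error.
Estimates are PSD-clipped at zero for reporting, with the unclipped
matrix retained internally for unbiased downstream corrections.

## Factor-analytic rank selection

Morphometric covariance matrices are strongly rank-deficient, so
`fit_factor_model()` restricts a component to
$\Lambda\Lambda' + \mathrm{diag}(\psi)$ with $\Lambda$ a $p \times m$
loading matrix (zero upper triangle, non-negative diagonal for
identifiability; $\psi$ floored at $10^{-10}$ of the trace). The
restricted likelihood is maximized by L-BFGS-B with analytic gradients,
three starts (eigendecomposition of the moment estimate plus jitter), and
the problem rescaled to unit variance for conditioning. The observed
information matrix (finite differences of the analytic gradient) supplies
the parameter sampling covariance.

`select_rank()` grows the dimensionality and stops when adding a
dimension no longer improves the fit significantly. Plain minimum-AIC
overfactors by one in roughly a fifth of replicates (the
likelihood-ratio statistic at a rank boundary is not chi-square), so the
default rule accepts a rank only when it both lowers AIC and passes the
sequential likelihood-ratio test at $\alpha = 0.01$; the conservative
level compensates for boundary over-rejection and for testing a sequence
of ranks. `rule = "aic"` restores plain minimum-AIC. Because the forward
rule stops at the first weak step, trailing dimensions with very small
eigenvalues can be missed at modest family numbers; that conservatism is
reported as-is in the AIC trace.

## Comparing covariance matrices

* **Common-subspace (Krzanowski-style) comparison.** Both matrices are
  projected on the leading $q = 6$ eigenvectors of an independently
  estimated reference (by default $\hat{\mathbf{P}}$), and the
  log-variances along the shared axes are related: Pearson's $r$ and the
  OLS slope $b$ of $\log v_B$ on $\log v_A$ (the predictor is
  $\mathbf{D}$, so $b$ answers how developmental variance predicts
  genetic variance). Six axes is the largest rank shared by all matrices
  in the emulated design.
* **Random skewers.** Unit "selection" vectors (components uniform on
  $[-1,1]$, then normalized — the classic convention; a Gaussian-sphere
  option is provided and both are tested against brute-force oracles)
  are applied to both matrices and the mean absolute cosine between the
  paired responses is reported, with an analytic null from the
  distribution of $|\cos\theta|$ between independent random directions
  ($\cos^2\theta \sim \mathrm{Beta}(\tfrac12, \tfrac{p-1}{2})$).
* **Leading eigenvectors.** `vector_correlation()`/`vector_angle()`
  compare $d_{max}$ and $g_{max}$, with a deterministic eigenvector sign
  convention (largest-magnitude element positive).

Uncertainty is propagated by **REML-MVN resampling**: parameter vectors
are drawn from the multivariate normal centered at the estimates with
the fit's sampling covariance — on the covariance ("G") scale, i.e. the
variance parameters themselves, not their logs — and a matrix is rebuilt
per draw. For moment estimates the half-vectorized matrix is drawn with
its Wishart sampling covariance. Draws are PSD-clipped for reported
matrices; the confidence-interval machinery (`krzanowski_compare_ci()`)
uses the *raw* draws, because clipping biases the resampled statistic
stream (empirically, nominal-95% coverage of the subspace correlation
fell from 94/100 to 87/100 when the stream was clipped). Intervals are
bias-corrected accelerated (BCa) percentiles; the acceleration constant
comes from jackknife values when units (families, individuals) are
available and is zero otherwise.

## Alignment with environmental shape change

Shape-change vectors come from multivariate least squares:
$\beta_L$ from family-mean shapes on latitude (plus mean size), and
$\beta_T$ from individual-mean shapes on the two-level temperature
contrast (plus size and population). Their alignment with a covariance
matrix $\mathbf{M}$ (scaled to unit trace) is

$$
e_\beta = \frac{\beta' \mathbf{M} \beta}{\lVert\beta\rVert^2} \in
[\lambda_{\min}, \lambda_{\max}],
$$

the fraction of the matrix's variance captured by the direction; it
equals $\lambda_1$ when $\beta$ runs along the leading eigenvector and
$1/p$ for an isotropic matrix. Significance is assessed one-sidedly
against a null of unstructured directions. The phrase "resampling the
shape vectors" admits more than one scheme, so both are implemented:
random element permutations of the observed vector (the default —
norm-preserving, destroys landmark structure; exact because spherical
and permutation-invariant nulls coincide) and isotropic random unit
vectors. Angle tests likewise permute both vectors (or draw isotropic
pairs) and count null angles at least as small as observed. Both tests
are type-I calibrated within [0.03, 0.07] at $\alpha = 0.05$ in the test
suite.

## What the synthetic generator emulates — and what it does not

`default_sim_params()` fixes the study conditions the package targets:

* **Design**: 8 landmarks (16 shape variables), 80 full-sib families × 4
  offspring split evenly across 19 and 27 °C, five source populations
  (one Mediterranean, four along the invaded latitudinal gradient;
  true population latitudes are not published, so a plausible monotone
  set is used — any monotone set supports the recovery tests), plus an
  unstructured laboratory cohort of 114 females: 434 individuals, and
  434 × 2 sides × 2 digitizations = 1736 records.
* **Covariance structure**: $\mathbf{D}$ has rank 7 and $\mathbf{G}$
  rank 6 inside the 12-dimensional shape space, the dimensionalities the
  design is built to exhibit. $\mathbf{G}$ shares $\mathbf{D}$'s eigenvectors
  with log-eigenvalues related with slope 1.9, a strong
  developmental–genetic alignment; $\mathbf{E}$ has
  its own full-rank structure.
* **Magnitudes**: variance components are calibrated so the bilateral
  ANOVA attributes about 11% of total shape variance to fluctuating
  asymmetry with a Goodall F near 4.7 (the FA-to-error mean-square ratio
  pins $\mathrm{tr}(\mathbf{D})/\mathrm{tr}(\Sigma_\varepsilon)$; the
  projection of raw digitizing noise into shape space — factor
  $(p-4)/p$ — is folded into that calibration). Allometry, temperature,
  latitude and cohort effects take a further ~20% of the
  among-individual variance.
* **Alignment pattern**: $\beta_T$ and $\beta_L$ are constructed
  orthogonal to $d_{max}$ and spread over trailing developmental
  dimensions, so the pipeline should find a strong D–G subspace
  correlation alongside non-significant $e_\beta$ and angles near
  80–90°: developmental variability predicting genetic covariation but
  not environmental shape change.

Deviations are generated in the tangent space of the mean shape,
orthogonal to the similarity transformations, so the true matrices live
in the same $(2k-4)$-dimensional space as the estimates; raw records then
receive the individual's size, a random rotation and translation, and the
left side is mirrored as a camera would see it. The generator does *not*
emulate: digitization at the pixel level (noise is added in tangent
space, so the second-order curvature of Procrustes alignment is the only
nonlinearity), landmark outliers or missing records, unbalanced family
sizes, maternal or common-environment effects confounded with family,
pedigree structure deeper than full sibs, or genuine among-population
differences in $\mathbf{G}$. Passing recovery tests therefore show the
estimators are correct under the declared model, not that real tibia data
meet that model.

## Numerical choices

* GPA: partial Procrustes (every record centered and at unit centroid
  size), rotation-only orthogonal fits (determinant +1), convergence at
  $10^{-10}$ RMS consensus change, 100 iterations cap.
* Covariance clipping at eigenvalue 0; effective rank counted above
  $10^{-8}$ of the leading eigenvalue.
* Optimizer: L-BFGS-B, `factr = 1e5`, 3000 iterations, analytic
  gradients; non-convergence is flagged on the result, never silent.
* Reconstructed factor matrices include the specific variances by
  default (`reconstruct_cov(include_specific = TRUE)`); the pure
  low-rank part is available with a flag, since published analyses are
  ambiguous about which convention they report.
* Resampling defaults follow the emulated study design (10 000 MVN draws,
  10 000 skewers, q = 6); the bundled tests and the acceptance script
  use 1000–2000 draws, 20 seeds for recovery checks, 1000 replicates for
  calibration and 100 for coverage — sizes chosen so the whole suite
  runs in a few minutes while keeping Monte-Carlo error well inside the
  asserted margins.
* All randomness flows from explicit seeds; stage seeds in the pipeline
  are derived deterministically from the master seed.

## Known limitations

The REML paths assume balanced or near-balanced designs when separating
measurement error (cells with a single replicate are rejected, not
imputed). The Wishart-based sampling covariance for moment estimates
ignores the (small) uncertainty of the error-variance correction. BCa
acceleration defaults to zero when no jackknife units are supplied.
The forward rank-selection rule is conservative for weak trailing
eigenvalues. Object (within-configuration) symmetry is out of scope; the
data model is strictly 2D matching symmetry.
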