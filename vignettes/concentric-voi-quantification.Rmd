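---
title: "Concentric oversized-VOI quantification: models, assumptions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concentric oversized-VOI quantification: models, assumptions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voiquant)
```

# The measurement model

A source much smaller than the scanner resolution appears on a reconstructed
SPECT image as a blurred blob whose counts leak well beyond the anatomical
boundary. `voiquant`'s core estimator sidesteps partial-volume correction
entirely: a spherical VOI large enough to contain *all* counts from the source
is delineated, together with at least two further concentric VOIs of
increasing volume. Writing $C_i$ for the count rate and $v_i$ for the volume
of VOI $i$, the model is

$$C_i = C_{v=0} + a\,v_i + \varepsilon_i,$$

where $C_{v=0}$ is the count rate originating solely from the source, $a$
(cps/ml) is the mean activity-concentration of the surroundings expressed in
count-rate units, and $\varepsilon_i$ collects counting noise and any
departure of the local background from volume-proportional growth. The
estimator is ordinary least squares; the intercept standard uncertainty

$$u^2(C_{v=0}) = \frac{\sum_i (C_i - a v_i - C_{v=0})^2}{n-2}\cdot
  \frac{\sum_i v_i^2}{n\sum_i v_i^2 - \left(\sum_i v_i\right)^2}$$

uses the residual scatter on $n-2$ degrees of freedom, so non-uniform
backgrounds — which bend the line — automatically inflate the reported
uncertainty rather than silently biasing the estimate. Activity follows as
$A = C_{v=0}/(QR)$ with $R = 1$ by construction, and

$$\left[\frac{u(A)}{A}\right]^2 = \left[\frac{u(Q)}{Q}\right]^2 +
  \left[\frac{u(C)}{C}\right]^2 .$$

Key assumptions, and what happens when they fail:

* **All source counts inside the innermost VOI.** The default plan puts the
  innermost radius at $1.5\times$ the PSF FWHM, which encloses all but a few
  tenths of a percent of an isotropic 3D Gaussian. The residual spill-out
  grows across the outer VOIs and drags the intercept down slightly — a bias
  of a few tenths of a percent at the default plan (measured in the test
  suite), shrinking as the base radius grows.
* **Locally linear background.** An axial gradient that is approximately
  linear across the VOI span averages out by symmetry; structured hot
  neighbours do not, and show up as enlarged residuals and hence a larger
  $u(C_{v=0})$.
* **Independent residuals.** Concentric VOIs are nested, so their counting
  errors are correlated; the OLS uncertainty is approximate in the pure
  counting-noise limit. In practice $u(Q)/Q$ dominates the budget (see the
  coverage simulation below).

The implementation uses the closed-form normal equations rather than a
generic linear-model routine; the test suite cross-checks it against
`stats::lm` to $10^{-9}$ relative on randomized series.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `psf_fwhm` | 15 | mm | representative of I-131 SPECT with high-energy collimators; sets the default VOI plan |
| `base_radius` | `1.5 * psf_fwhm` | mm | smallest sphere that still encloses essentially all source counts |
| `radius_step` | `0.5 * psf_fwhm` | mm | spreads the volume lever arm without hitting phantom walls |
| `n_vois` | 4 | — | one more than the minimum of 3, giving 2 df for the uncertainty |

The number of VOIs, radii and increments are genuinely open choices — no
standard prescription exists — and all are arguments of
`quantify_concentric()`. Two-point series are refused unless forced, and then
return no uncertainty ($n - 2 = 0$). Negative intercepts (possible in very low
count regimes) are reported with a warning, never clamped: clamping would bias
any downstream coverage analysis.

A related choice: the regression is performed on **count rates** (cps), not
raw counts, matching the sensitivity's cps/MBq units. For a fixed acquisition
duration the two are equivalent up to a constant factor that cancels in
$A = C/Q$.

## Voxel geometry

A voxel belongs to a sphere iff its *centre* lies inside, and the VOI volume
used as the regression abscissa is the included-voxel count times the voxel
volume — not the analytic sphere volume. Ordinate and abscissa are thus
computed over identical voxel sets, which removes discretization bias from the
fit: on an exactly uniform background the points fall exactly on a line
regardless of how coarsely the spheres are voxelized. Voxel centres sit at
$(\text{index} + 0.5)\times\text{spacing}$ from the volume corner (0-based
indices).

# Comparator methods

**Local-background VOI.** $A = (C_V - (V_V/V_B)\,C_B)/(QR)$ with $R = 1$: an
oversized VOI plus a second VOI in nearby background whose concentration is
assumed representative. No uncertainty is attached to this method
(`u_activity = NA`) — it has no internal replication from which to estimate
one, which is itself one of its weaknesses in non-uniform backgrounds.

**Recovery coefficient.** Counts in an anatomically sized VOI are divided by
$R(v) = 1 - 1/(1 + (v/b_1)^{b_2})$ fitted to sphere-insert observations by
nonlinear least squares (`minpack.lm::nlsLM`, log-parameterised so $b_1, b_2 >
0$; started at $b_1 =$ the volume whose observed recovery is nearest 0.5,
$b_2 = 1$). The per-insert recovery is computed as $R_i = C_i/(Q A_i)$, the
form in which $R$ is a unitless fraction consistent with $A = C/(QR)$ and $Q$
in cps/MBq. Uncertainty at a queried volume combines the delta-method
parameter-covariance term with $|\partial R/\partial v|\,u(v)$, where the
delineated-volume uncertainty $u(v)$ is a user input (deriving it from CT
voxel size is out of scope). Because the curve is steep at small volumes,
$u(R)/R$ grows without bound as $v \to 0$ at fixed absolute $u(v)$ — the
quantitative expression of why this method fails for small sources.

# The digital-phantom simulator

The generator emulates the validation conditions in *reconstructed-image
space*: activity map $\to$ isotropic Gaussian blur $\to$ Poisson counts.
Physical acquisitions would resample and re-reconstruct projection data;
tomographic reconstruction is out of scope here, and image-space emulation
preserves the statistical structure the quantification methods actually
consume (local count rates, their Poisson dispersion, and background
gradients). The important caveats: real OSEM reconstructions have spatially
varying, object-dependent noise correlation and a non-Gaussian, non-stationary
PSF with septal-penetration tails; passing the simulation-based tests
therefore demonstrates correctness of the estimator chain under the stated
model, not performance on clinical reconstructions.

Study conditions are frozen into the presets:

* grid $48^3$ at 4.8 mm (the reconstruction pixel scale of a $128\times128$
  matrix SPECT), duration 4320 s (72 projections × 60 s), sensitivity
  28.9 cps/MBq, PSF FWHM 15 mm;
* `cylinder-nobg` / `cylinder-uniform` / `cylinder-gradient`: a 33.3 MBq
  point-like capsule centred in a 20-cm-diameter water cylinder, with no
  background, a uniform 46 kBq/ml background, or that background thinned by an
  axial keep-probability ramp (1 → 0.2);
* `anthro`: ellipsoidal torso and liver/spleen/kidney organs at 130.8, 77.2,
  13.8, 17.0 and 13.4 MBq with four 0.12-ml point sources at 30 MBq/ml.

Background composition mimics a composite-acquisition protocol: source and
background are rendered as independent Poisson realizations and summed.
Non-uniform backgrounds are produced by **binomial thinning** of the integer
counts (each count kept with probability $p$), which maps a Poisson field
exactly onto a Poisson field with scaled mean — the discrete analogue of
resampling acquisition data. Axial profiles provided: a linear ramp across the
full length and a half-volume profile with a smooth cosine transition. The
exact profiles used in physical experiments are only known graphically; the
ramp parameterization is representative, not a reproduction. Similarly, the
anthropomorphic lesion locations are plausible placements, not a
reconstruction of any particular phantom; organ activities *add* where
elements overlap.

The Gaussian blur is separable with the kernel truncated at $4\sigma$ and
renormalised, so expected counts are conserved exactly in the grid interior;
mass blurred past the boundary is reported as a warning when it exceeds
0.5 percent. All randomness flows through explicit integer seeds
(`render`, `thin`, `simulate_preset`), restoring the caller's RNG state, and
identical spec + seed gives bit-identical volumes.

The synthetic recovery-curve generator uses six spherical inserts (diameters
1.0–6.5 cm) at 0.3 MBq/ml with multiplicative Gaussian noise on count rates.
Its default curve ($b_1 = 5.6$ ml, $b_2 = 1.04$) is the logistic through two
anchor recoveries characteristic of small-volume I-131 SPECT — $R(0.33\,
\text{ml}) = 0.05$ and $R(2.6\,\text{ml}) = 0.31$.

# Dosimetry chain

`fit_monoexponential()` fits $A(t) = A_0 e^{-\lambda t}$ by least squares on
$\log A$ versus $t$, **unweighted by default**. The weighting the clinical
workflow should use is genuinely ambiguous; the unweighted log-linear fit is
the choice that makes the chain self-consistent for small-$n$ serial imaging
(equal relative uncertainties), and a `weighting = "relative"` option
(inverse-variance on the log scale, $(A/u(A))^2$) is provided. The
time-integrated activity is the analytic integral $A_0/\lambda$ over
$[0, \infty)$ — no trapezoidal segment — and its uncertainty is the delta
method on $\mathrm{TIA} = e^{\ln A_0}/\lambda$ with the full
$(\ln A_0, \lambda)$ covariance:

$$u^2(\mathrm{TIA}) = \mathrm{TIA}^2\left[u^2(\ln A_0) +
  \frac{u^2(\lambda)}{\lambda^2} -
  \frac{2\,\mathrm{cov}(\ln A_0, \lambda)}{\lambda}\right].$$

This first-order treatment is an approximation; with only three time points
the covariance rests on a single residual degree of freedom, so the reported
$u(\mathrm{TIA})$ should be read as an order-of-magnitude statement.

Absorbed dose is the self-dose MIRD form $D = \mathrm{TIA}\times S$,
neglecting cross-dose from surrounding activity. The primary path for the
dose factor $S$ is a user-supplied table of sphere masses and factors with
log–log interpolation (`dose_factor_from_table()`; extrapolation outside the
table is refused). The built-in `sphere_dose_factor()` is a physics
surrogate: the mean electron energy per decay (0.192 MeV for I-131) deposited
locally,

$$S = \frac{E_e \cdot 1.602\times10^{-13} \cdot 3.6\times10^{9}}
  {m\,[\mathrm{kg}]}\ \mathrm{Gy/(MBq\,h)},$$

a slight underestimate of tabulated factors since photon self-absorption is
ignored (an optional photon term with a user-supplied absorbed fraction can be
added). It exists for validation and order-of-magnitude work, not to replace
tabulated S values.

Calibration plumbing: $Q = C_{\mathrm{VOI}}/A_{\mathrm{capsule}}$ with
relative uncertainties combined in quadrature; the count-rate term defaults to
Poisson ($\sqrt{CT}/T$) when the acquisition duration is known; the reference
activity uncertainty combines the standard deviation of the mean of repeated
calibrator readings with the quoted calibrator-factor uncertainty. Decay
referencing uses $T_{1/2} = 8.0252$ d for I-131, overridable per nuclide.

# Validation design and problem sizes

The test suite validates each claim at sizes chosen to keep the default run in
tens of seconds:

* **Oracle equivalence** — `fit_intercept` vs `stats::lm` on 100 random
  series of 3–10 VOIs, at $10^{-9}$ relative; plus a hand-computed worked
  example (intercept 515 cps, $u = \sqrt{615}$ cps).
* **Exactness on noiseless inputs** — a synthetic point source plus exact
  uniform background is recovered to machine precision; affine background
  shifts move only the gradient.
* **Bias and honesty of uncertainties** — 50 seeded replicates per background
  scenario (none / uniform / axial gradient) at the preset conditions; the
  median signed error and the median reported relative uncertainty are
  checked against the few-percent regime the method is designed for.
* **Coverage** — 200 uniform-background replicates in which both the Poisson
  noise *and* the calibration error are realised (the applied sensitivity is
  drawn from $N(Q, u(Q))$), testing that $|A - A_{\text{true}}| \le 1.96\,
  u(A)$ holds at a rate consistent with a 95 % interval. Realising the
  calibration error matters: it is the dominant term in $u(A)$, and a
  simulation that always applies the true $Q$ would trivially over-cover.
* **Recovery-curve identifiability** — 100 seeded refits at 1 % noise;
  simulator statistics — pooled index-of-dispersion test for Poisson counts
  and mean-scaling of binomial thinning.

# Known limitations

* Image-space simulation (no OSEM noise correlation, no septal penetration,
  no scatter/attenuation residuals); see the caveats above.
* The intercept uncertainty treats residuals as independent; nested VOIs make
  them correlated under pure counting noise. The coverage simulation bounds
  the practical impact under the study conditions.
* Nonlinear backgrounds (hot neighbours, reconstruction artefacts) violate the
  linear model; they inflate $u(C_{v=0})$ but a nonlinear extension (more
  VOIs, curved fits) is not implemented.
* The dose-uncertainty chain is first-order throughout; with large relative
  uncertainties (small volumes, the RC method) the linearisation degrades and
  the reported intervals become optimistic.
* `quantify_local_voi` intentionally reports no uncertainty, mirroring the
  method's lack of an internal error model.
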