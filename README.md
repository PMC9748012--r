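# voiquant

Activity quantification for *small* sources on reconstructed emission-tomography
(SPECT) images, with closed-form uncertainty estimation, and the downstream
lesion-dosimetry chain for molecular radiotherapy.

## The problem

Quantifying the activity of a source smaller than about three times the
scanner's spatial resolution is notoriously unreliable: partial-volume effects
spill counts out of any anatomically sized VOI, recovery-coefficient
corrections become extremely steep (so a small error in the delineated volume
produces a huge error in activity), and SPECT/CT mis-registration compounds
both. `voiquant` implements a quantification approach built for exactly this
regime, aimed at physicists doing lesion dosimetry for radionuclide therapies
(e.g. bone or lung metastases and thyroid remnants in I-131 treatments).

## The method

Delineate an **oversized** spherical VOI that encloses *all* counts from the
source, plus at least two further concentric VOIs of increasing volume. Counts
from the source are the same in every VOI; counts from surrounding activity
grow linearly with VOI volume. Ordinary least squares of VOI count rate
C&#7522; on VOI volume v&#7522; then separates the two:

- **intercept** C₍ᵥ₌₀₎ — count rate originating solely from the source,
- **gradient** a — the average background concentration (cps/ml),
- **u(C₍ᵥ₌₀₎)** — closed-form intercept uncertainty from the residual scatter
  with n − 2 degrees of freedom.

Activity follows as A = C/(QR) with the system sensitivity Q (cps/MBq) from a
reference-capsule calibration and R = 1 (no recovery correction is needed —
the VOI is oversized by construction). Relative uncertainties combine in
quadrature per the law of propagation of uncertainty:
\[u(A)/A\]² = \[u(Q)/Q\]² + \[u(C)/C\]².

The package also provides the two standard comparators (an oversized VOI with
local-background subtraction, and the recovery-coefficient method with a
two-parameter logistic recovery curve R(v) = 1 − 1/(1 + (v/b₁)^b₂)), a seeded
digital-phantom simulator (voxelized geometry → Gaussian PSF blur → Poisson
counts → binomial thinning for non-uniform backgrounds), and the dosimetry
chain: mono-exponential time–activity fit, time-integrated activity
TIA = A₀/λ, and absorbed dose D = TIA × S with propagated uncertainties.

## Worked example

Simulate the capsule-in-uniform-background phantom (33.3 MBq point-like
source centred in a 20-cm water cylinder at 46 kBq/ml, sensitivity
28.9 ± 0.4 cps/MBq) and quantify it:

```r
library(voiquant)
cal <- calibration(28.9, 0.4)                      # cps/MBq
sim <- simulate_preset("cylinder-uniform", seed = 7)
est <- quantify_concentric(sim$image, center = c(115.2, 115.2, 115.2), cal)
est
#> activity estimate (concentric method)
#>   A = 33.038 +/- 0.484 MBq (1.47%)
#>   background concentration: 1.3528 cps/ml
summary(est$fit)
#>      volume_ml count_rate_cps   fitted residual
#> [1,]   47.7757       1014.848 1019.446  -4.5973
#> [2,]  117.6699       1118.652 1114.002   4.6503
#> [3,]  222.0687       1257.167 1255.237   1.9299
#> [4,]  381.3212       1468.697 1470.680  -1.9829
#>
#> Source count rate (intercept): 954.813 +/- 4.59 cps
#> Background concentration (gradient): 1.35284 cps/ml
```

The estimate (33.04 ± 0.48 MBq) covers the simulated truth of 33.3 MBq; the
fitted gradient matches the rendered background concentration
(0.046 MBq/ml × 28.9 cps/MBq ≈ 1.33 cps/ml).

The clinical dosimetry chain, on the packaged serial measurements of a bone
metastasis (three SPECT time points):

```r
tac <- read_tac_csv(system.file("extdata", "tac_bone_metastasis.csv",
                                package = "voiquant"))
fit <- fit_monoexponential(data = tac[tac$method == "proposed", ])
fit
#> Mono-exponential time-activity fit
#>   A0 = 12.866 MBq, lambda = 0.011252 /h (T1/2,eff = 61.6 h)
#>   TIA = 1143.4 +/- 14 MBq.h
absorbed_dose(fit, sphere_dose_factor(2.6), mass = 2.6)
#> absorbed dose: D = 48.7 +/- 0.59 Gy  (TIA 1143.4 MBq.h, S 0.04259 Gy/MBq.h)
```

TIA is the area under A(t) extrapolated over all time (total decays, MBq·h);
the dose factor here is the built-in electron-local-deposition surrogate for a
2.6 g sphere — supply a tabulated S-value table via
`dose_factor_from_table()` for production work.

A command-line interface with `simulate`, `calibrate`, `quantify`,
`recovery-fit`, `tac-fit` and `dose` subcommands is installed at
`system.file("cli", "voiquant.R", package = "voiquant")`.

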