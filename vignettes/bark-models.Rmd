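---
title: "Modeling stem bark on young broadleaved trees: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling stem bark on young broadleaved trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stembark)
```

This vignette documents the models behind **stembark**, the assumptions and
unit conventions they carry, what the synthetic-data generator does and does
not emulate, and the design decisions taken where more than one defensible
choice existed.

## The modeling chain

Everything is driven by the stem-base diameter $D_0$ (mm), the one
predictor that exists for every small tree (breast-height diameter does not,
for trees under 1.3 m). Four regressions per species form the base layer:

* **Height** $H = D_0^2/(b_0 + b_1 D_0 + b_2 D_0^2)$ (m). With $b_2 > 0$
  the curve saturates at $1/b_2$; for the packaged species the asymptotes
  range from about 7 m (goat willow) to 48 m (aspen), far above any tree in
  the size range, so the curve behaves almost linearly where it is used.
* **Breast-height diameter** $DBH = b_0 + b_1 D_0$ (mm). The fitted lines
  cross zero at $D_0$ of 5–8 mm; predictions below that are negative and
  are deliberately not clamped by `predict_dbh()` — the caller decides.
* **Bark thickness** $T_b = b_0 D_0^{b_1} H_g^{b_2}$ (mm) and **stem
  radius** $r = b_0 D_0^{b_1} H_g^{b_2}$ (cm), both with the height above
  ground $H_g$ in cm, both fitted on the bottom 2.5 m of the stem.

The derived layer composes the taper model with truncated-cone (frustum)
geometry per vertical section $(h_1, h_2)$: lateral surface
$S_b = \pi (r_1 + r_2)\sqrt{(r_1 - r_2)^2 + l_s^2}$, bark volume
$V_b = V(r_{out}) - V(r_{in})$ with
$V = \tfrac{1}{3}\pi l_s (r_1^2 + r_1 r_2 + r_2^2)$, bark mass
$W_b = V_b \rho_b$, and specific surface mass $SPH = W_b / S_b$
(g dm$^{-2}$). All geometry is computed in centimetres internally;
`convert_units()` does the boundary conversions, and the mm-scaled
thickness is divided by 10 exactly once, where the under-bark radius is
formed.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `bark_density` | kg m$^{-3}$ | none — required | densities are site- and species-specific and were not part of the model fits; shipping a default would silently fabricate data. Plausible range enforced: (50, 1500). |
| `thickness_convention` | — | `"radial"` | see below. |
| `hg` floor for thickness | cm | 1 | the power law diverges at $H_g = 0$ and was fitted from measurements whose lowest positions sit above ground; 1 cm is below any caliper positioning accuracy. |
| ground-line radius | cm | $D_0/20$ | the base radius *is* a direct measurement ($D_0$ halved, mm→cm); the fitted taper curve approaches this value a few cm above ground. Used only at section bound $h = 0$. |
| extrapolation | — | warning | $D_0 > 100$ mm or $H_g > 250$ cm are outside the fitted ranges; predictions are returned with a warning rather than refused, since simulated whole stems legitimately extend past 2.5 m. |

## The factor-of-two thickness question

Field protocols of this kind measure bark thickness as the difference
between over-bark and under-bark *diameters* — which is twice the radial
bark depth. The reported magnitudes of specific surface mass (tens of
g dm$^{-2}$ with plausible densities of 400–600 kg m$^{-3}$), however, are
consistent with the modeled $T_b$ being the *radial* depth: in the
thin-bark limit $SPH \to \rho_b \cdot T_b$, and treating $T_b$ as a
diameter difference would require bark densities near 1000 kg m$^{-3}$ to
reach the same masses. **stembark** therefore treats the modeled thickness
as radial by default and exposes the alternative reading everywhere it
matters (`section_bark_volume()`, `bark_profile()`,
`to_observation_tables()`) via `thickness_convention = "diameter"`, which
halves the depth before it is subtracted from the over-bark radius. The
two conventions propagate multiplicatively to $V_b$, $W_b$ and $SPH$; no
in-package evidence can settle the question, so it stays a documented
switch.

## Fitting

`fit_dbh_linear()` is ordinary least squares. The two nonlinear forms are
fitted by Levenberg–Marquardt (via **minpack.lm**) *on the original
response scale*, because the reported residual variances (MSE) of the
power models are in squared response units; a log–log regression would
minimise a different criterion and its backtransformed scale parameter
would be biased low under additive noise. The log–log OLS fit serves only
as the initialiser (for the height model, the exact linearisation
$D_0^2/H$ quadratic in $D_0$ plays that role). Convergence control is
`ftol = ptol = 1e-12` with at most 200 iterations; non-convergence is an
error carrying the optimiser's message, never a silent result. One
numerical subtlety: on exactly interpolating (zero-residual) data the
optimiser can stop so close to a degenerate optimum that the finished
model's gradient fails its rank check; the fitter then refits from a
nudged start at the optimiser's default stopping tolerance, which returns
the same optimum at a numerically regular point.

Standard errors are asymptotic (Jacobian-based), p-values are two-sided
Wald $t$ on $n - k$ residual degrees of freedom, $R^2 = 1 - SSE/SST$ is
reported as computed (it may be negative for a fit worse than the mean,
and is undefined — `NA` — for a constant response), and
$MSE = SSE/(n - k)$. The $n - k$ denominator is a declared convention:
wherever a printed MSE is used as a noise variance, it is interpreted the
same way. No weighting is applied; the fitted criteria assume homoscedastic
additive errors.

## The synthetic population generator

`simulate_bark_population()` emulates the destructive-sampling design the
models come from, so that fitting and derivation stages can be exercised
end to end:

* per-species sample sizes (180 / 120 / 100 / 200 trees, 600 total) and
  stem-base diameter distributions (normal, truncated below at 5 mm, with
  the reported means and SDs) reproduce the study population;
* heights, DBH, radii and thicknesses are generated from the packaged
  curves plus additive Gaussian noise, with SD defaulting to
  $\sqrt{MSE}$ of the corresponding fit. The height model is the
  exception: its printed MSE is not on the metre scale of its response
  (the value is three orders of magnitude too large for heights of a few
  metres), so the height noise SD defaults to the unexplained share of
  the reported population height SD, $\sigma_H\sqrt{1 - R^2}$ — about
  0.8 m for aspen. This was decided once, from the reported statistics,
  and is not a tuning knob;
* whole stems are cut into $\max(4, \lceil \text{length}/1\,\text{m}
  \rceil)$ equal sections and calipered over and under bark at the lower
  end, middle and upper end of each section. A stem taller than 2.5 m is
  still cut whole (a 6 m tree yields 6 one-metre sections), but
  `to_observation_tables()` restricts the radius and thickness tables to
  $H_g \le 250$ cm, mirroring how the models are fitted only on the
  bottom 2.5 m;
* measurement positions at the ground line are recorded at
  $H_g = 1$ cm, where both power models are defined — this keeps
  noiseless populations exactly on the generating curves, so the
  refit-closure tests can demand $10^{-6}$ relative recovery;
* noise draws are kept physical with floors that never bind at zero
  noise: heights at $\min(0.3\,\text{m}, H_{true})$, DBH at 1 mm,
  over-bark diameters at 0.2 mm, and the over/under diameter gap at
  0.2 mm. The floors truncate the lower noise tail for the smallest
  trees; at the study's sample sizes the resulting coefficient bias is
  an order of magnitude below one printed standard error, and it is the
  price of never emitting a negative caliper reading.

The generator does **not** emulate: spatial stand structure or
competition, bio-sociological position, tree age (the study population
spans 2–12 years but the models carry no age term), measurement rounding,
between-stand variance components, or correlated errors along a stem.
Passing tests therefore demonstrate that the *fitting machinery* recovers
known truth under the stated noise model — not that the noise model
captures every feature of real caliper data.

## Numerical choices and degenerate inputs

* Frustum fields are validated by name; zero radii are allowed (cone
  limit), zero-length sections are not (they carry no information and
  break the $SPH$ division).
* The frustum formulas agree with quadrature over the linear-profile
  solid of revolution to $10^{-9}$ relative error (property-tested on
  1000 random frusta); they are symmetric in the radii by construction.
  Monotonicity in each radius holds for section-like shapes (length
  comfortably exceeding the radii); for pancake-shaped frusta the lateral
  surface can decrease as the narrower radius grows, which is why the
  property tests sweep $l_s \ge 10$ cm.
* A single frustum per 50 cm section linearises the convex taper curve.
  The discretisation error, measured against quadrature over the power
  profile, is largest for the strongest taper (goat willow, $b_2 =
  -0.179$) on the lowest modeled section, where it approaches 1% of the
  lateral surface; above 1 m it is well under 0.5% for all species, and
  halving a section provably moves the result toward the quadrature
  value. Tests assert those measured bounds.
* Partial top sections (trees shorter than the 250 cm profile) are
  emitted with their true length and flagged `partial`, never silently
  dropped — totals over a stem must not lose bark.
* Coefficient transcription keeps the printed three-decimal precision
  exactly; the JSON interchange schema (also used by
  `write_model_library()` for refitted coefficients) is validated on
  load, including the sign constraints that make the models physically
  meaningful.
* CSV round trips are faithful to the printed double precision
  (relative $10^{-12}$); byte-identical reproduction is guaranteed for
  repeated runs with the same seed, not across write–read cycles.

## Problem sizes used in the test suite

The suite fits noiselessly at $n$ of a few dozen trees per species (exact
closure does not need more), runs the seeded recovery study at the
study-scale sample sizes ($n = 600$ observations for the power models,
180 trees for the DBH line, 12 replicates with the median compared against
three printed standard errors), checks estimator unbiasedness over 200
Monte-Carlo replicates, and verifies the ≥ 95% three-standard-error
recovery rate over 60 seeded replicates of the full population generator.
A single $n = 600$ recovery replicate has estimator spread comparable to
the three-standard-error band itself (the printed standard errors come
from a several-fold larger measurement set), which is why the recovery
checks are made on a replicate set rather than a single draw.

## Known limitations

* The models stop at 2.5 m of stem and 100 mm of $D_0$; the package warns
  rather than refuses beyond that, and makes no claim about mature trees.
* Bark density enters as a single constant per species along the whole
  profile; any vertical density gradient folds into the error of $W_b$
  and $SPH$.
* The thickness-convention ambiguity above is a genuine one-bit
  uncertainty that rescales $V_b$, $W_b$ and $SPH$ by up to a factor of
  two; results that depend on absolute bark mass should state the
  convention used.
* Branch bark and whole-tree totals are out of scope; the quantities are
  strictly per stem section within the modeled profile.
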