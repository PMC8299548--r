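---
title: "Assessing physical consistency between paired vegetation ECV products"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing physical consistency between paired vegetation ECV products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecvagree)
```

## The problem

Leaf Area Index (LAI) and the Fraction of Absorbed Photosynthetically
Active Radiation (FAPAR) are physically linked terrestrial Essential
Climate Variables: LAI sets the optical depth of the canopy in which
radiation is absorbed, so when LAI changes, FAPAR must change in the same
direction (the senescence period, where leaf optical properties change at
roughly constant leaf area, is the known exception). Satellite products
deliver both variables with per-observation uncertainty estimates, and a
pair of products that is physically consistent should show coherent
simultaneous temporal changes once those uncertainties are taken into
account. `ecvagree` implements a framework for quantifying that coherence:
it classifies every consecutive change of each variable using its
uncertainty, cross-tabulates the simultaneous classifications, and reduces
the table to interpretable agreement and bias metrics, along the temporal,
spatial, threshold and resolution axes.

## Change confidence from uncertainty intervals

Each observation spans an interval `value ± uncertainty` (one-sigma
half-width, same units as the value). For two consecutive observations the
confidence of the change is the fraction of the combined range not shared
by the two intervals:

$$C_f = 100\,(1 - O_l / f_l)$$

with the overlap $O_l$ and full range $f_l$ evaluated branch-wise on the
sign of the change: for an increase, $O_l = (v_t + u_t) - (v_{t+1} -
u_{t+1})$ and $f_l = (v_{t+1} + u_{t+1}) - (v_t - u_t)$, and mirrored for
a decrease. Disjoint intervals (negative raw overlap, clamped to zero)
give $C_f = 100$; a zero change, or the degenerate case of identical
values with zero uncertainties, is defined as $C_f = 0$.

Two numerical subtleties deserve a note. First, the branch equations
reduce to the closed form $C_f = 200|\Delta| / (|\Delta| + u_t +
u_{t+1})$ (clamped at 100), which makes three properties immediate: $C_f$
is symmetric under reversing the step, invariant under rescaling all
values and uncertainties by a positive constant, and monotonically
non-increasing in either uncertainty at a fixed change. Second, when one
interval nests strictly inside the other the branch equations differ from
a naive geometric intersection-over-union of the two intervals; the
geometric reading would *increase* confidence as the wider interval grows,
which violates the monotonicity that makes $C_f$ usable as a confidence,
so the branch form is authoritative. Outside the nested corner the two
definitions coincide, which is what the grid-sampling oracle in the test
suite verifies on random pairs.

A change is classified an **increase** when $\Delta > 0$ and $C_f$
strictly exceeds the confidence threshold, a **decrease** when $\Delta <
0$ and $C_f$ exceeds it, and **non-significant (NC)** otherwise. The
default threshold is 50% — the conventional decision point, and the value
used throughout unless a sweep says otherwise. Strict comparison was
chosen because the classification is described as requiring confidence
*above* the threshold; at $C_f$ exactly equal to the threshold the change
stays non-significant. Missing or quality-flagged observations are
handled by pairwise deletion — a step contributes only if both variables
are valid at both ends — and never gap-filled, mirroring how low-quality
pixels are excluded rather than imputed in product intercomparisons.

## The contingency table and its metrics

Simultaneous class pairs populate a 3×3 table `n[i, j]` with rows for the
LAI class and columns for the FAPAR class (1 = decrease, 2 =
non-significant, 3 = increase). The diagonal holds the physically coherent
cases. Five metrics summarise it:

* **Overall agreement** $OA = (n_{11} + n_{22} + n_{33})/N$;
* **Increase / decrease sensitivity** — Dice coefficients
  $S_i = 2n_{33} / (2n_{33} + n_{32} + n_{31} + n_{23} + n_{13})$ and
  $S_d = 2n_{11} / (2n_{11} + n_{12} + n_{13} + n_{21} + n_{31})$,
  the conditional probabilities that a significant change seen by one
  product is coherently seen by the other during green-up and senescence;
* **Non-coherent bias** $B_{nc} = (n_{13} - n_{31})/N$, the imbalance
  between the two opposite-sign significant contradictions;
* **Non-significant bias** $B_{ns} = ((n_{21} + n_{23}) - (n_{12} +
  n_{32}))/N$, positive when non-significance falls more often on the LAI
  side.

All metrics are kept as fractions internally (percentages are a rendering
concern). Undefined values — an empty table, or a Dice denominator of
zero, which happens wherever no significant change of the relevant sign
was ever observed — propagate as `NA`, never as zero: a sensitivity of 0
(observed contradictions) and an unobservable sensitivity are different
findings. Swapping the two variables transposes the table, leaves $OA$,
$S_i$ and $S_d$ unchanged, and negates both biases; this antisymmetry is a
standing property test.

## Consistency axes

`temporal_agreement()` tabulates each consecutive time step over all the
pixels of a region (e.g. a land-cover class), yielding a metrics time
series plus the processed-pixel fraction; `spatial_agreement()` tabulates
each pixel over the full record, yielding metric maps. Summing the
per-step tables reproduces the pooled tabulation exactly — a conservation
property the tests enforce.

Short-term consistency is summarised by `monthly_climatology()`: the
multi-year mean and standard deviation of each metric by calendar month,
with composites keyed to months by their start date (stable across 8-, 10-
and 16-day cadences). Long-term consistency uses
`seasonal_mann_kendall()`: the Kendall score computed within each of 12
monthly seasons and summed, with within-season tie correction and a
continuity-corrected normal approximation. No inter-season covariance
correction is applied, and the significance level is 0.05 throughout with
no multiple-testing correction across pixels or strata — per-stratum tests
are reported as such. Product pairs are compared over a stratum with the
Welch unequal-variance t test and the two-sample Kolmogorov–Smirnov test
(`compare_products()`), pairwise. `zonal_mean()` provides area-unweighted
latitude-band averages over half-open bands `[lat, lat + width)`.

## Threshold sensitivity

The confidence threshold is the framework's one free parameter, so its
influence is mapped explicitly. `sweep_joint()` re-derives all metrics on
a grid of thresholds applied to both variables; because $C_f$ itself does
not depend on the threshold, confidences are computed once
(`paired_changes()`) and only reclassified per threshold. Two
monotonicities follow from thresholding and are tested: the matching
non-significant count $n_{22}$ never decreases, and the non-coherent count
$n_{13} + n_{31}$ never increases, with threshold.

`sweep_independent()` evaluates $B_{ns}$ on an independent
LAI-threshold × FAPAR-threshold grid (default 0–100% in 1% steps, endpoints
included), which exposes how the two products' uncertainty magnitudes
relate; `zero_bias_locus()` extracts the threshold combinations where
$|B_{ns}|$ drops below one half count — the tolerance is $1/(2N)$, below
the resolution of a count ratio — or changes sign, and reports the
diagonal (joint-threshold) crossing. Identical products give an exactly
antisymmetric surface with a zero diagonal; a surface that never changes
sign yields an empty locus with a diagnostic rather than a fabricated
crossing.

## Spatial aggregation

`aggregate_stack()` resamples a stack by an integer block factor using
inverse-variance weights $w_i = 1/\delta_i^2$:

$$R_s = \frac{\sum w_i \alpha_i}{\sum w_i}, \qquad
  \sigma_s = \frac{1}{\sqrt{\sum w_i}}.$$

The propagated uncertainty $\sigma_s$ is the standard inverse-variance
form consistent with the weights (the equal-uncertainty special case
$\sigma_s = \delta/\sqrt{n}$ is a test fixture). Membership is by pixel
center in half-open cells anchored at the grid origin, so exact nesting
never double-counts. Cells below a minimum valid-pixel fraction (default
0.5 — a majority of the cell should carry information; configurable) are
invalidated rather than extrapolated. Zero uncertainties would produce
infinite weights and are floored at `eps` (default 1e-6 in native units)
with a counted warning. Land-cover grids are resampled by majority filter
with ties broken deterministically toward the smallest class code.
`multiscale_agreement()` chains aggregation of both variables — each with
its own uncertainties — and the full tabulation per resolution and
land-cover stratum.

## What the synthetic generator emulates

Because the framework's statistical behaviour must be testable without
multi-decadal satellite archives, `generate_scenario()` builds paired
products with known truth. Per land-cover class (cropland, forest, shrub,
grassland by default, laid out as vertical bands), the true LAI follows a
clipped, sharpened seasonal sinusoid
`baseline + amplitude * max(0, sin(2π(doy − phase)/365))^sharpness`, and
the true FAPAR follows the exponential light-absorption link
`FAPAR = 1 − exp(−k·LAI)` with `k = 0.5` — the canonical Beer–Lambert
form for a physically consistent pair. Observations add Gaussian noise
with standard deviation tied to the stated uncertainty, truncated at the
physical bounds (LAI ≥ 0, FAPAR ∈ [0, 1]) with the clipping rate recorded
in the truth record.

Three uncertainty archetypes reproduce the qualitative structure of real
product families:

* `propagated_link` — a prior-dominated LAI budget (`0.5·LAI + 0.8`) with
  an observation-constrained FAPAR posterior (`0.05·F + 0.02`), i.e. a
  large relative LAI uncertainty against a small relative FAPAR one. Note
  that *exact* linear propagation of the LAI uncertainty through the link
  derivative would preserve the signal-to-uncertainty ratio of both
  variables identically and could never produce the non-significant-bias
  asymmetry such products show; the asymmetry comes from the prior, which
  is why the archetype is parameterised this way.
* `retrieval_spread` — small relative uncertainties with FAPAR's
  relatively larger (`0.05·LAI + 0.02` vs `0.10·F + 0.02`), as in
  LUT-ensemble retrievals.
* `decoupled` — independent uncertainty models per variable, as in
  separately trained retrieval chains.

Two deliberate decouplings of *stated* from *actual* uncertainty are
available because the confidence level is scale-invariant for
noise-dominated changes — inflating an uncertainty together with the noise
it describes cancels out of $C_f$ exactly, so pathologies that only exist
as calibration defects must be modelled as such:

* `uncertainty_calibration` (default 1) sets the realized error standard
  deviation as a fraction of the stated uncertainty; values below 1
  emulate conservative, prior-driven budgets.
* `unc_trend_slope` drifts the *stated* uncertainty linearly in time
  (after `break_time`) while the realized error stays put — the
  uncertainty-magnitude drift seen across sensor transitions — whereas
  `break_noise_factor` scales noise and stated uncertainty together, a
  genuine sensor change.

Non-coherence is injected by flipping the sign of the FAPAR increment at a
pixel-step with probability `p_noncoherent`; operating on increments
rather than levels keeps the marginal distributions realistic. Flips of a
zero increment (dormant season) are unobservable by construction, so
recovery experiments use an in-season window where every true increment is
nonzero. Quality dropout removes pixel-composites at random.

The generator does **not** emulate radiative-transfer detail, snow and
background-albedo effects, spatially correlated retrieval errors, or
real phenological interannual variability. Passing tests therefore
demonstrate that the framework recovers known statistical structure —
agreement under a perfect link, injected non-coherence rates, calibration
drifts, noise averaging under aggregation — not that any particular real
product pair is consistent.

## Study conditions used in the tests

The test suite exercises desk-scale problem sizes chosen to make the
statistics sharp: the confidence oracle runs on 10,000 random observation
pairs; non-coherence recovery uses a 25×25 grid over one in-season window
(10,000 pixel-steps) with `p = 0.1`, checked against the 95% binomial
interval; the calibration-drift detection experiment uses an 8×8 grid
over six dekadal years with the stated FAPAR uncertainty doubling across
the record (the kind of magnitude drift sensor transitions produce),
with detection power required above 0.9 across 100 replicates at α =
0.05; and the end-to-end pipeline run covers a 32×32 grid over three
years at three resolutions. The zero-noise linked scenario must give
`OA = 1` *exactly*: with no noise, every step is either coherently
significant or (in the dormant season) coherently non-significant, both
of which are diagonal.

## Known limitations

* The senescence exception — FAPAR decreasing at constant LAI — is not
  special-cased; such events are counted by the bias metrics by design,
  and a real senescing landscape will depress agreement accordingly.
* Latitude-band and regional means are area-unweighted; no geodesic
  weighting or reprojection is performed, and aggregation requires exact
  grid nesting.
* The seasonal Mann–Kendall variance omits the inter-season covariance
  term, which is anti-conservative for strongly autocorrelated series.
* Stacks are held in memory as dense arrays; the package targets
  regional/desk-scale analyses, not global 1-km archives.
* The text stack format is self-describing but uncompressed; it is meant
  for reproducible exchange of desk-scale cubes, not as an archive
  format.
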