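---
title: "Models and methods behind leafhydraulics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind leafhydraulics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafhydraulics)
```

`leafhydraulics` derives the critical water-potential thresholds of a
dehydrating leaf — turgor loss, stomatal closure, hydraulic decline, xylem
embolism — from four kinds of tabular or image measurements. This vignette
documents the models, the tunable parameters, the numerical choices, and
what the synthetic-data generators do and do not emulate.

## Pressure–volume elaboration

A pressure–volume curve records leaf water potential $\Psi$ and fresh mass
during slow bench dehydration. The analysis rests on the standard
osmometer picture of the leaf: once turgor is lost, $\Psi$ equals the
osmotic potential of a symplast that concentrates as it shrinks, so
$-1/\Psi$ is linear in the relative water deficit $d = 1 - RWC$. From that
line,

* $\pi_0 = -1/\text{intercept}$ (osmotic potential at full turgor);
* the deficit $d_0 = -\text{intercept}/\text{slope}$ at which the line
  reaches zero is where symplastic water would be exhausted, so the
  apoplastic water fraction is $AWF = 1 - d_0$;
* the turgor loss point is the least-dehydrated point inside the linear
  region (an option for the line/curve intersection convention was
  considered and rejected as less robust on sparse curves);
* turgor at the hydrated points is $P = \Psi - \pi$ with $\pi$
  extrapolated from the osmotic line (solute conservation), giving the
  elastic modulus $\varepsilon$ as the least-squares slope of $P$ against
  $RWC$. On the symplastic water basis
  $\varepsilon_{sym} = \varepsilon_{tot}(1 - AWF)$ exactly (chain rule) —
  the implementation computes it that way, so the identity is not a test
  of arithmetic but of the shared $AWF$.

**Finding the linear region.** The field's stopping rule — "linear
($R^2 > 0.95$) for at least four consecutive points" — under-determines an
algorithm. Taking the *longest* dry-end-anchored run with $R^2 > 0.95$
over-extends into the turgid region whenever the truly linear points are
many: a long exactly-linear run absorbs several curved points before
$R^2$ drops below so permissive a threshold, which visibly biases the
turgor loss point upward. We therefore shrink from the hydrated end:
starting from all points, the most-hydrated point of the candidate run is
dropped while the run is still non-linear ($R^2 \le 0.95$) or while
dropping it improves $R^2$; the final run must keep $\ge 4$ points with
$R^2 > 0.95$, else the curve is rejected. On noise-free osmometer curves
this recovers the post-turgor-loss set exactly; under 1% mass noise the
recovered $\pi_0$ is biased by well under 5% (checked over 200 seeded
replicates in the test suite).

**Capacitances.** $C_{leaf}$ is the least-squares slope of leaf water
(converted to mol with the molar mass of water, 18.015 g mol⁻¹, and
normalized by leaf area) against $\Psi$, computed separately before and
after the turgor loss point. An endpoint-difference option exists for
two-point branches; the slope is the default for robustness.

## Rehydration kinetics

A detached leaf rehydrating through its petiole relaxes exponentially, so
one trial gives

$$K_{leaf} = C_{leaf}\,\ln(\Psi_i/\Psi_f)\,/\,t,$$

with $C_{leaf,FT}$ used when $\Psi_i$ is above the turgor loss point and
$C_{leaf,TLP}$ otherwise; the boundary is assigned to the TLP branch
(documented tie rule). Capacitance is in mol m⁻² MPa⁻¹ and $K$ is reported
in mmol s⁻¹ m⁻² MPa⁻¹ (factor 1000 at output). Trials whose two
equilibration-check leaves differ by more than 0.1 MPa (boundary
inclusive) are discarded before analysis, mirroring bench practice.
Maximum conductance is the mean over trials with $\Psi_i > -0.7$ MPa, and
the conductance–$\Psi$ decline is fitted with the sigmoid below.

## Curve models and fitting

Three response models cover the pipeline, all fitted by bounded
Levenberg–Marquardt least squares (`minpack.lm::nlsLM`), unweighted, on
the scale the data arrive in (percent for embolism, raw conductance
otherwise):

* **Weibull** (percent embolism vs tension $x = -\Psi$):
  $F(x) = 100\,[1 - \exp(-(x/b)^c)]$. The optimizer works in
  $(P_{50}, S_{50})$ — the tension at 50% embolism and the slope there in
  % MPa⁻¹ — because percentile bootstrap intervals on $P_{50}$ are the
  quantity of interest and this parameterization keeps them well behaved.
  The mapping is $P_{50} = b(\ln 2)^{1/c}$,
  $S_{50} = 50\ln(2)\,c/P_{50}$, round-trip tested to 1e-10. Sign
  convention: users pass water potentials (MPa, negative); negation
  happens once at the module boundary.
* **Sigmoid** (conductance decline):
  $K(\Psi) = K_{max}/(1 + e^{a(\Psi_{50} - \Psi)})$ with free amplitude.
* **Log-logistic** (stomatal conductance):
  $g(\Psi) = lower + (upper - lower)/(1 + ((-\Psi)/e_{50})^{b})$, with the
  lower asymptote constrained $\ge 0$.

Starting values are deterministic and data-driven: midpoints from the
observation nearest half-response, slopes from local finite differences,
asymptotes from data extremes; non-convergence triggers a fixed ladder of
five slope-scaled restarts and is then *flagged*, never silent. $R^2$ is
$1 - SS_{res}/SS_{tot}$ on the fitted scale; constant-response data leave
it undefined and the fit flagged.

**Bootstrap.** Percentile method: rows resampled with replacement at the
original size, 2.5/97.5 percentiles over `n_boot` successful replicate
fits (1000 for vulnerability curves, 999 for the stomatal threshold).
Failed replicate fits are redrawn from the same RNG stream and counted;
more than 50% failures abort. One seed governs each call and is carried in
the result; the caller's RNG state is never disturbed. BCa intervals were
deliberately not implemented — the percentile method is the simplest
consistent choice and the one the downstream overlap test assumes. Two
estimates are reported "significantly different" when their 95% intervals
are disjoint.

## Optical vulnerability

Embolism events appear as abrupt local brightness changes between
consecutive frames of a transmitted-light stack. The detector takes
absolute differences of consecutive frames, binarizes at `diff_threshold`
(default: 3× the robust noise SD, estimated as the MAD of the signed
differences over the first five frame pairs — on noise-free stacks this
degenerates to zero and any change is an event), and removes connected
components smaller than `min_component_px` (default 4 px) under
8-connectivity. Surviving pixels are new events; their cumulative sum,
normalized by the experiment's final cumulative area, is the percent
embolism. Interactive cleanup steps of camera-based workflows are replaced
by this deterministic filter so that results are bit-reproducible. The
detector is invariant to constant intensity offsets by construction.

Water potential is assigned to frames by piecewise-linear interpolation of
the single concurrent $\Psi$ series of that experiment; extrapolation
beyond the series is refused and the affected frames dropped with a
warning. Per-method curves (pressure chamber, dewpoint hygrometer,
psychrometer) are fitted separately and pooled by unioning observations;
pairwise method differences use the CI-overlap rule.

**Vein densities.** Binary masks are thinned to 1-px centerlines
(Zhang–Suen, implemented in-package since no installed R package provides
2D thinning); length is the skeleton pixel count with diagonal adjacency
weighted $\sqrt 2$ ($L = N + (\sqrt2 - 1)D$ pixels), divided by leaf
area. This reproduces straight horizontal segments exactly and digital
diagonals to within 1%. Connected-component labeling is likewise
implemented in-package because the available image library labels under
4-connectivity only.

## Stomatal closure threshold

The water potential of 95% closure, $\Psi_{g95}$, is estimated by
resampling: 999 times, resample the drought-group points with replacement,
fit the log-logistic, evaluate the fitted curve on a $\Psi$ grid of step
$\le 0.005$ MPa spanning the resample's observed range (no extrapolation),
and linearly interpolate the $\Psi$ at which the curve crosses 5% of the
control reference. The reported estimate is the *mean* over replicates,
with percentile CIs. The reference is the mean of control-plant
conductances by default (a `max` option exists); interpolation acts on the
fitted curve, not the raw points — the raw-point alternative is noisier
and was rejected. Replicates whose fitted curve never reaches the
threshold inside the data range are redrawn and counted. The stomatal
safety margin is then $SSM = \Psi_{g95} - \Psi_{50xe}$, positive when
embolism lies safely beyond closure.

## Synthetic data and what passing tests mean

Each generator writes a truth record (generator name, parameters,
closed-form targets, seed) alongside its data, and all are deterministic
under a fixed seed.

* **Pressure–volume**: a linear-elastic osmometer — constant symplastic
  modulus, solute conservation, apoplastic fraction mixed in at constant
  proportion; fresh mass $= DW(1 + SWC \cdot RWC)$. Closed forms:
  $R_{tlp} = 1 + \pi_0/\varepsilon_{sym}$,
  $\Psi_{tlp} = \pi_0/R_{tlp}$. Defaults ($\pi_0 = -1.5$ MPa,
  $\varepsilon_{sym} = 9$ MPa, $AWF = 0.386$, $SWC = 2.4$, leaf area
  69.7 mm², dry mass 3.69 mg) describe a leaf whose derived traits sit at
  the values the package is validated around ($\Psi_{tlp} = -1.8$ MPa,
  $RWC_{tlp} = 89.7\%$, SLA 18.9 mm² mg⁻¹, capacitances near 0.4 and
  1.5 mol m⁻² MPa⁻¹). Real leaves need not have a constant modulus; the
  generator exists to test the analyzer, not to model any species.
* **Rehydration**: exact inversion of the kinetics equation, per-trial
  conductance and capacitance, Gaussian noise on $\Psi_f$.
* **Optical stacks**: a template of labeled vein segments (default: 12
  parallel veins of 4-px segments on a 96×96 grid — at 0.02 mm px⁻¹ a
  vein density of ≈6.2 mm mm⁻²); each segment draws an embolism tension
  from a Weibull ($b = 4.768$, $c = 3$, i.e. 50% embolism at −4.22 MPa)
  and brightens by a fixed intensity in the first frame whose interpolated
  $\Psi$ passes it, over a constant background with optional Gaussian
  pixel noise. Segment sizes must not fall below the detector's component
  threshold. Sensor realism deliberately omitted: no spatially correlated
  noise, no illumination drift, no leaf movement — so passing tests
  validate the detection/normalization/fitting chain, not robustness to
  camera artifacts.
* **Gas exchange**: log-logistic decline (upper 400 mmol m⁻² s⁻¹, slope 6,
  $e_{50} = 1.108$ MPa → 95% closure at −1.81 MPa), multiplicative
  lognormal noise of unit mean (CV 0.05 by default, preserving
  non-negativity), controls near −1.0 MPa at the upper asymptote.

Problem sizes used in the shipped tests and acceptance script — 40–200
point PV curves, 38–40 point vulnerability curves, 60 drought + 10
control gas-exchange points, 40-frame 96×96 stacks, 999/1000 bootstrap
replicates — were chosen as representative of a real campaign while
keeping full runs fast on a laptop.

## Degenerate inputs and numerical conventions

* Water potentials are MPa and strictly negative everywhere; times in
  seconds; masses in g (mg accepted when declared).
* Consecutive duplicate PV points are dropped, so re-appending the last
  reading is a no-op; curves need ≥ 6 points.
* Constant-response fits, all-zero conductances, empty vein masks, blank
  stacks and zero-water-loss capacitance branches are all flagged or
  warned, never silently fitted.
* Quantiles use R's default type-7 definition; percentile CIs always
  satisfy `lo <= hi`.
* CSV artifacts round-trip exactly (shortest-representation floats); TIFF
  stacks are stored as 32-bit float and round-trip to single precision
  (~1e-7), which is far below any detection threshold in use.

## Known limitations

* The turgor-loss-point convention (last point entering the linear region)
  quantizes the estimate to the dehydration grid; closely sampled curves
  are needed for fine resolution.
* The optical detector assumes a fixed camera and leaf; it has no motion
  compensation.
* $\Psi$ assignment to frames trusts a single concurrent series; no
  cross-instrument fusion or lag correction is attempted.
* Percentile (not BCa) bootstrap; with strongly skewed resampling
  distributions its intervals can be slightly off-center.
* The pipeline aggregates pressure–volume traits across leaves by simple
  means; no mixed-effects structure is modeled.
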