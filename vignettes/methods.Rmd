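---
title: "Methods: from humidity traces to water-loss physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from humidity traces to water-loss physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geckoflux)
```

`geckoflux` is built around one idea: every physiological quantity in a
seasonal water-loss study of small ectotherms is a deterministic function
of a handful of raw measurements — air temperature, relative humidity,
flow rate, skin temperature, linear body measurements, repeated body
temperatures, and frame-classified refuge states. This vignette documents
those functions, the assumptions behind them, and the choices made where
the methods literature leaves latitude.

## Psychrometric substrate

All conversions start from the saturation vapour pressure of water over a
liquid surface. We use the Arden Buck (1996) closed form by default,

$$e_s(T) = 0.61121 \exp\!\left[\left(18.678 - \tfrac{T}{234.5}\right)
\tfrac{T}{257.14 + T}\right] \;\text{kPa},$$

selected after evaluating Buck (1981) and Goff–Gratch (1946) against
standard meteorological tables: the three agree to about 0.1% over the
biological range and any of them can be requested through the
`formulation` argument of every psychrometric function. The constants
live in a single internal table so a different formulation can be swapped
in without touching call sites.

Vapour mass densities come from the ideal gas law for water vapour,
$AH = e / (R_w T_K)$ with $R_w = 461.5$ J kg⁻¹ K⁻¹ and
$T_K = T + 273.15$. Real moist air departs from ideality by roughly 0.1%
under chamber conditions (the enhancement factor), which is far below the
resolution of field hygrometry probes, so no non-ideality correction is
applied. Two caveats delimit the valid domain: temperatures are restricted
to [−40, 60] °C, where the closed forms are accurate over liquid water,
and no altitude/total-pressure correction is made — chambers are assumed
to sit at standard pressure. Unit policy: kPa for pressures, g m⁻³ for
absolute humidity in reports, g cm⁻³ for the vapour densities inside the
flux equations; conversions are centralised, never inlined.

## Open-flow water loss

A trial trace records downstream relative humidity and air temperature
while dried air passes through the animal chamber at flow rate $V_e$.
The mass balance of an open-flow system gives

$$M_w = V_e\,(VD_a - VD_i),$$

with $V_e$ converted from L min⁻¹ to cm³ s⁻¹ at the formula boundary and
each probe reading converted to vapour density at its *own measured*
temperature (the nominal incubator set point is metadata only). No STPD
correction is applied: the balance uses the measured volumetric flow
directly. The inflow air is assumed fully dried by the silica column, but
$VD_i$ is still measured from the baseline segments rather than assumed
zero.

**Resting-window rule.** Movement inflates water loss, so the resting
read is the 2-min window of lowest mean humidity that lies entirely
inside a flat stretch of at least 5 min. "Flat" is made operational as a
rolling standard deviation of RH at most `flat_sd_max` (default 0.5 %RH
— about twice the noise floor of a capacitive probe, small enough that a
movement excursion of a few %RH disqualifies a window). Both window
lengths and the threshold are arguments. Ties in mean humidity are
resolved in favour of the earliest window, making the reduction
deterministic; the tests verify the detector against an exhaustive scan
over every candidate window.

**Baselines.** $VD_i$ is the mean of the pre- and post-trial baseline
means, which makes it invariant to swapping the two segments. If they
disagree by more than `baseline_drift_tol_g_cm3` (default 2 × 10⁻⁷
g cm⁻³, roughly a 0.5 %RH shift at 30 °C) the trial is drift-corrected by
interpolating linearly in time between the two baseline means, evaluated
at the midpoint of the resting window, and a warning is raised: the
baseline-reconfirmation protocol says what was measured but not how to
reconcile a drift, so the package picks the least-structured rule and
surfaces it. A chamber reading *below* baseline beyond the same tolerance
flags the trial invalid rather than silently reporting negative water
loss.

**Derived rates.** $E_c = M_w / SA$ and $R = (VD_s - VD_a)/E_c$, with
$VD_s$ the saturation vapour density at the measured skin temperature.
$R$ is a *total* resistance: no attempt is made to partition cutaneous,
ocular and respiratory avenues, and a supersaturated chamber
($VD_s < VD_a$) yields `NA` with a warning rather than a negative
resistance.

## Surface area and body condition

The whole animal is modelled as six single-ended cylinders — torso
(snout to vent, head included), tail, four legs — each parameterised by
its length and greatest width. "Single-ended" is interpreted as the
lateral surface plus **one** end disc, the other end abutting the body:
$\pi w L + \pi (w/2)^2$, with the calliper width treated as the diameter.
The geometry gives identical areas whichever end carries the cap, so the
choice is cosmetic; the cap can be dropped altogether with
`capped = FALSE` for sensitivity analyses. Missing tails or limbs
(regeneration, injury) contribute zero area with a warning; a missing
torso is an error. Body condition is the ratio mass (g) / SVL (mm),
reported raw and arcsine-square-root transformed; the transform requires
the ratio in [0, 1], which holds by two orders of magnitude in these
units, and the error message names the unit convention because that is
the only way the precondition can fail in practice. Gravid females are
excluded from condition tables by an explicit filter, never implicitly.

## Thermal preference

The set-point range is the central 50% of an animal's repeated gradient
temperatures. With the nominal 12 hourly readings this must retain
exactly six values, which forces a *rank-based* reduction (drop the three
lowest and three highest) rather than interpolated percentiles. In
general the package drops $\lfloor n/4 \rfloor$ from each end, retaining
$n - 2\lfloor n/4 \rfloor$: exactly half whenever $4 \mid n$, and at most
one extra reading otherwise (a symmetric trim cannot retain an odd count
from an even $n$, so for $n \equiv 2 \pmod 4$ the package keeps the extra
reading rather than discarding information asymmetrically). Ties keep
their input order through a stable sort. Fewer than four readings is an
error — extrapolating a set-point range from two or three temperatures
would be noise dressed as physiology — and readings outside the physical
gradient span [20, 40] °C are rejected as measurement errors. The
preferred temperature is the mean of the retained block, and
`reduce_tpref()` also emits the retained readings in long form, the
natural input for a mixed model with animal identity as a random effect.

## Refuge occupancy

Each scored frame contributes one frame interval (nominally 10 s) to its
state's total; unscorable frames leave every denominator and are counted.
The two proportions that matter are time in any refuge over total time,
and time in the humid refuge over refuge time; raw durations are carried
so downstream models can weight by them. Humid-vs-dry preference is
tested against 0.5 with the one-sample chi-squared equal-proportions test
(continuity-corrected), treating frames as independent Bernoulli trials.
Frames 10 s apart are of course *not* independent — an animal that is
under a refuge now will almost surely be under it at the next frame — and
the package deliberately reproduces the conventional frame-counting
approach rather than correcting for autocorrelation; every test result
carries a `frames_assumed_independent` flag so the caveat travels with
the numbers. The tests verify the chi-squared p-values against an exact
binomial oracle within 10% wherever the p-value is numerically resolvable
(in the far tails both tests underflow toward zero and relative error is
meaningless).

## What the synthetic study emulates

The generator produces every input the pipeline consumes, under a single
master seed. Each animal, trace and trial draws from its own sub-stream
derived deterministically from the master seed and a string key, so
enlarging one sample never perturbs another — a property the tests assert
directly.

* **Masses** follow the per-species, per-season normal distributions of
  the emulated study design (e.g. zig-zag geckos near 1.5 g, house geckos
  near 3.5 g), truncated above zero; linear measurements follow fabricated
  allometric coefficients (SVL ∝ mass^⅓ with lognormal measurement
  noise). The coefficients are invented: only their positivity and rough
  gecko plausibility matter to the computation chain.
* **Water flux.** True per-animal $M_w$ is a species-level scale (set by
  the species' grand-mean mass to the ⅔-ish power, 4 × 10⁻⁶ g s⁻¹ g⁻⁰·⁶⁷)
  times the seasonal multiplier (0.655 in the dry season) times lognormal
  individual variation (log-sd 0.25). Using the species grand mean rather
  than each individual's mass makes the geometric-mean dry/wet ratio equal
  the configured multiplier *exactly* in expectation, even though the two
  seasons' mass distributions differ; flux and body size are therefore
  uncoupled within species, a deliberate trade of realism for an exact
  ground truth.
* **Resistance.** True total resistance is drawn around a wet-season
  median of 150 s cm⁻¹ (a mid-range value for scaled reptiles) times 1.54
  in the dry season (log-sd 0.2), and then *realised* by solving for the
  skin temperature whose saturation vapour density produces that
  resistance given the animal's flux and surface area. Skin temperatures
  are clamped to [16, 44] °C and the recorded ground truth is recomputed
  from the realised temperature, so the generator never stores a truth the
  physics of the trace cannot reproduce.
* **Traces** consist of dry baselines (2 %RH), an animal segment whose
  plateau sits at $VD_i + M_w/V_e$, Gaussian probe noise (default 0.2
  %RH), and Poisson-timed movement excursions with exponential decay. A
  600-s stretch of the animal segment is kept artefact-free so a resting
  read always exists; elsewhere the animal may also happen to rest, as in
  life. Traces are sampled every 5 s for 40 min — long enough for the
  5-min rest rule, short enough that a full study's traces generate and
  analyse in seconds.
* **Body temperatures** are normal draws about the configured species ×
  season preferred temperatures (the zig-zag gecko is configured 2.7 °C
  cooler in the wet season), truncated to the gradient.
* **Refuge logs** come from a sticky three-state Markov chain: stay with
  probability 0.98 per 10-s frame, otherwise redraw from the treatment's
  stationary distribution. This construction makes the stationary
  distribution *equal* the configured occupancy probabilities (humid use
  rising with humid-refuge temperature), with dwell bouts of realistic
  ~8-min scale; the price is geometric bout lengths and no diel rhythm.

What the generator does **not** emulate: behavioural sequence structure
(no day/night cycling, no temperature-dependent movement), measurement
drift within a trace (baselines are stationary unless you construct
drift), covariance between flux and body condition, and gravid-state
physiology. Passing recovery tests therefore demonstrate that the
*computation chain* is correct and unbiased under known structure — they
are not evidence about real animals.

## Numerical choices and degenerate inputs

Rolling window statistics are computed over the time axis (not row
counts) with cumulative sums, so irregular sampling is handled and a
uniform resampling of a trace leaves $M_w$ unchanged within interpolation
error; window boundaries are inclusive with a 10⁻⁹-s tolerance to keep
floating-point time grids from dropping edge points. `which.min`
tie-breaking makes every reduction deterministic. The skin-temperature
inversion uses `uniroot` on the saturation-vapour-density curve at
tolerance 10⁻¹⁰ over [15, 45] °C. Degenerate inputs fail loudly: traces
without an animal segment, non-increasing timestamps, humidity outside
[0, 100], zero refuge time in the preference test, fewer than four
gradient readings, non-positive surface area.

## Study-scale choices

The default configuration runs the full emulated design — 61 flow-through
trials across three species and two seasons, 50 thermal-preference
animals × 12 readings, and 25 refuge animals × 3 treatments × 7200
frames. The descriptive seasonal contrasts are geometric-mean dry/wet
ratios (the matching inferential models use log links), with seeded
bootstrap percentile intervals; the pooled ratio is the geometric mean of
the species-level ratios, weighting species equally so that seasonal
differences in catch numbers do not leak into the seasonal signal. These
are descriptive ratios: covariate-adjusted model estimates (surface area
or mass as covariates, posthoc contrasts) are deliberately out of scope,
and the package instead exports the tidy per-animal tables such models
consume. The bootstrap coverage test uses 200 replicates of a three-
species design at 15 animals per cell — large enough that percentile
intervals are honest, small enough to run in seconds.

## Known limitations

The equal-proportions test inherits the independence approximation
discussed above and will overstate significance for strongly
autocorrelated logs. The six-cylinder surface area ignores the head/torso
distinction and webbing, and carries whatever bias the "one cap" reading
of *single-ended* implies — the alternative is one switch away. The
psychrometric layer is liquid-water only (no ice phase) and
standard-pressure only. And the synthetic study, by design, contains no
effect the configuration did not put there: it validates arithmetic, not
biology.
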