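---
title: "Methods: multiplexed respirometry and load-cell biomonitoring in aviphen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplexed respirometry and load-cell biomonitoring in aviphen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

aviphen processes data from live-in metabolic phenotyping systems for small
birds: acrylic chambers holding a perch, food dish and water bottle on load
cells, continuously pulled by pumps into a multiplexed flow-through
respirometry chain, with an optional RFID antenna reading a
temperature-sensitive PIT tag. This vignette documents the models and the
design decisions behind each processing stage, the simulator used to
validate them, and the known limitations.

## The respirometry model

**Chamber washout.** A perfectly mixed chamber of volume $V$ pulled at flow
$FR$ relaxes toward its steady state with time constant $\tau = V/FR$; one
time constant replaces $1 - e^{-1} \approx 63.2\%$ of chamber air. For the
default geometry (13 L at 1700 ml min⁻¹) `time_constant()` gives 7.65 min.
Field descriptions of this class of system sometimes quote 7.5 min for the
same geometry, which corresponds to an effective mixed volume slightly
below the geometric volume; `process_gas_trace(tau_s =)` accepts an
override for exactly this reason, and the default stays at $V/FR$.

**Instantaneous (z-transform) correction.** Because the chamber integrates
the animal's signal over $\tau$, the instantaneous input is recovered as
$F_{\mathrm{in}}(t) = F(t) + \tau\,dF/dt$. `instantaneous_correct()`
smooths with a centered moving average (default 11 s) and differentiates by
central differences (one-sided at segment ends). On an exponential
approach $F_\infty(1-e^{-t/\tau})$ the correction returns $F_\infty$ up to
discretization error, for any $\tau$. The derivative amplifies sensor noise
by roughly $\tau/\sqrt{w}$ for smoothing width $w$; the 11 s default
balances that against bias on fast transients, and is exposed because
acquisition macros differ in their (usually unpublished) smoothing
parameters. The correction is applied to both O₂ and CO₂: washout dynamics
are gas-agnostic, and leaving CO₂ uncorrected produces large transient
errors whenever metabolism steps (for example at lights-on/lights-off).

**Order of operations.** Per dwell, the pipeline (i) aligns channel lags
(defaults 7 s for O₂, 5 s for CO₂/H₂O), (ii) converts O₂ and CO₂ to dry
fractions sample-by-sample using the dilution factor $1 - \mathrm{WVP}/BP$,
(iii) z-transforms the dry O₂ and CO₂, (iv) extracts the stable window,
and (v) baselines against interpolated ambient windows. Two orderings here
are deliberate and matter numerically:

* *Dry before baseline.* Subtracting ambient from wet fractions first and
  drying afterwards leaves a dilution artifact of order
  $F_{iO_2} \cdot \dot{V}_{H_2O}/FR$ — about 20% of a small bird's O₂
  deficit — because animal and baseline windows carry different water
  vapor. Each window must be dried with its own vapor pressure before
  differencing.
* *Dry before z-transform.* A wet-fraction transient is dominated by water
  vapor washout, so correcting the wet O₂ and then drying mixes two
  different dynamical states. Within each dwell the vapor-pressure channel
  used for the dilution factor is smoothed over 31 s (vapor pressure varies
  at the chamber time constant, so this adds no bias but keeps wvp sensor
  noise out of the z-transform's derivative).

**Stable windows.** Following standard multiplexed practice, only the final
30 s of each 60 s dwell is scored, and within it the contiguous segment
covering 50% (15 s) with the minimum O₂ standard deviation is selected by
exhaustive scan (ties to the earliest). Dwell runs shorter than 45 s
(edge-truncated) are skipped; the analyzer's switch transient
(first-order response, default $\tau$ = 3 s, giving a 10–90% step time of
$\ln 9 \cdot 3 \approx 6.6$ s) has decayed by ~10 half-lives before the
scored region begins. Points are stamped at the dwell end so chamber points
fall exactly on the multiplexer cadence.

**Baselining.** Ambient baseline windows (one 60 s slot per cycle) are
linearly interpolated in time per channel and subtracted; this removes any
analyzer drift that is affine in time exactly, and edge samples fall back
to the nearest single baseline. The water channel is treated specially:
ambient vapor pressure fluctuates (temperature and RH programs), the
chamber low-pass filters those fluctuations with $\tau$, but baseline slots
sample ambient directly. Subtracting raw interpolated ambient therefore
leaves a lag artifact of order $\tau \cdot d(\mathrm{WVP_{amb}})/dt$, which
under realistic RH variation reaches tens of percent of a small bird's
water signal. With `washout_aware_water = TRUE` (default) the interpolated
ambient vapor pressure is passed through the chamber's first-order dynamics
before subtraction, removing the artifact.

**Gas-exchange equations.** The chambers are leaky and at ambient pressure;
the pump pulls $FR$ and the net respiratory volume flux
($\dot{V}_{O_2} - \dot{V}_{CO_2} - \dot{V}_{H_2O,vap}$, under 0.2% of the
1700 ml min⁻¹ pull) enters through the leaks. Incurrent and excurrent dry
flows are therefore taken as equal, and with both gases measured and water
removed mathematically the pull-mode mass balance reduces to

$$\dot{V}_{O_2} = FR_{dry}\,(F_{iO_2}' - F_{eO_2}'), \qquad
  \dot{V}_{CO_2} = FR_{dry}\,(F_{eCO_2}' - F_{iCO_2}'),$$

with $FR_{dry} = FR\,(1-\mathrm{WVP}/BP)$ and primes denoting dry
fractions. The classical flow-imbalance (N₂-balance) corrections would
alter $\dot{V}_{O_2}$ by $\sim F_{iO_2}(1-\mathrm{RQ})\,\dot{V}_{O_2}$
(≈ 3% at RQ 0.85); they are intentionally not applied because the equal-flow
form is the exact inverse of the chamber model above — the same assumption
on both sides of the validation loop. Water loss comes from the
vapor-pressure excess carried by the total flow,
$\dot{V}_{H_2O} = FR \cdot \Delta \mathrm{WVP}/BP$ (ml vapor min⁻¹),
converted to mg min⁻¹ with 22 414 ml mol⁻¹ and 18.02 g mol⁻¹. Reported
water loss is uncorrected for fecal or spilled water.

## Energetics

Hourly and daily gas totals are trapezoidal areas under the metabolic-point
curve with linear interpolation across bin boundaries, so daily totals
equal the sum of the day's hourly totals. Bins whose bracketing coverage
falls below 50% (configurable), or that contain no points, are flagged.
Energy expenditure uses the protein-free two-term Weir form,
$EE\,(\mathrm{kJ}) = 4.184\,(3.941\,V_{O_2} + 1.106\,V_{CO_2})$ with
volumes in liters — stated prominently because laboratories differ in the
constants they carry. Daily minimum metabolic rate is the mean of the two
lowest $\dot{V}_{O_2}$ points per 24 h; day boundaries default to
experiment midnight (the lights schedule is anchored to clock hours), and
this choice is configurable because rate minima near a boundary can move
between days.

## The load-cell pipeline

Raw 1 Hz channels (perch, food, water) are reduced by a centered 60 s
rolling mean/SD; within each 600 s block the rolling mean with the lowest
rolling SD is kept (ties earliest). This is the three-orders-of-magnitude
data reduction: at most one point per channel per 10 min. Records are split
at tare events and differenced only within segments; consecutive stable
points give lag differences with propagated error
$\sqrt{sd_i^2 + sd_{i+1}^2}$.

Differences more than 3 SD from the channel's mean difference mark
*unstable measurements*. Two design points here:

* The reference mean/SD is computed over sub-threshold differences
  (|Δ| ≤ 20 g); refills and dish-perching steps are structural events
  classified by the threshold rules below, and including 150 g refill steps
  in the reference would inflate the SD until the rule never fired.
* A flagged difference indicates a bad *point*, not a bad quantity of
  food: by default (`rejected = "merge"`) the less stable endpoint is
  removed and the channel re-differenced once, so the mass it carried is
  conserved in a single spanning difference. The alternative
  (`rejected = "drop"`) discards flagged differences outright; because
  large differences coincide with high-intake (cold) hours, dropping them
  systematically attenuates intake–energy relationships, which is why merge
  is the default.

Classification on food/water channels: |Δ| in (20 g, 35 g] is recoded as a
body-mass measurement (birds sleeping on the dish or bottle; the recovered
mass is |Δ|, flagged by step direction since both step-on and step-off are
valid reads); |Δ| > 35 g is a refill/perching exclusion; remaining negative
differences are consumption. Intake per hour/day sums the negative
consumption differences only (spillage returns are excluded by default;
configurable), with each difference attributed to bins in proportion to the
overlap of its ~10 min gap — a hard midpoint assignment would always hand
the dusk-boundary difference to an excluded lights-off hour. Body mass per
bin averages perch points inside a plausibility band (default 15–45 g,
excluding empty-perch readings) together with recoded events. The
empty-chamber drift diagnostic is the daily max − min of each channel's
stable points.

## The statistical layer

`build_hourly_table()` joins hourly energetics, intake/mass and
environmental means per bird-hour and flags lights-off hours, which the
intake models exclude. `fit_model_set()` fits every predictor subset by
least squares and selects by AIC; rank-deficient designs are an error, not
silently dropped. Hour-of-day enters as a 24-level factor — it absorbs the
circadian profile without assuming a shape — and bird ID as a fixed effect.
Right-skewed responses (water loss, water intake) are log-transformed, and
log-scale coefficients are reported as percent effects,
$100\,(e^\beta - 1)$.

## The simulator

The bird model is deliberately minimal: a Scholander-type piecewise-linear
metabolic curve, $\dot{V}_{O_2} = a(t)\,\max(\mathrm{bmr},\,
\mathrm{bmr} + c\,(T_{lc} - T_a))$, with circadian activity $a(t)$ equal to
1.15 in lights-on and 0.85 in lights-off hours (mean exactly 1, so the
fitted temperature slope equals the configured one), fixed RQ, and
evaporative water loss multiplicative in temperature (+5%/°C) and RH
(−4%/%RH). The default thermal conductance is derived from a target energy
slope of 0.05 kJ h⁻¹ °C⁻¹ through the Weir conversion
(`conductance_for_ee_slope()`). Hour-level lognormal noise (2% on VO₂, 5%
on water loss and intake) stands in for biological variability, and the
intake couplings act on the *realized* hourly energy expenditure: food
(g/h) rises 0.1 g per kJ and water multiplicatively by 17% per kJ above a
common reference EE, anchored so daily intakes are ≈ 5.7 g food and
≈ 9.4 g water at thermoneutrality. Default basal rates (1.35/1.50/1.65
ml O₂ min⁻¹ across the three birds) keep measured daily minima — which
carry a ≈ −2σ selection bias from per-point noise — inside the 1.0–1.6
ml min⁻¹ range expected for captive house sparrows.

Feeding and drinking happen as ten 60 s bouts per channel per lights-on
hour in twelve 5-minute slots, uniform within-hour bout masses. The
granularity matters: intake records of this kind resolve roughly one intake
event per ten-minute stable point (~0.1 g per difference), and coarser bout
structures put the largest cold-hour differences beyond the 3-SD band,
wholesale-rejecting cold-day intake. Some nights the bird sleeps on the
food dish (probability 0.3 per night), which produces the ±(20–35) g steps
the recode rule rescues. Load cells have Gaussian 1 Hz noise (0.05 g) and
linear drift (0.5/0.04/0.05 g day⁻¹ for perch/food/water), re-zeroed at
tare events every 2 days; refills add +50 g (food) / +150 g (water) steps
every 4 days. RFID reads fire every 2 s while the bird's behavior places it
in antenna range (a state gate standing in for the ~13 cm physical range).

Chamber gas dynamics use the exact exponential update per 1 s step (never
forward Euler, so integrator error cannot masquerade as pipeline error):
dry O₂/CO₂ relax toward $F_{amb} - \dot{V}/FR_{dry}$, water vapor has its
own washout channel, and wet measured fractions are formed as
$F^{wet} = F^{dry}(1 - f_{H_2O})$. The rate coefficient for the dry-gas
recursion uses the mean dry flow while the steady-state term uses the exact
time-varying dry flow, so steady-state deficits are exact and the analysis
dry flow $FR(1-\mathrm{WVP}/BP)$ matches the simulator identically. The
analyzer chain applies a first-order response, channel lags, linear span
drift and additive Gaussian noise (defaults 1×10⁻⁶ O₂ fraction, 5×10⁻⁷
CO₂, 0.002 kPa water at 1 Hz — high-grade analyzer class; with the
z-transform in play, 1 Hz noise is what governs per-point VO₂ scatter).
The default temperature program steps 25 → 5 °C in daily decrements with
30-minute linear transitions — an environmental chamber cannot step
instantaneously, and a discontinuity would put unphysical transients
through every oracle. The humidity program is a daily sinusoid with seeded
day-to-day offsets so that hourly RH is not a pure function of hour-of-day
(otherwise the RH effect would be aliased by the hour factor).

What the simulator does *not* emulate — and what passing tests therefore do
not establish about real data: digestion/postprandial metabolism, activity
beyond the two-level circadian factor, social effects, body-mass dynamics,
non-Gaussian or spectrally structured sensor noise, RTC clock drift between
loggers, imperfect chamber mixing, and RFID antenna physics. Validation
against it demonstrates that the *processing* is faithful to its stated
model, not that the model captures every property of live birds.

## Numerical choices and degenerate inputs

Rolling means/SDs and the window scans use cumulative sums (exact to ~8
significant digits at these scales; the dedicated tests compare against
direct evaluation). All tie-breaks select the earliest candidate.
First-order recursions run through `stats::filter`. Non-finite parameters,
zero flows, lags longer than the trace, dwell schedules shorter than the
stable window, missing baselines, wvp ≥ bp, and rank-deficient designs are
rejected with named errors; empty inputs return empty structures. Negative
simulated masses are clamped to zero with a warning count. Fixed seeds give
bit-identical streams; every stochastic component derives its own stream
from the master seed.

## Validation problem sizes

The package validates itself on: the default three-bird, ten-day study
(720 bird-hours through the full gas + mass pipeline) for coefficient
recovery; one-bird, one-to-two-day noise-free runs for oracle equivalence
(steady-state recovery within 1%, ramped programs within 5%); and
analytic/property checks (exponential washout to machine precision, exact
removal of affine drift, dilution round-trips, intake conservation at zero
noise, threshold edges at 20/35 g, 600–1100× data reduction). These sizes
were chosen so the whole suite runs in minutes on a laptop while the
recovery fits still have hundreds of bird-hours behind them.
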