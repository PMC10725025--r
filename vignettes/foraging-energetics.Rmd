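---
title: "Foraging energetics from behavioral event logs: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foraging energetics from behavioral event logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeforage)
```

## The model

`beeforage` analyses experiments in which individual bumblebee workers
forage in a flight arena offering vertically and horizontally oriented
artificial flowers, each loaded with a 15 μL sucrose droplet, under three
concentration treatments (% w/w, vertical/horizontal): control 35/35,
low difference 50/35, high difference 50/20. Slippery vertical surfaces in
the test phase force hovering, so a bee choosing the vertical reward pays
flight-level metabolic costs during flower handling. An observer logs one
timestamped interval per behavioral activity (flying, visiting, drinking,
resting), with the locomotor state (landed/hover) and the flower identity.

From that log the package computes, per foraging trip,

$$\mathrm{RER} = \frac{E_{\mathrm{in}} - E_{\mathrm{out}}}{t},
\qquad
\mathrm{EE} = \frac{E_{\mathrm{in}} - E_{\mathrm{out}}}{E_{\mathrm{out}}},$$

the two classical foraging currencies. $E_{\mathrm{in}}$ comes from
estimated consumed volumes, $E_{\mathrm{out}}$ from integrating
mass-specific metabolic power over every event, and $t$ is the arena time
plus modeled nest time. Series of both currencies per consecutive ten
drinking visits, counterfactual re-computations under substituted
concentrations, choice-proportion GLMMs and a randomization test complete
the pipeline.

### Events, visits, choices

A *flower visit* merges consecutive interaction events with one flower:
a return to the same flower within 10 s of the end of the previous
interaction with it, with no other flower interaction in between, continues
the visit (the clock runs from the end of the previous interaction).
Drinking durations within a visit are summed; the visit is a *choice*
(drinking visit) when the summed tongue-contact time exceeds 2 s, the
threshold separating drinking from tasting. Both rules are exact
re-statements of the field protocol; the merge never crosses a trip
boundary because the bee returns to the nest between trips.

### Volume and intake

Drinking rate follows a mass power law $a\,(m/m_1)^b$ fitted separately for
35% ($a = 2.991$ μL s⁻¹, $b = 0.4602$) and 50% w/w ($a = 1.542$,
$b = 0.155$), with $m_1 = 1$ g. Drinking rate is constant below roughly
35–40% w/w, so concentrations at or below the plateau (default 35) reuse
the 35% model — this is how 20% sucrose is handled. Concentrations strictly
between the plateau and 50% have no fitted model: the default is an error,
with opt-in log-linear interpolation (`interpolate = TRUE`) for simulation
studies, so the fitted range is never silently extrapolated.

Per visit, volume = rate × summed drinking time, zero at or below the 2 s
threshold, and capped so that cumulative consumption per flower per trip
never exceeds the 15 μL reward (a bee can return to a partly drained
flower; the flower still only ever held 15 μL). Sucrose mass uses the
density polynomial $\rho(c) = 0.9988603 + 0.0037291c + 0.0000178c^2$
(g mL⁻¹) times $c/100$, and energy is 15.48 J per mg of sucrose.

### Expenditure and mass updating

Each event is costed at mass × mass-specific rate: flight (0.435 J g⁻¹ s⁻¹)
while flying between flowers *or interacting with a flower while hovering*;
probing (0.034 J g⁻¹ s⁻¹) while landed on a flower, resting, and for all
nest time. Hover and landed sub-intervals within one visit are costed
separately. The bee starts each trip at unladen mass and gains the consumed
*solution* mass (volume × ρ) at the end of each drinking bout; within-bout
power uses bout-start mass. Bout-level granularity is the finest unit the
volume estimates support. The robustness switch `mass_updating = FALSE`
fixes mass at unladen; on simulated data this perturbs RER by under 10% and
changes no treatment-level ordering, mirroring the published robustness
note about load-independent metabolic rate.

### Nest time

Offloading time is $10^{-1.652}\,(\mu_c/1\,\mathrm{mPa\,s})^{0.502}\times V$
seconds, with viscosity evaluated at the abdominal temperature
$16.8 + 0.438\,T_{\mathrm{lab}}$ (default lab temperature 21 °C). Viscosity
uses the Génotelle functional form
$\log_{10}\eta = 22.46N - 0.114 + \varphi(1.1 + 43.1N^{1.25})$, with $N$
the sucrose mole fraction and $\varphi = (30-T)/(91+T)$. The exact
coefficient set used by the original analysis is not printed in its
methods; the implemented literature set recovers pure water to ~4% at
20 °C and is injectable through `physiology_params(viscosity_coefs = ...)`
— flagged prominently because offloading time (seconds per trip) is a
small term in trip time.

Other nest time is fixed at 83.8 s per trip. Nest terms are always
*modeled*, not read from the log: the logging protocol records arena
behavior only, so literal `offload`/`nest_other` rows are accepted by
validation but ignored by energetics. Offloading is costed at probe rate at
laden mass, other nest time at unladen mass (the mass state in the nest is
ambiguous in the source protocol; this choice is flagged here and
configurable only by editing the trip routine deliberately).
Experimenter gate-holding between trips never enters the log and is
excluded from trip time by construction.

### Windows of ten drinking visits

Bees take different numbers of trips to complete the 90 test-phase choices,
so comparisons run per consecutive ten drinking visits. Every arena event
inherits the RER (or EE) of its trip; each event is assigned to the first
choice completing at or after the event ends; a window's value is the mean
over all events of its ten choices. A window spanning a trip transition is
thereby weighted between the two trips by event count. The original
description ("weighted appropriately") does not fix the weighting; event
counting is the default and `weighting = "duration"` provides the
event-duration alternative — on simulated data the two differ by well under
the between-bee spread. Handling time and handling energy divide the
window's total flower-interaction time (or its metabolic cost) by its
number of choices; between-flower flight time counts only `fly` events, so
hovering interaction is excluded by construction. A final window with fewer
than ten choices is reported with `complete = FALSE` and excluded from
cross-treatment summaries.

### Counterfactual strategies

The alternative-strategy estimate re-runs the entire energetics pipeline on
donor bees' observed event streams with another treatment's
orientation → concentration map: volumes, intake, mass updating and
offloading all change; timings and choices do not. This is valid because
drinking rate does not change below the ~35–40% plateau, so the substituted
behavior remains physically plausible (e.g. control donors at 35/35
re-computed under 20% horizontal; high-difference donors under 50/35). With
an identity map the observed energetics are reproduced exactly, which the
test suite asserts to 1e-12.

### Statistics

Per-trip proportions of vertical choices are modeled as a binomial GLMM
with a random intercept per bee and the cumulative number of completed
drinks at trip end as predictor (`lme4::glmer`). The model-predicted mean
proportion (MPMP) is the population-level prediction with random effects at
zero; confidence intervals use `lme4::bootMer` parametric bootstrap
(default 10,000 simulations, the published figure; the test suite scales to
500 for desk runtime). The predictor is internally divided by 100 for
optimizer stability. Separation or non-convergence raises a classed error
carrying the optimizer message rather than returning a silent fit.

The randomization test compares group mean final-ten-choice proportions:
pool the per-bee values, re-split at the original group sizes without
replacement (default 100,000 draws), and report the add-one-corrected
two-sided p-value on $|\Delta|$. Sidedness is not stated in the source
protocol; two-sided is the conservative default with one-sided flags. The
null draws resample from the sorted pool — exchangeability leaves the null
distribution unchanged, and it makes the p-value exactly invariant to group
labelling and location shifts at a fixed seed. Whether the original test
resampled per-bee proportions or pooled choices is also not stated;
per-bee is the default, `unit = "choices"` the alternative.

## The simulator: what it emulates, and what it does not

`simulate_experiment()` generates the full stated design: 36 bees (3
colonies × 3 treatments × 4 bees), unladen masses lognormal around the
171 mg forager median, a familiarization phase on easy-grip flowers through
the trip containing the 60th drinking visit, a test phase on slippery
flowers through the trip containing the 90th, a 15 + 15 flower grid with
15 μL rewards, and per-bee RNG substreams derived from (seed, bee id) so
datasets are byte-reproducible.

Mechanics: trips end when the crop reaches capacity (120 μL — not reported
by the study; chosen once so trips hold ~8–15 choices, consistent with 90
choices over a handful of trips, and flagged as a free parameter). Drinking
bout durations are generated by *inverting* the drinking-rate model from
target volumes, so the estimation pipeline recovers ground-truth
consumption exactly up to the 2 s and 15 μL rules. On slippery vertical
flowers 98% of drinking attempts hover, and hover bouts are interrupted at
a per-second slip hazard (0.12 s⁻¹); interrupted bees usually re-approach
within the 10 s merge window (probability 0.8), producing the partial-drink
and return-visit structure of the real protocol. Timing distributions
(between-flower flight median 3 s, landed approach 1.5 s, hover scrabbling
6 s, occasional rests) are lognormal with configurable medians — the source
reports no timing distributions, so these were chosen once to put simulated
median per-choice handling in the published 14–21 s band, and are not
revisited.

Choice policies are explicit data-generating devices, **not** claims about
bee cognition: `constant_p`, `learning_sigmoid` (treatment- and
phase-specific sigmoid trajectories of p(vertical) against choice number,
emulating the published switching curves), and `greedy_rer` / `greedy_ee`
(deterministic prospective comparison of per-choice currency values, with
the expected slip-interruption time and energy included in the hover
valuation). Under the greedy-RER policy the low-difference world switches
to horizontal while the high-difference world stays vertical, and under
greedy-EE both switch — the qualitative structure that makes the two
currencies distinguishable.

What a green test does **not** establish: the simulator has no spatial
flight paths (flower identity only), no scent-mark avoidance, no
bee-to-bee behavioral idiosyncrasy beyond mass and RNG stream, no
non-stationary motivation, and its expenditure structure is exactly the
model the pipeline assumes — so simulator-based tests validate bookkeeping
and statistical machinery, never the physiological model itself against
nature. Trip-level EE on simulated data is higher than published values
because simulated bees fly less between flowers than real ones; this
affects no tested quantity.

## Numerical choices

- Timestamps are integer milliseconds end-to-end; seconds appear only in
  physiology/energetics. Events of one trip must be non-overlapping and
  time-ordered; validation errors name the bee and trip.
- Phase labels are recomputed from the 60-drink boundary on ingest and
  mismatches warn rather than being trusted from the column.
- The per-flower cap is applied to *cumulative* per-trip consumption across
  repeat visits, before energy conversion.
- Energy conservation (trip intake = Σ per-visit energy; expenditure =
  Σ event power × duration + nest terms) is asserted at 1e-9 relative in
  the test suite.
- Zero-duration trips, zero denominators in RER/EE, unknown orientations,
  and unmodeled concentrations raise classed errors (`beeforage_schema`,
  `_config`, `_convergence`, `_missing_window`, `_validation`) that the CLI
  maps to distinct exit codes (2–6).
- Monte-Carlo p-values use the add-one correction, so p is never 0 and is
  reproducible under a recorded seed.

## Known limitations

- The deposited observation data's CSV schema is undocumented here; the
  canonical dialect plus `event_log_dialect()` mapping is the supported
  ingestion path, and `cmd_reproduce` expects a re-export in that dialect.
- Only the 35% and 50% drinking-rate models exist; the (35, 50)% interval
  is interpolated on request only.
- No thermoregulation beyond the affine abdominal-temperature relation, no
  load-dependent flight-cost curve (the robustness switch brackets the
  effect), and no crop physiology beyond the capacity that ends a trip.
- Welch/ANOVA/Tukey comparisons on the emitted summary tables are standard
  library calls and deliberately out of scope; the package emits the tidy
  per-window tables those tests consume.
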