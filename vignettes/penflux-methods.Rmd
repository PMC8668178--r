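---
title: "Methods: enclosure emissions, trial design, and dose-response in penflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enclosure emissions, trial design, and dose-response in penflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penflux)
```

`penflux` analyses dose-titration feeding trials run in sealed,
mechanically ventilated cattle pen enclosures (CPEs). This vignette is the
package's own account of the science it implements: the measurement model
and its assumptions, the statistical machinery, the synthetic-data
generator that stands in for raw trial data, and the numerical and design
choices made where the underlying procedure left the detail open.

## 1. The measurement model

### Flux from net concentration

Each gas (NH~3~, CH~4~, CO~2~, H~2~S, N~2~O) has one analyzer that samples
a rotating sequence of sources — ambient air, then each of the eight
enclosures — in 15-minute periods at a 15-second cadence, around the
clock. The enclosure is treated as perfectly mixed with a known outflow,
so the mass leaving per minute is the net concentration (enclosure minus
ambient) times the volumetric airflow, converted from a per-litre
concentration to grams via the molar volume at the analyzers' controlled
conditions ($V_s = 22.4$ L/mol, temperature-corrected to the sample
temperature in kelvin) and the species' molecular weight:

$$
\mathrm{flux}\;(\mathrm{g/min}) \;=\;
\frac{(C_\mathrm{cpe}-C_\mathrm{amb})\; Q \; 1000}
     {V_s \,(T+273.15)/273.15}\;\frac{MW}{D},
$$

where $D$ is $10^6$ for the mg/L gases (CH~4~, CO~2~, N~2~O) and $10^9$
for the µg/L gases (NH~3~, H~2~S). Two modelling assumptions matter:

* **Perfect mixing.** No spatial concentration model is attempted; the
  single sampling port is taken as representative. This is the standard
  assumption for this chamber design and the one under which the
  sealed-box recovery property (Section 5) is exact.
* **Negative net concentrations are data.** Enclosure N~2~O typically runs
  below ambient; clamping at zero would bias cumulative totals upward, so
  the sign is preserved end to end.

**Airflow.** Each enclosure has two fans, each calibrated at the start and
end of a cycle. Two calibration points admit only a linear decay curve, so
fan flow is interpolated linearly in time and enclosure outflow is the sum
over fans. Extrapolation outside the calibration window is an error, not a
guess.

**Temperature.** The "sample temperature" in the flux equation is taken
from the enclosure RH/T sensor, averaged over the sampling period. Which
sensor's temperature belongs in the equation is genuinely ambiguous
(analyzers hold their own temperature constant); the enclosure sensor is
the default because it reflects the air actually leaving the pen, and the
choice is confined to one argument of `period_flux()` so either convention
can be run.

**Ambient pairing.** Ambient air is sampled in its own period at the head
of every rotation sweep, not concurrently with the enclosures. Each
enclosure period is therefore paired with the most recent *valid* ambient
period of the same gas (the current sweep's ambient reading under normal
operation); if none precedes — possible only at the very start of a cycle
— the nearest later one is used. With a slowly varying ambient baseline
(the generator uses AR(1) deviations of a few percent) the pairing error
is second order.

### Validity rules

* Opening the large door or the feed-bunk flaps disturbs equilibrium:
  readings of the affected enclosure from 5 min before opening to 15 min
  after closing are excluded. Small-door entries exclude nothing.
  Overlapping windows union (the flag is set-based), which makes the
  operation idempotent — applying the event log twice changes nothing.
* A 15-min period is valid with at least 4 min of clean data — at least 16
  of its 60 readings, boundary inclusive.
* A gas-day (0800-anchored) needs at least four valid periods. A day that
  fails is replaced by the arithmetic mean of the per-animal daily values
  of days $d{-}2, d{-}1, d{+}1, d{+}2$; all four must exist and be valid,
  and there is deliberately no deeper fallback — an unrecoverable day is
  an error, because silent gap-filling would not be defensible for a
  cumulative endpoint.
* Substitution operates on the *daily per-animal series*, after
  aggregation — not on raw readings — matching how replacement data enter
  a cumulative total.

A period straddling the 0800 day boundary would be assigned to the day
containing its start time; with the 15-min grid aligned to the day this
does not arise in normal operation, but the rule is fixed and documented
rather than left to chance after a mid-day restart.

### Aggregation conventions

Daily per-animal emission is the mean over valid period fluxes × 1,440 min
÷ the head count present that day. Head count uses the inventory's
convention that an animal removed mid-day counts through its removal day —
conservative and deterministic. Cumulative windows labelled "0 to N" sum
the N complete days 0..N−1; the 0–91 window thus covers days 0..90, since
measurement stops at 0500 h on day 91 before a complete 0800–0759 day
(at the reported precision the alternative inclusion of the partial day is
nearly indistinguishable, but the convention must be fixed for the
conservation tests to be exact). Standardization divides by the pen mean
unshrunk body weight at the interval-end weigh day, and by pen mean hot
carcass weight for the final interval: the pen, not the animal, is the
experimental unit throughout.

## 2. The statistical engine

Each pen-level outcome is analysed as a balanced randomized complete block
design: fixed dose, sex, dose × sex; cycle as the block stratum; one pen
per dose × sex cell per cycle. In the standard design (3 cycles × 4 doses
× 2 sexes) the degrees of freedom are 2/3/1/3 with 14 residual. Because
the design is balanced, the classical sums-of-squares decomposition gives
exactly the treatment F-tests, least squares means, SEMs and contrasts
that a REML mixed model with random cycle would give, so the closed form
is implemented directly (`rcbd_fit()`) and verified against an explicit
design-matrix least-squares oracle in the tests. One simplification
relative to REML is noted: a negative cycle variance component cannot
arise in the fixed-stratum formulation.

Reporting follows an interaction gate: if dose × sex has $p \le 0.05$
(ties route within sex — the stricter reading of the two conventions
"not significant ($P > 0.05$)" and "significant ($P \le 0.05$)"), control
contrasts are reported within each sex; otherwise dose means pooled over
sex are used. Planned contrasts against control are unadjusted pairwise
t-tests on the residual df with $SE = \sqrt{2\,MSE/6}$ for pooled dose
means — no multiplicity correction, by design. Labels: $p \le 0.05$
significant, $0.05 < p \le 0.10$ a tendency.

Sparse categorical outcomes are fitted with a binomial logit GLM with
cycle as a fixed block (the fixed-block approximation to the binomial
GLMM; the exact denominator-df convention of the mixed version is not
reconstructable and is not guessed). When any dose arm has zero (or
saturated) counts, or the fit fails, the analysis falls back to Fisher's
exact test of control versus the pooled treated arms — base R's exact
conditional test, checked in the suite against a direct hypergeometric
enumeration.

## 3. Dose-response and effective doses

Five competing mean functions are compared on the dose grid
{0, 1.38, 5.5, 22} mg/kg DM: (1) linear throughout; (2) linear to 1.38
then plateau; (3) linear to 5.5 then plateau; (4) flat to 1.38, linear to
5.5, plateau; (5) flat to 1.38, linear to 22. Each is an intercept + slope
model in a piecewise-linear transform of dose, so continuity at the
breakpoints holds by construction (verified numerically to 10⁻⁹ in the
tests).

The published procedure fits the candidates "to the least squares means"
and selects by "smallest P-value". The exact test behind those p-values is
not specified, so the package implements a documented reconstruction: OLS
of each candidate on the four dose LSMeans (unweighted — a common SEM in a
balanced design makes weighting moot), with the slope tested against zero
using the SEM-derived standard error $SEM/\sqrt{S_{xx}}$ on the pooled
residual df (14). Ties break toward the model with fewer segments, then
the lower model number. Under this reconstruction selection reduces to
maximizing the regression sum of squares over the four means, which gives
the selection-consistency property the tests verify: means generated on
any candidate's shape select that candidate as noise vanishes.

Two caveats are documented rather than hidden. First, the published
per-model p-values depend on unpublished fitting details and are not
claimed reproducible. Second, on the reference trial's NH~3~/kg-HCW
LSMeans (22.3, 19.5, 18.7, 18.5; SEM 1.97) this reconstruction — and
every natural means-based criterion we examined (maximum explained sum of
squares, per-model residual t, fixed-intercept variants) — prefers the
linear-to-1.38 plateau shape, whereas the published analysis reported the
linear-to-5.5 plateau as best by a razor-thin margin (0.0001 vs 0.0002).
The corresponding acceptance test records this divergence as a failing
expectation by intent; the package does not special-case the selection to
force agreement.

The minimum effective dose is the smallest dose whose planned control
contrast is significant ($p < 0.05$) after a significant overall F-test;
on the reference contrast table this is 1.38 mg/kg DM. The maximum
effective dose is the join point of the selected model, declared only when
the selected model has a plateau and its slope differs from zero
($p \le 0.05$).

## 4. Growth, carcass and environment metrics

DMI = (delivered − orts) / cattle-days × diet DM fraction; ADG from pen
mean unshrunk BW at days 0 and 91; G:F = ADG/DMI; dressing percent =
100 × HCW / final BW. Yield grade uses the printed USDA linear formula,
with discrete classes by floor-and-clamp to 1..5. Quality classes map
marbling (100 points per degree, 500 = Small^00^) to the five grid-pricing
categories with the standard USDA breakpoints (700/600/500/400) — the
category names come from the trial's analysis plan, the cutoffs from
USDA convention, and the mapping assumes A/B maturity (older carcasses are
out of scope). THI uses the cattle heat-stress formula
$0.8\,T_A + (RH/100)(T_A - 14.4) + 46.4$. Shear force is the mean of
exactly six cores per steak. "Adjusted" fat thickness is treated as a
measured input; no adjustment procedure is modelled.

## 5. The synthetic trial generator

`simulate_trial()` emulates the statistical structure the analysis
assumes, not the biology that produced it — effects are injected
phenomenologically, and no rumen or nitrogen-balance mechanism is
simulated.

What it generates, per cycle: a random allocation of the 8 dose × sex
treatments to enclosures; 14 animals per pen with sex-specific initial
weights; per-day Bernoulli removals with a hard floor of 10 head per pen
(so the head-count denominator is exercised without degenerate pens);
interim weights at days 0/7/14/28/56/91; feed deliveries constructed so
the DMI formula recovers the pen's true intake exactly; carcass records
with dose-dependent means; fan calibrations with linear decay; a
sinusoidal climate; door events at configurable rates; and the full 15-s
reading stream, in which enclosure concentrations are obtained by exactly
inverting the flux equation at the instantaneous true emission rate,
airflow and temperature, plus the AR(1) ambient baseline and multiplicative
reading noise.

The emission truth model is multiplicative:
$$
r_{c,p,g,d} = \beta_g \cdot m_g(\mathrm{dose}) \cdot u^{cyc}_{c,g}
\cdot u^{pen}_{c,p,g} \cdot u^{day}_{c,p,g,d},
$$
with every $u$ a mean-one lognormal and a diurnal factor
$1 + A\cos(2\pi(h - h_{peak})/24)$ that integrates to one over a day.
Consequently the expected per-animal daily emission is available in closed
form (`expected_daily_emission()`), which the Monte-Carlo agreement tests
use, and the continuous rotation samples the diurnal cycle evenly — a
deliberately biased (e.g. daytime-only) schedule on this generator shows
the diurnal bias the continuous design eliminates.

Default parameters are the study conditions: doses {0, 1.38, 5.5, 22}
mg/kg DM, 3 cycles × 8 enclosures × 14 head × 91 d, NH~3~ baseline 85.5
g/animal/d with dose multipliers {1, 0.911, 0.881, 0.867}, CH~4~ 115,
CO~2~ 7,912, H~2~S 0.226, N~2~O −0.30 g/animal/d (net negative against
ambient), ADG 1.27 kg/d at control with multipliers {1, 1.118, 1.094,
1.126}, dressing fractions {0.615, 0.624, 0.627, 0.628}, and carcass-trait
means of the corresponding magnitudes. Within-day and between-pen
dispersion is not reported for the reference trial, so those defaults are
stated assumptions, chosen once to reproduce pen-level SEMs of the
reported order (pen CV 0.25, cycle CV 0.12, day CV 0.08, reading CV 0.10)
and not revisited: with 6 pens per dose they imply an SEM for the 91-d
NH~3~ total of roughly the published 855 g.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: analyzer drift and cross-sensitivity,
incomplete mixing and port placement, correlated weather, non-lognormal
emission bursts (pen disturbances, estrus activity), intake–emission
feedback, and seasonal confounding between cycles. The generator validates
the *pipeline arithmetic and inference*, not the chamber physics.

## 6. Numerical choices and problem sizes

* Exclusion windows are closed intervals at the 15-s grid; the 16-reading
  period threshold and 4-period day threshold are inclusive.
* The flux conversion and its inverse are exact to machine precision;
  flux-engine agreement with an independently coded dimensional-analysis
  oracle is required to 10⁻¹², and RCBD agreement with the design-matrix
  oracle to 10⁻¹⁰.
* The conservation identity (zero-noise generator → cumulative = days ×
  rate to 10⁻⁹ relative) holds exactly only when airflow, temperature and
  diurnal amplitude are constant; the sealed-box recovery check instead
  runs with realistic decay, climate and reading noise and requires
  recovery within 1%.
* Dose-response ties break toward fewer segments; the interaction-gate tie
  at exactly 0.05 routes within sex; `n_conservation()` computes its
  efficiency with the carcass-equivalence factor rounded to its reported
  precision (31.1 kg per kg NH~3~), reproducing the published worked
  example exactly (the unrounded chain differs by ≤ 0.1 percentage
  point, and the unrounded equivalents are returned alongside).
* Simulation sizes in the tests were chosen to make the checks sharp at
  interactive runtimes: 2,000 null trials for the type-I error of the dose
  F-test (binomial SE ≈ 0.005 around 0.05), 500 trials for contrast CI
  coverage with noise calibrated to the published SEM (1.97), 100 draws
  per generating shape for selection consistency, and reduced-duration
  (2–10 d) reading-level trials for the end-to-end pipeline properties,
  since the per-day arithmetic is identical at any duration.

## 7. Known limitations

* The statistical engine requires the balanced design; general unbalanced
  mixed models, Satterthwaite/Kenward–Roger df and multiplicity
  adjustments are out of scope.
* The dose-response p-values are a reconstruction (Section 3); only the
  qualitative selection machinery is claimed, and one published selection
  is knowingly not reproduced by it.
* The binomial category model approximates the random-cycle GLMM with a
  fixed block.
* Recovery-factor correction of fluxes is intentionally not applied; the
  recovery check is a validation property, not a calibration.
* WBSF covers core averaging only; cooking protocol, aging-time effects
  and grid pricing are not modelled.
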