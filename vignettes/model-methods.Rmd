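---
title: "Model structure, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bicea)
```

This vignette is the package's own account of the science inside it: what
the model assumes, which parameters matter, what the synthetic inputs
emulate, and where the design was genuinely open and a choice had to be
made.

## The decision problem and the model

Children born with severe-to-profound sensorineural hearing loss in both
ears can be treated with one cochlear implant plus a contralateral hearing
aid (bimodal hearing) or with implants in both ears, placed either in a
single surgery at age 1 (simultaneous) or two years apart (sequential,
second implant at age 3). The package evaluates each bilateral strategy
against bimodal hearing from a healthcare payer perspective.

The engine is a four-state Markov state-transition model over annual cycles
from age 1 to age 84: *use of 1st internal device*, *use of 2nd internal
device*, *use of 3rd internal device*, *death*. Transitions are driven by
three risks; their within-cycle resolution order is not dictated by the
model description we follow, so the package fixes one and applies it
identically in both engines (cohort and microsimulation):

1. **all-cause mortality** first (life-table `qx` at the current age);
2. **major complications**, conditional on survival, at 0.01/yr in the
   first year of each device and 0.001/yr thereafter, split half wound
   revision (no state change) and half explantation with re-implantation;
3. **internal-device failure**, conditional on no complication, at the
   time-dependent reliability hazard.

Mutually exclusive competing risks are assumed within a cycle: the original
TreeAge implementation's tie-breaking is unknown, and at the event rates
involved (~1e-2 and below) the difference between orderings is far below
every reported precision.

Two clock conventions matter. The failure/complication clock is *years
since the current device's implantation* and resets on every replacement,
so first-year surgical risk re-applies after each re-implantation
(surgical risk is per procedure). At most two replacements occur; in the
third-device state further explantation/failure events are suppressed but
wound revisions can still arise. In the sequential arm, no surgical
complications are attributed to the first implant, so the tracked event
chain starts at the second implantation (age 3); before that only mortality
applies.

A deliberate simplification inherited from the source model: one device
chain is tracked per patient, and bilateral arms pay **twice** the bimodal
replacement and complication costs rather than simulating two ears with
independent failures. The doubling is exact in expectation (the two ears
carry identical risks) and is verified to hold exactly in the cohort
traces.

## Effectiveness

QALYs accrue on the *gain over no implantation* scale — the no-implant
baseline is normalised to zero, so arm totals are streams of utility gain,
not absolute utilities. The schedule is age-banded: bimodal hearing is
worth 0.232/yr and the second implant a further 0.03/yr at full realisation
(ages 4–54), with scaling factors 28% (age 1), 91% (2–3) and a declining
tail from age 55 (98%, 96%, 91%, 84%, 72%).

The published table's cells embed their own rounding (e.g. 0.212 where
0.91 × 0.232 = 0.2111; 0.027 at three decimals where the same 91% scaling
appears elsewhere as 0.0273): the engine therefore consumes the *printed*
cells verbatim whenever the base increments equal their printed basis, and
switches to `scaling × base` the moment a base is overridden (sensitivity
analyses, PSA draws). This keeps the base case faithful to the published
table while making incremental QALYs exactly proportional to the bilateral
base increment under overrides — which is what lets halving 0.03 to 0.015
double the ICER to numerical precision.

Discounting is 3%/yr; the half-cycle correction applies to QALYs only
(credited mid-cycle, `(1+r)^-(cycle-0.5)`), costs at cycle start. Whether
costs were also mid-cycle discounted in the original is not stated;
cycle-start discounting is the conventional reading of "QALY gained only".
Nothing accrues beyond age 84, the end of the last utility band.

## Costs

Only resource use *incremental* to bimodal hearing is published. To make
arm-level totals reportable at all, the package reconstructs a first-implant
"backbone" (implantation plus device plus ward day in year 1, habilitation
tapering over years 1–3, one processor upgrade stream) applied identically
to every arm. Its composition is a reconstruction, not data — so it is
designed to cancel exactly from every incremental comparison, and a test
perturbs it and re-diffs to prove that. Arm-level totals are reported but
never treated as reproductions of the published ones.

Event costs: wound revision = revision surgery + 1 ward day; explantation
or failure = explant/re-implant surgery + 1 ward day + a replacement device
*only* past the 10-year warranty. Periodic items: external processor every
7 years anchored at each implant's implantation year (so the extra bilateral
processor stream starts 7 years after the second implant), hearing aid
every 5 years charged to the bimodal arm only (its contralateral aid; in the
bilateral arms that ear is implanted). The sequential arm's aid during the
two-year wait never reaches a 5-year replacement, so it contributes nothing
incremental.

Two quantities behind the published cost totals are not recoverable:

* **External-processor replacement price.** Absent from the published cost
  table, yet the 7-year upgrade stream is a large cost component. It is a
  *required* configuration field with no default; the packaged value
  (5,923.03 USD — plausible for a sound processor) is reconstructed by
  root-finding so that the cohort simultaneous-vs-bimodal incremental cost
  equals the published 53,451 USD, then held fixed everywhere. The
  sequential increment thereby becomes an out-of-sample plausibility check
  (it lands within 15% of the published value), and arm totals are not
  acceptance-tested.
* **The bimodal arm's absolute cost.** Depends on the backbone composition;
  reported, not validated.

The tornado's "cost of initial bilateral implantation" parameter is
implemented as a multiplier on the *acquisition* items (devices, implant
surgeries, ward day at implantation) of the bilateral arm only. This
back-infers the published behaviour: a ±10% swing moves the simultaneous
ICER by roughly ∓12%/+12%, implying the varied quantity is the full
bilateral acquisition (~2 devices + surgery), not the second device alone.

## Synthetic inputs: what they emulate, what they do not

**Life table.** The mortality source is a national statistics table that is
not reproduced. The package generates a Gompertz–Makeham table,
`qx(age) = 1 - exp(-(A + B·c^age))` with `A = 0.0002`, `c = 1.10`,
`max_age = 100`, and `B` calibrated by bisection so life expectancy at
birth (lx method) is 83.0 ± 0.05 years — the longevity of a high-income
country circa 2017. A single sex-averaged table is used and no excess
mortality is attached to deafness or surgery, matching the source model's
background-mortality-only design. Because discounting makes pre-age-55
survival dominate the results and any high-longevity table is near 1 there,
the stand-in reproduces the published QALY totals to about 1%; it does *not*
emulate the real table's age-specific detail, so results conditional on old
ages carry extra uncertainty.

**Device reliability.** The manufacturer survival data behind the failure
hazard are not reproduced; only the fitted extrapolation is published, as
"0.002911 × Nth year + 0.998749" valid from year 20 to 80. Read literally
as a probability with positive slope this exceeds 1, so the package adopts
the only reading consistent with survival data: cumulative survival
*declining* linearly, `S(t) = 0.998749 - 0.002911·t` (≈0.77 at year 80).
The packaged fixture places 19 annual points exactly on that line, which
makes the OLS fit recover the published coefficients exactly and the whole
fixture testable; it does not emulate the real curve's early-year shape
(real implant survival falls faster in year 1 than a straight line). All
brands are pooled. Extrapolated survival is floored at 0.01 so hazards stay
defined past year 80, and `S(0) = 1` by definition. Whether the published
function was applied to cumulative survival or directly to annual failure
probabilities is not stated; the cumulative reading is used and documented.

Passing tests on these fixtures therefore show that the *model logic*
reproduces the published results under faithful inputs — not that the
synthetic life table or reliability curve match the unpublished data.

## Sensitivity analyses

**One-way (tornado).** Each plan parameter is set to its low/high value
with all else at base, the cohort model is rerun for the strategy pair, and
entries are sorted by |ICER(high) − ICER(low)|. The default plan varies the
bilateral utility increment (0.015–0.06), the bilateral acquisition
multiplier (±10%) and three unit costs (±10%). Utility gain and acquisition
cost dominate the ordering, as in the published figures.

**Probabilistic.** 10,000 second-order draws: every unit cost from a gamma
and both utility base increments from a beta distribution, method-of-moments
with mean = base value and SD = CV × mean. The published text sets each
parameter's SD *equal to its mean*, so the default is CV = 1, taken
literally; because that yields extreme dispersion (exponential-shaped cost
draws), the CV is an explicit configuration field (`psa$cv_costs`,
`psa$cv_utilities`) and CV = 0 degenerates to the base case exactly.
Infeasible beta moments are truncated to 95% of the feasible SD bound with
a warning. Transition probabilities are held fixed (only "cost variables"
and "utility variables" are named as sampled). Each draw is evaluated in
cohort mode — second-order parameter uncertainty is the object of interest,
and cohort mode is the exact first-order expectation, so nested
microsimulation would only add noise.

Because state occupancy depends on neither costs nor utilities, cohort arm
results are *exactly linear* in the unit costs (through the discounted
expected resource-unit vector) and in the two utility bases (through
discounted exposure coefficients). `run_psa()` evaluates draws through this
decomposition after one cohort run per arm; a test re-evaluates a stored
draw through a full engine rerun and checks agreement to numerical
precision, so the fast path is an exact refactoring, not an approximation.

**CEAC.** For each willingness-to-pay λ, a strategy's probability of being
cost-effective is the fraction of draws in which its net monetary benefit
λ·QALY − cost is strictly highest (ties split equally) — the standard NMB
ranking, not pairwise ICER league tables.

One known consequence of the literal CV = 1 reading, verified by the test
suite: the λ at which the bimodal and simultaneous acceptability curves
cross sits meaningfully *above* the deterministic ICER (the crossing tracks
the median of the incremental cost/QALY ratio, and with exponential cost
draws and a right-skewed beta utility the median lies right of the ratio of
means). A PSA whose crossing coincides with the base-case ICER — as the
published one does — implies substantially smaller effective dispersion
than SD = mean. Users who want that behaviour should set the CVs below 1;
the package keeps the literal default and documents the discrepancy rather
than silently re-tuning it.

## Numerical choices and degenerate inputs

* Life tables must have consecutive integer ages; the terminal `qx` is
  coerced to 1 on file read (documented closure rule), and ages beyond the
  table return probability 1.
* Failure probabilities are clamped to [0, 1]; `S(t-1) = 0` returns 1.
* The device clock saturates at the horizon length (it cannot exceed the
  number of cycles anyway).
* ICERs are reported only when both increments share a sign; opposing signs
  become dominance verdicts, and a zero QALY increment leaves the ICER
  undefined rather than infinite.
* Root finding: processor-cost calibration via `uniroot` (tolerance 1e-6
  on the cost scale); life-expectancy calibration by bisection on the log
  of the Gompertz slope, stopping within 0.05 years.
* Validation is data, not exceptions: `validate_parameters()` returns a
  violation table, and both engines refuse to run unless it is empty. The
  printed bilateral utility cells are checked against `scaling × base` at
  each cell's own printed precision; the age-1 cell (0.009 vs 0.0084) is a
  documented inconsistency in the source table and is exempt, with the
  printed value used verbatim.

## Problem sizes

Cohort runs propagate an 84-cycle occupancy over (3 device states × 84
clock years). The microsimulation oracle check uses 200,000 individuals per
arm, which bounds the Monte Carlo SE of mean QALYs near 0.004 — tight
enough to detect any systematic disagreement with the cohort expectation at
3 SE. The PSA uses the published 10,000 draws. All of this runs in seconds
through the linear decomposition and vectorised engines.

## Limitations

* One-chain cost doubling is not a two-ear simulation: correlated or
  asymmetric ear outcomes cannot be represented.
* No education, productivity or hearing-level (dB) outcomes; no voluntary
  non-use of a functioning implant; no charge/cost distinction or
  inflation.
* The absolute cost level of each arm depends on a reconstructed backbone
  and processor price; only incremental quantities are meaningful.
* The synthetic life table and reliability fixture are stand-ins; see
  above for what that does and does not validate.
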