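---
title: "Modelling MRI-triage prostate cancer screening: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling MRI-triage prostate cancer screening: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mriscreen)
```

## The question the model answers

PSA-based prostate cancer screening finds lethal cancers early, but it also
finds indolent ones: cancers that would never have surfaced clinically during
the man's lifetime (overdiagnosis), and it sends many men with a positive PSA
test straight to a transrectal ultrasound-guided biopsy (TRUSGB). An
alternative pathway inserts multi-parametric MRI (mpMRI) as a triage test
after an elevated PSA and biopsies only mpMRI-positive men with an MRI-guided
biopsy (MRIGB). Because mpMRI is much more sensitive for high-grade
(Gleason ≥ 7) than for low-grade disease, the MRI pathway should detect
fewer indolent cancers, avoid many biopsies, and misclassify fewer
high-grade cancers as low grade — at the cost of missing some significant
cancers in mpMRI-negative men.

`mriscreen` is a microsimulation that quantifies this trade-off at the
population level. It simulates each man's counterfactual disease history
once and then replays it under three arms — no screening, the regular
pathway, and the MRI pathway — with every random draw shared across arms
(common random numbers), so arm differences are caused by the pathway, not
by sampling noise. All results are reported per 1000 men.

## Natural history

Disease begins with preclinical onset, modelled as a cured-fraction
Weibull: a man develops preclinical prostate cancer at all with probability
`prob`, and given onset the onset age follows a Weibull distribution
(defaults: `prob = 0.35`, shape 5, scale 75, a median onset near age 70).
The two-part form is deliberate: it lets a configuration express both "no
disease ever" and a deterministic onset age, which the analytic toy model
below exploits.

From onset the tumour occupies one of eighteen preclinical detectable
states — the cross of T stage (T1/T2/T3), Gleason category (<7, =7, >7)
and metastatic status (M0/M1). Entry is into a (T1, ·, M0) state according
to a configurable distribution; Gleason heterogeneity at onset is what
makes grade-specific test sensitivities consequential. The process is
semi-Markov with exponential clocks: in each state, every allowed
progression (one severity level up in one attribute, by default) and
clinical diagnosis compete; the earliest clock fires. Exponential sojourns
are the minimal choice given that only the state space and transitions are
specified, and they keep small models analytically solvable, which the
oracle tests use heavily. The transition graph itself is configuration
driven (`"T1_LT7_M0 -> T2_LT7_M0": rate`); the validator only requires that
every arrow strictly increases severity, which guarantees an acyclic graph
and monotone severity along every trajectory.

Two conventions matter downstream:

* The natural history is **not** truncated at the man's other-cause death
  age. Overdiagnosis is defined as screen detection of a cancer whose
  clinical diagnosis would have fallen after death (or never), so the
  counterfactual clinical-diagnosis age must be known even when it exceeds
  the death age.
* All event times live on one continuous axis, age in years from birth.
  State occupancy uses half-open intervals `[entry, next_entry)`.

Other-cause mortality comes from an annual life table whose `qx` is
mortality from causes *other than* prostate cancer (prostate-cancer death
is modelled separately; using all-cause rates would double-count). Death
ages are sampled by inverting the discrete survival curve with uniform
interpolation inside the death year; `qx = 1` at the terminal age makes
every death age finite. The packaged synthetic table is Gompertz–Makeham,
`qx(a) = 1 - exp(-(5e-4 + 3e-5 e^{0.093 a}))` over ages 0–100, with life
expectancy at birth near 79 years.

## Screening pathways

The protocol screens at ages 55 to 64 every 3 years (screens at 55, 58,
61, 64) with 80% attendance per round, drawn independently per man per
round. A man is eligible while alive and undiagnosed. PSA positivity at
the 3 ng/mL cut-off is represented as a per-state probability
(`psa_pos_prob`, increasing with stage and grade in the defaults) rather
than a continuous PSA level — no PSA growth model is specified by the
study design, and a per-state episode sensitivity is the minimal faithful
mechanism.

An attended episode detects the cancer when, in sequence:

* **Regular pathway** — PSA positive, biopsy compliance (0.90), TRUSGB
  sensitivity (0.90).
* **MRI pathway** — PSA positive, mpMRI positive at the grade-specific
  sensitivity (0.94 high / 0.74 low), biopsy compliance (0.90), MRIGB
  positive at the grade-specific sensitivity (0.91 high / 0.44 low).
  mpMRI uptake among PSA-positive men is 100%; the compliance probability
  attaches to the biopsy step in both pathways.

A negative episode has no memory. Men not screen-detected whose clinical
diagnosis precedes other-cause death present clinically; clinical
diagnosis is certain at that age, and its biopsy uses TRUSGB
characteristics in **both** pathways.

Grade misclassification only downgrades: a truly significant cancer is
recorded insignificant with probability 0.363 at TRUSGB (screen or
clinical) and 0.087 at MRIGB. A single misclassification uniform is drawn
per man and consumed by whichever biopsy records his grade. For the one
recording biopsy this is distributionally identical to a per-event draw,
and it preserves a man-level coupling property that a per-event draw would
break: moving a man's detection to an earlier screen (by raising a
sensitivity) can never re-roll his recorded grade. Detection counts by
significance use the *recorded* grade — that is what moves cancers between
the significant and insignificant rows when the two pathways'
misclassification rates differ — while treatment-relevant survival uses
the true state.

Biopsy counts follow the positive-predictive-value convention: men
biopsied = screen detections / PPV(screen) + clinical detections /
PPV(clinical), with PPVs 0.227 (regular screen), 0.58 (MRI pathway) and
0.358 (clinical). Expected counts stay fractional until the reporting
layer. Utility accounting, by contrast, uses the *simulated* biopsy
episodes (PSA-positive, mpMRI-positive where applicable, compliant),
because disutility accrues per procedure actually performed; the two
conventions are independent by design.

## Treatment and mortality

At detection a treatment — radical prostatectomy (RP), radiation therapy
(RT), active surveillance (AS) or palliative — is drawn from a
configurable distribution indexed by age band, T stage, *recorded* grade
and metastasis (M1 is always palliative). Assignment by recorded grade is
the mechanism by which misclassification causes under- or overtreatment.

Baseline survival after a clinical diagnosis is exponential with a
per-(grade, metastasis) rate — a declared configurable stand-in for a
registry-based survival model. RP and RT multiply the hazard by 0.56
(equivalently divide the survival draw by 0.56); AS and palliative change
nothing.

Screening's mortality benefit is a lead-time dependent cure probability
`c(L) = c_max (1 - e^{-λ L})` (defaults `c_max = 0.35`, `λ = 0.15`/yr):
the simplest two-parameter monotone form with `c(0) = 0`, saturating at
`c_max`. The cure draw applies only to screen-detected, non-metastatic
cancers (palliative treatment is declared ineffective, so extending cure
to M1 would be inconsistent; a config flag can toggle this). A cured man
never dies of prostate cancer. An uncured man keeps the **same** death
date and cause he would have had without screening: the per-man survival
uniform is drawn once and shared across arms, so this holds exactly,
man-by-man, and deaths averted are non-negative for every individual.

One consequence worth stating: because the mortality benefit flows only
through the cure draw, and the MRI pathway's high-grade detection
probability per attended episode (0.94 × 0.90 × 0.91 ≈ 0.77) is slightly
below the regular pathway's (0.90 × 0.90 = 0.81), the MRI arm of the
*synthetic* parameterization averts slightly fewer deaths than the regular
arm while overdiagnosing far less. In the calibrated model behind the
published comparison the two arms' mortality benefits were nearly equal.
The package asserts only the direction checks that are structural: fewer
men biopsied, fewer insignificant detections, more (recorded) significant
detections and a lower harm–benefit ratio in the MRI arm.

## Quality-of-life accounting

Each health-state event contributes `(1 - utility) × duration`, truncated
at death. Events: attended PSA tests, mpMRI scans (utility 0.96 for one
week), biopsies (TRUSGB utility 0.90 for three weeks; MRIGB carries half
the TRUSGB disutility at the same duration, i.e. utility 0.95), the
assigned treatment, and a terminal-illness state (utility 0.40, six
months) preceding every prostate-cancer death. Treatment and terminal
utilities are synthetic defaults in the style of published utility tables
for prostate-cancer states. Life-years are counted from age 0 to death —
the origin cancels in all between-arm differences, which are the reported
quantities — and QALYs are life-years minus utility loss, undiscounted.
The accounting identity `QALYs gained = LY gained − Δ utility loss` holds
exactly by construction and is asserted in the tests.

## Comparison table conventions

The comparison mirrors the published per-1000 layout: differences are
`regular − MRI` (printed as absolute values), and percent changes are
signed by `MRI − regular` with magnitude `|difference| / max(regular,
MRI) × 100` — dividing by the larger of the two values is the one
convention that reproduces every consistent published percent (−30%
biopsies from 118/396, +29.8% significant from 15.3/51.3, −43%
overdiagnosis, +2.7% deaths averted, +4% life-years). For derived-ratio
rows (harm–benefit, LY and QALYs per death averted) the published
difference and percent were computed from the ratios at their printed
precision (0.8 = 1.8 − 1.0, −44% = 0.8/1.8); `table2_from_values()`
reports full-precision values, and the printed figures are recovered by
rounding the ratios first. The published "+3%" for LY gained per death
averted does not follow any consistent convention (0.13/9.70 ≈ 1.3%) and
is excluded from the reproduced set. The percentage of significant cancers
missed in the MRI pathway is computed man-matched under common random
numbers: men whose significant cancer is screen-detected in the regular
arm but not screen-detected in the MRI arm, divided by the former.

## Sensitivity analyses

The tornado analysis reruns the paired simulation with each of the four
MRI test sensitivities at the ends of its interval (mpMRI high 0.70–0.97,
mpMRI low 0.66–0.81, MRIGB low 0.26–0.64, MRIGB high 0.87–0.94), others at
baseline, same seed, and reports the MRI-arm harm–benefit ratio at each
bound sorted by bar width. Endpoint evaluation (rather than a sweep) is
the documented reading of "varied using the confidence intervals".

The threshold analysis multiplies the low-grade sensitivities by
`(1 + δ)` (capped at 1) and the high-grade sensitivities by `(1 − δ)`
simultaneously, rerunning with the same seed at each grid point, and
interpolates the δ where QALYs gained per death averted in the MRI arm
falls to the regular arm's value. The multiplicative reading of "changed
by 14%" is forced by arithmetic: 0.94 × 0.86 = 0.81, 0.91 × 0.86 = 0.78,
0.74 × 1.14 = 0.84, 0.44 × 1.14 = 0.50 reproduce all four published
threshold sensitivities exactly, while an additive reading reproduces
none. The crossing δ itself depends on the natural-history
parameterization and is therefore not a reproduction target; only the
transformation arithmetic is.

Under this transform, man-by-man coupling guarantees that low-grade screen
detections never decrease in δ and high-grade screen detections (and the
recorded-significant count) never increase. The *aggregate* overdiagnosis
count has no parameterization-free direction: it rises with δ only where
low-grade detections dominate overdiagnosis. Under the synthetic defaults
high-grade detections dominate the MRI arm's overdiagnosis, so the
aggregate count falls with δ; the tests assert the grade-wise
decomposition, which is the structural content of the claim.

## Random-number architecture

Every source of randomness has a purpose-labelled stream whose seed is a
hash of `(master_seed, purpose)`: other-cause death, onset/progression,
attendance, PSA episodes, mpMRI, compliance, biopsy sensitivity,
misclassification, treatment, survival and cure. Per-screen purposes are
n × K uniform matrices; per-man purposes are length-n vectors. All arms
consume the same matrices, which is the entire common-random-numbers
contract: adding an arm, or evaluating arms in a different order, cannot
change any arm's draws (asserted in the tests). Derived seeds stay below
2³¹ − 1.

## The synthetic parameterization, and what the tests do (and do not) show

The natural-history rates, life table, PSA positivity, treatment mix,
baseline survival and cure curve behind the published absolute per-1000
counts were calibrated to trial and registry data that are not public.
The packaged defaults are a documented synthetic stand-in chosen once to
produce a non-degenerate screening problem: onset in about a third of
men, late-life incidence, multi-year preclinical sojourns, detections in
both grade classes, some overdiagnosis and some deaths averted at
n = 10⁵. They were not fitted to any incidence or mortality series, and
the absolute simulated counts (e.g. ~550 men biopsied per 1000 in the
regular arm) intentionally carry no claim of matching published absolute
counts. What the test suite establishes is: (a) every derived metric of
the published comparison is reproduced exactly from its printed inputs;
(b) the simulator obeys its structural invariants (determinism,
pathway-equivalence identity, monotone severity, per-man non-negative
deaths averted, QALY accounting identity, monotone sensitivity coupling);
(c) on small models with closed-form answers the full pipeline agrees
with the analytic values within 4 Monte Carlo standard errors; and (d)
the qualitative pathway comparison — fewer biopsies, fewer insignificant
and more significant detections, lower harm–benefit ratio in the MRI
arm — emerges at the base-case test characteristics. Passing tests do not
show that the synthetic world matches any real population's incidence,
nor that absolute per-1000 outcomes transfer to practice.

The analytic toy model (`analytic_toy_model()`) is the oracle harness for
(c): onset fixed at age 50 in the T1/Gleason-7/M0 state, no progression,
clinical-diagnosis rate 0.05/yr, one perfect screen at 60, death uniform
in [80, 81). Detection probability `e^{-λ(s-a)}`, overdiagnosis
probability given detection `E[e^{-λ(D-s)}]`, expected lead time `1/λ`,
and expected deaths averted `c_max (P(dx > s) − P(dx > D))` are all in
closed form. The toy's survival and cure-rise rates are set to 1000/yr so
those forms are exact in the limit; the residual error (~10⁻⁴) is two
orders of magnitude below the 4-SE test tolerance at n = 10⁵.

## Numerical and degenerate-input choices

* Within-year death times are uniform on `[a, a+1)`; the life-table
  sampler and `life_expectancy()` share the convention, so Monte Carlo
  means converge to the analytic value.
* A state from which neither progression nor clinical diagnosis can fire
  is absorbing: the man is never clinically diagnosed (diagnosis age NA),
  which downstream code treats as +∞ (lead time Inf saturates the cure
  curve at `c_max`).
* `deaths averted ≤ 0` makes the harm–benefit and per-death-averted
  ratios an NA sentinel, never an error.
* Percent change with both values zero is 0; negative inputs (possible
  for noisy gained-quantities at small n) yield NA rather than a signed
  artefact.
* Ties at probability thresholds use strict `u < p` everywhere, so `p = 0`
  never fires and `p = 1` always does (u is strictly in (0, 1)).
* Simulation sizes: the published analysis simulated 10⁷ men; the default
  configuration uses 10⁵, which resolves the per-1000 outcomes to roughly
  ±0.5 and runs a paired three-arm comparison in a couple of seconds. The
  test suite uses 2×10⁴–10⁵ depending on how sharp the assertion is.

## Known limitations

* No PSA growth model: episode sensitivity is per-state, so a man's PSA
  results are independent across screens given his state.
* No costs and no probabilistic sensitivity analysis (both explicitly out
  of scope for the comparison this package reproduces).
* The cure mechanism is the only mortality channel for screening; the
  treatment hazard ratio shapes the shared counterfactual death date, not
  the screen-vs-no-screen contrast.
* Detection counts accumulate over the whole lifetime (screen plus
  interval/clinical cancers), matching the published table's inclusion of
  interval cancers; a screening-window-only accounting would need a
  different definition.
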