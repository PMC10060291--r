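---
title: "Methods: claims-based LOT derivation and cost attribution for multiple myeloma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based LOT derivation and cost attribution for multiple myeloma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmlot)
```

## The problem

Administrative claims record reimbursements, not clinical decisions. For a
disease like multiple myeloma (MM) — incurable, treated in successive
lines of therapy (LOTs) whose composition and cost change with each
relapse — any burden analysis must therefore *reconstruct* both the
cohort (who is an incident, actively treated patient?) and the treatment
history (which dispensings form which line?) from dated claim streams.
`mmlot` implements that reconstruction and the downstream health care
resource utilisation (HCRU) and cost accounting as separately testable
stages, together with a synthetic claims generator that retains ground
truth so each stage can be scored exactly.

## Cohort model

A patient enters the cohort when:

* **Diagnosis is confirmed**: at least 2 hospital-stay MM diagnosis
  records (ICD-10 C90 or any C90.x, in primary, related or associated
  position), or at least 1 hospital-stay record plus a long-term-disease
  MM registration. Two hospital records on the same admission date count
  as one stay: requiring *distinct* stays is a deliberate reading of the
  two-record rule (the alternative is not stated anywhere) and is the
  conservative choice against coding duplication.
* **Index date** = earliest MM diagnosis inside the inclusion window
  (default 2013-01-01..2018-12-31, both ends inclusive).
* **Eligibility rules**, evaluated in a fixed order so that the first
  failed rule is reported and exclusion reasons partition the excluded
  set: age (see below); general-scheme affiliation (a boolean patient
  attribute — no attempt to model the French scheme taxonomy); at least
  365 days of observable history before index; no MM record in the 365
  days before index (washout: the cohort is incident); no other
  malignancy — ICD-10 C00–C97 minus C90 minus C44 (non-melanoma skin
  cancer) — in the 5 years before index; and at least one MM-indicated
  drug dispensing in `[index, index + 30]`, day 30 inclusive. The
  treatment rule distinguishes `untreated` (no MM drug ever after index)
  from `late_treatment` (first MM drug after day 30) because both strata
  appear separately in attrition reporting.

**The age boundary.** "Older than 18 years" is read literally: at least
19 completed years at index (`age_rule = "gt18"`). Completed years are
approximated as index year minus birth year, because claims carry birth
year only. A config switch (`age_rule = "ge18"`) implements the more
common ≥ 18 reading; the choice moves virtually no patients in an MM
cohort (median age near 70).

**Follow-up** runs from index to the earliest of death, the start of the
first claim-free gap of ≥ 365 days (end = last claim date before the
gap), or the administrative study end. A gap end is classed
`disenrollment` when an explicit coverage-termination date exists on the
patient record and `lost_to_follow_up` otherwise; the two categories are
reported separately even though the same gap rule triggers both. Months
are days / 30.4375 (the calendar-mean month) and person-years are
days / 365.25; both constants are fixed package-wide so PPPM × 12 = PPPY
identically on full-window fixtures.

**Charlson comorbidity index** sums the weights of distinct conditions
recorded in `[index − 365, index]` under a configurable ICD-10 prefix
map; the default is the standard claims-adapted mapping with classical
weights. MM itself maps to the malignancy condition (weight 2), so the
cohort minimum is 2 — a useful sanity floor for any MM cohort table.

## The LOT algorithm

Parameters (`lot_params()`): regimen window 28 days, discontinuation gap
90 days, overlap criterion 40 days, per-drug grace periods from the drug
catalogue (42 days for oral community/retrocession drugs, 49 for
injectable hospital drugs — proxies for the usual duration of one full
prescription; every test pins explicit values).

1. Line 1 starts at the first dispensing of a non-exempt, MM-indicated
   drug. All non-exempt drugs first dispensed within the regimen window
   belong to the regimen.
2. A non-exempt drug first appearing after the window ends the line the
   day before and starts the next line at its dispensing date. The
   previous regimen's drugs carry into the new regimen when their
   exposure (last dispensing + grace) extends at least `overlap_days`
   past the new start, or when they are re-dispensed inside the new
   line's window: a backbone still being dispensed makes the event an
   add-on combination, a stopping backbone makes it a switch. The
   overlap semantics are isolated behind `lot_params()` because the
   algorithm family this follows states the criterion without a full
   operational definition; alternative readings are testable by
   parameter.
3. Discontinuation: when no regimen drug is dispensed for at least
   `gap_days` after the latest exposure end, the line ends on the date
   the grace period ended, and the next dispensing opens the next line.
   The gap is measured as `next dispensing date − exposure end`.
4. Lines truncated by the end of follow-up are `censored`; a trailing
   line whose post-exposure gap cannot be observed for the full
   `gap_days` is also censored rather than declared discontinued.
5. Corticosteroids (`lot_exempt` in the catalogue) never open, join or
   end lines. Patients with only exempt or unobservable drugs get zero
   lines — the "undetermined LOT" stratum. Partially observable drugs
   (oral melphalan, cyclophosphamide) participate by default; a switch
   excludes them, mirroring the known risk that their invisible IV forms
   oversegment lines.
6. Ties: two new drugs first dispensed the same day join the same new
   regimen. A line ended by the new-drug rule ends the day *before* the
   new start so intervals never overlap (the alternative — ending on the
   start date — is not stated anywhere and would double-count one day).

The test suite checks the scanner against an independent brute-force
segmenter that enumerates every boundary placement and keeps those
consistent with the three rules; on random and exhaustive streams the
two must agree exactly, and exactly one placement may survive.

**Durations.** Each line's duration is reported descriptively (completed
lines only) and by Kaplan–Meier with censoring at end of follow-up, loss
to follow-up, or death. The KM median is the first time the survival
curve reaches 0.5 or below; with all observations censored it is "not
reached" (`NA`). The product-limit computation is delegated to
`survival::survfit` and validated against hand-computed curves; with no
censoring it must equal the empirical survivor function.

## Cost model

Every claim of a cohort patient inside follow-up becomes one ledger row
with exactly one of 16 HCRU categories (5 hospitalisation types from the
stay type, 4 drug classes from the dispensing setting class, 7
outpatient categories). Costs are annualised by a year → multiplier
price index; the default maps every year to 1 because actual deflators
are jurisdiction data, not package constants. Negative costs are
rejected.

Rates: PPPY divides a stratum's summed quantity by the stratum's summed
person-years *including non-users*; PPPM divides summed costs by summed
person-months; first-year variants truncate both numerator and
denominator to each patient's first 365 days (including patients who die
before month 12 with their shortened window — implied by the PPPM
definition).

**Attribution flags** (monotone: treatment-administration ⊂ MM-related):

* *MM treatment administration*: dispensings of MM-indicated drugs in
  any setting class; chemotherapy-session stays whose main diagnosis is
  a chemotherapy-session code with an MM related diagnosis (entire stay
  cost); transport dated on or one day after such a stay or dispensing
  (the linkage window is configurable — no source defines it); sick
  leave starting within 7 days after MM treatment or such a stay.
* *MM-related* adds stays with primary or associated MM diagnosis, home
  hospitalisation with any MM diagnosis, and rehabilitation stays
  admitted within one day of an MM-related discharge ("directly
  following", configurable). Outpatient laboratory tests, procedures,
  physician and paramedic visits and devices are never MM-related by
  definition.
* *Events of interest*: one event per stay whose *primary* diagnosis is
  on the configured AE list; associated-position codes never count.

**By-line attribution** assigns each ledger row to the line whose
interval contains its date; rows between lines attach to the preceding
line (a line's aftermath — e.g. sick leave — belongs to it; the
alternative `drop` policy is a config switch). For by-line first-year
monthly rates the denominator is the person-time spent *in that line*
within the first year; for SCT/total strata it is the full first-year
person-time. The share of MM treatment in total cost uses the stratum's
own total as denominator (the other reading — the overall total — is
noted as ambiguous and not implemented).

## The synthetic world

`sim_config()` states the generated world once; its defaults are the
conditions a French incident-MM claims cohort of 2013–2018 would
plausibly show, and they are *illustrative*, not estimates — the only
published anchors are marginal summaries (cohort mix, age by transplant
stratum, line-count distribution), which the defaults adopt where they
exist:

* 30% of patients in the stem-cell-transplantation (SCT) stratum; ages
  N(58, 8.1) / N(73.5, 9.7) by stratum; 52% male.
* Line counts with probabilities 0.029 / 0.398 / 0.277 / 0.142 / 0.063 /
  0.091 over {0 (undetermined), 1, 2, 3, 4, 5+}; line-1 regimens 97%
  bortezomib-based, later lines from a wider menu.
* Per-line median durations 200/150/120/90/60 days (lognormal,
  sdlog 0.55); dispensing cadence one claim per drug per 28-day cycle,
  which keeps intra-line gaps below every grace period.
* Inter-line gaps uniform on 140–260 days — always above grace + 90, so
  every true boundary is recoverable by the algorithm; per-month death
  hazards 0.005 (SCT) / 0.024 (non-SCT); 0.5% silent dropout.
* Costs are lognormal per component on plausible euro scales; no attempt
  to match actual tariffs.
* Noise: each dispensing drops independently with
  `p_missing_dispensing`; pre-index non-melanoma skin cancer records
  (which must *not* exclude) appear with `p_benign_skin_history`.
  Exclusion-worthy histories are injected separately by
  `inject_protocol_violations()`, which also updates the ground truth —
  keeping "verdicts equal truth at zero noise" a well-defined invariant.

What the generator does **not** emulate: regional epidemiology and
incidence trends, tariff schedules, miscoding of diagnoses, partially
observable hospital IV administrations, care pathways outside MM, and
regimen changes *without* an intervening gap (true boundaries are
gap-separated by construction). A green recovery test therefore
establishes that the engine inverts the generator's stated world — it
says nothing about regimen-switch boundaries tighter than the grace
period, which are exercised by the brute-force-oracle suite instead, nor
about real-world coding noise.

Determinism: each generator stage (trajectories, treatment claims,
background care, noise) draws from its own stream seeded from the master
seed, so identical `(config, seed)` gives byte-identical CSVs and
partial regeneration leaves untouched tables stable.

## Numerical and reporting conventions

* Dates are ISO-8601 throughout; all interval rules state both
  boundaries (windows written `[a, b]` are closed).
* Currency stays in full-precision euros in every computed table;
  rounding to the published precision (two decimals for K€/M€ cells, one
  for percentages) happens only in the `render_*` functions.
* Degenerate inputs: empty cohorts give typed empty tables (N = 0), zero
  person-time gives `NA` rates, an all-censored KM gives a not-reached
  median, and unknown ATC or category codes fail loudly with the
  offending code.

## Known limitations

* The two-record confirmation cannot distinguish true MM from persistent
  miscoding; the washout cannot see records before the history start.
* The overlap rule's placement is one of several defensible readings of
  the published algorithm family; it is parameter-isolated but a
  different reading changes regimen composition at switches (not line
  counts or boundaries).
* Sick-leave/transport linkage windows and the rehab adjacency window
  are conventions, not sourced values.
* The SCT code lists and event-of-interest lists shipped as defaults are
  synthetic stand-ins; real deployments must supply jurisdictional
  lists via `mmlot_config()`.
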