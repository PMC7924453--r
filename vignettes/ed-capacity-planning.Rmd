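---
title: "Modelling emergency-department patient flow and sizing capacity by designed experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling emergency-department patient flow and sizing capacity by designed experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edflow)
```

## The model

`edflow` simulates one week of patient flow through a Canadian-style
emergency department (ED) as a discrete-event system.  Patients arrive by a
nonhomogeneous Poisson process whose rate surface is indexed by weekday,
two-hour bin and CTAS acuity level (I resuscitation ... V non-urgent), and
repeats weekly.  Each patient carries a treatment category (fourteen
categories, from general/minor issues to substance misuse) drawn from the
packaged category mix, and an arrival mode: walk-ins are triaged and
registered, ambulance arrivals take the EHS call/triage tasks and skip
registration.

After triage, CTAS I–III patients occupy a bed in the bed area (BA) —
mental-health and substance-misuse patients target the mental-health bed
area (MBA) first and overflow to BA — while CTAS IV–V sit in the vertical
area (VA).  In the bed a fixed task chain runs: nurse assessment (duration
conditional on acuity), physician assessment, order writing; then any
ordered exams (seven exam types with per-category, per-acuity-group
probabilities; imaging requires porter escorts, plus a nurse for CTAS I,
and a result turnaround; lab samples are taken at the bedside), a review of
all results, an optional specialist consult (per-category probabilities,
response delays and availability windows, with Internal Medicine covering
cardiology and gastroenterology off-hours, and a sickest-first queue at each
specialist), and disposition.  Discharged patients get a care plan,
instructions and preparation; admitted patients complete paperwork, wait
for a short-stay-unit (SSU) bed and are transported there, holding the SSU
bed one to three days.  A daily 07:00 huddle and physician shift-change
briefings hold whoever is free when they start.

All resources are explicit pools: seven staff roles on shift schedules
(half-open `[start, end)` blocks, midnight wrap supported), four location
pools, and one pool per specialist.  Requests are served in ascending
(priority, request order) — priority is the CTAS numeral — with no passing
within a pool, no preemption and no reneging; staff finish a task in
progress past shift end before leaving.  Nurse–physician assessments and
multi-exam workups execute sequentially, so in an uncongested system a
patient's length of stay is exactly the sum of the sampled task durations
along their path — the property the no-congestion oracle tests check.

## Time axis and statistics

Time is in minutes from Monday 00:00.  The default horizon is 8 days with
the first day as warm-up; statistics are collected from Tuesday 00:00 to the
following Tuesday, attributing patients by arrival time.  Patients present
at warm-up end are retained; per-CTAS stay metrics include only completed
patients, and patients still queued for triage at the horizon are reported
as untriaged.  Whether in-service patients should enter the stay means was
an open choice; only completed patients are counted, and the full timestamp
log is returned so the alternative is computable.

Each replication derives named substreams (arrivals, attributes, durations,
exams, consults, routing) from the master seed and replication index; every
draw is an inverse-CDF transform of substream uniforms, so identical
`(scenario, seed, replication)` triples reproduce the event trace bit for
bit, and sensitivity sweeps reuse the same seeds across arrival scales
(common random numbers).

## Parameters and defaults

Task durations (mostly triangular, e.g. triage T(4,7,10) min), exam
probabilities, consult probabilities/durations, and the two scenario presets
ship as packaged defaults and are all overridable on the scenario object:

* `scenario_ip()` — initial planning: BA 45, MBA 3, VA 10, SSU 10; historical
  staff totals (TN 3, EDN1 9, EDN2 8, physicians 12, porters 3); off-site
  specialists.
* `scenario_fp()` — final planning: BA 45, MBA 5, VA 15, SSU 30; the
  published per-shift staffing (TN 4, EDN1 9, EDN2 9, physicians 10,
  porters 7); psychiatrist, neurologist and Crisis Response on site.

Several quantities the source system does not publish are explicit,
documented assumptions with package defaults:

* ambulance fraction `p_ems = 0.15` (affects only registration skipping and
  the EHS triage tasks);
* SSU admission probability `p_admit = 0.20`, read off the 20%/80%
  disposition-duration split.  Note the implied SSU offered load at full
  demand (about 0.2 × 1,500 patients/week × 2 days mean stay ≈ 86
  bed-equivalents) exceeds even the expanded 30-bed SSU, so under this
  default the SSU remains the binding constraint of the whole flow; values
  near 0.05 reproduce a regime where 30 beds suffice.  The parameter is a
  scenario field precisely because it is the model's most influential
  unpublished number;
* exam turnarounds (lab T(30,45,90), imaging T(20,30,60) min) and the DI
  transport leg (escort T(0.5,1,2) each way) — calibration knobs;
* nurse assessment for CTAS I = 15 min (same as CTAS II, which is the
  sickest level with a printed value);
* IP per-shift staffing splits (only totals are published): the low-level
  design vectors where the totals match, a (4,2,2,4) physician split, one
  porter per historical porter shift;
* Registration and ward-clerk (Admin) staffing: one each around the clock.

The category mix is renormalised from printed shares summing to 99.8%.
Briefings hold only the staff free at their start — a request for the full
scheduled headcount could outlive the shift able to grant it and
permanently block the pool — so busy staff finish their task and skip the
briefing.

## The synthetic arrival generator

The study's measured arrival-rate table is file-based input
(`read_rate_table()`, CSV columns `weekday, bin_start, ctas, rate`).  When
no file is supplied, `ed_profile_spec()` builds a separable synthetic
surface `rate[d, b, c] = total × weekday[d] × diurnal[b] × ctas[c]` with
weekly total 1,504, Tuesday–Thursday weighted 1.2× the Monday/Friday level
and weekends 0.8×, a smooth unimodal diurnal shape climbing from 08:00 to a
10:00–12:00 peak with an overnight trough, and a CTAS mix of
(0.02, 0.13, 0.40, 0.35, 0.10) dominated by levels III–IV.  The generator
reproduces the weekly totals, peak location, day ordering and acuity
dominance of the measured data but not its cell-level texture (bin-to-bin
jitter, acuity-specific diurnal differences, holidays or seasonality), so
passing tests demonstrate correct mechanics and faithful aggregate
structure, not cell-exact replication of the source ED.

## Validation

The test suite validates the engine against independent oracles rather than
against itself:

* a single-station M/M/c configuration of the same kernel matches the
  Erlang-C mean wait and Little's law within three Monte-Carlo standard
  errors over 20 replications;
* with infinite capacities and the full stochastic pathway, each patient's
  LOS equals the replayed sum of their sampled durations exactly;
* every packaged probability is recovered within three binomial standard
  errors at 100,000 draws;
* factorial effects match a saturated regression; the Lenth screen matches
  a literal transcription of the pseudo-standard-error recipe on 1,000
  random effect vectors, and flags a 20-SD injected effect in at least 95%
  of 200 noise repetitions;
* response-surface fits recover known quadratic surfaces, with PRESS checked
  against explicit leave-one-out refits;
* the lexicographic recommender matches brute-force grid enumeration;
* the one-sample TOST equivalence test reproduces the published
  confirmation-run conclusion from its summary statistics (n = 30, mean
  461.2, SD 20.7, benchmark 472.1, 5% margin: equivalence, p ≈ 1.1e-3 —
  the rounded inputs land a shade above the sub-0.001 value obtained from
  unrounded replicates);
* demand sensitivity at scales 1.0 → 0.1 with common random numbers gives
  nonincreasing LOS and a nondecreasing treated share;
* driving the simulator over the published 2⁴ location design and
  Lenth-screening the treated-patients response flags SSU capacity — the
  same bottleneck the source analysis reports — together with positive SSU
  main effects.

Problem sizes in the suite are chosen to keep the default run at a few
minutes: the queueing oracle uses 6,000-minute horizons, the no-congestion
oracle two simulated days, the sensitivity sweep and the end-to-end design
two and one replication per point.

## The experiment layer

`full_factorial()` builds 2^k coded designs in standard order;
`ccd_augment()` adds centre and rotatable axial points (k = 4 with seven
centre points gives the 31-run central composite design);
`estimate_effects()` uses contrast means; `lenth_screen()` implements
`s0 = 1.5·median|e|`, `PSE = 1.5·median{|e| : |e| < 2.5·s0}`,
`ME = t(1−α/2, m/3)·PSE`; `fit_rsm()` fits the full quadratic by least
squares and reports R², adjusted R² and PRESS-based predicted R²;
`recommend()` does integer grid search with lexicographic priorities
(treated patients, LOS, triage-to-bed, SSU transport) and fewest-resources
tie-breaks.  `levels_from_margin()` reproduces the ±20% level-setting rule
(floor/ceiling); the published location levels are shipped verbatim in
`ed_location_factors()` because two of the printed rows (SSU 10/20/30 and
VA's high of 15) do not follow that rule.  Staffing factors are encoded one
factor per staff group, whose two levels are entire per-shift headcount
vectors, matching the published level table; the printed physician row
(level− (3,0,2,3), level+ (6,2,1,6), high below low in the third shift) is
kept verbatim.  Axial points for staffing vectors round to the nearest
feasible integer vector.  Design replication defaults to common random
numbers across runs.  Reproducing the published *final* staffing exactly is
not attempted: it followed unspecified manual adjustments after the designed
experiments.

## Numerical choices and degenerate inputs

Events are ordered by (time, insertion sequence) in a binary heap —
simultaneous events process in insertion order.  Pool queues key on
(priority, sequence); a blocked head blocks its pool (no passing), which
preserves FIFO-within-priority and makes briefing seizes self-resolving.
Triangular sampling uses the inverse CDF.  Zero-capacity pools warn once
and queue forever (patients become untriaged at the horizon rather than
failing).  An empty event log yields zero counts and absent (`NA`) means,
not zeros.  Zero-variance equivalence samples inside the margin report the
smallest representable p-value.  A degenerate Lenth input (all effects
zero) sets a flag and declares nothing active.

## Known limitations

No preemption, staff breaks, reneging or balking; imaging and lab are
uncapacitated external services (only escorts and turnaround consume model
resources); "review tests" happens once per patient after all results; the
second-consult mechanism defaults to probability zero; specialist response
delays other than psychiatry (U[60, 360] min), neurology (15–90 min graded
by acuity) and crisis response (5 min) are zero beyond window waiting.  The
IP regime reproduces the qualitative congestion collapse of the source
system (a one-digit treated percentage is only reached under its exact
arrival table and routing constants); with the synthetic generator the IP
preset lands near 20% treated and the relative IP → FP ordering, the SSU
bottleneck and the sensitivity structure all match.
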