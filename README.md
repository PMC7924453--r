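# edflow

Discrete-event simulation of emergency-department (ED) patient flow, with a
designed-experiments layer for capacity planning.

`edflow` is for health-systems analysts who need to size an ED: how many
beds in the bed area (BA), mental-health bed area (MBA), vertical area (VA)
and short-stay unit (SSU), and how many triage nurses, ED nurses,
physicians and porters on each shift.  It simulates a week of patient flow
— nonhomogeneous Poisson arrivals by weekday × two-hour bin × CTAS acuity,
priority queueing (CTAS I first) at every resource, shift-scheduled staff,
probabilistic exam and specialist-consult pathways, discharge or admission
to a 1–3-day SSU stay — and reports KPIs with replication confidence
intervals: treated and triaged percentages, length of stay (LOS) overall
and per CTAS level, triage-to-bed and bed-to-SSU waits, and resource
utilisation.

On top of the simulator sits the experiment layer used to choose capacity:

* 2^k full factorial and central composite designs (`full_factorial()`,
  `ccd_augment()`), with effect estimation by contrast means;
* Lenth screening for unreplicated factorials:
  `s0 = 1.5·median|e|`, `PSE = 1.5·median{|e| : |e| < 2.5·s0}`,
  `ME = t(1−α/2, m/3)·PSE`;
* quadratic response-surface fits with adjusted and PRESS-based predicted
  R² (`fit_rsm()`), and lexicographic recommendations over integer factor
  grids (`recommend()`);
* the sizing heuristic `Q = t·p / 60` (`size_requirement()`), an M/M/c
  Erlang-C validation harness, arrival-scale sensitivity sweeps and a
  one-sample TOST equivalence test.

## Worked example

Simulate the final-planning configuration (45 BA / 5 MBA / 15 VA / 30 SSU,
published per-shift staffing, on-site psychiatry/neurology/crisis) under a
moderate synthetic demand of 700 patients/week:

```r
library(edflow)
scn <- scenario_fp(arrivals = ed_profile_spec(weekly_total = 700),
                   replications = 5)
sim <- ed_simulate(scn, seed = 1)
print(sim)
```

```
ED simulation: 5 replication(s), seed 1

KPI summary over 5 replication(s) (95% t-intervals)
             metric   mean     sd  lower  upper n
           arrivals  704.2  32.82  663.4  745.0 5
          completed  546.4  46.81  488.3  604.5 5
        treated_pct   77.7   6.58   69.5   85.8 5
        triaged_pct   99.9   0.13   99.8  100.1 5
           los_mean  559.7 263.88  232.1  887.4 5
 triage_to_bed_mean  232.6 242.89  -69.0  534.2 5
    bed_to_ssu_mean  767.2 234.31  476.3 1058.1 5
              ...
```

Reading: about 704 patients arrive per collected week, virtually all are
triaged, 77.7% complete treatment, and a completed patient spends 559.7
minutes in the department on average.  The wide bed-to-SSU interval is the
admission stream queueing for short-stay beds — under the default 20%
admission probability the SSU is the system's binding constraint (see the
vignette), which is exactly the lever the experiment layer is built to
study:

```r
d <- full_factorial(ed_location_factors())       # SSU/BA/MBA/VA at 2 levels
resp <- run_design(scenario_ip(), d, replications = 1, seed = 303)
lenth_screen(estimate_effects(d, resp$treated))
#> Lenth screening: PSE = 2.25  ME = 5.784 (alpha = 0.05)
#>   active: SSU, BA, MBA, VA, SSU:BA, SSU:VA
```

SSU capacity surfaces as the dominant factor for every KPI, with positive
main effect on weekly treated patients.

Scenario files are YAML (`read_rate_table()` reads measured arrival-rate
CSVs; `read_scenario()` reads full configurations — see
`inst/extdata/scenario-fp.yaml`), and `inst/cli/edsim.R` is a thin
command-line front end (`simulate`, `rates`, `sensitivity`).

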