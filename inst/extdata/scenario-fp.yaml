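# Final-planning scenario: expanded locations, published per-shift staffing,
# synthetic weekly arrival profile.
locations:
  BA: 45
  MBA: 5
  VA: 15
  SSU: 30
staffing:
  TN:
    - {start: "07:00", end: "19:00", count: 1}
    - {start: "11:00", end: "23:00", count: 1}
    - {start: "19:00", end: "07:00", count: 2}
  EDN1:
    - {start: "07:00", end: "19:00", count: 4}
    - {start: "09:00", end: "21:00", count: 2}
    - {start: "19:00", end: "07:00", count: 3}
  EDN2:
    - {start: "07:00", end: "19:00", count: 3}
    - {start: "09:00", end: "21:00", count: 1}
    - {start: "11:00", end: "23:00", count: 2}
    - {start: "19:00", end: "07:00", count: 3}
  Physician:
    - {start: "07:00", end: "19:00", count: 3}
    - {start: "09:00", end: "21:00", count: 2}
    - {start: "11:00", end: "23:00", count: 2}
    - {start: "19:00", end: "07:00", count: 3}
  Porter:
    - {start: "07:00", end: "19:00", count: 3}
    - {start: "09:00", end: "21:00", count: 1}
    - {start: "19:00", end: "07:00", count: 3}
arrivals:
  synthetic:
    weekly_total: 1504
specialists:
  preset: FP
p_ems: 0.15
p_admit: 0.2
run:
  warmup_min: 1440
  horizon_min: 11520
  replications: 30
  seed: 1
  scale: 1.0
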