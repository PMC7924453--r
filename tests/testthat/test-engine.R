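test_that("zero arrival rates produce an empty patient log", {
  scn <- freeflow_scenario(arrivals = ed_rate_table(array(0, c(7, 12, 5))),
                           horizon = 2880, warmup = 1440)
  r <- run_replication(scn, 1, seed = 1)
  expect_equal(nrow(r$patients), 0)
  k <- compute_kpis(r$patients, r$window)
  expect_equal(k$arrivals, 0)
  expect_equal(k$treated_pct, 0)
  expect_true(is.na(k$los_mean))
})

test_that("identical scenario and seed give bit-identical logs", {
  scn <- small_scenario()
  a <- run_replication(scn, 1, seed = 99)
  b <- run_replication(scn, 1, seed = 99)
  expect_identical(a$patients, b$patients)
  expect_identical(a$utilization, b$utilization)
  c1 <- run_replication(scn, 2, seed = 99)
  expect_false(identical(a$patients, c1$patients))
})

test_that("deterministic walk-in discharge path sums the task modes", {
  # collapse all stochastic durations to their modes; GMI CTAS III walk-in,
  # no exams, no consults, no admissions: LOS is the hand-summed chain
  # triage 7 + register 3 + escort 1 + nurse 10 + physician 12 + orders 4 +
  # disposition 3 + care plan 4 + instruction 5 + preparation 2 = 51
  scn <- freeflow_scenario(tasks = collapse_tasks(ed_tasks()),
                           transport_leg = dist_const(1),
                           p_admit = 0, horizon = 2880, warmup = 0)
  r <- run_replication(scn, 1, seed = 4)
  done <- r$patients[r$patients$outcome == "discharged", ]
  expect_gt(nrow(done), 10)
  expect_equal(done$departure - done$arrival_min, rep(51, nrow(done)))
  expect_equal(done$path_min, rep(51, nrow(done)))
})

test_that("deterministic admission path includes paperwork and transport", {
  # disposition 30 + care plan 10 + admission form 2 + transport 20 replace
  # the discharge tail: 7+3+1+10+12+4+30+10+2+20 = 99
  scn <- freeflow_scenario(tasks = collapse_tasks(ed_tasks()),
                           p_admit = 1, horizon = 2880, warmup = 0)
  r <- run_replication(scn, 1, seed = 4)
  adm <- r$patients[r$patients$outcome == "admitted_ssu", ]
  expect_gt(nrow(adm), 10)
  expect_equal(adm$departure - adm$arrival_min, rep(99, nrow(adm)))
  expect_true(all(adm$ssu_transfer - adm$ssu_request >= 0))
})

test_that("ambulance arrivals take EHS triage and skip registration", {
  scn <- freeflow_scenario(tasks = collapse_tasks(ed_tasks()),
                           p_ems = 1, p_admit = 0,
                           horizon = 2880, warmup = 0)
  r <- run_replication(scn, 1, seed = 4)
  done <- r$patients[r$patients$outcome == "discharged", ]
  expect_gt(nrow(done), 10)
  # EHS call 1 + EHS triage 7 replace triage 7 + registration 3
  expect_equal(done$departure - done$arrival_min, rep(49, nrow(done)))
})

test_that("every arrival is conserved across outcomes", {
  scn <- small_scenario()
  r <- run_replication(scn, 1, seed = 5)
  k <- compute_kpis(r$patients, r$window)
  expect_equal(k$arrivals, k$completed + k$in_system + k$untriaged)
  expect_true(all(r$patients$outcome %in%
                    c("discharged", "admitted_ssu", "in_system", "untriaged")))
  expect_equal(anyDuplicated(r$patients$patient_id), 0)
})

test_that("timestamp trails are monotone wherever defined", {
  scn <- small_scenario()
  r <- run_replication(scn, 1, seed = 6)
  p <- r$patients
  steps <- list(c("arrival_min", "triage_end"),
                c("triage_end", "bed_assigned"),
                c("bed_assigned", "first_physician"),
                c("first_physician", "disposition_time"),
                c("disposition_time", "departure"),
                c("ssu_request", "ssu_transfer"))
  for (s in steps) {
    ok <- !is.na(p[[s[1]]]) & !is.na(p[[s[2]]])
    expect_true(all(p[[s[2]]][ok] >= p[[s[1]]][ok] - 1e-9),
                label = paste(s[1], "<=", s[2]))
  }
})

test_that("occupancy never exceeds capacity; staff stay within schedule", {
  scn <- small_scenario()
  r <- run_replication(scn, 1, seed = 12)
  u <- r$utilization
  locs <- u[u$pool %in% c("BA", "MBA", "VA", "SSU"), ]
  expect_true(all(locs$max_busy <= locs$capacity))
  staff <- u[!u$pool %in% c("BA", "MBA", "VA", "SSU"), ]
  expect_true(all(staff$max_busy <= staff$capacity))
  expect_true(all(u$utilization >= 0 & u$utilization <= 1, na.rm = TRUE))
})

test_that("no-congestion runs have LOS equal to the sampled path time", {
  # full stochastic pathway (exams, consults, admissions) but infinite
  # capacity: departure - arrival must equal the replayed duration sum
  scn <- freeflow_scenario(p_ems = 0.15, p_admit = 0.2,
                           exam_probs = ed_exam_probs(),
                           categories = ed_categories(),
                           arrivals = ctas3_table(2),
                           horizon = 2880, warmup = 0)
  r <- run_replication(scn, 1, seed = 77)
  done <- r$patients[r$patients$outcome %in% c("discharged", "admitted_ssu"), ]
  expect_gt(nrow(done), 30)
  expect_equal(done$departure - done$arrival_min, done$path_min,
               tolerance = 1e-9)
})

test_that("untriaged patients are those still awaiting triage at horizon", {
  # one triage nurse never scheduled: nobody can be triaged
  staffing <- ed_staffing("IP")
  staffing$TN <- shift_schedule(c())
  scn <- small_scenario(staffing = staffing)
  suppressWarnings(r <- run_replication(scn, 1, seed = 3))
  expect_true(all(r$patients$outcome == "untriaged"))
  k <- compute_kpis(r$patients, r$window)
  expect_equal(k$triaged_pct, 0)
})

test_that("ed_simulate aggregates replications deterministically", {
  scn <- small_scenario(replications = 2)
  s1 <- ed_simulate(scn, seed = 21)
  s2 <- ed_simulate(scn, seed = 21)
  expect_identical(s1$summary, s2$summary)
  expect_equal(attr(s1$summary, "replications"), 2)
  expect_s3_class(s1, "ed_sim")
  expect_output(print(s1), "KPI summary")
})
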