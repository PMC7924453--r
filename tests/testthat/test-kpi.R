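mk_log <- function(...) {
  rows <- list(...)
  base <- list(patient_id = 1L, replication = 1L, arrival_min = 0,
               ctas = "III", category = "GMI", mode = "walk-in", area = "BA",
               triage_end = NA_real_, bed_assigned = NA_real_,
               first_physician = NA_real_, disposition_time = NA_real_,
               ssu_request = NA_real_, ssu_transfer = NA_real_,
               departure = NA_real_, path_min = 0, outcome = "in_system")
  do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- utils::modifyList(base, rows[[i]])
    r$patient_id <- i
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
}

test_that("KPI definitions follow the timestamp arithmetic", {
  log <- mk_log(list(arrival_min = 0, triage_end = 10, bed_assigned = 25,
                     first_physician = 40, ssu_request = 400,
                     ssu_transfer = 500, departure = 520,
                     outcome = "admitted_ssu"))
  k <- compute_kpis(log, c(0, 1000))
  expect_equal(k$los_mean, 520)
  expect_equal(k$triage_to_bed_mean, 15)
  expect_equal(k$bed_to_ssu_mean, 100)
  expect_equal(k$treated_pct, 100)
  expect_equal(k$los_by_ctas[["III"]], 520)
  expect_true(is.na(k$los_by_ctas[["I"]]))
})

test_that("triaged share counts patients who reached triage", {
  log <- mk_log(
    list(triage_end = 5, bed_assigned = 10, departure = 60,
         outcome = "discharged"),
    list(triage_end = 8, outcome = "in_system"),
    list(outcome = "untriaged"))
  k <- compute_kpis(log, c(0, 1000))
  expect_equal(k$arrivals, 3)
  expect_equal(k$triaged_pct, 66.7, tolerance = 1e-3)
  expect_equal(k$treated_pct, 100 / 3, tolerance = 1e-9)
  expect_equal(k$untriaged, 1)
  expect_equal(k$in_system, 1)
})

test_that("patients are attributed to the window by arrival time", {
  log <- mk_log(
    list(arrival_min = 100, triage_end = 110, departure = 200,
         outcome = "discharged"),                     # before window
    list(arrival_min = 1500, triage_end = 1510, departure = 1600,
         outcome = "discharged"))
  k <- compute_kpis(log, c(1440, 2000))
  expect_equal(k$arrivals, 1)
  expect_equal(k$los_mean, 100)
})

test_that("replication aggregation gives the hand-computed t-interval", {
  mk <- function(v) {
    k <- compute_kpis(mk_log(list(arrival_min = 0, triage_end = 1,
                                  departure = v, outcome = "discharged")),
                      c(0, 10000))
    k
  }
  agg <- aggregate_kpis(list(mk(10), mk(12), mk(14)))
  row <- as.data.frame(agg)[as.data.frame(agg)$metric == "los_mean", ]
  expect_equal(row$mean, 12)
  # t(0.975, 2) * sd / sqrt(3) = 4.303 * 2 / 1.732 = 4.969
  expect_equal(row$upper - row$mean, qt(0.975, 2) * 2 / sqrt(3),
               tolerance = 1e-9)
  # identical reports: zero-width interval
  agg0 <- aggregate_kpis(list(mk(10), mk(10), mk(10)))
  r0 <- as.data.frame(agg0)[as.data.frame(agg0)$metric == "los_mean", ]
  expect_equal(r0$lower, r0$upper)
  # single report: mean only
  agg1 <- aggregate_kpis(list(mk(10)))
  r1 <- as.data.frame(agg1)[as.data.frame(agg1)$metric == "los_mean", ]
  expect_true(is.na(r1$lower))
  expect_equal(r1$mean, 10)
})

test_that("aggregated means equal the mean of replication means", {
  scn <- small_scenario(replications = 3)
  sim <- ed_simulate(scn, seed = 17)
  los <- vapply(sim$kpis, function(k) k$los_mean, 0)
  row <- as.data.frame(sim$summary)
  expect_equal(row$mean[row$metric == "los_mean"], mean(los))
})

test_that("service levels score waits against acuity targets", {
  log <- mk_log(
    list(ctas = "II", triage_end = 0, first_physician = 10,
         bed_assigned = 5, departure = 100, outcome = "discharged"),
    list(ctas = "II", triage_end = 0, first_physician = 20,
         bed_assigned = 5, departure = 100, outcome = "discharged"),
    list(ctas = "V", triage_end = 0, first_physician = 121,
         bed_assigned = 5, departure = 100, outcome = "discharged"),
    list(ctas = "V", triage_end = 0, first_physician = 30,
         bed_assigned = 5, departure = 100, outcome = "discharged"))
  sl <- service_levels(compute_kpis(log, c(0, 1000)))
  expect_equal(sl$physician[["II"]], 0.5)   # 10 ok, 20 late
  expect_equal(sl$physician[["V"]], 0.5)    # 121 > 120
  # all-zero waits comply everywhere
  log0 <- mk_log(list(ctas = "I", triage_end = 0, first_physician = 0,
                      bed_assigned = 0, ssu_request = 0, ssu_transfer = 0,
                      departure = 10, outcome = "admitted_ssu"))
  sl0 <- service_levels(compute_kpis(log0, c(0, 1000)))
  expect_equal(sl0$physician[["I"]], 1)
  expect_equal(sl0$ssu, 1)
})

test_that("equivalence test follows the TOST definition", {
  # mean at benchmark, tiny spread: equivalent
  r <- equivalence_test(rnorm(30, 100, 0.01), 100, margin_pct = 5)
  expect_true(r$equivalent)
  # mean at twice the benchmark: not equivalent
  r2 <- equivalence_test(rnorm(30, 200, 1), 100, margin_pct = 5)
  expect_false(r2$equivalent)
  expect_gt(r2$p_value, 0.05)
  # zero variance inside the margin
  r3 <- equivalence_test(rep(100, 5), 101, margin_pct = 5)
  expect_true(r3$equivalent)
  expect_lt(r3$p_value, 1e-300)
})

test_that("TOST agrees with the 90% confidence-interval rule", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    x <- rnorm(n, runif(1, 90, 110), runif(1, 0.5, 15))
    bench <- 100
    res <- equivalence_test(x, bench, margin_pct = 5)
    ci <- mean(x) + c(-1, 1) * qt(0.95, n - 1) * sd(x) / sqrt(n)
    brute <- ci[1] > bench * 0.95 && ci[2] < bench * 1.05
    expect_equal(res$equivalent, brute)
  }
})
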