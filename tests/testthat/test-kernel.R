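test_that("events pop in (time, sequence) order", {
  sim <- sim_core(100)
  sim$handlers <- list(noop = function(sim, ev) NULL)
  schedule_event(sim, 5, "noop", "a")   # seq 1
  schedule_event(sim, 5, "noop", "b")   # seq 2
  schedule_event(sim, 3, "noop", "c")
  e1 <- pop_next_event(sim)
  expect_equal(e1$time, 3)
  e2 <- pop_next_event(sim)
  expect_equal(e2$data, "a")            # tie broken by insertion order
  e3 <- pop_next_event(sim)
  expect_equal(e3$data, "b")
  expect_null(pop_next_event(sim))      # empty calendar = end, not error
})

test_that("draining random events matches a sort oracle", {
  set.seed(31)
  times <- round(runif(1000, 0, 500), 3)
  sim <- sim_core(1000)
  for (t in times) schedule_event(sim, t, "noop", t)
  popped <- numeric(0)
  repeat {
    ev <- pop_next_event(sim)
    if (is.null(ev)) break
    popped <- c(popped, ev$time)
  }
  expect_identical(popped, sort(times))   # independent sort oracle
  expect_true(all(diff(popped) >= 0))
})

test_that("scheduled headcount follows half-open shift blocks with wrap", {
  # published final-planning physician row: 3/2/2/3 on the standard shifts
  ph <- shift_schedule(c("07:00-19:00" = 3, "09:00-21:00" = 2,
                         "11:00-23:00" = 2, "19:00-07:00" = 3))
  tue_noon <- 1440 + 12 * 60
  expect_equal(scheduled_headcount(ph, tue_noon), 7)   # 3 + 2 + 2 on duty
  night <- shift_schedule(c("19:00-07:00" = 2))
  expect_equal(scheduled_headcount(night, 3 * 60), 2)  # wraps midnight
  expect_equal(scheduled_headcount(night, 12 * 60), 0)
  day <- shift_schedule(c("07:00-19:00" = 3))
  expect_equal(scheduled_headcount(day, 19 * 60), 0)   # end-exclusive
  expect_equal(scheduled_headcount(day, 7 * 60), 3)    # start-inclusive
  allday <- shift_schedule(c("00:00-00:00" = 1))
  expect_equal(scheduled_headcount(allday, 1234), 1)
})

test_that("seize grants by priority then request order", {
  sim <- sim_core(100)
  granted <- character(0)
  sim$on_grant <- function(sim, req) granted <<- c(granted, req$tag)
  add_pool(sim, "bed", capacity = 1)
  seize(sim, c(bed = 1L), 3, "ctas3")    # takes the bed
  seize(sim, c(bed = 1L), 3, "ctas3b")
  seize(sim, c(bed = 1L), 1, "ctas1")
  expect_identical(granted, "ctas3")
  release(sim, c(bed = 1L))
  expect_identical(granted, c("ctas3", "ctas1"))   # priority I jumps queue
  release(sim, c(bed = 1L))
  expect_identical(granted, c("ctas3", "ctas1", "ctas3b"))
})

test_that("zero-capacity pools queue forever with a warning", {
  sim <- sim_core(100)
  granted <- 0
  sim$on_grant <- function(sim, req) granted <<- granted + 1
  add_pool(sim, "void", capacity = 0)
  expect_warning(seize(sim, c(void = 1L), 1, "x"), "never be granted")
  run_loop(sim)
  expect_equal(granted, 0)
})

test_that("random seize/release trace never exceeds capacity", {
  set.seed(77)
  sim <- sim_core(1e6)
  cap <- 3
  add_pool(sim, "p", capacity = cap)
  log <- data.frame(t = numeric(0), busy = numeric(0))
  sim$on_grant <- function(sim, req) {
    log <<- rbind(log, data.frame(t = sim$clock, busy = sim$pools$p$busy))
    schedule_event(sim, sim$clock + runif(1, 1, 20), "done", req$needs)
  }
  sim$handlers <- list(
    arrive = function(sim, ev) {
      n <- sample(1:2, 1)
      seize(sim, c(p = n), sample(1:5, 1), NULL)
      if (sim$clock < 400)
        schedule_event(sim, sim$clock + rexp(1, 0.3), "arrive", NULL)
    },
    done = function(sim, ev) {
      log <<- rbind(log, data.frame(t = sim$clock, busy = sim$pools$p$busy))
      release(sim, ev$data)
    })
  schedule_event(sim, 0, "arrive", NULL)
  run_loop(sim)
  expect_gt(nrow(log), 50)
  expect_true(all(log$busy <= cap))       # replay check over the event log
  expect_true(all(log$busy >= 0))
  expect_equal(sim$pools$p$max_busy, cap)
})

test_that("multi-pool requests hold all resources jointly", {
  sim <- sim_core(100)
  granted <- character(0)
  sim$on_grant <- function(sim, req) granted <<- c(granted, req$tag)
  add_pool(sim, "nurse", capacity = 1)
  add_pool(sim, "porter", capacity = 1)
  seize(sim, c(nurse = 1L), 2, "solo")
  seize(sim, c(nurse = 1L, porter = 1L), 1, "joint")  # blocked on nurse
  expect_identical(granted, "solo")
  expect_equal(sim$pools$porter$busy, 0L)   # not partially held
  release(sim, c(nurse = 1L))
  expect_identical(granted, c("solo", "joint"))
  expect_equal(sim$pools$porter$busy, 1L)
})

test_that("scheduled staff-minutes integrate wrap and window clipping", {
  sch <- shift_schedule(c("19:00-07:00" = 2))
  # one full day: 12 h * 2 staff
  expect_equal(scheduled_minutes(sch, 0, 1440), 1440)
  # window covering only 00:00-07:00
  expect_equal(scheduled_minutes(sch, 0, 420), 840)
})
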