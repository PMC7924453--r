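# Deterministic event-calendar kernel: a binary-heap future-event list keyed
# by (time, insertion sequence), capacity-limited resource pools (constant
# capacity for locations, shift-scheduled for staff), and priority seize /
# release with FIFO-within-priority queues and no passing.  The patient
# pathway and the M/M/c validation harness both run on this kernel.

# ---- event heap -----------------------------------------------------------

# binary min-heap ordered lexicographically by (time, sequence)
new_heap <- function() {
  h <- new.env(parent = emptyenv())
  h$time <- numeric(256)
  h$sq <- integer(256)
  h$val <- vector("list", 256)
  h$n <- 0L
  h
}

heap_push <- function(h, time, sq, val) {
  n <- h$n + 1L
  tv <- h$time; sv <- h$sq
  if (n > length(tv)) {
    tv <- c(tv, numeric(length(tv)))
    sv <- c(sv, integer(length(sv)))
    h$val <- c(h$val, vector("list", length(h$val)))
  }
  tv[n] <- time; sv[n] <- sq
  vv <- h$val; vv[[n]] <- val
  i <- n
  while (i > 1L) {
    p <- i %/% 2L
    if (tv[p] < tv[i] || (tv[p] == tv[i] && sv[p] < sv[i])) break
    tt <- tv[p]; tv[p] <- tv[i]; tv[i] <- tt
    ts <- sv[p]; sv[p] <- sv[i]; sv[i] <- ts
    tl <- vv[[p]]; vv[[p]] <- vv[[i]]; vv[[i]] <- tl
    i <- p
  }
  h$time <- tv; h$sq <- sv; h$val <- vv; h$n <- n
  invisible(h)
}

heap_pop <- function(h) {
  n <- h$n
  if (n == 0L) return(NULL)
  tv <- h$time; sv <- h$sq; vv <- h$val
  top <- vv[[1L]]
  tv[1L] <- tv[n]; sv[1L] <- sv[n]; vv[[1L]] <- vv[[n]]
  vv[n] <- list(NULL)
  n <- n - 1L
  i <- 1L
  while (TRUE) {
    l <- 2L * i; r <- l + 1L; s <- i
    if (l <= n && (tv[l] < tv[s] || (tv[l] == tv[s] && sv[l] < sv[s]))) s <- l
    if (r <= n && (tv[r] < tv[s] || (tv[r] == tv[s] && sv[r] < sv[s]))) s <- r
    if (s == i) break
    tt <- tv[s]; tv[s] <- tv[i]; tv[i] <- tt
    ts <- sv[s]; sv[s] <- sv[i]; sv[i] <- ts
    tl <- vv[[s]]; vv[[s]] <- vv[[i]]; vv[[i]] <- tl
    i <- s
  }
  h$time <- tv; h$sq <- sv; h$val <- vv; h$n <- n
  top
}

# ---- simulation core ------------------------------------------------------

#' Create a simulation core
#'
#' Low-level constructor for the event-calendar state: clock, future-event
#' heap, resource pools and the pending-request registry.  Exposed because the
#' queueing validation harness ([simulate_mmc()]) and tests drive the kernel
#' directly; model code normally goes through [run_replication()].
#'
#' @param horizon minutes; events past the horizon still in the calendar are
#'   not processed.
#' @param window length-2 numeric, the statistics collection window used for
#'   busy-time integrals.
#' @return an environment of class `ed_sim_core`.
#' @export
sim_core <- function(horizon, window = c(0, horizon)) {
  sim <- new.env(parent = emptyenv())
  sim$clock <- 0
  sim$heap <- new_heap()
  sim$seq <- 0L
  sim$pools <- list()
  sim$req <- vector("list", 1024)   # grows by doubling
  sim$req_n <- 0L
  sim$horizon <- horizon
  sim$window <- window
  sim$on_grant <- NULL     # function(sim, req) set by the model layer
  sim$handlers <- list()   # event kind -> function(sim, ev)
  class(sim) <- "ed_sim_core"
  sim
}

#' Schedule an event
#'
#' Events are processed in `(time, sequence)` lexicographic order; ties break
#' by insertion order.
#'
#' @param sim a [sim_core()].
#' @param time event time in minutes (must not precede the clock).
#' @param kind handler name registered in `sim$handlers`.
#' @param data arbitrary payload passed to the handler.
#' @export
schedule_event <- function(sim, time, kind, data = NULL) {
  stopifnot(time >= sim$clock - 1e-9)
  sim$seq <- sim$seq + 1L
  heap_push(sim$heap, time, sim$seq,
            list(time = time, seq = sim$seq, kind = kind, data = data))
  invisible(sim)
}

#' Pop the next event
#'
#' Removes and returns the calendar's minimal `(time, sequence)` event and
#' advances the clock to its time; `NULL` signals an empty calendar
#' (end of replication).
#'
#' @param sim a [sim_core()].
#' @export
pop_next_event <- function(sim) {
  ev <- heap_pop(sim$heap)
  if (is.null(ev)) return(NULL)
  stopifnot(ev$time >= sim$clock - 1e-9)  # time never decreases
  sim$clock <- ev$time
  ev
}

# ---- pools ----------------------------------------------------------------

#' Add a resource pool
#'
#' A location pool has constant capacity; a staff pool's capacity follows its
#' shift schedule (capacity-change events must be scheduled with
#' [schedule_shift_events()]).  Busy counts above a shrunken scheduled
#' headcount model staff finishing a task past shift end.
#'
#' @param sim a [sim_core()].
#' @param name pool name.
#' @param capacity fixed capacity (locations), or `NULL` for scheduled staff.
#' @param schedule a [shift_schedule()] for staff pools.
#' @export
add_pool <- function(sim, name, capacity = NULL, schedule = NULL) {
  p <- new.env(parent = emptyenv())
  p$name <- name
  p$capacity <- capacity
  p$schedule <- schedule
  if (is.null(capacity)) {        # precomputed schedule vectors (hot path)
    p$sch_start <- schedule$start
    p$sch_end <- schedule$end
    p$sch_count <- schedule$count
    p$dead <- nrow(schedule) == 0 || max(schedule$count) == 0
  } else {
    p$dead <- capacity == 0
  }
  p$busy <- 0L
  p$q_key <- numeric(64)   # preallocated; first q_n entries live
  p$q_id <- integer(64)
  p$q_n <- 0L
  p$busy_integral <- 0
  p$last_t <- 0
  p$max_busy <- 0L
  sim$pools[[name]] <- p
  invisible(p)
}

pool_capacity <- function(pool, t) {
  if (!is.null(pool$capacity)) return(pool$capacity)
  tod <- t %% 1440
  s <- pool$sch_start; e <- pool$sch_end
  active <- (e > s & tod >= s & tod < e) | (e <= s & (tod >= s | tod < e))
  sum(pool$sch_count[active])
}

# accumulate busy-minutes restricted to the collection window; overtime
# (busy staff past shift end) is clipped at the scheduled headcount so
# utilization = busy / scheduled stays in [0, 1]
pool_account <- function(sim, pool, t) {
  w <- sim$window
  lo <- max(pool$last_t, w[1]); hi <- min(t, w[2])
  if (hi > lo) {
    eff <- min(pool$busy, pool_capacity(pool, lo))
    pool$busy_integral <- pool$busy_integral + eff * (hi - lo)
  }
  pool$last_t <- t
}

#' Request resources
#'
#' Queues a request for one or more pools; grants fire when every requested
#' pool has free capacity and the request is not preceded in the scan order.
#' Waiting requests in a pool are served by ascending `(priority, sequence)` —
#' priority is the CTAS numeral for patient requests — with no passing within
#' a pool.  On grant the core calls `sim$on_grant(sim, req)`.
#'
#' @param sim a [sim_core()].
#' @param needs named integer vector: pool name -> units.
#' @param prio numeric priority (lower serves first).
#' @param tag continuation payload handed back on grant.
#' @return the request id (grants may have already fired on return).
#' @export
seize <- function(sim, needs, prio, tag) {
  # a pool that can never serve (zero capacity at all times) -> warn once
  for (nm in names(needs)) {
    p <- sim$pools[[nm]]
    if (is.null(p)) stop("no such pool: ", nm)
    if (p$dead && is.null(p$warned)) {
      warning("request for pool '", nm,
              "' can never be granted (zero capacity at all times)")
      p$warned <- TRUE
    }
  }
  sim$seq <- sim$seq + 1L
  sim$req_n <- sim$req_n + 1L
  id <- sim$req_n
  if (id > length(sim$req))
    sim$req <- c(sim$req, vector("list", length(sim$req)))
  sim$req[[id]] <- list(id = id, needs = needs, prio = prio,
                        seq = sim$seq, time = sim$clock, tag = tag)
  key <- prio * 1e9 + sim$seq
  for (nm in names(needs)) {
    p <- sim$pools[[nm]]
    n <- p$q_n + 1L
    if (n > length(p$q_key)) {
      p$q_key <- c(p$q_key, numeric(length(p$q_key)))
      p$q_id <- c(p$q_id, integer(length(p$q_id)))
    }
    p$q_key[n] <- key; p$q_id[n] <- id; p$q_n <- n
  }
  for (nm in names(needs)) pool_scan(sim, sim$pools[[nm]])
  id
}

# O(1) removal: swap the removed slot with the last live entry
queue_drop <- function(pool, i) {
  n <- pool$q_n
  if (i < n) {
    pool$q_key[i] <- pool$q_key[n]
    pool$q_id[i] <- pool$q_id[n]
  }
  pool$q_n <- n - 1L
}

# try to grant queued requests of one pool, in (priority, sequence) order;
# stop at the first request that cannot be satisfied (no passing)
pool_scan <- function(sim, pool) {
  t <- sim$clock
  repeat {
    if (pool$q_n == 0L) return(invisible())
    i <- which.min(pool$q_key[seq_len(pool$q_n)])
    id <- pool$q_id[i]
    r <- sim$req[[id]]
    if (is.null(r)) {            # already granted via another pool's scan
      queue_drop(pool, i)
      next
    }
    ok <- TRUE
    for (nm in names(r$needs)) {
      p2 <- sim$pools[[nm]]
      if (p2$busy + r$needs[[nm]] > pool_capacity(p2, t)) { ok <- FALSE; break }
    }
    if (!ok) return(invisible())
    # grant: NULL the registry slot (keeps list length stable)
    sim$req[id] <- list(NULL)
    for (nm in names(r$needs)) {
      p2 <- sim$pools[[nm]]
      pool_account(sim, p2, t)
      p2$busy <- p2$busy + r$needs[[nm]]
      if (p2$busy > p2$max_busy) p2$max_busy <- p2$busy
      j <- match(id, p2$q_id[seq_len(p2$q_n)])
      if (!is.na(j)) queue_drop(p2, j)
    }
    r$grant_time <- t
    sim$on_grant(sim, r)
  }
}

#' Release resources
#'
#' Returns units to their pools and wakes each pool's queue.
#'
#' @param sim a [sim_core()].
#' @param needs named integer vector: pool name -> units.
#' @export
release <- function(sim, needs) {
  t <- sim$clock
  for (nm in names(needs)) {
    p <- sim$pools[[nm]]
    pool_account(sim, p, t)
    p$busy <- p$busy - needs[[nm]]
    stopifnot(p$busy >= 0L)
  }
  for (nm in names(needs)) pool_scan(sim, sim$pools[[nm]])
  invisible(sim)
}

#' Schedule capacity-change wakeups for a staff pool
#'
#' Emits a `"shift"` event at every block boundary of the pool's schedule over
#' the horizon so queued requests are re-examined when headcount rises and
#' busy-time accounting stays exact across boundaries.
#'
#' @param sim a [sim_core()].
#' @param pool a staff pool (as returned by [add_pool()]).
#' @export
schedule_shift_events <- function(sim, pool) {
  sch <- pool$schedule
  if (is.null(sch) || nrow(sch) == 0) return(invisible())
  bounds <- sort(unique(c(sch$start, sch$end)))
  days <- seq(0, sim$horizon, by = 1440)
  for (d in days) for (b in bounds) {
    t <- d + b
    if (t <= sim$horizon && t > 0)
      schedule_event(sim, t, "shift", pool$name)
  }
  invisible(sim)
}

#' Run the event loop
#'
#' Processes events in `(time, sequence)` order until the calendar empties or
#' the horizon is passed.  Handlers are looked up in `sim$handlers` by event
#' kind; the built-in `"shift"` kind re-scans the named pool's queue.
#'
#' @param sim a [sim_core()].
#' @export
run_loop <- function(sim) {
  if (is.null(sim$handlers[["shift"]]))
    sim$handlers$shift <- function(sim, ev) {
      p <- sim$pools[[ev$data]]
      pool_account(sim, p, sim$clock)
      pool_scan(sim, p)
    }
  repeat {
    ev <- pop_next_event(sim)
    if (is.null(ev) || ev$time > sim$horizon) break
    h <- sim$handlers[[ev$kind]]
    if (is.null(h)) stop("no handler for event kind: ", ev$kind)
    h(sim, ev)
  }
  for (p in sim$pools) pool_account(sim, p, min(sim$clock, sim$window[2]))
  invisible(sim)
}

# scheduled staff-minutes of a schedule over [w1, w2)
scheduled_minutes <- function(schedule, w1, w2) {
  if (is.null(schedule) || nrow(schedule) == 0) return(0)
  total <- 0
  for (i in seq_len(nrow(schedule))) {
    s <- schedule$start[i]; e <- schedule$end[i]; cnt <- schedule$count[i]
    dur <- if (e > s) e - s else 1440 - s + e      # wrap
    if (e == s) dur <- 1440                        # 24 h block
    per_day <- dur * cnt
    # integrate day by day (windows here are whole days in practice)
    for (d in seq(floor(w1 / 1440) * 1440, w2 - 1, by = 1440)) {
      if (e > s) {
        lo <- max(w1, d + s); hi <- min(w2, d + e)
        if (hi > lo) total <- total + (hi - lo) * cnt
      } else {
        lo <- max(w1, d + s); hi <- min(w2, d + 1440)
        if (hi > lo) total <- total + (hi - lo) * cnt
        lo <- max(w1, d); hi <- min(w2, d + e)
        if (e > 0 && hi > lo) total <- total + (hi - lo) * cnt
      }
    }
  }
  total
}
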