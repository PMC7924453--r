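# Queueing validation harness: a single-station M/M/c model driven through
# the same event-calendar kernel as the ED pathway, plus the Erlang-C
# analytic benchmark.  Used to validate the kernel's queue discipline,
# clock and resource accounting against closed-form theory.

#' Erlang-C mean waiting time
#'
#' Analytic expected wait in queue for an M/M/c station.
#'
#' @param lambda arrival rate (per minute).
#' @param mu per-server service rate (per minute).
#' @param servers number of servers `c`.
#' @return list with `p_wait` (probability of queueing), `wq` (mean wait in
#'   queue, minutes), `lq`, and `l` (mean number in system).
#' @export
erlang_c <- function(lambda, mu, servers) {
  a <- lambda / mu
  rho <- a / servers
  stopifnot(rho < 1)
  k <- 0:(servers - 1)
  p0 <- 1 / (sum(a^k / factorial(k)) +
               a^servers / (factorial(servers) * (1 - rho)))
  p_wait <- a^servers / (factorial(servers) * (1 - rho)) * p0
  wq <- p_wait / (servers * mu - lambda)
  list(p_wait = p_wait, wq = wq, lq = lambda * wq,
       l = lambda * (wq + 1 / mu))
}

#' Simulate a single M/M/c station on the kernel
#'
#' Exponential interarrivals and services, `servers` identical servers, FIFO.
#' Collects mean wait in queue, mean sojourn, and the time-average number in
#' system over the post-warm-up window.
#'
#' @param lambda,mu rates per minute.
#' @param servers server count.
#' @param horizon,warmup minutes.
#' @param seed master seed.
#' @param replications replication count.
#' @return data.frame, one row per replication: `wq`, `sojourn`, `l`,
#'   `arrivals` (counting customers arriving inside the window).
#' @export
simulate_mmc <- function(lambda, mu, servers, horizon = 10000, warmup = 1000,
                         seed = 1L, replications = 1L) {
  one <- function(rep) {
    sim <- sim_core(horizon, window = c(warmup, horizon))
    st <- ed_streams(seed, rep, names = c("arrivals", "service"))
    add_pool(sim, "server", capacity = servers)
    sim$arrivals <- list()      # arrival time per customer
    sim$starts <- numeric(0)
    sim$ends <- numeric(0)
    sim$arr_t <- numeric(0)
    sim$n_in <- 0L
    sim$l_integral <- 0
    sim$l_last <- warmup
    account_l <- function(sim, t) {
      lo <- max(sim$l_last, warmup); hi <- min(t, horizon)
      if (hi > lo) sim$l_integral <- sim$l_integral + sim$n_in * (hi - lo)
      sim$l_last <- t
    }
    sim$on_grant <- function(sim, req) {
      id <- req$tag
      svc <- stats::qexp(stream_runif(st$service), mu)
      sim$starts[id] <- sim$clock
      schedule_event(sim, sim$clock + svc, "done", id)
    }
    sim$handlers <- list(
      arrive = function(sim, ev) {
        account_l(sim, sim$clock)
        sim$n_in <- sim$n_in + 1L
        sim$arr_t <- c(sim$arr_t, sim$clock)
        id <- length(sim$arr_t)
        sim$starts[id] <- NA_real_
        sim$ends[id] <- NA_real_
        seize(sim, c(server = 1L), 1, id)
        gap <- stats::qexp(stream_runif(st$arrivals), lambda)
        if (sim$clock + gap <= horizon)
          schedule_event(sim, sim$clock + gap, "arrive", NULL)
      },
      done = function(sim, ev) {
        account_l(sim, sim$clock)
        sim$n_in <- sim$n_in - 1L
        sim$ends[ev$data] <- sim$clock
        release(sim, c(server = 1L))
      })
    schedule_event(sim, stats::qexp(stream_runif(st$arrivals), lambda),
                   "arrive", NULL)
    run_loop(sim)
    account_l(sim, horizon)
    # per-customer waits/sojourns for customers arriving inside the window
    arr <- sim$arr_t
    inw <- arr >= warmup & !is.na(sim$starts)
    done_w <- inw & !is.na(sim$ends)
    data.frame(wq = mean(sim$starts[inw] - arr[inw]),
               sojourn = mean(sim$ends[done_w] - arr[done_w]),
               l = sim$l_integral / (horizon - warmup),
               arrivals = sum(arr >= warmup))
  }
  do.call(rbind, lapply(seq_len(replications), one))
}
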