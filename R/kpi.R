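# KPI layer: per-replication metrics with warm-up truncation, replication
# aggregation with Student-t intervals, CTAS service levels, arrival-scale
# sensitivity sweeps, and the one-sample TOST equivalence test.

#' Compute KPIs from one replication's event log
#'
#' Patients are attributed to the collection window by arrival time.
#' Definitions: LOS = departure - arrival (completed patients only);
#' triage-to-bed = bed/seat assignment - triage end; bed-to-SSU =
#' SSU transfer - SSU request; treated% = completed / arrivals x 100;
#' triaged% = patients with a triage end / arrivals x 100.
#'
#' @param log per-patient event log from [run_replication()].
#' @param window length-2 numeric collection window in minutes.
#' @return object of class `ed_kpi`: a named list of metrics; per-CTAS means
#'   are `NA` where no patient of that level completed.
#' @export
compute_kpis <- function(log, window) {
  d <- log[log$arrival_min >= window[1] & log$arrival_min < window[2], ,
           drop = FALSE]
  arrivals <- nrow(d)
  if (arrivals == 0) {
    out <- list(arrivals = 0L, completed = 0L, treated_pct = 0,
                triaged_pct = 0, los_mean = NA_real_,
                los_by_ctas = stats::setNames(rep(NA_real_, 5), CTAS_LEVELS),
                triage_to_bed_mean = NA_real_,
                triage_to_bed_by_ctas =
                  stats::setNames(rep(NA_real_, 5), CTAS_LEVELS),
                bed_to_ssu_mean = NA_real_,
                untriaged = 0L, in_system = 0L,
                physician_wait = NULL, window = window)
    class(out) <- "ed_kpi"
    return(out)
  }
  done <- d[d$outcome %in% c("discharged", "admitted_ssu"), , drop = FALSE]
  los <- done$departure - done$arrival_min
  t2b <- d$bed_assigned - d$triage_end
  b2s <- d$ssu_transfer - d$ssu_request
  by_ctas <- function(x, sub) {
    vapply(CTAS_LEVELS, function(l) {
      v <- x[sub$ctas == l]
      if (length(v) == 0) NA_real_ else mean(v, na.rm = TRUE)
    }, 0)
  }
  out <- list(
    arrivals = arrivals,
    completed = nrow(done),
    treated_pct = 100 * nrow(done) / arrivals,
    triaged_pct = 100 * sum(!is.na(d$triage_end)) / arrivals,
    los_mean = if (nrow(done)) mean(los) else NA_real_,
    los_by_ctas = by_ctas(los, done),
    triage_to_bed_mean = if (any(!is.na(t2b))) mean(t2b, na.rm = TRUE)
                         else NA_real_,
    triage_to_bed_by_ctas = by_ctas(t2b, d),
    bed_to_ssu_mean = if (any(!is.na(b2s))) mean(b2s, na.rm = TRUE)
                      else NA_real_,
    untriaged = sum(d$outcome == "untriaged"),
    in_system = sum(d$outcome == "in_system"),
    physician_wait = data.frame(ctas = d$ctas,
                                wait = d$first_physician - d$triage_end,
                                ssu_wait = b2s,
                                stringsAsFactors = FALSE),
    window = window)
  class(out) <- "ed_kpi"
  out
}

# metrics aggregated across replications
KPI_SCALAR <- c("arrivals", "completed", "treated_pct", "triaged_pct",
                "los_mean", "triage_to_bed_mean", "bed_to_ssu_mean")

#' Aggregate replication KPI reports
#'
#' Per metric: mean across replications, sample SD and the two-sided
#' Student-t confidence interval with `n - 1` degrees of freedom.  A single
#' replication yields means only (no interval).
#'
#' @param reports list of [compute_kpis()] reports.
#' @param alpha interval level is `1 - alpha`.
#' @return object of class `ed_kpi_summary`: a data.frame with one row per
#'   metric (including per-CTAS LOS and triage-to-bed means).
#' @export
aggregate_kpis <- function(reports, alpha = 0.05) {
  stopifnot(length(reports) >= 1)
  grab <- function(f) vapply(reports, f, 0)
  cols <- c(stats::setNames(lapply(KPI_SCALAR, function(m)
    grab(function(r) as.numeric(r[[m]]))), KPI_SCALAR))
  for (l in CTAS_LEVELS) {
    cols[[paste0("los_", l)]] <- grab(function(r) r$los_by_ctas[[l]])
    cols[[paste0("triage_to_bed_", l)]] <-
      grab(function(r) r$triage_to_bed_by_ctas[[l]])
  }
  n_reps <- length(reports)
  rows <- lapply(names(cols), function(m) {
    x <- cols[[m]][!is.na(cols[[m]])]
    n <- length(x)
    if (n == 0)
      return(data.frame(metric = m, mean = NA_real_, sd = NA_real_,
                        lower = NA_real_, upper = NA_real_, n = 0L))
    mu <- mean(x)
    if (n == 1)
      return(data.frame(metric = m, mean = mu, sd = NA_real_,
                        lower = NA_real_, upper = NA_real_, n = 1L))
    s <- stats::sd(x)
    half <- stats::qt(1 - alpha / 2, n - 1) * s / sqrt(n)
    data.frame(metric = m, mean = mu, sd = s,
               lower = mu - half, upper = mu + half, n = n)
  })
  out <- do.call(rbind, rows)
  attr(out, "replications") <- n_reps
  attr(out, "alpha") <- alpha
  class(out) <- c("ed_kpi_summary", "data.frame")
  out
}

#' @export
print.ed_kpi_summary <- function(x, digits = 1, ...) {
  cat("KPI summary over", attr(x, "replications"), "replication(s)",
      sprintf("(%d%% t-intervals)\n", round(100 * (1 - attr(x, "alpha")))))
  d <- as.data.frame(x)
  d$mean <- round(d$mean, digits); d$sd <- round(d$sd, digits + 1)
  d$lower <- round(d$lower, digits); d$upper <- round(d$upper, digits)
  print(d, row.names = FALSE)
  invisible(x)
}

#' CTAS service-level compliance
#'
#' Fraction of patients seen by a physician within their acuity target
#' (I immediate, II 15, III 30, IV 60, V 120 minutes after triage) and
#' fraction of admitted patients transferred to the short-stay unit within
#' the 180-minute target.
#'
#' @param report a [compute_kpis()] report.
#' @param targets see [ed_service_targets()].
#' @return list with `physician` (named per-CTAS fractions) and `ssu`.
#' @export
service_levels <- function(report, targets = ed_service_targets()) {
  pw <- report$physician_wait
  if (is.null(pw) || nrow(pw) == 0)
    return(list(physician = stats::setNames(rep(NA_real_, 5), CTAS_LEVELS),
                ssu = NA_real_))
  phys <- vapply(CTAS_LEVELS, function(l) {
    w <- pw$wait[pw$ctas == l & !is.na(pw$wait)]
    if (length(w) == 0) return(NA_real_)
    # "immediate" for level I is taken as within one minute
    lim <- max(targets$physician_wait[[l]], 1)
    mean(w <= lim)
  }, 0)
  sw <- pw$ssu_wait[!is.na(pw$ssu_wait)]
  list(physician = phys,
       ssu = if (length(sw)) mean(sw <= targets$ssu_transfer) else NA_real_)
}

#' Arrival-scale sensitivity sweep
#'
#' Re-simulates the scenario at a ladder of arrival-rate multipliers with
#' common random numbers (same master seed per scale) and summarises mean LOS
#' and treated percentage per scale.
#'
#' @param scenario an [ed_scenario()].
#' @param scales arrival multipliers in (0, 1].
#' @param replications per-scale replications.
#' @param seed master seed shared across scales.
#' @return data.frame with one row per scale.
#' @export
sensitivity_sweep <- function(scenario, scales = c(1, 0.75, 0.5, 0.25, 0.1),
                              replications = scenario$replications,
                              seed = scenario$seed) {
  stopifnot(all(scales > 0), all(scales <= 1))
  rows <- lapply(scales, function(s) {
    scn <- scenario
    scn$scale <- s
    sim <- ed_simulate(scn, replications = replications, seed = seed,
                       keep_patients = FALSE)
    sm <- as.data.frame(sim$summary)
    data.frame(scale = s,
               arrivals = sm$mean[sm$metric == "arrivals"],
               treated_pct = sm$mean[sm$metric == "treated_pct"],
               los_mean = sm$mean[sm$metric == "los_mean"],
               triage_to_bed = sm$mean[sm$metric == "triage_to_bed_mean"])
  })
  do.call(rbind, rows)
}

#' One-sample equivalence test (TOST)
#'
#' Two one-sided t-tests of the mean against the interval
#' `benchmark * (1 +/- margin)`.  The reported p-value is the larger of the
#' two one-sided p-values; equivalence is declared when it is below `alpha`.
#'
#' @param x sample values (length >= 2).
#' @param benchmark positive reference value.
#' @param margin_pct equivalence margin as a percentage of the benchmark.
#' @param alpha significance level.
#' @return list `p_value`, `equivalent`, `mean`, `sd`, `bounds`.
#' @export
equivalence_test <- function(x, benchmark, margin_pct = 5, alpha = 0.05) {
  stopifnot(length(x) >= 2, benchmark > 0, margin_pct > 0)
  n <- length(x)
  m <- mean(x)
  s <- stats::sd(x)
  lo <- benchmark * (1 - margin_pct / 100)
  hi <- benchmark * (1 + margin_pct / 100)
  if (s == 0) {
    inside <- m > lo && m < hi
    return(list(p_value = if (inside) .Machine$double.xmin else 1,
                equivalent = inside, mean = m, sd = s, bounds = c(lo, hi)))
  }
  se <- s / sqrt(n)
  p_lower <- stats::pt((m - lo) / se, n - 1, lower.tail = FALSE) # H0: mu <= lo
  p_upper <- stats::pt((m - hi) / se, n - 1)                     # H0: mu >= hi
  p <- max(p_lower, p_upper)
  list(p_value = p, equivalent = p < alpha, mean = m, sd = s,
       bounds = c(lo, hi))
}
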