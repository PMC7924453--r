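# Experiment-design layer: two-level full factorials, central composite
# augmentation, contrast-based effect estimation, Lenth pseudo-standard-error
# screening for unreplicated designs, quadratic response-surface fitting with
# adjusted and PRESS-based predicted R-squared, lexicographic recommendation,
# and the patients-per-hour sizing heuristic.

#' Define a design factor
#'
#' @param name factor name.
#' @param low,high natural-unit levels.  For staffing-vector factors these
#'   may be integer vectors (one headcount per shift); coded -1/+1 then maps
#'   to the whole vector.
#' @param center optional centre level (defaults to the midpoint).
#' @param kind `"location"` or `"staffing"`.
#' @return a `ed_factor` list.
#' @export
ed_factor <- function(name, low, high, center = NULL, kind = "location") {
  if (length(low) == 1 && low >= high)
    stop("degenerate factor '", name, "': low must be below high")
  if (is.null(center)) center <- (low + high) / 2
  structure(list(name = name, low = low, high = high, center = center,
                 kind = kind), class = "ed_factor")
}

#' Two-level factor bounds from a target and margin
#'
#' `low = floor(ideal * (1 - margin))`, `high = ceiling(ideal * (1 + margin))`.
#'
#' @param ideal sizing target (> 0).
#' @param margin fractional margin (default 20%), must be below 1.
#' @return length-2 integer vector `(low, high)`.
#' @export
levels_from_margin <- function(ideal, margin = 0.2) {
  stopifnot(ideal > 0)
  if (margin >= 1) stop("margin must be below 1")
  c(floor(ideal * (1 - margin)), ceiling(ideal * (1 + margin)))
}

#' Full two-level factorial design
#'
#' All `2^k` coded runs in standard order (first factor fastest).
#'
#' @param factors list of [ed_factor()]s (or bare names).
#' @return object of class `ed_design`: list with `coded` (data.frame of
#'   -1/+1 columns), `factors`, `type`.
#' @export
full_factorial <- function(factors) {
  factors <- lapply(factors, function(f)
    if (inherits(f, "ed_factor")) f else ed_factor(f, 0, 1))
  k <- length(factors)
  stopifnot(k >= 1)
  coded <- expand.grid(rep(list(c(-1, 1)), k))
  names(coded) <- vapply(factors, `[[`, "", "name")
  structure(list(coded = coded, factors = factors, type = "factorial"),
            class = "ed_design")
}

#' Augment a factorial into a central composite design
#'
#' Adds `n_center` centre runs and `2k` axial runs at distance `alpha`
#' (rotatable default `(2^k)^(1/4)`).  For `k = 4` with 7 centre points the
#' design totals 16 + 8 + 7 = 31 runs.
#'
#' @param design a factorial [full_factorial()] design.
#' @param n_center number of centre points.
#' @param axial `"rotatable"`, `"faces"` (alpha = 1), or a number.
#' @return an `ed_design` of type `"ccd"`.
#' @export
ccd_augment <- function(design, n_center = 7, axial = "rotatable") {
  stopifnot(inherits(design, "ed_design"), design$type == "factorial")
  k <- ncol(design$coded)
  if (k == 0) stop("cannot augment a zero-factor design")
  alpha <- if (identical(axial, "rotatable")) (2^k)^(1 / 4)
           else if (identical(axial, "faces")) 1
           else as.numeric(axial)
  centre <- as.data.frame(matrix(0, n_center, k))
  names(centre) <- names(design$coded)
  ax <- as.data.frame(matrix(0, 2 * k, k))
  names(ax) <- names(design$coded)
  for (j in seq_len(k)) {
    ax[2 * j - 1, j] <- -alpha
    ax[2 * j, j] <- alpha
  }
  structure(list(coded = rbind(design$coded, centre, ax),
                 factors = design$factors, type = "ccd", alpha = alpha,
                 n_center = n_center),
            class = "ed_design")
}

#' Map coded runs to natural units
#'
#' Coded -1/0/+1 (and axial) levels resolve linearly between each factor's
#' low/centre/high; staffing-vector factors interpolate per shift and round
#' to the nearest feasible integer vector.
#'
#' @param design an `ed_design`.
#' @return list of per-run natural settings (named lists).
#' @export
decode_runs <- function(design) {
  lapply(seq_len(nrow(design$coded)), function(i) {
    run <- lapply(seq_along(design$factors), function(j) {
      f <- design$factors[[j]]
      x <- design$coded[i, j]
      v <- f$center + x * (f$high - f$low) / 2
      if (f$kind == "staffing") pmax(0L, as.integer(round(v))) else v
    })
    names(run) <- names(design$coded)
    run
  })
}

#' Factorial effect estimates
#'
#' For every main effect and interaction, the contrast-mean difference
#' `mean(y | contrast = +1) - mean(y | contrast = -1)`, where interaction
#' contrasts are products of the coded factor columns.  Valid for the
#' factorial (orthogonal) portion of a design.
#'
#' @param design an `ed_design` (its factorial rows are used).
#' @param responses numeric responses, one per design row.
#' @param max_order highest interaction order to estimate (default all).
#' @return named numeric vector of effects.
#' @export
estimate_effects <- function(design, responses, max_order = NULL) {
  if (length(responses) != nrow(design$coded))
    stop("responses must match design runs one to one")
  fac_rows <- apply(abs(design$coded) == 1, 1, all)
  coded <- design$coded[fac_rows, , drop = FALSE]
  y <- responses[fac_rows]
  k <- ncol(coded)
  if (is.null(max_order)) max_order <- k
  out <- numeric(0)
  for (ord in seq_len(max_order)) {
    for (idx in utils::combn(k, ord, simplify = FALSE)) {
      contrast <- Reduce(`*`, coded[idx])
      nm <- paste(names(coded)[idx], collapse = ":")
      out[nm] <- mean(y[contrast > 0]) - mean(y[contrast < 0])
    }
  }
  out
}

#' Lenth screening of unreplicated factorial effects
#'
#' Pseudo-standard-error method: `s0 = 1.5 * median(|effects|)`;
#' `PSE = 1.5 * median(|effects| below 2.5 * s0)`; margin of error
#' `ME = t(1 - alpha/2, m/3) * PSE` with `m` the number of effects.  Effects
#' beyond the margin are declared active.
#'
#' @param effects named effect vector (length >= 3), e.g. from
#'   [estimate_effects()].
#' @param alpha significance level.
#' @return object of class `ed_lenth` with `effects`, `s0`, `pse`, `me`,
#'   `significant` (names) and a `degenerate` flag (all effects zero).
#' @export
lenth_screen <- function(effects, alpha = 0.05) {
  stopifnot(length(effects) >= 3)
  ae <- abs(effects)
  s0 <- 1.5 * stats::median(ae)
  if (s0 == 0) {
    out <- list(effects = effects, s0 = 0, pse = 0, me = 0,
                significant = character(0), degenerate = TRUE, alpha = alpha)
    class(out) <- "ed_lenth"
    return(out)
  }
  pse <- 1.5 * stats::median(ae[ae < 2.5 * s0])
  d <- length(effects) / 3
  me <- stats::qt(1 - alpha / 2, d) * pse
  out <- list(effects = effects, s0 = s0, pse = pse, me = me,
              significant = names(effects)[ae > me],
              degenerate = FALSE, alpha = alpha)
  class(out) <- "ed_lenth"
  out
}

#' @export
print.ed_lenth <- function(x, ...) {
  cat("Lenth screening: PSE =", signif(x$pse, 4),
      " ME =", signif(x$me, 4), sprintf("(alpha = %g)\n", x$alpha))
  if (x$degenerate) cat("  all effects zero (degenerate)\n")
  else if (length(x$significant))
    cat("  active:", paste(x$significant, collapse = ", "), "\n")
  else cat("  no active effects\n")
  invisible(x)
}

#' Fit a quadratic response surface
#'
#' Ordinary least squares on the full second-order model (intercept, linear,
#' two-way interactions, pure quadratics) over coded units.  Reports R^2,
#' adjusted R^2 and the PRESS-based predicted R^2 (leave-one-out, via hat
#' values).
#'
#' @param design an `ed_design` (usually a CCD).
#' @param responses numeric vector, one response per run.
#' @return object of class `ed_rsm` wrapping the `lm` fit, with
#'   `coefficients`, `r_squared`, `adj_r_squared`, `pred_r_squared` (all as
#'   fractions), and `design`.
#' @export
fit_rsm <- function(design, responses) {
  coded <- design$coded
  stopifnot(nrow(coded) == length(responses))
  k <- ncol(coded)
  p <- 1 + 2 * k + choose(k, 2)
  if (nrow(coded) <= p)
    stop("need more runs (", nrow(coded), ") than model terms (", p, ")")
  d <- as.data.frame(coded)
  vars <- names(d)
  d$.y <- responses
  sq <- paste0("I(", vars, "^2)", collapse = " + ")
  fml <- stats::as.formula(paste(".y ~ (", paste(vars, collapse = " + "),
                                 ")^2 +", sq))
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("aliased model terms: ", paste(bad, collapse = ", "))
  }
  res <- stats::residuals(fit)
  h <- stats::lm.influence(fit, do.coef = FALSE)$hat
  press <- sum((res / (1 - h))^2)
  sst <- sum((responses - mean(responses))^2)
  sse <- sum(res^2)
  n <- length(responses)
  out <- list(fit = fit,
              coefficients = stats::coef(fit),
              r_squared = 1 - sse / sst,
              adj_r_squared = 1 - (sse / (n - p)) / (sst / (n - 1)),
              pred_r_squared = 1 - press / sst,
              press = press, design = design)
  class(out) <- "ed_rsm"
  out
}

#' @export
print.ed_rsm <- function(x, ...) {
  cat("Quadratic response surface fit\n")
  cat(sprintf("  R2 = %.1f%%  adj R2 = %.1f%%  pred R2 = %.1f%%\n",
              100 * x$r_squared, 100 * x$adj_r_squared,
              100 * x$pred_r_squared))
  invisible(x)
}

#' @export
coef.ed_rsm <- function(object, ...) object$coefficients

#' @export
predict.ed_rsm <- function(object, newdata, ...) {
  stats::predict(object$fit, newdata = as.data.frame(newdata), ...)
}

#' Lexicographic factor recommendation
#'
#' Grid search over integer factor settings (coded via each factor's
#' low/centre/high mapping), optimising fitted responses in priority order:
#' later responses only break ties (to within `tol`) left by earlier ones;
#' remaining ties go to the fewest total resources.
#'
#' @param fits list of [fit_rsm()] objects, in priority order.
#' @param goals character vector, `"max"` or `"min"` per fit.
#' @param bounds named list of integer `c(lo, hi)` natural-unit bounds per
#'   factor (defaults to each factor's low..high range).
#' @param tol tie tolerance on predicted responses.
#' @return list with `settings` (named natural units), `predicted`
#'   (per-response), and the searched `grid` size.
#' @export
recommend <- function(fits, goals, bounds = NULL, tol = 1e-8) {
  stopifnot(length(fits) >= 1, length(goals) == length(fits),
            all(goals %in% c("max", "min")))
  factors <- fits[[1]]$design$factors
  nms <- vapply(factors, `[[`, "", "name")
  if (is.null(bounds))
    bounds <- stats::setNames(lapply(factors, function(f)
      c(f$low, f$high)), nms)
  grid <- expand.grid(lapply(nms, function(nm)
    seq(bounds[[nm]][1], bounds[[nm]][2])), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- nms
  if (nrow(grid) == 0) stop("empty feasible grid")
  # natural -> coded
  coded <- grid
  for (j in seq_along(factors)) {
    f <- factors[[j]]
    coded[[j]] <- (grid[[j]] - f$center) / ((f$high - f$low) / 2)
  }
  keep <- rep(TRUE, nrow(grid))
  preds <- matrix(NA_real_, nrow(grid), length(fits))
  for (i in seq_along(fits)) {
    preds[, i] <- predict(fits[[i]], coded)
    v <- preds[keep, i]
    best <- if (goals[i] == "max") max(v) else min(v)
    keep[keep] <- abs(v - best) <= tol
  }
  idx <- which(keep)
  if (length(idx) > 1)                       # fewest total resources
    idx <- idx[order(rowSums(grid[idx, , drop = FALSE]))][1]
  list(settings = unlist(grid[idx, , drop = FALSE]),
       predicted = stats::setNames(preds[idx, ], NULL),
       grid = nrow(grid))
}

#' Sizing heuristic: required units per patient-hour
#'
#' `Q = t * p / 60`: minutes a patient occupies the location or resource,
#' times patients per hour needing it, per 60 minutes.
#'
#' @param t_i mean occupation minutes per patient (>= 0).
#' @param p_i patients per hour needing the unit (>= 0).
#' @return required unit count (fractional; round up to provision).
#' @export
size_requirement <- function(t_i, p_i) {
  if (any(t_i < 0) || any(p_i < 0)) stop("t_i and p_i must be non-negative")
  t_i * p_i / 60
}

#' Packaged location design factors
#'
#' The four location factors with their published two-level (and centre)
#' settings: SSU 10/20/30, BA 45/49/53, MBA 3/4/5, VA 10/13/15.
#' @return list of [ed_factor()]s.
#' @export
ed_location_factors <- function() {
  list(ed_factor("SSU", 10, 30, center = 20),
       ed_factor("BA", 45, 53, center = 49),
       ed_factor("MBA", 3, 5, center = 4),
       ed_factor("VA", 10, 15, center = 13))
}

#' Simulate responses over a design
#'
#' Runs the simulator once per design run (location factors override the
#' scenario's capacities) with common random numbers across runs, and returns
#' the four priority-ordered responses per run: weekly treated patients, mean
#' LOS, mean triage-to-bed wait and mean bed-to-SSU wait.
#'
#' @param scenario base [ed_scenario()].
#' @param design an `ed_design` over location factors.
#' @param replications per-run replications.
#' @param seed master seed shared by all runs (common random numbers).
#' @return data.frame, one row per run: `treated`, `los`, `triage_to_bed`,
#'   `bed_to_ssu`.
#' @export
run_design <- function(scenario, design, replications = 5, seed = 1L) {
  runs <- decode_runs(design)
  rows <- lapply(runs, function(run) {
    scn <- scenario
    for (nm in names(run))
      if (nm %in% AREAS)
        scn$locations[[nm]] <- max(0L, as.integer(round(run[[nm]])))
    sim <- ed_simulate(scn, replications = replications, seed = seed,
                       keep_patients = FALSE)
    sm <- as.data.frame(sim$summary)
    g <- function(m) sm$mean[sm$metric == m]
    data.frame(treated = g("completed"), los = g("los_mean"),
               triage_to_bed = g("triage_to_bed_mean"),
               bed_to_ssu = g("bed_to_ssu_mean"))
  })
  do.call(rbind, rows)
}
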