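test_that("full factorials have 2^k orthogonal coded runs", {
  d4 <- full_factorial(ed_location_factors())
  expect_equal(nrow(d4$coded), 16)
  d3 <- full_factorial(list(ed_factor("P1", 2, 3), ed_factor("P2", 2, 3),
                            ed_factor("P3", 2, 3)))
  expect_equal(nrow(d3$coded), 8)
  d1 <- full_factorial(list(ed_factor("A", 0, 1)))
  expect_equal(sort(d1$coded[[1]]), c(-1, 1))
  # pairwise orthogonality of contrast columns
  m <- as.matrix(d4$coded)
  g <- crossprod(m)
  expect_true(all(g[upper.tri(g)] == 0))
  expect_error(ed_factor("X", 5, 5), "degenerate")
})

test_that("two-level bounds come from the 20% margin rule", {
  expect_equal(levels_from_margin(4), c(3, 5))
  expect_equal(levels_from_margin(10, 0), c(10, 10))
  expect_equal(levels_from_margin(13), c(10, 16))
  expect_error(levels_from_margin(10, 1.2), "margin")
})

test_that("central composite augmentation yields the standard run counts", {
  d4 <- ccd_augment(full_factorial(ed_location_factors()), n_center = 7)
  expect_equal(nrow(d4$coded), 31)          # 16 + 7 + 8
  expect_equal(d4$alpha, 2)                 # (2^4)^(1/4)
  d2 <- ccd_augment(full_factorial(list(ed_factor("A", 0, 2),
                                        ed_factor("B", 0, 2))), n_center = 1)
  expect_equal(nrow(d2$coded), 9)           # 4 + 1 + 4
  expect_equal(d2$alpha, sqrt(2))
  ax <- d2$coded[abs(d2$coded[[1]]) > 1 | abs(d2$coded[[2]]) > 1, ]
  expect_equal(nrow(ax), 4)
  expect_true(all(rowSums(ax != 0) == 1))   # axial rows: one nonzero
})

test_that("effects match contrast means and a regression oracle", {
  d <- full_factorial(list(ed_factor("A", 0, 1), ed_factor("B", 0, 1),
                           ed_factor("C", 0, 1)))
  y_const <- rep(5, 8)
  expect_true(all(estimate_effects(d, y_const) == 0))
  yA <- 3 * d$coded$A
  eA <- estimate_effects(d, yA)
  expect_equal(eA[["A"]], 6)
  expect_true(all(abs(eA[setdiff(names(eA), "A")]) < 1e-12))
  # random instance: effects are twice the saturated least-squares coefs
  set.seed(42)
  for (i in 1:20) {
    y <- rnorm(8)
    eff <- estimate_effects(d, y)
    fit <- lm(y ~ A * B * C, data = d$coded)
    co <- coef(fit)[-1]
    names(co) <- sub("(\\w):(\\w)", "\\1:\\2", names(co))
    expect_equal(eff[names(co)], 2 * co, tolerance = 1e-10)
  }
  expect_error(estimate_effects(d, rnorm(5)), "one to one")
})

test_that("Lenth screening reproduces the two-median construction", {
  effects <- c(1:10, 100)
  names(effects) <- paste0("e", 1:11)
  r <- lenth_screen(effects)
  expect_equal(r$s0, 1.5 * 6)          # median |effects| = 6
  expect_equal(r$pse, 1.5 * 5.5)       # trimmed set {1..10}
  expect_true("e11" %in% r$significant)
  z <- lenth_screen(setNames(rep(0, 7), paste0("z", 1:7)))
  expect_true(z$degenerate)
  expect_length(z$significant, 0)
})

test_that("Lenth matches a literal-formula oracle on random vectors", {
  lenth_oracle <- function(e, alpha = 0.05) {
    # independent transcription of the published pseudo-SE recipe
    s0 <- 1.5 * median(abs(e))
    pse <- 1.5 * median(abs(e)[abs(e) < 2.5 * s0])
    me <- qt(1 - alpha / 2, length(e) / 3) * pse
    names(e)[abs(e) > me]
  }
  set.seed(7)
  for (i in 1:1000) {
    m <- sample(c(7, 15, 31), 1)
    e <- rnorm(m, 0, sample(c(0.5, 1, 3), 1))
    if (runif(1) < 0.3) e[sample(m, 1)] <- rnorm(1, 0, 25)
    names(e) <- paste0("t", seq_len(m))
    r <- lenth_screen(e)
    expect_identical(r$significant, lenth_oracle(e))
    expect_gte(r$pse, 0)
  }
})

test_that("Lenth flags a single huge injected effect reliably", {
  set.seed(99)
  hits <- 0
  for (i in 1:200) {
    e <- rnorm(15, 0, 1)          # pure noise effects of a 2^4 design
    e[7] <- 20                    # one 20-SD effect
    names(e) <- paste0("t", 1:15)
    r <- lenth_screen(e)
    if ("t7" %in% r$significant) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})

test_that("quadratic surfaces are recovered with PRESS-based predicted R2", {
  d <- ccd_augment(full_factorial(list(ed_factor("x1", -1, 1),
                                       ed_factor("x2", -1, 1))), n_center = 3)
  x1 <- d$coded$x1; x2 <- d$coded$x2
  y_clean <- 5 + 2 * x1 - 3 * x2^2
  fit <- fit_rsm(d, y_clean)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$pred_r_squared, 1, tolerance = 1e-9)
  expect_equal(unname(coef(fit)["x1"]), 2, tolerance = 1e-9)
  expect_equal(unname(coef(fit)[["I(x2^2)"]]), -3, tolerance = 1e-9)
  # noisy recovery within 3 standard errors
  set.seed(5)
  y <- y_clean + rnorm(length(y_clean), 0, 0.3)
  fitn <- fit_rsm(d, y)
  se <- summary(fitn$fit)$coefficients[, "Std. Error"]
  expect_lt(abs(coef(fitn)[["x1"]] - 2), 3 * se[["x1"]])
  expect_lt(abs(coef(fitn)[["I(x2^2)"]] + 3), 3 * se[["I(x2^2)"]])
  # R2 >= adjusted R2 always
  for (i in 1:20) {
    yr <- rnorm(nrow(d$coded))
    f <- fit_rsm(d, yr)
    expect_gte(f$r_squared, f$adj_r_squared)
  }
  # PRESS matches explicit leave-one-out refits
  press_loo <- sum(vapply(seq_along(y), function(i) {
    dd <- as.data.frame(d$coded); dd$.y <- y
    f <- lm(.y ~ x1 + x2 + x1:x2 + I(x1^2) + I(x2^2), data = dd[-i, ])
    (y[i] - predict(f, dd[i, ]))^2
  }, 0))
  expect_equal(fitn$press, press_loo, tolerance = 1e-8)
})

test_that("lexicographic recommendation matches brute-force enumeration", {
  d <- ccd_augment(full_factorial(list(ed_factor("A", 10, 30, center = 20),
                                       ed_factor("B", 3, 5, center = 4))),
                   n_center = 3)
  # construct two known surfaces over coded units
  a <- d$coded$A; b <- d$coded$B
  y1 <- -(a - 0.5)^2 + 2          # maximise: coded optimum a = 0.5
  y2 <- (b + 0.5)^2               # minimise: coded optimum b = -0.5
  f1 <- fit_rsm(d, y1); f2 <- fit_rsm(d, y2)
  rec <- recommend(list(f1, f2), c("max", "min"))
  # brute force over the integer grid in natural units
  grid <- expand.grid(A = 10:30, B = 3:5)
  ca <- (grid$A - 20) / 10; cb <- (grid$B - 4) / 1
  p1 <- predict(f1, data.frame(A = ca, B = cb))
  p2 <- predict(f2, data.frame(A = ca, B = cb))
  best1 <- abs(p1 - max(p1)) <= 1e-8
  idx <- which(best1)[which.min(p2[best1])]
  expect_equal(unname(rec$settings), c(grid$A[idx], grid$B[idx]))
  # priority conflict: the first response decides
  recA <- recommend(list(f1), "max")
  expect_equal(unname(recA$settings["A"]), 25)  # coded 0.5 -> natural 25
})

test_that("single convex response lands on the rounded vertex", {
  d <- ccd_augment(full_factorial(list(ed_factor("S", 0, 20, center = 10))),
                   n_center = 3)
  y <- (d$coded$S - 0.37)^2       # coded vertex at 0.37 -> natural 13.7
  f <- fit_rsm(d, y)
  rec <- recommend(list(f), "min")
  expect_equal(unname(rec$settings[["S"]]), 14)
})

test_that("sizing heuristic is the patients-per-hour product", {
  expect_equal(size_requirement(60, 1), 1)
  expect_equal(size_requirement(45, 20), 15)
  expect_equal(size_requirement(2 * 45, 20), 2 * size_requirement(45, 20))
  expect_error(size_requirement(-1, 5), "non-negative")
})

test_that("staffing-vector factors decode to integer shift vectors", {
  f <- ed_factor("TN", low = c(1, 0, 1, 1), high = c(2, 1, 2, 2),
                 kind = "staffing")
  d <- full_factorial(list(f, ed_factor("VA", 10, 15)))
  runs <- decode_runs(d)
  expect_equal(runs[[1]]$TN, c(1L, 0L, 1L, 1L))   # coded -1
  hi <- runs[[which(d$coded$TN == 1)[1]]]$TN
  expect_equal(hi, c(2L, 1L, 2L, 2L))             # coded +1
})

test_that("simulated location factorial flags the SSU bottleneck", {
  # drive the simulator over the published 2^4 location design (common
  # random numbers) and Lenth-screen the weekly treated-patients response:
  # short-stay-unit capacity must surface as an active factor
  scn <- scenario_ip()
  d <- full_factorial(ed_location_factors())
  resp <- run_design(scn, d, replications = 1, seed = 303)
  expect_equal(nrow(resp), 16)
  scr_treated <- lenth_screen(estimate_effects(d, resp$treated))
  expect_true("SSU" %in% scr_treated$significant)
  scr_los <- lenth_screen(estimate_effects(d, resp$los))
  expect_true("SSU" %in% scr_los$significant)
  # more beds downstream move more patients through
  eff <- estimate_effects(d, resp$treated, max_order = 1)
  expect_gt(eff[["SSU"]], 0)
})
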