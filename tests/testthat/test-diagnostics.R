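test_that("order fitting recovers synthetic power laws", {
  dts <- c(0.1, 0.05, 0.025, 0.0125)
  expect_equal(as.numeric(fit_order(dts, 0.3 * sqrt(dts))), 0.5,
               tolerance = 1e-10)
  expect_equal(as.numeric(fit_order(dts, 2 * dts)), 1.0, tolerance = 1e-10)
  # two-point slope arithmetic: log(2) / log(4)
  expect_equal(as.numeric(fit_order(c(0.1, 0.025), c(0.1, 0.05))),
               log(2) / log(4), tolerance = 1e-12)
  # degenerate (zero) levels are excluded with a warning
  expect_warning(o <- fit_order(dts, c(0.1, 0.05, 0, 0)), "degenerate")
  expect_equal(attr(o, "excluded"), 3:4)
  w <- capture_warnings(o2 <- fit_order(dts, rep(0, 4)))
  expect_true(any(grepl("degenerate order fit", w)))
  expect_true(is.na(o2))
  expect_error(fit_order(0.1, 0.1), "pairs")
  expect_error(fit_order(c(-0.1, 0.1), c(1, 2)), "positive")
})

test_that("the coupled-level study sees first-order decay without noise", {
  p0 <- default_p(K3 = 0)
  res <- strong_error_study(p0, horizon = 5, finest_dt = 2^-9,
                            n_levels = 3L, n_paths = 1L, seed = 1L)
  expect_true(all(diff(res$dts) < 0))
  expect_true(all(res$rms_errors > 0))
  # errors shrink with dt
  expect_true(all(diff(res$rms_errors) < 0))
  # with the finest level as reference, a first-order error C*dt turns
  # into level differences C*dt_f*(2^l - 1), so the fitted slope over
  # factors 2, 4, 8 is the lsq slope of log(1, 3, 7) vs log(2, 4, 8)
  slope_137 <- coef(lm(log(c(1, 3, 7)) ~ log(c(2, 4, 8))))[[2]]
  expect_equal(res$fitted_order, slope_137, tolerance = 0.05)
  # against the exact solution the classical Euler order ~1 emerges
  ref <- ode_reference(5, p0)
  errs <- vapply(c(2^-7, 2^-8, 2^-9), function(dt) {
    mesh <- sde_mesh(0, 5, dt)
    tr <- integrate_sde(p0, mesh, sample_path(mesh, 1L))
    enorm(tr$states[mesh$n_steps + 1L, ] - ref)
  }, 0)
  o <- as.numeric(fit_order(c(2^-7, 2^-8, 2^-9), errs))
  expect_gt(o, 0.9)
  expect_lt(o, 1.1)
})

test_that("the additive-noise model fits a strong order of at least 0.5", {
  res <- strong_error_study(default_p(), horizon = 5, finest_dt = 2^-10,
                            n_levels = 3L, n_paths = 50L, seed = 2L)
  expect_gte(res$fitted_order, 0.5)
  # empirically additive-noise EM is first-order; the coupled-reference
  # design biases the 3-level slope up toward log(7)/log(4) ~ 1.4
  expect_gt(res$fitted_order, 0.8)
  expect_lt(res$fitted_order, 1.5)
  expect_equal(res$n_paths, 50L)
})

test_that("a fully degenerate model yields a flagged NA order", {
  frozen <- model_params(coeffs = linear_coefficients(0, 0, 0, 0, 0),
                         noise = noise_spec(0), x0 = c(0.5, 1))
  suppressWarnings(
    res <- strong_error_study(frozen, horizon = 5, finest_dt = 2^-8,
                              n_levels = 3L, n_paths = 2L, seed = 3L))
  expect_true(is.na(res$fitted_order))
  expect_equal(res$degenerate_levels, 1:3)
})

test_that("pullback differences decay in the lag and match the
           matrix-exponential oracle", {
  p <- default_p()
  res <- pullback_experiment(p, c(0.70, 0.10), c(0.65, 0.11),
                             t_fixed = 40, taus = c(10, 20, 40),
                             dt = 0.01, seed = 4L)
  expect_true(all(diff(res$diffs) < 0))
  expect_equal(res$epsilon, sqrt(0.05^2 + 0.01^2))
  # independent closed-form oracle
  M <- canonical_M()
  for (i in seq_along(res$taus)) {
    s <- 40 - res$taus[i]
    d0 <- enorm(oracle_expm(M * (40^2 - s^2) / 2) %*% c(0.05, -0.01))
    expect_lt(abs(res$diffs[i] - d0), 10 * res$dt)
    expect_equal(res$oracle[i], d0, tolerance = 1e-10)
  }
  # identical starts give identically zero differences
  same <- pullback_experiment(p, c(0.7, 0.1), c(0.7, 0.1),
                              t_fixed = 10, taus = c(1, 2), dt = 0.01,
                              seed = 5L)
  expect_identical(same$diffs, c(0, 0))
})

test_that("pullback differences are independent of the noise realisation", {
  p <- default_p()
  runs <- lapply(c(6L, 7L, 8L), function(s)
    pullback_experiment(p, c(0.70, 0.10), c(0.65, 0.11), t_fixed = 20,
                        taus = c(5, 10, 20), dt = 0.01, seed = s)$diffs)
  expect_equal(runs[[1]], runs[[2]], tolerance = 1e-11)
  expect_equal(runs[[1]], runs[[3]], tolerance = 1e-11)
})

test_that("pullback lags crossing time zero use the reflected path", {
  # with tau > t_fixed the start time is negative; the linear-in-time
  # coefficients make negative time anti-stable, so no monotone decay is
  # expected there -- only agreement with the matrix-exponential oracle
  res <- pullback_experiment(default_p(), c(0.70, 0.10), c(0.65, 0.11),
                             t_fixed = 2, taus = c(1, 4), dt = 0.01,
                             seed = 9L)
  expect_true(all(is.finite(res$diffs)))
  M <- canonical_M()
  for (i in seq_along(res$taus)) {
    s <- 2 - res$taus[i]
    d0 <- enorm(oracle_expm(M * (2^2 - s^2) / 2) %*% c(0.05, -0.01))
    expect_lt(abs(res$diffs[i] - d0), 10 * res$dt)
  }
})

test_that("trajectories from different starts coalesce at the rate set by
           the dominant eigenvalue", {
  p <- default_p()
  mesh <- sde_mesh(0, 40, 0.01)
  res <- trajectory_coalescence(p, list(c(0.70, 0.10), c(0.65, 0.11)),
                                mesh, seed = 10L)
  d <- res$diffs[, 1]
  n <- length(d)
  # the difference norm never grows (symmetric part of M is negative
  # definite) ...
  expect_true(all(diff(d) <= 1e-15))
  # ... and the terminal/initial ratio matches the discrete decay value
  # exp(lambda_max * 40^2 / 2) ~ 1.10e-3 (frozen from the deterministic
  # difference recursion at dt = 0.01)
  expect_equal(d[n] / d[1], 1.1046e-3, tolerance = 1e-3)
  # identical starts stay identical
  same <- trajectory_coalescence(p, list(c(0.7, 0.1), c(0.7, 0.1)),
                                 sde_mesh(0, 5, 0.01), seed = 10L)
  expect_true(all(same$diffs == 0))
  # the difference series does not depend on the seed
  res2 <- trajectory_coalescence(p, list(c(0.70, 0.10), c(0.65, 0.11)),
                                 mesh, seed = 99L)
  expect_equal(res$diffs, res2$diffs, tolerance = 1e-11)
  expect_error(trajectory_coalescence(p, list(c(1, 1)), mesh), "two")
})

test_that("ensemble summaries reduce correctly in the degenerate cases", {
  mesh <- sde_mesh(0, 2, 0.01)
  # no noise: zero variance at every time
  s0 <- ensemble_summary(default_p(K3 = 0), mesh, n_paths = 5L, seed = 1L)
  expect_true(all(s0$var_C == 0))
  expect_true(all(s0$var_N == 0))
  # a single path: the mean IS the trajectory
  p <- default_p()
  s1 <- ensemble_summary(p, mesh, n_paths = 1L, seed = 42L)
  set.seed(42)
  path <- sample_path(mesh, seed = NULL)
  traj <- integrate_sde(p, mesh, path)
  expect_equal(s1$mean_C, unname(traj$states[, "C"]))
  expect_true(all(s1$var_C == 0))
})

test_that("the ensemble mean series stays within Monte-Carlo bounds of
           the ODE mean", {
  p <- default_p()
  mesh <- sde_mesh(0, 5, 0.01)
  n_paths <- 300L
  s <- ensemble_summary(p, mesh, n_paths = n_paths, seed = 13L)
  for (tt in c(1, 3, 5)) {
    i <- which.min(abs(s$t - tt))
    ref <- ode_reference(tt, p)
    se_C <- sqrt(s$var_C[i] / n_paths)
    se_N <- sqrt(s$var_N[i] / n_paths)
    expect_lt(abs(s$mean_C[i] - ref[["C"]]), 3 * se_C + 1 * mesh$dt)
    expect_lt(abs(s$mean_N[i] - ref[["N"]]), 3 * se_N + 1 * mesh$dt)
  }
})

test_that("diagnostic results serialise to JSON", {
  res <- strong_error_study(default_p(K3 = 0), horizon = 5,
                            finest_dt = 2^-8, n_levels = 3L, n_paths = 1L,
                            seed = 1L)
  f <- tempfile(fileext = ".json")
  write_result_json(res, f)
  got <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(got$fitted_order, res$fitted_order)
  expect_equal(got$dts, res$dts)
})
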