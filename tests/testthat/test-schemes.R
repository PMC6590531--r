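test_that("one Euler-Maruyama step matches hand-evaluated arithmetic", {
  p <- default_p(K3 = 5)
  # drift and g1 vanish at t = 0; dW = 0 kills the g2 term
  expect_equal(em_step(c(0.65, 0.10), 0, 0.02, 0, p), c(0.65, 0.10))
  expect_equal(em_step(c(0.65, 0.10), 1, 0.01, 0.02, p),
               c(0.7339721, 0.1544827), tolerance = 1e-7)
  # dt = 0, dW = 0 is the identity
  expect_equal(em_step(c(0.3, 0.4), 2.5, 0, 0, p), c(0.3, 0.4))
})

test_that("the Milstein correction vanishes for additive noise and is
           exercised by a state-dependent scalar model", {
  p <- default_p()
  x <- c(0.65, 0.10)
  expect_identical(milstein_step(x, 1, 0.01, 0.02, p),
                   em_step(x, 1, 0.01, 0.02, p))
  expect_identical(milstein_step(x, 1, 0.01, 0.02, p,
                                 dB_dx = matrix(0, 2, 2)),
                   em_step(x, 1, 0.01, 0.02, p))
  # scalar multiplicative model B(x) = x at x = 1: dB/dx = 1
  expect_equal(milstein_correction(B = 1, dB_dx = 1, dW = 0.1, dt = 0.01), 0)
  expect_equal(milstein_correction(B = 1, dB_dx = 1, dW = 0.2, dt = 0.01),
               0.015)
})

test_that("integration folds the step over the mesh deterministically", {
  p <- default_p()
  mesh <- sde_mesh(0, 5, 0.01)
  path <- sample_path(mesh, seed = 17L)
  traj <- integrate_sde(p, mesh, path)
  expect_equal(nrow(traj$states), mesh$n_steps + 1L)
  expect_equal(traj$states[1, ], p$x0)
  expect_true(all(is.finite(traj$states)))
  # noise-free runs are seed-independent
  p0 <- default_p(K3 = 0)
  a <- integrate_sde(p0, mesh, sample_path(mesh, 1L))
  b <- integrate_sde(p0, mesh, sample_path(mesh, 2L))
  expect_identical(a$states, b$states)
  # mesh/path mismatch is refused
  expect_error(integrate_sde(p, sde_mesh(0, 4, 0.01), path), "mesh")
  # soft ordering violation (N < C at the start) is counted, not clipped
  expect_gt(traj$warnings$n_ordering, 0)
})

test_that("EM and Milstein trajectories are bitwise identical on a
           coupled run", {
  p <- default_p()
  mesh <- sde_mesh(0, 5, 0.01)
  path <- sample_path(mesh, seed = 23L)
  em <- integrate_sde(p, mesh, path, scheme = "em")
  mil <- integrate_sde(p, mesh, path, scheme = "milstein")
  expect_identical(em$states, mil$states)
})

test_that("blow-up aborts with the step index instead of propagating NaN", {
  stiff <- model_params(coeffs = linear_coefficients(lam_slope = 1e5,
                                                     theta_slope = 1e5))
  mesh <- sde_mesh(0, 100, 1)
  expect_error(integrate_sde(stiff, mesh, sample_path(mesh, 1L)),
               "blow-up at step")
})

test_that("the closed-form reference solves the noise-free system", {
  p <- default_p()
  expect_equal(ode_reference(0, p), p$x0)
  expect_equal(unname(ode_reference(200, p)), c(5, 7.5), tolerance = 1e-6)
  # independent high-accuracy ODE oracle
  skip_if_not_installed("deSolve")
  M <- canonical_M()
  f <- function(t, y, parms) list(t * (M %*% y + c(0, 0.05)))
  for (tt in c(1, 5, 20)) {
    sol <- deSolve::ode(y = unname(p$x0), times = c(0, tt), func = f,
                        parms = NULL, rtol = 1e-12, atol = 1e-14)
    expect_equal(unname(ode_reference(tt, p)), unname(sol[2, 2:3]),
                 tolerance = 1e-8)
  }
})

test_that("the internal 2x2 matrix exponential agrees with Matrix::expm", {
  skip_if_not_installed("Matrix")
  set.seed(19)
  for (i in 1:20) {
    A <- matrix(rnorm(4), 2, 2)
    expect_equal(diabsde:::expm_2x2(A),
                 as.matrix(Matrix::expm(Matrix::Matrix(A))),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("zero-noise EM converges to the reference at first order", {
  p0 <- default_p(K3 = 0)
  ref <- ode_reference(40, p0)
  err_at <- function(dt) {
    mesh <- sde_mesh(0, 40, dt)
    traj <- integrate_sde(p0, mesh, sample_path(mesh, 1L))
    max(abs(traj$states[mesh$n_steps + 1L, ] - ref))
  }
  e1 <- err_at(0.01)
  e2 <- err_at(0.005)
  expect_lt(e1, 10 * 0.01)
  # halving dt halves the error (first-order deterministic convergence)
  expect_gt(e2 / e1, 0.45)
  expect_lt(e2 / e1, 0.55)
})

test_that("the difference of two coupled trajectories obeys the
           noise-free recursion", {
  p <- default_p()
  mesh <- sde_mesh(0, 5, 0.01)
  path <- sample_path(mesh, seed = 11L)
  ta <- integrate_sde(model_params(x0 = c(0.70, 0.10)), mesh, path)
  tb <- integrate_sde(model_params(x0 = c(0.65, 0.11)), mesh, path)
  dser <- ta$states - tb$states
  M <- canonical_M()
  e <- c(0.05, -0.01)
  for (k in seq_len(mesh$n_steps)) {
    e <- e + mesh$dt * mesh$times[k] * drop(M %*% e)
    expect_equal(unname(dser[k + 1L, ]), e, tolerance = 1e-11)
  }
})

test_that("the ensemble mean tracks the affine-drift ODE mean", {
  p <- default_p()
  mesh <- sde_mesh(0, 5, 0.01)
  n_paths <- 400L
  set.seed(77)
  dW <- matrix(rnorm(mesh$n_steps * n_paths, 0, sqrt(mesh$dt)),
               mesh$n_steps, n_paths)
  run <- em_ensemble(p, mesh, dW)
  ref <- ode_reference(5, p)
  se_C <- sd(run$C) / sqrt(n_paths)
  se_N <- sd(run$N) / sqrt(n_paths)
  expect_lt(abs(mean(run$C) - ref[["C"]]), 3 * se_C + 1 * mesh$dt)
  expect_lt(abs(mean(run$N) - ref[["N"]]), 3 * se_N + 1 * mesh$dt)
})

test_that("single-column ensemble integration is bitwise the scalar loop", {
  p <- model_params(x0 = c(0.70, 0.10))
  mesh <- sde_mesh(0, 5, 0.01)
  path <- sample_path(mesh, seed = 31L)
  traj <- integrate_sde(p, mesh, path)
  run <- em_ensemble(p, mesh, matrix(path$increments, ncol = 1L))
  expect_identical(c(run$C, run$N),
                   unname(traj$states[mesh$n_steps + 1L, ]))
})

test_that("trajectories export to CSV with a JSON metadata sidecar", {
  p <- default_p()
  mesh <- sde_mesh(0, 1, 0.1)
  traj <- integrate_sde(p, mesh, sample_path(mesh, 8L))
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f)
  got <- read.csv(f)
  expect_equal(names(got), c("t", "C", "N"))
  expect_equal(got$C[1], 0.65)
  meta <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(meta$scheme, "em")
  expect_equal(meta$params$K3, 5)
})
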