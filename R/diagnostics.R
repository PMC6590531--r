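#' Fit a convergence order from step sizes and errors
#'
#' Least-squares slope of log(error) against log(dt).  Degenerate levels
#' (error at or below `tol`, e.g. a scheme that is exact for the model at
#' hand) are excluded with a warning; fewer than two usable levels yields
#' `NA` with a `"degenerate"` warning.
#'
#' @param dts positive step sizes.
#' @param errors corresponding error values.
#' @param tol errors at or below this are treated as exactly zero.
#' @return The fitted order (slope), with attribute `excluded` giving the
#'   indices of any dropped levels.
#' @export
#' @examples
#' fit_order(c(0.1, 0.05, 0.025), 0.3 * c(0.1, 0.05, 0.025)^0.5)  # 0.5
fit_order <- function(dts, errors, tol = 1e-14) {
  if (length(dts) != length(errors) || length(dts) < 2L)
    stop("need >= 2 (dt, error) pairs of equal length")
  if (any(dts <= 0)) stop("step sizes must be positive")
  valid <- is.finite(errors) & errors > tol
  excluded <- which(!valid)
  if (length(excluded))
    warning("excluding ", length(excluded),
            " degenerate (~zero) error level(s): index ",
            paste(excluded, collapse = ", "))
  if (sum(valid) < 2L) {
    warning("degenerate order fit: fewer than two positive error levels")
    return(structure(NA_real_, excluded = excluded))
  }
  co <- stats::coef(stats::lm(log(errors[valid]) ~ log(dts[valid])))
  structure(unname(co[2L]), excluded = excluded)
}

#' Strong (mean-square) convergence study with coupled dyadic levels
#'
#' Estimates the strong convergence order of the Euler--Maruyama scheme:
#' for each of `n_paths` seeded Brownian paths, the finest-step run is the
#' reference, the same path is dyadically coarsened (factors 2, 4, ...,
#' 2^n_levels) and re-integrated, and the terminal-state error e = X_level
#' - X_ref is recorded.  The root-mean-square error per level is fitted by
#' log-log least squares.  All levels share one Brownian path per replicate
#' (coupled), so level differences are purely discretisation.
#'
#' @param p a [model_params()] object.
#' @param t0,horizon integration interval (years).
#' @param finest_dt reference step size; `(horizon - t0) / finest_dt` must
#'   be divisible by `2^n_levels`.
#' @param n_levels number of coarsened comparison levels (>= 3 for a
#'   meaningful fit; the coarsest step is `finest_dt * 2^n_levels`).
#' @param n_paths Monte-Carlo replicates.
#' @param seed integer seed for the whole study.
#' @return An object of class `convergence_result`: `dts` (decreasing),
#'   `rms_errors`, `n_paths`, `fitted_order`, `intercept`, `n_aborted`.
#' @export
strong_error_study <- function(p, t0 = 0, horizon = 5, finest_dt = 2^-12,
                               n_levels = 3L, n_paths = 200L, seed = 42L) {
  n_levels <- as.integer(n_levels)
  if (n_levels < 1L) stop("n_levels must be >= 1")
  mesh <- sde_mesh(t0, horizon, finest_dt)
  if (mesh$n_steps %% 2L^n_levels != 0L)
    stop("the coarsest level (factor ", 2L^n_levels,
         ") does not divide the finest mesh (", mesh$n_steps, " steps)")
  set.seed(seed)
  dW <- matrix(stats::rnorm(mesh$n_steps * n_paths, 0, sqrt(finest_dt)),
               mesh$n_steps, n_paths)
  ref <- em_ensemble(p, mesh, dW)
  factors <- 2L^seq_len(n_levels)
  errs2 <- matrix(NA_real_, n_levels, n_paths)
  for (l in seq_len(n_levels)) {
    f <- factors[l]
    dWc <- dW
    dim(dWc) <- c(f, mesh$n_steps %/% f, n_paths)
    dWc <- colSums(dWc)
    cm <- sde_mesh(t0, horizon, finest_dt * f)
    run <- em_ensemble(p, cm, dWc)
    errs2[l, ] <- (run$C - ref$C)^2 + (run$N - ref$N)^2
  }
  ok <- ref$alive & apply(is.finite(errs2), 2L, all)
  n_aborted <- sum(!ok)
  if (n_aborted > 0L)
    warning(n_aborted, " path(s) blew up and were excluded")
  if (!any(ok)) stop("no usable paths in strong error study")
  rms <- sqrt(rowMeans(errs2[, ok, drop = FALSE]))
  dts <- finest_dt * factors
  # store coarse-to-fine: dts strictly decreasing
  o <- order(dts, decreasing = TRUE)
  dts <- dts[o]
  rms <- rms[o]
  order_fit <- fit_order(dts, rms)
  valid <- is.finite(rms) & rms > 1e-14
  intercept <- if (sum(valid) >= 2L)
    unname(stats::coef(stats::lm(log(rms[valid]) ~ log(dts[valid])))[1L])
  else NA_real_
  structure(list(dts = dts, rms_errors = rms, n_paths = sum(ok),
                 fitted_order = as.numeric(order_fit),
                 intercept = intercept,
                 degenerate_levels = attr(order_fit, "excluded"),
                 n_aborted = n_aborted, seed = seed),
            class = "convergence_result")
}

#' @export
print.convergence_result <- function(x, ...) {
  cat("Strong convergence study (", x$n_paths, " coupled paths)\n", sep = "")
  for (i in seq_along(x$dts))
    cat(sprintf("  dt = %-10.3g rms terminal error = %.4g\n",
                x$dts[i], x$rms_errors[i]))
  cat(sprintf("  fitted order: %.3f\n", x$fitted_order))
  if (length(x$degenerate_levels))
    cat("  degenerate levels excluded:",
        paste(x$degenerate_levels, collapse = ", "), "\n")
  invisible(x)
}

#' Pullback mean-square stability experiment
#'
#' Fixes the observation time `t_fixed` and pushes the start time back to
#' `t_fixed - tau` for each lag `tau`: both initial states are integrated
#' along the *same* Brownian path (built by reflection when the start time
#' is negative) and the Euclidean distance of the two solutions at
#' `t_fixed` is recorded.  Under additive noise the difference dynamics
#' are noise-free, so the recorded distances match the matrix-exponential
#' oracle `norm(expm(M (t^2 - s^2) / 2) (x0 - x0_hat))` up to
#' discretisation error, and are independent of the noise realisation.
#'
#' @param p a [model_params()] object (its own `x0` is ignored here).
#' @param x0,x0_hat the two initial states, `x0 != x0_hat` for a
#'   non-trivial run.
#' @param t_fixed observation time.
#' @param taus increasing positive pullback lags.
#' @param dt step size.
#' @param n_paths replicates per lag (averaged; 1 suffices since the
#'   difference is deterministic).
#' @param seed integer seed.
#' @param mode negative-time path construction, see [reflect()].
#' @return An object of class `stability_result`: `taus`, `diffs`,
#'   `oracle` (closed-form distances), `epsilon` (initial separation),
#'   `dt`, `t_fixed`.
#' @export
pullback_experiment <- function(p, x0, x0_hat, t_fixed, taus, dt = 0.01,
                                n_paths = 1L, seed = 42L,
                                mode = c("reflect", "independent")) {
  mode <- match.arg(mode)
  if (any(diff(taus) <= 0) || any(taus <= 0))
    stop("taus must be positive and strictly increasing")
  x0 <- state_vec(x0[[1L]], x0[[2L]])
  x0_hat <- state_vec(x0_hat[[1L]], x0_hat[[2L]])
  pa <- model_params(p$coeffs, p$noise, x0 = x0)
  pb <- model_params(p$coeffs, p$noise, x0 = x0_hat)
  M <- constant_matrix(p)
  set.seed(seed)
  diffs <- vapply(taus, function(tau) {
    s <- t_fixed - tau
    mean(vapply(seq_len(n_paths), function(i) {
      path <- brownian_on_interval(s, t_fixed, dt, seed = NULL, mode = mode)
      mesh <- path$mesh
      ta <- integrate_sde(pa, mesh, path)
      tb <- integrate_sde(pb, mesh, path)
      d <- ta$states[mesh$n_steps + 1L, ] - tb$states[mesh$n_steps + 1L, ]
      sqrt(sum(d^2))
    }, 0))
  }, 0)
  oracle <- vapply(taus, function(tau) {
    s <- t_fixed - tau
    d <- expm_2x2(M * (t_fixed^2 - s^2) / 2) %*% (x0 - x0_hat)
    sqrt(sum(d^2))
  }, 0)
  structure(list(taus = taus, diffs = diffs, oracle = oracle,
                 epsilon = sqrt(sum((x0 - x0_hat)^2)),
                 dt = dt, t_fixed = t_fixed, n_paths = n_paths,
                 seed = seed, mode = mode),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(
    "Pullback stability at t = %g (initial separation %.4g, dt = %g)\n",
    x$t_fixed, x$epsilon, x$dt))
  for (i in seq_along(x$taus))
    cat(sprintf("  tau = %-8g diff = %-12.4g oracle = %.4g\n",
                x$taus[i], x$diffs[i], x$oracle[i]))
  invisible(x)
}

#' Coalescence of trajectories from different starting points
#'
#' Integrates several initial states along one shared Brownian path and
#' returns the pairwise Euclidean distances over time.  With additive
#' noise the distances are noise-free and decay like
#' `exp(lambda_max t^2 / 2)` (lambda_max the dominant eigenvalue of M),
#' which is the quantitative content of the trajectory-coalescence claim.
#'
#' @param p a [model_params()] object (its `x0` is ignored).
#' @param starts list of >= 2 initial states.
#' @param mesh an [sde_mesh()].
#' @param seed integer seed for the shared path.
#' @return A list: `times`, `diffs` (matrix, one column per pair,
#'   labelled), `starts`.
#' @export
trajectory_coalescence <- function(p, starts, mesh, seed = 42L) {
  if (length(starts) < 2L) stop("need at least two starting points")
  path <- sample_path(mesh, seed)
  trajs <- lapply(starts, function(x0)
    integrate_sde(model_params(p$coeffs, p$noise, x0 = x0), mesh, path))
  pairs <- utils::combn(length(starts), 2L)
  diffs <- apply(pairs, 2L, function(ij) {
    d <- trajs[[ij[1L]]]$states - trajs[[ij[2L]]]$states
    sqrt(d[, 1L]^2 + d[, 2L]^2)
  })
  colnames(diffs) <- apply(pairs, 2L, paste, collapse = "-")
  list(times = mesh$times, diffs = diffs, starts = starts)
}

#' Ensemble mean and variance of the stochastic solution
#'
#' Integrates `n_paths` independent seeded replicates and returns the
#' per-time mean and variance of C and N.  Since the drift is affine and
#' the noise additive, the mean series solves the noise-free system and
#' can be checked against [ode_reference()].
#'
#' @param p a [model_params()] object.
#' @param mesh an [sde_mesh()].
#' @param n_paths number of replicates (>= 1).
#' @param seed integer seed.
#' @return A `data.frame` with columns `t`, `mean_C`, `mean_N`, `var_C`,
#'   `var_N` (variance is 0 when `n_paths = 1`).
#' @export
ensemble_summary <- function(p, mesh, n_paths = 200L, seed = 42L) {
  if (n_paths < 1L) stop("n_paths must be >= 1")
  set.seed(seed)
  dW <- matrix(stats::rnorm(mesh$n_steps * n_paths, 0, sqrt(mesh$dt)),
               mesh$n_steps, n_paths)
  run <- em_ensemble(p, mesh, dW, return_states = TRUE)
  rowvar <- function(m) {
    if (ncol(m) == 1L) rep(0, nrow(m))
    else apply(m, 1L, stats::var)
  }
  data.frame(t = mesh$times,
             mean_C = rowMeans(run$C), mean_N = rowMeans(run$N),
             var_C = rowvar(run$C), var_N = rowvar(run$N))
}

#' Export a convergence or stability result as JSON
#'
#' @param result a `convergence_result` or `stability_result`.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_result_json <- function(result, file) {
  out <- unclass(result)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
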