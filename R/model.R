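#' Linear-in-time rate coefficients
#'
#' The five transition rates of the diabetes compartment model are taken to
#' be proportional to time since baseline: lambda(t) = `lam_slope * t`, and
#' likewise for theta (combined removal gamma + mu + nu + delta), incidence
#' I(t), the severe-disability-plus-complication-mortality rate nu + delta,
#' and the background mortality mu.  Slopes have units rate / year^2; time
#' is measured in years since baseline.
#'
#' Defaults are the canonical calibrated values for the Fujian Province
#' surveillance series (lambda = 0.02 t, theta = 0.01 t, I = 0.05 t,
#' nu + delta = 0.007 t, mu = 0.002 t).
#'
#' @param lam_slope slope of the complication rate lambda(t) (>= 0).
#' @param theta_slope slope of the combined removal rate theta(t).
#' @param inc_slope slope of the incidence I(t) (>= 0).
#' @param nu_delta_slope slope of nu(t) + delta(t) (>= 0).
#' @param mu_slope slope of the mortality mu(t) (>= 0).
#' @return An object of class `linear_coefficients`.
#' @export
#' @examples
#' linear_coefficients()                  # canonical defaults
#' linear_coefficients(lam_slope = 0.03)
linear_coefficients <- function(lam_slope = 0.02, theta_slope = 0.01,
                                inc_slope = 0.05, nu_delta_slope = 0.007,
                                mu_slope = 0.002) {
  co <- list(lam_slope = lam_slope, theta_slope = theta_slope,
             inc_slope = inc_slope, nu_delta_slope = nu_delta_slope,
             mu_slope = mu_slope)
  for (nm in names(co)) {
    v <- co[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("coefficient slope '", nm, "' must be a finite number")
  }
  for (nm in c("lam_slope", "inc_slope", "nu_delta_slope", "mu_slope"))
    if (co[[nm]] < 0) stop("coefficient slope '", nm, "' must be >= 0")
  structure(co, class = "linear_coefficients")
}

#' Additive sinusoidal noise specification
#'
#' The diffusion term of the model is additive (state-independent) with a
#' single scalar Brownian driver: g1(t) = K3 sin(t), g2(t) = K3 cos(t).
#' The Euclidean norm of (g1, g2) is exactly K3 for every t, so K3 is both
#' the amplitude and the global noise bound K2 of the well-posedness
#' hypothesis.
#'
#' @param K3 noise amplitude (dimensionless, >= 0).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(K3 = 5) {
  if (!is.numeric(K3) || length(K3) != 1L || !is.finite(K3) || K3 < 0)
    stop("K3 must be a finite number >= 0")
  structure(list(K3 = K3), class = "noise_spec")
}

#' State vector of the compartment model
#'
#' The state is (C, N): diabetics with complications and all diabetics.
#' The derived compartment D = N - C (diabetics without complications) is
#' intended to be nonnegative, but this ordering is *not* enforced: additive
#' Gaussian noise can push components negative, and the published
#' experimental starting points themselves have N0 < C0.  Violations are
#' counted and reported by the integrators, never clipped.
#'
#' @param C abundance of diabetics with complications (finite real).
#' @param N abundance of all diabetics (finite real).
#' @return A named numeric vector `c(C = , N = )`.
#' @export
state_vec <- function(C, N) {
  x <- c(C = as.numeric(C), N = as.numeric(N))
  if (length(x) != 2L || !all(is.finite(x)))
    stop("state components C and N must be finite reals")
  x
}

#' Full model parameterisation
#'
#' Bundles rate coefficients, noise specification and the initial state.
#' `K1` is the declared bound on the initial compartments
#' (max(C0, D0) <= K1); it defaults to the smallest bound that holds for
#' the given initial state, and [lipschitz_bound()] reports a violation if
#' a user-declared `K1` is exceeded.
#'
#' @param coeffs a [linear_coefficients()] object.
#' @param noise a [noise_spec()] object.
#' @param x0 initial state, numeric `c(C0, N0)` (default the published
#'   starting point `c(0.65, 0.10)`).
#' @param K1 declared initial-value bound (default `max(C0, D0)`).
#' @return An object of class `model_params`.
#' @export
#' @examples
#' p <- model_params()
#' drift(c(1, 1), t = 1, p)
model_params <- function(coeffs = linear_coefficients(),
                         noise = noise_spec(),
                         x0 = c(0.65, 0.10),
                         K1 = NULL) {
  stopifnot(inherits(coeffs, "linear_coefficients"),
            inherits(noise, "noise_spec"))
  x0 <- state_vec(x0[[1L]], x0[[2L]])
  D0 <- x0[["N"]] - x0[["C"]]
  if (is.null(K1)) K1 <- max(x0[["C"]], D0)
  if (!is.numeric(K1) || length(K1) != 1L || !is.finite(K1))
    stop("K1 must be a finite number")
  structure(list(coeffs = coeffs, noise = noise, x0 = x0, K1 = K1),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  co <- x$coeffs
  cat("Stochastic diabetes compartment model\n")
  cat(sprintf("  lambda(t) = %g t   theta(t) = %g t   I(t) = %g t\n",
              co$lam_slope, co$theta_slope, co$inc_slope))
  cat(sprintf("  nu+delta(t) = %g t   mu(t) = %g t\n",
              co$nu_delta_slope, co$mu_slope))
  cat(sprintf("  noise: g1 = %g sin t, g2 = %g cos t (additive, one driver)\n",
              x$noise$K3, x$noise$K3))
  cat(sprintf("  x0 = (C = %g, N = %g), declared K1 = %g\n",
              x$x0[["C"]], x$x0[["N"]], x$K1))
  invisible(x)
}

check_state_time <- function(x, t) {
  if (!is.numeric(x) || length(x) != 2L || !all(is.finite(x)))
    stop("state must be a finite numeric 2-vector")
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t))
    stop("time must be a finite number")
}

#' Drift of the compartment SDE
#'
#' Evaluates the drift b(x, t) =
#' ( -(lambda(t) + theta(t)) C + lambda(t) N,
#'   I(t) - (nu(t) + delta(t)) C - mu(t) N ).
#' Negative times are allowed (coefficients are evaluated as given), which
#' pullback stability runs rely on.
#'
#' @param x state `c(C, N)`.
#' @param t time in years since baseline (may be negative).
#' @param p a [model_params()] object.
#' @return Numeric 2-vector (dC, dN).
#' @export
drift <- function(x, t, p) {
  check_state_time(x, t)
  co <- p$coeffs
  lam <- co$lam_slope * t
  theta <- co$theta_slope * t
  inc <- co$inc_slope * t
  nd <- co$nu_delta_slope * t
  mu <- co$mu_slope * t
  c(-(lam + theta) * x[[1L]] + lam * x[[2L]],
    inc - nd * x[[1L]] - mu * x[[2L]])
}

#' Diffusion of the compartment SDE
#'
#' Returns (g1(t), g2(t)) = (K3 sin t, K3 cos t).  The diffusion is
#' additive: it never depends on the state, which is why the Milstein
#' correction vanishes for this model.
#'
#' @inheritParams drift
#' @return Numeric 2-vector (g1, g2).
#' @export
diffusion <- function(t, p) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t))
    stop("time must be a finite number")
  K3 <- p$noise$K3
  c(K3 * sin(t), K3 * cos(t))
}

#' Time-varying coefficient matrix A(t)
#'
#' The drift is affine in the state: b(x, t) = A(t) x + (0, I(t)) with
#' A(t) = \[\[-(lambda+theta)(t), lambda(t)\], \[-(nu+delta)(t), -mu(t)\]\].
#' Because every rate is proportional to t, A(t) = t * M for the constant
#' matrix M = A(1), and the family \{A(t)\} commutes -- the basis of the
#' closed-form noise-free solution in [ode_reference()].
#'
#' @inheritParams drift
#' @return A 2x2 numeric matrix.
#' @export
coefficient_matrix <- function(t, p) {
  co <- p$coeffs
  lam <- co$lam_slope * t
  theta <- co$theta_slope * t
  nd <- co$nu_delta_slope * t
  mu <- co$mu_slope * t
  matrix(c(-(lam + theta), -nd, lam, -mu), nrow = 2L, ncol = 2L)
}

#' Constant part M of the coefficient matrix, A(t) = t * M
#' @param p a [model_params()] object.
#' @return A 2x2 numeric matrix.
#' @export
constant_matrix <- function(p) coefficient_matrix(1, p)

#' Deterministic equilibrium of the drift
#'
#' Solves M x* + (0, inc_slope) = 0, where M is the constant part of the
#' coefficient matrix.  Since A(t) = t * M and the inhomogeneity is
#' t * (0, inc_slope), the drift vanishes at x* for *every* t, making x*
#' the global attractor of the noise-free flow when M is Hurwitz.
#'
#' @param p a [model_params()] object.
#' @return State vector `c(C, N)` at equilibrium.
#' @export
#' @examples
#' equilibrium(model_params())  # (5, 7.5) for the canonical coefficients
equilibrium <- function(p) {
  M <- constant_matrix(p)
  if (abs(det(M)) < .Machine$double.eps * max(1, sum(abs(M))))
    stop("degenerate model: constant coefficient matrix M is singular")
  x <- solve(M, -c(0, p$coeffs$inc_slope))
  state_vec(x[1L], x[2L])
}

#' Well-posedness bounds on a finite horizon
#'
#' Computes the coefficient bound J = sup over \[0, horizon\] of
#' max(theta(t), lambda(t)), the noise bound K2 = sup max(|g1|, |g2|) = K3,
#' and the Lipschitz constant L = sqrt(7) J implied by the entrywise bound
#' (lambda+theta)^2 + lambda^2 + (nu+delta)^2 + mu^2 <= 7 J^2 on the
#' coefficient matrix.
#'
#' Global (all-time) boundedness of lambda and theta is *incompatible* with
#' linearly growing coefficients; whenever a slope is positive the report
#' flags `"global_boundedness"` rather than refusing to run -- all bounds
#' are understood on the declared finite horizon.  The report also flags a
#' declared-K1 failure (`"initial_bound"`) and the soft initial-ordering
#' violation N0 < C0 (`"initial_ordering"`).
#'
#' @param p a [model_params()] object.
#' @param horizon finite positive time horizon (years).
#' @return An object of class `hypothesis_report` with fields `horizon`,
#'   `J`, `K2`, `L` and `violations` (character vector, possibly empty).
#' @export
lipschitz_bound <- function(p, horizon) {
  if (!is.numeric(horizon) || length(horizon) != 1L ||
      !is.finite(horizon) || horizon <= 0)
    stop("horizon must be a finite positive number")
  co <- p$coeffs
  # linear coefficients: sup over [0, h] sits at 0 or h
  J <- max(0, horizon * co$lam_slope, horizon * co$theta_slope)
  K2 <- p$noise$K3
  L <- sqrt(7) * J
  violations <- character()
  if (co$lam_slope > 0 || co$theta_slope > 0)
    violations <- c(violations, "global_boundedness")
  D0 <- p$x0[["N"]] - p$x0[["C"]]
  if (max(p$x0[["C"]], D0) > p$K1)
    violations <- c(violations, "initial_bound")
  if (D0 < 0)
    violations <- c(violations, "initial_ordering")
  structure(list(horizon = horizon, J = J, K2 = K2, L = L,
                 violations = violations),
            class = "hypothesis_report")
}

#' @export
print.hypothesis_report <- function(x, ...) {
  cat(sprintf("Hypothesis report on [0, %g]:\n", x$horizon))
  cat(sprintf("  J = %g  K2 = %g  L = sqrt(7) J = %g\n", x$J, x$K2, x$L))
  if (length(x$violations) == 0L) cat("  no violations\n")
  else cat("  violations:", paste(x$violations, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize model parameters to a flat key-value list
#'
#' Keys: `lam_slope`, `theta_slope`, `inc_slope`, `nu_delta_slope`,
#' `mu_slope`, `K3`, `C0`, `N0`.
#'
#' @param p a [model_params()] object.
#' @param file optional path; when given the list is written as YAML.
#' @return The flat named list, invisibly when written to file.
#' @export
params_to_config <- function(p, file = NULL) {
  cfg <- list(lam_slope = p$coeffs$lam_slope,
              theta_slope = p$coeffs$theta_slope,
              inc_slope = p$coeffs$inc_slope,
              nu_delta_slope = p$coeffs$nu_delta_slope,
              mu_slope = p$coeffs$mu_slope,
              K3 = p$noise$K3,
              C0 = p$x0[["C"]],
              N0 = p$x0[["N"]])
  if (!is.null(file)) {
    yaml::write_yaml(cfg, file)
    return(invisible(cfg))
  }
  cfg
}

#' Deserialize model parameters from a flat key-value list or YAML file
#'
#' Missing keys fall back to the canonical defaults.
#'
#' @param config a named list or the path of a YAML file with the keys of
#'   [params_to_config()].
#' @return A [model_params()] object.
#' @export
params_from_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dflt <- params_to_config(model_params())
  unknown <- setdiff(names(config), names(dflt))
  if (length(unknown))
    stop("unknown model config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(dflt, config)
  model_params(
    coeffs = linear_coefficients(cfg$lam_slope, cfg$theta_slope,
                                 cfg$inc_slope, cfg$nu_delta_slope,
                                 cfg$mu_slope),
    noise = noise_spec(cfg$K3),
    x0 = c(cfg$C0, cfg$N0))
}
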