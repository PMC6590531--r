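#' Uniform time mesh
#'
#' A uniform grid on \[t0, T\] with step `dt` (years).  The step count is
#' derived as `round((T - t0) / dt)` and must reproduce the interval to
#' within a relative tolerance of 1e-9 of one step.
#'
#' @param t0 start time (years; may be negative for pullback runs).
#' @param T end time, `T > t0`.
#' @param dt positive step size.
#' @return An object of class `sde_mesh` with fields `t0`, `T`, `dt`,
#'   `n_steps` and `times` (length `n_steps + 1`).
#' @export
#' @examples
#' sde_mesh(0, 5, 0.01)
sde_mesh <- function(t0, T, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a finite positive number")
  if (!is.numeric(t0) || !is.numeric(T) || !is.finite(t0) || !is.finite(T) ||
      T <= t0)
    stop("mesh requires finite t0 < T")
  n_steps <- as.integer(round((T - t0) / dt))
  if (n_steps < 1L || abs(n_steps * dt - (T - t0)) >= dt * 1e-9)
    stop("dt does not evenly divide the interval [t0, T]")
  structure(list(t0 = t0, T = T, dt = dt, n_steps = n_steps,
                 times = t0 + dt * (0:n_steps)),
            class = "sde_mesh")
}

#' @export
print.sde_mesh <- function(x, ...) {
  cat(sprintf("mesh [%g, %g], dt = %g, %d steps\n",
              x$t0, x$T, x$dt, x$n_steps))
  invisible(x)
}

same_mesh <- function(a, b) {
  isTRUE(all.equal(c(a$t0, a$T, a$dt), c(b$t0, b$T, b$dt))) &&
    a$n_steps == b$n_steps
}

new_brownian_path <- function(mesh, increments, seed = NA_integer_,
                              anchor = c("start", "end")) {
  stopifnot(inherits(mesh, "sde_mesh"),
            length(increments) == mesh$n_steps)
  values <- c(0, cumsum(increments))
  if (match.arg(anchor) == "end") values <- values - values[length(values)]
  structure(list(mesh = mesh, increments = increments,
                 values = values, seed = seed),
            class = "brownian_path")
}

#' @export
print.brownian_path <- function(x, ...) {
  cat(sprintf("Wiener path on [%g, %g], dt = %g, W(t0) = %g, W(T) = %g\n",
              x$mesh$t0, x$mesh$T, x$mesh$dt, x$values[1L],
              x$values[length(x$values)]))
  invisible(x)
}

#' Sample a Wiener path on a mesh
#'
#' Draws independent Gaussian increments with mean 0 and variance `dt`,
#' anchors `W(t0) = 0` and accumulates.  Deterministic given `seed`; with
#' `seed = NULL` increments are drawn from the current RNG stream (used by
#' experiment drivers that manage a single seeded stream).
#'
#' @param mesh an [sde_mesh()].
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return An object of class `brownian_path` with fields `mesh`,
#'   `increments` (length `n_steps`, units sqrt(years)), `values`
#'   (length `n_steps + 1`, `values[1] = 0`) and `seed`.
#' @export
sample_path <- function(mesh, seed = NULL) {
  stopifnot(inherits(mesh, "sde_mesh"))
  if (!is.null(seed)) set.seed(seed)
  inc <- stats::rnorm(mesh$n_steps, mean = 0, sd = sqrt(mesh$dt))
  new_brownian_path(mesh, inc, if (is.null(seed)) NA_integer_ else seed)
}

#' Mirror a Wiener path across time zero
#'
#' Given a path anchored at zero at one end of its interval, returns the
#' path on the mirrored interval.  In `"reflect"` mode (the construction
#' used for negative-time runs here) the mirrored path is W(-t) := -W(t):
#' an involution, cheap, but *not* an independent two-sided Wiener process
#' -- acceptable for pullback diagnostics because the inter-solution
#' difference dynamics are noise-free under additive noise.  In
#' `"independent"` mode fresh increments are drawn instead, giving a
#' statistically correct two-sided process.
#'
#' @param path a `brownian_path` whose mesh has `t0 = 0` or `T = 0`.
#' @param mode `"reflect"` (default) or `"independent"`.
#' @param seed seed for `"independent"` mode (`NULL`: current RNG stream).
#' @return A `brownian_path` on the mirrored interval.
#' @export
reflect <- function(path, mode = c("reflect", "independent"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(path, "brownian_path"))
  m <- path$mesh
  if (abs(m$t0) > m$dt * 1e-9 && abs(m$T) > m$dt * 1e-9)
    stop("path must be anchored at time zero at one end of its interval")
  mirrored <- sde_mesh(-m$T, -m$t0, m$dt)
  # keep the mirrored path anchored to zero at its time-zero end
  anchor <- if (abs(mirrored$t0) <= m$dt * 1e-9) "start" else "end"
  if (mode == "independent") {
    if (!is.null(seed)) set.seed(seed)
    inc <- stats::rnorm(mirrored$n_steps, 0, sqrt(m$dt))
    return(new_brownian_path(mirrored, inc,
                             if (is.null(seed)) NA_integer_ else seed,
                             anchor = anchor))
  }
  # W(-t) = -W(t): mirrored increments are the reversed originals
  new_brownian_path(mirrored, rev(path$increments), path$seed,
                    anchor = anchor)
}

#' Dyadic coarsening of a Wiener path
#'
#' Sums consecutive increments in blocks of `factor`; the coarse path
#' visits exactly the original values at shared grid points (telescoping),
#' which is what couples the levels of a strong-convergence study to a
#' single underlying Brownian path.
#'
#' @param path a `brownian_path`.
#' @param factor integer >= 2 dividing the number of steps.
#' @return A `brownian_path` on the coarse mesh.
#' @export
coarsen <- function(path, factor) {
  stopifnot(inherits(path, "brownian_path"))
  factor <- as.integer(factor)
  n <- path$mesh$n_steps
  if (factor < 2L || n %% factor != 0L)
    stop("factor must be >= 2 and divide the number of steps (", n, ")")
  inc <- path$increments
  dim(inc) <- c(factor, n %/% factor)
  m <- path$mesh
  new_brownian_path(sde_mesh(m$t0, m$T, m$dt * factor), colSums(inc),
                    path$seed)
}

#' Wiener path on an arbitrary interval, via reflection for negative times
#'
#' For `t0 >= 0` this is [sample_path()].  For `t0 < 0` the positive-time
#' path is built first and its mirror (see [reflect()]) supplies the
#' negative-time part; values are re-anchored so `W(t0) = 0`.
#'
#' @param t0,T,dt mesh parameters as in [sde_mesh()].
#' @param seed integer seed or `NULL` (current RNG stream).
#' @param mode negative-time construction, `"reflect"` or `"independent"`.
#' @return A `brownian_path` on \[t0, T\].
#' @export
brownian_on_interval <- function(t0, T, dt, seed = NULL,
                                 mode = c("reflect", "independent")) {
  mode <- match.arg(mode)
  if (t0 >= 0) return(sample_path(sde_mesh(t0, T, dt), seed))
  if (!is.null(seed)) set.seed(seed)
  pos_end <- max(T, -t0)
  pos <- sample_path(sde_mesh(0, pos_end, dt), seed = NULL)
  neg <- reflect(if (pos_end > -t0 + dt * 1e-9) {
    # trim the positive path to [0, -t0] before mirroring
    k <- as.integer(round(-t0 / dt))
    new_brownian_path(sde_mesh(0, -t0, dt), pos$increments[seq_len(k)])
  } else pos, mode = mode, seed = NULL)
  inc <- neg$increments
  if (T > dt * 1e-9) {
    k <- as.integer(round(T / dt))
    inc <- c(inc, pos$increments[seq_len(k)])
  }
  new_brownian_path(sde_mesh(t0, T, dt), inc,
                    if (is.null(seed)) NA_integer_ else seed)
}

#' Export a Wiener path as a two-column CSV (t, W)
#'
#' @param path a `brownian_path`.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_path_csv <- function(path, file) {
  stopifnot(inherits(path, "brownian_path"))
  utils::write.csv(data.frame(t = path$mesh$times, W = path$values), file,
                   row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(file)
}
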