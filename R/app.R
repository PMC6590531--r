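#' Default run configuration
#'
#' The packaged defaults reproduce the canonical experiment: calibrated
#' coefficients, K3 = 5, starting point (0.65, 0.10), mesh \[0, 500\] with
#' dt = 0.01.
#'
#' @return A nested list with `model`, `mesh` and `experiment` blocks.
#' @export
default_config <- function() {
  list(model = params_to_config(model_params()),
       mesh = list(t0 = 0, T = 500, dt = 0.01),
       experiment = list(seed = 42L, n_paths = 200L, n_levels = 3L,
                         finest_dt = 2^-12, horizon = 5,
                         t_fixed = 40, taus = c(10, 20, 40),
                         x0_hat = c(0.70, 0.10),
                         baseline_year = 2011L,
                         table = NULL))
}

merge_config <- function(base, extra) {
  for (nm in names(extra)) {
    if (is.list(extra[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], extra[[nm]])
    else base[[nm]] <- extra[[nm]]
  }
  base
}

resolve_config <- function(config) {
  if (is.null(config)) return(default_config())
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), c("model", "mesh", "experiment"))
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  merge_config(default_config(), config)
}

#' Run a pipeline command
#'
#' Single entry point behind the `diabsde` command-line script.  Every run
#' writes a resolved-configuration echo (`config.json`) next to its result
#' artifacts so that outputs are reproducible from the output directory
#' alone.
#'
#' Commands:
#' \describe{
#'   \item{calibrate}{fit slopes from a surveillance CSV
#'     (`experiment$table`, default the packaged Fujian table) ->
#'     `calibration.json`.}
#'   \item{simulate}{one Euler--Maruyama trajectory on the configured mesh
#'     -> `trajectory.csv` (+ `.json` sidecar); hypothesis violations are
#'     raised as warnings.}
#'   \item{convergence}{[strong_error_study()] -> `convergence.json`.}
#'   \item{stability}{[pullback_experiment()] between the model `x0` and
#'     `experiment$x0_hat` -> `stability.json`.}
#'   \item{fixtures}{regenerate the packaged surveillance CSV
#'     (byte-identical) plus a synthetic table with the canonical slopes ->
#'     `fujian_rates_2012_2016.csv`, `synthetic_table.csv`.}
#' }
#'
#' @param command one of `"calibrate"`, `"simulate"`, `"convergence"`,
#'   `"stability"`, `"fixtures"`.
#' @param config `NULL` (defaults), a nested list overriding parts of
#'   [default_config()], or the path of a YAML file with the same shape.
#' @param seed optional integer overriding `experiment$seed`.
#' @param out output directory (default a fresh temporary directory).
#' @return Invisibly, a list with `status` (0 on success), `artifacts`
#'   (paths written) and `result` (the computed object).
#' @export
#' @examples
#' res <- run_command("calibrate", out = tempfile("diabsde"))
#' res$result$slopes$lam_slope
run_command <- function(command, config = NULL, seed = NULL, out = NULL) {
  commands <- c("calibrate", "simulate", "convergence", "stability",
                "fixtures")
  if (!is.character(command) || length(command) != 1L ||
      !command %in% commands)
    stop("unknown command; expected one of: ",
         paste(commands, collapse = ", "))
  cfg <- resolve_config(config)
  if (!is.null(seed)) cfg$experiment$seed <- as.integer(seed)
  if (is.null(out)) out <- tempfile("diabsde-run-")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out)) stop("cannot create output directory: ", out)
  p <- params_from_config(cfg$model)
  echo <- file.path(out, "config.json")
  jsonlite::write_json(list(command = command, config = cfg,
                            package_version =
                              as.character(utils::packageVersion("diabsde"))),
                       echo, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  artifacts <- echo
  ex <- cfg$experiment
  result <- switch(command,
    calibrate = {
      table_file <- if (is.null(ex$table)) surveillance_example()
                    else ex$table
      res <- calibrate(read_surveillance_table(table_file),
                       baseline_year = ex$baseline_year)
      f <- file.path(out, "calibration.json")
      write_calibration_json(res, f)
      artifacts <- c(artifacts, f)
      res
    },
    simulate = {
      mesh <- sde_mesh(cfg$mesh$t0, cfg$mesh$T, cfg$mesh$dt)
      rep_h <- lipschitz_bound(p, horizon = max(abs(mesh$t0), abs(mesh$T)))
      if (length(rep_h$violations))
        warning("hypothesis violations on the run horizon: ",
                paste(rep_h$violations, collapse = ", "))
      traj <- integrate_sde(p, mesh, sample_path(mesh, ex$seed))
      f <- file.path(out, "trajectory.csv")
      write_trajectory_csv(traj, f)
      artifacts <- c(artifacts, f, paste0(f, ".json"))
      traj
    },
    convergence = {
      res <- strong_error_study(p, t0 = 0, horizon = ex$horizon,
                                finest_dt = ex$finest_dt,
                                n_levels = ex$n_levels,
                                n_paths = ex$n_paths, seed = ex$seed)
      f <- file.path(out, "convergence.json")
      write_result_json(res, f)
      artifacts <- c(artifacts, f)
      res
    },
    stability = {
      res <- pullback_experiment(p, x0 = ex$x0_hat, x0_hat = p$x0,
                                 t_fixed = ex$t_fixed, taus = ex$taus,
                                 dt = cfg$mesh$dt, seed = ex$seed)
      f <- file.path(out, "stability.json")
      write_result_json(res, f)
      artifacts <- c(artifacts, f)
      res
    },
    fixtures = {
      f1 <- file.path(out, "fujian_rates_2012_2016.csv")
      write_surveillance_csv(fujian_table(), f1)
      f2 <- file.path(out, "synthetic_table.csv")
      write_surveillance_csv(
        generate_fixture(linear_coefficients(), n_years = 5L,
                         noise_sd = 0.001, seed = ex$seed), f2)
      artifacts <- c(artifacts, f1, f2)
      list(table = f1, synthetic = f2)
    })
  invisible(list(status = 0L, artifacts = artifacts, result = result))
}
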