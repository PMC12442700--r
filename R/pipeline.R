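# Orchestration: a JSON-configurable pipeline running
# simulate -> residence -> diffusivity -> theory and writing CSV/JSON
# tables. Every run is fully determined by (config, seed).

#' Build a pipeline run configuration
#'
#' @param params a \code{\link{motility_params}} object.
#' @param tb_centers tumble-bias bin centers analysed (default: 0.05-wide
#'   bins spanning (0.05, 0.95]).
#' @param n_residence trajectories per bin for the residence-time curve.
#' @param n_dxy trajectories per bin for the diffusivity curve.
#' @param slope_tol,count_floor three-phase window constants
#'   (\code{\link{rdc_phases}}).
#' @param transition_tolerance relative tolerance of
#'   \code{\link{transition_point}}.
#' @param seed master seed; fans out deterministically to all stages.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(params = motility_params(),
                       tb_centers = seq(0.075, 0.925, by = 0.05),
                       n_residence = 400, n_dxy = 500,
                       slope_tol = 0.05, count_floor = NULL,
                       transition_tolerance = 0.25, seed = 1L) {
  stopifnot(inherits(params, "motility_params"),
            all(tb_centers > 0), all(tb_centers < 1),
            n_residence >= 1, n_dxy >= 1)
  structure(list(params = params, tb_centers = tb_centers,
                 n_residence = n_residence, n_dxy = n_dxy,
                 slope_tol = slope_tol, count_floor = count_floor,
                 transition_tolerance = transition_tolerance,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from JSON
#'
#' The file may carry any subset of the \code{\link{run_config}} fields;
#' \code{params} is itself a named object of
#' \code{\link{motility_params}} fields.
#'
#' @param path JSON file path.
#' @return A \code{run_config} object.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(raw$params)) {
    args$params <- do.call(motility_params, as.list(raw$params))
  }
  for (f in c("tb_centers", "n_residence", "n_dxy", "slope_tol",
              "count_floor", "transition_tolerance", "seed")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  do.call(run_config, args)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass_recursive(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

unclass_recursive <- function(x) {
  if (is.list(x)) {
    lapply(x, unclass_recursive)
  } else {
    unclass(x)
  }
}

#' Run the full near-surface analysis pipeline
#'
#' Executes the four stages under one master seed and writes the result
#' tables to \code{out_dir}:
#' \describe{
#'   \item{events.csv}{per-trajectory surface events of the residence
#'     stage.}
#'   \item{curve.csv}{mean residence time per tumble-bias bin.}
#'   \item{dxy_curve.csv}{fitted surface diffusivity per bin.}
#'   \item{theory_curve.csv}{closed-form diffusivity on a fine grid.}
#'   \item{correction.json}{fitted curvature correction factor.}
#'   \item{summary.json}{plateau level, transition point, diffusivity peak
#'     and correction factor, plus the config hash.}
#'   \item{log.jsonl}{line-delimited stage log with per-stage seeds.}
#' }
#' Every table carries the configuration hash in a comment-free side
#' field of \code{summary.json}; rerunning with the same (config, seed)
#' reproduces all files exactly.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir output directory (created if needed).
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  logf <- file.path(out_dir, "log.jsonl")
  unlink(logf)
  log_line <- function(stage, ...) {
    rec <- list(stage = stage, config_hash = hash, ...)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
        sep = "", file = logf, append = TRUE)
  }
  stage_seed <- function(offset) config$seed + offset

  # stage 1+2: simulate and extract residence events
  log_line("residence", seed = stage_seed(0),
           n_per_bin = config$n_residence)
  ens <- simulate_residence_ensemble(config$tb_centers,
                                     config$n_residence, config$params,
                                     seed = stage_seed(0))
  events <- ens$events
  write.csv(events, file.path(out_dir, "events.csv"), row.names = FALSE)
  curve <- residence_curve(events)
  write.csv(curve, file.path(out_dir, "curve.csv"), row.names = FALSE)
  plateau_bins <- curve$tb_center > 0.25
  plateau <- mean(curve$mean_ts[plateau_bins], na.rm = TRUE)
  trans <- tryCatch(
    transition_point(curve, tolerance = config$transition_tolerance),
    error = function(e) NA_real_)

  # stage 3: surface diffusivity per bin
  log_line("diffusivity", seed = stage_seed(1000),
           n_per_bin = config$n_dxy)
  dcurve <- dxy_curve(config$tb_centers, config$n_dxy, config$params,
                      seed = stage_seed(1000),
                      slope_tol = config$slope_tol,
                      count_floor = config$count_floor)
  write.csv(dcurve, file.path(out_dir, "dxy_curve.csv"),
            row.names = FALSE)
  pk <- tryCatch(peak_tb(dcurve$tb_center, dcurve$dxy),
                 error = function(e) {
                   i <- which.max(dcurve$dxy)
                   list(tb_peak = dcurve$tb_center[i], boundary = NA)
                 })

  # stage 4: theory curve and correction factor
  log_line("theory", seed = stage_seed(2000))
  tcurve <- theory_curve(config$params)
  write.csv(tcurve, file.path(out_dir, "theory_curve.csv"),
            row.names = FALSE)
  corr <- tryCatch(fit_correction(dcurve, config$params),
                   error = function(e) {
                     list(c_factor = NA_real_, sse = NA_real_,
                          boundary = NA, error = conditionMessage(e))
                   })
  jsonlite::write_json(corr, file.path(out_dir, "correction.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  summary <- list(
    config_hash = hash,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("surfdwell")),
    plateau_mean_ts = plateau,
    transition_tb = trans,
    dxy_peak_tb = pk$tb_peak,
    dxy_peak_boundary = pk$boundary,
    correction_factor = corr$c_factor)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("done")
  invisible(summary)
}
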