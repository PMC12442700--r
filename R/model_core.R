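#' Physical parameters of the near-surface motility model
#'
#' Bundles the global constants of the two-state run/tumble model. Defaults
#' are read from the packaged configuration file
#' \code{system.file("extdata", "default_params.json", package = "surfdwell")},
#' which is the single source of truth for the model's measured values:
#' swimming speed \eqn{V = 19} um/s, tumble translational diffusion
#' \eqn{D_t = 6.61} um^2/s, characteristic switching frequency
#' \eqn{\omega = 9.27} /s, surface circling radius \eqn{R = 25} um, and the
#' 3 um / 8 um height criteria used to score surface arrival and escape.
#' The rotational diffusion coefficients (\code{run_rot_diffusion},
#' \code{tumble_rot_diffusion}) are literature-plausible defaults for
#' \emph{E. coli} runs and tumbles and are exposed for adjustment.
#'
#' @param ... named overrides of any default field. Recognised fields:
#'   \describe{
#'     \item{swim_speed}{run swimming speed \eqn{V}, um/s.}
#'     \item{tumble_diffusion}{tumble translational diffusion coefficient
#'       \eqn{D_t}, um^2/s.}
#'     \item{run_rot_diffusion}{run rotational diffusion coefficient
#'       \eqn{D_r}, rad^2/s.}
#'     \item{tumble_rot_diffusion}{tumble rotational diffusion coefficient
#'       \eqn{D_\theta}, rad^2/s.}
#'     \item{char_frequency}{characteristic switching frequency
#'       \eqn{\omega}, /s.}
#'     \item{curvature_radius}{surface circular-run radius \eqn{R}, um
#'       (physiological range 15--35).}
#'     \item{z_surface}{surface-interaction height criterion, um.}
#'     \item{z_bulk}{bulk height criterion, um.}
#'     \item{dt}{integration time step, s.}
#'     \item{t_cap}{maximum simulated time per trajectory, s.}
#'   }
#' @return An object of class \code{motility_params} (a validated named list).
#' @examples
#' p <- motility_params()
#' p$swim_speed
#' motility_params(curvature_radius = 15)$curvature_radius
#' @export
motility_params <- function(...) {
  p <- default_params()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("all overrides must be named")
    }
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
    }
    p[names(dots)] <- dots
  }
  validate_params(p)
}

#' Read model parameters from a JSON configuration file
#'
#' The file must contain exactly the fields documented in
#' \code{\link{motility_params}} (a subset is allowed; missing fields take
#' their defaults).
#'
#' @param path path to a JSON file of named scalar fields.
#' @return A validated \code{motility_params} object.
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(motility_params, as.list(raw))
}

default_params <- function() {
  path <- system.file("extdata", "default_params.json", package = "surfdwell")
  as.list(jsonlite::read_json(path, simplifyVector = TRUE))
}

validate_params <- function(p) {
  fields <- c("swim_speed", "tumble_diffusion", "run_rot_diffusion",
              "tumble_rot_diffusion", "char_frequency", "curvature_radius",
              "z_surface", "z_bulk", "dt", "t_cap")
  missing <- setdiff(fields, names(p))
  if (length(missing)) {
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))
  }
  p <- p[fields]
  for (f in fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", f, "' must be a finite numeric scalar")
    }
    if (f %in% c("run_rot_diffusion", "tumble_rot_diffusion")) {
      if (v < 0) stop("parameter '", f, "' must be >= 0")
    } else if (v <= 0) {
      stop("parameter '", f, "' must be > 0")
    }
  }
  if (p$z_bulk <= p$z_surface) {
    stop("z_bulk must exceed z_surface")
  }
  # dt must resolve the fastest switching: max rate over TB is omega/2 at
  # the relevant endpoint; requiring dt < 1/omega keeps
  # per-step switching probabilities well below 1
  if (p$dt >= 1 / p$char_frequency) {
    stop("dt must be < 1/char_frequency (= ",
         signif(1 / p$char_frequency, 4), " s) to resolve state switching")
  }
  structure(p, class = "motility_params")
}

#' @export
print.motility_params <- function(x, ...) {
  cat("Near-surface motility parameters (um, s, rad):\n")
  for (f in names(x)) cat(sprintf("  %-22s %g\n", f, x[[f]]))
  invisible(x)
}

#' Per-cell behavioural phenotype
#'
#' A cell is characterised by its tumble bias \code{tb}, the fraction of
#' time it spends in the tumble state, optionally with per-cell overrides
#' of swimming speed and surface circling radius.
#'
#' @param tb tumble bias, in \code{[0, 1]}. The endpoints denote frozen
#'   phenotypes: \code{tb = 0} never tumbles (smooth swimmer), \code{tb = 1}
#'   never runs (tumble-locked).
#' @param swim_speed,curvature_radius optional per-cell overrides, um/s and
#'   um respectively.
#' @return An object of class \code{cell_phenotype}.
#' @examples
#' cell_phenotype(0.25)
#' @export
cell_phenotype <- function(tb, swim_speed = NULL, curvature_radius = NULL) {
  if (!is.numeric(tb) || length(tb) != 1L || is.na(tb) || tb < 0 || tb > 1) {
    stop("tb must be a single value in [0, 1]")
  }
  for (ov in list(swim_speed, curvature_radius)) {
    if (!is.null(ov) && (!is.numeric(ov) || length(ov) != 1L || ov <= 0)) {
      stop("per-cell overrides must be positive scalars")
    }
  }
  structure(list(tb = tb, swim_speed = swim_speed,
                 curvature_radius = curvature_radius),
            class = "cell_phenotype")
}

#' Switching frequency as a function of tumble bias
#'
#' The total run/tumble switching frequency follows a symmetric quadratic
#' in tumble bias, \eqn{SF = \omega/4 - \omega (TB - 1/2)^2}, which is
#' algebraically \eqn{\omega \, TB (1 - TB)}: it vanishes for the frozen
#' phenotypes and is maximal at \eqn{TB = 1/2}.
#'
#' @param tb tumble bias, in \code{[0, 1]} (vectorised).
#' @param omega characteristic frequency \eqn{\omega}, /s.
#' @return Switching frequency, /s.
#' @examples
#' switching_frequency(0.5, 9.27)   # omega / 4
#' @export
switching_frequency <- function(tb, omega) {
  if (!is.numeric(tb) || any(is.na(tb)) || any(tb < 0) || any(tb > 1)) {
    stop("tb must lie in [0, 1]")
  }
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0) {
    stop("omega must be a positive scalar")
  }
  omega / 4 - omega * (tb - 0.5)^2
}

#' Run/tumble transition rates for a given tumble bias
#'
#' Splits a total switching frequency into the two Poisson rates of the
#' two-state Markov chain: \eqn{k_{RT} = SF / (2 (1 - TB))} (run to tumble)
#' and \eqn{k_{TR} = SF / (2 \, TB)} (tumble to run). When \code{sf} is the
#' quadratic \code{\link{switching_frequency}} these reduce to
#' \eqn{k_{RT} = \omega TB / 2} and \eqn{k_{TR} = \omega (1 - TB) / 2}.
#'
#' @param tb tumble bias, strictly inside \code{(0, 1)}. The frozen
#'   endpoints have no finite rate decomposition and must be special-cased
#'   by the caller.
#' @param sf total switching frequency, /s.
#' @return A list with components \code{k_rt} and \code{k_tr} (/s).
#' @examples
#' transition_rates(0.25, switching_frequency(0.25, 9.27))
#' @export
transition_rates <- function(tb, sf) {
  if (!is.numeric(tb) || length(tb) != 1L || is.na(tb) || tb <= 0 || tb >= 1) {
    stop("tb must lie strictly inside (0, 1); ",
         "tb = 0 or 1 denotes a frozen phenotype with no rate decomposition")
  }
  if (!is.numeric(sf) || length(sf) != 1L || is.na(sf) || sf < 0) {
    stop("sf must be a nonnegative scalar")
  }
  list(k_rt = sf / (2 * (1 - tb)), k_tr = sf / (2 * tb))
}

#' Stationary tumble fraction of the two-state chain
#'
#' The steady state of the run/tumble master equations puts probability
#' \eqn{k_{RT} / (k_{RT} + k_{TR})} on the tumble state; this inverts
#' \code{\link{transition_rates}} exactly.
#'
#' @param rates a list with components \code{k_rt}, \code{k_tr} (/s), as
#'   returned by \code{\link{transition_rates}}.
#' @return Stationary fraction of time in the tumble state.
#' @examples
#' stationary_tumble_fraction(list(k_rt = 2, k_tr = 2))
#' @export
stationary_tumble_fraction <- function(rates) {
  k_rt <- rates$k_rt
  k_tr <- rates$k_tr
  if (!is.numeric(k_rt) || !is.numeric(k_tr) ||
      !is.finite(k_rt) || !is.finite(k_tr) || k_rt < 0 || k_tr < 0) {
    stop("rates must be finite and nonnegative")
  }
  if (k_rt + k_tr == 0) {
    stop("both rates zero: stationary distribution undefined")
  }
  k_rt / (k_rt + k_tr)
}

# Rates for a phenotype under given params; frozen endpoints get zero rates
# (the state drawn at t = 0 never switches).
phenotype_rates <- function(tb, omega) {
  if (tb <= 0 || tb >= 1) {
    return(list(k_rt = 0, k_tr = 0))
  }
  transition_rates(tb, switching_frequency(tb, omega))
}
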