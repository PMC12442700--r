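# --- single-step primitives -------------------------------------------------
#
# These operate on a plain state list and draw their noise from R's RNG.
# They exist so the integration rules can be exercised in isolation; the
# ensemble generators below run the same scheme in compiled code.

new_sim_state <- function(r = c(0, 0, 0), e = c(1, 0, 0), theta = 0,
                          state = "run", surface_bound = FALSE) {
  list(r = r, e = e / sqrt(sum(e^2)), theta = theta, state = state,
       surface_bound = surface_bound)
}

# Gaussian increments in the tangent plane of unit vector e, per-axis
# variance 2*D*dt, followed by renormalization.
tangent_diffuse_r <- function(e, D, dt) {
  if (D <= 0) return(e)
  a <- c(0, 0, 0)
  a[which.min(abs(e))] <- 1
  u <- c(a[2] * e[3] - a[3] * e[2],
         a[3] * e[1] - a[1] * e[3],
         a[1] * e[2] - a[2] * e[1])
  u <- u / sqrt(sum(u^2))
  v <- c(e[2] * u[3] - e[3] * u[2],
         e[3] * u[1] - e[1] * u[3],
         e[1] * u[2] - e[2] * u[1])
  g <- sqrt(2 * D * dt) * rnorm(2)
  e <- e + g[1] * u + g[2] * v
  e / sqrt(sum(e^2))
}

align_state_to_surface <- function(s) {
  s$r[3] <- 0
  s$surface_bound <- TRUE
  lat <- sqrt(sum(s$e[1:2]^2))
  s$theta <- if (lat > 1e-12) atan2(s$e[2], s$e[1]) else runif(1, 0, 2 * pi)
  s$e <- c(cos(s$theta), sin(s$theta), 0)
  s
}

#' Advance one Euler-Maruyama step of a bulk run
#'
#' Ballistic advection at speed \eqn{V} along the orientation vector
#' \eqn{\hat e}, with rotational diffusion of \eqn{\hat e} (tangent-plane
#' Gaussian increments of per-axis variance \eqn{2 D_r \, dt}, then
#' renormalization). If the step carries the cell through the wall
#' (\eqn{z \le 0}) the surface-contact rule fires: \eqn{z} is clamped to 0,
#' the orientation aligns with the surface plane, and the azimuth is
#' inherited from the lateral component of \eqn{\hat e}.
#'
#' @param state a state list as produced by the simulator internals:
#'   components \code{r} (position, um), \code{e} (unit orientation),
#'   \code{theta} (azimuth, rad), \code{state} (\code{"run"} or
#'   \code{"tumble"}), \code{surface_bound} (logical).
#' @param params a \code{\link{motility_params}} object.
#' @return The advanced state list.
#' @export
step_run_bulk <- function(state, params) {
  stopifnot(state$state == "run", !state$surface_bound)
  state$r <- state$r + params$swim_speed * state$e * params$dt
  state$e <- tangent_diffuse_r(state$e, params$run_rot_diffusion, params$dt)
  if (state$r[3] <= 0) state <- align_state_to_surface(state)
  state
}

#' Advance one step of a surface-bound (circling) run
#'
#' On the surface the running cell is entrapped: it stays at \eqn{z = 0}
#' with its axis in the plane, and its azimuth rotates clockwise (viewed
#' from above, with \eqn{+z} pointing into the bulk) at angular speed
#' \eqn{\Omega = V / R}, perturbed by rotational diffusion:
#' \eqn{d\theta = -\Omega \, dt + \sqrt{2 D_r \, dt} \, N(0,1)}.
#'
#' @inheritParams step_run_bulk
#' @return The advanced state list.
#' @export
step_run_surface <- function(state, params) {
  stopifnot(state$state == "run", state$surface_bound, state$r[3] == 0)
  omega_c <- params$swim_speed / params$curvature_radius
  state$theta <- state$theta - omega_c * params$dt +
    sqrt(2 * params$run_rot_diffusion * params$dt) * rnorm(1)
  state$e <- c(cos(state$theta), sin(state$theta), 0)
  state$r <- state$r + params$swim_speed * state$e * params$dt
  state
}

#' Advance one step of a tumble
#'
#' The centroid undergoes translational Brownian motion with coefficient
#' \eqn{D_t} (independent Gaussian displacements per axis of variance
#' \eqn{2 D_t \, dt}); \eqn{z} is reflected at the wall
#' (\eqn{z \leftarrow |z|}); the orientation diffuses fast with
#' \eqn{D_\theta}. A tumble releases the surface-bound flag.
#'
#' @inheritParams step_run_bulk
#' @return The advanced state list.
#' @export
step_tumble <- function(state, params) {
  stopifnot(state$state == "tumble")
  s <- sqrt(2 * params$tumble_diffusion * params$dt)
  dr <- s * rnorm(3)
  state$r[1:2] <- state$r[1:2] + dr[1:2]
  state$r[3] <- abs(state$r[3] + dr[3])
  state$e <- tangent_diffuse_r(state$e, params$tumble_rot_diffusion,
                               params$dt)
  state$theta <- atan2(state$e[2], state$e[1])
  state$surface_bound <- FALSE
  state
}

# --- trajectory generators --------------------------------------------------

resolve_record_every <- function(record_dt, dt) {
  k <- record_dt / dt
  if (abs(k - round(k)) > 1e-8 || round(k) < 1) {
    stop("record_dt must be a positive integer multiple of dt")
  }
  as.integer(round(k))
}

resolve_phenotype <- function(phenotype, params) {
  if (is.numeric(phenotype)) phenotype <- cell_phenotype(phenotype)
  stopifnot(inherits(phenotype, "cell_phenotype"))
  if (!is.null(phenotype$swim_speed)) {
    params$swim_speed <- phenotype$swim_speed
  }
  if (!is.null(phenotype$curvature_radius)) {
    params$curvature_radius <- phenotype$curvature_radius
  }
  list(phenotype = phenotype, params = params)
}

#' Simulate one 3D near-surface trajectory
#'
#' Integrates the two-state run/tumble model in the half-space
#' \eqn{z \ge 0} with the surface entrapment rules: the cell starts at the
#' origin on the surface (surface-bound if its initial state, drawn
#' Bernoulli with probability \code{tb} of tumbling, is a run) with uniform
#' azimuth; runs at the surface circle clockwise with radius \eqn{R}; a run
#' that hits the wall aligns with the plane; tumbles diffuse with \eqn{z}
#' reflected at the wall. State switching is per-step Bernoulli with
#' probabilities \eqn{k_{RT} dt} and \eqn{k_{TR} dt}. Integration stops
#' when \eqn{z} first exceeds \code{z_bulk} (escape) or at \code{t_cap}
#' (censored).
#'
#' @param phenotype a \code{\link{cell_phenotype}} or a bare tumble-bias
#'   value in \code{[0, 1]}.
#' @param params a \code{\link{motility_params}} object.
#' @param seed master integer seed of the ensemble.
#' @param stream trajectory index within the ensemble; \code{(seed, stream)}
#'   determines an independent RNG stream, so ensembles are reproducible
#'   and order-independent.
#' @param record_dt sampling interval of the retained samples, s; must be a
#'   multiple of \code{params$dt}. The final (escape/cap) step is always
#'   retained.
#' @param handedness \code{+1} for the physical clockwise circling,
#'   \code{-1} for the mirrored process (used to verify that reported
#'   statistics are chirality-blind).
#' @return An object of class \code{trajectory}: a data frame with columns
#'   \code{t, x, y, z, ex, ey, ez, theta, phi, state, surface_bound}, with
#'   attributes \code{phenotype}, \code{params}, \code{seed}, \code{stream},
#'   \code{stop_reason} (\code{"escape"} or \code{"censored"}) and
#'   \code{stop_time}.
#' @examples
#' p <- motility_params(t_cap = 30)
#' tr <- simulate_trajectory(0.3, p, seed = 1)
#' attr(tr, "stop_reason")
#' @export
simulate_trajectory <- function(phenotype, params = motility_params(),
                                seed, stream = 1L, record_dt = 0.04,
                                handedness = 1) {
  rp <- resolve_phenotype(phenotype, params)
  params <- rp$params
  tb <- rp$phenotype$tb
  rates <- phenotype_rates(tb, params$char_frequency)
  rec <- resolve_record_every(record_dt, params$dt)
  init_state <- if (tb >= 1) "tumble" else if (tb <= 0) "run" else NA

  res <- .sim_trajectory_cpp(
    tb = if (is.na(init_state)) tb else as.numeric(init_state == "tumble"),
    V = params$swim_speed, Dt = params$tumble_diffusion,
    Dr = params$run_rot_diffusion, Dtheta = params$tumble_rot_diffusion,
    kRT = rates$k_rt, kTR = rates$k_tr,
    R = params$curvature_radius, z_bulk = params$z_bulk,
    dt = params$dt, t_cap = params$t_cap,
    record_every = rec, seed = as.integer(seed),
    stream_id = as.integer(stream), handedness = handedness)

  m <- res$samples
  df <- data.frame(
    t = m[, 1], x = m[, 2], y = m[, 3], z = m[, 4],
    ex = m[, 5], ey = m[, 6], ez = m[, 7], theta = m[, 8],
    phi = acos(pmin(pmax(m[, 7], -1), 1)),
    state = ifelse(m[, 9] == 0, "run", "tumble"),
    surface_bound = m[, 10] == 1,
    stringsAsFactors = FALSE)

  structure(df,
            class = c("trajectory", "data.frame"),
            phenotype = rp$phenotype, params = params,
            seed = as.integer(seed), stream = as.integer(stream),
            stop_reason = res$stop_reason, stop_time = res$stop_time)
}

#' Simulate the strictly planar surface process
#'
#' The planar counterpart of \code{\link{simulate_trajectory}}: the cell
#' never leaves the surface plane. Runs circle clockwise with radius
#' \eqn{R} and rotational diffusion \eqn{D_r}; tumbles are planar Brownian
#' motion with \eqn{D_t} and azimuthal diffusion \eqn{D_\theta}; runs
#' resume with the current azimuth. This process realises the planar
#' Fokker-Planck description whose long-time diffusivity is
#' \code{\link{dxy_closed_form}}, and serves as its stochastic oracle.
#'
#' @inheritParams simulate_trajectory
#' @param duration total simulated time, s.
#' @return A data frame of class \code{surface_process} with columns
#'   \code{t, x, y, theta, state}, and the same provenance attributes as
#'   \code{\link{simulate_trajectory}}.
#' @export
simulate_surface_process <- function(phenotype, params = motility_params(),
                                     duration, seed, stream = 1L,
                                     record_dt = 0.04, handedness = 1) {
  rp <- resolve_phenotype(phenotype, params)
  params <- rp$params
  tb <- rp$phenotype$tb
  rates <- phenotype_rates(tb, params$char_frequency)
  rec <- resolve_record_every(record_dt, params$dt)

  m <- .sim_surface_cpp(
    tb = tb, V = params$swim_speed, Dt = params$tumble_diffusion,
    Dr = params$run_rot_diffusion, Dtheta = params$tumble_rot_diffusion,
    kRT = rates$k_rt, kTR = rates$k_tr, R = params$curvature_radius,
    dt = params$dt, duration = duration, record_every = rec,
    seed = as.integer(seed), stream_id = as.integer(stream),
    handedness = handedness)

  df <- data.frame(
    t = m[, 1], x = m[, 2], y = m[, 3], theta = m[, 4],
    state = ifelse(m[, 5] == 0, "run", "tumble"),
    stringsAsFactors = FALSE)
  structure(df,
            class = c("surface_process", "data.frame"),
            phenotype = rp$phenotype, params = params,
            seed = as.integer(seed), stream = as.integer(stream))
}

#' Extract complete run/tumble dwell intervals from a state sequence
#'
#' Collapses a per-sample state sequence into dwell intervals via run-length
#' encoding. The first and last intervals are dropped because they are
#' censored by the observation window.
#'
#' @param states character vector of \code{"run"} / \code{"tumble"} at
#'   equally spaced samples.
#' @param dt sample spacing, s.
#' @return A data frame with columns \code{state} and \code{duration} (s).
#' @export
state_intervals <- function(states, dt) {
  r <- rle(states)
  n <- length(r$lengths)
  if (n <= 2) {
    return(data.frame(state = character(0), duration = numeric(0)))
  }
  keep <- 2:(n - 1)
  data.frame(state = r$values[keep], duration = r$lengths[keep] * dt,
             stringsAsFactors = FALSE)
}

# --- serialization ----------------------------------------------------------

#' Write / read a trajectory as CSV with a JSON sidecar
#'
#' The CSV holds the sample table; the sidecar (same path with
#' \code{.json} appended) records phenotype, parameters, seed, stream,
#' stop information and a schema version.
#'
#' @param traj a \code{trajectory} or \code{surface_process} object.
#' @param path output CSV path.
#' @return \code{write_trajectory} returns \code{path} invisibly;
#'   \code{read_trajectory} returns the reconstructed object.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  write.csv(df, path, row.names = FALSE)
  ph <- attr(traj, "phenotype")
  meta <- list(
    schema = "surfdwell-trajectory-1",
    kind = class(traj)[1],
    phenotype = list(tb = ph$tb, swim_speed = ph$swim_speed,
                     curvature_radius = ph$curvature_radius),
    params = unclass(attr(traj, "params")),
    seed = attr(traj, "seed"), stream = attr(traj, "stream"),
    stop_reason = attr(traj, "stop_reason"),
    stop_time = attr(traj, "stop_time"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @param path input CSV path (the sidecar must sit next to it).
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ph <- cell_phenotype(meta$phenotype$tb,
                       swim_speed = meta$phenotype$swim_speed,
                       curvature_radius = meta$phenotype$curvature_radius)
  structure(df,
            class = c(meta$kind, "data.frame"),
            phenotype = ph,
            params = validate_params(as.list(meta$params)),
            seed = meta$seed, stream = meta$stream,
            stop_reason = meta$stop_reason, stop_time = meta$stop_time)
}
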