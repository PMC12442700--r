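# Synthetic counterparts of the 3D single-cell tracking measurements:
# camera-rate decimation with optional localization noise, Poisson
# run/tumble interval sequences, and a small deterministic fixture battery.

#' Sample a simulated trajectory the way a tracking camera would
#'
#' Decimates a trajectory to a fixed frame grid (nearest retained sample,
#' no interpolation), truncates at the acquisition cap, and adds optional
#' independent Gaussian localization noise per frame and axis. The frame
#' grid is \eqn{t_k = k / fps} for \eqn{k = 0, 1, \dots} with
#' \eqn{t_k < t_{max}}.
#'
#' @param trajectory a \code{\link{simulate_trajectory}} result (or any
#'   data frame with columns \code{t, x, y, z}).
#' @param fps frame rate, frames/s (default 25, the acquisition rate
#'   emulated by the generator).
#' @param t_max acquisition cap, s (default 207). Frames at or beyond
#'   \code{t_max} are dropped and the track is flagged truncated.
#' @param sigma_xy,sigma_z localization noise standard deviation, um
#'   (defaults 0: noise off).
#' @param seed,stream RNG stream for the noise draws.
#' @return A data frame of class \code{sampled_track} with columns
#'   \code{frame, t, x_obs, y_obs, z_obs}; attributes \code{tb},
#'   \code{truncated}, \code{fps}.
#' @export
camera_sample <- function(trajectory, fps = 25, t_max = 207,
                          sigma_xy = 0, sigma_z = 0, seed = 1L,
                          stream = 1L) {
  if (fps <= 0) stop("fps must be positive")
  tt <- trajectory$t
  if (length(tt) < 2) stop("trajectory too short to sample")
  traj_dt <- median(diff(tt))
  if (traj_dt > 1 / fps + 1e-9) {
    stop("trajectory sampling (", signif(traj_dt, 3),
         " s) is coarser than the frame interval ", signif(1 / fps, 3), " s")
  }
  t_end <- tt[length(tt)]
  truncated <- t_end >= t_max
  n_frames <- min(floor(t_end * fps) + 1, ceiling(t_max * fps))
  frame_t <- (seq_len(n_frames) - 1) / fps
  frame_t <- frame_t[frame_t < t_max]
  idx <- findInterval(frame_t + traj_dt / 2, tt)
  idx[idx < 1] <- 1L

  set.seed(seed_stream(seed, stream))
  n <- length(frame_t)
  df <- data.frame(
    frame = seq_len(n) - 1L,
    t = frame_t,
    x_obs = trajectory$x[idx] + rnorm(n, 0, sigma_xy),
    y_obs = trajectory$y[idx] + rnorm(n, 0, sigma_xy),
    z_obs = trajectory$z[idx] + rnorm(n, 0, sigma_z))
  ph <- attr(trajectory, "phenotype")
  structure(df, class = c("sampled_track", "data.frame"),
            tb = if (!is.null(ph)) ph$tb else NA_real_,
            truncated = truncated, fps = fps)
}

# Fold (seed, stream) into one 31-bit scalar for R's RNG.
seed_stream <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 69621) %%
               2147483647)
}

#' Generate an alternating run/tumble interval sequence
#'
#' Dwell times are exponential with the Poisson rates of the two-state
#' chain (\code{\link{transition_rates}}); the initial state is drawn from
#' the stationary law. Generation continues until the summed duration
#' reaches \code{duration}.
#'
#' @param tb tumble bias, strictly inside \code{(0, 1)}.
#' @param omega characteristic switching frequency, /s.
#' @param duration minimum total duration of the sequence, s.
#' @param seed,stream RNG stream.
#' @return A data frame with columns \code{state} (\code{"run"} /
#'   \code{"tumble"}) and \code{duration} (s); attribute \code{tb}.
#' @export
generate_interval_sequence <- function(tb, omega, duration, seed = 1L,
                                       stream = 1L) {
  if (tb <= 0 || tb >= 1) {
    stop("tb must lie strictly inside (0, 1) for an interval sequence")
  }
  rates <- transition_rates(tb, switching_frequency(tb, omega))
  set.seed(seed_stream(seed, stream))
  state <- if (runif(1) < tb) "tumble" else "run"
  # draw in blocks to avoid growing vectors interval by interval
  mean_dwell <- 0.5 / rates$k_rt + 0.5 / rates$k_tr
  states <- character(0)
  durs <- numeric(0)
  total <- 0
  while (total < duration) {
    n_block <- max(64L, ceiling((duration - total) / mean_dwell))
    seq_states <- rep(c(state, setdiff(c("run", "tumble"), state)),
                      length.out = n_block)
    block <- ifelse(seq_states == "run",
                    rexp(n_block, rates$k_rt),
                    rexp(n_block, rates$k_tr))
    states <- c(states, seq_states)
    durs <- c(durs, block)
    total <- total + sum(block)
    state <- if (seq_states[n_block] == "run") "tumble" else "run"
  }
  cum <- cumsum(durs)
  keep <- seq_len(which(cum >= duration)[1])
  structure(data.frame(state = states[keep], duration = durs[keep],
                       stringsAsFactors = FALSE),
            tb = tb, class = c("interval_sequence", "data.frame"))
}

#' Write a small deterministic fixture battery
#'
#' Generates one short trajectory per scenario (tumble bias 0, 0.25, 0.5
#' and 1), one camera-sampled track and one interval sequence, all under a
#' reduced time cap so the battery stays small. Used by unit tests and
#' documentation examples.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed; the same seed yields byte-identical files.
#' @param t_cap per-trajectory time cap of the battery, s.
#' @return The directory path, invisibly. Files written:
#'   \code{traj_tb<percent>.csv} (+ JSON sidecars), \code{track_tb25.csv},
#'   \code{intervals_tb25.csv}, \code{manifest.json}.
#' @export
make_fixture_suite <- function(dir, seed = 1L, t_cap = 20) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- motility_params(t_cap = t_cap)
  tbs <- c(0, 0.25, 0.5, 1)
  files <- character(0)
  for (i in seq_along(tbs)) {
    tr <- simulate_trajectory(tbs[i], params, seed = seed, stream = i)
    f <- file.path(dir, sprintf("traj_tb%02d.csv", round(100 * tbs[i])))
    write_trajectory(tr, f)
    files <- c(files, basename(f), paste0(basename(f), ".json"))
    if (tbs[i] == 0.25) {
      trk <- camera_sample(tr, seed = seed, stream = 100L + i)
      fk <- file.path(dir, "track_tb25.csv")
      write.csv(as.data.frame(trk), fk, row.names = FALSE)
      files <- c(files, basename(fk))
    }
  }
  iv <- generate_interval_sequence(0.25, motility_params()$char_frequency,
                                   duration = 200, seed = seed,
                                   stream = 999L)
  fi <- file.path(dir, "intervals_tb25.csv")
  write.csv(as.data.frame(iv), fi, row.names = FALSE)
  files <- c(files, basename(fi))
  manifest <- list(schema = "surfdwell-fixtures-1", seed = seed,
                   t_cap = t_cap, scenarios = tbs, files = sort(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
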