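# Surface residence time extraction. An arrival-escape event is the
# sequence z > z_bulk -> z < z_surface -> z > z_bulk; the residence time
# T_s is the interval between the first and last crossings of z_surface.
# Simulated trajectories start on the surface, so their clock starts at 0.

#' Detect the surface residence event of one track
#'
#' Scans the height series for an arrival-escape event under the two
#' height criteria. Conventions: the start time is the first sample with
#' \code{z < z_surface} (time of the first sample if the track starts
#' below it); the escape time is the first later sample with
#' \code{z > z_bulk}; \eqn{T_s} is the time of the last sample below
#' \code{z_surface} before escape minus the start time. Crossing times use
#' the first sample on the far side, without interpolation, so the same
#' rule applies to simulated and camera-sampled tracks. If no escape
#' occurs before the track ends the event is censored and \eqn{T_s} is
#' undefined (\code{NA}).
#'
#' @param track a data frame with monotone \code{t} and a height column
#'   \code{z} (or \code{z_obs} for camera-sampled tracks).
#' @param z_surface surface-interaction height criterion, um.
#' @param z_bulk bulk height criterion, um.
#' @return A one-row data frame of class \code{surface_event}: columns
#'   \code{t_s} (s, \code{NA} if censored), \code{censored},
#'   \code{no_event} (track never went below \code{z_surface}),
#'   \code{tb}, \code{t_start}, \code{t_last_below}, \code{t_escape}.
#' @examples
#' trk <- data.frame(t = 0:5, z = c(9, 5, 2, 1, 2, 9))
#' detect_residence(trk, 3, 8)$t_s   # 2 s
#' @export
detect_residence <- function(track, z_surface = 3, z_bulk = 8) {
  z <- if (!is.null(track$z)) track$z else track$z_obs
  tt <- track$t
  if (is.null(z) || is.null(tt)) stop("track must have columns t and z")
  if (any(diff(tt) < 0)) stop("track time must be monotone")
  if (any(!is.finite(z))) stop("track heights must be finite")

  ph <- attr(track, "phenotype")
  tb <- if (!is.null(ph)) ph$tb else
    if (!is.null(attr(track, "tb"))) attr(track, "tb") else NA_real_

  empty <- data.frame(t_s = NA_real_, censored = FALSE, no_event = TRUE,
                      tb = tb, t_start = NA_real_, t_last_below = NA_real_,
                      t_escape = NA_real_)
  class(empty) <- c("surface_event", "data.frame")

  i_start <- which(z < z_surface)[1]
  if (is.na(i_start)) return(empty)

  after <- seq(i_start, length(z))
  i_escape <- after[which(z[after] > z_bulk)[1]]

  if (is.na(i_escape)) {
    ev <- data.frame(t_s = NA_real_, censored = TRUE, no_event = FALSE,
                     tb = tb, t_start = tt[i_start],
                     t_last_below = NA_real_, t_escape = NA_real_)
  } else {
    below <- which(z < z_surface & seq_along(z) < i_escape)
    i_last <- below[length(below)]
    ev <- data.frame(t_s = tt[i_last] - tt[i_start], censored = FALSE,
                     no_event = FALSE, tb = tb, t_start = tt[i_start],
                     t_last_below = tt[i_last], t_escape = tt[i_escape])
  }
  class(ev) <- c("surface_event", "data.frame")
  ev
}

#' Bin surface events by tumble bias and summarise residence times
#'
#' Censored events are excluded from the per-bin means (their fraction is
#' reported instead), mirroring how capped acquisitions underestimate the
#' residence time of rarely-tumbling cells. Bins with no uncensored events
#' are emitted with \code{NA} summaries.
#'
#' @param events a data frame of stacked \code{\link{detect_residence}}
#'   rows (one per track).
#' @param bin_width tumble-bias bin width (default 0.05); bins partition
#'   \code{[0, 1]}.
#' @return A data frame of class \code{residence_curve}: columns
#'   \code{tb_center}, \code{mean_ts}, \code{sem_ts}, \code{n},
#'   \code{n_censored}, \code{censored_fraction}.
#' @export
residence_curve <- function(events, bin_width = 0.05) {
  if (nrow(events) == 0) {
    out <- data.frame(tb_center = numeric(0), mean_ts = numeric(0),
                      sem_ts = numeric(0), n = integer(0),
                      n_censored = integer(0),
                      censored_fraction = numeric(0))
    class(out) <- c("residence_curve", "data.frame")
    return(out)
  }
  events <- events[!events$no_event, , drop = FALSE]
  edges <- seq(0, 1, by = bin_width)
  centers <- round(edges[-length(edges)] + bin_width / 2, 10)
  bin <- cut(events$tb, breaks = edges, include.lowest = TRUE,
             labels = FALSE)
  out <- do.call(rbind, lapply(seq_along(centers), function(b) {
    ev <- events[which(bin == b), , drop = FALSE]
    if (nrow(ev) == 0) return(NULL)
    ok <- ev[!ev$censored, , drop = FALSE]
    n_ok <- nrow(ok)
    data.frame(
      tb_center = centers[b],
      mean_ts = if (n_ok > 0) mean(ok$t_s) else NA_real_,
      sem_ts = if (n_ok > 1) sd(ok$t_s) / sqrt(n_ok) else NA_real_,
      n = n_ok,
      n_censored = sum(ev$censored),
      censored_fraction = sum(ev$censored) / nrow(ev))
  }))
  class(out) <- c("residence_curve", "data.frame")
  out
}

#' Locate the knee between the decreasing region and the plateau
#'
#' Operationalises the transition point of the mean residence-time curve:
#' the plateau level is the mean of bin means with centers inside
#' \code{plateau_range}, and the transition is the smallest bin center
#' whose mean \eqn{T_s} is within \code{tolerance} (relative) of that
#' level, i.e. \eqn{\bar T_s \le (1 + tolerance) \times} plateau.
#'
#' @param curve a \code{\link{residence_curve}} result.
#' @param plateau_range numeric length-2, the half-open interval of bin
#'   centers defining the plateau (default \code{(0.5, 1]}).
#' @param tolerance relative tolerance above the plateau level
#'   (default 0.25).
#' @return The transition tumble bias (a bin center), or \code{NA} with a
#'   warning if no bin qualifies.
#' @export
transition_point <- function(curve, plateau_range = c(0.5, 1),
                             tolerance = 0.25) {
  ok <- curve[!is.na(curve$mean_ts), , drop = FALSE]
  in_plateau <- ok$tb_center > plateau_range[1] &
    ok$tb_center <= plateau_range[2]
  if (nrow(ok) < 3 || !any(in_plateau)) {
    stop("curve must have >= 3 populated bins including the plateau range")
  }
  plateau <- mean(ok$mean_ts[in_plateau])
  hit <- which(ok$mean_ts <= (1 + tolerance) * plateau)
  if (length(hit) == 0) {
    warning("no bin within tolerance of the plateau level")
    return(NA_real_)
  }
  ok$tb_center[min(hit)]
}

#' Simulate an ensemble and extract its surface events
#'
#' Convenience driver used by the analysis pipeline: simulates
#' \code{n_per_bin} trajectories for each tumble-bias bin center, detects
#' the residence event of each, and (optionally) retains the planar
#' surface-residence segment for MSD analysis.
#'
#' @param tb_centers tumble-bias values (one ensemble per value).
#' @param n_per_bin trajectories per value.
#' @param params a \code{\link{motility_params}} object.
#' @param seed master seed; trajectory \code{j} of bin \code{i} uses a
#'   stream derived from \code{(seed, i, j)}.
#' @param record_dt trajectory sampling interval, s.
#' @param keep_segments if \code{TRUE}, returns the \code{(t, x, y)}
#'   samples of each uncensored surface-residence window
#'   \code{[t_start, t_last_below]}.
#' @return A list with \code{events} (stacked event rows, plus columns
#'   \code{bin} and \code{stream}) and, if requested, \code{segments}
#'   (a list of data frames, one per uncensored event, with attribute
#'   \code{tb}).
#' @export
simulate_residence_ensemble <- function(tb_centers, n_per_bin,
                                        params = motility_params(),
                                        seed = 1L, record_dt = 0.04,
                                        keep_segments = FALSE) {
  events <- vector("list", length(tb_centers) * n_per_bin)
  segments <- if (keep_segments) list() else NULL
  k <- 0L
  for (i in seq_along(tb_centers)) {
    for (j in seq_len(n_per_bin)) {
      k <- k + 1L
      stream <- i * 100000L + j
      tr <- simulate_trajectory(tb_centers[i], params, seed = seed,
                                stream = stream, record_dt = record_dt)
      ev <- detect_residence(tr, params$z_surface, params$z_bulk)
      ev$bin <- i
      ev$stream <- stream
      events[[k]] <- ev
      if (keep_segments && !ev$censored && !ev$no_event) {
        sel <- tr$t >= ev$t_start & tr$t <= ev$t_last_below
        seg <- data.frame(t = tr$t[sel] - ev$t_start,
                          x = tr$x[sel], y = tr$y[sel])
        attr(seg, "tb") <- tb_centers[i]
        segments[[length(segments) + 1L]] <- seg
      }
    }
  }
  out <- list(events = do.call(rbind, events))
  if (keep_segments) out$segments <- segments
  out
}
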