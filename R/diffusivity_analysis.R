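# Ensemble MSD during surface residence, three-phase fitting-window
# selection on the running diffusion constant (RDC = MSD/4t), and the
# linear-MSD fits for D_xy, D_t and the switching-frequency curve.

#' Ensemble mean-squared displacement of planar segments
#'
#' Computes the ensemble MSD over a set of planar paths with the origin at
#' each segment's start: \eqn{MSD(\tau)} is the mean of
#' \eqn{|r(\tau) - r(0)|^2} over the segments whose duration reaches
#' \eqn{\tau} (one displacement per segment per lag). This is the
#' estimator of choice for short, non-stationary residence segments; the
#' initial relaxation it retains is exactly what the three-phase rule
#' (\code{\link{rdc_phases}}) excises.
#'
#' @param segments a list of data frames with columns \code{t} (starting
#'   at 0, equally spaced), \code{x}, \code{y}.
#' @param lag_grid lags \eqn{\tau} at which to evaluate, s; must be
#'   multiples of the segment sampling interval.
#' @return A data frame of class \code{msd_curve}: columns \code{lag},
#'   \code{msd} (um^2, \code{NA} where no segment reaches the lag) and
#'   \code{n} (contributing segments).
#' @export
ensemble_msd <- function(segments, lag_grid) {
  if (!length(segments)) stop("no segments supplied")
  dt <- median(diff(segments[[1]]$t))
  lag_idx <- as.integer(round(lag_grid / dt))
  if (any(abs(lag_grid / dt - lag_idx) > 1e-6)) {
    stop("lag_grid must be multiples of the segment sampling interval")
  }
  sums <- numeric(length(lag_grid))
  counts <- integer(length(lag_grid))
  for (seg in segments) {
    n <- nrow(seg)
    ok <- which(lag_idx + 1L <= n)
    if (!length(ok)) next
    ii <- lag_idx[ok] + 1L
    d2 <- (seg$x[ii] - seg$x[1])^2 + (seg$y[ii] - seg$y[1])^2
    sums[ok] <- sums[ok] + d2
    counts[ok] <- counts[ok] + 1L
  }
  msd <- ifelse(counts > 0, sums / counts, NA_real_)
  structure(data.frame(lag = lag_grid, msd = msd, n = counts),
            class = c("msd_curve", "data.frame"))
}

#' Fit the tumble translational diffusion coefficient
#'
#' Least-squares slope of \eqn{MSD = 4 D_t \, t} through the origin, the
#' free-Brownian law obeyed by tumble-locked cells.
#'
#' @param msd an \code{\link{ensemble_msd}} curve.
#' @return \eqn{D_t}, um^2/s.
#' @export
fit_dt <- function(msd) {
  ok <- !is.na(msd$msd) & msd$lag > 0
  if (sum(ok) < 1 || length(unique(msd$lag[ok])) < 1) {
    stop("need at least one populated positive lag")
  }
  x <- 4 * msd$lag[ok]
  sum(x * msd$msd[ok]) / sum(x * x)
}

#' Select the MSD fitting window by the three-phase RDC rule
#'
#' The running diffusion constant \eqn{RDC(t) = MSD(t) / 4t} shows three
#' phases: (I) an initial relaxation while the process decorrelates, (II) a
#' flat stretch where the motion is diffusive, and (III) a data-starved
#' tail. The RDC is first averaged over sliding windows of
#' \code{window_s} seconds (which tames per-lag noise); the fitting
#' window opens at the earliest lag from which the relative change
#' between consecutive window averages stays below \code{slope_tol} for
#' at least a further \code{window_s} of lags (first sustained
#' convergence), and closes at the last lag whose segment count still
#' reaches \code{count_floor}.
#'
#' @param msd an \code{\link{ensemble_msd}} curve with counts.
#' @param slope_tol relative windowed RDC change tolerated in phase II
#'   (default 0.05).
#' @param count_floor minimum contributing segments per lag; default
#'   \code{max(50, 0.05 * max(msd$n))}.
#' @param window_s sliding-window length, s (default 1).
#' @return A list with \code{t_lo}, \code{t_hi} (s).
#' @export
rdc_phases <- function(msd, slope_tol = 0.05, count_floor = NULL,
                       window_s = 1) {
  if (is.null(count_floor)) count_floor <- max(50, 0.05 * max(msd$n))
  ok <- which(!is.na(msd$msd) & msd$lag > 0 & msd$n >= count_floor)
  if (length(ok) < 3) {
    stop("phase selection failed: only ", length(ok),
         " lags reach the count floor ", count_floor)
  }
  lag <- msd$lag[ok]
  rdc <- msd$msd[ok] / (4 * lag)
  t_hi <- lag[length(lag)]

  # windowed mean of the RDC over [t, t + window_s], then the relative
  # change between the window at t and the next, non-overlapping one
  n <- length(lag)
  sm <- vapply(seq_len(n), function(i) {
    mean(rdc[lag >= lag[i] & lag <= lag[i] + window_s])
  }, numeric(1))
  valid <- which(lag + 2 * window_s <= t_hi + 1e-9)
  if (!length(valid)) {
    stop("phase selection failed: fewer than ", 2 * window_s,
         " s of lags above the count floor ", count_floor)
  }
  flat <- vapply(valid, function(i) {
    j <- which(lag >= lag[i] + window_s)[1]
    abs(sm[j] - sm[i]) / sm[i] < slope_tol
  }, logical(1))
  # first lag from which flatness is sustained over a further window_s
  sustained <- vapply(seq_along(valid), function(k) {
    span <- which(lag[valid] >= lag[valid[k]] &
                    lag[valid] <= lag[valid[k]] + window_s)
    all(flat[span])
  }, logical(1))
  i_lo <- valid[which(sustained)[1]]
  if (is.na(i_lo)) {
    stop("phase selection failed: RDC never converges to a horizontal ",
         "line at slope_tol = ", slope_tol)
  }
  t_lo <- lag[i_lo]
  if (t_hi <= t_lo) {
    stop("phase selection failed: empty window [", t_lo, ", ", t_hi, "]")
  }
  list(t_lo = t_lo, t_hi = t_hi)
}

#' Fit the surface diffusivity over a fitting window
#'
#' Unweighted least-squares fit of \eqn{MSD = 4 D_{xy} t} through the
#' origin, restricted to lags inside the window.
#'
#' @param msd an \code{\link{ensemble_msd}} curve.
#' @param window a list or numeric pair \code{(t_lo, t_hi)}, s.
#' @return A list of class \code{diffusivity_result}: \code{dxy}
#'   (um^2/s), \code{window}, \code{residual} (root-mean-square fit
#'   residual, um^2), \code{n_lags}.
#' @export
fit_dxy <- function(msd, window) {
  if (is.list(window)) window <- c(window$t_lo, window$t_hi)
  sel <- which(!is.na(msd$msd) & msd$lag >= window[1] &
                 msd$lag <= window[2])
  if (length(sel) < 2) stop("fitting window covers fewer than 2 lags")
  x <- 4 * msd$lag[sel]
  y <- msd$msd[sel]
  dxy <- sum(x * y) / sum(x * x)
  structure(list(dxy = dxy, window = window,
                 residual = sqrt(mean((y - dxy * x)^2)),
                 n_lags = length(sel)),
            class = "diffusivity_result")
}

#' Fit the characteristic switching frequency
#'
#' Least-squares fit of the symmetric quadratic
#' \eqn{SF = \omega/4 - \omega (TB - 1/2)^2} to observed
#' (tumble bias, switching frequency) pairs; \eqn{\omega} enters linearly,
#' so the estimate is the ratio of cross- to auto-moments of the basis
#' \eqn{TB (1 - TB)}.
#'
#' @param points a data frame with columns \code{tb} and \code{sf}.
#' @return \eqn{\omega}, /s.
#' @export
fit_sf_curve <- function(points) {
  if (nrow(points) < 3 || length(unique(points$tb)) < 2) {
    stop("need >= 3 points spanning more than one tumble bias")
  }
  basis <- points$tb * (1 - points$tb)
  if (all(basis == 0)) stop("all points at frozen tumble bias")
  sum(basis * points$sf) / sum(basis * basis)
}

#' Exponential rate estimates of run and tumble dwell intervals
#'
#' Pools interval sequences by tumble-bias bin and, per bin and state,
#' returns the maximum-likelihood exponential rate (1/mean) and a
#' normalized histogram of the dwell times.
#'
#' @param sequences a list of \code{\link{generate_interval_sequence}}
#'   results (or data frames with columns \code{state}, \code{duration}
#'   and attribute \code{tb}).
#' @param tb_bins bin edges over tumble bias (default width 0.05 on
#'   \code{[0, 1]}).
#' @param n_breaks histogram bins per PDF (default 30).
#' @return A data frame of class \code{interval_pdfs} with one row per
#'   (bin, state): columns \code{tb_center}, \code{state}, \code{rate}
#'   (/s), \code{n}; attribute \code{histograms} holds the per-row density
#'   tables (\code{mid}, \code{density}).
#' @export
interval_pdfs <- function(sequences, tb_bins = seq(0, 1, 0.05),
                          n_breaks = 30) {
  tbs <- vapply(sequences, function(s) attr(s, "tb"), numeric(1))
  bin <- cut(tbs, breaks = tb_bins, include.lowest = TRUE, labels = FALSE)
  centers <- tb_bins[-length(tb_bins)] + diff(tb_bins) / 2
  rows <- list()
  hists <- list()
  for (b in sort(unique(bin))) {
    pooled <- do.call(rbind, lapply(sequences[bin == b], as.data.frame))
    for (st in c("run", "tumble")) {
      d <- pooled$duration[pooled$state == st]
      if (!length(d)) next
      h <- graphics::hist(d, breaks = n_breaks, plot = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        tb_center = centers[b], state = st, rate = 1 / mean(d),
        n = length(d))
      hists[[length(hists) + 1L]] <- data.frame(mids = h$mids,
                                                density = h$density)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "histograms") <- hists
  class(out) <- c("interval_pdfs", "data.frame")
  out
}

#' Surface diffusivity versus tumble bias from a simulated ensemble
#'
#' End-to-end driver for one radius of curvature: simulates an ensemble
#' per tumble-bias bin, extracts uncensored surface-residence segments,
#' computes the ensemble MSD, selects the fitting window by the
#' three-phase rule and fits \eqn{D_{xy}}. Each bin is also checked
#' against the heuristic that a trustworthy window should extend past
#' twice the bin's mean residence time (column \code{window_ok}).
#'
#' @param tb_centers tumble-bias bin centers.
#' @param n_per_bin trajectories per bin.
#' @param params a \code{\link{motility_params}} object.
#' @param seed master seed.
#' @param record_dt trajectory sampling interval, s.
#' @param max_lag largest MSD lag evaluated, s.
#' @param slope_tol,count_floor passed to \code{\link{rdc_phases}}.
#' @return A data frame of class \code{dxy_curve}: columns
#'   \code{tb_center}, \code{dxy}, \code{t_lo}, \code{t_hi},
#'   \code{n_segments}, \code{mean_ts}, \code{window_ok}.
#' @export
dxy_curve <- function(tb_centers, n_per_bin, params = motility_params(),
                      seed = 1L, record_dt = 0.04, max_lag = 40,
                      slope_tol = 0.05, count_floor = NULL) {
  rows <- vector("list", length(tb_centers))
  for (i in seq_along(tb_centers)) {
    ens <- simulate_residence_ensemble(tb_centers[i], n_per_bin, params,
                                       seed = seed + i,
                                       record_dt = record_dt,
                                       keep_segments = TRUE)
    segs <- ens$segments
    ev <- ens$events
    mean_ts <- mean(ev$t_s[!ev$censored & !ev$no_event], na.rm = TRUE)
    if (length(segs) < 2) {
      rows[[i]] <- data.frame(tb_center = tb_centers[i], dxy = NA_real_,
                              t_lo = NA_real_, t_hi = NA_real_,
                              n_segments = length(segs),
                              mean_ts = mean_ts,
                              slope_tol_used = NA_real_,
                              window_ok = FALSE)
      next
    }
    lag_grid <- seq(record_dt, max_lag, by = record_dt)
    msd <- ensemble_msd(segs, lag_grid)
    # progressively relax the flatness tolerance if the sampling noise of
    # a bin defeats the nominal one; the tolerance used is reported
    win <- NULL
    tol <- slope_tol
    while (is.null(win) && tol <= 4 * slope_tol + 1e-12) {
      win <- tryCatch(rdc_phases(msd, slope_tol = tol,
                                 count_floor = count_floor),
                      error = function(e) NULL)
      if (is.null(win)) tol <- tol * 2
    }
    if (is.null(win)) {
      rows[[i]] <- data.frame(tb_center = tb_centers[i], dxy = NA_real_,
                              t_lo = NA_real_, t_hi = NA_real_,
                              n_segments = length(segs),
                              mean_ts = mean_ts, slope_tol_used = NA_real_,
                              window_ok = FALSE)
      next
    }
    fit <- fit_dxy(msd, win)
    rows[[i]] <- data.frame(tb_center = tb_centers[i], dxy = fit$dxy,
                            t_lo = win$t_lo, t_hi = win$t_hi,
                            n_segments = length(segs), mean_ts = mean_ts,
                            slope_tol_used = tol,
                            window_ok = win$t_hi > 2 * mean_ts)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("dxy_curve", "data.frame")
  out
}
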