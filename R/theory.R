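# Closed-form planar surface diffusivity of the two-state process, the
# Taylor-Kubo (velocity-autocorrelation) estimator used as its stochastic
# oracle, peak location, and the curvature correction-factor fit.

#' Closed-form planar surface diffusivity
#'
#' Long-time effective diffusion coefficient of the planar run/tumble
#' process (perpetual clockwise circling runs, diffusive tumbles),
#' obtained from the planar Fokker-Planck description via the
#' velocity-correlation route:
#' \deqn{D_{xy} = TB \, D_t + \frac{V^2}{2} (1 - TB)
#'   \frac{(D_\theta + k_{TR})(D_r k_{TR} + D_\theta k_{RT} + D_r D_\theta)}
#'        {(D_\theta + k_{TR})^2 V^2 / R^2 +
#'         (D_r k_{TR} + D_\theta k_{RT} + D_r D_\theta)^2}}
#' with \eqn{k_{RT} = \omega TB / 2}, \eqn{k_{TR} = \omega (1 - TB) / 2}.
#' The two terms are the tumble and run contributions. The endpoints are
#' analytic limits: \eqn{TB = 1} gives \eqn{D_t}; \eqn{TB = 0} gives
#' \eqn{(V^2/2) D_r / (V^2 / R^2 + D_r^2)} (the common factor
#' \eqn{(D_\theta + k_{TR})^2} cancels as \eqn{k_{RT} \to 0}).
#'
#' @param tb tumble bias in \code{[0, 1]} (vectorised).
#' @param params a \code{\link{motility_params}} object.
#' @param r_scale multiplier applied to the curvature radius (the
#'   correction factor \eqn{C}; default 1).
#' @return \eqn{D_{xy}} in um^2/s, with attributes \code{tumble_term} and
#'   \code{run_term} carrying the two contributions separately.
#' @examples
#' dxy_closed_form(1, motility_params())   # = D_t
#' @export
dxy_closed_form <- function(tb, params = motility_params(), r_scale = 1) {
  stopifnot(all(tb >= 0), all(tb <= 1), r_scale > 0)
  V <- params$swim_speed
  Dt <- params$tumble_diffusion
  Dr <- params$run_rot_diffusion
  Dth <- params$tumble_rot_diffusion
  omega <- params$char_frequency
  R <- params$curvature_radius * r_scale

  k_rt <- omega * tb / 2
  k_tr <- omega * (1 - tb) / 2
  A <- Dth + k_tr
  B <- Dr * k_tr + Dth * k_rt + Dr * Dth
  run_num <- A * B
  run_den <- A^2 * V^2 / R^2 + B^2

  run <- (V^2 / 2) * (1 - tb) * run_num / run_den
  # tb = 1 with Dth = 0 would give 0/0; the (1 - tb) factor makes the run
  # term vanish there regardless
  run[tb == 1] <- 0
  # tb = 0 limit: cancel the common (Dth + k_tr)^2 factor (B -> Dr * A)
  at0 <- tb == 0
  if (any(at0)) run[at0] <- (V^2 / 2) * Dr / (V^2 / R^2 + Dr^2)

  tumble <- tb * Dt
  structure(tumble + run, tumble_term = tumble, run_term = run)
}

#' Taylor-Kubo diffusivity from velocity (or displacement) series
#'
#' Estimates the long-time planar diffusivity of a stationary process from
#' the empirical velocity autocorrelation,
#' \eqn{D = \frac{1}{2} \int_0^\infty \langle \vec v(0) \cdot \vec v(t)
#' \rangle \, dt} (the normalization matching \eqn{MSD = 4 D t} in two
#' dimensions), by trapezoidal integration to a cutoff where the
#' correlation has decayed into noise. A second estimator, the long-lag
#' limit of \eqn{MSD / 4t} computed from the same series, is returned
#' alongside; the two must agree for a genuinely diffusive input.
#'
#' @param vel a list of data frames with columns \code{t}, \code{vx},
#'   \code{vy} (equally spaced velocity samples of independent
#'   realisations), or a single such data frame.
#' @param cutoff integration cutoff, s; by default the first lag at which
#'   the autocorrelation drops below \code{noise_frac} of its initial
#'   value and stays there for ten consecutive lags.
#' @param noise_frac fraction of \eqn{C(0)} regarded as noise floor
#'   (default 0.01).
#' @param max_lag_s largest autocorrelation lag evaluated, s (default:
#'   the full series length). Correlations decay on the run/tumble
#'   timescale, so a cap well above it loses nothing and saves work.
#' @return A list of class \code{taylor_kubo}: \code{dxy} (the VACF
#'   estimate, um^2/s), \code{dxy_msd} (the MSD/4t cross-estimate),
#'   \code{cutoff}, \code{diverged} (\code{TRUE} when the correlation
#'   shows no decay within the series, as for ballistic input).
#' @export
taylor_kubo_dxy <- function(vel, cutoff = NULL, noise_frac = 0.01,
                            max_lag_s = NULL) {
  if (is.data.frame(vel)) vel <- list(vel)
  dt <- median(diff(vel[[1]]$t))
  n_lag <- min(vapply(vel, nrow, integer(1))) - 1L
  if (!is.null(max_lag_s)) n_lag <- min(n_lag, as.integer(max_lag_s / dt))

  # ensemble + time averaged VACF via FFT:
  # C(k dt) = < v(t) . v(t + k dt) >
  acf_sum <- numeric(n_lag + 1L)
  acf_n <- numeric(n_lag + 1L)
  for (v in vel) {
    n <- nrow(v)
    k_idx <- n + 0:min(n_lag, n - 1L)
    # convolve(x, x, type = "open") is the raw autocorrelation sequence
    # with lag 0 at index n (convolve reverses its second argument)
    sx <- stats::convolve(v$vx, v$vx, type = "open")[k_idx]
    sy <- stats::convolve(v$vy, v$vy, type = "open")[k_idx]
    kk <- seq_along(k_idx)
    acf_sum[kk] <- acf_sum[kk] + sx + sy
    acf_n[kk] <- acf_n[kk] + n - (kk - 1L)
  }
  C <- acf_sum / acf_n
  lags <- (0:n_lag) * dt

  if (is.null(cutoff)) {
    below <- abs(C) < noise_frac * C[1]
    run10 <- which(vapply(seq_len(max(1, length(below) - 9L)), function(i) {
      all(below[i:min(length(below), i + 9L)])
    }, logical(1)))
    if (!length(run10)) {
      # no decay to the noise floor within the series
      tail_mean <- mean(C[max(1, n_lag - 9L):(n_lag + 1L)])
      if (tail_mean > 0.5 * C[1]) {
        return(structure(list(dxy = NA_real_, dxy_msd = NA_real_,
                              cutoff = NA_real_, diverged = TRUE),
                         class = "taylor_kubo"))
      }
      cutoff <- lags[length(lags)]
    } else {
      cutoff <- lags[run10[1]]
    }
  }

  keep <- lags <= cutoff
  integral <- sum(diff(lags[keep]) *
                    (C[keep][-1] + C[keep][-sum(keep)]) / 2)
  dxy <- integral / 2

  # cross-estimate: ensemble MSD of the integrated series, slope of the
  # last half of the lag range
  msd <- numeric(n_lag)
  cnt <- numeric(n_lag)
  for (v in vel) {
    x <- cumsum(c(0, v$vx[-nrow(v)])) * dt
    y <- cumsum(c(0, v$vy[-nrow(v)])) * dt
    n <- length(x)
    ks <- seq_len(min(n - 1L, n_lag))
    i0 <- 1L
    msd[ks] <- msd[ks] + (x[ks + i0] - x[i0])^2 + (y[ks + i0] - y[i0])^2
    cnt[ks] <- cnt[ks] + 1
  }
  msd <- msd / cnt
  tl <- lags[-1]
  half <- tl >= max(tl) / 2
  dxy_msd <- sum(4 * tl[half] * msd[half]) / sum((4 * tl[half])^2)

  structure(list(dxy = dxy, dxy_msd = dxy_msd, cutoff = cutoff,
                 diverged = FALSE),
            class = "taylor_kubo")
}

#' Locate the peak of a diffusivity-versus-tumble-bias curve
#'
#' Grid argmax refined by a local quadratic through the maximal point and
#' its neighbours. A maximum at the grid boundary is flagged rather than
#' refined.
#'
#' @param tb grid of tumble-bias values.
#' @param value curve values at the grid (e.g. \eqn{D_{xy}}).
#' @return A list: \code{tb_peak}, \code{value_peak} (parabola apex),
#'   \code{boundary} (\code{TRUE} if the grid argmax sits on an edge, in
#'   which case no refinement is applied).
#' @export
peak_tb <- function(tb, value) {
  stopifnot(length(tb) == length(value))
  keep <- !is.na(value) & !is.na(tb)
  tb <- tb[keep]; value <- value[keep]
  stopifnot(length(tb) >= 5)
  o <- order(tb)
  tb <- tb[o]; value <- value[o]
  i <- which.max(value)
  if (i == 1L || i == length(tb)) {
    return(list(tb_peak = tb[i], value_peak = value[i], boundary = TRUE))
  }
  # three-point parabola; equal spacing not assumed
  x <- tb[(i - 1):(i + 1)]
  y <- value[(i - 1):(i + 1)]
  fit <- coef(lm(y ~ x + I(x^2)))
  if (!is.finite(fit[3]) || fit[3] >= 0) {
    return(list(tb_peak = tb[i], value_peak = value[i], boundary = FALSE))
  }
  apex <- -fit[2] / (2 * fit[3])
  list(tb_peak = unname(apex),
       value_peak = unname(fit[1] + fit[2] * apex + fit[3] * apex^2),
       boundary = FALSE)
}

#' Fit the curvature correction factor
#'
#' The planar closed form assumes the cell circles for the whole of every
#' run, whereas in the 3D simulation brief off-surface runs are straighter;
#' the mismatch is absorbed by scaling the radius of curvature to
#' \eqn{C R}. \eqn{C} is found by grid search (then parabolic refinement)
#' minimizing the squared difference between a simulated
#' \eqn{D_{xy}(TB)} curve and \code{\link{dxy_closed_form}} evaluated with
#' \code{r_scale = C} at the same bin centers.
#'
#' @param sim_curve a data frame with columns \code{tb_center} and
#'   \code{dxy} (a \code{\link{dxy_curve}} result).
#' @param params the \code{\link{motility_params}} the curve was
#'   simulated under.
#' @param c_grid candidate values of \eqn{C} (default 1.00 to 2.00,
#'   step 0.01).
#' @param tb_range fit restricted to bin centers inside this closed
#'   interval (default \code{[0.1, 0.9]}): the low-TB end is dominated by
#'   censoring and the high-TB end by the tumble term, where \eqn{C} has
#'   no leverage.
#' @return A list: \code{c_factor}, \code{sse}, \code{boundary}
#'   (\code{TRUE} if the grid optimum sits on an edge of \code{c_grid}).
#' @export
fit_correction <- function(sim_curve, params = motility_params(),
                           c_grid = seq(1, 2, by = 0.01),
                           tb_range = c(0.1, 0.9)) {
  sel <- !is.na(sim_curve$dxy) &
    sim_curve$tb_center >= tb_range[1] & sim_curve$tb_center <= tb_range[2]
  if (sum(sel) < 6) stop("need >= 6 populated bins inside tb_range")
  tb <- sim_curve$tb_center[sel]
  obs <- sim_curve$dxy[sel]
  sse <- vapply(c_grid, function(cc) {
    sum((obs - as.numeric(dxy_closed_form(tb, params, r_scale = cc)))^2)
  }, numeric(1))
  i <- which.min(sse)
  if (i == 1L || i == length(c_grid)) {
    return(list(c_factor = c_grid[i], sse = sse[i], boundary = TRUE))
  }
  x <- c_grid[(i - 1):(i + 1)]
  y <- sse[(i - 1):(i + 1)]
  fit <- coef(lm(y ~ x + I(x^2)))
  c_ref <- if (is.finite(fit[3]) && fit[3] > 0) {
    unname(-fit[2] / (2 * fit[3]))
  } else {
    c_grid[i]
  }
  list(c_factor = c_ref, sse = sse[i], boundary = FALSE)
}

#' Closed-form diffusivity curve over a tumble-bias grid
#'
#' @param params a \code{\link{motility_params}} object.
#' @param tb_grid grid of tumble-bias values (default 0 to 1 step 0.005).
#' @param r_scale correction factor applied to the radius (default 1).
#' @return A data frame of class \code{theory_curve}: columns \code{tb},
#'   \code{dxy}, \code{tumble_term}, \code{run_term}.
#' @export
theory_curve <- function(params = motility_params(),
                         tb_grid = seq(0, 1, by = 0.005), r_scale = 1) {
  d <- dxy_closed_form(tb_grid, params, r_scale = r_scale)
  structure(data.frame(tb = tb_grid, dxy = as.numeric(d),
                       tumble_term = attr(d, "tumble_term"),
                       run_term = attr(d, "run_term")),
            class = c("theory_curve", "data.frame"))
}
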