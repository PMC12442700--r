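ou_velocity <- function(n, dt, v2, tau, seed) {
  # planar velocity with <v(0).v(t)> = v2 * exp(-t/tau): constant speed
  # sqrt(v2) with Brownian heading of angular variance (2/tau) per unit
  # time, since <cos(theta(t) - theta(0))> = exp(-var t / 2)
  set.seed(seed)
  th <- cumsum(c(runif(1, 0, 2 * pi), rnorm(n - 1, 0, sqrt(2 * dt / tau))))
  data.frame(t = (0:(n - 1)) * dt,
             vx = sqrt(v2) * cos(th), vy = sqrt(v2) * sin(th))
}

test_that("closed-form diffusivity hits its analytic endpoints", {
  p <- motility_params()
  expect_equal(as.numeric(dxy_closed_form(1, p)), p$tumble_diffusion)
  v2 <- p$swim_speed^2
  d0 <- (v2 / 2) * p$run_rot_diffusion /
    (v2 / p$curvature_radius^2 + p$run_rot_diffusion^2)
  expect_equal(as.numeric(dxy_closed_form(0, p)), d0)
  # ~19.25 um^2/s with the default parameter set
  expect_equal(as.numeric(dxy_closed_form(0, p)), 19.2469, tolerance = 1e-4)

  # continuity at the endpoints: interior evaluation converges to limits
  for (eps in c(1e-7, 1e-9)) {
    expect_equal(as.numeric(dxy_closed_form(eps, p)),
                 as.numeric(dxy_closed_form(0, p)), tolerance = 1e-5)
    expect_equal(as.numeric(dxy_closed_form(1 - eps, p)),
                 as.numeric(dxy_closed_form(1, p)), tolerance = 1e-5)
  }
})

test_that("closed form is monotone in Dt and in R", {
  p <- motility_params()
  tb <- c(0.1, 0.3, 0.5, 0.9)
  hi <- dxy_closed_form(tb, motility_params(tumble_diffusion = 10))
  expect_true(all(hi > dxy_closed_form(tb, p)))
  # weaker circular confinement raises the run contribution
  r_big <- attr(dxy_closed_form(tb, p, r_scale = 1.4), "run_term")
  r_base <- attr(dxy_closed_form(tb, p), "run_term")
  expect_true(all(r_big > r_base))
})

test_that("tumble and run terms decompose the closed form", {
  p <- motility_params()
  tb <- seq(0, 1, 0.05)
  d <- dxy_closed_form(tb, p)
  expect_equal(as.numeric(d),
               attr(d, "tumble_term") + attr(d, "run_term"))
  expect_equal(attr(d, "tumble_term"), tb * p$tumble_diffusion)
})

test_that("Taylor-Kubo estimator integrates a known correlation", {
  # exponential velocity correlation, <|v|^2> = 100, tau = 0.5:
  # D = integral / 2 = v2 tau / 2 = 25 (verified against the direct MSD
  # of the integrated paths, the second estimator)
  vels <- lapply(1:200, function(i) ou_velocity(4000, 0.01, 100, 0.5, i))
  tk <- taylor_kubo_dxy(vels, max_lag_s = 10)
  expect_false(tk$diverged)
  expect_lt(abs(tk$dxy - 25) / 25, 0.05)
  # the two estimators agree on diffusive input
  expect_lt(abs(tk$dxy - tk$dxy_msd) / tk$dxy, 0.10)
})

test_that("Taylor-Kubo recovers Brownian D from displacement input", {
  set.seed(12)
  D <- 5; dt <- 0.05
  vels <- lapply(1:100, function(i) {
    n <- 2000
    data.frame(t = (0:(n - 1)) * dt,
               vx = rnorm(n, 0, sqrt(2 * D / dt)),
               vy = rnorm(n, 0, sqrt(2 * D / dt)))
  })
  tk <- taylor_kubo_dxy(vels, max_lag_s = 5)
  expect_lt(abs(tk$dxy - D) / D, 0.05)
})

test_that("ballistic input raises the divergence flag", {
  v <- data.frame(t = seq(0, 50, 0.05), vx = 10, vy = 0)
  tk <- taylor_kubo_dxy(list(v, v))
  expect_true(tk$diverged)
  expect_true(is.na(tk$dxy))
})

test_that("peak location refines through a local parabola", {
  # hand-computed apex of the parabola through (0.1,1), (0.2,3), (0.3,2):
  # 0.2 + 0.05 * (y1 - y3) / (y1 - 2 y2 + y3) = 0.2167
  pk <- peak_tb(c(0.1, 0.2, 0.3, 0.4, 0.5), c(1, 3, 2, 1.5, 1))
  expect_false(pk$boundary)
  expect_equal(pk$tb_peak, 0.2 + 0.05 * (1 - 2) / (1 - 6 + 2),
               tolerance = 1e-10)

  # an exact symmetric parabola is recovered exactly
  tb <- seq(0.1, 0.7, 0.1)
  pk <- peak_tb(tb, 5 - (tb - 0.4)^2)
  expect_equal(pk$tb_peak, 0.4)

  # monotone curve: boundary flag, no refinement
  pk <- peak_tb(tb, tb * 2)
  expect_true(pk$boundary)
  expect_equal(pk$tb_peak, 0.7)
})

test_that("correction-factor fit is self-consistent", {
  # a curve generated from the closed form with R -> 1.3 R plus small
  # noise must recover C = 1.30 within the grid resolution
  p <- motility_params()
  tb <- seq(0.125, 0.875, by = 0.05)
  set.seed(5)
  sim <- data.frame(
    tb_center = tb,
    dxy = as.numeric(dxy_closed_form(tb, p, r_scale = 1.3)) *
      (1 + rnorm(length(tb), 0, 0.01)))
  fit <- fit_correction(sim, p)
  expect_false(fit$boundary)
  expect_lt(abs(fit$c_factor - 1.30), 0.02)

  expect_error(fit_correction(sim[1:3, ], p), ">= 6")
})

test_that("planar process agrees with the closed form (oracle check)", {
  # stochastic oracle for the closed form: long-time MSD/4t of the
  # planar surface process at a mid-range tumble bias
  p <- motility_params()
  tb <- 0.5
  paths <- lapply(1:300, function(i) {
    simulate_surface_process(tb, p, duration = 40, seed = 6, stream = i,
                             record_dt = 0.2)
  })
  msd <- ensemble_msd(
    lapply(paths, function(s) data.frame(t = s$t, x = s$x, y = s$y)),
    lag_grid = seq(1, 40, by = 1))
  f <- fit_dxy(msd, c(15, 40))
  ref <- as.numeric(dxy_closed_form(tb, p))
  expect_lt(abs(f$dxy - ref) / ref, 0.10)
})
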