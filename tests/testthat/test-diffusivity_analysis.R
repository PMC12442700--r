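brownian_segment <- function(n_steps, dt, D, seed) {
  set.seed(seed)
  data.frame(t = (0:n_steps) * dt,
             x = cumsum(c(0, rnorm(n_steps, 0, sqrt(2 * D * dt)))),
             y = cumsum(c(0, rnorm(n_steps, 0, sqrt(2 * D * dt)))))
}

test_that("ensemble MSD averages one displacement per segment per lag", {
  seg1 <- data.frame(t = 0:2, x = c(0, 3, 0), y = c(0, 4, 0))
  seg2 <- data.frame(t = 0:2, x = c(5, 5, 5), y = c(1, 1, 1))
  msd <- ensemble_msd(list(seg1, seg2), lag_grid = c(1, 2))
  expect_equal(msd$msd[1], (25 + 0) / 2)   # (3,4) and (0,0)
  expect_equal(msd$n, c(2L, 2L))

  # lags beyond every segment are missing with zero count
  short <- data.frame(t = 0:3, x = rnorm(4), y = rnorm(4))
  msd <- ensemble_msd(list(short), lag_grid = c(1, 5))
  expect_true(is.na(msd$msd[2]))
  expect_equal(msd$n[2], 0L)
})

test_that("ensemble MSD recovers a known Brownian coefficient", {
  segs <- lapply(1:2000, function(i) brownian_segment(50, 0.1, 5, i))
  msd <- ensemble_msd(segs, seq(0.5, 5, by = 0.5))
  d_hat <- fit_dt(msd)
  expect_lt(abs(d_hat - 5) / 5, 0.05)
})

test_that("origin-anchored linear fits are exact on exact lines", {
  msd <- data.frame(lag = 1:10, msd = 20 * (1:10), n = 100L)
  expect_equal(fit_dt(msd), 5)
  # single noise-free lag pair
  msd1 <- data.frame(lag = 2, msd = 52.88, n = 100L)
  expect_equal(fit_dt(msd1), 6.61)

  msd <- data.frame(lag = seq(0.1, 30, 0.1), n = 1000L)
  msd$msd <- 200 * msd$lag
  f <- fit_dxy(msd, c(3, 20))
  expect_equal(f$dxy, 50)
  expect_equal(f$residual, 0)
  expect_error(fit_dxy(msd, c(3, 3.05)), "fewer than 2")
})

test_that("three-phase rule brackets the relaxation of an analytic MSD", {
  # MSD of an exponentially decorrelating walker:
  # MSD = 4 D (t - tau (1 - exp(-t/tau))), D = 10, tau = 1
  lag <- seq(0.1, 30, by = 0.1)
  D <- 10; tau <- 1
  msd <- data.frame(lag = lag,
                    msd = 4 * D * (lag - tau * (1 - exp(-lag / tau))),
                    n = ifelse(lag <= 20 + 1e-9, 1000L, 10L))
  win <- rdc_phases(msd, slope_tol = 0.05, count_floor = 50)
  # convergence begins a few tau in; the tail cut sits at the count floor
  expect_gt(win$t_lo, tau)
  expect_lt(win$t_lo, 10 * tau)
  expect_equal(win$t_hi, 20)
  # the origin-anchored fit carries a small negative bias of order
  # tau / mean(window lag) from the relaxation offset; 10% bounds it here
  expect_lt(abs(fit_dxy(msd, win)$dxy - D) / D, 0.10)

  # an exactly linear MSD opens the window at the first lag
  lin <- data.frame(lag = lag, msd = 4 * D * lag,
                    n = ifelse(lag <= 20 + 1e-9, 1000L, 10L))
  win <- rdc_phases(lin, count_floor = 50)
  expect_equal(win$t_lo, lag[1])

  # counts all below the floor is an error
  starved <- lin
  starved$n <- 5L
  expect_error(rdc_phases(starved, count_floor = 50), "count floor")
})

test_that("switching-frequency fit recovers omega", {
  tb <- seq(0.05, 0.95, by = 0.05)
  pts <- data.frame(tb = tb, sf = switching_frequency(tb, 9.27))
  expect_equal(fit_sf_curve(pts), 9.27)

  # from generated interval sequences of 50 cells
  cells <- seq(0.1, 0.9, length.out = 50)
  pts <- do.call(rbind, lapply(seq_along(cells), function(i) {
    iv <- generate_interval_sequence(cells[i], 9.27, duration = 200,
                                     seed = 8, stream = i)
    total <- sum(iv$duration)
    data.frame(tb = sum(iv$duration[iv$state == "tumble"]) / total,
               sf = (nrow(iv) - 1) / total)
  }))
  expect_lt(abs(fit_sf_curve(pts) - 9.27) / 9.27, 0.05)

  expect_error(fit_sf_curve(data.frame(tb = 0.5, sf = 2)), ">= 3")
  expect_error(fit_sf_curve(data.frame(tb = c(0.5, 0.5, 0.5),
                                       sf = c(2, 2, 2))), "spanning")
})

test_that("interval PDFs give consistent exponential rates", {
  # known exponential input
  set.seed(31)
  iv <- data.frame(state = rep(c("run", "tumble"), 5000),
                   duration = rexp(10000, 2))
  attr(iv, "tb") <- 0.22
  out <- interval_pdfs(list(iv))
  for (r in out$rate) {
    se <- 2 / sqrt(5000)
    expect_lt(abs(r - 2), 3 * se)
  }

  # histograms integrate to one
  h <- attr(out, "histograms")[[1]]
  width <- diff(h$mids[1:2])
  expect_equal(sum(h$density) * width, 1, tolerance = 0.01)

  # rates from generated sequences match the rate identities
  seqs <- lapply(1:20, function(i)
    generate_interval_sequence(0.22, 9.27, duration = 500, seed = 4,
                               stream = i))
  out <- interval_pdfs(seqs)
  run_rate <- out$rate[out$state == "run"]
  tum_rate <- out$rate[out$state == "tumble"]
  n_run <- out$n[out$state == "run"]
  expect_lt(abs(run_rate - 9.27 * 0.22 / 2), 3 * run_rate / sqrt(n_run))
  expect_lt(abs(tum_rate - 9.27 * 0.78 / 2),
            3 * tum_rate / sqrt(out$n[out$state == "tumble"]))
})

test_that("full-pipeline diffusivity exceeds the uncorrected closed form
           near the peak and meets Dt at high tumble bias", {
  p <- motility_params()
  dc <- dxy_curve(c(0.225, 0.975), 400, p, seed = 83)
  # mid-range: straighter off-surface runs make the 3D process more
  # diffusive than perpetual circling predicts
  expect_gt(dc$dxy[1], dxy_closed_form(0.225, p))
  # tumble-dominated limit approaches Dt within 10%
  expect_lt(abs(dc$dxy[2] - p$tumble_diffusion) / p$tumble_diffusion,
            0.10)
  # the fitting window extends past twice the mean residence time
  expect_true(all(dc$window_ok))
})
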