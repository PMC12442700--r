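params_fast <- function(...) motility_params(t_cap = 30, ...)

test_that("a noiseless bulk run advances ballistically", {
  p <- motility_params(run_rot_diffusion = 0, dt = 0.1)
  s <- surfdwell:::new_sim_state(r = c(0, 0, 5), e = c(1, 0, 0))
  s2 <- step_run_bulk(s, p)
  expect_equal(s2$r, c(1.9, 0, 5))
  expect_equal(s2$e, c(1, 0, 0))
})

test_that("run orientation diffuses at the small-angle rate", {
  # mean squared angular deviation per step ~ 4 Dr dt (two tangent dims)
  set.seed(7)
  p <- motility_params(dt = 0.001)
  n <- 1e5
  dev2 <- replicate(n, {
    e2 <- surfdwell:::tangent_diffuse_r(c(0, 0, 1), p$run_rot_diffusion,
                                        p$dt)
    acos(min(1, e2[3]))^2
  })
  expected <- 4 * p$run_rot_diffusion * p$dt
  se <- sd(dev2) / sqrt(n)
  expect_lt(abs(mean(dev2) - expected), 3 * se)
})

test_that("orientation stays a unit vector under repeated diffusion", {
  set.seed(8)
  e <- c(1, 0, 0)
  for (i in 1:2e4) e <- surfdwell:::tangent_diffuse_r(e, 3.5, 0.001)
  expect_lt(abs(sqrt(sum(e^2)) - 1), 1e-9)
})

test_that("a noiseless surface run is a clockwise circle of radius R", {
  p <- motility_params(run_rot_diffusion = 0, dt = 0.001)
  s <- surfdwell:::new_sim_state(r = c(0, 0, 0), e = c(1, 0, 0),
                                 theta = 0, surface_bound = TRUE)
  period <- 2 * pi * p$curvature_radius / p$swim_speed
  n <- round(period / p$dt)
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    s <- step_run_surface(s, p)
    xs[i] <- s$r[1]; ys[i] <- s$r[2]
  }
  # returns to start within one step length
  expect_lt(sqrt(s$r[1]^2 + s$r[2]^2), 2 * p$swim_speed * p$dt)
  # the swept circle has radius R (centre at the mean of the loop)
  radii <- sqrt((xs - mean(xs))^2 + (ys - mean(ys))^2)
  expect_equal(mean(radii), p$curvature_radius, tolerance = 1e-3)
  # clockwise under right-handed axes: signed area negative
  area <- sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys) / 2
  expect_lt(area, 0)
})

test_that("tumble displacement is Brownian and respects the wall", {
  set.seed(9)
  p <- motility_params(dt = 0.01)
  n <- 1e4
  k <- 20   # steps per walker
  disp <- replicate(n, {
    s <- surfdwell:::new_sim_state(r = c(0, 0, 50), state = "tumble")
    for (i in seq_len(k)) s <- step_tumble(s, p)
    s$r[1]
  })
  # MSD_x = 2 Dt t
  expected <- 2 * p$tumble_diffusion * k * p$dt
  se <- sd(disp^2) / sqrt(n)
  expect_lt(abs(mean(disp^2) - expected), 3 * se)

  # reflection: a walker started on the wall never goes below it
  s <- surfdwell:::new_sim_state(r = c(0, 0, 0), state = "tumble")
  zs <- replicate(2e3, {
    s <<- step_tumble(s, p)
    s$r[3]
  })
  expect_true(all(zs >= 0))

  # frozen orientation when tumble rotational diffusion is off
  p0 <- motility_params(tumble_rot_diffusion = 0)
  s <- surfdwell:::new_sim_state(r = c(0, 0, 5), e = c(0, 1, 0),
                                 state = "tumble")
  s2 <- step_tumble(s, p0)
  expect_equal(s2$e, c(0, 1, 0))
})

test_that("trajectory invariants hold across an ensemble", {
  p <- params_fast()
  for (i in 1:20) {
    tr <- simulate_trajectory(0.3, p, seed = 5, stream = i)
    expect_true(all(tr$z >= 0))
    norms <- sqrt(tr$ex^2 + tr$ey^2 + tr$ez^2)
    expect_true(all(abs(norms - 1) < 1e-9))
    sb <- tr$surface_bound
    expect_true(all(tr$state[sb] == "run"))
    expect_true(all(tr$z[sb] == 0))
    expect_true(all(abs(tr$phi[sb] - pi / 2) < 1e-9))
    expect_true(attr(tr, "stop_reason") %in% c("escape", "censored"))
  }
})

test_that("a tumble-locked cell diffuses with the configured Dt", {
  # an unreachable bulk criterion keeps every walker for the full window
  # so the lateral MSD is not conditioned on late escape
  p <- motility_params(t_cap = 3, z_bulk = 1e6)
  segs <- lapply(1:2000, function(i) {
    tr <- simulate_trajectory(1, p, seed = 31, stream = i)
    data.frame(t = tr$t, x = tr$x, y = tr$y)
  })
  msd <- ensemble_msd(segs, seq(0.2, 2, by = 0.2))
  expect_lt(abs(fit_dt(msd) - p$tumble_diffusion) / p$tumble_diffusion,
            0.05)
})

test_that("a smooth swimmer with no rotational noise circles forever", {
  p <- motility_params(run_rot_diffusion = 0, t_cap = 20)
  tr <- simulate_trajectory(0, p, seed = 3)
  expect_identical(attr(tr, "stop_reason"), "censored")
  expect_true(all(tr$z == 0))
  expect_true(all(tr$state == "run"))
  # the bounding box of >= 1 full period has side 2R
  expect_equal((max(tr$x) - min(tr$x)) / 2, p$curvature_radius,
               tolerance = 5e-3)
  expect_equal((max(tr$y) - min(tr$y)) / 2, p$curvature_radius,
               tolerance = 5e-3)
})

test_that("state occupancy matches the stationary law at TB = 0.5", {
  p <- params_fast()
  frac <- vapply(1:200, function(i) {
    tr <- simulate_trajectory(0.5, p, seed = 17, stream = i)
    mean(tr$state == "tumble")
  }, numeric(1))
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 0.5), 3 * se)
})

test_that("dwell intervals are exponential with the model rates", {
  # record at the integration step so intervals are resolved, then
  # compare against the exponential law (mirrors interval-PDF analysis
  # of tracked cells)
  p <- motility_params(t_cap = 60)
  tb <- 0.4
  rates <- transition_rates(tb, switching_frequency(tb, p$char_frequency))
  iv <- do.call(rbind, lapply(1:60, function(i) {
    tr <- simulate_surface_process(tb, p, duration = 60, seed = 23,
                                   stream = i, record_dt = p$dt)
    state_intervals(tr$state, p$dt)
  }))
  runs <- iv$duration[iv$state == "run"]
  tums <- iv$duration[iv$state == "tumble"]
  expect_gt(length(runs), 3e3)
  # KS distance below the 1% critical value 1.63/sqrt(n)
  ks_run <- suppressWarnings(
    stats::ks.test(runs, "pexp", rate = rates$k_rt))
  ks_tum <- suppressWarnings(
    stats::ks.test(tums, "pexp", rate = rates$k_tr))
  expect_lt(unname(ks_run$statistic), 1.63 / sqrt(length(runs)))
  expect_lt(unname(ks_tum$statistic), 1.63 / sqrt(length(tums)))
})

test_that("no spurious escapes when the bulk criterion is unreachable", {
  p <- motility_params(z_bulk = 1e6, t_cap = 5)
  for (i in 1:10) {
    tr <- simulate_trajectory(0.5, p, seed = 11, stream = i)
    expect_identical(attr(tr, "stop_reason"), "censored")
  }
})

test_that("residence statistics are chirality-blind", {
  # mirrored circling (counterclockwise) must give the same mean
  # residence time within sampling error
  p <- params_fast(t_cap = 60)
  ts_for <- function(hand) {
    vapply(1:150, function(i) {
      tr <- simulate_trajectory(0.35, p, seed = 29, stream = i,
                                handedness = hand)
      ev <- detect_residence(tr, p$z_surface, p$z_bulk)
      if (ev$censored) NA_real_ else ev$t_s
    }, numeric(1))
  }
  cw <- ts_for(1); ccw <- ts_for(-1)
  se <- sqrt(sd(cw, na.rm = TRUE)^2 / sum(!is.na(cw)) +
               sd(ccw, na.rm = TRUE)^2 / sum(!is.na(ccw)))
  expect_lt(abs(mean(cw, na.rm = TRUE) - mean(ccw, na.rm = TRUE)), 3 * se)
})

test_that("trajectories round-trip through CSV + JSON sidecar", {
  p <- params_fast(t_cap = 2)
  tr <- simulate_trajectory(0.25, p, seed = 13)
  path <- file.path(tempdir(), "traj.csv")
  write_trajectory(tr, path)
  tr2 <- read_trajectory(path)
  expect_equal(as.data.frame(tr2), as.data.frame(tr), tolerance = 1e-12)
  expect_equal(attr(tr2, "params")$t_cap, 2)
  expect_equal(attr(tr2, "phenotype")$tb, 0.25)
  expect_identical(attr(tr2, "stop_reason"), attr(tr, "stop_reason"))
})

test_that("identical seeds and streams reproduce a trajectory exactly", {
  p <- params_fast(t_cap = 3)
  a <- simulate_trajectory(0.4, p, seed = 99, stream = 7)
  b <- simulate_trajectory(0.4, p, seed = 99, stream = 7)
  c <- simulate_trajectory(0.4, p, seed = 99, stream = 8)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})
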