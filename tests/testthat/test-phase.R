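test_that("circular-linear regression recovers noiseless relations", {
  x <- seq(0, 100, length.out = 40)
  fit <- circular_linear_regression((360 - 1.2 * x) %% 360, x)
  expect_equal(fit$slope, -1.2, tolerance = 1e-3)
  expect_equal(fit$fit_score, 1, tolerance = 1e-6)
  # phase locking: constant phase
  lock <- circular_linear_regression(rep(310, 30), runif(30, 0, 100))
  expect_equal(lock$slope, 0, tolerance = 1e-3)
  expect_equal(lock$fit_score, 1, tolerance = 1e-6)
  expect_equal(lock$offset, 310, tolerance = 1e-3)
  expect_error(circular_linear_regression(1:4, 1:4), "at least 5")
  expect_error(circular_linear_regression(runif(9, 0, 360), rep(2, 9)),
               "variance")
})

test_that("regression is invariant to full phase cycles", {
  set.seed(31)
  x <- runif(60, 0, 100)
  ph <- (350 - 2 * x + rnorm(60, 0, 25)) %% 360
  f1 <- circular_linear_regression(ph, x)
  f2 <- circular_linear_regression(ph + 360, x)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-6)
  expect_equal(f1$fit_score, f2$fit_score, tolerance = 1e-9)
})

test_that("uniform random phases give low fit scores at large n", {
  set.seed(7)
  scores <- replicate(5, {
    x <- runif(500, 0, 100)
    circular_linear_regression(runif(500, 0, 360), x,
                               slope_bounds = c(-14.4, 14.4))$fit_score
  })
  expect_true(all(scores < 0.15))
})

test_that("optimized slope matches a fine grid-search oracle", {
  set.seed(42)
  for (k in 1:50) {
    n <- sample(20:80, 1)
    x <- runif(n, 0, 100)
    true_slope <- runif(1, -3, 3)
    ph <- (true_slope * x + runif(1, 0, 360) + rnorm(n, 0, 40)) %% 360
    fit <- circular_linear_regression(ph, x, slope_bounds = c(-14.4, 14.4))
    # oracle: exhaustive grid at 0.01 deg/percent resolution
    grid <- seq(-14.4, 14.4, by = 0.01)
    R <- vapply(grid, function(a)
      Mod(mean(exp(1i * (ph - a * x) * pi / 180))), 0)
    expect_lt(abs(fit$slope - grid[which.max(R)]), 0.05)
  }
})

test_that("circular-linear correlation behaves at its extremes", {
  x <- seq(0, 100, length.out = 50)
  expect_equal(abs(circular_linear_correlation((360 - 1.5 * x) %% 360, x)),
               1, tolerance = 1e-6)
  set.seed(12)
  r0 <- circular_linear_correlation(runif(800, 0, 360), runif(800, 0, 100))
  expect_lt(abs(r0), 0.15)
  # mirroring positions flips the regression slope exactly
  set.seed(13)
  xx <- runif(60, 0, 100)
  ph <- (355 - 1.8 * xx + rnorm(60, 0, 20)) %% 360
  f1 <- circular_linear_regression(ph, xx, slope_bounds = c(-14.4, 14.4))
  f2 <- circular_linear_regression(ph, -xx, slope_bounds = c(-14.4, 14.4))
  expect_equal(f1$slope, -f2$slope, tolerance = 1e-3)
})

test_that("subgroup classification uses the stated cutoffs exactly", {
  expect_equal(classify_phase_behavior(0.2, -5), "independent")
  expect_equal(classify_phase_behavior(0.39999, -5), "independent")
  expect_equal(classify_phase_behavior(0.8, -0.2), "locking")  # range 20
  expect_equal(classify_phase_behavior(0.8, -1.5), "precessing") # range 150
  expect_equal(classify_phase_behavior(0.4, 0.6), "precessing")  # at cutoffs
  expect_equal(classify_phase_behavior(0.4, 0.59999), "locking")
})

test_that("spike density maps expose locking ridges and flat nulls", {
  set.seed(5)
  lock <- data.frame(progress = runif(2000, 0, 100),
                     phase_deg = (rnorm(2000, 0, 18)) %% 360)
  m <- spike_density_map(lock)
  ridge <- density_ridge(m)
  expect_true(all(abs(ridge$phase_deg - 360) < 40, na.rm = TRUE))
  unif <- data.frame(progress = runif(4000, 0, 100),
                     phase_deg = runif(4000, 0, 360))
  mu <- spike_density_map(unif, smooth_sd = 0)
  expect_lt(stats::sd(mu$density) / mean(mu$density), 0.5)
  expect_equal(sum(mu$density), 1)
})

test_that("direction and speed stratification summarize known structure", {
  set.seed(8)
  mk <- function(nrn, dir, slope, speed) {
    x <- runif(30, 0, 100)
    ph <- (350 + slope * x + rnorm(30, 0, 15)) %% 360
    data.frame(neuron = nrn, direction = dir, field = 1, pos_cm = x,
               progress = x, phase_deg = ph, speed = speed, lap = 1,
               t_ms = seq_along(x))
  }
  # genuine precession: phase falls with field progress in both directions
  samples <- do.call(rbind, c(
    lapply(1:6, function(k) mk(paste0("R", k), 1, -1.2, 0.5)),
    lapply(1:6, function(k) mk(paste0("L", k), -1, -1.2, 0.5))))
  st <- phase_precession_stats(samples)
  strat <- directionality_and_speed_stratification(st)
  ds <- strat$direction_summary
  # in track-position units: negative on rightward, positive on leftward laps
  expect_gt(ds$frac_negative_slope[ds$direction == 1], 0.5)
  expect_lt(ds$frac_negative_slope[ds$direction == -1], 0.5)
  # mirrored spike set flips slope signs
  flipped <- samples
  flipped$progress <- 100 - flipped$progress
  stf <- phase_precession_stats(flipped)
  m <- merge(st, stf, by = c("neuron", "direction"))
  expect_equal(m$slope.x, -m$slope.y, tolerance = 1e-2)
  # built-in speed effect detected by the Kruskal-Wallis test
  sp_samples <- do.call(rbind, lapply(1:24, function(k) {
    spd <- c(0.2, 0.5, 0.9)[1 + (k %% 3)]
    mk(paste0("S", k), 1, -0.6 - spd * 2, spd)
  }))
  sst <- phase_precession_stats(sp_samples)
  sstrat <- directionality_and_speed_stratification(sst)
  expect_lt(sstrat$kw_range$p.value, 0.05)
})
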