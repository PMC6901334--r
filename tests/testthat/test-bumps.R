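disc_image <- function(n, centers, radius, amp = 10) {
  img <- matrix(0, n, n)
  for (c in centers) {
    d2 <- outer((seq_len(n) - c[1])^2, (seq_len(n) - c[2])^2, "+")
    img[d2 <= radius^2] <- amp
  }
  img
}

test_that("bump segmentation recovers synthetic discs", {
  img <- disc_image(64, list(c(32, 32)), 5)
  b <- segment_bumps(img, smooth_sigma = 0.8, threshold_frac = 0.3,
                     central_frac = Inf)
  expect_equal(nrow(b), 1)
  expect_equal(b$diameter, 10, tolerance = 0.15)
  expect_equal(c(b$x, b$y), c(32, 32), tolerance = 0.1)
  b2 <- segment_bumps(disc_image(64, list(c(20, 20), c(46, 46)), 4),
                      smooth_sigma = 0.8, central_frac = Inf)
  expect_equal(nrow(b2), 2)
  expect_equal(nrow(segment_bumps(matrix(0, 32, 32))), 0)
})

test_that("the threshold-pass model produces precessing spikes", {
  # diameter law: linear decrease with drive that releases the neuron at
  # the most inhibited phases, as the measured bumps do
  dlaw <- function(a) pmax(46 - 50 * a, 0)   # ~20 at 0.52, 0 at 0.92
  sp <- simulate_threshold_pass(dlaw, v = 40)
  expect_gt(nrow(sp), 10)
  # deterministic: identical on repetition
  expect_identical(sp, simulate_threshold_pass(dlaw, v = 40))
  # first spike of each lap arrives just below 360 degrees
  first <- do.call(rbind, lapply(split(sp, sp$lap), function(s)
    s[which.min(s$t_ms), ]))
  expect_gt(mean(first$phase_deg > 235), 0.7)
  expect_gt(stats::median(first$phase_deg), 270)
  # each cycle's entry spike (after a gap beyond the refractory clock)
  # drifts to earlier phases as the pass progresses
  entry <- do.call(rbind, lapply(split(sp, sp$lap), function(s) {
    g <- c(Inf, diff(s$t_ms))
    s[g > 60, ]
  }))
  fit <- circular_linear_regression(entry$phase_deg,
                                    entry$t_ms / max(sp$t_ms) * 100,
                                    slope_bounds = c(-7.2, 7.2))
  expect_lt(fit$slope, 0)
  # constant diameter: spikes every refractory period regardless of phase
  spc <- simulate_threshold_pass(function(a) 20, v = 20,
                                 initial_phases_deg = 0)
  expect_true(all(diff(spc$t_ms) == 40))
})

test_that("the Poisson-pass model shifts behaviour with activity level", {
  # synthetic average bump: Gaussian envelope whose amplitude follows theta
  bump_fun <- function(phase_deg, offset) {
    amp <- 0.5 * (1 + cos(phase_deg * pi / 180))      # max at phase 0/360
    amp * exp(-offset^2 / (2 * 6^2))
  }
  hi <- simulate_poisson_pass(bump_fun, max_rate = 100, v = 40, seed = 2)
  lo <- simulate_poisson_pass(bump_fun, max_rate = 40, v = 40, seed = 2)
  none <- simulate_poisson_pass(function(p, o) 0, max_rate = 100, v = 40)
  expect_equal(nrow(none), 0)
  expect_gt(nrow(hi), nrow(lo))
  st_hi <- attr(hi, "stats"); st_lo <- attr(lo, "stats")
  # low activity: firing confined to the most permissive phase, near 360
  ph_lo <- lo$phase_deg
  m_lo <- (Arg(mean(exp(1i * ph_lo * pi / 180))) * 180 / pi) %% 360
  expect_true(m_lo > 300 || m_lo < 60)
  expect_gt(st_lo$fit_score, st_hi$fit_score)
})

test_that("the average bump is phase-resolved with its size tied to the drive", {
  cfg <- grid_config(n = 128)
  ab <- average_bump_shape(cfg, duration_ms = 3000, seed = 7,
                           settle_ms = 800)
  tot <- apply(ab$activity, 1, sum)
  ph <- ab$phase_centers
  # most active near the drive trough (0/360), least around mid-cycle
  near0 <- tot[ph < 60 | ph > 300]
  mid <- tot[ph > 120 & ph < 240]
  expect_gt(mean(near0), 3 * mean(mid))
  # the lattice advances at a speed consistent with path integration
  expect_gt(ab$ref_speed, 10)
  expect_lt(ab$ref_speed, 90)
  # profile along the motion axis peaks inside the window
  expect_true(all(abs(ab$peak_offset) <= 16))
})
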