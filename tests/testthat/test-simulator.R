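test_that("the Euler step matches the leaky-integrator closed form", {
  cfg <- isolated_config()
  # drive 0.8, tau 40, dt 1: phi goes 0 -> 0.02 in one step
  r <- run_uniform(cfg, 1, a_exc = 0.8, phi0 = 0)
  expect_equal(unique(round(r$state$phi[, 1], 10)), 0.02)
  # k steps: phi_k = a (1 - (1 - dt/tau)^k), exact for the discrete update
  r2 <- run_uniform(cfg, 100, a_exc = 0.8, phi0 = 0)
  expect_equal(unique(round(r2$state$phi[, 2], 9)),
               round(0.8 * (1 - (1 - 1 / 40)^100), 9))
  # inhibitory population uses tau = 20 and the inhibitory drive
  r3 <- run_uniform(cfg, 50, a_exc = 0, a_inh = 0.6, phi0 = 0)
  expect_equal(unique(round(r3$state$phi[, 5], 9)),
               round(0.6 * (1 - (1 - 1 / 20)^50), 9))
})

test_that("threshold crossing spikes and resets; potentials stay in range", {
  cfg <- isolated_config()
  # phi_k = 2 (1 - (39/40)^k) crosses 1 at the first k with (39/40)^k < 0.5
  k_spike <- which(2 * (1 - (1 - 1 / 40)^(1:60)) >= 1)[1]
  r <- run_uniform(cfg, 60, a_exc = 2, phi0 = 0)
  ev <- r$events[r$events$pop == "N" & r$events$x == 5 & r$events$y == 5, ]
  expect_equal(ev$t[1], k_spike - 1)      # steps are 0-based
  expect_true(all(r$state$phi < 1))
  # hyperpolarization floor: strong negative drive pins phi at -1
  rf <- run_uniform(cfg, 300, a_exc = -5, phi0 = 0)
  expect_true(all(rf$state$phi[, 1:4] == -1))
})

test_that("identical seed and config reproduce the identical spike record", {
  cfg <- small_config()
  maps <- list(excitatory_drive_field(cfg, "run"))
  T <- 300
  run1 <- run_network(cfg, maps, rep(1L, T), rep(0.72, T),
                      cbind(rep(0.3, T), 0), seed = 9)
  run2 <- run_network(cfg, maps, rep(1L, T), rep(0.72, T),
                      cbind(rep(0.3, T), 0), seed = 9)
  expect_identical(run1$events, run2$events)
  expect_identical(run1$state$phi, run2$state$phi)
  run3 <- run_network(cfg, maps, rep(1L, T), rep(0.72, T),
                      cbind(rep(0.3, T), 0), seed = 10)
  expect_false(identical(run1$events, run3$events))
})

test_that("a session split across calls equals one uninterrupted call", {
  # exercises delay-buffer handoff and the counter-based noise keying
  cfg <- small_config()
  maps <- list(excitatory_drive_field(cfg, "run"))
  T <- 240
  vel <- cbind(rep(0.4, T), 0)
  a <- rep(0.72, T)
  whole <- run_network(cfg, maps, rep(1L, T), a, vel, seed = 4)
  half1 <- run_network(cfg, maps, rep(1L, T / 2), a[1:(T / 2)],
                       vel[1:(T / 2), ], seed = 4)
  half2 <- run_network(cfg, maps, rep(1L, T / 2), a[(T / 2 + 1):T],
                       vel[(T / 2 + 1):T, ], seed = 4, state = half1$state)
  expect_equal(half2$state$phi, whole$state$phi, tolerance = 1e-12)
  joined <- rbind(half1$events, half2$events)
  expect_equal(joined$t, whole$events$t)
  expect_equal(joined$x, whole$events$x)
  # spike-count conservation: every recorded event appears exactly once
  expect_equal(nrow(joined), nrow(whole$events))
})

test_that("the settled network forms a triangular bump lattice", {
  snap <- settled_snapshot()
  expect_gt(sum(snap), 0)
  # coherent central patch, local-mean removed to strip the drive envelope
  sm <- gauss_smooth2d(snap, 2)[47:186, 47:186]
  ac <- rate_map_autocorrelation(sm, detrend_sigma = 15)
  expect_equal(ac[140, 140], 1)           # zero lag is 1 by normalization
  pk <- autocorr_inner_peaks(ac)
  expect_equal(pk$n_peaks, 6)
  gaps <- diff(c(sort(pk$angles), min(pk$angles) + 360))
  expect_true(all(abs(gaps - 60) < 30))
  expect_lt(stats::sd(pk$radii) / mean(pk$radii), 0.2)  # near-equal ring
})

test_that("bump displacement path-integrates velocity", {
  # stationarity, direction, and reversal symmetry; the speed-doubling
  # check runs on the full-size sheet in the acceptance suite
  cfg <- grid_config(n = 128)
  still <- path_integration_displacement(cfg, c(0, 0), 1500, seed = 6,
                                         frame_ms = 250)
  expect_lt(still$magnitude, 4)
  d2 <- path_integration_displacement(cfg, c(0.5, 0), 2400, seed = 6,
                                      frame_ms = 200)
  dr <- path_integration_displacement(cfg, c(-0.5, 0), 2400, seed = 6,
                                      frame_ms = 200)
  expect_gt(d2$displacement[1], 20)       # moves substantially, along +x
  expect_lt(abs(d2$displacement[2]), 0.25 * abs(d2$displacement[1]))
  expect_lt(abs(dr$displacement[1] + d2$displacement[1]) /
              abs(d2$displacement[1]), 0.15)
})

test_that("periodic boundaries with uniform drive have no edge gradient", {
  cfg <- grid_config(n = 96, boundary = "periodic", uniform_drive = TRUE)
  maps <- list(excitatory_drive_field(cfg, "run"))
  T <- 2500
  # move the pattern so the time average is not pinned to one arrangement
  r <- run_network(cfg, maps, rep(1L, T), rep(0.72, T),
                   cbind(rep(0.5, T), rep(0.25, T)), seed = 3,
                   rec_mask = rep(0L, 96^2))
  tal <- r$tally
  ctr <- (96 + 1) / 2
  rho <- sqrt(outer((seq_len(96) - ctr)^2, (seq_len(96) - ctr)^2, "+"))
  inner <- mean(tal[rho < 24])
  outer_ring <- mean(tal[rho > 36])
  expect_lt(abs(inner - outer_ring) / inner, 0.25)
  expect_gt(inner, 0)
})
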