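test_that("recording regions sit on a ring at equally spaced angles", {
  cfg <- grid_config(n = 232)
  A <- select_recording_regions(cfg, seed = 3, set_id = "A")
  B <- select_recording_regions(cfg, seed = 3, set_id = "B")
  ctr <- (cfg$n + 1) / 2
  dA <- sqrt(rowSums((A$centers - ctr)^2))
  expect_true(all(abs(dA - 95) < 0.5))
  angA <- sort(atan2(A$centers[, 2] - ctr, A$centers[, 1] - ctr))
  gaps <- diff(c(angA, angA[1] + 2 * pi)) * 180 / pi
  expect_equal(gaps, rep(90, 4), tolerance = 1e-6)
  angB <- sort(atan2(B$centers[, 2] - ctr, B$centers[, 1] - ctr))
  off <- (angB - angA) * 180 / pi
  expect_equal(off %% 90, rep(45, 4), tolerance = 1e-6)
  expect_error(select_recording_regions(grid_config(n = 96)), "exceeds")
})

# synthetic sessions: neurons with hand-built place fields
make_field_session <- function(n_laps = 4, centers, stable = TRUE,
                               seed = 2, peak_hz = 25) {
  cfg <- grid_config(n = 144, idle_duration_s = 0.5, seed = seed)
  nrns <- region_neurons(cfg, length(centers), seed)
  ses <- synthetic_session(n_laps, nrns, function(traj, track_x, neurons) {
    evs <- list()
    for (i in seq_len(nrow(neurons))) {
      ctr_fun <- if (stable) function(l) centers[i] else
        function(l) centers[i] + 20 * l     # drifts across laps
      run <- which(traj$state == "run")
      set.seed(seed * 1000 + i)
      rate <- peak_hz * exp(-(track_x[run] - ctr_fun(traj$lap[run]))^2 /
                              (2 * 6^2))
      fire <- run[runif(length(run)) < rate / 1000]
      if (!length(fire)) next
      evs[[i]] <- data.frame(pop = neurons$pop[i], x = neurons$x[i],
                             y = neurons$y[i], t = fire - 1,
                             t_ms = traj$t_ms[fire])
    }
    do.call(rbind, evs)
  }, seed = seed)
  ses
}

test_that("stable neurons are kept and drifting or silent ones dropped", {
  centers <- seq(20, 80, length.out = 12)
  ses <- make_field_session(centers = centers, stable = TRUE)
  sel <- select_stable_neurons(ses, "A")
  expect_gte(nrow(sel), 10)
  expect_true(attr(sel, "usable"))
  # drifting fields fail the lap-to-lap stability requirement
  ses_d <- make_field_session(centers = centers, stable = FALSE)
  expect_warning(sel_d <- select_stable_neurons(ses_d, "A"), "unusable")
  expect_lt(nrow(sel_d), 3)
})

test_that("rate maps are occupancy-normalized and conserve total spikes", {
  centers <- c(30, 50, 70)
  ses <- make_field_session(centers = centers, stable = TRUE)
  sel <- suppressWarnings(select_stable_neurons(ses, "A"))
  ff <- compute_rate_maps(ses, sel)
  # each neuron's field covers its construction centre
  for (i in seq_len(nrow(sel))) {
    k <- which.min(abs(centers - ff$bin_centers[which.max(ff$rate[i, ])]))
    expect_lt(abs(centers[k] - ff$bin_centers[which.max(ff$rate[i, ])]), 8)
    expect_gte(ff$n_fields[i], 1)
  }
  # occupancy-weighted mean rate equals total spikes / total run time
  ev <- gridwave:::.set_events(ses, "A")
  ev <- ev[ev$state == "run" & ev$neuron %in% sel$neuron, ]
  total_t <- sum(ff$occupancy)
  for (i in seq_len(min(3, nrow(sel)))) {
    nsp <- sum(ev$neuron == sel$neuron[i])
    expect_equal(sum(ff$rate[i, ] * ff$occupancy) / total_t,
                 nsp / total_t, tolerance = 0.06)
  }
})

test_that("autocorrelograms normalize at zero lag and find hexagonal peaks", {
  # ideal hexagonal lattice fixture
  n <- 120
  img <- matrix(0, n, n)
  a1 <- c(24, 0); a2 <- c(12, 12 * sqrt(3))
  for (i in -8:8) for (j in -8:8) {
    p <- round(60 + i * a1 + j * a2)
    if (all(p >= 1 & p <= n)) img[p[1], p[2]] <- 1
  }
  img <- gauss_smooth2d(img, 2.5)
  ac <- rate_map_autocorrelation(img)
  expect_equal(ac[n, n], 1)
  expect_equal(max(ac), 1)
  pk <- autocorr_inner_peaks(ac, r_min = 14, r_max = 34)
  expect_equal(pk$n_peaks, 6)
  gaps <- diff(c(sort(pk$angles), min(pk$angles) + 360))
  expect_true(all(abs(gaps - 60) < 10))
})

test_that("theta cycles are labelled from drive troughs", {
  cfg <- grid_config(n = 144, idle_duration_s = 0.5)
  traj <- generate_track_trajectory(cfg, 2, seed = 5)
  p <- resolve_params(cfg, "run")
  run <- traj$state == "run"
  psi0 <- 1.1
  trace <- numeric(nrow(traj))
  trace[run] <- p$a_mag_inh - p$a_theta_inh *
    cos(2 * pi * p$f_theta * traj$t_ms[run] / 1000 + psi0)
  ses <- list(trajectory = traj, drive_trace = trace,
              config = cfg)
  class(ses) <- "grid_session"
  cyc <- label_theta(ses)
  expect_gt(nrow(cyc), 10)
  expect_true(all(abs((cyc$t_end_ms - cyc$t_start_ms) - 125) <= 2))
  # phase is 0 at boundaries and 180 at the drive maximum
  mid <- (cyc$t_start_ms[1] + cyc$t_end_ms[1]) / 2
  expect_equal(theta_phase_at(mid, cyc), 180, tolerance = 3)
  expect_equal(theta_phase_at(cyc$t_start_ms[2] + 0.01, cyc), 0,
               tolerance = 1)
  # idle times carry no phase
  expect_true(is.na(theta_phase_at(100, cyc)))
  # shifting psi0 translates every boundary by psi0 / (2 pi f)
  trace2 <- numeric(nrow(traj))
  trace2[run] <- p$a_mag_inh - p$a_theta_inh *
    cos(2 * pi * p$f_theta * traj$t_ms[run] / 1000 + psi0 + pi / 4)
  ses$drive_trace <- trace2
  cyc2 <- label_theta(ses)
  dshift <- (cyc$t_start_ms[5] - cyc2$t_start_ms[5]) %% 125
  expected <- ((pi / 4) / (2 * pi * 8) * 1000) %% 125
  expect_lt(min(abs(dshift - expected), abs(125 - dshift - expected)), 2)
})

test_that("theta-binned multiunit activity reflects the spike phases", {
  cyc <- data.frame(cycle_id = 1:40, t_start_ms = (0:39) * 125,
                    t_end_ms = (1:40) * 125, lap = 1L)
  set.seed(4)
  t_unif <- runif(4000, 0, 5000)
  m <- theta_mua(t_unif, cyc)
  expect_lt(stats::sd(m$rate) / mean(m$rate), 0.2)   # flat
  # doubling the spikes doubles the rate
  m2 <- theta_mua(rep(t_unif, 2), cyc)
  expect_equal(m2$rate, 2 * m$rate)
  # phase-locked spikes near the trough produce a peak near 0/360
  t_lock <- (0:39) * 125 + rnorm(40, 2, 1)
  ml <- theta_mua(t_lock[t_lock > 0 & t_lock < 5000], cyc, n_bins = 12)
  expect_equal(ml$phase_deg[which.max(ml$rate)], 15)
})
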