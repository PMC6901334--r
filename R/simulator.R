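#' Low-level network run
#'
#' Advances the five-population leaky integrate-and-fire sheet for a given
#' schedule of drives and velocities. This is the thin R wrapper around the
#' compiled core; sessions, setup and sweeps are built on top of it.
#'
#' The update per step is the explicit Euler form of the leaky-integrator
#' dynamics: `phi <- phi + (dt/tau_m) * (-phi + synaptic input + drive + noise)`,
#' followed by threshold (`phi >= 1` emits a spike and resets to 0) and a
#' hyperpolarization floor at -1. Synaptic input is the convolution of spike
#' fields, delayed by the synaptic delays, with the connectivity kernels.
#'
#' @param config a `grid_config`.
#' @param drive_maps list of `n x n` excitatory drive maps.
#' @param drive_idx integer vector (length T): which map is active per step.
#' @param a_inh_t numeric vector (length T): inhibitory drive per step.
#' @param vel `T x 2` matrix of animal velocity (m/s).
#' @param seed noise stream key (integer).
#' @param state network state to continue from (as returned in `$state`), or
#'   `NULL` to initialize with i.i.d. uniform \[0,1) potentials.
#' @param rec_mask logical/0-1 vector or matrix over sheet locations at which
#'   spike events are recorded; default records everywhere.
#' @param snapshot_every snapshot cadence in steps (0 = no snapshots).
#' @param snapshot_pop population for activity snapshots: `"N"`, `"S"`, `"W"`,
#'   `"E"` or `"exc"` (sum of all four).
#' @param init_seed seed for the initial membrane potentials (defaults to
#'   `seed`).
#' @return list with `events` (data.frame `pop`, `x`, `y`, `t` in steps;
#'   populations `N,S,W,E,inh`), `counts` (T x 5 spikes per step), `tally`
#'   (`n x n` excitatory spike counts), `snapshots` (n x n x S array or
#'   `NULL`), and `state` (to pass to a continuation call).
#' @export
run_network <- function(config, drive_maps, drive_idx, a_inh_t, vel,
                        seed = config$seed, state = NULL, rec_mask = NULL,
                        snapshot_every = 0, snapshot_pop = "S",
                        init_seed = seed) {
  n <- config$n
  T <- length(drive_idx)
  stopifnot(length(a_inh_t) == T, nrow(vel) == T)
  spec <- .kernel_spectra(config)
  Ahat <- (spec$exc_hat + spec$inh_hat) / 2
  Bhat <- (spec$exc_hat - spec$inh_hat) / 2
  dm <- vapply(drive_maps, as.vector, numeric(n * n))
  dm <- matrix(dm, nrow = n * n)
  lag_ee <- max(1L, as.integer(round(config$tau_s_ee / config$dt)))
  lag_ei <- max(1L, as.integer(round(config$tau_s_ei / config$dt)))
  lag_in <- max(1L, as.integer(round(config$tau_s_inh / config$dt)))
  prm <- list(dt = config$dt, tau_m_exc = config$tau_m_exc,
              tau_m_inh = config$tau_m_inh,
              lag_ee = lag_ee, lag_ei = lag_ei, lag_inh = lag_in,
              alpha_gain = config$alpha_gain,
              sd_exc = sqrt(config$noise_var_exc),
              sd_inh = sqrt(config$noise_var_inh),
              xi_shift = as.integer(config$xi_shift))
  if (is.null(state)) {
    old <- .Random.seed_save(); set.seed(init_seed)
    phi <- matrix(runif(n * n * 5), n * n, 5)
    .Random.seed_restore(old)
    state <- list(phi = phi,
                  Chist = matrix(0, n * n, lag_ee),
                  Dhist = matrix(0, n * n, lag_in),
                  t_next = 0L)
  }
  if (is.null(rec_mask)) rec_mask <- rep(1L, n * n)
  rec_mask <- as.integer(as.vector(rec_mask) != 0)
  sp <- switch(snapshot_pop, N = 0L, S = 1L, W = 2L, E = 3L, exc = -1L,
               stop("snapshot_pop must be N/S/W/E/exc"))
  res <- lif_core_cpp(n, spec$m, Ahat, Bhat, dm, as.integer(drive_idx),
                      a_inh_t, vel, prm, config$boundary == "periodic",
                      rec_mask, as.integer(snapshot_every), sp,
                      as.numeric(seed), as.integer(state$t_next),
                      state$phi, state$Chist, state$Dhist)
  ev <- as.data.frame(res$events)
  ev$pop <- c("N", "S", "W", "E", "inh")[ev$pop]
  list(events = ev,
       counts = res$counts,
       tally = res$tally,
       snapshots = res$snapshots,
       state = list(phi = res$phi, Chist = res$Chist, Dhist = res$Dhist,
                    t_next = state$t_next + T))
}

# state-resolved drive maps for a config: indices 1=run, 2=idle
.base_drive_maps <- function(config) {
  list(run = excitatory_drive_field(config, "run"),
       idle = excitatory_drive_field(config, "idle"))
}

#' Allocentric setup phase
#'
#' Before the main simulation, the network learns the bump configurations at
#' the two track ends in an accelerated manner: starting from random membrane
#' potentials the lattice settles, the animal runs once in each direction, and
#' after each run a stationary learning period tallies excitatory spikes per
#' sheet location. The tallies are linearly rescaled into the two allocentric
#' drive maps ([learn_allocentric_drive()]).
#'
#' @param config a `grid_config` with `allocentric_enabled = TRUE`.
#' @param seed integer seed.
#' @param settle_ms settling time before the first run.
#' @return list with `maps` (list `end0`, `endL` of `n x n` drive maps),
#'   `state` (network state at the 0-cm end, ready to start a session there),
#'   and `gain_check` (bump displacement of the two learned maps).
#' @export
setup_phase <- function(config, seed = config$seed, settle_ms = 1000) {
  maps <- .base_drive_maps(config)
  p_run <- resolve_params(config, "run")
  n <- config$n
  L <- config$track_length_cm
  v <- config$run_speed_target
  run_ms <- round(L / 100 / v * 1000 / config$dt)
  mask0 <- rep(0L, n * n)   # no event recording during setup

  seg <- function(T, a_inh, vx, state, snap = 0) {
    run_network(config, maps, rep(1L, T),
                rep(a_inh, T), cbind(rep(vx, T), 0),
                seed = seed, state = state, rec_mask = mask0,
                snapshot_every = snap, init_seed = seed)
  }
  Ts <- round(settle_ms / config$dt)
  Tl <- round(config$setup_learn_ms / config$dt)
  r <- seg(Ts, p_run$a_mag_inh, 0, NULL)            # settle at x = 0
  r <- seg(run_ms, p_run$a_mag_inh, v, r$state)     # run 0 -> L
  rl <- seg(Tl, p_run$a_mag_inh, 0, r$state)        # learn at L
  tallies_L <- rl$tally
  r <- seg(run_ms, p_run$a_mag_inh, -v, rl$state)   # run L -> 0
  r0 <- seg(Tl, p_run$a_mag_inh, 0, r$state)        # learn at 0
  tallies_0 <- r0$tally
  if (all(tallies_0 == 0) || all(tallies_L == 0))
    stop("allocentric setup failed: degenerate spike tallies", call. = FALSE)
  list(maps = list(end0 = learn_allocentric_drive(tallies_0, config),
                   endL = learn_allocentric_drive(tallies_L, config)),
       state = r0$state,
       tallies = list(end0 = tallies_0, endL = tallies_L))
}

#' Simulate a full session
#'
#' Runs the network through a behavioural trajectory: during `run` segments
#' the excitatory drive is the radial run profile modulated by velocity and
#' the inhibitory drive oscillates at theta frequency (phase offset redrawn at
#' the start of every lap); during `idle` segments both drives drop (and the
#' oscillation stops), which replaces central attractor bumps by traveling
#' wavefronts toward the sheet edge; `allo` segments inject the learned
#' allocentric map for the track end the animal occupies.
#'
#' Spike events are recorded at the union of the two tetrode-style recording
#' sets ([select_recording_regions()]), or everywhere if
#' `record = "all"`.
#'
#' @param config a `grid_config`.
#' @param trajectory a `grid_trajectory` from [generate_track_trajectory()].
#' @param seed integer seed (noise, theta offsets, region placement).
#' @param setup result of [setup_phase()]; computed here when `NULL` and
#'   `allocentric_enabled`.
#' @param record `"regions"` (default) or `"all"`.
#' @param snapshot_every optional snapshot cadence in steps.
#' @return a `grid_session` object: list with `events` (data.frame `pop`,
#'   `x`, `y`, `t_ms`), `trajectory`, `drive_trace` (inhibitory drive per
#'   step), `psi0` (per lap), `regions` (recording sets), `allo_maps`,
#'   `counts`, `config`, `seed`.
#' @export
run_session <- function(config, trajectory, seed = config$seed, setup = NULL,
                        record = "regions", snapshot_every = 0) {
  stopifnot(inherits(trajectory, "grid_trajectory"))
  if (!is.null(attr(trajectory, "config_n")) &&
      attr(trajectory, "config_n") != config$n)
    stop("trajectory was generated for a different sheet size", call. = FALSE)
  n <- config$n
  T <- nrow(trajectory)
  L <- config$track_length_cm
  maps <- .base_drive_maps(config)
  if (isTRUE(config$allocentric_enabled)) {
    if (is.null(setup)) setup <- setup_phase(config, seed)
    maps$allo0 <- setup$maps$end0
    maps$alloL <- setup$maps$endL
    state0 <- setup$state
  } else {
    state0 <- NULL
  }

  st <- trajectory$state
  track_x <- attr(trajectory, "track_pos_cm")
  if (is.null(track_x)) track_x <- trajectory$x_cm
  drive_idx <- rep(1L, T)
  drive_idx[st == "idle"] <- 2L
  if (isTRUE(config$allocentric_enabled)) {
    allo <- st == "allo"
    drive_idx[allo & track_x < L / 2] <- 3L
    drive_idx[allo & track_x >= L / 2] <- 4L
  } else {
    drive_idx[st == "allo"] <- 2L   # no correction: stay in idle drive
  }

  # per-lap theta offsets
  old <- .Random.seed_save(); set.seed(seed + 77L)
  n_laps <- max(trajectory$lap)
  psi0 <- runif(max(n_laps, 1), 0, 2 * pi)
  .Random.seed_restore(old)

  p_run <- resolve_params(config, "run")
  p_allo <- resolve_params(config, "allo")
  t_ms <- trajectory$t_ms
  a_inh_t <- numeric(T)
  run_rows <- which(st == "run")
  if (length(run_rows)) {
    lp <- trajectory$lap[run_rows]
    a_inh_t[run_rows] <- p_run$a_mag_inh - p_run$a_theta_inh *
      cos(2 * pi * p_run$f_theta * t_ms[run_rows] / 1000 + psi0[lp])
  }
  a_inh_t[st == "allo"] <-
    if (isTRUE(config$allocentric_enabled)) p_allo$a_mag_inh else
      resolve_params(config, "idle")$a_mag_inh
  # idle rows: a_mag_inh[idle] = 0 by default
  a_inh_t[st == "idle"] <- resolve_params(config, "idle")$a_mag_inh

  regions <- list(A = select_recording_regions(config, seed, "A"),
                  B = select_recording_regions(config, seed, "B"))
  rec_mask <- if (identical(record, "all")) rep(1L, n * n) else
    .region_mask(config, regions)

  vel <- cbind(trajectory$vx_mps, trajectory$vy_mps)
  res <- run_network(config, maps, drive_idx, a_inh_t, vel, seed = seed,
                     state = state0, rec_mask = rec_mask,
                     snapshot_every = snapshot_every,
                     init_seed = seed)
  ev <- res$events
  # convert to session-relative ms (state0 may carry a time offset)
  t0 <- if (!is.null(state0)) state0$t_next else 0L
  ev$t_ms <- (ev$t - t0) * config$dt
  structure(list(events = ev, trajectory = trajectory,
                 drive_trace = a_inh_t, psi0 = psi0, regions = regions,
                 allo_maps = if (isTRUE(config$allocentric_enabled))
                   setup$maps else NULL,
                 counts = res$counts, snapshots = res$snapshots,
                 config = config, seed = seed),
            class = "grid_session")
}

#' @export
print.grid_session <- function(x, ...) {
  cat("<grid_session> ", nrow(x$trajectory), " ms, ",
      max(x$trajectory$lap), " laps, ", nrow(x$events),
      " recorded spikes\n", sep = "")
  invisible(x)
}

#' Path-integration displacement
#'
#' Measures how far the attractor-bump lattice moves on the sheet while the
#' (virtual) animal runs at a fixed velocity: snapshots of one excitatory
#' population are cross-correlated snapshot-to-snapshot and the incremental
#' lattice shifts are summed.
#'
#' @param config a `grid_config`.
#' @param fixed_vel velocity `(vx, vy)` in m/s.
#' @param duration_ms measurement duration after settling.
#' @param seed integer seed.
#' @param settle_ms settling time with zero velocity.
#' @param oscillate if `TRUE` keep the theta oscillation on; default uses the
#'   fixed mean inhibitory drive.
#' @param frame_ms frame length over which successive lattice shifts are
#'   measured. Choose it so the expected shift per frame is a few neurons:
#'   much smaller shifts are biased toward zero by peak locking, much larger
#'   ones risk ambiguity with the lattice period.
#' @param a_inh fixed inhibitory drive; defaults to the run-state mean.
#' @param state optional pre-settled network state (skips settling).
#' @return list with `displacement` (neurons, vector `(dx, dy)` on the sheet),
#'   `magnitude`, `per_s` (neurons per second), the frame count, and the
#'   final network `state`.
#' @export
path_integration_displacement <- function(config, fixed_vel, duration_ms,
                                          seed = config$seed,
                                          settle_ms = 800,
                                          oscillate = FALSE,
                                          frame_ms = 250,
                                          a_inh = NULL,
                                          state = NULL) {
  p <- resolve_params(config, "run")
  if (is.null(a_inh)) a_inh <- p$a_mag_inh
  maps <- .base_drive_maps(config)
  Tm <- round(duration_ms / config$dt)
  frame <- max(1L, round(frame_ms / config$dt))
  nomask <- rep(0L, config$n^2)
  if (is.null(state)) {
    Ts <- round(settle_ms / config$dt)
    r <- run_network(config, maps, rep(1L, Ts), rep(a_inh, Ts),
                     cbind(rep(0, Ts), 0), seed = seed, rec_mask = nomask)
    state <- r$state
  }
  a_m <- if (oscillate)
    a_inh - p$a_theta_inh *
      cos(2 * pi * p$f_theta * seq_len(Tm) * config$dt / 1000)
  else rep(a_inh, Tm)
  r <- run_network(config, maps, rep(1L, Tm), a_m,
                   cbind(rep(fixed_vel[1], Tm), rep(fixed_vel[2], Tm)),
                   seed = seed, state = state, rec_mask = nomask,
                   snapshot_every = frame, snapshot_pop = "S")
  snaps <- r$snapshots
  if (is.null(snaps) || dim(snaps)[3] < 2)
    stop("not enough frames to track the lattice", call. = FALSE)
  tr <- .track_lattice(snaps, sigma = 2,
                       max_step = ceiling(config$r_w_inh) + 2)
  disp <- tr$displacement
  dur_s <- (dim(snaps)[3] - 1) * frame * config$dt / 1000
  list(displacement = disp, magnitude = sqrt(sum(disp^2)),
       per_s = sqrt(sum(disp^2)) / dur_s, n_frames = dim(snaps)[3],
       state = r$state)
}

# mask of sheet locations within the recording regions
.region_mask <- function(config, regions) {
  n <- config$n
  m <- matrix(0L, n, n)
  centers <- rbind(regions$A$centers, regions$B$centers)
  rad <- config$region_radius
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    xs <- max(1, floor(cx - rad)):min(n, ceiling(cx + rad))
    ys <- max(1, floor(cy - rad)):min(n, ceiling(cy + rad))
    for (y in ys) {
      dx2 <- (xs - cx)^2 + (y - cy)^2
      m[xs[dx2 <= rad^2], y] <- 1L
    }
  }
  m
}

#' Gaussian smoothing of a matrix (reflective edges)
#' @param x matrix.
#' @param sigma s.d. in pixels; 0 returns `x`.
#' @return smoothed matrix.
#' @export
gauss_smooth2d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad <- function(v) c(rev(v[seq_len(r)]), v, rev(v[(length(v) - r + 1):length(v)]))
  sm1 <- function(v) stats::filter(pad(v), k)[(r + 1):(r + length(v))]
  x <- apply(x, 2, sm1)
  t(apply(x, 1, sm1))
}

# subpixel peak of the circular cross-correlation between two matrices,
# restricted to shifts within max_shift of `center`. Positive shift means the
# content of `b` is displaced by +shift relative to `a`.
.xcorr_shift <- function(a, b, max_shift, center = c(0, 0)) {
  a <- a - mean(a); b <- b - mean(b)
  X <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE))
  n1 <- nrow(X); n2 <- ncol(X)
  center <- round(center)
  sh1 <- (center[1] - max_shift):(center[1] + max_shift)
  sh2 <- (center[2] - max_shift):(center[2] + max_shift)
  idx1 <- (sh1 %% n1) + 1
  idx2 <- (sh2 %% n2) + 1
  W <- X[idx1, idx2]
  pk <- which(W == max(W), arr.ind = TRUE)[1, ]
  # parabolic subpixel refinement
  ref <- function(im1, i0, ip1) {
    den <- im1 - 2 * i0 + ip1
    if (abs(den) < 1e-12) 0 else 0.5 * (im1 - ip1) / den
  }
  dx <- sh1[pk[1]]; dy <- sh2[pk[2]]
  if (pk[1] > 1 && pk[1] < length(sh1))
    dx <- dx + ref(W[pk[1] - 1, pk[2]], W[pk[1], pk[2]], W[pk[1] + 1, pk[2]])
  if (pk[2] > 1 && pk[2] < length(sh2))
    dy <- dy + ref(W[pk[1], pk[2] - 1], W[pk[1], pk[2]], W[pk[1], pk[2] + 1])
  list(shift = c(dx, dy), value = W[pk[1], pk[2]])
}

# track cumulative lattice displacement across a snapshot cube, predicting
# each frame-to-frame shift from the previous one
.track_lattice <- function(snaps, sigma = 2, max_step = 10) {
  disp <- c(0, 0); inc <- c(0, 0)
  prev <- gauss_smooth2d(snaps[, , 1], sigma)
  K <- dim(snaps)[3]
  path <- matrix(0, K, 2)
  for (k in 2:K) {
    cur <- gauss_smooth2d(snaps[, , k], sigma)
    s <- .xcorr_shift(prev, cur, max_step, center = inc)
    inc <- s$shift
    disp <- disp + inc
    path[k, ] <- disp
    prev <- cur
  }
  list(displacement = disp, path = path)
}
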