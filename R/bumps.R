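#' Segment attractor bumps in an activity snapshot
#'
#' Smooths a spike-count snapshot, thresholds at a fraction of its maximum,
#' and labels connected supra-threshold components. Each component becomes a
#' bump with a centroid and an equivalent-circle diameter.
#'
#' @param snapshot `n x n` matrix of spike counts (e.g. a 10 ms window of one
#'   excitatory population).
#' @param smooth_sigma Gaussian smoothing s.d. (neurons).
#' @param threshold_frac threshold as a fraction of the smoothed maximum.
#' @param central_frac restrict to bumps whose centroid lies within this
#'   fraction of the sheet half-width from the centre (`Inf` keeps all);
#'   with the radial drive profile, outer bumps sit in a weaker-drive
#'   environment and are not representative.
#' @param min_area minimum component area (pixels).
#' @return data frame `x`, `y` (centroid), `area`, `diameter` (neurons),
#'   `peak` (smoothed peak activity).
#' @export
segment_bumps <- function(snapshot, smooth_sigma = 1.5, threshold_frac = 0.3,
                          central_frac = 0.6, min_area = 4) {
  sm <- gauss_smooth2d(snapshot, smooth_sigma)
  mx <- max(sm)
  out <- data.frame(x = numeric(0), y = numeric(0), area = numeric(0),
                    diameter = numeric(0), peak = numeric(0))
  if (mx <= 0) return(out)
  lab <- label_components_cpp(sm, threshold_frac * mx)
  nlab <- max(lab)
  if (nlab == 0) return(out)
  n <- nrow(snapshot)
  ctr <- (n + 1) / 2
  rows <- list()
  for (k in seq_len(nlab)) {
    ix <- which(lab == k, arr.ind = TRUE)
    if (nrow(ix) < min_area) next
    w <- sm[ix]
    cx <- sum(ix[, 1] * w) / sum(w); cy <- sum(ix[, 2] * w) / sum(w)
    if (sqrt((cx - ctr)^2 + (cy - ctr)^2) > central_frac * n / 2) next
    rows[[length(rows) + 1]] <- data.frame(
      x = cx, y = cy, area = nrow(ix),
      diameter = 2 * sqrt(nrow(ix) / pi), peak = max(w))
  }
  if (length(rows)) out <- do.call(rbind, rows)
  out
}

#' Bump size and speed under fixed inhibitory drive
#'
#' Runs run-state simulations with the theta oscillation switched off
#' (`a_theta_inh = 0`) at a set of fixed inhibitory drive levels and constant
#' animal velocity. At each level the mean attractor-bump diameter is
#' measured by segmentation of short activity snapshots, and the bump speed
#' by tracking the lattice displacement across coarser frames. Both
#' quantities are regressed linearly on the drive level: the diameter
#' decreases and the speed increases with inhibitory drive.
#'
#' @param config a `grid_config`.
#' @param levels fixed inhibitory drive levels; the default spans the range
#'   visited by the theta oscillation of the run state
#'   (`a_mag_inh +/- a_theta_inh`).
#' @param fixed_vel constant velocity (m/s).
#' @param duration_ms measurement duration per level.
#' @param seed integer seed.
#' @param settle_ms settling time per level.
#' @param speed_frame_ms frame length for the speed measurement.
#' @return object of class `bump_metrics`: list with `levels` (data frame:
#'   `a_inh`, `diameter`, `speed`, `n_bumps`), `diameter_fit` and `speed_fit`
#'   (each: slope, intercept, r_squared, anova_p).
#' @export
fixed_drive_sweep <- function(config, levels = NULL, fixed_vel = c(0.5, 0),
                              duration_ms = 2000, seed = config$seed,
                              settle_ms = 800, speed_frame_ms = 100) {
  p <- resolve_params(config, "run")
  if (is.null(levels))
    levels <- seq(p$a_mag_inh - p$a_theta_inh, p$a_mag_inh + p$a_theta_inh,
                  length.out = 5)
  maps <- .base_drive_maps(config)
  snap <- max(1L, round(config$snapshot_ms / config$dt))
  nomask <- rep(0L, config$n^2)
  # settle the standard lattice at the mean run-state drive once; each level
  # then continues from it, as the oscillating drive does within theta cycles
  Ts <- round(settle_ms / config$dt)
  base <- run_network(config, maps, rep(1L, Ts), rep(p$a_mag_inh, Ts),
                      cbind(rep(0, Ts), 0), seed = seed, rec_mask = nomask)
  rows <- list()
  for (a in levels) {
    Tb <- round(400 / config$dt)         # re-equilibrate at the target level
    Tm <- round(duration_ms / config$dt)
    r <- run_network(config, maps, rep(1L, Tb), rep(a, Tb),
                     cbind(rep(0, Tb), 0), seed = seed, state = base$state,
                     rec_mask = nomask)
    r <- run_network(config, maps, rep(1L, Tm), rep(a, Tm),
                     cbind(rep(fixed_vel[1], Tm), rep(fixed_vel[2], Tm)),
                     seed = seed, state = r$state,
                     rec_mask = nomask,
                     snapshot_every = snap, snapshot_pop = "S")
    sn <- r$snapshots
    if (is.null(sn)) next
    # diameters from individual short snapshots
    dia <- numeric(0); nb <- 0L
    for (k in seq(1, dim(sn)[3], by = 2)) {
      b <- segment_bumps(sn[, , k], config$bump_smooth_sigma,
                         config$bump_threshold_frac)
      dia <- c(dia, b$diameter); nb <- nb + nrow(b)
    }
    if (!length(dia)) { message("no bumps at a_inh = ", a); next }
    # the median is robust to occasional merged neighbouring bumps
    dia_stat <- stats::median(dia)
    # speed from coarse frames
    agg <- round(speed_frame_ms / config$snapshot_ms)
    K <- floor(dim(sn)[3] / agg)
    fr <- array(0, c(dim(sn)[1], dim(sn)[2], K))
    for (k in seq_len(K))
      fr[, , k] <- apply(sn[, , ((k - 1) * agg + 1):(k * agg)], c(1, 2), sum)
    tr <- .track_lattice(fr, sigma = 2, max_step = ceiling(config$r_w_inh) + 2)
    sp <- sqrt(sum(tr$displacement^2)) /
      ((K - 1) * speed_frame_ms / 1000)
    rows[[length(rows) + 1]] <- data.frame(a_inh = a, diameter = dia_stat,
                                           mean_diameter = mean(dia),
                                           speed = sp, n_bumps = nb)
  }
  lev <- do.call(rbind, rows)
  lin <- function(y) {
    fit <- stats::lm(y ~ lev$a_inh)
    an <- stats::anova(fit)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = summary(fit)$r.squared,
         anova_p = an$`Pr(>F)`[1])
  }
  structure(list(levels = lev,
                 diameter_fit = lin(lev$diameter),
                 speed_fit = lin(lev$speed)),
            class = "bump_metrics")
}

#' Phase-resolved average bump shape
#'
#' Runs a run-state simulation with the theta oscillation on and constant
#' velocity, tracks the lattice displacement, and averages activity around
#' the predicted bump position in a constant-velocity reference frame,
#' binned by theta phase. The average bump is largest near phase 0/360
#' (lowest inhibition) and its peak moves in a sawtooth: lagging the uniform
#' motion early in the cycle and surging ahead mid-cycle.
#'
#' @param config a `grid_config`.
#' @param duration_ms measurement duration (whole theta cycles are used).
#' @param fixed_vel constant velocity (m/s).
#' @param seed integer seed.
#' @param n_phase_bins theta phase bins.
#' @param halfwidth window half-width (neurons) around the predicted centre.
#' @param frame_ms snapshot cadence; must divide the theta period.
#' @param settle_ms settling time.
#' @return object of class `average_bump`: list with `activity` (array
#'   `n_phase_bins x (2*halfwidth+1) x (2*halfwidth+1)`), `phase_centers`
#'   (deg), `axis_profile` (phase x offset along the motion axis),
#'   `peak_offset` (neurons, per phase bin, relative to the reference),
#'   `ref_speed` (neurons/s).
#' @export
average_bump_shape <- function(config, duration_ms = 4000,
                               fixed_vel = c(0.5, 0), seed = config$seed,
                               n_phase_bins = 12, halfwidth = 16,
                               frame_ms = 5, settle_ms = 1000) {
  p <- resolve_params(config, "run")
  maps <- .base_drive_maps(config)
  Ts <- round(settle_ms / config$dt)
  Tm <- round(duration_ms / config$dt)
  frame <- max(1L, round(frame_ms / config$dt))
  nomask <- rep(0L, config$n^2)
  r <- run_network(config, maps, rep(1L, Ts), rep(p$a_mag_inh, Ts),
                   cbind(rep(0, Ts), 0), seed = seed, rec_mask = nomask)
  tvec <- seq_len(Tm) * config$dt
  a_m <- p$a_mag_inh - p$a_theta_inh *
    cos(2 * pi * p$f_theta * tvec / 1000)      # psi0 = 0: phase = 2 pi f t
  r <- run_network(config, maps, rep(1L, Tm), a_m,
                   cbind(rep(fixed_vel[1], Tm), rep(fixed_vel[2], Tm)),
                   seed = seed, state = r$state, rec_mask = nomask,
                   snapshot_every = frame, snapshot_pop = "S")
  sn <- r$snapshots
  K <- dim(sn)[3]
  if (K < 8) stop("too few snapshots for bump averaging", call. = FALSE)
  # track lattice on theta-cycle frames to get the smooth reference motion
  cyc_ms <- 1000 / p$f_theta
  agg <- max(1L, round(cyc_ms / frame_ms))
  Kc <- floor(K / agg)
  fr <- array(0, c(dim(sn)[1], dim(sn)[2], Kc))
  for (k in seq_len(Kc))
    fr[, , k] <- apply(sn[, , ((k - 1) * agg + 1):(k * agg)], c(1, 2), sum)
  trk <- .track_lattice(fr, sigma = 2, max_step = ceiling(config$r_w_inh) + 2)
  # constant-velocity reference: least-squares line through cycle positions
  tc <- (seq_len(Kc) - 0.5) * cyc_ms
  vfit_x <- stats::lm(trk$path[, 1] ~ tc)
  vfit_y <- stats::lm(trk$path[, 2] ~ tc)
  # initial bump nearest the sheet centre (from the first cycle frame)
  b0 <- segment_bumps(fr[, , 1], config$bump_smooth_sigma,
                      config$bump_threshold_frac, central_frac = 0.5)
  if (!nrow(b0)) stop("no central bump found", call. = FALSE)
  n <- config$n
  ctr <- (n + 1) / 2
  b0 <- b0[which.min((b0$x - ctr)^2 + (b0$y - ctr)^2), ]
  W <- halfwidth
  acc <- array(0, c(n_phase_bins, 2 * W + 1, 2 * W + 1))
  cnt <- numeric(n_phase_bins)
  for (k in seq_len(K)) {
    tmid <- (k - 0.5) * frame_ms
    phase <- (360 * p$f_theta * tmid / 1000) %% 360
    pb <- min(n_phase_bins, 1 + floor(phase / 360 * n_phase_bins))
    px <- round(b0$x + stats::predict(vfit_x,
                                      newdata = data.frame(tc = tmid)))
    py <- round(b0$y + stats::predict(vfit_y,
                                      newdata = data.frame(tc = tmid)))
    if (px - W < 1 || px + W > n || py - W < 1 || py + W > n) next
    acc[pb, , ] <- acc[pb, , ] + sn[px + (-W:W), py + (-W:W), k]
    cnt[pb] <- cnt[pb] + 1
  }
  for (b in seq_len(n_phase_bins))
    if (cnt[b] > 0) acc[b, , ] <- acc[b, , ] / cnt[b]
  # profile along the motion axis (x for the default eastward velocity)
  axis_profile <- matrix(0, n_phase_bins, 2 * W + 1)
  peak_offset <- numeric(n_phase_bins)
  for (b in seq_len(n_phase_bins)) {
    sl <- gauss_smooth2d(acc[b, , ], 1.5)
    prof <- rowSums(sl[, (W - 3):(W + 5)])    # central band
    axis_profile[b, ] <- prof
    peak_offset[b] <- (-W:W)[which.max(prof)]
  }
  structure(list(activity = acc,
                 phase_centers = (seq_len(n_phase_bins) - 0.5) *
                   360 / n_phase_bins,
                 axis_profile = axis_profile, peak_offset = peak_offset,
                 ref_speed = sqrt(stats::coef(vfit_x)[2]^2 +
                                    stats::coef(vfit_y)[2]^2) * 1000,
                 counts = cnt),
            class = "average_bump")
}

#' Conceptual model: threshold pass through an oscillating bump
#'
#' A point neuron at location 0 is crossed by an attractor bump whose centre
#' moves at constant speed and whose diameter follows the fitted linear
#' dependence on the oscillating inhibitory drive. The neuron fires whenever
#' it lies inside the bump, subject to a 40 ms refractory period. Each lap
#' uses a different initial theta phase; pooled spikes show phase precession.
#'
#' @param diameter_law function mapping inhibitory drive to bump diameter
#'   (neurons), e.g. built from a [fixed_drive_sweep()] fit.
#' @param v bump speed (neurons/s).
#' @param refractory_ms refractory period.
#' @param initial_phases_deg initial theta phase per lap.
#' @param f_theta,a_mag,a_theta inhibitory drive parameters.
#' @param dt_ms time step.
#' @return data frame `lap`, `t_ms` (time from field entry of the bump
#'   centre), `phase_deg`.
#' @export
simulate_threshold_pass <- function(diameter_law, v, refractory_ms = 40,
                                    initial_phases_deg = seq(0, 330, by = 30),
                                    f_theta = 8, a_mag = 0.72, a_theta = 0.2,
                                    dt_ms = 1) {
  dmax <- diameter_law(a_mag - a_theta)
  x0 <- -0.75 * dmax
  T <- ceiling(2 * abs(x0) / v * 1000 / dt_ms)
  rows <- list()
  for (l in seq_along(initial_phases_deg)) {
    psi <- initial_phases_deg[l] * pi / 180
    last <- -Inf
    for (k in seq_len(T)) {
      t <- k * dt_ms
      a <- a_mag - a_theta * cos(2 * pi * f_theta * t / 1000 + psi)
      D <- max(diameter_law(a), 0)
      xc <- x0 + v * t / 1000
      if (abs(xc) <= D / 2 && t - last >= refractory_ms) {
        phase <- ((2 * pi * f_theta * t / 1000 + psi) * 180 / pi) %% 360
        rows[[length(rows) + 1]] <- data.frame(lap = l, t_ms = t,
                                               phase_deg = phase)
        last <- t
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(lap = integer(0), t_ms = numeric(0), phase_deg = numeric(0))
}

#' Conceptual model: Poisson pass through the average bump
#'
#' A point neuron is crossed by the phase-resolved average bump; it fires as
#' an inhomogeneous point process with rate proportional to the bump activity
#' at its location (rescaled to `max_rate`), thinned by a refractory period.
#' High maximal rates produce phase independence, low rates phase locking
#' near 360 degrees, and intermediate rates phase precession.
#'
#' @param average_bump an `average_bump` object, or a function
#'   `f(phase_deg, offset_neurons)` returning relative activity in \[0, 1\].
#' @param max_rate maximal firing rate (spikes/s).
#' @param v bump speed (neurons/s).
#' @param n_laps laps (initial phases drawn uniformly).
#' @param seed integer seed.
#' @param refractory_ms refractory period.
#' @param f_theta theta frequency (Hz).
#' @param dt_ms time step.
#' @return data frame `lap`, `t_ms`, `phase_deg`, plus attribute `stats`
#'   (circular-linear regression of phase on time across the pass).
#' @export
simulate_poisson_pass <- function(average_bump, max_rate, v, n_laps = 40,
                                  seed = 1, refractory_ms = 40, f_theta = 8,
                                  dt_ms = 1) {
  act <- if (is.function(average_bump)) average_bump else {
    ab <- average_bump
    mx <- max(ab$axis_profile)
    function(phase_deg, offset) {
      pb <- 1 + floor((phase_deg %% 360) / 360 * length(ab$phase_centers))
      pb <- min(pb, length(ab$phase_centers))
      W <- (ncol(ab$axis_profile) - 1) / 2
      o <- round(offset)
      if (abs(o) > W) return(0)
      ab$axis_profile[pb, o + W + 1] / mx
    }
  }
  # pass length: activity support
  halfspan <- 25
  T <- ceiling(2 * halfspan / v * 1000 / dt_ms)
  old <- .Random.seed_save(); set.seed(seed)
  psis <- runif(n_laps, 0, 360)
  rows <- list()
  for (l in seq_len(n_laps)) {
    last <- -Inf
    u <- runif(T)
    for (k in seq_len(T)) {
      t <- k * dt_ms
      phase <- (360 * f_theta * t / 1000 + psis[l]) %% 360
      offset <- -(-halfspan + v * t / 1000)  # neuron at 0, bump centre moves
      rate <- max_rate * act(phase, offset)
      if (t - last >= refractory_ms && u[k] < rate * dt_ms / 1000) {
        rows[[length(rows) + 1]] <- data.frame(lap = l, t_ms = t,
                                               phase_deg = phase)
        last <- t
      }
    }
  }
  .Random.seed_restore(old)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lap = integer(0), t_ms = numeric(0), phase_deg = numeric(0))
  if (nrow(out) >= 5 && diff(range(out$t_ms)) > 0) {
    fit <- circular_linear_regression(out$phase_deg,
                                      out$t_ms / max(out$t_ms) * 100)
    attr(out, "stats") <- data.frame(
      fit_score = fit$fit_score, slope = fit$slope * 100,
      subgroup = classify_phase_behavior(fit$fit_score, fit$slope * 100,
                                         field_span = 1))
  }
  out
}
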