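#' Generate a 1D track trajectory
#'
#' Builds a session trajectory of alternating end-to-end runs along a linear
#' track separated by idle periods, with a brief allocentric-correction pulse
#' between the end of each idle period and the start of the following run.
#' Running speed fluctuates around `run_speed_target` following a fractional
#' Brownian motion (fractional Gaussian noise) perturbation; instantaneous
#' speed is clipped at `min_speed`.
#'
#' @param config a `grid_config`.
#' @param n_laps number of runs (a lap = one end-to-end traversal).
#' @param seed integer seed for the speed process.
#' @param reversed if `TRUE`, produce the velocity-reversed twin of the same
#'   trajectory: identical speed profiles but every run's direction flipped
#'   (runs start from the opposite end).
#' @return an object of class `grid_trajectory`: a data frame with columns
#'   `t_ms`, `x_cm`, `y_cm`, `vx_mps`, `vy_mps`, `state`
#'   (`"run"`, `"idle"`, `"allo"`), `lap` (0 outside runs) and `direction`
#'   (+1 rightward, -1 leftward, 0 outside runs), one row per timestep.
#' @export
generate_track_trajectory <- function(config, n_laps, seed = config$seed,
                                      reversed = FALSE) {
  stopifnot(n_laps >= 1)
  dt_s <- config$dt / 1000
  L <- config$track_length_cm
  idle_steps <- round(config$idle_duration_s * 1000 / config$dt)
  allo_steps <- round(config$allo_duration_ms / config$dt)

  # one long fGn speed perturbation, sliced across run segments
  max_run_steps <- ceiling(2 * L / 100 / config$run_speed_target / dt_s)
  noise <- fgn(n_laps * max_run_steps, config$fbm_hurst, seed)
  noise <- noise / stats::sd(noise)

  segs <- list()
  pos <- if (reversed) L else 0
  d <- if (reversed) -1L else 1L
  ni <- 1
  for (k in seq_len(n_laps)) {
    # idle at current end, then allocentric pulse, then run
    segs[[length(segs) + 1]] <- data.frame(
      x = pos, v = 0,
      state = rep(c("idle", "allo"), c(idle_steps, allo_steps)),
      lap = 0L, dir = 0L)
    # run until the far end is reached
    if (ni + max_run_steps - 1 > length(noise)) ni <- 1
    sp <- config$run_speed_target *
      (1 + config$fbm_rel_amp * noise[ni:(ni + max_run_steps - 1)])
    sp <- pmax(sp, config$min_speed)
    disp <- cumsum(sp * dt_s * 100)        # cm travelled
    nsteps <- which(disp >= L)[1]
    if (is.na(nsteps)) nsteps <- max_run_steps
    ni <- ni + nsteps
    x <- pos + d * disp[seq_len(nsteps)]
    x <- pmin(pmax(x, 0), L)
    # recorded velocity is the realized step displacement, so position is
    # exactly the discrete integral of velocity (differs from the drawn
    # speed only at the clipped final step of a run)
    v_eff <- diff(c(pos, x)) / (dt_s * 100)
    segs[[length(segs) + 1]] <- data.frame(
      x = x, v = v_eff, state = "run", lap = k, dir = d)
    pos <- x[nsteps]
    d <- -d
  }
  # terminal idle period
  segs[[length(segs) + 1]] <- data.frame(
    x = pos, v = 0, state = rep("idle", idle_steps), lap = 0L, dir = 0L)
  full <- do.call(rbind, segs)
  xs <- full$x; vx <- full$v; state <- full$state
  lap <- full$lap; dir <- full$dir

  ang <- config$track_angle_deg * pi / 180
  out <- data.frame(
    t_ms = (seq_along(xs) - 1) * config$dt,
    x_cm = xs * cos(ang), y_cm = xs * sin(ang),
    vx_mps = vx * cos(ang), vy_mps = vx * sin(ang),
    state = state, lap = lap, direction = dir)
  attr(out, "track_pos_cm") <- xs    # 1D coordinate along the track
  attr(out, "config_n") <- config$n
  class(out) <- c("grid_trajectory", "data.frame")
  out
}

#' Generate a 2D open-field trajectory
#'
#' Smooth random-walk path in a square arena with reflective walls, used for
#' validating 2D grid firing. Velocity follows an Ornstein-Uhlenbeck process
#' whose stationary mean speed equals `run_speed_target`.
#'
#' @param config a `grid_config` (`arena_cm` sets the side length).
#' @param duration_s duration in seconds.
#' @param seed integer seed.
#' @return a `grid_trajectory` data frame (columns as in
#'   [generate_track_trajectory()], all states `"run"`).
#' @export
generate_open_field_trajectory <- function(config, duration_s,
                                           seed = config$seed) {
  T <- round(duration_s * 1000 / config$dt)
  if (T == 0) {
    out <- data.frame(t_ms = numeric(0), x_cm = numeric(0), y_cm = numeric(0),
                      vx_mps = numeric(0), vy_mps = numeric(0),
                      state = character(0), lap = integer(0),
                      direction = integer(0))
    class(out) <- c("grid_trajectory", "data.frame")
    return(out)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  dt_s <- config$dt / 1000
  tau <- 0.7                      # s, velocity correlation time
  sigma <- config$run_speed_target / sqrt(pi / 2)  # Rayleigh mean -> target
  A <- config$arena_cm
  v <- c(0, 0); p <- c(A / 2, A / 2)
  xs <- ys <- vxs <- vys <- numeric(T)
  sq <- sigma * sqrt(2 * dt_s / tau)
  for (t in seq_len(T)) {
    v <- v + (-v / tau) * dt_s + sq * rnorm(2)
    p <- p + v * dt_s * 100
    for (i in 1:2) {              # reflective walls
      if (p[i] < 0) { p[i] <- -p[i]; v[i] <- -v[i] }
      if (p[i] > A) { p[i] <- 2 * A - p[i]; v[i] <- -v[i] }
    }
    xs[t] <- p[1]; ys[t] <- p[2]; vxs[t] <- v[1]; vys[t] <- v[2]
  }
  out <- data.frame(t_ms = (seq_len(T) - 1) * config$dt,
                    x_cm = xs, y_cm = ys, vx_mps = vxs, vy_mps = vys,
                    state = "run", lap = 1L, direction = 0L)
  class(out) <- c("grid_trajectory", "data.frame")
  out
}

#' Velocity modulation of the excitatory drive
#'
#' Each excitatory population P prefers a spatial direction
#' (N = +y, S = -y, W = -x, E = +x); its drive is scaled by
#' `1 + alpha_gain * (E_P . V)`.
#'
#' @param vel velocity vector `(vx, vy)` in m/s, or a matrix with two columns.
#' @param population one of `"N"`, `"S"`, `"W"`, `"E"`.
#' @param alpha_gain gain in s/m.
#' @return dimensionless multiplier(s).
#' @export
velocity_drive_factor <- function(vel, population, alpha_gain = 0.25) {
  E <- switch(population, N = c(0, 1), S = c(0, -1),
              W = c(-1, 0), E = c(1, 0),
              stop("unknown population: ", population))
  if (is.matrix(vel)) 1 + alpha_gain * drop(vel %*% E)
  else 1 + alpha_gain * sum(vel * E)
}

#' Export a trajectory as CSV
#' @param trajectory a `grid_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

# fractional Gaussian noise by circulant embedding (Davies-Harte);
# increments of fractional Brownian motion with Hurst exponent H
fgn <- function(N, H, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  g <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                            abs(k - 1)^(2 * H))
  M <- 2 * .good_fft_size(N)
  row1 <- g(c(0:(M / 2), (M / 2 - 1):1))
  lam <- Re(stats::fft(row1))
  lam[lam < 0] <- 0               # guard tiny negatives
  z <- stats::rnorm(M) + 1i * stats::rnorm(M)
  x <- Re(stats::fft(sqrt(lam / M) * z))
  x[seq_len(N)]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
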