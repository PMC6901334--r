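#' Select tetrode-style recording regions
#'
#' Picks four circular recording areas on the neural sheet, centred at a
#' fixed distance from the sheet centre (95 neurons on the default 232-wide
#' sheet, scaled proportionally for other sheet sizes) at equally spaced but
#' randomly rotated clock positions. Set `"B"` uses the same radius with
#' angles offset 45 degrees from set `"A"`.
#'
#' @param config a `grid_config`.
#' @param seed integer seed (drives the common angular offset; sets A and B
#'   from the same seed differ by exactly 45 degrees).
#' @param set_id `"A"` or `"B"`.
#' @return a list of class `recording_set`: `centers` (4 x 2 matrix of sheet
#'   coordinates), `set_id`, `distance`, `radius`.
#' @export
select_recording_regions <- function(config, seed = config$seed,
                                     set_id = "A") {
  stopifnot(set_id %in% c("A", "B"))
  n <- config$n
  dist <- config$region_distance
  if (is.na(dist)) dist <- round(95 / 232 * n)
  if (dist + config$region_radius > (n - 1) / 2)
    stop("recording radius exceeds the sheet", call. = FALSE)
  old <- .Random.seed_save(); set.seed(seed + 101L)
  theta0 <- runif(1, 0, 2 * pi)
  .Random.seed_restore(old)
  if (set_id == "B") theta0 <- theta0 + pi / 4
  ang <- theta0 + (0:3) * pi / 2
  ctr <- (n + 1) / 2
  centers <- cbind(ctr + dist * cos(ang), ctr + dist * sin(ang))
  structure(list(centers = centers, set_id = set_id, distance = dist,
                 radius = config$region_radius),
            class = "recording_set")
}

# excitatory spike events of a session restricted to one recording set,
# with neuron ids and track positions/velocities at spike times
.set_events <- function(session, set = "A") {
  reg <- session$regions[[set]]
  ev <- session$events
  ev <- ev[ev$pop != "inh", ]
  keep <- rep(FALSE, nrow(ev))
  for (i in seq_len(nrow(reg$centers)))
    keep <- keep | ((ev$x - reg$centers[i, 1])^2 +
                      (ev$y - reg$centers[i, 2])^2 <= reg$radius^2)
  ev <- ev[keep, ]
  tr <- session$trajectory
  ix <- ev$t_ms / session$config$dt + 1
  ix <- pmin(pmax(round(ix), 1), nrow(tr))
  track_x <- attr(tr, "track_pos_cm")
  ev$pos_cm <- track_x[ix]
  ev$state <- tr$state[ix]
  ev$lap <- tr$lap[ix]
  ev$direction <- tr$direction[ix]
  ev$speed <- abs(tr$vx_mps[ix] + 1i * tr$vy_mps[ix])
  ev$neuron <- paste(ev$pop, ev$x, ev$y, sep = "_")
  ev
}

#' Select stable recorded neurons
#'
#' From the excitatory neurons inside one recording set's regions, keeps up to
#' `max_recorded` whose firing fields are stable from lap to lap: the standard
#' deviation of the per-lap field-peak position is below `stability_sd_cm` and
#' the peak firing rate exceeds `min_peak_rate`. When more qualify than the
#' cap, the most stable (smallest peak spread) are retained.
#'
#' @param session a `grid_session`.
#' @param set `"A"` or `"B"`.
#' @return data frame with one row per selected neuron (`neuron`, `pop`, `x`,
#'   `y`, `peak_sd_cm`, `peak_rate`, `n_laps_active`); attribute `usable` is
#'   `FALSE` (with a warning) when fewer than 10 qualify.
#' @export
select_stable_neurons <- function(session, set = "A") {
  cfg <- session$config
  ev <- .set_events(session, set)
  ev <- ev[ev$state == "run", ]
  tr <- session$trajectory
  L <- cfg$track_length_cm
  bw <- cfg$rate_bin_cm
  breaks <- seq(0, L, by = bw)
  mids <- breaks[-1] - bw / 2
  n_laps <- max(tr$lap)
  if (n_laps < 2) stop("need at least 2 laps", call. = FALSE)

  # per-lap occupancy (s) per bin
  occ <- matrix(0, n_laps, length(mids))
  track_x <- attr(tr, "track_pos_cm")
  run_rows <- tr$state == "run"
  occ_tab <- table(factor(tr$lap[run_rows], levels = seq_len(n_laps)),
                   cut(track_x[run_rows], breaks, include.lowest = TRUE))
  occ[] <- as.numeric(occ_tab) * cfg$dt / 1000
  sm <- cfg$rate_smooth_cm / bw

  stats_list <- lapply(split(ev, ev$neuron), function(e) {
    peaks <- rep(NA_real_, n_laps)
    rates <- numeric(n_laps)
    for (l in seq_len(n_laps)) {
      el <- e[e$lap == l, ]
      if (nrow(el) < 3) next
      h <- tabulate(findInterval(el$pos_cm, breaks,
                                 rightmost.closed = TRUE, all.inside = TRUE),
                    nbins = length(mids))
      r <- h / pmax(occ[l, ], 1e-6)
      r <- gauss_smooth1d(r, sm)
      peaks[l] <- mids[which.max(r)]
      rates[l] <- max(r)
    }
    ok <- !is.na(peaks)
    data.frame(pop = e$pop[1], x = e$x[1], y = e$y[1],
               n_laps_active = sum(ok),
               peak_sd_cm = if (sum(ok) >= 2) sd(peaks[ok]) else NA_real_,
               peak_rate = max(rates))
  })
  st <- do.call(rbind, stats_list)
  st$neuron <- rownames(st)
  keep <- !is.na(st$peak_sd_cm) &
    st$n_laps_active >= max(2, floor(n_laps / 2)) &
    st$peak_sd_cm < cfg$stability_sd_cm &
    st$peak_rate > cfg$min_peak_rate
  sel <- st[keep, ]
  sel <- sel[order(sel$peak_sd_cm), ]
  if (nrow(sel) > cfg$max_recorded) sel <- sel[seq_len(cfg$max_recorded), ]
  usable <- nrow(sel) >= 10
  if (!usable)
    warning("fewer than 10 stable neurons in set ", set,
            "; recording flagged unusable")
  rownames(sel) <- NULL
  attr(sel, "usable") <- usable
  attr(sel, "set") <- set
  sel
}

#' 1D Gaussian smoothing
#' @param v numeric vector.
#' @param sigma s.d. in samples; 0 returns `v`.
#' @return smoothed vector (reflective edges).
#' @export
gauss_smooth1d <- function(v, sigma) {
  if (sigma <= 0) return(v)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma); k <- k / sum(k)
  vp <- c(rev(v[seq_len(r)]), v, rev(v[(length(v) - r + 1):length(v)]))
  as.numeric(stats::filter(vp, k)[(r + 1):(r + length(v))])
}

#' Compute rate maps and firing fields
#'
#' Occupancy-normalized firing rate per track bin, accrued from all laps in
#' both directions, Gaussian-smoothed. Fields are contiguous runs of bins
#' above `field_threshold_frac` of the neuron's peak rate.
#'
#' @param session a `grid_session`.
#' @param neurons data frame from [select_stable_neurons()] (or any data frame
#'   with a `neuron` column).
#' @return an object of class `firing_fields`: list with `rate`
#'   (neurons x bins matrix, spikes/s), `bin_centers` (cm), `fields` (per
#'   neuron: matrix of `lo`, `hi` bounds in cm), `n_fields`, `neurons`.
#' @export
compute_rate_maps <- function(session, neurons) {
  cfg <- session$config
  L <- cfg$track_length_cm
  bw <- cfg$rate_bin_cm
  breaks <- seq(0, L, by = bw)
  mids <- breaks[-1] - bw / 2
  tr <- session$trajectory
  track_x <- attr(tr, "track_pos_cm")
  run_rows <- tr$state == "run"
  occ <- tabulate(findInterval(track_x[run_rows], breaks,
                               rightmost.closed = TRUE, all.inside = TRUE),
                  nbins = length(mids)) * cfg$dt / 1000
  zero_occ <- occ <= 0
  ev <- .set_events(session, attr(neurons, "set") %||% "A")
  ev <- ev[ev$state == "run" & ev$neuron %in% neurons$neuron, ]
  sm <- cfg$rate_smooth_cm / bw
  rate <- matrix(0, nrow(neurons), length(mids),
                 dimnames = list(neurons$neuron, NULL))
  evs <- split(ev, factor(ev$neuron, levels = neurons$neuron))
  for (i in seq_along(evs)) {
    h <- tabulate(findInterval(evs[[i]]$pos_cm, breaks,
                               rightmost.closed = TRUE, all.inside = TRUE),
                  nbins = length(mids))
    r <- h / pmax(occ, 1e-9)
    if (any(zero_occ))  # interpolate unvisited bins
      r[zero_occ] <- stats::approx(mids[!zero_occ], r[!zero_occ],
                                   mids[zero_occ], rule = 2)$y
    rate[i, ] <- gauss_smooth1d(r, sm)
  }
  fields <- vector("list", nrow(neurons))
  names(fields) <- neurons$neuron
  for (i in seq_len(nrow(neurons))) {
    r <- rate[i, ]
    thr <- cfg$field_threshold_frac * max(r)
    above <- r >= thr & max(r) > 0
    rl <- rle(above)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    fi <- cbind(lo = breaks[starts[rl$values]],
                hi = breaks[ends[rl$values] + 1])
    fields[[i]] <- fi[fi[, 2] - fi[, 1] >= 2 * bw, , drop = FALSE]
  }
  structure(list(rate = rate, bin_centers = mids, occupancy = occ,
                 fields = fields, n_fields = vapply(fields, nrow, 0L),
                 neurons = neurons, bin_cm = bw, track_length_cm = L),
            class = "firing_fields")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' 2D spatial autocorrelation
#'
#' Normalized autocorrelogram of a (rate) map, computed with zero padding;
#' value 1 at zero lag. Used to verify the hexagonal (six inner peaks at 60
#' degree spacing) symmetry of grid maps and lattice snapshots.
#'
#' @param map2d numeric matrix.
#' @param detrend_sigma optional s.d. (pixels) of a Gaussian local-mean that
#'   is subtracted first. Sheet-activity snapshots carry the radial drive
#'   envelope on top of the bump lattice; removing the smooth component at a
#'   scale around half the lattice period exposes the lattice ring.
#' @return matrix of size `(2*nrow-1) x (2*ncol-1)` with the zero-lag at the
#'   centre.
#' @export
rate_map_autocorrelation <- function(map2d, detrend_sigma = NULL) {
  if (!is.null(detrend_sigma))
    map2d <- map2d - gauss_smooth2d(map2d, detrend_sigma)
  a <- map2d - mean(map2d)
  n1 <- nrow(a); n2 <- ncol(a)
  p1 <- 2 * n1; p2 <- 2 * n2
  ap <- matrix(0, p1, p2); ap[1:n1, 1:n2] <- a
  A <- stats::fft(ap)
  ac <- Re(stats::fft(A * Conj(A), inverse = TRUE)) / (p1 * p2)
  # reorder so zero lag is central; lags -(n-1)..(n-1)
  ix1 <- c((p1 - n1 + 2):p1, 1:n1)
  ix2 <- c((p2 - n2 + 2):p2, 1:n2)
  out <- ac[ix1, ix2]
  out / out[n1, n2]
}

#' Count the inner peaks of a lattice autocorrelogram
#'
#' Finds local maxima of the autocorrelogram in the annulus around the central
#' peak and reports their count and angular spacing; a triangular lattice
#' gives six peaks about 60 degrees apart.
#'
#' @param ac autocorrelogram from [rate_map_autocorrelation()].
#' @param r_min,r_max annulus radii in pixels; defaults estimate the lattice
#'   spacing from the first ring.
#' @return list with `n_peaks`, `angles` (deg), `radii`.
#' @export
autocorr_inner_peaks <- function(ac, r_min = NULL, r_max = NULL) {
  c1 <- (nrow(ac) + 1) / 2; c2 <- (ncol(ac) + 1) / 2
  xs <- row(ac) - c1; ys <- col(ac) - c2
  rr <- sqrt(xs^2 + ys^2)
  if (is.null(r_min) || is.null(r_max)) {
    # radial profile: first local max beyond the central peak
    rp <- tapply(as.vector(ac), round(as.vector(rr)), mean)
    rv <- as.numeric(names(rp))
    prof <- as.numeric(rp)
    cand <- which(diff(sign(diff(prof))) == -2) + 1
    cand <- cand[rv[cand] > 3]
    if (!length(cand)) return(list(n_peaks = 0L, angles = numeric(0),
                                   radii = numeric(0)))
    r0 <- rv[cand[1]]
    r_min <- 0.5 * r0; r_max <- 1.5 * r0
  }
  sm <- gauss_smooth2d(ac, 1)
  ann <- rr >= r_min & rr <= r_max
  # local maxima in 8-neighbourhood
  n1 <- nrow(sm); n2 <- ncol(sm)
  is_max <- matrix(TRUE, n1, n2)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    sh <- matrix(-Inf, n1, n2)
    i1 <- max(1, 1 + di):min(n1, n1 + di)
    j1 <- max(1, 1 + dj):min(n2, n2 + dj)
    sh[i1 - di, j1 - dj] <- sm[i1, j1]
    is_max <- is_max & (sm >= sh)
  }
  pk <- which(is_max & ann & sm > 0.1 * max(sm[ann]), arr.ind = TRUE)
  if (nrow(pk) == 0) return(list(n_peaks = 0L, angles = numeric(0),
                                 radii = numeric(0)))
  angs <- atan2(pk[, 2] - c2, pk[, 1] - c1) * 180 / pi
  rads <- sqrt((pk[, 1] - c1)^2 + (pk[, 2] - c2)^2)
  ord <- order(angs)
  list(n_peaks = nrow(pk), angles = angs[ord], radii = rads[ord])
}

#' Label theta cycles
#'
#' Cycle boundaries are the troughs of the oscillating inhibitory drive during
#' run segments; theta phase runs linearly from 0 to 360 degrees between
#' consecutive troughs, so phase 0 is the most disinhibited point of the
#' cycle. Idle segments emit no cycles.
#'
#' @param session a `grid_session` (uses its `drive_trace` and trajectory).
#' @return data frame of class `theta_cycles` with `cycle_id`, `t_start_ms`,
#'   `t_end_ms`, `lap`.
#' @export
label_theta <- function(session) {
  tr <- session$trajectory
  trace <- session$drive_trace
  dt <- session$config$dt
  out <- list()
  cid <- 0L
  for (l in seq_len(max(tr$lap))) {
    rows <- which(tr$lap == l & tr$state == "run")
    if (length(rows) < 3) next
    seg <- trace[rows]
    if (max(seg) - min(seg) < 1e-9) next   # no oscillation
    loc <- which(diff(sign(diff(seg))) == 2) + 1   # local minima
    if (length(loc) < 2) next
    tb <- tr$t_ms[rows[loc]]
    for (k in seq_len(length(tb) - 1)) {
      cid <- cid + 1L
      out[[cid]] <- data.frame(cycle_id = cid, t_start_ms = tb[k],
                               t_end_ms = tb[k + 1], lap = l)
    }
  }
  cyc <- if (length(out)) do.call(rbind, out) else
    data.frame(cycle_id = integer(0), t_start_ms = numeric(0),
               t_end_ms = numeric(0), lap = integer(0))
  class(cyc) <- c("theta_cycles", "data.frame")
  cyc
}

#' Theta phase of time points
#'
#' Linear interpolation of phase within labelled cycles; times outside any
#' cycle get `NA`.
#'
#' @param t_ms numeric times (ms).
#' @param cycles a `theta_cycles` data frame.
#' @return phases in degrees, `[0, 360)`.
#' @export
theta_phase_at <- function(t_ms, cycles) {
  ph <- rep(NA_real_, length(t_ms))
  if (!nrow(cycles)) return(ph)
  ix <- findInterval(t_ms, cycles$t_start_ms)
  ok <- ix >= 1 & ix <= nrow(cycles) & t_ms < cycles$t_end_ms[pmax(ix, 1)]
  i <- ix[ok]
  ph[ok] <- 360 * (t_ms[ok] - cycles$t_start_ms[i]) /
    (cycles$t_end_ms[i] - cycles$t_start_ms[i])
  ph
}

#' Theta-binned multiunit activity
#'
#' Pools the spikes of the recorded set over all labelled theta cycles and
#' returns the cycle-averaged multiunit rate per phase bin.
#'
#' @param spike_t_ms spike times (ms) of the pooled recorded neurons.
#' @param cycles a `theta_cycles` data frame.
#' @param n_bins number of phase bins.
#' @return data frame `phase_deg` (bin centres), `rate` (spikes/s per cycle,
#'   pooled over neurons).
#' @export
theta_mua <- function(spike_t_ms, cycles, n_bins = 24) {
  ph <- theta_phase_at(spike_t_ms, cycles)
  ph <- ph[!is.na(ph)]
  edges <- seq(0, 360, length.out = n_bins + 1)
  h <- tabulate(findInterval(ph, edges, all.inside = TRUE), nbins = n_bins)
  # time spent per phase bin across cycles
  tot_ms <- sum(cycles$t_end_ms - cycles$t_start_ms)
  bin_s <- tot_ms / n_bins / 1000
  data.frame(phase_deg = edges[-1] - diff(edges) / 2,
             rate = h / pmax(bin_s, 1e-9))
}
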