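#' Circular-linear regression of spike phase on position
#'
#' Fits `phase ~ slope * x + offset` where phase is circular, by maximizing
#' the mean resultant length
#' `R(a) = | mean_j exp(i (phi_j - a x_j)) |`
#' over a bounded slope range (Kempter-style regression). The maximized
#' resultant length is returned as the fit score in \[0, 1\]; the offset is
#' the circular mean of the residuals at the optimal slope.
#'
#' @param phase_deg spike theta phases in degrees.
#' @param x linear covariate (e.g. field progress in percent).
#' @param slope_bounds slope search interval in deg per unit of `x`; default
#'   spans four phase cycles over the range of `x`.
#' @param coarse_step coarse grid step (deg per unit) before local refinement.
#' @return list with `slope` (deg per unit of `x`), `offset` (deg, in
#'   \[0, 360)), `fit_score`.
#' @export
circular_linear_regression <- function(phase_deg, x, slope_bounds = NULL,
                                       coarse_step = NULL) {
  stopifnot(length(phase_deg) == length(x))
  if (length(x) < 5)
    stop("need at least 5 spikes for circular-linear regression",
         call. = FALSE)
  span <- diff(range(x))
  if (span <= 0)
    stop("zero positional variance", call. = FALSE)
  if (is.null(slope_bounds)) slope_bounds <- c(-1, 1) * 4 * 360 / span
  if (is.null(coarse_step)) coarse_step <- diff(slope_bounds) / 800
  phi <- phase_deg * pi / 180
  xr <- x * pi / 180                     # so that slope in deg/unit: phi - a*x
  Rfun <- function(a) Mod(mean(exp(1i * (phi - a * xr))))
  grid <- seq(slope_bounds[1], slope_bounds[2], by = coarse_step)
  vals <- vapply(grid, Rfun, 0)
  i0 <- which.max(vals)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  op <- stats::optimize(Rfun, c(lo, hi), maximum = TRUE, tol = 1e-6)
  a <- op$maximum
  off <- Arg(mean(exp(1i * (phi - a * xr)))) * 180 / pi
  list(slope = a, offset = off %% 360, fit_score = op$objective)
}

#' Circular-linear correlation
#'
#' Correlation between a circular variable (spike phase) and a linear one
#' (position), following the circular-circular correlation between the phase
#' and the fitted linear predictor: with the regression slope `a`, the
#' position is circularized as `theta_j = a * x_j` and
#' `rho = sum(sin(phi - mphi) sin(theta - mtheta)) /
#'        sqrt(sum(sin^2(phi - mphi)) sum(sin^2(theta - mtheta)))`
#' with circular means `mphi`, `mtheta`. The sign follows the fitted slope;
#' magnitudes are reported in population summaries.
#'
#' @param phase_deg spike phases (degrees).
#' @param x positions.
#' @param slope regression slope (deg per unit of `x`); fitted when `NULL`.
#' @return correlation coefficient in \[-1, 1\].
#' @export
circular_linear_correlation <- function(phase_deg, x, slope = NULL) {
  if (length(x) < 5) return(NA_real_)
  if (diff(range(x)) <= 0) return(NA_real_)
  if (is.null(slope))
    slope <- circular_linear_regression(phase_deg, x)$slope
  phi <- phase_deg * pi / 180
  th <- slope * x * pi / 180
  cmean <- function(v) Arg(mean(exp(1i * v)))
  sp <- sin(phi - cmean(phi)); st <- sin(th - cmean(th))
  den <- sqrt(sum(sp^2) * sum(st^2))
  # a near-constant circularized predictor (slope ~ 0) carries no positional
  # signal: the correlation is 0 by convention, as for phase-locking cells
  if (den < 1e-12 || sqrt(mean(st^2)) < 1e-3) return(0)
  sum(sp * st) / den
}

#' Classify phase behaviour
#'
#' Neurons are phase-independent when the regression fit score is below 0.4;
#' otherwise the phase precession range (|slope| times the field span, in
#' degrees per field) separates phase-locking (< 60 degrees) from
#' phase-precessing (>= 60 degrees).
#'
#' @param fit_score regression fit score.
#' @param slope regression slope in deg per unit of the progress variable.
#' @param field_span span of the progress variable over the field (100 when
#'   progress is in percent).
#' @param fit_cutoff,range_cutoff classification cutoffs.
#' @return one of `"independent"`, `"locking"`, `"precessing"`.
#' @export
classify_phase_behavior <- function(fit_score, slope, field_span = 100,
                                    fit_cutoff = 0.4, range_cutoff = 60) {
  if (is.na(fit_score)) return(NA_character_)
  if (fit_score < fit_cutoff) return("independent")
  if (abs(slope) * field_span >= range_cutoff) "precessing" else "locking"
}

#' Extract in-field phase samples from a session
#'
#' One row per in-field run spike of the selected neurons: theta phase, track
#' position, field progress (0% at field entry, 100% at exit, with entry
#' defined by the lap direction), lap direction, and running speed at the
#' spike.
#'
#' @param session a `grid_session`.
#' @param fields a `firing_fields` object.
#' @param cycles a `theta_cycles` data frame ([label_theta()]).
#' @return data frame of class `phase_samples` with columns `neuron`,
#'   `direction`, `field` (index), `pos_cm`, `progress` (percent),
#'   `phase_deg`, `speed`, `lap`, `t_ms`.
#' @export
phase_samples <- function(session, fields, cycles) {
  ev <- .set_events(session, attr(fields$neurons, "set") %||% "A")
  ev <- ev[ev$state == "run" & ev$neuron %in% fields$neurons$neuron, ]
  ev$phase_deg <- theta_phase_at(ev$t_ms, cycles)
  ev <- ev[!is.na(ev$phase_deg), ]
  out <- list()
  for (nm in rownames(fields$rate)) {
    fb <- fields$fields[[nm]]
    if (is.null(fb) || nrow(fb) == 0) next
    e <- ev[ev$neuron == nm, ]
    if (!nrow(e)) next
    fi <- rep(NA_integer_, nrow(e))
    for (k in seq_len(nrow(fb)))
      fi[e$pos_cm >= fb[k, 1] & e$pos_cm <= fb[k, 2]] <- k
    e <- e[!is.na(fi), ]; fi <- fi[!is.na(fi)]
    if (!nrow(e)) next
    lo <- fb[fi, 1]; hi <- fb[fi, 2]
    prog <- ifelse(e$direction > 0,
                   (e$pos_cm - lo) / (hi - lo),
                   (hi - e$pos_cm) / (hi - lo)) * 100
    out[[nm]] <- data.frame(neuron = nm, direction = e$direction, field = fi,
                            pos_cm = e$pos_cm, progress = prog,
                            phase_deg = e$phase_deg, speed = e$speed,
                            lap = e$lap, t_ms = e$t_ms)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(neuron = character(0), direction = integer(0),
               field = integer(0), pos_cm = numeric(0), progress = numeric(0),
               phase_deg = numeric(0), speed = numeric(0), lap = integer(0),
               t_ms = numeric(0))
  rownames(res) <- NULL
  class(res) <- c("phase_samples", "data.frame")
  res
}

#' Per-neuron phase statistics
#'
#' Circular-linear regression and correlation of theta phase versus field
#' progress, per neuron and lap direction, with subgroup classification.
#' Neurons contributing fewer than `min_spikes` in-field spikes in a
#' direction are excluded.
#'
#' @param samples a `phase_samples` data frame.
#' @param min_spikes minimum spikes per neuron and direction.
#' @param field_sizes optional named vector of field sizes (cm) to record.
#' @return data frame with `neuron`, `direction`, `n_spikes`, `corr`,
#'   `slope` (deg per field of progress: genuine precession is negative in
#'   both directions), `slope_vs_position` (deg per field of track position:
#'   precession is negative on rightward and positive on leftward laps),
#'   `offset`, `fit_score`, `precession_range` (deg), `subgroup`,
#'   `mean_speed`.
#' @export
phase_precession_stats <- function(samples, min_spikes = 5,
                                   field_sizes = NULL) {
  key <- interaction(samples$neuron, samples$direction, drop = TRUE)
  rows <- lapply(split(samples, key), function(s) {
    if (nrow(s) < min_spikes || diff(range(s$progress)) <= 0) return(NULL)
    # slope bounded to +/- 2 theta cycles per field (progress in percent):
    # wider bounds admit aliased optima at realistic in-field spike counts,
    # because phase recurs every cycle within a single field pass
    fit <- circular_linear_regression(s$phase_deg, s$progress,
                                      slope_bounds = c(-7.2, 7.2))
    corr <- circular_linear_correlation(s$phase_deg, s$progress,
                                        slope = fit$slope)
    rng <- abs(fit$slope) * 100
    data.frame(neuron = s$neuron[1], direction = s$direction[1],
               n_spikes = nrow(s), corr = corr, slope = fit$slope * 100,
               slope_vs_position = s$direction[1] * fit$slope * 100,
               offset = fit$offset, fit_score = fit$fit_score,
               precession_range = rng,
               subgroup = classify_phase_behavior(fit$fit_score,
                                                  fit$slope * 100,
                                                  field_span = 1),
               mean_speed = mean(s$speed))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(neuron = character(0), direction = integer(0),
                      n_spikes = integer(0), corr = numeric(0),
                      slope = numeric(0), slope_vs_position = numeric(0),
                      offset = numeric(0),
                      fit_score = numeric(0), precession_range = numeric(0),
                      subgroup = character(0), mean_speed = numeric(0))
  rownames(out) <- NULL
  out
}

#' Spike density over field progress and theta phase
#'
#' Normalized 2D histogram of spikes in (field progress, theta phase), pooled
#' over the neurons of one subgroup. Spikes are counted once (duplication of
#' the phase axis is for display only).
#'
#' @param samples a `phase_samples` data frame (typically filtered to one
#'   subgroup via the stats table).
#' @param prog_bins,phase_bins bin counts.
#' @param smooth_sd smoothing s.d. in bins (phase axis wraps circularly).
#' @return list of class `spike_density`: `density` (prog x phase, sums to 1),
#'   `prog_centers` (percent), `phase_centers` (deg).
#' @export
spike_density_map <- function(samples, prog_bins = 20, phase_bins = 36,
                              smooth_sd = 1) {
  pe <- seq(0, 100, length.out = prog_bins + 1)
  fe <- seq(0, 360, length.out = phase_bins + 1)
  ip <- findInterval(pmin(pmax(samples$progress, 0), 100), pe,
                     all.inside = TRUE)
  jp <- findInterval(samples$phase_deg %% 360, fe, all.inside = TRUE)
  d <- matrix(0, prog_bins, phase_bins)
  for (k in seq_along(ip)) d[ip[k], jp[k]] <- d[ip[k], jp[k]] + 1
  if (smooth_sd > 0) {
    # smooth: reflective in progress, circular in phase
    r <- ceiling(3 * smooth_sd)
    kk <- stats::dnorm(seq(-r, r), sd = smooth_sd); kk <- kk / sum(kk)
    if (prog_bins > r)
      d <- apply(d, 2, function(v) {
        vp <- c(rev(v[seq_len(r)]), v, rev(v[(length(v) - r + 1):length(v)]))
        as.numeric(stats::filter(vp, kk)[(r + 1):(r + length(v))])
      })
    d <- matrix(d, prog_bins, phase_bins)
    if (phase_bins > r)
      d <- t(apply(d, 1, function(v) {
        vp <- c(v[(length(v) - r + 1):length(v)], v, v[seq_len(r)])
        as.numeric(stats::filter(vp, kk)[(r + 1):(r + length(v))])
      }))
  }
  if (sum(d) > 0) d <- d / sum(d)
  structure(list(density = d, prog_centers = pe[-1] - diff(pe) / 2,
                 phase_centers = fe[-1] - diff(fe) / 2),
            class = "spike_density")
}

#' Ridge of a spike density map
#'
#' Modal theta phase per field-progress bin, reported on (180, 540\] so that
#' phases just above 0 appear near 360 (0 and 360 degrees are equivalent and
#' the subgroups of interest peak near the cycle trough). By default the
#' ridge is tracked: from the second progress bin on, the mode is searched
#' within `track_window` degrees of the previous ridge value, so that a
#' secondary density blob elsewhere in the cycle (such as the one around
#' mid-field at mid-cycle phases) does not capture the main ridge.
#'
#' @param sd_map a `spike_density` object.
#' @param track_window half-width (degrees) of the tracked search window;
#'   `Inf` gives the global mode per bin.
#' @return data frame `progress`, `phase_deg`.
#' @export
density_ridge <- function(sd_map, track_window = 60) {
  ph <- sd_map$phase_centers
  nb <- length(ph)
  rep540 <- function(p) if (p < 180) p + 360 else p
  ridge <- rep(NA_real_, nrow(sd_map$density))
  prev <- NA_real_
  for (i in seq_len(nrow(sd_map$density))) {
    v <- sd_map$density[i, ]
    if (all(v == 0)) next
    if (is.na(prev) || !is.finite(track_window)) {
      p <- ph[which.max(v)]
    } else {
      # circular distance of each phase bin to the previous ridge
      d <- abs(((ph - prev + 180) %% 360) - 180)
      cand <- which(d <= track_window)
      p <- ph[cand[which.max(v[cand])]]
    }
    prev <- p
    ridge[i] <- rep540(p)
  }
  data.frame(progress = sd_map$prog_centers, phase_deg = ridge)
}

#' Direction and speed stratification of phase statistics
#'
#' Summarizes regression slope signs per lap direction in track-position
#' units (precession appears as negative position-slopes on rightward laps
#' and positive on leftward laps) and compares precession range and
#' correlation magnitude across running-speed terciles with the
#' Kruskal-Wallis H test.
#'
#' @param stats per-neuron stats from [phase_precession_stats()].
#' @param fit_cutoff restrict the slope-sign summary to fits at or above this
#'   score.
#' @return list with `direction_summary` (data frame: direction, n,
#'   frac_negative_slope, in position units), `speed_groups` (per-tercile
#'   medians), and `kw_range`, `kw_corr` (Kruskal-Wallis results, `NULL`
#'   when all strata are not populated).
#' @export
directionality_and_speed_stratification <- function(stats, fit_cutoff = 0.4) {
  hi <- stats[!is.na(stats$fit_score) & stats$fit_score >= fit_cutoff, ]
  dirsum <- do.call(rbind, lapply(split(hi, hi$direction), function(s)
    data.frame(direction = s$direction[1], n = nrow(s),
               frac_negative_slope = mean(s$slope_vs_position < 0))))
  q <- stats::quantile(stats$mean_speed, c(1 / 3, 2 / 3), na.rm = TRUE)
  brk <- unique(c(-Inf, q, Inf))
  terc <- cut(stats$mean_speed, brk,
              labels = c("slow", "mid", "fast")[seq_len(length(brk) - 1)])
  grp <- split(stats, terc)
  speed_groups <- do.call(rbind, lapply(names(grp), function(g)
    data.frame(tercile = g, n = nrow(grp[[g]]),
               median_range = stats::median(grp[[g]]$precession_range,
                                            na.rm = TRUE),
               median_abs_corr = stats::median(abs(grp[[g]]$corr),
                                               na.rm = TRUE))))
  kw_range <- kw_corr <- NULL
  if (length(grp) >= 2 && all(vapply(grp, nrow, 0L) >= 2)) {
    kw_range <- stats::kruskal.test(stats$precession_range, terc)
    kw_corr <- stats::kruskal.test(abs(stats$corr), terc)
  }
  list(direction_summary = dirsum, speed_groups = speed_groups,
       kw_range = kw_range, kw_corr = kw_corr)
}

#' Entry phase and drop of the precessing-subgroup ridge
#'
#' Fits a line to the tracked density ridge over the first half of field
#' progress and reports the fitted phase at field entry and the drop over
#' the first 50% of progress.
#'
#' @param samples pooled `phase_samples` of the phase-precessing subgroup.
#' @param max_progress last progress (percent) included in the fit.
#' @return list with `entry_phase` (deg, on (180, 540\]), `drop50` (deg,
#'   positive = phase decreases), `ridge` (the tracked ridge).
#' @export
precession_ridge_drop <- function(samples, max_progress = 55) {
  m <- spike_density_map(samples)
  r <- density_ridge(m)
  use <- !is.na(r$phase_deg) & r$progress <= max_progress
  if (sum(use) < 4) stop("too few ridge points", call. = FALSE)
  fit <- stats::lm(phase_deg ~ progress, data = r[use, ])
  list(entry_phase = unname(stats::coef(fit)[1]),
       drop50 = -unname(stats::coef(fit)[2]) * 50,
       ridge = r)
}
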