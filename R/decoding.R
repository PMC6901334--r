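#' Bayesian position decoding
#'
#' Standard memoryless Bayesian decoder with independent Poisson spike counts
#' and a uniform prior over track positions:
#' `P(x | n) ~ prod_i lambda_i(x)^(n_i) * exp(-tau * sum_i lambda_i(x))`,
#' computed in log space and normalized per time bin.
#'
#' @param counts neurons x bins matrix of spike counts.
#' @param rates neurons x positions matrix of expected rates (spikes/s), e.g.
#'   the rate maps of a `firing_fields` object.
#' @param bin_s decoding bin width tau in seconds.
#' @param rate_floor lower bound applied to rates so the log is finite.
#' @return list with `posterior` (bins x positions, rows sum to 1) and `ml`
#'   (index of the maximum-likelihood position per bin).
#' @export
decode_position <- function(counts, rates, bin_s, rate_floor = 0.01) {
  stopifnot(nrow(counts) == nrow(rates))
  lam <- pmax(rates, rate_floor)
  lp <- t(counts) %*% log(lam)
  lp <- sweep(lp, 2, bin_s * colSums(lam), "-")
  lp <- lp - apply(lp, 1, max)
  post <- exp(lp)
  post <- post / rowSums(post)
  list(posterior = post, ml = max.col(post, ties.method = "first"))
}

#' Decode a session segment-by-segment
#'
#' Slides a decoding window (`decode_bin_ms` wide, stepped by
#' `decode_step_ms`) over the session, counts spikes of the recorded neurons
#' per window, and decodes track position with [decode_position()] using the
#' run-derived firing fields.
#'
#' @param session a `grid_session`.
#' @param fields a `firing_fields` object (defines the neurons and rates).
#' @param states behavioural states to decode (default both run and idle).
#' @return object of class `decoded_trajectory`: data frame `t_ms` (bin
#'   centres), `state`, `lap`, `ml_cm`, `actual_cm`, `mua` (summed counts per
#'   bin), plus attributes `posterior` (bins x positions) and `positions_cm`.
#' @export
decode_session <- function(session, fields, states = c("run", "idle")) {
  cfg <- session$config
  tr <- session$trajectory
  step <- cfg$decode_step_ms
  win <- cfg$decode_bin_ms
  half <- win / 2
  t_end <- max(tr$t_ms)
  centers <- seq(half, t_end - half, by = step)
  ev <- .set_events(session, attr(fields$neurons, "set") %||% "A")
  ev <- ev[ev$neuron %in% fields$neurons$neuron, ]
  nrn <- rownames(fields$rate)
  # counts per neuron per window via sub-bin accumulation
  sub_edges <- seq(0, t_end + step, by = step)
  sub_ix <- findInterval(ev$t_ms, sub_edges, rightmost.closed = FALSE)
  nsub <- length(sub_edges) - 1
  cs <- matrix(0L, length(nrn), nsub, dimnames = list(nrn, NULL))
  tab <- table(factor(ev$neuron, levels = nrn), factor(sub_ix,
               levels = seq_len(nsub)))
  cs[] <- as.integer(tab)
  k <- max(1L, round(win / step))
  nb <- length(centers)
  counts <- matrix(0L, length(nrn), nb)
  for (j in seq_len(k)) {
    cols <- seq_len(nb) + (j - 1)
    cols[cols > nsub] <- nsub
    counts <- counts + cs[, cols, drop = FALSE]
  }
  dec <- decode_position(counts, fields$rate, win / 1000)
  rows <- pmin(pmax(round(centers / cfg$dt) + 1, 1), nrow(tr))
  track_x <- attr(tr, "track_pos_cm")
  out <- data.frame(t_ms = centers, state = tr$state[rows],
                    lap = tr$lap[rows],
                    ml_cm = fields$bin_centers[dec$ml],
                    actual_cm = track_x[rows],
                    mua = colSums(counts))
  keep <- out$state %in% states
  out <- out[keep, ]
  attr(out, "posterior") <- dec$posterior[keep, , drop = FALSE]
  attr(out, "positions_cm") <- fields$bin_centers
  attr(out, "bin_s") <- win / 1000
  class(out) <- c("decoded_trajectory", "data.frame")
  out
}

#' Average decoded position over theta-cycle quadruplets
#'
#' Takes quadruplets of consecutive theta cycles within laps, discards those
#' whose decoded position comes near the track ends, reverses the position
#' axis for right-to-left motion, shifts each quadruplet's decoded density by
#' the actual animal position at the quadruplet midpoint, and averages the
#' shifted densities. Within-cycle forward sweeps of the average expose theta
#' sequences.
#'
#' @param decoded a `decoded_trajectory` (run state included).
#' @param cycles a `theta_cycles` data frame.
#' @param session the `grid_session` the decoding came from.
#' @return object of class `theta_sequence_summary`: list with `density`
#'   (time-in-quadruplet x relative position), `t_rel_ms`, `offset_cm`,
#'   `mean_pos` (density-weighted mean relative position per time bin),
#'   `ml_pos`, `n_quadruplets`, `cycle_ms`.
#' @export
average_theta_quadruplets <- function(decoded, cycles, session) {
  cfg <- session$config
  L <- cfg$track_length_cm
  excl <- cfg$end_exclusion_cm
  pos <- attr(decoded, "positions_cm")
  post <- attr(decoded, "posterior")
  bw <- pos[2] - pos[1]
  run <- decoded$state == "run"
  cyc_ms <- 1000 / cfg$f_theta
  step <- cfg$decode_step_ms
  nt <- floor(4 * cyc_ms / step)           # bins per quadruplet
  # relative-position grid spans the full track both ways
  off <- seq(-L, L, by = bw)
  acc <- matrix(0, nt, length(off))
  used <- 0L
  for (l in unique(cycles$lap)) {
    cl <- cycles[cycles$lap == l, ]
    if (nrow(cl) < 4) next
    for (q in seq_len(nrow(cl) - 3)) {
      t0 <- cl$t_start_ms[q]
      tq <- t0 + (seq_len(nt) - 1) * step
      ix <- findInterval(tq, decoded$t_ms)
      ix[ix < 1] <- 1
      ok <- abs(decoded$t_ms[ix] - tq) <= step & run[ix]
      if (!all(ok)) next
      ml <- decoded$ml_cm[ix]
      # discard quadruplets whose decoding spends time near the track ends
      # (multi-field aliasing makes isolated end hops common, so the rule is
      # on the fraction of bins, not single bins)
      if (mean(ml < excl | ml > L - excl) > 0.25) next
      mid <- decoded$actual_cm[ix[round(nt / 2)]]
      dirn <- session$trajectory$direction[
        min(nrow(session$trajectory), max(1, round(t0 / cfg$dt) + 1))]
      P <- post[ix, , drop = FALSE]
      x <- pos
      if (dirn < 0) { P <- P[, rev(seq_along(pos)), drop = FALSE]
                      x <- L - rev(pos); mid <- L - mid }
      # deposit each position bin at its offset from the midpoint position
      oix <- round((x - mid - off[1]) / bw) + 1
      keep <- oix >= 1 & oix <= length(off)
      acc[, oix[keep]] <- acc[, oix[keep]] + P[, keep, drop = FALSE]
      used <- used + 1L
    }
  }
  if (used == 0) warning("no usable theta quadruplets")
  dens <- if (used > 0) acc / used else acc
  # position traces from the density near the animal: with multi-field
  # neurons, alias lines a lattice period away would otherwise dilute them
  win <- abs(off) <= 30
  mp <- apply(dens[, win, drop = FALSE], 1, function(v)
    if (sum(v) > 0) sum(v * off[win]) / sum(v) else NA_real_)
  mlp <- apply(dens[, win, drop = FALSE], 1, function(v)
    if (sum(v) > 0) off[win][which.max(v)] else NA_real_)
  structure(list(density = dens, t_rel_ms = (seq_len(nt) - 1) * step,
                 offset_cm = off, mean_pos = mp, ml_pos = mlp,
                 n_quadruplets = used, cycle_ms = cyc_ms),
            class = "theta_sequence_summary")
}

#' Theta-sequence speed
#'
#' Finds the sliding time window (within a single theta cycle) over which the
#' quadruplet-averaged decoded position increases most steeply, fits a line,
#' and reports its slope as the sequence speed.
#'
#' @param summary a `theta_sequence_summary`.
#' @param window_ms fit window length (default half a theta cycle).
#' @param use one of `"mean"` (density-weighted mean position, default) or
#'   `"ml"`.
#' @return list with `speed_mps`, `window_ms` (start/end of the best window),
#'   `slope_cm_per_ms`.
#' @export
theta_sequence_speed <- function(summary, window_ms = NULL, use = "mean") {
  if (is.null(window_ms)) window_ms <- summary$cycle_ms / 2
  t <- summary$t_rel_ms
  yv <- if (use == "ml") summary$ml_pos else summary$mean_pos
  step <- t[2] - t[1]
  wlen <- max(2L, round(window_ms / step))
  best <- c(slope = -Inf, start = NA)
  for (s in seq_len(length(t) - wlen + 1)) {
    idx <- s:(s + wlen - 1)
    # restrict to windows inside one theta cycle
    if (floor(t[idx[1]] / summary$cycle_ms) !=
        floor((t[idx[wlen]] - 1e-9) / summary$cycle_ms)) next
    if (any(is.na(yv[idx]))) next
    sl <- unname(stats::coef(stats::lm(yv[idx] ~ t[idx]))[2])
    if (!is.na(sl) && sl > best["slope"]) best <- c(slope = sl, start = s)
  }
  if (!is.finite(best["slope"])) stop("no valid fit window", call. = FALSE)
  s <- best["start"]
  list(speed_mps = unname(best["slope"]) * 10,   # cm/ms -> m/s
       window_ms = c(t[s], t[s + wlen - 1]),
       slope_cm_per_ms = unname(best["slope"]))
}
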