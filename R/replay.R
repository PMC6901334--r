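#' Detect replay events in idle-period activity
#'
#' During quiescence the network produces traveling wavefronts; when one
#' passes through the recorded regions it is decoded as a rapid positional
#' sweep. Candidate events are windows where the smoothed recorded multiunit
#' rate exceeds a z-score threshold (relative to the idle baseline),
#' extended down to a lower edge threshold, lasting 50-300 ms. Within each
#' window a single line is fit to the maximum-likelihood decoded positions
#' by a consensus (RANSAC-style) search: with multi-field neurons the
#' decoded distribution can split between parallel alias lines, and the
#' consensus fit recovers the dominant one. Events are kept when the inlier
#' span covers a minimum fraction of the track, enough bins lie on the
#' line, and the inlier fit is good.
#'
#' @param decoded a `decoded_trajectory` containing idle bins (decoded with
#'   the run-derived firing fields).
#' @param config the session's `grid_config` (thresholds: `replay_mua_z`,
#'   `replay_min_ms`, `replay_max_ms`, `replay_span_frac`, `replay_r2_min`).
#' @return data frame of class `replay_events`: `t_start_ms`, `t_end_ms`,
#'   `duration_ms`, `speed_mps`, `p_start_cm`, `p_end_cm`, `actual_cm`,
#'   `direction` (`"away"`/`"toward"`), `r2`, `n_bins`.
#' @export
detect_replays <- function(decoded, config) {
  idle <- decoded[decoded$state == "idle", ]
  out <- data.frame(t_start_ms = numeric(0), t_end_ms = numeric(0),
                    duration_ms = numeric(0), speed_mps = numeric(0),
                    p_start_cm = numeric(0), p_end_cm = numeric(0),
                    actual_cm = numeric(0), direction = character(0),
                    r2 = numeric(0), n_bins = integer(0))
  class(out) <- c("replay_events", "data.frame")
  if (!nrow(idle)) return(out)
  step <- if (nrow(idle) > 1) stats::median(diff(idle$t_ms)) else 5
  mua <- gauss_smooth1d(idle$mua,
                        (config$replay_mua_sd_ms %||% 10) / step)
  mu <- mean(mua); s <- stats::sd(mua)
  if (is.na(s) || s == 0) return(out)
  z <- (mua - mu) / s
  core <- z > config$replay_mua_z
  edge <- z > (config$replay_mua_edge %||% 0.5)
  # extend each core segment to the surrounding edge-level segment
  re <- rle(edge)
  e_ends <- cumsum(re$lengths); e_starts <- e_ends - re$lengths + 1
  hot <- rep(FALSE, length(z))
  for (k in which(re$values))
    if (any(core[e_starts[k]:e_ends[k]]))
      hot[e_starts[k]:e_ends[k]] <- TRUE
  r <- rle(hot)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  L <- config$track_length_cm
  tol <- config$replay_inlier_cm %||% 8
  rows <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    tt <- idle$t_ms[i0:i1]
    # candidate must be contiguous in time (idle rows can span segments)
    if (any(diff(tt) > 2 * step)) next
    dur <- tt[length(tt)] - tt[1] + step
    if (dur < config$replay_min_ms || dur > config$replay_max_ms) next
    ml <- idle$ml_cm[i0:i1]
    if (diff(range(ml)) < config$replay_span_frac * L) next
    cons <- .consensus_line(tt, ml, tol)
    if (is.null(cons)) next
    inl <- cons$inliers
    if (mean(inl) < (config$replay_inlier_frac %||% 0.5)) next
    if (diff(range(ml[inl])) < config$replay_span_frac * L) next
    r2 <- cons$r2
    if (is.na(r2) || r2 < config$replay_r2_min) next
    slope <- cons$slope                   # cm/ms
    if (abs(slope) < 1e-6) next
    actual <- stats::median(idle$actual_cm[i0:i1])
    p0 <- cons$intercept + slope * tt[1]
    p1 <- cons$intercept + slope * tt[length(tt)]
    # direction relative to the animal's resting position
    dir <- if (abs(p1 - actual) >= abs(p0 - actual)) "away" else "toward"
    rows[[length(rows) + 1]] <- data.frame(
      t_start_ms = tt[1], t_end_ms = tt[length(tt)], duration_ms = dur,
      speed_mps = abs(slope) * 10, p_start_cm = p0, p_end_cm = p1,
      actual_cm = actual, direction = dir, r2 = r2,
      n_bins = length(tt))
  }
  if (length(rows)) out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("replay_events", "data.frame")
  out
}

# consensus (RANSAC-style) line through (t, y): exhaustive over point pairs
# (windows are small), keeping the line with most inliers within tol, then
# least-squares refit on the inliers. Deterministic.
.consensus_line <- function(t, y, tol) {
  n <- length(t)
  if (n < 4) return(NULL)
  best <- NULL; best_n <- -1L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (t[j] == t[i]) next
    sl <- (y[j] - y[i]) / (t[j] - t[i])
    ic <- y[i] - sl * t[i]
    res <- abs(y - (ic + sl * t))
    ninl <- sum(res <= tol)
    if (ninl > best_n) { best_n <- ninl; best <- res <= tol }
  }
  if (is.null(best) || sum(best) < 3) return(NULL)
  fit <- stats::lm(y[best] ~ t[best])
  pred_in <- stats::fitted(fit)
  r2 <- if (stats::sd(y[best]) > 0) stats::cor(y[best], pred_in)^2 else NA
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       inliers = best, r2 = r2)
}

#' Summarize replay speeds over replicate simulations
#'
#' @param events_list list of `replay_events` data frames (one per
#'   simulation).
#' @param run_speed_mps mean actual run speed, for the speed ratio.
#' @return list with `n_events` (per simulation), `mean_speed`, `sd_speed`,
#'   `speed_ratio` (to run speed; `NA` when not supplied), `speeds` (pooled).
#' @export
replay_speed_summary <- function(events_list, run_speed_mps = NA) {
  if (inherits(events_list, "data.frame")) events_list <- list(events_list)
  speeds <- unlist(lapply(events_list, function(e) e$speed_mps))
  n <- vapply(events_list, nrow, 0L)
  if (!length(speeds)) {
    warning("no replay events detected")
    return(list(n_events = n, mean_speed = NA_real_, sd_speed = NA_real_,
                speed_ratio = NA_real_, speeds = numeric(0)))
  }
  list(n_events = n, mean_speed = mean(speeds),
       sd_speed = if (length(speeds) > 1) stats::sd(speeds) else 0,
       speed_ratio = mean(speeds) / run_speed_mps, speeds = speeds)
}

#' Replay direction bias
#'
#' With low velocity gain, sheet locations correspond one-to-one to track
#' positions and replays preferentially propagate away from the resting
#' animal. Counts away/toward events per simulation and end, compares the
#' per-simulation counts with the Mann-Whitney U test, and compares the
#' distances from the actual position to the decoded start versus end of each
#' replay with the Wilcoxon test.
#'
#' @param events_list list of `replay_events` data frames (one per
#'   simulation).
#' @param track_length_cm track length (classifies the resting end).
#' @return list with `counts` (data frame: sim, end, away, toward),
#'   `mw_test` (away vs toward counts), `start_end_test` (start vs end
#'   distances), `frac_away`.
#' @export
direction_bias <- function(events_list, track_length_cm = 100) {
  if (inherits(events_list, "data.frame")) events_list <- list(events_list)
  counts <- list(); d_start <- numeric(0); d_end <- numeric(0)
  for (s in seq_along(events_list)) {
    e <- events_list[[s]]
    if (!nrow(e)) next
    end_lab <- ifelse(e$actual_cm < track_length_cm / 2, "0", "L")
    for (en in unique(end_lab)) {
      ee <- e[end_lab == en, ]
      counts[[length(counts) + 1]] <- data.frame(
        sim = s, end = en, away = sum(ee$direction == "away"),
        toward = sum(ee$direction == "toward"))
    }
    d_start <- c(d_start, abs(e$p_start_cm - e$actual_cm))
    d_end <- c(d_end, abs(e$p_end_cm - e$actual_cm))
  }
  counts <- if (length(counts)) do.call(rbind, counts) else
    data.frame(sim = integer(0), end = character(0), away = integer(0),
               toward = integer(0))
  mw <- if (nrow(counts) >= 2)
    stats::wilcox.test(counts$away, counts$toward, exact = FALSE) else NULL
  se <- if (length(d_start) >= 2)
    stats::wilcox.test(d_start, d_end, paired = TRUE, exact = FALSE) else NULL
  tot <- sum(counts$away) + sum(counts$toward)
  list(counts = counts, mw_test = mw, start_end_test = se,
       frac_away = if (tot > 0) sum(counts$away) / tot else NA_real_)
}
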