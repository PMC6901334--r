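# synthetic idle decoding: maximum-likelihood positions follow given segments
synthetic_idle_decoded <- function(segments, total_ms = 4000, step = 5,
                                   L = 100, actual = 2, base_mua = 5,
                                   hot_mua = 60, seed = 1, noise_cm = 0) {
  set.seed(seed)
  t <- seq(step / 2, total_ms, by = step)
  ml <- rep(actual, length(t))
  mua <- rep(base_mua, length(t)) + rnorm(length(t), 0, 0.5)
  for (s in segments) {
    ix <- which(t >= s$t0 & t < s$t1)
    frac <- (t[ix] - s$t0) / (s$t1 - s$t0)
    ml[ix] <- s$p0 + frac * (s$p1 - s$p0) + rnorm(length(ix), 0, noise_cm)
    mua[ix] <- hot_mua
  }
  pos <- seq(1, L - 1, by = 2)
  out <- data.frame(t_ms = t, state = "idle", lap = 0L,
                    ml_cm = pos[pmax(1, pmin(length(pos),
                                             round(ml / 2 + 0.5)))],
                    actual_cm = actual, mua = mua)
  attr(out, "positions_cm") <- pos
  class(out) <- c("decoded_trajectory", "data.frame")
  out
}

test_that("a silent idle period yields no replay events", {
  cfg <- grid_config(n = 64)
  dec <- synthetic_idle_decoded(list(), total_ms = 2000)
  expect_equal(nrow(detect_replays(dec, cfg)), 0)
  # and an empty decoded frame is handled
  expect_equal(nrow(detect_replays(dec[0, ], cfg)), 0)
})

test_that("a constructed sweep is detected with the right speed", {
  cfg <- grid_config(n = 64)
  dec <- synthetic_idle_decoded(list(list(t0 = 1000, t1 = 1100,
                                          p0 = 0, p1 = 80)))
  ev <- detect_replays(dec, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$speed_mps, 8, tolerance = 0.15)
  expect_equal(ev$direction, "away")
  expect_true(ev$r2 > 0.9)
})

test_that("detection is invariant to track reflection", {
  cfg <- grid_config(n = 64)
  segs <- list(list(t0 = 500, t1 = 620, p0 = 10, p1 = 90),
               list(t0 = 2000, t1 = 2100, p0 = 85, p1 = 12))
  dec <- synthetic_idle_decoded(segs, noise_cm = 3)
  ev <- detect_replays(dec, cfg)
  refl <- dec
  refl$ml_cm <- 100 - refl$ml_cm
  refl$actual_cm <- 100 - refl$actual_cm
  attr(refl, "positions_cm") <- attr(dec, "positions_cm")
  ev2 <- detect_replays(refl, cfg)
  expect_equal(nrow(ev), nrow(ev2))
  expect_equal(ev$speed_mps, ev2$speed_mps, tolerance = 0.12)
  expect_equal(ev$direction, ev2$direction)
})

test_that("fitted replay speed recovers ground truth across seeds", {
  cfg <- grid_config(n = 64)
  err <- vapply(1:50, function(s) {
    v_true <- runif(1, 4, 10)            # m/s
    dur <- 100
    span <- v_true * dur / 10            # cm
    p0 <- runif(1, 0, 95 - min(span, 95))
    dec <- synthetic_idle_decoded(
      list(list(t0 = 1000, t1 = 1000 + dur, p0 = p0,
                p1 = min(p0 + span, 99))),
      seed = s, noise_cm = 2, total_ms = 2500)
    ev <- detect_replays(dec, cfg)
    if (nrow(ev) != 1) return(NA_real_)
    abs(ev$speed_mps - min(v_true, (99 - p0) / dur * 10)) /
      v_true
  }, 0)
  expect_gt(mean(!is.na(err)), 0.8)
  expect_lt(stats::median(err, na.rm = TRUE), 0.1)
  expect_lt(stats::quantile(err, 0.9, na.rm = TRUE), 0.15)
})

test_that("direction bias counts swap under mirroring and tests run", {
  cfg <- grid_config(n = 64)
  mk <- function(seed) {
    segs <- list(list(t0 = 500, t1 = 600, p0 = 5, p1 = 70),
                 list(t0 = 1500, t1 = 1600, p0 = 3, p1 = 60),
                 list(t0 = 2500, t1 = 2600, p0 = 75, p1 = 8))
    detect_replays(synthetic_idle_decoded(segs, seed = seed, noise_cm = 2),
                   cfg)
  }
  evs <- lapply(1:4, mk)
  db <- direction_bias(evs, 100)
  expect_equal(sum(db$counts$away), 4 * 2)
  expect_equal(sum(db$counts$toward), 4 * 1)
  expect_gt(db$frac_away, 0.5)
  expect_s3_class(db$mw_test, "htest")
  expect_s3_class(db$start_end_test, "htest")
  # mirrored events swap away/toward exactly
  evs_m <- lapply(evs, function(e) {
    e$p_start_cm <- 100 - e$p_start_cm
    e$p_end_cm <- 100 - e$p_end_cm
    e$actual_cm <- 100 - e$actual_cm
    e$direction <- e$direction           # direction recomputed below
    d0 <- abs(e$p_start_cm - e$actual_cm); d1 <- abs(e$p_end_cm - e$actual_cm)
    e$direction <- ifelse(d1 >= d0, "away", "toward")
    e
  })
  db_m <- direction_bias(evs_m, 100)
  expect_equal(sum(db_m$counts$away), sum(db$counts$away))
  expect_equal(sum(db_m$counts$toward), sum(db$counts$toward))
})

test_that("replay summaries pool events across simulations", {
  e1 <- data.frame(speed_mps = 7)
  s <- replay_speed_summary(list(e1), run_speed_mps = 0.5)
  expect_equal(s$mean_speed, 7)
  expect_equal(s$sd_speed, 0)
  expect_equal(s$speed_ratio, 14)
  expect_warning(replay_speed_summary(list(e1[0, , drop = FALSE])),
                 "no replay")
})
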