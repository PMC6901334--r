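test_that("decoder matches a brute-force product-of-Poissons oracle", {
  # 3 neurons, 4 positions, several count vectors
  lam <- matrix(c(2, 8, 1, 0.5,
                  5, 1, 3, 2,
                  0.1, 4, 6, 1), nrow = 3, byrow = TRUE)
  tau <- 0.02
  counts <- matrix(c(1, 0, 2,
                     0, 0, 0,
                     3, 1, 0,
                     2, 2, 2), nrow = 3)
  dec <- decode_position(counts, lam, tau, rate_floor = 1e-6)
  for (b in seq_len(ncol(counts))) {
    post <- vapply(seq_len(ncol(lam)), function(x)
      prod(stats::dpois(counts[, b], tau * lam[, x])), 0)
    post <- post / sum(post)
    expect_equal(dec$posterior[b, ], post, tolerance = 1e-12)
  }
})

test_that("decoder is equivariant under neuron relabelling", {
  set.seed(3)
  lam <- matrix(runif(40, 0.1, 20), 8, 5)
  counts <- matrix(rpois(24, 1), 8, 3)
  p1 <- decode_position(counts, lam, 0.01)$posterior
  perm <- sample(8)
  p2 <- decode_position(counts[perm, ], lam[perm, ], 0.01)$posterior
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("decoder limits: single informative spike and silence", {
  lam <- matrix(0.01, 4, 10)
  lam[1, 7] <- 30                       # neuron 1 has a narrow field at x=7
  counts <- matrix(0, 4, 2)
  counts[1, 1] <- 1
  dec <- decode_position(counts, lam, 0.01)
  expect_equal(dec$ml[1], 7)
  # zero spikes: posterior maximal where summed rate is minimal
  lam2 <- matrix(runif(40, 1, 10), 4, 10)
  d2 <- decode_position(matrix(0, 4, 1), lam2, 0.05)
  expect_equal(d2$ml[1], which.min(colSums(lam2)))
})

# build a synthetic decoded trajectory + cycles for sequence-analysis tests
synthetic_decoded <- function(ml_fun, speed = 0.5, n_cycles = 12,
                              step = 5, L = 100, sd_post = 2) {
  cyc_ms <- 125
  t <- seq(step / 2, n_cycles * cyc_ms, by = step)
  actual <- 20 + speed * t / 10          # cm (speed m/s -> cm/ms = /10)
  ml <- ml_fun(t, actual)
  pos <- seq(1, L - 1, by = 2)
  post <- t(vapply(ml, function(m) {
    d <- stats::dnorm(pos, m, sd_post); d / sum(d)
  }, numeric(length(pos))))
  out <- data.frame(t_ms = t, state = "run", lap = 1L,
                    ml_cm = pos[max.col(post)], actual_cm = actual,
                    mua = 50)
  attr(out, "posterior") <- post
  attr(out, "positions_cm") <- pos
  class(out) <- c("decoded_trajectory", "data.frame")
  cycles <- data.frame(cycle_id = seq_len(n_cycles),
                       t_start_ms = (seq_len(n_cycles) - 1) * cyc_ms,
                       t_end_ms = seq_len(n_cycles) * cyc_ms, lap = 1L)
  ses <- list(config = grid_config(n = 64, track_length_cm = L),
              trajectory = {
                tr <- data.frame(t_ms = seq(0, max(t) + 10),
                                 state = "run", lap = 1L, direction = 1L)
                attr(tr, "track_pos_cm") <- 20 + speed * tr$t_ms / 10
                tr
              })
  list(decoded = out, cycles = cycles, session = ses)
}

test_that("perfect decoding averages to a line at the run speed", {
  fx <- synthetic_decoded(function(t, actual) actual, speed = 0.5)
  q <- average_theta_quadruplets(fx$decoded, fx$cycles, fx$session)
  expect_gt(q$n_quadruplets, 4)
  sp <- theta_sequence_speed(q)
  expect_equal(sp$speed_mps, 0.5, tolerance = 0.1)
})

test_that("built-in within-cycle sweeps raise the sequence speed", {
  # sawtooth: decoded sweeps forward at 2x speed within each cycle
  fx <- synthetic_decoded(function(t, actual) {
    ph <- (t %% 125) / 125
    actual + 0.5 / 10 * 125 * (ph - 0.5)   # adds a 2x-speed sawtooth
  }, speed = 0.5)
  q <- average_theta_quadruplets(fx$decoded, fx$cycles, fx$session)
  sp <- theta_sequence_speed(q)
  expect_gt(sp$speed_mps, 0.75)
  expect_equal(sp$speed_mps, 1.0, tolerance = 0.15)   # 2x the run speed
  # the averaged trace advances within cycles and retreats at boundaries
  rel <- q$mean_pos
  per_cyc <- floor(125 / (q$t_rel_ms[2] - q$t_rel_ms[1]))
  # allow half-bin alignment wobble at the cycle boundary
  jumps <- rel[per_cyc * (1:3) + 2] - rel[per_cyc * (1:3)]
  expect_true(all(jumps < 0))
  within <- diff(rel[(per_cyc + 2):(2 * per_cyc - 1)])
  expect_true(mean(within) > 0)
})

test_that("quadruplets near track ends are excluded", {
  fx <- synthetic_decoded(function(t, actual) pmin(actual, 95), speed = 2)
  # actual quickly exceeds the track: most quadruplets decode near the end
  q <- suppressWarnings(
    average_theta_quadruplets(fx$decoded, fx$cycles, fx$session))
  fx2 <- synthetic_decoded(function(t, actual) actual, speed = 0.3)
  q2 <- average_theta_quadruplets(fx2$decoded, fx2$cycles, fx2$session)
  expect_lt(q$n_quadruplets, q2$n_quadruplets)
})
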