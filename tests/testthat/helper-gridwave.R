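# Shared fixtures. Expensive simulations are computed once per test run and
# memoized here; sizes are chosen so the whole suite stays lightweight while
# preserving the sheet geometry (kernel radii, shift, drive profile are the
# main-model values throughout).

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small sheet for dynamics tests (no recording geometry needed)
small_config <- function(...) grid_config(n = 96, ...)

# a quiet config: negligible coupling, so single-neuron dynamics are isolated
isolated_config <- function(n = 24, ...) {
  grid_config(n = n, w_mag_exc = 1e-9, w_mag_inh = 1e-9,
              noise_var_exc = 0, noise_var_inh = 0, ...)
}

# run the network with a uniform excitatory drive value
run_uniform <- function(config, T, a_exc, a_inh = 0, vel = c(0, 0),
                        seed = 1, state = NULL, phi0 = NULL, ...) {
  n <- config$n
  maps <- list(matrix(a_exc, n, n))
  if (!is.null(phi0) && is.null(state)) {
    state <- list(phi = matrix(phi0, n * n, 5),
                  Chist = matrix(0, n * n,
                                 max(1, round(config$tau_s_ee / config$dt))),
                  Dhist = matrix(0, n * n,
                                 max(1, round(config$tau_s_inh / config$dt))),
                  t_next = 0L)
  }
  run_network(config, maps, rep(1L, T), rep(a_inh, T),
              cbind(rep(vel[1], T), rep(vel[2], T)), seed = seed,
              state = state, ...)
}

# settled run-state activity of the full-size sheet (n = 232, 4 s; the
# radial drive packs bumps into rings on small sheets, so the triangular
# lattice is checked at the main model size)
settled_snapshot <- function() fixture("settled_snapshot", {
  cfg <- grid_config(n = 232)
  maps <- list(excitatory_drive_field(cfg, "run"))
  T <- 4000
  r <- run_network(cfg, maps, rep(1L, T), rep(0.72, T),
                   cbind(rep(0, T), 0), seed = 2,
                   rec_mask = rep(0L, 232^2),
                   snapshot_every = 10, snapshot_pop = "S")
  # aggregate the last second
  apply(r$snapshots[, , 301:400], c(1, 2), sum)
})

# synthetic session-like object for analysis-module tests: hand-built events
# with known rate structure over a simple two-lap trajectory
synthetic_session <- function(n_laps = 4, neurons, spike_fun,
                              track_length = 100, seed = 1) {
  cfg <- grid_config(n = 144, track_length_cm = track_length,
                     idle_duration_s = 0.5, seed = seed)
  traj <- generate_track_trajectory(cfg, n_laps, seed = seed)
  track_x <- attr(traj, "track_pos_cm")
  p <- resolve_params(cfg, "run")
  psi0 <- rep(0, n_laps)
  a_inh <- numeric(nrow(traj))
  run <- traj$state == "run"
  a_inh[run] <- p$a_mag_inh - p$a_theta_inh *
    cos(2 * pi * p$f_theta * traj$t_ms[run] / 1000)
  ev <- spike_fun(traj, track_x, neurons)
  regions <- list(A = select_recording_regions(cfg, seed, "A"),
                  B = select_recording_regions(cfg, seed, "B"))
  structure(list(events = ev, trajectory = traj, drive_trace = a_inh,
                 psi0 = psi0, regions = regions, allo_maps = NULL,
                 counts = NULL, snapshots = NULL, config = cfg, seed = seed),
            class = "grid_session")
}

# place neurons inside the first region of set A
region_neurons <- function(cfg, k, seed = 1) {
  reg <- select_recording_regions(cfg, seed, "A")
  ctr <- reg$centers[1, ]
  data.frame(pop = "E", x = round(ctr[1]) + seq_len(k) %% 5 - 2,
             y = round(ctr[2]) + seq_len(k) %/% 5 - 2)
}

# Poisson spikes for a neuron with a Gaussian place field on the track
field_spikes <- function(traj, track_x, nrn, center_cm, width_cm = 8,
                         peak_hz = 20, seed = 1, phase_fun = NULL) {
  set.seed(seed)
  run <- which(traj$state == "run")
  rate <- peak_hz * exp(-(track_x[run] - center_cm)^2 / (2 * width_cm^2))
  fire <- run[runif(length(run)) < rate / 1000]
  if (!length(fire)) return(NULL)
  data.frame(pop = nrn$pop, x = nrn$x, y = nrn$y, t = fire - 1,
             t_ms = traj$t_ms[fire])
}
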