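#' Model configuration
#'
#' Builds the full parameter set of the spiking continuous-attractor grid-cell
#' network. Defaults are the main model values: a 232x232 sheet of five
#' overlapping populations (N, S, W, E excitatory plus one inhibitory),
#' 1 ms timestep, cosine-bump connectivity kernels, velocity-modulated
#' excitatory drive and theta-oscillating (8 Hz) inhibitory drive.
#' Several drive parameters depend on the behavioural state (`run`, `idle`,
#' `allo`); they are stored as named vectors and resolved per state with
#' [resolve_params()].
#'
#' @param ... named overrides of any default parameter. Unknown names are an
#'   error. State-dependent parameters (`a_max_exc`, `rho_a_exc`, `a_mag_inh`,
#'   `a_theta_inh`) may be given either as a full named vector or as a single
#'   number applied to all states.
#'
#' @return an object of class `grid_config`: a named list of parameters.
#'
#' @details Units: membrane and synaptic time constants in ms, kernel radii
#'   and the output shift `xi_shift` in neurons (sheet lattice units), drives
#'   and weights in the arbitrary units of the membrane potential (spike
#'   threshold = 1), `alpha_gain` in s/m, `f_theta` in Hz, track length in cm,
#'   speeds in m/s.
#'
#' @examples
#' cfg <- grid_config(n = 64, track_length_cm = 80)
#' resolve_params(cfg, "idle")$a_max_exc
#' @export
grid_config <- function(...) {
  defaults <- list(
    # -- network core (main model values) --
    n            = 232L,   # neurons per side, per population
    dt           = 1,      # ms
    tau_m_exc    = 40,     # ms
    tau_m_inh    = 20,     # ms
    tau_s_ee     = 5,      # ms, exc -> exc synaptic delay
    tau_s_ei     = 2,      # ms, exc -> inh
    tau_s_inh    = 2,      # ms, inh -> exc
    a_max_exc    = c(run = 2.0, idle = 1.6, allo = 2.0),
    a_min_exc    = 0.8,
    rho_a_exc    = c(run = 1.2, idle = 0.9, allo = 1.2),
    a_mag_inh    = c(run = 0.72, idle = 0.0, allo = 0.72),
    a_theta_inh  = c(run = 0.2, idle = 0, allo = 0),
    f_theta      = 8,      # Hz
    w_mag_exc    = 0.2,
    r_w_exc      = 6,      # neurons
    w_mag_inh    = 2.8,
    r_w_inh      = 12,     # neurons
    xi_shift     = 3,      # neurons
    alpha_gain   = 0.25,   # s/m
    noise_var_exc = 0.002^2,
    noise_var_inh = 0.002^2,
    boundary     = "nonperiodic",  # or "periodic"
    uniform_drive = FALSE,
    allocentric_enabled = TRUE,
    seed         = 1L,
    # -- behaviour / trajectory --
    track_length_cm  = 100,
    run_speed_target = 0.5,   # m/s
    arena_cm         = 100,   # open-field side
    fbm_hurst        = 0.8,
    fbm_rel_amp      = 0.1,   # relative speed fluctuation amplitude
    idle_duration_s  = 3,
    allo_duration_ms = 100,
    track_angle_deg  = 0,
    min_speed        = 0.05,  # m/s clip floor
    # -- setup (allocentric learning) --
    setup_learn_ms   = 1000,
    allo_rescale_min = NA_real_,  # NA -> a_min_exc
    allo_rescale_max = NA_real_,  # NA -> a_max_exc["allo"]
    # -- recording emulation --
    region_distance  = NA_real_,  # neurons; NA -> round(95/232 * n)
    region_radius    = 12,
    max_recorded     = 150L,
    stability_sd_cm  = 10,
    min_peak_rate    = 1,     # spikes/s
    rate_bin_cm      = 2,
    rate_smooth_cm   = 4,
    field_threshold_frac = 0.2,
    # -- decoding / sequences --
    decode_bin_ms    = 10,
    decode_step_ms   = 5,
    end_exclusion_cm = 10,
    seq_window_ms    = 62.5,
    # -- replay detection --
    replay_mua_z     = 1.0,   # core threshold on smoothed multiunit z-score
    replay_mua_edge  = 0.3,   # segments extend down to this z
    replay_mua_sd_ms = 20,    # MUA smoothing s.d.
    replay_min_ms    = 80,   # shorter windows leave too few decode bins to fit
    replay_max_ms    = 300,
    replay_span_frac = 0.5,
    replay_r2_min    = 0.5,
    replay_inlier_cm = 8,     # line-fit inlier tolerance
    replay_inlier_frac = 0.5, # minimum fraction of bins on the fitted line
    # -- bump analysis --
    snapshot_ms      = 10,
    bump_smooth_sigma = 1.5,  # neurons
    bump_threshold_frac = 0.3
  )
  dots <- list(...)
  if (length(dots)) {
    nm <- names(dots)
    if (is.null(nm) || any(nm == ""))
      stop("all configuration overrides must be named", call. = FALSE)
    unknown <- setdiff(nm, names(defaults))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    state_keys <- c("a_max_exc", "rho_a_exc", "a_mag_inh", "a_theta_inh")
    for (k in nm) {
      v <- dots[[k]]
      if (k %in% state_keys) {
        if (length(v) == 1L && is.null(names(v))) {
          v <- stats::setNames(rep(as.numeric(v), 3), c("run", "idle", "allo"))
        } else {
          full <- defaults[[k]]
          if (is.null(names(v)) || !all(names(v) %in% names(full)))
            stop("state-dependent key '", k,
                 "' must be named with states run/idle/allo", call. = FALSE)
          full[names(v)] <- v
          v <- full
        }
      }
      defaults[[k]] <- v
    }
  }
  cfg <- structure(defaults, class = "grid_config")
  validate_config(cfg)
  cfg
}

#' Validate a configuration
#'
#' Checks positivity of time constants, radii and magnitudes, the boundary /
#' drive pairing (periodic boundaries are only meaningful with uniform drive),
#' and that kernels fit on the sheet.
#'
#' @param config a `grid_config`.
#' @param allow_periodic_radial allow `boundary = "periodic"` without
#'   `uniform_drive` (normally rejected, since the radial drive profile exists
#'   to tame sheet edges that periodic boundaries do not have).
#' @return the config, invisibly; errors on violation.
#' @export
validate_config <- function(config, allow_periodic_radial = FALSE) {
  stopifnot(inherits(config, "grid_config"))
  pos <- c("dt", "tau_m_exc", "tau_m_inh", "tau_s_ee", "tau_s_ei", "tau_s_inh",
           "f_theta", "w_mag_exc", "r_w_exc", "w_mag_inh", "r_w_inh",
           "a_min_exc", "track_length_cm", "run_speed_target")
  for (k in pos)
    if (!is.numeric(config[[k]]) || any(config[[k]] <= 0))
      stop("configuration parameter '", k, "' must be strictly positive",
           call. = FALSE)
  if (config$n < 2 * (config$r_w_exc + config$xi_shift))
    stop("sheet too small for the excitatory kernel plus output shift",
         call. = FALSE)
  if (!config$boundary %in% c("nonperiodic", "periodic"))
    stop("boundary must be 'nonperiodic' or 'periodic'", call. = FALSE)
  if (config$boundary == "periodic" && !config$uniform_drive &&
      !allow_periodic_radial)
    stop("periodic boundary requires uniform_drive (override with ",
         "allow_periodic_radial = TRUE)", call. = FALSE)
  for (k in c("a_max_exc", "rho_a_exc", "a_mag_inh", "a_theta_inh"))
    if (!all(c("run", "idle", "allo") %in% names(config[[k]])))
      stop("state-dependent parameter '", k, "' lacks run/idle/allo values",
           call. = FALSE)
  invisible(config)
}

#' Resolve state-dependent parameters
#'
#' Substitutes the behavioural-state-specific values of the drive parameters
#' (`a_max_exc`, `rho_a_exc`, `a_mag_inh`, `a_theta_inh`) so that every
#' parameter is a scalar. All other fields are returned unchanged.
#'
#' @param config a `grid_config`.
#' @param state one of `"run"`, `"idle"`, `"allo"` (also accepts
#'   `"allocentric"`).
#' @return a named list of fully resolved scalar parameters, class
#'   `grid_params`.
#' @export
resolve_params <- function(config, state) {
  validate_config(config, allow_periodic_radial = TRUE)
  if (identical(state, "allocentric")) state <- "allo"
  if (!is.character(state) || length(state) != 1 ||
      !state %in% c("run", "idle", "allo"))
    stop("unknown behavioural state: ", paste(state, collapse = ","),
         call. = FALSE)
  out <- unclass(config)
  for (k in c("a_max_exc", "rho_a_exc", "a_mag_inh", "a_theta_inh"))
    out[[k]] <- unname(out[[k]][[state]])
  out$state <- state
  structure(out, class = "grid_params")
}

#' Write / read a configuration file
#'
#' The configuration is stored as a flat YAML document; state-dependent
#' parameters appear as small `run`/`idle`/`allo` maps. Reading applies the
#' same rules as [grid_config()]: unknown keys error, missing keys take the
#' defaults.
#'
#' @param config a `grid_config`.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `grid_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "grid_config"))
  x <- lapply(unclass(config), function(v) {
    if (!is.null(names(v))) as.list(v) else v
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x <- lapply(x, function(v) if (is.list(v)) unlist(v) else v)
  # yaml reads integers as integer, logicals fine; rebuild through grid_config
  do.call(grid_config, x)
}

#' @export
print.grid_config <- function(x, ...) {
  cat("<grid_config> ", x$n, "x", x$n, " sheet, dt=", x$dt, " ms, boundary=",
      x$boundary, if (x$uniform_drive) " (uniform drive)", "\n", sep = "")
  st <- sapply(c("run", "idle", "allo"), function(s) {
    p <- resolve_params(x, s)
    sprintf("  %-5s a_max+=%.2f rho_a=%.2f a_mag-=%.2f a_theta-=%.2f",
            s, p$a_max_exc, p$rho_a_exc, p$a_mag_inh, p$a_theta_inh)
  })
  cat(st, sep = "\n")
  cat("\n")
  invisible(x)
}
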