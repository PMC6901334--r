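#' Configuration for a named network variant
#'
#' Maps the variant tags used throughout the package to configuration
#' overrides: `"default"`; `"low-gain"` (velocity gain halved, giving a
#' one-to-one sheet-track correspondence and directionally biased replays);
#' `"periodic-uniform"` (periodic boundaries with uniform excitatory drive,
#' bumps and wavefronts across the whole sheet); `"no-allocentric"`
#' (allocentric corrections disabled).
#'
#' @param variant variant tag.
#' @param ... further overrides passed to [grid_config()].
#' @return a `grid_config`.
#' @export
variant_config <- function(variant = "default", ...) {
  extra <- switch(variant,
    "default" = list(),
    "low-gain" = list(alpha_gain = 0.125),
    "periodic-uniform" = list(boundary = "periodic", uniform_drive = TRUE),
    "no-allocentric" = list(allocentric_enabled = FALSE),
    stop("unknown variant: ", variant, call. = FALSE))
  do.call(grid_config, utils::modifyList(extra, list(...)))
}

#' Analyze one recording set of a session
#'
#' The full analysis pipeline on one tetrode-style recording set: stable
#' neuron selection, rate maps and fields, theta-cycle labelling, per-neuron
#' phase statistics, Bayesian decoding of run and idle periods,
#' theta-quadruplet averaging with sequence speed, and replay detection.
#'
#' @param session a `grid_session`.
#' @param set `"A"` or `"B"`.
#' @return list of class `session_analysis` with elements `neurons`,
#'   `fields`, `cycles`, `samples`, `phase_stats`, `decoded`, `quadruplets`,
#'   `sequence_speed`, `replays`, `run_speed`, `set`, `usable`.
#' @export
analyze_session <- function(session, set = "A") {
  neurons <- select_stable_neurons(session, set)
  usable <- isTRUE(attr(neurons, "usable"))
  fields <- compute_rate_maps(session, neurons)
  cycles <- label_theta(session)
  samples <- phase_samples(session, fields, cycles)
  stats <- phase_precession_stats(samples)
  decoded <- decode_session(session, fields)
  quad <- average_theta_quadruplets(decoded, cycles, session)
  seq_speed <- tryCatch(theta_sequence_speed(quad), error = function(e) NULL)
  replays <- detect_replays(decoded, session$config)
  tr <- session$trajectory
  run_speed <- mean(abs(tr$vx_mps[tr$state == "run"] +
                          1i * tr$vy_mps[tr$state == "run"]))
  structure(list(neurons = neurons, fields = fields, cycles = cycles,
                 samples = samples, phase_stats = stats, decoded = decoded,
                 quadruplets = quad, sequence_speed = seq_speed,
                 replays = replays, run_speed = run_speed, set = set,
                 usable = usable),
            class = "session_analysis")
}

#' @export
print.session_analysis <- function(x, ...) {
  cat("<session_analysis> set ", x$set, ": ", nrow(x$neurons), " neurons, ",
      nrow(x$phase_stats), " phase fits, ", nrow(x$replays), " replays",
      if (!is.null(x$sequence_speed))
        sprintf(", theta-seq %.2f m/s", x$sequence_speed$speed_mps),
      "\n", sep = "")
  invisible(x)
}

#' Run a replicate experiment
#'
#' Executes simulate -> record -> analyze for each manifest entry and writes
#' per-run CSV tables plus pooled summaries. Each run is simulated once and
#' its two recording sets are analyzed independently (each set counts as one
#' recording in the pooled tables). A failed run is recorded and the
#' remaining runs continue.
#'
#' @param manifest data frame with columns `seed` (unique per run) and
#'   optionally `variant` (default `"default"`), `n_laps` (default 8),
#'   `reversed` (default `FALSE`), `n` (sheet size override).
#' @param out_dir output directory; per-run tables go to
#'   `<out_dir>/run_<seed>/`, pooled tables to `<out_dir>/pooled/`.
#' @param config_overrides named list of extra [grid_config()] overrides
#'   applied to every run.
#' @return invisibly, a list with `runs` (per-run analysis summaries) and
#'   `pooled` (data frame of per-recording headline numbers).
#' @export
run_experiment <- function(manifest, out_dir = NULL,
                           config_overrides = list()) {
  stopifnot(is.data.frame(manifest), !is.null(manifest$seed))
  if (anyDuplicated(manifest$seed))
    stop("manifest seeds must be unique", call. = FALSE)
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  runs <- list(); pooled <- list()
  for (i in seq_len(nrow(manifest))) {
    entry <- manifest[i, ]
    variant <- if (!is.null(entry$variant)) as.character(entry$variant)
               else "default"
    n_laps <- if (!is.null(entry$n_laps)) entry$n_laps else 8
    reversed <- isTRUE(entry$reversed)
    ov <- config_overrides
    if (!is.null(entry$n) && !is.na(entry$n)) ov$n <- as.integer(entry$n)
    res <- tryCatch({
      cfg <- do.call(variant_config, c(list(variant = variant), ov,
                                       list(seed = as.integer(entry$seed))))
      traj <- generate_track_trajectory(cfg, n_laps, seed = entry$seed,
                                        reversed = reversed)
      ses <- run_session(cfg, traj, seed = entry$seed)
      lapply(c("A", "B"), function(s) analyze_session(ses, s))
    }, error = function(e) e)
    tag <- paste0("run_", entry$seed)
    if (inherits(res, "error")) {
      warning("run ", tag, " failed: ", conditionMessage(res))
      runs[[tag]] <- res
      next
    }
    runs[[tag]] <- res
    for (an in res) {
      pooled[[length(pooled) + 1]] <- data.frame(
        run = tag, set = an$set, variant = variant,
        n_neurons = nrow(an$neurons),
        run_speed = an$run_speed,
        seq_speed = if (!is.null(an$sequence_speed))
          an$sequence_speed$speed_mps else NA_real_,
        mean_abs_corr = mean(abs(an$phase_stats$corr), na.rm = TRUE),
        n_replays = nrow(an$replays),
        replay_speed = if (nrow(an$replays)) mean(an$replays$speed_mps)
          else NA_real_)
      if (!is.null(out_dir)) {
        rd <- file.path(out_dir, tag)
        dir.create(rd, showWarnings = FALSE)
        utils::write.csv(an$phase_stats,
                         file.path(rd, paste0("phase_stats_", an$set, ".csv")),
                         row.names = FALSE)
        utils::write.csv(an$replays,
                         file.path(rd, paste0("replays_", an$set, ".csv")),
                         row.names = FALSE)
        utils::write.csv(as.data.frame(an$fields$rate),
                         file.path(rd, paste0("rate_maps_", an$set, ".csv")),
                         row.names = TRUE)
      }
    }
  }
  pooled <- if (length(pooled)) do.call(rbind, pooled) else NULL
  if (!is.null(out_dir) && !is.null(pooled)) {
    dir.create(file.path(out_dir, "pooled"), showWarnings = FALSE)
    utils::write.csv(pooled, file.path(out_dir, "pooled", "summary.csv"),
                     row.names = FALSE)
  }
  invisible(list(runs = runs, pooled = pooled))
}

#' Render summary figures
#'
#' Regenerates the standard panels from a session and its analysis: sheet
#' activity snapshot, spike raster of the recorded set, phase-position
#' scatter, quadruplet-averaged decoded density, and replay fits.
#'
#' @param session a `grid_session` (needs `snapshots` for the sheet panel;
#'   others work without).
#' @param analysis a `session_analysis`.
#' @param out_dir directory for the figure files (PNG).
#' @return character vector of files written; errors if nothing could be
#'   rendered.
#' @export
render_figures <- function(session, analysis, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  pngf <- function(name, code, width = 900, height = 700) {
    f <- file.path(out_dir, name)
    ok <- tryCatch({
      grDevices::png(f, width = width, height = height)
      on.exit(grDevices::dev.off(), add = TRUE)
      code()
      TRUE
    }, error = function(e) { message("skipping ", name, ": ",
                                     conditionMessage(e)); FALSE })
    if (ok) written <<- c(written, f)
  }
  if (!is.null(session$snapshots))
    pngf("sheet_activity.png", function() {
      graphics::image(session$snapshots[, , dim(session$snapshots)[3]],
                      col = grDevices::gray.colors(32, rev = TRUE),
                      axes = FALSE, main = "S population activity")
    })
  pngf("raster.png", function() {
    ev <- .set_events(session, analysis$set)
    ev <- ev[ev$neuron %in% analysis$neurons$neuron, ]
    ord <- rank(apply(analysis$fields$rate, 1, which.max),
                ties.method = "first")
    graphics::plot(ev$t_ms / 1000, ord[match(ev$neuron,
                   rownames(analysis$fields$rate))],
                   pch = ".", xlab = "time (s)", ylab = "neuron (by field)",
                   main = "recorded spikes")
  })
  pngf("phase_scatter.png", function() {
    s <- analysis$samples
    if (!nrow(s)) stop("no phase samples")
    graphics::plot(rep(s$progress, 2),
                   c(s$phase_deg, s$phase_deg + 360), pch = 16,
                   cex = 0.4, xlab = "field progress (%)",
                   ylab = "theta phase (deg)", main = "phase vs progress")
  })
  pngf("theta_quadruplets.png", function() {
    q <- analysis$quadruplets
    if (q$n_quadruplets == 0) stop("no quadruplets")
    keep <- abs(q$offset_cm) <= 30
    graphics::image(q$t_rel_ms, q$offset_cm[keep],
                    q$density[, keep], col = grDevices::hcl.colors(32),
                    xlab = "time in quadruplet (ms)",
                    ylab = "decoded - actual (cm)",
                    main = "averaged theta quadruplets")
    graphics::lines(q$t_rel_ms, q$mean_pos, col = "white")
  })
  pngf("replays.png", function() {
    rp <- analysis$replays
    if (!nrow(rp)) stop("no replays")
    dec <- analysis$decoded
    idle <- dec[dec$state == "idle", ]
    graphics::plot(idle$t_ms / 1000, idle$ml_cm, pch = ".",
                   xlab = "time (s)", ylab = "decoded position (cm)",
                   main = sprintf("replays (n = %d)", nrow(rp)))
    for (k in seq_len(nrow(rp)))
      graphics::segments(rp$t_start_ms[k] / 1000, rp$p_start_cm[k],
                         rp$t_end_ms[k] / 1000, rp$p_end_cm[k],
                         col = "cyan", lwd = 2)
  })
  if (!length(written))
    stop("no figures could be rendered", call. = FALSE)
  written
}
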