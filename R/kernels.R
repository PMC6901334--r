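#' Synaptic kernels
#'
#' Radial connectivity profiles of the network. Excitatory neurons excite all
#' populations through a nonnegative raised-cosine kernel of radius `r_w_exc`;
#' inhibitory neurons inhibit only excitatory neurons through a surround
#' kernel that is zero at the origin, most negative (`-w_mag_inh`) at
#' `r_w_inh`, and vanishes at `2 * r_w_inh`. There are no
#' inhibitory-to-inhibitory connections.
#'
#' @param offset displacement on the neural sheet: either a numeric radius
#'   (vectorized) or a length-2 vector `(dx, dy)`.
#' @param w_mag kernel magnitude (potential a.u.).
#' @param r_w kernel radius (neurons).
#' @return synaptic weight(s), in potential a.u.
#' @examples
#' excitatory_kernel(0)            # = w_mag_exc
#' inhibitory_kernel(12)           # = -w_mag_inh
#' @export
excitatory_kernel <- function(offset, w_mag = 0.2, r_w = 6) {
  r <- .offset_radius(offset)
  ifelse(r < r_w, w_mag * (1 + cos(pi * r / r_w)) / 2, 0)
}

#' @rdname excitatory_kernel
#' @export
inhibitory_kernel <- function(offset, w_mag = 2.8, r_w = 12) {
  r <- .offset_radius(offset)
  ifelse(r < 2 * r_w, -w_mag * (1 - cos(pi * r / r_w)) / 2, 0)
}

.offset_radius <- function(offset) {
  if (is.matrix(offset)) sqrt(rowSums(offset^2))
  else if (length(offset) == 2 && is.null(dim(offset)))
    sqrt(sum(offset^2))
  else abs(offset)
}

#' Build connectivity stencils
#'
#' Materializes the five outgoing-weight stencils: one per excitatory
#' population (N, S, W, E), each the radial excitatory kernel translated by
#' `xi_shift` neurons along that population's preferred sheet direction
#' (up, down, left, right respectively), plus the inhibitory surround stencil.
#'
#' @param config a `grid_config`.
#' @return a list of class `grid_kernels` with elements `N`, `S`, `W`, `E`
#'   (square matrices of side `2*(r_w_exc + xi_shift) + 1`), `inh`
#'   (side `4*r_w_inh + 1`), and the sheet direction unit vectors `e_P`.
#'   Row index = sheet x displacement, column index = sheet y displacement,
#'   both centred.
#' @export
build_kernels <- function(config) {
  validate_config(config, allow_periodic_radial = TRUE)
  if (config$r_w_exc + config$xi_shift > config$n / 2)
    stop("excitatory kernel plus shift exceeds sheet half-size", call. = FALSE)
  e_P <- list(N = c(0, 1), S = c(0, -1), W = c(-1, 0), E = c(1, 0))
  R <- ceiling(config$r_w_exc + config$xi_shift)
  d <- seq(-R, R)
  exc <- lapply(e_P, function(e) {
    dx <- outer(d - config$xi_shift * e[1], rep(1, length(d)))
    dy <- outer(rep(1, length(d)), d - config$xi_shift * e[2])
    m <- excitatory_kernel(cbind(as.vector(dx), as.vector(dy)),
                           config$w_mag_exc, config$r_w_exc)
    matrix(m, length(d), length(d), dimnames = list(d, d))
  })
  Ri <- 2 * ceiling(config$r_w_inh)
  di <- seq(-Ri, Ri)
  dd <- sqrt(outer(di^2, di^2, "+"))
  inh <- matrix(inhibitory_kernel(as.vector(dd), config$w_mag_inh,
                                  config$r_w_inh),
                length(di), length(di), dimnames = list(di, di))
  structure(c(exc, list(inh = inh, e_P = e_P)), class = "grid_kernels")
}

#' Excitatory drive field
#'
#' Per-neuron baseline drive. With the default nonperiodic boundary the drive
#' is a raised-cosine radial profile: `a_max` at the sheet centre, decaying to
#' `a_min` at a scaled radial distance `rho_a`, where
#' `rho = dist((x, y), centre) / (n / 2)` so that `rho` is 0 at the centre and
#' about 1 at the midpoint of a sheet edge. With `uniform_drive` the field is
#' constant at `a_max` (used with periodic boundaries).
#'
#' @param config a `grid_config`.
#' @param state behavioural state, `"run"` or `"idle"` (the allocentric state
#'   uses a learned map, see [learn_allocentric_drive()]).
#' @return an `n x n` matrix of drives (a.u.), rows = sheet x, cols = sheet y.
#' @export
excitatory_drive_field <- function(config, state) {
  p <- resolve_params(config, state)
  n <- p$n
  if (isTRUE(p$uniform_drive))
    return(matrix(p$a_max_exc, n, n))
  ctr <- (n + 1) / 2
  rho <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")) / (n / 2)
  a <- matrix(p$a_min_exc, n, n)
  inside <- rho < p$rho_a_exc
  a[inside] <- p$a_min_exc + (p$a_max_exc - p$a_min_exc) *
    (1 + cos(pi * rho[inside] / p$rho_a_exc)) / 2
  a
}

#' Inhibitory drive
#'
#' Scalar drive common to all interneurons:
#' `a_mag - a_theta * cos(2 pi f t + psi0)`. The theta phase convention puts
#' phase 0 at troughs of this drive (where `cos = 1`), i.e. where excitatory
#' cells are most disinhibited.
#'
#' @param t time in ms (vectorized).
#' @param psi0 theta phase offset in radians (redrawn each lap).
#' @param params resolved parameters from [resolve_params()] (uses
#'   `a_mag_inh`, `a_theta_inh`, `f_theta`).
#' @return drive values (a.u.).
#' @export
inhibitory_drive <- function(t, psi0, params) {
  params$a_mag_inh -
    params$a_theta_inh * cos(2 * pi * params$f_theta * t / 1000 + psi0)
}

#' Learn an allocentric drive map
#'
#' Converts per-neuron spike tallies, collected while the animal rests at one
#' track end during simulation setup, into an excitatory drive map: tallies
#' are linearly rescaled so the most active sheet location receives the
#' allocentric `a_max_exc` and silent locations receive `a_min_exc`. The map
#' is later injected as the excitatory drive during brief allocentric
#' correction pulses, snapping attractor bumps back to the learned locations.
#'
#' @param tallies `n x n` matrix of excitatory spike counts.
#' @param config a `grid_config` (rescale bounds default to
#'   `[a_min_exc, a_max_exc[allo]]`, overridable via `allo_rescale_min/max`).
#' @return an `n x n` drive map (a.u.).
#' @export
learn_allocentric_drive <- function(tallies, config) {
  stopifnot(is.matrix(tallies), all(tallies >= 0))
  if (all(tallies == 0))
    stop("allocentric setup failed: no spikes tallied", call. = FALSE)
  lo <- config$allo_rescale_min
  hi <- config$allo_rescale_max
  if (is.na(lo)) lo <- config$a_min_exc
  if (is.na(hi)) hi <- unname(config$a_max_exc[["allo"]])
  mx <- max(tallies)
  lo + (hi - lo) * tallies / mx
}

# Padded, wrap-origin kernel transforms for the FFT convolution core.
# Returns the real spectra of the unshifted excitatory kernel and the
# inhibitory kernel on an m x m grid (m = n for periodic boundaries, an
# FFT-friendly size >= n + 2*(2*r_w_inh) otherwise).
.kernel_spectra <- function(config) {
  n <- config$n
  reach <- max(config$r_w_exc + config$xi_shift, 2 * config$r_w_inh)
  m <- if (config$boundary == "periodic") n
       else .good_fft_size(n + ceiling(reach) + 1)
  idx <- c(seq(0, floor(m / 2)), seq(-(ceiling(m / 2) - 1), -1)) # wrap coords
  dd <- sqrt(outer(idx^2, idx^2, "+"))
  ke <- matrix(excitatory_kernel(as.vector(dd), config$w_mag_exc,
                                 config$r_w_exc), m, m)
  ki <- matrix(inhibitory_kernel(as.vector(dd), config$w_mag_inh,
                                 config$r_w_inh), m, m)
  list(m = m,
       exc_hat = Re(stats::fft(ke)),
       inh_hat = Re(stats::fft(ki)))
}

.good_fft_size <- function(k) {
  # next integer >= k with only factors 2, 3, 5, 7
  repeat {
    x <- k
    for (p in c(2, 3, 5, 7)) while (x %% p == 0) x <- x / p
    if (x == 1) return(as.integer(k))
    k <- k + 1
  }
}
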