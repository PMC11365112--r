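# Closed-form photophysical models: multi-exponential intensity decay,
# polarized detection, dipolar-relaxation curve, and IRF convolution.
# Everything here is deterministic and noise-free.

#' Uniform time grid for TCSPC histograms
#'
#' @param t_start start time of the first bin (ns)
#' @param dt bin width (ns), must be positive
#' @param n_bins number of bins (integer >= 2)
#' @return an object of class `time_grid`
#' @export
time_grid <- function(t_start = 0, dt, n_bins) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a single positive number (ns)")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L)
    stop("`n_bins` must be an integer >= 2")
  structure(list(t_start = t_start, dt = dt, n_bins = n_bins),
            class = "time_grid")
}

#' Bin-center times of a time grid
#' @param grid a [time_grid()]
#' @return numeric vector of length `n_bins` (ns)
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  grid$t_start + (seq_len(grid$n_bins) - 1L) * grid$dt
}

same_grid <- function(a, b, tol = 1e-9) {
  abs(a$t_start - b$t_start) < tol && abs(a$dt - b$dt) < tol * a$dt &&
    a$n_bins == b$n_bins
}

#' Default acquisition grid (0-50 ns, 4096 bins)
#'
#' Resolves ~0.4-ns components while keeping reconvolution fits fast.
#' @return a [time_grid()]
#' @export
default_grid <- function() time_grid(0, 50 / 4096, 4096L)

#' Multi-exponential fluorescence decay model
#'
#' The intensity law F(t) = sum_i A_i exp(-t / tau_i) with up to three
#' components; lifetimes are stored sorted ascending.
#'
#' @param amplitudes non-negative amplitudes A_i (relative intensity
#'   units).  With `allow_negative = TRUE`, negative pre-exponentials are
#'   permitted: they arise as rise terms in red-edge decays during
#'   spectral relaxation and are required to represent them.
#' @param lifetimes positive lifetimes tau_i (ns), at most 3
#' @param allow_negative permit negative pre-exponentials (rise terms)
#' @return an object of class `multiexp_model`
#' @export
multiexp_model <- function(amplitudes, lifetimes, allow_negative = FALSE) {
  if (length(amplitudes) != length(lifetimes))
    stop("amplitudes and lifetimes must have equal length")
  if (length(lifetimes) < 1L || length(lifetimes) > 3L)
    stop("between 1 and 3 components are supported")
  if (any(!is.finite(lifetimes)) || any(lifetimes <= 0))
    stop("all lifetimes must be positive and finite")
  if (any(!is.finite(amplitudes)))
    stop("all amplitudes must be finite")
  if (!allow_negative && any(amplitudes < 0))
    stop("all amplitudes must be non-negative")
  if (max(amplitudes) <= 0)
    stop("at least one amplitude must be positive")
  o <- order(lifetimes)
  structure(list(amplitudes = as.numeric(amplitudes[o]),
                 lifetimes = as.numeric(lifetimes[o])),
            class = "multiexp_model")
}

#' Evaluate a multi-exponential decay
#'
#' @param model a [multiexp_model()]
#' @param t times (ns), all >= 0
#' @return relative intensity F(t)
#' @export
multiexp_intensity <- function(model, t) {
  stopifnot(inherits(model, "multiexp_model"))
  if (any(t < 0)) stop("`t` must be non-negative")
  out <- numeric(length(t))
  for (i in seq_along(model$lifetimes))
    out <- out + model$amplitudes[i] * exp(-t / model$lifetimes[i])
  out
}

#' Amplitude-averaged fluorescence lifetime
#'
#' tau_av = sum(A_i tau_i) / sum(A_i); lies in [min tau, max tau].
#'
#' @param model a [multiexp_model()]
#' @return lifetime (ns)
#' @export
amplitude_avg_lifetime <- function(model) {
  stopifnot(inherits(model, "multiexp_model"))
  s <- sum(model$amplitudes)
  if (s <= 0) stop("invalid model: all amplitudes are zero")
  sum(model$amplitudes * model$lifetimes) / s
}

#' Anisotropy decay model
#'
#' r(t) = B exp(-t / phi) + r_inf, with the instrument G-factor carried
#' alongside.  A fundamental (one-photon) limit r0 = B + r_inf <= 0.4
#' applies physically; fits exceeding it warn rather than fail so that
#' excursions stay visible.
#'
#' @param B anisotropy decay amplitude (dimensionless)
#' @param phi rotational correlation time (ns), positive
#' @param r_inf limiting anisotropy, in [-0.2, 0.4]
#' @param G polarization detection correction factor, positive
#' @return an object of class `anisotropy_model`
#' @export
anisotropy_model <- function(B, phi, r_inf, G = 1) {
  if (!is.finite(phi) || phi <= 0) stop("`phi` must be positive")
  if (!is.finite(G) || G <= 0) stop("`G` must be positive")
  if (r_inf < -0.2 || r_inf > 0.4)
    stop("`r_inf` must lie within [-0.2, 0.4]")
  if (B + r_inf > 0.4)
    warning("r0 = B + r_inf = ", signif(B + r_inf, 4),
            " exceeds the one-photon limit 0.4")
  structure(list(B = B, phi = phi, r_inf = r_inf, G = G),
            class = "anisotropy_model")
}

#' Dipolar relaxation model
#'
#' nu(t) = C exp(-t / t_relax) + nu_inf describing the time course of the
#' spectral center of gravity; `nu_inf` is the limiting relaxation level
#' and `C` the detectable part of the total shift.
#'
#' @param C pre-exponential spectral amplitude (cm^-1), >= 0
#' @param t_relax dipolar relaxation time (ns), positive
#' @param nu_inf limiting relaxation level (cm^-1), positive
#' @return an object of class `relaxation_model`
#' @export
relaxation_model <- function(C, t_relax, nu_inf) {
  if (!is.finite(t_relax) || t_relax <= 0) stop("`t_relax` must be positive")
  if (!is.finite(C) || C < 0) stop("`C` must be non-negative")
  if (!is.finite(nu_inf) || nu_inf <= 0) stop("`nu_inf` must be positive")
  structure(list(C = C, t_relax = t_relax, nu_inf = nu_inf),
            class = "relaxation_model")
}

#' Instrument response function on a time grid
#'
#' @param grid a [time_grid()]
#' @param counts non-negative per-bin values; total must be positive
#' @return an object of class `instrument_response`
#' @export
instrument_response <- function(grid, counts) {
  stopifnot(inherits(grid, "time_grid"))
  if (length(counts) != grid$n_bins)
    stop("`counts` length must equal the grid's n_bins")
  if (any(counts < 0)) stop("IRF counts must be non-negative")
  if (sum(counts) <= 0) stop("IRF total counts must be positive")
  structure(list(grid = grid, counts = as.numeric(counts)),
            class = "instrument_response")
}

#' Exact magic angle in degrees
#'
#' arccos(1/sqrt(3)) = 54.7356...; at this polarizer angle polarized
#' detection is insensitive to rotational dynamics.
#' @return angle in degrees
#' @export
magic_angle <- function() acos(1 / sqrt(3)) * 180 / pi

#' Polarized-detection matching factor k(theta)/3
#'
#' k(theta)/3 = cos^2(theta) + sin^2(theta)/G.  Equals 1 at theta = 0
#' (vertical), 1/G at 90 degrees (horizontal), and (2 + G)/(3 G) at the
#' magic angle.
#'
#' @param theta emission polarizer angle (degrees)
#' @param G detection correction factor, positive
#' @return dimensionless factor
#' @export
polarizer_factor <- function(theta, G) {
  if (any(!is.finite(G)) || any(G <= 0)) stop("`G` must be positive")
  th <- theta * pi / 180
  cos(th)^2 + sin(th)^2 / G
}

#' Polarized fluorescence decay
#'
#' I(theta, t) = k(theta)/3 * sum_i A_i e^(-t/tau_i) *
#'   \[1 + (3 cos^2 theta - 1) (B e^(-t/phi) + r_inf)\].
#' At the magic angle the bracket is exactly 1 and the unpolarized decay
#' is recovered.
#'
#' @param model a [multiexp_model()]
#' @param aniso an [anisotropy_model()] (supplies B, phi, r_inf, G)
#' @param theta emission polarizer angle (degrees)
#' @param t times (ns), >= 0
#' @return relative intensity
#' @export
polarized_intensity <- function(model, aniso, theta, t) {
  stopifnot(inherits(aniso, "anisotropy_model"))
  k3 <- polarizer_factor(theta, aniso$G)
  th <- theta * pi / 180
  geom <- 3 * cos(th)^2 - 1
  r_t <- aniso$B * exp(-t / aniso$phi) + aniso$r_inf
  k3 * multiexp_intensity(model, t) * (1 + geom * r_t)
}

#' Evaluate the dipolar relaxation curve nu(t)
#'
#' @param model a [relaxation_model()]
#' @param t times (ns), >= 0
#' @return wavenumber (cm^-1)
#' @export
relaxation_curve <- function(model, t) {
  stopifnot(inherits(model, "relaxation_model"))
  if (any(t < 0)) stop("`t` must be non-negative")
  model$C * exp(-t / model$t_relax) + model$nu_inf
}

#' Convolve a model curve with an instrument response
#'
#' Linear (zero-padded, causal) discrete convolution on the shared uniform
#' grid; the IRF is normalized to unit sum first, so the curve's total is
#' preserved whenever the shifted support still fits inside the grid.  No
#' circular wraparound is used, so decay tails cannot alias into t ~ 0.
#'
#' @param curve intensity values on `irf$grid`
#' @param irf an [instrument_response()]
#' @return expected (noise-free) counts on the same grid
#' @export
convolve_with_irf <- function(curve, irf) {
  stopifnot(inherits(irf, "instrument_response"))
  n <- irf$grid$n_bins
  if (length(curve) != n)
    stop("curve and IRF must share one time grid (length mismatch)")
  h <- irf$counts / sum(irf$counts)
  out <- conv_causal(h, curve)
  # FFT round-off can leave tiny negatives on zero bins
  out[abs(out) < 1e-12 * max(abs(out))] <- 0
  out
}

# Causal linear convolution of two equal-length vectors, zero-padded to a
# power-of-two FFT length (no circular wraparound); returns the first n
# bins.  Power-of-two padding keeps the FFT O(n log n) for any n.
conv_causal <- function(h, curve) {
  n <- length(curve)
  L <- stats::nextn(2L * n, 2)
  H <- stats::fft(c(h, numeric(L - n)))
  Cv <- stats::fft(c(curve, numeric(L - n)))
  Re(stats::fft(H * Cv, inverse = TRUE))[seq_len(n)] / L
}

# Shift an IRF by `shift` ns (linear interpolation, zero outside support),
# renormalized to unit sum.  Used by reconvolution fits.
shift_irf_counts <- function(irf, shift) {
  t <- grid_times(irf$grid)
  if (abs(shift) < 1e-15) {
    h <- irf$counts
  } else {
    h <- stats::approx(t, irf$counts, xout = t - shift, rule = 1)$y
    h[is.na(h)] <- 0
  }
  s <- sum(h)
  if (s <= 0) return(NULL)   # shift moved all mass outside the grid
  h / s
}
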