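# Assembly of time-resolved emission spectra from per-wavelength decay
# fits, spectral center of gravity and FWHM, the dipolar-relaxation fit,
# and the heavy-water relaxation-time ratio.

#' Peak-normalized emission spectrum at a fixed delay
#'
#' @param wavelengths emission wavelengths (nm), strictly increasing
#' @param intensities non-negative relative intensities
#' @param time_stamp delay after excitation (ns)
#' @return an object of class `spectrum` (intensities peak-normalized)
#' @export
emission_spectrum <- function(wavelengths, intensities, time_stamp = NA_real_) {
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("`wavelengths` must be strictly increasing")
  if (length(intensities) != length(wavelengths))
    stop("length mismatch between wavelengths and intensities")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  m <- max(intensities)
  if (m <= 0) stop("spectrum has no positive intensity")
  structure(list(wavelengths = as.numeric(wavelengths),
                 intensities = as.numeric(intensities) / m,
                 time_stamp = time_stamp),
            class = "spectrum")
}

#' Assemble TRES from per-wavelength decay fits
#'
#' Evaluates each wavelength's reconstructed (noise-free, IRF-free) decay
#' at the requested times and peak-normalizes each time's spectrum.
#' Requires converged fits carrying `wavelength_nm` metadata.
#'
#' @param per_wavelength_fits list of [fit_multiexp_reconvolution()]
#'   results with `wavelength_nm` in their `meta`
#' @param times delays after excitation (ns), strictly increasing
#' @return list of [spectrum()] objects, one per time
#' @export
build_tres <- function(per_wavelength_fits, times) {
  wl <- vapply(per_wavelength_fits,
               function(f) as.numeric(f$meta$wavelength_nm %||% NA_real_),
               numeric(1))
  if (anyNA(wl)) stop("every fit needs `wavelength_nm` metadata")
  if (anyDuplicated(wl)) stop("duplicate wavelengths in the fit set")
  if (length(wl) < 8L) stop("at least 8 wavelengths are required")
  if (is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing")
  conv <- vapply(per_wavelength_fits, function(f) isTRUE(f$converged),
                 logical(1))
  if (any(!conv))
    stop("unconverged fit(s) at wavelength(s): ",
         paste(wl[!conv], collapse = ", "), " nm")
  o <- order(wl)
  fits <- per_wavelength_fits[o]; wl <- wl[o]
  mat <- vapply(fits, function(f) multiexp_intensity(f$model, times),
                numeric(length(times)))
  if (length(times) == 1L) mat <- matrix(mat, nrow = 1L)
  # signed pre-exponentials (red-edge rise terms) can dip marginally
  # below zero near t = 0; clamp for the spectral representation
  mat[mat < 0] <- 0
  lapply(seq_along(times), function(j)
    emission_spectrum(wl, mat[j, ], time_stamp = times[j]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spectral center of gravity (wavenumber)
#'
#' nu = sum_lambda I(lambda) / lambda  /  sum_lambda I(lambda), with the
#' wavelength in cm so the result is in cm^-1.  Invariant to uniform
#' intensity rescaling and to appending zero-intensity wavelengths.
#'
#' @param spec a [spectrum()]
#' @return wavenumber (cm^-1)
#' @export
center_of_gravity <- function(spec) {
  stopifnot(inherits(spec, "spectrum"))
  s <- sum(spec$intensities)
  if (s <= 0) stop("center of gravity undefined for an all-zero spectrum")
  sum(spec$intensities * 1e7 / spec$wavelengths) / s
}

#' Spectral width at half maximum (wavenumber domain)
#'
#' Converts the spectrum to the wavenumber axis, locates the half-maximum
#' crossing on each flank by linear interpolation (outermost crossing when
#' noise produces several), and returns the high-flank minus low-flank
#' wavenumber.
#'
#' @param spec a [spectrum()] with an interior maximum
#' @return width (cm^-1)
#' @export
spectral_fwhm <- function(spec) {
  stopifnot(inherits(spec, "spectrum"))
  nu <- rev(1e7 / spec$wavelengths)           # ascending wavenumber
  I <- rev(spec$intensities)
  i_max <- which.max(I)
  if (i_max == 1L || i_max == length(I))
    stop("spectrum has no interior maximum; cannot measure FWHM")
  half <- max(I) / 2
  cross <- function(idx_lo, idx_hi) {
    # outermost half-max crossing within nu[idx_lo..idx_hi]
    above <- I >= half
    xs <- c()
    for (i in idx_lo:(idx_hi - 1L)) {
      if (above[i] != above[i + 1L]) {
        xs <- c(xs, nu[i] + (half - I[i]) / (I[i + 1L] - I[i]) *
                  (nu[i + 1L] - nu[i]))
      }
    }
    xs
  }
  lo_x <- cross(1L, i_max)
  if (!length(lo_x)) {
    if (I[1] >= half)
      stop("low-wavenumber (red) flank never crosses half maximum; ",
           "spectrum is truncated")
    lo_x <- nu[1]
  }
  hi_x <- cross(i_max, length(I))
  if (!length(hi_x)) {
    if (I[length(I)] >= half)
      stop("high-wavenumber (blue) flank never crosses half maximum; ",
           "spectrum is truncated")
    hi_x <- nu[length(nu)]
  }
  max(hi_x) - min(lo_x)
}

#' Fit the dipolar-relaxation law to a nu(t) series
#'
#' Least-squares fit of nu(t) = C exp(-t/t_relax) + nu_inf, optionally
#' restricted to a time window (used when nu(t) rises again at late times
#' and only the initial decay is meaningful).  A robust coarse grid over
#' t_relax (with C and nu_inf solved linearly) seeds a Levenberg-Marquardt
#' refinement.  Standard errors are attached as the `se` attribute; a
#' rising trend (fitted C < 0) is flagged with a warning but returned.
#'
#' @param times delays (ns)
#' @param nu_values center-of-gravity values (cm^-1)
#' @param window optional `c(t_lo, t_hi)` restricting the fit
#' @return a [relaxation_model()] with attributes `se` (named vector) and
#'   `negative_C` (logical)
#' @export
fit_relaxation <- function(times, nu_values, window = NULL) {
  if (length(times) != length(nu_values)) stop("length mismatch")
  if (!is.null(window)) {
    keep <- times >= window[1] & times <= window[2]
    times <- times[keep]; nu_values <- nu_values[keep]
  }
  if (length(times) < 5L)
    stop("at least 5 points inside the window are required")
  # coarse grid: linear solve of (C, nu_inf) for candidate t_relax
  span <- max(times) - min(times)
  trs <- exp(seq(log(span / 200), log(span * 5), length.out = 60))
  best <- NULL
  for (tr in trs) {
    X <- cbind(exp(-times / tr), 1)
    cf <- tryCatch(qr.coef(qr(X), nu_values), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) next
    ssr <- sum((nu_values - X %*% cf)^2)
    if (is.null(best) || ssr < best$ssr)
      best <- list(tr = tr, C = cf[1], nu_inf = cf[2], ssr = ssr)
  }
  if (is.null(best)) stop("relaxation fit failed on the coarse grid")
  df <- data.frame(t = times, nu = nu_values)
  fit <- tryCatch(
    minpack.lm::nlsLM(nu ~ C * exp(-t / tr) + nu_inf, data = df,
                      start = list(C = best$C, tr = best$tr,
                                   nu_inf = best$nu_inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    cf <- c(C = best$C, tr = best$tr, nu_inf = best$nu_inf)
    se <- c(C = NA_real_, tr = NA_real_, nu_inf = NA_real_)
  } else {
    cf <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, 3))
    names(se) <- names(cf)
  }
  neg_C <- cf[["C"]] < -1e-8 * abs(cf[["nu_inf"]])
  if (neg_C)
    warning("fitted C < 0: nu(t) trend is non-decreasing over the window")
  model <- relaxation_model(C = max(cf[["C"]], 0),
                            t_relax = abs(cf[["tr"]]),
                            nu_inf = cf[["nu_inf"]])
  attr(model, "se") <- c(C = unname(se["C"]), t_relax = unname(se["tr"]),
                         nu_inf = unname(se["nu_inf"]))
  attr(model, "negative_C") <- neg_C
  model
}

#' Heavy-water relaxation-time ratio
#'
#' R_D/H = t_relax(D2O) / t_relax(H2O), with a first-order propagated
#' standard error when both fits carry one.
#'
#' @param fit_D2O,fit_H2O [relaxation_model()] objects (e.g., from
#'   [fit_relaxation()])
#' @return ratio with an `se` attribute
#' @export
relaxation_time_ratio <- function(fit_D2O, fit_H2O) {
  stopifnot(inherits(fit_D2O, "relaxation_model"),
            inherits(fit_H2O, "relaxation_model"))
  r <- fit_D2O$t_relax / fit_H2O$t_relax
  get_se <- function(m) {
    s <- attr(m, "se")
    if (is.null(s) || !"t_relax" %in% names(s)) NA_real_ else s[["t_relax"]]
  }
  se_d <- get_se(fit_D2O)
  se_h <- get_se(fit_H2O)
  se <- if (is.finite(se_d) && is.finite(se_h))
    r * sqrt((se_d / fit_D2O$t_relax)^2 + (se_h / fit_H2O$t_relax)^2)
  else NA_real_
  attr(r, "se") <- se
  r
}

#' Full TRES analysis pipeline on a wavelength-resolved decay set
#'
#' Fits every wavelength's decay by reconvolution, assembles TRES at the
#' requested times, computes the center of gravity nu(t) and FWHM(t), and
#' fits the relaxation law to nu(t).
#'
#' @param decays list of [decay_histogram()] with `wavelength_nm` metadata
#' @param irf shared [instrument_response()]
#' @param times delays (ns) at which spectra are assembled
#' @param n_components components for the per-wavelength empirical fits
#' @param fit_window optional window for the relaxation fit `c(t_lo,t_hi)`
#' @param decay_window optional fit window passed to the decay fits
#' @param n_starts multi-start count for the decay fits
#' @param mle use the Poisson-deviance objective for the per-wavelength
#'   fits (default TRUE: band-edge decays are photon-starved and the
#'   Neyman weights systematically suppress their tails)
#' @return an object of class `tres_result` with `spectra`, `times`,
#'   `nu_t`, `fwhm_t`, `relax_fit`, `fit_window`, `fits`
#' @export
tres_pipeline <- function(decays, irf, times, n_components = 3,
                          fit_window = NULL, decay_window = NULL,
                          n_starts = 3, mle = TRUE) {
  # adjacent wavelengths have nearly identical decay structure, so each
  # fit warm-starts its neighbor; the brightest decay (best statistics)
  # is fitted first with the full multi-start set, then warm starts
  # propagate outward toward the faint band edges
  fits <- vector("list", length(decays))
  i0 <- which.max(vapply(decays, function(d) max(d$counts), numeric(1)))
  order_out <- order(abs(seq_along(decays) - i0))
  for (i in order_out) {
    nb <- if (i < i0) i + 1L else if (i > i0) i - 1L else NA_integer_
    init <- if (!is.na(nb) && isTRUE(fits[[nb]]$converged) &&
                length(fits[[nb]]$model$lifetimes) == n_components)
      list(lifetimes = fits[[nb]]$model$lifetimes) else NULL
    fits[[i]] <- fit_multiexp_reconvolution(
      decays[[i]], irf, n_components = n_components,
      init = init, window = decay_window, nonneg = FALSE, mle = mle,
      n_starts = if (is.null(init)) n_starts else 1)
  }
  spectra <- build_tres(fits, times)
  nu_t <- vapply(spectra, center_of_gravity, numeric(1))
  fwhm_t <- vapply(spectra, function(s)
    tryCatch(spectral_fwhm(s), error = function(e) NA_real_), numeric(1))
  relax_fit <- fit_relaxation(times, nu_t, window = fit_window)
  structure(list(spectra = spectra, times = times, nu_t = nu_t,
                 fwhm_t = fwhm_t, relax_fit = relax_fit,
                 fit_window = fit_window %||% range(times), fits = fits),
            class = "tres_result")
}
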