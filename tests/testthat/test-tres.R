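test_that("center of gravity matches hand-computed wavenumber means", {
  expect_equal(center_of_gravity(emission_spectrum(c(310, 320, 330),
                                                   c(0, 1, 0))),
               1e7 / 320)
  expect_equal(center_of_gravity(emission_spectrum(c(300, 400), c(1, 1))),
               (1e7 / 300 + 1e7 / 400) / 2)
  expect_equal(center_of_gravity(emission_spectrum(c(300, 350), c(1, 3))),
               (1e7 / 300 + 3 * 1e7 / 350) / 4, tolerance = 1e-9)
  # invariance under rescaling and zero-padding
  s1 <- emission_spectrum(c(320, 340, 360), c(1, 2, 1))
  s2 <- emission_spectrum(c(300, 320, 340, 360, 380), c(0, 1, 2, 1, 0))
  expect_equal(center_of_gravity(s1), center_of_gravity(s2))
  s3 <- emission_spectrum(c(320, 340, 360), 5 * c(1, 2, 1))
  expect_equal(center_of_gravity(s1), center_of_gravity(s3))
})

test_that("spectral FWHM matches the analytic Gaussian width", {
  wl <- seq(300, 420, 2)
  nu <- 1e7 / wl
  I <- exp(-0.5 * ((nu - 29500) / 800)^2)
  sp <- emission_spectrum(wl, I)
  expect_equal(spectral_fwhm(sp), 2 * sqrt(2 * log(2)) * 800,
               tolerance = 0.01)
  sp2 <- emission_spectrum(wl, 2 * I)
  expect_equal(spectral_fwhm(sp), spectral_fwhm(sp2))
  # monotone spectrum has no interior maximum
  expect_error(spectral_fwhm(emission_spectrum(wl, seq_along(wl))),
               "interior maximum")
  # truncated flank is reported by name
  It <- exp(-0.5 * ((nu - 33000) / 3000)^2)
  expect_error(spectral_fwhm(emission_spectrum(wl, It)), "flank")
})

test_that("TRES assembly validates inputs and is flat for identical decays", {
  g <- test_grid(256L, 25)
  irf <- test_irf(g)
  m <- multiexp_model(c(0.6, 0.4), c(1, 4))
  wl <- seq(310, 380, 10)
  fits <- lapply(wl, function(w) {
    h <- noisefree_histogram(m, g, irf, peak = 1e6,
                             meta = list(wavelength_nm = w))
    fit_multiexp_reconvolution(h, irf, 2, n_starts = 2)
  })
  sp <- build_tres(fits, times = c(1, 5, 10))
  for (s in sp) expect_equal(s$intensities, rep(1, length(wl)),
                             tolerance = 1e-4)
  expect_error(build_tres(fits[1:3], 1:3), "at least 8")
  fits_dup <- fits
  fits_dup[[2]]$meta$wavelength_nm <- wl[1]
  expect_error(build_tres(fits_dup, c(1, 2)), "duplicate")
  fits_bad <- fits
  fits_bad[[4]]$converged <- FALSE
  expect_error(build_tres(fits_bad, c(1, 2)), "340")
})

test_that("relaxation fit recovers exact and windowed curves", {
  t <- seq(0, 20, 0.5)
  truth <- relaxation_model(C = 700, t_relax = 1.5, nu_inf = 28900)
  fit <- fit_relaxation(t, relaxation_curve(truth, t))
  expect_lt(abs(fit$t_relax - 1.5), 1e-6)
  expect_lt(abs(fit$C - 700), 1e-3)
  expect_lt(abs(fit$nu_inf - 28900), 1e-3)
  # window restriction ignores a late-time rise
  nu <- relaxation_curve(truth, t)
  nu[t > 2] <- nu[t > 2] + 300 * (t[t > 2] - 2)
  fitw <- fit_relaxation(t, nu, window = c(0, 2))
  expect_lt(abs(fitw$t_relax - 1.5) / 1.5, 0.05)
  expect_error(fit_relaxation(t[1:3], nu[1:3]), "at least 5")
  # rising trend is flagged, not fatal
  expect_warning(fit_relaxation(t, rev(relaxation_curve(truth, t))),
                 "non-decreasing")
})

test_that("heavy-water ratio divides relaxation times and propagates error", {
  a <- relaxation_model(500, 1.53, 28900)
  b <- relaxation_model(500, 1.00, 28900)
  expect_equal(as.numeric(relaxation_time_ratio(a, a)), 1)
  expect_equal(as.numeric(relaxation_time_ratio(a, b)), 1.53)
  expect_equal(as.numeric(relaxation_time_ratio(
    relaxation_model(500, 1.2, 28900), b)), 1.2)
  attr(a, "se") <- c(C = 1, t_relax = 0.05, nu_inf = 1)
  attr(b, "se") <- c(C = 1, t_relax = 0.04, nu_inf = 1)
  r <- relaxation_time_ratio(a, b)
  expect_equal(attr(r, "se"),
               1.53 * sqrt((0.05 / 1.53)^2 + (0.04 / 1)^2))
})

test_that("full TRES pipeline recovers homogeneous relaxation", {
  g <- test_grid(512L, 50)
  irf <- test_irf(g)
  sc <- relax_scenario(t_relax = 1.5, C = 0.8e3, nu_inf = 29.0e3)
  times <- seq(0.1, 10, length.out = 25)
  t_rec <- nu_rec <- numeric(4)
  for (s in 1:4) {
    d <- simulate_tres_dataset(sc, tres_wavelengths, peak_counts = 2e4,
                               seed = 60 + s, grid = g, irf = irf)
    tr <- tres_pipeline(d, irf, times)
    t_rec[s] <- tr$relax_fit$t_relax
    nu_rec[s] <- tr$relax_fit$nu_inf
  }
  # homogeneous scenario, noise-free counts: nu(t) monotone non-increasing
  t <- grid_times(g)
  conv <- apply(tres_surface(sc, tres_wavelengths, t - t[1]), 1,
                function(row) convolve_with_irf(row, irf))
  nf <- lapply(seq_along(tres_wavelengths), function(i)
    decay_histogram(g, round(conv[, i] / max(conv) * 2e4),
                    list(wavelength_nm = tres_wavelengths[i])))
  tr0 <- tres_pipeline(nf, irf, times)
  expect_true(all(diff(tr0$nu_t) < 1))
  expect_lt(abs(mean(t_rec) - 1.5) / 1.5, 0.10)
  # the finite wavelength window truncates the band, so the asymptotic
  # center of gravity sits at the truncated-band oracle, not at the raw
  # generating nu_inf
  nu_grid <- 1e7 / tres_wavelengths
  band_inf <- exp(-0.5 * ((nu_grid - 29.0e3) /
                            sc$spectral_width_sigma)^2)
  nu_inf_oracle <- center_of_gravity(
    emission_spectrum(tres_wavelengths, band_inf))
  expect_lt(abs(mean(nu_rec) - nu_inf_oracle), 30)
})
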