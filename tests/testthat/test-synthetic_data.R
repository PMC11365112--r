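test_that("scenario table returns the study's endpoint values", {
  v <- scenario_from_table("V4W")
  expect_equal(v$Kd, 23)
  expect_equal(v$aniso_aq$r_inf, 0.005)
  expect_equal(v$aniso_m$r_inf, 0.080)
  expect_equal(v$relax_aq$nu_inf, 28.70e3)
  expect_equal(v$relax_m$nu_inf, 29.59e3)
  l5 <- scenario_from_table("L5W")
  expect_equal(l5$Kd, 17)
  expect_equal(l5$aniso_m$r_inf, 0.070)
  expect_equal(l5$relax_m$nu_inf, 28.90e3)
  expect_error(scenario_from_table("X9W"), "unknown peptide_id")
  prov <- attr(v, "provenance")
  expect_equal(unname(prov["Kd"]), "table")
  expect_equal(unname(prov["lifetimes"]), "invented")
})

test_that("Gaussian IRF is normalized, centered, and degenerates to a delta", {
  g <- test_grid(2048L, 25)
  irf <- make_gaussian_irf(0.2, center = 2, grid = g)
  expect_equal(sum(irf$counts), 1)
  t <- grid_times(g)
  expect_equal(t[which.max(irf$counts)], 2, tolerance = g$dt)
  # empirical FWHM within a bin of requested
  half <- max(irf$counts) / 2
  above <- which(irf$counts >= half)
  fwhm_emp <- t[max(above)] - t[min(above)]
  expect_lt(abs(fwhm_emp - 0.2), g$dt + 1e-12)
  # degenerate width: single-bin delta
  d <- make_gaussian_irf(g$dt / 100, center = 2, grid = g)
  expect_equal(sum(d$counts > 0), 1L)
  expect_error(make_gaussian_irf(0.2, center = 100, grid = g), "inside")
  expect_error(make_gaussian_irf(-1, center = 2, grid = g), "positive")
})

test_that("Poisson sampling is seeded-deterministic and unbiased", {
  g <- test_grid(512L, 25)
  curve <- multiexp_intensity(multiexp_model(1, 3), grid_times(g))
  h1 <- simulate_decay(curve, 1e4, seed = 11, grid = g)
  h2 <- simulate_decay(curve, 1e4, seed = 11, grid = g)
  expect_identical(h1$counts, h2$counts)
  h3 <- simulate_decay(curve, 1e4, seed = 12, grid = g)
  expect_false(identical(h1$counts, h3$counts))
  # zero expectation, zero background -> all-zero counts
  h0 <- simulate_decay(numeric(512), 1, 0, seed = 1, grid = g)
  expect_true(all(h0$counts == 0))
  expect_error(simulate_decay(curve, 1e4, background = -1, grid = g),
               "non-negative")
  # moment oracle: standardized residuals average to ~0 over replicates
  lam <- curve / max(curve) * 1e4
  keep <- lam > 20
  z <- vapply(1:200, function(s) {
    h <- simulate_decay(curve, 1e4, seed = 1000 + s, grid = g)
    mean((h$counts[keep] - lam[keep]) / sqrt(lam[keep]))
  }, numeric(1))
  expect_gt(mean(z), -0.01)
  expect_lt(mean(z), 0.01)
})

test_that("polarized set generator honors the polarized decay law", {
  sc <- scenario_from_table("L1W")
  g <- test_grid(512L, 25)
  irf <- test_irf(g)
  expect_error(simulate_polarized_set(sc, numeric(0), grid = g, irf = irf),
               "non-empty")
  # noise-free mode: construction identity recovers r(t)
  cur <- simulate_polarized_set(sc, c(0, 90), G = 1.2, peak_counts = NULL,
                                grid = g, irf = irf)
  an <- sc$aniso_m
  t <- grid_times(g)
  # compare after the IRF has passed (convolution distorts early bins)
  late <- t > 4
  r_t <- construct_anisotropy_decay(cur[[1]], cur[[2]], G = 1.2)
  truth <- an$B * exp(-(t - 2) / an$phi) + an$r_inf
  expect_lt(max(abs(r_t[late] - truth[late])), 0.02)
  # with noise: histograms carry the angle metadata
  hs <- simulate_polarized_set(sc, c(0, magic_angle(), 90), G = 1.1,
                               peak_counts = 5e3, seed = 3, grid = g,
                               irf = irf)
  expect_equal(vapply(hs, function(h) h$meta$polarizer_deg, numeric(1)),
               c(0, magic_angle(), 90))
})

test_that("TRES surface center of gravity and width follow the analytic law", {
  sc <- relax_scenario(t_relax = 3, C = 0.9e3, nu_inf = 29.0e3)
  # narrow band fully covered by the wavelength window; the discrete
  # center of gravity then differs from the band center only by the
  # wavelength-sampling bias: lambda-equidistant points weight the
  # wavenumber axis with density ~ 1/nu^2, shifting a Gaussian band by
  # -2 sigma^2 / nu_c (analytic oracle)
  sc$spectral_width_sigma <- 800
  wl <- seq(300, 420, 2)
  times <- seq(0, 20, 1)
  surf <- tres_surface(sc, wl, times)
  nu_c <- relaxation_curve(sc$relax_m, times)
  offs <- vapply(seq_along(times), function(j)
    center_of_gravity(emission_spectrum(wl, surf[, j], times[j])) -
      nu_c[j], numeric(1))
  expect_lt(max(abs(offs - (-2 * 800^2 / nu_c))), 2)
  # the bias is essentially constant in time, so nu(t) tracks nu_c(t)
  expect_lt(diff(range(offs)), 10)
  # homogeneous: FWHM constant within 2%
  fw <- vapply(seq_along(times), function(j)
    spectral_fwhm(emission_spectrum(wl, surf[, j])), numeric(1))
  expect_lt(diff(range(fw)) / mean(fw), 0.02)
  # steady-state center of gravity lies strictly between the limits
  tt <- seq(0, 40, 0.02)
  ss <- rowSums(tres_surface(sc, wl, tt))
  nu_ss <- center_of_gravity(emission_spectrum(wl, ss))
  expect_gt(nu_ss, sc$relax_m$nu_inf)
  expect_lt(nu_ss, relaxation_curve(sc$relax_m, 0))
})

test_that("two-fraction relaxation produces a transient FWHM maximum", {
  sc <- relax_scenario(t_relax = 1, C = 1.2e3, nu_inf = 29.0e3,
                       hetero = 0.5, t_slow = 10)
  wl <- seq(300, 420, 2)
  times <- seq(0, 40, 0.25)
  surf <- tres_surface(sc, wl, times)
  fw <- vapply(seq_along(times), function(j)
    spectral_fwhm(emission_spectrum(wl, surf[, j])), numeric(1))
  i_max <- which.max(fw)
  expect_gt(i_max, 1)
  expect_lt(i_max, length(times))
  expect_gt(fw[i_max], fw[1])
  expect_gt(fw[i_max], fw[length(times)])
  # location agrees with the analytic mixture-variance argmax within 1 ns
  mix_var <- function(t) {
    d <- sc$relax_m$C * (exp(-t / sc$relax_m$t_relax) -
                           exp(-t / sc$t_relax_slow))
    sc$spectral_width_sigma^2 + 0.25 * d^2
  }
  t_star <- stats::optimize(function(t) -mix_var(t), c(0, 40))$minimum
  expect_lt(abs(times[i_max] - t_star), 1)
})

test_that("TRES dataset generator validates input and stamps metadata", {
  sc <- relax_scenario(3)
  g <- test_grid(256L, 25)
  expect_error(simulate_tres_dataset(sc, c(340, 330, 350), grid = g),
               "strictly increasing")
  expect_error(simulate_tres_dataset(sc, seq(330, 360, 10), grid = g),
               "at least 8")
  hs <- simulate_tres_dataset(sc, seq(300, 420, 15), peak_counts = 2e3,
                              seed = 5, grid = g, irf = test_irf(g))
  expect_equal(vapply(hs, function(h) h$meta$wavelength_nm, numeric(1)),
               seq(300, 420, 15))
  hs2 <- simulate_tres_dataset(sc, seq(300, 420, 15), peak_counts = 2e3,
                               seed = 5, grid = g, irf = test_irf(g))
  expect_identical(lapply(hs, `[[`, "counts"), lapply(hs2, `[[`, "counts"))
})

test_that("quench series follows the rate-addition law", {
  sc <- scenario_from_table("NATA")
  sc$lifetimes <- multiexp_model(1, 3)   # monoexponential F0
  g <- test_grid(512L, 25)
  irf <- test_irf(g)
  expect_error(simulate_quench_series(sc, Q_list = c(0.1, 0.2), grid = g,
                                      irf = irf), "include 0")
  expect_error(simulate_quench_series(sc, Q_list = c(0, -0.1), grid = g,
                                      irf = irf), "non-negative")
  # noise-free law check via large counts: effective lifetime 1/(1/3+0.1)
  hs <- simulate_quench_series(sc, Q_list = c(0, 0.1), kq = 1,
                               peak_counts = 1e6, seed = 2, grid = g,
                               irf = irf)
  t <- grid_times(g)
  late <- t > 5 & t < 15
  slope <- stats::coef(stats::lm(log(pmax(hs[[2]]$counts[late], 1)) ~
                                   t[late]))[2]
  expect_equal(unname(-1 / slope), 1 / (1 / 3 + 0.1), tolerance = 0.02)
  expect_equal(hs[[1]]$meta$quencher_M, 0)
})

test_that("calcein sample construction inverts the leakage formula", {
  g <- test_grid(2048L, 25)
  irf <- test_irf(g)
  s <- simulate_calcein_sample(0.5, BF0_fraction = 0, Q_stat = 1.2,
                               peak_counts = 1e4, seed = 1, grid = g,
                               irf = irf)
  tr <- attr(s, "truth")
  expect_equal(tr$B_F / tr$B_E, 1.2)
  t1 <- attr(simulate_calcein_sample(1, peak_counts = 1e3, grid = g,
                                     irf = irf), "truth")
  expect_equal(t1$B_E, 0)
  t0 <- attr(simulate_calcein_sample(0, BF0_fraction = 0.2,
                                     peak_counts = 1e3, grid = g,
                                     irf = irf), "truth")
  expect_equal(t0$B_F, 0.2)   # baseline only
  expect_error(simulate_calcein_sample(1.2, grid = g, irf = irf),
               "leak_fraction")
})

test_that("partition titration generator follows the binding isotherm", {
  ep <- data.frame(wavelength_nm = c(330, 350), I0 = c(800, 1000),
                   I100 = c(1500, 1900))
  tab <- simulate_partition_titration(20, c(0, 50, 200), ep,
                                      noise_cv = 0, seed = 1)
  at <- function(wl, cl) tab$intensity[tab$wavelength_nm == wl &
                                         tab$lipid_uM == cl]
  expect_equal(at(330, 0), 800)
  expect_equal(at(350, 0), 1000)
  expect_equal(at(330, 200), (10 / 11) * 1500 + (1 / 11) * 800)
  expect_error(simulate_partition_titration(-5, c(0, 10), ep), "positive")
  expect_error(simulate_partition_titration(20, c(10, 20), ep),
               "include 0")
  # seeded determinism of the noisy generator
  a <- simulate_partition_titration(20, c(0, 15, 30), ep, 0.02, seed = 9)
  b <- simulate_partition_titration(20, c(0, 15, 30), ep, 0.02, seed = 9)
  expect_identical(a, b)
})
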