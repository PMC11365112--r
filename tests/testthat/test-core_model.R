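test_that("multi-exponential intensity matches hand-evaluated values", {
  m1 <- multiexp_model(1, 2)
  expect_equal(multiexp_intensity(m1, 0), 1)
  expect_equal(multiexp_intensity(m1, 2), exp(-1))
  m2 <- multiexp_model(c(2, 1), c(1, 4))
  expect_equal(multiexp_intensity(m2, 1), 2 * exp(-1) + exp(-0.25))
  expect_equal(multiexp_intensity(m2, 0), 3)
  # strictly decreasing
  t <- seq(0, 10, 0.1)
  expect_true(all(diff(multiexp_intensity(m2, t)) < 0))
  expect_error(multiexp_intensity(m2, -1), "non-negative")
})

test_that("model constructors enforce their invariants", {
  expect_error(multiexp_model(c(1, 1), c(1, -2)), "positive")
  expect_error(multiexp_model(c(-1, 1), c(1, 2)), "non-negative")
  expect_error(multiexp_model(c(0, 0), c(1, 2)), "positive")
  expect_error(multiexp_model(rep(1, 4), rep(1, 4)), "3 components")
  # lifetimes stored sorted
  m <- multiexp_model(c(1, 2), c(4, 1))
  expect_equal(m$lifetimes, c(1, 4))
  expect_equal(m$amplitudes, c(2, 1))
  expect_error(relaxation_model(-1, 1, 2e4), "non-negative")
  expect_error(relaxation_model(100, 0, 2e4), "positive")
  expect_error(anisotropy_model(0.1, -1, 0.05), "positive")
  expect_error(anisotropy_model(0.1, 1, 0.9), "r_inf")
  expect_warning(anisotropy_model(0.38, 1, 0.1), "one-photon")
})

test_that("amplitude-averaged lifetime is the amplitude-weighted mean", {
  expect_equal(amplitude_avg_lifetime(multiexp_model(1, 3)), 3)
  expect_equal(amplitude_avg_lifetime(multiexp_model(c(0.5, 0.5), c(1, 3))), 2)
  expect_equal(amplitude_avg_lifetime(multiexp_model(c(2, 1), c(1, 4))), 2)
  # invariant to uniform amplitude rescaling
  m <- multiexp_model(c(0.3, 0.5, 0.2), c(0.5, 2, 5))
  m2 <- multiexp_model(m$amplitudes * 7.3, m$lifetimes)
  expect_equal(amplitude_avg_lifetime(m), amplitude_avg_lifetime(m2))
})

test_that("polarizer factor reproduces the printed special cases", {
  for (G in c(0.5, 1, 1.2, 2, 5)) {
    expect_equal(polarizer_factor(0, G), 1)
    expect_equal(polarizer_factor(90, G), 1 / G)
    expect_equal(polarizer_factor(magic_angle(), G), (2 + G) / (3 * G))
  }
  expect_error(polarizer_factor(30, 0), "positive")
  expect_error(polarizer_factor(30, -1), "positive")
})

test_that("polarized intensity matches hand evaluation and magic angle", {
  m <- multiexp_model(1, 3)
  an <- anisotropy_model(B = 0.2, phi = 1, r_inf = 0.1, G = 1)
  expect_equal(polarized_intensity(m, an, 0, 0), 1.6)
  expect_equal(polarized_intensity(m, an, 90, 0), 0.7)
  # magic-angle independence over random parameter sets
  set.seed(42)
  t <- seq(0, 20, 0.5)
  for (i in 1:100) {
    mm <- multiexp_model(stats::runif(2, 0.1, 2), sort(stats::runif(2, 0.3, 6)))
    aa <- anisotropy_model(B = stats::runif(1, 0, 0.25),
                           phi = stats::runif(1, 0.2, 8),
                           r_inf = stats::runif(1, 0, 0.1),
                           G = stats::runif(1, 0.8, 1.5))
    expect_equal(polarized_intensity(mm, aa, magic_angle(), t) /
                   polarizer_factor(magic_angle(), aa$G),
                 multiexp_intensity(mm, t), tolerance = 1e-12)
  }
})

test_that("VV/VH construction identity recovers the anisotropy decay", {
  m <- multiexp_model(c(0.5, 0.5), c(1, 4))
  an <- anisotropy_model(B = 0.18, phi = 2.3, r_inf = 0.07, G = 1.3)
  t <- seq(0, 25, 0.05)
  Ivv <- polarized_intensity(m, an, 0, t)
  Ivh <- polarized_intensity(m, an, 90, t)
  r_t <- construct_anisotropy_decay(Ivv, Ivh, G = an$G)
  expect_lt(max(abs(r_t - (an$B * exp(-t / an$phi) + an$r_inf))), 1e-9)
})

test_that("relaxation curve has the right endpoints and hand value", {
  rm <- relaxation_model(C = 1000, t_relax = 2, nu_inf = 29000)
  expect_equal(relaxation_curve(rm, 0), 30000)
  expect_equal(relaxation_curve(rm, 2), 29000 + 1000 / exp(1))
  expect_equal(relaxation_curve(rm, 1e6), 29000)
  t <- seq(0, 50, 0.5)
  expect_true(all(diff(relaxation_curve(rm, t)) <= 0))
})

test_that("IRF convolution is causal, conserving, and delta-exact", {
  g <- time_grid(0, 0.05, 512L)
  t <- grid_times(g)
  curve <- multiexp_intensity(multiexp_model(1, 2), t)
  # delta at bin 0 (degenerate-width Gaussian at t = 0): identity
  d0 <- make_gaussian_irf(1e-9, center = 0, grid = g)
  expect_equal(convolve_with_irf(curve, d0), curve, tolerance = 1e-12)
  # delta at bin k: delay by k bins, zero-padded in front
  counts <- numeric(512); counts[21] <- 5
  dk <- instrument_response(g, counts)
  out <- convolve_with_irf(curve, dk)
  expect_equal(out[21:512], curve[1:492], tolerance = 1e-9)
  expect_equal(out[1:20], rep(0, 20), tolerance = 1e-9)
  # sum conservation when the support fits the grid
  irf <- make_gaussian_irf(0.25, center = 2, grid = g)
  short <- multiexp_intensity(multiexp_model(1, 1), t)  # dies by ~15 ns
  conv <- convolve_with_irf(short, irf)
  expect_lt(abs(sum(conv) - sum(short)) / sum(short), 1e-9)
  # unit-sum kernel preserves a constant curve over the interior
  const <- rep(1, 512)
  ci <- convolve_with_irf(const, irf)
  expect_equal(ci[100:500], rep(1, 401), tolerance = 1e-9)
  expect_error(convolve_with_irf(curve[1:100], irf), "share one time grid")
})
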