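# Shared small fixtures: a coarse grid keeps reconvolution fits fast
# while still resolving the 0.25-ns IRF.

test_grid <- function(n_bins = 1024L, t_max = 50)
  time_grid(0, t_max / n_bins, n_bins)

test_irf <- function(grid = test_grid()) default_irf(grid)

# Noise-free decay histogram: law evaluated on the grid, convolved with
# the IRF, scaled to `peak` and rounded (quantization ~0.5 counts).
noisefree_histogram <- function(model, grid, irf, peak = 1e7,
                                meta = list()) {
  t <- grid_times(grid)
  curve <- convolve_with_irf(multiexp_intensity(model, t - t[1]), irf)
  decay_histogram(grid, round(curve / max(curve) * peak), meta)
}

# Homogeneous-relaxation scenario with a chosen membrane relaxation law.
relax_scenario <- function(t_relax, C = 0.8e3, nu_inf = 28.70e3,
                           hetero = 0, t_slow = 10) {
  sc <- scenario_from_table("V4W")
  sc$hetero_fraction <- hetero
  sc$t_relax_slow <- t_slow
  sc$relax_m <- relaxation_model(C, t_relax, nu_inf)
  sc
}

tres_wavelengths <- seq(300, 420, 8)
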