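# Shared fixtures for the test suite.

ref_si <- si_params()                      # alpha = pi, aspect ratio 2
ref_pool <- pooling_params(0.24, 0.85, 0.54)

# Small deterministic sheet reused across tests (cheap to build once).
ref_sheet <- make_cortical_sheet(nx = 100L, ny = 70L, pixel_um = 10,
                                 seed = 42L)

# Population generator under the standard study conditions.
make_pop <- function(n = 100, scatter = 0.2, f1f0_noise = 0.15, seed = 1,
                     sheet = ref_sheet, pool = ref_pool) {
  sample_population(sheet, pool, ref_si, n_cells = n, scatter_sd = scatter,
                    f1f0_noise_sd = f1f0_noise, seed = seed)
}

# Direct log-normal fo sample matching the calibrated marginals, for
# estimator tests that do not need the spatial maps.
draw_fo <- function(n, seed, mean_log2 = 0.95, sd_log2 = 0.64) {
  set.seed(seed)
  2^(mean_log2 + sd_log2 * rnorm(n))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
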