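# Shared fixtures, built in code and memoized per test file.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small but realistic simulated set: 10 subjects, 8 in-range clusters,
# 1024 points over 3-8 kDa
small_sim <- function() memo("small_sim", {
  cl <- default_clusters(8)
  cl$center_mz <- seq(3350, 7650, length.out = 8) *
    (1 + 0.003 * sin(1:8 * 2.3))
  cfg <- sim_config(n_points = 1024, mz_range = c(3000, 8000),
                    clusters = cl, n_spectra = 10, seed = 42)
  simulate_spectrum_set(cfg)
})

# a flat-noise spectrum on a simple grid
noise_spectrum <- function(n = 512, sd = 1, seed = 1, stage = "raw") {
  set.seed(seed)
  s <- spectrum(seq(1000, 2000, length.out = n), rnorm(n, 0, sd))
  s$stage <- stage
  s
}

# Gaussian bump helper
gauss_bump <- function(grid, center, height, sigma)
  height * exp(-0.5 * ((grid - center) / sigma)^2)
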