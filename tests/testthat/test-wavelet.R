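# wavelet_denoise: filter construction, sparse operator vs cascade
# oracle, cache behavior, shrinkage, cycle spinning

test_that("Daubechies filters are orthonormal with vanishing moments", {
  for (p in c(2, 4, 8)) {
    h <- daubechies_filter(p)
    expect_length(h, 2 * p)
    expect_equal(sum(h), sqrt(2), tolerance = 1e-10)
    expect_equal(sum(h^2), 1, tolerance = 1e-10)
    for (k in seq_len(p - 1))
      expect_lt(abs(sum(h[1:(2 * p - 2 * k)] * h[(2 * k + 1):(2 * p)])), 1e-10)
    g <- seldiproc:::quadrature_mirror(h)
    for (m in 0:(p - 1))
      expect_lt(abs(sum((seq_along(g) - 1)^m * g)), 1e-6)
  }
})

test_that("operator is orthonormal and equals the cascade oracle", {
  for (n in c(256, 1024)) {
    op <- wavelet_operator(n, p = 8, cache_dir = FALSE)
    set.seed(n)
    h <- daubechies_filter(8)
    for (rep in 1:3) {
      y <- rnorm(n)
      wy <- as.numeric(op$W %*% y)
      expect_lt(abs(sqrt(sum(wy^2)) - sqrt(sum(y^2))) / sqrt(sum(y^2)), 1e-8)
      expect_lt(max(abs(wy - oracle_dwt_cascade(y, h, op$levels))), 1e-10)
    }
    # sparsity claim for large operators
    if (n >= 1024)
      expect_gt(1 - length(op$W@x) / as.numeric(n)^2, 0.9)
  }
  expect_error(wavelet_operator(100), "power of 2")
})

test_that("warm cache returns a bit-identical operator", {
  cache <- withr::local_tempdir()
  op1 <- wavelet_operator(256, p = 4, cache_dir = cache)
  expect_true(file.exists(op1$cache_file))
  op2 <- wavelet_operator(256, p = 4, cache_dir = cache)
  expect_identical(op1$W, op2$W)
})

test_that("shrinkage kills pure noise but preserves tall peaks", {
  # deep decomposition: the untouched approximation band holds only
  # 4096/2^8 = 16 coefficients, so thresholding must remove >95% of the
  # energy of pure noise
  op_deep <- wavelet_operator(4096, levels = 8, cache_dir = FALSE)
  expect_equal(denoise_shrink(numeric(4096), op_deep), numeric(4096))
  ratios <- vapply(1:20, function(seed) {
    set.seed(seed)
    y <- rnorm(4096)
    d <- denoise_shrink(y, op_deep)
    sum(d^2) / sum(y^2)
  }, 0)
  expect_lt(max(ratios), 0.05)
  # at the default shallow depth the approx band (1/16 of coefficients)
  # is the only survivor of pure noise
  op <- wavelet_operator(4096, cache_dir = FALSE)
  set.seed(99)
  y <- rnorm(4096)
  expect_lt(sum(denoise_shrink(y, op)^2) / sum(y^2), 0.10)

  grid <- seq_len(4096)
  peak <- gauss_bump(grid, 2048, 50, 40)   # apex 50 sigma in unit noise
  d <- denoise_shrink(peak, op)
  expect_lt(abs(max(d) - 50) / 50, 0.15)
})

test_that("single-shift cycle spin equals plain shrinkage", {
  op <- wavelet_operator(256, cache_dir = FALSE)
  set.seed(4)
  y <- rnorm(256)
  expect_equal(cycle_spin(y, op, q = NULL, shifts = c(0L)),
               denoise_shrink(y, op))
  expect_error(cycle_spin(y, op, shifts = integer()), "empty")
  expect_error(cycle_spin(y, op, shifts = c(0L, 0L)), "distinct")
})

test_that("full-shift cycle spinning is translation-equivariant at n=64", {
  n <- 64
  op <- wavelet_operator(n, p = 4, levels = 2, cache_dir = FALSE)
  set.seed(6)
  y <- rnorm(n) + gauss_bump(seq_len(n), 32, 10, 3)
  full <- cycle_spin(y, op, q = NULL, shifts = 0:(n - 1))
  rot <- function(x, k) seldiproc:::circshift(x, k)
  for (k in c(1, 7, 31, 63)) {
    lhs <- cycle_spin(rot(y, k), op, q = NULL, shifts = 0:(n - 1))
    expect_lt(max(abs(lhs - rot(full, k))), 1e-10)
  }
})

test_that("cycle spinning reduces artifact energy near a step", {
  n <- 256
  op <- wavelet_operator(n, p = 8, levels = 3, cache_dir = FALSE)
  step <- c(rep(0, 128), rep(8, 128))
  set.seed(13)
  y <- step + rnorm(n)
  single <- denoise_shrink(y, op)
  spun <- cycle_spin(y, op, q = NULL, shifts = 32)
  # pseudo-Gibbs energy: squared error in a window around the edge
  win <- 113:144
  expect_lte(sum((spun[win] - step[win])^2),
             sum((single[win] - step[win])^2))
})

test_that("QVF-aware denoising reduces RMSE on simulated spectra", {
  cfg <- sim_config(n_spectra = 4, seed = 7)   # default stated world
  sim <- simulate_spectrum_set(cfg)
  q <- qvf(cfg$qvf[1], cfg$qvf[2], cfg$qvf[3])
  grid <- sim$set$common_grid
  op <- wavelet_operator(length(grid), cache_dir = FALSE)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  for (i in 1:4) {
    s <- sim$set$spectra[[i]]
    clean <- cfg$baseline$amplitude *
      exp(-(grid - cfg$mz_range[1]) / cfg$baseline$decay)
    pk <- sim$truth$peaks[sim$truth$peaks$subject == s$subject, ]
    for (j in seq_len(nrow(pk)))
      clean <- clean + gauss_bump(grid, pk$mz[j], pk$height[j],
                                  cfg$width_coeff * pk$mz[j])
    single <- denoise_spectrum(s, q = q, shifts = 1, op = op)
    spun <- denoise_spectrum(s, q = q, shifts = 16, op = op)
    expect_lt(rmse(spun$intensity, clean), rmse(s$intensity, clean))
    # averaging over shifts does not hurt the estimate
    expect_lt(rmse(spun$intensity, clean),
              rmse(single$intensity, clean) * 1.02)
  }
})

test_that("padding round-trips non-dyadic lengths", {
  s <- spectrum(seq(1000, 2000, length.out = 1000),
                rnorm(1000) + gauss_bump(seq(1000, 2000, length.out = 1000),
                                         1500, 30, 20))
  s$stage <- "normalized"
  d <- denoise_spectrum(s, q = NULL, shifts = 4, cache_dir = FALSE)
  expect_length(d$intensity, 1000)
  expect_equal(d$stage, "denoised")
})
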