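# peaks: detection, quantification, clustering, reproducibility rule,
# benchmark metrics

mk_stage <- function(mz, y, stage = "denoised", id = "s1") {
  s <- spectrum(mz, y, id = id)
  s$stage <- stage
  s
}

test_that("local maxima with plateau and valley rules", {
  tri <- mk_stage(1:3, c(0, 1, 0))
  pk <- detect_local_maxima(tri)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$mz, 2)
  expect_equal(pk$left_mz, 1); expect_equal(pk$right_mz, 3)

  plat <- detect_local_maxima(mk_stage(1:4, c(0, 1, 1, 0)))
  expect_equal(plat$mz, 2)   # left-of-center on even plateaus

  expect_equal(nrow(detect_local_maxima(mk_stage(1:5, rep(1, 5)))), 0)
  expect_error(detect_local_maxima(spectrum(1:3, c(0, 1, 0))), "denoised")

  # min_height filters
  two <- mk_stage(1:7, c(0, 5, 0, 0, 2, 0, 0))
  expect_equal(nrow(detect_local_maxima(two, min_height = 3)), 1)

  # planted well-separated Gaussians on a smooth (denoised-like) trace
  # recovered at the right apexes
  grid <- seq(1000, 2000, length.out = 2048)
  centers <- c(1150, 1350, 1500, 1700, 1900)
  y <- rowSums(vapply(centers, function(cc) gauss_bump(grid, cc, 20, 8),
                      numeric(2048)))
  y <- y + 0.2 * sin(grid / 3)   # low-amplitude smooth ripple
  s <- mk_stage(grid, y)
  pk <- detect_local_maxima(s, min_height = 5)
  expect_equal(nrow(pk), 5)
  for (cc in centers)
    expect_lte(min(abs(pk$mz - cc)), diff(grid)[1])
})

test_that("quantification matches analytic areas and survives smoothing", {
  # unit triangle, base 2 Da, zero valleys: area 1, height 1
  grid <- seq(0, 10, by = 0.25)
  y <- pmax(0, 1 - abs(grid - 5))
  s <- mk_stage(grid, y, "smoothed")
  pk <- data.frame(spectrum_id = "s1", mz = 5, height = NA_real_,
                   area = NA_real_, left_mz = 4, right_mz = 6,
                   apex_idx = which(grid == 5))
  out <- quantify_peak(s, pk)
  expect_equal(out$height, 1)
  expect_equal(out$area, 1)

  # valley-chord subtraction removes a linear ramp exactly
  ramp <- 0.7 * grid + 2
  s2 <- mk_stage(grid, y + ramp, "smoothed")
  out2 <- quantify_peak(s2, pk)
  expect_equal(out2$area, 1, tolerance = 1e-9)

  # planted Gaussian after default FIR smoothing: height within 5%
  grid <- seq(1000, 3000, length.out = 1024)
  step <- diff(grid)[1]
  y <- gauss_bump(grid, grid[512], 10, 5 * step)
  sm <- zero_phase_filter({
    s <- spectrum(grid, y); s$stage <- "normalized"; s
  }, design_quant_filter())
  pk <- detect_local_maxima(sm, min_height = 1)
  pk <- quantify_peak(sm, pk)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$height - 10) / 10, 0.05)

  bad <- pk; bad$left_mz <- bad$right_mz + 1
  expect_error(quantify_peak(sm, bad), "inverted")
})

test_that("clustering matches the pairwise-linkage oracle and is order-free", {
  set.seed(33)
  for (rep in 1:5) {
    centers <- sort(runif(8, 1000, 5000))
    mz <- unlist(lapply(centers, function(cc)
      cc * (1 + runif(sample(3:20, 1), -0.001, 0.001))))
    n <- length(mz)
    pool <- data.frame(spectrum_id = paste0("s", seq_len(n)), mz = mz,
                       height = 1, area = 1, left_mz = mz - 1,
                       right_mz = mz + 1, apex_idx = seq_len(n))
    cl <- cluster_peaks(pool, n_spectra = n, tolerance_frac = 0.003)
    oc <- oracle_cluster(mz, 0.003)
    # identical partitions (every peak kept: distinct spectrum ids)
    got <- cl$members[order(cl$members$mz), "cluster_id"]
    want <- oc[order(mz)]
    expect_equal(as.integer(factor(got, levels = unique(got))),
                 as.integer(factor(want, levels = unique(want))))
    # order invariance
    perm <- sample.int(n)
    cl2 <- cluster_peaks(pool[perm, ], n_spectra = n, tolerance_frac = 0.003)
    expect_equal(cl2$clusters$mean_mz, cl$clusters$mean_mz)
    # tolerance invariant: members within tolerance of cluster mean
    for (g in cl$clusters$cluster_id) {
      mem <- cl$members$mz[cl$members$cluster_id == g]
      m <- cl$clusters$mean_mz[cl$clusters$cluster_id == g]
      expect_true(all(abs(mem - m) <= 0.003 * m * 1.5))
    }
  }

  # jittered single cluster and clearly separated pair
  one <- data.frame(spectrum_id = paste0("s", 1:10),
                    mz = 1000 * (1 + runif(10, -0.001, 0.001)),
                    height = 1, area = 1, left_mz = 0, right_mz = 2000,
                    apex_idx = 1)
  c1 <- cluster_peaks(one, n_spectra = 10)
  expect_equal(nrow(c1$clusters), 1)
  expect_equal(c1$clusters$mean_mz, 1000, tolerance = 1e-3 * 1000)
  two <- rbind(one, within(one, mz <- mz * 1.01))
  two$spectrum_id <- paste0("s", 1:20)
  expect_equal(nrow(cluster_peaks(two, n_spectra = 20)$clusters), 2)

  # one peak per spectrum within a cluster
  dup <- data.frame(spectrum_id = rep("s1", 3),
                    mz = c(1000, 1000.5, 1001), height = 1, area = 1,
                    left_mz = 0, right_mz = 2000, apex_idx = 1)
  cd <- cluster_peaks(dup, n_spectra = 1)
  expect_equal(nrow(cd$members), 1)
  expect_equal(cd$clusters$prevalence, 1)
})

test_that("the 80% prevalence rule keeps 24/30 and rejects 23/30", {
  mk_cl <- function(k, n) {
    pool <- data.frame(spectrum_id = paste0("s", seq_len(k)),
                       mz = 5000 * (1 + runif(k, -5e-4, 5e-4)),
                       height = 1, area = 1, left_mz = 0, right_mz = 1e4,
                       apex_idx = 1)
    cluster_peaks(pool, n_spectra = n)
  }
  set.seed(4)
  expect_equal(nrow(reproducible_clusters(mk_cl(24, 30))$clusters), 1)
  expect_equal(mk_cl(24, 30)$clusters$prevalence, 0.8)
  expect_equal(nrow(reproducible_clusters(mk_cl(23, 30))$clusters), 0)
  full <- mk_cl(30, 30)
  expect_equal(reproducible_clusters(full)$clusters$prevalence, 1)
})

test_that("benchmark counts follow the sensitivity/FDR definitions", {
  perfect <- benchmark_sens_fdr(c(1000, 2000), c(1000.5, 2001))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$fdr, 0)

  # 7 matched, 3 unmatched predictions, 1 missed truth
  truth <- seq(1000, 8000, length.out = 8)
  pred <- c(truth[1:7] * 1.0005, 1500, 4600, 9500)
  b <- benchmark_sens_fdr(pred, truth)
  expect_equal(b$tp, 7L); expect_equal(b$fp, 3L); expect_equal(b$fn, 1L)
  expect_equal(b$sensitivity, 7 / 8)
  expect_equal(b$fdr, 0.3)

  z <- benchmark_sens_fdr(numeric(), truth)
  expect_equal(z$sensitivity, 0)
  expect_equal(z$fdr, 0)
  expect_true(z$degenerate)
})

test_that("sensitivity does not decrease with planted peak SNR", {
  sens_at <- function(hmul) {
    cfg <- sim_config(n_points = 2048, n_spectra = 8,
                      clusters = within(default_clusters(10),
                                        height <- height * hmul),
                      seed = 55)
    sim <- simulate_spectrum_set(cfg)
    res <- run_pipeline(sim$set)
    truth <- sim$truth$clusters
    benchmark_sens_fdr(res$reproducible,
                       truth$center_mz[truth$prevalence_realized >= 0.8]
                       )$sensitivity
  }
  lo <- sens_at(0.15); hi <- sens_at(1)
  expect_lte(lo, hi)
})
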