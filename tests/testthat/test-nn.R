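# nn_validator: forward/cost/gradient oracles, CG training, lambda
# selection, splitting, accuracy, cluster validation

test_that("forward pass matches the hand-unrolled oracle", {
  set.seed(50)
  m <- nn_model(d = 7, hidden = 5, seed = 50)
  for (rep in 1:5) {
    x <- rnorm(7)
    expect_equal(nn_forward(m, x),
                 oracle_nn_forward(m$theta1, m$theta2, x),
                 tolerance = 1e-12)
  }
  zero <- m
  zero$theta1[] <- 0; zero$theta2[] <- 0
  expect_equal(nn_forward(zero, rnorm(7)), 0.5)
  # monotone in the output bias
  up <- m; up$theta2[1, 1] <- m$theta2[1, 1] + 50
  expect_gt(nn_forward(up, rnorm(7)), nn_forward(m, rnorm(7)))
  expect_error(nn_forward(m, rnorm(9)), "dimension")
})

test_that("cost matches closed forms and the loop oracle", {
  m <- nn_model(d = 4, hidden = 3, lambda = 0, seed = 2)
  m$theta1[] <- 0; m$theta2[] <- 0
  expect_equal(nn_cost(m, matrix(rnorm(4), 1), 1), log(2), tolerance = 1e-12)

  set.seed(51)
  m <- nn_model(d = 4, hidden = 3, lambda = 0, seed = 51)
  X <- matrix(rnorm(10 * 4), 10)
  t <- rbinom(10, 1, 0.5)
  J0 <- nn_cost(m, X, t)
  expect_equal(J0, oracle_nn_cost(m$theta1, m$theta2, X, t, 0),
               tolerance = 1e-10)
  mr <- m; mr$lambda <- 0.7
  expect_equal(nn_cost(mr, X, t),
               J0 + 0.7 / 20 * (sum(m$theta1[, -1]^2) + sum(m$theta2[, -1]^2)),
               tolerance = 1e-12)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(52)
  for (lambda in c(0, 0.5)) {
    m <- nn_model(d = 6, hidden = 4, lambda = lambda, seed = 52)
    X <- matrix(rnorm(12 * 6), 12)
    t <- rbinom(12, 1, 0.5)
    g <- nn_gradient(m, X, t)
    gv <- c(as.numeric(g$theta1), as.numeric(g$theta2))
    par <- c(as.numeric(m$theta1), as.numeric(m$theta2))
    h <- 1e-5
    coords <- sample(seq_along(par), 20)
    for (j in coords) {
      pp <- par; pp[j] <- pp[j] + h
      pm <- par; pm[j] <- pm[j] - h
      fd <- (nn_cost(seldiproc:::unflatten(m, pp), X, t) -
               nn_cost(seldiproc:::unflatten(m, pm), X, t)) / (2 * h)
      expect_equal(gv[j], fd, tolerance = 1e-6)
    }
    # regularization contributes exactly (lambda/m) * weight off-bias
    if (lambda > 0) {
      m0 <- m; m0$lambda <- 0
      g0 <- nn_gradient(m0, X, t)
      expect_equal(g$theta1[, -1] - g0$theta1[, -1],
                   lambda / 12 * m$theta1[, -1], tolerance = 1e-12)
      expect_equal(g$theta1[, 1], g0$theta1[, 1])   # bias unpenalized
    }
  }
})

test_that("CG training solves a separable toy and is deterministic", {
  set.seed(53)
  n <- 60
  X <- matrix(0, n, 62)
  t <- rep(c(0, 1), n / 2)
  X[, 1] <- ifelse(t == 1, 1, -1) + rnorm(n, 0, 0.1)
  X[, 2] <- rnorm(n)
  m1 <- nn_train(X, t, lambda = 0, max_iter = 400, seed = 7)
  expect_equal(evaluate_accuracy(m1, X, t), 1)
  # J non-increasing over accepted steps
  expect_true(all(diff(m1$trace) <= 1e-12))
  # determinism
  m2 <- nn_train(X, t, lambda = 0, max_iter = 400, seed = 7)
  expect_identical(m1$theta1, m2$theta1)
  expect_identical(m1$theta2, m2$theta2)
  # near-stationary at the solution
  g <- nn_gradient(m1, X, t)
  expect_lt(sqrt(sum(unlist(g)^2)), 1e-3)
})

test_that("split_data gives exact 50/25/25 counts and is seed-stable", {
  sp <- split_data(100, seed = 3)
  expect_equal(as.integer(table(sp)), c(50L, 25L, 25L))
  expect_identical(sp, split_data(100, seed = 3))
  expect_false(identical(sp, split_data(100, seed = 4)))
  sp2 <- split_data(101, seed = 3)
  expect_equal(sum(table(sp2)), 101)
  expect_error(split_data(3), "m >= 4")

  # label balance within 4 binomial s.d. of the overall rate
  set.seed(9)
  t <- rbinom(400, 1, 0.57)
  sp3 <- split_data(400, seed = 5)
  for (lv in levels(sp3)) {
    n <- sum(sp3 == lv)
    expect_lt(abs(mean(t[sp3 == lv]) - mean(t)),
              4 * sqrt(0.57 * 0.43 / n))
  }
})

test_that("accuracy threshold convention counts p = 0.5 as class 1", {
  m <- nn_model(d = 3, hidden = 2, seed = 1)
  m$theta1[] <- 0; m$theta2[] <- 0   # constant p = 0.5
  X <- matrix(rnorm(20 * 3), 20)
  t <- rbinom(20, 1, 0.4)
  expect_equal(evaluate_accuracy(m, X, t), mean(t == 1))
  # matches the loop oracle
  set.seed(54)
  m2 <- nn_model(d = 3, hidden = 2, seed = 54)
  acc <- mean(vapply(seq_len(20), function(i)
    (oracle_nn_forward(m2$theta1, m2$theta2, X[i, ]) >= 0.5) == (t[i] == 1),
    TRUE))
  expect_equal(evaluate_accuracy(m2, X, t), acc)
})

test_that("lambda selection prefers less regularization when it must", {
  set.seed(55)
  n <- 120
  X <- matrix(rnorm(n * 62, 0, 0.3), n, 62)
  t <- rep(c(0, 1), n / 2)
  X[, 1] <- X[, 1] + ifelse(t == 1, 1.2, -1.2)
  sp <- split_data(n, seed = 2)
  grid <- c(0.01, 10000)   # absurd upper end forces underfitting
  sel <- select_lambda(X, t, sp, grid = grid, max_iter = 100, seed = 3)
  expect_lt(sel$lambda, max(grid))
  expect_equal(sel$model$lambda, sel$lambda)
  one <- select_lambda(X, t, sp, grid = 0.3, max_iter = 30, seed = 3)
  expect_equal(one$lambda, 0.3)
  # default grid covers the documented range
  g <- lambda_grid()
  expect_length(g, 13)
  expect_equal(range(g), c(0.003, 10))
})

test_that("cluster validation with an oracle-sharp validator", {
  # plant one cluster in 15 of 16 spectra; validator = strongly biased
  # network that accepts anything peak-shaped via the concavity feature
  set.seed(56)
  grid <- seq(2900, 3150, length.out = 512)
  n <- 16
  present <- c(rep(TRUE, 15), FALSE)
  spectra <- lapply(seq_len(n), function(i) {
    y <- 2 + 0.05 * sin(grid)
    if (present[i]) y <- y + gauss_bump(grid, 3017, 30, 6)
    s <- spectrum(grid, y, id = sprintf("s%02d", i))
    s$stage <- "smoothed"
    s
  })
  proc <- spectrum_set(spectra, common_grid = grid)
  raw <- spectrum_set(lapply(spectra, function(s) {
    r <- s; r$stage <- "raw"; r
  }), common_grid = grid)
  # train a tiny validator on features from this construction
  feats <- list(); labs <- integer()
  for (i in seq_len(n)) {
    x_pos <- tryCatch(extract_features(raw$spectra[[i]], proc$spectra[[i]],
                                       3017, 0.003), error = function(e) NULL)
    if (present[i] && !is.null(x_pos)) {
      feats[[length(feats) + 1]] <- x_pos; labs <- c(labs, 1L)
    }
    x_neg <- extract_features(raw$spectra[[i]], proc$spectra[[i]],
                              3100, 0.003)
    feats[[length(feats) + 1]] <- x_neg; labs <- c(labs, 0L)
  }
  Xf <- do.call(rbind, feats)
  sc <- fit_scaler(Xf)
  model <- nn_train(apply_scaler(Xf, sc), labs, lambda = 0.01,
                    max_iter = 200, seed = 8, scaler = sc)
  out <- validate_cluster(raw, proc, 3017, model, window_frac = 0.003)
  expect_equal(out$prevalence, 15 / 16)   # the printed 0.938 analog
  expect_equal(nrow(out$members), 15)
  expect_lte(max(table(out$members$spectrum_id)), 1)
  expect_true(all(out$members$prob >= 0.5))
  # a window with no maxima contributes nothing
  flat <- spectrum_set(lapply(seq_len(4), function(i) {
    s <- spectrum(grid, seq(1, 2, length.out = 512), id = paste0("f", i))
    s$stage <- "smoothed"
    s
  }), common_grid = grid)
  flat_raw <- spectrum_set(lapply(flat$spectra, function(s) {
    r <- s; r$stage <- "raw"; r
  }), common_grid = grid)
  out2 <- validate_cluster(flat_raw, flat, 3017, model)
  expect_equal(out2$prevalence, 0)
})
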