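# Feed-forward neural-network peak validator: one sigmoid hidden layer,
# regularized cross-entropy objective, backpropagation gradient,
# Polak-Ribiere conjugate-gradient training with a strong-Wolfe line
# search, lambda selection by validation error, and the 4-step cluster
# validation procedure.

sigmoid <- function(z) 1 / (1 + exp(-z))

EPS_P <- 1e-12  # probability clipping in the log-loss

#' Construct or initialize the network
#'
#' Topology: 62 inputs + bias (63 input nodes), 20 sigmoid hidden units +
#' bias (21 hidden nodes), 1 sigmoid output. `theta1` is
#' `hidden x (d + 1)`, `theta2` is `1 x (hidden + 1)`; the first column of
#' each holds the bias weights. Weights are initialized uniformly in
#' `(-eps, eps)` with `eps = sqrt(6) / sqrt(fan_in + fan_out)`.
#'
#' @param d input dimension (default 62).
#' @param hidden hidden units excluding bias (default 20).
#' @param lambda regularization weight.
#' @param scaler optional `FeatureScaler` stored with the model.
#' @param seed RNG seed for the initial weights.
#' @return object of class `"NNModel"`.
#' @export
nn_model <- function(d = 62, hidden = 20, lambda = 0, scaler = NULL,
                     seed = 1) {
  set.seed(seed)
  e1 <- sqrt(6) / sqrt(d + 1 + hidden)
  e2 <- sqrt(6) / sqrt(hidden + 2)
  structure(list(
    theta1 = matrix(stats::runif(hidden * (d + 1), -e1, e1), hidden, d + 1),
    theta2 = matrix(stats::runif(hidden + 1, -e2, e2), 1, hidden + 1),
    d = d, hidden = hidden, lambda = lambda, scaler = scaler, seed = seed,
    trace = NULL), class = "NNModel")
}

#' @export
print.NNModel <- function(x, ...) {
  cat(sprintf("<NNModel> %d-%d-1 (+bias), lambda=%g%s\n", x$d, x$hidden,
              x$lambda, if (is.null(x$trace)) "" else
                sprintf(", trained %d iters, J=%.5f",
                        length(x$trace) - 1, min(x$trace))))
  invisible(x)
}

#' Forward pass
#'
#' `p = sigmoid(theta2 %*% c(1, sigmoid(theta1 %*% c(1, x))))`, vectorized
#' over the rows of a matrix. Inputs must already be standardized with the
#' model's scaler statistics.
#'
#' @param model an `NNModel`.
#' @param X standardized feature vector (length `d`) or matrix
#'   (`m x d`).
#' @return probability vector in `(0, 1)`.
#' @export
nn_forward <- function(model, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != model$d) stop("feature dimension mismatch")
  A1 <- cbind(1, X)
  Z2 <- tcrossprod(A1, model$theta1)
  A2 <- cbind(1, sigmoid(Z2))
  as.numeric(sigmoid(tcrossprod(A2, model$theta2)))
}

#' Regularized cross-entropy cost and its gradient
#'
#' `J = -(1/m) * sum(t*log(p) + (1-t)*log(1-p))
#'    + (lambda/(2m)) * sum(non-bias weights^2)`;
#' bias columns are excluded from the penalty. Probabilities are clipped
#' to `[1e-12, 1 - 1e-12]` inside the logs. The gradient is the exact
#' analytic backpropagation gradient of this objective.
#'
#' @param model an `NNModel`.
#' @param X standardized feature matrix (`m x d`).
#' @param t 0/1 labels of length `m`.
#' @return `nn_cost()`: scalar J. `nn_gradient()`: list with `theta1` and
#'   `theta2` gradient matrices.
#' @export
nn_cost <- function(model, X, t) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  m <- nrow(X)
  p <- pmin(pmax(nn_forward(model, X), EPS_P), 1 - EPS_P)
  J <- -mean(t * log(p) + (1 - t) * log(1 - p))
  if (model$lambda > 0)
    J <- J + model$lambda / (2 * m) *
      (sum(model$theta1[, -1]^2) + sum(model$theta2[, -1]^2))
  J
}

#' @rdname nn_cost
#' @export
nn_gradient <- function(model, X, t) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  m <- nrow(X)
  A1 <- cbind(1, X)                         # m x (d+1)
  Z2 <- tcrossprod(A1, model$theta1)        # m x hidden
  A2 <- cbind(1, sigmoid(Z2))               # m x (hidden+1)
  p <- as.numeric(sigmoid(tcrossprod(A2, model$theta2)))
  d3 <- p - t                               # m x 1 output delta
  g2 <- crossprod(matrix(d3, ncol = 1), A2) / m         # 1 x (hidden+1)
  d2 <- (d3 %o% as.numeric(model$theta2[, -1])) *
    (A2[, -1, drop = FALSE] * (1 - A2[, -1, drop = FALSE]))  # m x hidden
  g1 <- crossprod(d2, A1) / m               # hidden x (d+1)
  if (model$lambda > 0) {
    g1[, -1] <- g1[, -1] + model$lambda / m * model$theta1[, -1]
    g2[, -1] <- g2[, -1] + model$lambda / m * model$theta2[, -1]
  }
  list(theta1 = g1, theta2 = g2)
}

flatten <- function(model) c(as.numeric(model$theta1), as.numeric(model$theta2))

unflatten <- function(model, par) {
  n1 <- length(model$theta1)
  model$theta1 <- matrix(par[1:n1], nrow(model$theta1))
  model$theta2 <- matrix(par[-(1:n1)], 1)
  model
}

# Strong-Wolfe line search (bracket + zoom). Returns the accepted step or
# ok = FALSE when no acceptable step exists within machine limits.
wolfe_search <- function(phi, dphi, f0, g0, a_init = 1,
                         c1 = 1e-4, c2 = 0.2, max_expand = 20) {
  zoom <- function(lo, hi, flo) {
    for (k in 1:30) {
      a <- (lo + hi) / 2
      fa <- phi(a)
      if (fa > f0 + c1 * a * g0 || fa >= flo) hi <- a
      else {
        ga <- dphi(a)
        if (abs(ga) <= -c2 * g0) return(list(ok = TRUE, a = a, f = fa))
        if (ga * (hi - lo) >= 0) hi <- lo
        lo <- a; flo <- fa
      }
      if (abs(hi - lo) < 1e-14 * max(1, abs(lo)))
        return(list(ok = TRUE, a = lo, f = flo))
    }
    list(ok = TRUE, a = lo, f = flo)
  }
  a_prev <- 0; f_prev <- f0
  a <- a_init
  for (k in seq_len(max_expand)) {
    fa <- phi(a)
    if (fa > f0 + c1 * a * g0 || (k > 1 && fa >= f_prev))
      return(zoom(a_prev, a, f_prev))
    ga <- dphi(a)
    if (abs(ga) <= -c2 * g0) return(list(ok = TRUE, a = a, f = fa))
    if (ga >= 0) return(zoom(a, a_prev, fa))
    a_prev <- a; f_prev <- fa
    a <- 2 * a
  }
  list(ok = FALSE)
}

#' Train the validator by Polak-Ribiere conjugate gradients
#'
#' Nonlinear CG with the Polak-Ribiere(+) update and a strong-Wolfe line
#' search, run for at most `max_iter` iterations on the regularized
#' cross-entropy objective. The cost sequence over accepted steps is
#' non-increasing, and the returned model carries the weights with the
#' lowest training cost encountered (`$trace` holds the J sequence).
#'
#' @param X standardized training feature matrix.
#' @param t 0/1 training labels.
#' @param lambda regularization weight.
#' @param max_iter iteration cap (default 400, where convergence is
#'   typically observed).
#' @param seed seed for the weight initialization.
#' @param hidden hidden units.
#' @param scaler optional `FeatureScaler` stored with the model.
#' @return the trained `NNModel`.
#' @export
nn_train <- function(X, t, lambda = 0, max_iter = 400, seed = 1,
                     hidden = 20, scaler = NULL) {
  X <- as.matrix(X)
  stopifnot(all(t %in% c(0, 1)), nrow(X) == length(t))
  model <- nn_model(d = ncol(X), hidden = hidden, lambda = lambda,
                    scaler = scaler, seed = seed)
  par <- flatten(model)
  fn <- function(p) nn_cost(unflatten(model, p), X, t)
  gr <- function(p) {
    g <- nn_gradient(unflatten(model, p), X, t)
    c(as.numeric(g$theta1), as.numeric(g$theta2))
  }
  f <- fn(par); g <- gr(par)
  if (!is.finite(f)) stop("non-finite initial cost")
  d <- -g
  trace <- f
  best_par <- par; best_f <- f
  a_prev <- 1
  for (it in seq_len(max_iter)) {
    gd <- sum(g * d)
    if (gd >= 0) { d <- -g; gd <- sum(g * d) }   # restart on non-descent
    phi <- function(a) fn(par + a * d)
    dphi <- function(a) sum(gr(par + a * d) * d)
    ls <- wolfe_search(phi, dphi, f, gd, a_init = a_prev)
    if (!ls$ok) break
    par_new <- par + ls$a * d
    g_new <- gr(par_new)
    if (!is.finite(ls$f)) stop("non-finite cost during training (iter ", it, ")")
    beta <- max(0, sum(g_new * (g_new - g)) / sum(g * g))   # PR+
    d <- -g_new + beta * d
    a_prev <- ls$a
    par <- par_new; f <- ls$f; g <- g_new
    trace <- c(trace, f)
    if (f < best_f) { best_f <- f; best_par <- par }
    if (sqrt(sum(g^2)) < 1e-8 * max(1, abs(f))) break
  }
  model <- unflatten(model, best_par)
  model$trace <- trace
  model
}

#' Random 50/25/25 split into training/validation/test sets
#'
#' Uniform random assignment with exact counts (largest-remainder
#' rounding), deterministic per seed.
#'
#' @param m number of examples (>= 4).
#' @param fractions split fractions summing to 1.
#' @param seed RNG seed.
#' @return factor of length `m` with levels `train`, `val`, `test`.
#' @export
split_data <- function(m, fractions = c(0.5, 0.25, 0.25), seed = 1) {
  stopifnot(m >= 4, abs(sum(fractions) - 1) < 1e-9)
  counts <- floor(m * fractions)
  rem <- m - sum(counts)
  if (rem > 0) {
    o <- order(m * fractions - counts, decreasing = TRUE)
    counts[o[seq_len(rem)]] <- counts[o[seq_len(rem)]] + 1
  }
  set.seed(seed)
  lab <- rep(c("train", "val", "test"), counts)
  factor(lab[sample.int(m)], levels = c("train", "val", "test"))
}

#' Classification accuracy at threshold 0.5
#'
#' Predictions with `p >= 0.5` count as class 1 (the boundary keeps the
#' peak).
#'
#' @param model an `NNModel`.
#' @param X standardized feature matrix.
#' @param t 0/1 labels.
#' @return fraction of correct calls.
#' @export
evaluate_accuracy <- function(model, X, t) {
  if (length(t) == 0) stop("empty evaluation split")
  mean((nn_forward(model, as.matrix(X)) >= 0.5) == (t == 1))
}

#' Select the regularization weight on the validation split
#'
#' Trains one model per candidate lambda on the training split and keeps
#' the one with the lowest validation misclassification rate (ties go to
#' the smallest lambda). The default grid is 13 log-spaced points on
#' `[0.003, 10]`.
#'
#' @param X standardized feature matrix (all examples).
#' @param t 0/1 labels.
#' @param split factor from [split_data()].
#' @param grid candidate lambda values.
#' @param max_iter,seed,hidden,scaler passed to [nn_train()].
#' @return list with `model` (refit summary: the winning trained model),
#'   `lambda`, and `val_error` per grid point.
#' @export
select_lambda <- function(X, t, split, grid = lambda_grid(),
                          max_iter = 400, seed = 1, hidden = 20,
                          scaler = NULL) {
  stopifnot(length(grid) >= 1)
  if (!any(split == "val")) stop("empty validation split")
  X <- as.matrix(X)
  tr <- split == "train"; va <- split == "val"
  grid <- sort(grid)
  models <- lapply(grid, function(l)
    nn_train(X[tr, , drop = FALSE], t[tr], lambda = l, max_iter = max_iter,
             seed = seed, hidden = hidden, scaler = scaler))
  verr <- vapply(models, function(m)
    1 - evaluate_accuracy(m, X[va, , drop = FALSE], t[va]), 0)
  best <- which.min(verr)   # which.min takes the first (smallest lambda) tie
  list(model = models[[best]], lambda = grid[best],
       val_error = stats::setNames(verr, format(grid)))
}

#' @rdname select_lambda
#' @param n number of grid points.
#' @param range lambda range endpoints.
#' @export
lambda_grid <- function(n = 13, range = c(0.003, 10)) {
  10^seq(log10(range[1]), log10(range[2]), length.out = n)
}

#' Validate a predicted peak cluster with the neural network
#'
#' The 4-step cluster validation: for every spectrum, (1) look for local
#' maxima of the processed trace in the window
#' `c * (1 +/- window_frac)`; if any exist take the highest as the
#' candidate peak, (2) extract the 62-feature descriptor at the candidate
#' apex from the raw/processed pair and standardize it with the model's
#' scaler, (3) keep the peak iff the network output is at least 0.5, and
#' (4) report the prevalence as kept peaks over all spectra, with heights
#' and areas of the kept peaks for the group-analysis step.
#'
#' @param raw_set,processed_set aligned `SpectrumSet`s (same ids, same
#'   order, common grid); the processed set is the quantification track.
#' @param c_mz predicted cluster mean m/z.
#' @param model a trained `NNModel` carrying its `FeatureScaler`.
#' @param window_frac search/feature window half-width (default 0.003).
#' @return list with `mean_mz` (of kept peaks), `prevalence`, `n_spectra`,
#'   and `members` (spectrum_id, mz, height, area, prob).
#' @export
validate_cluster <- function(raw_set, processed_set, c_mz, model,
                             window_frac = 0.003) {
  stopifnot(inherits(raw_set, "SpectrumSet"),
            inherits(processed_set, "SpectrumSet"),
            identical(set_ids(raw_set), set_ids(processed_set)))
  if (is.null(model$scaler)) stop("model carries no feature scaler")
  n <- length(raw_set$spectra)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- processed_set$spectra[[i]]
    sr <- raw_set$spectra[[i]]
    lo <- c_mz * (1 - window_frac); hi <- c_mz * (1 + window_frac)
    if (lo < min(sp$mz) || hi > max(sp$mz))
      stop("cluster window outside spectrum range")
    idx <- which(sp$mz >= lo & sp$mz <= hi)
    if (length(idx) < 3) next
    loc <- find_extrema(sp$intensity[idx], "max")
    if (length(loc) == 0) next
    apex_local <- loc[which.max(sp$intensity[idx][loc])]
    apex <- idx[apex_local]
    x <- tryCatch(extract_features(sr, sp, sp$mz[apex], window_frac),
                  error = function(e) NULL)
    if (is.null(x)) next
    p <- nn_forward(model, apply_scaler(x, model$scaler))
    if (p >= 0.5) {
      mins <- sort(unique(c(1L, find_extrema(sp$intensity, "min"),
                            length(sp$mz))))
      pk <- data.frame(spectrum_id = sp$id, mz = sp$mz[apex],
                       height = sp$intensity[apex], area = NA_real_,
                       left_mz = sp$mz[max(mins[mins < apex])],
                       right_mz = sp$mz[min(mins[mins > apex])],
                       apex_idx = apex)
      pk <- quantify_peak(sp, pk)
      pk$prob <- p
      rows[[i]] <- pk
    }
  }
  members <- do.call(rbind, rows)
  kept <- if (is.null(members)) 0L else nrow(members)
  list(mean_mz = if (kept) mean(members$mz) else c_mz,
       prevalence = kept / n, n_spectra = n,
       members = members)
}
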