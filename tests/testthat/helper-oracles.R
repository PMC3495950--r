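# Independent oracle implementations used to cross-check the package.
# Each is written as directly as possible (loops, enumeration) and stays
# independent of the code path it checks.

# pyramid (cascade) periodic DWT: filter + downsample level by level
oracle_dwt_cascade <- function(x, h, levels) {
  L <- length(h)
  g <- numeric(L)
  for (k in seq_len(L)) g[k] <- (-1)^(k - 1) * h[L - k + 1]
  a <- x
  details <- numeric(0)
  for (lev in seq_len(levels)) {
    n <- length(a)
    half <- n / 2
    anew <- numeric(half); d <- numeric(half)
    for (i in seq_len(half)) {
      idx <- ((2 * (i - 1) + 0:(L - 1)) %% n) + 1
      anew[i] <- sum(h * a[idx])
      d[i] <- sum(g * a[idx])
    }
    details <- c(d, details)
    a <- anew
  }
  c(a, details)
}

# pointwise linear interpolation, one target at a time
oracle_interp <- function(x, y, xout) {
  vapply(xout, function(t) {
    j <- max(which(x <= t))
    if (x[j] == t) return(y[j])
    y[j] + (y[j + 1] - y[j]) * (t - x[j]) / (x[j + 1] - x[j])
  }, 0)
}

# per-point mean and unbiased variance loops
oracle_mean_var <- function(Y) {
  n <- nrow(Y)
  mu <- numeric(n); v <- numeric(n)
  for (i in seq_len(n)) {
    mu[i] <- sum(Y[i, ]) / ncol(Y)
    v[i] <- sum((Y[i, ] - mu[i])^2) / (ncol(Y) - 1)
  }
  list(mu = mu, var = v)
}

# least squares of v on [1, mu, mu^2] by explicit 3x3 normal equations
oracle_quad_ls <- function(mu, v) {
  X <- cbind(1, mu, mu^2)
  solve(t(X) %*% X, t(X) %*% v)[, 1]
}

# brute-force windowed extreme
oracle_roll_extreme <- function(x, w, fun) {
  n <- length(x)
  half_l <- (w - 1) %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half_l)
    hi <- min(n, i + (w - 1 - half_l))
    # replicate-padded edges: clamp indices into range
    fun(x[lo:hi])
  }, 0)
}

# direct DTFT magnitude at one normalized frequency (1 = Nyquist)
oracle_dtft_mag <- function(h, f) {
  Mod(sum(h * exp(-1i * pi * f * (seq_along(h) - 1))))
}

# pairwise single-linkage 1-D clustering: union-find over all pairs whose
# gap is within the relative tolerance (equivalent to the sorted chain cut)
oracle_cluster <- function(mz, tol) {
  n <- length(mz)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(mz[i] - mz[j]) <= tol * (mz[i] + mz[j]) / 2) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  # renumber components in sorted-m/z order for comparability
  o <- order(mz)
  cid <- integer(n); cur <- 0L; seen <- integer(0)
  for (k in o) {
    r <- roots[k]
    if (!r %in% seen) { cur <- cur + 1L; seen <- c(seen, r) }
    cid[k] <- match(roots[k], seen)
  }
  return(cid)
}

oracle_chain_cluster <- function(mz, tol) {
  n <- length(mz)
  o <- order(mz)
  cid <- integer(n); cur <- 1L
  cid[o[1]] <- 1L
  for (k in 2:n) {
    if (mz[o[k]] - mz[o[k - 1]] > tol * (mz[o[k]] + mz[o[k - 1]]) / 2)
      cur <- cur + 1L
    cid[o[k]] <- cur
  }
  cid
}

# per-example loops for the network: forward, cost, accuracy
oracle_nn_forward <- function(theta1, theta2, x) {
  sig <- function(z) 1 / (1 + exp(-z))
  hidden <- numeric(nrow(theta1))
  for (u in seq_len(nrow(theta1))) {
    acc <- theta1[u, 1]
    for (k in seq_along(x)) acc <- acc + theta1[u, k + 1] * x[k]
    hidden[u] <- sig(acc)
  }
  acc <- theta2[1, 1]
  for (u in seq_along(hidden)) acc <- acc + theta2[1, u + 1] * hidden[u]
  sig(acc)
}

oracle_nn_cost <- function(theta1, theta2, X, t, lambda) {
  m <- nrow(X)
  J <- 0
  for (i in seq_len(m)) {
    p <- oracle_nn_forward(theta1, theta2, X[i, ])
    p <- min(max(p, 1e-12), 1 - 1e-12)
    J <- J - (t[i] * log(p) + (1 - t[i]) * log(1 - p)) / m
  }
  J + lambda / (2 * m) * (sum(theta1[, -1]^2) + sum(theta2[, -1]^2))
}

# full enumeration of the two-sided Mann-Whitney p (no ties)
oracle_mw_exact <- function(a, b) {
  na <- length(a); nb <- length(b)
  vals <- c(a, b)
  combos <- utils::combn(na + nb, na)
  ustat <- function(ia) {
    r <- rank(vals)
    sum(r[ia]) - na * (na + 1) / 2
  }
  u_obs <- ustat(seq_len(na))
  us <- apply(combos, 2, function(ia) {
    r <- rank(vals)
    sum(r[ia]) - na * (na + 1) / 2
  })
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# hypergeometric enumeration of the two-sided mid-P over all tables
oracle_fisher_midp <- function(tab) {
  a <- tab[1, 1]; K <- sum(tab[, 1]); N <- sum(tab); n1 <- sum(tab[1, ])
  lo <- max(0, n1 - (N - K)); hi <- min(n1, K)
  probs <- vapply(lo:hi, function(k)
    choose(K, k) * choose(N - K, n1 - k) / choose(N, n1), 0)
  names(probs) <- lo:hi
  p_obs <- probs[as.character(a)]
  expect <- n1 * K / N
  if (a < expect)
    one <- sum(probs[as.numeric(names(probs)) < a]) + p_obs / 2
  else if (a > expect)
    one <- sum(probs[as.numeric(names(probs)) > a]) + p_obs / 2
  else one <- min(sum(probs[as.numeric(names(probs)) < a]),
                  sum(probs[as.numeric(names(probs)) > a])) + p_obs / 2
  min(1, 2 * one)
}

# Savitzky-Golay smoothing taps: central row of the polynomial projector
oracle_sg_taps <- function(window, degree) {
  half <- (window - 1) / 2
  A <- outer(-half:half, 0:degree, `^`)
  P <- A %*% solve(t(A) %*% A) %*% t(A)
  P[half + 1, ]
}
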