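#' Quadratic variance function (QVF) detector-noise model
#'
#' The detector response is modeled as additive noise whose variance is a
#' quadratic function of the local mean intensity:
#' `v(mu) = c0 + c1*mu + c2*mu^2`. The model is estimated by ordinary
#' least squares from pointwise mean/variance pairs computed across
#' spectra in user-chosen peak-free regions, and is the engine behind the
#' variance-stabilizing transform used by the wavelet denoiser.
#'
#' @param c0,c1,c2 quadratic coefficients (intensity^2 units).
#' @param floor lower floor applied to predicted variances (OLS fits can
#'   dip negative near zero mean); `NULL` means no floor.
#' @return an object of class `"QVF"`.
#' @export
qvf <- function(c0, c1, c2, floor = NULL) {
  stopifnot(is.finite(c0), is.finite(c1), is.finite(c2))
  structure(list(c0 = c0, c1 = c1, c2 = c2, floor = floor,
                 diagnostics = NULL),
            class = "QVF")
}

#' @export
print.QVF <- function(x, ...) {
  cat(sprintf("<QVF> v(mu) = %.6g + %.6g*mu + %.6g*mu^2", x$c0, x$c1, x$c2))
  if (!is.null(x$diagnostics))
    cat(sprintf("  [fit on %d points, rss %.4g]",
                x$diagnostics$n, x$diagnostics$rss))
  cat("\n")
  invisible(x)
}

#' @rdname qvf
#' @param q a `QVF`.
#' @param mu mean intensities at which to evaluate the variance.
#' @export
predict_qvf <- function(q, mu) {
  v <- q$c0 + q$c1 * mu + q$c2 * mu^2
  if (!is.null(q$floor)) v <- pmax(v, q$floor)
  v
}

#' Across-spectra pointwise mean and variance in selected regions
#'
#' @param set a `SpectrumSet` (>= 2 spectra) on a common grid.
#' @param regions list of `(low, high)` m/z intervals, or a 2-column
#'   matrix; every grid point inside any interval contributes.
#' @return list with `mu` (pointwise means), `var` (unbiased pointwise
#'   sample variances), and `idx` (grid indices used).
#' @export
pointwise_mean_var <- function(set, regions) {
  stopifnot(inherits(set, "SpectrumSet"))
  if (is.null(set$common_grid)) stop("pointwise statistics require a common grid")
  if (length(set$spectra) < 2) stop("need at least 2 spectra")
  if (is.matrix(regions)) regions <- asplit(regions, 1)
  if (length(regions) == 0) stop("no regions supplied")
  grid <- set$common_grid
  inside <- rep(FALSE, length(grid))
  for (r in regions) inside <- inside | (grid >= r[1] & grid <= r[2])
  idx <- which(inside)
  if (length(idx) == 0) stop("regions contain no grid points")
  Y <- vapply(set$spectra, function(s) s$intensity[idx], numeric(length(idx)))
  mu <- rowMeans(Y)
  v <- rowSums((Y - mu)^2) / (ncol(Y) - 1)
  list(mu = mu, var = v, idx = idx)
}

#' Propose peak-free regions from a spectrum set
#'
#' Stands in for manual selection: grid points whose smoothed set-mean
#' intensity lies below a quantile threshold are collected into contiguous
#' m/z intervals. Intended as a starting point a user can edit.
#'
#' @param set a `SpectrumSet` on a common grid.
#' @param quantile quantile of the smoothed set-mean below which a point
#'   counts as peak-free (default 0.25).
#' @param smooth_window width (points) of the moving-average smoother.
#' @return list of `(low, high)` m/z intervals.
#' @export
propose_peak_free_regions <- function(set, quantile = 0.25,
                                      smooth_window = 31) {
  stopifnot(inherits(set, "SpectrumSet"))
  if (is.null(set$common_grid)) stop("requires a common grid")
  grid <- set$common_grid
  m <- rowMeans(vapply(set$spectra, `[[`, numeric(length(grid)), "intensity"))
  k <- rep(1 / smooth_window, smooth_window)
  sm <- stats::filter(m, k, sides = 2)
  sm[is.na(sm)] <- m[is.na(sm)]
  low <- sm <= stats::quantile(sm, quantile)
  r <- rle(as.vector(low))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  lapply(keep, function(i) c(grid[starts[i]], grid[ends[i]]))
}

#' Fit the QVF by least squares on mean/variance points
#'
#' Ordinary least squares of pointwise variances on `[1, mu, mu^2]`.
#' The returned model carries a variance floor equal to the smallest
#' positive observed variance, guarding against negative OLS predictions
#' at small means.
#'
#' @param mu,var pointwise means and variances (from
#'   [pointwise_mean_var()]).
#' @return a `QVF` with fit diagnostics.
#' @export
fit_qvf <- function(mu, var) {
  stopifnot(length(mu) == length(var))
  if (length(unique(mu)) < 3) stop("need at least 3 distinct mean values")
  X <- cbind(1, mu, mu^2)
  fit <- stats::lm.fit(X, var)
  if (fit$rank < 3) stop("rank-deficient QVF design")
  cf <- unname(fit$coefficients)
  q <- qvf(cf[1], cf[2], cf[3],
           floor = if (any(var > 0)) min(var[var > 0]) else NULL)
  q$diagnostics <- list(rss = sum(fit$residuals^2), n = length(mu))
  q
}

#' Variance-stabilizing transform under a QVF
#'
#' Maps intensities `y` to `z = integral dy / sqrt(v(y))`, evaluated in
#' closed form per branch of the quadratic, so that additive noise with
#' variance `v(y)` becomes approximately unit-variance. Strictly monotone
#' increasing; [unstabilize_variance()] inverts it exactly.
#'
#' Branches: `c2 > 0` uses the logarithmic antiderivative
#' `log(2*sqrt(c2*v) + 2*c2*y + c1)/sqrt(c2)`; `c2 < 0` (possible from a
#' noisy fit) the arcsine branch
#' `asin(-(c1 + 2*c2*y)/sqrt(c1^2 - 4*c0*c2))/sqrt(-c2)`; `c2 = 0,
#' c1 != 0` the square-root (Poisson-like) branch `2*sqrt(v)/c1`;
#' constant variance gives `y/sqrt(c0)`.
#'
#' @param y intensity vector; `v(y)` must be positive throughout.
#' @param q a `QVF`.
#' @return the stabilized vector `z`.
#' @export
stabilize_variance <- function(y, q) {
  v <- q$c0 + q$c1 * y + q$c2 * y^2   # no floor: need the exact quadratic
  if (any(v <= 0)) stop("v(y) <= 0 encountered; QVF not valid at these intensities")
  if (q$c2 > 0) {
    arg <- 2 * sqrt(q$c2 * v) + 2 * q$c2 * y + q$c1
    if (any(arg <= 0)) stop("stabilization argument non-positive")
    log(arg) / sqrt(q$c2)
  } else if (q$c2 < 0) {
    disc <- q$c1^2 - 4 * q$c0 * q$c2
    asin(-(q$c1 + 2 * q$c2 * y) / sqrt(disc)) / sqrt(-q$c2)
  } else if (q$c1 != 0) {
    2 * sqrt(v) / q$c1
  } else {
    y / sqrt(q$c0)
  }
}

#' @rdname stabilize_variance
#' @param z stabilized values to map back to the intensity scale.
#' @export
unstabilize_variance <- function(z, q) {
  if (q$c2 > 0) {
    u <- exp(sqrt(q$c2) * z)
    disc <- 4 * q$c0 * q$c2 - q$c1^2
    ((u - disc / u) / 2 - q$c1) / (2 * q$c2)
  } else if (q$c2 < 0) {
    disc <- q$c1^2 - 4 * q$c0 * q$c2
    (-q$c1 - sqrt(disc) * sin(sqrt(-q$c2) * z)) / (2 * q$c2)
  } else if (q$c1 != 0) {
    ((q$c1 * z / 2)^2 - q$c0) / q$c1
  } else {
    z * sqrt(q$c0)
  }
}
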