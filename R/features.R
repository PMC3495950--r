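# 62-dimensional candidate-peak descriptors and their standardization.

#' Extract the 62-dimensional feature vector for a candidate peak
#'
#' Everything an expert needs to judge a candidate peak at m/z `mu` is in
#' a local window `[mu*(1-window_frac), mu*(1+window_frac)]` of the raw
#' and processed traces. The descriptor is, in fixed order:
#' \enumerate{
#'   \item concavity: the quadratic coefficient of the OLS parabola fit to
#'     the raw intensities on `(m - mu)`, `(m - mu)^2` over the window
#'     (good peaks look like a healthy concave-down quadratic, so negative
#'     values indicate peak-like curvature; stored unmodified);
#'   \item mass: `mu` itself (peak shapes change with mass);
#'   \item 30 linearly interpolated processed intensities on an even grid
#'     spanning the window exactly;
#'   \item 30 linearly interpolated raw intensities on the same grid.
#' }
#'
#' @param raw,processed `Spectrum` objects on the same grid.
#' @param mu candidate m/z (Da).
#' @param window_frac half-width of the window as a fraction of `mu`
#'   (default 0.003, the clustering tolerance).
#' @return numeric vector of length 62 with names
#'   `c("concavity", "mass", proc01..proc30, raw01..raw30)`.
#' @export
extract_features <- function(raw, processed, mu, window_frac = 0.003) {
  validate_spectrum(raw); validate_spectrum(processed)
  if (!isTRUE(all.equal(raw$mz, processed$mz)))
    stop("raw and processed spectra must share a grid")
  lo <- mu * (1 - window_frac); hi <- mu * (1 + window_frac)
  if (lo < min(raw$mz) || hi > max(raw$mz))
    stop("feature window outside spectrum range")
  idx <- which(raw$mz >= lo & raw$mz <= hi)
  if (length(idx) < 4)
    stop("feature window contains fewer than 4 grid points")
  dm <- raw$mz[idx] - mu
  cf <- stats::lm.fit(cbind(1, dm, dm^2), raw$intensity[idx])$coefficients
  grid30 <- seq(lo, hi, length.out = 30)
  proc30 <- stats::approx(processed$mz, processed$intensity, xout = grid30)$y
  raw30 <- stats::approx(raw$mz, raw$intensity, xout = grid30)$y
  stats::setNames(c(unname(cf[3]), mu, proc30, raw30),
                  c("concavity", "mass",
                    sprintf("proc%02d", 1:30), sprintf("raw%02d", 1:30)))
}

#' Per-dimension standardization fitted on the training set
#'
#' `fit_scaler()` records the mean and standard deviation of every feature
#' dimension across the training matrix; `apply_scaler()` maps
#' `(x - mean) / sd`. The scaler is fitted on the training split only and
#' reused unchanged for validation, test, and clinical data. Dimensions
#' with zero spread get sd 1 (with a warning) to avoid division by zero.
#'
#' @param X feature matrix (rows = candidates, 62 columns).
#' @return `fit_scaler()`: object of class `"FeatureScaler"` with `means`
#'   and `sds`.
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 training vectors")
  means <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant feature dimension(s); sd set to 1")
    sds[sds == 0] <- 1
  }
  structure(list(means = means, sds = sds), class = "FeatureScaler")
}

#' @rdname fit_scaler
#' @param x a feature vector or matrix to standardize.
#' @param scaler a `FeatureScaler`.
#' @export
apply_scaler <- function(x, scaler) {
  stopifnot(inherits(scaler, "FeatureScaler"))
  if (is.matrix(x))
    sweep(sweep(x, 2, scaler$means), 2, scaler$sds, "/")
  else
    (x - scaler$means) / scaler$sds
}
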