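# Baseline correction and total-ion-current normalization.

# Running min/max over a centered window, van Herk style: O(n) using
# blockwise prefix/suffix scans. Edges handled by replicate-padding, so a
# constant signal is a fixed point of both erosion and dilation.
roll_extreme <- function(x, w, op = c("min", "max")) {
  op <- match.arg(op)
  n <- length(x)
  if (w >= n) stop("window (", w, ") must be smaller than the signal (", n, ")")
  if (w <= 1) return(x)
  half_l <- (w - 1L) %/% 2L
  half_r <- w - 1L - half_l
  xp <- c(rep(x[1], w), x, rep(x[n], w))
  np <- length(xp)
  pad_to <- ceiling(np / w) * w
  xp <- c(xp, rep(xp[np], pad_to - np))
  m <- matrix(xp, nrow = w)
  cum <- if (op == "min") cummin else cummax
  pref <- as.vector(apply(m, 2, cum))
  suff <- as.vector(apply(m[w:1, , drop = FALSE], 2, cum))[
    rep((seq_len(pad_to %/% w) - 1) * w, each = w) + rep(w:1, pad_to %/% w)]
  # window covering padded indices [i, i+w-1]
  comb <- if (op == "min") pmin else pmax
  win <- comb(suff[seq_len(pad_to - w + 1)], pref[seq_len(pad_to - w + 1) + w - 1L])
  # centered window for original index i starts at padded index (i + w) - half_l
  win[(seq_len(n) + w) - half_l]
}

#' Morphological-opening baseline subtraction
#'
#' Estimates the baseline as the morphological opening of the intensity
#' trace (rolling minimum followed by rolling maximum over a window of
#' `window_frac * n` points) and subtracts it pointwise. The opening lies
#' on or below the signal everywhere, so subtraction never increases an
#' intensity; negative outputs are allowed (no clipping), preserving the
#' noise distribution for the QVF fit.
#'
#' @param s a `Spectrum` with `stage = "raw"`.
#' @param window_frac window width as a fraction of the spectrum length;
#'   must be much wider than a peak and narrower than baseline features.
#' @return the baseline-corrected `Spectrum`; the estimated baseline is in
#'   `$meta$baseline`.
#' @export
subtract_baseline <- function(s, window_frac = 0.05) {
  validate_spectrum(s)
  if (s$stage != "raw") stop("subtract_baseline expects a raw spectrum")
  n <- length(s$intensity)
  w <- max(3L, as.integer(round(window_frac * n)))
  if (w %% 2L == 0L) w <- w + 1L   # symmetric window: opening <= signal
  if (w >= n) stop("baseline window larger than spectrum")
  baseline <- roll_extreme(roll_extreme(s$intensity, w, "min"), w, "max")
  s$meta$baseline <- baseline
  s$intensity <- s$intensity - baseline
  advance_stage(s, "baseline_corrected")
}

#' Total-ion-current normalization across a spectrum set
#'
#' Rescales every spectrum so its summed intensity over `mz_range` equals
#' the set mean of the pre-scaling sums, making spectra comparable before
#' pointwise statistics. Scale factors are recorded in each spectrum's
#' `$meta$tic_scale`.
#'
#' @param set a `SpectrumSet` of baseline-corrected spectra on a common grid.
#' @param mz_range optional `(low, high)` restriction of the TIC window
#'   (default: full spectrum).
#' @return the normalized `SpectrumSet`.
#' @export
tic_normalize <- function(set, mz_range = NULL) {
  stopifnot(inherits(set, "SpectrumSet"))
  if (is.null(set$common_grid)) stop("TIC normalization requires a common grid")
  grid <- set$common_grid
  idx <- if (is.null(mz_range)) seq_along(grid) else
    which(grid >= mz_range[1] & grid <= mz_range[2])
  if (length(idx) == 0) stop("empty TIC m/z range")
  sums <- vapply(set$spectra, function(s) sum(s$intensity[idx]), 0)
  if (any(sums <= 0)) stop("zero or negative total ion current in spectrum ",
                           set_ids(set)[which(sums <= 0)[1]])
  target <- mean(sums)
  out <- lapply(seq_along(set$spectra), function(i) {
    s <- set$spectra[[i]]
    s$meta$tic_scale <- target / sums[i]
    s$intensity <- s$intensity * (target / sums[i])
    advance_stage(s, "normalized")
  })
  spectrum_set(out, common_grid = grid)
}
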