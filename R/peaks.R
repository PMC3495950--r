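# Per-spectrum peak detection and quantification, cross-spectrum
# clustering by mass tolerance, the reproducibility (prevalence) rule,
# and the sensitivity/FDR benchmark against ground truth.
#
# Peaks are rows of a data frame (spectrum_id, mz, height, area, left_mz,
# right_mz, apex_idx); clusters are a list of class "PeakClusterSet" with
# a summary table and a members table.

#' Detect local maxima in a processed spectrum
#'
#' Strict local maxima above `min_height`; plateaus of equal values with
#' lower neighbors on both sides are resolved to their center sample
#' (left-of-center on even plateaus). Flanking valleys are the nearest
#' local minima on each side (spectrum ends count as valleys).
#'
#' @param s a `Spectrum` with stage `"denoised"` or `"smoothed"`.
#' @param min_height minimum apex intensity to report.
#' @return data frame of peaks (possibly 0 rows).
#' @export
detect_local_maxima <- function(s, min_height = 0) {
  validate_spectrum(s)
  if (!s$stage %in% c("denoised", "smoothed"))
    stop("peak detection expects a denoised or smoothed spectrum")
  x <- s$intensity
  n <- length(x)
  apex <- find_extrema(x, "max")
  if (length(apex)) apex <- apex[x[apex] >= min_height]
  if (length(apex) == 0)
    return(data.frame(spectrum_id = character(), mz = numeric(),
                      height = numeric(), area = numeric(),
                      left_mz = numeric(), right_mz = numeric(),
                      apex_idx = integer()))
  mins <- sort(unique(c(1L, find_extrema(x, "min"), n)))
  left <- vapply(apex, function(a) max(mins[mins < a]), 0L)
  right <- vapply(apex, function(a) min(mins[mins > a]), 0L)
  data.frame(spectrum_id = s$id, mz = s$mz[apex], height = x[apex],
             area = NA_real_, left_mz = s$mz[left], right_mz = s$mz[right],
             apex_idx = apex)
}

# interior local extrema with plateau handling; returns center indices
find_extrema <- function(x, what = c("max", "min")) {
  what <- match.arg(what)
  if (what == "min") x <- -x
  n <- length(x)
  if (n < 3) return(integer())
  d <- diff(x)
  out <- integer()
  i <- 1L
  while (i < n) {
    if (d[i] > 0) {
      j <- i + 1L                      # x rises into a candidate at j
      while (j < n && d[j] == 0) j <- j + 1L
      # plateau spans samples (i+1)..j; a peak iff the next move is down
      if (j <= n && (j == n || d[j] < 0)) {
        if (j < n) {                   # interior peak (ends are not peaks)
          lo <- i + 1L; hi <- j
          out <- c(out, lo + (hi - lo) %/% 2L)
        }
        i <- j
      } else i <- j
    } else i <- i + 1L
  }
  out
}

#' Quantify peaks on the smoothed (quantification-path) spectrum
#'
#' For each detected peak, height is the smoothed intensity at the apex
#' grid point, and area is the trapezoidal integral of the smoothed
#' intensity between the flanking valleys minus the chord under the
#' valley endpoints (local-baseline-corrected area, in Da * a.u.).
#'
#' @param smoothed a `Spectrum` (stage `"smoothed"`) on the same grid the
#'   peaks were detected on.
#' @param peaks peak data frame from [detect_local_maxima()].
#' @return the data frame with `height` and `area` filled from `smoothed`.
#' @export
quantify_peak <- function(smoothed, peaks) {
  validate_spectrum(smoothed)
  if (nrow(peaks) == 0) return(peaks)
  if (any(peaks$left_mz >= peaks$mz | peaks$right_mz <= peaks$mz))
    stop("inverted peak bounds")
  grid <- smoothed$mz
  y <- smoothed$intensity
  for (i in seq_len(nrow(peaks))) {
    a <- which.min(abs(grid - peaks$left_mz[i]))
    b <- which.min(abs(grid - peaks$right_mz[i]))
    apex <- which.min(abs(grid - peaks$mz[i]))
    if (a >= b) stop("inverted peak bounds")
    seg <- a:b
    total <- sum(diff(grid[seg]) * (y[seg][-1] + y[seg][-length(seg)]) / 2)
    chord <- (grid[b] - grid[a]) * (y[a] + y[b]) / 2
    peaks$height[i] <- y[apex]
    peaks$area[i] <- total - chord
  }
  peaks
}

#' Cluster peaks across spectra by mass tolerance
#'
#' Single-linkage clustering of the pooled, sorted apex list: adjacent
#' apexes stay linked while their m/z gap is at most
#' `tolerance_frac * mean(pair)`; links with larger gaps are cut. Within a
#' cluster at most one peak per spectrum is kept (the one closest to the
#' cluster mean), the mean m/z is recomputed after assignment, and the
#' prevalence is the number of member spectra over `n_spectra`.
#'
#' @param peaklists either a single pooled peak data frame or a list of
#'   per-spectrum peak data frames.
#' @param n_spectra prevalence denominator (number of spectra searched).
#' @param tolerance_frac relative mass tolerance (default 0.003, i.e.
#'   0.3\%).
#' @return an object of class `"PeakClusterSet"`: list with `clusters`
#'   (cluster_id, mean_mz, n_members, prevalence) and `members` (cluster
#'   assignment of every kept peak).
#' @export
cluster_peaks <- function(peaklists, n_spectra, tolerance_frac = 0.003) {
  pool <- if (is.data.frame(peaklists)) peaklists else
    do.call(rbind, peaklists)
  if (is.null(pool) || nrow(pool) == 0)
    return(structure(list(
      clusters = data.frame(cluster_id = integer(), mean_mz = numeric(),
                            n_members = integer(), prevalence = numeric()),
      members = cbind(data.frame(cluster_id = integer()),
                      pool[0, , drop = FALSE]),
      n_spectra = n_spectra, tolerance_frac = tolerance_frac),
      class = "PeakClusterSet"))
  pool <- pool[order(pool$mz), , drop = FALSE]
  gaps <- diff(pool$mz)
  pairmean <- (pool$mz[-1] + pool$mz[-nrow(pool)]) / 2
  cut <- gaps > tolerance_frac * pairmean
  cid <- cumsum(c(1L, as.integer(cut)))
  keep <- logical(nrow(pool))
  mean_mz <- numeric(max(cid))
  for (g in seq_len(max(cid))) {
    idx <- which(cid == g)
    m <- mean(pool$mz[idx])
    # one peak per spectrum: the member closest to the cluster mean
    for (sid in unique(pool$spectrum_id[idx])) {
      cand <- idx[pool$spectrum_id[idx] == sid]
      keep[cand[which.min(abs(pool$mz[cand] - m))]] <- TRUE
    }
    mean_mz[g] <- mean(pool$mz[idx[keep[idx]]])
  }
  members <- cbind(data.frame(cluster_id = cid[keep]),
                   pool[keep, , drop = FALSE])
  rownames(members) <- NULL
  counts <- table(factor(members$cluster_id, levels = seq_len(max(cid))))
  clusters <- data.frame(cluster_id = seq_len(max(cid)), mean_mz = mean_mz,
                         n_members = as.integer(counts),
                         prevalence = as.integer(counts) / n_spectra)
  structure(list(clusters = clusters, members = members,
                 n_spectra = n_spectra, tolerance_frac = tolerance_frac),
            class = "PeakClusterSet")
}

#' @export
print.PeakClusterSet <- function(x, ...) {
  cat(sprintf("<PeakClusterSet> %d clusters from %d spectra (tolerance %.2f%%)\n",
              nrow(x$clusters), x$n_spectra, 100 * x$tolerance_frac))
  invisible(x)
}

#' Keep clusters meeting the reproducibility (prevalence) rule
#'
#' A cluster is reproducible when its peak is present in at least
#' `min_prevalence` of the spectra (default 80\%, e.g. 24 of 30 spectra).
#'
#' @param cl a `PeakClusterSet`.
#' @param min_prevalence prevalence threshold in `[0, 1]`.
#' @return the filtered `PeakClusterSet`.
#' @export
reproducible_clusters <- function(cl, min_prevalence = 0.8) {
  stopifnot(inherits(cl, "PeakClusterSet"))
  keep <- cl$clusters$prevalence >= min_prevalence
  cl$clusters <- cl$clusters[keep, , drop = FALSE]
  cl$members <- cl$members[cl$members$cluster_id %in%
                             cl$clusters$cluster_id, , drop = FALSE]
  cl
}

#' Sensitivity and FDR of predicted clusters against ground truth
#'
#' Greedy one-to-one matching by |m/z| distance: a predicted cluster
#' within `tolerance_frac` of an unmatched true center is a true
#' positive; unmatched predictions are false positives; unmatched true
#' centers are false negatives. Sensitivity = TP/(TP+FN),
#' FDR = FP/(TP+FP); an empty prediction list yields FDR 0 with
#' `degenerate = TRUE`.
#'
#' @param predicted_mz predicted cluster mean m/z values (or a
#'   `PeakClusterSet`).
#' @param true_mz true cluster centers.
#' @param tolerance_frac relative matching tolerance (default 0.003).
#' @return list with `tp`, `fp`, `fn`, `sensitivity`, `fdr`, `degenerate`.
#' @export
benchmark_sens_fdr <- function(predicted_mz, true_mz, tolerance_frac = 0.003) {
  if (inherits(predicted_mz, "PeakClusterSet"))
    predicted_mz <- predicted_mz$clusters$mean_mz
  predicted_mz <- as.numeric(predicted_mz)
  true_mz <- as.numeric(true_mz)
  np <- length(predicted_mz); nt <- length(true_mz)
  if (np && nt) {
    d <- abs(outer(predicted_mz, true_mz, "-"))
    tol <- tolerance_frac * outer(predicted_mz, true_mz,
                                  function(a, b) (a + b) / 2)
    cand <- which(d <= tol, arr.ind = TRUE)
    cand <- cand[order(d[cand]), , drop = FALSE]
    used_p <- logical(np); used_t <- logical(nt)
    tp <- 0L
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!used_p[i] && !used_t[j]) {
        used_p[i] <- TRUE; used_t[j] <- TRUE; tp <- tp + 1L
      }
    }
  } else tp <- 0L
  fp <- np - tp
  fn <- nt - tp
  list(tp = tp, fp = fp, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else 0,
       fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
       degenerate = (tp + fp) == 0)
}
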