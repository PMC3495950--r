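#' Simulation configuration for synthetic SELDI-like spectrum sets
#'
#' The generator states a world matching the data model the rest of the
#' package assumes: Gaussian peaks whose width grows linearly with mass
#' (TOF resolution degrades with m/z), per-cluster Bernoulli presence with
#' a fixed prevalence, small multiplicative m/z jitter across spectra
#' (inside the 0.3\% clustering tolerance), a smooth exponentially decaying
#' baseline, and additive heteroscedastic Gaussian noise whose variance is
#' a quadratic function of the clean signal (the QVF detector model).
#'
#' @param n_points grid length per spectrum.
#' @param mz_range numeric `(low, high)` m/z span in Da.
#' @param clusters data frame with columns `center_mz`, `height`,
#'   `prevalence`, and optionally `jitter_frac` (default 0.001).
#' @param width_coeff peak sigma per Da of mass: `sigma = width_coeff * mz`.
#' @param baseline list with `amplitude` and `decay` (Da) of the
#'   exponential baseline `amplitude * exp(-(m - low)/decay)`.
#' @param qvf numeric `(c0, c1, c2)` of the noise variance
#'   `v(mu) = c0 + c1*mu + c2*mu^2`; must be positive over the simulated
#'   intensity range.
#' @param n_spectra number of subjects.
#' @param n_replicates replicate spectra per subject (same planted peaks,
#'   independent noise).
#' @param group group label applied to all spectra.
#' @param seed RNG seed; the full draw record is reproducible from it.
#' @return a list of class `"SimConfig"`.
#' @export
sim_config <- function(n_points = 4096, mz_range = c(3000, 15000),
                       clusters = default_clusters(), width_coeff = 0.004,
                       baseline = list(amplitude = 20, decay = 4000),
                       qvf = c(1, 0.05, 0.001), n_spectra = 30,
                       n_replicates = 1, group = "QC", seed = 1) {
  stopifnot(length(mz_range) == 2, mz_range[1] < mz_range[2],
            is.data.frame(clusters),
            all(c("center_mz", "height", "prevalence") %in% names(clusters)),
            all(clusters$prevalence >= 0 & clusters$prevalence <= 1),
            length(qvf) == 3)
  if (is.null(clusters$jitter_frac)) clusters$jitter_frac <- 0.001
  if (any(clusters$jitter_frac > 0.003))
    warning("jitter_frac above the 0.3% clustering tolerance")
  cfg <- structure(list(n_points = as.integer(n_points),
                        mz_range = as.numeric(mz_range), clusters = clusters,
                        width_coeff = width_coeff, baseline = baseline,
                        qvf = as.numeric(qvf), n_spectra = as.integer(n_spectra),
                        n_replicates = as.integer(n_replicates),
                        group = group, seed = as.integer(seed)),
                   class = "SimConfig")
  # QVF must be a valid variance over the realizable intensity range
  mu_max <- sum(clusters$height) + baseline$amplitude
  mu_chk <- seq(0, mu_max, length.out = 256)
  if (any(qvf[1] + qvf[2] * mu_chk + qvf[3] * mu_chk^2 <= 0))
    stop("qvf coefficients give non-positive variance over the intensity range")
  cfg
}

#' @rdname sim_config
#' @param n_clusters number of planted clusters.
#' @export
default_clusters <- function(n_clusters = 20) {
  # deterministic, irregularly spaced centers with a mix of prevalences:
  # roughly half fully prevalent, the rest between 0.8 and 0.95, plus a
  # couple of sub-threshold clusters that the 80% rule should drop
  centers <- seq(3400, 14200, length.out = n_clusters)
  centers <- centers * (1 + 0.004 * sin(seq_len(n_clusters) * 2.3))
  heights <- 40 + 60 * abs(sin(seq_len(n_clusters) * 1.7))
  prev <- rep(1, n_clusters)
  idx <- seq_len(n_clusters)
  prev[idx %% 3 == 1] <- 0.9
  prev[idx %% 5 == 0] <- 0.85
  if (n_clusters >= 8) prev[c(4, 8)] <- c(0.5, 0.3)  # below the 80% rule
  data.frame(center_mz = centers, height = heights, prevalence = prev,
             jitter_frac = 0.001)
}

#' Simulate a spectrum set with known ground truth
#'
#' Draws, for every subject and cluster, a Bernoulli presence indicator at
#' the cluster prevalence, a jittered center `center_mz * (1 + U(-j, +j))`,
#' then renders Gaussian bumps with `sigma = width_coeff * center_mz`, adds
#' the exponential baseline, and adds pointwise Gaussian noise with
#' variance `v(clean)` from the QVF. Every draw is recorded in the returned
#' ground truth.
#'
#' @param config a [sim_config()].
#' @return list with `set` (a `SpectrumSet` on a common grid, stage `"raw"`)
#'   and `truth` (class `"GroundTruth"`: `$peaks` data frame of planted
#'   peaks per subject, `$clusters` per-cluster truth with true and
#'   realized prevalence, `$grid`).
#' @export
simulate_spectrum_set <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  grid <- seq(config$mz_range[1], config$mz_range[2],
              length.out = config$n_points)
  cl <- config$clusters
  q <- config$qvf
  peaks_rec <- vector("list", config$n_spectra)
  spectra <- vector("list", config$n_spectra * config$n_replicates)
  present_counts <- integer(nrow(cl))
  k <- 0L
  for (i in seq_len(config$n_spectra)) {
    present <- stats::runif(nrow(cl)) < cl$prevalence
    jit <- stats::runif(nrow(cl), -cl$jitter_frac, cl$jitter_frac)
    mz_i <- cl$center_mz * (1 + jit)
    present_counts <- present_counts + present
    clean <- config$baseline$amplitude *
      exp(-(grid - config$mz_range[1]) / config$baseline$decay)
    for (j in which(present)) {
      sig <- config$width_coeff * cl$center_mz[j]
      clean <- clean + cl$height[j] * exp(-0.5 * ((grid - mz_i[j]) / sig)^2)
    }
    v <- q[1] + q[2] * clean + q[3] * clean^2
    if (any(v <= 0)) stop("non-positive noise variance encountered")
    subj <- sprintf("subj%02d", i)
    peaks_rec[[i]] <- if (any(present))
      data.frame(subject = subj, cluster = which(present),
                 mz = mz_i[present], height = cl$height[present]) else NULL
    for (r in seq_len(config$n_replicates)) {
      k <- k + 1L
      y <- clean + stats::rnorm(config$n_points, 0, sqrt(v))
      spectra[[k]] <- spectrum(grid, y,
                               id = sprintf("%s_r%d", subj, r),
                               subject = subj, replicate = r,
                               group = config$group)
    }
  }
  truth <- structure(
    list(peaks = do.call(rbind, peaks_rec),
         clusters = data.frame(cluster = seq_len(nrow(cl)),
                               center_mz = cl$center_mz, height = cl$height,
                               prevalence_true = cl$prevalence,
                               n_present = present_counts,
                               prevalence_realized =
                                 present_counts / config$n_spectra),
         grid = grid, config = config),
    class = "GroundTruth")
  list(set = spectrum_set(spectra, common_grid = grid), truth = truth)
}

#' Labeled peak candidates from a simulated set
#'
#' Builds an annotated training fixture for the neural-network validator:
#' positives are planted peak apexes; negatives are local maxima of the raw
#' trace lying at least 3 peak-sigmas away from every planted peak in that
#' spectrum (noise or baseline bumps an expert would reject). The class
#' balance defaults to the 57.07\% positive share of the expert-annotated
#' corpus the validator is modeled on.
#'
#' @param set,truth output of [simulate_spectrum_set()].
#' @param n_candidates total number of labeled candidates requested.
#' @param true_fraction fraction of positives (default 0.5707).
#' @param seed RNG seed for sampling.
#' @param edge_frac candidates whose `mz * (1 +/- edge_frac)` window
#'   leaves the spectrum span are excluded, so downstream feature
#'   windows stay in range (default 0.004, just above the 0.3\% feature
#'   window).
#' @return data frame with columns `spectrum_id`, `mz`, `label` (0/1).
#' @export
generate_annotated_candidates <- function(set, truth, n_candidates = 4000,
                                          true_fraction = 0.5707, seed = 1,
                                          edge_frac = 0.004) {
  stopifnot(inherits(set, "SpectrumSet"), inherits(truth, "GroundTruth"))
  set.seed(seed)
  span <- range(truth$grid)
  in_span <- function(mz) mz * (1 - edge_frac) >= span[1] &
    mz * (1 + edge_frac) <= span[2]
  n_pos <- round(n_candidates * true_fraction)
  n_neg <- n_candidates - n_pos
  subj <- vapply(set$spectra, `[[`, "", "subject")
  ids <- set_ids(set)
  wc <- truth$config$width_coeff
  # positive pool: planted apexes in every spectrum of that subject
  pos_pool <- do.call(rbind, lapply(seq_along(set$spectra), function(i) {
    pk <- truth$peaks[truth$peaks$subject == subj[i], , drop = FALSE]
    pk <- pk[in_span(pk$mz), , drop = FALSE]
    if (nrow(pk) == 0) return(NULL)
    data.frame(spectrum_id = ids[i], mz = pk$mz)
  }))
  # negative pool: raw local maxima >= 3 sigma from all planted peaks
  neg_pool <- do.call(rbind, lapply(seq_along(set$spectra), function(i) {
    s <- set$spectra[[i]]
    pk <- truth$peaks[truth$peaks$subject == subj[i], , drop = FALSE]
    lm_idx <- which(diff(sign(diff(s$intensity))) < 0) + 1L
    if (length(lm_idx) == 0) return(NULL)
    cand_mz <- s$mz[lm_idx]
    ok <- in_span(cand_mz)
    for (j in seq_len(nrow(pk)))
      ok <- ok & abs(cand_mz - pk$mz[j]) >= 3 * wc * pk$mz[j]
    if (!any(ok)) return(NULL)
    data.frame(spectrum_id = ids[i], mz = cand_mz[ok])
  }))
  if (is.null(pos_pool) || nrow(pos_pool) < n_pos)
    stop("insufficient planted peaks for requested positives")
  if (is.null(neg_pool) || nrow(neg_pool) < n_neg)
    stop("insufficient decoy locations for requested negatives")
  pos <- pos_pool[sample.int(nrow(pos_pool), n_pos), , drop = FALSE]
  neg <- neg_pool[sample.int(nrow(neg_pool), n_neg), , drop = FALSE]
  pos$label <- rep(1L, nrow(pos)); neg$label <- rep(0L, nrow(neg))
  out <- rbind(pos, neg)
  out <- out[sample.int(nrow(out)), ]
  rownames(out) <- NULL
  out
}
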