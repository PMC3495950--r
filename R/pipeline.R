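# End-to-end orchestration: import -> baseline -> TIC -> replicate
# averaging -> QVF estimation -> cycle-spin denoising (detection track) ->
# zero-phase FIR smoothing (quantification track) -> detection ->
# clustering -> reproducibility filter -> optional NN validation ->
# group statistics. Both processed tracks are retained: the denoised
# track drives detection, the FIR-smoothed track drives quantification.

#' Pipeline configuration
#'
#' Defaults are the package's published operating point: 0.3\% clustering
#' tolerance, 80\% prevalence rule, morphological baseline window 5\% of
#' the spectrum, 32 cycle-spin shifts of a db8 wavelet, the order-67
#' zero-phase equiripple smoother, and an SNR-5 detection threshold on
#' the denoised track.
#'
#' @param baseline_window_frac baseline opening window fraction.
#' @param tic_range optional `(low, high)` TIC window.
#' @param qvf_regions list of peak-free m/z intervals for the QVF fit;
#'   `NULL` proposes regions automatically.
#' @param qvf_quantile quantile for automatic region proposal.
#' @param shifts cycle-spin shift count (or explicit shifts).
#' @param wavelet_p Daubechies vanishing moments.
#' @param wavelet_levels decomposition depth (`NULL` = default).
#' @param fir an `FIRFilter`; `NULL` uses [design_quant_filter()].
#' @param snr_min detection threshold in units of the baseline noise sd
#'   (from the fitted QVF at the median denoised intensity).
#' @param tolerance_frac clustering mass tolerance.
#' @param min_prevalence reproducibility rule threshold.
#' @param window_frac feature / validation window half-width.
#' @param nn_model optional trained `NNModel` enabling the validation
#'   stage.
#' @param alpha report threshold for group statistics.
#' @param cache_dir wavelet operator cache directory.
#' @return list of class `"PipelineConfig"`.
#' @export
pipeline_config <- function(baseline_window_frac = 0.05, tic_range = NULL,
                            qvf_regions = NULL, qvf_quantile = 0.25,
                            shifts = 32, wavelet_p = 8,
                            wavelet_levels = NULL, fir = NULL,
                            snr_min = 5, tolerance_frac = 0.003,
                            min_prevalence = 0.8, window_frac = 0.003,
                            nn_model = NULL, alpha = 0.05,
                            cache_dir = NULL) {
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Run the full preprocessing and analysis pipeline
#'
#' Executes every stage in order on a raw `SpectrumSet`, optionally writes
#' per-stage TSV artifacts and a parameter log, and returns all
#' intermediate products. Reruns with the same inputs and configuration
#' are bit-identical (the pipeline itself draws no random numbers).
#'
#' @param set a raw `SpectrumSet` on a common grid (resample first if
#'   needed).
#' @param config a [pipeline_config()].
#' @param groups optional named vector mapping subject id to group label;
#'   when it contains two groups, group statistics are computed.
#' @param out_dir optional directory for stage artifacts (TSV + log).
#' @return list with `preprocessed`, `averaged`, `qvf`, `denoised`,
#'   `smoothed`, `peaks`, `clusters`, `reproducible`, `validated` (if a
#'   model was supplied), `report` (if groups were supplied), `log`.
#' @export
run_pipeline <- function(set, config = pipeline_config(), groups = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(set, "SpectrumSet"), inherits(config, "PipelineConfig"))
  if (is.null(set$common_grid)) stop("stage import: set needs a common grid")
  logline <- character()
  say <- function(...) logline <<- c(logline, sprintf(...))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  bl <- run_stage("baseline", {
    spectrum_set(lapply(set$spectra, subtract_baseline,
                        window_frac = config$baseline_window_frac),
                 common_grid = set$common_grid)
  })
  say("baseline: morphological opening, window_frac=%g",
      config$baseline_window_frac)

  norm <- run_stage("tic", tic_normalize(bl, config$tic_range))
  say("tic: %s range", if (is.null(config$tic_range)) "full" else
    paste(config$tic_range, collapse = "-"))

  avg <- run_stage("average", average_replicates(norm))
  say("average: %d spectra -> %d subjects", length(norm), length(avg))

  q <- run_stage("qvf", {
    regions <- config$qvf_regions
    if (is.null(regions))
      regions <- propose_peak_free_regions(avg, config$qvf_quantile)
    mv <- pointwise_mean_var(avg, regions)
    fit_qvf(mv$mu, mv$var)
  })
  say("qvf: c=(%.4g, %.4g, %.4g)", q$c0, q$c1, q$c2)

  n <- length(avg$common_grid)
  op <- run_stage("wavelet", {
    N <- 2^ceiling(log2(n))
    wavelet_operator(N, p = config$wavelet_p, levels = config$wavelet_levels,
                     cache_dir = config$cache_dir)
  })
  den <- run_stage("denoise", {
    spectrum_set(lapply(avg$spectra, denoise_spectrum, q = q,
                        shifts = config$shifts, op = op),
                 common_grid = avg$common_grid)
  })
  say("denoise: db%d, %d levels, %s shifts", op$p, op$levels,
      if (length(config$shifts) == 1) config$shifts else
        length(config$shifts))

  fir <- if (is.null(config$fir)) design_quant_filter() else config$fir
  smo <- run_stage("smooth", {
    spectrum_set(lapply(avg$spectra, zero_phase_filter, f = fir),
                 common_grid = avg$common_grid)
  })
  say("smooth: order-%d zero-phase FIR", fir$order)

  peaks <- run_stage("detect", {
    lapply(seq_along(den$spectra), function(i) {
      s <- den$spectra[[i]]
      noise_sd <- sqrt(predict_qvf(q, stats::median(s$intensity)))
      pk <- detect_local_maxima(s, min_height = config$snr_min * noise_sd)
      quantify_peak(smo$spectra[[i]], pk)
    })
  })
  say("detect: snr_min=%g, %d peaks total", config$snr_min,
      sum(vapply(peaks, nrow, 0L)))

  cl <- run_stage("cluster",
                  cluster_peaks(peaks, n_spectra = length(avg),
                                tolerance_frac = config$tolerance_frac))
  rep_cl <- run_stage("reproducible",
                      reproducible_clusters(cl, config$min_prevalence))
  say("cluster: %d clusters, %d reproducible at prevalence >= %g",
      nrow(cl$clusters), nrow(rep_cl$clusters), config$min_prevalence)

  validated <- NULL
  if (!is.null(config$nn_model)) {
    validated <- run_stage("validate", {
      lapply(rep_cl$clusters$mean_mz, function(cmz)
        validate_cluster(avg, smo, cmz, config$nn_model,
                         window_frac = config$window_frac))
    })
    say("validate: %d clusters through the neural network", length(validated))
  }

  report <- NULL
  if (!is.null(groups) && length(unique(groups)) == 2) {
    report <- run_stage("stats", {
      cl_list <- if (!is.null(validated)) validated else
        lapply(split(rep_cl$members, rep_cl$members$cluster_id), function(m)
          list(mean_mz = mean(m$mz), members = m,
               prevalence = nrow(m) / rep_cl$n_spectra,
               n_spectra = rep_cl$n_spectra))
      cluster_report(cl_list, groups, alpha = config$alpha)
    })
    say("stats: %d rows below alpha=%g (no multiplicity correction)",
        nrow(report), config$alpha)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(do.call(rbind, peaks),
                       file.path(out_dir, "peaks.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(rep_cl$clusters,
                       file.path(out_dir, "clusters.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(report))
      utils::write.table(report, file.path(out_dir, "report.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(logline, file.path(out_dir, "pipeline.log"))
  }

  list(preprocessed = norm, averaged = avg, qvf = q, denoised = den,
       smoothed = smo, peaks = peaks, clusters = cl,
       reproducible = rep_cl, validated = validated, report = report,
       log = logline)
}
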