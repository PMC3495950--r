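#' Spectrum and SpectrumSet containers
#'
#' A `Spectrum` is a single TOF trace: parallel vectors of m/z (Da) and
#' detector intensity (arbitrary units), plus sample metadata. A
#' `SpectrumSet` is an ordered collection of spectra, optionally sharing a
#' common m/z grid (required by all pointwise cross-spectrum operations).
#'
#' Processing stages move strictly forward through the pipeline:
#' `raw -> baseline_corrected -> normalized -> {denoised, smoothed}`.
#' The two terminal stages are parallel tracks: denoised spectra drive peak
#' detection, FIR-smoothed spectra drive quantification.
#'
#' @param mz numeric vector of m/z values (Da), strictly increasing.
#' @param intensity numeric vector, same length as `mz`, all finite.
#' @param id spectrum identifier (unique within a set).
#' @param subject subject identifier (replicates share a subject).
#' @param replicate integer replicate index within subject.
#' @param group group label: one of `"QC"`, `"CIN0"`, `"CIN3"`, `"other"`.
#' @param stage processing stage (see Details).
#' @return `spectrum()` returns an object of class `"Spectrum"`.
#' @export
spectrum <- function(mz, intensity, id = "s1", subject = id,
                     replicate = 1L, group = "QC", stage = "raw") {
  s <- structure(
    list(mz = as.numeric(mz), intensity = as.numeric(intensity),
         id = as.character(id), subject = as.character(subject),
         replicate = as.integer(replicate), group = match_group(group),
         stage = match_stage(stage), meta = list()),
    class = "Spectrum")
  validate_spectrum(s)
  s
}

.stages <- c("raw", "baseline_corrected", "normalized", "denoised", "smoothed")
.groups <- c("QC", "CIN0", "CIN3", "other")

match_stage <- function(stage) match.arg(stage, .stages)
match_group <- function(group) match.arg(group, .groups)

#' @rdname spectrum
#' @param s a `Spectrum`.
#' @export
validate_spectrum <- function(s) {
  stopifnot(inherits(s, "Spectrum"))
  if (length(s$mz) != length(s$intensity))
    stop("mz and intensity lengths differ")
  if (!all(is.finite(s$mz)) || !all(is.finite(s$intensity)))
    stop("non-finite values in spectrum")
  if (length(s$mz) > 1 && any(diff(s$mz) <= 0))
    stop("mz must be strictly increasing")
  invisible(s)
}

# stage bookkeeping: refuse to move backwards through the pipeline
advance_stage <- function(s, to) {
  to <- match_stage(to)
  if (match(to, .stages) < match(s$stage, .stages))
    stop(sprintf("stage transition %s -> %s goes backwards", s$stage, to))
  s$stage <- to
  s
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf("<Spectrum %s> %d points, m/z [%.1f, %.1f], stage=%s, subject=%s, rep=%d, group=%s\n",
              x$id, length(x$mz), min(x$mz), max(x$mz), x$stage,
              x$subject, x$replicate, x$group))
  invisible(x)
}

#' @rdname spectrum
#' @param spectra list of `Spectrum` objects with unique ids.
#' @param common_grid optional shared m/z grid; when set, every member's
#'   `mz` must equal it.
#' @return `spectrum_set()` returns an object of class `"SpectrumSet"`.
#' @export
spectrum_set <- function(spectra, common_grid = NULL) {
  stopifnot(is.list(spectra))
  lapply(spectra, validate_spectrum)
  ids <- vapply(spectra, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("spectrum ids must be unique")
  if (!is.null(common_grid)) {
    for (s in spectra)
      if (!isTRUE(all.equal(s$mz, as.numeric(common_grid), tolerance = 1e-12)))
        stop("spectrum ", s$id, " is not on the common grid")
  }
  structure(list(spectra = spectra, common_grid = common_grid),
            class = "SpectrumSet")
}

#' @export
print.SpectrumSet <- function(x, ...) {
  cat(sprintf("<SpectrumSet> %d spectra%s\n", length(x$spectra),
              if (is.null(x$common_grid)) "" else
                sprintf(", common grid of %d points", length(x$common_grid))))
  invisible(x)
}

#' @export
length.SpectrumSet <- function(x) length(x$spectra)

set_ids <- function(set) vapply(set$spectra, `[[`, "", "id")

#' Read a spectrum from a two-column CSV file
#'
#' Parses a comma-separated file with columns (m/z, intensity), `.` decimal
#' point, and an optional single header line (auto-detected). Rows are
#' sorted by m/z.
#'
#' @param path file path.
#' @param meta named list of metadata fields (`id`, `subject`, `replicate`,
#'   `group`) applied to the result; defaults derive `id` from the filename.
#' @return a `Spectrum` with `stage = "raw"`.
#' @export
read_spectrum_csv <- function(path, meta = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  skip <- 0L
  fields <- strsplit(first, ",")[[1]]
  # header iff a leading field fails to parse as numeric at all
  # ("NaN" parses, and must reach the finiteness check below)
  num <- suppressWarnings(as.numeric(fields[seq_len(min(2, length(fields)))]))
  if (length(fields) >= 2 && any(is.na(num) & !is.nan(num)))
    skip <- 1L
  d <- utils::read.csv(path, header = FALSE, skip = skip,
                       colClasses = "character", strip.white = TRUE)
  if (ncol(d) < 2) stop("expected two columns in ", path)
  mz <- suppressWarnings(as.numeric(d[[1]]))
  y <- suppressWarnings(as.numeric(d[[2]]))
  if (anyNA(mz) || anyNA(y) || !all(is.finite(mz)) || !all(is.finite(y)))
    stop("non-numeric or non-finite values in ", path)
  o <- order(mz)
  mz <- mz[o]; y <- y[o]
  if (any(diff(mz) <= 0)) stop("duplicate m/z values in ", path)
  id <- if (!is.null(meta$id)) meta$id else
    sub("\\.[Cc][Ss][Vv]$", "", basename(path))
  spectrum(mz, y, id = id,
           subject = if (!is.null(meta$subject)) meta$subject else id,
           replicate = if (!is.null(meta$replicate)) meta$replicate else 1L,
           group = if (!is.null(meta$group)) meta$group else "QC")
}

#' @rdname read_spectrum_csv
#' @param s a `Spectrum` to write.
#' @param header write a `mz,intensity` header line?
#' @export
write_spectrum_csv <- function(s, path, header = TRUE) {
  validate_spectrum(s)
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines("mz,intensity", con)
  writeLines(paste(format(s$mz, digits = 17, trim = TRUE, scientific = FALSE),
                   format(s$intensity, digits = 17, trim = TRUE),
                   sep = ","), con)
  invisible(path)
}

#' Interpolate a spectrum set onto a shared m/z grid
#'
#' Linear interpolation of every member spectrum onto `grid`. Pointwise
#' cross-spectrum statistics (mean/variance, TIC matching, replicate
#' averaging) require a common grid.
#'
#' @param set a `SpectrumSet`.
#' @param grid target m/z grid; default: the grid of the first spectrum.
#' @return a `SpectrumSet` with `common_grid` set.
#' @export
resample_to_common_grid <- function(set, grid = NULL) {
  stopifnot(inherits(set, "SpectrumSet"))
  if (length(set$spectra) == 0) return(spectrum_set(list(), common_grid = grid))
  if (is.null(grid)) grid <- set$spectra[[1]]$mz
  grid <- as.numeric(grid)
  out <- lapply(set$spectra, function(s) {
    if (min(grid) < min(s$mz) || max(grid) > max(s$mz))
      stop("grid outside m/z span of spectrum ", s$id)
    if (length(s$mz) == length(grid) && all(s$mz == grid)) return(s)
    s$intensity <- stats::approx(s$mz, s$intensity, xout = grid)$y
    s$mz <- grid
    s
  })
  spectrum_set(out, common_grid = grid)
}

#' Average replicate spectra within each subject
#'
#' Collapses a set to one spectrum per subject by the arithmetic pointwise
#' mean of that subject's replicates. Applied after baseline correction and
#' TIC normalization, before peak detection.
#'
#' @param set a `SpectrumSet` on a common grid.
#' @return a `SpectrumSet` with one `Spectrum` per subject (id = subject).
#' @export
average_replicates <- function(set) {
  stopifnot(inherits(set, "SpectrumSet"))
  if (is.null(set$common_grid)) stop("replicate averaging requires a common grid")
  subj <- vapply(set$spectra, `[[`, "", "subject")
  out <- lapply(unique(subj), function(u) {
    members <- set$spectra[subj == u]
    grp <- unique(vapply(members, `[[`, "", "group"))
    if (length(grp) > 1)
      stop("subject ", u, " has spectra in multiple groups: ",
           paste(grp, collapse = ", "))
    avg <- members[[1]]
    avg$intensity <- rowMeans(vapply(members, `[[`, numeric(length(avg$mz)),
                                     "intensity"))
    avg$id <- u; avg$subject <- u; avg$replicate <- 1L
    avg
  })
  spectrum_set(out, common_grid = set$common_grid)
}
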