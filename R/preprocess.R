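# The serum-spectrum preprocessing chain: fingerprint band selection,
# Savitzky-Golay smoothing, airPLS baseline correction, replicate-correlation
# outlier screening, and area normalization — applied in exactly that order.

.PREPROCESS_STAGES <- c("band", "smooth", "baseline", "outlier", "normalize")

#' Preprocessing configuration
#'
#' Collects every knob of the preprocessing chain. The stage order is fixed
#' (band selection, smoothing, baseline correction, outlier removal,
#' normalization); `stages` may drop stages but any reordering is rejected by
#' the validator.
#'
#' @param band_low,band_high Fingerprint band limits in cm^-1 (closed
#'   interval; defaults 500 and 2000).
#' @param sg_window Savitzky-Golay window in points, odd, greater than
#'   `sg_order` (default 9).
#' @param sg_order Savitzky-Golay polynomial order (default 2).
#' @param airpls_lambda,airpls_max_iter,airpls_tol See [baselineAirPLS()].
#' @param outlier_min_corr Minimum Pearson correlation with the leave-one-out
#'   mean spectrum, in (-1, 1]; default 0.95.
#' @param normalization `"area"` (unit trapezoidal integral) or `"none"`.
#' @param stages Subset of `c("band","smooth","baseline","outlier","normalize")`
#'   in canonical order.
#' @return A validated list of class `"preprocessConfig"`.
#' @export
preprocessConfig <- function(band_low = 500, band_high = 2000,
                             sg_window = 9L, sg_order = 2L,
                             airpls_lambda = 1e5, airpls_max_iter = 30L,
                             airpls_tol = 1e-3,
                             outlier_min_corr = 0.95,
                             normalization = c("area", "none"),
                             stages = .PREPROCESS_STAGES) {
  normalization <- match.arg(normalization)
  if (band_low >= band_high) stop("band_low must be < band_high")
  if (sg_window %% 2 == 0) stop("sg_window must be odd")
  if (sg_window <= sg_order) stop("sg_window must exceed sg_order")
  if (airpls_lambda <= 0) stop("airpls_lambda must be > 0")
  if (airpls_max_iter < 1) stop("airpls_max_iter must be >= 1")
  if (airpls_tol <= 0 || airpls_tol >= 1) stop("airpls_tol must lie in (0,1)")
  if (outlier_min_corr <= -1 || outlier_min_corr > 1) {
    stop("outlier_min_corr must lie in (-1, 1]")
  }
  stages <- as.character(stages)
  unknown <- setdiff(stages, .PREPROCESS_STAGES)
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  if (!identical(stages, .PREPROCESS_STAGES[.PREPROCESS_STAGES %in% stages])) {
    stop("stages must keep the canonical order: ",
         paste(.PREPROCESS_STAGES, collapse = " -> "),
         " (normalization never precedes baseline correction)")
  }
  structure(list(band_low = band_low, band_high = band_high,
                 sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order),
                 airpls_lambda = airpls_lambda,
                 airpls_max_iter = as.integer(airpls_max_iter),
                 airpls_tol = airpls_tol,
                 outlier_min_corr = outlier_min_corr,
                 normalization = normalization,
                 stages = stages),
            class = "preprocessConfig")
}

#' Restrict spectra to a wavenumber band
#'
#' Keeps exactly the axis points with `low <= wavenumber <= high` (closed
#' interval) and subsets the intensity matrix consistently.
#'
#' @param x A [SpectrumSet-class].
#' @param low,high Band limits in cm^-1.
#' @return The band-restricted [SpectrumSet-class].
#' @export
selectBand <- function(x, low = 500, high = 2000) {
  stopifnot(methods::is(x, "SpectrumSet"), low < high)
  keep <- which(wavenumbers(x) >= low & wavenumbers(x) <= high)
  if (!length(keep)) {
    stop(sprintf("band [%g, %g] excludes all points", low, high))
  }
  x[keep, ]
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing of every spectrum
#' (via [signal::sgolayfilt()]). Edge points are handled by evaluating the
#' polynomial fit of the terminal window, so a polynomial of degree <=
#' `order` is reproduced exactly everywhere, edges included. The filter
#' operates on the point index; the axis is assumed (near-)uniformly sampled.
#'
#' @param x A [SpectrumSet-class].
#' @param window Odd window length in points (> `order`), default 9.
#' @param order Polynomial order, default 2.
#' @return The smoothed [SpectrumSet-class].
#' @export
smoothSpectra <- function(x, window = 9L, order = 2L) {
  stopifnot(methods::is(x, "SpectrumSet"))
  if (window %% 2 == 0 || window <= order) {
    stop("window must be odd and greater than order")
  }
  if (nrow(x) < window) {
    stop(sprintf("spectrum has %d points, fewer than the %d-point window",
                 nrow(x), window))
  }
  m <- intensities(x)
  sm <- apply(m, 2, function(col) signal::sgolayfilt(col, p = order, n = window))
  if (!is.matrix(sm)) sm <- matrix(sm, ncol = ncol(m))
  set_intensities(x, sm)
}

#' Remove outlying spectra by leave-one-out correlation
#'
#' Drops every spectrum whose Pearson correlation with the mean of the
#' remaining spectra falls below `min_corr` — the standard replicate screen
#' for spectra corrupted by cosmic events, focus loss, or bubbles. The
#' removal report (spectrum id + correlation) is stored in
#' `metadata(x)$removed_outliers` and printed by [outlierReport()].
#'
#' @param x A [SpectrumSet-class] with at least 3 spectra.
#' @param min_corr Threshold in (-1, 1]; default 0.95.
#' @return The filtered [SpectrumSet-class].
#' @export
removeOutliers <- function(x, min_corr = 0.95) {
  stopifnot(methods::is(x, "SpectrumSet"))
  S <- ncol(x)
  if (S < 3) stop("outlier screening needs at least 3 spectra")
  m <- intensities(x)
  tot <- rowSums(m)
  cors <- vapply(seq_len(S), function(i) {
    stats::cor(m[, i], (tot - m[, i]) / (S - 1))
  }, numeric(1))
  drop <- which(cors < min_corr)
  if (length(drop) == S) stop("outlier screen would remove every spectrum")
  report <- data.frame(spectrum_id = colnames(x)[drop],
                       correlation = cors[drop])
  out <- if (length(drop)) x[, -drop] else x
  S4Vectors::metadata(out)$removed_outliers <- report
  out
}

#' @rdname removeOutliers
#' @export
outlierReport <- function(x) {
  S4Vectors::metadata(x)$removed_outliers %||%
    data.frame(spectrum_id = character(), correlation = numeric())
}

#' Normalize each spectrum to unit integrated area
#'
#' Scales every spectrum so that its trapezoidal integral over the
#' wavenumber axis equals 1 (the axis may be non-uniform). Spectra with a
#' non-positive integral cannot be area-normalized and raise an error naming
#' the spectrum.
#'
#' @param x A [SpectrumSet-class].
#' @return The normalized [SpectrumSet-class].
#' @export
normalizeArea <- function(x) {
  stopifnot(methods::is(x, "SpectrumSet"))
  wn <- wavenumbers(x)
  m <- intensities(x)
  areas <- apply(m, 2, function(col) trapz_integral(wn, col))
  bad <- which(areas <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive integrated area for spectrum '%s' (%.3g)",
                 colnames(x)[bad[1]], areas[bad[1]]))
  }
  set_intensities(x, sweep(m, 2, areas, "/"))
}

#' Normalize each spectrum to unit absolute (L1) area
#'
#' Scales every spectrum by the trapezoidal integral of its absolute value.
#' For ordinary serum spectra — nonnegative up to small baseline-correction
#' undershoot — this coincides with [normalizeArea()]; unlike it, it remains
#' well defined for signals whose net area vanishes (for example peakless,
#' baseline-corrected spectra), which makes it the right way to bring such
#' spectra onto the intensity scale a trained model expects.
#'
#' @param x A [SpectrumSet-class].
#' @return The normalized [SpectrumSet-class].
#' @export
normalizeAbsoluteArea <- function(x) {
  stopifnot(methods::is(x, "SpectrumSet"))
  wn <- wavenumbers(x)
  m <- intensities(x)
  areas <- apply(abs(m), 2, function(col) trapz_integral(wn, col))
  bad <- which(areas <= 0)
  if (length(bad)) {
    stop(sprintf("zero absolute area for spectrum '%s'", colnames(x)[bad[1]]))
  }
  set_intensities(x, sweep(m, 2, areas, "/"))
}

#' Run the full preprocessing chain
#'
#' Applies, in order: band selection, Savitzky-Golay smoothing, airPLS
#' baseline correction, leave-one-out-correlation outlier removal, and area
#' normalization. Per-stage spectrum counts (and the outlier report) are
#' recorded in `metadata(x)$preprocess_log`.
#'
#' @param x A [SpectrumSet-class] of raw spectra.
#' @param config A [preprocessConfig()].
#' @param verbose Print per-stage counts (default `FALSE`).
#' @return The preprocessed [SpectrumSet-class].
#' @export
preprocessSpectra <- function(x, config = preprocessConfig(), verbose = FALSE) {
  stopifnot(methods::is(x, "SpectrumSet"),
            inherits(config, "preprocessConfig"))
  log <- data.frame(stage = character(), spectra = integer(),
                    points = integer())
  note <- function(stage) {
    log <<- rbind(log, data.frame(stage = stage, spectra = ncol(x),
                                  points = nrow(x)))
    if (verbose) message(sprintf("%-10s %d spectra x %d points",
                                 stage, ncol(x), nrow(x)))
  }
  note("input")
  for (stage in config$stages) {
    x <- switch(stage,
      band = selectBand(x, config$band_low, config$band_high),
      smooth = smoothSpectra(x, config$sg_window, config$sg_order),
      baseline = baselineAirPLS(x, config$airpls_lambda,
                                config$airpls_max_iter, config$airpls_tol)$set,
      outlier = removeOutliers(x, config$outlier_min_corr),
      normalize = if (config$normalization == "area") normalizeArea(x) else x)
    note(stage)
  }
  S4Vectors::metadata(x)$preprocess_log <- log
  x
}

#' Mean spectrum, optionally per class
#'
#' @param x A [SpectrumSet-class].
#' @param by_label Average within each class label (labels required) rather
#'   than over all spectra.
#' @return A [SpectrumSet-class] of group means on the same axis (one column
#'   per group).
#' @export
meanSpectrum <- function(x, by_label = FALSE) {
  stopifnot(methods::is(x, "SpectrumSet"))
  if (ncol(x) == 0) stop("cannot average an empty SpectrumSet")
  m <- intensities(x)
  if (by_label) {
    lab <- droplevels(classLabels(x))
    if (all(is.na(lab))) stop("by_label = TRUE requires class labels")
    if (anyNA(lab)) stop("some spectra are unlabeled")
    groups <- levels(lab)
    means <- vapply(groups, function(g) rowMeans(m[, lab == g, drop = FALSE]),
                    numeric(nrow(m)))
    SpectrumSet(wavenumbers(x), means, subject_id = groups, label = groups,
                spectrum_id = groups)
  } else {
    SpectrumSet(wavenumbers(x), cbind(mean = rowMeans(m)))
  }
}

#' Locate peaks in a single spectrum by topographic prominence
#'
#' Finds interior local maxima and computes each one's prominence (height
#' above the higher of the two key saddles separating it from higher
#' terrain; for the global maximum, above the signal minimum). Peaks with
#' prominence >= `min_prominence` are reported as axis positions, ascending.
#'
#' @param x A [SpectrumSet-class] with a single spectrum, or a numeric
#'   vector (then `wavenumber` must be given).
#' @param min_prominence Minimum prominence, in intensity units.
#' @param wavenumber Axis for the vector input form.
#' @return A data.frame with columns `wavenumber`, `height`, `prominence`
#'   (possibly zero rows).
#' @export
findSpectralPeaks <- function(x, min_prominence = 0, wavenumber = NULL) {
  if (methods::is(x, "SpectrumSet")) {
    if (ncol(x) != 1) stop("findSpectralPeaks expects a single spectrum")
    wavenumber <- wavenumbers(x)
    y <- as.numeric(intensities(x))
  } else {
    y <- as.numeric(x)
    if (is.null(wavenumber)) wavenumber <- seq_along(y)
  }
  P <- length(y)
  if (P < 3) stop("need at least 3 points")
  empty <- data.frame(wavenumber = numeric(), height = numeric(),
                      prominence = numeric())
  is_max <- which(y[2:(P - 1)] > y[1:(P - 2)] & y[2:(P - 1)] >= y[3:P]) + 1L
  if (!length(is_max)) return(empty)
  prom <- vapply(is_max, function(i) {
    h <- y[i]
    left <- y[seq_len(i - 1)]
    hi <- which(left > h)
    lbase <- if (length(hi)) min(left[(max(hi) + 1):(i - 1)]) else min(left)
    right <- y[(i + 1):P]
    hi <- which(right > h)
    rbase <- if (length(hi)) min(right[seq_len(min(hi) - 1)]) else min(right)
    h - max(lbase, rbase)
  }, numeric(1))
  keep <- prom >= min_prominence & prom > 0
  data.frame(wavenumber = wavenumber[is_max[keep]],
             height = y[is_max[keep]],
             prominence = prom[keep])
}
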