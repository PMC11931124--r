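# Synthetic serum-like Raman spectra with class-differential biochemical
# peaks, a smooth fluorescence background, subject-level amplitude effects
# and replicate-level noise.

#' Build a peak table
#'
#' A peak table is a data.frame with one row per Raman band: `center` and
#' `width` in cm^-1, `profile` (`"gaussian"` or `"lorentzian"`; `width` is
#' the Gaussian sd / Lorentzian half-width), and two matrix columns
#' `amplitude_mean` and `amplitude_sd` with one column per class.
#'
#' @param center,width Numeric vectors, one entry per peak (`width > 0`).
#' @param amplitude_mean,amplitude_sd Matrices (n_peaks x n_classes) with
#'   class names as column names (`amplitude_sd >= 0`).
#' @param profile Character vector, `"gaussian"` (default) or `"lorentzian"`.
#' @return A classed data.frame usable as `peaks` in [syntheticConfig()].
#' @export
peakTable <- function(center, width, amplitude_mean, amplitude_sd,
                      profile = "gaussian") {
  amplitude_mean <- as.matrix(amplitude_mean)
  amplitude_sd <- as.matrix(amplitude_sd)
  stopifnot(length(center) == length(width),
            nrow(amplitude_mean) == length(center),
            all(dim(amplitude_sd) == dim(amplitude_mean)),
            all(width > 0), all(amplitude_sd >= 0),
            !is.null(colnames(amplitude_mean)))
  profile <- rep_len(match.arg(profile, c("gaussian", "lorentzian"),
                               several.ok = TRUE), length(center))
  out <- data.frame(center = as.numeric(center), width = as.numeric(width),
                    profile = profile)
  out$amplitude_mean <- amplitude_mean
  out$amplitude_sd <- amplitude_sd
  class(out) <- c("peakTable", "data.frame")
  out
}

# Serum Raman bands of the fingerprint region with tentative assignments:
# amide I (1653), CH2 scissoring of lipids (1432), deoxyribose (1425),
# guanine/CH deformation (1320), amide III / proline (1246, 1260),
# glycogen (1048), tyrosine ring breathing (852), DNA backbone (720),
# aromatic C-C twist (631), OH out-of-plane (559). 1444 (lipid CH2 bending)
# joins the activity-task table.
.SERUM_BANDS <- data.frame(
  center = c(559, 631, 720, 852, 1048, 1246, 1260, 1320, 1425, 1432, 1653),
  base = c(0.45, 0.40, 0.50, 0.65, 0.60, 0.70, 0.65, 0.75, 0.50, 0.80, 1.00))

#' Default class-differential peak tables
#'
#' For the diagnosis task, all serum fingerprint bands are present in both
#' classes (the spectra of SLE and non-SLE sera are qualitatively similar);
#' the classes differ only in peak magnitude, with the SLE class amplified at
#' 1653, 1432, 1320, 1246, 852 and 720 cm^-1 and most strongly at the
#' 1048 cm^-1 glycogen band. For the activity task, amplitudes at 559, 631,
#' 1260, 1444 and 1653 cm^-1 grade upward with activity level.
#'
#' @param scheme A [labelScheme()] (default: diagnosis).
#' @return A [peakTable()].
#' @examples
#' tab <- defaultPeakTable(labelScheme("diagnosis"))
#' tab[tab$center == 1048, "amplitude_mean"]
#' @export
defaultPeakTable <- function(scheme = labelScheme("diagnosis")) {
  stopifnot(inherits(scheme, "labelScheme"))
  if (scheme$task == "diagnosis") {
    centers <- .SERUM_BANDS$center
    base <- .SERUM_BANDS$base
    amp <- cbind(base, base)
    colnames(amp) <- scheme$classes
    up <- centers %in% c(1653, 1432, 1320, 1246, 852, 720)
    amp[up, 2] <- amp[up, 2] * 1.3
    amp[centers == 1048, 2] <- amp[centers == 1048, 2] * 1.4
  } else {
    centers <- c(.SERUM_BANDS$center, 1444)
    base <- c(.SERUM_BANDS$base, 0.70)
    k <- length(scheme$classes)
    amp <- matrix(base, nrow = length(centers), ncol = k)
    colnames(amp) <- scheme$classes
    graded <- centers %in% c(559, 631, 1260, 1444, 1653)
    for (j in seq_len(k)) amp[graded, j] <- base[graded] * (1 + 0.25 * (j - 1))
    ord <- order(centers)
    centers <- centers[ord]; amp <- amp[ord, , drop = FALSE]
  }
  sd <- matrix(0.08, nrow = length(centers), ncol = ncol(amp),
               dimnames = list(NULL, colnames(amp)))
  peakTable(centers, width = rep(12, length(centers)),
            amplitude_mean = amp, amplitude_sd = sd)
}

#' Simulator configuration
#'
#' Emulates the acquisition design of a serum Raman study: ~80 subjects per
#' class, 3 replicate spectra per subject recorded at different sample
#' positions, a 500-2000 cm^-1 axis. Each subject draws per-peak amplitudes
#' from class-conditional normals truncated at 0 (shared by that subject's
#' replicates); each replicate adds its own random smooth cubic fluorescence
#' background with a positive upward trend and i.i.d. Gaussian noise.
#'
#' @param scheme A [labelScheme()].
#' @param peaks A [peakTable()]; default [defaultPeakTable()] for the scheme.
#' @param axis_low,axis_high,n_points Axis definition (defaults 500, 2000,
#'   1501 -> 1 cm^-1 spacing).
#' @param baseline_scale Overall scale of the fluorescence background
#'   relative to peak heights (default 3).
#' @param noise_sd Replicate-level Gaussian noise sd (default 0.02, about 2%
#'   of the strongest peak).
#' @param subjects_per_class Default 80.
#' @param replicates Spectra per subject, default 3.
#' @param seed RNG seed for reproducibility.
#' @return A list of class `"syntheticConfig"`.
#' @export
syntheticConfig <- function(scheme = labelScheme("diagnosis"),
                            peaks = defaultPeakTable(scheme),
                            axis_low = 500, axis_high = 2000,
                            n_points = 1501L,
                            baseline_scale = 3, noise_sd = 0.02,
                            subjects_per_class = 80L, replicates = 3L,
                            seed = 1L) {
  stopifnot(inherits(scheme, "labelScheme"), inherits(peaks, "peakTable"),
            n_points >= 2, replicates >= 1, subjects_per_class >= 1,
            axis_low < axis_high, noise_sd >= 0, baseline_scale >= 0)
  if (!identical(colnames(peaks$amplitude_mean), scheme$classes)) {
    stop("peak table classes must match the label scheme classes")
  }
  structure(list(scheme = scheme, peaks = peaks, axis_low = axis_low,
                 axis_high = axis_high, n_points = as.integer(n_points),
                 baseline_scale = baseline_scale, noise_sd = noise_sd,
                 subjects_per_class = as.integer(subjects_per_class),
                 replicates = as.integer(replicates), seed = seed),
            class = "syntheticConfig")
}

.peak_profile <- function(wn, center, width, profile) {
  if (profile == "gaussian") exp(-(wn - center)^2 / (2 * width^2))
  else width^2 / ((wn - center)^2 + width^2)
}

.profile_matrix <- function(wn, peaks) {
  vapply(seq_len(nrow(peaks)), function(p) {
    .peak_profile(wn, peaks$center[p], peaks$width[p], peaks$profile[p])
  }, numeric(length(wn)))
}

.sample_baseline_coef <- function(n, scale) {
  # random cubic on u = (wn - low)/(high - low) in [0, 1]; positive offset
  # and positive leading trend mimic a fluorescence background that rises
  # across the window and is removable by airPLS.
  cbind(c0 = stats::runif(n, 0.8, 1.6) * scale,
        c1 = stats::runif(n, 0.1, 0.5) * scale,
        c2 = stats::runif(n, -0.3, 0.3) * scale,
        c3 = stats::runif(n, 0.1, 0.6) * scale)
}

.baseline_curves <- function(u, coef) {
  U <- cbind(1, u, u^2, u^3)
  U %*% t(coef)
}

#' Generate a labeled synthetic dataset
#'
#' See [syntheticConfig()] for the generative model. The draw is fully
#' determined by `cfg$seed`; the sampled ground truth (per-subject peak
#' amplitudes, per-spectrum baseline coefficients, class assignments) is
#' stored in `metadata()$ground_truth` and returned by [groundTruth()].
#'
#' @param cfg A [syntheticConfig()].
#' @return A labeled [SpectrumSet-class].
#' @examples
#' cfg <- syntheticConfig(subjects_per_class = 3, n_points = 201, seed = 7)
#' simulateSpectra(cfg)
#' @export
simulateSpectra <- function(cfg = syntheticConfig()) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  with_seed(cfg$seed, {
    wn <- seq(cfg$axis_low, cfg$axis_high, length.out = cfg$n_points)
    u <- (wn - cfg$axis_low) / (cfg$axis_high - cfg$axis_low)
    classes <- cfg$scheme$classes
    n_sub <- cfg$subjects_per_class * length(classes)
    subj_class <- rep(classes, each = cfg$subjects_per_class)
    subj_id <- sprintf("%s_s%02d", gsub("[^[:alnum:]]", "", subj_class),
                       rep(seq_len(cfg$subjects_per_class), length(classes)))
    npk <- nrow(cfg$peaks)
    # subject-level truncated-normal amplitudes (shared across replicates)
    amps <- matrix(0, n_sub, npk,
                   dimnames = list(subj_id, paste0("pk", cfg$peaks$center)))
    for (i in seq_len(n_sub)) {
      mu <- cfg$peaks$amplitude_mean[, subj_class[i]]
      sd <- cfg$peaks$amplitude_sd[, subj_class[i]]
      amps[i, ] <- pmax(0, stats::rnorm(npk, mu, sd))
    }
    S <- n_sub * cfg$replicates
    spec_subj <- rep(seq_len(n_sub), each = cfg$replicates)
    repl <- rep(seq_len(cfg$replicates), n_sub)
    coef <- .sample_baseline_coef(S, cfg$baseline_scale)
    prof <- .profile_matrix(wn, cfg$peaks)              # P x npk
    signal <- prof %*% t(amps)                          # P x n_sub
    m <- signal[, spec_subj] + .baseline_curves(u, coef)
    if (cfg$noise_sd > 0) {
      m <- m + matrix(stats::rnorm(length(m), 0, cfg$noise_sd), nrow(m))
    }
    ids <- sprintf("%s_r%d", subj_id[spec_subj], repl)
    out <- SpectrumSet(wn, m, subject_id = subj_id[spec_subj],
                       replicate = repl,
                       label = factor(subj_class[spec_subj],
                                      levels = classes),
                       spectrum_id = ids)
    S4Vectors::metadata(out)$ground_truth <- list(
      amplitudes = amps, classes = stats::setNames(subj_class, subj_id),
      baseline_coefficients = coef, config = cfg)
    out
  })
}

#' @rdname simulateSpectra
#' @param x A simulated [SpectrumSet-class].
#' @export
groundTruth <- function(x) S4Vectors::metadata(x)$ground_truth

#' Generate out-of-distribution spectra (background + noise only)
#'
#' Draws spectra with the same fluorescence background and noise model as
#' [simulateSpectra()] but with no Raman peaks at all — inputs lacking the
#' structure the classifier is trained on, used to probe predictive
#' uncertainty.
#'
#' @param cfg A [syntheticConfig()].
#' @param n Number of spectra (>= 1).
#' @param seed Seed (default `cfg$seed + 1` so OOD draws differ from the
#'   training draw under a shared config).
#' @return A [SpectrumSet-class] labeled `"OOD"`.
#' @export
simulateOodSpectra <- function(cfg = syntheticConfig(), n = 50L, seed = NULL) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  if (n < 1) stop("n must be >= 1")
  seed <- seed %||% (cfg$seed + 1L)
  with_seed(seed, {
    wn <- seq(cfg$axis_low, cfg$axis_high, length.out = cfg$n_points)
    u <- (wn - cfg$axis_low) / (cfg$axis_high - cfg$axis_low)
    coef <- .sample_baseline_coef(n, cfg$baseline_scale)
    m <- .baseline_curves(u, coef)
    if (cfg$noise_sd > 0) {
      m <- m + matrix(stats::rnorm(length(m), 0, cfg$noise_sd), nrow(m))
    }
    ids <- sprintf("ood_s%03d_r1", seq_len(n))
    SpectrumSet(wn, m, subject_id = sub("_r1$", "", ids),
                replicate = rep(1L, n), label = rep("OOD", n),
                spectrum_id = ids)
  })
}
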