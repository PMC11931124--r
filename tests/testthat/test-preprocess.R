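make_set <- function(wn, ...) {
  cols <- list(...)
  SpectrumSet(wn, do.call(cbind, cols))
}

test_that("band selection keeps the closed interval and errors when empty", {
  wn <- c(400, 500, 1000, 2000, 2100)
  ss <- make_set(wn, a = seq_along(wn))
  sel <- selectBand(ss, 500, 2000)
  expect_equal(wavenumbers(sel), c(500, 1000, 2000))
  expect_equal(unname(intensities(sel)[, 1]), c(2, 3, 4))
  # identity when already inside the band
  expect_equal(intensities(selectBand(sel, 500, 2000)), intensities(sel))
  expect_error(selectBand(ss, 2150, 2200), "excludes all points")
})

test_that("Savitzky-Golay smoothing reproduces low-order polynomials", {
  wn <- seq(500, 1000, by = 1)
  const <- make_set(wn, a = rep(5, length(wn)))
  expect_lt(max(abs(intensities(smoothSpectra(const)) - 5)), 1e-10)

  quad <- 2e-4 * wn^2 - 3 * wn + 1
  sq <- smoothSpectra(make_set(wn, a = quad), window = 9, order = 2)
  interior <- 5:(length(wn) - 4)
  expect_lt(max(abs(intensities(sq)[interior, 1] - quad[interior])), 1e-8)
  # terminal-window fit keeps edges exact on quadratics too
  expect_lt(max(abs(intensities(sq)[, 1] - quad)), 1e-8)
})

test_that("smoothing shrinks white-noise variance and validates its window", {
  set.seed(11)
  noise <- rnorm(1e4)
  sm <- smoothSpectra(make_set(seq_len(1e4), a = noise))
  expect_lt(var(as.numeric(intensities(sm))), var(noise))
  expect_error(smoothSpectra(make_set(1:5, a = rnorm(5)), window = 9),
               "fewer than")
  expect_error(smoothSpectra(make_set(1:20, a = rnorm(20)), window = 8),
               "odd")
})

test_that("airPLS follows a peakless smooth signal almost exactly", {
  wn <- seq(500, 2000, by = 1)
  u <- (wn - 500) / 1500
  cubic <- 2 + u + 0.5 * u^2 + 0.8 * u^3
  res <- baselineAirPLS(make_set(wn, a = cubic), lambda = 1e5)
  expect_lt(max(abs(res$baseline[, 1] - cubic)),
            0.01 * diff(range(cubic)))
})

test_that("airPLS recovers a linear ramp under two Gaussian peaks", {
  wn <- seq(500, 2000, by = 1)
  ramp <- 0.001 * (wn - 500)
  peaks <- 10 * exp(-(wn - 800)^2 / (2 * 15^2)) +
    10 * exp(-(wn - 1500)^2 / (2 * 15^2))
  res <- baselineAirPLS(make_set(wn, a = ramp + peaks))
  outside <- abs(wn - 800) > 45 & abs(wn - 1500) > 45
  rmse <- sqrt(mean((res$baseline[outside, 1] - ramp[outside])^2))
  expect_lt(rmse, 0.1)  # 1% of the 10-unit peak height
  # corrected is the identity decomposition
  expect_lt(max(abs(res$corrected + res$baseline - (ramp + peaks))), 1e-12)
  # the baseline stays at or below the signal nearly everywhere
  tol <- 1e-3 * sum(abs(ramp + peaks))
  expect_gte(mean(res$baseline[, 1] <= ramp + peaks + tol), 0.95)
})

test_that("sparse airPLS solve agrees with a dense Whittaker oracle", {
  set.seed(21)
  for (P in c(50, 200)) {
    x <- cumsum(rnorm(P))
    w <- runif(P)
    lam <- 100
    sparse <- DBayesNet:::whittaker_solve(x, w, lam)
    expect_lt(max(abs(sparse - dense_whittaker(x, w, lam))), 1e-8)
  }
})

test_that("leave-one-out correlation screening removes only true outliers", {
  set.seed(31)
  wn <- seq(500, 2000, length.out = 200)
  base <- exp(-(wn - 1200)^2 / (2 * 40^2))
  good <- sapply(1:10, function(i) base + rnorm(200, 0, 0.01))
  bad <- rnorm(200, 0, 0.1)
  ss <- SpectrumSet(wn, cbind(good, noise = bad),
                    spectrum_id = c(paste0("g", 1:10), "noise"))
  kept <- removeOutliers(ss, min_corr = 0.9)
  expect_equal(ncol(kept), 10L)
  rep <- outlierReport(kept)
  expect_equal(rep$spectrum_id, "noise")
  expect_lt(rep$correlation, 0.5)

  # vacuous threshold removes nothing
  expect_equal(ncol(removeOutliers(ss, min_corr = -0.999)), 11L)

  # identical spectra all have correlation 1
  same <- SpectrumSet(wn, cbind(a = base, b = base, c = base))
  expect_equal(ncol(removeOutliers(same, min_corr = 0.99)), 3L)

  expect_error(removeOutliers(SpectrumSet(wn, cbind(a = base)), 0.5),
               "at least 3")
})

test_that("area normalization yields unit trapezoid integrals", {
  wn <- seq(500, 2000, by = 1)
  ss <- make_set(wn, a = rep(2, length(wn)),
                 b = 3 * exp(-(wn - 1000)^2 / 500))
  nm <- normalizeArea(ss)
  # constant spectrum over a 1500 cm^-1 span -> 1/1500
  expect_equal(unname(intensities(nm)[1, "a"]), 1 / 1500, tolerance = 1e-12)
  ints <- apply(intensities(nm), 2, pracma::trapz, x = wn)
  expect_lt(max(abs(ints - 1)), 1e-9)
  # scale invariance: scalar multiples normalize identically
  tw <- make_set(wn, a = intensities(ss)[, 2], b = 7 * intensities(ss)[, 2])
  ntw <- intensities(normalizeArea(tw))
  expect_lt(max(abs(ntw[, 1] - ntw[, 2])), 1e-12)
  # idempotence
  expect_lt(max(abs(intensities(normalizeArea(nm)) - intensities(nm))), 1e-12)
  neg <- make_set(wn, a = rep(-1, length(wn)))
  expect_error(normalizeArea(neg), "non-positive")
})

test_that("the pipeline applies stages in the canonical order only", {
  cfg <- preprocessConfig()
  expect_equal(cfg$stages, c("band", "smooth", "baseline", "outlier",
                             "normalize"))
  # reordering normalization before baseline correction is rejected
  expect_error(preprocessConfig(stages = c("band", "smooth", "normalize",
                                           "baseline", "outlier")),
               "canonical order")
  expect_error(preprocessConfig(sg_window = 2, sg_order = 2), "odd")
  expect_error(preprocessConfig(band_low = 900, band_high = 800), "band_low")
  expect_error(preprocessConfig(airpls_tol = 2), "airpls_tol")

  cfg2 <- syntheticConfig(subjects_per_class = 3L, n_points = 301L, seed = 5)
  clean <- preprocessSpectra(simulateSpectra(cfg2))
  wn <- wavenumbers(clean)
  expect_true(all(wn >= 500 & wn <= 2000))
  ints <- apply(intensities(clean), 2, pracma::trapz, x = wn)
  expect_lt(max(abs(ints - 1)), 1e-9)
  log <- S4Vectors::metadata(clean)$preprocess_log
  expect_equal(log$stage, c("input", "band", "smooth", "baseline",
                            "outlier", "normalize"))

  # normalization toggle leaves integrals unconstrained
  loose <- preprocessSpectra(simulateSpectra(cfg2),
                             preprocessConfig(normalization = "none"))
  ints2 <- apply(intensities(loose), 2, pracma::trapz, x = wavenumbers(loose))
  expect_gt(max(abs(ints2 - 1)), 0.1)
})

test_that("the pipeline is near-idempotent on peakless input", {
  wn <- seq(500, 2000, by = 1)
  u <- (wn - 500) / 1500
  ramp <- 1 + 0.5 * u
  cfg <- preprocessConfig(stages = c("band", "smooth", "baseline"))
  one <- preprocessSpectra(make_set(wn, a = ramp, b = 2 * ramp), cfg)
  two <- preprocessSpectra(one, cfg)
  expect_lt(max(abs(intensities(two) - intensities(one))),
            1e-6 * diff(range(ramp)))
})

test_that("mean spectra average correctly overall and per class", {
  wn <- c(500, 600, 700)
  ss <- SpectrumSet(wn, cbind(a = rep(0, 3), b = rep(2, 3)),
                    label = c("x", "y"))
  expect_equal(unname(intensities(meanSpectrum(ss))[, 1]), rep(1, 3))
  by <- meanSpectrum(ss, by_label = TRUE)
  expect_equal(unname(intensities(by)[, "x"]), rep(0, 3))
  expect_equal(unname(intensities(by)[, "y"]), rep(2, 3))
  # a single-spectrum group is its own mean
  solo <- SpectrumSet(wn, cbind(a = 1:3), label = "x")
  expect_equal(unname(intensities(meanSpectrum(solo, TRUE))[, 1]), 1:3)
  expect_error(meanSpectrum(SpectrumSet(wn, cbind(a = 1:3)), TRUE), "label")
})

test_that("class mean spectra differ most at the differential peaks", {
  cfg <- syntheticConfig(subjects_per_class = 25L, noise_sd = 0.005,
                         seed = 42)
  clean <- preprocessSpectra(simulateSpectra(cfg),
                             preprocessConfig(stages = c("band", "smooth",
                                                         "baseline")))
  by <- meanSpectrum(clean, by_label = TRUE)
  delta <- abs(intensities(by)[, "SLE"] - intensities(by)[, "non-SLE"])
  top <- wavenumbers(by)[which.max(delta)]
  # the argmax of the class difference sits on a configured
  # class-differential band
  differential <- c(1653, 1432, 1320, 1246, 1048, 852, 720)
  step <- diff(wavenumbers(by)[1:2])
  expect_lte(min(abs(top - differential)), 2 * step)
  # and the glycogen band is higher in the SLE class
  i1048 <- which.min(abs(wavenumbers(by) - 1048))
  expect_gt(intensities(by)[i1048, "SLE"], intensities(by)[i1048, "non-SLE"])
})

test_that("peak finding reports prominent local maxima as axis values", {
  wn <- seq(500, 2000, by = 1)
  spec <- exp(-(wn - 1048)^2 / (2 * 12^2)) +
    0.8 * exp(-(wn - 1653)^2 / (2 * 12^2))
  pk <- findSpectralPeaks(spec, min_prominence = 0.3, wavenumber = wn)
  expect_equal(pk$wavenumber, c(1048, 1653), tolerance = 1.01)
  # strictly monotone spectrum has no peaks
  expect_equal(nrow(findSpectralPeaks(seq_len(100) * 1.0,
                                      min_prominence = 0)), 0L)
  # threshold above the largest prominence silences everything
  expect_equal(nrow(findSpectralPeaks(spec, min_prominence = 5,
                                      wavenumber = wn)), 0L)
})
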