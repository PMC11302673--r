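test_that("welch_psd finds a sinusoid's spectral line and scales as amplitude^2", {
  fs <- 500
  t <- seq(0, 6, by = 1 / fs)[-1]
  x <- sin(2 * pi * 10 * t)
  p <- welch_psd(x, fs)
  expect_equal(p$freq[which.max(p$psd)], 10)
  # exact quadratic amplitude scaling
  p3 <- welch_psd(3 * x, fs)
  expect_equal(p3$psd, 9 * p$psd, tolerance = 1e-12)
  # zero signal -> zero PSD
  expect_true(all(welch_psd(numeric(2000), fs)$psd == 0))
  # too-short signal refused
  expect_error(welch_psd(rnorm(600), fs), "too short")
})

test_that("welch_psd integrates to the signal variance (Parseval)", {
  errs <- vapply(1:20, function(seed) {
    set.seed(seed)
    x <- rnorm(8000, sd = 2)
    p <- welch_psd(x, fs = 200)
    df <- p$freq[2] - p$freq[1]
    abs(sum(p$psd) * df - var(x)) / var(x)
  }, numeric(1))
  expect_lt(median(errs), 0.1)
  expect_lt(mean(errs), 0.15)
})

test_that("log_spaced_bands covers 2-90 Hz geometrically", {
  b <- log_spaced_bands()
  expect_equal(dim(b), c(32L, 2L))
  expect_identical(unname(b[1, 1]), 2)
  expect_identical(unname(b[32, 2]), 90)
  ratios <- b[, 2] / b[, 1]
  expect_equal(ratios, rep((90 / 2)^(1 / 32), 32), tolerance = 1e-9)
  expect_equal(b[-1, 1], b[-32, 2])    # contiguous
  b1 <- log_spaced_bands(n = 1)
  expect_equal(unname(b1[1, ]), c(2, 90))
})

test_that("band power ratios: uniform density, partition identity, errors", {
  f <- seq(1, 120, by = 0.25)
  flat <- new_spectral_decomposition(f, matrix(1, length(f), 2),
                                     matrix(1, length(f), 2), fs = 500)
  b <- band_power_ratio(flat, rbind(thetaalpha = c(4, 12)), component = "total")
  expect_equal(as.numeric(unclass(b)), rep(8 / 89, 2), tolerance = 1e-12)

  part <- band_power_ratio(flat, log_spaced_bands(2, 90, 32), component = "total")
  # a 2-90 partition holds 88/89 of the 1-90 analysis band
  expect_equal(unname(rowSums(unclass(part))), rep(88 / 89, 2), tolerance = 1e-9)

  zero <- new_spectral_decomposition(f, matrix(0, length(f), 1),
                                     matrix(0, length(f), 1), fs = 500)
  expect_error(band_power_ratio(zero, rbind(c(4, 12))), "zero total power")
  expect_error(band_power_ratio(flat, rbind(c(0.5, 4))), "analysis band")
})

test_that("irasa leaves power laws fixed and captures oscillations as periodic", {
  fs <- 500
  cfg <- synthetic_study_config(
    n_subjects = 1, n_regions = 4, fs_meg = fs, duration_meg = 60,
    conditions = c("rest", "task"), chi_rest = 2, peaks = list(),
    rings = list(list(regions = 1:4, within_rest = 0.3, within_task = 0.5,
                      cross = 0.1)),
    dc_confound = NULL, coupling_strength = 0, seed = 21)
  x <- t(generate_meg_like(cfg, "rest")$data[1, 1, , ])
  dec <- irasa(x, fs)
  sel <- dec$freqs >= 2 & dec$freqs <= 45
  relerr <- abs(dec$aperiodic[sel, ] - dec$total[sel, ]) / dec$total[sel, ]
  expect_lt(median(relerr), 0.1)
  # integrated over the band, total and aperiodic power agree closely
  i_tot <- homscaffold:::band_integral(dec$freqs, dec$total, 2, 45)
  i_ap <- homscaffold:::band_integral(dec$freqs, dec$aperiodic, 2, 45)
  expect_true(all(abs(i_ap - i_tot) / i_tot < 0.1))
  # additivity is exact by construction
  expect_identical(dec$total, dec$aperiodic + dec$periodic)

  # strong 10 Hz oscillation goes to the periodic component
  cfg2 <- synthetic_study_config(
    n_subjects = 1, n_regions = 4, fs_meg = fs, duration_meg = 40,
    conditions = c("rest", "task"), chi_rest = 2,
    peaks = list(list(center = 10, amplitude = 1, bandwidth = 1)),
    rings = list(list(regions = 1:4, within_rest = 0.3, within_task = 0.5,
                      cross = 0.1)),
    dc_confound = NULL, coupling_strength = 0, seed = 22)
  x2 <- t(generate_meg_like(cfg2, "rest")$data[1, 1, , ])
  dec2 <- irasa(x2, fs)
  sel2 <- dec2$freqs >= 9.5 & dec2$freqs <= 10.5
  per <- dec2$periodic[sel2, ]
  expect_gt(sum(pmax(per, 0)) / sum(abs(per)), 0.8)

  # flat white noise: aperiodic tracks total (slope 0 is resampling-invariant);
  # per-bin Welch noise is ~15%, so compare band-integrated power
  set.seed(31)
  w <- matrix(rnorm(fs * 60), ncol = 1)
  decw <- irasa(w, fs)
  iw_tot <- homscaffold:::band_integral(decw$freqs, decw$total, 2, 45)
  iw_ap <- homscaffold:::band_integral(decw$freqs, decw$aperiodic, 2, 45)
  expect_lt(abs(iw_ap - iw_tot) / iw_tot, 0.05)
})

test_that("irasa rejects invalid resampling factors and truncates low fs", {
  x <- rnorm(5000)
  expect_error(irasa(x, 500, hset = c(1, 1.5)), "non-integer")
  expect_error(irasa(x, 500, hset = c(1.5, 2)), "non-integer")
  expect_warning(dec <- irasa(x, 200), "truncated")
  expect_lte(max(dec$freqs), 100)
})

test_that("aperiodic exponent: exact power law, white noise, chi recovery", {
  f <- seq(1, 120, by = 0.5)
  pl <- matrix(3 * f^-3, ncol = 1)
  dec <- new_spectral_decomposition(f, pl, pl, fs = 500)
  expect_equal(unname(aperiodic_exponent(dec, c(2, 45))), 3, tolerance = 1e-12)

  set.seed(8)
  w <- matrix(rnorm(500 * 40), ncol = 1)
  expect_lt(abs(aperiodic_exponent(irasa(w, 500), c(2, 45))), 0.1)

  cfg <- synthetic_study_config(
    n_subjects = 1, n_regions = 4, fs_meg = 500, duration_meg = 60,
    conditions = c("rest", "task"), chi_rest = 2, peaks = list(),
    rings = list(list(regions = 1:4, within_rest = 0.3, within_task = 0.5,
                      cross = 0.1)),
    dc_confound = NULL, coupling_strength = 0, seed = 5)
  x <- t(generate_meg_like(cfg, "rest")$data[1, 1, , ])
  est <- aperiodic_exponent(irasa(x, 500), c(2, 45))
  expect_true(all(abs(est - 2) < 0.1))
})

test_that("epoch averaging preserves grids, identity and linearity", {
  f <- seq(1, 100, by = 0.5)
  mk <- function(scale) new_spectral_decomposition(
    f, matrix(scale, length(f), 2), matrix(scale / 2, length(f), 2), fs = 250)
  avg <- average_epoch_spectra(list(mk(1), mk(3)))
  expect_equal(unname(avg$total[1, 1]), 2)
  expect_equal(unname(avg$aperiodic[1, 1]), 1)
  expect_identical(avg$total, avg$aperiodic + avg$periodic)
  expect_equal(average_epoch_spectra(list(mk(1), mk(1)))$total, mk(1)$total)
  bad <- new_spectral_decomposition(f[-1], matrix(1, length(f) - 1, 2),
                                    matrix(1, length(f) - 1, 2), fs = 250)
  expect_error(average_epoch_spectra(list(mk(1), bad)), "grid")
})
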