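#' Welch power spectral density
#'
#' One-sided PSD by averaging periodograms of Hann-windowed segments
#' (default 2-second windows with 1-second hops, i.e. 50% overlap).  Density
#' normalisation: the integral of the PSD over frequency approximates the
#' signal variance.
#'
#' @param x Numeric vector, or time x region matrix (all columns at once).
#' @param fs Sampling rate in Hz.
#' @param window_sec,hop_sec Segment length and hop in seconds.
#' @return List with `freq` (Hz) and `psd` (frequency x region matrix; a
#'   one-column matrix for vector input).
#' @export
welch_psd <- function(x, fs, window_sec = 2, hop_sec = 1) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  n <- nrow(x); R <- ncol(x)
  nwin <- round(window_sec * fs)
  hop <- round(hop_sec * fs)
  stop_if(nwin < 4L || hop < 1L, "window too short for the sampling rate")
  stop_if(n < 2L * nwin - hop,
          "signal too short: need at least two ", window_sec, "-second windows")
  starts <- seq(1L, n - nwin + 1L, by = hop)
  nseg <- length(starts)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nwin - 1L)) / nwin)   # periodic Hann
  U <- sum(w^2)
  idx <- as.vector(outer(seq_len(nwin), starts - 1L, `+`))
  seg <- x[idx, , drop = FALSE]                 # (nwin*nseg) x R
  dim(seg) <- c(nwin, nseg * R)
  ft <- mvfft(seg * w)
  nf <- nwin %/% 2L + 1L
  p <- Mod(ft[seq_len(nf), , drop = FALSE])^2 / (fs * U)
  scale2 <- rep(2, nf); scale2[1L] <- 1
  if (nwin %% 2L == 0L) scale2[nf] <- 1
  p <- p * scale2
  dim(p) <- c(nf, nseg, R)
  psd <- colMeans(aperm(p, c(2L, 1L, 3L)))   # average periodograms per region
  dim(psd) <- c(nf, R)
  colnames(psd) <- colnames(x)
  list(freq = (0:(nf - 1L)) * fs / nwin, psd = psd)
}

# Fourier-domain resampling of every column of x to n_out samples (the
# irregular-resampling primitive of IRASA).  Band-limited interpolation:
# spectrum copied up to the shared bandwidth, remainder zero-padded/truncated.
resample_fft <- function(x, n_out) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  if (n_out == nrow(x)) return(x)
  resample_from_fft(mvfft(x), nrow(x), n_out)
}

# nearest length with only 2/3/5 prime factors (fast mixed-radix FFT)
good_fft_length <- function(target) {
  smooth <- function(x) {
    for (p in c(2L, 3L, 5L)) while (x %% p == 0L) x <- x %/% p
    x == 1L
  }
  for (d in 0:target) {
    if (smooth(target + d)) return(target + d)
    if (target - d > 1L && smooth(target - d)) return(target - d)
  }
  target
}

# same, from a precomputed forward FFT (shared across IRASA factors);
# inverse transforms are packed two real outputs per complex FFT
resample_from_fft <- function(X, n, n_out) {
  K <- min(n, n_out)
  h <- (K - 1L) %/% 2L
  R <- ncol(X)
  Y <- matrix(0 + 0i, n_out, R)
  Y[1L, ] <- X[1L, ]
  if (h >= 1L) {
    Y[2L:(h + 1L), ] <- X[2L:(h + 1L), , drop = FALSE]
    Y[(n_out - h + 1L):n_out, ] <- X[(n - h + 1L):n, , drop = FALSE]
  }
  if (R %% 2L == 1L) Y <- cbind(Y, 0 + 0i)
  half <- ncol(Y) %/% 2L
  Z <- mvfft(Y[, 2L * seq_len(half) - 1L, drop = FALSE] +
             1i * Y[, 2L * seq_len(half), drop = FALSE], inverse = TRUE)
  out <- matrix(0, n_out, 2L * half)
  out[, 2L * seq_len(half) - 1L] <- Re(Z)
  out[, 2L * seq_len(half)] <- Im(Z)
  out[, seq_len(R), drop = FALSE] / n
}

#' IRASA aperiodic/periodic spectral decomposition
#'
#' Irregular-resampling auto-spectral analysis: for each resampling factor h,
#' the signal is resampled by h and by 1/h, the Welch spectra of the pair are
#' geometrically averaged (which leaves scale-free 1/f^chi spectra fixed but
#' displaces narrowband peaks), and the aperiodic spectrum is the median of
#' these averages across factors.  The periodic spectrum is total minus
#' aperiodic, exactly, on the shared grid.
#'
#' @param x Numeric vector or time x region matrix.
#' @param fs Sampling rate (Hz).  If below 240 Hz the 1-120 Hz estimation
#'   band is truncated at Nyquist, with a warning.
#' @param hset Resampling factors: non-integer values > 1.
#' @param window_sec,hop_sec Welch parameters, as in `welch_psd()`.
#' @return A `spectral_decomposition`: `freqs`, matrices `total`, `aperiodic`,
#'   `periodic` (frequency x region), `fs`, `estimation_band`, `analysis_band`.
#' @export
irasa <- function(x, fs, hset = seq(1.1, 1.9, by = 0.05),
                  window_sec = 2, hop_sec = 1) {
  stop_if(any(hset <= 1) || any(hset %% 1 == 0),
          "hset must contain non-integer factors > 1")
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  n <- nrow(x); R <- ncol(x)
  base <- welch_psd(x, fs, window_sec, hop_sec)
  nf <- length(base$freq)
  geo <- matrix(0, nf * R, length(hset))
  X <- mvfft(x)
  for (q in seq_along(hset)) {
    h <- hset[q]
    n_up <- good_fft_length(round(n * h))
    n_dn <- good_fft_length(round(n^2 / n_up))   # keep the pair reciprocal
    up <- resample_from_fft(X, n, n_up)
    dn <- resample_from_fft(X, n, n_dn)
    stop_if(nrow(dn) < 2L * round(window_sec * fs) - round(hop_sec * fs),
            "signal too short for IRASA resampling at h = ", h)
    pu <- welch_psd(up, fs, window_sec, hop_sec)$psd
    pd <- welch_psd(dn, fs, window_sec, hop_sec)$psd
    geo[, q] <- sqrt(as.vector(pu) * as.vector(pd))
  }
  ap <- matrix(row_medians_small(geo), nf, R)
  est_hi <- 120
  if (fs < 240) {
    est_hi <- fs / 2
    warning("fs < 240 Hz: estimation band truncated at Nyquist (",
            est_hi, " Hz)", call. = FALSE)
  }
  keep <- base$freq >= 1 & base$freq <= est_hi
  new_spectral_decomposition(
    freqs = base$freq[keep],
    total = base$psd[keep, , drop = FALSE],
    aperiodic = ap[keep, , drop = FALSE],
    fs = fs, estimation_band = c(1, est_hi),
    analysis_band = c(1, min(90, est_hi)),
    labels = colnames(x))
}

#' Construct a spectral decomposition
#'
#' Low-level constructor (also useful for analytic fixtures): the periodic
#' component is defined as `total - aperiodic` so additivity holds exactly.
#'
#' @param freqs Frequency grid (Hz, increasing).
#' @param total,aperiodic Nonnegative frequency x region matrices.
#' @param fs Sampling rate.
#' @param estimation_band,analysis_band Length-2 Hz ranges.
#' @param labels Region labels.
#' @export
new_spectral_decomposition <- function(freqs, total, aperiodic, fs,
                                       estimation_band = c(1, 120),
                                       analysis_band = c(1, 90),
                                       labels = NULL) {
  total <- as.matrix(total); aperiodic <- as.matrix(aperiodic)
  stopifnot(length(freqs) == nrow(total), identical(dim(total), dim(aperiodic)),
            !is.unsorted(freqs), all(total >= 0), all(aperiodic >= 0))
  if (is.null(labels)) labels <- colnames(total)
  if (is.null(labels)) labels <- paste0("R", seq_len(ncol(total)))
  colnames(total) <- colnames(aperiodic) <- labels
  structure(list(freqs = freqs, total = total, aperiodic = aperiodic,
                 periodic = total - aperiodic, fs = fs,
                 estimation_band = estimation_band,
                 analysis_band = analysis_band, labels = labels),
            class = "spectral_decomposition")
}

#' Aperiodic exponent by log-log regression
#'
#' Least-squares slope of log10 aperiodic power against log10 frequency over
#' a band; the exponent chi is minus that slope.
#'
#' @param decomp A `spectral_decomposition`.
#' @param band Length-2 Hz range (must lie inside the analysis band).
#' @return Named numeric vector of exponents, one per region.
#' @export
aperiodic_exponent <- function(decomp, band = c(2, 45)) {
  stopifnot(inherits(decomp, "spectral_decomposition"))
  sel <- decomp$freqs >= band[1L] & decomp$freqs <= band[2L]
  stop_if(sum(sel) < 3L, "fewer than 3 frequency bins in band")
  p <- decomp$aperiodic[sel, , drop = FALSE]
  stop_if(any(p <= 0), "non-positive aperiodic PSD values in band")
  lf <- log10(decomp$freqs[sel])
  lf <- lf - mean(lf)
  slope <- colSums(log10(p) * lf) / sum(lf^2)
  stats::setNames(-slope, decomp$labels)
}

#' Logarithmically spaced frequency bands
#'
#' `n` contiguous bands whose `n + 1` edges are geometrically spaced from
#' `lo` to `hi` (default: the 32-band 2-90 Hz scheme).
#'
#' @param lo,hi Band range in Hz.
#' @param n Number of bands.
#' @return n x 2 matrix with columns `lo`, `hi`.
#' @export
log_spaced_bands <- function(lo = 2, hi = 90, n = 32L) {
  stopifnot(lo < hi, n >= 1L)
  edges <- exp(seq(log(lo), log(hi), length.out = n + 1L))
  edges[1L] <- lo; edges[n + 1L] <- hi
  cbind(lo = edges[-(n + 1L)], hi = edges[-1L])
}

#' Canonical electrophysiology bands
#'
#' delta 2-4, theta 4-8, alpha 8-12, beta 12-25, gamma 25-90 Hz; the combined
#' theta-alpha band is 4-12 Hz.
#'
#' @return 5 x 2 matrix with row names.
#' @export
canonical_bands <- function() {
  b <- rbind(delta = c(2, 4), theta = c(4, 8), alpha = c(8, 12),
             beta = c(12, 25), gamma = c(25, 90))
  colnames(b) <- c("lo", "hi")
  b
}

# trapezoidal integral of each column of Y over [lo, hi], with linear
# interpolation at the band edges
band_integral <- function(f, Y, lo, hi) {
  stopifnot(lo < hi, lo >= f[1L], hi <= f[length(f)])
  sel <- which(f > lo & f < hi)
  interp_row <- function(x0) {
    j <- findInterval(x0, f)
    j <- min(max(j, 1L), length(f) - 1L)
    a <- (x0 - f[j]) / (f[j + 1L] - f[j])
    Y[j, ] * (1 - a) + Y[j + 1L, ] * a
  }
  fg <- c(lo, f[sel], hi)
  Yg <- rbind(interp_row(lo), Y[sel, , drop = FALSE], interp_row(hi))
  d <- diff(fg)
  colSums((Yg[-1L, , drop = FALSE] + Yg[-nrow(Yg), , drop = FALSE]) / 2 * d)
}

#' Band power ratios
#'
#' BPR(region, band) = integral of the chosen spectral component over the
#' band, divided by the integral of a full-analysis-band reference.  The
#' default reference is total power over the whole 1-90 Hz analysis band,
#' making band ratios comparable across regions and conditions; the
#' aperiodic-only reference is available as an option.
#'
#' @param decomp A `spectral_decomposition`.
#' @param band_edges n x 2 matrix of band (lo, hi) in Hz, inside the analysis
#'   band.
#' @param component Which component to integrate: "aperiodic" (default),
#'   "total" or "periodic".
#' @param denominator Full-band reference: "total_fullband" or
#'   "aperiodic_fullband".
#' @return A `band_power_ratios`: region x band matrix with attributes
#'   `band_edges`, `component`, `denominator`.
#' @export
band_power_ratio <- function(decomp, band_edges = canonical_bands(),
                             component = c("aperiodic", "total", "periodic"),
                             denominator = c("total_fullband", "aperiodic_fullband")) {
  stopifnot(inherits(decomp, "spectral_decomposition"))
  component <- match.arg(component)
  denominator <- match.arg(denominator)
  band_edges <- as.matrix(band_edges)
  ab <- decomp$analysis_band
  stop_if(any(band_edges[, 1L] < ab[1L] - 1e-9) || any(band_edges[, 2L] > ab[2L] + 1e-9),
          "bands must lie within the analysis band [", ab[1L], ", ", ab[2L], "] Hz")
  Yc <- decomp[[component]]
  Yd <- if (denominator == "total_fullband") decomp$total else decomp$aperiodic
  ref <- band_integral(decomp$freqs, Yd, ab[1L], ab[2L])
  stop_if(any(ref <= 0), "zero total power in the analysis band")
  bpr <- vapply(seq_len(nrow(band_edges)), function(b) {
    band_integral(decomp$freqs, Yc, band_edges[b, 1L], band_edges[b, 2L]) / ref
  }, numeric(ncol(Yc)))
  bpr <- matrix(bpr, nrow = ncol(Yc),
                dimnames = list(decomp$labels, rownames(band_edges)))
  structure(bpr, band_edges = band_edges, component = component,
            denominator = denominator, class = "band_power_ratios")
}

#' Average spectral decompositions across epochs
#'
#' Pointwise arithmetic mean of each component across epoch-level
#' decompositions on identical frequency grids; preserves the
#' total = aperiodic + periodic identity by linearity.
#'
#' @param decomps List of `spectral_decomposition` with identical grids.
#' @return A `spectral_decomposition`.
#' @export
average_epoch_spectra <- function(decomps) {
  stopifnot(length(decomps) >= 1L)
  d1 <- decomps[[1L]]
  for (d in decomps) {
    stopifnot(inherits(d, "spectral_decomposition"))
    stop_if(!isTRUE(all.equal(d$freqs, d1$freqs)), "frequency grid mismatch")
  }
  k <- length(decomps)
  new_spectral_decomposition(
    freqs = d1$freqs,
    total = Reduce(`+`, lapply(decomps, `[[`, "total")) / k,
    aperiodic = Reduce(`+`, lapply(decomps, `[[`, "aperiodic")) / k,
    fs = d1$fs, estimation_band = d1$estimation_band,
    analysis_band = d1$analysis_band, labels = d1$labels)
}

#' @export
print.spectral_decomposition <- function(x, ...) {
  cat("spectral decomposition:", length(x$freqs), "bins (",
      min(x$freqs), "-", max(x$freqs), "Hz ),", ncol(x$total), "regions\n")
  invisible(x)
}
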