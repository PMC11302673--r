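#' Configuration of a paired synthetic study
#'
#' Defines a bimodal synthetic study: BOLD-like regional time series whose
#' connectomes carry planted persistent rings (cycles of strongly correlated
#' regions with weaker chords), and paired MEG-like series that are sums of
#' 1/f^chi aperiodic processes, narrowband oscillators and white noise.  Each
#' ring's within-ring correlation differs between rest and task, planting a
#' persistence centrality change of known sign per region, and the task
#' aperiodic exponent of each modulated region is offset so that its
#' theta-alpha aperiodic band power changes in the same direction, scaled by
#' `coupling_strength`.
#'
#' Defaults mirror a small simultaneous-cohort design: one resting condition
#' plus eight task conditions (four motor, four working-memory), 10 subjects,
#' 30 regions.
#'
#' @param n_subjects,n_regions,n_timepoints_bold Study dimensions.
#' @param fs_meg,duration_meg MEG-like sampling rate (Hz) and duration (s;
#'   at least 12 s so Welch has enough 2-s segments).
#' @param conditions Condition labels; the first is the resting state.
#' @param rings List of planted rings, each a list with `regions` (>= 4
#'   indices), `within_rest`, `within_task` (within-ring correlations; their
#'   difference plants the PC change: positive sign when the ring strengthens
#'   under task), and `cross` (chord/cross correlation).
#' @param dc_confound Optional degree confound: a block of regions whose
#'   mutual correlations change uniformly between rest and task (`regions`,
#'   `r_rest`, `r_task`).  A dense clique fills immediately in the flag
#'   complex, so it moves degree centrality strongly while leaving
#'   persistence centrality and the spectral coupling untouched -
#'   dissociating Delta DC from Delta PC as observed in real connectomes.
#'   `NULL` disables it.
#' @param chi_rest Baseline aperiodic exponent (all regions, resting state).
#' @param delta_chi Task exponent offset magnitude; modulated regions get
#'   `chi_rest - delta_chi * coupling_strength * sign` under task (a shallower
#'   slope raises theta-alpha band power relative to the 1-90 Hz total).
#' @param peaks List of oscillatory peaks, each `list(center, amplitude,
#'   bandwidth)` in Hz; applied to every region in every condition, so the
#'   periodic component carries no planted effect.
#' @param coupling_strength Scalar in `[0, 1]` linking the planted PC change to
#'   the theta-alpha aperiodic power change; 0 = no coupling (null study).
#' @param hset IRASA resampling factors used by `run_study()`.
#' @param seed Master seed; all per-(subject, condition) streams derive from
#'   it.
#' @return A validated `synthetic_study_config`.
#' @export
synthetic_study_config <- function(n_subjects = 10L, n_regions = 30L,
                                   n_timepoints_bold = 400L,
                                   fs_meg = 250, duration_meg = 12,
                                   conditions = c("rest",
                                                  "motor_lh", "motor_rh",
                                                  "motor_lf", "motor_rf",
                                                  "wm0_faces", "wm0_tools",
                                                  "wm2_faces", "wm2_tools"),
                                   rings = NULL,
                                   dc_confound = list(regions = 13:20,
                                                      r_rest = 0.15,
                                                      r_task = 0.45),
                                   chi_rest = 1.5, delta_chi = 0.4,
                                   peaks = list(list(center = 10, amplitude = 1,
                                                     bandwidth = 1)),
                                   coupling_strength = 1,
                                   hset = seq(1.1, 1.9, by = 0.2),
                                   seed = 1L) {
  if (is.null(rings)) {
    rings <- list(
      list(regions = 1:6, within_rest = 0.35, within_task = 0.65, cross = 0.1),
      list(regions = 7:12, within_rest = 0.65, within_task = 0.35, cross = 0.1))
  }
  stop_if(length(conditions) < 2L, "need a resting condition and >= 1 task")
  stop_if(anyDuplicated(conditions) > 0L, "duplicate condition labels")
  for (rg in rings) {
    stop_if(length(rg$regions) < 4L,
            "ring subsets need >= 4 regions (a 3-clique fills and yields no H1)")
    stop_if(max(rg$regions) > n_regions || min(rg$regions) < 1L,
            "ring regions out of range")
    cors <- c(rg$within_rest, rg$within_task, rg$cross)
    stop_if(any(cors <= -1 | cors >= 1), "ring correlations must lie in (-1, 1)")
    stop_if(rg$cross >= min(rg$within_rest, rg$within_task),
            "cross correlation must be below the within-ring correlation")
  }
  ringsets <- unlist(lapply(rings, `[[`, "regions"))
  stop_if(anyDuplicated(ringsets) > 0L, "rings must not share regions")
  if (!is.null(dc_confound)) {
    stop_if(max(dc_confound$regions) > n_regions || min(dc_confound$regions) < 1L,
            "confound regions out of range")
    stop_if(any(dc_confound$regions %in% ringsets),
            "degree confound must not overlap planted rings")
    stop_if(any(c(dc_confound$r_rest, dc_confound$r_task) <= -1) ||
            any(c(dc_confound$r_rest, dc_confound$r_task) >= 1),
            "confound correlations must lie in (-1, 1)")
  }
  stop_if(chi_rest <= 0, "aperiodic exponent must be positive")
  for (p in peaks) stop_if(p$center <= 0 || p$center >= fs_meg / 2,
                           "peak centers must lie in (0, fs/2)")
  stop_if(duration_meg < 12, "duration must be >= 12 s for stable Welch spectra")
  stop_if(coupling_strength < 0 || coupling_strength > 1,
          "coupling_strength must lie in [0, 1]")
  # planted PC-change sign per region
  mod <- integer(n_regions)
  for (rg in rings) mod[rg$regions] <- sign(rg$within_task - rg$within_rest)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_regions = as.integer(n_regions),
                 n_timepoints_bold = as.integer(n_timepoints_bold),
                 fs_meg = fs_meg, duration_meg = duration_meg,
                 conditions = conditions, rings = rings,
                 dc_confound = dc_confound,
                 chi_rest = chi_rest, delta_chi = delta_chi, peaks = peaks,
                 coupling_strength = coupling_strength, hset = hset,
                 seed = as.integer(seed), modulation = mod,
                 regions = paste0("R", seq_len(n_regions))),
            class = "synthetic_study_config")
}

regional_ts_set <- function(data, modality, fs, subjects, conditions, regions) {
  structure(list(data = data, modality = modality, fs = fs,
                 subjects = subjects, conditions = conditions,
                 regions = regions), class = "regional_ts_set")
}

# target correlation matrix for one condition, projected to the nearest
# feasible (positive semi-definite, unit-diagonal) matrix
target_correlation <- function(config, condition) {
  n <- config$n_regions
  C <- diag(n)
  is_task <- condition != config$conditions[1L]
  for (rg in config$rings) {
    reg <- rg$regions; k <- length(reg)
    within <- if (is_task) rg$within_task else rg$within_rest
    sub <- matrix(rg$cross, k, k)
    diag(sub) <- 1
    for (q in seq_len(k)) {
      q2 <- if (q == k) 1L else q + 1L
      sub[q, q2] <- sub[q2, q] <- within
    }
    C[reg, reg] <- sub
  }
  if (!is.null(config$dc_confound)) {
    cf <- config$dc_confound
    rr <- if (is_task) cf$r_task else cf$r_rest
    sub <- matrix(rr, length(cf$regions), length(cf$regions))
    diag(sub) <- 1
    C[cf$regions, cf$regions] <- sub
  }
  e <- eigen(C, symmetric = TRUE)
  v <- pmax(e$values, 1e-6)
  C2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(C2))
  C2 / outer(d, d)
}

#' Generate BOLD-like regional time series
#'
#' Gaussian latent-factor construction: each subject's regional series are
#' drawn from a multivariate normal whose correlation matrix carries the
#' planted rings of the configuration (strong correlations around each ring,
#' weak chords), projected to the nearest positive semi-definite correlation
#' matrix; regions outside every ring are independent noise.  The empirical
#' connectome therefore contains a high-correlation cycle whose chords are
#' weaker, guaranteeing an H1 feature.  Deterministic given the config seed.
#'
#' @param config A `synthetic_study_config`.
#' @param condition One of `config$conditions`.
#' @return A `regional_ts_set` (bold-like) with data array
#'   subject x 1 x region x time.
#' @export
generate_bold_like <- function(config, condition) {
  stopifnot(inherits(config, "synthetic_study_config"))
  ci <- match(condition, config$conditions)
  stop_if(is.na(ci), "unknown condition: ", condition)
  n <- config$n_regions; Tn <- config$n_timepoints_bold
  if (Tn < 3L * n) warning("fewer than 3 x n_regions timepoints: unstable FC",
                           call. = FALSE)
  L <- chol(target_correlation(config, condition))
  data <- array(NA_real_, c(config$n_subjects, 1L, n, Tn))
  for (s in seq_len(config$n_subjects)) {
    z <- with_seed(derive_seed(config$seed, s, ci, 1L),
                   matrix(rnorm(Tn * n), Tn, n))
    data[s, 1L, , ] <- t(z %*% L)
  }
  regional_ts_set(data, "bold-like", NA_real_, seq_len(config$n_subjects),
                  condition, config$regions)
}

#' Generate MEG-like regional time series
#'
#' Per region, the signal is the sum of three independent components built by
#' spectral shaping of white noise: a 1/f^chi aperiodic process (exact target
#' power law in expectation), narrowband Gaussian-profile oscillators from
#' the configured peaks, and a white measurement-noise floor.  Under task
#' conditions the aperiodic exponent of each modulated region is offset by
#' `-delta_chi * coupling_strength * sign(planted PC change)`, which moves its
#' theta-alpha aperiodic band power in the direction of the planted PC
#' change.  Deterministic given the config seed.
#'
#' @inheritParams generate_bold_like
#' @return A `regional_ts_set` (meg-like) with sampling rate `fs_meg`.
#' @export
generate_meg_like <- function(config, condition) {
  stopifnot(inherits(config, "synthetic_study_config"))
  ci <- match(condition, config$conditions)
  stop_if(is.na(ci), "unknown condition: ", condition)
  fs <- config$fs_meg
  n <- round(fs * config$duration_meg)
  R <- config$n_regions
  is_task <- ci > 1L
  chi <- rep(config$chi_rest, R)
  if (is_task) {
    chi <- chi - config$delta_chi * config$coupling_strength * config$modulation
  }
  # two-sided frequency grid magnitudes for shaping
  f <- (0:(n - 1L)) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]
  fclip <- pmax(f, 0.5)                      # keep the DC region bounded
  amp_peak <- numeric(n)
  for (p in config$peaks) {
    amp_peak <- amp_peak +
      p$amplitude * exp(-(f - p$center)^2 / (2 * p$bandwidth^2))
  }
  amp_peak <- sqrt(amp_peak)
  white_sd <- 0.001
  data <- array(NA_real_, c(config$n_subjects, 1L, R, n))
  for (s in seq_len(config$n_subjects)) {
    z <- with_seed(derive_seed(config$seed, s, ci, 2L),
                   matrix(rnorm(3L * n * R), n, 3L * R))
    # scaled so that amp is in the same per-sample units as a plain noise sd:
    # a flat amp = a reproduces white noise of standard deviation a
    shape <- function(w, amp) Re(mvfft(mvfft(w) * amp, inverse = TRUE)) / n
    ap <- shape(z[, seq_len(R), drop = FALSE],
                outer(fclip, chi, function(fr, ch) fr^(-ch / 2)))
    pk <- shape(z[, R + seq_len(R), drop = FALSE],
                matrix(amp_peak, n, R))
    wn <- white_sd * z[, 2L * R + seq_len(R), drop = FALSE]
    data[s, 1L, , ] <- t(ap + pk + wn)
  }
  regional_ts_set(data, "meg-like", fs, seq_len(config$n_subjects),
                  condition, config$regions)
}

#' Analytic ring connectome fixture
#'
#' Exact correlation matrix of an n-ring: consecutive regions get `ring_r`,
#' every other pair `chord_r`.  Downstream, the pseudo-distances put ring
#' edges at 1 - ring_r and chords at 1 - chord_r, so the H1 barcode has
#' exactly one interval and the volume-optimal cycle is the planted ring.
#'
#' @param n Number of regions (>= 4; a 3-ring fills immediately).
#' @param ring_r,chord_r Ring-edge and chord correlations,
#'   0 < chord_r < ring_r < 1.
#' @return A `functional_connectome`.
#' @export
fixture_ring_connectome <- function(n, ring_r, chord_r) {
  stop_if(n < 4L, "ring fixtures need n >= 4")
  stop_if(!(chord_r > 0 && ring_r < 1 && chord_r < ring_r),
          "need 0 < chord_r < ring_r < 1")
  r <- matrix(chord_r, n, n)
  diag(r) <- 1
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    r[i, j] <- r[j, i] <- ring_r
  }
  functional_connectome(r)
}

#' @export
print.synthetic_study_config <- function(x, ...) {
  cat("synthetic study:", x$n_subjects, "subjects x", length(x$conditions),
      "conditions x", x$n_regions, "regions;", length(x$rings),
      "planted rings; coupling", x$coupling_strength, "; seed", x$seed, "\n")
  invisible(x)
}

#' @export
print.regional_ts_set <- function(x, ...) {
  d <- dim(x$data)
  cat(x$modality, "time series:", d[1L], "subjects x", d[2L], "condition x",
      d[3L], "regions x", d[4L], "samples\n")
  invisible(x)
}
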