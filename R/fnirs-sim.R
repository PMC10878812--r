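# Synthetic two-wavelength fNIRS with known evoked amplitudes.

# Haemoglobin extinction coefficients at the two laser wavelengths,
# 1/(cm * M), from the W. B. Gratzer compilation as shipped with the
# standard NIRS analysis toolboxes.
EXTINCTION <- matrix(
  c(1486.5865, 3843.707,   # 760 nm: HbO, HbR
    2526.391, 1798.643),   # 850 nm: HbO, HbR
  nrow = 2, byrow = TRUE,
  dimnames = list(c("760", "850"), c("hbo", "hbr"))
)

#' Canonical haemodynamic response function
#'
#' Double-gamma impulse response (peak 6 s, undershoot 16 s, undershoot
#' ratio 1/6), the standard shape for modelling evoked haemodynamics.
#'
#' @param t time points, seconds.
#' @param peak_delay,undershoot_delay gamma peak locations, s.
#' @param undershoot_ratio relative undershoot amplitude.
#' @return HRF values at `t` (unit peak of the positive lobe is not
#'   enforced; regressors are normalized downstream).
#' @export
canonical_hrf <- function(t, peak_delay = 6, undershoot_delay = 16,
                          undershoot_ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak_delay, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_delay, rate = 1)
  h[t < 0] <- 0
  h
}

# Task regressor: `duration`-s boxcar at each onset convolved with the
# canonical HRF, scaled so an isolated block's response peaks at 1 (so GLM
# amplitudes are in concentration units). Shared by the generator and
# build_design_matrix so the forward and inverse models match exactly.
task_regressor <- function(onsets, n, rate, duration = 16) {
  dt <- 1 / rate
  hrf <- canonical_hrf(seq(0, 40, by = dt))
  box1 <- rep(1, max(1L, round(duration * rate)))
  unit <- stats::convolve(c(box1, numeric(length(hrf))), rev(hrf),
                          type = "open") * dt
  scale <- max(unit)
  stim <- numeric(n)
  idx <- round(onsets * rate) + 1L
  idx <- idx[idx >= 1 & idx <= n]
  for (i in idx) {
    j <- i:min(n, i + length(box1) - 1L)
    stim[j] <- stim[j] + 1
  }
  reg <- stats::convolve(c(stim, numeric(length(hrf))), rev(hrf),
                         type = "open")[seq_len(n)] * dt
  reg / scale
}

# Zero-phase low-pass with mean removal and odd-reflection padding, taming
# the filter's zero-state edge transients (a constant series passes through
# exactly).
pad_filtfilt <- function(bf, x) {
  n <- length(x)
  np <- min(n - 1, 120L)
  mu <- mean(x)
  xc <- x - mu
  xp <- c(2 * xc[1] - rev(xc[2:(np + 1)]), xc,
          2 * xc[n] - rev(xc[(n - np):(n - 1)]))
  y <- signal::filtfilt(bf, xp)
  y[(np + 1):(np + n)] + mu
}

# Shared anti-alias decimation: zero-phase low-pass then interpolation onto
# the target grid. Returns list(values, time).
decimate_series <- function(values, rate, target_hz, cutoff_hz = 0.3) {
  stopifnot(target_hz < rate)
  bf <- signal::butter(4, min(cutoff_hz, 0.45 * target_hz * 2) / (rate / 2),
                       type = "low")
  filt <- apply(as.matrix(values), 2, function(col) pad_filtfilt(bf, col))
  n <- nrow(as.matrix(values))
  time <- (seq_len(n) - 1) / rate
  new_time <- seq(0, time[n], by = 1 / target_hz)
  out <- apply(as.matrix(filt), 2,
               function(col) stats::approx(time, col, xout = new_time)$y)
  list(values = as.matrix(out), time = new_time)
}

#' Parameters for the fNIRS forward generator
#'
#' @param true_amplitude evoked amplitude table: tibble with `roi`,
#'   `block_type`, `chromophore` (`hbo`/`hbr`) and `amplitude` (uM).
#'   Default: HbO 0.8 uM in AllGo and 1.2 uM in Mixed blocks for every ROI,
#'   HbR at the canonical -1/3 of HbO.
#' @param systemic_amplitude scalp/systemic signal amplitude, uM (applied
#'   to all channels with random per-channel gains).
#' @param mayer_freq Mayer-wave frequency, Hz.
#' @param ar1_rho lag-1 autocorrelation of the instrument noise, |rho| < 1.
#' @param noise_sd marginal SD of the AR(1) noise, uM.
#' @param sampling_rate acquisition rate, Hz.
#' @param ppf partial pathlength factor of the Beer-Lambert step.
#' @param seed integer seed.
#' @return List of class `fnirs_params`.
#' @export
fnirs_params <- function(true_amplitude = NULL, systemic_amplitude = 0.6,
                         mayer_freq = 0.095, ar1_rho = 0.6, noise_sd = 0.4,
                         sampling_rate = 4.5, ppf = 0.1, seed = 1L) {
  stopifnot(abs(ar1_rho) < 1, sampling_rate > 0, noise_sd >= 0,
            systemic_amplitude >= 0, ppf > 0)
  structure(
    list(true_amplitude = true_amplitude,
         systemic_amplitude = systemic_amplitude, mayer_freq = mayer_freq,
         ar1_rho = ar1_rho, noise_sd = noise_sd,
         sampling_rate = sampling_rate, ppf = ppf, seed = as.integer(seed)),
    class = "fnirs_params"
  )
}

default_amplitudes <- function(rois, hbo_allgo = 0.8, hbo_mixed = 1.2) {
  tidyr::expand_grid(
    roi = rois, block_type = c("AllGo", "Mixed"), chromophore = c("hbo", "hbr")
  ) |>
    dplyr::mutate(
      amplitude = ifelse(.data$block_type == "AllGo", hbo_allgo, hbo_mixed) *
        ifelse(.data$chromophore == "hbr", -1 / 3, 1)
    )
}

ar1_noise <- function(n, rho, sd_marginal) {
  if (sd_marginal == 0) return(numeric(n))
  if (rho == 0) return(rnorm(n, 0, sd_marginal))
  as.numeric(stats::arima.sim(list(ar = rho), n,
                              sd = sd_marginal * sqrt(1 - rho^2)))
}

#' Simulate a raw two-wavelength fNIRS recording
#'
#' Forward model with known ground truth: per-ROI evoked concentration
#' responses (16-s boxcar convolved with the canonical HRF, amplitude in
#' uM), a shared systemic component (slow drift plus a Mayer-wave
#' sinusoid) added to every channel with random per-channel gains, and
#' AR(1) instrument noise. Short channels carry systemic signal and noise
#' but no evoked component. Concentrations are converted to two-wavelength
#' intensity by the forward modified Beer-Lambert law, so the analysis
#' pipeline's optical-density inversion recovers them.
#'
#' @param params an [fnirs_params()] object.
#' @param events block events: tibble with `onset` (s), `condition`,
#'   `duration` (s), e.g. from a task schedule; blocks must not overlap
#'   within 16 s.
#' @param montage a montage tibble (see [default_montage()]).
#' @param duration_s recording length; default covers the last event plus
#'   40 s.
#' @return An `fnirs_series` of kind `"intensity"`, with the generating
#'   truth in `$truth`.
#' @export
simulate_fnirs <- function(params = fnirs_params(),
                           events, montage = default_montage(),
                           duration_s = NULL) {
  stopifnot(inherits(params, "fnirs_params"))
  events <- tibble::as_tibble(events)
  if (any(diff(sort(events$onset)) < 16)) {
    stop("simulate_fnirs(): overlapping blocks (onsets closer than 16 s)")
  }
  rate <- params$sampling_rate
  duration_s <- duration_s %||% (max(events$onset) + 40)
  n <- floor(duration_s * rate) + 1L
  time <- (seq_len(n) - 1) / rate
  amp <- params$true_amplitude %||% default_amplitudes(unique(montage$roi))
  with_seed(params$seed, {
    regs <- lapply(
      setNames(unique(events$condition), unique(events$condition)),
      function(cond) task_regressor(events$onset[events$condition == cond],
                                    n, rate)
    )
    # shared systemic signals (uM scale before per-channel gains): slow
    # drift, Mayer wave, and broadband slow vasomotion overlapping the task
    # frequency band (the component only short-channel regression can remove)
    drift <- sin(2 * pi * 0.004 * time + runif(1, 0, 2 * pi)) +
      0.5 * (time - mean(time)) / max(time)
    mayer <- sin(2 * pi * params$mayer_freq * time + runif(1, 0, 2 * pi))
    vaso_f <- runif(3, 0.015, 0.08)
    vaso_ph <- runif(3, 0, 2 * pi)
    vaso <- colSums(sin(outer(2 * pi * vaso_f, time) + vaso_ph)) / sqrt(3)
    conc <- matrix(0, n, 2 * nrow(montage))
    info <- tidyr::expand_grid(
      channel = montage$channel, chromophore = c("hbo", "hbr")
    ) |>
      dplyr::left_join(montage, by = "channel")
    for (k in seq_len(nrow(info))) {
      ch <- info$channel[k]; chrom <- info$chromophore[k]
      y <- numeric(n)
      if (!info$is_short[k]) {
        for (cond in names(regs)) {
          a <- amp$amplitude[amp$roi == info$roi[k] &
                               amp$block_type == cond &
                               amp$chromophore == chrom]
          if (length(a) == 1 && a != 0) y <- y + a * regs[[cond]]
        }
      }
      if (params$systemic_amplitude > 0) {
        gains <- runif(3, 0.5, 1.5) * params$systemic_amplitude *
          ifelse(chrom == "hbr", 0.3, 1)
        y <- y + gains[1] * drift + gains[2] * mayer + gains[3] * vaso
      }
      y <- y + ar1_noise(n, params$ar1_rho, params$noise_sd)
      conc[, k] <- y
    }
    # forward Beer-Lambert to two-wavelength intensity
    wl_info <- tidyr::expand_grid(
      channel = montage$channel, wavelength = c(760L, 850L)
    ) |>
      dplyr::left_join(montage, by = "channel")
    inten <- matrix(0, n, nrow(wl_info))
    for (k in seq_len(nrow(wl_info))) {
      ch <- wl_info$channel[k]
      wl <- as.character(wl_info$wavelength[k])
      hbo <- conc[, which(info$channel == ch & info$chromophore == "hbo")]
      hbr <- conc[, which(info$channel == ch & info$chromophore == "hbr")]
      L_cm <- wl_info$separation_mm[k] / 10
      od <- (EXTINCTION[wl, "hbo"] * hbo + EXTINCTION[wl, "hbr"] * hbr) *
        1e-6 * L_cm * params$ppf
      inten[, k] <- exp(-od)
    }
    new_fnirs_series(
      inten, wl_info, time, rate, montage, events, "intensity",
      extra = list(truth = list(amplitude = amp, params = params),
                   native_rate = rate, native_n = n)
    )
  })
}
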