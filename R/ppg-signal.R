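#' A dual-wavelength PPG waveform
#'
#' Container for a reflective photoplethysmogram recorded simultaneously at
#' 660 nm (red) and 880 nm (near infrared), sampled at `fs` Hz. Both channels
#' must be the same length, at least two seconds long, and finite.
#'
#' @param red,ir Numeric sample vectors (intensity, arbitrary units).
#' @param fs Sampling frequency, Hz.
#' @return An object of class `ppg_waveform`.
#' @export
ppg_waveform <- function(red, ir, fs) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive sampling frequency in Hz",
         call. = FALSE)
  }
  if (length(red) != length(ir)) {
    stop("red and ir channels must have the same length", call. = FALSE)
  }
  if (length(red) < 2 * fs) {
    stop("waveform too short: need at least 2*fs samples (2 s)",
         call. = FALSE)
  }
  if (any(!is.finite(red)) || any(!is.finite(ir))) {
    stop("PPG channels must be finite", call. = FALSE)
  }
  structure(list(red = as.numeric(red), ir = as.numeric(ir), fs = fs),
            class = "ppg_waveform")
}

#' Detect systolic peaks in a PPG channel
#'
#' Conditions the channel with a zero-phase band-pass filter over the
#' cardiac band (0.5-8 Hz, 2nd-order Butterworth run forward and backward),
#' then searches for local maxima subject to a minimum inter-peak distance
#' of `fs * 60 / max_rate` samples (default ceiling 220 bpm) and a relative
#' prominence floor on the filtered amplitude. Deterministic for a fixed
#' input.
#'
#' @param x Numeric sample vector (one PPG channel).
#' @param fs Sampling frequency, Hz.
#' @param max_rate Physiological ceiling on heart rate, bpm; sets the
#'   minimum distance between accepted peaks.
#' @param prominence Relative prominence floor: peaks in the filtered signal
#'   below `prominence * max(|filtered|)` are discarded.
#' @return An object of class `peak_set`: a list with `indices` (strictly
#'   increasing sample positions), `npeak`, `xstart` and `xend` (first and
#'   last peak positions).
#' @examples
#' t <- seq(0, 10, by = 0.01)[-1001]
#' p <- detect_peaks(sin(2 * pi * t), fs = 100)
#' p$npeak
#' @export
detect_peaks <- function(x, fs, max_rate = 220, prominence = 0.25) {
  if (length(x) < 2 * fs) {
    stop("channel too short: need at least 2*fs samples", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("insufficient pulsatility: channel is constant", call. = FALSE)
  }
  nyq <- fs / 2
  hi <- min(8, 0.9 * nyq)
  bp <- signal::butter(2, c(0.5, hi) / nyq, type = "pass")
  xf <- signal::filtfilt(bp, x - mean(x))

  n <- length(xf)
  cand <- which(xf[2:(n - 1)] > xf[1:(n - 2)] & xf[2:(n - 1)] >= xf[3:n]) + 1L
  floor_amp <- prominence * max(abs(xf))
  cand <- cand[xf[cand] >= floor_amp]
  if (length(cand) >= 2) {
    # greedy: take candidates in decreasing amplitude, enforce min spacing
    min_dist <- fs * 60 / max_rate
    keep <- logical(length(cand))
    ord <- order(xf[cand], decreasing = TRUE)
    taken <- integer(0)
    for (j in ord) {
      if (!length(taken) || all(abs(cand[j] - taken) >= min_dist)) {
        keep[j] <- TRUE
        taken <- c(taken, cand[j])
      }
    }
    cand <- sort(cand[keep])
  }
  if (length(cand) < 2) {
    stop("insufficient pulsatility: fewer than 2 peaks detected",
         call. = FALSE)
  }
  # snap each peak to the raw-signal maximum nearby, undoing the small
  # systolic-foot bias the band-pass conditioning can introduce
  w <- as.integer(max(1, floor(fs * 60 / max_rate / 4)))
  cand <- vapply(cand, function(i) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  cand <- sort(unique(cand))
  structure(list(indices = cand,
                 npeak = length(cand),
                 xstart = cand[1],
                 xend = cand[length(cand)]),
            class = "peak_set")
}

#' Heart rate from detected peaks
#'
#' `HR = fs * (Npeak - 1) / (xend - xstart) * 60` beats per minute: the mean
#' beat-to-beat interval across the detected systolic peaks, converted to a
#' rate.
#'
#' @param peaks A [detect_peaks()] result (`peak_set`).
#' @param fs Sampling frequency, Hz.
#' @return Heart rate, bpm.
#' @examples
#' heart_rate(structure(list(indices = seq(1, 1001, 100), npeak = 11,
#'                           xstart = 1, xend = 1001),
#'                      class = "peak_set"), fs = 100)
#' @export
heart_rate <- function(peaks, fs) {
  if (peaks$npeak < 2) {
    stop("heart rate undefined with fewer than 2 peaks", call. = FALSE)
  }
  fs * (peaks$npeak - 1) / (peaks$xend - peaks$xstart) * 60
}

#' Perfusion (ratio-of-ratios) ratio from a dual-wavelength PPG
#'
#' The light-intensity absorption ratio used in pulse oximetry:
#' `r = (AC_red / DC_red) / (AC_ir / DC_ir)`. The DC level is the channel
#' mean over the analysis window (the full record); the AC amplitude is the
#' per-beat peak-to-trough excursion, averaged over beats. Beats are
#' delimited by systolic peaks detected on the infrared channel, which has
#' the stronger pulsatile component at these wavelengths.
#'
#' @param waveform A [ppg_waveform()], or `red` and `ir` passed with `fs`.
#' @param red,ir Optional raw channel vectors (alternative to `waveform`).
#' @param fs Sampling frequency, Hz (required with raw channels).
#' @return The dimensionless perfusion ratio `r`.
#' @export
perfusion_ratio <- function(waveform = NULL, red = NULL, ir = NULL,
                            fs = NULL) {
  if (!is.null(waveform)) {
    red <- waveform$red; ir <- waveform$ir; fs <- waveform$fs
  }
  dc_red <- mean(red)
  dc_ir <- mean(ir)
  if (dc_red <= 0 || dc_ir <= 0) {
    stop("non-positive DC level: both channels need a positive mean",
         call. = FALSE)
  }
  peaks <- detect_peaks(ir, fs)
  idx <- peaks$indices
  amp <- function(ch) {
    a <- numeric(length(idx) - 1L)
    for (i in seq_along(a)) {
      seg <- ch[idx[i]:idx[i + 1L]]
      a[i] <- max(seg) - min(seg)
    }
    mean(a)
  }
  ac_ir <- amp(ir)
  if (ac_ir <= 0) {
    stop("zero infrared pulsatility: perfusion ratio undefined",
         call. = FALSE)
  }
  (amp(red) / dc_red) / (ac_ir / dc_ir)
}

#' Hemoglobin absorption coefficients at 660 / 880 nm
#'
#' Molar absorption of oxyhemoglobin (`k1_*`) and deoxyhemoglobin (`k2_*`)
#' at the two probe wavelengths. Defaults follow published hemoglobin
#' extinction spectra (L mmol^-1 cm^-1): at 660 nm deoxyhemoglobin absorbs
#' far more than oxyhemoglobin, at 880 nm the order reverses — the property
#' that makes the saturation map monotone decreasing in the perfusion ratio.
#' All saturation arithmetic uses only ratios of these coefficients, so the
#' unit convention cancels.
#'
#' @param k1_red,k1_ir Oxyhemoglobin absorption at 660 / 880 nm.
#' @param k2_red,k2_ir Deoxyhemoglobin absorption at 660 / 880 nm.
#' @return An object of class `absorption_coefficients`.
#' @export
absorption_coefficients <- function(k1_red = 0.32, k2_red = 3.23,
                                    k1_ir = 1.15, k2_ir = 0.73) {
  v <- c(k1_red = k1_red, k2_red = k2_red, k1_ir = k1_ir, k2_ir = k2_ir)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("absorption coefficients must be positive and finite", call. = FALSE)
  }
  if (k2_red <= k1_red || k1_ir <= k2_ir) {
    stop(paste0("coefficient order violated: need k2_red > k1_red ",
                "(deoxyhemoglobin dominates red absorption) and ",
                "k1_ir > k2_ir (oxyhemoglobin dominates infrared)"),
         call. = FALSE)
  }
  structure(as.list(v), class = "absorption_coefficients")
}

#' Oxygen saturation from the perfusion ratio
#'
#' Inverts the two-wavelength Lambert-Beer absorption ratio for the
#' oxygenated fraction of hemoglobin:
#' `SpO2 = 100 * (k2_ir * r - k2_red) / ((k2_ir - k1_ir) * r + (k1_red - k2_red))`.
#' The pure-species limits are exact: `r = k1_red/k1_ir` maps to 100% and
#' `r = k2_red/k2_ir` to 0%. Values slightly outside `[0, 100]` (from noisy
#' `r`) are clamped with a warning rather than rejected.
#'
#' @param r Perfusion ratio from [perfusion_ratio()] (vectorized).
#' @param coeffs An [absorption_coefficients()] object.
#' @param clamp Clamp out-of-range saturations into `[0, 100]`?
#' @return Oxygen saturation, percent.
#' @examples
#' co <- absorption_coefficients()
#' spo2_from_ratio(co$k1_red / co$k1_ir, co)  # 100
#' @export
spo2_from_ratio <- function(r, coeffs = absorption_coefficients(),
                            clamp = TRUE) {
  den <- (coeffs$k2_ir - coeffs$k1_ir) * r + (coeffs$k1_red - coeffs$k2_red)
  scale <- abs(coeffs$k1_red - coeffs$k2_red)
  if (any(abs(den) < 1e-12 * scale)) {
    stop("saturation map singular at this perfusion ratio", call. = FALSE)
  }
  s <- 100 * (coeffs$k2_ir * r - coeffs$k2_red) / den
  out <- s < 0 | s > 100
  if (any(out)) {
    if (clamp) {
      warning(sprintf("%d saturation value(s) outside [0, 100]%% clamped",
                      sum(out)), call. = FALSE)
      s <- pmin(pmax(s, 0), 100)
    }
  }
  s
}

#' Perfusion ratio implied by a known oxygen saturation
#'
#' Forward Lambert-Beer composition: for an oxygenated fraction
#' `s = SpO2/100`, the absorption ratio is
#' `r = (k1_red*s + k2_red*(1-s)) / (k1_ir*s + k2_ir*(1-s))`. Exact inverse
#' of [spo2_from_ratio()]; used by the synthetic generator and round-trip
#' tests.
#'
#' @param spo2 Oxygen saturation, percent (vectorized).
#' @param coeffs An [absorption_coefficients()] object.
#' @return The perfusion ratio `r`.
#' @export
ratio_from_spo2 <- function(spo2, coeffs = absorption_coefficients()) {
  if (any(spo2 < 0) || any(spo2 > 100)) {
    stop("`spo2` must lie in [0, 100] percent", call. = FALSE)
  }
  s <- spo2 / 100
  (coeffs$k1_red * s + coeffs$k2_red * (1 - s)) /
    (coeffs$k1_ir * s + coeffs$k2_ir * (1 - s))
}

#' Vital signs from a dual-wavelength PPG waveform
#'
#' Runs the full optical chain: systolic peak detection on the infrared
#' channel, heart rate from the peak set, perfusion ratio by
#' ratio-of-ratios, and oxygen saturation from the absorption model.
#'
#' @param waveform A [ppg_waveform()].
#' @param coeffs An [absorption_coefficients()] object.
#' @return An object of class `vital_signs`: list with `HR` (bpm),
#'   `r` (dimensionless) and `SpO2` (percent).
#' @export
process_ppg <- function(waveform, coeffs = absorption_coefficients()) {
  peaks <- detect_peaks(waveform$ir, waveform$fs)
  hr <- heart_rate(peaks, waveform$fs)
  r <- perfusion_ratio(waveform)
  structure(list(HR = hr, r = r, SpO2 = spo2_from_ratio(r, coeffs)),
            class = "vital_signs")
}
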