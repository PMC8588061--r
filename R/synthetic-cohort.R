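#' Configuration of the synthetic wrist-sensor cohort
#'
#' Describes the cohort the simulator emulates: a meal-challenge study in
#' healthy adults, 211 measurement records with reference glucose confined
#' to the normoglycemic band 4.1-10 mmol/L, sampled 30 min before and 30,
#' 60, 90 and 120 min after meals. The generator makes the unknown
#' glucose-to-physiology relation explicit as a configurable ground-truth
#' family (see [ground_truth_F()]), so every recovery claim downstream is
#' stated against a known truth.
#'
#' Default physiological ranges are resting-adult values: HR 60-100 bpm,
#' SpO2 94-99%, laser-Doppler blood flow 5-25 perfusion units, ambient
#' temperature 20-26 C, relative humidity 0.30-0.70, radiometric offset
#' from skin contact temperature within +/-0.5 K, PPG at 100 Hz for 10 s.
#' Reference glucose carries multiplicative Gaussian noise (default sd 5%,
#' the scale-proportional error typical of strip glucometers), clipped into
#' `bg_range`.
#'
#' @param n_records Number of measurement records (default 211).
#' @param bg_range Reference glucose range, mmol/L (default `c(4.1, 10)`).
#' @param noise_sd Multiplicative noise sd on reference glucose (fraction).
#' @param truth Ground-truth family name: `"mpr4-span"` or `"saturating"`.
#' @param truth_params Optional parameter override for the family.
#' @param hr_range,spo2_range,bf_range Vital-sign sampling ranges
#'   (bpm, percent, perfusion units).
#' @param ts_range,he_range Ambient temperature (C) and humidity (fraction).
#' @param tr_offset_range Radiometric-minus-contact temperature offset, K.
#' @param fs PPG sampling frequency, Hz.
#' @param duration PPG record duration, s.
#' @param ppg Generate per-record PPG waveforms? (Disable for large
#'   frame-only draws.)
#' @param coeffs [absorption_coefficients()] used for waveform synthesis.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_records = 211L,
                          bg_range = c(4.1, 10),
                          noise_sd = 0.05,
                          truth = c("mpr4-span", "saturating"),
                          truth_params = NULL,
                          hr_range = c(60, 100),
                          spo2_range = c(94, 99),
                          bf_range = c(5, 25),
                          ts_range = c(20, 26),
                          he_range = c(0.30, 0.70),
                          tr_offset_range = c(-0.5, 0.5),
                          fs = 100,
                          duration = 10,
                          ppg = TRUE,
                          coeffs = absorption_coefficients()) {
  truth <- match.arg(truth)
  stopifnot(n_records >= 1, length(bg_range) == 2, bg_range[1] > 0,
            bg_range[1] < bg_range[2], noise_sd >= 0,
            hr_range[1] >= 40, hr_range[2] <= 180,
            spo2_range[1] >= 0, spo2_range[2] <= 100,
            bf_range[1] > 0, he_range[1] >= 0, he_range[2] <= 1,
            ts_range[1] > min_skin_temperature(),
            fs > 0, duration >= 2)
  structure(list(n_records = as.integer(n_records), bg_range = bg_range,
                 noise_sd = noise_sd, truth = truth,
                 truth_params = truth_params,
                 hr_range = hr_range, spo2_range = spo2_range,
                 bf_range = bf_range, ts_range = ts_range,
                 he_range = he_range, tr_offset_range = tr_offset_range,
                 fs = fs, duration = duration, ppg = ppg, coeffs = coeffs),
            class = "cohort_config")
}

truth_defaults <- function(family) {
  switch(family,
    "mpr4-span" = list(a0 = -42, a1 = 0.095, a3 = 0.012, a4 = 0.05,
                       a10 = 4e-4),
    "saturating" = list(base = 3.8, span = 6.5, h0 = 500, scale = 12,
                        hr_coef = 0.004, hr_ref = 75),
    stop("unknown ground-truth family: ", family, call. = FALSE))
}

#' Ground-truth glucose map of the synthetic cohort
#'
#' The simulated cohort needs an explicit version of the method's core
#' assumption, glucose = F(metabolic heat, SpO2, HR, blood flow). Two
#' registered families are provided, both strictly increasing in H so the
#' generator can invert them for the heat production a target glucose
#' demands:
#'
#' * `"mpr4-span"` (default): a fixed sparse coefficient set on the MPR4
#'   interaction terms — `a0 + a1*H + a3*HR + a4*BF + a10*HR*BF` with
#'   a0 = -42, a1 = 0.095, a3 = 0.012, a4 = 0.05, a10 = 4e-4. Because it
#'   lies in the MPR4 span, a noiseless fit recovers it exactly.
#' * `"saturating"`: a logistic response in H,
#'   `base + span / (1 + exp(-(H - h0)/scale)) + hr_coef*(HR - hr_ref)` —
#'   smooth and outside the interaction-polynomial span, so the network
#'   model has genuine nonlinearity to exploit.
#'
#' @param H Metabolic heat production, W/m^2 (vectorized).
#' @param SpO2 Oxygen saturation, percent.
#' @param HR Heart rate, bpm.
#' @param BF Blood flow, perfusion units.
#' @param family Family name.
#' @param params Optional named parameter overrides.
#' @return Blood glucose, mmol/L (unclipped).
#' @export
ground_truth_F <- function(H, SpO2, HR, BF,
                           family = c("mpr4-span", "saturating"),
                           params = NULL) {
  family <- match.arg(family)
  p <- utils::modifyList(truth_defaults(family), as.list(params %||% list()))
  switch(family,
    "mpr4-span" = p$a0 + p$a1 * H + p$a3 * HR + p$a4 * BF + p$a10 * HR * BF,
    "saturating" = p$base + p$span / (1 + exp(-(H - p$h0) / p$scale)) +
      p$hr_coef * (HR - p$hr_ref))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Invert the ground truth for the metabolic heat a target glucose demands.
invert_truth_for_H <- function(bg, SpO2, HR, BF, family, params,
                               interval = c(300, 800)) {
  f <- function(h) ground_truth_F(h, SpO2, HR, BF, family, params) - bg
  lo <- f(interval[1]); hi <- f(interval[2])
  if (lo > 0 || hi < 0) {
    stop("ground truth not invertible for this record: glucose target ",
         "outside the reachable heat range", call. = FALSE)
  }
  stats::uniroot(f, interval, tol = 1e-10)$root
}

# Solve the wrist skin temperature whose frame reproduces a target H, with
# ambient conditions and the radiometric offset already drawn. Monotone in
# tw for tw > ts, so bisection via uniroot is exact.
solve_frame_for_H <- function(H_target, ts, He, tr_offset,
                              constants = energy_constants(),
                              tw_max = 42) {
  h_of_tw <- function(tw) {
    radiative_heat(tw + 273.15 + tr_offset, constants) +
      convective_heat(tw, ts, constants) +
      evaporative_heat(tw, He, constants) - H_target
  }
  lower <- max(ts + 1e-6, min_skin_temperature(constants) + 1e-6)
  if (h_of_tw(lower) > 0 || h_of_tw(tw_max) < 0) return(NULL)
  tw <- stats::uniroot(h_of_tw, c(lower, tw_max), tol = 1e-10)$root
  list(tw = tw, Tr = tw + 273.15 + tr_offset)
}

#' Generate a synthetic dual-wavelength PPG waveform
#'
#' Builds a two-channel pulse waveform with a known beat rate and a known
#' implied oxygen saturation: a per-beat pulse template (sharp systolic
#' upstroke plus a dicrotic shoulder) rides on each channel's DC level, and
#' the channels' peak-to-trough AC/DC ratios are set so the ratio-of-ratios
#' equals the perfusion ratio the absorption model maps to `target_spo2`.
#' Doubling both DC offsets leaves the implied ratio unchanged.
#'
#' @param target_hr Target heart rate, bpm, in `[40, 180]`.
#' @param target_spo2 Target oxygen saturation, percent.
#' @param coeffs [absorption_coefficients()] defining the saturation map.
#' @param fs Sampling frequency, Hz.
#' @param duration Record length, s.
#' @param dc Named numeric: DC intensity per channel (arbitrary units).
#' @param ir_acdc Infrared AC/DC pulsatile fraction.
#' @return A [ppg_waveform()].
#' @export
generate_ppg <- function(target_hr, target_spo2,
                         coeffs = absorption_coefficients(),
                         fs = 100, duration = 10,
                         dc = c(red = 20000, ir = 24000),
                         ir_acdc = 0.04) {
  if (target_hr < 40 || target_hr > 180) {
    stop("`target_hr` must lie in [40, 180] bpm", call. = FALSE)
  }
  if (target_spo2 < 0 || target_spo2 > 100) {
    stop("`target_spo2` must lie in [0, 100] percent", call. = FALSE)
  }
  r_target <- ratio_from_spo2(target_spo2, coeffs)
  red_acdc <- r_target * ir_acdc
  if (red_acdc <= 0) {
    stop("target saturation requires non-positive red amplitude under ",
         "these coefficients", call. = FALSE)
  }
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  phase <- (t * target_hr / 60) %% 1
  pulse <- pulse_template(phase)
  mk <- function(level, acdc) {
    level * (1 + acdc * (pulse - mean(pulse)))
  }
  ppg_waveform(red = mk(dc[["red"]], red_acdc),
               ir = mk(dc[["ir"]], ir_acdc),
               fs = fs)
}

# Systolic bump + dicrotic shoulder over one beat phase in [0, 1),
# normalized to range [0, 1] so peak-to-trough amplitude is exactly the
# configured AC fraction.
pulse_template <- function(phase) {
  raw <- function(p) {
    exp(-0.5 * ((p - 0.30) / 0.09)^2) + 0.35 * exp(-0.5 * ((p - 0.62) / 0.14)^2)
  }
  grid <- raw(seq(0, 1, length.out = 2001))
  (raw(phase) - min(grid)) / (max(grid) - min(grid))
}

#' Generate the synthetic cohort
#'
#' Draws a full seeded cohort: per-subject meal trajectories of true
#' glucose (baseline plus a log-normal-shaped postprandial excursion
#' peaking 30-60 min after the meal, sampled at the five protocol
#' timepoints), vital signs from the configured ranges, and for each record
#' a sensor frame constructed so that [metabolic_heat()] reproduces exactly
#' the heat production the ground-truth relation demands for that record's
#' true glucose. Reference glucose adds the configured multiplicative
#' measurement noise, clipped into `bg_range`. Optionally each record gets
#' a synthetic PPG waveform carrying its HR and SpO2.
#'
#' The result is fully reproducible from `(config, seed)`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param max_retries Ambient-condition redraws allowed per record before
#'   the generator gives up.
#' @return A data.frame of class `bg_cohort` with one row per record:
#'   identifiers (`record_id`, `subject_id`, `timepoint_label`), the frame
#'   (`Tr_K`, `tw_C`, `ts_C`, `He_frac`, `BF_pu`), ground truth
#'   (`HR_true_bpm`, `SpO2_true_pct`, `H_true_Wm2`, `BG_true_mmolL`) and
#'   the noisy reference `BG_ref_mmolL`. Waveforms (if generated) are in
#'   `attr(, "waveforms")`; the config and seed in `attr(, "config")` /
#'   `attr(, "seed")`.
#' @examples
#' head(generate_cohort(cohort_config(n_records = 12, ppg = FALSE), seed = 1))
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L,
                            max_retries = 20L) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))

  n <- config$n_records
  timepoints <- c("pre-meal", "30min", "60min", "90min", "120min")
  times <- c(-30, 30, 60, 90, 120)

  # per-subject meal trajectories, 5 records per meal, until n reached
  bg_true <- numeric(0); subject <- integer(0); tp <- character(0)
  sid <- 0L
  while (length(bg_true) < n) {
    sid <- sid + 1L
    baseline <- stats::runif(1, 4.4, 5.6)
    for (meal in 1:3) {
      amp <- stats::runif(1, 1.5, 4.5)
      tpk <- stats::runif(1, 30, 60)
      bump <- numeric(length(times))
      post <- times > 0
      bump[post] <- amp * exp(-(log(times[post] / tpk))^2 / (2 * 0.5^2))
      bg <- pmin(pmax(baseline + bump, config$bg_range[1]),
                 config$bg_range[2])
      bg_true <- c(bg_true, bg)
      subject <- c(subject, rep(sid, length(bg)))
      tp <- c(tp, timepoints)
      if (length(bg_true) >= n) break
    }
  }
  keep <- seq_len(n)
  bg_true <- bg_true[keep]; subject <- subject[keep]; tp <- tp[keep]

  hr <- stats::runif(n, config$hr_range[1], config$hr_range[2])
  spo2 <- stats::runif(n, config$spo2_range[1], config$spo2_range[2])
  bf <- stats::runif(n, config$bf_range[1], config$bf_range[2])

  tw <- Tr <- ts <- he <- h_true <- numeric(n)
  for (i in seq_len(n)) {
    h_i <- invert_truth_for_H(bg_true[i], spo2[i], hr[i], bf[i],
                              config$truth, config$truth_params)
    sol <- NULL
    for (try in seq_len(max_retries)) {
      ts_i <- stats::runif(1, config$ts_range[1], config$ts_range[2])
      he_i <- stats::runif(1, config$he_range[1], config$he_range[2])
      off_i <- stats::runif(1, config$tr_offset_range[1],
                            config$tr_offset_range[2])
      sol <- solve_frame_for_H(h_i, ts_i, he_i, off_i)
      if (!is.null(sol)) break
    }
    if (is.null(sol)) {
      stop(sprintf(paste0("record %d: no admissible frame reproduces ",
                          "H = %.1f W/m^2 after %d ambient redraws"),
                   i, h_i, max_retries), call. = FALSE)
    }
    tw[i] <- sol$tw; Tr[i] <- sol$Tr; ts[i] <- ts_i; he[i] <- he_i
    h_true[i] <- h_i
  }

  bg_ref <- bg_true * (1 + stats::rnorm(n, 0, config$noise_sd))
  bg_ref <- pmin(pmax(bg_ref, config$bg_range[1]), config$bg_range[2])

  waveforms <- NULL
  if (isTRUE(config$ppg)) {
    waveforms <- lapply(seq_len(n), function(i) {
      generate_ppg(hr[i], spo2[i], config$coeffs,
                   fs = config$fs, duration = config$duration)
    })
  }

  out <- data.frame(
    record_id = sprintf("r%03d", seq_len(n)),
    subject_id = sprintf("s%02d", subject),
    timepoint_label = tp,
    Tr_K = Tr, tw_C = tw, ts_C = ts, He_frac = he, BF_pu = bf,
    HR_true_bpm = hr, SpO2_true_pct = spo2,
    H_true_Wm2 = h_true,
    BG_true_mmolL = bg_true, BG_ref_mmolL = bg_ref,
    stringsAsFactors = FALSE)
  attr(out, "waveforms") <- waveforms
  attr(out, "config") <- config
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("bg_cohort", "data.frame")
  out
}
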