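#' Physical constants of the wrist energy-balance model
#'
#' Bundles the constants used to decompose resting metabolic heat production
#' into radiative, convective and evaporative surface losses. Defaults are the
#' model's published empirical values: skin emissivity 0.96, the
#' Stefan-Boltzmann constant, a convective coefficient of
#' 2.38 W m^-2 K^-1.25, a fused evaporative constant (latent heat of
#' vaporization times skin permeability) of 3.054, and a linear saturation
#' vapor pressure approximation Psk* = 0.256 tw - 3.37 kPa for skin
#' temperature tw in degrees Celsius.
#'
#' @param emissivity Skin emissivity, dimensionless in (0, 1].
#' @param stefan_boltzmann Stefan-Boltzmann constant, W m^-2 K^-4.
#' @param convective_coefficient Base of the convective term,
#'   W m^-2 K^-1.25; the composed convective flux is
#'   `convective_coefficient * (tw - ts)^1.25`.
#' @param evaporative_rm Fused evaporative constant r*m (latent heat of
#'   vaporization of water times wrist-skin permeability); the two factors
#'   are never separated in this model.
#' @param saturation_slope,saturation_intercept Slope (kPa per degree C) and
#'   intercept (kPa) of the linear saturation vapor pressure approximation.
#' @return An object of class `energy_constants` (a named list).
#' @examples
#' energy_constants()
#' energy_constants(emissivity = 0.98)
#' @export
energy_constants <- function(emissivity = 0.96,
                             stefan_boltzmann = 5.67e-8,
                             convective_coefficient = 2.38,
                             evaporative_rm = 3.054,
                             saturation_slope = 0.256,
                             saturation_intercept = 3.37) {
  if (!is.numeric(emissivity) || length(emissivity) != 1L ||
      emissivity <= 0 || emissivity > 1) {
    stop("`emissivity` must be a single number in (0, 1]", call. = FALSE)
  }
  vals <- c(stefan_boltzmann = stefan_boltzmann,
            convective_coefficient = convective_coefficient,
            evaporative_rm = evaporative_rm,
            saturation_slope = saturation_slope,
            saturation_intercept = saturation_intercept)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all energy-model coefficients must be strictly positive and finite",
         call. = FALSE)
  }
  structure(list(emissivity = emissivity,
                 stefan_boltzmann = stefan_boltzmann,
                 convective_coefficient = convective_coefficient,
                 evaporative_rm = evaporative_rm,
                 saturation_slope = saturation_slope,
                 saturation_intercept = saturation_intercept),
            class = "energy_constants")
}

#' Minimum admissible skin temperature (degrees C)
#'
#' Root of the linear saturation vapor pressure form: below this skin
#' temperature the approximation turns negative and the evaporative term is
#' out of the model's domain.
#' @param constants An [energy_constants()] object.
#' @return Skin temperature in degrees C at which Psk* = 0.
#' @export
min_skin_temperature <- function(constants = energy_constants()) {
  constants$saturation_intercept / constants$saturation_slope
}

#' One wrist sensor frame
#'
#' Validates a single measurement episode's raw physical readings. Units are
#' strict and deliberately asymmetric: `Tr` is an absolute radiometric
#' temperature in kelvin (the fourth-power radiation law requires an absolute
#' scale), `tw` and `ts` are in degrees Celsius, and `He` is a relative
#' humidity *fraction* in `[0, 1]`, not a percentage.
#'
#' @param Tr Absolute radiometric wrist temperature, K. May be `NA` if
#'   `tr_fallback = TRUE`, in which case `Tr = tw + 273.15` is substituted
#'   and a message is emitted (never silently).
#' @param tw Wrist skin temperature, degrees C; must exceed
#'   [min_skin_temperature()].
#' @param ts Ambient temperature, degrees C.
#' @param He Ambient relative humidity, fraction in `[0, 1]`.
#' @param BF Blood flow (laser Doppler perfusion units), strictly positive.
#'   Optional: carried as a regression feature, not used by the heat model.
#' @param tr_fallback Substitute `tw + 273.15` for a missing `Tr`?
#' @return An object of class `sensor_frame` (a one-row list).
#' @examples
#' sensor_frame(Tr = 306.15, tw = 33, ts = 24, He = 0.5, BF = 12)
#' @export
sensor_frame <- function(Tr, tw, ts, He, BF = NA_real_, tr_fallback = FALSE) {
  if (is.na(Tr)) {
    if (!tr_fallback) {
      stop("field `Tr`: missing radiometric temperature ",
           "(set tr_fallback = TRUE to substitute tw + 273.15)", call. = FALSE)
    }
    Tr <- tw + 273.15
    message("sensor_frame: Tr missing; falling back to tw + 273.15 = ",
            format(Tr), " K")
  }
  if (!is.finite(Tr) || Tr <= 0) {
    stop("field `Tr`: must be a positive absolute temperature in kelvin",
         call. = FALSE)
  }
  tmin <- min_skin_temperature()
  if (!is.finite(tw) || tw <= tmin) {
    stop(sprintf("field `tw`: skin temperature must exceed %.7f degC (got %s)",
                 tmin, format(tw)), call. = FALSE)
  }
  if (!is.finite(ts)) stop("field `ts`: must be finite", call. = FALSE)
  if (!is.finite(He) || He < 0 || He > 1) {
    stop("field `He`: relative humidity must be a fraction in [0, 1]",
         call. = FALSE)
  }
  if (!is.na(BF) && (!is.finite(BF) || BF <= 0)) {
    stop("field `BF`: blood flow must be strictly positive", call. = FALSE)
  }
  structure(list(Tr = Tr, tw = tw, ts = ts, He = He, BF = BF),
            class = "sensor_frame")
}

#' Radiative heat flux from the wrist
#'
#' Gray-body radiation at the absolute radiometric temperature of the skin:
#' `R = emissivity * sigma * Tr^4`. No radiative exchange term with the
#' surroundings is subtracted; the model uses the absolute emission as
#' printed.
#'
#' @param Tr Absolute radiometric temperature, K (vectorized).
#' @param constants An [energy_constants()] object.
#' @return Radiative flux, W/m^2.
#' @examples
#' radiative_heat(306.15)
#' @export
radiative_heat <- function(Tr, constants = energy_constants()) {
  if (any(!is.finite(Tr)) || any(Tr < 0)) {
    stop("field `Tr`: absolute temperature must be >= 0 K", call. = FALSE)
  }
  constants$emissivity * constants$stefan_boltzmann * Tr^4
}

#' Convective heat flux from the wrist
#'
#' Newton cooling with a temperature-dependent transfer coefficient; the
#' composed form is `C = 2.38 * (tw - ts)^1.25` W/m^2. The model assumes net
#' heat loss (`tw >= ts`): an ambient warmer than the skin puts the 1.25
#' power outside the reals, and by default such frames are rejected with an
#' out-of-model condition. `allow_signed = TRUE` opts into the exploratory
#' signed extension `-2.38 * |tw - ts|^1.25`.
#'
#' @param tw Wrist skin temperature, degrees C (vectorized).
#' @param ts Ambient temperature, degrees C.
#' @param constants An [energy_constants()] object.
#' @param allow_signed Compute a signed flux when `tw < ts` instead of
#'   raising an error.
#' @return Convective flux, W/m^2.
#' @examples
#' convective_heat(33, 24)
#' convective_heat(33, 32)  # 2.38 at a 1 degC difference
#' @export
convective_heat <- function(tw, ts, constants = energy_constants(),
                            allow_signed = FALSE) {
  if (any(!is.finite(tw)) || any(!is.finite(ts))) {
    stop("fields `tw`, `ts`: temperatures must be finite", call. = FALSE)
  }
  dt <- tw - ts
  if (any(dt < 0) && !allow_signed) {
    stop(structure(
      class = c("glucoheat_out_of_model", "error", "condition"),
      list(message = paste0(
             "field `ts`: ambient exceeds skin temperature (tw < ts); ",
             "the convective model assumes net heat loss. ",
             "Use allow_signed = TRUE for the signed extension."),
           call = NULL)))
  }
  sign(dt) * constants$convective_coefficient * abs(dt)^1.25
}

#' Saturation vapor pressure of water at skin temperature
#'
#' Linear approximation `Psk* = 0.256 tw - 3.37` kPa, valid only where it is
#' non-negative (skin temperature above [min_skin_temperature()], about
#' 13.16 degC — comfortably below any live skin reading).
#'
#' @inheritParams convective_heat
#' @return Saturation vapor pressure at the skin, kPa.
#' @examples
#' saturation_vapor_pressure(33)  # 5.078 kPa
#' @export
saturation_vapor_pressure <- function(tw, constants = energy_constants()) {
  if (any(!is.finite(tw))) stop("field `tw`: must be finite", call. = FALSE)
  tmin <- min_skin_temperature(constants)
  if (any(tw < tmin)) {
    stop(sprintf(paste0("field `tw`: %.7f degC is below the admissible range ",
                        "(> %.7f degC); the linear saturation pressure would ",
                        "be negative"), min(tw), tmin), call. = FALSE)
  }
  constants$saturation_slope * tw - constants$saturation_intercept
}

#' Evaporative heat flux from the wrist
#'
#' `E = 3.054 * Psk*(tw) * (1 - He)` W/m^2: the fused latent-heat times
#' skin-permeability constant times the skin-to-air vapor pressure deficit,
#' where the ambient partial pressure is `He * Psk*`. Saturated air
#' (`He = 1`) shuts evaporation off.
#'
#' @param He Ambient relative humidity, fraction in `[0, 1]` (vectorized).
#' @inheritParams convective_heat
#' @return Evaporative flux, W/m^2.
#' @examples
#' evaporative_heat(33, 0.5)
#' @export
evaporative_heat <- function(tw, He, constants = energy_constants()) {
  if (any(!is.finite(He)) || any(He < 0) || any(He > 1)) {
    stop("field `He`: relative humidity must be a fraction in [0, 1]",
         call. = FALSE)
  }
  constants$evaporative_rm * saturation_vapor_pressure(tw, constants) * (1 - He)
}

#' Metabolic heat production from a sensor frame
#'
#' At rest the body is assumed thermally balanced, so metabolic heat
#' production equals total surface heat loss:
#' `H = R + C + E = eps*sigma*Tr^4 + 2.38*(tw-ts)^1.25 +
#' 3.054*(0.256 tw - 3.37)*(1 - He)`.
#' The returned decomposition sums to `H` exactly. `H` is a flux (W/m^2);
#' no whole-body surface-area scaling is applied, because downstream
#' regression absorbs the scale.
#'
#' @param frame A [sensor_frame()], or a list/data.frame with fields
#'   `Tr`, `tw`, `ts`, `He` (vectorized over rows).
#' @param constants An [energy_constants()] object.
#' @return A data.frame of class `heat_flux` with columns `R`, `C`, `E`, `H`
#'   (all W/m^2), one row per input frame.
#' @examples
#' metabolic_heat(sensor_frame(Tr = 306.15, tw = 33, ts = 24, He = 0.5))
#' @export
metabolic_heat <- function(frame, constants = energy_constants()) {
  need <- c("Tr", "tw", "ts", "He")
  missing_f <- setdiff(need, names(frame))
  if (length(missing_f)) {
    stop("frame is missing field(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  R <- radiative_heat(frame$Tr, constants)
  C <- convective_heat(frame$tw, frame$ts, constants)
  E <- evaporative_heat(frame$tw, frame$He, constants)
  structure(data.frame(R = R, C = C, E = E, H = R + C + E),
            class = c("heat_flux", "data.frame"))
}
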