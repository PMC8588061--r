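#' Glucose prediction accuracy metrics
#'
#' Paired accuracy metrics between reference glucose `reference` (Xi) and
#' predicted glucose `predicted` (Yi), both in mmol/L:
#'
#' * `mard()` — mean absolute relative difference,
#'   `mean(|Yi - Xi| / Xi) * 100` percent; requires all Xi > 0.
#' * `corr_coefficient()` — Pearson product-moment correlation.
#' * `mad_printed()` — mean absolute deviation of the *predictions about
#'   their own mean*, `mean(|Yi - mean(Y)|)`. This self-referential form is
#'   the convention this model family reports; it never sees the reference
#'   values, so a companion is provided:
#' * `mad_conventional()` — `mean(|Yi - Xi|)`, the usual mean absolute
#'   error.
#' * `rmse()` — root mean squared error.
#' * `sep()` — standard error of prediction: the standard deviation of the
#'   residuals `Yi - Xi` about their mean (divisor n - 1 by default,
#'   configurable to n). SEP measures residual spread, not bias: a constant
#'   offset gives SEP = 0.
#'
#' @param reference Reference glucose Xi, mmol/L.
#' @param predicted Predicted glucose Yi, mmol/L.
#' @param divisor For `sep()`: `"n-1"` (sample sd, default) or `"n"`.
#' @return A single numeric value (mARD in percent; CORR dimensionless;
#'   others in mmol/L).
#' @examples
#' mard(c(4, 5), c(5, 4))      # 22.5
#' mad_printed(c(1, 2, 6))     # 2
#' @name accuracy_metrics
NULL

check_pairs <- function(reference, predicted) {
  if (length(reference) != length(predicted)) {
    stop("reference and predicted must have equal length", call. = FALSE)
  }
  if (any(!is.finite(reference)) || any(!is.finite(predicted))) {
    stop("reference and predicted must be finite", call. = FALSE)
  }
}

#' @rdname accuracy_metrics
#' @export
mard <- function(reference, predicted) {
  check_pairs(reference, predicted)
  if (any(reference <= 0)) {
    stop("mARD undefined: all reference values must be > 0", call. = FALSE)
  }
  mean(abs(predicted - reference) / reference) * 100
}

#' @rdname accuracy_metrics
#' @export
corr_coefficient <- function(reference, predicted) {
  check_pairs(reference, predicted)
  if (length(reference) < 2) stop("correlation needs n >= 2", call. = FALSE)
  if (stats::sd(reference) == 0 || stats::sd(predicted) == 0) {
    stop("correlation undefined: a series has zero variance", call. = FALSE)
  }
  stats::cor(reference, predicted)
}

#' @rdname accuracy_metrics
#' @export
mad_printed <- function(predicted) {
  if (any(!is.finite(predicted))) stop("predicted must be finite",
                                       call. = FALSE)
  mean(abs(predicted - mean(predicted)))
}

#' @rdname accuracy_metrics
#' @export
mad_conventional <- function(reference, predicted) {
  check_pairs(reference, predicted)
  mean(abs(predicted - reference))
}

#' @rdname accuracy_metrics
#' @export
rmse <- function(reference, predicted) {
  check_pairs(reference, predicted)
  sqrt(mean((reference - predicted)^2))
}

#' @rdname accuracy_metrics
#' @export
sep <- function(reference, predicted, divisor = c("n-1", "n")) {
  check_pairs(reference, predicted)
  divisor <- match.arg(divisor)
  e <- predicted - reference
  if (length(e) < 2) stop("SEP needs n >= 2", call. = FALSE)
  ss <- sum((e - mean(e))^2)
  sqrt(ss / (length(e) - (divisor == "n-1")))
}

#' mmol/L to mg/dL conversion factor for glucose
#' @export
MGDL_PER_MMOLL <- 18.016

#' Clarke error grid zone assignment
#'
#' Classifies each (reference, predicted) glucose pair into the canonical
#' Clarke (1987) error-grid zones, the clinical gold standard for glucose
#' monitor accuracy:
#'
#' * **A** — clinically accurate: within 20% of the reference (inclusive:
#'   a deviation of exactly 20% is still zone A), or both values below the
#'   70 mg/dL hypoglycemic threshold.
#' * **B** — benign errors outside 20% that would not lead to inappropriate
#'   treatment.
#' * **C** — errors that would trigger unnecessary corrective treatment.
#' * **D** — dangerous failures to detect hypo-/hyperglycemia (bands at the
#'   70 and 180 mg/dL clinical thresholds).
#' * **E** — errors that would confuse hypo- and hyperglycemic treatment.
#'
#' The grid geometry is defined in mg/dL; mmol/L inputs are converted at
#' 18.016 mg/dL per mmol/L.
#'
#' @param reference Reference glucose Xi.
#' @param predicted Predicted glucose Yi.
#' @param units Units of both inputs: `"mmol/L"` (default) or `"mg/dL"`.
#' @return A factor of zone labels (levels A-E) with attribute
#'   `"percentages"`, a named numeric vector of per-zone percentages summing
#'   to 100. See [clarke_zone_table()] for the tabulated form.
#' @examples
#' z <- clarke_zones(c(5, 6, 7), c(5, 6, 7))
#' attr(z, "percentages")
#' @export
clarke_zones <- function(reference, predicted,
                         units = c("mmol/L", "mg/dL")) {
  check_pairs(reference, predicted)
  units <- match.arg(units)
  if (any(reference <= 0) || any(predicted <= 0)) {
    stop("glucose concentrations must be strictly positive", call. = FALSE)
  }
  f <- if (units == "mmol/L") MGDL_PER_MMOLL else 1
  x <- reference * f
  y <- predicted * f
  zone <- character(length(x))
  for (i in seq_along(x)) {
    zone[i] <- clarke_zone_one(x[i], y[i])
  }
  zone <- factor(zone, levels = c("A", "B", "C", "D", "E"))
  pct <- 100 * as.numeric(table(zone)) / length(zone)
  names(pct) <- levels(zone)
  attr(zone, "percentages") <- pct
  zone
}

# Canonical 1987 piecewise grid in mg/dL, evaluated in zone priority order.
clarke_zone_one <- function(x, y) {
  if ((x < 70 && y < 70) || abs(y - x) <= 0.2 * x) return("A")
  if ((x >= 180 && y <= 70) || (x <= 70 && y >= 180)) return("E")
  if ((x >= 70 && x <= 290 && y >= x + 110) ||
      (x >= 130 && x <= 180 && y <= (7 / 5) * x - 182)) return("C")
  if ((x >= 240 && y >= 70 && y <= 180) ||
      (x <= 175 / 3 && y >= 70 && y <= 180) ||
      (x > 175 / 3 && x <= 70 && y >= (6 / 5) * x && y <= 180)) return("D")
  "B"
}

#' Tabulate Clarke error grid zone percentages
#'
#' @inheritParams clarke_zones
#' @return A data.frame with columns `zone`, `n`, `percent`.
#' @export
clarke_zone_table <- function(reference, predicted,
                              units = c("mmol/L", "mg/dL")) {
  z <- clarke_zones(reference, predicted, units)
  data.frame(zone = levels(z),
             n = as.integer(table(z)),
             percent = as.numeric(attr(z, "percentages")))
}

#' Full accuracy report for a glucose prediction set
#'
#' Computes every accuracy metric (mARD, Pearson correlation, both MAD
#' conventions, RMSE, SEP) and the Clarke error grid zone percentages in one
#' call.
#'
#' @inheritParams clarke_zones
#' @param sep_divisor Divisor convention for [sep()].
#' @return An object of class `bg_evaluation` (a list) with fields `n`,
#'   `mARD`, `CORR`, `MAD_printed`, `MAD_conventional`, `RMSE`, `SEP` and
#'   `clarke` (the zone table).
#' @export
evaluate_predictions <- function(reference, predicted,
                                 units = c("mmol/L", "mg/dL"),
                                 sep_divisor = c("n-1", "n")) {
  units <- match.arg(units)
  structure(list(
    n = length(reference),
    mARD = mard(reference, predicted),
    CORR = corr_coefficient(reference, predicted),
    MAD_printed = mad_printed(predicted),
    MAD_conventional = mad_conventional(reference, predicted),
    RMSE = rmse(reference, predicted),
    SEP = sep(reference, predicted, divisor = match.arg(sep_divisor)),
    clarke = clarke_zone_table(reference, predicted, units)
  ), class = "bg_evaluation")
}

#' @export
print.bg_evaluation <- function(x, ...) {
  cat(sprintf("Glucose prediction accuracy (n = %d)\n", x$n))
  cat(sprintf("  mARD: %.3f %%   CORR: %.3f\n", x$mARD, x$CORR))
  cat(sprintf("  MAD (about prediction mean): %.3f mmol/L   ",
              x$MAD_printed))
  cat(sprintf("MAD (vs reference): %.3f mmol/L\n", x$MAD_conventional))
  cat(sprintf("  RMSE: %.3f mmol/L   SEP: %.3f mmol/L\n", x$RMSE, x$SEP))
  cat("  Clarke error grid:\n")
  for (i in seq_len(nrow(x$clarke))) {
    cat(sprintf("    zone %s: %6.3f %% (n = %d)\n", x$clarke$zone[i],
                x$clarke$percent[i], x$clarke$n[i]))
  }
  invisible(x)
}

#' Plot the Clarke error grid
#'
#' Base-graphics scatter of predicted against reference glucose over the
#' zone boundaries. Cosmetic companion to [clarke_zones()] — the zone counts
#' are the contract, the picture is for reports.
#'
#' @inheritParams clarke_zones
#' @param ... Passed to [graphics::points()].
#' @return Invisibly, the zone factor.
#' @export
plot_clarke_grid <- function(reference, predicted,
                             units = c("mmol/L", "mg/dL"), ...) {
  units <- match.arg(units)
  f <- if (units == "mmol/L") MGDL_PER_MMOLL else 1
  x <- reference * f
  y <- predicted * f
  lim <- c(0, max(400, x, y))
  graphics::plot(NA, xlim = lim, ylim = lim,
                 xlab = "Reference glucose (mg/dL)",
                 ylab = "Predicted glucose (mg/dL)",
                 main = "Clarke error grid")
  seg <- function(x0, y0, x1, y1) graphics::segments(x0, y0, x1, y1,
                                                     col = "grey40")
  up <- lim[2]
  seg(0, 0, up, up)
  seg(58.3, 70, up, 1.2 * up)          # upper 20% line from its 70 crossing
  seg(70, 56, up, 0.8 * up)            # lower 20% line
  seg(70, 180, 290, 400); seg(70, 0, 70, 56)
  seg(130, 0, 180, 70)                 # lower C wedge
  seg(240, 70, 240, 180); seg(240, 180, up, 180)
  seg(0, 70, 58.3, 70); seg(58.3, 70, 70, 84); seg(70, 84, 70, 180)
  seg(180, 0, 180, 70); seg(180, 70, up, 70)
  zone <- clarke_zones(reference, predicted, units)
  graphics::points(x, y, pch = 16,
                   col = c(A = "forestgreen", B = "steelblue", C = "orange",
                           D = "darkorange3", E = "firebrick")[as.character(zone)],
                   ...)
  invisible(zone)
}
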