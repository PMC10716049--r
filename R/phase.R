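#' Cloud-point temperature from a turbidity ramp
#'
#' Extracts the phase-separation cloud point T_c from an absorbance
#' (A340) versus temperature curve as the temperature of the maximum of
#' the first-order derivative, after optional centered moving-average
#' smoothing. The orientation is LCST: absorbance rises with temperature
#' and the derivative maximum is sought on the rising edge.
#'
#' Quality flags: `"clear"` for a well-formed peak, `"flat"` when the
#' derivative peak does not exceed 5x the derivative noise floor (e.g. a
#' zero-amplitude curve), `"edge"` when the maximum falls on the first or
#' last usable grid point (the transition is not fully sampled).
#'
#' @param curve data frame with columns `T` (strictly increasing, deg C)
#'   and `A340`, or a numeric vector of temperatures.
#' @param A340 absorbances, if `curve` is given as a vector.
#' @param smooth_window centered moving-average window (points; odd, >= 1).
#' @return an object of class `cloud_point` with `Tc`, `peak_height`
#'   (A340 per deg C), `flag` and the derivative curve.
#' @export
cloud_point <- function(curve, A340 = NULL, smooth_window = 5) {
  if (is.data.frame(curve)) {
    Tc_grid <- curve$T; y <- curve$A340
  } else {
    Tc_grid <- curve; y <- A340
  }
  if (length(Tc_grid) < 10) stop("need at least 10 points")
  if (any(diff(Tc_grid) <= 0)) stop("temperature grid must be strictly increasing")
  smooth_window <- max(1L, as.integer(smooth_window))
  if (smooth_window %% 2L == 0L) smooth_window <- smooth_window + 1L
  ys <- if (smooth_window > 1) {
    as.numeric(stats::filter(y, rep(1 / smooth_window, smooth_window),
                             sides = 2))
  } else y
  ok <- !is.na(ys)
  Tk <- Tc_grid[ok]; yk <- ys[ok]
  n <- length(yk)
  if (n < 5) stop("too few points after smoothing")
  # centered finite difference on the (possibly non-uniform) grid
  deriv <- (yk[3:n] - yk[1:(n - 2)]) / (Tk[3:n] - Tk[1:(n - 2)])
  Td <- Tk[2:(n - 1)]
  imax <- which.max(deriv)
  peak <- deriv[imax]
  # noise floor from the baseline: exclude the top quartile of derivative
  # values, which carries the transition peak wherever it sits on the ramp
  base_d <- deriv[deriv <= stats::quantile(deriv, 0.75)]
  noise_floor <- stats::mad(base_d, center = stats::median(base_d))
  flag <- "clear"
  Tc <- Td[imax]
  if (peak <= 5 * noise_floor || peak <= .Machine$double.eps^0.5 *
      max(abs(yk), 1)) {
    flag <- "flat"; Tc <- NA_real_
  } else if (imax == 1L || imax == length(deriv)) {
    flag <- "edge"
  }
  structure(list(Tc = Tc, peak_height = peak, flag = flag,
                 derivative = data.frame(T = Td, dA340_dT = deriv),
                 smooth_window = smooth_window),
            class = "cloud_point")
}

#' @export
print.cloud_point <- function(x, ...) {
  if (is.na(x$Tc)) {
    cat("Cloud point: not detected (flag =", x$flag, ")\n")
  } else {
    cat(sprintf("Cloud point Tc = %.2f degC (peak %.4g A340/degC, flag = %s)\n",
                x$Tc, x$peak_height, x$flag))
  }
  invisible(x)
}

#' Dense/light-phase partition coefficient
#'
#' The partition coefficient of a species between the condensed (dense)
#' and dilute (light) phases: \eqn{P = c_{dense,measured} \cdot D /
#' c_{light}}, where D is the dilution factor applied to the dense phase
#' before measurement (default 9, i.e. diluted nine times). If standard
#' deviations are supplied, the s.e. of P is propagated to first order;
#' if >= 3 replicate pairs are supplied, the replicate-level mean and s.d.
#' are reported instead.
#'
#' @param c_light concentration in the light phase (scalar or replicate
#'   vector), must be > 0.
#' @param c_dense_measured measured concentration of the diluted dense
#'   phase (same units and length).
#' @param dilution_factor dilution applied to the dense phase (>= 1).
#' @param sd_light,sd_dense optional standard deviations for scalar inputs.
#' @return an object of class `partition_measurement` with `P` and,
#'   when available, `se`.
#' @export
partition_coefficient <- function(c_light, c_dense_measured,
                                  dilution_factor = 9,
                                  sd_light = NULL, sd_dense = NULL) {
  if (any(c_light <= 0)) stop("'c_light' must be > 0 (P undefined)")
  if (dilution_factor < 1) stop("'dilution_factor' must be >= 1")
  stopifnot(length(c_light) == length(c_dense_measured))
  P_i <- c_dense_measured * dilution_factor / c_light
  if (length(P_i) >= 3) {
    out <- list(P = mean(P_i), se = stats::sd(P_i), replicates = P_i,
                dilution_factor = dilution_factor, method = "replicates")
  } else {
    se <- if (!is.null(sd_light) && !is.null(sd_dense)) {
      P_i[1L] * sqrt((sd_dense / c_dense_measured[1L])^2 +
                     (sd_light / c_light[1L])^2)
    } else NA_real_
    out <- list(P = P_i[1L], se = se, replicates = P_i,
                dilution_factor = dilution_factor, method = "delta")
  }
  structure(out, class = "partition_measurement")
}

#' @export
print.partition_measurement <- function(x, digits = 3, ...) {
  cat("Partition coefficient P =", format(x$P, digits = digits))
  if (!is.na(x$se)) cat(" +/-", format(x$se, digits = digits))
  cat(" (dense-phase dilution factor ", x$dilution_factor, ")\n", sep = "")
  invisible(x)
}

#' Concentration from a linear calibration curve
#'
#' Fits ordinary least squares through `(concentration, peak area)`
#' calibration points and inverse-predicts the concentration of a sample
#' from its chromatographic peak area. Areas outside the calibrated range
#' are extrapolated with a warning flag.
#'
#' @param peak_area sample peak area(s).
#' @param calibration data frame with columns `conc` and `area`
#'   (>= 4 points recommended, matching four-standard calibration).
#' @param intercept fit an intercept (default TRUE); with `FALSE` a
#'   zero-area sample maps to zero concentration exactly.
#' @return data frame with `peak_area`, `conc` and `extrapolated`.
#' @export
calibration_concentration <- function(peak_area, calibration,
                                      intercept = TRUE) {
  calibration <- as.data.frame(calibration)
  stopifnot(all(c("conc", "area") %in% names(calibration)),
            nrow(calibration) >= 2)
  fit <- if (intercept) stats::lm(area ~ conc, data = calibration)
    else stats::lm(area ~ conc + 0, data = calibration)
  co <- stats::coef(fit)
  slope <- co[["conc"]]
  b0 <- if (intercept) co[["(Intercept)"]] else 0
  if (abs(slope) < .Machine$double.eps)
    stop("calibration has zero slope; cannot invert")
  conc <- (peak_area - b0) / slope
  extrap <- peak_area < min(calibration$area) - 1e-12 |
    peak_area > max(calibration$area) + 1e-12
  if (any(extrap))
    warning("peak area outside calibration range; extrapolating")
  data.frame(peak_area = peak_area, conc = conc, extrapolated = extrap)
}
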