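# Forward side of the population-based threshold models.
#
# Thermal time accumulates (T - Tb)*t below the optimum and (Tc - T)*t
# above it; hydrotime accumulates (psi - psi_b)*t; hydrothermal time
# accumulates (psi - psi_b)*(T - Tb)*t. A seed fraction g germinates
# once its accumulated total reaches the lot constant, and the spread
# of base water potentials across seeds is Normal(psi_b50, sigma_psib),
# which makes the cumulative germination fraction a probit surface.

#' Sub-optimal thermal time constant
#'
#' `theta_T1 = (T - Tb) * tg`: degree-hours above the base temperature
#' accumulated by germination fraction g at its germination time `tg`.
#'
#' @param temperature incubation temperature T, degC (> Tb).
#' @param Tb base temperature, degC.
#' @param tg germination time of the fraction, hours (> 0).
#' @return thermal time, degC h.
#' @export
thermal_time_sub <- function(temperature, Tb, tg) {
  if (any(temperature <= Tb)) {
    gt_stop("below base temperature: T <= Tb", "germtime_domain_error")
  }
  stopifnot(all(tg > 0))
  (temperature - Tb) * tg
}

#' Supra-optimal thermal time constant
#'
#' `theta_T2 = (Tc - T) * tg`: degree-hours below the ceiling
#' temperature accumulated by germination fraction g.
#'
#' @param temperature incubation temperature T, degC (< Tc).
#' @param Tc ceiling temperature, degC.
#' @inheritParams thermal_time_sub
#' @return thermal time, degC h.
#' @export
thermal_time_supra <- function(temperature, Tc, tg) {
  if (any(temperature >= Tc)) {
    gt_stop("above ceiling temperature: T >= Tc", "germtime_domain_error")
  }
  stopifnot(all(tg > 0))
  (Tc - temperature) * tg
}

#' Hydrotime constant
#'
#' `theta_H = (psi - psi_b) * tg`: megapascal-hours of water potential
#' in excess of the base potential accumulated by germination.
#'
#' @param psi water potential of the medium, MPa.
#' @param psi_b base water potential of the fraction, MPa (< psi).
#' @inheritParams thermal_time_sub
#' @return hydrotime, MPa h.
#' @export
hydrotime_constant <- function(psi, psi_b, tg) {
  if (any(psi <= psi_b)) {
    gt_stop("below base water potential: psi <= psi_b",
            "germtime_domain_error")
  }
  stopifnot(all(tg > 0))
  (psi - psi_b) * tg
}

#' Hydrothermal time constant
#'
#' `theta_HT = (psi - psi_b) * (T - Tb) * tg`.
#'
#' @inheritParams hydrotime_constant
#' @inheritParams thermal_time_sub
#' @return hydrothermal time, MPa degC h.
#' @export
hydrothermal_constant <- function(psi, psi_b, temperature, Tb, tg) {
  if (any(psi <= psi_b)) {
    gt_stop("below base water potential: psi <= psi_b",
            "germtime_domain_error")
  }
  if (any(temperature <= Tb)) {
    gt_stop("below base temperature: T <= Tb", "germtime_domain_error")
  }
  stopifnot(all(tg > 0))
  (psi - psi_b) * (temperature - Tb) * tg
}

#' Thermal-time germination rate
#'
#' `GR = (T - Tb) / theta_T1`, the reciprocal of the predicted
#' germination time at a sub-optimal temperature. At or below the base
#' temperature the rate is 0 (flagged with a warning).
#'
#' @param theta_T1 sub-optimal thermal time constant, degC h (> 0).
#' @inheritParams thermal_time_sub
#' @return rate in 1/h.
#' @export
gr_thermal <- function(theta_T1, temperature, Tb) {
  stopifnot(all(theta_T1 > 0))
  sub <- temperature <= Tb
  if (any(sub)) warning("sub-threshold: T <= Tb, rate set to 0", call. = FALSE)
  ifelse(sub, 0, (temperature - Tb) / theta_T1)
}

#' Hydrotime germination rate
#'
#' `GR = (psi - psi_b) / theta_H`. At or below the base water potential
#' the rate is 0 (flagged with a warning).
#'
#' @param theta_H hydrotime constant, MPa h (> 0).
#' @inheritParams hydrotime_constant
#' @return rate in 1/h.
#' @export
gr_hydro <- function(theta_H, psi, psi_b) {
  stopifnot(all(theta_H > 0))
  sub <- psi <= psi_b
  if (any(sub)) {
    warning("sub-threshold: psi <= psi_b, rate set to 0", call. = FALSE)
  }
  ifelse(sub, 0, (psi - psi_b) / theta_H)
}

#' Hydrothermal model parameter set
#'
#' Container for the parameters of the hydrothermal threshold model:
#' the lot constant `theta_HT` (MPa degC h), the base temperature `Tb`
#' (degC), the median base water potential `psi_b50` (MPa) and its
#' standard deviation `sigma_psib` (MPa) across seeds, and optionally
#' the optimum `To` and ceiling `Tc` temperatures (degC) and the
#' supra-optimal shift slope `kT` (MPa/degC) by which the median base
#' water potential rises above `To`.
#'
#' @param theta_HT hydrothermal time constant, MPa degC h (> 0).
#' @param Tb base temperature, degC.
#' @param psi_b50 median base water potential, MPa (normally < 0).
#' @param sigma_psib standard deviation of base water potentials, MPa
#'   (> 0).
#' @param To optimum temperature, degC (`NA` if not modelled).
#' @param Tc ceiling temperature, degC (`NA` if not modelled).
#' @param kT supra-optimal shift of `psi_b50`, MPa per degC above `To`
#'   (`NA` disables the supra-optimal branch).
#' @return an `htt_params` object.
#' @export
htt_params <- function(theta_HT, Tb, psi_b50, sigma_psib,
                       To = NA_real_, Tc = NA_real_, kT = NA_real_) {
  stopifnot(theta_HT > 0, sigma_psib > 0)
  if (!is.na(To) && To <= Tb) {
    gt_stop("optimum temperature must exceed base temperature",
            "germtime_validation_error")
  }
  if (!is.na(Tc) && ((!is.na(To) && Tc <= To) || Tc <= Tb)) {
    gt_stop("ceiling temperature must exceed optimum and base",
            "germtime_validation_error")
  }
  if (psi_b50 >= 0) {
    warning("psi_b50 >= 0 MPa is unusual for a real seed lot", call. = FALSE)
  }
  structure(list(theta_HT = theta_HT, Tb = Tb, psi_b50 = psi_b50,
                 sigma_psib = sigma_psib, To = To, Tc = Tc, kT = kT),
            class = "htt_params")
}

#' @export
print.htt_params <- function(x, ...) {
  cat("Hydrothermal time model parameters\n")
  cat(sprintf("  theta_HT : %.2f MPa degC h\n", x$theta_HT))
  cat(sprintf("  Tb       : %.2f degC\n", x$Tb))
  if (!is.na(x$To)) cat(sprintf("  To       : %.2f degC\n", x$To))
  if (!is.na(x$Tc)) cat(sprintf("  Tc       : %.2f degC\n", x$Tc))
  cat(sprintf("  psi_b50  : %.2f MPa\n", x$psi_b50))
  cat(sprintf("  sigma    : %.2f MPa\n", x$sigma_psib))
  if (!is.na(x$kT)) cat(sprintf("  kT       : %.3f MPa/degC\n", x$kT))
  invisible(x)
}

# Effective median base potential and thermal width at temperature T.
# Above the optimum the median base potential rises with slope kT and
# thermal time stops accumulating beyond To (width To - Tb).
htt_effective <- function(params, temperature) {
  psi_b50 <- rep(params$psi_b50, length(temperature))
  width <- temperature - params$Tb
  supra <- !is.na(params$To) & temperature > params$To
  if (any(supra)) {
    if (is.na(params$kT)) {
      warning(
        "temperature above optimum but kT not supplied: no germination predicted",
        call. = FALSE)
      width[supra] <- NA_real_
    } else {
      psi_b50[supra] <- params$psi_b50 + params$kT *
        (temperature[supra] - params$To)
      width[supra] <- params$To - params$Tb
    }
  }
  list(psi_b50 = psi_b50, width = width)
}

#' Predicted germination fraction under the hydrothermal model
#'
#' The cumulative fraction germinated by time `t` at water potential
#' `psi` and temperature `T`:
#' `g = Phi((psi - theta_HT / ((T - Tb) t) - psi_b50) / sigma_psib)`,
#' with `Phi` the standard normal CDF. For `T` above the optimum the
#' median base potential is shifted by `kT (T - To)` and the thermal
#' width capped at `To - Tb`. At or below `Tb` (and at or above `Tc`,
#' when given) the fraction is 0.
#'
#' @param params an [htt_params()] object.
#' @param psi water potential, MPa.
#' @param temperature temperature, degC.
#' @param time time since imbibition, hours (> 0).
#' @return fraction(s) in `[0, 1]`.
#' @export
predict_fraction <- function(params, psi, temperature, time) {
  stopifnot(inherits(params, "htt_params"), all(time > 0))
  n <- max(length(psi), length(temperature), length(time))
  psi <- rep_len(psi, n); temperature <- rep_len(temperature, n)
  time <- rep_len(time, n)
  eff <- htt_effective(params, temperature)
  z <- (psi - params$theta_HT / (eff$width * time) - eff$psi_b50) /
    params$sigma_psib
  g <- stats::pnorm(z)
  g[temperature <= params$Tb] <- 0
  if (!is.na(params$Tc)) g[temperature >= params$Tc] <- 0
  g[is.na(g)] <- 0  # supra branch without kT
  g
}

#' Predicted germination time under the hydrothermal model
#'
#' Closed-form inverse of [predict_fraction()]:
#' `tg = theta_HT / ((T - Tb) (psi - psi_b50 - sigma_psib * z_g))` with
#' `z_g` the standard normal quantile of `g`. A fraction whose
#' threshold potential exceeds `psi` can never germinate there.
#'
#' @inheritParams predict_fraction
#' @param g target fraction(s) in (0, 1), below the asymptotic maximum
#'   `Phi((psi - psi_b50)/sigma_psib)`.
#' @param strict if `TRUE` (default) an unreachable fraction raises an
#'   error; otherwise `NA` is returned for it.
#' @return germination time(s), hours.
#' @export
predict_time <- function(params, psi, temperature, g, strict = TRUE) {
  stopifnot(inherits(params, "htt_params"), all(g > 0), all(g < 1))
  n <- max(length(psi), length(temperature), length(g))
  psi <- rep_len(psi, n); temperature <- rep_len(temperature, n)
  g <- rep_len(g, n)
  if (any(temperature <= params$Tb)) {
    gt_stop("below base temperature: T <= Tb", "germtime_domain_error")
  }
  eff <- htt_effective(params, temperature)
  denom <- eff$width * (psi - eff$psi_b50 - params$sigma_psib * stats::qnorm(g))
  bad <- !is.finite(denom) | denom <= 0
  if (any(bad) && strict) {
    gt_stop(sprintf(
      "unreachable fraction: g = %.3f cannot germinate at psi = %g MPa, T = %g degC",
      g[bad][1L], psi[bad][1L], temperature[bad][1L]),
      "germtime_domain_error")
  }
  out <- params$theta_HT / denom
  out[bad] <- NA_real_
  out
}
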