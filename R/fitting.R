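# Inverse side: repeated probit regression.
#
# The germination fraction surface is linear in probit space:
#   probit(g) = (x - psi_b50) / sigma_psib
# with x = psi - theta_H / tg            (hydrotime, one temperature)
# or   x = psi - theta_HT / ((T - Tb) tg) (hydrothermal).
# For a candidate time constant theta the percentile observations
# (g, tg, psi, T) give x values; ordinary least squares of
# qnorm(g) on x scores the candidate by R^2, and the repeated probit
# scheme keeps the theta maximizing R^2 (coarse log-spaced grid, then
# golden-section refinement). psi_b50 = -intercept/slope and
# sigma_psib = 1/slope of the winning line.

#' Extract percentile observations for probit fitting
#'
#' For each treatment (replicates pooled by default) and each requested
#' percentile `g`, extracts the germination time `t(g)` by linear
#' interpolation of the cumulative germination curve. Percentiles never
#' reached by a treatment are skipped and the reason recorded in the
#' `"skipped"` attribute; fractions of exactly 0 or 1 never enter
#' probit space.
#'
#' @param ds a [germ_data] object.
#' @param percentiles target fractions, each in (0, 1). Default: the
#'   deciles 0.1..0.9.
#' @param pooled pool replicate dishes per treatment first (default
#'   `TRUE`); otherwise every dish contributes its own percentiles.
#' @return data.frame with columns `temperature_C`,
#'   `water_potential_MPa`, `g`, `tg_h`; attribute `"skipped"` holds a
#'   character log of unreachable percentiles.
#' @export
probit_points <- function(ds, percentiles = seq(0.1, 0.9, by = 0.1),
                          pooled = TRUE) {
  stopifnot(all(percentiles > 0), all(percentiles < 1))
  data <- if (pooled) pool_replicates(ds) else ds
  tcs <- timecourses(data)
  skipped <- character(0)
  rows <- lapply(tcs, function(tc) {
    tg <- time_to_fraction(tc, percentiles, strict = FALSE)
    miss <- is.na(tg)
    if (any(miss)) {
      skipped <<- c(skipped, sprintf(
        "%g degC / %g MPa (rep %s): percentile(s) %s beyond final fraction %.3f",
        tc$temperature, tc$water_potential, tc$replicate,
        paste(percentiles[miss], collapse = ", "),
        max(tc$cum_germinated) / tc$n_sown))
    }
    if (all(miss)) return(NULL)
    data.frame(temperature_C = tc$temperature,
               water_potential_MPa = tc$water_potential,
               g = percentiles[!miss], tg_h = tg[!miss])
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) < 3L) {
    gt_stop("insufficient data: fewer than 3 usable percentile points",
            "germtime_fit_error", data = list(skipped = skipped))
  }
  rownames(out) <- NULL
  structure(out, skipped = skipped)
}

#' Probit regression line
#'
#' Ordinary least squares of `qnorm(g)` on the threshold-adjusted
#' predictor `x`. Reports slope, intercept, R^2, residual standard
#' error, the regression F statistic (the squared slope t), the slope t
#' statistic and its two-sided p value, plus the implied median base
#' water potential `psi_b50 = -intercept/slope` and spread
#' `sigma_psib = 1/slope`.
#'
#' @param x predictor values (e.g. `psi - theta_H/tg`), not all equal.
#' @param g germination fractions in (0, 1), same length as `x`
#'   (>= 3 points).
#' @return a `probit_fit` object.
#' @export
fit_probit_line <- function(x, g) {
  stopifnot(length(x) == length(g), all(g > 0), all(g < 1))
  if (length(x) < 3L) {
    gt_stop("at least 3 points required for a probit fit",
            "germtime_fit_error")
  }
  if (stats::sd(x) == 0) {
    gt_stop("no variation in predictor", "germtime_fit_error")
  }
  y <- stats::qnorm(g)
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  slope <- unname(cf[2L]); intercept <- unname(cf[1L])
  res <- stats::residuals(fit)
  n <- length(x)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else 1 - rss / tss
  se <- sqrt(rss / (n - 2L))
  if (se > 0) {
    t_stat <- slope / (se / sqrt(sum((x - mean(x))^2)))
    p <- 2 * stats::pt(abs(t_stat), df = n - 2L, lower.tail = FALSE)
  } else {             # perfect fit: infinite evidence for the slope
    t_stat <- Inf * sign(slope)
    p <- 0
  }
  structure(list(slope = slope, intercept = intercept,
                 r2 = max(0, min(1, r2)), se = se,
                 f_stat = t_stat^2, t_stat = t_stat, p_value = p,
                 n_points = n,
                 psi_b50 = -intercept / slope,
                 sigma_psib = 1 / slope),
            class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("Probit regression fit\n")
  cat(sprintf("  psi_b50    : %.2f MPa\n", x$psi_b50))
  cat(sprintf("  sigma_psib : %.2f MPa\n", x$sigma_psib))
  cat(sprintf("  R^2 = %.3f, SE = %.3f, F = %.2f, t = %.2f, p = %.3g (n = %d)\n",
              x$r2, x$se, x$f_stat, x$t_stat, x$p_value, x$n_points))
  invisible(x)
}

# R^2 of qnorm(g) against x; 0 when x is degenerate.
probit_r2 <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

# Deterministic golden-section maximization of f on [lower, upper] to
# relative tolerance tol; ties resolved toward the smaller argument.
golden_section_max <- function(f, lower, upper, tol = 1e-4) {
  phi <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while ((b - a) > tol * max(abs(a), abs(b), 1e-12)) {
    if (f1 >= f2) {        # >= keeps the left (smaller) candidate on ties
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    }
  }
  if (f1 >= f2) list(x = x1, value = f1) else list(x = x2, value = f2)
}

# Coarse log-spaced grid then golden-section refinement of obj(theta).
search_theta <- function(obj, lower = 1, upper = 1e5, n_grid = 64,
                         tol = 1e-4) {
  grid <- exp(seq(log(lower), log(upper), length.out = n_grid))
  vals <- vapply(grid, obj, numeric(1))
  i <- which.max(vals)                    # first maximum = smaller theta
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  ref <- golden_section_max(obj, lo, hi, tol = tol)
  if (vals[i] > ref$value) list(theta = grid[i], value = vals[i]) else
    list(theta = ref$x, value = ref$value)
}

subset_treatments <- function(ds, temperature = NULL, psi = NULL) {
  df <- as.data.frame(ds)
  if (!is.null(temperature)) df <- df[df$temperature_C %in% temperature, ]
  if (!is.null(psi)) df <- df[df$water_potential_MPa %in% psi, ]
  germ_data(df, metadata = attr(ds, "metadata"))
}

#' Fit the hydrotime model at one temperature
#'
#' Repeated probit regression: for each candidate hydrotime constant
#' `theta_H` the predictor `x = psi - theta_H/tg` is formed from the
#' percentile observations and `qnorm(g)` is regressed on it; the
#' `theta_H` maximizing R^2 wins (coarse log-spaced grid followed by
#' golden-section refinement, deterministic given the grid
#' specification). The winning line yields `psi_b50 = -intercept/slope`
#' and `sigma_psib = 1/slope`.
#'
#' @param ds a [germ_data] object.
#' @param temperature the temperature (degC) whose treatments to fit;
#'   at least two distinct water potentials must yield usable
#'   percentiles there.
#' @param percentiles target fractions for [probit_points()].
#' @param theta_range search interval for `theta_H`, MPa h.
#' @param n_grid coarse grid size.
#' @param pooled pool replicates first (default `TRUE`).
#' @return list of class `ht_fit` with elements `params` (a list with
#'   `theta_H`, `psi_b50`, `sigma_psib`), `fit` (the winning
#'   [fit_probit_line()] object) and `points`.
#' @export
fit_hydrotime <- function(ds, temperature,
                          percentiles = seq(0.1, 0.9, by = 0.1),
                          theta_range = c(1, 1e5), n_grid = 64,
                          pooled = TRUE) {
  sub <- subset_treatments(ds, temperature = temperature)
  if (nrow(sub) == 0L) {
    gt_stop(sprintf("no treatments at %g degC", temperature),
            "germtime_fit_error")
  }
  pts <- probit_points(sub, percentiles, pooled = pooled)
  if (length(unique(pts$water_potential_MPa)) < 2L) {
    gt_stop("insufficient germination for HT fit: need >= 2 water potentials",
            "germtime_fit_error")
  }
  y <- stats::qnorm(pts$g)
  obj <- function(theta) probit_r2(pts$water_potential_MPa - theta / pts$tg_h, y)
  best <- search_theta(obj, theta_range[1], theta_range[2], n_grid)
  fit <- fit_probit_line(pts$water_potential_MPa - best$theta / pts$tg_h,
                         pts$g)
  if (fit$slope <= 0) {
    gt_stop("HT fit failed: non-positive probit slope", "germtime_fit_error")
  }
  structure(list(params = list(theta_H = best$theta,
                               psi_b50 = fit$psi_b50,
                               sigma_psib = fit$sigma_psib),
                 fit = fit, points = pts, temperature = temperature),
            class = "ht_fit")
}

#' @export
print.ht_fit <- function(x, ...) {
  cat(sprintf("Hydrotime fit at %g degC\n", x$temperature))
  cat(sprintf("  theta_H = %.2f MPa h, psi_b50 = %.2f MPa, sigma = %.2f MPa, R^2 = %.3f\n",
              x$params$theta_H, x$params$psi_b50, x$params$sigma_psib,
              x$fit$r2))
  invisible(x)
}

# GR of the given percentile per temperature (pooled), at the
# least-negative water potential present unless psi is given.
gr_by_temperature <- function(ds, psi = NULL, percentile = 0.5) {
  df <- as.data.frame(ds)
  if (is.null(psi)) psi <- max(df$water_potential_MPa)
  sub <- subset_treatments(ds, psi = psi)
  pooled <- pool_replicates(sub)
  tcs <- timecourses(pooled)
  temps <- vapply(tcs, function(tc) tc$temperature, numeric(1))
  gr <- vapply(tcs, function(tc) {
    tg <- time_to_fraction(tc, percentile, strict = FALSE)
    if (is.na(tg)) NA_real_ else 1 / tg
  }, numeric(1))
  ok <- !is.na(gr)
  data.frame(temperature_C = temps[ok], gr = gr[ok], psi = psi)
}

#' Fit the thermal time model and cardinal temperatures
#'
#' Computes the germination rate `GR = 1/t(g)` of the chosen percentile
#' at each temperature (one water potential, pooled replicates), splits
#' the temperatures into sub- and supra-optimal branches at the
#' rate-maximizing temperature (or a supplied optimum), and regresses
#' GR on temperature in each branch. The base temperature `Tb` is the
#' x-intercept of the rising branch, the ceiling `Tc` the x-intercept
#' of the falling branch, the optimum `To` their intersection;
#' `theta_T1 = 1/slope_sub` and `theta_T2 = -1/slope_supra`.
#'
#' @param ds a [germ_data] object.
#' @param psi the water potential (MPa) at which to take the rates;
#'   default the least-negative one present.
#' @param To_hint optional optimum temperature overriding the
#'   rate-maximizing split.
#' @param percentile percentile whose rate is regressed (default 0.5).
#' @return list of class `tt_fit` with `params` (`Tb`, `Tc`,
#'   `theta_T1`, `theta_T2`), `cardinal` (`Tb`, `To`, `Tc`,
#'   `sub_slope`, `supra_slope`, `r2_sub`, `r2_supra`) and the GR
#'   `points`. A branch with fewer than 2 temperatures leaves its
#'   parameters `NA` with a warning.
#' @export
fit_thermaltime <- function(ds, psi = NULL, To_hint = NULL,
                            percentile = 0.5) {
  pts <- gr_by_temperature(ds, psi = psi, percentile = percentile)
  if (nrow(pts) < 3L) {
    gt_stop("need GR at >= 3 temperatures for a thermal time fit",
            "germtime_fit_error")
  }
  if (stats::sd(pts$gr) == 0) {
    gt_stop("no thermal response: germination rate identical at all temperatures",
            "germtime_fit_error")
  }
  T_opt <- if (!is.null(To_hint)) To_hint else
    pts$temperature_C[which.max(pts$gr)]
  line_fit <- function(p) {
    fit <- stats::lm(gr ~ temperature_C, data = p)
    cf <- stats::coef(fit)
    tss <- sum((p$gr - mean(p$gr))^2)
    r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
    list(slope = unname(cf[2L]), intercept = unname(cf[1L]), r2 = r2)
  }
  sub <- pts[pts$temperature_C <= T_opt, , drop = FALSE]
  supra <- pts[pts$temperature_C >= T_opt, , drop = FALSE]
  sub_fit <- supra_fit <- NULL
  if (nrow(sub) >= 2L) sub_fit <- line_fit(sub) else
    warning("fewer than 2 sub-optimal temperatures: Tb/theta_T1 not estimated",
            call. = FALSE)
  if (nrow(supra) >= 2L) supra_fit <- line_fit(supra) else
    warning("fewer than 2 supra-optimal temperatures: Tc/theta_T2 not estimated",
            call. = FALSE)
  Tb <- To <- Tc <- theta_T1 <- theta_T2 <- NA_real_
  sub_slope <- supra_slope <- r2_sub <- r2_supra <- NA_real_
  if (!is.null(sub_fit)) {
    if (sub_fit$slope <= 0) {
      gt_stop("no thermal response: sub-optimal branch slope not positive",
              "germtime_fit_error")
    }
    Tb <- -sub_fit$intercept / sub_fit$slope
    theta_T1 <- 1 / sub_fit$slope
    sub_slope <- sub_fit$slope; r2_sub <- sub_fit$r2
  }
  if (!is.null(supra_fit)) {
    if (supra_fit$slope >= 0) {
      gt_stop("supra-optimal branch slope not negative",
              "germtime_fit_error")
    }
    Tc <- -supra_fit$intercept / supra_fit$slope
    theta_T2 <- -1 / supra_fit$slope
    supra_slope <- supra_fit$slope; r2_supra <- supra_fit$r2
  }
  if (!is.null(sub_fit) && !is.null(supra_fit)) {
    To <- (supra_fit$intercept - sub_fit$intercept) /
      (sub_fit$slope - supra_fit$slope)
  } else {
    To <- T_opt
  }
  structure(list(params = list(Tb = Tb, Tc = Tc, theta_T1 = theta_T1,
                               theta_T2 = theta_T2),
                 cardinal = list(Tb = Tb, To = To, Tc = Tc,
                                 sub_slope = sub_slope,
                                 supra_slope = supra_slope,
                                 r2_sub = r2_sub, r2_supra = r2_supra),
                 points = pts),
            class = "tt_fit")
}

#' @export
print.tt_fit <- function(x, ...) {
  cat("Thermal time fit\n")
  cat(sprintf("  Tb = %.2f, To = %.2f, Tc = %.2f degC\n",
              x$cardinal$Tb, x$cardinal$To, x$cardinal$Tc))
  cat(sprintf("  theta_T1 = %.2f, theta_T2 = %.2f degC h\n",
              x$params$theta_T1, x$params$theta_T2))
  invisible(x)
}

#' Fit the hydrothermal time model
#'
#' Repeated probit regression over the sub-optimal treatments
#' (temperatures at or below the optimum): for candidate
#' `(theta_HT, Tb)` the predictor is
#' `x = psi - theta_HT / ((T - Tb) tg)` and the candidate maximizing
#' the R^2 of `qnorm(g)` on `x` wins. With `Tb` fixed the search is the
#' 1-D grid-plus-golden-section scheme; with `Tb = "estimate"` a grid
#' of base temperatures is profiled and refined the same way.
#'
#' @param ds a [germ_data] object.
#' @param Tb base temperature in degC, or `"estimate"`.
#' @param percentiles target fractions for [probit_points()].
#' @param theta_range search interval for `theta_HT`, MPa degC h.
#' @param n_grid coarse grid size for the `theta_HT` search.
#' @param To optimum temperature bounding the sub-optimal subset;
#'   default: the temperature with the fastest median germination.
#' @param pooled pool replicates first (default `TRUE`).
#' @return list of class `htt_fit` with `params` (an [htt_params()]
#'   object, `kT` unset), `fit` (the winning probit line), `points`,
#'   and `To`.
#' @export
fit_htt <- function(ds, Tb = "estimate",
                    percentiles = seq(0.1, 0.9, by = 0.1),
                    theta_range = c(1, 1e5), n_grid = 64, To = NULL,
                    pooled = TRUE) {
  if (is.null(To)) {
    gr <- gr_by_temperature(ds)
    To <- gr$temperature_C[which.max(gr$gr)]
  }
  df <- as.data.frame(ds)
  sub <- subset_treatments(ds,
                           temperature = unique(df$temperature_C[df$temperature_C <= To]))
  pts <- probit_points(sub, percentiles, pooled = pooled)
  if (length(unique(pts$water_potential_MPa)) < 2L ||
      length(unique(pts$temperature_C)) < 2L) {
    gt_stop("HTT fit needs >= 2 water potentials and >= 2 sub-optimal temperatures",
            "germtime_fit_error")
  }
  y <- stats::qnorm(pts$g)
  obj_theta <- function(theta, tb) {
    probit_r2(pts$water_potential_MPa -
                theta / ((pts$temperature_C - tb) * pts$tg_h), y)
  }
  if (identical(Tb, "estimate")) {
    tb_hi <- min(pts$temperature_C) - 0.5
    tb_grid <- seq(0, tb_hi, by = 0.5)
    profile <- function(tb) {
      search_theta(function(th) obj_theta(th, tb),
                   theta_range[1], theta_range[2], n_grid)$value
    }
    vals <- vapply(tb_grid, profile, numeric(1))
    i <- which.max(vals)
    ref <- golden_section_max(profile,
                              tb_grid[max(1L, i - 1L)],
                              tb_grid[min(length(tb_grid), i + 1L)],
                              tol = 1e-4)
    Tb_hat <- if (vals[i] > ref$value) tb_grid[i] else ref$x
  } else {
    stopifnot(is.numeric(Tb))
    if (any(pts$temperature_C <= Tb)) {
      gt_stop("fixed Tb is not below every sub-optimal treatment temperature",
              "germtime_fit_error")
    }
    Tb_hat <- Tb
  }
  best <- search_theta(function(th) obj_theta(th, Tb_hat),
                       theta_range[1], theta_range[2], n_grid)
  x <- pts$water_potential_MPa -
    best$theta / ((pts$temperature_C - Tb_hat) * pts$tg_h)
  fit <- fit_probit_line(x, pts$g)
  if (fit$slope <= 0) {
    gt_stop("HTT fit failed: non-positive probit slope",
            "germtime_fit_error",
            data = list(theta = best$theta, r2 = fit$r2))
  }
  params <- htt_params(theta_HT = best$theta, Tb = Tb_hat,
                       psi_b50 = fit$psi_b50,
                       sigma_psib = fit$sigma_psib, To = To)
  structure(list(params = params, fit = fit, points = pts, To = To),
            class = "htt_fit")
}

#' @export
print.htt_fit <- function(x, ...) {
  cat("Hydrothermal time fit (sub-optimal treatments)\n")
  print(x$params)
  cat(sprintf("  R^2 = %.3f on %d percentile points\n",
              x$fit$r2, x$fit$n_points))
  invisible(x)
}

#' Supra-optimal shift slope kT
#'
#' Above the optimum temperature the median base water potential rises
#' approximately linearly. For every supra-optimal temperature the
#' median base potential is back-solved from the observed median
#' germination times, `psi_b50(T) = psi - theta_HT / ((To - Tb) t50)`,
#' averaged over water potentials, and regressed on `T - To`; `kT` is
#' the slope.
#'
#' @param ds a [germ_data] object.
#' @param params an [htt_params()] object with `To` set (e.g. from
#'   [fit_htt()]).
#' @param percentile percentile used for the back-solve (default 0.5).
#' @return `kT` in MPa/degC, with the per-temperature back-solved
#'   medians in attribute `"points"`; `NA` (with a warning) when fewer
#'   than 2 supra-optimal temperatures have usable times.
#' @export
fit_supra_kT <- function(ds, params, percentile = 0.5) {
  stopifnot(inherits(params, "htt_params"))
  if (is.na(params$To)) {
    gt_stop("params$To must be set to identify supra-optimal treatments",
            "germtime_fit_error")
  }
  df <- as.data.frame(ds)
  supra_T <- sort(unique(df$temperature_C[df$temperature_C > params$To]))
  rows <- list()
  for (temp in supra_T) {
    pooled <- pool_replicates(subset_treatments(ds, temperature = temp))
    for (tc in timecourses(pooled)) {
      t50 <- time_to_fraction(tc, percentile, strict = FALSE)
      if (is.na(t50)) next
      rows[[length(rows) + 1L]] <- data.frame(
        temperature_C = temp,
        psi_b50_T = tc$water_potential -
          params$theta_HT / ((params$To - params$Tb) * t50))
    }
  }
  pts <- do.call(rbind, rows)
  if (is.null(pts) || length(unique(pts$temperature_C)) < 2L) {
    warning("fewer than 2 supra-optimal temperatures with usable times: kT not estimated",
            call. = FALSE)
    return(structure(NA_real_, points = pts))
  }
  med <- stats::aggregate(psi_b50_T ~ temperature_C, data = pts, FUN = mean)
  fit <- stats::lm(psi_b50_T ~ I(temperature_C - params$To), data = med)
  structure(unname(stats::coef(fit)[2L]), points = med)
}
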