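# Pipeline assembly: configuration, parameter JSON IO, combined
# reports, and the command-line dispatcher used by the inst/exec
# wrapper script. Skipped dishes and unreachable percentiles are
# logged to standard error: silent exclusion is the main
# reproducibility hazard in germination fitting.

CONFIG_DEFAULTS <- list(
  input = NULL, traits = NULL, time_unit = "hours",
  percentiles = seq(0.1, 0.9, by = 0.1),
  theta_lower = 1, theta_upper = 1e5, n_grid = 64L,
  tb = "estimate", to = NULL, tc = NULL, psi_b = NULL,
  output_dir = ".", seed = NULL, verbosity = "INFO")

CONFIG_TYPES <- list(
  input = "character", traits = "character", time_unit = "character",
  percentiles = "numeric", theta_lower = "numeric",
  theta_upper = "numeric", n_grid = "numeric", tb = "any",
  to = "numeric", tc = "numeric", psi_b = "numeric",
  output_dir = "character", seed = "numeric", verbosity = "character")

#' Load a run configuration
#'
#' Reads a YAML key-value file, fills defaults, and validates. Unknown
#' keys and type mismatches are rejected by name. Percentiles may be
#' given as a YAML list or a comma-separated string and must lie
#' strictly inside (0, 1); `tb` is either a number or the string
#' `"estimate"`.
#'
#' @param path YAML file; an empty file yields all defaults.
#' @return a validated named list of class `germ_config`.
#' @export
load_config <- function(path) {
  raw <- if (file.exists(path)) yaml::read_yaml(path) else
    gt_stop(sprintf("config file not found: %s", path), "germtime_io_error")
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(CONFIG_DEFAULTS))
  if (length(unknown) > 0L) {
    gt_stop(sprintf("unknown config key(s): %s",
                    paste(unknown, collapse = ", ")),
            "germtime_schema_error")
  }
  cfg <- utils::modifyList(CONFIG_DEFAULTS, raw)
  if (is.character(cfg$percentiles) && length(cfg$percentiles) == 1L) {
    cfg$percentiles <- as.numeric(strsplit(cfg$percentiles, ",")[[1L]])
  }
  cfg$percentiles <- as.numeric(unlist(cfg$percentiles))
  for (key in names(raw)) {
    want <- CONFIG_TYPES[[key]]
    if (identical(want, "any")) next
    val <- cfg[[key]]
    ok <- switch(want,
                 character = is.character(val),
                 numeric = is.numeric(val) && !anyNA(val))
    if (!ok) {
      gt_stop(sprintf("config key '%s' must be %s", key, want),
              "germtime_schema_error")
    }
  }
  if (anyNA(cfg$percentiles) || any(cfg$percentiles <= 0) ||
      any(cfg$percentiles >= 1)) {
    gt_stop("config key 'percentiles' must lie strictly inside (0, 1)",
            "germtime_schema_error")
  }
  if (!identical(cfg$tb, "estimate") && !is.null(cfg$tb) &&
      !is.numeric(cfg$tb)) {
    gt_stop("config key 'tb' must be a number or \"estimate\"",
            "germtime_schema_error")
  }
  if (!cfg$time_unit %in% c("hours", "days")) {
    gt_stop("config key 'time_unit' must be \"hours\" or \"days\"",
            "germtime_schema_error")
  }
  structure(cfg, class = "germ_config")
}

#' Write a hydrothermal parameter set as JSON
#'
#' Keys are unit-annotated (`theta_HT_MPa_C_h`, `Tb_C`, `To_C`, `Tc_C`,
#' `psi_b50_MPa`, `sigma_psib_MPa`, `kT_MPa_per_C`).
#'
#' @param params an [htt_params()] object.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "htt_params"))
  obj <- list(theta_HT_MPa_C_h = params$theta_HT, Tb_C = params$Tb,
              To_C = params$To, Tc_C = params$Tc,
              psi_b50_MPa = params$psi_b50,
              sigma_psib_MPa = params$sigma_psib,
              kT_MPa_per_C = params$kT)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a hydrothermal parameter set from JSON
#'
#' @param path JSON file written by [write_params()] (or by hand with
#'   the same unit-annotated keys).
#' @return an [htt_params()] object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) {
    gt_stop(sprintf("params file not found: %s", path), "germtime_io_error")
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("theta_HT_MPa_C_h", "Tb_C", "psi_b50_MPa", "sigma_psib_MPa")
  missing_keys <- setdiff(need, names(obj))
  if (length(missing_keys) > 0L) {
    gt_stop(sprintf("params file missing key(s): %s",
                    paste(missing_keys, collapse = ", ")),
            "germtime_schema_error")
  }
  grab <- function(key) {
    v <- obj[[key]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  htt_params(theta_HT = grab("theta_HT_MPa_C_h"), Tb = grab("Tb_C"),
             psi_b50 = grab("psi_b50_MPa"),
             sigma_psib = grab("sigma_psib_MPa"),
             To = grab("To_C"), Tc = grab("Tc_C"),
             kT = grab("kT_MPa_per_C"))
}

#' Per-treatment threshold-model constants table
#'
#' Recomputes, for each treatment, the germination time of the chosen
#' percentile and the model constants from their defining equations:
#' `theta_T1 = (T - Tb) tg`, `theta_T2 = (Tc - T) tg`,
#' `theta_H = (psi - psi_b) tg`, `theta_HT = (psi - psi_b)(T - Tb) tg`,
#' and the rates `GR_TT = (T - Tb)/theta_T1 = 1/tg` and
#' `GR_HT = (psi - psi_b)/theta_H`.
#'
#' @param ds a [germ_data] object.
#' @param Tb base temperature, degC.
#' @param Tc ceiling temperature, degC.
#' @param psi_b base water potential used for the hydro constants, MPa.
#' @param percentile percentile whose time is used (default 0.5).
#' @return data.frame, one row per treatment; treatments that never
#'   reach the percentile carry `NA` constants.
#' @export
constants_table <- function(ds, Tb, Tc, psi_b, percentile = 0.5) {
  pooled <- pool_replicates(ds)
  rows <- lapply(timecourses(pooled), function(tc) {
    tg <- time_to_fraction(tc, percentile, strict = FALSE)
    base <- data.frame(temperature_C = tc$temperature,
                       water_potential_MPa = tc$water_potential,
                       tg_h = tg)
    if (is.na(tg)) {
      base[c("theta_T1", "theta_T2", "theta_H", "theta_HT",
             "gr_tt", "gr_ht")] <- NA_real_
      return(base)
    }
    base$theta_T1 <- if (tc$temperature > Tb)
      thermal_time_sub(tc$temperature, Tb, tg) else NA_real_
    base$theta_T2 <- if (tc$temperature < Tc)
      thermal_time_supra(tc$temperature, Tc, tg) else NA_real_
    base$theta_H <- if (tc$water_potential > psi_b)
      hydrotime_constant(tc$water_potential, psi_b, tg) else NA_real_
    base$theta_HT <- if (tc$water_potential > psi_b && tc$temperature > Tb)
      hydrothermal_constant(tc$water_potential, psi_b, tc$temperature,
                            Tb, tg) else NA_real_
    base$gr_tt <- if (!is.na(base$theta_T1))
      gr_thermal(base$theta_T1, tc$temperature, Tb) else NA_real_
    base$gr_ht <- if (!is.na(base$theta_H))
      gr_hydro(base$theta_H, tc$water_potential, psi_b) else NA_real_
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Combined analysis report
#'
#' Runs the whole estimation pipeline on a dataset: the thermal-time /
#' cardinal-temperature fit, one hydrotime fit per temperature, the
#' global hydrothermal fit over the sub-optimal treatments (plus the
#' supra-optimal `kT` when estimable), and the per-treatment constants
#' recomputed from the fitted thresholds.
#'
#' @param ds a [germ_data] object.
#' @param percentiles percentile set for the probit fits.
#' @param Tb base temperature or `"estimate"` (default).
#' @param To optional optimum temperature override.
#' @return list of class `germ_report` with elements `constants`
#'   (per-treatment data.frame), `ht_by_temperature` (data.frame of
#'   per-temperature hydrotime fits), `htt` (the [fit_htt()] result),
#'   `tt` (the [fit_thermaltime()] result or `NULL`), and `kT`.
#' @export
run_report <- function(ds, percentiles = seq(0.1, 0.9, by = 0.1),
                       Tb = "estimate", To = NULL) {
  tt <- tryCatch(fit_thermaltime(ds),
                 germtime_error = function(e) {
                   message("thermal time fit skipped: ",
                           conditionMessage(e))
                   NULL
                 })
  htt <- fit_htt(ds, Tb = Tb, percentiles = percentiles, To = To)
  log_skipped(attr(htt$points, "skipped"))
  kT <- suppressWarnings(fit_supra_kT(ds, htt$params))
  if (!is.na(kT)) htt$params$kT <- as.numeric(kT)

  df <- as.data.frame(ds)
  ht_rows <- lapply(sort(unique(df$temperature_C)), function(temp) {
    res <- tryCatch(fit_hydrotime(ds, temp, percentiles = percentiles),
                    germtime_error = function(e) {
                      message(sprintf("hydrotime fit at %g degC skipped: %s",
                                      temp, conditionMessage(e)))
                      NULL
                    })
    if (is.null(res)) return(NULL)
    data.frame(temperature_C = temp, theta_H = res$params$theta_H,
               psi_b50 = res$params$psi_b50,
               sigma_psib = res$params$sigma_psib,
               r2 = res$fit$r2, se = res$fit$se, f = res$fit$f_stat,
               t = res$fit$t_stat, sig = res$fit$p_value,
               n_points = res$fit$n_points)
  })
  ht_tab <- do.call(rbind, ht_rows)

  Tc_use <- if (!is.null(tt) && !is.na(tt$params$Tc)) tt$params$Tc else
    max(df$temperature_C) + 5
  constants <- constants_table(ds, Tb = htt$params$Tb, Tc = Tc_use,
                               psi_b = htt$params$psi_b50)
  structure(list(constants = constants, ht_by_temperature = ht_tab,
                 htt = htt, tt = tt, kT = as.numeric(kT)),
            class = "germ_report")
}

#' @export
print.germ_report <- function(x, ...) {
  cat("=== Germination model report ===\n\n")
  cat("Global hydrothermal fit:\n")
  print(x$htt)
  if (!is.na(x$kT)) cat(sprintf("  kT = %.3f MPa/degC\n", x$kT))
  if (!is.null(x$tt)) {
    cat("\n")
    print(x$tt)
  }
  if (!is.null(x$ht_by_temperature)) {
    cat("\nHydrotime fits by temperature:\n")
    tab <- x$ht_by_temperature
    tab[-1] <- lapply(tab[-1], function(v) round(v, 3))
    print(tab, row.names = FALSE)
  }
  cat(sprintf("\nPer-treatment constants: %d treatments (see $constants)\n",
              nrow(x$constants)))
  invisible(x)
}

log_skipped <- function(skipped) {
  for (s in skipped) message("skipped: ", s)
}

cli_usage <- function() {
  paste(
    "usage: germtime <subcommand> [--key value ...]",
    "subcommands:",
    "  simulate --params p.json [--design d.yaml] --seed N --out data.csv [--truth truth.csv]",
    "  indices  --input data.csv [--traits traits.csv] --out report.csv",
    "  fit-tt   --input data.csv --out fit.json [--psi P]",
    "  fit-ht   --input data.csv --temp T --out fit.json [--percentiles 0.2,0.5,0.8]",
    "  fit-htt  --input data.csv --out fit.json [--tb 10|estimate] [--percentiles ...]",
    "  predict  --params fit.json --psi P --temp T --time H",
    "  report   --input data.csv --out-dir DIR [--tb 10|estimate]",
    sep = "\n")
}

parse_cli_args <- function(argv) {
  opts <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) {
      gt_stop(sprintf("unexpected argument: %s", a), "germtime_cli_error")
    }
    if (i + 1L > length(argv)) {
      gt_stop(sprintf("flag %s needs a value", a), "germtime_cli_error")
    }
    opts[[sub("^--", "", a)]] <- argv[i + 1L]
    i <- i + 2L
  }
  opts
}

need_opt <- function(opts, name) {
  if (is.null(opts[[name]])) {
    gt_stop(sprintf("missing required flag --%s", name),
            "germtime_cli_error")
  }
  opts[[name]]
}

parse_percentiles <- function(opts) {
  if (is.null(opts$percentiles)) return(seq(0.1, 0.9, by = 0.1))
  p <- as.numeric(strsplit(opts$percentiles, ",")[[1L]])
  if (anyNA(p) || any(p <= 0) || any(p >= 1)) {
    gt_stop("percentiles must lie strictly inside (0, 1)",
            "germtime_cli_error")
  }
  p
}

write_manifest <- function(opts, subcommand, outputs, seed = NULL) {
  dir <- opts[["out-dir"]]
  if (is.null(dir)) dir <- dirname(outputs[[1L]])
  path <- file.path(dir, "manifest.json")
  obj <- list(tool = "germtime",
              version = as.character(utils::packageVersion("germtime")),
              subcommand = subcommand,
              options = opts,
              seed = seed,
              outputs = outputs,
              r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

fit_to_json <- function(res, path, kT = NA_real_) {
  p <- res$params
  obj <- list(theta_HT_MPa_C_h = p$theta_HT, theta_H_MPa_h = p$theta_H,
              Tb_C = p$Tb, To_C = p$To, Tc_C = p$Tc,
              psi_b50_MPa = p$psi_b50, sigma_psib_MPa = p$sigma_psib,
              kT_MPa_per_C = if (is.na(kT)) p$kT else kT,
              r2 = res$fit$r2, se = res$fit$se, f = res$fit$f_stat,
              t = res$fit$t_stat, sig = res$fit$p_value,
              n_points = res$fit$n_points)
  obj <- obj[!vapply(obj, is.null, logical(1))]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Command-line dispatcher
#'
#' Implements the `germtime` command line (see `inst/exec/germtime`
#' for the Rscript wrapper): subcommands `simulate`, `indices`,
#' `fit-tt`, `fit-ht`, `fit-htt`, `predict`, `report`. Messages go to
#' standard error; every file-producing run writes a `manifest.json`
#' beside its outputs recording options, seed and package version.
#'
#' @param argv character vector of arguments (excluding the program
#'   name).
#' @return exit status, invisibly: 0 on success, 2 on usage or
#'   validation errors.
#' @export
germtime_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L) {
    message(cli_usage())
    return(invisible(2L))
  }
  sub <- argv[1L]
  res <- tryCatch({
    opts <- parse_cli_args(argv[-1L])
    switch(
      sub,
      simulate = cli_simulate(opts),
      indices = cli_indices(opts),
      `fit-tt` = cli_fit_tt(opts),
      `fit-ht` = cli_fit_ht(opts),
      `fit-htt` = cli_fit_htt(opts),
      predict = cli_predict(opts),
      report = cli_report(opts),
      {
        message("unknown subcommand: ", sub)
        message(cli_usage())
        2L
      })
  }, germtime_error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(res)
}

cli_simulate <- function(opts) {
  params <- read_params(need_opt(opts, "params"))
  design <- if (!is.null(opts$design)) {
    d <- yaml::read_yaml(opts$design)
    do.call(simulation_design, d)
  } else simulation_design()
  seed <- if (!is.null(opts$seed)) as.integer(opts$seed) else NULL
  message("simulate: seed = ", if (is.null(seed)) "none" else seed)
  out <- need_opt(opts, "out")
  ds <- simulate_experiment(params, design, seed = seed,
                            truth = !is.null(opts$truth))
  write_dataset(ds, out)
  if (!is.null(opts$truth)) {
    utils::write.table(attr(ds, "truth"), opts$truth, sep = ",",
                       row.names = FALSE, quote = FALSE)
  }
  write_manifest(opts, "simulate", out, seed = seed)
  0L
}

cli_indices <- function(opts) {
  ds <- read_dataset(need_opt(opts, "input"))
  traits <- if (!is.null(opts$traits)) read_traits(opts$traits) else NULL
  out <- need_opt(opts, "out")
  rep <- germination_indices(ds, traits = traits)
  num <- vapply(rep, is.numeric, logical(1))
  rep[num] <- lapply(rep[num], function(v) round(v, 4))
  utils::write.table(rep, out, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  write_manifest(opts, "indices", out)
  0L
}

cli_fit_tt <- function(opts) {
  ds <- read_dataset(need_opt(opts, "input"))
  psi <- if (!is.null(opts$psi)) as.numeric(opts$psi) else NULL
  res <- fit_thermaltime(ds, psi = psi)
  out <- need_opt(opts, "out")
  obj <- c(res$params, res$cardinal[c("To", "sub_slope", "supra_slope",
                                      "r2_sub", "r2_supra")])
  jsonlite::write_json(obj, out, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  write_manifest(opts, "fit-tt", out)
  0L
}

cli_fit_ht <- function(opts) {
  ds <- read_dataset(need_opt(opts, "input"))
  temp <- as.numeric(need_opt(opts, "temp"))
  res <- fit_hydrotime(ds, temp, percentiles = parse_percentiles(opts))
  log_skipped(attr(res$points, "skipped"))
  out <- need_opt(opts, "out")
  obj <- list(temperature_C = temp, theta_H_MPa_h = res$params$theta_H,
              psi_b50_MPa = res$params$psi_b50,
              sigma_psib_MPa = res$params$sigma_psib,
              r2 = res$fit$r2, se = res$fit$se, f = res$fit$f_stat,
              t = res$fit$t_stat, sig = res$fit$p_value,
              n_points = res$fit$n_points)
  jsonlite::write_json(obj, out, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  write_manifest(opts, "fit-ht", out)
  0L
}

cli_fit_htt <- function(opts) {
  ds <- read_dataset(need_opt(opts, "input"))
  tb <- if (is.null(opts$tb) || opts$tb == "estimate") "estimate" else
    as.numeric(opts$tb)
  res <- fit_htt(ds, Tb = tb, percentiles = parse_percentiles(opts))
  log_skipped(attr(res$points, "skipped"))
  kT <- suppressWarnings(fit_supra_kT(ds, res$params))
  out <- need_opt(opts, "out")
  fit_to_json(res, out, kT = as.numeric(kT))
  write_manifest(opts, "fit-htt", out)
  0L
}

cli_predict <- function(opts) {
  params <- read_params(need_opt(opts, "params"))
  psi <- as.numeric(need_opt(opts, "psi"))
  temp <- as.numeric(need_opt(opts, "temp"))
  time <- as.numeric(need_opt(opts, "time"))
  g <- predict_fraction(params, psi, temp, time)
  cat(sprintf("%.6f\n", g))
  0L
}

cli_report <- function(opts) {
  ds <- read_dataset(need_opt(opts, "input"))
  dir <- need_opt(opts, "out-dir")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tb <- if (is.null(opts$tb) || opts$tb == "estimate") "estimate" else
    as.numeric(opts$tb)
  rep <- run_report(ds, Tb = tb)
  # rounding mirrors the conventional reporting precision:
  # constants to 2 decimals, rates to 3, potentials to 2
  constants <- rep$constants
  for (col in c("theta_T1", "theta_T2", "theta_H", "theta_HT")) {
    constants[[col]] <- round(constants[[col]], 2)
  }
  for (col in c("gr_tt", "gr_ht")) {
    constants[[col]] <- round(constants[[col]], 3)
  }
  constants$tg_h <- round(constants$tg_h, 2)
  utils::write.table(constants, file.path(dir, "constants.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(rep$ht_by_temperature)) {
    ht <- rep$ht_by_temperature
    ht[-1] <- lapply(ht[-1], function(v) round(v, 3))
    utils::write.table(ht, file.path(dir, "hydrotime_by_temperature.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE, na = "")
  }
  fit_to_json(rep$htt, file.path(dir, "htt_fit.json"), kT = rep$kT)
  write_manifest(opts, "report",
                 file.path(dir, c("constants.csv", "htt_fit.json")))
  0L
}
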