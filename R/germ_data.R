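# Core data model: germination time courses and delimited-text IO.
#
# A dataset is a data.frame (class "germ_data") with one row per
# dish x observation and columns
#   temperature_C, water_potential_MPa, replicate, time_h,
#   n_sown, germinated_cum
# Times are hours since imbibition throughout the package.

GERM_COLUMNS <- c("temperature_C", "water_potential_MPa", "replicate",
                  "time_h", "n_sown", "germinated_cum")

TRAIT_COLUMNS <- c("temperature_C", "water_potential_MPa", "replicate",
                   "seedling_length_cm", "fresh_weight_mg", "dry_weight_mg")

gt_stop <- function(message, class, data = NULL, call. = FALSE) {
  cond <- structure(
    class = c(class, "germtime_error", "error", "condition"),
    list(message = message, call = NULL, data = data)
  )
  stop(cond)
}

#' Construct a germination dataset
#'
#' Builds a validated germination dataset from a data.frame with one row
#' per dish and observation time. Counts are cumulative within a dish.
#' Internally all times are hours since imbibition; data recorded on a
#' daily schedule can be ingested with `time_unit = "days"`, which
#' multiplies the time column by 24.
#'
#' @param df data.frame with columns `temperature_C`,
#'   `water_potential_MPa`, `replicate`, `time_h`, `n_sown`,
#'   `germinated_cum`.
#' @param time_unit unit of the time column on input: `"hours"`
#'   (default) or `"days"`.
#' @param metadata optional named list of free-form provenance
#'   (species, seed lot, notes), stored as an attribute.
#' @return A `germ_data` object: the validated data.frame sorted by
#'   temperature, water potential (descending, so 0 MPa first),
#'   replicate and time.
#' @export
germ_data <- function(df, time_unit = c("hours", "days"),
                      metadata = list()) {
  time_unit <- match.arg(time_unit)
  df <- as.data.frame(df)
  missing_cols <- setdiff(GERM_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    gt_stop(sprintf("missing required column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "germtime_schema_error", data = list(columns = missing_cols))
  }
  df <- df[GERM_COLUMNS]
  for (col in c("temperature_C", "water_potential_MPa", "time_h")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$replicate <- as.character(df$replicate)
  df$n_sown <- as.integer(round(as.numeric(df$n_sown)))
  df$germinated_cum <- as.integer(round(as.numeric(df$germinated_cum)))
  if (time_unit == "days") df$time_h <- df$time_h * 24

  if (nrow(df) > 0L) {
    if (anyNA(df)) {
      gt_stop("missing values in required columns", "germtime_schema_error")
    }
    validate_germ_rows(df)
  }
  df <- sort_germ_rows(df)
  rownames(df) <- NULL
  structure(df, class = c("germ_data", "data.frame"), metadata = metadata)
}

sort_germ_rows <- function(df) {
  df[order(df$temperature_C, -df$water_potential_MPa,
           df$replicate, df$time_h), , drop = FALSE]
}

dish_key <- function(df) {
  paste0(df$temperature_C, "C/", df$water_potential_MPa, "MPa/rep ",
         df$replicate)
}

validate_germ_rows <- function(df) {
  if (any(df$water_potential_MPa > 0)) {
    gt_stop("water_potential_MPa must be <= 0 (osmotica only lower the potential)",
            "germtime_validation_error")
  }
  out_of_range <- df$temperature_C < 0 | df$temperature_C > 60
  if (any(!is.finite(df$temperature_C))) {
    gt_stop("temperature_C must be finite", "germtime_validation_error")
  }
  if (any(out_of_range)) {
    warning("temperature outside the physically usual 0-60 degC range",
            call. = FALSE)
  }
  if (any(df$time_h <= 0)) {
    gt_stop("observation times must be > 0 hours", "germtime_validation_error")
  }
  if (any(df$n_sown < 1L)) {
    gt_stop("n_sown must be >= 1", "germtime_validation_error")
  }
  key <- dish_key(df)
  dup <- duplicated(paste0(key, "@", df$time_h))
  if (any(dup)) {
    gt_stop(sprintf("duplicate observation for %s at time %g h",
                    key[dup][1L], df$time_h[dup][1L]),
            "germtime_validation_error")
  }
  for (k in unique(key)) {
    rows <- df[key == k, , drop = FALSE]
    rows <- rows[order(rows$time_h), , drop = FALSE]
    if (length(unique(rows$n_sown)) != 1L) {
      gt_stop(sprintf("n_sown varies within dish %s", k),
              "germtime_validation_error")
    }
    if (any(rows$germinated_cum < 0 | rows$germinated_cum > rows$n_sown)) {
      gt_stop(sprintf("cumulative count outside [0, n_sown] in dish %s", k),
              "germtime_validation_error")
    }
    dec <- diff(rows$germinated_cum) < 0L
    if (any(dec)) {
      i <- which(dec)[1L] + 1L
      gt_stop(sprintf("cumulative count decreases in dish %s at time %g h",
                      k, rows$time_h[i]),
              "germtime_validation_error",
              data = list(dish = k, time_h = rows$time_h[i]))
    }
  }
  invisible(df)
}

#' Read a germination dataset from delimited text
#'
#' Reads a CSV (default) or TSV file with the header
#' `temperature_C, water_potential_MPa, replicate, time_h, n_sown,
#' germinated_cum` and returns a validated [germ_data] object. Counts
#' are coerced to integers; rows are grouped by dish and sorted by
#' time. A missing column raises a schema error naming the column; a
#' decreasing cumulative count raises a validation error naming the
#' dish and time.
#'
#' @param path file to read.
#' @param sep field separator; `NULL` (default) chooses `"\t"` for
#'   `.tsv`/`.tab` files and `","` otherwise.
#' @param time_unit unit of the time column, `"hours"` or `"days"`.
#' @return a [germ_data] object.
#' @export
read_dataset <- function(path, sep = NULL, time_unit = c("hours", "days")) {
  if (!file.exists(path)) {
    gt_stop(sprintf("file not found: %s", path), "germtime_io_error")
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE,
                          fileEncoding = "UTF-8")
  germ_data(df, time_unit = match.arg(time_unit))
}

#' Write a germination dataset to delimited text
#'
#' Writes in a deterministic row order (temperature ascending, water
#' potential descending so that 0 MPa comes first, then replicate, then
#' time), so that write -> read -> write is byte-identical.
#'
#' @param ds a [germ_data] object.
#' @param path destination file.
#' @param sep field separator (default `","`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, sep = ",") {
  stopifnot(inherits(ds, "germ_data"))
  df <- sort_germ_rows(as.data.frame(ds))
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a seedling-traits table
#'
#' Expects columns `temperature_C, water_potential_MPa, replicate,
#' seedling_length_cm, fresh_weight_mg, dry_weight_mg` (one row per
#' dish). Dry weight must be positive and not exceed fresh weight;
#' seedling length must be non-negative.
#'
#' @param path file to read.
#' @param sep field separator; `NULL` auto-detects as in
#'   [read_dataset()].
#' @return validated data.frame of traits.
#' @export
read_traits <- function(path, sep = NULL) {
  if (!file.exists(path)) {
    gt_stop(sprintf("file not found: %s", path), "germtime_io_error")
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_traits(df)
}

validate_traits <- function(df) {
  missing_cols <- setdiff(TRAIT_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    gt_stop(sprintf("traits table missing column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "germtime_schema_error")
  }
  df$replicate <- as.character(df$replicate)
  if (any(df$dry_weight_mg <= 0)) {
    gt_stop("dry_weight_mg must be > 0", "germtime_validation_error")
  }
  if (any(df$fresh_weight_mg < df$dry_weight_mg)) {
    gt_stop("fresh_weight_mg must be >= dry_weight_mg",
            "germtime_validation_error")
  }
  if (any(df$seedling_length_cm < 0)) {
    gt_stop("seedling_length_cm must be >= 0", "germtime_validation_error")
  }
  df
}

#' Split a dataset into per-dish time courses
#'
#' @param ds a [germ_data] object.
#' @return list of `timecourse` objects, one per (treatment, replicate).
#' @export
timecourses <- function(ds) {
  stopifnot(inherits(ds, "germ_data"))
  df <- as.data.frame(ds)
  if (nrow(df) == 0L) return(list())
  key <- dish_key(df)
  lapply(split(df, factor(key, levels = unique(key))), function(rows) {
    rows <- rows[order(rows$time_h), , drop = FALSE]
    timecourse(temperature = rows$temperature_C[1L],
               water_potential = rows$water_potential_MPa[1L],
               replicate = rows$replicate[1L],
               n_sown = rows$n_sown[1L],
               times = rows$time_h,
               cum_germinated = rows$germinated_cum)
  })
}

#' Construct a single-dish time course
#'
#' @param temperature incubation temperature, degC.
#' @param water_potential osmotic potential of the medium, MPa (<= 0).
#' @param replicate dish identifier.
#' @param n_sown number of seeds sown in the dish.
#' @param times observation times, hours since imbibition, strictly
#'   increasing and positive.
#' @param cum_germinated cumulative germinated counts aligned with
#'   `times`, non-decreasing, within `[0, n_sown]`.
#' @return a `timecourse` object.
#' @export
timecourse <- function(temperature, water_potential, replicate,
                       n_sown, times, cum_germinated) {
  if (length(times) != length(cum_germinated) || length(times) < 1L) {
    gt_stop("times and cum_germinated must have equal length >= 1",
            "germtime_validation_error")
  }
  if (any(times <= 0) || any(diff(times) <= 0)) {
    gt_stop("times must be strictly increasing and > 0",
            "germtime_validation_error")
  }
  if (any(diff(cum_germinated) < 0)) {
    gt_stop("cum_germinated must be non-decreasing",
            "germtime_validation_error")
  }
  if (any(cum_germinated < 0 | cum_germinated > n_sown)) {
    gt_stop("cum_germinated must lie in [0, n_sown]",
            "germtime_validation_error")
  }
  structure(list(temperature = as.numeric(temperature),
                 water_potential = as.numeric(water_potential),
                 replicate = as.character(replicate),
                 n_sown = as.integer(n_sown),
                 times = as.numeric(times),
                 cum_germinated = as.integer(cum_germinated)),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("Time course: %g degC, %g MPa, rep %s, %d seeds, %d obs\n",
              x$temperature, x$water_potential, x$replicate, x$n_sown,
              length(x$times)))
  invisible(x)
}

#' Germinated fraction at a given time
#'
#' Step-function evaluation of the cumulative germinated fraction
#' (relative to seeds sown): the count at the latest observation at or
#' before `t`, divided by `n_sown`; 0 before the first observation.
#'
#' @param tc a [timecourse()] object.
#' @param t time(s) in hours, >= 0.
#' @return germination fraction(s) in `[0, 1]`.
#' @export
fraction_at_time <- function(tc, t) {
  stopifnot(inherits(tc, "timecourse"), all(t >= 0))
  idx <- findInterval(t, tc$times)
  counts <- c(0L, tc$cum_germinated)[idx + 1L]
  counts / tc$n_sown
}

#' Time to reach a germination fraction
#'
#' Inverts the cumulative germination curve by linear interpolation of
#' fraction against time, starting from the implicit origin (0 h, 0).
#' Returns the earliest time at which the interpolated fraction equals
#' `g`; if the fraction is first reached exactly at an observation, that
#' observation time is returned.
#'
#' @param tc a [timecourse()] object.
#' @param g target fraction(s), each strictly inside (0, 1).
#' @param strict if `TRUE` (default), a fraction never reached raises a
#'   condition of class `germtime_fraction_unreached` carrying the
#'   achieved maximum; if `FALSE`, `NA` is returned for it instead.
#' @return time(s) in hours.
#' @export
time_to_fraction <- function(tc, g, strict = TRUE) {
  stopifnot(inherits(tc, "timecourse"), all(g > 0), all(g < 1))
  f <- c(0, tc$cum_germinated / tc$n_sown)
  tt <- c(0, tc$times)
  fmax <- f[length(f)]
  vapply(g, function(gi) {
    if (fmax < gi) {
      if (strict) {
        gt_stop(sprintf(
          "fraction never reached: target %.3f, achieved maximum %.3f", gi, fmax),
          "germtime_fraction_unreached",
          data = list(target = gi, achieved = fmax))
      }
      return(NA_real_)
    }
    i <- which(f >= gi)[1L]   # earliest observation attaining g
    if (f[i] == gi) return(tt[i])
    # f[i-1] < g < f[i]: interpolate on the rising segment
    tt[i - 1L] + (gi - f[i - 1L]) / (f[i] - f[i - 1L]) * (tt[i] - tt[i - 1L])
  }, numeric(1))
}

#' Pool replicate dishes within each treatment
#'
#' Sums seeds sown and cumulative counts across the replicate dishes of
#' each treatment, so that pooled fractions are weighted by seeds sown.
#' All replicates of a treatment must share the observation schedule;
#' no resampling is attempted.
#'
#' @param ds a [germ_data] object.
#' @return a [germ_data] object with one pooled dish (replicate
#'   `"pooled"`) per treatment.
#' @export
pool_replicates <- function(ds) {
  stopifnot(inherits(ds, "germ_data"))
  df <- as.data.frame(ds)
  if (nrow(df) == 0L) return(ds)
  trt <- paste0(df$temperature_C, "C/", df$water_potential_MPa, "MPa")
  pooled <- lapply(split(df, factor(trt, levels = unique(trt))), function(rows) {
    per_rep <- split(rows, rows$replicate)
    sched <- lapply(per_rep, function(r) sort(r$time_h))
    if (length(unique(vapply(sched, paste, character(1), collapse = ","))) != 1L) {
      gt_stop(sprintf(
        "replicates of treatment %gC/%gMPa have different observation schedules",
        rows$temperature_C[1L], rows$water_potential_MPa[1L]),
        "germtime_validation_error")
    }
    times <- sched[[1L]]
    cum <- Reduce(`+`, lapply(per_rep, function(r)
      r$germinated_cum[order(r$time_h)]))
    data.frame(temperature_C = rows$temperature_C[1L],
               water_potential_MPa = rows$water_potential_MPa[1L],
               replicate = "pooled",
               time_h = times,
               n_sown = sum(vapply(per_rep, function(r) r$n_sown[1L],
                                   numeric(1))),
               germinated_cum = cum)
  })
  germ_data(do.call(rbind, pooled), metadata = attr(ds, "metadata"))
}

#' @export
print.germ_data <- function(x, ...) {
  df <- as.data.frame(x)
  n_trt <- length(unique(paste(df$temperature_C, df$water_potential_MPa)))
  n_dish <- length(unique(dish_key(df)))
  cat(sprintf(
    "Germination dataset: %d rows, %d treatment(s), %d dish(es)\n",
    nrow(df), n_trt, n_dish))
  if (nrow(df) > 0L) print(utils::head(df, 6L))
  invisible(x)
}
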