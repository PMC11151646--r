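# Closed-form germination and agronomic indices from daily counts.
#
# All daily-count operations take d = seeds newly germinated on each
# counting day, the day numbers, and total seeds sown. A time course on
# an arbitrary hourly schedule is first resampled to a daily grid with
# daily_counts().

check_daily <- function(d, days) {
  if (length(d) != length(days)) {
    gt_stop("d and days must have equal length", "germtime_validation_error")
  }
  if (length(days) > 0L && (any(days < 1) || any(diff(days) <= 0))) {
    gt_stop("days must be strictly increasing and >= 1",
            "germtime_validation_error")
  }
  if (any(d < 0)) {
    gt_stop("daily counts must be >= 0", "germtime_validation_error")
  }
  invisible(NULL)
}

#' Resample a time course to daily incremental counts
#'
#' Evaluates the cumulative step function at 24 h intervals and
#' differences it, giving the seeds newly germinated on each day. The
#' number of days spans the observation horizon.
#'
#' @param tc a [timecourse()] object.
#' @return list with `d` (incremental counts per day), `days` (1..D),
#'   and `n_sown`.
#' @export
daily_counts <- function(tc) {
  stopifnot(inherits(tc, "timecourse"))
  n_days <- ceiling(max(tc$times) / 24)
  cum <- round(fraction_at_time(tc, 24 * seq_len(n_days)) * tc$n_sown)
  list(d = as.integer(diff(c(0, cum))), days = seq_len(n_days),
       n_sown = tc$n_sown)
}

#' Germination percentage
#'
#' `G% = 100 * Ne / Nt`, the percentage of sown seeds (`Nt`) that
#' germinated (`Ne`). No viability correction is applied.
#'
#' @param d incremental germinated counts per counting day.
#' @param n_sown total seeds sown (> 0).
#' @return percentage in `[0, 100]`.
#' @export
germination_percentage <- function(d, n_sown) {
  stopifnot(n_sown > 0)
  if (sum(d) > n_sown) {
    gt_stop("total germinated exceeds seeds sown", "germtime_validation_error")
  }
  100 * sum(d) / n_sown
}

#' Germination energy
#'
#' `GE = sum_j (X_j - X_(j-1)) / Y_j` with `X_0 = 0`: each day's newly
#' germinated seeds divided by the day number, summed over counting
#' days.
#'
#' @param d incremental counts per counting day.
#' @param days counting day numbers (strictly increasing, >= 1).
#' @return the rate sum (seeds per day, summed).
#' @export
germination_energy <- function(d, days) {
  check_daily(d, days)
  sum(d / days)
}

#' Mean germination time
#'
#' `MGT = sum(f * x) / sum(f)` where `f` is the count of seeds newly
#' germinated on day `x`. Undefined (NA) when no seed germinated.
#'
#' @inheritParams germination_energy
#' @return days; `NA` if total germination is zero.
#' @export
mean_germination_time <- function(d, days) {
  check_daily(d, days)
  if (sum(d) == 0) return(NA_real_)
  sum(d * days) / sum(d)
}

#' Mean germination rate
#'
#' The reciprocal of the mean germination time.
#'
#' @param mgt mean germination time in days (> 0), possibly `NA`.
#' @return 1/days; `NA` propagates.
#' @export
mean_germination_rate <- function(mgt) {
  if (is.na(mgt)) return(NA_real_)
  stopifnot(mgt > 0)
  1 / mgt
}

#' Germination index
#'
#' Weighted count giving early germination the largest weight:
#' `GI = sum_j (D - day_j + 1) * d_j`, the generalization of the
#' classical 10-day form `10*n1 + 9*n2 + ... + 1*n10` to an assay of
#' `D` days.
#'
#' @inheritParams germination_energy
#' @param n_days total assay length `D` in days (default: last
#'   counting day).
#' @return weighted count.
#' @export
germination_index <- function(d, days, n_days = max(days)) {
  check_daily(d, days)
  stopifnot(n_days >= max(c(days, 1)))
  sum((n_days - days + 1) * d)
}

#' Germination rate index
#'
#' `GRI = G1/1 + G2/2 + ... + Gx/x` where `G_j` is the incremental
#' germination percentage on day `j` (`100 * d_j / Nt`).
#'
#' @inheritParams germination_energy
#' @param n_sown total seeds sown.
#' @return percent-per-day sum.
#' @export
germination_rate_index <- function(d, days, n_sown) {
  check_daily(d, days)
  stopifnot(n_sown > 0)
  sum(100 * d / n_sown / days)
}

#' Timson germination index
#'
#' The default (`mode = "cumulative"`, the common Timson reading of
#' "sum of G over T") averages the cumulative daily germination
#' percentage over the `D` assay days. `mode = "incremental"` instead
#' sums incremental daily percentages and divides by `D`, which
#' collapses to `G%/D`.
#'
#' @inheritParams germination_rate_index
#' @param n_days total assay length `D` in days.
#' @param mode `"cumulative"` (default) or `"incremental"`.
#' @return percent.
#' @export
timson_index <- function(d, days, n_sown, n_days = max(days),
                         mode = c("cumulative", "incremental")) {
  mode <- match.arg(mode)
  check_daily(d, days)
  stopifnot(n_sown > 0, n_days >= max(c(days, 1)))
  if (mode == "incremental") return(100 * sum(d) / n_sown / n_days)
  full_days <- seq_len(n_days)
  cum <- vapply(full_days, function(j) sum(d[days <= j]), numeric(1))
  sum(100 * cum / n_sown) / n_days
}

#' Seed vigor index I (length based)
#'
#' `SVI-I = seedling length (cm) x germination percentage`.
#'
#' @param length_cm seedling length, cm (>= 0).
#' @param g_pct germination percentage.
#' @return cm x percent.
#' @export
seed_vigor_index_I <- function(length_cm, g_pct) {
  stopifnot(all(length_cm >= 0))
  length_cm * g_pct
}

#' Seed vigor index II (dry-weight based)
#'
#' `SVI-II = seedling dry weight (mg) x germination percentage`.
#'
#' @param dry_mg seedling dry weight, mg (>= 0).
#' @param g_pct germination percentage.
#' @return mg x percent.
#' @export
seed_vigor_index_II <- function(dry_mg, g_pct) {
  stopifnot(all(dry_mg >= 0))
  dry_mg * g_pct
}

#' Mean moisture content
#'
#' `MMC = (fresh weight - dry weight) / dry weight`, a dimensionless
#' water-to-dry-matter ratio.
#'
#' @param fresh_mg fresh weight, mg.
#' @param dry_mg dry weight, mg (> 0, <= fresh weight).
#' @return ratio >= 0.
#' @export
mean_moisture_content <- function(fresh_mg, dry_mg) {
  stopifnot(all(dry_mg > 0))
  if (any(fresh_mg < dry_mg)) {
    gt_stop("fresh weight below dry weight", "germtime_validation_error")
  }
  (fresh_mg - dry_mg) / dry_mg
}

#' Full index report for a dataset
#'
#' Computes every index for each treatment (replicates pooled, the
#' default) or each dish. Counts are resampled to a daily grid first.
#' Vigor indices and moisture content are filled in where a traits
#' table is supplied; traits of pooled treatments are replicate means.
#' Undefined values (e.g. MGT with zero germination) are `NA`, never 0.
#'
#' @param ds a [germ_data] object.
#' @param traits optional traits data.frame (see [read_traits()]).
#' @param by `"treatment"` (pooled, default) or `"dish"`.
#' @param timson_mode passed to [timson_index()].
#' @return data.frame with one row per treatment or dish and columns
#'   `g_pct, ge, mgt, mgr, gi, gri, tgi, svi1, svi2, mmc`.
#' @export
germination_indices <- function(ds, traits = NULL,
                                by = c("treatment", "dish"),
                                timson_mode = c("cumulative", "incremental")) {
  by <- match.arg(by)
  timson_mode <- match.arg(timson_mode)
  if (!is.null(traits)) traits <- validate_traits(as.data.frame(traits))
  data <- if (by == "treatment") pool_replicates(ds) else ds
  tcs <- timecourses(data)
  rows <- lapply(tcs, function(tc) {
    dc <- daily_counts(tc)
    g_pct <- germination_percentage(dc$d, dc$n_sown)
    mgt <- mean_germination_time(dc$d, dc$days)
    tr <- trait_means(traits, tc, pooled = (by == "treatment"))
    data.frame(
      temperature_C = tc$temperature,
      water_potential_MPa = tc$water_potential,
      replicate = tc$replicate,
      n_sown = dc$n_sown,
      g_pct = g_pct,
      ge = germination_energy(dc$d, dc$days),
      mgt = mgt,
      mgr = mean_germination_rate(mgt),
      gi = germination_index(dc$d, dc$days),
      gri = germination_rate_index(dc$d, dc$days, dc$n_sown),
      tgi = timson_index(dc$d, dc$days, dc$n_sown, mode = timson_mode),
      svi1 = if (is.na(tr$length_cm)) NA_real_ else
        seed_vigor_index_I(tr$length_cm, g_pct),
      svi2 = if (is.na(tr$dry_mg)) NA_real_ else
        seed_vigor_index_II(tr$dry_mg, g_pct),
      mmc = if (is.na(tr$fresh_mg) || is.na(tr$dry_mg)) NA_real_ else
        mean_moisture_content(tr$fresh_mg, tr$dry_mg)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

trait_means <- function(traits, tc, pooled) {
  empty <- list(length_cm = NA_real_, fresh_mg = NA_real_, dry_mg = NA_real_)
  if (is.null(traits)) return(empty)
  sel <- traits$temperature_C == tc$temperature &
    traits$water_potential_MPa == tc$water_potential
  if (!pooled) sel <- sel & traits$replicate == tc$replicate
  rows <- traits[sel, , drop = FALSE]
  if (nrow(rows) == 0L) return(empty)
  list(length_cm = mean(rows$seedling_length_cm),
       fresh_mg = mean(rows$fresh_weight_mg),
       dry_mg = mean(rows$dry_weight_mg))
}
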