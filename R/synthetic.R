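# Monte-Carlo generator of germination experiments.
#
# The generator and the forward model are the same law: seed i of a
# dish draws its base water potential psi_b,i ~ Normal(psi_b50,
# sigma_psib) and germinates at
#   tg,i = theta_HT / ((psi - psi_b,i) * (T - Tb))
# when psi > psi_b,i and Tb < T (<= To; above the optimum the shifted
# supra-optimal branch applies when kT is available). Observation is
# interval-censored to the scoring schedule, mirroring daily counting:
# fitting never sees exact event times.

#' Simulation design for a germination experiment
#'
#' The default design mirrors a standard osmotic-stress germination
#' assay: 6 temperatures (15-40 degC) x 5 PEG-imposed water potentials
#' (0 to -1.2 MPa) x 3 replicate dishes of 10 seeds, scored daily for
#' 14 days.
#'
#' @param temperatures incubation temperatures, degC.
#' @param potentials water potentials, MPa (<= 0).
#' @param replicates dishes per treatment.
#' @param seeds_per_dish seeds sown per dish (>= 1).
#' @param schedule observation times in hours, strictly increasing.
#' @param viability fraction of seeds capable of germinating at all,
#'   in (0, 1].
#' @return a `sim_design` object.
#' @export
simulation_design <- function(temperatures = c(15, 20, 25, 30, 35, 40),
                              potentials = c(0, -0.3, -0.6, -0.9, -1.2),
                              replicates = 3,
                              seeds_per_dish = 10,
                              schedule = 24 * (1:14),
                              viability = 1) {
  stopifnot(seeds_per_dish >= 1, replicates >= 1,
            viability > 0, viability <= 1,
            length(schedule) >= 1, all(schedule > 0))
  if (any(diff(schedule) <= 0)) {
    gt_stop("schedule must be strictly increasing",
            "germtime_validation_error")
  }
  if (any(potentials > 0)) {
    gt_stop("water potentials must be <= 0", "germtime_validation_error")
  }
  structure(list(temperatures = as.numeric(temperatures),
                 potentials = as.numeric(potentials),
                 replicates = as.integer(replicates),
                 seeds_per_dish = as.integer(seeds_per_dish),
                 schedule = as.numeric(schedule),
                 viability = viability),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf(
    "Simulation design: %d T x %d psi x %d reps x %d seeds, %d observations to %g h\n",
    length(x$temperatures), length(x$potentials), x$replicates,
    x$seeds_per_dish, length(x$schedule), max(x$schedule)))
  invisible(x)
}

# Exact germination time of each seed given its base potential;
# Inf for seeds that can never germinate under the treatment.
seed_times <- function(params, psi, temperature, psi_b) {
  if (temperature <= params$Tb) return(rep(Inf, length(psi_b)))
  if (!is.na(params$Tc) && temperature >= params$Tc) {
    return(rep(Inf, length(psi_b)))
  }
  width <- temperature - params$Tb
  if (!is.na(params$To) && temperature > params$To) {
    if (is.na(params$kT)) return(rep(Inf, length(psi_b)))
    psi_b <- psi_b + params$kT * (temperature - params$To)
    width <- params$To - params$Tb
  }
  tg <- rep(Inf, length(psi_b))
  can <- psi_b < psi
  tg[can] <- params$theta_HT / ((psi - psi_b[can]) * width)
  tg
}

#' Simulate a germination experiment
#'
#' Draws per-seed base water potentials from
#' `Normal(psi_b50, sigma_psib)`, computes each seed's exact
#' germination time under the hydrothermal model and censors it to the
#' scoring schedule: the cumulative count at a scheduled time is the
#' number of viable seeds whose germination time has passed. Seeds
#' whose base potential is at or above the medium potential never
#' germinate under the treatment; non-viable seeds never germinate
#' anywhere. Both produce the same observable but are distinguished in
#' the truth records.
#'
#' @param params an [htt_params()] object.
#' @param design a [simulation_design()] object.
#' @param seed integer RNG seed (R's default Mersenne-Twister stream);
#'   `NULL` leaves the RNG state alone.
#' @param truth if `TRUE`, attach a per-seed data.frame (dish, seed,
#'   `psi_b`, `viable`, exact `tg_h`, `Inf` when never germinating) as
#'   attribute `"truth"`. Truth records are for diagnostics and oracle
#'   tests; fitting must never read them.
#' @return a [germ_data] object.
#' @export
simulate_experiment <- function(params, design, seed = NULL,
                                truth = FALSE) {
  stopifnot(inherits(params, "htt_params"), inherits(design, "sim_design"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (all(outer(design$temperatures, params$Tb, `<=`))) {
    warning("all treatment temperatures are at or below Tb: dataset will be all zeros",
            call. = FALSE)
  }
  rows <- list(); truth_rows <- list()
  for (temp in design$temperatures) {
    for (psi in design$potentials) {
      for (rep_i in seq_len(design$replicates)) {
        n <- design$seeds_per_dish
        psi_b <- stats::rnorm(n, params$psi_b50, params$sigma_psib)
        viable <- stats::runif(n) <= design$viability
        tg <- seed_times(params, psi, temp, psi_b)
        tg[!viable] <- Inf
        cum <- vapply(design$schedule, function(s) sum(tg <= s), integer(1))
        rows[[length(rows) + 1L]] <- data.frame(
          temperature_C = temp, water_potential_MPa = psi,
          replicate = as.character(rep_i), time_h = design$schedule,
          n_sown = n, germinated_cum = cum)
        if (truth) {
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            temperature_C = temp, water_potential_MPa = psi,
            replicate = as.character(rep_i), seed = seq_len(n),
            psi_b = psi_b, viable = viable, tg_h = tg)
        }
      }
    }
  }
  ds <- germ_data(do.call(rbind, rows),
                  metadata = list(source = "simulated",
                                  seed = if (is.null(seed)) NA else seed))
  if (truth) attr(ds, "truth") <- do.call(rbind, truth_rows)
  ds
}

#' Simulate seedling traits
#'
#' One traits row per dish from a linear response surface:
#' `value = baseline + effect_psi * psi + effect_T * (T - T_ref) +
#' Normal(0, noise)`. Dry weight never exceeds fresh weight and both
#' stay positive by construction (values are floored).
#'
#' @param design a [simulation_design()] object.
#' @param trait_model named list with baselines `length_cm`,
#'   `fresh_mg`, `dry_mg`; slopes `length_per_MPa`, `fresh_per_MPa`,
#'   `dry_per_MPa` (per MPa of water potential), `length_per_C`,
#'   `fresh_per_C`, `dry_per_C` (per degC away from `T_ref`); `T_ref`;
#'   and `noise` (common Gaussian SD). Missing entries default to 0
#'   effects, `T_ref = 25`, `noise = 0`.
#' @param seed integer RNG seed; `NULL` leaves the RNG state alone.
#' @return traits data.frame as accepted by [germination_indices()].
#' @export
simulate_traits <- function(design, trait_model = list(), seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  tm <- utils::modifyList(list(length_cm = 5, fresh_mg = 120, dry_mg = 40,
                               length_per_MPa = 0, fresh_per_MPa = 0,
                               dry_per_MPa = 0, length_per_C = 0,
                               fresh_per_C = 0, dry_per_C = 0,
                               T_ref = 25, noise = 0),
                          trait_model)
  rows <- list()
  for (temp in design$temperatures) {
    for (psi in design$potentials) {
      for (rep_i in seq_len(design$replicates)) {
        dT <- temp - tm$T_ref
        noise <- if (tm$noise > 0) stats::rnorm(3, 0, tm$noise) else c(0, 0, 0)
        len <- tm$length_cm + tm$length_per_MPa * psi +
          tm$length_per_C * dT + noise[1L]
        fresh <- tm$fresh_mg + tm$fresh_per_MPa * psi +
          tm$fresh_per_C * dT + noise[2L]
        dry <- tm$dry_mg + tm$dry_per_MPa * psi +
          tm$dry_per_C * dT + noise[3L]
        dry <- max(dry, 0.1)
        fresh <- max(fresh, dry)
        rows[[length(rows) + 1L]] <- data.frame(
          temperature_C = temp, water_potential_MPa = psi,
          replicate = as.character(rep_i),
          seedling_length_cm = max(len, 0),
          fresh_weight_mg = fresh, dry_weight_mg = dry)
      }
    }
  }
  validate_traits(do.call(rbind, rows))
}
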