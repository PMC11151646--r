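# Fixture builders shared across test files. All fixtures are built in
# code; nothing is read from disk except files the tests write first.

# One dish as data.frame rows.
dish_rows <- function(temperature, psi, rep, times, cum, n_sown = 10) {
  data.frame(temperature_C = temperature, water_potential_MPa = psi,
             replicate = as.character(rep), time_h = times,
             n_sown = n_sown, germinated_cum = cum)
}

# Dataset whose pooled median germination time is exactly t50 for each
# treatment: two seeds, the first germinating exactly at t50.
exact_t50_dataset <- function(temperatures, potentials, t50_fun) {
  rows <- list()
  for (temp in temperatures) {
    for (psi in potentials) {
      t50 <- t50_fun(temp, psi)
      if (is.na(t50)) next
      rows[[length(rows) + 1L]] <- dish_rows(
        temp, psi, "1", c(t50, t50 + 24), c(1L, 2L), n_sown = 2)
    }
  }
  germ_data(do.call(rbind, rows))
}

# Near-exact cumulative-fraction dataset: n_sown large so that
# round(n * g(t)) tracks the analytic fraction to ~1e-6. g_fun(t)
# returns the model fraction at each time.
fraction_dataset <- function(temperatures, potentials, g_fun,
                             schedule = seq(4, 600, by = 4),
                             n_sown = 1e6L) {
  rows <- list()
  for (temp in temperatures) {
    for (psi in potentials) {
      g <- g_fun(temp, psi, schedule)
      rows[[length(rows) + 1L]] <- dish_rows(
        temp, psi, "1", schedule, as.integer(round(g * n_sown)),
        n_sown = n_sown)
    }
  }
  germ_data(do.call(rbind, rows))
}

# Standard lot used in recovery tests: the generating truth.
truth_params <- function(To = 35) {
  htt_params(theta_HT = 1500, Tb = 10, psi_b50 = -1.2,
             sigma_psib = 0.19, To = To)
}

# Analytic sub-optimal hydrothermal fraction surface for the truth lot.
truth_fraction <- function(params) {
  function(temp, psi, t) {
    stats::pnorm((psi - params$theta_HT / ((temp - params$Tb) * t) -
                    params$psi_b50) / params$sigma_psib)
  }
}
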