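# Repeated probit regression: percentile extraction, probit lines,
# hydrotime / thermal time / hydrothermal fits, supra-optimal kT.

test_that("probit_points extracts reachable percentiles and logs the rest", {
  df <- rbind(dish_rows(25, 0, 1, 24 * (1:6), c(1L, 3L, 6L, 8L, 9L, 9L)),
              dish_rows(25, -1.2, 1, 24 * (1:6), rep(0L, 6)),
              dish_rows(25, -0.6, 1, 24 * (1:6), c(0L, 2L, 4L, 5L, 6L, 6L)))
  pts <- probit_points(germ_data(df))
  # first dish reaches 0.9 exactly, second nothing, third 0.6
  expect_setequal(pts$g[pts$water_potential_MPa == 0],
                  seq(0.1, 0.9, by = 0.1))
  expect_setequal(pts$g[pts$water_potential_MPa == -0.6],
                  seq(0.1, 0.6, by = 0.1))
  expect_false(any(pts$water_potential_MPa == -1.2))
  expect_true(any(grepl("-1.2 MPa", attr(pts, "skipped"))))

  df <- rbind(df, dish_rows(25, -0.3, 1, 24 * (1:6),
                            c(1L, 2L, 5L, 7L, 8L, 8L)))
  pts50 <- probit_points(germ_data(df), percentiles = 0.5)
  expect_equal(nrow(pts50), 3L)   # one point per treatment above 50%

  none <- germ_data(dish_rows(25, 0, 1, 24 * (1:3), c(0L, 0L, 0L)))
  expect_error(probit_points(none), "insufficient",
               class = "germtime_fit_error")
})

test_that("a noise-free probit line returns the generating parameters", {
  # points exactly on probit(g) = (x - psi_b50)/sigma with
  # psi_b50 = -1.2, sigma = 0.19
  x <- seq(-1.5, -0.9, by = 0.1)
  g <- pnorm((x + 1.2) / 0.19)
  fit <- fit_probit_line(x, g)
  expect_equal(fit$slope, 1 / 0.19, tolerance = 1e-9)
  expect_equal(fit$psi_b50, -1.2, tolerance = 1e-9)
  expect_equal(fit$sigma_psib, 0.19, tolerance = 1e-9)
  expect_equal(fit$r2, 1)
  expect_equal(fit$se, 0, tolerance = 1e-12)
  expect_lt(fit$p_value, 1e-10)
  expect_gt(fit$f_stat, 1e6)
})

test_that("three collinear points give a perfect but honest fit", {
  x <- c(-1, -0.5, 0)
  g <- pnorm(2 * x + 1)
  fit <- fit_probit_line(x, g)
  expect_equal(fit$r2, 1)
  expect_equal(fit$se, 0, tolerance = 1e-12)
  expect_equal(fit$n_points, 3L)
  expect_error(fit_probit_line(rep(-0.5, 4), c(0.2, 0.4, 0.6, 0.8)),
               "no variation", class = "germtime_fit_error")
  expect_error(fit_probit_line(c(0, 1), c(0.3, 0.7)),
               class = "germtime_fit_error")
})

test_that("balanced symmetric perturbations leave the OLS slope unchanged", {
  x <- c(-1.2, -0.9, -0.6, -0.3)
  y0 <- 2 * x + 1
  eps <- 0.05
  y <- y0 + c(eps, -eps, -eps, eps)   # orthogonal to x
  fit <- fit_probit_line(x, pnorm(y))
  # closed-form OLS oracle
  slope_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit$slope, slope_oracle, tolerance = 1e-12)
  expect_equal(slope_oracle, 2, tolerance = 1e-12)
})

test_that("hydrotime fitting recovers generating parameters from clean data", {
  theta_H <- 100; psi_b50 <- -1.2; sigma <- 0.2
  g_fun <- function(temp, psi, t) pnorm((psi - theta_H / t - psi_b50) / sigma)
  ds <- fraction_dataset(20, c(0, -0.3, -0.6), g_fun,
                         schedule = seq(2, 400, by = 2))
  res <- fit_hydrotime(ds, 20)
  expect_equal(res$params$theta_H, 100, tolerance = 0.005)
  expect_equal(res$params$psi_b50, -1.2, tolerance = 0.01)
  expect_equal(res$params$sigma_psib, 0.2, tolerance = 0.01)
  expect_gt(res$fit$r2, 0.999)
})

test_that("the hydrotime optimizer matches exhaustive grid search", {
  theta_H <- 120; psi_b50 <- -1.1; sigma <- 0.25
  g_fun <- function(temp, psi, t) pnorm((psi - theta_H / t - psi_b50) / sigma)
  ds <- fraction_dataset(25, c(0, -0.4, -0.8), g_fun,
                         schedule = seq(2, 500, by = 2))
  res <- fit_hydrotime(ds, 25)
  grid <- 1:300
  r2 <- brute_force_ht(res$points, grid)
  expect_gte(res$fit$r2, max(r2) - 1e-4)
  expect_lte(abs(res$params$theta_H - grid[which.max(r2)]), 1)
})

test_that("hydrotime fitting refuses a single water potential", {
  theta_H <- 100
  g_fun <- function(temp, psi, t) pnorm((psi - theta_H / t + 1.2) / 0.2)
  ds <- fraction_dataset(20, 0, g_fun, schedule = seq(2, 300, by = 2))
  expect_error(fit_hydrotime(ds, 20), ">= 2 water potentials",
               class = "germtime_fit_error")
})

test_that("thermal time fit solves exact two-branch rate lines", {
  # GR = (T-10)/1000 rising to T = 30, GR = (45-T)/750 falling after
  temps <- c(15, 20, 25, 30, 35, 40)
  t50_fun <- function(temp, psi) {
    if (temp <= 30) 1000 / (temp - 10) else 750 / (45 - temp)
  }
  ds <- exact_t50_dataset(temps, 0, t50_fun)
  res <- fit_thermaltime(ds, psi = 0)
  expect_equal(res$params$Tb, 10, tolerance = 1e-9)
  expect_equal(res$params$Tc, 45, tolerance = 1e-9)
  expect_equal(res$params$theta_T1, 1000, tolerance = 1e-6)
  expect_equal(res$params$theta_T2, 750, tolerance = 1e-6)
  expect_equal(res$cardinal$To, 30, tolerance = 1e-9)
  expect_equal(res$cardinal$r2_sub, 1)
  expect_equal(res$cardinal$r2_supra, 1)
})

test_that("degenerate thermal responses are rejected or partially fitted", {
  flat <- exact_t50_dataset(c(15, 25, 35), 0, function(temp, psi) 100)
  expect_error(fit_thermaltime(flat), "no thermal response",
               class = "germtime_fit_error")
  # two sub-optimal points only: Tb from the exact line through them
  two <- exact_t50_dataset(c(15, 20, 25), 0, function(temp, psi) {
    if (temp <= 20) 1000 / (temp - 10) else 4000 / (temp - 10)
  })
  # rate peaks at 20; supra branch has the 20-25 pair
  res <- suppressWarnings(fit_thermaltime(two))
  expect_equal(res$cardinal$sub_slope, 1 / 1000, tolerance = 1e-9)
  expect_equal(res$params$Tb, 10, tolerance = 1e-6)
})

test_that("hydrothermal fitting recovers generating parameters from clean data", {
  truth <- truth_params()
  ds <- fraction_dataset(c(15, 20, 25, 30), c(0, -0.3, -0.6, -0.9, -1.2),
                         truth_fraction(truth),
                         schedule = seq(4, 700, by = 4))
  res <- fit_htt(ds, Tb = 10)
  expect_equal(res$params$theta_HT, 1500, tolerance = 0.005)
  expect_equal(res$params$psi_b50, -1.2, tolerance = 0.01)
  expect_equal(res$params$sigma_psib, 0.19, tolerance = 0.01)
  expect_gt(res$fit$r2, 0.999)
  # estimating Tb jointly lands on the truth as well
  res2 <- fit_htt(ds, Tb = "estimate")
  expect_equal(res2$params$Tb, 10, tolerance = 0.3)
  expect_equal(res2$params$theta_HT, 1500, tolerance = 0.05)
})

test_that("the hydrothermal optimizer matches a 2-D exhaustive grid", {
  truth <- truth_params()
  ds <- fraction_dataset(c(15, 22, 30), c(0, -0.5, -1.0),
                         truth_fraction(truth),
                         schedule = seq(4, 700, by = 4))
  res <- fit_htt(ds, Tb = "estimate")
  thetas <- seq(500, 3000, by = 50)
  tbs <- seq(4, 14, by = 1)
  best <- -Inf; best_theta <- NA; best_tb <- NA
  for (tb in tbs) {
    r2 <- brute_force_htt(res$points, thetas, tb)
    if (max(r2) > best) {
      best <- max(r2); best_theta <- thetas[which.max(r2)]; best_tb <- tb
    }
  }
  expect_gte(res$fit$r2, best - 0.01 * best)
  expect_lte(abs(res$params$theta_HT - best_theta), 50)
  expect_lte(abs(res$params$Tb - best_tb), 1)
})

test_that("fits are deterministic given the same inputs and grid", {
  truth <- truth_params()
  ds <- simulate_experiment(truth, simulation_design(), seed = 77)
  f1 <- fit_htt(ds, Tb = 10)
  f2 <- fit_htt(ds, Tb = 10)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$fit, f2$fit)
})

test_that("estimates tighten as seeds per dish grow", {
  # a fine scoring schedule keeps interval-censoring error small, so
  # what remains is sampling error, which must shrink with dish size
  truth <- truth_params()
  err_at <- function(n, seed) {
    d <- simulation_design(seeds_per_dish = n, replicates = 3,
                           schedule = seq(6, 720, by = 6))
    ds <- simulate_experiment(truth, d, seed = seed)
    abs(fit_htt(ds, Tb = 10)$params$psi_b50 - truth$psi_b50)
  }
  e_small <- vapply(1:5, function(s) err_at(10, s), numeric(1))
  e_large <- vapply(1:5, function(s) err_at(1000, 100 + s), numeric(1))
  expect_lt(mean(e_large), mean(e_small))
  expect_lt(mean(e_large), 0.02)
})

test_that("the supra-optimal shift slope is recovered from exact lines", {
  params <- htt_params(1500, 10, -1.2, 0.19, To = 30)
  t50_fun_k <- function(kT) function(temp, psi) {
    psib <- -1.2 + kT * (temp - 30)
    if (psi <= psib) return(NA_real_)
    1500 / ((psi - psib) * (30 - 10))
  }
  ds <- exact_t50_dataset(c(33, 36, 39), c(0, -0.3), t50_fun_k(0.1))
  expect_equal(as.numeric(fit_supra_kT(ds, params)), 0.1, tolerance = 1e-9)
  ds0 <- exact_t50_dataset(c(33, 36), 0, t50_fun_k(0))
  expect_equal(as.numeric(fit_supra_kT(ds0, params)), 0, tolerance = 1e-9)
  # nothing above the optimum: flagged, not invented
  sub_only <- exact_t50_dataset(c(20, 25), 0, function(temp, psi) 100)
  expect_warning(k <- fit_supra_kT(sub_only, params), "supra-optimal")
  expect_true(is.na(k))
})
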