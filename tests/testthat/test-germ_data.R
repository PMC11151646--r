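# Data model, IO and time-course extraction.

test_that("reading a one-temperature CSV yields one time course per dish", {
  # 5 potentials x 3 reps x 6 daily observations = 90 rows
  set.seed(11)
  rows <- list()
  for (psi in c(0, -0.3, -0.6, -0.9, -1.2)) {
    for (rep in 1:3) {
      cum <- cumsum(c(sample(0:3, 1), sample(0:2, 5, replace = TRUE)))
      cum <- pmin(cum, 10L)
      rows[[length(rows) + 1L]] <- dish_rows(20, psi, rep, 24 * (1:6), cum)
    }
  }
  df <- do.call(rbind, rows)
  expect_equal(nrow(df), 90L)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  ds <- read_dataset(path)
  expect_s3_class(ds, "germ_data")
  expect_length(timecourses(ds), 15L)
  expect_true(is.integer(ds$germinated_cum))
})

test_that("schema and validation errors name the offending piece", {
  df <- dish_rows(20, -0.3, 1, c(24, 48), c(2L, 4L))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[setdiff(names(df), "n_sown")], path, row.names = FALSE)
  expect_error(read_dataset(path), "n_sown",
               class = "germtime_schema_error")

  bad <- dish_rows(20, -0.3, 1, c(24, 48), c(5L, 4L))
  expect_error(germ_data(bad), "decreases.*48",
               class = "germtime_validation_error")

  dup <- rbind(df, df[1, ])
  expect_error(germ_data(dup), "duplicate",
               class = "germtime_validation_error")

  pos_psi <- dish_rows(20, 0.3, 1, 24, 1L)
  expect_error(germ_data(pos_psi), class = "germtime_validation_error")
})

test_that("write -> read round-trips and a second write is byte-identical", {
  set.seed(7)
  ds <- simulate_experiment(truth_params(),
                            simulation_design(temperatures = c(20, 25),
                                              potentials = c(0, -0.6),
                                              schedule = 24 * (1:6)),
                            seed = 7)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, p1)
  back <- read_dataset(p1)
  expect_equal(as.data.frame(back), as.data.frame(ds), ignore_attr = TRUE)
  write_dataset(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("an empty dataset writes a header-only file", {
  empty <- germ_data(data.frame(temperature_C = numeric(0),
                                water_potential_MPa = numeric(0),
                                replicate = character(0),
                                time_h = numeric(0), n_sown = integer(0),
                                germinated_cum = integer(0)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(empty, path)
  expect_length(readLines(path), 1L)
})

test_that("a daily-unit reader converts days to hours on ingest", {
  df <- dish_rows(20, 0, 1, 1:3, c(1L, 3L, 6L))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  ds <- read_dataset(path, time_unit = "days")
  expect_equal(sort(ds$time_h), c(24, 48, 72))
})

test_that("fraction_at_time is a right-continuous step function", {
  tc <- timecourse(25, 0, "1", 10, times = c(24, 48), cum_germinated = c(2, 6))
  expect_equal(fraction_at_time(tc, 30), 0.2)
  expect_equal(fraction_at_time(tc, 0), 0)
  expect_equal(fraction_at_time(tc, 1000), 0.6)
  expect_equal(fraction_at_time(tc, 24), 0.2)  # jump at the observation
})

test_that("fraction_at_time is non-decreasing for random time courses", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    times <- sort(sample(seq(6, 400, by = 2), 8))
    cum <- cumsum(sample(0:3, 8, replace = TRUE))
    cum <- pmin(cum, n)
    tc <- timecourse(25, 0, "1", n, times, cum)
    f <- fraction_at_time(tc, seq(0, 420, by = 1))
    expect_true(all(diff(f) >= 0))
  }
})

test_that("time_to_fraction interpolates linearly with earliest-time ties", {
  tc <- timecourse(25, 0, "1", 10, c(24, 48, 72), c(2, 6, 9))
  expect_equal(time_to_fraction(tc, 0.5), 42)     # between 0.2@24 and 0.6@48
  expect_equal(time_to_fraction(tc, 0.2), 24)     # exact hit at an observation
  expect_equal(time_to_fraction(tc, 0.1), 12)     # rises from the origin

  flat <- timecourse(25, 0, "1", 10, c(24, 48, 72), c(5, 5, 9))
  expect_equal(time_to_fraction(flat, 0.5), 24)   # earliest time on the plateau

  short <- timecourse(25, 0, "1", 10, c(24, 48), c(2, 4))
  err <- tryCatch(time_to_fraction(short, 0.5), condition = identity)
  expect_s3_class(err, "germtime_fraction_unreached")
  expect_equal(err$data$achieved, 0.4)
  expect_true(is.na(time_to_fraction(short, 0.5, strict = FALSE)))
})

test_that("time_to_fraction and fraction_at_time agree at observations", {
  set.seed(9)
  for (i in 1:25) {
    times <- sort(sample(seq(12, 300, by = 12), 6))
    cum <- pmin(cumsum(sample(0:3, 6, replace = TRUE)), 10)
    tc <- timecourse(25, 0, "1", 10, times, cum)
    fmax <- max(cum) / 10
    for (g in c(0.1, 0.3, 0.5, 0.7)) {
      if (fmax < g) next
      tg <- time_to_fraction(tc, g)
      if (tg %in% times) expect_gte(fraction_at_time(tc, tg), g)
    }
  }
})

test_that("pooling sums counts and seeds and rejects mismatched schedules", {
  df <- rbind(dish_rows(25, 0, 1, 24, 2L), dish_rows(25, 0, 2, 24, 3L),
              dish_rows(25, 0, 3, 24, 4L))
  pooled <- pool_replicates(germ_data(df))
  expect_equal(pooled$n_sown, 30)
  expect_equal(pooled$germinated_cum, 9L)

  single <- germ_data(dish_rows(25, 0, 1, c(24, 48), c(2L, 5L)))
  pooled1 <- pool_replicates(single)
  expect_equal(pooled1$germinated_cum, single$germinated_cum)
  expect_equal(pooled1$n_sown, single$n_sown)

  mism <- rbind(dish_rows(25, 0, 1, c(24, 48), c(1L, 2L)),
                dish_rows(25, 0, 2, c(24, 72), c(1L, 2L)))
  expect_error(pool_replicates(germ_data(mism)), "schedule",
               class = "germtime_validation_error")
})

test_that("pooling preserves total germinated and total sown exactly", {
  ds <- simulate_experiment(truth_params(),
                            simulation_design(temperatures = c(20, 30),
                                              potentials = c(0, -0.9),
                                              schedule = 24 * (1:8)),
                            seed = 3)
  pooled <- pool_replicates(ds)
  last_per_dish <- function(d) {
    df <- as.data.frame(d)
    key <- paste(df$temperature_C, df$water_potential_MPa, df$replicate)
    vapply(split(df, key), function(r) {
      c(r$germinated_cum[which.max(r$time_h)], r$n_sown[1L])
    }, numeric(2))
  }
  expect_equal(sum(last_per_dish(pooled)[1, ]), sum(last_per_dish(ds)[1, ]))
  expect_equal(sum(last_per_dish(pooled)[2, ]), sum(last_per_dish(ds)[2, ]))
})
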