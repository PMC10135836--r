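make_ratio_df <- function(values, day = 9, grid = tiny_grid(3)) {
  # constant ratio across the grid per egg
  df <- expand.grid(frequency_hz = as.numeric(grid),
                    egg_id = names(values),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$day <- day
  df$ratio <- values[df$egg_id]
  structure(df[, c("egg_id", "day", "frequency_hz", "ratio")], grid = grid)
}

test_that("threshold classifier calls male above 1, female below, boundary unknown", {
  g <- tiny_grid(3)
  cfg <- classifier_config(day = 9, frequency = as.numeric(g)[2])
  r <- make_ratio_df(c(a = 1.122262, b = 0.953107, c = 1.0), grid = g)
  calls <- classify_eggs(r, cfg)
  expect_identical(calls$sex[match(c("a", "b", "c"), calls$egg_id)],
                   c("male", "female", "unknown"))
  expect_identical(unique(calls$source), "impedance")
})

test_that("margin widens the indeterminate zone and classification is monotone", {
  g <- tiny_grid(3)
  cfg <- classifier_config(day = 9, frequency = as.numeric(g)[1],
                           margin = 0.05)
  r <- make_ratio_df(c(lo = 0.90, mid = 1.03, hi = 1.10), grid = g)
  calls <- classify_eggs(r, cfg)
  expect_identical(calls$sex[match(c("lo", "mid", "hi"), calls$egg_id)],
                   c("female", "unknown", "male"))
  # monotone: increasing r walks female -> unknown -> male, never back
  rs <- seq(0.5, 1.5, by = 0.01)
  lab <- vapply(rs, function(v) {
    classify_eggs(make_ratio_df(c(x = v), grid = g), cfg)$sex
  }, character(1))
  code <- c(female = 1L, unknown = 2L, male = 3L)[lab]
  expect_true(all(diff(code) >= 0))
})

test_that("off-grid frequencies are rejected with a pointer to the snapper", {
  r <- make_ratio_df(c(a = 1.2))
  expect_error(classify_eggs(r, classifier_config(frequency = 12345)),
               "nearest_grid_frequency")
})

test_that("band-average classification uses the mean in-band ratio", {
  g <- frequency_grid(c(1e5, 4e5, 1e6, 3e6, 1e7))
  df <- make_ratio_df(c(a = 1), grid = g)
  # above 1 inside the default band, far below outside: band average decides
  df$ratio <- ifelse(df$frequency_hz >= 3.76e5 & df$frequency_hz <= 2.79e6,
                     1.2, 0.2)
  cfg <- classifier_config(day = 9, band_average = TRUE)
  expect_identical(classify_eggs(df, cfg)$sex, "male")
})

test_that("evaluation reports confusion, accuracy and indeterminates", {
  truth <- sex_labels(c("1", "2", "3", "4"),
                      c("male", "male", "female", "female"))
  pred <- sex_labels(c("1", "2", "3", "4"),
                     c("male", "female", "female", "unknown"),
                     source = "impedance")
  rep <- evaluate(pred, truth)
  expect_identical(rep$n_indeterminate, 1L)
  expect_identical(rep$n_classified, 3L)
  expect_equal(rep$accuracy, 2 / 3)
  expect_equal(rep$male_sensitivity, 0.5)
  expect_equal(rep$female_sensitivity, 1)
  # perfect predictions
  perfect <- evaluate(truth, truth)
  expect_equal(perfect$accuracy, 1)
  # all indeterminate: accuracy undefined, counted
  allu <- sex_labels(c("1", "2", "3", "4"), "unknown", source = "impedance")
  repu <- evaluate(allu, truth)
  expect_true(is.na(repu$accuracy))
  expect_identical(repu$n_indeterminate, 4L)
  expect_error(evaluate(sex_labels("9", "male", "impedance"), truth), "9")
})

test_that("closed-form sensitivities behave and match the reference operating point", {
  sym <- expected_accuracy(1, 0.1, 1, 0.1, threshold = 1)
  expect_equal(unlist(sym), c(male_sens = 0.5, female_sens = 0.5,
                              balanced = 0.5))
  ref <- expected_accuracy(1.122262, 0.112674, 0.953107, 0.124892)
  expect_equal(ref$male_sens, pnorm(0.122262 / 0.112674), tolerance = 1e-12)
  expect_equal(ref$female_sens, pnorm(0.046893 / 0.124892), tolerance = 1e-12)
  # monotone in mu_m
  mus <- seq(0.9, 1.3, by = 0.05)
  ms <- vapply(mus, function(m) expected_accuracy(m, 0.1, 0.95, 0.1)$male_sens,
               numeric(1))
  expect_true(all(diff(ms) > 0))
  expect_error(expected_accuracy(1, 0, 1, 0.1), "sd")
})

test_that("empirical sensitivities converge to the closed form (moderate n)", {
  sim <- suppressMessages(simulate_cohort(cohort_sim_config(
    n_male = 600, n_female = 600, days = 9, seed = 99)))
  r <- ratio_dataset(sim$sweeps)
  f <- nearest_grid_frequency(attr(r, "grid"), 3.76e5)$frequency
  rep <- evaluate(classify_eggs(r, classifier_config(frequency = f)),
                  sim$labels)
  ref <- expected_accuracy(1.122262, 0.112674, 0.953107, 0.124892)
  expect_lt(abs(rep$male_sensitivity - ref$male_sens), 0.05)
  expect_lt(abs(rep$female_sensitivity - ref$female_sens), 0.05)
})
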