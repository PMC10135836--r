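test_that("t_test_raw agrees with stats::t.test for welch and pooled", {
  set.seed(21)
  for (i in 1:50) {
    x <- rnorm(sample(3:12, 1), 1, runif(1, 0.05, 0.3))
    y <- rnorm(sample(3:12, 1), runif(1, 0.8, 1.2), runif(1, 0.05, 0.3))
    w <- t_test_raw(x, y, scan_config(variant = "welch"))
    ref <- t.test(x, y)
    expect_equal(w$t_stat, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-12)
    p <- t_test_raw(x, y, scan_config(variant = "pooled"))
    refp <- t.test(x, y, var.equal = TRUE)
    expect_equal(p$p_value, refp$p.value, tolerance = 1e-12)
    expect_identical(p$df, length(x) + length(y) - 2)
    # one-tailed p is half the two-tailed p at the same |t|
    w1 <- t_test_raw(x, y, scan_config(tails = 1))
    expect_equal(w1$p_value, w$p_value / 2, tolerance = 1e-12)
  }
})

test_that("identical groups give t = 0, two-tailed p = 1", {
  x <- c(1.0, 1.1, 0.9, 1.05)
  r <- t_test_raw(x, x)
  expect_equal(r$t_stat, 0)
  expect_equal(r$p_value, 1)
})

test_that("summary-statistic test equals the raw-data test to 1e-12", {
  set.seed(33)
  for (i in 1:200) {
    x <- rnorm(sample(3:10, 1)); y <- rnorm(sample(3:10, 1))
    for (v in c("welch", "pooled")) {
      cfg <- scan_config(variant = v)
      a <- t_test_raw(x, y, cfg)
      b <- t_test_summary(mean(x), sd(x), length(x),
                          mean(y), sd(y), length(y), cfg)
      expect_equal(a$t_stat, b$t_stat, tolerance = 1e-12)
      expect_equal(a$df, b$df, tolerance = 1e-12)
      expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    }
  }
})

test_that("p-values agree with a quadrature oracle on the t density", {
  # independent route: integrate the explicit t density instead of pt()
  t_density <- function(x, df) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(sample(4:9, 1)); y <- rnorm(sample(4:9, 1), 0.5)
    r <- t_test_raw(x, y)
    tail <- integrate(t_density, abs(r$t_stat), Inf, df = r$df,
                      rel.tol = 1e-10)$value
    expect_equal(r$p_value, 2 * tail, tolerance = 1e-6)
  }
})

test_that("degenerate zero-variance groups warn instead of failing", {
  expect_warning(r <- t_test_raw(c(1, 1, 1), c(1, 1, 1)), "zero variance")
  expect_equal(r$p_value, 1)
  expect_warning(r2 <- t_test_raw(c(2, 2), c(1, 1)), "zero variance")
  expect_gt(r2$p_value, 0)   # p stays inside (0, 1]
  expect_lte(r2$p_value, 1)
})

test_that("group summaries compute n, mean and sample SD per cell", {
  g <- frequency_grid(c(100, 1000))
  r <- data.frame(egg_id = rep(c("a", "b", "c", "d"), each = 2),
                  day = 1,
                  frequency_hz = rep(c(100, 1000), 4),
                  ratio = c(1.0, 2, 1.2, 2, 0.9, 3, 0.9, 3))
  lab <- sex_labels(c("a", "b", "c", "d"),
                    c("male", "male", "female", "female"))
  gs <- group_summaries(structure(r, grid = g), lab)
  m100 <- gs[gs$group == "male" & gs$frequency_hz == 100, ]
  expect_equal(m100$mean, 1.1)
  expect_equal(m100$sd, sd(c(1.0, 1.2)))   # 0.1414214, n-1 denominator
  expect_identical(m100$n, 2)
  f100 <- gs[gs$group == "female" & gs$frequency_hz == 100, ]
  expect_equal(f100$sd, 0)   # identical values
  expect_equal(f100$mean, 0.9)
  # unlabeled egg is an error naming the id
  expect_error(group_summaries(structure(r, grid = g), lab[-1, ]), "a")
})

test_that("persistence onset finds the earliest continuously significant day", {
  expect_identical(persistence_onset(c(0.04, 0.2, 0.03, 0.01)), 3L)
  expect_identical(persistence_onset(c(0.2, 0.3, 0.6)), NA_integer_)
  expect_identical(persistence_onset(c(0.01, 0.01), days = 5:6), 5L)
  # non-significant final day blocks everything
  expect_identical(persistence_onset(c(0.01, 0.01, 0.9)), NA_integer_)
  expect_error(persistence_onset(numeric(0)), "empty")
  expect_error(persistence_onset(c(0.1, 0.1), days = c(1, 3)), "contiguous")
})

test_that("scan recovers a planted persistent band and is order invariant", {
  sim <- suppressMessages(simulate_cohort(cohort_sim_config(
    n_male = 12, n_female = 12, seed = 42)))
  r <- ratio_dataset(sim$sweeps)
  sc <- suppressMessages(scan(r, sim$labels))
  expect_s3_class(sc, "scan_result")
  expect_identical(dim(sc$p_matrix), c(13L, 100L))
  expect_identical(sc$sig_mask, sc$p_matrix < sc$alpha)
  expect_false(is.na(sc$onset_day))
  expect_true(sc$band[["f_lo"]] <= sc$best_frequency,
              sc$best_frequency <= sc$band[["f_hi"]])
  # shuffling row order changes nothing
  set.seed(1)
  perm <- r[sample(nrow(r)), ]
  attributes(perm)[c("grid", "num_pair", "den_pair")] <-
    attributes(r)[c("grid", "num_pair", "den_pair")]
  sc2 <- suppressMessages(scan(perm, sim$labels[rev(seq_len(nrow(sim$labels))), ]))
  expect_equal(sc2$p_matrix, sc$p_matrix)
  expect_identical(sc2$onset_day, sc$onset_day)
})

test_that("an effect everywhere yields onset day 1 and the full-grid band", {
  g <- tiny_grid(4)
  set.seed(2)
  days <- 1:4
  rows <- list()
  for (e in 1:6) {
    male <- e <= 3
    for (d in days) {
      base <- if (male) rnorm(1, 1.4, 0.05) else rnorm(1, 0.7, 0.05)
      rows[[length(rows) + 1L]] <- data.frame(
        egg_id = sprintf("e%d", e), day = d,
        frequency_hz = as.numeric(g), ratio = base)
    }
  }
  r <- structure(do.call(rbind, rows), grid = g)
  lab <- sex_labels(sprintf("e%d", 1:6), rep(c("male", "female"), each = 3))
  sc <- scan(r, lab, scan_config(final_day = 4))
  expect_identical(sc$onset_day, 1L)
  expect_equal(unname(sc$band), range(as.numeric(g)))
})

test_that("scan reports absence of a persistent discriminator under the null", {
  g <- tiny_grid(3)
  set.seed(4)
  rows <- expand.grid(egg_id = sprintf("e%d", 1:8), day = 1:3,
                      frequency_hz = as.numeric(g),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$ratio <- exp(rnorm(nrow(rows), 0, 0.1))
  lab <- sex_labels(sprintf("e%d", 1:8), rep(c("male", "female"), 4))
  # force the final day to be non-significant by using identical group values
  rows$ratio[rows$day == 3] <- 1
  sc <- suppressMessages(suppressWarnings(
    scan(structure(rows, grid = g), lab, scan_config(final_day = 3))))
  expect_identical(sc$onset_day, NA_integer_)
  expect_null(sc$band)
})

test_that("daily table stars exactly the persistent tail of the reference cohort", {
  tab <- daily_ratio_table(reference_daily_input())
  expect_identical(tab$day[tab$star], 9:13)
  # recomputed p tracks the reported column closely away from day 9
  ref <- reference_daily_summaries()
  off <- abs(tab$p_value - ref$p_reported) / ref$p_reported
  expect_true(all(off[tab$day != 9] < 0.05))
  # single non-significant day: no stars
  one <- daily_ratio_table(reference_daily_input()[5, ])
  expect_false(any(one$star))
})

test_that("bonferroni option tightens the per-cell threshold", {
  sim <- suppressMessages(simulate_cohort(cohort_sim_config(
    n_male = 6, n_female = 6, days = 1:3, seed = 10)))
  r <- ratio_dataset(sim$sweeps)
  sc <- suppressMessages(scan(r, sim$labels,
                              scan_config(final_day = 3, bonferroni = TRUE)))
  expect_equal(sc$alpha, 0.05 / 100)
})
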