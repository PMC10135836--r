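test_that("default grid spans 20 Hz to 10 MHz in 100 log-spaced points", {
  g <- make_default_grid()
  expect_length(g, 100)
  expect_identical(as.numeric(g)[1], 20)
  expect_identical(as.numeric(g)[100], 1e7)
  expect_true(all(diff(as.numeric(g)) > 0))
  # closed-form log spacing: point k (0-based) is 20 * (1e7/20)^(k/99)
  expect_equal(as.numeric(g)[51], 20 * (1e7 / 20)^(50 / 99), tolerance = 1e-12)
  expect_equal(as.numeric(g)[26], 20 * (1e7 / 20)^(25 / 99), tolerance = 1e-12)
})

test_that("frequency_grid rejects malformed grids", {
  expect_error(frequency_grid(numeric(0)), "non-empty")
  expect_error(frequency_grid(c(100, 100)), "strictly increasing")
  expect_error(frequency_grid(c(200, 100)), "strictly increasing")
  expect_error(frequency_grid(c(10, 100)), "within")
  expect_error(frequency_grid(c(100, 2e7)), "within")
})

test_that("nearest_grid_frequency matches exhaustive log-distance search", {
  g <- make_default_grid()
  expect_equal(nearest_grid_frequency(g, 20), list(index = 1L, frequency = 20))
  expect_equal(nearest_grid_frequency(g, 1e7),
               list(index = 100L, frequency = 1e7))
  set.seed(11)
  targets <- 10^runif(1000, log10(20), 7)
  for (f in targets) {
    got <- nearest_grid_frequency(g, f)
    brute <- which.min(abs(log10(as.numeric(g)) - log10(f)))
    expect_identical(got$index, brute)
  }
  expect_error(nearest_grid_frequency(frequency_grid(20)[0], 100), "empty")
})

test_that("376 kHz maps onto the grid point at 363.8 kHz", {
  g <- make_default_grid()
  hit <- nearest_grid_frequency(g, 3.76e5)
  expect_identical(hit$index, 75L)
  expect_equal(hit$frequency, 20 * (1e7 / 20)^(74 / 99), tolerance = 1e-12)
})

test_that("electrode pairs are canonicalized and validated", {
  expect_identical(electrode_pair("3-2"), "2-3")
  expect_identical(electrode_pair(c("2-3", "4-1")), c("2-3", "1-4"))
  expect_identical(electrode_pair(c(4, 2)), "2-4")
  expect_error(electrode_pair("2-5"), "1..4")
  expect_error(electrode_pair("2-2"), "distinct")
  expect_error(electrode_pair("23"), "form")
})

test_that("sweep write/read round-trips bit-exactly", {
  g <- tiny_grid(7)
  set.seed(42)
  df <- rbind(flat_sweep("a", 3, "2-3", 1, g), flat_sweep("a", 3, "2-4", 1, g))
  df$z_mod_ohm <- exp(rnorm(nrow(df), log(500), 1))
  df$phase_deg <- runif(nrow(df), -90, 0)
  sw <- as_sweep_df(df, grid = g)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweeps(sw, path)
  back <- read_sweeps(path)
  expect_identical(back$z_mod_ohm, sw$z_mod_ohm)
  expect_identical(back$frequency_hz, sw$frequency_hz)
  expect_identical(back$phase_deg, sw$phase_deg)
  expect_identical(back$egg_id, sw$egg_id)
  # idempotence: a second round trip writes the identical file
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_sweeps(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("sweep validation rejects bad tables and counts records", {
  g <- tiny_grid()
  sw <- two_pair_sweeps(2, days = 1, grid = g)
  d <- sweep_diagnostics(sw)
  expect_identical(d$n_sweeps, 4L)   # 2 eggs x 2 pairs
  expect_identical(d$n_rows, 4L * length(g))

  dup <- rbind(as.data.frame(sw), as.data.frame(sw)[1, ])
  expect_error(as_sweep_df(dup), "duplicate.*egg1.*2-3")

  bad <- as.data.frame(sw)
  bad$z_mod_ohm[3] <- -1
  expect_error(as_sweep_df(bad), "> 0")

  mixed <- rbind(as.data.frame(flat_sweep(grid = tiny_grid(5))),
                 as.data.frame(flat_sweep(egg = "e2", grid = tiny_grid(6))))
  expect_error(as_sweep_df(mixed), "inconsistent")
})

test_that("writing an empty sweep table yields a header-only file", {
  sw <- as_sweep_df(flat_sweep()[0, ])
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweeps(sw, path)
  expect_length(readLines(path), 1L)
})

test_that("label io maps M/F/NA shorthand and guards the unfertilized source", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("egg_id,sex", "1,M", "2,F", "3,N/A"), path)
  lab <- read_labels(path)
  expect_identical(lab$sex, c("male", "female", "unfertilized"))
  expect_identical(unique(lab$source), "pcr")
  expect_error(sex_labels("x", "unfertilized", source = "impedance"),
               "PCR")
})
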