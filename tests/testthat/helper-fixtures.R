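# shared fixtures: small hand-built sweep tables and the reference summary
# table, constructed in code so nothing binary ships with the package

# a tiny strictly increasing grid inside the instrument range
tiny_grid <- function(n = 5) {
  frequency_grid(10^seq(log10(20), 7, length.out = n))
}

# one flat sweep at a constant |Z|
flat_sweep <- function(egg = "e1", day = 1, pair = "2-3", z = 100,
                       grid = tiny_grid()) {
  data.frame(egg_id = egg, day = day, pair = pair,
             frequency_hz = as.numeric(grid), z_mod_ohm = z,
             stringsAsFactors = FALSE)
}

# complete two-pair dataset: n_eggs eggs x days, both ratio pairs
two_pair_sweeps <- function(n_eggs = 2, days = 1:2, grid = tiny_grid(),
                            z23 = 200, z24 = 160) {
  rows <- list()
  for (e in sprintf("egg%d", seq_len(n_eggs))) {
    for (d in days) {
      rows[[length(rows) + 1L]] <- flat_sweep(e, d, "2-3", z23, grid)
      rows[[length(rows) + 1L]] <- flat_sweep(e, d, "2-4", z24, grid)
    }
  }
  as_sweep_df(do.call(rbind, rows), grid = grid)
}

# reference per-day summaries in daily_ratio_table() layout
reference_daily_input <- function() {
  ref <- reference_daily_summaries()
  data.frame(day = ref$day,
             male_mean = ref$male_mean, male_sd = ref$male_sd,
             n_male = ref$n_male,
             female_mean = ref$female_mean, female_sd = ref$female_sd,
             n_female = ref$n_female)
}
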