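#' Cole-model egg simulation parameters
#'
#' An incubating egg behaves like a cell suspension: the shell and membranes
#' act as capacitors, so |Z| falls from a low-frequency plateau R0 to a
#' high-frequency plateau Rinf through a dispersion governed by the time
#' constant tau and the broadening exponent alpha (the Cole model,
#' Z = Rinf + (R0 - Rinf) / (1 + (i 2 pi f tau)^alpha)).
#'
#' Circuit defaults (R0 = 10 kOhm, Rinf = 200 Ohm, tau = 1 us, alpha = 0.85)
#' are illustrative values producing a falling spectrum whose dispersion sits
#' inside the 20 Hz-10 MHz sweep; they are not estimates from measured eggs.
#' Measurement noise is multiplicative log-normal, heteroscedastic in
#' frequency: the shell blocks low-frequency currents, so sweeps are much
#' noisier below ~200 kHz than above.
#'
#' @param r0 Low-frequency resistance, Ohm (> r_inf).
#' @param r_inf High-frequency resistance, Ohm (> 0).
#' @param tau Dispersion time constant, s.
#' @param cole_alpha Dispersion exponent in (0, 1].
#' @param pair_gain Named geometric scale factors per electrode pair.
#' @param noise_sd_low Log-scale noise SD below \code{noise_cutoff_hz}.
#' @param noise_sd_high Log-scale noise SD at/above \code{noise_cutoff_hz}.
#' @param noise_cutoff_hz Heteroscedasticity cutoff, Hz (default 200 kHz).
#' @param day_drift Per-day multiplicative trend of |Z| (embryo growth).
#' @return Object of class \code{egg_sim_params}.
#' @export
egg_sim_params <- function(r0 = 10000, r_inf = 200, tau = 1e-6,
                           cole_alpha = 0.85,
                           pair_gain = c("1-2" = 1.10, "1-3" = 1.05,
                                         "1-4" = 1.05, "2-3" = 1.00,
                                         "2-4" = 1.00, "3-4" = 0.95),
                           noise_sd_low = 0.15, noise_sd_high = 0.02,
                           noise_cutoff_hz = 2e5, day_drift = 1.01) {
  stopifnot(r0 > r_inf, r_inf > 0, tau > 0,
            cole_alpha > 0, cole_alpha <= 1,
            noise_sd_low >= 0, noise_sd_high >= 0,
            noise_cutoff_hz > 0, day_drift > 0, all(pair_gain > 0))
  names(pair_gain) <- electrode_pair(names(pair_gain))
  structure(list(r0 = r0, r_inf = r_inf, tau = tau, cole_alpha = cole_alpha,
                 pair_gain = pair_gain, noise_sd_low = noise_sd_low,
                 noise_sd_high = noise_sd_high,
                 noise_cutoff_hz = noise_cutoff_hz, day_drift = day_drift),
            class = "egg_sim_params")
}

#' Cole impedance magnitude
#'
#' @param params An \code{\link{egg_sim_params}}.
#' @param f Frequencies in Hz (> 0), vectorized.
#' @return |Z(f)| in Ohm: the modulus of
#'   Rinf + (R0 - Rinf) / (1 + (i 2 pi f tau)^alpha).
#' @export
cole_magnitude <- function(params, f) {
  if (!inherits(params, "egg_sim_params")) stop("need egg_sim_params")
  if (any(f <= 0)) stop("frequencies must be > 0")
  jwt <- complex(modulus = (2 * pi * f * params$tau)^params$cole_alpha,
                 argument = params$cole_alpha * pi / 2)
  Mod(params$r_inf + (params$r0 - params$r_inf) / (1 + jwt))
}

# log-normal measurement noise, heteroscedastic in frequency
sweep_noise <- function(params, f, n_rep = 1L) {
  sd_f <- ifelse(f < params$noise_cutoff_hz,
                 params$noise_sd_low, params$noise_sd_high)
  exp(stats::rnorm(length(f) * n_rep, 0, rep(sd_f, n_rep)))
}

#' Simulate one egg's sweeps for the ratio pairs
#'
#' Builds the denominator pair (2-4) as Cole curve x pair gain x day drift x
#' log-normal noise, and the numerator pair (2-3) as the same base curve
#' multiplied by the egg's intended ratio profile (then its own independent
#' noise). With noise switched off, the pipeline ratio therefore reproduces
#' \code{ratio_targets} exactly.
#'
#' @param params An \code{\link{egg_sim_params}}.
#' @param ratio_targets Matrix of intended noise-free ratios, one row per
#'   day (rownames = day numbers) and one column per grid point.
#' @param grid A \code{frequency_grid}.
#' @param egg_id Identifier for the emitted records.
#' @param seed Optional integer seed (set for standalone use; inside
#'   \code{\link{simulate_cohort}} the per-egg substream is already seeded).
#' @param num_pair,den_pair Pairs to emit (default 2-3 and 2-4).
#' @return A \code{sweep_df} with both pairs for every day in
#'   \code{ratio_targets}.
#' @export
simulate_egg <- function(params, ratio_targets, grid, egg_id = "egg1",
                         seed = NULL, num_pair = "2-3", den_pair = "2-4") {
  if (!is.null(seed)) set.seed(seed)
  cols <- egg_sweep_columns(params, ratio_targets, grid, egg_id,
                            num_pair, den_pair)
  as_sweep_df(as.data.frame(cols, stringsAsFactors = FALSE), grid = grid)
}

# column-vector core of simulate_egg, shared with simulate_cohort so large
# cohorts assemble one data.frame instead of rbinding thousands
egg_sweep_columns <- function(params, ratio_targets, grid, egg_id,
                              num_pair = "2-3", den_pair = "2-4") {
  f <- as.numeric(grid)
  if (ncol(ratio_targets) != length(f)) {
    stop("ratio_targets must have one column per grid point")
  }
  days <- as.integer(rownames(ratio_targets))
  if (anyNA(days)) stop("ratio_targets rownames must be day numbers")
  num_pair <- electrode_pair(num_pair)
  den_pair <- electrode_pair(den_pair)
  gain <- params$pair_gain[[den_pair]]
  nf <- length(f)
  nd <- length(days)
  # base curve per (day, frequency), day-major
  base <- as.vector(t(outer(params$day_drift^days,
                            cole_magnitude(params, f) * gain)))
  z_num <- base * as.vector(t(ratio_targets)) * sweep_noise(params, f, nd)
  z_den <- base * sweep_noise(params, f, nd)
  list(egg_id = rep(egg_id, 2L * nd * nf),
       day = c(rep(days, each = nf), rep(days, each = nf)),
       pair = rep(c(num_pair, den_pair), each = nd * nf),
       frequency_hz = rep(f, 2L * nd),
       z_mod_ohm = c(z_num, z_den))
}

#' Cohort simulation configuration
#'
#' Defaults reproduce the reference study conditions: 8 male and 8 female
#' eggs over incubation days 1-13, a sex effect confined to the 376 kHz-
#' 2.79 MHz band from day 9 onward, and day-9 ratio distributions calibrated
#' to the reference cohort (male Normal(1.122262, 0.112674), female
#' Normal(0.953107, 0.124892)). Outside the band and before onset, each
#' (egg, day) draws a baseline ratio from Normal(1, baseline_ratio_sd).
#'
#' @param n_male,n_female Cohort sizes.
#' @param effect_band Length-2 Hz range carrying the sex effect; band edges
#'   are snapped to the log-nearest grid points at simulation time.
#' @param effect_onset_day First day the effect is present.
#' @param mu_male,sd_male,mu_female,sd_female Target ratio distributions in
#'   the effect band.
#' @param baseline_ratio_sd Ratio dispersion outside band/before onset.
#' @param days Simulated incubation days.
#' @param seed Integer PRNG seed.
#' @return Object of class \code{cohort_sim_config}.
#' @export
cohort_sim_config <- function(n_male = 8, n_female = 8,
                              effect_band = c(3.76e5, 2.79e6),
                              effect_onset_day = 9,
                              mu_male = 1.122262, sd_male = 0.112674,
                              mu_female = 0.953107, sd_female = 0.124892,
                              baseline_ratio_sd = 0.12,
                              days = 1:13, seed = 1L) {
  stopifnot(n_male >= 0, n_female >= 0,
            length(effect_band) == 2L, effect_band[1] < effect_band[2],
            sd_male > 0, sd_female > 0, baseline_ratio_sd > 0)
  structure(list(n_male = as.integer(n_male), n_female = as.integer(n_female),
                 effect_band = effect_band,
                 effect_onset_day = as.integer(effect_onset_day),
                 mu_male = mu_male, sd_male = sd_male,
                 mu_female = mu_female, sd_female = sd_female,
                 baseline_ratio_sd = baseline_ratio_sd,
                 days = as.integer(days), seed = as.integer(seed)),
            class = "cohort_sim_config")
}

# draws truncated to [0.5, 2] so ratios stay physical; truncation is logged
truncated_ratio_draw <- function(n, mu, sd) {
  x <- stats::rnorm(n, mu, sd)
  bad <- x < 0.5 | x > 2
  if (any(bad)) {
    message("truncated ", sum(bad), " ratio draw(s) to [0.5, 2]")
    x <- pmin(pmax(x, 0.5), 2)
  }
  x
}

#' Simulate a labeled egg cohort
#'
#' Per male egg, one effect-level ratio is drawn from
#' Normal(mu_male, sd_male) and applied at every in-band grid point from the
#' onset day through the last day — the sex signature is an egg property, so
#' it persists across days (females analogously). Before onset and outside
#' the band, each (egg, day) draws its own baseline ratio from
#' Normal(1, baseline_ratio_sd), modelling session-to-session variation
#' without any sex information. Each egg consumes its own PRNG substream, so
#' output is reproducible and independent of cohort ordering.
#'
#' @param cfg A \code{\link{cohort_sim_config}}.
#' @param params An \code{\link{egg_sim_params}}.
#' @param grid A \code{frequency_grid}.
#' @return List: \code{sweeps} (a \code{sweep_df}), \code{labels} (PCR-source
#'   ground truth), \code{band_indices} (grid indices carrying the effect).
#' @export
simulate_cohort <- function(cfg, params = egg_sim_params(),
                            grid = make_default_grid()) {
  f <- as.numeric(grid)
  lo <- nearest_grid_frequency(grid, cfg$effect_band[1])$index
  hi <- nearest_grid_frequency(grid, cfg$effect_band[2])$index
  in_band <- seq(lo, hi)
  n_tot <- cfg$n_male + cfg$n_female
  ids <- c(sprintf("M%02d", seq_len(cfg$n_male)),
           sprintf("F%02d", seq_len(cfg$n_female)))
  sexes <- rep(c("male", "female"), c(cfg$n_male, cfg$n_female))
  set.seed(cfg$seed)
  egg_seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
  sweeps <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    set.seed(egg_seeds[i])
    mu <- if (sexes[i] == "male") cfg$mu_male else cfg$mu_female
    sd <- if (sexes[i] == "male") cfg$sd_male else cfg$sd_female
    effect <- truncated_ratio_draw(1L, mu, sd)
    targets <- matrix(
      truncated_ratio_draw(length(cfg$days), 1, cfg$baseline_ratio_sd),
      nrow = length(cfg$days), ncol = length(f))
    post <- cfg$days >= cfg$effect_onset_day
    targets[post, in_band] <- effect
    rownames(targets) <- cfg$days
    sweeps[[i]] <- egg_sweep_columns(params, targets, grid, egg_id = ids[i])
  }
  cols <- lapply(stats::setNames(nm = names(sweeps[[1L]])), function(nm)
    unlist(lapply(sweeps, `[[`, nm), use.names = FALSE))
  all_sweeps <- as_sweep_df(as.data.frame(cols, stringsAsFactors = FALSE),
                            grid = grid)
  list(sweeps = all_sweeps,
       labels = sex_labels(ids, sexes, source = "pcr"),
       band_indices = in_band)
}
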