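#' Carbon-epoxy electrode specification
#'
#' Geometry and material constants of the dried carbon-epoxy electrode: bulk
#' resistivity of the carbon epoxy, film thickness, cross-sectional area, and
#' the contact resistance of the adhesive conductive cloth per cm^2. Defaults
#' reproduce the nominal 2.05 ohm electrode (40 ohm cm epoxy, 0.05 cm film
#' over a 1 cm^2 cloth with 0.05 ohm/cm^2 contact resistance).
#'
#' Note the 40 uL drop spread over 1 cm^2 geometrically implies a 0.04 cm
#' film (giving 1.65 ohm); the nominal figure corresponds to 0.05 cm. Both
#' are reachable through the \code{thickness_cm} argument.
#'
#' @param resistivity_ohm_cm Bulk resistivity, ohm cm.
#' @param thickness_cm Film thickness (current path length), cm.
#' @param area_cm2 Cross-sectional area, cm^2.
#' @param contact_r_per_cm2 Contact resistance of the cloth, ohm per cm^2.
#' @return Object of class \code{electrode_spec}.
#' @export
electrode_spec <- function(resistivity_ohm_cm = 40, thickness_cm = 0.05,
                           area_cm2 = 1, contact_r_per_cm2 = 0.05) {
  vals <- c(resistivity_ohm_cm, thickness_cm, area_cm2, contact_r_per_cm2)
  if (any(!is.finite(vals)) || any(vals[-1] <= 0) || vals[1] < 0) {
    stop("electrode geometry must be positive (resistivity may be 0)")
  }
  structure(list(resistivity_ohm_cm = resistivity_ohm_cm,
                 thickness_cm = thickness_cm,
                 area_cm2 = area_cm2,
                 contact_r_per_cm2 = contact_r_per_cm2),
            class = "electrode_spec")
}

#' Total electrode resistance from the resistivity relation
#'
#' Inverts rho = R * A / l for the film: R_bulk = rho * l / A, then adds the
#' cloth contact term referenced to 1 cm^2: R_contact = contact * 1 cm^2 / A.
#' With the defaults this gives 40 * 0.05 / 1 + 0.05 = 2.05 ohm.
#'
#' @param spec An \code{\link{electrode_spec}}.
#' @return Resistance in ohms.
#' @export
electrode_resistance <- function(spec) {
  if (!inherits(spec, "electrode_spec")) stop("need an electrode_spec")
  with(spec, resistivity_ohm_cm * thickness_cm / area_cm2 +
         contact_r_per_cm2 * 1 / area_cm2)
}

#' Relative standard deviation across repeat sweeps
#'
#' Repeatability QC: given >= 2 sweeps of the same egg and electrode pair
#' (typically across days of an unfertilized control egg), computes the
#' per-frequency relative standard deviation 100 * SD / mean of |Z| (sample
#' SD, n-1 denominator). The electrode passes when RSD stays below the
#' threshold at every grid point at or above \code{min_pass_frequency}; low
#' frequencies are excluded because electrode polarization makes them
#' intrinsically noisy. Defaults: 5 percent, 100 Hz.
#'
#' @param sweeps A sweep data.frame holding the repeats (one egg, one pair,
#'   several days), or a numeric matrix with one row per repeat and one
#'   column per grid point.
#' @param pass_threshold_percent QC bound in percent.
#' @param min_pass_frequency Lowest frequency (Hz) the bound applies to.
#' @param grid Grid for matrix input (taken from the sweep table otherwise).
#' @return Object of class \code{rsd_profile}: grid, per-frequency
#'   \code{rsd_percent}, threshold, \code{min_pass_frequency}, and
#'   \code{pass} (logical).
#' @export
rsd_across_repeats <- function(sweeps, pass_threshold_percent = 5,
                               min_pass_frequency = 100, grid = NULL) {
  if (is.matrix(sweeps)) {
    z <- sweeps
    if (is.null(grid)) stop("matrix input requires an explicit grid")
  } else {
    if (length(unique(sweeps$egg_id)) != 1L ||
        length(unique(sweeps$pair)) != 1L) {
      stop("repeats must come from a single egg and a single electrode pair")
    }
    grid <- attr(sweeps, "grid")
    if (is.null(grid)) grid <- frequency_grid(sort(unique(sweeps$frequency_hz)))
    sweeps <- sweeps[order(sweeps$day, sweeps$frequency_hz), , drop = FALSE]
    z <- matrix(sweeps$z_mod_ohm, nrow = length(unique(sweeps$day)),
                ncol = length(grid), byrow = TRUE)
  }
  if (nrow(z) < 2L) stop("need at least 2 repeat sweeps to compute RSD")
  if (ncol(z) != length(grid)) stop("sweep length does not match grid")
  m <- colMeans(z)
  s <- apply(z, 2L, stats::sd)
  rsd <- 100 * s / m
  eval_pts <- as.numeric(grid) >= min_pass_frequency
  structure(list(grid = grid,
                 rsd_percent = rsd,
                 pass_threshold_percent = pass_threshold_percent,
                 min_pass_frequency = min_pass_frequency,
                 pass = all(rsd[eval_pts] < pass_threshold_percent)),
            class = "rsd_profile")
}

#' @export
print.rsd_profile <- function(x, ...) {
  cat(sprintf(
    "<rsd_profile: %d points; max RSD %.3g%% overall, %.3g%% at >= %g Hz; %s>\n",
    length(x$grid), max(x$rsd_percent),
    max(x$rsd_percent[as.numeric(x$grid) >= x$min_pass_frequency]),
    x$min_pass_frequency, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
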