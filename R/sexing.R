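#' Classifier configuration
#'
#' Operating point of the ratio-threshold sex classifier. The default is the
#' discriminative optimum found by the frequency scan: day 9, the grid point
#' nearest 376 kHz, threshold 1 (male ratios sit above 1, female below).
#' A ratio inside \code{threshold +/- margin} is called indeterminate rather
#' than forced into a class — the two distributions overlap.
#'
#' @param day Incubation day the classifier reads.
#' @param frequency Operating frequency in Hz; must be a grid point (use
#'   \code{\link{nearest_grid_frequency}} to snap a nominal value).
#' @param threshold Decision threshold on the ratio (> 0).
#' @param margin Half-width of the indeterminate zone (>= 0).
#' @param band_average If \code{TRUE}, classify on the mean ratio over
#'   \code{band} instead of the single frequency.
#' @param band Length-2 Hz range for \code{band_average} (default the
#'   discriminative band 376 kHz-2.79 MHz).
#' @return Object of class \code{classifier_config}.
#' @export
classifier_config <- function(day = 9, frequency = 3.76e5, threshold = 1,
                              margin = 0, band_average = FALSE,
                              band = c(3.76e5, 2.79e6)) {
  stopifnot(threshold > 0, margin >= 0, frequency > 0,
            length(band) == 2L, band[1] < band[2])
  structure(list(day = as.integer(day), frequency = frequency,
                 threshold = threshold, margin = margin,
                 band_average = isTRUE(band_average), band = band),
            class = "classifier_config")
}

# ratio value each egg is classified on, at cfg's operating point
operating_ratio <- function(ratios, cfg) {
  sel <- ratios[ratios$day == cfg$day, , drop = FALSE]
  if (!nrow(sel)) stop("no ratio spectra for day ", cfg$day)
  if (cfg$band_average) {
    inb <- sel$frequency_hz >= cfg$band[1] & sel$frequency_hz <= cfg$band[2]
    if (!any(inb)) stop("no grid points inside the band ",
                        cfg$band[1], "-", cfg$band[2], " Hz")
    sel <- sel[inb, , drop = FALSE]
    r <- tapply(sel$ratio, sel$egg_id, mean)
  } else {
    hit <- abs(sel$frequency_hz - cfg$frequency) <= 1e-9 * cfg$frequency
    if (!any(hit)) {
      stop("frequency ", cfg$frequency, " Hz is not a grid point; ",
           "snap it with nearest_grid_frequency() first")
    }
    sel <- sel[hit, , drop = FALSE]
    r <- stats::setNames(sel$ratio, sel$egg_id)
  }
  r
}

#' Classify eggs by the ratio threshold
#'
#' Reads each egg's self-normalized ratio at the configured day and
#' frequency (or band average) and calls male when it exceeds
#' \code{threshold + margin}, female when it falls below
#' \code{threshold - margin}, and unknown (indeterminate) otherwise.
#'
#' @param ratios A \code{ratio_df}.
#' @param cfg A \code{\link{classifier_config}}.
#' @return Sex labels with \code{source = "impedance"}.
#' @export
classify_eggs <- function(ratios, cfg = classifier_config()) {
  r <- operating_ratio(ratios, cfg)
  sex <- ifelse(r > cfg$threshold + cfg$margin, "male",
                ifelse(r < cfg$threshold - cfg$margin, "female", "unknown"))
  sex_labels(names(r), sex, source = "impedance")
}

#' Classify a single egg's ratio spectrum
#'
#' @param ratio One egg's \code{ratio_df} (single egg, containing the
#'   configured day).
#' @param cfg A \code{\link{classifier_config}}.
#' @return One-row label data.frame, \code{source = "impedance"}.
#' @export
classify_egg <- function(ratio, cfg = classifier_config()) {
  if (length(unique(ratio$egg_id)) != 1L) stop("classify_egg takes one egg")
  classify_eggs(ratio, cfg)
}

#' Evaluate impedance calls against PCR ground truth
#'
#' @param predictions Labels from \code{\link{classify_eggs}}.
#' @param truth PCR labels. Eggs the truth marks unfertilized/unknown are
#'   set aside (counted, not scored); predicted indeterminates are counted
#'   separately and excluded from the accuracy denominator.
#' @return Object of class \code{evaluation_report}: \code{confusion} (truth
#'   x prediction), per-class sensitivity, \code{accuracy},
#'   \code{balanced_accuracy}, \code{n_indeterminate}, \code{n_excluded}.
#' @export
evaluate <- function(predictions, truth) {
  extra <- setdiff(predictions$egg_id, truth$egg_id)
  if (length(extra)) {
    stop("predictions for eggs absent from truth: ",
         paste(extra, collapse = ", "))
  }
  tr <- truth$sex[match(predictions$egg_id, truth$egg_id)]
  scoreable <- tr %in% c("male", "female")
  n_excluded <- sum(!scoreable)
  pr <- predictions$sex[scoreable]
  tr <- tr[scoreable]
  n_ind <- sum(pr == "unknown")
  det <- pr != "unknown"
  conf <- table(truth = factor(tr[det], levels = c("male", "female")),
                predicted = factor(pr[det], levels = c("male", "female")))
  n_cls <- sum(conf)
  sens <- function(cls) {
    tot <- sum(conf[cls, ])
    if (tot == 0) NA_real_ else conf[cls, cls] / tot
  }
  male_sens <- sens("male")
  female_sens <- sens("female")
  structure(list(
    confusion = conf,
    male_sensitivity = male_sens,
    female_sensitivity = female_sens,
    accuracy = if (n_cls == 0) NA_real_ else sum(diag(conf)) / n_cls,
    balanced_accuracy = mean(c(male_sens, female_sens)),
    n_classified = n_cls,
    n_indeterminate = n_ind,
    n_excluded = n_excluded
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$confusion)
  cat(sprintf(
    "  accuracy %.3f | balanced %.3f | male sens %.3f | female sens %.3f\n",
    x$accuracy, x$balanced_accuracy, x$male_sensitivity,
    x$female_sensitivity))
  cat(sprintf("  indeterminate %d | excluded (not M/F truth) %d\n",
              x$n_indeterminate, x$n_excluded))
  invisible(x)
}

#' Closed-form classifier accuracy under a normal ratio model
#'
#' If male ratios are Normal(mu_m, sd_m) and female ratios Normal(mu_f,
#' sd_f), a threshold classifier has male sensitivity
#' Phi((mu_m - threshold)/sd_m) and female sensitivity
#' Phi((threshold - mu_f)/sd_f). With the reference day-9 parameters
#' (1.122262/0.112674 male, 0.953107/0.124892 female) and threshold 1 this
#' gives roughly 0.861 / 0.646 (balanced 0.754).
#'
#' @param mu_m,sd_m Male ratio mean and SD (sd > 0).
#' @param mu_f,sd_f Female ratio mean and SD (sd > 0).
#' @param threshold Decision threshold.
#' @return List: \code{male_sens}, \code{female_sens}, \code{balanced}.
#' @export
expected_accuracy <- function(mu_m, sd_m, mu_f, sd_f, threshold = 1) {
  stopifnot(sd_m > 0, sd_f > 0)
  ms <- stats::pnorm((mu_m - threshold) / sd_m)
  fs <- stats::pnorm((threshold - mu_f) / sd_f)
  list(male_sens = ms, female_sens = fs, balanced = (ms + fs) / 2)
}
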