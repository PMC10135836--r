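#' Scan configuration
#'
#' Settings for the day-by-frequency significance scan: per-cell significance
#' level, t-test variant and tails, the last incubation day considered, and
#' an optional Bonferroni correction across frequencies (off by default; the
#' persistence rule is the implicit multiplicity guard).
#'
#' @param alpha Per-cell significance level in (0, 1).
#' @param variant \code{"welch"} (unequal variances, Welch-Satterthwaite df)
#'   or \code{"pooled"}.
#' @param tails 1 or 2.
#' @param final_day Last incubation day of the scan.
#' @param bonferroni If \code{TRUE}, alpha is divided by the number of
#'   frequencies before thresholding.
#' @return Object of class \code{scan_config}.
#' @export
scan_config <- function(alpha = 0.05, variant = c("welch", "pooled"),
                        tails = 2, final_day = 13, bonferroni = FALSE) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            tails %in% c(1, 2), final_day >= 1)
  structure(list(alpha = alpha, variant = variant, tails = as.integer(tails),
                 final_day = as.integer(final_day),
                 bonferroni = isTRUE(bonferroni)),
            class = "scan_config")
}

# vectorized two-sample t kernel from summary statistics
t_kernel <- function(m1, s1, n1, m2, s2, n2, variant = "welch", tails = 2L) {
  if (any(n1 < 2L) || any(n2 < 2L)) stop("each group needs n >= 2")
  if (any(s1 < 0) || any(s2 < 0)) stop("standard deviations must be >= 0")
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  if (variant == "welch") {
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t <- (m1 - m2) / se
  degen <- se == 0
  if (any(degen)) {
    warning("zero variance in both groups; p set to 1 (equal means) or ",
            "the smallest positive double (unequal means)")
    t[degen] <- ifelse(m1[degen] == m2[degen], 0, Inf * sign(m1 - m2)[degen])
    df[degen] <- n1[degen] + n2[degen] - 2
  }
  p <- tails * stats::pt(-abs(t), df)
  p[degen & m1 == m2] <- 1
  p <- pmax(p, .Machine$double.xmin)
  list(t_stat = t, df = df, p_value = p)
}

#' Independent two-sample t-test from summary statistics
#'
#' Computes the test directly from group means, SDs and sizes — exactly what
#' a published summary table provides. Agrees with \code{\link{t_test_raw}}
#' whenever the raw data have these summaries.
#'
#' @param m1,s1,n1 Mean, sample SD (n-1 denominator), size of group 1.
#' @param m2,s2,n2 Same for group 2.
#' @param cfg A \code{\link{scan_config}} (variant and tails are used).
#' @return Object of class \code{ttest_result}: \code{t_stat}, \code{df}
#'   (fractional for Welch), \code{p_value}, \code{tails}, \code{variant}.
#' @export
t_test_summary <- function(m1, s1, n1, m2, s2, n2, cfg = scan_config()) {
  k <- t_kernel(m1, s1, n1, m2, s2, n2, cfg$variant, cfg$tails)
  structure(list(t_stat = k$t_stat, df = k$df, p_value = k$p_value,
                 tails = cfg$tails, variant = cfg$variant),
            class = "ttest_result")
}

#' Independent two-sample t-test from raw values
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param cfg A \code{\link{scan_config}}.
#' @return A \code{ttest_result}, identical to feeding the groups' summary
#'   statistics to \code{\link{t_test_summary}}.
#' @export
t_test_raw <- function(x, y, cfg = scan_config()) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs >= 2 values")
  t_test_summary(mean(x), stats::sd(x), length(x),
                 mean(y), stats::sd(y), length(y), cfg)
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("<%s t-test (%d-tailed): t = %.4g, df = %.4g, p = %.4g>\n",
              x$variant, x$tails, x$t_stat[1L], x$df[1L], x$p_value[1L]))
  invisible(x)
}

#' Per-(day, frequency, sex) group summaries of the ratio statistic
#'
#' @param ratios A \code{ratio_df}.
#' @param labels Sex labels covering every egg in \code{ratios}; eggs labeled
#'   unfertilized/unknown are excluded, eggs with no label at all are an
#'   error.
#' @return Data.frame: \code{day}, \code{frequency_hz}, \code{group}
#'   (male/female), \code{n}, \code{mean}, \code{sd} (n-1 denominator).
#' @export
group_summaries <- function(ratios, labels) {
  sex <- labels$sex[match(ratios$egg_id, labels$egg_id)]
  if (anyNA(sex)) {
    stop("unlabeled egg(s): ",
         paste(unique(ratios$egg_id[is.na(sex)]), collapse = ", "))
  }
  keep <- sex %in% c("male", "female")
  ratios <- ratios[keep, , drop = FALSE]
  sex <- sex[keep]
  ord <- order(ratios$day, ratios$frequency_hz, sex)
  ratios <- ratios[ord, , drop = FALSE]
  sex <- sex[ord]
  g <- paste(ratios$day, format(ratios$frequency_hz, digits = 17), sex,
             sep = "|")
  first <- !duplicated(g)
  n <- as.vector(rowsum(rep(1, nrow(ratios)), g, reorder = FALSE))
  sm <- as.vector(rowsum(ratios$ratio, g, reorder = FALSE))
  # centered second moment per group, numerically safe for tight clusters
  m <- sm / n
  dev <- ratios$ratio - m[match(g, g[first])]
  ss <- as.vector(rowsum(dev^2, g, reorder = FALSE))
  s <- ifelse(n > 1, sqrt(ss / (n - 1)), 0)
  out <- data.frame(day = ratios$day[first],
                    frequency_hz = ratios$frequency_hz[first],
                    group = sex[first],
                    n = n, mean = m, sd = s,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Persistence onset day
#'
#' Earliest day d such that p < alpha on every day from d through the final
#' day — the "continuous significance" rule that guards the per-cell tests.
#' Returns \code{NA} when the final day itself is non-significant.
#'
#' @param p_by_day Numeric p-values for contiguous days.
#' @param alpha Significance level.
#' @param days Day numbers (contiguous); defaults to 1..length(p).
#' @return The onset day, or \code{NA_integer_} if none.
#' @export
persistence_onset <- function(p_by_day, alpha = 0.05,
                              days = seq_along(p_by_day)) {
  if (length(p_by_day) == 0L) stop("empty p-value sequence")
  if (length(days) != length(p_by_day)) stop("days and p-values differ in length")
  if (length(days) > 1L && any(diff(days) != 1L)) stop("days must be contiguous")
  ok <- p_by_day < alpha
  # persistent from position i iff all of ok[i..end]
  tail_ok <- rev(cumprod(rev(ok))) > 0
  if (!any(tail_ok)) return(NA_integer_)
  as.integer(days[which(tail_ok)[1L]])
}

#' Day-by-frequency significance scan
#'
#' Runs an independent two-sample t-test (male vs female ratio values) in
#' every (day, frequency) cell, then applies the persistence rule per
#' frequency: a frequency is discriminative from day d if p < alpha on every
#' day d..final_day. The scan reports the earliest such onset day, the
#' maximal contiguous frequency band persistent from that day, and the
#' frequency minimizing p on the onset day (ties toward the lower
#' frequency).
#'
#' @param ratios A \code{ratio_df}.
#' @param labels Sex labels (see \code{\link{group_summaries}}).
#' @param cfg A \code{\link{scan_config}}.
#' @return Object of class \code{scan_result}: \code{p_matrix} (days x
#'   frequencies), \code{sig_mask}, \code{band} (Hz lo/hi or NULL),
#'   \code{onset_day} (or NA), \code{best_frequency} (or NA), \code{alpha},
#'   \code{days}, \code{frequencies}.
#' @export
scan <- function(ratios, labels, cfg = scan_config()) {
  gs <- group_summaries(ratios, labels)
  gs <- gs[gs$day >= 1L & gs$day <= cfg$final_day, , drop = FALSE]
  if (any(gs$n < 2L)) stop("need >= 2 eggs per group per day")
  days <- sort(unique(gs$day))
  freqs <- sort(unique(gs$frequency_hz))
  ml <- gs[gs$group == "male", , drop = FALSE]
  fl <- gs[gs$group == "female", , drop = FALSE]
  key <- function(d) paste(d$day, format(d$frequency_hz, digits = 15))
  full <- expand.grid(day = days, frequency_hz = freqs,
                      KEEP.OUT.ATTRS = FALSE)
  im <- match(key(full), key(ml))
  if_ <- match(key(full), key(fl))
  if (anyNA(im) || anyNA(if_)) stop("missing male or female group in some cell")
  k <- t_kernel(ml$mean[im], ml$sd[im], ml$n[im],
                fl$mean[if_], fl$sd[if_], fl$n[if_],
                cfg$variant, cfg$tails)
  p <- matrix(k$p_value, nrow = length(days), ncol = length(freqs),
              dimnames = list(day = days, frequency_hz = signif(freqs, 8)))
  alpha_eff <- if (cfg$bonferroni) cfg$alpha / length(freqs) else cfg$alpha
  sig <- p < alpha_eff
  onset_f <- apply(p, 2L, persistence_onset, alpha = alpha_eff, days = days)
  onset_day <- if (all(is.na(onset_f))) NA_integer_ else
    as.integer(min(onset_f, na.rm = TRUE))
  band <- NULL
  best_frequency <- NA_real_
  if (!is.na(onset_day)) {
    persist <- apply(sig[days >= onset_day, , drop = FALSE], 2L, all)
    p_onset <- p[match(onset_day, days), ]
    best_idx <- which(persist)[which.min(p_onset[persist])]
    r <- rle(persist)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    run <- which(r$values & starts <= best_idx & ends >= best_idx)
    band <- c(f_lo = freqs[starts[run]], f_hi = freqs[ends[run]])
    best_frequency <- freqs[best_idx]
  } else {
    message("scan: no persistent discriminator (no frequency stays ",
            "significant through day ", cfg$final_day, ")")
  }
  structure(list(p_matrix = p, sig_mask = sig, band = band,
                 onset_day = onset_day, best_frequency = best_frequency,
                 alpha = alpha_eff, days = days, frequencies = freqs,
                 config = cfg),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result: %d days x %d frequencies, alpha = %g>\n",
              length(x$days), length(x$frequencies), x$alpha))
  if (is.na(x$onset_day)) {
    cat("  no persistent discriminator\n")
  } else {
    cat(sprintf("  onset day %d; band %.4g Hz .. %.4g Hz; best %.4g Hz\n",
                x$onset_day, x$band[["f_lo"]], x$band[["f_hi"]],
                x$best_frequency))
  }
  invisible(x)
}

#' Per-day summary table at one frequency, with persistence stars
#'
#' Re-derives the familiar per-day report from group summaries: one row per
#' incubation day with male/female mean, SD, the recomputed p-value, and a
#' star on every day belonging to the persistent significant tail (p < alpha
#' continuously through the final day).
#'
#' @param daily Data.frame with columns \code{day}, \code{male_mean},
#'   \code{male_sd}, \code{n_male}, \code{female_mean}, \code{female_sd},
#'   \code{n_female} — e.g. \code{\link{reference_daily_summaries}} or the
#'   output of \code{\link{group_summaries}} reshaped via
#'   \code{\link{daily_summaries_at}}.
#' @param cfg A \code{\link{scan_config}}.
#' @return The input with added columns \code{p_value} and \code{star}
#'   (logical persistence flag).
#' @export
daily_ratio_table <- function(daily, cfg = scan_config()) {
  need <- c("day", "male_mean", "male_sd", "n_male",
            "female_mean", "female_sd", "n_female")
  miss <- setdiff(need, names(daily))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  daily <- daily[order(daily$day), , drop = FALSE]
  k <- t_kernel(daily$male_mean, daily$male_sd, daily$n_male,
                daily$female_mean, daily$female_sd, daily$n_female,
                cfg$variant, cfg$tails)
  daily$p_value <- k$p_value
  onset <- persistence_onset(daily$p_value, cfg$alpha, days = daily$day)
  daily$star <- if (is.na(onset)) rep(FALSE, nrow(daily)) else daily$day >= onset
  rownames(daily) <- NULL
  daily
}

#' Reshape group summaries to one row per day at a single frequency
#'
#' @param gs Output of \code{\link{group_summaries}}.
#' @param frequency_hz A grid frequency present in \code{gs}.
#' @return Data.frame in the layout \code{\link{daily_ratio_table}} expects.
#' @export
daily_summaries_at <- function(gs, frequency_hz) {
  sel <- gs[abs(gs$frequency_hz - frequency_hz) <=
              1e-9 * frequency_hz, , drop = FALSE]
  if (!nrow(sel)) stop("frequency ", frequency_hz, " not present in summaries")
  ml <- sel[sel$group == "male", ]
  fl <- sel[sel$group == "female", ]
  days <- sort(intersect(ml$day, fl$day))
  drop <- setdiff(union(ml$day, fl$day), days)
  if (length(drop)) warning("days missing one group omitted: ",
                            paste(drop, collapse = ", "))
  data.frame(day = days,
             male_mean = ml$mean[match(days, ml$day)],
             male_sd = ml$sd[match(days, ml$day)],
             n_male = ml$n[match(days, ml$day)],
             female_mean = fl$mean[match(days, fl$day)],
             female_sd = fl$sd[match(days, fl$day)],
             n_female = fl$n[match(days, fl$day)])
}
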