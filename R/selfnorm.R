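#' Self-normalized ratio spectrum for one egg and day
#'
#' The core statistic: at each frequency, |Z| measured on one electrode pair
#' divided by |Z| measured simultaneously on another pair of the same egg.
#' Egg-level scale (shell thickness, size) and instrument gain multiply both
#' pairs and cancel, leaving a dimensionless spectrum comparable across eggs.
#'
#' @param num Single-sweep data.frame (one egg, day, pair) for the numerator
#'   pair, as a subset of a \code{sweep_df}.
#' @param den Same egg and day, the denominator pair.
#' @return Data.frame with columns \code{egg_id}, \code{day},
#'   \code{frequency_hz}, \code{ratio}; attributes \code{num_pair},
#'   \code{den_pair}.
#' @export
ratio_spectrum <- function(num, den) {
  one_sweep <- function(d, nm) {
    if (length(unique(d$egg_id)) != 1L || length(unique(d$day)) != 1L ||
        length(unique(d$pair)) != 1L) {
      stop(nm, " must be a single sweep (one egg, one day, one pair)")
    }
    d[order(d$frequency_hz), , drop = FALSE]
  }
  num <- one_sweep(num, "num")
  den <- one_sweep(den, "den")
  if (num$egg_id[1L] != den$egg_id[1L] || num$day[1L] != den$day[1L]) {
    stop("numerator and denominator sweeps must share egg_id and day")
  }
  if (num$pair[1L] == den$pair[1L]) {
    stop("numerator and denominator must be different electrode pairs")
  }
  if (nrow(num) != nrow(den) ||
      !isTRUE(all.equal(num$frequency_hz, den$frequency_hz, tolerance = 1e-9))) {
    stop("numerator and denominator sweeps are on different grids")
  }
  out <- data.frame(egg_id = num$egg_id, day = num$day,
                    frequency_hz = num$frequency_hz,
                    ratio = num$z_mod_ohm / den$z_mod_ohm,
                    stringsAsFactors = FALSE)
  structure(out, num_pair = num$pair[1L], den_pair = den$pair[1L],
            class = c("ratio_df", "data.frame"))
}

#' Ratio spectra for a whole dataset
#'
#' Forms the pair ratio (default 2-3 over 2-4) for every (egg, day) that
#' carries both pairs. Combinations missing either pair are skipped, never
#' imputed; the skipped (egg, day) list is attached as attribute
#' \code{"exclusions"} and reported via a message.
#'
#' @param sweeps A \code{sweep_df}.
#' @param num_pair,den_pair Electrode pairs, canonicalized via
#'   \code{\link{electrode_pair}}.
#' @return A \code{ratio_df}: columns \code{egg_id}, \code{day},
#'   \code{frequency_hz}, \code{ratio}; attributes \code{num_pair},
#'   \code{den_pair}, \code{grid}, \code{exclusions}.
#' @export
ratio_dataset <- function(sweeps, num_pair = "2-3", den_pair = "2-4") {
  num_pair <- electrode_pair(num_pair)
  den_pair <- electrode_pair(den_pair)
  if (num_pair == den_pair) stop("num_pair and den_pair must differ")
  grid <- attr(sweeps, "grid")
  nd <- sweeps[sweeps$pair == num_pair, , drop = FALSE]
  dd <- sweeps[sweeps$pair == den_pair, , drop = FALSE]
  key_n <- unique(nd[, c("egg_id", "day")])
  key_d <- unique(dd[, c("egg_id", "day")])
  both <- merge(key_n, key_d)
  all_keys <- unique(sweeps[, c("egg_id", "day")])
  excl <- all_keys[!paste(all_keys$egg_id, all_keys$day) %in%
                     paste(both$egg_id, both$day), , drop = FALSE]
  if (nrow(excl)) {
    message("ratio_dataset: skipped ", nrow(excl),
            " (egg, day) combination(s) missing pair ", num_pair,
            " or ", den_pair, ": ",
            paste(paste0(excl$egg_id, "/d", excl$day), collapse = ", "))
  }
  # both tables are sorted egg/day/frequency, so rows align after filtering
  keep <- paste(nd$egg_id, nd$day) %in% paste(both$egg_id, both$day)
  nd <- nd[keep, , drop = FALSE]
  dd <- dd[paste(dd$egg_id, dd$day) %in% paste(both$egg_id, both$day), ,
           drop = FALSE]
  stopifnot(nrow(nd) == nrow(dd),
            all(nd$egg_id == dd$egg_id), all(nd$day == dd$day))
  out <- data.frame(egg_id = nd$egg_id, day = nd$day,
                    frequency_hz = nd$frequency_hz,
                    ratio = nd$z_mod_ohm / dd$z_mod_ohm,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, num_pair = num_pair, den_pair = den_pair, grid = grid,
            exclusions = excl, class = c("ratio_df", "data.frame"))
}

#' Write a ratio table to CSV
#' @param ratios A \code{ratio_df}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_ratios <- function(ratios, path) {
  out <- data.frame(egg_id = ratios$egg_id, day = ratios$day,
                    frequency_hz = sprintf("%.17g", ratios$frequency_hz),
                    ratio = sprintf("%.17g", ratios$ratio),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ratio table from CSV
#' @param path CSV with columns \code{egg_id}, \code{day},
#'   \code{frequency_hz}, \code{ratio}.
#' @return A \code{ratio_df} (grid inferred from the data).
#' @export
read_ratios <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(egg_id = "character"))
  need <- c("egg_id", "day", "frequency_hz", "ratio")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ratio CSV missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$ratio <= 0)) stop("ratio values must be > 0")
  df <- df[order(df$egg_id, df$day, df$frequency_hz), need]
  rownames(df) <- NULL
  structure(df, grid = frequency_grid(sort(unique(df$frequency_hz))),
            class = c("ratio_df", "data.frame"))
}
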