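#' Frequency grids for impedance sweeps
#'
#' A frequency grid is an ordered set of measurement frequencies in Hz. The
#' default instrument sweep covers 20 Hz to 10 MHz in 100 logarithmically
#' spaced points (six decades), the standard configuration of a precision
#' impedance analyzer / LCR meter.
#'
#' @param points Numeric vector of frequencies in Hz, strictly increasing,
#'   all within \[20, 1e7\].
#' @return An object of class \code{frequency_grid} (a numeric vector).
#' @export
frequency_grid <- function(points) {
  points <- as.numeric(points)
  if (length(points) == 0L) stop("frequency grid must be non-empty")
  if (any(!is.finite(points))) stop("frequency grid contains non-finite values")
  if (any(diff(points) <= 0)) stop("frequency grid must be strictly increasing")
  if (min(points) < 20 || max(points) > 1e7) {
    stop("frequency grid points must lie within [20 Hz, 10 MHz]")
  }
  structure(points, class = "frequency_grid")
}

#' Default 100-point logarithmic sweep grid, 20 Hz to 10 MHz
#'
#' @return A \code{frequency_grid} with exactly 100 points; the first is
#'   20 Hz and the last 10 MHz, log-spaced in between.
#' @examples
#' g <- make_default_grid()
#' length(g)   # 100
#' range(g)    # 20 1e7
#' @export
make_default_grid <- function() {
  n <- 100L
  f <- 20 * (1e7 / 20)^((seq_len(n) - 1) / (n - 1))
  f[1L] <- 20
  f[n] <- 1e7
  frequency_grid(f)
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("<frequency_grid: %d points, %.6g Hz .. %.6g Hz>\n",
              length(x), x[1L], x[length(x)]))
  invisible(x)
}

#' Sweep configuration
#'
#' Drive amplitude, dwell time and frequency grid of one impedance sweep.
#' Defaults match the measurement protocol: 100 mV rms excitation, 80 ms per
#' point, 100-point log grid over 20 Hz-10 MHz.
#'
#' @param excitation_mv Drive amplitude, mV rms (> 0).
#' @param dwell_ms Per-point measurement time, ms (> 0).
#' @param grid A \code{frequency_grid}.
#' @return An object of class \code{sweep_config}.
#' @export
sweep_config <- function(excitation_mv = 100, dwell_ms = 80,
                         grid = make_default_grid()) {
  stopifnot(is.numeric(excitation_mv), length(excitation_mv) == 1L,
            excitation_mv > 0,
            is.numeric(dwell_ms), length(dwell_ms) == 1L, dwell_ms > 0)
  if (!inherits(grid, "frequency_grid")) grid <- frequency_grid(grid)
  structure(list(excitation_mv = excitation_mv, dwell_ms = dwell_ms,
                 grid = grid),
            class = "sweep_config")
}

#' Canonicalize an electrode pair
#'
#' Electrodes are numbered 1-4: 1 and 2 at the broad and narrow ends of the
#' egg (height axis), 3 and 4 diametrically opposite on the width
#' circumference. A pair is written \code{"a-b"} with \code{a < b}; input
#' order is normalized, so \code{"3-2"} becomes \code{"2-3"}.
#'
#' @param pair Character vector like \code{"2-3"}, or a length-2 integer
#'   vector for a single pair.
#' @return Canonical \code{"a-b"} character vector.
#' @export
electrode_pair <- function(pair) {
  if (is.numeric(pair) && length(pair) == 2L) {
    pair <- paste(pair, collapse = "-")
  }
  parts <- strsplit(as.character(pair), "-", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2L) stop("electrode pair must have form 'a-b'")
    ab <- suppressWarnings(as.integer(p))
    if (any(is.na(ab)) || any(!ab %in% 1:4)) {
      stop("electrode indices must be integers in 1..4, got '",
           paste(p, collapse = "-"), "'")
    }
    if (ab[1L] == ab[2L]) stop("electrode pair must use two distinct electrodes")
    paste(sort(ab), collapse = "-")
  }, character(1L))
}

#' Nearest grid frequency (log scale)
#'
#' Maps an arbitrary target frequency onto the measured grid: returns the
#' grid point minimizing the distance in log10 frequency, ties broken toward
#' the lower index. Use this to place a nominal operating frequency (e.g.
#' 376 kHz) on the actual sweep grid.
#'
#' @param grid A \code{frequency_grid}.
#' @param f_target Target frequency in Hz (> 0), scalar.
#' @return List with \code{index} (1-based) and \code{frequency} (Hz).
#' @export
nearest_grid_frequency <- function(grid, f_target) {
  if (length(grid) == 0L) stop("empty frequency grid")
  stopifnot(is.numeric(f_target), length(f_target) == 1L, f_target > 0)
  i <- which.min(abs(log10(as.numeric(grid)) - log10(f_target)))
  list(index = i, frequency = as.numeric(grid)[i])
}

valid_sexes <- c("male", "female", "unfertilized", "unknown")
valid_sources <- c("pcr", "impedance")

#' Construct a sex-label table
#'
#' @param egg_id Character vector of egg identifiers.
#' @param sex One of \code{"male"}, \code{"female"}, \code{"unfertilized"},
#'   \code{"unknown"} per egg.
#' @param source Label provenance, \code{"pcr"} or \code{"impedance"}.
#'   Unfertilized calls can only come from PCR.
#' @return A data.frame with columns \code{egg_id}, \code{sex}, \code{source}.
#' @export
sex_labels <- function(egg_id, sex, source = "pcr") {
  egg_id <- as.character(egg_id)
  sex <- as.character(sex)
  source <- rep_len(as.character(source), length(egg_id))
  if (!all(sex %in% valid_sexes)) {
    stop("sex must be one of: ", paste(valid_sexes, collapse = ", "))
  }
  if (!all(source %in% valid_sources)) {
    stop("source must be one of: ", paste(valid_sources, collapse = ", "))
  }
  if (any(sex == "unfertilized" & source != "pcr")) {
    stop("'unfertilized' labels can only originate from PCR")
  }
  data.frame(egg_id = egg_id, sex = sex, source = source,
             stringsAsFactors = FALSE)
}

# normalize a sweep table: canonical pairs, sorted rows, type checks
normalize_sweep_frame <- function(df, context = "sweep table") {
  need <- c("egg_id", "day", "pair", "frequency_hz", "z_mod_ohm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(context, " is missing required columns: ", paste(miss, collapse = ", "))
  }
  df$egg_id <- as.character(df$egg_id)
  df$day <- as.integer(df$day)
  if (any(is.na(df$day)) || any(df$day < 0L) || any(df$day > 13L)) {
    stop("incubation day must be an integer in 0..13")
  }
  df$pair <- electrode_pair(df$pair)
  df$frequency_hz <- as.numeric(df$frequency_hz)
  df$z_mod_ohm <- as.numeric(df$z_mod_ohm)
  if (any(!is.finite(df$z_mod_ohm)) || any(df$z_mod_ohm <= 0)) {
    stop("|Z| values must be finite and > 0")
  }
  if (!"phase_deg" %in% names(df)) df$phase_deg <- rep(NA_real_, nrow(df))
  df$phase_deg <- suppressWarnings(as.numeric(df$phase_deg))
  key <- paste(df$egg_id, df$day, df$pair, format(df$frequency_hz, digits = 15))
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (egg_id, day, pair, frequency) row: ", d)
  }
  df <- df[order(df$egg_id, df$day, df$pair, df$frequency_hz), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("egg_id", "day", "pair", "frequency_hz", "z_mod_ohm", "phase_deg")]
}

# check each (egg, day, pair) sweep against a grid; infer the grid if NULL
resolve_sweep_grid <- function(df, grid = NULL) {
  sweeps <- split(df$frequency_hz,
                  interaction(df$egg_id, df$day, df$pair, drop = TRUE))
  if (is.null(grid)) grid <- frequency_grid(sweeps[[1L]])
  ref <- as.numeric(grid)
  ok <- vapply(sweeps, function(f) {
    length(f) == length(ref) && isTRUE(all.equal(f, ref, tolerance = 1e-9))
  }, logical(1L))
  if (!all(ok)) {
    stop("sweeps on inconsistent frequency grids: ",
         paste(names(sweeps)[!ok], collapse = ", "))
  }
  grid
}

#' Read impedance sweeps from a long-format CSV
#'
#' Expected columns: \code{egg_id}, \code{day}, \code{pair} (e.g.
#' \code{"2-3"}), \code{frequency_hz}, \code{z_mod_ohm}, optional
#' \code{phase_deg}. One row per measured frequency. Every sweep (one
#' \code{(egg_id, day, pair)} combination) must cover the same grid.
#'
#' @param path CSV file path.
#' @param grid Optional \code{frequency_grid} to validate against; if
#'   \code{NULL} (default, "infer" policy) the grid is taken from the data.
#' @return A sweep data.frame (class \code{sweep_df}) sorted by egg, day,
#'   pair, frequency, with the grid attached as attribute \code{"grid"}.
#' @export
read_sweeps <- function(path, grid = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(egg_id = "character"))
  as_sweep_df(df, grid = grid, context = path)
}

#' Validate a long-format sweep data.frame
#'
#' @param df Data.frame in the layout of \code{\link{read_sweeps}}.
#' @param grid Optional grid to validate against (inferred when \code{NULL}).
#' @param context Name used in error messages.
#' @return A \code{sweep_df}.
#' @export
as_sweep_df <- function(df, grid = NULL, context = "sweep table") {
  df <- normalize_sweep_frame(df, context = context)
  if (nrow(df) > 0L) {
    grid <- resolve_sweep_grid(df, grid)
  } else if (is.null(grid)) {
    grid <- make_default_grid()
  }
  structure(df, grid = grid, class = c("sweep_df", "data.frame"))
}

#' Write impedance sweeps to CSV
#'
#' Rows are emitted in the deterministic order (egg_id, day, pair, frequency
#' ascending) with full double precision (17 significant digits), so
#' \code{read_sweeps(write_sweeps(x))} reproduces values bit-exactly.
#'
#' @param df A sweep data.frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_sweeps <- function(df, path) {
  if (nrow(df) > 0L) df <- normalize_sweep_frame(df)
  out <- data.frame(
    egg_id = df$egg_id,
    day = df$day,
    pair = df$pair,
    frequency_hz = sprintf("%.17g", df$frequency_hz),
    z_mod_ohm = sprintf("%.17g", df$z_mod_ohm),
    phase_deg = ifelse(is.na(df$phase_deg), "",
                       sprintf("%.17g", df$phase_deg)),
    stringsAsFactors = FALSE
  )
  if (nrow(df) == 0L) out <- out[0L, , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sex-label CSV
#'
#' Columns \code{egg_id}, \code{sex} (\code{M}/\code{F}/\code{NA} shorthand
#' or full names), optional \code{source} (default \code{"pcr"}).
#'
#' @param path CSV file path.
#' @return A label data.frame as from \code{\link{sex_labels}}.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(egg_id = "character"),
                        na.strings = character(0L))
  sx <- tolower(df$sex)
  sx[sx %in% c("m", "male")] <- "male"
  sx[sx %in% c("f", "female")] <- "female"
  sx[sx %in% c("na", "n/a", "unfertilized", "")] <- "unfertilized"
  src <- if ("source" %in% names(df)) df$source else "pcr"
  sex_labels(df$egg_id, sx, src)
}

#' Write a sex-label CSV
#' @param labels Label data.frame (\code{egg_id}, \code{sex}, \code{source}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize a sweep table (counts and grid diagnostics)
#'
#' @param df A \code{sweep_df}.
#' @return List with record counts per egg/day/pair and the grid; printed by
#'   the \code{validate} command-line verb.
#' @export
sweep_diagnostics <- function(df) {
  grid <- attr(df, "grid")
  key <- unique(df[, c("egg_id", "day", "pair")])
  list(
    n_rows = nrow(df),
    n_sweeps = nrow(key),
    n_eggs = length(unique(df$egg_id)),
    days = sort(unique(df$day)),
    pairs = sort(unique(df$pair)),
    grid_points = length(grid),
    grid_range_hz = if (length(grid)) range(as.numeric(grid)) else c(NA, NA)
  )
}
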