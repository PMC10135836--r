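#' Call sex from PCR gel band sizes
#'
#' CHD-locus sexing on a 2% agarose gel: a single ~552 bp fragment marks a
#' male (ZZ) embryo; two fragments at ~552 bp and ~358 bp mark a female
#' (ZW). Gel reads are approximate, so a band matches a marker when it lies
#' within \code{tol_bp} of the nominal size (default 15 bp). A record with
#' no matching bands is unknown — unless the accompanying survival flag says
#' the egg was not fertilized, in which case it is labeled unfertilized.
#'
#' @param bands Numeric vector of observed fragment sizes in bp (may be
#'   empty).
#' @param tol_bp Band-size matching tolerance in bp.
#' @param fertilized \code{TRUE}/\code{FALSE}/\code{NA} survival flag;
#'   only \code{FALSE} converts a no-signal record to "unfertilized".
#' @return One of \code{"male"}, \code{"female"}, \code{"unfertilized"},
#'   \code{"unknown"}.
#' @export
call_sex_from_bands <- function(bands, tol_bp = 15, fertilized = NA) {
  bands <- as.numeric(bands)
  bands <- bands[!is.na(bands)]
  if (any(bands <= 0)) stop("band sizes must be positive")
  has552 <- any(abs(bands - 552) <= tol_bp)
  has358 <- any(abs(bands - 358) <= tol_bp)
  if (has552 && has358) return("female")
  if (has552) return("male")
  if (has358) {
    warning("358 bp band without the 552 bp band: calling unknown")
    return("unknown")
  }
  if (isFALSE(fertilized)) "unfertilized" else "unknown"
}

#' Read a PCR banding CSV and call sex labels
#'
#' Expected columns: \code{egg_id}; \code{bands}, semicolon-separated
#' fragment sizes in bp (may be empty); optional \code{survival} with
#' \code{"+"} for fertilized and \code{"NA"}/\code{"N/A"} for not
#' fertilized.
#'
#' @param path Banding CSV path.
#' @param tol_bp Matching tolerance passed to
#'   \code{\link{call_sex_from_bands}}.
#' @return Sex labels with \code{source = "pcr"}.
#' @export
pcr_labels <- function(path, tol_bp = 15) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = character(0L))
  if (!all(c("egg_id", "bands") %in% names(df))) {
    stop("banding CSV needs columns egg_id, bands")
  }
  fert <- if ("survival" %in% names(df)) {
    ifelse(trimws(df$survival) == "+", TRUE,
           ifelse(toupper(trimws(df$survival)) %in% c("NA", "N/A"), FALSE, NA))
  } else rep(NA, nrow(df))
  sex <- vapply(seq_len(nrow(df)), function(i) {
    b <- strsplit(df$bands[i], ";", fixed = TRUE)[[1L]]
    b <- suppressWarnings(as.numeric(trimws(b)))
    call_sex_from_bands(b[!is.na(b)], tol_bp = tol_bp,
                        fertilized = fert[i])
  }, character(1L))
  sex_labels(df$egg_id, sex, source = "pcr")
}

#' Tally sex labels
#'
#' @param labels Label data.frame with unique egg ids.
#' @return Named integer vector with counts of male, female, unfertilized,
#'   unknown.
#' @export
tally_labels <- function(labels) {
  if (anyDuplicated(labels$egg_id)) {
    stop("duplicate egg ids: ",
         paste(unique(labels$egg_id[duplicated(labels$egg_id)]),
               collapse = ", "))
  }
  counts <- table(factor(labels$sex, levels = valid_sexes))
  stats::setNames(as.integer(counts), valid_sexes)
}

#' Reference cohort PCR records
#'
#' The bundled 17-egg reference cohort: per-egg survival flag and PCR sex
#' call (8 male, 8 female, 1 unfertilized). The companion banding file
#' \code{reference_pcr_bands.csv} is reconstructed from these calls via the
#' band-call rule (552 bp for males, 552+358 bp for females; no per-egg gel
#' sizes were published), and is labeled accordingly.
#'
#' @param what \code{"labels"} for the survival/sex table or \code{"bands"}
#'   for the reconstructed banding CSV path.
#' @return For \code{"labels"}, a label data.frame; for \code{"bands"}, the
#'   file path (feed it to \code{\link{pcr_labels}}).
#' @export
reference_pcr_records <- function(what = c("labels", "bands")) {
  what <- match.arg(what)
  if (what == "bands") {
    return(system.file("extdata", "reference_pcr_bands.csv",
                       package = "ovosex", mustWork = TRUE))
  }
  read_labels(system.file("extdata", "reference_pcr_records.csv",
                          package = "ovosex", mustWork = TRUE))
}

#' Reference per-day ratio summaries at 376 kHz
#'
#' The bundled per-day group summary statistics of the 2-3 / 2-4 impedance
#' ratio at 376 kHz for the 8+8-egg reference cohort across incubation days
#' 1-13: male/female mean and SD, group sizes, and the originally reported
#' two-tailed independent t-test p-value. This table is both the
#' verification target for the scan statistics and the calibration source of
#' the synthetic generator's day-9 effect sizes.
#'
#' @return Data.frame: \code{day}, \code{male_mean}, \code{male_sd},
#'   \code{n_male}, \code{female_mean}, \code{female_sd}, \code{n_female},
#'   \code{p_reported}.
#' @export
reference_daily_summaries <- function() {
  utils::read.csv(system.file("extdata", "reference_daily_summaries.csv",
                              package = "ovosex", mustWork = TRUE))
}
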