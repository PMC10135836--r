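#' Run the full analysis pipeline
#'
#' Orchestrates simulate/ingest -> normalize -> scan -> classify -> evaluate
#' from a single config (a YAML/JSON file path or an equivalent named list)
#' and writes \code{ratios.csv}, \code{scan.json}, \code{calls.csv},
#' \code{report.json} and \code{run_log.txt} into \code{out_dir}. Outputs are
#' a pure function of (inputs, config, seed); the run log records the config
#' hash so a bundle can be traced to its configuration.
#'
#' Config blocks (unknown keys are errors):
#' \describe{
#'   \item{input}{\code{sweeps}, \code{labels}: CSV paths.}
#'   \item{simulate}{any \code{\link{cohort_sim_config}} argument; used when
#'     no \code{input} block is given.}
#'   \item{normalize}{\code{num_pair}, \code{den_pair}.}
#'   \item{scan}{any \code{\link{scan_config}} argument.}
#'   \item{classify}{any \code{\link{classifier_config}} argument;
#'     \code{frequency} is snapped to the grid. Optional block.}
#'   \item{evaluate}{\code{enabled}: logical (default true when labels
#'     exist).}
#' }
#'
#' @param config Path to a YAML/JSON config file, or a named list.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results: \code{ratios},
#'   \code{scan}, \code{calls}, \code{report}, \code{paths}.
#' @export
run_pipeline <- function(config, out_dir = ".") {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a file path or a named list")
  known <- c("input", "simulate", "normalize", "scan", "classify", "evaluate")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown config block(s): ",
                            paste(unknown, collapse = ", "))
  check_keys <- function(block, allowed, name) {
    bad <- setdiff(names(block), allowed)
    if (length(bad)) stop("unknown key(s) in '", name, "' block: ",
                          paste(bad, collapse = ", "))
    block
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0L)
  say <- function(...) {
    msg <- paste0(...)
    message("[ovosex] ", msg)
    log_lines <<- c(log_lines, msg)
  }
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(fileext = ".json")
  writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  say("config hash ", cfg_hash)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- inputs -----------------------------------------------------------
  labels <- NULL
  if (!is.null(cfg$input)) {
    check_keys(cfg$input, c("sweeps", "labels"), "input")
    if (is.null(cfg$input$sweeps)) stop("'input' block must name 'sweeps'")
    sweeps <- stage("input", read_sweeps(cfg$input$sweeps))
    if (!is.null(cfg$input$labels)) {
      labels <- stage("input", read_labels(cfg$input$labels))
    }
    say("loaded ", nrow(sweeps), " sweep rows from ", cfg$input$sweeps)
  } else {
    sim_args <- check_keys(cfg$simulate %||% list(),
                           names(formals(cohort_sim_config)), "simulate")
    sim_cfg <- do.call(cohort_sim_config, sim_args)
    sim <- stage("simulate", simulate_cohort(sim_cfg))
    sweeps <- sim$sweeps
    labels <- sim$labels
    say("simulated cohort: ", sim_cfg$n_male, " male + ", sim_cfg$n_female,
        " female eggs, seed ", sim_cfg$seed)
  }

  # --- normalize --------------------------------------------------------
  nb <- check_keys(cfg$normalize %||% list(), c("num_pair", "den_pair"),
                   "normalize")
  ratios <- stage("normalize", ratio_dataset(
    sweeps,
    num_pair = nb$num_pair %||% "2-3",
    den_pair = nb$den_pair %||% "2-4"))
  ratio_path <- file.path(out_dir, "ratios.csv")
  write_ratios(ratios, ratio_path)
  say("wrote ", ratio_path)

  # --- scan -------------------------------------------------------------
  if (is.null(labels)) stop("scan requires labels: provide input$labels ",
                            "or a simulate block")
  sb <- check_keys(cfg$scan %||% list(), names(formals(scan_config)), "scan")
  scan_cfg <- do.call(scan_config, sb)
  sc <- stage("scan", scan(ratios, labels, scan_cfg))
  scan_path <- file.path(out_dir, "scan.json")
  jsonlite::write_json(list(
    config_hash = cfg_hash,
    alpha = sc$alpha,
    days = sc$days,
    frequencies = sc$frequencies,
    p_matrix = apply(sc$p_matrix, 1L, identity, simplify = FALSE),
    onset_day = sc$onset_day,
    band = as.list(sc$band),
    best_frequency = sc$best_frequency
  ), scan_path, auto_unbox = TRUE, digits = NA, na = "null")
  say("wrote ", scan_path, if (!is.na(sc$onset_day))
    paste0(" (onset day ", sc$onset_day, ")") else " (no persistent band)")

  # --- classify / evaluate ---------------------------------------------
  calls <- NULL
  report <- NULL
  cb <- check_keys(cfg$classify %||% list(),
                   names(formals(classifier_config)), "classify")
  cls_cfg <- do.call(classifier_config, cb)
  grid <- attr(ratios, "grid")
  cls_cfg$frequency <- nearest_grid_frequency(grid, cls_cfg$frequency)$frequency
  calls <- stage("classify", classify_eggs(ratios, cls_cfg))
  calls_path <- file.path(out_dir, "calls.csv")
  write_labels(calls, calls_path)
  say("wrote ", calls_path)

  eb <- check_keys(cfg$evaluate %||% list(), "enabled", "evaluate")
  do_eval <- isTRUE(eb$enabled %||% !is.null(labels))
  if (do_eval) {
    if (is.null(labels)) stop("'evaluate' is enabled but no labels were ",
                              "provided (missing input$labels)")
    report <- stage("evaluate", evaluate(calls, labels))
  }
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(list(
    config_hash = cfg_hash,
    onset_day = sc$onset_day,
    band = as.list(sc$band),
    best_frequency = sc$best_frequency,
    classifier = list(day = cls_cfg$day, frequency = cls_cfg$frequency,
                      threshold = cls_cfg$threshold, margin = cls_cfg$margin),
    evaluation = if (!is.null(report)) list(
      confusion = as.list(as.data.frame(report$confusion)),
      accuracy = report$accuracy,
      balanced_accuracy = report$balanced_accuracy,
      male_sensitivity = report$male_sensitivity,
      female_sensitivity = report$female_sensitivity,
      n_indeterminate = report$n_indeterminate,
      n_excluded = report$n_excluded
    )
  ), report_path, auto_unbox = TRUE, digits = NA, na = "null")
  say("wrote ", report_path)

  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    paste0("config_hash: ", cfg_hash),
    paste0("R_version: ", R.version.string),
    paste0("ovosex_version: ",
           as.character(utils::packageVersion("ovosex"))),
    log_lines), log_path)

  invisible(list(ratios = ratios, scan = sc, calls = calls, report = report,
                 paths = list(ratios = ratio_path, scan = scan_path,
                              calls = calls_path, report = report_path,
                              log = log_path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
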