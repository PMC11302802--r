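#' Read a per-event QC catch log
#'
#' Expects a UTF-8 comma-separated file with header columns `plan_id`,
#' `fm_id`, `check_layer` (1-based integer layer that caught the FM).  Each
#' (plan, FM) pair may appear at most once — an FM is caught once per plan —
#' and offending rows are reported by number.
#'
#' @param path CSV file path.
#' @param n_layers Number of QC layers in place; rows referencing higher
#'   layers are a parse error.
#' @return Tibble with columns `plan_id`, `fm_id`, `layer_caught`,
#'   `recorded` (`TRUE`: a real log only contains recorded catches),
#'   suitable for [aggregate_events()].
#' @export
read_event_log <- function(path, n_layers = 2) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("plan_id", "fm_id", "check_layer")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("event log ", path, " is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    return(tibble::tibble(plan_id = integer(), fm_id = character(),
                          layer_caught = integer(), recorded = logical()))
  }
  layer <- as.numeric(raw$check_layer)
  bad <- which(is.na(layer) | layer != floor(layer) | layer < 1)
  if (length(bad)) {
    stop("non-positive or non-integer check_layer at rows: ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (layers are 1-based)", call. = FALSE)
  }
  over <- which(layer > n_layers)
  if (length(over)) {
    stop("check_layer exceeds n_layers = ", n_layers, " at rows: ",
         paste(utils::head(over, 5), collapse = ", "), call. = FALSE)
  }
  dup <- which(duplicated(raw[c("plan_id", "fm_id")]))
  if (length(dup)) {
    stop("duplicate (plan_id, fm_id) at rows: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(plan_id = raw$plan_id, fm_id = as.character(raw$fm_id),
                 layer_caught = as.integer(layer), recorded = TRUE)
}

#' @rdname read_event_log
#' @param events Event tibble (e.g. from [simulate_clinic()]); only
#'   recorded catches are written, mirroring what a real log contains.
#' @export
write_event_log <- function(events, path) {
  events <- tibble::as_tibble(events)
  if (!"recorded" %in% names(events)) events$recorded <- TRUE
  obs <- dplyr::filter(events, .data$recorded, !is.na(.data$layer_caught))
  readr::write_csv(
    tibble::tibble(plan_id = obs$plan_id, fm_id = obs$fm_id,
                   check_layer = obs$layer_caught),
    path
  )
  invisible(path)
}

#' Read pre-aggregated per-FM catch counts
#'
#' CSV with header `fm_id`, `n1`, `n2` (case-insensitive: `N1`/`N2`
#' accepted).
#'
#' @param path CSV file path.
#' @return Tibble with columns `fm_id`, `n1`, `n2`.
#' @export
read_check_counts <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(raw) <- tolower(names(raw))
  need <- c("fm_id", "n1", "n2")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("counts file ", path, " is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  check_count_args(raw$n1, raw$n2)
  tibble::tibble(fm_id = as.character(raw$fm_id),
                 n1 = as.integer(raw$n1), n2 = as.integer(raw$n2))
}

#' Read a consensus (O, S, D) table
#'
#' CSV with header `fm_id`, `O`, `S`, `D` (case-insensitive; `S` may be
#' blank).  One-decimal consensus scores are accepted.
#'
#' @param path CSV file path.
#' @return Tibble with columns `fm_id`, `o`, `s`, `d`.
#' @export
read_consensus <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(raw) <- tolower(names(raw))
  missing <- setdiff(c("fm_id", "o", "d"), names(raw))
  if (length(missing)) {
    stop("consensus file ", path, " is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"s" %in% names(raw)) raw$s <- NA_real_
  check_consensus(raw)
  tibble::tibble(fm_id = as.character(raw$fm_id),
                 o = as.numeric(raw$o), s = as.numeric(raw$s),
                 d = as.numeric(raw$d))
}

#' Assemble a run configuration
#'
#' Bundles input paths and settings for [run_estimate()].  Exactly one of
#' `events` (per-event log) or `counts` (pre-aggregated) must be supplied;
#' `n_plans` is always required and never inferred from the log.
#'
#' @param events,counts Path to the event-log CSV or the counts CSV.
#' @param n_plans Number of plans covered by the log.
#' @param n_layers Number of QC layers (default 2).
#' @param consensus Optional path to a consensus CSV; when given,
#'   validation columns are appended to the report.
#' @param o_scale,d_scale Optional paths to scale JSON files (defaults:
#'   bundled tables).
#' @param severity Optional single severity score applied to all FMs, or a
#'   path to a CSV with columns `fm_id`, `severity`.
#' @param n_reps,n_boot,level,seed Monte-Carlo and bootstrap settings.
#' @return A `run_config` list.
#' @export
run_config <- function(events = NULL, counts = NULL, n_plans, n_layers = 2,
                       consensus = NULL, o_scale = NULL, d_scale = NULL,
                       severity = NULL, n_reps = 1e5, n_boot = 2000,
                       level = 0.95, seed = 1) {
  if (is.null(events) == is.null(counts)) {
    stop("supply exactly one of `events` or `counts`", call. = FALSE)
  }
  structure(
    list(events = events, counts = counts, n_plans = n_plans,
         n_layers = n_layers, consensus = consensus,
         o_scale = o_scale, d_scale = d_scale, severity = severity,
         n_reps = n_reps, n_boot = n_boot, level = level,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full estimation (and optional validation) pipeline
#'
#' Reads the configured inputs, estimates per-FM risk scores, optionally
#' validates against a consensus table, and returns one report row per
#' failure mode, sorted by `fm_id`.  FMs whose estimate breaks down appear
#' with a `status` flag, never dropped.  Progress and provenance (input
#' sizes, seed) are logged to `stderr`.
#'
#' @param config A [run_config()].
#' @return A `risk_estimates` tibble (with validation columns joined when a
#'   consensus table was configured).
#' @export
run_estimate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  o_table <- if (is.null(config$o_scale)) default_scale("occurrence")
             else read_scale_json(config$o_scale)
  d_table <- if (is.null(config$d_scale)) default_scale("detectability")
             else read_scale_json(config$d_scale)
  counts <- if (!is.null(config$counts)) {
    read_check_counts(config$counts)
  } else {
    events <- read_event_log(config$events, n_layers = config$n_layers)
    message(sprintf("read %d events from %s", nrow(events), config$events))
    aggregate_events(events, n_plans = config$n_plans,
                     n_layers = config$n_layers)[c("fm_id", "n1", "n2")]
  }
  if (nrow(counts) == 0) {
    warning("no failure modes in input; empty report", call. = FALSE)
  }
  sev <- config$severity
  if (is.character(sev) && length(sev) == 1 && file.exists(sev)) {
    sev_tab <- readr::read_csv(sev, show_col_types = FALSE, progress = FALSE)
    names(sev_tab) <- tolower(names(sev_tab))
    counts <- dplyr::left_join(counts,
                               sev_tab[c("fm_id", "severity")], by = "fm_id")
    sev <- NULL
  }
  message(sprintf("estimating %d FMs over %d plans, %d layers, seed %d",
                  nrow(counts), config$n_plans, config$n_layers, config$seed))
  est <- estimate_risk(counts, n_plans = config$n_plans,
                       n_layers = config$n_layers,
                       severity = if (is.numeric(sev)) sev else NULL,
                       o_table = o_table, d_table = d_table)
  est <- dplyr::arrange(est, .data$fm_id)
  if (!is.null(config$consensus)) {
    cons <- read_consensus(config$consensus)
    val <- validate_consensus(
      tibble::as_tibble(est)[c("fm_id", "n1", "n2")], cons,
      n_plans = config$n_plans, n_layers = config$n_layers,
      o_table = o_table, d_table = d_table,
      n_reps = config$n_reps, n_boot = config$n_boot,
      level = config$level, alpha = 0.05, seed = config$seed
    )
    est <- dplyr::left_join(
      est,
      dplyr::select(tibble::as_tibble(val), -"n1", -"n2"),
      by = "fm_id"
    )
    class(est) <- c("risk_estimates", class(tibble::tibble()))
  }
  est
}

#' Write a report as CSV or JSON
#'
#' @param report A tibble (e.g. from [run_estimate()]).
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_csv(tibble::as_tibble(report), path)
  } else {
    jsonlite::write_json(tibble::as_tibble(report), path,
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}
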