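#' Check efficacy from two-layer catch counts
#'
#' When the same failure mode (FM) is checked for twice — e.g. at initial
#' physics chart check and again at the first weekly check — and both checks
#' catch it with the same per-check probability CE, the observed catch counts
#' satisfy `N1 = N0 * CE` and `N2 = (N0 - N1) * CE`, where `N0` is the true
#' (caught plus uncaught) number of occurrences.  Solving gives
#' `CE = 1 - N2/N1` and `N0 = N1^2 / (N1 - N2)`.
#'
#' `check_efficacy()` and `total_occurrences()` are the vectorised scalar
#' kernels; most users will call [estimate_risk()] on a data frame of counts.
#'
#' @param n1 Catches at the first check layer (vectorised).
#' @param n2 Catches at the second check layer.
#' @return `check_efficacy()`: CE in (0, 1].  `NA` where the estimate is
#'   undefined (`n1 == 0`, insufficient data) or breaks down (`n2 >= n1`);
#'   see [estimate_risk()] for per-FM status flags.
#' @examples
#' check_efficacy(8, 2)      # 0.75
#' total_occurrences(8, 2)   # 10.67 (rounds to 11); 0.67 passed undetected
#' @export
check_efficacy <- function(n1, n2) {
  check_count_args(n1, n2)
  ifelse(n1 > 0 & n2 < n1, 1 - n2 / n1, NA_real_)
}

#' @rdname check_efficacy
#' @return `total_occurrences()`: a tibble with columns `n0_continuous`
#'   (`n1^2/(n1 - n2)`), `n0` (nearest integer, ties away from zero) and
#'   `undetected_count` (`n2^2/(n1 - n2)`, the estimated number that passed
#'   every check).
#' @export
total_occurrences <- function(n1, n2) {
  check_count_args(n1, n2)
  ok <- n1 > 0 & n2 < n1
  n0c <- ifelse(ok, n1^2 / (n1 - n2), NA_real_)
  tibble::tibble(
    n0_continuous = n0c,
    n0 = round_half_away(n0c),
    undetected_count = ifelse(ok, n2^2 / (n1 - n2), NA_real_)
  )
}

#' @rdname check_efficacy
#' @param n_plans Number of plans (or chart checks) the log covers; the
#'   denominator turning `N0` into a per-plan occurrence probability.  Must
#'   be supplied externally — it cannot be inferred from a catch log.
#' @return `occurrence_fraction()`: `n0_continuous / n_plans`.
#' @export
occurrence_fraction <- function(n1, n2, n_plans) {
  if (any(n_plans < 1)) stop("`n_plans` must be >= 1", call. = FALSE)
  total_occurrences(n1, n2)$n0_continuous / n_plans
}

#' Probability a failure mode escapes all check layers
#'
#' With `n_layers` sequential checks each catching the FM independently with
#' probability `ce`, the FM goes undetected with probability
#' `(1 - ce)^n_layers` — the quantity the detectability scale scores.
#' Adding layers of defence lowers D: a CE of 84% gives D = 8 with one
#' check but D below 3 with three.
#'
#' @param ce Single-check efficacy, in \[0, 1\] (vectorised).
#' @param n_layers Number of QC layers in place (default 2: initial plus
#'   first weekly check).
#' @return Undetected probability in \[0, 1\].
#' @examples
#' undetected_probability(0.75, 2)  # 0.0625
#' @export
undetected_probability <- function(ce, n_layers = 2) {
  if (any(!is.na(ce) & (ce < 0 | ce > 1))) {
    stop("`ce` must lie in [0, 1]", call. = FALSE)
  }
  if (any(n_layers < 1)) stop("`n_layers` must be >= 1", call. = FALSE)
  (1 - ce)^n_layers
}

#' Risk priority number
#'
#' The product O x S x D used to rank failure modes.  Because severity is
#' not independent of occurrence and detectability, very different triplets
#' can yield comparable products (10 x 10 x 2 = 200 vs 5 x 6 x 6.2 = 186).
#'
#' @param o,s,d Occurrence, severity and detectability scores, each in
#'   \[1, 10\] (vectorised; one-decimal consensus values are accepted).
#' @return Numeric RPN.
#' @export
rpn <- function(o, s, d) {
  for (x in list(o, s, d)) {
    if (any(!is.na(x) & (x < 1 | x > 10))) {
      stop("RPN components must lie in [1, 10]", call. = FALSE)
    }
  }
  o * s * d
}

check_count_args <- function(n1, n2) {
  if (any(!is.na(n1) & (n1 < 0 | n1 != floor(n1))) ||
      any(!is.na(n2) & (n2 < 0 | n2 != floor(n2)))) {
    stop("`n1` and `n2` must be non-negative integer counts", call. = FALSE)
  }
  invisible(NULL)
}

count_status <- function(n1, n2) {
  dplyr::case_when(
    n1 == 0           ~ "insufficient_data",
    n2 >= n1          ~ "breakdown",
    TRUE              ~ "ok"
  )
}

#' Estimate occurrence and detectability risk scores per failure mode
#'
#' The end-to-end estimator: from per-FM catch counts at the first and
#' second check layers it computes check efficacy, the true occurrence
#' count, the per-plan occurrence fraction and the all-layer undetected
#' probability, and maps the two probabilities onto the 10-point occurrence
#' and detectability scales.  All downstream quantities use the
#' *continuous* `N0`; rounded values are reported alongside.
#'
#' Failure modes whose estimate is undefined (`n1 == 0`) or broken down
#' (`n2 >= n1`, i.e. the FM was caught at least as often by the second
#' check — a sample-size artefact under the equal-efficacy model) are kept
#' in the output with a `status` flag and `NA` estimates rather than
#' aborting the batch.
#'
#' @param data Data frame with columns `fm_id`, `n1`, `n2`; optional columns
#'   `n_plans`, `n_layers` and `severity` override the arguments row-wise.
#' @param n_plans Number of plans covered by the log (required here or as a
#'   column).
#' @param n_layers Number of QC layers in place (default 2).
#' @param severity Optional severity score(s) in \[1, 10\]; when present the
#'   RPN is reported both with integer O/D (`rpn`) and continuous O/D
#'   (`rpn_continuous`).
#' @param o_table,d_table Occurrence and detectability [scale_table]s.
#' @return A tibble of class `risk_estimates`, one row per input FM, with
#'   columns `fm_id`, `n1`, `n2`, `n_plans`, `n_layers`, `status`, `ce`,
#'   `n0_continuous`, `n0`, `undetected_count`, `occurrence_fraction`,
#'   `undetected_prob`, `o_continuous`, `o_score`, `d_continuous`,
#'   `d_score`, `severity`, `rpn`, `rpn_continuous`.
#' @examples
#' estimate_risk(
#'   data.frame(fm_id = "dose calculation error", n1 = 8, n2 = 2),
#'   n_plans = 2358
#' )
#' @export
estimate_risk <- function(data, n_plans = NULL, n_layers = 2, severity = NULL,
                          o_table = default_scale("occurrence"),
                          d_table = default_scale("detectability")) {
  if (!is.data.frame(data) || !all(c("fm_id", "n1", "n2") %in% names(data))) {
    stop("`data` must have columns fm_id, n1, n2", call. = FALSE)
  }
  assert_scale(o_table, "o_table"); assert_scale(d_table, "d_table")
  out <- tibble::as_tibble(data)
  if (!"n_plans" %in% names(out)) {
    if (is.null(n_plans)) {
      stop("`n_plans` must be supplied (argument or column); it cannot be ",
           "inferred from the catch log", call. = FALSE)
    }
    out$n_plans <- n_plans
  }
  if (!"n_layers" %in% names(out)) out$n_layers <- n_layers
  if (!"severity" %in% names(out)) out$severity <- severity %||% NA_real_
  if (any(out$n_plans < 1)) stop("`n_plans` must be >= 1", call. = FALSE)
  if (any(out$n_layers < 1)) stop("`n_layers` must be >= 1", call. = FALSE)
  check_count_args(out$n1, out$n2)

  occ <- total_occurrences(out$n1, out$n2)
  out$status <- count_status(out$n1, out$n2)
  out$ce <- check_efficacy(out$n1, out$n2)
  out$n0_continuous <- occ$n0_continuous
  out$n0 <- occ$n0
  out$undetected_count <- occ$undetected_count
  out$occurrence_fraction <- out$n0_continuous / out$n_plans
  out$undetected_prob <- undetected_probability(out$ce, out$n_layers)
  out$o_continuous <- prob_to_score(out$occurrence_fraction, o_table)
  out$o_score <- round_half_away(out$o_continuous)
  out$d_continuous <- prob_to_score(out$undetected_prob, d_table)
  out$d_score <- round_half_away(out$d_continuous)
  out$rpn <- ifelse(is.na(out$severity), NA_real_,
                    rpn(out$o_score, out$severity, out$d_score))
  out$rpn_continuous <- ifelse(is.na(out$severity), NA_real_,
                               rpn(out$o_continuous, out$severity,
                                   out$d_continuous))
  flagged <- out$occurrence_fraction
  if (any(!is.na(flagged) & flagged > 1)) {
    warning("estimated N0 exceeds n_plans for some failure modes; ",
            "check that n_plans covers the logging period", call. = FALSE)
  }
  class(out) <- c("risk_estimates", class(tibble::tibble()))
  out
}
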