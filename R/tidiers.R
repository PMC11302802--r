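#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for risk estimates, bootstrap intervals and bias experiments
#'
#' Broom-style accessors: `tidy()` returns the per-row results as a plain
#' tibble, `glance()` a one-row summary.
#'
#' @param x A `risk_estimates`, `rpn_boot`, `validation_report` or
#'   `bias_experiment` object.
#' @param ... Unused.
#' @return A tibble.
#' @name qcrpn-tidiers
NULL

#' @rdname qcrpn-tidiers
#' @export
tidy.risk_estimates <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname qcrpn-tidiers
#' @export
glance.risk_estimates <- function(x, ...) {
  tibble::tibble(
    n_fm = nrow(x),
    n_ok = sum(x$status == "ok"),
    n_breakdown = sum(x$status == "breakdown"),
    n_insufficient = sum(x$status == "insufficient_data"),
    n_plans = if (nrow(x)) max(x$n_plans) else NA_real_,
    median_rpn = stats::median(x$rpn, na.rm = TRUE)
  )
}

#' @rdname qcrpn-tidiers
#' @export
tidy.rpn_boot <- function(x, ...) x$intervals

#' @rdname qcrpn-tidiers
#' @export
glance.rpn_boot <- function(x, ...) {
  tibble::tibble(n_boot = x$n_boot, n_breakdown = x$n_breakdown,
                 level = x$level, indeterminate = x$indeterminate,
                 seed = x$seed)
}

#' @rdname qcrpn-tidiers
#' @export
tidy.validation_report <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname qcrpn-tidiers
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(
    n_fm = nrow(x),
    n_inconsistent = sum(x$verdict == "inconsistent"),
    n_consistent = sum(x$verdict == "consistent"),
    n_indeterminate = sum(x$verdict == "indeterminate")
  )
}

#' @rdname qcrpn-tidiers
#' @export
tidy.bias_experiment <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}
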