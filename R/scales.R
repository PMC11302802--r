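#' TG-100-style occurrence and detectability scale tables
#'
#' A scale table maps the 10-point FMEA scores used for occurrence (O) and
#' detectability (D) to probabilities: for occurrence, the probability that a
#' plan carries the failure mode; for detectability, the probability that the
#' failure mode escapes *all* checks undetected (higher score = harder to
#' detect).  Lookups in both directions are piecewise-linear in probability
#' between integer anchor scores, so continuous scores such as 5.8 can be
#' reported alongside nearest-integer scores.
#'
#' The bundled defaults are anchored at
#'
#' * occurrence:    1:1e-4, 2:2e-4, 3:5e-4, 4:1e-3, 5:2e-3, 6:5e-3,
#'                  7:1e-2, 8:2e-2, 9:5e-2
#' * detectability: 1:1e-4, 2:2e-3, 3:5e-3, 4:1e-2, 5:2e-2, 6:5e-2,
#'                  7:0.10, 8:0.15, 9:0.20
#'
#' The top score is an open-ended category ("more than 5%" occurrence, "more
#' than 20%" undetected); the tables carry a nominal score-10 probability
#' (0.10 occurrence, 0.30 detectability) so that both lookup directions are
#' defined on the whole 1-10 range, and any probability above it clamps to
#' 10.  Clinics holding the exact published anchor values can substitute them
#' via [read_scale_json()].
#'
#' @param kind `"occurrence"` or `"detectability"`.
#' @param anchors Data frame with columns `score` (integers 1-10, each
#'   exactly once) and `probability` (strictly increasing, in (0, 1]).
#'
#' @return A `scale_table`: a tibble of anchors with a `kind` attribute.
#' @examples
#' occ <- default_scale("occurrence")
#' prob_to_score(0.005, occ)   # anchor point -> 6
#' score_to_prob(4.4, occ)     # 0.0014
#' @export
scale_table <- function(kind = c("occurrence", "detectability"), anchors) {
  kind <- match.arg(kind)
  if (!is.data.frame(anchors) ||
      !all(c("score", "probability") %in% names(anchors))) {
    stop("`anchors` must be a data frame with columns `score` and `probability`",
         call. = FALSE)
  }
  anchors <- tibble::as_tibble(anchors[c("score", "probability")])
  anchors <- dplyr::arrange(anchors, .data$score)
  if (!identical(as.integer(anchors$score), 1:10)) {
    stop("scale anchors must cover scores 1..10 exactly once", call. = FALSE)
  }
  p <- anchors$probability
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1) || any(diff(p) <= 0)) {
    stop("anchor probabilities must lie in (0, 1] and strictly increase with score",
         call. = FALSE)
  }
  structure(anchors, kind = kind, class = c("scale_table", class(anchors)))
}

#' @rdname scale_table
#' @export
default_scale <- function(kind = c("occurrence", "detectability")) {
  kind <- match.arg(kind)
  prob <- switch(kind,
    occurrence    = c(1e-4, 2e-4, 5e-4, 1e-3, 2e-3, 5e-3, 1e-2, 2e-2, 5e-2, 0.10),
    detectability = c(1e-4, 2e-3, 5e-3, 1e-2, 2e-2, 5e-2, 0.10, 0.15, 0.20, 0.30)
  )
  scale_table(kind, tibble::tibble(score = 1:10, probability = prob))
}

scale_kind <- function(table) attr(table, "kind", exact = TRUE)

assert_scale <- function(table, arg = "table") {
  if (!inherits(table, "scale_table")) {
    stop("`", arg, "` must be a scale_table (see default_scale())", call. = FALSE)
  }
  invisible(table)
}

#' Convert a probability to a continuous 1-10 scale score
#'
#' Linear interpolation of the score between the two anchor probabilities
#' bracketing `p`.  Probabilities at or below the score-1 anchor clamp to 1;
#' probabilities at or above the score-10 anchor clamp to 10 (the top
#' category is open-ended).
#'
#' @param p Probability (vectorised), each in \[0, 1\].
#' @param table A [scale_table].
#' @return Numeric vector of continuous scores in \[1, 10\].
#' @examples
#' d <- default_scale("detectability")
#' prob_to_score(0.0625, d)  # 6.25
#' prob_to_score(0.62, d)    # clamps to 10
#' @export
prob_to_score <- function(p, table) {
  assert_scale(table)
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  stats::approx(x = table$probability, y = table$score, xout = p,
                method = "linear", rule = 2, ties = "ordered")$y
}

#' Convert a continuous 1-10 scale score to a probability
#'
#' Inverse of [prob_to_score()]: linear interpolation of probability between
#' the bracketing integer anchors, exact at integer scores.
#'
#' @param s Continuous score (vectorised), each in \[1, 10\].
#' @inheritParams prob_to_score
#' @return Numeric vector of probabilities.
#' @examples
#' score_to_prob(4.7, default_scale("detectability"))  # 0.017
#' @export
score_to_prob <- function(s, table) {
  assert_scale(table)
  if (any(!is.na(s) & (s < 1 | s > 10))) {
    stop("scores must lie in [1, 10]", call. = FALSE)
  }
  stats::approx(x = table$score, y = table$probability, xout = s,
                method = "linear", rule = 2, ties = "ordered")$y
}

#' Round a continuous score to the conventional integer score
#'
#' Nearest integer with ties at .5 rounded half away from zero (so 10.67
#' rounds to 11 and 8.5 to 9), matching the convention used when integer
#' scores are quoted next to continuous ones.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Read or write a scale table as JSON
#'
#' The JSON schema is
#' `{"kind": "occurrence"|"detectability", "anchors": [{"score": 1, "probability": 1e-4}, ...]}`,
#' so clinics can substitute the exact published anchor values for the
#' bundled reconstructions.
#'
#' @param path File path.
#' @return `read_scale_json()` returns a [scale_table];
#'   `write_scale_json()` returns `path` invisibly.
#' @export
read_scale_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$kind) || is.null(obj$anchors)) {
    stop("scale JSON must contain `kind` and `anchors`: ", path, call. = FALSE)
  }
  scale_table(obj$kind, tibble::as_tibble(obj$anchors))
}

#' @rdname read_scale_json
#' @param table A [scale_table] to serialise.
#' @export
write_scale_json <- function(table, path) {
  assert_scale(table)
  jsonlite::write_json(
    list(kind = scale_kind(table),
         anchors = data.frame(score = as.integer(table$score),
                              probability = table$probability)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Plot a scale table
#'
#' Shows the anchor points and the piecewise-linear interpolation used for
#' lookups, on a log probability axis.
#'
#' @param table A [scale_table].
#' @return A ggplot object.
#' @export
plot_scale <- function(table) {
  assert_scale(table)
  ggplot2::ggplot(table, ggplot2::aes(x = .data$probability, y = .data$score)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_continuous(breaks = 1:10) +
    ggplot2::labs(x = "probability", y = "score",
                  title = paste(scale_kind(table), "scale")) +
    ggplot2::theme_minimal()
}
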