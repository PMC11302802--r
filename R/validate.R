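#' Expected catch counts under consensus scores
#'
#' Converts consensus (O, D) scores into the catch counts a clinic would
#' expect to record: O maps to a per-plan occurrence probability, D to the
#' probability of escaping all `n_layers` checks, from which the per-check
#' efficacy is recovered as `ce = 1 - p_undetected^(1/n_layers)` (consensus
#' D is read as the undetected probability across *all* existing layers).
#' Then `N0 = p_occ * n_plans`, `E[N1] = N0 * ce`,
#' `E[N2] = (N0 - E[N1]) * ce`.
#'
#' @param consensus Data frame with columns `fm_id`, `o`, `d` (and
#'   optionally `s`), e.g. transcribed published consensus values;
#'   one-decimal scores are interpolated on the scale tables.
#' @inheritParams estimate_risk
#' @return A tibble with columns `fm_id`, `p_occ`, `p_undetected`, `ce`,
#'   `n0`, `expected_n1`, `expected_n2`.
#' @examples
#' expected_counts(data.frame(fm_id = "FM36", o = 5.7, d = 4.7),
#'                 n_plans = 2358)
#' @export
expected_counts <- function(consensus, n_plans, n_layers = 2,
                            o_table = default_scale("occurrence"),
                            d_table = default_scale("detectability")) {
  check_consensus(consensus)
  p_occ <- score_to_prob(consensus$o, o_table)
  p_undet <- score_to_prob(consensus$d, d_table)
  ce <- 1 - p_undet^(1 / n_layers)
  n0 <- p_occ * n_plans
  e1 <- n0 * ce
  tibble::tibble(
    fm_id = consensus$fm_id,
    p_occ = p_occ, p_undetected = p_undet, ce = ce, n0 = n0,
    expected_n1 = e1, expected_n2 = (n0 - e1) * ce
  )
}

check_consensus <- function(consensus) {
  if (!is.data.frame(consensus) ||
      !all(c("fm_id", "o", "d") %in% names(consensus))) {
    stop("`consensus` must have columns fm_id, o, d (optionally s)",
         call. = FALSE)
  }
  for (col in intersect(c("o", "s", "d"), names(consensus))) {
    x <- consensus[[col]]
    if (any(!is.na(x) & (x < 1 | x > 10))) {
      stop("consensus `", col, "` scores must lie in [1, 10]", call. = FALSE)
    }
  }
  invisible(consensus)
}

#' Monte-Carlo tail probability of observed catches under consensus scores
#'
#' Simulates the clinic implied by consensus (O, D) — per-plan Bernoulli
#' occurrence at the O-implied probability, each occurrence caught by any of
#' `n_layers` checks with the D-implied per-check efficacy — and returns the
#' probability that the total catches `N1 + N2` fall at least as far from
#' their expectation as the observed total (two-sided by distance from
#' expectation).  A small value means the recorded counts would have been
#' very unlikely if the consensus scores described this clinic.
#'
#' @param o,d Consensus occurrence and detectability scores in \[1, 10\].
#' @param n1,n2 Observed catch counts.
#' @inheritParams estimate_risk
#' @param n_reps Number of Monte-Carlo replicates (>= 1000).
#' @param seed Integer seed; results are reproducible given the seed and do
#'   not disturb the caller's RNG state.
#' @return A single probability in \[0, 1\].
#' @examples
#' tail_probability(o = 4.4, d = 4.7, n1 = 8, n2 = 2, n_plans = 2358,
#'                  n_reps = 10000, seed = 1)
#' @export
tail_probability <- function(o, d, n1, n2, n_plans, n_layers = 2,
                             o_table = default_scale("occurrence"),
                             d_table = default_scale("detectability"),
                             n_reps = 1e5, seed = 1) {
  if (n_reps < 1000) stop("`n_reps` must be >= 1000", call. = FALSE)
  p_occ <- score_to_prob(o, o_table)
  p_undet <- score_to_prob(d, d_table)
  p_catch <- 1 - p_undet
  expected <- n_plans * p_occ * p_catch
  observed <- n1 + n2
  total <- withr::with_seed(seed, {
    n_occ <- stats::rbinom(n_reps, size = n_plans, prob = p_occ)
    stats::rbinom(n_reps, size = n_occ, prob = p_catch)
  })
  mean(abs(total - expected) >= abs(observed - expected))
}

#' Ratio of estimated to consensus-implied occurrence counts
#'
#' How many times more (or fewer) occurrences the clinic's estimate implies
#' than a consensus O score would predict over the same number of plans:
#' `n0_continuous / (score_to_prob(o) * n_plans)`.  A value near 3 reads as
#' "the consensus score predicts three-fold fewer recorded instances".
#'
#' @inheritParams tail_probability
#' @return A positive ratio (`NA` if the estimate breaks down).
#' @examples
#' occurrence_ratio(o = 4.4, n1 = 8, n2 = 2, n_plans = 2358)  # ~3.2
#' @export
occurrence_ratio <- function(o, n1, n2, n_plans,
                             o_table = default_scale("occurrence")) {
  n0 <- total_occurrences(n1, n2)$n0_continuous
  n0 / (score_to_prob(o, o_table) * n_plans)
}

#' Parametric bootstrap intervals for CE, N0, O and D
#'
#' Resamples the fitted clinic: occurrences per plan at the fitted per-plan
#' probability, then catches at each of two checks at the fitted efficacy,
#' re-estimating all quantities on each replicate and taking percentile
#' intervals.  Replicates where the estimator breaks down (no first-check
#' catches, or second-check catches >= first-check) are counted and
#' reported, never silently dropped; if more than half break down the
#' result is flagged indeterminate.
#'
#' @inheritParams tail_probability
#' @param n_boot Number of bootstrap replicates (>= 200).
#' @param level Confidence level (default 0.95).
#' @return An object of class `rpn_boot`: a list with `intervals` (tibble of
#'   `quantity`, `estimate`, `lower`, `upper`), `n_boot`, `n_breakdown`,
#'   `level`, `seed` and `indeterminate`.  [tidy()][generics::tidy] returns
#'   the intervals tibble.
#' @examples
#' bootstrap_intervals(n1 = 8, n2 = 2, n_plans = 2358, n_boot = 500, seed = 1)
#' @export
bootstrap_intervals <- function(n1, n2, n_plans, n_layers = 2,
                                n_boot = 2000, level = 0.95, seed = 1,
                                o_table = default_scale("occurrence"),
                                d_table = default_scale("detectability")) {
  if (n_boot < 200) stop("`n_boot` must be >= 200", call. = FALSE)
  fit <- estimate_risk(
    tibble::tibble(fm_id = "fit", n1 = n1, n2 = n2),
    n_plans = n_plans, n_layers = n_layers,
    o_table = o_table, d_table = d_table
  )
  if (fit$status != "ok") {
    stop("point estimate is not estimable (status: ", fit$status, ")",
         call. = FALSE)
  }
  reps <- withr::with_seed(seed, {
    occ <- stats::rbinom(n_boot, size = n_plans, prob = fit$occurrence_fraction)
    b1 <- stats::rbinom(n_boot, size = occ, prob = fit$ce)
    b2 <- stats::rbinom(n_boot, size = occ - b1, prob = fit$ce)
    tibble::tibble(n1 = b1, n2 = b2)
  })
  ok <- reps$n1 > 0 & reps$n2 < reps$n1
  n_breakdown <- sum(!ok)
  ce_b <- 1 - reps$n2[ok] / reps$n1[ok]
  n0_b <- reps$n1[ok]^2 / (reps$n1[ok] - reps$n2[ok])
  o_b <- prob_to_score(pmin(n0_b / n_plans, 1), o_table)
  d_b <- prob_to_score((1 - ce_b)^n_layers, d_table)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  pct <- function(x) stats::quantile(x, probs = probs, names = FALSE, type = 7)
  qs <- list(ce = ce_b, n0 = n0_b, o_continuous = o_b, d_continuous = d_b)
  est <- c(fit$ce, fit$n0_continuous, fit$o_continuous, fit$d_continuous)
  ints <- purrr::imap_dfr(qs, function(x, nm) {
    ci <- if (length(x)) pct(x) else c(NA_real_, NA_real_)
    tibble::tibble(quantity = nm, lower = ci[1], upper = ci[2])
  })
  ints$estimate <- est
  structure(
    list(intervals = ints[c("quantity", "estimate", "lower", "upper")],
         n_boot = n_boot, n_breakdown = n_breakdown, level = level,
         seed = seed, indeterminate = n_breakdown > n_boot / 2),
    class = "rpn_boot"
  )
}

#' @export
print.rpn_boot <- function(x, ...) {
  cat(sprintf("Parametric bootstrap (%d replicates, %d breakdown, %.0f%% level%s)\n",
              x$n_boot, x$n_breakdown, 100 * x$level,
              if (x$indeterminate) ", INDETERMINATE" else ""))
  print(x$intervals)
  invisible(x)
}

#' Validate consensus (O, S, D) values against observed catch counts
#'
#' For each failure mode present in both the counts and the consensus
#' table, computes the expected catch counts under the consensus scores,
#' the Monte-Carlo tail probability of the observed total catches, the
#' ratio of estimated to consensus-implied occurrences, and bootstrap
#' intervals for the fitted quantities, and issues a verdict:
#' `"inconsistent"` when the tail probability falls below `alpha`,
#' `"consistent"` otherwise, `"indeterminate"` when the estimator or the
#' bootstrap breaks down.  The paper-style reading: a consensus O that
#' would predict three-fold fewer recorded instances than were actually
#' logged is flagged inconsistent, while a consensus D whose expected
#' counts sit within sampling noise of the observed ones is not.
#'
#' @param counts Data frame with columns `fm_id`, `n1`, `n2` (e.g. from
#'   [aggregate_events()] or [read_check_counts()]).
#' @param consensus Data frame with columns `fm_id`, `o`, `d`, optional `s`.
#' @inheritParams estimate_risk
#' @inheritParams tail_probability
#' @inheritParams bootstrap_intervals
#' @param alpha Tail-probability threshold below which consensus scores are
#'   deemed inconsistent (default 0.05; the judgement is otherwise only
#'   qualitative).
#' @return A tibble of class `validation_report`, one row per FM, with
#'   observed and expected counts, `tail_prob`, `occurrence_ratio`,
#'   bootstrap interval columns (`ce_lower`, `ce_upper`, ..., for ce, n0,
#'   o_continuous, d_continuous) and `verdict`.
#' @export
validate_consensus <- function(counts, consensus, n_plans, n_layers = 2,
                               o_table = default_scale("occurrence"),
                               d_table = default_scale("detectability"),
                               n_reps = 1e5, n_boot = 2000, level = 0.95,
                               alpha = 0.05, seed = 1) {
  check_consensus(consensus)
  fits <- estimate_risk(counts, n_plans = n_plans, n_layers = n_layers,
                        o_table = o_table, d_table = d_table)
  joined <- dplyr::inner_join(
    tibble::as_tibble(fits),
    tibble::as_tibble(consensus)[intersect(names(consensus),
                                           c("fm_id", "o", "s", "d"))],
    by = "fm_id"
  )
  rows <- purrr::pmap_dfr(
    list(seq_len(nrow(joined))),
    function(i) {
      row <- joined[i, ]
      exp <- expected_counts(
        tibble::tibble(fm_id = row$fm_id, o = row$o, d = row$d),
        n_plans = row$n_plans, n_layers = row$n_layers,
        o_table = o_table, d_table = d_table
      )
      sub_seed <- derive_seed(seed, row$fm_id)
      tp <- tail_probability(row$o, row$d, row$n1, row$n2,
                             n_plans = row$n_plans, n_layers = row$n_layers,
                             o_table = o_table, d_table = d_table,
                             n_reps = n_reps, seed = sub_seed)
      orat <- occurrence_ratio(row$o, row$n1, row$n2, row$n_plans, o_table)
      boot_ok <- row$status == "ok"
      boot <- if (boot_ok) {
        bootstrap_intervals(row$n1, row$n2, row$n_plans, row$n_layers,
                            n_boot = n_boot, level = level, seed = sub_seed,
                            o_table = o_table, d_table = d_table)
      }
      verdict <- if (!boot_ok || (boot_ok && boot$indeterminate)) {
        "indeterminate"
      } else if (tp < alpha) "inconsistent" else "consistent"
      ci <- if (boot_ok) {
        ints <- boot$intervals
        stats::setNames(
          as.list(c(rbind(ints$lower, ints$upper))),
          c(rbind(paste0(ints$quantity, "_lower"),
                  paste0(ints$quantity, "_upper")))
        )
      } else list()
      tibble::tibble(
        fm_id = row$fm_id, n1 = row$n1, n2 = row$n2,
        consensus_o = row$o, consensus_d = row$d,
        expected_n1 = exp$expected_n1, expected_n2 = exp$expected_n2,
        tail_prob = tp, occurrence_ratio = orat,
        !!!ci,
        n_breakdown = if (boot_ok) boot$n_breakdown else NA_integer_,
        verdict = verdict
      )
    }
  )
  out <- dplyr::arrange(rows, .data$fm_id)
  class(out) <- c("validation_report", class(tibble::tibble()))
  out
}
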