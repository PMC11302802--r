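# deterministic per-FM substream seed (djb2 string hash folded with the
# global seed, kept inside the 32-bit integer range) so adding a failure
# mode to a configuration does not perturb the draws of the others
derive_seed <- function(seed, fm_id) {
  h <- 5381
  for (b in utf8ToInt(as.character(fm_id))) h <- (h * 33 + b) %% 2147483647
  as.integer((seed + h) %% 2147483647)
}

#' Configure a synthetic clinic-QC simulation
#'
#' Defines the generative model the estimator assumes, plus the two
#' violations worth studying: on each plan every failure mode occurs
#' independently with its per-plan probability; an occurred FM is then
#' passed through the check layers in order, each layer catching it
#' independently with that layer's efficacy *only if all earlier layers
#' missed it*; a caught FM is actually logged with probability `p_record`
#' (under-reporting; an unrecorded catch is lost entirely, not deferred).
#' Unequal `layer_efficacies` model a second check performed less
#' rigorously than the first.
#'
#' @param n_plans Number of plans to simulate.
#' @param fm Data frame with columns `fm_id`, `p_occ` (per-plan occurrence
#'   probability) and optional `severity`.
#' @param layer_efficacies Numeric vector of per-layer catch probabilities,
#'   one per QC layer.
#' @param p_record Probability a caught FM is actually logged (default 1).
#' @param seed Integer seed; per-FM substreams are derived from it so the
#'   event list is bit-reproducible.
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(2358, data.frame(fm_id = "FM36", p_occ = 0.005),
#'                   layer_efficacies = c(0.75, 0.75), seed = 42)
#' @export
sim_config <- function(n_plans, fm, layer_efficacies = c(0.75, 0.75),
                       p_record = 1, seed = 1) {
  if (!is.data.frame(fm) || !all(c("fm_id", "p_occ") %in% names(fm))) {
    stop("`fm` must have columns fm_id and p_occ", call. = FALSE)
  }
  fm <- tibble::as_tibble(fm)
  if (!"severity" %in% names(fm)) fm$severity <- NA_real_
  probs <- c(fm$p_occ, layer_efficacies, p_record)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (length(layer_efficacies) < 1) stop("need at least one QC layer", call. = FALSE)
  if (n_plans < 1) stop("`n_plans` must be >= 1", call. = FALSE)
  if (anyDuplicated(fm$fm_id)) stop("duplicate fm_id in `fm`", call. = FALSE)
  structure(
    list(n_plans = as.integer(n_plans), fm = fm,
         layer_efficacies = layer_efficacies,
         n_layers = length(layer_efficacies),
         p_record = p_record, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a clinic's QC catch log with known truth
#'
#' Runs the generative model of [sim_config()] and returns both the event
#' log a clinic would (partially) observe and the full truth needed for
#' parameter-recovery and bias experiments.
#'
#' @param config A [sim_config()].
#' @return An object of class `clinic_sim`: a list with
#'   * `events` — tibble of one row per *occurred* FM instance: `plan_id`,
#'     `fm_id`, `layer_caught` (1-based; `NA` if it escaped every layer) and
#'     `recorded` (whether the catch was actually logged; always `FALSE`
#'     for undetected instances);
#'   * `truth` — per-FM tibble with true `n0`, `n_undetected`, `n_recorded`;
#'   * `layer_catches` — per-FM, per-layer true catch counts;
#'   * `config`.
#' @examples
#' sim <- simulate_clinic(sim_config(1000,
#'   data.frame(fm_id = "FM36", p_occ = 0.01), seed = 7))
#' aggregate_events(sim$events, n_plans = 1000)
#' @export
simulate_clinic <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  eff <- config$layer_efficacies
  n_layers <- config$n_layers
  per_fm <- purrr::map(seq_len(nrow(config$fm)), function(i) {
    fm_id <- config$fm$fm_id[[i]]
    p_occ <- config$fm$p_occ[[i]]
    withr::with_seed(derive_seed(config$seed, fm_id), {
      occurred <- which(stats::runif(config$n_plans) < p_occ)
      n_occ <- length(occurred)
      if (n_occ == 0) {
        return(list(events = NULL,
                    truth = tibble::tibble(fm_id = fm_id, n0 = 0L,
                                           n_undetected = 0L, n_recorded = 0L),
                    layers = tibble::tibble(fm_id = fm_id,
                                            layer = seq_len(n_layers),
                                            n_caught = 0L)))
      }
      # layer j is attempted only if layers 1..j-1 missed
      u <- matrix(stats::runif(n_occ * n_layers), nrow = n_occ)
      hit <- sweep(u, 2, eff, `<`)
      layer_caught <- apply(hit, 1, function(h) {
        j <- which(h)[1]
        if (is.na(j)) NA_integer_ else as.integer(j)
      })
      caught <- !is.na(layer_caught)
      recorded <- rep(FALSE, n_occ)
      recorded[caught] <- stats::runif(sum(caught)) < config$p_record
      events <- tibble::tibble(
        plan_id = occurred, fm_id = fm_id,
        layer_caught = layer_caught, recorded = recorded
      )
      list(
        events = events,
        truth = tibble::tibble(fm_id = fm_id, n0 = n_occ,
                               n_undetected = sum(!caught),
                               n_recorded = sum(recorded)),
        layers = tibble::tibble(
          fm_id = fm_id, layer = seq_len(n_layers),
          n_caught = vapply(seq_len(n_layers),
                            function(j) sum(layer_caught == j, na.rm = TRUE),
                            integer(1))
        )
      )
    })
  })
  structure(
    list(
      events = dplyr::bind_rows(purrr::map(per_fm, "events")),
      truth = dplyr::bind_rows(purrr::map(per_fm, "truth")),
      layer_catches = dplyr::bind_rows(purrr::map(per_fm, "layers")),
      config = config
    ),
    class = "clinic_sim"
  )
}

#' @export
print.clinic_sim <- function(x, ...) {
  cat(sprintf("Simulated clinic: %d plans, %d FMs, %d layers, seed %d\n",
              x$config$n_plans, nrow(x$config$fm), x$config$n_layers,
              x$config$seed))
  print(x$truth)
  invisible(x)
}

#' Aggregate an event log into per-FM two-layer catch counts
#'
#' Counts *recorded* catches at layer 1 (`n1`) and layer 2 (`n2`) per
#' failure mode — the observable quantities of a real log.  Undetected and
#' unrecorded instances contribute nothing (they are unobservable).
#'
#' @param events Tibble with columns `fm_id`, `layer_caught` and optionally
#'   `recorded` (assumed `TRUE` when absent, as in a real log read with
#'   [read_event_log()]).
#' @param n_plans Number of plans the log covers (must be supplied
#'   externally).
#' @param n_layers Number of QC layers in place (default 2); events
#'   referencing higher layers are an error.
#' @return Tibble with columns `fm_id`, `n1`, `n2`, `n_plans`, `n_layers`,
#'   one row per FM appearing in the log, sorted by `fm_id`.
#' @export
aggregate_events <- function(events, n_plans, n_layers = 2) {
  events <- tibble::as_tibble(events)
  if (!all(c("fm_id", "layer_caught") %in% names(events))) {
    stop("`events` must have columns fm_id and layer_caught", call. = FALSE)
  }
  if (!"recorded" %in% names(events)) events$recorded <- TRUE
  bad <- which(!is.na(events$layer_caught) & events$layer_caught > n_layers)
  if (length(bad)) {
    stop("events reference layers beyond n_layers = ", n_layers,
         " at rows: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  obs <- dplyr::filter(events, .data$recorded, !is.na(.data$layer_caught))
  out <- obs |>
    dplyr::group_by(.data$fm_id) |>
    dplyr::summarise(n1 = sum(.data$layer_caught == 1L),
                     n2 = sum(.data$layer_caught == 2L),
                     .groups = "drop") |>
    dplyr::arrange(.data$fm_id)
  out$n_plans <- n_plans
  out$n_layers <- n_layers
  out
}

#' Bias experiment: estimator behaviour when its assumptions are violated
#'
#' Repeatedly simulates clinics over a grid of scenarios, estimates CE, N0
#' and the undetected probability from the simulated logs, and compares
#' Monte-Carlo mean estimates with the model truth.  Designed to reproduce
#' the two documented violations: a weaker second check (both occurrence
#' and undetected probability are underestimated, because
#' `1 - N2/N1` then overstates the efficacy of the layers as a whole) and
#' under-reporting (occurrence underestimated in proportion to the
#' recording rate, CE unbiased, since thinning scales N1 and N2 equally).
#'
#' @param scenarios Data frame with columns `scenario` (label), `n_plans`,
#'   `p_occ`, `efficacies` (list-column of per-layer efficacy vectors) and
#'   optionally `p_record` (default 1).
#' @param n_reps Simulated clinics per scenario (>= 100).
#' @param seed Integer seed.
#' @return A tibble of class `bias_experiment`, one row per scenario, with
#'   truth (`n0_true` = `p_occ * n_plans`, `undetected_prob_true`,
#'   `ce_implied` = efficacy of the first layer), Monte-Carlo means
#'   (`ce_hat`, `n0_hat`, `undetected_prob_hat`), biases and the number of
#'   breakdown replicates.
#' @export
bias_experiment <- function(scenarios, n_reps = 100, seed = 1) {
  if (n_reps < 100) stop("`n_reps` must be >= 100", call. = FALSE)
  scenarios <- tibble::as_tibble(scenarios)
  if (!"p_record" %in% names(scenarios)) scenarios$p_record <- 1
  out <- purrr::pmap_dfr(
    list(seq_len(nrow(scenarios))),
    function(k) {
      sc <- scenarios[k, ]
      eff <- sc$efficacies[[1]]
      n_layers <- length(eff)
      rep_seed <- derive_seed(seed, sc$scenario)
      ests <- purrr::map_dfr(seq_len(n_reps), function(r) {
        cfg <- sim_config(sc$n_plans,
                          tibble::tibble(fm_id = "fm", p_occ = sc$p_occ),
                          layer_efficacies = eff, p_record = sc$p_record,
                          seed = (rep_seed + r) %% 2147483647)
        counts <- aggregate_events(simulate_clinic(cfg)$events,
                                   n_plans = sc$n_plans, n_layers = n_layers)
        if (nrow(counts) == 0 || counts$n1 == 0 || counts$n2 >= counts$n1) {
          return(tibble::tibble(ce = NA_real_, n0 = NA_real_, up = NA_real_))
        }
        ce <- 1 - counts$n2 / counts$n1
        tibble::tibble(ce = ce,
                       n0 = counts$n1^2 / (counts$n1 - counts$n2),
                       up = (1 - ce)^n_layers)
      })
      ok <- !is.na(ests$ce)
      truth_up <- prod(1 - eff)
      tibble::tibble(
        scenario = sc$scenario, n_plans = sc$n_plans, p_occ = sc$p_occ,
        p_record = sc$p_record, n_layers = n_layers,
        n0_true = sc$p_occ * sc$n_plans,
        undetected_prob_true = truth_up,
        ce_hat = mean(ests$ce[ok]), n0_hat = mean(ests$n0[ok]),
        undetected_prob_hat = mean(ests$up[ok]),
        n0_bias = mean(ests$n0[ok]) - sc$p_occ * sc$n_plans,
        undetected_prob_bias = mean(ests$up[ok]) - truth_up,
        n_breakdown = sum(!ok), n_reps = n_reps
      )
    }
  )
  class(out) <- c("bias_experiment", class(tibble::tibble()))
  out
}
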