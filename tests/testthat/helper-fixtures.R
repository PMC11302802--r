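# the dose-calculation-error clinic log: caught 8 times at initial chart
# check, 2 times at first weekly check, over 2358 chart-checked plans
dose_calc_counts <- function() {
  tibble::tibble(fm_id = "FM36_dose_calc", n1 = 8L, n2 = 2L)
}

dose_calc_plans <- 2358L

occ_table <- default_scale("occurrence")
det_table <- default_scale("detectability")

# build an event-log CSV on disk from (fm_id, layer) repetition counts
write_fixture_log <- function(spec, path = tempfile(fileext = ".csv")) {
  rows <- purrr::pmap_dfr(spec, function(fm_id, layer, times) {
    tibble::tibble(plan_id = seq_len(times), fm_id = fm_id, check_layer = layer)
  })
  # plan ids must be unique per (plan, fm): offset layers
  rows <- dplyr::group_by(rows, fm_id)
  rows <- dplyr::mutate(rows, plan_id = dplyr::row_number())
  rows <- dplyr::ungroup(rows)
  readr::write_csv(rows, path)
  path
}
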