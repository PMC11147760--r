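#' Elimination efficiency of a killing assay
#'
#' `EE% = (1 - count_with_t / count_alone) * 100`: percent reduction of
#' target cells co-cultured with effector T cells relative to targets
#' cultured alone. Negative values (target outgrowth in co-culture) are
#' permitted and flagged by the caller-facing summaries; EE can never exceed
#' 100.
#'
#' @param count_with_t Target cell count after co-culture (>= 0); vectorised.
#' @param count_alone Target cell count cultured alone (> 0); vectorised.
#' @return Numeric EE percentages.
#' @examples
#' elimination_efficiency(250, 1000)  # 75
#' @export
elimination_efficiency <- function(count_with_t, count_alone) {
  if (any(count_alone <= 0))
    abort("count_alone must be positive", class = "amlprog_zero_alone")
  assert_that(all(count_with_t >= 0), "count_with_t must be nonnegative")
  (1 - count_with_t / count_alone) * 100
}

#' Classify killing sensitivity from elimination efficiency
#'
#' Strict cutoffs: EE above `sens_cut` (default 50) is sensitive, EE below
#' `res_cut` (default 25) resistant, anything else (including the boundary
#' values themselves) indeterminate.
#'
#' @param ee_percent Numeric EE values.
#' @param sens_cut,res_cut Strict thresholds; `res_cut < sens_cut` required.
#' @return Character vector in `{"sensitive", "resistant", "indeterminate"}`.
#' @examples
#' classify_sensitivity(c(75, 25, 10))
#' @export
classify_sensitivity <- function(ee_percent, sens_cut = 50, res_cut = 25) {
  assert_that(res_cut < sens_cut, "res_cut must be below sens_cut")
  dplyr::case_when(ee_percent > sens_cut ~ "sensitive",
                   ee_percent < res_cut ~ "resistant",
                   TRUE ~ "indeterminate")
}

#' Summarise killing records across effector donors
#'
#' Median EE and interquartile range per target across replicate effector
#' donors; the sensitivity class is assigned from the median EE.
#'
#' @param records Tibble with `target_id`, `donor_id`, and either
#'   `ee_percent` or raw `count_with_t` + `count_alone` columns.
#' @param sens_cut,res_cut Passed to [classify_sensitivity()].
#' @return Tibble `target_id`, `n_donors`, `median_ee`, `iqr_ee`, `class`,
#'   `any_negative`.
#' @export
summarize_replicates <- function(records, sens_cut = 50, res_cut = 25) {
  records <- as_tibble(records)
  if (!"ee_percent" %in% names(records)) {
    assert_that(all(c("count_with_t", "count_alone") %in% names(records)),
                "need ee_percent or count columns")
    records$ee_percent <- elimination_efficiency(records$count_with_t,
                                                 records$count_alone)
  }
  assert_that(nrow(records) >= 1, "need at least one record")
  records |>
    group_by(.data$target_id) |>
    summarise(n_donors = dplyr::n_distinct(.data$donor_id),
              median_ee = median(.data$ee_percent),
              iqr_ee = IQR(.data$ee_percent),
              any_negative = any(.data$ee_percent < 0),
              .groups = "drop") |>
    mutate(class = classify_sensitivity(.data$median_ee, sens_cut, res_cut))
}

#' Read a killing-assay CSV
#'
#' Columns: `target_id`, `donor_id`, `count_with_t`, `count_alone`.
#'
#' @param path CSV path.
#' @return Tibble with computed `ee_percent` and `class` per record.
#' @export
read_killing_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  assert_that(all(c("target_id", "donor_id", "count_with_t",
                    "count_alone") %in% names(df)),
              "killing CSV must have target_id, donor_id, count columns")
  df |>
    mutate(ee_percent = elimination_efficiency(.data$count_with_t,
                                               .data$count_alone),
           class = classify_sensitivity(.data$ee_percent))
}
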