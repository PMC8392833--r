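#' Linkage-map summary statistics
#'
#' Per-linkage-group marker counts, map length, average adjacent-marker
#' distance, and maximum gap, plus a `Total` row. The average-distance
#' convention is **length / marker count** (not length / (count - 1)); this
#' is the convention under which published per-group averages for two-way
#' pseudo-testcross conifer maps reproduce (e.g. 154.4 cM / 42 markers =
#' 3.7, 1986.2 / 486 = 4.1 after 1-decimal rounding). Full precision is
#' retained in `avg_dist_cm`; `avg_dist_display` applies half-up 1-decimal
#' rounding for table display.
#'
#' @param map Map tibble (`marker`, `lg`, `pos_cm`).
#' @return Tibble with columns `lg` (integer, or `"Total"`), `n_markers`,
#'   `length_cm`, `avg_dist_cm`, `avg_dist_display`, `max_gap_cm`,
#'   `single_marker` (flag: gap undefined, reported as 0).
#' @export
summarize_map <- function(map) {
  check_map(map)
  per_lg <- map |>
    dplyr::group_by(.data$lg) |>
    dplyr::arrange(.data$pos_cm, .by_group = TRUE) |>
    dplyr::summarise(
      n_markers = dplyr::n(),
      length_cm = max(.data$pos_cm) - min(.data$pos_cm),
      max_gap_cm = if (dplyr::n() > 1) max(diff(.data$pos_cm)) else 0,
      single_marker = dplyr::n() == 1,
      .groups = "drop"
    ) |>
    dplyr::mutate(lg = as.character(.data$lg))
  total <- tibble::tibble(
    lg = "Total",
    n_markers = sum(per_lg$n_markers),
    length_cm = sum(per_lg$length_cm),
    max_gap_cm = max(per_lg$max_gap_cm),
    single_marker = FALSE
  )
  dplyr::bind_rows(per_lg, total) |>
    dplyr::mutate(
      avg_dist_cm = .data$length_cm / .data$n_markers,
      avg_dist_display = round_half_up(.data$avg_dist_cm, 1)
    ) |>
    dplyr::select("lg", "n_markers", "length_cm", "avg_dist_cm",
                  "avg_dist_display", "max_gap_cm", "single_marker")
}

#' Recompute average spacing from a published map table
#'
#' Applies the length/count spacing convention with half-up 1-decimal
#' rounding to a table of per-linkage-group marker counts and lengths, for
#' checking a printed average-distance column.
#'
#' @param tbl Data frame with columns `n_markers` and `length_cm`.
#' @return The input with a column `avg_recomputed` appended.
#' @export
recompute_avg_spacing <- function(tbl) {
  stop_if_not(all(c("n_markers", "length_cm") %in% names(tbl)),
              "table must have n_markers and length_cm columns")
  dplyr::mutate(tibble::as_tibble(tbl),
                avg_recomputed = round_half_up(.data$length_cm / .data$n_markers, 1))
}
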