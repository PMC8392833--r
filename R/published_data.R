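#' Published Sakhalin fir linkage-map summary table
#'
#' Per-linkage-group marker counts, map lengths (cM), printed average
#' adjacent-marker distances, and maximum gaps for the two parental maps
#' (P336, male; P236, female) of a published Sakhalin fir
#' (*Abies sachalinensis*) high x low altitude full-sib cross of 252
#' progeny, built from aa x ab and ab x aa pseudo-testcross ddRAD markers.
#' `Total` rows are the printed totals. Note the printed P236 total length
#' (1932.8) differs from the sum of its printed per-group lengths (1933.1),
#' a rounding artifact of the source table.
#'
#' @return Tibble: `map`, `lg` (`"1"`..`"12"` or `"Total"`), `n_markers`,
#'   `length_cm`, `avg_dist_cm` (printed, 1 decimal), `max_gap_cm`.
#' @export
fir_map_table <- function() {
  p336 <- tibble::tribble(
    ~lg, ~n_markers, ~length_cm, ~avg_dist_cm, ~max_gap_cm,
    "1", 42, 154.4, 3.7, 17.3,
    "2", 30, 174.9, 5.8, 21.8,
    "3", 31, 145.6, 4.7, 17.6,
    "4", 50, 192.9, 3.9, 22.2,
    "5", 28, 128.6, 4.6, 15.8,
    "6", 40, 147.5, 3.7, 29.8,
    "7", 44, 208.1, 4.7, 18.0,
    "8", 45, 162.5, 3.6, 14.1,
    "9", 51, 151.3, 3.0, 10.1,
    "10", 36, 192.6, 5.4, 26.3,
    "11", 45, 151.8, 3.4, 20.9,
    "12", 44, 176.0, 4.0, 27.8,
    "Total", 486, 1986.2, 4.1, 29.8
  )
  p236 <- tibble::tribble(
    ~lg, ~n_markers, ~length_cm, ~avg_dist_cm, ~max_gap_cm,
    "1", 51, 185.0, 3.6, 18.7,
    "2", 45, 189.5, 4.2, 27.3,
    "3", 35, 131.7, 3.8, 13.7,
    "4", 44, 180.7, 4.1, 19.9,
    "5", 31, 126.6, 4.1, 17.4,
    "6", 39, 141.3, 3.6, 22.2,
    "7", 54, 180.1, 3.3, 18.5,
    "8", 43, 185.8, 4.3, 18.5,
    "9", 43, 155.2, 3.6, 19.0,
    "10", 44, 166.1, 3.8, 18.3,
    "11", 43, 136.4, 3.2, 12.5,
    "12", 44, 154.7, 3.5, 13.7,
    "Total", 516, 1932.8, 3.7, 27.3
  )
  dplyr::bind_rows(
    dplyr::mutate(p336, map = "P336", .before = 1),
    dplyr::mutate(p236, map = "P236", .before = 1)
  )
}

#' Published Sakhalin fir QTL table
#'
#' The QTLs reported for the 15 functional traits of the same study:
#' marker locus, parental map and linkage group, position (cM), significance
#' mark (`**` = 95% credible interval excludes zero, `*` = 80%), and
#' percentage variance explained by single-marker simple regression.
#'
#' @return Tibble: `category`, `trait`, `locus`, `map`, `lg`, `pos_cm`,
#'   `sig`, `pve`.
#' @export
fir_qtl_table <- function() {
  tibble::tribble(
    ~category, ~trait, ~locus, ~map, ~lg, ~pos_cm, ~sig, ~pve,
    "Growth", "D16", "#12865", "P236", 7, 102.8, "*", 6.70,
    "Growth", "H16", "#10164", "P336", 9, 88.7, "*", 4.27,
    "Growth", "H16", "#12865", "P236", 7, 102.8, "**", 9.17,
    "Growth", "H17", "#10758", "P336", 4, 50.7, "*", 4.16,
    "Growth", "H17", "#10541", "P336", 9, 100.9, "*", 4.57,
    "Growth", "H17", "#10758", "P236", 4, 47.5, "*", 4.16,
    "Growth", "H17", "#12865", "P236", 7, 102.8, "**", 7.81,
    "Growth", "CR17", "#6809", "P336", 10, 95.9, "*", 2.62,
    "Growth", "CR17", "#10829", "P336", 10, 144.6, "**", 5.66,
    "Growth", "CR17", "#1970", "P336", 11, 45.2, "*", 5.45,
    "Growth", "CR17", "#10541", "P336", 9, 100.9, "*", 4.28,
    "Growth", "CR17", "#6809", "P236", 10, 81.5, "*", 2.62,
    "Phenology", "Bud_fl", "#6899", "P336", 5, 117.2, "*", 6.07,
    "Phenology", "Bud_fl", "#6899", "P236", 5, 105.4, "*", 6.07,
    "Phenology", "Freez_tol", "#25432", "P336", 5, 123.8, "*", 7.40,
    "Morphology", "Lw_ratio", "#24342", "P336", 3, 60.0, "*", 5.96,
    "Morphology", "Lw_ratio", "#7510", "P336", 6, 82.0, "*", 2.97,
    "Morphology", "Lw_ratio", "#30964", "P236", 7, 5.2, "*", 5.28,
    "Photosynthesis", "NPQ", "#2055", "P336", 7, 92.6, "*", 6.12,
    "Photosynthesis", "NPQ", "#2055", "P236", 7, 80.1, "*", 6.12,
    "Photosynthesis", "Phi_NO", "#2055", "P336", 7, 92.6, "**", 9.32,
    "Photosynthesis", "Phi_NO", "#27288", "P336", 9, 117.1, "**", 7.24,
    "Photosynthesis", "Phi_NO", "#2055", "P236", 7, 80.1, "**", 9.32,
    "Photosynthesis", "Phi_NO", "#27288", "P236", 9, 121.3, "**", 7.24
  )
}

#' Count QTL tiers from a significance column
#'
#' Applies the credible-interval tier convention (`**` = significant at the
#' 95% level, `*` = suggestive at the 80% level) to a reported QTL table.
#'
#' @param qtls Data frame with a `sig` column of `"*"` / `"**"` marks.
#' @return Tibble with columns `tier` and `n`.
#' @export
count_qtl_tiers <- function(qtls) {
  stop_if_not("sig" %in% names(qtls), "table must have a sig column")
  tibble::tibble(
    tier = c("significant", "suggestive"),
    n = c(sum(qtls$sig == "**"), sum(qtls$sig == "*"))
  )
}
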