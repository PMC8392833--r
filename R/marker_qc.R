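#' Drop markers with excess missing data
#'
#' Removes markers whose missing-call fraction is strictly greater than
#' `max_missing` (default 20%). Individuals are never removed.
#'
#' @param geno Genotype tibble (`id` column plus one 0/1/`NA` column per marker).
#' @param max_missing Maximum tolerated missing fraction (default 0.20).
#' @return List with `geno` (filtered tibble) and `report` (tibble: `marker`,
#'   `missing_fraction`, `decision`).
#' @export
filter_missing <- function(geno, max_missing = 0.20) {
  stop_if_not(max_missing >= 0 && max_missing <= 1, "max_missing must be in [0, 1]")
  m <- as_geno_matrix(geno)
  stop_if_not(ncol(m) > 0 && nrow(m) > 0, "genotype matrix is empty")
  frac <- colMeans(is.na(m))
  keep <- frac <= max_missing
  report <- tibble::tibble(
    marker = colnames(m),
    missing_fraction = unname(frac),
    decision = unname(ifelse(keep, "kept", "dropped_missing"))
  )
  list(geno = dplyr::select(geno, dplyr::all_of(c("id", colnames(m)[keep]))),
       report = report)
}

#' Chi-square test of 1:1 Mendelian segregation
#'
#' Pseudo-testcross markers segregate 1:1 in progeny; this tests each marker
#' with a one-degree-of-freedom chi-square without continuity correction,
#' `X^2 = (n0 - n1)^2 / (n0 + n1)`, missing calls excluded. Markers with
#' `p < alpha` are flagged as distorted and dropped.
#'
#' @param geno Genotype tibble of pseudo-testcross (0/1) markers.
#' @param alpha Significance level for segregation distortion (default 0.001).
#' @return List with `geno` (markers passing the test) and `report` (tibble:
#'   `marker`, `n0`, `n1`, `chi_square`, `p_value`, `decision`).
#' @export
segregation_test <- function(geno, alpha = 0.001) {
  m <- as_geno_matrix(geno)
  stop_if_not(ncol(m) > 0, "genotype matrix is empty")
  n1 <- colSums(m == 1, na.rm = TRUE)
  n0 <- colSums(m == 0, na.rm = TRUE)
  tot <- n0 + n1
  chi <- ifelse(tot > 0, (n0 - n1)^2 / tot, NA_real_)
  p <- ifelse(tot > 0, stats::pchisq(chi, df = 1, lower.tail = FALSE), NA_real_)
  decision <- dplyr::case_when(
    tot == 0 ~ "dropped_no_calls",
    p < alpha ~ "dropped_segregation",
    TRUE ~ "kept"
  )
  report <- tibble::tibble(
    marker = colnames(m), n0 = unname(n0), n1 = unname(n1),
    chi_square = unname(chi), p_value = unname(p), decision = decision
  )
  keep <- report$marker[report$decision == "kept"]
  list(geno = dplyr::select(geno, dplyr::all_of(c("id", keep))),
       report = report)
}

#' Split markers into the two parental map sets
#'
#' In a two-way pseudo-testcross design, `AAxAB` markers (heterozygous in
#' the male parent) are informative only for the male parental map and
#' `ABxAA` markers only for the female map; `ABxAB` markers are excluded
#' from both sets.
#'
#' @param geno Genotype tibble.
#' @param map Map tibble with `seg_type` for every marker present in `geno`.
#' @return List with elements `male` and `female`, each a list of `geno` and
#'   `map` restricted to that parent's informative markers, plus `excluded`
#'   (character vector of ABxAB markers left out).
#' @export
split_parental_maps <- function(geno, map) {
  check_map(map)
  stop_if_not("seg_type" %in% names(map), "map must carry a seg_type column")
  markers <- setdiff(names(geno), "id")
  miss <- setdiff(markers, map$marker)
  stop_if_not(length(miss) == 0, "markers missing from map: %s",
              paste(utils::head(miss, 5), collapse = ", "))
  map <- dplyr::filter(map, .data$marker %in% markers)
  bad <- setdiff(unique(map$seg_type), c("AAxAB", "ABxAA", "ABxAB"))
  stop_if_not(length(bad) == 0, "unknown seg_type value(s): %s",
              paste(bad, collapse = ", "))

  pick <- function(type) {
    mk <- map$marker[map$seg_type == type]
    list(geno = dplyr::select(geno, dplyr::all_of(c("id", mk))),
         map = dplyr::filter(map, .data$marker %in% mk))
  }
  male <- pick("AAxAB")
  female <- pick("ABxAA")
  excluded <- map$marker[map$seg_type == "ABxAB"]
  if (nrow(male$map) == 0) warning("male map set is empty", call. = FALSE)
  if (nrow(female$map) == 0) warning("female map set is empty", call. = FALSE)
  if (length(excluded)) {
    message(length(excluded), " ABxAB marker(s) excluded from both parental sets")
  }
  list(male = male, female = female, excluded = excluded)
}

#' Prune collinear markers in close proximity
#'
#' Before the multi-marker scan, one member of each same-linkage-group
#' marker pair closer than `max_dist_cm` (< 1 cM) with absolute pairwise
#' correlation above `min_r` (> 0.7, pairwise-complete 0/1 codes) is
#' removed. Tie-break: the member with more missing data is dropped; if
#' equal, the later marker in map order. Pairs are visited in (lg, position)
#' order so the result does not depend on input column order.
#'
#' @param geno Genotype tibble of 0/1 markers.
#' @param map Map tibble covering all markers in `geno`.
#' @param max_dist_cm Distance threshold, strict (default 1 cM).
#' @param min_r Absolute-correlation threshold, strict (default 0.7).
#' @return List with `geno` (pruned), `report` (per-marker decisions), and
#'   `pairs` (violating pairs inspected: `marker1`, `marker2`, `dist_cm`, `r`,
#'   `dropped`).
#' @export
prune_collinear <- function(geno, map, max_dist_cm = 1.0, min_r = 0.7) {
  check_map(map)
  m <- as_geno_matrix(geno)
  unmapped <- setdiff(colnames(m), map$marker)
  stop_if_not(length(unmapped) == 0, "unmapped marker(s): %s",
              paste(utils::head(unmapped, 5), collapse = ", "))
  map <- map |>
    dplyr::filter(.data$marker %in% colnames(m)) |>
    dplyr::arrange(.data$lg, .data$pos_cm, .data$marker)

  n_miss <- colSums(is.na(m))
  dropped <- character(0)
  pair_rows <- list()

  for (lg in unique(map$lg)) {
    sub <- map[map$lg == lg, ]
    M <- nrow(sub)
    if (M < 2) next
    for (i in seq_len(M - 1)) {
      if (sub$marker[i] %in% dropped) next
      j <- i + 1
      while (j <= M && (sub$pos_cm[j] - sub$pos_cm[i]) < max_dist_cm) {
        if (!(sub$marker[j] %in% dropped)) {
          a <- m[, sub$marker[i]]; b <- m[, sub$marker[j]]
          r <- suppressWarnings(stats::cor(a, b, use = "pairwise.complete.obs"))
          if (!is.na(r) && abs(r) > min_r) {
            mi <- n_miss[sub$marker[i]]; mj <- n_miss[sub$marker[j]]
            victim <- if (mj >= mi) sub$marker[j] else sub$marker[i]
            dropped <- c(dropped, victim)
            pair_rows[[length(pair_rows) + 1]] <- tibble::tibble(
              marker1 = sub$marker[i], marker2 = sub$marker[j],
              dist_cm = sub$pos_cm[j] - sub$pos_cm[i], r = r, dropped = victim
            )
            if (victim == sub$marker[i]) break # i gone; restart from next i
          }
        }
        j <- j + 1
      }
    }
  }

  keep <- setdiff(map$marker, dropped)
  report <- tibble::tibble(
    marker = map$marker,
    decision = ifelse(map$marker %in% dropped, "dropped_collinear", "kept")
  )
  list(
    geno = dplyr::select(geno, dplyr::all_of(c("id", keep))),
    report = report,
    pairs = if (length(pair_rows)) dplyr::bind_rows(pair_rows) else
      tibble::tibble(marker1 = character(), marker2 = character(),
                     dist_cm = numeric(), r = numeric(), dropped = character())
  )
}

#' Full marker QC chain
#'
#' Missingness filter, 1:1 segregation test, and collinearity pruning in the
#' order they are applied before a scan, with a combined per-marker report.
#'
#' @inheritParams filter_missing
#' @inheritParams prune_collinear
#' @param alpha Segregation-test significance level.
#' @return List with `geno`, `map` (restricted), and `report` (one decision
#'   per input marker).
#' @export
qc_markers <- function(geno, map, max_missing = 0.20, alpha = 0.001,
                       max_dist_cm = 1.0, min_r = 0.7) {
  s1 <- filter_missing(geno, max_missing)
  # the 1:1 test applies to pseudo-testcross (two-class) markers only;
  # ABxAB markers pass through here and are excluded at the parental split
  if ("seg_type" %in% names(map)) {
    two_class <- map$marker[map$seg_type %in% c("AAxAB", "ABxAA")]
    testable <- intersect(names(s1$geno), c("id", two_class))
    s2 <- segregation_test(dplyr::select(s1$geno, dplyr::all_of(testable)), alpha)
    passthrough <- setdiff(names(s1$geno), testable)
    s2$geno <- dplyr::bind_cols(s2$geno,
                                dplyr::select(s1$geno, dplyr::all_of(passthrough)))
  } else {
    s2 <- segregation_test(s1$geno, alpha)
  }
  s3 <- prune_collinear(s2$geno, map, max_dist_cm, min_r)
  decisions <- dplyr::bind_rows(
    dplyr::filter(s1$report, .data$decision != "kept"),
    dplyr::filter(s2$report, .data$decision != "kept"),
    dplyr::filter(s3$report, .data$decision != "kept")
  ) |>
    dplyr::select("marker", "decision")
  all_markers <- setdiff(names(geno), "id")
  report <- tibble::tibble(marker = all_markers) |>
    dplyr::left_join(decisions, by = "marker") |>
    dplyr::mutate(decision = dplyr::coalesce(.data$decision, "kept")) |>
    dplyr::left_join(dplyr::select(s1$report, "marker", "missing_fraction"),
                     by = "marker") |>
    dplyr::left_join(dplyr::select(s2$report, "marker", "chi_square", "p_value"),
                     by = "marker")
  kept <- setdiff(names(s3$geno), "id")
  list(geno = s3$geno,
       map = dplyr::filter(map, .data$marker %in% kept),
       report = report)
}
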