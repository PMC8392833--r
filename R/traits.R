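#' Chlorophyll-fluorescence parameters from raw PAM readings
#'
#' Computes the standard pulse-amplitude-modulation fluorometry parameters
#' from dark- and light-adapted readings:
#' \deqn{F_v/F_m = (F_m - F_0)/F_m, \quad
#'       \Phi_{II} = (F_m' - F_s)/F_m', \quad
#'       NPQ = (F_m - F_m')/F_m',}
#' \deqn{\Phi_{NO} = F_s/F_m, \quad
#'       \Phi_{NPQ} = F_s/F_m' - F_s/F_m.}
#' The three quantum yields partition absorbed light energy at photosystem II
#' and satisfy \eqn{\Phi_{II} + \Phi_{NPQ} + \Phi_{NO} = 1} exactly.
#'
#' @param readings Data frame with positive columns `F0` (dark minimal),
#'   `Fm` (dark maximal), `Fm_prime` (light-adapted maximal), and `Fs`
#'   (steady state under actinic light).
#' @return The input tibble with columns `FvFm`, `Phi_II`, `NPQ`, `Phi_NPQ`,
#'   `Phi_NO` appended, plus a logical `flag_ordering` that is `TRUE` for rows
#'   violating the physical ordering `Fm >= Fm_prime >= Fs` or `Fm >= F0`
#'   (flagged, never silently corrected).
#' @export
#' @examples
#' fluorescence_params(data.frame(F0 = 0.2, Fm = 1, Fm_prime = 0.5, Fs = 0.3))
fluorescence_params <- function(readings) {
  stop_if_not(is.data.frame(readings), "readings must be a data frame")
  need <- c("F0", "Fm", "Fm_prime", "Fs")
  miss <- setdiff(need, names(readings))
  stop_if_not(length(miss) == 0, "readings missing column(s): %s",
              paste(miss, collapse = ", "))
  vals <- readings[need]
  stop_if_not(all(vapply(vals, function(v) all(v > 0), logical(1))),
              "all fluorescence readings must be > 0")

  out <- tibble::as_tibble(readings)
  flag <- with(out, Fm < Fm_prime | Fm_prime < Fs | Fm < F0)
  if (any(flag)) {
    warning(sum(flag), " reading(s) violate the ordering Fm >= Fm' >= Fs ",
            "(or Fm >= F0); flagged in 'flag_ordering'", call. = FALSE)
  }
  dplyr::mutate(out,
    FvFm = (.data$Fm - .data$F0) / .data$Fm,
    Phi_II = (.data$Fm_prime - .data$Fs) / .data$Fm_prime,
    NPQ = (.data$Fm - .data$Fm_prime) / .data$Fm_prime,
    Phi_NO = .data$Fs / .data$Fm,
    Phi_NPQ = .data$Fs / .data$Fm_prime - .data$Fs / .data$Fm,
    flag_ordering = flag
  )
}

#' Pairwise trait correlations with p-values
#'
#' Pearson correlations between all trait pairs on pairwise-complete
#' observations, with two-sided p-values from the t distribution
#' (`t = r * sqrt((n-2)/(1-r^2))` on `n-2` df). Constant traits yield `NA`
#' correlations with a warning.
#'
#' @param pheno Data frame with an `id` column and one numeric column per trait.
#' @return Tibble with one row per unordered trait pair: `trait1`, `trait2`,
#'   `r`, `n` (complete pairs), `p_value`; plus an attribute `"method"`
#'   recording the pairwise-complete convention.
#' @export
trait_correlations <- function(pheno) {
  stop_if_not(is.data.frame(pheno), "pheno must be a data frame")
  traits <- setdiff(names(pheno), "id")
  stop_if_not(length(traits) >= 2, "need at least two traits")
  m <- as.matrix(pheno[traits])
  storage.mode(m) <- "double"

  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(!is.na(sds) & sds == 0)) {
    warning("constant trait(s): ", paste(traits[!is.na(sds) & sds == 0],
            collapse = ", "), "; correlations reported as NA", call. = FALSE)
  }

  pairs <- utils::combn(traits, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    x <- m[, pr[1]]; y <- m[, pr[2]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(tibble::tibble(trait1 = pr[1], trait2 = pr[2], r = NA_real_,
                            n = n, p_value = NA_real_))
    }
    r <- stats::cor(x[ok], y[ok])
    p <- if (abs(r) >= 1) 0 else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
    }
    tibble::tibble(trait1 = pr[1], trait2 = pr[2], r = r, n = n, p_value = p)
  })
  attr(out, "method") <- "pearson, pairwise-complete observations"
  out
}

#' Trait correlation matrix
#'
#' Square symmetric matrix form of [trait_correlations()] (unit diagonal).
#'
#' @inheritParams trait_correlations
#' @return Numeric matrix, traits x traits.
#' @export
trait_correlation_matrix <- function(pheno) {
  traits <- setdiff(names(pheno), "id")
  cc <- trait_correlations(pheno)
  m <- diag(1, length(traits))
  dimnames(m) <- list(traits, traits)
  for (k in seq_len(nrow(cc))) {
    m[cc$trait1[k], cc$trait2[k]] <- m[cc$trait2[k], cc$trait1[k]] <- cc$r[k]
  }
  m
}

#' Trait correlation network edge list
#'
#' Thresholds the pairwise correlations at a minimum absolute coefficient to
#' produce the edge list of the trait relationship network (layout is
#' presentation and left to plotting).
#'
#' @param corr Either the tibble returned by [trait_correlations()] or a
#'   square correlation matrix.
#' @param min_abs_r Minimum `|r|` for an edge (default 0.1).
#' @return Tibble with columns `trait1`, `trait2`, `r` for pairs with
#'   `|r| >= min_abs_r`.
#' @export
correlation_network <- function(corr, min_abs_r = 0.1) {
  stop_if_not(min_abs_r >= 0 && min_abs_r <= 1, "min_abs_r must be in [0, 1]")
  if (is.matrix(corr)) {
    traits <- colnames(corr)
    pairs <- utils::combn(seq_along(traits), 2)
    corr <- tibble::tibble(
      trait1 = traits[pairs[1, ]], trait2 = traits[pairs[2, ]],
      r = corr[t(pairs)]
    )
  }
  dplyr::filter(corr, !is.na(.data$r), abs(.data$r) >= min_abs_r) |>
    dplyr::select("trait1", "trait2", "r")
}

#' Plot a trait correlation network
#'
#' Simple circular-layout ggplot of the thresholded trait network; edge
#' width scales with `|r|`, colour with the sign.
#'
#' @param edges Edge tibble from [correlation_network()].
#' @return A ggplot object.
#' @export
plot_trait_network <- function(edges) {
  traits <- sort(unique(c(edges$trait1, edges$trait2)))
  th <- seq(0, 2 * pi, length.out = length(traits) + 1)[seq_along(traits)]
  nodes <- tibble::tibble(trait = traits, x = cos(th), y = sin(th))
  seg <- edges |>
    dplyr::left_join(nodes, by = c(trait1 = "trait")) |>
    dplyr::rename(x1 = "x", y1 = "y") |>
    dplyr::left_join(nodes, by = c(trait2 = "trait")) |>
    dplyr::rename(x2 = "x", y2 = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2, yend = .data$y2,
                   linewidth = abs(.data$r), colour = .data$r > 0),
      alpha = 0.7, show.legend = c(linewidth = FALSE, colour = TRUE)
    ) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y), size = 2) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x * 1.12, .data$y * 1.12,
                                    label = .data$trait), size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b"),
                                 labels = c(`TRUE` = "r > 0", `FALSE` = "r < 0"),
                                 name = NULL) +
    ggplot2::scale_linewidth(range = c(0.2, 1.6)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
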