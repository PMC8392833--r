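#' Map-distance to recombination fraction
#'
#' Converts a genetic distance in centimorgans into a recombination fraction
#' under the Haldane (no interference) or Kosambi map function.
#'
#' @param distance_cm Genetic distance(s) in cM, non-negative.
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
#' @examples
#' recomb_fraction(10)              # 0.0906...
#' recomb_fraction(10, "kosambi")   # 0.0987...
recomb_fraction <- function(distance_cm, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  stop_if_not(all(is.finite(distance_cm)) && all(distance_cm >= 0),
              "map distances must be finite and >= 0 cM (got negative or non-finite values)")
  d <- distance_cm / 100
  switch(map_function,
    haldane = (1 - exp(-2 * d)) / 2,
    kosambi = tanh(2 * d) / 2
  )
}

#' Simulate a two-way pseudo-testcross genetic map
#'
#' Lays out markers on `n_lg` linkage groups with exponentially distributed
#' adjacent spacings (mean `mean_gap_cm`), and assigns each marker a CP
#' segregation type: `AAxAB` (heterozygous in the male parent, informative
#' for the male map), `ABxAA` (female-informative), or `ABxAB` (both parents
#' heterozygous; generated but excluded from both parental map sets by
#' [split_parental_maps()], mirroring common practice for two-way
#' pseudo-testcross maps).
#'
#' Defaults emulate a conifer full-sib cross mapped with roughly 480-520
#' markers per parental map over 12 linkage groups at ~4 cM average spacing:
#' 84 markers per group in a shared frame (~2 cM combined spacing) with the
#' two informative types in equal proportion.
#'
#' @param n_lg Number of linkage groups.
#' @param markers_per_lg Markers per linkage group (all types combined).
#' @param mean_gap_cm Mean adjacent-marker gap in the combined frame, cM.
#' @param p_seg Named probabilities for types `AAxAB`, `ABxAA`, `ABxAB`.
#' @param seed Integer seed; the map is reproducible from it.
#' @return A tibble with columns `marker`, `lg`, `pos_cm`, `seg_type`.
#' @export
sim_genetic_map <- function(n_lg = 12, markers_per_lg = 84, mean_gap_cm = 2,
                            p_seg = c(AAxAB = 0.475, ABxAA = 0.475, ABxAB = 0.05),
                            seed = 1L) {
  stop_if_not(n_lg >= 1 && markers_per_lg >= 1, "need at least one LG and one marker")
  stop_if_not(all(p_seg >= 0) && abs(sum(p_seg) - 1) < 1e-8,
              "p_seg must be non-negative and sum to 1")
  stop_if_not(all(names(p_seg) %in% c("AAxAB", "ABxAA", "ABxAB")),
              "p_seg names must be AAxAB, ABxAA, ABxAB")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  purrr::map_dfr(seq_len(n_lg), function(lg) {
    gaps <- stats::rexp(markers_per_lg - 1, rate = 1 / mean_gap_cm)
    pos <- c(0, cumsum(gaps))
    types <- sample(names(p_seg), markers_per_lg, replace = TRUE, prob = p_seg)
    tibble::tibble(
      marker = sprintf("M%02d_%03d", lg, seq_len(markers_per_lg)),
      lg = lg,
      pos_cm = pos,
      seg_type = types
    )
  })
}

# Inheritance matrix for one parent on one LG: n x m of {0,1}, Markov chain
# along the chromosome with switch probability r between adjacent markers.
simulate_inheritance <- function(n, r_adj) {
  m <- length(r_adj) + 1L
  h <- matrix(0L, n, m)
  h[, 1] <- stats::rbinom(n, 1, 0.5)
  if (m > 1) for (k in 2:m) {
    sw <- stats::rbinom(n, 1, r_adj[k - 1])
    h[, k] <- bitwXor(h[, k - 1], sw)
  }
  h
}

#' Simulate a full-sib outbred cross
#'
#' Generates progeny genotype calls for a two-way pseudo-testcross design.
#' Within each linkage group, each parent transmits a gamete produced by
#' sequential transmission with crossover probability
#' `recomb_fraction(gap, map_function)` between adjacent markers (no
#' crossover interference under the default Haldane function). A marker's
#' call records the allele transmitted by its heterozygous parent: `0`/`1`
#' are the two progeny classes, expected to segregate 1:1. `ABxAB` markers
#' are coded 0/1/2 (number of second-haplotype alleles received); they are
#' not pseudo-testcross markers and are excluded from parental analysis sets
#' downstream.
#'
#' Symmetric genotyping errors (class flips) and missingness are applied
#' independently at the configured rates after transmission; `ABxAB` errors
#' re-draw one transmitted allele.
#'
#' @param map Genetic map tibble from [sim_genetic_map()] (columns `marker`,
#'   `lg`, `pos_cm`, `seg_type`).
#' @param n_progeny Number of F1 progeny (default 252).
#' @param missing_rate Per-call missing probability in `[0,1]` (default 0.05).
#' @param error_rate Per-call symmetric genotyping-error probability (default 0.005).
#' @param map_function Map function used for crossover probabilities.
#' @param seed Integer seed; output is byte-identical for identical inputs.
#' @return A list of class `sim_cross` with elements `geno` (observed calls,
#'   tibble `id` x markers, `NA` = missing), `geno_true` (error- and
#'   missingness-free calls used to generate phenotypes), `map`, and `config`.
#' @export
sim_cross <- function(map, n_progeny = 252, missing_rate = 0.05,
                      error_rate = 0.005, map_function = c("haldane", "kosambi"),
                      seed = 1L) {
  check_map(map)
  stop_if_not("seg_type" %in% names(map), "map must carry a seg_type column")
  stop_if_not(nrow(map) >= 1, "map must be non-empty")
  stop_if_not(n_progeny >= 2, "need at least two progeny")
  stop_if_not(missing_rate >= 0 && missing_rate <= 1 &&
                error_rate >= 0 && error_rate <= 1,
              "missing_rate and error_rate must lie in [0, 1]")
  map_function <- match.arg(map_function)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)

  map <- dplyr::arrange(map, .data$lg, .data$pos_cm)
  ids <- sprintf("ind%04d", seq_len(n_progeny))
  calls <- matrix(NA_real_, n_progeny, nrow(map),
                  dimnames = list(ids, map$marker))

  for (lg in unique(map$lg)) {
    idx <- which(map$lg == lg)
    r_adj <- recomb_fraction(diff(map$pos_cm[idx]), map_function)
    h_f <- simulate_inheritance(n_progeny, r_adj) # female-parent gamete
    h_m <- simulate_inheritance(n_progeny, r_adj) # male-parent gamete
    st <- map$seg_type[idx]
    for (k in seq_along(idx)) {
      calls[, idx[k]] <- switch(st[k],
        AAxAB = h_m[, k],
        ABxAA = h_f[, k],
        ABxAB = h_f[, k] + h_m[, k],
        stop("unknown seg_type: ", st[k])
      )
    }
  }

  true_calls <- calls

  if (error_rate > 0) {
    flip <- matrix(stats::rbinom(length(calls), 1, error_rate) == 1,
                   nrow(calls), ncol(calls))
    two_class <- map$seg_type != "ABxAB"
    for (j in which(two_class)) {
      calls[flip[, j], j] <- 1 - calls[flip[, j], j]
    }
    for (j in which(!two_class)) {
      n_e <- sum(flip[, j])
      if (n_e > 0) {
        # re-draw one transmitted allele: +/-1 bounded to {0,1,2}
        delta <- ifelse(stats::rbinom(n_e, 1, 0.5) == 1, 1, -1)
        calls[flip[, j], j] <- pmin(2, pmax(0, calls[flip[, j], j] + delta))
      }
    }
  }

  if (missing_rate > 0) {
    drop <- matrix(stats::rbinom(length(calls), 1, missing_rate) == 1,
                   nrow(calls), ncol(calls))
    calls[drop] <- NA_real_
  }

  structure(
    list(
      geno = geno_as_tibble(calls, ids),
      geno_true = geno_as_tibble(true_calls, ids),
      map = map,
      config = list(
        n_progeny = n_progeny, missing_rate = missing_rate,
        error_rate = error_rate, map_function = map_function, seed = seed
      )
    ),
    class = "sim_cross"
  )
}

#' @export
print.sim_cross <- function(x, ...) {
  cat(sprintf(
    "Simulated full-sib cross: %d progeny x %d markers on %d LGs (%s map function)\n",
    nrow(x$geno), nrow(x$map), length(unique(x$map$lg)), x$config$map_function
  ))
  tab <- table(x$map$seg_type)
  cat("  marker types:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate multi-QTL phenotypes on a simulated cross
#'
#' For each requested trait, plants additive QTLs at the marker nearest each
#' requested position and generates
#' `phenotype = intercept + sum(effect_q * code_q) + Normal(0, residual_sd)`.
#' Effects are scaled from the realized marker variances so that the
#' single-locus variance fraction matches `pve` when loci are independent
#' (different linkage groups or well separated): with variance fractions
#' `p_q`, `effect_q = residual_sd * sqrt(p_q / (1 - sum(p))) / sd(code_q)`.
#' Phenotypes are generated from the error-free genotype calls; the observed
#' (noisy, incomplete) calls are what the analysis sees.
#'
#' @param cross A `sim_cross` object.
#' @param qtl_spec Tibble with one row per planted QTL: columns `trait`,
#'   `lg`, `pos_cm`, `pve` (fraction of trait variance in `[0,1)`), and
#'   optionally `sign` (+1/-1, default alternating) and `intercept`,
#'   `residual_sd` (per trait; defaults 0 and 1). Traits named in `traits`
#'   but absent here become pure-noise traits.
#' @param traits Optional character vector of trait names to generate
#'   (defaults to the traits in `qtl_spec`).
#' @param seed Integer seed.
#' @param informative_only If not `NULL`, restrict candidate causal markers
#'   to this segregation type (e.g. `"AAxAB"` to place all causal loci on
#'   one parental map).
#' @return List with `pheno` (tibble `id` x traits) and `truth` (tibble of
#'   planted QTLs: trait, marker, lg, pos_cm, effect, pve).
#' @export
sim_phenotypes <- function(cross, qtl_spec = NULL, traits = NULL, seed = 1L,
                           informative_only = NULL) {
  stop_if_not(inherits(cross, "sim_cross"), "cross must be a sim_cross object")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)

  map <- cross$map
  g_true <- as_geno_matrix(cross$geno_true)
  n <- nrow(g_true)
  if (is.null(qtl_spec)) {
    qtl_spec <- tibble::tibble(trait = character(), lg = integer(),
                               pos_cm = numeric(), pve = numeric())
  }
  traits <- traits %||% unique(qtl_spec$trait)
  stop_if_not(length(traits) >= 1, "no traits requested")

  cand <- map
  if (!is.null(informative_only)) {
    cand <- dplyr::filter(map, .data$seg_type %in% informative_only)
    stop_if_not(nrow(cand) > 0, "no markers of the requested seg type")
  }

  pheno <- matrix(NA_real_, n, length(traits),
                  dimnames = list(rownames(g_true), traits))
  truth <- list()

  for (tr in traits) {
    spec_t <- dplyr::filter(qtl_spec, .data$trait == tr)
    p <- spec_t$pve %||% numeric(0)
    stop_if_not(all(p >= 0) && sum(p) < 1,
                "per-trait pve values must be >= 0 and sum to < 1 (trait %s)", tr)
    intercept <- if ("intercept" %in% names(spec_t) && nrow(spec_t) > 0) {
      spec_t$intercept[1]
    } else 0
    residual_sd <- if ("residual_sd" %in% names(spec_t) && nrow(spec_t) > 0) {
      spec_t$residual_sd[1]
    } else 1

    y <- intercept + stats::rnorm(n, 0, residual_sd)
    if (nrow(spec_t) > 0) {
      signs <- if ("sign" %in% names(spec_t)) spec_t$sign else {
        rep_len(c(1, -1), nrow(spec_t))
      }
      for (q in seq_len(nrow(spec_t))) {
        lg_q <- spec_t$lg[q]
        in_lg <- dplyr::filter(cand, .data$lg == lg_q)
        stop_if_not(nrow(in_lg) > 0, "no candidate markers on LG %s", lg_q)
        span <- range(in_lg$pos_cm)
        stop_if_not(spec_t$pos_cm[q] >= span[1] && spec_t$pos_cm[q] <= span[2],
                    "QTL position %.1f cM outside LG %s span [%.1f, %.1f]",
                    spec_t$pos_cm[q], lg_q, span[1], span[2])
        mk <- in_lg$marker[which.min(abs(in_lg$pos_cm - spec_t$pos_cm[q]))]
        code <- g_true[, mk]
        sd_g <- stats::sd(code)
        stop_if_not(sd_g > 0, "causal marker %s is monomorphic", mk)
        eff <- if (sum(p) > 0 && spec_t$pve[q] > 0) {
          signs[q] * residual_sd * sqrt(spec_t$pve[q] / (1 - sum(p))) / sd_g
        } else 0
        y <- y + eff * (code - mean(code))
        truth[[length(truth) + 1]] <- tibble::tibble(
          trait = tr, marker = mk, lg = lg_q,
          pos_cm = in_lg$pos_cm[in_lg$marker == mk],
          effect = eff, pve = spec_t$pve[q]
        )
      }
    }
    pheno[, tr] <- y
  }

  list(
    pheno = dplyr::bind_cols(tibble::tibble(id = rownames(g_true)),
                             tibble::as_tibble(pheno)),
    truth = if (length(truth)) dplyr::bind_rows(truth) else
      tibble::tibble(trait = character(), marker = character(), lg = integer(),
                     pos_cm = numeric(), effect = numeric(), pve = numeric())
  )
}

#' Simulate a complete study-design dataset
#'
#' One-call wrapper reproducing the assumed study geometry: a 252-progeny
#' full-sib cross over 12 linkage groups with ~480 informative markers per
#' parental map, and one or more traits each controlled by ~5 QTLs of 2-10%
#' variance explained.
#'
#' @param n_progeny,n_lg,markers_per_lg,mean_gap_cm,missing_rate,error_rate
#'   Passed to the map and cross simulators.
#' @param qtl_pve Numeric vector of per-QTL variance fractions for the single
#'   simulated trait (default five QTLs, 5-9%); use `numeric(0)` for a
#'   pure-noise trait.
#' @param qtl_seg_type Parental map on which causal loci are placed.
#' @param seed Integer seed controlling map, cross, and phenotypes.
#' @return List with `map`, `cross`, `pheno`, `truth`.
#' @export
sim_study <- function(n_progeny = 252, n_lg = 12, markers_per_lg = 84,
                      mean_gap_cm = 2, missing_rate = 0.05, error_rate = 0.005,
                      qtl_pve = c(0.05, 0.06, 0.07, 0.08, 0.09),
                      qtl_seg_type = "AAxAB", seed = 1L) {
  seeds <- derive_seeds(seed, 3)
  map <- sim_genetic_map(n_lg = n_lg, markers_per_lg = markers_per_lg,
                         mean_gap_cm = mean_gap_cm, seed = seeds[1])
  cross <- sim_cross(map, n_progeny = n_progeny, missing_rate = missing_rate,
                     error_rate = error_rate, seed = seeds[2])
  qtl_spec <- if (length(qtl_pve) > 0) {
    # spread causal loci over distinct LGs at mid-chromosome positions
    lgs <- rep_len(seq_len(n_lg), length(qtl_pve))
    pos <- purrr::map_dbl(lgs, function(l) {
      stats::median(map$pos_cm[map$lg == l])
    })
    tibble::tibble(trait = "trait1", lg = lgs, pos_cm = pos, pve = qtl_pve)
  } else NULL
  ph <- sim_phenotypes(cross, qtl_spec, traits = "trait1", seed = seeds[3],
                       informative_only = qtl_seg_type)
  list(map = map, cross = cross, pheno = ph$pheno, truth = ph$truth)
}
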