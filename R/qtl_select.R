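#' Project reference-model draws onto a marker subset
#'
#' For each posterior draw of the reference model, the fitted mean
#' `X beta + b0` is projected by least squares onto the column span of the
#' selected markers (plus intercept) — the KL-minimizing projection for a
#' Gaussian likelihood — yielding a draw of submodel coefficients. The
#' projected residual variance is inflated per draw by the mean squared
#' projection discrepancy:
#' `sigma_proj^2 = sigma^2 + mean((mu - mu_proj)^2)`.
#'
#' @param input An `hs_scan_input`.
#' @param fit The reference `hs_fit`.
#' @param markers Character or integer subset of markers (non-empty,
#'   linearly independent columns). The full set projects to the reference
#'   itself.
#' @return List of class `hs_projection`: `beta` (draws x subset, standardized
#'   scale), `intercept`, `sigma`, `markers`, `discrepancy` (per draw).
#' @export
project_submodel <- function(input, fit, markers) {
  stop_if_not(length(markers) >= 1, "marker subset must be non-empty")
  if (is.numeric(markers)) markers <- input$markers[markers]
  stop_if_not(all(markers %in% colnames(fit$beta)),
              "subset contains markers absent from the fit")
  Xs <- input$X[, markers, drop = FALSE]
  qrX <- qr(cbind(1, Xs))
  stop_if_not(qrX$rank == length(markers) + 1,
              "selected marker columns are rank-deficient")

  mu <- tcrossprod(fit$beta, input$X) + fit$intercept  # draws x n
  coefs <- qr.coef(qrX, t(mu))                         # (k+1) x draws
  mu_proj <- t(qr.fitted(qrX, t(mu)))
  disc <- rowMeans((mu - mu_proj)^2)
  structure(
    list(
      beta = t(coefs[-1, , drop = FALSE]),
      intercept = coefs[1, ],
      sigma = sqrt(fit$sigma^2 + disc),
      markers = markers,
      discrepancy = disc
    ),
    class = "hs_projection"
  )
}

# mean log pointwise predictive density of projected (or reference) draws
lppd_pointwise <- function(mu, sigma, y) {
  # mu: draws x n; sigma: per-draw SD
  ll <- -0.5 * log(2 * pi) - log(sigma) - 0.5 * sweep(-mu, 2, y, "+")^2 / sigma^2
  col_logsumexp(ll) - log(nrow(ll))
}

#' Greedy projection-predictive forward search
#'
#' Starting from the intercept-only submodel, repeatedly adds the marker
#' whose inclusion most reduces the squared discrepancy between the
#' reference model's mean fitted values and their projection onto the
#' submodel span, up to `max_size` markers (default `2 * p0`). The chosen
#' submodel size is the smallest whose projected predictive score comes
#' within one standard error of the reference model's score; the SE is that
#' of the pointwise score differences. Both scores are leave-one-out
#' expected log predictive densities: the reference's own PSIS-LOO elpd,
#' and for each projected submodel the LOO score obtained by reweighting
#' its pointwise predictive densities with the reference model's smoothed
#' importance weights. Scoring both sides by LOO is what makes the search
#' stop at sparse sizes: the reference's in-sample score is optimistic by
#' its many weakly shrunk effects and would never be approached.
#'
#' @param input An `hs_scan_input`.
#' @param fit The reference `hs_fit` (run after [loo_gate()] passes).
#' @param max_size Cap on submodel size (default `2 * p0`).
#' @param ref_loo Optional `hs_loo` of the reference fit computed with
#'   `return_weights = TRUE`; computed when missing.
#' @return List of class `hs_selection`: `path` (markers in inclusion
#'   order), `scores` (tibble per size 0..max: `size`, `lppd`, `delta_ref`,
#'   `se_delta`), `size` (chosen), `markers` (chosen subset).
#' @export
forward_select <- function(input, fit, max_size = NULL, ref_loo = NULL) {
  max_size <- max_size %||% (2 * fit$config$p0)
  D <- ncol(fit$beta)
  max_size <- min(max_size, D, input$n - 2)
  X <- input$X; y <- input$y

  if (is.null(ref_loo) || is.null(ref_loo$log_weights)) {
    ref_loo <- psis_loo(fit, input, return_weights = TRUE)
  }
  ref_lppd_i <- ref_loo$pointwise$elpd_i
  lw <- ref_loo$log_weights
  lw_norm <- col_logsumexp(lw)

  mu_draws <- tcrossprod(fit$beta, X) + fit$intercept
  mu_bar <- colMeans(mu_draws)

  # greedy ranking on the mean fitted values (Gram-based least squares)
  mu_c <- mu_bar - mean(mu_bar)
  Xty <- drop(crossprod(X, mu_c))
  G <- crossprod(X)            # columns are centered+scaled already
  path <- integer(0)
  avail <- seq_len(D)
  for (step in seq_len(max_size)) {
    best <- NA_integer_; best_gain <- -Inf
    for (j in avail) {
      S <- c(path, j)
      GS <- G[S, S, drop = FALSE]
      sol <- tryCatch(solve(GS, Xty[S]), error = function(e) NULL)
      if (is.null(sol)) next
      gain <- sum(Xty[S] * sol)   # explained SS of the reference mean
      if (gain > best_gain + 1e-12) { best_gain <- gain; best <- j }
    }
    if (is.na(best)) break
    path <- c(path, best)
    avail <- setdiff(avail, best)
  }
  path_markers <- colnames(fit$beta)[path]

  # Per-size projected submodel score: LOO elpd via the reference model's
  # smoothed importance weights applied to the submodel's pointwise
  # predictive densities.
  loo_lppd <- function(mu, sigma) {
    ll <- -0.5 * log(2 * pi) - log(sigma) -
      0.5 * sweep(-mu, 2, y, "+")^2 / sigma^2
    col_logsumexp(lw + ll) - lw_norm
  }
  scores <- purrr::map_dfr(0:length(path), function(k) {
    if (k == 0) {
      mu0 <- matrix(rowMeans(mu_draws), nrow(mu_draws), length(y))
      disc <- rowMeans((mu_draws - mu0)^2)
      lppd_i <- loo_lppd(mu0, sqrt(fit$sigma^2 + disc))
    } else {
      pr <- project_submodel(input, fit, path_markers[seq_len(k)])
      mu_k <- tcrossprod(pr$beta, X[, pr$markers, drop = FALSE]) + pr$intercept
      lppd_i <- loo_lppd(mu_k, pr$sigma)
    }
    d <- ref_lppd_i - lppd_i
    tibble::tibble(size = k, lppd = sum(lppd_i), delta_ref = sum(d),
                   se_delta = sqrt(length(d) * stats::var(d)))
  })

  ok <- scores$delta_ref <= scores$se_delta
  size <- if (any(ok)) scores$size[which(ok)[1]] else length(path)
  structure(
    list(path = path_markers, scores = scores, size = size,
         markers = if (size > 0) path_markers[seq_len(size)] else character(0)),
    class = "hs_selection"
  )
}

#' @export
print.hs_selection <- function(x, ...) {
  cat(sprintf("Projection-predictive forward search: chose %d of %d ranked markers\n",
              x$size, length(x$path)))
  if (x$size > 0) cat("  selected:", paste(x$markers, collapse = ", "), "\n")
  invisible(x)
}

#' Percentage variance explained by a single marker
#'
#' `PVE = 100 * r^2`, the coefficient of determination of the simple
#' regression of the trait on one marker's codes (pairwise-complete
#' observations).
#'
#' @param y Trait values.
#' @param marker_codes 0/1 codes (may contain `NA`).
#' @return PVE in percent.
#' @export
pve <- function(y, marker_codes) {
  ok <- stats::complete.cases(y, marker_codes)
  stop_if_not(sum(ok) >= 3, "fewer than 3 complete trait/marker pairs")
  if (stats::sd(marker_codes[ok]) == 0) {
    warning("constant marker; PVE undefined", call. = FALSE)
    return(NA_real_)
  }
  100 * stats::cor(y[ok], marker_codes[ok])^2
}

#' Classify selected markers into QTL significance tiers
#'
#' Equal-tailed credible intervals from the projected submodel draws decide
#' the tier: a marker whose 95% interval excludes zero is a significant QTL
#' (`**`), one whose 80% interval excludes zero (but 95% does not) is
#' suggestive (`*`); others are not reported. PVE is the single-marker
#' simple-regression R-squared on the raw data.
#'
#' @param projection An `hs_projection` of the chosen submodel.
#' @param input The `hs_scan_input` (raw trait and marker codes for PVE).
#' @param map Map tibble for locus positions (optional columns used:
#'   `marker`, `lg`, `pos_cm`).
#' @param trait Trait name for the report.
#' @return Tibble (possibly empty): `trait`, `marker`, `lg`, `pos_cm`,
#'   `tier`, `sig`, `effect` (posterior mean, trait units per allele),
#'   `ci95_lo`, `ci95_hi`, `ci80_lo`, `ci80_hi`, `pve`.
#' @export
classify_qtls <- function(projection, input, map = NULL, trait = input$trait %||% "trait") {
  empty <- tibble::tibble(
    trait = character(), marker = character(), lg = integer(),
    pos_cm = numeric(), tier = character(), sig = character(),
    effect = numeric(), ci95_lo = numeric(), ci95_hi = numeric(),
    ci80_lo = numeric(), ci80_hi = numeric(), pve = numeric()
  )
  if (length(projection$markers) == 0) return(empty)
  map <- map %||% input$map

  rows <- purrr::map_dfr(seq_along(projection$markers), function(k) {
    mk <- projection$markers[k]
    b <- projection$beta[, k] * (input$y_scale %||% 1) / (input$x_scale[mk] %||% 1)
    q95 <- stats::quantile(b, c(0.025, 0.975), names = FALSE)
    q80 <- stats::quantile(b, c(0.10, 0.90), names = FALSE)
    tier <- if (q95[1] > 0 || q95[2] < 0) "significant"
    else if (q80[1] > 0 || q80[2] < 0) "suggestive"
    else NA_character_
    tibble::tibble(
      trait = trait, marker = mk,
      tier = tier,
      sig = unname(c(significant = "**", suggestive = "*")[tier]),
      effect = mean(b),
      ci95_lo = q95[1], ci95_hi = q95[2], ci80_lo = q80[1], ci80_hi = q80[2],
      pve = pve(input$y_raw, input$X_raw[, mk])
    )
  })
  rows <- dplyr::filter(rows, !is.na(.data$tier))
  if (nrow(rows) == 0) return(empty)
  if (!is.null(map)) {
    rows <- dplyr::left_join(rows, dplyr::select(map, "marker", "lg", "pos_cm"),
                             by = "marker")
  } else {
    rows$lg <- NA_integer_; rows$pos_cm <- NA_real_
  }
  dplyr::select(rows, "trait", "marker", "lg", "pos_cm", "tier", "sig",
                "effect", dplyr::starts_with("ci"), "pve")
}

#' Full per-trait QTL scan
#'
#' The complete post-QC inference chain for one trait on one parental map:
#' standardize ([prepare_scan()]), fit the regularized-horseshoe reference
#' model ([fit_horseshoe()]), check convergence ([gelman_rubin()]), gate
#' against the intercept-only null by PSIS-LOO ([loo_gate()]), run the
#' projection-predictive forward search ([forward_select()]), and classify
#' the chosen submodel's markers into credible-interval tiers
#' ([classify_qtls()]).
#'
#' @param geno Genotype tibble (post-QC).
#' @param map Map tibble.
#' @param pheno Phenotype tibble.
#' @param trait Trait column name.
#' @param config An [hs_config()].
#' @param gate_k LOO gate multiple (default 2).
#' @param max_size Forward-search cap (default `2 * p0`).
#' @param halt_on_rhat Stop (error) if split-R-hat exceeds its threshold
#'   (default `TRUE`, matching the pipeline contract); `FALSE` records the
#'   failure and continues.
#' @return List of class `hs_scan`: `report` (QTL tibble), `fit`, `loo_ref`,
#'   `loo_null`, `gate` (logical with elpd attributes), `selection`,
#'   `projection`, `convergence`.
#' @export
scan_trait <- function(geno, map, pheno, trait, config = hs_config(),
                       gate_k = 2, max_size = NULL, halt_on_rhat = TRUE) {
  input <- prepare_scan(geno, pheno, trait, map = map)
  fit <- fit_horseshoe(input, config)

  conv_ok <- is.null(fit$convergence) || attr(fit$convergence, "pass")
  if (!conv_ok) {
    bad <- dplyr::filter(fit$convergence, .data$rhat >= config$rhat_threshold)
    msg <- sprintf(
      "convergence failure for trait '%s': %d parameter(s) with split-R-hat >= %.2f (worst %.3f: %s)",
      trait, nrow(bad), config$rhat_threshold, max(bad$rhat),
      bad$parameter[which.max(bad$rhat)]
    )
    if (halt_on_rhat) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }

  seeds <- derive_seeds(config$seed, 2)
  loo_ref <- psis_loo(fit, input, return_weights = TRUE)
  null <- fit_null(input, draws = nrow(fit$beta), seed = seeds[1],
                   a_sigma = config$a_sigma, b_sigma = config$b_sigma)
  loo_null <- psis_loo(null, input)
  gate <- loo_gate(loo_ref, loo_null, k = gate_k)

  if (isTRUE(conv_ok) && isTRUE(as.logical(gate))) {
    selection <- forward_select(input, fit, max_size, ref_loo = loo_ref)
    projection <- if (selection$size > 0) {
      project_submodel(input, fit, selection$markers)
    } else NULL
    report <- if (!is.null(projection)) {
      classify_qtls(projection, input, map, trait)
    } else classify_qtls(structure(list(markers = character(0)),
                                   class = "hs_projection"), input, map, trait)
  } else {
    selection <- NULL; projection <- NULL
    report <- classify_qtls(structure(list(markers = character(0)),
                                      class = "hs_projection"), input, map, trait)
  }

  structure(
    list(report = report, fit = fit, loo_ref = loo_ref, loo_null = loo_null,
         gate = gate, selection = selection, projection = projection,
         convergence = fit$convergence, input = input, trait = trait),
    class = "hs_scan"
  )
}

#' @export
print.hs_scan <- function(x, ...) {
  cat(sprintf("QTL scan for trait '%s': gate %s (elpd diff %.2f, SE %.2f)\n",
              x$trait, if (isTRUE(as.logical(x$gate))) "open" else "closed",
              attr(x$gate, "elpd_diff"), attr(x$gate, "se_diff")))
  if (nrow(x$report) > 0) print(x$report) else cat("  no QTLs reported\n")
  invisible(x)
}

#' Sensitivity of QTL detection to the p0 calibration
#'
#' Repeats the full scan over a range of `p0` values (default 1 through 9)
#' with a fixed seed policy, collecting the per-`p0` QTL reports for
#' stability inspection.
#'
#' @inheritParams scan_trait
#' @param p0_values Integer vector of expected-relevant-variable counts.
#' @return Tibble of QTL rows with a `p0` column prepended.
#' @export
p0_sensitivity <- function(geno, map, pheno, trait, config = hs_config(),
                           p0_values = 1:9, gate_k = 2) {
  purrr::map_dfr(p0_values, function(p0) {
    cfg <- config
    cfg$p0 <- p0
    sc <- scan_trait(geno, map, pheno, trait, cfg, gate_k = gate_k,
                     halt_on_rhat = FALSE)
    if (nrow(sc$report) > 0) dplyr::mutate(sc$report, p0 = p0, .before = 1) else
      tibble::tibble(p0 = integer(0))
  })
}
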