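# Generalized Pareto tail fit (Zhang & Stephens 2009 style profile
# posterior mean), parameterized so the density is
# f(x) = (b/k) (1 - b x)^(1/k - 1), giving GPD shape xi = -k, scale k/b.
# Used to smooth the largest importance ratios.
gpd_fit <- function(x, wip = TRUE) {
  x <- sort(x[is.finite(x)])
  N <- length(x)
  stop_if_not(N >= 5, "too few tail samples for a generalized-Pareto fit")
  M <- 30 + floor(sqrt(N))
  jj <- seq_len(M)
  xstar <- x[max(1, floor(N / 4 + 0.5))]
  bgrid <- 1 / x[N] + (1 - sqrt(M / (jj - 0.5))) / (3 * xstar)
  khat <- vapply(bgrid, function(b) -mean(log1p(-b * x)), numeric(1))
  ll <- N * (log(bgrid / khat) + khat - 1)
  w <- exp(ll - max(ll)); w <- w / sum(w)
  b <- sum(bgrid * w)
  k <- -mean(log1p(-b * x))
  # weak prior pulling the shape toward 0.5 stabilizes short tails
  # (k here is the Zhang-Stephens sign convention, = -shape)
  if (wip) k <- (N * k - 5) / (N + 10)
  list(xi = -k, sigma = k / b) # xi is the usual Pareto shape (positive = heavy)
}

gpd_quantile <- function(p, xi, sigma) {
  if (abs(xi) < 1e-12) -sigma * log1p(-p) else sigma * expm1(-xi * log1p(-p)) / xi
}

# Pareto-smoothed importance sampling weights for one observation.
# lw: vector of log importance ratios (one per draw). Returns smoothed,
# max-normalized log weights and the fitted Pareto shape.
psis_smooth <- function(lw, tail_frac = 0.2) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(tail_frac * S)
  if (M < 5) return(list(log_weights = lw, k = NA_real_))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cut <- exp(lw[ord[S - M]])           # largest non-tail weight
  tail_w <- exp(lw[tail_ids])
  exceed <- tail_w - cut
  if (all(exceed <= 0) || length(unique(tail_w)) < 3) {
    return(list(log_weights = lw, k = NA_real_))
  }
  if (sum(exceed > 0) < 5) return(list(log_weights = lw, k = NA_real_))
  fit <- gpd_fit(exceed[exceed > 0])
  if (!is.finite(fit$xi) || !is.finite(fit$sigma) || fit$sigma <= 0) {
    return(list(log_weights = lw, k = fit$xi))
  }
  qs <- gpd_quantile((seq_len(M) - 0.5) / M, fit$xi, fit$sigma)
  sm <- pmin(pmax(cut + qs, cut), exp(0)) # truncate at the raw maximum (=1)
  lw[tail_ids] <- log(sm) # tail_ids already in increasing-weight order
  list(log_weights = lw, k = fit$xi)
}

#' Pointwise log-likelihood matrix of a horseshoe fit
#'
#' Gaussian log density of each observation under each posterior draw, on
#' the standardized scale used by the sampler.
#'
#' @param fit An `hs_fit` (or the intercept-only null fit from [fit_null()]).
#' @param input The `hs_scan_input` the model was fitted to.
#' @return Matrix draws x observations.
#' @export
log_lik_matrix <- function(fit, input) {
  mu <- if (ncol(fit$beta) > 0) tcrossprod(fit$beta, input$X) else
    matrix(0, length(fit$intercept), length(input$y))
  mu <- mu + fit$intercept
  s <- fit$sigma
  -0.5 * log(2 * pi) - log(s) - 0.5 * sweep(-mu, 2, input$y, "+")^2 / s^2
}

#' PSIS-LOO cross-validation from posterior draws
#'
#' Leave-one-out expected log pointwise predictive density estimated from a
#' single posterior sample by Pareto-smoothed importance sampling: per
#' observation the importance ratios `1/p(y_i | theta_s)` are computed, the
#' largest 20% are replaced by quantiles of a generalized-Pareto
#' distribution fitted to them (truncated at the raw maximum), and
#' `elpd_i = log( sum_s w_s p(y_i|theta_s) / sum_s w_s )`. Observations with
#' Pareto shape diagnostic above 0.7 are flagged unreliable.
#'
#' @param fit An `hs_fit` or `hs_null_fit`.
#' @param input The matching `hs_scan_input`.
#' @param tail_frac Fraction of draws treated as the smoothed tail (default 0.2).
#' @param return_weights Keep the smoothed log importance weights (draws x
#'   observations); used to score projected submodels by LOO.
#' @return List of class `hs_loo`: `elpd`, `se` (SE of the elpd sum),
#'   `pointwise` (tibble: `elpd_i`, `pareto_k`, `unreliable`), `n`, and
#'   `log_weights` when requested.
#' @export
psis_loo <- function(fit, input, tail_frac = 0.2, return_weights = FALSE) {
  ll <- log_lik_matrix(fit, input)
  S <- nrow(ll); n <- ncol(ll)
  elpd_i <- numeric(n); k_i <- numeric(n)
  lw_mat <- if (return_weights) matrix(NA_real_, S, n) else NULL
  for (i in seq_len(n)) {
    sm <- psis_smooth(-ll[, i], tail_frac)
    lw <- sm$log_weights
    elpd_i[i] <- logsumexp(lw + ll[, i]) - logsumexp(lw)
    k_i[i] <- sm$k
    if (return_weights) lw_mat[, i] <- lw
  }
  unreliable <- !is.na(k_i) & k_i > 0.7
  if (any(unreliable)) {
    warning(sum(unreliable), " observation(s) with Pareto k > 0.7; ",
            "PSIS-LOO estimate may be unreliable for them", call. = FALSE)
  }
  structure(
    list(
      elpd = sum(elpd_i),
      se = sqrt(n * stats::var(elpd_i)),
      pointwise = tibble::tibble(elpd_i = elpd_i, pareto_k = k_i,
                                 unreliable = unreliable),
      n = n,
      log_weights = lw_mat
    ),
    class = "hs_loo"
  )
}

#' @export
print.hs_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd = %.2f (SE %.2f), n = %d, %d unreliable k\n",
              x$elpd, x$se, x$n, sum(x$pointwise$unreliable)))
  invisible(x)
}

#' Intercept-only null model fit
#'
#' Conjugate posterior draws for the null model `y = b0 + e` on the
#' standardized scale (flat prior on `b0`, inverse-gamma on `sigma^2`
#' matching the horseshoe configuration), shaped like an `hs_fit` so it can
#' feed [psis_loo()].
#'
#' @param input An `hs_scan_input`.
#' @param draws Number of posterior draws.
#' @param seed Integer seed.
#' @param a_sigma,b_sigma Inverse-gamma hyperparameters for `sigma^2`.
#' @return A list of class `hs_null_fit` with `beta` (0-column matrix),
#'   `intercept`, `sigma`.
#' @export
fit_null <- function(input, draws = 4000, seed = 1L, a_sigma = 0.5, b_sigma = 0.5) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  y <- input$y; n <- length(y)
  ss <- sum((y - mean(y))^2)
  # sigma^2 | y with b0 marginalized under its flat prior
  sigma2 <- 1 / stats::rgamma(draws, a_sigma + (n - 1) / 2, b_sigma + ss / 2)
  b0 <- stats::rnorm(draws, mean(y), sqrt(sigma2 / n))
  structure(
    list(beta = matrix(numeric(0), nrow = draws, ncol = 0),
         intercept = b0, sigma = sqrt(sigma2)),
    class = c("hs_null_fit", "hs_fit")
  )
}

#' Compare two PSIS-LOO results
#'
#' @param loo_a,loo_b `hs_loo` objects on the same observations.
#' @return Tibble: `elpd_diff` (a minus b), `se_diff` (paired SE).
#' @export
loo_compare_pair <- function(loo_a, loo_b) {
  stop_if_not(loo_a$n == loo_b$n,
              "LOO results computed on different observation sets")
  d <- loo_a$pointwise$elpd_i - loo_b$pointwise$elpd_i
  tibble::tibble(elpd_diff = sum(d), se_diff = sqrt(length(d) * stats::var(d)))
}

#' Reference-vs-null LOO gate
#'
#' Variable selection proceeds only when the reference model carries
#' significantly more predictive information than the intercept-only null:
#' `elpd(reference) - elpd(null) > k * SE(difference)` (default `k = 2`).
#' When the gate is closed the trait yields zero QTLs.
#'
#' @param loo_ref,loo_null `hs_loo` results on identical observations.
#' @param k Multiple of the difference SE required (default 2).
#' @return Logical scalar with attributes `elpd_diff` and `se_diff`.
#' @export
loo_gate <- function(loo_ref, loo_null, k = 2) {
  cmp <- loo_compare_pair(loo_ref, loo_null)
  out <- cmp$elpd_diff > k * cmp$se_diff
  attr(out, "elpd_diff") <- cmp$elpd_diff
  attr(out, "se_diff") <- cmp$se_diff
  out
}
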