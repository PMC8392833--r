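#' Dense-grid quadrature of the horseshoe posterior (small D)
#'
#' Independent numerical-integration route for validating the MCMC sampler
#' on problems with one or two markers. The coefficient block is
#' marginalized in closed form (the conditional posterior given the scales
#' is Gaussian), and the scale posterior is integrated on a dense rectangular
#' grid over `(log tau, log lambda_1, ..., log lambda_D)`. The residual SD
#' and slab scale are held fixed so the integrand is the exact posterior of
#' a [fit_horseshoe()] run with `sigma_fixed`/`slab_fixed` set and
#' `intercept = FALSE`. Shares no sampling code with the MCMC path.
#'
#' @param X Standardized design matrix with 1 or 2 columns.
#' @param y Centered/standardized response.
#' @param tau0 Global-scale calibration (see [compute_tau0()]).
#' @param sigma Fixed residual SD.
#' @param slab Fixed slab scale `c`.
#' @param n_grid Grid points per dimension (default 80).
#' @param span Half-width of each grid in log-scale units (default 9).
#' @return List with `mean` (posterior means of the coefficients), `sd`
#'   (posterior SDs), and `log_norm` (log normalizing constant up to a
#'   constant).
#' @export
hs_quadrature <- function(X, y, tau0, sigma, slab, n_grid = 80, span = 9) {
  D <- ncol(X)
  stop_if_not(D %in% c(1L, 2L), "quadrature oracle supports D = 1 or 2 only")
  sigma2 <- sigma^2
  c2 <- slab^2
  S <- crossprod(X)             # D x D
  b <- drop(crossprod(X, y)) / sigma2

  lt <- seq(log(tau0) - span, log(tau0) + span, length.out = n_grid)
  ll <- seq(-span, span, length.out = n_grid)

  # log prior densities incl. Jacobians of the log transforms
  lp_tau <- lt - log1p(exp(2 * (lt - log(tau0))))
  lp_lam <- ll - log1p_e2u(ll)

  if (D == 1L) {
    g <- expand.grid(t = lt, l1 = ll)
    pri <- lp_tau[match(g$t, lt)] + lp_lam[match(g$l1, ll)]
    v1 <- 1 / (exp(-2 * g$l1) / exp(2 * g$t) + 1 / c2)
    A11 <- S[1, 1] / sigma2 + 1 / v1
    m1 <- b[1] / A11
    logm <- -0.5 * log(A11) - 0.5 * log(v1) + 0.5 * b[1] * m1
    lw <- pri + logm
    w <- exp(lw - max(lw)); w <- w / sum(w)
    mean1 <- sum(w * m1)
    e2 <- sum(w * (1 / A11 + m1^2))
    return(list(mean = mean1, sd = sqrt(e2 - mean1^2),
                log_norm = logsumexp(lw)))
  }

  g <- expand.grid(t = lt, l1 = ll, l2 = ll)
  pri <- lp_tau[match(g$t, lt)] + lp_lam[match(g$l1, ll)] + lp_lam[match(g$l2, ll)]
  tau2 <- exp(2 * g$t)
  v1 <- 1 / (exp(-2 * g$l1) / tau2 + 1 / c2)
  v2 <- 1 / (exp(-2 * g$l2) / tau2 + 1 / c2)
  A11 <- S[1, 1] / sigma2 + 1 / v1
  A22 <- S[2, 2] / sigma2 + 1 / v2
  A12 <- S[1, 2] / sigma2
  det <- A11 * A22 - A12^2
  m1 <- (A22 * b[1] - A12 * b[2]) / det
  m2 <- (A11 * b[2] - A12 * b[1]) / det
  logm <- -0.5 * log(det) - 0.5 * (log(v1) + log(v2)) +
    0.5 * (b[1] * m1 + b[2] * m2)
  lw <- pri + logm
  w <- exp(lw - max(lw)); w <- w / sum(w)
  mean_ <- c(sum(w * m1), sum(w * m2))
  # conditional covariance entries of A^-1
  e2 <- c(sum(w * (A22 / det + m1^2)), sum(w * (A11 / det + m2^2)))
  list(mean = mean_, sd = sqrt(pmax(e2 - mean_^2, 0)),
       log_norm = logsumexp(lw))
}
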