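#' Global-scale calibration for the regularized horseshoe
#'
#' The global shrinkage scale is set from the expected number of relevant
#' variables: \deqn{\tau_0 = \frac{p_0}{D - p_0}\,\frac{\sigma}{\sqrt{n}}}
#' where `p0` is the expected number of relevant variables, `D` the number
#' of variables, and `n` the number of observations. With the response
#' standardized, `sigma_proxy = 1`.
#'
#' @param p0 Expected number of relevant variables, `0 < p0 < D`.
#' @param D Number of candidate variables (markers).
#' @param n Number of observations.
#' @param sigma_proxy Residual-scale proxy (default 1 for a standardized response).
#' @return The global scale `tau0`.
#' @export
#' @examples
#' compute_tau0(5, 486, 252) # 6.548e-4
compute_tau0 <- function(p0, D, n, sigma_proxy = 1) {
  stop_if_not(p0 > 0, "p0 must be positive")
  stop_if_not(p0 < D, "p0 must be smaller than the number of variables D")
  stop_if_not(n >= 1, "n must be >= 1")
  p0 / (D - p0) * sigma_proxy / sqrt(n)
}

#' Sampler configuration for the regularized-horseshoe scan
#'
#' @param p0 Expected number of relevant markers (default 5).
#' @param chains Number of MCMC chains (default 4).
#' @param warmup Burn-in iterations discarded per chain (default 1000).
#' @param iter Post-warmup iterations retained per chain (default 5000).
#' @param slab_scale,slab_df Scale and degrees of freedom of the
#'   scaled-inverse-chi-square prior on the slab variance `c^2` (defaults 2, 4).
#' @param rhat_threshold Convergence threshold on split-R-hat (default 1.1).
#' @param seed Integer seed; chains get independent derived streams.
#' @param sigma_fixed Optional fixed residual SD (standardized scale); `NULL`
#'   samples `sigma^2` under an inverse-gamma(`a_sigma`, `b_sigma`) prior.
#' @param slab_fixed Optional fixed slab scale `c`; `NULL` samples `c^2`.
#' @param intercept Include a flat-prior intercept (default `TRUE`).
#' @param a_sigma,b_sigma Inverse-gamma hyperparameters for `sigma^2`
#'   (defaults 0.5, 0.5: a unit-scale, 1-df scaled-inverse-chi-square).
#' @param engine `"cpp"` (compiled chain, default) or `"r"` (reference R
#'   implementation of the identical scheme; used for cross-validation).
#' @return A list of class `hs_config`.
#' @export
hs_config <- function(p0 = 5, chains = 4, warmup = 1000, iter = 5000,
                      slab_scale = 2, slab_df = 4, rhat_threshold = 1.1,
                      seed = 1L, sigma_fixed = NULL, slab_fixed = NULL,
                      intercept = TRUE, a_sigma = 0.5, b_sigma = 0.5,
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stop_if_not(p0 >= 1, "p0 must be >= 1")
  stop_if_not(chains >= 1 && warmup >= 0 && iter >= 1,
              "chains and iteration counts must be positive")
  structure(
    list(p0 = p0, chains = chains, warmup = warmup, iter = iter,
         slab_scale = slab_scale, slab_df = slab_df,
         rhat_threshold = rhat_threshold, seed = seed,
         sigma_fixed = sigma_fixed, slab_fixed = slab_fixed,
         intercept = intercept, a_sigma = a_sigma, b_sigma = b_sigma,
         engine = engine),
    class = "hs_config"
  )
}

#' Assemble a scan input from genotype and phenotype tables
#'
#' Joins genotyped and phenotyped individuals, drops individuals with a
#' missing phenotype, mean-imputes missing genotype calls per marker, drops
#' zero-variance markers with a warning, and standardizes both the design
#' columns and the response (transforms retained for back-conversion).
#'
#' @param geno Genotype tibble (`id` + 0/1/`NA` marker columns).
#' @param pheno Phenotype tibble (`id` + trait columns).
#' @param trait Name of the trait column to scan.
#' @param map Optional map tibble carried along for reporting.
#' @return A list of class `hs_scan_input`: standardized design `X`, response
#'   `y`, raw copies, centers/scales, `markers`, `ids`, `n`, `d`, `map`.
#' @export
prepare_scan <- function(geno, pheno, trait, map = NULL) {
  stop_if_not(trait %in% names(pheno), "trait '%s' not found in phenotype table", trait)
  ids <- intersect(geno$id, pheno$id)
  ph <- pheno[match(ids, pheno$id), c("id", trait)]
  keep <- !is.na(ph[[trait]])
  ids <- ids[keep]
  stop_if_not(length(ids) >= 3, "fewer than 3 individuals with genotype and phenotype")
  y_raw <- ph[[trait]][keep]
  m <- as_geno_matrix(geno)[ids, , drop = FALSE]

  all_missing <- colMeans(is.na(m)) == 1
  if (any(all_missing)) {
    warning(sum(all_missing), " marker(s) with no calls dropped", call. = FALSE)
    m <- m[, !all_missing, drop = FALSE]
  }
  # per-marker mean imputation
  cm <- colMeans(m, na.rm = TRUE)
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx)) m[idx] <- cm[idx[, 2]]

  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance marker(s) dropped before fitting",
            call. = FALSE)
    m <- m[, sds > 0, drop = FALSE]
    cm <- cm[sds > 0]; sds <- sds[sds > 0]
  }
  stop_if_not(ncol(m) >= 1, "no usable markers remain")
  sd_y <- stats::sd(y_raw)
  stop_if_not(sd_y > 0, "trait '%s' is constant", trait)

  X <- sweep(sweep(m, 2, colMeans(m), "-"), 2, sds, "/")
  structure(
    list(
      X = X, y = (y_raw - mean(y_raw)) / sd_y,
      X_raw = m, y_raw = y_raw,
      x_center = colMeans(m), x_scale = sds,
      y_center = mean(y_raw), y_scale = sd_y,
      markers = colnames(m), ids = ids,
      n = nrow(m), d = ncol(m), trait = trait,
      map = if (!is.null(map)) dplyr::filter(map, .data$marker %in% colnames(m))
    ),
    class = "hs_scan_input"
  )
}

# ---- slice sampling -------------------------------------------------------

# Vectorized univariate slice sampler: each coordinate has an independent
# conditional; logf maps a vector of coordinates to per-coordinate log
# densities. Stepping-out + shrinkage (Neal 2003).
slice_sample_vec <- function(u0, logf, w = 1, max_step = 30, max_shrink = 200) {
  d <- length(u0)
  z <- logf(u0) - stats::rexp(d)
  lo <- u0 - stats::runif(d) * w
  hi <- lo + w
  for (it in seq_len(max_step)) {
    m <- logf(lo) > z
    if (!any(m)) break
    lo[m] <- lo[m] - w
  }
  for (it in seq_len(max_step)) {
    m <- logf(hi) > z
    if (!any(m)) break
    hi[m] <- hi[m] + w
  }
  u <- u0
  todo <- rep(TRUE, d)
  for (it in seq_len(max_shrink)) {
    prop <- stats::runif(d, lo, hi)
    fp <- logf(prop)
    acc <- todo & (fp >= z)
    u[acc] <- prop[acc]
    todo <- todo & !acc
    if (!any(todo)) break
    sl <- todo & (prop < u0); lo[sl] <- prop[sl]
    sh <- todo & (prop >= u0); hi[sh] <- prop[sh]
  }
  u
}

# log(1 + e^(2u)) without overflow
log1p_e2u <- function(u) ifelse(u > 0, 2 * u + log1p(exp(-2 * u)), log1p(exp(2 * u)))

# effective per-coefficient prior variance tau^2 * lambda_tilde^2
hs_prior_var <- function(log_lambda, tau, c2) {
  1 / (exp(-2 * log_lambda) / tau^2 + 1 / c2)
}

# Draw beta ~ N(A^-1 X'r/s2, A^-1), A = X'X/s2 + diag(1/v). Two routes:
# a D x D Cholesky (XtX precomputed) or the n x n auxiliary draw that is
# cheaper when D greatly exceeds n.
draw_beta <- function(X, XtX, r, sigma2, v) {
  n <- nrow(X); D <- ncol(X)
  if (D <= 2.1 * n) {
    A <- XtX / sigma2
    diag(A) <- diag(A) + 1 / v
    R <- chol(A)
    b <- crossprod(X, r) / sigma2
    mean <- backsolve(R, backsolve(R, b, transpose = TRUE))
    drop(mean + backsolve(R, stats::rnorm(D)))
  } else {
    u <- stats::rnorm(D, 0, sqrt(v))
    delta <- stats::rnorm(n)
    s <- sqrt(sigma2)
    vv <- X %*% u / s + delta
    W <- sweep(X, 2, v, "*")
    Phi <- tcrossprod(W, X) / sigma2
    diag(Phi) <- diag(Phi) + 1
    w <- solve(Phi, r / s - vv)
    drop(u + v * crossprod(X, w) / s)
  }
}

# closed-form conditional moments of beta given scales (ridge posterior)
beta_conditional_moments <- function(X, r, sigma2, v) {
  A <- crossprod(X) / sigma2
  diag(A) <- diag(A) + 1 / v
  Sigma <- solve(A)
  list(mean = drop(Sigma %*% crossprod(X, r)) / sigma2, cov = Sigma)
}

run_hs_chain_r <- function(X, y, tau0, config, seed, swap_pairs = NULL) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  n <- nrow(X); D <- ncol(X)
  XtX <- if (D <= 2.1 * n) crossprod(X) else NULL
  xtx_diag <- colSums(X^2)

  slab_df <- config$slab_df
  slab_s2 <- config$slab_scale^2
  fixed_c2 <- if (!is.null(config$slab_fixed)) config$slab_fixed^2 else NULL
  fixed_s2 <- if (!is.null(config$sigma_fixed)) config$sigma_fixed^2 else NULL

  beta <- numeric(D)
  log_lambda <- numeric(D)
  log_tau <- log(tau0)
  c2 <- fixed_c2 %||% slab_s2
  sigma2 <- fixed_s2 %||% 1
  b0 <- 0

  S <- config$iter
  out_beta <- matrix(NA_real_, S, D)
  out <- matrix(NA_real_, S, 4,
                dimnames = list(NULL, c("intercept", "sigma", "tau", "c")))

  total <- config$warmup + S
  for (it in seq_len(total)) {
    tau <- exp(log_tau)
    v <- hs_prior_var(log_lambda, tau, c2)
    r <- y - b0
    beta <- draw_beta(X, XtX, r, sigma2, v)
    if (!all(is.finite(beta))) {
      stop("non-finite coefficient draw at iteration ", it,
           "; chain aborted (numerical divergence)", call. = FALSE)
    }
    fitted <- drop(X %*% beta)

    if (config$intercept) {
      b0 <- stats::rnorm(1, mean(y - fitted), sqrt(sigma2 / n))
    }
    resid <- y - b0 - fitted
    if (is.null(fixed_s2)) {
      sigma2 <- 1 / stats::rgamma(1, config$a_sigma + n / 2,
                                  config$b_sigma + sum(resid^2) / 2)
    }

    # The scale block is repeated several times per coefficient draw;
    # see the compiled engine for rationale (global-scale mixing).
    for (sweep in 1:4) {
      tau <- exp(log_tau)
      # Local scales: collapsed updates. lambda_j is slice-sampled with
      # beta_j integrated out analytically, then beta_j redrawn conjugately;
      # lets a local scale jump between shrunk and active regimes directly.
      resid_cur <- y - b0 - fitted
      for (j in seq_len(D)) {
        bj_old <- beta[j]
        sj <- xtx_diag[j]
        xr <- sum(X[, j] * resid_cur) + sj * bj_old
        q <- xr / sigma2
        s_s2 <- sj / sigma2
        log_lambda[j] <- slice_sample_vec(log_lambda[j], function(u) {
          vv <- hs_prior_var(u, tau, c2)
          a <- s_s2 + 1 / vv
          u - log1p_e2u(u) - 0.5 * log(vv * a) + 0.5 * q^2 / a
        }, w = 1.5)
        vv <- hs_prior_var(log_lambda[j], tau, c2)
        a <- s_s2 + 1 / vv
        beta[j] <- q / a + stats::rnorm(1) / sqrt(a)
        if (beta[j] != bj_old) resid_cur <- resid_cur - (beta[j] - bj_old) * X[, j]
      }
      fitted <- y - b0 - resid_cur
      bj2 <- beta^2

      # global scale: slice on log(tau), half-Cauchy(0, tau0) prior
      log_tau <- slice_sample_vec(log_tau, function(t) {
        vapply(t, function(ti) {
          vv <- hs_prior_var(log_lambda, exp(ti), c2)
          ti - log1p(exp(2 * (ti - log(tau0)))) -
            sum(0.5 * log(vv) + bj2 / (2 * vv))
        }, numeric(1))
      }, w = 2)

      # slab: slice on log(c^2), scaled-inv-chi-square(slab_df, slab_scale^2)
      if (is.null(fixed_c2)) {
        tau <- exp(log_tau)
        log_c2 <- slice_sample_vec(log(c2), function(wv) {
          vapply(wv, function(wi) {
            vv <- hs_prior_var(log_lambda, tau, exp(wi))
            -(slab_df / 2) * wi - slab_df * slab_s2 / (2 * exp(wi)) -
              sum(0.5 * log(vv) + bj2 / (2 * vv))
          }, numeric(1))
        }, w = 2)
        c2 <- exp(log_c2)
      }

      # Interweaved (non-centered) update for tau: slice on log(tau) with
      # z = beta / prior SD held fixed (ASIS); beta rebuilt at the new scale.
      {
        tau <- exp(log_tau)
        z_nc <- beta / sqrt(hs_prior_var(log_lambda, tau, c2))
        log_tau <- slice_sample_vec(log_tau, function(t) {
          vapply(t, function(ti) {
            bp <- z_nc * sqrt(hs_prior_var(log_lambda, exp(ti), c2))
            res <- y - b0 - drop(X %*% bp)
            ti - log1p(exp(2 * (ti - log(tau0)))) - sum(res^2) / (2 * sigma2)
          }, numeric(1))
        }, w = 1)
        beta <- z_nc * sqrt(hs_prior_var(log_lambda, exp(log_tau), c2))
        fitted <- drop(X %*% beta)
      }

    }
    resid_cur <- y - b0 - fitted
    # Pairwise swap move between nearby correlated markers: exchanging
    # (beta, lambda) of a marker pair is a symmetric proposal whose prior
    # terms cancel, accepted on the likelihood change alone. Lets the
    # posterior hop between the near-equivalent modes that arise when
    # tightly linked markers compete for one signal.
    if (!is.null(swap_pairs) && nrow(swap_pairs) > 0) {
      np <- nrow(swap_pairs)
      take <- if (np > 400) sample.int(np, 400) else sample.int(np)
      logu2 <- log(stats::runif(length(take)))
      for (s in seq_along(take)) {
        i <- swap_pairs$i[take[s]]; j <- swap_pairs$j[take[s]]
        d_s <- beta[j] - beta[i]
        if (d_s == 0) next
        u_vec <- X[, i] - X[, j]
        uu <- xtx_diag[i] + xtx_diag[j] - 2 * swap_pairs$gij[take[s]]
        ur <- sum(u_vec * resid_cur)
        ll_diff <- (2 * d_s * ur - d_s^2 * uu) / (2 * sigma2)
        if (logu2[s] < ll_diff) {
          beta[c(i, j)] <- beta[c(j, i)]
          log_lambda[c(i, j)] <- log_lambda[c(j, i)]
          resid_cur <- resid_cur - d_s * u_vec
        }
      }
    }
    fitted <- y - b0 - resid_cur

    if (it > config$warmup) {
      k <- it - config$warmup
      out_beta[k, ] <- beta
      out[k, ] <- c(b0, sqrt(sigma2), exp(log_tau), sqrt(c2))
    }
  }
  list(beta = out_beta, scalars = out)
}

#' Fit the regularized-horseshoe marker model by MCMC
#'
#' Samples the posterior of the linear model
#' `y = b0 + X beta + e`, `e ~ Normal(0, sigma^2)`, with the regularized
#' horseshoe prior on the standardized coefficients:
#' `beta_j ~ Normal(0, tau^2 * lambda_tilde_j^2)`,
#' `lambda_tilde_j^2 = c^2 lambda_j^2 / (c^2 + tau^2 lambda_j^2)`,
#' `lambda_j ~ half-Cauchy(0, 1)`, `tau ~ half-Cauchy(0, tau0)`, and slab
#' `c^2 ~ scaled-inv-chi-square(slab_df, slab_scale^2)`, with `tau0` from
#' [compute_tau0()]. The sampler alternates a conjugate Gaussian block for
#' `beta` (closed-form ridge conditional), conjugate inverse-gamma for
#' `sigma^2`, and exact univariate slice updates on the log local/global/slab
#' scales. Chains use independent seeded streams.
#'
#' @param input An `hs_scan_input` from [prepare_scan()], or a list with
#'   standardized `X` and `y`.
#' @param config An [hs_config()].
#' @return A list of class `hs_fit`: `beta` (draws x markers), `intercept`,
#'   `sigma`, `tau`, `c`, `chain` (integer label per draw), `tau0`, `config`,
#'   `input`, and `convergence` (split-R-hat report from [gelman_rubin()]).
#' @export
fit_horseshoe <- function(input, config = hs_config()) {
  X <- input$X; y <- input$y
  stop_if_not(is.matrix(X) && length(y) == nrow(X), "X/y dimensions inconsistent")
  D <- ncol(X); n <- nrow(X)
  stop_if_not(config$p0 < D, "p0 (%s) must be smaller than the number of markers (%s)",
              config$p0, D)
  tau0 <- compute_tau0(config$p0, D, n, sigma_proxy = 1)

  # fixed list of tightly correlated marker pairs for the swap move
  swap_pairs <- NULL
  if (D >= 3) {
    G <- crossprod(X)
    nrm <- sqrt(diag(G))
    C <- abs(G / outer(nrm, nrm))
    diag(C) <- 0
    pr <- which(C > 0.4 & upper.tri(C), arr.ind = TRUE)
    if (nrow(pr) > 0) {
      ord <- order(C[pr], decreasing = TRUE)
      pr <- pr[ord[seq_len(min(4L * D, nrow(pr)))], , drop = FALSE]
      swap_pairs <- tibble::tibble(i = pr[, 1], j = pr[, 2], gij = G[pr])
    }
  }

  engine <- config$engine %||% "cpp"
  seeds <- derive_seeds(config$seed, config$chains)
  chains <- lapply(seq_len(config$chains), function(ch) {
    if (engine == "cpp") {
      old <- get_rng_state(); on.exit(restore_rng_state(old))
      set.seed(seeds[ch])
      res <- .hs_chain_cpp(
        X, y, tau0,
        as.integer(config$warmup), as.integer(config$iter),
        config$slab_df, config$slab_scale^2,
        is.null(config$slab_fixed),
        (config$slab_fixed %||% config$slab_scale)^2,
        is.null(config$sigma_fixed), (config$sigma_fixed %||% 1)^2,
        isTRUE(config$intercept), config$a_sigma, config$b_sigma,
        if (is.null(swap_pairs)) integer(0) else as.integer(swap_pairs$i - 1L),
        if (is.null(swap_pairs)) integer(0) else as.integer(swap_pairs$j - 1L),
        if (is.null(swap_pairs)) numeric(0) else swap_pairs$gij
      )
      colnames(res$scalars) <- c("intercept", "sigma", "tau", "c")
      res
    } else {
      run_hs_chain_r(X, y, tau0, config, seeds[ch], swap_pairs = swap_pairs)
    }
  })

  beta <- do.call(rbind, lapply(chains, `[[`, "beta"))
  colnames(beta) <- colnames(X)
  scal <- do.call(rbind, lapply(chains, `[[`, "scalars"))
  fit <- structure(
    list(
      beta = beta,
      intercept = scal[, "intercept"],
      sigma = scal[, "sigma"],
      tau = scal[, "tau"],
      c = scal[, "c"],
      chain = rep(seq_len(config$chains), each = config$iter),
      tau0 = tau0, config = config, input = input
    ),
    class = "hs_fit"
  )
  fit$convergence <- if (config$chains >= 2) gelman_rubin(fit) else NULL
  fit
}

#' @export
print.hs_fit <- function(x, ...) {
  cat(sprintf(
    "Regularized-horseshoe fit: %d markers, %d individuals, %d chains x %d draws (tau0 = %.3g)\n",
    ncol(x$beta), length(x$input$y),
    x$config$chains, x$config$iter, x$tau0
  ))
  if (!is.null(x$convergence)) {
    cat(sprintf("  max split-R-hat = %.3f (%s threshold %.2f)\n",
                max(x$convergence$rhat, na.rm = TRUE),
                if (attr(x$convergence, "pass")) "passes" else "FAILS",
                x$config$rhat_threshold))
  }
  invisible(x)
}

# ---- convergence ----------------------------------------------------------

split_chains <- function(draws, chain) {
  # draws: vector; returns matrix iterations x (2 * n_chains) of half-chains
  ch <- split(draws, chain)
  halves <- unlist(lapply(ch, function(v) {
    h <- floor(length(v) / 2)
    list(v[seq_len(h)], v[h + seq_len(h)])
  }), recursive = FALSE)
  do.call(cbind, halves)
}

rhat_one <- function(draws, chain) {
  m <- split_chains(draws, chain)
  nit <- nrow(m)
  if (nit < 2) return(NA_real_)
  W <- mean(apply(m, 2, stats::var))
  B <- nit * stats::var(colMeans(m))
  if (!is.finite(W) || W == 0) return(1) # degenerate constant chains
  sqrt(((nit - 1) / nit * W + B / nit) / W)
}

ess_one <- function(draws, chain) {
  m <- split_chains(draws, chain)
  nit <- nrow(m); nch <- ncol(m)
  if (nit < 4) return(NA_real_)
  W <- mean(apply(m, 2, stats::var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- nit * stats::var(colMeans(m))
  var_plus <- (nit - 1) / nit * W + B / nit
  lag_max <- min(nit - 2, 200)
  acov <- sapply(seq_len(nch), function(j) {
    a <- stats::acf(m[, j], lag.max = lag_max, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    a
  })
  rho <- 1 - (W - rowMeans(acov)[-1]) / var_plus
  # Geyer initial positive sequence on paired sums
  npair <- floor(length(rho) / 2)
  if (npair < 1) return(nit * nch)
  psums <- rho[2 * seq_len(npair) - 1] + rho[2 * seq_len(npair)]
  cut <- which(psums < 0)
  if (length(cut)) psums <- psums[seq_len(cut[1] - 1)]
  tau_int <- 1 + 2 * sum(pmax(psums, 0))
  max(nit * nch / tau_int, 1)
}

#' Split-R-hat convergence diagnostics
#'
#' Gelman-Rubin potential scale reduction with each chain split in half
#' (between/within half-chain variance ratio), plus a basic effective sample
#' size, for every monitored parameter (each marker coefficient, the
#' intercept, `sigma`, and `tau`). Constant chains yield R-hat 1 and are
#' flagged degenerate.
#'
#' @param fit An `hs_fit` (needs >= 2 chains).
#' @return Tibble (`parameter`, `rhat`, `ess`, `degenerate`) with attribute
#'   `"pass"`: `TRUE` iff all R-hat values are below the configured threshold.
#' @export
gelman_rubin <- function(fit) {
  stop_if_not(inherits(fit, "hs_fit"), "fit must be an hs_fit")
  stop_if_not(fit$config$chains >= 2, "R-hat requires at least 2 chains")
  pars <- c(as.list(as.data.frame(fit$beta)),
            list(intercept = fit$intercept, sigma = fit$sigma, tau = fit$tau))
  names(pars) <- c(colnames(fit$beta), "intercept", "sigma", "tau")
  if (!is.null(fit$config$sigma_fixed)) pars$sigma <- NULL
  rh <- vapply(pars, rhat_one, numeric(1), chain = fit$chain)
  degen <- vapply(pars, function(v) stats::var(v) == 0, logical(1))
  ess <- vapply(pars, ess_one, numeric(1), chain = fit$chain)
  out <- tibble::tibble(parameter = names(pars), rhat = unname(rh),
                        ess = unname(ess), degenerate = unname(degen))
  attr(out, "pass") <- all(out$rhat < fit$config$rhat_threshold, na.rm = TRUE)
  out
}

# ---- broom-style methods --------------------------------------------------

#' Tidy a horseshoe fit
#'
#' Posterior summaries for every marker coefficient: mean, SD, and an
#' equal-tailed credible interval, on the original trait scale per allele
#' copy (`original_scale = TRUE`) or the standardized scale used by the
#' sampler.
#'
#' @param x An `hs_fit`.
#' @param conf_level Credible level (default 0.95).
#' @param original_scale Back-transform to trait units (default `TRUE`).
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `std.error`, `conf.low`, `conf.high`.
#' @method tidy hs_fit
#' @export
tidy.hs_fit <- function(x, conf_level = 0.95, original_scale = TRUE, ...) {
  b <- x$beta
  if (original_scale && !is.null(x$input$y_scale)) {
    b <- sweep(b, 2, x$input$y_scale / x$input$x_scale, "*")
  }
  a <- (1 - conf_level) / 2
  qs <- apply(b, 2, stats::quantile, probs = c(a, 1 - a))
  tibble::tibble(
    term = colnames(b),
    estimate = colMeans(b),
    std.error = apply(b, 2, stats::sd),
    conf.low = qs[1, ],
    conf.high = qs[2, ]
  )
}

#' Glance at a horseshoe fit
#'
#' @param x An `hs_fit`.
#' @param ... Unused.
#' @return One-row tibble: sizes, `tau0`, `max_rhat`, `converged`.
#' @method glance hs_fit
#' @export
glance.hs_fit <- function(x, ...) {
  tibble::tibble(
    n = x$input$n %||% nrow(x$input$X),
    d = ncol(x$beta),
    chains = x$config$chains,
    draws = nrow(x$beta),
    tau0 = x$tau0,
    max_rhat = if (!is.null(x$convergence)) max(x$convergence$rhat, na.rm = TRUE) else NA_real_,
    converged = if (!is.null(x$convergence)) attr(x$convergence, "pass") else NA
  )
}

#' Plot posterior coefficient intervals of a horseshoe fit
#'
#' Posterior means with 95% equal-tailed intervals for each marker, ordered
#' along the genetic map when the scan input carries one.
#'
#' @param object An `hs_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hs_fit
#' @export
autoplot.hs_fit <- function(object, ...) {
  td <- tidy.hs_fit(object)
  if (!is.null(object$input$map)) {
    td <- dplyr::left_join(td, object$input$map, by = c(term = "marker")) |>
      dplyr::arrange(.data$lg, .data$pos_cm) |>
      dplyr::mutate(index = dplyr::row_number(), lg = factor(.data$lg))
    p <- ggplot2::ggplot(td, ggplot2::aes(.data$index, .data$estimate,
                                          colour = .data$lg))
  } else {
    td <- dplyr::mutate(td, index = dplyr::row_number())
    p <- ggplot2::ggplot(td, ggplot2::aes(.data$index, .data$estimate))
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$conf.low,
                                         ymax = .data$conf.high), alpha = 0.6) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "marker (map order)", y = "effect (trait units/allele)",
                  colour = "LG") +
    ggplot2::theme_minimal()
}
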