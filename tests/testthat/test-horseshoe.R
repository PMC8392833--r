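test_that("tau0 calibration matches its closed form", {
  expect_equal(compute_tau0(5, 486, 252), 5 / 481 / sqrt(252), tolerance = 1e-12)
  expect_equal(compute_tau0(5, 486, 252), 6.5482e-4, tolerance = 1e-4)
  expect_equal(compute_tau0(5, 10, 1), 1)
  expect_equal(compute_tau0(1, 2, 100, sigma_proxy = 2), 0.2)
  expect_error(compute_tau0(10, 10, 50), "smaller")
  expect_error(compute_tau0(0, 10, 50), "positive")
})

test_that("prepare_scan standardizes, imputes, and round-trips", {
  set.seed(5)
  m <- matrix(rbinom(200, 1, 0.5), 50, 4)
  m[1:15, 2] <- NA
  m[, 4] <- 1 # zero variance
  g <- geno_tbl(m, ids = sprintf("i%02d", 1:50))
  ph <- tibble::tibble(id = g$id, y = rnorm(50) * 3 + 10)
  ph$y[1:5] <- NA
  expect_warning(inp <- prepare_scan(g, ph, "y"), "zero-variance")
  expect_equal(inp$n, 45)
  expect_equal(inp$d, 3)
  expect_equal(unname(colMeans(inp$X)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(inp$X, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_equal(mean(inp$y), 0, tolerance = 1e-12)
  # imputed cells equal the mean of the marker's observed calls
  obs_mean <- mean(m[16:50, 2])        # rows 6..15 are NA among kept ids 6..50
  imp <- inp$X_raw[inp$ids %in% g$id[6:15], 2]
  expect_equal(unname(imp), rep(obs_mean, 10))
  # back-transform recovers the raw codes
  back <- sweep(sweep(inp$X, 2, inp$x_scale, "*"), 2, inp$x_center, "+")
  expect_equal(unname(back), unname(inp$X_raw), tolerance = 1e-12)
  # all phenotypes missing -> error
  ph2 <- dplyr::mutate(ph, y = NA_real_)
  expect_error(prepare_scan(g, ph2, "y"), "fewer than 3")
})

test_that("the coefficient block reproduces the closed-form ridge posterior", {
  set.seed(9)
  n <- 60; D <- 4
  X <- scale(matrix(rbinom(n * D, 1, 0.5), n, D))
  beta_true <- c(1, -0.5, 0, 0)
  y <- drop(X %*% beta_true + rnorm(n))
  sigma2 <- 1.3
  v <- c(0.5, 0.2, 0.05, 1.5) # frozen prior variances

  # independent closed form
  A <- crossprod(X) / sigma2 + diag(1 / v)
  Sigma <- solve(A)
  mu <- drop(Sigma %*% crossprod(X, y)) / sigma2

  mom <- hsqtl:::beta_conditional_moments(X, y, sigma2, v)
  expect_equal(mom$mean, mu, tolerance = 1e-10)
  expect_equal(mom$cov, Sigma, tolerance = 1e-10)

  # the sampling routine (both algebraic routes) matches in distribution
  draws_d <- t(replicate(4000, hsqtl:::draw_beta(X, crossprod(X), y, sigma2, v)))
  expect_equal(unname(colMeans(draws_d)), unname(mu), tolerance = 0.05)
  expect_equal(unname(cov(draws_d)), unname(Sigma), tolerance = 0.05)
  # force the n x n auxiliary route by making D > 2.1 * n
  n2 <- 10; D2 <- 30
  X2 <- scale(matrix(rnorm(n2 * D2), n2, D2))
  y2 <- rnorm(n2)
  v2 <- runif(D2, 0.01, 0.5)
  A2 <- crossprod(X2) / 1 + diag(1 / v2)
  mu2 <- drop(solve(A2, crossprod(X2, y2)))
  draws_n <- t(replicate(4000, hsqtl:::draw_beta(X2, NULL, y2, 1, v2)))
  expect_equal(unname(colMeans(draws_n)), unname(mu2), tolerance = 0.08)
})

test_that("MCMC marginals match the dense-grid quadrature oracle (D = 2)", {
  set.seed(42)
  n <- 30
  X <- matrix(rbinom(2 * n, 1, 0.5), n, 2)
  X <- scale(X); colnames(X) <- c("m1", "m2")
  y <- drop(0.8 * X[, 1] + rnorm(n)); y <- (y - mean(y)) / sd(y)
  tau0 <- compute_tau0(1, 2, n)

  q <- hs_quadrature(X, y, tau0, sigma = 1, slab = 2)
  cfg <- hs_config(p0 = 1, chains = 4, warmup = 500, iter = 2500,
                   sigma_fixed = 1, slab_fixed = 2, intercept = FALSE, seed = 7)
  fit <- fit_horseshoe(list(X = X, y = y, n = n, d = 2), cfg)
  expect_lt(max(abs(colMeans(fit$beta) - q$mean)), 0.02)
  expect_lt(max(abs(apply(fit$beta, 2, sd) - q$sd)), 0.03)

  # the R reference engine targets the same posterior
  cfg_r <- cfg; cfg_r$engine <- "r"; cfg_r$chains <- 2; cfg_r$iter <- 1500
  fit_r <- fit_horseshoe(list(X = X, y = y, n = n, d = 2), cfg_r)
  expect_lt(max(abs(colMeans(fit_r$beta) - q$mean)), 0.03)
})

test_that("posterior concentrates on a strong single effect", {
  set.seed(13)
  n <- 200
  g <- rbinom(n, 1, 0.5)
  y <- 2 * g + rnorm(n)           # true effect: 2 trait units per allele
  ys <- (y - mean(y)) / sd(y)
  # p0 must be < D, so pad with a noise marker
  X2 <- cbind(scale(g), scale(rbinom(n, 1, 0.5)))
  colnames(X2) <- c("m1", "m2")
  cfg <- hs_config(p0 = 1, chains = 2, warmup = 300, iter = 1000, seed = 3)
  fit <- fit_horseshoe(list(X = X2, y = ys, n = n, d = 2), cfg)
  b_orig <- fit$beta[, "m1"] * sd(y) / sd(g)
  expect_lt(abs(mean(b_orig) - 2), 3 * sd(b_orig))
})

test_that("shrinkage under a pure-noise response keeps intervals on zero", {
  set.seed(77)
  n <- 120; D <- 100
  X <- scale(matrix(rbinom(n * D, 1, 0.5), n, D))
  colnames(X) <- sprintf("m%03d", 1:D)
  y <- rnorm(n); y <- (y - mean(y)) / sd(y)
  cfg <- hs_config(p0 = 5, chains = 2, warmup = 200, iter = 600, seed = 19)
  fit <- fit_horseshoe(list(X = X, y = y, n = n, d = D), cfg)
  td <- tidy(fit, original_scale = FALSE)
  covered <- mean(td$conf.low <= 0 & td$conf.high >= 0)
  expect_gte(covered, 0.95)
})

test_that("permuting marker columns permutes posterior summaries identically", {
  set.seed(23)
  n <- 80; D <- 12
  X <- scale(matrix(rbinom(n * D, 1, 0.5), n, D))
  colnames(X) <- sprintf("m%02d", 1:D)
  y <- drop(X[, 3] * 0.8 + rnorm(n)); y <- (y - mean(y)) / sd(y)
  cfg <- hs_config(p0 = 2, chains = 2, warmup = 200, iter = 500, seed = 4)
  fit1 <- fit_horseshoe(list(X = X, y = y, n = n, d = D), cfg)
  perm <- c(4, 1, 3, 2, 7, 5, 6, 12, 8, 9, 11, 10)
  fit2 <- fit_horseshoe(list(X = X[, perm], y = y, n = n, d = D), cfg)
  m1 <- colMeans(fit1$beta)[colnames(X)[perm]]
  m2 <- colMeans(fit2$beta)
  # identical modulo MC noise (RNG stream couples to column order, so the
  # draws differ but the posterior is exchangeable)
  expect_equal(unname(m1), unname(m2), tolerance = 0.05)
})

test_that("decreasing p0 weakly decreases the count of 95% CIs excluding zero", {
  set.seed(91)
  n <- 100; D <- 40
  X <- scale(matrix(rbinom(n * D, 1, 0.5), n, D))
  colnames(X) <- sprintf("m%02d", 1:D)
  y <- drop(X[, 1] - 0.8 * X[, 2] + 0.6 * X[, 3] + rnorm(n))
  y <- (y - mean(y)) / sd(y)
  count_sig <- function(p0) {
    cfg <- hs_config(p0 = p0, chains = 2, warmup = 200, iter = 600, seed = 5)
    td <- tidy(fit_horseshoe(list(X = X, y = y, n = n, d = D), cfg))
    sum(td$conf.low > 0 | td$conf.high < 0)
  }
  expect_lte(count_sig(1), count_sig(8))
})

test_that("split-R-hat flags unmixed chains and passes well-mixed ones", {
  set.seed(6)
  mk_fit <- function(draws_per_chain) {
    structure(list(
      beta = matrix(draws_per_chain, ncol = 1, dimnames = list(NULL, "m1")),
      intercept = draws_per_chain, sigma = abs(draws_per_chain) + 1,
      tau = abs(draws_per_chain) + 0.1,
      chain = rep(1:4, each = length(draws_per_chain) / 4),
      config = hs_config(p0 = 1, chains = 4, warmup = 0, iter = length(draws_per_chain) / 4)
    ), class = "hs_fit")
  }
  good <- mk_fit(rnorm(10000))
  gr <- gelman_rubin(good)
  expect_lt(max(gr$rhat), 1.01)
  expect_true(attr(gr, "pass"))

  bad_draws <- c(rnorm(5000), rnorm(5000, 5))  # chains 1-2 vs 3-4 disagree
  bad <- mk_fit(bad_draws)
  gr2 <- gelman_rubin(bad)
  expect_gt(max(gr2$rhat), 1.5)
  expect_false(attr(gr2, "pass"))

  # constant chains are degenerate, R-hat treated as 1
  const <- mk_fit(rep(1, 8000))
  gr3 <- gelman_rubin(const)
  expect_equal(gr3$rhat[gr3$parameter == "m1"], 1)
  expect_true(gr3$degenerate[gr3$parameter == "m1"])

  one_chain <- good; one_chain$config$chains <- 1
  expect_error(gelman_rubin(one_chain), "2 chains")
})

test_that("tidy and glance summarize fits on the requested scale", {
  set.seed(3)
  n <- 60
  X <- scale(matrix(rbinom(n * 3, 1, 0.5), n, 3))
  colnames(X) <- c("a", "b", "c")
  y <- drop(X[, 1] + rnorm(n))
  g <- geno_tbl(matrix((X > 0) * 1, n, 3), ids = sprintf("i%02d", 1:n))
  names(g) <- c("id", "a", "b", "c")
  ph <- tibble::tibble(id = g$id, t = y)
  inp <- prepare_scan(g, ph, "t")
  cfg <- hs_config(p0 = 1, chains = 2, warmup = 150, iter = 400, seed = 8)
  fit <- fit_horseshoe(inp, cfg)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "conf.low", "conf.high"))
  expect_equal(td$term, c("a", "b", "c"))
  td_std <- tidy(fit, original_scale = FALSE)
  expect_equal(td$estimate, td_std$estimate * inp$y_scale / inp$x_scale,
               tolerance = 1e-10, ignore_attr = TRUE)
  gl <- glance(fit)
  expect_equal(gl$d, 3)
  expect_equal(gl$draws, 800)
  expect_s3_class(autoplot(fit), "ggplot")
})
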