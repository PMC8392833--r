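test_that("PSIS-LOO matches exact closed-form LOO for a conjugate Gaussian model", {
  # y_i ~ N(mu, s0^2) with known s0 and conjugate prior mu ~ N(0, v0):
  # both the posterior and every leave-one-out predictive are exact.
  set.seed(101)
  n <- 50; s0 <- 1.2; v0 <- 10
  y <- rnorm(n, 1.5, s0)

  post_var <- 1 / (n / s0^2 + 1 / v0)
  post_mean <- post_var * sum(y) / s0^2
  exact_loo <- sum(vapply(seq_len(n), function(i) {
    vi <- 1 / ((n - 1) / s0^2 + 1 / v0)
    mi <- vi * sum(y[-i]) / s0^2
    dnorm(y[i], mi, sqrt(s0^2 + vi), log = TRUE)
  }, numeric(1)))

  S <- 4000
  mu_draws <- rnorm(S, post_mean, sqrt(post_var))
  fit <- structure(list(
    beta = matrix(numeric(0), S, 0), intercept = mu_draws,
    sigma = rep(s0, S)
  ), class = "hs_fit")
  input <- list(X = matrix(numeric(0), n, 0), y = y)
  loo <- psis_loo(fit, input)
  expect_lt(abs(loo$elpd - exact_loo), 0.5)
  expect_true(all(loo$pointwise$pareto_k < 0.7, na.rm = TRUE))
})

test_that("the generalized-Pareto tail fit recovers known shapes", {
  set.seed(55)
  rgpd <- function(n, xi, sigma) sigma * (runif(n)^(-xi) - 1) / xi
  for (xi in c(0.2, 0.5)) {
    x <- rgpd(4000, xi, 1)
    f <- hsqtl:::gpd_fit(x)
    expect_lt(abs(f$xi - xi), 0.1)
    expect_lt(abs(f$sigma - 1), 0.15)
  }
})

test_that("the LOO gate opens only for informative reference models", {
  set.seed(33)
  # identical models -> difference 0, gate closed
  n <- 40; S <- 500
  fit <- structure(list(beta = matrix(numeric(0), S, 0),
                        intercept = rnorm(S, 0, 0.1), sigma = rep(1, S)),
                   class = "hs_fit")
  input <- list(X = matrix(numeric(0), n, 0), y = rnorm(n))
  l1 <- psis_loo(fit, input)
  expect_false(as.logical(loo_gate(l1, l1)))
  expect_equal(attr(loo_gate(l1, l1), "elpd_diff"), 0)

  # a strong true effect (PVE ~20%, n=252) opens the gate decisively
  n <- 252
  g <- rbinom(n, 1, 0.5)
  y <- sqrt(0.2 / 0.8) * (g - mean(g)) / sd(g) + rnorm(n)
  geno <- geno_tbl(cbind(m1 = g, m2 = rbinom(n, 1, 0.5), m3 = rbinom(n, 1, 0.5)),
                   ids = sprintf("i%03d", 1:n))
  ph <- tibble::tibble(id = geno$id, t = y)
  inp <- prepare_scan(geno, ph, "t")
  cfg <- hs_config(p0 = 1, chains = 2, warmup = 200, iter = 500, seed = 2)
  hs <- fit_horseshoe(inp, cfg)
  loo_ref <- psis_loo(hs, inp)
  loo_null <- psis_loo(fit_null(inp, draws = 1000, seed = 3), inp)
  cmp <- loo_compare_pair(loo_ref, loo_null)
  expect_gt(cmp$elpd_diff, 2 * cmp$se_diff)
  expect_true(as.logical(loo_gate(loo_ref, loo_null)))

  # mismatched observation sets are rejected
  l3 <- psis_loo(fit, list(X = matrix(numeric(0), 39, 0), y = rnorm(39)))
  expect_error(loo_compare_pair(l1, l3), "different observation sets")
})

test_that("projection onto subsets behaves like least squares on fitted values", {
  set.seed(8)
  n <- 50; S <- 200
  x <- scale(rbinom(n, 1, 0.5))[, 1]
  X <- cbind(c1 = x, c2 = x) # identical duplicate columns
  beta <- matrix(1, S, 2, dimnames = list(NULL, c("c1", "c2")))
  fit <- structure(list(beta = beta, intercept = rep(0, S), sigma = rep(1, S)),
                   class = "hs_fit")
  input <- list(X = X, y = drop(2 * x + rnorm(n)), markers = c("c1", "c2"), n = n)

  # beta_ref = (1,1) on duplicate columns projects to coefficient 2 on one
  pr <- project_submodel(input, fit, "c1")
  expect_equal(unname(pr$beta[, 1]), rep(2, S), tolerance = 1e-10)
  expect_equal(pr$discrepancy, rep(0, S), tolerance = 1e-10)
  expect_equal(pr$sigma, fit$sigma, tolerance = 1e-10)

  # projecting onto the full span is the identity
  X2 <- cbind(c1 = x, c2 = scale(rnorm(n))[, 1])
  beta2 <- matrix(rnorm(S * 2), S, 2, dimnames = list(NULL, c("c1", "c2")))
  fit2 <- structure(list(beta = beta2, intercept = rnorm(S), sigma = rep(1, S)),
                    class = "hs_fit")
  input2 <- list(X = X2, y = rnorm(n), markers = c("c1", "c2"), n = n)
  pr2 <- project_submodel(input2, fit2, c("c1", "c2"))
  expect_equal(unname(pr2$beta), unname(beta2), tolerance = 1e-8)

  # a subset orthogonal to the signal concentrates near zero
  x_orth <- scale(residuals(lm(rnorm(n) ~ x)))[, 1]
  X3 <- cbind(sig = x, null = x_orth)
  beta3 <- cbind(rnorm(S, 1, 0.05), rep(0, S))
  colnames(beta3) <- c("sig", "null")
  fit3 <- structure(list(beta = beta3, intercept = rep(0, S), sigma = rep(1, S)),
                    class = "hs_fit")
  input3 <- list(X = X3, y = rnorm(n), markers = colnames(X3), n = n)
  pr3 <- project_submodel(input3, fit3, "null")
  expect_lt(max(abs(colMeans(pr3$beta))), 0.05)

  # rank-deficient subset rejected
  expect_error(project_submodel(input, fit, c("c1", "c2")), "rank-deficient")
})

test_that("forward search finds planted effects before noise and stops sparsely", {
  set.seed(14)
  n <- 252; D <- 30
  X <- scale(matrix(rbinom(n * D, 1, 0.5), n, D))
  colnames(X) <- sprintf("m%02d", 1:D)
  y <- drop(sqrt(0.15 / 0.85) * X[, 5] + rnorm(n))
  y <- (y - mean(y)) / sd(y)
  inp <- list(X = X, y = y, n = n, d = D, markers = colnames(X))
  cfg <- hs_config(p0 = 2, chains = 2, warmup = 200, iter = 500, seed = 6)
  fit <- fit_horseshoe(inp, cfg)
  sel <- forward_select(inp, fit)
  expect_equal(sel$path[1], "m05")
  expect_lte(sel$size, 4)
  expect_gte(sel$size, 1)
  expect_true("m05" %in% sel$markers)
  # scores tibble covers sizes 0..path length; the gap to the reference
  # shrinks as the true effect enters and SEs are well defined
  expect_equal(sel$scores$size, 0:length(sel$path))
  expect_lt(sel$scores$delta_ref[2], sel$scores$delta_ref[1])
  expect_true(all(sel$scores$se_delta >= 0))
})

test_that("PVE is the squared correlation in percent", {
  set.seed(4)
  g <- rbinom(400, 1, 0.5)
  expect_equal(pve(g * 2.5 - 1, g), 100)
  y_ind <- rnorm(400)
  expect_lt(pve(y_ind, g), 3)
  # constructed r = 0.3 exactly -> PVE 9
  x <- scale(rnorm(400))[, 1]
  e <- scale(residuals(lm(rnorm(400) ~ x)))[, 1]
  y <- 0.3 * x + sqrt(1 - 0.09) * e
  expect_equal(pve(y, x), 9, tolerance = 1e-6)
  expect_warning(out <- pve(y_ind, rep(1, 400)), "constant")
  expect_true(is.na(out))
  expect_error(pve(c(1, 2), c(0, 1)), "fewer than 3")
})

test_that("credible-interval classification follows the two-tier rule", {
  S <- 2000
  mk_proj <- function(draws) {
    structure(list(beta = matrix(draws, ncol = 1, dimnames = list(NULL, "mk")),
                   intercept = rep(0, S), sigma = rep(1, S), markers = "mk"),
              class = "hs_projection")
  }
  input <- list(
    y_raw = rnorm(S), X_raw = matrix(rbinom(S, 1, 0.5), S, 1,
                                     dimnames = list(NULL, "mk")),
    x_scale = c(mk = 1), y_scale = 1, trait = "t"
  )
  map <- tibble::tibble(marker = "mk", lg = 3L, pos_cm = 12.5)

  # 95% interval excluding zero -> significant
  set.seed(1)
  r1 <- classify_qtls(mk_proj(rnorm(S, 0.5, 0.1)), input, map)
  expect_equal(r1$tier, "significant")
  expect_equal(r1$sig, "**")
  expect_equal(r1$lg, 3L)

  # 80% excludes zero but 95% does not -> suggestive
  b <- rnorm(S, 1.5, 1) * 0.1 # q10 ~ 0.02 > 0, q2.5 ~ -0.05 < 0
  r2 <- classify_qtls(mk_proj(b), input, map)
  expect_equal(r2$tier, "suggestive")
  expect_equal(r2$sig, "*")

  # symmetric at zero -> not reported
  r3 <- classify_qtls(mk_proj(rnorm(S, 0, 0.2)), input, map)
  expect_equal(nrow(r3), 0)
})

test_that("tier invariants hold on every reported row of a real scan", {
  set.seed(70)
  st <- sim_study(n_lg = 4, markers_per_lg = 30, qtl_pve = c(0.12, 0.10),
                  seed = 70)
  qc <- qc_markers(st$cross$geno, st$map)
  sp <- suppressMessages(suppressWarnings(split_parental_maps(qc$geno, qc$map)))
  cfg <- hs_config(p0 = 2, chains = 2, warmup = 200, iter = 500, seed = 71)
  sc <- suppressWarnings(scan_trait(sp$male$geno, sp$male$map, st$pheno,
                                    "trait1", cfg, halt_on_rhat = FALSE))
  rep <- sc$report
  if (nrow(rep) > 0) {
    sig <- rep[rep$tier == "significant", ]
    expect_true(all(sig$ci95_lo > 0 | sig$ci95_hi < 0))
    sug <- rep[rep$tier == "suggestive", ]
    expect_true(all(sug$ci80_lo > 0 | sug$ci80_hi < 0))
    expect_true(all(sug$ci95_lo <= 0 & sug$ci95_hi >= 0))
    expect_true(all(rep$pve >= 0 & rep$pve <= 100))
  }
  # a strong planted QTL is found
  expect_gte(nrow(rep), 1)
})

test_that("a strong QTL is detected across the p0 sensitivity range", {
  st <- sim_study(n_lg = 3, markers_per_lg = 24, qtl_pve = 0.15, seed = 81)
  qc <- qc_markers(st$cross$geno, st$map)
  sp <- suppressMessages(suppressWarnings(split_parental_maps(qc$geno, qc$map)))
  cfg <- hs_config(chains = 2, warmup = 200, iter = 400, seed = 82)
  sens <- suppressWarnings(p0_sensitivity(sp$male$geno, sp$male$map, st$pheno,
                                          "trait1", cfg, p0_values = c(1, 5, 9)))
  # the planted locus (or a tightly linked marker) appears at every p0
  for (p in c(1, 5, 9)) {
    rows <- sens[sens$p0 == p, ]
    expect_true(any(rows$lg == st$truth$lg &
                      abs(rows$pos_cm - st$truth$pos_cm) <= 15),
                info = paste("p0 =", p))
  }
})
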