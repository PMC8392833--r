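test_that("map functions convert distance to recombination fraction", {
  expect_equal(recomb_fraction(0), 0)
  expect_equal(recomb_fraction(10), (1 - exp(-0.2)) / 2, tolerance = 1e-12)
  expect_equal(recomb_fraction(10), 0.090635, tolerance = 1e-5)
  expect_equal(recomb_fraction(1e6), 0.5, tolerance = 1e-9)
  expect_equal(recomb_fraction(10, "kosambi"), tanh(0.2) / 2, tolerance = 1e-12)
  # monotone increasing
  d <- seq(0, 300, by = 5)
  expect_true(all(diff(recomb_fraction(d)) > 0))
  expect_true(all(diff(recomb_fraction(d, "kosambi")) > 0))
  expect_error(recomb_fraction(-1), "negative|>= 0")
})

test_that("simulated pseudo-testcross markers segregate 1:1 and are reproducible", {
  map <- tibble::tibble(marker = "m1", lg = 1L, pos_cm = 0, seg_type = "AAxAB")
  cr <- sim_cross(map, n_progeny = 100000, missing_rate = 0, error_rate = 0, seed = 3)
  p1 <- mean(cr$geno$m1)
  se <- sqrt(0.25 / 100000)
  expect_lt(abs(p1 - 0.5), 4 * se)

  # byte-identical reruns from the same seed
  cr2 <- sim_cross(map, n_progeny = 100000, missing_rate = 0, error_rate = 0, seed = 3)
  expect_identical(cr$geno, cr2$geno)
})

test_that("linkage in simulated gametes matches the map function", {
  # co-inheritance at zero distance
  map0 <- tibble::tibble(marker = c("a", "b"), lg = 1L, pos_cm = c(5, 5),
                         seg_type = "AAxAB")
  cr0 <- sim_cross(map0, n_progeny = 500, missing_rate = 0, error_rate = 0, seed = 2)
  expect_identical(cr0$geno$a, cr0$geno$b)

  # recombinant fraction at 20 cM within 4 SE of the Haldane value
  map20 <- tibble::tibble(marker = c("a", "b"), lg = 1L, pos_cm = c(0, 20),
                          seg_type = "ABxAA")
  n <- 100000
  cr <- sim_cross(map20, n_progeny = n, missing_rate = 0, error_rate = 0, seed = 4)
  r_obs <- mean(cr$geno$a != cr$geno$b)
  r_exp <- recomb_fraction(20)
  expect_equal(r_exp, 0.16484, tolerance = 1e-4)
  expect_lt(abs(r_obs - r_exp), 4 * sqrt(r_exp * (1 - r_exp) / n))

  # estimated fraction inverts to the generating distance (Haldane inverse)
  d_est <- -50 * log(1 - 2 * r_obs)
  expect_lt(abs(d_est - 20), 1.5)
})

test_that("missingness and genotyping error are applied at the configured rates", {
  map <- tiny_map()
  cr <- sim_cross(map, n_progeny = 400, missing_rate = 0.15, error_rate = 0, seed = 9)
  m <- as.matrix(cr$geno[-1])
  expect_lt(abs(mean(is.na(m)) - 0.15), 0.01)
  # errors flip observed vs true calls
  cr_e <- sim_cross(map, n_progeny = 400, missing_rate = 0, error_rate = 0.05, seed = 9)
  two_class <- map$marker[map$seg_type != "ABxAB"]
  obs <- as.matrix(cr_e$geno[two_class])
  tru <- as.matrix(cr_e$geno_true[two_class])
  expect_lt(abs(mean(obs != tru) - 0.05), 0.01)
  expect_error(sim_cross(map, missing_rate = 1.2), "\\[0, 1\\]")
})

test_that("chi-square 1:1 rejections are calibrated at the nominal rate under the null", {
  # many error-free 1:1 markers at n=252: p < 0.001 should fire ~0.1% of the time
  map <- sim_genetic_map(n_lg = 10, markers_per_lg = 100, mean_gap_cm = 1e6,
                         p_seg = c(AAxAB = 1, ABxAA = 0, ABxAB = 0), seed = 21)
  hits <- 0L; total <- 0L
  for (s in 1:12) {
    cr <- sim_cross(map, n_progeny = 252, missing_rate = 0, error_rate = 0, seed = s)
    rep <- segregation_test(cr$geno)$report
    hits <- hits + sum(rep$decision == "dropped_segregation")
    total <- total + nrow(rep)
  }
  # 12000 markers, expected ~12 rejections; generous binomial band
  expect_gt(total, 10000)
  expect_lt(hits / total, 0.003)
})

test_that("phenotype simulation hits the requested per-locus variance fractions", {
  map <- tiny_map(seed = 8)
  cr <- sim_cross(map, n_progeny = 10000, missing_rate = 0, error_rate = 0, seed = 8)

  # single locus at 9% PVE: realized squared correlation concentrates
  spec <- tibble::tibble(trait = "t", lg = 1L,
                         pos_cm = stats::median(map$pos_cm[map$lg == 1]), pve = 0.09)
  ph <- sim_phenotypes(cr, spec, seed = 11)
  r2 <- stats::cor(ph$pheno$t, cr$geno_true[[ph$truth$marker]])^2
  expect_gt(r2, 0.08)
  expect_lt(r2, 0.10)

  # two orthogonal loci add variance
  spec2 <- tibble::tibble(trait = "t", lg = c(1L, 2L),
                          pos_cm = c(spec$pos_cm,
                                     stats::median(map$pos_cm[map$lg == 2])),
                          pve = c(0.05, 0.05))
  ph2 <- sim_phenotypes(cr, spec2, seed = 12)
  g <- as.matrix(cr$geno_true[ph2$truth$marker])
  r2tot <- summary(stats::lm(ph2$pheno$t ~ g))$r.squared
  expect_lt(abs(r2tot - 0.10), 0.02)

  # zero-PVE trait is pure noise
  ph0 <- sim_phenotypes(cr, traits = "noise", seed = 13)
  rs <- abs(stats::cor(ph0$pheno$noise, as.matrix(cr$geno_true[-1])))
  expect_lt(max(rs), 4 / sqrt(10000))

  expect_error(
    sim_phenotypes(cr, tibble::tibble(trait = "t", lg = 1L, pos_cm = 1,
                                      pve = c(0.6, 0.5))),
    "sum"
  )
})
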