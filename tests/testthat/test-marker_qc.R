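test_that("missingness filter uses a strict 20% threshold", {
  set.seed(2)
  m <- matrix(rbinom(252 * 3, 1, 0.5), 252, 3)
  m[1:51, 2] <- NA   # 51/252 = 0.2024 > 0.20 -> dropped
  m[1:50, 3] <- NA   # 50/252 = 0.1984 <= 0.20 -> kept
  g <- geno_tbl(m)
  out <- filter_missing(g)
  expect_equal(out$report$decision, c("kept", "dropped_missing", "kept"))
  expect_named(out$geno, c("id", "mk001", "mk003"))
  expect_equal(nrow(out$geno), 252) # individuals never removed
  # idempotent
  again <- filter_missing(out$geno)
  expect_identical(again$geno, out$geno)
})

test_that("segregation chi-square matches hand-computed worked examples", {
  g <- geno_tbl(cbind(
    perfect = rep(c(0, 1), each = 126),
    mild = rep(c(0, 1), c(150, 102)),
    distorted = rep(c(0, 1), c(170, 82))
  ))
  out <- segregation_test(g)
  rep <- out$report
  expect_equal(rep$chi_square, c(0, 9.142857, 30.73016), tolerance = 1e-6)
  expect_equal(rep$p_value[1], 1)
  expect_equal(rep$p_value[2], 0.0024969, tolerance = 1e-5)
  expect_equal(rep$p_value[3], 2.9652e-8, tolerance = 1e-4)
  expect_equal(rep$decision, c("kept", "kept", "dropped_segregation"))
  expect_named(out$geno, c("id", "perfect", "mild"))
  # marker with zero informative calls gets its own reason
  g2 <- geno_tbl(cbind(empty = rep(NA_real_, 10), ok = rep(c(0, 1), 5)))
  expect_equal(segregation_test(g2)$report$decision[1], "dropped_no_calls")
})

test_that("parental split sends marker types to the correct map", {
  map <- tibble::tibble(
    marker = c("a1", "a2", "b1", "x1"),
    lg = 1L, pos_cm = c(0, 5, 10, 15),
    seg_type = c("AAxAB", "AAxAB", "ABxAA", "ABxAB")
  )
  g <- geno_tbl(matrix(rbinom(40, 1, 0.5), 10, 4), ids = sprintf("i%02d", 1:10))
  names(g) <- c("id", map$marker)
  expect_message(sp <- split_parental_maps(g, map), "ABxAB")
  expect_named(sp$male$geno, c("id", "a1", "a2"))
  expect_named(sp$female$geno, c("id", "b1"))
  expect_equal(sp$excluded, "x1")
  # empty side warns
  map2 <- dplyr::filter(map, seg_type == "AAxAB")
  g2 <- dplyr::select(g, id, a1, a2)
  expect_warning(split_parental_maps(g2, map2), "female map set is empty")
  # unknown type rejected
  map3 <- dplyr::mutate(map, seg_type = replace(seg_type, 1, "ABxCD"))
  expect_error(split_parental_maps(g, map3), "unknown seg_type")
})

test_that("collinearity pruning drops one of each close, correlated pair", {
  set.seed(7)
  n <- 200
  base <- rbinom(n, 1, 0.5)
  noisy <- function(p) ifelse(runif(n) < p, 1 - base, base)
  m <- cbind(dup1 = base, dup2 = base,          # d = 0, r = 1
             near = noisy(0.25),                # r ~ 0.5 at 0.5 cM
             far = noisy(0.05))                 # r ~ 0.9 at 2 cM
  map <- tibble::tibble(marker = colnames(m), lg = 1L,
                        pos_cm = c(0, 0, 0.5, 2.5))
  g <- geno_tbl(m, ids = sprintf("i%03d", 1:n))
  names(g) <- c("id", map$marker)
  out <- prune_collinear(g, map)
  expect_equal(sum(out$report$decision == "dropped_collinear"), 1)
  expect_true(out$report$decision[out$report$marker == "dup2"] == "dropped_collinear")
  # pair at 0.5 cM with r ~ 0.5 and pair at 2 cM with r ~ 0.9 both survive
  expect_true(all(c("near", "far") %in% names(out$geno)))

  # tie-break prefers dropping the marker with more missing data
  m2 <- m
  m2[1:20, "dup1"] <- NA
  g2 <- geno_tbl(m2, ids = sprintf("i%03d", 1:n))
  names(g2) <- c("id", map$marker)
  out2 <- prune_collinear(g2, map)
  expect_equal(out2$report$decision[out2$report$marker == "dup1"], "dropped_collinear")

  # order-safety: shuffling input columns leaves the decision set unchanged
  g3 <- dplyr::select(g, id, far, dup2, near, dup1)
  out3 <- prune_collinear(g3, map)
  expect_setequal(out3$report$marker[out3$report$decision == "dropped_collinear"],
                  out$report$marker[out$report$decision == "dropped_collinear"])

  # idempotence
  out4 <- prune_collinear(out$geno, map)
  expect_equal(sum(out4$report$decision == "dropped_collinear"), 0)
  expect_error(prune_collinear(g, dplyr::slice(map, 1:3)), "unmapped")
})

test_that("qc chain combines decisions and keeps ABxAB markers out of the 1:1 test", {
  map <- tiny_map(seed = 44)
  cr <- sim_cross(map, n_progeny = 252, missing_rate = 0.05, error_rate = 0, seed = 44)
  out <- qc_markers(cr$geno, map)
  expect_equal(nrow(out$report), nrow(map))
  expect_true(all(out$report$decision %in%
    c("kept", "dropped_missing", "dropped_segregation", "dropped_no_calls",
      "dropped_collinear")))
  # ABxAB markers must never be dropped for 1:1 distortion
  abxab <- map$marker[map$seg_type == "ABxAB"]
  expect_false(any(out$report$decision[out$report$marker %in% abxab] ==
                     "dropped_segregation"))
  expect_equal(sort(setdiff(names(out$geno), "id")), sort(out$map$marker))
})
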