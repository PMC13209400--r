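toy_matrix <- function() {
  m <- rbind(c1 = c(TRUE, TRUE, TRUE),
             c2 = c(TRUE, TRUE, FALSE),
             c3 = c(FALSE, FALSE, TRUE),
             c4 = c(TRUE, FALSE, FALSE))
  colnames(m) <- c("g1", "g2", "g3")
  m
}

test_that("partition applies the core/accessory/unique definitions", {
  p <- partition(toy_matrix())
  expect_identical(p$core, "c1")
  expect_identical(p$accessory, "c2")
  expect_identical(p$unique$g3, "c3")
  expect_identical(p$unique$g1, "c4")
  # conservation: the three compartments exhaust the matrix
  expect_equal(p$counts$core + p$counts$accessory + p$counts$unique_total,
               p$counts$total)
  expect_error(partition(toy_matrix()[c(1, 2, 4), 1, drop = FALSE]),
               "2 genomes")
})

test_that("partition is idempotent and independent of row/column order", {
  sim <- default_sim()
  p1 <- partition(sim$matrix)
  set.seed(2)
  m2 <- sim$matrix[sample.int(nrow(sim$matrix)), sample.int(ncol(sim$matrix))]
  p2 <- partition(m2)
  expect_setequal(p1$core, p2$core)
  expect_setequal(p1$accessory, p2$accessory)
  expect_equal(p1$counts$unique_per_genome[sort(names(p1$unique))],
               p2$counts$unique_per_genome[sort(names(p2$unique))])
})

test_that("rarefaction on an all-core matrix is flat", {
  m <- matrix(TRUE, 5, 4, dimnames = list(paste0("c", 1:5), paste0("g", 1:4)))
  rc <- rarefaction_curves(m, n_permutations = 5, seed = 1)
  expect_equal(rc$pan_median, rep(5, 4))
  expect_equal(rc$core_median, rep(5, 4))
})

test_that("two-genome rarefaction enumerates both orderings exactly", {
  # 3 clusters only in A, 2 only in B, 5 shared
  m <- rbind(matrix(c(TRUE, FALSE), 3, 2, byrow = TRUE),
             matrix(c(FALSE, TRUE), 2, 2, byrow = TRUE),
             matrix(TRUE, 5, 2))
  dimnames(m) <- list(paste0("c", 1:10), c("A", "B"))
  rc <- rarefaction_curves(m, n_permutations = 20, seed = 99)
  expect_equal(rc$n_permutations, 2L)  # 2! orderings enumerated
  expect_equal(rc$pan_median, c(7.5, 10))
  expect_equal(rc$core_median, c(7.5, 5))
})

test_that("rarefaction curves are monotone per permutation and seed-stable", {
  sim <- default_sim()
  rc1 <- rarefaction_curves(sim$matrix, n_permutations = 8, seed = 5)
  rc2 <- rarefaction_curves(sim$matrix, n_permutations = 8, seed = 5)
  rc3 <- rarefaction_curves(sim$matrix, n_permutations = 8, seed = 6)
  expect_identical(rc1$pan, rc2$pan)
  expect_false(identical(rc1$pan[, -ncol(rc1$pan)], rc3$pan[, -ncol(rc3$pan)]))
  # endpoints are permutation-invariant
  n <- ncol(sim$matrix)
  expect_true(all(rc1$pan[, n] == nrow(sim$matrix)))
  expect_true(all(rc1$core[, n] == length(partition(sim$matrix)$core)))
  # every single permutation is monotone, not only the medians
  expect_true(all(apply(rc1$pan, 1, function(r) all(diff(r) >= 0))))
  expect_true(all(apply(rc1$core, 1, function(r) all(diff(r) <= 0))))
})

test_that("power-law fit is exact on noise-free data", {
  x <- 1:8
  f <- fit_power_law(x, 2 * x^0.5)
  expect_equal(f$A, 2, tolerance = 1e-9)
  expect_equal(f$b, 0.5, tolerance = 1e-9)
  expect_lt(f$rss, 1e-12)
  expect_true(f$open)
  fc <- fit_power_law(1:6, rep(5, 6))
  expect_equal(fc$b, 0, tolerance = 1e-12)
  expect_equal(fc$A, 5, tolerance = 1e-9)
  fsuper <- fit_power_law(1:6, 3 * (1:6)^1.4)
  expect_false(fsuper$open)
})

test_that("power-law fit recovers planted openness under 1% noise", {
  x <- 1:16
  b_hat <- vapply(1:5, function(i) {
    set.seed(100 + i)
    y <- 1000 * x^0.38 * exp(rnorm(16, 0, 0.01))
    fit_power_law(x, y)$b
  }, numeric(1))
  expect_true(all(abs(b_hat - 0.38) <= 0.03))
})

test_that("power-law fit rejects degenerate input", {
  expect_error(fit_power_law(1:2, c(1, 2)), "3 points")
  expect_error(fit_power_law(1:3, c(1, 0, 2)), "positive")
})

test_that("per-compartment COG profiles count clusters once per letter", {
  m <- toy_matrix()
  p <- partition(m)
  cogs <- list(c1 = c("T", "P"), c2 = "T", c3 = character(0), c4 = "S")
  prof <- partition_cog_profile(p, cogs)
  get <- function(comp, cat) prof$count[prof$compartment == comp &
                                          prof$category == cat]
  expect_equal(get("core", "T"), 1L)
  expect_equal(get("core", "P"), 1L)
  expect_equal(get("accessory", "T"), 1L)
  expect_equal(get("unique", "S"), 1L)
  expect_equal(sum(prof$count), 4L)
})
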