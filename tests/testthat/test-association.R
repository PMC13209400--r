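test_that("Fisher p-values match closed-form cases", {
  # 2 HTV carriers, 0 of 14 non-HTV: the most extreme 2-vs-14 table
  expect_equal(fisher_exact_2x2(2, 0, 0, 14), 1 / 120, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(0, 2, 0, 14), 1)
  expect_equal(fisher_exact_2x2(1, 1, 7, 7), 1)
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "negative")
})

test_that("Fisher p-values equal hypergeometric enumeration (margins <= 12)", {
  for (r1 in 0:12) for (r2 in 0:12) {
    if (r1 + r2 == 0) next
    for (a in 0:r1) {
      for (cc in unique(c(0, r2 %/% 2, r2))) {
        expect_equal(fisher_exact_2x2(a, r1 - a, cc, r2 - cc),
                     enum_fisher_p(a, r1 - a, cc, r2 - cc),
                     tolerance = 1e-9,
                     info = sprintf("(%d,%d|%d,%d)", a, r1 - a, cc, r2 - cc))
      }
    }
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  set.seed(7)
  for (i in 1:5) {
    p <- runif(sample(3:50, 1))^2
    q <- bh_adjust(p)
    expect_equal(q, stepup_bh(p))
    expect_true(all(q >= p))
    expect_equal(order(q[order(p)]), seq_along(p))  # rank-preserving
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("association testing excludes core and calls planted directions", {
  md <- data.frame(genome_id = sprintf("G%02d", 1:16),
                   environment = c("HTV", "HTV", rep("nonHTV", 14)),
                   name = sprintf("s%d", 1:16))
  m <- rbind(
    core1 = rep(TRUE, 16),
    htv_only = c(TRUE, TRUE, rep(FALSE, 14)),
    non_only = c(FALSE, FALSE, rep(TRUE, 14)),
    scattered = c(TRUE, FALSE, rep(c(TRUE, FALSE), 7)))
  colnames(m) <- md$genome_id
  res <- environment_association(m, md)
  expect_false("core1" %in% res$cluster_id)
  htv <- res[res$cluster_id == "htv_only", ]
  expect_equal(htv$p, 1 / 120, tolerance = 1e-12)
  expect_true(htv$significant)
  expect_identical(htv$direction, "HTV")
  non <- res[res$cluster_id == "non_only", ]
  expect_true(non$significant)
  expect_identical(non$direction, "nonHTV")
  expect_false(res[res$cluster_id == "scattered", "significant"])
  # q >= p everywhere; direction 'none' exactly for non-significant clusters
  expect_true(all(res$q >= res$p))
  expect_identical(res$direction != "none", res$significant)
})

test_that("attainable 2-vs-14 significance region matches enumeration", {
  # enumerate every (a, c) table with margins 2 and 14 and find which are
  # significant at alpha = 0.05; compare with the direction rules
  sig <- list()
  for (a in 0:2) for (cc in 0:14) {
    p <- enum_fisher_p(a, 2 - a, cc, 14 - cc)
    # a table whose exact p *equals* alpha (e.g. 91/1820 = 0.05) is not
    # significant; guard the float summation against that tie
    if (p < 0.05 && abs(p - 0.05) > 1e-9) sig[[length(sig) + 1L]] <- c(a, cc)
  }
  sig <- do.call(rbind, sig)
  htv_calls <- sig[sig[, 1] / 2 > sig[, 2] / 14, , drop = FALSE]
  non_calls <- sig[sig[, 1] / 2 < sig[, 2] / 14, , drop = FALSE]
  # HTV-specific calls need both HTV genomes and at most 1 non-HTV genome
  expect_true(all(htv_calls[, 1] == 2 & htv_calls[, 2] <= 1))
  # non-HTV-specific calls need zero HTV genomes and at least 13 non-HTV
  expect_true(all(non_calls[, 1] == 0 & non_calls[, 2] >= 13))
})

test_that("planted associations are recovered exactly on the study fixture", {
  sim <- default_sim()
  res <- environment_association(sim$matrix, sim$metadata, alpha = 0.05)
  called_htv <- res$cluster_id[res$significant & res$direction == "HTV"]
  called_non <- res$cluster_id[res$significant & res$direction == "nonHTV"]
  expect_setequal(called_htv, sim$truth$planted_htv)
  expect_setequal(called_non, sim$truth$planted_nonhtv)
  cnt <- association_counts(res)
  expect_equal(cnt$significant, 139L)
  expect_equal(cnt$htv, 57L)
  expect_equal(cnt$nonhtv, 82L)
})

test_that("significant counts are invariant under genome permutation", {
  sim <- default_sim()
  res1 <- environment_association(sim$matrix, sim$metadata)
  set.seed(3)
  perm <- sample.int(ncol(sim$matrix))
  res2 <- environment_association(sim$matrix[, perm], sim$metadata)
  expect_equal(sum(res1$significant), sum(res2$significant))
})
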