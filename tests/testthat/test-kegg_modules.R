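mod5 <- list(module_id = "M1",
             steps = list("K00001", c("K00002", "K00010"), "K00003",
                          "K00004", "K00005"))

test_that("module completeness follows the four-category rule", {
  all_kos <- c("K00001", "K00002", "K00003", "K00004", "K00005")
  expect_identical(module_completeness(mod5, all_kos)$category, "complete")
  # an alternative KO satisfies its step
  expect_identical(
    module_completeness(mod5, c("K00001", "K00010", "K00003", "K00004",
                                "K00005"))$category, "complete")
  expect_identical(module_completeness(mod5, all_kos[1:4])$category,
                   "almost_complete")  # 1 step missing
  expect_identical(module_completeness(mod5, all_kos[1:3])$category,
                   "almost_complete")  # 2 steps missing
  expect_identical(module_completeness(mod5, all_kos[1:2])$category,
                   "partially_complete")  # 3 missing, KOs present
  expect_identical(module_completeness(mod5, character(0))$category, "absent")
  expect_identical(module_completeness(mod5, "K99999")$category, "absent")
  mc <- module_completeness(mod5, all_kos[1:3])
  expect_equal(mc$n_missing, 2L)
  expect_equal(mc$score, 2L)
})

test_that("scores are strictly monotone in completeness for any admissible map", {
  kos_by_cat <- list(absent = character(0),
                     partially_complete = c("K00001", "K00002"),
                     almost_complete = c("K00001", "K00002", "K00003"),
                     complete = c("K00001", "K00002", "K00003", "K00004",
                                  "K00005"))
  for (map in list(c(absent = 0L, partially_complete = 1L,
                     almost_complete = 2L, complete = 3L),
                   c(absent = 0L, partially_complete = 1L,
                     almost_complete = 3L, complete = 4L))) {
    scores <- vapply(kos_by_cat, function(k) {
      module_completeness(mod5, k, score_map = map)$score
    }, integer(1))
    expect_true(all(diff(scores) > 0))
  }
  bad_map <- c(absent = 3L, partially_complete = 1L, almost_complete = 2L,
               complete = 0L)
  expect_error(module_completeness(mod5, character(0), score_map = bad_map),
               "increasing")
})

test_that("completeness matrix is deterministic and column-consistent", {
  sim <- default_sim()
  m <- completeness_matrix(sim$ko_sets, sim$modules)
  # empty KO set gives an all-zero column
  m0 <- completeness_matrix(c(sim$ko_sets, list(empty = character(0))),
                            sim$modules)
  expect_true(all(m0[, "empty"] == 0))
  # identical KO sets give identical columns
  twin <- sim$ko_sets[["G01"]]
  m2 <- completeness_matrix(c(sim$ko_sets, list(twin = twin)), sim$modules)
  expect_identical(unname(m2[, "twin"]), unname(m2[, "G01"]))
  # double-entry oracle: straight-line recomputation of every cell
  for (g in colnames(m)) {
    for (mid in rownames(m)) {
      steps <- sim$modules[[mid]]$steps
      hit <- vapply(steps, function(s) any(s %in% sim$ko_sets[[g]]), logical(1))
      miss <- sum(!hit)
      expected <- if (!any(hit)) 0L else if (miss == 0L) 3L
                  else if (miss <= 2L) 2L else 1L
      expect_identical(m[mid, g], expected,
                       info = paste(mid, g))
    }
  }
})

test_that("adding a KO never decreases any module score", {
  sim <- default_sim()
  m <- completeness_matrix(sim$ko_sets, sim$modules)
  all_kos <- unique(unlist(lapply(sim$modules, function(x) unlist(x$steps))))
  set.seed(19)
  for (i in 1:20) {
    g <- sample(names(sim$ko_sets), 1)
    ko <- sample(all_kos, 1)
    augmented <- sim$ko_sets
    augmented[[g]] <- union(augmented[[g]], ko)
    m2 <- completeness_matrix(augmented, sim$modules)
    expect_true(all(m2[, g] >= m[, g]))
  }
})

test_that("profile distance is Euclidean, symmetric and metric", {
  m <- cbind(g1 = c(0, 0), g2 = c(3, 4), g3 = c(0, 1))
  d <- profile_distance(m)
  expect_equal(d["g1", "g2"], 5)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_true(isSymmetric(d))
  sim <- default_sim()
  ds <- profile_distance(completeness_matrix(sim$ko_sets, sim$modules))
  ids <- colnames(ds)
  set.seed(23)
  for (i in 1:25) {
    tr <- sample(ids, 3)
    expect_lte(ds[tr[1], tr[3]], ds[tr[1], tr[2]] + ds[tr[2], tr[3]] + 1e-12)
  }
})

test_that("UPGMA reproduces hand-computed dendrograms", {
  d2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  u2 <- upgma(d2)
  expect_equal(u2$height, 2)
  d3 <- matrix(c(0, 2, 6,
                 2, 0, 6,
                 6, 6, 0), 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  u3 <- upgma(d3)
  expect_equal(u3$height, c(1, 3))
  expect_identical(first_merge_pair(u3), c("A", "B"))
  # ultrametric input: cophenetic distances reproduce the input exactly
  expect_equal(cophenetic_distance(u3)[c("A", "B", "C"), c("A", "B", "C")], d3)
  bad <- d3; bad[1, 2] <- 99
  expect_error(upgma(bad), "symmetric")
})

test_that("vent genomes sharing planted modules merge first", {
  sim <- default_sim()
  scores <- completeness_matrix(sim$ko_sets, sim$modules)
  dend <- upgma(profile_distance(scores))
  htv <- sim$metadata$genome_id[sim$metadata$environment == "HTV"]
  expect_identical(first_merge_pair(dend), sort(htv))
})

test_that("Newick output round-trips through ape with the same topology", {
  sim <- default_sim()
  dend <- upgma(profile_distance(completeness_matrix(sim$ko_sets,
                                                     sim$modules)))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(dend, f)
  tree <- ape::read.tree(f)
  expect_setequal(tree$tip.label, dend$labels)
  expect_true(ape::is.ultrametric(tree, tol = 1e-8))
})

test_that("KO sets derived from the annotation table match the generator", {
  sim <- default_sim()
  derived <- ko_sets_from_annotation(sim$annotation)
  for (g in names(sim$ko_sets)) {
    expect_setequal(derived[[g]], unique(sim$ko_sets[[g]]))
  }
})
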