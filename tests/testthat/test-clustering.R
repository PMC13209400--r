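proteins_df <- function(ids, genomes, seqs) {
  data.frame(protein_id = ids, genome_id = genomes, sequence = seqs,
             stringsAsFactors = FALSE)
}

test_that("identical proteins collapse to a single cluster", {
  set.seed(3)
  s <- random_protein(150)
  pr <- proteins_df(paste0("p", 1:6), paste0("G0", 1:6), rep(s, 6))
  cl <- cluster_proteins(pr)
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]$members), 6L)
  expect_true(cl[[1]]$centroid %in% cl[[1]]$members$protein_id)
})

test_that("families below the identity threshold stay separate", {
  set.seed(9)
  a <- random_protein(200)
  b <- random_protein(200)  # unrelated: ~random identity, far below 0.5
  pr <- proteins_df(c("a1", "a2", "b1", "b2"), rep(c("G01", "G02"), 2),
                    c(a, a, b, b))
  cl <- cluster_proteins(pr, identity_threshold = 0.5)
  expect_length(cl, 2L)
})

test_that("clustering recovers planted families and forms a partition", {
  sim <- simulate_proteomes(6, 40, divergence = 0.10, seed = 17)
  cl <- cluster_proteins(sim$proteins)
  expect_length(cl, 40L)
  fam <- setNames(sim$proteins$family, sim$proteins$protein_id)
  purity <- vapply(cl, function(x) {
    length(unique(fam[x$members$protein_id])) == 1L
  }, logical(1))
  expect_true(all(purity))
  # partition property: cluster sizes sum to the protein count
  expect_equal(sum(vapply(cl, function(x) nrow(x$members), integer(1))),
               nrow(sim$proteins))
})

test_that("high divergence shatters families into more clusters", {
  sim <- simulate_proteomes(3, 10, divergence = 0.70, seed = 29)
  cl <- cluster_proteins(sim$proteins, identity_threshold = 0.5)
  expect_gt(length(cl), 10L)
})

test_that("raising the identity threshold never merges clusters", {
  sim <- simulate_proteomes(4, 15, divergence = 0.25, seed = 41)
  sizes <- vapply(c(0.3, 0.6, 0.9), function(thr) {
    length(cluster_proteins(sim$proteins, identity_threshold = thr))
  }, integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("clustering is invariant to input row order", {
  sim <- simulate_proteomes(4, 12, divergence = 0.15, seed = 53)
  cl1 <- cluster_proteins(sim$proteins)
  set.seed(1)
  shuffled <- sim$proteins[sample.int(nrow(sim$proteins)), ]
  cl2 <- cluster_proteins(shuffled)
  key <- function(cl) lapply(cl, function(x) sort(x$members$protein_id))
  expect_identical(key(cl1), key(cl2))
})

test_that("presence matrix collapses paralogs and covers metadata genomes", {
  md <- data.frame(genome_id = c("G01", "G02", "G03"),
                   environment = c("HTV", "nonHTV", "nonHTV"),
                   name = paste("s", 1:3))
  cl <- list(
    list(cluster_id = "GC00001", centroid = "p1",
         members = data.frame(genome_id = c("G01", "G01"),  # paralogs
                              protein_id = c("p1", "p2"))),
    list(cluster_id = "GC00002", centroid = "p3",
         members = data.frame(genome_id = c("G01", "G02", "G03"),
                              protein_id = c("p3", "p4", "p5")))
  )
  m <- build_presence_matrix(cl, md)
  expect_identical(dim(m), c(2L, 3L))
  expect_identical(unname(m["GC00001", ]), c(TRUE, FALSE, FALSE))
  expect_identical(unname(m["GC00002", ]), c(TRUE, TRUE, TRUE))
  # row sums recount distinct genomes per cluster
  expect_equal(unname(rowSums(m)), c(1, 3))
  expect_error(build_presence_matrix(cl, md[1:2, ]), "missing from metadata")
})

test_that("cluster annotation reports majority letters and KO unions", {
  ann <- data.frame(protein_id = c("p1", "p2", "p3"),
                    genome_id = c("G01", "G02", "G03"),
                    stringsAsFactors = FALSE)
  ann$cog_letters <- list(c("T"), c("T", "P"), character(0))
  ann$kos <- list("K00001", c("K00002"), "K00003")
  cl <- list(list(cluster_id = "GC00001", centroid = "p1",
                  members = data.frame(genome_id = paste0("G0", 1:3),
                                       protein_id = c("p1", "p2", "p3"))))
  ca <- cluster_annotation(cl, ann)
  expect_identical(ca$cog_letters[[1]], "T")  # P in 1/2 annotated, no majority
  expect_setequal(ca$kos[[1]], c("K00001", "K00002", "K00003"))
})
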