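test_that("local alignment handles the identity case and self-alignments", {
  sc <- scoring_scheme("nucleotide")
  al <- align_local("ACGT", "ACGT", sc)
  expect_equal(al$score, 4)
  expect_equal(al$identity, 1)
  expect_equal(al$query_coverage, 1)
  expect_equal(al$target_coverage, 1)
  set.seed(7)
  for (s in replicate(5, random_dna(sample(30:200, 1)))) {
    a <- align_local(s, s, sc)
    expect_equal(a$identity, 1)
    expect_equal(a$query_coverage, 1)
  }
  expect_error(align_local("", "ACGT", sc), "empty")
})

test_that("alignment score is symmetric under a symmetric matrix", {
  sc <- scoring_scheme("nucleotide")
  scp <- scoring_scheme("protein")
  set.seed(11)
  for (i in 1:5) {
    a <- random_dna(60); b <- random_dna(80)
    expect_equal(align_local(a, b, sc)$score, align_local(b, a, sc)$score)
    p <- random_protein(50); q <- random_protein(40)
    expect_equal(align_local(p, q, scp)$score, align_local(q, p, scp)$score)
  }
})

test_that("alignment of a sequence to its reverse is not the identity", {
  sc <- scoring_scheme("nucleotide")
  s <- "ACGTTGCAAC"
  r <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  al <- align_local(s, r, sc)
  expect_lt(al$identity * al$query_coverage, 1)
})

test_that("DP score equals brute-force enumeration on tiny strings", {
  sc <- scoring_scheme("nucleotide")
  set.seed(23)
  for (i in 1:12) {
    a <- random_dna(sample(3:6, 1))
    b <- random_dna(sample(3:6, 1))
    expect_equal(align_local(a, b, sc)$score, brute_local_score(a, b, sc),
                 info = paste(a, b))
  }
  scp <- scoring_scheme("protein")
  for (i in 1:3) {
    p <- random_protein(5); q <- random_protein(5)
    expect_equal(align_local(p, q, scp)$score, brute_local_score(p, q, scp),
                 info = paste(p, q))
  }
})

test_that("k-mer prescreen orders targets sensibly", {
  set.seed(5)
  targets <- setNames(vapply(rep(60, 6), random_dna, character(1)),
                      paste0("t", 1:6))
  # min_shared = 0 keeps every target
  expect_setequal(kmer_prescreen(random_dna(60), targets, k = 8, min_shared = 0),
                  names(targets))
  # a query identical to one target ranks that target first
  expect_identical(kmer_prescreen(targets[["t3"]], targets, k = 8)[1], "t3")
  # sequences shorter than k yield no k-mers and cannot be screened in
  short <- c(targets, s1 = "ACGT")
  expect_false("s1" %in% kmer_prescreen(random_dna(60), short, k = 8,
                                        min_shared = 1))
})

test_that("prescreen recovers the true best-identity target on diverged families", {
  set.seed(31)
  # families at ~80% identity to their queries (evolved directly at d = 0.2)
  n_fam <- 15
  ancestors <- vapply(sample(120:250, n_fam, replace = TRUE), random_protein,
                      character(1))
  targets <- list()
  for (f in seq_len(n_fam)) {
    for (g in 1:2) {
      targets[[sprintf("f%02d_g%d", f, g)]] <-
        evolve_sequence(ancestors[f], 0.2, alphabet = "protein",
                        seed = f * 100 + g)
    }
  }
  targets <- unlist(targets)
  scp <- scoring_scheme("protein")
  hits <- 0L
  for (f in seq_len(n_fam)) {
    query <- ancestors[f]
    # oracle: full alignment against every target, best hit by score (raw
    # local identity alone can be inflated by short spurious alignments)
    score <- vapply(targets, function(t) align_local(query, t, scp)$score,
                    numeric(1))
    best_true <- names(targets)[which.max(score)]
    ranked <- kmer_prescreen(query, targets, k = 4, min_shared = 1)
    hits <- hits + (best_true %in% head(ranked, 5))
  }
  expect_gte(hits / n_fam, 0.99)
})

test_that("E-values follow the Karlin-Altschul closed form", {
  sc <- scoring_scheme("protein", lambda = 0.267, K = 0.041)
  e <- evalue(40, 100, 100, sc)
  expect_equal(e, 0.041 * 100 * 100 * exp(-0.267 * 40))
  expect_equal(e, 9.43e-3, tolerance = 0.01)
  # strictly decreasing in score; linear in database size
  expect_true(all(diff(vapply(30:40, evalue, numeric(1), m = 100, n = 100,
                              scoring = sc)) < 0))
  expect_equal(evalue(40, 100, 200, sc), 2 * e)
  expect_error(evalue(40, 0, 100, sc), "positive")
})
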