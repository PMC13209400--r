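# Independent oracles and shared fixtures for the test suite.

# Brute-force optimal local alignment score by enumerating every alignment
# path (affine gaps: a gap of length L costs |open| + L * |extend|). A
# maximal-scoring local alignment never starts or ends with a gap, so
# enumeration starts from every aligned pair. Exponential; only for tiny
# strings.
brute_local_score <- function(a, b, scoring) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  sub <- scoring$submat
  open <- abs(scoring$gap_open)
  ext <- abs(scoring$gap_extend)
  best <- 0
  explore <- function(i, j, score, state) {
    best <<- max(best, score)
    if (i > length(A) && j > length(B)) return(invisible())
    if (i <= length(A) && j <= length(B)) {
      explore(i + 1L, j + 1L, score + sub[A[i], B[j]], "m")
    }
    if (i <= length(A)) {
      explore(i + 1L, j, score - if (state == "d") ext else open + ext, "d")
    }
    if (j <= length(B)) {
      explore(i, j + 1L, score - if (state == "i") ext else open + ext, "i")
    }
  }
  for (i in seq_along(A)) {
    for (j in seq_along(B)) {
      explore(i + 1L, j + 1L, sub[A[i], B[j]], "m")
    }
  }
  best
}

# Two-sided Fisher exact p by direct hypergeometric enumeration over the
# table's support (sum of point probabilities <= observed, with a relative
# tie tolerance).
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  w <- a + c
  m <- a + b + c + d
  p_obs <- dhyper(a, w, m - w, r1)
  support <- max(0L, w - (c + d)):min(r1, w)
  probs <- dhyper(support, w, m - w, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hand-rolled BH step-up: q_(i) = min_{j >= i} min(1, m p_(j) / j), mapped
# back to input order.
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, m * p[o] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

random_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, replace = TRUE),
        collapse = "")
}

# default synthetic study fixture, built once per test run
.fixture_env <- new.env()
default_sim <- function(seed = 20240101 %% 99991) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_pangenome(seed = seed)
  }
  .fixture_env[[key]]
}
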