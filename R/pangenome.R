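# Pan-genome structure: the core/accessory/unique partition, permutation
# rarefaction curves, and the power-law openness fit y = A * x^b (b < 1
# diagnoses an open pan-genome).

#' Partition gene clusters into core, accessory and unique
#'
#' Core clusters are present in every genome; unique clusters in exactly
#' one; accessory clusters in at least two but not all.
#'
#' @param matrix Logical presence matrix (clusters x genomes, >= 2 genomes).
#' @return Object of class `pan_partition`: `core` and `accessory`
#'   cluster-id vectors, `unique` (named list genome -> cluster ids), and
#'   `counts` (total, core, accessory, unique_total, unique_per_genome).
#' @export
partition <- function(matrix) {
  validate_presence_matrix(matrix)
  if (ncol(matrix) < 2L) stop("partition needs at least 2 genomes")
  npres <- rowSums(matrix)
  core <- rownames(matrix)[npres == ncol(matrix)]
  uniq_rows <- npres == 1L
  accessory <- rownames(matrix)[!uniq_rows & npres < ncol(matrix)]
  unique_map <- setNames(vector("list", ncol(matrix)), colnames(matrix))
  for (g in colnames(matrix)) {
    unique_map[[g]] <- rownames(matrix)[uniq_rows & matrix[, g]]
  }
  structure(list(
    core = core, accessory = accessory, unique = unique_map,
    counts = list(
      total = nrow(matrix),
      core = length(core),
      accessory = length(accessory),
      unique_total = sum(uniq_rows),
      unique_per_genome = vapply(unique_map, length, integer(1))
    )
  ), class = "pan_partition")
}

#' @export
print.pan_partition <- function(x, ...) {
  cat("Pan-genome partition:", x$counts$total, "gene clusters\n")
  cat("  core:     ", x$counts$core, "\n")
  cat("  accessory:", x$counts$accessory, "\n")
  cat("  unique:   ", x$counts$unique_total, "\n")
  invisible(x)
}

# all permutations of 1..n (used when n! is within the permutation budget)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Pan and core rarefaction curves over random genome orderings
#'
#' For each genome ordering, the cumulative union (pan) and intersection
#' (core) of gene clusters at 1..N genomes; summarised by the per-step
#' median across orderings. When `factorial(N) <= n_permutations` all
#' orderings are enumerated instead of sampled, so small cases are exact.
#'
#' @param matrix Logical presence matrix.
#' @param n_permutations Number of random genome orderings (>= 1).
#' @param seed Integer seed for the orderings.
#' @return Object of class `rarefaction_curve`: `x`, `pan_median`,
#'   `core_median`, per-permutation matrices `pan` and `core`,
#'   `n_permutations`, `seed`.
#' @export
rarefaction_curves <- function(matrix, n_permutations = 20L, seed = 1L) {
  validate_presence_matrix(matrix)
  stopifnot(n_permutations >= 1L)
  n <- ncol(matrix)
  orderings <- if (factorial(n) <= n_permutations) {
    all_permutations(n)
  } else {
    with_seed(seed, replicate(n_permutations, sample.int(n), simplify = FALSE))
  }
  pan <- core <- base::matrix(NA_real_, nrow = length(orderings), ncol = n)
  storage <- matrix + 0L
  for (i in seq_along(orderings)) {
    m <- storage[, orderings[[i]], drop = FALSE]
    cum <- m
    if (n >= 2L) for (j in 2:n) cum[, j] <- cum[, j - 1L] + m[, j]
    pan[i, ] <- colSums(cum > 0L)
    core[i, ] <- colSums(cum == rep(seq_len(n), each = nrow(cum)))
  }
  structure(list(
    x = seq_len(n),
    pan_median = apply(pan, 2, median),
    core_median = apply(core, 2, median),
    pan = pan, core = core,
    n_permutations = length(orderings), seed = seed
  ), class = "rarefaction_curve")
}

#' Fit the pan-genome power law y = A * x^b
#'
#' Ordinary least squares on the log-log scale provides the starting values;
#' a Gauss-Newton pass then minimises squared error on the original scale
#' (log-log OLS alone biases `b` under additive noise). On noise-free
#' power-law data the log-log fit is already exact and is returned as-is.
#' The pan-genome is called open when `b < 1`.
#'
#' @param x Positive numeric vector (genome counts), >= 3 points.
#' @param y Positive numeric vector (pan-genome sizes).
#' @return Object of class `power_law_fit`: `A`, `b`, `rss`, `open`.
#' @export
fit_power_law <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points")
  if (any(y <= 0)) stop("y must be positive")
  if (any(x <= 0)) stop("x must be positive")
  ols <- lm(log(y) ~ log(x))
  A0 <- exp(coef(ols)[[1]])
  b0 <- coef(ols)[[2]]
  A <- A0; b <- b0
  fit <- tryCatch(
    nls(y ~ A * x^b, start = list(A = A0, b = b0),
        control = list(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)  # zero-residual data: OLS start is the optimum
  if (!is.null(fit)) {
    cf <- coef(fit)
    # keep the refinement only if it does not worsen the original-scale rss
    if (sum((y - cf[["A"]] * x^cf[["b"]])^2) <= sum((y - A0 * x^b0)^2)) {
      A <- cf[["A"]]; b <- cf[["b"]]
    }
  }
  structure(list(A = A, b = b,
                 rss = sum((y - A * x^b)^2),
                 open = b < 1),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: y = %.4g * x^%.4g (rss %.4g) -> %s pan-genome\n",
              x$A, x$b, x$rss, if (x$open) "open" else "closed"))
  invisible(x)
}

#' COG category counts per pan-genome compartment
#'
#' Tabulates, for each of core/accessory/unique, how many clusters carry each
#' COG category letter (a cluster counts once per letter it carries).
#'
#' @param part A [partition()] result.
#' @param cluster_cogs Named list cluster_id -> COG letters.
#' @return Data.frame `compartment`, `category`, `count`.
#' @export
partition_cog_profile <- function(part, cluster_cogs) {
  compartments <- list(core = part$core, accessory = part$accessory,
                       unique = unlist(part$unique, use.names = FALSE))
  rows <- lapply(names(compartments), function(nm) {
    letters_list <- cluster_cogs[compartments[[nm]]]
    tab <- table(factor(unlist(letters_list), levels = COG_LETTERS))
    data.frame(compartment = nm, category = names(tab),
               count = as.integer(tab), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
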