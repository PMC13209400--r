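# Environment-association testing of gene clusters: two-sided Fisher exact
# tests on 2x2 presence/absence tables (HTV vs non-HTV genomes), BH FDR
# adjustment, and direction-of-association calls. Core clusters are excluded
# before testing: a cluster present everywhere carries no contrast.

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' The table rows are the two environment groups and the columns
#' present/absent: `(a, b)` = present/absent in HTV, `(c, d)` = present/
#' absent in non-HTV. Two-sided in the usual sense: the sum of hypergeometric
#' point probabilities not exceeding that of the observed table.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return The p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative cell count")
  stats::fisher.test(base::matrix(cells, nrow = 2, byrow = TRUE))$p.value
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Test every non-core gene cluster for environment association
#'
#' One Fisher exact test per accessory or unique cluster against the HTV /
#' non-HTV grouping. Significance is called on the raw p-value
#' (`p < alpha`); BH-adjusted q-values are reported alongside for every
#' tested cluster. With very small group sizes (e.g. 2 vs 14 genomes) the
#' smallest attainable two-sided p is 1/choose(16, 2) = 1/120, which cannot
#' survive FDR correction across thousands of clusters, so the raw-p rule is
#' the one under which environment-specific clusters are recoverable at all;
#' both thresholds are explicit arguments. The direction of a significant
#' association is the group with the higher presence fraction; a significant
#' test with equal fractions (possible only in unbalanced designs) is
#' demoted to `direction = "none"`, not significant.
#'
#' @param matrix Logical presence matrix (clusters x genomes).
#' @param metadata Metadata data.frame with `genome_id`, `environment`.
#' @param alpha Raw-p significance threshold.
#' @return Data.frame of class `association_result`: `cluster_id`, cells
#'   `a`,`b`,`c`,`d`, `p`, `q`, `direction` (`HTV`/`nonHTV`/`none`),
#'   `significant`.
#' @export
environment_association <- function(matrix, metadata, alpha = 0.05) {
  validate_presence_matrix(matrix)
  stopifnot(alpha > 0, alpha < 1)
  missing <- setdiff(colnames(matrix), metadata$genome_id)
  if (length(missing) > 0L) {
    stop("genome(s) absent from metadata: ", paste(missing, collapse = ", "))
  }
  env <- setNames(metadata$environment, metadata$genome_id)[colnames(matrix)]
  htv <- env == "HTV"
  n_htv <- sum(htv); n_non <- sum(!htv)
  if (n_htv == 0L || n_non == 0L) stop("both environment groups must be nonempty")

  tested <- rowSums(matrix) < ncol(matrix)  # exclude core before testing
  ids <- rownames(matrix)[tested]
  a <- rowSums(matrix[tested, htv, drop = FALSE])
  cc <- rowSums(matrix[tested, !htv, drop = FALSE])
  p <- vapply(seq_along(ids), function(i) {
    fisher_exact_2x2(a[i], n_htv - a[i], cc[i], n_non - cc[i])
  }, numeric(1))
  q <- bh_adjust(p)
  significant <- p < alpha
  frac_htv <- a / n_htv
  frac_non <- cc / n_non
  direction <- rep("none", length(ids))
  direction[significant & frac_htv > frac_non] <- "HTV"
  direction[significant & frac_non > frac_htv] <- "nonHTV"
  significant <- significant & direction != "none"
  out <- data.frame(
    cluster_id = ids, a = as.integer(a), b = as.integer(n_htv - a),
    c = as.integer(cc), d = as.integer(n_non - cc),
    p = p, q = q, direction = direction, significant = significant,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("association_result", "data.frame")
  out
}

#' Summarise association calls by direction
#' @param assoc An [environment_association()] result.
#' @return Named list: `significant`, `htv`, `nonhtv`, `tested`.
#' @export
association_counts <- function(assoc) {
  list(tested = nrow(assoc),
       significant = sum(assoc$significant),
       htv = sum(assoc$direction == "HTV"),
       nonhtv = sum(assoc$direction == "nonHTV"))
}
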