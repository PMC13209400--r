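# Binomial enrichment index for COG functional categories: the number of
# binomial standard deviations by which a category's count in a focal gene
# set departs from its expectation under the background proportion. An index
# above 2 is called significantly enriched (one-sided z > 2, p < 0.05).

#' Binomial enrichment index
#'
#' `EI = (x - n * p_bg) / sqrt(n * p_bg * (1 - p_bg))`: standard deviations
#' from the binomial expectation.
#'
#' @param x Observed category count in the focal set (0 <= x <= n).
#' @param n Focal set size (annotated genes, >= 1).
#' @param p_bg Background category proportion, strictly inside (0, 1).
#' @return The enrichment index.
#' @export
enrichment_index <- function(x, n, p_bg) {
  stopifnot(n >= 1)
  if (x > n || x < 0) stop("x must lie in [0, n]")
  if (p_bg <= 0 || p_bg >= 1) stop("p_bg must be strictly inside (0, 1)")
  (x - n * p_bg) / sqrt(n * p_bg * (1 - p_bg))
}

# count genes carrying each category letter (a gene counts once per letter)
category_counts <- function(letters_list) {
  annotated <- letters_list[vapply(letters_list, length, integer(1)) > 0]
  tab <- table(factor(unlist(annotated), levels = COG_LETTERS))
  list(n = length(annotated), counts = tab)
}

#' COG category enrichment of a focal gene set against a background
#'
#' For every category letter present in the background, the enrichment index
#' of its focal count against the background proportion. Genes without COG
#' annotation are excluded from both set sizes; genes carrying several
#' letters contribute once to each. Categories with background proportion 0
#' or 1 are untestable and skipped. Significance is strictly `EI > ei_threshold`.
#'
#' @param focal List of COG-letter vectors, one per focal gene.
#' @param background List of COG-letter vectors, one per background gene
#'   (the whole pan-genome by default usage; the complement is the other
#'   defensible choice and can simply be passed instead).
#' @param ei_threshold Significance threshold on the index (default 2).
#' @return Data.frame `category`, `x`, `n`, `p_bg`, `ei`, `significant`.
#' @export
category_enrichment <- function(focal, background, ei_threshold = 2) {
  stopifnot(length(background) > 0)
  bg <- category_counts(background)
  if (bg$n == 0L) stop("background has no COG-annotated genes")
  fc <- category_counts(focal)
  if (fc$n == 0L) stop("focal set has no COG-annotated genes")
  p_bg <- as.numeric(bg$counts) / bg$n
  keep <- p_bg > 0 & p_bg < 1
  cats <- names(bg$counts)[keep]
  x <- as.integer(fc$counts[cats])
  ei <- vapply(seq_along(cats), function(i) {
    enrichment_index(x[i], fc$n, p_bg[keep][i])
  }, numeric(1))
  data.frame(category = cats, x = x, n = fc$n, p_bg = p_bg[keep], ei = ei,
             significant = ei > ei_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}
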