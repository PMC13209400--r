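# KEGG-module completeness per genome, numeric score profiles, and UPGMA
# clustering of genomes by profile. A module is an ordered list of steps,
# each satisfied by any of its alternative KOs; completeness is judged by
# the number of unsatisfied steps.

MODULE_CATEGORIES <- c("absent", "partially_complete", "almost_complete",
                       "complete")

DEFAULT_SCORE_MAP <- c(absent = 0L, partially_complete = 1L,
                       almost_complete = 2L, complete = 3L)

#' Completeness of one KEGG module in one genome
#'
#' Categories: `complete` (no step missing), `almost_complete` (1-2 steps
#' missing), `partially_complete` (>= 3 steps missing but at least one KO of
#' the module annotated), `absent` (no KO of the module annotated). The
#' numeric score is a strictly monotone mapping of the category; any such
#' mapping preserves every ordinal conclusion, and the default is
#' absent 0 / partially 1 / almost 2 / complete 3.
#'
#' @param module A module definition (`module_id`, `steps`; see
#'   [read_modules()]).
#' @param kos Character vector of KO ids annotated in the genome.
#' @param score_map Named integer vector mapping the four categories to
#'   scores (strictly increasing in completeness).
#' @return List `module_id`, `n_steps`, `n_missing`, `category`, `score`.
#' @export
module_completeness <- function(module, kos, score_map = DEFAULT_SCORE_MAP) {
  stopifnot(length(module$steps) >= 1L,
            all(MODULE_CATEGORIES %in% names(score_map)))
  if (is.unsorted(score_map[MODULE_CATEGORIES], strictly = TRUE)) {
    stop("score_map must be strictly increasing in completeness")
  }
  satisfied <- vapply(module$steps, function(step) any(step %in% kos),
                      logical(1))
  n_missing <- sum(!satisfied)
  category <- if (!any(satisfied)) "absent"
    else if (n_missing == 0L) "complete"
    else if (n_missing <= 2L) "almost_complete"
    else "partially_complete"
  list(module_id = module$module_id,
       n_steps = length(module$steps),
       n_missing = as.integer(n_missing),
       category = category,
       score = unname(score_map[category]))
}

#' Module completeness score matrix (modules x genomes)
#'
#' @param ko_sets Named list: genome id -> character vector of annotated KOs.
#' @param modules Named list of module definitions.
#' @param score_map Category-to-score mapping (see [module_completeness()]).
#' @return Integer matrix, rows/columns sorted by module/genome id.
#' @export
completeness_matrix <- function(ko_sets, modules,
                                score_map = DEFAULT_SCORE_MAP) {
  stopifnot(length(ko_sets) >= 1L, length(modules) >= 1L)
  genome_ids <- sort(names(ko_sets))
  module_ids <- sort(vapply(modules, `[[`, character(1), "module_id"))
  modules <- setNames(modules, vapply(modules, `[[`, character(1), "module_id"))
  m <- base::matrix(0L, length(module_ids), length(genome_ids),
                    dimnames = list(module_ids, genome_ids))
  for (g in genome_ids) {
    for (mid in module_ids) {
      m[mid, g] <- module_completeness(modules[[mid]], ko_sets[[g]],
                                       score_map)$score
    }
  }
  m
}

#' Long-format module completeness table
#'
#' @inheritParams completeness_matrix
#' @return Data.frame `genome_id`, `module_id`, `n_steps`, `n_missing`,
#'   `category`, `score`.
#' @export
completeness_table <- function(ko_sets, modules,
                               score_map = DEFAULT_SCORE_MAP) {
  rows <- list()
  for (g in sort(names(ko_sets))) {
    for (m in modules) {
      mc <- module_completeness(m, ko_sets[[g]], score_map)
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = g, module_id = mc$module_id, n_steps = mc$n_steps,
        n_missing = mc$n_missing, category = mc$category, score = mc$score,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-genome KO sets from a protein annotation table
#'
#' @param annotation Annotation data.frame ([read_annotation()]).
#' @return Named list: genome id -> character vector of distinct KO ids.
#' @export
ko_sets_from_annotation <- function(annotation) {
  lapply(split(annotation$kos, annotation$genome_id),
         function(kos) unique(unlist(kos)))
}

#' Euclidean distance between genome module profiles
#'
#' @param matrix Numeric matrix (modules x genomes).
#' @return Symmetric distance matrix over genomes with zero diagonal.
#' @export
profile_distance <- function(matrix) {
  if (ncol(matrix) < 2L) stop("need at least 2 genomes")
  as.matrix(stats::dist(t(matrix), method = "euclidean"))
}

#' UPGMA (average-linkage) hierarchical clustering
#'
#' Agglomerates by unweighted average linkage; merge heights are half the
#' between-cluster average distance (so two leaves at distance `d` merge at
#' height `d/2` and their cophenetic distance is `d`). Labels are sorted
#' before clustering so ties break deterministically and the result does not
#' depend on input order.
#'
#' @param dist Symmetric distance matrix (or `dist` object), N >= 2.
#' @return Object of class `upgma_dendrogram`: `labels`, `merge`, `height`
#'   (merge heights, nondecreasing), and the underlying `hclust`.
#' @export
upgma <- function(dist) {
  d <- if (inherits(dist, "dist")) as.matrix(dist) else dist
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  if (nrow(d) < 2L) stop("need at least 2 leaves")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("L", seq_len(nrow(d)))
  }
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- hclust(as.dist(d), method = "average")
  structure(list(labels = hc$labels, merge = hc$merge,
                 height = hc$height / 2, hclust = hc),
            class = "upgma_dendrogram")
}

#' Cophenetic distances implied by a UPGMA dendrogram
#' @param dendrogram An [upgma()] result.
#' @return Symmetric matrix of cophenetic distances (twice the merge height
#'   of each pair's lowest common ancestor).
#' @export
cophenetic_distance <- function(dendrogram) {
  as.matrix(cophenetic(dendrogram$hclust))
}

#' Leaves joined by the first (lowest) merge
#' @param dendrogram An [upgma()] result.
#' @return Character vector of the leaf labels under the lowest merge that
#'   joins two singletons.
#' @export
first_merge_pair <- function(dendrogram) {
  m <- dendrogram$merge
  i <- which(m[, 1] < 0 & m[, 2] < 0)[1]
  sort(dendrogram$labels[-m[i, ]])
}

# convert to an ape phylo with ultrametric branch lengths (leaf-to-root
# height = top merge height)
as_phylo <- function(dendrogram) {
  hc <- dendrogram$hclust
  hc$height <- dendrogram$height
  ape::as.phylo(hc)
}
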