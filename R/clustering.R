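# Greedy centroid-based clustering of proteins into orthologous gene
# clusters, and construction of the presence/absence matrix. The scheme is
# the classic incremental one: proteins are visited from longest to shortest
# and join the first existing centroid they align to above the identity and
# coverage thresholds, otherwise they found a new cluster. The canonical
# visiting order (length, then id) makes the result independent of input
# order.

#' Cluster proteins into orthologous gene clusters
#'
#' Greedy first-fit centroid clustering: proteins sorted by decreasing length
#' (ties by protein id) are assigned to the first centroid, in centroid
#' creation order, whose local alignment reaches `identity_threshold` and
#' covers at least `coverage_threshold` of the shorter sequence; otherwise
#' the protein founds a new cluster with itself as centroid. A k-mer
#' prescreen limits which centroids are fully aligned.
#'
#' @param proteins Data.frame with columns `protein_id`, `genome_id`,
#'   `sequence` (one row per protein; ids unique).
#' @param identity_threshold Minimum alignment identity in (0, 1].
#' @param coverage_threshold Minimum aligned fraction of the shorter
#'   sequence, in (0, 1].
#' @param scoring Protein [scoring_scheme()].
#' @param k,min_shared Prescreen parameters; centroids sharing fewer than
#'   `min_shared` distinct k-mers with the query are not aligned.
#' @return List of gene clusters, each a list with `cluster_id`, `centroid`
#'   (protein id) and `members` (data.frame `genome_id`, `protein_id`), in
#'   centroid creation order.
#' @export
cluster_proteins <- function(proteins, identity_threshold = 0.5,
                             coverage_threshold = 0.8,
                             scoring = scoring_scheme("protein"),
                             k = 5L, min_shared = 2L) {
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "genome_id", "sequence") %in% names(proteins)))
  if (nrow(proteins) == 0L) stop("no proteins to cluster")
  if (anyDuplicated(proteins$protein_id)) stop("duplicate protein ids")
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            coverage_threshold > 0, coverage_threshold <= 1)

  ord <- order(-nchar(proteins$sequence), proteins$protein_id)
  proteins <- proteins[ord, ]

  cent_seq <- character(0)
  cent_id <- character(0)
  cent_kmers <- list()
  assignment <- integer(nrow(proteins))

  for (i in seq_len(nrow(proteins))) {
    q <- proteins$sequence[i]
    qk <- kmer_set(q, k)
    hit <- 0L
    if (length(cent_seq) > 0L) {
      shared <- vapply(cent_kmers, function(ck) sum(qk %in% ck), integer(1))
      for (j in which(shared >= min_shared)) {  # creation order: first fit
        al <- align_local(q, cent_seq[j], scoring)
        shorter_cov <- if (nchar(q) <= nchar(cent_seq[j])) {
          al$query_coverage
        } else al$target_coverage
        if (al$identity >= identity_threshold &&
            shorter_cov >= coverage_threshold) {
          hit <- j
          break
        }
      }
    }
    if (hit == 0L) {
      cent_seq <- c(cent_seq, q)
      cent_id <- c(cent_id, proteins$protein_id[i])
      cent_kmers[[length(cent_seq)]] <- qk
      hit <- length(cent_seq)
    }
    assignment[i] <- hit
  }

  lapply(seq_along(cent_id), function(j) {
    m <- proteins[assignment == j, c("genome_id", "protein_id")]
    rownames(m) <- NULL
    list(cluster_id = sprintf("GC%05d", j),
         centroid = cent_id[j],
         members = m)
  })
}

#' Build a presence/absence matrix from gene clusters
#'
#' Cell `(c, g)` is `TRUE` when cluster `c` has at least one member from
#' genome `g`; paralog multiplicity collapses to presence. Rows are sorted by
#' cluster id and columns by genome id, so the matrix is deterministic.
#'
#' @param clusters List of gene clusters from [cluster_proteins()].
#' @param metadata Metadata data.frame ([read_metadata()]); every member
#'   genome must appear in it.
#' @return Logical matrix (clusters x genomes) covering exactly the metadata
#'   genomes.
#' @export
build_presence_matrix <- function(clusters, metadata) {
  stopifnot(length(clusters) > 0L)
  genomes <- sort(metadata$genome_id)
  member_genomes <- unique(unlist(lapply(clusters, function(cl) cl$members$genome_id)))
  missing <- setdiff(member_genomes, genomes)
  if (length(missing) > 0L) {
    stop("cluster member genome(s) missing from metadata: ",
         paste(missing, collapse = ", "))
  }
  ids <- sort(vapply(clusters, `[[`, character(1), "cluster_id"))
  mat <- matrix(FALSE, nrow = length(ids), ncol = length(genomes),
                dimnames = list(ids, genomes))
  for (cl in clusters) {
    mat[cl$cluster_id, unique(cl$members$genome_id)] <- TRUE
  }
  validate_presence_matrix(mat)
  mat
}

#' Summarise per-cluster annotation
#'
#' Majority COG letters and union of KO ids per cluster, from a per-protein
#' annotation table.
#'
#' @param clusters List of gene clusters.
#' @param annotation Annotation data.frame ([read_annotation()]).
#' @return Data.frame `cluster_id`, list columns `cog_letters` (letters
#'   carried by more than half of the annotated members) and `kos` (union).
#' @export
cluster_annotation <- function(clusters, annotation) {
  idx <- setNames(seq_len(nrow(annotation)), annotation$protein_id)
  rows <- lapply(clusters, function(cl) {
    i <- idx[cl$members$protein_id]
    i <- i[!is.na(i)]
    letters_all <- annotation$cog_letters[i]
    annotated <- letters_all[vapply(letters_all, length, integer(1)) > 0]
    maj <- character(0)
    if (length(annotated) > 0) {
      tab <- table(unlist(annotated))
      maj <- names(tab)[tab > length(annotated) / 2]
    }
    list(cluster_id = cl$cluster_id, cog_letters = maj,
         kos = unique(unlist(annotation$kos[i])))
  })
  out <- data.frame(cluster_id = vapply(rows, `[[`, character(1), "cluster_id"),
                    stringsAsFactors = FALSE)
  out$cog_letters <- lapply(rows, `[[`, "cog_letters")
  out$kos <- lapply(rows, function(r) if (is.null(r$kos)) character(0) else r$kos)
  out
}
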