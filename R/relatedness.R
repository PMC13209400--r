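# Pairwise genome relatedness indices: fragment-based ANI (ANIb-style),
# reciprocal-best-hit AAI, and POCP, with the conventional interpretation
# thresholds (same species at ANI >= 95%; genus evidence at AAI >= ~65% and
# POCP >= 50%). The search engine behind all three is the package's own
# k-mer-guided Smith-Waterman, so absolute values are reproductions of the
# BLAST-based originals up to search-engine differences; the thresholds, not
# the exact values, carry the semantics and every filter is configurable.

relatedness_result <- function(genome_a, genome_b, metric, value, n_support) {
  structure(list(
    genome_a = genome_a, genome_b = genome_b, metric = metric,
    value = value, n_support = n_support,
    same_species = metric == "ANI" && !is.na(value) && value >= 95,
    same_genus_aai = metric == "AAI" && !is.na(value) && value >= 65,
    same_genus_pocp = metric == "POCP" && !is.na(value) && value >= 50
  ), class = "relatedness_result")
}

#' @export
print.relatedness_result <- function(x, ...) {
  cat(sprintf("%s(%s, %s) = %s (n = %d)\n", x$metric, x$genome_a, x$genome_b,
              if (is.na(x$value)) "undefined" else sprintf("%.2f%%", x$value),
              x$n_support))
  invisible(x)
}

# locate the homologous window of `subject` for one fragment via shared
# k-mer offsets; returns NULL when neither strand anchors
locate_window <- function(fragment, subject_kmers, subject_rev_kmers,
                          subject, subject_rev, k, pad) {
  fk_pos <- seq_len(max(nchar(fragment) - k + 1L, 0L))
  if (length(fk_pos) == 0L) return(NULL)
  fk <- substring(fragment, fk_pos, fk_pos + k - 1L)
  hit_fwd <- match(fk, subject_kmers)
  hit_rev <- match(fk, subject_rev_kmers)
  n_fwd <- sum(!is.na(hit_fwd)); n_rev <- sum(!is.na(hit_rev))
  if (n_fwd == 0L && n_rev == 0L) return(NULL)
  if (n_fwd >= n_rev) {
    target <- subject; hits <- hit_fwd
  } else {
    target <- subject_rev; hits <- hit_rev
  }
  offs <- hits - fk_pos
  off <- median(offs, na.rm = TRUE)
  lo <- max(1L, floor(off) + 1L - pad)
  hi <- min(nchar(target), floor(off) + nchar(fragment) + pad)
  substr(target, lo, hi)
}

ani_directed <- function(query, subject, fragment_bp, min_identity,
                         min_coverage, scoring, k, pad) {
  n_frag <- nchar(query) %/% fragment_bp  # trailing short fragment dropped
  if (n_frag == 0L) return(numeric(0))
  starts <- (seq_len(n_frag) - 1L) * fragment_bp + 1L
  subject_rev <- reverse_complement(subject)
  sk_pos <- seq_len(nchar(subject) - k + 1L)
  subject_kmers <- substring(subject, sk_pos, sk_pos + k - 1L)
  subject_rev_kmers <- substring(subject_rev, sk_pos, sk_pos + k - 1L)
  idents <- numeric(0)
  for (s in starts) {
    frag <- substr(query, s, s + fragment_bp - 1L)
    win <- locate_window(frag, subject_kmers, subject_rev_kmers,
                         subject, subject_rev, k, pad)
    if (is.null(win) || nchar(win) == 0L) next
    al <- align_local(frag, win, scoring)
    if (al$identity >= min_identity && al$query_coverage >= min_coverage) {
      idents <- c(idents, al$identity)
    }
  }
  idents
}

#' Average nucleotide identity between two genomes (fragment-based)
#'
#' The query genome is cut into consecutive `fragment_bp` fragments (the
#' trailing short fragment is dropped); each fragment is locally aligned
#' against the other genome (both strands; a shared-k-mer anchor restricts
#' the alignment to the candidate homologous window). Fragments reaching
#' `min_identity` and covering at least `min_coverage` of their length are
#' retained, and ANI is the mean retained identity, symmetrised as the mean
#' of the two directed values.
#'
#' @param a,b Named single-element character vectors, or plain strings plus
#'   `id_a`/`id_b`.
#' @param fragment_bp Fragment width in bp (default 1020).
#' @param min_identity,min_coverage Retention filters on each fragment.
#' @param scoring Nucleotide [scoring_scheme()].
#' @param k Anchor k-mer size.
#' @param window_pad Extra bp of the subject aligned either side of the
#'   anchored window.
#' @param id_a,id_b Genome ids for the result.
#' @return A `relatedness_result` (value in percent; `NA` with
#'   `n_support = 0` when no fragment is retained).
#' @export
ani <- function(a, b, fragment_bp = 1020L, min_identity = 0.3,
                min_coverage = 0.7, scoring = scoring_scheme("nucleotide"),
                k = 12L, window_pad = 200L,
                id_a = if (!is.null(names(a))) names(a)[1] else "a",
                id_b = if (!is.null(names(b))) names(b)[1] else "b") {
  a <- unname(a[[1]]); b <- unname(b[[1]])
  if (nchar(a) < fragment_bp || nchar(b) < fragment_bp) {
    stop("both genomes must be at least one fragment long")
  }
  i_ab <- ani_directed(a, b, fragment_bp, min_identity, min_coverage,
                       scoring, k, window_pad)
  i_ba <- ani_directed(b, a, fragment_bp, min_identity, min_coverage,
                       scoring, k, window_pad)
  n <- length(i_ab) + length(i_ba)
  value <- if (n == 0L) NA_real_ else {
    # mean of the two directed ANIs (each the mean retained identity)
    mean(c(if (length(i_ab)) mean(i_ab) else NA_real_,
           if (length(i_ba)) mean(i_ba) else NA_real_), na.rm = TRUE) * 100
  }
  relatedness_result(id_a, id_b, "ANI", value, n)
}

# directed best hits of every protein in `qs` against `ts`, under the AAI
# filters; returns a data.frame query -> target with identity
best_hits <- function(qs, ts, scoring, min_identity, min_coverage, max_evalue,
                      k = 4L, top_n = 5L) {
  idx <- kmer_index(ts, k)
  n_db <- sum(nchar(ts))
  rows <- list()
  for (qid in names(qs)) {
    al <- best_local_hit(qs[[qid]], ts, scoring, k = k, min_shared = 1L,
                         top_n = top_n, index = idx, query_id = qid)
    if (is.null(al)) next
    shorter_cov <- if (nchar(qs[[qid]]) <= nchar(ts[[al$target_id]])) {
      al$query_coverage
    } else al$target_coverage
    if (al$identity < min_identity || shorter_cov < min_coverage) next
    if (al$score <= 0) next
    if (evalue(al$score, nchar(qs[[qid]]), n_db, scoring) > max_evalue) next
    rows[[qid]] <- data.frame(query = qid, target = al$target_id,
                              identity = al$identity,
                              stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(query = character(0), target = character(0),
                      identity = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Average amino-acid identity between two proteomes (reciprocal best hits)
#'
#' Best hits are computed in both directions under identity, coverage (of
#' the shorter sequence) and E-value filters; reciprocal best-hit pairs are
#' retained and AAI is their mean identity, averaged over the two directed
#' measurements.
#'
#' @param a,b Named character vectors of protein sequences (one proteome
#'   each).
#' @param min_identity,min_coverage,max_evalue Hit filters.
#' @param scoring Protein [scoring_scheme()].
#' @param id_a,id_b Genome ids for the result.
#' @return A `relatedness_result` (value in percent; `NA` with
#'   `n_support = 0` when there are no reciprocal best hits).
#' @export
aai <- function(a, b, min_identity = 0.3, min_coverage = 0.7,
                max_evalue = 1e-3, scoring = scoring_scheme("protein"),
                id_a = "a", id_b = "b") {
  stopifnot(length(a) > 0, length(b) > 0)
  ab <- best_hits(a, b, scoring, min_identity, min_coverage, max_evalue)
  ba <- best_hits(b, a, scoring, min_identity, min_coverage, max_evalue)
  if (nrow(ab) == 0L || nrow(ba) == 0L) {
    return(relatedness_result(id_a, id_b, "AAI", NA_real_, 0L))
  }
  back <- setNames(ba$target, ba$query)
  recip <- ab[!is.na(back[ab$target]) & back[ab$target] == ab$query, ]
  if (nrow(recip) == 0L) {
    return(relatedness_result(id_a, id_b, "AAI", NA_real_, 0L))
  }
  ba_ident <- setNames(ba$identity, ba$query)
  value <- mean(c(mean(recip$identity), mean(ba_ident[recip$target]))) * 100
  relatedness_result(id_a, id_b, "AAI", value, nrow(recip))
}

# count of a's proteins with >= 1 qualifying hit in b (POCP filters)
pocp_conserved <- function(qs, ts, scoring, max_evalue, min_identity,
                           min_query_coverage, k = 4L, top_n = 10L) {
  idx <- kmer_index(ts, k)
  n_db <- sum(nchar(ts))
  conserved <- 0L
  for (qid in names(qs)) {
    cand <- kmer_prescreen(qs[[qid]], ts, k = k, min_shared = 1L, index = idx)
    for (tid in head(cand, top_n)) {
      al <- align_local(qs[[qid]], ts[[tid]], scoring)
      if (al$score <= 0) next
      if (al$identity >= min_identity &&
          al$query_coverage >= min_query_coverage &&
          evalue(al$score, nchar(qs[[qid]]), n_db, scoring) <= max_evalue) {
        conserved <- conserved + 1L
        break
      }
    }
  }
  conserved
}

#' Percentage of conserved proteins between two proteomes
#'
#' `POCP = 100 * (C1 + C2) / (T1 + T2)` where `C1` is the number of proteins
#' of `a` with at least one hit in `b` passing the E-value, identity and
#' query-coverage filters (and `C2` symmetrically); `T1`, `T2` are the
#' proteome sizes. Zero is a valid value.
#'
#' @param a,b Named character vectors of protein sequences.
#' @param max_evalue,min_identity,min_query_coverage Hit filters (coverage is
#'   measured against the query, per the original POCP description).
#' @param scoring Protein [scoring_scheme()].
#' @param id_a,id_b Genome ids for the result.
#' @return A `relatedness_result` (value in percent).
#' @export
pocp <- function(a, b, max_evalue = 1e-5, min_identity = 0.4,
                 min_query_coverage = 0.5,
                 scoring = scoring_scheme("protein"),
                 id_a = "a", id_b = "b") {
  stopifnot(length(a) > 0, length(b) > 0)
  c1 <- pocp_conserved(a, b, scoring, max_evalue, min_identity,
                       min_query_coverage)
  c2 <- pocp_conserved(b, a, scoring, max_evalue, min_identity,
                       min_query_coverage)
  value <- 100 * (c1 + c2) / (length(a) + length(b))
  relatedness_result(id_a, id_b, "POCP", value, c1 + c2)
}

#' All-pairs relatedness matrix for one metric
#'
#' @param inputs Named list: genomes (single DNA strings) for `"ANI"`,
#'   proteomes (named character vectors) for `"AAI"`/`"POCP"`.
#' @param metric `"ANI"`, `"AAI"` or `"POCP"`.
#' @param ... Passed to [ani()], [aai()] or [pocp()].
#' @return List with `long` (data.frame of pairs) and `matrix` (symmetric,
#'   100 on the diagonal).
#' @export
relatedness_matrix <- function(inputs, metric = c("ANI", "AAI", "POCP"), ...) {
  metric <- match.arg(metric)
  ids <- names(inputs)
  stopifnot(length(ids) >= 2L)
  fun <- switch(metric, ANI = ani, AAI = aai, POCP = pocp)
  m <- base::matrix(100, length(ids), length(ids), dimnames = list(ids, ids))
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      r <- fun(inputs[[ids[i]]], inputs[[ids[j]]], ...,
               id_a = ids[i], id_b = ids[j])
      m[ids[i], ids[j]] <- m[ids[j], ids[i]] <- r$value
      rows[[length(rows) + 1L]] <- data.frame(
        genome_a = ids[i], genome_b = ids[j], metric = metric,
        value = r$value, n_support = r$n_support, stringsAsFactors = FALSE)
    }
  }
  list(long = do.call(rbind, rows), matrix = m)
}
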