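# Shared pairwise-alignment machinery used by ortholog clustering, ANI, AAI
# and POCP: Smith-Waterman local alignment with affine gaps (via Biostrings),
# identity/coverage bookkeeping, a k-mer candidate prescreen, and
# Karlin-Altschul E-values approximating the BLAST-style E-value filters.

#' Build an alignment scoring scheme
#'
#' Nucleotide scoring is match/mismatch based; protein scoring uses a named
#' substitution matrix shipped with Biostrings (BLOSUM62 by default). Gap
#' penalties are negative scores: a gap of length L contributes
#' `gap_open + L * gap_extend` to the score. `lambda` and `K` are the
#' Karlin-Altschul parameters used by [evalue()]; defaults are the standard
#' gapped values for each alphabet.
#'
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param match,mismatch Nucleotide match/mismatch scores (ignored for
#'   protein).
#' @param matrix Protein substitution matrix name (ignored for nucleotide).
#' @param gap_open,gap_extend Negative gap penalties; `|gap_extend|` must not
#'   exceed `|gap_open|`.
#' @param lambda,K Karlin-Altschul parameters (both > 0).
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(alphabet = c("nucleotide", "protein"),
                           match = 1L, mismatch = -2L,
                           matrix = "BLOSUM62",
                           gap_open = if (alphabet == "protein") -11L else -5L,
                           gap_extend = if (alphabet == "protein") -1L else -2L,
                           lambda = if (alphabet == "protein") 0.267 else 1.28,
                           K = if (alphabet == "protein") 0.041 else 0.46) {
  alphabet <- match.arg(alphabet)
  stopifnot(gap_open < 0, gap_extend < 0, abs(gap_extend) <= abs(gap_open),
            lambda > 0, K > 0)
  submat <- if (alphabet == "nucleotide") {
    Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                             baseOnly = FALSE)
  } else {
    get(utils::data(list = matrix, package = "Biostrings",
                    envir = environment()), envir = environment())
  }
  structure(list(alphabet = alphabet, match = match, mismatch = mismatch,
                 matrix_name = if (alphabet == "protein") matrix else NA_character_,
                 submat = submat,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

as_xstring <- function(x, alphabet) {
  if (alphabet == "nucleotide") Biostrings::DNAString(x) else Biostrings::AAString(x)
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman local alignment under affine gap penalties. Identity is
#' computed over all alignment columns, internal gap columns included (the
#' stricter BLAST-style "identities / alignment length"); coverage is the
#' fraction of each full sequence inside the aligned region.
#'
#' @param a,b Sequences (single strings) over the scheme's alphabet.
#' @param scoring A [scoring_scheme()].
#' @param query_id,target_id Optional ids carried into the result.
#' @return A list of class `pairwise_alignment` with elements `query_id`,
#'   `target_id`, `score`, `n_columns`, `n_matches`, `identity`,
#'   `query_coverage`, `target_coverage`, `query_range`, `target_range`.
#' @export
align_local <- function(a, b, scoring = scoring_scheme(),
                        query_id = NA_character_, target_id = NA_character_) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("cannot align an empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    as_xstring(a, scoring$alphabet), as_xstring(b, scoring$alphabet),
    type = "local", substitutionMatrix = scoring$submat,
    gapOpening = abs(scoring$gap_open), gapExtension = abs(scoring$gap_extend))
  n_columns <- Biostrings::nchar(pa)
  n_matches <- Biostrings::nmatch(pa)
  qr <- c(Biostrings::start(Biostrings::pattern(pa)),
          Biostrings::end(Biostrings::pattern(pa)))
  tr <- c(Biostrings::start(Biostrings::subject(pa)),
          Biostrings::end(Biostrings::subject(pa)))
  structure(list(
    query_id = query_id, target_id = target_id,
    score = Biostrings::score(pa),
    n_columns = n_columns, n_matches = n_matches,
    identity = if (n_columns > 0L) n_matches / n_columns else 0,
    query_coverage = (qr[2] - qr[1] + 1) / nchar(a),
    target_coverage = (tr[2] - tr[1] + 1) / nchar(b),
    query_range = qr, target_range = tr
  ), class = "pairwise_alignment")
}

# distinct k-mers of one sequence (character(0) when shorter than k)
kmer_set <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) return(character(0))
  unique(substring(sequence, 1:(n - k + 1L), k:n))
}

#' Rank alignment targets by shared k-mer content
#'
#' Fast prescreen used to order and limit full local alignments: targets are
#' ranked by the number of distinct k-mers they share with the query, and
#' targets sharing fewer than `min_shared` are dropped (`min_shared = 0`
#' keeps every target). The prescreen is a heuristic ordering device; it
#' makes no superset guarantee relative to downstream alignment filters.
#'
#' @param query Query sequence.
#' @param targets Named character vector of target sequences.
#' @param k K-mer size (>= 4).
#' @param min_shared Minimum shared distinct k-mer count.
#' @param index Optional precomputed list of target k-mer sets (from
#'   [kmer_index()]), to amortise indexing across queries.
#' @return Character vector of target ids, best candidate first (stable in
#'   input order on ties).
#' @export
kmer_prescreen <- function(query, targets, k = 8L, min_shared = 1L,
                           index = NULL) {
  stopifnot(k >= 4L)
  if (is.null(index)) index <- kmer_index(targets, k)
  qk <- kmer_set(query, k)
  counts <- vapply(index, function(tk) sum(qk %in% tk), integer(1))
  ord <- order(-counts)
  ids <- names(targets)[ord]
  if (min_shared > 0L) ids <- ids[counts[ord] >= min_shared]
  ids
}

#' Precompute distinct k-mer sets for a target collection
#' @param targets Named character vector of sequences.
#' @param k K-mer size.
#' @return Named list of character vectors (distinct k-mers per target).
#' @export
kmer_index <- function(targets, k = 8L) {
  lapply(targets, kmer_set, k = k)
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of local
#' alignments scoring at least `S` between a random query of length `m` and a
#' database of length `n`. An acknowledged approximation of BLAST's E-value;
#' downstream modules expose every E-value threshold so the filters, not the
#' exact E, carry the semantics.
#'
#' @param score Alignment score (> 0).
#' @param m Query length.
#' @param n Database length (total residues searched).
#' @param scoring A [scoring_scheme()] supplying `lambda` and `K`.
#' @return The E-value.
#' @export
evalue <- function(score, m, n, scoring = scoring_scheme()) {
  stopifnot(score > 0)
  if (m <= 0 || n <= 0) stop("m and n must be positive")
  scoring$K * m * n * exp(-scoring$lambda * score)
}

#' Best local-alignment hit of a query against a target collection
#'
#' Prescreens targets by shared k-mers, fully aligns the top candidates and
#' returns the highest-scoring alignment (or `NULL` when no candidate
#' passes the prescreen).
#'
#' @param query Query sequence.
#' @param targets Named character vector of target sequences.
#' @param scoring A [scoring_scheme()].
#' @param k,min_shared Prescreen parameters (see [kmer_prescreen()]).
#' @param top_n Number of top-ranked candidates to align fully.
#' @param index Optional precomputed [kmer_index()].
#' @param query_id Optional id carried into the alignment.
#' @return A `pairwise_alignment` or `NULL`.
#' @export
best_local_hit <- function(query, targets, scoring, k = 4L, min_shared = 1L,
                           top_n = 5L, index = NULL, query_id = NA_character_) {
  cand <- kmer_prescreen(query, targets, k = k, min_shared = min_shared,
                         index = index)
  if (length(cand) == 0L) return(NULL)
  cand <- head(cand, top_n)
  best <- NULL
  for (id in cand) {
    al <- align_local(query, targets[[id]], scoring,
                      query_id = query_id, target_id = id)
    if (is.null(best) || al$score > best$score) best <- al
  }
  best
}

#' Reverse complement of a DNA string
#' @param sequence DNA sequence over `A,C,G,T,N`.
#' @return The reverse complement string.
#' @export
reverse_complement <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}
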