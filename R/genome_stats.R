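# Descriptive genome statistics: GC content, coding fraction, mean gene
# length, and interval spans for features such as genomic islands.

# half-away-from-zero rounding (base round() rounds half to even)
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' GC content of a DNA sequence
#'
#' Percentage of G and C bases over the full sequence length. Ambiguous `N`
#' bases count in the denominator (the usual assembly-report convention);
#' complete genomes typically contain none, so the choice is immaterial for
#' finished assemblies.
#'
#' @param sequence A single DNA sequence string over `A,C,G,T,N`.
#' @return GC percentage in `[0, 100]`, rounded half-up to 2 decimals.
#' @export
gc_content <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  if (n == 0L) stop("empty sequence")
  gc <- nchar(gsub("[^GCgc]", "", sequence))
  round_half_up(100 * gc / n, 2L)
}

#' Coding fraction and mean gene length
#'
#' Given the combined length of all predicted ORFs, the ORF count and the
#' genome length, returns the coding percentage (to 2 decimals, half-up) and
#' the mean gene length (nearest integer). Overlapping ORFs can push the
#' combined ORF length past the genome length; that case warns rather than
#' fails.
#'
#' @param total_orf_bp Combined length of all ORFs in bp.
#' @param n_orfs Number of ORFs (> 0).
#' @param genome_length_bp Genome length in bp.
#' @return List with `coding_percent` and `mean_gene_length_bp`.
#' @export
coding_statistics <- function(total_orf_bp, n_orfs, genome_length_bp) {
  stopifnot(total_orf_bp > 0, genome_length_bp > 0)
  if (n_orfs <= 0) stop("n_orfs must be positive")
  if (total_orf_bp > genome_length_bp) {
    warning("combined ORF length exceeds genome length (overlapping ORFs?)")
  }
  list(
    coding_percent = round_half_up(100 * total_orf_bp / genome_length_bp, 2L),
    mean_gene_length_bp = as.integer(round_half_up(total_orf_bp / n_orfs))
  )
}

#' Span of a genomic interval
#'
#' Length of a coordinate interval under the half-open convention
#' `[start, end)`: `end - start`. This is the convention under which the
#' printed totals of annotated genomic islands match their printed
#' coordinates exactly.
#'
#' @param start,end Integer coordinates with `end >= start`.
#' @return `end - start`.
#' @export
interval_span <- function(start, end) {
  stopifnot(is.numeric(start), is.numeric(end))
  if (any(end < start)) stop("end must be >= start")
  as.integer(end - start)
}

#' Summarise a genome
#'
#' @param genome_id Genome identifier.
#' @param sequence Genome DNA sequence.
#' @param total_orf_bp Combined ORF length in bp.
#' @param n_orfs Number of ORFs.
#' @return A one-row data.frame (`genome_id`, `length_bp`, `gc_percent`,
#'   `n_orfs`, `total_orf_bp`, `coding_percent`, `mean_gene_length_bp`).
#' @export
genome_summary <- function(genome_id, sequence, total_orf_bp, n_orfs) {
  cs <- coding_statistics(total_orf_bp, n_orfs, nchar(sequence))
  data.frame(
    genome_id = genome_id,
    length_bp = nchar(sequence),
    gc_percent = gc_content(sequence),
    n_orfs = as.integer(n_orfs),
    total_orf_bp = as.integer(total_orf_bp),
    coding_percent = cs$coding_percent,
    mean_gene_length_bp = cs$mean_gene_length_bp,
    stringsAsFactors = FALSE
  )
}
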