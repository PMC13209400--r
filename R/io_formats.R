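# Readers and writers for the external formats the pipeline consumes and
# produces: FASTA (genomes, proteomes), tab-separated annotation/metadata/
# module tables, presence matrices, Newick dendrograms and JSON reports.
# All readers validate; corrupt input is an error, never silently masked.

NUC_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased on read; for nucleotide input, `U` is folded to
#' `T` so RNA-convention files read as DNA. Any residue outside the declared
#' alphabet (`A,C,G,T,N` for nucleotide; the 20 standard amino acids plus `X`
#' for protein) is an error naming the offending record, as are duplicate ids
#' and empty sequences.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  # keep only the id token of each header
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (alphabet == "nucleotide") seqs <- gsub("U", "T", seqs, fixed = TRUE)
  names(seqs) <- ids
  allowed <- if (alphabet == "nucleotide") NUC_ALPHABET else AA_ALPHABET
  bad_re <- paste0("[^", paste(allowed, collapse = ""), "]")
  for (i in seq_along(seqs)) {
    if (nchar(seqs[[i]]) == 0L) {
      stop("empty sequence for record '", ids[[i]], "' in ", path)
    }
    if (grepl(bad_re, seqs[[i]])) {
      offending <- unique(strsplit(gsub(paste0("[", paste(allowed, collapse = ""), "]"),
                                        "", seqs[[i]]), "")[[1]])
      stop("record '", ids[[i]], "' contains characters outside the ",
           alphabet, " alphabet: ", paste(offending, collapse = ", "))
    }
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (cosmetic; any width reads back identically).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

# shared TSV reader: header line, '#' comment lines skipped, UTF-8
read_tsv_checked <- function(path, required, label) {
  if (!file.exists(path)) stop(label, " table not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE,
                   fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(label, " table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), required)
  if (length(extra) > 0L) {
    warning(label, " table ", path, ": ignoring unknown column(s) ",
            paste(extra, collapse = ", "))
  }
  df[required]
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a protein annotation table
#'
#' Expects tab-separated columns `protein_id`, `genome_id`, `cog` (COG
#' category letters, concatenated, may be empty) and `kos` (semicolon-joined
#' KEGG Orthology ids, may be empty). COG letters must be among the 26
#' category letters; KO ids must match `K` + 5 digits.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `protein_id`, `genome_id`, and list
#'   columns `cog_letters`, `kos`.
#' @export
read_annotation <- function(path) {
  df <- read_tsv_checked(path, c("protein_id", "genome_id", "cog", "kos"),
                         "annotation")
  if (anyDuplicated(df$protein_id)) {
    stop("duplicate protein_id in annotation table: ",
         paste(head(unique(df$protein_id[duplicated(df$protein_id)]), 5L),
               collapse = ", "))
  }
  cog_letters <- lapply(toupper(trimws(df$cog)), function(s) {
    if (is.na(s) || s == "") character(0) else unique(strsplit(s, "")[[1]])
  })
  bad_cog <- vapply(cog_letters, function(x) any(!x %in% COG_LETTERS), logical(1))
  if (any(bad_cog)) {
    stop("invalid COG category letter(s) for protein(s): ",
         paste(head(df$protein_id[bad_cog], 5L), collapse = ", "))
  }
  kos <- lapply(trimws(df$kos), function(s) {
    if (is.na(s) || s == "") character(0)
    else unique(trimws(strsplit(s, ";", fixed = TRUE)[[1]]))
  })
  bad_ko <- vapply(kos, function(x) any(!grepl(KO_PATTERN, x)), logical(1))
  if (any(bad_ko)) {
    stop("malformed KO identifier(s) for protein(s): ",
         paste(head(df$protein_id[bad_ko], 5L), collapse = ", "),
         " (expected K followed by 5 digits)")
  }
  out <- data.frame(protein_id = df$protein_id, genome_id = df$genome_id,
                    stringsAsFactors = FALSE)
  out$cog_letters <- cog_letters
  out$kos <- kos
  out
}

#' Read a genome metadata table
#'
#' Expects tab-separated columns `genome_id`, `environment` (one of `HTV`,
#' `nonHTV`) and `name` (free-text display name).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `genome_id`, `environment`, `name`.
#' @export
read_metadata <- function(path) {
  df <- read_tsv_checked(path, c("genome_id", "environment", "name"),
                         "metadata")
  if (anyDuplicated(df$genome_id)) {
    stop("duplicate genome_id in metadata: ",
         paste(unique(df$genome_id[duplicated(df$genome_id)]), collapse = ", "))
  }
  bad <- !df$environment %in% ENV_LEVELS
  if (any(bad)) {
    stop("environment label(s) outside {HTV, nonHTV}: ",
         paste(unique(df$environment[bad]), collapse = ", "))
  }
  df
}

#' Read KEGG module definitions
#'
#' Expects tab-separated columns `module_id`, `step_index` and `kos`
#' (comma-joined KO alternatives for that step). A module is an ordered list
#' of steps; a step is satisfied when any one of its alternative KOs is
#' annotated.
#'
#' @param path Path to the TSV file.
#' @return A named list of module definitions; each is a list with elements
#'   `module_id` and `steps` (a list of character vectors of KO ids, in step
#'   order).
#' @export
read_modules <- function(path) {
  df <- read_tsv_checked(path, c("module_id", "step_index", "kos"), "module")
  df$step_index <- as.integer(df$step_index)
  if (anyNA(df$step_index)) stop("non-integer step_index in module table")
  mods <- lapply(split(df, df$module_id), function(m) {
    m <- m[order(m$step_index), ]
    steps <- lapply(m$kos, function(s) {
      kos <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
      kos <- kos[nzchar(kos)]
      if (length(kos) == 0L) stop("empty KO step in module ", m$module_id[1])
      bad <- !grepl(KO_PATTERN, kos)
      if (any(bad)) {
        stop("malformed KO id in module ", m$module_id[1], ": ",
             paste(kos[bad], collapse = ", "))
      }
      kos
    })
    list(module_id = m$module_id[1], steps = steps)
  })
  mods[order(names(mods))]
}

#' Write an annotation table to TSV
#'
#' Inverse of [read_annotation()]: list columns are re-joined (`cog` letters
#' concatenated, KO ids semicolon-separated).
#'
#' @param annotation Annotation data.frame as returned by [read_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  df <- data.frame(
    protein_id = annotation$protein_id,
    genome_id = annotation$genome_id,
    cog = vapply(annotation$cog_letters, paste, character(1), collapse = ""),
    kos = vapply(annotation$kos, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}

#' Write a genome metadata table to TSV
#' @param metadata Metadata data.frame as returned by [read_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  write_tsv(metadata[c("genome_id", "environment", "name")], path)
}

#' Write module definitions to TSV
#' @param modules Named list of module definitions (see [read_modules()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_modules <- function(modules, path) {
  rows <- do.call(rbind, lapply(modules, function(m) {
    data.frame(module_id = m$module_id,
               step_index = seq_along(m$steps),
               kos = vapply(m$steps, paste, character(1), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  write_tsv(rows, path)
}

#' Write a presence/absence matrix to TSV
#'
#' Rows are gene clusters, columns genomes; cells are 0/1. The first column,
#' `cluster_id`, carries the row names.
#'
#' @param matrix Logical matrix with cluster-id rownames and genome-id
#'   colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(matrix, path) {
  df <- data.frame(cluster_id = rownames(matrix),
                   matrix + 0L, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a presence/absence matrix from TSV
#' @param path Path written by [write_presence_matrix()].
#' @return Logical matrix (clusters x genomes).
#' @export
read_presence_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "cluster_id") stop("presence matrix must start with a cluster_id column")
  m <- as.matrix(df[, -1, drop = FALSE]) > 0
  rownames(m) <- df$cluster_id
  validate_presence_matrix(m)
  m
}

validate_presence_matrix <- function(matrix) {
  if (!is.matrix(matrix) || !is.logical(matrix)) {
    stop("presence matrix must be a logical matrix")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("presence matrix needs cluster-id rownames and genome-id colnames")
  }
  empty <- rowSums(matrix) == 0L
  if (any(empty)) {
    stop("presence matrix has all-absent row(s): ",
         paste(head(rownames(matrix)[empty], 5L), collapse = ", "))
  }
  invisible(matrix)
}

#' Write a dendrogram to a Newick file
#' @param dendrogram A dendrogram as returned by [upgma()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendrogram, path) {
  ape::write.tree(as_phylo(dendrogram), file = path)
  invisible(path)
}
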