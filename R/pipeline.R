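# End-to-end orchestration over the synthetic study design: simulate a
# pan-genome, partition it, fit openness, test environment association,
# score COG enrichment per direction, profile module completeness, and
# (optionally) exercise the sequence-level stages (ortholog clustering and
# ANI) at a small scale. One root seed drives every stage deterministically.

#' Build and validate a pipeline configuration
#'
#' All thresholds of every stage in one place. Defaults mirror the study
#' design the synthetic generator emulates: 16 genomes split 2 HTV vs 14
#' non-HTV, ~800 core families, a U-shaped accessory spectrum, and planted
#' 57 HTV-specific plus 82 non-HTV-specific clusters.
#'
#' @param seed Root seed (mandatory; every stochastic stage derives its own
#'   seed from it).
#' @param out_dir Output directory (created if needed); `NULL` for no files.
#' @param n_genomes,n_htv,n_core,n_accessory,unique_rate,n_planted_htv,n_planted_nonhtv
#'   Generator design (see [simulate_pangenome()]).
#' @param alpha Raw-p significance threshold of the association stage.
#' @param ei_threshold COG enrichment-index threshold.
#' @param n_permutations Rarefaction permutations.
#' @param identity_threshold,coverage_threshold Ortholog clustering cutoffs.
#' @param do_sequences Run the sequence-level demonstration stages.
#' @param seq_n_families,seq_divergence Proteome simulation for the
#'   clustering stage.
#' @param ani_genome_bp,ani_divergence Genome-pair simulation for the ANI
#'   stage.
#' @return Validated config list of class `run_config`.
#' @export
run_config <- function(seed, out_dir = NULL,
                       n_genomes = 16L, n_htv = 2L,
                       n_core = 800L, n_accessory = 1200L, unique_rate = 40,
                       n_planted_htv = 57L, n_planted_nonhtv = 82L,
                       alpha = 0.05, ei_threshold = 2,
                       n_permutations = 20L,
                       identity_threshold = 0.5, coverage_threshold = 0.8,
                       do_sequences = TRUE,
                       seq_n_families = 25L, seq_divergence = 0.10,
                       ani_genome_bp = 20000L, ani_divergence = 0.05) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("a single integer seed is mandatory")
  }
  config <- list(seed = as.integer(seed), out_dir = out_dir,
                 n_genomes = n_genomes, n_htv = n_htv, n_core = n_core,
                 n_accessory = n_accessory, unique_rate = unique_rate,
                 n_planted_htv = n_planted_htv,
                 n_planted_nonhtv = n_planted_nonhtv,
                 alpha = alpha, ei_threshold = ei_threshold,
                 n_permutations = n_permutations,
                 identity_threshold = identity_threshold,
                 coverage_threshold = coverage_threshold,
                 do_sequences = isTRUE(do_sequences),
                 seq_n_families = seq_n_families,
                 seq_divergence = seq_divergence,
                 ani_genome_bp = ani_genome_bp,
                 ani_divergence = ani_divergence)
  with(config, {
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    if (identity_threshold <= 0 || identity_threshold > 1) {
      stop("identity_threshold must be in (0, 1]")
    }
    if (coverage_threshold <= 0 || coverage_threshold > 1) {
      stop("coverage_threshold must be in (0, 1]")
    }
    if (n_permutations < 1) stop("n_permutations must be >= 1")
    if (n_htv < 1 || n_htv >= n_genomes) stop("need 1 <= n_htv < n_genomes")
    if (seq_divergence < 0 || seq_divergence >= 1 ||
        ani_divergence < 0 || ani_divergence >= 1) {
      stop("divergences must lie in [0, 1)")
    }
  })
  structure(config, class = c("run_config", "list"))
}

# deterministic per-stage seeds below 2^31, derived from the root seed
stage_seed <- function(seed, stage) {
  (abs(seed) %% 1000003L) * 1009L + stage * 101L + 1L
}

# tiny FNV-1a hash of the deparsed config, for provenance
config_hash <- function(config) {
  s <- paste(deparse(config[sort(names(config))]), collapse = "")
  h <- 84696351  # FNV offset basis folded into 31 bits
  for (code in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h), as.integer(code))
    h <- (h * 16777619) %% 2147483648
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full pipeline on a simulated study
#'
#' Stages: simulate -> partition -> rarefaction + power-law fit ->
#' environment association -> COG enrichment per direction -> module
#' completeness + UPGMA -> (optionally) small-scale ortholog clustering and
#' ANI demonstrations. Writes stage outputs and a JSON report when
#' `config$out_dir` is set. Reruns with the same config are bit-identical.
#'
#' @param config A [run_config()].
#' @return The run report (list), invisibly also written as JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) {
    dir.create(out, recursive = TRUE)
  }
  emit <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }

  sim <- simulate_pangenome(
    n_genomes = config$n_genomes, n_htv = config$n_htv,
    n_core = config$n_core, n_accessory = config$n_accessory,
    unique_rate = config$unique_rate,
    n_planted_htv = config$n_planted_htv,
    n_planted_nonhtv = config$n_planted_nonhtv,
    plant_alpha = config$alpha,
    seed = stage_seed(config$seed, 1L))
  emit("simulate", sprintf("%d clusters x %d genomes",
                           nrow(sim$matrix), ncol(sim$matrix)))

  part <- partition(sim$matrix)
  emit("partition", sprintf("core %d / accessory %d / unique %d",
                            part$counts$core, part$counts$accessory,
                            part$counts$unique_total))

  curves <- rarefaction_curves(sim$matrix,
                               n_permutations = config$n_permutations,
                               seed = stage_seed(config$seed, 2L))
  fit <- fit_power_law(curves$x, curves$pan_median)
  emit("pangenome", sprintf("b = %.4f (%s)", fit$b,
                            if (fit$open) "open" else "closed"))

  assoc <- environment_association(sim$matrix, sim$metadata,
                                   alpha = config$alpha)
  counts <- association_counts(assoc)
  emit("associate", sprintf("%d significant (%d HTV + %d nonHTV) of %d tested",
                            counts$significant, counts$htv, counts$nonhtv,
                            counts$tested))

  fam_cogs <- sim$truth$fam_cogs
  background <- fam_cogs
  enrich <- list()
  for (dir in c("HTV", "nonHTV")) {
    focal_ids <- assoc$cluster_id[assoc$significant & assoc$direction == dir]
    enrich[[dir]] <- if (length(focal_ids) > 0L) {
      category_enrichment(fam_cogs[focal_ids], background,
                          ei_threshold = config$ei_threshold)
    } else NULL
  }
  emit("enrich", sprintf("HTV: %s; nonHTV: %s",
                         paste(enrich$HTV$category[enrich$HTV$significant],
                               collapse = ","),
                         paste(enrich$nonHTV$category[enrich$nonHTV$significant],
                               collapse = ",")))

  scores <- completeness_matrix(sim$ko_sets, sim$modules)
  dend <- upgma(profile_distance(scores))
  emit("modules", sprintf("%d modules x %d genomes; first merge: %s",
                          nrow(scores), ncol(scores),
                          paste(first_merge_pair(dend), collapse = "+")))

  seq_report <- NULL
  if (config$do_sequences) {
    prot <- simulate_proteomes(n_genomes = min(config$n_genomes, 8L),
                               n_families = config$seq_n_families,
                               divergence = config$seq_divergence,
                               seed = stage_seed(config$seed, 3L))
    clusters <- cluster_proteins(prot$proteins,
                                 identity_threshold = config$identity_threshold,
                                 coverage_threshold = config$coverage_threshold)
    fam_of <- setNames(prot$proteins$family, prot$proteins$protein_id)
    pure <- vapply(clusters, function(cl) {
      length(unique(fam_of[cl$members$protein_id])) == 1L
    }, logical(1))
    anc_seed <- stage_seed(config$seed, 4L)
    ancestor <- simulate_genome(config$ani_genome_bp, seed = anc_seed)
    derived <- evolve_sequence(ancestor, config$ani_divergence,
                               seed = anc_seed + 1L)
    ani_res <- ani(ancestor, derived, id_a = "ancestor", id_b = "derived")
    seq_report <- list(
      n_families = config$seq_n_families,
      n_clusters = length(clusters),
      clusters_pure = all(pure),
      ani_divergence = config$ani_divergence,
      ani_value = ani_res$value,
      ani_n_support = ani_res$n_support)
    emit("sequences", sprintf("%d clusters from %d families; ANI %.2f",
                              length(clusters), config$seq_n_families,
                              ani_res$value))
  }

  report <- list(
    version = as.character(utils::packageVersion("panvent")),
    seed = config$seed,
    config_hash = config_hash(unclass(config)),
    partition = part$counts,
    rarefaction = list(n_permutations = curves$n_permutations,
                       pan_final = curves$pan_median[length(curves$x)],
                       core_final = curves$core_median[length(curves$x)]),
    fit = list(A = fit$A, b = fit$b, rss = fit$rss, open = fit$open),
    association = counts,
    enrichment = list(
      HTV = enrich$HTV$category[enrich$HTV$significant],
      nonHTV = enrich$nonHTV$category[enrich$nonHTV$significant]),
    modules = list(n_modules = nrow(scores),
                   first_merge = first_merge_pair(dend)),
    sequences = seq_report
  )
  # internal consistency: every stage must agree on the cluster ledger
  stopifnot(part$counts$core + part$counts$accessory +
              part$counts$unique_total == part$counts$total,
            counts$significant == counts$htv + counts$nonhtv,
            counts$tested == part$counts$accessory + part$counts$unique_total)

  if (!is.null(out)) {
    write_presence_matrix(sim$matrix, file.path(out, "presence_matrix.tsv"))
    write_metadata(sim$metadata, file.path(out, "metadata.tsv"))
    write_tsv(data.frame(cluster_id = c(part$core, part$accessory,
                                        unlist(part$unique, use.names = FALSE)),
                         compartment = rep(c("core", "accessory", "unique"),
                                           c(part$counts$core,
                                             part$counts$accessory,
                                             part$counts$unique_total))),
              file.path(out, "partition.tsv"))
    write_tsv(data.frame(x = curves$x, pan_median = curves$pan_median,
                         core_median = curves$core_median),
              file.path(out, "rarefaction.tsv"))
    write_tsv(as.data.frame(assoc), file.path(out, "association.tsv"))
    for (dir in names(enrich)) {
      if (!is.null(enrich[[dir]])) {
        write_tsv(enrich[[dir]],
                  file.path(out, sprintf("enrichment_%s.tsv", dir)))
      }
    }
    write_tsv(data.frame(module_id = rownames(scores),
                         as.data.frame(scores), check.names = FALSE),
              file.path(out, "module_scores.tsv"))
    write_newick(dend, file.path(out, "modules.nwk"))
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
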