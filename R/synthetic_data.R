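# Seeded generators for every kind of input the pipeline consumes: presence/
# absence pan-genomes with planted core/accessory/unique structure and
# environment-specific clusters, COG and KO annotations with known module
# content, and nucleotide/protein sequences evolved at controlled divergence.
# Each generator is a pure function of its parameters plus a seed, so the
# planted truth is an exact oracle for the downstream stages.

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

# default COG category frequencies, loosely shaped like a small bacterial
# genome (metabolism- and signalling-heavy, large unknown-function class)
default_cog_weights <- function() {
  w <- c(J = 5, A = 0.2, K = 5, L = 4, B = 0.2,
         D = 1, Y = 0.2, V = 2, T = 7, M = 6, N = 3, Z = 0.2, W = 0.5, U = 2,
         O = 4, C = 8, G = 5, E = 8, F = 2, H = 6, I = 3, P = 7, Q = 2,
         R = 8, S = 10, X = 1)
  w / sum(w)
}

#' Simulate a random genome sequence
#'
#' @param length_bp Genome length in bp.
#' @param gc Target GC fraction in (0, 1).
#' @param seed Integer seed.
#' @return A single DNA string.
#' @export
simulate_genome <- function(length_bp, gc = 0.38, seed = 1L) {
  stopifnot(length_bp >= 1, gc > 0, gc < 1)
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), length_bp, replace = TRUE, prob = p), collapse = "")
  })
}

#' Evolve a sequence by point substitution and optional indels
#'
#' Each site is substituted with probability `substitution_rate` to a
#' uniformly chosen different symbol. Indels are applied per site at
#' `indel_rate` (half deletions, half single-symbol insertions). With
#' `indel_rate = 0` the expected pairwise identity to the ancestor is exactly
#' `1 - substitution_rate`, which makes the divergence parameter an
#' analytical oracle for ANI/AAI checks.
#'
#' @param ancestor Sequence string.
#' @param substitution_rate Per-site substitution probability in `[0, 1)`.
#' @param indel_rate Per-site indel probability in `[0, 1)`.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param seed Integer seed.
#' @return The evolved sequence string.
#' @export
evolve_sequence <- function(ancestor, substitution_rate = 0,
                            indel_rate = 0,
                            alphabet = c("nucleotide", "protein"),
                            seed = 1L) {
  alphabet <- match.arg(alphabet)
  stopifnot(substitution_rate >= 0, substitution_rate < 1,
            indel_rate >= 0, indel_rate < 1)
  if (nchar(ancestor) == 0L) stop("empty ancestor sequence")
  symbols <- if (alphabet == "nucleotide") c("A", "C", "G", "T") else AA20
  with_seed(seed, {
    chars <- strsplit(ancestor, "", fixed = TRUE)[[1]]
    n <- length(chars)
    if (substitution_rate > 0) {
      hit <- which(runif(n) < substitution_rate)
      if (length(hit) > 0L) {
        # uniform over the other symbols
        repl <- vapply(chars[hit], function(ch) {
          sample(setdiff(symbols, ch), 1L)
        }, character(1))
        chars[hit] <- repl
      }
    }
    if (indel_rate > 0) {
      u <- runif(length(chars))
      del <- u < indel_rate / 2
      ins <- u >= indel_rate / 2 & u < indel_rate
      pieces <- chars
      pieces[del] <- ""
      if (any(ins)) {
        pieces[ins] <- paste0(chars[ins],
                              sample(symbols, sum(ins), replace = TRUE))
      }
      chars <- strsplit(paste(pieces, collapse = ""), "", fixed = TRUE)[[1]]
    }
    paste(chars, collapse = "")
  })
}

#' Simulate proteomes with known family labels
#'
#' Draws one random ancestor protein per family (length uniform in
#' `length_range`), then evolves one descendant per genome at the given
#' divergence. The returned truth table labels every protein with its family,
#' providing an exact oracle for ortholog clustering.
#'
#' @param n_genomes Number of genomes.
#' @param n_families Number of gene families (>= 1).
#' @param divergence Per-site amino-acid substitution rate.
#' @param seed Integer seed.
#' @param length_range Ancestor length range (residues).
#' @return List with `proteins` (data.frame `protein_id`, `genome_id`,
#'   `sequence`, `family`), `proteomes` (named list of named character
#'   vectors per genome), and `ancestors`.
#' @export
simulate_proteomes <- function(n_genomes, n_families, divergence = 0.1,
                               seed = 1L, length_range = c(80L, 400L)) {
  stopifnot(n_families >= 1, n_genomes >= 1)
  with_seed(seed, {
    genome_ids <- sprintf("G%02d", seq_len(n_genomes))
    fam_ids <- sprintf("fam%03d", seq_len(n_families))
    lens <- sample(seq(length_range[1], length_range[2]), n_families,
                   replace = TRUE)
    ancestors <- setNames(vapply(lens, function(L) {
      paste(sample(AA20, L, replace = TRUE), collapse = "")
    }, character(1)), fam_ids)
    rows <- vector("list", n_genomes * n_families)
    i <- 0L
    for (g in genome_ids) {
      for (f in fam_ids) {
        i <- i + 1L
        child_seed <- sample.int(.Machine$integer.max, 1L)
        rows[[i]] <- data.frame(
          protein_id = paste0(g, "_", f),
          genome_id = g,
          sequence = evolve_sequence(ancestors[[f]], divergence,
                                     alphabet = "protein", seed = child_seed),
          family = f,
          stringsAsFactors = FALSE
        )
      }
    }
    proteins <- do.call(rbind, rows)
    proteomes <- lapply(split(proteins, proteins$genome_id), function(d) {
      setNames(d$sequence, d$protein_id)
    })
    list(proteins = proteins, proteomes = proteomes, ancestors = ancestors)
  })
}

# two-sided Fisher p for a 2x2 presence table, used to keep non-planted
# accessory families clear of the association caller's significance region
table_p <- function(n_in, n_htv, n_non) {
  a <- sum(n_in[1]); cc <- n_in[2]
  stats::fisher.test(matrix(c(a, n_htv - a, cc, n_non - cc), nrow = 2,
                            byrow = TRUE))$p.value
}

#' Simulate a pan-genome presence/absence dataset with planted structure
#'
#' Emulates a small multi-genome comparative study: a fixed core present in
#' every genome, an accessory compartment whose per-family occurrence
#' probabilities are drawn from a U-shaped Beta distribution (mimicking the
#' bimodal gene-frequency spectrum of open pan-genomes), Poisson-distributed
#' strain-unique families, and planted environment-specific clusters
#' (present in every HTV genome and in at most `planted_leak` non-HTV
#' genomes, and vice versa). Non-planted accessory families whose occurrence
#' pattern would reach Fisher significance at `plant_alpha` by chance are
#' resampled (then neutralised), so the planted sets are exactly the
#' significant associations — the generator guarantees separability so its
#' truth record is an exact oracle.
#'
#' COG category letters are attached per family from `cog_weights`; planted
#' HTV families are biased toward the configured enrichment letters
#' (amino-acid and coenzyme metabolism by default), planted non-HTV families
#' toward unknown function, mirroring the kind of functional signal the
#' association stage is meant to expose. KO content follows a module plan:
#' "vent" modules complete only in HTV genomes, housekeeping modules complete
#' everywhere, and one variable module spanning all four completeness
#' categories.
#'
#' @param n_genomes Total genomes.
#' @param n_htv Genomes labelled HTV (listed first).
#' @param n_core Core families.
#' @param n_accessory Accessory families drawn from the Beta spectrum.
#' @param beta_shape Two Beta shape parameters for occurrence probabilities.
#' @param unique_rate Expected unique families per genome (Poisson).
#' @param n_planted_htv,n_planted_nonhtv Planted environment-specific counts.
#' @param planted_leak Maximum opposite-group genomes carrying a planted
#'   family (0 = strictly specific).
#' @param plant_alpha Significance level the generator keeps non-planted
#'   families away from.
#' @param cog_weights Named category probabilities (26 COG letters).
#' @param seed Integer seed.
#' @return List with `matrix` (logical presence matrix), `annotation`
#'   (per-protein data.frame as from [read_annotation()]), `metadata`,
#'   `modules` (definitions as from [read_modules()]), `ko_sets` (named list
#'   genome -> KO ids), and `truth` (planted structure and expected counts).
#' @export
simulate_pangenome <- function(n_genomes = 16L, n_htv = 2L,
                               n_core = 800L, n_accessory = 1200L,
                               beta_shape = c(0.3, 0.3),
                               unique_rate = 40,
                               n_planted_htv = 57L, n_planted_nonhtv = 82L,
                               planted_leak = 0L,
                               plant_alpha = 0.05,
                               cog_weights = default_cog_weights(),
                               seed = 1L) {
  stopifnot(n_htv >= 1, n_htv < n_genomes, n_core >= 0, n_accessory >= 0,
            all(beta_shape > 0), unique_rate >= 0, planted_leak >= 0)
  with_seed(seed, {
    genome_ids <- sprintf("G%02d", seq_len(n_genomes))
    environment <- c(rep("HTV", n_htv), rep("nonHTV", n_genomes - n_htv))
    metadata <- data.frame(
      genome_id = genome_ids,
      environment = environment,
      name = c(sprintf("vent strain %d", seq_len(n_htv)),
               sprintf("reference strain %d", seq_len(n_genomes - n_htv))),
      stringsAsFactors = FALSE
    )
    htv_ids <- genome_ids[environment == "HTV"]
    non_ids <- genome_ids[environment == "nonHTV"]
    n_non <- length(non_ids)

    rows <- list()
    add_row <- function(id, present) rows[[id]] <<- present

    if (n_core > 0) {
      for (i in seq_len(n_core)) {
        add_row(sprintf("core%04d", i), rep(TRUE, n_genomes))
      }
    }

    # accessory spectrum, kept clear of the association significance region
    if (n_accessory > 0) {
      q <- rbeta(n_accessory, beta_shape[1], beta_shape[2])
      for (i in seq_len(n_accessory)) {
        ok <- FALSE
        for (try in 1:50) {
          pres <- runif(n_genomes) < q[i]
          if (!any(pres)) next
          if (all(pres)) { ok <- TRUE; break }  # lands core-like: never tested
          p <- table_p(c(sum(pres[environment == "HTV"]),
                         sum(pres[environment == "nonHTV"])), n_htv, n_non)
          if (p >= plant_alpha) { ok <- TRUE; break }
        }
        if (!ok) {
          # deterministic neutral pattern: one HTV genome, half the others
          pres <- c(rep(c(TRUE, FALSE), length.out = n_htv),
                    rep(c(TRUE, FALSE), length.out = n_non))
        }
        add_row(sprintf("acc%04d", i), pres)
      }
    }

    # strain-unique families
    unique_ids <- setNames(vector("list", n_genomes), genome_ids)
    for (g in seq_len(n_genomes)) {
      k <- stats::rpois(1L, unique_rate)
      if (k > 0) {
        ids <- sprintf("uniq_%s_%03d", genome_ids[g], seq_len(k))
        for (id in ids) {
          pres <- rep(FALSE, n_genomes); pres[g] <- TRUE
          add_row(id, pres)
        }
        unique_ids[[g]] <- ids
      } else unique_ids[[g]] <- character(0)
    }

    # planted environment-specific families
    plant <- function(prefix, n, in_idx, out_idx) {
      ids <- character(n)
      for (i in seq_len(n)) {
        pres <- rep(FALSE, n_genomes)
        pres[in_idx] <- TRUE
        if (planted_leak > 0) {
          n_leak <- sample(0:min(planted_leak, length(out_idx)), 1L)
          if (n_leak > 0) pres[sample(out_idx, n_leak)] <- TRUE
        }
        ids[i] <- sprintf("%s%03d", prefix, i)
        add_row(ids[i], pres)
      }
      ids
    }
    htv_idx <- which(environment == "HTV")
    non_idx <- which(environment == "nonHTV")
    planted_htv <- plant("pat_htv_", n_planted_htv, htv_idx, non_idx)
    planted_nonhtv <- plant("pat_non_", n_planted_nonhtv, non_idx, htv_idx)

    if (length(rows) == 0L) stop("specification yields zero gene families")
    cluster_ids <- sort(names(rows))
    mat <- do.call(rbind, rows[cluster_ids])
    dimnames(mat) <- list(cluster_ids, genome_ids)

    # COG letters per family; planted families biased toward their
    # characteristic categories (3x boost)
    boost <- function(w, letters, factor = 3) {
      w[letters] <- w[letters] * factor
      w / sum(w)
    }
    draw_letters <- function(w) {
      k <- 1L + (runif(1) < 0.15)  # ~15% of families carry two letters
      sample(names(w), k, prob = w)
    }
    fam_cogs <- setNames(vector("list", length(cluster_ids)), cluster_ids)
    w_htv <- boost(cog_weights, c("E", "H"))
    w_non <- boost(cog_weights, "S")
    for (id in cluster_ids) {
      w <- if (id %in% planted_htv) w_htv
           else if (id %in% planted_nonhtv) w_non
           else cog_weights
      fam_cogs[[id]] <- draw_letters(w)
    }

    modules <- default_module_plan()
    ko_sets <- module_plan_ko_sets(modules, genome_ids, htv_ids)

    # per-protein annotation: one protein per (family, genome) occurrence;
    # each genome's KOs are spread over its core proteins
    ann_rows <- list()
    for (g in genome_ids) {
      fams <- cluster_ids[mat[, g]]
      pid <- paste0(g, "|", fams)
      kos <- rep(list(character(0)), length(fams))
      gk <- ko_sets[[g]]
      if (length(gk) > 0) {
        # spread the genome's KOs over its first proteins (cyclically if few)
        slot <- rep(seq_len(length(fams)), length.out = length(gk))
        for (j in unique(slot)) kos[[j]] <- gk[slot == j]
      }
      d <- data.frame(protein_id = pid, genome_id = g, stringsAsFactors = FALSE)
      d$cog_letters <- unname(fam_cogs[fams])
      d$kos <- kos
      d$cluster_id <- fams
      ann_rows[[g]] <- d
    }
    annotation <- do.call(rbind, ann_rows)
    rownames(annotation) <- NULL

    truth <- list(
      seed = seed,
      n_genomes = n_genomes, n_htv = n_htv,
      core_ids = grep("^core", cluster_ids, value = TRUE),
      accessory_sampled = grep("^acc", cluster_ids, value = TRUE),
      unique_ids = unique_ids,
      planted_htv = planted_htv,
      planted_nonhtv = planted_nonhtv,
      fam_cogs = fam_cogs,
      htv_cog_letters = c("E", "H"),
      nonhtv_cog_letters = "S",
      module_plan = attr(ko_sets, "plan")
    )
    list(matrix = mat, annotation = annotation, metadata = metadata,
         modules = modules, ko_sets = ko_sets, truth = truth)
  })
}

# module definitions used by the generator: three vent-only modules (analogues
# of heme/glycine-cleavage/lipoate units), two housekeeping modules complete
# everywhere, one module spanning all completeness categories
default_module_plan <- function() {
  mk <- function(module_id, n_steps, first_ko, alt_steps = integer(0)) {
    kos <- sprintf("K9%04d", first_ko + seq_len(n_steps) - 1L)
    steps <- lapply(seq_len(n_steps), function(i) {
      if (i %in% alt_steps) c(kos[i], sprintf("K9%04d", first_ko + 50L + i)) else kos[i]
    })
    list(module_id = module_id, steps = steps)
  }
  mods <- list(
    mk("M_vent_heme", 5L, 100L, alt_steps = 2L),
    mk("M_vent_gcs", 4L, 200L),
    mk("M_vent_lip", 3L, 300L),
    mk("M_house_info", 6L, 400L, alt_steps = 5L),
    mk("M_house_energy", 5L, 500L),
    mk("M_variable", 5L, 600L)
  )
  setNames(mods, vapply(mods, `[[`, character(1), "module_id"))
}

# which genomes carry which module KOs: vent modules complete in HTV genomes
# only; housekeeping complete in all; the variable module complete in some
# genomes, missing 1-2 steps in others, missing >= 3 in others, absent in
# the rest (cycled deterministically over the non-HTV genomes)
module_plan_ko_sets <- function(modules, genome_ids, htv_ids) {
  first_ko <- function(step) step[1]
  full <- function(m) vapply(m$steps, first_ko, character(1))
  plan <- list()
  ko_sets <- setNames(rep(list(character(0)), length(genome_ids)), genome_ids)
  for (g in genome_ids) {
    kos <- c(full(modules[["M_house_info"]]), full(modules[["M_house_energy"]]))
    if (g %in% htv_ids) {
      kos <- c(kos, full(modules[["M_vent_heme"]]),
               full(modules[["M_vent_gcs"]]), full(modules[["M_vent_lip"]]))
    }
    ko_sets[[g]] <- kos
  }
  var_kos <- full(modules[["M_variable"]])
  non_htv <- setdiff(genome_ids, htv_ids)
  for (i in seq_along(non_htv)) {
    g <- non_htv[i]
    kind <- (i - 1L) %% 4L  # 0 complete, 1 missing 1, 2 missing 3, 3 absent
    keep <- switch(as.character(kind),
                   "0" = var_kos,
                   "1" = var_kos[-1],
                   "2" = var_kos[1:2],
                   "3" = character(0))
    ko_sets[[g]] <- c(ko_sets[[g]], keep)
    plan[[g]] <- list(M_variable = kind)
  }
  # HTV genomes also carry the variable module completely
  for (g in intersect(genome_ids, htv_ids)) {
    ko_sets[[g]] <- c(ko_sets[[g]], var_kos)
  }
  structure(ko_sets, plan = plan)
}
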