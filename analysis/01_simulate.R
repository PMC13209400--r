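#!/usr/bin/env Rscript
# Stage 1: generate the synthetic comparative study that stands in for the
# 16-genome dataset (2 hydrothermal-vent strains vs 14 others): a presence/
# absence pan-genome with a planted core, a U-shaped accessory spectrum,
# strain-unique families, 57 + 82 planted environment-specific clusters,
# COG letters, and KO content for six KEGG-style modules.
suppressPackageStartupMessages(library(panvent))

seed <- 20260921L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- simulate_pangenome(seed = seed)

write_presence_matrix(sim$matrix, file.path(out, "presence_matrix.tsv"))
write_metadata(sim$metadata, file.path(out, "metadata.tsv"))
write_annotation(sim$annotation, file.path(out, "annotation.tsv"))
write_modules(sim$modules, file.path(out, "modules.tsv"))
write.table(data.frame(cluster_id = names(sim$truth$fam_cogs),
                       cog = vapply(sim$truth$fam_cogs, paste, character(1),
                                    collapse = "")),
            file.path(out, "cluster_cogs.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(
  list(seed = seed,
       planted_htv = sim$truth$planted_htv,
       planted_nonhtv = sim$truth$planted_nonhtv,
       n_core = length(sim$truth$core_ids),
       htv_cog_letters = sim$truth$htv_cog_letters,
       nonhtv_cog_letters = sim$truth$nonhtv_cog_letters),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("simulated %d gene clusters x %d genomes (%d HTV / %d non-HTV)\n",
            nrow(sim$matrix), ncol(sim$matrix),
            sum(sim$metadata$environment == "HTV"),
            sum(sim$metadata$environment == "nonHTV")))
cat(sprintf("planted %d HTV-specific and %d non-HTV-specific clusters\n",
            length(sim$truth$planted_htv), length(sim$truth$planted_nonhtv)))
cat("inputs written under", out, "\n")
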