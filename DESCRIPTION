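Package: panvent
Title: Comparative Pan-Genomics of Environment-Associated Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative bacterial pan-genome analysis
    across environments, built around hydrothermal-vent versus non-vent
    contrasts in sulfur-cycling Campylobacterota such as Sulfurospirillum.
    Provides greedy centroid ortholog clustering of proteomes, core/accessory/
    unique pan-genome partitioning with permutation rarefaction and power-law
    openness fitting, fragment-based average nucleotide identity (ANI),
    reciprocal-best-hit average amino-acid identity (AAI) and percentage of
    conserved proteins (POCP), Fisher exact environment-association testing of
    gene clusters with Benjamini-Hochberg correction, a binomial enrichment
    index for COG functional categories, KEGG-module completeness scoring with
    UPGMA profile clustering, and a fully seeded synthetic-data generator that
    plants known pan-genome structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
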