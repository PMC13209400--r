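# panvent

Comparative pan-genomics of environment-associated bacterial genomes, built
for the hydrothermal-vent (HTV) versus non-vent contrast in sulfur-cycling
Campylobacterota such as *Sulfurospirillum*. The package implements, as one
tested pipeline, the analyses a comparative study of a 16-genome genus
dataset (2 vent strains vs 14 others) runs end to end:

- **Ortholog clustering.** Greedy centroid clustering of all proteins
  (longest first; join the first centroid with identity ≥ 50% and coverage
  ≥ 80% of the shorter sequence), producing gene clusters (GCs) and the
  presence/absence matrix.
- **Pan-genome structure.** Core (in all genomes) / accessory (≥ 2 but not
  all) / unique (exactly one) partition; permutation rarefaction curves; and
  the power-law fit *y = A·x^b* to the pan curve, with *b* < 1 diagnosing an
  open pan-genome.
- **Genome relatedness.** Fragment-based ANI (1020-bp fragments, both
  strands), reciprocal-best-hit AAI, and POCP
  (100·(C1+C2)/(T1+T2)), with the conventional thresholds: species at
  ANI ≥ 95%, genus evidence at AAI ≥ ~65% and POCP ≥ 50%.
- **Environment association.** A two-sided Fisher exact test per non-core
  cluster on its 2×2 presence table across HTV / non-HTV genomes, raw
  p < 0.05 with Benjamini–Hochberg q-values reported alongside.
- **Functional enrichment.** The binomial enrichment index
  EI = (x − n·p)/√(n·p·(1−p)) per COG category of an associated gene set
  against the pan-genome background; EI > 2 is called enriched.
- **Metabolic profiling.** KEGG-module completeness per genome (absent /
  partially complete, ≥ 3 KOs missing / almost complete, 1–2 missing /
  complete), a numeric score matrix, and UPGMA clustering of genomes by
  profile.
- **Synthetic data.** A fully seeded generator that emulates the study
  design — planted core size, U-shaped accessory frequency spectrum,
  57 + 82 planted environment-specific clusters, COG letters, module KO
  content, and sequences evolved at controlled divergence — so every stage
  is validated against known truth.

The local-alignment engine behind clustering/ANI/AAI/POCP is k-mer-guided
Smith–Waterman (via Biostrings) with Karlin–Altschul E-values; absolute
relatedness values therefore reproduce BLAST-based tools up to
search-engine differences, while all thresholds are explicit arguments.

## Worked example

```r
library(panvent)

sim <- simulate_pangenome(seed = 7)       # 16 genomes, 2 HTV vs 14 non-HTV
part <- partition(sim$matrix)
print(part)
#> Pan-genome partition: 2794 gene clusters
#>   core:      1066
#>   accessory: 826
#>   unique:    902

rc  <- rarefaction_curves(sim$matrix, n_permutations = 20, seed = 8)
fit <- fit_power_law(rc$x, rc$pan_median)
print(fit)
#> Power-law fit: y = 1497 * x^0.2169 (rss 2.201e+04) -> open pan-genome

assoc <- environment_association(sim$matrix, sim$metadata, alpha = 0.05)
association_counts(assoc)
#> $tested      [1] 1728
#> $significant [1] 139
#> $htv         [1] 57
#> $nonhtv      [1] 82
```

The partition conserves the cluster ledger (core + accessory + unique =
total); the pan curve's exponent *b* ≈ 0.22 < 1 says the simulated genus has
an open pan-genome (each added genome still brings new clusters); and the
association stage recovers exactly the 57 HTV-specific and 82
non-HTV-specific clusters the generator planted — with 2 vs 14 genomes the
most extreme table attains p = 1/120 ≈ 0.0083, so only strictly
group-specific patterns can be called.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (simulation → genome statistics → pan-genome → relatedness →
association/enrichment → module profiles), writing tables under `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

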