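---
title: "Methods: comparative pan-genomics with panvent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative pan-genomics with panvent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panvent)
```

panvent implements the comparative pan-genome analysis of a small bacterial
genus whose members split across two environments — hydrothermal vents (HTV)
and everything else — and asks which parts of the gene repertoire track that
split. This vignette explains the models and procedures, the parameters
that matter, what the synthetic data do and do not emulate, and the
numerical choices taken where the design was genuinely open.

## Ortholog clustering and the presence/absence matrix

All proteins from all genomes are clustered by the classic greedy
incremental scheme: visit proteins from longest to shortest (ties broken by
protein id, which makes the result independent of input order) and join the
first existing centroid whose Smith–Waterman local alignment reaches the
identity threshold (default 0.5, the common default of pan-genome
clustering tools) *and* covers at least 80% of the shorter sequence;
otherwise the protein founds a new cluster. The coverage floor exists
because greedy clustering on identity alone chains unrelated
domain-sharing proteins. Assignment is first-fit in centroid creation
order — not best-fit — which is the O(candidates) classic scheme and, with
the canonical visiting order, fully deterministic. Paralogs (several members
from one genome) may share a cluster; the presence matrix collapses them to
a boolean, since all downstream statistics are presence/absence.

A k-mer prescreen (default k = 5 for proteins, minimum 2 shared distinct
k-mers) limits which centroids are fully aligned. It is an ordering/limiting
heuristic and promises no superset of downstream filters; at the 10–25%
divergences where clustering is expected to be reliable, family members
share dozens of k-mers and the prescreen is effectively lossless (the test
suite measures recall of the best-scoring target against an all-vs-all
alignment oracle).

## Pan-genome partition, rarefaction, and openness

Core clusters occur in every genome, unique clusters in exactly one,
accessory clusters in between. Rarefaction draws random genome orderings
(default 20, the customary iteration count of pan-genome pipelines) and
records cumulative union (pan) and intersection (core) sizes, summarised by
the per-step median; when N! does not exceed the permutation budget the
orderings are enumerated instead, so small cases are exact. The pan curve
is fit by the power law $y = A x^b$: ordinary least squares on the log–log
scale provides starting values, then a Gauss–Newton pass (stats::nls)
minimises squared error on the original scale, because pure log–log OLS
biases $b$ under additive noise; on noise-free data the log–log solution is
already exact and is kept (nls aborts on zero-residual problems). The
refined fit is only accepted when it does not worsen the original-scale
residual sum of squares. $b < 1$ is reported as an open pan-genome.

## Relatedness indices

*ANI* follows the fragment-based (ANIb-style) convention: the query genome
is cut into consecutive 1020-bp fragments (the trailing short fragment is
dropped), each fragment is aligned against the subject on both strands, and
fragments with identity ≥ 0.3 and coverage ≥ 0.7 are retained; ANI is the
mean retained identity, symmetrised as the mean of both directions. To keep
fragment alignment O(fragment × window) rather than O(fragment × genome), a
shared-k-mer anchor (k = 12) locates the candidate homologous window (median
offset of matched k-mers, ±200 bp of padding) and the strand is chosen by
anchor count. A fragment with no anchor on either strand is dropped — at
the divergences where ANI is meaningful (< 25%) anchors are abundant, and
a genome pair with no retained fragments reports an undefined value with
`n_support = 0` rather than failing.

*AAI* takes reciprocal best hits under identity ≥ 0.3, coverage ≥ 0.7 of
the shorter sequence, and E ≤ 1e−3; the value is the mean RBH identity,
averaged over both directed measurements. *POCP* counts, in each direction,
query proteins with at least one hit passing E ≤ 1e−5, identity ≥ 0.4 and
query coverage ≥ 0.5, and reports $100 (C_1+C_2)/(T_1+T_2)$.

E-values use the Karlin–Altschul form $E = K m n e^{-\lambda S}$ with the
standard gapped parameters (protein $\lambda = 0.267$, $K = 0.041$;
nucleotide $\lambda = 1.28$, $K = 0.46$). They are acknowledged
approximations of BLAST's; every E-value threshold is an explicit argument,
so the filters rather than the exact E carry the semantics. Identity is
counted over all alignment columns including internal gaps (the stricter
BLAST-style convention); one convention had to be fixed and this is the
common one. Because the search engine differs from BLAST, published
absolute values from BLAST-based tools are reproduced with tolerance, not
expected digit-for-digit; the species/genus threshold calls (ANI 95%, AAI
~65%, POCP 50%) are preserved.

## Environment association

Each non-core cluster yields a 2×2 table of presence against the HTV /
non-HTV grouping, tested with the two-sided Fisher exact test
(stats::fisher.test, the same engine the original analysis used) and
BH-adjusted with stats::p.adjust. Core clusters are excluded before
testing: a cluster present everywhere has no contrast and would only
dilute the FDR.

Significance is called on the raw p-value (default α = 0.05), with
q-values reported alongside, for an arithmetic reason: with 2 vs 14
genomes the most extreme attainable two-sided p is
$1/\binom{16}{2} = 1/120 \approx 0.0083$, which cannot survive FDR
correction across thousands of tests — under a q-threshold nothing is ever
significant in this design, so group-specific clusters are only
recoverable on raw p. Enumeration of all attainable tables (asserted in the
tests) shows raw p < 0.05 admits exactly: presence in both HTV genomes and
at most one non-HTV genome (HTV-specific), or absence from both HTV
genomes with presence in at least 13 of 14 (non-HTV-specific). A boundary
subtlety: tables such as (2,0 | 2,12) attain p = 1/20 exactly, which is
*equal* to α and therefore not significant; the strict comparison on
fisher.test's output handles this correctly. The direction of a
significant association is the group with the higher presence fraction;
an (unbalanced-design) tie demotes the call to none.

## COG enrichment index

For a focal gene set (e.g. the HTV-associated clusters) the index per
category is $EI = (x - np)/\sqrt{np(1-p)}$ — standard deviations from the
binomial expectation — with EI > 2 (strictly) called enriched. Genes
without COG annotation are excluded from $n$; a gene carrying several
category letters counts once per letter, on both sides. The background
proportion $p$ is computed from the full pan-genome's annotated clusters by
default; the complement (background excluding the focal set) is the other
defensible choice and can simply be passed as the background argument —
for focal sets that are a small fraction of the pan-genome the two differ
negligibly. Monte-Carlo calibration under the null (focal sets drawn
uniformly from the background) is part of the test suite and keeps the
EI > 2 exceedance below 5%, consistent with the one-sided normal tail
(~2.3%) plus discreteness in rare categories.

## KEGG-module completeness

Module definitions are flattened to an ordered list of steps, each a set of
alternative KOs; a step is satisfied when any of its KOs is annotated. This
representation supports the missing-KO completeness criterion exactly;
parsing the full KEGG boolean grammar (complexes, optional components) is
out of scope. Categories: complete (0 steps missing), almost complete (1–2
missing), partially complete (≥ 3 missing but at least one module KO
present), absent (no module KO annotated). The numeric scale maps these to
0/1/2/3 by default; the four categories do not pin a unique mapping, and
any strictly monotone mapping preserves every ordinal conclusion (the test
suite checks two). Genome profiles are compared by Euclidean distance on
score columns and clustered by UPGMA; neither choice is forced by the
procedure being reproduced (the original used an interactive tool), so
both are plain arguments. UPGMA merge heights are half the between-cluster
average distance, so two leaves at distance $d$ merge at height $d/2$ and
cophenetic distances reproduce ultrametric inputs exactly; labels are
sorted before clustering for deterministic tie-breaking.

## The synthetic study design

The generator emulates the structure of the real 16-genome dataset rather
than its sequences: 2 HTV vs 14 non-HTV genomes; ~800 core families;
1200 accessory families whose per-genome occurrence probabilities are drawn
from Beta(0.3, 0.3) — the U-shaped spectrum that makes empirical
pan-genomes open (sampled families with probability near 1 land in the
core compartment, so the realised core exceeds the planted 800; the
partition operates on the realised matrix); Poisson(40) unique families
per genome; and planted association patterns mirroring the published
counts, 57 HTV-specific and 82 non-HTV-specific. Planted HTV families draw
their COG letters with a 3× boost on amino-acid (E) and coenzyme (H)
metabolism, non-HTV families on unknown function (S), mirroring the kind of
functional signal the enrichment stage is meant to expose. Module content
plants three vent-only modules (heme/glycine-cleavage/lipoate analogues)
complete in the HTV genomes and absent elsewhere, two housekeeping modules
complete everywhere, and one variable module spanning all four
completeness categories.

Two generator properties make the planted truth an *exact* oracle. First,
every generator is a pure function of its parameters and seed. Second, a
separability guarantee: accessory families whose randomly sampled
occurrence vector would itself reach Fisher significance at the planting α
are resampled (bounded retries, then neutralised to a provably
non-significant pattern), so the significant set equals the planted set
exactly — without this, roughly 0.5–1% of accessory families would land in
the significance region by chance and "exact recovery" would be
ill-defined. Unique families cannot reach significance in the 2-vs-14
design (their most extreme p is 0.125), and need no such guard.

Sequence evolution is site-wise substitution at rate $d$ to a uniformly
chosen different symbol, with optional indels (default 0), so the expected
identity of an evolved copy to its ancestor is exactly $1 - d$ — the
analytical oracle behind the ANI and AAI checks (ANI at 5% divergence must
land at 95.0 ± 0.5). What the generator does *not* emulate: phylogenetic
correlation among genomes (gene gain/loss on a tree), codon structure,
compositional heterogeneity, paralog families, and annotation noise.
Passing tests therefore demonstrate correctness of the statistical
machinery under known truth, not robustness to the correlated errors of
real annotation pipelines.

## Problem sizes and runtime choices

The default study fixture is the full 16-genome design (~2800 clusters),
used as-is by the tests and the acceptance script. Sequence-level checks
use sizes chosen to keep the whole suite in a few minutes on one CPU while
leaving the conclusions scale-independent: clustering recovery on 6 genomes
× 30–50 families (the combinatorics of greedy clustering do not change
with family count), ANI on one 100-kb pair per divergence (196 fragment
alignments; the estimator's variance at that size is already well inside
the ±0.5 tolerance), AAI/POCP on 10–25-protein proteomes, and brute-force
alignment oracles on strings of length ≤ 6 (the enumeration is exponential;
lengths beyond that add cost but no new structure).

## Known limitations

- The greedy first-fit clustering reproduces the *scheme* of standard
  pan-genome tools, not any specific binary's internals; cluster counts on
  real data are expected to land near, not on, those of USEARCH-based
  pipelines.
- E-values are Karlin–Altschul approximations with fixed parameters, not
  matrix- and composition-adjusted BLAST values.
- The association test treats genomes as independent; phylogenetically
  corrected pan-GWAS is explicitly out of scope.
- ANI's k-mer anchoring assumes collinear homologous segments within a
  fragment's window; heavy rearrangement at fragment scale would drop
  fragments rather than mis-align them.
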