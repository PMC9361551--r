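---
title: "Methods: comparative ecogenomics across the salinity divide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative ecogenomics across the salinity divide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picopan)
```

## What this package computes

`picopan` implements the comparative-genomics procedure used to separate
marine, brackish, and freshwater picocyanobacteria (cluster-5
*Synechococcus*/*Cyanobium* and relatives) into habitat- and lineage-level
groups:

1. **Genome descriptors and group tests** — genome size, %GC, CDS count,
   median intergenic spacer and coding density per genome; means and sample
   SDs per habitat and sub-cluster; pairwise one-way ANOVA between groups.
2. **ANI / AAI and species delineation** — fragment-based average
   nucleotide identity, bidirectional-best-hit average amino acid identity,
   and single-linkage threshold clustering into species (ANI > 95%) and
   clades (ANI ≥ 90%).
3. **Pangenome structure** — reciprocal-homology gene families, a binary
   presence/absence matrix, the strict core / soft core / shell / cloud
   partition, core/pangenome rarefaction curves, and per-habitat occupancy
   profiles with a habitat-specificity flag.
4. **Proteome pI spectra** — per-protein isoelectric points by
   charge-balance bisection, reduced to 28 relative-frequency bins of 0.5 pH
   units on [0, 14].
5. **Resemblance and ordination** — Bray-Curtis dissimilarity on
   square-root-transformed spectra, Kulczynski similarity on
   presence/absence, principal coordinates analysis, and group-average
   (UPGMA) clustering sliced at 75–95% similarity.

Because the real strain collections behind such studies are large genome
archives, the package ships a **synthetic collection generator** with
complete ground truth (family memberships, expected ANI, habitat labels),
so every stage is tested end to end without downloading anything.

## The synthetic generator

A collection is described by `group_spec()` entries (habitat, sub-cluster,
number of genomes, genome size mean ± SD in kb, GC target, proteome acidity
shift δ, within-group divergence) and one `pool_spec()` (counts of strict
core, soft core, shell, cloud and habitat-specific families; mean gene
length; mean spacer length).

**Evolution model.** One ancestral nucleotide sequence is drawn per family
(length ~ Normal(mean, 10%), rounded to a codon multiple, stop codons
removed by a deterministic last-base remap). Each group evolves a *group
ancestor* from the pool (per-site substitution probability
`divergence_from_pool`, default 0.15), and each genome evolves from its
group ancestor at the group's `divergence`. Substitution targets are drawn
with G/C probability equal to the group's GC target and may equal the
original base, so the expected identity of a descendant against its
ancestor is the closed form `(1 - p) + p * sum(f_b q_b)` (`expected_identity()`).
There are **no indels**: this keeps expected ANI in closed form and makes
per-site oracles exact. The two-level star topology reproduces the
structure of real collections — within-group pairs above the species
threshold, between-group pairs far below the clade threshold — and the
ground truth records the exact expected identity for every pair via the
4×4 substitution kernels.

**Occupancy plan.** Strict-core families go to all `n` genomes; soft-core
families to the smallest `k` with `k/n ≥ 0.95` and `k < n` (so a soft core
requires at least 20 genomes — requesting one with fewer raises an error
that states the arithmetic); cloud families to 1–2 genomes; shell families
to an intermediate count below the soft-core cut; habitat-specific families
to every genome of their habitat and none elsewhere. Accessory families
with occupancy ≥ 2 are seeded into two habitats before random filling, so
no non-specific family can masquerade as habitat-specific: the specificity
ground truth is unambiguous by construction (with single-genome habitats a
cloud family could still trip the ≥ 50% flag, so configurations should give
each habitat at least three genomes).

**GC control.** Gene ancestors are shared across groups (core families must
stay homologous collection-wide), so coding GC cannot carry the full
between-habitat GC contrast. Each genome is assembled as alternating
ancestral spacers and genes in canonical family order, padded to its drawn
target size with non-coding filler; the group's spacer/filler ancestors are
generated at a *compensated* GC chosen so realized whole-genome GC lands on
the group's target (clipped to [0.02, 0.98]). With a uniform GC target the
realized GC is within ±1% of target on a 100-kb genome.

**Proteomes.** Each gene is translated with the standard code;
substitution-created internal stop codons are recorded as `X` (the
ambiguity codes `X/B/Z` are non-ionizable in the charge model, so they do
not perturb pI). The habitat contrast in proteome acidity is imposed
post-translation: with shift δ > 0 each K/R is replaced by D or E with
probability δ (the reverse for δ < 0). Acting at the protein level avoids
codon bookkeeping and gives direct, monotone control of the pI spectrum.

**Determinism.** A single mandatory seed expands into per-genome, per-group
and per-stage substreams by a stable string hash, so outputs are
byte-identical across runs and independent of iteration order.

**Default study conditions.** `default_config()` encodes a reduced-scale
analogue of a 132-genome field collection: 12 marine (SC 5.1, 60 ± 5.5 kb,
58.5% GC, δ = +0.10), 4 brackish (SC 5.2, 64.5 ± 8.9 kb, 64% GC,
δ = +0.03), 13 freshwater (SC 5.2, 70 ± 9.8 kb, 64% GC, δ = −0.10) and 4
freshwater (SC 5.3, 62 ± 6 kb, 53% GC, δ = −0.10) genomes over a pool of
28 strict-core, 6 soft-core, 24 shell, 12 cloud and 4 habitat-specific
families per habitat. Sizes and GC keep the field ratios
(marine < brackish < freshwater sizes; low-GC SC 5.3 freshwater strains);
the ~60 kb scale and ~80-family pool keep a full run on one CPU in seconds
while every occupancy class stays populated. The acidity shifts ±0.10 are
calibration choices for the qualitative marine-acidic/freshwater-basic
contrast, not field-measured values; the within-group divergences
(0.015–0.03) put within-group ANI in the species range (> 95%) and the deep
divergence 0.15 puts between-group ANI near 77%.

## Fragment ANI

The query genome is cut into consecutive, non-overlapping 1020-bp
fragments per contig (terminal remainders discarded). Each fragment is
placed on the reference by shared 15-mer seeding on both strands: every
shared k-mer votes for a diagonal offset, the best-supported offset wins
(ties to the smaller offset; k-mers occurring more than 10 times in the
reference are masked as repeats). A gap-free comparison at that offset
scores percent identity; fragments reaching ≥ 30% identity over ≥ 70% of
their length are retained, the directed ANI is the mean retained identity,
and the reported ANI is the mean of the two directions (exactly symmetric
by construction). Pairs with no retained fragment are *missing*, not 0. A
gap-free extension is exact for the generator's indel-free sequences; the
fragment length and both retention thresholds are arguments.

Species and clades are connected components of the thresholded ANI graph —
single linkage, the weakest assumption, since the underlying convention
names a threshold but no linkage. The species edge is strict (`> 95`), the
clade edge inclusive (`>= 90`), following the usual statements of the two
criteria; both thresholds are arguments.

## Protein homology, AAI and gene families

All-vs-all protein comparison uses a shared-4-mer prefilter (candidates
must share ≥ 2 distinct 4-mers) followed by ends-free pairwise alignment
with BLOSUM62 and BLASTP-style gap costs (open 12, extend 1). Identity is
matches over alignment columns excluding terminal gaps; each direction's
coverage is its aligned residues over its sequence length. Hits must reach
30% identity, the coverage rule (> 50% for family clustering, ≥ 50% for
AAI best hits) and a minimum raw score of 60. The score floor plays the
role of a database search's E-value cut-off: ends-free alignment of
unrelated short proteins occasionally reaches 30% identity through gappy
stitching, with raw scores an order of magnitude below those of genuine
homologs, and a search tool would never report such hits.

AAI is the mean identity over bidirectional best-hit pairs (undefined when
there are none). Gene families are connected components of the
reciprocal-hit graph — reciprocal means the coverage rule holds in both
directions — so the partition is independent of input order; every protein
belongs to exactly one family and singletons stand alone.

## Pangenome partition

With `n` genomes and occupancy = number of genomes carrying a family
(paralogs collapse), categories are evaluated in order: occupancy `= n` →
strict core; `>= 0.95 n` → soft core; `<= 2` → cloud; otherwise shell. The
categories are mutually exclusive (category percentages add to 100), and
the precedence strict > soft > cloud > shell settles small-`n` conflicts:
occupancy 2 of 3 is cloud. Occupancies between 90% and 95% fall to the
shell by the remainder rule, since the source conventions leave that band
unassigned. The 95% soft-core cut is applied to the exact fraction
(no rounding of genome counts).

Rarefaction draws `R` random genome orderings (seeded) and tracks the
running intersection (core) and union (pangenome) of family sets;
means ± SD per genome count are reported.

## Isoelectric points

The charge model is composition-only Henderson-Hasselbalch: one N-terminal
and one C-terminal group per chain plus the side chains of K, R, H (basic)
and D, E, C, Y (acidic), with the EMBOSS constants (N-term 8.6, C-term
3.6, K 10.8, R 12.5, H 6.5, D 3.9, E 4.1, C 8.5, Y 10.1) as a swappable
`pka_table()`. Net charge is strictly decreasing in pH, so the pI is the
unique root on [0, 14], found by bisection to an interval < 1e-4 and
clamped to the boundary if the charge never changes sign. Each proteome is
reduced to 28 half-open bins of width 0.5 ([x, x+0.5), last bin closed at
14), one equally weighted count per protein — per-protein weighting matches
how per-protein pI lists are summarized in practice; the binning uses the
unrounded pI.

## Resemblance and ordination

Bray-Curtis (`100 * Σ|x−y| / Σ(x+y)`) is computed on square-root
transformed relative frequencies for the pI path — transform first, then
resemblance. Kulczynski similarity on binary rows is
`100 * (a/(a+b) + a/(a+c)) / 2`; its PCO uses the fixed conversion
`d = 100 − s`. PCO is the eigendecomposition of the Gower-centered
`−d²/2`: coordinates come from positive eigenvalues only, percent
variation is relative to the positive sum, and the magnitude of negative
eigenvalues is reported untouched (no Lingoes/Cailliez correction — users
can judge the distortion). Axis signs are canonicalized (first nonzero
loading positive) so runs and platforms agree. Clustering is group-average
(UPGMA) — the default of the ordination software this workflow mirrors —
with labels sorted before merging so ties break lexicographically; merge
heights are kept on the similarity scale and trees are sliced at the
conventional 75/80/85/90/95% overlays, which always yields nested
partitions.

## One-way ANOVA

Group tests are classical one-way ANOVAs; "pairwise" tests run each
unordered pair of habitats or sub-clusters as a two-group ANOVA with no
multiple-testing correction (all p-values are reported; correction is the
caller's choice). The F tail probability is computed in-package through
the regularized incomplete beta function (Lentz continued fraction), not
delegated, and is validated against numeric quadrature of the F density to
1e-6; two-group F equals the squared pooled-variance t statistic
identically. Zero within-group variance with unequal means is a
"degenerate F" error; all-identical data gives F = 0, p = 1.

## Numerical and design notes

- Alphabets are strict: nucleotide `ACGTN`, protein 20 letters + `XBZ`;
  anything else fails fast at the read boundary rather than being coerced.
- Coordinates are 1-based inclusive (GFF3 convention) everywhere.
- Intergenic gaps are strand-agnostic, clamped at 0 for overlapping CDS,
  pooled across contigs, and contig edges contribute nothing (draft
  assemblies make edge gaps meaningless); an even-sized gap pool takes the
  mean of the central pair rounded half up, so the statistic is integer bp.
- Coding density uses merged CDS spans, so `density × size` is exactly the
  merged coding length.
- Square matrices are written at 6 decimals and must be symmetric within
  1e-9 with the fixed diagonal of their kind (100 similarity / 0
  dissimilarity).
- FASTA is written wrapped at 70 columns; any wrapping is accepted on read.

## What the synthetic tests do and do not show

The generator reproduces the *structure* the method assumes — occupancy
classes, a two-level divergence hierarchy with known expected ANI, a
monotone pI shift, habitat-specific accessory genes — under a star
topology with no indels, no rearrangements, no HGT, no codon-usage
realism. Passing tests therefore demonstrate that the implementation
recovers known parameters under the stated model (ANI within ±0.5 points
for p ≤ 0.10, exact family partitions when between-family identity is far
below 30%, exact specificity flags), not that the biological conclusions
of any particular field collection would be reproduced; those depend on
real sequence data. Problem sizes in the tests and acceptance script
(~60-kb genomes, ~80 families, 100-kb ANI ladders, 3 replicate seeds) were
chosen to exercise every code path at desk scale.
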