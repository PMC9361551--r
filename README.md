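# picopan

Comparative ecogenomics of habitat-structured picocyanobacterial genome
collections: what, at the genome level, separates a marine strain from a
freshwater one?

Cluster-5 picocyanobacteria (*Synechococcus*, *Cyanobium* and relatives)
have colonized marine, brackish, and freshwater habitats. Collections that
span this salinity divide are compared along five axes, all implemented
here as a tested R pipeline:

- **Genome descriptors + group tests** — size, %GC, CDS count, median
  intergenic spacer, coding density; per-habitat/per-sub-cluster means ± SD
  and pairwise one-way ANOVA (F = MS\_between/MS\_within, p from the
  regularized incomplete beta, implemented in-package).
- **ANI / AAI and species delineation** — fragment-based average nucleotide
  identity (1020-bp fragments, shared 15-mer seeding on both strands,
  retention at ≥30% identity over ≥70% of the fragment), bidirectional
  best-hit average amino acid identity, and single-linkage clustering into
  species (ANI > 95%) and clades (ANI ≥ 90%).
- **Pangenome structure** — reciprocal-homology gene families (≥30%
  identity, >50% coverage), presence/absence matrix, and the partition into
  strict core (all genomes), soft core (≥95%), shell (remainder), cloud
  (≤2 genomes), with rarefaction curves and habitat occupancy profiles.
- **Proteome pI spectra** — per-protein isoelectric points solved by
  bisection of the Henderson–Hasselbalch net charge
  `Z(pH) = Σ_basic 1/(1+10^(pH−pKa)) − Σ_acidic 1/(1+10^(pKa−pH))`,
  binned into 28 relative frequencies (0.5 pH units over 0–14).
- **Resemblance + ordination** — Bray-Curtis on square-root-transformed
  spectra, Kulczynski similarity on presence/absence, principal coordinates
  (Gower-centered −d²/2), UPGMA with 75–95% similarity slices.

A deterministic synthetic-collection generator with full ground truth
(family memberships, expected pairwise ANI from the substitution kernel,
habitat-specific gene labels, a controlled proteome acidity shift) makes
every stage testable end to end; see `vignettes/methods.Rmd` for the model
and its limits.

## Worked example

```r
library(picopan)

col <- synthesize_collection(default_config(seed = 42))

# pangenome partition over the collection's gene-family incidence
partition_pangenome(pa_from_truth(col$truth))
#> <pangenome_partition> 82 families over 33 genomes:
#>   strict_core    28 (34.1%)
#>   soft_core       6 (7.3%)
#>   shell          36 (43.9%)
#>   cloud          12 (14.6%)

# fragment ANI of a within-group pair vs the generator's expectation
pairwise_ani(col$assemblies$marine51_01, col$assemblies$marine51_02)$ani
#> [1] 97.89985
col$truth$expected_ani["marine51_01", "marine51_02"]
#> [1] 97.79132

# the marine-acidic vs freshwater-basic proteome contrast on PCO axis 1
spectra <- pi_spectrum_table(col$proteomes)
r <- pco(bray_curtis(sqrt_transform(spectra)))
round(r$percent_variation[1], 1)
#> [1] 78.4
```

The partition says the 33-genome collection carries 82 gene families of
which 28 are shared by every genome; the ANI pair sits in the species range
(>95%) and agrees with the closed-form expectation to ~0.1 points; and the
first principal coordinate of the pI spectra (78% of the positive
eigenvalue mass) is the habitat axis.

The numbered scripts under `analysis/` run the full workflow
(`01_simulate.R` … `06_ordination_presence_absence.R`), printing what each
stage finds and writing tables under `results/`.

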