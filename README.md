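# markermine

Marker discovery and genetic diversity analysis for allotetraploid
crops.

Orphan cereals like finger millet (*Eleusine coracana*, AABB,
2n = 4x = 36) lack the marker resources that drive modern breeding.
Building them from sequencing data poses two recurring problems that
this package addresses for bioinformaticians and breeders working on
polyploid crops:

1. **Marker mining.** Finding perfect di-/tri-/tetra-nucleotide SSRs in
   assembled contigs, and filtering candidate SNPs — in an
   allotetraploid, divergence between the AA and BB sub-genomes shows
   up as heterozygous-looking calls within a single inbred individual
   ("homeologous SNPs") and must be subtracted before any site is
   called a marker.
2. **Marker evaluation and use.** Scoring validated markers across a
   germplasm panel (major allele frequency, gene diversity, observed
   heterozygosity, Botstein PIC, per-group polymorphism), and inferring
   panel structure (IBS distance, UPGMA dendrograms, STRUCTURE-style
   admixture with Evanno ΔK model choice).

The statistics at the core:

- **PIC** (polymorphism information content, Botstein):
  `PIC = 1 − Σᵢ pᵢ² − Σᵢ<ⱼ 2 pᵢ² pⱼ²` for locus allele frequencies
  `pᵢ`; gene diversity `Hₑ = 1 − Σᵢ pᵢ²`; always `PIC ≤ Hₑ`.
- **Admixture model**: each allele copy of individual *i* descends
  from ancestral population *k* with probability `q_ik` and is drawn
  from that population's allele frequencies; a Gibbs sampler returns
  posterior-mean `Q`, `P` and the data log-likelihood trace.
  Model choice uses `LnP(D)` (trace mean minus half its variance) and
  `ΔK = |L″(K)| / sd(L(K))` across replicate runs.
- **Homeolog filter**: quality ≥ 30, ≤ 2 alleles, depth ≥ 3, then
  removal of every position present in any genotype's self-mapped
  variant set.

A synthetic-data module generates all inputs (contigs with planted
SSRs, self/combined variant sets, admixed genotype matrices) with known
ground truth, so every stage is testable against planted truth and
independent oracles.

## Worked example

```r
library(markermine)

## marker informativeness: 4 A/A, 2 A/G and 4 G/G calls at one locus
p <- allele_frequencies(c(rep("A:A", 4), rep("A:G", 2), rep("G:G", 4)))
#>   A   G
#> 0.5 0.5
gene_diversity(p)        # 0.5
round_half_up(pic(p))    # 0.38  -- a balanced bi-allelic SNP caps at 0.375

## homeolog-aware SNP filtering on synthetic allotetraploid data
sim  <- simulate_allotetraploid_variants(100000, n_genotypes = 2, seed = 1)
hom  <- homeolog_positions(sim$self_sets)
kept <- subtract_homeologs(filter_sites(sim$combined), hom)
nrow(sim$combined); length(hom); nrow(kept)
#> 182 candidates; 154 homeologous positions; 28 allelic SNPs retained
summarize_variants(kept, 100000)$tstv       # 1.8
summarize_variants(kept, 100000)$frequency  # "1 per 3.6 kb"

## diversity across an admixed two-population panel
g    <- simulate_genotype_matrix(K = 2, n_per_pop = 15, n_loci = 60, seed = 1)
qc   <- qc_filter(g$matrix)      # drops 80%-missing samples, 90%-missing
summ <- locus_summary(qc$matrix) # and monomorphic loci
head(summ, 3)
#>   locus   maf k gene_diversity ho   pic pic_pop1 pic_pop2
#> 1    L1 0.679 2          0.436  0 0.341    0.117    0.361
#> 2    L2 0.600 2          0.480  0 0.365    0.374    0.346
#> 3    L3 0.538 2          0.497  0 0.374    0.335    0.292
round_half_up(mean(summ$pic))            # 0.30 across the 54 retained loci
polymorphic_count(summ, "pop1")          # 46 of 54 loci segregate in pop1

## population structure
run <- gibbs_admixture(qc$matrix, K = 2, burnin = 200, reps = 1000, seed = 1)
round(head(run$Q, 3), 3)
#>     [,1]  [,2]
#> S1 0.791 0.209   # posterior-mean ancestry proportions per sample
#> S2 0.901 0.099
#> S3 0.928 0.072
tree <- upgma(ibs_distance(qc$matrix))   # ultrametric rooted dendrogram
```

Observed heterozygosity is ~0 throughout because the generator's
default selfing rate (0.95) emulates a highly inbred crop; the Ts/Tv of
1.8 reflects the generator's transition-biased substitution classes.

`run_pipeline()` chains all stages (simulate → mine-ssr → filter-snps →
diversity → structure) and writes every intermediate plus a run log;
`inst/cli/markermine.R` exposes the same stages as shell subcommands:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","markermine.R",package="markermine"))')" \
    run-all --out-dir out --seed 1
```

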