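---
title: "Methods: SSR/SNP marker discovery and diversity analysis in an allotetraploid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSR/SNP marker discovery and diversity analysis in an allotetraploid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markermine)
```

# Scope and model of the data

`markermine` implements the downstream, sequence-level half of a
marker-discovery study in a highly inbred allotetraploid crop such as
finger millet (*Eleusine coracana*, AABB, 2n = 4x = 36): given assembled
contigs and variant call sets, it mines microsatellite (SSR) markers,
separates true allelic SNPs from homeologous artifacts, scores marker
informativeness across a germplasm panel, and infers population
structure.  Read trimming, assembly and variant calling are upstream of
the package; its inputs are FASTA contigs, VCF variant sets and
KASPar-style genotype call matrices.

Because raw sequencing data are not part of the package, a first-class
synthetic-data module generates every input with known ground truth.
Its defaults are the study conditions the analysis assumes, and the test
suite treats them as fixed.

# SSR mining

An SSR locus is a perfect tandem repeat of a 2--4 bp motif.  The miner
reports maximal runs with at least `min_repeats = 5` complete copies
spanning at least `min_length = 10` bp.  Conventions the mining
literature leaves open are pinned down as follows:

* **Maximality and phase.**  A reported run cannot be extended by one
  unit on either side; of the up-to-`u` phases of a periodic stretch,
  the leftmost is reported, and a trailing partial unit does not count
  toward the repeat number.
* **Reducible motifs.**  A motif that is itself a repetition of a
  shorter unit ("ATAT", "AAA") is never reported at the longer unit
  size.  In particular mononucleotide runs, whose would-be
  di-nucleotide motif is reducible, are excluded entirely --
  homopolymers are the dominant sequencing-error mode and
  mononucleotide SSRs are poorly informative.
* **Overlap.**  Where qualifying runs of different unit sizes overlap,
  the smallest unit wins; this makes the output a deterministic
  function of the sequence.
* **Classes.**  Motifs are grouped into strand-pair classes (the
  rotation minimum of the motif and of its reverse complement), so
  "GA", "AG", "CT" and "TC" all fall in the class rendered `AG/CT`.
  The rotation-minimal spelling is canonical and totally ordered; a
  class that other reports might spell `CAA/TTG` renders here as
  `AAC/GTT` -- the membership is identical, only the label differs.
* **Coordinates** are 0-based half-open internally and in the locus
  tables; the pipeline's human-readable report adds a 1-based start
  column.  Marker densities are rendered `1 per X kb` with one decimal
  (switching to Mb above 1000 kb); printed sources round this quantity
  with mixed precision, and any differences are cosmetic.

The miner is validated against an exhaustive-enumeration oracle that
tests every (start, unit, count) triple by direct substring comparison,
on random sequences up to 20 kb.

# Homeologous SNP filtering

In an allotetraploid, divergence between the AA and BB sub-genomes
masquerades as heterozygous variant calls within a single individual.
The operational definition adopted here: map each genotype's reads back
to its own assembly; variant positions in that "self" set are
homeologous, not allelic.  The filter

1. keeps candidate sites with quality >= 30, at most 2 total alleles
   and depth >= 3 (thresholds inclusive; an unknown quality or depth
   fails its filter),
2. forms the union of all genotypes' self-set positions, and
3. removes those positions from the candidate set everywhere --
   homeology is a property of the position, not of the allele pair, and
   a position flagged in one genotype is distrusted in all.

Substitutions are classified as transitions (A<->G, C<->T) or
transversions, and the spectrum over the four strand-collapsed classes
`CT/AG`, `AC/GT`, `AT`, `CG` is reported alongside the Ts/Tv ratio and
per-bp density.

# Diversity statistics

For allele frequencies $p_i$ at a locus (counted two alleles per
non-missing diploid call):

* gene diversity (expected heterozygosity) $H_e = 1 - \sum_i p_i^2$;
* Botstein's polymorphism information content
  $PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$;
* observed heterozygosity $H_o$ = fraction of non-missing calls whose
  two alleles differ.

$PIC \le H_e$ always, with equality only for a monomorphic locus (both
zero).  For a bi-allelic locus PIC peaks at 0.375 when $p = 0.5$.
Reported tables round to two decimals, half away from zero, so a
0.50/0.50 locus prints PIC 0.38.

Panel QC mirrors standard marker-validation practice and its narrative
order: samples with more than 80% missing calls are dropped first, then
loci with more than 90% missing calls or monomorphic across the
retained samples (both thresholds strict).  Group-wise PIC (e.g. wild
vs cultivated accessions) uses group-restricted allele frequencies and
is reported as `NA` where a locus is monomorphic within the group; the
count of defined group PICs is the number of markers polymorphic in
that group.  Frequencies are plain counts; no EM imputation of missing
calls is attempted, matching the summary software conventions of
marker-validation reports.

# Population structure

**IBS distance.**  For two samples, each shared locus contributes
(number of shared alleles between the two unordered call pairs)/2; the
distance is one minus the mean over shared non-missing loci.

**UPGMA.**  Standard average-linkage agglomeration; the two clusters at
the smallest average distance merge at a node of height half that
distance, giving an ultrametric rooted tree.  Ties are broken toward
the lexicographically smallest pair of cluster labels, so the tree is a
deterministic function of the matrix.  Because UPGMA trees are already
rooted, the outgroup option only rotates the named taxon to the top for
display -- it does not re-root.

**Admixture model.**  Each of the two allele copies an individual
carries at a locus originates in one of $K$ ancestral populations,
drawn with the individual's admixture proportions $q_i$; conditional on
the origin $k$, the allele is drawn from that population's frequencies
$p_{k\ell}$.  A Gibbs sampler alternates: origins given $(Q, P)$;
$P$ rows from their Dirichlet posterior under a uniform prior; $Q$ rows
from Dirichlet($\alpha$ + origin counts).  Missing calls contribute no
counts and are skipped in the likelihood.  Two deliberate design
choices:

* **Independent allele frequencies.**  The correlated-frequencies
  variant of the admixture model needs hyperparameters that are rarely
  reported; the independent-frequency model keeps the analysis
  structure (Q, P, LnP(D), delta-K) intact and its parameter recovery
  is directly testable on synthetic truth.  Results on strongly
  differentiated panels are expected to be very similar; weakly
  differentiated subpopulations may need more markers to resolve than
  under the correlated model.
* **alpha fixed** (default 1.0, settable).  A Metropolis update for
  alpha adds tuning burden without changing the recovery behaviour on
  the panels this package targets.

**Model choice.**  Each run's evidence is summarized as
LnP(D) = mean of the post-burn-in log-likelihood trace minus half its
variance.  Over replicate runs at consecutive $K$, the Evanno statistic
is $\Delta K = |L''(K)| / \mathrm{sd}(L(K))$, with $L''$ the second
difference of the mean LnP(D); its argmax over interior $K$ suggests
the number of subpopulations.  $\Delta K$ is undefined at zero
across-run spread and at the boundary $K$ values.

**Replicate alignment.**  Cluster labels are arbitrary, so replicate
runs are aligned to the first run by the column permutation minimizing
squared Q differences -- exhaustively for $K \le 8$, greedily beyond --
and then averaged.

**Chain lengths.**  Defaults are desk-scale: burn-in 1,000 and 5,000
retained sweeps, which recover Q on strongly differentiated synthetic
panels to well within 0.1 mean absolute error.  Classic practice for
real panels (burn-in 10,000, 100,000 sweeps, $K = 1..10$, 10 runs per
$K$) is available by argument.  The package's own test fixture for
recovery uses 50 samples by 100 loci.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with exact ground truth:

* **Contigs and SSRs.**  I.i.d. background bases at a user-set
  composition (default uniform).  Planted SSR templates are written
  verbatim at their coordinates; background windows that by chance form
  a qualifying run, or that extend a planted one, are rejected and
  resampled, so planted truth is exactly the set of minable loci and
  recall/precision assertions are exact rather than probabilistic.
  The default planted class mix is 80% di-, 18.3% tri- and 1.2%
  tetra-nucleotide, the class abundances reported for grass genome
  surveys (printed percentages are renormalized to sum to one).
* **Variant sets.**  Homeologous sites are drawn at 1/657 bp, the
  denser of the two sub-genome divergence rates reported for finger
  millet, and appear as heterozygous-like calls in the self-mapped set
  of a random non-empty subset of genotypes.  Allelic SNPs are drawn at
  1/3300 bp (the genome-wide non-homeologous SNP density, 1 per
  3.3 kb) and segregate as alternative homozygotes between genotypes.
  Each bp carries at most one truth.  Homeolog substitution classes
  default to CT/AG 62% and CG 7.5% as reported for the crop's
  homeologous spectrum; the split of the remaining 30.5% between the
  two transversion classes is not reported anywhere and is set evenly
  (15.25% each) -- a choice that affects only the spectrum's middle
  classes, not any filtering behaviour.  Emitted sites pass the
  quality/depth thresholds unless a stated fraction is deliberately
  degraded for filter tests.
* **Genotype matrices.**  Population allele frequencies follow a
  Balding--Nichols divergence model (`divergence` plays the role of
  $F_{ST}$; 1 forces fixed opposite alleles).  Admixture rows are
  Dirichlet draws centred on the sample's home population.  Selfing
  copies the first allele with probability `selfing`; the default 0.95
  reflects a highly inbred crop, and 1 forces complete homozygosity.
  The default missing rate 0.07 mirrors the ~93% allele call rate
  typical of KASPar validation panels.

What the generator does *not* emulate: read-level error, coverage
heterogeneity, linkage between loci, null alleles, and genotyping batch
effects.  Passing tests therefore demonstrate correctness of the
algorithms under the model's assumptions, not robustness of the
upstream calling pipeline to real-data artifacts.

# Numerical conventions and degenerate inputs

* Thresholds are inclusive everywhere a cutoff is stated (>= 30, >= 3,
  <= 2 alleles); QC missingness thresholds are strict (> 80%, > 90%)
  as their narrative states.
* Zero markers make a density undefined (`NA`), never a division
  error; an all-missing locus is an error naming the locus; a sample
  pair sharing no non-missing locus is an error naming the pair.
* Spectra must sum to 1 within 1e-9; Q rows sum to 1 after every
  update; UPGMA output is ultrametric within 1e-9.
* All generators and samplers are seed-deterministic; the pipeline
  writes a run log from which any bundle can be reproduced exactly.

# Known limitations

Perfect repeats only (no compound or interrupted SSRs); site-level
depth filtering (per-sample depths ignored); independent-frequency
admixture model only; no Hardy--Weinberg tests, F-statistics or
linkage analysis; no tree bootstrap support.  These match the scope of
the reports the package is designed to reproduce.
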