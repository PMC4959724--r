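Package: markermine
Title: SSR and Homeolog-Aware SNP Marker Discovery with Diversity and
    Population Structure Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Marker discovery and genetic diversity analysis for
    allotetraploid crops such as finger millet (Eleusine coracana).
    Mines perfect di-, tri- and tetra-nucleotide simple sequence
    repeats (SSRs) from assembled contigs, filters candidate SNPs with
    quality/allele-number/depth thresholds and removes homeologous
    sites identified from per-genotype self-mapped variant sets,
    computes per-locus diversity statistics (major allele frequency,
    gene diversity, observed heterozygosity, Botstein polymorphism
    information content), and analyses population structure via
    identity-by-state distance, UPGMA clustering, a Gibbs sampler for
    the admixture model, and Evanno delta-K model choice with
    CLUMPP-style alignment of replicate runs.  Includes a
    synthetic-data generator that plants SSRs, homeologous and allelic
    variants, and admixed genotype matrices with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    ape,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
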