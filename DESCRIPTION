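Package: npyassoc
Title: SNP Diversity and Marker-Trait Association for Candidate-Gene
    Studies in Hens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Population-genetic characterisation and marker-trait
    association analysis for biallelic SNP markers in candidate-gene
    studies of laying hens. Computes per-breed genotype and allele
    frequencies by gene counting, polymorphism information content,
    expected heterozygosity, and Hardy-Weinberg chi-square tests;
    fits one-way fixed-effect linear models of egg-production traits
    on genotype or breed with least-squares means, pairwise
    comparisons and compact letter displays; discovers variant sites
    from a multiple sequence alignment of a candidate-gene coding
    region; and simulates genotype-phenotype studies with known
    structure for calibration and power analysis. Ships the published
    genotype counts and trait summaries for seven coding-region SNPs
    of the chicken neuropeptide Y (NPY) gene in Thai native,
    black-bone and commercial laying hen breeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
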