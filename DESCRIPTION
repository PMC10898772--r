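Package: hybridtraits
Title: Hybrid Diagnosis from SNP Panels and Quantitative Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for diagnosing natural hybrids from reduced-representation
    SNP panels and morphometric data. Provides DArT-style genotype input, a
    five-stage locus filtering cascade (monomorphic, call rate,
    reproducibility, secondaries, minor allele frequency), supervised
    maximum-likelihood estimation of admixture proportions and interclass
    heterozygosity against parental reference panels with rule-based
    F1/backcross calling, per-character transgressive segregation
    classification (ANOVA/Tukey or Kruskal-Wallis/Dunn pathways), and
    desk-scale approximate Bayesian computation with random-forest model
    choice over explicit admixture scenarios, including generation-to-time
    conversion. A synthetic-data generator with known hybrid classes and
    planted trait categories makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    car,
    jsonlite,
    randomForest,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
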