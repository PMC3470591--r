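Package: ships
Title: Spectral Hierarchical Clustering for the Inference of Population Structure
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters individuals into genetically homogeneous sub-populations
    from SNP genotype matrices coded 0/1/2 and estimates the number of
    sub-populations. A similarity matrix based on the allele sharing distance
    is bisected recursively by normalized spectral clustering with a
    Gaussian-mixture assignment, the resulting binary tree is reduced-error
    pruned into a nested partition sequence, and the optimal number of
    clusters is selected with a no-logarithm gap statistic against uniform
    genotype null references. Includes readers for 012 matrices, PLINK raw
    tables and minimal VCF, an adjusted-Rand-index evaluator, and a
    population simulator (hierarchical allele-frequency drift and discrete
    admixture by iterated random mating) so every stage can be verified on
    data with known structure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: mclust, stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, vcfR, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
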