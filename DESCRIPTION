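Package: ldne
Title: Linkage-Disequilibrium Estimation of Effective Population Size and
    Effective Number of Breeders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-sample estimation of the effective number of breeders (Nb)
    and generational effective population size (Ne) from SNP genotypes using
    the linkage-disequilibrium method: Burrows' composite disequilibrium r2
    with sampling-expectation correction, rare-allele screening, and
    delete-one-individual jackknife confidence intervals. Includes the bias
    corrections for physical linkage (chromosome number) and age structure
    (adult lifespan and age at maturity) used for iteroparous species with
    overlapping generations, supporting population-genetic summaries
    (heterozygosity, FIS, pairwise Weir-Cockerham FST with permutation tests,
    PCA with modal-genotype imputation), readers and writers for VCF and
    Genepop, and forward simulators (discrete Wright-Fisher and age-structured
    with pedigree-derived demographic truth) for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
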