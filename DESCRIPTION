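Package: alleleCI
Type: Package
Title: Exact Confidence Intervals for Allele Frequencies in Finite Diploid Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact, guaranteed-coverage (>= 1 - alpha) confidence intervals and
    confidence regions for population allele frequencies when N diploid
    individuals are sampled without replacement from a finite diploid
    population of M individuals with any degree of deviation from
    Hardy-Weinberg equilibrium. Intervals are obtained by inverting exact
    tests based on the multivariate hypergeometric sampling distribution of
    genotype counts. Includes minimum-sample-size determination for a target
    interval length, Bonferroni joint confidence regions over several alleles,
    a confidence interval for Jost's D between two populations obtained by
    constrained optimisation over the joint regions, a synthetic finite
    population simulator used as an empirical oracle, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lhs,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
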