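Package: enuscreen
Title: Simulation and Meiotic Mapping of ENU Saturation-Mutagenesis Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying forward-genetic screens for binary phenotypes
    in mice mutagenized with N-ethyl-N-nitrosourea (ENU). Simulates the
    G0-G1-G2-G3 backcross breeding design on an autosomal genetic map with
    Haldane (Poisson) crossovers, assigns binary phenotypes under configurable
    penetrance, background misclassification and homozygous lethality, and
    reimplements automated meiotic mapping: per-allele logistic regression of
    phenotype on recessive, dominant or additive genotype encodings with Wald
    p-values, a Firth penalized-likelihood fallback under separation, and
    per-pedigree Bonferroni correction for the number of ENU alleles tested.
    Screen-level analytics cover affected-pedigree classification, penetrance
    estimation, mapped-versus-unmapped comparisons, saturation counting and
    simulation-driven power curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    withr
Config/testthat/edition: 3
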