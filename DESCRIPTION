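Package: hybridqg
Title: Quantitative Genetics of Immortalized F2 Hybrid Populations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for biparental doubled-haploid
    (DH) panels and the immortalized F2 hybrid populations derived from them.
    Provides marker quality control and hybrid genotype inference, Rogers
    kinship and shrinkage additive/dominance/Gaussian relationship matrices,
    one-step GCA/SCA variance decomposition with broad-sense heritability,
    kinship-corrected single-marker and full two-dimensional epistasis scans
    with permutation and Bonferroni-Holm multiplicity control, multi-kernel
    GBLUP prediction of hybrid performance with bespoke cross-validation and
    independent validation, and Bayesian partition of genetic variance over
    additive, dominance and digenic-epistatic effect classes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
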