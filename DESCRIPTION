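Package: riskhapscan
Title: Post-GWAS Characterization of a Founder Risk Haplotype from Phased
    Case-Control Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize a focal disease-risk locus after a
    case-control association scan: dosage-penetrance modeling with
    Firth-penalized and maximum-likelihood logistic regression, stratified
    allelic association (Cochran-Mantel-Haenszel, Breslow-Day), core-SNP
    haplotype inference by EM with score tests and haplotype-dosage models,
    extended haplotype homozygosity (EHH), integrated EHH and unstandardized
    cross-class XP-EHH, pairwise shared-tract statistics, identity-by-descent
    interval summaries with a tract-length founder-dating heuristic,
    KING-robust kinship contrasts, and carrier modifier analyses with
    time-varying-covariate Cox regression. A forward Wright-Fisher simulator
    of a founder haplotype expanding under recombination generates phased
    cohorts with dosage-dependent penetrance so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
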