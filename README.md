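# riskhapscan

Post-GWAS characterization of a founder risk haplotype from phased
case–control genotypes.

When an association scan in a structured population (the motivating case:
idiopathic epilepsy in a two-lineage purebred dog cohort) lands on a single
strongly associated marker, this package answers the follow-up questions:

* **How does risk scale with allele dosage?** Firth-penalized logistic
  regression of status on dosage (0/1/2) with cohort covariates — the
  penalty ℓ*(β) = ℓ(β) + ½ log det I(β) keeps estimates finite when a
  dosage class contains no controls — plus an ML GLM sensitivity fit,
  contingency/penetrance summaries, allelic and Cochran–Mantel–Haenszel /
  Breslow–Day stratified tests, Bonferroni/FDR/λ_GC utilities.
* **Is the allele on one founder haplotype?** Focal-allele partitioning of
  phased chromosomes; pairwise shared-tract lengths; EHH decay curves,
  integrated EHH (iES) and unstandardized XP-EHH = log(iES_risk/iES_non-risk);
  half-decay spans; seeded down-sampling.
* **How recently did it spread?** IBD-segment interval summaries (sharing
  proportion, median per-pair maximum length) and the founder-dating
  heuristic g ≈ 50 / L_cM; KING-robust kinship with a carrier-pair Wilcoxon
  contrast to separate founder sharing from plain close relatedness.
* **What modifies expression among carriers?** Core-SNP haplotype EM with
  score tests and a haplotype-dosage Firth model; onset summaries; a
  temporality-constrained gonadectomy exposure; Firth modifier models and
  counting-process Cox regression with a time-varying gonadectomy covariate
  and cluster-robust errors.
* **A forward simulator** (Wright–Fisher, two lineages, founder haplotype
  expanding over g generations under recombination on a 1 cM/Mb map, with
  dosage-dependent penetrance and sex/gonadectomy onset modifiers) emits
  phased VCF, phenotype tables and true IBD segments, so the whole pipeline
  is testable against known ancestry.

## Worked example

```r
library(riskhapscan)

cfg <- simulationConfig(seed = 42)     # g = 11 founder expansion, 200 dogs
sim <- simulateCohort(cfg)

foc  <- focalMarker(sim$truth$focal_id, sim$truth$risk_allele)
dose <- dosageAt(sim$haps, foc)
fit  <- fitDosageModel(dosageTable(sim$cohort, dose), estimator = "firth")
fit
#> Logistic risk model (firth estimator)
#>               coef     se      OR  ci_lo  ci_hi         p
#> (Intercept) -1.656 0.2015  0.1909 -2.069 -1.278 5.020e-22
#> dosage       2.477 0.5637 11.9000  1.441  3.633 2.254e-06
#> Overall LRT p = 2.254e-06

part <- partitionByFocalAllele(sim$haps, foc)
medianSharedTracts(sim$haps, part$risk, part$focal_index, "risk")
#> Shared-tract summary [risk]: 17 haplotypes, panel median 11.584 Mb, mean 10.218 Mb
ctrl_idx <- downsampleClass(part$nonrisk, 40, seed = 7)
medianSharedTracts(sim$haps, ctrl_idx, part$focal_index, "non-risk")
#> Shared-tract summary [non-risk]: 40 haplotypes, panel median 0.063 Mb, mean 0.052 Mb

ies_r <- integratedEhh(ehhCurve(sim$haps, part$risk, part$focal_index))
ies_n <- integratedEhh(ehhCurve(sim$haps, ctrl_idx, part$focal_index))
xpehhUnstandardized(ies_r, ies_n)
#> [1] 4.071374

ibd <- trueIbdSegments(sim$truth)
cls <- data.frame(dog = hapDogIds(sim$haps)[part$risk],
                  side = hapSides(sim$haps)[part$risk])
classIbdSummary(ibd, cls, "chr3", 87771875, 88894884)
#> IBD interval summary: 136/136 pairs sharing (100.0%)
#>   median max overlap 8.68 cM -> g ~ 5.8 generations
```

Reading the output: the per-allele odds ratio in this simulated cohort is
11.9 (the generator's true value is exp(1.9) ≈ 6.7; with 17 carrier
chromosomes the estimate is noisy but the profile CI [1.44, 3.63] on the
log scale covers the truth). Risk-class chromosomes share a median 11.6 Mb
around the focal marker against 0.06 Mb for non-risk chromosomes, XP-EHH is
strongly positive, and every risk–risk pair shares true IBD over the focal
interval. The heuristic date (~6 generations for a true depth of 11)
illustrates the documented ~0.6·g bias of g ≈ 50/L applied to a median —
treat it as an order of magnitude.

Real data enter through `readPhasedVcf()` (phased VCF),
`readPhenotypes()` (delimited phenotype/covariate table) and
`readIbdSegments()` (hap-IBD-style TSV); all analysis functions take those
objects directly.

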