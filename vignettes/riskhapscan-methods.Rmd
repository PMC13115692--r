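---
title: "Characterizing a founder risk haplotype: models and design choices"
author: "riskhapscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a founder risk haplotype: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskhapscan)
```

# The scientific problem

After a case-control association scan points at a single strongly
associated marker, the interesting questions are no longer "is there a
signal" but "what kind of signal is it": how does disease risk scale with
the number of risk-allele copies, is the allele carried on one long
founder-derived chromosome segment or on many backgrounds, how recently
did that segment spread, and do non-genetic factors (sex, gonadectomy
timing) modify expression among carriers. riskhapscan implements that
post-scan characterization pipeline for phased SNP genotypes around a
focal marker, together with a forward simulator that generates cohorts
with known founder ancestry so every statistic can be validated against
truth.

The motivating setting is a two-lineage purebred dog cohort (a show/pet
lineage group and a working lineage group) of roughly 100-200 dogs, with
a rare risk allele carried on one extended haplotype concentrated in the
show/pet group, dosage-dependent penetrance (every dosage-2 dog affected,
most dosage-1 dogs affected, no dosage-2 controls), and sex/gonadectomy
effects on onset age among carriers.

# Dosage-penetrance models

The primary estimator is Firth-penalized logistic regression of
case/control status on risk-allele dosage (0/1/2) with a cohort
indicator:

$$\ell^*(\beta) = \ell(\beta) + \tfrac12 \log \det I(\beta),$$

maximized by modified-score Newton iterations with step-halving. The
Jeffreys penalty keeps estimates finite under the quasi-separation that
this data pattern guarantees (a dosage class with no controls), which is
exactly why it is the primary estimator; the unpenalized binomial GLM is
fitted alongside as a sensitivity analysis, with separation detected and
flagged. Counted data (a dosage-by-status table) are fitted through the
grouped likelihood, which is algebraically identical to the expanded
individual-level fit and fast.

Inference is by penalized likelihood-ratio tests per term and profile
penalized-likelihood confidence intervals found by expanding-bracket
bisection on the penalized LR statistic (tolerance 1e-6 on the
coefficient); Wald intervals from the inverse penalized information are
also reported because published fits do not always state which
convention was used. Convergence is declared when the largest modified
score falls below 1e-6 (at most 50 iterations).

Around the single-marker model sit the standard association summaries:
carrier fractions and per-dosage penetrance from the contingency table,
the unadjusted allelic chi-square and cross-product odds ratio (0.5
continuity correction only when a cell is zero, and flagged),
Cochran-Mantel-Haenszel stratified association with a Breslow-Day
homogeneity test, Bonferroni thresholds, Benjamini-Hochberg FDR, and the
genomic inflation factor computed from two-sided p-values via the 1-df
chi-square quantile transform. The Mantel-Haenszel formulas are
evaluated directly so that the single-stratum case reduces cleanly to
the allelic odds ratio; `stats::mantelhaen.test()` is used as an
independent cross-check in the test suite rather than as the
implementation.

# Core-SNP haplotypes

Haplotype frequencies over a handful of core SNPs are estimated from
unphased genotypes by EM under Hardy-Weinberg equilibrium, starting from
uniform frequencies over the compatible haplotypes and stopping when the
log-likelihood improves by less than 1e-8. Association uses score tests
built from posterior-expected haplotype counts (the haplo.score
construction): the global statistic is a quadratic form with a
generalized inverse, referred to chi-square with degrees of freedom
equal to the rank of the variance; per-haplotype signed scores are
standard-normal under the null.

The haplotype-dosage risk model codes each non-reference haplotype as a
0-2 dosage, collapses haplotypes below a 5% frequency floor into one
rare category (floor applied before the reference check; ties at the
floor kept), omits a pre-specified reference haplotype, and fits the
Firth model with optional covariates. Because phase is inferred rather
than observed, the default dosage is the maximum-posterior diplotype
(hard call) with posteriors reported; a posterior-weighted coding is
available. The hard call is attenuating when diplotypes are genuinely
ambiguous, which is the main caveat for effect sizes from this model.
Haplotypes below the score-test floor can either be skipped or pooled
into a rare class — both behaviors are exposed because published
analyses rarely state which was used.

# Haplotype sharing around the focal marker

Phased chromosomes are partitioned by the allele carried at the focal
marker (unpolarized; no ancestral/derived orientation). Three related
statistics describe sharing:

* **Pairwise shared tracts** extend from the focal marker in both
  directions while two haplotypes agree at every marker. The tract
  boundary is the position of the farthest matching marker — a
  conservative, marker-supported choice; the midpoint convention
  (halfway to the first mismatch) is available behind a flag since the
  boundary definition is genuinely open. Tracts reaching the region edge
  are kept at their truncated length and flagged censored; summaries are
  reported both with censored pairs included (primary, appropriate when
  the region covers the whole relevant decay) and excluded.
* **EHH** at marker x is the probability that two randomly drawn
  class haplotypes are identical everywhere between the focal marker and
  x, computed by group splitting; it is 1 at the focal marker and
  non-increasing outward by construction.
* **iES / XP-EHH** integrate EHH over physical distance (trapezoid, Mb
  units) and contrast classes as log(iES_a / iES_b), unstandardized.
  When EHH has not fallen below a cutoff (default 0.05, configurable)
  before the region border, the integral is truncated at the border and
  flagged rather than silently returned; the truncation removes more
  area from the longer-haplotype class, so it biases the contrast toward
  zero, never away from it.

Half-decay spans locate the first crossing of EHH below 0.5 on each side
by linear interpolation between markers, reporting censored sides as
missing. Class down-sampling (seeded, without replacement) supports
sensitivity analyses to unequal class sizes, mirroring the common
practice of down-sampling the majority class to the carrier count.

# IBD summaries, founder dating, kinship

IBD segments are consumed, not detected: the detection step belongs to
external haplotype-IBD callers (and the simulator emits truth segments
in the same 8-column dialect), so the package summarizes. For a focal
interval, a within-class haplotype pair "shares" if any segment
overlaps the interval under the inclusive rule (segment end >= interval
start and segment start <= interval end); per sharing pair the maximum
overlapping segment length in cM is taken, and the class summary reports
the sharing proportion over all n(n-1)/2 pairs and the median of the
per-pair maxima. The founder-dating heuristic g = 50 / L applies to that
median. It is deliberately rough: for a star-shaped genealogy of depth g
the median two-sided segment around the focal point is about 84/g cM,
so the heuristic recovers roughly 0.6 g; a factor-of-two band is the
honest resolution, and the package documents and tests it as such.

Pairwise kinship uses the KING-robust moment estimator
phi = (N_het,het - 2 N_opp-hom) / (N_het,i + N_het,j) over markers
passing MAF >= 0.05 and missingness <= 0.05 filters (LD pruning, when
wanted, is accepted as an upstream marker list). Negative values are
retained — under population structure they carry the between-lineage
signal. The carrier contrast assigns each dog pair to carrier-carrier,
carrier-noncarrier or noncarrier-noncarrier (carrier = dosage >= 1) and
compares the first and last categories with a two-sided Wilcoxon
rank-sum test; the reported W is the rank-sum of the carrier-carrier
group, an orientation that matters when comparing published statistics.

# Carrier modifier analyses

Onset summaries use linear-interpolation (type 7) quantiles, stated
because published medians rarely name their convention. The gonadectomy
exposure has a temporality constraint: a case counts as exposed only if
gonadectomy preceded both seizure onset and the landmark age (5 years
primary, 2 years sensitivity); controls only need gonadectomy before the
landmark. The constraint avoids reverse causation — a gonadectomy after
onset cannot have modified it.

Two models are fitted among carriers: a Firth logistic model of status
on exposure and sex (delegating to the same penalized engine), and a Cox
model on age scale with gonadectomy as a time-varying covariate in a
counting-process (start-stop) structure — one interval for dogs never
exposed, two (unexposed then exposed, split at the gonadectomy age) for
dogs gonadectomized before the landmark and before their endpoint. All
dogs enter at birth (no left truncation); ties use the Efron
approximation; variances are cluster-robust by dog; zero-length exposed
intervals (gonadectomy exactly at the endpoint) are disallowed and
collapse to one unexposed interval. Proportional hazards are checked
with scaled Schoenfeld residuals (`survival::cox.zph`). Dogs missing
gonadectomy information are dropped with their ids recorded on the fit.

# The synthetic cohort generator

The simulator is a diploid Wright-Fisher model with non-overlapping
generations and random mating within two lineages (default 200 breeding
dogs each, 1% migration) — deliberately simple, because what downstream
statistics need from it is correct tract-length structure, not a
realistic pedigree. Markers (default 1,000) are placed uniformly over a
14 Mb region at array-like density with the focal marker inserted at a
fixed position; background alternate-allele frequencies are drawn from
Beta(2, 2); recombination is linear at 1 cM/Mb with Poisson crossover
counts per meiosis. The risk allele enters on identical copies of one
founder haplotype in generation 0 (default 19 copies) and carriers get a
mild fecundity advantage (weight 1.07 per copy), emulating
popular-sire-style amplification; after the default 11 generations about
40 population haplotypes — on the order of 19 sampled chromosomes in a
200-dog cohort — carry the founder segment, the condition under which
the sharing statistics are exercised. Because the generation-0 copies
are clones, the haplotype's common ancestor sits exactly g generations
back, which is what the dating heuristic is supposed to see. If drift
loses the allele the run retries with a derived seed (bounded, default
25, reported), keeping runs deterministic: identical seeds give
identical outputs.

Phenotypes follow the logistic penetrance model with defaults
baseline = -1.52 and per-allele log-OR = 1.9, chosen so dosage 0/1/2
dogs are cases with probability about 0.18/0.61/0.92 — the ascertained
case-enriched cohort pattern, not a population prevalence. Onset ages
come from a Weibull proportional-hazards model (shape 2, scale 4.7;
median near 3.9 years for intact females and 2.4 for males at the
default male log-HR of log 3.1) with the gonadectomy effect switching on
at the gonadectomy age for pre-landmark gonadectomies, truncated to the
0.5-9 year onset window by inverse-CDF sampling. Gonadectomy ages are
assigned independently of genotype so modifier effects can be recovered
cleanly; a confounding knob (`gdx_confound_log_or`) shifts gonadectomy
probability by case status for explicit confounding experiments.
Controls get follow-up ages of at least 7.5 years.

What the generator does **not** emulate: linkage disequilibrium among
background markers in generation 0 (founder haplotypes are drawn
site-independently, so background LD builds up only through the g
simulated generations), mutation, genotyping error, overlapping
generations, or realistic dog family structure. Passing tests therefore
show that the statistics behave correctly under a clean founder
expansion; they do not show robustness to array artifacts or to deep
pedigree structure in real cohorts.

# Numerical choices and degenerate inputs

* Coordinates are 1-based and intervals inclusive on both ends
  everywhere; genetic positions derive from the linear 1 cM/Mb map
  unless supplied.
* Missing genotypes are rejected at load: every sharing statistic in the
  package is undefined under missingness, so an error beats silent
  dropping. Phase is taken from the input VCF as given and never
  reordered.
* Monomorphic markers yield NA r2 in the LD profile (reported, not
  dropped); a monomorphic lead marker or focal marker is an error.
* A degenerate score-test variance drops the haplotype with a record of
  what was dropped; an all-reference cohort is an error for the
  haplotype-dosage model.
* Wilcoxon p-values use the exact distribution only where
  `stats::wilcox.test` would (small, tie-free samples); ties force the
  normal approximation with tie correction.
* The simulator's retry-on-loss uses seed + attempt - 1, so a retried
  run is as reproducible as a first-attempt run.

# Problem sizes in the test suite

The packaged tests validate operators against brute-force oracles on
fixtures of at most a few dozen haplotypes, and validate the pipeline's
discriminating behavior on 100 seeded replicates of the default
founder-expansion configuration (g = 11, ~19 carrier chromosomes,
1,000 markers, 200 sampled dogs), plus null-coverage studies of a few
hundred replicates for the penalized logistic and Cox models. These
sizes give Monte-Carlo standard errors comfortably inside the asserted
bounds while keeping a full run of the suite in the minutes range.

# Known limitations

* The dating heuristic inherits the bias described above; treat its
  output as an order-of-magnitude statement.
* Hard-call haplotype dosages attenuate effects when phase is ambiguous;
  use the expected-count coding for sensitivity.
* The EHH border flag tells you the region was too short for full decay;
  iES values flagged that way are lower bounds.
* KING-robust kinship for a pair is undefined when neither dog is
  heterozygous on the shared marker set (reported as NA).
* The simulator's two lineages are exchangeable apart from where the
  founder haplotype is seeded; it makes no attempt to match real
  within-breed divergence times.
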