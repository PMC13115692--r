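# Shared fixtures and independent oracles. Oracles here are deliberately
# naive re-implementations (position-by-position scans, pair enumeration)
# kept independent of the package's algorithms.

# small deterministic haplotype set: H haplotypes x M markers
makeHaps <- function(a, start_bp = 1e6, spacing = 1e5, dog_ids = NULL) {
  a <- as.matrix(a)
  M <- ncol(a)
  map <- markerMap(paste0("m", seq_len(M)), "chr3",
                   as.integer(start_bp + (seq_len(M) - 1L) * spacing),
                   rep("A", M), rep("G", M))
  if (is.null(dog_ids)) dog_ids <- paste0("d", seq_len(nrow(a) / 2))
  phasedHaplotypeSet(a, dog_ids, map)
}

# lead-marker genotype counts by cohort (dosage x status)
table1Counts <- function() {
  countsTable(
    GWAS = cbind(case = c(11, 9, 4), control = c(86, 3, 0)),
    Sanger = cbind(case = c(13, 10, 1), control = c(24, 9, 0)))
}

# brute-force shared tract: scan outward marker by marker
oracleTract <- function(h1, h2, f, pos) {
  li <- f
  while (li > 1 && h1[li - 1] == h2[li - 1]) li <- li - 1
  ri <- f
  while (ri < length(pos) && h1[ri + 1] == h2[ri + 1]) ri <- ri + 1
  if (h1[f] != h2[f]) return(0)
  pos[ri] - pos[li]
}

# brute-force EHH at every marker by enumerating all pairs
oracleEhh <- function(a, f) {
  n <- nrow(a); M <- ncol(a)
  pairs <- utils::combn(n, 2)
  sapply(seq_len(M), function(x) {
    rng <- if (x >= f) f:x else x:f
    mean(apply(pairs, 2, function(pr)
      all(a[pr[1], rng] == a[pr[2], rng])))
  })
}

# lazy cache of the 100-replicate founder-expansion study (g = 11,
# ~19 carrier chromosomes); shared across test files so the heavy
# simulation runs once per suite.
.simStudyCache <- new.env(parent = emptyenv())

founderExpansionStudy <- function(n_rep = 100) {
  key <- paste0("study", n_rep)
  if (!is.null(.simStudyCache[[key]])) return(.simStudyCache[[key]])
  res <- lapply(seq_len(n_rep), function(r) {
    cfg <- simulationConfig(seed = 20000 + r)
    sim <- simulateHaplotypes(cfg)
    foc <- focalMarker(sim$truth$focal_id, sim$truth$risk_allele)
    part <- tryCatch(partitionByFocalAllele(sim$haps, foc),
                     error = function(e) NULL)
    if (is.null(part) || length(part$risk) < 2)
      return(list(ok = FALSE))
    mr <- medianSharedTracts(sim$haps, part$risk, part$focal_index)
    nr_idx <- downsampleClass(part$nonrisk, 40, seed = r)
    mn <- medianSharedTracts(sim$haps, nr_idx, part$focal_index)
    ir <- integratedEhh(ehhCurve(sim$haps, part$risk, part$focal_index))
    inr <- integratedEhh(ehhCurve(sim$haps, nr_idx, part$focal_index))
    ibd <- trueIbdSegments(sim$truth)
    cls <- data.frame(dog = hapDogIds(sim$haps)[part$risk],
                      side = hapSides(sim$haps)[part$risk])
    isum <- classIbdSummary(ibd, cls, "chr3", 87771875, 88894884)
    nr_cls <- data.frame(dog = hapDogIds(sim$haps)[nr_idx],
                         side = hapSides(sim$haps)[nr_idx])
    nsum <- classIbdSummary(ibd, nr_cls, "chr3", 87771875, 88894884)
    list(ok = TRUE, n_carriers = length(part$risk),
         med_risk_mb = mr$panel_median_mb, med_nonrisk_mb = mn$panel_median_mb,
         xpehh = xpehhUnstandardized(ir, inr),
         g_hat = isum$g_hat, prop_sharing = isum$prop_sharing,
         prop_sharing_nonrisk = nsum$prop_sharing)
  })
  out <- list(
    ok = vapply(res, function(x) x$ok, TRUE),
    n_carriers = vapply(res, function(x) if (x$ok) x$n_carriers else NA_real_, 0),
    med_risk = vapply(res, function(x) if (x$ok) x$med_risk_mb else NA_real_, 0),
    med_nonrisk = vapply(res, function(x) if (x$ok) x$med_nonrisk_mb else NA_real_, 0),
    xpehh = vapply(res, function(x) if (x$ok) x$xpehh else NA_real_, 0),
    g_hat = vapply(res, function(x) if (x$ok) x$g_hat else NA_real_, 0),
    prop_sharing = vapply(res, function(x) if (x$ok) x$prop_sharing else NA_real_, 0),
    prop_sharing_nonrisk =
      vapply(res, function(x) if (x$ok) x$prop_sharing_nonrisk else NA_real_, 0))
  .simStudyCache[[key]] <- out
  out
}
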