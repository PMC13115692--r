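smallCfg <- function(seed, ...) {
  simulationConfig(seed = seed, n_markers = 120L, region_span_bp = 6e6,
                   region_start_bp = 85e6, focal_bp = 88e6,
                   pop_size = c(ShowPet = 60L, Working = 60L),
                   n_dogs = c(ShowPet = 30L, Working = 30L),
                   founder_risk_copies = 8L, ...)
}

test_that("config validation enforces sane parameters", {
  expect_error(simulationConfig(), "seed")
  expect_error(simulationConfig(seed = 1, migration_rate = 2))
  expect_error(simulationConfig(seed = 1, focal_bp = 1))
  expect_s3_class(simulationConfig(seed = 1), "SimulationConfig")
})

test_that("identical seeds give identical cohorts", {
  s1 <- simulateCohort(smallCfg(3))
  s2 <- simulateCohort(smallCfg(3))
  expect_identical(haplotypes(s1$haps), haplotypes(s2$haps))
  expect_identical(posBp(markerMapOf(s1$haps)), posBp(markerMapOf(s2$haps)))
  expect_identical(s1$truth$descent, s2$truth$descent)
  expect_equal(as.data.frame(s1$cohort), as.data.frame(s2$cohort))
  s3 <- simulateCohort(smallCfg(4))
  expect_false(identical(haplotypes(s1$haps), haplotypes(s3$haps)))
})

test_that("zero recombination keeps full-span founder tracts on carriers", {
  sim <- simulateHaplotypes(smallCfg(5, recomb_rate_cM_per_Mb = 0))
  pos <- posBp(markerMapOf(sim$haps))
  d <- sim$truth$descent
  expect_gt(nrow(d), 0)
  expect_true(all(d$start_bp == min(pos)))
  expect_true(all(d$end_bp == max(pos)))
  # every risk-allele copy lies inside a founder-descent tract
  fcol <- haplotypes(sim$haps)[, sim$truth$focal_index]
  carriers <- which(fcol == 1L)
  keys <- paste(rep(dogIds(sim$haps), each = 2), rep(1:2, nDogs(sim$haps)))
  expect_true(all(keys[carriers] %in% paste(d$dog, d$side)))
  # with no recombination every carrier pair shares one full-span segment
  ibd <- trueIbdSegments(sim$truth)
  s <- ibdSegments(ibd)
  expect_true(all(s$start_bp == min(pos) & s$end_bp == max(pos)))
  k <- length(carriers)
  expect_lte(length(ibd), k * (k - 1) / 2)
})

test_that("g = 0 samples exact copies of the founder haplotype", {
  sim <- simulateHaplotypes(smallCfg(6, g_generations = 0L))
  a <- haplotypes(sim$haps)
  f <- sim$truth$focal_index
  carriers <- a[a[, f] == 1L, , drop = FALSE]
  if (nrow(carriers) >= 2)
    for (i in 2:nrow(carriers))
      expect_identical(carriers[i, ], carriers[1, ])
})

test_that("descent tracts are disjoint per haplotype and contain risk copies", {
  sim <- simulateHaplotypes(smallCfg(7))
  d <- sim$truth$descent
  for (key in unique(paste(d$dog, d$side))) {
    tr <- d[paste(d$dog, d$side) == key, ]
    tr <- tr[order(tr$start_bp), ]
    expect_true(all(tr$start_bp <= tr$end_bp))
    if (nrow(tr) > 1)
      expect_true(all(tr$start_bp[-1] > tr$end_bp[-nrow(tr)]))
  }
  fcol <- haplotypes(sim$haps)[, sim$truth$focal_index]
  keys <- paste(rep(dogIds(sim$haps), each = 2), rep(1:2, nDogs(sim$haps)))
  for (h in which(fcol == 1L)) {
    tr <- d[paste(d$dog, d$side) == keys[h], ]
    foc_pos <- posBp(markerMapOf(sim$haps))[sim$truth$focal_index]
    expect_true(any(tr$start_bp <= foc_pos & tr$end_bp >= foc_pos))
  }
})

test_that("one-sided descent extent matches an independent breakpoint simulator", {
  # marginal distribution of the tract boundary right of the focal marker:
  # the minimum over g meioses of the nearest breakpoint, Poisson crossovers
  cfgs <- lapply(1:6, function(s)
    simulationConfig(seed = 3000 + s, n_markers = 600L,
                     pop_size = c(ShowPet = 80L, Working = 80L),
                     n_dogs = c(ShowPet = 80L, Working = 80L),
                     founder_risk_copies = 12L, risk_fitness = 1))
  ext <- unlist(lapply(cfgs, function(cfg) {
    sim <- simulateHaplotypes(cfg)
    f_pos <- posBp(markerMapOf(sim$haps))[sim$truth$focal_index]
    d <- sim$truth$descent
    cover <- d[d$start_bp <= f_pos & d$end_bp >= f_pos, ]
    cover$end_bp - f_pos
  }))
  cfg <- cfgs[[1]]
  g <- cfg$g_generations
  lam <- cfg$recomb_rate_cM_per_Mb * (cfg$region_span_bp / 1e6) / 100
  end <- cfg$region_start_bp + cfg$region_span_bp
  set.seed(99)
  oracle <- replicate(4000, {
    dmin <- end - cfg$focal_bp
    for (i in seq_len(g)) {
      k <- rpois(1, lam)
      if (k > 0) {
        b <- runif(k, cfg$region_start_bp, end)
        rb <- b[b > cfg$focal_bp]
        if (length(rb)) dmin <- min(dmin, min(rb) - cfg$focal_bp)
      }
    }
    dmin
  })
  # marker-grid truncation biases the simulator down by about half the
  # inter-marker spacing (~12 kb here); allow 3 MC standard errors on top
  se <- sd(oracle) / sqrt(length(ext) / 4)   # tracts are correlated; be lax
  expect_lt(abs(mean(ext) - mean(oracle)), 3 * se + 2.5e4)
})

test_that("null dosage effect gives dosage-independent case rates", {
  set.seed(70)
  n <- 5000
  a <- matrix(rbinom(2 * n * 3, 1, 0.3), 2 * n, 3)
  haps <- makeHaps(a, dog_ids = paste0("d", 1:n))
  cfg <- simulationConfig(seed = 71, per_allele_log_OR = 0)
  co <- simulatePhenotypes(haps, NULL, cfg, focal = focalMarker("m2", "G"))
  dose <- dosageAt(haps, focalMarker("m2", "G"))
  tab <- table(dose, co$status)
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("configured per-allele effect is recovered by the Firth fit", {
  set.seed(72)
  n <- 2000
  a <- matrix(rbinom(2 * n * 3, 1, 0.25), 2 * n, 3)
  haps <- makeHaps(a, dog_ids = paste0("d", 1:n))
  cfg <- simulationConfig(seed = 73)   # per_allele_log_OR = 1.9
  co <- simulatePhenotypes(haps, NULL, cfg, focal = focalMarker("m2", "G"))
  dose <- dosageAt(haps, focalMarker("m2", "G"))
  fit <- firthLogistic(cbind(1, dose), as.integer(co$status == "case"))
  expect_lt(abs(fit$coef[2] - cfg$per_allele_log_OR), 2 * fit$se[2])
})

test_that("a huge dosage effect makes every carrier a case", {
  set.seed(74)
  n <- 300
  a <- matrix(rbinom(2 * n * 2, 1, 0.4), 2 * n, 2)
  haps <- makeHaps(a, dog_ids = paste0("d", 1:n))
  cfg <- simulationConfig(seed = 75, per_allele_log_OR = 40)
  co <- simulatePhenotypes(haps, NULL, cfg, focal = focalMarker("m1", "G"))
  dose <- dosageAt(haps, focalMarker("m1", "G"))
  expect_true(all(co$status[dose >= 1] == "case"))
})

test_that("phenotypes satisfy the cohort invariants and onset window", {
  sim <- simulateCohort(smallCfg(9))
  co <- sim$cohort
  expect_s3_class(co, "CohortTable")
  cases <- co[co$status == "case", ]
  expect_true(all(cases$age_onset_years >= 0.5 &
                  cases$age_onset_years <= 9))
  expect_true(all(cases$age_onset_years <= cases$age_last_followup_years))
  ctrl <- co[co$status == "control", ]
  expect_true(all(is.na(ctrl$age_onset_years)))
  expect_true(all(ctrl$age_last_followup_years >= 7.5))
})

test_that("emitted files reload to the identical data model", {
  sim <- simulateCohort(smallCfg(10))
  out <- tempfile("simout")
  paths <- emitCohort(sim, out)
  rt <- readPhasedVcf(paths["vcf"])
  expect_identical(unname(haplotypes(rt$haps)), unname(haplotypes(sim$haps)))
  expect_identical(posBp(rt$map), posBp(markerMapOf(sim$haps)))
  co <- readPhenotypes(paths["phenotypes"])
  expect_equal(co$status, sim$cohort$status)
  expect_equal(co$age_onset_years, sim$cohort$age_onset_years,
               tolerance = 1e-9)
  ibd_rt <- readIbdSegments(paths["ibd"])
  ibd <- trueIbdSegments(sim$truth)
  expect_equal(ibdSegments(ibd_rt)$start_bp, ibdSegments(ibd)$start_bp)
  expect_equal(ibdSegments(ibd_rt)$length_cm, ibdSegments(ibd)$length_cm,
               tolerance = 1e-5)
})

test_that("carrier tract length shrinks in expectation as g grows", {
  med_for <- function(g) {
    meds <- vapply(1:6, function(s) {
      sim <- simulateHaplotypes(smallCfg(400 + s, g_generations = g))
      foc <- focalMarker(sim$truth$focal_id, sim$truth$risk_allele)
      part <- tryCatch(partitionByFocalAllele(sim$haps, foc),
                       error = function(e) NULL)
      if (is.null(part) || length(part$risk) < 2) return(NA_real_)
      medianSharedTracts(sim$haps, part$risk,
                         part$focal_index)$panel_median_mb
    }, 0)
    mean(meds, na.rm = TRUE)
  }
  m5 <- med_for(5L); m11 <- med_for(11L); m25 <- med_for(25L)
  expect_gt(m5, m11 * 0.99)
  expect_gt(m11, m25)
})

test_that("background allele-frequency spectrum is preserved under drift", {
  sim <- simulateHaplotypes(smallCfg(11, risk_fitness = 1))
  a <- haplotypes(sim$haps)
  freqs <- colMeans(a[, -sim$truth$focal_index])
  # Beta(2, 2) base: mean 0.5; drift is mean-preserving
  expect_lt(abs(mean(freqs) - 0.5), 3 * sd(freqs) / sqrt(length(freqs)) + 0.02)
})
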