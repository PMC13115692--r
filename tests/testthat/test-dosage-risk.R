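test_that("Firth estimate matches a dense grid search of the penalized likelihood", {
  # 2-parameter toy data: intercept + slope
  X <- cbind(1, c(0, 0, 1, 1, 2, 2, 0, 1))
  y <- c(0, 1, 0, 1, 1, 1, 0, 0)
  fit <- firthLogistic(X, y)
  plog <- function(b) {
    eta <- drop(X %*% b); pr <- plogis(eta)
    W <- pr * (1 - pr)
    sum(y * log(pr) + (1 - y) * log(1 - pr)) +
      0.5 * determinant(crossprod(X, X * W))$modulus
  }
  grid <- expand.grid(b0 = seq(-3, 3, 0.002), b1 = fit$coef[2])
  v0 <- apply(grid, 1, function(g) plog(c(g[1], g[2])))
  expect_lt(abs(grid$b0[which.max(v0)] - fit$coef[1]), 1e-3)
  grid <- expand.grid(b0 = fit$coef[1], b1 = seq(-3, 3, 0.002))
  v1 <- apply(grid, 1, function(g) plog(c(g[1], g[2])))
  expect_lt(abs(grid$b1[which.max(v1)] - fit$coef[2]), 1e-3)
  # the joint fit attains at least the best grid value
  expect_gte(fit$loglik + 1e-8, max(v1))
})

test_that("perfectly balanced dosage table gives a zero dosage effect", {
  tab <- countsTable(GWAS = cbind(case = c(20, 10, 5), control = c(20, 10, 5)))
  fit <- fitDosageModel(tab, "firth")
  expect_lt(abs(fit$coef["dosage"]), 1e-6)
})

test_that("Firth stays finite under separation while the MLE diverges", {
  # complete separation: all dosage>=1 are cases, all dosage 0 controls
  X <- cbind(1, rep(c(0, 1, 2), each = 10))
  y <- rep(c(0, 1, 1), each = 10)
  ffit <- firthLogistic(X, y)
  expect_true(all(is.finite(ffit$coef)))
  expect_true(ffit$converged)
  mfit <- mleLogistic(X, y)
  expect_true(mfit$separation)
})

test_that("Firth is finite on every separated small 3-level dosage table", {
  # exhaustive small tables with at least one zero cell
  for (c0 in c(0, 3)) for (c1 in c(0, 2)) for (c2 in c(0, 2))
    for (k0 in c(0, 4)) for (k1 in c(0, 1)) {
      tab <- countsTable(G = cbind(case = c(c0, c1, c2),
                                   control = c(k0, k1, 0)))
      d <- riskhapscan:::expandDosageRecords(tab)
      if (nrow(d) < 2 || length(unique(d$status)) < 2) next
      if (length(unique(d$dosage)) < 2) next
      fit <- suppressWarnings(
        firthLogistic(cbind(1, d$dosage), d$status, weights = d$n))
      expect_true(all(is.finite(fit$coef)))
    }
})

test_that("profile CI endpoints sit on the penalized LR critical contour", {
  X <- cbind(1, c(0, 0, 1, 1, 2, 2, 0, 1, 1, 2))
  y <- c(0, 1, 0, 1, 1, 1, 0, 0, 1, 1)
  fit <- firthLogistic(X, y)
  crit <- qchisq(0.95, 1)
  for (j in 1:2) {
    expect_lt(fit$ci_lower[j], fit$coef[j])
    expect_gt(fit$ci_upper[j], fit$coef[j])
    for (b in c(fit$ci_lower[j], fit$ci_upper[j])) {
      pl_b <- riskhapscan:::.plProfile(X, y, rep(1, length(y)), j, b,
                                       fit$coef, 1e-6, 50)
      expect_lt(abs(2 * (fit$loglik - pl_b) - crit), 1e-3)
    }
  }
})

test_that("Firth and MLE agree on large non-separated data", {
  set.seed(42)
  n <- 5000
  x <- rbinom(n, 2, 0.4)
  y <- rbinom(n, 1, plogis(-0.5 + 0.6 * x))
  ffit <- firthLogistic(cbind(1, x), y)
  mfit <- mleLogistic(cbind(1, x), y)
  expect_lt(abs(ffit$coef[2] - mfit$coef[2]) / abs(mfit$coef[2]), 0.1)
})

test_that("dosage tables reproduce cohort margins and pool additively", {
  tab <- table1Counts()
  expect_equal(sum(unclass(tab)[, , "GWAS"]), 113)
  expect_equal(sum(unclass(tab)[, , "Sanger"]), 57)
  expect_equal(poolCohorts(tab),
               unclass(tab)[, , "GWAS"] + unclass(tab)[, , "Sanger"])
  # built from a cohort data.frame
  ct <- cohortTable(data.frame(
    dog_id = c("a", "b", "c"), status = c("case", "control", "case"),
    sex = "M", lineage = "pet", cohort_label = "GWAS"))
  t2 <- dosageTable(ct, c(a = 2L, b = 0L, c = 1L))
  expect_equal(unclass(t2)[, "case", "GWAS"], c(`0` = 0L, `1` = 1L, `2` = 1L))
  empty <- dosageTable(ct[0, ], integer(0))
  expect_true(all(unclass(empty) == 0))
})

test_that("contingency summaries give carrier fractions and penetrance", {
  s <- contingencySummaries(countsTable(
    G = cbind(case = c(11, 9, 4), control = c(86, 3, 0))))
  expect_equal(unname(s$carrier_fraction["case"]), 13 / 24)
  expect_equal(unname(s$carrier_fraction["control"]), 3 / 89)
  allctrl <- contingencySummaries(countsTable(
    G = cbind(case = c(0, 0, 0), control = c(5, 3, 2))))
  expect_equal(unname(allctrl$penetrance), c(0, 0, 0))
})

test_that("allelic association matches hand computation and symmetries", {
  t0 <- matrix(c(10, 10, 90, 90), 2)   # equal frequencies
  r0 <- allelicAssoc(t0)
  expect_equal(r0$or, 1)
  expect_equal(r0$chisq, 0)
  t1 <- matrix(c(10, 2, 90, 98), 2)
  r1 <- allelicAssoc(t1)
  expect_equal(r1$or, (10 * 98) / (90 * 2))
  expect_false(r1$continuity_corrected)
  # swapping both rows and both columns leaves chi-square and OR unchanged
  t2 <- t1[2:1, 2:1]
  r2 <- allelicAssoc(t2)
  expect_equal(r2$chisq, r1$chisq)
  expect_equal(r2$or, r1$or)
  rz <- allelicAssoc(matrix(c(5, 0, 10, 20), 2))
  expect_true(rz$continuity_corrected)
})

test_that("CMH reduces to the allelic OR for one stratum and matches mantelhaen.test", {
  t1 <- matrix(c(10, 2, 90, 98), 2)
  cm1 <- cmhTest(t1)
  expect_equal(cm1$common_or, allelicAssoc(t1)$or)
  # two identical strata: common OR = stratum OR, Breslow-Day p ~ 1
  arr <- array(c(t1, t1), dim = c(2, 2, 2))
  cm2 <- cmhTest(arr)
  expect_equal(cm2$common_or, allelicAssoc(t1)$or)
  bd <- breslowDay(arr)
  expect_gt(bd$p, 0.99)
  # independent oracle for K = 2
  t2 <- matrix(c(6, 8, 40, 60), 2)
  arr2 <- array(c(t1, t2), dim = c(2, 2, 2))
  mh <- mantelhaen.test(arr2, correct = FALSE)
  cm3 <- cmhTest(arr2)
  expect_equal(cm3$chisq, unname(mh$statistic), tolerance = 1e-10)
  expect_equal(cm3$common_or, unname(mh$estimate), tolerance = 1e-10)
  # strongly heterogeneous ORs are detected
  t3 <- matrix(c(40, 5, 10, 45), 2)
  t4 <- matrix(c(5, 40, 45, 10), 2)
  expect_lt(breslowDay(array(c(t3, t4), dim = c(2, 2, 2)))$p, 0.001)
})

test_that("multiple-testing utilities follow their definitions", {
  expect_equal(signif(bonferroniThreshold(0.05, 153704), 3), 3.25e-7)
  p <- c(0.01, 0.02, 0.03, 0.04)
  # hand step-up: 0.04, 0.04, 0.04, 0.04
  expect_equal(bhFdr(p), rep(0.04, 4))
  expect_true(all(bhFdr(p) >= p))
  set.seed(1)
  ps <- runif(200)
  sh <- sample(200)
  expect_equal(bhFdr(ps)[sh], bhFdr(ps[sh]))
  expect_equal(lambdaGC(rep(0.5, 99)), 1)
})

test_that("per-group allele frequencies pool by chromosome weighting", {
  af <- alleleFreqByGroup(c(0, 1, 2, 1, 0, 0), c("a", "a", "a", "b", "b", "b"))
  pooled <- af[af$group == "(pooled)", ]
  expect_equal(pooled$freq, sum(c(0, 1, 2, 1, 0, 0)) / 12)
  byg <- af[af$group != "(pooled)", ]
  expect_equal(pooled$freq,
               sum(byg$freq * byg$chromosomes) / sum(byg$chromosomes))
  mono <- alleleFreqByGroup(c(0, 0), c("g", "g"))
  expect_equal(mono$freq[1], 0)
})
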