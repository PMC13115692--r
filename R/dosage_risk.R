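#' Dosage x status contingency table by cohort
#'
#' Cross-tabulates risk-allele dosage (0/1/2) against case/control status,
#' per cohort and pooled. This is the shape in which single-marker
#' penetrance patterns are reported (all dosage-2 individuals affected, most
#' dosage-1 affected, no dosage-2 controls).
#'
#' @param cohort a cohort data.frame (see [cohortTable()]) with a
#'   `cohort_label` column.
#' @param dosages integer vector of dosages named by `dog_id` (as returned
#'   by [dosageAt()]), or unnamed and aligned with `cohort`.
#' @return A `"ContingencyTable"`: a 3 x 2 x K array with dimnames
#'   dosage (0,1,2) x status (case, control) x cohort.
#' @export
dosageTable <- function(cohort, dosages) {
  if (!is.null(names(dosages))) {
    idx <- match(cohort$dog_id, names(dosages))
    if (anyNA(idx)) stop("dosage missing for dog(s): ",
                         paste(cohort$dog_id[is.na(idx)], collapse = ", "))
    dosages <- dosages[idx]
  }
  if (length(dosages) != nrow(cohort))
    stop("dosage vector length must match the cohort")
  if (!all(dosages %in% 0:2)) stop("dosages must be 0, 1 or 2")
  cohorts <- if (nrow(cohort)) unique(as.character(cohort$cohort_label))
             else "GWAS"
  counts <- array(0L, dim = c(3L, 2L, length(cohorts)),
                  dimnames = list(dosage = 0:2, status = c("case", "control"),
                                  cohort = cohorts))
  if (nrow(cohort))
    for (i in seq_len(nrow(cohort)))
      counts[dosages[i] + 1L, cohort$status[i],
             as.character(cohort$cohort_label[i])] <-
        counts[dosages[i] + 1L, cohort$status[i],
               as.character(cohort$cohort_label[i])] + 1L
  structure(counts, class = "ContingencyTable")
}

#' Build a ContingencyTable directly from counts
#'
#' @param ... one 3 x 2 matrix per cohort (rows dosage 0/1/2, columns
#'   case/control), named by cohort label.
#' @return A `"ContingencyTable"` array.
#' @examples
#' countsTable(GWAS = cbind(case = c(11, 9, 4), control = c(86, 3, 0)))
#' @export
countsTable <- function(...) {
  mats <- list(...)
  counts <- array(0L, dim = c(3L, 2L, length(mats)),
                  dimnames = list(dosage = 0:2, status = c("case", "control"),
                                  cohort = names(mats)))
  for (k in seq_along(mats)) counts[, , k] <- as.integer(mats[[k]])
  structure(counts, class = "ContingencyTable")
}

#' Pool a ContingencyTable over cohorts
#' @param tab a `"ContingencyTable"`.
#' @return 3 x 2 matrix of pooled counts.
#' @export
poolCohorts <- function(tab) apply(unclass(tab), c(1, 2), sum)

# Expand a contingency table into grouped records for model fitting.
expandDosageRecords <- function(tab) {
  d <- expand.grid(dosage = 0:2, status = c(1, 0),
                   cohort = dimnames(tab)$cohort, stringsAsFactors = FALSE)
  d$n <- as.vector(unclass(tab))
  d[d$n > 0, , drop = FALSE]
}

#' Fit the additive dosage risk model to a contingency table
#'
#' Convenience wrapper: expands the counts into grouped records and fits
#' `status ~ dosage + cohort` (cohort indicators only when more than one
#' cohort is present) with [firthLogistic()] or [mleLogistic()], using the
#' count-weighted likelihood.
#'
#' @param tab a `"ContingencyTable"`.
#' @param estimator `"firth"` (primary) or `"mle"` (sensitivity).
#' @param ... passed to the estimator.
#' @return A `"riskModelFit"`; the per-allele effect is the `dosage` term.
#' @export
fitDosageModel <- function(tab, estimator = c("firth", "mle"), ...) {
  estimator <- match.arg(estimator)
  d <- expandDosageRecords(tab)
  X <- cbind("(Intercept)" = 1, dosage = d$dosage)
  if (length(unique(d$cohort)) > 1L) {
    f <- factor(d$cohort)
    mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(mm) <- paste0("cohort", levels(f)[-1])
    X <- cbind(X, mm)
  }
  fn <- if (estimator == "firth") firthLogistic else mleLogistic
  fn(X, d$status, weights = d$n, ...)
}

#' Carrier fractions and per-dosage penetrance
#'
#' Summarizes a dosage x status table: the carrier fraction per status
#' (share of individuals with dosage >= 1) and the penetrance per dosage
#' class (cases / (cases + controls)).
#'
#' @param tab a `"ContingencyTable"` or a 3 x 2 matrix of pooled counts.
#' @return list with `carrier_fraction` (named by status), `penetrance`
#'   (named by dosage; NaN where a dosage class is empty) and the pooled
#'   `counts`.
#' @export
contingencySummaries <- function(tab) {
  m <- if (inherits(tab, "ContingencyTable")) poolCohorts(tab) else as.matrix(tab)
  totals <- colSums(m)
  carrier <- colSums(m[2:3, , drop = FALSE]) / totals
  pen <- m[, "case"] / rowSums(m)
  list(carrier_fraction = carrier, penetrance = pen, counts = m)
}

#' Unadjusted allelic association test
#'
#' Pearson chi-square and cross-product odds ratio on a 2 x 2 allele-count
#' table (rows case/control, columns risk/other allele). A 0.5 continuity
#' correction is added to the OR only when a cell is zero, and this is
#' flagged in the result, never silent.
#'
#' @param counts 2 x 2 matrix of allele counts, rows = (case, control),
#'   columns = (risk allele, other allele).
#' @return list with `chisq`, `p`, `or`, `freq` (case/control risk-allele
#'   frequencies) and `continuity_corrected`.
#' @export
allelicAssoc <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(dim(counts) == c(2, 2))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("allele table has a zero margin")
  cs <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  cc <- any(counts == 0)
  m <- if (cc) counts + 0.5 else counts
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  list(chisq = unname(cs$statistic), p = unname(cs$p.value), or = or,
       freq = counts[, 1] / rowSums(counts), continuity_corrected = cc)
}

#' Cochran-Mantel-Haenszel test over stratified 2 x 2 tables
#'
#' Mantel-Haenszel pooled odds ratio and 1-df continuity-uncorrected
#' chi-square across K strata (e.g. allele-count tables stratified by
#' lineage). With a single stratum this reduces exactly to the unadjusted
#' allelic odds ratio. The formulas are evaluated directly so the K = 1
#' reduction is well defined; [stats::mantelhaen.test()] agrees for K >= 2.
#'
#' @param tables 2 x 2 x K array, or a list of 2 x 2 matrices, rows =
#'   (case, control), columns = (risk allele, other allele).
#' @return list with `chisq`, `p`, `common_or`, `k`.
#' @export
cmhTest <- function(tables) {
  a <- .asStrataArray(tables)
  K <- dim(a)[3]
  n  <- apply(a, 3, sum)
  x11 <- a[1, 1, ]; r1 <- a[1, 1, ] + a[1, 2, ]; c1 <- a[1, 1, ] + a[2, 1, ]
  E <- r1 * c1 / n
  V <- r1 * (n - r1) * c1 * (n - c1) / (n^2 * (n - 1))
  V[n <= 1] <- 0
  chisq <- sum(x11 - E)^2 / sum(V)
  R <- sum(a[1, 1, ] * a[2, 2, ] / n)
  S <- sum(a[1, 2, ] * a[2, 1, ] / n)
  list(chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       common_or = R / S, k = K)
}

#' Breslow-Day test of odds-ratio homogeneity across strata
#'
#' Tests whether the stratum-specific odds ratios are compatible with the
#' Mantel-Haenszel common odds ratio; the statistic is compared with a
#' chi-square with K - 1 degrees of freedom.
#'
#' @inheritParams cmhTest
#' @return list with `statistic`, `df`, `p`, `common_or`.
#' @export
breslowDay <- function(tables) {
  a <- .asStrataArray(tables)
  K <- dim(a)[3]
  or_mh <- cmhTest(a)$common_or
  stat <- 0
  for (k in seq_len(K)) {
    t2 <- a[, , k]
    r1 <- sum(t2[1, ]); c1 <- sum(t2[, 1]); n <- sum(t2)
    # expected a-cell under the common OR: root of the quadratic
    # a (n - r1 - c1 + a) * OR = (r1 - a)(c1 - a) rearranged
    A <- or_mh - 1
    B <- -((r1 + c1) * or_mh + (n - r1 - c1))
    C <- or_mh * r1 * c1
    ea <- if (abs(A) < 1e-12) -C / B else {
      disc <- sqrt(B^2 - 4 * A * C)
      cand <- c((-B + disc) / (2 * A), (-B - disc) / (2 * A))
      cand[cand >= max(0, r1 + c1 - n) & cand <= min(r1, c1)][1]
    }
    vb <- 1 / ea + 1 / (r1 - ea) + 1 / (c1 - ea) + 1 / (n - r1 - c1 + ea)
    va <- 1 / vb
    stat <- stat + (t2[1, 1] - ea)^2 / va
  }
  list(statistic = stat, df = K - 1L,
       p = stats::pchisq(stat, df = K - 1L, lower.tail = FALSE),
       common_or = or_mh)
}

.asStrataArray <- function(tables) {
  if (is.list(tables))
    tables <- array(unlist(tables), dim = c(2, 2, length(tables)))
  if (length(dim(tables)) == 2) dim(tables) <- c(2, 2, 1)
  stopifnot(dim(tables)[1:2] == c(2, 2))
  tables
}

#' Bonferroni significance threshold
#' @param alpha family-wise error rate.
#' @param m number of tests.
#' @return `alpha / m`.
#' @examples
#' bonferroniThreshold(0.05, 153704)  # 3.25e-7
#' @export
bonferroniThreshold <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment via [stats::p.adjust()]; returned in input
#' order (the adjustment is invariant to input order).
#'
#' @param p raw p-values in (0, 1].
#' @return adjusted p-values.
#' @export
bhFdr <- function(p) stats::p.adjust(p, method = "BH")

#' Genomic inflation factor (lambda GC)
#'
#' Ratio of the observed median 1-df chi-square statistic (obtained from
#' two-sided p-values by the quantile transform) to the null median 0.4549.
#'
#' @param p vector of two-sided p-values.
#' @return lambda.
#' @export
lambdaGC <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Per-group risk-allele frequency
#'
#' Frequency of the risk allele within labelled groups, reported with the
#' underlying allele and chromosome counts.
#'
#' @param dosages integer vector of per-individual dosages (0/1/2).
#' @param groups group labels aligned with `dosages`.
#' @return data.frame with columns `group`, `risk_alleles`, `chromosomes`,
#'   `freq`, plus a pooled row labelled `"(pooled)"`.
#' @export
alleleFreqByGroup <- function(dosages, groups) {
  groups <- as.character(groups)
  if (length(groups) != length(dosages)) stop("groups must align with dosages")
  counts <- tapply(dosages, groups, sum)
  chroms <- 2L * tapply(rep(1L, length(dosages)), groups, sum)
  out <- data.frame(group = names(counts),
                    risk_alleles = as.integer(counts),
                    chromosomes = as.integer(chroms),
                    freq = as.numeric(counts) / as.numeric(chroms),
                    stringsAsFactors = FALSE, row.names = NULL)
  pooled <- data.frame(group = "(pooled)",
                       risk_alleles = sum(out$risk_alleles),
                       chromosomes = sum(out$chromosomes),
                       freq = sum(out$risk_alleles) / sum(out$chromosomes),
                       stringsAsFactors = FALSE)
  rbind(out, pooled)
}

#' Pooled frequency from per-group allele counts
#'
#' Helper for reference-panel summaries reported as "risk alleles /
#' chromosomes" per subpopulation.
#'
#' @param risk_alleles,chromosomes integer vectors per group.
#' @return pooled frequency (sum of counts over sum of chromosomes).
#' @export
pooledAlleleFreq <- function(risk_alleles, chromosomes) {
  sum(risk_alleles) / sum(chromosomes)
}
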