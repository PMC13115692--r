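# Core-SNP haplotype machinery: EM haplotype-frequency estimation from
# unphased genotypes under HWE, case-control score tests on posterior
# expected haplotype counts, and a haplotype-dosage penalized model.

# Enumerate compatible diplotypes per individual. Genotypes are alt-allele
# dosages (0/1/2) over k SNPs; a haplotype is encoded as an integer bitmask
# (bit j set = alt allele at SNP j). Returns flattened arrays for fast EM.
.enumDiplotypes <- function(G) {
  k <- ncol(G)
  n <- nrow(G)
  dogL <- hapAL <- hapBL <- vector("list", n)
  bits <- 2L^(seq_len(k) - 1L)
  for (i in seq_len(n)) {
    g <- G[i, ]
    hom <- sum(bits[g == 2L])
    het <- which(g == 1L)
    h <- length(het)
    if (h == 0L) {
      a <- b <- hom
    } else {
      # fix the first het site on haplotype A to avoid double counting
      m <- 2L^(h - 1L)
      rest <- het[-1L]
      a <- b <- integer(m)
      for (d in seq_len(m)) {
        assign_ <- as.integer(intToBits(d - 1L))[seq_len(max(h - 1L, 1L))]
        aset <- hom + bits[het[1L]]
        bset <- hom
        if (h > 1L) {
          onA <- rest[assign_[seq_len(h - 1L)] == 1L]
          onB <- setdiff(rest, onA)
          aset <- aset + sum(bits[onA])
          bset <- bset + sum(bits[onB])
        }
        a[d] <- aset; b[d] <- bset
      }
    }
    dogL[[i]] <- rep.int(i, length(a))
    hapAL[[i]] <- a; hapBL[[i]] <- b
  }
  hapA <- unlist(hapAL); hapB <- unlist(hapBL)
  list(dog = unlist(dogL), hapA = hapA, hapB = hapB,
       het = as.numeric(hapA != hapB))
}

.hapLabel <- function(codes, k, alleles = NULL) {
  m <- vapply(codes, function(cd) {
    bits <- as.integer(intToBits(cd))[seq_len(k)]
    if (is.null(alleles)) paste(bits, collapse = "")
    else paste(vapply(seq_len(k),
                      function(j) alleles[[j]][bits[j] + 1L], ""),
               collapse = "-")
  }, "")
  m
}

#' EM haplotype-frequency inference over a small set of core SNPs
#'
#' Estimates haplotype frequencies from unphased genotypes at k SNPs by the
#' expectation-maximization algorithm under Hardy-Weinberg equilibrium,
#' starting from uniform frequencies over the compatible haplotypes and
#' iterating until the log-likelihood change falls below `tol`. Per-dog
#' diplotype posteriors are computed from the final frequencies.
#'
#' @param G genotype matrix, individuals x SNPs, alt-allele dosages 0/1/2
#'   with no missing entries; at most `max_snps` SNPs.
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations (non-convergence is flagged).
#' @param alleles optional list (one entry per SNP) of c(ref, alt)
#'   characters used to label haplotypes like "A-G-A"; defaults to 0/1
#'   strings.
#' @param max_snps guard on the enumeration size.
#' @return An object of class `"HaplotypeFreqs"`: `haplotypes` (labels),
#'   `freq` (summing to 1), `loglik`, `iterations`, `converged`,
#'   `posterior` (data.frame of per-dog diplotypes with posterior
#'   probabilities), `expected_counts` (individuals x haplotypes matrix of
#'   posterior-expected copy counts), `map_dosage` (hard-call dosages from
#'   the maximum-posterior diplotype).
#' @export
emHaplotypeFreqs <- function(G, tol = 1e-8, max_iter = 500, alleles = NULL,
                             max_snps = 10L) {
  G <- as.matrix(G)
  if (anyNA(G) || !all(G %in% 0:2)) stop("genotypes must be complete 0/1/2")
  k <- ncol(G); n <- nrow(G)
  if (k > max_snps) stop("too many SNPs for exhaustive diplotype enumeration")
  e <- .enumDiplotypes(G)
  haps <- sort(unique(c(e$hapA, e$hapB)))
  ia <- match(e$hapA, haps); ib <- match(e$hapB, haps)
  H <- length(haps)
  f <- rep(1 / H, H)
  ll_old <- -Inf; conv <- FALSE; it <- 0L
  mult <- 1 + e$het   # 2 p_a p_b for heterozygous diplotypes
  while (it < max_iter) {
    it <- it + 1L
    pr <- mult * f[ia] * f[ib]
    tot <- rowsum(pr, e$dog)[, 1]
    post <- pr / tot[e$dog]
    ll <- sum(log(tot))
    # M-step: expected haplotype counts over 2n chromosomes
    cnt <- rowsum(c(post, post), c(ia, ib))[, 1]
    f <- as.numeric(cnt) / (2 * n)
    names(f) <- NULL
    if (ll - ll_old < tol && it > 1L) { conv <- TRUE; break }
    ll_old <- ll
  }
  pr <- mult * f[ia] * f[ib]
  tot <- rowsum(pr, e$dog)[, 1]
  post <- pr / tot[e$dog]
  labels <- .hapLabel(haps, k, alleles)
  # posterior-expected copy counts per dog x haplotype
  EC <- matrix(0, n, H, dimnames = list(rownames(G), labels))
  for (j in seq_len(H)) {
    contrib <- post * ((ia == j) + (ib == j))
    s <- rowsum(contrib, e$dog)
    EC[as.integer(rownames(s)), j] <- s[, 1]
  }
  # hard-call (maximum-posterior) diplotype dosages
  MD <- matrix(0L, n, H, dimnames = list(rownames(G), labels))
  ord <- order(e$dog, -post)
  top <- ord[!duplicated(e$dog[ord])]
  for (t in top) {
    MD[e$dog[t], ia[t]] <- MD[e$dog[t], ia[t]] + 1L
    MD[e$dog[t], ib[t]] <- MD[e$dog[t], ib[t]] + 1L
  }
  structure(list(
    haplotypes = labels, freq = stats::setNames(f, labels),
    loglik = sum(log(tot)), iterations = it, converged = conv,
    posterior = data.frame(dog = e$dog, hap1 = labels[ia], hap2 = labels[ib],
                           posterior = post, stringsAsFactors = FALSE),
    expected_counts = EC, map_dosage = MD, n = n, k = k),
    class = "HaplotypeFreqs")
}

#' @export
print.HaplotypeFreqs <- function(x, ...) {
  cat("EM haplotype frequencies (", x$n, "individuals,", x$k, "SNPs,",
      x$iterations, "iterations )\n")
  print(round(sort(x$freq, decreasing = TRUE), 4))
  invisible(x)
}

#' Case-control haplotype score test
#'
#' Global and haplotype-specific score tests of association between
#' EM-inferred haplotypes and a binary trait, built from posterior-expected
#' haplotype counts contrasted between cases and controls (the haplo.score
#' construction). The global statistic is the quadratic form U' V^- U with
#' a generalized inverse; its reference distribution is chi-square with
#' degrees of freedom equal to the rank of V.
#'
#' @param hf a `"HaplotypeFreqs"` fit.
#' @param status binary vector (1 = case) aligned with the genotype rows.
#' @param min_freq haplotypes below this frequency floor are excluded from
#'   testing ("skip") or merged into one rare category ("pool").
#' @param rare floor handling, `"skip"` or `"pool"`.
#' @return `"HaplotypeScoreResult"`: `global_stat`, `global_df`, `global_p`,
#'   and a data.frame `scores` with per-haplotype signed score statistics
#'   and two-sided p-values; haplotypes dropped for degenerate variance are
#'   listed in `dropped`.
#' @export
haploScoreTest <- function(hf, status, min_freq = 0.005,
                           rare = c("skip", "pool")) {
  rare <- match.arg(rare)
  y <- as.numeric(status)
  if (!all(y %in% c(0, 1))) stop("status must be binary 0/1")
  Z <- hf$expected_counts
  if (nrow(Z) != length(y)) stop("status length must match individuals")
  keep <- hf$freq >= min_freq
  if (rare == "pool" && any(!keep)) {
    Z <- cbind(Z[, keep, drop = FALSE],
               rare = rowSums(Z[, !keep, drop = FALSE]))
  } else {
    Z <- Z[, keep, drop = FALSE]
  }
  ybar <- mean(y)
  v <- ybar * (1 - ybar)
  if (v == 0) stop("status is constant")
  Zc <- sweep(Z, 2, colMeans(Z))
  U <- drop(crossprod(Z, y - ybar))
  V <- v * crossprod(Zc)
  dV <- diag(V)
  ok <- dV > 1e-12 * max(dV, 1)
  dropped <- colnames(Z)[!ok]
  U <- U[ok]; V <- V[ok, ok, drop = FALSE]
  eg <- eigen(V, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  Vinv <- eg$vectors[, pos, drop = FALSE] %*%
    ((1 / eg$values[pos]) * t(eg$vectors[, pos, drop = FALSE]))
  gstat <- drop(t(U) %*% Vinv %*% U)
  df <- sum(pos)
  zscore <- U / sqrt(diag(V))
  structure(list(
    global_stat = gstat, global_df = df,
    global_p = stats::pchisq(gstat, df = df, lower.tail = FALSE),
    scores = data.frame(haplotype = names(U), score = zscore,
                        p = 2 * stats::pnorm(-abs(zscore)),
                        freq = colMeans(Z) / 2,
                        stringsAsFactors = FALSE, row.names = NULL),
    dropped = dropped),
    class = "HaplotypeScoreResult")
}

#' @export
print.HaplotypeScoreResult <- function(x, ...) {
  cat(sprintf("Global haplotype score test: stat = %.3f (df = %d), p = %.3g\n",
              x$global_stat, x$global_df, x$global_p))
  print(transform(x$scores, score = round(score, 3), p = signif(p, 3),
                  freq = round(freq, 4)))
  invisible(x)
}

#' Haplotype-dosage penalized risk model
#'
#' Codes inferred haplotypes as per-individual dosages (0-2 copies),
#' collapses haplotypes below a frequency floor into a single rare
#' category, omits a pre-specified reference haplotype to avoid
#' collinearity, and fits a Firth-penalized logistic model with optional
#' covariates. Dosages come from the maximum-posterior diplotype by
#' default; a posterior-weighted (expected-count) coding is available since
#' phase is inferred, not observed.
#'
#' @param hf a `"HaplotypeFreqs"` fit.
#' @param status binary outcome (1 = case).
#' @param covariates optional numeric matrix/data.frame of covariates
#'   (e.g. principal components).
#' @param reference label of the reference haplotype; must be at or above
#'   the floor.
#' @param min_freq frequency floor below which haplotypes are merged into
#'   "rare" (applied before the reference check; ties at the floor kept).
#' @param dosage `"map"` (hard call) or `"expected"` (posterior weighted).
#' @param ... passed to [firthLogistic()].
#' @return A `"riskModelFit"` with one term per non-reference haplotype
#'   (plus covariates).
#' @export
haplotypeDosageModel <- function(hf, status, covariates = NULL,
                                 reference, min_freq = 0.05,
                                 dosage = c("map", "expected"), ...) {
  dosage <- match.arg(dosage)
  D <- if (dosage == "map") hf$map_dosage else hf$expected_counts
  keep <- hf$freq >= min_freq
  if (!reference %in% names(hf$freq)[keep])
    stop("reference haplotype '", reference,
         "' is below the frequency floor or absent")
  Dk <- D[, keep, drop = FALSE]
  if (any(!keep)) {
    rare <- rowSums(D[, !keep, drop = FALSE])
    if (any(rare > 0)) Dk <- cbind(Dk, rare = rare)
  }
  Dk <- Dk[, setdiff(colnames(Dk), reference), drop = FALSE]
  estimable <- apply(Dk, 2, function(col) stats::var(col) > 0)
  if (!any(estimable))
    stop("no estimable haplotype terms: all individuals are homozygous for ",
         "the reference haplotype")
  Dk <- Dk[, estimable, drop = FALSE]
  X <- cbind("(Intercept)" = 1, Dk)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (is.null(colnames(cv))) colnames(cv) <- paste0("cov", seq_len(ncol(cv)))
    X <- cbind(X, cv)
  }
  firthLogistic(X, as.numeric(status), ...)
}
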