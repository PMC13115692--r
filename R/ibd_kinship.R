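# IBD interval-overlap summaries, the tract-length founder-dating
# heuristic, KING-robust pairwise kinship and the carrier-relatedness
# contrast.

#' Inclusive interval overlap rule for IBD segments
#'
#' A segment overlaps the interval iff segment end >= interval start and
#' segment start <= interval end (both ends inclusive; coordinates 1-based).
#'
#' @param seg_start,seg_end segment bounds (bp).
#' @param int_start,int_end interval bounds (bp).
#' @return logical (vectorized over segments).
#' @export
overlapsInterval <- function(seg_start, seg_end, int_start, int_end) {
  seg_end >= int_start & seg_start <= int_end
}

#' Within-class IBD sharing over a focal interval
#'
#' For each unordered within-class haplotype pair, takes the maximum genetic
#' length (cM) among its segments overlapping the interval; summarizes the
#' median over sharing pairs, the proportion of all n(n-1)/2 possible pairs
#' with at least one overlapping segment, and the implied generations to a
#' common ancestor via [tmrcaHeuristic()].
#'
#' @param ibd an [IBDSegmentSet-class].
#' @param class_haps data.frame (or 2-column matrix) of the class members:
#'   columns `dog` and `side`.
#' @param chrom interval chromosome (segments on other chromosomes ignored).
#' @param int_start,int_end interval bounds (bp, inclusive).
#' @return An `"IBDIntervalSummary"`: list with `n_haps`, `n_pairs`,
#'   `n_sharing`, `prop_sharing`, `median_max_cm` (NA when no pair shares),
#'   `g_hat` (50 / median, NA likewise), and `per_pair` data.frame.
#' @export
classIbdSummary <- function(ibd, class_haps, chrom, int_start, int_end) {
  ch <- as.data.frame(class_haps)
  colnames(ch)[1:2] <- c("dog", "side")
  if (nrow(ch) < 2L) stop("class size must be >= 2")
  keys <- paste(ch$dog, ch$side, sep = "\r")
  if (anyDuplicated(keys)) stop("duplicate haplotypes in class")
  n <- nrow(ch)
  s <- ibdSegments(ibd)
  s <- s[s$chrom == chrom &
           overlapsInterval(s$start_bp, s$end_bp, int_start, int_end), ,
         drop = FALSE]
  ka <- paste(s$dog_a, s$side_a, sep = "\r")
  kb <- paste(s$dog_b, s$side_b, sep = "\r")
  inclass <- ka %in% keys & kb %in% keys
  s <- s[inclass, , drop = FALSE]
  pairkey <- paste(ka[inclass], kb[inclass], sep = "\n")
  if (nrow(s)) {
    mx <- tapply(s$length_cm, pairkey, max)
    per_pair <- data.frame(pair = names(mx), max_cm = as.numeric(mx),
                           stringsAsFactors = FALSE, row.names = NULL)
  } else {
    per_pair <- data.frame(pair = character(), max_cm = numeric())
  }
  n_pairs <- n * (n - 1L) / 2L
  n_sharing <- nrow(per_pair)
  med <- if (n_sharing) stats::median(per_pair$max_cm) else NA_real_
  structure(list(n_haps = n, n_pairs = n_pairs, n_sharing = n_sharing,
                 prop_sharing = n_sharing / n_pairs,
                 median_max_cm = med,
                 g_hat = if (is.na(med)) NA_real_ else tmrcaHeuristic(med)$g,
                 per_pair = per_pair),
            class = "IBDIntervalSummary")
}

#' @export
print.IBDIntervalSummary <- function(x, ...) {
  cat(sprintf("IBD interval summary: %d/%d pairs sharing (%.1f%%)\n",
              x$n_sharing, x$n_pairs, 100 * x$prop_sharing))
  if (!is.na(x$median_max_cm))
    cat(sprintf("  median max overlap %.2f cM -> g ~ %.1f generations\n",
                x$median_max_cm, x$g_hat))
  invisible(x)
}

#' Founder-dating heuristic from shared tract length
#'
#' Approximate generations to the common ancestor of a set of chromosomes
#' from the median shared IBD segment length: g ~ 50 / L_cM. A rough guide
#' only — local recombination-rate variation and segment-calling thresholds
#' shift it — reported raw and rounded.
#'
#' @param L_cm median shared segment length in cM (> 0).
#' @return list with `g` (raw) and `g_rounded` (nearest integer).
#' @examples
#' tmrcaHeuristic(4.46)  # ~11 generations
#' @export
tmrcaHeuristic <- function(L_cm) {
  if (any(L_cm <= 0)) stop("tract length must be > 0")
  g <- 50 / L_cm
  list(g = g, g_rounded = round(g))
}

#' KING-robust pairwise kinship from dosage genotypes
#'
#' Moment estimator of pairwise kinship robust to population structure:
#' for dogs i and j,
#' \deqn{\phi_{ij} = (N_{het,het} - 2 N_{opp hom}) / (N_{het,i} + N_{het,j})}
#' with counts over markers non-missing in both. Negative values for
#' between-population pairs are retained (they are informative, not
#' artifacts). Self-comparison under the same (duplicate) formula gives 0.5
#' whenever a dog has at least one heterozygous marker.
#'
#' @param dosage individuals x markers matrix of 0/1/2 genotypes; NA allowed.
#' @param maf_min minimum minor-allele frequency filter.
#' @param miss_max maximum per-marker missing rate.
#' @return A `"KinshipMatrix"`: list with `phi` (symmetric matrix, diagonal
#'   0.5, NA where a pair has no heterozygous markers), `n_markers_used`
#'   (per-pair marker counts), `n_snps` retained after filtering.
#' @export
kingRobust <- function(dosage, maf_min = 0.05, miss_max = 0.05) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  if (n < 2L) stop("need at least 2 individuals")
  missr <- colMeans(is.na(dosage))
  af <- colMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- missr <= miss_max & maf >= maf_min & !is.na(maf)
  d <- dosage[, keep, drop = FALSE]
  m <- ncol(d)
  if (m == 0L) stop("no markers pass the MAF/missingness filters")
  obs <- !is.na(d)
  het <- (d == 1L) & obs
  aa <- (d == 0L) & obs
  bb <- (d == 2L) & obs
  storage.mode(het) <- storage.mode(aa) <- storage.mode(bb) <-
    storage.mode(obs) <- "double"
  Nhh <- tcrossprod(het)                      # both het
  Nopp <- tcrossprod(aa, bb); Nopp <- Nopp + t(Nopp)  # opposite homozygotes
  # per-pair het counts restricted to jointly observed markers
  Nhet_i <- tcrossprod(het, obs)              # [i,j] = het_i over obs_j
  denom <- Nhet_i + t(Nhet_i)
  phi <- (Nhh - 2 * Nopp) / denom
  phi[denom == 0] <- NA_real_
  diag(phi) <- 0.5
  used <- tcrossprod(obs)
  ids <- rownames(dosage) %||% as.character(seq_len(n))
  dimnames(phi) <- dimnames(used) <- list(ids, ids)
  structure(list(phi = phi, n_markers_used = used, n_snps = m),
            class = "KinshipMatrix")
}

#' Carrier-relatedness contrast
#'
#' Assigns every unordered pair of dogs to carrier-carrier,
#' carrier-noncarrier or noncarrier-noncarrier (carrier = dosage >= 1 of
#' the risk allele at the lead marker) and compares the kinship
#' distributions of the carrier-carrier and noncarrier-noncarrier
#' categories with a two-sided Wilcoxon rank-sum test. W is the rank-sum
#' statistic of the carrier-carrier group (first-named); the orientation
#' matters when comparing published W values.
#'
#' @param kin a `"KinshipMatrix"` from [kingRobust()] (or a symmetric
#'   matrix of kinship coefficients).
#' @param carrier logical vector (or 0/1) per dog, aligned with the matrix.
#' @param exact use the exact Wilcoxon distribution (default: only for tiny
#'   samples, as [stats::wilcox.test()] decides; ties force the normal
#'   approximation with tie correction).
#' @return A `"CarrierPairContrast"`: list with `categories` (data.frame of
#'   per-pair category and kinship), `n_by_category`, `medians`, `W`, `p`.
#' @export
carrierPairContrast <- function(kin, carrier, exact = NULL) {
  phi <- if (is.list(kin)) kin$phi else as.matrix(kin)
  n <- nrow(phi)
  carrier <- as.logical(carrier)
  if (length(carrier) != n) stop("carrier flags must align with the matrix")
  ij <- which(upper.tri(phi), arr.ind = TRUE)
  cc <- carrier[ij[, 1]] + carrier[ij[, 2]]
  cat_lab <- c("noncarrier-noncarrier", "carrier-noncarrier",
               "carrier-carrier")[cc + 1L]
  k <- phi[upper.tri(phi)]
  d <- data.frame(category = cat_lab, kinship = k, stringsAsFactors = FALSE)
  d <- d[!is.na(d$kinship), , drop = FALSE]
  x <- d$kinship[d$category == "carrier-carrier"]
  y <- d$kinship[d$category == "noncarrier-noncarrier"]
  if (length(x) < 2L || length(y) < 2L)
    stop("need >= 2 pairs in each contrasted category")
  wt <- if (is.null(exact)) stats::wilcox.test(x, y)
        else stats::wilcox.test(x, y, exact = exact)
  # wilcox.test reports Mann-Whitney U; convert to the rank-sum W of the
  # first-named (carrier-carrier) group
  W <- unname(wt$statistic) + length(x) * (length(x) + 1) / 2
  structure(list(categories = d,
                 n_by_category = table(d$category),
                 medians = tapply(d$kinship, d$category, stats::median),
                 W = W, U = unname(wt$statistic), p = wt$p.value),
            class = "CarrierPairContrast")
}

#' @export
print.CarrierPairContrast <- function(x, ...) {
  cat("Carrier-pair kinship contrast (Wilcoxon rank-sum, two-sided)\n")
  print(x$n_by_category)
  cat(sprintf("  medians: %s\n",
              paste(names(x$medians), signif(x$medians, 3),
                    sep = " = ", collapse = ", ")))
  cat(sprintf("  W = %.0f, p = %.4g\n", x$W, x$p))
  invisible(x)
}
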