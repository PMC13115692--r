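# Focal-allele partitioning and haplotype-sharing statistics: pairwise
# shared tracts around the lead marker, EHH decay, integrated EHH (iES),
# unstandardized cross-class XP-EHH and half-decay spans. All statistics
# are unpolarized: classes are defined purely by the allele carried at the
# focal marker, with no ancestral/derived orientation.

#' Partition phased haplotypes by the allele at the focal marker
#'
#' @param haps a [PhasedHaplotypeSet-class].
#' @param focal a [FocalMarkerSpec-class]; the focal marker must be
#'   polymorphic in the sample.
#' @return An `"AllelePartition"`: list with `risk` and `nonrisk` haplotype
#'   row indices (disjoint, jointly exhaustive), `focal_index`, and
#'   `risk_code` (the 0/1 allele code of the risk allele).
#' @export
partitionByFocalAllele <- function(haps, focal) {
  r <- resolveFocal(markerMapOf(haps), focal)
  col <- haplotypes(haps)[, r$index]
  risk <- which(col == r$riskCode)
  nonrisk <- which(col != r$riskCode)
  if (length(risk) == 0L || length(nonrisk) == 0L)
    stop("focal marker is monomorphic in this sample")
  structure(list(risk = risk, nonrisk = nonrisk, focal_index = r$index,
                 risk_code = r$riskCode), class = "AllelePartition")
}

#' Shared tract length around the focal marker for one haplotype pair
#'
#' Extends from the focal marker leftward and rightward while the two
#' haplotypes carry identical alleles at every marker. The tract boundary
#' is the position of the farthest matching marker (a conservative,
#' marker-supported length); the midpoint between the last match and the
#' first mismatch is available via `boundary = "midpoint"`. Tracts reaching
#' a region edge are truncated at the edge marker and flagged censored.
#'
#' @param h1,h2 0/1 allele vectors over the same markers.
#' @param focal_index column index of the focal marker.
#' @param map the [MarkerMap-class] giving marker positions.
#' @param boundary `"marker"` (default) or `"midpoint"`.
#' @return list with `length_bp`, `length_mb`, `left_pos`, `right_pos`,
#'   `censored_left`, `censored_right`. If the haplotypes differ at the
#'   focal marker itself the length is 0.
#' @export
sharedTractLength <- function(h1, h2, focal_index, map,
                              boundary = c("marker", "midpoint")) {
  boundary <- match.arg(boundary)
  pos <- posBp(map)
  M <- length(pos)
  mism <- which(h1 != h2)
  f <- focal_index
  if (f %in% mism) {
    p <- pos[f]
    return(list(length_bp = 0, length_mb = 0, left_pos = p, right_pos = p,
                censored_left = FALSE, censored_right = FALSE))
  }
  lm <- mism[mism < f]
  rm_ <- mism[mism > f]
  cl <- length(lm) == 0L
  cr <- length(rm_) == 0L
  li <- if (cl) 1L else max(lm) + 1L
  ri <- if (cr) M else min(rm_) - 1L
  lp <- pos[li]; rp <- pos[ri]
  if (boundary == "midpoint") {
    if (!cl) lp <- (pos[li] + pos[li - 1L]) / 2
    if (!cr) rp <- (pos[ri] + pos[ri + 1L]) / 2
  }
  list(length_bp = rp - lp, length_mb = (rp - lp) / 1e6,
       left_pos = lp, right_pos = rp,
       censored_left = cl, censored_right = cr)
}

# All pairwise tract lengths within a set of haplotype rows; returns the
# n x n symmetric matrix of lengths in bp (diagonal NA) plus censor counts.
.pairwiseTracts <- function(a, f, map, boundary = "marker") {
  n <- nrow(a)
  L <- matrix(NA_real_, n, n)
  cens <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    hi <- a[i, ]
    for (j in (i + 1L):n) {
      t <- sharedTractLength(hi, a[j, ], f, map, boundary)
      L[i, j] <- L[j, i] <- t$length_bp
      cens[i, j] <- cens[j, i] <- t$censored_left || t$censored_right
    }
  }
  list(lengths = L, censored = cens)
}

#' Per-haplotype median shared-tract lengths within an allele class
#'
#' For each haplotype in the class, the median of its pairwise shared-tract
#' lengths with every other class member (diagonal excluded), plus panel
#' median and mean. Border-censored tracts are included at their truncated
#' length (the observed-length treatment); the summary with censored pairs
#' excluded is also reported since the appropriate handling depends on how
#' much of the chromosome the region covers.
#'
#' @param haps a [PhasedHaplotypeSet-class].
#' @param hap_indices row indices of the class (size >= 2).
#' @param focal_index focal marker column index.
#' @param class_label optional label stored in the output.
#' @param boundary tract boundary convention, see [sharedTractLength()].
#' @return A `"SharedTractSummary"`: list with `per_hap` (data.frame of
#'   per-haplotype medians in bp and Mb, with censored-pair counts),
#'   `panel_median_mb`, `panel_mean_mb`, `panel_median_uncensored_mb`,
#'   `class_label`, `n`.
#' @export
medianSharedTracts <- function(haps, hap_indices, focal_index,
                               class_label = NA_character_,
                               boundary = "marker") {
  if (length(hap_indices) < 2L) stop("class size must be >= 2")
  a <- haplotypes(haps)[hap_indices, , drop = FALSE]
  pw <- .pairwiseTracts(a, focal_index, markerMapOf(haps), boundary)
  L <- pw$lengths
  med <- apply(L, 1L, stats::median, na.rm = TRUE)
  Lu <- L; Lu[pw$censored] <- NA
  med_u <- apply(Lu, 1L, function(x)
    if (all(is.na(x))) NA_real_ else stats::median(x, na.rm = TRUE))
  per <- data.frame(hap = rownames(a) %||% as.character(hap_indices),
                    median_bp = med, median_mb = med / 1e6,
                    median_uncensored_mb = med_u / 1e6,
                    n_censored_pairs = rowSums(pw$censored) -
                      diag(pw$censored),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(per_hap = per,
                 panel_median_mb = stats::median(per$median_mb),
                 panel_mean_mb = mean(per$median_mb),
                 panel_median_uncensored_mb =
                   stats::median(per$median_uncensored_mb, na.rm = TRUE),
                 class_label = class_label, n = length(hap_indices)),
            class = "SharedTractSummary")
}

#' @export
print.SharedTractSummary <- function(x, ...) {
  cat(sprintf("Shared-tract summary%s: %d haplotypes, panel median %.3f Mb, mean %.3f Mb\n",
              if (is.na(x$class_label)) "" else paste0(" [", x$class_label, "]"),
              x$n, x$panel_median_mb, x$panel_mean_mb))
  invisible(x)
}

#' EHH decay curve for one allele class
#'
#' Extended haplotype homozygosity at marker x is the probability that two
#' haplotypes drawn at random from the class are identical at every marker
#' from the focal marker out to x:
#' \eqn{EHH(x) = \sum_g \binom{n_g}{2} / \binom{n}{2}} over the groups of
#' haplotypes identical on \[focal..x\]. It equals 1 at the focal marker and
#' is non-increasing moving away from it; the two directions are computed
#' independently.
#'
#' @param haps a [PhasedHaplotypeSet-class].
#' @param hap_indices rows of the class (size >= 2).
#' @param focal_index focal marker column index.
#' @return An `"EHHCurve"` data.frame with columns `index`, `pos_bp`,
#'   `offset_mb` (signed physical offset from the focal marker), `ehh`,
#'   `nhaplo` (contributing haplotypes); attribute `focal_pos_bp`.
#' @export
ehhCurve <- function(haps, hap_indices, focal_index) {
  n <- length(hap_indices)
  if (n < 2L) stop("class size must be >= 2")
  a <- haplotypes(haps)[hap_indices, , drop = FALSE]
  pos <- posBp(markerMapOf(haps))
  M <- ncol(a)
  denom <- choose(n, 2)
  ehhFrom <- function(cols) {
    g <- rep.int(1L, n)
    out <- numeric(length(cols))
    for (k in seq_along(cols)) {
      g <- g * 2L + a[, cols[k]]
      g <- match(g, unique(g))   # renumber to keep integers small
      tab <- tabulate(g)
      out[k] <- sum(choose(tab, 2)) / denom
    }
    out
  }
  left_cols <- if (focal_index > 1L) (focal_index - 1L):1L else integer(0)
  right_cols <- if (focal_index < M) (focal_index + 1L):M else integer(0)
  idx <- c(rev(left_cols), focal_index, right_cols)
  ehh <- c(rev(ehhFrom(left_cols)), 1, ehhFrom(right_cols))
  out <- data.frame(index = idx, pos_bp = pos[idx],
                    offset_mb = (pos[idx] - pos[focal_index]) / 1e6,
                    ehh = ehh, nhaplo = n)
  attr(out, "focal_pos_bp") <- pos[focal_index]
  attr(out, "focal_index") <- focal_index
  class(out) <- c("EHHCurve", "data.frame")
  out
}

#' Integrated EHH (iES) for one class
#'
#' Trapezoidal integral of the EHH curve over physical distance (Mb), both
#' sides of the focal marker. When EHH has not fallen below `cutoff` before
#' a region border the integral on that side is truncated at the border and
#' the side is flagged — mirroring border-discard behaviour while still
#' reporting the (conservative, downward-biased) value.
#'
#' @param curve an `"EHHCurve"`.
#' @param cutoff EHH level regarded as fully decayed.
#' @return list with `ies` (Mb units), `border_left_ok`, `border_right_ok`,
#'   `flagged` (TRUE when either side did not decay below `cutoff`).
#' @export
integratedEhh <- function(curve, cutoff = 0.05) {
  x <- curve$offset_mb
  y <- curve$ehh
  trap <- function(xx, yy) {
    if (length(xx) < 2L) return(0)
    sum(diff(xx) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
  }
  left <- x <= 0
  right <- x >= 0
  ies <- trap(rev(-x[left]), rev(y[left])) + trap(x[right], y[right])
  bl <- y[which.min(x)] < cutoff
  br <- y[which.max(x)] < cutoff
  list(ies = ies, border_left_ok = bl, border_right_ok = br,
       flagged = !(bl && br))
}

#' Unstandardized cross-class XP-EHH
#'
#' @param ies_a,ies_b integrated EHH of the two classes (either the value
#'   or the list returned by [integratedEhh()]).
#' @return `log(ies_a / ies_b)`; positive when class a carries the longer
#'   homozygous background. Swapping the classes negates the value.
#' @export
xpehhUnstandardized <- function(ies_a, ies_b) {
  va <- if (is.list(ies_a)) ies_a$ies else ies_a
  vb <- if (is.list(ies_b)) ies_b$ies else ies_b
  if (va <= 0 || vb <= 0) stop("iES must be positive")
  log(va / vb)
}

#' Half-decay span of an EHH curve
#'
#' First position in each direction where EHH drops below `threshold`, with
#' linear interpolation between the flanking markers; the span is the
#' distance between the two crossings. A side where EHH never crosses
#' before the region border is reported as NA (censored).
#'
#' @param curve an `"EHHCurve"`.
#' @param threshold decay threshold (default 0.5).
#' @return list with `left_pos_bp`, `right_pos_bp`, `span_bp`, `span_mb`,
#'   `censored_left`, `censored_right`.
#' @export
halfDecaySpan <- function(curve, threshold = 0.5) {
  cross <- function(df) {
    # df ordered outward from focal: first row has offset 0
    below <- which(df$ehh < threshold)
    if (length(below) == 0L) return(NA_real_)
    i <- below[1L]
    if (i == 1L) return(df$pos_bp[1L])
    x0 <- df$pos_bp[i - 1L]; y0 <- df$ehh[i - 1L]
    x1 <- df$pos_bp[i]; y1 <- df$ehh[i]
    if (y1 == y0) return(x1)
    x0 + (threshold - y0) * (x1 - x0) / (y1 - y0)
  }
  cu <- curve[order(curve$offset_mb), ]
  leftdf <- cu[cu$offset_mb <= 0, ]
  leftdf <- leftdf[rev(seq_len(nrow(leftdf))), ]   # outward from focal
  rightdf <- cu[cu$offset_mb >= 0, ]
  lp <- cross(leftdf)
  rp <- cross(rightdf)
  list(left_pos_bp = lp, right_pos_bp = rp,
       span_bp = rp - lp, span_mb = (rp - lp) / 1e6,
       censored_left = is.na(lp), censored_right = is.na(rp))
}

#' Seeded down-sampling of an allele class
#'
#' Uniform subsample without replacement; the caller's RNG state is left
#' untouched. Identity when `n` equals the class size.
#'
#' @param hap_indices class haplotype row indices.
#' @param n target number of haplotypes (<= class size).
#' @param seed integer seed.
#' @return subset of `hap_indices`.
#' @export
downsampleClass <- function(hap_indices, n, seed) {
  if (n > length(hap_indices)) stop("n exceeds class size")
  if (n == length(hap_indices)) return(hap_indices)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  sort(sample(hap_indices, n))
}
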