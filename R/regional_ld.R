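#' LD profile of a region relative to the lead marker
#'
#' Computes r^2 between every regional marker and the lead marker as the
#' squared Pearson correlation of individual-level dosages (0/1/2), the
#' convention used for regional association colouring. Evaluation is
#' blockwise over marker columns for memory efficiency; the result is
#' identical to direct per-marker correlation.
#'
#' @param dosage matrix of dosages, individuals x markers (column names are
#'   marker ids), or a [PhasedHaplotypeSet-class] (dosages of the alternate
#'   allele are derived per individual).
#' @param lead id (or column index) of the lead marker; must be polymorphic.
#' @param block_size number of marker columns per block.
#' @return An `"LDProfile"` data.frame: `marker`, `r2` (NA for monomorphic
#'   markers), and `bin` (from [ldBins()] with default breakpoints).
#' @export
ldToLead <- function(dosage, lead, block_size = 512L) {
  if (is(dosage, "PhasedHaplotypeSet")) {
    a <- haplotypes(dosage)
    H <- nrow(a)
    dm <- a[seq(1L, H, 2L), , drop = FALSE] + a[seq(2L, H, 2L), , drop = FALSE]
    rownames(dm) <- dogIds(dosage)
    dosage <- dm
  }
  dosage <- as.matrix(dosage)
  if (nrow(dosage) < 2) stop("need at least 2 individuals")
  li <- if (is.character(lead)) match(lead, colnames(dosage)) else as.integer(lead)
  if (is.na(li) || li < 1 || li > ncol(dosage)) stop("lead marker not found")
  x <- dosage[, li]
  if (stats::var(x) == 0) stop("lead marker is monomorphic")
  xc <- x - mean(x)
  ssx <- sum(xc^2)
  M <- ncol(dosage)
  r2 <- rep(NA_real_, M)
  for (start in seq(1L, M, by = block_size)) {
    cols <- start:min(start + block_size - 1L, M)
    B <- dosage[, cols, drop = FALSE]
    Bc <- sweep(B, 2L, colMeans(B))
    ssy <- colSums(Bc^2)
    num <- drop(crossprod(Bc, xc))
    ok <- ssy > 0
    r2[cols[ok]] <- (num[ok]^2) / (ssy[ok] * ssx)
  }
  r2 <- pmin(r2, 1)
  out <- data.frame(marker = colnames(dosage) %||% as.character(seq_len(M)),
                    r2 = r2, stringsAsFactors = FALSE)
  out$bin <- ldBins(out$r2)
  class(out) <- c("LDProfile", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bin r-squared values for regional plotting
#'
#' Half-open bins \[b_i, b_{i+1}) with the top bin closed at its upper end,
#' mirroring conventional regional association plots.
#'
#' @param r2 numeric vector of r^2 values in \[0, 1\] (NA preserved).
#' @param breakpoints increasing breakpoints in \[0, 1\], including both
#'   endpoints.
#' @return factor of bin labels like "\[0.8,1\]".
#' @export
ldBins <- function(r2, breakpoints = c(0, 0.2, 0.4, 0.6, 0.8, 1)) {
  if (is.unsorted(breakpoints, strictly = TRUE) ||
      breakpoints[1] < 0 || breakpoints[length(breakpoints)] > 1)
    stop("breakpoints must be strictly increasing within [0, 1]")
  nb <- length(breakpoints) - 1L
  labels <- c(sprintf("[%g,%g)", breakpoints[-c(nb, nb + 1L)],
                      breakpoints[2:nb]),
              sprintf("[%g,%g]", breakpoints[nb], breakpoints[nb + 1L]))
  idx <- findInterval(r2, breakpoints, rightmost.closed = TRUE)
  factor(labels[idx], levels = labels)
}
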