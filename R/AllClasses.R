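#' @import methods
NULL

#' MarkerMap: ordered SNP markers with physical and genetic coordinates
#'
#' Holds biallelic SNP markers on a single (or several) chromosome(s), with
#' 1-based physical positions and genetic positions in centimorgans. Unless a
#' genetic map is supplied, genetic positions are derived from the linear
#' 1 cM/Mb map (see [linearGeneticMap()]).
#'
#' @slot markerId character vector of marker names.
#' @slot chrom character vector of chromosome labels.
#' @slot posBp integer vector of 1-based physical positions, strictly
#'   increasing within a chromosome.
#' @slot posCm numeric vector of genetic positions (cM).
#' @slot ref,alt single-character nucleotides in \{A,C,G,T\}.
#'
#' @seealso [markerMap()]
#' @export
setClass("MarkerMap",
  representation(markerId = "character", chrom = "character",
                 posBp = "integer", posCm = "numeric",
                 ref = "character", alt = "character"))

setValidity("MarkerMap", function(object) {
  n <- length(object@markerId)
  msgs <- character()
  if (length(object@chrom) != n || length(object@posBp) != n ||
      length(object@posCm) != n || length(object@ref) != n ||
      length(object@alt) != n)
    msgs <- c(msgs, "all slots must have equal length")
  if (anyDuplicated(object@markerId))
    msgs <- c(msgs, "marker ids must be unique")
  if (n > 0) {
    if (any(object@posBp < 0L)) msgs <- c(msgs, "positions must be >= 0")
    for (ch in unique(object@chrom)) {
      p <- object@posBp[object@chrom == ch]
      if (is.unsorted(p, strictly = TRUE))
        msgs <- c(msgs, sprintf(
          "positions must be strictly increasing on chromosome %s", ch))
    }
    bad <- !(object@ref %in% c("A", "C", "G", "T")) |
           !(object@alt %in% c("A", "C", "G", "T"))
    if (any(bad))
      msgs <- c(msgs, sprintf("non-ACGT allele at marker(s): %s",
                              paste(object@markerId[bad], collapse = ", ")))
    if (any(object@ref == object@alt))
      msgs <- c(msgs, "ref and alt alleles must differ")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MarkerMap
#'
#' @param marker_id,chrom,pos_bp,ref,alt per-marker fields; `pos_bp` is
#'   1-based and must be strictly increasing within a chromosome.
#' @param pos_cm genetic positions in cM; defaults to the linear 1 cM/Mb map.
#' @return A [MarkerMap-class] object.
#' @examples
#' markerMap(c("m1", "m2"), "chr3", c(100L, 200L), c("A", "C"), c("G", "T"))
#' @export
markerMap <- function(marker_id, chrom, pos_bp, ref, alt,
                      pos_cm = linearGeneticMap(pos_bp)) {
  new("MarkerMap", markerId = as.character(marker_id),
      chrom = rep_len(as.character(chrom), length(marker_id)),
      posBp = as.integer(pos_bp), posCm = as.numeric(pos_cm),
      ref = toupper(as.character(ref)), alt = toupper(as.character(alt)))
}

#' @describeIn MarkerMap-class number of markers
#' @param x a MarkerMap
#' @export
setMethod("length", "MarkerMap", function(x) length(x@markerId))

#' @describeIn MarkerMap-class subset markers (order-preserving)
#' @param i index vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "MarkerMap", function(x, i, j, ..., drop = FALSE) {
  new("MarkerMap", markerId = x@markerId[i], chrom = x@chrom[i],
      posBp = x@posBp[i], posCm = x@posCm[i], ref = x@ref[i], alt = x@alt[i])
})

setMethod("show", "MarkerMap", function(object) {
  cat("MarkerMap with", length(object), "markers on",
      length(unique(object@chrom)), "chromosome(s)\n")
  if (length(object) > 0)
    cat("  span:", min(object@posBp), "-", max(object@posBp), "bp (",
        sprintf("%.3f", max(object@posCm) - min(object@posCm)), "cM )\n")
})

#' @rdname markerAccessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))
#' @rdname markerAccessors
#' @export
setGeneric("posBp", function(x) standardGeneric("posBp"))
#' @rdname markerAccessors
#' @export
setGeneric("posCm", function(x) standardGeneric("posCm"))
#' @rdname markerAccessors
#' @export
setGeneric("refAllele", function(x) standardGeneric("refAllele"))
#' @rdname markerAccessors
#' @export
setGeneric("altAllele", function(x) standardGeneric("altAllele"))
#' @rdname markerAccessors
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))

#' Accessors for MarkerMap fields
#'
#' @param x a [MarkerMap-class] (or an object carrying one).
#' @name markerAccessors
#' @rdname markerAccessors
#' @export
setMethod("markerIds", "MarkerMap", function(x) x@markerId)
#' @rdname markerAccessors
#' @export
setMethod("posBp", "MarkerMap", function(x) x@posBp)
#' @rdname markerAccessors
#' @export
setMethod("posCm", "MarkerMap", function(x) x@posCm)
#' @rdname markerAccessors
#' @export
setMethod("refAllele", "MarkerMap", function(x) x@ref)
#' @rdname markerAccessors
#' @export
setMethod("altAllele", "MarkerMap", function(x) x@alt)
#' @rdname markerAccessors
#' @export
setMethod("chromName", "MarkerMap", function(x) x@chrom)

#' PhasedHaplotypeSet: phased 0/1 allele matrix tied to a marker map
#'
#' Rows are haplotypes (two consecutive rows per individual: side 1 then
#' side 2, in VCF GT order), columns are markers of the associated
#' [MarkerMap-class]. Entries are 0 (reference allele) or 1 (alternate);
#' missing entries are not representable — the analyses here assume complete
#' phased data.
#'
#' @slot alleles integer H x M matrix of 0/1 codes.
#' @slot dogIds character vector of individual ids (H = 2 * length(dogIds)).
#' @slot map the [MarkerMap-class].
#' @export
setClass("PhasedHaplotypeSet",
  representation(alleles = "matrix", dogIds = "character", map = "MarkerMap"))

setValidity("PhasedHaplotypeSet", function(object) {
  msgs <- character()
  a <- object@alleles
  if (nrow(a) != 2L * length(object@dogIds))
    msgs <- c(msgs, "haplotype count must equal 2 x number of individuals")
  if (ncol(a) != length(object@map))
    msgs <- c(msgs, "column count must equal marker count")
  if (anyNA(a))
    msgs <- c(msgs, "missing allele codes are not allowed (phased, complete data required)")
  else if (!all(a %in% c(0L, 1L)))
    msgs <- c(msgs, "allele codes must be 0 or 1")
  if (anyDuplicated(object@dogIds))
    msgs <- c(msgs, "individual ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PhasedHaplotypeSet
#'
#' @param alleles integer H x M matrix of 0/1 allele codes; rows ordered
#'   (dog1 side1, dog1 side2, dog2 side1, ...).
#' @param dog_ids character vector of individual ids.
#' @param map a [MarkerMap-class] with M markers.
#' @return A [PhasedHaplotypeSet-class].
#' @export
phasedHaplotypeSet <- function(alleles, dog_ids, map) {
  a <- matrix(as.integer(alleles), nrow = nrow(alleles))
  rownames(a) <- paste0(rep(dog_ids, each = 2L), "_", rep(1:2, length(dog_ids)))
  colnames(a) <- markerIds(map)
  new("PhasedHaplotypeSet", alleles = a, dogIds = as.character(dog_ids),
      map = map)
}

#' @rdname hapAccessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' @rdname hapAccessors
#' @export
setGeneric("markerMapOf", function(x) standardGeneric("markerMapOf"))
#' @rdname hapAccessors
#' @export
setGeneric("dogIds", function(x) standardGeneric("dogIds"))
#' @rdname hapAccessors
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))
#' @rdname hapAccessors
#' @export
setGeneric("nDogs", function(x) standardGeneric("nDogs"))
#' @rdname hapAccessors
#' @export
setGeneric("hapDogIds", function(x) standardGeneric("hapDogIds"))
#' @rdname hapAccessors
#' @export
setGeneric("hapSides", function(x) standardGeneric("hapSides"))

#' Accessors for PhasedHaplotypeSet
#'
#' `haplotypes()` returns the H x M 0/1 matrix; `hapDogIds()` / `hapSides()`
#' give the owning individual and chromosome side (1 or 2) of each row.
#'
#' @param x a [PhasedHaplotypeSet-class].
#' @name hapAccessors
#' @rdname hapAccessors
#' @export
setMethod("haplotypes", "PhasedHaplotypeSet", function(x) x@alleles)
#' @rdname hapAccessors
#' @export
setMethod("markerMapOf", "PhasedHaplotypeSet", function(x) x@map)
#' @rdname hapAccessors
#' @export
setMethod("dogIds", "PhasedHaplotypeSet", function(x) x@dogIds)
#' @rdname hapAccessors
#' @export
setMethod("nHaplotypes", "PhasedHaplotypeSet", function(x) nrow(x@alleles))
#' @rdname hapAccessors
#' @export
setMethod("nDogs", "PhasedHaplotypeSet", function(x) length(x@dogIds))
#' @rdname hapAccessors
#' @export
setMethod("hapDogIds", "PhasedHaplotypeSet",
          function(x) rep(x@dogIds, each = 2L))
#' @rdname hapAccessors
#' @export
setMethod("hapSides", "PhasedHaplotypeSet",
          function(x) rep.int(c(1L, 2L), length(x@dogIds)))

setMethod("show", "PhasedHaplotypeSet", function(object) {
  cat("PhasedHaplotypeSet:", nrow(object@alleles), "haplotypes (",
      length(object@dogIds), "individuals ) x", ncol(object@alleles),
      "markers\n")
  show(object@map)
})

#' IBDSegmentSet: pairwise identity-by-descent segments
#'
#' Stores hap-IBD-style segments between haplotype pairs. Pairs are
#' canonically ordered (smaller (dog, side) first) so that an unordered pair
#' has a single representation; multiple segments per pair are allowed.
#'
#' @slot segments data.frame with columns dog_a, side_a, dog_b, side_b,
#'   chrom, start_bp, end_bp, length_cm.
#' @export
setClass("IBDSegmentSet", representation(segments = "data.frame"))

setValidity("IBDSegmentSet", function(object) {
  s <- object@segments
  need <- c("dog_a", "side_a", "dog_b", "side_b", "chrom",
            "start_bp", "end_bp", "length_cm")
  if (!all(need %in% names(s)))
    return(paste("segments must have columns:", paste(need, collapse = ", ")))
  msgs <- character()
  if (any(s$start_bp > s$end_bp)) msgs <- c(msgs, "start_bp must be <= end_bp")
  if (any(s$length_cm < 0)) msgs <- c(msgs, "length_cm must be >= 0")
  key_a <- paste(s$dog_a, s$side_a, sep = "\r")
  key_b <- paste(s$dog_b, s$side_b, sep = "\r")
  if (any(key_a > key_b))
    msgs <- c(msgs, "pairs must be canonically ordered (dog_a, side_a) <= (dog_b, side_b)")
  if (length(msgs)) msgs else TRUE
})

#' Construct an IBDSegmentSet (canonicalizing pair order)
#'
#' @param dog_a,side_a,dog_b,side_b the two haplotypes of each segment
#'   (side in \{1, 2\}).
#' @param chrom,start_bp,end_bp segment interval (1-based, inclusive).
#' @param length_cm genetic length; if `NULL`, recomputed from the linear
#'   1 cM/Mb map as `(end_bp - start_bp) / 1e6`.
#' @return An [IBDSegmentSet-class].
#' @export
ibdSegmentSet <- function(dog_a, side_a, dog_b, side_b, chrom,
                          start_bp, end_bp, length_cm = NULL) {
  if (is.null(length_cm))
    length_cm <- (as.numeric(end_bp) - as.numeric(start_bp)) / 1e6
  s <- data.frame(dog_a = as.character(dog_a), side_a = as.integer(side_a),
                  dog_b = as.character(dog_b), side_b = as.integer(side_b),
                  chrom = as.character(chrom),
                  start_bp = as.numeric(start_bp), end_bp = as.numeric(end_bp),
                  length_cm = as.numeric(length_cm),
                  stringsAsFactors = FALSE)
  key_a <- paste(s$dog_a, s$side_a, sep = "\r")
  key_b <- paste(s$dog_b, s$side_b, sep = "\r")
  swap <- key_a > key_b
  if (any(swap)) {
    tmp_d <- s$dog_a[swap]; tmp_s <- s$side_a[swap]
    s$dog_a[swap] <- s$dog_b[swap]; s$side_a[swap] <- s$side_b[swap]
    s$dog_b[swap] <- tmp_d; s$side_b[swap] <- tmp_s
  }
  new("IBDSegmentSet", segments = s)
}

#' @rdname ibdAccessors
#' @export
setGeneric("ibdSegments", function(x) standardGeneric("ibdSegments"))

#' Accessor for IBD segment records
#' @param x an [IBDSegmentSet-class].
#' @return data.frame of segments.
#' @name ibdAccessors
#' @rdname ibdAccessors
#' @export
setMethod("ibdSegments", "IBDSegmentSet", function(x) x@segments)

setMethod("length", "IBDSegmentSet", function(x) nrow(x@segments))

setMethod("show", "IBDSegmentSet", function(object) {
  cat("IBDSegmentSet with", nrow(object@segments), "segments\n")
  if (nrow(object@segments))
    cat("  median length:",
        sprintf("%.3f cM", stats::median(object@segments$length_cm)), "\n")
})

#' FocalMarkerSpec: the lead risk marker and its summary interval
#'
#' @slot markerId id of the focal (lead) marker.
#' @slot riskAllele single-character risk allele (must match the marker's ref
#'   or alt allele when resolved against a map).
#' @slot intervalStartBp,intervalEndBp 1-based inclusive bounds of the
#'   association summary interval containing the marker.
#' @export
setClass("FocalMarkerSpec",
  representation(markerId = "character", riskAllele = "character",
                 intervalStartBp = "numeric", intervalEndBp = "numeric"))

setValidity("FocalMarkerSpec", function(object) {
  msgs <- character()
  if (length(object@markerId) != 1L) msgs <- c(msgs, "one marker id required")
  if (!object@riskAllele %in% c("A", "C", "G", "T"))
    msgs <- c(msgs, "risk allele must be one of A, C, G, T")
  if (object@intervalStartBp > object@intervalEndBp)
    msgs <- c(msgs, "interval start must be <= end")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FocalMarkerSpec
#'
#' @param marker_id focal marker id.
#' @param risk_allele single-character risk allele.
#' @param interval_start_bp,interval_end_bp summary interval (1-based,
#'   inclusive); defaults give a degenerate interval resolved later.
#' @return A [FocalMarkerSpec-class].
#' @export
focalMarker <- function(marker_id, risk_allele,
                        interval_start_bp = -Inf, interval_end_bp = Inf) {
  new("FocalMarkerSpec", markerId = as.character(marker_id),
      riskAllele = toupper(as.character(risk_allele)),
      intervalStartBp = as.numeric(interval_start_bp),
      intervalEndBp = as.numeric(interval_end_bp))
}

# Resolve a focal spec against a map: column index and the 0/1 code of the
# risk allele. Internal; errors name the offending marker.
resolveFocal <- function(map, focal) {
  idx <- match(focal@markerId, markerIds(map))
  if (is.na(idx))
    stop("focal marker '", focal@markerId, "' not present in the marker map")
  ra <- focal@riskAllele
  code <- if (ra == altAllele(map)[idx]) 1L
          else if (ra == refAllele(map)[idx]) 0L
          else stop("risk allele '", ra, "' matches neither ref ('",
                    refAllele(map)[idx], "') nor alt ('", altAllele(map)[idx],
                    "') at marker '", focal@markerId, "'")
  pos <- posBp(map)[idx]
  if (is.finite(focal@intervalStartBp) &&
      (pos < focal@intervalStartBp || pos > focal@intervalEndBp))
    stop("summary interval does not contain the focal marker")
  list(index = idx, riskCode = code, posBp = pos)
}
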