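#' Linear genetic map: physical position to centimorgans
#'
#' Converts a physical position to genetic distance under the linear
#' 1 cM/Mb map used throughout the package (cM = bp / 1e6).
#'
#' @param position_bp non-negative physical position(s) in bp.
#' @return Genetic position(s) in cM.
#' @examples
#' linearGeneticMap(1e6)        # 1 cM
#' linearGeneticMap(88803651)   # 88.803651 cM
#' @export
linearGeneticMap <- function(position_bp) {
  if (any(position_bp < 0)) stop("physical positions must be >= 0")
  as.numeric(position_bp) / 1e6
}

#' Read a phased VCF into a haplotype matrix
#'
#' Parses a VCF 4.2 file of biallelic A/C/G/T SNPs with phased GT fields
#' ("0|1" style) into a [MarkerMap-class] and [PhasedHaplotypeSet-class].
#' Unphased or missing genotypes, multiallelic sites and non-ACGT allele
#' codes are rejected with the offending site named: all downstream
#' haplotype statistics are undefined under missingness, so incomplete
#' input is an error, not a warning.
#'
#' @param path path to an (optionally gzipped) VCF file.
#' @return list with elements `map` ([MarkerMap-class]) and
#'   `haps` ([PhasedHaplotypeSet-class]).
#' @seealso [writePhasedVcf()] for the inverse.
#' @export
readPhasedVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  ref <- toupper(fix[, "REF"]); alt <- toupper(fix[, "ALT"])
  bad <- is.na(alt) | nchar(ref) != 1L | nchar(alt) != 1L |
    !(ref %in% c("A", "C", "G", "T")) | !(alt %in% c("A", "C", "G", "T"))
  if (any(bad))
    stop("non-biallelic-SNP or non-ACGT site(s): ",
         paste(ids[bad], collapse = ", "))
  map <- markerMap(ids, fix[, "CHROM"], as.integer(fix[, "POS"]), ref, alt)

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  ok <- grepl("^[01]\\|[01]$", gt)
  if (!all(ok)) {
    badsite <- ids[(which(!ok) - 1L) %% nrow(gt) + 1L]
    stop("unphased, missing or non-biallelic GT at site(s): ",
         paste(unique(badsite), collapse = ", "))
  }
  samples <- colnames(gt)
  H <- 2L * length(samples); M <- nrow(gt)
  a <- matrix(0L, nrow = H, ncol = M)
  a[seq(1L, H, by = 2L), ] <- t(substr(gt, 1L, 1L) == "1")
  a[seq(2L, H, by = 2L), ] <- t(substr(gt, 3L, 3L) == "1")
  list(map = map, haps = phasedHaplotypeSet(a, samples, map))
}

#' Write a PhasedHaplotypeSet as a phased VCF
#'
#' Emits a minimal VCF 4.2 file with phased GT fields that round-trips
#' through [readPhasedVcf()].
#'
#' @param haps a [PhasedHaplotypeSet-class].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
writePhasedVcf <- function(haps, path) {
  map <- markerMapOf(haps)
  a <- haplotypes(haps)
  H <- nrow(a)
  g1 <- t(a[seq(1L, H, by = 2L), , drop = FALSE])   # M x nDogs
  g2 <- t(a[seq(2L, H, by = 2L), , drop = FALSE])
  gt <- matrix(paste0(g1, "|", g2), nrow = nrow(g1))
  header <- c("##fileformat=VCFv4.2",
              "##source=riskhapscan",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", dogIds(haps)), collapse = "\t"))
  body <- paste(chromName(map), posBp(map), markerIds(map), refAllele(map),
                altAllele(map), ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Risk-allele dosage per individual at the focal marker
#'
#' Counts copies (0, 1 or 2) of the risk allele carried by each individual
#' over its two phased haplotypes.
#'
#' @param haps a [PhasedHaplotypeSet-class].
#' @param focal a [FocalMarkerSpec-class]; the marker must be in the map and
#'   the risk allele must match its ref or alt allele.
#' @return Named integer vector of dosages (one per individual).
#' @export
dosageAt <- function(haps, focal) {
  r <- resolveFocal(markerMapOf(haps), focal)
  col <- haplotypes(haps)[, r$index]
  carr <- if (r$riskCode == 1L) col else 1L - col
  H <- length(carr)
  d <- carr[seq(1L, H, by = 2L)] + carr[seq(2L, H, by = 2L)]
  names(d) <- dogIds(haps)
  d
}

#' Read hap-IBD-style segment output
#'
#' Parses the 8-column hap-IBD TSV dialect (sample1, hap-index1, sample2,
#' hap-index2, chromosome, start, end, length-cM) into an
#' [IBDSegmentSet-class], canonicalizing pair order. When the length column
#' is absent or empty it is recomputed from the linear 1 cM/Mb map.
#'
#' @param path path to the TSV (no header expected; a header line starting
#'   with non-numeric start/end is tolerated and skipped).
#' @return An [IBDSegmentSet-class].
#' @export
readIbdSegments <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(ibdSegmentSet(character(), integer(), character(), integer(),
                         character(), numeric(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  first <- fields[[1]]
  skip <- length(first) >= 7 && (is.na(suppressWarnings(as.numeric(first[6]))))
  start_i <- if (skip) 2L else 1L
  recs <- vector("list", length(lines) - start_i + 1L)
  for (i in seq(start_i, length(lines))) {
    f <- fields[[i]]
    if (!(length(f) %in% c(7L, 8L)))
      stop("malformed IBD record at line ", i, ": expected 7 or 8 fields, got ",
           length(f))
    s <- suppressWarnings(as.numeric(f[6])); e <- suppressWarnings(as.numeric(f[7]))
    h1 <- suppressWarnings(as.integer(f[2])); h2 <- suppressWarnings(as.integer(f[4]))
    if (anyNA(c(s, e, h1, h2)))
      stop("malformed IBD record at line ", i, ": non-numeric field")
    len <- if (length(f) == 8L && nzchar(f[8]))
      suppressWarnings(as.numeric(f[8])) else NA_real_
    recs[[i - start_i + 1L]] <- list(f[1], h1, f[3], h2, f[5], s, e, len)
  }
  m <- do.call(rbind, lapply(recs, function(r) {
    data.frame(dog_a = r[[1]], side_a = r[[2]], dog_b = r[[3]], side_b = r[[4]],
               chrom = r[[5]], start_bp = r[[6]], end_bp = r[[7]],
               length_cm = r[[8]], stringsAsFactors = FALSE)
  }))
  miss <- is.na(m$length_cm)
  m$length_cm[miss] <- (m$end_bp[miss] - m$start_bp[miss]) / 1e6
  ibdSegmentSet(m$dog_a, m$side_a, m$dog_b, m$side_b, m$chrom,
                m$start_bp, m$end_bp, m$length_cm)
}

#' Write an IBDSegmentSet in the hap-IBD TSV dialect
#'
#' @param ibd an [IBDSegmentSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeIbdSegments <- function(ibd, path) {
  s <- ibdSegments(ibd)
  lines <- sprintf("%s\t%d\t%s\t%d\t%s\t%.0f\t%.0f\t%.6f",
                   s$dog_a, s$side_a, s$dog_b, s$side_b, s$chrom,
                   s$start_bp, s$end_bp, s$length_cm)
  writeLines(lines, path)
  invisible(path)
}

.lineageGroups <- c(show = "ShowPet", pet = "ShowPet", `sled-show` = "ShowPet",
                    `husky-mix` = "ShowPet", racing = "Working",
                    seppala = "Working")

#' Map owner-reported lineage to its broad lineage group
#'
#' Pet, show, sled-show and husky-mix dogs form the ShowPet group; racing and
#' seppala dogs form the Working group.
#'
#' @param lineage character vector of lineage labels.
#' @return character vector of "ShowPet"/"Working".
#' @export
lineageGroup <- function(lineage) {
  g <- .lineageGroups[tolower(as.character(lineage))]
  if (anyNA(g))
    stop("unknown lineage label(s): ",
         paste(unique(lineage[is.na(g)]), collapse = ", "))
  unname(g)
}

#' Validate (and derive fields of) a cohort phenotype table
#'
#' Ensures the per-individual phenotype/covariate table satisfies the cohort
#' data model: case/control status, sex, lineage (with derived
#' `lineage_group`), cohort label, onset and follow-up ages, and gonadectomy
#' information. Controls must not have an onset age; cases with an onset must
#' have onset <= last follow-up.
#'
#' @param df data.frame with at least columns `dog_id`, `status`, `sex`,
#'   `lineage`; optional `cohort_label`, `age_onset_years`,
#'   `age_last_followup_years`, `age_gonadectomy_years`, `gonadal_status`,
#'   and arbitrary numeric covariate columns (e.g. PC1..PC5).
#' @return The validated data.frame with `lineage_group` derived, classed
#'   `"CohortTable"`.
#' @export
cohortTable <- function(df) {
  need <- c("dog_id", "status", "sex", "lineage")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  df$dog_id <- as.character(df$dog_id)
  if (anyDuplicated(df$dog_id)) stop("duplicate dog_id values")
  df$status <- tolower(as.character(df$status))
  if (!all(df$status %in% c("case", "control")))
    stop("status must be 'case' or 'control'")
  df$sex <- toupper(as.character(df$sex))
  if (!all(df$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  df$lineage_group <- lineageGroup(df$lineage)
  if (is.null(df$cohort_label)) df$cohort_label <- "GWAS"
  for (col in c("age_onset_years", "age_last_followup_years",
                "age_gonadectomy_years"))
    if (!is.null(df[[col]])) df[[col]] <- as.numeric(df[[col]])
  if (!is.null(df$age_onset_years)) {
    ctrl_onset <- df$status == "control" & !is.na(df$age_onset_years)
    if (any(ctrl_onset))
      stop("control(s) with an onset age: ",
           paste(df$dog_id[ctrl_onset], collapse = ", "))
    if (!is.null(df$age_last_followup_years)) {
      bad <- df$status == "case" & !is.na(df$age_onset_years) &
        !is.na(df$age_last_followup_years) &
        df$age_onset_years > df$age_last_followup_years
      if (any(bad))
        stop("case(s) with onset after last follow-up: ",
             paste(df$dog_id[bad], collapse = ", "))
    }
  }
  if (!is.null(df$gonadal_status)) {
    df$gonadal_status <- tolower(as.character(df$gonadal_status))
    if (!all(df$gonadal_status %in% c("intact", "gonadectomized")))
      stop("gonadal_status must be 'intact' or 'gonadectomized'")
  }
  class(df) <- c("CohortTable", "data.frame")
  df
}

#' Read a phenotype/covariate table
#'
#' Reads a tab- or comma-delimited text file with a header naming the cohort
#' fields and validates it via [cohortTable()].
#'
#' @param path path to the delimited file (separator auto-detected from the
#'   header line).
#' @return A validated cohort data.frame.
#' @export
readPhenotypes <- function(path) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  cohortTable(df)
}

#' Write a phenotype table
#'
#' @param cohort a cohort data.frame (see [cohortTable()]).
#' @param path output path; written tab-delimited.
#' @return `path`, invisibly.
#' @export
writePhenotypes <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
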