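# Forward Wright-Fisher simulator: a single founder chromosome carrying the
# risk allele expands over g generations under recombination and a
# fecundity advantage (emulating popular-sire amplification), in two
# partially isolated lineages. Phenotypes follow a dosage-penetrance
# logistic model with sex and time-varying gonadectomy modifiers of onset.
# The simulator records the truth (founder-descent tracts per haplotype) so
# every downstream statistic can be checked against known ancestry.

#' Simulation configuration
#'
#' Validated parameter set for [simulateHaplotypes()] /
#' [simulatePhenotypes()]. Defaults emulate the study conditions this
#' package targets: a two-lineage Siberian-Husky-like cohort of ~200
#' sampled dogs, a rare risk allele introduced on one founder chromosome
#' 11 generations ago on a 1 cM/Mb linear map, array-like marker density,
#' dosage-dependent penetrance (dogs at dosage 0/1/2 are cases with
#' probability ~0.18 / ~0.61 / ~0.92, the ascertained-cohort pattern), and
#' sex/gonadectomy modifiers of onset age.
#'
#' @param seed integer seed (mandatory; all randomness derives from it).
#' @param n_markers number of SNP markers in the region.
#' @param region_start_bp,region_span_bp simulated region (default
#'   chr3-like 80-94 Mb).
#' @param focal_bp position at which the focal risk marker is placed.
#' @param recomb_rate_cM_per_Mb recombination rate of the linear map.
#' @param g_generations generations of Wright-Fisher propagation.
#' @param pop_size named vector: breeding dogs per lineage per generation.
#' @param n_dogs named vector: dogs sampled into the cohort per lineage.
#' @param migration_rate per-parent probability of drawing a parent from
#'   the other lineage.
#' @param founder_risk_copies identical copies of the founder haplotype
#'   seeded in generation 0 (ShowPet lineage); the copies are clones, so
#'   the haplotype's common ancestor sits exactly `g_generations` back.
#' @param risk_fitness relative parent-sampling weight per risk-allele
#'   copy; > 1 makes the founder haplotype expand further (popular-sire
#'   style amplification). The defaults grow ~19 generation-0 copies to
#'   around 40 population haplotypes over 11 generations, giving on the
#'   order of 19 carrier chromosomes in the sampled cohort.
#' @param base_alt_shape1,base_alt_shape2 Beta parameters for background
#'   alternate-allele frequencies.
#' @param baseline_log_odds,per_allele_log_OR penetrance model:
#'   P(case) = logistic(baseline + beta * dosage).
#' @param male_log_HR,gonadectomy_log_HR,landmark_years onset modifiers:
#'   log hazard ratios for male sex and for gonadectomy before the
#'   landmark age (time-varying, switching at the gonadectomy age).
#' @param weibull_shape,weibull_scale baseline (intact female) Weibull
#'   onset hazard; defaults give a median onset near 3.9 years for intact
#'   females and ~2.4 for males.
#' @param onset_min,onset_max onset ages are drawn from the hazard model
#'   truncated to this window (years).
#' @param control_min_age minimum last-follow-up age for controls.
#' @param followup_max maximum follow-up age.
#' @param male_prob,gdx_prob probability of male sex / of gonadectomy.
#' @param gdx_age_min,gdx_age_max gonadectomy ages are uniform on this
#'   range, independent of genotype.
#' @param gdx_confound_log_or log-OR shift of gonadectomy probability for
#'   cases (0 = no confounding, the default, so modifier effects can be
#'   recovered cleanly; set non-zero for explicit confounding experiments).
#' @param min_ibd_cm minimum emitted true-IBD segment length (cM).
#' @param max_retries bounded retries (with derived seeds) when the risk
#'   allele is lost by drift.
#' @return A validated `"SimulationConfig"` list.
#' @export
simulationConfig <- function(seed,
                             n_markers = 1000L,
                             region_start_bp = 80e6,
                             region_span_bp = 14e6,
                             focal_bp = 88803651,
                             recomb_rate_cM_per_Mb = 1.0,
                             g_generations = 11L,
                             pop_size = c(ShowPet = 200L, Working = 200L),
                             n_dogs = c(ShowPet = 100L, Working = 100L),
                             migration_rate = 0.01,
                             founder_risk_copies = 19L,
                             risk_fitness = 1.07,
                             base_alt_shape1 = 2, base_alt_shape2 = 2,
                             baseline_log_odds = -1.52,
                             per_allele_log_OR = 1.9,
                             male_log_HR = log(3.1),
                             gonadectomy_log_HR = log(2.7),
                             landmark_years = 5,
                             weibull_shape = 2, weibull_scale = 4.7,
                             onset_min = 0.5, onset_max = 9,
                             control_min_age = 7.5, followup_max = 14,
                             male_prob = 0.55, gdx_prob = 0.6,
                             gdx_age_min = 0.5, gdx_age_max = 8,
                             gdx_confound_log_or = 0,
                             min_ibd_cm = 0.5,
                             max_retries = 25L) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_markers >= 2, region_span_bp > 0,
              recomb_rate_cM_per_Mb >= 0, g_generations >= 0,
              all(pop_size >= 2), all(n_dogs >= 1),
              all(n_dogs <= pop_size),
              migration_rate >= 0, migration_rate <= 1,
              founder_risk_copies >= 1, risk_fitness > 0,
              landmark_years > 0, weibull_shape > 0, weibull_scale > 0,
              onset_min > 0, onset_max > onset_min,
              control_min_age > 0, followup_max > control_min_age,
              male_prob >= 0, male_prob <= 1, gdx_prob >= 0, gdx_prob <= 1,
              gdx_age_max > gdx_age_min, min_ibd_cm >= 0, max_retries >= 1)
    stopifnot(focal_bp > region_start_bp,
              focal_bp < region_start_bp + region_span_bp)
  })
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "SimulationConfig")
}

# one meiosis: recombine the parent's two haplotypes (and descent masks)
.meiosis <- function(a1, a2, d1, d2, pos, lambda, span_start, span_end) {
  k <- stats::rpois(1L, lambda)
  first <- stats::runif(1) < 0.5
  if (k == 0L) {
    if (first) return(list(a = a1, d = d1)) else return(list(a = a2, d = d2))
  }
  bp <- sort(stats::runif(k, span_start, span_end))
  seg <- findInterval(pos, bp)                 # 0..k
  fromA <- (seg %% 2L == 0L) == first
  list(a = ifelse(fromA, a1, a2), d = ifelse(fromA, d1, d2))
}

#' Simulate phased haplotypes under a founder-haplotype expansion
#'
#' Diploid Wright-Fisher propagation with non-overlapping generations,
#' random mating within lineage (parents drawn from the other lineage with
#' probability `migration_rate`), per-meiosis crossover counts Poisson with
#' mean `recomb_rate * span`, and a fecundity weight `risk_fitness^dosage`
#' that lets the founder haplotype expand. Generation 0 carries background
#' alleles at Beta-distributed frequencies; the focal marker is monomorphic
#' reference except on the founder chromosome(s). If the risk allele is
#' lost by drift the run is retried (bounded, derived seeds) and the number
#' of attempts reported.
#'
#' @param config a [simulationConfig()].
#' @return list with `map` ([MarkerMap-class]), `haps`
#'   ([PhasedHaplotypeSet-class] of the sampled cohort), and `truth`: list
#'   with `descent` (data.frame dog, side, start_bp, end_bp of
#'   founder-descent tracts), `carrier` (per-dog logical), `lineage`
#'   (per-dog), `focal_index`, `focal_id`, `risk_allele`,
#'   `n_carrier_haps`, `attempts`, `config`.
#' @export
simulateHaplotypes <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  for (attempt in seq_len(config$max_retries)) {
    set.seed(config$seed + attempt - 1L)
    res <- .simOnce(config)
    if (!is.null(res)) {
      res$truth$attempts <- attempt
      if (attempt > 1L)
        message("risk allele lost by drift; succeeded on attempt ", attempt)
      return(res)
    }
  }
  stop("risk allele lost by drift in all ", config$max_retries, " attempts")
}

.simOnce <- function(cfg) {
  start <- cfg$region_start_bp
  end <- start + cfg$region_span_bp
  pos <- sort(unique(c(round(stats::runif(cfg$n_markers - 1L, start + 1, end - 1)),
                       cfg$focal_bp)))
  while (length(pos) < cfg$n_markers)
    pos <- sort(unique(c(pos, round(stats::runif(cfg$n_markers - length(pos),
                                                 start + 1, end - 1)))))
  M <- length(pos)
  fidx <- match(cfg$focal_bp, pos)
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, M, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), "")
  map <- markerMap(sprintf("snp%05d", seq_len(M)), "chr3", pos, ref, alt)

  lineages <- names(cfg$pop_size)
  Npop <- as.integer(cfg$pop_size)
  names(Npop) <- lineages
  Htot <- 2L * sum(Npop)
  p_alt <- stats::rbeta(M, cfg$base_alt_shape1, cfg$base_alt_shape2)
  p_alt[fidx] <- 0
  A <- matrix(stats::rbinom(Htot * M, 1L, rep(p_alt, each = Htot)),
              nrow = Htot, ncol = M)
  D <- matrix(FALSE, Htot, M)
  lin_of_dog <- rep(lineages, times = Npop)
  # founder haplotype: first chromosome of the first ShowPet dog, replicated
  sp_first_hap <- 2L * (match("ShowPet", lin_of_dog) - 1L) + 1L
  founder <- A[sp_first_hap, ]
  founder[fidx] <- 1L
  for (cpy in seq_len(cfg$founder_risk_copies)) {
    row <- sp_first_hap + 2L * (cpy - 1L)     # one copy per dog
    A[row, ] <- founder
    D[row, ] <- TRUE
  }

  lambda <- cfg$recomb_rate_cM_per_Mb * (cfg$region_span_bp / 1e6) / 100
  dog_lin <- lin_of_dog
  for (gen in seq_len(cfg$g_generations)) {
    dose <- A[seq(1L, Htot, 2L), fidx] + A[seq(2L, Htot, 2L), fidx]
    w <- cfg$risk_fitness^dose
    A2 <- matrix(0L, Htot, M)
    D2 <- matrix(FALSE, Htot, M)
    child <- 0L
    for (l in lineages) {
      idx_l <- which(dog_lin == l)
      idx_o <- which(dog_lin != l)
      for (ch in seq_len(Npop[[l]])) {
        child <- child + 1L
        for (side in 1:2) {
          pool <- if (length(idx_o) &&
                      stats::runif(1) < cfg$migration_rate) idx_o else idx_l
          par <- pool[sample.int(length(pool), 1L, prob = w[pool])]
          r1 <- 2L * par - 1L
          gam <- .meiosis(A[r1, ], A[r1 + 1L, ], D[r1, ], D[r1 + 1L, ],
                          pos, lambda, start, end)
          row <- 2L * (child - 1L) + side
          A2[row, ] <- gam$a
          D2[row, ] <- gam$d
        }
      }
    }
    A <- A2; D <- D2
    if (sum(A[, fidx]) == 0L) return(NULL)    # lost: caller retries
  }

  # sample the cohort
  samp <- unlist(lapply(lineages, function(l) {
    idx <- which(dog_lin == l)
    sort(sample(idx, cfg$n_dogs[[l]]))
  }))
  rows <- as.vector(rbind(2L * samp - 1L, 2L * samp))
  As <- A[rows, , drop = FALSE]
  Ds <- D[rows, , drop = FALSE]
  if (sum(As[, fidx]) == 0L) return(NULL)     # lost from the sample
  n_s <- length(samp)
  ids <- sprintf("%s%03d", c(ShowPet = "SP", Working = "WK")[dog_lin[samp]],
                 seq_len(n_s))
  haps <- phasedHaplotypeSet(As, ids, map)
  descent <- .maskToTracts(Ds, pos, ids)
  dose_s <- As[seq(1L, 2L * n_s, 2L), fidx] + As[seq(2L, 2L * n_s, 2L), fidx]
  truth <- list(descent = descent,
                carrier = stats::setNames(dose_s >= 1L, ids),
                lineage = stats::setNames(dog_lin[samp], ids),
                focal_index = fidx,
                focal_id = markerIds(map)[fidx],
                risk_allele = altAllele(map)[fidx],
                n_carrier_haps = sum(As[, fidx]),
                config = cfg)
  list(map = map, haps = haps, truth = truth)
}

# runs of TRUE in the descent mask -> bp intervals at marker positions
.maskToTracts <- function(Dmat, pos, ids) {
  out <- list()
  H <- nrow(Dmat)
  for (h in seq_len(H)) {
    r <- rle(Dmat[h, ])
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- which(r$values)
    out[[length(out) + 1L]] <- data.frame(
      dog = ids[ceiling(h / 2)], side = 2L - h %% 2L,
      start_bp = pos[starts[k]], end_bp = pos[ends[k]])
  }
  if (!length(out))
    return(data.frame(dog = character(), side = integer(),
                      start_bp = numeric(), end_bp = numeric()))
  do.call(rbind, out)
}

#' True IBD segments from founder-descent tracts
#'
#' Pairwise intersections of founder-descent tracts between all haplotype
#' pairs, in the hap-IBD dialect; segments shorter than `min_cm` on the
#' linear map are dropped (matching the minimum reported segment length of
#' typical IBD callers).
#'
#' @param truth the `truth` element of [simulateHaplotypes()] output.
#' @param min_cm minimum segment length (defaults to the config value).
#' @return An [IBDSegmentSet-class].
#' @export
trueIbdSegments <- function(truth, min_cm = truth$config$min_ibd_cm) {
  d <- truth$descent
  if (nrow(d) < 2L)
    return(ibdSegmentSet(character(), integer(), character(), integer(),
                         character(), numeric(), numeric()))
  recs <- list()
  key <- paste(d$dog, d$side)
  haps <- unique(key)
  for (i in seq_len(length(haps) - 1L)) {
    ti <- d[key == haps[i], , drop = FALSE]
    for (j in (i + 1L):length(haps)) {
      tj <- d[key == haps[j], , drop = FALSE]
      for (a in seq_len(nrow(ti))) for (b in seq_len(nrow(tj))) {
        s <- max(ti$start_bp[a], tj$start_bp[b])
        e <- min(ti$end_bp[a], tj$end_bp[b])
        if (e > s && (e - s) / 1e6 >= min_cm)
          recs[[length(recs) + 1L]] <-
            data.frame(dog_a = ti$dog[1], side_a = ti$side[1],
                       dog_b = tj$dog[1], side_b = tj$side[1],
                       start_bp = s, end_bp = e)
      }
    }
  }
  if (!length(recs))
    return(ibdSegmentSet(character(), integer(), character(), integer(),
                         character(), numeric(), numeric()))
  r <- do.call(rbind, recs)
  ibdSegmentSet(r$dog_a, r$side_a, r$dog_b, r$side_b, "chr3",
                r$start_bp, r$end_bp)
}

#' Simulate phenotypes with dosage-dependent penetrance and onset modifiers
#'
#' Case status is Bernoulli with
#' P(case) = logistic(baseline_log_odds + per_allele_log_OR * dosage).
#' Cases draw an onset age from a Weibull proportional-hazards model with a
#' male effect and a time-varying gonadectomy effect (hazard multiplied by
#' exp(gonadectomy_log_HR) after the gonadectomy age, for gonadectomies
#' before the landmark), truncated to the plausible onset window. Controls
#' receive a last-follow-up age of at least `control_min_age`. Gonadectomy
#' ages are assigned independently of genotype.
#'
#' @param haps a [PhasedHaplotypeSet-class].
#' @param truth truth list from [simulateHaplotypes()] (used for lineage
#'   labels and the focal marker), or `NULL` when `focal` is given.
#' @param config a [simulationConfig()].
#' @param focal optional [FocalMarkerSpec-class] overriding the truth focal.
#' @return A validated cohort data.frame (see [cohortTable()]).
#' @export
simulatePhenotypes <- function(haps, truth, config, focal = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 100000L)
  if (is.null(focal))
    focal <- focalMarker(truth$focal_id, truth$risk_allele)
  dose <- dosageAt(haps, focal)
  n <- nDogs(haps)
  ids <- dogIds(haps)
  sex <- ifelse(stats::runif(n) < config$male_prob, "M", "F")
  p_case <- stats::plogis(config$baseline_log_odds +
                          config$per_allele_log_OR * dose)
  is_case <- stats::runif(n) < p_case
  p_gdx <- stats::plogis(stats::qlogis(config$gdx_prob) +
                         config$gdx_confound_log_or * is_case)
  gdx <- stats::runif(n) < p_gdx
  gdx_age <- ifelse(gdx, stats::runif(n, config$gdx_age_min,
                                      config$gdx_age_max), NA_real_)
  onset <- rep(NA_real_, n)
  for (i in which(is_case))
    onset[i] <- .drawOnset(sex[i] == "M", gdx_age[i], config)
  followup <- ifelse(is_case,
                     pmin(onset + stats::runif(n, 0, 4), config$followup_max),
                     stats::runif(n, config$control_min_age,
                                  config$followup_max))
  lin <- if (!is.null(truth)) truth$lineage[ids]
         else rep("ShowPet", n)
  lineage <- ifelse(lin == "ShowPet",
                    ifelse(stats::runif(n) < 0.5, "show", "pet"),
                    ifelse(stats::runif(n) < 0.8, "racing", "seppala"))
  cohortTable(data.frame(
    dog_id = ids,
    status = ifelse(is_case, "case", "control"),
    sex = sex, lineage = lineage, cohort_label = "GWAS",
    age_onset_years = onset,
    age_last_followup_years = followup,
    age_gonadectomy_years = gdx_age,
    gonadal_status = ifelse(gdx, "gonadectomized", "intact"),
    stringsAsFactors = FALSE))
}

# inverse-CDF draw from the truncated piecewise-Weibull PH onset model
.drawOnset <- function(male, gdx_age, cfg) {
  k <- cfg$weibull_shape; b <- cfg$weibull_scale
  lp_base <- if (male) cfg$male_log_HR else 0
  switch_at <- if (!is.na(gdx_age) && gdx_age < cfg$landmark_years)
    gdx_age else Inf
  H <- function(t) {
    h0 <- function(u) (pmax(u, 0) / b)^k
    if (t <= switch_at) exp(lp_base) * h0(t)
    else exp(lp_base) * (h0(switch_at) +
                         exp(cfg$gonadectomy_log_HR) * (h0(t) - h0(switch_at)))
  }
  Fmin <- 1 - exp(-H(cfg$onset_min))
  Fmax <- 1 - exp(-H(cfg$onset_max))
  u <- stats::runif(1, Fmin, Fmax)
  target <- -log(1 - u)
  stats::uniroot(function(t) H(t) - target,
                 c(cfg$onset_min, cfg$onset_max), tol = 1e-8)$root
}

#' Simulate a full cohort (haplotypes + phenotypes)
#'
#' @param config a [simulationConfig()].
#' @return list with `map`, `haps`, `truth`, `cohort`.
#' @export
simulateCohort <- function(config) {
  sim <- simulateHaplotypes(config)
  sim$cohort <- simulatePhenotypes(sim$haps, sim$truth, config)
  sim
}

#' Write a simulated dataset to files
#'
#' Emits the phased VCF, the phenotype table and the true-IBD TSV (hap-IBD
#' dialect) into a directory; the emitted files reload to the identical
#' data model via the package readers.
#'
#' @param sim output of [simulateCohort()].
#' @param out_dir directory (created if needed).
#' @return named character vector of paths, invisibly.
#' @export
emitCohort <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(out_dir, "cohort.vcf")
  phe <- file.path(out_dir, "phenotypes.tsv")
  ibd <- file.path(out_dir, "true_ibd.tsv")
  writePhasedVcf(sim$haps, vcf)
  writePhenotypes(sim$cohort, phe)
  writeIbdSegments(trueIbdSegments(sim$truth), ibd)
  invisible(c(vcf = vcf, phenotypes = phe, ibd = ibd))
}
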