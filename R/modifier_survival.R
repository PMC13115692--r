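# Carrier-restricted modifier analyses: onset summaries, the
# temporality-constrained gonadectomy exposure, a Firth logistic modifier
# model, counting-process construction and time-varying Cox regression.

#' Onset-age summary by sex
#'
#' Median and interquartile range of age at first seizure among carrier
#' cases, stratified by sex. Quantiles use the linear-interpolation
#' (type 7) convention.
#'
#' @param cohort a cohort data.frame; only rows with `status == "case"` and
#'   a non-missing `age_onset_years` contribute.
#' @return An `"OnsetSummary"` data.frame with columns `sex`, `n`, `median`,
#'   `q25`, `q75`.
#' @export
onsetSummary <- function(cohort) {
  d <- cohort[cohort$status == "case" & !is.na(cohort$age_onset_years), ,
              drop = FALSE]
  if (nrow(d) == 0) stop("no cases with an onset age")
  out <- do.call(rbind, lapply(split(d, d$sex), function(g) {
    q <- stats::quantile(g$age_onset_years, c(0.25, 0.5, 0.75), type = 7)
    data.frame(sex = g$sex[1], n = nrow(g), median = unname(q[2]),
               q25 = unname(q[1]), q75 = unname(q[3]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("OnsetSummary", "data.frame")
  out
}

#' Gonadectomy exposure with the temporality constraint
#'
#' Classifies each dog as exposed or unexposed under the landmark
#' definition: a case is exposed only if gonadectomy occurred before
#' seizure onset AND before the landmark age; a control is exposed if
#' gonadectomy occurred before the landmark age. Intact dogs, dogs
#' gonadectomized at or after the landmark, and cases gonadectomized after
#' onset are unexposed. The constraint exists to avoid reverse causation:
#' a gonadectomy after onset cannot have modified the onset.
#'
#' @param cohort a cohort data.frame with `status`, `age_onset_years`,
#'   `age_gonadectomy_years`, `gonadal_status`.
#' @param landmark_years landmark age (5 primary; 2 as a stricter
#'   sensitivity window).
#' @return integer vector of 0/1 exposure flags; NA where a gonadectomized
#'   dog lacks a gonadectomy age (such dogs must be dropped explicitly).
#' @export
classifyExposure <- function(cohort, landmark_years = 5) {
  if (landmark_years <= 0) stop("landmark must be > 0")
  g <- cohort$age_gonadectomy_years
  gon <- !is.null(cohort$gonadal_status) &
    cohort$gonadal_status == "gonadectomized"
  exposed <- integer(nrow(cohort))
  exposed[gon & is.na(g)] <- NA_integer_
  has_g <- gon & !is.na(g)
  is_case <- cohort$status == "case"
  onset <- cohort$age_onset_years
  exposed[has_g & is_case] <-
    as.integer(g[has_g & is_case] < onset[has_g & is_case] &
               g[has_g & is_case] < landmark_years)
  exposed[has_g & !is_case] <- as.integer(g[has_g & !is_case] < landmark_years)
  exposed
}

#' Firth logistic modifier model among carriers
#'
#' Case status regressed on gonadectomy exposure and sex with
#' Firth-penalized likelihood (the cell counts here are small and
#' separation is likely). Delegates to [firthLogistic()]; odds ratios carry
#' profile penalized-likelihood CIs and the overall fit a penalized
#' likelihood-ratio test.
#'
#' @param cohort carrier-restricted cohort data.frame.
#' @param landmark_years exposure landmark; see [classifyExposure()].
#' @param drop_missing drop dogs with unknown exposure (gonadectomized with
#'   no recorded age); dropped ids are attached as attribute `"dropped"`.
#' @param ... passed to [firthLogistic()].
#' @return A `"riskModelFit"` with terms `exposed` and `sexM`.
#' @export
firthModifierModel <- function(cohort, landmark_years = 5,
                               drop_missing = TRUE, ...) {
  expo <- classifyExposure(cohort, landmark_years)
  dropped <- cohort$dog_id[is.na(expo)]
  if (length(dropped)) {
    if (!drop_missing) stop("dogs with unknown exposure: ",
                            paste(dropped, collapse = ", "))
    keep <- !is.na(expo)
    cohort <- cohort[keep, , drop = FALSE]
    expo <- expo[keep]
  }
  X <- cbind("(Intercept)" = 1, exposed = expo,
             sexM = as.integer(cohort$sex == "M"))
  fit <- firthLogistic(X, as.integer(cohort$status == "case"), ...)
  attr(fit, "dropped") <- dropped
  fit
}

#' Counting-process (start-stop) table with time-varying gonadectomy
#'
#' Builds the start-stop age intervals for age-scale survival analysis.
#' The endpoint is onset age for cases and last-follow-up age for controls
#' (right censored). A dog contributes a single unexposed interval from
#' birth to the endpoint if never gonadectomized, gonadectomized at or
#' after the landmark, or (for cases) gonadectomized after onset; it
#' contributes two intervals — unexposed \[0, gonadectomy) then exposed
#' \[gonadectomy, endpoint) — if gonadectomized before the landmark and
#' before the endpoint. Gonadectomy exactly at the endpoint yields a single
#' unexposed interval (zero-length intervals are disallowed). The event
#' flag is 1 only on a case's final interval. All dogs enter at birth (no
#' left truncation).
#'
#' @param cohort carrier-restricted cohort data.frame; every dog needs an
#'   endpoint age (onset for cases, `age_last_followup_years` for controls).
#' @param landmark_years exposure landmark age.
#' @return A `"CountingProcessTable"` data.frame with columns `dog_id`,
#'   `start`, `stop`, `exposed`, `event`, `sex`.
#' @export
buildCountingProcess <- function(cohort, landmark_years = 5) {
  endpoint <- ifelse(cohort$status == "case",
                     cohort$age_onset_years,
                     cohort$age_last_followup_years)
  if (anyNA(endpoint))
    stop("endpoint age missing for dog(s): ",
         paste(cohort$dog_id[is.na(endpoint)], collapse = ", "))
  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    ev <- as.integer(cohort$status[i] == "case")
    g <- cohort$age_gonadectomy_years[i]
    gon <- !is.na(g) &&
      (is.null(cohort$gonadal_status) ||
         cohort$gonadal_status[i] == "gonadectomized")
    split_ <- gon && g < landmark_years && g < endpoint[i]
    if (split_) {
      rows[[i]] <- data.frame(
        dog_id = cohort$dog_id[i],
        start = c(0, g), stop = c(g, endpoint[i]),
        exposed = c(0L, 1L), event = c(0L, ev),
        sex = cohort$sex[i], stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(
        dog_id = cohort$dog_id[i],
        start = 0, stop = endpoint[i], exposed = 0L, event = ev,
        sex = cohort$sex[i], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (any(out$stop <= out$start))
    stop("non-positive interval for dog(s): ",
         paste(unique(out$dog_id[out$stop <= out$start]), collapse = ", "))
  class(out) <- c("CountingProcessTable", "data.frame")
  out
}

#' Time-varying Cox model on the counting-process table
#'
#' Cox partial likelihood on the start-stop data with age as the time
#' scale, gonadectomy as the time-varying exposure and sex as a fixed
#' covariate; Efron tie handling and robust sandwich variance clustered by
#' dog. A monotone likelihood (e.g. every event in the exposed state) is
#' flagged.
#'
#' @param cp a `"CountingProcessTable"` from [buildCountingProcess()].
#' @param ci_level confidence level.
#' @return A `"SurvivalFit"`: list with `coef`, `hr`, `se` (model-based),
#'   `robust_se`, `ci_lower`, `ci_upper` (robust Wald, HR scale), `p`
#'   (robust Wald), `n_events`, `monotone_flag`, and the underlying
#'   [survival::coxph()] fit in `$coxph`.
#' @export
coxTvFit <- function(cp, ci_level = 0.95) {
  if (sum(cp$event) == 0) stop("no events in the counting-process table")
  cp2 <- as.data.frame(cp)
  cp2$sexM <- as.integer(cp2$sex == "M")
  fit <- survival::coxph(
    survival::Surv(start, stop, event) ~ exposed + sexM +
      survival::cluster(dog_id),
    data = cp2, ties = "efron")
  beta <- stats::coef(fit)
  rse <- stats::setNames(sqrt(diag(fit$var)), names(beta))  # robust (clustered)
  mse <- stats::setNames(sqrt(diag(fit$naive.var %||% fit$var)), names(beta))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  monotone <- any(abs(beta) > 10) || !is.null(fit$flags) &&
    any(unlist(fit$flags) != 0)
  structure(list(coef = beta, hr = exp(beta), se = mse, robust_se = rse,
                 ci_lower = exp(beta - z * rse),
                 ci_upper = exp(beta + z * rse),
                 p = 2 * stats::pnorm(-abs(beta / rse)),
                 n_events = sum(cp$event), ci_level = ci_level,
                 monotone_flag = monotone, coxph = fit),
            class = "SurvivalFit")
}

#' @export
print.SurvivalFit <- function(x, ...) {
  cat("Time-varying Cox fit (age scale, robust clustered SEs)\n")
  tab <- data.frame(coef = x$coef, HR = x$hr, robust_se = x$robust_se,
                    ci_lo = x$ci_lower, ci_hi = x$ci_upper, p = x$p)
  print(signif(tab, 4))
  cat(sprintf("%d events%s\n", x$n_events,
              if (x$monotone_flag) " [monotone likelihood flagged]" else ""))
  invisible(x)
}

#' Proportional-hazards check via scaled Schoenfeld residuals
#'
#' Wrapper around [survival::cox.zph()]: score test of the correlation
#' between scaled Schoenfeld residuals (defined only at event times) and a
#' transform of event time, per term and globally.
#'
#' @param fit a `"SurvivalFit"` from [coxTvFit()].
#' @param transform time transform passed to `cox.zph`.
#' @return the `cox.zph` table (rows per term plus GLOBAL).
#' @export
phCheck <- function(fit, transform = "km") {
  zp <- survival::cox.zph(fit$coxph, transform = transform)
  zp$table
}
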