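.siteCounts <- c(
  stomach = 22198, lung = 21227, colorectal = 21043, liver = 19924,
  pancreatic = 5514, bile_duct = 3361, gallbladder = 1989,
  small_intestine = 646, multiple_myeloma = 1894, kidney = 2895,
  ureter = 620, bladder = 4489, laryngeal = 1197, prostate = 5509,
  anal = 184, esophageal = 2224, other = 55045
)
.siteDmCounts <- c(
  stomach = 2800, lung = 3260, colorectal = 2829, liver = 4254,
  pancreatic = 1649, bile_duct = 763, gallbladder = 308,
  small_intestine = 100, multiple_myeloma = 285, kidney = 444,
  ureter = 91, bladder = 643, laryngeal = 153, prostate = 674,
  anal = 22, esophageal = 258, other = 3360
)
.siteHtnCounts <- c(
  stomach = 4854, lung = 5541, colorectal = 4861, liver = 4534,
  pancreatic = 1552, bile_duct = 1056, gallbladder = 531,
  small_intestine = 146, multiple_myeloma = 496, kidney = 854,
  ureter = 189, bladder = 1233, laryngeal = 245, prostate = 1477,
  anal = 43, esophageal = 490, other = 6563
)

.siteEmitCode <- c(
  stomach = "C16.0", lung = "C34.9", colorectal = "C18.9", liver = "C22.0",
  pancreatic = "C25.9", bile_duct = "C24.0", gallbladder = "C23",
  small_intestine = "C17.9", multiple_myeloma = "C90.0", kidney = "C64",
  ureter = "C66", bladder = "C67.9", laryngeal = "C32.9", prostate = "C61",
  anal = "C21.0", esophageal = "C15.9", other = "C80.9"
)

#' Joint probability planting a target lift on two binary marginals
#'
#' Inverts the lift definition: p(A,B) = lift x p(A) x p(B), then verifies
#' the result against the Frechet bounds
#' `[max(0, pA + pB - 1), min(pA, pB)]` — a lift can be infeasible for given
#' marginals, in which case the violated bound is named in the error.
#'
#' @param pA,pB marginal probabilities in (0, 1).
#' @param targetLift positive lift to plant (1 = independence).
#' @return the joint probability `pAB`.
#' @export
#' @examples
#' plantPairwiseJoint(0.129, 0.204, 2.629) # ~0.0692
plantPairwiseJoint <- function(pA, pB, targetLift) {
  stopifnot(pA > 0, pA < 1, pB > 0, pB < 1, targetLift > 0)
  pAB <- targetLift * pA * pB
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  if (pAB > hi + 1e-12)
    stopf("infeasible lift %g: joint %g exceeds upper Frechet bound min(pA, pB) = %g",
          targetLift, pAB, hi)
  if (pAB < lo - 1e-12)
    stopf("infeasible lift %g: joint %g below lower Frechet bound max(0, pA+pB-1) = %g",
          targetLift, pAB, lo)
  pAB
}

#' Configuration for the synthetic discharge-cohort generator
#'
#' Defaults reproduce the moments of the registry cohort the analysis
#' emulates: the cancer-site distribution and site-conditional DM/HTN
#' prevalences of the published prevalence table, overall comorbidity
#' marginals (DM 12.9%, HTN 20.4%, hyperthyroidism 0.2%, hypothyroidism
#' 1.1%), a planted global DM-HTN lift of 2.629, sex split 53.9% male, the
#' four-group age distribution, treatment rates (surgery 40.7%, chemotherapy
#' 11.4%, radiotherapy 0.4%), and a logistic death mechanism whose exposure
#' coefficients are the published all-cancer mortality model with a
#' reference-group death rate of 6.1%.
#'
#' @param n cohort size.
#' @param seed RNG seed (integer).
#' @param siteDistribution named probabilities over cancer sites (must sum
#'   to 1).
#' @param comorbidityMarginals named prevalences for `dm`, `htn`,
#'   `hyperthyroidism`, `hypothyroidism`.
#' @param siteConditional `NULL`, or a list with named numeric vectors `dm`
#'   and `htn` giving per-site prevalences; when present, DM/HTN are drawn
#'   from per-site joints scaled so the GLOBAL planted lift is hit exactly
#'   in expectation.
#' @param plantedLiftDmHtn target global DM-HTN lift.
#' @param mortalityCoefficients named log-odds coefficients for the death
#'   model (terms as in [buildDesign()] plus `intercept`).
#' @param baselineDeathRate death probability of the reference group
#'   (female, 19--44, no flags); sets the default intercept.
#' @param pMale probability of male sex.
#' @param ageDistribution probabilities of the four age groups 19--44,
#'   45--64, 65--74, 75+.
#' @param treatmentRates named rates for `surgery`, `chemotherapy`,
#'   `radiotherapy`.
#' @param insuranceDistribution,admissionDistribution categorical
#'   probabilities for the two administrative fields.
#' @param outcomeSplit conditional probabilities of non-death outcomes
#'   (improved, not_improved, other), renormalized internally.
#' @return a validated config list of class `"SyntheticCohortConfig"`.
#' @export
syntheticCohortConfig <- function(
    n = 169959L,
    seed = 1L,
    siteDistribution = .siteCounts / sum(.siteCounts),
    comorbidityMarginals = c(dm = 0.129, htn = 0.204,
                             hyperthyroidism = 0.002, hypothyroidism = 0.011),
    siteConditional = list(dm = .siteDmCounts / .siteCounts,
                           htn = .siteHtnCounts / .siteCounts),
    plantedLiftDmHtn = 2.629,
    mortalityCoefficients = c(
      intercept = stats::qlogis(0.061),
      dm = -0.086, htn = 0.182, hypothyroidism = 0.033,
      hyperthyroidism = 0.568,
      sexMale = 0.4, age45_64 = 0.6, age65_74 = 0.9, age75plus = 1.3,
      surgery = -0.8, chemotherapy = 0.2, radiotherapy = 0.1),
    baselineDeathRate = 0.061,
    pMale = 0.539,
    ageDistribution = c(`19-44` = 0.145, `45-64` = 0.446,
                        `65-74` = 0.257, `75+` = 0.152),
    treatmentRates = c(surgery = 0.407, chemotherapy = 0.114,
                       radiotherapy = 0.004),
    insuranceDistribution = c(national_health = 0.95, medicaid_1 = 0.03,
                              medicaid_2 = 0.01, other = 0.01),
    admissionDistribution = c(outpatient = 0.70, emergency = 0.25,
                              other = 0.05),
    outcomeSplit = c(improved = 0.888, not_improved = 0.048, other = 0.003)) {
  cfg <- list(n = as.integer(n), seed = as.integer(seed),
              siteDistribution = siteDistribution,
              comorbidityMarginals = comorbidityMarginals,
              siteConditional = siteConditional,
              plantedLiftDmHtn = plantedLiftDmHtn,
              mortalityCoefficients = mortalityCoefficients,
              baselineDeathRate = baselineDeathRate,
              pMale = pMale, ageDistribution = ageDistribution,
              treatmentRates = treatmentRates,
              insuranceDistribution = insuranceDistribution,
              admissionDistribution = admissionDistribution,
              outcomeSplit = outcomeSplit / sum(outcomeSplit))
  class(cfg) <- "SyntheticCohortConfig"
  validateSyntheticConfig(cfg)
  cfg
}

validateSyntheticConfig <- function(cfg) {
  if (cfg$n < 0) stopf("n must be >= 0")
  if (abs(sum(cfg$siteDistribution) - 1) > 1e-9)
    stopf("siteDistribution must sum to 1")
  probs <- c(cfg$siteDistribution, cfg$comorbidityMarginals, cfg$pMale,
             cfg$ageDistribution, cfg$treatmentRates,
             cfg$insuranceDistribution, cfg$admissionDistribution,
             cfg$baselineDeathRate)
  if (any(probs < 0 | probs > 1)) stopf("all probabilities must be in [0, 1]")
  if (abs(sum(cfg$ageDistribution) - 1) > 1e-9)
    stopf("ageDistribution must sum to 1")
  # feasibility of the planted DM-HTN structure (errors if violated)
  invisible(plannedDmHtnJoint(cfg))
  invisible(cfg)
}

# Per-site (or global) planned DM/HTN joint cell probabilities.
# With site-conditional prevalences the within-site joint is
# p11_s = lambda * pDM_s * pHTN_s with lambda chosen so the GLOBAL lift
# equals the target: lambda = L * pDM * pHTN / sum_s w_s pDM_s pHTN_s,
# where pDM/pHTN are the mixture marginals. Each per-site joint is checked
# against its Frechet bounds.
plannedDmHtnJoint <- function(cfg) {
  L <- cfg$plantedLiftDmHtn
  if (is.null(cfg$siteConditional)) {
    pA <- cfg$comorbidityMarginals[["dm"]]
    pB <- cfg$comorbidityMarginals[["htn"]]
    p11 <- plantPairwiseJoint(pA, pB, L)
    return(data.frame(site = "_all_", pA = pA, pB = pB, p11 = p11,
                      stringsAsFactors = FALSE))
  }
  sites <- names(cfg$siteDistribution)
  w <- cfg$siteDistribution
  pAs <- cfg$siteConditional$dm[sites]
  pBs <- cfg$siteConditional$htn[sites]
  if (anyNA(pAs) || anyNA(pBs))
    stopf("siteConditional must cover every site in siteDistribution")
  pA <- sum(w * pAs); pB <- sum(w * pBs)
  lambda <- L * pA * pB / sum(w * pAs * pBs)
  p11 <- lambda * pAs * pBs
  for (s in seq_along(sites)) {
    lo <- max(0, pAs[s] + pBs[s] - 1); hi <- min(pAs[s], pBs[s])
    if (p11[s] > hi + 1e-12 || p11[s] < lo - 1e-12)
      stopf("planted lift %g infeasible within site %s: joint %g outside Frechet bounds [%g, %g]",
            L, sites[s], p11[s], lo, hi)
  }
  data.frame(site = sites, pA = unname(pAs), pB = unname(pBs),
             p11 = unname(p11), stringsAsFactors = FALSE)
}

#' Generate a synthetic discharge cohort
#'
#' Draws one discharge episode per row under the configured moments and
#' emits ICD-coded records (not flags): a representative site code as the
#' principal diagnosis (dotted and undotted forms mixed, so normalization is
#' exercised), comorbidity codes in the secondary-diagnosis list, procedure
#' codes for chemotherapy/radiotherapy, and a non-empty main surgery code for
#' operated episodes — so the phenotyping stage is exercised end to end and
#' recovers the planted flags exactly. Death is drawn from the configured
#' logistic model; the same config and seed always produce an identical
#' cohort.
#'
#' Draw order (one seeded Mersenne-Twister stream, fields drawn in fixed
#' vectorized order): site, DM/HTN joint, hyperthyroidism, hypothyroidism,
#' sex, age group, age within group, surgery, chemotherapy, radiotherapy,
#' death, non-death outcome, insurance type, admission route.
#'
#' @param config a [syntheticCohortConfig()] list.
#' @return a cohort `data.frame` with the [readCohort()] schema.
#' @export
#' @examples
#' cohort <- generateCohort(syntheticCohortConfig(n = 100, seed = 7))
#' table(phenotypeCohort(cohort)$dm)
generateCohort <- function(config) {
  validateSyntheticConfig(config)
  n <- config$n
  if (n == 0L) {
    out <- data.frame(matrix(character(0), 0, length(.cohortColumns),
                             dimnames = list(NULL, .cohortColumns)),
                      stringsAsFactors = FALSE)
    out$age_years <- integer(0)
    return(out[, .cohortColumns])
  }
  set.seed(config$seed, kind = "Mersenne-Twister")

  sites <- names(config$siteDistribution)
  site <- sample(sites, n, replace = TRUE, prob = config$siteDistribution)

  joint <- plannedDmHtnJoint(config)
  if (identical(joint$site, "_all_")) {
    pA <- rep(joint$pA, n); pB <- rep(joint$pB, n); p11 <- rep(joint$p11, n)
  } else {
    idx <- match(site, joint$site)
    pA <- joint$pA[idx]; pB <- joint$pB[idx]; p11 <- joint$p11[idx]
  }
  u <- stats::runif(n)
  dm <- u < p11 | (u >= p11 & u < p11 + (pA - p11))
  htn <- u < p11 | (u >= p11 + (pA - p11) & u < pA + pB - p11)

  hyper <- stats::runif(n) < config$comorbidityMarginals[["hyperthyroidism"]]
  hypo <- stats::runif(n) < config$comorbidityMarginals[["hypothyroidism"]]
  sex <- ifelse(stats::runif(n) < config$pMale, "male", "female")
  ageGroup <- sample(names(config$ageDistribution), n, replace = TRUE,
                     prob = config$ageDistribution)
  lo <- c(`19-44` = 19L, `45-64` = 45L, `65-74` = 65L, `75+` = 75L)[ageGroup]
  hi <- c(`19-44` = 44L, `45-64` = 64L, `65-74` = 74L, `75+` = 94L)[ageGroup]
  age <- lo + as.integer(floor(stats::runif(n) * (hi - lo + 1L)))
  surgery <- stats::runif(n) < config$treatmentRates[["surgery"]]
  chemo <- stats::runif(n) < config$treatmentRates[["chemotherapy"]]
  radio <- stats::runif(n) < config$treatmentRates[["radiotherapy"]]

  b <- config$mortalityCoefficients
  eta <- b[["intercept"]] +
    b[["dm"]] * dm + b[["htn"]] * htn +
    b[["hypothyroidism"]] * hypo + b[["hyperthyroidism"]] * hyper +
    b[["sexMale"]] * (sex == "male") +
    b[["age45_64"]] * (ageGroup == "45-64") +
    b[["age65_74"]] * (ageGroup == "65-74") +
    b[["age75plus"]] * (ageGroup == "75+") +
    b[["surgery"]] * surgery +
    b[["chemotherapy"]] * chemo + b[["radiotherapy"]] * radio
  died <- stats::runif(n) < stats::plogis(eta)
  alt <- sample(names(config$outcomeSplit), n, replace = TRUE,
                prob = config$outcomeSplit)
  outcome <- ifelse(died, "death", alt)
  insurance <- sample(names(config$insuranceDistribution), n, replace = TRUE,
                      prob = config$insuranceDistribution)
  admission <- sample(names(config$admissionDistribution), n, replace = TRUE,
                      prob = config$admissionDistribution)

  joinCodes <- function(...) {
    parts <- list(...)
    s <- do.call(paste0, lapply(parts, function(p)
      ifelse(p$on, paste0(p$code, ";"), "")))
    sub(";$", "", s)
  }
  secondary <- joinCodes(list(on = dm, code = "E11.9"),
                         list(on = htn, code = "I10"),
                         list(on = hyper, code = "E05.0"),
                         list(on = hypo, code = "E03.9"))
  procs <- joinCodes(list(on = chemo, code = "99.25"),
                     list(on = radio, code = "92.24"))

  data.frame(
    record_id = sprintf("R%07d", seq_len(n)),
    sex = sex,
    age_years = age,
    insurance_type = insurance,
    admission_route = admission,
    treatment_outcome = outcome,
    principal_dx = unname(.siteEmitCode[site]),
    secondary_dx = unname(secondary),
    procedure_codes = unname(procs),
    main_surgery_code = ifelse(surgery, "OP01", ""),
    stringsAsFactors = FALSE
  )
}
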