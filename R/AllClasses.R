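#' @import methods
NULL

#' CodeMap: named ICD code-range phenotype definitions
#'
#' Maps condition labels (comorbidities, treatments and cancer sites) to
#' inclusive code intervals in either the ICD-10 diagnosis or the ICD-9-CM
#' procedure system. Codes are stored normalized (uppercase, dots stripped),
#' so the interval written E11.0--E14.9 is held as `["E110", "E149"]`.
#'
#' Validity enforces that every interval is well formed (`start <= end` under
#' the normalized ordering), that cancer-site intervals are mutually disjoint,
#' and that every site interval lies inside the malignancy chapter C00--C97.
#' The site label `"other"` is the fallback for principal malignancy codes not
#' covered by any named site and carries no intervals of its own.
#'
#' @slot intervals data.frame with columns `label`, `start`, `end`, `system`
#'   (`"icd10_dx"` or `"icd9cm_proc"`), normalized codes.
#' @slot siteLabels character vector of labels that partition the malignancy
#'   chapter (includes `"other"`).
#'
#' @seealso [defaultCodeMap()], [codeInRange()], [phenotypeCohort()]
#' @export
setClass("CodeMap", representation(
  intervals = "data.frame",
  siteLabels = "character"
))

setValidity("CodeMap", function(object) {
  iv <- object@intervals
  need <- c("label", "start", "end", "system")
  if (!all(need %in% names(iv)))
    return(paste("intervals must have columns", paste(need, collapse = ", ")))
  if (nrow(iv) == 0) return("CodeMap has no intervals")
  bad <- !iv$system %in% c("icd10_dx", "icd9cm_proc")
  if (any(bad)) return("system must be icd10_dx or icd9cm_proc")
  lo <- codeSortKey(iv$start, "low")
  hi <- codeSortKey(iv$end, "high")
  if (any(lo > hi))
    return(paste("interval start exceeds end for label(s):",
                 paste(unique(iv$label[lo > hi]), collapse = ", ")))
  sites <- setdiff(object@siteLabels, "other")
  si <- iv[iv$label %in% sites, , drop = FALSE]
  if (nrow(si)) {
    if (any(si$system != "icd10_dx"))
      return("site intervals must be in the icd10_dx system")
    slo <- codeSortKey(si$start, "low")
    shi <- codeSortKey(si$end, "high")
    if (any(slo < codeSortKey("C00", "low")) ||
        any(shi > codeSortKey("C97", "high")))
      return("site intervals must lie within C00-C97")
    o <- order(slo)
    slo <- slo[o]; shi <- shi[o]; lbl <- si$label[o]
    if (nrow(si) > 1) {
      ov <- which(slo[-1] <= shi[-nrow(si)])
      if (length(ov))
        return(paste("site intervals overlap:", lbl[ov[1]], "and", lbl[ov[1] + 1]))
    }
  }
  required <- c("dm", "htn", "hyperthyroidism", "hypothyroidism",
                "chemotherapy", "radiotherapy")
  miss <- setdiff(required, unique(iv$label))
  if (length(miss))
    return(paste("missing required labels:", paste(miss, collapse = ", ")))
  TRUE
})

#' Transactions: one disease itemset per discharge episode
#'
#' The transactional view of a phenotyped cohort used by the Apriori miner:
#' each discharge episode contributes one (possibly empty) set of item labels
#' drawn from the comorbidity flags and the cancer-site label. Episodes with
#' empty itemsets still count toward the denominator N, because support is
#' defined over all study participants.
#'
#' @slot items list of character vectors, one per episode, each a duplicate-free
#'   set of item labels.
#' @slot recordId character vector of episode identifiers, parallel to `items`.
#' @slot itemLabels character vector, the item universe.
#'
#' @seealso [buildTransactions()], [apriori()], [mineRules()]
#' @export
setClass("Transactions", representation(
  items = "list",
  recordId = "character",
  itemLabels = "character"
))

setValidity("Transactions", function(object) {
  if (length(object@items) != length(object@recordId))
    return("items and recordId lengths differ")
  if (anyDuplicated(object@recordId))
    return("recordId must be unique")
  dup <- vapply(object@items, anyDuplicated, 0L) > 0L
  if (any(dup)) return("transactions contain duplicate items")
  known <- vapply(object@items,
                  function(x) all(x %in% object@itemLabels), TRUE)
  if (!all(known)) return("transaction items outside itemLabels")
  TRUE
})

#' RuleSet: mined association rules with interest metrics
#'
#' Association rules between disease items, each carrying the joint count and
#' the four interest metrics: support, confidence, lift, and the
#' interest-support score IS = sqrt(support x lift). Produced by
#' [generateRules()] / [mineRules()] and ordered by [rankRules()].
#'
#' @slot rules data.frame with columns `antecedent` (list of character
#'   vectors), `consequent` (list of character vectors), `label`, `count`,
#'   `support`, `confidence`, `lift`, `isScore` (full precision).
#' @slot nTransactions integer, the denominator N.
#' @slot itemSupport named numeric, support of each single item (for graph
#'   export and symmetry checks).
#' @slot thresholds named numeric with `minSupport`, `minConfidence`,
#'   `minLift` applied (all strict `>`).
#'
#' @seealso [mineRules()], [ruleTable()], [exportRuleGraph()]
#' @export
setClass("RuleSet", representation(
  rules = "data.frame",
  nTransactions = "integer",
  itemSupport = "numeric",
  thresholds = "numeric"
))

setValidity("RuleSet", function(object) {
  r <- object@rules
  need <- c("antecedent", "consequent", "label", "count",
            "support", "confidence", "lift", "isScore")
  if (!all(need %in% names(r)))
    return(paste("rules must have columns", paste(need, collapse = ", ")))
  if (nrow(r)) {
    disj <- mapply(function(a, b) length(intersect(a, b)) == 0,
                   r$antecedent, r$consequent)
    if (!all(disj)) return("antecedent and consequent must be disjoint")
    if (any(r$confidence < r$support - 1e-12))
      return("confidence below support: inconsistent counts")
  }
  if (object@nTransactions < 0L) return("nTransactions must be >= 0")
  TRUE
})

#' LogisticFit: a fitted logistic mortality model
#'
#' Result container for the in-hospital death models: per-term coefficients,
#' Wald standard errors, odds ratios with 95 percent confidence intervals and
#' Wald p-values, plus bookkeeping on convergence, separation and any terms
#' dropped before fitting (e.g. zero variance in a cancer-site subset).
#'
#' @slot table data.frame with columns `term`, `B`, `SE`, `OR`, `ciLow`,
#'   `ciHigh`, `p` (full precision; see [oddsRatioReport()] for rounding).
#' @slot nUsed integer, rows used in the fit.
#' @slot converged logical, IRLS convergence flag.
#' @slot separation logical, quasi-separation flag (unbounded coefficients).
#' @slot droppedTerms data.frame with columns `term`, `reason`.
#' @slot outcome character, description of the modelled outcome.
#' @slot subset character, cancer-site restriction (`"all"` for the full
#'   cohort).
#'
#' @seealso [fitMortality()], [oddsRatioReport()], [forestPlotData()]
#' @export
setClass("LogisticFit", representation(
  table = "data.frame",
  nUsed = "integer",
  converged = "logical",
  separation = "logical",
  droppedTerms = "data.frame",
  outcome = "character",
  subset = "character"
))

setValidity("LogisticFit", function(object) {
  tb <- object@table
  need <- c("term", "B", "SE", "OR", "ciLow", "ciHigh", "p")
  if (!all(need %in% names(tb)))
    return(paste("table must have columns", paste(need, collapse = ", ")))
  if (nrow(tb)) {
    if (any(tb$ciLow > tb$OR + 1e-8) || any(tb$OR > tb$ciHigh + 1e-8))
      return("CI must bracket OR")
  }
  TRUE
})
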