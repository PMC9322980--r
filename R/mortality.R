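.exposureTerms <- c("dm", "htn", "hypothyroidism", "hyperthyroidism")
.controlTerms <- c("sexMale", "age45_64", "age65_74", "age75plus",
                   "surgery", "chemotherapy", "radiotherapy")

#' Build a mortality-model design from phenotype profiles
#'
#' Outcome is in-hospital death (treatment outcome "death" vs all others).
#' Exposure terms are the four comorbidity flags; controls are sex (male
#' indicator), age group as three indicators with 19--44 as reference,
#' surgery, chemotherapy and radiotherapy. Optionally restricts to one
#' cancer-site subset. Zero-variance columns are NOT dropped here — that is
#' the fitter's job, which records the reason.
#'
#' @param profiles a phenotype-profile `data.frame`.
#' @param subset a cancer-site label (e.g. `"liver"`) or `NULL` for the full
#'   cohort.
#' @param includeSurgery keep the surgery control (default TRUE).
#' @return list with `design` (data.frame of 0/1 indicators), `outcome`
#'   (logical vector) and `subset` (label used).
#' @export
buildDesign <- function(profiles, subset = NULL, includeSurgery = TRUE) {
  if (!is.null(subset)) {
    profiles <- profiles[as.character(profiles$cancer_site) == subset, ,
                         drop = FALSE]
    if (!nrow(profiles)) stopf("buildDesign: empty subset %s", sQuote(subset))
  }
  ag <- as.character(profiles$age_group)
  design <- data.frame(
    dm = as.integer(profiles$dm),
    htn = as.integer(profiles$htn),
    hypothyroidism = as.integer(profiles$hypothyroidism),
    hyperthyroidism = as.integer(profiles$hyperthyroidism),
    sexMale = as.integer(profiles$sex == "male"),
    age45_64 = as.integer(ag == "45-64"),
    age65_74 = as.integer(ag == "65-74"),
    age75plus = as.integer(ag == "75+"),
    surgery = as.integer(profiles$surgery),
    chemotherapy = as.integer(profiles$chemotherapy),
    radiotherapy = as.integer(profiles$radiotherapy)
  )
  if (!includeSurgery) design$surgery <- NULL
  list(design = design, outcome = profiles$died,
       subset = subset %||% "all")
}

#' Fit the logistic in-hospital-death model
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares ([stats::glm()] with binomial family), standard errors from the
#' inverse observed information. Columns with zero variance in the (possibly
#' subsetted) data are dropped before fitting and listed with a reason, as
#' are inestimable exposure cells (no events among the exposed, the
#' registry-table "-" case). Non-convergence and quasi-separation
#' (coefficients running away) are flagged on the result, never silently
#' reported.
#'
#' @param designObj list from [buildDesign()].
#' @param level confidence level for Wald intervals (default 0.95, i.e. the
#'   1.96 normal quantile).
#' @param maxit IRLS iteration cap (default 100).
#' @return a [LogisticFit-class] object.
#' @export
fitMortality <- function(designObj, level = 0.95, maxit = 100L) {
  X <- designObj$design
  y <- designObj$outcome
  if (!any(y) || all(y))
    stopf("fitMortality: outcome is degenerate (all events or no events)")
  dropped <- data.frame(term = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  keep <- character(0)
  for (term in names(X)) {
    v <- X[[term]]
    if (length(unique(v)) < 2) {
      dropped <- rbind(dropped, data.frame(
        term = term, reason = "zero variance in subset"))
    } else if (sum(y[v == 1]) == 0 || sum(!y[v == 1]) == 0) {
      dropped <- rbind(dropped, data.frame(
        term = term,
        reason = sprintf("inestimable: %s among exposed",
                         if (sum(y[v == 1]) == 0) "no deaths"
                         else "no survivors")))
    } else keep <- c(keep, term)
  }
  X <- X[, keep, drop = FALSE]
  dat <- cbind(X, .y = y)
  fit <- stats::glm(.y ~ ., family = stats::binomial(), data = dat,
                    control = stats::glm.control(maxit = maxit,
                                                 epsilon = 1e-10))
  B <- stats::coef(fit)
  SE <- sqrt(diag(stats::vcov(fit)))
  separation <- any(abs(B) > 15) || any(SE > 100)
  z <- stats::qnorm(1 - (1 - level) / 2)
  tb <- data.frame(term = names(B), B = unname(B), SE = unname(SE),
                   OR = exp(unname(B)),
                   ciLow = exp(unname(B) - z * SE),
                   ciHigh = exp(unname(B) + z * SE),
                   p = 2 * stats::pnorm(-abs(unname(B) / SE)),
                   stringsAsFactors = FALSE)
  tb$term[tb$term == "(Intercept)"] <- "intercept"
  new("LogisticFit", table = tb, nUsed = length(y),
      converged = fit$converged, separation = separation,
      droppedTerms = dropped, outcome = "in-hospital death",
      subset = designObj$subset)
}

#' Wald odds ratio and confidence interval from a coefficient
#'
#' The reporting arithmetic used for every model row: OR = exp(B), Wald CI
#' exp(B +/- 1.96 SE) at the default level, p = 2 Phi(-|B/SE|).
#'
#' @param B coefficient(s) on the log-odds scale.
#' @param SE standard error(s).
#' @param level confidence level (default 0.95).
#' @return `data.frame` with columns `OR`, `ciLow`, `ciHigh`, `p` (full
#'   precision).
#' @export
#' @examples
#' waldOddsRatio(0.235, 0.065) # OR 1.265, CI about (1.113, 1.437)
waldOddsRatio <- function(B, SE, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(OR = exp(B), ciLow = exp(B - z * SE), ciHigh = exp(B + z * SE),
             p = 2 * stats::pnorm(-abs(B / SE)))
}

#' Rounded odds-ratio report for a fitted model
#'
#' One row per term with B, SE, OR and the 95 percent CI rounded half-up to
#' 3 decimals (table convention), and the Wald p-value.
#'
#' @param fit a [LogisticFit-class].
#' @param includeIntercept keep the intercept row (default FALSE).
#' @return `data.frame` with columns `term`, `B`, `SE`, `OR`, `ciLow`,
#'   `ciHigh`, `p`.
#' @export
oddsRatioReport <- function(fit, includeIntercept = FALSE) {
  if (!fit@converged)
    warning("oddsRatioReport: model did not converge; estimates unreliable")
  tb <- coefTable(fit)
  if (!includeIntercept) tb <- tb[tb$term != "intercept", , drop = FALSE]
  out <- data.frame(term = tb$term,
                    B = roundHalfUp(tb$B, 3), SE = roundHalfUp(tb$SE, 3),
                    OR = roundHalfUp(tb$OR, 3),
                    ciLow = roundHalfUp(tb$ciLow, 3),
                    ciHigh = roundHalfUp(tb$ciHigh, 3),
                    p = tb$p, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Long-format forest-plot data for a set of per-cancer fits
#'
#' Exposure-term rows (comorbidity flags only) across fits, suitable for any
#' plotting front-end; inestimable/dropped terms are omitted and reported in
#' the `"omitted"` attribute, mirroring the "-" entries of registry tables.
#'
#' @param fits a non-empty named list of [LogisticFit-class] objects (names
#'   are the cohort labels, e.g. `"all"`, `"liver"`).
#' @return `data.frame` with columns `cancer`, `term`, `OR`, `ciLow`,
#'   `ciHigh`, `p`; attribute `"omitted"` lists dropped exposure terms.
#' @export
forestPlotData <- function(fits) {
  if (!length(fits)) stopf("forestPlotData: no fits")
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f@subset, "")
  rows <- list(); omitted <- list()
  for (nm in names(fits)) {
    tb <- coefTable(fits[[nm]])
    tb <- tb[tb$term %in% .exposureTerms, , drop = FALSE]
    if (nrow(tb))
      rows[[nm]] <- data.frame(cancer = nm, tb[, c("term", "OR", "ciLow",
                                                   "ciHigh", "p")],
                               stringsAsFactors = FALSE)
    dr <- droppedTerms(fits[[nm]])
    dr <- dr[dr$term %in% .exposureTerms, , drop = FALSE]
    if (nrow(dr))
      omitted[[nm]] <- data.frame(cancer = nm, dr, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "omitted") <- if (length(omitted))
    do.call(rbind, c(omitted, list(make.row.names = FALSE)))
  else data.frame(cancer = character(0), term = character(0),
                  reason = character(0))
  out
}

#' Render a forest plot of odds ratios
#'
#' @param plotData output of [forestPlotData()].
#' @return a `ggplot` object (log-scaled OR axis with a reference line at 1).
#' @export
plotForest <- function(plotData) {
  ggplot2::ggplot(plotData,
                  ggplot2::aes(x = OR, y = term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = ciLow, xmax = ciHigh),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~cancer) +
    ggplot2::labs(x = "Odds ratio of in-hospital death (95% CI)",
                  y = NULL) +
    ggplot2::theme_bw()
}
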