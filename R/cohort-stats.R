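#' Prevalence of a condition by stratum
#'
#' One row per stratum value plus a `Total` row, with counts and the
#' percentage rounded half-up to 1 decimal as conventionally printed in
#' registry tables. Strata with no records are omitted.
#'
#' @param profiles a phenotype-profile `data.frame` (see [phenotypeCohort()]),
#'   or any data.frame holding the two columns below.
#' @param stratifier name of the stratifying column (e.g. `"sex"`,
#'   `"cancer_site"`, `"age_group"`).
#' @param condition name of a logical flag column (e.g. `"dm"`, `"htn"`).
#' @return `data.frame` with columns `stratum`, `n_total`, `n_condition`,
#'   `pct`.
#' @export
prevalenceTable <- function(profiles, stratifier, condition) {
  if (!nrow(profiles)) stopf("prevalenceTable: empty cohort")
  for (col in c(stratifier, condition))
    if (!col %in% names(profiles))
      stopf("prevalenceTable: no column %s in profiles", sQuote(col))
  flag <- profiles[[condition]]
  if (!is.logical(flag)) stopf("condition column must be logical")
  strat <- factor(profiles[[stratifier]])
  nTot <- as.vector(table(strat))
  nCond <- as.vector(tapply(flag, strat, sum, default = 0L))
  keep <- nTot > 0
  out <- data.frame(
    stratum = c(levels(strat)[keep], "Total"),
    n_total = c(nTot[keep], length(flag)),
    n_condition = as.integer(c(nCond[keep], sum(flag))),
    stringsAsFactors = FALSE
  )
  out$pct <- roundHalfUp(100 * out$n_condition / out$n_total, 1)
  out
}

#' Pearson chi-squared test with Bonferroni correction
#'
#' Plain Pearson chi-squared test of independence (no continuity correction;
#' the counts here come from large registries) with a family-wise Bonferroni
#' adjustment `p_adj = min(1, m * p_raw)`. The family size m is explicit in
#' both the call and the result so the multiplicity convention is always
#' reproducible.
#'
#' @param counts a contingency table of non-negative counts (matrix, at least
#'   2x2) with positive row and column margins.
#' @param m Bonferroni family size (default 1, i.e. no correction).
#' @return `data.frame` with columns `statistic`, `df`, `p_raw`, `p_adj`, `m`.
#' @export
#' @examples
#' chiSquareTest(matrix(c(10, 20, 30, 40), 2, 2), m = 4)
chiSquareTest <- function(counts, m = 1L) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("chiSquareTest: negative counts")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stopf("chiSquareTest: degenerate table (zero row or column margin)")
  if (m < 1) stopf("chiSquareTest: family size m must be >= 1")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  data.frame(statistic = unname(ct$statistic), df = unname(ct$parameter),
             p_raw = ct$p.value, p_adj = min(1, m * ct$p.value), m = m)
}

#' Condition-by-stratum prevalence with tests
#'
#' Convenience wrapper producing, for each condition, the prevalence table
#' and a chi-squared test of the condition x stratifier contingency, sharing
#' one Bonferroni family across all conditions requested.
#'
#' @inheritParams prevalenceTable
#' @param conditions character vector of flag columns.
#' @param m Bonferroni family size; defaults to the number of conditions
#'   (one test per condition within this table).
#' @return named list (per condition) of lists with elements `table` and
#'   `test`.
#' @export
prevalenceReport <- function(profiles, stratifier, conditions,
                             m = length(conditions)) {
  stats::setNames(lapply(conditions, function(cond) {
    tab <- prevalenceTable(profiles, stratifier, cond)
    body <- tab[tab$stratum != "Total", , drop = FALSE]
    counts <- rbind(yes = body$n_condition,
                    no = body$n_total - body$n_condition)
    test <- if (ncol(counts) >= 2 && all(colSums(counts) > 0) &&
                all(rowSums(counts) > 0))
      chiSquareTest(counts, m = m)
    else NULL
    list(table = tab, test = test)
  }), conditions)
}
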