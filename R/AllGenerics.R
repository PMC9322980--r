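#' @rdname Transactions-class
#' @param x a `Transactions` or `RuleSet` object.
#' @export
setGeneric("nTransactions", function(x) standardGeneric("nTransactions"))

#' @rdname Transactions-class
#' @export
setGeneric("itemLabels", function(x) standardGeneric("itemLabels"))

#' @rdname Transactions-class
#' @export
setGeneric("transactionItems", function(x) standardGeneric("transactionItems"))

#' @rdname RuleSet-class
#' @export
setGeneric("ruleTable", function(x) standardGeneric("ruleTable"))

#' @rdname RuleSet-class
#' @export
setGeneric("itemSupport", function(x) standardGeneric("itemSupport"))

#' @rdname LogisticFit-class
#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))

#' @rdname LogisticFit-class
#' @export
setGeneric("droppedTerms", function(x) standardGeneric("droppedTerms"))

#' @rdname CodeMap-class
#' @param x a `CodeMap` object.
#' @export
setGeneric("codeIntervals", function(x) standardGeneric("codeIntervals"))

#' @rdname CodeMap-class
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))

#' @rdname Transactions-class
#' @export
setMethod("nTransactions", "Transactions", function(x) length(x@items))

#' @rdname Transactions-class
#' @export
setMethod("itemLabels", "Transactions", function(x) x@itemLabels)

#' @rdname Transactions-class
#' @export
setMethod("transactionItems", "Transactions", function(x) {
  stats::setNames(x@items, x@recordId)
})

#' @rdname RuleSet-class
#' @export
setMethod("nTransactions", "RuleSet", function(x) x@nTransactions)

#' @rdname RuleSet-class
#' @export
setMethod("ruleTable", "RuleSet", function(x) x@rules)

#' @rdname RuleSet-class
#' @export
setMethod("itemSupport", "RuleSet", function(x) x@itemSupport)

#' @rdname LogisticFit-class
#' @export
setMethod("coefTable", "LogisticFit", function(x) x@table)

#' @rdname LogisticFit-class
#' @export
setMethod("droppedTerms", "LogisticFit", function(x) x@droppedTerms)

#' @rdname CodeMap-class
#' @export
setMethod("codeIntervals", "CodeMap", function(x) x@intervals)

#' @rdname CodeMap-class
#' @export
setMethod("siteLabels", "CodeMap", function(x) x@siteLabels)

setMethod("show", "CodeMap", function(object) {
  iv <- object@intervals
  cat("CodeMap with", length(unique(iv$label)), "labels,",
      nrow(iv), "code intervals\n")
  cat("  cancer sites:", paste(object@siteLabels, collapse = ", "), "\n")
})

setMethod("show", "Transactions", function(object) {
  n <- length(object@items)
  sz <- lengths(object@items)
  cat("Transactions:", n, "episodes over",
      length(object@itemLabels), "items\n")
  if (n) cat("  itemset sizes: min", min(sz), "median", stats::median(sz),
             "max", max(sz), "(", sum(sz == 0), "empty )\n")
})

setMethod("show", "RuleSet", function(object) {
  r <- object@rules
  cat("RuleSet:", nrow(r), "rules over N =", object@nTransactions,
      "transactions\n")
  th <- object@thresholds
  if (length(th))
    cat("  thresholds:", paste(names(th), ">", signif(th, 3), collapse = ", "),
        "\n")
  if (nrow(r)) {
    top <- utils::head(r, 5)
    cat("  top rules by IS:\n")
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %s  count=%d support=%.3f conf=%.3f lift=%.3f IS=%.3f\n",
                  top$label[i], top$count[i], top$support[i],
                  top$confidence[i], top$lift[i], top$isScore[i]))
  }
})

setMethod("show", "LogisticFit", function(object) {
  cat("LogisticFit (", object@subset, "): n =", object@nUsed,
      if (!object@converged) "[NOT CONVERGED]" else "",
      if (object@separation) "[SEPARATION]" else "", "\n")
  tb <- object@table
  tb$B <- roundHalfUp(tb$B, 3); tb$SE <- roundHalfUp(tb$SE, 3)
  tb$OR <- roundHalfUp(tb$OR, 3)
  tb$ciLow <- roundHalfUp(tb$ciLow, 3); tb$ciHigh <- roundHalfUp(tb$ciHigh, 3)
  tb$p <- signif(tb$p, 3)
  print(tb, row.names = FALSE)
  if (nrow(object@droppedTerms)) {
    cat("  dropped terms:\n")
    for (i in seq_len(nrow(object@droppedTerms)))
      cat("   ", object@droppedTerms$term[i], "-",
          object@droppedTerms$reason[i], "\n")
  }
})
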