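itemsetKey <- function(items) paste(sort(items), collapse = "\r")

#' Level-wise Apriori frequent-itemset mining
#'
#' Standard Apriori: level k candidates are generated by joining frequent
#' (k-1)-itemsets sharing their first k-2 items, pruned by anti-monotonicity
#' (every (k-1)-subset must itself be frequent), then counted against the
#' transaction incidence matrix. An itemset is emitted iff its support is
#' strictly greater than `minSupport`.
#'
#' @param transactions a [Transactions-class] object.
#' @param minSupport strict support threshold in (0, 1] (default 0.01).
#' @return `data.frame` with columns `items` (list of sorted character
#'   vectors), `size`, `count`, `support`, ordered by size then label.
#' @export
#' @seealso [generateRules()], [mineRules()]
apriori <- function(transactions, minSupport = 0.01) {
  n <- nTransactions(transactions)
  if (n < 1) stopf("apriori: no transactions")
  if (minSupport <= 0 || minSupport > 1)
    stopf("apriori: minSupport must be in (0, 1]")
  labels <- sort(itemLabels(transactions))
  inc <- matrix(FALSE, n, length(labels), dimnames = list(NULL, labels))
  flat <- unlist(transactions@items)
  if (length(flat))
    inc[cbind(rep.int(seq_len(n), lengths(transactions@items)),
              match(flat, labels))] <- TRUE

  emit <- list()
  # level 1
  cnt <- colSums(inc)
  keep <- which(cnt / n > minSupport)
  frequent <- lapply(labels[keep], identity)
  counts <- cnt[keep]
  for (i in seq_along(frequent))
    emit[[length(emit) + 1L]] <- list(items = frequent[[i]],
                                      count = as.integer(counts[i]))
  prevSets <- frequent
  prevKeys <- vapply(prevSets, itemsetKey, "")
  while (length(prevSets) > 1) {
    # join step: sorted itemsets sharing all but the last item
    cand <- list()
    pref <- vapply(prevSets, function(s) itemsetKey(s[-length(s)]), "")
    last <- vapply(prevSets, function(s) s[length(s)], "")
    ord <- order(pref, last)
    prevSets <- prevSets[ord]; pref <- pref[ord]; last <- last[ord]
    i <- 1L
    while (i <= length(prevSets)) {
      j <- i
      while (j <= length(prevSets) && pref[j] == pref[i]) j <- j + 1L
      grp <- i:(j - 1L)
      if (length(grp) > 1)
        for (a in grp) for (b in grp) if (a < b)
          cand[[length(cand) + 1L]] <- c(prevSets[[a]], last[b])
      i <- j
    }
    if (!length(cand)) break
    # prune step: all (k-1)-subsets must be frequent
    keepC <- vapply(cand, function(s) {
      all(vapply(seq_along(s),
                 function(d) itemsetKey(s[-d]) %in% prevKeys, TRUE))
    }, TRUE)
    cand <- cand[keepC]
    if (!length(cand)) break
    cnt <- vapply(cand, function(s) sum(rowSums(inc[, s, drop = FALSE]) ==
                                          length(s)), 0)
    keep <- which(cnt / n > minSupport)
    prevSets <- cand[keep]
    prevKeys <- vapply(prevSets, itemsetKey, "")
    for (k in seq_along(prevSets))
      emit[[length(emit) + 1L]] <- list(items = prevSets[[k]],
                                        count = as.integer(cnt[keep[k]]))
  }
  out <- data.frame(size = vapply(emit, function(e) length(e$items), 0L),
                    count = vapply(emit, function(e) e$count, 0L))
  out$items <- lapply(emit, function(e) e$items)
  out$support <- out$count / n
  lab <- vapply(out$items, function(s) paste(s, collapse = ", "), "")
  out <- out[order(out$size, lab), c("items", "size", "count", "support")]
  rownames(out) <- NULL
  out
}

#' Interest metrics of an association rule from raw counts
#'
#' Given the joint count of antecedent-and-consequent, the two marginal
#' counts, and the cohort size, returns the four rule metrics:
#' support = n(A,B)/N, confidence = n(A,B)/n(A),
#' lift = support / (P(A) P(B)), and the interest-support score
#' IS = sqrt(support x lift), equivalently support / sqrt(P(A) P(B)) (the
#' cosine measure). A zero joint count yields all-zero metrics.
#'
#' @param countAB joint count, `0 <= countAB <= min(countA, countB)`.
#' @param countA,countB marginal counts, both positive.
#' @param n cohort size.
#' @return named list with `support`, `confidence`, `lift`, `isScore`
#'   at full precision.
#' @export
#' @examples
#' m <- computeMetrics(11740, 21893, 34665, 169959)
#' roundHalfUp(unlist(m), 3) # 0.069 0.536 2.629 0.426
computeMetrics <- function(countAB, countA, countB, n) {
  if (n < 1) stopf("computeMetrics: n must be >= 1")
  if (countA <= 0 || countB <= 0)
    stopf("computeMetrics: undefined rule (zero marginal count)")
  if (countAB < 0 || countAB > min(countA, countB) || max(countA, countB) > n)
    stopf("computeMetrics: inconsistent counts")
  if (countAB == 0)
    return(list(support = 0, confidence = 0, lift = 0, isScore = 0))
  countAB <- as.numeric(countAB); countA <- as.numeric(countA)
  countB <- as.numeric(countB); n <- as.numeric(n)
  support <- countAB / n
  confidence <- countAB / countA
  # count products stay exact in doubles (never near 2^53 for registry
  # sizes), so lift == 1 is detected exactly at the strict threshold,
  # where support/(P(A)P(B)) can round past 1
  lift <- (countAB * n) / (countA * countB)
  list(support = support, confidence = confidence, lift = lift,
       isScore = sqrt(support * lift))
}

#' Generate association rules from frequent itemsets
#'
#' For every frequent itemset of size >= 2 and every choice of consequent
#' (single items by default, as in disease-pair mining), emits the rule iff
#' confidence is strictly above `minConfidence` ("minimum reliability") and
#' lift strictly above `minLift` (lift <= 1 marks coincidental or negative
#' patterns). All marginal counts are looked up in the frequent-itemset table
#' itself; by anti-monotonicity every antecedent and consequent of an emitted
#' rule is frequent, so a missing entry is an internal consistency error.
#'
#' @param frequent frequent-itemset `data.frame` from [apriori()].
#' @param n number of transactions the itemsets were counted over.
#' @param minConfidence strict confidence threshold (default 0.1).
#' @param minLift strict lift threshold (default 1).
#' @param singleConsequent restrict consequents to single items (default
#'   TRUE); FALSE allows every proper non-empty subset as consequent.
#' @return a [RuleSet-class] (unranked; see [rankRules()]).
#' @export
generateRules <- function(frequent, n, minConfidence = 0.1, minLift = 1,
                          singleConsequent = TRUE) {
  countOf <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(frequent)))
    assign(itemsetKey(frequent$items[[i]]), frequent$count[i], envir = countOf)
  lookup <- function(items) {
    key <- itemsetKey(items)
    if (!exists(key, envir = countOf, inherits = FALSE))
      stopf("generateRules: missing frequent sub-itemset {%s}",
            paste(items, collapse = ", "))
    get(key, envir = countOf)
  }
  singles <- frequent[frequent$size == 1, , drop = FALSE]
  itemSup <- stats::setNames(singles$support,
                             vapply(singles$items, `[[`, "", 1))
  rows <- list()
  big <- frequent[frequent$size >= 2, , drop = FALSE]
  for (i in seq_len(nrow(big))) {
    set <- big$items[[i]]
    nAB <- big$count[i]
    maxK <- if (singleConsequent) 1L else length(set) - 1L
    for (k in seq_len(maxK)) {
      cons <- utils::combn(set, k, simplify = FALSE)
      for (cq in cons) {
        ant <- setdiff(set, cq)
        m <- computeMetrics(nAB, lookup(ant), lookup(cq), n)
        if (m$confidence > minConfidence && m$lift > minLift)
          rows[[length(rows) + 1L]] <- list(
            antecedent = sort(ant), consequent = sort(cq),
            count = nAB, support = m$support, confidence = m$confidence,
            lift = m$lift, isScore = m$isScore)
      }
    }
  }
  rules <- data.frame(
    count = vapply(rows, function(r) as.integer(r$count), 0L),
    support = vapply(rows, function(r) r$support, 0),
    confidence = vapply(rows, function(r) r$confidence, 0),
    lift = vapply(rows, function(r) r$lift, 0),
    isScore = vapply(rows, function(r) r$isScore, 0)
  )
  rules$antecedent <- lapply(rows, function(r) r$antecedent)
  rules$consequent <- lapply(rows, function(r) r$consequent)
  rules$label <- ruleLabel(rules$antecedent, rules$consequent)
  rules <- rules[, c("antecedent", "consequent", "label", "count",
                     "support", "confidence", "lift", "isScore")]
  new("RuleSet", rules = rules, nTransactions = as.integer(n),
      itemSupport = itemSup,
      thresholds = c(minSupport = NA_real_, minConfidence = minConfidence,
                     minLift = minLift))
}

ruleLabel <- function(antecedents, consequents) {
  if (!length(antecedents)) return(character(0))
  mapply(function(a, b) sprintf("(%s) -> (%s)", paste(a, collapse = ", "),
                                paste(b, collapse = ", ")),
         antecedents, consequents, USE.NAMES = FALSE)
}

#' Rank rules by interest support
#'
#' Orders rules by descending IS score; ties are broken by descending
#' confidence (the convention of the published rule table, where each
#' bidirectional pair lists the higher-confidence direction first), then by
#' descending count, then lexicographically by rule label, giving a
#' deterministic total order. A `rank` column is added.
#'
#' @param ruleSet a [RuleSet-class].
#' @return the [RuleSet-class] with rules reordered and a `rank` column.
#' @export
rankRules <- function(ruleSet) {
  r <- ruleTable(ruleSet)
  if (nrow(r)) {
    r <- r[order(-r$isScore, -r$confidence, -r$count, r$label), , drop = FALSE]
    r$rank <- seq_len(nrow(r))
    rownames(r) <- NULL
  } else r$rank <- integer(0)
  ruleSet@rules <- r
  ruleSet
}

#' Mine ranked association rules from transactions
#'
#' Convenience front-end: [apriori()] then [generateRules()] then
#' [rankRules()], with the study's default thresholds (support > 0.01,
#' confidence > 0.1, lift > 1, all strict).
#'
#' @inheritParams apriori
#' @inheritParams generateRules
#' @return a ranked [RuleSet-class].
#' @export
mineRules <- function(transactions, minSupport = 0.01, minConfidence = 0.1,
                      minLift = 1, singleConsequent = TRUE) {
  freq <- apriori(transactions, minSupport = minSupport)
  rs <- generateRules(freq, n = nTransactions(transactions),
                      minConfidence = minConfidence, minLift = minLift,
                      singleConsequent = singleConsequent)
  rs@thresholds["minSupport"] <- minSupport
  rankRules(rs)
}

#' Format a ranked rule table for reporting
#'
#' @param ruleSet a ranked [RuleSet-class].
#' @param digits decimals for the four metrics (half-up rounding; default 3,
#'   as printed in the source tables).
#' @return `data.frame` with columns `rank`, `rule`, `count`, `support`,
#'   `confidence`, `lift`, `IS`.
#' @export
formatRuleTable <- function(ruleSet, digits = 3) {
  r <- ruleTable(ruleSet)
  data.frame(rank = r$rank %||% seq_len(nrow(r)),
             rule = r$label, count = r$count,
             support = roundHalfUp(r$support, digits),
             confidence = roundHalfUp(r$confidence, digits),
             lift = roundHalfUp(r$lift, digits),
             IS = roundHalfUp(r$isScore, digits),
             stringsAsFactors = FALSE)
}
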