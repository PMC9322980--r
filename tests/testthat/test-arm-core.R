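test_that("transactions are built from flags and site labels", {
  prof <- data.frame(
    record_id = c("a", "b", "c"),
    dm = c(TRUE, FALSE, FALSE), htn = c(TRUE, FALSE, FALSE),
    hyperthyroidism = FALSE, hypothyroidism = FALSE,
    cancer_site = factor(c("liver", "other", "other"),
                         levels = c("liver", "other"))
  )
  tx <- buildTransactions(prof)
  expect_equal(nTransactions(tx), 3)
  expect_setequal(transactionItems(tx)[["a"]], c("DM", "HTN", "Liver cancer"))
  expect_equal(transactionItems(tx)[["b"]], "Other")
  # excluding the Other item leaves an empty itemset that still counts in N
  tx2 <- buildTransactions(prof, includeOther = FALSE)
  expect_equal(nTransactions(tx2), 3)
  expect_length(transactionItems(tx2)[["b"]], 0)
  expect_error(buildTransactions(prof[0, ]), "no profiles")
})

test_that("apriori equals exhaustive enumeration on a handcrafted set", {
  txList <- list(c("A", "B", "C"), c("A", "B"), c("B", "C"), "D",
                 c("A", "B", "C"))
  oracle <- bruteForceMine(txList, minSupport = 0.2)
  freq <- apriori(asTransactions(txList), minSupport = 0.2)
  gotKeys <- vapply(freq$items, setKey, "")
  expect_setequal(gotKeys, names(oracle$frequent))
  for (i in seq_len(nrow(freq)))
    expect_equal(freq$count[i], oracle$frequent[[gotKeys[i]]]$count)
})

test_that("single-transaction edge cases behave", {
  tx <- asTransactions(list("A"))
  freq <- apriori(tx, minSupport = 0.999)
  expect_equal(vapply(freq$items, setKey, ""), "A")
  expect_error(apriori(asTransactions(list()), minSupport = 0.1),
               "no transactions")
  expect_error(apriori(tx, minSupport = 0), "minSupport")
})

test_that("metric arithmetic matches definitions and degenerate cases", {
  m <- computeMetrics(11740, 21893, 34665, 169959)
  expect_equal(roundHalfUp(unlist(m), 3),
               c(support = 0.069, confidence = 0.536, lift = 2.629,
                 isScore = 0.426))
  expect_equal(unlist(computeMetrics(0, 10, 10, 100)),
               c(support = 0, confidence = 0, lift = 0, isScore = 0))
  expect_equal(unlist(computeMetrics(50, 50, 50, 50)),
               c(support = 1, confidence = 1, lift = 1, isScore = 1))
  expect_error(computeMetrics(5, 0, 10, 100), "undefined rule")
  expect_error(computeMetrics(20, 10, 30, 100), "inconsistent")
})

test_that("rule generation applies strict thresholds", {
  # A and B independent (lift exactly 1) -> excluded; C co-occurs with A
  txList <- c(rep(list(c("A", "B")), 2), rep(list("A"), 2),
              rep(list("B"), 2), rep(list(character(0)), 2))
  freq <- apriori(asTransactions(txList, c("A", "B")), minSupport = 0.1)
  rs <- generateRules(freq, n = 8, minConfidence = 0.1, minLift = 1)
  expect_equal(nrow(ruleTable(rs)), 0)  # lift == 1 is excluded

  txList2 <- rep(list(c("A", "B"), "C"), 5)
  rs2 <- mineRules(asTransactions(txList2), minSupport = 0.1,
                   minConfidence = 0.1, minLift = 1)
  r2 <- ruleTable(rs2)
  expect_equal(sort(r2$label), sort(c("(A) -> (B)", "(B) -> (A)")))
  expect_equal(r2$confidence, c(1, 1))  # always co-occur
  expect_equal(r2$lift, c(2, 2))
})

test_that("mined rules equal brute-force enumeration on random toys", {
  set.seed(9021)
  for (rep in 1:40) {
    txList <- randomToyTransactions(sample(3:7, 1), sample(5:40, 1))
    if (!length(unlist(txList))) next
    ms <- sample(c(0.02, 0.1, 0.25), 1)
    mc <- sample(c(0, 0.2), 1)
    ml <- sample(c(0, 1), 1)
    oracle <- bruteForceMine(txList, ms, mc, ml)
    rs <- mineRules(asTransactions(txList), minSupport = ms,
                    minConfidence = mc, minLift = ml)
    got <- ruleTable(rs)
    gotKeys <- if (nrow(got))
      paste(vapply(got$antecedent, setKey, ""), "=>",
            vapply(got$consequent, setKey, ""))
    else character(0)
    expect_setequal(gotKeys, as.character(names(oracle$rules)))
    for (i in seq_along(gotKeys)) {
      o <- oracle$rules[[gotKeys[i]]]
      expect_equal(got$support[i], o$support, tolerance = 1e-14)
      expect_equal(got$confidence[i], o$confidence, tolerance = 1e-14)
      expect_equal(got$lift[i], o$lift, tolerance = 1e-14)
      expect_equal(got$isScore[i], o$isScore, tolerance = 1e-14)
    }
  }
})

test_that("anti-monotonicity: subsets of frequent itemsets are frequent", {
  set.seed(77)
  txList <- randomToyTransactions(6, 80)
  freq <- apriori(asTransactions(txList), minSupport = 0.05)
  keys <- vapply(freq$items, setKey, "")
  for (i in which(freq$size >= 2)) {
    s <- freq$items[[i]]
    for (d in seq_along(s))
      expect_true(setKey(s[-d]) %in% keys)
  }
})

test_that("ranking reconstructs the published 22-rule order", {
  t3 <- table3Counts()
  rows <- lapply(t3$rules, function(r) {
    m <- computeMetrics(r$ab, r$a, r$b, t3$N)
    data.frame(count = r$ab, support = m$support, confidence = m$confidence,
               lift = m$lift, isScore = m$isScore)
  })
  rules <- do.call(rbind, rows)
  rules$antecedent <- lapply(t3$rules, `[[`, "ant")
  rules$consequent <- lapply(t3$rules, function(r) r$cons)
  rules$label <- mapply(function(a, b)
    sprintf("(%s) -> (%s)", paste(a, collapse = ", "), b),
    rules$antecedent, rules$consequent)
  rs <- new("RuleSet", rules = rules, nTransactions = as.integer(t3$N),
            itemSupport = t3$marginals[1:6] / t3$N,
            thresholds = c(minSupport = 0.01, minConfidence = 0.1,
                           minLift = 1))
  ranked <- ruleTable(rankRules(rs))
  expect_equal(ranked$label,
               mapply(function(r) sprintf("(%s) -> (%s)",
                                          paste(r$ant, collapse = ", "),
                                          r$cons), t3$rules),
               ignore_attr = TRUE)
})

test_that("ranking is a deterministic total order under exact ties", {
  mk <- function(lbl, is, conf, cnt) data.frame(
    label = lbl, count = cnt, support = 0.1, confidence = conf,
    lift = 2, isScore = is)
  rules <- rbind(mk("(B) -> (C)", 0.5, 0.3, 10), mk("(A) -> (C)", 0.5, 0.3, 10),
                 mk("(C) -> (A)", 0.6, 0.2, 5))
  rules$antecedent <- list("B", "A", "C")
  rules$consequent <- list("C", "C", "A")
  rs <- new("RuleSet", rules = rules, nTransactions = 100L,
            itemSupport = c(A = 0.2, B = 0.2, C = 0.5),
            thresholds = c(minSupport = 0.01, minConfidence = 0.1, minLift = 1))
  for (i in 1:3)
    expect_equal(ruleTable(rankRules(rs))$label,
                 c("(C) -> (A)", "(A) -> (C)", "(B) -> (C)"))
  empty <- rankRules(mineRules(asTransactions(list("A", "B")),
                               minSupport = 0.9))
  expect_equal(nrow(ruleTable(empty)), 0)
})
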