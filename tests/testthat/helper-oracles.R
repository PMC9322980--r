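# Independent oracles and toy-data builders shared across tests.
# The brute-force miner enumerates every itemset and every rule split
# directly from the raw transactions, using its own metric formulas; it
# never calls the package's miner.

setKey <- function(items) paste(sort(items), collapse = "|")

bruteForceMine <- function(itemsList, minSupport, minConfidence = 0.1,
                           minLift = 1) {
  n <- length(itemsList)
  universe <- sort(unique(unlist(itemsList)))
  M <- sapply(universe, function(it)
    vapply(itemsList, function(tx) it %in% tx, TRUE))
  if (is.null(dim(M))) M <- matrix(M, nrow = n, dimnames = list(NULL, universe))
  countSet <- function(s)
    sum(rowSums(M[, s, drop = FALSE]) == length(s))
  freq <- list()
  for (k in seq_along(universe)) {
    for (s in utils::combn(universe, k, simplify = FALSE)) {
      cnt <- countSet(s)
      if (cnt / n > minSupport)
        freq[[setKey(s)]] <- list(items = sort(s), count = cnt)
    }
  }
  rules <- list()
  for (f in freq) {
    if (length(f$items) < 2) next
    for (cons in f$items) {
      ant <- setdiff(f$items, cons)
      nA <- countSet(ant); nB <- countSet(cons)
      sup <- f$count / n
      conf <- f$count / nA
      lift <- f$count * n / (nA * nB)
      is <- sup / sqrt((nA / n) * (nB / n))
      if (conf > minConfidence && lift > minLift)
        rules[[paste(setKey(ant), "=>", cons)]] <-
          list(antecedent = sort(ant), consequent = cons, count = f$count,
               support = sup, confidence = conf, lift = lift, isScore = is)
    }
  }
  list(frequent = freq, rules = rules)
}

# random toy transaction list over letters
randomToyTransactions <- function(nItems, nTx) {
  universe <- LETTERS[seq_len(nItems)]
  lapply(seq_len(nTx), function(i) {
    k <- sample(0:nItems, 1)
    if (k == 0) character(0) else sample(universe, k)
  })
}

# wrap a raw transaction list in the package's Transactions class
asTransactions <- function(itemsList,
                           universe = as.character(sort(unique(unlist(itemsList))))) {
  new("Transactions",
      items = lapply(itemsList, function(x) unname(sort(x))),
      recordId = sprintf("t%04d", seq_along(itemsList)),
      itemLabels = universe)
}

# minimal valid discharge record(s) for io/phenotyping tests
makeRecords <- function(n = 1, principal = "C16.0", age = 60L,
                        secondary = "", procedures = "", surgery = "",
                        outcome = "improved", sex = "male") {
  data.frame(
    record_id = sprintf("r%03d", seq_len(n)),
    sex = rep_len(sex, n),
    age_years = rep_len(as.integer(age), n),
    insurance_type = rep_len("national_health", n),
    admission_route = rep_len("outpatient", n),
    treatment_outcome = rep_len(outcome, n),
    principal_dx = rep_len(principal, n),
    secondary_dx = rep_len(secondary, n),
    procedure_codes = rep_len(procedures, n),
    main_surgery_code = rep_len(surgery, n),
    stringsAsFactors = FALSE
  )
}

# profiles data.frame with given flag counts, for prevalence tests
makeFlagProfiles <- function(strata, totals, flagCounts, stratifier = "g",
                             flagName = "f") {
  out <- data.frame(
    s = rep(strata, totals),
    f = unlist(mapply(function(tot, yes) rep(c(TRUE, FALSE), c(yes, tot - yes)),
                      totals, flagCounts, SIMPLIFY = FALSE))
  )
  names(out) <- c(stratifier, flagName)
  out
}

# The published 22-rule table reconstructed from its printed counts and the
# cohort marginals (N, DM, HTN and the four major-site totals), together with
# the printed values of the four metrics (3 dp).
table3Counts <- function() {
  N <- 169959
  marg <- c(DM = 21893, HTN = 34665, Liver = 19924, Lung = 21227,
            Colorectal = 21043, Stomach = 22198,
            `DM+HTN` = 11740, `HTN+Liver` = 4534, `DM+Lung` = 3260,
            `HTN+Lung` = 5541, `DM+Liver` = 4254)
  r <- function(ant, cons, ab, sup, conf, lift, is)
    list(ant = ant, cons = cons, ab = ab, a = unname(marg[paste(ant, collapse = "+")]),
         b = unname(marg[cons]), sup = sup, conf = conf, lift = lift, is = is)
  rules <- list(
    r("DM", "HTN", 11740, 0.069, 0.536, 2.629, 0.426),
    r("HTN", "DM", 11740, 0.069, 0.339, 2.629, 0.426),
    r("Lung", "HTN", 5541, 0.033, 0.261, 1.280, 0.204),
    r("HTN", "Lung", 5541, 0.033, 0.160, 1.280, 0.204),
    r("Liver", "DM", 4254, 0.025, 0.214, 1.658, 0.204),
    r("DM", "Liver", 4254, 0.025, 0.194, 1.658, 0.204),
    r(c("HTN", "Liver"), "DM", 1964, 0.012, 0.433, 3.363, 0.197),
    r("Colorectal", "HTN", 4861, 0.029, 0.231, 1.133, 0.180),
    r("HTN", "Colorectal", 4861, 0.029, 0.140, 1.133, 0.180),
    r("Stomach", "HTN", 4854, 0.029, 0.219, 1.072, 0.175),
    r("HTN", "Stomach", 4854, 0.029, 0.140, 1.072, 0.175),
    r("Liver", "HTN", 4534, 0.027, 0.228, 1.116, 0.173),
    r("HTN", "Liver", 4534, 0.027, 0.131, 1.116, 0.173),
    r(c("DM", "Lung"), "HTN", 1813, 0.011, 0.556, 2.727, 0.171),
    r(c("HTN", "Lung"), "DM", 1813, 0.011, 0.327, 2.540, 0.165),
    r(c("DM", "Liver"), "HTN", 1964, 0.012, 0.462, 2.264, 0.162),
    r("Lung", "DM", 3260, 0.019, 0.154, 1.192, 0.151),
    r("DM", "Lung", 3260, 0.019, 0.149, 1.192, 0.151),
    r("Colorectal", "DM", 2829, 0.017, 0.134, 1.044, 0.132),
    r("DM", "Colorectal", 2829, 0.017, 0.129, 1.044, 0.132),
    r(c("DM", "HTN"), "Liver", 1964, 0.012, 0.167, 1.427, 0.128),
    r(c("DM", "HTN"), "Lung", 1813, 0.011, 0.154, 1.236, 0.115)
  )
  list(N = N, marginals = marg, rules = rules)
}
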