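syntheticProfiles <- function(n, seed) {
  co <- generateCohort(syntheticCohortConfig(n = n, seed = seed))
  phenotypeCohort(filterCohort(co, quiet = TRUE))
}

test_that("intercept-only fit recovers logit of the event fraction", {
  prof <- syntheticProfiles(4000, 5)
  d <- buildDesign(prof)
  d$design <- d$design[, 0, drop = FALSE]  # no covariates
  fit <- fitMortality(d)
  p <- mean(d$outcome)
  expect_equal(coefTable(fit)$B[coefTable(fit)$term == "intercept"],
               stats::qlogis(p), tolerance = 1e-8)
})

test_that("single binary covariate equals the 2x2 closed-form log OR", {
  set.seed(31)
  x <- rep(c(1L, 0L), c(300, 700))
  y <- c(stats::runif(300) < 0.25, stats::runif(700) < 0.10)
  fit <- fitMortality(list(design = data.frame(exposure = x), outcome = y,
                           subset = "all"))
  n11 <- sum(x == 1 & y); n10 <- sum(x == 1 & !y)
  n01 <- sum(x == 0 & y); n00 <- sum(x == 0 & !y)
  expect_equal(coefTable(fit)$B[coefTable(fit)$term == "exposure"],
               log(n11 * n00 / (n10 * n01)), tolerance = 1e-6)
  # closed-form SE of a 2x2 log odds ratio
  expect_equal(coefTable(fit)$SE[coefTable(fit)$term == "exposure"],
               sqrt(1 / n11 + 1 / n10 + 1 / n01 + 1 / n00), tolerance = 1e-4)
})

test_that("zero-variance and inestimable terms are dropped with reasons", {
  prof <- syntheticProfiles(3000, 7)
  prof$radiotherapy <- FALSE                      # zero variance
  prof$hyperthyroidism <- !prof$died & seq_len(nrow(prof)) <= 30
  # hyperthyroid only among survivors -> no deaths among exposed
  fit <- fitMortality(buildDesign(prof))
  dr <- droppedTerms(fit)
  expect_true("radiotherapy" %in% dr$term)
  expect_match(dr$reason[dr$term == "radiotherapy"], "zero variance")
  expect_true("hyperthyroidism" %in% dr$term)
  expect_match(dr$reason[dr$term == "hyperthyroidism"], "no deaths")
  expect_false("radiotherapy" %in% coefTable(fit)$term)
})

test_that("degenerate outcomes error; fits are permutation invariant", {
  prof <- syntheticProfiles(500, 9)
  prof$died <- FALSE
  expect_error(fitMortality(buildDesign(prof)), "degenerate")

  prof2 <- syntheticProfiles(3000, 13)
  d <- buildDesign(prof2)
  f1 <- fitMortality(d)
  perm <- sample(nrow(d$design))
  f2 <- fitMortality(list(design = d$design[perm, ], outcome = d$outcome[perm],
                          subset = "all"))
  expect_equal(coefTable(f1)$B, coefTable(f2)$B, tolerance = 1e-8)
})

test_that("subset designs restrict rows; empty subsets error", {
  prof <- syntheticProfiles(5000, 21)
  d <- buildDesign(prof, subset = "liver")
  expect_equal(nrow(d$design), sum(prof$cancer_site == "liver"))
  expect_equal(d$subset, "liver")
  prof2 <- prof[prof$cancer_site != "anal", ]
  expect_error(buildDesign(prof2, subset = "anal"), "empty subset")
})

test_that("OR/CI reporting arithmetic matches the Wald closed form", {
  w <- waldOddsRatio(0.235, 0.065)
  expect_equal(roundHalfUp(w$OR, 3), 1.265)
  expect_equal(w$ciLow, exp(0.235 - stats::qnorm(0.975) * 0.065),
               tolerance = 1e-12)
  w0 <- waldOddsRatio(0, 0.1)
  expect_equal(w0$OR, 1)
  expect_equal(w0$ciLow * w0$ciHigh, 1, tolerance = 1e-12) # symmetric in log
  expect_equal(w0$p, 1)

  prof <- syntheticProfiles(3000, 23)
  rep <- oddsRatioReport(fitMortality(buildDesign(prof)))
  expect_false("intercept" %in% rep$term)
  expect_true(all(rep$ciLow <= rep$OR & rep$OR <= rep$ciHigh))
})

test_that("forest-plot data is long-format with omissions recorded", {
  prof <- syntheticProfiles(20000, 29)
  fits <- list(all = fitMortality(buildDesign(prof)),
               liver = fitMortality(buildDesign(prof, subset = "liver")))
  fp <- forestPlotData(fits)
  expect_true(all(fp$term %in% c("dm", "htn", "hypothyroidism",
                                 "hyperthyroidism")))
  expect_true(nrow(fp) <= 8)
  expect_setequal(unique(fp$cancer), c("all", "liver"))
  omitted <- attr(fp, "omitted")
  expect_equal(nrow(fp) + nrow(omitted), 8)
  expect_error(forestPlotData(list()), "no fits")
  expect_s3_class(plotForest(fp), "ggplot")
})
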