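test_that("code normalization strips dots and case, rejects garbage", {
  expect_equal(normalizeCode(c("e11.5", "I10", "C34.9", " 99.25")),
               c("E115", "I10", "C349", "9925"))
  expect_error(normalizeCode(""), "invalid code")
  expect_error(normalizeCode("C34-9"), "invalid code")
})

test_that("range membership follows category/subdivision semantics", {
  # diabetes range E11.0-E14.9
  expect_true(codeInRange("E115", "E110", "E149"))
  expect_false(codeInRange("E101", "E110", "E149")) # type 1 precedes range
  expect_true(codeInRange("E11", "E110", "E149"))   # bare category inside
  expect_false(codeInRange("E109", "E110", "E149"))
  # lung range C33-C34.9: bare-category endpoint covers the whole category
  expect_true(codeInRange("C33", "C33", "C349"))
  expect_true(codeInRange("C331", "C33", "C349"))
  expect_false(codeInRange("C35", "C33", "C349"))
  # single bare-category interval I10 covers its subdivisions, not I11
  expect_true(codeInRange("I10", "I10", "I10"))
  expect_true(codeInRange("I101", "I10", "I10"))
  expect_false(codeInRange("I11", "I10", "I10"))
  # E89.0 endpoint does not leak to E89.1
  expect_true(codeInRange("E890", "E890", "E890"))
  expect_false(codeInRange("E891", "E890", "E890"))
})

test_that("default code map is valid and round-trips through YAML", {
  cm <- defaultCodeMap()
  expect_true(validObject(cm))
  expect_setequal(
    setdiff(siteLabels(cm), "other"),
    c("stomach", "lung", "colorectal", "liver", "pancreatic", "bile_duct",
      "gallbladder", "small_intestine", "multiple_myeloma", "kidney",
      "ureter", "bladder", "laryngeal", "prostate", "anal", "esophageal"))
  path <- withr::local_tempfile(fileext = ".yaml")
  writeCodeMap(cm, path)
  cm2 <- readCodeMap(path)
  expect_equal(codeIntervals(cm2)[order(codeIntervals(cm2)$label,
                                        codeIntervals(cm2)$start), ],
               codeIntervals(cm)[order(codeIntervals(cm)$label,
                                       codeIntervals(cm)$start), ],
               ignore_attr = TRUE)
})

test_that("overlapping site ranges are rejected by CodeMap validity", {
  expect_error(
    codeMap(list(
      dm = list(system = "icd10_dx", codes = "E11.0-E14.9"),
      htn = list(system = "icd10_dx", codes = "I10"),
      hyperthyroidism = list(system = "icd10_dx", codes = "E05.0-E05.9"),
      hypothyroidism = list(system = "icd10_dx", codes = "E02-E03.9"),
      chemotherapy = list(system = "icd9cm_proc", codes = "99.25"),
      radiotherapy = list(system = "icd9cm_proc", codes = "92.21-92.27"),
      liver = list(system = "icd10_dx", codes = "C22.0-C22.9"),
      bile_duct = list(system = "icd10_dx", codes = "C22.1-C24.9")
    ), siteLabels = c("liver", "bile_duct", "other")),
    "overlap")
})

test_that("phenotyping maps codes to flags, site and groups as defined", {
  rec <- makeRecords(1, principal = "C22.0", secondary = "E11.9;I10")
  p <- phenotypeRecord(rec)
  expect_equal(as.character(p$cancer_site), "liver")
  expect_true(p$dm); expect_true(p$htn)
  expect_false(p$hyperthyroidism); expect_false(p$chemotherapy)

  p2 <- phenotypeRecord(makeRecords(1, principal = "C16.4"))
  expect_equal(as.character(p2$cancer_site), "stomach")
  expect_false(any(unlist(p2[c("dm", "htn", "hyperthyroidism",
                               "hypothyroidism", "surgery", "chemotherapy",
                               "radiotherapy")])))

  # chemotherapy via procedure 99.25 or diagnosis Z51.1; radiotherapy range
  expect_true(phenotypeRecord(makeRecords(1, procedures = "99.25"))$chemotherapy)
  expect_true(phenotypeRecord(makeRecords(1, secondary = "Z51.1"))$chemotherapy)
  expect_true(phenotypeRecord(makeRecords(1, procedures = "92.24"))$radiotherapy)
  expect_true(phenotypeRecord(makeRecords(1, procedures = "92.29"))$radiotherapy)
  expect_false(phenotypeRecord(makeRecords(1, procedures = "92.28"))$radiotherapy)

  # surgery from non-empty main surgery code; death from outcome
  expect_true(phenotypeRecord(makeRecords(1, surgery = "OP9"))$surgery)
  expect_true(phenotypeRecord(makeRecords(1, outcome = "death"))$died)

  # age groups at the cut points
  ages <- c(19, 44, 45, 64, 65, 74, 75, 90)
  pr <- phenotypeCohort(makeRecords(8, age = ages))
  expect_equal(as.character(pr$age_group),
               c("19-44", "19-44", "45-64", "45-64", "65-74", "65-74",
                 "75+", "75+"))
})

test_that("a malignant principal outside named sites falls back to other", {
  p <- phenotypeRecord(makeRecords(1, principal = "C50.9"))
  expect_equal(as.character(p$cancer_site), "other")
  expect_error(phenotypeCohort(makeRecords(1, principal = "I10")),
               "outside C00-C97")
})

test_that("phenotype is order-independent and flags are monotone", {
  a <- phenotypeRecord(makeRecords(1, secondary = "E11.9;I10;E03.9"))
  b <- phenotypeRecord(makeRecords(1, secondary = "E03.9;I10;E11.9"))
  expect_identical(a, b)
  # adding a code never turns a true flag false
  base <- phenotypeRecord(makeRecords(1, secondary = "E11.9"))
  more <- phenotypeRecord(makeRecords(1, secondary = "E11.9;E05.0;I10"))
  flags <- c("dm", "htn", "hyperthyroidism", "hypothyroidism")
  expect_true(all(unlist(more[flags]) >= unlist(base[flags])))
})

test_that("every record gets exactly one site label (partition property)", {
  set.seed(424)
  co <- generateCohort(syntheticCohortConfig(n = 2000, seed = 17))
  pr <- phenotypeCohort(co)
  expect_false(anyNA(pr$cancer_site))
  expect_equal(nrow(pr), nrow(co))
})
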