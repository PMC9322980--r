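.ageBreaks <- c(19, 45, 65, 75, Inf)
.ageLabels <- c("19-44", "45-64", "65-74", "75+")

# split a vector of joined list-cells into a long (row, code) frame
explodeCodes <- function(cells, listSep = ";") {
  cells[is.na(cells)] <- ""
  parts <- strsplit(cells, listSep, fixed = TRUE)
  parts <- lapply(parts, function(x) x[nzchar(trimws(x))])
  n <- lengths(parts)
  data.frame(row = rep.int(seq_along(cells), n),
             code = trimws(unlist(parts)) %||% character(0),
             stringsAsFactors = FALSE)
}

# TRUE for rows having any code of `label` (in `system`) in the long frame
anyCodeMatch <- function(long, nRows, intervals, label, system) {
  out <- rep(FALSE, nRows)
  if (!nrow(long)) return(out)
  iv <- intervals[intervals$label == label & intervals$system == system, ,
                  drop = FALSE]
  if (!nrow(iv)) return(out)
  hit <- codeInLabel(long$code, iv)
  out[unique(long$row[hit])] <- TRUE
  out
}

#' Phenotype a filtered cohort
#'
#' Maps each discharge episode to boolean disease and treatment flags and a
#' single cancer-site label. Comorbidity flags (DM, hypertension,
#' hyper-/hypothyroidism) are true if ANY diagnosis, principal or secondary,
#' falls in the label's code ranges — in a cohort whose principal diagnosis is
#' a malignancy by definition, comorbidities can only appear in secondary
#' position. Chemotherapy is true on either the 99.25 procedure or the Z51.1
#' diagnosis; radiotherapy on procedures 92.21--92.27 or 92.29; surgery iff
#' the main surgery code is non-empty. The cancer site comes from the
#' principal diagnosis alone; principal codes inside C00--C97 but outside all
#' named site ranges are labelled `"other"`.
#'
#' @param cohort a filtered cohort `data.frame` (see [filterCohort()]).
#' @param map a [CodeMap-class] (default [defaultCodeMap()]).
#' @param listSep separator used in the list-valued cells.
#' @return a `data.frame` of phenotype profiles with columns `record_id`,
#'   `dm`, `htn`, `hyperthyroidism`, `hypothyroidism`, `surgery`,
#'   `chemotherapy`, `radiotherapy`, `cancer_site`, `died`, `sex`,
#'   `age_group`.
#' @export
#' @examples
#' rec <- data.frame(record_id = "r1", sex = "male", age_years = 60L,
#'   insurance_type = "national_health", admission_route = "outpatient",
#'   treatment_outcome = "improved", principal_dx = "C22.0",
#'   secondary_dx = "E11.9;I10", procedure_codes = "",
#'   main_surgery_code = "")
#' phenotypeCohort(rec)[, c("cancer_site", "dm", "htn")]
phenotypeCohort <- function(cohort, map = defaultCodeMap(), listSep = ";") {
  n <- nrow(cohort)
  if (!n) stopf("phenotypeCohort: empty cohort")
  iv <- codeIntervals(map)
  principal <- normalizeCode(cohort$principal_dx)
  if (!all(codeInRange(principal, "C00", "C979")))
    stopf("phenotypeCohort: principal diagnosis outside C00-C97 (run filterCohort first)")

  sec <- explodeCodes(cohort$secondary_dx, listSep)
  if (nrow(sec)) sec$code <- normalizeCode(sec$code)
  dxLong <- rbind(data.frame(row = seq_len(n), code = principal,
                             stringsAsFactors = FALSE), sec)
  proc <- explodeCodes(cohort$procedure_codes, listSep)
  if (nrow(proc)) proc$code <- normalizeCode(proc$code)

  flag <- function(lbl) anyCodeMatch(dxLong, n, iv, lbl, "icd10_dx")
  chemo <- anyCodeMatch(proc, n, iv, "chemotherapy", "icd9cm_proc") |
    anyCodeMatch(dxLong, n, iv, "chemotherapy", "icd10_dx")
  radio <- anyCodeMatch(proc, n, iv, "radiotherapy", "icd9cm_proc")

  site <- rep("other", n)
  for (lbl in setdiff(siteLabels(map), "other")) {
    ivl <- iv[iv$label == lbl & iv$system == "icd10_dx", , drop = FALSE]
    hit <- codeInLabel(principal, ivl)
    site[hit] <- lbl   # site intervals are disjoint by CodeMap validity
  }

  surgery <- !is.na(cohort$main_surgery_code) &
    nzchar(trimws(cohort$main_surgery_code))

  data.frame(
    record_id = cohort$record_id,
    dm = flag("dm"),
    htn = flag("htn"),
    hyperthyroidism = flag("hyperthyroidism"),
    hypothyroidism = flag("hypothyroidism"),
    surgery = surgery,
    chemotherapy = chemo,
    radiotherapy = radio,
    cancer_site = factor(site, levels = siteLabels(map)),
    died = cohort$treatment_outcome == "death",
    sex = factor(cohort$sex, levels = .enumLevels$sex),
    age_group = cut(cohort$age_years, breaks = .ageBreaks,
                    labels = .ageLabels, right = FALSE),
    stringsAsFactors = FALSE
  )
}

#' @rdname phenotypeCohort
#' @param record a one-row cohort `data.frame`.
#' @export
phenotypeRecord <- function(record, map = defaultCodeMap(), listSep = ";") {
  stopifnot(nrow(record) == 1)
  phenotypeCohort(record, map = map, listSep = listSep)
}
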