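#' Normalize an ICD-10 / ICD-9-CM code string
#'
#' Uppercases and strips dots and whitespace, so `"e11.5"` becomes `"E115"`
#' and `"99.25"` becomes `"9925"`. All range matching in the package operates
#' on normalized codes; the raw form is kept only for error messages.
#'
#' @param raw character vector of raw code strings.
#' @return character vector of normalized codes.
#' @export
#' @examples
#' normalizeCode(c("e11.5", "I10", "C34.9"))
normalizeCode <- function(raw) {
  if (!length(raw)) return(character(0))
  out <- toupper(gsub("[.[:space:]]", "", as.character(raw)))
  bad <- is.na(out) | out == "" | !grepl("^[A-Z0-9]+$", out)
  if (any(bad))
    stopf("invalid code(s) after normalization: %s",
          paste(sQuote(raw[bad]), collapse = ", "))
  out
}

# Sortable key for a normalized code: 3-char category + subdivision padded
# to 4 with "0" (side = "low") or "9" (side = "high"). A bare category thus
# spans its whole subdivision range.
codeSortKey <- function(code, side = c("low", "high")) {
  side <- match.arg(side)
  fill <- if (side == "low") "0" else "9"
  paste0(substr(code, 1, 3), padRight(substring(code, 4), 4, fill))
}

#' Test ICD code membership in an inclusive code interval
#'
#' Membership uses category-and-subdivision semantics: a bare-category
#' endpoint (e.g. `"C33"` in C33--C34.9) covers the whole category, and a bare
#' category code inside the interval's category span matches (prefix
#' semantics: `"E11"` is in E11.0--E14.9). Codes must already be normalized
#' (see [normalizeCode()]).
#'
#' @param codes character vector of normalized codes.
#' @param start,end normalized interval endpoints (inclusive).
#' @return logical vector, one element per code.
#' @export
#' @examples
#' codeInRange(c("E115", "E101", "E11"), "E110", "E149") # TRUE FALSE TRUE
#' codeInRange(c("C33", "C35"), "C33", "C349")           # TRUE FALSE
codeInRange <- function(codes, start, end) {
  stopifnot(length(start) == 1, length(end) == 1)
  if (codeSortKey(start, "low") > codeSortKey(end, "high"))
    stopf("interval start %s exceeds end %s", start, end)
  cat3 <- substr(codes, 1, 3)
  sub <- substring(codes, 4)
  sCat <- substr(start, 1, 3); sSub <- substring(start, 4)
  eCat <- substr(end, 1, 3);   eSub <- substring(end, 4)
  inCat <- cat3 >= sCat & cat3 <= eCat
  lowOK <- cat3 > sCat | sub == "" |
    padRight(sub, 4, "9") >= padRight(sSub, 4, "0")
  highOK <- cat3 < eCat | sub == "" | eSub == "" |
    padRight(sub, 4, "0") <= padRight(eSub, 4, "9")
  inCat & lowOK & highOK
}

# membership of codes in all intervals of one label (OR over intervals)
codeInLabel <- function(codes, intervals, system = NULL) {
  if (!is.null(system))
    intervals <- intervals[intervals$system == system, , drop = FALSE]
  if (!nrow(intervals)) return(rep(FALSE, length(codes)))
  hit <- rep(FALSE, length(codes))
  for (i in seq_len(nrow(intervals)))
    hit <- hit | codeInRange(codes, intervals$start[i], intervals$end[i])
  hit
}

# "E11.0-E14.9" / "I10" -> normalized (start, end)
parseCodeSpec <- function(spec) {
  parts <- strsplit(spec, "-", fixed = TRUE)[[1]]
  if (length(parts) == 1) parts <- c(parts, parts)
  if (length(parts) != 2 || any(!nzchar(parts)))
    stopf("cannot parse code interval %s", sQuote(spec))
  normalizeCode(parts)
}

.siteOrder <- c("stomach", "lung", "colorectal", "liver", "pancreatic",
                "bile_duct", "gallbladder", "small_intestine",
                "multiple_myeloma", "kidney", "ureter", "bladder",
                "laryngeal", "prostate", "anal", "esophageal", "other")

#' Construct a CodeMap from interval specifications
#'
#' @param spec named list; each element is a list with fields `system` (a
#'   single system, or a vector parallel to `codes`) and `codes` (a character
#'   vector of `"START-END"` ranges or single codes, dotted or not).
#' @param siteLabels labels (a subset of the names of `spec`, plus `"other"`)
#'   treated as the cancer-site partition.
#' @return a validated [CodeMap-class] object.
#' @export
codeMap <- function(spec, siteLabels = .siteOrder) {
  rows <- lapply(names(spec), function(lbl) {
    el <- spec[[lbl]]
    sys <- rep_len(el$system, length(el$codes))
    ends <- vapply(el$codes, parseCodeSpec, character(2))
    data.frame(label = lbl, start = ends[1, ], end = ends[2, ],
               system = sys, stringsAsFactors = FALSE, row.names = NULL)
  })
  new("CodeMap", intervals = do.call(rbind, rows),
      siteLabels = siteLabels)
}

#' Default phenotype code map
#'
#' The comorbidity, treatment and cancer-site code ranges used throughout the
#' package. Comorbidities and the four printed site ranges (stomach
#' C16.0--C16.9, colorectal C18.0--C19, liver C22.0--C22.9, lung C33--C34.9)
#' follow the registry's published definitions; the remaining site ranges are
#' conventional ICD-10 site categories and are assumptions, overridable via
#' [readCodeMap()]. The liver range contains intrahepatic bile duct (C22.1),
#' so `bile_duct` is restricted to C24 to keep the site partition disjoint.
#' Chemotherapy is matched by either the ICD-9-CM procedure 99.25 or the
#' ICD-10 diagnosis Z51.1; radiotherapy by procedures 92.21--92.27 or 92.29.
#'
#' @return a [CodeMap-class] object.
#' @export
#' @examples
#' cm <- defaultCodeMap()
#' siteLabels(cm)
defaultCodeMap <- function() {
  codeMap(list(
    dm = list(system = "icd10_dx", codes = "E11.0-E14.9"),
    htn = list(system = "icd10_dx", codes = "I10"),
    hyperthyroidism = list(system = "icd10_dx", codes = "E05.0-E05.9"),
    hypothyroidism = list(system = "icd10_dx", codes = c("E02-E03.9", "E89.0")),
    chemotherapy = list(system = c("icd9cm_proc", "icd10_dx"),
                        codes = c("99.25", "Z51.1")),
    radiotherapy = list(system = "icd9cm_proc",
                        codes = c("92.21-92.27", "92.29")),
    stomach = list(system = "icd10_dx", codes = "C16.0-C16.9"),
    lung = list(system = "icd10_dx", codes = "C33-C34.9"),
    colorectal = list(system = "icd10_dx", codes = "C18.0-C19"),
    liver = list(system = "icd10_dx", codes = "C22.0-C22.9"),
    pancreatic = list(system = "icd10_dx", codes = "C25-C25.9"),
    bile_duct = list(system = "icd10_dx", codes = "C24-C24.9"),
    gallbladder = list(system = "icd10_dx", codes = "C23-C23.9"),
    small_intestine = list(system = "icd10_dx", codes = "C17-C17.9"),
    multiple_myeloma = list(system = "icd10_dx", codes = "C90-C90.9"),
    kidney = list(system = "icd10_dx", codes = "C64-C64.9"),
    ureter = list(system = "icd10_dx", codes = "C66-C66.9"),
    bladder = list(system = "icd10_dx", codes = "C67-C67.9"),
    laryngeal = list(system = "icd10_dx", codes = "C32-C32.9"),
    prostate = list(system = "icd10_dx", codes = "C61-C61.9"),
    anal = list(system = "icd10_dx", codes = "C21-C21.9"),
    esophageal = list(system = "icd10_dx", codes = "C15-C15.9")
  ))
}

#' Read / write a CodeMap as YAML
#'
#' The on-disk form is a mapping from label to `{system, codes}` where
#' `codes` is a list of `"START-END"` or single-code strings and `system` is
#' one system name or a parallel list (the chemotherapy label legitimately
#' mixes a procedure code with a diagnosis code).
#'
#' @param path YAML file path.
#' @param siteLabels site partition labels (read: defaults to the labels of
#'   the default map that appear in the file, plus `"other"`).
#' @return `readCodeMap()`: a [CodeMap-class]; `writeCodeMap()`: `path`,
#'   invisibly.
#' @export
readCodeMap <- function(path, siteLabels = NULL) {
  spec <- yaml::read_yaml(path)
  spec <- lapply(spec, function(el)
    list(system = unlist(el$system), codes = unlist(el$codes)))
  if (is.null(siteLabels))
    siteLabels <- c(intersect(.siteOrder, names(spec)), "other")
  codeMap(spec, siteLabels = unique(siteLabels))
}

#' @rdname readCodeMap
#' @param map a [CodeMap-class] object.
#' @export
writeCodeMap <- function(map, path) {
  iv <- codeIntervals(map)
  out <- lapply(split(iv, factor(iv$label, unique(iv$label))), function(d) {
    codes <- ifelse(d$start == d$end, d$start, paste0(d$start, "-", d$end))
    sys <- if (length(unique(d$system)) == 1) d$system[1] else d$system
    list(system = sys, codes = as.list(codes))
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
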