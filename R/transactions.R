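.itemLabelMap <- c(
  dm = "DM", htn = "HTN",
  hyperthyroidism = "Hyperthyroidism", hypothyroidism = "Hypothyroidism",
  stomach = "Stomach cancer", lung = "Lung cancer",
  colorectal = "Colorectal cancer", liver = "Liver cancer",
  pancreatic = "Pancreatic cancer", bile_duct = "Bile duct cancer",
  gallbladder = "Gallbladder cancer", small_intestine = "Small intestine cancer",
  multiple_myeloma = "Multiple myeloma", kidney = "Kidney cancer",
  ureter = "Ureter cancer", bladder = "Bladder cancer",
  laryngeal = "Laryngeal cancer", prostate = "Prostate cancer",
  anal = "Anal cancer", esophageal = "Esophageal cancer", other = "Other"
)

#' Build disease transactions from phenotype profiles
#'
#' One transaction per episode: the comorbidity flags that are true plus the
#' episode's cancer-site label, using display labels ("DM", "HTN", "Liver
#' cancer", ...). Episodes whose itemset is empty still count toward the
#' denominator N, since support is defined over all study participants.
#'
#' @param profiles a phenotype-profile `data.frame` (see [phenotypeCohort()]).
#' @param includeOther include the `"Other"` cancer-site item (default TRUE);
#'   when FALSE, episodes at unnamed sites contribute only their comorbidity
#'   items.
#' @return a [Transactions-class] object.
#' @export
buildTransactions <- function(profiles, includeOther = TRUE) {
  if (!nrow(profiles)) stopf("buildTransactions: no profiles")
  flags <- c("dm", "htn", "hyperthyroidism", "hypothyroidism")
  mat <- sapply(flags, function(f) profiles[[f]])
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  site <- .itemLabelMap[as.character(profiles$cancer_site)]
  if (!includeOther) site[site == "Other"] <- NA_character_
  items <- lapply(seq_len(nrow(profiles)), function(i) {
    it <- c(.itemLabelMap[flags[mat[i, ]]], site[i])
    unname(it[!is.na(it)])
  })
  universe <- unname(c(.itemLabelMap[flags],
                       .itemLabelMap[levels(factor(profiles$cancer_site))]))
  if (!includeOther) universe <- setdiff(universe, "Other")
  new("Transactions", items = items,
      recordId = as.character(profiles$record_id),
      itemLabels = universe)
}
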