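#' Export the rule network as GraphML and DOT
#'
#' Bipartite rule-vertex convention: every item is a node carrying its
#' support, every rule is a small intermediate node carrying support,
#' confidence, lift and IS; edges run antecedent-item -> rule-node ->
#' consequent-item. This is the layout used for disease-association network
#' figures where node size encodes support and colour encodes lift.
#'
#' @param ruleSet a (preferably ranked) [RuleSet-class].
#' @param path output path without extension; `<path>.graphml` and
#'   `<path>.dot` are written.
#' @param formats subset of `c("graphml", "dot")`.
#' @return invisibly, the `igraph` graph object. An empty rule set produces
#'   a warning and an empty graph.
#' @export
exportRuleGraph <- function(ruleSet, path,
                            formats = c("graphml", "dot")) {
  formats <- match.arg(formats, several.ok = TRUE)
  r <- ruleTable(ruleSet)
  if (!nrow(r)) {
    warning("exportRuleGraph: no rules; writing empty graph")
    g <- igraph::make_empty_graph(directed = TRUE)
  } else {
    itemNodes <- sort(unique(unlist(c(r$antecedent, r$consequent))))
    sup <- itemSupport(ruleSet)
    ruleIds <- sprintf("rule_%03d", seq_len(nrow(r)))
    edges <- character(0)
    for (i in seq_len(nrow(r))) {
      edges <- c(edges,
                 as.vector(rbind(r$antecedent[[i]], ruleIds[i])),
                 as.vector(rbind(ruleIds[i], r$consequent[[i]])))
    }
    g <- igraph::make_graph(edges, directed = TRUE)
    vn <- igraph::V(g)$name
    isRule <- vn %in% ruleIds
    igraph::V(g)$type <- ifelse(isRule, "rule", "item")
    igraph::V(g)$label <- ifelse(isRule, r$label[match(vn, ruleIds)], vn)
    igraph::V(g)$support <- ifelse(isRule, r$support[match(vn, ruleIds)],
                                   unname(sup[vn]))
    igraph::V(g)$confidence <- ifelse(isRule,
                                      r$confidence[match(vn, ruleIds)], NA)
    igraph::V(g)$lift <- ifelse(isRule, r$lift[match(vn, ruleIds)], NA)
    igraph::V(g)$IS <- ifelse(isRule, r$isScore[match(vn, ruleIds)], NA)
  }
  if ("graphml" %in% formats)
    igraph::write_graph(g, paste0(path, ".graphml"), format = "graphml")
  if ("dot" %in% formats)
    igraph::write_graph(g, paste0(path, ".dot"), format = "dot")
  invisible(g)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full comorbidity-mining pipeline
#'
#' simulate (or read) -> filter -> phenotype -> prevalence tables ->
#' association rules -> mortality models -> rule graph + forest plot, with a
#' provenance manifest. Config is a list (or YAML file path) with elements:
#' \describe{
#'   \item{simulate}{arguments for [syntheticCohortConfig()], OR}
#'   \item{input}{path to a cohort CSV for [readCohort()]}
#'   \item{codeMap}{optional YAML path for [readCodeMap()]}
#'   \item{minSupport, minConfidence, minLift}{rule thresholds (defaults
#'     0.01, 0.1, 1; all strict)}
#'   \item{mortalitySubsets}{site labels to fit in addition to the full
#'     cohort (default stomach, colorectal, liver, lung)}
#' }
#'
#' @param config list or YAML path.
#' @param outDir output directory (created if needed).
#' @return invisibly, the manifest list. Files written: `prevalence_*.tsv`,
#'   `rules.tsv`, `mortality_*.tsv`, `rule_network.graphml` / `.dot`,
#'   `forest_plot.pdf`, `manifest.json`.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- "configuration"
  counts <- list()
  tryCatch({
    stage <- "cohort acquisition"
    cohort <- if (!is.null(config$simulate))
      generateCohort(do.call(syntheticCohortConfig, config$simulate))
    else if (!is.null(config$input))
      readCohort(config$input)
    else stopf("config needs a 'simulate' block or an 'input' path")
    counts$raw <- nrow(cohort)

    stage <- "cohort filter"
    cohort <- filterCohort(cohort, quiet = TRUE)
    counts$filtered <- nrow(cohort)

    stage <- "phenotyping"
    map <- if (!is.null(config$codeMap)) readCodeMap(config$codeMap)
           else defaultCodeMap()
    profiles <- phenotypeCohort(cohort, map = map)
    counts$phenotyped <- nrow(profiles)

    stage <- "prevalence tables"
    for (strat in c("sex", "age_group", "cancer_site")) {
      pr <- prevalenceReport(profiles, strat, c("dm", "htn"))
      for (cond in names(pr)) {
        tab <- pr[[cond]]$table
        if (!is.null(pr[[cond]]$test))
          tab <- cbind(tab, pr[[cond]]$test[rep(1, nrow(tab)),
                                            c("p_raw", "p_adj")])
        writeTsv(tab, file.path(outDir,
                                sprintf("prevalence_%s_%s.tsv", strat, cond)))
      }
    }

    stage <- "association rules"
    tx <- buildTransactions(profiles)
    rules <- mineRules(tx,
                       minSupport = config$minSupport %||% 0.01,
                       minConfidence = config$minConfidence %||% 0.1,
                       minLift = config$minLift %||% 1)
    counts$rules <- nrow(ruleTable(rules))
    writeTsv(formatRuleTable(rules), file.path(outDir, "rules.tsv"))

    stage <- "rule graph"
    exportRuleGraph(rules, file.path(outDir, "rule_network"))

    stage <- "mortality models"
    subsets <- config$mortalitySubsets %||%
      c("stomach", "colorectal", "liver", "lung")
    fits <- list(all = fitMortality(buildDesign(profiles)))
    for (s in subsets)
      fits[[s]] <- fitMortality(buildDesign(profiles, subset = s))
    for (nm in names(fits))
      writeTsv(oddsRatioReport(fits[[nm]]),
               file.path(outDir, sprintf("mortality_%s.tsv", nm)))

    stage <- "forest plot"
    fp <- forestPlotData(fits)
    grDevices::pdf(file.path(outDir, "forest_plot.pdf"), width = 8,
                   height = 6)
    print(plotForest(fp))
    grDevices::dev.off()

    stage <- "manifest"
    manifest <- list(
      package = "comorbidARM",
      version = as.character(utils::packageVersion("comorbidARM")),
      configHash = hashConfig(config),
      seed = config$simulate$seed %||% NA,
      thresholds = list(minSupport = config$minSupport %||% 0.01,
                        minConfidence = config$minConfidence %||% 0.1,
                        minLift = config$minLift %||% 1),
      rowCounts = counts
    )
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
}

# stable content hash of a config list (canonical JSON -> md5)
hashConfig <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  canon <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = 15)
  writeLines(canon, tmp)
  unname(tools::md5sum(tmp))
}
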