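# End-to-end orchestration: ingest -> phenotype -> density filter -> cross-G
# scores -> distance panel -> distribution groups -> survival statistics,
# from a single validated config, with a manifest for reproducibility.
# Result tables are written to a staging directory and renamed into place so
# a failed stage leaves no partially written final tables.

#' Build a pipeline config
#'
#' @param cells path to the cell table (or an in-memory data.frame).
#' @param clinical path to the clinical table (or a data.frame).
#' @param rules path to a phenotype rules file; NULL for the shipped
#'   defaults. Use NA to match the cell table's ground-truth
#'   \code{phenotype} column instead of marker rules.
#' @param outputDir directory for result tables.
#' @param pairs path to a reference/target pair table (TSV with columns
#'   reference, target); NULL for [defaultDistancePairs()].
#' @param window,edgeCorrection,rMax,minRef,minTarget spatial settings.
#' @param densityThreshold median-density inclusion threshold (cells/mm^2).
#' @param anchor anchor phenotype for the group taxonomy.
#' @param clinicalTerms clinical adjusters for the Cox models (must be
#'   columns of the clinical table).
#' @param timeCol,eventCol outcome columns in the clinical table.
#' @param seed integer seed recorded in the manifest.
#' @return config list of class "pipelineConfig".
#' @export
pipelineConfig <- function(cells, clinical, rules = NULL,
                           outputDir = "spatialTME-results", pairs = NULL,
                           window = "convex_hull",
                           edgeCorrection = "border", rMax = 200,
                           densityThreshold = 2, minRef = 5L,
                           minTarget = 5L, anchor = "CD3+",
                           clinicalTerms = c("histology", "smoker",
                                             "tumor_size_cm"),
                           timeCol = "os_months", eventCol = "os_event",
                           seed = 1L) {
  structure(list(cells = cells, clinical = clinical, rules = rules,
                 outputDir = outputDir, pairs = pairs, window = window,
                 edgeCorrection = edgeCorrection, rMax = rMax,
                 densityThreshold = densityThreshold,
                 minRef = as.integer(minRef),
                 minTarget = as.integer(minTarget), anchor = anchor,
                 clinicalTerms = clinicalTerms, timeCol = timeCol,
                 eventCol = eventCol, seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Read a pipeline config from YAML or JSON
#'
#' Relative paths are resolved against the config file's directory.
#'
#' @param path config file path.
#' @return config list, as [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || is.na(p) || !is.character(p)) return(p)
    if (file.exists(p)) p else file.path(base, p)
  }
  args <- raw
  for (f in c("cells", "clinical", "rules", "pairs")) {
    if (!is.null(args[[f]])) args[[f]] <- resolve(args[[f]])
  }
  do.call(pipelineConfig, args)
}

#' Validate a pipeline config
#'
#' Problems are returned as data, not thrown; an empty character vector
#' means the config is runnable.
#'
#' @param config a pipeline config.
#' @return character vector of problems, each naming the offending field.
#' @export
validateConfig <- function(config) {
  problems <- character()
  chk <- function(field, obj) {
    if (is.character(obj) && !file.exists(obj)) {
      sprintf("%s: file not found (%s)", field, obj)
    } else NULL
  }
  for (f in c("cells", "clinical")) {
    if (is.null(config[[f]])) {
      problems <- c(problems, paste0(f, ": missing"))
    } else if (!is.data.frame(config[[f]])) {
      problems <- c(problems, chk(f, config[[f]]))
    }
  }
  if (!is.null(config$rules) && !identical(config$rules, NA) &&
      is.character(config$rules) && !file.exists(config$rules)) {
    problems <- c(problems, sprintf("rules: file not found (%s)",
                                    config$rules))
  }
  if (!is.null(config$pairs) && is.character(config$pairs) &&
      !file.exists(config$pairs)) {
    problems <- c(problems, sprintf("pairs: file not found (%s)",
                                    config$pairs))
  }
  if (!is.numeric(config$rMax) || config$rMax <= 0) {
    problems <- c(problems, "rMax: must be > 0")
  }
  if (!is.numeric(config$densityThreshold) || config$densityThreshold < 0) {
    problems <- c(problems, "densityThreshold: must be >= 0")
  }
  if (!config$edgeCorrection %in% c("border", "none")) {
    problems <- c(problems, "edgeCorrection: must be 'border' or 'none'")
  }
  if (!is.numeric(config$seed)) problems <- c(problems, "seed: not numeric")
  problems
}

#' Run the full spatial immune-profiling pipeline
#'
#' Executes ingest, phenotype assignment, density filtering, cross-G
#' scoring, the distance panel, group assignment and the survival models,
#' and writes the result tables plus a run manifest to
#' \code{config$outputDir}.
#'
#' @param config a validated pipeline config.
#' @return invisibly, a list with all result tables.
#' @export
runPipeline <- function(config) {
  problems <- validateConfig(config)
  if (length(problems)) {
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "))
  }
  set.seed(config$seed)
  warningsLog <- character()
  logW <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warningsLog <<- c(warningsLog, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  cells <- if (is.data.frame(config$cells)) config$cells else {
    readCellTable(config$cells)
  }
  clinical <- if (is.data.frame(config$clinical)) config$clinical else {
    readClinicalTable(config$clinical)
  }
  groundTruth <- identical(config$rules, NA)
  rules <- if (groundTruth) NULL else if (is.null(config$rules)) {
    defaultPhenotypeRules()
  } else readPhenotypeRules(config$rules)
  pairs <- if (is.null(config$pairs)) defaultDistancePairs() else {
    utils::read.table(config$pairs, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  taicNames <- if (groundTruth) {
    setdiff(unique(cells$phenotype), MALIGNANT_PHENOTYPE)
  } else {
    nm <- vapply(rules, `[[`, character(1), "name")
    nm[!startsWith(nm, "CK")]
  }
  # stage 1: densities and phenotype filter
  dens <- subjectDensities(cells, taicNames, rules, config$window)
  included <- filterPhenotypesByMedianDensity(dens,
                                              config$densityThreshold)
  # stage 2: cross-G mixing scores
  coreScores <- logW(scoreAllPhenotypes(
    cells, included, rules, window = config$window,
    edgeCorrection = config$edgeCorrection, rMax = config$rMax,
    minRef = config$minRef, minTarget = config$minTarget))
  subjectScores <- aggregateScoresBySubject(coreScores)
  scoreSummary <- summarizeScores(subjectScores, clinical)
  # stage 3: distance panel
  pairs <- pairs[pairs$target %in% included |
                 pairs$target %in% unique(cells$phenotype), , drop = FALSE]
  panel <- logW(distancePanel(cells, pairs, rules))
  panel <- classifyDistances(panel)
  # stage 4: group taxonomy (degenerate filters propagate empty tables)
  anchorScored <- config$anchor %in% subjectScores$phenotype &&
    any(panel$reference == MALIGNANT_PHENOTYPE &
        panel$target == config$anchor)
  if (anchorScored) {
    assignments <- groupAssignments(subjectScores, panel,
                                    anchor = config$anchor)
    prevalence <- groupPrevalence(assignments$group)
    groupDensities <- logW(densitiesByGroup(dens, assignments))
  } else {
    warningsLog <- c(warningsLog, paste0(
      "anchor phenotype '", config$anchor,
      "' not scored (filtered out or absent); group and survival stages ",
      "produce empty tables"))
    assignments <- data.frame(subject_id = character(),
                              phenotype = character(),
                              pattern = character(),
                              distance_class = character(),
                              group = integer(), stringsAsFactors = FALSE)
    prevalence <- stats::setNames(rep(NA_real_, 4), paste0("group", 1:4))
    groupDensities <- data.frame(phenotype = character(),
                                 group1 = numeric(), group2 = numeric(),
                                 group3 = numeric(), group4 = numeric(),
                                 kw_statistic = numeric(),
                                 p_value = numeric(),
                                 stringsAsFactors = FALSE)
  }
  # stage 5: survival
  surv <- merge(assignments, clinical, by = "subject_id")
  survTables <- list()
  clin <- intersect(config$clinicalTerms, names(surv))
  usable <- vapply(clin, function(t) {
    length(unique(stats::na.omit(surv[[t]]))) > 1
  }, logical(1))
  clin <- clin[usable]
  if (all(c(config$timeCol, config$eventCol) %in% names(surv)) &&
      sum(surv[[config$eventCol]], na.rm = TRUE) > 0) {
    tryFit <- function(...) {
      tryCatch(logW(multivariableReport(...)), error = function(e) {
        warningsLog <<- c(warningsLog,
                          paste("survival stage skipped:",
                                conditionMessage(e)))
        NULL
      })
    }
    surv$group <- factor(surv$group)
    fitGroup <- tryFit(surv, time = config$timeCol,
                       event = config$eventCol, spatialTerms = "group",
                       clinicalTerms = clin)
    if (!is.null(fitGroup)) survTables$cox_group <- fitGroup$table
    surv$pattern_mixed <- as.integer(surv$pattern == "mixed")
    surv$distance_close <- as.integer(surv$distance_class == "close")
    fitFeat <- tryFit(surv, time = config$timeCol,
                      event = config$eventCol,
                      spatialTerms = c("pattern_mixed", "distance_close"),
                      clinicalTerms = clin)
    if (!is.null(fitFeat)) survTables$cox_features <- fitFeat$table
  }
  results <- list(densities = dens,
                  included_phenotypes = data.frame(phenotype = included,
                                                   stringsAsFactors = FALSE),
                  core_scores = coreScores, subject_scores = subjectScores,
                  score_summary = scoreSummary, distances = panel,
                  group_assignments = assignments,
                  group_prevalence = data.frame(
                    group = 1:4, prevalence = as.numeric(prevalence)),
                  group_densities = groupDensities)
  results <- c(results, survTables)
  writeResultBundle(results, config, warningsLog)
  invisible(results)
}

writeResultBundle <- function(results, config, warningsLog) {
  outDir <- config$outputDir
  staging <- paste0(outDir, ".staging")
  dir.create(staging, recursive = TRUE, showWarnings = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(results)) {
    f <- file.path(staging, paste0(nm, ".tsv"))
    utils::write.table(results[[nm]], f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("spatialTME")),
    r_version = R.version.string,
    seed = config$seed,
    config = config[!vapply(config, is.data.frame, logical(1))],
    config_hash = configHash(config),
    tables = paste0(names(results), ".tsv"),
    warnings = warningsLog,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  # atomic publish: everything staged successfully, now rename into place
  for (f in list.files(staging)) {
    file.rename(file.path(staging, f), file.path(outDir, f))
  }
  unlink(staging, recursive = TRUE)
  invisible(outDir)
}

configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[order(names(config))], tmp)
  unname(tools::md5sum(tmp))
}
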