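# Synthetic tissue cores and cohorts with known ground-truth spatial
# regimes. Malignant (CK+) cells are a homogeneous Poisson process in the
# core window; immune phenotypes are placed under one of three regimes:
# complete spatial randomness, attraction to malignant cells (Gaussian
# offsets around malignant parents), or segregated Thomas clusters whose
# parents keep a minimum distance from every malignant cell.

#' Construct a phenotype simulation spec
#'
#' @param name phenotype label.
#' @param regime "csr", "attraction" or "segregated_cluster".
#' @param intensity expected cells/mm^2 (csr, attraction).
#' @param attractionScale Gaussian offset sd in um (attraction).
#' @param clusterParentIntensity parents/mm^2 (segregated_cluster).
#' @param clusterOffspringMean expected offspring per parent.
#' @param clusterScale offspring Gaussian sd in um.
#' @param exclusionRadius minimum parent distance from malignant cells, um.
#' @return a [PhenotypeSimSpec-class].
#' @export
phenotypeSimSpec <- function(name, regime = c("csr", "attraction",
                                              "segregated_cluster"),
                             intensity = NA_real_,
                             attractionScale = NA_real_,
                             clusterParentIntensity = NA_real_,
                             clusterOffspringMean = NA_real_,
                             clusterScale = NA_real_,
                             exclusionRadius = 0) {
  regime <- match.arg(regime)
  new("PhenotypeSimSpec", name = name, regime = regime,
      intensity = as.numeric(intensity),
      attractionScale = as.numeric(attractionScale),
      clusterParentIntensity = as.numeric(clusterParentIntensity),
      clusterOffspringMean = as.numeric(clusterOffspringMean),
      clusterScale = as.numeric(clusterScale),
      exclusionRadius = as.numeric(exclusionRadius))
}

#' Construct a core simulation config
#'
#' @param malignantIntensity malignant (CK+) cells per mm^2.
#' @param phenotypes list of [PhenotypeSimSpec-class] objects.
#' @param windowShape "circle" (a TMA core) or "rectangle".
#' @param windowDiameter diameter/side in micrometres (default 1000, a
#'   1-mm-diameter core).
#' @param seed integer RNG seed.
#' @return a [CoreSimConfig-class].
#' @export
coreSimConfig <- function(malignantIntensity, phenotypes = list(),
                          windowShape = c("circle", "rectangle"),
                          windowDiameter = 1000, seed = 1L) {
  windowShape <- match.arg(windowShape)
  new("CoreSimConfig", windowShape = windowShape,
      windowDiameter = as.numeric(windowDiameter),
      malignantIntensity = as.numeric(malignantIntensity),
      phenotypes = phenotypes, seed = as.integer(seed))
}

coreWindow <- function(shape, diameter) {
  if (shape == "circle") {
    circleWindow(c(0, 0), diameter)
  } else {
    polygonWindow(rbind(c(0, 0), c(diameter, 0),
                        c(diameter, diameter), c(0, diameter)))
  }
}

#' Simulate one tissue core
#'
#' Draws malignant cells as a homogeneous Poisson process and each phenotype
#' under its regime. Points falling outside the window are redrawn so the
#' realised intensity stays near nominal. All cells carry their ground-truth
#' regime label. Output is bit-identical for a fixed config (seed included).
#'
#' @param config a [CoreSimConfig-class].
#' @param subjectId,coreId identifiers stamped on the rows.
#' @return data.frame with columns subject_id, core_id, panel, x_um, y_um,
#'   phenotype, regime.
#' @examples
#' cfg <- coreSimConfig(100, list(phenotypeSimSpec("CD3+", "csr",
#'                                                 intensity = 50)),
#'                      seed = 7)
#' head(simulateCore(cfg))
#' @export
simulateCore <- function(config, subjectId = "S1", coreId = "C1") {
  stopifnot(is(config, "CoreSimConfig"))
  validObject(config)
  withSeed(config@seed,
           simulateCoreImpl(config, subjectId, coreId))
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

simulateCoreImpl <- function(config, subjectId, coreId) {
  win <- coreWindow(config@windowShape, config@windowDiameter)
  area <- windowAreaMM2(win)
  nMal <- stats::rpois(1, config@malignantIntensity * area)
  mal <- runifWindow(nMal, win)
  pieces <- list(cellRows(mal, subjectId, coreId, MALIGNANT_PHENOTYPE,
                          "malignant"))
  for (sp in config@phenotypes) {
    xy <- switch(sp@regime,
      csr = runifWindow(stats::rpois(1, sp@intensity * area), win),
      attraction = drawAttraction(sp, mal, win, area),
      segregated_cluster = drawSegregatedClusters(sp, mal, win, area)
    )
    pieces <- c(pieces, list(cellRows(xy, subjectId, coreId, sp@name,
                                      sp@regime)))
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

cellRows <- function(xy, subjectId, coreId, phenotype, regime) {
  data.frame(subject_id = rep(subjectId, nrow(xy)),
             core_id = rep(coreId, nrow(xy)), panel = rep(0L, nrow(xy)),
             x_um = xy[, 1], y_um = xy[, 2],
             phenotype = rep(phenotype, nrow(xy)),
             regime = rep(regime, nrow(xy)), stringsAsFactors = FALSE)
}

# attraction: each point is a Gaussian offset around a randomly chosen
# malignant cell; offsets leaving the window are redrawn (fresh parent).
drawAttraction <- function(sp, mal, win, area) {
  n <- stats::rpois(1, sp@intensity * area)
  if (n == 0) return(mal[0, , drop = FALSE])
  if (nrow(mal) == 0) {
    stop("attraction regime for phenotype '", sp@name,
         "' needs malignant cells in the core")
  }
  out <- matrix(NA_real_, n, 2)
  todo <- seq_len(n)
  tries <- 0L
  while (length(todo) && tries < 1000L) {
    par <- mal[sample.int(nrow(mal), length(todo), replace = TRUE), ,
               drop = FALSE]
    cand <- par + matrix(stats::rnorm(2 * length(todo),
                                      sd = sp@attractionScale),
                         ncol = 2)
    ok <- boundaryDistance(cand, win) >= 0
    out[todo[ok], ] <- cand[ok, , drop = FALSE]
    todo <- todo[!ok]
    tries <- tries + 1L
  }
  if (length(todo)) {
    stop("could not place attraction points inside the window for ",
         "phenotype '", sp@name, "'")
  }
  colnames(out) <- c("x", "y")
  out
}

# segregated Thomas clusters: Poisson parents placed uniformly but at least
# exclusionRadius from every malignant cell, Poisson offspring counts with
# Gaussian offsets; offspring leaving the window are redrawn, then dropped
# after a retry cap.
drawSegregatedClusters <- function(sp, mal, win, area) {
  nPar <- stats::rpois(1, sp@clusterParentIntensity * area)
  if (nPar == 0) return(mal[0, , drop = FALSE])
  parents <- matrix(NA_real_, nPar, 2)
  placed <- 0L
  tries <- 0L
  maxTries <- 2000L
  while (placed < nPar && tries < maxTries) {
    cand <- runifWindow(max(64L, 4L * (nPar - placed)), win)
    if (nrow(mal) > 0 && sp@exclusionRadius > 0) {
      d <- nearestNeighborDistances(cand, mal)
      cand <- cand[d >= sp@exclusionRadius, , drop = FALSE]
    }
    take <- min(nrow(cand), nPar - placed)
    if (take > 0) {
      parents[placed + seq_len(take), ] <- cand[seq_len(take), ,
                                                drop = FALSE]
      placed <- placed + take
    }
    tries <- tries + 1L
  }
  if (placed < nPar) {
    stop("window too small to place cluster parents at exclusion radius ",
         sp@exclusionRadius, " um for phenotype '", sp@name, "'")
  }
  counts <- stats::rpois(nPar, sp@clusterOffspringMean)
  if (sum(counts) == 0) return(mal[0, , drop = FALSE])
  centre <- parents[rep(seq_len(nPar), counts), , drop = FALSE]
  n <- nrow(centre)
  out <- matrix(NA_real_, n, 2)
  todo <- seq_len(n)
  tries <- 0L
  while (length(todo) && tries < 200L) {
    cand <- centre[todo, , drop = FALSE] +
      matrix(stats::rnorm(2 * length(todo), sd = sp@clusterScale), ncol = 2)
    ok <- boundaryDistance(cand, win) >= 0
    out[todo[ok], ] <- cand[ok, , drop = FALSE]
    todo <- todo[!ok]
    tries <- tries + 1L
  }
  out <- out[stats::complete.cases(out), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Construct a cohort simulation config
#'
#' @param nSubjects number of subjects.
#' @param groupProbabilities probabilities of the four cellular immunologic
#'   distribution groups (sum to 1).
#' @param logHazardByGroup log hazard ratios per group (group 1 reference).
#' @param baselineHazard event hazard per month.
#' @param censoringRate censoring hazard per month.
#' @param coresPerSubject cores per subject (triplicate by default).
#' @param covariateFrequencies named Bernoulli frequencies for binary
#'   clinical covariates.
#' @param seed integer RNG seed.
#' @return a [CohortSimConfig-class].
#' @export
cohortSimConfig <- function(nSubjects,
                            groupProbabilities = c(0.25, 0.30, 0.10, 0.35),
                            logHazardByGroup = c(0, 0, 0, log(2)),
                            baselineHazard = 0.02,
                            censoringRate = 0.01,
                            coresPerSubject = 3L,
                            covariateFrequencies = c(smoker = 0.7,
                                                     kras_mut = 0.3,
                                                     egfr_mut = 0.15),
                            seed = 1L) {
  new("CohortSimConfig", nSubjects = as.integer(nSubjects),
      coresPerSubject = as.integer(coresPerSubject),
      groupProbabilities = as.numeric(groupProbabilities),
      baselineHazard = as.numeric(baselineHazard),
      logHazardByGroup = as.numeric(logHazardByGroup),
      censoringRate = as.numeric(censoringRate),
      covariateFrequencies = covariateFrequencies,
      seed = as.integer(seed))
}

#' Spatial regime presets realising the four distribution groups
#'
#' Presets for the anchor phenotype (CD3+ by default) that realise each
#' cellular immunologic distribution group in simulated cores:
#' group 1 = attraction with a short offset scale (mixed pattern, close
#' distances), group 2 = sparse CSR (mixed, long), group 3 = dense
#' small-exclusion clusters (unmixed, close), group 4 = sparser clusters
#' with a larger exclusion radius tuned so its malignant-to-anchor distances
#' match group 2 (unmixed, long). Groups 2 and 4 share one distance
#' distribution so that cohort-median dichotomization splits their subjects
#' proportionally. A CSR macrophage background (CD68+) is included in every
#' group.
#'
#' @param anchor anchor phenotype name.
#' @return list of four lists, each with elements \code{malignantIntensity}
#'   and \code{phenotypes}.
#' @export
groupRegimePresets <- function(anchor = "CD3+") {
  bg <- phenotypeSimSpec("CD68+", "csr", intensity = 80)
  list(
    list(malignantIntensity = 400, phenotypes = list(
      phenotypeSimSpec(anchor, "attraction", intensity = 250,
                       attractionScale = 20), bg)),
    list(malignantIntensity = 400, phenotypes = list(
      phenotypeSimSpec(anchor, "csr", intensity = 28), bg)),
    list(malignantIntensity = 400, phenotypes = list(
      phenotypeSimSpec(anchor, "segregated_cluster",
                       clusterParentIntensity = 80, clusterOffspringMean = 4,
                       clusterScale = 10, exclusionRadius = 20), bg)),
    list(malignantIntensity = 400, phenotypes = list(
      phenotypeSimSpec(anchor, "segregated_cluster",
                       clusterParentIntensity = 25.5, clusterOffspringMean = 8,
                       clusterScale = 15, exclusionRadius = 40), bg))
  )
}

#' Simulate a patient cohort with ground-truth spatial groups
#'
#' Each subject draws a ground-truth group from \code{groupProbabilities};
#' its cores are simulated under the matching preset; overall survival is
#' exponential with hazard \code{baselineHazard * exp(logHazardByGroup[g])}
#' and independent exponential censoring; recurrence-free survival uses an
#' independent draw of the same model; binary covariates are Bernoulli.
#'
#' @param config a [CohortSimConfig-class].
#' @param presets group presets from [groupRegimePresets()].
#' @param anchor anchor phenotype name (used by the presets).
#' @return list with elements \code{cells} (cohort cell table with
#'   ground-truth \code{phenotype}/\code{regime} columns) and
#'   \code{clinical} (one row per subject, including \code{group_true}).
#' @export
simulateCohort <- function(config, presets = groupRegimePresets(anchor),
                           anchor = "CD3+") {
  stopifnot(is(config, "CohortSimConfig"))
  validObject(config)
  withSeed(config@seed, {
    n <- config@nSubjects
    groups <- sample.int(4L, n, replace = TRUE,
                         prob = config@groupProbabilities)
    ids <- sprintf("S%04d", seq_len(n))
    hazards <- config@baselineHazard * exp(config@logHazardByGroup[groups])
    evt <- stats::rexp(n, hazards)
    cens <- if (config@censoringRate > 0) {
      stats::rexp(n, config@censoringRate)
    } else rep(Inf, n)
    rfsEvt <- stats::rexp(n, hazards)
    rfsCens <- if (config@censoringRate > 0) {
      stats::rexp(n, config@censoringRate)
    } else rep(Inf, n)
    clinical <- data.frame(
      subject_id = ids,
      group_true = groups,
      histology = ifelse(stats::runif(n) < 0.63, "ADC", "SCC"),
      tumor_size_cm = round(stats::rlnorm(n, log(3.3), 0.35), 2),
      stage = sample(c("I", "II", "III"), n, replace = TRUE,
                     prob = c(0.5, 0.25, 0.25)),
      os_months = pmin(evt, cens),
      os_event = as.integer(evt <= cens),
      rfs_months = pmin(rfsEvt, rfsCens),
      rfs_event = as.integer(rfsEvt <= rfsCens),
      stringsAsFactors = FALSE)
    for (cv in names(config@covariateFrequencies)) {
      clinical[[cv]] <- as.integer(
        stats::runif(n) < config@covariateFrequencies[[cv]])
    }
    cellPieces <- vector("list", n * config@coresPerSubject)
    k <- 0L
    for (i in seq_len(n)) {
      preset <- presets[[groups[i]]]
      for (cc in seq_len(config@coresPerSubject)) {
        cfg <- new("CoreSimConfig", windowShape = "circle",
                   windowDiameter = 1000,
                   malignantIntensity = preset$malignantIntensity,
                   phenotypes = preset$phenotypes, seed = 0L)
        k <- k + 1L
        cellPieces[[k]] <- simulateCoreImpl(cfg, ids[i],
                                            sprintf("%s_core%d", ids[i], cc))
      }
    }
    list(cells = do.call(rbind, cellPieces), clinical = clinical)
  })
}
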