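#' @import methods
NULL

#' PointPattern: a typed planar point pattern in an observation window
#'
#' Holds the coordinates (micrometres) of all cells of one phenotype within a
#' tissue core, together with the observation window used for intensity and
#' edge computations. Windows are either circles (centre + radius) or simple
#' polygons (vertex matrix, implicitly closed).
#'
#' @slot coords two-column numeric matrix of x/y positions in micrometres.
#' @slot window list describing the window: either
#'   \code{list(type = "circle", centre = c(x, y), radius = r)} or
#'   \code{list(type = "polygon", vertices = <n x 2 matrix>)}.
#' @slot phenotype phenotype label of the points.
#' @slot coreId identifier of the tissue core the pattern came from.
#'
#' @seealso [buildPointPattern()], [areaMM2()], [npoints()]
#' @export
setClass("PointPattern",
  representation(
    coords = "matrix",
    window = "list",
    phenotype = "character",
    coreId = "character"
  )
)

setValidity("PointPattern", function(object) {
  msgs <- character()
  xy <- object@coords
  if (ncol(xy) != 2L) msgs <- c(msgs, "coords must have two columns")
  if (nrow(xy) > 0 && any(!is.finite(xy))) {
    msgs <- c(msgs, "coordinates must be finite")
  }
  w <- object@window
  if (is.null(w$type) || !w$type %in% c("circle", "polygon")) {
    msgs <- c(msgs, "window$type must be 'circle' or 'polygon'")
  } else if (w$type == "circle") {
    if (!is.numeric(w$radius) || w$radius <= 0) {
      msgs <- c(msgs, "circle window needs radius > 0")
    }
  } else {
    if (is.null(w$vertices) || nrow(w$vertices) < 3L) {
      msgs <- c(msgs, "polygon window needs >= 3 vertices")
    }
  }
  if (length(msgs) == 0 && windowAreaMM2(w) <= 0) {
    msgs <- c(msgs, "window area must be positive")
  }
  # closed window: boundary points count as inside (small tolerance)
  if (length(msgs) == 0 && nrow(xy) > 0) {
    if (any(boundaryDistance(xy, w) < -1e-6)) {
      msgs <- c(msgs, "all points must lie inside the window")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' CrossGResult: cross-type nearest-neighbour G analysis of one core
#'
#' Result container for the comparison of the empirical cross-G function
#' (reference phenotype to target phenotype, typically malignant to immune)
#' with the theoretical Poisson curve of the same target intensity, including
#' the normalised mixing score and the mixed/unmixed classification.
#'
#' @slot r increasing distance grid in micrometres.
#' @slot gEmp empirical G values per r (may contain NA where the border
#'   correction leaves no usable reference point).
#' @slot gTheo theoretical Poisson G values per r.
#' @slot lambda target intensity in cells/mm^2 used for the Poisson curve.
#' @slot nRef,nTarget point counts of the reference and target patterns.
#' @slot score mixing score (percent area deviation); NA when undefined.
#' @slot pattern "mixed", "unmixed" or NA.
#' @slot attraction TRUE when the score falls below -10 (stronger contact
#'   with malignant cells than CSR predicts); such cores remain "mixed".
#' @slot edgeCorrection "border" or "none".
#'
#' @seealso [crossG()], [mixingScore()], [classifyPattern()]
#' @export
setClass("CrossGResult",
  representation(
    r = "numeric",
    gEmp = "numeric",
    gTheo = "numeric",
    lambda = "numeric",
    nRef = "integer",
    nTarget = "integer",
    score = "numeric",
    pattern = "character",
    attraction = "logical",
    edgeCorrection = "character"
  )
)

setValidity("CrossGResult", function(object) {
  msgs <- character()
  if (length(object@r) != length(object@gEmp) ||
      length(object@r) != length(object@gTheo)) {
    msgs <- c(msgs, "r, gEmp and gTheo must have equal length")
  }
  if (is.unsorted(object@r, strictly = TRUE)) {
    msgs <- c(msgs, "r grid must be strictly increasing")
  }
  ok <- !is.na(object@gEmp)
  if (any(object@gEmp[ok] < 0 | object@gEmp[ok] > 1)) {
    msgs <- c(msgs, "gEmp must lie in [0, 1]")
  }
  if (any(object@gTheo < -1e-12 | object@gTheo > 1 + 1e-12)) {
    msgs <- c(msgs, "gTheo must lie in [0, 1]")
  }
  if (length(object@r) && object@r[1] == 0 && object@gTheo[1] != 0) {
    msgs <- c(msgs, "gTheo(0) must be 0")
  }
  if (!is.na(object@pattern) && !object@pattern %in% c("mixed", "unmixed")) {
    msgs <- c(msgs, "pattern must be 'mixed', 'unmixed' or NA")
  }
  if (!is.na(object@pattern) && !is.finite(object@score)) {
    msgs <- c(msgs, "score must be finite when a pattern is assigned")
  }
  if (length(msgs)) msgs else TRUE
})

#' PhenotypeSimSpec: simulation recipe for one immune phenotype
#'
#' Describes how the points of one phenotype are placed in a simulated core:
#' complete spatial randomness ("csr"), attraction to malignant cells
#' ("attraction": each point is a Gaussian offset around a randomly chosen
#' malignant cell), or segregated Thomas clusters ("segregated_cluster":
#' Poisson cluster parents kept at least \code{exclusionRadius} away from
#' every malignant cell, with Poisson-count Gaussian offspring).
#'
#' @slot name phenotype label.
#' @slot intensity expected intensity in cells/mm^2 (csr and attraction).
#' @slot regime one of "csr", "attraction", "segregated_cluster".
#' @slot attractionScale Gaussian offset sd in micrometres (attraction).
#' @slot clusterParentIntensity cluster parents per mm^2 (segregated).
#' @slot clusterOffspringMean expected offspring per parent (segregated).
#' @slot clusterScale Gaussian offspring sd in micrometres (segregated).
#' @slot exclusionRadius minimum parent distance from any malignant cell, um.
#'
#' @seealso [phenotypeSimSpec()], [simulateCore()]
#' @export
setClass("PhenotypeSimSpec",
  representation(
    name = "character",
    intensity = "numeric",
    regime = "character",
    attractionScale = "numeric",
    clusterParentIntensity = "numeric",
    clusterOffspringMean = "numeric",
    clusterScale = "numeric",
    exclusionRadius = "numeric"
  )
)

setValidity("PhenotypeSimSpec", function(object) {
  msgs <- character()
  if (!object@regime %in% c("csr", "attraction", "segregated_cluster")) {
    msgs <- c(msgs, "regime must be csr, attraction or segregated_cluster")
  }
  if (object@regime %in% c("csr", "attraction") &&
      (!is.finite(object@intensity) || object@intensity < 0)) {
    msgs <- c(msgs, "intensity must be >= 0")
  }
  if (object@regime == "attraction" &&
      (!is.finite(object@attractionScale) || object@attractionScale <= 0)) {
    msgs <- c(msgs, "attractionScale must be > 0")
  }
  if (object@regime == "segregated_cluster") {
    if (!is.finite(object@clusterParentIntensity) ||
        object@clusterParentIntensity < 0) {
      msgs <- c(msgs, "clusterParentIntensity must be >= 0")
    }
    if (!is.finite(object@clusterOffspringMean) ||
        object@clusterOffspringMean < 0) {
      msgs <- c(msgs, "clusterOffspringMean must be >= 0")
    }
    if (!is.finite(object@clusterScale) || object@clusterScale <= 0) {
      msgs <- c(msgs, "clusterScale must be > 0")
    }
    if (!is.finite(object@exclusionRadius) || object@exclusionRadius < 0) {
      msgs <- c(msgs, "exclusionRadius must be >= 0")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' CoreSimConfig: configuration of a single simulated tissue core
#'
#' @slot windowShape "circle" (default, emulating a 1-mm TMA core) or
#'   "rectangle".
#' @slot windowDiameter core diameter (circle) or side length (rectangle)
#'   in micrometres.
#' @slot malignantIntensity intensity of malignant (CK+) cells in cells/mm^2.
#' @slot phenotypes list of [PhenotypeSimSpec-class] objects.
#' @slot seed integer RNG seed; a fixed seed makes the output bit-identical.
#'
#' @seealso [coreSimConfig()], [simulateCore()]
#' @export
setClass("CoreSimConfig",
  representation(
    windowShape = "character",
    windowDiameter = "numeric",
    malignantIntensity = "numeric",
    phenotypes = "list",
    seed = "integer"
  )
)

setValidity("CoreSimConfig", function(object) {
  msgs <- character()
  if (!object@windowShape %in% c("circle", "rectangle")) {
    msgs <- c(msgs, "windowShape must be 'circle' or 'rectangle'")
  }
  if (!is.finite(object@windowDiameter) || object@windowDiameter <= 0) {
    msgs <- c(msgs, "windowDiameter must be > 0")
  }
  if (!is.finite(object@malignantIntensity) || object@malignantIntensity < 0) {
    msgs <- c(msgs, "malignantIntensity must be >= 0")
  }
  for (sp in object@phenotypes) {
    if (!is(sp, "PhenotypeSimSpec")) {
      msgs <- c(msgs, "phenotypes must be PhenotypeSimSpec objects")
      break
    }
    v <- validObject(sp, test = TRUE)
    if (!isTRUE(v)) msgs <- c(msgs, v)
  }
  nm <- vapply(object@phenotypes, function(sp) sp@name, character(1))
  if (anyDuplicated(nm)) msgs <- c(msgs, "phenotype names must be unique")
  if (length(msgs)) msgs else TRUE
})

#' CohortSimConfig: configuration of a synthetic patient cohort
#'
#' Each subject is assigned a ground-truth cellular immunologic distribution
#' group (1-4); its cores are simulated under regime/intensity presets that
#' realise that group; survival is exponential with a group-dependent hazard
#' and independent exponential censoring; binary clinical covariates are
#' Bernoulli draws.
#'
#' @slot nSubjects number of subjects.
#' @slot coresPerSubject cores per subject (triplicate cores by default).
#' @slot groupProbabilities 4-vector of group probabilities summing to 1.
#' @slot baselineHazard event hazard per month for the reference group.
#' @slot logHazardByGroup 4-vector of log hazard ratios (group 1 = reference
#'   when its entry is 0).
#' @slot censoringRate censoring hazard per month (0 = no censoring).
#' @slot covariateFrequencies named numeric vector of Bernoulli frequencies
#'   for binary clinical covariates.
#' @slot seed integer RNG seed.
#'
#' @seealso [cohortSimConfig()], [simulateCohort()]
#' @export
setClass("CohortSimConfig",
  representation(
    nSubjects = "integer",
    coresPerSubject = "integer",
    groupProbabilities = "numeric",
    baselineHazard = "numeric",
    logHazardByGroup = "numeric",
    censoringRate = "numeric",
    covariateFrequencies = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSimConfig", function(object) {
  msgs <- character()
  if (object@nSubjects < 1L) msgs <- c(msgs, "nSubjects must be >= 1")
  if (object@coresPerSubject < 1L) {
    msgs <- c(msgs, "coresPerSubject must be >= 1")
  }
  p <- object@groupProbabilities
  if (length(p) != 4L || any(p < 0) || any(p > 1)) {
    msgs <- c(msgs, "groupProbabilities must be a 4-vector in [0, 1]")
  } else if (abs(sum(p) - 1) > 1e-12) {
    msgs <- c(msgs, "groupProbabilities must sum to 1 (tolerance 1e-12)")
  }
  if (!is.finite(object@baselineHazard) || object@baselineHazard <= 0) {
    msgs <- c(msgs, "baselineHazard must be > 0")
  }
  if (length(object@logHazardByGroup) != 4L ||
      any(!is.finite(object@logHazardByGroup))) {
    msgs <- c(msgs, "logHazardByGroup must be a finite 4-vector")
  }
  if (!is.finite(object@censoringRate) || object@censoringRate < 0) {
    msgs <- c(msgs, "censoringRate must be >= 0")
  }
  cf <- object@covariateFrequencies
  if (length(cf) && (is.null(names(cf)) || any(cf < 0) || any(cf > 1))) {
    msgs <- c(msgs, "covariateFrequencies must be named probabilities")
  }
  if (length(msgs)) msgs else TRUE
})
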