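# Cross-type nearest-neighbour G analysis. The empirical cross-G function is
# the cumulative distribution of the distance from each reference cell
# (typically CK+ malignant) to its nearest target cell (an immune
# phenotype); it is compared with the theoretical Poisson curve
# G(r) = 1 - exp(-lambda * pi * r^2) of a completely random pattern with the
# same target intensity. The normalised area between the two curves is the
# mixing score used to call mixed vs unmixed distribution patterns.

#' Nearest-neighbour distances between two point sets
#'
#' Euclidean distance from each reference point to the closest target point.
#' When reference and target are the same set, pass \code{self = TRUE} so a
#' point's zero distance to itself is excluded.
#'
#' @param reference,target two-column coordinate matrices (micrometres), or
#'   [PointPattern-class] objects.
#' @param self TRUE when reference and target are the same points, row for
#'   row.
#' @return numeric vector, one distance per reference point.
#' @examples
#' nearestNeighborDistances(rbind(c(0, 0)), rbind(c(3, 4), c(10, 0)))  # 5
#' @export
nearestNeighborDistances <- function(reference, target, self = FALSE) {
  reference <- patternCoords(reference)
  target <- patternCoords(target)
  if (nrow(target) == 0L) {
    stop("target phenotype absent in core: cannot compute ",
         "nearest-neighbour distances")
  }
  if (self && nrow(reference) < 2L) {
    stop("self nearest-neighbour distances need >= 2 points")
  }
  nRef <- nrow(reference)
  out <- numeric(nRef)
  # block the reference rows so the distance matrix stays small
  block <- max(1L, floor(4e6 / max(1L, nrow(target))))
  for (start in seq(1L, nRef, by = block)) {
    idx <- start:min(nRef, start + block - 1L)
    dx <- outer(reference[idx, 1], target[, 1], "-")
    dy <- outer(reference[idx, 2], target[, 2], "-")
    d2 <- dx * dx + dy * dy
    if (self) {
      d2[cbind(seq_along(idx), idx)] <- Inf
    }
    out[idx] <- sqrt(apply(d2, 1L, min))
  }
  out
}

patternCoords <- function(x) {
  if (is(x, "PointPattern")) return(x@coords)
  x <- as.matrix(x)
  stopifnot(ncol(x) == 2)
  x
}

#' Empirical cross-G function
#'
#' Proportion of reference points whose nearest target neighbour lies within
#' distance r. With the border (reduced-sample) correction, only reference
#' points farther than r from the window boundary enter at each r, with the
#' denominator recomputed per r; this removes the censoring bias of points
#' whose true nearest neighbour may lie outside the window.
#'
#' @param reference,target [PointPattern-class] objects sharing a window, or
#'   coordinate matrices (then \code{window} must be given for the border
#'   correction).
#' @param rGrid increasing distances in micrometres.
#' @param edgeCorrection "border" or "none".
#' @param window observation window (taken from \code{reference} when it is
#'   a PointPattern).
#' @return numeric vector of G values per r; NA where the correction leaves
#'   no usable reference point (a warning is emitted once).
#' @export
empiricalCrossG <- function(reference, target, rGrid,
                            edgeCorrection = c("border", "none"),
                            window = NULL) {
  edgeCorrection <- match.arg(edgeCorrection)
  if (is.null(window) && is(reference, "PointPattern")) {
    window <- reference@window
  }
  refXY <- patternCoords(reference)
  d <- nearestNeighborDistances(refXY, target)
  if (edgeCorrection == "none") {
    return(vapply(rGrid, function(r) mean(d <= r), numeric(1)))
  }
  if (is.null(window)) {
    stop("border correction needs an observation window")
  }
  b <- boundaryDistance(refXY, window)
  g <- vapply(rGrid, function(r) {
    keep <- b > r
    if (!any(keep)) return(NA_real_)
    mean(d[keep] <= r)
  }, numeric(1))
  if (anyNA(g)) {
    warning("border correction left no reference point at r >= ",
            min(rGrid[is.na(g)]),
            " um; score integration truncates there")
  }
  monotonizeCDF(g)
}

# The reduced-sample estimator is a ratio with an r-dependent denominator
# and can dip locally; G is a CDF, so the running maximum is imposed.
monotonizeCDF <- function(g) {
  ok <- !is.na(g)
  g[ok] <- cummax(g[ok])
  g
}

#' Theoretical Poisson cross-G curve
#'
#' Under complete spatial randomness of the target phenotype with intensity
#' lambda, the nearest-neighbour distance distribution is
#' G(r) = 1 - exp(-lambda * pi * r^2).
#'
#' @param lambda target intensity in cells/mm^2 (converted internally to
#'   cells/um^2).
#' @param rGrid distances in micrometres.
#' @return numeric vector of G values.
#' @export
theoreticalPoissonG <- function(lambda, rGrid) {
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be >= 0")
  lamUM <- lambda / UM2_PER_MM2
  1 - exp(-lamUM * pi * rGrid^2)
}

#' Default distance grid for the cross-G analysis
#'
#' 1-um steps from 0 to the distance where the theoretical Poisson curve
#' reaches 0.99, capped at \code{cap} (about the core radius), so the score
#' is not dominated by the flat tail of the curves.
#'
#' @param lambda target intensity in cells/mm^2.
#' @param cap maximum r in micrometres.
#' @return numeric grid.
#' @export
defaultRGrid <- function(lambda, cap = 200) {
  lamUM <- lambda / UM2_PER_MM2
  rMax <- if (lamUM > 0) sqrt(log(100) / (lamUM * pi)) else cap
  0:ceiling(min(cap, rMax))
}

#' @rdname mixingScore
#' @param gTheo theoretical curve values (numeric method).
#' @param r distance grid (numeric method).
#' @export
setMethod("mixingScore", "numeric", function(x, gTheo, r) {
  gEmp <- x
  stopifnot(length(gEmp) == length(gTheo), length(r) == length(gTheo))
  valid <- !is.na(gEmp)
  if (!any(valid)) return(NA_real_)
  last <- if (all(valid)) length(gEmp) else min(which(!valid)) - 1L
  if (last < 2L) return(NA_real_)
  keep <- seq_len(last)
  denom <- trapezoid(r[keep], gTheo[keep])
  if (denom <= 0) return(NA_real_)
  100 * trapezoid(r[keep], gTheo[keep] - gEmp[keep]) / denom
})

#' @rdname mixingScore
#' @export
setMethod("mixingScore", "CrossGResult", function(x, ...) {
  mixingScore(x@gEmp, gTheo = x@gTheo, r = x@r)
})

trapezoid <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Classify a mixing score as mixed or unmixed
#'
#' Scores from -10 to 10 indicate a mixed (heterogeneous) pattern and scores
#' above 10 an unmixed (clustering) pattern. Scores below -10 indicate
#' attraction beyond randomness; they remain "mixed" (the band for unmixed
#' is only defined above 10) and are flagged via [attractionFlag()].
#'
#' @param score numeric vector of mixing scores.
#' @return character vector "mixed"/"unmixed" with NA propagated.
#' @export
classifyPattern <- function(score) {
  ifelse(is.na(score), NA_character_,
         ifelse(score > 10, "unmixed", "mixed"))
}

#' @rdname classifyPattern
#' @return \code{attractionFlag}: logical, TRUE where score < -10.
#' @export
attractionFlag <- function(score) {
  !is.na(score) & score < -10
}

#' Cross-G analysis of one reference/target phenotype pair in one core
#'
#' Runs the full comparison: empirical cross-G of the reference pattern
#' against the target pattern, theoretical Poisson curve at the target's
#' realised intensity, mixing score and pattern classification. Cores with
#' fewer than \code{minRef} reference or \code{minTarget} target cells give
#' an NA score and pattern (degenerate empirical CDFs are not interpreted).
#'
#' @param reference,target [PointPattern-class] objects sharing a window.
#' @param edgeCorrection "border" (default) or "none".
#' @param rMax optional cap for the distance grid in micrometres.
#' @param minRef,minTarget minimum cell counts per core.
#' @return a [CrossGResult-class].
#' @export
crossG <- function(reference, target, edgeCorrection = c("border", "none"),
                   rMax = 200, minRef = 5L, minTarget = 5L) {
  edgeCorrection <- match.arg(edgeCorrection)
  stopifnot(is(reference, "PointPattern"), is(target, "PointPattern"))
  nRef <- npoints(reference)
  nTarget <- npoints(target)
  lambda <- nTarget / areaMM2(reference)
  rGrid <- defaultRGrid(lambda, cap = rMax)
  gTheo <- theoreticalPoissonG(lambda, rGrid)
  if (nRef < minRef || nTarget < minTarget) {
    return(new("CrossGResult", r = as.numeric(rGrid),
               gEmp = rep(NA_real_, length(rGrid)), gTheo = gTheo,
               lambda = lambda, nRef = as.integer(nRef),
               nTarget = as.integer(nTarget), score = NA_real_,
               pattern = NA_character_, attraction = NA,
               edgeCorrection = edgeCorrection))
  }
  same <- identical(reference@coords, target@coords)
  gEmp <- if (same) {
    d <- nearestNeighborDistances(reference@coords, target@coords,
                                  self = TRUE)
    borderedCDF(d, reference@coords, reference@window, rGrid, edgeCorrection)
  } else {
    empiricalCrossG(reference, target, rGrid, edgeCorrection)
  }
  score <- mixingScore(gEmp, gTheo = gTheo, r = rGrid)
  new("CrossGResult", r = as.numeric(rGrid), gEmp = gEmp, gTheo = gTheo,
      lambda = lambda, nRef = as.integer(nRef),
      nTarget = as.integer(nTarget), score = score,
      pattern = classifyPattern(score),
      attraction = attractionFlag(score),
      edgeCorrection = edgeCorrection)
}

borderedCDF <- function(d, refXY, window, rGrid, edgeCorrection) {
  if (edgeCorrection == "none") {
    return(vapply(rGrid, function(r) mean(d <= r), numeric(1)))
  }
  b <- boundaryDistance(refXY, window)
  monotonizeCDF(vapply(rGrid, function(r) {
    keep <- b > r
    if (!any(keep)) return(NA_real_)
    mean(d[keep] <= r)
  }, numeric(1)))
}

setMethod("show", "CrossGResult", function(object) {
  cat(sprintf(
    "CrossGResult: n_ref=%d n_target=%d lambda=%.1f cells/mm^2\n",
    object@nRef, object@nTarget, object@lambda))
  cat(sprintf("  score = %s, pattern = %s%s (edge correction: %s)\n",
              formatC(object@score, digits = 3, format = "fg"),
              object@pattern,
              if (isTRUE(object@attraction)) " [attraction]" else "",
              object@edgeCorrection))
})

#' Plot a cross-G analysis
#'
#' Draws the empirical cross-G curve against the theoretical Poisson curve.
#'
#' @param x a [CrossGResult-class].
#' @param y ignored.
#' @param ... passed to \code{matplot}.
#' @return invisibly, x.
#' @export
plotCrossG <- function(x, y, ...) {
  graphics::matplot(x@r, cbind(x@gTheo, x@gEmp), type = "l", lty = c(2, 1),
                    col = c("grey40", "red3"), xlab = "r (um)", ylab = "G(r)",
                    ...)
  graphics::legend("bottomright", bty = "n", lty = c(2, 1),
                   col = c("grey40", "red3"),
                   legend = c("theoretical Poisson", "empirical cross-G"))
  graphics::mtext(sprintf("score = %.1f (%s)", x@score, x@pattern), cex = 0.9)
  invisible(x)
}
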