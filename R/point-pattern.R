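#' Build a typed point pattern from a cell table
#'
#' Selects the cells carrying a phenotype label and wraps them, with an
#' observation window, into a [PointPattern-class]. The default window is
#' the convex hull of *all* cells in the core (not only the phenotype), so a
#' reference and a target pattern from the same core share one window and one
#' area. A fitted circle (centred on the cell centroid, radius to the
#' farthest cell) or an explicit window may be used instead.
#'
#' @param cells data.frame with columns \code{x_um}, \code{y_um} and, unless
#'   \code{phenotype} is NULL, a logical column named after the phenotype
#'   (as produced by [assignPhenotypes()]) or a \code{phenotype} column.
#' @param phenotype phenotype label to select, or NULL to use all cells.
#' @param window "convex_hull" (default), "circle" (fitted), or a window list
#'   from [circleWindow()]/[polygonWindow()].
#' @param coreId core identifier stored in the result.
#' @return a [PointPattern-class].
#' @examples
#' cells <- data.frame(x_um = c(0, 500, 500, 0), y_um = c(0, 0, 500, 500))
#' p <- buildPointPattern(cells, window = "convex_hull")
#' areaMM2(p)  # 0.25
#' @export
buildPointPattern <- function(cells, phenotype = NULL,
                              window = "convex_hull", coreId = "core") {
  stopifnot(all(c("x_um", "y_um") %in% names(cells)))
  allXY <- cbind(x = cells$x_um, y = cells$y_um)
  if (is.character(window)) {
    window <- match.arg(window, c("convex_hull", "circle"))
    if (nrow(allXY) < 3L) {
      stop("need >= 3 cells in the core to fit a ", window, " window")
    }
    if (window == "convex_hull") {
      hull <- grDevices::chull(allXY)
      window <- polygonWindow(allXY[hull, , drop = FALSE])
    } else {
      ctr <- colMeans(allXY)
      rad <- sqrt(max((allXY[, 1] - ctr[1])^2 + (allXY[, 2] - ctr[2])^2))
      window <- circleWindow(ctr, 2 * rad)
    }
  }
  if (is.null(phenotype)) {
    xy <- allXY
    phenotype <- "all"
  } else if (phenotype %in% names(cells)) {
    xy <- allXY[as.logical(cells[[phenotype]]), , drop = FALSE]
  } else if ("phenotype" %in% names(cells)) {
    xy <- allXY[cells$phenotype == phenotype, , drop = FALSE]
  } else {
    stop("no column for phenotype '", phenotype, "' in the cell table")
  }
  new("PointPattern", coords = xy, window = window,
      phenotype = phenotype, coreId = as.character(coreId))
}

#' @rdname npoints
#' @export
setMethod("npoints", "PointPattern", function(x) nrow(x@coords))

#' @rdname areaMM2
#' @export
setMethod("areaMM2", "PointPattern", function(x) windowAreaMM2(x@window))

setMethod("show", "PointPattern", function(object) {
  cat(sprintf("PointPattern: %d '%s' cells in a %s window of %.4f mm^2 (core %s)\n",
              npoints(object), object@phenotype, object@window$type,
              areaMM2(object), object@coreId))
})

#' Cell density of a point pattern
#'
#' Density in cells/mm^2: point count divided by window area.
#'
#' @param pattern a [PointPattern-class].
#' @return one-row data.frame with columns \code{phenotype}, \code{core_id},
#'   \code{density}.
#' @export
computeDensity <- function(pattern) {
  stopifnot(is(pattern, "PointPattern"))
  a <- areaMM2(pattern)
  if (a <= 0) stop("window area is zero")
  data.frame(phenotype = pattern@phenotype, core_id = pattern@coreId,
             density = npoints(pattern) / a, stringsAsFactors = FALSE)
}

#' Filter phenotypes by cohort median density
#'
#' A phenotype is retained when its median density across samples is at or
#' above the threshold (default 2 cells/mm^2); less abundant phenotypes are
#' excluded from the spatial analysis to avoid unstable estimates.
#'
#' @param densities data.frame with columns \code{phenotype} and
#'   \code{density} (one row per sample and phenotype).
#' @param threshold minimum median density in cells/mm^2.
#' @return character vector of retained phenotype names.
#' @export
filterPhenotypesByMedianDensity <- function(densities, threshold = 2) {
  stopifnot(is.data.frame(densities),
            all(c("phenotype", "density") %in% names(densities)))
  if (nrow(densities) == 0) stop("empty density table")
  med <- tapply(densities$density, densities$phenotype,
                stats::median, na.rm = TRUE)
  names(med)[!is.na(med) & med >= threshold]
}
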