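#' Number of points in a pattern
#'
#' @param x a [PointPattern-class].
#' @return integer point count.
#' @export
setGeneric("npoints", function(x) standardGeneric("npoints"))

#' Window area in square millimetres
#'
#' @param x a [PointPattern-class].
#' @return numeric area in mm^2.
#' @export
setGeneric("areaMM2", function(x) standardGeneric("areaMM2"))

#' Mixing score of a cross-G analysis
#'
#' The normalised area deviation between the theoretical Poisson curve and
#' the empirical cross-G curve:
#' \deqn{score = 100 \frac{\int_0^{r_{max}} [G_{theo}(r) - G_{emp}(r)]\,dr}
#'                        {\int_0^{r_{max}} G_{theo}(r)\,dr}}
#' computed by trapezoidal integration. Positive scores mean nearest target
#' neighbours are farther from reference cells than complete spatial
#' randomness predicts (segregation/clustering); scores near zero indicate
#' mixing; negative scores indicate attraction.
#'
#' @param x a [CrossGResult-class], or a numeric vector of empirical G values
#'   (then supply \code{gTheo} and \code{r}).
#' @param ... passed to methods.
#' @return numeric score (NA when the theoretical curve is identically 0).
#' @export
setGeneric("mixingScore", function(x, ...) standardGeneric("mixingScore"))
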