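# Window geometry helpers. Coordinates are micrometres throughout; areas are
# reported in mm^2 (1 mm^2 = 1e6 um^2).

UM2_PER_MM2 <- 1e6

#' Construct a circular observation window
#'
#' @param centre numeric length-2 centre (micrometres).
#' @param diameter circle diameter in micrometres.
#' @return window list usable in [PointPattern-class] objects.
#' @export
circleWindow <- function(centre = c(0, 0), diameter = 1000) {
  stopifnot(is.numeric(centre), length(centre) == 2, diameter > 0)
  list(type = "circle", centre = as.numeric(centre),
       radius = diameter / 2)
}

#' Construct a polygonal observation window
#'
#' @param vertices n x 2 matrix of vertices (micrometres), implicitly closed.
#' @return window list.
#' @export
polygonWindow <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3)
  list(type = "polygon", vertices = vertices)
}

# Shoelace formula; vertices in either orientation.
polygonAreaUM2 <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

windowAreaMM2 <- function(window) {
  a <- switch(window$type,
    circle = pi * window$radius^2,
    polygon = polygonAreaUM2(window$vertices),
    stop("unknown window type: ", window$type)
  )
  a / UM2_PER_MM2
}

# Signed distance from points to the window boundary; positive inside.
boundaryDistance <- function(xy, window) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  if (window$type == "circle") {
    d <- sqrt((xy[, 1] - window$centre[1])^2 +
              (xy[, 2] - window$centre[2])^2)
    return(window$radius - d)
  }
  v <- window$vertices
  n <- nrow(v)
  dmin <- rep(Inf, nrow(xy))
  for (i in seq_len(n)) {
    a <- v[i, ]
    b <- v[if (i == n) 1L else i + 1L, ]
    dmin <- pmin(dmin, pointSegmentDistance(xy, a, b))
  }
  inside <- pointInPolygon(xy, v)
  ifelse(inside, dmin, -dmin)
}

pointSegmentDistance <- function(xy, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return(sqrt((xy[, 1] - a[1])^2 + (xy[, 2] - a[2])^2))
  }
  t <- ((xy[, 1] - a[1]) * ab[1] + (xy[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  px <- a[1] + t * ab[1]
  py <- a[2] + t * ab[2]
  sqrt((xy[, 1] - px)^2 + (xy[, 2] - py)^2)
}

# Ray-casting test; boundary points are treated as inside by the small
# tolerance applied by callers.
pointInPolygon <- function(xy, v) {
  n <- nrow(v)
  inside <- rep(FALSE, nrow(xy))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > xy[, 2]) != (yj > xy[, 2])) &
      (xy[, 1] < (xj - xi) * (xy[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  # count points on the boundary as inside (closed window)
  onb <- rep(FALSE, nrow(xy))
  jj <- n
  for (i in seq_len(n)) {
    onb <- onb | pointSegmentDistance(xy, v[i, ], v[jj, ]) < 1e-9
    jj <- i
  }
  inside | onb
}

# Uniform points in a window by rejection from the bounding box.
runifWindow <- function(n, window) {
  if (n == 0) {
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("x", "y"))))
  }
  if (window$type == "circle") {
    r <- window$radius * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    out <- cbind(x = window$centre[1] + r * cos(th),
                 y = window$centre[2] + r * sin(th))
    return(out)
  }
  v <- window$vertices
  xr <- range(v[, 1]); yr <- range(v[, 2])
  got <- matrix(numeric(0), ncol = 2)
  while (nrow(got) < n) {
    m <- max(2L * (n - nrow(got)), 16L)
    cand <- cbind(stats::runif(m, xr[1], xr[2]),
                  stats::runif(m, yr[1], yr[2]))
    keep <- pointInPolygon(cand, v)
    got <- rbind(got, cand[keep, , drop = FALSE])
  }
  out <- got[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}
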