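# Independent oracles (deliberately naive double loops / closed forms) and
# small fixture builders used across the test files.

# O(n*m) scan: distance from each reference point to its nearest target.
bruteNN <- function(ref, tgt, self = FALSE) {
  vapply(seq_len(nrow(ref)), function(i) {
    d <- sqrt((tgt[, 1] - ref[i, 1])^2 + (tgt[, 2] - ref[i, 2])^2)
    if (self) d[i] <- Inf
    min(d)
  }, numeric(1))
}

# Uncorrected empirical cross-G by explicit double loop.
bruteCrossG <- function(ref, tgt, rGrid) {
  d <- bruteNN(ref, tgt)
  vapply(rGrid, function(r) sum(d <= r) / length(d), numeric(1))
}

# Border-corrected cross-G written independently of the package internals,
# for a circular window centred at the origin.
slowBorderG <- function(ref, tgt, radius, rGrid) {
  d <- bruteNN(ref, tgt)
  b <- radius - sqrt(ref[, 1]^2 + ref[, 2]^2)
  g <- vapply(rGrid, function(r) {
    keep <- which(b > r)
    if (length(keep) == 0) return(NA_real_)
    sum(d[keep] <= r) / length(keep)
  }, numeric(1))
  # running maximum: the estimand is a CDF
  best <- -Inf
  for (i in seq_along(g)) {
    if (is.na(g[i])) next
    best <- max(best, g[i])
    g[i] <- best
  }
  g
}

# Shoelace polygon area (um^2), vertex loop written out long-hand.
shoelaceArea <- function(v) {
  n <- nrow(v)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + v[i, 1] * v[j, 2] - v[j, 1] * v[i, 2]
  }
  abs(s) / 2
}

randomPoints <- function(n, radius = 500) {
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th))
}

# one CSR core as a raw cell table (reference + one target phenotype)
csrCoreCells <- function(seed, lambdaRef = 100, lambdaTarget = 100) {
  cfg <- coreSimConfig(lambdaRef,
                       list(phenotypeSimSpec("T", "csr",
                                             intensity = lambdaTarget)),
                       seed = seed)
  simulateCore(cfg)
}

circleWin1mm <- function() circleWindow(c(0, 0), 1000)

corePatterns <- function(cells, target = "T", window = circleWin1mm()) {
  list(ref = buildPointPattern(cells, "CK+", window = window),
       tgt = buildPointPattern(cells, target, window = window))
}
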