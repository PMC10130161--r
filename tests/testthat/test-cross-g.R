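test_that("nearest-neighbour distances match hand geometry and exclude self", {
  expect_equal(nearestNeighborDistances(rbind(c(0, 0)),
                                        rbind(c(3, 4), c(10, 0))), 5)
  two <- rbind(c(0, 0), c(7, 0))
  expect_equal(nearestNeighborDistances(two, two, self = TRUE), c(7, 7))
  expect_error(nearestNeighborDistances(rbind(c(0, 0)), two[0, ]),
               "absent")
})

test_that("nearest-neighbour distances equal the brute-force scan", {
  set.seed(11)
  for (i in 1:5) {
    ref <- randomPoints(50)
    tgt <- randomPoints(80)
    expect_identical(nearestNeighborDistances(ref, tgt), bruteNN(ref, tgt))
    expect_identical(nearestNeighborDistances(ref, ref, self = TRUE),
                     bruteNN(ref, ref, self = TRUE))
  }
})

test_that("uncorrected empirical G is the NN-distance ECDF", {
  ref <- rbind(c(0, 0), c(100, 0), c(200, 0))
  tgt <- rbind(c(2, 0), c(104, 0), c(206, 0))  # NN distances 2, 4, 6
  g <- empiricalCrossG(ref, tgt, rGrid = 5, edgeCorrection = "none")
  expect_equal(g, 2 / 3)
  expect_equal(empiricalCrossG(ref, tgt, 1.9, edgeCorrection = "none"), 0)
  expect_equal(empiricalCrossG(ref, tgt, 6, edgeCorrection = "none"), 1)
})

test_that("border-corrected G matches an independent slow implementation", {
  set.seed(23)
  win <- circleWin1mm()
  rGrid <- 0:150
  for (i in 1:3) {
    ref <- randomPoints(120)
    tgt <- randomPoints(90)
    fast <- empiricalCrossG(ref, tgt, rGrid, "border", window = win)
    slow <- slowBorderG(ref, tgt, 500, rGrid)
    expect_equal(fast, slow)
  }
})

test_that("theoretical Poisson G matches its closed form", {
  r <- c(0, 1, 5, 20, 100)
  for (lam in c(0, 10, 100, 1000)) {
    expect_equal(theoreticalPoissonG(lam, r),
                 1 - exp(-(lam / 1e6) * pi * r^2), tolerance = 1e-14)
  }
  expect_equal(theoreticalPoissonG(0, r), rep(0, 5))
  expect_equal(theoreticalPoissonG(123, 0), 0)
  # lambda*pi*r^2 = ln 2  =>  G = 1/2
  lam <- 100
  r50 <- sqrt(log(2) / ((lam / 1e6) * pi))
  expect_equal(theoreticalPoissonG(lam, r50), 0.5)
  expect_error(theoreticalPoissonG(-1, r), "lambda")
})

test_that("mixing score is 0 on identity and 100 on an empty empirical CDF", {
  r <- 0:100
  gTheo <- theoreticalPoissonG(200, r)
  expect_identical(mixingScore(gTheo, gTheo = gTheo, r = r), 0)
  expect_identical(mixingScore(rep(0, length(r)), gTheo = gTheo, r = r), 100)
  # lambda = 0: theoretical curve identically zero, score undefined
  expect_true(is.na(mixingScore(rep(0, 101), gTheo = rep(0, 101), r = r)))
})

test_that("pattern classification follows the -10/10 band", {
  expect_equal(classifyPattern(0), "mixed")
  expect_equal(classifyPattern(15), "unmixed")
  expect_equal(classifyPattern(10), "mixed")       # boundary stays mixed
  expect_equal(classifyPattern(-25), "mixed")      # attraction side
  expect_true(attractionFlag(-25))
  expect_false(attractionFlag(-3))
  expect_true(is.na(classifyPattern(NA)))
})

test_that("computed G curves are nondecreasing and bounded in [0, 1]", {
  for (i in 1:10) {
    cells <- csrCoreCells(300 + i)
    pats <- corePatterns(cells)
    res <- crossG(pats$ref, pats$tgt)
    ok <- !is.na(res@gEmp)
    expect_true(all(diff(res@gEmp[ok]) >= 0))
    expect_true(all(res@gEmp[ok] >= 0 & res@gEmp[ok] <= 1))
    expect_true(all(diff(res@gTheo) >= 0))
    expect_equal(res@gTheo[1], 0)
  }
})

test_that("the score is invariant to rigid motions of the coordinates", {
  cells <- csrCoreCells(77)
  pats <- corePatterns(cells)
  s0 <- crossG(pats$ref, pats$tgt)@score
  th <- 1.1
  rot <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  xy <- as.matrix(cells[, c("x_um", "y_um")]) %*% rot
  moved <- cells
  moved$x_um <- xy[, 1] + 5000
  moved$y_um <- xy[, 2] - 3000
  pats2 <- corePatterns(moved,
                        window = circleWindow(c(5000, -3000), 1000))
  expect_equal(crossG(pats2$ref, pats2$tgt)@score, s0, tolerance = 1e-9)
})

test_that("cores below the minimum counts yield NA scores", {
  cells <- csrCoreCells(9, lambdaRef = 100, lambdaTarget = 4)
  pats <- corePatterns(cells)
  res <- crossG(pats$ref, pats$tgt, minTarget = 10L)
  expect_true(is.na(res@score))
  expect_true(is.na(res@pattern))
})

test_that("cohort scoring returns an empty table for no phenotypes", {
  cells <- csrCoreCells(2)
  out <- scoreAllPhenotypes(cells, character(0), rules = NULL)
  expect_s3_class(out, "data.frame")
  expect_equal(nrow(out), 0L)
})
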