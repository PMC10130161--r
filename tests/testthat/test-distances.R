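test_that("median NN distance matches hand values and the brute oracle", {
  ref <- rbind(c(0, 0), c(100, 0), c(200, 0))
  tgt <- rbind(c(2, 0), c(104, 0), c(206, 0))
  expect_equal(medianNNDistance(ref, tgt), 4)  # distances 2, 4, 6
  expect_equal(medianNNDistance(rbind(c(0, 0)), rbind(c(10, 0))), 10)
  set.seed(31)
  for (i in 1:5) {
    a <- randomPoints(100)
    b <- randomPoints(100)
    expect_identical(medianNNDistance(a, b), median(bruteNN(a, b)))
  }
  expect_warning(d <- medianNNDistance(ref, ref[0, ]), "empty")
  expect_true(is.na(d))
})

test_that("median NN distance is rigid-motion invariant and scales linearly", {
  set.seed(13)
  a <- randomPoints(60)
  b <- randomPoints(40)
  d0 <- medianNNDistance(a, b)
  th <- 0.4
  rot <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  shift <- c(111, -222)
  expect_equal(medianNNDistance(sweep(a %*% rot, 2, shift),
                                sweep(b %*% rot, 2, shift)), d0,
               tolerance = 1e-10)
  expect_equal(medianNNDistance(3 * a, 3 * b), 3 * d0, tolerance = 1e-10)
})

test_that("a superset phenotype is never farther than its subset", {
  # CD3+ contains CD3+CD8+: the nearest CD3+ cell is at most as far as the
  # nearest CD3+CD8+ cell, for every core
  set.seed(17)
  for (i in 1:10) {
    mal <- randomPoints(50)
    cd3cd8 <- randomPoints(30)
    cd3only <- randomPoints(40)
    cd3 <- rbind(cd3cd8, cd3only)
    expect_lte(medianNNDistance(mal, cd3), medianNNDistance(mal, cd3cd8))
  }
})

test_that("the default pair list has the full 128 measured distances", {
  pairs <- defaultDistancePairs()
  expect_equal(nrow(pairs), 128L)
  expect_equal(anyDuplicated(pairs), 0L)
  expect_equal(sum(pairs$reference == "CK+"), 26L)
  expect_true(all(c("CK+PD-L1+", "CK+PD-L1neg", "CK+B7-H3+", "CK+B7-H4+",
                    "CK+IDO-1+", "CD3+CD8negFOXP3+") %in% pairs$reference))
})

test_that("dichotomization at the cohort median follows the tie rule", {
  expect_identical(dichotomizeAtCohortMedian(c(1, 2, 3, 4)),
                   c("close", "close", "long", "long"))
  expect_identical(dichotomizeAtCohortMedian(c(5, 5, 5)),
                   rep("close", 3))  # all equal: all at-or-below median
  expect_identical(dichotomizeAtCohortMedian(c(5, NA, 7)),
                   c("close", NA, "long"))
  expect_error(dichotomizeAtCohortMedian(c(NA_real_, NA_real_)), "non-NA")
})

test_that("close counts dominate and the split is monotone-invariant", {
  set.seed(29)
  for (i in 1:50) {
    v <- switch(1 + i %% 3,
                rnorm(sample(3:40, 1)),
                rexp(sample(3:40, 1)),
                sample(1:5, sample(3:40, 1), replace = TRUE))
    cl <- dichotomizeAtCohortMedian(v)
    expect_gte(sum(cl == "close"), sum(cl == "long"))
    # strictly increasing transforms preserve the split
    expect_identical(dichotomizeAtCohortMedian(exp(v)), cl)
    expect_identical(dichotomizeAtCohortMedian(v^3), cl)
  }
})

test_that("attraction shortens distances relative to CSR at equal intensity", {
  deltas <- vapply(1:20, function(i) {
    specs <- list(
      phenotypeSimSpec("att", "attraction", intensity = 60,
                       attractionScale = 20),
      phenotypeSimSpec("csr", "csr", intensity = 60))
    cells <- simulateCore(coreSimConfig(80, specs, seed = 700 + i))
    mal <- as.matrix(cells[cells$phenotype == "CK+", c("x_um", "y_um")])
    att <- as.matrix(cells[cells$phenotype == "att", c("x_um", "y_um")])
    csr <- as.matrix(cells[cells$phenotype == "csr", c("x_um", "y_um")])
    medianNNDistance(mal, csr) - medianNNDistance(mal, att)
  }, numeric(1))
  expect_true(all(deltas > 0))
})

test_that("the distance panel aggregates cores by median per subject", {
  cells1 <- simulateCore(coreSimConfig(40, list(
    phenotypeSimSpec("T", "csr", intensity = 40)), seed = 1),
    subjectId = "s1", coreId = "c1")
  panel <- distancePanel(cells1,
                         data.frame(reference = "CK+", target = "T"),
                         rules = NULL)
  # one-core subject: the subject value equals the core value
  mal <- as.matrix(cells1[cells1$phenotype == "CK+", c("x_um", "y_um")])
  tgt <- as.matrix(cells1[cells1$phenotype == "T", c("x_um", "y_um")])
  expect_equal(panel$median_nn_um, medianNNDistance(mal, tgt))
  # absent phenotype: pair dropped with a warning
  expect_warning(
    distancePanel(cells1, data.frame(reference = "CK+", target = "ghost"),
                  rules = NULL),
    "absent")
})
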