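test_that("core simulation is bit-identical under a fixed seed", {
  cfg <- coreSimConfig(80, list(
    phenotypeSimSpec("T", "attraction", intensity = 60,
                     attractionScale = 25),
    phenotypeSimSpec("C", "segregated_cluster", clusterParentIntensity = 10,
                     clusterOffspringMean = 5, clusterScale = 15,
                     exclusionRadius = 30)), seed = 99)
  expect_identical(simulateCore(cfg), simulateCore(cfg))
  # different seed, different draw
  cfg2 <- coreSimConfig(80, cfg@phenotypes, seed = 100)
  expect_false(identical(simulateCore(cfg), simulateCore(cfg2)))
})

test_that("zero intensity yields zero cells of that phenotype", {
  cfg <- coreSimConfig(50, list(phenotypeSimSpec("T", "csr",
                                                 intensity = 0)), seed = 3)
  cells <- simulateCore(cfg)
  expect_equal(sum(cells$phenotype == "T"), 0L)
  expect_gt(sum(cells$phenotype == "CK+"), 0L)
})

test_that("realised counts match lambda * area in expectation", {
  # 200 replicates of a CSR core at 100 cells/mm^2 in a 1-mm circle:
  # expected count 100 * pi/4 = 78.54, Poisson distributed
  counts <- vapply(1:200, function(i) {
    sum(simulateCore(coreSimConfig(0, list(
      phenotypeSimSpec("T", "csr", intensity = 100)),
      seed = i))$phenotype == "T")
  }, numeric(1))
  expected <- 100 * pi / 4
  se <- sqrt(expected / 200)  # Poisson SE of the mean
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("attraction points hug malignant cells; clusters segregate", {
  win <- circleWin1mm()
  deltas <- vapply(1:10, function(i) {
    specs <- list(
      phenotypeSimSpec("near", "attraction", intensity = 100,
                       attractionScale = 20),
      phenotypeSimSpec("far", "segregated_cluster",
                       clusterParentIntensity = 10,
                       clusterOffspringMean = 10, clusterScale = 20,
                       exclusionRadius = 100))
    cells <- simulateCore(coreSimConfig(60, specs, seed = 500 + i))
    mal <- as.matrix(cells[cells$phenotype == "CK+", c("x_um", "y_um")])
    near <- as.matrix(cells[cells$phenotype == "near", c("x_um", "y_um")])
    far <- as.matrix(cells[cells$phenotype == "far", c("x_um", "y_um")])
    medianNNDistance(mal, far) - medianNNDistance(mal, near)
  }, numeric(1))
  expect_true(all(deltas > 0))
})

test_that("infeasible exclusion radius raises an error naming the phenotype", {
  cfg <- coreSimConfig(500, list(
    phenotypeSimSpec("blocked", "segregated_cluster",
                     clusterParentIntensity = 20, clusterOffspringMean = 5,
                     clusterScale = 10, exclusionRadius = 400)), seed = 8)
  expect_error(simulateCore(cfg), "blocked")
})

test_that("config validity catches bad probabilities and hazards", {
  expect_error(cohortSimConfig(10, groupProbabilities = c(0.3, 0.3, 0.3, 0.3)),
               "sum to 1")
  expect_error(cohortSimConfig(10, baselineHazard = 0), "baselineHazard")
  expect_error(phenotypeSimSpec("x", "attraction", intensity = 5),
               "attractionScale")
  expect_error(coreSimConfig(-5), "malignantIntensity")
})

test_that("cohort simulation: censoring, ground truth and determinism", {
  cfg <- cohortSimConfig(40, censoringRate = 0, seed = 21,
                         coresPerSubject = 1L)
  cohort <- simulateCohort(cfg)
  expect_true(all(cohort$clinical$os_event == 1L))  # no censoring
  expect_true(all(cohort$clinical$group_true %in% 1:4))
  expect_equal(nrow(cohort$clinical), 40L)
  expect_identical(simulateCohort(cfg), cohort)
  # every subject contributed cells for malignant and anchor phenotypes
  byS <- table(cohort$cells$subject_id, cohort$cells$phenotype)
  expect_true(all(byS[, "CK+"] > 0))
  expect_true(all(byS[, "CD3+"] > 0))
})

test_that("null group hazards give exchangeable survival across groups", {
  cfg <- cohortSimConfig(300, logHazardByGroup = c(0, 0, 0, 0),
                         seed = 77, coresPerSubject = 1L)
  # survival draws only; skip the spatial part by reading the clinical table
  cl <- simulateCohort(cfg)$clinical
  sd <- survival::survdiff(
    survival::Surv(os_months, os_event) ~ factor(group_true), data = cl)
  p <- stats::pchisq(sd$chisq, df = 3, lower.tail = FALSE)
  expect_gt(p, 0.01)
})
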