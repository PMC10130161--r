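test_that("the four-way group mapping is exactly as defined", {
  expect_equal(assignGroup("mixed", "close"), 1L)
  expect_equal(assignGroup("mixed", "long"), 2L)
  expect_equal(assignGroup("unmixed", "close"), 3L)
  expect_equal(assignGroup("unmixed", "long"), 4L)
  # bijection between the label pairs and 1..4
  combos <- expand.grid(pattern = c("mixed", "unmixed"),
                        dc = c("close", "long"),
                        stringsAsFactors = FALSE)
  g <- assignGroup(combos$pattern, combos$dc)
  expect_setequal(g, 1:4)
  expect_true(is.na(assignGroup(NA, "close")))
  expect_true(is.na(assignGroup("mixed", NA)))
  expect_error(assignGroup("odd", "close"), "pattern")
})

test_that("group prevalence sums to one and ignores order", {
  expect_equal(unname(groupPrevalence(c(1, 1, 2, 4))),
               c(0.5, 0.25, 0, 0.25))
  expect_equal(unname(groupPrevalence(rep(3, 7))), c(0, 0, 1, 0))
  set.seed(3)
  g <- sample(1:4, 50, replace = TRUE)
  expect_identical(groupPrevalence(g), groupPrevalence(rev(g)))
  expect_equal(sum(groupPrevalence(g)), 1, tolerance = 1e-12)
  expect_error(groupPrevalence(NA_integer_), "non-NA")
})

test_that("identical density distributions give a null Kruskal-Wallis", {
  set.seed(8)
  n <- 80
  asg <- data.frame(subject_id = sprintf("s%03d", 1:n),
                    group = rep(1:4, each = n / 4))
  dens <- data.frame(subject_id = asg$subject_id, phenotype = "CD3+",
                     density = rep(c(5, 7, 9, 11), times = n / 4))
  out <- densitiesByGroup(dens, asg)
  expect_lt(out$kw_statistic, 1)
  expect_gt(out$p_value, 0.5)
})

test_that("an inflamed group with 5x densities is detected", {
  set.seed(15)
  n <- 200
  asg <- data.frame(subject_id = sprintf("s%03d", 1:n),
                    group = sample(1:4, n, replace = TRUE))
  base <- rlnorm(n, log(40), 0.4)
  dens <- data.frame(subject_id = asg$subject_id, phenotype = "CD3+",
                     density = ifelse(asg$group == 2, 5 * base, base))
  out <- densitiesByGroup(dens, asg)
  expect_lt(out$p_value, 0.01)
  expect_equal(which.max(unlist(out[1, c("group1", "group2", "group3",
                                         "group4")])), 2L,
               ignore_attr = TRUE)
})

test_that("sparse groups report medians but skip the test", {
  asg <- data.frame(subject_id = c("a", "b", "c"), group = c(1, 1, 2))
  dens <- data.frame(subject_id = c("a", "b", "c"), phenotype = "p",
                     density = c(4, 6, 9))
  expect_warning(out <- densitiesByGroup(dens, asg), "skipped")
  expect_equal(out$group1, 5)
  expect_true(is.na(out$p_value))
})

test_that("strong-effect presets recover the intended group per core batch", {
  # cores simulated under each preset end in the matching group when
  # pattern and distance are classified against the other presets
  presets <- groupRegimePresets()
  perGroup <- lapply(1:4, function(g) {
    vapply(1:12, function(i) {
      cfg <- coreSimConfig(presets[[g]]$malignantIntensity,
                           presets[[g]]$phenotypes, seed = g * 100 + i)
      cells <- simulateCore(cfg)
      ref <- buildPointPattern(cells, "CK+", window = "convex_hull")
      tgt <- buildPointPattern(cells, "CD3+", window = ref@window)
      c(score = crossG(ref, tgt)@score,
        dist = medianNNDistance(ref, tgt))
    }, numeric(2))
  })
  # dichotomize distances across all cores, classify patterns per core
  allDist <- unlist(lapply(perGroup, function(m) m["dist", ]))
  dc <- dichotomizeAtCohortMedian(allDist)
  pat <- classifyPattern(unlist(lapply(perGroup,
                                       function(m) m["score", ])))
  got <- assignGroup(pat, dc)
  truth <- rep(1:4, each = 12)
  # attraction+near cores recover group 1 with high frequency
  expect_gte(mean(got[truth == 1] == 1), 0.8)
  expect_gte(mean(got == truth), 0.7)
})
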