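test_that("rank tests dispatch on the number of clinical levels", {
  set.seed(4)
  d <- data.frame(score = rnorm(60),
                  smoker = rep(c(0, 1), 30),
                  stage = rep(c("I", "II", "III"), 20))
  out2 <- featureClinicalTests(d, "score", "smoker")
  out3 <- featureClinicalTests(d, "score", "stage")
  expect_equal(out2$test, "wilcoxon")
  expect_equal(out3$test, "kruskal-wallis")
})

test_that("identical groups give a null rank test; constants are skipped", {
  d <- data.frame(score = rep(c(1, 2, 3, 4, 5), 4),
                  arm = rep(c("a", "b"), each = 10))
  out <- featureClinicalTests(d, "score", "arm")
  expect_gte(out$p_value, 0.95)
  d$flat <- 1
  expect_warning(out2 <- featureClinicalTests(d, "flat", "arm"),
                 "constant")
  expect_true(is.na(out2$p_value))
})

test_that("a shifted score separates clinical groups with power", {
  set.seed(19)
  hits <- vapply(1:20, function(i) {
    d <- data.frame(score = c(rnorm(100, 0, 10), rnorm(100, 15, 10)),
                    smoker = rep(0:1, each = 100))
    featureClinicalTests(d, "score", "smoker")$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("rank tests are invariant to monotone transforms of the feature", {
  set.seed(2)
  d <- data.frame(score = rexp(40), arm = rep(c("x", "y"), 20))
  p1 <- featureClinicalTests(d, "score", "arm")$p_value
  d$score <- log(d$score + 1)
  expect_equal(featureClinicalTests(d, "score", "arm")$p_value, p1)
})

test_that("log-rank on identical arms is exactly null and label-symmetric", {
  t0 <- c(2, 4, 6, 8, 10, 12)
  d <- data.frame(time = rep(t0, 2), event = 1,
                  arm = rep(c("a", "b"), each = 6))
  out <- kmLogrank(d$time, d$event, d$arm)
  expect_equal(out$chisq, 0, tolerance = 1e-12)
  expect_equal(out$p, 1, tolerance = 1e-12)
  swapped <- kmLogrank(d$time, d$event, ifelse(d$arm == "a", "b", "a"))
  expect_equal(swapped$p, out$p)
  # KM estimates are nonincreasing step functions within [0, 1]
  s <- out$fit$surv
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(diff(out$fit$surv[1:out$fit$strata[1]]) <= 0))
  expect_error(kmLogrank(d$time, rep(0, 12), d$arm), "event")
})

test_that("log-rank detects a doubled hazard with power", {
  set.seed(6)
  hits <- vapply(1:30, function(i) {
    time <- c(rexp(200, 0.02), rexp(200, 0.04))
    arm <- rep(c("a", "b"), each = 200)
    cens <- rexp(400, 0.005)
    kmLogrank(pmin(time, cens), as.integer(time <= cens), arm)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Cox recovery: a true HR of 2 is estimated without material bias", {
  set.seed(10)
  est <- vapply(c(100, 500), function(n) {
    hrs <- vapply(1:20, function(i) {
      x <- rbinom(n, 1, 0.5)
      time <- rexp(n, 0.02 * 2^x)
      cens <- rexp(n, 0.01)
      d <- data.frame(time = pmin(time, cens),
                      event = as.integer(time <= cens), x = x)
      coxPH(survival::Surv(time, event) ~ x, d)$table$HR
    }, numeric(1))
    median(log(hrs))
  }, numeric(1))
  # bias of log-HR shrinks toward 0 with n and is small at n = 500
  expect_lt(abs(est[2] - log(2)), 0.15)
  expect_lte(abs(est[2] - log(2)), abs(est[1] - log(2)) + 0.1)
})

test_that("Cox guards: constant covariates and separation are surfaced", {
  d <- data.frame(time = rexp(40), event = rbinom(40, 1, 0.9), x = 1)
  expect_error(coxPH(survival::Surv(time, event) ~ x, d), "constant")
  # complete separation: the covariate splits event times perfectly
  d2 <- data.frame(time = c(1:20, 101:120), event = 1,
                   x = rep(c(1, 0), each = 20))
  w <- capture_warnings(fit <- coxPH(survival::Surv(time, event) ~ x, d2))
  expect_true(any(grepl("separation", w)))
  expect_true(any(fit$separation))
})

test_that("multivariable report drops collinear features and reduces cleanly", {
  set.seed(12)
  n <- 120
  d <- data.frame(time = rexp(n, 0.05), event = rbinom(n, 1, 0.8),
                  a = rbinom(n, 1, 0.5), smoker = rbinom(n, 1, 0.5))
  d$b <- d$a  # exact copy
  expect_warning(
    fit <- multivariableReport(d, time = "time", event = "event",
                               spatialTerms = c("a", "b"),
                               clinicalTerms = "smoker"),
    "collinear")
  expect_equal(fit$dropped, "b")
  # no spatial features: identical to the clinical-only fit
  f1 <- multivariableReport(d, time = "time", event = "event",
                            clinicalTerms = "smoker")
  f2 <- coxPH(survival::Surv(time, event) ~ smoker, d)
  expect_equal(f1$table$B, f2$table$B)
  expect_equal(f1$table$SE, f2$table$SE)
})
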