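# Association and survival statistics for spatial features: rank tests
# against clinical variables, Kaplan-Meier/log-rank comparisons and Cox
# proportional hazards models (Efron tie handling). Tests are two-sided and
# p-values are reported unadjusted; an optional Benjamini-Hochberg column is
# available for users who want multiplicity control.

#' Rank tests of a spatial feature across clinical groups
#'
#' Wilcoxon rank-sum for two-level grouping variables, Kruskal-Wallis for
#' more levels. Constant features are skipped with a warning.
#'
#' @param data data.frame holding feature and grouping columns.
#' @param features character vector of numeric feature columns (e.g. mixing
#'   scores or distances).
#' @param by name of the grouping column (a clinical variable).
#' @param adjust add a Benjamini-Hochberg adjusted column.
#' @return data.frame: feature, test, statistic, p_value (and p_adjusted).
#' @export
featureClinicalTests <- function(data, features, by, adjust = FALSE) {
  g <- factor(data[[by]])
  if (nlevels(droplevels(g)) < 2L) {
    stop("grouping variable '", by, "' needs >= 2 observed levels")
  }
  if (any(table(droplevels(g)) < 2L)) {
    stop("each level of '", by, "' needs >= 2 observations")
  }
  rows <- lapply(features, function(f) {
    x <- data[[f]]
    ok <- !is.na(x) & !is.na(g)
    if (length(unique(x[ok])) < 2L) {
      warning("feature '", f, "' is constant; test skipped")
      return(data.frame(feature = f, test = NA_character_,
                        statistic = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    gg <- droplevels(g[ok])
    if (nlevels(gg) == 2L) {
      t <- stats::wilcox.test(x[ok] ~ gg, exact = FALSE)
      data.frame(feature = f, test = "wilcoxon",
                 statistic = unname(t$statistic), p_value = t$p.value,
                 stringsAsFactors = FALSE)
    } else {
      t <- stats::kruskal.test(x[ok], gg)
      data.frame(feature = f, test = "kruskal-wallis",
                 statistic = unname(t$statistic), p_value = t$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Kaplan-Meier curves and log-rank test for a binary feature
#'
#' @param time,event survival time and 0/1 event indicator.
#' @param feature binary grouping (factor/character/numeric with 2 levels).
#' @return list with \code{fit} (a \code{survfit} object), \code{chisq},
#'   \code{p} (two-sided log-rank p-value), and per-level \code{n} and
#'   \code{events}.
#' @export
kmLogrank <- function(time, event, feature) {
  f <- factor(feature)
  f <- droplevels(f)
  if (nlevels(f) != 2L) stop("feature must have exactly 2 observed levels")
  ev <- tapply(event, f, sum)
  if (any(ev < 1)) {
    stop("both feature levels need at least one event")
  }
  d <- data.frame(time = time, event = event, f = f)
  fit <- survival::survfit(survival::Surv(time, event) ~ f, data = d)
  sd <- survival::survdiff(survival::Surv(time, event) ~ f, data = d)
  p <- stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
  list(fit = fit, chisq = unname(sd$chisq), p = p,
       n = as.vector(table(f)), events = as.vector(ev))
}

#' Cox proportional hazards fit with a tabulated report
#'
#' Partial-likelihood fit with Efron tie handling. The report mirrors the
#' conventional regression table: unstandardised coefficient (B), its SE,
#' the Wald statistic, the hazard ratio with a 95 percent CI, and the
#' p-value. Coefficients with extreme magnitude or SE are flagged as likely
#' separation (monotone likelihood); such rows should not be interpreted.
#'
#' @param formula a \code{Surv(...) ~ covariates} formula.
#' @param data data.frame.
#' @return list: \code{table} (one row per coefficient), \code{n},
#'   \code{events}, \code{loglik}, \code{fit} (the coxph object),
#'   \code{separation} (logical vector per coefficient).
#' @examples
#' d <- data.frame(time = rexp(50), event = rbinom(50, 1, 0.8),
#'                 x = rbinom(50, 1, 0.5))
#' coxPH(survival::Surv(time, event) ~ x, d)$table
#' @export
coxPH <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)[, -1, drop = FALSE]
  const <- apply(X, 2, function(v) stats::var(v) == 0)
  if (any(const)) {
    stop("constant covariate(s): ", paste(colnames(X)[const],
                                          collapse = ", "))
  }
  fit <- survival::coxph(formula, data = data, ties = "efron")
  if (!is.null(fit$info) && grepl("did not converge", fit$info)) {
    stop("Cox fit did not converge: ", fit$info)
  }
  events <- fit$nevent
  k <- length(stats::coef(fit))
  if (events / k < 5) {
    warning("only ", events, " events for ", k,
            " covariates (events per covariate < 5); estimates may be ",
            "unstable")
  }
  s <- summary(fit)
  tab <- data.frame(
    term = rownames(s$coefficients),
    B = s$coefficients[, "coef"],
    SE = s$coefficients[, "se(coef)"],
    Wald = (s$coefficients[, "coef"] / s$coefficients[, "se(coef)"])^2,
    HR = s$coefficients[, "exp(coef)"],
    ci_lower = s$conf.int[, "lower .95"],
    ci_upper = s$conf.int[, "upper .95"],
    p_value = s$coefficients[, "Pr(>|z|)"],
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  sep <- abs(tab$B) > 10 | tab$SE > 10
  if (any(sep)) {
    warning("possible separation (monotone likelihood) for: ",
            paste(tab$term[sep], collapse = ", "))
  }
  list(table = tab, n = fit$n, events = events,
       loglik = fit$loglik[2], fit = fit, separation = sep)
}

#' Joint multivariable Cox report over spatial feature blocks
#'
#' One joint fit of the dichotomized spatial feature blocks (density class,
#' pattern, distance class per phenotype) together with clinical adjusters.
#' Perfectly collinear feature pairs are resolved by dropping the second
#' member with a warning naming both.
#'
#' @param data subject-level data.frame with outcome and feature columns.
#' @param time,event column names of the outcome.
#' @param spatialTerms,clinicalTerms character vectors of covariate columns.
#' @return as [coxPH()], plus \code{dropped} (collinear terms removed).
#' @export
multivariableReport <- function(data, time = "os_months",
                                event = "os_event",
                                spatialTerms = character(),
                                clinicalTerms = character()) {
  terms <- c(clinicalTerms, spatialTerms)
  if (length(terms) == 0L) stop("no covariates given")
  keep <- terms
  dropped <- character()
  # resolve exact collinearity on the numeric design
  num <- function(v) if (is.numeric(v)) v else as.numeric(factor(v))
  M <- vapply(terms, function(t) num(data[[t]]), numeric(nrow(data)))
  if (length(terms) > 1L) {
    cc <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
    for (i in seq_len(ncol(cc) - 1L)) {
      for (j in seq((i + 1L), ncol(cc))) {
        if (!is.na(cc[i, j]) && abs(cc[i, j]) > 0.999 &&
            terms[j] %in% keep && terms[i] %in% keep) {
          warning("collinear pair '", terms[i], "' / '", terms[j],
                  "': dropping '", terms[j], "'")
          keep <- setdiff(keep, terms[j])
          dropped <- c(dropped, terms[j])
        }
      }
    }
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(keep, collapse = " + ")))
  out <- coxPH(fml, data)
  out$dropped <- dropped
  out
}
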