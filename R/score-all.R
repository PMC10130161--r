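# Cohort-level scoring: cross-G mixing scores per core and phenotype,
# aggregated to subjects (median over triplicate cores) and summarised per
# phenotype, optionally by histology.

#' Cross-G mixing scores for every core and phenotype of a cohort
#'
#' For each tissue core, builds one shared observation window from all cells
#' of the core, takes the reference pattern (CK+ malignant cells by default)
#' and computes the cross-G mixing score against every requested phenotype.
#' Cores with fewer than \code{minRef}/\code{minTarget} cells contribute NA.
#'
#' @param cells cohort cell table with \code{subject_id}, \code{core_id},
#'   coordinates and either marker columns (use \code{rules}) or a
#'   \code{phenotype} column.
#' @param phenotypes character vector of target phenotype labels.
#' @param rules phenotype rules used to derive membership from markers; NULL
#'   to match on the \code{phenotype} column (simulated ground truth).
#' @param reference reference phenotype label (default CK+ malignant cells).
#' @param window window policy for [buildPointPattern()].
#' @param edgeCorrection,rMax,minRef,minTarget passed to [crossG()].
#' @return data.frame with one row per core and phenotype: subject_id,
#'   core_id, phenotype, n_ref, n_target, lambda, score, pattern, attraction.
#' @seealso [aggregateScoresBySubject()], [summarizeScores()]
#' @export
scoreAllPhenotypes <- function(cells, phenotypes, rules = NULL,
                               reference = MALIGNANT_PHENOTYPE,
                               window = "convex_hull",
                               edgeCorrection = "border", rMax = 200,
                               minRef = 5L, minTarget = 5L) {
  if (length(phenotypes) == 0L) {
    return(data.frame(subject_id = character(), core_id = character(),
                      phenotype = character(), n_ref = integer(),
                      n_target = integer(), lambda = numeric(),
                      score = numeric(), pattern = character(),
                      attraction = logical(), stringsAsFactors = FALSE))
  }
  member <- phenotypeMembership(cells, c(reference, phenotypes), rules)
  key <- paste(cells$subject_id, cells$core_id, sep = "\r")
  idxByCore <- split(seq_len(nrow(cells)), key)
  rows <- vector("list", length(idxByCore) * length(phenotypes))
  k <- 0L
  for (idx in idxByCore) {
    sub <- cells[idx, , drop = FALSE]
    if (nrow(sub) < 3L) next
    win <- hullOrSpec(sub, window)
    refPat <- makePattern(sub, member[idx, reference], reference, win)
    for (p in phenotypes) {
      tgtPat <- makePattern(sub, member[idx, p], p, win)
      res <- crossG(refPat, tgtPat, edgeCorrection = edgeCorrection,
                    rMax = rMax, minRef = minRef, minTarget = minTarget)
      k <- k + 1L
      rows[[k]] <- data.frame(
        subject_id = sub$subject_id[1], core_id = sub$core_id[1],
        phenotype = p, n_ref = res@nRef, n_target = res@nTarget,
        lambda = res@lambda, score = res@score, pattern = res@pattern,
        attraction = res@attraction, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

# membership matrix for the requested labels, from rules or ground truth
phenotypeMembership <- function(cells, labels, rules) {
  labels <- unique(labels)
  if (!is.null(rules)) {
    nm <- vapply(rules, `[[`, character(1), "name")
    use <- rules[match(labels, nm)]
    if (anyNA(match(labels, nm))) {
      stop("no rule for phenotype(s): ",
           paste(setdiff(labels, nm), collapse = ", "))
    }
    return(assignPhenotypes(cells, use))
  }
  if (!"phenotype" %in% names(cells)) {
    stop("cell table has no 'phenotype' column and no rules were given")
  }
  out <- vapply(labels, function(p) cells$phenotype == p,
                logical(nrow(cells)))
  colnames(out) <- labels
  out
}

hullOrSpec <- function(sub, window) {
  if (!is.character(window)) return(window)
  allXY <- cbind(sub$x_um, sub$y_um)
  if (window == "convex_hull") {
    polygonWindow(allXY[grDevices::chull(allXY), , drop = FALSE])
  } else {
    ctr <- colMeans(allXY)
    rad <- sqrt(max((allXY[, 1] - ctr[1])^2 + (allXY[, 2] - ctr[2])^2))
    circleWindow(ctr, 2 * rad)
  }
}

makePattern <- function(sub, member, label, win) {
  xy <- cbind(x = sub$x_um, y = sub$y_um)[as.logical(member), , drop = FALSE]
  new("PointPattern", coords = xy, window = win, phenotype = label,
      coreId = as.character(sub$core_id[1]))
}

#' Aggregate per-core scores to subjects
#'
#' Subject-level score is the median over the subject's cores (NA cores
#' excluded); the mixed/unmixed pattern is re-derived from the median score.
#'
#' @param coreScores output of [scoreAllPhenotypes()].
#' @return data.frame with one row per subject and phenotype.
#' @export
aggregateScoresBySubject <- function(coreScores) {
  if (nrow(coreScores) == 0L) {
    return(data.frame(subject_id = character(), phenotype = character(),
                      score = numeric(), pattern = character(),
                      attraction = logical(), n_cores = integer(),
                      stringsAsFactors = FALSE))
  }
  sp <- split(coreScores,
              list(coreScores$subject_id, coreScores$phenotype),
              drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    s <- stats::median(d$score, na.rm = TRUE)
    if (is.nan(s)) s <- NA_real_
    data.frame(subject_id = d$subject_id[1], phenotype = d$phenotype[1],
               score = s, pattern = classifyPattern(s),
               attraction = attractionFlag(s),
               n_cores = sum(!is.na(d$score)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Phenotype-level score summary, optionally by histology
#'
#' Cohort median mixing score and pattern per phenotype, overall and within
#' each histology subgroup when a clinical table with a \code{histology}
#' column is supplied.
#'
#' @param subjectScores output of [aggregateScoresBySubject()].
#' @param clinical optional clinical table with \code{subject_id} and
#'   \code{histology}.
#' @return data.frame with one row per phenotype (and per histology level
#'   when given): phenotype, group ("all" or histology level), n, median
#'   score, pattern of the median.
#' @export
summarizeScores <- function(subjectScores, clinical = NULL) {
  if (nrow(subjectScores) == 0L) {
    return(data.frame(phenotype = character(), group = character(),
                      n = integer(), median_score = numeric(),
                      pattern = character(), stringsAsFactors = FALSE))
  }
  one <- function(d, label) {
    s <- stats::median(d$score, na.rm = TRUE)
    if (is.nan(s)) s <- NA_real_
    data.frame(phenotype = d$phenotype[1], group = label,
               n = sum(!is.na(d$score)), median_score = s,
               pattern = classifyPattern(s), stringsAsFactors = FALSE)
  }
  pieces <- lapply(split(subjectScores, subjectScores$phenotype),
                   one, label = "all")
  if (!is.null(clinical) && "histology" %in% names(clinical)) {
    m <- merge(subjectScores, clinical[, c("subject_id", "histology")],
               by = "subject_id")
    for (h in unique(m$histology)) {
      sub <- m[m$histology == h, , drop = FALSE]
      pieces <- c(pieces, lapply(split(sub, sub$phenotype), one, label = h))
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$phenotype, out$group), , drop = FALSE]
}
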