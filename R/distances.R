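# Median nearest-neighbour distance metrics between phenotype pairs and
# cohort-median dichotomization into close/long classes. No edge correction
# is applied: these are medians of per-reference-point distances, not CDF
# estimates.

#' Median nearest-neighbour distance between two patterns
#'
#' Median of the per-reference-point distances to the nearest target point.
#' When reference and target are the same phenotype, self-distances are
#' excluded.
#'
#' @param reference,target [PointPattern-class] objects or coordinate
#'   matrices.
#' @return median distance in micrometres; NA (with a warning) when the
#'   target is empty.
#' @export
medianNNDistance <- function(reference, target) {
  refXY <- patternCoords(reference)
  tgtXY <- patternCoords(target)
  if (nrow(refXY) == 0L) {
    warning("empty reference pattern; median distance is NA")
    return(NA_real_)
  }
  if (nrow(tgtXY) == 0L) {
    warning("empty target pattern; median distance is NA")
    return(NA_real_)
  }
  same <- identical(refXY, tgtXY)
  if (same && nrow(refXY) < 2L) {
    warning("single self-referential point; median distance is NA")
    return(NA_real_)
  }
  stats::median(nearestNeighborDistances(refXY, tgtXY, self = same))
}

#' Default reference/target pair list for the distance panel
#'
#' 128 pairs: the malignant-cell reference (CK+) against each of the 26
#' distinct retained immune phenotypes, plus six special references (the
#' checkpoint-positive/negative malignant phenotypes CK+PD-L1+, CK+PD-L1neg,
#' CK+B7-H3+, CK+B7-H4+, CK+IDO-1+ and the regulatory T-cell phenotype
#' CD3+CD8negFOXP3+) each against the 17 lymphocyte phenotypes (the 16 CD3+
#' subsets and CD20+ B-cells).
#'
#' @return data.frame with columns \code{reference} and \code{target}.
#' @export
defaultDistancePairs <- function() {
  rules <- defaultPhenotypeRules()
  nm <- vapply(rules, `[[`, character(1), "name")
  taic <- nm[!startsWith(nm, "CK")]
  lymph <- c(taic[startsWith(taic, "CD3+")], "CD20+")
  special <- c("CK+PD-L1+", "CK+PD-L1neg", "CK+B7-H3+", "CK+B7-H4+",
               "CK+IDO-1+", "CD3+CD8negFOXP3+")
  out <- rbind(
    data.frame(reference = MALIGNANT_PHENOTYPE, target = taic,
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(special, function(ref) {
      data.frame(reference = ref, target = lymph, stringsAsFactors = FALSE)
    }))
  )
  rownames(out) <- NULL
  out
}

#' Per-subject median nearest-neighbour distances for phenotype pairs
#'
#' For each (reference, target) pair: per-core median NN distance, then the
#' median over the subject's cores. Pairs whose reference or target is
#' absent cohort-wide are dropped with a warning.
#'
#' @param cells cohort cell table (see [scoreAllPhenotypes()]).
#' @param pairs data.frame with columns \code{reference}, \code{target};
#'   defaults to [defaultDistancePairs()] when rules are supplied.
#' @param rules phenotype rules, or NULL to match the \code{phenotype}
#'   column.
#' @return data.frame: subject_id, reference, target, median_nn_um.
#' @seealso [dichotomizeAtCohortMedian()]
#' @export
distancePanel <- function(cells, pairs, rules = NULL) {
  labels <- unique(c(pairs$reference, pairs$target))
  member <- phenotypeMembership(cells, labels, rules)
  present <- colSums(member) > 0
  drop <- !(pairs$reference %in% labels[present]) |
    !(pairs$target %in% labels[present])
  if (any(drop)) {
    absent <- setdiff(unique(c(pairs$reference[drop], pairs$target[drop])),
                      labels[present])
    warning(sum(drop), " pair(s) dropped: phenotype absent cohort-wide (",
            paste(absent, collapse = ", "), ")")
    pairs <- pairs[!drop, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) {
    return(data.frame(subject_id = character(), reference = character(),
                      target = character(), median_nn_um = numeric(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(cells$subject_id, cells$core_id, sep = "\r")
  idxByCore <- split(seq_len(nrow(cells)), key)
  rows <- vector("list", length(idxByCore) * nrow(pairs))
  k <- 0L
  for (idx in idxByCore) {
    sub <- cells[idx, , drop = FALSE]
    xy <- cbind(sub$x_um, sub$y_um)
    mem <- member[idx, , drop = FALSE]
    for (j in seq_len(nrow(pairs))) {
      refXY <- xy[mem[, pairs$reference[j]], , drop = FALSE]
      tgtXY <- xy[mem[, pairs$target[j]], , drop = FALSE]
      d <- if (nrow(refXY) == 0L || nrow(tgtXY) == 0L ||
               (pairs$reference[j] == pairs$target[j] && nrow(refXY) < 2L)) {
        NA_real_
      } else if (pairs$reference[j] == pairs$target[j]) {
        stats::median(nearestNeighborDistances(refXY, tgtXY, self = TRUE))
      } else {
        stats::median(nearestNeighborDistances(refXY, tgtXY))
      }
      k <- k + 1L
      rows[[k]] <- data.frame(subject_id = sub$subject_id[1],
                              reference = pairs$reference[j],
                              target = pairs$target[j],
                              median_nn_um = d, stringsAsFactors = FALSE)
    }
  }
  percore <- do.call(rbind, rows[seq_len(k)])
  agg <- stats::aggregate(median_nn_um ~ subject_id + reference + target,
                          data = percore, FUN = stats::median,
                          na.action = stats::na.omit)
  # subjects with all-NA cores keep an NA row
  full <- unique(percore[, c("subject_id", "reference", "target")])
  out <- merge(full, agg, all.x = TRUE)
  out[order(out$reference, out$target, out$subject_id), , drop = FALSE]
}

#' Dichotomize values at the cohort median
#'
#' Values at or below the cohort median are "close" (or low, for densities);
#' values above are "long" (high). NA values are excluded from the median
#' and stay NA. Ties go to "close", so close counts are always at least
#' long counts, and the split depends only on ranks.
#'
#' @param values numeric vector (one value per subject).
#' @param labels two labels for (at-or-below, above); use
#'   \code{c("low", "high")} for densities.
#' @return character vector of classes.
#' @examples
#' dichotomizeAtCohortMedian(c(1, 2, 3, 4))  # close close long long
#' @export
dichotomizeAtCohortMedian <- function(values, labels = c("close", "long")) {
  stopifnot(length(labels) == 2)
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("need >= 2 non-NA values to dichotomize")
  med <- stats::median(values[ok])
  out <- rep(NA_character_, length(values))
  out[ok] <- ifelse(values[ok] <= med, labels[1], labels[2])
  out
}

#' Add distance classes to a distance panel
#'
#' Dichotomizes each (reference, target) pair's subject values at the cohort
#' median, optionally within histology subgroups (when a clinical table with
#' a \code{histology} column is supplied and \code{byHistology} is TRUE).
#'
#' @param panel output of [distancePanel()].
#' @param clinical optional clinical table.
#' @param byHistology compute the dichotomizing median within histology.
#' @return panel with a \code{distance_class} column.
#' @export
classifyDistances <- function(panel, clinical = NULL, byHistology = FALSE) {
  panel$distance_class <- NA_character_
  if (byHistology) {
    if (is.null(clinical) || !"histology" %in% names(clinical)) {
      stop("byHistology = TRUE needs a clinical table with 'histology'")
    }
    panel$histology <- clinical$histology[
      match(panel$subject_id, clinical$subject_id)]
    grp <- paste(panel$reference, panel$target, panel$histology, sep = "\r")
  } else {
    grp <- paste(panel$reference, panel$target, sep = "\r")
  }
  for (g in unique(grp)) {
    i <- grp == g
    if (sum(!is.na(panel$median_nn_um[i])) >= 2L) {
      panel$distance_class[i] <-
        dichotomizeAtCohortMedian(panel$median_nn_um[i])
    }
  }
  panel$histology <- NULL
  panel
}
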