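# The four-group cellular immunologic distribution taxonomy: crossing the
# mixed/unmixed distribution pattern with the close/long distance class.
#   group 1: mixed,   close    group 2: mixed,   long
#   group 3: unmixed, close    group 4: unmixed, long

#' Map pattern and distance class to a distribution group
#'
#' @param pattern "mixed" or "unmixed" (vectorised; NA propagates).
#' @param distanceClass "close" or "long".
#' @return integer group 1-4 (NA when either input is NA).
#' @examples
#' assignGroup("mixed", "close")    # 1
#' assignGroup("unmixed", "long")   # 4
#' @export
assignGroup <- function(pattern, distanceClass) {
  ok <- !is.na(pattern) & !is.na(distanceClass)
  if (any(!pattern[ok] %in% c("mixed", "unmixed"))) {
    stop("pattern must be 'mixed' or 'unmixed'")
  }
  if (any(!distanceClass[ok] %in% c("close", "long"))) {
    stop("distanceClass must be 'close' or 'long'")
  }
  out <- rep(NA_integer_, length(pattern))
  out[ok] <- 1L + (pattern[ok] == "unmixed") * 2L +
    (distanceClass[ok] == "long") * 1L
  out
}

#' Group prevalence
#'
#' Proportion of subjects in each of the four groups, over non-NA
#' assignments.
#'
#' @param groups integer vector of group assignments (1-4, NA allowed).
#' @return named numeric 4-vector summing to 1.
#' @export
groupPrevalence <- function(groups) {
  ok <- !is.na(groups)
  if (!any(ok)) stop("no non-NA group assignments")
  tab <- tabulate(groups[ok], nbins = 4L)
  stats::setNames(tab / sum(tab), paste0("group", 1:4))
}

#' Per-subject group assignments for an anchor phenotype
#'
#' Combines the subject-level mixed/unmixed pattern of the anchor phenotype
#' (from [aggregateScoresBySubject()]) with the subject's close/long class
#' for the malignant-to-anchor distance (from [classifyDistances()]).
#'
#' @param subjectScores output of [aggregateScoresBySubject()].
#' @param classifiedPanel output of [classifyDistances()].
#' @param anchor anchor phenotype (default CD3+, the predominant T-cell
#'   population).
#' @param reference distance reference phenotype (malignant cells).
#' @return data.frame: subject_id, phenotype, pattern, distance_class, group.
#' @export
groupAssignments <- function(subjectScores, classifiedPanel,
                             anchor = "CD3+",
                             reference = MALIGNANT_PHENOTYPE) {
  sc <- subjectScores[subjectScores$phenotype == anchor, , drop = FALSE]
  di <- classifiedPanel[classifiedPanel$reference == reference &
                        classifiedPanel$target == anchor, , drop = FALSE]
  if (nrow(sc) == 0L) stop("no scores for anchor phenotype '", anchor, "'")
  if (nrow(di) == 0L) stop("no distances for pair ", reference,
                           " -> ", anchor)
  m <- merge(sc[, c("subject_id", "pattern")],
             di[, c("subject_id", "distance_class")], by = "subject_id")
  m$phenotype <- anchor
  m$group <- assignGroup(m$pattern, m$distance_class)
  m[, c("subject_id", "phenotype", "pattern", "distance_class", "group")]
}

#' Phenotype densities by distribution group
#'
#' Median density of each phenotype within each group, with a
#' Kruskal-Wallis test across groups. Groups with fewer than two subjects
#' keep their median but the test is skipped with a warning.
#'
#' @param densities data.frame with \code{subject_id}, \code{phenotype},
#'   \code{density} (per-subject densities; aggregate cores first).
#' @param assignments output of [groupAssignments()].
#' @return data.frame: phenotype, median density per group (columns
#'   group1..group4), kw_statistic, p_value.
#' @export
densitiesByGroup <- function(densities, assignments) {
  grp <- assignments$group[match(densities$subject_id,
                                 assignments$subject_id)]
  densities$group <- grp
  densities <- densities[!is.na(densities$group), , drop = FALSE]
  if (nrow(densities) == 0L) stop("no subjects with group assignments")
  out <- lapply(split(densities, densities$phenotype), function(d) {
    med <- vapply(1:4, function(g) {
      v <- d$density[d$group == g]
      if (length(v)) stats::median(v, na.rm = TRUE) else NA_real_
    }, numeric(1))
    sizes <- tabulate(d$group, 4L)
    usable <- sum(sizes >= 2L)
    if (usable >= 2L && stats::var(d$density, na.rm = TRUE) > 0) {
      kw <- stats::kruskal.test(d$density, factor(d$group, levels = 1:4))
      stat <- unname(kw$statistic); p <- kw$p.value
    } else {
      warning("Kruskal-Wallis skipped for phenotype '", d$phenotype[1],
              "': fewer than two groups with >= 2 subjects or constant ",
              "densities")
      stat <- NA_real_; p <- NA_real_
    }
    data.frame(phenotype = d$phenotype[1], group1 = med[1], group2 = med[2],
               group3 = med[3], group4 = med[4], kw_statistic = stat,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-subject phenotype densities
#'
#' Density of each phenotype in each core (count over the core's window
#' area), aggregated per subject by median.
#'
#' @param cells cohort cell table.
#' @param phenotypes phenotype labels.
#' @param rules phenotype rules or NULL (ground-truth matching).
#' @param window window policy for the core area.
#' @return data.frame: subject_id, phenotype, density.
#' @export
subjectDensities <- function(cells, phenotypes, rules = NULL,
                             window = "convex_hull") {
  member <- phenotypeMembership(cells, phenotypes, rules)
  key <- paste(cells$subject_id, cells$core_id, sep = "\r")
  idxByCore <- split(seq_len(nrow(cells)), key)
  rows <- vector("list", length(idxByCore))
  k <- 0L
  for (idx in idxByCore) {
    sub <- cells[idx, , drop = FALSE]
    if (nrow(sub) < 3L) next
    a <- windowAreaMM2(hullOrSpec(sub, window))
    k <- k + 1L
    rows[[k]] <- data.frame(subject_id = sub$subject_id[1],
                            phenotype = phenotypes,
                            density = colSums(member[idx, phenotypes,
                                                     drop = FALSE]) / a,
                            stringsAsFactors = FALSE)
  }
  percore <- do.call(rbind, rows[seq_len(k)])
  agg <- stats::aggregate(density ~ subject_id + phenotype, data = percore,
                          FUN = stats::median)
  agg[order(agg$phenotype, agg$subject_id), , drop = FALSE]
}
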