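# Phenotype rules: marker co-expression definitions. A rule names the
# markers that must be positive and those that must be negative; a cell may
# match several rules (CD3+CD8+ cells also match CD3+). Malignant cells are
# those matching the "CK+" rule.

MALIGNANT_PHENOTYPE <- "CK+"

#' Define a phenotype rule
#'
#' @param name phenotype label, e.g. "CD3+CD8+" or "CD3+CD8negFOXP3+".
#' @param positive character vector of markers required positive.
#' @param negative character vector of markers required negative.
#' @param panel integer panel identifier (1-5 in the default five-panel
#'   design); 0 denotes a panel-agnostic rule.
#' @return a list of class "PhenotypeRule".
#' @export
phenotypeRule <- function(name, positive, negative = character(), panel = 0L) {
  stopifnot(is.character(name), length(name) == 1, length(positive) >= 1)
  if (length(intersect(positive, negative))) {
    stop("rule '", name, "': a marker cannot be required both positive ",
         "and negative")
  }
  structure(list(name = name, panel = as.integer(panel),
                 positive = as.character(positive),
                 negative = as.character(negative)),
            class = "PhenotypeRule")
}

#' Read phenotype rules from a YAML or JSON file
#'
#' The file holds a list of entries with fields \code{name}, \code{panel},
#' \code{positive} and (optionally) \code{negative}. An optional top-level
#' \code{panels} map of panel id to marker set enables marker validation at
#' load time: a rule referencing a marker absent from its panel is an error.
#'
#' @param path path to the rules file (.yaml/.yml or .json).
#' @return list of phenotype rules.
#' @export
readPhenotypeRules <- function(path) {
  if (!file.exists(path)) stop("rules file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  panels <- raw$panels
  entries <- if (!is.null(raw$rules)) raw$rules else raw
  rules <- lapply(entries, function(e) {
    phenotypeRule(e$name, unlist(e$positive),
                  if (is.null(e$negative)) character() else unlist(e$negative),
                  if (is.null(e$panel)) 0L else e$panel)
  })
  nm <- vapply(rules, `[[`, character(1), "name")
  pn <- vapply(rules, `[[`, integer(1), "panel")
  if (anyDuplicated(paste(nm, pn))) {
    stop("duplicate rule name within a panel")
  }
  if (!is.null(panels)) {
    for (r in rules) {
      pset <- unlist(panels[[as.character(r$panel)]])
      if (is.null(pset)) next
      bad <- setdiff(c(r$positive, r$negative), pset)
      if (length(bad)) {
        stop("rule '", r$name, "' references marker(s) absent from panel ",
             r$panel, ": ", paste(bad, collapse = ", "))
      }
    }
  }
  rules
}

#' Default phenotype rules shipped with the package
#'
#' The 26 distinct tumor-associated immune cell phenotypes retained in the
#' five-panel design, plus the malignant-cell rule (CK+), checkpoint-positive
#' malignant phenotypes and the regulatory T-cell reference used by the
#' distance panel.
#'
#' @return list of phenotype rules.
#' @export
defaultPhenotypeRules <- function() {
  readPhenotypeRules(system.file("extdata", "phenotype_rules.yaml",
                                 package = "spatialTME", mustWork = TRUE))
}

#' Assign phenotypes to cells by marker co-expression
#'
#' A cell matches a rule iff all required-positive markers are TRUE and all
#' required-negative markers are FALSE. Matching is not exclusive: a
#' CD3+CD8+ cell matches both "CD3+" and "CD3+CD8+".
#'
#' @param cells data.frame with one logical (or 0/1) column per marker.
#' @param rules list of rules from [phenotypeRule()]/[readPhenotypeRules()].
#' @return logical matrix, one row per cell and one column per rule (named
#'   by phenotype); attach with \code{cbind(cells, matches)}.
#' @examples
#' cells <- data.frame(CD3 = c(TRUE, TRUE), CD8 = c(TRUE, FALSE),
#'                     FOXP3 = c(FALSE, TRUE))
#' rules <- list(phenotypeRule("CD3+", "CD3"),
#'               phenotypeRule("CD3+CD8negFOXP3+", c("CD3", "FOXP3"), "CD8"))
#' assignPhenotypes(cells, rules)
#' @export
assignPhenotypes <- function(cells, rules) {
  markers <- unique(unlist(lapply(rules, function(r) c(r$positive, r$negative))))
  missing <- setdiff(markers, names(cells))
  if (length(missing)) {
    stop("marker column(s) absent from the cell table: ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(cells)
  out <- matrix(FALSE, nrow = n,
                ncol = length(rules),
                dimnames = list(NULL,
                                vapply(rules, `[[`, character(1), "name")))
  for (j in seq_along(rules)) {
    r <- rules[[j]]
    m <- rep(TRUE, n)
    for (mk in r$positive) m <- m & as.logical(cells[[mk]])
    for (mk in r$negative) m <- m & !as.logical(cells[[mk]])
    out[, j] <- m
  }
  out
}
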