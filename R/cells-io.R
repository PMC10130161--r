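# Cell-table I/O. The on-disk format is a delimited text file (TSV or CSV by
# extension) with one row per segmented cell: subject/core identifiers, x/y
# coordinates in micrometres, and one column per marker holding boolean
# positivity in any of the encodings 0/1, TRUE/FALSE or +/-.

#' Describe the column layout of a cell table
#'
#' @param subject,core,panel,x,y column names of the mandatory fields.
#' @param markers character vector of marker column names, or NULL to treat
#'   every remaining column with a boolean-like encoding as a marker.
#' @param scale multiplicative factor applied to coordinates on read (e.g.
#'   a pixel size in micrometres when coordinates are stored in pixels).
#' @return schema list for [readCellTable()].
#' @export
cellTableSchema <- function(subject = "subject_id", core = "core_id",
                            panel = "panel", x = "x_um", y = "y_um",
                            markers = NULL, scale = 1) {
  list(subject = subject, core = core, panel = panel, x = x, y = y,
       markers = markers, scale = scale)
}

truthyToLogical <- function(v) {
  if (is.logical(v)) return(v)
  if (is.numeric(v)) return(v != 0)
  s <- trimws(as.character(v))
  out <- rep(NA, length(s))
  out[s %in% c("1", "TRUE", "true", "T", "+", "pos", "yes")] <- TRUE
  out[s %in% c("0", "FALSE", "false", "F", "-", "neg", "no")] <- FALSE
  out
}

#' Read and validate a per-cell table
#'
#' Rows with non-finite coordinates are dropped with a warning naming their
#' line numbers. A missing mandatory column is an error; a column that is
#' neither mandatory nor boolean-encoded is ignored with a warning.
#'
#' @param path path to a .tsv/.txt (tab) or .csv file with a header row.
#' @param schema column layout from [cellTableSchema()].
#' @return data.frame with columns \code{subject_id}, \code{core_id},
#'   \code{panel}, \code{x_um}, \code{y_um}, one logical column per marker,
#'   and any passthrough columns (e.g. simulation ground truth).
#' @export
readCellTable <- function(path, schema = cellTableSchema()) {
  if (!file.exists(path)) stop("cell table not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (f in c("subject", "core", "x", "y")) {
    if (!schema[[f]] %in% names(raw)) {
      stop("mandatory column missing from ", path, ": ", schema[[f]])
    }
  }
  out <- data.frame(
    subject_id = as.character(raw[[schema$subject]]),
    core_id = as.character(raw[[schema$core]]),
    panel = if (schema$panel %in% names(raw)) {
      as.integer(raw[[schema$panel]])
    } else 0L,
    x_um = as.numeric(raw[[schema$x]]) * schema$scale,
    y_um = as.numeric(raw[[schema$y]]) * schema$scale,
    stringsAsFactors = FALSE
  )
  used <- c(schema$subject, schema$core, schema$panel, schema$x, schema$y)
  rest <- setdiff(names(raw), used)
  markerCols <- if (is.null(schema$markers)) rest else schema$markers
  for (cn in markerCols) {
    if (!cn %in% names(raw)) {
      if (!is.null(schema$markers)) {
        warning("declared marker column absent, ignored: ", cn)
      }
      next
    }
    v <- truthyToLogical(raw[[cn]])
    if (anyNA(v) && is.null(schema$markers)) {
      # not boolean-encoded: keep as passthrough column
      out[[cn]] <- raw[[cn]]
      next
    }
    if (anyNA(v)) {
      warning("marker column '", cn, "' has unrecognised values; ignored")
      next
    }
    out[[cn]] <- v
  }
  bad <- !is.finite(out$x_um) | !is.finite(out$y_um)
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-finite coordinates dropped (lines ",
            paste(which(bad) + 1L, collapse = ", "), ")")
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write a cell table
#'
#' When \code{rules} are supplied and the table has a \code{phenotype} column
#' but no marker columns (as produced by [simulateCore()]), marker columns
#' are derived first: a cell receives the positive markers of its phenotype's
#' rule and FALSE elsewhere.
#'
#' @param cells cell data.frame.
#' @param path output path (.tsv or .csv).
#' @param rules optional phenotype rules used to expand marker columns.
#' @return path, invisibly.
#' @export
writeCellTable <- function(cells, path, rules = NULL) {
  if (!is.null(rules) && "phenotype" %in% names(cells)) {
    cells <- expandMarkers(cells, rules)
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- cells
  for (cn in names(df)) if (is.logical(df[[cn]])) df[[cn]] <- as.integer(df[[cn]])
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Expand ground-truth phenotype labels into marker columns
#'
#' @param cells data.frame with a \code{phenotype} column.
#' @param rules phenotype rules; each cell's phenotype must name a rule.
#' @return cells with one logical column per marker appearing in the rules.
#' @export
expandMarkers <- function(cells, rules) {
  nm <- vapply(rules, `[[`, character(1), "name")
  markers <- unique(unlist(lapply(rules, function(r) c(r$positive, r$negative))))
  unknown <- setdiff(unique(cells$phenotype), nm)
  if (length(unknown)) {
    stop("no rule for phenotype(s): ", paste(unknown, collapse = ", "))
  }
  for (mk in markers) cells[[mk]] <- FALSE
  for (r in rules) {
    hit <- cells$phenotype == r$name
    if (!any(hit)) next
    for (mk in r$positive) cells[[mk]][hit] <- TRUE
  }
  cells
}

#' Read a clinical table
#'
#' Expected columns: \code{subject_id}, optional clinicopathologic covariates
#' (histology, smoker, tumor_size_cm, stage, kras, egfr) and the outcome
#' columns \code{os_months}, \code{os_event} (and \code{rfs_months},
#' \code{rfs_event} when recurrence-free survival is analysed).
#'
#' @param path path to a CSV/TSV file.
#' @return data.frame, one row per subject.
#' @export
readClinicalTable <- function(path) {
  if (!file.exists(path)) stop("clinical table not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  cl <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(cl)) {
    stop("mandatory column missing from ", path, ": subject_id")
  }
  cl$subject_id <- as.character(cl$subject_id)
  if (anyDuplicated(cl$subject_id)) {
    stop("duplicated subject_id in clinical table")
  }
  if ("os_months" %in% names(cl) && any(cl$os_months < 0, na.rm = TRUE)) {
    stop("negative survival times in clinical table")
  }
  cl
}
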