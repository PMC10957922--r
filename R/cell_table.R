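#' Cell phenotype vocabulary
#'
#' The closed 7-class phenotype vocabulary used throughout the package:
#' cancer cells, four lymphoid/myeloid immune classes, B cells, and
#' "negative" cells (cells scoring negative for every panel antibody,
#' i.e. stromal cells plus unpanelled immune cells).
#'
#' @return Character vector of the seven valid `cell_type` labels.
#' @export
cell_types <- function() {
  c("cancer", "cd8_t", "foxp3_t", "t_helper", "b_cell", "macrophage", "negative")
}

immune_cell_types <- function() {
  setdiff(cell_types(), c("cancer", "negative"))
}

#' Construct a validated cell table
#'
#' A cell table is the universal input of the package: one row per cell with
#' its sample of origin, planar nucleus-centroid coordinates in micrometers,
#' and phenotype. Focus membership and tumor/stroma compartment start
#' unassigned and are filled in by [split_foci()] and [assign_compartments()].
#'
#' Exact duplicate rows (same sample, coordinates and phenotype) are dropped
#' with a warning; near-duplicates are kept, since two distinct nuclei can
#' legitimately sit less than a micrometer apart.
#'
#' @param sample_id character vector of sample identifiers.
#' @param x,y numeric coordinates in micrometers (finite).
#' @param cell_type character vector drawn from [cell_types()].
#' @param focus_id optional integer focus labels (`NA` = unassigned).
#' @param compartment optional `"tumor"`/`"stroma"` labels (`NA` = unassigned).
#' @return A `data.frame` of class `cell_table` with columns
#'   `sample_id`, `x`, `y`, `cell_type`, `focus_id`, `compartment`.
#' @export
cell_table <- function(sample_id, x, y, cell_type, focus_id = NA_integer_,
                       compartment = NA_character_) {
  n <- length(sample_id)
  if (length(focus_id) == 1L) focus_id <- rep_len(focus_id, n)
  if (length(compartment) == 1L) compartment <- rep_len(compartment, n)
  df <- data.frame(
    sample_id = as.character(sample_id),
    x = as.numeric(x),
    y = as.numeric(y),
    cell_type = as.character(cell_type),
    focus_id = as.integer(focus_id),
    compartment = as.character(compartment),
    stringsAsFactors = FALSE
  )
  validate_cell_table(df)
}

#' Validate a cell table
#'
#' Checks coordinate finiteness and the phenotype vocabulary, and drops exact
#' duplicate `(sample_id, x, y, cell_type)` rows. Validation is idempotent.
#'
#' @param df a data.frame with the `cell_table` columns.
#' @return The validated `cell_table`.
#' @export
validate_cell_table <- function(df) {
  required <- c("sample_id", "x", "y", "cell_type")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("cell table is missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) {
    bad <- which(!is.finite(df$x) | !is.finite(df$y))
    stop("non-finite coordinate at row(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  }
  unknown <- setdiff(unique(df$cell_type), cell_types())
  if (length(unknown)) {
    stop("unknown cell_type label(s): ", paste(unknown, collapse = ", "),
         " (valid: ", paste(cell_types(), collapse = ", "), ")")
  }
  if (is.null(df$focus_id)) df$focus_id <- NA_integer_
  if (is.null(df$compartment)) df$compartment <- NA_character_
  comp_ok <- is.na(df$compartment) | df$compartment %in% c("tumor", "stroma")
  if (!all(comp_ok)) {
    stop("compartment must be 'tumor', 'stroma' or NA")
  }
  dup <- duplicated(df[, required])
  if (any(dup)) {
    warning(sum(dup), " exact duplicate cell row(s) dropped")
    df <- df[!dup, , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- unique(c("cell_table", class(df)))
  df
}

#' Read a cell table from CSV/TSV
#'
#' Reads a delimited per-cell export (one row per cell) and validates it.
#' Column names can be remapped so exports from common image-analysis
#' platforms load without editing; canonical names are
#' `sample_id`, `x`, `y`, `cell_type`.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"csv"`; default guessed from the file extension.
#' @param col_map named character vector mapping canonical names to the names
#'   used in the file, e.g. `c(x = "Cell X Position")`.
#' @return A validated [cell_table()].
#' @export
read_cell_table <- function(path, dialect = NULL, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dialect <- dialect %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  sep <- switch(match.arg(dialect, c("tsv", "csv")), tsv = "\t", csv = ",")
  raw <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "", quote = "\"")
  canonical <- c("sample_id", "x", "y", "cell_type")
  for (cn in names(col_map %||% character())) {
    if (!col_map[[cn]] %in% names(raw)) {
      stop("mapped column '", col_map[[cn]], "' not present in ", path)
    }
    names(raw)[names(raw) == col_map[[cn]]] <- cn
  }
  missing <- setdiff(canonical, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  for (cn in c("x", "y")) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(v) & !is.na(raw[[cn]]))
    if (length(bad)) {
      stop("non-numeric ", cn, " coordinate at data row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    raw[[cn]] <- v
  }
  cell_table(raw$sample_id, raw$x, raw$y, raw$cell_type,
             focus_id = if ("focus_id" %in% names(raw)) raw$focus_id else NA_integer_,
             compartment = if ("compartment" %in% names(raw)) raw$compartment else NA_character_)
}

#' Write a cell table to TSV
#'
#' @param ct a [cell_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(ct, path) {
  utils::write.table(as.data.frame(ct), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read cohort response labels
#'
#' Two-column CSV/TSV with `sample_id` and `response`
#' (`responder`/`non_responder`).
#'
#' @param path file path.
#' @param sample_ids optional character vector of known cohort samples; every
#'   labeled sample must be among them.
#' @return data.frame with columns `sample_id`, `response`.
#' @export
read_cohort_labels <- function(path, sample_ids = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  cohort_labels(df$sample_id, df$response, sample_ids = sample_ids)
}

#' Construct validated cohort labels
#'
#' @param sample_id character vector.
#' @param response character vector, `"responder"` or `"non_responder"`.
#' @param sample_ids optional vector of known cohort sample ids to check against.
#' @return data.frame of class `cohort_labels`.
#' @export
cohort_labels <- function(sample_id, response, sample_ids = NULL) {
  if (!all(response %in% c("responder", "non_responder"))) {
    stop("response labels must be 'responder' or 'non_responder'")
  }
  if (anyDuplicated(sample_id)) stop("duplicated sample_id in labels")
  if (!is.null(sample_ids)) {
    unknown <- setdiff(sample_id, sample_ids)
    if (length(unknown)) {
      stop("labeled sample(s) absent from cohort: ", paste(unknown, collapse = ", "))
    }
  }
  out <- data.frame(sample_id = as.character(sample_id),
                    response = as.character(response),
                    stringsAsFactors = FALSE)
  class(out) <- unique(c("cohort_labels", class(out)))
  out
}
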