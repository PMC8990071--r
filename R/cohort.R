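#' @useDynLib apoptosens, .registration = TRUE
#' @importFrom stats median quantile qnorm sd rnorm rlnorm rbeta runif
#'   lm coef predict complete.cases var cor dist rbinom
#' @importFrom utils read.table write.table head
"_PACKAGE"

# canonical marker names -------------------------------------------------

APOPTOSIS_MARKERS <- c("BAK", "BAX", "BCL2", "BCL(X)L", "MCL1",
                       "PRO-CASPASE 3", "PRO-CASPASE 9", "SMAC", "XIAP")
LINEAGE_MARKERS <- c("CD3", "CD4", "CD8", "CD45", "FOXP3", "PCK26", "AE1")

CELL_TYPES <- c("cancer", "helper_T", "cytotoxic_T", "regulatory_T",
                "other_immune", "stroma", "unassigned")

ID_COLUMNS <- c("cell_id", "patient_id", "slide_id", "core_id", "position_id")
COORD_COLUMNS <- c("x", "y")

#' Marker panel definition
#'
#' A marker panel lists the markers quantified per cell, their role
#' (apoptosis pathway protein, lineage marker, or other), and the pixel
#' dimensions of one imaging position; the image dimensions are needed by
#' [filter_margins()].
#'
#' The default panel carries the nine apoptosis proteins (BAK, BAX, BCL2,
#' BCL(X)L, MCL1, PRO-CASPASE 3, PRO-CASPASE 9, SMAC, XIAP) and seven
#' lineage markers (CD3, CD4, CD8, CD45, FOXP3, PCK26, AE1).
#'
#' @param markers character vector of marker names.
#' @param roles character vector (same length), each one of
#'   `"apoptosis"`, `"lineage"`, `"other"`.
#' @param image_width,image_height pixels per imaging position.
#' @return An object of class `marker_panel`: a data.frame with columns
#'   `name` and `role` and attributes `image_width`/`image_height`.
#' @export
marker_panel <- function(markers = c(APOPTOSIS_MARKERS, LINEAGE_MARKERS),
                         roles = c(rep("apoptosis", length(APOPTOSIS_MARKERS)),
                                   rep("lineage", length(LINEAGE_MARKERS))),
                         image_width = 2048, image_height = 2048) {
  stopifnot(length(markers) == length(roles),
            all(roles %in% c("apoptosis", "lineage", "other")),
            !anyDuplicated(markers),
            image_width > 0, image_height > 0)
  panel <- data.frame(name = as.character(markers), role = as.character(roles),
                      stringsAsFactors = FALSE)
  attr(panel, "image_width") <- image_width
  attr(panel, "image_height") <- image_height
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

#' Markers of a panel or cohort
#'
#' @param x a `marker_panel` or `cohort_table`.
#' @param role optionally restrict to one role (`"apoptosis"`, `"lineage"`).
#' @return character vector of marker names.
#' @export
panel_markers <- function(x, role = NULL) {
  panel <- if (inherits(x, "cohort_table")) attr(x, "panel") else x
  stopifnot(inherits(panel, "marker_panel"))
  if (is.null(role)) panel$name else panel$name[panel$role %in% role]
}

# cohort table -----------------------------------------------------------

#' Construct a cohort table of segmented single cells
#'
#' The central data container: one row per segmented cell, carrying cell,
#' position, core, slide and patient identifiers, per-position pixel
#' centroid coordinates, a segmentation QC score in \[0, 1\], one intensity
#' column per panel marker (mean intensity, arbitrary units, non-negative)
#' and a `cell_type` assignment. A free-text provenance log records every
#' operation applied.
#'
#' @param records data.frame with columns `cell_id`, `patient_id`,
#'   `slide_id`, `core_id`, `position_id`, `x`, `y`, `qc_score`, one column
#'   per panel marker, and optionally `cell_type` (default `"unassigned"`).
#' @param panel a [marker_panel()].
#' @param provenance character vector of log lines.
#' @param .allow_negative_markers internal: skip the non-negativity check
#'   on marker columns (standardized batch-corrected values may be
#'   negative).
#' @return An object of class `cohort_table` (a validated data.frame with
#'   `panel` and `provenance` attributes).
#' @export
cohort_table <- function(records, panel = marker_panel(),
                         provenance = character(),
                         .allow_negative_markers = FALSE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- c(ID_COLUMNS, COORD_COLUMNS, "qc_score")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0)
    stop("cohort table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  missing_mk <- setdiff(panel$name, names(records))
  if (length(missing_mk) > 0)
    stop("cohort table is missing intensity column(s): ",
         paste(missing_mk, collapse = ", "), call. = FALSE)
  if (!"cell_type" %in% names(records))
    records$cell_type <- rep("unassigned", nrow(records))

  for (col in ID_COLUMNS) records[[col]] <- as.character(records[[col]])
  if (nrow(records) > 0) {
    if (anyDuplicated(records$cell_id))
      stop("cell_id values must be unique within a cohort", call. = FALSE)
    if (any(!is.finite(records$x)) || any(!is.finite(records$y)) ||
        any(records$x < 0) || any(records$y < 0))
      stop("coordinates must be finite and non-negative", call. = FALSE)
    if (any(!is.finite(records$qc_score)) ||
        any(records$qc_score < 0 | records$qc_score > 1))
      stop("qc_score must lie in [0, 1]", call. = FALSE)
    for (mk in panel$name) {
      v <- records[[mk]]
      if (!is.numeric(v) || any(!is.finite(v)) ||
          (!.allow_negative_markers && any(v < 0)))
        stop("intensities for marker '", mk,
             "' must be finite and non-negative", call. = FALSE)
    }
    if (any(!records$cell_type %in% CELL_TYPES))
      stop("cell_type must be one of: ", paste(CELL_TYPES, collapse = ", "),
           call. = FALSE)
  }
  canonical <- c(ID_COLUMNS, COORD_COLUMNS, "qc_score", "cell_type",
                 panel$name)
  extra <- setdiff(names(records), canonical)
  records <- records[, c(canonical, extra), drop = FALSE]
  rownames(records) <- NULL
  attr(records, "panel") <- panel
  attr(records, "provenance") <- provenance
  class(records) <- c("cohort_table", "data.frame")
  records
}

#' @export
print.cohort_table <- function(x, ...) {
  panel <- attr(x, "panel")
  cat("cohort_table: ", nrow(x), " cells, ",
      length(unique(x$core_id)), " cores, ",
      length(unique(x$slide_id)), " slides, ",
      length(unique(x$patient_id)), " patients; ",
      nrow(panel), " markers\n", sep = "")
  typed <- x$cell_type != "unassigned"
  if (any(typed)) {
    tab <- table(x$cell_type[typed])
    cat("cell types:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

add_provenance <- function(table, line) {
  attr(table, "provenance") <- c(attr(table, "provenance"),
                                 sprintf("[%s] %s", format(Sys.time()), line))
  table
}

#' Provenance log of a cohort table
#' @param table a `cohort_table`.
#' @return character vector of log lines.
#' @export
provenance <- function(table) attr(table, "provenance")

# keep class & attributes when subsetting rows through the constructor-free
# path used internally
subset_cohort <- function(table, idx) {
  out <- as.data.frame(table)[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "panel") <- attr(table, "panel")
  attr(out, "provenance") <- attr(table, "provenance")
  class(out) <- c("cohort_table", "data.frame")
  out
}
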