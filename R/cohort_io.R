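# Readers/writers for delimited single-cell tables, and the record-level
# filters applied before any analysis.

guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a segmented single-cell cohort from a delimited file
#'
#' Reads one header row plus one row per cell. Column names may differ from
#' the canonical schema; `format_spec` maps canonical names (ids,
#' coordinates, `qc_score`, marker names) to the file's column names.
#' Rows with non-numeric coordinates, QC scores or intensities are rejected
#' with a warning and counted in the provenance log; a missing mandatory
#' column is a hard error naming that column.
#'
#' @param path file to read.
#' @param panel a [marker_panel()]; defaults to the 16-marker panel.
#' @param format_spec named list/character mapping canonical column name ->
#'   file column name (or a YAML/JSON file path containing such a map).
#'   Unmapped canonical names are looked up verbatim.
#' @param sep field separator; guessed from the extension by default.
#' @return a [cohort_table()].
#' @export
read_cohort <- function(path, panel = marker_panel(), format_spec = NULL,
                        sep = guess_sep(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(format_spec) && length(format_spec) == 1 &&
      file.exists(format_spec)) {
    format_spec <- if (grepl("\\.ya?ml$", format_spec)) {
      yaml::read_yaml(format_spec)
    } else {
      jsonlite::read_json(format_spec, simplifyVector = TRUE)
    }
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "",
                           quote = "\"")
  canonical <- c(ID_COLUMNS, COORD_COLUMNS, "qc_score", panel$name)
  file_name_of <- function(canon) {
    if (!is.null(format_spec) && canon %in% names(format_spec))
      format_spec[[canon]] else canon
  }
  for (canon in canonical) {
    fn <- file_name_of(canon)
    if (!fn %in% names(raw))
      stop("input file is missing mandatory column: ", canon,
           if (fn != canon) paste0(" (mapped to '", fn, "')"),
           call. = FALSE)
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in ID_COLUMNS) out[[canon]] <- raw[[file_name_of(canon)]]
  numeric_cols <- c(COORD_COLUMNS, "qc_score", panel$name)
  for (canon in numeric_cols)
    out[[canon]] <- suppressWarnings(as.numeric(raw[[file_name_of(canon)]]))
  ct_col <- file_name_of("cell_type")
  out$cell_type <- if (ct_col %in% names(raw)) raw[[ct_col]] else "unassigned"

  ok <- stats::complete.cases(out[, numeric_cols, drop = FALSE])
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    warning(n_rejected, " row(s) rejected (non-numeric coordinate, QC or ",
            "intensity value)", call. = FALSE)
    out <- out[ok, , drop = FALSE]
  }
  table <- cohort_table(out, panel = panel)
  add_provenance(table, sprintf(
    "read_cohort: %d cells read from '%s' (%d row(s) rejected)",
    nrow(table), path, n_rejected))
}

#' Write a cohort table to a delimited file
#'
#' Numeric fields are written at full double precision so that
#' `read_cohort(write_cohort(t))` reproduces `t` field-for-field. The
#' provenance log is written to a sidecar file `<path>.log`.
#'
#' @param table a [cohort_table()].
#' @param path output file; extension decides the separator (`.csv` comma,
#'   otherwise tab) unless `sep` is given.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, sep = guess_sep(path)) {
  stopifnot(inherits(table, "cohort_table"))
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  for (col in names(df)[num]) df[[col]] <- sprintf("%.15g", df[[col]])
  utils::write.table(df, path, sep = sep, quote = TRUE, row.names = FALSE,
                     col.names = TRUE)
  prov <- provenance(table)
  if (length(prov) > 0) writeLines(prov, paste0(path, ".log"))
  invisible(path)
}

#' Drop cells within the image margins
#'
#' Removes cells whose centroid falls inside a margin of `x_margin` pixels
#' on the x-axis or `y_margin` pixels on the y-axis of their imaging
#' position (both sides; defaults 15 px and 10 px). Coordinates are
#' 0-based per-position pixel centroids.
#'
#' @param table a [cohort_table()] whose panel carries the image size.
#' @param x_margin,y_margin margin widths in pixels.
#' @return the filtered `cohort_table`; the number of removed cells is
#'   logged in the provenance.
#' @export
filter_margins <- function(table, x_margin = 15, y_margin = 10) {
  stopifnot(inherits(table, "cohort_table"))
  panel <- attr(table, "panel")
  w <- attr(panel, "image_width")
  h <- attr(panel, "image_height")
  if (x_margin >= w / 2 || y_margin >= h / 2)
    stop("margins of ", x_margin, "/", y_margin,
         " px would drop the whole ", w, "x", h, " position", call. = FALSE)
  keep <- table$x >= x_margin & table$x <= w - x_margin &
          table$y >= y_margin & table$y <= h - y_margin
  out <- subset_cohort(table, keep)
  add_provenance(out, sprintf(
    "filter_margins: dropped %d of %d cells (x_margin=%g, y_margin=%g)",
    sum(!keep), nrow(table), x_margin, y_margin))
}

#' Gate a cell population on a minimum size
#'
#' Heterogeneity metrics are only computed on sufficiently large
#' populations. This returns its input unchanged when the population is at
#' least `min_n` cells and `NULL` (the "not computed" sentinel that
#' downstream summaries propagate) otherwise. The boundary is inclusive:
#' exactly `min_n` cells pass; set `inclusive = FALSE` for a strict
#' threshold.
#'
#' @param cells a `cohort_table`, data.frame or vector.
#' @param min_n minimum population size (default 100).
#' @param inclusive if `TRUE` (default) a population of exactly `min_n`
#'   passes.
#' @return `cells` or `NULL`.
#' @export
filter_population <- function(cells, min_n = 100, inclusive = TRUE) {
  stopifnot(min_n >= 1)
  n <- if (is.data.frame(cells)) nrow(cells) else length(cells)
  pass <- if (inclusive) n >= min_n else n > min_n
  if (pass) cells else NULL
}
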