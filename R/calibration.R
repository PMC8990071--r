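# Conversion of batch-corrected intensities (arbitrary units) to molar
# concentrations: MOMP proteins against cell-line standards, caspase
# pathway proteins by robust median/IQR alignment to a reference cohort.

# canonical short keys used by the ODE models
PROFILE_KEYS <- c(BAK = "BAK", BAX = "BAX", BCL2 = "BCL2",
                  "BCL(X)L" = "BCLXL", MCL1 = "MCL1",
                  "PRO-CASPASE 3" = "PC3", "PRO-CASPASE 9" = "PC9",
                  SMAC = "SMAC", XIAP = "XIAP")
MOMP_MARKERS <- c("BAK", "BAX", "BCL2", "BCL(X)L", "MCL1")
CASPASE_MARKERS <- c("PRO-CASPASE 3", "PRO-CASPASE 9", "SMAC", "XIAP")

#' Reference standards for molar calibration
#'
#' Holds (i) mean HeLa-cell intensities and the corresponding literature
#' molar concentrations used to calibrate the five MOMP proteins, (ii)
#' reference-cohort medians and IQRs (in micromolar) used to align the
#' four caspase-pathway proteins, and (iii) the fixed APAF1 input
#' concentration (0.123 uM by default, the apoptosome-limiting value).
#'
#' The shipped default table is a synthetic example on the intensity scale
#' of the bundled cohort generator, with concentrations in the
#' physiological 0.01-1 uM range; real analyses supply their own measured
#' standards.
#'
#' @param hela_mean_intensity named vector, mean HeLa intensity (a.u.)
#'   for BAK, BAX, BCL2, BCL(X)L, MCL1.
#' @param hela_concentration named vector, HeLa concentrations (uM) for
#'   the same five proteins.
#' @param cohort_reference data.frame with columns `marker`, `median_uM`,
#'   `iqr_uM` for PRO-CASPASE 3, PRO-CASPASE 9, SMAC, XIAP.
#' @param apaf1_concentration fixed APAF1 concentration in uM.
#' @return a `reference_standards` list.
#' @export
reference_standards <- function(
    hela_mean_intensity = c("BAK" = 400, "BAX" = 350, "BCL2" = 200,
                            "BCL(X)L" = 280, "MCL1" = 110),
    hela_concentration = c("BAK" = 0.15, "BAX" = 0.15, "BCL2" = 0.25,
                           "BCL(X)L" = 0.2, "MCL1" = 0.15),
    cohort_reference = data.frame(
      marker = CASPASE_MARKERS,
      median_uM = c(0.12, 0.02, 0.15, 0.25),
      iqr_uM = c(0.08, 0.015, 0.10, 0.25),
      stringsAsFactors = FALSE),
    apaf1_concentration = 0.123) {
  stopifnot(all(MOMP_MARKERS %in% names(hela_mean_intensity)),
            all(MOMP_MARKERS %in% names(hela_concentration)),
            all(hela_concentration > 0),
            all(CASPASE_MARKERS %in% cohort_reference$marker),
            all(cohort_reference$median_uM > 0),
            all(cohort_reference$iqr_uM > 0),
            apaf1_concentration > 0)
  if (any(hela_mean_intensity <= 0))
    stop("HeLa mean intensities must be positive", call. = FALSE)
  structure(list(hela_mean_intensity = hela_mean_intensity,
                 hela_concentration = hela_concentration,
                 cohort_reference = cohort_reference,
                 apaf1_concentration = apaf1_concentration),
            class = "reference_standards")
}

#' Calibrate the MOMP proteins against cell-line standards
#'
#' Converts corrected intensities of BAK, BAX, BCL2, BCL(X)L and MCL1 to
#' molar concentrations as
#' `conc = intensity / hela_mean_intensity * hela_concentration`,
#' per marker and cell.
#'
#' @param table a batch-corrected [cohort_table()] (or any data.frame with
#'   `cell_id` and the five marker columns).
#' @param standards a [reference_standards()].
#' @return data.frame: `cell_id` plus columns `BAK`, `BAX`, `BCL2`,
#'   `BCLXL`, `MCL1` in uM.
#' @export
calibrate_momp_proteins <- function(table, standards = reference_standards()) {
  stopifnot(inherits(standards, "reference_standards"))
  out <- data.frame(cell_id = table$cell_id, stringsAsFactors = FALSE)
  for (mk in MOMP_MARKERS) {
    ref_i <- standards$hela_mean_intensity[[mk]]
    if (ref_i <= 0)
      stop("HeLa mean intensity for '", mk, "' must be positive",
           call. = FALSE)
    out[[PROFILE_KEYS[[mk]]]] <-
      pmax(table[[mk]], 0) / ref_i * standards$hela_concentration[[mk]]
  }
  out
}

#' Calibrate the caspase-pathway proteins against a reference cohort
#'
#' Robustly aligns the cohort's intensity distribution of PRO-CASPASE 3,
#' PRO-CASPASE 9, SMAC and XIAP onto the reference-cohort concentration
#' scale: the linear map sending the cohort intensity (median, IQR) onto
#' the reference (median uM, IQR uM) is applied per marker; negative
#' mapped concentrations are floored at 0 and counted.
#'
#' @inheritParams calibrate_momp_proteins
#' @param alignment optionally a pre-fitted alignment from
#'   [fit_caspase_alignment()]; by default the alignment is fitted on
#'   `table` itself (cohort-global).
#' @return data.frame: `cell_id` plus columns `PC3`, `PC9`, `SMAC`,
#'   `XIAP` in uM, with attribute `"n_floored"`.
#' @export
calibrate_caspase_proteins <- function(table,
                                       standards = reference_standards(),
                                       alignment = NULL) {
  stopifnot(inherits(standards, "reference_standards"))
  if (is.null(alignment))
    alignment <- fit_caspase_alignment(table, standards)
  out <- data.frame(cell_id = table$cell_id, stringsAsFactors = FALSE)
  n_floored <- 0L
  for (mk in CASPASE_MARKERS) {
    al <- alignment[[mk]]
    conc <- al$median_uM + (table[[mk]] - al$center) * al$scale
    n_floored <- n_floored + sum(conc < 0)
    out[[PROFILE_KEYS[[mk]]]] <- pmax(conc, 0)
  }
  attr(out, "n_floored") <- n_floored
  out
}

#' Fit the intensity-to-micromolar alignment for the caspase proteins
#'
#' Per marker, computes the linear map that sends the cohort intensity
#' (median, IQR) onto the reference-cohort (median uM, IQR uM).
#'
#' @inheritParams calibrate_momp_proteins
#' @return named list per marker: `center` (cohort median intensity),
#'   `scale` (uM per intensity unit), `median_uM`.
#' @export
fit_caspase_alignment <- function(table,
                                  standards = reference_standards()) {
  ref <- standards$cohort_reference
  alignment <- list()
  for (mk in CASPASE_MARKERS) {
    x <- table[[mk]]
    m <- stats::median(x)
    iqr <- stats::quantile(x, 0.75, names = FALSE) -
      stats::quantile(x, 0.25, names = FALSE)
    if (iqr == 0)
      stop("marker '", mk, "': zero IQR in cohort intensities; ",
           "alignment is undefined", call. = FALSE)
    e <- ref[ref$marker == mk, ]
    alignment[[mk]] <- list(center = m, scale = e$iqr_uM / iqr,
                            median_uM = e$median_uM)
  }
  alignment
}

#' Full per-cell protein profiles for the apoptosis models
#'
#' Combines [calibrate_momp_proteins()], [calibrate_caspase_proteins()]
#' and the fixed APAF1 concentration into one profile table, the input of
#' [simulate_momp()] and [simulate_caspase()].
#'
#' @inheritParams calibrate_caspase_proteins
#' @return data.frame keyed by `cell_id` with columns `BAK`, `BAX`,
#'   `BCL2`, `BCLXL`, `MCL1`, `PC3`, `PC9`, `SMAC`, `XIAP`, `APAF1` (uM).
#' @export
protein_profiles <- function(table, standards = reference_standards(),
                             alignment = NULL) {
  momp <- calibrate_momp_proteins(table, standards)
  casp <- calibrate_caspase_proteins(table, standards, alignment)
  out <- merge(momp, casp, by = "cell_id", sort = FALSE)
  out$APAF1 <- standards$apaf1_concentration
  out
}

#' Aggregate a cohort to per-core protein profiles
#'
#' Aggregates the batch-corrected intensities across all cells of each
#' core (by median, by default) first, and converts the aggregated
#' intensities to molar concentrations afterwards
#' (aggregate-then-convert). The caspase-pathway alignment is fitted on
#' the distribution of the per-core aggregates.
#'
#' @inheritParams calibrate_caspase_proteins
#' @param cell_types optionally restrict aggregation to these cell types.
#' @param agg aggregation function (default `median`).
#' @return data.frame keyed by `core_id` (carried in column `cell_id` for
#'   interface uniformity, duplicated as `core_id`) with the profile
#'   columns in uM.
#' @export
aggregate_core_profile <- function(table, standards = reference_standards(),
                                   cell_types = NULL, agg = stats::median,
                                   alignment = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  if (!is.null(cell_types)) {
    table <- subset_cohort(table, table$cell_type %in% cell_types)
  }
  if (nrow(table) == 0) stop("no cells to aggregate", call. = FALSE)
  markers <- c(MOMP_MARKERS, CASPASE_MARKERS)
  cores <- sort(unique(table$core_id))
  agg_tab <- data.frame(cell_id = cores, core_id = cores,
                        stringsAsFactors = FALSE)
  for (mk in markers) {
    agg_tab[[mk]] <- vapply(cores, function(cid)
      agg(table[table$core_id == cid, mk]), numeric(1))
  }
  prof <- protein_profiles(agg_tab, standards, alignment)
  prof$core_id <- prof$cell_id
  prof
}
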