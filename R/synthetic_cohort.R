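# Seeded synthetic-cohort generator with ground truth: lognormal marker
# intensities per cell type, Dirichlet cell-type mixtures per core,
# multiplicative/additive slide batch distortions, and spatial layouts
# (clustered cancer nests, dispersed immune cells, plus analytic lattice
# test patterns).

#' Default lognormal marker model per cell type
#'
#' Mean log-intensities (arbitrary units) per (cell type, marker), with a
#' common log-sd. Lineage markers separate the six cell types (positive
#' markers around e^6.4, negative around e^3.4, i.e. several log-sds
#' apart); apoptosis markers encode the qualitative enrichment directions
#' of the modeled tissue: BCL2 high in immune cells, BAK/XIAP/SMAC and the
#' pro-caspases high in cancer cells, MCL1 lowest overall.
#'
#' @param sdlog common log-sd of intensities (default 0.35).
#' @return list with `meanlog` (type x marker matrix) and `sdlog`.
#' @export
default_marker_models <- function(sdlog = 0.35) {
  types <- setdiff(CELL_TYPES, "unassigned")
  markers <- c(APOPTOSIS_MARKERS, LINEAGE_MARKERS)
  m <- matrix(log(30), nrow = length(types), ncol = length(markers),
              dimnames = list(types, markers))
  set_mean <- function(type, marker, value) m[type, marker] <<- log(value)
  pos <- 600
  # lineage gates
  set_mean("cancer", "AE1", pos); set_mean("cancer", "PCK26", pos)
  for (t in c("helper_T", "cytotoxic_T", "regulatory_T"))
    set_mean(t, "CD3", pos)
  for (t in c("helper_T", "cytotoxic_T", "regulatory_T", "other_immune"))
    set_mean(t, "CD45", pos)
  set_mean("helper_T", "CD4", pos)
  set_mean("regulatory_T", "CD4", pos)
  set_mean("regulatory_T", "FOXP3", pos)
  set_mean("cytotoxic_T", "CD8", pos)
  # apoptosis proteins
  ap <- function(type, bak, bax, bcl2, bclxl, mcl1, pc3, pc9, smac, xiap) {
    m[type, APOPTOSIS_MARKERS] <<-
      log(c(bak, bax, bcl2, bclxl, mcl1, pc3, pc9, smac, xiap))
  }
  ap("cancer",       500, 400, 150, 300, 100, 400, 350, 500, 400)
  imm <- c(250, 300, 450, 250, 80, 250, 200, 250, 200)
  for (t in c("helper_T", "cytotoxic_T", "regulatory_T", "other_immune"))
    m[t, APOPTOSIS_MARKERS] <- log(imm)
  ap("stroma",       300, 300, 250, 250, 120, 300, 250, 300, 250)
  list(meanlog = m, sdlog = sdlog)
}

#' Synthetic-cohort generator configuration
#'
#' Defaults describe the tissue-microarray setting the pipeline targets:
#' per-core cell counts from a truncated Normal(6492, 1228); per-core
#' cell-type mixtures from a Dirichlet whose mean puts under 20% of cells
#' in the immune compartment; lognormal marker intensities per cell type
#' ([default_marker_models()]); mild per-slide affine batch distortions;
#' QC scores from a Beta skewed toward 1 (median approximately 0.95);
#' clustered spatial layout (cancer nests, dispersed immune cells).
#'
#' @param n_patients number of patients.
#' @param cores_per_patient cores per patient (1-3).
#' @param n_slides slides the cores are spread over.
#' @param cells_per_core list `(mean, sd, min)` of the truncated normal.
#' @param type_mixture named mean fractions over the six cell types
#'   (must sum to 1).
#' @param mixture_concentration Dirichlet concentration (larger = less
#'   core-to-core variation).
#' @param marker_models list as returned by [default_marker_models()].
#' @param batch_model list `(gain_sdlog, offset_sd)`: per slide x marker,
#'   gains are lognormal around 1 and offsets truncated-normal at 0; set
#'   both to 0 for a distortion-free cohort.
#' @param spatial_model list `(kind, n_nests, nest_radius)`; kind one of
#'   `"clustered"`, `"random"`.
#' @param qc_model list `(shape1, shape2)` of the QC Beta.
#' @param panel a [marker_panel()].
#' @param seed integer seed; a fixed seed reproduces the cohort exactly.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_patients = 8,
                             cores_per_patient = 2,
                             n_slides = 5,
                             cells_per_core = list(mean = 6492, sd = 1228,
                                                   min = 50),
                             type_mixture = c(cancer = 0.55,
                                              helper_T = 0.03,
                                              cytotoxic_T = 0.03,
                                              regulatory_T = 0.03,
                                              other_immune = 0.06,
                                              stroma = 0.30),
                             mixture_concentration = 50,
                             marker_models = default_marker_models(),
                             batch_model = list(gain_sdlog = 0.15,
                                                offset_sd = 5),
                             spatial_model = list(kind = "clustered",
                                                  n_nests = 4,
                                                  nest_radius = 250),
                             qc_model = list(shape1 = 14, shape2 = 1),
                             panel = marker_panel(),
                             seed = 1L) {
  stopifnot(n_patients >= 1, cores_per_patient >= 1, cores_per_patient <= 3,
            n_slides >= 1,
            cells_per_core$mean > 0, cells_per_core$sd >= 0,
            abs(sum(type_mixture) - 1) < 1e-8,
            all(names(type_mixture) %in% CELL_TYPES),
            marker_models$sdlog > 0,
            is.null(batch_model$gain_sdlog) || batch_model$gain_sdlog >= 0)
  structure(list(n_patients = n_patients,
                 cores_per_patient = cores_per_patient,
                 n_slides = n_slides, cells_per_core = cells_per_core,
                 type_mixture = type_mixture,
                 mixture_concentration = mixture_concentration,
                 marker_models = marker_models, batch_model = batch_model,
                 spatial_model = spatial_model, qc_model = qc_model,
                 panel = panel, seed = as.integer(seed)),
            class = "generator_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

rtruncnorm_count <- function(n, mean, sd, min) {
  out <- round(stats::rnorm(n, mean, sd))
  bad <- which(out < min)
  while (length(bad) > 0) {
    out[bad] <- round(stats::rnorm(length(bad), mean, sd))
    bad <- which(out < min)
  }
  out
}

# coordinates for one core: cancer in Gaussian nests, others dispersed
core_coordinates <- function(types, spatial, width, height, margin = 20) {
  n <- length(types)
  x <- stats::runif(n, margin, width - margin)
  y <- stats::runif(n, margin, height - margin)
  if (identical(spatial$kind, "clustered")) {
    idx <- which(types == "cancer")
    if (length(idx) > 0) {
      k <- max(1L, spatial$n_nests)
      cx <- stats::runif(k, width * 0.2, width * 0.8)
      cy <- stats::runif(k, height * 0.2, height * 0.8)
      nest <- sample.int(k, length(idx), replace = TRUE)
      x[idx] <- pmin(pmax(stats::rnorm(length(idx), cx[nest],
                                       spatial$nest_radius), margin),
                     width - margin)
      y[idx] <- pmin(pmax(stats::rnorm(length(idx), cy[nest],
                                       spatial$nest_radius), margin),
                     height - margin)
    }
  }
  cbind(x = x, y = y)
}

#' Generate a synthetic single-cell cohort with ground truth
#'
#' Draws a full cohort according to the configuration: per-core cell
#' counts, per-core Dirichlet cell-type mixtures, per-cell lognormal
#' marker intensities given the true type, spatial coordinates, Beta QC
#' scores, and per-slide affine batch distortions applied on top of the
#' true intensities. The returned ground truth carries the true cell type,
#' the pre-batch intensities and the slide batch factors, enabling
#' recovery tests of every downstream stage.
#'
#' @param config a [generator_config()].
#' @return list with elements `table` (a [cohort_table()], `cell_type`
#'   left `"unassigned"`) and `truth` (list: `cells` data.frame of
#'   `cell_id`, `true_type` and true intensities; `batch` data.frame of
#'   `slide_id`, `marker`, `gain`, `offset`; `mixtures` per-core true
#'   mixture fractions).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  panel <- config$panel
  markers <- panel$name
  width <- attr(panel, "image_width")
  height <- attr(panel, "image_height")
  types <- names(config$type_mixture)
  mm <- config$marker_models

  n_cores_total <- config$n_patients * config$cores_per_patient
  counts <- rtruncnorm_count(n_cores_total, config$cells_per_core$mean,
                             config$cells_per_core$sd,
                             config$cells_per_core$min)
  alpha <- config$type_mixture * config$mixture_concentration

  recs <- vector("list", n_cores_total)
  mixtures <- vector("list", n_cores_total)
  core_idx <- 0L
  for (p in seq_len(config$n_patients)) {
    patient_id <- sprintf("P%03d", p)
    slide_id <- sprintf("S%d", ((p - 1L) %% config$n_slides) + 1L)
    for (cc in seq_len(config$cores_per_patient)) {
      core_idx <- core_idx + 1L
      core_id <- sprintf("%s_C%d", patient_id, cc)
      n <- counts[core_idx]
      mix <- rdirichlet1(alpha)
      names(mix) <- types
      mixtures[[core_idx]] <- data.frame(core_id = core_id,
                                         t(mix), check.names = FALSE)
      true_type <- sample(types, n, replace = TRUE, prob = mix)
      xy <- core_coordinates(true_type, config$spatial_model, width, height)
      intens <- matrix(0, nrow = n, ncol = length(markers),
                       dimnames = list(NULL, markers))
      for (ty in unique(true_type)) {
        rows <- true_type == ty
        for (mk in markers)
          intens[rows, mk] <- stats::rlnorm(sum(rows),
                                            mm$meanlog[ty, mk], mm$sdlog)
      }
      df <- data.frame(cell_id = sprintf("%s_%06d", core_id, seq_len(n)),
                       patient_id = patient_id, slide_id = slide_id,
                       core_id = core_id, position_id = core_id,
                       x = xy[, "x"], y = xy[, "y"],
                       qc_score = stats::rbeta(n, config$qc_model$shape1,
                                               config$qc_model$shape2),
                       true_type = true_type,
                       stringsAsFactors = FALSE, check.names = FALSE)
      recs[[core_idx]] <- cbind(df, as.data.frame(intens,
                                                  check.names = FALSE))
    }
  }
  all <- do.call(rbind, recs)
  rownames(all) <- NULL

  truth_cells <- all[, c("cell_id", "true_type", markers)]
  records <- all[, setdiff(names(all), "true_type")]
  table <- cohort_table(records, panel = panel)
  table <- add_provenance(table, sprintf(
    "generate_cohort: %d cells, %d cores, %d patients, seed=%d",
    nrow(table), n_cores_total, config$n_patients, config$seed))

  bm <- config$batch_model
  table <- inject_batch_effects(table, bm)
  batch <- attr(table, "batch_factors")

  list(table = table,
       truth = list(cells = truth_cells, batch = batch,
                    mixtures = do.call(rbind, mixtures)))
}

#' Analytic spatial test patterns on a lattice
#'
#' Binary label fields with known spatial autocorrelation, used to test
#' Moran's I: `"checkerboard"` (perfect dispersion, I = -1 under rook
#' adjacency), `"split"` (left half one label, the clustered extreme) and
#' `"random"` (a seeded permutation of a balanced label vector).
#'
#' @param kind one of `"checkerboard"`, `"split"`, `"random"`.
#' @param n_side lattice side length (>= 2).
#' @param spacing_px lattice spacing in pixels.
#' @param seed seed for the `"random"` pattern.
#' @return list with `coords` (data.frame `x`, `y`) and integer `labels`
#'   in {0, 1}.
#' @export
generate_spatial_pattern <- function(kind, n_side, spacing_px = 1,
                                     seed = 1L) {
  stopifnot(n_side >= 2)
  grid <- expand.grid(i = seq_len(n_side) - 1L, j = seq_len(n_side) - 1L)
  labels <- switch(kind,
    checkerboard = (grid$i + grid$j) %% 2L,
    split = as.integer(grid$i < n_side / 2),
    random = {
      set.seed(seed)
      base <- rep(c(0L, 1L), length.out = nrow(grid))
      sample(base)
    },
    stop("unknown spatial pattern kind: ", kind, call. = FALSE))
  list(coords = data.frame(x = grid$i * spacing_px, y = grid$j * spacing_px),
       labels = as.integer(labels))
}

#' Inject per-slide affine batch distortions
#'
#' Applies `intensity' = gain(slide, marker) * intensity + offset(slide,
#' marker)`, clipped at 0. The batch model is either an explicit
#' data.frame of factors (`slide_id`, `marker`, `gain`, `offset`) or a
#' sampling recipe `list(gain_sdlog, offset_sd)` from which factors are
#' drawn (lognormal gains around 1; half-normal offsets).
#'
#' @param table a [cohort_table()].
#' @param batch_model factors data.frame or sampling recipe.
#' @param seed optional seed used when factors are sampled.
#' @return the distorted `cohort_table`, with the factors attached as
#'   attribute `"batch_factors"`.
#' @export
inject_batch_effects <- function(table, batch_model, seed = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  markers <- panel_markers(table)
  slides <- sort(unique(table$slide_id))
  if (is.data.frame(batch_model)) {
    factors <- batch_model
    stopifnot(all(c("slide_id", "marker", "gain", "offset") %in%
                    names(factors)))
  } else {
    if (!is.null(seed)) set.seed(seed)
    grid <- expand.grid(slide_id = slides, marker = markers,
                        stringsAsFactors = FALSE)
    gs <- batch_model$gain_sdlog %||% 0
    os <- batch_model$offset_sd %||% 0
    factors <- data.frame(grid,
                          gain = stats::rlnorm(nrow(grid), 0, gs),
                          offset = abs(stats::rnorm(nrow(grid), 0, os)))
  }
  if (any(factors$gain <= 0))
    stop("batch gains must be positive", call. = FALSE)
  if (any(!is.finite(factors$offset)))
    stop("batch offsets must be finite", call. = FALSE)
  out <- as.data.frame(table)
  for (r in seq_len(nrow(factors))) {
    rows <- out$slide_id == factors$slide_id[r]
    mk <- factors$marker[r]
    if (!mk %in% markers || !any(rows)) next
    out[rows, mk] <- pmax(factors$gain[r] * out[rows, mk] +
                            factors$offset[r], 0)
  }
  res <- cohort_table(out, panel = attr(table, "panel"),
                      provenance = provenance(table))
  res <- add_provenance(res, sprintf(
    "inject_batch_effects: %d slide x marker factors applied",
    nrow(factors)))
  attr(res, "batch_factors") <- factors
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
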