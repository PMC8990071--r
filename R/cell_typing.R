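# Rule-gate annotation of a training subset and random-forest
# classification of all cells into the six phenotypes.

#' Derive marker positivity thresholds
#'
#' Computes one positivity threshold per lineage marker on the corrected
#' intensities. The default method is an Otsu-style split of the
#' log-intensity histogram (maximum between-class variance), which suits
#' the bimodal positive/negative structure of lineage markers; a quantile
#' rule is available as an alternative.
#'
#' @param table a [cohort_table()].
#' @param markers markers to gate (default: the lineage markers).
#' @param method `"otsu"` (default) or `"quantile"`.
#' @param probs quantile used when `method = "quantile"`.
#' @param n_bins histogram bins for the Otsu split.
#' @return a `gate_config`: named vector of intensity thresholds.
#' @export
derive_gates <- function(table, markers = panel_markers(table, "lineage"),
                         method = c("otsu", "quantile"), probs = 0.8,
                         n_bins = 256) {
  method <- match.arg(method)
  thresholds <- vapply(markers, function(mk) {
    x <- table[[mk]]
    if (method == "quantile")
      return(stats::quantile(x, probs, names = FALSE))
    # exact zeros (e.g. floored after restoration) are negative by
    # definition and must not drive the bimodal split
    lx <- log1p(x[x > 0])
    otsu_threshold(lx, n_bins)
  }, numeric(1))
  names(thresholds) <- markers
  structure(thresholds, class = "gate_config")
}

# maximum between-class variance split on a numeric vector
otsu_threshold <- function(x, n_bins = 256) {
  rng <- range(x)
  if (diff(rng) == 0) return(expm1(rng[1]))
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu_t <- mu1[n_bins]
  between <- (mu_t * w1 - mu1)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  expm1(mids[which.max(between)])
}

gate_positive <- function(table, gates, marker) {
  table[[marker]] > unclass(gates)[[marker]]
}

#' Annotate a training subset by the gating hierarchy
#'
#' Applies the ordered gating hierarchy to a random subset of cells:
#' epithelial cells first (AE1 or pan-cytokeratin PCK26 positive become
#' `cancer`), then CD3-positive T cells (FOXP3 positive become
#' `regulatory_T`, else CD8 positive `cytotoxic_T`, else CD4 positive
#' `helper_T`, else `other_immune`), then CD3-negative cells positive for
#' CD4, CD45 or CD8 become `other_immune`, and cells below every lineage
#' gate become `stroma`. Cells satisfying both the epithelial and the CD3
#' gate are resolved by hierarchy order (epithelial first) and flagged.
#'
#' @param table a batch-corrected [cohort_table()].
#' @param gates a [derive_gates()] result (or named threshold vector).
#' @param sample_frac fraction of cells to annotate (default 0.006,
#'   roughly the manual-annotation workload the pipeline assumes).
#' @param seed seed for the subsampling.
#' @return the sampled `cohort_table` rows with columns `gate_label` and
#'   `gate_ambiguous`.
#' @export
annotate_by_gates <- function(table, gates, sample_frac = 0.006,
                              seed = 1L) {
  stopifnot(inherits(table, "cohort_table"),
            sample_frac > 0, sample_frac <= 1)
  set.seed(seed)
  n <- max(1L, round(nrow(table) * sample_frac))
  idx <- sort(sample.int(nrow(table), n))
  sub <- subset_cohort(table, idx)

  epithelial <- gate_positive(sub, gates, "AE1") |
    gate_positive(sub, gates, "PCK26")
  cd3 <- gate_positive(sub, gates, "CD3")
  cd4 <- gate_positive(sub, gates, "CD4")
  cd8 <- gate_positive(sub, gates, "CD8")
  cd45 <- gate_positive(sub, gates, "CD45")
  foxp3 <- gate_positive(sub, gates, "FOXP3")

  label <- rep("stroma", nrow(sub))
  label[!epithelial & !cd3 & (cd4 | cd45 | cd8)] <- "other_immune"
  label[!epithelial & cd3] <- "other_immune"
  label[!epithelial & cd3 & cd4] <- "helper_T"
  label[!epithelial & cd3 & cd8] <- "cytotoxic_T"
  label[!epithelial & cd3 & foxp3] <- "regulatory_T"
  label[epithelial] <- "cancer"

  sub$gate_label <- label
  sub$gate_ambiguous <- epithelial & cd3
  add_provenance(sub, sprintf(
    "annotate_by_gates: %d cells annotated (%d ambiguous double-positives)",
    nrow(sub), sum(sub$gate_ambiguous)))
}

#' Train the random-forest cell-type classifier
#'
#' Fits a random forest (default 2000 trees) on the lineage-marker
#' intensities of a gate-annotated training subset and reports the
#' out-of-bag per-class error (the false-negative rate per class).
#'
#' @param labeled output of [annotate_by_gates()] (needs `gate_label`).
#' @param features feature columns (default: the seven lineage markers).
#' @param n_trees number of trees (default 2000).
#' @param min_train minimum training cells required per class (default
#'   20).
#' @param seed seed for the forest construction.
#' @return a `cell_classifier`: list with the fitted forest, the feature
#'   list, class labels and the out-of-bag per-class error table.
#' @export
train_classifier <- function(labeled, features = LINEAGE_MARKERS,
                             n_trees = 2000, min_train = 20, seed = 1L) {
  stopifnot("gate_label" %in% names(labeled))
  missing_feat <- setdiff(features, names(labeled))
  if (length(missing_feat) > 0)
    stop("training data lacks feature column(s): ",
         paste(missing_feat, collapse = ", "), call. = FALSE)
  classes <- setdiff(CELL_TYPES, "unassigned")
  counts <- table(factor(labeled$gate_label, levels = classes))
  short <- names(counts)[counts < min_train]
  if (length(short) > 0)
    stop("class(es) with fewer than ", min_train, " training cells: ",
         paste(short, collapse = ", "), call. = FALSE)
  x <- as.data.frame(labeled)[, features, drop = FALSE]
  names(x) <- make.names(names(x))
  y <- factor(labeled$gate_label, levels = classes)
  set.seed(seed)
  forest <- randomForest::randomForest(x = x, y = y, ntree = n_trees)
  oob <- forest$confusion[, "class.error"]
  structure(list(forest = forest, features = features,
                 classes = classes, oob_class_error = oob,
                 n_trees = n_trees),
            class = "cell_classifier")
}

#' @export
print.cell_classifier <- function(x, ...) {
  cat("cell_classifier:", x$n_trees, "trees on",
      length(x$features), "lineage features\n")
  cat("out-of-bag per-class error:\n")
  print(round(x$oob_class_error, 4))
  invisible(x)
}

#' Classify all cells of a cohort
#'
#' Predicts the cell type of every cell with the trained forest and fills
#' the `cell_type` column.
#'
#' @param table a batch-corrected [cohort_table()].
#' @param model a `cell_classifier` from [train_classifier()].
#' @return the `cohort_table` with `cell_type` assigned for every cell.
#' @export
classify_cells <- function(table, model) {
  stopifnot(inherits(table, "cohort_table"),
            inherits(model, "cell_classifier"))
  missing_feat <- setdiff(model$features, names(table))
  if (length(missing_feat) > 0)
    stop("cohort lacks feature column(s): ",
         paste(missing_feat, collapse = ", "), call. = FALSE)
  x <- as.data.frame(table)[, model$features, drop = FALSE]
  names(x) <- make.names(names(x))
  pred <- predict(model$forest, newdata = x)
  out <- as.data.frame(table)
  out$cell_type <- as.character(pred)
  res <- cohort_table(out, attr(table, "panel"), provenance(table),
                      .allow_negative_markers = TRUE)
  add_provenance(res, sprintf(
    "classify_cells: %d cells classified (%s)", nrow(res),
    paste(names(table(pred)), table(pred), sep = "=", collapse = ", ")))
}

#' Per-core cell-type composition
#'
#' @param table a typed `cohort_table`.
#' @return data.frame: one row per core with the fraction of each cell
#'   type (rows sum to 1).
#' @export
core_composition <- function(table) {
  classes <- setdiff(CELL_TYPES, "unassigned")
  tab <- table(table$core_id, factor(table$cell_type, levels = classes))
  frac <- sweep(unclass(tab), 1, rowSums(tab), "/")
  data.frame(core_id = rownames(frac), frac, check.names = FALSE,
             row.names = NULL, stringsAsFactors = FALSE)
}
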