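# explicit gates at intensity 100 for hand-built cells
unit_gates <- function() {
  lineage <- c("CD3", "CD4", "CD8", "CD45", "FOXP3", "PCK26", "AE1")
  structure(setNames(rep(100, length(lineage)), lineage),
            class = "gate_config")
}

cell_with <- function(positive) {
  tab <- manual_table(1, intensity = 10)
  df <- as.data.frame(tab)
  for (mk in positive) df[[mk]] <- 500
  cohort_table(df, attr(tab, "panel"))
}

gate_label_of <- function(positive) {
  tab <- cell_with(positive)
  annotate_by_gates(tab, unit_gates(), sample_frac = 1)$gate_label
}

test_that("the gating hierarchy annotates canonical marker combinations", {
  expect_equal(gate_label_of("AE1"), "cancer")
  expect_equal(gate_label_of("PCK26"), "cancer")
  expect_equal(gate_label_of(c("CD3", "CD4")), "helper_T")
  expect_equal(gate_label_of(c("CD3", "CD8")), "cytotoxic_T")
  expect_equal(gate_label_of(c("CD3", "CD4", "FOXP3")), "regulatory_T")
  expect_equal(gate_label_of(c("CD45")), "other_immune")
  expect_equal(gate_label_of(c("CD4")), "other_immune")   # CD3-negative
  expect_equal(gate_label_of(character(0)), "stroma")
  # epithelial gate has precedence over CD3; the conflict is flagged
  tab <- cell_with(c("AE1", "CD3", "CD8"))
  ann <- annotate_by_gates(tab, unit_gates(), sample_frac = 1)
  expect_equal(ann$gate_label, "cancer")
  expect_true(ann$gate_ambiguous)
})

test_that("derived gates separate the synthetic positive and negative populations", {
  out <- small_cohort(seed = 17, mean_cells = 400,
                      batch_model = list(gain_sdlog = 0, offset_sd = 0))
  tab <- out$table
  gates <- derive_gates(tab)
  # generator: negatives around e^3.4 ~ 30, positives around e^6.4 ~ 600
  expect_true(all(unclass(gates) > 50 & unclass(gates) < 450))
  # gate annotation recovers ground truth almost everywhere
  ann <- annotate_by_gates(tab, gates, sample_frac = 1, seed = 1)
  truth <- out$truth$cells$true_type[match(ann$cell_id,
                                           out$truth$cells$cell_id)]
  expect_gt(mean(ann$gate_label == truth), 0.95)
})

test_that("the trained forest reports small out-of-bag errors on separable mixtures", {
  out <- small_cohort(seed = 19, mean_cells = 500)
  tab <- out$table
  gates <- derive_gates(tab)
  labeled <- annotate_by_gates(tab, gates, sample_frac = 0.5, seed = 5)
  model <- train_classifier(labeled, n_trees = 300, seed = 6)
  expect_true(all(model$oob_class_error < 0.10))
  expect_equal(model$features, panel_markers(tab, "lineage"))
})

test_that("training refuses a class with too few examples", {
  out <- small_cohort(seed = 23, mean_cells = 300)
  gates <- derive_gates(out$table)
  labeled <- annotate_by_gates(out$table, gates, sample_frac = 1, seed = 1)
  one_class <- subset_cohort(labeled, labeled$gate_label == "cancer")
  expect_error(train_classifier(one_class, n_trees = 50),
               "helper_T|fewer")
})

test_that("classification reproduces gate labels on separable data and is deterministic", {
  out <- small_cohort(seed = 29, mean_cells = 500)
  tab <- out$table
  gates <- derive_gates(tab)
  labeled <- annotate_by_gates(tab, gates, sample_frac = 0.4, seed = 2)
  model <- train_classifier(labeled, n_trees = 300, seed = 3)
  typed <- classify_cells(tab, model)
  # resubstitution on the training cells
  pred_on_train <- typed$cell_type[match(labeled$cell_id, typed$cell_id)]
  expect_gt(mean(pred_on_train == labeled$gate_label), 0.9)
  # determinism: same model, same input, same labels
  typed2 <- classify_cells(tab, model)
  expect_identical(typed$cell_type, typed2$cell_type)
  # missing feature is an error
  broken <- as.data.frame(tab)
  broken$CD3 <- NULL
  expect_error(classify_cells(
    cohort_table(broken, marker_panel(setdiff(attr(tab, "panel")$name,
                                              "CD3"),
                                      rep("other", 15))), model),
    "CD3")
})

test_that("confusion diagonal on ground truth is high for major classes", {
  out <- small_cohort(seed = 37, mean_cells = 600)
  tab <- out$table
  gates <- derive_gates(tab)
  labeled <- annotate_by_gates(tab, gates, sample_frac = 0.4, seed = 2)
  model <- train_classifier(labeled, n_trees = 300, seed = 3)
  typed <- classify_cells(tab, model)
  truth <- out$truth$cells$true_type[match(typed$cell_id,
                                           out$truth$cells$cell_id)]
  cm <- table(truth = truth, pred = typed$cell_type)
  recall <- diag(cm[, rownames(cm)]) / rowSums(cm)
  for (cls in c("cancer", "stroma", "other_immune"))
    expect_gt(recall[[cls]], 0.9)
  for (cls in c("helper_T", "cytotoxic_T", "regulatory_T"))
    expect_gt(recall[[cls]], 0.7)
})

test_that("an all-negative cell is classified as stroma", {
  out <- small_cohort(seed = 41, mean_cells = 400)
  tab <- out$table
  gates <- derive_gates(tab)
  labeled <- annotate_by_gates(tab, gates, sample_frac = 0.5, seed = 2)
  model <- train_classifier(labeled, n_trees = 300, seed = 3)
  zero <- manual_table(1, intensity = 0)
  typed <- classify_cells(zero, model)
  expect_equal(typed$cell_type, "stroma")
})

test_that("core compositions are proper fractions tracking the configured mixture", {
  mix <- c(cancer = 0.7, helper_T = 0.02, cytotoxic_T = 0.02,
           regulatory_T = 0.02, other_immune = 0.04, stroma = 0.20)
  out <- small_cohort(seed = 43, mean_cells = 400, type_mixture = mix)
  tab <- typed_cohort(out)
  comp <- core_composition(tab)
  expect_equal(rowSums(comp[, -1]), rep(1, nrow(comp)), tolerance = 1e-12)
  expect_gt(mean(comp$cancer), 0.5)
})
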