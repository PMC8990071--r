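# uses ground-truth-typed synthetic cohorts so the reference T-cell
# populations are known exactly

clean_typed <- function(seed = 31, n_slides = 2, mean_cells = 400,
                        n_patients = 4) {
  mix <- c(cancer = 0.40, helper_T = 0.10, cytotoxic_T = 0.05,
           regulatory_T = 0.10, other_immune = 0.05, stroma = 0.30)
  out <- small_cohort(seed = seed, n_patients = n_patients,
                      n_slides = n_slides, mean_cells = mean_cells,
                      type_mixture = mix,
                      batch_model = list(gain_sdlog = 0, offset_sd = 0))
  typed_cohort(out)
}

test_that("upper-quantile normalization equalizes group quantiles at the geometric mean", {
  tab <- clean_typed()
  # make slide S2 an exact 2x copy of itself
  distorted <- inject_batch_effects(tab, data.frame(slide_id = "S2",
                                                    marker = "BCL2",
                                                    gain = 2, offset = 0))
  normed <- upper_quantile_normalize(distorted)
  q_by_slide <- tapply(normed$BCL2, normed$slide_id, quantile, 0.75)
  expect_equal(unname(q_by_slide[1]), unname(q_by_slide[2]),
               tolerance = 1e-10)
  # the common value is the geometric mean of the group quantiles
  q_orig <- tapply(distorted$BCL2, distorted$slide_id, quantile, 0.75)
  expect_equal(unname(q_by_slide[1]), exp(mean(log(q_orig))),
               tolerance = 1e-10)
})

test_that("a single slide is only rescaled to its own quantile (factors 1)", {
  tab <- clean_typed(n_slides = 1, n_patients = 2)
  normed <- upper_quantile_normalize(tab)
  f <- attr(normed, "uq_factors")
  expect_true(all(abs(f$uq_factor - 1) < 1e-12))
})

test_that("an all-zero group is rejected by name", {
  tab <- clean_typed(n_patients = 2)
  df <- as.data.frame(tab)
  df$MCL1 <- 0
  zero <- cohort_table(df, attr(tab, "panel"))
  expect_error(upper_quantile_normalize(zero), "MCL1")
})

test_that("rankit regression recovers the reference mean and sd", {
  # reference values drawn from Normal(mu, sigma): a ~ mu, b ~ sigma
  set.seed(4)
  n <- 400
  mu <- 50
  sigma <- 8
  tab <- manual_table(n, x = runif(n, 200, 1800), y = runif(n, 200, 1800))
  df <- as.data.frame(tab)
  df$cell_type <- "helper_T"
  for (mk in panel_markers(tab)) df[[mk]] <- rnorm(n, mu, sigma)
  df[df < 0] <- 0
  tab <- cohort_table(df, attr(tab, "panel"))
  model <- fit_rankit_affine(tab)
  e <- model$affine[model$affine$marker == "BAK", ]
  # SE of the mean ~ sigma/sqrt(n); slope SE is of the same order
  expect_lt(abs(e$a - mu), 3 * sigma / sqrt(n))
  expect_lt(abs(e$b - sigma), 4 * sigma / sqrt(n))
})

test_that("identical slides get identical affine coefficients", {
  tab <- clean_typed(n_slides = 1, n_patients = 2)
  df <- as.data.frame(tab)
  df2 <- df
  df2$slide_id <- "S2"
  df2$cell_id <- paste0(df2$cell_id, "_b")
  both <- cohort_table(rbind(df, df2), attr(tab, "panel"))
  model <- fit_rankit_affine(both)
  aff <- model$affine
  a1 <- aff[aff$slide_id == "S1", c("a", "b")]
  a2 <- aff[aff$slide_id == "S2", c("a", "b")]
  expect_equal(a1$a, a2$a, tolerance = 1e-12)
  expect_equal(a1$b, a2$b, tolerance = 1e-12)
})

test_that("an injected affine distortion shows up in the fitted coefficients", {
  tab <- clean_typed(mean_cells = 600)
  g <- 1.8
  o <- 20
  distorted <- inject_batch_effects(tab, data.frame(slide_id = "S2",
                                                    marker = "BCL2",
                                                    gain = g, offset = o))
  # fit on the raw (not uq-normalized) scale to read the factors directly
  model <- fit_rankit_affine(distorted)
  aff <- model$affine[model$affine$marker == "BCL2", ]
  b1 <- aff$b[aff$slide_id == "S1"]
  b2 <- aff$b[aff$slide_id == "S2"]
  a1 <- aff$a[aff$slide_id == "S1"]
  a2 <- aff$a[aff$slide_id == "S2"]
  expect_equal(b2 / b1, g, tolerance = 0.15)
  expect_equal(a2 - g * a1, o, tolerance = o * 0.5)
})

test_that("applying the model aligns reference distributions across slides", {
  tab <- clean_typed(mean_cells = 600)
  distorted <- inject_batch_effects(tab, data.frame(
    slide_id = c("S2", "S2"), marker = c("BCL2", "BAK"),
    gain = c(2, 0.5), offset = c(30, 10)))
  normed <- upper_quantile_normalize(distorted)
  model <- fit_rankit_affine(normed)
  corrected <- apply_batch_model(normed, model)
  ref <- corrected$cell_type %in% c("regulatory_T", "helper_T")
  for (mk in c("BCL2", "BAK")) {
    ks <- suppressWarnings(ks.test(
      corrected[ref & corrected$slide_id == "S1", mk],
      corrected[ref & corrected$slide_id == "S2", mk]))
    expect_lt(unname(ks$statistic), 0.12)
  }
})

test_that("correction preserves within-slide rank order and the identity model is a no-op", {
  tab <- clean_typed(n_patients = 2)
  normed <- upper_quantile_normalize(tab)
  model <- fit_rankit_affine(normed)
  corrected <- apply_batch_model(normed, model)
  for (s in unique(tab$slide_id)) {
    expect_equal(order(corrected$BAK[corrected$slide_id == s]),
                 order(normed$BAK[normed$slide_id == s]))
  }
  ident <- model
  ident$affine$a <- 0
  ident$affine$b <- 1
  same <- apply_batch_model(normed, ident)
  expect_equal(same$BAK, normed$BAK, tolerance = 1e-12)
})

test_that("a missing model entry is an error", {
  tab <- clean_typed(n_patients = 2)
  normed <- upper_quantile_normalize(tab)
  model <- fit_rankit_affine(normed)
  model$affine <- model$affine[model$affine$marker != "BAK", ]
  expect_error(apply_batch_model(normed, model), "no entry")
})

test_that("restoration is the exact identity path without batch structure", {
  # one slide: the pooled regression of x_uq on z is an exact line, so
  # restoration reproduces the normalized intensities to machine precision
  tab <- clean_typed(n_slides = 1, n_patients = 2)
  normed <- upper_quantile_normalize(tab)
  model <- fit_rankit_affine(normed)
  corrected <- apply_batch_model(normed, model)
  restored <- restore_intensity_scale(corrected, model)
  for (mk in panel_markers(tab))
    expect_equal(restored[[mk]], normed[[mk]], tolerance = 1e-6)
  # two undistorted slides: the coefficients differ only by reference
  # sampling noise, so restoration stays very close to the identity
  tab2 <- clean_typed(n_patients = 4)
  n2 <- upper_quantile_normalize(tab2)
  m2 <- fit_rankit_affine(n2)
  r2 <- restore_intensity_scale(apply_batch_model(n2, m2), m2)
  for (mk in c("BAK", "BCL2"))
    expect_gt(cor(r2[[mk]], n2[[mk]]), 0.98)
})

test_that("injected slide gains are recovered and per-slide medians agree after restoration", {
  # near-fixed mixture so slide composition differences do not masquerade
  # as batch structure
  mix <- c(cancer = 0.40, helper_T = 0.10, cytotoxic_T = 0.05,
           regulatory_T = 0.10, other_immune = 0.05, stroma = 0.30)
  out <- small_cohort(seed = 31, n_patients = 6, n_slides = 3,
                      mean_cells = 700, type_mixture = mix,
                      mixture_concentration = 1e5,
                      batch_model = list(gain_sdlog = 0, offset_sd = 0))
  tab <- typed_cohort(out)
  gains <- data.frame(slide_id = c("S1", "S2", "S3"), marker = "BCL2",
                      gain = c(0.5, 1, 2), offset = 0)
  distorted <- inject_batch_effects(tab, gains)
  normed <- upper_quantile_normalize(distorted)
  model <- fit_rankit_affine(normed)
  corrected <- apply_batch_model(normed, model)
  restored <- restore_intensity_scale(corrected, model)
  meds <- tapply(restored$BCL2, restored$slide_id, median)
  expect_lt(max(meds) / min(meds) - 1, 0.05)
  # end-to-end gain recovery: fitted slopes on the raw scale carry the
  # injected gains (median relative error < 10%)
  raw_model <- fit_rankit_affine(distorted)
  aff <- raw_model$affine[raw_model$affine$marker == "BCL2", ]
  b <- aff$b[match(gains$slide_id, aff$slide_id)]
  rel <- (b / b[2]) / gains$gain
  expect_lt(median(abs(rel - 1)), 0.10)
  # KS distance between slides in the reference population is reduced
  ref <- tab$cell_type %in% c("regulatory_T", "helper_T")
  ks_of <- function(t) suppressWarnings(unname(ks.test(
    t[ref & t$slide_id == "S1", "BCL2"],
    t[ref & t$slide_id == "S3", "BCL2"])$statistic))
  expect_lt(ks_of(as.data.frame(restored)),
            ks_of(as.data.frame(distorted)))
})

test_that("negative restored values are floored at zero and logged", {
  tab <- clean_typed(n_patients = 2)
  bc <- correct_batch_effects(tab)
  expect_true(all(bc$table$BAK >= 0))
  expect_true(any(grepl("floored", provenance(bc$table))))
  # raw intensities preserved alongside
  expect_true(all(paste0("raw_", panel_markers(tab)) %in%
                    names(bc$table)))
})
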