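# Two-step slide batch correction: upper-quantile normalization per
# (marker, slide), then an affine transform fitted by rankit regression in
# the reference T-cell populations, then restoration to the
# normalized-intensity scale by pooled linear regression.

#' Upper-quantile normalization grouped by marker and slide
#'
#' Scales each (slide, marker) group so that its upper quantile (default
#' the 75th percentile) equals the across-slide geometric mean of that
#' marker's group quantiles. This removes gross multiplicative slide
#' differences before the rankit-affine fit.
#'
#' @param table a [cohort_table()].
#' @param q quantile used (default 0.75).
#' @param min_nonzero minimum number of cells with nonzero intensity
#'   required per group.
#' @return the normalized `cohort_table`; the applied factors are attached
#'   as attribute `"uq_factors"` (data.frame `slide_id`, `marker`,
#'   `uq_factor`).
#' @export
upper_quantile_normalize <- function(table, q = 0.75, min_nonzero = 10) {
  stopifnot(inherits(table, "cohort_table"), q > 0, q < 1)
  markers <- panel_markers(table)
  slides <- sort(unique(table$slide_id))
  out <- as.data.frame(table)
  factors <- list()
  for (mk in markers) {
    qv <- vapply(slides, function(s) {
      x <- out[out$slide_id == s, mk]
      if (sum(x > 0) < min_nonzero)
        stop("slide ", s, ", marker '", mk, "': fewer than ", min_nonzero,
             " cells with nonzero intensity", call. = FALSE)
      stats::quantile(x, q, names = FALSE)
    }, numeric(1))
    if (any(qv <= 0))
      stop("upper quantile is zero for marker '", mk, "' on slide(s) ",
           paste(slides[qv <= 0], collapse = ", "), call. = FALSE)
    target <- exp(mean(log(qv)))
    for (i in seq_along(slides)) {
      rows <- out$slide_id == slides[i]
      out[rows, mk] <- out[rows, mk] * (target / qv[i])
    }
    factors[[mk]] <- data.frame(slide_id = slides, marker = mk,
                                uq_factor = target / qv,
                                stringsAsFactors = FALSE)
  }
  res <- cohort_table(out, panel = attr(table, "panel"),
                      provenance = provenance(table))
  res <- add_provenance(res, sprintf(
    "upper_quantile_normalize: q=%g over %d slide x marker groups",
    q, length(slides) * length(markers)))
  attr(res, "uq_factors") <- do.call(rbind, c(factors,
                                              make.row.names = FALSE))
  res
}

rankits <- function(n) stats::qnorm((seq_len(n) - 3 / 8) / (n + 1 / 4))

#' Fit the rankit-based affine batch model in reference T cells
#'
#' For each slide and marker, the ordered upper-quantile-normalized
#' intensities of the reference population (regulatory and helper T cells
#' by default) are regressed on their rankits, the expected standard
#' normal order statistics `qnorm((i - 3/8) / (n + 1/4))`. The fitted
#' intercept `a` and slope `b` define the affine correction
#' `z = (x - a) / b` that maps the reference distribution of every slide
#' onto a common standardized scale (the quantile-rankit line becomes the
#' main diagonal). Reference cells within `exclusion_margin_frac` of the
#' image margins are excluded from the fit.
#'
#' @param table an upper-quantile-normalized [cohort_table()] with cell
#'   types assigned (gate annotations suffice).
#' @param reference_types cell types forming the reference population.
#' @param exclusion_margin_frac fraction of the image dimension excluded
#'   at each margin when collecting reference cells (default 0.05).
#' @param min_ref minimum reference cells required per slide (default 50).
#' @return a `batch_model`: list with `q`-normalization factors (if
#'   present on `table`), the `affine` table (`slide_id`, `marker`, `a`,
#'   `b`) and reference metadata.
#' @export
fit_rankit_affine <- function(table,
                              reference_types = c("regulatory_T",
                                                  "helper_T"),
                              exclusion_margin_frac = 0.05,
                              min_ref = 50) {
  stopifnot(inherits(table, "cohort_table"))
  panel <- attr(table, "panel")
  w <- attr(panel, "image_width")
  h <- attr(panel, "image_height")
  ref <- table$cell_type %in% reference_types &
    table$x >= exclusion_margin_frac * w &
    table$x <= (1 - exclusion_margin_frac) * w &
    table$y >= exclusion_margin_frac * h &
    table$y <= (1 - exclusion_margin_frac) * h
  markers <- panel_markers(table)
  slides <- sort(unique(table$slide_id))
  rows <- list()
  for (s in slides) {
    idx <- ref & table$slide_id == s
    n <- sum(idx)
    if (n < min_ref)
      stop("slide ", s, ": only ", n, " reference cells (need >= ",
           min_ref, ")", call. = FALSE)
    r <- rankits(n)
    for (mk in markers) {
      qs <- sort(table[idx, mk])
      if (stats::sd(qs) == 0)
        stop("slide ", s, ", marker '", mk,
             "': zero spread in reference population", call. = FALSE)
      fit <- stats::lm.fit(cbind(1, r), qs)
      a <- fit$coefficients[1]
      b <- fit$coefficients[2]
      if (!is.finite(b) || b <= 0)
        stop("slide ", s, ", marker '", mk,
             "': non-positive rankit slope", call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(slide_id = s, marker = mk,
                                              a = a, b = b, n_ref = n,
                                              stringsAsFactors = FALSE)
    }
  }
  structure(list(q = 0.75,
                 uq_factors = attr(table, "uq_factors"),
                 affine = do.call(rbind, c(rows, make.row.names = FALSE)),
                 reference_types = reference_types,
                 exclusion_margin_frac = exclusion_margin_frac),
            class = "batch_model")
}

#' Apply a fitted affine batch model to all cells
#'
#' Transforms every cell's normalized intensity as `z = (x - a) / b` using
#' its slide's fitted coefficients, for every marker. With positive slopes
#' the rank order within each slide and marker is preserved.
#'
#' @param table an upper-quantile-normalized [cohort_table()].
#' @param model a `batch_model` from [fit_rankit_affine()] covering every
#'   (slide, marker) present in `table`.
#' @return the corrected `cohort_table` (marker columns hold `z`).
#' @export
apply_batch_model <- function(table, model) {
  stopifnot(inherits(table, "cohort_table"), inherits(model, "batch_model"))
  markers <- panel_markers(table)
  slides <- unique(table$slide_id)
  aff <- model$affine
  out <- as.data.frame(table)
  for (s in slides) {
    rows <- out$slide_id == s
    for (mk in markers) {
      e <- aff[aff$slide_id == s & aff$marker == mk, ]
      if (nrow(e) != 1)
        stop("batch model has no entry for slide ", s, ", marker '", mk,
             "'", call. = FALSE)
      out[rows, mk] <- (out[rows, mk] - e$a) / e$b
    }
  }
  res <- cohort_table(out, attr(table, "panel"), provenance(table),
                      .allow_negative_markers = TRUE)
  add_provenance(res, "apply_batch_model: affine correction applied")
}

#' Restore corrected values to the normalized-intensity scale
#'
#' Fits, per marker, one pooled linear regression of the
#' upper-quantile-normalized intensities (reconstructed from the affine
#' model) on the corrected values `z` across all slides, and maps
#' `restored = c0 + c1 * z`, floored at 0. After restoration all slides
#' share a common intensity scale.
#'
#' @param table the corrected `cohort_table` from [apply_batch_model()].
#' @param model the same `batch_model`.
#' @return the restored `cohort_table`, with the per-marker regression
#'   coefficients attached as attribute `"restore_coef"`.
#' @export
restore_intensity_scale <- function(table, model) {
  stopifnot(inherits(table, "cohort_table"), inherits(model, "batch_model"))
  markers <- panel_markers(table)
  aff <- model$affine
  out <- as.data.frame(table)
  coefs <- list()
  n_floored <- 0L
  for (mk in markers) {
    z <- out[[mk]]
    a <- aff$a[match(paste(out$slide_id, mk), paste(aff$slide_id,
                                                    aff$marker))]
    b <- aff$b[match(paste(out$slide_id, mk), paste(aff$slide_id,
                                                    aff$marker))]
    x_uq <- a + b * z
    if (stats::var(z) == 0)
      stop("marker '", mk, "': zero variance in corrected values; ",
           "restoration regression is degenerate", call. = FALSE)
    fit <- stats::lm.fit(cbind(1, z), x_uq)
    c0 <- fit$coefficients[1]
    c1 <- fit$coefficients[2]
    restored <- c0 + c1 * z
    n_floored <- n_floored + sum(restored < 0)
    out[[mk]] <- pmax(restored, 0)
    coefs[[mk]] <- data.frame(marker = mk, c0 = c0, c1 = c1,
                              stringsAsFactors = FALSE)
  }
  res <- cohort_table(out, panel = attr(table, "panel"),
                      provenance = provenance(table))
  res <- add_provenance(res, sprintf(
    "restore_intensity_scale: pooled per-marker regression; %d value(s) floored at 0",
    n_floored))
  attr(res, "restore_coef") <- do.call(rbind, c(coefs,
                                                make.row.names = FALSE))
  res
}

#' One-call slide batch correction
#'
#' Convenience wrapper chaining [upper_quantile_normalize()],
#' [fit_rankit_affine()], [apply_batch_model()] and
#' [restore_intensity_scale()]. The raw intensities are preserved in
#' `raw_<marker>` columns of the result.
#'
#' @inheritParams upper_quantile_normalize
#' @inheritParams fit_rankit_affine
#' @return list with `table` (corrected, restored cohort) and `model`
#'   (the fitted `batch_model`).
#' @export
correct_batch_effects <- function(table, q = 0.75,
                                  reference_types = c("regulatory_T",
                                                      "helper_T"),
                                  exclusion_margin_frac = 0.05,
                                  min_ref = 50) {
  raw <- as.data.frame(table)[, panel_markers(table), drop = FALSE]
  names(raw) <- paste0("raw_", names(raw))
  normed <- upper_quantile_normalize(table, q = q)
  model <- fit_rankit_affine(normed, reference_types = reference_types,
                             exclusion_margin_frac = exclusion_margin_frac,
                             min_ref = min_ref)
  corrected <- apply_batch_model(normed, model)
  restored <- restore_intensity_scale(corrected, model)
  out <- cbind(as.data.frame(restored), raw)
  res <- cohort_table(out, panel = attr(table, "panel"),
                      provenance = provenance(restored))
  list(table = res, model = model)
}
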