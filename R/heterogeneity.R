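# Inter-/intra-tumor heterogeneity statistics: quartile coefficient of
# dispersion, binary and binned Shannon entropy, distance-capped Moran's I
# with outlier handling, the seeded bootstrap of core-composition pairing,
# and the per-core summary table.

EPS_ENTROPY <- 1e-10

#' Quartile coefficient of dispersion
#'
#' `(Q3 - Q1) / (Q3 + Q1)` with linear-interpolation quartiles
#' (`quantile(type = 7)`), a scale-invariant measure of spread for
#' non-negative data.
#'
#' @param values numeric vector (>= 4 values).
#' @return the COD, a non-negative scalar for non-negative data.
#' @export
quartile_cod <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4)
    stop("quartile COD needs at least 4 values", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  if (q[1] + q[2] == 0)
    stop("Q1 + Q3 is zero; quartile COD is undefined", call. = FALSE)
  (q[2] - q[1]) / (q[2] + q[1])
}

#' Binary Shannon entropy
#'
#' Entropy of a two-class label vector in bits:
#' `H = -sum((p + eps) * log2(p + eps))` over the two class proportions,
#' with `eps = 1e-10` guarding `log 0`. A 50/50 split gives 1 bit; a
#' single-class population gives approximately 0 (homogeneous states).
#'
#' @param labels vector with at most two distinct values (e.g.
#'   `"low"`/`"high"`).
#' @return entropy in bits.
#' @export
shannon_entropy_binary <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) stop("empty label vector", call. = FALSE)
  lv <- unique(labels)
  if (length(lv) > 2)
    stop("binary entropy requires at most two classes", call. = FALSE)
  p1 <- mean(labels == lv[1])
  p <- c(p1, 1 - p1)
  -sum((p + EPS_ENTROPY) * log2(p + EPS_ENTROPY))
}

#' Binned Shannon entropy of a continuous variable
#'
#' Z-scores the values, bins them at a fixed width in SD units (default
#' 0.1), and returns `H = -sum(p_i * log(p_i + eps))` in nats over the
#' occupied-bin proportions, with `eps = 1e-10`.
#'
#' @param values numeric vector (>= 2 values, positive SD).
#' @param bin_width_sd bin width on the z-score scale (default 0.1).
#' @return entropy in nats.
#' @export
shannon_entropy_binned <- function(values, bin_width_sd = 0.1) {
  values <- values[!is.na(values)]
  if (length(values) < 2)
    stop("binned entropy needs at least 2 values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("zero SD; binned entropy is undefined", call. = FALSE)
  z <- (values - mean(values)) / s
  bins <- floor(z / bin_width_sd)
  p <- as.numeric(table(bins)) / length(bins)
  -sum(p * log(p + EPS_ENTROPY))
}

#' Binary rook-adjacency weights on a lattice
#'
#' Weight 1 between horizontally or vertically adjacent lattice sites
#' (centers one spacing apart), 0 otherwise; zero diagonal.
#'
#' @param coords data.frame/matrix with columns `x`, `y`.
#' @param spacing lattice spacing; by default the smallest positive
#'   pairwise distance.
#' @return symmetric binary weight matrix.
#' @export
rook_adjacency <- function(coords, spacing = NULL) {
  d <- as.matrix(stats::dist(coords[, c("x", "y")]))
  if (is.null(spacing)) spacing <- min(d[d > 0])
  w <- (abs(d - spacing) < 1e-9) * 1
  diag(w) <- 0
  w
}

#' Inverse-distance weights with a distance cap
#'
#' `w_ij = 1 / min(d_ij, cap)` with zero diagonal: pairwise distances
#' beyond the cap (default 2000 px) are treated as exactly the cap, so
#' very distant cells retain a small constant weight.
#'
#' @param coords data.frame/matrix with columns `x`, `y`.
#' @param distance_cap cap in pixels (default 2000).
#' @return symmetric non-negative weight matrix.
#' @export
inverse_distance_weights <- function(coords, distance_cap = 2000) {
  d <- as.matrix(stats::dist(coords[, c("x", "y")]))
  d <- pmin(d, distance_cap)
  w <- 1 / d
  diag(w) <- 0
  w[!is.finite(w)] <- 0  # coincident points contribute no self-likeness
  w
}

#' Moran's I spatial autocorrelation
#'
#' `I = (N / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) /
#' sum_i (x_i - xbar)^2` with symmetric non-negative weights. The default
#' scheme is inverse distance with distances capped at 2000 px; binary
#' rook adjacency is available for analytic lattice patterns (a
#' checkerboard then gives exactly -1, perfect dispersion; values near 1
#' indicate spatial clustering, near 0 randomness). Outliers in `values`
#' are removed by Tukey fences (1.5 x IQR) by default, and populations
#' below `min_n` cells return `NA` (the "not computed" sentinel).
#'
#' @param values numeric vector.
#' @param coords data.frame/matrix with columns `x`, `y` (one row per
#'   value); ignored when `weights` is supplied.
#' @param weights optional explicit symmetric weight matrix.
#' @param scheme `"inverse_distance_capped"` (default) or
#'   `"rook_adjacency"` when building weights from `coords`.
#' @param distance_cap distance cap in px (default 2000).
#' @param min_n minimum population after outlier removal (default 100).
#' @param outlier_rule `"tukey"` (default) or `"none"`.
#' @return Moran's I, or `NA` when fewer than `min_n` cells remain.
#' @export
morans_i <- function(values, coords = NULL, weights = NULL,
                     scheme = c("inverse_distance_capped",
                                "rook_adjacency"),
                     distance_cap = 2000, min_n = 100,
                     outlier_rule = c("tukey", "none")) {
  scheme <- match.arg(scheme)
  outlier_rule <- match.arg(outlier_rule)
  keep <- !is.na(values)
  if (outlier_rule == "tukey") {
    q <- stats::quantile(values[keep], c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    keep <- keep & values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr
  }
  x <- values[keep]
  n <- length(x)
  if (n < min_n) return(NA_real_)
  if (stats::var(x) == 0)
    stop("zero variance after outlier removal; Moran's I is undefined",
         call. = FALSE)
  if (is.null(weights)) {
    if (is.null(coords))
      stop("either coords or a weight matrix is required", call. = FALSE)
    coords <- as.data.frame(coords)[keep, , drop = FALSE]
    weights <- switch(scheme,
                      inverse_distance_capped =
                        inverse_distance_weights(coords, distance_cap),
                      rook_adjacency = rook_adjacency(coords))
  } else {
    weights <- weights[keep, keep, drop = FALSE]
  }
  z <- x - mean(x)
  W <- sum(weights)
  if (W <= 0) stop("total weight must be positive", call. = FALSE)
  (n / W) * sum(weights * tcrossprod(z)) / sum(z^2)
}

#' Bootstrap test of within-patient core-composition similarity
#'
#' Tests whether the cell-type compositions of cores from the same
#' patient are more similar than random core pairings. The observed
#' statistic is the mean within-patient pairwise distance between
#' core-composition vectors; the null distribution re-pairs the cores at
#' random (preserving the multiset of group sizes) `n_reps` times under a
#' fixed seed. The empirical p-value is the fraction of null statistics
#' at or below the observed one.
#'
#' @param compositions numeric matrix/data.frame, one row per core,
#'   columns the cell-type fractions (e.g. from [core_composition()]).
#' @param patient_ids vector assigning each core to a patient.
#' @param n_reps bootstrap repetitions (default 100000).
#' @param seed seed (default 42).
#' @param metric `"euclidean"` (default) or `"jensen_shannon"`.
#' @return list: `observed`, `null` (numeric vector), `p_value`.
#' @export
bootstrap_composition_pairing <- function(compositions, patient_ids,
                                          n_reps = 1e5, seed = 42,
                                          metric = c("euclidean",
                                                     "jensen_shannon")) {
  metric <- match.arg(metric)
  compositions <- as.matrix(compositions)
  stopifnot(nrow(compositions) == length(patient_ids))
  sizes <- table(patient_ids)
  multi <- names(sizes)[sizes >= 2]
  if (length(multi) < 2)
    stop("need at least two patients with two or more cores",
         call. = FALSE)
  keep <- patient_ids %in% multi
  compositions <- compositions[keep, , drop = FALSE]
  patient_ids <- patient_ids[keep]
  n <- nrow(compositions)

  D <- if (metric == "euclidean") {
    as.matrix(stats::dist(compositions))
  } else {
    js <- function(p, q) {
      m <- (p + q) / 2
      kl <- function(a, b) sum(ifelse(a > 0, a * log(a / b), 0))
      sqrt((kl(p, m) + kl(q, m)) / 2)
    }
    out <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      out[i, j] <- out[j, i] <- js(compositions[i, ], compositions[j, ])
    }
    out
  }

  groups <- split(seq_len(n), patient_ids)
  # within-group pair positions are fixed; only the core assignment varies
  pairs <- do.call(cbind, lapply(groups, utils::combn, m = 2))
  stat_for <- function(assign)
    mean(D[cbind(assign[pairs[1, ]], assign[pairs[2, ]])])
  observed <- stat_for(seq_len(n))
  set.seed(seed)
  null <- vapply(seq_len(n_reps), function(i) stat_for(sample.int(n)),
                 numeric(1))
  list(observed = observed, null = null,
       p_value = mean(null <= observed))
}

#' Per-core, per-stratum summary of model results and heterogeneity
#'
#' For every core and cell-type stratum: cell counts, low/high fractions
#' for both models, the four pathway-quadrant fractions, quartile COD per
#' apoptosis marker, binary entropies of the two model classes, binned
#' entropy per marker, and (optionally) Moran's I of the two model
#' readouts. Heterogeneity metrics are reported as `NA` for strata below
#' `min_n` cells; fractions are always reported.
#'
#' @param table a typed, batch-corrected [cohort_table()].
#' @param results data.frame keyed by `cell_id` with columns
#'   `max_pore_pct`, `momp_class`, `sc_pct`, `caspase_class` (e.g. from
#'   [simulate_apoptosis()]).
#' @param strata cell types to stratify over (default cancer, the pooled
#'   immune compartment, stroma).
#' @param min_n population threshold for heterogeneity metrics (default
#'   100).
#' @param morans compute Moran's I of the model readouts (default TRUE).
#' @param distance_cap Moran's I distance cap in px.
#' @return data.frame, one row per core x stratum.
#' @export
core_summary <- function(table, results,
                         strata = list(cancer = "cancer",
                                       immune = c("helper_T",
                                                  "cytotoxic_T",
                                                  "regulatory_T",
                                                  "other_immune"),
                                       stroma = "stroma"),
                         min_n = 100, morans = TRUE,
                         distance_cap = 2000) {
  stopifnot(inherits(table, "cohort_table"))
  df <- merge(as.data.frame(table), results, by = "cell_id", sort = FALSE)
  df$quadrant <- quadrant_classify(df$momp_class, df$caspase_class)
  markers <- panel_markers(table, "apoptosis")
  rows <- list()
  for (core in sort(unique(df$core_id))) {
    core_df <- df[df$core_id == core, ]
    for (sname in names(strata)) {
      sub <- core_df[core_df$cell_type %in% strata[[sname]], ]
      n <- nrow(sub)
      row <- list(core_id = core, patient_id = core_df$patient_id[1],
                  stratum = sname, n_cells = n)
      if (n > 0) {
        row$frac_momp_low <- mean(sub$momp_class == "low")
        row$frac_momp_high <- mean(sub$momp_class == "high")
        row$frac_caspase_low <- mean(sub$caspase_class == "low")
        row$frac_caspase_high <- mean(sub$caspase_class == "high")
        for (qd in c("both_high", "momp_only", "caspase_only", "both_low"))
          row[[paste0("frac_", qd)]] <- mean(sub$quadrant == qd)
      }
      if (!is.null(filter_population(sub, min_n = min_n))) {
        row$entropy_momp <- shannon_entropy_binary(sub$momp_class)
        row$entropy_caspase <- shannon_entropy_binary(sub$caspase_class)
        for (mk in markers) {
          key <- gsub("[^A-Za-z0-9]+", "", mk)
          row[[paste0("cod_", key)]] <-
            if (sum(sub[[mk]], na.rm = TRUE) > 0)
              quartile_cod(sub[[mk]]) else NA_real_
          row[[paste0("entropy_", key)]] <-
            if (stats::sd(sub[[mk]]) > 0)
              shannon_entropy_binned(sub[[mk]]) else NA_real_
        }
        if (morans) {
          coords <- sub[, c("x", "y")]
          row$morans_momp <- tryCatch(
            morans_i(sub$max_pore_pct, coords, distance_cap = distance_cap,
                     min_n = min_n),
            error = function(e) NA_real_)
          row$morans_caspase <- tryCatch(
            morans_i(sub$sc_pct, coords, distance_cap = distance_cap,
                     min_n = min_n),
            error = function(e) NA_real_)
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  all_names <- unique(unlist(lapply(rows, names)))
  out <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(all_names, names(r))] <- NA
    as.data.frame(r[all_names], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
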