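test_that("quartile COD matches direct quartile computation and is scale invariant", {
  # {1..5} with linear-interpolation quartiles: Q1=2, Q3=4 -> 1/3
  expect_equal(quartile_cod(1:5), 1 / 3)
  expect_equal(quartile_cod(rep(7, 10)), 0)
  set.seed(2)
  x <- rlnorm(500)
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  expect_equal(quartile_cod(x), (q[2] - q[1]) / (q[2] + q[1]))
  expect_equal(quartile_cod(3.7 * x), quartile_cod(x))
  expect_error(quartile_cod(c(1, 2, 3)), "at least 4")
  expect_error(quartile_cod(rep(0, 8)), "undefined")
})

test_that("binary entropy matches the closed form in bits", {
  expect_equal(shannon_entropy_binary(rep(c("a", "b"), 50)), 1,
               tolerance = 1e-8)
  expect_lt(shannon_entropy_binary(rep("a", 40)), 1e-7)
  # p = 0.25: -0.25*log2(0.25) - 0.75*log2(0.75) = 0.8112781...
  h <- shannon_entropy_binary(c(rep("low", 25), rep("high", 75)))
  expect_equal(h, -(0.25 * log2(0.25) + 0.75 * log2(0.75)),
               tolerance = 1e-8)
  expect_equal(round(h, 4), 0.8113)
  # permutation invariance
  set.seed(1)
  lab <- sample(c("x", "y"), 60, replace = TRUE)
  expect_equal(shannon_entropy_binary(lab),
               shannon_entropy_binary(sample(lab)))
  expect_error(shannon_entropy_binary(character(0)), "empty")
})

test_that("binned entropy matches an independent histogram oracle", {
  # uniform occupancy over k bins -> ln k
  k <- 8
  vals <- rep(seq_len(k), each = 25)   # equal mass per distinct value
  h <- shannon_entropy_binned(vals, bin_width_sd = 1 / sd(vals) *
                                (diff(range(vals)) / k) * 1.0001)
  # simpler analytic case: two equally occupied bins
  two <- c(rep(0, 50), rep(10, 50))
  expect_equal(shannon_entropy_binned(two, bin_width_sd = 0.5), log(2),
               tolerance = 1e-6)
  # large-sample standard normal vs independently computed histogram
  set.seed(9)
  x <- rnorm(1e5)
  h_pkg <- shannon_entropy_binned(x, 0.1)
  z <- (x - mean(x)) / sd(x)
  counts <- table(floor(z / 0.1))
  p <- as.numeric(counts) / length(z)
  h_oracle <- -sum(p * log(p + 1e-10))
  expect_equal(h_pkg, h_oracle, tolerance = 1e-6)
  expect_error(shannon_entropy_binned(rep(1, 10)), "zero SD")
})

test_that("Moran's I on the checkerboard with rook weights is exactly -1", {
  cb <- generate_spatial_pattern("checkerboard", 8)
  w <- rook_adjacency(cb$coords)
  i <- morans_i(cb$labels, weights = w, min_n = 1,
                outlier_rule = "none")
  expect_identical(round(i, 12), -1)
})

test_that("Moran's I equals the brute-force double loop and ape on irregular data", {
  set.seed(21)
  n <- 120
  coords <- data.frame(x = runif(n, 0, 1000), y = runif(n, 0, 1000))
  vals <- rnorm(n) + coords$x / 500
  w <- inverse_distance_weights(coords, distance_cap = 400)
  i_pkg <- morans_i(vals, coords, distance_cap = 400, min_n = 1,
                    outlier_rule = "none")
  i_bf <- morans_i_bruteforce(vals, w)
  expect_equal(i_pkg, i_bf, tolerance = 1e-10)
  # independent implementation cross-check (ape row-standardizes its
  # weights internally, so feed the standardized matrix to ours)
  skip_if_not_installed("ape")
  w_rs <- w / rowSums(w)
  i_rs <- morans_i(vals, weights = w_rs, min_n = 1, outlier_rule = "none")
  i_ape <- ape::Moran.I(vals, w)$observed
  expect_equal(i_rs, i_ape, tolerance = 1e-10)
})

test_that("Moran's I orders split > random > checkerboard on the same lattice", {
  sp <- generate_spatial_pattern("split", 8)
  rd <- generate_spatial_pattern("random", 8, seed = 5)
  cb <- generate_spatial_pattern("checkerboard", 8)
  w <- rook_adjacency(sp$coords)
  i_split <- morans_i(sp$labels, weights = w, min_n = 1,
                      outlier_rule = "none")
  i_rand <- morans_i(rd$labels, weights = w, min_n = 1,
                     outlier_rule = "none")
  i_cb <- morans_i(cb$labels, weights = w, min_n = 1,
                   outlier_rule = "none")
  expect_gt(i_split, i_rand)
  expect_gt(i_rand, i_cb)
  expect_gt(i_split, 0.5)
})

test_that("the permutation null of Moran's I is centered at -1/(N-1)", {
  cb <- generate_spatial_pattern("checkerboard", 6)
  w <- rook_adjacency(cb$coords)
  n <- length(cb$labels)
  set.seed(11)
  null <- replicate(3000, morans_i(sample(cb$labels), weights = w,
                                   min_n = 1, outlier_rule = "none"))
  # Monte-Carlo oracle: mean over permutations ~ -1/(N-1)
  expect_equal(mean(null), -1 / (n - 1), tolerance = 5 / sqrt(3000))
})

test_that("small populations return the sentinel and constants are an error", {
  coords <- data.frame(x = 1:50, y = 1:50)
  expect_true(is.na(morans_i(rnorm(50), coords, min_n = 100)))
  expect_error(morans_i(rep(1, 200), data.frame(x = 1:200, y = 1:200),
                        min_n = 10, outlier_rule = "none"),
               "zero variance")
})

test_that("the Tukey outlier rule removes isolated extremes before Moran's I", {
  set.seed(8)
  n <- 150
  coords <- data.frame(x = runif(n, 0, 500), y = runif(n, 0, 500))
  vals <- runif(n, -1, 1)   # bounded bulk: only the spike is an outlier
  vals[1] <- 100
  i_with <- morans_i(vals, coords, min_n = 1, outlier_rule = "tukey")
  i_clean <- morans_i(vals[-1], coords[-1, ], min_n = 1,
                      outlier_rule = "none")
  expect_equal(i_with, i_clean, tolerance = 1e-12)
})

test_that("bootstrap pairing flags patient-specific composition structure", {
  # strong patient effect: each patient's two cores share a signature
  set.seed(6)
  n_pat <- 8
  comp <- NULL
  pats <- character(0)
  for (p in seq_len(n_pat)) {
    centre <- c(runif(1, 0.2, 0.8))
    rows <- cbind(centre, 1 - centre)[c(1, 1), ] +
      matrix(rnorm(4, 0, 0.01), 2)
    comp <- rbind(comp, rows)
    pats <- c(pats, rep(sprintf("P%d", p), 2))
  }
  res <- bootstrap_composition_pairing(comp, pats, n_reps = 5000,
                                       seed = 42)
  expect_lt(res$p_value, 0.01)
  expect_equal(length(res$null), 5000)
  # determinism under the fixed seed
  res2 <- bootstrap_composition_pairing(comp, pats, n_reps = 5000,
                                        seed = 42)
  expect_identical(res$null, res2$null)
  # identical compositions: observed 0, p ~ 1
  flat <- matrix(0.5, nrow = 6, ncol = 2)
  res3 <- bootstrap_composition_pairing(flat, rep(c("A", "B", "C"),
                                                  each = 2),
                                        n_reps = 200, seed = 1)
  expect_equal(res3$observed, 0)
  expect_equal(res3$p_value, 1)
  expect_error(bootstrap_composition_pairing(flat[1:3, ],
                                             c("A", "B", "C"),
                                             n_reps = 10),
               "two or more cores")
})

test_that("core summaries stratify fractions that partition and respect the population gate", {
  out <- small_cohort(seed = 51, n_patients = 2, mean_cells = 300)
  tab <- typed_cohort(out)
  prof <- protein_profiles(tab)
  set.seed(1)
  # synthetic model results: construct a known 30% low-MOMP cancer core
  res <- data.frame(cell_id = tab$cell_id, stringsAsFactors = FALSE)
  is_cancer <- tab$cell_type == "cancer"
  res$max_pore_pct <- ifelse(runif(nrow(tab)) < 0.3, 5, 50)
  res$momp_class <- classify_momp_sensitivity(res$max_pore_pct)
  res$sc_pct <- runif(nrow(tab), 0, 100)
  res$caspase_class <- classify_caspase_activity(res$sc_pct)
  summ <- core_summary(tab, res, min_n = 100, morans = FALSE)
  expect_true(all(c("cancer", "immune", "stroma") %in% summ$stratum))
  filled <- !is.na(summ$frac_both_high)
  sums <- unname(rowSums(summ[filled, c("frac_both_high", "frac_momp_only",
                                        "frac_caspase_only",
                                        "frac_both_low")]))
  expect_equal(sums, rep(1, sum(filled)), tolerance = 1e-12)
  # the constructed 30% low fraction is recovered within binomial 3 SE
  big_cancer <- summ$stratum == "cancer" & summ$n_cells >= 100
  for (i in which(big_cancer)) {
    se <- sqrt(0.3 * 0.7 / summ$n_cells[i])
    expect_lt(abs(summ$frac_momp_low[i] - 0.3), 3 * se)
  }
  # heterogeneity metrics are sentinels below the population threshold
  small <- summ$n_cells < 100
  expect_true(all(is.na(summ$entropy_momp[small])))
})
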