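# Shared fixture builders: everything is generated in code at test time.

# a cohort table built by hand, cell by cell (no generator involved)
manual_table <- function(n = 5, panel = marker_panel(),
                         x = NULL, y = NULL, intensity = 100) {
  markers <- panel$name
  df <- data.frame(cell_id = sprintf("c%03d", seq_len(n)),
                   patient_id = rep("P1", n), slide_id = rep("S1", n),
                   core_id = rep("C1", n), position_id = rep("pos1", n),
                   x = if (is.null(x)) rep(1024, n) else x,
                   y = if (is.null(y)) rep(1024, n) else y,
                   qc_score = rep(0.9, n), stringsAsFactors = FALSE)
  for (mk in markers) df[[mk]] <- rep_len(intensity, n)
  cohort_table(df, panel = panel)
}

# small seeded synthetic cohort for stage tests
small_cohort <- function(seed = 7, n_patients = 4, cores_per_patient = 2,
                         n_slides = 2, mean_cells = 400, ...) {
  generate_cohort(generator_config(
    n_patients = n_patients, cores_per_patient = cores_per_patient,
    n_slides = n_slides,
    cells_per_core = list(mean = mean_cells, sd = mean_cells / 10,
                          min = 50),
    seed = seed, ...))
}

# cohort with ground-truth types written into cell_type
typed_cohort <- function(out) {
  tab <- out$table
  tab$cell_type <- out$truth$cells$true_type[
    match(tab$cell_id, out$truth$cells$cell_id)]
  tab
}

# profile helpers for the ODE models
momp_profile <- function(BAK = 0.15, BAX = 0.15, BCL2 = 0.1, BCLXL = 0.1,
                         MCL1 = 0.05) {
  list(BAK = BAK, BAX = BAX, BCL2 = BCL2, BCLXL = BCLXL, MCL1 = MCL1)
}

caspase_profile <- function(PC3 = 0.12, PC9 = 0.02, SMAC = 0.15,
                            XIAP = 0.1, APAF1 = 0.123) {
  list(PC3 = PC3, PC9 = PC9, SMAC = SMAC, XIAP = XIAP, APAF1 = APAF1)
}

random_profiles <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(cell_id = sprintf("p%04d", seq_len(n)),
             BAK = rlnorm(n, log(0.15), 0.4),
             BAX = rlnorm(n, log(0.15), 0.4),
             BCL2 = rlnorm(n, log(0.15), 0.4),
             BCLXL = rlnorm(n, log(0.12), 0.4),
             MCL1 = rlnorm(n, log(0.08), 0.4),
             PC3 = rlnorm(n, log(0.12), 0.4),
             PC9 = rlnorm(n, log(0.02), 0.4),
             SMAC = rlnorm(n, log(0.15), 0.4),
             XIAP = rlnorm(n, log(0.2), 0.4),
             APAF1 = 0.123, stringsAsFactors = FALSE)
}

# brute-force Moran's I oracle: explicit double loop over the definition
morans_i_bruteforce <- function(values, weights) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  W <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + weights[i, j] * z[i] * z[j]
    W <- W + weights[i, j]
  }
  (n / W) * num / sum(z^2)
}
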