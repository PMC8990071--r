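# Deterministic ODE model of executioner caspase activation downstream of
# MOMP: APAF1-limited apoptosome formation (cytochrome c saturating at
# t = 0), procaspase-9 recruitment, catalytic caspase-3 activation, XIAP
# inhibition of both caspases with XIAP-mediated caspase-3 degradation,
# SMAC relief of XIAP, and cleavage of a normalized substrate as readout.

#' Parameters of the caspase-activation model
#'
#' Kinetic constants and simulation controls. Defaults give switch-like
#' substrate cleavage over the physiological 0.01-1 uM input range and are
#' plain configuration entries; measured constants can be substituted
#' without code changes. The apoptosome-procaspase-9 dissociation constant
#' `kd_apop9` closes the reversible recruitment step. Units: uM, seconds.
#'
#' @param k_apop apoptosome formation rate from APAF1 (s^-1); cytochrome c
#'   is saturating at t = 0, so APAF1 alone limits formation.
#' @param k_bind9 apoptosome-procaspase-9 association (uM^-1 s^-1).
#' @param kd_apop9 apoptosome-caspase-9 dissociation constant (uM).
#' @param k_c9 catalytic PC3 -> C3 rate by apoptosome-bound caspase-9
#'   (uM^-1 s^-1).
#' @param k_on_x association rate of all XIAP bindings (uM^-1 s^-1).
#' @param kd_xiap_c3,kd_xiap_c9,kd_xiap_smac XIAP dissociation constants
#'   (uM) for caspase-3, apoptosome-bound caspase-9, and SMAC.
#' @param k_deg3 XIAP-mediated caspase-3 degradation rate (s^-1).
#' @param k_sub substrate cleavage rate by free caspase-3 (uM^-1 s^-1);
#'   the substrate pool is normalized to 1.
#' @param t_sc readout time in seconds (default 60 min).
#' @param sc_threshold_pct high/low cutoff on substrate cleavage %
#'   (default 25; high at or above).
#' @param rtol,atol solver tolerances.
#' @return a `caspase_parameters` list.
#' @export
caspase_parameters <- function(k_apop = 0.01, k_bind9 = 1,
                               kd_apop9 = 0.001, k_c9 = 0.1,
                               k_on_x = 1, kd_xiap_c3 = 0.002,
                               kd_xiap_c9 = 0.002, kd_xiap_smac = 0.001,
                               k_deg3 = 1e-3, k_sub = 1,
                               t_sc = 3600, sc_threshold_pct = 25,
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(k_apop > 0, k_bind9 > 0, kd_apop9 > 0, k_c9 > 0, k_on_x > 0,
            kd_xiap_c3 > 0, kd_xiap_c9 > 0, kd_xiap_smac > 0,
            k_deg3 >= 0, k_sub > 0, t_sc > 0,
            sc_threshold_pct > 0, sc_threshold_pct < 100)
  structure(list(k_apop = k_apop, k_bind9 = k_bind9, kd_apop9 = kd_apop9,
                 k_c9 = k_c9, k_on_x = k_on_x, kd_xiap_c3 = kd_xiap_c3,
                 kd_xiap_c9 = kd_xiap_c9, kd_xiap_smac = kd_xiap_smac,
                 k_deg3 = k_deg3, k_sub = k_sub, t_sc = t_sc,
                 sc_threshold_pct = sc_threshold_pct,
                 rtol = rtol, atol = atol),
            class = "caspase_parameters")
}

caspase_state_names <- c("APAF1", "Apop", "PC9", "ApopC9", "PC3", "C3",
                         "XIAP", "XIAPC3", "XIAPApopC9", "SMAC",
                         "SMACXIAP", "C3deg", "Sub", "cleavedSub")

#' Simulate executioner caspase activation
#'
#' Integrates the mass-action network for one protein profile (SMAC fully
#' cytosolic at t = 0, i.e. MOMP has occurred) and returns the substrate
#' cleavage percentage `SC% = 100 * cleavedSub(t_sc)`.
#'
#' @param profile named list/vector with `PC3`, `PC9`, `SMAC`, `XIAP` and
#'   `APAF1` in uM (e.g. one row of [protein_profiles()]).
#' @param params a [caspase_parameters()].
#' @param times optional output time grid (seconds) for the trajectory.
#' @return list with `substrate_cleavage_pct` and, when `times` is given,
#'   `trajectory`.
#' @export
simulate_caspase <- function(profile, params = caspase_parameters(),
                             times = NULL) {
  stopifnot(inherits(params, "caspase_parameters"))
  need <- c("PC3", "PC9", "SMAC", "XIAP", "APAF1")
  p <- unlist(profile[need])
  if (any(is.na(p)) || any(p < 0))
    stop("caspase profile must provide non-negative PC3, PC9, SMAC, ",
         "XIAP, APAF1 concentrations (uM)", call. = FALSE)
  y0 <- c(p[["APAF1"]], 0, p[["PC9"]], 0, p[["PC3"]], 0,
          p[["XIAP"]], 0, 0, p[["SMAC"]], 0, 0, 1, 0)
  parms <- c(params$k_apop, params$k_bind9, params$kd_apop9, params$k_c9,
             params$k_on_x, params$kd_xiap_c3, params$kd_xiap_c9,
             params$kd_xiap_smac, params$k_deg3, params$k_sub)
  tt <- if (is.null(times)) c(0, params$t_sc) else
    sort(unique(c(0, times, params$t_sc)))
  out <- deSolve::lsoda(y0, tt, func = "casp_deriv", parms = parms,
                        dllname = "apoptosens", initfunc = "casp_init",
                        rtol = params$rtol, atol = params$atol)
  if (attr(out, "istate")[1] < 0)
    stop("caspase ODE solver failed to converge (istate=",
         attr(out, "istate")[1], ")", call. = FALSE)
  colnames(out) <- c("time", caspase_state_names)
  sc <- 100 * out[out[, "time"] == params$t_sc, "cleavedSub"]
  res <- list(substrate_cleavage_pct = unname(sc))
  if (!is.null(times)) res$trajectory <- out
  res
}

#' Classify caspase activity from the substrate-cleavage readout
#'
#' High caspase activity at or above the threshold (closed lower bound),
#' low strictly below.
#'
#' @param sc_pct substrate cleavage % in \[0, 100\] (vectorized).
#' @param threshold_pct cutoff (default 25).
#' @return character vector, `"low"` or `"high"`.
#' @export
classify_caspase_activity <- function(sc_pct, threshold_pct = 25) {
  if (any(sc_pct < 0 | sc_pct > 100 + 1e-9, na.rm = TRUE))
    stop("substrate cleavage % must lie in [0, 100]", call. = FALSE)
  ifelse(sc_pct >= threshold_pct, "high", "low")
}

#' Pathway-quadrant classification
#'
#' Combines the two per-cell model classes into one of four pathway
#' quadrants: `both_high` (high MOMP sensitivity and high caspase
#' activity), `momp_only`, `caspase_only`, `both_low`. Per-core fractions
#' over the four labels sum to 1.
#'
#' @param momp_class `"low"`/`"high"` MOMP sensitivity (vectorized).
#' @param caspase_class `"low"`/`"high"` caspase activity.
#' @return character vector of quadrant labels; `NA` where either input
#'   is `NA`.
#' @export
quadrant_classify <- function(momp_class, caspase_class) {
  stopifnot(length(momp_class) == length(caspase_class))
  ok_m <- momp_class %in% c("low", "high")
  ok_c <- caspase_class %in% c("low", "high")
  out <- rep(NA_character_, length(momp_class))
  both <- ok_m & ok_c
  out[both] <- ifelse(momp_class[both] == "high",
                      ifelse(caspase_class[both] == "high",
                             "both_high", "momp_only"),
                      ifelse(caspase_class[both] == "high",
                             "caspase_only", "both_low"))
  out
}
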