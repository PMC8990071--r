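# Deterministic ODE model of BCL2-family controlled mitochondrial outer
# membrane permeabilization. A catalytic BH3-only "stress" species
# activates the effectors BAK and BAX; the anti-apoptotic proteins BCL2,
# BCL(X)L and MCL1 reversibly sequester both the stress species and the
# activated effectors with member-specific affinities; activated effectors
# irreversibly dimerize into pores. The readout is the maximum % of pores
# relative to total effector, and the stress dose required to reach the
# pore threshold.

MOMP_ANTI <- c("BCL2", "BCLXL", "MCL1")

#' Parameters of the MOMP model
#'
#' Kinetic constants and simulation controls of the pore-formation model.
#' The kinetic defaults encode canonical BCL2-family selectivity: BCL2
#' binds activated BAX tightly (0.002 uM) but activated BAK weakly (1 uM),
#' MCL1 the converse, BCL(X)L binds both tightly; all three sequester the
#' stress species at 0.01 uM. The tight Kd is chosen so that
#' anti-apoptotic sequestration genuinely withholds effectors from the
#' irreversible pore sink on the 3 h horizon: with a looser Kd the slow
#' release of sequestered effectors drains every profile into pores and
#' the low/high readout degenerates. All entries are plain configuration values,
#' so measured constants can be substituted without code changes.
#' Internal units are uM and seconds; stress doses cross the interface in
#' nM.
#'
#' @param kd 3x2 matrix of dissociation constants (uM), rows BCL2,
#'   BCL(X)L, MCL1, columns activated BAK, activated BAX.
#' @param kd_stress per anti-apoptotic Kd for the stress species (uM).
#' @param k_on association rate for all reversible bindings
#'   (uM^-1 s^-1).
#' @param k_act catalytic effector-activation rate (uM^-1 s^-1).
#' @param k_pore effector dimerization rate (uM^-1 s^-1).
#' @param t_end simulation horizon in seconds (default 3 h).
#' @param reference_stress_dose_nM reference stress dose (default 200 nM).
#' @param pore_threshold_pct low/high sensitivity cutoff on pore %
#'   (default 10; low is strictly below).
#' @param rtol,atol solver tolerances.
#' @param bracket_max_nM upper bisection bracket for the required dose
#'   (default 10000 nM).
#' @param bisect_tol_nM bisection tolerance (default 1 nM).
#' @return a `momp_parameters` list.
#' @export
momp_parameters <- function(kd = rbind(BCL2 = c(BAK = 1, BAX = 0.002),
                                       BCLXL = c(BAK = 0.002, BAX = 0.002),
                                       MCL1 = c(BAK = 0.002, BAX = 1)),
                            kd_stress = c(BCL2 = 0.01, BCLXL = 0.01,
                                          MCL1 = 0.01),
                            k_on = 1, k_act = 0.1, k_pore = 0.05,
                            t_end = 3 * 3600,
                            reference_stress_dose_nM = 200,
                            pore_threshold_pct = 10,
                            rtol = 1e-8, atol = 1e-10,
                            bracket_max_nM = 1e4, bisect_tol_nM = 1) {
  stopifnot(all(kd > 0), all(kd_stress > 0),
            k_on > 0, k_act > 0, k_pore > 0, t_end > 0,
            reference_stress_dose_nM >= 0,
            pore_threshold_pct > 0, pore_threshold_pct < 100,
            bracket_max_nM > 0, bisect_tol_nM > 0)
  structure(list(kd = kd, kd_stress = kd_stress, k_on = k_on,
                 k_act = k_act, k_pore = k_pore, t_end = t_end,
                 reference_stress_dose_nM = reference_stress_dose_nM,
                 pore_threshold_pct = pore_threshold_pct,
                 rtol = rtol, atol = atol,
                 bracket_max_nM = bracket_max_nM,
                 bisect_tol_nM = bisect_tol_nM),
            class = "momp_parameters")
}

momp_state_names <- c("S", "BAK", "BAX", "aBAK", "aBAX", "P_BAK", "P_BAX",
                      paste0("A_", MOMP_ANTI),
                      paste0("AS_", MOMP_ANTI),
                      paste0("ABAK_", MOMP_ANTI),
                      paste0("ABAX_", MOMP_ANTI))

momp_profile_vector <- function(profile) {
  need <- c("BAK", "BAX", "BCL2", "BCLXL", "MCL1")
  p <- unlist(profile[need])
  if (any(is.na(p)) || any(p < 0))
    stop("MOMP profile must provide non-negative BAK, BAX, BCL2, BCLXL, ",
         "MCL1 concentrations (uM)", call. = FALSE)
  p
}

#' Simulate MOMP pore formation under a stress dose
#'
#' Integrates the mass-action network for one protein profile and one
#' BH3-only stress dose and returns the maximum % level of pores, defined
#' as `100 * 2 * (P_BAK + P_BAX) / (BAK0 + BAX0)` (pores are dimers, so
#' the numerator counts effector molecules in pores). Pore formation is
#' irreversible, so the maximum over the horizon is the value at `t_end`.
#'
#' @param profile named list/vector with `BAK`, `BAX`, `BCL2`, `BCLXL`,
#'   `MCL1` in uM (e.g. one row of [protein_profiles()]).
#' @param stress_dose_nM BH3-only stress dose in nM.
#' @param params a [momp_parameters()].
#' @param times optional output time grid (seconds) for the trajectory.
#' @return list with `max_pore_pct` and, when `times` is given,
#'   `trajectory` (matrix of time and named species concentrations).
#' @export
simulate_momp <- function(profile, stress_dose_nM,
                          params = momp_parameters(), times = NULL) {
  stopifnot(inherits(params, "momp_parameters"), stress_dose_nM >= 0)
  p <- momp_profile_vector(profile)
  total_effector <- p[["BAK"]] + p[["BAX"]]
  if (total_effector <= 0)
    stop("total effector (BAK + BAX) is zero; pore % is undefined",
         call. = FALSE)
  y0 <- c(stress_dose_nM / 1000, p[["BAK"]], p[["BAX"]], 0, 0, 0, 0,
          p[["BCL2"]], p[["BCLXL"]], p[["MCL1"]], rep(0, 9))
  parms <- c(params$k_on, params$k_act, params$k_pore,
             params$kd_stress[MOMP_ANTI],
             params$kd[MOMP_ANTI, "BAK"], params$kd[MOMP_ANTI, "BAX"])
  tt <- if (is.null(times)) c(0, params$t_end) else
    sort(unique(c(0, times)))
  out <- deSolve::lsoda(y0, tt, func = "momp_deriv", parms = parms,
                        dllname = "apoptosens", initfunc = "momp_init",
                        rtol = params$rtol, atol = params$atol)
  if (attr(out, "istate")[1] < 0)
    stop("MOMP ODE solver failed to converge (istate=",
         attr(out, "istate")[1], ") for dose ", stress_dose_nM, " nM",
         call. = FALSE)
  colnames(out) <- c("time", momp_state_names)
  pore_pct <- 100 * 2 * (out[, "P_BAK"] + out[, "P_BAX"]) / total_effector
  res <- list(max_pore_pct = max(pore_pct))
  if (!is.null(times)) {
    res$trajectory <- cbind(out, pore_pct = pore_pct)
  }
  res
}

#' Classify MOMP sensitivity from the pore readout
#'
#' A cell has low sensitivity for MOMP when its maximum % level of pores
#' under the reference stress dose is strictly below the threshold
#' (default 10%); at or above the threshold it is high.
#'
#' @param max_pore_pct pore % in \[0, 100\] (vectorized).
#' @param threshold_pct cutoff (default 10).
#' @return character vector, `"low"` or `"high"`.
#' @export
classify_momp_sensitivity <- function(max_pore_pct, threshold_pct = 10) {
  if (any(max_pore_pct < 0 | max_pore_pct > 100 + 1e-9, na.rm = TRUE))
    stop("pore % must lie in [0, 100]", call. = FALSE)
  ifelse(max_pore_pct < threshold_pct, "low", "high")
}

#' Required stress dose for MOMP
#'
#' Finds, by bisection over `[0, bracket_max_nM]`, the smallest stress
#' dose at which the maximum pore % reaches the pore threshold. Returns
#' `Inf` (the "unreachable" sentinel) when even the upper bracket fails to
#' permeabilize the cell.
#'
#' @inheritParams simulate_momp
#' @return required dose in nM, or `Inf` if unreachable within the
#'   bracket.
#' @export
required_stress_dose <- function(profile, params = momp_parameters()) {
  pore_at <- function(dose)
    simulate_momp(profile, dose, params)$max_pore_pct
  thr <- params$pore_threshold_pct
  hi <- params$bracket_max_nM
  if (pore_at(hi) < thr) return(Inf)
  lo <- 0
  while (hi - lo > params$bisect_tol_nM) {
    mid <- (lo + hi) / 2
    if (pore_at(mid) >= thr) hi <- mid else lo <- mid
  }
  hi
}
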