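/* Mass-action right-hand sides for the two apoptosis ODE models,
 * in the deSolve compiled-model interface (initfunc + derivs).
 * Concentrations in uM, time in seconds. */

#include <R.h>
#include <R_ext/Rdynload.h>

/* ---------------- MOMP (BCL2-family / pore formation) ----------------
 * parms (12): k_on, k_act, k_pore,
 *             kd_stress[3], kd_bak[3], kd_bax[3]
 *             (anti-apoptotic order: BCL2, BCL(X)L, MCL1)
 * state (19): 0 S, 1 BAK, 2 BAX, 3 aBAK, 4 aBAX, 5 P_BAK, 6 P_BAX,
 *             7-9 A_j, 10-12 A_j.S, 13-15 A_j.aBAK, 16-18 A_j.aBAX
 */

static double momp_parms[12];

void momp_init(void (*odeparms)(int *, double *)) {
  int n = 12;
  odeparms(&n, momp_parms);
}

void momp_deriv(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip) {
  const double k_on = momp_parms[0], k_act = momp_parms[1],
               k_pore = momp_parms[2];
  double S = y[0], aBak = y[3], aBax = y[4];
  double act_bak = k_act * S * y[1];
  double act_bax = k_act * S * y[2];
  double dim_bak = k_pore * aBak * aBak;
  double dim_bax = k_pore * aBax * aBax;
  double dS = 0.0;
  double daBak = act_bak - 2.0 * dim_bak;
  double daBax = act_bax - 2.0 * dim_bax;

  ydot[1] = -act_bak;
  ydot[2] = -act_bax;
  ydot[5] = dim_bak;
  ydot[6] = dim_bax;

  for (int j = 0; j < 3; j++) {
    double A = y[7 + j];
    double on_s  = k_on * A * S;
    double off_s = k_on * momp_parms[3 + j] * y[10 + j];
    double on_k  = k_on * A * aBak;
    double off_k = k_on * momp_parms[6 + j] * y[13 + j];
    double on_x  = k_on * A * aBax;
    double off_x = k_on * momp_parms[9 + j] * y[16 + j];
    dS    += off_s - on_s;
    daBak += off_k - on_k;
    daBax += off_x - on_x;
    ydot[7 + j]  = off_s - on_s + off_k - on_k + off_x - on_x;
    ydot[10 + j] = on_s - off_s;
    ydot[13 + j] = on_k - off_k;
    ydot[16 + j] = on_x - off_x;
  }
  ydot[0] = dS;
  ydot[3] = daBak;
  ydot[4] = daBax;
}

/* ------------- caspase activation (apoptosome / XIAP / SMAC) ----------
 * parms (10): k_apop, k_bind9, kd_apop9, k_c9, k_on_x,
 *             kd_xiap_c3, kd_xiap_c9, kd_xiap_smac, k_deg3, k_sub
 * state (14): 0 APAF1, 1 Apop, 2 PC9, 3 Apop.C9, 4 PC3, 5 C3,
 *             6 XIAP, 7 XIAP.C3, 8 XIAP.Apop.C9, 9 SMAC, 10 SMAC.XIAP,
 *             11 C3deg, 12 Sub, 13 cleavedSub
 */

static double casp_parms[10];

void casp_init(void (*odeparms)(int *, double *)) {
  int n = 10;
  odeparms(&n, casp_parms);
}

void casp_deriv(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip) {
  const double k_apop = casp_parms[0], k_bind9 = casp_parms[1],
               kd_apop9 = casp_parms[2], k_c9 = casp_parms[3],
               k_on_x = casp_parms[4], kd_x3 = casp_parms[5],
               kd_x9 = casp_parms[6], kd_xs = casp_parms[7],
               k_deg3 = casp_parms[8], k_sub = casp_parms[9];

  double v_form  = k_apop * y[0];                 /* APAF1 -> Apop        */
  double v9_on   = k_bind9 * y[1] * y[2];         /* Apop + PC9 -> Apop.C9 */
  double v9_off  = k_bind9 * kd_apop9 * y[3];
  double v_cat   = k_c9 * y[3] * y[4];            /* PC3 -> C3            */
  double vx3_on  = k_on_x * y[6] * y[5];          /* XIAP + C3            */
  double vx3_off = k_on_x * kd_x3 * y[7];
  double vx9_on  = k_on_x * y[6] * y[3];          /* XIAP + Apop.C9       */
  double vx9_off = k_on_x * kd_x9 * y[8];
  double vxs_on  = k_on_x * y[9] * y[6];          /* SMAC + XIAP          */
  double vxs_off = k_on_x * kd_xs * y[10];
  double v_deg   = k_deg3 * y[7];                 /* XIAP.C3 -> XIAP + C3deg */
  double v_sub   = k_sub * y[5] * y[12];          /* Sub -> cleavedSub    */

  ydot[0]  = -v_form;
  ydot[1]  = v_form - v9_on + v9_off;
  ydot[2]  = -v9_on + v9_off;
  ydot[3]  = v9_on - v9_off - vx9_on + vx9_off;
  ydot[4]  = -v_cat;
  ydot[5]  = v_cat - vx3_on + vx3_off;
  ydot[6]  = -vx3_on + vx3_off - vx9_on + vx9_off - vxs_on + vxs_off + v_deg;
  ydot[7]  = vx3_on - vx3_off - v_deg;
  ydot[8]  = vx9_on - vx9_off;
  ydot[9]  = -vxs_on + vxs_off;
  ydot[10] = vxs_on - vxs_off;
  ydot[11] = v_deg;
  ydot[12] = -v_sub;
  ydot[13] = v_sub;
}

static const R_CMethodDef cMethods[] = {
  {NULL, NULL, 0}
};

void R_init_apoptosens(DllInfo *dll) {
  R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
  R_useDynamicSymbols(dll, TRUE); /* deSolve looks the derivs up by name */
}
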