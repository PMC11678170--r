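/* Compiled right-hand side of the secukinumab PK/PD ODE system for deSolve.
 *
 * States (0-based):
 *   y[0]  depot     SC absorption site amount (mg)
 *   y[1]  central   central compartment amount (mg)
 *   y[2]  periph    peripheral compartment amount (mg)
 *   y[3..6] P1..P4  prePASI transit chain
 *   y[7]  PASI      observed severity state
 *   y[8..10] M1..M3 tolerance mediator chain
 */
#include <R.h>
#include <R_ext/Rdynload.h>

static double parms[12];
#define p_ka      parms[0]
#define p_cl      parms[1]
#define p_v2      parms[2]
#define p_v3      parms[3]
#define p_q       parms[4]
#define p_kin     parms[5]
#define p_kout    parms[6]
#define p_ktr     parms[7]
#define p_imax    parms[8]
#define p_ic50    parms[9]
#define p_slp     parms[10]
#define p_ktol    parms[11]

void secu_initmod(void (*odeparms)(int *, double *))
{
    int n = 12;
    odeparms(&n, parms);
}

void secu_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double conc = y[1] / p_v2;
    if (conc < 0.0) conc = 0.0;

    /* Imax inhibition of kin, attenuated by the third tolerance mediator;
     * floored at zero because Imax > 1 makes the raw term negative at
     * high exposure and lesion production cannot be negative. */
    double inh = 1.0 - p_imax * conc / (p_ic50 + conc) / (1.0 + y[10]);
    if (inh < 0.0) inh = 0.0;

    double k21 = (p_v3 > 0.0) ? p_q / p_v3 : 0.0;

    ydot[0] = -p_ka * y[0];
    ydot[1] = p_ka * y[0] - (p_cl / p_v2) * y[1]
              - (p_q / p_v2) * y[1] + k21 * y[2];
    ydot[2] = (p_q / p_v2) * y[1] - k21 * y[2];

    ydot[3] = p_kin * inh - p_ktr * y[3];
    ydot[4] = p_ktr * (y[3] - y[4]);
    ydot[5] = p_ktr * (y[4] - y[5]);
    ydot[6] = p_ktr * (y[5] - y[6]);
    ydot[7] = p_ktr * y[6] - p_kout * y[7];

    ydot[8]  = p_slp * conc - p_ktol * y[8];
    ydot[9]  = p_ktol * (y[8] - y[9]);
    ydot[10] = p_ktol * (y[9] - y[10]);
}

/* PD-only subsystem driven by a precomputed concentration forcing.
 * Used by the individual-estimation layer, where the PK profile is fixed
 * (PK parameters carry no sampled random effects) and re-integrating the
 * drug states at every Metropolis-Hastings iteration would be wasted work.
 *
 * States: y[0..3] P1..P4, y[4] PASI, y[5..7] M1..M3.
 */
static double pd_parms[7];
#define q_kin   pd_parms[0]
#define q_kout  pd_parms[1]
#define q_ktr   pd_parms[2]
#define q_imax  pd_parms[3]
#define q_ic50  pd_parms[4]
#define q_slp   pd_parms[5]
#define q_ktol  pd_parms[6]

static double pd_forc[1];   /* concentration C(t), linearly interpolated */

void secu_pd_initmod(void (*odeparms)(int *, double *))
{
    int n = 7;
    odeparms(&n, pd_parms);
}

void secu_pd_initforc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, pd_forc);
}

void secu_pd_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double conc = pd_forc[0];
    if (conc < 0.0) conc = 0.0;

    double inh = 1.0 - q_imax * conc / (q_ic50 + conc) / (1.0 + y[7]);
    if (inh < 0.0) inh = 0.0;

    ydot[0] = q_kin * inh - q_ktr * y[0];
    ydot[1] = q_ktr * (y[0] - y[1]);
    ydot[2] = q_ktr * (y[1] - y[2]);
    ydot[3] = q_ktr * (y[2] - y[3]);
    ydot[4] = q_ktr * y[3] - q_kout * y[4];

    ydot[5] = q_slp * conc - q_ktol * y[5];
    ydot[6] = q_ktol * (y[5] - y[6]);
    ydot[7] = q_ktol * (y[6] - y[7]);
}

static const R_CMethodDef cMethods[] = {
    {NULL, NULL, 0}
};

void R_init_secumipd(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
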