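/* Compiled right-hand sides for the batch-culture consumer-resource models,
 * in the deSolve compiled-code calling convention (initfunc/derivs/root).
 *
 * Two model families are implemented:
 *
 *  crm_*  — multi-species community on shared carbon pool(s): competitive,
 *           facilitation (beta premultiplied in R), niche-partitioned
 *           (two static pools), and cross-feeding (producers leak a fraction
 *           pp of consumed carbon into a cross-fed pool eaten by consumers).
 *           State: [x_1..x_n, R_1..R_nrt, B]; nrt = n_static + has_crossfed.
 *
 *  ssmc_* — one species on m substitutable carbon sources plus one essential
 *           nitrogen pool, growth under Liebig's law of the minimum.
 *           State: [x, C_1..C_m, N].
 *
 * Parameters arrive via the deSolve initfunc as a fixed-length packed vector
 * (padded in R to PARMS_LEN); per-species arrays live at fixed offsets.
 */

#include <R.h>
#include <math.h>

#define PARMS_LEN 1024

static double parms[PARMS_LEN];

void crmge_init(void (*odeparms)(int *, double *))
{
    int n = PARMS_LEN;
    odeparms(&n, parms);
}

/* slot indices in the packed header */
#define P_N      0
#define P_NRES   1
#define P_CF     2
#define P_SCALE  3
#define P_THR    4
#define P_EQ6    5
#define P_BTOTAL 6   /* producer byproduct on total (not retained) carbon */

static double clip0(double v) { return v > 0.0 ? v : 0.0; }

/* community families ------------------------------------------------------ */

static void crm_core(double *y, double *ydot, double *maxpercap, double *cons)
{
    int n    = (int) parms[P_N];
    int nres = (int) parms[P_NRES];
    int cf   = (int) parms[P_CF];
    int nrt  = nres + cf;
    int eq6  = (int) parms[P_EQ6];
    int btot = (int) parms[P_BTOTAL];
    const double *mu   = parms + 8;
    const double *K    = mu + n;
    const double *invY = K + n;      /* consumption per unit biomass growth */
    const double *pp   = invY + n;
    const double *beta = pp + n;
    const double *res  = beta + n;
    const double *Yraw = res + n;

    double dB = 0.0, mg = 0.0, qtot = 0.0;
    int i, r;

    for (r = 0; r < nrt; r++) ydot[n + r] = 0.0;

    for (i = 0; i < n; i++) {
        int ri = (int) res[i];
        double R = clip0(y[n + ri]);
        double M = R / (K[i] + R);
        double percap = mu[i] * M;
        double g = percap * clip0(y[i]);   /* biomass growth rate */
        double q = g * invY[i];            /* carbon consumption rate */
        ydot[i] = g;
        ydot[n + ri] -= q;
        if (cf && pp[i] > 0.0)
            ydot[n + nres] += pp[i] * q;   /* leak into cross-fed pool */
        /* byproduct per unit carbon routed through growth (retained for
         * producers), or per total consumed / times yield under the
         * comparison variants */
        dB += eq6 ? beta[i] * Yraw[i] * g
                  : beta[i] * (btot ? q : (1.0 - pp[i]) * q);
        if (percap > mg) mg = percap;
        qtot += q;
    }
    ydot[n + nrt] = dB;
    if (maxpercap) *maxpercap = mg;
    if (cons)      *cons = qtot;
}

void crm_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    crm_core(y, ydot, NULL, NULL);
}

void crm_root(int *neq, double *t, double *y, int *ng, double *gout,
              double *out, int *ip)
{
    double ydot[256];
    double mg, cons;
    crm_core(y, ydot, &mg, &cons);
    {
        double thr = parms[P_THR], scale = parms[P_SCALE];
        double a = mg - thr;
        double b = cons / scale - thr;
        gout[0] = a > b ? a : b;
    }
}

/* single species, many carbons, one nitrogen ------------------------------ */

static void ssmc_core(double *y, double *ydot, double *maxpercap, double *cons)
{
    int m = (int) parms[P_N];
    const double *rC = parms + 8;
    const double *YC = rC + m;
    const double *KC = YC + m;
    double rN = parms[8 + 3 * m];
    double YN = parms[8 + 3 * m + 1];
    double KN = parms[8 + 3 * m + 2];

    double x = clip0(y[0]);
    double N = clip0(y[m + 1]);
    double sumC = 0.0, drain = 0.0;
    int i;

    for (i = 0; i < m; i++) {
        double C = clip0(y[1 + i]);
        double M = rC[i] * C / (KC[i] + C);   /* uptake term r*C/(K+C) */
        ydot[1 + i] = -x * M;
        drain += x * M;
        sumC += YC[i] * M;
    }
    {
        double gN = YN * rN * N / (KN + N);
        double g = sumC < gN ? sumC : gN;     /* Liebig minimum */
        ydot[0] = x * g;
        ydot[m + 1] = -x * g / YN;
        if (maxpercap) *maxpercap = g;
        if (cons) *cons = drain + x * g / YN;
    }
}

void ssmc_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    ssmc_core(y, ydot, NULL, NULL);
}

void ssmc_root(int *neq, double *t, double *y, int *ng, double *gout,
               double *out, int *ip)
{
    double ydot[256];
    double mg, cons;
    ssmc_core(y, ydot, &mg, &cons);
    {
        double thr = parms[P_THR], scale = parms[P_SCALE];
        double a = mg - thr;
        double b = cons / scale - thr;
        gout[0] = a > b ? a : b;
    }
}
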