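#include <R.h>
#include <R_ext/Rdynload.h>

/* Mass-action right-hand sides for the strand-exchange schemes, in the
   compiled-model form expected by deSolve (initfunc + derivs).  Parameters
   and state are in nM and s; the filament is a single kinetic species. */

static double p3[6]; /* k1, k_m1, k2, k_m2, k3, k_m3 */
static double p2[4]; /* k1, k_m1, k2, k_m2 */

void strandex_init3(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, p3);
}

void strandex_init2(void (*odeparms)(int *, double *))
{
    int n = 4;
    odeparms(&n, p2);
}

/* y = (A, B, C1, C2, D, E) */
void strandex_deriv3(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double v1 = p3[0] * y[0] * y[1] - p3[1] * y[2];
    double v2 = p3[2] * y[2] - p3[3] * y[3];
    double v3 = p3[4] * y[3] - p3[5] * y[4] * y[5];
    ydot[0] = -v1;
    ydot[1] = -v1;
    ydot[2] = v1 - v2;
    ydot[3] = v2 - v3;
    ydot[4] = v3;
    ydot[5] = v3;
}

/* y = (A, B, C1, D, E) — single intermediate */
void strandex_deriv2(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double v1 = p2[0] * y[0] * y[1] - p2[1] * y[2];
    double v2 = p2[2] * y[2] - p2[3] * y[3] * y[4];
    ydot[0] = -v1;
    ydot[1] = -v1;
    ydot[2] = v1 - v2;
    ydot[3] = v2;
    ydot[4] = v2;
}

static const R_CMethodDef CEntries[] = {
    {"strandex_init3",  (DL_FUNC) &strandex_init3,  1},
    {"strandex_init2",  (DL_FUNC) &strandex_init2,  1},
    {"strandex_deriv3", (DL_FUNC) &strandex_deriv3, 6},
    {"strandex_deriv2", (DL_FUNC) &strandex_deriv2, 6},
    {NULL, NULL, 0}
};

void R_init_strandex(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
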