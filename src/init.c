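#include <R.h>
#include <R_ext/Rdynload.h>

/* Routines are resolved by deSolve through getNativeSymbolInfo(), so they
 * are registered here and dynamic symbol lookup stays enabled. */

void crmge_init(void (*odeparms)(int *, double *));
void crm_derivs(int *, double *, double *, double *, double *, int *);
void crm_root(int *, double *, double *, int *, double *, double *, int *);
void ssmc_derivs(int *, double *, double *, double *, double *, int *);
void ssmc_root(int *, double *, double *, int *, double *, double *, int *);

static const R_CMethodDef CEntries[] = {
    {"crmge_init",  (DL_FUNC) &crmge_init,  1},
    {"crm_derivs",  (DL_FUNC) &crm_derivs,  6},
    {"crm_root",    (DL_FUNC) &crm_root,    7},
    {"ssmc_derivs", (DL_FUNC) &ssmc_derivs, 6},
    {"ssmc_root",   (DL_FUNC) &ssmc_root,   7},
    {NULL, NULL, 0}
};

void R_init_crmge(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
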