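#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void circ_initmod(void (*odeparms)(int *, double *));
void circ_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"circ_initmod", (DL_FUNC) &circ_initmod, 1},
    {"circ_derivs",  (DL_FUNC) &circ_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_hepacirc(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    /* deSolve looks the routines up by name */
    R_useDynamicSymbols(dll, TRUE);
    R_forceSymbols(dll, FALSE);
}
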