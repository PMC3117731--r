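#include <R.h>
#include <R_ext/Rdynload.h>

void atorkin_initmod(void (*odeparms)(int *, double *));
void atorkin_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"atorkin_initmod", (DL_FUNC) &atorkin_initmod, 1},
    {"atorkin_derivs", (DL_FUNC) &atorkin_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_atorkin(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
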