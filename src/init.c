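#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void carrtdex_init(void (*odeparms)(int *, double *));
void carrtdex_deriv_nonaut(int *, double *, double *, double *, double *, int *);
void carrtdex_deriv_aut(int *, double *, double *, double *, double *, int *);

static const R_CMethodDef CEntries[] = {
    {"carrtdex_init",         (DL_FUNC) &carrtdex_init,         1},
    {"carrtdex_deriv_nonaut", (DL_FUNC) &carrtdex_deriv_nonaut, 6},
    {"carrtdex_deriv_aut",    (DL_FUNC) &carrtdex_deriv_aut,    6},
    {NULL, NULL, 0}
};

void R_init_carrtdex(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
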