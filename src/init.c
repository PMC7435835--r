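#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP C_conv1d_fwd(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP C_conv1d_bwd_data(SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP C_conv1d_bwd_weights(SEXP, SEXP, SEXP, SEXP, SEXP);

static const R_CallMethodDef callMethods[] = {
    {"C_conv1d_fwd", (DL_FUNC) &C_conv1d_fwd, 6},
    {"C_conv1d_bwd_data", (DL_FUNC) &C_conv1d_bwd_data, 5},
    {"C_conv1d_bwd_weights", (DL_FUNC) &C_conv1d_bwd_weights, 5},
    {NULL, NULL, 0}
};

void R_init_apneaCNN(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
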