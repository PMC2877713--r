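#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* Rcpp exports (RcppExports.cpp) */
extern SEXP _operonet_ma_rhs_field(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP _operonet_ma_flux_field(SEXP, SEXP, SEXP, SEXP, SEXP);

/* deSolve compiled model (field_derivs.c) */
extern void operonet_initmod(void (*odeparms)(int *, double *));
extern void operonet_derivs(int *, double *, double *, double *, double *, int *);

static const R_CallMethodDef CallEntries[] = {
    {"_operonet_ma_rhs_field",  (DL_FUNC) &_operonet_ma_rhs_field,  8},
    {"_operonet_ma_flux_field", (DL_FUNC) &_operonet_ma_flux_field, 5},
    {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
    {"operonet_initmod", (DL_FUNC) &operonet_initmod, 1},
    {"operonet_derivs",  (DL_FUNC) &operonet_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_operonet(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
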