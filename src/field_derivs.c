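/* Compiled deSolve right-hand side for stacked per-position mass-action
   systems (no R callback). The model structure is packed into the parms
   vector (padded to MAXPAR, see R/.pack_field_parms):
     parms[0..4] = S, P, R, n_terms, n_gamma
     then n_terms triplets (reaction, species, power)   [1-based]
     then n_gamma triplets (species, reaction, value)   [1-based]
     then kfac, an R x P matrix column-major.
   State layout: position-major blocks of S species. */

#include <R.h>
#include <Rinternals.h>

#define OPERONET_MAXPAR 40000
#define OPERONET_MAXFLUX 4096

static double operonet_parms[OPERONET_MAXPAR];

void operonet_initmod(void (*odeparms)(int *, double *))
{
    int n = OPERONET_MAXPAR;
    odeparms(&n, operonet_parms);
}

void operonet_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const double *p = operonet_parms;
    const int S = (int) p[0], P = (int) p[1], R = (int) p[2];
    const int nt = (int) p[3], ng = (int) p[4];
    const double *term = p + 5;
    const double *gam = term + 3 * nt;
    const double *kfac = gam + 3 * ng;
    double flux[OPERONET_MAXFLUX];

    if (R > OPERONET_MAXFLUX)
        error("operonet_derivs: too many reactions (%d)", R);

    for (int pos = 0; pos < P; pos++) {
        const double *x = y + (size_t) pos * S;
        double *dx = ydot + (size_t) pos * S;
        const double *kf = kfac + (size_t) pos * R;
        for (int r = 0; r < R; r++) flux[r] = kf[r];
        for (int ti = 0; ti < nt; ti++) {
            const int r = (int) term[3 * ti] - 1;
            const int s = (int) term[3 * ti + 1] - 1;
            const int pw = (int) term[3 * ti + 2];
            double v = x[s];
            if (v < 0) v = 0;
            double f = v;
            for (int q = 1; q < pw; q++) f *= v;
            flux[r] *= f;
        }
        for (int i = 0; i < S; i++) dx[i] = 0;
        for (int tg = 0; tg < ng; tg++) {
            const int i = (int) gam[3 * tg] - 1;
            const int j = (int) gam[3 * tg + 1] - 1;
            dx[i] += gam[3 * tg + 2] * flux[j];
        }
    }
}
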