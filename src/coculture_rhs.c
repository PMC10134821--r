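/* Right-hand side of the two-compartment syntrophic coculture ODE,
 * compiled for use through deSolve's compiled-model interface. The ABC
 * loop integrates this system thousands of times at a maximum step of
 * 0.0025 h, so the derivative must be cheap.
 *
 * State vector (length 10), amounts in mmol, biomass in gDW:
 *   y[0] B strain1 comp1   y[1] B strain2 comp1
 *   y[2] B strain1 comp2   y[3] B strain2 comp2
 *   y[4..6]  N glucose, lysine, isoleucine in comp1
 *   y[7..9]  N glucose, lysine, isoleucine in comp2
 *
 * Parameter vector (length 22):
 *   p[0] d (L/h)  p[1] V1 (L)  p[2] V2 (L)  p[3] ncomp (1 or 2)
 *   p[4..12]  strain1: vmax_glc, km_glc, vmax_aa, km_aa, y_glc, y_aa,
 *             e_leak, req_idx (1=lys, 2=ile), leak_idx
 *   p[13..21] strain2: same layout
 */
#include <R.h>

static double parms[22];

void coculture_initmod(void (*odeparms)(int *, double *))
{
    int n = 22;
    odeparms(&n, parms);
}

void coculture_deriv(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const double d = parms[0];
    const int ncomp = (int) parms[3];
    double C[2][3]; /* concentration [comp][met], met 0=glc 1=lys 2=ile */
    int w, s, m;

    for (m = 0; m < 10; m++) ydot[m] = 0.0;

    for (w = 0; w < ncomp; w++) {
        const double V = parms[1 + w];
        for (m = 0; m < 3; m++) {
            double n_amt = y[4 + 3 * w + m];
            C[w][m] = (n_amt > 0.0 ? n_amt : 0.0) / V;
        }
    }

    for (w = 0; w < ncomp; w++) {
        for (s = 0; s < 2; s++) {
            const double *p = parms + 4 + 9 * s;
            const double vmax_glc = p[0], km_glc = p[1];
            const double vmax_aa = p[2], km_aa = p[3];
            const double y_glc = p[4], y_aa = p[5], e_leak = p[6];
            const int req = (int) p[7], leak = (int) p[8];
            double B = y[2 * w + s];
            double mu_glc, mu_aa, mu;

            if (B < 0.0) B = 0.0;
            mu_glc = y_glc * vmax_glc * C[w][0] / (km_glc + C[w][0]);
            mu_aa = y_aa * vmax_aa * C[w][req] / (km_aa + C[w][req]);
            mu = (mu_glc < mu_aa) ? mu_glc : mu_aa;

            ydot[2 * w + s] += mu * B;
            ydot[4 + 3 * w + 0] -= mu / y_glc * B;
            ydot[4 + 3 * w + req] -= mu / y_aa * B;
            ydot[4 + 3 * w + leak] += e_leak * mu * B;
        }
    }

    if (ncomp == 2) {
        for (m = 0; m < 3; m++) {
            const double flux = d * (C[0][m] - C[1][m]); /* mmol/h, 1 -> 2 */
            ydot[4 + m] -= flux;
            ydot[7 + m] += flux;
        }
    }
}
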