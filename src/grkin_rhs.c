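/* Compiled mass-action right-hand side for deSolve.
 *
 * State layout (0-based): gene g has mRNA at 2g and protein at 2g+1,
 * g = 0..ng-1 in model order (latent intermediate included); the active
 * GR pool (GRa) sits at index 2*ng.
 *
 * Parameter vector layout (padded to GRKIN_PARMS_LEN doubles):
 *   [0] ng  [1] ne  [2] 1-based gene index of GR  [3] k_act * D
 *   [4 .. 4+4*ng)   per-gene blocks: s, dm, tl, dp
 *   [4+4*ng .. )    per-edge quads: 1-based source state index,
 *                   1-based target gene index, activation flag, rate
 */
#include <R.h>

#define GRKIN_PARMS_LEN 128

static double parms[GRKIN_PARMS_LEN];

void grkin_init(void (*odeparms)(int *, double *))
{
    int n = GRKIN_PARMS_LEN;
    odeparms(&n, parms);
}

void grkin_rhs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    int ng = (int) parms[0];
    int ne = (int) parms[1];
    int igr = (int) parms[2] - 1;
    double kD = parms[3];
    const double *s = parms + 4;
    const double *dm = s + ng;
    const double *tl = dm + ng;
    const double *dp = tl + ng;
    const double *ed = parms + 4 + 4 * ng;
    int ia = 2 * ng;
    int g, e;

    for (g = 0; g < ng; g++) {
        ydot[2 * g] = s[g] - dm[g] * y[2 * g];
        ydot[2 * g + 1] = tl[g] * y[2 * g] - dp[g] * y[2 * g + 1];
    }
    for (e = 0; e < ne; e++) {
        int src = (int) ed[4 * e] - 1;
        int tgt = (int) ed[4 * e + 1] - 1;
        int act = (int) ed[4 * e + 2];
        double drive = ed[4 * e + 3] * y[src];
        if (act)
            ydot[2 * tgt] += drive;
        else
            ydot[2 * tgt] -= drive * y[2 * tgt];
    }
    {
        double conv = kD * y[2 * igr + 1];
        ydot[2 * igr + 1] -= conv;
        ydot[ia] = conv - dp[igr] * y[ia];
    }
}
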