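/* Compiled right-hand side of the hybrid cybernetic ODE system, used by
 * deSolve through its dllname/initfunc interface. State layout matches the
 * R fallback: (extracellular species x, pseudo-enzymes e_1..e_L, cellmass).
 *
 * Parameter block layout (packed on the R side, padded to HCM_PARMS_LEN):
 *   p[0] n_ext, p[1] L, p[2] kE,
 *   then 7 blocks of length L: k, Ksat, alpha, beta, z_s, z_mu,
 *   substrate index (1-based into x, 0 = no uptake substrate),
 *   then SZ (n_ext x L, column-major) = extracellular stoichiometry
 *   collapsed over modes.
 */
#include <R.h>

#define HCM_PARMS_LEN 512
#define HCM_MAX_L 32

static double hcm_p[HCM_PARMS_LEN];

void hcm_initmod(void (*odeparms)(int *, double *))
{
    int n = HCM_PARMS_LEN;
    odeparms(&n, hcm_p);
}

void hcm_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const int n_ext = (int) hcm_p[0];
    const int L = (int) hcm_p[1];
    const double kE = hcm_p[2];
    const double *k = hcm_p + 3;
    const double *Ksat = k + L;
    const double *alpha = Ksat + L;
    const double *beta = alpha + L;
    const double *z_s = beta + L;
    const double *z_mu = z_s + L;
    const double *sub = z_mu + L;
    const double *SZ = sub + L;

    double sat[HCM_MAX_L], qbar[HCM_MAX_L], w[HCM_MAX_L], q[HCM_MAX_L];
    double total = 0.0, wmax = 0.0, rG = 0.0;
    int i, l;

    const double c_mass = y[n_ext + L] > 0 ? y[n_ext + L] : 0;

    for (l = 0; l < L; l++) {
        int si = (int) sub[l];
        double s = 0.0, e = y[n_ext + l] > 0 ? y[n_ext + l] : 0;
        if (si > 0) {
            s = y[si - 1];
            if (s < 0) s = 0;
        }
        sat[l] = (si > 0) ? s / (Ksat[l] + s) : 0.0;
        qbar[l] = k[l] * e * sat[l];
        w[l] = z_s[l] * qbar[l];
        total += w[l];
        if (w[l] > wmax) wmax = w[l];
    }
    for (l = 0; l < L; l++) {
        double u = total > 0 ? w[l] / total : 0.0;
        double v = total > 0 ? w[l] / wmax : 0.0;
        double e = y[n_ext + l] > 0 ? y[n_ext + l] : 0;
        q[l] = v * qbar[l];
        rG += z_mu[l] * q[l];
        /* enzyme balance, growth-rate dilution term added below */
        ydot[n_ext + l] = alpha[l] + kE * sat[l] * u - beta[l] * e;
    }
    for (l = 0; l < L; l++) {
        double e = y[n_ext + l] > 0 ? y[n_ext + l] : 0;
        ydot[n_ext + l] -= rG * e;
    }
    for (i = 0; i < n_ext; i++) {
        double dx = 0.0;
        for (l = 0; l < L; l++)
            dx += SZ[i + l * n_ext] * q[l];
        ydot[i] = dx * c_mass;
    }
    ydot[n_ext + L] = rG * c_mass;
}
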