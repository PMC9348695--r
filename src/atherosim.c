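/* Compiled right-hand side of the seven-compartment plaque model for
 * deSolve. State order: MONO_B, MONO, IM, L, F, L_B, R.
 * Parameter vector (16): k_MONO, d_MONO_B, a, alpha, epsilon, c, b,
 * k_LDL, f, e, d_LDL, d_F, xi, d_L_B, din, clamp.
 */
#include <R.h>

static double parms[16];

#define P_k_MONO   parms[0]
#define P_d_MONO_B parms[1]
#define P_a        parms[2]
#define P_alpha    parms[3]
#define P_epsilon  parms[4]
#define P_c        parms[5]
#define P_b        parms[6]
#define P_k_LDL    parms[7]
#define P_f        parms[8]
#define P_e        parms[9]
#define P_d_LDL    parms[10]
#define P_d_F      parms[11]
#define P_xi       parms[12]
#define P_d_L_B    parms[13]
#define P_din      parms[14]
#define P_clamp    parms[15]

void atherosim_init(void (*odeparms)(int *, double *))
{
    int n = 16;
    odeparms(&n, parms);
}

void atherosim_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double s[7];
    int i;
    for (i = 0; i < 7; i++) {
        s[i] = y[i];
        /* integrator noise below the clamp is treated as exactly zero */
        if (s[i] < 0 && s[i] > -P_clamp) s[i] = 0;
    }
    double MONO_B = s[0], MONO = s[1], IM = s[2], L = s[3], F = s[4],
           L_B = s[5], R = s[6];
    if (R < 1e-12) R = 1e-12; /* divergence is detected on the output grid */

    double R3 = R * R * R;
    double dF = P_b * IM * L - P_d_F * F;

    ydot[0] = P_k_MONO - P_d_MONO_B * MONO_B;
    ydot[1] = P_a * R3 / (R3 + P_alpha) * L / (1 + L) * MONO_B
              - (P_epsilon + P_c) * MONO;
    ydot[2] = P_c * MONO - P_b * IM * L;
    ydot[3] = P_k_LDL * L_B * MONO / (P_f + MONO) - P_e * L * IM
              - P_d_LDL * L;
    ydot[4] = dF;
    ydot[5] = P_din - P_d_L_B * L_B;
    ydot[6] = P_xi / 2 * (R - 1 / R) * dF;
}

/* Root function: stops integration when the radius collapses toward full
 * occlusion (the model is invalid there; callers raise an error). */
void atherosim_root(int *neq, double *t, double *y, int *ng, double *gout)
{
    gout[0] = y[6] - 0.02;
}
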