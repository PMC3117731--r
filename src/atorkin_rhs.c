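/* Compiled right-hand side of the 18-state atorvastatin biotransformation
 * model, for use with deSolve's compiled-model interface. Mirrors ode_rhs()
 * in R/ode.R (the reference implementation); both are cross-checked in the
 * test suite.
 *
 * State order (compound-major): for each compound j in
 * {AS, ASL, ASpOH, ASoOH, ASLpOH, ASLoOH}: medium, intracellular free,
 * intracellular bound.
 *
 * Parameter vector layout (see params_to_cvec() in R/ode_compiled.R):
 *  0-3   CYP3A4 rmax (channels ASpOH, ASoOH, ASLpOH, ASLoOH)
 *  4-7   CYP3A4 K_M
 *  8-10  UGT1A3 rmax, K_M, K_I
 *  11-13 k_CR, k_PON_ASL, k_PON_ASLOH
 *  14-16 k_dis, fu_acid, fu_lactone
 *  17-18 beta-ox k_AS, k_ASOH
 *  19-20 V_m, V_c
 *  21    full-variant flag (0 = reduced, 1 = full/hybrid)
 *  22-27 rmax_1B1, K_M_1B1, rmax_2B1, K_M_2B1, rmax_ex, K_M_ex (AS transport)
 *  28-32 k_im for ASL, ASpOH, ASoOH, ASLpOH, ASLoOH
 *  33-37 k_ex for the same compounds
 *  38-43 P per compound
 *  44-49 lumped_im flags, 50-55 lumped_ex flags
 *  56-61 kappa_im (ml/min), 62-67 kappa_ex (ml/min)
 */
#include <R.h>
#include <math.h>
#include <R_ext/Rdynload.h>

#define NPAR 68
static double p[NPAR];

void atorkin_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

/* compound indices */
#define AS 0
#define ASL 1
#define ASpOH 2
#define ASoOH 3
#define ASLpOH 4
#define ASLoOH 5

void atorkin_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double cm[6], cc[6], cb[6];
    int j;
    for (j = 0; j < 6; j++) {
        cm[j] = fmax(y[3 * j], 0.0);
        cc[j] = fmax(y[3 * j + 1], 0.0);
        cb[j] = fmax(y[3 * j + 2], 0.0);
    }

    /* CYP3A4: shared competitive denominator over the four channels */
    double den = 1.0 + cc[AS] / p[4] + cc[AS] / p[5] +
                 cc[ASL] / p[6] + cc[ASL] / p[7];
    double r_cyp[4];
    r_cyp[0] = p[0] * (cc[AS] / p[4]) / den;
    r_cyp[1] = p[1] * (cc[AS] / p[5]) / den;
    r_cyp[2] = p[2] * (cc[ASL] / p[6]) / den;
    r_cyp[3] = p[3] * (cc[ASL] / p[7]) / den;

    /* UGT1A3 substrate inhibition */
    double r_ugt = p[8] * cc[AS] / (p[9] + cc[AS] + cc[AS] * cc[AS] / p[10]);

    double k_cr = p[11];
    double r_pon[6] = {0, 0, 0, 0, 0, 0};
    r_pon[ASL] = p[12] * cc[ASL];
    r_pon[ASLpOH] = p[13] * cc[ASLpOH];
    r_pon[ASLoOH] = p[13] * cc[ASLoOH];

    /* net binding free -> bound */
    double r_bind[6];
    for (j = 0; j < 6; j++) {
        double fu = (j == AS || j == ASpOH || j == ASoOH) ? p[15] : p[16];
        r_bind[j] = p[14] * (((1.0 - fu) / fu) * cc[j] - cb[j]);
    }

    /* transport amount flux, medium -> cell (pmol/min) */
    double flux[6];
    int full = p[21] > 0.5;
    for (j = 0; j < 6; j++) {
        double imp, ex;
        int lim = full ? (p[44 + j] > 0.5) : 1;
        int lex = full ? (p[50 + j] > 0.5) : 1;
        if (lim) {
            imp = p[56 + j] * cm[j];
        } else if (j == AS) {
            imp = p[22] * cm[j] / (p[23] + cm[j]) +
                  p[24] * cm[j] / (p[25] + cm[j]) + p[38 + j] * cm[j];
        } else {
            imp = p[28 + j - 1] * cm[j] + p[38 + j] * cm[j];
        }
        if (lex) {
            ex = p[62 + j] * cc[j];
        } else if (j == AS) {
            ex = p[26] * cc[j] / (p[27] + cc[j]) + p[38 + j] * cc[j];
        } else {
            ex = p[33 + j - 1] * cc[j] + p[38 + j] * cc[j];
        }
        flux[j] = imp - ex;
    }

    /* intracellular reaction stoichiometry (pmol/min/ml intracellular) */
    double rx[6];
    rx[AS] = -r_cyp[0] - r_cyp[1] - r_ugt + k_cr * cc[ASL] + r_pon[ASL];
    rx[ASL] = r_ugt - r_cyp[2] - r_cyp[3] - k_cr * cc[ASL] - r_pon[ASL];
    rx[ASpOH] = r_cyp[0] + k_cr * cc[ASLpOH] + r_pon[ASLpOH];
    rx[ASoOH] = r_cyp[1] + k_cr * cc[ASLoOH] + r_pon[ASLoOH];
    rx[ASLpOH] = r_cyp[2] - k_cr * cc[ASLpOH] - r_pon[ASLpOH];
    rx[ASLoOH] = r_cyp[3] - k_cr * cc[ASLoOH] - r_pon[ASLoOH];

    double sink[6] = {0, 0, 0, 0, 0, 0};
    sink[AS] = p[17] * cc[AS];
    sink[ASpOH] = p[18] * cc[ASpOH];
    sink[ASoOH] = p[18] * cc[ASoOH];

    for (j = 0; j < 6; j++) {
        double dcm = -flux[j] / p[19];
        if (j == ASL || j == ASLpOH || j == ASLoOH)
            dcm -= k_cr * cm[j];
        if (j == AS)
            dcm += k_cr * cm[ASL];
        if (j == ASpOH)
            dcm += k_cr * cm[ASLpOH];
        if (j == ASoOH)
            dcm += k_cr * cm[ASLoOH];
        ydot[3 * j] = dcm;
        ydot[3 * j + 1] = flux[j] / p[20] + rx[j] - r_bind[j] - sink[j];
        ydot[3 * j + 2] = r_bind[j];
    }
}
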