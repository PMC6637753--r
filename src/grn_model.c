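/* Compiled right-hand side of the coupled Let-7 / cell-cycle /
 * transformation ODE system, for use with deSolve's compiled-code
 * interface.  Mirrors the reference implementation in R/model.R
 * (grn_rhs); the two are tested to agree to machine precision.
 *
 * Parameter macros are generated from the canonical order of
 * default_parameters(); integrate_model() always passes parameters in
 * that order.
 */
#include <R.h>
#include <math.h>

#define N_PARMS 99
static double parms[N_PARMS];

#define GF parms[0]
#define Src parms[1]
#define V_SMCYC parms[2]
#define V_SMD parms[3]
#define e_MD parms[4]
#define K_AGF parms[5]
#define kd_MD parms[6]
#define V_SME parms[7]
#define e_ME parms[8]
#define V_SMA parms[9]
#define e_MA parms[10]
#define K_AE2F parms[11]
#define kd_ME parms[12]
#define kd_MA parms[13]
#define V_SMB parms[14]
#define kd_MB parms[15]
#define kA_MD parms[16]
#define kA_ME parms[17]
#define kA_MA parms[18]
#define kA_MB parms[19]
#define kD_MD parms[20]
#define kD_ME parms[21]
#define kD_MA parms[22]
#define kD_MB parms[23]
#define kdCL_MD parms[24]
#define kdCL_ME parms[25]
#define kdCL_MA parms[26]
#define kdCL_MB parms[27]
#define kT_CD parms[28]
#define kT_CE parms[29]
#define kT_CA parms[30]
#define kT_CB parms[31]
#define kd_CD parms[32]
#define kd_CE parms[33]
#define kd_CA parms[34]
#define kd_CB parms[35]
#define K_ACB parms[36]
#define kdAPC_CA parms[37]
#define kdAPC_CB parms[38]
#define V_SE2F parms[39]
#define kd_E2F parms[40]
#define V_AE2F parms[41]
#define K_AE2FC parms[42]
#define K_AE2FP parms[43]
#define V_I0E2F parms[44]
#define V_IE2F parms[45]
#define K_IE2F parms[46]
#define V_AAPC parms[47]
#define K_AAPC parms[48]
#define V_IAPC parms[49]
#define K_IAPC parms[50]
#define V_SLET7 parms[51]
#define kd_LET7 parms[52]
#define kdL7_LIN28 parms[53]
#define k_AA1NFKB parms[54]
#define k_AA2NFKB parms[55]
#define k_AA3NFKB parms[56]
#define n_STAT3 parms[57]
#define K_S3NFKB parms[58]
#define K_ANFKB parms[59]
#define V_INFKB parms[60]
#define k_PTENNFKB parms[61]
#define K_INFKB parms[62]
#define V_SLIN28 parms[63]
#define K_ALIN28 parms[64]
#define n_LIN28 parms[65]
#define kd_MLIN28 parms[66]
#define kT_LIN28 parms[67]
#define kd_LIN28 parms[68]
#define V_S0MIL6 parms[69]
#define V_SMIL6 parms[70]
#define K_AMIL6 parms[71]
#define kd_MIL6 parms[72]
#define kA_MIL6 parms[73]
#define kD_MIL6 parms[74]
#define kdCL_MIL6 parms[75]
#define kT_IL6 parms[76]
#define kd_IL6 parms[77]
#define V_A1STAT3 parms[78]
#define V_A2STAT3 parms[79]
#define K_ASTAT3 parms[80]
#define V_ISTAT3 parms[81]
#define K_ISTAT3 parms[82]
#define V_SMIR21 parms[83]
#define K_AMIR21 parms[84]
#define kd_MIR21 parms[85]
#define V_SMPTEN parms[86]
#define kd_MPTEN parms[87]
#define kT_PTEN parms[88]
#define K_MIR21PTEN parms[89]
#define kd_PTEN parms[90]
#define V_SMRAS parms[91]
#define kd_MRAS parms[92]
#define kA_MRAS parms[93]
#define kD_MRAS parms[94]
#define kdCL_MRAS parms[95]
#define kT_RAS parms[96]
#define kd_RAS parms[97]
#define k_GFRAS parms[98]

void grn_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

/* state layout:
 *  y[0]  Md    y[1]  Me     y[2]  Ma     y[3]  Mb
 *  y[4]  CLd   y[5]  CLe    y[6]  CLa    y[7]  CLb
 *  y[8]  Cd    y[9]  Ce     y[10] Ca     y[11] Cb
 *  y[12] E2F   y[13] E2Ftot y[14] APC
 *  y[15] Let7  y[16] NFKB   y[17] MLin28 y[18] Lin28
 *  y[19] MIL6  y[20] CL_IL6 y[21] IL6    y[22] STAT3
 *  y[23] miR21 y[24] MPTEN  y[25] PTEN
 *  y[26] MRas  y[27] CL_Ras y[28] Ras
 */
void grn_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double Md = y[0], Me = y[1], Ma = y[2], Mb = y[3];
    const double CLd = y[4], CLe = y[5], CLa = y[6], CLb = y[7];
    const double Cd = y[8], Ce = y[9], Ca = y[10], Cb = y[11];
    const double E2F = y[12], E2Ftot = y[13], APC = y[14];
    const double Let7 = y[15], NFKB = y[16], MLin28 = y[17], Lin28 = y[18];
    const double MIL6 = y[19], CL_IL6 = y[20], IL6 = y[21], STAT3 = y[22];
    const double miR21 = y[23], MPTEN = y[24], PTEN = y[25];
    const double MRas = y[26], CL_Ras = y[27], Ras = y[28];

    const double s_GF  = GF / (K_AGF + GF);
    const double s_E2F = E2F / (K_AE2F + E2F);

    const double bind_d  = kA_MD * Let7 * Md,     unb_d  = kD_MD * CLd;
    const double bind_e  = kA_ME * Let7 * Me,     unb_e  = kD_ME * CLe;
    const double bind_a  = kA_MA * Let7 * Ma,     unb_a  = kD_MA * CLa;
    const double bind_b  = kA_MB * Let7 * Mb,     unb_b  = kD_MB * CLb;
    const double bind_i6 = kA_MIL6 * Let7 * MIL6, unb_i6 = kD_MIL6 * CL_IL6;
    const double bind_rs = kA_MRAS * Let7 * MRas, unb_rs = kD_MRAS * CL_Ras;

    /* cyclin mRNAs */
    ydot[0] = V_SMCYC * V_SMD * (e_MD + s_GF) - kd_MD * Md - bind_d + unb_d;
    ydot[1] = V_SMCYC * V_SME * (e_ME + s_E2F) - kd_ME * Me - bind_e + unb_e;
    ydot[2] = V_SMCYC * V_SMA * (e_MA + s_E2F) - kd_MA * Ma - bind_a + unb_a;
    ydot[3] = V_SMCYC * V_SMB - kd_MB * Mb - bind_b + unb_b;

    /* Let-7 . cyclin mRNA complexes */
    ydot[4] = bind_d - unb_d - kdCL_MD * CLd;
    ydot[5] = bind_e - unb_e - kdCL_ME * CLe;
    ydot[6] = bind_a - unb_a - kdCL_MA * CLa;
    ydot[7] = bind_b - unb_b - kdCL_MB * CLb;

    /* cyclin/Cdk complexes */
    ydot[8]  = kT_CD * Md - kd_CD * Cd;
    ydot[9]  = kT_CE * Me - kd_CE * Ce;
    ydot[10] = kT_CA * Ma - kd_CA * Ca - kdAPC_CA * APC * Ca;
    ydot[11] = kT_CB * Mb * Ca / (K_ACB + Ca) - kd_CB * Cb
               - kdAPC_CB * APC * Cb;

    /* E2F */
    {
        double e2f_in = E2Ftot - E2F;
        if (e2f_in < 0.0) e2f_in = 0.0;
        ydot[13] = V_SE2F - kd_E2F * E2Ftot;
        ydot[12] = V_AE2F * ((Cd + Ce) / (K_AE2FC + Cd + Ce))
                   * e2f_in / (K_AE2FP + e2f_in)
                   - (V_I0E2F + V_IE2F * Ca) * E2F / (K_IE2F + E2F)
                   - kd_E2F * E2F;
    }

    /* APC */
    {
        double apc_in = 1.0 - APC;
        if (apc_in < 0.0) apc_in = 0.0;
        ydot[14] = V_AAPC * Cb * apc_in / (K_AAPC + apc_in)
                   - V_IAPC * APC / (K_IAPC + APC);
    }

    /* Let-7 */
    ydot[15] = V_SLET7 - (kd_LET7 + kdL7_LIN28 * Lin28) * Let7
               - (bind_d + bind_e + bind_a + bind_b + bind_i6 + bind_rs)
               + (unb_d + unb_e + unb_a + unb_b + unb_i6 + unb_rs);

    /* NF-kB */
    {
        double s3h = pow(STAT3, n_STAT3)
                     / (pow(K_S3NFKB, n_STAT3) + pow(STAT3, n_STAT3));
        double nfkb_in = 1.0 - NFKB;
        if (nfkb_in < 0.0) nfkb_in = 0.0;
        ydot[16] = (k_AA1NFKB * Src + k_AA2NFKB * s3h + k_AA3NFKB * Ras)
                   * nfkb_in / (K_ANFKB + nfkb_in)
                   - V_INFKB * (1.0 + k_PTENNFKB * PTEN) * NFKB
                     / (K_INFKB + NFKB);
    }

    /* Lin28 */
    ydot[17] = V_SLIN28 * pow(NFKB, n_LIN28)
               / (pow(K_ALIN28, n_LIN28) + pow(NFKB, n_LIN28))
               - kd_MLIN28 * MLin28;
    ydot[18] = kT_LIN28 * MLin28 - kd_LIN28 * Lin28;

    /* IL6 */
    ydot[19] = V_S0MIL6 + V_SMIL6 * NFKB / (K_AMIL6 + NFKB)
               - kd_MIL6 * MIL6 - bind_i6 + unb_i6;
    ydot[20] = bind_i6 - unb_i6 - kdCL_MIL6 * CL_IL6;
    ydot[21] = kT_IL6 * MIL6 - kd_IL6 * IL6;

    /* STAT3 */
    {
        double s3_in = 1.0 - STAT3;
        if (s3_in < 0.0) s3_in = 0.0;
        ydot[22] = (V_A1STAT3 * IL6 + V_A2STAT3 * NFKB)
                   * s3_in / (K_ASTAT3 + s3_in)
                   - V_ISTAT3 * STAT3 / (K_ISTAT3 + STAT3);
    }

    /* miR-21 */
    ydot[23] = V_SMIR21 * STAT3 / (K_AMIR21 + STAT3) - kd_MIR21 * miR21;

    /* PTEN */
    ydot[24] = V_SMPTEN - kd_MPTEN * MPTEN;
    ydot[25] = kT_PTEN * MPTEN * K_MIR21PTEN / (K_MIR21PTEN + miR21)
               - kd_PTEN * PTEN;

    /* Ras */
    ydot[26] = V_SMRAS - kd_MRAS * MRas - bind_rs + unb_rs;
    ydot[27] = bind_rs - unb_rs - kdCL_MRAS * CL_Ras;
    ydot[28] = (kT_RAS + k_GFRAS * GF) * MRas - kd_RAS * Ras;
}
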