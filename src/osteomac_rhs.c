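/* Compiled right-hand side of the coupled bone-injury model, in the deSolve
 * compiled-model convention. Parameter vector layout (30 doubles): the three
 * hypothesis indices a, b, c followed by the 27 rate parameters in the
 * package's canonical order (see parameterNames() on the R side). State
 * order: Mo, M, M1, M2, Mo1, OB, OC, B, D.
 */
#include <R.h>
#include <R_ext/Rdynload.h>

#define N_PARMS 30
static double parms[N_PARMS];

/* indices into parms */
#define HYP_A      parms[0]
#define HYP_B      parms[1]
#define HYP_C      parms[2]
#define DELTA_MO   parms[3]
#define DELTA_M    parms[4]
#define DELTA_OB   parms[5]
#define DELTA_OC   parms[6]
#define GAMMA_OB   parms[7]
#define DELTA_B    parms[8]
#define PI_B       parms[9]
#define ALPHA      parms[10]
#define BETA       parms[11]
#define H_MO       parms[12]
#define H_M        parms[13]
#define H_OB       parms[14]
#define D_OC       parms[15]
#define D_OC2      parms[16]
#define INHIB_OC   parms[17]
#define INHIB_OC2  parms[18]
#define DELTA_D    parms[19]
#define I_1        parms[20]
#define I_2        parms[21]
#define P_31       parms[22]
#define P_32       parms[23]
#define P_11       parms[24]
#define P_12       parms[25]
#define P_2        parms[26]
#define DEPOL_1    parms[27]
#define DEPOL_2    parms[28]
#define DEPOL_3    parms[29]

void osteomac_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void osteomac_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const double Mo = y[0], M = y[1], M1 = y[2], M2 = y[3], Mo1 = y[4];
    const double OB = y[5], OC = y[6], B = y[7], D = y[8];
    const double P = M1 + Mo1;
    const int a = (int) HYP_A, b = (int) HYP_B, c = (int) HYP_C;

    double p1, p21, p22, p3, depol1, depol21, depol22, depol3;
    double dOCr, deltaOCr, gammaOBr;

    if (c == 1) {
        p1 = P_11 * D + P_12 * D * P;
        depol1 = DEPOL_1 * M2;
        p21 = 0.0;
        p22 = P_2 * D;
        depol21 = DEPOL_2;
        depol22 = 0.0;
        p3 = P_31 * D + P_32 * D * P;
        depol3 = DEPOL_3 * M2;
    } else if (c == 2) {
        p1 = P_11 * D + P_12 * D * P;
        depol1 = DEPOL_1 * M2;
        p21 = P_2 * P;
        p22 = 0.0;
        depol21 = DEPOL_2;
        depol22 = 0.0;
        p3 = P_31 * D + P_32 * D * P;
        depol3 = DEPOL_3 * M2;
    } else {
        p1 = P_11 * D;
        depol1 = 0.0;
        p21 = 0.0;
        p22 = P_2 * D;
        depol21 = 0.0;
        depol22 = DEPOL_2;
        p3 = P_32 * M1;
        depol3 = DEPOL_3;
    }

    if (a == 1) {
        dOCr = (D_OC + D_OC2 * P) / (1.0 + INHIB_OC * M2);
        deltaOCr = DELTA_OC * (1.0 + INHIB_OC2 * M2);
    } else if (a == 2) {
        dOCr = (D_OC + D_OC2 * P) / (1.0 + INHIB_OC * OB);
        deltaOCr = DELTA_OC * (1.0 + INHIB_OC2 * OB);
    } else {
        dOCr = D_OC * OB / (1.0 + INHIB_OC * M2);
        deltaOCr = DELTA_OC * (1.0 + INHIB_OC2 * M2);
    }

    gammaOBr = (b == 1) ? GAMMA_OB * M2 : GAMMA_OB * D;

    ydot[0] = H_MO - DELTA_MO * Mo + I_1 * P + I_2 * D - p3 * Mo
        + depol3 * Mo1;
    ydot[1] = H_M - DELTA_M * M - dOCr * M - p1 * M - p21 * M
        + depol1 * M1 + depol21 * M2;
    ydot[2] = p1 * M - depol1 * M1 - p22 * M1 + depol22 * M2 - DELTA_M * M1;
    ydot[3] = p21 * M + p22 * M1 - depol21 * M2 - depol22 * M2
        - DELTA_M * M2;
    ydot[4] = p3 * Mo - depol3 * Mo1 - DELTA_MO * Mo1;
    ydot[5] = H_OB * OC + gammaOBr - DELTA_OB * OB * B;
    ydot[6] = dOCr * M - deltaOCr * OC;
    ydot[7] = PI_B * (1.0 + BETA * M2) * OB
        - DELTA_B * (1.0 + ALPHA * P) * OC * B;
    ydot[8] = -DELTA_D * P * D;
}

static const R_CMethodDef cMethods[] = {
    {"osteomac_derivs", (DL_FUNC) &osteomac_derivs, 6},
    {"osteomac_initmod", (DL_FUNC) &osteomac_initmod, 1},
    {NULL, NULL, 0}
};

void R_init_osteomac(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
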