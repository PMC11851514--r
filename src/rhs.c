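/* Compiled right-hand sides of the staged post-MI remodeling model,
 * in the deSolve compiled-model convention (initmod + derivs).
 *
 * Parameter vector layout (65 doubles) mirrors R/parameters.R
 * (.param_names) plus one trailing flag; state layout mirrors
 * R/state.R (.state_names).  Both orderings are load-bearing.
 */
#include <R.h>

#define NPAR 65
static double p[NPAR];

void postmi_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

/* parameters */
#define K(i)      p[(i) - 1]        /* k1..k22 -> p[0..21] */
#define C1        p[22]
#define C2        p[23]
#define C3        p[24]
#define C_IL10_C  p[25]
#define C_IL1_C   p[26]
#define C_IL10_F  p[27]
#define C_IL17_MC p[28]
#define C_IL1_M0  p[29]
#define C_IL10_M0 p[30]
#define C_IL17_M0 p[31]
#define C_IL17    p[32]
#define D_IL1     p[33]
#define D_IL10    p[34]
#define D_IL17    p[35]
#define D_R       p[36]
#define Y_MC      p[37]
#define Y_F       p[38]
#define M_MC      p[39]
#define M_F       p[40]
#define MU_MC     p[41]
#define MU_M      p[42]
#define MU_N      p[43]
#define MU_S      p[44]
#define MU_T      p[45]
#define MUR(j)    p[46 + (j)]       /* Mc,N,M0,M1,M2,S,T -> j = 0..6 */
#define CR(j)     p[53 + (j)]
#define OMEGA     p[60]
#define GAMMA     p[61]
#define DELTA     p[62]
#define RC        p[63]
#define ROS_STAGE1 p[64]            /* 1: integrate ROS during ischemia */

/* state indices */
#define I_MC 0
#define I_MD 1
#define I_IL1 2
#define I_IL10 3
#define I_IL17 4
#define I_N 5
#define I_M0 6
#define I_M1 7
#define I_M2 8
#define I_C 9
#define I_F 10
#define I_S 11
#define I_T 12
#define I_R 13

static double sat(double x, double c)
{
    return x / (x + c);
}

static void rhs(int stage, double *y, double *dy)
{
    double Mc = y[I_MC], Md = y[I_MD], IL1 = y[I_IL1], IL10 = y[I_IL10],
           IL17 = y[I_IL17], N = y[I_N], M0 = y[I_M0], M1 = y[I_M1],
           M2 = y[I_M2], Cc = y[I_C], F = y[I_F], S = y[I_S], T = y[I_T],
           R = y[I_R];

    double fIL17Mc = sat(IL17, C_IL17_MC);
    double fIL1M0 = sat(IL1, C_IL1_M0);
    double fIL10M0 = sat(IL10, C_IL10_M0);
    double fIL17M0 = sat(IL17, C_IL17_M0);

    /* shared cytokine balances (identical in both stages) */
    dy[I_IL1] = K(3) * Md + K(4) * M1 * C1 / (C1 + IL10) - D_IL1 * IL1;
    dy[I_IL10] = K(21) * T * C3 / (C3 + IL10)
               + K(5) * M2 * C2 / (C2 + IL10) - D_IL10 * IL10;
    dy[I_IL17] = K(22) * T * C3 / (C3 + IL10) - D_IL17 * IL17;
    dy[I_C] = K(10) * F * sat(IL10, C_IL10_C)
            - K(11) * Cc * sat(IL1, C_IL1_C);

    if (stage == 1) {
        dy[I_MC] = -K(15) * Mc * fIL17Mc - K(16) * N * Mc - MU_MC * Mc;
        dy[I_MD] = K(15) * Mc * fIL17Mc + MU_MC * Mc - K(2) * M1 * Md
                 - K(17) * N * Md;
        dy[I_N] = K(18) * Md + K(19) * sat(IL17, C_IL17) - MU_N * N;
        dy[I_M0] = K(6) * Md - K(7) * M0 * fIL1M0 - K(8) * M0 * fIL10M0
                 - K(20) * M0 * fIL17M0 - MU_M * M0;
        dy[I_M1] = K(7) * M0 * fIL1M0 + K(20) * M0 * fIL17M0
                 - K(9) * M1 - MU_M * M1;
        dy[I_M2] = K(8) * M0 * fIL10M0 + K(9) * M1 - MU_M * M2;
        dy[I_F] = K(12) * F * sat(IL10, C_IL10_F);
        dy[I_S] = -MU_S * S;
        dy[I_T] = K(13) * Md - MU_T * T;
        /* ROS balance carried through ischemia with the oxygenation
         * multiplier pinned at 1 (no treatment yet); optionally frozen */
        dy[I_R] = (ROS_STAGE1 != 0.0) ? K(1) * N - D_R * R : 0.0;
    } else {
        /* thresholded reperfusion damage: inactive below Rc */
        double g = (R < RC) ? 0.0 : GAMMA * R;
        double rdMc = g * MUR(0) / (R + CR(0));
        double rdN  = g * MUR(1) / (R + CR(1));
        double rdM0 = g * MUR(2) / (R + CR(2));
        double rdM1 = g * MUR(3) / (R + CR(3));
        double rdM2 = g * MUR(4) / (R + CR(4));
        double rdS  = g * MUR(5) / (R + CR(5));
        double rdT  = g * MUR(6) / (R + CR(6));
        double regenMc = Y_MC * S * sat(IL10, M_MC);
        double regenF = Y_F * S * sat(IL10, M_F);

        dy[I_MC] = regenMc - K(15) * Mc * fIL17Mc - K(16) * N * Mc
                 - rdMc * Mc;
        dy[I_MD] = K(15) * Mc * fIL17Mc + rdMc * Mc - K(2) * M1 * Md
                 - K(17) * N * Md;
        dy[I_N] = DELTA * K(18) * Md + K(19) * sat(IL17, C_IL17)
                - MU_N * N - rdN * N;
        dy[I_M0] = K(6) * Md - K(7) * M0 * fIL1M0 - K(8) * M0 * fIL10M0
                 - K(20) * M0 * fIL17M0 - MU_M * M0 - rdM0 * M0;
        dy[I_M1] = K(7) * M0 * fIL1M0 + K(20) * M0 * fIL17M0
                 - K(9) * M1 - MU_M * M1 - rdM1 * M1;
        dy[I_M2] = K(8) * M0 * fIL10M0 + K(9) * M1 - MU_M * M2 - rdM2 * M2;
        dy[I_F] = regenF + K(12) * F * sat(IL10, C_IL10_F);
        dy[I_S] = -regenMc - regenF - K(14) * M1 * S - MU_S * S - rdS * S;
        dy[I_T] = K(13) * Md - MU_T * T - rdT * T;
        dy[I_R] = OMEGA * K(1) * N - D_R * R;
    }
}

void postmi_derivs1(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    rhs(1, y, ydot);
}

void postmi_derivs2(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    rhs(2, y, ydot);
}
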