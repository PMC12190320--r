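/* Compiled right-hand side of the glucose-insulin-beta-cell progression
 * model family, for use with deSolve (lsoda).  Mirrors model_rhs() in R;
 * the test suite asserts the two agree to machine precision.
 *
 * Parameter vector layout must match .parm_names in R/params.R.
 */

#include <stddef.h>
#include <math.h>
#include <R_ext/Rdynload.h>

#define NPARMS 74

static double p[NPARMS];

/* named accessors into the packed parameter vector */
#define GIN      p[0]
#define SG       p[1]
#define SI_BASE  p[2]
#define C_DECAY  p[3]
#define ALPHA    p[4]
#define B0       p[5]
#define GB1      p[6]
#define GB2      p[7]
#define KCLR     p[8]
#define TAU_BETA p[9]
#define SIG_CST  p[10]
#define GX1      p[11]
#define GX2      p[12]
#define GX3      p[13]
#define GA0      p[14]
#define GA1      p[15]
#define GA2      p[16]
#define GA3      p[17]
#define GI1      p[18]
#define GI2      p[19]
#define I_0      p[20]
#define HEPA_B   p[21]
#define HEPA_MAX p[22]
#define HK0      p[23]
#define HEPASX   p[24]
#define IIR_MIN  p[25]
#define IIR_K    p[26]
#define IIR_H    p[27]
#define MEAL     p[28]
#define K1       p[29]
#define K2       p[30]
#define CA_B     p[31]
#define CA1      p[32]
#define CA2      p[33]
#define CA3      p[34]
#define MT       p[35]
#define MZ       p[36]
#define S0       p[37]
#define S1       p[38]
#define S2       p[39]
#define S3       p[40]
#define S4       p[41]
#define S5       p[42]
#define S6       p[43]
#define S7       p[44]
#define S8       p[45]
#define SGAM     p[46]
#define S10      p[47]
#define S11      p[48]
#define S12      p[49]
#define TAU_SIG  p[50]
#define ENH3     p[51]
#define ENH4     p[52]
#define BB1      p[53]
#define BB2      p[54]
#define BB3      p[55]
#define BB4      p[56]
#define BB5      p[57]
#define GG1      p[58]
#define BMAX     p[59]
#define AGE0     p[60]
#define F_SI     p[61]
#define F_TOPP   p[62]
#define F_HGP    p[63]
#define F_CLEAR  p[64]
#define F_SIGDYN p[65]
#define F_ENH    p[66]
#define F_LMASS  p[67]
#define F_LIPO   p[68]
#define FORCE_MODE p[69]
#define FORCE_DROP p[70]
#define FORCE_T0   p[71]
#define FORCE_T1   p[72]
#define FORCE_TAU  p[73]

static double forc[1];          /* forc[0]: PFAT(t), interpolated by deSolve */

void dmprog_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, p);
}

void dmprog_initforc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forc);
}

static double clampd(double x, double lo, double hi)
{
    return x < lo ? lo : (x > hi ? hi : x);
}

void dmprog_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double G = y[0] > 0 ? y[0] : 0;
    double I = y[1] > 0 ? y[1] : 0;
    double beta = y[2] > 0 ? y[2] : 0;
    double tt = *t;

    double X = clampd((forc[0] - 7.0) / 45.0, 0.0, 1.1);

    /* insulin sensitivity with optional attenuation factors and forcing */
    double si = SI_BASE * exp(-C_DECAY * tt);
    int simode = (int) F_SI;
    if (simode >= 1)
        si *= 1.0 - GX1 / (1.0 + exp(-GX2 * (X - GX3)));
    if (simode >= 2)
        si *= 1.0 - GA1 / (1.0 + exp(-(AGE0 / GA0 + tt / GA2 - GA3)));
    if (simode >= 3) {
        double d = I - I_0;
        si *= 1.0 - GI1 * d * d / (d * d + GI2 * GI2);
    }
    int fmode = (int) FORCE_MODE;
    if (fmode == 1) {
        if (tt >= FORCE_T0 && tt <= FORCE_T1) si *= 1.0 - FORCE_DROP;
    } else if (fmode == 2) {
        si *= 1.0 - FORCE_DROP * (1.0 - exp(-tt / FORCE_TAU));
    }

    /* glucose influx */
    double influx;
    if (F_HGP > 0.5) {
        double x4 = X * X * X * X;
        double km = HK0 * (1.0 - HEPASX * x4 / (x4 + 0.0625));
        double iir = IIR_MIN + (1.0 - IIR_MIN) / (1.0 + pow(I / IIR_K, IIR_H));
        influx = MEAL + HEPA_B + HEPA_MAX / (km + iir * I);
    } else {
        influx = GIN;
    }
    ydot[0] = influx - SG * G - si * I * G;

    /* insulin: secretion minus clearance */
    double sigma, drive, Ca = 0.0;
    if (F_SIGDYN > 0.5) {
        sigma = y[3] > 0 ? y[3] : 0;
        double gm = pow(G, MT);
        Ca = CA_B + CA1 * gm / (gm + pow(CA2, MT));
        double cz = pow(Ca - CA_B, MZ);
        drive = cz / (cz + pow(CA3, MZ));
    } else {
        sigma = SIG_CST;
        drive = G * G / (G * G + ALPHA * ALPHA);
    }
    double clr = (F_CLEAR > 0.5) ? K1 / (K2 + I) : KCLR;
    ydot[1] = sigma * drive * beta - clr * I;

    /* beta-cell mass */
    double fb;
    if (F_TOPP > 0.5) {
        fb = B0 * (G - GB1) * (GB2 - G);
        ydot[2] = fb * beta / TAU_BETA;
    } else {
        double u = (G - GG1) / BB2;
        fb = BB1 / (u * u * u * u + 1.0) - BB3;
        if (F_LMASS > 0.5) {
            double x6 = pow(X, 6.0);
            fb -= BB4 * x6 / (x6 + pow(BB5, 6.0));
        }
        ydot[2] = fb * beta * (1.0 - beta / BMAX) / TAU_BETA;
    }

    /* secretory capacity relaxation */
    if (F_SIGDYN > 0.5) {
        double s3 = S3 * (F_ENH > 0.5 ? ENH3 : 1.0);
        double s4 = S4 * (F_ENH > 0.5 ? ENH4 : 1.0);
        double f_gd = S2 / (1.0 + exp(-s3 * (G - s4)));
        double ca6 = pow(Ca, 6.0);
        double sCa = S7 - S8 * ca6 / (ca6 + pow(SGAM, 6.0));
        double f_bd = 1.0 - 1.0 / (1.0 + S5 * exp(-S6 * (G - sCa)));
        double f_glu = f_gd * f_bd + S1;
        double f2 = 1.0;
        int lip = (int) F_LIPO;
        if (lip == 1) {
            double x6 = pow(X, 6.0);
            f2 = 1.0 - S10 * x6 / (x6 + pow(S11, 6.0));
        } else if (lip == 2) {
            double x8 = pow(X, 8.0), x9 = pow(X, 9.0);
            f2 = 1.0 + x8 / (x8 + pow(S10, 8.0))
                     - S11 * x9 / (x9 + pow(S12, 9.0));
        }
        double s_inf = S0 * f_glu * f2;
        if (s_inf < 0) s_inf = 0;
        ydot[3] = (s_inf - sigma) / TAU_SIG;
    }
}

static const R_CMethodDef CEntries[] = {
    {NULL, NULL, 0}
};

void R_init_dmprog(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);  /* deSolve looks up symbols by name */
}
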