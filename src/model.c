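/* Right-hand side of the motoneuron model, compiled for deSolve.
 *
 * State vector (order fixed across the package):
 *   y[0] V     membrane potential (mV)
 *   y[1] mNaT  transient-Na activation
 *   y[2] hNaT  transient-Na inactivation
 *   y[3] mNaP  persistent-Na activation
 *   y[4] mKf   fast-K activation
 *   y[5] hKf1  fast-K inactivation, component 1 (weight 0.95)
 *   y[6] hKf2  fast-K inactivation, component 2 (weight 0.05, tau 116 ms)
 *   y[7] nKs   slow-K activation
 *   y[8] Na    intracellular sodium in the sub-membrane shell (mM)
 *
 * Units: mV, ms, nS, pA, pF, mM, pL.  nS*mV = pA and pA/pF = mV/ms, so the
 * voltage equation needs no conversion; the sodium balance uses the single
 * constant kNa = 1/(F*Vol) in mM / (pA ms).
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPARMS 24

/* parameter slots (kept in step with .model_parms_vector in R/dynamics.R) */
#define P_CM        0
#define P_GNAT      1
#define P_GNAP      2
#define P_GNALEAK   3
#define P_GKF       4
#define P_GKS       5
#define P_GKLEAK    6
#define P_EK        7
#define P_IPUMPMAX  8
#define P_NAH       9
#define P_NAS      10
#define P_NAOUT    11
#define P_RTF      12
#define P_ENAREST  13
#define P_KNA      14
#define P_NADYN    15
#define P_ENADYN   16
#define P_STYPE    17
#define P_SP1      18
#define P_SP2      19
#define P_SP3      20
#define P_SP4      21
#define P_ST0      22
#define P_ST1      23

static double parms[NPARMS];

void pumpneuron_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

static double boltz(double V, double half, double slope)
{
    return 1.0 / (1.0 + exp((V + half) / slope));
}

/* injected current for the active stimulus segment; half-open window
 * [st0, st1): the sample at the offset itself carries 0 pA */
static double stim_current(double t, const double *p)
{
    int type = (int) p[P_STYPE];
    double t0 = p[P_ST0], t1 = p[P_ST1];

    if (t < t0 || t >= t1)
        return 0.0;

    switch (type) {
    case 0: /* constant */
        return p[P_SP1];
    case 1: /* linear ramp piece: I = p1 + p2*(t - t0), slope in pA/ms */
        return p[P_SP1] + p[P_SP2] * (t - t0);
    case 2: { /* zap chirp: p1 Izapmax (pA), p2 f0 (Hz), p3 lambda (1/s),
               * p4 tau_half (s); deceleration = time mirror of acceleration */
        double tl = (t - t0) / 1000.0; /* s since zap onset */
        double th = p[P_SP4];
        double ta = (tl <= th) ? tl : 2.0 * th - tl;
        double phase;
        if (ta < 0.0)
            return 0.0;
        phase = 2.0 * M_PI * p[P_SP2] / p[P_SP3] * expm1(p[P_SP3] * ta);
        return p[P_SP1] * (0.5 + 0.5 * cos(phase + M_PI));
    }
    default:
        return 0.0;
    }
}

/* dy and (if out != NULL) out = {ENa, Ipump, Iinj} */
static void derivs_core(double t, const double *y, double *dy, double *out,
                        const double *p)
{
    const double V = y[0], mNaT = y[1], hNaT = y[2], mNaP = y[3];
    const double mKf = y[4], hKf1 = y[5], hKf2 = y[6], nKs = y[7];
    const double Na = y[8];

    const double ENa = (p[P_ENADYN] != 0.0)
        ? p[P_RTF] * log(p[P_NAOUT] / Na)
        : p[P_ENAREST];

    const double INaT = p[P_GNAT] * mNaT * mNaT * mNaT * hNaT * (V - ENa);
    const double INaP = p[P_GNAP] * mNaP * (V - ENa);
    const double INaleak = p[P_GNALEAK] * (V - ENa);
    const double hKf = 0.95 * hKf1 + 0.05 * hKf2;
    const double IKf = p[P_GKF] * mKf * mKf * mKf * mKf * hKf * (V - p[P_EK]);
    const double nKs4 = nKs * nKs * nKs * nKs;
    const double IKs = p[P_GKS] * nKs4 * (V - p[P_EK]);
    const double IKleak = p[P_GKLEAK] * (V - p[P_EK]);
    const double Ipump = p[P_IPUMPMAX] / (1.0 + exp((p[P_NAH] - Na) / p[P_NAS]));
    const double Iinj = stim_current(t, p);

    dy[0] = -(INaT + INaP + INaleak + IKf + IKs + IKleak + Ipump - Iinj)
            / p[P_CM];

    dy[1] = (boltz(V, 29.13, -8.922) - mNaT)
            / (3.861 - 3.434 / (1.0 + exp((V + 51.35) / -5.98)));
    dy[2] = (boltz(V, 40.0, 6.048) - hNaT)
            / (2.834 - 2.371 / (1.0 + exp((V + 2.19) / -2.641)));
    dy[3] = boltz(V, 48.77, -3.68) - mNaP;          /* tau = 1 ms */
    dy[4] = (boltz(V, 17.55, -7.27) - mKf)
            / (1.94 + 2.66 / (1.0 + exp((V - 8.12) / 7.96)));
    dy[5] = (boltz(V, 45.0, 6.0) - hKf1)
            / (1.79 + 515.8 / (1.0 + exp((V + 147.4) / -28.66)));
    dy[6] = (boltz(V, 44.2, 1.5) - hKf2) / 116.0;
    dy[7] = (boltz(V, 12.85, -19.91) - nKs)
            / (2.03 + 1.96 / (1.0 + exp((V - 29.83) / 3.32)));

    dy[8] = (p[P_NADYN] != 0.0)
        ? -(INaT + INaP + INaleak + 3.0 * Ipump) * p[P_KNA]
        : 0.0;

    if (out != NULL) {
        out[0] = ENa;
        out[1] = Ipump;
        out[2] = Iinj;
    }
}

/* deSolve derivative entry point (nout = 3 auxiliary outputs) */
void pumpneuron_derivs(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    if (ip[0] < 3)
        error("nout should be at least 3");
    derivs_core(*t, y, ydot, yout, parms);
}

/* direct evaluation for tests and rest-state polishing:
 * returns c(dy[1..9], ENa, Ipump, Iinj) */
SEXP C_pumpneuron_derivs(SEXP t, SEXP y, SEXP p)
{
    SEXP ans;
    double dy[9], out[3];
    int i;

    if (LENGTH(y) != 9)
        error("state vector must have length 9");
    if (LENGTH(p) != NPARMS)
        error("parameter vector must have length %d", NPARMS);

    derivs_core(REAL(t)[0], REAL(y), dy, out, REAL(p));

    ans = PROTECT(allocVector(REALSXP, 12));
    for (i = 0; i < 9; i++)
        REAL(ans)[i] = dy[i];
    for (i = 0; i < 3; i++)
        REAL(ans)[9 + i] = out[i];
    UNPROTECT(1);
    return ans;
}

/* vectorised stimulus evaluation (cross-check against the R evaluator) */
SEXP C_pumpneuron_stim(SEXP t, SEXP p)
{
    int i, n = LENGTH(t);
    SEXP ans = PROTECT(allocVector(REALSXP, n));

    if (LENGTH(p) != NPARMS)
        error("parameter vector must have length %d", NPARMS);
    for (i = 0; i < n; i++)
        REAL(ans)[i] = stim_current(REAL(t)[i], REAL(p));
    UNPROTECT(1);
    return ans;
}

static const R_CallMethodDef callMethods[] = {
    {"C_pumpneuron_derivs", (DL_FUNC) &C_pumpneuron_derivs, 3},
    {"C_pumpneuron_stim",   (DL_FUNC) &C_pumpneuron_stim,   2},
    {NULL, NULL, 0}
};

void R_init_pumpneuron(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    /* deSolve looks up the derivs/initmod entry points by name */
    R_useDynamicSymbols(info, TRUE);
}
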