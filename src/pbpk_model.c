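/* Minimal whole-body PBPK model for imatinib.
 *
 * Compartments: oral depot, gut wall, liver (flow-limited, well-stirred),
 * central (plasma + rapidly equilibrating tissues), peripheral; cumulative
 * elimination sinks per route.  Enzyme activity states (hepatic CYP3A4,
 * gut CYP3A4, hepatic CYP2C8) follow a turnover model with mechanism-based
 * inactivation and (for gut CYP3A4) induction by a perpetrator.
 *
 * The perpetrator is an analytic one-compartment oral forcing function
 * (optionally with a formed metabolite, Bateman cascade), not a co-integrated
 * state.  Plasma protein binding to AAG is a one-site saturable equilibrium
 * solved in closed form at every evaluation.
 *
 * Intended for use with deSolve (compiled model interface).
 */
#include <R.h>
#include <math.h>

#define NPARMS 50
static double p[NPARMS];

/* parameter slots (keep in sync with .engine_parms() on the R side) */
#define P_KA      0   /* imatinib first-order absorption, 1/h */
#define P_FA      1   /* fraction absorbed */
#define P_KGW     2   /* gut wall -> liver transfer, 1/h */
#define P_KGM     3   /* gut wall metabolic rate at activity 1, 1/h */
#define P_QH      4   /* effective hepatic plasma flow Qh_blood * Rbp, L/h */
#define P_VL      5   /* liver volume, L */
#define P_KPL     6   /* liver:plasma partition coefficient */
#define P_VC      7   /* central volume, L */
#define P_VP      8   /* peripheral volume, L */
#define P_Q       9   /* inter-compartmental clearance, L/h */
#define P_CLR    10   /* renal clearance, L/h */
#define P_M34    11   /* hepatic CYP3A4 unbound CLint at activity 1, L/h */
#define P_M28    12   /* hepatic CYP2C8 unbound CLint, L/h */
#define P_MOTH   13   /* other-CYP unbound CLint (not modulated), L/h */
#define P_BIL    14   /* biliary (P-gp + BCRP) unbound CLint, L/h */
#define P_KD     15   /* AAG binding Kd, mg/L drug equivalents */
#define P_BMAX   16   /* AAG binding capacity, mg/L drug equivalents */
#define P_FUFIX  17   /* if > 0: constant fu (linearised binding) */
#define P_KDEG34 18   /* hepatic CYP3A4 degradation, 1/h */
#define P_KDEGG  19   /* gut CYP3A4 degradation, 1/h */
#define P_KDEG28 20   /* hepatic CYP2C8 degradation, 1/h */
#define P_KIIMA  21   /* imatinib CYP3A4 MBI KI, mg/L unbound */
#define P_KINIMA 22   /* imatinib CYP3A4 MBI kinact, 1/h (0 disables) */
/* 23, 24 reserved */
#define P_PON    25   /* perpetrator present */
#define P_PDOSE  26
#define P_PTAU   27
#define P_PND    28
#define P_PT0    29
#define P_PKA    30
#define P_PKE    31
#define P_PV     32
#define P_PFU    33
#define P_PMFR   34   /* metabolite formation fraction (0 = none) */
#define P_PMKE   35
#define P_PMV    36
#define P_PMFU   37
#define P_KI28C  38   /* competitive Ki on hepatic CYP2C8, mg/L unbound (0 = none) */
#define P_KI34C  39   /* competitive Ki on hepatic CYP3A4 */
#define P_KI34M  40   /* MBI KI on hepatic CYP3A4 */
#define P_KIN34M 41   /* MBI kinact on hepatic CYP3A4 (0 = none) */
#define P_KI28M  42   /* MBI KI on hepatic CYP2C8 (driver: metabolite if formed) */
#define P_KIN28M 43
#define P_KIG34M 44   /* MBI KI on gut CYP3A4 */
#define P_KING34 45
#define P_INDG   46   /* gut CYP3A4 induction Indmax */
#define P_IC50G  47   /* gut CYP3A4 induction IndC50, mg/L unbound */
#define P_INDH   48   /* hepatic CYP3A4 induction Indmax */
#define P_IC50H  49

void imat_initmod(void (*odeparms)(int *, double *)) {
    int n = NPARMS;
    odeparms(&n, p);
}

/* unbound plasma concentrations (mg/L) of perpetrator parent and metabolite */
static void perp_conc(double t, double *cpu, double *cmu) {
    double Cp = 0.0, Cm = 0.0;
    *cpu = 0.0; *cmu = 0.0;
    if (p[P_PON] < 0.5 || p[P_PDOSE] <= 0.0) return;
    {
        double dose = p[P_PDOSE], tau = p[P_PTAU], t0 = p[P_PT0];
        double ka = p[P_PKA], ke = p[P_PKE], V = p[P_PV];
        double fm = p[P_PMFR], km = p[P_PMKE], Vm = p[P_PMV];
        int nd = (int) (p[P_PND] + 0.5), i;
        for (i = 0; i < nd; i++) {
            double s = t - (t0 + i * tau);
            if (s <= 0.0) break;
            if (fabs(ka - ke) > 1e-9)
                Cp += dose / V * ka / (ka - ke) * (exp(-ke * s) - exp(-ka * s));
            else
                Cp += dose / V * ka * s * exp(-ka * s);
            if (fm > 0.0) {
                double d1 = (ke - ka) * (km - ka);
                double d2 = (ka - ke) * (km - ke);
                double d3 = (ka - km) * (ke - km);
                double Am = dose * fm * ka * ke *
                    (exp(-ka * s) / d1 + exp(-ke * s) / d2 + exp(-km * s) / d3);
                Cm += Am / Vm;
            }
        }
        *cpu = p[P_PFU] * Cp;
        if (fm > 0.0) *cmu = p[P_PMFU] * Cm;
    }
}

/* unbound fraction from one-site saturable AAG binding (quadratic root) */
static double fu_plasma(double C) {
    double Kd, Bmax, b, Cu, fu;
    if (p[P_FUFIX] > 0.0) return p[P_FUFIX];
    Kd = p[P_KD]; Bmax = p[P_BMAX];
    if (Bmax <= 0.0) return 1.0;
    if (C < 1e-12) return Kd / (Kd + Bmax);
    b = Kd + Bmax - C;
    Cu = 0.5 * (-b + sqrt(b * b + 4.0 * Kd * C));
    fu = Cu / C;
    if (fu > 1.0) fu = 1.0;
    if (fu < 1e-12) fu = 1e-12;
    return fu;
}

void imat_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip) {
    double Cc, fu, Cout, CuL, cpu, cmu;
    double a34 = 1.0, a28 = 1.0;
    double abs_flux, gutmet, m34, m28, mot, bil, renal;
    double kin_i = 0.0, kin34p = 0.0, kin28p = 0.0, kingp = 0.0;
    double sh = 1.0, sg = 1.0, drv28;

    Cc = y[3] / p[P_VC];
    if (Cc < 0.0) Cc = 0.0;
    fu = fu_plasma(Cc);
    Cout = (y[2] / p[P_VL]) / p[P_KPL];
    if (Cout < 0.0) Cout = 0.0;
    CuL = fu * Cout;

    perp_conc(*t, &cpu, &cmu);

    if (p[P_KI34C] > 0.0) a34 = 1.0 / (1.0 + cpu / p[P_KI34C]);
    if (p[P_KI28C] > 0.0) a28 = 1.0 / (1.0 + cpu / p[P_KI28C]);

    abs_flux = p[P_KA] * y[0];
    gutmet = p[P_KGM] * y[6] * y[1];

    m34 = p[P_M34] * y[5] * a34 * CuL;
    m28 = p[P_M28] * y[7] * a28 * CuL;
    mot = p[P_MOTH] * CuL;
    bil = p[P_BIL] * CuL;
    renal = p[P_CLR] * Cc;

    ydot[0] = -abs_flux;
    ydot[1] = p[P_FA] * abs_flux - p[P_KGW] * y[1] - gutmet;
    ydot[2] = p[P_KGW] * y[1] + p[P_QH] * (Cc - Cout) - (m34 + m28 + mot + bil);
    ydot[3] = p[P_QH] * (Cout - Cc) - renal - p[P_Q] * (Cc - y[4] / p[P_VP]);
    ydot[4] = p[P_Q] * (Cc - y[4] / p[P_VP]);

    /* enzyme turnover: hepatic CYP3A4 (imatinib autoinhibition + perpetrator) */
    if (p[P_KINIMA] > 0.0) kin_i = p[P_KINIMA] * CuL / (p[P_KIIMA] + CuL);
    if (p[P_KIN34M] > 0.0) kin34p = p[P_KIN34M] * cpu / (p[P_KI34M] + cpu);
    if (p[P_INDH] > 0.0) sh = 1.0 + p[P_INDH] * cpu / (p[P_IC50H] + cpu);
    ydot[5] = p[P_KDEG34] * sh - y[5] * (p[P_KDEG34] + kin_i + kin34p);

    /* gut CYP3A4: systemic unbound drives both inactivation and induction */
    if (p[P_KING34] > 0.0) kingp = p[P_KING34] * cpu / (p[P_KIG34M] + cpu);
    if (p[P_INDG] > 0.0) sg = 1.0 + p[P_INDG] * cpu / (p[P_IC50G] + cpu);
    ydot[6] = p[P_KDEGG] * sg - y[6] * (p[P_KDEGG] + kin_i + kingp);

    /* hepatic CYP2C8: perpetrator MBI only (metabolite-driven if formed) */
    drv28 = (p[P_PMFR] > 0.0) ? cmu : cpu;
    if (p[P_KIN28M] > 0.0) kin28p = p[P_KIN28M] * drv28 / (p[P_KI28M] + drv28);
    ydot[7] = p[P_KDEG28] - y[7] * (p[P_KDEG28] + kin28p);

    /* cumulative elimination sinks */
    ydot[8] = m34;
    ydot[9] = m28;
    ydot[10] = mot;
    ydot[11] = bil;
    ydot[12] = renal;
    ydot[13] = gutmet;
    ydot[14] = (1.0 - p[P_FA]) * abs_flux;

    if (*ip >= 5) {
        yout[0] = Cc;
        yout[1] = fu;
        yout[2] = CuL;
        yout[3] = cpu;
        yout[4] = cmu;
    }
}
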