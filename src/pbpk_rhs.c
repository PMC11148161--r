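/* Whole-body PBPK right-hand side for osimertinib.
 *
 * States (concentrations in uM, amounts in umol):
 *  0 A_st_solid   undissolved drug in stomach
 *  1 A_st_diss    dissolved drug in stomach
 *  2 A_int_solid  undissolved drug in intestinal lumen
 *  3 A_int_diss   dissolved drug in intestinal lumen
 *  4..14 tissue concentrations: gut, liver, kidney, muscle, adipose, skin,
 *        heart, spleen, bone, rest, lung (flow-limited, total conc)
 * 15 C_art  16 C_ven   arterial / venous plasma (Rbp = 1)
 * 17 C_bvp  brain vascular plasma    18 C_bvc brain vascular blood cells
 * 19 C_is   brain interstitial free  20 C_ic  brain intracellular total
 * 21..24 cumulative eliminated: hepatic, gut-wall, renal, fecal (umol)
 * 25..27 relative enzyme amounts (induction turnover): CYP1A2, 2C9, 3A4
 *
 * The perpetrator unbound concentration is evaluated in closed form
 * (superposed one-compartment oral doses) so no forcing functions are
 * needed. Dosing of the victim is handled by deSolve "add" events on
 * state 0; the dose calendar is also passed in the parameter vector so
 * the Weibull dissolution hazard can use time-since-last-dose.
 */

#include <math.h>
#include <R.h>

#define NPARMS 209
static double p[NPARMS];

void pbpkeo_init(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, p);
}

/* parameter layout (keep in step with make_parms() on the R side) */
#define V_GUT    p[0]
#define V_LIV    p[1]
#define V_KID    p[2]
#define V_MUS    p[3]
#define V_ADI    p[4]
#define V_SKIN   p[5]
#define V_HEART  p[6]
#define V_SPL    p[7]
#define V_BONE   p[8]
#define V_REST   p[9]
#define V_LUNG   p[10]
#define V_ART    p[11]
#define V_VEN    p[12]
#define V_BVP    p[13]
#define V_BVC    p[14]
#define V_IS     p[15]
#define V_IC     p[16]
#define KP(i)    p[17 + (i)]   /* gut..lung, same order as states 4..14 */
#define Q_GUT    p[28]
#define Q_HA     p[29]
#define Q_KID    p[30]
#define Q_MUS    p[31]
#define Q_ADI    p[32]
#define Q_SKIN   p[33]
#define Q_HEART  p[34]
#define Q_SPL    p[35]
#define Q_BONE   p[36]
#define Q_REST   p[37]
#define Q_BP     p[38]
#define Q_BC     p[39]
#define CO_      p[40]
#define FU       p[41]
#define KA       p[42]
#define KGE      p[43]
#define KLOSS    p[44]
#define WT50     p[45]
#define WSHAPE   p[46]
#define CLR      p[47]
#define CLGUT    p[48]
#define PS_BBB   p[49]
#define CLE_B1   p[50]
#define CLE_BCRP p[51]
#define PSC      p[52]
#define KBRT     p[53]
#define KIC      p[54]
#define KBC      p[55]
#define KEX      p[56]
#define CLHEP(i) p[57 + (i)]   /* 1A2, 2A6, 2C9, 2E1, 3A4, 3A5 */
#define KDEG_ENZ p[63]
#define KI_1A2   p[64]
#define KI_2C9   p[65]
#define KI_3A4   p[66]
#define EMAX_1A2 p[67]
#define EC50_1A2 p[68]
#define EMAX_2C9 p[69]
#define EC50_2C9 p[70]
#define EMAX_3A4 p[71]
#define EC50_3A4 p[72]
#define P_KA     p[73]
#define P_KE     p[74]
#define P_VF     p[75]
#define P_FU     p[76]
#define P_DOSE   p[77]   /* umol per perpetrator dose */
#define N_DOSE_O p[78]
#define N_DOSE_P p[79]
#define T_DOSE_O(i) p[80 + (i)]    /* up to 64 victim dose times, h */
#define T_DOSE_P(i) p[144 + (i)]   /* up to 64 perpetrator dose times, h */
#define DOSE_O   p[208]  /* umol per victim dose */

static double weibull_hazard(double tsince)
{
    double r;
    if (tsince < 1e-6) tsince = 1e-6;
    r = tsince / WT50;
    return M_LN2 * WSHAPE / WT50 * pow(r, WSHAPE - 1.0);
}

/* unbound perpetrator concentration at the enzyme, uM */
static double perp_cu(double t)
{
    int i, n = (int) (N_DOSE_P + 0.5);
    double c = 0.0, dt, ka = P_KA, ke = P_KE;
    if (n <= 0 || P_DOSE <= 0.0) return 0.0;
    for (i = 0; i < n; i++) {
        dt = t - T_DOSE_P(i);
        if (dt <= 0.0) continue;
        c += P_DOSE * ka / (P_VF * (ka - ke)) *
             (exp(-ke * dt) - exp(-ka * dt));
    }
    return P_FU * c;
}

void pbpkeo_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double tt = *t;
    int i, ndo = (int) (N_DOSE_O + 0.5);

    /* time since most recent victim dose (dissolution clock) */
    double tsince = -1.0;
    for (i = 0; i < ndo; i++) {
        if (T_DOSE_O(i) <= tt + 1e-9) {
            double d = tt - T_DOSE_O(i);
            if (tsince < 0.0 || d < tsince) tsince = d;
        }
    }
    double haz = (tsince >= 0.0) ? weibull_hazard(tsince) : 0.0;

    /* interaction multipliers on intrinsic clearance */
    double iu = perp_cu(tt);
    double inh1a2 = (KI_1A2 > 0.0) ? 1.0 / (1.0 + iu / KI_1A2) : 1.0;
    double inh2c9 = (KI_2C9 > 0.0) ? 1.0 / (1.0 + iu / KI_2C9) : 1.0;
    double inh3a4 = (KI_3A4 > 0.0) ? 1.0 / (1.0 + iu / KI_3A4) : 1.0;
    double m1a2 = y[25] * inh1a2;
    double m2c9 = y[26] * inh2c9;
    double m3a4 = y[27] * inh3a4;

    /* absorption chain */
    double a_ss = y[0], a_sd = y[1], a_is = y[2], a_id = y[3];
    ydot[0] = -haz * a_ss - KGE * a_ss;
    ydot[1] = haz * a_ss - KGE * a_sd;
    ydot[2] = KGE * a_ss - haz * a_is - KLOSS * a_is;
    ydot[3] = KGE * a_sd + haz * a_is - KA * a_id - KLOSS * a_id;
    double r_abs = KA * a_id;            /* umol/h into gut tissue */

    double c_gut = y[4], c_liv = y[5], c_kid = y[6], c_mus = y[7];
    double c_adi = y[8], c_ski = y[9], c_hea = y[10], c_spl = y[11];
    double c_bon = y[12], c_res = y[13], c_lun = y[14];
    double c_art = y[15], c_ven = y[16];
    double c_bvp = y[17], c_bvc = y[18], c_isf = y[19], c_ic = y[20];

    /* venous-equilibrated outflow concentrations */
    double o_gut = c_gut / KP(0), o_liv = c_liv / KP(1), o_kid = c_kid / KP(2);
    double o_mus = c_mus / KP(3), o_adi = c_adi / KP(4), o_ski = c_ski / KP(5);
    double o_hea = c_hea / KP(6), o_spl = c_spl / KP(7), o_bon = c_bon / KP(8);
    double o_res = c_res / KP(9), o_lun = c_lun / KP(10);

    /* gut wall: CYP3A4 first-pass on unbound tissue concentration */
    double r_met_gut = CLGUT * m3a4 * FU * o_gut;
    ydot[4] = (Q_GUT * (c_art - o_gut) + r_abs - r_met_gut) / V_GUT;

    /* liver: six-enzyme unbound intrinsic clearance */
    double cu_liv = FU * o_liv;
    double r_met_hep = (CLHEP(0) * m1a2 + CLHEP(1) + CLHEP(2) * m2c9 +
                        CLHEP(3) + (CLHEP(4) + CLHEP(5)) * m3a4) * cu_liv;
    double q_liv_out = Q_HA + Q_GUT + Q_SPL;
    ydot[5] = (Q_HA * c_art + Q_GUT * o_gut + Q_SPL * o_spl -
               q_liv_out * o_liv - r_met_hep) / V_LIV;

    ydot[6] = Q_KID * (c_art - o_kid) / V_KID;
    ydot[7] = Q_MUS * (c_art - o_mus) / V_MUS;
    ydot[8] = Q_ADI * (c_art - o_adi) / V_ADI;
    ydot[9] = Q_SKIN * (c_art - o_ski) / V_SKIN;
    ydot[10] = Q_HEART * (c_art - o_hea) / V_HEART;
    ydot[11] = Q_SPL * (c_art - o_spl) / V_SPL;
    ydot[12] = Q_BONE * (c_art - o_bon) / V_BONE;
    ydot[13] = Q_REST * (c_art - o_res) / V_REST;

    /* lung receives total venous return */
    ydot[14] = CO_ * (c_ven - o_lun) / V_LUNG;

    /* renal filtration (CLR = GFR x fup) acts on arterial plasma */
    double r_ren = CLR * c_art;
    double q_sum = Q_HA + Q_GUT + Q_SPL + Q_KID + Q_MUS + Q_ADI + Q_SKIN +
                   Q_HEART + Q_BONE + Q_REST + Q_BP + Q_BC;
    ydot[15] = (CO_ * o_lun - q_sum * c_art - r_ren) / V_ART;

    double venous_in = q_liv_out * o_liv + Q_KID * o_kid + Q_MUS * o_mus +
                       Q_ADI * o_adi + Q_SKIN * o_ski + Q_HEART * o_hea +
                       Q_BONE * o_bon + Q_REST * o_res +
                       Q_BP * c_bvp + Q_BC * c_bvc;
    ydot[16] = (venous_in - CO_ * c_ven) / V_VEN;

    /* brain: permeability-limited, 4 sub-compartments.
     * Passive BBB flux equilibrates interstitial free drug with
     * KBRT x fu x vascular plasma (ion-trapping partition of the base);
     * ABCB1/BCRP efflux returns interstitial drug to vascular plasma. */
    double f_pass = PS_BBB * (KBRT * FU * c_bvp - c_isf);
    double f_eff = (CLE_B1 + CLE_BCRP) * c_isf;
    double f_cell = PSC * (c_isf - c_ic / KIC);
    ydot[17] = (Q_BP * (c_art - c_bvp) - f_pass + f_eff +
                KEX * (c_bvc - KBC * c_bvp)) / V_BVP;
    ydot[18] = (Q_BC * (c_art - c_bvc) - KEX * (c_bvc - KBC * c_bvp)) / V_BVC;
    ydot[19] = (f_pass - f_eff - f_cell) / V_IS;
    ydot[20] = f_cell / V_IC;

    /* cumulative elimination */
    ydot[21] = r_met_hep;
    ydot[22] = r_met_gut;
    ydot[23] = r_ren;
    ydot[24] = KLOSS * (a_is + a_id);

    /* enzyme induction turnover (relative amounts, baseline 1) */
    double ind1a2 = (EMAX_1A2 > 0.0) ?
        1.0 + EMAX_1A2 * iu / (EC50_1A2 + iu) : 1.0;
    double ind2c9 = (EMAX_2C9 > 0.0) ?
        1.0 + EMAX_2C9 * iu / (EC50_2C9 + iu) : 1.0;
    double ind3a4 = (EMAX_3A4 > 0.0) ?
        1.0 + EMAX_3A4 * iu / (EC50_3A4 + iu) : 1.0;
    ydot[25] = KDEG_ENZ * (ind1a2 - y[25]);
    ydot[26] = KDEG_ENZ * (ind2c9 - y[26]);
    ydot[27] = KDEG_ENZ * (ind3a4 - y[27]);
}
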