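/* Compiled right-hand side of the closed-loop circulation ODE system,
 * in the deSolve compiled-model interface.  Mirrors assemble_rhs() in
 * R/model_core.R; the parameter-vector layout matches .pack_params().
 *
 * Units: Pa, mm^3, s.
 * States (15): V_lv, V_rv, Q_mv, Q_av, Q_tv, Q_puv,
 *              P_ha, P_dig, P_pv, P_hs, P_oth, P_lung, P_cv, P_la, P_ra
 * Aux outputs (9): P_lv, P_rv, P_art, P_vj, Q_ha_d, Q_pv_d, Q_hs_out,
 *                  Q_dig_out, Q_oth_out
 */

#include <R.h>
#include <math.h>

#define NPAR 50
static double parms[NPAR];

/* heart */
#define EMAXL parms[0]
#define EMINL parms[1]
#define V0L   parms[2]
#define EMAXR parms[3]
#define EMINR parms[4]
#define V0R   parms[5]
#define TCYC  parms[6]
#define TMAX  parms[7]
#define TRELAX parms[8]
/* valves: R, L, steepness, closed factor */
#define R_MV parms[9]
#define L_MV parms[10]
#define S_MV parms[11]
#define F_MV parms[12]
#define R_AV parms[13]
#define L_AV parms[14]
#define S_AV parms[15]
#define F_AV parms[16]
#define R_TV parms[17]
#define L_TV parms[18]
#define S_TV parms[19]
#define F_TV parms[20]
#define R_PUV parms[21]
#define L_PUV parms[22]
#define S_PUV parms[23]
#define F_PUV parms[24]
/* RCR compartments: R_p, C, R_d */
#define RP_LU parms[25]
#define C_LU  parms[26]
#define RD_LU parms[27]
#define RP_DG parms[28]
#define C_DG  parms[29]
#define RD_DG parms[30]
#define RP_OO parms[31]
#define C_OO  parms[32]
#define RD_OO parms[33]
#define RP_CV parms[34]
#define C_CV  parms[35]
#define RD_CV parms[36]
/* hepatic subsystem */
#define R_PVP parms[37]
#define R_PVD parms[38]
#define C_PV  parms[39]
#define R_HAP parms[40]
#define R_HAD parms[41]
#define C_HA  parms[42]
#define R_HS  parms[43]
#define C_HS  parms[44]
#define R_LHV parms[45]
#define R_MHV parms[46]
#define R_RHV parms[47]
/* passive atrial compliances */
#define C_LA  parms[48]
#define C_RA  parms[49]

void circ_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, parms);
}

static double elastance(double tc, double emax, double emin)
{
    double dE = emax - emin;
    if (tc <= TMAX)
        return emin + 0.5 * dE * (1.0 - cos(M_PI * tc / TMAX));
    if (tc <= TMAX + TRELAX)
        return emin + 0.5 * dE * (1.0 + cos(M_PI * (tc - TMAX) / TRELAX));
    return emin;
}

static double valve_reff(double dP, double R, double steep, double fac)
{
    double o = 0.5 * (1.0 + tanh(dP / steep));
    double omin = 1.0 / fac;
    if (o < omin) o = omin;
    return R / o;
}

void circ_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double V_lv = y[0], V_rv = y[1];
    double Q_mv = y[2], Q_av = y[3], Q_tv = y[4], Q_puv = y[5];
    double P_ha = y[6], P_dig = y[7], P_pv = y[8], P_hs = y[9];
    double P_oth = y[10], P_lung = y[11], P_cv = y[12];
    double P_la = y[13], P_ra = y[14];

    double tc = fmod(*t, TCYC);
    if (tc < 0) tc += TCYC;
    double P_lv = elastance(tc, EMAXL, EMINL) * (V_lv - V0L);
    double P_rv = elastance(tc, EMAXR, EMINR) * (V_rv - V0R);

    /* systemic arterial junction */
    double g_ha = 1.0 / R_HAP, g_dig = 1.0 / RP_DG, g_oth = 1.0 / RP_OO;
    double P_art = (Q_av + P_ha * g_ha + P_dig * g_dig + P_oth * g_oth) /
                   (g_ha + g_dig + g_oth);

    /* hepatic-venous confluence */
    double R_hv = 1.0 / (1.0 / R_LHV + 1.0 / R_MHV + 1.0 / R_RHV);
    double g_sin = 1.0 / (R_HS + R_hv), g_oo = 1.0 / RD_OO, g_cv = 1.0 / RP_CV;
    double P_vj = (P_hs * g_sin + P_oth * g_oo + P_cv * g_cv) /
                  (g_sin + g_oo + g_cv);

    /* valve branches */
    double dQ_mv = (P_la - P_lv -
        valve_reff(P_la - P_lv, R_MV, S_MV, F_MV) * Q_mv) / L_MV;
    double dQ_av = (P_lv - P_art -
        valve_reff(P_lv - P_art, R_AV, S_AV, F_AV) * Q_av) / L_AV;
    double dQ_tv = (P_ra - P_rv -
        valve_reff(P_ra - P_rv, R_TV, S_TV, F_TV) * Q_tv) / L_TV;
    double dQ_puv = (P_rv - P_lung -
        (valve_reff(P_rv - P_lung, R_PUV, S_PUV, F_PUV) + RP_LU) * Q_puv) / L_PUV;

    /* branch flows */
    double Q_ha_in  = (P_art - P_ha) * g_ha;
    double Q_ha_d   = (P_ha - P_hs) / R_HAD;
    double Q_dig_in = (P_art - P_dig) * g_dig;
    double Q_dig_out = (P_dig - P_pv) / (RD_DG + R_PVP);
    double Q_pv_d   = (P_pv - P_hs) / R_PVD;
    double Q_hs_out = (P_hs - P_vj) * g_sin;
    double Q_oth_in = (P_art - P_oth) * g_oth;
    double Q_oth_out = (P_oth - P_vj) * g_oo;
    double Q_cv_in  = (P_vj - P_cv) * g_cv;
    double Q_lung_out = (P_lung - P_la) / RD_LU;
    double Q_cv_out = (P_cv - P_ra) / RD_CV;

    ydot[0] = Q_mv - Q_av;
    ydot[1] = Q_tv - Q_puv;
    ydot[2] = dQ_mv;
    ydot[3] = dQ_av;
    ydot[4] = dQ_tv;
    ydot[5] = dQ_puv;
    ydot[6] = (Q_ha_in - Q_ha_d) / C_HA;
    ydot[7] = (Q_dig_in - Q_dig_out) / C_DG;
    ydot[8] = (Q_dig_out - Q_pv_d) / C_PV;
    ydot[9] = (Q_pv_d + Q_ha_d - Q_hs_out) / C_HS;
    ydot[10] = (Q_oth_in - Q_oth_out) / C_OO;
    ydot[11] = (Q_puv - Q_lung_out) / C_LU;
    ydot[12] = (Q_cv_in - Q_cv_out) / C_CV;
    ydot[13] = (Q_lung_out - Q_mv) / C_LA;
    ydot[14] = (Q_cv_out - Q_tv) / C_RA;

    if (ip[0] >= 9) {
        yout[0] = P_lv;
        yout[1] = P_rv;
        yout[2] = P_art;
        yout[3] = P_vj;
        yout[4] = Q_ha_d;
        yout[5] = Q_pv_d;
        yout[6] = Q_hs_out;
        yout[7] = Q_dig_out;
        yout[8] = Q_oth_out;
    }
}
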