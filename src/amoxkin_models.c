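/* Compiled right-hand sides for the two amoxicillin synthesis models,
 * in the form deSolve expects (initfunc + derivs pair per model).
 *
 * Parameter layout (set from R, see simulate_reactor):
 *   model 1: Kcat1 Kcat2 KM1 KM2 Tmax KEN kAB kAN kAOH kNH CEZ FAB FNH (13)
 *   model 2: k2 k3 k4 km4 k5 KN KS KP CEZ FAB FNH                      (11)
 *
 * FAB/FNH are the (piecewise-constant) feed rates for the current
 * integration segment; zero in batch mode. States are clipped at zero
 * before rate evaluation so that integrator overshoot cannot generate
 * spurious negative rates.
 */
#include <R.h>

static double p1[13];
static double p2[11];

void amox_init1(void (*odeparms)(int *, double *))
{
    int n = 13;
    odeparms(&n, p1);
}

void amox_derivs1(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double CAB  = y[0] > 0 ? y[0] : 0;
    double CAN  = y[1] > 0 ? y[1] : 0;
    double CNH  = y[2] > 0 ? y[2] : 0;
    double CAOH = y[3] > 0 ? y[3] : 0;
    double Kcat1 = p1[0], Kcat2 = p1[1], KM1 = p1[2], KM2 = p1[3];
    double Tmax = p1[4], KEN = p1[5], kAB = p1[6], kAN = p1[7];
    double kAOH = p1[8], kNH = p1[9], CEZ = p1[10], fab = p1[11], fnh = p1[12];

    double vAB = Kcat1 * CAB * CEZ /
                 (KM1 * (1 + CAN / kAN + CAOH / kAOH) + CAB);
    double vS  = vAB * Tmax * CNH / (KEN + CNH);
    double vAN = Kcat2 * CAN * CEZ /
                 (KM2 * (1 + CAB / kAB + CNH / kNH + CAOH / kAOH) + CAN);

    ydot[0] = -vAB + fab;
    ydot[1] = vS - vAN;
    ydot[2] = vAN - vS + fnh;
    ydot[3] = vAB - vS + vAN;
}

void amox_init2(void (*odeparms)(int *, double *))
{
    int n = 11;
    odeparms(&n, p2);
}

void amox_derivs2(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double CAB = y[0] > 0 ? y[0] : 0;
    double CAN = y[1] > 0 ? y[1] : 0;
    double CNH = y[2] > 0 ? y[2] : 0;
    double k2 = p2[0], k3 = p2[1], k4 = p2[2], km4 = p2[3], k5 = p2[4];
    double KN = p2[5], KS = p2[6], KP = p2[7], CEZ = p2[8];
    double fab = p2[9], fnh = p2[10];

    double D  = k3 * KN + k4 * CNH + k5 * CNH;
    double RP = CEZ * (k2 * k4 * CAB * CNH / KS -
                       km4 * CAN * (k3 * KN + k5 * CNH) / KP) / D;
    double RB = CEZ * (k3 * KN + k5 * CNH) *
                (k2 * CAB / KS - km4 * CAN / KP) / D;

    ydot[0] = -(RP + RB) + fab;
    ydot[1] = RP;
    ydot[2] = -RP + fnh;
    ydot[3] = RB;
}
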