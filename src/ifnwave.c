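/* Right-hand side of the first/second-responder IFN model, compiled for use
 * by deSolve during fitting (the same equations as ifn_derivatives() in R).
 *
 * Parameter order (must match the R side): fr, sr, kon, koff, kf, df, T, H.
 * States: y[0] = f1, y[1] = f2, y[2] = [IFN] (pg/mL).
 */
#include <R.h>
#include <Rmath.h>

static double parms[8];
#define p_fr   parms[0]
#define p_sr   parms[1]
#define p_kon  parms[2]
#define p_koff parms[3]
#define p_kf   parms[4]
#define p_df   parms[5]
#define p_T    parms[6]
#define p_H    parms[7]

void ifnwave_initmod(void (*odeparms)(int *, double *))
{
    int n = 8;
    odeparms(&n, parms);
}

void ifnwave_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double hill = 0.0;
    if (y[2] > 0.0) {
        double r = pow(y[2] / p_T, p_H);
        hill = R_FINITE(r) ? r / (1.0 + r) : 1.0;
    }
    ydot[0] = p_kon * (p_fr - y[0]) - p_koff * y[0];
    ydot[1] = p_kon * hill * (p_sr - y[1]) - p_koff * y[1];
    ydot[2] = p_kf * (y[0] + y[1]) - p_df * y[2];
}
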