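/* Compiled right-hand sides for deSolve.
 *
 * Parameter vector layout (shared by both systems):
 *   0 rho, 1 K, 2 kappa1, 3 kappa2, 4 theta, 5 c0, 6 c3, 7 sigma
 * For the nonautonomous system c0/c3 are the rescaled constants (D0
 * absorbed); for the autonomous system they are the unscaled constants
 * multiplying the Dex state D.
 *
 * The logistic term uses rho(t)*x - (rho/K)*x^2, exact because
 * rho(t)/K(t) == rho/K by construction, and finite even when K(t) -> 0.
 */
#include <R.h>
#include <math.h>

static double parms[8];

void carrtdex_init(void (*odeparms)(int *, double *))
{
    int n = 8;
    odeparms(&n, parms);
}

/* two-species nonautonomous system: y = (x, y) */
void carrtdex_deriv_nonaut(int *neq, double *t, double *y, double *ydot,
                           double *yout, int *ip)
{
    double rho = parms[0], K = parms[1], kappa1 = parms[2],
           kappa2 = parms[3], theta = parms[4], c0 = parms[5],
           c3 = parms[6], sigma = parms[7];
    double decay = exp(-sigma * (*t));
    double rho_t = rho - c0 * decay;
    double theta_t = theta + c3 * decay;
    double x = y[0], yy = y[1];

    ydot[0] = rho_t * x - (rho / K) * x * x - kappa1 * x * yy;
    ydot[1] = kappa2 * x * yy - theta_t * yy;
}

/* three-species autonomous system: y = (x, y, D); c0/c3 unscaled */
void carrtdex_deriv_aut(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    double rho = parms[0], K = parms[1], kappa1 = parms[2],
           kappa2 = parms[3], theta = parms[4], c0 = parms[5],
           c3 = parms[6], sigma = parms[7];
    double x = y[0], yy = y[1], D = y[2];

    ydot[0] = rho * x - (rho / K) * x * x - kappa1 * x * yy - c0 * D * x;
    ydot[1] = kappa2 * x * yy - theta * yy - c3 * D * yy;
    ydot[2] = -sigma * D;
}
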