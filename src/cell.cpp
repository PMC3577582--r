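#include <Rcpp.h>
#include "model.h"
using namespace Rcpp;

// Space-clamped forward-Euler integration of the four-current model.
// events: matrix with columns (t_on, t_off, amplitude); a positive
// amplitude depolarizes. Records every rec_steps steps starting at t0.
// [[Rcpp::export]]
List simulate_cell_cpp(NumericVector state0, NumericVector params,
                       double dt, double t0, int nsteps,
                       NumericMatrix events, int rec_steps,
                       bool record_gates) {
  const double* p = REAL(params);
  GateConsts gc; gc.init(p);
  const double inv_vc = 1.0 / p[P_VC];
  double V = state0[0], h = state0[1], f = state0[2],
         r = state0[3], s = state0[4];
  const int nev = events.nrow();
  const int nrec = nsteps / rec_steps + 1;
  NumericVector t_out(nrec), V_out(nrec);
  NumericMatrix g_out = record_gates ? NumericMatrix(nrec, 4)
                                     : NumericMatrix(0, 0);
  int irec = 0;
  for (int step = 0; step <= nsteps; ++step) {
    if (step % rec_steps == 0 && irec < nrec) {
      t_out[irec] = t0 + step * dt;
      V_out[irec] = V;
      if (record_gates) {
        g_out(irec, 0) = h; g_out(irec, 1) = f;
        g_out(irec, 2) = r; g_out(irec, 3) = s;
      }
      ++irec;
      if (!std::isfinite(V))
        stop("non-finite membrane potential at t = %f ms", t0 + step * dt);
    }
    if (step == nsteps) break;
    const double t = t0 + step * dt;
    double Jstim = 0.0;
    for (int e = 0; e < nev; ++e)
      if (t >= events(e, 0) && t < events(e, 1)) Jstim += events(e, 2);
    const double dV = -ionic_current(V, h, f, r, s, p, si_factor(V, p), inv_vc) + Jstim;
    gate_step(V, h, f, r, s, gc, dt);
    V += dt * dV;
  }
  return List::create(_["t"] = t_out, _["V"] = V_out, _["gates"] = g_out,
                      _["state"] = NumericVector::create(V, h, f, r, s));
}
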