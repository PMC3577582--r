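#pragma once
#include <cmath>
#include <vector>

// Parameter vector layout; must match param_vec() on the R side.
enum ParIdx {
  P_TAU_HP = 0, P_TAU_HM, P_TAU_FP, P_TAU_FM, P_TAU_RP, P_TAU_RM,
  P_TAU_SP, P_TAU_SM, P_GFI, P_VFI, P_GSO, P_GSI, P_BETA1, P_BETA2,
  P_V1, P_V2, P_GTO, P_VC, P_VSW, P_VR, P_VTO, NPAR
};

// Heaviside with Theta(0) = 1 (right-continuous); the single place the
// convention lives on the C++ side.
inline double heav(double x) { return x >= 0.0 ? 1.0 : 0.0; }

// Slow-inward voltage factor g_si * d_inf(V) * f'_inf(V); the only
// transcendental part of the right-hand side, tabulated for tissue runs.
inline double si_factor(double V, const double* p) {
  const double d_inf = heav(V - p[P_VC]) *
    0.5 * (1.0 + std::tanh(p[P_BETA1] * (V - p[P_V1])));
  const double fp_inf = 0.5 * (1.0 - std::tanh(p[P_BETA2] * (V - p[P_V2])));
  return p[P_GSI] * d_inf * fp_inf;
}

struct SiTable {
  double v0, v1, inv_h;
  std::vector<double> val;
  void build(const double* p, double lo = -2.0, double hi = 4.0, double h = 1e-4) {
    v0 = lo; v1 = hi; inv_h = 1.0 / h;
    size_t n = static_cast<size_t>((hi - lo) * inv_h) + 2;
    val.resize(n);
    for (size_t k = 0; k < n; ++k) val[k] = si_factor(lo + k * h, p);
  }
  inline double operator()(double V) const {
    if (V <= v0) return val.front();
    if (V >= v1) return val[val.size() - 2];
    double u = (V - v0) * inv_h;
    size_t k = static_cast<size_t>(u);
    double w = u - k;
    return val[k] * (1.0 - w) + val[k + 1] * w;
  }
};

// Total ionic current J_fi + J_si + J_so + J_to (ms^-1), with the
// slow-inward factor supplied (exact or tabulated).
inline double ionic_current(double V, double h, double f, double r, double s,
                            const double* p, double si_fac,
                            double inv_vc) {
  const double th_c = heav(V - p[P_VC]);
  const double m_inf = (V - p[P_VC]) * th_c;
  const double Jfi = -p[P_GFI] * h * m_inf * (p[P_VFI] - V);
  const double Jsi = -si_fac * f;
  const double k_inf = th_c + (1.0 - th_c) * V * inv_vc;
  const double Jso = p[P_GSO] * k_inf;
  const double Jto = p[P_GTO] * r * s * (V - p[P_VTO]);
  return Jfi + Jsi + Jso + Jto;
}

// Per-run derived constants (reciprocal time constants keep divisions
// out of the inner loop; identical arithmetic up to fp rounding).
struct GateConsts {
  double ihp, ihm, ifp, ifm, irp, irm, isp, ism, vc, vr, vsw;
  void init(const double* p) {
    ihp = 1.0 / p[P_TAU_HP]; ihm = 1.0 / p[P_TAU_HM];
    ifp = 1.0 / p[P_TAU_FP]; ifm = 1.0 / p[P_TAU_FM];
    irp = 1.0 / p[P_TAU_RP]; irm = 1.0 / p[P_TAU_RM];
    isp = 1.0 / p[P_TAU_SP]; ism = 1.0 / p[P_TAU_SM];
    vc = p[P_VC]; vr = p[P_VR]; vsw = p[P_VSW];
  }
};

// Forward-Euler gate update (saturation kinetics with step-switched
// steady states and time constants).
inline void gate_step(double V, double& h, double& f, double& r, double& s,
                      const GateConsts& gc, double dt) {
  const bool up_c = V >= gc.vc;
  const bool up_r = V >= gc.vr;
  const bool up_s = V >= gc.vsw;
  const double hf_inf = up_c ? 0.0 : 1.0;
  h += dt * (hf_inf - h) * (up_c ? gc.ihm : gc.ihp);
  f += dt * (hf_inf - f) * (up_c ? gc.ifm : gc.ifp);
  r += dt * ((up_r ? 1.0 : 0.0) - r) * (up_r ? gc.irp : gc.irm);
  s += dt * ((up_s ? 0.0 : 1.0) - s) * (up_s ? gc.ism : gc.isp);
}
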