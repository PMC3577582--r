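#include <Rcpp.h>
#include "model.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Fast path: rectangular 1D/2D grid, scalar diffusion, no mask.
// Column-major layout (i + nx*j), zero-flux boundaries.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List run_sheet_cpp(List state, int nx, int ny, double D, double dx,
                   NumericVector params, double dt, double t0, int nsteps,
                   List events, IntegerVector probe_idx, int rec_steps,
                   int snap_steps, double snap_from, double snap_to) {
  const double* p = REAL(params);
  GateConsts gc; gc.init(p);
  const double inv_vc = 1.0 / p[P_VC];
  SiTable si; si.build(p);
  const int n = nx * ny;
  NumericVector V = clone(as<NumericVector>(state["V"]));
  NumericVector h = clone(as<NumericVector>(state["h"]));
  NumericVector f = clone(as<NumericVector>(state["f"]));
  NumericVector r = clone(as<NumericVector>(state["r"]));
  NumericVector s = clone(as<NumericVector>(state["s"]));
  std::vector<double> Vn(n);
  const double alpha = D / (dx * dx);

  const int nev = events.size();
  std::vector<IntegerVector> ev_idx; std::vector<double> ev_on, ev_off, ev_amp;
  for (int e = 0; e < nev; ++e) {
    List ev = events[e];
    ev_idx.push_back(as<IntegerVector>(ev["idx"]));
    ev_on.push_back(as<double>(ev["t_on"]));
    ev_off.push_back(as<double>(ev["t_off"]));
    ev_amp.push_back(as<double>(ev["amplitude"]));
  }

  const int npr = probe_idx.size();
  const int nrec = nsteps / rec_steps + 1;
  NumericVector t_out(nrec);
  NumericMatrix pr_out(nrec, npr);

  int nframes = 0;
  if (snap_steps > 0)
    for (int st = 0; st <= nsteps; st += snap_steps) {
      double t = t0 + st * dt;
      if (t >= snap_from && t <= snap_to) ++nframes;
    }
  NumericMatrix frames(snap_steps > 0 ? n : 0, nframes);
  NumericVector frame_t(nframes);
  int ifr = 0, irec = 0;

  double* Vp = REAL(V); double* hp = REAL(h); double* fp = REAL(f);
  double* rp = REAL(r); double* sp = REAL(s);

  for (int step = 0; step <= nsteps; ++step) {
    const double t = t0 + step * dt;
    if (step % rec_steps == 0 && irec < nrec) {
      t_out[irec] = t;
      for (int q = 0; q < npr; ++q) pr_out(irec, q) = Vp[probe_idx[q]];
      ++irec;
      double chk = 0.0;
      for (int k = 0; k < n; ++k) chk += Vp[k];
      if (!std::isfinite(chk))
        stop("non-finite field detected at t = %f ms", t);
    }
    if (snap_steps > 0 && step % snap_steps == 0 &&
        t >= snap_from && t <= snap_to && ifr < nframes) {
      std::copy(Vp, Vp + n, frames.begin() + (R_xlen_t)ifr * n);
      frame_t[ifr] = t; ++ifr;
    }
    if (step == nsteps) break;

    for (int j = 0; j < ny; ++j) {
      const int off = nx * j;
      for (int i = 0; i < nx; ++i) {
        const int k = off + i;
        const double Vk = Vp[k];
        double lap = 0.0;
        if (i > 0)      lap += Vp[k - 1]  - Vk;
        if (i < nx - 1) lap += Vp[k + 1]  - Vk;
        if (j > 0)      lap += Vp[k - nx] - Vk;
        if (j < ny - 1) lap += Vp[k + nx] - Vk;
        const double dV = alpha * lap -
          ionic_current(Vk, hp[k], fp[k], rp[k], sp[k], p, si(Vk), inv_vc);
        gate_step(Vk, hp[k], fp[k], rp[k], sp[k], gc, dt);
        Vn[k] = Vk + dt * dV;
      }
    }
    for (int e = 0; e < nev; ++e)
      if (t >= ev_on[e] && t < ev_off[e]) {
        const double add = ev_amp[e] * dt;
        const IntegerVector& ix = ev_idx[e];
        for (int q = 0; q < ix.size(); ++q) Vn[ix[q]] += add;
      }
    std::copy(Vn.begin(), Vn.end(), Vp);
  }

  return List::create(
    _["state"] = List::create(_["V"] = V, _["h"] = h, _["f"] = f,
                              _["r"] = r, _["s"] = s),
    _["t"] = t_out, _["probes"] = pr_out,
    _["frames"] = frames, _["frame_t"] = frame_t,
    _["t_end"] = t0 + nsteps * dt);
}

// ---------------------------------------------------------------------------
// General path: masked voxel grid (1-3D), scalar or transversely
// anisotropic tensor diffusion, conservative flux-form differencing.
// Every interior face carries a flux F; node rates get +F/-F, so the
// scheme conserves the field sum to round-off under zero-flux boundaries.
// ---------------------------------------------------------------------------

struct FaceOp {
  std::vector<int> fi, fj;          // voxel pair of each face
  std::vector<double> wn;           // normal-gradient weight (Daa_face/dx^2)
  std::vector<int> ptr;             // CSR pointers into cross-term arrays
  std::vector<int> cidx;
  std::vector<double> cw;
  std::vector<int> nodes;           // in-tissue voxel list
};

static inline int coord_ok(int c, int d) { return c >= 0 && c < d; }

// centered (mask-aware, one-sided fallback) difference stencil of axis b
// at voxel k, appended as (node, weight) pairs scaled by `scale`.
static void append_cdiff(int k, int b, const int* dims, const int* stride,
                         const int* mask, double scale,
                         std::vector<int>& cidx, std::vector<double>& cw) {
  int cb = (k / stride[b]) % dims[b];
  bool up = coord_ok(cb + 1, dims[b]) && mask[k + stride[b]];
  bool dn = coord_ok(cb - 1, dims[b]) && mask[k - stride[b]];
  if (up && dn) {
    cidx.push_back(k + stride[b]); cw.push_back(0.5 * scale);
    cidx.push_back(k - stride[b]); cw.push_back(-0.5 * scale);
  } else if (up) {
    cidx.push_back(k + stride[b]); cw.push_back(scale);
    cidx.push_back(k);             cw.push_back(-scale);
  } else if (dn) {
    cidx.push_back(k);             cw.push_back(scale);
    cidx.push_back(k - stride[b]); cw.push_back(-scale);
  }
}

static void build_faces(const IntegerVector& dims_in, double dx,
                        const IntegerVector& mask_in,
                        const NumericMatrix& tensor,  // nnodes x 6 (xx,yy,zz,xy,xz,yz)
                        FaceOp& op) {
  int dims[3] = {1, 1, 1};
  for (int a = 0; a < dims_in.size(); ++a) dims[a] = dims_in[a];
  const int n = dims[0] * dims[1] * dims[2];
  const int stride[3] = {1, dims[0], dims[0] * dims[1]};
  const int* mask = INTEGER(mask_in);
  const double inv_dx2 = 1.0 / (dx * dx);
  // component column of D_ab for axis pair (a,b)
  const int comp[3][3] = {{0, 3, 4}, {3, 1, 5}, {4, 5, 2}};

  for (int k = 0; k < n; ++k) if (mask[k]) op.nodes.push_back(k);
  op.ptr.push_back(0);
  for (int a = 0; a < 3; ++a) {
    if (dims[a] == 1) continue;
    for (size_t q = 0; q < op.nodes.size(); ++q) {
      const int u = op.nodes[q];
      const int ca = (u / stride[a]) % dims[a];
      if (!coord_ok(ca + 1, dims[a])) continue;
      const int v = u + stride[a];
      if (!mask[v]) continue;
      op.fi.push_back(u); op.fj.push_back(v);
      op.wn.push_back(0.5 * (tensor(u, comp[a][a]) + tensor(v, comp[a][a])) * inv_dx2);
      for (int b = 0; b < 3; ++b) {
        if (b == a || dims[b] == 1) continue;
        const double Dab = 0.5 * (tensor(u, comp[a][b]) + tensor(v, comp[a][b]));
        if (Dab == 0.0) continue;
        // 0.5 * (cdiff at u + cdiff at v), folded with Dab/dx^2
        append_cdiff(u, b, dims, stride, mask, 0.5 * Dab * inv_dx2, op.cidx, op.cw);
        append_cdiff(v, b, dims, stride, mask, 0.5 * Dab * inv_dx2, op.cidx, op.cw);
      }
      op.ptr.push_back((int)op.cidx.size());
    }
  }
}

static void apply_faces(const FaceOp& op, const double* V, double* rate) {
  const size_t nf = op.fi.size();
  for (size_t f = 0; f < nf; ++f) {
    double F = op.wn[f] * (V[op.fj[f]] - V[op.fi[f]]);
    for (int k = op.ptr[f]; k < op.ptr[f + 1]; ++k)
      F += op.cw[k] * V[op.cidx[k]];
    rate[op.fi[f]] += F;
    rate[op.fj[f]] -= F;
  }
}

// [[Rcpp::export]]
NumericVector diffusion_term_cpp(NumericVector V, IntegerVector dims,
                                 double dx, IntegerVector mask,
                                 NumericMatrix tensor) {
  FaceOp op;
  build_faces(dims, dx, mask, tensor, op);
  NumericVector out(V.size());
  std::vector<double> rate(V.size(), 0.0);
  apply_faces(op, REAL(V), rate.data());
  std::copy(rate.begin(), rate.end(), REAL(out));
  return out;
}

// [[Rcpp::export]]
List run_voxel_cpp(List state, IntegerVector dims, double dx,
                   IntegerVector mask, NumericMatrix tensor,
                   NumericVector params, double dt, double t0, int nsteps,
                   List events, IntegerVector probe_idx, int rec_steps,
                   bool record_dipole, NumericVector center) {
  const double* p = REAL(params);
  GateConsts gc; gc.init(p);
  const double inv_vc = 1.0 / p[P_VC];
  SiTable si; si.build(p);
  FaceOp op;
  build_faces(dims, dx, mask, tensor, op);
  const int n = as<NumericVector>(state["V"]).size();

  NumericVector V = clone(as<NumericVector>(state["V"]));
  NumericVector h = clone(as<NumericVector>(state["h"]));
  NumericVector f = clone(as<NumericVector>(state["f"]));
  NumericVector r = clone(as<NumericVector>(state["r"]));
  NumericVector s = clone(as<NumericVector>(state["s"]));
  double* Vp = REAL(V); double* hp = REAL(h); double* fp = REAL(f);
  double* rp = REAL(r); double* sp = REAL(s);
  std::vector<double> rate(n, 0.0);

  // dipole position weights r_i (cm) relative to the geometric center
  int d3[3] = {1, 1, 1};
  for (int a = 0; a < dims.size(); ++a) d3[a] = dims[a];
  std::vector<double> rx, ry, rz;
  if (record_dipole) {
    rx.resize(op.nodes.size()); ry.resize(op.nodes.size()); rz.resize(op.nodes.size());
    for (size_t q = 0; q < op.nodes.size(); ++q) {
      int k = op.nodes[q];
      rx[q] = (k % d3[0]) * dx - center[0];
      ry[q] = ((k / d3[0]) % d3[1]) * dx - center[1];
      rz[q] = (k / (d3[0] * d3[1])) * dx - center[2];
    }
  }
  const double vox = dx * dx * dx;

  const int nev = events.size();
  std::vector<IntegerVector> ev_idx; std::vector<double> ev_on, ev_off, ev_amp;
  for (int e = 0; e < nev; ++e) {
    List ev = events[e];
    ev_idx.push_back(as<IntegerVector>(ev["idx"]));
    ev_on.push_back(as<double>(ev["t_on"]));
    ev_off.push_back(as<double>(ev["t_off"]));
    ev_amp.push_back(as<double>(ev["amplitude"]));
  }

  const int npr = probe_idx.size();
  const int nrec = nsteps / rec_steps + 1;
  NumericVector t_out(nrec);
  NumericMatrix pr_out(nrec, npr);
  NumericMatrix dip_out(record_dipole ? nrec : 0, 3);
  int irec = 0;

  for (int step = 0; step <= nsteps; ++step) {
    const double t = t0 + step * dt;
    std::fill(rate.begin(), rate.end(), 0.0);
    apply_faces(op, Vp, rate.data());

    if (step % rec_steps == 0 && irec < nrec) {
      t_out[irec] = t;
      for (int q = 0; q < npr; ++q) pr_out(irec, q) = Vp[probe_idx[q]];
      if (record_dipole) {
        double Jx = 0, Jy = 0, Jz = 0;
        for (size_t q = 0; q < op.nodes.size(); ++q) {
          const double w = rate[op.nodes[q]] * vox;
          Jx += rx[q] * w; Jy += ry[q] * w; Jz += rz[q] * w;
        }
        dip_out(irec, 0) = Jx; dip_out(irec, 1) = Jy; dip_out(irec, 2) = Jz;
      }
      double chk = 0.0;
      for (size_t q = 0; q < op.nodes.size(); ++q) chk += Vp[op.nodes[q]];
      if (!std::isfinite(chk))
        stop("non-finite field detected at t = %f ms", t);
      ++irec;
    }
    if (step == nsteps) break;

    for (size_t q = 0; q < op.nodes.size(); ++q) {
      const int k = op.nodes[q];
      const double Vk = Vp[k];
      const double dV = rate[k] -
        ionic_current(Vk, hp[k], fp[k], rp[k], sp[k], p, si(Vk), inv_vc);
      gate_step(Vk, hp[k], fp[k], rp[k], sp[k], gc, dt);
      Vp[k] = Vk + dt * dV;
    }
    for (int e = 0; e < nev; ++e)
      if (t >= ev_on[e] && t < ev_off[e]) {
          const double add = ev_amp[e] * dt;
          const IntegerVector& ix = ev_idx[e];
          for (int q2 = 0; q2 < ix.size(); ++q2) Vp[ix[q2]] += add;
        }
  }

  return List::create(
    _["state"] = List::create(_["V"] = V, _["h"] = h, _["f"] = f,
                              _["r"] = r, _["s"] = s),
    _["t"] = t_out, _["probes"] = pr_out, _["dipole"] = dip_out,
    _["t_end"] = t0 + nsteps * dt);
}
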