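// Steady incompressible Navier-Stokes on a uniform staggered (MAC) voxel
// grid with SIMPLE pressure-velocity coupling.
//
//  - momentum: finite-volume, first-order upwind convection with an optional
//    deferred second-order-upwind correction, implicit diffusion; no-slip
//    walls enter through wall-distance-corrected one-sided gradients (the
//    true wall position along each grid line is supplied by the caller from
//    the implicit geometry, which restores near-second-order accuracy of
//    wall shear on the stair-step mesh);
//  - inlet: fixed normal velocity on the top grid plane; outlet: zero normal
//    gradient with global mass-flux correction and zero mean gauge pressure;
//  - pressure correction: SIMPLE with conjugate-gradient Poisson solve
//    (pure Neumann system, mean projected out);
//  - residuals are normalized by the largest raw residual of the first
//    iterations (standard practice for SIMPLE convergence monitoring).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double NEUMANN = 1e30;

struct Grid {
  int nx, ny, nz;
  double h;
  const int *mask; // 1 = lumen
  inline int ic(int i, int j, int k) const { return i + nx * (j + ny * k); }
  inline int iu(int i, int j, int k) const { return i + (nx + 1) * (j + ny * k); }
  inline int iv(int i, int j, int k) const { return i + nx * (j + (ny + 1) * k); }
  inline int iw(int i, int j, int k) const { return i + nx * (j + ny * k); } // k in 0..nz
  inline bool lum(int i, int j, int k) const {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    return mask[ic(i, j, k)] != 0;
  }
};

// face classification
enum { F_INACT = 0, F_ACT = 1, F_WALL = 2, F_INLET = 3, F_OUTLET = 4 };

struct Component {
  // one velocity component on its staggered grid
  int n;                       // total staggered slots
  std::vector<int8_t> type;
  std::vector<double> val;     // velocity value
  std::vector<double> ap;      // relaxed diagonal (active faces)
  std::vector<int> active;     // indices of active faces
  std::vector<int> ai, aj, ak; // coordinates of active faces
};

// assemble + sweep one momentum component. axis: 0=u,1=v,2=w.
// Returns raw L1 residual (unrelaxed equation).
static double momentum_sweep(const Grid &g, int axis, Component &C,
                             const Component &U, const Component &V,
                             const Component &W, const std::vector<double> &p,
                             const double *dists, // 4 lateral dist arrays, concatenated
                             double rho, double mu, double alpha,
                             bool sou, int nsweep) {
  const int nx = g.nx, ny = g.ny, nz = g.nz;
  const double h = g.h, A = h * h;
  const size_t nact = C.active.size();
  std::vector<double> aP(nact), b(nact);
  std::vector<double> anb(nact * 6);
  std::vector<int> nbi(nact * 6);

  // stride of a step along `dir` on this component's staggered grid
  int strides[3];
  if (axis == 0) { strides[0] = 1; strides[1] = nx + 1; strides[2] = (nx + 1) * ny; }
  else if (axis == 1) { strides[0] = 1; strides[1] = nx; strides[2] = nx * (ny + 1); }
  else { strides[0] = 1; strides[1] = nx; strides[2] = nx * ny; }

  double rawres = 0.0;

  for (size_t a = 0; a < nact; ++a) {
    const int f = C.active[a];
    const int i = C.ai[a], j = C.aj[a], k = C.ak[a];
    double ap_ = 0.0, b_ = 0.0;
    double anb_[6] = {0, 0, 0, 0, 0, 0};
    int nbi_[6] = {-1, -1, -1, -1, -1, -1};

    // outward volumetric transport at the 6 CV faces
    double Ft[6];
    if (axis == 0) { // u at x-face between cells (i-1,*) and (i,*)
      Ft[0] = -A * 0.5 * (U.val[g.iu(i - 1, j, k)] + U.val[f]);           // -x
      Ft[1] =  A * 0.5 * (U.val[g.iu(i + 1, j, k)] + U.val[f]);           // +x
      Ft[2] = -A * 0.5 * (V.val[g.iv(i - 1, j, k)] + V.val[g.iv(i, j, k)]);       // -y
      Ft[3] =  A * 0.5 * (V.val[g.iv(i - 1, j + 1, k)] + V.val[g.iv(i, j + 1, k)]); // +y
      Ft[4] = -A * 0.5 * (W.val[g.iw(i - 1, j, k)] + W.val[g.iw(i, j, k)]);       // -z
      Ft[5] =  A * 0.5 * (W.val[g.iw(i - 1, j, k + 1)] + W.val[g.iw(i, j, k + 1)]); // +z
    } else if (axis == 1) { // v at y-face between (*,j-1,*) and (*,j,*)
      Ft[0] = -A * 0.5 * (U.val[g.iu(i, j - 1, k)] + U.val[g.iu(i, j, k)]);
      Ft[1] =  A * 0.5 * (U.val[g.iu(i + 1, j - 1, k)] + U.val[g.iu(i + 1, j, k)]);
      Ft[2] = -A * 0.5 * (V.val[g.iv(i, j - 1, k)] + V.val[f]);
      Ft[3] =  A * 0.5 * (V.val[g.iv(i, j + 1, k)] + V.val[f]);
      Ft[4] = -A * 0.5 * (W.val[g.iw(i, j - 1, k)] + W.val[g.iw(i, j, k)]);
      Ft[5] =  A * 0.5 * (W.val[g.iw(i, j - 1, k + 1)] + W.val[g.iw(i, j, k + 1)]);
    } else { // w at z-face between (*,*,k-1) and (*,*,k)
      Ft[0] = -A * 0.5 * (U.val[g.iu(i, j, k - 1)] + U.val[g.iu(i, j, k)]);
      Ft[1] =  A * 0.5 * (U.val[g.iu(i + 1, j, k - 1)] + U.val[g.iu(i + 1, j, k)]);
      Ft[2] = -A * 0.5 * (V.val[g.iv(i, j, k - 1)] + V.val[g.iv(i, j, k)]);
      Ft[3] =  A * 0.5 * (V.val[g.iv(i, j + 1, k - 1)] + V.val[g.iv(i, j + 1, k)]);
      Ft[4] = -A * 0.5 * (W.val[g.iw(i, j, k - 1)] + W.val[f]);
      Ft[5] =  A * 0.5 * (W.val[g.iw(i, j, k + 1)] + W.val[f]);
    }

    for (int d = 0; d < 6; ++d) {
      const int dir = d / 2;         // 0=x,1=y,2=z
      const int sgn = (d % 2) ? 1 : -1;
      const int nb = f + sgn * strides[dir];
      const double F = rho * Ft[d];
      const int8_t nt = (nb >= 0 && nb < C.n) ? C.type[nb] : (int8_t)F_INACT;

      if (nt == F_ACT) {
        nbi_[d] = nb;
        anb_[d] += std::max(-F, 0.0);
        ap_ += std::max(F, 0.0);
        ap_ += mu * h; // diffusion, A/h = h
        anb_[d] += mu * h;
        if (sou) {
          // deferred second-order upwind: face value extrapolated from the
          // upwind side; falls back to first order at walls/ports
          double phiU, phiUU;
          bool have = false;
          if (F >= 0) { // upwind = this face
            phiU = C.val[f];
            const int uu = f - sgn * strides[dir];
            if (uu >= 0 && uu < C.n && C.type[uu] == F_ACT) { phiUU = C.val[uu]; have = true; }
          } else {      // upwind = neighbor
            phiU = C.val[nb];
            const int uu = nb + sgn * strides[dir];
            if (uu >= 0 && uu < C.n && C.type[uu] == F_ACT) { phiUU = C.val[uu]; have = true; }
          }
          if (have) b_ -= F * 0.5 * (phiU - phiUU);
        }
      } else if (nt == F_WALL && dir != axis) {
        // lateral staircase wall: no-slip at the bisected wall distance
        nbi_[d] = -1;
        ap_ += std::max(F, 0.0);
        anb_[d] = -1.0; // sentinel: distance-based diffusion below
      } else if (nt == F_WALL || nt == F_INLET || nt == F_OUTLET) {
        const double vb = C.val[nb];
        anb_[d] = 0.0;
        ap_ += std::max(F, 0.0);
        b_ += std::max(-F, 0.0) * vb;
        ap_ += mu * h;
        b_ += mu * h * vb;
        nbi_[d] = -1;
      } else {
        // no neighbor slot: lateral wall or port plane; the wall-distance
        // array decides Dirichlet-0 (at distance) vs Neumann (outflow).
        // Convection: outward flux leaves with the upwind value, inward
        // flux carries zero tangential velocity.
        nbi_[d] = -1;
        ap_ += std::max(F, 0.0);
        anb_[d] = -1.0; // sentinel: diffusion handled below
      }
    }

    // lateral wall-distance diffusion for missing neighbors: dists holds 4
    // arrays (two lateral directions, +/-) packed per component slot
    for (int d = 0; d < 6; ++d) {
      if (anb_[d] >= 0.0) continue;
      anb_[d] = 0.0;
      const int dir = d / 2;
      if (dir == axis) { // streamwise missing neighbor: treat as wall at h
        ap_ += mu * h;
        continue;
      }
      // lateral index within the packed array: order (-x,+x,-y,+y,-z,+z)
      // skipping the component's own axis
      int slot = 0, cnt = 0;
      for (int dd = 0; dd < 6; ++dd) {
        if (dd / 2 == axis) continue;
        if (dd == d) { slot = cnt; break; }
        ++cnt;
      }
      const double dist = dists[(size_t)slot * (size_t)C.n + (size_t)f];
      if (dist >= NEUMANN) continue;           // zero-gradient (outlet plane)
      const double dd = (dist > 1e-12) ? dist : 0.5 * h;
      ap_ += mu * A / dd;                      // Dirichlet 0 at distance dd
    }

    // pressure gradient across the face
    if (axis == 0) b_ += (p[g.ic(i - 1, j, k)] - p[g.ic(i, j, k)]) * A;
    else if (axis == 1) b_ += (p[g.ic(i, j - 1, k)] - p[g.ic(i, j, k)]) * A;
    else b_ += (p[g.ic(i, j, k - 1)] - p[g.ic(i, j, k)]) * A;

    // raw residual of the unrelaxed equation
    double res = ap_ * C.val[f] - b_;
    for (int d = 0; d < 6; ++d) if (nbi_[d] >= 0) res -= anb_[d] * C.val[nbi_[d]];
    rawres += std::fabs(res);

    // implicit under-relaxation
    const double apr = ap_ / alpha;
    b_ += (apr - ap_) * C.val[f];
    aP[a] = apr; b[a] = b_;
    for (int d = 0; d < 6; ++d) { anb[a * 6 + d] = anb_[d]; nbi[a * 6 + d] = nbi_[d]; }
    C.ap[f] = apr;
  }

  for (int s = 0; s < nsweep; ++s) {
    for (size_t a = 0; a < nact; ++a) {
      double acc = b[a];
      for (int d = 0; d < 6; ++d) {
        const int nb = nbi[a * 6 + d];
        if (nb >= 0) acc += anb[a * 6 + d] * C.val[nb];
      }
      C.val[C.active[a]] = acc / aP[a];
    }
  }
  return rawres;
}

// [[Rcpp::export]]
List solve_simple_cpp(IntegerVector dims, double h, IntegerVector mask,
                      NumericVector inlet_w,  // (nx*ny), fixed w at k=nz (<=0)
                      NumericVector dist_u, NumericVector dist_v, NumericVector dist_w,
                      double rho, double mu, double tol, int max_iter,
                      double alpha_u, double alpha_p,
                      int sou_after, int nsweep, int verbose) {
  Grid g{dims[0], dims[1], dims[2], h, INTEGER(mask)};
  const int nx = g.nx, ny = g.ny, nz = g.nz;
  const double A = h * h;

  Component U, V, W;
  U.n = (nx + 1) * ny * nz; V.n = nx * (ny + 1) * nz; W.n = nx * ny * (nz + 1);
  for (Component *C : {&U, &V, &W}) {
    C->type.assign(C->n, F_INACT);
    C->val.assign(C->n, 0.0);
    C->ap.assign(C->n, 1.0);
  }

  // classify faces
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        const bool a = g.lum(i - 1, j, k), b = g.lum(i, j, k);
        const int f = g.iu(i, j, k);
        if (a && b) { U.type[f] = F_ACT; U.active.push_back(f); U.ai.push_back(i); U.aj.push_back(j); U.ak.push_back(k); }
        else if (a || b) U.type[f] = F_WALL;
      }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const bool a = g.lum(i, j - 1, k), b = g.lum(i, j, k);
        const int f = g.iv(i, j, k);
        if (a && b) { V.type[f] = F_ACT; V.active.push_back(f); V.ai.push_back(i); V.aj.push_back(j); V.ak.push_back(k); }
        else if (a || b) V.type[f] = F_WALL;
      }
  int n_out = 0;
  for (int k = 0; k <= nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const bool a = g.lum(i, j, k - 1), b = g.lum(i, j, k);
        const int f = g.iw(i, j, k);
        if (a && b) { W.type[f] = F_ACT; W.active.push_back(f); W.ai.push_back(i); W.aj.push_back(j); W.ak.push_back(k); }
        else if (k == nz && a) { W.type[f] = F_INLET; W.val[f] = inlet_w[i + nx * j]; }
        else if (k == 0 && b) { W.type[f] = F_OUTLET; ++n_out; }
        else if (a || b) W.type[f] = F_WALL;
      }

  // inflow
  double Qin = 0.0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (W.type[g.iw(i, j, nz)] == F_INLET) Qin -= W.val[g.iw(i, j, nz)] * A;
  if (Qin <= 0) stop("inlet flux must be positive");

  // initial plug outflow
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (W.type[g.iw(i, j, 0)] == F_OUTLET) W.val[g.iw(i, j, 0)] = -Qin / (n_out * A);

  const int ncell = nx * ny * nz;
  std::vector<double> p(ncell, 0.0), pc(ncell, 0.0);

  // CG work arrays
  std::vector<double> r(ncell), z(ncell), q(ncell);
  std::vector<int> cells;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (g.lum(i, j, k)) cells.push_back(g.ic(i, j, k));

  NumericMatrix resid_hist(max_iter, 4);
  double scale_u = -1, scale_v = -1, scale_w = -1, scale_c = rho * Qin;
  bool converged = false;
  int it_done = 0;

  auto outlet_correct = [&]() {
    // zero-gradient extrapolation plus a uniform additive shift that
    // restores exact global mass balance
    double Qraw = 0.0;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int f = g.iw(i, j, 0);
        if (W.type[f] == F_OUTLET) {
          double wa = (W.type[g.iw(i, j, 1)] != F_INACT) ? W.val[g.iw(i, j, 1)] : W.val[f];
          W.val[f] = wa;
          Qraw -= wa * A;
        }
      }
    const double shift = (Qin - Qraw) / (n_out * A);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int f = g.iw(i, j, 0);
        if (W.type[f] == F_OUTLET) W.val[f] -= shift;
      }
  };

  for (int it = 0; it < max_iter; ++it) {
    const bool sou = (it >= sou_after);
    outlet_correct();
    const double ru = momentum_sweep(g, 0, U, U, V, W, p, REAL(dist_u), rho, mu, alpha_u, sou, nsweep);
    const double rv = momentum_sweep(g, 1, V, U, V, W, p, REAL(dist_v), rho, mu, alpha_u, sou, nsweep);
    const double rw = momentum_sweep(g, 2, W, U, V, W, p, REAL(dist_w), rho, mu, alpha_u, sou, nsweep);
    outlet_correct();

    // pressure-correction coefficients d = A / aP on active faces
    auto du = [&](int f) { return (U.type[f] == F_ACT) ? A / U.ap[f] : 0.0; };
    auto dv = [&](int f) { return (V.type[f] == F_ACT) ? A / V.ap[f] : 0.0; };
    auto dw = [&](int f) { return (W.type[f] == F_ACT) ? A / W.ap[f] : 0.0; };

    // continuity imbalance
    double rc = 0.0, bsum = 0.0;
    std::fill(r.begin(), r.end(), 0.0);
    for (int c : cells) {
      const int k = c / (nx * ny), j = (c / nx) % ny, i = c % nx;
      const double m = rho * A * (U.val[g.iu(i + 1, j, k)] - U.val[g.iu(i, j, k)] +
                                  V.val[g.iv(i, j + 1, k)] - V.val[g.iv(i, j, k)] +
                                  W.val[g.iw(i, j, k + 1)] - W.val[g.iw(i, j, k)]);
      r[c] = -m;
      rc += std::fabs(m);
      bsum += -m;
    }
    // project out the mean (pure Neumann system)
    const double mean_b = bsum / cells.size();
    for (int c : cells) r[c] -= mean_b;

    // CG on  a_P pc_P - sum a_nb pc_nb = r
    std::fill(pc.begin(), pc.end(), 0.0);
    auto applyA = [&](const std::vector<double> &x, std::vector<double> &y) {
      for (int c : cells) {
        const int k = c / (nx * ny), j = (c / nx) % ny, i = c % nx;
        const double cxm = rho * A * du(g.iu(i, j, k));
        const double cxp = rho * A * du(g.iu(i + 1, j, k));
        const double cym = rho * A * dv(g.iv(i, j, k));
        const double cyp = rho * A * dv(g.iv(i, j + 1, k));
        const double czm = rho * A * dw(g.iw(i, j, k));
        const double czp = rho * A * dw(g.iw(i, j, k + 1));
        double acc = (cxm + cxp + cym + cyp + czm + czp) * x[c];
        if (cxm > 0) acc -= cxm * x[c - 1];
        if (cxp > 0) acc -= cxp * x[c + 1];
        if (cym > 0) acc -= cym * x[c - nx];
        if (cyp > 0) acc -= cyp * x[c + nx];
        if (czm > 0) acc -= czm * x[c - nx * ny];
        if (czp > 0) acc -= czp * x[c + nx * ny];
        y[c] = acc;
      }
    };
    std::vector<double> rr = r, pdir = r, Ap(ncell, 0.0);
    double rs = 0.0;
    for (int c : cells) rs += rr[c] * rr[c];
    const double rs0 = rs;
    for (int cg = 0; cg < 500 && rs > 1e-6 * rs0 && rs > 1e-300; ++cg) {
      applyA(pdir, Ap);
      double pAp = 0.0;
      for (int c : cells) pAp += pdir[c] * Ap[c];
      if (pAp <= 0) break;
      const double alpha = rs / pAp;
      for (int c : cells) { pc[c] += alpha * pdir[c]; rr[c] -= alpha * Ap[c]; }
      double rs2 = 0.0;
      for (int c : cells) rs2 += rr[c] * rr[c];
      const double beta = rs2 / rs;
      rs = rs2;
      for (int c : cells) pdir[c] = rr[c] + beta * pdir[c];
    }
    // remove mean of the correction
    double mpc = 0.0;
    for (int c : cells) mpc += pc[c];
    mpc /= cells.size();
    for (int c : cells) pc[c] -= mpc;

    // corrections
    for (int c : cells) p[c] += alpha_p * pc[c];
    for (size_t a = 0; a < U.active.size(); ++a) {
      const int f = U.active[a];
      U.val[f] += du(f) * (pc[g.ic(U.ai[a] - 1, U.aj[a], U.ak[a])] - pc[g.ic(U.ai[a], U.aj[a], U.ak[a])]);
    }
    for (size_t a = 0; a < V.active.size(); ++a) {
      const int f = V.active[a];
      V.val[f] += dv(f) * (pc[g.ic(V.ai[a], V.aj[a] - 1, V.ak[a])] - pc[g.ic(V.ai[a], V.aj[a], V.ak[a])]);
    }
    for (size_t a = 0; a < W.active.size(); ++a) {
      const int f = W.active[a];
      W.val[f] += dw(f) * (pc[g.ic(W.ai[a], W.aj[a], W.ak[a] - 1)] - pc[g.ic(W.ai[a], W.aj[a], W.ak[a])]);
    }

    // scaled residuals (normalized by the max over the first iterations)
    if (it < 5) {
      scale_u = std::max(scale_u, ru); scale_v = std::max(scale_v, rv);
      scale_w = std::max(scale_w, rw); scale_c = std::max(scale_c, rc);
    }
    const double su = ru / std::max(scale_u, 1e-300);
    const double sv = rv / std::max(scale_v, 1e-300);
    const double sw = rw / std::max(scale_w, 1e-300);
    const double sc = rc / std::max(scale_c, 1e-300);
    resid_hist(it, 0) = su; resid_hist(it, 1) = sv;
    resid_hist(it, 2) = sw; resid_hist(it, 3) = sc;
    it_done = it + 1;
    if (verbose && (it % 200 == 0)) {
      Rcpp::Rcout << "iter " << it << "  res u " << su << " v " << sv
                  << " w " << sw << " cont " << sc << "\n";
    }
    if (it > 10 && su < tol && sv < tol && sw < tol && sc < tol) {
      converged = true;
      break;
    }
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }

  outlet_correct();

  // gauge: zero mean pressure in the outlet-adjacent cell layer
  double pout = 0.0; int nout = 0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (W.type[g.iw(i, j, 0)] == F_OUTLET) { pout += p[g.ic(i, j, 0)]; ++nout; }
  if (nout) { pout /= nout; for (int c : cells) p[c] -= pout; }

  double Qout = 0.0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (W.type[g.iw(i, j, 0)] == F_OUTLET) Qout -= W.val[g.iw(i, j, 0)] * A;

  return List::create(_["u"] = NumericVector(U.val.begin(), U.val.end()),
                      _["v"] = NumericVector(V.val.begin(), V.val.end()),
                      _["w"] = NumericVector(W.val.begin(), W.val.end()),
                      _["p"] = NumericVector(p.begin(), p.end()),
                      _["residuals"] = resid_hist(Range(0, it_done - 1), _),
                      _["iterations"] = it_done,
                      _["converged"] = converged,
                      _["Q_in"] = Qin, _["Q_out"] = Qout);
}
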