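#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Explicit diffusion sub-steps on a packed active-voxel set.
//
// conc_active : concentrations on active voxels (packed order)
// nbr         : nActive x 6 matrix; entry >= 0 is the packed index of the
//               face neighbour, -1 a perfect-sink neighbour (value 0),
//               -2 a sealed (reflecting) face.
// alpha       : D * dt_sub / h^2 (must be <= 1/6 for stability)
// nsub        : number of sub-steps making up one tick
// ---------------------------------------------------------------------------
// conc: nActive x nspecies matrix (each column one species sharing the
// same alpha). nbr: nActive x 6, entries in [0, nActive]: a real packed
// neighbour index, nActive for a sink face (a phantom voxel held at
// zero), or the voxel's own index for a sealed face (zero flux). The
// boundary outflux is recovered as the change in total mass.
// [[Rcpp::export]]
List diffuse_sub_cpp(NumericMatrix conc, IntegerMatrix nbr,
                     double alpha, int nsub) {
  int n = conc.nrow(), m = conc.ncol();
  if (nbr.nrow() != n) stop("neighbour table does not match active set");
  // contiguous neighbour table, 6 entries per voxel
  std::vector<int> nb(6 * (size_t)n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 6; ++k) nb[6 * (size_t)i + k] = nbr(i, k);
  NumericMatrix out(n, m);
  NumericVector outflux(m);
  std::vector<double> a((size_t)n + 1), b((size_t)n + 1, 0.0);
  for (int sp = 0; sp < m; ++sp) {
    double mass0 = 0.0;
    for (int i = 0; i < n; ++i) { a[i] = conc(i, sp); mass0 += a[i]; }
    a[n] = 0.0;                       // phantom sink voxel
    for (int s = 0; s < nsub; ++s) {
      for (int i = 0; i < n; ++i) {
        const int *p = &nb[6 * (size_t)i];
        double acc = a[p[0]] + a[p[1]] + a[p[2]] + a[p[3]] + a[p[4]]
                     + a[p[5]];
        b[i] = (1.0 - 6.0 * alpha) * a[i] + alpha * acc;
      }
      b[n] = 0.0;
      a.swap(b);
    }
    double mass1 = 0.0;
    for (int i = 0; i < n; ++i) { out(i, sp) = a[i]; mass1 += a[i]; }
    outflux[sp] = mass0 - mass1;
  }
  return List::create(_["conc"] = out, _["outflux"] = outflux);
}

// ---------------------------------------------------------------------------
// One chemotaxis step for every mobile agent (26-connected neighbourhood).
// Agents move to the admissible neighbouring wall voxel (free capacity for
// the agent's volume) with the highest chemoattractant, provided it is
// strictly higher than the current voxel's; ties are broken uniformly at
// random using R's RNG. `occupied` is updated in place on a local copy and
// returned together with the new voxel assignment.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List chemotaxis_step_cpp(IntegerVector vox, NumericVector vol,
                         IntegerVector order, NumericVector occupied,
                         IntegerVector cls, NumericVector attract,
                         IntegerVector dims, double capacity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nxy = nx * ny;
  int n = vox.size();
  IntegerVector newvox = clone(vox);
  NumericVector occ = clone(occupied);
  std::vector<int> cand(26);

  for (int oo = 0; oo < n; ++oo) {
    int a = order[oo];                 // 0-based agent id
    int v = newvox[a] - 1;             // 0-based linear index
    int k = v / nxy, rem = v % nxy, j = rem / nx, i = rem % nx;
    double best = attract[v];
    int nbest = 0;
    for (int dz = -1; dz <= 1; ++dz) {
      int kk = k + dz;
      if (kk < 0 || kk >= nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int jj = j + dy;
        if (jj < 0 || jj >= ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int ii = i + dx;
          if (ii < 0 || ii >= nx) continue;
          int w = ii + jj * nx + kk * nxy;
          if (cls[w] != 2) continue;                      // WALL only
          if (occ[w] + vol[a] > capacity + 1e-9) continue; // no space
          double s = attract[w];
          if (s > best + 1e-15) {
            best = s; nbest = 1; cand[0] = w;
          } else if (nbest > 0 && std::abs(s - best) <= 1e-15) {
            cand[nbest++] = w;
          }
        }
      }
    }
    if (nbest > 0) {
      int pick = cand[0];
      if (nbest > 1) {
        int u = (int)std::floor(unif_rand() * nbest);
        if (u >= nbest) u = nbest - 1;
        pick = cand[u];
      }
      occ[v] -= vol[a];
      occ[pick] += vol[a];
      newvox[a] = pick + 1;
    }
  }
  return List::create(_["vox"] = newvox, _["occupied"] = occ);
}

// ---------------------------------------------------------------------------
// Steady axisymmetric stream-function / vorticity solver on the
// area-equivalent profile R(z). Pseudo-time marching of chi = omega/r with
// first-order upwind convection, SOR for the stream function, Thom-type
// wall vorticity. Returns wall shear stress per xi node (Pa, signed:
// negative inside a recirculation bubble).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List axisym_solve_cpp(NumericVector Rz, double dxi, double Q, double mu,
                      double rho, int neta, int max_outer, double tol,
                      Nullable<NumericMatrix> psi0 = R_NilValue,
                      Nullable<NumericMatrix> chi0 = R_NilValue) {
  int nxi = Rz.size();
  double nu = mu / rho;
  double deta = 1.0 / (neta - 1);
  double psiw = Q / (2.0 * M_PI);

  NumericMatrix psi(nxi, neta), chi(nxi, neta);
  bool warm = psi0.isNotNull() && chi0.isNotNull();
  if (warm) {
    NumericMatrix p0(psi0.get()), c0(chi0.get());
    if (p0.nrow() == nxi && p0.ncol() == neta) {
      psi = clone(p0); chi = clone(c0);
    } else warm = false;
  }
  if (!warm) {
    for (int i = 0; i < nxi; ++i) {
      double chip = 4.0 * Q / (M_PI * std::pow(Rz[i], 4));
      for (int j = 0; j < neta; ++j) {
        double eta = j * deta;
        psi(i, j) = psiw * (2.0 * eta * eta - std::pow(eta, 4));
        chi(i, j) = chip;
      }
    }
  }

  // metric terms
  std::vector<double> Rp(nxi), Rpp(nxi);
  for (int i = 0; i < nxi; ++i) {
    int im = std::max(i - 1, 0), ip = std::min(i + 1, nxi - 1);
    Rp[i] = (Rz[ip] - Rz[im]) / ((ip - im) * dxi);
    Rpp[i] = (i > 0 && i < nxi - 1)
      ? (Rz[i + 1] - 2.0 * Rz[i] + Rz[i - 1]) / (dxi * dxi) : 0.0;
  }

  // inlet profile (fixed) and wall/axis boundary values
  double chi_in = 4.0 * Q / (M_PI * std::pow(Rz[0], 4));
  for (int j = 0; j < neta; ++j) {
    double eta = j * deta;
    psi(0, j) = psiw * (2.0 * eta * eta - std::pow(eta, 4));
    chi(0, j) = chi_in;
  }
  for (int i = 0; i < nxi; ++i) {
    psi(i, 0) = 0.0;
    psi(i, neta - 1) = psiw;
  }

  // stability limit for the pseudo-time step (recomputed from velocities
  // every outer cycle block)
  double omega_sor = 1.5, relax_wall = 0.4;
  NumericMatrix chin(nxi, neta);
  std::vector<double> tau_prev(nxi, 0.0);
  double resid = 1e30;
  int outer;
  double umax = Q / (M_PI * Rz[0] * Rz[0]) * 2.0;

  for (outer = 0; outer < max_outer; ++outer) {
    // ---- SOR sweeps for psi (2 per outer cycle)
    for (int sweep = 0; sweep < 2; ++sweep) {
      for (int i = 1; i < nxi - 1; ++i) {
        double R = Rz[i], s = Rp[i] / R;
        double g = (2.0 * Rp[i] * Rp[i] - R * Rpp[i]) / (R * R);
        for (int j = 1; j < neta - 1; ++j) {
          double eta = j * deta;
          double r = eta * R;
          double Aee = eta * eta * s * s + 1.0 / (R * R);
          double Axe = -2.0 * eta * s;
          double Ae = eta * g - 1.0 / (eta * R * R);
          double pxx = (psi(i + 1, j) + psi(i - 1, j)) / (dxi * dxi);
          double pee = (psi(i, j + 1) + psi(i, j - 1)) / (deta * deta);
          double pxe = (psi(i + 1, j + 1) - psi(i + 1, j - 1)
                        - psi(i - 1, j + 1) + psi(i - 1, j - 1))
                       / (4.0 * dxi * deta);
          double pe = (psi(i, j + 1) - psi(i, j - 1)) / (2.0 * deta);
          double diag = -2.0 / (dxi * dxi) - 2.0 * Aee / (deta * deta);
          double rhs = -(pxx + Aee * pee + Axe * pxe + Ae * pe
                         + r * r * chi(i, j)) - diag * psi(i, j);
          psi(i, j) += omega_sor * (rhs / diag);
        }
      }
      // outlet: zero gradient
      for (int j = 0; j < neta; ++j) psi(nxi - 1, j) = psi(nxi - 2, j);
    }

    // ---- wall vorticity (Thom), under-relaxed
    for (int i = 1; i < nxi; ++i) {
      double R = Rz[i];
      double gam = 2.0 * (psiw - psi(i, neta - 2))
                   / (std::pow(R, 3) * deta * deta);       // du_s/dn at wall
      double target = gam / R;                              // chi = omega/r
      chi(i, neta - 1) = (1.0 - relax_wall) * chi(i, neta - 1)
                         + relax_wall * target;
    }

    // ---- pseudo-time step for chi
    // velocity scale and dt
    double dtmin = 1e30;
    for (int i = 1; i < nxi - 1; ++i) {
      double R = Rz[i];
      double Aee = 1.0 / (R * R);
      double diff = 2.0 * nu * (1.0 / (dxi * dxi) + Aee / (deta * deta))
                    + 3.0 * nu / (deta * deta * R * R);
      double conv = umax / dxi + umax / (R * deta);
      double dt = 1.0 / (diff + conv);
      if (dt < dtmin) dtmin = dt;
    }
    double dt = 0.35 * dtmin;

    double umax_new = 0.0;
    for (int i = 1; i < nxi - 1; ++i) {
      double R = Rz[i], s = Rp[i] / R;
      double g = (2.0 * Rp[i] * Rp[i] - R * Rpp[i]) / (R * R);
      for (int j = 1; j < neta - 1; ++j) {
        double eta = j * deta;
        double pe = (psi(i, j + 1) - psi(i, j - 1)) / (2.0 * deta);
        double px = (psi(i + 1, j) - psi(i - 1, j)) / (2.0 * dxi);
        double uz = pe / (eta * R * R);
        double ur = -(px - eta * s * pe) / (eta * R);
        double az = uz;                              // coeff of chi_xi
        double ae = ur / R - uz * eta * s;           // coeff of chi_eta
        double am = std::abs(uz) + std::abs(ur);
        if (am > umax_new) umax_new = am;

        // upwind first derivatives
        double cxu = (az >= 0) ? (chi(i, j) - chi(i - 1, j)) / dxi
                               : (chi(i + 1, j) - chi(i, j)) / dxi;
        double ceu = (ae >= 0) ? (chi(i, j) - chi(i, j - 1)) / deta
                               : (chi(i, j + 1) - chi(i, j)) / deta;
        // diffusion (central); the near-axis 3/r term is one-sided for
        // stability at the first ring of nodes
        double Aee = eta * eta * s * s + 1.0 / (R * R);
        double cxx = (chi(i + 1, j) - 2.0 * chi(i, j) + chi(i - 1, j))
                     / (dxi * dxi);
        double cee = (chi(i, j + 1) - 2.0 * chi(i, j) + chi(i, j - 1))
                     / (deta * deta);
        double cxe = (chi(i + 1, j + 1) - chi(i + 1, j - 1)
                      - chi(i - 1, j + 1) + chi(i - 1, j - 1))
                     / (4.0 * dxi * deta);
        double ce = (chi(i, j + 1) - chi(i, j - 1)) / (2.0 * deta);
        double cef = (chi(i, j + 1) - chi(i, j)) / deta;
        double lap = cxx + Aee * cee - 2.0 * eta * s * cxe + eta * g * ce
                     + 3.0 / (eta * R * R) * cef;
        chin(i, j) = chi(i, j) + dt * (nu * lap - az * cxu - ae * ceu);
      }
    }
    umax = std::max(umax_new, 1e-6);

    for (int i = 1; i < nxi - 1; ++i)
      for (int j = 1; j < neta - 1; ++j) chi(i, j) = chin(i, j);
    // axis symmetry + outlet
    for (int i = 1; i < nxi; ++i) chi(i, 0) = chi(i, 1);
    for (int j = 0; j < neta; ++j) chi(nxi - 1, j) = chi(nxi - 2, j);

    // convergence: wall shear profile stationary between checks
    if (outer % 100 == 99) {
      double dmax = 0.0, tmax = 1e-30;
      for (int i = 1; i < nxi - 1; ++i) {
        double gam = 2.0 * (psiw - psi(i, neta - 2))
                     / (std::pow(Rz[i], 3) * deta * deta);
        double t = mu * gam;
        double d = std::abs(t - tau_prev[i]);
        if (d > dmax) dmax = d;
        if (std::abs(t) > tmax) tmax = std::abs(t);
        tau_prev[i] = t;
      }
      resid = dmax / tmax;
      if (outer > 500 && resid < tol) break;
    }
  }

  // wall shear stress: tau = mu * du_s/dn, mild-slope approximation
  NumericVector tau(nxi);
  for (int i = 0; i < nxi; ++i) {
    double R = Rz[i];
    double gam = 2.0 * (psiw - psi(i, neta - 2))
                 / (std::pow(R, 3) * deta * deta);
    tau[i] = mu * gam / std::sqrt(1.0 + Rp[i] * Rp[i]);
  }
  return List::create(_["tau"] = tau, _["psi"] = psi, _["chi"] = chi,
                      _["iters"] = outer + 1, _["resid"] = resid);
}
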