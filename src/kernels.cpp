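#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Voxel-centred convention: voxel (ix,iy,iz), 0-based, sits at coordinate
// (ix,iy,iz) in voxel units. Linear index = ix + n1*(iy + n2*iz), matching
// R array order. All kernels are deterministic and single-threaded.

static inline int lin(int ix, int iy, int iz, int n1, int n2) {
  return ix + n1 * (iy + n2 * iz);
}

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// ---------------------------------------------------------------------------
// 7-point Neumann (zero-flux) Laplacian: (Lu)_i = sum_nb (u_nb - u_i).
static void laplacian(const double *u, double *out, int n1, int n2, int n3) {
  for (int iz = 0; iz < n3; ++iz)
    for (int iy = 0; iy < n2; ++iy)
      for (int ix = 0; ix < n1; ++ix) {
        const int i = lin(ix, iy, iz, n1, n2);
        double acc = 0.0;
        if (ix > 0)      acc += u[i - 1]       - u[i];
        if (ix < n1 - 1) acc += u[i + 1]       - u[i];
        if (iy > 0)      acc += u[i - n1]      - u[i];
        if (iy < n2 - 1) acc += u[i + n1]      - u[i];
        if (iz > 0)      acc += u[i - n1 * n2] - u[i];
        if (iz < n3 - 1) acc += u[i + n1 * n2] - u[i];
        out[i] = acc;
      }
}

// [[Rcpp::export(name = ".cppLaplacian")]]
NumericVector cppLaplacian(NumericVector u, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericVector out(u.size());
  laplacian(u.begin(), out.begin(), n1, n2, n3);
  out.attr("dim") = dims;
  return out;
}

// Conjugate gradient for (I - sigma*L) x = b. SPD for sigma >= 0 because
// -L is positive semidefinite under Neumann boundaries.
static int diffuse_cg(const double *b, double *x, int n1, int n2, int n3,
                      double sigma, double tol, int maxit, double *resid_out) {
  const int n = n1 * n2 * n3;
  if (sigma == 0.0) {
    std::copy(b, b + n, x);
    if (resid_out) *resid_out = 0.0;
    return 0;
  }
  std::vector<double> r(n), p(n), Ap(n), lap(n);
  std::copy(b, b + n, x);                    // warm start at b
  laplacian(x, lap.data(), n1, n2, n3);
  double bnorm2 = 0.0, rr = 0.0;
  for (int i = 0; i < n; ++i) {
    const double Ax = x[i] - sigma * lap[i];
    r[i] = b[i] - Ax;
    p[i] = r[i];
    bnorm2 += b[i] * b[i];
    rr += r[i] * r[i];
  }
  const double stop2 = tol * tol * (bnorm2 > 0 ? bnorm2 : 1.0);
  int it = 0;
  while (rr > stop2 && it < maxit) {
    laplacian(p.data(), lap.data(), n1, n2, n3);
    double pAp = 0.0;
    for (int i = 0; i < n; ++i) {
      Ap[i] = p[i] - sigma * lap[i];
      pAp += p[i] * Ap[i];
    }
    if (pAp <= 0.0) break;
    const double alpha = rr / pAp;
    double rr_new = 0.0;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * Ap[i];
      rr_new += r[i] * r[i];
    }
    const double beta = rr_new / rr;
    for (int i = 0; i < n; ++i) p[i] = r[i] + beta * p[i];
    rr = rr_new;
    ++it;
  }
  if (resid_out) *resid_out = std::sqrt(rr / (bnorm2 > 0 ? bnorm2 : 1.0));
  return it;
}

// [[Rcpp::export(name = ".cppDiffuseCG")]]
List cppDiffuseCG(NumericVector b, IntegerVector dims, double sigma,
                  double tol, int maxit) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericVector x(b.size());
  double resid = 0.0;
  int it = diffuse_cg(b.begin(), x.begin(), n1, n2, n3, sigma, tol, maxit, &resid);
  x.attr("dim") = dims;
  return List::create(_["x"] = x, _["iterations"] = it, _["residual"] = resid);
}

// ---------------------------------------------------------------------------
// Mass-preserving push-forward advection: each voxel's mass is deposited at
// its displaced position with trilinear weights; displaced positions are
// clamped inside the domain so no mass leaves the grid.
static void deposit(const double *rho, const double *vx, const double *vy,
                    const double *vz, double *out, int n1, int n2, int n3) {
  const int n = n1 * n2 * n3;
  std::fill(out, out + n, 0.0);
  for (int iz = 0; iz < n3; ++iz)
    for (int iy = 0; iy < n2; ++iy)
      for (int ix = 0; ix < n1; ++ix) {
        const int i = lin(ix, iy, iz, n1, n2);
        const double m = rho[i];
        if (m == 0.0) continue;
        double x = clampd(ix + vx[i], 0.0, n1 - 1.0);
        double y = clampd(iy + vy[i], 0.0, n2 - 1.0);
        double z = clampd(iz + vz[i], 0.0, n3 - 1.0);
        int i0 = std::min((int)std::floor(x), n1 - 2); if (n1 == 1) i0 = 0;
        int j0 = std::min((int)std::floor(y), n2 - 2); if (n2 == 1) j0 = 0;
        int k0 = std::min((int)std::floor(z), n3 - 2); if (n3 == 1) k0 = 0;
        const double fx = x - i0, fy = y - j0, fz = z - k0;
        const double wx[2] = {1.0 - fx, fx};
        const double wy[2] = {1.0 - fy, fy};
        const double wz[2] = {1.0 - fz, fz};
        for (int c = 0; c < 2; ++c)
          for (int b = 0; b < 2; ++b)
            for (int a = 0; a < 2; ++a) {
              const double w = wx[a] * wy[b] * wz[c];
              if (w != 0.0)
                out[lin(std::min(i0 + a, n1 - 1), std::min(j0 + b, n2 - 1),
                        std::min(k0 + c, n3 - 1), n1, n2)] += m * w;
            }
      }
}

// Adjoint of deposit: trilinear interpolation of `field` at x_i + v_i.
// Also (optionally) the gradient of that interpolant w.r.t. the displacement,
// which is zero in any axis where the displaced position was clamped.
static void pullback(const double *field, const double *vx, const double *vy,
                     const double *vz, double *out,
                     double *gx, double *gy, double *gz,
                     int n1, int n2, int n3) {
  for (int iz = 0; iz < n3; ++iz)
    for (int iy = 0; iy < n2; ++iy)
      for (int ix = 0; ix < n1; ++ix) {
        const int i = lin(ix, iy, iz, n1, n2);
        const double rx = ix + vx[i], ry = iy + vy[i], rz = iz + vz[i];
        const double x = clampd(rx, 0.0, n1 - 1.0);
        const double y = clampd(ry, 0.0, n2 - 1.0);
        const double z = clampd(rz, 0.0, n3 - 1.0);
        const bool cx = (rx != x), cy = (ry != y), cz = (rz != z);
        int i0 = std::min((int)std::floor(x), n1 - 2); if (n1 == 1) i0 = 0;
        int j0 = std::min((int)std::floor(y), n2 - 2); if (n2 == 1) j0 = 0;
        int k0 = std::min((int)std::floor(z), n3 - 2); if (n3 == 1) k0 = 0;
        const double fx = x - i0, fy = y - j0, fz = z - k0;
        const double wx[2] = {1.0 - fx, fx}, dwx[2] = {-1.0, 1.0};
        const double wy[2] = {1.0 - fy, fy}, dwy[2] = {-1.0, 1.0};
        const double wz[2] = {1.0 - fz, fz}, dwz[2] = {-1.0, 1.0};
        double val = 0.0, dx = 0.0, dy = 0.0, dz = 0.0;
        for (int c = 0; c < 2; ++c)
          for (int b = 0; b < 2; ++b)
            for (int a = 0; a < 2; ++a) {
              const double f = field[lin(std::min(i0 + a, n1 - 1),
                                         std::min(j0 + b, n2 - 1),
                                         std::min(k0 + c, n3 - 1), n1, n2)];
              val += f * wx[a] * wy[b] * wz[c];
              dx  += f * dwx[a] * wy[b] * wz[c];
              dy  += f * wx[a] * dwy[b] * wz[c];
              dz  += f * wx[a] * wy[b] * dwz[c];
            }
        out[i] = val;
        if (gx) {
          gx[i] = cx ? 0.0 : dx;
          gy[i] = cy ? 0.0 : dy;
          gz[i] = cz ? 0.0 : dz;
        }
      }
}

// [[Rcpp::export(name = ".cppAdvect")]]
NumericVector cppAdvect(NumericVector rho, NumericVector v, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int n = n1 * n2 * n3;
  NumericVector out(n);
  deposit(rho.begin(), v.begin(), v.begin() + n, v.begin() + 2 * n,
          out.begin(), n1, n2, n3);
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Forward advection-diffusion trajectory over m substeps.
// V is (n x 3 x m) flattened; returns (n x (m+1)) trajectory matrix.
// [[Rcpp::export(name = ".cppForward")]]
NumericMatrix cppForward(NumericVector rho0, NumericVector V, IntegerVector dims,
                         int msub, double sigma, double cg_tol, int cg_maxit) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int n = n1 * n2 * n3;
  NumericMatrix traj(n, msub + 1);
  std::vector<double> adv(n);
  std::copy(rho0.begin(), rho0.end(), traj.column(0).begin());
  for (int k = 0; k < msub; ++k) {
    const double *vk = V.begin() + (size_t)k * 3 * n;
    deposit(&traj(0, k), vk, vk + n, vk + 2 * n, adv.data(), n1, n2, n3);
    double resid;
    diffuse_cg(adv.data(), &traj(0, k + 1), n1, n2, n3, sigma, cg_tol,
               cg_maxit, &resid);
    if (sigma > 0 && resid > cg_tol * 100)
      stop("diffusion CG did not converge (relative residual %e)", resid);
  }
  return traj;
}

// ---------------------------------------------------------------------------
// rOMT energy and adjoint gradient.
//   E = msub * sum_k sum_i rho_k[i] |v_k[i]|^2  +  beta * ||rho_m - rho1||^2
// (voxel units: dV = 1, pseudo-time of one frame interval = 1, so a constant
// per-substep displacement d/msub yields kinetic energy = mass * |d|^2, the
// squared Wasserstein-2 distance of a pure translation).
// [[Rcpp::export(name = ".cppEnergyGrad")]]
List cppEnergyGrad(NumericVector rho0, NumericVector rho1, NumericVector V,
                   IntegerVector dims, int msub, double sigma, double beta,
                   LogicalVector mask, bool wantGrad, double cg_tol,
                   int cg_maxit) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int n = n1 * n2 * n3;

  // forward trajectory
  NumericMatrix traj(n, msub + 1);
  {
    std::vector<double> adv(n);
    std::copy(rho0.begin(), rho0.end(), traj.column(0).begin());
    for (int k = 0; k < msub; ++k) {
      const double *vk = V.begin() + (size_t)k * 3 * n;
      deposit(&traj(0, k), vk, vk + n, vk + 2 * n, adv.data(), n1, n2, n3);
      double resid;
      diffuse_cg(adv.data(), &traj(0, k + 1), n1, n2, n3, sigma, cg_tol,
                 cg_maxit, &resid);
    }
  }

  double kinetic = 0.0;
  for (int k = 0; k < msub; ++k) {
    const double *vk = V.begin() + (size_t)k * 3 * n;
    const double *rk = &traj(0, k);
    double acc = 0.0;
    for (int i = 0; i < n; ++i)
      acc += rk[i] * (vk[i] * vk[i] + vk[n + i] * vk[n + i] +
                      vk[2 * n + i] * vk[2 * n + i]);
    kinetic += acc;
  }
  kinetic *= msub;

  double mismatch = 0.0;
  for (int i = 0; i < n; ++i) {
    const double d = traj(i, msub) - rho1[i];
    mismatch += d * d;
  }
  mismatch *= beta;

  List out = List::create(_["total"] = kinetic + mismatch,
                          _["kinetic"] = kinetic,
                          _["mismatch"] = mismatch,
                          _["trajectory"] = traj);
  if (!wantGrad) return out;

  // adjoint sweep
  NumericVector grad((size_t)3 * n * msub);
  std::vector<double> lam(n), y(n), pb(n), gx(n), gy(n), gz(n);
  for (int i = 0; i < n; ++i) lam[i] = 2.0 * beta * (traj(i, msub) - rho1[i]);
  for (int k = msub - 1; k >= 0; --k) {
    // y = (I - sigma L)^{-1} lam  (diffusion operator is self-adjoint)
    double resid;
    diffuse_cg(lam.data(), y.data(), n1, n2, n3, sigma, cg_tol, cg_maxit, &resid);
    const double *vk = V.begin() + (size_t)k * 3 * n;
    pullback(y.data(), vk, vk + n, vk + 2 * n, pb.data(),
             gx.data(), gy.data(), gz.data(), n1, n2, n3);
    double *gk = grad.begin() + (size_t)k * 3 * n;
    const double *rk = &traj(0, k);
    for (int i = 0; i < n; ++i) {
      if (mask[i]) {
        gk[i]         = 2.0 * msub * rk[i] * vk[i]         + rk[i] * gx[i];
        gk[n + i]     = 2.0 * msub * rk[i] * vk[n + i]     + rk[i] * gy[i];
        gk[2 * n + i] = 2.0 * msub * rk[i] * vk[2 * n + i] + rk[i] * gz[i];
      } else {
        gk[i] = gk[n + i] = gk[2 * n + i] = 0.0;
      }
      // lambda_k = msub * |v_k|^2 + A_k^T y
      lam[i] = msub * (vk[i] * vk[i] + vk[n + i] * vk[n + i] +
                       vk[2 * n + i] * vk[2 * n + i]) + pb[i];
    }
  }
  out["gradient"] = grad;
  return out;
}

// ---------------------------------------------------------------------------
// Independent phantom integrator: dimension-unsplit flux-form first-order
// upwind advection with explicit Neumann diffusion, face-centred velocities.
// cvx: (n1+1) x n2 x n3 Courant numbers (v*dt/dx) at x-faces, etc.
// dnum = sigma*dt/dx^2. Runs nsteps forward-Euler steps. Used only by the
// synthetic-data generator, never by the solver (anti-inverse-crime).
// [[Rcpp::export(name = ".cppUpwind")]]
NumericVector cppUpwind(NumericVector rho, NumericVector cvx, NumericVector cvy,
                        NumericVector cvz, IntegerVector dims, double dnum,
                        int nsteps) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int n = n1 * n2 * n3;
  std::vector<double> cur(rho.begin(), rho.end()), nxt(n);
  const double *vx = cvx.begin(), *vy = cvy.begin(), *vz = cvz.begin();
  for (int s = 0; s < nsteps; ++s) {
    // diffusion part
    laplacian(cur.data(), nxt.data(), n1, n2, n3);
    for (int i = 0; i < n; ++i) nxt[i] = cur[i] + dnum * nxt[i];
    // advective fluxes across interior faces (zero-flux at boundaries)
    for (int iz = 0; iz < n3; ++iz)
      for (int iy = 0; iy < n2; ++iy)
        for (int ix = 1; ix < n1; ++ix) {
          const double c = vx[ix + (n1 + 1) * (iy + n2 * iz)];
          const int iR = lin(ix, iy, iz, n1, n2);
          const double f = c > 0 ? c * cur[iR - 1] : c * cur[iR];
          nxt[iR - 1] -= f;
          nxt[iR]     += f;
        }
    for (int iz = 0; iz < n3; ++iz)
      for (int iy = 1; iy < n2; ++iy)
        for (int ix = 0; ix < n1; ++ix) {
          const double c = vy[ix + n1 * (iy + (n2 + 1) * iz)];
          const int iR = lin(ix, iy, iz, n1, n2);
          const double f = c > 0 ? c * cur[iR - n1] : c * cur[iR];
          nxt[iR - n1] -= f;
          nxt[iR]      += f;
        }
    for (int iz = 1; iz < n3; ++iz)
      for (int iy = 0; iy < n2; ++iy)
        for (int ix = 0; ix < n1; ++ix) {
          const double c = vz[ix + n1 * (iy + n2 * iz)];
          const int iR = lin(ix, iy, iz, n1, n2);
          const double f = c > 0 ? c * cur[iR - n1 * n2] : c * cur[iR];
          nxt[iR - n1 * n2] -= f;
          nxt[iR]           += f;
        }
    std::swap(cur, nxt);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Pathline tracing: one classical RK4 step per substep through the
// trilinearly interpolated, piecewise-constant-in-pseudo-time velocity field.
// V: (n x 3 x S) voxels/substep; seeds: (p x 3) voxel coordinates.
// Returns positions ((S+1) x 3 x p) and per-step speeds (S x p).
static void interp_vec(const double *V, int n1, int n2, int n3, int n,
                       double x, double y, double z, double *out) {
  x = clampd(x, 0.0, n1 - 1.0);
  y = clampd(y, 0.0, n2 - 1.0);
  z = clampd(z, 0.0, n3 - 1.0);
  int i0 = std::min((int)std::floor(x), n1 - 2); if (n1 == 1) i0 = 0;
  int j0 = std::min((int)std::floor(y), n2 - 2); if (n2 == 1) j0 = 0;
  int k0 = std::min((int)std::floor(z), n3 - 2); if (n3 == 1) k0 = 0;
  const double fx = x - i0, fy = y - j0, fz = z - k0;
  const double wx[2] = {1.0 - fx, fx}, wy[2] = {1.0 - fy, fy}, wz[2] = {1.0 - fz, fz};
  out[0] = out[1] = out[2] = 0.0;
  for (int c = 0; c < 2; ++c)
    for (int b = 0; b < 2; ++b)
      for (int a = 0; a < 2; ++a) {
        const double w = wx[a] * wy[b] * wz[c];
        const int idx = lin(std::min(i0 + a, n1 - 1), std::min(j0 + b, n2 - 1),
                            std::min(k0 + c, n3 - 1), n1, n2);
        out[0] += w * V[idx];
        out[1] += w * V[n + idx];
        out[2] += w * V[2 * n + idx];
      }
}

// [[Rcpp::export(name = ".cppTrace")]]
List cppTrace(NumericVector V, IntegerVector dims, int nsub, NumericMatrix seeds) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int n = n1 * n2 * n3;
  const int p = seeds.nrow();
  NumericVector pos((size_t)(nsub + 1) * 3 * p);
  pos.attr("dim") = IntegerVector::create(nsub + 1, 3, p);
  NumericMatrix spd(nsub, p);
  double k1[3], k2[3], k3[3], k4[3];
  for (int q = 0; q < p; ++q) {
    double x = seeds(q, 0), y = seeds(q, 1), z = seeds(q, 2);
    double *P = pos.begin() + (size_t)q * (nsub + 1) * 3;
    P[0] = x; P[nsub + 1] = y; P[2 * (nsub + 1)] = z;
    for (int s = 0; s < nsub; ++s) {
      const double *Vs = V.begin() + (size_t)s * 3 * n;
      interp_vec(Vs, n1, n2, n3, n, x, y, z, k1);
      spd(s, q) = std::sqrt(k1[0] * k1[0] + k1[1] * k1[1] + k1[2] * k1[2]);
      interp_vec(Vs, n1, n2, n3, n, x + 0.5 * k1[0], y + 0.5 * k1[1],
                 z + 0.5 * k1[2], k2);
      interp_vec(Vs, n1, n2, n3, n, x + 0.5 * k2[0], y + 0.5 * k2[1],
                 z + 0.5 * k2[2], k3);
      interp_vec(Vs, n1, n2, n3, n, x + k3[0], y + k3[1], z + k3[2], k4);
      x = clampd(x + (k1[0] + 2 * k2[0] + 2 * k3[0] + k4[0]) / 6.0, 0.0, n1 - 1.0);
      y = clampd(y + (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1]) / 6.0, 0.0, n2 - 1.0);
      z = clampd(z + (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2]) / 6.0, 0.0, n3 - 1.0);
      P[s + 1] = x; P[nsub + 1 + s + 1] = y; P[2 * (nsub + 1) + s + 1] = z;
    }
  }
  return List::create(_["positions"] = pos, _["speeds"] = spd);
}

// ---------------------------------------------------------------------------
// Speed-map deposition: per-step speeds land in the voxel containing the
// step's start position; voxel value = mean of all deposited speeds.
// positions: (S+1) x 3 x p (voxel coords), speeds: S x p.
// [[Rcpp::export(name = ".cppSpeedDeposit")]]
List cppSpeedDeposit(NumericVector pos, NumericMatrix spd, LogicalVector keep,
                     IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int n = n1 * n2 * n3;
  IntegerVector posDims = pos.attr("dim");
  const int S1 = posDims[0];          // nsub + 1
  const int p = posDims[2];
  const int nsub = spd.nrow();
  NumericVector sum(n);
  IntegerVector cnt(n);
  for (int q = 0; q < p; ++q) {
    if (!keep[q]) continue;
    const double *P = pos.begin() + (size_t)q * S1 * 3;
    for (int s = 0; s < nsub; ++s) {
      const int ix = (int)std::lround(clampd(P[s], 0.0, n1 - 1.0));
      const int iy = (int)std::lround(clampd(P[S1 + s], 0.0, n2 - 1.0));
      const int iz = (int)std::lround(clampd(P[2 * S1 + s], 0.0, n3 - 1.0));
      const int i = lin(ix, iy, iz, n1, n2);
      sum[i] += spd(s, q);
      cnt[i] += 1;
    }
  }
  sum.attr("dim") = dims;
  cnt.attr("dim") = dims;
  return List::create(_["sum"] = sum, _["count"] = cnt);
}

// ---------------------------------------------------------------------------
// Separable 1D convolution along each axis with mirror (reflective) boundary;
// conserves the total of symmetric kernels.
static void conv_axis(std::vector<double> &vol, const std::vector<double> &ker,
                      int n1, int n2, int n3, int axis) {
  const int r = ((int)ker.size() - 1) / 2;
  const int len = axis == 0 ? n1 : (axis == 1 ? n2 : n3);
  const int stride = axis == 0 ? 1 : (axis == 1 ? n1 : n1 * n2);
  std::vector<double> line(len);
  const int nOuter = n1 * n2 * n3 / len;
  for (int o = 0; o < nOuter; ++o) {
    // base index of this line
    int base;
    if (axis == 0) base = o * n1;
    else if (axis == 1) { const int x = o % n1, z = o / n1; base = x + n1 * n2 * z; }
    else base = o;
    for (int t = 0; t < len; ++t) line[t] = vol[base + t * stride];
    for (int t = 0; t < len; ++t) {
      double acc = 0.0;
      for (int k = -r; k <= r; ++k) {
        int s = t + k;
        if (s < 0) s = -s - 1;                 // mirror: -1 -> 0, -2 -> 1
        if (s >= len) s = 2 * len - 1 - s;
        if (s < 0) s = 0;
        if (s >= len) s = len - 1;
        acc += ker[k + r] * line[s];
      }
      vol[base + t * stride] = acc;
    }
  }
}

// [[Rcpp::export(name = ".cppGaussSmooth")]]
NumericVector cppGaussSmooth(NumericVector vol, IntegerVector dims,
                             NumericVector sigmaVox) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  std::vector<double> v(vol.begin(), vol.end());
  for (int axis = 0; axis < 3; ++axis) {
    const double s = sigmaVox[axis];
    if (s <= 0) continue;
    const int r = std::max(1, (int)std::ceil(4.0 * s));
    std::vector<double> ker(2 * r + 1);
    double tot = 0.0;
    for (int k = -r; k <= r; ++k) {
      ker[k + r] = std::exp(-0.5 * k * k / (s * s));
      tot += ker[k + r];
    }
    for (auto &w : ker) w /= tot;
    conv_axis(v, ker, n1, n2, n3, axis);
  }
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Gauss-Newton Hessian-vector product for the rOMT energy.
// Linearization of rho_{k+1} = D A(v_k) rho_k around the current v:
//   drho_{k+1} = D [ A(v_k) drho_k + B_k dv_k ],
// where (B_k dv)[j] = sum_i rho_k[i] * (grad_x w_j)(x_i+v_i) . dv_i  is the
// derivative of the deposition w.r.t. the displacement (zero in clamped
// axes, matching the adjoint). The GN product is
//   (H dv)_k = 2 m rho_k (.) dv_k  +  rho_k (.) grad interp(D nu_{k+1})
// with nu_m = 2 beta drho_m and nu_k = A_k^T D nu_{k+1} (mismatch term
// linearized only; kinetic term kept with rho frozen). PSD by construction.

static void deposit_dv(const double *rho, const double *vx, const double *vy,
                       const double *vz, const double *dvx, const double *dvy,
                       const double *dvz, double *out, int n1, int n2, int n3) {
  const int n = n1 * n2 * n3;
  std::fill(out, out + n, 0.0);
  for (int iz = 0; iz < n3; ++iz)
    for (int iy = 0; iy < n2; ++iy)
      for (int ix = 0; ix < n1; ++ix) {
        const int i = lin(ix, iy, iz, n1, n2);
        const double m = rho[i];
        if (m == 0.0) continue;
        const double rx = ix + vx[i], ry = iy + vy[i], rz = iz + vz[i];
        const double x = clampd(rx, 0.0, n1 - 1.0);
        const double y = clampd(ry, 0.0, n2 - 1.0);
        const double z = clampd(rz, 0.0, n3 - 1.0);
        const double ax = (rx != x) ? 0.0 : dvx[i];
        const double ay = (ry != y) ? 0.0 : dvy[i];
        const double az = (rz != z) ? 0.0 : dvz[i];
        if (ax == 0.0 && ay == 0.0 && az == 0.0) continue;
        int i0 = std::min((int)std::floor(x), n1 - 2); if (n1 == 1) i0 = 0;
        int j0 = std::min((int)std::floor(y), n2 - 2); if (n2 == 1) j0 = 0;
        int k0 = std::min((int)std::floor(z), n3 - 2); if (n3 == 1) k0 = 0;
        const double fx = x - i0, fy = y - j0, fz = z - k0;
        const double wx[2] = {1.0 - fx, fx}, dwx[2] = {-1.0, 1.0};
        const double wy[2] = {1.0 - fy, fy}, dwy[2] = {-1.0, 1.0};
        const double wz[2] = {1.0 - fz, fz}, dwz[2] = {-1.0, 1.0};
        for (int c = 0; c < 2; ++c)
          for (int b = 0; b < 2; ++b)
            for (int a = 0; a < 2; ++a) {
              const double w = dwx[a] * wy[b] * wz[c] * ax +
                               wx[a] * dwy[b] * wz[c] * ay +
                               wx[a] * wy[b] * dwz[c] * az;
              if (w != 0.0)
                out[lin(std::min(i0 + a, n1 - 1), std::min(j0 + b, n2 - 1),
                        std::min(k0 + c, n3 - 1), n1, n2)] += m * w;
            }
      }
}

// [[Rcpp::export(name = ".cppGnHvp")]]
NumericVector cppGnHvp(NumericMatrix traj, NumericVector V, NumericVector dV,
                       IntegerVector dims, int msub, double sigma, double beta,
                       LogicalVector mask, double damping, double cg_tol,
                       int cg_maxit) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int n = n1 * n2 * n3;
  // forward linearized sweep
  std::vector<double> drho(n, 0.0), tmp(n), tmp2(n);
  for (int k = 0; k < msub; ++k) {
    const double *vk = V.begin() + (size_t)k * 3 * n;
    const double *dvk = dV.begin() + (size_t)k * 3 * n;
    deposit(drho.data(), vk, vk + n, vk + 2 * n, tmp.data(), n1, n2, n3);
    deposit_dv(&traj(0, k), vk, vk + n, vk + 2 * n, dvk, dvk + n,
               dvk + 2 * n, tmp2.data(), n1, n2, n3);
    for (int i = 0; i < n; ++i) tmp[i] += tmp2[i];
    double resid;
    diffuse_cg(tmp.data(), drho.data(), n1, n2, n3, sigma, cg_tol, cg_maxit,
               &resid);
  }
  // backward sweep
  NumericVector H((size_t)3 * n * msub);
  std::vector<double> nu(n), y(n), pb(n), gx(n), gy(n), gz(n);
  for (int i = 0; i < n; ++i) nu[i] = 2.0 * beta * drho[i];
  for (int k = msub - 1; k >= 0; --k) {
    double resid;
    diffuse_cg(nu.data(), y.data(), n1, n2, n3, sigma, cg_tol, cg_maxit,
               &resid);
    const double *vk = V.begin() + (size_t)k * 3 * n;
    const double *dvk = dV.begin() + (size_t)k * 3 * n;
    pullback(y.data(), vk, vk + n, vk + 2 * n, pb.data(), gx.data(),
             gy.data(), gz.data(), n1, n2, n3);
    double *hk = H.begin() + (size_t)k * 3 * n;
    const double *rk = &traj(0, k);
    for (int i = 0; i < n; ++i) {
      if (mask[i]) {
        const double diag = 2.0 * msub * rk[i] + damping;
        hk[i]         = diag * dvk[i]         + rk[i] * gx[i];
        hk[n + i]     = diag * dvk[n + i]     + rk[i] * gy[i];
        hk[2 * n + i] = diag * dvk[2 * n + i] + rk[i] * gz[i];
      } else {
        hk[i] = hk[n + i] = hk[2 * n + i] = 0.0;
      }
      nu[i] = pb[i];
    }
  }
  return H;
}
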