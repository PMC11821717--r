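// Core simulation kernels: implicit diffusion-decay, ECM-aware motility,
// center-based pairwise mechanics, and cell-driven ECM remodeling.
// All stochastic draws go through R's RNG so runs are reproducible from
// set.seed() alone.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- cell parameter matrix column layout (keep in step with R/cells.R) ----
enum ParCol {
  P_SMAX = 0, P_BIAS, P_SENS, P_TAUP, P_CCA, P_CCR,
  P_RF0, P_RA0, P_RRHO, P_RHOT, P_INSTANT,
  P_RHOL, P_RHOI, P_RHOH, P_CHEMO_MODEL, P_CHEMO_SUB
};

static const double V_REF = 1.0; // speed normalization for remodeling rates, um/min

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline int voxel_of(double x, double origin, double h, int n) {
  return clampi((int)std::floor((x - origin) / h), 0, n - 1);
}

// piecewise-linear density-speed tent
static inline double tent(double rho, double rl, double ri, double rh) {
  if (rho <= rl || rho >= rh) {
    // open interval: maximum attained only at rho == ri; rho at/below rl or
    // at/above rh gives zero (with the degenerate rl == ri or ri == rh edges
    // handled below)
    if (rho == ri) return 1.0;
    return 0.0;
  }
  if (rho < ri) return (ri > rl) ? (rho - rl) / (ri - rl) : 1.0;
  if (rho > ri) return (rh > ri) ? (rh - rho) / (rh - ri) : 1.0;
  return 1.0;
}

// [[Rcpp::export]]
double cpp_density_speed_factor(double rho, double rl, double ri, double rh) {
  return tent(rho, rl, ri, rh);
}

// ---------------------------------------------------------------------------
// Tridiagonal (Thomas) solve for the 1-D implicit diffusion operator along a
// strided line of the concentration array. No-flux ends by construction.
// Ends are either no-flux (diag 1+alpha) or held fixed (Dirichlet voxel:
// excluded from the unknowns, entering the adjacent equation as a source).
static void thomas_line(double* c, int n, int stride, double alpha,
                        bool fix_lo, bool fix_hi,
                        std::vector<double>& cp, std::vector<double>& dp) {
  int i0 = fix_lo ? 1 : 0;
  int i1 = fix_hi ? n - 2 : n - 1;
  int m = i1 - i0 + 1;
  if (m <= 0) return;
  if (m == 1) {
    double b = 1.0 + (fix_lo ? alpha : 0.0) + (fix_hi ? alpha : 0.0);
    double rhs = c[(size_t)i0 * stride];
    if (fix_lo) rhs += alpha * c[(size_t)(i0 - 1) * stride];
    if (fix_hi) rhs += alpha * c[(size_t)(i1 + 1) * stride];
    c[(size_t)i0 * stride] = rhs / b;
    return;
  }
  double b0 = fix_lo ? (1.0 + 2.0 * alpha) : (1.0 + alpha);
  double rhs0 = c[(size_t)i0 * stride] +
                (fix_lo ? alpha * c[(size_t)(i0 - 1) * stride] : 0.0);
  cp[0] = -alpha / b0;
  dp[0] = rhs0 / b0;
  for (int q = 1; q < m; ++q) {
    int i = i0 + q;
    bool last = (q == m - 1);
    double b = last ? (fix_hi ? (1.0 + 2.0 * alpha) : (1.0 + alpha))
                    : (1.0 + 2.0 * alpha);
    double rhs = c[(size_t)i * stride] +
                 ((last && fix_hi) ? alpha * c[(size_t)(i + 1) * stride] : 0.0);
    double den = b + alpha * cp[q - 1];
    cp[q] = -alpha / den;
    dp[q] = (rhs + alpha * dp[q - 1]) / den;
  }
  c[(size_t)i1 * stride] = dp[m - 1];
  for (int q = m - 2; q >= 0; --q)
    c[(size_t)(i0 + q) * stride] = dp[q] - cp[q] * c[(size_t)(i0 + q + 1) * stride];
}

// one operator-split implicit diffusion + exact decay step, in place
static void pin_dirichlet(std::vector<double>& conc, int nx, int ny, int nz,
                          const double* dirich) {
  if (!dirich) return;
  if (!ISNAN(dirich[0]))
    for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j)
      conc[(size_t)nx * (j + (size_t)ny * k)] = dirich[0];
  if (!ISNAN(dirich[1]))
    for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j)
      conc[nx - 1 + (size_t)nx * (j + (size_t)ny * k)] = dirich[1];
  if (!ISNAN(dirich[2]))
    for (int k = 0; k < nz; ++k) for (int i = 0; i < nx; ++i)
      conc[i + (size_t)nx * ((size_t)ny * k)] = dirich[2];
  if (!ISNAN(dirich[3]))
    for (int k = 0; k < nz; ++k) for (int i = 0; i < nx; ++i)
      conc[i + (size_t)nx * (ny - 1 + (size_t)ny * k)] = dirich[3];
  if (!ISNAN(dirich[4]))
    for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i)
      conc[i + (size_t)nx * j] = dirich[4];
  if (!ISNAN(dirich[5]))
    for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i)
      conc[i + (size_t)nx * (j + (size_t)ny * (nz - 1))] = dirich[5];
}

static void diffuse_decay(std::vector<double>& conc, int nx, int ny, int nz,
                          double h, double D, double lambda, double dt,
                          const double* dirich) {
  double alpha = D * dt / (h * h);
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> cp(nmax), dp(nmax);
  bool dir[6] = {false, false, false, false, false, false};
  if (dirich)
    for (int q = 0; q < 6; ++q) dir[q] = !ISNAN(dirich[q]);
  pin_dirichlet(conc, nx, ny, nz, dirich);
  if (nx > 1 && alpha > 0) {
    for (int k = 0; k < nz; ++k) {
      if ((dir[4] && k == 0) || (dir[5] && k == nz - 1)) continue;
      for (int j = 0; j < ny; ++j) {
        if ((dir[2] && j == 0) || (dir[3] && j == ny - 1)) continue;
        thomas_line(&conc[(size_t)nx * (j + (size_t)ny * k)], nx, 1, alpha,
                    dir[0], dir[1], cp, dp);
      }
    }
  }
  if (ny > 1 && alpha > 0) {
    for (int k = 0; k < nz; ++k) {
      if ((dir[4] && k == 0) || (dir[5] && k == nz - 1)) continue;
      for (int i = 0; i < nx; ++i) {
        if ((dir[0] && i == 0) || (dir[1] && i == nx - 1)) continue;
        thomas_line(&conc[i + (size_t)nx * ny * k], ny, nx, alpha,
                    dir[2], dir[3], cp, dp);
      }
    }
  }
  if (nz > 1 && alpha > 0) {
    for (int j = 0; j < ny; ++j) {
      if ((dir[2] && j == 0) || (dir[3] && j == ny - 1)) continue;
      for (int i = 0; i < nx; ++i) {
        if ((dir[0] && i == 0) || (dir[1] && i == nx - 1)) continue;
        thomas_line(&conc[i + (size_t)nx * j], nz, nx * ny, alpha,
                    dir[4], dir[5], cp, dp);
      }
    }
  }
  if (lambda > 0) {
    double f = std::exp(-lambda * dt);
    for (size_t i = 0; i < conc.size(); ++i) conc[i] *= f;
  }
  // re-pin Dirichlet faces after decay (order: xmin,xmax,ymin,ymax,zmin,zmax;
  // NaN = no-flux)
  pin_dirichlet(conc, nx, ny, nz, dirich);
  // negative concentrations are clipped (can only arise from sources/round-off)
  for (size_t i = 0; i < conc.size(); ++i) if (conc[i] < 0) conc[i] = 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_diffusion_step(NumericVector conc, IntegerVector dims,
                                 double h, double D, double lambda, double dt,
                                 NumericVector dirichlet) {
  std::vector<double> c(conc.begin(), conc.end());
  diffuse_decay(c, dims[0], dims[1], dims[2], h, D, lambda, dt,
                dirichlet.size() == 6 ? &dirichlet[0] : nullptr);
  NumericVector out(c.begin(), c.end());
  for (int i = 0; i < out.size(); ++i)
    if (!R_finite(out[i]))
      stop("non-finite concentration at voxel %d after diffusion step", i + 1);
  return out;
}

// implicit per-voxel secretion/uptake update (exact for the single-voxel ODE)
// c <- (c + dt*f*S*cstar) / (1 + dt*f*(S+U)), f = Vcell/Vvoxel
// [[Rcpp::export]]
NumericVector cpp_apply_sources(NumericVector conc, IntegerVector dims,
                                NumericVector origin, double h,
                                NumericMatrix pos, NumericVector volume,
                                NumericVector secrete, NumericVector target,
                                NumericVector uptake, double dt) {
  NumericVector c = clone(conc);
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double vvox = h * h * h;
  for (int n = 0; n < pos.nrow(); ++n) {
    double S = secrete[n], U = uptake[n];
    if (S <= 0 && U <= 0) continue;
    int i = voxel_of(pos(n, 0), origin[0], h, nx);
    int j = voxel_of(pos(n, 1), origin[1], h, ny);
    int k = voxel_of(pos(n, 2), origin[2], h, nz);
    size_t idx = i + (size_t)nx * (j + (size_t)ny * k);
    double f = volume[n] / vvox;
    c[idx] = (c[idx] + dt * f * S * target[n]) / (1.0 + dt * f * (S + U));
  }
  return c;
}

static inline void gradient_voxel(const double* c, int nx, int ny, int nz,
                                  double h, int i, int j, int k, double* g) {
  size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
  size_t idx = i + (size_t)nx * (j + (size_t)ny * k);
  // central difference at interior voxels, one-sided at boundaries
  if (nx > 1) {
    if (i == 0)            g[0] = (c[idx + sx] - c[idx]) / h;
    else if (i == nx - 1)  g[0] = (c[idx] - c[idx - sx]) / h;
    else                   g[0] = (c[idx + sx] - c[idx - sx]) / (2 * h);
  } else g[0] = 0.0;
  if (ny > 1) {
    if (j == 0)            g[1] = (c[idx + sy] - c[idx]) / h;
    else if (j == ny - 1)  g[1] = (c[idx] - c[idx - sy]) / h;
    else                   g[1] = (c[idx + sy] - c[idx - sy]) / (2 * h);
  } else g[1] = 0.0;
  if (nz > 1) {
    if (k == 0)            g[2] = (c[idx + sz] - c[idx]) / h;
    else if (k == nz - 1)  g[2] = (c[idx] - c[idx - sz]) / h;
    else                   g[2] = (c[idx + sz] - c[idx - sz]) / (2 * h);
  } else g[2] = 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_gradient_at(NumericVector conc, IntegerVector dims,
                              NumericVector origin, double h,
                              NumericVector position) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int i = voxel_of(position[0], origin[0], h, nx);
  int j = voxel_of(position[1], origin[1], h, ny);
  int k = voxel_of(position[2], origin[2], h, nz);
  NumericVector g(3);
  gradient_voxel(&conc[0], nx, ny, nz, h, i, j, k, &g[0]);
  return g;
}

// ---------------------------------------------------------------------------
// pairwise adhesion/repulsion velocities via a uniform cell list
static void pair_velocities(const NumericMatrix& pos, const NumericVector& radius,
                            const NumericVector& cca, const NumericVector& ccr,
                            double adh_factor, const double* lo, const double* hi,
                            NumericMatrix& pv) {
  int n = pos.nrow();
  std::fill(pv.begin(), pv.end(), 0.0);
  if (n < 2) return;
  double maxR = 0.0;
  for (int i = 0; i < n; ++i) maxR = std::max(maxR, radius[i]);
  double reach = adh_factor * 2.0 * maxR + 1e-9;
  int nbx = std::max(1, (int)std::floor((hi[0] - lo[0]) / reach));
  int nby = std::max(1, (int)std::floor((hi[1] - lo[1]) / reach));
  int nbz = std::max(1, (int)std::floor((hi[2] - lo[2]) / reach));
  double bx = (hi[0] - lo[0]) / nbx, by = (hi[1] - lo[1]) / nby,
         bz = (hi[2] - lo[2]) / nbz;
  std::vector<int> binof(n), head(nbx * nby * nbz, -1), nxt(n, -1);
  for (int i = 0; i < n; ++i) {
    int ix = clampi((int)((pos(i, 0) - lo[0]) / bx), 0, nbx - 1);
    int iy = clampi((int)((pos(i, 1) - lo[1]) / by), 0, nby - 1);
    int iz = clampi((int)((pos(i, 2) - lo[2]) / bz), 0, nbz - 1);
    int b = ix + nbx * (iy + nby * iz);
    binof[i] = b;
    nxt[i] = head[b];
    head[b] = i;
  }
  for (int iz = 0; iz < nbz; ++iz)
    for (int iy = 0; iy < nby; ++iy)
      for (int ix = 0; ix < nbx; ++ix) {
        int b = ix + nbx * (iy + nby * iz);
        for (int i = head[b]; i != -1; i = nxt[i]) {
          // same bin: pairs with later list entries; neighbor bins: all entries
          for (int j = nxt[i]; j != -1; j = nxt[j]) {
            // handled below through common code path
            double dx = pos(j, 0) - pos(i, 0), dy = pos(j, 1) - pos(i, 1),
                   dz = pos(j, 2) - pos(i, 2);
            double d = std::sqrt(dx * dx + dy * dy + dz * dz);
            double Rp = radius[i] + radius[j], Ra = adh_factor * Rp;
            if (d >= Ra) continue;
            double ux, uy, uz;
            if (d < 1e-12) {
              double th = 2.0 * M_PI * unif_rand();
              ux = std::cos(th); uy = std::sin(th); uz = 0.0; d = 1e-6;
            } else { ux = dx / d; uy = dy / d; uz = dz / d; }
            double mag = 0.0;
            if (d < Rp) {
              double t = 1.0 - d / Rp;
              mag -= std::sqrt(ccr[i] * ccr[j]) * t * t;
            }
            { double t = 1.0 - d / Ra; mag += std::sqrt(cca[i] * cca[j]) * t * t; }
            pv(i, 0) += mag * ux; pv(i, 1) += mag * uy; pv(i, 2) += mag * uz;
            pv(j, 0) -= mag * ux; pv(j, 1) -= mag * uy; pv(j, 2) -= mag * uz;
          }
          for (int dz1 = 0; dz1 <= 1; ++dz1)
            for (int dy1 = (dz1 == 0 ? 0 : -1); dy1 <= 1; ++dy1)
              for (int dx1 = ((dz1 == 0 && dy1 == 0) ? 1 : -1); dx1 <= 1; ++dx1) {
                int jx = ix + dx1, jy = iy + dy1, jz = iz + dz1;
                if (jx < 0 || jx >= nbx || jy < 0 || jy >= nby || jz < 0 ||
                    jz >= nbz)
                  continue;
                int b2 = jx + nbx * (jy + nby * jz);
                for (int j = head[b2]; j != -1; j = nxt[j]) {
                  double dxx = pos(j, 0) - pos(i, 0),
                         dyy = pos(j, 1) - pos(i, 1),
                         dzz = pos(j, 2) - pos(i, 2);
                  double d = std::sqrt(dxx * dxx + dyy * dyy + dzz * dzz);
                  double Rp = radius[i] + radius[j], Ra = adh_factor * Rp;
                  if (d >= Ra) continue;
                  double ux, uy, uz;
                  if (d < 1e-12) {
                    double th = 2.0 * M_PI * unif_rand();
                    ux = std::cos(th); uy = std::sin(th); uz = 0.0; d = 1e-6;
                  } else { ux = dxx / d; uy = dyy / d; uz = dzz / d; }
                  double mag = 0.0;
                  if (d < Rp) {
                    double t = 1.0 - d / Rp;
                    mag -= std::sqrt(ccr[i] * ccr[j]) * t * t;
                  }
                  { double t = 1.0 - d / Ra;
                    mag += std::sqrt(cca[i] * cca[j]) * t * t; }
                  pv(i, 0) += mag * ux; pv(i, 1) += mag * uy; pv(i, 2) += mag * uz;
                  pv(j, 0) -= mag * ux; pv(j, 1) -= mag * uy; pv(j, 2) -= mag * uz;
                }
              }
        }
      }
}

// [[Rcpp::export]]
NumericMatrix cpp_pair_velocities(NumericMatrix pos, NumericVector radius,
                                  NumericVector cca, NumericVector ccr,
                                  double adh_factor, NumericVector lo,
                                  NumericVector hi) {
  NumericMatrix pv(pos.nrow(), 3);
  RNGScope scope;
  pair_velocities(pos, radius, cca, ccr, adh_factor, &lo[0], &hi[0], pv);
  return pv;
}

// ---------------------------------------------------------------------------
// one motility-direction refresh + motility vector, shared by the engine and
// by the exported per-population updater
static void motility_one(int n, const NumericMatrix& par, const NumericMatrix& pos,
                         NumericMatrix& motdir, NumericMatrix& motvec,
                         const IntegerVector& dead,
                         const std::vector<const double*>& subs,
                         const double* fmat, const double* avec,
                         const double* rvec, int nx, int ny, int nz,
                         const double* origin, double h, double dt, bool two_d,
                         int necm) {
  double taup = par(n, P_TAUP);
  int i = voxel_of(pos(n, 0), origin[0], h, nx);
  int j = voxel_of(pos(n, 1), origin[1], h, ny);
  int k = voxel_of(pos(n, 2), origin[2], h, nz);
  size_t eidx = i + (size_t)nx * (j + (size_t)ny * k);
  double aval = avec[eidx], rho = rvec[eidx];
  bool refresh = (taup <= dt) || (unif_rand() < dt / taup);
  if (refresh && !dead[n]) {
    // (1) chemotactic/random base cue
    double beta = 0.0, gx = 0.0, gy = 0.0, gz = 0.0;
    int cm = (int)par(n, P_CHEMO_MODEL);
    int cs = (int)par(n, P_CHEMO_SUB); // 1-based, 0 = none
    if (cm > 0 && cs > 0 && cs <= (int)subs.size()) {
      double g[3];
      gradient_voxel(subs[cs - 1], nx, ny, nz, h, i, j, k, g);
      if (two_d) g[2] = 0.0;
      double gn = std::sqrt(g[0] * g[0] + g[1] * g[1] + g[2] * g[2]);
      if (gn > 0) {
        gx = g[0] / gn; gy = g[1] / gn; gz = g[2] / gn;
        // Model II reads the anisotropy through the cell's ECM sensitivity:
        // an ECM-blind cell (s = 0) cannot use microstructure as a cue
        beta = (cm == 1) ? par(n, P_BIAS) : par(n, P_SENS) * aval;
      }
    }
    double xx, xy, xz;
    if (two_d) {
      double th = 2.0 * M_PI * unif_rand();
      xx = std::cos(th); xy = std::sin(th); xz = 0.0;
    } else {
      double u = 2.0 * unif_rand() - 1.0, th = 2.0 * M_PI * unif_rand();
      double r = std::sqrt(std::max(0.0, 1.0 - u * u));
      xx = r * std::cos(th); xy = r * std::sin(th); xz = u;
    }
    double cx, cy, cz;
    if (beta > 0) {
      cx = beta * gx + (1 - beta) * xx;
      cy = beta * gy + (1 - beta) * xy;
      cz = beta * gz + (1 - beta) * xz;
    } else { cx = xx; cy = xy; cz = xz; }
    double cn = std::sqrt(cx * cx + cy * cy + cz * cz);
    if (cn > 1e-12) {
      cx /= cn; cy /= cn; cz /= cn;
      // (2) sign-matched fiber, (3) anisotropy-weighted contact guidance
      double sa = par(n, P_SENS) * aval;
      if (sa < 0) sa = 0; if (sa > 1) sa = 1;
      double fx = fmat[eidx], fy = fmat[eidx + necm], fz = fmat[eidx + 2 * (size_t)necm];
      double sgn = (fx * cx + fy * cy + fz * cz) >= 0 ? 1.0 : -1.0;
      double ddx = (1 - sa) * cx + sa * sgn * fx;
      double ddy = (1 - sa) * cy + sa * sgn * fy;
      double ddz = (1 - sa) * cz + sa * sgn * fz;
      double dn = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      if (dn > 1e-12) {
        motdir(n, 0) = ddx / dn; motdir(n, 1) = ddy / dn; motdir(n, 2) = ddz / dn;
      } // exact cancellation: retain previous direction
    }   // degenerate base cue: retain previous direction
  }
  // (4) density-dependent speed, recomputed every step from the local element
  double sp = dead[n] ? 0.0
                      : par(n, P_SMAX) *
                            tent(rho, par(n, P_RHOL), par(n, P_RHOI), par(n, P_RHOH));
  motvec(n, 0) = sp * motdir(n, 0);
  motvec(n, 1) = sp * motdir(n, 1);
  motvec(n, 2) = sp * motdir(n, 2);
}

// [[Rcpp::export]]
List cpp_update_motility(NumericMatrix pos, NumericMatrix motdir,
                         NumericMatrix par, IntegerVector dead, List subs_conc,
                         NumericMatrix ecm_f, NumericVector ecm_a,
                         NumericVector ecm_rho, IntegerVector dims,
                         NumericVector origin, double h, double dt, bool two_d) {
  RNGScope scope;
  int n = pos.nrow();
  NumericMatrix md = clone(motdir), mv(n, 3);
  std::vector<const double*> subs;
  for (int s = 0; s < subs_conc.size(); ++s)
    subs.push_back(REAL((SEXP)subs_conc[s]));
  int necm = ecm_f.nrow();
  for (int i = 0; i < n; ++i)
    motility_one(i, par, pos, md, mv, dead, subs, &ecm_f[0], &ecm_a[0],
                 &ecm_rho[0], dims[0], dims[1], dims[2], &origin[0], h, dt,
                 two_d, necm);
  return List::create(_["motdir"] = md, _["motvec"] = mv);
}

// contact census: cells i and j are in contact when their center distance is
// below R_i + R_j. Returns N x (ntypes + 1): live contacts per type, then
// contacts with dead cells (any type) in the final column.
// [[Rcpp::export]]
IntegerMatrix cpp_contact_counts(NumericMatrix pos, NumericVector radius,
                                 IntegerVector dead, IntegerVector type,
                                 int ntypes) {
  int n = pos.nrow();
  IntegerMatrix cnt(n, ntypes + 1);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(j, 0) - pos(i, 0);
      double dy = pos(j, 1) - pos(i, 1);
      double dz = pos(j, 2) - pos(i, 2);
      double R = radius[i] + radius[j];
      if (dx * dx + dy * dy + dz * dz >= R * R) continue;
      if (dead[j]) cnt(i, ntypes)++; else cnt(i, type[j] - 1)++;
      if (dead[i]) cnt(j, ntypes)++; else cnt(j, type[i] - 1)++;
    }
  return cnt;
}

// ---------------------------------------------------------------------------
// full engine: n_steps mechanics steps with nested diffusion substeps
// [[Rcpp::export]]
List cpp_engine_advance(NumericMatrix pos0, NumericMatrix motdir0,
                        NumericVector radius0, NumericVector volume0,
                        IntegerVector dead, NumericMatrix par,
                        NumericMatrix sec_rate, NumericMatrix sec_target,
                        NumericMatrix upt_rate, NumericMatrix ecm_f0,
                        NumericVector ecm_a0, NumericVector ecm_rho0,
                        List subs, IntegerVector dims, NumericVector origin,
                        double h, NumericVector dom_lo, NumericVector dom_hi,
                        int n_steps, double dt_mech, int n_diff, double dt_diff,
                        bool two_d, bool wrap_x, double adh_factor,
                        double shrink_rate) {
  RNGScope scope;
  int n = pos0.nrow();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  NumericMatrix pos = clone(pos0), motdir = clone(motdir0);
  NumericVector radius = clone(radius0), volume = clone(volume0);
  NumericMatrix ecm_f = clone(ecm_f0);
  NumericVector ecm_a = clone(ecm_a0), ecm_rho = clone(ecm_rho0);
  NumericMatrix motvec(n, 3), pv(n, 3), vel(n, 3);
  int necm = ecm_f.nrow();
  double zc = 0.5 * (dom_lo[2] + dom_hi[2]);

  // substrate working copies
  int nsub = subs.size();
  std::vector<std::vector<double>> conc(nsub);
  std::vector<double> Dv(nsub), Lv(nsub);
  std::vector<int> isstatic(nsub);
  std::vector<std::vector<double>> dirich(nsub);
  for (int s = 0; s < nsub; ++s) {
    List sb = subs[s];
    NumericVector cc = sb["conc"];
    conc[s].assign(cc.begin(), cc.end());
    Dv[s] = as<double>(sb["D"]);
    Lv[s] = as<double>(sb["lambda"]);
    isstatic[s] = as<bool>(sb["static"]);
    NumericVector dd = sb["dirichlet"];
    dirich[s].assign(dd.begin(), dd.end());
  }
  std::vector<const double*> subptr(nsub);
  for (int s = 0; s < nsub; ++s) subptr[s] = conc[s].data();

  double vvox = h * h * h;
  for (int step = 0; step < n_steps; ++step) {
    // --- diffusion substeps with cell sources/uptake ---
    for (int s = 0; s < nsub; ++s) {
      if (isstatic[s]) continue;
      for (int d = 0; d < n_diff; ++d) {
        for (int c = 0; c < n; ++c) {
          double S = sec_rate(c, s), U = upt_rate(c, s);
          if (S <= 0 && U <= 0) continue;
          int i = voxel_of(pos(c, 0), origin[0], h, nx);
          int j = voxel_of(pos(c, 1), origin[1], h, ny);
          int k = voxel_of(pos(c, 2), origin[2], h, nz);
          size_t idx = i + (size_t)nx * (j + (size_t)ny * k);
          double f = volume[c] / vvox;
          conc[s][idx] = (conc[s][idx] + dt_diff * f * S * sec_target(c, s)) /
                         (1.0 + dt_diff * f * (S + U));
        }
        diffuse_decay(conc[s], nx, ny, nz, h, Dv[s], Lv[s], dt_diff,
                      dirich[s].data());
      }
    }
    // --- motility ---
    for (int c = 0; c < n; ++c)
      motility_one(c, par, pos, motdir, motvec, dead, subptr, &ecm_f[0],
                   &ecm_a[0], &ecm_rho[0], nx, ny, nz, &origin[0], h, dt_mech,
                   two_d, necm);
    // --- pairwise mechanics ---
    {
      NumericVector cca(n), ccr(n);
      for (int c = 0; c < n; ++c) { cca[c] = par(c, P_CCA); ccr[c] = par(c, P_CCR); }
      pair_velocities(pos, radius, cca, ccr, adh_factor, &dom_lo[0], &dom_hi[0], pv);
    }
    // --- advance positions (explicit Euler, reflecting boundaries) ---
    for (int c = 0; c < n; ++c) {
      for (int ax = 0; ax < 3; ++ax) {
        double v = motvec(c, ax) + pv(c, ax);
        vel(c, ax) = v;
        double x = pos(c, ax) + dt_mech * v;
        if (ax == 0 && wrap_x) {
          double w = dom_hi[0] - dom_lo[0];
          while (x >= dom_hi[0]) x -= w;
          while (x < dom_lo[0]) x += w;
        } else {
          if (x < dom_lo[ax]) x = std::min(2.0 * dom_lo[ax] - x, dom_hi[ax]);
          if (x > dom_hi[ax]) x = std::max(2.0 * dom_hi[ax] - x, dom_lo[ax]);
        }
        pos(c, ax) = x;
      }
      if (two_d) pos(c, 2) = zc;
    }
    // --- ECM remodeling, in cell storage (id) order ---
    for (int c = 0; c < n; ++c) {
      if (dead[c]) continue;
      double rf0 = par(c, P_RF0), ra0 = par(c, P_RA0), rrho = par(c, P_RRHO);
      bool inst = par(c, P_INSTANT) > 0.5;
      if (rf0 <= 0 && ra0 <= 0 && rrho <= 0) continue;
      double vx = vel(c, 0), vy = vel(c, 1), vz = vel(c, 2);
      double speed = std::sqrt(vx * vx + vy * vy + vz * vz);
      int i = voxel_of(pos(c, 0), origin[0], h, nx);
      int j = voxel_of(pos(c, 1), origin[1], h, ny);
      int k = voxel_of(pos(c, 2), origin[2], h, nz);
      size_t e = i + (size_t)nx * (j + (size_t)ny * k);
      if (speed > 0 && (rf0 > 0 || ra0 > 0)) {
        double ux = vx / speed, uy = vy / speed, uz = vz / speed;
        double fx = ecm_f(e, 0), fy = ecm_f(e, 1), fz = ecm_f(e, 2);
        if (inst) {
          ecm_f(e, 0) = ux; ecm_f(e, 1) = uy; ecm_f(e, 2) = uz;
          ecm_a[e] = 1.0;
        } else {
          if (rf0 > 0) {
            double sgn = (fx * ux + fy * uy + fz * uz) >= 0 ? 1.0 : -1.0;
            double kblend = std::min(1.0, rf0 * speed * dt_mech / V_REF);
            double nfx = (1 - kblend) * fx + kblend * sgn * ux;
            double nfy = (1 - kblend) * fy + kblend * sgn * uy;
            double nfz = (1 - kblend) * fz + kblend * sgn * uz;
            double nn = std::sqrt(nfx * nfx + nfy * nfy + nfz * nfz);
            if (nn > 1e-12) {
              ecm_f(e, 0) = nfx / nn; ecm_f(e, 1) = nfy / nn; ecm_f(e, 2) = nfz / nn;
            }
          }
          if (ra0 > 0)
            ecm_a[e] = 1.0 - (1.0 - ecm_a[e]) *
                                 std::exp(-ra0 * speed / V_REF * dt_mech);
        }
      }
      if (rrho > 0) {
        double rt = par(c, P_RHOT);
        ecm_rho[e] = rt + (ecm_rho[e] - rt) * std::exp(-rrho * dt_mech);
      }
      if (ecm_a[e] < 0) ecm_a[e] = 0; if (ecm_a[e] > 1) ecm_a[e] = 1;
      if (ecm_rho[e] < 0) ecm_rho[e] = 0; if (ecm_rho[e] > 1) ecm_rho[e] = 1;
    }
    // --- dead cell shrinkage ---
    if (shrink_rate > 0) {
      double f = std::exp(-shrink_rate * dt_mech);
      for (int c = 0; c < n; ++c) {
        if (!dead[c]) continue;
        volume[c] *= f;
        radius[c] = std::cbrt(3.0 * volume[c] / (4.0 * M_PI));
      }
    }
  }
  for (int c = 0; c < n; ++c)
    for (int ax = 0; ax < 3; ++ax)
      if (!R_finite(pos(c, ax)))
        stop("non-finite position for cell %d (mechanics)", c + 1);
  List subs_out(nsub);
  for (int s = 0; s < nsub; ++s)
    subs_out[s] = NumericVector(conc[s].begin(), conc[s].end());
  return List::create(_["pos"] = pos, _["motdir"] = motdir, _["vel"] = vel,
                      _["radius"] = radius, _["volume"] = volume,
                      _["ecm_f"] = ecm_f, _["ecm_a"] = ecm_a,
                      _["ecm_rho"] = ecm_rho, _["subs_conc"] = subs_out);
}
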