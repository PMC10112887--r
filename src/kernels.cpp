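// Low-level lattice kernels for the multi-phase-field monolayer model.
//
// Conventions shared with the R side:
//  * 3D arrays are column-major (R order), index = x + nx*(y + ny*z), 0-based here.
//  * The lattice is periodic in x and y, bounded in z with no-flux (mirror)
//    boundaries for Laplacians and one-sided differences for gradients.
//  * Each cell field lives on a rectangular subdomain with a 0-based global
//    offset `off`; x/y offsets may wrap around the periodic box.
//  * Stencils assume unit grid spacing; physical factors of the grid spacing
//    a0 are folded into the coefficients passed from R.
//  * Gradient-squared energy terms use forward differences so that the
//    7-point Laplacian in the functional derivative is their exact discrete
//    adjoint (the analytic derivative then matches a central-difference
//    variation of the discrete energy to round-off).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int wrap(int i, int n) {
  int r = i % n;
  return r < 0 ? r + n : r;
}

// mirror index for no-flux z boundaries
static inline int mirror(int i, int n) {
  if (i < 0) return -i - 1;
  if (i >= n) return 2 * n - i - 1;
  return i;
}

// [[Rcpp::export]]
void cpp_scatter_add(NumericVector global, IntegerVector gdim,
                     NumericVector sub, IntegerVector sdim,
                     IntegerVector off, int power) {
  const int nx = gdim[0], ny = gdim[1], nz = gdim[2];
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int ox = off[0], oy = off[1], oz = off[2];
  for (int k = 0; k < sz; ++k) {
    int gz = oz + k;
    if (gz < 0 || gz >= nz) continue;
    for (int j = 0; j < sy; ++j) {
      int gy = wrap(oy + j, ny);
      for (int i = 0; i < sx; ++i) {
        int gx = wrap(ox + i, nx);
        double v = sub[i + sx * (j + sy * k)];
        if (power == 2) v *= v;
        global[gx + nx * (gy + ny * gz)] += v;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gather(NumericVector global, IntegerVector gdim,
                         IntegerVector off, IntegerVector sdim) {
  const int nx = gdim[0], ny = gdim[1], nz = gdim[2];
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int ox = off[0], oy = off[1], oz = off[2];
  NumericVector out((R_xlen_t)sx * sy * sz);
  for (int k = 0; k < sz; ++k) {
    int gz = oz + k;
    if (gz < 0 || gz >= nz) continue;  // zero-Dirichlet z halo
    for (int j = 0; j < sy; ++j) {
      int gy = wrap(oy + j, ny);
      for (int i = 0; i < sx; ++i) {
        int gx = wrap(ox + i, nx);
        out[i + sx * (j + sy * k)] = global[gx + nx * (gy + ny * gz)];
      }
    }
  }
  return out;
}

// Re-box a subdomain field: copy values into a new subdomain (offset/dims),
// zero where the old subdomain does not cover the new one.
// [[Rcpp::export]]
NumericVector cpp_crop_pad(NumericVector phi, IntegerVector sdimOld, IntegerVector offOld,
                           IntegerVector offNew, IntegerVector sdimNew, IntegerVector gdim) {
  const int nx = gdim[0], ny = gdim[1];
  const int ax = sdimOld[0], ay = sdimOld[1], az = sdimOld[2];
  const int bx = sdimNew[0], by = sdimNew[1], bz = sdimNew[2];
  NumericVector out((R_xlen_t)bx * by * bz);
  for (int k = 0; k < bz; ++k) {
    int gz = offNew[2] + k;
    int ak = gz - offOld[2];
    if (ak < 0 || ak >= az) continue;
    for (int j = 0; j < by; ++j) {
      int gy = offNew[1] + j;
      int aj = wrap(gy - offOld[1], ny);
      if (aj >= ay) continue;
      for (int i = 0; i < bx; ++i) {
        int gx = offNew[0] + i;
        int ai = wrap(gx - offOld[0], nx);
        if (ai >= ax) continue;
        out[i + bx * (j + by * k)] = phi[ai + ax * (aj + ay * ak)];
      }
    }
  }
  return out;
}

// 7-point Laplacian, periodic in x/y, zero-Dirichlet in z (unit spacing) --
// the same halo convention the cell fields use, keeping the functional
// derivative the exact adjoint of the discrete energy at the z boundaries.
// [[Rcpp::export]]
NumericVector cpp_lap_global(NumericVector f, IntegerVector gdim) {
  const int nx = gdim[0], ny = gdim[1], nz = gdim[2];
  NumericVector out(f.size());
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      int jp = wrap(j + 1, ny), jm = wrap(j - 1, ny);
      for (int i = 0; i < nx; ++i) {
        int ip = wrap(i + 1, nx), im = wrap(i - 1, nx);
        double c = f[i + nx * (j + ny * k)];
        double up = (k + 1 < nz) ? f[i + nx * (j + ny * (k + 1))] : 0.0;
        double dn = (k - 1 >= 0) ? f[i + nx * (j + ny * (k - 1))] : 0.0;
        out[i + nx * (j + ny * k)] =
          f[ip + nx * (j + ny * k)] + f[im + nx * (j + ny * k)] +
          f[i + nx * (jp + ny * k)] + f[i + nx * (jm + ny * k)] +
          up + dn - 6.0 * c;
      }
    }
  }
  return out;
}

// Central gradient, periodic x/y; one-sided first-order at z boundaries.
// [[Rcpp::export]]
List cpp_grad_global(NumericVector f, IntegerVector gdim) {
  const int nx = gdim[0], ny = gdim[1], nz = gdim[2];
  NumericVector gx(f.size()), gy(f.size()), gz(f.size());
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      int jp = wrap(j + 1, ny), jm = wrap(j - 1, ny);
      for (int i = 0; i < nx; ++i) {
        int ip = wrap(i + 1, nx), im = wrap(i - 1, nx);
        R_xlen_t idx = i + nx * (j + (R_xlen_t)ny * k);
        gx[idx] = 0.5 * (f[ip + nx * (j + ny * k)] - f[im + nx * (j + ny * k)]);
        gy[idx] = 0.5 * (f[i + nx * (jp + ny * k)] - f[i + nx * (jm + ny * k)]);
        if (k == 0) {
          gz[idx] = f[i + nx * (j + ny * 1)] - f[i + nx * (j + ny * 0)];
        } else if (k == nz - 1) {
          gz[idx] = f[i + nx * (j + ny * k)] - f[i + nx * (j + ny * (k - 1))];
        } else {
          gz[idx] = 0.5 * (f[i + nx * (j + ny * (k + 1))] - f[i + nx * (j + ny * (k - 1))]);
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gy"] = gy, _["gz"] = gz);
}

// Laplacian on a subdomain with zero-Dirichlet halo (cell fields vanish at the
// subdomain boundary by construction).
// [[Rcpp::export]]
NumericVector cpp_lap_sub(NumericVector f, IntegerVector sdim) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  NumericVector out(f.size());
  auto at = [&](int i, int j, int k) -> double {
    if (i < 0 || i >= sx || j < 0 || j >= sy || k < 0 || k >= sz) return 0.0;
    return f[i + sx * (j + sy * k)];
  };
  for (int k = 0; k < sz; ++k)
    for (int j = 0; j < sy; ++j)
      for (int i = 0; i < sx; ++i)
        out[i + sx * (j + sy * k)] =
          at(i + 1, j, k) + at(i - 1, j, k) + at(i, j + 1, k) + at(i, j - 1, k) +
          at(i, j, k + 1) + at(i, j, k - 1) - 6.0 * at(i, j, k);
  return out;
}

// Central gradient on a subdomain with zero halo (unit spacing).
// [[Rcpp::export]]
List cpp_grad_sub(NumericVector f, IntegerVector sdim) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  NumericVector gx(f.size()), gy(f.size()), gz(f.size());
  auto at = [&](int i, int j, int k) -> double {
    if (i < 0 || i >= sx || j < 0 || j >= sy || k < 0 || k >= sz) return 0.0;
    return f[i + sx * (j + sy * k)];
  };
  for (int k = 0; k < sz; ++k)
    for (int j = 0; j < sy; ++j)
      for (int i = 0; i < sx; ++i) {
        R_xlen_t idx = i + sx * (j + (R_xlen_t)sy * k);
        gx[idx] = 0.5 * (at(i + 1, j, k) - at(i - 1, j, k));
        gy[idx] = 0.5 * (at(i, j + 1, k) - at(i, j - 1, k));
        gz[idx] = 0.5 * (at(i, j, k + 1) - at(i, j, k - 1));
      }
  return List::create(_["gx"] = gx, _["gy"] = gy, _["gz"] = gz);
}

// Functional derivative of the free energy with respect to one cell field,
// evaluated on its subdomain.  Cross terms enter through the cell-summed
// fields S2 = sum_j phi_j^2 and lapS = lap(sum_j phi_j) gathered on the
// subdomain; the cell's own contribution is subtracted in place.  Substrate
// terms depend on z only and are passed as per-plane vectors indexed by the
// global z of the subdomain.  All c_* coefficients are prefolded in R:
//   c_ch  = 8 gamma / lambda
//   c_lap = 2 gamma lambda / a0^2
//   c_vol = (4 mu / V0) (1 - Vi / V0)
//   c_rep = 4 kappa_cc / lambda
//   c_adh = 2 omega_cc lambda^2 / a0^2
//   c_wrep = 2 kappa_cw / lambda
//   c_wadh = omega_cw lambda^2 / a0^2   (times discrete d2(phi_w)/dz2)
// [[Rcpp::export]]
NumericVector cpp_func_deriv(NumericVector phi, NumericVector lapphi,
                             IntegerVector sdim, int zoff,
                             NumericVector S2sub, NumericVector lapSsub,
                             NumericVector phiw2_z, NumericVector phiwdd_z,
                             double c_ch, double c_lap, double c_vol,
                             double c_rep, double c_adh,
                             double c_wrep, double c_wadh) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  NumericVector out(phi.size());
  for (int k = 0; k < sz; ++k) {
    int gz = zoff + k;
    double pw2 = phiw2_z[gz], pwdd = phiwdd_z[gz];
    for (int j = 0; j < sy; ++j) {
      for (int i = 0; i < sx; ++i) {
        R_xlen_t idx = i + sx * (j + (R_xlen_t)sy * k);
        double p = phi[idx], lp = lapphi[idx];
        out[idx] = c_ch * p * (1.0 - p) * (1.0 - 2.0 * p) - c_lap * lp
                 - c_vol * p
                 + c_rep * p * (S2sub[idx] - p * p)
                 - c_adh * (lapSsub[idx] - lp)
                 + c_wrep * p * pw2
                 - c_wadh * pwdd;
      }
    }
  }
  return out;
}

// Raw per-cell energy sums (unit spacing, no coefficients):
//   out[0] = sum 4 phi^2 (1-phi)^2
//   out[1] = sum_axes (D+ phi)^2                      (forward differences)
//   out[2] = sum phi^2 (S2 - phi^2)
//   out[3] = sum_axes D+ phi . (D+ S - D+ phi)
//   out[4] = sum phi^2 phiw^2(z)
//   out[5] = sum (D+z phi) dwz(z)                     (dwz = forward diff of phiw)
// Forward differences are summed over x = -1 .. sx-1 per axis (the -1 face
// terms, where D+ phi = phi(0) - 0, belong to the discrete energy whose exact
// adjoint is the zero-halo 7-point Laplacian).  Shalo is S gathered on the
// subdomain plus a one-point halo on every side (dims + 2, offset - 1);
// phiwdz_z has length nz + 1 and is indexed by global z + 1, so its first
// entry is the forward difference below the box floor.
// [[Rcpp::export]]
NumericVector cpp_energy_sums(NumericVector phi, IntegerVector sdim, int zoff,
                              NumericVector S2sub, NumericVector Shalo,
                              NumericVector phiw2_z, NumericVector phiwdz_z) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int hx = sx + 2, hy = sy + 2;
  auto at = [&](int i, int j, int k) -> double {
    if (i < 0 || i >= sx || j < 0 || j >= sy || k < 0 || k >= sz) return 0.0;
    return phi[i + sx * (j + sy * k)];
  };
  auto sat = [&](int i, int j, int k) -> double {  // S with halo, shifted by +1
    return Shalo[(i + 1) + hx * ((j + 1) + hy * (k + 1))];
  };
  double e_bulk = 0, e_grad = 0, e_rep = 0, e_adh = 0, e_wrep = 0, e_wadh = 0;
  for (int k = 0; k < sz; ++k) {
    int gz = zoff + k;
    double pw2 = phiw2_z[gz], pwdz = phiwdz_z[gz + 1];
    for (int j = 0; j < sy; ++j) {
      for (int i = 0; i < sx; ++i) {
        double p = at(i, j, k);
        double dpx = at(i + 1, j, k) - p;
        double dpy = at(i, j + 1, k) - p;
        double dpz = at(i, j, k + 1) - p;
        double om = 1.0 - p;
        e_bulk += 4.0 * p * p * om * om;
        e_grad += dpx * dpx + dpy * dpy + dpz * dpz;
        double p2 = p * p;
        e_rep += p2 * (S2sub[i + sx * (j + sy * k)] - p2);
        double s = sat(i, j, k);
        double dsx = sat(i + 1, j, k) - s;
        double dsy = sat(i, j + 1, k) - s;
        double dsz = sat(i, j, k + 1) - s;
        e_adh += dpx * (dsx - dpx) + dpy * (dsy - dpy) + dpz * (dsz - dpz);
        e_wrep += p2 * pw2;
        e_wadh += dpz * pwdz;
      }
    }
  }
  // low-face forward differences (index -1 per axis): D+ phi = phi(0) - 0
  for (int k = 0; k < sz; ++k)
    for (int j = 0; j < sy; ++j) {
      double dp = at(0, j, k);
      double ds = sat(0, j, k) - sat(-1, j, k);
      e_grad += dp * dp;
      e_adh += dp * (ds - dp);
    }
  for (int k = 0; k < sz; ++k)
    for (int i = 0; i < sx; ++i) {
      double dp = at(i, 0, k);
      double ds = sat(i, 0, k) - sat(i, -1, k);
      e_grad += dp * dp;
      e_adh += dp * (ds - dp);
    }
  {
    double pwdz_m1 = phiwdz_z[zoff];  // forward diff below the box floor
    for (int j = 0; j < sy; ++j)
      for (int i = 0; i < sx; ++i) {
        double dp = at(i, j, 0);
        double ds = sat(i, j, 0) - sat(i, j, -1);
        e_grad += dp * dp;
        e_adh += dp * (ds - dp);
        e_wadh += dp * pwdz_m1;
      }
  }
  return NumericVector::create(e_bulk, e_grad, e_rep, e_adh, e_wrep, e_wadh);
}

// First-order upwind v . grad(phi) for a rigid per-cell velocity, zero halo.
// [[Rcpp::export]]
NumericVector cpp_upwind_advect(NumericVector phi, IntegerVector sdim,
                                double vx, double vy, double vz) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  NumericVector out(phi.size());
  auto at = [&](int i, int j, int k) -> double {
    if (i < 0 || i >= sx || j < 0 || j >= sy || k < 0 || k >= sz) return 0.0;
    return phi[i + sx * (j + sy * k)];
  };
  for (int k = 0; k < sz; ++k)
    for (int j = 0; j < sy; ++j)
      for (int i = 0; i < sx; ++i) {
        double c = at(i, j, k);
        double dx = (vx >= 0) ? (c - at(i - 1, j, k)) : (at(i + 1, j, k) - c);
        double dy = (vy >= 0) ? (c - at(i, j - 1, k)) : (at(i, j + 1, k) - c);
        double dz = (vz >= 0) ? (c - at(i, j, k - 1)) : (at(i, j, k + 1) - c);
        out[i + sx * (j + sy * k)] = vx * dx + vy * dy + vz * dz;
      }
  return out;
}

// sum over the subdomain of phi * g for three global fields.
// [[Rcpp::export]]
NumericVector cpp_weighted_grad_sum(NumericVector phi, IntegerVector sdim,
                                    IntegerVector off,
                                    NumericVector gx, NumericVector gy,
                                    NumericVector gz, IntegerVector gdim) {
  const int nx = gdim[0], ny = gdim[1], nz = gdim[2];
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int ox = off[0], oy = off[1], oz = off[2];
  double tx = 0, ty = 0, tz = 0;
  for (int k = 0; k < sz; ++k) {
    int gzi = oz + k;
    if (gzi < 0 || gzi >= nz) continue;
    for (int j = 0; j < sy; ++j) {
      int gyi = wrap(oy + j, ny);
      for (int i = 0; i < sx; ++i) {
        int gxi = wrap(ox + i, nx);
        double p = phi[i + sx * (j + sy * k)];
        R_xlen_t idx = gxi + nx * (gyi + (R_xlen_t)ny * gzi);
        tx += p * gx[idx];
        ty += p * gy[idx];
        tz += p * gz[idx];
      }
    }
  }
  return NumericVector::create(tx, ty, tz);
}

// phi-weighted first moments in subdomain coordinates plus total weight.
// [[Rcpp::export]]
NumericVector cpp_com(NumericVector phi, IntegerVector sdim) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  double wx = 0, wy = 0, wz = 0, w = 0;
  for (int k = 0; k < sz; ++k)
    for (int j = 0; j < sy; ++j)
      for (int i = 0; i < sx; ++i) {
        double p = phi[i + sx * (j + sy * k)];
        w += p; wx += p * i; wy += p * j; wz += p * k;
      }
  return NumericVector::create(wx, wy, wz, w);
}

// Bounding box of phi > thr in subdomain coordinates, or all -1 if empty.
// [[Rcpp::export]]
IntegerVector cpp_support_bbox(NumericVector phi, IntegerVector sdim, double thr) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  int x0 = sx, x1 = -1, y0 = sy, y1 = -1, z0 = sz, z1 = -1;
  for (int k = 0; k < sz; ++k)
    for (int j = 0; j < sy; ++j)
      for (int i = 0; i < sx; ++i)
        if (phi[i + sx * (j + sy * k)] > thr) {
          if (i < x0) x0 = i; if (i > x1) x1 = i;
          if (j < y0) y0 = j; if (j > y1) y1 = j;
          if (k < z0) z0 = k; if (k > z1) z1 = k;
        }
  if (x1 < 0) return IntegerVector::create(-1, -1, -1, -1, -1, -1);
  return IntegerVector::create(x0, x1, y0, y1, z0, z1);
}

// Overlap integral sum phiA^2 phiB^2 over the periodic intersection of two
// subdomains (unit quadrature weight).
// [[Rcpp::export]]
double cpp_pair_overlap(NumericVector phiA, IntegerVector sdimA, IntegerVector offA,
                        NumericVector phiB, IntegerVector sdimB, IntegerVector offB,
                        IntegerVector gdim) {
  const int nx = gdim[0], ny = gdim[1], nz = gdim[2];
  const int ax = sdimA[0], ay = sdimA[1], az = sdimA[2];
  const int bx = sdimB[0], by = sdimB[1], bz = sdimB[2];
  double acc = 0.0;
  for (int k = 0; k < az; ++k) {
    int gz = offA[2] + k;
    if (gz < 0 || gz >= nz) continue;
    int bk = gz - offB[2];
    if (bk < 0 || bk >= bz) continue;
    for (int j = 0; j < ay; ++j) {
      int gy = wrap(offA[1] + j, ny);
      int bj = wrap(gy - offB[1], ny);
      if (bj >= by) continue;
      for (int i = 0; i < ax; ++i) {
        int gx = wrap(offA[0] + i, nx);
        int bi = wrap(gx - offB[0], nx);
        if (bi >= bx) continue;
        double a = phiA[i + ax * (j + ay * k)];
        double b = phiB[bi + bx * (bj + by * bk)];
        acc += a * a * b * b;
      }
    }
  }
  return acc;
}

// Coarse-grained stress: partition the lattice into cubic blocks of side b,
// sigma_ij = 1/(2 Vcg) * sum_{m in block} (T_i(x_m) e_j + T_j(x_m) e_i),
// e = (x0 - x_m)/|x0 - x_m|, x0 the block center; the point x_m = x0 (only
// possible for odd b) is excluded since e is undefined there.
// Returns six arrays (xx, yy, zz, xy, xz, yz) of dim floor(gdim/b).
// [[Rcpp::export]]
List cpp_coarse_stress(NumericVector Tx, NumericVector Ty, NumericVector Tz,
                       IntegerVector gdim, int b, double a0) {
  const int nx = gdim[0], ny = gdim[1];
  const int cx = nx / b, cy = ny / b, cz = gdim[2] / b;
  const double vcg = std::pow(b * a0, 3);
  R_xlen_t n = (R_xlen_t)cx * cy * cz;
  NumericVector sxx(n), syy(n), szz(n), sxy(n), sxz(n), syz(n);
  for (int K = 0; K < cz; ++K)
    for (int J = 0; J < cy; ++J)
      for (int I = 0; I < cx; ++I) {
        double x0 = I * b + (b - 1) / 2.0;
        double y0 = J * b + (b - 1) / 2.0;
        double z0 = K * b + (b - 1) / 2.0;
        double xx = 0, yy = 0, zz = 0, xy = 0, xz = 0, yz = 0;
        for (int k = K * b; k < (K + 1) * b; ++k)
          for (int j = J * b; j < (J + 1) * b; ++j)
            for (int i = I * b; i < (I + 1) * b; ++i) {
              double ex = x0 - i, ey = y0 - j, ez = z0 - k;
              double r = std::sqrt(ex * ex + ey * ey + ez * ez);
              if (r < 1e-12) continue;
              ex /= r; ey /= r; ez /= r;
              R_xlen_t idx = i + nx * (j + (R_xlen_t)ny * k);
              double tx = Tx[idx], ty = Ty[idx], tz = Tz[idx];
              xx += tx * ex; yy += ty * ey; zz += tz * ez;
              xy += 0.5 * (tx * ey + ty * ex);
              xz += 0.5 * (tx * ez + tz * ex);
              yz += 0.5 * (ty * ez + tz * ey);
            }
        R_xlen_t cidx = I + cx * (J + (R_xlen_t)cy * K);
        // diagonal entries: (T_i e_i + T_i e_i)/2 = T_i e_i
        sxx[cidx] = xx / vcg; syy[cidx] = yy / vcg; szz[cidx] = zz / vcg;
        sxy[cidx] = xy / vcg; sxz[cidx] = xz / vcg; syz[cidx] = yz / vcg;
      }
  return List::create(_["xx"] = sxx, _["yy"] = syy, _["zz"] = szz,
                      _["xy"] = sxy, _["xz"] = sxz, _["yz"] = syz);
}

// Mean of a coarse field over one cell's body (phi >= 0.5): returns the sum
// of coarse values visited (one per lattice point of the body) and the count.
// [[Rcpp::export]]
NumericVector cpp_region_mean(NumericVector phi, IntegerVector sdim, IntegerVector off,
                              NumericVector coarse, IntegerVector cdim, int b,
                              IntegerVector gdim) {
  const int nx = gdim[0], ny = gdim[1], nz = gdim[2];
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int cx = cdim[0], cy = cdim[1], cz = cdim[2];
  double acc = 0; double cnt = 0;
  for (int k = 0; k < sz; ++k) {
    int gz = off[2] + k;
    if (gz < 0 || gz >= nz) continue;
    int ck = gz / b; if (ck >= cz) continue;
    for (int j = 0; j < sy; ++j) {
      int gy = wrap(off[1] + j, ny);
      int cj = gy / b; if (cj >= cy) continue;
      for (int i = 0; i < sx; ++i) {
        int gx = wrap(off[0] + i, nx);
        int ci = gx / b; if (ci >= cx) continue;
        if (phi[i + sx * (j + sy * k)] >= 0.5) {
          acc += coarse[ci + cx * (cj + (R_xlen_t)cy * ck)];
          cnt += 1;
        }
      }
    }
  }
  return NumericVector::create(acc, cnt);
}

// Central-difference v . grad(phi) for a rigid per-cell velocity, zero halo.
// [[Rcpp::export]]
NumericVector cpp_central_advect(NumericVector phi, IntegerVector sdim,
                                 double vx, double vy, double vz) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  NumericVector out(phi.size());
  auto at = [&](int i, int j, int k) -> double {
    if (i < 0 || i >= sx || j < 0 || j >= sy || k < 0 || k >= sz) return 0.0;
    return phi[i + sx * (j + sy * k)];
  };
  for (int k = 0; k < sz; ++k)
    for (int j = 0; j < sy; ++j)
      for (int i = 0; i < sx; ++i)
        out[i + sx * (j + sy * k)] =
          vx * 0.5 * (at(i + 1, j, k) - at(i - 1, j, k)) +
          vy * 0.5 * (at(i, j + 1, k) - at(i, j - 1, k)) +
          vz * 0.5 * (at(i, j, k + 1) - at(i, j, k - 1));
  return out;
}

// Fused per-cell derivative pass: computes the zero-halo Laplacian of phi and
// the cross-terms (gathered from the global S2 and lapS fields by index
// arithmetic) in one sweep, returns dF on the subdomain and accumulates -dF
// into the global interaction scalar pi.
// [[Rcpp::export]]
NumericVector cpp_func_deriv_fused(NumericVector phi, IntegerVector sdim,
                                   IntegerVector off, IntegerVector gdim,
                                   NumericVector S2, NumericVector lapS,
                                   NumericVector phiw2_z, NumericVector phiwdd_z,
                                   double c_ch, double c_lap, double c_vol,
                                   double c_rep, double c_adh,
                                   double c_wrep, double c_wadh,
                                   NumericVector pi_field) {
  const int nx = gdim[0], ny = gdim[1], nz = gdim[2];
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int ox = off[0], oy = off[1], oz = off[2];
  NumericVector out(phi.size());
  auto at = [&](int i, int j, int k) -> double {
    if (i < 0 || i >= sx || j < 0 || j >= sy || k < 0 || k >= sz) return 0.0;
    return phi[i + sx * (j + sy * k)];
  };
  for (int k = 0; k < sz; ++k) {
    int gz = oz + k;
    if (gz < 0 || gz >= nz) continue;
    double pw2 = phiw2_z[gz], pwdd = phiwdd_z[gz];
    for (int j = 0; j < sy; ++j) {
      int gy = wrap(oy + j, ny);
      for (int i = 0; i < sx; ++i) {
        int gx = wrap(ox + i, nx);
        R_xlen_t sidx = i + sx * (j + (R_xlen_t)sy * k);
        R_xlen_t gidx = gx + nx * (gy + (R_xlen_t)ny * gz);
        double p = phi[sidx];
        double lp = at(i + 1, j, k) + at(i - 1, j, k) + at(i, j + 1, k) +
                    at(i, j - 1, k) + at(i, j, k + 1) + at(i, j, k - 1) - 6.0 * p;
        double v = c_ch * p * (1.0 - p) * (1.0 - 2.0 * p) - c_lap * lp
                 - c_vol * p
                 + c_rep * p * (S2[gidx] - p * p)
                 - c_adh * (lapS[gidx] - lp)
                 + c_wrep * p * pw2
                 - c_wadh * pwdd;
        out[sidx] = v;
        pi_field[gidx] -= v;
      }
    }
  }
  return out;
}

// Fused advection + explicit Euler update: phi <- phi - dt (v.grad(phi) + dF).
// [[Rcpp::export]]
NumericVector cpp_advect_update(NumericVector phi, IntegerVector sdim,
                                NumericVector dF, double vx, double vy,
                                double vz, double dt, bool upwind) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  NumericVector out(phi.size());
  auto at = [&](int i, int j, int k) -> double {
    if (i < 0 || i >= sx || j < 0 || j >= sy || k < 0 || k >= sz) return 0.0;
    return phi[i + sx * (j + sy * k)];
  };
  for (int k = 0; k < sz; ++k)
    for (int j = 0; j < sy; ++j)
      for (int i = 0; i < sx; ++i) {
        R_xlen_t idx = i + sx * (j + (R_xlen_t)sy * k);
        double c = phi[idx];
        double adv;
        if (upwind) {
          double dx = (vx >= 0) ? (c - at(i - 1, j, k)) : (at(i + 1, j, k) - c);
          double dy = (vy >= 0) ? (c - at(i, j - 1, k)) : (at(i, j + 1, k) - c);
          double dz = (vz >= 0) ? (c - at(i, j, k - 1)) : (at(i, j, k + 1) - c);
          adv = vx * dx + vy * dy + vz * dz;
        } else {
          adv = vx * 0.5 * (at(i + 1, j, k) - at(i - 1, j, k)) +
                vy * 0.5 * (at(i, j + 1, k) - at(i, j - 1, k)) +
                vz * 0.5 * (at(i, j, k + 1) - at(i, j, k - 1));
        }
        out[idx] = c - dt * (adv + dF[idx]);
      }
  return out;
}

// Scatter phi and phi^2 into two global accumulators in one sweep.
// [[Rcpp::export]]
void cpp_scatter_add2(NumericVector S, NumericVector S2, IntegerVector gdim,
                      NumericVector sub, IntegerVector sdim, IntegerVector off) {
  const int nx = gdim[0], ny = gdim[1], nz = gdim[2];
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int ox = off[0], oy = off[1], oz = off[2];
  for (int k = 0; k < sz; ++k) {
    int gz = oz + k;
    if (gz < 0 || gz >= nz) continue;
    for (int j = 0; j < sy; ++j) {
      int gy = wrap(oy + j, ny);
      for (int i = 0; i < sx; ++i) {
        int gx = wrap(ox + i, nx);
        double v = sub[i + sx * (j + sy * k)];
        R_xlen_t g = gx + nx * (gy + (R_xlen_t)ny * gz);
        S[g] += v;
        S2[g] += v * v;
      }
    }
  }
}

// One-pass per-cell field statistics: phi-weighted moments, support bounding
// box at `thr`, and the field's min/max.
// Returns c(wx, wy, wz, w, x0, x1, y0, y1, z0, z1, min, max).
// [[Rcpp::export]]
NumericVector cpp_field_stats(NumericVector phi, IntegerVector sdim, double thr) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  double wx = 0, wy = 0, wz = 0, w = 0, mn = R_PosInf, mx = R_NegInf;
  int x0 = sx, x1 = -1, y0 = sy, y1 = -1, z0 = sz, z1 = -1;
  for (int k = 0; k < sz; ++k)
    for (int j = 0; j < sy; ++j)
      for (int i = 0; i < sx; ++i) {
        double p = phi[i + sx * (j + sy * k)];
        w += p; wx += p * i; wy += p * j; wz += p * k;
        if (p < mn) mn = p;
        if (p > mx) mx = p;
        if (p > thr) {
          if (i < x0) x0 = i; if (i > x1) x1 = i;
          if (j < y0) y0 = j; if (j > y1) y1 = j;
          if (k < z0) z0 = k; if (k > z1) z1 = k;
        }
      }
  return NumericVector::create(wx, wy, wz, w, x0, x1, y0, y1, z0, z1, mn, mx);
}

// [[Rcpp::export]]
double cpp_sumsq(NumericVector phi) {
  double acc = 0;
  for (R_xlen_t i = 0; i < phi.size(); ++i) acc += phi[i] * phi[i];
  return acc;
}
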