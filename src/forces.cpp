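// Energy, forces and virial for the coarse-grained bilayer engine.
// Internal units: nm, kJ/mol, amu, ps, elementary charges.
// Orthorhombic periodic box, minimum-image convention.
//
// Nonbonded: Lennard-Jones with the potential shifted to zero at the
// cutoff (forces untouched), per-type-pair epsilon/sigma tables.
// Bonded: harmonic bonds, cosine-harmonic angles (MARTINI functional
// forms); first bonded neighbours (1-2) are excluded from nonbonded terms.
// Electrostatics: smooth Ewald summation (real + reciprocal + self +
// excluded-pair correction) for charged beads.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double min_image(double d, double L) {
  return d - L * std::round(d / L);
}

// [[Rcpp::export]]
List cg_energy_forces(NumericMatrix coords, NumericVector box,
                      IntegerVector tidx, NumericVector charge,
                      NumericMatrix eps, NumericMatrix sig, double rcut,
                      IntegerMatrix bonds, NumericVector bond_r0,
                      NumericVector bond_k, IntegerMatrix angles,
                      NumericVector angle_theta0, NumericVector angle_fc,
                      bool do_coulomb, double ke, double alpha,
                      IntegerVector kmax) {
  const int n = coords.nrow();
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const double rc2 = rcut * rcut;
  NumericMatrix F(n, 3);
  NumericVector W(3);  // virial tensor diagonal, sum r_ab * f_ab
  double e_lj = 0.0, e_bond = 0.0, e_angle = 0.0;
  double e_real = 0.0, e_recip = 0.0, e_self = 0.0, e_excl = 0.0;
  double min_r = R_PosInf;

  // 1-2 exclusions from the bond list
  std::vector<std::vector<int>> excl(n);
  const int nb = bonds.nrow();
  for (int b = 0; b < nb; ++b) {
    excl[bonds(b, 0)].push_back(bonds(b, 1));
    excl[bonds(b, 1)].push_back(bonds(b, 0));
  }
  auto excluded = [&](int i, int j) {
    for (int q : excl[i]) if (q == j) return true;
    return false;
  };

  const double sqrt_pi = std::sqrt(M_PI);

  // flat copies: the inner loop must not pay Rcpp accessor overhead
  const int nt = eps.nrow();
  std::vector<double> X(n), Y(n), Z(n), Q(n), EPS(nt * nt), SIG(nt * nt);
  std::vector<int> T(n);
  for (int i = 0; i < n; ++i) {
    X[i] = coords(i, 0); Y[i] = coords(i, 1); Z[i] = coords(i, 2);
    Q[i] = charge[i]; T[i] = tidx[i];
  }
  for (int a = 0; a < nt; ++a)
    for (int b = 0; b < nt; ++b) {
      EPS[a * nt + b] = eps(a, b);
      SIG[a * nt + b] = sig(a, b);
    }
  std::vector<double> FX(n, 0.0), FY(n, 0.0), FZ(n, 0.0);

  // ---- nonbonded pair loop (LJ + Ewald real space) -----------------------
  for (int i = 0; i < n - 1; ++i) {
    const double xi = X[i], yi = Y[i], zi = Z[i];
    const int ti = tidx[i];
    const double qi = charge[i];
    for (int j = i + 1; j < n; ++j) {
      double dx = min_image(xi - X[j], Lx);
      double dy = min_image(yi - Y[j], Ly);
      double dz = min_image(zi - Z[j], Lz);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) continue;
      if (!excl[i].empty() && excluded(i, j)) continue;
      double r = std::sqrt(r2);
      if (r < min_r) min_r = r;
      const int tj = T[j];
      const double e = EPS[ti * nt + tj], s = SIG[ti * nt + tj];
      // shifted LJ: V(r) - V(rc); exactly 0 at the cutoff
      double sr2 = s * s / r2;
      double sr6 = sr2 * sr2 * sr2;
      double sr12 = sr6 * sr6;
      double src2 = s * s / rc2;
      double src6 = src2 * src2 * src2;
      double vshift = 4.0 * e * (src6 * src6 - src6);
      e_lj += 4.0 * e * (sr12 - sr6) - vshift;
      double fr = 24.0 * e * (2.0 * sr12 - sr6) / r2;  // (1/r) dV/dr * (-1/r)
      double qq = qi * charge[j];
      if (do_coulomb && qq != 0.0) {
        double erfc_ar = std::erfc(alpha * r);
        e_real += ke * qq * erfc_ar / r;
        fr += ke * qq *
              (erfc_ar / r + 2.0 * alpha / sqrt_pi * std::exp(-alpha * alpha * r2)) /
              r2;
      }
      double fx = fr * dx, fy = fr * dy, fz = fr * dz;
      FX[i] += fx; FY[i] += fy; FZ[i] += fz;
      FX[j] -= fx; FY[j] -= fy; FZ[j] -= fz;
      W[0] += dx * fx; W[1] += dy * fy; W[2] += dz * fz;
    }
  }
  for (int i = 0; i < n; ++i) {
    F(i, 0) += FX[i]; F(i, 1) += FY[i]; F(i, 2) += FZ[i];
  }

  // ---- bonds -------------------------------------------------------------
  for (int b = 0; b < nb; ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double dx = min_image(coords(i, 0) - coords(j, 0), Lx);
    double dy = min_image(coords(i, 1) - coords(j, 1), Ly);
    double dz = min_image(coords(i, 2) - coords(j, 2), Lz);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - bond_r0[b];
    e_bond += 0.5 * bond_k[b] * dr * dr;
    double fr = -bond_k[b] * dr / r;  // force on i along +d
    double fx = fr * dx, fy = fr * dy, fz = fr * dz;
    F(i, 0) += fx; F(i, 1) += fy; F(i, 2) += fz;
    F(j, 0) -= fx; F(j, 1) -= fy; F(j, 2) -= fz;
    W[0] += dx * fx; W[1] += dy * fy; W[2] += dz * fz;
  }

  // ---- angles (cosine harmonic, V = fc/2 (cos t - cos t0)^2) -------------
  const int na = angles.nrow();
  for (int a = 0; a < na; ++a) {
    int i = angles(a, 0), j = angles(a, 1), k = angles(a, 2);  // j is centre
    double ax = min_image(coords(i, 0) - coords(j, 0), Lx);
    double ay = min_image(coords(i, 1) - coords(j, 1), Ly);
    double az = min_image(coords(i, 2) - coords(j, 2), Lz);
    double bx = min_image(coords(k, 0) - coords(j, 0), Lx);
    double by = min_image(coords(k, 1) - coords(j, 1), Ly);
    double bz = min_image(coords(k, 2) - coords(j, 2), Lz);
    double la = std::sqrt(ax * ax + ay * ay + az * az);
    double lb = std::sqrt(bx * bx + by * by + bz * bz);
    double ct = (ax * bx + ay * by + az * bz) / (la * lb);
    if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
    double ct0 = std::cos(angle_theta0[a]);
    double dV = angle_fc[a] * (ct - ct0);  // dV/dcos
    e_angle += 0.5 * angle_fc[a] * (ct - ct0) * (ct - ct0);
    // dcos/da = b/(la lb) - cos * a/la^2 ; F_i = -dV * dcos/da
    double fix = -dV * (bx / (la * lb) - ct * ax / (la * la));
    double fiy = -dV * (by / (la * lb) - ct * ay / (la * la));
    double fiz = -dV * (bz / (la * lb) - ct * az / (la * la));
    double fkx = -dV * (ax / (la * lb) - ct * bx / (lb * lb));
    double fky = -dV * (ay / (la * lb) - ct * by / (lb * lb));
    double fkz = -dV * (az / (la * lb) - ct * bz / (lb * lb));
    F(i, 0) += fix; F(i, 1) += fiy; F(i, 2) += fiz;
    F(k, 0) += fkx; F(k, 1) += fky; F(k, 2) += fkz;
    F(j, 0) -= fix + fkx; F(j, 1) -= fiy + fky; F(j, 2) -= fiz + fkz;
    W[0] += ax * fix + bx * fkx;
    W[1] += ay * fiy + by * fky;
    W[2] += az * fiz + bz * fkz;
  }

  // ---- Ewald reciprocal space, self term, excluded-pair correction -------
  if (do_coulomb) {
    std::vector<int> ch;
    for (int i = 0; i < n; ++i) if (charge[i] != 0.0) ch.push_back(i);
    const int nc = (int)ch.size();
    if (nc > 0) {
      const double V = Lx * Ly * Lz;
      const int kx = kmax[0], ky = kmax[1], kz = kmax[2];
      const double tpx = 2.0 * M_PI / Lx, tpy = 2.0 * M_PI / Ly,
                   tpz = 2.0 * M_PI / Lz;
      // per-particle phase tables e^{i m g x} for m = 0..kmax
      auto mk_tab = [&](int km, double g, int axis,
                        std::vector<double>& c, std::vector<double>& s) {
        c.assign((size_t)(km + 1) * nc, 0.0);
        s.assign((size_t)(km + 1) * nc, 0.0);
        for (int p = 0; p < nc; ++p) {
          double x = coords(ch[p], axis);
          c[p] = 1.0; s[p] = 0.0;
          double c1 = std::cos(g * x), s1 = std::sin(g * x);
          for (int m = 1; m <= km; ++m) {
            c[(size_t)m * nc + p] =
                c[(size_t)(m - 1) * nc + p] * c1 - s[(size_t)(m - 1) * nc + p] * s1;
            s[(size_t)m * nc + p] =
                s[(size_t)(m - 1) * nc + p] * c1 + c[(size_t)(m - 1) * nc + p] * s1;
          }
        }
      };
      std::vector<double> cx, sx, cy, sy, cz, sz;
      mk_tab(kx, tpx, 0, cx, sx);
      mk_tab(ky, tpy, 1, cy, sy);
      mk_tab(kz, tpz, 2, cz, sz);
      const double kcut2 = -4.0 * alpha * alpha * std::log(1e-12);
      std::vector<double> cph(nc), sph(nc);
      for (int mx = 0; mx <= kx; ++mx) {
        for (int my = (mx == 0 ? 0 : -ky); my <= ky; ++my) {
          for (int mz = -kz; mz <= kz; ++mz) {
            if (mx == 0 && my == 0 && mz <= 0) continue;
            if (mx == 0 && my < 0) continue;
            double gx = mx * tpx, gy = my * tpy, gz = mz * tpz;
            double k2 = gx * gx + gy * gy + gz * gz;
            if (k2 > kcut2) continue;
            double A = std::exp(-k2 / (4.0 * alpha * alpha)) / k2;
            double reS = 0.0, imS = 0.0;
            int ay_ = std::abs(my), az_ = std::abs(mz);
            for (int p = 0; p < nc; ++p) {
              double cxy = cx[(size_t)mx * nc + p] * cy[(size_t)ay_ * nc + p] -
                           sx[(size_t)mx * nc + p] *
                               (my < 0 ? -sy[(size_t)ay_ * nc + p]
                                       : sy[(size_t)ay_ * nc + p]);
              double sxy = sx[(size_t)mx * nc + p] * cy[(size_t)ay_ * nc + p] +
                           cx[(size_t)mx * nc + p] *
                               (my < 0 ? -sy[(size_t)ay_ * nc + p]
                                       : sy[(size_t)ay_ * nc + p]);
              double szz = (mz < 0 ? -sz[(size_t)az_ * nc + p]
                                   : sz[(size_t)az_ * nc + p]);
              double czz = cz[(size_t)az_ * nc + p];
              double cp = cxy * czz - sxy * szz;
              double sp = sxy * czz + cxy * szz;
              cph[p] = cp; sph[p] = sp;
              double q = charge[ch[p]];
              reS += q * cp;
              imS += q * sp;
            }
            // half-space sum: each k stands for the +k/-k pair
            double pref = 2.0 * (2.0 * M_PI * ke / V) * A;
            double s2 = reS * reS + imS * imS;
            e_recip += pref * s2;
            for (int p = 0; p < nc; ++p) {
              double q = charge[ch[p]];
              double f = 2.0 * pref * q * (sph[p] * reS - cph[p] * imS);
              F(ch[p], 0) += f * gx;
              F(ch[p], 1) += f * gy;
              F(ch[p], 2) += f * gz;
            }
            double wfac = pref * s2;
            double c2 = 2.0 * (1.0 / k2 + 1.0 / (4.0 * alpha * alpha));
            W[0] += wfac * (1.0 - c2 * gx * gx);
            W[1] += wfac * (1.0 - c2 * gy * gy);
            W[2] += wfac * (1.0 - c2 * gz * gz);
          }
        }
      }
      double q2 = 0.0;
      for (int p = 0; p < nc; ++p) q2 += charge[ch[p]] * charge[ch[p]];
      e_self = -ke * alpha / sqrt_pi * q2;
      // excluded 1-2 pairs: remove the full-lattice (erf) part
      for (int b = 0; b < nb; ++b) {
        int i = bonds(b, 0), j = bonds(b, 1);
        double qq = charge[i] * charge[j];
        if (qq == 0.0) continue;
        double dx = min_image(coords(i, 0) - coords(j, 0), Lx);
        double dy = min_image(coords(i, 1) - coords(j, 1), Ly);
        double dz = min_image(coords(i, 2) - coords(j, 2), Lz);
        double r2 = dx * dx + dy * dy + dz * dz;
        double r = std::sqrt(r2);
        double erf_ar = std::erf(alpha * r);
        e_excl -= ke * qq * erf_ar / r;
        double fr = -ke * qq *
                    (erf_ar / r - 2.0 * alpha / sqrt_pi * std::exp(-alpha * alpha * r2)) /
                    r2;
        double fx = fr * dx, fy = fr * dy, fz = fr * dz;
        F(i, 0) += fx; F(i, 1) += fy; F(i, 2) += fz;
        F(j, 0) -= fx; F(j, 1) -= fy; F(j, 2) -= fz;
        W[0] += dx * fx; W[1] += dy * fy; W[2] += dz * fz;
      }
    }
  }

  double e_coul = e_real + e_recip + e_self + e_excl;
  return List::create(
      _["potential"] = e_lj + e_bond + e_angle + e_coul,
      _["lj"] = e_lj, _["bond"] = e_bond, _["angle"] = e_angle,
      _["coulomb"] = e_coul, _["coul_real"] = e_real,
      _["coul_recip"] = e_recip, _["coul_self"] = e_self,
      _["coul_excl"] = e_excl, _["forces"] = F, _["virial"] = W,
      _["min_dist"] = min_r);
}
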