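// Voxel Monte Carlo photon transport for frequency-domain diffuse optical
// tomography under the microscopic Beer-Lambert law (mBLL): trajectories are
// sampled independently of absorption, per-voxel partial pathlengths of
// detected photons are recorded, and weights / FD measurements / absorption
// Jacobians are recomputed afterwards for any absorption field ("replay").
//
// Conventions: lengths mm, time ns, coefficients mm^-1, frequency GHz.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double C_VACUUM = 299.792458; // mm / ns

// ---- counter-based RNG: each photon owns an independent splitmix64 stream
struct Splitmix {
  uint64_t s;
  explicit Splitmix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  // uniform in (0, 1]; never 0 so -log() is finite
  double unif() {
    return (double)((next() >> 11) + 1) * (1.0 / 9007199254740993.0);
  }
};

static uint64_t mix_seed(uint64_t seed, uint64_t idx) {
  // distinct, well-separated stream origin per (run seed, launch index)
  uint64_t z = seed * 0x9e3779b97f4a7c15ULL + idx * 0xd1b54a32d192ed03ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// unpolarized Fresnel reflectance, incidence cosine ci from n_i into n_t
static double fresnel_R(double ci, double n_i, double n_t) {
  if (ci > 1.0) ci = 1.0;
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = n_i / n_t * si;
  if (st >= 1.0) return 1.0; // total internal reflection
  double ct = std::sqrt(std::max(0.0, 1.0 - st * st));
  double rs = (n_i * ci - n_t * ct) / (n_i * ci + n_t * ct);
  double rp = (n_i * ct - n_t * ci) / (n_i * ct + n_t * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein deflection: rotate dir by sampled (theta, phi)
static void hg_scatter(double g, Splitmix &rng, double dir[3]) {
  double ct;
  double u = rng.unif();
  if (std::fabs(g) < 1e-7) {
    ct = 1.0 - 2.0 * u;
  } else {
    double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
    ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
  }
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * rng.unif();
  double cp = std::cos(phi), sp = std::sin(phi);
  double ux = dir[0], uy = dir[1], uz = dir[2];
  if (std::fabs(uz) > 0.99999) {
    dir[0] = st * cp;
    dir[1] = st * sp;
    dir[2] = (uz > 0 ? ct : -ct);
  } else {
    double denom = std::sqrt(1.0 - uz * uz);
    dir[0] = st * (ux * uz * cp - uy * sp) / denom + ux * ct;
    dir[1] = st * (uy * uz * cp + ux * sp) / denom + uy * ct;
    dir[2] = -st * cp * denom + uz * ct;
  }
  // renormalize occasionally for numerical hygiene
  double nrm = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] + dir[2] * dir[2]);
  dir[0] /= nrm; dir[1] /= nrm; dir[2] /= nrm;
}

// [[Rcpp::export(name = ".mc_transport_cpp")]]
List mc_transport_cpp(IntegerVector labels, IntegerVector dims, double spacing,
                      NumericVector origin, NumericVector mus_tab,
                      NumericVector g_tab, NumericVector n_tab, double n_ext,
                      NumericVector source, NumericVector target,
                      double src_radius, NumericMatrix detectors,
                      double det_radius, NumericVector photon_idx,
                      double seed, double tmax) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const double h = spacing;
  const int ndet = detectors.nrow();

  // launch frame: beam axis toward the target (probe centre of curvature)
  double dlaunch[3] = {target[0] - source[0], target[1] - source[1],
                       target[2] - source[2]};
  double dn = std::sqrt(dlaunch[0] * dlaunch[0] + dlaunch[1] * dlaunch[1] +
                        dlaunch[2] * dlaunch[2]);
  if (dn <= 0) stop("launch target coincides with the source");
  for (int a = 0; a < 3; ++a) dlaunch[a] /= dn;
  // orthonormal basis of the source disk
  double e1[3], e2[3];
  if (std::fabs(dlaunch[0]) < 0.9) { e1[0] = 0; e1[1] = -dlaunch[2]; e1[2] = dlaunch[1]; }
  else { e1[0] = -dlaunch[2]; e1[1] = 0; e1[2] = dlaunch[0]; }
  double e1n = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
  for (int a = 0; a < 3; ++a) e1[a] /= e1n;
  e2[0] = dlaunch[1] * e1[2] - dlaunch[2] * e1[1];
  e2[1] = dlaunch[2] * e1[0] - dlaunch[0] * e1[2];
  e2[2] = dlaunch[0] * e1[1] - dlaunch[1] * e1[0];

  // per-photon sparse path accumulation (stamp trick)
  std::vector<int64_t> stamp(nvox, -1);
  std::vector<double> acc(nvox, 0.0);
  std::vector<int> touched;
  touched.reserve(4096);

  // outputs
  std::vector<int> out_det;
  std::vector<double> out_tof;
  std::vector<double> out_ptr(1, 0.0);
  std::vector<int> out_vox;
  std::vector<double> out_len;
  std::vector<double> out_launch;
  double n_terminated = 0, n_escaped = 0, n_miss = 0;

  const double inv_c = 1.0 / C_VACUUM;
  const R_xlen_t nph = photon_idx.size();

  for (R_xlen_t ip = 0; ip < nph; ++ip) {
    const double pidx = photon_idx[ip];
    Splitmix rng(mix_seed((uint64_t)seed, (uint64_t)pidx));

    // sample launch point on the source disk
    double r = src_radius * std::sqrt(rng.unif());
    double th = 2.0 * M_PI * rng.unif();
    double pos[3], dir[3] = {dlaunch[0], dlaunch[1], dlaunch[2]};
    for (int a = 0; a < 3; ++a)
      pos[a] = source[a] + r * (std::cos(th) * e1[a] + std::sin(th) * e2[a]);

    // march from slightly outside toward the head to find the entry voxel;
    // specular reflection at launch is not considered (full weight inside)
    int ix = -1, iy = -1, iz = -1, lab = 0;
    {
      double t0 = -2.0 * h;
      bool found = false;
      for (int k = 0; k <= 160 && !found; ++k) {
        double t = t0 + k * (h / 16.0);
        double q[3] = {pos[0] + t * dir[0], pos[1] + t * dir[1],
                       pos[2] + t * dir[2]};
        int jx = (int)std::floor((q[0] - origin[0]) / h);
        int jy = (int)std::floor((q[1] - origin[1]) / h);
        int jz = (int)std::floor((q[2] - origin[2]) / h);
        if (jx < 0 || jy < 0 || jz < 0 || jx >= nx || jy >= ny || jz >= nz)
          continue;
        int l = labels[(R_xlen_t)jx + nx * ((R_xlen_t)jy + (R_xlen_t)ny * jz)];
        if (l > 0) {
          ix = jx; iy = jy; iz = jz; lab = l;
          // snap back to the exact entry face of this voxel so ballistic
          // chords are exact (launch point sits on the boundary)
          double tin = -1e300;
          for (int a = 0; a < 3; ++a) {
            if (std::fabs(dir[a]) < 1e-14) continue;
            int ja = (a == 0) ? jx : (a == 1) ? jy : jz;
            double lo = origin[a] + ja * h, hi = lo + h;
            double ta = ((dir[a] > 0 ? lo : hi) - pos[a]) / dir[a];
            if (ta > tin) tin = ta;
          }
          if (tin < 0) tin = 0; // launch point already inside the voxel
          for (int a = 0; a < 3; ++a) pos[a] = pos[a] + tin * dir[a];
          found = true;
        }
      }
      if (!found) { n_miss += 1; continue; }
    }

    double t_fl = 0.0;            // time of flight, ns
    double s_left = -std::log(rng.unif()); // dimensionless scattering length
    int64_t me = (int64_t)ip;
    touched.clear();
    bool alive = true;
    int det_hit = -1;

    while (alive) {
      R_xlen_t lin = (R_xlen_t)ix + nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz);
      double mus = mus_tab[lab];
      double nmed = n_tab[lab];

      // distance to the voxel faces along dir
      double vx0 = origin[0] + ix * h, vy0 = origin[1] + iy * h,
             vz0 = origin[2] + iz * h;
      double tface = 1e300;
      int axis = -1, sgn = 0;
      if (dir[0] > 1e-14) {
        double t = (vx0 + h - pos[0]) / dir[0];
        if (t < tface) { tface = t; axis = 0; sgn = 1; }
      } else if (dir[0] < -1e-14) {
        double t = (vx0 - pos[0]) / dir[0];
        if (t < tface) { tface = t; axis = 0; sgn = -1; }
      }
      if (dir[1] > 1e-14) {
        double t = (vy0 + h - pos[1]) / dir[1];
        if (t < tface) { tface = t; axis = 1; sgn = 1; }
      } else if (dir[1] < -1e-14) {
        double t = (vy0 - pos[1]) / dir[1];
        if (t < tface) { tface = t; axis = 1; sgn = -1; }
      }
      if (dir[2] > 1e-14) {
        double t = (vz0 + h - pos[2]) / dir[2];
        if (t < tface) { tface = t; axis = 2; sgn = 1; }
      } else if (dir[2] < -1e-14) {
        double t = (vz0 - pos[2]) / dir[2];
        if (t < tface) { tface = t; axis = 2; sgn = -1; }
      }
      if (tface < 0) tface = 0;

      double lgeo = (mus > 0) ? s_left / mus : 1e300;
      double step = (lgeo < tface) ? lgeo : tface;

      // accumulate partial path and time
      if (step > 0) {
        if (stamp[lin] != me) { stamp[lin] = me; acc[lin] = step; touched.push_back((int)lin); }
        else acc[lin] += step;
        t_fl += step * nmed * inv_c;
        for (int a = 0; a < 3; ++a) pos[a] += step * dir[a];
      }
      if (t_fl > tmax) { n_terminated += 1; alive = false; break; }

      if (lgeo < tface) {
        // scattering event inside the voxel
        hg_scatter(g_tab[lab], rng, dir);
        s_left = -std::log(rng.unif());
        continue;
      }

      // face crossing
      s_left -= tface * mus;
      if (s_left < 0) s_left = 0;
      int jx = ix, jy = iy, jz = iz;
      if (axis == 0) jx += sgn; else if (axis == 1) jy += sgn; else jz += sgn;
      int lnew = 0;
      if (jx >= 0 && jy >= 0 && jz >= 0 && jx < nx && jy < ny && jz < nz)
        lnew = labels[(R_xlen_t)jx + nx * ((R_xlen_t)jy + (R_xlen_t)ny * jz)];

      if (lnew > 0) { // interior crossing; n constant across tissues by default
        ix = jx; iy = jy; iz = jz; lab = lnew;
        continue;
      }

      // exterior boundary: binary Fresnel reflect-or-exit
      double ci = std::fabs(dir[axis]);
      double RF = (std::fabs(nmed - n_ext) < 1e-12) ? 0.0
                                                    : fresnel_R(ci, nmed, n_ext);
      if (rng.unif() < RF) {
        dir[axis] = -dir[axis];
        continue; // stays in the same voxel
      }
      // exits the domain at pos; detector capture by chord distance
      det_hit = -1;
      double best = det_radius * det_radius;
      for (int d = 0; d < ndet; ++d) {
        double dx = pos[0] - detectors(d, 0);
        double dy = pos[1] - detectors(d, 1);
        double dz = pos[2] - detectors(d, 2);
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 <= best) { best = d2; det_hit = d; }
      }
      alive = false;
    }

    if (det_hit >= 0) {
      out_det.push_back(det_hit + 1);
      out_tof.push_back(t_fl);
      out_launch.push_back(pidx);
      for (size_t q = 0; q < touched.size(); ++q) {
        out_vox.push_back(touched[q] + 1);
        out_len.push_back(acc[touched[q]]);
      }
      out_ptr.push_back((double)out_vox.size());
    } else if (det_hit < 0 && !alive && t_fl <= tmax) {
      n_escaped += 1;
    }
  }

  return List::create(
    _["detector"] = wrap(out_det), _["tof"] = wrap(out_tof),
    _["ptr"] = wrap(out_ptr), _["voxel"] = wrap(out_vox),
    _["pathlen"] = wrap(out_len), _["launchIndex"] = wrap(out_launch),
    _["nTerminated"] = n_terminated, _["nEscaped"] = n_escaped,
    _["nMissed"] = n_miss);
}

// photon weights under mBLL for a given per-voxel absorption field
// [[Rcpp::export(name = ".mc_weights_cpp")]]
NumericVector mc_weights_cpp(NumericVector ptr, IntegerVector voxel,
                             NumericVector pathlen, NumericVector mua) {
  R_xlen_t P = ptr.size() - 1;
  NumericVector w(P);
  for (R_xlen_t p = 0; p < P; ++p) {
    double s = 0.0;
    for (R_xlen_t q = (R_xlen_t)ptr[p]; q < (R_xlen_t)ptr[p + 1]; ++q)
      s += mua[voxel[q] - 1] * pathlen[q];
    w[p] = std::exp(-s);
  }
  return w;
}

// exact FD replay derivatives: X, Y per detector and dX/dmua, dY/dmua per
// (voxel, detector); all normalized per launched photon
// [[Rcpp::export(name = ".mc_replay_cpp")]]
List mc_replay_cpp(NumericVector ptr, IntegerVector voxel,
                   NumericVector pathlen, IntegerVector detector,
                   NumericVector tof, NumericVector mua, double f, int ndet,
                   double n_launched) {
  R_xlen_t P = ptr.size() - 1;
  R_xlen_t nvox = mua.size();
  NumericVector X(ndet), Y(ndet);
  NumericMatrix dX(nvox, ndet), dY(nvox, ndet);
  double twopif = 2.0 * M_PI * f;
  for (R_xlen_t p = 0; p < P; ++p) {
    double s = 0.0;
    R_xlen_t q0 = (R_xlen_t)ptr[p], q1 = (R_xlen_t)ptr[p + 1];
    for (R_xlen_t q = q0; q < q1; ++q)
      s += mua[voxel[q] - 1] * pathlen[q];
    double w = std::exp(-s);
    double c = std::cos(twopif * tof[p]), sn = std::sin(twopif * tof[p]);
    int d = detector[p] - 1;
    X[d] += w * c;
    Y[d] += w * sn;
    double wc = w * c, ws = w * sn;
    for (R_xlen_t q = q0; q < q1; ++q) {
      dX(voxel[q] - 1, d) -= pathlen[q] * wc;
      dY(voxel[q] - 1, d) -= pathlen[q] * ws;
    }
  }
  for (int d = 0; d < ndet; ++d) { X[d] /= n_launched; Y[d] /= n_launched; }
  for (R_xlen_t j = 0; j < nvox; ++j)
    for (int d = 0; d < ndet; ++d) { dX(j, d) /= n_launched; dY(j, d) /= n_launched; }
  return List::create(_["X"] = X, _["Y"] = Y, _["dX"] = dX, _["dY"] = dY);
}

// central difference-quotient sums: for every voxel j and detector d the
// re-weighted sums X(mua_j +/- delta), Y(mua_j +/- delta); reweighting only,
// no re-transport (mBLL)
// [[Rcpp::export(name = ".mc_diffq_cpp")]]
List mc_diffq_cpp(NumericVector ptr, IntegerVector voxel,
                  NumericVector pathlen, IntegerVector detector,
                  NumericVector tof, NumericVector mua, double f, int ndet,
                  double n_launched, double delta) {
  R_xlen_t P = ptr.size() - 1;
  R_xlen_t nvox = mua.size();
  NumericVector X(ndet), Y(ndet);
  NumericMatrix Xp(nvox, ndet), Xm(nvox, ndet), Yp(nvox, ndet), Ym(nvox, ndet);
  double twopif = 2.0 * M_PI * f;
  for (R_xlen_t p = 0; p < P; ++p) {
    double s = 0.0;
    R_xlen_t q0 = (R_xlen_t)ptr[p], q1 = (R_xlen_t)ptr[p + 1];
    for (R_xlen_t q = q0; q < q1; ++q)
      s += mua[voxel[q] - 1] * pathlen[q];
    double w = std::exp(-s);
    double c = std::cos(twopif * tof[p]), sn = std::sin(twopif * tof[p]);
    int d = detector[p] - 1;
    X[d] += w * c;
    Y[d] += w * sn;
    for (R_xlen_t q = q0; q < q1; ++q) {
      R_xlen_t j = voxel[q] - 1;
      double ep = std::exp(-delta * pathlen[q]) - 1.0; // +delta perturbation
      double em = std::exp(delta * pathlen[q]) - 1.0;  // -delta perturbation
      Xp(j, d) += w * c * ep;
      Xm(j, d) += w * c * em;
      Yp(j, d) += w * sn * ep;
      Ym(j, d) += w * sn * em;
    }
  }
  // convert corrections into full perturbed sums, normalized
  for (R_xlen_t j = 0; j < nvox; ++j)
    for (int d = 0; d < ndet; ++d) {
      Xp(j, d) = (X[d] + Xp(j, d)) / n_launched;
      Xm(j, d) = (X[d] + Xm(j, d)) / n_launched;
      Yp(j, d) = (Y[d] + Yp(j, d)) / n_launched;
      Ym(j, d) = (Y[d] + Ym(j, d)) / n_launched;
    }
  for (int d = 0; d < ndet; ++d) { X[d] /= n_launched; Y[d] /= n_launched; }
  return List::create(_["X"] = X, _["Y"] = Y, _["Xp"] = Xp, _["Xm"] = Xm,
                      _["Yp"] = Yp, _["Ym"] = Ym);
}

// brute-force nearest-neighbour indices (small point sets)
// [[Rcpp::export(name = ".nn_index_cpp")]]
IntegerVector nn_index_cpp(NumericMatrix query, NumericMatrix ref) {
  int nq = query.nrow(), nr = ref.nrow();
  IntegerVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    int bj = 0;
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    for (int j = 0; j < nr; ++j) {
      double dx = qx - ref(j, 0), dy = qy - ref(j, 1), dz = qz - ref(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    out[i] = bj + 1;
  }
  return out;
}
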