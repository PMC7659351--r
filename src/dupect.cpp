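// Compiled kernels: exact rasterization of hyperbolic response curves onto
// the image grid, and the stochastic origin ensemble Metropolis chain.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// n * log(n) with the 0^0 == 1 convention (0 * log 0 == 0); tabulated for
// the integer event counts the chain actually sees.
static const int XLOGX_N = 1 << 16;
static inline double xlogx(double n) {
  static std::vector<double> tab = [] {
    std::vector<double> t(XLOGX_N);
    t[0] = 0.0;
    for (int i = 1; i < XLOGX_N; ++i) t[i] = i * std::log((double)i);
    return t;
  }();
  if (n >= 0 && n < XLOGX_N && n == std::floor(n)) return tab[(int)n];
  return n > 0 ? n * std::log(n) : 0.0;
}

// Amanatides-Woo traversal of the segment p0 -> p1 over the grid; records
// every in-FOV cell crossed, first-visit order preserved via `visited`.
static void traverse_segment(double x0w, double y0w, double x1w, double y1w,
                             int nx, int ny, double ps, double gx0, double gy0,
                             const std::vector<uint8_t>& mask,
                             std::vector<uint8_t>& visited,
                             std::vector<int>& touched,
                             std::vector<int>& out) {
  double dx = x1w - x0w, dy = y1w - y0w;
  double len = std::sqrt(dx * dx + dy * dy);
  if (len < 1e-12) len = 1e-12;
  double inv_dx = dx / len, inv_dy = dy / len;

  int ix = (int)std::floor((x0w - gx0) / ps);
  int iy = (int)std::floor((y0w - gy0) / ps);
  int ix1 = (int)std::floor((x1w - gx0) / ps);
  int iy1 = (int)std::floor((y1w - gy0) / ps);

  int step_x = (inv_dx > 0) ? 1 : -1;
  int step_y = (inv_dy > 0) ? 1 : -1;

  double tmax_x, tmax_y, tdelta_x, tdelta_y;
  if (std::fabs(inv_dx) > 1e-15) {
    double next_x = gx0 + (ix + (step_x > 0 ? 1 : 0)) * ps;
    tmax_x = (next_x - x0w) / inv_dx;
    tdelta_x = ps / std::fabs(inv_dx);
  } else {
    tmax_x = R_PosInf; tdelta_x = R_PosInf;
  }
  if (std::fabs(inv_dy) > 1e-15) {
    double next_y = gy0 + (iy + (step_y > 0 ? 1 : 0)) * ps;
    tmax_y = (next_y - y0w) / inv_dy;
    tdelta_y = ps / std::fabs(inv_dy);
  } else {
    tmax_y = R_PosInf; tdelta_y = R_PosInf;
  }

  int guard = 4 * (nx + ny) + 8;
  while (guard-- > 0) {
    if (ix >= 0 && ix < nx && iy >= 0 && iy < ny) {
      int v = ix + iy * nx;
      if (mask[v] && !visited[v]) {
        visited[v] = 1;
        touched.push_back(v);
        out.push_back(v);
      }
    }
    if (ix == ix1 && iy == iy1) break;
    if (tmax_x < tmax_y) {
      if (tmax_x > len) break;
      ix += step_x; tmax_x += tdelta_x;
    } else {
      if (tmax_y > len) break;
      iy += step_y; tmax_y += tdelta_y;
    }
  }
}

// March one branch direction (sign = +1/-1 in t) from the vertex outward
// until the canonical point leaves the stopping disk.
static void march_direction(double cx, double cy, double ux, double uy,
                            double a, double b, double step, double r_stop,
                            int sign, int nx, int ny, double ps,
                            double gx0, double gy0,
                            const std::vector<uint8_t>& mask,
                            std::vector<uint8_t>& visited,
                            std::vector<int>& touched,
                            std::vector<int>& out) {
  double vx = -uy, vy = ux;   // unit vector perpendicular to the focal axis
  double t = 0.0;
  double px = cx + ux * a, py = cy + uy * a;  // vertex
  double r2_stop = r_stop * r_stop;
  int guard = 100000;
  while (guard-- > 0) {
    double ds_dt = std::sqrt(a * a * std::sinh(t) * std::sinh(t) +
                             b * b * std::cosh(t) * std::cosh(t));
    double dt = step / std::max(ds_dt, 1e-12);
    if (dt > 5.0) dt = 5.0;
    double tn, qx, qy;
    for (int halve = 0; halve < 64; ++halve) {
      tn = t + sign * dt;
      double chv = std::cosh(tn), shv = std::sinh(tn);
      qx = cx + ux * a * chv + vx * b * shv;
      qy = cy + uy * a * chv + vy * b * shv;
      double seg2 = (qx - px) * (qx - px) + (qy - py) * (qy - py);
      if (seg2 <= 2.25 * step * step) break;
      dt *= 0.5;
    }
    traverse_segment(px, py, qx, qy, nx, ny, ps, gx0, gy0,
                     mask, visited, touched, out);
    px = qx; py = qy; t = tn;
    if (px * px + py * py > r2_stop) break;
  }
}

// [[Rcpp::export]]
List cpp_enumerate_candidates(NumericVector cx, NumericVector cy,
                              NumericVector ux, NumericVector uy,
                              NumericVector a, NumericVector b,
                              int nx, int ny, double ps,
                              double gx0, double gy0,
                              double mask_cx, double mask_cy,
                              double fov_radius, double step) {
  int n = cx.size();
  std::vector<uint8_t> mask(nx * ny);
  double r2 = fov_radius * fov_radius + 1e-9;
  for (int iy = 0; iy < ny; ++iy) {
    double yc = gy0 + (iy + 0.5) * ps - mask_cy;
    for (int ix = 0; ix < nx; ++ix) {
      double xc = gx0 + (ix + 0.5) * ps - mask_cx;
      mask[ix + iy * nx] = (xc * xc + yc * yc <= r2);
    }
  }

  std::vector<uint8_t> visited(nx * ny, 0);
  std::vector<int> touched;
  std::vector<int> voxels;
  IntegerVector offsets(n + 1);
  voxels.reserve((size_t)n * 32);

  for (int k = 0; k < n; ++k) {
    touched.clear();
    std::vector<int> out;
    // coincident foci (same transaxial column after rebinning): the curve
    // is undefined in 2D; empty candidate set, event dropped upstream
    if (!std::isfinite(ux[k]) || !std::isfinite(uy[k]) ||
        !std::isfinite(a[k]) || !std::isfinite(b[k])) {
      offsets[k + 1] = (int)voxels.size();
      continue;
    }
    // Stopping disk: must contain both foci (they sit on the detector
    // ring) so that the connected in-disk arc of the branch covers the
    // whole in-FOV portion. |focus| <= |center| + sqrt(a^2+b^2), which is
    // bounded by |center| + a + b.
    double r_stop = std::max(std::sqrt(cx[k] * cx[k] + cy[k] * cy[k]) +
                                 a[k] + b[k] + 2 * ps,
                             1.2 * fov_radius);

    if (a[k] < 1e-9) {
      // TDOA == 0: perpendicular bisector chord through the center
      double vx = -uy[k], vy = ux[k];
      double half = r_stop + 2 * ps;
      traverse_segment(cx[k], cy[k], cx[k] + vx * half, cy[k] + vy * half,
                       nx, ny, ps, gx0, gy0, mask, visited, touched, out);
      // restart from center for deterministic ordering of the other half
      traverse_segment(cx[k], cy[k], cx[k] - vx * half, cy[k] - vy * half,
                       nx, ny, ps, gx0, gy0, mask, visited, touched, out);
    } else {
      march_direction(cx[k], cy[k], ux[k], uy[k], a[k], b[k], step, r_stop,
                      +1, nx, ny, ps, gx0, gy0, mask, visited, touched, out);
      march_direction(cx[k], cy[k], ux[k], uy[k], a[k], b[k], step, r_stop,
                      -1, nx, ny, ps, gx0, gy0, mask, visited, touched, out);
    }
    for (size_t i = 0; i < touched.size(); ++i) visited[touched[i]] = 0;
    voxels.insert(voxels.end(), out.begin(), out.end());
    offsets[k + 1] = (int)voxels.size();
  }
  return List::create(_["voxels"] = IntegerVector(voxels.begin(), voxels.end()),
                      _["offsets"] = offsets);
}

// Metropolis acceptance (log space) for moving one event from a voxel with
// count ci (including the event itself) to a voxel with count cj.
static inline bool accept_move(double ci, double cj) {
  double logA = xlogx(ci) + xlogx(cj + 1) - xlogx(ci + 1) - xlogx(cj);
  if (logA >= 0) return true;
  return std::log(unif_rand()) < logA;
}

// [[Rcpp::export]]
List cpp_soe_steps(IntegerVector voxels, IntegerVector offsets,
                   IntegerVector assign, IntegerVector density,
                   int n_steps) {
  IntegerVector as = clone(assign);
  IntegerVector dens = clone(density);
  int n_events = offsets.size() - 1;
  long accepted = 0;
  for (int s = 0; s < n_steps; ++s) {
    int k = (int)(unif_rand() * n_events);
    if (k >= n_events) k = n_events - 1;
    int len = offsets[k + 1] - offsets[k];
    int j = voxels[offsets[k] + (int)(unif_rand() * len) % len];
    int i = as[k];
    if (i == j) { ++accepted; continue; }
    if (dens[i] < 1) stop("state corruption: event occupies an empty voxel");
    if (accept_move((double)dens[i], (double)dens[j])) {
      --dens[i]; ++dens[j];
      as[k] = j;
      ++accepted;
    }
  }
  return List::create(_["assign"] = as, _["density"] = dens,
                      _["n_accepted"] = (double)accepted);
}

// [[Rcpp::export]]
List cpp_soe_chain(IntegerVector voxels, IntegerVector offsets, int n_vox,
                   int n_sweeps, int n_average, bool record_trace,
                   Nullable<IntegerVector> init_assign = R_NilValue) {
  int n_events = offsets.size() - 1;
  std::vector<int> as(n_events);
  std::vector<int> dens(n_vox, 0);

  if (init_assign.isNotNull()) {
    IntegerVector ia(init_assign);
    for (int k = 0; k < n_events; ++k) { as[k] = ia[k]; ++dens[as[k]]; }
  } else {
    for (int k = 0; k < n_events; ++k) {
      int len = offsets[k + 1] - offsets[k];
      as[k] = voxels[offsets[k] + (int)(unif_rand() * len) % len];
      ++dens[as[k]];
    }
  }

  std::vector<double> avg(n_vox, 0.0);
  NumericVector accept_rate(n_sweeps);
  NumericMatrix trace(record_trace ? n_sweeps : 0,
                      record_trace ? n_vox : 0);
  int burn = n_sweeps - n_average;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    long accepted = 0;
    for (int s = 0; s < n_events; ++s) {
      int k = (int)(unif_rand() * n_events);
      if (k >= n_events) k = n_events - 1;
      int len = offsets[k + 1] - offsets[k];
      int j = voxels[offsets[k] + (int)(unif_rand() * len) % len];
      int i = as[k];
      if (i == j) { ++accepted; continue; }
      if (accept_move((double)dens[i], (double)dens[j])) {
        --dens[i]; ++dens[j];
        as[k] = j;
        ++accepted;
      }
    }
    accept_rate[sweep] = n_events > 0 ? (double)accepted / n_events : 0.0;
    if (sweep >= burn)
      for (int v = 0; v < n_vox; ++v) avg[v] += dens[v];
    if (record_trace)
      for (int v = 0; v < n_vox; ++v) trace(sweep, v) = dens[v];
    if (sweep % 64 == 0) Rcpp::checkUserInterrupt();
  }
  for (int v = 0; v < n_vox; ++v) avg[v] /= std::max(1, n_average);

  return List::create(_["oe_average"] = NumericVector(avg.begin(), avg.end()),
                      _["accept_rate"] = accept_rate,
                      _["assign"] = IntegerVector(as.begin(), as.end()),
                      _["density"] = IntegerVector(dens.begin(), dens.end()),
                      _["trace"] = trace);
}

// Fused per-chunk simulation kernel: cascade channel selection, isotropic
// emission, ray-cylinder transport, crystal binning, efficiency, energy and
// timing blur. Returns detected singles sorted by blurred timestamp.
// Statistically identical to the staged R operations (cross-checked in the
// test suite); uses R's RNG stream.
// [[Rcpp::export]]
List cpp_sim_chunk(NumericVector x, NumericVector y, NumericVector z,
                   NumericVector t, NumericVector e1, NumericVector e2,
                   NumericVector hl_ps, NumericVector cum_prob,
                   double ring_radius, double efficiency,
                   int n_trans, int n_rings, double pitch_ax,
                   NumericVector r511, double ctr_ps) {
  int n = x.size();
  int n_ch = cum_prob.size();
  double z0 = -n_rings / 2.0 * pitch_ax;
  double fwhm2sd = 1.0 / (2.0 * std::sqrt(2.0 * std::log(2.0)));
  double sd_t = ctr_ps > 0 ? ctr_ps / 1000.0 * fwhm2sd / std::sqrt(2.0) : 0.0;
  double c_mm_ns = 299.792458;
  double two_pi = 2.0 * M_PI;

  std::vector<int> v_decay, v_cid, v_ring;
  std::vector<double> v_x, v_y, v_etrue, v_ttrue, v_e, v_tns;
  size_t cap = (size_t)(n * 0.5) + 64;
  v_decay.reserve(cap); v_cid.reserve(cap); v_ring.reserve(cap);
  v_x.reserve(cap); v_y.reserve(cap); v_etrue.reserve(cap);
  v_ttrue.reserve(cap); v_e.reserve(cap); v_tns.reserve(cap);
  long n_photons = 0;

  for (int i = 0; i < n; ++i) {
    double u = unif_rand();
    int ch = -1;
    for (int c = 0; c < n_ch; ++c) {
      if (u < cum_prob[c]) { ch = c; break; }
    }
    if (ch < 0) continue;
    n_photons += 2;
    double delay_ns = hl_ps[ch] > 0
      ? exp_rand() * hl_ps[ch] / std::log(2.0) / 1000.0 : 0.0;
    for (int ph = 0; ph < 2; ++ph) {
      double cz = unif_rand() * 2.0 - 1.0;
      double phi = unif_rand() * two_pi;
      double s2 = 1.0 - cz * cz;
      if (s2 <= 0) continue;
      double sxy = std::sqrt(s2);
      double ux = sxy * std::cos(phi), uy = sxy * std::sin(phi);
      double b = x[i] * ux + y[i] * uy;
      double cc = x[i] * x[i] + y[i] * y[i] - ring_radius * ring_radius;
      double upar = (-b + std::sqrt(b * b - s2 * cc)) / s2;
      double z_hit = z[i] + upar * cz;
      int ring = (int)std::floor((z_hit - z0) / pitch_ax);
      if (ring < 0 || ring >= n_rings) continue;
      if (unif_rand() >= efficiency) continue;
      double ang = std::atan2(y[i] + upar * uy, x[i] + upar * ux);
      if (ang < 0) ang += two_pi;
      int ti = (int)std::lround(ang / two_pi * n_trans) % n_trans;
      int cid = ring * n_trans + ti;
      double E = ph == 0 ? e1[ch] : e2[ch];
      double sd_e = r511[cid] * std::sqrt(511.0 / E) * E * fwhm2sd;
      double e = E + norm_rand() * sd_e;
      while (e <= 0) e = E + norm_rand() * sd_e;
      double cang = two_pi * ti / n_trans;
      double t_true = t[i] + (ph == 1 ? delay_ns : 0.0) + upar / c_mm_ns;
      v_decay.push_back(i + 1);
      v_cid.push_back(cid);
      v_ring.push_back(ring);
      v_x.push_back(ring_radius * std::cos(cang));
      v_y.push_back(ring_radius * std::sin(cang));
      v_etrue.push_back(E);
      v_ttrue.push_back(t_true);
      v_e.push_back(e);
      v_tns.push_back(sd_t > 0 ? t_true + norm_rand() * sd_t : t_true);
    }
  }

  int m = (int)v_decay.size();
  std::vector<int> idx(m);
  for (int i = 0; i < m; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return v_tns[a] < v_tns[b]; });
  IntegerVector decay(m), cid(m), ring(m);
  NumericVector ox(m), oy(m), oet(m), ott(m), oe(m), otn(m);
  for (int i = 0; i < m; ++i) {
    int j = idx[i];
    decay[i] = v_decay[j]; cid[i] = v_cid[j]; ring[i] = v_ring[j];
    ox[i] = v_x[j]; oy[i] = v_y[j]; oet[i] = v_etrue[j];
    ott[i] = v_ttrue[j]; oe[i] = v_e[j]; otn[i] = v_tns[j];
  }
  return List::create(_["decay_id"] = decay, _["crystal_id"] = cid,
                      _["ring_index"] = ring, _["x"] = ox, _["y"] = oy,
                      _["energy_true"] = oet, _["t_true"] = ott,
                      _["energy_keV"] = oe, _["t_ns"] = otn,
                      _["n_photons"] = (double)n_photons);
}

// Rejection sampler for piecewise-constant activity phantoms: candidates
// uniform in the bounding cylinder, accepted in proportion to the local
// activity; later primitives override earlier ones.
// [[Rcpp::export]]
List cpp_sample_phantom(int n, NumericVector px, NumericVector py,
                        NumericVector r2, NumericVector halfz,
                        NumericVector act, double bound_r, double half_z,
                        double act_max) {
  int n_prim = px.size();
  NumericVector ox(n), oy(n), oz(n);
  int got = 0;
  long guard = 200L * (long)n + 100000L;
  while (got < n && guard-- > 0) {
    double r = bound_r * std::sqrt(unif_rand());
    double th = unif_rand() * 2.0 * M_PI;
    double x = r * std::cos(th), y = r * std::sin(th);
    double z = half_z > 0 ? (unif_rand() * 2.0 - 1.0) * half_z : 0.0;
    double a = 0.0;
    for (int i = n_prim - 1; i >= 0; --i) {
      double dx = x - px[i], dy = y - py[i];
      if (dx * dx + dy * dy <= r2[i] && std::fabs(z) <= halfz[i]) {
        a = act[i];
        break;
      }
    }
    if (a <= 0) continue;
    if (unif_rand() * act_max < a) {
      ox[got] = x; oy[got] = y; oz[got] = z;
      ++got;
    }
  }
  if (got < n) stop("phantom sampling failed to converge");
  return List::create(_["x"] = ox, _["y"] = oy, _["z"] = oz);
}
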