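// Overdamped Langevin propagator for particles diffusing across a
// slab-embedded cylindrical channel, with per-species channel affinity,
// optional single-file blocking, and an on-the-fly ground-truth crossing
// log that applies the same region rules as the R-level event detector
// at every integration step.
//
// Reduced units: kT = 1, lengths nm, times ns.  Uses R's RNG so runs are
// reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double pwrap(double x, double box) {
  return x - box * std::floor(x / box + 0.5);  // into [-box/2, box/2)
}

// cosine ramp: 1 deep inside, 0 outside, smooth in between
static inline double ramp_weight(double s, double edge, double width,
                                 double* dw) {
  // s >= 0 distance-like coordinate; weight 1 for s <= edge - width,
  // 0 for s >= edge
  if (s <= edge - width) { *dw = 0.0; return 1.0; }
  if (s >= edge)         { *dw = 0.0; return 0.0; }
  double u = (s - (edge - width)) / width;
  *dw = -0.5 * M_PI / width * std::sin(M_PI * u);
  return 0.5 * (1.0 + std::cos(M_PI * u));
}

// region codes matching the R detector: 1 below, 2 inside, 3 above,
// 4 outside-lateral
static inline int region(double x, double y, double z, double radius,
                         double zlo, double zhi) {
  double r = std::sqrt(x * x + y * y);
  if (r > radius) return 4;
  if (z < zlo) return 1;
  if (z > zhi) return 3;
  return 2;
}

// [[Rcpp::export]]
List bd_core(NumericMatrix x0, NumericVector D, NumericVector U,
             LogicalVector blocker, bool blocking,
             double box, double slab_half, double chan_radius,
             double ramp_z, double ramp_r, double barrier, double c6_amp,
             double dt, int n_steps, int stride,
             double det_radius, double det_zlo, double det_zhi) {
  const int n = x0.nrow();
  const int n_frames = n_steps / stride + 1;
  NumericVector coords(static_cast<R_xlen_t>(n_frames) * n * 3);
  std::vector<double> px(n), py(n), pz(n);
  std::vector<int> armed(n, 0), prev(n, 0), entry_step(n, 0);
  std::vector<long> chan_steps(n, 0);
  std::vector<int> cross_step, cross_particle, cross_dir;
  int occ = 0;  // blockers currently in the channel

  for (int i = 0; i < n; ++i) {
    px[i] = x0(i, 0); py[i] = x0(i, 1); pz[i] = x0(i, 2);
    prev[i] = region(px[i], py[i], pz[i], det_radius, det_zlo, det_zhi);
    if (blocking && blocker[i] &&
        std::sqrt(px[i] * px[i] + py[i] * py[i]) < chan_radius &&
        std::fabs(pz[i]) < slab_half)
      ++occ;
  }
  // frame 0
  for (int i = 0; i < n; ++i) {
    coords[0 + n_frames * (R_xlen_t)i + (R_xlen_t)n_frames * n * 0] = px[i];
    coords[0 + n_frames * (R_xlen_t)i + (R_xlen_t)n_frames * n * 1] = py[i];
    coords[0 + n_frames * (R_xlen_t)i + (R_xlen_t)n_frames * n * 2] = pz[i];
  }

  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      double x = px[i], y = py[i], z = pz[i];
      double r = std::sqrt(x * x + y * y);
      // potential E = wz(|z|) * ((1-c(r))*B + c(r)*U_i*(1 + a*cos 6 theta))
      double dwz, dc;
      double wz = ramp_weight(std::fabs(z), slab_half, ramp_z, &dwz);
      double cr = ramp_weight(r, chan_radius, ramp_r, &dc);
      double fx = 0.0, fy = 0.0, fz = 0.0;
      if (wz > 0.0 || dwz != 0.0) {
        double ui = U[i], dE_dtheta = 0.0;
        if (c6_amp != 0.0 && ui != 0.0 && r > 1e-12) {
          double th = std::atan2(y, x);
          dE_dtheta = wz * cr * ui * c6_amp * (-6.0 * std::sin(6.0 * th));
          ui *= (1.0 + c6_amp * std::cos(6.0 * th));
        }
        double well = (1.0 - cr) * barrier + cr * ui;
        double dE_dz = dwz * ((z >= 0.0) ? 1.0 : -1.0) * well;
        double dE_dr = wz * dc * (ui - barrier);
        fz = -dE_dz;
        if (r > 1e-12) {
          fx = -dE_dr * x / r - dE_dtheta * (-y / (r * r));
          fy = -dE_dr * y / r - dE_dtheta * (x / (r * r));
        }
      }
      double s = std::sqrt(2.0 * D[i] * dt);
      double nx = pwrap(x + D[i] * dt * fx + s * norm_rand(), box);
      double ny = pwrap(y + D[i] * dt * fy + s * norm_rand(), box);
      double nz = pwrap(z + D[i] * dt * fz + s * norm_rand(), box);

      if (blocking) {
        bool was_in = (r < chan_radius) && (std::fabs(z) < slab_half);
        double nr = std::sqrt(nx * nx + ny * ny);
        bool now_in = (nr < chan_radius) && (std::fabs(nz) < slab_half);
        if (now_in && !was_in && occ >= 1) {
          // channel occupied by a blocker: entry rejected for everyone
          // (a second blocker or any tracer)
          nx = x; ny = y; nz = z; now_in = was_in;
        }
        if (blocker[i]) {
          if (now_in && !was_in) ++occ;
          else if (!now_in && was_in) --occ;
        }
      }
      px[i] = nx; py[i] = ny; pz[i] = nz;
      if (std::sqrt(nx * nx + ny * ny) < chan_radius &&
          std::fabs(nz) < slab_half)
        ++chan_steps[i];

      // ground-truth crossing FSM (mirrors the analysis detector)
      int cur = region(nx, ny, nz, det_radius, det_zlo, det_zhi);
      int pv = prev[i];
      if (cur != pv) {
        if (pv == 2) {
          if (armed[i] == -1 && cur == 3) {
            cross_step.push_back(step); cross_particle.push_back(i + 1);
            cross_dir.push_back(+1);
          } else if (armed[i] == +1 && cur == 1) {
            cross_step.push_back(step); cross_particle.push_back(i + 1);
            cross_dir.push_back(-1);
          }
          armed[i] = 0;
        } else if (cur == 2) {
          if (pv == 1) { armed[i] = -1; entry_step[i] = step; }
          else if (pv == 3) { armed[i] = +1; entry_step[i] = step; }
          else armed[i] = 0;
        } else {
          // below<->above jump in one dt: vanishingly rare at valid dt;
          // never across the periodic face (|dz| <= box/2 would fail)
          armed[i] = 0;
        }
        prev[i] = cur;
      }
    }
    if (step % stride == 0) {
      int f = step / stride;
      for (int i = 0; i < n; ++i) {
        coords[f + n_frames * (R_xlen_t)i + (R_xlen_t)n_frames * n * 0] = px[i];
        coords[f + n_frames * (R_xlen_t)i + (R_xlen_t)n_frames * n * 1] = py[i];
        coords[f + n_frames * (R_xlen_t)i + (R_xlen_t)n_frames * n * 2] = pz[i];
      }
    }
  }

  coords.attr("dim") = IntegerVector::create(n_frames, n, 3);
  return List::create(
    _["coords"] = coords,
    _["cross_step"] = IntegerVector(cross_step.begin(), cross_step.end()),
    _["cross_particle"] = IntegerVector(cross_particle.begin(), cross_particle.end()),
    _["cross_dir"] = IntegerVector(cross_dir.begin(), cross_dir.end()),
    _["channel_steps"] = NumericVector(chan_steps.begin(), chan_steps.end()),
    _["n_frames"] = n_frames);
}
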