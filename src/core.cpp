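#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Discrete fixel field layout (shared by all routines):
//   dirs: numeric, dim c(3 comp, 3 fixel, nx, ny, nz), unit vectors
//   amps: numeric, dim c(3 fixel, nx, ny, nz), >= 0
//   nfix: integer, dim c(nx, ny, nz), 0..3
// Voxel index convention: 0-based in C++; voxel i has centre
//   origin + i * vox (mm). R passes 1-based masks as flat logical arrays.

struct Field {
  const double *dirs, *amps;
  const int *nfix;
  int nx, ny, nz;
  double vx, vy, vz, ox, oy, oz;

  inline bool voxel_of(const double *p, int *v) const {
    v[0] = (int)std::lround((p[0] - ox) / vx);
    v[1] = (int)std::lround((p[1] - oy) / vy);
    v[2] = (int)std::lround((p[2] - oz) / vz);
    return v[0] >= 0 && v[0] < nx && v[1] >= 0 && v[1] < ny &&
           v[2] >= 0 && v[2] < nz;
  }
  inline long lin(const int *v) const {
    return (long)v[0] + (long)nx * ((long)v[1] + (long)ny * v[2]);
  }
  inline int n_at(long l) const { return nfix[l]; }
  inline double amp_at(long l, int f) const { return amps[f + 3 * l]; }
  inline const double *dir_at(long l, int f) const {
    return dirs + 3 * (f + 3 * l);
  }
};

static inline double dot3(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Draw from a von Mises-Fisher-like lobe of concentration kappa around
// axis d (the discrete stand-in for sampling a direction from a fiber
// orientation distribution lobe).
static void lobe_sample(const double *d, double kappa, double *out) {
  double u = unif_rand();
  double z = 1.0 + std::log(u + (1.0 - u) * std::exp(-2.0 * kappa)) / kappa;
  if (z > 1.0) z = 1.0;
  if (z < -1.0) z = -1.0;
  double phi = 2.0 * M_PI * unif_rand();
  double s = std::sqrt(std::max(0.0, 1.0 - z * z));
  // orthonormal basis (e1, e2, d)
  double e1[3];
  if (std::fabs(d[0]) < 0.9) { e1[0] = 0; e1[1] = -d[2]; e1[2] = d[1]; }
  else { e1[0] = -d[1]; e1[1] = d[0]; e1[2] = 0; }
  double n1 = std::sqrt(dot3(e1, e1));
  for (int k = 0; k < 3; ++k) e1[k] /= n1;
  double e2[3] = { d[1] * e1[2] - d[2] * e1[1],
                   d[2] * e1[0] - d[0] * e1[2],
                   d[0] * e1[1] - d[1] * e1[0] };
  for (int k = 0; k < 3; ++k)
    out[k] = z * d[k] + s * (std::cos(phi) * e1[k] + std::sin(phi) * e2[k]);
}

// One half-track: propagate from p0 with initial heading h0 until termination.
// Appends successive points (excluding p0) to pts. Returns number of steps.
static int half_track(const Field &F, const double *p0, const double *h0,
                      int algorithm, double step, double cos_thr,
                      double cutoff, double max_len, double kappa,
                      std::vector<double> &pts) {
  double p[3] = { p0[0], p0[1], p0[2] };
  double h[3] = { h0[0], h0[1], h0[2] };
  int nstep = 0;
  int max_steps = (int)std::floor(max_len / step + 1e-9);
  while (nstep < max_steps) {
    int v[3];
    if (!F.voxel_of(p, v)) break;
    long l = F.lin(v);
    int nf = F.n_at(l);
    // candidate fixels: amplitude >= cutoff, angle to heading <= threshold
    int cand[3]; double ccos[3], camp[3]; int ncand = 0;
    double sgn[3];
    for (int f = 0; f < nf; ++f) {
      double a = F.amp_at(l, f);
      if (a < cutoff) continue;
      const double *d = F.dir_at(l, f);
      double c = dot3(d, h);
      double s = (c < 0) ? -1.0 : 1.0; // fixels are axial: flip to forward
      c *= s;
      if (c >= cos_thr) {
        cand[ncand] = f; ccos[ncand] = c; camp[ncand] = a; sgn[ncand] = s;
        ++ncand;
      }
    }
    if (ncand == 0) break;
    double nd[3];
    if (algorithm == 0) { // deterministic: most collinear, ties -> lowest index
      int best = 0;
      for (int k = 1; k < ncand; ++k) if (ccos[k] > ccos[best]) best = k;
      const double *d = F.dir_at(l, cand[best]);
      for (int k = 0; k < 3; ++k) nd[k] = sgn[best] * d[k];
    } else {            // probabilistic: amplitude-weighted draw + lobe sample
      double tot = 0; for (int k = 0; k < ncand; ++k) tot += camp[k];
      double u = unif_rand() * tot; int pick = ncand - 1;
      for (int k = 0; k < ncand; ++k) { u -= camp[k]; if (u <= 0) { pick = k; break; } }
      const double *d = F.dir_at(l, cand[pick]);
      double axis[3] = { sgn[pick] * d[0], sgn[pick] * d[1], sgn[pick] * d[2] };
      bool ok = false;
      for (int tries = 0; tries < 50 && !ok; ++tries) {
        lobe_sample(axis, kappa, nd);
        if (dot3(nd, h) >= cos_thr) ok = true; // hard turn constraint
      }
      if (!ok) break;
    }
    double pn[3] = { p[0] + step * nd[0], p[1] + step * nd[1],
                     p[2] + step * nd[2] };
    int vn[3];
    if (!F.voxel_of(pn, vn)) break; // grid exit
    pts.push_back(pn[0]); pts.push_back(pn[1]); pts.push_back(pn[2]);
    for (int k = 0; k < 3; ++k) { p[k] = pn[k]; h[k] = nd[k]; }
    ++nstep;
  }
  return nstep;
}

// Bidirectional propagation from one seed. Returns R_NilValue on rejection
// (seed outside grid or no supra-cutoff fixel at the seed voxel).
static SEXP track_one(const Field &F, const double *seed, int algorithm,
                      double step, double cos_thr, double cutoff,
                      double max_len, double kappa) {
  int v[3];
  if (!F.voxel_of(seed, v)) return R_NilValue;
  long l = F.lin(v);
  int nf = F.n_at(l);
  double h0[3]; int pick = -1;
  if (algorithm == 0) { // largest-amplitude fixel (ties: lowest index)
    double best = -1.0;
    for (int f = 0; f < nf; ++f) {
      double a = F.amp_at(l, f);
      if (a >= cutoff && a > best) { best = a; pick = f; }
    }
  } else {              // amplitude-weighted draw among supra-cutoff fixels
    double tot = 0;
    for (int f = 0; f < nf; ++f) if (F.amp_at(l, f) >= cutoff) tot += F.amp_at(l, f);
    if (tot > 0) {
      double u = unif_rand() * tot;
      for (int f = 0; f < nf; ++f) {
        if (F.amp_at(l, f) < cutoff) continue;
        u -= F.amp_at(l, f);
        if (u <= 0) { pick = f; break; }
        pick = f;
      }
    }
  }
  if (pick < 0) return R_NilValue;
  const double *d0 = F.dir_at(l, pick);
  for (int k = 0; k < 3; ++k) h0[k] = d0[k];

  std::vector<double> fwd, bwd;
  int nf_steps = half_track(F, seed, h0, algorithm, step, cos_thr, cutoff,
                            max_len, kappa, fwd);
  double rem = max_len - step * nf_steps;
  // The backward half starts against the *realized* first forward step (not
  // the raw initial fixel), so the turn at the seed junction also respects
  // the angle threshold.
  double h0r[3] = { -h0[0], -h0[1], -h0[2] };
  if (nf_steps > 0) {
    for (int k = 0; k < 3; ++k) h0r[k] = (seed[k] - fwd[k]) / step;
  }
  half_track(F, seed, h0r, algorithm, step, cos_thr, cutoff, rem, kappa,
             bwd);

  int nb = (int)bwd.size() / 3, nfp = (int)fwd.size() / 3;
  NumericMatrix out(nb + 1 + nfp, 3);
  for (int i = 0; i < nb; ++i)       // backward half, reversed
    for (int k = 0; k < 3; ++k) out(i, k) = bwd[3 * (nb - 1 - i) + k];
  for (int k = 0; k < 3; ++k) out(nb, k) = seed[k];
  for (int i = 0; i < nfp; ++i)
    for (int k = 0; k < 3; ++k) out(nb + 1 + i, k) = fwd[3 * i + k];
  out.attr("seed_index") = nb + 1; // 1-based
  return out;
}

static Field make_field(NumericVector dirs, NumericVector amps,
                        IntegerVector nfix, IntegerVector dim,
                        NumericVector vox, NumericVector origin) {
  Field F;
  F.dirs = REAL(dirs); F.amps = REAL(amps); F.nfix = INTEGER(nfix);
  F.nx = dim[0]; F.ny = dim[1]; F.nz = dim[2];
  F.vx = vox[0]; F.vy = vox[1]; F.vz = vox[2];
  F.ox = origin[0]; F.oy = origin[1]; F.oz = origin[2];
  return F;
}

// [[Rcpp::export]]
SEXP cpp_track(NumericVector dirs, NumericVector amps, IntegerVector nfix,
               IntegerVector dim, NumericVector vox, NumericVector origin,
               NumericVector seed, int algorithm, double step,
               double angle_deg, double cutoff, double max_len,
               double lobe_kappa) {
  Field F = make_field(dirs, amps, nfix, dim, vox, origin);
  double cos_thr = std::cos(angle_deg * M_PI / 180.0);
  return track_one(F, REAL(seed), algorithm, step, cos_thr, cutoff, max_len,
                   lobe_kappa);
}

static bool hits_mask(const Field &F, NumericMatrix pts, const int *mask) {
  int n = pts.nrow();
  for (int i = 0; i < n; ++i) {
    double p[3] = { pts(i, 0), pts(i, 1), pts(i, 2) };
    int v[3];
    if (F.voxel_of(p, v) && mask[F.lin(v)]) return true;
  }
  return false;
}

// Rejection-sampling tract selection: draw uniform seed points within the
// seed-ROI voxels, keep streamlines that cross every inclusion mask, avoid
// the exclusion mask and satisfy the length window.
// [[Rcpp::export]]
List cpp_seed_select(NumericVector dirs, NumericVector amps, IntegerVector nfix,
                     IntegerVector dim, NumericVector vox, NumericVector origin,
                     IntegerMatrix seed_vox, List include_masks,
                     LogicalVector exclude_mask, int algorithm, double step,
                     double angle_deg, double cutoff, double min_len,
                     double max_len, double cap_len, int n_want,
                     int max_attempts, double lobe_kappa) {
  Field F = make_field(dirs, amps, nfix, dim, vox, origin);
  double cos_thr = std::cos(angle_deg * M_PI / 180.0);
  int nseed = seed_vox.nrow();
  int nincl = include_masks.size();
  std::vector<const int *> incl(nincl);
  for (int j = 0; j < nincl; ++j)
    incl[j] = LOGICAL(as<LogicalVector>(include_masks[j]));
  const int *excl = exclude_mask.size() > 0 ? LOGICAL(exclude_mask) : nullptr;

  List keep(n_want);
  int accepted = 0, attempts = 0;
  while (accepted < n_want && attempts < max_attempts) {
    ++attempts;
    int row = (int)std::floor(unif_rand() * nseed);
    if (row >= nseed) row = nseed - 1;
    double seed[3];
    seed[0] = F.ox + (seed_vox(row, 0) - 1 + unif_rand() - 0.5) * F.vx;
    seed[1] = F.oy + (seed_vox(row, 1) - 1 + unif_rand() - 0.5) * F.vy;
    seed[2] = F.oz + (seed_vox(row, 2) - 1 + unif_rand() - 0.5) * F.vz;
    SEXP s = track_one(F, seed, algorithm, step, cos_thr, cutoff, cap_len,
                       lobe_kappa);
    if (s == R_NilValue) continue;
    NumericMatrix pts(s);
    double len = step * (pts.nrow() - 1);
    if (min_len > 0 && len < min_len) continue;
    if (max_len > 0 && len > max_len) continue;
    bool ok = true;
    for (int j = 0; j < nincl && ok; ++j)
      if (!hits_mask(F, pts, incl[j])) ok = false;
    if (ok && excl && hits_mask(F, pts, excl)) ok = false;
    if (!ok) continue;
    keep[accepted++] = pts;
  }
  if (accepted < n_want) keep = head(keep, accepted);
  return List::create(_["streamlines"] = keep, _["attempts"] = attempts,
                      _["accepted"] = accepted);
}

// Short-tracks seeding over a whole mask; tracks truncated at max_len by the
// propagation length budget, tracks shorter than min_len discarded.
// [[Rcpp::export]]
List cpp_short_tracks(NumericVector dirs, NumericVector amps,
                      IntegerVector nfix, IntegerVector dim, NumericVector vox,
                      NumericVector origin, IntegerMatrix seed_vox,
                      int algorithm, double step, double angle_deg,
                      double cutoff, double min_len, double max_len,
                      int n_want, int max_attempts, double lobe_kappa) {
  Field F = make_field(dirs, amps, nfix, dim, vox, origin);
  double cos_thr = std::cos(angle_deg * M_PI / 180.0);
  int nseed = seed_vox.nrow();
  List keep(n_want);
  int accepted = 0, attempts = 0;
  while (accepted < n_want && attempts < max_attempts) {
    ++attempts;
    int row = (int)std::floor(unif_rand() * nseed);
    if (row >= nseed) row = nseed - 1;
    double seed[3];
    seed[0] = F.ox + (seed_vox(row, 0) - 1 + unif_rand() - 0.5) * F.vx;
    seed[1] = F.oy + (seed_vox(row, 1) - 1 + unif_rand() - 0.5) * F.vy;
    seed[2] = F.oz + (seed_vox(row, 2) - 1 + unif_rand() - 0.5) * F.vz;
    SEXP s = track_one(F, seed, algorithm, step, cos_thr, cutoff, max_len,
                       lobe_kappa);
    if (s == R_NilValue) continue;
    NumericMatrix pts(s);
    double len = step * (pts.nrow() - 1);
    if (len < min_len) continue;
    keep[accepted++] = pts;
  }
  if (accepted < n_want) keep = head(keep, accepted);
  return List::create(_["streamlines"] = keep, _["attempts"] = attempts,
                      _["accepted"] = accepted);
}

// Track-density binning on a grid refined by `factor` per axis.
// Each streamline increments `count` once per visited target voxel (dense
// resampling at <= 1/4 of the target voxel edge so no voxel is skipped) and
// adds its AFD weight to `wsum` under the same uniqueness rule; `rgb`/`nseg`
// accumulate per-sample |unit segment direction| for the DEC contrast.
// [[Rcpp::export]]
List cpp_tdi(List streamlines, NumericVector weights, IntegerVector dim,
             NumericVector vox, NumericVector origin, int factor,
             double res = -1.0) {
  int nx = dim[0] * factor, ny = dim[1] * factor, nz = dim[2] * factor;
  double vx = vox[0] / factor, vy = vox[1] / factor, vz = vox[2] / factor;
  // target voxel 0 centre so that the refined grid tiles the base grid
  double ox = origin[0] - vox[0] / 2.0 + vx / 2.0;
  double oy = origin[1] - vox[1] / 2.0 + vy / 2.0;
  double oz = origin[2] - vox[2] / 2.0 + vz / 2.0;
  long nvox = (long)nx * ny * nz;
  IntegerVector count(nvox, 0);
  NumericVector wsum(nvox, 0.0), rgb(nvox * 3, 0.0);
  IntegerVector nseg(nvox, 0);
  std::vector<int> stamp(nvox, -1);
  if (res <= 0) res = std::min(vx, std::min(vy, vz)) / 4.0;
  int ns = streamlines.size();
  for (int s = 0; s < ns; ++s) {
    NumericMatrix pts = streamlines[s];
    int np = pts.nrow();
    double w = weights.size() > s ? weights[s] : 1.0;
    for (int i = 0; i < std::max(1, np - 1); ++i) {
      double a[3] = { pts(i, 0), pts(i, 1), pts(i, 2) };
      double del[3] = { 0, 0, 0 }, seg[3] = { 0, 0, 0 }, slen = 0;
      int nsub = 1;
      if (np > 1) {
        int j = i + 1;
        for (int k = 0; k < 3; ++k) del[k] = pts(j, k) - a[k];
        slen = std::sqrt(dot3(del, del));
        if (slen > 0) for (int k = 0; k < 3; ++k) seg[k] = del[k] / slen;
        nsub = std::max(1, (int)std::ceil(slen / res));
      }
      int last = (i == np - 2 || np == 1) ? nsub : nsub - 1;
      for (int t = 0; t <= last; ++t) {
        double frac = (nsub > 0) ? (double)t / nsub : 0.0;
        double p[3] = { a[0] + frac * del[0],
                        a[1] + frac * del[1],
                        a[2] + frac * del[2] };
        int v[3];
        v[0] = (int)std::lround((p[0] - ox) / vx);
        v[1] = (int)std::lround((p[1] - oy) / vy);
        v[2] = (int)std::lround((p[2] - oz) / vz);
        if (v[0] < 0 || v[0] >= nx || v[1] < 0 || v[1] >= ny ||
            v[2] < 0 || v[2] >= nz) continue;
        long l = (long)v[0] + (long)nx * ((long)v[1] + (long)ny * v[2]);
        if (stamp[l] != s) {
          stamp[l] = s;
          count[l] += 1;
          wsum[l] += w;
        }
        if (slen > 0) {
          for (int k = 0; k < 3; ++k) rgb[l + nvox * k] += std::fabs(seg[k]);
          nseg[l] += 1;
        }
      }
    }
  }
  count.attr("dim") = IntegerVector::create(nx, ny, nz);
  wsum.attr("dim") = IntegerVector::create(nx, ny, nz);
  nseg.attr("dim") = IntegerVector::create(nx, ny, nz);
  rgb.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return List::create(_["count"] = count, _["wsum"] = wsum, _["rgb"] = rgb,
                      _["nseg"] = nseg,
                      _["vox"] = NumericVector::create(vx, vy, vz),
                      _["origin"] = NumericVector::create(ox, oy, oz));
}

// For every voxel centre within `radius` of the (densely sampled) polyline,
// return its 1-based linear index, the index of the nearest sample point and
// the distance. Used to rasterize tube bundles and ground-truth masks.
// [[Rcpp::export]]
List cpp_polyline_rast(NumericMatrix pts, IntegerVector dim, NumericVector vox,
                       NumericVector origin, double radius) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long nvox = (long)nx * ny * nz;
  std::vector<double> best(nvox, -1.0);
  std::vector<int> which(nvox, -1);
  int np = pts.nrow();
  for (int i = 0; i < np; ++i) {
    double p[3] = { pts(i, 0), pts(i, 1), pts(i, 2) };
    int lo[3], hi[3];
    double v3[3] = { vox[0], vox[1], vox[2] };
    double o3[3] = { origin[0], origin[1], origin[2] };
    int nn[3] = { nx, ny, nz };
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::max(0, (int)std::floor((p[k] - radius - o3[k]) / v3[k]));
      hi[k] = std::min(nn[k] - 1,
                       (int)std::ceil((p[k] + radius - o3[k]) / v3[k]));
    }
    for (int z = lo[2]; z <= hi[2]; ++z)
      for (int y = lo[1]; y <= hi[1]; ++y)
        for (int x = lo[0]; x <= hi[0]; ++x) {
          double c[3] = { o3[0] + x * v3[0], o3[1] + y * v3[1],
                          o3[2] + z * v3[2] };
          double d2 = 0;
          for (int k = 0; k < 3; ++k) d2 += (c[k] - p[k]) * (c[k] - p[k]);
          double d = std::sqrt(d2);
          if (d <= radius) {
            long l = (long)x + (long)nx * ((long)y + (long)ny * z);
            if (best[l] < 0 || d < best[l]) { best[l] = d; which[l] = i; }
          }
        }
  }
  std::vector<int> idx; std::vector<double> dist; std::vector<int> nearest;
  for (long l = 0; l < nvox; ++l)
    if (best[l] >= 0) {
      idx.push_back((int)(l + 1));
      nearest.push_back(which[l] + 1);
      dist.push_back(best[l]);
    }
  return List::create(_["index"] = wrap(idx), _["nearest"] = wrap(nearest),
                      _["dist"] = wrap(dist));
}
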