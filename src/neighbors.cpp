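#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// Dense uniform grid over a 3D point set for fixed-radius neighbour queries.
// Equivalent to the k-d-tree searches used for touch detection, but with
// O(1) cell addressing; results are compared against a brute-force oracle in
// the test suite.
struct Grid {
  double cell, x0, y0, z0;
  int nx, ny, nz;
  std::vector<int> start;   // CSR offsets per cell
  std::vector<int> idx;     // point indices ordered by cell
  const double* px; const double* py; const double* pz;
  int npts;

  void build(const NumericMatrix& pts, double cell_size) {
    npts = pts.nrow();
    cell = cell_size;
    px = &pts(0, 0); py = &pts(0, 1); pz = &pts(0, 2);
    double xmin = R_PosInf, ymin = R_PosInf, zmin = R_PosInf;
    double xmax = R_NegInf, ymax = R_NegInf, zmax = R_NegInf;
    for (int i = 0; i < npts; ++i) {
      xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
      ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
      zmin = std::min(zmin, pz[i]); zmax = std::max(zmax, pz[i]);
    }
    if (npts == 0) { xmin = ymin = zmin = 0; xmax = ymax = zmax = 1; }
    x0 = xmin; y0 = ymin; z0 = zmin;
    nx = std::max(1, (int)std::floor((xmax - xmin) / cell) + 1);
    ny = std::max(1, (int)std::floor((ymax - ymin) / cell) + 1);
    nz = std::max(1, (int)std::floor((zmax - zmin) / cell) + 1);
    std::vector<int> count((size_t)nx * ny * nz + 1, 0);
    std::vector<int> ci(npts);
    for (int i = 0; i < npts; ++i) {
      int cx = (int)((px[i] - x0) / cell), cy = (int)((py[i] - y0) / cell),
          cz = (int)((pz[i] - z0) / cell);
      ci[i] = (cx * ny + cy) * nz + cz;
      count[ci[i] + 1]++;
    }
    for (size_t c = 1; c < count.size(); ++c) count[c] += count[c - 1];
    start = count;
    idx.resize(npts);
    std::vector<int> cursor(start.begin(), start.end() - 1);
    for (int i = 0; i < npts; ++i) idx[cursor[ci[i]]++] = i;
  }

  // visit all points within `r` of (x, y, z); f(i, d2)
  template <class F>
  void query(double x, double y, double z, double r, F f) const {
    if (npts == 0) return;
    double r2 = r * r;
    int cx0 = (int)std::floor((x - r - x0) / cell),
        cx1 = (int)std::floor((x + r - x0) / cell),
        cy0 = (int)std::floor((y - r - y0) / cell),
        cy1 = (int)std::floor((y + r - y0) / cell),
        cz0 = (int)std::floor((z - r - z0) / cell),
        cz1 = (int)std::floor((z + r - z0) / cell);
    cx0 = std::max(cx0, 0); cy0 = std::max(cy0, 0); cz0 = std::max(cz0, 0);
    cx1 = std::min(cx1, nx - 1); cy1 = std::min(cy1, ny - 1);
    cz1 = std::min(cz1, nz - 1);
    for (int cx = cx0; cx <= cx1; ++cx)
      for (int cy = cy0; cy <= cy1; ++cy)
        for (int cz = cz0; cz <= cz1; ++cz) {
          int c = (cx * ny + cy) * nz + cz;
          for (int k = start[c]; k < start[c + 1]; ++k) {
            int i = idx[k];
            double dx = px[i] - x, dy = py[i] - y, dz = pz[i] - z;
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 <= r2) f(i, d2);
          }
        }
  }
};

// Distinct (pre-cell, post-cell) pairs with at least one pre point within
// `radius` of the post position; reports the minimal point distance per pair.
// [[Rcpp::export]]
List cpp_pairs_points_cells(NumericMatrix pre_pts, IntegerVector pre_cell,
                            NumericMatrix post_pos, double radius) {
  Grid grid;
  grid.build(pre_pts, std::max(radius, 1e-9));
  std::vector<int> out_pre, out_post;
  std::vector<double> out_d;
  int npost = post_pos.nrow();
  std::vector<std::pair<int, double> > local;
  for (int j = 0; j < npost; ++j) {
    local.clear();
    grid.query(post_pos(j, 0), post_pos(j, 1), post_pos(j, 2), radius,
               [&](int i, double d2) {
                 local.push_back(std::make_pair(pre_cell[i], d2));
               });
    if (local.empty()) continue;
    std::sort(local.begin(), local.end());
    for (size_t k = 0; k < local.size(); ++k) {
      if (k > 0 && local[k].first == local[k - 1].first) continue;
      double dmin = local[k].second;
      for (size_t m = k + 1; m < local.size() && local[m].first == local[k].first; ++m)
        dmin = std::min(dmin, local[m].second);
      out_pre.push_back(local[k].first);
      out_post.push_back(j + 1);
      out_d.push_back(std::sqrt(dmin));
    }
  }
  return List::create(_["pre"] = wrap(out_pre), _["post"] = wrap(out_post),
                      _["dist_um"] = wrap(out_d));
}

struct Cand { int goc; float d2; float path; };

static void push_cand(std::vector<Cand>& v, int goc, double d2, double path) {
  v.push_back(Cand{goc, (float)d2, (float)path});
}

// Streaming ascending-axon / parallel-fiber touch detection. Ascending-axon
// and parallel-fiber points are generated per granule cell on the fly
// (deterministically from `seed`), queried against the basolateral and
// apical dendrite point clouds, and collapsed to distinct cell pairs.
// phase 1 counts candidate pairs per Golgi cell; phase 2 re-generates the
// identical geometry and emits edges accepted with probabilities p_aa / p_pf
// (counter-based RNG keyed by the pair, so acceptance is order-independent).
// [[Rcpp::export]]
List cpp_aa_pf_connect(NumericMatrix grc_pos,
                       NumericMatrix apical_pts, IntegerVector apical_goc,
                       NumericMatrix baso_pts, IntegerVector baso_goc,
                       List geom, double r_aa, double r_pf,
                       double p_aa, double p_pf,
                       double seed, int phase, int n_goc) {
  double aa_len = as<double>(geom["aa_length_um"]);
  double aa_sp = as<double>(geom["aa_spacing_um"]);
  double pf_half = as<double>(geom["pf_half_length_um"]);
  double pf_sp = as<double>(geom["pf_spacing_um"]);
  double jit = as<double>(geom["jitter_sd_um"]);

  Grid g_api, g_bas;
  g_api.build(apical_pts, std::max(10.0, r_pf));
  g_bas.build(baso_pts, std::max(10.0, r_aa));

  int n_aa = (int)std::floor(aa_len / aa_sp + 1e-9) + 1;  // includes origin
  int n_arm = (int)std::floor(pf_half / pf_sp + 1e-9);

  std::vector<double> aa_counts(n_goc, 0), pf_counts(n_goc, 0);
  std::vector<int> e_grc_aa, e_goc_aa, e_grc_pf, e_goc_pf;
  std::vector<double> e_path_aa, e_path_pf;

  int ngrc = grc_pos.nrow();
  std::vector<Cand> caa, cpf;
  uint64_t acc_seed = splitmix64((uint64_t)seed + 0x5eedULL);

  for (int i = 0; i < ngrc; ++i) {
    Rng rng(splitmix64((uint64_t)seed) ^ (uint64_t)(i + 1));
    double sx = grc_pos(i, 0), sy = grc_pos(i, 1), sz = grc_pos(i, 2);
    caa.clear(); cpf.clear();

    for (int k = 0; k < n_aa; ++k) {   // ascending axon, vertical
      double path = k * aa_sp;
      double x = sx + jit * rng.rnorm(), y = sy + jit * rng.rnorm(),
             z = sz + path + jit * rng.rnorm();
      g_bas.query(x, y, z, r_aa, [&](int p, double d2) {
        push_cand(caa, baso_goc[p], d2, path);
      });
    }
    double bz = sz + aa_len;           // bifurcation point
    for (int arm = -1; arm <= 1; arm += 2) {  // parallel fiber, transverse
      for (int k = 1; k <= n_arm; ++k) {
        double along = k * pf_sp;
        double x = sx + arm * along + jit * rng.rnorm(),
               y = sy + jit * rng.rnorm(), z = bz + jit * rng.rnorm();
        g_api.query(x, y, z, r_pf, [&](int p, double d2) {
          push_cand(cpf, apical_goc[p], d2, aa_len + along);
        });
      }
    }

    for (int kind = 0; kind < 2; ++kind) {
      std::vector<Cand>& v = kind == 0 ? caa : cpf;
      if (v.empty()) continue;
      std::sort(v.begin(), v.end(),
                [](const Cand& a, const Cand& b) {
                  return a.goc < b.goc || (a.goc == b.goc && a.d2 < b.d2);
                });
      for (size_t k = 0; k < v.size(); ++k) {
        if (k > 0 && v[k].goc == v[k - 1].goc) continue;
        int goc = v[k].goc;
        if (phase == 1) {
          (kind == 0 ? aa_counts : pf_counts)[goc - 1] += 1;
        } else {
          double u = hash_runif(acc_seed, (uint64_t)(i + 1), (uint64_t)goc,
                                (uint64_t)kind + 1);
          if (u < (kind == 0 ? p_aa : p_pf)) {
            if (kind == 0) {
              e_grc_aa.push_back(i + 1); e_goc_aa.push_back(goc);
              e_path_aa.push_back(v[k].path);
            } else {
              e_grc_pf.push_back(i + 1); e_goc_pf.push_back(goc);
              e_path_pf.push_back(v[k].path);
            }
          }
        }
      }
    }
  }

  if (phase == 1)
    return List::create(_["aa_counts"] = wrap(aa_counts),
                        _["pf_counts"] = wrap(pf_counts));
  return List::create(
      _["aa"] = List::create(_["pre"] = wrap(e_grc_aa),
                             _["post"] = wrap(e_goc_aa),
                             _["path_um"] = wrap(e_path_aa)),
      _["pf"] = List::create(_["pre"] = wrap(e_grc_pf),
                             _["post"] = wrap(e_goc_pf),
                             _["path_um"] = wrap(e_path_pf)));
}
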