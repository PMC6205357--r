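#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Stochastic 26-connected region growing over a 3D probability field.
//
// prob:  full-grid probability values (column-major 3D array as a vector);
//        voxels with prob <= 0 are outside the territory support.
// dims:  grid dimensions (length 3).
// seed_voxel: 1-based linear index of the starting voxel (prob > 0 required).
// target: number of voxels to grow to.
//
// At each step one frontier voxel is sampled with probability proportional
// to its territory value times (lesioned-neighbour count)^gamma, added to
// the lesion, and its 26-neighbours that lie in the support are pushed
// onto the frontier. gamma > 0 acts as surface tension: concavities fill
// first, producing the spatially coherent lesion shapes of vascular
// infarcts (gamma = 0 recovers rough Eden-like growth). Uses R's RNG
// stream, so results are reproducible under set.seed(). Returns the
// 1-based linear indices of lesioned voxels, in growth order; length <
// target means the support was exhausted (the R wrapper raises the
// error).
// [[Rcpp::export]]
IntegerVector grow_lesion_cpp(NumericVector prob, IntegerVector dims,
                              int seed_voxel, int target, double gamma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (seed_voxel < 1 || seed_voxel > nvox)
    stop("seed voxel out of range");
  if (prob[seed_voxel - 1] <= 0)
    stop("seed voxel outside territory support");

  std::vector<char> in_mask(nvox, 0), in_frontier(nvox, 0);
  std::vector<int> frontier;           // 0-based linear indices
  std::vector<int> ncnt(nvox, 0);      // lesioned-neighbour counts
  std::vector<int> grown;
  grown.reserve(target);

  // neighbour offsets are recomputed per voxel from (x,y,z) to respect edges
  int cur = seed_voxel - 1;
  in_mask[cur] = 1;
  grown.push_back(cur + 1);

  auto visit_neighbours = [&](int idx) {
    int x = idx % nx, y = (idx / nx) % ny, z = idx / (nx * ny);
    for (int dz = -1; dz <= 1; ++dz) {
      int zz = z + dz;
      if (zz < 0 || zz >= nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int yy = y + dy;
        if (yy < 0 || yy >= ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          int j = xx + nx * (yy + ny * zz);
          if (in_mask[j]) continue;
          ncnt[j]++;
          if (!in_frontier[j] && prob[j] > 0) {
            in_frontier[j] = 1;
            frontier.push_back(j);
          }
        }
      }
    }
  };

  visit_neighbours(cur);
  std::vector<double> fw(0);

  while ((int)grown.size() < target && !frontier.empty()) {
    fw.resize(frontier.size());
    double total = 0.0;
    for (size_t i = 0; i < frontier.size(); ++i) {
      int j = frontier[i];
      double w = prob[j];
      if (gamma > 0) w *= std::pow((double)ncnt[j], gamma);
      fw[i] = w;
      total += w;
    }
    double u = unif_rand() * total, acc = 0.0;
    size_t pick = frontier.size() - 1;
    for (size_t i = 0; i < fw.size(); ++i) {
      acc += fw[i];
      if (u <= acc) { pick = i; break; }
    }
    int j = frontier[pick];
    // swap-pop
    frontier[pick] = frontier.back(); frontier.pop_back();
    in_frontier[j] = 0;
    in_mask[j] = 1;
    grown.push_back(j + 1);
    visit_neighbours(j);
  }

  return wrap(grown);
}
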