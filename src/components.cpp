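#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 3D connected-component labelling of a binary mask by breadth-first
// search. Connectivity 6 (faces), 18 (faces + edges) or 26 (+ corners).
// Labels are assigned in ascending order of the first foreground voxel
// encountered in linear array order (first array axis fastest), which
// makes the labelling deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim,
                                   int connectivity) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector labels(n, 0);

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nz = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nz == 0) continue;
        if (connectivity == 6 && nz > 1) continue;
        if (connectivity == 18 && nz > 2) continue;
        offs.push_back({dx, dy, dz});
      }

  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || labels[s] != 0) continue;
    ++next;
    labels[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front();
      q.pop();
      int i1 = (int)(cur % d1);
      int i2 = (int)((cur / d1) % d2);
      int i3 = (int)(cur / ((R_xlen_t)d1 * d2));
      for (size_t k = 0; k < offs.size(); ++k) {
        int j1 = i1 + offs[k][0], j2 = i2 + offs[k][1], j3 = i3 + offs[k][2];
        if (j1 < 0 || j2 < 0 || j3 < 0 || j1 >= d1 || j2 >= d2 || j3 >= d3)
          continue;
        R_xlen_t idx = j1 + (R_xlen_t)j2 * d1 + (R_xlen_t)j3 * d1 * d2;
        if (mask[idx] != 0 && labels[idx] == 0) {
          labels[idx] = next;
          q.push(idx);
        }
      }
    }
  }
  labels.attr("n_components") = next;
  return labels;
}
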