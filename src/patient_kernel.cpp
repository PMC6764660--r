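#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// One synthetic patient inside the tumor bounding box: classify fine
// voxels against the tumor and brain spheres, fit the resection cavity
// radius as the k-th smallest center distance (smallest radius covering
// >= the target fraction of tumor voxels), optionally prune the cavity
// of the avoidance sphere, and return tumor and residue voxel indices
// (1-based, relative to the box).
//
// xs, ys, zs: mm coordinates of the box voxel centers per axis.
// tc, ec: tumor and effect-region centers (mm); cavity_u: uniform draw
// selecting the cavity center among tumor voxels.
// [[Rcpp::export(name = ".patient_kernel")]]
List patient_kernel(NumericVector xs, NumericVector ys, NumericVector zs,
                    NumericVector tc, double rt2, double R2,
                    double cavity_u, double eor, bool avoided,
                    NumericVector ec, double re2) {
  const int nx = xs.size(), ny = ys.size(), nz = zs.size();
  std::vector<int> idxt;
  idxt.reserve((size_t)nx * ny * nz / 2);
  for (int k = 0; k < nz; ++k) {
    const double dz2 = (zs[k] - tc[2]) * (zs[k] - tc[2]);
    const double bz2 = zs[k] * zs[k];
    for (int j = 0; j < ny; ++j) {
      const double dyz2 = dz2 + (ys[j] - tc[1]) * (ys[j] - tc[1]);
      const double byz2 = bz2 + ys[j] * ys[j];
      if (dyz2 > rt2) continue;
      const int base = (k * ny + j) * nx;
      for (int i = 0; i < nx; ++i) {
        const double dx = xs[i] - tc[0];
        if (dyz2 + dx * dx <= rt2 && byz2 + xs[i] * xs[i] <= R2)
          idxt.push_back(base + i + 1);
      }
    }
  }
  const int nT = (int)idxt.size();
  if (nT == 0) stop("tumor contains no voxels");

  int ci = (int)(cavity_u * nT);
  if (ci >= nT) ci = nT - 1;
  const int c0 = idxt[ci] - 1;
  const double ccx = xs[c0 % nx];
  const double ccy = ys[(c0 / nx) % ny];
  const double ccz = zs[c0 / (nx * ny)];

  std::vector<double> dc2(nT);
  for (int m = 0; m < nT; ++m) {
    const int v = idxt[m] - 1;
    const double dx = xs[v % nx] - ccx;
    const double dy = ys[(v / nx) % ny] - ccy;
    const double dz = zs[v / (nx * ny)] - ccz;
    dc2[m] = dx * dx + dy * dy + dz * dz;
  }
  int kth = (int)std::ceil(eor * nT);
  if (kth < 1) kth = 1;
  if (kth > nT) kth = nT;
  std::vector<double> tmp(dc2);
  std::nth_element(tmp.begin(), tmp.begin() + (kth - 1), tmp.end());
  const double rad2 = tmp[kth - 1];

  std::vector<int> idxr;
  idxr.reserve(nT);
  for (int m = 0; m < nT; ++m) {
    bool in_cav = dc2[m] <= rad2;
    if (in_cav && avoided) {
      const int v = idxt[m] - 1;
      const double dx = xs[v % nx] - ec[0];
      const double dy = ys[(v / nx) % ny] - ec[1];
      const double dz = zs[v / (nx * ny)] - ec[2];
      if (dx * dx + dy * dy + dz * dz <= re2) in_cav = false;
    }
    if (!in_cav) idxr.push_back(idxt[m]);
  }
  return List::create(_["idx_t"] = wrap(idxt), _["idx_r"] = wrap(idxr),
                      _["radius2"] = rad2);
}
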