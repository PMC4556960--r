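// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>
using namespace Rcpp;

// Blocked thresholded-correlation sums.
//
// Z: T x n matrix of standardized time series (column mean 0, unit L2 norm),
//    so crossprod(Z) yields Pearson correlations.
// coords: 3 x n voxel-center coordinates in mm.
// Computes, for each voxel i, the sum of r(i, j) over j != i with
// r > r_threshold, split by center-to-center distance into
//   local:   d <= local_radius
//   gap:     local_radius < d <= distant_radius
//   distant: d > distant_radius
// The full n x n correlation matrix is never materialized; the working set
// is one block_size x n slab, so memory is O(block_size * n) regardless of n.
// [[Rcpp::export]]
List fcd_sums_cpp(const arma::mat& Z, const arma::mat& coords,
                  double r_threshold, double local_radius_mm,
                  double distant_radius_mm, int block_size) {
  const int n = Z.n_cols;
  arma::vec total(n, arma::fill::zeros), local(n, arma::fill::zeros),
      gap(n, arma::fill::zeros), distant(n, arma::fill::zeros);
  const double rl2 = local_radius_mm * local_radius_mm;
  const double rd2 = distant_radius_mm * distant_radius_mm;
  // r(i,j) = r(j,i): visit each unordered block pair once and credit both
  // endpoints, halving the matrix products
  for (int sa = 0; sa < n; sa += block_size) {
    const int ea = std::min(sa + block_size, n) - 1;
    for (int sb = sa; sb < n; sb += block_size) {
      const int eb = std::min(sb + block_size, n) - 1;
      const arma::mat R = Z.cols(sa, ea).t() * Z.cols(sb, eb);
      for (int i = sa; i <= ea; ++i) {
        const double* ci = coords.colptr(i);
        const int j0 = (sb == sa) ? std::max(i + 1, sb) : sb;
        double ti = 0.0, li = 0.0, gi = 0.0, di = 0.0;
        for (int j = j0; j <= eb; ++j) {
          const double r = R(i - sa, j - sb);
          if (r > r_threshold) {
            const double* cj = coords.colptr(j);
            const double dx = ci[0] - cj[0], dy = ci[1] - cj[1],
                         dz = ci[2] - cj[2];
            const double d2 = dx * dx + dy * dy + dz * dz;
            ti += r;
            if (d2 <= rl2) {
              li += r; local[j] += r;
            } else if (d2 > rd2) {
              di += r; distant[j] += r;
            } else {
              gi += r; gap[j] += r;
            }
            total[j] += r;
          }
        }
        total[i] += ti; local[i] += li; gap[i] += gi; distant[i] += di;
      }
    }
  }
  return List::create(_["total"] = total, _["local"] = local,
                      _["gap"] = gap, _["distant"] = distant);
}

// Connected-component labeling of a 3D logical array.
// connectivity: 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
// Labels are assigned in order of first-encountered linear index (1-based
// caller side uses R's column-major order), which makes labeling fully
// deterministic.
// [[Rcpp::export]]
IntegerVector label_components_cpp(const LogicalVector& arr,
                                   const IntegerVector& dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector labels(n, 0);
  // neighbor offsets
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if ((connectivity == 6 && m > 1) || (connectivity == 18 && m > 2))
          continue;
        offs.push_back({dx, dy, dz});
      }
  int next_label = 0;
  std::queue<int> q;
  for (int idx = 0; idx < n; ++idx) {
    if (!arr[idx] || labels[idx] != 0) continue;
    labels[idx] = ++next_label;
    q.push(idx);
    while (!q.empty()) {
      const int cur = q.front();
      q.pop();
      const int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
      for (const auto& o : offs) {
        const int x = cx + o[0], y = cy + o[1], z = cz + o[2];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        const int nb = x + nx * (y + ny * z);
        if (arr[nb] && labels[nb] == 0) {
          labels[nb] = next_label;
          q.push(nb);
        }
      }
    }
  }
  return labels;
}
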