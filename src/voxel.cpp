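// Voxel-level primitives for 3D cell segmentation: connected-component
// labelling, grayscale reconstruction by erosion (for h-minima seeding) and
// seeded watershed by priority flooding. All use 6-connectivity and operate
// on R arrays with dim = c(nx, ny, nz), column-major.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static const int DX[6] = {1, -1, 0, 0, 0, 0};
static const int DY[6] = {0, 0, 1, -1, 0, 0};
static const int DZ[6] = {0, 0, 0, 0, 1, -1};

struct Dim3 {
  int nx, ny, nz;
  Dim3(SEXP x) {
    IntegerVector d = Rf_getAttrib(x, R_DimSymbol);
    if (d.size() != 3) stop("expected a 3D array");
    nx = d[0]; ny = d[1]; nz = d[2];
  }
  inline R_xlen_t idx(int i, int j, int k) const {
    return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
  }
  inline bool inside(int i, int j, int k) const {
    return i >= 0 && j >= 0 && k >= 0 && i < nx && j < ny && k < nz;
  }
};

// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask) {
  Dim3 d(mask);
  R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  lab.attr("dim") = mask.attr("dim");
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int k = 0; k < d.nz; ++k)
    for (int j = 0; j < d.ny; ++j)
      for (int i = 0; i < d.nx; ++i) {
        R_xlen_t p = d.idx(i, j, k);
        if (!mask[p] || lab[p]) continue;
        lab[p] = ++next;
        stack.clear();
        stack.push_back(p);
        while (!stack.empty()) {
          R_xlen_t q = stack.back(); stack.pop_back();
          int qi = q % d.nx, qj = (q / d.nx) % d.ny, qk = q / ((R_xlen_t)d.nx * d.ny);
          for (int m = 0; m < 6; ++m) {
            int ii = qi + DX[m], jj = qj + DY[m], kk = qk + DZ[m];
            if (!d.inside(ii, jj, kk)) continue;
            R_xlen_t r = d.idx(ii, jj, kk);
            if (mask[r] && !lab[r]) { lab[r] = next; stack.push_back(r); }
          }
        }
      }
  return lab;
}

// Reconstruction by erosion of `marker` constrained from below by `mask`
// (marker >= mask pointwise). Hybrid raster/anti-raster scans + FIFO queue.
// [[Rcpp::export(name = ".grey_reconstruct_erosion")]]
NumericVector grey_reconstruct_erosion(NumericVector marker, NumericVector mask) {
  Dim3 d(marker);
  R_xlen_t n = marker.size();
  if (mask.size() != n) stop("marker/mask size mismatch");
  NumericVector J = clone(marker);
  // raster scan
  for (int k = 0; k < d.nz; ++k)
    for (int j = 0; j < d.ny; ++j)
      for (int i = 0; i < d.nx; ++i) {
        R_xlen_t p = d.idx(i, j, k);
        double v = J[p];
        if (i > 0) v = std::min(v, J[d.idx(i - 1, j, k)]);
        if (j > 0) v = std::min(v, J[d.idx(i, j - 1, k)]);
        if (k > 0) v = std::min(v, J[d.idx(i, j, k - 1)]);
        J[p] = std::max(v, mask[p]);
      }
  // anti-raster scan, queueing pixels whose neighbours could still shrink
  std::queue<R_xlen_t> fifo;
  for (int k = d.nz - 1; k >= 0; --k)
    for (int j = d.ny - 1; j >= 0; --j)
      for (int i = d.nx - 1; i >= 0; --i) {
        R_xlen_t p = d.idx(i, j, k);
        double v = J[p];
        if (i < d.nx - 1) v = std::min(v, J[d.idx(i + 1, j, k)]);
        if (j < d.ny - 1) v = std::min(v, J[d.idx(i, j + 1, k)]);
        if (k < d.nz - 1) v = std::min(v, J[d.idx(i, j, k + 1)]);
        J[p] = std::max(v, mask[p]);
        for (int m = 0; m < 6; ++m) {
          int ii = i + DX[m], jj = j + DY[m], kk = k + DZ[m];
          if (!d.inside(ii, jj, kk)) continue;
          R_xlen_t q = d.idx(ii, jj, kk);
          if (J[q] > J[p] && J[q] > mask[q]) { fifo.push(p); break; }
        }
      }
  while (!fifo.empty()) {
    R_xlen_t p = fifo.front(); fifo.pop();
    int i = p % d.nx, j = (p / d.nx) % d.ny, k = p / ((R_xlen_t)d.nx * d.ny);
    for (int m = 0; m < 6; ++m) {
      int ii = i + DX[m], jj = j + DY[m], kk = k + DZ[m];
      if (!d.inside(ii, jj, kk)) continue;
      R_xlen_t q = d.idx(ii, jj, kk);
      double cand = std::max(J[p], mask[q]);
      if (J[q] > cand) { J[q] = cand; fifo.push(q); }
    }
  }
  return J;
}

// Regional minima of a 3D image restricted to a mask: plateau-aware.
// Returns labelled minima (0 elsewhere).
// [[Rcpp::export(name = ".regional_minima_3d")]]
IntegerVector regional_minima_3d(NumericVector img, LogicalVector mask) {
  Dim3 d(img);
  R_xlen_t n = img.size();
  IntegerVector lab(n, 0);
  lab.attr("dim") = img.attr("dim");
  std::vector<signed char> state(n, 0); // 0 unvisited, 1 in-plateau, 2 rejected
  int next = 0;
  std::vector<R_xlen_t> comp, stack;
  for (R_xlen_t p0 = 0; p0 < n; ++p0) {
    if (!mask[p0] || state[p0]) continue;
    double v = img[p0];
    comp.clear(); stack.clear();
    stack.push_back(p0); state[p0] = 1;
    bool is_min = true;
    while (!stack.empty()) {
      R_xlen_t q = stack.back(); stack.pop_back();
      comp.push_back(q);
      int i = q % d.nx, j = (q / d.nx) % d.ny, k = q / ((R_xlen_t)d.nx * d.ny);
      for (int m = 0; m < 6; ++m) {
        int ii = i + DX[m], jj = j + DY[m], kk = k + DZ[m];
        if (!d.inside(ii, jj, kk)) continue;
        R_xlen_t r = d.idx(ii, jj, kk);
        if (!mask[r]) continue;
        if (img[r] < v) { is_min = false; continue; }
        if (img[r] == v && !state[r]) { state[r] = 1; stack.push_back(r); }
      }
    }
    if (is_min) {
      ++next;
      for (R_xlen_t q : comp) lab[q] = next;
    } else {
      for (R_xlen_t q : comp) state[q] = 2;
    }
  }
  return lab;
}

struct WsNode {
  double value;
  std::uint64_t order;
  R_xlen_t pos;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.value != b.value) return a.value > b.value; // min-heap on value
    return a.order > b.order;                         // FIFO tie-break
  }
};

// Seeded watershed on `img` (flood from low to high) inside `mask`.
// `seeds` carries positive integer labels; output extends them over the mask.
// [[Rcpp::export(name = ".watershed_seeded_3d")]]
IntegerVector watershed_seeded_3d(NumericVector img, IntegerVector seeds,
                                  LogicalVector mask) {
  Dim3 d(img);
  R_xlen_t n = img.size();
  IntegerVector lab = clone(seeds);
  lab.attr("dim") = img.attr("dim");
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  std::uint64_t counter = 0;
  std::vector<char> queued(n, 0);
  for (R_xlen_t p = 0; p < n; ++p)
    if (lab[p] > 0 && mask[p]) {
      pq.push(WsNode{img[p], counter++, p});
      queued[p] = 1;
    }
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    R_xlen_t p = nd.pos;
    int i = p % d.nx, j = (p / d.nx) % d.ny, k = p / ((R_xlen_t)d.nx * d.ny);
    int lp = lab[p];
    for (int m = 0; m < 6; ++m) {
      int ii = i + DX[m], jj = j + DY[m], kk = k + DZ[m];
      if (!d.inside(ii, jj, kk)) continue;
      R_xlen_t q = d.idx(ii, jj, kk);
      if (!mask[q] || lab[q] > 0 || queued[q]) continue;
      lab[q] = lp;
      pq.push(WsNode{img[q], counter++, q});
      queued[q] = 1;
    }
  }
  return lab;
}
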