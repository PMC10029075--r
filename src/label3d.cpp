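#include <Rcpp.h>
#include <vector>

// 26-connected component labeling of a 3D logical mask by breadth-first
// search. mask: logical vector in R array order (dim = c(nz, ny, nx), first
// index fastest). Returns integer labels (0 = background), contiguous 1..n
// in discovery (raster) order.
// [[Rcpp::export(name = ".label3d_cc")]]
Rcpp::IntegerVector label3d_cc(Rcpp::LogicalVector mask, int nz, int ny, int nx) {
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) Rcpp::stop("mask length does not match dimensions");
  Rcpp::IntegerVector lab(n, 0);
  std::vector<R_xlen_t> queue;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      R_xlen_t v = queue.back();
      queue.pop_back();
      int z = (int)(v % nz);
      int y = (int)((v / nz) % ny);
      int x = (int)(v / ((R_xlen_t)nz * ny));
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx;
        if (xx < 0 || xx >= nx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;
            R_xlen_t w = (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
            if (mask[w] && lab[w] == 0) {
              lab[w] = next;
              queue.push_back(w);
            }
          }
        }
      }
    }
  }
  return lab;
}
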