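#include <Rcpp.h>
using namespace Rcpp;

// 8-connected component labeling of a 0/1 mask, iterative flood fill.
// Labels are assigned in raster (column-major) discovery order, starting at 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int ci = idx % nr, cj = idx / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back(ni + nj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Valid-mode cross-correlation: C(i,j) = sum_{x,y} t(x,y) * p(x+i, y+j),
// evaluated only where the template lies fully inside the image.
// Output size (nrp - nrt + 1) x (ncp - nct + 1).
// [[Rcpp::export]]
NumericMatrix cpp_cross_correlation(const NumericMatrix& p,
                                    const NumericMatrix& t) {
  const int nrp = p.nrow(), ncp = p.ncol();
  const int nrt = t.nrow(), nct = t.ncol();
  if (nrt > nrp || nct > ncp)
    stop("template dimensions exceed image dimensions");
  const int nro = nrp - nrt + 1, nco = ncp - nct + 1;
  NumericMatrix out(nro, nco);
  for (int j = 0; j < nco; ++j) {
    for (int i = 0; i < nro; ++i) {
      double acc = 0.0;
      for (int y = 0; y < nct; ++y) {
        const double* pc = &p(i, j + y);
        const double* tc = &t(0, y);
        for (int x = 0; x < nrt; ++x) acc += tc[x] * pc[x];
      }
      out(i, j) = acc;
    }
  }
  return out;
}
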