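#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labelling of a binary image. Labels are assigned
// 1..k in column-major scan order of each component's first pixel, so
// counts and label identities are reproducible. NA is treated as background.
// [[Rcpp::export(name = ".label_components8")]]
IntegerMatrix label_components8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == TRUE && lab(i, j) == 0) {
        ++next;
        lab(i, j) = next;
        stack.push_back(i + j * nr);
        while (!stack.empty()) {
          const int idx = stack.back();
          stack.pop_back();
          const int ci = idx % nr, cj = idx / nr;
          for (int dj = -1; dj <= 1; ++dj) {
            for (int di = -1; di <= 1; ++di) {
              const int ni = ci + di, nj = cj + dj;
              if (ni >= 0 && ni < nr && nj >= 0 && nj < nc &&
                  mask(ni, nj) == TRUE && lab(ni, nj) == 0) {
                lab(ni, nj) = next;
                stack.push_back(ni + nj * nr);
              }
            }
          }
        }
      }
    }
  }
  return lab;
}
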