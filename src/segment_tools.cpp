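#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Connected-component labeling on a binary matrix.
// connectivity: 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
// Labels are assigned in column-major scan order, starting at 1.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const LogicalMatrix& x, int connectivity) {
  const int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!x(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + nr * c);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < nn; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (x(qr, qc) && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr + nr * qc);
          }
        }
      }
    }
  }
  return lab;
}

struct PixEntry {
  double prio;   // priority (higher floods first)
  long order;    // insertion order, breaks ties deterministically (FIFO)
  int idx;       // linear pixel index
};
struct PixCmp {
  bool operator()(const PixEntry& a, const PixEntry& b) const {
    if (a.prio != b.prio) return a.prio < b.prio;  // max-heap on priority
    return a.order > b.order;                      // earlier pushes first
  }
};

// Seeded watershed by priority flooding: seeds grow into `mask` in order of
// decreasing `height` (equivalently, watershed on -height). Pixels outside
// the mask, and masked pixels unreachable from any seed, stay 0.
// [[Rcpp::export(name = ".watershed_flood")]]
IntegerMatrix watershed_flood(const NumericMatrix& height,
                              const IntegerMatrix& seeds,
                              const LogicalMatrix& mask) {
  const int nr = height.nrow(), nc = height.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc || mask.nrow() != nr || mask.ncol() != nc)
    stop("height, seeds and mask must share dimensions");
  IntegerMatrix lab(nr, nc);
  std::priority_queue<PixEntry, std::vector<PixEntry>, PixCmp> pq;
  long order = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0 && mask(r, c)) {
        lab(r, c) = seeds(r, c);
        pq.push({height(r, c), order++, r + nr * c});
      }
  const int dr[] = {-1, 1, 0, 0}, dc[] = {0, 0, -1, 1};
  while (!pq.empty()) {
    PixEntry e = pq.top(); pq.pop();
    int pr = e.idx % nr, pc = e.idx / nr;
    int l = lab(pr, pc);
    for (int k = 0; k < 4; ++k) {
      int qr = pr + dr[k], qc = pc + dc[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      if (mask(qr, qc) && lab(qr, qc) == 0) {
        lab(qr, qc) = l;
        pq.push({height(qr, qc), order++, qr + nr * qc});
      }
    }
  }
  return lab;
}
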