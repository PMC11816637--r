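#include <Rcpp.h>
#include <queue>
#include <vector>

using namespace Rcpp;

// Priority-flood seeded watershed (Meyer-style flooding).
//
// Pixels are flooded in non-descending order of the relief value; among
// equal values the pixel queued first wins (FIFO). Pixels are queued in
// lexicographic (row, col) order: the initial frontier is built by a
// row-major scan, and a newly labeled pixel queues its 4-neighbours in
// (r-1,c), (r,c-1), (r,c+1), (r+1,c) order. This makes the result fully
// deterministic, including on plateaus.
//
// A popped pixel whose labeled 4-neighbours carry >= 2 distinct labels
// becomes a watershed-line pixel (label -1) and does not propagate.

struct QEntry {
  double value;
  long long order;
  int idx;
};

struct QCompare {
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.value != b.value) return a.value > b.value; // min-heap on relief
    return a.order > b.order;                         // FIFO among equals
  }
};

// [[Rcpp::export(name = ".ws_flood")]]
List ws_flood(NumericMatrix relief, IntegerMatrix seeds) {
  const int nr = relief.nrow(), nc = relief.ncol();
  IntegerMatrix lab(nr, nc); // 0 unlabeled, >0 basin, -1 line
  std::vector<char> queued(static_cast<size_t>(nr) * nc, 0);

  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      lab(r, c) = seeds(r, c) > 0 ? seeds(r, c) : 0;

  const int dr[4] = {-1, 0, 0, 1};
  const int dc[4] = {0, -1, 1, 0};

  std::priority_queue<QEntry, std::vector<QEntry>, QCompare> pq;
  long long ord = 0;

  // The flood may seal off small pockets behind freshly drawn line pixels;
  // re-seed the frontier until no unlabeled pixel with a basin neighbour is
  // left so that basins + line partition the image.
  bool progress = true;
  while (progress) {
    progress = false;
    // initial / re-seeded frontier, row-major scan
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) {
        if (lab(r, c) != 0 || queued[r + static_cast<size_t>(c) * nr]) continue;
        for (int k = 0; k < 4; ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && lab(rr, cc) > 0) {
            queued[r + static_cast<size_t>(c) * nr] = 1;
            pq.push({relief(r, c), ord++, r + c * nr});
            break;
          }
        }
      }
    }
    while (!pq.empty()) {
      QEntry e = pq.top();
      pq.pop();
      int r = e.idx % nr, c = e.idx / nr;
      if (lab(r, c) != 0) continue;
      int found = 0;
      bool line = false;
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          if (found == 0) found = l;
          else if (found != l) { line = true; break; }
        }
      }
      if (line) {
        lab(r, c) = -1;
        progress = true;
        continue; // line pixels do not propagate labels
      }
      if (found == 0) continue; // neighbours turned into line; handled by re-seed
      lab(r, c) = found;
      progress = true;
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && lab(rr, cc) == 0 &&
            !queued[rr + static_cast<size_t>(cc) * nr]) {
          queued[rr + static_cast<size_t>(cc) * nr] = 1;
          pq.push({relief(rr, cc), ord++, rr + cc * nr});
        }
      }
    }
    // allow re-queueing of pixels that were dequeued without resolution
    if (progress) {
      for (int c = 0; c < nc; ++c)
        for (int r = 0; r < nr; ++r)
          if (lab(r, c) == 0) queued[r + static_cast<size_t>(c) * nr] = 0;
    }
  }

  // pockets fully enclosed by line pixels (no basin contact) join the line
  LogicalMatrix line(nr, nc);
  IntegerMatrix labels(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (lab(r, c) > 0) {
        labels(r, c) = lab(r, c);
      } else {
        labels(r, c) = 0;
        line(r, c) = true;
      }
    }
  }
  return List::create(_["labels"] = labels, _["line"] = line);
}
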