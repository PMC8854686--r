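#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <vector>
using namespace Rcpp;

// Marker-controlled watershed by priority flooding.  Flooding starts at
// the marker pixels and grows into the foreground in order of increasing
// relief, 8-connectivity; every reachable foreground pixel is assigned to
// exactly one marker label (no watershed-line pixels are kept, so labels
// partition the reachable foreground).  Ties in relief are resolved by
// insertion order, which makes the result deterministic.
// [[Rcpp::export]]
IntegerMatrix marker_watershed_cpp(NumericMatrix relief, IntegerMatrix markers,
                                   LogicalMatrix fg) {
  const int H = relief.nrow(), W = relief.ncol();
  if (markers.nrow() != H || markers.ncol() != W ||
      fg.nrow() != H || fg.ncol() != W)
    stop("relief, markers and fg must share dimensions");

  IntegerMatrix labels(H, W);
  typedef std::tuple<double, long, int> Node;  // (relief, tick, linear idx)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  long tick = 0;

  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (markers(r, c) > 0 && fg(r, c)) {
        labels(r, c) = markers(r, c);
        pq.push(Node(relief(r, c), tick++, r + c * H));
      }

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  while (!pq.empty()) {
    int idx = std::get<2>(pq.top());
    pq.pop();
    int r = idx % H, c = idx / H;
    int lab = labels(r, c);
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      if (!fg(rr, cc) || labels(rr, cc) != 0) continue;
      labels(rr, cc) = lab;
      pq.push(Node(relief(rr, cc), tick++, rr + cc * H));
    }
  }
  return labels;
}
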