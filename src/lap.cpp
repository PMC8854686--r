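#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Minimum-cost square linear assignment by shortest augmenting paths
// (Jonker-Volgenant style, one Dijkstra sweep per row).  Forbidden
// entries are passed as +Inf; the solve fails only if no finite complete
// assignment exists.  Returns, for each row, the assigned column
// (1-based), or feasible = FALSE.
// [[Rcpp::export]]
List lap_solve_cpp(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  if (n == 0)
    return List::create(_["feasible"] = true, _["col4row"] = IntegerVector(0));

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> col4row(n, -1), row4col(n, -1);
  std::vector<double> u(n, 0.0), v(n, 0.0);

  for (int curRow = 0; curRow < n; ++curRow) {
    std::vector<double> shortest(n, INF);
    std::vector<int> pred(n, -1);
    std::vector<char> doneRow(n, 0), doneCol(n, 0);
    double minVal = 0.0;
    int i = curRow, sink = -1;

    while (sink == -1) {
      doneRow[i] = 1;
      double lowest = INF;
      int jLow = -1;
      for (int j = 0; j < n; ++j) {
        if (doneCol[j]) continue;
        double r = minVal + cost(i, j) - u[i] - v[j];
        if (r < shortest[j]) { shortest[j] = r; pred[j] = i; }
        if (shortest[j] < lowest ||
            (shortest[j] == lowest && jLow >= 0 &&
             row4col[j] == -1 && row4col[jLow] != -1)) {
          lowest = shortest[j];
          jLow = j;
        }
      }
      if (!std::isfinite(lowest))
        return List::create(_["feasible"] = false);
      minVal = lowest;
      doneCol[jLow] = 1;
      if (row4col[jLow] == -1) sink = jLow; else i = row4col[jLow];
    }

    u[curRow] += minVal;
    for (int k = 0; k < n; ++k)
      if (doneRow[k] && k != curRow) u[k] += minVal - shortest[col4row[k]];
    for (int j = 0; j < n; ++j)
      if (doneCol[j]) v[j] -= minVal - shortest[j];

    int j = sink;
    for (;;) {
      int i2 = pred[j];
      row4col[j] = i2;
      int tmp = col4row[i2];
      col4row[i2] = j;
      j = tmp;
      if (i2 == curRow) break;
    }
  }

  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = col4row[i] + 1;
  return List::create(_["feasible"] = true, _["col4row"] = out);
}
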