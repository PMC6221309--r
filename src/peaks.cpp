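#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Topographic prominence of every strict local maximum of a height grid.
//
// Cells equal to -Inf are barriers (non-measured). Cells are processed in
// descending height order (ties broken by linear index); components are
// grown with union-find over the 8-neighbourhood. A new component is
// founded at each local maximum; when two components meet, the one whose
// founding peak is lower dies and its prominence is its peak height minus
// the merge (saddle) height. Surviving founders get peak height minus the
// lowest height absorbed into their component (for the global maximum of a
// region this is height above the regional minimum).

static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// [[Rcpp::export]]
List peak_prominence_cpp(NumericMatrix z) {
  const int nr = z.nrow(), nc = z.ncol(), N = nr * nc;
  std::vector<int> order;
  order.reserve(N);
  for (int idx = 0; idx < N; ++idx) {
    if (R_finite(z[idx])) order.push_back(idx);
  }
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return z[a] > z[b]; });

  std::vector<int> parent(N, -1), founder(N, -1);
  std::vector<double> comp_low(N, 0.0);
  std::vector<double> prom(N, -1.0);
  std::vector<char> done(N, 0);

  const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  for (size_t t = 0; t < order.size(); ++t) {
    const int idx = order[t];
    const int i = idx % nr, j = idx / nr;
    parent[idx] = idx;
    founder[idx] = idx;
    comp_low[idx] = z[idx];
    done[idx] = 1;
    for (int a = 0; a < 8; ++a) {
      const int ni = i + di[a], nj = j + dj[a];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      const int nidx = ni + nj * nr;
      if (!done[nidx]) continue;
      int rc = uf_find(parent, idx);
      int rn = uf_find(parent, nidx);
      if (rc == rn) continue;
      // merge at saddle height z[idx]; lower-peak component dies
      int keep = rc, kill = rn;
      if (z[founder[rn]] > z[founder[rc]] ||
          (z[founder[rn]] == z[founder[rc]] && founder[rn] < founder[rc])) {
        keep = rn; kill = rc;
      }
      prom[founder[kill]] = z[founder[kill]] - z[idx];
      parent[kill] = keep;
      comp_low[keep] = std::min(comp_low[keep],
                                std::min(comp_low[kill], z[idx]));
    }
    int r = uf_find(parent, idx);
    comp_low[r] = std::min(comp_low[r], z[idx]);
  }

  // surviving roots: prominence relative to their component minimum
  for (size_t t = 0; t < order.size(); ++t) {
    const int idx = order[t];
    if (uf_find(parent, idx) == idx && prom[founder[idx]] < 0.0) {
      prom[founder[idx]] = z[founder[idx]] - comp_low[idx];
    }
  }

  // report strict local maxima only (founders are exactly these when the
  // surface has no tied neighbouring heights)
  std::vector<int> rows, cols;
  std::vector<double> p_out;
  for (int idx = 0; idx < N; ++idx) {
    if (prom[idx] < 0.0 && !(done[idx] && uf_find(parent, idx) == idx))
      continue;
    if (founder[idx] != idx || !done[idx]) continue;
    // verify strict local maximum against measured neighbours
    const int i = idx % nr, j = idx / nr;
    bool ismax = true;
    for (int a = 0; a < 8 && ismax; ++a) {
      const int ni = i + di[a], nj = j + dj[a];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      const double nz = z[ni + nj * nr];
      if (R_finite(nz) && nz >= z[idx]) ismax = false;
    }
    if (!ismax) continue;
    rows.push_back(i + 1);
    cols.push_back(j + 1);
    p_out.push_back(prom[idx]);
  }
  return List::create(_["rows"] = wrap(rows), _["cols"] = wrap(cols),
                      _["prominence"] = wrap(p_out));
}
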