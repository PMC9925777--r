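#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Persistence pairs of the cubical sublevel-set filtration of a 2D scalar
// field under the V-construction: pixels are vertices, edges join
// 4-neighbours, unit squares fill 2x2 blocks, and a cell's filtration value
// is the max over its vertices.
//
// H0 is computed by union-find over the edges in increasing filtration order
// (elder rule: a merge kills the component with the younger, i.e. larger,
// birth). H1 uses planar duality: a 1-cycle is created by an edge whose
// endpoints are already connected, and dies when its bounded region fills in;
// equivalently, running union-find on the dual graph (squares plus one outer
// node) over the edges in *decreasing* order pairs each cycle-creating edge
// with the smaller of the two maximal square values it separates.

namespace {

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    int r = x;
    while (parent[r] != r) r = parent[r];
    while (parent[x] != r) { int nx = parent[x]; parent[x] = r; x = nx; }
    return r;
  }
};

struct Edge {
  double value;
  int a, b;      // vertex ids (primal endpoints)
  int da, db;    // dual node ids (adjacent squares; outer node if on border)
  int id;
};

} // namespace

// [[Rcpp::export]]
DataFrame cubical_pairs_cpp(NumericMatrix field) {
  const int H = field.nrow(), W = field.ncol();
  const int V = H * W;
  auto vid = [W](int i, int j) { return i * W + j; };

  std::vector<double> fv(V);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j)
      fv[vid(i, j)] = field(i, j);

  // vertex a is "older" than b when (value, index) is smaller
  auto older = [&fv](int a, int b) {
    return fv[a] < fv[b] || (fv[a] == fv[b] && a < b);
  };

  const int nSqRows = std::max(0, H - 1), nSqCols = std::max(0, W - 1);
  const int nSq = nSqRows * nSqCols;
  const int OUTER = nSq;
  auto sqid = [nSqCols](int i, int j) { return i * nSqCols + j; };

  std::vector<double> sqv(nSq);
  for (int i = 0; i < nSqRows; ++i)
    for (int j = 0; j < nSqCols; ++j)
      sqv[sqid(i, j)] = std::max(std::max(field(i, j), field(i, j + 1)),
                                 std::max(field(i + 1, j), field(i + 1, j + 1)));

  std::vector<Edge> edges;
  edges.reserve(2 * V);
  int eid = 0;
  // horizontal edges (i,j)-(i,j+1); dual neighbours: squares above and below
  for (int i = 0; i < H; ++i)
    for (int j = 0; j + 1 < W; ++j) {
      Edge e;
      e.a = vid(i, j); e.b = vid(i, j + 1);
      e.value = std::max(fv[e.a], fv[e.b]);
      e.da = (i > 0 && j < nSqCols) ? sqid(i - 1, j) : OUTER;
      e.db = (i < nSqRows && j < nSqCols) ? sqid(i, j) : OUTER;
      e.id = eid++;
      edges.push_back(e);
    }
  // vertical edges (i,j)-(i+1,j); dual neighbours: squares left and right
  for (int i = 0; i + 1 < H; ++i)
    for (int j = 0; j < W; ++j) {
      Edge e;
      e.a = vid(i, j); e.b = vid(i + 1, j);
      e.value = std::max(fv[e.a], fv[e.b]);
      e.da = (j > 0 && i < nSqRows) ? sqid(i, j - 1) : OUTER;
      e.db = (j < nSqCols && i < nSqRows) ? sqid(i, j) : OUTER;
      e.id = eid++;
      edges.push_back(e);
    }

  std::vector<int> ord(edges.size());
  for (size_t k = 0; k < ord.size(); ++k) ord[k] = (int)k;
  std::sort(ord.begin(), ord.end(), [&edges](int x, int y) {
    if (edges[x].value != edges[y].value) return edges[x].value < edges[y].value;
    return edges[x].id < edges[y].id;
  });

  std::vector<int> out_dim;
  std::vector<double> out_birth, out_death;
  std::vector<int> out_row, out_col;
  std::vector<int> out_ess;

  // ---- H0: union-find over vertices, edges ascending -------------------
  {
    UnionFind uf(V);
    std::vector<int> birth_vertex(V);
    for (int v = 0; v < V; ++v) birth_vertex[v] = v;
    for (int k : ord) {
      const Edge &e = edges[k];
      int ra = uf.find(e.a), rb = uf.find(e.b);
      if (ra == rb) continue;
      int ba = birth_vertex[ra], bb = birth_vertex[rb];
      int elder_root = older(ba, bb) ? ra : rb;
      int young_root = (elder_root == ra) ? rb : ra;
      int yb = birth_vertex[young_root];
      if (e.value > fv[yb]) {
        out_dim.push_back(0);
        out_birth.push_back(fv[yb]);
        out_death.push_back(e.value);
        out_row.push_back(yb / W + 1);
        out_col.push_back(yb % W + 1);
        out_ess.push_back(0);
      }
      uf.parent[young_root] = elder_root;
      birth_vertex[elder_root] = older(ba, bb) ? ba : bb;
    }
    int root = uf.find(0);
    int gb = birth_vertex[root];
    out_dim.push_back(0);
    out_birth.push_back(fv[gb]);
    out_death.push_back(R_PosInf);
    out_row.push_back(gb / W + 1);
    out_col.push_back(gb % W + 1);
    out_ess.push_back(1);
  }

  // ---- H1: union-find over dual nodes, edges descending ----------------
  if (nSq >= 0) {
    UnionFind uf(nSq + 1);
    std::vector<double> comp_max(nSq + 1);
    for (int s = 0; s < nSq; ++s) comp_max[s] = sqv[s];
    comp_max[OUTER] = R_PosInf;
    for (auto it = ord.rbegin(); it != ord.rend(); ++it) {
      const Edge &e = edges[*it];
      int ra = uf.find(e.da), rb = uf.find(e.db);
      if (ra == rb) continue;
      double death = std::min(comp_max[ra], comp_max[rb]);
      if (death > e.value) {
        // birth pixel: the endpoint realising the edge value (tie: smaller id)
        int bp = (fv[e.a] >= fv[e.b]) ? e.a : e.b;
        if (fv[e.a] == fv[e.b]) bp = std::min(e.a, e.b);
        out_dim.push_back(1);
        out_birth.push_back(e.value);
        out_death.push_back(death);
        out_row.push_back(bp / W + 1);
        out_col.push_back(bp % W + 1);
        out_ess.push_back(0);
      }
      int keep = (comp_max[ra] >= comp_max[rb]) ? ra : rb;
      int drop = (keep == ra) ? rb : ra;
      uf.parent[drop] = keep;
    }
  }

  return DataFrame::create(
      Named("dim") = out_dim,
      Named("birth") = out_birth,
      Named("death") = out_death,
      Named("birth_row") = out_row,
      Named("birth_col") = out_col,
      Named("essential") = LogicalVector(out_ess.begin(), out_ess.end()));
}
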