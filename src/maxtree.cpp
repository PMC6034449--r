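// Max-tree (component tree) core: construction by union-find on value-sorted
// pixels, incremental attribute propagation, extinction values, attribute
// opening and node pixel-set materialisation.
//
// Conventions shared with the R side:
//  * images are R integer matrices (column-major), grey levels in [0, 255];
//  * pixels are addressed by 0-based linear index p = row + col * H;
//  * pixel-centre coordinates are x = col, y = row (0-based);
//  * node ids are 1-based; children always have smaller ids than their parent,
//    so id order is a valid bottom-up (leaves-first) traversal; the root is
//    the last node.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Pt {
  int x, y;  // doubled coordinates (pixel corners live on the half-grid)
};

inline long long cross(const Pt& o, const Pt& a, const Pt& b) {
  return (long long)(a.x - o.x) * (b.y - o.y) -
         (long long)(a.y - o.y) * (b.x - o.x);
}

// Andrew's monotone chain; points may contain duplicates. Returns hull in
// counter-clockwise order without the closing point.
std::vector<Pt> convex_hull(std::vector<Pt>& pts) {
  std::sort(pts.begin(), pts.end(), [](const Pt& a, const Pt& b) {
    return a.x < b.x || (a.x == b.x && a.y < b.y);
  });
  pts.erase(std::unique(pts.begin(), pts.end(), [](const Pt& a, const Pt& b) {
              return a.x == b.x && a.y == b.y;
            }),
            pts.end());
  size_t n = pts.size();
  if (n <= 2) return pts;
  std::vector<Pt> h(2 * n);
  size_t k = 0;
  for (size_t i = 0; i < n; ++i) {  // lower hull
    while (k >= 2 && cross(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
    h[k++] = pts[i];
  }
  size_t lower = k + 1;
  for (size_t i = n - 1; i-- > 0;) {  // upper hull
    while (k >= lower && cross(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
    h[k++] = pts[i];
  }
  h.resize(k - 1);
  return h;
}

double hull_area_doubled(const std::vector<Pt>& h) {
  // shoelace on doubled coordinates: divide by 2 (shoelace) and 4 (scale)
  if (h.size() < 3) return 0.0;
  long long s = 0;
  for (size_t i = 0, n = h.size(); i < n; ++i) {
    const Pt& a = h[i];
    const Pt& b = h[(i + 1) % n];
    s += (long long)a.x * b.y - (long long)b.x * a.y;
  }
  return (double)s / 8.0;
}

inline int find_root(std::vector<int>& zpar, int p) {
  int r = p;
  while (zpar[r] != r) r = zpar[r];
  while (zpar[p] != r) {  // path compression
    int q = zpar[p];
    zpar[p] = r;
    p = q;
  }
  return r;
}

}  // namespace

// Build the canonical max-tree of an 8-bit image and propagate all node
// attributes (area, raw moment sums, grey extrema, convex-hull area) from the
// leaves to the root. Each pixel's coordinates enter the moment sums exactly
// once, at its own node.
// [[Rcpp::export(name = ".mt_build")]]
List mt_build(IntegerMatrix img, int connectivity, bool keep_hull_points) {
  const int H = img.nrow(), W = img.ncol();
  const int N = H * W;
  if (N == 0) stop("empty image");
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");

  const int* f = INTEGER(img);
  for (int p = 0; p < N; ++p)
    if (f[p] < 0 || f[p] > 255 || f[p] == NA_INTEGER)
      stop("image values must be integers in [0, 255]");

  // counting sort: descending grey value, ascending linear index within level
  std::vector<int> order(N), bucket(257, 0);
  for (int p = 0; p < N; ++p) ++bucket[f[p]];
  std::vector<int> start(256);
  {
    int acc = 0;
    for (int v = 255; v >= 0; --v) { start[v] = acc; acc += bucket[v]; }
  }
  {
    std::vector<int> pos(start);
    for (int p = 0; p < N; ++p) order[pos[f[p]]++] = p;
  }

  std::vector<int> par(N), zpar(N);
  std::vector<char> dealt(N, 0);

  const int dr4[4] = {-1, 1, 0, 0}, dc4[4] = {0, 0, -1, 1};
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = connectivity == 4 ? dr4 : dr8;
  const int* dc = connectivity == 4 ? dc4 : dc8;
  const int nn = connectivity;

  for (int i = 0; i < N; ++i) {
    int p = order[i];
    par[p] = p;
    zpar[p] = p;
    dealt[p] = 1;
    int r0 = p % H, c0 = p / H;
    for (int j = 0; j < nn; ++j) {
      int r = r0 + dr[j], c = c0 + dc[j];
      if (r < 0 || r >= H || c < 0 || c >= W) continue;
      int q = r + c * H;
      if (!dealt[q]) continue;
      int rt = find_root(zpar, q);
      if (rt != p) {
        par[rt] = p;
        zpar[rt] = p;
      }
    }
  }

  // canonical element of each pixel's node; reverse pass so that par[p]
  // (processed later during construction) is already resolved
  std::vector<int> cano(N);
  for (int i = N - 1; i >= 0; --i) {
    int p = order[i];
    int q = par[p];
    cano[p] = (q == p || f[q] != f[p]) ? p : cano[q];
  }

  // node ids in processing order: children before parents
  std::vector<int> id(N, 0);
  int nnode = 0;
  for (int i = 0; i < N; ++i) {
    int p = order[i];
    if (cano[p] == p) id[p] = ++nnode;
  }

  IntegerVector node_of_pixel(N), parent(nnode), level(nnode);
  std::vector<int> canpix(nnode);
  for (int p = 0; p < N; ++p) node_of_pixel[p] = id[cano[p]];
  for (int i = 0; i < N; ++i) {
    int p = order[i];
    if (cano[p] != p) continue;
    int nid = id[p];
    canpix[nid - 1] = p;
    level[nid - 1] = f[p];
    parent[nid - 1] = (par[p] == p) ? nid : id[cano[par[p]]];
  }

  // per-node accumulators, own pixels first
  NumericVector area(nnode, 0.0), sx(nnode, 0.0), sy(nnode, 0.0),
      sxx(nnode, 0.0), syy(nnode, 0.0), sxy(nnode, 0.0), hull_area(nnode);
  IntegerVector fmin(nnode), fmax(nnode), minpix(nnode);
  std::fill(fmin.begin(), fmin.end(), 256);
  std::fill(fmax.begin(), fmax.end(), -1);
  std::fill(minpix.begin(), minpix.end(), N);

  // proper pixels grouped by node for hull construction
  std::vector<int> npix_own(nnode, 0);
  for (int p = 0; p < N; ++p) ++npix_own[node_of_pixel[p] - 1];
  std::vector<int> own_off(nnode + 1, 0);
  for (int i = 0; i < nnode; ++i) own_off[i + 1] = own_off[i] + npix_own[i];
  std::vector<int> own(N);
  {
    std::vector<int> pos(own_off.begin(), own_off.end() - 1);
    for (int p = 0; p < N; ++p) own[pos[node_of_pixel[p] - 1]++] = p;
  }

  for (int p = 0; p < N; ++p) {
    int i = node_of_pixel[p] - 1;
    double x = p / H, y = p % H;
    area[i] += 1.0;
    sx[i] += x; sy[i] += y;
    sxx[i] += x * x; syy[i] += y * y; sxy[i] += x * y;
    if (f[p] < fmin[i]) fmin[i] = f[p];
    if (f[p] > fmax[i]) fmax[i] = f[p];
    if (p < minpix[i]) minpix[i] = p;
  }

  // bottom-up aggregation (ids ascending = children first)
  std::vector<std::vector<Pt>> pending(nnode);
  List hull_pts(keep_hull_points ? nnode : 0);
  for (int i = 0; i < nnode; ++i) {
    std::vector<Pt> pts = std::move(pending[i]);
    pts.reserve(pts.size() + 4 * (size_t)npix_own[i]);
    for (int k = own_off[i]; k < own_off[i + 1]; ++k) {
      int p = own[k];
      int x2 = 2 * (p / H), y2 = 2 * (p % H);
      pts.push_back({x2 - 1, y2 - 1});
      pts.push_back({x2 - 1, y2 + 1});
      pts.push_back({x2 + 1, y2 - 1});
      pts.push_back({x2 + 1, y2 + 1});
    }
    std::vector<Pt> h = convex_hull(pts);
    hull_area[i] = hull_area_doubled(h);
    if (keep_hull_points) {
      NumericMatrix m(h.size(), 2);
      for (size_t k = 0; k < h.size(); ++k) {
        m(k, 0) = h[k].x / 2.0;
        m(k, 1) = h[k].y / 2.0;
      }
      hull_pts[i] = m;
    }
    int pa = parent[i] - 1;
    if (pa != i) {
      area[pa] += area[i];
      sx[pa] += sx[i]; sy[pa] += sy[i];
      sxx[pa] += sxx[i]; syy[pa] += syy[i]; sxy[pa] += sxy[i];
      if (fmin[i] < fmin[pa]) fmin[pa] = fmin[i];
      if (fmax[i] > fmax[pa]) fmax[pa] = fmax[i];
      if (minpix[i] < minpix[pa]) minpix[pa] = minpix[i];
      std::vector<Pt>& dst = pending[pa];
      dst.insert(dst.end(), h.begin(), h.end());
    }
  }

  List out = List::create(
      _["node_of_pixel"] = node_of_pixel, _["parent"] = parent,
      _["level"] = level, _["area"] = area, _["sx"] = sx, _["sy"] = sy,
      _["sxx"] = sxx, _["syy"] = syy, _["sxy"] = sxy, _["fmin"] = fmin,
      _["fmax"] = fmax, _["hull_area"] = hull_area, _["min_pixel"] = minpix,
      _["root"] = nnode);
  if (keep_hull_points) out["hull_points"] = hull_pts;
  return out;
}

// Grey-range extinction values (contrast dynamics) for every leaf.
// Bottom-up tournament: each node carries its dominant leaf (highest grey
// value, ties to the smallest proper-pixel linear index of the leaf); when
// two subtrees merge, every losing dominant leaf is extinguished at the merge
// node's level. The overall winner receives the full image grey range.
// Returns, per node, the extinction value (NA for non-leaves).
// [[Rcpp::export(name = ".mt_extinction")]]
NumericVector mt_extinction(IntegerVector parent, IntegerVector level,
                            IntegerVector min_pixel, LogicalVector is_leaf) {
  int n = parent.size();
  NumericVector ext(n, NA_REAL);
  std::vector<int> best(n, -1);  // node id-1 of dominant leaf, -1 = unset
  for (int i = 0; i < n; ++i) {
    if (is_leaf[i]) best[i] = i;
    int pa = parent[i] - 1;
    if (pa == i) {  // root: extinguish its winner with the full range
      if (best[i] >= 0) ext[best[i]] = level[best[i]] - level[i];
      continue;
    }
    if (best[i] < 0) continue;
    if (best[pa] < 0) {
      best[pa] = best[i];
    } else {
      int a = best[pa], b = best[i];
      // dominance: higher leaf level wins, ties to smaller pixel index
      bool a_wins = (level[a] > level[b]) ||
                    (level[a] == level[b] && min_pixel[a] <= min_pixel[b]);
      int winner = a_wins ? a : b, loser = a_wins ? b : a;
      ext[loser] = level[loser] - level[pa];
      best[pa] = winner;
    }
  }
  return ext;
}

// Area opening on the tree: every node with area < T is assigned the level of
// its nearest surviving ancestor (the root always survives at its own level
// when nothing else does). Returns the filtered image.
// [[Rcpp::export(name = ".mt_area_opening")]]
IntegerMatrix mt_area_opening(IntegerVector node_of_pixel, IntegerVector parent,
                              IntegerVector level, NumericVector area,
                              double t_area, int H, int W) {
  int n = parent.size();
  std::vector<int> out_level(n);
  for (int i = n - 1; i >= 0; --i) {  // root first (largest id)
    int pa = parent[i] - 1;
    if (area[i] >= t_area || pa == i)
      out_level[i] = (area[i] >= t_area) ? level[i] : level[n - 1];
    else
      out_level[i] = out_level[pa];
  }
  IntegerMatrix out(H, W);
  int N = H * W;
  for (int p = 0; p < N; ++p) out[p] = out_level[node_of_pixel[p] - 1];
  return out;
}

// Pixel membership of the union of the subtrees rooted at `nodes`.
// [[Rcpp::export(name = ".mt_mask_nodes")]]
LogicalVector mt_mask_nodes(IntegerVector node_of_pixel, IntegerVector parent,
                            IntegerVector nodes) {
  int n = parent.size();
  std::vector<char> keep(n, 0);
  for (int k = 0; k < nodes.size(); ++k) {
    int v = nodes[k];
    if (v < 1 || v > n) stop("invalid node id");
    keep[v - 1] = 1;
  }
  for (int i = n - 1; i >= 0; --i) {
    int pa = parent[i] - 1;
    if (pa != i && keep[pa]) keep[i] = 1;
  }
  int N = node_of_pixel.size();
  LogicalVector mask(N);
  for (int p = 0; p < N; ++p) mask[p] = keep[node_of_pixel[p] - 1] != 0;
  return mask;
}

// Image reconstruction: each pixel takes the level of its owning node.
// [[Rcpp::export(name = ".mt_reconstruct")]]
IntegerMatrix mt_reconstruct(IntegerVector node_of_pixel, IntegerVector level,
                             int H, int W) {
  IntegerMatrix out(H, W);
  int N = H * W;
  for (int p = 0; p < N; ++p) out[p] = level[node_of_pixel[p] - 1];
  return out;
}
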