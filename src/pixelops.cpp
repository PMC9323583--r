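#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Flat row-major uint8 view used by the thinning loop. Neighbour order
// P2..P9: clockwise from north.
struct Grid {
  std::vector<unsigned char> v;
  int H, W;
  Grid(int h, int w) : v((size_t)h * w, 0), H(h), W(w) {}
  inline unsigned char at(int r, int c) const {
    if (r < 0 || c < 0 || r >= H || c >= W) return 0;
    return v[(size_t)r * W + c];
  }
  inline void set(int r, int c, unsigned char x) { v[(size_t)r * W + c] = x; }
};

static inline void neighbours8(const Grid &g, int r, int c, int p[8]) {
  p[0] = g.at(r - 1, c);     // P2 N
  p[1] = g.at(r - 1, c + 1); // P3 NE
  p[2] = g.at(r, c + 1);     // P4 E
  p[3] = g.at(r + 1, c + 1); // P5 SE
  p[4] = g.at(r + 1, c);     // P6 S
  p[5] = g.at(r + 1, c - 1); // P7 SW
  p[6] = g.at(r, c - 1);     // P8 W
  p[7] = g.at(r - 1, c - 1); // P9 NW
}

// Hilditch crossing/connectivity number for 8-connected foreground:
// C = sum over the four 4-neighbours i in {P2,P4,P6,P8} of
//     (1 - Pi) * (P(i+1) | P(i+2)).  Deleting p with C == 1 preserves
// 8-connectivity of the foreground.
static int conn_number(const int p[8]) {
  int c = 0;
  for (int i = 0; i < 8; i += 2) {
    int pi = p[i], p1 = p[(i + 1) % 8], p2 = p[(i + 2) % 8];
    c += (1 - pi) * ((p1 | p2) != 0 ? 1 : 0);
  }
  return c;
}

// 8-connected foreground component count on the flat grid
static int count_components8(const Grid &g) {
  std::vector<int> lab((size_t)g.H * g.W, 0);
  static const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  std::vector<int> stack;
  int ncomp = 0;
  for (int r0 = 0; r0 < g.H; ++r0) {
    for (int c0 = 0; c0 < g.W; ++c0) {
      size_t v0 = (size_t)r0 * g.W + c0;
      if (!g.v[v0] || lab[v0]) continue;
      ++ncomp;
      lab[v0] = ncomp;
      stack.push_back((int)v0);
      while (!stack.empty()) {
        int v = stack.back();
        stack.pop_back();
        int r = v / g.W, c = v % g.W;
        for (int i = 0; i < 8; ++i) {
          int r2 = r + dr[i], c2 = c + dc[i];
          if (r2 < 0 || c2 < 0 || r2 >= g.H || c2 >= g.W) continue;
          size_t v2 = (size_t)r2 * g.W + c2;
          if (g.v[v2] && !lab[v2]) {
            lab[v2] = ncomp;
            stack.push_back((int)v2);
          }
        }
      }
    }
  }
  return ncomp;
}

// Zhang-Suen two-subiteration parallel thinning, plus a cleanup pass that
// deletes one 8-simple pixel from any residual fully-foreground 2x2 block.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix input) {
  int H = input.nrow(), W = input.ncol();
  Grid g(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      g.set(r, c, input(r, c) ? 1 : 0);

  std::vector<int> kill;
  kill.reserve(4096);
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int r = 0; r < H; ++r) {
        const size_t row = (size_t)r * W;
        for (int c = 0; c < W; ++c) {
          if (!g.v[row + c]) continue;
          int p[8];
          neighbours8(g, r, c, p);
          int B = p[0] + p[1] + p[2] + p[3] + p[4] + p[5] + p[6] + p[7];
          if (B < 2 || B > 6) continue;
          int A = 0; // 0 -> 1 transitions around the ring
          for (int i = 0; i < 8; ++i)
            if (p[i] == 0 && p[(i + 1) % 8] == 1) ++A;
          if (A != 1) continue;
          // p[0]=P2 p[2]=P4 p[4]=P6 p[6]=P8
          if (sub == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          kill.push_back(r * W + c);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t i = 0; i < kill.size(); ++i) g.v[kill[i]] = 0;
      }
    }
  }

  bool blocks = true;
  while (blocks) {
    blocks = false;
    bool removed = false;
    for (int r = 0; r + 1 < H && !removed; ++r) {
      for (int c = 0; c + 1 < W && !removed; ++c) {
        if (g.at(r, c) && g.at(r, c + 1) && g.at(r + 1, c) &&
            g.at(r + 1, c + 1)) {
          blocks = true;
          const int rr[4] = {r, r, r + 1, r + 1};
          const int cc[4] = {c, c + 1, c, c + 1};
          // fast path: a locally 8-simple pixel
          for (int i = 0; i < 4 && !removed; ++i) {
            int p[8];
            neighbours8(g, rr[i], cc[i], p);
            if (conn_number(p) == 1) {
              g.set(rr[i], cc[i], 0);
              removed = true;
            }
          }
          // X-junction blocks have no locally simple pixel, but a
          // deletion may still be bridged elsewhere: accept any pixel
          // whose removal keeps the global 8-component count
          if (!removed) {
            int before = count_components8(g);
            for (int i = 0; i < 4 && !removed; ++i) {
              g.set(rr[i], cc[i], 0);
              if (count_components8(g) <= before) {
                removed = true;
              } else {
                g.set(rr[i], cc[i], 1);
              }
            }
          }
        }
      }
    }
    if (blocks && !removed) break; // topology forbids thinning this block
  }

  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      out(r, c) = g.at(r, c);
  return out;
}

// [[Rcpp::export]]
List cpp_label_components(IntegerMatrix img, int connectivity) {
  int H = img.nrow(), W = img.ncol();
  IntegerMatrix lab(H, W);
  int ncomp = 0;
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[4] = {-1, 0, 0, 1};
  static const int dc4[4] = {0, -1, 1, 0};
  int nn = (connectivity == 4) ? 4 : 8;
  const int *dr = (connectivity == 4) ? dr4 : dr8;
  const int *dc = (connectivity == 4) ? dc4 : dc8;
  std::vector<int> stack;
  stack.reserve(H * W / 4 + 1);
  for (int r0 = 0; r0 < H; ++r0) {
    for (int c0 = 0; c0 < W; ++c0) {
      if (!img(r0, c0) || lab(r0, c0)) continue;
      ++ncomp;
      lab(r0, c0) = ncomp;
      stack.push_back(r0 * W + c0);
      while (!stack.empty()) {
        int v = stack.back();
        stack.pop_back();
        int r = v / W, c = v % W;
        for (int i = 0; i < nn; ++i) {
          int r2 = r + dr[i], c2 = c + dc[i];
          if (r2 < 0 || c2 < 0 || r2 >= H || c2 >= W) continue;
          if (img(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = ncomp;
            stack.push_back(r2 * W + c2);
          }
        }
      }
    }
  }
  return List::create(_["n"] = ncomp, _["labels"] = lab);
}

// Occupied-box count for one mesh size: cells of s x s pixels anchored at
// the top-left corner, partial cells at the right/bottom edges included.
// [[Rcpp::export]]
int cpp_box_count(IntegerMatrix img, int s) {
  int H = img.nrow(), W = img.ncol();
  int ch = (H + s - 1) / s, cw = (W + s - 1) / s;
  std::vector<char> occ((size_t)ch * cw, 0);
  int count = 0;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!img(r, c)) continue;
      size_t cell = (size_t)(r / s) * cw + (c / s);
      if (!occ[cell]) {
        occ[cell] = 1;
        ++count;
      }
    }
  }
  return count;
}

// Stamp an anti-aliased stroke from (x0, y0) to (x1, y1) of the given
// width into the canvas, max-composited, IN PLACE. Coordinates follow the
// R convention used by the generator: x = column, y = row, 1-based pixel
// centres; the linear alpha ramp spans one pixel at the stroke boundary.
// [[Rcpp::export]]
void cpp_stamp(NumericMatrix canvas, double x0, double y0, double x1,
               double y1, double width, double intensity) {
  int H = canvas.nrow(), W = canvas.ncol();
  double half = width / 2.0;
  int pad = (int)std::ceil(half + 1.0);
  int cmin = std::max(1, (int)std::floor(std::min(x0, x1)) - pad);
  int cmax = std::min(W, (int)std::ceil(std::max(x0, x1)) + pad);
  int rmin = std::max(1, (int)std::floor(std::min(y0, y1)) - pad);
  int rmax = std::min(H, (int)std::ceil(std::max(y0, y1)) + pad);
  double dx = x1 - x0, dy = y1 - y0;
  double len2 = dx * dx + dy * dy;
  for (int c = cmin; c <= cmax; ++c) {
    for (int r = rmin; r <= rmax; ++r) {
      double px = c, py = r, d;
      if (len2 < 1e-12) {
        d = std::sqrt((px - x0) * (px - x0) + (py - y0) * (py - y0));
      } else {
        double t = ((px - x0) * dx + (py - y0) * dy) / len2;
        t = std::max(0.0, std::min(1.0, t));
        double qx = x0 + t * dx, qy = y0 + t * dy;
        d = std::sqrt((px - qx) * (px - qx) + (py - qy) * (py - qy));
      }
      double a = std::max(0.0, std::min(1.0, half + 0.5 - d)) * intensity;
      double &cell = canvas(r - 1, c - 1);
      if (a > cell) cell = a;
    }
  }
}
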