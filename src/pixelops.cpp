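#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Offsets of a disk structuring element: dx^2 + dy^2 <= r^2.
static std::vector<std::pair<int, int>> disk_offsets(int radius) {
  std::vector<std::pair<int, int>> off;
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx)
      if (dx * dx + dy * dy <= radius * radius) off.push_back({dy, dx});
  return off;
}

// Binary erosion/dilation with a disk element. Pixels outside the image are
// treated as background, so erosion shaves foreground touching the border
// and dilation never grows from outside.
// [[Rcpp::export(".morph_disk")]]
LogicalMatrix morph_disk(const LogicalMatrix& mask, int radius, bool erode) {
  if (radius < 0) stop("radius must be >= 0");
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  if (radius == 0) {
    std::copy(mask.begin(), mask.end(), out.begin());
    return out;
  }
  std::vector<std::pair<int, int>> off = disk_offsets(radius);
  // Only foreground pixels can survive erosion or seed dilation, so both
  // passes iterate over foreground pixels alone.
  std::fill(out.begin(), out.end(), false);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      if (erode) {
        bool keep = true;
        for (size_t k = 0; k < off.size(); ++k) {
          const int ii = i + off[k].first, jj = j + off[k].second;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc || !mask(ii, jj)) {
            keep = false;
            break;
          }
        }
        out(i, j) = keep;
      } else {
        for (size_t k = 0; k < off.size(); ++k) {
          const int ii = i + off[k].first, jj = j + off[k].second;
          if (ii >= 0 && ii < nr && jj >= 0 && jj < nc) out(ii, jj) = true;
        }
      }
    }
  }
  return out;
}

// 8-connected component labelling; labels assigned 1..k in column-major
// scan order of each component's first-visited pixel.
// [[Rcpp::export(".label_components")]]
IntegerMatrix label_components(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({i, j});
      lab(i, j) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int ii = p.first + di, jj = p.second + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back({ii, jj});
            }
          }
        }
      }
    }
  }
  return lab;
}

// Colour-range test for an 8-bit RGB frame (column-major planes, grey
// levels 0-255). In HSV mode hue is degrees [0, 360), saturation and
// value are fractions, matching the usual max/min hexcone conversion.
// Bounds are k x 3 windows combined with OR.
// [[Rcpp::export(".color_mask_cpp")]]
LogicalMatrix color_mask_cpp(const NumericVector& frame, int H, int W,
                             const NumericMatrix& lower,
                             const NumericMatrix& upper, bool hsv) {
  const int n = H * W;
  LogicalMatrix out(H, W);
  const int k = lower.nrow();
  for (int i = 0; i < n; ++i) {
    double c1 = frame[i], c2 = frame[i + n], c3 = frame[i + 2 * n];
    if (hsv) {
      const double r = c1, g = c2, b = c3;
      const double mx = std::max(r, std::max(g, b));
      const double mn = std::min(r, std::min(g, b));
      const double d = mx - mn;
      double h = 0.0;
      if (d > 0) {
        if (mx == r) h = (g - b) / d;
        else if (mx == g) h = 2.0 + (b - r) / d;
        else h = 4.0 + (r - g) / d;
        h *= 60.0;
        if (h < 0) h += 360.0;
      }
      c1 = h;
      c2 = mx > 0 ? d / mx : 0.0;
      c3 = mx / 255.0;
    }
    bool fg = false;
    for (int w = 0; w < k && !fg; ++w) {
      fg = c1 >= lower(w, 0) && c1 <= upper(w, 0) &&
           c2 >= lower(w, 1) && c2 <= upper(w, 1) &&
           c3 >= lower(w, 2) && c3 <= upper(w, 2);
    }
    out[i] = fg;
  }
  return out;
}
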