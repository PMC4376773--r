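#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Per-object statistics for feature extraction, one pass over the mask:
// area, moment eccentricity, bounding box, foreground intensity mean/sd,
// and background-ring intensity mean/sd. The ring is the set of non-object
// pixels (of any label) within Euclidean distance <= ring_radius of the
// object. A per-pixel stamp avoids double counting within one object while
// letting a pixel belong to the rings of several objects.
// [[Rcpp::export]]
NumericMatrix object_feature_stats_cpp(IntegerMatrix mask,
                                       NumericMatrix image,
                                       double ring_radius) {
  const int nr = mask.nrow(), nc = mask.ncol(), npix = nr * nc;
  int nlab = 0;
  for (int k = 0; k < npix; ++k) nlab = std::max(nlab, mask[k]);
  NumericMatrix out(nlab, 13);
  colnames(out) = CharacterVector::create(
    "area", "ecc", "rmin", "rmax", "cmin", "cmax",
    "fg_mean", "fg_sd", "bg_mean", "bg_sd", "cx", "cy", "hull_area");
  if (nlab == 0) return out;

  // bucket pixel indices by label
  std::vector<int> counts(nlab + 1, 0);
  for (int k = 0; k < npix; ++k) if (mask[k] > 0) ++counts[mask[k]];
  std::vector<int> offset(nlab + 2, 0);
  for (int o = 1; o <= nlab; ++o) offset[o + 1] = offset[o] + counts[o];
  std::vector<int> bucket(offset[nlab + 1]);
  {
    std::vector<int> cur(offset.begin(), offset.end() - 1);
    for (int k = 0; k < npix; ++k)
      if (mask[k] > 0) bucket[cur[mask[k]]++] = k;
  }

  // disc offsets for the ring
  const int rr = (int)std::floor(ring_radius);
  std::vector<int> ddi, ddj;
  for (int dj = -rr; dj <= rr; ++dj)
    for (int di = -rr; di <= rr; ++di)
      if (di * di + dj * dj <= ring_radius * ring_radius &&
          !(di == 0 && dj == 0)) {
        ddi.push_back(di); ddj.push_back(dj);
      }

  // convex-hull pixel area (rasterized hull, "convex image" semantics):
  // monotone-chain hull of the pixel centres, then count lattice points of
  // the bounding box lying inside all hull half-planes. Degenerate
  // (collinear) objects fall back to their own pixel count.
  struct Pt { int x, y; };
  auto cross = [](const Pt& o, const Pt& a, const Pt& b) -> long long {
    return (long long)(a.x - o.x) * (b.y - o.y) -
           (long long)(a.y - o.y) * (b.x - o.x);
  };
  auto hull_pixel_area = [&](std::vector<Pt>& pts) -> double {
    const size_t n = pts.size();
    if (n <= 2) return (double)n;
    std::sort(pts.begin(), pts.end(), [](const Pt& a, const Pt& b) {
      return a.x < b.x || (a.x == b.x && a.y < b.y);
    });
    pts.erase(std::unique(pts.begin(), pts.end(),
                          [](const Pt& a, const Pt& b) {
                            return a.x == b.x && a.y == b.y;
                          }), pts.end());
    const size_t m = pts.size();
    if (m <= 2) return (double)n;
    std::vector<Pt> h(2 * m);
    size_t k = 0;
    for (size_t i = 0; i < m; ++i) {          // lower hull
      while (k >= 2 && cross(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
      h[k++] = pts[i];
    }
    const size_t lower = k + 1;
    for (size_t i = m - 1; i-- > 0;) {        // upper hull
      while (k >= lower && cross(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
      h[k++] = pts[i];
    }
    h.resize(k - 1);
    if (h.size() <= 2) return (double)n;      // collinear
    int xmin = h[0].x, xmax = h[0].x, ymin = h[0].y, ymax = h[0].y;
    for (size_t i = 1; i < h.size(); ++i) {
      xmin = std::min(xmin, h[i].x); xmax = std::max(xmax, h[i].x);
      ymin = std::min(ymin, h[i].y); ymax = std::max(ymax, h[i].y);
    }
    long long cnt = 0;
    for (int x = xmin; x <= xmax; ++x)
      for (int y = ymin; y <= ymax; ++y) {
        bool inside = true;
        for (size_t i = 0; i < h.size() && inside; ++i) {
          const Pt& a = h[i];
          const Pt& b = h[(i + 1) % h.size()];
          // hull is counter-clockwise: inside means cross >= 0
          if ((long long)(b.x - a.x) * (y - a.y) -
              (long long)(b.y - a.y) * (x - a.x) < 0) inside = false;
        }
        if (inside) ++cnt;
      }
    return (double)std::max(cnt, (long long)n);
  };

  std::vector<int> stamp(npix, 0);
  std::vector<Pt> pts;
  for (int o = 1; o <= nlab; ++o) {
    const int n = counts[o];
    double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
    double fs = 0, fss = 0, bs = 0, bss = 0;
    int bn = 0;
    int rmin = nr, rmax = -1, cmin = nc, cmax = -1;
    pts.clear();
    for (int q = offset[o]; q < offset[o + 1]; ++q) {
      const int p = bucket[q];
      const int i = p % nr, j = p / nr;
      pts.push_back(Pt{i, j});
      sx += i; sy += j;
      sxx += double(i) * i; syy += double(j) * j; sxy += double(i) * j;
      const double v = image[p];
      fs += v; fss += v * v;
      if (i < rmin) rmin = i;
      if (i > rmax) rmax = i;
      if (j < cmin) cmin = j;
      if (j > cmax) cmax = j;
      for (size_t k = 0; k < ddi.size(); ++k) {
        const int ii = i + ddi[k], jj = j + ddj[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        const int p2 = ii + jj * nr;
        if (mask[p2] != 0 || stamp[p2] == o) continue;
        stamp[p2] = o;
        const double b = image[p2];
        bs += b; bss += b * b; ++bn;
      }
    }
    double ecc = 0;
    if (n >= 2) {
      const double mxx = sxx / n - (sx / n) * (sx / n);
      const double myy = syy / n - (sy / n) * (sy / n);
      const double mxy = sxy / n - (sx / n) * (sy / n);
      const double tr = mxx + myy;
      if (tr > 0) {
        double disc = tr * tr / 4.0 - (mxx * myy - mxy * mxy);
        if (disc < 0) disc = 0;
        const double l1 = tr / 2.0 + std::sqrt(disc);
        const double l2 = tr / 2.0 - std::sqrt(disc);
        double e2 = l1 > 0 ? 1.0 - l2 / l1 : 0.0;
        if (e2 < 0) e2 = 0;
        ecc = std::sqrt(e2);
      }
    }
    const double fmean = n > 0 ? fs / n : 0;
    const double fvar = n > 1 ? (fss - n * fmean * fmean) / (n - 1) : 0;
    const double bmean = bn > 0 ? bs / bn : 0;
    const double bvar = bn > 1 ? (bss - bn * bmean * bmean) / (bn - 1) : 0;
    out(o - 1, 0) = n;
    out(o - 1, 1) = ecc;
    out(o - 1, 2) = rmin + 1;  // 1-based
    out(o - 1, 3) = rmax + 1;
    out(o - 1, 4) = cmin + 1;
    out(o - 1, 5) = cmax + 1;
    out(o - 1, 6) = fmean;
    out(o - 1, 7) = fvar > 0 ? std::sqrt(fvar) : 0;
    out(o - 1, 8) = bmean;
    out(o - 1, 9) = bvar > 0 ? std::sqrt(bvar) : 0;
    out(o - 1, 10) = n > 0 ? sx / n + 1 : NA_REAL;
    out(o - 1, 11) = n > 0 ? sy / n + 1 : NA_REAL;
    out(o - 1, 12) = hull_pixel_area(pts);
  }
  return out;
}
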