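#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Spiking cortical model with single-shot (fire-once) neurons.
//
// Per iteration n (E holds E(n-1) on entry):
//   U(n) = f*U(n-1) + S * sum_kl W_kl * Y_kl(n-1) + S
//   Y(n) = 1  if U(n) > E(n-1) and the neuron has not fired yet
//   E(n) = g*E(n-1) + h*Y(n)
// Fired neurons are frozen: Y stays 0 afterwards, U/E no longer updated.
// The time matrix records each pixel's first-firing iteration;
// pixels that never fire within max_iter get sentinel = max_iter + 1.

// [[Rcpp::export]]
IntegerMatrix scm_time_matrix_cpp(NumericMatrix S, double f, double g, double h,
                                  NumericMatrix W, int max_iter) {
  const int nr = S.nrow(), nc = S.ncol(), npix = nr * nc;
  std::vector<double> U(npix, 0.0), E(npix, 1.0);
  std::vector<unsigned char> Yprev(npix, 0), Ycur(npix, 0), fired(npix, 0);
  IntegerMatrix tm(nr, nc);
  std::fill(tm.begin(), tm.end(), max_iter + 1);
  int n_unfired = npix;

  for (int n = 1; n <= max_iter && n_unfired > 0; ++n) {
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        const int idx = i + j * nr;
        if (fired[idx]) { Ycur[idx] = 0; continue; }
        double nb = 0.0;
        for (int dj = -1; dj <= 1; ++dj) {
          const int jj = j + dj;
          if (jj < 0 || jj >= nc) continue;
          for (int di = -1; di <= 1; ++di) {
            const int ii = i + di;
            if (ii < 0 || ii >= nr) continue;
            if (Yprev[ii + jj * nr]) nb += W(di + 1, dj + 1);
          }
        }
        const double s = S(i, j);
        const double u = f * U[idx] + s * nb + s;
        U[idx] = u;
        if (u > E[idx]) {
          Ycur[idx] = 1;
          fired[idx] = 1;
          tm(i, j) = n;
          E[idx] = g * E[idx] + h;
          --n_unfired;
        } else {
          Ycur[idx] = 0;
          E[idx] = g * E[idx];
        }
      }
    }
    std::swap(Yprev, Ycur);
  }
  return tm;
}

static inline void offsets_for(int connectivity, std::vector<int>& di,
                               std::vector<int>& dj) {
  if (connectivity == 4) {
    di = { -1, 1, 0, 0 };
    dj = { 0, 0, -1, 1 };
  } else {
    di = { -1, 1, 0, 0, -1, -1, 1, 1 };
    dj = { 0, 0, -1, 1, -1, 1, -1, 1 };
  }
}

// Connected-component labelling of a binary mask (4- or 8-connectivity).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> di, dj;
  offsets_for(connectivity, di, dj);
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j0 = 0; j0 < nc; ++j0) {
    for (int i0 = 0; i0 < nr; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0)) continue;
      lab(i0, j0) = ++next;
      stack.push_back(i0 + j0 * nr);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int i = p % nr, j = p / nr;
        for (size_t k = 0; k < di.size(); ++k) {
          const int ii = i + di[k], jj = j + dj[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && !lab(ii, jj)) {
            lab(ii, jj) = next;
            stack.push_back(ii + jj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Regional minima of an integer-valued surface: connected plateaus of equal
// value none of whose outside neighbours is lower. Pixels at >= exclude_from
// (the sentinel) are never part of a minimum. Returns labelled seed plateaus.
// [[Rcpp::export]]
IntegerMatrix regional_minima_cpp(IntegerMatrix tm, int exclude_from,
                                  int connectivity) {
  const int nr = tm.nrow(), nc = tm.ncol();
  std::vector<int> di, dj;
  offsets_for(connectivity, di, dj);
  IntegerMatrix lab(nr, nc);
  std::vector<unsigned char> visited(nr * nc, 0);
  std::vector<int> plateau, stack;
  int next = 0;
  for (int j0 = 0; j0 < nc; ++j0) {
    for (int i0 = 0; i0 < nr; ++i0) {
      const int p0 = i0 + j0 * nr;
      if (visited[p0] || tm(i0, j0) >= exclude_from) continue;
      const int v = tm(i0, j0);
      bool is_min = true;
      plateau.clear();
      stack.clear();
      visited[p0] = 1;
      stack.push_back(p0);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        plateau.push_back(p);
        const int i = p % nr, j = p / nr;
        for (size_t k = 0; k < di.size(); ++k) {
          const int ii = i + di[k], jj = j + dj[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          const int w = tm(ii, jj);
          if (w < v) { is_min = false; continue; }
          if (w == v && !visited[ii + jj * nr]) {
            visited[ii + jj * nr] = 1;
            stack.push_back(ii + jj * nr);
          }
        }
      }
      if (is_min) {
        ++next;
        for (size_t k = 0; k < plateau.size(); ++k)
          lab[plateau[k]] = next;
      }
    }
  }
  return lab;
}

struct ObjStats {
  double n = 0, sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  void add(int i, int j) {
    n += 1; sx += i; sy += j; sxx += double(i) * i;
    syy += double(j) * j; sxy += double(i) * j;
  }
  double ecc() const {
    if (n < 2) return 0.0;
    const double mxx = sxx / n - (sx / n) * (sx / n);
    const double myy = syy / n - (sy / n) * (sy / n);
    const double mxy = sxy / n - (sx / n) * (sy / n);
    const double tr = mxx + myy;
    if (tr <= 0) return 0.0;
    double disc = tr * tr / 4.0 - (mxx * myy - mxy * mxy);
    if (disc < 0) disc = 0;
    const double l1 = tr / 2.0 + std::sqrt(disc);
    const double l2 = tr / 2.0 - std::sqrt(disc);
    if (l1 <= 0) return 0.0;
    double e2 = 1.0 - l2 / l1;
    if (e2 < 0) e2 = 0;
    return std::sqrt(e2);
  }
};

// Grow labelled seeds over the time matrix. At each pulse level t (ascending)
// every still-active object annexes, breadth-first, the unassigned adjacent
// pixels with tm <= t. If annexing a level would push the object past
// area_limit or eccentricity_limit the whole level is reverted for that
// object and it stops growing. Objects never merge; pixels at or beyond the
// sentinel are never annexed.
// [[Rcpp::export]]
IntegerMatrix grow_mask_cpp(IntegerMatrix tm, IntegerMatrix seeds, int sentinel,
                            double area_limit, double ecc_limit,
                            int connectivity) {
  const int nr = tm.nrow(), nc = tm.ncol();
  std::vector<int> di, dj;
  offsets_for(connectivity, di, dj);

  int nlab = 0;
  for (int k = 0; k < nr * nc; ++k) nlab = std::max(nlab, seeds[k]);
  IntegerMatrix lab = clone(seeds);

  std::vector<ObjStats> st(nlab + 1);
  std::vector<std::vector<int> > pix(nlab + 1);
  std::vector<unsigned char> active(nlab + 1, 1);
  int tmax = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      const int o = lab(i, j);
      if (o > 0) {
        st[o].add(i, j);
        pix[o].push_back(i + j * nr);
      }
      if (tm(i, j) < sentinel && tm(i, j) > tmax) tmax = tm(i, j);
    }
  // a seed already past the limits cannot grow
  for (int o = 1; o <= nlab; ++o)
    if (st[o].n >= area_limit || st[o].ecc() > ecc_limit) active[o] = 0;

  std::vector<int> queue, annexed;
  for (int t = 1; t <= tmax; ++t) {
    for (int o = 1; o <= nlab; ++o) {
      if (!active[o]) continue;
      const ObjStats saved = st[o];
      const size_t npix_before = pix[o].size();
      annexed.clear();
      queue.clear();
      // frontier: unassigned neighbours of current object pixels at <= t
      for (size_t q = 0; q < pix[o].size(); ++q) {
        const int i = pix[o][q] % nr, j = pix[o][q] / nr;
        for (size_t k = 0; k < di.size(); ++k) {
          const int ii = i + di[k], jj = j + dj[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (lab(ii, jj) == 0 && tm(ii, jj) <= t && tm(ii, jj) < sentinel)
            queue.push_back(ii + jj * nr);
        }
      }
      bool violated = false;
      size_t head = 0;
      while (head < queue.size()) {
        const int p = queue[head++];
        if (lab[p] != 0) continue;
        const int i = p % nr, j = p / nr;
        lab[p] = o;
        st[o].add(i, j);
        pix[o].push_back(p);
        annexed.push_back(p);
        if (st[o].n > area_limit) { violated = true; break; }
        for (size_t k = 0; k < di.size(); ++k) {
          const int ii = i + di[k], jj = j + dj[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (lab(ii, jj) == 0 && tm(ii, jj) <= t && tm(ii, jj) < sentinel)
            queue.push_back(ii + jj * nr);
        }
      }
      if (!violated && st[o].ecc() > ecc_limit) violated = true;
      if (violated) {
        for (size_t k = 0; k < annexed.size(); ++k) lab[annexed[k]] = 0;
        st[o] = saved;
        pix[o].resize(npix_before);
        active[o] = 0;
      }
    }
  }
  return lab;
}

// Per-label pixel counts, centroids and moment eccentricity of a label mask.
// Returns a matrix with one row per label 1..max(labels):
// columns area, ecc, cx(row), cy(col).
// [[Rcpp::export]]
NumericMatrix label_shape_stats_cpp(IntegerMatrix lab) {
  int nlab = 0;
  for (int k = 0; k < lab.nrow() * lab.ncol(); ++k)
    nlab = std::max(nlab, lab[k]);
  std::vector<ObjStats> st(nlab + 1);
  for (int j = 0; j < lab.ncol(); ++j)
    for (int i = 0; i < lab.nrow(); ++i)
      if (lab(i, j) > 0) st[lab(i, j)].add(i, j);
  NumericMatrix out(nlab, 4);
  colnames(out) = CharacterVector::create("area", "ecc", "cx", "cy");
  for (int o = 1; o <= nlab; ++o) {
    out(o - 1, 0) = st[o].n;
    out(o - 1, 1) = st[o].ecc();
    out(o - 1, 2) = st[o].n > 0 ? st[o].sx / st[o].n + 1 : NA_REAL;  // 1-based
    out(o - 1, 3) = st[o].n > 0 ? st[o].sy / st[o].n + 1 : NA_REAL;
  }
  return out;
}
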