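#include <Rcpp.h>
using namespace Rcpp;

// Intersecting cortical model iteration loop.
//
// Per step, using the previous pulse image Y and previous threshold E:
//   F' = f * F + S + (W correlated with Y, zero padded)
//   Y' = (F' > E) ? 1 : 0          (strict inequality; ties do not fire)
//   E' = g * E + h * Y'
// Returns the pulse image after n iterations (and, optionally, the pulse
// image at every iteration).
//
// [[Rcpp::export]]
List icm_run_cpp(NumericMatrix s, double f, double g, double h, int n,
                 double e_init, NumericMatrix w, bool history) {
  const int nr = s.nrow(), nc = s.ncol();
  NumericMatrix F(nr, nc), E(nr, nc);
  IntegerMatrix Y(nr, nc);
  std::fill(E.begin(), E.end(), e_init);

  List hist(history ? n : 0);
  bool any_fired = false;

  for (int it = 0; it < n; ++it) {
    // F' = f*F + S + link input from previous Y
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i)
        F(i, j) = f * F(i, j) + s(i, j);
    if (any_fired) {
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          double acc = 0.0;
          for (int a = -1; a <= 1; ++a) {
            const int ii = i + a;
            if (ii < 0 || ii >= nr) continue;
            for (int b = -1; b <= 1; ++b) {
              const int jj = j + b;
              if (jj < 0 || jj >= nc) continue;
              const double wv = w(a + 1, b + 1);
              if (wv != 0.0 && Y(ii, jj))
                acc += wv;
            }
          }
          F(i, j) += acc;
        }
      }
    }
    // pulse against the previous threshold, then decay/push the threshold
    any_fired = false;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        const int y = (F(i, j) > E(i, j)) ? 1 : 0;
        Y(i, j) = y;
        E(i, j) = g * E(i, j) + h * y;
        if (y) any_fired = true;
      }
    }
    if (history) {
      NumericMatrix snap(nr, nc);
      for (int k = 0; k < nr * nc; ++k) snap[k] = Y[k];
      hist[it] = snap;
    }
  }

  NumericMatrix mask(nr, nc);
  for (int k = 0; k < nr * nc; ++k) mask[k] = Y[k];
  return List::create(_["mask"] = mask, _["history"] = hist);
}

// Connected-component labelling of a binary mask (4- or 8-connectivity).
// Labels are assigned in order of first encounter in column-major scan;
// background pixels get 0.
//
// [[Rcpp::export]]
IntegerMatrix region_label_cpp(NumericMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol(), n = nr * nc;
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(256);
  int next = 0;
  const bool diag = (connectivity == 8);
  for (int k = 0; k < n; ++k) {
    if (mask[k] == 0.0 || lab[k] != 0) continue;
    ++next;
    lab[k] = next;
    stack.push_back(k);
    while (!stack.empty()) {
      const int p = stack.back();
      stack.pop_back();
      const int i = p % nr, j = p / nr;
      for (int a = -1; a <= 1; ++a) {
        const int ii = i + a;
        if (ii < 0 || ii >= nr) continue;
        for (int b = -1; b <= 1; ++b) {
          if (a == 0 && b == 0) continue;
          if (!diag && a != 0 && b != 0) continue;
          const int jj = j + b;
          if (jj < 0 || jj >= nc) continue;
          const int q = jj * nr + ii;
          if (mask[q] != 0.0 && lab[q] == 0) {
            lab[q] = next;
            stack.push_back(q);
          }
        }
      }
    }
  }
  return lab;
}

// Feature-level mask refinement in one pass: label regions (4- or
// 8-connectivity), drop regions touching the border band, regions whose
// minimum original-frame intensity exceeds `threshold` (no head-dark core)
// and regions smaller than `min_area`, and return the reassembled mask.
//
// [[Rcpp::export]]
NumericMatrix refine_mask_cpp(NumericMatrix mask, NumericMatrix image,
                              int connectivity, int border_margin,
                              double threshold, int min_area) {
  const int nr = mask.nrow(), nc = mask.ncol(), n = nr * nc;
  IntegerMatrix lab = region_label_cpp(mask, connectivity);
  int nlab = 0;
  for (int k = 0; k < n; ++k) nlab = std::max(nlab, lab[k]);
  NumericMatrix out(nr, nc);
  if (nlab == 0) return out;

  std::vector<double> vmin(nlab + 1, 1e300);
  std::vector<int> area(nlab + 1, 0);
  std::vector<char> border(nlab + 1, 0);
  for (int j = 0; j < nc; ++j) {
    const bool jb = (j < border_margin) || (j >= nc - border_margin);
    for (int i = 0; i < nr; ++i) {
      const int l = lab(i, j);
      if (l == 0) continue;
      if (image(i, j) < vmin[l]) vmin[l] = image(i, j);
      ++area[l];
      if (jb || i < border_margin || i >= nr - border_margin) border[l] = 1;
    }
  }
  std::vector<char> keep(nlab + 1, 0);
  for (int l = 1; l <= nlab; ++l) {
    keep[l] = !border[l] && vmin[l] <= threshold && area[l] >= min_area;
  }
  for (int k = 0; k < n; ++k) {
    if (lab[k] != 0 && keep[lab[k]]) out[k] = 1.0;
  }
  return out;
}
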