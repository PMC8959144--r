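#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

//' 8-connected component labelling of a binary image.
//'
//' Two-pass union-find labelling; labels are consecutive integers starting
//' at 1, assigned in raster order of each component's first pixel.
//' Background (FALSE/0) maps to 0.
//'
//' @param mask logical or numeric matrix; non-zero is foreground.
//' @return integer matrix of the same shape with component labels.
//' @keywords internal
// [[Rcpp::export(name = ".label_components8")]]
IntegerMatrix label_components8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(1024);
  parent.push_back(0); // label 0 = background sentinel

  // Column-major scan; for each foreground pixel look at the four
  // already-visited 8-neighbours: (r-1,c-1), (r,c-1), (r+1,c-1), (r-1,c).
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int neigh[4];
      int nn = 0;
      if (c > 0) {
        if (r > 0 && lab(r - 1, c - 1)) neigh[nn++] = lab(r - 1, c - 1);
        if (lab(r, c - 1)) neigh[nn++] = lab(r, c - 1);
        if (r + 1 < nr && lab(r + 1, c - 1)) neigh[nn++] = lab(r + 1, c - 1);
      }
      if (r > 0 && lab(r - 1, c)) neigh[nn++] = lab(r - 1, c);
      if (nn == 0) {
        int newlab = (int)parent.size();
        parent.push_back(newlab);
        lab(r, c) = newlab;
      } else {
        int m = neigh[0];
        for (int i = 1; i < nn; ++i) m = std::min(m, neigh[i]);
        lab(r, c) = m;
        for (int i = 0; i < nn; ++i) uf_union(parent, m, neigh[i]);
      }
    }
  }

  // Resolve equivalences and renumber consecutively.
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c)) {
        int root = uf_find(parent, lab(r, c));
        if (!remap[root]) remap[root] = ++next;
        lab(r, c) = remap[root];
      }
  return lab;
}

//' Boundary-following perimeter of each labelled component.
//'
//' Moore-neighbour (8-connected) boundary tracing from each component's
//' first pixel in raster order; the contour length counts 1 for
//' axis-parallel steps and sqrt(2) for diagonal steps. Single-pixel
//' components are assigned a perimeter of 4 (their bounding-square
//' contour), matching common particle-analysis conventions.
//'
//' @param lab integer matrix of component labels (0 = background).
//' @param nlab number of labels.
//' @return numeric vector of perimeters, one per label.
//' @keywords internal
// [[Rcpp::export(name = ".trace_perimeters")]]
NumericVector trace_perimeters(IntegerMatrix lab, int nlab) {
  const int nr = lab.nrow(), nc = lab.ncol();
  NumericVector per(nlab, 0.0);
  std::vector<int> startr(nlab, -1), startc(nlab, -1);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l > 0 && startr[l - 1] < 0) { startr[l - 1] = r; startc[l - 1] = c; }
    }

  // Moore neighbourhood in clockwise order starting from W.
  const int dr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const double step[8] = {1, M_SQRT2, 1, M_SQRT2, 1, M_SQRT2, 1, M_SQRT2};

  for (int l = 0; l < nlab; ++l) {
    int r0 = startr[l], c0 = startc[l];
    if (r0 < 0) continue;
    // Detect isolated pixel.
    bool isolated = true;
    for (int k = 0; k < 8; ++k) {
      int rr = r0 + dr[k], cc = c0 + dc[k];
      if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && lab(rr, cc) == l + 1) {
        isolated = false;
        break;
      }
    }
    if (isolated) { per[l] = 4.0; continue; }

    // Moore boundary tracing; stop when the (pixel, move-direction) state
    // of the first step repeats, which closes the contour exactly once.
    int r = r0, c = c0;
    int backtrack = 0; // scan order guarantees the W neighbour is background
    double length = 0.0;
    int first_r = -1, first_c = -1, first_dir = -1;
    long guard = 0, guardmax = 8L * (long)nr * (long)nc;
    while (++guard <= guardmax) {
      int k = (backtrack + 1) % 8;
      int found = -1;
      for (int i = 0; i < 8; ++i) {
        int kk = (k + i) % 8;
        int rr = r + dr[kk], cc = c + dc[kk];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && lab(rr, cc) == l + 1) {
          found = kk;
          break;
        }
      }
      if (found < 0) break; // unreachable: isolated handled above
      if (first_dir < 0) {
        first_r = r; first_c = c; first_dir = found;
      } else if (r == first_r && c == first_c && found == first_dir) {
        break; // contour closed
      }
      r += dr[found];
      c += dc[found];
      length += step[found];
      backtrack = (found + 4) % 8;
    }
    per[l] = length;
  }
  return per;
}

//' Per-label pixel statistics for detected objects.
//'
//' @param lab integer label matrix.
//' @param img numeric intensity matrix of the same shape.
//' @param nlab number of labels.
//' @return list with per-label area, centroid row/col (1-based), and
//'   mean intensity.
//' @keywords internal
// [[Rcpp::export(name = ".component_stats")]]
List component_stats(IntegerMatrix lab, NumericMatrix img, int nlab) {
  NumericVector area(nlab), sumr(nlab), sumc(nlab), sumi(nlab);
  const int nr = lab.nrow(), nc = lab.ncol();
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l > 0) {
        area[l - 1] += 1;
        sumr[l - 1] += r + 1;
        sumc[l - 1] += c + 1;
        sumi[l - 1] += img(r, c);
      }
    }
  NumericVector cr(nlab), cc(nlab), mi(nlab);
  for (int l = 0; l < nlab; ++l) {
    cr[l] = sumr[l] / area[l];
    cc[l] = sumc[l] / area[l];
    mi[l] = sumi[l] / area[l];
  }
  return List::create(_["area"] = area, _["centroid_row"] = cr,
                      _["centroid_col"] = cc, _["mean_intensity"] = mi);
}
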