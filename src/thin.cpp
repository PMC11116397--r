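#include <Rcpp.h>
using namespace Rcpp;

// Guo-Hall topology-preserving thinning of a binary mask.
// Two sub-iterations per pass; repeats until stable. Input and output are
// integer matrices in {0,1}; the skeleton is 8-connected and one pixel wide
// except at junctions.

static inline int px(const IntegerMatrix &m, int i, int j) {
  if (i < 0 || j < 0 || i >= m.nrow() || j >= m.ncol()) return 0;
  return m(i, j);
}

// [[Rcpp::export(name = ".thin_guo_hall")]]
IntegerMatrix thin_guo_hall(IntegerMatrix mask) {
  IntegerMatrix im = clone(mask);
  int nr = im.nrow(), nc = im.ncol();
  IntegerMatrix del(nr, nc);
  bool changed = true;
  while (changed) {
    changed = false;
    for (int iter = 0; iter < 2; ++iter) {
      for (int i = 0; i < nr; ++i) {
        for (int j = 0; j < nc; ++j) {
          del(i, j) = 0;
          if (!im(i, j)) continue;
          // neighbours: p2 up, p3 up-right, p4 right, p5 down-right,
          //             p6 down, p7 down-left, p8 left, p9 up-left
          int p2 = px(im, i, j - 1);
          int p3 = px(im, i + 1, j - 1);
          int p4 = px(im, i + 1, j);
          int p5 = px(im, i + 1, j + 1);
          int p6 = px(im, i, j + 1);
          int p7 = px(im, i - 1, j + 1);
          int p8 = px(im, i - 1, j);
          int p9 = px(im, i - 1, j - 1);
          int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                  ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          int N = N1 < N2 ? N1 : N2;
          int m = iter == 0 ? ((p6 | p7 | (!p9)) & p8)
                            : ((p2 | p3 | (!p5)) & p4);
          if (C == 1 && N >= 2 && N <= 3 && m == 0) del(i, j) = 1;
        }
      }
      for (int i = 0; i < nr; ++i)
        for (int j = 0; j < nc; ++j)
          if (del(i, j)) { im(i, j) = 0; changed = true; }
    }
  }
  return im;
}

// Count of 8-neighbours on the skeleton for every skeleton pixel (0 elsewhere).
// [[Rcpp::export(name = ".skel_neighbour_count")]]
IntegerMatrix skel_neighbour_count(IntegerMatrix skel) {
  int nr = skel.nrow(), nc = skel.ncol();
  IntegerMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!skel(i, j)) { out(i, j) = 0; continue; }
      int n = 0;
      for (int di = -1; di <= 1; ++di)
        for (int dj = -1; dj <= 1; ++dj)
          if ((di || dj) && px(skel, i + di, j + dj)) ++n;
      out(i, j) = n;
    }
  }
  return out;
}
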