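#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Draw worms as filled capsules (thick segments with round caps) on a binary
// image. Positions are continuous (x = column, y = row, 1-based pixel
// centres); worms whose capsule leaves the image are clipped.
// [[Rcpp::export]]
IntegerMatrix cpp_render_worms(NumericVector x, NumericVector y,
                               NumericVector heading, double len,
                               double width, int nrow, int ncol) {
  IntegerMatrix img(nrow, ncol);
  const double half = (len - width) / 2.0; // capsule axis half-length
  const double rad = width / 2.0;
  const double rad2 = rad * rad;
  for (int w = 0; w < x.size(); ++w) {
    double dx = std::cos(heading[w]), dy = std::sin(heading[w]);
    double ax = x[w] - half * dx, ay = y[w] - half * dy;
    double bx = x[w] + half * dx, by = y[w] + half * dy;
    int c0 = std::max(0, (int)std::floor(std::min(ax, bx) - rad) - 1);
    int c1 = std::min(ncol - 1, (int)std::ceil(std::max(ax, bx) + rad));
    int r0 = std::max(0, (int)std::floor(std::min(ay, by) - rad) - 1);
    int r1 = std::min(nrow - 1, (int)std::ceil(std::max(ay, by) + rad));
    double abx = bx - ax, aby = by - ay;
    double ab2 = abx * abx + aby * aby;
    for (int r = r0; r <= r1; ++r) {
      for (int c = c0; c <= c1; ++c) {
        double px = c + 1.0, py = r + 1.0; // pixel centre, 1-based
        double t = 0.0;
        if (ab2 > 0) {
          t = ((px - ax) * abx + (py - ay) * aby) / ab2;
          if (t < 0) t = 0; else if (t > 1) t = 1;
        }
        double qx = ax + t * abx - px, qy = ay + t * aby - py;
        if (qx * qx + qy * qy <= rad2) img(r, c) = 1;
      }
    }
  }
  return img;
}

// Adaptive local threshold: foreground iff img > (local mean in a
// window x window box) + offset. Box mean via integral image with
// truncation at the borders.
// [[Rcpp::export]]
IntegerMatrix cpp_box_threshold(NumericMatrix img, int window, double offset) {
  int nr = img.nrow(), nc = img.ncol();
  int h = window / 2;
  std::vector<double> sat((nr + 1) * (nc + 1), 0.0);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      sat[(r + 1) + (c + 1) * (nr + 1)] =
        img(r, c) + sat[r + (c + 1) * (nr + 1)] + sat[(r + 1) + c * (nr + 1)] -
        sat[r + c * (nr + 1)];
    }
  }
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    int cl = std::max(0, c - h), cr = std::min(nc - 1, c + h);
    for (int r = 0; r < nr; ++r) {
      int rt = std::max(0, r - h), rb = std::min(nr - 1, r + h);
      double s = sat[(rb + 1) + (cr + 1) * (nr + 1)] -
                 sat[rt + (cr + 1) * (nr + 1)] -
                 sat[(rb + 1) + cl * (nr + 1)] + sat[rt + cl * (nr + 1)];
      double mean = s / ((rb - rt + 1) * (cr - cl + 1));
      out(r, c) = img(r, c) > mean + offset ? 1 : 0;
    }
  }
  return out;
}

// 8-connected component labelling of a binary image, returning per-blob
// area, centroid, pixel set and boundary pixel set (pixels with at least one
// 8-neighbour outside the component or on the image edge). Components with
// area < min_area are discarded. Coordinates returned 1-based (row, col).
// [[Rcpp::export]]
List cpp_label8(IntegerMatrix bin, double min_area) {
  int nr = bin.nrow(), nc = bin.ncol();
  std::vector<int> lab(nr * nc, 0);
  int nlab = 0;
  std::vector<int> stack;
  std::vector<std::vector<int> > comp_r, comp_c;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int idx = r + c * nr;
      if (bin(r, c) != 0 && lab[idx] == 0) {
        ++nlab;
        comp_r.push_back(std::vector<int>());
        comp_c.push_back(std::vector<int>());
        lab[idx] = nlab;
        stack.clear();
        stack.push_back(idx);
        while (!stack.empty()) {
          int cur = stack.back();
          stack.pop_back();
          int cr = cur % nr, cc = cur / nr;
          comp_r[nlab - 1].push_back(cr);
          comp_c[nlab - 1].push_back(cc);
          for (int k = 0; k < 8; ++k) {
            int r2 = cr + dr[k], c2 = cc + dc[k];
            if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc) {
              int idx2 = r2 + c2 * nr;
              if (bin(r2, c2) != 0 && lab[idx2] == 0) {
                lab[idx2] = nlab;
                stack.push_back(idx2);
              }
            }
          }
        }
      }
    }
  }
  // collect blobs passing the area filter
  std::vector<int> keep;
  for (int i = 0; i < nlab; ++i)
    if ((double)comp_r[i].size() >= min_area) keep.push_back(i);
  int nb = keep.size();
  IntegerVector area(nb);
  NumericVector cx(nb), cy(nb);
  List pixels(nb), boundary(nb);
  for (int b = 0; b < nb; ++b) {
    int i = keep[b];
    int n = comp_r[i].size();
    area[b] = n;
    double sx = 0, sy = 0;
    IntegerMatrix px(n, 2);
    std::vector<int> br, bc;
    for (int j = 0; j < n; ++j) {
      int r = comp_r[i][j], c = comp_c[i][j];
      px(j, 0) = r + 1;
      px(j, 1) = c + 1;
      sx += c + 1;
      sy += r + 1;
      bool edge = false;
      for (int k = 0; k < 8 && !edge; ++k) {
        int r2 = r + dr[k], c2 = c + dc[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc || bin(r2, c2) == 0)
          edge = true;
      }
      if (edge) { br.push_back(r + 1); bc.push_back(c + 1); }
    }
    cx[b] = sx / n;
    cy[b] = sy / n;
    IntegerMatrix bd(br.size(), 2);
    for (size_t j = 0; j < br.size(); ++j) { bd(j, 0) = br[j]; bd(j, 1) = bc[j]; }
    pixels[b] = px;
    boundary[b] = bd;
  }
  return List::create(_["area"] = area, _["x"] = cx, _["y"] = cy,
                      _["pixels"] = pixels, _["boundary"] = boundary);
}

// Minimum boundary-pixel distances between blobs of two consecutive frames.
// boundA/boundB: lists of (row, col) integer matrices. Returns an edge list
// (from, to, dist) for pairs whose minimum distance <= max_dist. Pairs are
// pre-filtered by bounding-box distance.
// [[Rcpp::export]]
DataFrame cpp_min_dist_edges(List boundA, List boundB, double max_dist) {
  int na = boundA.size(), nb = boundB.size();
  std::vector<int> from, to;
  std::vector<double> dist;
  // bounding boxes
  std::vector<double> ar0(na), ar1(na), ac0(na), ac1(na);
  std::vector<double> br0(nb), br1(nb), bc0(nb), bc1(nb);
  for (int i = 0; i < na; ++i) {
    IntegerMatrix m = boundA[i];
    double r0 = 1e18, r1 = -1e18, c0 = 1e18, c1 = -1e18;
    for (int j = 0; j < m.nrow(); ++j) {
      r0 = std::min(r0, (double)m(j, 0)); r1 = std::max(r1, (double)m(j, 0));
      c0 = std::min(c0, (double)m(j, 1)); c1 = std::max(c1, (double)m(j, 1));
    }
    ar0[i] = r0; ar1[i] = r1; ac0[i] = c0; ac1[i] = c1;
  }
  for (int i = 0; i < nb; ++i) {
    IntegerMatrix m = boundB[i];
    double r0 = 1e18, r1 = -1e18, c0 = 1e18, c1 = -1e18;
    for (int j = 0; j < m.nrow(); ++j) {
      r0 = std::min(r0, (double)m(j, 0)); r1 = std::max(r1, (double)m(j, 0));
      c0 = std::min(c0, (double)m(j, 1)); c1 = std::max(c1, (double)m(j, 1));
    }
    br0[i] = r0; br1[i] = r1; bc0[i] = c0; bc1[i] = c1;
  }
  for (int i = 0; i < na; ++i) {
    IntegerMatrix A = boundA[i];
    for (int j = 0; j < nb; ++j) {
      double gr = std::max(0.0, std::max(br0[j] - ar1[i], ar0[i] - br1[j]));
      double gc = std::max(0.0, std::max(bc0[j] - ac1[i], ac0[i] - bc1[j]));
      if (std::sqrt(gr * gr + gc * gc) > max_dist) continue;
      IntegerMatrix B = boundB[j];
      double best = 1e18;
      for (int p = 0; p < A.nrow(); ++p) {
        for (int q = 0; q < B.nrow(); ++q) {
          double dr = A(p, 0) - B(q, 0), dc = A(p, 1) - B(q, 1);
          double d2 = dr * dr + dc * dc;
          if (d2 < best) best = d2;
        }
        if (best == 0.0) break;
      }
      best = std::sqrt(best);
      if (best <= max_dist) {
        from.push_back(i + 1);
        to.push_back(j + 1);
        dist.push_back(best);
      }
    }
  }
  return DataFrame::create(_["from"] = from, _["to"] = to, _["dist"] = dist);
}

// Per-pixel temporal median of a stack of frames given as a (npix x nframes)
// matrix; returns a numeric vector of length npix.
// [[Rcpp::export]]
NumericVector cpp_row_median(NumericMatrix m) {
  int n = m.nrow(), k = m.ncol();
  NumericVector out(n);
  std::vector<double> buf(k);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) buf[j] = m(i, j);
    std::sort(buf.begin(), buf.end());
    out[i] = (k % 2 == 1) ? buf[k / 2] : 0.5 * (buf[k / 2 - 1] + buf[k / 2]);
  }
  return out;
}

// Fused per-frame segmentation for the synthetic pipeline: renders the
// worms, subtracts the background (positive part), applies the adaptive
// box threshold and labels 8-connected components, all in one pass
// without intermediate R allocations.
// [[Rcpp::export]]
List cpp_segment_rendered(NumericVector x, NumericVector y,
                          NumericVector heading, double len, double width,
                          int nrow, int ncol, NumericMatrix bg, int window,
                          double offset, double min_area) {
  IntegerMatrix img = cpp_render_worms(x, y, heading, len, width, nrow, ncol);
  int nr = nrow, nc = ncol;
  std::vector<double> diff((size_t)nr * nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double d = (double)img(r, c) - bg(r, c);
      diff[r + (size_t)c * nr] = d > 0 ? d : 0;
    }
  // integral image
  std::vector<double> sat(((size_t)nr + 1) * (nc + 1), 0.0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      sat[(r + 1) + (size_t)(c + 1) * (nr + 1)] =
        diff[r + (size_t)c * nr] + sat[r + (size_t)(c + 1) * (nr + 1)] +
        sat[(r + 1) + (size_t)c * (nr + 1)] - sat[r + (size_t)c * (nr + 1)];
  int h = window / 2;
  IntegerMatrix bin(nr, nc);
  for (int c = 0; c < nc; ++c) {
    int cl = std::max(0, c - h), cr = std::min(nc - 1, c + h);
    for (int r = 0; r < nr; ++r) {
      int rt = std::max(0, r - h), rb = std::min(nr - 1, r + h);
      double s = sat[(rb + 1) + (size_t)(cr + 1) * (nr + 1)] -
                 sat[rt + (size_t)(cr + 1) * (nr + 1)] -
                 sat[(rb + 1) + (size_t)cl * (nr + 1)] +
                 sat[rt + (size_t)cl * (nr + 1)];
      double mean = s / ((rb - rt + 1) * (cr - cl + 1));
      bin(r, c) = diff[r + (size_t)c * nr] > mean + offset ? 1 : 0;
    }
  }
  return cpp_label8(bin, min_area);
}
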