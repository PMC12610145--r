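// Low-level image primitives: sliding-window statistics with symmetric
// (reflect) padding, small-kernel convolution, nearest-foreground distances,
// and the full 3-D Hough circle accumulator.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// symmetric reflection: index map for out-of-range i given extent n
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
List cpp_local_stats(const arma::mat& x, int wh, int ww) {
  const int H = x.n_rows, W = x.n_cols;
  const int rh = wh / 2, rw = ww / 2;
  const int m = wh * ww;
  arma::mat mu(H, W), med(H, W), v(H, W);
  std::vector<double> buf(m);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int k = 0;
      double s = 0.0;
      for (int dj = -rw; dj <= rw; ++dj) {
        int cc = reflect_idx(c + dj, W);
        for (int di = -rh; di <= rh; ++di) {
          double val = x(reflect_idx(r + di, H), cc);
          buf[k++] = val;
          s += val;
        }
      }
      double mean = s / m;
      mu(r, c) = mean;
      // shifted two-pass population variance: exactly 0 on constant windows
      const double a = buf[0];
      double ss = 0.0;
      for (int q = 0; q < m; ++q) ss += (buf[q] - a) * (buf[q] - a);
      double var = ss / m - (mean - a) * (mean - a);
      v(r, c) = var > 0.0 ? var : 0.0;
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
      double hi = buf[m / 2];
      if (m % 2 == 1) {
        med(r, c) = hi;
      } else {
        std::nth_element(buf.begin(), buf.begin() + m / 2 - 1, buf.end());
        med(r, c) = 0.5 * (hi + buf[m / 2 - 1]);
      }
    }
  }
  return List::create(_["mean"] = mu, _["median"] = med, _["var"] = v);
}

// true convolution (kernel flipped) with reflect padding; kernel odd x odd
// [[Rcpp::export]]
arma::mat cpp_convolve_reflect(const arma::mat& x, const arma::mat& k) {
  const int H = x.n_rows, W = x.n_cols;
  const int kh = k.n_rows, kw = k.n_cols;
  const int ch = kh / 2, cw = kw / 2;
  arma::mat out(H, W, arma::fill::zeros);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double acc = 0.0;
      for (int j = 0; j < kw; ++j) {
        int cc = reflect_idx(c - (j - cw), W);
        for (int i = 0; i < kh; ++i)
          acc += k(i, j) * x(reflect_idx(r - (i - ch), H), cc);
      }
      out(r, c) = acc;
    }
  return out;
}

// for each row of `from` (r,c coords), Euclidean distance to nearest row of `to`
// [[Rcpp::export]]
arma::vec cpp_nearest_dist(const arma::mat& from, const arma::mat& to) {
  const int n = from.n_rows, m = to.n_rows;
  arma::vec out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double r = from(i, 0), c = from(i, 1);
    for (int j = 0; j < m; ++j) {
      double dr = r - to(j, 0), dc = c - to(j, 1);
      double d2 = dr * dr + dc * dc;
      if (d2 < best) best = d2;
    }
    out(i) = std::sqrt(best);
  }
  return out;
}

// Full 3-D accumulator Hough circle transform. Each edge pixel votes for every
// center at (rounded) integer distance r in [rmin, rmax]. Peaks are cells that
// reach min_votes[r - rmin] and are maximal over their 3x3x3 neighbourhood,
// ordered by votes (desc), then radius (asc), then row, then col (1-based).
// [[Rcpp::export]]
DataFrame cpp_hough(const arma::umat& edges, int rmin, int rmax,
                    const arma::vec& min_votes) {
  const int H = edges.n_rows, W = edges.n_cols;
  const int nr = rmax - rmin + 1;
  // offsets per radius: all (di,dj) with round(hypot) == r
  std::vector<std::vector<std::pair<int, int> > > offs(nr);
  for (int dj = -rmax; dj <= rmax; ++dj)
    for (int di = -rmax; di <= rmax; ++di) {
      int rr = (int)std::lround(std::sqrt((double)(di * di + dj * dj)));
      if (rr >= rmin && rr <= rmax)
        offs[rr - rmin].push_back(std::make_pair(di, dj));
    }
  std::vector<arma::Mat<int> > acc(nr, arma::Mat<int>(H, W, arma::fill::zeros));
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (!edges(r, c)) continue;
      for (int k = 0; k < nr; ++k) {
        arma::Mat<int>& A = acc[k];
        const std::vector<std::pair<int, int> >& o = offs[k];
        for (size_t q = 0; q < o.size(); ++q) {
          int cy = r + o[q].first, cx = c + o[q].second;
          if (cy >= 0 && cy < H && cx >= 0 && cx < W) A(cy, cx)++;
        }
      }
    }
  std::vector<int> prow, pcol, prad, pvot;
  for (int k = 0; k < nr; ++k) {
    const arma::Mat<int>& A = acc[k];
    double thr = min_votes[k];
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        int v = A(r, c);
        if (v < thr || v <= 0) continue;
        bool peak = true;
        for (int dk = -1; dk <= 1 && peak; ++dk) {
          if (k + dk < 0 || k + dk >= nr) continue;
          const arma::Mat<int>& B = acc[k + dk];
          for (int dc = -1; dc <= 1 && peak; ++dc)
            for (int dr = -1; dr <= 1; ++dr) {
              if (dr == 0 && dc == 0 && dk == 0) continue;
              int rr = r + dr, cc = c + dc;
              if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
              if (B(rr, cc) > v) { peak = false; break; }
            }
        }
        if (peak) {
          prow.push_back(r + 1);
          pcol.push_back(c + 1);
          prad.push_back(k + rmin);
          pvot.push_back(v);
        }
      }
  }
  // order: votes desc, radius asc, row asc, col asc
  std::vector<size_t> idx(prow.size());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](size_t a, size_t b) {
    if (pvot[a] != pvot[b]) return pvot[a] > pvot[b];
    if (prad[a] != prad[b]) return prad[a] < prad[b];
    if (prow[a] != prow[b]) return prow[a] < prow[b];
    return pcol[a] < pcol[b];
  });
  IntegerVector orow(idx.size()), ocol(idx.size()), orad(idx.size()), ovot(idx.size());
  for (size_t i = 0; i < idx.size(); ++i) {
    orow[i] = prow[idx[i]];
    ocol[i] = pcol[idx[i]];
    orad[i] = prad[idx[i]];
    ovot[i] = pvot[idx[i]];
  }
  return DataFrame::create(_["center_row"] = orow, _["center_col"] = ocol,
                           _["radius"] = orad, _["votes"] = ovot);
}
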