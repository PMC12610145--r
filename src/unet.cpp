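// Compact U-Net (encoder/decoder with skip connections) for 1-channel images:
// 3x3 same convolutions + batch norm + ReLU, 2x2 max pooling, 2x2
// up-convolutions, 1x1 sigmoid head, trained against binary masks with MSE
// loss. Forward and backward passes live here; the Adam update runs in R.
//
// Feature maps are arma::cube (H, W, C); batches are std::vector<cube>.
// Convolutions use im2col with zero padding so a layer is one matrix product.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;

static const double BN_EPS = 1e-5;

// transposed im2col layout, (H*W) x (C*9): column q = c*9 + (di+1)*3 + (dj+1)
// holds the (di, dj)-shifted image, so every copy is a contiguous subvector
static mat im2col3(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat cols(H * W, C * 9, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& s = x.slice(c);
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        const int q = c * 9 + (di + 1) * 3 + (dj + 1);
        const int i0 = std::max(0, -di), i1 = H - 1 - std::max(0, di);
        for (int j = 0; j < W; ++j) {
          const int cc = j + dj;
          if (cc < 0 || cc >= W) continue;
          cols.col(q).subvec(j * H + i0, j * H + i1) =
              s.col(cc).subvec(i0 + di, i1 + di);
        }
      }
  }
  return cols;
}

static cube col2im3(const mat& dcols, int H, int W, int C) {
  cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& s = dx.slice(c);
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        const int q = c * 9 + (di + 1) * 3 + (dj + 1);
        const int i0 = std::max(0, -di), i1 = H - 1 - std::max(0, di);
        for (int j = 0; j < W; ++j) {
          const int cc = j + dj;
          if (cc < 0 || cc >= W) continue;
          s.col(cc).subvec(i0 + di, i1 + di) +=
              dcols.col(q).subvec(j * H + i0, j * H + i1);
        }
      }
  }
  return dx;
}

static cube mat2cube(const mat& z, int H, int W) {
  const int C = z.n_rows;
  cube out(H, W, C);
  for (int c = 0; c < C; ++c) out.slice(c) = arma::reshape(z.row(c), H, W);
  return out;
}

static mat cube2mat(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat z(C, H * W);
  for (int c = 0; c < C; ++c) z.row(c) = arma::vectorise(x.slice(c)).t();
  return z;
}

// cache for one conv + batch-norm + ReLU layer
struct LC {
  std::vector<mat> cols;   // im2col of the layer input, per sample
  std::vector<mat> xhat;   // normalized pre-activation
  std::vector<mat> act;    // post-ReLU activation (C x P)
  vec invstd;              // per-channel 1/sqrt(var + eps)
  int H, W, Cin, Cout;
};

struct UNet {
  const List& params;
  List& running;           // BN running stats, mutated when training
  bool training;
  double momentum;

  UNet(const List& p, List& r, bool tr, double mom)
      : params(p), running(r), training(tr), momentum(mom) {}

  mat P(const std::string& nm) const { return as<mat>(params[nm]); }
  vec Pv(const std::string& nm) const { return as<vec>(params[nm]); }

  // conv 3x3 -> BN -> ReLU on a batch; fills cache, returns output cubes
  std::vector<cube> cbr(const std::vector<cube>& xs, const std::string& pre, LC& lc) {
    const int N = xs.size();
    const int H = xs[0].n_rows, W = xs[0].n_cols;
    const mat Wt = P(pre + "_W");
    const vec b = Pv(pre + "_b"), g = Pv(pre + "_g"), be = Pv(pre + "_beta");
    const int Cout = Wt.n_rows;
    const int Pn = H * W;
    lc.H = H; lc.W = W; lc.Cin = xs[0].n_slices; lc.Cout = Cout;
    lc.cols.resize(N); lc.xhat.resize(N); lc.act.resize(N);
    std::vector<mat> z(N);
    for (int n = 0; n < N; ++n) {
      lc.cols[n] = im2col3(xs[n]);
      z[n] = Wt * lc.cols[n].t();
      z[n].each_col() += b;
    }
    vec mean_(Cout), var_(Cout);
    if (training) {
      const double M = (double)N * Pn;
      mean_.zeros(); var_.zeros();
      for (int n = 0; n < N; ++n) mean_ += arma::sum(z[n], 1);
      mean_ /= M;
      for (int n = 0; n < N; ++n) {
        mat d = z[n];
        d.each_col() -= mean_;
        var_ += arma::sum(d % d, 1);
      }
      var_ /= M;
      vec rm = as<vec>(running[pre + "_rm"]), rv = as<vec>(running[pre + "_rv"]);
      running[pre + "_rm"] = wrap((1.0 - momentum) * rm + momentum * mean_);
      running[pre + "_rv"] = wrap((1.0 - momentum) * rv + momentum * var_);
    } else {
      mean_ = as<vec>(running[pre + "_rm"]);
      var_ = as<vec>(running[pre + "_rv"]);
    }
    lc.invstd = 1.0 / arma::sqrt(var_ + BN_EPS);
    std::vector<cube> out(N);
    for (int n = 0; n < N; ++n) {
      mat xh = z[n];
      xh.each_col() -= mean_;
      xh.each_col() %= lc.invstd;
      lc.xhat[n] = xh;
      mat a = xh;
      a.each_col() %= g;
      a.each_col() += be;
      a.transform([](double v) { return v > 0.0 ? v : 0.0; });
      lc.act[n] = a;
      out[n] = mat2cube(a, H, W);
    }
    return out;
  }

  // backward through one cbr layer; returns gradient wrt the layer input
  std::vector<cube> cbr_bwd(const std::vector<mat>& dact, const std::string& pre,
                            const LC& lc, List& grads) {
    const int N = dact.size();
    const mat Wt = P(pre + "_W");
    const vec g = Pv(pre + "_g");
    const int Cout = lc.Cout;
    const double M = (double)N * lc.H * lc.W;
    std::vector<mat> dy(N);
    vec dbeta(Cout, arma::fill::zeros), dg(Cout, arma::fill::zeros);
    vec sum_dxh(Cout, arma::fill::zeros), sum_dxh_xh(Cout, arma::fill::zeros);
    for (int n = 0; n < N; ++n) {
      dy[n] = dact[n];
      // ReLU mask from stored activations
      const mat& a = lc.act[n];
      for (arma::uword k = 0; k < a.n_elem; ++k)
        if (a(k) <= 0.0) dy[n](k) = 0.0;
      dbeta += arma::sum(dy[n], 1);
      dg += arma::sum(dy[n] % lc.xhat[n], 1);
      mat dxh = dy[n];
      dxh.each_col() %= g;
      sum_dxh += arma::sum(dxh, 1);
      sum_dxh_xh += arma::sum(dxh % lc.xhat[n], 1);
    }
    mat dW(arma::size(Wt), arma::fill::zeros);
    vec db(Cout, arma::fill::zeros);
    std::vector<cube> dx(N);
    for (int n = 0; n < N; ++n) {
      mat dxh = dy[n];
      dxh.each_col() %= g;
      mat dz = M * dxh;
      dz.each_col() -= sum_dxh;
      mat t = lc.xhat[n];
      t.each_col() %= sum_dxh_xh;
      dz -= t;
      dz.each_col() %= (lc.invstd / M);
      dW += dz * lc.cols[n];
      db += arma::sum(dz, 1);
      dx[n] = col2im3(dz.t() * Wt, lc.H, lc.W, lc.Cin);
    }
    grads[pre + "_W"] = wrap(dW);
    grads[pre + "_b"] = wrap(db);
    grads[pre + "_g"] = wrap(dg);
    grads[pre + "_beta"] = wrap(dbeta);
    return dx;
  }
};

static std::vector<cube> pool_fwd(const std::vector<cube>& xs,
                                  std::vector<arma::ucube>& argmax) {
  const int N = xs.size();
  const int H = xs[0].n_rows, W = xs[0].n_cols, C = xs[0].n_slices;
  std::vector<cube> out(N);
  argmax.resize(N);
  for (int n = 0; n < N; ++n) {
    out[n].set_size(H / 2, W / 2, C);
    argmax[n].set_size(H / 2, W / 2, C);
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < W / 2; ++j)
        for (int i = 0; i < H / 2; ++i) {
          double best = -1e300;
          unsigned code = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              double v = xs[n](2 * i + di, 2 * j + dj, c);
              if (v > best) { best = v; code = di * 2 + dj; }
            }
          out[n](i, j, c) = best;
          argmax[n](i, j, c) = code;
        }
  }
  return out;
}

static std::vector<cube> pool_bwd(const std::vector<cube>& d,
                                  const std::vector<arma::ucube>& argmax) {
  const int N = d.size();
  const int h = d[0].n_rows, w = d[0].n_cols, C = d[0].n_slices;
  std::vector<cube> dx(N);
  for (int n = 0; n < N; ++n) {
    dx[n].zeros(2 * h, 2 * w, C);
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < w; ++j)
        for (int i = 0; i < h; ++i) {
          unsigned code = argmax[n](i, j, c);
          dx[n](2 * i + code / 2, 2 * j + code % 2, c) = d[n](i, j, c);
        }
  }
  return dx;
}

// 2x2 stride-2 transposed convolution; Wu is (Cout, Cin*4), offset k = di*2+dj.
// Each offset k is one gemm against the (Cout x Cin) weight submatrix, plus a
// scatter/gather over the strided output positions.
struct UpMaps {
  std::vector<mat> Wk;            // per-offset Cout x Cin weights
  std::vector<arma::uvec> colsk;  // columns of Wu per offset
  std::vector<std::vector<arma::uword> > idx; // input pixel -> output element
  int H, W, Cin, Cout, P;
};

static UpMaps up_maps(const mat& Wu, int H, int W, int Cin) {
  UpMaps m;
  m.H = H; m.W = W; m.Cin = Cin; m.Cout = Wu.n_rows; m.P = H * W;
  m.Wk.resize(4); m.colsk.resize(4); m.idx.resize(4);
  for (int k = 0; k < 4; ++k) {
    arma::uvec ck(Cin);
    for (int ci = 0; ci < Cin; ++ci) ck(ci) = ci * 4 + k;
    m.colsk[k] = ck;
    m.Wk[k] = Wu.cols(ck);
    const int di = k / 2, dj = k % 2;
    std::vector<arma::uword> id(m.P);
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        id[i + j * H] = (arma::uword)((2 * i + di) + (size_t)(2 * j + dj) * (2 * H));
    m.idx[k] = id;
  }
  return m;
}

static std::vector<cube> upconv_fwd(const std::vector<cube>& xs, const mat& Wu,
                                    const vec& b) {
  const int N = xs.size();
  UpMaps mp = up_maps(Wu, xs[0].n_rows, xs[0].n_cols, xs[0].n_slices);
  std::vector<cube> out(N);
  for (int n = 0; n < N; ++n) {
    mat xm = cube2mat(xs[n]); // Cin x P
    out[n].set_size(2 * mp.H, 2 * mp.W, mp.Cout);
    for (int co = 0; co < mp.Cout; ++co) out[n].slice(co).fill(b(co));
    for (int k = 0; k < 4; ++k) {
      mat zk = mp.Wk[k] * xm; // Cout x P
      for (int co = 0; co < mp.Cout; ++co) {
        double* sl = out[n].slice_memptr(co);
        const double* zr = zk.memptr();
        const std::vector<arma::uword>& id = mp.idx[k];
        for (int p = 0; p < mp.P; ++p) sl[id[p]] += zr[co + (size_t)p * mp.Cout];
      }
    }
  }
  return out;
}

static std::vector<cube> upconv_bwd(const std::vector<cube>& dout,
                                    const std::vector<cube>& xs, const mat& Wu,
                                    mat& dWu, vec& dbu) {
  const int N = xs.size();
  UpMaps mp = up_maps(Wu, xs[0].n_rows, xs[0].n_cols, xs[0].n_slices);
  dWu.zeros(arma::size(Wu));
  dbu.zeros(mp.Cout);
  std::vector<cube> dx(N);
  for (int n = 0; n < N; ++n) {
    mat xm = cube2mat(xs[n]);
    for (int co = 0; co < mp.Cout; ++co) dbu(co) += arma::accu(dout[n].slice(co));
    mat dxm(mp.Cin, mp.P, arma::fill::zeros);
    for (int k = 0; k < 4; ++k) {
      mat dzk(mp.Cout, mp.P);
      double* dzr = dzk.memptr();
      const std::vector<arma::uword>& id = mp.idx[k];
      for (int co = 0; co < mp.Cout; ++co) {
        const double* sl = dout[n].slice_memptr(co);
        for (int p = 0; p < mp.P; ++p) dzr[co + (size_t)p * mp.Cout] = sl[id[p]];
      }
      mat dwk = dzk * xm.t(); // Cout x Cin
      dWu.cols(mp.colsk[k]) += dwk;
      dxm += mp.Wk[k].t() * dzk;
    }
    dx[n] = mat2cube(dxm, mp.H, mp.W);
  }
  return dx;
}

static std::string enc_pre(int lvl, int k) {
  return "enc" + std::to_string(lvl + 1) + "_c" + std::to_string(k);
}
static std::string dec_pre(int lvl, int k) {
  return "dec" + std::to_string(lvl + 1) + "_c" + std::to_string(k);
}

// One pass over a batch. x, y: (H, W, N) cubes; y ignored unless loss wanted.
// Returns sigmoid outputs, loss, grads (if backward), updated running stats.
// [[Rcpp::export]]
List cpp_unet_run(const List& params, const List& running_in, const arma::cube& x,
                  const arma::cube& y, const IntegerVector& channels,
                  double momentum, bool training, bool backward, bool has_y) {
  const int L = channels.size();
  const int N = x.n_slices;
  const int H0 = x.n_rows, W0 = x.n_cols;
  List running = clone(running_in);
  UNet net(params, running, training, momentum);

  std::vector<cube> cur(N);
  for (int n = 0; n < N; ++n) {
    cur[n].set_size(H0, W0, 1);
    cur[n].slice(0) = x.slice(n);
  }

  std::vector<LC> encC(2 * L), decC(2 * (L - 1));
  std::vector<std::vector<cube> > skip(L - 1), up_in(L - 1);
  std::vector<std::vector<arma::ucube> > parg(L - 1);

  for (int i = 0; i < L; ++i) {
    cur = net.cbr(cur, enc_pre(i, 1), encC[2 * i]);
    cur = net.cbr(cur, enc_pre(i, 2), encC[2 * i + 1]);
    if (i < L - 1) {
      skip[i] = cur;
      cur = pool_fwd(cur, parg[i]);
    }
  }
  for (int i = L - 2; i >= 0; --i) {
    up_in[i] = cur;
    std::vector<cube> up = upconv_fwd(
        cur, net.P("dec" + std::to_string(i + 1) + "_up_W"),
        net.Pv("dec" + std::to_string(i + 1) + "_up_b"));
    std::vector<cube> cat(N);
    for (int n = 0; n < N; ++n) cat[n] = arma::join_slices(up[n], skip[i][n]);
    cur = net.cbr(cat, dec_pre(i, 1), decC[2 * i]);
    cur = net.cbr(cur, dec_pre(i, 2), decC[2 * i + 1]);
  }

  const mat Wout = net.P("out_W");
  const vec bout = net.Pv("out_b");
  std::vector<mat> feat(N), a(N);
  cube pred(H0, W0, N);
  double loss = NA_REAL;
  const double M0 = (double)N * H0 * W0;
  double sse = 0.0;
  for (int n = 0; n < N; ++n) {
    feat[n] = cube2mat(cur[n]);
    mat z = Wout * feat[n];
    z += bout(0);
    a[n] = 1.0 / (1.0 + arma::exp(-z));
    pred.slice(n) = arma::reshape(a[n].row(0), H0, W0);
    if (has_y) {
      mat d = pred.slice(n) - y.slice(n);
      sse += arma::accu(d % d);
    }
  }
  if (has_y) loss = sse / M0;

  List out = List::create(_["pred"] = pred, _["loss"] = loss,
                          _["running"] = running);
  if (!backward) return out;

  List grads = clone(params);
  mat dWout(arma::size(Wout), arma::fill::zeros);
  double dbout = 0.0;
  std::vector<mat> dcur_m(N);
  for (int n = 0; n < N; ++n) {
    mat da = (2.0 / M0) * (a[n] - arma::reshape(arma::vectorise(y.slice(n)), 1, H0 * W0));
    mat dz = da % a[n] % (1.0 - a[n]);
    dWout += dz * feat[n].t();
    dbout += arma::accu(dz);
    dcur_m[n] = Wout.t() * dz;
  }
  grads["out_W"] = wrap(dWout);
  grads["out_b"] = wrap(vec(1, arma::fill::value(dbout)));

  // decoder backward (shallowest block first)
  std::vector<cube> dcur(N);
  for (int n = 0; n < N; ++n) dcur[n] = mat2cube(dcur_m[n], H0, W0);
  std::vector<std::vector<cube> > dskip(L - 1);
  for (int i = 0; i <= L - 2; ++i) {
    std::vector<mat> d2(N);
    for (int n = 0; n < N; ++n) d2[n] = cube2mat(dcur[n]);
    std::vector<cube> dcat = net.cbr_bwd(d2, dec_pre(i, 2), decC[2 * i + 1], grads);
    // decC[2i+1] input was output of decC[2i]; chain directly
    std::vector<mat> d1(N);
    for (int n = 0; n < N; ++n) d1[n] = cube2mat(dcat[n]);
    std::vector<cube> dcatin = net.cbr_bwd(d1, dec_pre(i, 1), decC[2 * i], grads);
    const int cch = channels[i];
    std::vector<cube> dup(N);
    dskip[i].resize(N);
    for (int n = 0; n < N; ++n) {
      dup[n] = dcatin[n].slices(0, cch - 1);
      dskip[i][n] = dcatin[n].slices(cch, 2 * cch - 1);
    }
    mat dWu;
    vec dbu;
    std::vector<cube> ddeep = upconv_bwd(
        dup, up_in[i], net.P("dec" + std::to_string(i + 1) + "_up_W"), dWu, dbu);
    grads["dec" + std::to_string(i + 1) + "_up_W"] = wrap(dWu);
    grads["dec" + std::to_string(i + 1) + "_up_b"] = wrap(dbu);
    dcur = ddeep;
  }
  // encoder backward from the bottleneck down to the input
  for (int i = L - 1; i >= 0; --i) {
    std::vector<cube> d(N);
    if (i == L - 1) {
      d = dcur;
    } else {
      d = pool_bwd(dcur, parg[i]);
      for (int n = 0; n < N; ++n) d[n] += dskip[i][n];
    }
    std::vector<mat> d2(N);
    for (int n = 0; n < N; ++n) d2[n] = cube2mat(d[n]);
    std::vector<cube> dmid = net.cbr_bwd(d2, enc_pre(i, 2), encC[2 * i + 1], grads);
    std::vector<mat> d1(N);
    for (int n = 0; n < N; ++n) d1[n] = cube2mat(dmid[n]);
    dcur = net.cbr_bwd(d1, enc_pre(i, 1), encC[2 * i], grads);
  }
  out["grads"] = grads;
  return out;
}
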