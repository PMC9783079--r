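// Residual 1D convolutional classifier (plus simple baselines) with manual
// backpropagation, implemented on Armadillo. The network consumes the 6x3x500
// voltammogram tensor flattened to 18 channels x 500 potential samples; the
// first convolution spans the full channel extent with a width-7 kernel along
// the potential axis, followed by four stages of residual blocks (two blocks
// each, widths w/2w/4w/8w, strides along the potential axis only), global
// average pooling and a 5-way linear head. All randomness (init, shuffling,
// noise augmentation) is drawn from R's RNG so training is reproducible under
// set.seed(). Training regenerates the input tensors from the stored raw
// curves every minibatch with fresh Gaussian noise (on-the-fly augmentation).
//
// Gradient conventions: the loss is the batch-mean cross-entropy, and dlogits
// passed to backward() is already divided by the batch size, so layer
// backwards accumulate plain sums. For input-importance maps backward runs in
// eval-BN mode (running statistics; BN is then a fixed linear map).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// A batch is one wide matrix (channels x length*B); sample s occupies the
// column block [s*L, (s+1)*L). This keeps every layer a single large GEMM or
// elementwise pass, which is what makes CPU training practical.
struct BT {
  arma::mat m;
  int L = 0, B = 0;
};

static inline arma::mat relu_mask(const arma::mat& x) {
  return arma::conv_to<arma::mat>::from(x > 0);
}

// ---------------------------------------------------------------------------
// preprocessing: raw analysis-cycle curves -> 18 x 500 tensor (mirrors the R
// pipeline in preprocess.R exactly; equality is pinned by a test)
// ---------------------------------------------------------------------------

static const int TCOLS = 500;
static const double VLO = 0.05, VHI = 2.0;
static const int SM_HALF = 4;
static const double REV_PEAK_MIN = 0.05;
static const int EDGE_SAMPLES = 5;

static arma::vec movavg(const arma::vec& x) {
  int m = x.n_elem;
  arma::vec out(m);
  for (int j = 0; j < m; ++j) {
    int lo = std::max(0, j - SM_HALF), hi = std::min(m - 1, j + SM_HALF);
    double s = 0;
    for (int t = lo; t <= hi; ++t) s += x(t);
    out(j) = s / (hi - lo + 1);
  }
  return out;
}

// linear interpolation of (xs ascending, ys) at q; 0 outside the data range
static double interp0(const arma::vec& xs, const arma::vec& ys, double q) {
  int m = xs.n_elem;
  if (q < xs(0) || q > xs(m - 1)) return 0.0;
  int lo = 0, hi = m - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (xs(mid) <= q) lo = mid; else hi = mid;
  }
  double denom = xs(hi) - xs(lo);
  if (denom == 0.0) return ys(lo);
  double w = (q - xs(lo)) / denom;
  return ys(lo) + w * (ys(hi) - ys(lo));
}

// Build the 18 x 500 tensor for one system from its raw analysis-cycle curves.
// noise_stage: 0 = raw curves before preprocessing, 1 = normalized tensor
// (the training default, matching the protocol of adding noise to inputs that
// were normalized to a global absolute current of 1).
arma::mat tensor_from_raw_impl(const List& raw, double sigma, int n_used,
                               bool ablate_v, int noise_stage) {
  arma::vec v = as<arma::vec>(raw["v"]);
  arma::vec Ef = as<arma::vec>(raw["Ef"]);
  arma::vec Er = as<arma::vec>(raw["Er"]);
  arma::mat If = as<arma::mat>(raw["If"]);
  arma::mat Ir = as<arma::mat>(raw["Ir"]);
  int n = v.n_elem;
  if (n_used > 0 && n_used < n) {
    n = n_used;
    v = v.head(n); If = If.head_cols(n); Ir = Ir.head_cols(n);
  }
  const int mf = Ef.n_elem, mr = Er.n_elem;

  // raw-stage noise: sd relative to the (noiseless) maximum of the kept curves
  if (sigma > 0 && noise_stage == 0) {
    double imax0 = std::max(arma::abs(If).max(), arma::abs(Ir).max());
    double sd = sigma * imax0;
    for (int j = 0; j < n; ++j) {      // same draw order as the R pipeline
      for (int t = 0; t < mf; ++t) If(t, j) += ::norm_rand() * sd;
      for (int t = 0; t < mr; ++t) Ir(t, j) += ::norm_rand() * sd;
    }
  }

  // sign so the forward principal feature is positive, then set-max scaling
  double fsum = arma::accu(If);
  double s = (fsum >= 0) ? 1.0 : -1.0;
  double imax = std::max(arma::abs(If).max(), arma::abs(Ir).max());
  if (imax > 0) { If *= s / imax; Ir *= s / imax; }

  // reference potential from the slowest curve
  arma::vec smf = movavg(If.col(0)), smr = movavg(Ir.col(0));
  int fpk = smf.index_max(), rpk = smr.index_min();
  double E_ref;
  // noise-adaptive return-peak threshold: MAD of successive differences
  // estimates the per-sample noise; smoothing (9-window mean) divides it by 3
  arma::vec dr = arma::abs(arma::diff(Ir.col(0)));
  double sigma_hat = arma::median(dr) / (std::sqrt(2.0) * 0.6745);
  double tau = std::max(REV_PEAK_MIN, 5.0 * sigma_hat / 3.0);
  bool has_return = smr(rpk) <= -tau &&
    rpk >= EDGE_SAMPLES && rpk < mr - EDGE_SAMPLES;
  if (has_return) {
    E_ref = 0.5 * (Ef(fpk) + Er(rpk));
  } else {
    int hi = (fpk >= 2) ? fpk : mf - 1;     // R: fpk >= 3 (1-based) else full
    double best = -1; int jmax = 1;
    for (int j = 1; j <= hi; ++j) {
      double sl = std::fabs((smf(j) - smf(j - 1)) / (Ef(j) - Ef(j - 1)));
      if (sl > best) { best = sl; jmax = j; }
    }
    E_ref = Ef(jmax);
  }

  double Emin = std::min(Ef.min(), Er.min()), Emax = std::max(Ef.max(), Er.max());
  // mirror R's seq(from, to, length.out): identical fp arithmetic, so the
  // boundary samples land identically in both preprocessing paths
  double gfrom = Emin - E_ref, gto = Emax - E_ref;
  double gby = (gto - gfrom) / (TCOLS - 1);
  arma::vec grid(TCOLS);
  for (int k = 0; k < TCOLS; ++k) grid(k) = gfrom + k * gby;

  // forward potentials descend (reductive convention): flip to ascending
  arma::vec Efa = arma::reverse(Ef - E_ref);
  arma::vec Era = Er - E_ref;
  bool rev_ascending = (mr < 2) || (Era(1) > Era(0));
  if (!rev_ascending) Era = arma::reverse(Era);

  arma::mat x(18, TCOLS, arma::fill::zeros);
  double chmax = 0;
  for (int r = 0; r < n; ++r) {
    arma::vec yf = arma::reverse(If.col(r));
    arma::vec yr = rev_ascending ? arma::vec(Ir.col(r)) : arma::reverse(Ir.col(r));
    for (int k = 0; k < TCOLS; ++k) {
      double a = interp0(Efa, yf, grid(k));
      double b = interp0(Era, yr, grid(k));
      x(3 * r + 0, k) = a;
      x(3 * r + 1, k) = b;
      double aa = std::fabs(a), bb = std::fabs(b);
      if (aa > chmax) chmax = aa;
      if (bb > chmax) chmax = bb;
    }
    if (!ablate_v) {
      double venc = (std::log10(v(r)) - std::log10(VLO)) /
                    (std::log10(VHI) - std::log10(VLO));
      x.row(3 * r + 2).fill(venc);
    }
  }
  if (chmax > 0)
    for (int r = 0; r < n; ++r) {
      x.row(3 * r + 0) /= chmax;
      x.row(3 * r + 1) /= chmax;
    }
  // tensor-stage noise on the populated current channels (max is 1 by
  // construction, so the relative sigma is the absolute sd); padding rows and
  // the v channel stay exactly zero / clean
  if (sigma > 0 && noise_stage == 1)
    for (int r = 0; r < n; ++r)
      for (int k = 0; k < TCOLS; ++k) {
        x(3 * r + 0, k) += ::norm_rand() * sigma;
        x(3 * r + 1, k) += ::norm_rand() * sigma;
      }
  return x;
}

// [[Rcpp::export]]
arma::mat cpp_tensor_from_raw(List raw, double sigma, int n_used, bool ablate_v,
                              int noise_stage = 1) {
  return tensor_from_raw_impl(raw, sigma, n_used, ablate_v, noise_stage);
}


// ---------------------------------------------------------------------------
// layers
// ---------------------------------------------------------------------------

struct ParamReg {
  std::vector<std::string> names;
  std::vector<arma::mat*> params;      // trainable
  std::vector<arma::mat*> grads;
  std::vector<bool> decay;             // apply weight decay?
  std::vector<std::string> state_names;
  std::vector<arma::mat*> state;       // BN running stats
  void add(const std::string& nm, arma::mat* w, arma::mat* g, bool dec) {
    names.push_back(nm); params.push_back(w); grads.push_back(g);
    decay.push_back(dec);
  }
  void add_state(const std::string& nm, arma::mat* s) {
    state_names.push_back(nm); state.push_back(s);
  }
};

struct Conv1d {
  int in_c, out_c, k, stride, pad, in_len, out_len;
  arma::mat W, dW;                      // (out_c, in_c*k)
  arma::mat col;                        // cached im2col of the whole batch
  void build(int ic, int oc, int kk, int ss, int pp, int il) {
    in_c = ic; out_c = oc; k = kk; stride = ss; pad = pp; in_len = il;
    out_len = (il + 2 * pp - kk) / ss + 1;
    W.set_size(oc, ic * kk);
    double sdv = std::sqrt(2.0 / (ic * kk));
    for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = ::norm_rand() * sdv;
    dW.zeros(oc, ic * kk);
  }
  void reg(ParamReg& pr, const std::string& nm) { pr.add(nm + ".W", &W, &dW, true); }
  arma::mat im2col(const BT& x) const {
    arma::mat c(in_c * k, (size_t)out_len * x.B, arma::fill::zeros);
    for (int s = 0; s < x.B; ++s) {
      const int xoff = s * in_len, coff = s * out_len;
      for (int o = 0; o < out_len; ++o) {
        int start = o * stride - pad;
        int t0 = std::max(0, -start), t1 = std::min(k - 1, in_len - 1 - start);
        double* dst = c.colptr(coff + o);
        for (int t = t0; t <= t1; ++t) {
          const double* srcc = x.m.colptr(xoff + start + t);
          for (int cc = 0; cc < in_c; ++cc) dst[cc * k + t] = srcc[cc];
        }
      }
    }
    return c;
  }
  BT forward(const BT& x, bool cache) {
    arma::mat c = im2col(x);
    BT y; y.L = out_len; y.B = x.B;
    y.m = W * c;
    if (cache) col = std::move(c);
    return y;
  }
  BT backward(const BT& dy) {
    dW = dy.m * col.t();
    arma::mat dcol = W.t() * dy.m;
    BT dx; dx.L = in_len; dx.B = dy.B;
    dx.m.zeros(in_c, (size_t)in_len * dy.B);
    for (int s = 0; s < dy.B; ++s) {
      const int xoff = s * in_len, coff = s * out_len;
      for (int o = 0; o < out_len; ++o) {
        int start = o * stride - pad;
        int t0 = std::max(0, -start), t1 = std::min(k - 1, in_len - 1 - start);
        const double* src = dcol.colptr(coff + o);
        for (int t = t0; t <= t1; ++t) {
          double* dstc = dx.m.colptr(xoff + start + t);
          for (int cc = 0; cc < in_c; ++cc) dstc[cc] += src[cc * k + t];
        }
      }
    }
    return dx;
  }
};

// Group normalization over 4 channel groups, computed per sample. Unlike
// batch normalization there are no running statistics: inference normalizes
// each input by its own feature statistics, so the network's behaviour does
// not depend on how closely the evaluation noise level matches the training
// one, and the input gradient is the exact gradient of the inference-time
// function (the statistics' gradient terms are included in backward()).
struct GroupNorm1d {
  int C, G = 4;
  arma::mat g, b, dg, db;             // stored as C x 1
  double eps = 1e-5;
  arma::mat xhat;
  arma::mat invstd;                   // G x B
  void build(int c) {
    C = c;
    if (C % G != 0) G = 1;
    g.ones(c, 1); b.zeros(c, 1); dg.zeros(c, 1); db.zeros(c, 1);
  }
  void reg(ParamReg& pr, const std::string& nm) {
    pr.add(nm + ".g", &g, &dg, false);
    pr.add(nm + ".b", &b, &db, false);
  }
  BT forward(const BT& x, bool, bool cache) {
    BT y; y.L = x.L; y.B = x.B;
    const int Cg = C / G;
    arma::mat xh(arma::size(x.m));
    arma::mat istd(G, x.B);
    for (int s = 0; s < x.B; ++s) {
      for (int gr = 0; gr < G; ++gr) {
        auto blk = x.m.submat(gr * Cg, (size_t)s * x.L,
                              (gr + 1) * Cg - 1, (size_t)(s + 1) * x.L - 1);
        double mu = arma::mean(arma::vectorise(blk));
        double va = arma::mean(arma::square(arma::vectorise(blk) - mu));
        double is = 1.0 / std::sqrt(va + eps);
        istd(gr, s) = is;
        xh.submat(gr * Cg, (size_t)s * x.L,
                  (gr + 1) * Cg - 1, (size_t)(s + 1) * x.L - 1) = (blk - mu) * is;
      }
    }
    y.m = (xh.each_col() % g.col(0)).each_col() + b.col(0);
    if (cache) { xhat = std::move(xh); invstd = std::move(istd); }
    return y;
  }
  BT backward(const BT& dy) {
    const int Cg = C / G;
    dg.col(0) = arma::sum(dy.m % xhat, 1);
    db.col(0) = arma::sum(dy.m, 1);
    BT dx; dx.L = dy.L; dx.B = dy.B;
    dx.m.set_size(arma::size(dy.m));
    arma::mat dxh = dy.m.each_col() % g.col(0);
    const double N = double(Cg) * dy.L;
    for (int s = 0; s < dy.B; ++s) {
      for (int gr = 0; gr < G; ++gr) {
        auto d = dxh.submat(gr * Cg, (size_t)s * dy.L,
                            (gr + 1) * Cg - 1, (size_t)(s + 1) * dy.L - 1);
        auto xh = xhat.submat(gr * Cg, (size_t)s * dy.L,
                              (gr + 1) * Cg - 1, (size_t)(s + 1) * dy.L - 1);
        double sum_d = arma::accu(d);
        double sum_dxh = arma::accu(d % xh);
        dx.m.submat(gr * Cg, (size_t)s * dy.L,
                    (gr + 1) * Cg - 1, (size_t)(s + 1) * dy.L - 1) =
          (d * N - sum_d - xh * sum_dxh) * (invstd(gr, s) / N);
      }
    }
    return dx;
  }
  BT backward_eval(const BT& dy) { return backward(dy); }
};
typedef GroupNorm1d BatchNorm1d;

struct ReLU {
  arma::mat mask;
  BT forward(const BT& x, bool cache) {
    BT y; y.L = x.L; y.B = x.B;
    y.m = arma::clamp(x.m, 0.0, arma::datum::inf);
    if (cache) mask = relu_mask(x.m);
    return y;
  }
  BT backward(const BT& dy) {
    BT dx; dx.L = dy.L; dx.B = dy.B;
    dx.m = dy.m % mask;
    return dx;
  }
};

struct Pool1d {
  int k = 3, stride = 2, pad = 1, in_len = 0, out_len = 0, C = 0;
  bool avg = true;          // average pooling: robust to additive input noise
  arma::imat arg;
  std::vector<std::pair<int,int>> win;
  BT forward(const BT& x, bool cache) {
    C = x.m.n_rows; in_len = x.L;
    out_len = (in_len + 2 * pad - k) / stride + 1;
    BT y; y.L = out_len; y.B = x.B;
    y.m.set_size(C, (size_t)out_len * x.B);
    if (!avg && cache) arg.set_size(C, (size_t)out_len * x.B);
    win.resize(out_len);
    for (int o = 0; o < out_len; ++o) {
      int start = o * stride - pad;
      win[o] = {std::max(0, start), std::min(in_len - 1, start + k - 1)};
    }
    for (int s = 0; s < x.B; ++s) {
      const int xoff = s * in_len, yoff = s * out_len;
      for (int o = 0; o < out_len; ++o) {
        int lo = win[o].first, hi = win[o].second;
        if (avg) {
          double inv = 1.0 / (hi - lo + 1);
          for (int c = 0; c < C; ++c) {
            double acc = 0;
            for (int p = lo; p <= hi; ++p) acc += x.m(c, xoff + p);
            y.m(c, yoff + o) = acc * inv;
          }
        } else {
          for (int c = 0; c < C; ++c) {
            double best = x.m(c, xoff + lo); int bi = lo;
            for (int p = lo + 1; p <= hi; ++p)
              if (x.m(c, xoff + p) > best) { best = x.m(c, xoff + p); bi = p; }
            y.m(c, yoff + o) = best;
            if (cache) arg(c, yoff + o) = xoff + bi;
          }
        }
      }
    }
    return y;
  }
  BT backward(const BT& dy) {
    BT dx; dx.L = in_len; dx.B = dy.B;
    dx.m.zeros(C, (size_t)in_len * dy.B);
    if (avg) {
      for (int s = 0; s < dy.B; ++s) {
        const int xoff = s * in_len, yoff = s * out_len;
        for (int o = 0; o < out_len; ++o) {
          int lo = win[o].first, hi = win[o].second;
          double inv = 1.0 / (hi - lo + 1);
          for (int c = 0; c < C; ++c) {
            double d = dy.m(c, yoff + o) * inv;
            for (int p = lo; p <= hi; ++p) dx.m(c, xoff + p) += d;
          }
        }
      }
    } else {
      for (arma::uword j = 0; j < dy.m.n_cols; ++j)
        for (int c = 0; c < C; ++c)
          dx.m(c, arg(c, j)) += dy.m(c, j);
    }
    return dx;
  }
};
typedef Pool1d MaxPool1d;

struct Linear {
  arma::mat W, dW, b, db;
  void build(int in, int out) {
    W.set_size(out, in);
    double sdv = std::sqrt(2.0 / in);
    for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = ::norm_rand() * sdv;
    b.zeros(out, 1);
    dW.zeros(out, in); db.zeros(out, 1);
  }
  void reg(ParamReg& pr, const std::string& nm) {
    pr.add(nm + ".W", &W, &dW, true);
    pr.add(nm + ".b", &b, &db, false);
  }
};

// ---------------------------------------------------------------------------
// residual network
// ---------------------------------------------------------------------------

struct ResBlock {
  Conv1d c1, c2, cd;
  BatchNorm1d bn1, bn2, bnd;
  ReLU r1, r2;
  bool down = false;
  void build(int in_c, int out_c, int stride, int in_len) {
    down = (stride != 1 || in_c != out_c);
    c1.build(in_c, out_c, 3, stride, 1, in_len);
    bn1.build(out_c);
    c2.build(out_c, out_c, 3, 1, 1, c1.out_len);
    bn2.build(out_c);
    if (down) { cd.build(in_c, out_c, 1, stride, 0, in_len); bnd.build(out_c); }
  }
  void reg(ParamReg& pr, const std::string& nm) {
    c1.reg(pr, nm + ".c1"); bn1.reg(pr, nm + ".bn1");
    c2.reg(pr, nm + ".c2"); bn2.reg(pr, nm + ".bn2");
    if (down) { cd.reg(pr, nm + ".cd"); bnd.reg(pr, nm + ".bnd"); }
  }
  int out_len() const { return c2.out_len; }
  BT forward(const BT& x, bool train, bool cache) {
    BT h = bn1.forward(c1.forward(x, cache), train, cache);
    h = r1.forward(h, cache);
    h = bn2.forward(c2.forward(h, cache), train, cache);
    BT sc = down ? bnd.forward(cd.forward(x, cache), train, cache) : x;
    h.m += sc.m;
    return r2.forward(h, cache);
  }
  BT backward(const BT& dy, bool eval_bn) {
    BT d = r2.backward(dy);
    BT d1 = eval_bn ? bn2.backward_eval(d) : bn2.backward(d);
    d1 = c2.backward(d1);
    d1 = r1.backward(d1);
    d1 = eval_bn ? bn1.backward_eval(d1) : bn1.backward(d1);
    d1 = c1.backward(d1);
    if (down) {
      BT d2 = eval_bn ? bnd.backward_eval(d) : bnd.backward(d);
      d2 = cd.backward(d2);
      d1.m += d2.m;
    } else {
      d1.m += d.m;
    }
    return d1;
  }
};

struct ResNet {
  int width, n_class = 5;
  Conv1d conv1;
  BatchNorm1d bn1;
  ReLU relu1;
  MaxPool1d pool;
  std::vector<ResBlock> blocks;
  Linear fc;
  arma::mat fc_in;                     // cached GAP features (C x B)
  int feat_len = 0, feat_c = 0;
  ParamReg pr;

  void build(int w) {
    width = w;
    conv1.build(18, w, 7, 2, 3, TCOLS);
    bn1.build(w);
    int plen = (conv1.out_len + 2 * 1 - 3) / 2 + 1;   // after maxpool
    int widths[4] = {w, 2 * w, 4 * w, 8 * w};
    int in_c = w, L = plen;
    blocks.resize(8);
    int bi = 0;
    for (int stg = 0; stg < 4; ++stg) {
      for (int j = 0; j < 2; ++j) {
        int stride = (stg > 0 && j == 0) ? 2 : 1;
        blocks[bi].build(in_c, widths[stg], stride, L);
        L = blocks[bi].out_len();
        in_c = widths[stg];
        ++bi;
      }
    }
    feat_len = L; feat_c = in_c;
    fc.build(in_c, n_class);
    conv1.reg(pr, "conv1"); bn1.reg(pr, "bn1");
    for (int i = 0; i < 8; ++i) blocks[i].reg(pr, "block" + std::to_string(i));
    fc.reg(pr, "fc");
  }

  arma::mat forward(const BT& x, bool train, bool cache) {
    BT h = relu1.forward(bn1.forward(conv1.forward(x, cache), train, cache), cache);
    h = pool.forward(h, cache);
    for (auto& b : blocks) h = b.forward(h, train, cache);
    int B = h.B;
    arma::mat feat(feat_c, B);
    for (int s = 0; s < B; ++s)
      feat.col(s) = arma::mean(h.m.cols((size_t)s * feat_len,
                                        (size_t)(s + 1) * feat_len - 1), 1);
    if (cache) fc_in = feat;
    return fc.W * feat + arma::repmat(fc.b, 1, B);
  }

  BT backward(const arma::mat& dlogits, bool eval_bn) {
    int B = dlogits.n_cols;
    fc.dW = dlogits * fc_in.t();
    fc.db = arma::sum(dlogits, 1);
    arma::mat dfeat = fc.W.t() * dlogits;     // C x B
    BT dh; dh.L = feat_len; dh.B = B;
    dh.m.set_size(feat_c, (size_t)feat_len * B);
    for (int s = 0; s < B; ++s) {
      arma::vec d = dfeat.col(s) / feat_len;
      dh.m.cols((size_t)s * feat_len, (size_t)(s + 1) * feat_len - 1) =
        arma::repmat(d, 1, feat_len);
    }
    for (int i = 7; i >= 0; --i) dh = blocks[i].backward(dh, eval_bn);
    dh = pool.backward(dh);
    dh = relu1.backward(dh);
    dh = eval_bn ? bn1.backward_eval(dh) : bn1.backward(dh);
    return conv1.backward(dh);
  }
};

// ---------------------------------------------------------------------------
// baselines: linear, mlp, mlp_shared (shared first layer per curve row),
// mlp_attention (shared row encoder + attention pooling over rows)
// ---------------------------------------------------------------------------

struct SimpleNet {
  std::string kind;
  int n_class = 5, n_rows = 6, row_dim = 3 * TCOLS, full_dim = 18 * TCOLS;
  int hid = 64;
  Linear l1, l2, l3, enc, att;
  ParamReg pr;
  arma::mat X, H1, H2, POOL, ALPHA;
  std::vector<arma::mat> HR, Xrows;

  void build(const std::string& k) {
    kind = k;
    if (kind == "linear") {
      l3.build(full_dim, n_class); l3.reg(pr, "l3");
    } else if (kind == "mlp") {
      l1.build(full_dim, 256); l2.build(256, 128); l3.build(128, n_class);
      l1.reg(pr, "l1"); l2.reg(pr, "l2"); l3.reg(pr, "l3");
    } else if (kind == "mlp_shared") {
      enc.build(row_dim, hid); l2.build(n_rows * hid, 128); l3.build(128, n_class);
      enc.reg(pr, "enc"); l2.reg(pr, "l2"); l3.reg(pr, "l3");
    } else if (kind == "mlp_attention") {
      enc.build(row_dim, hid); att.build(hid, 1); l3.build(hid, n_class);
      enc.reg(pr, "enc"); att.reg(pr, "att"); l3.reg(pr, "l3");
    } else stop("unknown model kind: " + kind);
  }

  // column s = flattened sample s (column-major over the 18 x 500 block)
  static arma::mat flatten(const BT& x) {
    arma::mat X(x.m.n_rows * x.L, x.B);
    for (int s = 0; s < x.B; ++s)
      X.col(s) = arma::vectorise(x.m.cols((size_t)s * x.L,
                                          (size_t)(s + 1) * x.L - 1));
    return X;
  }
  static arma::mat row_slice(const BT& x, int r) {
    arma::mat X(3 * TCOLS, x.B);
    for (int s = 0; s < x.B; ++s)
      X.col(s) = arma::vectorise(
        x.m.submat(3 * r, (size_t)s * x.L, 3 * r + 2, (size_t)(s + 1) * x.L - 1));
    return X;
  }

  arma::mat forward(const BT& xs, bool) {
    int B = xs.B;
    if (kind == "linear") {
      X = flatten(xs);
      return l3.W * X + arma::repmat(l3.b, 1, B);
    }
    if (kind == "mlp") {
      X = flatten(xs);
      H1 = arma::clamp(l1.W * X + arma::repmat(l1.b, 1, B), 0.0, arma::datum::inf);
      H2 = arma::clamp(l2.W * H1 + arma::repmat(l2.b, 1, B), 0.0, arma::datum::inf);
      return l3.W * H2 + arma::repmat(l3.b, 1, B);
    }
    if (kind == "mlp_shared") {
      HR.assign(n_rows, arma::mat()); Xrows.assign(n_rows, arma::mat());
      arma::mat cat(n_rows * hid, B);
      for (int r = 0; r < n_rows; ++r) {
        Xrows[r] = row_slice(xs, r);
        HR[r] = arma::clamp(enc.W * Xrows[r] + arma::repmat(enc.b, 1, B),
                            0.0, arma::datum::inf);
        cat.rows(r * hid, (r + 1) * hid - 1) = HR[r];
      }
      H1 = cat;
      H2 = arma::clamp(l2.W * cat + arma::repmat(l2.b, 1, B), 0.0, arma::datum::inf);
      return l3.W * H2 + arma::repmat(l3.b, 1, B);
    }
    // mlp_attention
    HR.assign(n_rows, arma::mat()); Xrows.assign(n_rows, arma::mat());
    arma::mat scores(n_rows, B);
    for (int r = 0; r < n_rows; ++r) {
      Xrows[r] = row_slice(xs, r);
      HR[r] = arma::clamp(enc.W * Xrows[r] + arma::repmat(enc.b, 1, B),
                          0.0, arma::datum::inf);
      scores.row(r) = att.W * HR[r] + arma::repmat(att.b, 1, B);
    }
    scores.each_row() -= arma::max(scores, 0);
    ALPHA = arma::exp(scores);
    ALPHA.each_row() /= arma::sum(ALPHA, 0);
    POOL.zeros(hid, B);
    for (int r = 0; r < n_rows; ++r)
      POOL += HR[r].each_row() % ALPHA.row(r);
    return l3.W * POOL + arma::repmat(l3.b, 1, B);
  }

  BT unflatten(const arma::mat& dX) {
    BT dx; dx.L = TCOLS; dx.B = dX.n_cols;
    dx.m.set_size(18, (size_t)TCOLS * dX.n_cols);
    for (arma::uword s = 0; s < dX.n_cols; ++s)
      dx.m.cols((size_t)s * TCOLS, (size_t)(s + 1) * TCOLS - 1) =
        arma::reshape(dX.col(s), 18, TCOLS);
    return dx;
  }

  BT backward(const arma::mat& dlogits, bool) {
    int B = dlogits.n_cols;
    if (kind == "linear") {
      l3.dW = dlogits * X.t();
      l3.db = arma::sum(dlogits, 1);
      return unflatten(l3.W.t() * dlogits);
    }
    if (kind == "mlp") {
      l3.dW = dlogits * H2.t(); l3.db = arma::sum(dlogits, 1);
      arma::mat d2 = (l3.W.t() * dlogits) % relu_mask(H2);
      l2.dW = d2 * H1.t(); l2.db = arma::sum(d2, 1);
      arma::mat d1 = (l2.W.t() * d2) % relu_mask(H1);
      l1.dW = d1 * X.t(); l1.db = arma::sum(d1, 1);
      return unflatten(l1.W.t() * d1);
    }
    if (kind == "mlp_shared") {
      l3.dW = dlogits * H2.t(); l3.db = arma::sum(dlogits, 1);
      arma::mat d2 = (l3.W.t() * dlogits) % relu_mask(H2);
      l2.dW = d2 * H1.t(); l2.db = arma::sum(d2, 1);
      arma::mat dcat = l2.W.t() * d2;
      enc.dW.zeros(); enc.db.zeros();
      BT dxs; dxs.L = TCOLS; dxs.B = B;
      dxs.m.zeros(18, (size_t)TCOLS * B);
      for (int r = 0; r < n_rows; ++r) {
        arma::mat dh = dcat.rows(r * hid, (r + 1) * hid - 1) % relu_mask(HR[r]);
        enc.dW += dh * Xrows[r].t();
        enc.db += arma::sum(dh, 1);
        arma::mat dxr = enc.W.t() * dh;
        for (int s = 0; s < B; ++s)
          dxs.m.submat(3 * r, (size_t)s * TCOLS, 3 * r + 2,
                       (size_t)(s + 1) * TCOLS - 1) =
            arma::reshape(dxr.col(s), 3, TCOLS);
      }
      return dxs;
    }
    // mlp_attention
    l3.dW = dlogits * POOL.t(); l3.db = arma::sum(dlogits, 1);
    arma::mat dpool = l3.W.t() * dlogits;
    arma::mat dalpha(n_rows, B);
    for (int r = 0; r < n_rows; ++r)
      dalpha.row(r) = arma::sum(dpool % HR[r], 0);
    arma::mat ds = ALPHA % (dalpha.each_row() - arma::sum(ALPHA % dalpha, 0));
    enc.dW.zeros(); enc.db.zeros(); att.dW.zeros(); att.db.zeros();
    BT dxs; dxs.L = TCOLS; dxs.B = B;
    dxs.m.zeros(18, (size_t)TCOLS * B);
    for (int r = 0; r < n_rows; ++r) {
      arma::mat dh = dpool.each_row() % ALPHA.row(r);
      dh += att.W.t() * ds.row(r);
      dh = dh % relu_mask(HR[r]);
      att.dW += ds.row(r) * HR[r].t();
      att.db(0, 0) += arma::accu(ds.row(r));
      enc.dW += dh * Xrows[r].t();
      enc.db += arma::sum(dh, 1);
      arma::mat dxr = enc.W.t() * dh;
      for (int s = 0; s < B; ++s)
        dxs.m.submat(3 * r, (size_t)s * TCOLS, 3 * r + 2,
                     (size_t)(s + 1) * TCOLS - 1) =
          arma::reshape(dxr.col(s), 3, TCOLS);
    }
    return dxs;
  }
};

// ---------------------------------------------------------------------------
// model handle
// ---------------------------------------------------------------------------

struct Model {
  std::string kind;
  int width;
  ResNet res;
  SimpleNet simp;
  bool is_res;
  ParamReg* reg() { return is_res ? &res.pr : &simp.pr; }
  void build(const std::string& k, int w) {
    kind = k; width = w;
    is_res = (k == "resnet18" || k == "resnet");
    if (is_res) res.build(w); else simp.build(k);
  }
  arma::mat forward(const BT& x, bool train, bool cache) {
    return is_res ? res.forward(x, train, cache) : simp.forward(x, train);
  }
  BT backward(const arma::mat& dl, bool eval_bn) {
    return is_res ? res.backward(dl, eval_bn) : simp.backward(dl, eval_bn);
  }
  void load(const List& params) {
    ParamReg* p = reg();
    for (size_t i = 0; i < p->names.size(); ++i) {
      arma::mat m = as<arma::mat>(params[p->names[i]]);
      if (m.n_rows != p->params[i]->n_rows || m.n_cols != p->params[i]->n_cols)
        stop("parameter shape mismatch for " + p->names[i]);
      *(p->params[i]) = m;
    }
    for (size_t i = 0; i < p->state_names.size(); ++i)
      if (params.containsElementNamed(p->state_names[i].c_str()))
        *(p->state[i]) = as<arma::mat>(params[p->state_names[i]]);
  }
  List dump() {
    ParamReg* p = reg();
    List out;
    for (size_t i = 0; i < p->names.size(); ++i) out[p->names[i]] = *(p->params[i]);
    for (size_t i = 0; i < p->state_names.size(); ++i)
      out[p->state_names[i]] = *(p->state[i]);
    return out;
  }
};

// [[Rcpp::export]]
List nn_init_cpp(std::string kind, int width) {
  Model m;
  m.build(kind, width);
  return m.dump();
}

static arma::mat softmax_cols(const arma::mat& logits) {
  arma::mat z = logits.each_row() - arma::max(logits, 0);
  arma::mat e = arma::exp(z);
  e.each_row() /= arma::sum(e, 0);
  return e;
}

static BT make_batch(const List& raws, const arma::ivec& idx, double sigma,
                     int n_used, bool ablate_v, int noise_stage) {
  BT x; x.L = TCOLS; x.B = idx.n_elem;
  x.m.set_size(18, (size_t)TCOLS * idx.n_elem);
  for (arma::uword s = 0; s < idx.n_elem; ++s)
    x.m.cols((size_t)s * TCOLS, (size_t)(s + 1) * TCOLS - 1) =
      tensor_from_raw_impl(as<List>(raws[idx(s)]), sigma, n_used, ablate_v,
                           noise_stage);
  return x;
}

// [[Rcpp::export]]
List nn_train_cpp(List params, std::string kind, int width,
                  List raws, arma::ivec labels, arma::ivec train_idx,
                  double sigma, int n_used, bool ablate_v,
                  int epochs, int batch, double lr, double weight_decay,
                  bool cosine_lr, bool verbose,
                  int noise_stage = 1, bool n_random = false) {
  Model m;
  m.build(kind, width);
  m.load(params);
  ParamReg* pr = m.reg();
  size_t np = pr->params.size();
  std::vector<arma::mat> adam_m(np), adam_v(np);
  for (size_t i = 0; i < np; ++i) {
    adam_m[i].zeros(arma::size(*pr->params[i]));
    adam_v[i].zeros(arma::size(*pr->params[i]));
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long tstep = 0;
  int N = train_idx.n_elem;
  NumericVector hist_loss(epochs), hist_acc(epochs);

  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = train_idx(i);

  // With tensor-stage noise and a fixed scan-rate count the clean tensors are
  // constant across epochs: build them once and add noise per minibatch.
  bool use_cache = (noise_stage == 1) && !n_random;
  arma::mat cache;
  std::vector<int> cache_pos(raws.size(), -1), npop(N);
  if (use_cache) {
    cache.set_size(18, (size_t)TCOLS * N);
    for (int i = 0; i < N; ++i) {
      int gi = train_idx(i);
      cache.cols((size_t)i * TCOLS, (size_t)(i + 1) * TCOLS - 1) =
        tensor_from_raw_impl(as<List>(raws[gi]), 0.0, n_used, ablate_v, 1);
      cache_pos[gi] = i;
      int nsys = as<arma::vec>(as<List>(raws[gi])["v"]).n_elem;
      npop[i] = (n_used > 0 && n_used < nsys) ? n_used : nsys;
    }
  }

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = N - 1; i > 0; --i) {        // Fisher-Yates via R RNG
      int j = int(::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double lr_ep = lr;
    if (cosine_lr && epochs > 1)
      lr_ep = lr * (0.05 + 0.95 * 0.5 * (1.0 + std::cos(M_PI * ep / (epochs - 1))));
    double tot_loss = 0; int tot_correct = 0;
    for (int off = 0; off < N; off += batch) {
      int bs = std::min(batch, N - off);
      arma::ivec bidx(bs);
      for (int s = 0; s < bs; ++s) bidx(s) = order[off + s];
      BT xs;
      if (use_cache) {
        xs.L = TCOLS; xs.B = bs;
        xs.m.set_size(18, (size_t)TCOLS * bs);
        for (int s = 0; s < bs; ++s) {
          int ci = cache_pos[bidx(s)];
          xs.m.cols((size_t)s * TCOLS, (size_t)(s + 1) * TCOLS - 1) =
            cache.cols((size_t)ci * TCOLS, (size_t)(ci + 1) * TCOLS - 1);
          if (sigma > 0)
            for (int r = 0; r < npop[ci]; ++r)
              for (int k = 0; k < TCOLS; ++k) {
                xs.m(3 * r + 0, (size_t)s * TCOLS + k) += ::norm_rand() * sigma;
                xs.m(3 * r + 1, (size_t)s * TCOLS + k) += ::norm_rand() * sigma;
              }
        }
      } else if (n_random) {
        xs.L = TCOLS; xs.B = bs;
        xs.m.set_size(18, (size_t)TCOLS * bs);
        for (int s = 0; s < bs; ++s) {
          int nr = 1 + int(::unif_rand() * 6.0);
          if (nr > 6) nr = 6;
          xs.m.cols((size_t)s * TCOLS, (size_t)(s + 1) * TCOLS - 1) =
            tensor_from_raw_impl(as<List>(raws[bidx(s)]), sigma, nr, ablate_v,
                                 noise_stage);
        }
      } else {
        xs = make_batch(raws, bidx, sigma, n_used, ablate_v, noise_stage);
      }
      arma::mat logits = m.forward(xs, true, true);
      arma::mat probs = softmax_cols(logits);
      arma::mat dlog = probs;
      for (int s = 0; s < bs; ++s) {
        int y = labels(bidx(s)) - 1;
        tot_loss += -std::log(std::max(probs(y, s), 1e-12));
        if (probs.col(s).index_max() == arma::uword(y)) ++tot_correct;
        dlog(y, s) -= 1.0;
      }
      dlog /= bs;                            // batch-mean loss
      if (!std::isfinite(tot_loss))
        stop("training diverged (loss is not finite) at epoch " +
             std::to_string(ep + 1));
      m.backward(dlog, false);
      ++tstep;
      double bc1 = 1.0 - std::pow(b1, tstep), bc2 = 1.0 - std::pow(b2, tstep);
      for (size_t i = 0; i < np; ++i) {
        arma::mat g = *pr->grads[i];
        if (pr->decay[i] && weight_decay > 0) g += weight_decay * (*pr->params[i]);
        adam_m[i] = b1 * adam_m[i] + (1 - b1) * g;
        adam_v[i] = b2 * adam_v[i] + (1 - b2) * arma::square(g);
        *pr->params[i] -= lr_ep * (adam_m[i] / bc1) /
                          (arma::sqrt(adam_v[i] / bc2) + eps);
      }
    }
    hist_loss[ep] = tot_loss / N;
    hist_acc[ep] = double(tot_correct) / N;
    if (verbose)
      Rcpp::Rcout << "epoch " << ep + 1 << "/" << epochs
                  << " loss " << hist_loss[ep]
                  << " acc " << hist_acc[ep] << std::endl;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = m.dump(), _["loss"] = hist_loss,
                      _["acc"] = hist_acc);
}

// [[Rcpp::export]]
arma::mat nn_predict_pool_cpp(List params, std::string kind, int width,
                              List raws, arma::ivec idx, double sigma,
                              int n_used, bool ablate_v, int batch = 128,
                              int noise_stage = 1) {
  Model m;
  m.build(kind, width);
  m.load(params);
  int N = idx.n_elem;
  arma::mat probs(5, N);
  for (int off = 0; off < N; off += batch) {
    int bs = std::min(batch, N - off);
    arma::ivec bidx = idx.subvec(off, off + bs - 1);
    BT xs = make_batch(raws, bidx, sigma, n_used, ablate_v, noise_stage);
    probs.cols(off, off + bs - 1) = softmax_cols(m.forward(xs, false, false));
  }
  return probs.t();
}

// [[Rcpp::export]]
arma::mat nn_predict_tensor_cpp(List params, std::string kind, int width,
                                arma::mat x) {
  Model m;
  m.build(kind, width);
  m.load(params);
  BT xs; xs.L = TCOLS; xs.B = 1; xs.m = x;
  return softmax_cols(m.forward(xs, false, false)).t();
}

// Gradient of one logit with respect to the input (eval-mode batch norm).
// target_class is 0-based; -1 selects the predicted class.
// [[Rcpp::export]]
List nn_input_grad_cpp(List params, std::string kind, int width,
                       arma::mat x, int target_class) {
  Model m;
  m.build(kind, width);
  m.load(params);
  BT xs; xs.L = TCOLS; xs.B = 1; xs.m = x;
  arma::mat logits = m.forward(xs, false, true);
  int cls = (target_class >= 0) ? target_class : int(logits.col(0).index_max());
  arma::mat dlog(5, 1, arma::fill::zeros);
  dlog(cls, 0) = 1.0;
  BT dx = m.backward(dlog, true);
  return List::create(_["grad"] = dx.m, _["logits"] = logits.col(0),
                      _["class0"] = cls);
}
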