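// Core numerical engine: per-channel CNN encoder, channel-wise attention
// transformer with [CLS] token, attention-derived marker positivity,
// gradient-reversed modality head, and the three training losses with
// analytic gradients. Dense linear algebra via Armadillo/BLAS.
//
// Conventions:
//  - CNN feature maps: arma::mat (C, P*N); column q + P*g is spatial position
//    q of image g, q = i + H*j (i = row pixel, j = column pixel).
//  - Transformer activations: per batch item, arma::mat (L, d); row 0 is the
//    [CLS] token, rows 1..L-1 are the item's real channels in slot order.
//  - All computations in double precision; no RNG lives in C++ (all
//    stochasticity is injected from R so runs are seed-reproducible).

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <chrono>
// [[Rcpp::depends(RcppArmadillo)]]

// lightweight section profiler (accumulated wall times returned to R)
struct Prof {
  std::map<std::string, double> t;
  std::chrono::high_resolution_clock::time_point last;
  Prof() : last(std::chrono::high_resolution_clock::now()) {}
  void tick(const char* nm) {
    auto now = std::chrono::high_resolution_clock::now();
    t[nm] += std::chrono::duration<double>(now - last).count();
    last = now;
  }
};

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::cube;
using arma::uword;

static const double BN_EPS = 1e-5;
static const double LN_EPS = 1e-5;

// ---------------------------------------------------------------------------
// small helpers
// ---------------------------------------------------------------------------

static inline mat silu(const mat& z) {
  return z % (1.0 / (1.0 + arma::exp(-z)));
}

static inline mat silu_grad(const mat& z) {
  mat s = 1.0 / (1.0 + arma::exp(-z));
  return s % (1.0 + z % (1.0 - s));
}

// silu gradient reusing a cached sigmoid
static inline mat silu_grad_s(const mat& z, const mat& s) {
  return s % (1.0 + z % (1.0 - s));
}

static void softmax_rows(mat& S) {
  for (uword i = 0; i < S.n_rows; ++i) {
    double m = S.row(i).max();
    rowvec e = arma::exp(S.row(i) - m);
    S.row(i) = e / arma::accu(e);
  }
}

// Layer normalization over the feature (column) axis of an (L, d) matrix.
// Caches normalized values and inverse stddev for the backward pass.
static void ln_forward(const mat& X, const vec& g, const vec& b,
                       mat& Xn, vec& iv, mat& Y) {
  const uword L = X.n_rows, d = X.n_cols;
  Xn.set_size(L, d);
  iv.set_size(L);
  Y.set_size(L, d);
  for (uword r = 0; r < L; ++r) {
    double mu = arma::mean(X.row(r));
    double va = arma::mean(arma::square(X.row(r) - mu));
    double ivr = 1.0 / std::sqrt(va + LN_EPS);
    iv(r) = ivr;
    Xn.row(r) = (X.row(r) - mu) * ivr;
    Y.row(r) = Xn.row(r) % g.t() + b.t();
  }
}

static void ln_backward(const mat& dY, const mat& Xn, const vec& iv,
                        const vec& g, mat& dX, vec& dg, vec& db) {
  const uword L = dY.n_rows, d = dY.n_cols;
  dX.set_size(L, d);
  for (uword r = 0; r < L; ++r) {
    dg += (dY.row(r) % Xn.row(r)).t();
    db += dY.row(r).t();
    rowvec dxn = dY.row(r) % g.t();
    double m1 = arma::mean(dxn);
    double m2 = arma::mean(dxn % Xn.row(r));
    dX.row(r) = iv(r) * (dxn - m1 - Xn.row(r) * m2);
  }
}

static mat get_mat(const List& params, const std::string& nm) {
  NumericMatrix M = params[nm];
  return mat(M.begin(), M.nrow(), M.ncol());
}

static vec get_vec(const List& params, const std::string& nm) {
  NumericVector v = params[nm];
  return vec(v.begin(), v.size());
}

// Dihedral-group pixel map for 64x64 augmentation. code = r + 4*f:
// rotate r times by 90 degrees, then (if f) flip rows.
static inline void aug_map(int code, int n, int i, int j, int& si, int& sj) {
  si = i; sj = j;
  int r = code % 4;
  for (int t = 0; t < r; ++t) {
    int ti = si;
    si = sj;
    sj = n - 1 - ti;
  }
  if (code >= 4) si = n - 1 - si;
}

// cached source-index tables (dst pixel -> src pixel) for the 8 group elements
static const int* aug_table(int code) {
  static std::vector<std::vector<int>> tab;
  if (tab.empty()) {
    tab.assign(8, std::vector<int>(64 * 64));
    for (int c = 0; c < 8; ++c)
      for (int j = 0; j < 64; ++j)
        for (int i = 0; i < 64; ++i) {
          int si, sj;
          aug_map(c, 64, i, j, si, sj);
          tab[c][i + 64 * j] = si + 64 * sj;
        }
  }
  return tab[code].data();
}

// ---------------------------------------------------------------------------
// losses
// ---------------------------------------------------------------------------

// d/dp of the focal NLL term (1-p)^gamma * (-log p)
static inline double focal_fprime(double p, double gamma) {
  p = std::min(std::max(p, 1e-12), 1.0);
  double q = 1.0 - p;
  double t1 = 0.0;
  if (gamma > 0.0 && q > 1e-15) t1 = gamma * std::pow(q, gamma - 1.0) * std::log(p);
  return t1 - std::pow(q, gamma) / p;
}

static inline double focal_f(double p, double gamma) {
  p = std::min(std::max(p, 1e-12), 1.0);
  return std::pow(1.0 - p, gamma) * (-std::log(p));
}

// Symmetric focal CLIP contrastive loss on N matched (image, text) pairs.
// Rows of I and T are L2-normalized, S = I_hat T_hat' / tau, row softmax on
// both S and S', focal NLL against the diagonal, averaged over both sides.
static void focal_clip_core(const mat& I, const mat& T, double gamma, double tau,
                            double& loss, mat& dI, mat& dT, double& dtau,
                            int& n_guard, bool want_grads) {
  const uword N = I.n_rows;
  n_guard = 0;

  vec nI(N), nT(N);
  mat Ih(N, I.n_cols), Th(N, T.n_cols);
  for (uword i = 0; i < N; ++i) {
    double a = arma::norm(I.row(i), 2);
    double b = arma::norm(T.row(i), 2);
    if (a < 1e-12) { a = 1e-12; ++n_guard; }
    if (b < 1e-12) { b = 1e-12; ++n_guard; }
    nI(i) = a; nT(i) = b;
    Ih.row(i) = I.row(i) / a;
    Th.row(i) = T.row(i) / b;
  }

  mat S = (Ih * Th.t()) / tau;
  mat P1 = S;  softmax_rows(P1);
  mat P2 = S.t(); softmax_rows(P2);

  double L1 = 0.0, L2 = 0.0;
  for (uword i = 0; i < N; ++i) {
    L1 += focal_f(P1(i, i), gamma);
    L2 += focal_f(P2(i, i), gamma);
  }
  L1 /= N; L2 /= N;
  loss = 0.5 * (L1 + L2);

  if (!want_grads) return;

  // dL/dS: for each softmax row, f'(p_t) * p_t * (delta - P_row)
  mat G(N, N, arma::fill::zeros);
  for (uword i = 0; i < N; ++i) {
    double p = P1(i, i);
    double c = 0.5 * focal_fprime(p, gamma) * p / N;
    for (uword j = 0; j < N; ++j)
      G(i, j) += c * ((j == i ? 1.0 : 0.0) - P1(i, j));
    double q = P2(i, i);
    double c2 = 0.5 * focal_fprime(q, gamma) * q / N;
    for (uword j = 0; j < N; ++j)
      G(j, i) += c2 * ((j == i ? 1.0 : 0.0) - P2(i, j));
  }

  mat dIh = (G * Th) / tau;
  mat dTh = (G.t() * Ih) / tau;
  dtau = -arma::accu(G % S) / tau;

  dI.set_size(arma::size(I));
  dT.set_size(arma::size(T));
  for (uword i = 0; i < N; ++i) {
    rowvec gi = dIh.row(i);
    dI.row(i) = (gi - arma::dot(gi, Ih.row(i)) * Ih.row(i)) / nI(i);
    rowvec gt = dTh.row(i);
    dT.row(i) = (gt - arma::dot(gt, Th.row(i)) * Th.row(i)) / nT(i);
  }
}

// [[Rcpp::export]]
List cpp_focal_clip(const arma::mat& I, const arma::mat& T, double gamma,
                    double tau, bool want_grads = true) {
  double loss = 0.0, dtau = 0.0;
  mat dI, dT;
  int n_guard = 0;
  focal_clip_core(I, T, gamma, tau, loss, dI, dT, dtau, n_guard, want_grads);
  if (!want_grads)
    return List::create(_["loss"] = loss, _["n_guarded"] = n_guard);
  return List::create(_["loss"] = loss, _["grad_I"] = dI, _["grad_T"] = dT,
                      _["grad_tau"] = dtau, _["n_guarded"] = n_guard);
}

// Mean binary cross-entropy over entries with wmask == 1, targets smoothed as
// t' = t (1 - s) + s/2, scores clamped to [eps, 1-eps] (clamped entries get
// zero gradient).
static void bce_core(const mat& S, const mat& Tt, const mat& W, double smooth,
                     double eps, double& loss, mat& dS, bool want_grads) {
  double acc = 0.0;
  uword n = 0;
  if (want_grads) dS.zeros(arma::size(S));
  for (uword idx = 0; idx < S.n_elem; ++idx) {
    if (W(idx) <= 0.0) continue;
    ++n;
    double tp = Tt(idx) * (1.0 - smooth) + smooth / 2.0;
    double s = S(idx);
    bool clamped = (s < eps) || (s > 1.0 - eps);
    double sc = std::min(std::max(s, eps), 1.0 - eps);
    acc += -(tp * std::log(sc) + (1.0 - tp) * std::log(1.0 - sc));
    if (want_grads && !clamped)
      dS(idx) = -tp / sc + (1.0 - tp) / (1.0 - sc);
  }
  if (n == 0) { loss = 0.0; return; }
  loss = acc / n;
  if (want_grads) dS /= (double)n;
}

// [[Rcpp::export]]
List cpp_bce_smoothed(const arma::mat& scores, const arma::mat& targets,
                      const arma::mat& wmask, double smoothing,
                      double eps = 1e-6, bool want_grads = true) {
  double loss = 0.0;
  mat dS;
  bce_core(scores, targets, wmask, smoothing, eps, loss, dS, want_grads);
  if (!want_grads) return List::create(_["loss"] = loss);
  return List::create(_["loss"] = loss, _["grad_scores"] = dS);
}

// Cross-entropy with uniform label smoothing over K classes; rows of `logits`
// are items, y is 0-based.
static void ce_core(const mat& logits, const arma::ivec& y, double smooth,
                    double& loss, mat& dL, bool want_grads) {
  const uword B = logits.n_rows, K = logits.n_cols;
  mat P = logits;
  softmax_rows(P);
  loss = 0.0;
  if (want_grads) dL.set_size(B, K);
  for (uword b = 0; b < B; ++b) {
    for (uword k = 0; k < K; ++k) {
      double q = smooth / K + ((int)k == y(b) ? 1.0 - smooth : 0.0);
      double p = std::max(P(b, k), 1e-12);
      loss += -q * std::log(p);
      if (want_grads) dL(b, k) = (P(b, k) - q) / B;
    }
  }
  loss /= B;
}

// [[Rcpp::export]]
List cpp_ce_smoothed(const arma::mat& logits, const arma::ivec& y,
                     double smoothing, bool want_grads = true) {
  double loss = 0.0;
  mat dL;
  ce_core(logits, y, smoothing, loss, dL, want_grads);
  if (!want_grads) return List::create(_["loss"] = loss);
  return List::create(_["loss"] = loss, _["grad_logits"] = dL);
}

// ---------------------------------------------------------------------------
// CNN plumbing
// ---------------------------------------------------------------------------

static inline int conv_out(int H, int stride) {
  return (H + 2 - 3) / stride + 1;
}

// im2col for N images held in Y (C, Hin*Win*N); kernel 3x3, pad 1.
// Row layout of M: o*C + c with kernel offset o = dj*3 + di, so each offset
// occupies a contiguous block of C rows (the matching weight layout is used
// throughout; only internal consistency matters).
static void im2col(const mat& Y, int C, int H, int W, int N, int stride,
                   mat& M, int& Ho, int& Wo) {
  Ho = conv_out(H, stride);
  Wo = conv_out(W, stride);
  const int P = Ho * Wo, Pin = H * W;
  M.set_size(9 * C, (uword)P * N);
  const double* y = Y.memptr();
  double* m = M.memptr();
  const uword MR = 9 * C;
  for (int g = 0; g < N; ++g) {
    const double* yg = y + (uword)C * Pin * g;
    double* mg = m + MR * (uword)P * g;
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int o = dj * 3 + di;
        for (int oj = 0; oj < Wo; ++oj) {
          const int jj = oj * stride - 1 + dj;
          double* mcol = mg + MR * (uword)(Ho * oj) + (uword)o * C;
          if (jj < 0 || jj >= W) {
            for (int oi = 0; oi < Ho; ++oi, mcol += MR)
              std::memset(mcol, 0, sizeof(double) * C);
            continue;
          }
          const double* ycol = yg + (uword)C * (H * jj);
          for (int oi = 0; oi < Ho; ++oi, mcol += MR) {
            const int ii = oi * stride - 1 + di;
            if (ii < 0 || ii >= H)
              std::memset(mcol, 0, sizeof(double) * C);
            else
              std::memcpy(mcol, ycol + (uword)C * ii, sizeof(double) * C);
          }
        }
      }
    }
  }
}

static void col2im(const mat& dM, int C, int H, int W, int N, int stride,
                   mat& dY) {
  const int Ho = conv_out(H, stride), Wo = conv_out(W, stride);
  const int P = Ho * Wo, Pin = H * W;
  dY.zeros(C, (uword)Pin * N);
  const double* m = dM.memptr();
  double* y = dY.memptr();
  const uword MR = 9 * C;
  for (int g = 0; g < N; ++g) {
    double* yg = y + (uword)C * Pin * g;
    const double* mg = m + MR * (uword)P * g;
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int o = dj * 3 + di;
        for (int oj = 0; oj < Wo; ++oj) {
          const int jj = oj * stride - 1 + dj;
          if (jj < 0 || jj >= W) continue;
          const double* mcol = mg + MR * (uword)(Ho * oj) + (uword)o * C;
          double* ycol = yg + (uword)C * (H * jj);
          for (int oi = 0; oi < Ho; ++oi, mcol += MR) {
            const int ii = oi * stride - 1 + di;
            if (ii < 0 || ii >= H) continue;
            double* dst = ycol + (uword)C * ii;
            for (int c = 0; c < C; ++c) dst[c] += mcol[c];
          }
        }
      }
    }
  }
}

struct ConvCache {
  mat M;       // im2col of the layer input
  mat Z;       // pre-activation
  mat Sg;      // sigmoid(Z), cached for the SiLU backward
  mat A;       // post-SiLU (input to batch norm)
  vec bmean, bvar, ivar;  // normalization statistics used
  int Hin, Win, Hout, Wout;
};

// ---------------------------------------------------------------------------
// full model: fused forward (+ optional losses and backward)
// ---------------------------------------------------------------------------

struct TfCache {
  mat x;           // layer input (L, d)
  mat xn1; vec iv1;
  mat Q, K, V;
  cube A;          // (L, L, n_heads)
  mat Ocat;        // concatenated head outputs, pre-Wo
  mat h1;          // after attention residual
  mat xn2; vec iv2;
  mat f1;          // feed-forward pre-activation (L, ff)
};

// [[Rcpp::export]]
List cpp_model_run(List params, List cfg,
                   NumericVector patch_store,
                   IntegerVector img_off, IntegerVector img_item,
                   IntegerVector img_slot, IntegerVector img_aug,
                   int n_items,
                   NumericVector Tm, IntegerVector Tm_dim,
                   const arma::mat& Ty,
                   const arma::mat& pos_t, const arma::mat& pos_lab,
                   IntegerVector mod_y,
                   List loss_cfg,
                   bool training, bool want_grads,
                   double bn_momentum = 0.1) {
  const arma::ivec widths = as<arma::ivec>(cfg["cnn_widths"]);
  const arma::ivec strides = as<arma::ivec>(cfg["cnn_strides"]);
  const int n_conv = widths.n_elem;
  const int d = as<int>(cfg["d_model"]);
  const int n_tf = as<int>(cfg["n_layers"]);
  const int nh = as<int>(cfg["n_heads"]);
  const int ff = as<int>(cfg["ff_dim"]);
  const int n_mod = as<int>(cfg["n_modalities"]);
  const int pos_mode = as<int>(cfg["pos_mode"]);  // 0 = max-rescale, 1 = sum
  const int pool_in = cfg.containsElementNamed("pool_in") ?
      as<int>(cfg["pool_in"]) : 1;  // average-pool factor on encoder input
  const int dh = d / nh;
  const int H0 = 64 / pool_in;
  if (n_tf < 1) stop("at least one transformer layer is required");

  Prof prof;
  const int d_raw = Tm_dim[0], C_max = Tm_dim[1], B = n_items;
  const int N = img_off.size();

  const double w_cls = as<double>(loss_cfg["w_cls"]);
  const double w_pos = as<double>(loss_cfg["w_pos"]);
  const double lambda = as<double>(loss_cfg["lambda"]);
  const double gamma = as<double>(loss_cfg["gamma"]);
  const double smooth_pos = as<double>(loss_cfg["smooth_pos"]);
  const double smooth_mod = as<double>(loss_cfg["smooth_mod"]);
  const double eps_clip = as<double>(loss_cfg["eps_clip"]);

  const bool do_cls = w_cls > 0.0 && Ty.n_rows == (uword)B;
  const bool do_pos = w_pos > 0.0 && pos_lab.n_elem > 0 &&
                      arma::accu(pos_lab) > 0;
  const bool do_adv = mod_y.size() == B && n_mod >= 2;

  // ---- gather + augment (+ optional average-pool) into layer-1 input ------
  const int P0 = H0 * H0;
  mat X0(3, (uword)P0 * N);
  const double* store = patch_store.begin();
  for (int g = 0; g < N; ++g) {
    const uword off = (uword)img_off[g];
    const int* map = aug_table(img_aug[g]);
    for (int p = 0; p < 3; ++p) {
      const double* src = store + off + (uword)4096 * p;
      double* dst = X0.memptr() + p;
      const uword base = (uword)P0 * g;
      if (pool_in == 1) {
        for (int q = 0; q < 4096; ++q)
          dst[3 * (base + q)] = src[map[q]];
      } else {
        const int k = pool_in;
        const double inv = 1.0 / (k * k);
        for (int j = 0; j < H0; ++j)
          for (int i = 0; i < H0; ++i) {
            double s = 0.0;
            for (int bj = 0; bj < k; ++bj)
              for (int bi = 0; bi < k; ++bi)
                s += src[map[(k * i + bi) + 64 * (k * j + bj)]];
            dst[3 * (base + i + H0 * j)] = s * inv;
          }
      }
    }
  }

prof.tick("gather");
  // ---- CNN forward --------------------------------------------------------
  std::vector<ConvCache> cc(n_conv);
  List bn_upd;
  mat Ycur = X0;
  int H = H0, W = H0, Cin = 3;
  arma::ivec spatial(n_conv);
  for (int l = 0; l < n_conv; ++l) {
    char nm[32];
    std::snprintf(nm, sizeof(nm), "cnn_W%d", l + 1);
    mat Wl = get_mat(params, nm);
    std::snprintf(nm, sizeof(nm), "cnn_b%d", l + 1);
    vec bl = get_vec(params, nm);
    std::snprintf(nm, sizeof(nm), "bn_g%d", l + 1);
    vec gl = get_vec(params, nm);
    std::snprintf(nm, sizeof(nm), "bn_b%d", l + 1);
    vec bb = get_vec(params, nm);

    ConvCache& c = cc[l];
    c.Hin = H; c.Win = W;
    im2col(Ycur, Cin, H, W, N, strides(l), c.M, c.Hout, c.Wout);
    c.Z = Wl * c.M;
    c.Z.each_col() += bl;

    // fused SiLU + moment accumulation (single pass)
    const uword nr = c.Z.n_rows, ncol = c.Z.n_cols;
    c.Sg.set_size(nr, ncol);
    c.A.set_size(nr, ncol);
    vec s1(nr, arma::fill::zeros), s2(nr, arma::fill::zeros);
    {
      const double* z = c.Z.memptr();
      double* sg = c.Sg.memptr();
      double* a = c.A.memptr();
      double* q1 = s1.memptr();
      double* q2 = s2.memptr();
      for (uword col = 0; col < ncol; ++col) {
        const uword o = col * nr;
        for (uword r = 0; r < nr; ++r) {
          const double zz = z[o + r];
          const double s = 1.0 / (1.0 + std::exp(-zz));
          const double av = zz * s;
          sg[o + r] = s;
          a[o + r] = av;
          q1[r] += av;
          q2[r] += av * av;
        }
      }
    }

    const double Mn = (double)ncol;
    if (training) {
      c.bmean = s1 / Mn;
      c.bvar = s2 / Mn - arma::square(c.bmean);
      c.bvar.transform([](double v) { return v < 0 ? 0 : v; });
      std::snprintf(nm, sizeof(nm), "bn_m%d", l + 1);
      vec rm = get_vec(params, nm);
      std::snprintf(nm, sizeof(nm), "bn_v%d", l + 1);
      vec rv = get_vec(params, nm);
      double ub = Mn > 1 ? Mn / (Mn - 1.0) : 1.0;
      rm = (1.0 - bn_momentum) * rm + bn_momentum * c.bmean;
      rv = (1.0 - bn_momentum) * rv + bn_momentum * (c.bvar * ub);
      std::snprintf(nm, sizeof(nm), "bn_m%d", l + 1);
      bn_upd[std::string(nm)] = NumericVector(rm.begin(), rm.end());
      std::snprintf(nm, sizeof(nm), "bn_v%d", l + 1);
      bn_upd[std::string(nm)] = NumericVector(rv.begin(), rv.end());
    } else {
      std::snprintf(nm, sizeof(nm), "bn_m%d", l + 1);
      c.bmean = get_vec(params, nm);
      std::snprintf(nm, sizeof(nm), "bn_v%d", l + 1);
      c.bvar = get_vec(params, nm);
    }
    c.ivar = 1.0 / arma::sqrt(c.bvar + BN_EPS);

    vec sc = gl % c.ivar;
    vec sh = bb - c.bmean % sc;
    Ycur = c.A;
    Ycur.each_col() %= sc;
    Ycur.each_col() += sh;

    H = c.Hout; W = c.Wout; Cin = widths(l);
    spatial(l) = H;
  }

prof.tick("cnn_fwd");
  // global average pool + linear projection to d_model
  const int Plast = H * W;
  const int Clast = Cin;
  mat E(Clast, N);
  for (int g = 0; g < N; ++g)
    E.col(g) = arma::mean(Ycur.cols((uword)Plast * g, (uword)Plast * (g + 1) - 1), 1);
  mat img_W = get_mat(params, "img_W");
  vec img_b = get_vec(params, "img_b");
  mat ImgEmb = img_W * E;
  ImgEmb.each_col() += img_b;

prof.tick("gap");
  // ---- text projection of marker embeddings -------------------------------
  mat txt_W = get_mat(params, "txt_W");
  vec txt_b = get_vec(params, "txt_b");
  mat TmFlat(d_raw, N);
  const double* tm = Tm.begin();
  for (int g = 0; g < N; ++g) {
    const uword base = ((uword)img_item[g] * C_max + img_slot[g]) * d_raw;
    TmFlat.col(g) = vec(const_cast<double*>(tm + base), d_raw);
  }
  mat TxtEmb = txt_W * TmFlat;
  TxtEmb.each_col() += txt_b;

prof.tick("txt");
  // ---- assemble token sequences -------------------------------------------
  vec cls_tok = get_vec(params, "cls_tok");
  std::vector<std::vector<int>> imgs_of(B);   // image indices per item
  for (int g = 0; g < N; ++g) imgs_of[img_item[g]].push_back(g);

  std::vector<mat> tokens(B);
  for (int b = 0; b < B; ++b) {
    const int Lb = 1 + (int)imgs_of[b].size();
    if (Lb < 2) stop("batch item %d has no real channels", b + 1);
    mat x(Lb, d);
    x.row(0) = cls_tok.t();
    for (int k = 1; k < Lb; ++k) {
      int g = imgs_of[b][k - 1];
      x.row(k) = (ImgEmb.col(g) + TxtEmb.col(g)).t();
    }
    tokens[b] = x;
  }

prof.tick("tokens");
  // ---- transformer forward ------------------------------------------------
  std::vector<std::vector<TfCache>> tc(B, std::vector<TfCache>(n_tf));
  std::vector<mat> h2fin(B), hf(B), xnf(B);
  std::vector<vec> ivf(B);
  const double scl = 1.0 / std::sqrt((double)dh);

  std::vector<mat> Wq(n_tf), Wk(n_tf), Wv(n_tf), Wo(n_tf), F1(n_tf), F2(n_tf);
  std::vector<vec> bq(n_tf), bk(n_tf), bv(n_tf), bo(n_tf), b1(n_tf), b2(n_tf),
      l1g(n_tf), l1b(n_tf), l2g(n_tf), l2b(n_tf);
  for (int l = 0; l < n_tf; ++l) {
    char nm[32];
    std::snprintf(nm, sizeof(nm), "tf%d_", l + 1);
    std::string p(nm);
    Wq[l] = get_mat(params, p + "Wq"); bq[l] = get_vec(params, p + "bq");
    Wk[l] = get_mat(params, p + "Wk"); bk[l] = get_vec(params, p + "bk");
    Wv[l] = get_mat(params, p + "Wv"); bv[l] = get_vec(params, p + "bv");
    Wo[l] = get_mat(params, p + "Wo"); bo[l] = get_vec(params, p + "bo");
    F1[l] = get_mat(params, p + "ff1_W"); b1[l] = get_vec(params, p + "ff1_b");
    F2[l] = get_mat(params, p + "ff2_W"); b2[l] = get_vec(params, p + "ff2_b");
    l1g[l] = get_vec(params, p + "ln1_g"); l1b[l] = get_vec(params, p + "ln1_b");
    l2g[l] = get_vec(params, p + "ln2_g"); l2b[l] = get_vec(params, p + "ln2_b");
  }
  vec lnf_g = get_vec(params, "lnf_g"), lnf_b = get_vec(params, "lnf_b");

  mat attn_raw(B, C_max);
  attn_raw.fill(arma::datum::nan);

  for (int b = 0; b < B; ++b) {
    mat x = tokens[b];
    const int Lb = x.n_rows;
    for (int l = 0; l < n_tf; ++l) {
      TfCache& c = tc[b][l];
      c.x = x;
      mat xn1y;
      ln_forward(x, l1g[l], l1b[l], c.xn1, c.iv1, xn1y);
      c.Q = xn1y * Wq[l].t(); c.Q.each_row() += bq[l].t();
      c.K = xn1y * Wk[l].t(); c.K.each_row() += bk[l].t();
      c.V = xn1y * Wv[l].t(); c.V.each_row() += bv[l].t();
      c.A.set_size(Lb, Lb, nh);
      c.Ocat.set_size(Lb, d);
      for (int h = 0; h < nh; ++h) {
        mat Qh = c.Q.cols(h * dh, (h + 1) * dh - 1);
        mat Kh = c.K.cols(h * dh, (h + 1) * dh - 1);
        mat Vh = c.V.cols(h * dh, (h + 1) * dh - 1);
        mat S = Qh * Kh.t() * scl;
        softmax_rows(S);
        c.A.slice(h) = S;
        c.Ocat.cols(h * dh, (h + 1) * dh - 1) = S * Vh;
      }
      mat attn_out = c.Ocat * Wo[l].t();
      attn_out.each_row() += bo[l].t();
      c.h1 = x + attn_out;
      mat xn2y;
      ln_forward(c.h1, l2g[l], l2b[l], c.xn2, c.iv2, xn2y);
      c.f1 = xn2y * F1[l].t();
      c.f1.each_row() += b1[l].t();
      mat f2 = silu(c.f1) * F2[l].t();
      f2.each_row() += b2[l].t();
      x = c.h1 + f2;
    }
    h2fin[b] = x;
    mat y;
    ln_forward(x, lnf_g, lnf_b, xnf[b], ivf[b], y);
    hf[b] = y;

    // head-averaged [CLS] -> channel attention of the final layer
    const TfCache& cl = tc[b][n_tf - 1];
    for (int k = 1; k < (int)x.n_rows; ++k) {
      double a = 0.0;
      for (int h = 0; h < nh; ++h) a += cl.A(0, k, h);
      attn_raw(b, img_slot[imgs_of[b][k - 1]]) = a / nh;
    }
  }

prof.tick("tf_fwd");
  // ---- outputs -------------------------------------------------------------
  mat cls(d, B);
  cube chan_emb(d, C_max, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    cls.col(b) = hf[b].row(0).t();
    for (int k = 1; k < (int)hf[b].n_rows; ++k)
      chan_emb.slice(b).col(img_slot[imgs_of[b][k - 1]]) = hf[b].row(k).t();
  }

  // positivity scores from attention
  mat posit(B, C_max);
  posit.fill(arma::datum::nan);
  vec pos_denom(B, arma::fill::ones);
  arma::ivec argmax_slot(B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    double mx = -1.0, sm = 0.0;
    int js = -1;
    for (const int g : imgs_of[b]) {
      double a = attn_raw(b, img_slot[g]);
      sm += a;
      if (a > mx) { mx = a; js = img_slot[g]; }
    }
    double den = (pos_mode == 0) ? mx : sm;
    if (den <= 0) den = 1e-12;
    pos_denom(b) = den;
    argmax_slot(b) = js;
    for (const int g : imgs_of[b])
      posit(b, img_slot[g]) = attn_raw(b, img_slot[g]) / den;
  }

  // modality head (forward pass is identical with or without reversal)
  mat mod_W1, mod_W2, mod_W3;
  vec mod_b1, mod_b2, mod_b3;
  mat mz1, mz2, mod_logits;
  mod_W1 = get_mat(params, "mod_W1"); mod_b1 = get_vec(params, "mod_b1");
  mod_W2 = get_mat(params, "mod_W2"); mod_b2 = get_vec(params, "mod_b2");
  mod_W3 = get_mat(params, "mod_W3"); mod_b3 = get_vec(params, "mod_b3");
  mz1 = mod_W1 * cls; mz1.each_col() += mod_b1;
  mat ma1 = silu(mz1);
  mz2 = mod_W2 * ma1; mz2.each_col() += mod_b2;
  mat ma2 = silu(mz2);
  mod_logits = mod_W3 * ma2; mod_logits.each_col() += mod_b3;

prof.tick("outputs");
  // ---- losses --------------------------------------------------------------
  double tau = std::exp(get_vec(params, "log_tau")(0));
  double L_cls = 0.0, L_pos = 0.0, L_adv = 0.0;
  mat dZc_cls, dTtxt, dPos, dAdvLogits;
  double dtau = 0.0;
  int n_guard = 0;
  mat Ttxt;

  if (do_cls) {
    Ttxt = Ty * txt_W.t();
    Ttxt.each_row() += txt_b.t();
    focal_clip_core(cls.t(), Ttxt, gamma, tau, L_cls, dZc_cls, dTtxt, dtau,
                    n_guard, want_grads);
  }
  if (do_pos) {
    mat pscore = posit;
    pscore.replace(arma::datum::nan, 0.0);
    bce_core(pscore, pos_t, pos_lab, smooth_pos, eps_clip, L_pos, dPos,
             want_grads);
  }
  if (do_adv) {
    arma::ivec yv(B);
    for (int b = 0; b < B; ++b) yv(b) = mod_y[b];
    ce_core(mod_logits.t(), yv, smooth_mod, L_adv, dAdvLogits, want_grads);
  }
  double L_tot = w_cls * L_cls + w_pos * L_pos + lambda * L_adv;

  List out = List::create(
      _["cls"] = cls, _["channel_emb"] = chan_emb,
      _["attn_raw"] = attn_raw, _["positivity"] = posit,
      _["mod_logits"] = mod_logits,
      _["loss_cls"] = L_cls, _["loss_pos"] = L_pos, _["loss_adv"] = L_adv,
      _["loss_total"] = L_tot, _["tau"] = tau,
      _["cnn_spatial"] = IntegerVector(spatial.begin(), spatial.end()),
      _["n_guarded"] = n_guard);
  if (training) out["bn_updates"] = bn_upd;
  if (!want_grads) return out;

prof.tick("losses");
  // =========================================================================
  // backward
  // =========================================================================
  std::map<std::string, mat> G;
  auto acc = [&](const std::string& nm, const mat& g) {
    auto it = G.find(nm);
    if (it == G.end()) G[nm] = g; else it->second += g;
  };

  // gradient reaching each item's final-LN output rows
  mat dcls(d, B, arma::fill::zeros);
  if (do_cls) dcls += w_cls * dZc_cls.t();

  // Modality head backward. The reversal layer sits between the trunk and
  // the MLP: head parameters train on the plain (unscaled) classification
  // gradient, while the gradient entering the trunk is negated and scaled
  // by the ramp weight lambda.
  if (do_adv) {
    mat dlog = dAdvLogits.t();  // (n_mod, B)
    acc("mod_W3", dlog * ma2.t());
    acc("mod_b3", arma::sum(dlog, 1));
    mat da2 = mod_W3.t() * dlog;
    mat dz2 = da2 % silu_grad(mz2);
    acc("mod_W2", dz2 * ma1.t());
    acc("mod_b2", arma::sum(dz2, 1));
    mat da1 = mod_W2.t() * dz2;
    mat dz1 = da1 % silu_grad(mz1);
    acc("mod_W1", dz1 * cls.t());
    acc("mod_b1", arma::sum(dz1, 1));
    dcls += (-lambda) * (mod_W1.t() * dz1);   // gradient reversal
  }

  // text-side CLIP gradient -> projection parameters
  if (do_cls) {
    acc("txt_W", w_cls * (dTtxt.t() * Ty));
    acc("txt_b", w_cls * arma::sum(dTtxt.t(), 1));
    acc("log_tau", mat(1, 1, arma::fill::value(w_cls * dtau * tau)));
  }

  // positivity loss gradient w.r.t. raw head-mean attention, per item/slot
  mat dAraw(B, C_max, arma::fill::zeros);
  if (do_pos) {
    for (int b = 0; b < B; ++b) {
      double den = pos_denom(b);
      double corr = 0.0;
      for (const int g : imgs_of[b]) {
        int s = img_slot[g];
        corr += dPos(b, s) * attn_raw(b, s) / (den * den);
      }
      for (const int g : imgs_of[b]) {
        int s = img_slot[g];
        dAraw(b, s) = w_pos * dPos(b, s) / den;
      }
      if (pos_mode == 0) {
        dAraw(b, argmax_slot(b)) -= w_pos * corr;
      } else {
        for (const int g : imgs_of[b]) dAraw(b, img_slot[g]) -= w_pos * corr;
      }
    }
  }

prof.tick("head_bwd");
  // transformer backward (per item, layers in reverse)
  mat dImgEmb(d, N, arma::fill::zeros);
  mat dTxtFlat(d, N, arma::fill::zeros);
  vec dcls_tok(d, arma::fill::zeros);

  vec g_lnf_g(d, arma::fill::zeros), g_lnf_b(d, arma::fill::zeros);
  std::vector<mat> gWq(n_tf, mat(d, d, arma::fill::zeros)),
      gWk(n_tf, mat(d, d, arma::fill::zeros)),
      gWv(n_tf, mat(d, d, arma::fill::zeros)),
      gWo(n_tf, mat(d, d, arma::fill::zeros)),
      gF1(n_tf, mat(ff, d, arma::fill::zeros)),
      gF2(n_tf, mat(d, ff, arma::fill::zeros));
  std::vector<vec> gbq(n_tf, vec(d, arma::fill::zeros)),
      gbk(n_tf, vec(d, arma::fill::zeros)),
      gbv(n_tf, vec(d, arma::fill::zeros)),
      gbo(n_tf, vec(d, arma::fill::zeros)),
      gb1(n_tf, vec(ff, arma::fill::zeros)),
      gb2(n_tf, vec(d, arma::fill::zeros)),
      gl1g(n_tf, vec(d, arma::fill::zeros)),
      gl1b(n_tf, vec(d, arma::fill::zeros)),
      gl2g(n_tf, vec(d, arma::fill::zeros)),
      gl2b(n_tf, vec(d, arma::fill::zeros));

  for (int b = 0; b < B; ++b) {
    const int Lb = h2fin[b].n_rows;
    mat dhf(Lb, d, arma::fill::zeros);
    dhf.row(0) = dcls.col(b).t();
    mat dx;
    ln_backward(dhf, xnf[b], ivf[b], lnf_g, dx, g_lnf_g, g_lnf_b);

    for (int l = n_tf - 1; l >= 0; --l) {
      TfCache& c = tc[b][l];
      // feed-forward branch
      mat dh2 = dx;
      mat df2 = dh2;
      mat a1 = silu(c.f1);
      gF2[l] += df2.t() * a1;
      gb2[l] += arma::sum(df2, 0).t();
      mat da1 = df2 * F2[l];
      mat df1 = da1 % silu_grad(c.f1);
      mat xn2y = c.xn2;
      xn2y.each_row() %= l2g[l].t();
      xn2y.each_row() += l2b[l].t();
      gF1[l] += df1.t() * xn2y;
      gb1[l] += arma::sum(df1, 0).t();
      mat dxn2y = df1 * F1[l];
      mat dh1;
      ln_backward(dxn2y, c.xn2, c.iv2, l2g[l], dh1, gl2g[l], gl2b[l]);
      dh1 += dh2;   // residual

      // attention branch
      mat dattn = dh1;
      gWo[l] += dattn.t() * c.Ocat;
      gbo[l] += arma::sum(dattn, 0).t();
      mat dO = dattn * Wo[l];
      mat dQ(Lb, d, arma::fill::zeros), dK(Lb, d, arma::fill::zeros),
          dV(Lb, d, arma::fill::zeros);
      for (int h = 0; h < nh; ++h) {
        mat dOh = dO.cols(h * dh, (h + 1) * dh - 1);
        mat Ah = c.A.slice(h);
        mat Vh = c.V.cols(h * dh, (h + 1) * dh - 1);
        mat dAh = dOh * Vh.t();
        if (l == n_tf - 1 && do_pos) {
          for (int k = 1; k < Lb; ++k)
            dAh(0, k) += dAraw(b, img_slot[imgs_of[b][k - 1]]) / nh;
        }
        // softmax rows backward
        mat dS(Lb, Lb);
        for (int r = 0; r < Lb; ++r) {
          double dot = arma::dot(dAh.row(r), Ah.row(r));
          dS.row(r) = Ah.row(r) % (dAh.row(r) - dot);
        }
        dS *= scl;
        mat Qh = c.Q.cols(h * dh, (h + 1) * dh - 1);
        mat Kh = c.K.cols(h * dh, (h + 1) * dh - 1);
        dQ.cols(h * dh, (h + 1) * dh - 1) = dS * Kh;
        dK.cols(h * dh, (h + 1) * dh - 1) = dS.t() * Qh;
        dV.cols(h * dh, (h + 1) * dh - 1) = Ah.t() * dOh;
      }
      mat xn1y = c.xn1;
      xn1y.each_row() %= l1g[l].t();
      xn1y.each_row() += l1b[l].t();
      gWq[l] += dQ.t() * xn1y; gbq[l] += arma::sum(dQ, 0).t();
      gWk[l] += dK.t() * xn1y; gbk[l] += arma::sum(dK, 0).t();
      gWv[l] += dV.t() * xn1y; gbv[l] += arma::sum(dV, 0).t();
      mat dxn1y = dQ * Wq[l] + dK * Wk[l] + dV * Wv[l];
      mat dxa;
      ln_backward(dxn1y, c.xn1, c.iv1, l1g[l], dxa, gl1g[l], gl1b[l]);
      dx = dh1 + dxa;   // residual into the layer input
    }

    dcls_tok += dx.row(0).t();
    for (int k = 1; k < Lb; ++k) {
      int g = imgs_of[b][k - 1];
      dImgEmb.col(g) += dx.row(k).t();
      dTxtFlat.col(g) += dx.row(k).t();
    }
  }

  acc("lnf_g", g_lnf_g); acc("lnf_b", g_lnf_b);
  acc("cls_tok", dcls_tok);
  for (int l = 0; l < n_tf; ++l) {
    char nm[32];
    std::snprintf(nm, sizeof(nm), "tf%d_", l + 1);
    std::string p(nm);
    acc(p + "Wq", gWq[l]); acc(p + "bq", gbq[l]);
    acc(p + "Wk", gWk[l]); acc(p + "bk", gbk[l]);
    acc(p + "Wv", gWv[l]); acc(p + "bv", gbv[l]);
    acc(p + "Wo", gWo[l]); acc(p + "bo", gbo[l]);
    acc(p + "ff1_W", gF1[l]); acc(p + "ff1_b", gb1[l]);
    acc(p + "ff2_W", gF2[l]); acc(p + "ff2_b", gb2[l]);
    acc(p + "ln1_g", gl1g[l]); acc(p + "ln1_b", gl1b[l]);
    acc(p + "ln2_g", gl2g[l]); acc(p + "ln2_b", gl2b[l]);
  }

prof.tick("tf_bwd");
  // text projection from marker tokens
  acc("txt_W", dTxtFlat * TmFlat.t());
  acc("txt_b", arma::sum(dTxtFlat, 1));

  // image projection + GAP
  acc("img_W", dImgEmb * E.t());
  acc("img_b", arma::sum(dImgEmb, 1));
  mat dE = img_W.t() * dImgEmb;
  mat dY(Clast, (uword)Plast * N);
  for (int g = 0; g < N; ++g) {
    mat rep = arma::repmat(dE.col(g) / (double)Plast, 1, Plast);
    dY.cols((uword)Plast * g, (uword)Plast * (g + 1) - 1) = rep;
  }

prof.tick("proj_bwd");
  // CNN backward
  H = 64; W = 64;
  for (int l = n_conv - 1; l >= 0; --l) {
    ConvCache& c = cc[l];
    char nm[32];
    std::snprintf(nm, sizeof(nm), "bn_g%d", l + 1);
    vec gl = get_vec(params, nm);
    std::snprintf(nm, sizeof(nm), "cnn_W%d", l + 1);
    mat Wl = get_mat(params, nm);

    // fused batch-norm + SiLU backward (two passes)
    const uword nr = dY.n_rows, ncol = dY.n_cols;
    const double Mn = (double)ncol;
    vec dgamma(nr, arma::fill::zeros), dbeta(nr, arma::fill::zeros);
    mat dZ(nr, ncol);
    {
      const double* dy = dY.memptr();
      const double* a = c.A.memptr();
      const double* mb = c.bmean.memptr();
      const double* iv = c.ivar.memptr();
      double* g1 = dgamma.memptr();
      double* g2 = dbeta.memptr();
      for (uword col = 0; col < ncol; ++col) {
        const uword o = col * nr;
        for (uword r = 0; r < nr; ++r) {
          const double d0 = dy[o + r];
          g1[r] += d0 * (a[o + r] - mb[r]) * iv[r];
          g2[r] += d0;
        }
      }
      // per-channel constants: dxhat sums follow from dgamma/dbeta
      const double* z = c.Z.memptr();
      const double* sg = c.Sg.memptr();
      const vec& gv = gl;
      double* dz = dZ.memptr();
      for (uword col = 0; col < ncol; ++col) {
        const uword o = col * nr;
        for (uword r = 0; r < nr; ++r) {
          const double g = gv(r);
          double da;
          if (training) {
            const double xh = (a[o + r] - mb[r]) * iv[r];
            da = (iv[r] / Mn) *
                 (Mn * g * dy[o + r] - g * g2[r] - xh * g * g1[r]);
          } else {
            da = g * iv[r] * dy[o + r];
          }
          const double s = sg[o + r];
          dz[o + r] = da * s * (1.0 + z[o + r] * (1.0 - s));
        }
      }
    }

    std::snprintf(nm, sizeof(nm), "bn_g%d", l + 1);
    acc(nm, dgamma);
    std::snprintf(nm, sizeof(nm), "bn_b%d", l + 1);
    acc(nm, dbeta);
    std::snprintf(nm, sizeof(nm), "cnn_W%d", l + 1);
    acc(nm, dZ * c.M.t());
    std::snprintf(nm, sizeof(nm), "cnn_b%d", l + 1);
    acc(nm, arma::sum(dZ, 1));

    if (l > 0) {
      mat dM = Wl.t() * dZ;
      int Cprev = widths(l - 1);
      col2im(dM, Cprev, c.Hin, c.Win, N, strides(l), dY);
    }
  }

prof.tick("cnn_bwd");
  List grads;
  for (auto& kv : G) {
    if (kv.second.n_cols == 1 && kv.first.rfind("cnn_W", 0) != 0 &&
        kv.first.rfind("img_W", 0) != 0)
      grads[kv.first] = NumericVector(kv.second.begin(), kv.second.end());
    else
      grads[kv.first] = wrap(kv.second);
  }
  out["grads"] = grads;
  {
    List pt;
    for (auto& kv : prof.t) pt[kv.first] = kv.second;
    out["prof"] = pt;
  }
  return out;
}
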