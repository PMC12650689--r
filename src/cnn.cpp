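// Minimal 1-D convolutional network trainer (three fixed architecture
// variants) with Adam. The feature vector is treated as a length-d,
// 1-channel sequence: conv1d with 64 kernels of width 3 (valid padding),
// ReLU, max-pool of width 2, dropout, and a dense head (one logistic unit
// for two classes, softmax otherwise); variants 2/3 insert a dense-128 ReLU
// stage with dropout on both sides of the pool/flatten block.
//
// Tensors are single precision (the deep-learning convention) with fused
// elementwise/pool/dropout loops; the matrix products go through BLAS.
// Reproducibility: epoch shuffles and initialization come from the R RNG;
// dropout masks from a xorshift128+ stream seeded from the R RNG per fit.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s0, s1;
  explicit XorShift(uint64_t seed) {
    uint64_t z = seed;
    auto nxt = [&z]() {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      return t ^ (t >> 31);
    };
    s0 = nxt(); s1 = nxt();
  }
  uint64_t nextu() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() { return (nextu() >> 11) * (1.0 / 9007199254740992.0); }
  // fill with inverted-dropout mask values (0 or 1/(1-p)); the common rates
  // 0.5 and 0.25 draw random bits, anything else draws per-element uniforms
  void mask(arma::fmat& m, double p) {
    const float scale = (float) (1.0 / (1.0 - p));
    float* q = m.memptr();
    const arma::uword n = m.n_elem;
    if (p == 0.5) {
      uint64_t bits = 0; int left = 0;
      for (arma::uword i = 0; i < n; ++i) {
        if (left == 0) { bits = nextu(); left = 64; }
        q[i] = (bits & 1ULL) ? 0.0f : scale;
        bits >>= 1; --left;
      }
    } else if (p == 0.25) {
      uint64_t bits = 0; int left = 0;
      for (arma::uword i = 0; i < n; ++i) {
        if (left == 0) { bits = nextu(); left = 32; }
        q[i] = ((bits & 3ULL) == 0ULL) ? 0.0f : scale;
        bits >>= 2; --left;
      }
    } else {
      for (arma::uword i = 0; i < n; ++i) q[i] = (unif() < p) ? 0.0f : scale;
    }
  }
};

struct Adam {
  arma::fmat m, v;
  void init(const arma::fmat& w) {
    m.zeros(w.n_rows, w.n_cols);
    v.zeros(w.n_rows, w.n_cols);
  }
  void step(arma::fmat& w, const arma::fmat& g, double lr, long t,
            double b1, double b2, double eps) {
    m = (float) b1 * m + (float) (1.0 - b1) * g;
    v = (float) b2 * v + (float) (1.0 - b2) * arma::square(g);
    const float c1 = (float) (1.0 - std::pow(b1, (double) t));
    const float c2 = (float) (1.0 - std::pow(b2, (double) t));
    w -= (float) lr * (m / c1) / (arma::sqrt(v / c2) + (float) eps);
  }
};

// lagged design matrix for a width-3 valid convolution (row index = b + B*i)
void lag3(const arma::fmat& Xb, int L, arma::fmat& M) {
  const int B = Xb.n_rows;
  M.set_size((arma::uword) B * L, 3);
  for (int k = 0; k < 3; ++k) {
    std::memcpy(M.colptr(k), Xb.colptr(k), sizeof(float) * (size_t) B * L);
  }
}

arma::mat probs_from_logits(const arma::mat& Z, int out_dim) {
  if (out_dim == 1) return 1.0 / (1.0 + arma::exp(-Z));
  arma::mat P = Z;
  P.each_col() -= arma::max(Z, 1);
  P = arma::exp(P);
  P.each_col() /= arma::sum(P, 1);
  return P;
}


arma::fmat as_fmat(SEXP s) {
  return arma::conv_to<arma::fmat>::from(as<arma::mat>(s));
}

// accepts plain numeric vectors as well as 1 x k matrices
arma::fmat as_frow(SEXP s) {
  NumericVector v(s);
  arma::fmat out(1, v.size());
  for (int i = 0; i < v.size(); ++i) out(0, i) = (float) v[i];
  return out;
}

} // namespace

// Forward pass without dropout; returns class probabilities (n x out_dim).
// [[Rcpp::export]]
arma::mat cnn_forward_cpp(const arma::mat& X, const List w, const int variant,
                          const int out_dim) {
  const arma::mat W1 = w["W1"];
  const arma::rowvec b1 = w["b1"];
  const arma::mat Wout = w["Wout"];
  const arma::rowvec bout = w["bout"];
  const int B = X.n_rows, d = X.n_cols;
  const int L = d - 2, Lp = L / 2;
  arma::mat M((arma::uword) B * L, 3);
  for (int k = 0; k < 3; ++k) {
    M.col(k) = arma::vectorise(X.cols(k, k + L - 1));
  }
  arma::mat A = M * W1;
  A.each_row() += b1;
  A.transform([](double z) { return z > 0.0 ? z : 0.0; });
  arma::mat P((arma::uword) B * Lp, 64);
  for (int f = 0; f < 64; ++f) {
    const double* a = A.colptr(f);
    double* p = P.colptr(f);
    for (int j = 0; j < Lp; ++j) {
      const double* a1 = a + (size_t) 2 * j * B;
      const double* a2 = a1 + B;
      double* pj = p + (size_t) j * B;
      for (int b = 0; b < B; ++b) pj[b] = std::max(a1[b], a2[b]);
    }
  }
  arma::mat F = arma::reshape(P, B, (arma::uword) Lp * 64);
  arma::mat Z;
  if (variant == 1) {
    Z = F * Wout;
  } else {
    const arma::mat Wd = w["Wd"];
    const arma::rowvec bd = w["bd"];
    arma::mat H = F * Wd;
    H.each_row() += bd;
    H.transform([](double z) { return z > 0.0 ? z : 0.0; });
    Z = H * Wout;
  }
  Z.each_row() += bout;
  return probs_from_logits(Z, out_dim);
}

// Train with Adam. y: integer labels in 0..out_dim-1 (0/1 for out_dim == 1).
// Returns fitted weights and the mean training loss per epoch.
// [[Rcpp::export]]
List cnn_train_cpp(const arma::mat& X, const IntegerVector y,
                   const int out_dim, const int variant, const int epochs,
                   const double lr, const int batch_size, const List w0,
                   const double p_conv, const double p_pool,
                   const double p_dense, const double beta1,
                   const double beta2, const double adam_eps) {
  const int n = X.n_rows, d = X.n_cols;
  const int L = d - 2, Lp = L / 2;
  const bool dense128 = variant != 1;
  const arma::fmat Xf = arma::conv_to<arma::fmat>::from(X);

  arma::fmat W1 = as_fmat(w0["W1"]);
  arma::fmat b1 = as_frow(w0["b1"]);
  arma::fmat Wout = as_fmat(w0["Wout"]);
  arma::fmat bout = as_frow(w0["bout"]);
  arma::fmat Wd, bd;
  if (dense128) {
    Wd = as_fmat(w0["Wd"]);
    bd = as_frow(w0["bd"]);
  }

  Adam aW1, ab1, aWd, abd, aWout, about;
  aW1.init(W1); ab1.init(b1); aWout.init(Wout); about.init(bout);
  if (dense128) { aWd.init(Wd); abd.init(bd); }

  XorShift xs((uint64_t) std::floor(unif_rand() * 9007199254740992.0));
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;

  arma::fmat Xb, M, A, Amask, P, Pmask, dF, dA, H, Hrelu, Hmask, Zf;
  arma::vec loss_hist(epochs);
  long t = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int) std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    double ep_loss = 0.0;
    for (int off = 0; off < n; off += batch_size) {
      const int B = std::min(batch_size, n - off);
      Xb.set_size(B, d);
      for (int i = 0; i < B; ++i) Xb.row(i) = Xf.row(perm[off + i]);

      // conv + bias + relu (A stored post-relu for the backward pass)
      lag3(Xb, L, M);
      A = M * W1;
      for (int f = 0; f < 64; ++f) {
        const float bf = b1(f);
        float* a = A.colptr(f);
        const size_t nBL = (size_t) B * L;
        for (size_t r = 0; r < nBL; ++r) {
          const float z = a[r] + bf;
          a[r] = z > 0.0f ? z : 0.0f;
        }
      }
      if (dense128 && p_conv > 0.0) {
        Amask.set_size(A.n_rows, A.n_cols);
        xs.mask(Amask, p_conv);
        A %= Amask;
      }
      // max-pool width 2 (pairs are contiguous B-blocks in this layout)
      P.set_size((arma::uword) B * Lp, 64);
      for (int f = 0; f < 64; ++f) {
        const float* a = A.colptr(f);
        float* p = P.colptr(f);
        for (int j = 0; j < Lp; ++j) {
          const float* a1 = a + (size_t) 2 * j * B;
          const float* a2 = a1 + B;
          float* pj = p + (size_t) j * B;
          for (int b = 0; b < B; ++b) pj[b] = std::max(a1[b], a2[b]);
        }
      }
      if (!dense128 && p_pool > 0.0) {
        Pmask.set_size(P.n_rows, P.n_cols);
        xs.mask(Pmask, p_pool);
        P %= Pmask;
      }
      // flatten is a no-op in this layout: P (B*Lp x 64) and
      // F (B x Lp*64) order their elements identically
      arma::fmat F(P.memptr(), B, (arma::uword) Lp * 64, false, true);
      if (dense128) {
        H = F * Wd;
        H.each_row() += arma::frowvec(bd.memptr(), bd.n_elem);
        H.transform([](float z) { return z > 0.0f ? z : 0.0f; });
        Hrelu = H; // post-relu, pre-dropout (relu mask recomputed from it)
        if (p_dense > 0.0) {
          Hmask.set_size(H.n_rows, H.n_cols);
          xs.mask(Hmask, p_dense);
          H %= Hmask;
        }
        Zf = H * Wout;
      } else {
        Zf = F * Wout;
      }
      Zf.each_row() += arma::frowvec(bout.memptr(), bout.n_elem);

      arma::mat Pr = probs_from_logits(arma::conv_to<arma::mat>::from(Zf),
                                       out_dim);
      arma::mat Y(B, out_dim, arma::fill::zeros);
      double loss = 0.0;
      if (out_dim == 1) {
        for (int i = 0; i < B; ++i) {
          Y(i, 0) = (double) y[perm[off + i]];
          const double p = std::min(std::max(Pr(i, 0), 1e-12), 1.0 - 1e-12);
          loss -= Y(i, 0) * std::log(p) + (1.0 - Y(i, 0)) * std::log(1.0 - p);
        }
      } else {
        for (int i = 0; i < B; ++i) {
          Y(i, y[perm[off + i]]) = 1.0;
          loss -= std::log(std::max(Pr(i, y[perm[off + i]]), 1e-12));
        }
      }
      ep_loss += loss;
      arma::fmat dZ = arma::conv_to<arma::fmat>::from((Pr - Y) / B);

      ++t;
      if (dense128) {
        arma::fmat dWout_g = H.t() * dZ;
        arma::fmat dbout_g = arma::sum(dZ, 0);
        arma::fmat dH = dZ * Wout.t();
        if (p_dense > 0.0) dH %= Hmask;
        float* dh = dH.memptr();
        const float* hr = Hrelu.memptr();
        for (arma::uword r = 0; r < dH.n_elem; ++r) {
          if (hr[r] <= 0.0f) dh[r] = 0.0f;
        }
        arma::fmat dWd_g = F.t() * dH;
        arma::fmat dbd_g = arma::sum(dH, 0);
        dF = dH * Wd.t();
        aWd.step(Wd, dWd_g, lr, t, beta1, beta2, adam_eps);
        abd.step(bd, dbd_g, lr, t, beta1, beta2, adam_eps);
        aWout.step(Wout, dWout_g, lr, t, beta1, beta2, adam_eps);
        about.step(bout, dbout_g, lr, t, beta1, beta2, adam_eps);
      } else {
        arma::fmat dWout_g = F.t() * dZ;
        arma::fmat dbout_g = arma::sum(dZ, 0);
        dF = dZ * Wout.t();
        aWout.step(Wout, dWout_g, lr, t, beta1, beta2, adam_eps);
        about.step(bout, dbout_g, lr, t, beta1, beta2, adam_eps);
      }

      arma::fmat dP(dF.memptr(), (arma::uword) B * Lp, 64, false, true);
      dA.zeros((arma::uword) B * L, 64);
      for (int f = 0; f < 64; ++f) {
        const float* a = A.colptr(f);
        const float* dp = dP.colptr(f);
        const float* pm = (!dense128 && p_pool > 0.0) ? Pmask.colptr(f) : 0;
        float* da = dA.colptr(f);
        for (int j = 0; j < Lp; ++j) {
          const size_t o1 = (size_t) 2 * j * B, o2 = o1 + B;
          const size_t op = (size_t) j * B;
          for (int b = 0; b < B; ++b) {
            float g = dp[op + b];
            if (pm) g *= pm[op + b];
            // route to the pooled arg-max, gated by the ReLU (stored
            // activations are post-relu, so > 0 identifies active units)
            if (a[o1 + b] >= a[o2 + b]) {
              da[o1 + b] = a[o1 + b] > 0.0f ? g : 0.0f;
            } else {
              da[o2 + b] = a[o2 + b] > 0.0f ? g : 0.0f;
            }
          }
        }
      }
      if (dense128 && p_conv > 0.0) dA %= Amask;
      arma::fmat dW1_g = M.t() * dA;
      arma::fmat db1_g = arma::sum(dA, 0);
      aW1.step(W1, dW1_g, lr, t, beta1, beta2, adam_eps);
      ab1.step(b1, db1_g, lr, t, beta1, beta2, adam_eps);
    }
    loss_hist(ep) = ep_loss / n;
  }

  List w = List::create(
    Named("W1") = arma::conv_to<arma::mat>::from(W1),
    Named("b1") = arma::conv_to<arma::rowvec>::from(b1),
    Named("Wout") = arma::conv_to<arma::mat>::from(Wout),
    Named("bout") = arma::conv_to<arma::rowvec>::from(bout));
  if (dense128) {
    w["Wd"] = arma::conv_to<arma::mat>::from(Wd);
    w["bd"] = arma::conv_to<arma::rowvec>::from(bd);
  }
  return List::create(Named("weights") = w, Named("loss") = loss_hist);
}
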