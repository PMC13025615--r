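// Feed-forward network for emulating association test statistics.
//
// Architecture: when n_groups > 1 the input row of length n_groups * C is
// treated as an n_groups x C matrix (one row per individual, one column per
// channel, e.g. genotype and transformed residual); the hidden dense layers
// share weights across individuals (pointwise / 1-D-convolution style), and a
// final linear layer maps the flattened per-individual features to the scalar
// statistic. n_groups == 1 gives an ordinary flat MLP. Hidden layers carry
// batch normalization, ReLU and inverted dropout; optimizer is Adam;
// loss = MSE + lambda_var * (sd(pred) - sd(target))^2 + l1 * sum|W|.
// After training, batch-normalization statistics are recalibrated with a
// dropout-free pass over the training data so that inference activations
// match the statistics they are normalized by.
// Training arithmetic is single precision (ample for SGD); exported weights
// and predictions are double. All randomness derives from R's RNG (set.seed()
// in R fixes the whole trajectory); dropout masks use an internal xorshift
// generator seeded from R's RNG for speed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static const float BN_EPS = 1e-5f;

namespace {

struct AdamState {
  fmat mW, vW; frowvec mb, vb; frowvec mg, vg; frowvec mbe, vbe;
};

struct Layer {
  fmat W;            // fan_in x fan_out
  frowvec b;
  bool bn;
  frowvec gamma, beta;
  frowvec run_mean, run_var;
  float dropout;
};

// xorshift128+, seeded from R's RNG; fast uniforms for dropout masks
struct FastRng {
  uint64_t s0, s1;
  explicit FastRng() {
    s0 = (uint64_t)(unif_rand() * 4294967296.0) << 32 |
         (uint64_t)(unif_rand() * 4294967296.0);
    s1 = (uint64_t)(unif_rand() * 4294967296.0) << 32 |
         (uint64_t)(unif_rand() * 4294967296.0);
    if (s0 == 0 && s1 == 0) s1 = 0x9E3779B97F4A7C15ULL;
  }
  inline uint64_t next() {
    uint64_t x = s0; const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  inline float unif() { return (next() >> 40) * (1.0f / 16777216.0f); }
};

// Fisher-Yates with R's RNG
uvec shuffle_idx(int n) {
  uvec idx = regspace<uvec>(0, n - 1);
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
  return idx;
}

fmat he_init(int fan_in, int fan_out, double scale) {
  fmat W(fan_in, fan_out);
  double sd = std::sqrt(scale / (double)fan_in);
  for (uword k = 0; k < W.n_elem; ++k) W[k] = (float)(norm_rand() * sd);
  return W;
}

void adam_step(fmat &p, fmat &m, fmat &v, const fmat &g, float lr, double t) {
  m = 0.9f * m + 0.1f * g;
  v = 0.999f * v + 0.001f * square(g);
  const float c1 = (float)(1.0 / (1.0 - std::pow(0.9, t)));
  const float c2 = (float)(1.0 / (1.0 - std::pow(0.999, t)));
  p -= lr * (c1 * m) / (sqrt(c2 * v) + 1e-8f);
}

void adam_step(frowvec &p, frowvec &m, frowvec &v, const frowvec &g, float lr, double t) {
  m = 0.9f * m + 0.1f * g;
  v = 0.999f * v + 0.001f * square(g);
  const float c1 = (float)(1.0 / (1.0 - std::pow(0.9, t)));
  const float c2 = (float)(1.0 / (1.0 - std::pow(0.999, t)));
  p -= lr * (c1 * m) / (sqrt(c2 * v) + 1e-8f);
}

// B x (G*C), channel-blocked columns -> (B*G) x C, row index = i*B + b
template <typename M>
void to_rows_into(const M &Xb, int G, int C, M &out) {
  int B = Xb.n_rows;
  out.set_size(B * G, C);
  for (int c = 0; c < C; ++c)
    out.col(c) = vectorise(Xb.cols(c * G, c * G + G - 1));
}

template <typename M>
M to_rows(const M &Xb, int G, int C) {
  M out;
  to_rows_into(Xb, G, C, out);
  return out;
}

// (B*G) x h -> B x (G*h), inverse of to_rows applied feature-wise
template <typename M>
M from_rows(const M &Min, int G, int B) {
  int h = Min.n_cols;
  M F(B, G * h);
  for (int j = 0; j < h; ++j)
    F.cols(j * G, j * G + G - 1) = reshape(Min.col(j), B, G);
  return F;
}

} // namespace

// [[Rcpp::export(rng = true)]]
List mlp_train_cpp(const arma::mat &X, const arma::vec &y,
                   const arma::ivec &hidden, const arma::vec &dropout,
                   double l1, double lr, int epochs, int batch_size,
                   double lambda_var, double bn_momentum, bool use_bn,
                   int n_groups, int pointwise_layers) {
  const int n = X.n_rows, p = X.n_cols;
  const int L = hidden.n_elem;
  const int G = n_groups;
  if (p % G != 0) Rcpp::stop("feature count %d not divisible by n_groups %d", p, G);
  const int C = p / G;
  // hidden layers [0, pw) share weights across the G individuals; the
  // activation is flattened to B x (G*h) before layer pw (pw = 0: flat MLP)
  const int pw = (G > 1) ? std::min(pointwise_layers, (int)L) : 0;
  const float l1f = (float)l1, lrf = (float)lr;
  const float mom = (float)bn_momentum;

  FastRng drop_rng;
  const fmat Xf = conv_to<fmat>::from(X);
  const fvec yf = conv_to<fvec>::from(y);

  std::vector<Layer> layers(L + 1);
  std::vector<AdamState> opt(L + 1);
  int fan_in = (pw > 0) ? C : p;
  for (int l = 0; l <= L; ++l) {
    int fan_out;
    if (l == pw && pw > 0) fan_in = G * fan_in;   // flatten boundary
    if (l < L) {
      fan_out = hidden[l];
    } else {
      fan_out = 1;
    }
    layers[l].W = he_init(fan_in, fan_out, l < L ? 2.0 : 1.0);
    layers[l].b = zeros<frowvec>(fan_out);
    layers[l].bn = use_bn && l < L;
    layers[l].dropout = (l < L) ? (float)dropout[l] : 0.0f;
    if (layers[l].bn) {
      layers[l].gamma = ones<frowvec>(fan_out);
      layers[l].beta = zeros<frowvec>(fan_out);
      layers[l].run_mean = zeros<frowvec>(fan_out);
      layers[l].run_var = ones<frowvec>(fan_out);
    }
    opt[l].mW = zeros<fmat>(size(layers[l].W)); opt[l].vW = zeros<fmat>(size(layers[l].W));
    opt[l].mb = zeros<frowvec>(fan_out); opt[l].vb = zeros<frowvec>(fan_out);
    if (layers[l].bn) {
      opt[l].mg = zeros<frowvec>(fan_out); opt[l].vg = zeros<frowvec>(fan_out);
      opt[l].mbe = zeros<frowvec>(fan_out); opt[l].vbe = zeros<frowvec>(fan_out);
    }
    fan_in = fan_out;
  }

  vec history(epochs, fill::zeros);
  double t_adam = 0.0;

  std::vector<fmat> A(L + 2), Zhat(L + 1), Mask(L + 1);
  std::vector<frowvec> inv_sd(L + 1);
  fmat Xbuf, Fbuf, dFbuf, delta, dWbuf, dprev;

  for (int ep = 0; ep < epochs; ++ep) {
    // step decay of the initial learning rate at 50% and 75% of training
    float lr_ep = lrf;
    if (ep >= (3 * epochs) / 4) lr_ep = lrf * 0.01f;
    else if (ep >= epochs / 2) lr_ep = lrf * 0.1f;
    uvec perm = shuffle_idx(n);
    double ep_loss = 0.0; int n_batches = 0;
    for (int start = 0; start < n; start += batch_size) {
      int bend = std::min(start + batch_size, n);
      int B = bend - start;
      if (B < 2) continue;  // sd undefined on a single row
      uvec idx = perm.subvec(start, bend - 1);
      Xbuf = Xf.rows(idx);
      fvec yb = yf.elem(idx);
      if (pw > 0) to_rows_into(Xbuf, G, C, A[0]); else A[0] = Xbuf;

      // ---- forward: pointwise stack on (B*G) x C rows, then flat ----
      for (int l = 0; l < L; ++l) {
        if (l == pw && pw > 0) A[l] = from_rows(A[l], G, B);
        fmat &Z = A[l + 1];
        Z = A[l] * layers[l].W;
        const int rows = Z.n_rows, cols = Z.n_cols;
        const float rate = layers[l].dropout;
        const float keep = 1.0f - rate, inv_keep = rate > 0 ? 1.0f / keep : 1.0f;
        if (rate > 0.0f) Mask[l].set_size(rows, cols);
        if (layers[l].bn) {
          Zhat[l].set_size(rows, cols);
          inv_sd[l].set_size(cols);
          for (int j = 0; j < cols; ++j) {
            float *z = Z.colptr(j);
            const float bj = layers[l].b[j];
            // column mean/var in one pass
            double s = 0.0, s2 = 0.0;
            for (int k = 0; k < rows; ++k) {
              const float v = z[k] + bj;
              z[k] = v; s += v; s2 += (double)v * v;
            }
            const float m = (float)(s / rows);
            const float v = (float)(s2 / rows) - m * m;
            layers[l].run_mean[j] = mom * layers[l].run_mean[j] + (1 - mom) * m;
            layers[l].run_var[j] = mom * layers[l].run_var[j] + (1 - mom) * v;
            const float isd = 1.0f / std::sqrt(v + BN_EPS);
            inv_sd[l][j] = isd;
            const float g = layers[l].gamma[j], be = layers[l].beta[j];
            float *zh = Zhat[l].colptr(j);
            float *mk = rate > 0 ? Mask[l].colptr(j) : nullptr;
            for (int k = 0; k < rows; ++k) {
              const float h = (z[k] - m) * isd;
              zh[k] = h;
              float a = g * h + be;
              if (a < 0.0f) a = 0.0f;          // ReLU
              if (rate > 0.0f) {               // inverted dropout
                if (drop_rng.unif() < keep) { mk[k] = inv_keep; a *= inv_keep; }
                else { mk[k] = 0.0f; a = 0.0f; }
              }
              z[k] = a;
            }
          }
        } else {
          Z.each_row() += layers[l].b;
          float *z = Z.memptr();
          const uword ne = Z.n_elem;
          if (rate > 0.0f) {
            float *mk = Mask[l].memptr();
            for (uword k = 0; k < ne; ++k) {
              float a = z[k] > 0.0f ? z[k] : 0.0f;
              if (drop_rng.unif() < keep) { mk[k] = inv_keep; a *= inv_keep; }
              else { mk[k] = 0.0f; a = 0.0f; }
              z[k] = a;
            }
          } else {
            for (uword k = 0; k < ne; ++k) if (z[k] < 0.0f) z[k] = 0.0f;
          }
        }
      }
      // ---- linear output ----
      if (pw == L && pw > 0) { Fbuf = from_rows(A[L], G, B); } else { Fbuf = A[L]; }
      const fmat &F = Fbuf;
      fvec pred = F * layers[L].W + layers[L].b[0] * ones<fvec>(B);

      // ---- loss ----
      fvec diff = pred - yb;
      double mse = dot(diff, diff) / B;
      double sd_p = stddev(pred), sd_t = stddev(yb);
      double loss = mse + lambda_var * std::pow(sd_p - sd_t, 2.0);
      if (l1 > 0.0)
        for (int l = 0; l < L; ++l) loss += l1 * accu(abs(layers[l].W));
      ep_loss += loss; ++n_batches;
      if (!std::isfinite(loss))
        Rcpp::stop("training aborted: non-finite loss at epoch %d", ep + 1);

      // ---- backward ----
      fvec dpred = 2.0f * diff / (float)B;
      if (lambda_var > 0.0 && sd_p > 0.0) {
        float mp = mean(pred);
        dpred += (float)(lambda_var * 2.0 * (sd_p - sd_t)) * (pred - mp) /
                 (float)((B - 1.0) * sd_p);
      }
      t_adam += 1.0;

      fmat dWout = F.t() * dpred;
      frowvec dbout(1); dbout[0] = accu(dpred);
      dFbuf = dpred * layers[L].W.t();
      if (pw == L && pw > 0) to_rows_into(dFbuf, G, (int)A[L].n_cols, delta);
      else delta = dFbuf;
      adam_step(layers[L].W, opt[L].mW, opt[L].vW, dWout, lr_ep, t_adam);
      adam_step(layers[L].b, opt[L].mb, opt[L].vb, dbout, lr_ep, t_adam);

      for (int l = L - 1; l >= 0; --l) {
        // fused dropout-mask + ReLU derivative (A[l+1] > 0 iff active & kept)
        {
          const float *a = A[l + 1].memptr();
          float *dl = delta.memptr();
          const uword ne = delta.n_elem;
          if (layers[l].dropout > 0.0f) {
            const float *mk = Mask[l].memptr();
            for (uword k = 0; k < ne; ++k) dl[k] = a[k] > 0.0f ? dl[k] * mk[k] : 0.0f;
          } else {
            for (uword k = 0; k < ne; ++k) if (a[k] <= 0.0f) dl[k] = 0.0f;
          }
        }
        frowvec dgamma, dbeta_bn;
        if (layers[l].bn) {
          const int rows = delta.n_rows, cols = delta.n_cols;
          dgamma.set_size(cols); dbeta_bn.set_size(cols);
          const float invB = 1.0f / (float)rows;
          for (int j = 0; j < cols; ++j) {
            float *dl = delta.colptr(j);
            const float *zh = Zhat[l].colptr(j);
            const float g = layers[l].gamma[j];
            double sg = 0.0, sb = 0.0, s1 = 0.0, s2 = 0.0;
            for (int k = 0; k < rows; ++k) {
              sg += (double)dl[k] * zh[k];
              sb += dl[k];
            }
            dgamma[j] = (float)sg; dbeta_bn[j] = (float)sb;
            s1 = g * sb;           // sum(dzh)
            s2 = g * sg;           // sum(dzh % zhat)
            const float isd = inv_sd[l][j];
            const float c1 = (float)s1 * invB, c2 = (float)s2 * invB;
            for (int k = 0; k < rows; ++k) {
              dl[k] = (g * dl[k] - c1 - zh[k] * c2) * isd;
            }
          }
        }
        dWbuf = A[l].t() * delta;
        fmat &dW = dWbuf;
        if (l1 > 0.0) dW += l1f * sign(layers[l].W);
        frowvec db = sum(delta, 0);
        if (l > 0) {
          dprev = delta * layers[l].W.t();
          delta.swap(dprev);
          // crossing the flatten boundary: back to (B*G)-row layout with one
          // column per feature of the last pointwise layer's output
          if (l == pw && pw > 0) {
            dprev = delta;
            to_rows_into(dprev, G, (int)layers[l - 1].W.n_cols, delta);
          }
        }
        adam_step(layers[l].W, opt[l].mW, opt[l].vW, dW, lr_ep, t_adam);
        adam_step(layers[l].b, opt[l].mb, opt[l].vb, db, lr_ep, t_adam);
        if (layers[l].bn) {
          adam_step(layers[l].gamma, opt[l].mg, opt[l].vg, dgamma, lr_ep, t_adam);
          adam_step(layers[l].beta, opt[l].mbe, opt[l].vbe, dbeta_bn, lr_ep, t_adam);
        }
      }
    }
    history[ep] = n_batches > 0 ? ep_loss / n_batches : NA_REAL;
  }

  // ---- recalibrate BN statistics: dropout-free pass over the training set ----
  if (use_bn && epochs > 0) {
    fmat Acur = (pw > 0) ? to_rows(Xf, G, C) : Xf;
    for (int l = 0; l < L; ++l) {
      if (l == pw && pw > 0) Acur = from_rows(Acur, G, (int)X.n_rows);
      fmat Z = Acur * layers[l].W;
      Z.each_row() += layers[l].b;
      if (layers[l].bn) {
        frowvec m = mean(Z, 0);
        frowvec v = mean(square(Z.each_row() - m), 0);
        layers[l].run_mean = m;
        layers[l].run_var = v;
        Z.each_row() -= m;
        Z.each_row() /= sqrt(v + BN_EPS);
        Z.each_row() %= layers[l].gamma;
        Z.each_row() += layers[l].beta;
      }
      Z.transform([](float x) { return x > 0.0f ? x : 0.0f; });
      Acur = std::move(Z);
    }
  }

  List lw(L + 1), lb(L + 1), lg(L + 1), lbe(L + 1), lrm(L + 1), lrv(L + 1);
  for (int l = 0; l <= L; ++l) {
    lw[l] = conv_to<mat>::from(layers[l].W);
    lb[l] = conv_to<rowvec>::from(layers[l].b);
    if (layers[l].bn) {
      lg[l] = conv_to<rowvec>::from(layers[l].gamma);
      lbe[l] = conv_to<rowvec>::from(layers[l].beta);
      lrm[l] = conv_to<rowvec>::from(layers[l].run_mean);
      lrv[l] = conv_to<rowvec>::from(layers[l].run_var);
    } else {
      lg[l] = R_NilValue; lbe[l] = R_NilValue; lrm[l] = R_NilValue; lrv[l] = R_NilValue;
    }
  }
  return List::create(_["W"] = lw, _["b"] = lb, _["gamma"] = lg, _["beta"] = lbe,
                      _["run_mean"] = lrm, _["run_var"] = lrv,
                      _["history"] = history);
}

// [[Rcpp::export(rng = false)]]
arma::vec mlp_predict_cpp(const List &params, const arma::mat &X, int n_groups,
                          int pointwise_layers) {
  List lw = params["W"], lb = params["b"], lg = params["gamma"],
       lbe = params["beta"], lrm = params["run_mean"], lrv = params["run_var"];
  int nlay = lw.size();
  int B = X.n_rows;
  int G = n_groups;
  int pw = (G > 1) ? std::min(pointwise_layers, nlay - 1) : 0;
  mat A = (pw > 0) ? to_rows(X, G, (int)X.n_cols / G) : X;
  for (int l = 0; l < nlay - 1; ++l) {
    if (l == pw && pw > 0) A = from_rows(A, G, B);
    mat W = as<mat>(lw[l]);
    rowvec b = as<rowvec>(lb[l]);
    mat Z = A * W;
    Z.each_row() += b;
    if (!Rf_isNull(lg[l])) {
      rowvec gamma = as<rowvec>(lg[l]), beta = as<rowvec>(lbe[l]);
      rowvec rm = as<rowvec>(lrm[l]), rv = as<rowvec>(lrv[l]);
      Z.each_row() -= rm;
      Z.each_row() /= sqrt(rv + (double)BN_EPS);
      Z.each_row() %= gamma;
      Z.each_row() += beta;
    }
    Z.transform([](double x) { return x > 0.0 ? x : 0.0; });
    A = std::move(Z);
  }
  mat F = (pw == nlay - 1 && pw > 0) ? from_rows(A, G, B) : A;
  mat Wout = as<mat>(lw[nlay - 1]);
  rowvec bout = as<rowvec>(lb[nlay - 1]);
  return F * Wout + bout[0] * ones(B);
}
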