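// Monte-Carlo-dropout feed-forward network for binary classification.
//
// Architecture: linear -> batch-norm -> ReLU -> dropout, followed by
// n_blocks residual blocks (linear -> batch-norm, add skip, ReLU, dropout)
// and a final linear layer producing one logit. Trained with binary
// cross-entropy on logits, Adam with weight decay, and a cosine-annealing
// learning-rate schedule with warm restarts.
//
// All randomness (init, shuffling, dropout masks) flows from a single
// std::mt19937 seeded by the caller, so runs are reproducible bit-for-bit.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;

// 53-bit uniform in [0, 1)
static double runif01(std::mt19937 &rng) {
  double a = (double)(rng() >> 5); // 27 bits
  double b = (double)(rng() >> 6); // 26 bits
  return (a * 67108864.0 + b) / 9007199254740992.0;
}

struct Params {
  std::vector<mat> W;       // W[0]: d x h, W[1..B]: h x h, W[B+1]: h x 1
  std::vector<rowvec> b;    // biases
  std::vector<rowvec> gamma, beta;       // batch-norm scale/shift
  std::vector<rowvec> run_mean, run_var; // running statistics
  int n_blocks() const { return (int)gamma.size() - 1; }
};

struct Grads {
  std::vector<mat> W;
  std::vector<rowvec> b, gamma, beta;
};

static Params init_params(int d, int h, int n_blocks, std::mt19937 &rng) {
  Params p;
  int L = n_blocks + 2;
  p.W.resize(L);
  p.b.resize(L);
  p.gamma.resize(n_blocks + 1);
  p.beta.resize(n_blocks + 1);
  p.run_mean.resize(n_blocks + 1);
  p.run_var.resize(n_blocks + 1);
  for (int l = 0; l < L; ++l) {
    int fan_in = (l == 0) ? d : h;
    int fan_out = (l == L - 1) ? 1 : h;
    double bound = 1.0 / std::sqrt((double)fan_in);
    p.W[l].set_size(fan_in, fan_out);
    for (arma::uword j = 0; j < p.W[l].n_elem; ++j)
      p.W[l](j) = (2.0 * runif01(rng) - 1.0) * bound;
    p.b[l].set_size(fan_out);
    for (arma::uword j = 0; j < p.b[l].n_elem; ++j)
      p.b[l](j) = (2.0 * runif01(rng) - 1.0) * bound;
  }
  for (int l = 0; l <= n_blocks; ++l) {
    p.gamma[l] = rowvec(h, arma::fill::ones);
    p.beta[l] = rowvec(h, arma::fill::zeros);
    p.run_mean[l] = rowvec(h, arma::fill::zeros);
    p.run_var[l] = rowvec(h, arma::fill::ones);
  }
  return p;
}

// Intermediates needed for backprop, one entry per batch-norm layer.
struct LayerCache {
  mat z;            // pre-BN linear output
  mat xhat;         // normalised z
  rowvec invstd;
  mat act;          // post-ReLU (pre-dropout)
  mat mask;         // dropout mask scaled by 1/(1-p); empty => identity
  mat input;        // layer input (weight grads / skip connection)
  mat drop;         // layer output
};

// Training-mode forward (batch statistics). Optionally updates running
// statistics in-place. Returns the logit column.
static vec forward_train(Params &p, const mat &X, double dropout_p,
                         std::mt19937 &rng, std::vector<LayerCache> &caches,
                         bool update_stats) {
  int B = p.n_blocks();
  double m = (double)X.n_rows;
  mat cur = X;
  caches.resize(B + 1);
  for (int l = 0; l <= B; ++l) {
    LayerCache &c = caches[l];
    c.input = cur;
    c.z = cur * p.W[l];
    c.z.each_row() += p.b[l];
    rowvec mu = arma::mean(c.z, 0);
    rowvec var = arma::mean(arma::square(c.z.each_row() - mu), 0); // biased
    c.invstd = 1.0 / arma::sqrt(var + BN_EPS);
    c.xhat = c.z.each_row() - mu;
    c.xhat.each_row() %= c.invstd;
    mat bn = c.xhat;
    bn.each_row() %= p.gamma[l];
    bn.each_row() += p.beta[l];
    if (update_stats) {
      rowvec var_unb = (m > 1.5) ? rowvec(var * (m / (m - 1.0))) : var;
      p.run_mean[l] = (1.0 - BN_MOMENTUM) * p.run_mean[l] + BN_MOMENTUM * mu;
      p.run_var[l] = (1.0 - BN_MOMENTUM) * p.run_var[l] + BN_MOMENTUM * var_unb;
    }
    mat pre = (l == 0) ? bn : mat(bn + c.input); // residual skip
    c.act = arma::clamp(pre, 0.0, arma::datum::inf);
    if (dropout_p > 0.0) {
      c.mask.set_size(c.act.n_rows, c.act.n_cols);
      double scale = 1.0 / (1.0 - dropout_p);
      for (arma::uword j = 0; j < c.mask.n_elem; ++j)
        c.mask(j) = (runif01(rng) < dropout_p) ? 0.0 : scale;
      c.drop = c.act % c.mask;
    } else {
      c.mask.reset();
      c.drop = c.act;
    }
    cur = c.drop;
  }
  return cur * p.W[B + 1] + p.b[B + 1](0);
}

// Mean weighted BCE-with-logits, numerically stable.
static double bce_loss(const vec &logit, const vec &y, const vec &w) {
  vec loss = arma::clamp(logit, 0.0, arma::datum::inf) - logit % y +
             arma::log1p(arma::exp(-arma::abs(logit)));
  return arma::mean(w % loss);
}

// Backward pass from dL/dlogit. Returns gradients for every parameter.
static Grads backward(const Params &p, const std::vector<LayerCache> &caches,
                      const vec &dlogit) {
  int B = p.n_blocks();
  int L = B + 2;
  Grads g;
  g.W.resize(L);
  g.b.resize(L);
  g.gamma.resize(B + 1);
  g.beta.resize(B + 1);

  g.W[B + 1] = caches[B].drop.t() * dlogit;
  g.b[B + 1] = rowvec(1);
  g.b[B + 1](0) = arma::accu(dlogit);
  mat dcur = dlogit * p.W[B + 1].t(); // grad w.r.t. layer output

  for (int l = B; l >= 0; --l) {
    const LayerCache &c = caches[l];
    mat dact = c.mask.is_empty() ? dcur : mat(dcur % c.mask);
    mat dpre = dact % arma::conv_to<mat>::from(c.act > 0.0); // ReLU
    // residual blocks: pre-activation = bn + input
    g.gamma[l] = arma::sum(dpre % c.xhat, 0);
    g.beta[l] = arma::sum(dpre, 0);
    mat dxhat = dpre;
    dxhat.each_row() %= p.gamma[l];
    double mb = (double)c.z.n_rows;
    rowvec s1 = arma::sum(dxhat, 0);
    rowvec s2 = arma::sum(dxhat % c.xhat, 0);
    mat dz = mb * dxhat;
    dz.each_row() -= s1;
    mat corr = c.xhat;
    corr.each_row() %= s2;
    dz -= corr;
    dz.each_row() %= (c.invstd / mb);
    g.W[l] = c.input.t() * dz;
    g.b[l] = arma::sum(dz, 0);
    dcur = dz * p.W[l].t();
    if (l > 0)
      dcur += dpre; // skip-connection gradient
  }
  return g;
}

// Inference-mode forward with running statistics. Non-empty mask rowvecs
// are applied identically to every row (shared per-pass dropout mask).
// first_bn, when non-null, supplies the precomputed first-layer
// batch-normalised activations (they do not depend on dropout masks and
// can be shared across the T passes of a prediction call).
static vec forward_eval(const Params &p, const mat &X,
                        const std::vector<rowvec> &masks,
                        const mat *first_bn = nullptr) {
  int B = p.n_blocks();
  mat cur;
  for (int l = 0; l <= B; ++l) {
    mat z;
    if (l == 0 && first_bn != nullptr) {
      z = *first_bn;
    } else {
      z = (l == 0 ? X : cur) * p.W[l];
      z.each_row() += p.b[l];
      rowvec invstd = 1.0 / arma::sqrt(p.run_var[l] + BN_EPS);
      z.each_row() -= p.run_mean[l];
      z.each_row() %= (invstd % p.gamma[l]);
      z.each_row() += p.beta[l];
    }
    mat pre = (l == 0) ? z : mat(z + cur);
    cur = arma::clamp(pre, 0.0, arma::datum::inf);
    if (!masks.empty() && masks[l].n_elem > 0)
      cur.each_row() %= masks[l];
  }
  return cur * p.W[B + 1] + p.b[B + 1](0);
}

// The first-layer batch-normalised pre-activation (mask-independent).
static mat first_layer_bn(const Params &p, const mat &X) {
  mat z = X * p.W[0];
  z.each_row() += p.b[0];
  rowvec invstd = 1.0 / arma::sqrt(p.run_var[0] + BN_EPS);
  z.each_row() -= p.run_mean[0];
  z.each_row() %= (invstd % p.gamma[0]);
  z.each_row() += p.beta[0];
  return z;
}

struct AdamState {
  std::vector<mat> mW, vW;
  std::vector<rowvec> mb, vb, mg, vg, mbe, vbe;
  long step = 0;
};

static void adam_mat(mat &w, const mat &g, mat &m, mat &v, double lr,
                     double wd, long t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  mat gd = g + wd * w; // L2-coupled weight decay (Adam convention)
  m = b1 * m + (1.0 - b1) * gd;
  v = b2 * v + (1.0 - b2) * (gd % gd);
  w -= lr * (m / (1.0 - std::pow(b1, (double)t))) /
       (arma::sqrt(v / (1.0 - std::pow(b2, (double)t))) + eps);
}

static void adam_row(rowvec &w, const rowvec &g, rowvec &m, rowvec &v,
                     double lr, double wd, long t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  rowvec gd = g + wd * w;
  m = b1 * m + (1.0 - b1) * gd;
  v = b2 * v + (1.0 - b2) * (gd % gd);
  w -= lr * (m / (1.0 - std::pow(b1, (double)t))) /
       (arma::sqrt(v / (1.0 - std::pow(b2, (double)t))) + eps);
}

static List params_to_list(const Params &p) {
  int B = p.n_blocks();
  List W(B + 2), b(B + 2), gam(B + 1), bet(B + 1), rm(B + 1), rv(B + 1);
  for (int l = 0; l <= B + 1; ++l) {
    W[l] = p.W[l];
    b[l] = NumericVector(p.b[l].begin(), p.b[l].end());
  }
  for (int l = 0; l <= B; ++l) {
    gam[l] = NumericVector(p.gamma[l].begin(), p.gamma[l].end());
    bet[l] = NumericVector(p.beta[l].begin(), p.beta[l].end());
    rm[l] = NumericVector(p.run_mean[l].begin(), p.run_mean[l].end());
    rv[l] = NumericVector(p.run_var[l].begin(), p.run_var[l].end());
  }
  return List::create(Named("W") = W, Named("b") = b, Named("gamma") = gam,
                      Named("beta") = bet, Named("run_mean") = rm,
                      Named("run_var") = rv);
}

static Params params_from_list(const List &lst) {
  Params p;
  List W = lst["W"], b = lst["b"], gam = lst["gamma"], bet = lst["beta"],
       rm = lst["run_mean"], rv = lst["run_var"];
  int L = W.size(), B = L - 2;
  p.W.resize(L);
  p.b.resize(L);
  p.gamma.resize(B + 1);
  p.beta.resize(B + 1);
  p.run_mean.resize(B + 1);
  p.run_var.resize(B + 1);
  for (int l = 0; l < L; ++l) {
    p.W[l] = as<mat>(W[l]);
    NumericVector bv = b[l];
    p.b[l] = rowvec(bv.begin(), bv.size());
  }
  for (int l = 0; l <= B; ++l) {
    NumericVector g = gam[l], be = bet[l], m = rm[l], v = rv[l];
    p.gamma[l] = rowvec(g.begin(), g.size());
    p.beta[l] = rowvec(be.begin(), be.size());
    p.run_mean[l] = rowvec(m.begin(), m.size());
    p.run_var[l] = rowvec(v.begin(), v.size());
  }
  return p;
}

// [[Rcpp::export(name = ".bnn_train_cpp")]]
List bnn_train_cpp(const arma::mat &X, const arma::vec &y, int hidden_dim,
                   int n_blocks, double dropout_p, double lr,
                   double weight_decay, int epochs, int batch_size,
                   int lr_cycle, double pos_weight, int seed) {
  int n = X.n_rows;
  std::mt19937 rng((uint32_t)seed);
  Params p = init_params(X.n_cols, hidden_dim, n_blocks, rng);

  AdamState st;
  int L = n_blocks + 2;
  st.mW.resize(L);
  st.vW.resize(L);
  st.mb.resize(L);
  st.vb.resize(L);
  st.mg.resize(n_blocks + 1);
  st.vg.resize(n_blocks + 1);
  st.mbe.resize(n_blocks + 1);
  st.vbe.resize(n_blocks + 1);
  for (int l = 0; l < L; ++l) {
    st.mW[l] = mat(arma::size(p.W[l]), arma::fill::zeros);
    st.vW[l] = st.mW[l];
    st.mb[l] = rowvec(p.b[l].n_elem, arma::fill::zeros);
    st.vb[l] = st.mb[l];
  }
  for (int l = 0; l <= n_blocks; ++l) {
    st.mg[l] = rowvec(hidden_dim, arma::fill::zeros);
    st.vg[l] = st.mg[l];
    st.mbe[l] = st.mg[l];
    st.vbe[l] = st.mg[l];
  }

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i)
    idx[i] = i;
  NumericVector loss_trace(epochs);
  const double PI = 3.14159265358979323846;

  for (int epoch = 0; epoch < epochs; ++epoch) {
    // cosine annealing with warm restarts every lr_cycle epochs
    double lr_t = 0.5 * lr * (1.0 + std::cos(PI * (double)(epoch % lr_cycle) /
                                             (double)lr_cycle));
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0;
    int n_seen = 0;
    for (int start = 0; start < n; start += batch_size) {
      int end = std::min(start + batch_size, n);
      int m = end - start;
      if (m < 2)
        continue; // degenerate batch-norm statistics
      arma::uvec rows(m);
      for (int k = 0; k < m; ++k)
        rows[k] = (arma::uword)idx[start + k];
      mat Xb = X.rows(rows);
      vec yb = y.elem(rows);
      vec wb = (pos_weight == 1.0) ? vec(m, arma::fill::ones)
                                   : vec(1.0 + (pos_weight - 1.0) * yb);

      std::vector<LayerCache> caches;
      vec logit = forward_train(p, Xb, dropout_p, rng, caches, true);
      double loss = bce_loss(logit, yb, wb);
      if (!std::isfinite(loss))
        return List::create(Named("diverged") = true,
                            Named("epoch") = epoch + 1);
      vec dlogit = (1.0 / (1.0 + arma::exp(-logit)) - yb) % wb / (double)m;
      Grads g = backward(p, caches, dlogit);

      ep_loss += loss * m;
      n_seen += m;
      st.step += 1;
      for (int l = 0; l < L; ++l) {
        adam_mat(p.W[l], g.W[l], st.mW[l], st.vW[l], lr_t, weight_decay,
                 st.step);
        adam_row(p.b[l], g.b[l], st.mb[l], st.vb[l], lr_t, weight_decay,
                 st.step);
      }
      for (int l = 0; l <= n_blocks; ++l) {
        adam_row(p.gamma[l], g.gamma[l], st.mg[l], st.vg[l], lr_t,
                 weight_decay, st.step);
        adam_row(p.beta[l], g.beta[l], st.mbe[l], st.vbe[l], lr_t,
                 weight_decay, st.step);
      }
    }
    loss_trace[epoch] = (n_seen > 0) ? ep_loss / n_seen : NA_REAL;
  }

  List out = params_to_list(p);
  out["loss_trace"] = loss_trace;
  out["diverged"] = false;
  return out;
}

// T stochastic forward passes. With dropout_active, one dropout mask per
// layer is sampled per pass and shared across all rows of X, i.e. each pass
// is a single sampled submodel phi^(t); pool and target points evaluated in
// the same call therefore see identical masks -- the paired draws the EPIG
// estimator requires. Batch-norm always uses running statistics. Returns a
// T x n matrix of p(y = 1).
// [[Rcpp::export(name = ".bnn_predict_cpp")]]
arma::mat bnn_predict_cpp(const List &model, const arma::mat &X, int T,
                          bool dropout_active, double dropout_p, int seed) {
  Params p = params_from_list(model);
  int B = p.n_blocks();
  int h = p.gamma[0].n_elem;
  std::mt19937 rng((uint32_t)seed);
  mat out(T, X.n_rows);
  mat bn0 = first_layer_bn(p, X);
  for (int t = 0; t < T; ++t) {
    std::vector<rowvec> masks;
    if (dropout_active && dropout_p > 0.0) {
      masks.resize(B + 1);
      double scale = 1.0 / (1.0 - dropout_p);
      for (int l = 0; l <= B; ++l) {
        masks[l].set_size(h);
        for (int j = 0; j < h; ++j)
          masks[l](j) = (runif01(rng) < dropout_p) ? 0.0 : scale;
      }
    }
    vec logit = forward_eval(p, X, masks, &bn0);
    out.row(t) = (1.0 / (1.0 + arma::exp(-logit))).t();
  }
  return out;
}

// Finite-difference check of the analytic gradients (training-mode forward,
// no dropout, fixed batch). Returns the maximum absolute difference between
// analytic and central-difference gradients over all parameter entries.
// [[Rcpp::export(name = ".bnn_grad_check_cpp")]]
double bnn_grad_check_cpp(const arma::mat &X, const arma::vec &y,
                          int hidden_dim, int n_blocks, int seed,
                          double fd_eps) {
  std::mt19937 rng((uint32_t)seed);
  Params p = init_params(X.n_cols, hidden_dim, n_blocks, rng);
  vec ones(y.n_elem, arma::fill::ones);
  std::vector<LayerCache> caches;
  vec logit = forward_train(p, X, 0.0, rng, caches, false);
  vec dlogit = (1.0 / (1.0 + arma::exp(-logit)) - y) / (double)y.n_elem;
  Grads g = backward(p, caches, dlogit);

  auto loss_at = [&]() {
    std::vector<LayerCache> cc;
    vec lg = forward_train(p, X, 0.0, rng, cc, false);
    return bce_loss(lg, y, ones);
  };
  double max_diff = 0.0;
  auto probe = [&](double &wj, double gj) {
    double orig = wj;
    wj = orig + fd_eps;
    double lp = loss_at();
    wj = orig - fd_eps;
    double lm = loss_at();
    wj = orig;
    max_diff = std::max(max_diff, std::abs((lp - lm) / (2.0 * fd_eps) - gj));
  };
  int L = n_blocks + 2;
  for (int l = 0; l < L; ++l) {
    for (arma::uword j = 0; j < p.W[l].n_elem; ++j)
      probe(p.W[l](j), g.W[l](j));
    for (arma::uword j = 0; j < p.b[l].n_elem; ++j)
      probe(p.b[l](j), g.b[l](j));
  }
  for (int l = 0; l <= n_blocks; ++l) {
    for (arma::uword j = 0; j < p.gamma[l].n_elem; ++j)
      probe(p.gamma[l](j), g.gamma[l](j));
    for (arma::uword j = 0; j < p.beta[l].n_elem; ++j)
      probe(p.beta[l](j), g.beta[l](j));
  }
  return max_diff;
}
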