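// Small 1D-CNN and two-layer Elman RNN regressors trained with Adam.
// Architectures: CNN = conv(F filters, kernel K, activation) -> max-pool
// (width `pool`) -> flatten -> dense linear; RNN = recurrent(H1, return
// sequences) -> recurrent(H2) -> dense linear, the feature vector read as
// a length-p sequence of scalars.  All randomness (init, shuffling) draws
// from R's RNG so R-level set.seed() controls reproducibility.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// activation codes: 0 linear, 1 relu, 2 elu, 3 tanh, 4 sigmoid
static mat act(const mat& z, int code) {
  switch (code) {
    case 0: return z;
    case 1: return clamp(z, 0.0, datum::inf);
    case 2: { mat a = z; a.elem(find(z < 0)) = exp(z.elem(find(z < 0))) - 1.0; return a; }
    case 3: return tanh(z);
    default: return 1.0 / (1.0 + exp(-z));
  }
}

// derivative of the activation given preactivation z and activation a
static mat dact(const mat& z, const mat& a, int code) {
  switch (code) {
    case 0: return ones<mat>(z.n_rows, z.n_cols);
    case 1: return conv_to<mat>::from(z > 0);
    case 2: { mat d = ones<mat>(z.n_rows, z.n_cols);
              d.elem(find(z < 0)) = a.elem(find(z < 0)) + 1.0; return d; }
    case 3: return 1.0 - square(a);
    default: return a % (1.0 - a);
  }
}

static mat r_uniform_mat(int r, int c, double lim) {
  mat M(r, c);
  for (uword j = 0; j < M.n_cols; ++j)
    for (uword i = 0; i < M.n_rows; ++i)
      M(i, j) = R::runif(-lim, lim);
  return M;
}

static uvec r_permutation(int n) {
  // Fisher-Yates using R's RNG
  uvec idx = regspace<uvec>(0, n - 1);
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(R::unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
  return idx;
}

struct Adam {
  double lr, b1, b2, eps; int t;
  std::vector<mat> m, v;
  Adam(double lr_) : lr(lr_), b1(0.9), b2(0.999), eps(1e-8), t(0) {}
  void init(const std::vector<mat*>& params) {
    for (auto p : params) { m.push_back(zeros<mat>(p->n_rows, p->n_cols));
                            v.push_back(zeros<mat>(p->n_rows, p->n_cols)); }
  }
  void step(std::vector<mat*>& params, const std::vector<mat>& grads) {
    ++t;
    double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * grads[i];
      v[i] = b2 * v[i] + (1 - b2) * square(grads[i]);
      *params[i] -= lr * (m[i] / c1) / (sqrt(v[i] / c2) + eps);
    }
  }
};

// ---------------------------------------------------------------- CNN ----

struct CnnW { mat Wc; rowvec bc; vec wd; double bd; int K, F, pool, actc; };

static CnnW cnn_from_list(const List& w) {
  CnnW s;
  s.Wc = as<mat>(w["Wc"]); s.bc = as<rowvec>(w["bc"]);
  s.wd = as<vec>(w["wd"]); s.bd = as<double>(w["bd"]);
  s.K = as<int>(w["kernel"]); s.F = as<int>(w["n_filters"]);
  s.pool = as<int>(w["pool"]); s.actc = as<int>(w["activation"]);
  return s;
}

static List cnn_to_list(const CnnW& s) {
  return List::create(_["Wc"] = s.Wc, _["bc"] = s.bc, _["wd"] = s.wd,
                      _["bd"] = s.bd, _["kernel"] = s.K, _["n_filters"] = s.F,
                      _["pool"] = s.pool, _["activation"] = s.actc);
}

// forward pass; fills caches when training
static vec cnn_forward(const CnnW& w, const mat& X, cube* Zc, cube* Ac,
                       umat* argmax, mat* flat) {
  int B = X.n_rows, p = X.n_cols;
  int L = p - w.K + 1, Lp = L / w.pool;
  mat fl(B, Lp * w.F);
  umat am(B, Lp * w.F);
  if (Zc) { Zc->set_size(B, w.F, L); Ac->set_size(B, w.F, L); }
  std::vector<mat> Aslices(L);
  for (int l = 0; l < L; ++l) {
    mat Z = X.cols(l, l + w.K - 1) * w.Wc;
    Z.each_row() += w.bc;
    mat A = act(Z, w.actc);
    if (Zc) { Zc->slice(l) = Z; Ac->slice(l) = A; }
    Aslices[l] = A;
  }
  for (int j = 0; j < Lp; ++j)
    for (int f = 0; f < w.F; ++f)
      for (int b = 0; b < B; ++b) {
        double best = -datum::inf; int bl = j * w.pool;
        for (int u = 0; u < w.pool; ++u) {
          double v = Aslices[j * w.pool + u](b, f);
          if (v > best) { best = v; bl = j * w.pool + u; }
        }
        fl(b, j * w.F + f) = best;
        am(b, j * w.F + f) = bl;
      }
  if (argmax) *argmax = am;
  if (flat) *flat = fl;
  return fl * w.wd + w.bd;
}

// [[Rcpp::export]]
NumericVector cpp_cnn_predict(List weights, NumericMatrix X_) {
  CnnW w = cnn_from_list(weights);
  mat X = as<mat>(X_);
  vec out = cnn_forward(w, X, nullptr, nullptr, nullptr, nullptr);
  return wrap(out);
}

// gradient of the scalar output w.r.t. each input feature
// [[Rcpp::export]]
NumericMatrix cpp_cnn_input_grad(List weights, NumericMatrix X_) {
  CnnW w = cnn_from_list(weights);
  mat X = as<mat>(X_);
  int B = X.n_rows, p = X.n_cols;
  int L = p - w.K + 1, Lp = L / w.pool;
  cube Z, A; umat am; mat fl;
  cnn_forward(w, X, &Z, &A, &am, &fl);
  mat G(B, p, fill::zeros);
  for (int j = 0; j < Lp; ++j)
    for (int f = 0; f < w.F; ++f)
      for (int b = 0; b < B; ++b) {
        int l = am(b, j * w.F + f);
        double up = w.wd(j * w.F + f);
        double dz = up * dact(mat{Z(b, f, l)}, mat{A(b, f, l)}, w.actc)(0, 0);
        for (int u = 0; u < w.K; ++u)
          G(b, l + u) += dz * w.Wc(u, f);
      }
  return wrap(G);
}

// [[Rcpp::export]]
List cpp_cnn_train(NumericMatrix X_, NumericVector y_, int n_filters,
                   int kernel, int pool, int activation, double lr,
                   int epochs, int batch_size, NumericMatrix Xval_,
                   NumericVector yval_, int eval_every) {
  mat X = as<mat>(X_); vec y = as<vec>(y_);
  mat Xval = as<mat>(Xval_); vec yval = as<vec>(yval_);
  int n = X.n_rows, p = X.n_cols;
  if (p < kernel) stop("feature count smaller than the kernel size");
  int L = p - kernel + 1, Lp = L / pool;
  if (Lp < 1) stop("pooling removes all positions");
  CnnW w; w.K = kernel; w.F = n_filters; w.pool = pool; w.actc = activation;
  double lim_c = std::sqrt(6.0 / (kernel + n_filters));
  w.Wc = r_uniform_mat(kernel, n_filters, lim_c);
  w.bc = zeros<rowvec>(n_filters);
  double lim_d = std::sqrt(6.0 / (Lp * n_filters + 1));
  w.wd = vectorise(r_uniform_mat(Lp * n_filters, 1, lim_d));
  w.bd = 0.0;
  mat bd_m(1, 1); bd_m(0, 0) = w.bd;
  mat wd_m(w.wd); mat bc_m(w.bc.t());
  std::vector<mat*> params{&w.Wc, &bc_m, &wd_m, &bd_m};
  Adam opt(lr); opt.init(params);
  std::vector<double> loss_trace, val_epochs, val_mse;
  List best_weights = cnn_to_list(w);
  double best_val = datum::inf; int best_epoch = epochs;
  bool diverged = false;
  for (int ep = 1; ep <= epochs && !diverged; ++ep) {
    uvec perm = r_permutation(n);
    double ep_loss = 0; int nb = 0;
    for (int s = 0; s < n; s += batch_size) {
      int e = std::min(s + batch_size, n) - 1;
      uvec idx = perm.subvec(s, e);
      mat Xb = X.rows(idx); vec yb = y.elem(idx);
      int B = Xb.n_rows;
      cube Z, A; umat am; mat fl;
      vec pred = cnn_forward(w, Xb, &Z, &A, &am, &fl);
      vec err = pred - yb;
      double loss = dot(err, err) / B;
      if (!std::isfinite(loss) || loss > 1e10) { diverged = true; break; }
      ep_loss += loss; ++nb;
      vec dout = 2.0 * err / B;
      mat dWc(kernel, n_filters, fill::zeros);
      rowvec dbc(n_filters, fill::zeros);
      vec dwd = fl.t() * dout;
      double dbd = accu(dout);
      // route gradient through the max-pool winners
      std::vector<mat> dZ(L, zeros<mat>(B, n_filters));
      for (int j = 0; j < Lp; ++j)
        for (int f = 0; f < n_filters; ++f)
          for (int b = 0; b < B; ++b) {
            int l = am(b, j * n_filters + f);
            double da = dout(b) * w.wd(j * n_filters + f);
            dZ[l](b, f) += da;
          }
      for (int l = 0; l < L; ++l) {
        mat d = dZ[l] % dact(Z.slice(l), A.slice(l), activation);
        dWc += Xb.cols(l, l + kernel - 1).t() * d;
        dbc += sum(d, 0);
      }
      mat dbd_m(1, 1); dbd_m(0, 0) = dbd;
      std::vector<mat> grads{dWc, mat(dbc.t()), mat(dwd), dbd_m};
      opt.step(params, grads);
      w.bc = bc_m.t(); w.wd = vectorise(wd_m); w.bd = bd_m(0, 0);
    }
    loss_trace.push_back(nb ? ep_loss / nb : datum::nan);
    if (!diverged && Xval.n_rows > 0 && (ep % eval_every == 0 || ep == epochs)) {
      vec pv = cnn_forward(w, Xval, nullptr, nullptr, nullptr, nullptr);
      double vm = accu(square(pv - yval)) / Xval.n_rows;
      val_epochs.push_back(ep); val_mse.push_back(vm);
      if (std::isfinite(vm) && vm < best_val) {
        best_val = vm; best_epoch = ep; best_weights = cnn_to_list(w);
      }
    }
  }
  if (Xval.n_rows == 0) { best_weights = cnn_to_list(w); best_epoch = epochs; }
  return List::create(_["weights"] = cnn_to_list(w),
                      _["best_weights"] = best_weights,
                      _["best_epoch"] = best_epoch,
                      _["loss_trace"] = loss_trace,
                      _["val_epochs"] = val_epochs, _["val_mse"] = val_mse,
                      _["diverged"] = diverged);
}

// ---------------------------------------------------------------- RNN ----

struct RnnW {
  rowvec w1; mat U1; rowvec b1;   // layer 1: input scalar -> H1
  mat W2, U2; rowvec b2;          // layer 2: H1 -> H2
  vec wd; double bd; int H1, H2, actc;
};

static RnnW rnn_from_list(const List& w) {
  RnnW s;
  s.w1 = as<rowvec>(w["w1"]); s.U1 = as<mat>(w["U1"]); s.b1 = as<rowvec>(w["b1"]);
  s.W2 = as<mat>(w["W2"]); s.U2 = as<mat>(w["U2"]); s.b2 = as<rowvec>(w["b2"]);
  s.wd = as<vec>(w["wd"]); s.bd = as<double>(w["bd"]);
  s.H1 = s.U1.n_rows; s.H2 = s.U2.n_rows; s.actc = as<int>(w["activation"]);
  return s;
}

static List rnn_to_list(const RnnW& s) {
  return List::create(_["w1"] = s.w1, _["U1"] = s.U1, _["b1"] = s.b1,
                      _["W2"] = s.W2, _["U2"] = s.U2, _["b2"] = s.b2,
                      _["wd"] = s.wd, _["bd"] = s.bd,
                      _["activation"] = s.actc);
}

static vec rnn_forward(const RnnW& w, const mat& X, cube* Z1c, cube* A1c,
                       cube* Z2c, cube* A2c) {
  int B = X.n_rows, p = X.n_cols;
  mat H1 = zeros<mat>(B, w.H1), H2 = zeros<mat>(B, w.H2);
  if (Z1c) { Z1c->set_size(B, w.H1, p); A1c->set_size(B, w.H1, p);
             Z2c->set_size(B, w.H2, p); A2c->set_size(B, w.H2, p); }
  for (int t = 0; t < p; ++t) {
    mat Z1 = X.col(t) * w.w1 + H1 * w.U1;
    Z1.each_row() += w.b1;
    H1 = act(Z1, w.actc);
    mat Z2 = H1 * w.W2 + H2 * w.U2;
    Z2.each_row() += w.b2;
    H2 = act(Z2, w.actc);
    if (Z1c) { Z1c->slice(t) = Z1; A1c->slice(t) = H1;
               Z2c->slice(t) = Z2; A2c->slice(t) = H2; }
  }
  return H2 * w.wd + w.bd;
}

// [[Rcpp::export]]
NumericVector cpp_rnn_predict(List weights, NumericMatrix X_) {
  RnnW w = rnn_from_list(weights);
  mat X = as<mat>(X_);
  vec out = rnn_forward(w, X, nullptr, nullptr, nullptr, nullptr);
  return wrap(out);
}

// [[Rcpp::export]]
NumericMatrix cpp_rnn_input_grad(List weights, NumericMatrix X_) {
  RnnW w = rnn_from_list(weights);
  mat X = as<mat>(X_);
  int B = X.n_rows, p = X.n_cols;
  cube Z1, A1, Z2, A2;
  rnn_forward(w, X, &Z1, &A1, &Z2, &A2);
  mat G(B, p, fill::zeros);
  mat carry2 = repmat(w.wd.t(), B, 1);   // dOut/dA2_p
  mat carry1 = zeros<mat>(B, w.H1);
  for (int t = p - 1; t >= 0; --t) {
    mat dZ2 = carry2 % dact(Z2.slice(t), A2.slice(t), w.actc);
    carry2 = dZ2 * w.U2.t();
    mat dA1 = dZ2 * w.W2.t() + carry1;
    mat dZ1 = dA1 % dact(Z1.slice(t), A1.slice(t), w.actc);
    carry1 = dZ1 * w.U1.t();
    G.col(t) = dZ1 * w.w1.t();
  }
  return wrap(G);
}

// [[Rcpp::export]]
List cpp_rnn_train(NumericMatrix X_, NumericVector y_, int H1, int H2,
                   int activation, double lr, int epochs, int batch_size,
                   NumericMatrix Xval_, NumericVector yval_, int eval_every) {
  mat X = as<mat>(X_); vec y = as<vec>(y_);
  mat Xval = as<mat>(Xval_); vec yval = as<vec>(yval_);
  int n = X.n_rows, p = X.n_cols;
  RnnW w; w.H1 = H1; w.H2 = H2; w.actc = activation;
  w.w1 = r_uniform_mat(1, H1, std::sqrt(6.0 / (1 + H1)));
  w.U1 = r_uniform_mat(H1, H1, std::sqrt(6.0 / (2 * H1)));
  w.b1 = zeros<rowvec>(H1);
  w.W2 = r_uniform_mat(H1, H2, std::sqrt(6.0 / (H1 + H2)));
  w.U2 = r_uniform_mat(H2, H2, std::sqrt(6.0 / (2 * H2)));
  w.b2 = zeros<rowvec>(H2);
  w.wd = vectorise(r_uniform_mat(H2, 1, std::sqrt(6.0 / (H2 + 1))));
  w.bd = 0.0;
  mat w1_m(w.w1.t()), b1_m(w.b1.t()), b2_m(w.b2.t()), wd_m(w.wd);
  mat bd_m(1, 1); bd_m(0, 0) = 0.0;
  std::vector<mat*> params{&w1_m, &w.U1, &b1_m, &w.W2, &w.U2, &b2_m,
                           &wd_m, &bd_m};
  Adam opt(lr); opt.init(params);
  std::vector<double> loss_trace, val_epochs, val_mse;
  List best_weights = rnn_to_list(w);
  double best_val = datum::inf; int best_epoch = epochs;
  bool diverged = false;
  for (int ep = 1; ep <= epochs && !diverged; ++ep) {
    uvec perm = r_permutation(n);
    double ep_loss = 0; int nb = 0;
    for (int s = 0; s < n; s += batch_size) {
      int e = std::min(s + batch_size, n) - 1;
      uvec idx = perm.subvec(s, e);
      mat Xb = X.rows(idx); vec yb = y.elem(idx);
      int B = Xb.n_rows;
      cube Z1, A1, Z2, A2;
      vec pred = rnn_forward(w, Xb, &Z1, &A1, &Z2, &A2);
      vec err = pred - yb;
      double loss = dot(err, err) / B;
      if (!std::isfinite(loss) || loss > 1e10) { diverged = true; break; }
      ep_loss += loss; ++nb;
      vec dout = 2.0 * err / B;
      mat dw1(1, H1, fill::zeros), dU1(H1, H1, fill::zeros);
      rowvec db1(H1, fill::zeros);
      mat dW2(H1, H2, fill::zeros), dU2(H2, H2, fill::zeros);
      rowvec db2(H2, fill::zeros);
      vec dwd = A2.slice(p - 1).t() * dout;
      double dbd = accu(dout);
      mat carry2 = dout * w.wd.t();
      mat carry1 = zeros<mat>(B, H1);
      for (int t = p - 1; t >= 0; --t) {
        mat dZ2 = carry2 % dact(Z2.slice(t), A2.slice(t), activation);
        mat A2prev = (t > 0) ? A2.slice(t - 1) : zeros<mat>(B, H2);
        dW2 += A1.slice(t).t() * dZ2;
        dU2 += A2prev.t() * dZ2;
        db2 += sum(dZ2, 0);
        carry2 = dZ2 * w.U2.t();
        mat dA1 = dZ2 * w.W2.t() + carry1;
        mat dZ1 = dA1 % dact(Z1.slice(t), A1.slice(t), activation);
        mat A1prev = (t > 0) ? A1.slice(t - 1) : zeros<mat>(B, H1);
        dw1 += Xb.col(t).t() * dZ1;
        dU1 += A1prev.t() * dZ1;
        db1 += sum(dZ1, 0);
        carry1 = dZ1 * w.U1.t();
      }
      mat dbd_m(1, 1); dbd_m(0, 0) = dbd;
      std::vector<mat> grads{mat(dw1.t()), dU1, mat(db1.t()), dW2, dU2,
                             mat(db2.t()), mat(dwd), dbd_m};
      opt.step(params, grads);
      w.w1 = w1_m.t(); w.b1 = b1_m.t(); w.b2 = b2_m.t();
      w.wd = vectorise(wd_m); w.bd = bd_m(0, 0);
    }
    loss_trace.push_back(nb ? ep_loss / nb : datum::nan);
    if (!diverged && Xval.n_rows > 0 && (ep % eval_every == 0 || ep == epochs)) {
      vec pv = rnn_forward(w, Xval, nullptr, nullptr, nullptr, nullptr);
      double vm = accu(square(pv - yval)) / Xval.n_rows;
      val_epochs.push_back(ep); val_mse.push_back(vm);
      if (std::isfinite(vm) && vm < best_val) {
        best_val = vm; best_epoch = ep; best_weights = rnn_to_list(w);
      }
    }
  }
  if (Xval.n_rows == 0) { best_weights = rnn_to_list(w); best_epoch = epochs; }
  return List::create(_["weights"] = rnn_to_list(w),
                      _["best_weights"] = best_weights,
                      _["best_epoch"] = best_epoch,
                      _["loss_trace"] = loss_trace,
                      _["val_epochs"] = val_epochs, _["val_mse"] = val_mse,
                      _["diverged"] = diverged);
}
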