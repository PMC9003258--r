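// Minimal 1-D convolutional network engine: same-padded convolutions with
// ReLU, max-pooling by 2, two fully connected layers and a linear scalar
// output, trained with Adam on mean-squared error.  Batched im2col + GEMM so
// single-CPU training of a ~150k-parameter network stays in the minutes
// range.  All randomness (init, shuffling) is injected from R for exact
// reproducibility.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct ConvLayer {
  mat W;     // (C_in * K) x C_out, column block k*C_in + c for offset k
  rowvec b;  // C_out
  bool pool;
};

struct Net {
  std::vector<ConvLayer> convs;
  mat W1; rowvec b1;   // fc1
  mat W2; rowvec b2;   // fc2
  mat Wo; rowvec bo;   // linear output (1 unit)
  int K, pad, L0;
};

Net parse_net(const Rcpp::List& params) {
  Net net;
  Rcpp::List convs = params["convs"];
  for (int i = 0; i < convs.size(); ++i) {
    Rcpp::List cl = convs[i];
    ConvLayer c;
    c.W = Rcpp::as<mat>(cl["W"]);
    c.b = Rcpp::as<rowvec>(cl["b"]);
    c.pool = Rcpp::as<bool>(cl["pool"]);
    net.convs.push_back(c);
  }
  net.W1 = Rcpp::as<mat>(params["W1"]); net.b1 = Rcpp::as<rowvec>(params["b1"]);
  net.W2 = Rcpp::as<mat>(params["W2"]); net.b2 = Rcpp::as<rowvec>(params["b2"]);
  net.Wo = Rcpp::as<mat>(params["Wo"]); net.bo = Rcpp::as<rowvec>(params["bo"]);
  net.K = Rcpp::as<int>(params["kernel"]);
  net.pad = net.K / 2;
  net.L0 = Rcpp::as<int>(params["input_len"]);
  return net;
}

Rcpp::List unparse_net(const Net& net) {
  Rcpp::List convs(net.convs.size());
  for (size_t i = 0; i < net.convs.size(); ++i)
    convs[i] = Rcpp::List::create(
        Rcpp::Named("W") = net.convs[i].W,
        Rcpp::Named("b") = net.convs[i].b,
        Rcpp::Named("pool") = net.convs[i].pool);
  return Rcpp::List::create(
      Rcpp::Named("convs") = convs,
      Rcpp::Named("W1") = net.W1, Rcpp::Named("b1") = net.b1,
      Rcpp::Named("W2") = net.W2, Rcpp::Named("b2") = net.b2,
      Rcpp::Named("Wo") = net.Wo, Rcpp::Named("bo") = net.bo,
      Rcpp::Named("kernel") = net.K, Rcpp::Named("input_len") = net.L0);
}

// A holds B stacked samples of length L (rows b*L + t), C_in columns.
mat im2col(const mat& A, int B, int L, int K, int pad) {
  const int C = A.n_cols;
  mat out(B * (size_t)L, (size_t)C * K, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int k = 0; k < K; ++k) {
      const int shift = k - pad;
      const int t0 = std::max(0, -shift), t1 = std::min(L, L - shift);
      if (t1 > t0)
        out.submat(b * L + t0, (size_t)k * C,
                   b * L + t1 - 1, (size_t)k * C + C - 1) =
            A.submat(b * L + t0 + shift, 0, b * L + t1 - 1 + shift, C - 1);
    }
  return out;
}

// reverse of im2col: scatter-add gradient contributions back to the input
mat col2im(const mat& G, int B, int L, int K, int pad, int C) {
  mat out(B * (size_t)L, C, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int k = 0; k < K; ++k) {
      const int shift = k - pad;
      const int t0 = std::max(0, -shift), t1 = std::min(L, L - shift);
      if (t1 > t0)
        out.submat(b * L + t0 + shift, 0, b * L + t1 - 1 + shift, C - 1) +=
            G.submat(b * L + t0, (size_t)k * C,
                     b * L + t1 - 1, (size_t)k * C + C - 1);
    }
  return out;
}

struct ConvCache {
  mat pre;      // pre-ReLU activations (B*L x C)
  mat imc;      // im2col of the layer input
  umat argmax;  // pooling selectors (B*L2 x C), values 0/1
  int L_in, L_out;
};

struct FwdCache {
  std::vector<ConvCache> conv;
  mat flat, h1, h2;  // per-batch dense activations
  vec yhat;
};

vec forward(const Net& net, const mat& X, int B, FwdCache* cache) {
  // X: B x L0 (one row per segment)
  int L = net.L0;
  mat A(B * (size_t)L, 1);
  for (int b = 0; b < B; ++b)
    A.submat(b * L, 0, b * L + L - 1, 0) = X.row(b).t();
  if (cache) cache->conv.resize(net.convs.size());
  for (size_t l = 0; l < net.convs.size(); ++l) {
    const ConvLayer& cl = net.convs[l];
    mat imc = im2col(A, B, L, net.K, net.pad);
    mat Z = imc * cl.W;
    Z.each_row() += cl.b;
    mat pre = Z;
    Z.transform([](double v) { return v > 0 ? v : 0.0; });
    int L2 = L;
    umat amax;
    if (cl.pool) {
      L2 = L / 2;
      mat P(B * (size_t)L2, Z.n_cols);
      amax.set_size(B * (size_t)L2, Z.n_cols);
      for (int b = 0; b < B; ++b)
        for (int t = 0; t < L2; ++t) {
          const size_t r0 = b * (size_t)L + 2 * t, ro = b * (size_t)L2 + t;
          for (uword c = 0; c < Z.n_cols; ++c) {
            const double a = Z(r0, c), d = Z(r0 + 1, c);
            P(ro, c) = a >= d ? a : d;
            amax(ro, c) = a >= d ? 0 : 1;
          }
        }
      if (cache) {
        cache->conv[l].pre = std::move(pre);
        cache->conv[l].imc = std::move(imc);
        cache->conv[l].argmax = std::move(amax);
        cache->conv[l].L_in = L; cache->conv[l].L_out = L2;
      }
      A = std::move(P);
    } else {
      if (cache) {
        cache->conv[l].pre = std::move(pre);
        cache->conv[l].imc = std::move(imc);
        cache->conv[l].L_in = L; cache->conv[l].L_out = L;
      }
      A = std::move(Z);
    }
    L = L2;
  }
  // flatten: sample b -> row of length L * C (column-major over (t, c))
  const int C = A.n_cols;
  mat flat(B, (size_t)L * C);
  for (int b = 0; b < B; ++b)
    flat.row(b) = vectorise(A.rows(b * L, b * L + L - 1)).t();
  mat h1 = flat * net.W1; h1.each_row() += net.b1;
  h1.transform([](double v) { return v > 0 ? v : 0.0; });
  mat h2 = h1 * net.W2; h2.each_row() += net.b2;
  h2.transform([](double v) { return v > 0 ? v : 0.0; });
  vec yhat = h2 * net.Wo + net.bo(0);
  if (cache) {
    cache->flat = std::move(flat);
    cache->h1 = std::move(h1);
    cache->h2 = std::move(h2);
    cache->yhat = yhat;
  }
  return yhat;
}

struct Grads {
  std::vector<mat> dW;      // conv weight grads
  std::vector<rowvec> db;
  mat dW1, dW2, dWo; rowvec db1, db2, dbo;
};

// MSE loss and full backward pass for one batch; returns loss
double backward(const Net& net, const mat& X, const vec& y, int B,
                Grads& g) {
  FwdCache cache;
  forward(net, X, B, &cache);
  vec diff = cache.yhat - y;
  double loss = dot(diff, diff) / B;
  vec dy = 2.0 * diff / B;

  g.dWo = cache.h2.t() * dy;
  g.dbo = rowvec{accu(dy)};
  mat dh2 = dy * net.Wo.t();
  dh2 %= conv_to<mat>::from(cache.h2 > 0);
  g.dW2 = cache.h1.t() * dh2;
  g.db2 = sum(dh2, 0);
  mat dh1 = dh2 * net.W2.t();
  dh1 %= conv_to<mat>::from(cache.h1 > 0);
  g.dW1 = cache.flat.t() * dh1;
  g.db1 = sum(dh1, 0);
  mat dflat = dh1 * net.W1.t();

  const int nconv = net.convs.size();
  g.dW.resize(nconv); g.db.resize(nconv);
  // un-flatten
  int L = cache.conv[nconv - 1].L_out;
  int C = net.convs[nconv - 1].W.n_cols;
  mat dA(B * (size_t)L, C);
  for (int b = 0; b < B; ++b)
    dA.rows(b * L, b * L + L - 1) =
        reshape(dflat.row(b).t(), L, C);
  for (int l = nconv - 1; l >= 0; --l) {
    const ConvLayer& cl = net.convs[l];
    const ConvCache& cc = cache.conv[l];
    mat dZ;
    if (cl.pool) {
      dZ.zeros(B * (size_t)cc.L_in, dA.n_cols);
      for (int b = 0; b < B; ++b)
        for (int t = 0; t < cc.L_out; ++t) {
          const size_t r0 = b * (size_t)cc.L_in + 2 * t;
          const size_t ro = b * (size_t)cc.L_out + t;
          for (uword c = 0; c < dA.n_cols; ++c)
            dZ(r0 + cc.argmax(ro, c), c) = dA(ro, c);
        }
    } else {
      dZ = dA;
    }
    dZ %= conv_to<mat>::from(cc.pre > 0);
    g.dW[l] = cc.imc.t() * dZ;
    g.db[l] = sum(dZ, 0);
    if (l > 0) {
      mat dimc = dZ * cl.W.t();
      const int C_in = net.convs[l - 1].W.n_cols;
      dA = col2im(dimc, B, cc.L_in, net.K, net.pad, C_in);
    }
  }
  return loss;
}

struct AdamState {
  std::vector<mat> mW, vW; std::vector<rowvec> mb, vb;
  mat m1, v1, m2, v2, mo, vo; rowvec mb1, vb1, mb2, vb2, mbo, vbo;
  long t = 0;
  void init(const Net& net) {
    for (const auto& c : net.convs) {
      mW.push_back(zeros<mat>(size(c.W))); vW.push_back(zeros<mat>(size(c.W)));
      mb.push_back(zeros<rowvec>(c.b.n_elem));
      vb.push_back(zeros<rowvec>(c.b.n_elem));
    }
    m1.zeros(size(net.W1)); v1.zeros(size(net.W1));
    m2.zeros(size(net.W2)); v2.zeros(size(net.W2));
    mo.zeros(size(net.Wo)); vo.zeros(size(net.Wo));
    mb1.zeros(net.b1.n_elem); vb1.zeros(net.b1.n_elem);
    mb2.zeros(net.b2.n_elem); vb2.zeros(net.b2.n_elem);
    mbo.zeros(net.bo.n_elem); vbo.zeros(net.bo.n_elem);
  }
};

template <class M>
void adam_step(M& w, M& m, M& v, const M& g, double lr, double b1, double b2,
               double eps, double bc1, double bc2) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  w -= lr * (m / bc1) / (sqrt(v / bc2) + eps);
}

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericVector cpp_cnn_forward(Rcpp::List params,
                                    Rcpp::NumericMatrix Xr,
                                    int chunk = 256) {
  Net net = parse_net(params);
  mat X(Xr.begin(), Xr.nrow(), Xr.ncol(), false);
  const int n = X.n_rows;
  vec out(n);
  for (int i0 = 0; i0 < n; i0 += chunk) {
    const int i1 = std::min(n, i0 + chunk);
    out.subvec(i0, i1 - 1) =
        forward(net, X.rows(i0, i1 - 1), i1 - i0, nullptr);
  }
  return Rcpp::NumericVector(out.begin(), out.end());
}

// [[Rcpp::export]]
Rcpp::List cpp_cnn_loss_grad(Rcpp::List params, Rcpp::NumericMatrix Xr,
                             Rcpp::NumericVector yr) {
  Net net = parse_net(params);
  mat X(Xr.begin(), Xr.nrow(), Xr.ncol(), false);
  vec y(yr.begin(), yr.size(), false);
  Grads g;
  double loss = backward(net, X, y, X.n_rows, g);
  Rcpp::List convs(g.dW.size());
  for (size_t i = 0; i < g.dW.size(); ++i)
    convs[i] = Rcpp::List::create(Rcpp::Named("W") = g.dW[i],
                                  Rcpp::Named("b") = g.db[i]);
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss, Rcpp::Named("convs") = convs,
      Rcpp::Named("W1") = g.dW1, Rcpp::Named("b1") = g.db1,
      Rcpp::Named("W2") = g.dW2, Rcpp::Named("b2") = g.db2,
      Rcpp::Named("Wo") = g.dWo, Rcpp::Named("bo") = g.dbo);
}

// order: epochs x n matrix of 1-based shuffled row indices (from R's RNG)
// [[Rcpp::export]]
Rcpp::List cpp_cnn_train(Rcpp::List params, Rcpp::NumericMatrix Xr,
                         Rcpp::NumericVector yr, Rcpp::IntegerMatrix order,
                         int batch = 64, double lr = 1e-3,
                         double beta1 = 0.9, double beta2 = 0.999,
                         double eps = 1e-8) {
  Net net = parse_net(params);
  mat X(Xr.begin(), Xr.nrow(), Xr.ncol(), false);
  vec y(yr.begin(), yr.size(), false);
  const int n = X.n_rows, epochs = order.nrow();
  AdamState st; st.init(net);
  vec history(epochs, fill::zeros);
  for (int e = 0; e < epochs; ++e) {
    double epoch_loss = 0; int nb = 0;
    for (int i0 = 0; i0 < n; i0 += batch) {
      const int i1 = std::min(n, i0 + batch), B = i1 - i0;
      mat Xb(B, X.n_cols); vec yb(B);
      for (int j = 0; j < B; ++j) {
        const int idx = order(e, i0 + j) - 1;
        Xb.row(j) = X.row(idx); yb(j) = y(idx);
      }
      Grads g;
      epoch_loss += backward(net, Xb, yb, B, g);
      ++nb;
      ++st.t;
      const double bc1 = 1 - std::pow(beta1, (double)st.t);
      const double bc2 = 1 - std::pow(beta2, (double)st.t);
      for (size_t l = 0; l < net.convs.size(); ++l) {
        adam_step(net.convs[l].W, st.mW[l], st.vW[l], g.dW[l], lr, beta1,
                  beta2, eps, bc1, bc2);
        adam_step(net.convs[l].b, st.mb[l], st.vb[l], g.db[l], lr, beta1,
                  beta2, eps, bc1, bc2);
      }
      adam_step(net.W1, st.m1, st.v1, g.dW1, lr, beta1, beta2, eps, bc1, bc2);
      adam_step(net.b1, st.mb1, st.vb1, g.db1, lr, beta1, beta2, eps, bc1, bc2);
      adam_step(net.W2, st.m2, st.v2, g.dW2, lr, beta1, beta2, eps, bc1, bc2);
      adam_step(net.b2, st.mb2, st.vb2, g.db2, lr, beta1, beta2, eps, bc1, bc2);
      adam_step(net.Wo, st.mo, st.vo, g.dWo, lr, beta1, beta2, eps, bc1, bc2);
      adam_step(net.bo, st.mbo, st.vbo, g.dbo, lr, beta1, beta2, eps, bc1, bc2);
    }
    history(e) = epoch_loss / nb;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("params") = unparse_net(net),
                            Rcpp::Named("history") = history);
}
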