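// 1-D convolutional network for vital-sign windows.
//
// Five blocks of (same-padding convolution, ReLU, max-pool, inverted
// dropout) followed by a dense sigmoid head; trained with Adam on a
// class-weighted binary cross-entropy. All randomness (initialisation,
// shuffling, dropout) comes from a single std::mt19937 seeded from R, so
// training is bit-reproducible for a given seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct LayerCfg {
  int c_in, c_out, k, pool, l_in, l_out, l_pool;
};

struct Net {
  std::vector<LayerCfg> cfg;
  std::vector<mat> W;    // (c_out, c_in * k)
  std::vector<vec> b;
  vec w_dense;
  double b_dense;
  int flat_dim;
};

// columns of the im2col matrix: sample-major, position-minor
void im2col(const cube& A, const uvec& idx, int k, mat& out) {
  const int C = A.n_rows, L = A.n_cols, pad = k / 2;
  const int B = idx.n_elem;
  out.set_size(C * k, (size_t)B * L);
  out.zeros();
  for (int s = 0; s < B; ++s) {
    const mat& a = A.slice(idx[s]);
    for (int j = 0; j < L; ++j) {
      double* col = out.colptr((size_t)s * L + j);
      for (int t = 0; t < k; ++t) {
        int src = j - pad + t;
        if (src >= 0 && src < L) {
          const double* ap = a.colptr(src);
          for (int c = 0; c < C; ++c) col[t * C + c] = ap[c];
        }
      }
    }
  }
}

void col2im(const mat& dcol, int C, int L, int k, int B, cube& dA) {
  const int pad = k / 2;
  dA.set_size(C, L, B);
  dA.zeros();
  for (int s = 0; s < B; ++s) {
    mat& da = dA.slice(s);
    for (int j = 0; j < L; ++j) {
      const double* col = dcol.colptr((size_t)s * L + j);
      for (int t = 0; t < k; ++t) {
        int src = j - pad + t;
        if (src >= 0 && src < L) {
          double* dp = da.colptr(src);
          for (int c = 0; c < C; ++c) dp[c] += col[t * C + c];
        }
      }
    }
  }
}

struct Cache {
  mat Xcol, Z;          // pre-activation
  umat argmax;          // (c_out, B * l_pool)
  mat mask;             // dropout mask on pooled output
  cube pooled;          // (c_out, l_pool, B)
};

// forward one block; returns pooled (+ dropout if training) activations
cube block_forward(const cube& A, const uvec& idx, const LayerCfg& lc,
                   const mat& W, const vec& b, double drop, bool training,
                   std::mt19937& rng, Cache* cache) {
  const int B = idx.n_elem;
  mat Xcol;
  im2col(A, idx, lc.k, Xcol);
  mat Z = W * Xcol;
  Z.each_col() += b;
  mat R = clamp(Z, 0.0, datum::inf);
  cube P(lc.c_out, lc.l_pool, B);
  umat amax(lc.c_out, (size_t)B * lc.l_pool);
  for (int s = 0; s < B; ++s) {
    for (int j = 0; j < lc.l_pool; ++j) {
      size_t base = (size_t)s * lc.l_out + (size_t)j * lc.pool;
      for (int c = 0; c < lc.c_out; ++c) {
        double best = R(c, base);
        int bidx = 0;
        for (int t = 1; t < lc.pool; ++t) {
          if (R(c, base + t) > best) { best = R(c, base + t); bidx = t; }
        }
        P(c, j, s) = best;
        amax(c, (size_t)s * lc.l_pool + j) = base + bidx;
      }
    }
  }
  mat mask;
  if (training && drop > 0) {
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    mask.set_size(lc.c_out, (size_t)B * lc.l_pool);
    for (size_t i = 0; i < mask.n_elem; ++i)
      mask(i) = unif(rng) < drop ? 0.0 : 1.0 / (1.0 - drop);
    for (int s = 0; s < B; ++s)
      P.slice(s) %= mask.cols((size_t)s * lc.l_pool,
                              (size_t)(s + 1) * lc.l_pool - 1);
  }
  if (cache) {
    cache->Xcol = std::move(Xcol);
    cache->Z = std::move(Z);
    cache->argmax = std::move(amax);
    cache->mask = std::move(mask);
    cache->pooled = P;
  }
  return P;
}

uvec all_indices(int n) { return regspace<uvec>(0, n - 1); }

vec net_forward(const Net& net, const cube& X, const uvec& idx,
                bool training, double drop, std::mt19937& rng,
                std::vector<Cache>* caches) {
  cube A = X;
  uvec cur = idx;
  for (size_t l = 0; l < net.cfg.size(); ++l) {
    Cache* cc = caches ? &(*caches)[l] : nullptr;
    A = block_forward(A, cur, net.cfg[l], net.W[l], net.b[l], drop,
                      training, rng, cc);
    cur = all_indices(A.n_slices);
  }
  const int B = A.n_slices;
  vec z(B);
  for (int s = 0; s < B; ++s)
    z[s] = dot(net.w_dense, vectorise(A.slice(s))) + net.b_dense;
  return 1.0 / (1.0 + exp(-z));
}

double weighted_bce(const vec& p, const vec& y, double w0, double w1) {
  vec pc = clamp(p, 1e-12, 1.0 - 1e-12);
  vec wt = y * w1 + (1.0 - y) * w0;
  return mean(-wt % (y % log(pc) + (1.0 - y) % log(1.0 - pc)));
}

struct Adam {
  std::vector<mat> mW, vW;
  std::vector<vec> mb, vb;
  vec mw_d, vw_d;
  double mb_d = 0, vb_d = 0;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;

  void init(const Net& net) {
    for (size_t l = 0; l < net.W.size(); ++l) {
      mW.push_back(zeros<mat>(size(net.W[l])));
      vW.push_back(zeros<mat>(size(net.W[l])));
      mb.push_back(zeros<vec>(net.b[l].n_elem));
      vb.push_back(zeros<vec>(net.b[l].n_elem));
    }
    mw_d = zeros<vec>(net.w_dense.n_elem);
    vw_d = zeros<vec>(net.w_dense.n_elem);
  }
  template <typename T>
  void upd(T& par, T& m, T& v, const T& g, double lr) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    T mh = m / (1 - std::pow(b1, (double)t));
    T vh = v / (1 - std::pow(b2, (double)t));
    par -= lr * mh / (sqrt(vh) + eps);
  }
  void upd_scalar(double& par, double& m, double& v, double g, double lr) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * g * g;
    par -= lr * (m / (1 - std::pow(b1, (double)t))) /
           (std::sqrt(v / (1 - std::pow(b2, (double)t))) + eps);
  }
};

Net build_net(int C, int T, int kernel, const ivec& filters, int pool,
              std::mt19937& rng) {
  Net net;
  int c_in = C, L = T;
  for (size_t l = 0; l < filters.n_elem; ++l) {
    LayerCfg lc;
    lc.c_in = c_in; lc.c_out = filters[l]; lc.k = kernel; lc.pool = pool;
    lc.l_in = L; lc.l_out = L; lc.l_pool = L / pool;
    if (lc.l_pool < 1)
      Rcpp::stop("window too short for the configured pooling depth");
    net.cfg.push_back(lc);
    std::normal_distribution<double> gauss(0.0,
        std::sqrt(2.0 / (c_in * kernel)));
    mat W(lc.c_out, c_in * kernel);
    for (size_t i = 0; i < W.n_elem; ++i) W(i) = gauss(rng);
    net.W.push_back(W);
    net.b.push_back(zeros<vec>(lc.c_out));
    c_in = lc.c_out; L = lc.l_pool;
  }
  net.flat_dim = c_in * L;
  std::normal_distribution<double> gauss(0.0, std::sqrt(1.0 / net.flat_dim));
  net.w_dense.set_size(net.flat_dim);
  for (int i = 0; i < net.flat_dim; ++i) net.w_dense[i] = gauss(rng);
  net.b_dense = 0.0;
  return net;
}

Rcpp::List net_to_list(const Net& net) {
  Rcpp::List Ws, bs;
  for (size_t l = 0; l < net.W.size(); ++l) {
    Ws.push_back(Rcpp::wrap(net.W[l]));
    bs.push_back(Rcpp::wrap(net.b[l]));
  }
  return Rcpp::List::create(
      Rcpp::Named("conv_w") = Ws, Rcpp::Named("conv_b") = bs,
      Rcpp::Named("dense_w") = Rcpp::wrap(net.w_dense),
      Rcpp::Named("dense_b") = net.b_dense);
}

void list_to_net(const Rcpp::List& wl, int C, int T, int kernel,
                 const ivec& filters, int pool, Net& net) {
  std::mt19937 dummy(1);
  net = build_net(C, T, kernel, filters, pool, dummy);
  Rcpp::List Ws = wl["conv_w"], bs = wl["conv_b"];
  for (size_t l = 0; l < net.W.size(); ++l) {
    net.W[l] = Rcpp::as<mat>(Ws[l]);
    net.b[l] = Rcpp::as<vec>(bs[l]);
  }
  net.w_dense = Rcpp::as<vec>(wl["dense_w"]);
  net.b_dense = Rcpp::as<double>(wl["dense_b"]);
}

}  // namespace

// [[Rcpp::export(name = ".cnn_train_cpp")]]
Rcpp::List cnn_train_cpp(const arma::cube& X, const arma::vec& y,
                         int kernel, const arma::ivec& filters, int pool,
                         double dropout, double lr, int batch, int epochs,
                         int patience, double w0, double w1,
                         const arma::uvec& val_idx, int seed) {
  const int C = X.n_rows, T = X.n_cols, N = X.n_slices;
  std::mt19937 rng((unsigned)seed);
  Net net = build_net(C, T, kernel, filters, pool, rng);
  Adam opt;
  opt.init(net);

  std::vector<char> is_val(N, 0);
  for (size_t i = 0; i < val_idx.n_elem; ++i) is_val[val_idx[i]] = 1;
  std::vector<unsigned> train_i;
  for (int i = 0; i < N; ++i) if (!is_val[i]) train_i.push_back(i);
  const int n_layers = net.cfg.size();

  double best_val = datum::inf;
  Rcpp::List best_weights = net_to_list(net);
  int best_epoch = 0, bad = 0;
  std::vector<double> train_trace, val_trace;

  for (int ep = 1; ep <= epochs; ++ep) {
    std::shuffle(train_i.begin(), train_i.end(), rng);
    double ep_loss = 0; int n_batches = 0;
    for (size_t off = 0; off < train_i.size(); off += batch) {
      size_t hi = std::min(off + batch, train_i.size());
      uvec idx(hi - off);
      for (size_t i = off; i < hi; ++i) idx[i - off] = train_i[i];
      const int B = idx.n_elem;

      std::vector<Cache> caches(n_layers);
      vec p = net_forward(net, X, idx, true, dropout, rng, &caches);
      vec yy(B);
      for (int s = 0; s < B; ++s) yy[s] = y[idx[s]];
      ep_loss += weighted_bce(p, yy, w0, w1);
      ++n_batches;

      // dense backward
      vec wt = yy * w1 + (1.0 - yy) * w0;
      vec dz = wt % (p - yy) / B;
      const cube& last = caches[n_layers - 1].pooled;
      vec gw = zeros<vec>(net.flat_dim);
      double gb = 0;
      mat dflat(net.flat_dim, B);
      for (int s = 0; s < B; ++s) {
        vec xs = vectorise(last.slice(s));
        gw += dz[s] * xs;
        gb += dz[s];
        dflat.col(s) = dz[s] * net.w_dense;
      }

      // backprop through blocks
      cube dA;  // gradient w.r.t. pooled output of current layer
      {
        const LayerCfg& lc = net.cfg[n_layers - 1];
        dA.set_size(lc.c_out, lc.l_pool, B);
        for (int s = 0; s < B; ++s)
          dA.slice(s) = reshape(dflat.col(s), lc.c_out, lc.l_pool);
      }
      std::vector<mat> gW(n_layers);
      std::vector<vec> gB(n_layers);
      for (int l = n_layers - 1; l >= 0; --l) {
        const LayerCfg& lc = net.cfg[l];
        Cache& cc = caches[l];
        // dropout
        if (cc.mask.n_elem) {
          for (int s = 0; s < B; ++s)
            dA.slice(s) %= cc.mask.cols((size_t)s * lc.l_pool,
                                        (size_t)(s + 1) * lc.l_pool - 1);
        }
        // un-pool
        mat dR(lc.c_out, (size_t)B * lc.l_out, fill::zeros);
        for (int s = 0; s < B; ++s) {
          for (int j = 0; j < lc.l_pool; ++j) {
            for (int c = 0; c < lc.c_out; ++c) {
              size_t src = cc.argmax(c, (size_t)s * lc.l_pool + j);
              dR(c, src) += dA(c, j, s);
            }
          }
        }
        // ReLU
        dR %= conv_to<mat>::from(cc.Z > 0);
        gW[l] = dR * cc.Xcol.t();
        gB[l] = sum(dR, 1);
        if (l > 0) {
          mat dcol = net.W[l].t() * dR;
          col2im(dcol, lc.c_in, lc.l_in, lc.k, B, dA);
        }
      }

      // Adam step
      ++opt.t;
      for (int l = 0; l < n_layers; ++l) {
        opt.upd(net.W[l], opt.mW[l], opt.vW[l], gW[l], lr);
        opt.upd(net.b[l], opt.mb[l], opt.vb[l], gB[l], lr);
      }
      opt.upd(net.w_dense, opt.mw_d, opt.vw_d, gw, lr);
      opt.upd_scalar(net.b_dense, opt.mb_d, opt.vb_d, gb, lr);
    }
    train_trace.push_back(ep_loss / std::max(1, n_batches));

    if (val_idx.n_elem > 0) {
      vec pv = net_forward(net, X, val_idx, false, 0.0, rng, nullptr);
      vec yv(val_idx.n_elem);
      for (size_t i = 0; i < val_idx.n_elem; ++i) yv[i] = y[val_idx[i]];
      double vl = weighted_bce(pv, yv, w0, w1);
      val_trace.push_back(vl);
      if (vl < best_val - 1e-6) {
        best_val = vl; best_epoch = ep; bad = 0;
        best_weights = net_to_list(net);
      } else if (++bad >= patience) {
        break;
      }
    } else {
      best_weights = net_to_list(net);
      best_epoch = ep;
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = best_weights,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("train_loss") = train_trace,
      Rcpp::Named("val_loss") = val_trace);
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
arma::vec cnn_predict_cpp(const Rcpp::List& weights, const arma::cube& X,
                          int kernel, const arma::ivec& filters, int pool) {
  Net net;
  list_to_net(weights, X.n_rows, X.n_cols, kernel, filters, pool, net);
  std::mt19937 rng(1);
  return net_forward(net, X, all_indices(X.n_slices), false, 0.0, rng,
                     nullptr);
}

// Harrell concordance pair counting on (time, event, prediction) with
// ties in predictions counting one half.
// [[Rcpp::export(name = ".concordance_pairs_cpp")]]
Rcpp::NumericVector concordance_pairs(const arma::vec& time,
                                      const arma::ivec& event,
                                      const arma::vec& pred) {
  const int n = time.n_elem;
  double conc = 0, comp = 0;
  for (int i = 0; i < n; ++i) {
    if (event[i] != 1) continue;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      bool comparable = (time[i] < time[j]) ||
                        (time[i] == time[j] && event[j] == 0);
      if (!comparable) continue;
      comp += 1.0;
      if (pred[i] > pred[j]) conc += 1.0;
      else if (pred[i] == pred[j]) conc += 0.5;
    }
  }
  return Rcpp::NumericVector::create(conc, comp);
}
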