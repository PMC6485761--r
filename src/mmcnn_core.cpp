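// Core numerics of the bimodal multi-sized-filter CNN: forward pass,
// backpropagation, Adadelta training and response extraction.
//
// Layout conventions (all 0-based):
//  - sequence input: L x 4 one-hot (A,U,G,C), structure input: sparse
//    triplets (i, j, v) of the symmetric L x L stem-pair probability matrix.
//  - convolution along the position axis uses "same" zero padding with the
//    patch for output position i covering input rows [i - f/2, i + f/2).
//  - first-layer weights: seq (f*4 x K1) with patch index a*4 + c; structure
//    (f*f x K1) with patch index a*f + b (a = offset on the position axis,
//    b = offset on the pairing-partner axis).
//  - the stacked combined representation has channel blocks
//    [seq_s1 | shape_s1 | seq_s2 | shape_s2 | ...] of K1 each, matching the
//    filter-type order (seq8, shape8, seq16, shape16, seq32, shape32).
//  - combined layer weights: (f*C x K2), patch index a*C + ch; after each
//    combined layer the three size outputs are stacked size-major (S*K2
//    channels) and the position axis is max-pooled by 2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>
#include <algorithm>
#include <vector>

using namespace arma;

struct Config {
  int L;                 // input length
  std::vector<int> fs;   // filter sizes
  int K1;                // filters per size, first layer
  int K2;                // filters per size, combined layers
  int ncomb;             // number of combined MCM layers (pool 2 each)
  int dense;             // dense units
  double keep1, keep2;   // dropout keep-probabilities
};

static Config read_config(const Rcpp::List& cfg) {
  Config c;
  c.L = Rcpp::as<int>(cfg["length"]);
  Rcpp::IntegerVector f = cfg["filter_sizes"];
  c.fs.assign(f.begin(), f.end());
  c.K1 = Rcpp::as<int>(cfg["filters_per_size"]);
  c.K2 = Rcpp::as<int>(cfg["combined_filters"]);
  c.ncomb = Rcpp::as<int>(cfg["n_combined_layers"]);
  c.dense = Rcpp::as<int>(cfg["dense_units"]);
  c.keep1 = Rcpp::as<double>(cfg["dropout_keep_conv"]);
  c.keep2 = Rcpp::as<double>(cfg["dropout_keep_dense"]);
  return c;
}

// Flat parameter order (must match weights_flatten() on the R side):
//   seq_w[s], seq_b[s], str_w[s], str_b[s] for each size s,
//   then per combined layer l: comb_w[l][s], comb_b[l][s],
//   then d1_w, d1_b, d2_w, d2_b.
static std::vector<mat> params_from_list(const Rcpp::List& w) {
  std::vector<mat> p;
  p.reserve(w.size());
  for (int i = 0; i < w.size(); ++i)
    p.push_back(Rcpp::as<mat>(w[i]));
  return p;
}

static Rcpp::List params_to_list(const std::vector<mat>& p) {
  Rcpp::List out(p.size());
  for (size_t i = 0; i < p.size(); ++i) out[i] = Rcpp::wrap(p[i]);
  return out;
}

struct ParamIdx {
  int S;
  int seq_w(int s) const { return s; }
  int seq_b(int s) const { return S + s; }
  int str_w(int s) const { return 2 * S + s; }
  int str_b(int s) const { return 3 * S + s; }
  int comb_w(int l, int s) const { return 4 * S + l * 2 * S + s; }
  int comb_b(int l, int s) const { return 4 * S + l * 2 * S + S + s; }
  int d1_w(int ncomb) const { return 4 * S + ncomb * 2 * S; }
  int d1_b(int ncomb) const { return d1_w(ncomb) + 1; }
  int d2_w(int ncomb) const { return d1_w(ncomb) + 2; }
  int d2_b(int ncomb) const { return d1_w(ncomb) + 3; }
  int total(int ncomb) const { return d1_w(ncomb) + 4; }
};

static void im2col(const mat& A, int f, mat& P) {
  const int L = A.n_rows, C = A.n_cols;
  P.zeros(L, f * C);
  const int half = f / 2;
  for (int a = 0; a < f; ++a) {
    const int lo = std::max(0, half - a);          // i range with p in [0,L)
    const int hi = std::min(L, L + half - a);
    for (int ch = 0; ch < C; ++ch) {
      const double* src = A.colptr(ch);
      double* dst = P.colptr(a * C + ch);
      for (int i = lo; i < hi; ++i) dst[i] = src[i - half + a];
    }
  }
}

static void col2im_add(const mat& dP, int f, mat& dA) {
  const int L = dA.n_rows, C = dA.n_cols;
  const int half = f / 2;
  for (int a = 0; a < f; ++a) {
    const int lo = std::max(0, half - a);
    const int hi = std::min(L, L + half - a);
    for (int ch = 0; ch < C; ++ch) {
      const double* src = dP.colptr(a * C + ch);
      double* dst = dA.colptr(ch);
      for (int i = lo; i < hi; ++i) dst[i - half + a] += src[i];
    }
  }
}

// Sparse 2-D structure convolution, ReLU after a global max over the
// pairing-partner axis (max and ReLU commute since ReLU is monotone).
// tr: nnz x 3 triplets (i, j, v); byP buckets triplet rows by i.
// Wt is the K x f*f transposed filter bank. Outputs: pre (pre-ReLU max),
// argj (partner-axis argmax, -1 when an all-zero column wins), O = ReLU.
struct StructScratch {
  mat B;                       // K x L accumulation buffer
  std::vector<int> lastTouch;  // row epoch marks
  std::vector<int> touched;
};

static void struct_forward(const mat& tr, const std::vector<std::vector<int>>& byP,
                           const mat& Wt, const vec& b, int L, int f,
                           mat& pre, imat& argj, mat& O, StructScratch& sc) {
  const int K = Wt.n_rows;
  const int half = f / 2;
  pre.set_size(L, K); argj.set_size(L, K); O.set_size(L, K);
  sc.B.set_size(K, L);
  sc.lastTouch.assign(L, -1);
  const int nnz = tr.n_rows;
  for (int i = 0; i < L; ++i) {
    sc.touched.clear();
    if (nnz > 0) {
      for (int a = 0; a < f; ++a) {
        const int p = i - half + a;
        if (p < 0 || p >= L) continue;
        for (int idx : byP[p]) {
          const int q = (int)tr(idx, 1);
          const double v = tr(idx, 2);
          const int b_lo = std::max(0, q + half - (L - 1));
          const int b_hi = std::min(f - 1, q + half);
          for (int bq = b_lo; bq <= b_hi; ++bq) {
            const int j = q + half - bq;
            double* Bj = sc.B.colptr(j);
            if (sc.lastTouch[j] != i) {
              sc.lastTouch[j] = i;
              std::fill(Bj, Bj + K, 0.0);
              sc.touched.push_back(j);
            }
            const double* wc = Wt.colptr(a * f + bq);
            for (int k = 0; k < K; ++k) Bj[k] += v * wc[k];
          }
        }
      }
    }
    std::sort(sc.touched.begin(), sc.touched.end());
    const bool has_empty = (int)sc.touched.size() < L;
    for (int k = 0; k < K; ++k) {
      double m = has_empty ? b[k] : -datum::inf;
      int arg = has_empty ? -1 : -2;
      for (int j : sc.touched) {
        const double val = sc.B(k, j) + b[k];
        if (val > m) { m = val; arg = j; }
      }
      pre(i, k) = m;
      argj(i, k) = arg;
      O(i, k) = m > 0 ? m : 0.0;
    }
  }
}

static void struct_backward(const mat& tr, const std::vector<std::vector<int>>& byP,
                            const mat& dS, const mat& pre, const imat& argj,
                            int L, int f, mat& dW, mat& db) {
  const int K = dS.n_cols;
  const int half = f / 2;
  for (int i = 0; i < L; ++i)
    for (int k = 0; k < K; ++k)
      if (pre(i, k) > 0 && dS(i, k) != 0) db(k, 0) += dS(i, k);
  if (tr.n_rows == 0) return;
  for (int i = 0; i < L; ++i) {
    for (int a = 0; a < f; ++a) {
      const int p = i - half + a;
      if (p < 0 || p >= L) continue;
      for (int idx : byP[p]) {
        const int q = (int)tr(idx, 1);
        const double v = tr(idx, 2);
        for (int k = 0; k < K; ++k) {
          if (pre(i, k) <= 0 || dS(i, k) == 0) continue;
          const int j = argj(i, k);
          if (j < 0) continue;
          const int bq = q + half - j;
          if (bq < 0 || bq >= f) continue;
          dW(a * f + bq, k) += dS(i, k) * v;
        }
      }
    }
  }
}

// Per-sample forward cache (buffers reused across samples).
struct Cache {
  std::vector<mat> seqP, seqPre, seqO;       // per size
  std::vector<mat> strPre, strO;
  std::vector<imat> strArg;
  mat Z0;                                    // stacked combined input (pre dropout)
  mat mask1;                                 // dropout mask on Z0
  std::vector<mat> A;                        // combined layer inputs, A[0] = dropped Z0
  std::vector<std::vector<mat>> P, Opre;     // [layer][size] im2col / ReLU'd pre-pool
  std::vector<std::vector<imat>> poolArg;    // pooled row parity argmax
  vec flat, mask2, h1pre, h1;
  double score, spre;
};

static std::vector<std::vector<int>> bucket_by_p(const mat& tr, int L) {
  std::vector<std::vector<int>> byP(L);
  for (uword r = 0; r < tr.n_rows; ++r) {
    int p = (int)tr(r, 0);
    if (p >= 0 && p < L) byP[p].push_back((int)r);
  }
  return byP;
}

static double forward_one(const Config& c, const ParamIdx& ix,
                          const std::vector<mat>& par,
                          const std::vector<mat>& strWt,
                          const mat& X, const mat& tr,
                          const std::vector<std::vector<int>>& byP,
                          Cache& cc, bool train, std::mt19937_64* rng,
                          StructScratch& sc) {
  const int S = (int)c.fs.size();
  const int C0 = 2 * S * c.K1;
  cc.seqP.resize(S); cc.seqPre.resize(S); cc.seqO.resize(S);
  cc.strPre.resize(S); cc.strO.resize(S); cc.strArg.resize(S);
  // sequence path
  for (int s = 0; s < S; ++s) {
    im2col(X, c.fs[s], cc.seqP[s]);
    cc.seqPre[s] = cc.seqP[s] * par[ix.seq_w(s)];
    cc.seqPre[s].each_row() += par[ix.seq_b(s)].t();
    cc.seqO[s] = clamp(cc.seqPre[s], 0.0, datum::inf);
  }
  // structure path
  for (int s = 0; s < S; ++s)
    struct_forward(tr, byP, strWt[s], par[ix.str_b(s)].col(0), c.L, c.fs[s],
                   cc.strPre[s], cc.strArg[s], cc.strO[s], sc);
  // stack: [seq_s | shape_s] blocks of K1
  cc.Z0.set_size(c.L, C0);
  for (int s = 0; s < S; ++s) {
    cc.Z0.cols(2 * s * c.K1, (2 * s + 1) * c.K1 - 1) = cc.seqO[s];
    cc.Z0.cols((2 * s + 1) * c.K1, (2 * s + 2) * c.K1 - 1) = cc.strO[s];
  }
  cc.A.resize(c.ncomb + 1);
  if (train && c.keep1 < 1.0) {
    std::uniform_real_distribution<double> U(0.0, 1.0);
    cc.mask1.set_size(c.L, C0);
    for (uword t = 0; t < cc.mask1.n_elem; ++t)
      cc.mask1[t] = U(*rng) < c.keep1 ? 1.0 / c.keep1 : 0.0;
    cc.A[0] = cc.Z0 % cc.mask1;
  } else {
    cc.A[0] = cc.Z0;
  }
  // combined layers
  cc.P.assign(c.ncomb, std::vector<mat>(S));
  cc.Opre.assign(c.ncomb, std::vector<mat>(S));
  cc.poolArg.assign(c.ncomb, std::vector<imat>(S));
  int Ll = c.L;
  for (int l = 0; l < c.ncomb; ++l) {
    const int Lh = Ll / 2;
    cc.A[l + 1].set_size(Lh, S * c.K2);
    for (int s = 0; s < S; ++s) {
      im2col(cc.A[l], c.fs[s], cc.P[l][s]);
      mat pre = cc.P[l][s] * par[ix.comb_w(l, s)];
      pre.each_row() += par[ix.comb_b(l, s)].t();
      cc.Opre[l][s] = clamp(pre, 0.0, datum::inf);
      cc.poolArg[l][s].set_size(Lh, c.K2);
      for (int i = 0; i < Lh; ++i)
        for (int k = 0; k < c.K2; ++k) {
          const double v0 = cc.Opre[l][s](2 * i, k), v1 = cc.Opre[l][s](2 * i + 1, k);
          const int w = v1 > v0 ? 1 : 0;   // tie -> lower position
          cc.poolArg[l][s](i, k) = w;
          cc.A[l + 1](i, s * c.K2 + k) = w ? v1 : v0;
        }
    }
    Ll = Lh;
  }
  cc.flat = vectorise(cc.A[c.ncomb]);
  if (train && c.keep2 < 1.0) {
    std::uniform_real_distribution<double> U(0.0, 1.0);
    cc.mask2.set_size(cc.flat.n_elem);
    for (uword t = 0; t < cc.mask2.n_elem; ++t)
      cc.mask2[t] = U(*rng) < c.keep2 ? 1.0 / c.keep2 : 0.0;
    cc.flat %= cc.mask2;
  }
  cc.h1pre = par[ix.d1_w(c.ncomb)].t() * cc.flat + par[ix.d1_b(c.ncomb)].col(0);
  cc.h1 = clamp(cc.h1pre, 0.0, datum::inf);
  cc.spre = dot(par[ix.d2_w(c.ncomb)].col(0), cc.h1) + par[ix.d2_b(c.ncomb)](0, 0);
  cc.score = 1.0 / (1.0 + std::exp(-cc.spre));
  return cc.score;
}

static void backward_one(const Config& c, const ParamIdx& ix,
                         const std::vector<mat>& par, const mat& tr,
                         const std::vector<std::vector<int>>& byP,
                         const Cache& cc, double y, bool train,
                         std::vector<mat>& g) {
  const int S = (int)c.fs.size();
  const double dspre = cc.score - y;  // d(BCE)/d(pre-sigmoid)
  g[ix.d2_b(c.ncomb)](0, 0) += dspre;
  g[ix.d2_w(c.ncomb)].col(0) += dspre * cc.h1;
  vec dh1 = dspre * par[ix.d2_w(c.ncomb)].col(0);
  dh1.elem(find(cc.h1pre <= 0)).zeros();
  g[ix.d1_b(c.ncomb)].col(0) += dh1;
  g[ix.d1_w(c.ncomb)] += cc.flat * dh1.t();
  vec dflat = par[ix.d1_w(c.ncomb)] * dh1;
  if (train && c.keep2 < 1.0) dflat %= cc.mask2;
  const int Lf = c.L >> c.ncomb;
  mat dA = reshape(dflat, Lf, S * c.K2);
  for (int l = c.ncomb - 1; l >= 0; --l) {
    const int Ll = c.L >> l;
    const int Lh = Ll / 2;
    mat dAprev(Ll, cc.A[l].n_cols, fill::zeros);
    for (int s = 0; s < S; ++s) {
      mat dPre(Ll, c.K2, fill::zeros);
      for (int i = 0; i < Lh; ++i)
        for (int k = 0; k < c.K2; ++k) {
          const int row = 2 * i + cc.poolArg[l][s](i, k);
          if (cc.Opre[l][s](row, k) > 0) dPre(row, k) = dA(i, s * c.K2 + k);
        }
      g[ix.comb_w(l, s)] += cc.P[l][s].t() * dPre;
      g[ix.comb_b(l, s)].col(0) += sum(dPre, 0).t();
      mat dP = dPre * par[ix.comb_w(l, s)].t();
      col2im_add(dP, c.fs[s], dAprev);
    }
    dA = std::move(dAprev);
  }
  // dA is gradient on A[0]; undo dropout to reach Z0 blocks
  if (train && c.keep1 < 1.0) dA %= cc.mask1;
  for (int s = 0; s < S; ++s) {
    mat dSeq = dA.cols(2 * s * c.K1, (2 * s + 1) * c.K1 - 1);
    dSeq.elem(find(cc.seqPre[s] <= 0)).zeros();
    g[ix.seq_w(s)] += cc.seqP[s].t() * dSeq;
    g[ix.seq_b(s)].col(0) += sum(dSeq, 0).t();
    mat dStr = dA.cols((2 * s + 1) * c.K1, (2 * s + 2) * c.K1 - 1);
    struct_backward(tr, byP, dStr, cc.strPre[s], cc.strArg[s], c.L, c.fs[s],
                    g[ix.str_w(s)], g[ix.str_b(s)]);
  }
}

static std::vector<mat> transposed_struct_filters(const Config& c, const ParamIdx& ix,
                                                  const std::vector<mat>& par) {
  std::vector<mat> wt(c.fs.size());
  for (size_t s = 0; s < c.fs.size(); ++s) wt[s] = par[ix.str_w((int)s)].t();
  return wt;
}

static double bce(double p, double y) {
  const double eps = 1e-12;
  return -(y * std::log(p + eps) + (1.0 - y) * std::log(1.0 - p + eps));
}

// [[Rcpp::export]]
Rcpp::List cpp_forward(Rcpp::List weights, arma::cube seqs, Rcpp::List str,
                       Rcpp::List cfg, bool responses = false) {
  const Config c = read_config(cfg);
  const ParamIdx ix{(int)c.fs.size()};
  std::vector<mat> par = params_from_list(weights);
  std::vector<mat> strWt = transposed_struct_filters(c, ix, par);
  const int n = seqs.n_slices;
  Rcpp::NumericVector scores(n);
  Rcpp::List resp(responses ? n : 0);
  Cache cc; StructScratch sc;
  for (int i = 0; i < n; ++i) {
    mat tr = Rcpp::as<mat>(str[i]);
    auto byP = bucket_by_p(tr, c.L);
    scores[i] = forward_one(c, ix, par, strWt, seqs.slice(i), tr, byP, cc,
                            false, nullptr, sc);
    if (responses) {
      Rcpp::List rs, rt, r1;
      for (size_t s = 0; s < c.fs.size(); ++s) {
        rs.push_back(Rcpp::wrap(cc.seqO[s]));
        rt.push_back(Rcpp::wrap(cc.strO[s]));
        const int Lh = c.L / 2;
        mat c1(Lh, c.K2);
        for (int p = 0; p < Lh; ++p)
          for (int k = 0; k < c.K2; ++k)
            c1(p, k) = cc.A[1](p, (int)s * c.K2 + k);
        r1.push_back(Rcpp::wrap(c1));
      }
      resp[i] = Rcpp::List::create(
        Rcpp::Named("sequence") = rs,
        Rcpp::Named("structure") = rt,
        Rcpp::Named("combined_input") = Rcpp::wrap(cc.Z0),
        Rcpp::Named("combined_response") = r1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("scores") = scores,
                            Rcpp::Named("responses") = resp);
}

// Deterministic (dropout-free) mean loss and gradients on a batch; used for
// gradient verification and by the trainer via train_epochs.
// [[Rcpp::export]]
Rcpp::List cpp_grads(Rcpp::List weights, arma::cube seqs, Rcpp::List str,
                     arma::vec labels, Rcpp::List cfg) {
  const Config c = read_config(cfg);
  const ParamIdx ix{(int)c.fs.size()};
  std::vector<mat> par = params_from_list(weights);
  std::vector<mat> strWt = transposed_struct_filters(c, ix, par);
  std::vector<mat> g(par.size());
  for (size_t t = 0; t < par.size(); ++t) g[t] = zeros<mat>(par[t].n_rows, par[t].n_cols);
  const int n = seqs.n_slices;
  double loss = 0;
  Cache cc; StructScratch sc;
  for (int i = 0; i < n; ++i) {
    mat tr = Rcpp::as<mat>(str[i]);
    auto byP = bucket_by_p(tr, c.L);
    double p = forward_one(c, ix, par, strWt, seqs.slice(i), tr, byP, cc,
                           false, nullptr, sc);
    loss += bce(p, labels[i]);
    backward_one(c, ix, par, tr, byP, cc, labels[i], false, g);
  }
  loss /= n;
  for (size_t t = 0; t < g.size(); ++t) g[t] /= n;
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = params_to_list(g));
}

// Adadelta minibatch training with early stopping on validation loss.
// [[Rcpp::export]]
Rcpp::List cpp_train(Rcpp::List weights, arma::cube seqs, Rcpp::List str,
                     arma::vec labels, arma::uvec train_idx, arma::uvec valid_idx,
                     Rcpp::List cfg, Rcpp::List opt) {
  const Config c = read_config(cfg);
  const ParamIdx ix{(int)c.fs.size()};
  std::vector<mat> par = params_from_list(weights);
  const int epochs = Rcpp::as<int>(opt["epochs"]);
  const int batch = Rcpp::as<int>(opt["batch_size"]);
  const double lr = Rcpp::as<double>(opt["learning_rate"]);
  const double rho = Rcpp::as<double>(opt["rho"]);
  const double eps = Rcpp::as<double>(opt["epsilon"]);
  const std::string optimizer = Rcpp::as<std::string>(opt["optimizer"]);
  const bool use_adam = optimizer == "adam";
  const int patience = Rcpp::as<int>(opt["patience"]);
  const uint64_t seed = (uint64_t)Rcpp::as<double>(opt["seed"]);
  const bool verbose = Rcpp::as<bool>(opt["verbose"]);
  std::mt19937_64 rng(seed);

  // pre-extract structure triplets and buckets
  const int n = seqs.n_slices;
  std::vector<mat> trs(n);
  std::vector<std::vector<std::vector<int>>> byPs(n);
  for (int i = 0; i < n; ++i) {
    trs[i] = Rcpp::as<mat>(str[i]);
    byPs[i] = bucket_by_p(trs[i], c.L);
  }

  std::vector<mat> g(par.size()), Eg(par.size()), Ex(par.size());
  for (size_t t = 0; t < par.size(); ++t) {
    g[t] = zeros<mat>(par[t].n_rows, par[t].n_cols);
    Eg[t] = g[t]; Ex[t] = g[t];
  }
  std::vector<uword> order(train_idx.begin(), train_idx.end());
  std::vector<double> train_hist, valid_hist;
  std::vector<mat> best = par;
  double best_valid = datum::inf;
  int best_epoch = -1, stale = 0;
  long step = 0;
  Cache cc; StructScratch sc;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0; int ep_n = 0;
    for (size_t start = 0; start < order.size(); start += batch) {
      const size_t stop = std::min(order.size(), start + batch);
      for (size_t t = 0; t < g.size(); ++t) g[t].zeros();
      std::vector<mat> strWt = transposed_struct_filters(c, ix, par);
      double bloss = 0;
      for (size_t u = start; u < stop; ++u) {
        const int i = (int)order[u];
        double p = forward_one(c, ix, par, strWt, seqs.slice(i), trs[i],
                               byPs[i], cc, true, &rng, sc);
        bloss += bce(p, labels[i]);
        backward_one(c, ix, par, trs[i], byPs[i], cc, labels[i], true, g);
      }
      const double bn = (double)(stop - start);
      bloss /= bn;
      if (!std::isfinite(bloss))
        Rcpp::stop("training aborted: non-finite loss at epoch %d", ep + 1);
      ep_loss += bloss * bn; ep_n += (int)bn;
      ++step;
      for (size_t t = 0; t < g.size(); ++t) {
        g[t] /= bn;
        if (use_adam) {
          // Eg: second moment, Ex: first moment; beta1 0.9, beta2 = rho
          Ex[t] = 0.9 * Ex[t] + 0.1 * g[t];
          Eg[t] = rho * Eg[t] + (1.0 - rho) * square(g[t]);
          const double bc1 = 1.0 - std::pow(0.9, step);
          const double bc2 = 1.0 - std::pow(rho, step);
          par[t] -= lr * (Ex[t] / bc1) / (sqrt(Eg[t] / bc2) + eps);
        } else {
          Eg[t] = rho * Eg[t] + (1.0 - rho) * square(g[t]);
          mat dx = -(sqrt(Ex[t] + eps) / sqrt(Eg[t] + eps)) % g[t];
          Ex[t] = rho * Ex[t] + (1.0 - rho) * square(dx);
          par[t] += lr * dx;
        }
      }
    }
    train_hist.push_back(ep_loss / ep_n);
    // validation
    double vloss = 0;
    if (valid_idx.n_elem > 0) {
      std::vector<mat> strWt = transposed_struct_filters(c, ix, par);
      for (uword u = 0; u < valid_idx.n_elem; ++u) {
        const int i = (int)valid_idx[u];
        double p = forward_one(c, ix, par, strWt, seqs.slice(i), trs[i],
                               byPs[i], cc, false, nullptr, sc);
        vloss += bce(p, labels[i]);
      }
      vloss /= valid_idx.n_elem;
      valid_hist.push_back(vloss);
      if (vloss < best_valid) {
        best_valid = vloss; best = par; best_epoch = ep; stale = 0;
      } else if (++stale > patience) {
        if (verbose) Rcpp::Rcout << "early stop at epoch " << ep + 1 << "\n";
        break;
      }
    } else {
      best = par; best_epoch = ep;
    }
    if (verbose)
      Rcpp::Rcout << "epoch " << ep + 1 << " train " << train_hist.back()
                  << (valid_idx.n_elem ? " valid " + std::to_string(vloss) : "")
                  << "\n";
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = params_to_list(best),
    Rcpp::Named("train_loss") = train_hist,
    Rcpp::Named("valid_loss") = valid_hist,
    Rcpp::Named("best_epoch") = best_epoch + 1);
}
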