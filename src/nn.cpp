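// CNN backend: forward, backprop, Adam training loop and Grad-CAM gradients
// for the enhancer window classifier.  The network is small and fixed in
// topology (7 conv layers, SE gates between them, 2 pools, 2 dense layers);
// filter count, dense width and input width are read from the parameter
// shapes so toy models used in tests share this exact code path.
//
// The code is templated on the element type: training runs in single
// precision (the convention for this model class), prediction and Grad-CAM
// run in double precision.
//
// Input layout: one sample is a 5 x W matrix (assays x bins) flattened
// column-major, i.e. element (r, c) sits at index 5*c + r of the row.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using Rcpp::List;
using Rcpp::Named;
using Rcpp::stop;

static const int H = 5;       // assay rows
static const int KW2 = 10;    // 2D kernel width (5 x 10)
static const int KW1 = 4;     // 1D kernel width (1 x 4)
static const int PW = 4;      // max-pool width
static const int NSE = 6;     // SE blocks sit after conv1..conv6
static const int N1D = 5;     // conv3..conv7

// ---- parameter bookkeeping -------------------------------------------------

static std::vector<std::string> param_names() {
  std::vector<std::string> nm;
  nm.push_back("conv1_W"); nm.push_back("conv1_b");
  for (int l = 1; l <= NSE; ++l) {
    std::string p = "se" + std::to_string(l) + "_";
    nm.push_back(p + "Wr"); nm.push_back(p + "br");
    nm.push_back(p + "We"); nm.push_back(p + "be");
  }
  nm.push_back("conv2_W"); nm.push_back("conv2_b");
  for (int l = 3; l <= 7; ++l) {
    std::string p = "conv" + std::to_string(l) + "_";
    nm.push_back(p + "W"); nm.push_back(p + "b");
  }
  nm.push_back("dense1_W"); nm.push_back("dense1_b");
  nm.push_back("dense2_w"); nm.push_back("dense2_b");
  return nm;
}

template <typename eT>
struct Net {
  int nf, nfr, W, W1p, W2p, F, du;
  std::vector<arma::Mat<eT> > P;
  int i_c1W, i_c1b, i_se0, i_c2W, i_c2b, i_c3, i_d1W, i_d1b, i_d2w, i_d2b;
};

template <typename eT>
static Net<eT> build_net(const List& params, int ncols) {
  Net<eT> n;
  std::vector<std::string> nm = param_names();
  n.P.reserve(nm.size());
  for (size_t i = 0; i < nm.size(); ++i) {
    if (!params.containsElementNamed(nm[i].c_str()))
      stop("missing parameter '%s'", nm[i].c_str());
    arma::mat tmp = Rcpp::as<arma::mat>(params[nm[i]]);
    n.P.push_back(arma::conv_to<arma::Mat<eT> >::from(tmp));
  }
  n.i_c1W = 0; n.i_c1b = 1; n.i_se0 = 2;
  n.i_c2W = 2 + 4 * NSE; n.i_c2b = n.i_c2W + 1;
  n.i_c3  = n.i_c2b + 1;
  n.i_d1W = n.i_c3 + 2 * N1D; n.i_d1b = n.i_d1W + 1;
  n.i_d2w = n.i_d1b + 1; n.i_d2b = n.i_d2w + 1;

  n.nf  = (int) n.P[n.i_c1W].n_cols;
  n.nfr = (int) n.P[n.i_se0].n_rows;
  if (ncols % H != 0) stop("input length not a multiple of 5");
  n.W   = ncols / H;
  n.W1p = n.W / PW;
  n.W2p = n.W1p / PW;
  if (n.W2p < 1) stop("input width too small (need >= 16 bins)");
  n.F   = n.nf * n.W2p;
  n.du  = (int) n.P[n.i_d1W].n_cols;
  if ((int) n.P[n.i_c1W].n_rows != H * KW2) stop("conv1_W must be %d x nf", H * KW2);
  if ((int) n.P[n.i_c2W].n_rows != n.nf * H * KW2) stop("conv2_W shape mismatch");
  if ((int) n.P[n.i_d1W].n_rows != n.F)
    stop("dense1_W rows (%d) do not match flattened width (%d); model built for a different input width",
         (int) n.P[n.i_d1W].n_rows, n.F);
  return n;
}

template <typename eT>
static List net_to_list(const Net<eT>& n) {
  std::vector<std::string> nm = param_names();
  List out(nm.size());
  out.names() = Rcpp::wrap(nm);
  for (size_t i = 0; i < nm.size(); ++i)
    out[i] = arma::conv_to<arma::mat>::from(n.P[i]);
  return out;
}

// ---- forward ---------------------------------------------------------------

template <typename eT>
struct SECache { arma::Col<eT> z, hpre, h, s; };

template <typename eT>
struct Cache {
  arma::Mat<eT> C1, A1, U1;          // conv1: (5W x 50) -> (5W x nf)
  SECache<eT> se1;
  arma::Mat<eT> P1; arma::umat am1;  // pool1: (5*W1p x nf)
  arma::Mat<eT> C2;                  // (W1p x 50nf)
  arma::Mat<eT> A[6], U[5], C1d[5];  // A[j]: conv(2+j) post-relu; U: post-SE
  SECache<eT> se[5];                 // se2..se6
  arma::Mat<eT> P2; arma::umat am2;  // (W2p x nf)
  arma::Col<eT> f, h1pre, h1, dmask;
  // backward scratch (reused across samples)
  arma::Mat<eT> dA, dU, dC, dP1, dU1;
  eT logit;
};

template <typename eT>
static inline eT sigmoid_(eT x) { return (eT) (1.0 / (1.0 + std::exp((double) -x))); }

template <typename eT>
static inline void relu_inplace(arma::Mat<eT>& A) {
  eT* p = A.memptr();
  const arma::uword n = A.n_elem;
  for (arma::uword i = 0; i < n; ++i) if (p[i] < eT(0)) p[i] = eT(0);
}

// out = grad .* (act > 0), written into grad in place
template <typename eT>
static inline void relu_mask(arma::Mat<eT>& grad, const arma::Mat<eT>& act) {
  eT* g = grad.memptr(); const eT* a = act.memptr();
  const arma::uword n = grad.n_elem;
  for (arma::uword i = 0; i < n; ++i) if (a[i] <= eT(0)) g[i] = eT(0);
}

template <typename eT>
static void se_forward(const arma::Mat<eT>& Wr, const arma::Mat<eT>& br,
                       const arma::Mat<eT>& We, const arma::Mat<eT>& be,
                       const arma::Mat<eT>& A, SECache<eT>& c, arma::Mat<eT>& U) {
  c.z = arma::mean(A, 0).t();
  c.hpre = Wr * c.z + br.col(0);
  c.h = arma::clamp(c.hpre, eT(0), arma::Datum<eT>::inf);
  arma::Col<eT> spre = We * c.h + be.col(0);
  c.s = spre;
  for (arma::uword i = 0; i < c.s.n_elem; ++i) c.s(i) = sigmoid_(spre(i));
  U.set_size(A.n_rows, A.n_cols);
  for (arma::uword k = 0; k < A.n_cols; ++k) {
    const eT s = c.s(k); const eT* a = A.colptr(k); eT* u = U.colptr(k);
    for (arma::uword i = 0; i < A.n_rows; ++i) u[i] = s * a[i];
  }
}

// dU -> dA (written into dA_out); parameter grads accumulated if g != NULL
template <typename eT>
static void se_backward(const arma::Mat<eT>& Wr, const arma::Mat<eT>& We,
                        const arma::Mat<eT>& A, const SECache<eT>& c,
                        const arma::Mat<eT>& dU, arma::Mat<eT>& dA_out,
                        arma::Mat<eT>* gWr, arma::Mat<eT>* gbr,
                        arma::Mat<eT>* gWe, arma::Mat<eT>* gbe) {
  const arma::uword S = A.n_rows, nf = A.n_cols;
  dA_out.set_size(S, nf);
  arma::Col<eT> ds(nf);
  for (arma::uword k = 0; k < nf; ++k) {
    const eT s = c.s(k);
    const eT* du = dU.colptr(k); const eT* a = A.colptr(k);
    eT* da = dA_out.colptr(k);
    eT acc = eT(0);
    for (arma::uword i = 0; i < S; ++i) { da[i] = s * du[i]; acc += du[i] * a[i]; }
    ds(k) = acc;
  }
  arma::Col<eT> dspre = ds % c.s % (eT(1) - c.s);
  arma::Col<eT> dh = We.t() * dspre;
  for (arma::uword i = 0; i < dh.n_elem; ++i) if (c.hpre(i) <= eT(0)) dh(i) = eT(0);
  arma::Col<eT> dz = Wr.t() * dh;
  for (arma::uword k = 0; k < nf; ++k) {
    const eT add = dz(k) / (eT) S;
    eT* da = dA_out.colptr(k);
    for (arma::uword i = 0; i < S; ++i) da[i] += add;
  }
  if (gWr) {
    *gWe += dspre * c.h.t(); gbe->col(0) += dspre;
    *gWr += dh * c.z.t();    gbr->col(0) += dh;
  }
}

// column-major-friendly im2col builders -------------------------------------

template <typename eT>
static void im2col_1(const Net<eT>& n, const double* x, arma::Mat<eT>& C) {
  const int W = n.W;
  C.zeros(H * W, H * KW2);
  for (int dr = -2; dr <= 2; ++dr)
    for (int dc = -4; dc <= 5; ++dc) {
      const int q = (dr + 2) * KW2 + (dc + 4);
      eT* col = C.colptr(q);
      const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
      const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
      for (int r = r0; r < r1; ++r) {
        const int rr = r + dr;
        eT* dst = col + r * W;
        for (int c = c0; c < c1; ++c)
          dst[c] = (eT) x[H * (c + dc) + rr];
      }
    }
}

template <typename eT>
static void im2col_2(const Net<eT>& n, const arma::Mat<eT>& P1, arma::Mat<eT>& C) {
  const int W1p = n.W1p, nf = n.nf;
  C.zeros(W1p, nf * H * KW2);
  for (int k = 0; k < nf; ++k) {
    const eT* src = P1.colptr(k);
    for (int r = 0; r < H; ++r)
      for (int dc = -4; dc <= 5; ++dc) {
        const int q = (k * H + r) * KW2 + (dc + 4);
        eT* col = C.colptr(q);
        const int c0 = std::max(0, -dc), c1 = std::min(W1p, W1p - dc);
        const eT* s = src + r * W1p + dc;
        for (int c = c0; c < c1; ++c) col[c] = s[c];
      }
  }
}

template <typename eT>
static void im2col_1d(const Net<eT>& n, const arma::Mat<eT>& U, arma::Mat<eT>& C) {
  const int W1p = n.W1p, nf = n.nf;
  C.zeros(W1p, nf * KW1);
  for (int k = 0; k < nf; ++k) {
    const eT* src = U.colptr(k);
    for (int dc = -1; dc <= 2; ++dc) {
      eT* col = C.colptr(k * KW1 + (dc + 1));
      const int c0 = std::max(0, -dc), c1 = std::min(W1p, W1p - dc);
      const eT* s = src + dc;
      for (int c = c0; c < c1; ++c) col[c] = s[c];
    }
  }
}

static inline double runif01(std::mt19937& g) { return g() * (1.0 / 4294967296.0); }

template <typename eT>
static void forward_sample(const Net<eT>& n, const double* x, Cache<eT>& c,
                           bool train, double dropout, std::mt19937* rng) {
  const int nf = n.nf, W = n.W, W1p = n.W1p, W2p = n.W2p;
  // conv1 (2D 5x10, same padding) + ReLU + SE1
  im2col_1(n, x, c.C1);
  c.A1 = c.C1 * n.P[n.i_c1W];
  c.A1.each_row() += n.P[n.i_c1b].col(0).t();
  relu_inplace(c.A1);
  se_forward(n.P[n.i_se0], n.P[n.i_se0 + 1], n.P[n.i_se0 + 2], n.P[n.i_se0 + 3],
             c.A1, c.se1, c.U1);
  // pool1 (1x4 over the bin axis, per assay row)
  c.P1.set_size(H * W1p, nf); c.am1.set_size(H * W1p, nf);
  for (int k = 0; k < nf; ++k) {
    const eT* u = c.U1.colptr(k);
    eT* o = c.P1.colptr(k);
    arma::uword* am = c.am1.colptr(k);
    for (int r = 0; r < H; ++r)
      for (int cc = 0; cc < W1p; ++cc) {
        int best = r * W + PW * cc;
        eT bv = u[best];
        for (int d = 1; d < PW; ++d) {
          const int p = r * W + PW * cc + d;
          if (u[p] > bv) { bv = u[p]; best = p; }
        }
        o[r * W1p + cc] = bv; am[r * W1p + cc] = best;
      }
  }
  // conv2 (2D 5x10, valid height -> 1D) + ReLU + SE2
  im2col_2(n, c.P1, c.C2);
  c.A[0] = c.C2 * n.P[n.i_c2W];
  c.A[0].each_row() += n.P[n.i_c2b].col(0).t();
  relu_inplace(c.A[0]);
  // conv3..conv7 (1D 1x4, same padding); SE after conv2..conv6
  for (int j = 0; j < N1D; ++j) {
    const int lse = n.i_se0 + 4 * (j + 1);
    se_forward(n.P[lse], n.P[lse + 1], n.P[lse + 2], n.P[lse + 3],
               c.A[j], c.se[j], c.U[j]);
    im2col_1d(n, c.U[j], c.C1d[j]);
    c.A[j + 1] = c.C1d[j] * n.P[n.i_c3 + 2 * j];
    c.A[j + 1].each_row() += n.P[n.i_c3 + 2 * j + 1].col(0).t();
    relu_inplace(c.A[j + 1]);
  }
  // pool2 + flatten
  c.P2.set_size(W2p, nf); c.am2.set_size(W2p, nf);
  for (int k = 0; k < nf; ++k) {
    const eT* a = c.A[N1D].colptr(k);
    eT* o = c.P2.colptr(k);
    arma::uword* am = c.am2.colptr(k);
    for (int cc = 0; cc < W2p; ++cc) {
      int best = PW * cc; eT bv = a[best];
      for (int d = 1; d < PW; ++d)
        if (a[PW * cc + d] > bv) { bv = a[PW * cc + d]; best = PW * cc + d; }
      o[cc] = bv; am[cc] = best;
    }
  }
  c.f = arma::vectorise(c.P2);
  // dense head
  c.h1pre = n.P[n.i_d1W].t() * c.f + n.P[n.i_d1b].col(0);
  c.h1 = arma::clamp(c.h1pre, eT(0), arma::Datum<eT>::inf);
  if (train && dropout > 0.0) {
    c.dmask.set_size(n.du);
    const double keep = 1.0 - dropout;
    for (int i = 0; i < n.du; ++i)
      c.dmask(i) = (runif01(*rng) < keep) ? (eT) (1.0 / keep) : eT(0);
    c.h1 %= c.dmask;
  } else {
    c.dmask.reset();
  }
  c.logit = arma::dot(n.P[n.i_d2w].col(0), c.h1) + n.P[n.i_d2b](0, 0);
}

// ---- backward --------------------------------------------------------------

// actgrads (if non-null) receives d(score)/d(post-ReLU activation) for the 7
// conv layers; g (if non-null) accumulates parameter gradients.
template <typename eT>
static void backward_sample(const Net<eT>& n, Cache<eT>& c, eT dlogit,
                            std::vector<arma::Mat<eT> >* g,
                            std::vector<arma::Mat<eT> >* actgrads) {
  const int nf = n.nf, W = n.W, W1p = n.W1p;
  arma::Col<eT> dh1 = dlogit * n.P[n.i_d2w].col(0);
  if (g) {
    (*g)[n.i_d2w].col(0) += dlogit * c.h1;
    (*g)[n.i_d2b](0, 0) += dlogit;
  }
  if (c.dmask.n_elem) dh1 %= c.dmask;
  for (arma::uword i = 0; i < dh1.n_elem; ++i)
    if (c.h1pre(i) <= eT(0)) dh1(i) = eT(0);
  if (g) {
    (*g)[n.i_d1W] += c.f * dh1.t();
    (*g)[n.i_d1b].col(0) += dh1;
  }
  arma::Col<eT> df = n.P[n.i_d1W] * dh1;
  c.dA.zeros(W1p, nf);                               // d wrt A7 (post-relu)
  for (int k = 0; k < nf; ++k) {
    eT* da = c.dA.colptr(k);
    const arma::uword* am = c.am2.colptr(k);
    const eT* dp = df.memptr() + (arma::uword) k * n.W2p;
    for (int cc = 0; cc < n.W2p; ++cc) da[am[cc]] += dp[cc];
  }
  if (actgrads) (*actgrads)[6] = c.dA;
  // conv7 .. conv3 backward
  for (int j = N1D - 1; j >= 0; --j) {
    relu_mask(c.dA, c.A[j + 1]);
    if (g) {
      (*g)[n.i_c3 + 2 * j] += c.C1d[j].t() * c.dA;
      (*g)[n.i_c3 + 2 * j + 1].col(0) += arma::sum(c.dA, 0).t();
    }
    c.dC = c.dA * n.P[n.i_c3 + 2 * j].t();
    c.dU.zeros(W1p, nf);
    for (int k = 0; k < nf; ++k) {
      eT* du = c.dU.colptr(k);
      for (int dc = -1; dc <= 2; ++dc) {
        const eT* s = c.dC.colptr(k * KW1 + (dc + 1));
        const int c0 = std::max(0, -dc), c1 = std::min(W1p, W1p - dc);
        eT* d = du + dc;
        for (int c2 = c0; c2 < c1; ++c2) d[c2] += s[c2];
      }
    }
    const int lse = n.i_se0 + 4 * (j + 1);
    se_backward(n.P[lse], n.P[lse + 2], c.A[j], c.se[j], c.dU, c.dA,
                g ? &(*g)[lse] : (arma::Mat<eT>*) NULL,
                g ? &(*g)[lse + 1] : (arma::Mat<eT>*) NULL,
                g ? &(*g)[lse + 2] : (arma::Mat<eT>*) NULL,
                g ? &(*g)[lse + 3] : (arma::Mat<eT>*) NULL);
    if (actgrads) (*actgrads)[j + 1] = c.dA;
  }
  // conv2 backward (c.dA holds grad wrt A2 post-relu)
  relu_mask(c.dA, c.A[0]);
  if (g) {
    (*g)[n.i_c2W] += c.C2.t() * c.dA;
    (*g)[n.i_c2b].col(0) += arma::sum(c.dA, 0).t();
  }
  c.dC = c.dA * n.P[n.i_c2W].t();
  c.dP1.zeros(H * W1p, nf);
  for (int k = 0; k < nf; ++k) {
    eT* dp = c.dP1.colptr(k);
    for (int r = 0; r < H; ++r)
      for (int dc = -4; dc <= 5; ++dc) {
        const eT* s = c.dC.colptr((k * H + r) * KW2 + (dc + 4));
        const int c0 = std::max(0, -dc), c1 = std::min(W1p, W1p - dc);
        eT* d = dp + r * W1p + dc;
        for (int c2 = c0; c2 < c1; ++c2) d[c2] += s[c2];
      }
  }
  // pool1 backward
  c.dU1.zeros(H * W, nf);
  for (int k = 0; k < nf; ++k) {
    eT* du = c.dU1.colptr(k);
    const eT* dp = c.dP1.colptr(k);
    const arma::uword* am = c.am1.colptr(k);
    for (int i = 0; i < H * W1p; ++i) du[am[i]] += dp[i];
  }
  // SE1 backward
  se_backward(n.P[n.i_se0], n.P[n.i_se0 + 2], c.A1, c.se1, c.dU1, c.dA,
              g ? &(*g)[n.i_se0] : (arma::Mat<eT>*) NULL,
              g ? &(*g)[n.i_se0 + 1] : (arma::Mat<eT>*) NULL,
              g ? &(*g)[n.i_se0 + 2] : (arma::Mat<eT>*) NULL,
              g ? &(*g)[n.i_se0 + 3] : (arma::Mat<eT>*) NULL);
  if (actgrads) (*actgrads)[0] = c.dA;
  if (g) {
    relu_mask(c.dA, c.A1);
    (*g)[n.i_c1W] += c.C1.t() * c.dA;
    (*g)[n.i_c1b].col(0) += arma::sum(c.dA, 0).t();
  }
}

// ---- exported entry points -------------------------------------------------

// [[Rcpp::export]]
arma::vec nn_forward(Rcpp::List params, arma::mat X) {
  Net<double> n = build_net<double>(params, (int) X.n_cols);
  Cache<double> c;
  arma::vec out(X.n_rows);
  arma::rowvec xr;
  for (arma::uword i = 0; i < X.n_rows; ++i) {
    xr = X.row(i);
    forward_sample(n, xr.memptr(), c, false, 0.0, (std::mt19937*) NULL);
    out(i) = c.logit;
  }
  return out;
}

static inline double bce_logit(double logit, double y) {
  // softplus(logit) - y*logit, numerically stable
  double sp = logit > 0 ? logit + std::log1p(std::exp(-logit))
                        : std::log1p(std::exp(logit));
  return sp - y * logit;
}

// [[Rcpp::export]]
Rcpp::List nn_train(Rcpp::List params,
                    arma::mat Xtr, arma::vec ytr, arma::vec wtr,
                    arma::mat Xva, arma::vec yva, arma::vec wva,
                    double lr, int epochs, int batch, int patience,
                    int seed, double dropout) {
  typedef float eT;
  Net<eT> n = build_net<eT>(params, (int) Xtr.n_cols);
  const int ntr = (int) Xtr.n_rows, nva = (int) Xva.n_rows;
  std::mt19937 rng((unsigned int) seed);
  std::vector<arma::Mat<eT> > g(n.P.size()), m(n.P.size()), v(n.P.size());
  for (size_t j = 0; j < n.P.size(); ++j) {
    g[j].zeros(n.P[j].n_rows, n.P[j].n_cols);
    m[j] = g[j]; v[j] = g[j];
  }
  std::vector<arma::Mat<eT> > bestP = n.P;
  std::vector<int> idx(ntr);
  for (int i = 0; i < ntr; ++i) idx[i] = i;
  Cache<eT> c;
  std::vector<double> tl, vl;
  const eT b1 = (eT) 0.9, b2 = (eT) 0.999, eps = (eT) 1e-8;
  long t = 0;
  double best = arma::datum::inf;
  int wait = 0, best_epoch = 0, ran = 0;
  arma::rowvec xr;
  for (int ep = 0; ep < epochs; ++ep) {
    // deterministic Fisher-Yates shuffle
    for (int i = ntr - 1; i > 0; --i) {
      int j = (int) (rng() % (unsigned int) (i + 1));
      std::swap(idx[i], idx[j]);
    }
    double lsum = 0.0;
    for (int s = 0; s < ntr; s += batch) {
      const int e = std::min(s + batch, ntr), B = e - s;
      for (size_t j = 0; j < g.size(); ++j) g[j].zeros();
      for (int i = s; i < e; ++i) {
        const int ii = idx[i];
        xr = Xtr.row(ii);
        forward_sample(n, xr.memptr(), c, true, dropout, &rng);
        lsum += wtr(ii) * bce_logit((double) c.logit, ytr(ii));
        const eT dlogit = (eT) (wtr(ii) * (sigmoid_((double) c.logit) - ytr(ii)) / B);
        backward_sample(n, c, dlogit, &g, (std::vector<arma::Mat<eT> >*) NULL);
      }
      ++t;
      const eT a = (eT) (lr * std::sqrt(1.0 - std::pow((double) b2, (double) t)) /
                         (1.0 - std::pow((double) b1, (double) t)));
      for (size_t j = 0; j < g.size(); ++j) {
        m[j] = b1 * m[j] + (eT(1) - b1) * g[j];
        v[j] = b2 * v[j] + (eT(1) - b2) * (g[j] % g[j]);
        n.P[j] -= a * m[j] / (arma::sqrt(v[j]) + eps);
      }
    }
    tl.push_back(lsum / ntr);
    double vsum = 0.0;
    for (int i = 0; i < nva; ++i) {
      xr = Xva.row(i);
      forward_sample(n, xr.memptr(), c, false, 0.0, (std::mt19937*) NULL);
      vsum += wva(i) * bce_logit((double) c.logit, yva(i));
    }
    const double vloss = nva > 0 ? vsum / nva : tl.back();
    vl.push_back(vloss);
    ran = ep + 1;
    if (vloss < best - 1e-9) {
      best = vloss; bestP = n.P; best_epoch = ep + 1; wait = 0;
    } else if (++wait >= patience) break;
    Rcpp::checkUserInterrupt();
  }
  if (best_epoch > 0) n.P = bestP;  // restore best weights
  return List::create(Named("params") = net_to_list(n),
                      Named("train_loss") = tl,
                      Named("val_loss") = vl,
                      Named("best_epoch") = best_epoch,
                      Named("epochs_run") = ran);
}

// [[Rcpp::export]]
Rcpp::List nn_gradcam(Rcpp::List params, arma::rowvec x, bool post_sigmoid) {
  Net<double> n = build_net<double>(params, (int) x.n_elem);
  Cache<double> c;
  forward_sample(n, x.memptr(), c, false, 0.0, (std::mt19937*) NULL);
  const double p = sigmoid_(c.logit);
  std::vector<arma::mat> ag(7);
  const double dlogit = post_sigmoid ? p * (1.0 - p) : 1.0;
  // activations must be copied before backward reuses the cache scratch
  List A(7);
  A[0] = c.A1;
  for (int j = 0; j < 6; ++j) A[j + 1] = c.A[j];
  backward_sample(n, c, dlogit, (std::vector<arma::mat>*) NULL, &ag);
  List G(7);
  for (int j = 0; j < 7; ++j) G[j] = ag[j];
  return List::create(Named("activations") = A, Named("gradients") = G,
                      Named("logit") = c.logit, Named("prob") = p,
                      Named("width") = n.W, Named("pooled_width") = n.W1p);
}
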