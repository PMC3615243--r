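// Core numerics: equal-width quantization, plug-in mutual information,
// greedy mRMR ranking, per-instance SGD training of a sigmoid MLP with
// momentum and instance weights, and a whole-fold routine for binary
// leave-one-out cross-validation.  These sit in compiled code because the
// cross-validated (F, Q) search evaluates them hundreds of thousands of
// times; the R wrappers call the same routines so that fast and plain
// paths are bit-identical.
#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- binning

static void quantize_core(const double* x, int n, int Q, int* lev,
                          double& lo, double& hi) {
  lo = x[0]; hi = x[0];
  for (int i = 1; i < n; ++i) { if (x[i] < lo) lo = x[i]; if (x[i] > hi) hi = x[i]; }
  if (lo == hi) { for (int i = 0; i < n; ++i) lev[i] = 0; return; }
  const double width = (hi - lo) / Q;
  for (int i = 0; i < n; ++i) {
    int l = (int)std::floor((x[i] - lo) / width);
    if (l < 0) l = 0;
    if (l > Q - 1) l = Q - 1;  // right-inclusive top bin
    lev[i] = l;
  }
}

// [[Rcpp::export]]
List cpp_quantize(NumericVector x, int Q) {
  const int n = x.size();
  if (n == 0) stop("empty vector");
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(x[i])) stop("values must be finite");
  if (Q < 2) stop("Q must be >= 2");
  IntegerVector lev(n);
  double lo, hi;
  quantize_core(REAL(x), n, Q, INTEGER(lev), lo, hi);
  if (lo == hi) hi = lo + 1.0;
  NumericVector edges(Q + 1);
  const double width = (hi - lo) / Q;
  for (int k = 0; k <= Q; ++k) edges[k] = lo + k * width;
  edges[Q] = hi;
  return List::create(_["levels"] = lev, _["edges"] = edges);
}

// ------------------------------------------------------ mutual information

static double mi_bits(const int* x, const int* y, int n) {
  int nx = 0, ny = 0;
  for (int i = 0; i < n; ++i) {
    if (x[i] < 0 || y[i] < 0) stop("discrete levels must be non-negative");
    if (x[i] + 1 > nx) nx = x[i] + 1;
    if (y[i] + 1 > ny) ny = y[i] + 1;
  }
  std::vector<double> pxy((size_t)nx * ny, 0.0), px(nx, 0.0), py(ny, 0.0);
  const double inv = 1.0 / n;
  for (int i = 0; i < n; ++i) {
    pxy[(size_t)x[i] * ny + y[i]] += inv;
    px[x[i]] += inv;
    py[y[i]] += inv;
  }
  double mi = 0.0;
  for (int a = 0; a < nx; ++a)
    for (int b = 0; b < ny; ++b) {
      double p = pxy[(size_t)a * ny + b];
      if (p > 0.0) mi += p * std::log2(p / (px[a] * py[b]));
    }
  return mi > 0.0 ? mi : 0.0;  // clip tiny negative rounding residue
}

// [[Rcpp::export]]
double cpp_mi(IntegerVector x, IntegerVector y) {
  if (x.size() != y.size()) stop("x and y must have equal length");
  if (x.size() == 0) stop("empty input");
  return mi_bits(INTEGER(x), INTEGER(y), x.size());
}

// ------------------------------------------------------------------- mRMR

// Greedy mRMR on a pre-quantized matrix (columns = features) with the
// mutual-information-difference (MID) score
//   score(f) = I(f;c) - mean_{s in S} I(f;s)
// or the quotient (MIQ) variant.  Ties break to the earlier column.
static void mrmr_core(const std::vector<int>& Xq, int n, int p,
                      const int* y, int F, bool quotient,
                      std::vector<int>& order, std::vector<double>& relevance,
                      std::vector<double>& score) {
  std::vector<double> rel(p);
  for (int j = 0; j < p; ++j) rel[j] = mi_bits(&Xq[(size_t)j * n], y, n);
  std::vector<bool> sel(p, false);
  std::vector<double> redsum(p, 0.0);
  order.resize(F); relevance.resize(F); score.resize(F);
  for (int k = 0; k < F; ++k) {
    int best = -1;
    double bestscore = 0.0;
    for (int j = 0; j < p; ++j) {
      if (sel[j]) continue;
      double s;
      if (k == 0) s = rel[j];
      else if (quotient) s = rel[j] / (redsum[j] / k + 1e-12);
      else s = rel[j] - redsum[j] / k;
      if (best < 0 || s > bestscore) { bestscore = s; best = j; }
    }
    sel[best] = true;
    order[k] = best;
    relevance[k] = rel[best];
    score[k] = bestscore;
    if (k + 1 < F)
      for (int j = 0; j < p; ++j)
        if (!sel[j])
          redsum[j] += mi_bits(&Xq[(size_t)j * n], &Xq[(size_t)best * n], n);
  }
}

// [[Rcpp::export]]
List cpp_mrmr(IntegerMatrix Xq, IntegerVector y, int F, bool quotient) {
  const int n = Xq.nrow(), p = Xq.ncol();
  if (y.size() != n) stop("label length mismatch");
  if (F < 1 || F > p) stop("F out of range");
  std::vector<int> X((size_t)n * p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) X[(size_t)j * n + i] = Xq(i, j);
  std::vector<int> order; std::vector<double> rel, sc;
  mrmr_core(X, n, p, INTEGER(y), F, quotient, order, rel, sc);
  IntegerVector ord(F);
  for (int k = 0; k < F; ++k) ord[k] = order[k] + 1;  // 1-based for R
  return List::create(_["order"] = ord, _["relevance"] = NumericVector(rel.begin(), rel.end()),
                      _["score"] = NumericVector(sc.begin(), sc.end()));
}

// -------------------------------------------------------------------- MLP

static inline double sigm(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// Flattened sigmoid MLP: weights for layer l occupy a contiguous block of
// (sizes[l] + 1) * sizes[l+1] doubles (bias row last), column j of the
// next layer at stride sizes[l+1].
struct MlpResult {
  std::vector<double> W;
  int restarts = 0, longest_run = 0, seed_used = 0;
  bool converged = false;
};

static size_t mlp_nweights(const std::vector<int>& sizes) {
  size_t m = 0;
  for (size_t l = 0; l + 1 < sizes.size(); ++l)
    m += (size_t)(sizes[l] + 1) * sizes[l + 1];
  return m;
}

static void mlp_forward(const std::vector<double>& W,
                        const std::vector<int>& sizes,
                        const double* x, std::vector<std::vector<double>>& acts) {
  const int L = (int)sizes.size() - 1;
  for (int i = 0; i < sizes[0]; ++i) acts[0][i] = x[i];
  size_t off = 0;
  for (int l = 0; l < L; ++l) {
    const int in = sizes[l], out = sizes[l + 1];
    const double* Wl = &W[off];
    for (int j = 0; j < out; ++j) {
      double z = Wl[(size_t)in * out + j];  // bias
      for (int i = 0; i < in; ++i) z += acts[l][i] * Wl[(size_t)i * out + j];
      acts[l + 1][j] = sigm(z);
    }
    off += (size_t)(in + 1) * out;
  }
}

// Squared-error SGD with one-hot targets, momentum on the previous weight
// change, instance weights scaling the error signal, instances visited in
// a seed-shuffled order fixed across epochs.  Restarts with a derived
// seed when the trained model has a run of more than max_consec
// consecutive training errors (in visiting order) or non-finite weights.
static MlpResult mlp_train_core(const std::vector<double>& Xr, int n, int d,
                                const int* y, const double* wts,
                                const std::vector<int>& hidden, int nclass,
                                double lr, double momentum, int epochs,
                                int seed, int max_consec, int max_restarts) {
  std::vector<int> sizes;
  sizes.push_back(d);
  for (int h : hidden) sizes.push_back(h);
  sizes.push_back(nclass);
  const int L = (int)sizes.size() - 1;
  const size_t nw = mlp_nweights(sizes);

  std::vector<std::vector<double>> acts(sizes.size()), delta(sizes.size());
  for (size_t l = 0; l < sizes.size(); ++l) {
    acts[l].assign(sizes[l], 0.0);
    delta[l].assign(sizes[l], 0.0);
  }
  MlpResult res;
  res.W.assign(nw, 0.0);
  std::vector<double> dW(nw, 0.0);
  std::vector<int> ord(n);

  for (int attempt = 0; attempt <= max_restarts; ++attempt) {
    res.seed_used = (int)(((long long)seed + 1000003LL * attempt) % 2147483647LL);
    std::mt19937 gen((unsigned)res.seed_used);
    std::uniform_real_distribution<double> U(-0.5, 0.5);
    for (size_t i = 0; i < nw; ++i) res.W[i] = U(gen);
    std::fill(dW.begin(), dW.end(), 0.0);
    for (int i = 0; i < n; ++i) ord[i] = i;
    for (int i = n - 1; i > 0; --i) {
      std::uniform_int_distribution<int> D(0, i);
      std::swap(ord[i], ord[D(gen)]);
    }
    bool finite = true;
    for (int ep = 0; ep < epochs && finite; ++ep) {
      for (int oi = 0; oi < n; ++oi) {
        const int i = ord[oi];
        mlp_forward(res.W, sizes, &Xr[(size_t)i * d], acts);
        for (int j = 0; j < nclass; ++j) {
          double o = acts[L][j];
          double t = (y[i] == j) ? 1.0 : 0.0;
          delta[L][j] = (t - o) * o * (1.0 - o) * wts[i];
        }
        // backpropagate through hidden layers
        {
          size_t off_end = nw;
          for (int l = L - 1; l >= 1; --l) {
            const int out = sizes[l + 1];
            off_end -= (size_t)(sizes[l] + 1) * out;
            const double* Wl = &res.W[off_end];
            for (int i2 = 0; i2 < sizes[l]; ++i2) {
              double s = 0.0;
              for (int j = 0; j < out; ++j)
                s += delta[l + 1][j] * Wl[(size_t)i2 * out + j];
              double a = acts[l][i2];
              delta[l][i2] = s * a * (1.0 - a);
            }
          }
        }
        // weight updates with momentum
        size_t off = 0;
        for (int l = 0; l < L; ++l) {
          const int in = sizes[l], out = sizes[l + 1];
          double* Wl = &res.W[off];
          double* dWl = &dW[off];
          for (int i2 = 0; i2 <= in; ++i2) {
            const double a = (i2 == in) ? 1.0 : acts[l][i2];
            for (int j = 0; j < out; ++j) {
              const size_t idx = (size_t)i2 * out + j;
              const double ch = lr * delta[l + 1][j] * a + momentum * dWl[idx];
              Wl[idx] += ch;
              dWl[idx] = ch;
            }
          }
          off += (size_t)(in + 1) * out;
        }
      }
      for (size_t i = 0; i < nw && finite; ++i)
        if (!std::isfinite(res.W[i])) finite = false;
    }
    // divergence guard: longest run of consecutive training errors
    res.longest_run = 0;
    int run = 0;
    if (finite) {
      for (int oi = 0; oi < n; ++oi) {
        const int i = ord[oi];
        mlp_forward(res.W, sizes, &Xr[(size_t)i * d], acts);
        int pred = 0;
        for (int j = 1; j < nclass; ++j)
          if (acts[L][j] > acts[L][pred]) pred = j;
        run = (pred == y[i]) ? 0 : run + 1;
        if (run > res.longest_run) res.longest_run = run;
      }
    }
    res.restarts = attempt;
    if (finite && res.longest_run <= max_consec) { res.converged = true; break; }
  }
  return res;
}

static List weights_to_r(const std::vector<double>& W,
                         const std::vector<int>& sizes) {
  const int L = (int)sizes.size() - 1;
  List out(L);
  size_t off = 0;
  for (int l = 0; l < L; ++l) {
    const int in = sizes[l], nxt = sizes[l + 1];
    NumericMatrix M(in + 1, nxt);
    for (int i = 0; i <= in; ++i)
      for (int j = 0; j < nxt; ++j)
        M(i, j) = W[off + (size_t)i * nxt + j];
    out[l] = M;
    off += (size_t)(in + 1) * nxt;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_mlp_train(NumericMatrix X, IntegerVector y, NumericVector wts,
                   IntegerVector hidden, int nclass, double lr,
                   double momentum, int epochs, int seed, int max_consec,
                   int max_restarts) {
  const int n = X.nrow(), d = X.ncol();
  if (y.size() != n || wts.size() != n) stop("row count mismatch");
  if (nclass < 2) stop("need at least two classes");
  std::vector<int> hid(hidden.begin(), hidden.end());
  for (int h : hid) if (h < 1) stop("hidden layer sizes must be >= 1");
  std::vector<double> Xr((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) Xr[(size_t)i * d + j] = X(i, j);
  MlpResult r = mlp_train_core(Xr, n, d, INTEGER(y), REAL(wts), hid, nclass,
                               lr, momentum, epochs, seed, max_consec,
                               max_restarts);
  std::vector<int> sizes;
  sizes.push_back(d);
  for (int h : hid) sizes.push_back(h);
  sizes.push_back(nclass);
  return List::create(_["weights"] = weights_to_r(r.W, sizes),
                      _["restarts"] = r.restarts,
                      _["longest_error_run"] = r.longest_run,
                      _["converged"] = r.converged,
                      _["seed_used"] = r.seed_used);
}

// [[Rcpp::export]]
NumericMatrix cpp_mlp_forward(List weights, NumericMatrix X) {
  const int L = weights.size();
  const int n = X.nrow();
  NumericMatrix cur = X;
  for (int l = 0; l < L; ++l) {
    NumericMatrix W = weights[l];
    const int in = W.nrow() - 1, out = W.ncol();
    if (cur.ncol() != in) stop("input width does not match model topology");
    NumericMatrix nxt(n, out);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < out; ++j) {
        double z = W(in, j);
        for (int k = 0; k < in; ++k) z += cur(i, k) * W(k, j);
        nxt(i, j) = sigm(z);
      }
    cur = nxt;
  }
  return cur;
}

// ----------------------------------------------- whole-fold binary CL1OCV

// One leave-one-out fold of the binary pipeline, entirely in C++ but
// using the identical primitives as the R path: quantize the n-1
// training rows, mRMR-rank, keep the top F columns, range-normalize to
// [-1, 1] from training extrema (held-out row clipped), cost-weight
// (class-0 instances by the class-1 count and vice versa, normalized to
// sum to n-1), train, and predict the held-out row.  y must be 0/1 with
// class 1 = the positive (epilepsy) class.
// [[Rcpp::export]]
List cpp_fold_binary(NumericMatrix X, IntegerVector y, int leave_out, int F,
                     int Q, bool quotient, IntegerVector hidden, double lr,
                     double momentum, int epochs, int seed, int max_consec,
                     int max_restarts) {
  const int n = X.nrow(), p = X.ncol();
  if (leave_out < 1 || leave_out > n) stop("leave_out out of range");
  if (F < 1 || F > p) stop("F out of range");
  const int lo_i = leave_out - 1;
  const int m = n - 1;
  // training columns (column-major) and labels
  std::vector<double> tr((size_t)m * p);
  std::vector<int> ytr(m);
  {
    int r = 0;
    for (int i = 0; i < n; ++i) {
      if (i == lo_i) continue;
      for (int j = 0; j < p; ++j) tr[(size_t)j * m + r] = X(i, j);
      ytr[r] = y[i];
      ++r;
    }
  }
  int n1 = 0;
  for (int i = 0; i < m; ++i) n1 += ytr[i];
  const int n0 = m - n1;
  if (n0 == 0 || n1 == 0) stop("fold lost a class");
  // quantize + mRMR
  std::vector<int> Xq((size_t)m * p);
  double qlo, qhi;
  for (int j = 0; j < p; ++j)
    quantize_core(&tr[(size_t)j * m], m, Q, &Xq[(size_t)j * m], qlo, qhi);
  std::vector<int> order; std::vector<double> rel, sc;
  mrmr_core(Xq, m, p, ytr.data(), F, quotient, order, rel, sc);
  // normalize selected columns; build row-major training matrix
  std::vector<double> Xtr((size_t)m * F), xte(F);
  for (int k = 0; k < F; ++k) {
    const double* col = &tr[(size_t)order[k] * m];
    double cmin = col[0], cmax = col[0];
    for (int i = 1; i < m; ++i) {
      if (col[i] < cmin) cmin = col[i];
      if (col[i] > cmax) cmax = col[i];
    }
    const double center = (cmax + cmin) / 2, half = (cmax - cmin) / 2;
    for (int i = 0; i < m; ++i)
      Xtr[(size_t)i * F + k] = (half > 0) ? (col[i] - center) / half : 0.0;
    double tv = X(lo_i, order[k]);
    tv = (half > 0) ? (tv - center) / half : 0.0;
    if (tv < -1) tv = -1;
    if (tv > 1) tv = 1;
    xte[k] = tv;
  }
  // cost weights: misclassifying a control (0) costs n1, a positive costs n0
  std::vector<double> w(m);
  double wsum = 0.0;
  for (int i = 0; i < m; ++i) { w[i] = (ytr[i] == 0) ? (double)n1 : (double)n0; wsum += w[i]; }
  for (int i = 0; i < m; ++i) w[i] = w[i] * (double)m / wsum;
  std::vector<int> hid(hidden.begin(), hidden.end());
  MlpResult r = mlp_train_core(Xtr, m, F, ytr.data(), w.data(), hid, 2, lr,
                               momentum, epochs, seed, max_consec, max_restarts);
  if (!r.converged) stop("training did not satisfy the divergence guard");
  // predict held-out row
  std::vector<int> sizes;
  sizes.push_back(F);
  for (int h : hid) sizes.push_back(h);
  sizes.push_back(2);
  std::vector<std::vector<double>> acts(sizes.size());
  for (size_t l = 0; l < sizes.size(); ++l) acts[l].assign(sizes[l], 0.0);
  mlp_forward(r.W, sizes, xte.data(), acts);
  const double a0 = acts[sizes.size() - 1][0], a1 = acts[sizes.size() - 1][1];
  const int pred = (a1 > a0) ? 1 : 0;
  IntegerVector ord(F);
  for (int k = 0; k < F; ++k) ord[k] = order[k] + 1;
  return List::create(_["predicted"] = pred,
                      _["confidence"] = std::max(a0, a1) / (a0 + a1),
                      _["order"] = ord, _["restarts"] = r.restarts,
                      _["longest_error_run"] = r.longest_run);
}
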