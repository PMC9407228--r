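// CropNet: contracting 3D convolutional patch classifier.
//
// Activations for a batch of N cubic patches of side S with C channels are
// held as an (N*S^3) x C matrix; row r = n*S^3 + x + S*(y + S*z).  A 3^3
// convolution with zero padding is evaluated as 27 shifted GEMMs, so BLAS
// carries the arithmetic.  Weights for one layer form a (27*Cin) x Cout
// matrix whose rows are grouped by offset o = (dx+1) + 3*(dy+1) + 9*(dz+1),
// dx,dy,dz in {-1,0,1}; the offset-negation o -> 26-o is used in the
// backward pass.

#include <RcppArmadillo.h>
#include <random>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// The training step allocates and frees multi-hundred-MB im2col buffers on
// every iteration; with glibc's default mmap threshold each one is a fresh
// mmap/munmap pair whose page faults dominate the GEMM time.  Keep large
// blocks on the heap so they are reused across iterations.
#ifdef __GLIBC__
static int nsbm_alloc_tuning = []() {
  mallopt(M_MMAP_THRESHOLD, 1 << 30);
  mallopt(M_TRIM_THRESHOLD, 1 << 30);
  return 0;
}();
#endif

// Per-voxel source index (or -1 outside the cube) for each of the 27 offsets.
static std::vector<std::vector<int>> offset_maps(int S) {
  int V = S * S * S;
  std::vector<std::vector<int>> maps(27, std::vector<int>(V));
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int o = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
        std::vector<int>& m = maps[o];
        for (int z = 0; z < S; ++z)
          for (int y = 0; y < S; ++y)
            for (int x = 0; x < S; ++x) {
              int v = x + S * (y + S * z);
              int xs = x + dx, ys = y + dy, zs = z + dz;
              m[v] = (xs < 0 || xs >= S || ys < 0 || ys >= S || zs < 0 ||
                      zs >= S)
                         ? -1
                         : xs + S * (ys + S * zs);
            }
      }
  return maps;
}

// Gather the offset-shifted copy of A (zero padding outside the cube)
// into the caller-provided buffer.
static void gather_rows(const arma::mat& A, const std::vector<int>& map,
                        int N, int V, arma::mat& G) {
  G.set_size(A.n_rows, A.n_cols);
  for (arma::uword c = 0; c < A.n_cols; ++c) {
    const double* src = A.colptr(c);
    double* dst = G.colptr(c);
    for (int n = 0; n < N; ++n) {
      size_t base = (size_t)n * V;
      for (int v = 0; v < V; ++v) {
        int s = map[v];
        dst[base + v] = (s < 0) ? 0.0 : src[base + s];
      }
    }
  }
}

static arma::mat conv_forward(const arma::mat& A, const arma::mat& W,
                              const arma::rowvec& b, int N, int V,
                              const std::vector<std::vector<int>>& maps,
                              arma::mat& scratch) {
  int Cin = A.n_cols, Cout = W.n_cols;
  arma::mat Y(A.n_rows, Cout, arma::fill::none);
  Y.each_row() = b;
  for (int o = 0; o < 27; ++o) {
    if (o == 13) {  // centre offset needs no shift
      Y += A * W.rows(13 * Cin, 13 * Cin + Cin - 1);
      continue;
    }
    gather_rows(A, maps[o], N, V, scratch);
    Y += scratch * W.rows(o * Cin, o * Cin + Cin - 1);
  }
  return Y;
}

// dA, dW, db for one conv layer given upstream dY.
static void conv_backward(const arma::mat& A, const arma::mat& W,
                          const arma::mat& dY, int N, int V,
                          const std::vector<std::vector<int>>& maps,
                          arma::mat& dA, arma::mat& dW, arma::rowvec& db,
                          arma::mat& scratch, bool need_dA) {
  int Cin = A.n_cols;
  if (need_dA) dA.zeros(A.n_rows, A.n_cols);
  dW.set_size(W.n_rows, W.n_cols);
  db = arma::sum(dY, 0);
  for (int o = 0; o < 27; ++o) {
    if (o == 13) {
      dW.rows(13 * Cin, 13 * Cin + Cin - 1) = A.t() * dY;
      if (need_dA)
        dA += dY * W.rows(13 * Cin, 13 * Cin + Cin - 1).t();
      continue;
    }
    gather_rows(A, maps[o], N, V, scratch);
    dW.rows(o * Cin, o * Cin + Cin - 1) = scratch.t() * dY;
    if (need_dA) {
      gather_rows(dY, maps[26 - o], N, V, scratch);
      dA += scratch * W.rows(o * Cin, o * Cin + Cin - 1).t();
    }
  }
}

struct PoolCache {
  arma::umat argmax;  // (N*V2) x C source row indices
};

static arma::mat maxpool_forward(const arma::mat& A, int N, int S,
                                 PoolCache& cache) {
  int S2 = S / 2, V = S * S * S, V2 = S2 * S2 * S2;
  int C = A.n_cols;
  arma::mat P((size_t)N * V2, C, arma::fill::none);
  cache.argmax.set_size((size_t)N * V2, C);
  for (int c = 0; c < C; ++c) {
    const double* src = A.colptr(c);
    double* dst = P.colptr(c);
    arma::uword* am = cache.argmax.colptr(c);
    for (int n = 0; n < N; ++n) {
      size_t ibase = (size_t)n * V, obase = (size_t)n * V2;
      for (int z2 = 0; z2 < S2; ++z2)
        for (int y2 = 0; y2 < S2; ++y2)
          for (int x2 = 0; x2 < S2; ++x2) {
            size_t out = obase + x2 + (size_t)S2 * (y2 + (size_t)S2 * z2);
            double best = -1e300;
            size_t besti = 0;
            for (int dz = 0; dz <= 1; ++dz)
              for (int dy = 0; dy <= 1; ++dy)
                for (int dx = 0; dx <= 1; ++dx) {
                  size_t in =
                      ibase + (2 * x2 + dx) +
                      (size_t)S * ((2 * y2 + dy) + (size_t)S * (2 * z2 + dz));
                  if (src[in] > best) { best = src[in]; besti = in; }
                }
            dst[out] = best;
            am[out] = besti;
          }
    }
  }
  return P;
}

static arma::mat maxpool_backward(const arma::mat& dP, const PoolCache& cache,
                                  size_t rows_in) {
  arma::mat dA(rows_in, dP.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < dP.n_cols; ++c) {
    const double* g = dP.colptr(c);
    const arma::uword* am = cache.argmax.colptr(c);
    double* dst = dA.colptr(c);
    for (arma::uword r = 0; r < dP.n_rows; ++r) dst[am[r]] += g[r];
  }
  return dA;
}

// Flatten (N*Vf) x C -> N x (Vf*C) with element (n, c*Vf + v).
static arma::mat flatten_batch(const arma::mat& A, int N, int Vf) {
  int C = A.n_cols;
  arma::mat F(N, (size_t)Vf * C, arma::fill::none);
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int v = 0; v < Vf; ++v)
        F(n, (size_t)c * Vf + v) = A((size_t)n * Vf + v, c);
  return F;
}

static arma::mat unflatten_batch(const arma::mat& F, int N, int Vf, int C) {
  arma::mat A((size_t)N * Vf, C, arma::fill::none);
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int v = 0; v < Vf; ++v)
        A((size_t)n * Vf + v, c) = F(n, (size_t)c * Vf + v);
  return A;
}

struct NetCache {
  std::vector<arma::mat> conv_in;    // input to each conv layer
  std::vector<arma::mat> relu_mask;  // 0/1
  std::vector<arma::mat> drop_mask;  // scaled inverted dropout (or empty)
  std::vector<PoolCache> pools;
  arma::mat F;       // flattened final activation
  arma::vec z, p;    // logits, probabilities
  arma::mat scratch; // reused gather buffer
};

// Runs the network forward; fills cache when keep_cache.
static void net_forward(const List& W, const List& b, const arma::vec& wd,
                        double bd, const arma::vec& x, int N, int side,
                        int levels, int blocks, const IntegerVector& widths,
                        double dropout, int dropout_seed, bool keep_cache,
                        NetCache& cache) {
  bool training = dropout_seed >= 0 && dropout > 0;
  std::mt19937 rng((unsigned)std::max(dropout_seed, 0));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  int S = side;
  int V = S * S * S;
  arma::mat A(const_cast<double*>(x.memptr()), (size_t)N * V, 1, true, true);
  int k = 0;
  for (int l = 0; l < levels; ++l) {
    std::vector<std::vector<int>> maps = offset_maps(S);
    for (int j = 0; j < blocks; ++j, ++k) {
      arma::mat Wk = W[k];
      arma::rowvec bk = as<arma::rowvec>(b[k]);
      if (keep_cache) cache.conv_in.push_back(A);
      arma::mat Z = conv_forward(A, Wk, bk, N, V, maps, cache.scratch);
      arma::mat mask = arma::conv_to<arma::mat>::from(Z > 0);
      A = Z % mask;
      if (keep_cache) cache.relu_mask.push_back(mask);
      if (training) {
        arma::mat dm(A.n_rows, A.n_cols, arma::fill::none);
        double scale = 1.0 / (1.0 - dropout);
        for (arma::uword i = 0; i < dm.n_elem; ++i)
          dm[i] = (unif(rng) < dropout) ? 0.0 : scale;
        A %= dm;
        if (keep_cache) cache.drop_mask.push_back(dm);
      } else if (keep_cache) {
        cache.drop_mask.push_back(arma::mat());
      }
    }
    if (l < levels - 1) {
      PoolCache pc;
      A = maxpool_forward(A, N, S, pc);
      if (keep_cache) cache.pools.push_back(pc);
      S /= 2;
      V = S * S * S;
    }
  }
  arma::mat F = flatten_batch(A, N, V);
  arma::vec z = F * wd + bd;
  arma::vec p = 1.0 / (1.0 + arma::exp(-z));
  cache.F = F;
  cache.z = z;
  cache.p = p;
}

// [[Rcpp::export(name = ".cn_forward_cpp")]]
NumericVector cn_forward_cpp(List W, List b, arma::vec wd, double bd,
                             arma::vec x, int N, int side, int levels,
                             int blocks, IntegerVector widths, double dropout,
                             int dropout_seed) {
  NetCache cache;
  net_forward(W, b, wd, bd, x, N, side, levels, blocks, widths, dropout,
              dropout_seed, false, cache);
  return wrap(cache.p);
}

// Forward + backward: weighted binary cross-entropy loss
//   loss = sum_i wts_i * bce(p_i, y_i)     (wts encode the half-means)
// Returns loss, per-parameter gradients and the probabilities.
// [[Rcpp::export(name = ".cn_grad_cpp")]]
List cn_grad_cpp(List W, List b, arma::vec wd, double bd, arma::vec x, int N,
                 int side, int levels, int blocks, IntegerVector widths,
                 double dropout, int dropout_seed, arma::vec y,
                 arma::vec wts) {
  NetCache cache;
  net_forward(W, b, wd, bd, x, N, side, levels, blocks, widths, dropout,
              dropout_seed, true, cache);
  const double eps = 1e-7;
  arma::vec pc = arma::clamp(cache.p, eps, 1.0 - eps);
  double loss = arma::accu(wts % (-y % arma::log(pc) -
                                  (1.0 - y) % arma::log(1.0 - pc)));
  // d loss / d z for the clipped sigmoid cross-entropy
  arma::vec dz = wts % (pc - y);

  arma::vec gwd = cache.F.t() * dz;
  double gbd = arma::accu(dz);
  arma::mat dF = dz * wd.t();

  int nconv = levels * blocks;
  List gW(nconv), gb(nconv);

  int Sf = side >> (levels - 1);
  int Vf = Sf * Sf * Sf;
  int Cf = widths[levels - 1];
  arma::mat dA = unflatten_batch(dF, N, Vf, Cf);

  int k = nconv - 1;
  for (int l = levels - 1; l >= 0; --l) {
    int S = side >> l;
    int V = S * S * S;
    if (l < levels - 1) {
      dA = maxpool_backward(dA, cache.pools[l], (size_t)N * V);
    }
    std::vector<std::vector<int>> maps = offset_maps(S);
    for (int j = blocks - 1; j >= 0; --j, --k) {
      if (!cache.drop_mask[k].is_empty()) dA %= cache.drop_mask[k];
      dA %= cache.relu_mask[k];
      arma::mat Wk = W[k];
      arma::mat dW;
      arma::rowvec db;
      arma::mat dAin;
      conv_backward(cache.conv_in[k], Wk, dA, N, V, maps, dAin, dW, db,
                    cache.scratch, k > 0);
      gW[k] = dW;
      gb[k] = db;
      dA = dAin;
    }
  }
  return List::create(Named("loss") = loss, Named("gW") = gW,
                      Named("gb") = gb, Named("gwd") = gwd,
                      Named("gbd") = gbd, Named("probs") = wrap(cache.p));
}
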