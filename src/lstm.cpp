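// Hot numerical kernels: LSTM sequence forward/backward over the flat
// step-major layout, and the attention einsum contractions.  These mirror
// the reference R implementations (lstm_dir_forward_flat_r and friends),
// which remain in the package and are tested for exact agreement.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::span;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// [[Rcpp::export(name = ".lstm_dir_forward_cpp")]]
List lstm_dir_forward_cpp(const arma::mat& Xflat, int S, int B,
                          const arma::mat& W, const arma::vec& b,
                          bool reverse, bool keep_cache) {
  const int H = W.n_cols / 4;
  const int din = W.n_rows - H;
  mat Wx = W.rows(0, din - 1);
  mat Wh = W.rows(din, din + H - 1);
  mat ZX = Xflat * Wx;
  ZX.each_row() += rowvec(b.t());
  mat h(B, H, arma::fill::zeros), cc(B, H, arma::fill::zeros);
  mat Hout(S * B, H);
  mat I, F, G, O, TC, CPREV, HPREV;
  if (keep_cache) {
    I.set_size(S * B, H); F.set_size(S * B, H); G.set_size(S * B, H);
    O.set_size(S * B, H); TC.set_size(S * B, H);
    CPREV.set_size(S * B, H); HPREV.set_size(S * B, H);
  }
  for (int k = 0; k < S; ++k) {
    const int t = reverse ? (S - 1 - k) : k;
    const span rows(t * B, (t + 1) * B - 1);
    mat z = ZX.rows(rows) + h * Wh;
    mat i = sigm(z.cols(0, H - 1));
    mat f = sigm(z.cols(H, 2 * H - 1));
    mat g = arma::tanh(z.cols(2 * H, 3 * H - 1));
    mat o = sigm(z.cols(3 * H, 4 * H - 1));
    if (keep_cache) {
      I.rows(rows) = i; F.rows(rows) = f; G.rows(rows) = g; O.rows(rows) = o;
      CPREV.rows(rows) = cc; HPREV.rows(rows) = h;
    }
    cc = f % cc + i % g;
    mat tc = arma::tanh(cc);
    h = o % tc;
    if (keep_cache) TC.rows(rows) = tc;
    Hout.rows(rows) = h;
  }
  if (!keep_cache) return List::create(_["h"] = Hout);
  return List::create(
      _["h"] = Hout,
      _["cache"] = List::create(_["I"] = I, _["F"] = F, _["G"] = G,
                                _["O"] = O, _["TC"] = TC, _["CPREV"] = CPREV,
                                _["HPREV"] = HPREV, _["Xflat"] = Xflat));
}

// [[Rcpp::export(name = ".lstm_dir_backward_cpp")]]
List lstm_dir_backward_cpp(const arma::mat& dH, const List& cache,
                           const arma::mat& W, int S, int B, bool reverse) {
  const int H = W.n_cols / 4;
  const int din = W.n_rows - H;
  const mat Wx = W.rows(0, din - 1);
  const mat Wh = W.rows(din, din + H - 1);
  const mat tWh = Wh.t();
  // zero-copy views onto the cached R matrices
  auto view = [&](const char* nm) {
    NumericMatrix m = cache[nm];
    return mat(REAL(m), m.nrow(), m.ncol(), false, true);
  };
  const mat I = view("I"), F = view("F"), G = view("G"), O = view("O"),
            TC = view("TC"), CPREV = view("CPREV"), HPREV = view("HPREV"),
            Xflat = view("Xflat");
  mat dZ(S * B, 4 * H);
  mat dh_carry(B, H, arma::fill::zeros), dc_carry(B, H, arma::fill::zeros);
  for (int k = 0; k < S; ++k) {
    const int t = reverse ? k : (S - 1 - k);  // reverse temporal order
    const span rows(t * B, (t + 1) * B - 1);
    mat i = I.rows(rows), f = F.rows(rows), g = G.rows(rows),
        o = O.rows(rows), tc = TC.rows(rows);
    mat dh = dH.rows(rows) + dh_carry;
    mat dcv = dc_carry + dh % o % (1.0 - tc % tc);
    mat dz(B, 4 * H);
    dz.cols(0, H - 1) = (dcv % g) % i % (1.0 - i);
    dz.cols(H, 2 * H - 1) = (dcv % CPREV.rows(rows)) % f % (1.0 - f);
    dz.cols(2 * H, 3 * H - 1) = (dcv % i) % (1.0 - g % g);
    dz.cols(3 * H, 4 * H - 1) = (dh % tc) % o % (1.0 - o);
    dZ.rows(rows) = dz;
    dh_carry = dz * tWh;
    dc_carry = dcv % f;
  }
  mat dW = arma::join_cols(Xflat.t() * dZ, HPREV.t() * dZ);
  arma::rowvec db = arma::sum(dZ, 0);
  mat dX = dZ * Wx.t();
  return List::create(_["dW"] = dW,
                      _["db"] = NumericVector(db.begin(), db.end()),
                      _["dX"] = dX);
}

// einsum 'bsd,bd->bs' on the flat (B*S) x D layout
// [[Rcpp::export(name = ".flat_dot_cpp")]]
NumericMatrix flat_dot_cpp(const NumericMatrix Hflat, const NumericMatrix v,
                           int B, int S) {
  const int D = Hflat.ncol();
  NumericMatrix out(B, S);
  double* o = REAL(out);
  for (int d = 0; d < D; ++d) {
    const double* hcol = &Hflat(0, d);
    const double* vcol = &v(0, d);
    for (int s = 0; s < S; ++s)
      for (int b = 0; b < B; ++b)
        o[s * B + b] += hcol[s * B + b] * vcol[b];
  }
  return out;
}

// weighted sum over steps: out[b,] = sum_s w[(s-1)B+b] * M[(s-1)B+b,]
// [[Rcpp::export(name = ".flat_contract_cpp")]]
NumericMatrix flat_contract_cpp(const NumericMatrix M, const NumericVector w,
                                int B, int S) {
  const int D = M.ncol();
  NumericMatrix out(B, D);
  for (int d = 0; d < D; ++d) {
    const double* mcol = &M(0, d);
    double* ocol = &out(0, d);
    for (int s = 0; s < S; ++s) {
      const double* wv = &w[0] + (R_xlen_t)s * B;
      const double* mv = mcol + (R_xlen_t)s * B;
      for (int b = 0; b < B; ++b) ocol[b] += wv[b] * mv[b];
    }
  }
  return out;
}

// in-place accumulation M[(s-1)B+b,] += w[(s-1)B+b] * v[b,]; M is owned by
// the caller and freshly allocated, so in-place mutation is safe
// [[Rcpp::export(name = ".flat_scatter_add_cpp")]]
void flat_scatter_add_cpp(NumericMatrix M, const NumericVector w,
                          const NumericMatrix v, int B, int S) {
  const int D = M.ncol();
  for (int d = 0; d < D; ++d) {
    double* mcol = &M(0, d);
    const double* vcol = &v(0, d);
    for (int s = 0; s < S; ++s) {
      const double* wv = &w[0] + (R_xlen_t)s * B;
      double* mv = mcol + (R_xlen_t)s * B;
      for (int b = 0; b < B; ++b) mv[b] += wv[b] * vcol[b];
    }
  }
}
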