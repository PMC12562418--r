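// Low-level numerical kernels for the 1D spectral network family.
//
// Layout convention: activations are (channels, length, batch) arrays,
// column-major, matching R's dim = c(C, L, N). Internally float32 so the
// BLAS-heavy paths (im2col GEMMs, projections) run at sgemm speed on one
// thread. Backward functions recompute forward intermediates from their
// inputs instead of carrying caches across the R boundary; the recomputation
// is cheap relative to the weight-gradient GEMMs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

typedef arma::fmat fmat;
typedef arma::fcube fcube;
typedef arma::fvec fvec;

static fcube as_fcube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array");
  fcube out(d[0], d[1], d[2]);
  const double* src = x.begin();
  float* dst = out.memptr();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) dst[i] = static_cast<float>(src[i]);
  return out;
}

static fmat as_fmat(const NumericMatrix& x) {
  fmat out(x.nrow(), x.ncol());
  const double* src = x.begin();
  float* dst = out.memptr();
  const R_xlen_t n = static_cast<R_xlen_t>(x.nrow()) * x.ncol();
  for (R_xlen_t i = 0; i < n; ++i) dst[i] = static_cast<float>(src[i]);
  return out;
}

static fvec as_fvec(const NumericVector& x) {
  fvec out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = static_cast<float>(x[i]);
  return out;
}

static NumericVector wrap_cube(const fcube& x) {
  NumericVector out(static_cast<R_xlen_t>(x.n_elem));
  const float* src = x.memptr();
  for (R_xlen_t i = 0; i < out.size(); ++i) out[i] = src[i];
  out.attr("dim") = IntegerVector::create(x.n_rows, x.n_cols, x.n_slices);
  return out;
}

static NumericMatrix wrap_mat(const fmat& x) {
  NumericMatrix out(x.n_rows, x.n_cols);
  const float* src = x.memptr();
  for (R_xlen_t i = 0; i < out.size(); ++i) out[i] = src[i];
  return out;
}

static NumericVector wrap_vec(const fvec& x) {
  NumericVector out(x.n_elem);
  for (R_xlen_t i = 0; i < out.size(); ++i) out[i] = x[i];
  return out;
}

// im2col for same-padded 1D convolution: col is (C_in * k, L * N) with
// col(j * C_in + c, t + n * L) = x(c, t + j - pad_left, n), zeros outside.
static fmat im2col1d(const fcube& x, int k) {
  const int C = x.n_rows, L = x.n_cols, N = x.n_slices;
  const int padl = (k - 1) / 2;
  fmat col(C * k, static_cast<arma::uword>(L) * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const fmat& xs = x.slice(n);
    for (int j = 0; j < k; ++j) {
      const int off = j - padl;
      const int t0 = std::max(0, -off), t1 = std::min(L, L - off);
      if (t1 > t0)
        col.submat(j * C, n * L + t0, (j + 1) * C - 1, n * L + t1 - 1) =
          xs.cols(t0 + off, t1 - 1 + off);
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector nn_conv1d_forward(NumericVector x, NumericMatrix w, NumericVector b, int k) {
  fcube xc = as_fcube(x);
  fmat wf = as_fmat(w);
  fvec bf = as_fvec(b);
  const int L = xc.n_cols, N = xc.n_slices;
  fmat col = im2col1d(xc, k);
  fmat y = wf * col;               // (C_out, L * N)
  y.each_col() += bf;
  fcube out(y.memptr(), wf.n_rows, L, N);
  return wrap_cube(out);
}

// [[Rcpp::export]]
List nn_conv1d_backward(NumericVector x, NumericMatrix w, NumericVector dy, int k) {
  fcube xc = as_fcube(x);
  fmat wf = as_fmat(w);
  fcube dyc = as_fcube(dy);
  const int C = xc.n_rows, L = xc.n_cols, N = xc.n_slices;
  const int padl = (k - 1) / 2;
  fmat dyf(dyc.memptr(), dyc.n_rows, static_cast<arma::uword>(L) * N, false);
  fmat col = im2col1d(xc, k);
  fmat dw = dyf * col.t();                       // (C_out, C_in * k)
  fvec db = arma::sum(dyf, 1);
  fmat dcol = wf.t() * dyf;                      // (C_in * k, L * N)
  fcube dx(C, L, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    fmat& dxs = dx.slice(n);
    for (int j = 0; j < k; ++j) {
      const int off = j - padl;
      const int t0 = std::max(0, -off), t1 = std::min(L, L - off);
      if (t1 > t0)
        dxs.cols(t0 + off, t1 - 1 + off) +=
          dcol.submat(j * C, n * L + t0, (j + 1) * C - 1, n * L + t1 - 1);
    }
  }
  return List::create(_["dx"] = wrap_cube(dx), _["dw"] = wrap_mat(dw), _["db"] = wrap_vec(db));
}

// [[Rcpp::export]]
NumericVector nn_maxpool2_forward(NumericVector x) {
  fcube xc = as_fcube(x);
  const int C = xc.n_rows, L = xc.n_cols, N = xc.n_slices;
  if (L % 2 != 0) stop("sequence length must be even for pool factor 2");
  // pair consecutive positions: view as (2C, L/2 * N) and take rowwise max
  fmat pairs(xc.memptr(), 2 * C, static_cast<arma::uword>(L / 2) * N, false);
  fmat y = arma::max(pairs.rows(0, C - 1), pairs.rows(C, 2 * C - 1));
  fcube out(y.memptr(), C, L / 2, N);
  return wrap_cube(out);
}

// [[Rcpp::export]]
NumericVector nn_maxpool2_backward(NumericVector x, NumericVector dy) {
  fcube xc = as_fcube(x);
  fcube dyc = as_fcube(dy);
  const int C = xc.n_rows, L = xc.n_cols, N = xc.n_slices;
  fmat pairs(xc.memptr(), 2 * C, static_cast<arma::uword>(L / 2) * N, false);
  fmat dyf(dyc.memptr(), C, static_cast<arma::uword>(L / 2) * N, false);
  // ties route to the earlier position, matching forward's max choice
  arma::umat first = pairs.rows(0, C - 1) >= pairs.rows(C, 2 * C - 1);
  fmat mask = arma::conv_to<fmat>::from(first);
  fmat dxp(2 * C, dyf.n_cols);
  dxp.rows(0, C - 1) = dyf % mask;
  dxp.rows(C, 2 * C - 1) = dyf % (1.0f - mask);
  fcube dx(dxp.memptr(), C, L, N);
  return wrap_cube(dx);
}

// Layer normalisation across channels at each (position, sample),
// vectorised over the flattened (channels, length * batch) view.
// [[Rcpp::export]]
NumericVector nn_layernorm_forward(NumericVector x, NumericVector gamma, NumericVector beta,
                                   double eps) {
  fcube xc = as_fcube(x);
  fvec g = as_fvec(gamma), be = as_fvec(beta);
  const int C = xc.n_rows;
  fmat xf(xc.memptr(), C, static_cast<arma::uword>(xc.n_cols) * xc.n_slices, false);
  arma::frowvec mu = arma::mean(xf, 0);
  fmat xhat = xf;
  xhat.each_row() -= mu;
  arma::frowvec inv = 1.0f / arma::sqrt(arma::mean(xhat % xhat, 0) +
                                        static_cast<float>(eps));
  xhat.each_row() %= inv;
  xhat.each_col() %= g;
  xhat.each_col() += be;
  fcube y(xhat.memptr(), C, xc.n_cols, xc.n_slices);
  return wrap_cube(y);
}

// [[Rcpp::export]]
List nn_layernorm_backward(NumericVector x, NumericVector gamma, NumericVector dy, double eps) {
  fcube xc = as_fcube(x);
  fvec g = as_fvec(gamma);
  fcube dyc = as_fcube(dy);
  const int C = xc.n_rows;
  fmat xf(xc.memptr(), C, static_cast<arma::uword>(xc.n_cols) * xc.n_slices, false);
  fmat dyf(dyc.memptr(), C, xf.n_cols, false);
  arma::frowvec mu = arma::mean(xf, 0);
  fmat xhat = xf;
  xhat.each_row() -= mu;
  arma::frowvec inv = 1.0f / arma::sqrt(arma::mean(xhat % xhat, 0) +
                                        static_cast<float>(eps));
  xhat.each_row() %= inv;
  fvec dgamma = arma::sum(dyf % xhat, 1);
  fvec dbeta = arma::sum(dyf, 1);
  fmat dxh = dyf;
  dxh.each_col() %= g;
  arma::frowvec m1 = arma::mean(dxh, 0);
  arma::frowvec m2 = arma::mean(dxh % xhat, 0);
  xhat.each_row() %= m2;
  dxh.each_row() -= m1;
  dxh -= xhat;
  dxh.each_row() %= inv;
  fcube dx(dxh.memptr(), C, xc.n_cols, xc.n_slices);
  return List::create(_["dx"] = wrap_cube(dx), _["dgamma"] = wrap_vec(dgamma),
                      _["dbeta"] = wrap_vec(dbeta));
}

static inline fmat silu(const fmat& x) {
  return x / (1.0f + arma::exp(-x));
}
static inline fmat silu_grad(const fmat& x) {
  fmat s = 1.0f / (1.0f + arma::exp(-x));
  return s % (1.0f + x % (1.0f - s));
}

// ---- float-level primitives shared by the exported wrappers and the fused
// ---- stage/block kernels

static fmat im2col_f(const fmat& xf, int C, int L, int N, int k) {
  const int padl = (k - 1) / 2;
  fmat col(C * k, static_cast<arma::uword>(L) * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < k; ++j) {
      const int off = j - padl;
      const int t0 = std::max(0, -off), t1 = std::min(L, L - off);
      if (t1 > t0)
        col.submat(j * C, n * L + t0, (j + 1) * C - 1, n * L + t1 - 1) =
          xf.cols(n * L + t0 + off, n * L + t1 - 1 + off);
    }
  return col;
}

// xf: (C_in, L*N) -> (C_out, L*N)
static fmat conv_fwd_f(const fmat& xf, const fmat& w, const fvec& b,
                       int L, int N, int k) {
  fmat col = im2col_f(xf, xf.n_rows, L, N, k);
  fmat y = w * col;
  y.each_col() += b;
  return y;
}

static void conv_bwd_f(const fmat& xf, const fmat& w, const fmat& dyf,
                       int L, int N, int k,
                       fmat& dx, fmat& dw, fvec& db) {
  const int C = xf.n_rows;
  const int padl = (k - 1) / 2;
  fmat col = im2col_f(xf, C, L, N, k);
  dw = dyf * col.t();
  db = arma::sum(dyf, 1);
  fmat dcol = w.t() * dyf;
  dx.zeros(C, xf.n_cols);
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < k; ++j) {
      const int off = j - padl;
      const int t0 = std::max(0, -off), t1 = std::min(L, L - off);
      if (t1 > t0)
        dx.cols(n * L + t0 + off, n * L + t1 - 1 + off) +=
          dcol.submat(j * C, n * L + t0, (j + 1) * C - 1, n * L + t1 - 1);
    }
}

static fmat ln_fwd_f(const fmat& xf, const fvec& g, const fvec& be, float eps) {
  arma::frowvec mu = arma::mean(xf, 0);
  fmat xhat = xf;
  xhat.each_row() -= mu;
  arma::frowvec inv = 1.0f / arma::sqrt(arma::mean(xhat % xhat, 0) + eps);
  xhat.each_row() %= inv;
  xhat.each_col() %= g;
  xhat.each_col() += be;
  return xhat;
}

static void ln_bwd_f(const fmat& xf, const fvec& g, const fmat& dyf, float eps,
                     fmat& dx, fvec& dgamma, fvec& dbeta) {
  arma::frowvec mu = arma::mean(xf, 0);
  fmat xhat = xf;
  xhat.each_row() -= mu;
  arma::frowvec inv = 1.0f / arma::sqrt(arma::mean(xhat % xhat, 0) + eps);
  xhat.each_row() %= inv;
  dgamma = arma::sum(dyf % xhat, 1);
  dbeta = arma::sum(dyf, 1);
  fmat dxh = dyf;
  dxh.each_col() %= g;
  arma::frowvec m1 = arma::mean(dxh, 0);
  arma::frowvec m2 = arma::mean(dxh % xhat, 0);
  xhat.each_row() %= m2;
  dx = dxh;
  dx.each_row() -= m1;
  dx -= xhat;
  dx.each_row() %= inv;
}

// pooled = rowwise max over consecutive position pairs; xf (C, L*N), L even
static fmat pool_fwd_f(const fmat& xf, int C, int L, int N) {
  fmat pairs(const_cast<float*>(xf.memptr()), 2 * C,
             static_cast<arma::uword>(L / 2) * N, false);
  return arma::max(pairs.rows(0, C - 1), pairs.rows(C, 2 * C - 1));
}

static fmat pool_bwd_f(const fmat& xf, const fmat& dyf, int C, int L, int N) {
  fmat pairs(const_cast<float*>(xf.memptr()), 2 * C,
             static_cast<arma::uword>(L / 2) * N, false);
  arma::umat first = pairs.rows(0, C - 1) >= pairs.rows(C, 2 * C - 1);
  fmat mask = arma::conv_to<fmat>::from(first);
  fmat dxp(2 * C, dyf.n_cols);
  dxp.rows(0, C - 1) = dyf % mask;
  dxp.rows(C, 2 * C - 1) = dyf % (1.0f - mask);
  return fmat(dxp.memptr(), C, static_cast<arma::uword>(L) * N);
}

// full residual (or plain) stage: conv1 -> ReLU [-> conv2 -> LN, + skip]
// -> maxpool/2. Returns the pooled output; backward recomputes.
struct StageParams {
  fmat conv1_w, conv2_w, proj_w;
  fvec conv1_b, conv2_b, ln_gamma, ln_beta;
  bool residual, has_proj;
  int k;
};

static fmat stage_fwd_f(const fmat& xf, const StageParams& sp, int L, int N,
                        fmat* keep_out = nullptr) {
  fmat a1 = conv_fwd_f(xf, sp.conv1_w, sp.conv1_b, L, N, sp.k);
  fmat r1 = arma::clamp(a1, 0.0f, std::numeric_limits<float>::max());
  fmat out;
  if (sp.residual) {
    fmat a2 = conv_fwd_f(r1, sp.conv2_w, sp.conv2_b, L, N, sp.k);
    out = ln_fwd_f(a2, sp.ln_gamma, sp.ln_beta, 1e-5f);
    if (sp.has_proj) {
      fvec zb(sp.proj_w.n_rows, arma::fill::zeros);
      out += conv_fwd_f(xf, sp.proj_w, zb, L, N, 1);
    } else {
      out += xf;
    }
  } else {
    out = r1;
  }
  if (keep_out) *keep_out = out;
  return pool_fwd_f(out, out.n_rows, L, N);
}

// [[Rcpp::export]]
NumericVector nn_stage_forward(NumericVector x, List params) {
  fcube xc = as_fcube(x);
  const int L = xc.n_cols, N = xc.n_slices;
  StageParams sp;
  sp.conv1_w = as_fmat(params["conv1_w"]); sp.conv1_b = as_fvec(params["conv1_b"]);
  sp.k = as<int>(params["kernel_size"]);
  sp.residual = as<bool>(params["residual"]);
  sp.has_proj = params.containsElementNamed("proj_w") &&
    !Rf_isNull(params["proj_w"]);
  if (sp.residual) {
    sp.conv2_w = as_fmat(params["conv2_w"]); sp.conv2_b = as_fvec(params["conv2_b"]);
    sp.ln_gamma = as_fvec(params["ln_gamma"]); sp.ln_beta = as_fvec(params["ln_beta"]);
  }
  if (sp.has_proj) sp.proj_w = as_fmat(params["proj_w"]);
  fmat xf(xc.memptr(), xc.n_rows, static_cast<arma::uword>(L) * N, false);
  fmat y = stage_fwd_f(xf, sp, L, N);
  fcube out(y.memptr(), y.n_rows, L / 2, N);
  return wrap_cube(out);
}

// [[Rcpp::export]]
List nn_stage_backward(NumericVector x, List params, NumericVector dy) {
  fcube xc = as_fcube(x);
  fcube dyc = as_fcube(dy);
  const int L = xc.n_cols, N = xc.n_slices;
  StageParams sp;
  sp.conv1_w = as_fmat(params["conv1_w"]); sp.conv1_b = as_fvec(params["conv1_b"]);
  sp.k = as<int>(params["kernel_size"]);
  sp.residual = as<bool>(params["residual"]);
  sp.has_proj = params.containsElementNamed("proj_w") &&
    !Rf_isNull(params["proj_w"]);
  if (sp.residual) {
    sp.conv2_w = as_fmat(params["conv2_w"]); sp.conv2_b = as_fvec(params["conv2_b"]);
    sp.ln_gamma = as_fvec(params["ln_gamma"]); sp.ln_beta = as_fvec(params["ln_beta"]);
  }
  if (sp.has_proj) sp.proj_w = as_fmat(params["proj_w"]);
  fmat xf(xc.memptr(), xc.n_rows, static_cast<arma::uword>(L) * N, false);
  fmat dyf(dyc.memptr(), dyc.n_rows, static_cast<arma::uword>(L / 2) * N, false);
  // recompute forward intermediates
  fmat a1 = conv_fwd_f(xf, sp.conv1_w, sp.conv1_b, L, N, sp.k);
  fmat r1 = arma::clamp(a1, 0.0f, std::numeric_limits<float>::max());
  fmat out;
  fmat a2;
  if (sp.residual) {
    a2 = conv_fwd_f(r1, sp.conv2_w, sp.conv2_b, L, N, sp.k);
    out = ln_fwd_f(a2, sp.ln_gamma, sp.ln_beta, 1e-5f);
    if (sp.has_proj) {
      fvec zb(sp.proj_w.n_rows, arma::fill::zeros);
      out += conv_fwd_f(xf, sp.proj_w, zb, L, N, 1);
    } else out += xf;
  } else out = r1;
  fmat dout = pool_bwd_f(out, dyf, out.n_rows, L, N);
  List res;
  fmat dx;
  if (sp.residual) {
    fmat dln, da2, dr1, dw2, dw1, dwp;
    fvec dg, dbta, db2, db1, dbp;
    ln_bwd_f(a2, sp.ln_gamma, dout, 1e-5f, da2, dg, dbta);
    conv_bwd_f(r1, sp.conv2_w, da2, L, N, sp.k, dr1, dw2, db2);
    fmat da1 = dr1 % arma::conv_to<fmat>::from(a1 > 0.0f);
    conv_bwd_f(xf, sp.conv1_w, da1, L, N, sp.k, dx, dw1, db1);
    if (sp.has_proj) {
      fmat dxp;
      conv_bwd_f(xf, sp.proj_w, dout, L, N, 1, dxp, dwp, dbp);
      dx += dxp;
      res["proj_w"] = wrap_mat(dwp);
    } else {
      dx += dout;
    }
    res["conv1_w"] = wrap_mat(dw1); res["conv1_b"] = wrap_vec(db1);
    res["conv2_w"] = wrap_mat(dw2); res["conv2_b"] = wrap_vec(db2);
    res["ln_gamma"] = wrap_vec(dg); res["ln_beta"] = wrap_vec(dbta);
  } else {
    fmat da1 = dout % arma::conv_to<fmat>::from(a1 > 0.0f);
    fmat dw1; fvec db1;
    conv_bwd_f(xf, sp.conv1_w, da1, L, N, sp.k, dx, dw1, db1);
    res["conv1_w"] = wrap_mat(dw1); res["conv1_b"] = wrap_vec(db1);
  }
  fcube dxc(dx.memptr(), xc.n_rows, L, N);
  res["dx"] = wrap_cube(dxc);
  return res;
}


// ---- selective state-space (Mamba) block ------------------------------------
//
// Projections are batched over (length x batch) as single GEMMs; only the
// recurrent scan walks positions per sample. Backward recomputes the forward
// intermediates (cheap next to the weight-gradient GEMMs) instead of
// carrying caches across the R boundary.

struct MambaParams {
  fmat W_in, conv_w, W_x, W_dt, A, A_log, W_out;
  fvec conv_b, b_dt, D;
  int d, di, L, N, K, dtr, st;
};

struct MambaFwd {
  fmat x1, z, x1c, xa, dr, Bm, Cm, dpre, Delta, ys, sz, yg;
};

static MambaParams mamba_params(const fcube& x, const NumericMatrix& W_in,
                                const NumericMatrix& conv_w, const NumericVector& conv_b,
                                const NumericMatrix& W_x, const NumericMatrix& W_dt,
                                const NumericVector& b_dt, const NumericMatrix& A_log,
                                const NumericVector& D, const NumericMatrix& W_out) {
  MambaParams p;
  p.W_in = as_fmat(W_in); p.conv_w = as_fmat(conv_w); p.W_x = as_fmat(W_x);
  p.W_dt = as_fmat(W_dt); p.A_log = as_fmat(A_log); p.W_out = as_fmat(W_out);
  p.conv_b = as_fvec(conv_b); p.b_dt = as_fvec(b_dt); p.D = as_fvec(D);
  p.A = -arma::exp(p.A_log);
  p.d = x.n_rows; p.L = x.n_cols; p.N = x.n_slices;
  p.di = p.conv_w.n_rows; p.K = p.conv_w.n_cols;
  p.st = p.A_log.n_cols; p.dtr = p.W_dt.n_cols;
  if ((int)p.W_in.n_rows != 2 * p.di) stop("W_in rows must be 2 * inner dim");
  return p;
}

// batched forward up to the gated output; scan state is not kept
static void mamba_fwd_all(const MambaParams& p, const fmat& x_flat, MambaFwd& w) {
  const int di = p.di, L = p.L, N = p.N, K = p.K, dtr = p.dtr, st = p.st;
  fmat xz = p.W_in * x_flat;                 // (2 di, L N)
  w.x1 = xz.rows(0, di - 1);
  w.z = xz.rows(di, 2 * di - 1);
  w.x1c.set_size(di, w.x1.n_cols);
  w.x1c.each_col() = p.conv_b;
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < K; ++j) {
      const int t0 = K - 1 - j;              // first valid output position
      if (t0 >= L) continue;
      fmat blk = w.x1.cols(n * L, n * L + (L - 1 - t0));
      blk.each_col() %= p.conv_w.col(j);
      w.x1c.cols(n * L + t0, n * L + L - 1) += blk;
    }
  w.xa = silu(w.x1c);
  fmat dbc = p.W_x * w.xa;
  w.dr = dbc.rows(0, dtr - 1);
  w.Bm = dbc.rows(dtr, dtr + st - 1);
  w.Cm = dbc.rows(dtr + st, dtr + 2 * st - 1);
  w.dpre = p.W_dt * w.dr;
  w.dpre.each_col() += p.b_dt;
  w.Delta = arma::log1p(arma::exp(-arma::abs(w.dpre))) +
            arma::max(w.dpre, arma::zeros<fmat>(arma::size(w.dpre)));
  // selective scan
  w.ys.set_size(di, w.xa.n_cols);
  fmat h(di, st), dAmat(di, st);
  fvec u(di);
  for (int n = 0; n < N; ++n) {
    h.zeros();
    for (int t = 0; t < L; ++t) {
      const int c = n * L + t;
      dAmat = p.A;
      dAmat.each_col() %= w.Delta.col(c);
      dAmat = arma::exp(dAmat);
      h %= dAmat;
      u = w.Delta.col(c) % w.xa.col(c);
      for (int s = 0; s < st; ++s) h.unsafe_col(s) += w.Bm(s, c) * u;
      w.ys.col(c) = h * w.Cm.col(c) + p.D % w.xa.col(c);
    }
  }
  w.sz = silu(w.z);
  w.yg = w.ys % w.sz;
}

// [[Rcpp::export]]
NumericVector nn_mamba_forward(NumericVector x, NumericMatrix W_in, NumericMatrix conv_w,
                               NumericVector conv_b, NumericMatrix W_x, NumericMatrix W_dt,
                               NumericVector b_dt, NumericMatrix A_log, NumericVector D,
                               NumericMatrix W_out) {
  fcube xc = as_fcube(x);
  MambaParams p = mamba_params(xc, W_in, conv_w, conv_b, W_x, W_dt, b_dt, A_log, D, W_out);
  fmat x_flat(xc.memptr(), p.d, static_cast<arma::uword>(p.L) * p.N, false);
  MambaFwd w;
  mamba_fwd_all(p, x_flat, w);
  fmat out = p.W_out * w.yg;
  fcube y = xc;
  fmat y_flat(y.memptr(), p.d, x_flat.n_cols, false);
  y_flat += out;
  return wrap_cube(y);
}

// core of the backward pass: gradients of y = input + W_out * yg(input)
// wrt input (without the +dy residual term when add_residual is false)
static void mamba_bwd_core(const MambaParams& p, const fmat& x_flat,
                           const fmat& dy_flat, bool add_residual,
                           fmat& dx_flat, fmat& dW_in, fmat& dconv_w,
                           fvec& dconv_b, fmat& dW_x, fmat& dW_dt, fvec& db_dt,
                           fmat& dA_log, fvec& dD, fmat& dW_out) {
  const int di = p.di, L = p.L, N = p.N, K = p.K, st = p.st;
  MambaFwd w;
  mamba_fwd_all(p, x_flat, w);

  dW_out = dy_flat * w.yg.t();
  fmat dyg = p.W_out.t() * dy_flat;
  fmat dys = dyg % w.sz;
  fmat dz = dyg % w.ys % silu_grad(w.z);
  dD = arma::sum(dys % w.xa, 1);
  fmat dxa = dys;
  dxa.each_col() %= p.D;

  fmat dBm(st, dys.n_cols, arma::fill::zeros), dCm(st, dys.n_cols);
  fmat dDelta(di, dys.n_cols);
  fmat dA_acc(arma::size(p.A), arma::fill::zeros);
  fcube hs(di, st, L + 1);                  // reused per-sample state history
  fmat h(di, st), dAmat(di, st), dh(di, st), ddA(di, st);
  fvec u(di), dhB(di);
  for (int n = 0; n < N; ++n) {
    hs.slice(0).zeros();
    h.zeros();
    for (int t = 0; t < L; ++t) {
      const int c = n * L + t;
      dAmat = p.A; dAmat.each_col() %= w.Delta.col(c); dAmat = arma::exp(dAmat);
      h %= dAmat;
      u = w.Delta.col(c) % w.xa.col(c);
      for (int ss = 0; ss < st; ++ss) h.unsafe_col(ss) += w.Bm(ss, c) * u;
      hs.slice(t + 1) = h;
    }
    dh.zeros();
    for (int t = L - 1; t >= 0; --t) {
      const int c = n * L + t;
      for (int ss = 0; ss < st; ++ss) dh.unsafe_col(ss) += w.Cm(ss, c) * dys.col(c);
      dCm.col(c) = (dys.col(c).t() * hs.slice(t + 1)).t();
      dAmat = p.A; dAmat.each_col() %= w.Delta.col(c); dAmat = arma::exp(dAmat);
      ddA = dh % hs.slice(t);
      dhB = dh * w.Bm.col(c);
      dDelta.col(c) = arma::sum(ddA % dAmat % p.A, 1) + w.xa.col(c) % dhB;
      dBm.col(c) = dh.t() * (w.Delta.col(c) % w.xa.col(c));
      dxa.col(c) += w.Delta.col(c) % dhB;
      ddA %= dAmat;
      ddA.each_col() %= w.Delta.col(c);
      dA_acc += ddA;
      dh %= dAmat;
    }
  }
  fmat ddpre = dDelta % (1.0f / (1.0f + arma::exp(-w.dpre)));
  db_dt = arma::sum(ddpre, 1);
  dW_dt = ddpre * w.dr.t();
  fmat ddr = p.W_dt.t() * ddpre;
  fmat ddbc = arma::join_cols(ddr, arma::join_cols(dBm, dCm));
  dW_x = ddbc * w.xa.t();
  dxa += p.W_x.t() * ddbc;
  fmat dx1c = dxa % silu_grad(w.x1c);
  dconv_b = arma::sum(dx1c, 1);
  dconv_w.zeros(arma::size(p.conv_w));
  fmat dx1(di, dx1c.n_cols, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < K; ++j) {
      const int t0 = K - 1 - j;
      if (t0 >= L) continue;
      dconv_w.col(j) += arma::sum(dx1c.cols(n * L + t0, n * L + L - 1) %
                                  w.x1.cols(n * L, n * L + (L - 1 - t0)), 1);
      fmat blk = dx1c.cols(n * L + t0, n * L + L - 1);
      blk.each_col() %= p.conv_w.col(j);
      dx1.cols(n * L, n * L + (L - 1 - t0)) += blk;
    }
  fmat dxz = arma::join_cols(dx1, dz);
  dW_in = dxz * x_flat.t();
  dx_flat = p.W_in.t() * dxz;
  if (add_residual) dx_flat += dy_flat;
  dA_log = dA_acc % p.A;
}

// [[Rcpp::export]]
List nn_mamba_backward(NumericVector x, NumericMatrix W_in, NumericMatrix conv_w,
                       NumericVector conv_b, NumericMatrix W_x, NumericMatrix W_dt,
                       NumericVector b_dt, NumericMatrix A_log, NumericVector D,
                       NumericMatrix W_out, NumericVector dy) {
  fcube xc = as_fcube(x), dyc = as_fcube(dy);
  MambaParams p = mamba_params(xc, W_in, conv_w, conv_b, W_x, W_dt, b_dt, A_log, D, W_out);
  fmat x_flat(xc.memptr(), p.d, static_cast<arma::uword>(p.L) * p.N, false);
  fmat dy_flat(dyc.memptr(), p.d, x_flat.n_cols, false);
  fmat dx_flat, dW_in, dconv_w, dW_x, dW_dt, dA_log_out, dW_out;
  fvec dconv_b, db_dt, dD;
  mamba_bwd_core(p, x_flat, dy_flat, true, dx_flat, dW_in, dconv_w, dconv_b,
                 dW_x, dW_dt, db_dt, dA_log_out, dD, dW_out);
  fcube dx(dx_flat.memptr(), p.d, p.L, p.N);
  return List::create(_["dx"] = wrap_cube(dx), _["dW_in"] = wrap_mat(dW_in),
                      _["dconv_w"] = wrap_mat(dconv_w), _["dconv_b"] = wrap_vec(dconv_b),
                      _["dW_x"] = wrap_mat(dW_x), _["dW_dt"] = wrap_mat(dW_dt),
                      _["db_dt"] = wrap_vec(db_dt), _["dA_log"] = wrap_mat(dA_log_out),
                      _["dD"] = wrap_vec(dD), _["dW_out"] = wrap_mat(dW_out));
}

// pre-normalised Mamba block: y = x + Out(Block(LN(x))); fused so the whole
// block crosses the R boundary once in each direction
// [[Rcpp::export]]
NumericVector nn_mamba_pre_forward(NumericVector x, NumericVector ln_gamma,
                                   NumericVector ln_beta, NumericMatrix W_in,
                                   NumericMatrix conv_w, NumericVector conv_b,
                                   NumericMatrix W_x, NumericMatrix W_dt,
                                   NumericVector b_dt, NumericMatrix A_log,
                                   NumericVector D, NumericMatrix W_out) {
  fcube xc = as_fcube(x);
  MambaParams p = mamba_params(xc, W_in, conv_w, conv_b, W_x, W_dt, b_dt, A_log, D, W_out);
  fmat x_flat(xc.memptr(), p.d, static_cast<arma::uword>(p.L) * p.N, false);
  fmat xn = ln_fwd_f(x_flat, as_fvec(ln_gamma), as_fvec(ln_beta), 1e-5f);
  MambaFwd w;
  mamba_fwd_all(p, xn, w);
  fmat y = x_flat + p.W_out * w.yg;
  fcube out(y.memptr(), p.d, p.L, p.N);
  return wrap_cube(out);
}

// [[Rcpp::export]]
List nn_mamba_pre_backward(NumericVector x, NumericVector ln_gamma,
                           NumericVector ln_beta, NumericMatrix W_in,
                           NumericMatrix conv_w, NumericVector conv_b,
                           NumericMatrix W_x, NumericMatrix W_dt,
                           NumericVector b_dt, NumericMatrix A_log,
                           NumericVector D, NumericMatrix W_out,
                           NumericVector dy) {
  fcube xc = as_fcube(x), dyc = as_fcube(dy);
  MambaParams p = mamba_params(xc, W_in, conv_w, conv_b, W_x, W_dt, b_dt, A_log, D, W_out);
  fvec lg = as_fvec(ln_gamma), lb = as_fvec(ln_beta);
  fmat x_flat(xc.memptr(), p.d, static_cast<arma::uword>(p.L) * p.N, false);
  fmat dy_flat(dyc.memptr(), p.d, x_flat.n_cols, false);
  fmat xn = ln_fwd_f(x_flat, lg, lb, 1e-5f);
  fmat dxn, dW_in, dconv_w, dW_x, dW_dt, dA_log, dW_out;
  fvec dconv_b, db_dt, dD;
  mamba_bwd_core(p, xn, dy_flat, false, dxn, dW_in, dconv_w, dconv_b, dW_x,
                 dW_dt, db_dt, dA_log, dD, dW_out);
  fmat dln; fvec dg, dbt;
  ln_bwd_f(x_flat, lg, dxn, 1e-5f, dln, dg, dbt);
  dln += dy_flat;
  fcube dx(dln.memptr(), p.d, p.L, p.N);
  return List::create(_["dx"] = wrap_cube(dx), _["dln_gamma"] = wrap_vec(dg),
                      _["dln_beta"] = wrap_vec(dbt),
                      _["dW_in"] = wrap_mat(dW_in),
                      _["dconv_w"] = wrap_mat(dconv_w), _["dconv_b"] = wrap_vec(dconv_b),
                      _["dW_x"] = wrap_mat(dW_x), _["dW_dt"] = wrap_mat(dW_dt),
                      _["db_dt"] = wrap_vec(db_dt), _["dA_log"] = wrap_mat(dA_log),
                      _["dD"] = wrap_vec(dD), _["dW_out"] = wrap_mat(dW_out));
}

// 4-connected component labelling of a binary matrix; 0 = background,
// components numbered 1.. in scan order of their first pixel.
// [[Rcpp::export]]
IntegerMatrix label_components_4(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % nr, pj = p / nr;
        const int ni[4] = {pi - 1, pi + 1, pi, pi};
        const int nj[4] = {pj, pj, pj - 1, pj + 1};
        for (int q = 0; q < 4; ++q) {
          if (ni[q] < 0 || ni[q] >= nr || nj[q] < 0 || nj[q] >= nc) continue;
          if (mask(ni[q], nj[q]) && lab(ni[q], nj[q]) == 0) {
            lab(ni[q], nj[q]) = next;
            stack.push_back(ni[q] + nj[q] * nr);
          }
        }
      }
    }
  return lab;
}
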