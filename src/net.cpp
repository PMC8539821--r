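// Network engine: bidirectional LSTM encoder, two 4-conv/3-pool feature
// stacks, dense sigmoid head; exact backpropagation and Adam.
//
// Conventions
//   * Sequences arrive as 1-based alphabet indices (n x T integer matrix,
//     0 = padding row); the one-hot input to the first LSTM layer is never
//     materialized — pre-activations are gathered straight from the rows
//     of its input weight matrix.
//   * LSTM gate order within the 4h pre-activation block: [i, f, g, o];
//     c_t = f*c_{t-1} + i*g, h_t = o * tanh(c_t).
//   * Time-batch layout: per-position quantities live in (B*T) x k
//     matrices with row index b + B*t, so the input and weight-gradient
//     products collapse into single GEMMs and only the recurrent term is
//     applied step by step.
//   * Convolution is valid cross-correlation. Kernels for a layer with
//     kh x kw windows over cin channels are stored as a (kh*kw*cin) x K
//     matrix whose row index is i + kh*j + kh*kw*c (row offset fastest).
//   * Images are arma::cube (height, width, channels); flattening is
//     arma::vectorise order (column-major, channels last). Workspaces are
//     allocated once per run and reused across examples and batches; the
//     im2col buffers filled by the forward pass are reused by the
//     backward pass.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

enum Variant { FULL = 0, BLSTM = 1, BLSTM_CONV1 = 2, CONV2 = 3 };

struct Config {
  int variant, T, L, nlayers, h, dense_hidden;
  ivec kc;          // kernels per conv layer (4)
  imat ks;          // 4 x 2 kernel sizes
  int ph, pw;       // pool window (= stride)
  double lambda;
  bool use_lstm, use_conv1, use_conv2;
};

Config parse_config(const Rcpp::List& cfg) {
  Config c;
  c.variant = Rcpp::as<int>(cfg["variant"]);
  c.T = Rcpp::as<int>(cfg["l_max"]);
  c.L = Rcpp::as<int>(cfg["n_labels"]);
  c.nlayers = Rcpp::as<int>(cfg["lstm_layers"]);
  c.h = Rcpp::as<int>(cfg["lstm_hidden"]);
  c.dense_hidden = Rcpp::as<int>(cfg["dense_hidden"]);
  c.kc = Rcpp::as<ivec>(cfg["kernel_counts"]);
  c.ks = Rcpp::as<imat>(cfg["kernel_sizes"]);
  ivec pool = Rcpp::as<ivec>(cfg["pool"]);
  c.ph = (int)pool(0); c.pw = (int)pool(1);
  c.lambda = Rcpp::as<double>(cfg["l2_lambda"]);
  c.use_lstm = (c.variant != CONV2);
  c.use_conv1 = (c.variant == FULL || c.variant == BLSTM_CONV1);
  c.use_conv2 = (c.variant == FULL || c.variant == CONV2);
  return c;
}

// ---- parameter registry -------------------------------------------------

struct Net {
  Config cfg;
  std::vector<std::string> names;
  std::vector<mat> P;

  int idx(const std::string& nm) const {
    for (size_t i = 0; i < names.size(); ++i)
      if (names[i] == nm) return (int)i;
    Rcpp::stop("missing parameter '%s'", nm.c_str());
    return -1;
  }
  const mat& get(const std::string& nm) const { return P[idx(nm)]; }
};

std::vector<std::string> param_names(const Config& c) {
  std::vector<std::string> nm;
  char buf[64];
  if (c.use_lstm) {
    for (int l = 1; l <= c.nlayers; ++l)
      for (int d = 0; d < 2; ++d) {
        const char dir = d == 0 ? 'f' : 'b';
        snprintf(buf, sizeof buf, "lstm%d_%c_W", l, dir); nm.push_back(buf);
        snprintf(buf, sizeof buf, "lstm%d_%c_U", l, dir); nm.push_back(buf);
        snprintf(buf, sizeof buf, "lstm%d_%c_b", l, dir); nm.push_back(buf);
      }
  }
  for (int br = 1; br <= 2; ++br) {
    if ((br == 1 && !c.use_conv1) || (br == 2 && !c.use_conv2)) continue;
    for (int cl = 1; cl <= 4; ++cl) {
      snprintf(buf, sizeof buf, "conv%d_%d_W", br, cl); nm.push_back(buf);
      snprintf(buf, sizeof buf, "conv%d_%d_b", br, cl); nm.push_back(buf);
    }
  }
  if (c.dense_hidden > 0) {
    nm.push_back("dense1_W"); nm.push_back("dense1_b");
    nm.push_back("dense2_W"); nm.push_back("dense2_b");
  } else {
    nm.push_back("dense_W"); nm.push_back("dense_b");
  }
  return nm;
}

Net load_net(const Rcpp::List& params, const Config& cfg) {
  Net net;
  net.cfg = cfg;
  net.names = param_names(cfg);
  for (const auto& nm : net.names) {
    if (!params.containsElementNamed(nm.c_str()))
      Rcpp::stop("parameter list is missing '%s'", nm.c_str());
    Rcpp::RObject obj = params[nm];
    Rcpp::NumericVector v(obj);
    if (Rf_isMatrix(obj)) {
      Rcpp::NumericMatrix m(obj);
      net.P.push_back(mat(m.begin(), m.nrow(), m.ncol()));
    } else {
      net.P.push_back(mat(v.begin(), 1, v.size()));  // bias row vector
    }
  }
  return net;
}

Rcpp::List dump_params(const Net& net) {
  Rcpp::List out;
  for (size_t i = 0; i < net.names.size(); ++i) {
    const mat& m = net.P[i];
    bool is_bias = net.names[i].size() >= 2 &&
      net.names[i].compare(net.names[i].size() - 2, 2, "_b") == 0;
    if (is_bias) {
      out[net.names[i]] = Rcpp::NumericVector(m.begin(), m.end());
    } else {
      Rcpp::NumericMatrix rm(m.n_rows, m.n_cols);
      std::copy(m.begin(), m.end(), rm.begin());
      out[net.names[i]] = rm;
    }
  }
  return out;
}

bool is_conv_kernel(const std::string& nm) {
  return nm.rfind("conv", 0) == 0 &&
         nm.compare(nm.size() - 2, 2, "_W") == 0;
}

// ---- LSTM ---------------------------------------------------------------

// All per-position state in (B*T) x k matrices, row index r = b + B*t.
struct LstmCache {
  mat A;      // gates i|f|g|o after forward, (B*T) x 4h
  mat C, H;   // cell state and output, (B*T) x h
  mat Hprev;  // output at the previous processing step, (B*T) x h
};

// Layer-1 pre-activations: gather rows of W by alphabet index (padding
// rows contribute nothing, i.e. stay at the bias).
void gather_embedding(const Rcpp::IntegerMatrix& idx, const uvec& rows,
                      int T, const mat& W, mat& A) {
  const int B = rows.n_elem;
  for (int t = 0; t < T; ++t)
    for (int b = 0; b < B; ++b) {
      int a = idx(rows(b), t);
      if (a > 0) A.row(b + B * t) = W.row(a - 1);
      else A.row(b + B * t).zeros();
    }
}

// dir = +1 forward (reads t = 0..T-1), -1 backward (reads t = T-1..0).
// Xin: (B*T) x in, or nullptr for layer 1 (use idx/rows gather instead).
void lstm_forward(const mat& W, const mat& U, const rowvec& b,
                  const mat* Xin, const Rcpp::IntegerMatrix* idx,
                  const uvec* rows, int B, int T, int dir, LstmCache& cc) {
  const int h = U.n_rows;
  cc.A.set_size(B * T, 4 * h);
  if (Xin) cc.A = (*Xin) * W;
  else gather_embedding(*idx, *rows, T, W, cc.A);
  cc.A.each_row() += b;
  cc.C.set_size(B * T, h);
  cc.H.set_size(B * T, h);
  cc.Hprev.set_size(B * T, h);
  mat hp(B, h, fill::zeros), cp(B, h, fill::zeros);
  for (int k = 0; k < T; ++k) {
    const int t = dir > 0 ? k : T - 1 - k;
    const int r0 = t * B, r1 = t * B + B - 1;
    cc.Hprev.rows(r0, r1) = hp;
    cc.A.rows(r0, r1) += hp * U;
    mat i = 1.0 / (1.0 + exp(-cc.A.submat(r0, 0, r1, h - 1)));
    mat f = 1.0 / (1.0 + exp(-cc.A.submat(r0, h, r1, 2 * h - 1)));
    mat g = tanh(cc.A.submat(r0, 2 * h, r1, 3 * h - 1));
    mat o = 1.0 / (1.0 + exp(-cc.A.submat(r0, 3 * h, r1, 4 * h - 1)));
    cc.A.submat(r0, 0, r1, h - 1) = i;
    cc.A.submat(r0, h, r1, 2 * h - 1) = f;
    cc.A.submat(r0, 2 * h, r1, 3 * h - 1) = g;
    cc.A.submat(r0, 3 * h, r1, 4 * h - 1) = o;
    cp = f % cp + i % g;
    cc.C.rows(r0, r1) = cp;
    hp = o % tanh(cp);
    cc.H.rows(r0, r1) = hp;
  }
}

// Accumulates dW/dU/db; writes the input gradient into dXin (nullptr for
// layer 1, where the gradient is scattered straight into dW rows).
void lstm_backward(const mat& W, const mat& U,
                   const mat* Xin, const Rcpp::IntegerMatrix* idx,
                   const uvec* rows, int B, int T, int dir,
                   const LstmCache& cc, const mat& dH,
                   mat& dW, mat& dU, rowvec& db, mat* dXin, mat& dA) {
  const int h = U.n_rows;
  dA.set_size(B * T, 4 * h);
  mat dh_carry(B, h, fill::zeros), dc_carry(B, h, fill::zeros);
  const mat Ut = U.t();
  for (int k = T - 1; k >= 0; --k) {
    const int t = dir > 0 ? k : T - 1 - k;
    const int tp = dir > 0 ? t - 1 : t + 1;  // valid iff k > 0
    const int r0 = t * B, r1 = t * B + B - 1;
    mat i = cc.A.submat(r0, 0, r1, h - 1);
    mat f = cc.A.submat(r0, h, r1, 2 * h - 1);
    mat g = cc.A.submat(r0, 2 * h, r1, 3 * h - 1);
    mat o = cc.A.submat(r0, 3 * h, r1, 4 * h - 1);
    mat tc = tanh(cc.C.rows(r0, r1));
    mat dh = dH.rows(r0, r1) + dh_carry;
    mat do_ = dh % tc;
    mat dc = dh % o % (1.0 - square(tc)) + dc_carry;
    mat di = dc % g;
    mat dg = dc % i;
    mat df(B, h, fill::zeros);
    if (k > 0) df = dc % cc.C.rows(tp * B, tp * B + B - 1);
    dc_carry = dc % f;
    dA.submat(r0, 0, r1, h - 1)         = di % i % (1.0 - i);
    dA.submat(r0, h, r1, 2 * h - 1)     = df % f % (1.0 - f);
    dA.submat(r0, 2 * h, r1, 3 * h - 1) = dg % (1.0 - square(g));
    dA.submat(r0, 3 * h, r1, 4 * h - 1) = do_ % o % (1.0 - o);
    dh_carry = dA.rows(r0, r1) * Ut;
  }
  db += sum(dA, 0);
  dU += cc.Hprev.t() * dA;
  if (Xin) {
    dW += Xin->t() * dA;
    if (dXin) *dXin += dA * W.t();
  } else {
    const int BB = rows->n_elem;
    for (int t = 0; t < T; ++t)
      for (int b = 0; b < BB; ++b) {
        int a = (*idx)(( *rows)(b), t);
        if (a > 0) dW.row(a - 1) += dA.row(b + BB * t);
      }
  }
}

struct BlstmCache {
  std::vector<mat> layer_in;           // input per layer >= 2, (B*T) x 2h
  std::vector<LstmCache> fwd, bwd;     // per layer
  mat top;                             // (B*T) x 2h final-layer output
  mat dA;                              // scratch shared by backward passes
  int B = 0;
};

void blstm_forward_all(const Net& net, const Rcpp::IntegerMatrix& idx,
                       const uvec& rows, BlstmCache& bc) {
  const Config& c = net.cfg;
  const int B = rows.n_elem, T = c.T, h = c.h;
  bc.B = B;
  bc.layer_in.resize(c.nlayers);
  bc.fwd.resize(c.nlayers);
  bc.bwd.resize(c.nlayers);
  char buf[64];
  const mat* in = nullptr;
  for (int l = 1; l <= c.nlayers; ++l) {
    snprintf(buf, sizeof buf, "lstm%d_f_W", l);
    const mat& Wf = net.get(buf);
    snprintf(buf, sizeof buf, "lstm%d_f_U", l);
    const mat& Uf = net.get(buf);
    snprintf(buf, sizeof buf, "lstm%d_f_b", l);
    rowvec bf = net.get(buf).row(0);
    lstm_forward(Wf, Uf, bf, in, &idx, &rows, B, T, +1, bc.fwd[l - 1]);
    snprintf(buf, sizeof buf, "lstm%d_b_W", l);
    const mat& Wb = net.get(buf);
    snprintf(buf, sizeof buf, "lstm%d_b_U", l);
    const mat& Ub = net.get(buf);
    snprintf(buf, sizeof buf, "lstm%d_b_b", l);
    rowvec bb = net.get(buf).row(0);
    lstm_forward(Wb, Ub, bb, in, &idx, &rows, B, T, -1, bc.bwd[l - 1]);
    mat& out = (l == c.nlayers) ? bc.top : bc.layer_in[l];
    out.set_size(B * T, 2 * h);
    out.cols(0, h - 1) = bc.fwd[l - 1].H;
    out.cols(h, 2 * h - 1) = bc.bwd[l - 1].H;
    in = &out;
  }
}

// dTop: gradient on the final-layer output, (B*T) x 2h.
void blstm_backward_all(const Net& net, const Rcpp::IntegerMatrix& idx,
                        const uvec& rows, BlstmCache& bc, const mat& dTop,
                        std::vector<mat>& G) {
  const Config& c = net.cfg;
  const int B = bc.B, T = c.T, h = c.h;
  char buf[64];
  mat dout = dTop;
  for (int l = c.nlayers; l >= 1; --l) {
    const bool first = (l == 1);
    const mat* in = first ? nullptr : &bc.layer_in[l - 1];
    mat dIn;
    if (!first) dIn.zeros(B * T, 2 * h);
    snprintf(buf, sizeof buf, "lstm%d_f_W", l);
    int iWf = net.idx(buf);
    snprintf(buf, sizeof buf, "lstm%d_f_U", l);
    int iUf = net.idx(buf);
    snprintf(buf, sizeof buf, "lstm%d_f_b", l);
    int ibf = net.idx(buf);
    rowvec dbf = G[ibf].row(0);
    lstm_backward(net.P[iWf], net.P[iUf], in, &idx, &rows, B, T, +1,
                  bc.fwd[l - 1], dout.cols(0, h - 1).eval(),
                  G[iWf], G[iUf], dbf, first ? nullptr : &dIn, bc.dA);
    G[ibf].row(0) = dbf;
    snprintf(buf, sizeof buf, "lstm%d_b_W", l);
    int iWb = net.idx(buf);
    snprintf(buf, sizeof buf, "lstm%d_b_U", l);
    int iUb = net.idx(buf);
    snprintf(buf, sizeof buf, "lstm%d_b_b", l);
    int ibb = net.idx(buf);
    rowvec dbb = G[ibb].row(0);
    lstm_backward(net.P[iWb], net.P[iUb], in, &idx, &rows, B, T, -1,
                  bc.bwd[l - 1], dout.cols(h, 2 * h - 1).eval(),
                  G[iWb], G[iUb], dbb, first ? nullptr : &dIn, bc.dA);
    G[ibb].row(0) = dbb;
    if (!first) dout = dIn;
  }
}

// ---- convolution stack --------------------------------------------------

struct ConvDims {
  int ih, iw, ic;      // input image
  int oh, ow, k;       // conv output
  int poh, pow;        // after pooling (layers 1-3)
};

// Workspace for one branch, allocated once from the geometry and reused
// for every example. The im2col buffers written by the forward pass are
// still valid in the backward pass.
struct ConvWS {
  ConvDims d[4];
  cube input[4];       // input image per layer
  mat cols[4];         // im2col of input[cl]
  cube out[4];         // post-ReLU conv output
  uvec pidx[3];        // pooling argmax (linear index into out[cl])
  vec flat;            // flattened final output
  mat dz[4];
  cube dout_buf[4];
  int flat_size = 0;
  bool ready = false;
};

void conv_ws_init(const Config& c, int width, ConvWS& ws) {
  int ih = c.T, iw = width, ic = 1;
  for (int cl = 0; cl < 4; ++cl) {
    ConvDims& d = ws.d[cl];
    d.ih = ih; d.iw = iw; d.ic = ic;
    const int kh = (int)c.ks(cl, 0), kw = (int)c.ks(cl, 1);
    d.k = (int)c.kc(cl);
    d.oh = ih - kh + 1; d.ow = iw - kw + 1;
    if (d.oh < 1 || d.ow < 1)
      Rcpp::stop("conv layer %d collapses the input", cl + 1);
    ws.input[cl].set_size(ih, iw, ic);
    ws.cols[cl].set_size(d.oh * d.ow, kh * kw * ic);
    ws.out[cl].set_size(d.oh, d.ow, d.k);
    ws.dz[cl].set_size(d.oh * d.ow, d.k);
    ws.dout_buf[cl].set_size(d.oh, d.ow, d.k);
    if (cl < 3) {
      d.poh = d.oh / c.ph; d.pow = d.ow / c.pw;
      if (d.poh < 1 || d.pow < 1)
        Rcpp::stop("pool after conv layer %d collapses the input", cl + 1);
      ws.pidx[cl].set_size(d.poh * d.pow * d.k);
      ih = d.poh; iw = d.pow;
    } else {
      ih = d.oh; iw = d.ow;
    }
    ic = d.k;
  }
  ws.flat_size = ih * iw * ic;
  ws.flat.set_size(ws.flat_size);
  ws.ready = true;
}

void im2col_fill(const cube& X, int kh, int kw, mat& out) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int oh = H - kh + 1, ow = W - kw + 1;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        const int col = i + kh * j + kh * kw * c;
        double* dst = out.colptr(col);
        for (int ox = 0; ox < ow; ++ox) {
          const double* src = X.slice_colptr(c, j + ox) + i;
          std::copy(src, src + oh, dst + ox * oh);
        }
      }
}

void col2im_add(const mat& dcols, int kh, int kw, cube& dX) {
  const int H = dX.n_rows, C = dX.n_slices;
  const int oh = H - kh + 1, ow = dX.n_cols - kw + 1;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        const int col = i + kh * j + kh * kw * c;
        const double* src = dcols.colptr(col);
        for (int ox = 0; ox < ow; ++ox) {
          double* dst = dX.slice_colptr(c, j + ox) + i;
          const double* s = src + ox * oh;
          for (int q = 0; q < oh; ++q) dst[q] += s[q];
        }
      }
}

// br: 0 = conv1 (BLSTM image), 1 = conv2 (PSSM image)
void conv_forward(const Net& net, int br, const mat& img, ConvWS& ws) {
  const Config& c = net.cfg;
  char buf[64];
  ws.input[0].slice(0) = img;
  for (int cl = 0; cl < 4; ++cl) {
    const ConvDims& d = ws.d[cl];
    const int kh = (int)c.ks(cl, 0), kw = (int)c.ks(cl, 1);
    snprintf(buf, sizeof buf, "conv%d_%d_W", br + 1, cl + 1);
    const mat& W = net.get(buf);
    snprintf(buf, sizeof buf, "conv%d_%d_b", br + 1, cl + 1);
    rowvec b = net.get(buf).row(0);
    im2col_fill(ws.input[cl], kh, kw, ws.cols[cl]);
    mat z = ws.cols[cl] * W;
    z.each_row() += b;
    z.clamp(0.0, datum::inf);  // ReLU
    std::copy(z.begin(), z.end(), ws.out[cl].begin());
    if (cl < 3) {
      cube& pooled = ws.input[cl + 1];
      const cube& out = ws.out[cl];
      uvec& pidx = ws.pidx[cl];
      std::vector<double> best(d.poh);
      std::vector<uword> barg(d.poh);
      for (int k = 0; k < d.k; ++k) {
        const uword koff = (uword)d.oh * d.ow * k;
        for (int px = 0; px < d.pow; ++px) {
          std::fill(best.begin(), best.end(), -datum::inf);
          // scan window columns once each; rows are contiguous in memory
          for (int jj = px * c.pw; jj < (px + 1) * c.pw; ++jj) {
            const double* col = out.slice_colptr(k, jj);
            const uword coff = (uword)d.oh * jj;
            for (int py = 0; py < d.poh; ++py) {
              const int i0 = py * c.ph;
              for (int ii = i0; ii < i0 + c.ph; ++ii) {
                if (col[ii] > best[py]) {
                  best[py] = col[ii];
                  barg[py] = ii + coff;
                }
              }
            }
          }
          double* pcol = pooled.slice_colptr(k, px);
          for (int py = 0; py < d.poh; ++py) {
            pcol[py] = best[py];
            pidx(py + (uword)d.poh * px + (uword)d.poh * d.pow * k) =
              barg[py] + koff;
          }
        }
      }
    }
  }
  std::copy(ws.out[3].begin(), ws.out[3].end(), ws.flat.begin());
}

// Walks the stack top-down. The gradient w.r.t. input[cl] is written into
// ws.input[cl] itself: its forward values are no longer needed (the im2col
// buffers from the forward pass carry them), and its dimensions are exactly
// the pooled grid the next (lower) unpooling step expects.
void conv_backward(const Net& net, int br, const vec& dflat, ConvWS& ws,
                   std::vector<mat>& G, mat& dimg) {
  const Config& c = net.cfg;
  char buf[64];
  for (int cl = 3; cl >= 0; --cl) {
    const cube& ro = ws.out[cl];
    cube& dout = ws.dout_buf[cl];
    if (cl == 3) {
      std::copy(dflat.begin(), dflat.end(), dout.begin());
    } else {
      // unpool: ws.input[cl + 1] holds the gradient w.r.t. the pooled grid
      dout.zeros();
      const uvec& pidx = ws.pidx[cl];
      const cube& dpooled = ws.input[cl + 1];
      for (uword r = 0; r < pidx.n_elem; ++r) dout(pidx(r)) += dpooled(r);
    }
    // ReLU mask
    for (uword q = 0; q < dout.n_elem; ++q)
      if (ro(q) <= 0.0) dout(q) = 0.0;
    const int kh = (int)c.ks(cl, 0), kw = (int)c.ks(cl, 1);
    mat& dz = ws.dz[cl];
    std::copy(dout.begin(), dout.end(), dz.begin());
    snprintf(buf, sizeof buf, "conv%d_%d_W", br + 1, cl + 1);
    int iW = net.idx(buf);
    snprintf(buf, sizeof buf, "conv%d_%d_b", br + 1, cl + 1);
    int ib = net.idx(buf);
    G[iW] += ws.cols[cl].t() * dz;
    G[ib].row(0) += sum(dz, 0);
    mat dcols = dz * net.P[iW].t();
    ws.input[cl].zeros();
    col2im_add(dcols, kh, kw, ws.input[cl]);
    if (cl == 0) dimg = ws.input[0].slice(0);
  }
}

// ---- dense head + loss --------------------------------------------------

double bce(const rowvec& y, const rowvec& yhat) {
  const double eps = 1e-7;
  rowvec p = clamp(yhat, eps, 1.0 - eps);
  return -mean(y % log(p) + (1.0 - y) % log(1.0 - p));
}

// ---- batch forward/backward ---------------------------------------------

struct Workspaces {
  BlstmCache bc;
  ConvWS ws1, ws2;
  mat img1, dimg1, dimg2;
};

struct BatchResult {
  double loss_sum = 0.0;  // sum over examples of per-example BCE
  mat scores;             // batch x L
};

// One full batch: forward, and (when G != nullptr) backward with gradient
// accumulation (gradient of the SUM of per-example losses; caller divides).
// When img_store is non-null the BLSTM is frozen: its per-example state
// images (T x 2h slices) are read from the cache and no gradient flows
// into it.
BatchResult run_batch(const Net& net, const Rcpp::IntegerMatrix& idx,
                      const cube& pssm, const mat& Y, const uvec& rows,
                      Workspaces& wk, std::vector<mat>* G,
                      const cube* img_store = nullptr) {
  const Config& c = net.cfg;
  const int B = rows.n_elem, h = c.h, T = c.T;
  BatchResult res;
  res.scores.set_size(B, c.L);

  if (c.use_lstm && !img_store) blstm_forward_all(net, idx, rows, wk.bc);
  if (c.use_conv1 && !wk.ws1.ready) conv_ws_init(c, 2 * h, wk.ws1);
  if (c.use_conv2 && !wk.ws2.ready) conv_ws_init(c, 43, wk.ws2);

  mat dTop;
  if (G && c.use_lstm && !img_store) dTop.zeros(B * T, 2 * h);

  const bool hidden = c.dense_hidden > 0;
  int iW1 = -1, ib1 = -1, iW2 = -1, ib2 = -1, iWd = -1, ibd = -1;
  if (hidden) {
    iW1 = net.idx("dense1_W"); ib1 = net.idx("dense1_b");
    iW2 = net.idx("dense2_W"); ib2 = net.idx("dense2_b");
  } else {
    iWd = net.idx("dense_W"); ibd = net.idx("dense_b");
  }

  if (c.use_conv1) {
    wk.img1.set_size(T, 2 * h);
  }

  for (int b = 0; b < B; ++b) {
    // ---- features
    vec feat;
    if (c.variant == BLSTM) {
      feat.set_size(2 * h);
      if (img_store) {
        feat.subvec(0, h - 1) =
          img_store->slice(rows(b)).row(T - 1).cols(0, h - 1).t();
        feat.subvec(h, 2 * h - 1) =
          img_store->slice(rows(b)).row(0).cols(h, 2 * h - 1).t();
      } else {
        feat.subvec(0, h - 1) =
          wk.bc.top.row((T - 1) * B + b).cols(0, h - 1).t();
        feat.subvec(h, 2 * h - 1) =
          wk.bc.top.row(b).cols(h, 2 * h - 1).t();
      }
    } else {
      if (c.use_conv1) {
        if (img_store) {
          wk.img1 = img_store->slice(rows(b));
        } else {
          for (int t = 0; t < T; ++t)
            wk.img1.row(t) = wk.bc.top.row(b + B * t);
        }
        conv_forward(net, 0, wk.img1, wk.ws1);
      }
      if (c.use_conv2) {
        conv_forward(net, 1, pssm.slice(rows(b)), wk.ws2);
      }
      if (c.use_conv1 && c.use_conv2) {
        feat = join_cols(wk.ws1.flat, wk.ws2.flat);
      } else if (c.use_conv1) {
        feat = wk.ws1.flat;
      } else {
        feat = wk.ws2.flat;
      }
    }

    // ---- dense head
    rowvec logits, h1;
    if (hidden) {
      h1 = feat.t() * net.P[iW1] + net.P[ib1].row(0);
      h1.clamp(0.0, datum::inf);
      logits = h1 * net.P[iW2] + net.P[ib2].row(0);
    } else {
      logits = feat.t() * net.P[iWd] + net.P[ibd].row(0);
    }
    rowvec yhat = 1.0 / (1.0 + exp(-logits));
    res.scores.row(b) = yhat;

    const rowvec y = Y.row(rows(b));
    res.loss_sum += bce(y, yhat);

    if (!G) continue;

    // ---- backward
    rowvec dlog = (yhat - y) / (double)c.L;
    vec dfeat;
    if (hidden) {
      (*G)[iW2] += h1.t() * dlog;
      (*G)[ib2].row(0) += dlog;
      rowvec dh1 = dlog * net.P[iW2].t();
      for (uword q = 0; q < dh1.n_elem; ++q) if (h1(q) <= 0.0) dh1(q) = 0.0;
      (*G)[iW1] += feat * dh1;
      (*G)[ib1].row(0) += dh1;
      dfeat = net.P[iW1] * dh1.t();
    } else {
      (*G)[iWd] += feat * dlog;
      (*G)[ibd].row(0) += dlog;
      dfeat = net.P[iWd] * dlog.t();
    }

    if (c.variant == BLSTM) {
      if (!img_store) {
        dTop.row((T - 1) * B + b).cols(0, h - 1) +=
          dfeat.subvec(0, h - 1).t();
        dTop.row(b).cols(h, 2 * h - 1) += dfeat.subvec(h, 2 * h - 1).t();
      }
    } else {
      int off = 0;
      if (c.use_conv1) {
        const int n1 = wk.ws1.flat_size;
        conv_backward(net, 0, dfeat.subvec(0, n1 - 1), wk.ws1, *G, wk.dimg1);
        if (!img_store) {
          for (int t = 0; t < T; ++t) dTop.row(b + B * t) += wk.dimg1.row(t);
        }
        off = n1;
      }
      if (c.use_conv2) {
        conv_backward(net, 1, dfeat.subvec(off, dfeat.n_elem - 1), wk.ws2,
                      *G, wk.dimg2);  // PSSM input gradient discarded
      }
    }
  }

  if (G && c.use_lstm && !img_store)
    blstm_backward_all(net, idx, rows, wk.bc, dTop, *G);
  return res;
}

// Precompute the per-example BLSTM state images of a frozen encoder.
cube build_image_store(const Net& net, const Rcpp::IntegerMatrix& idx) {
  const Config& c = net.cfg;
  const int n = idx.nrow(), T = c.T, h = c.h;
  cube imgs(T, 2 * h, n);
  const int chunk = 128;
  BlstmCache bc;
  for (int s = 0; s < n; s += chunk) {
    const int e = std::min(n, s + chunk);
    uvec rows = regspace<uvec>(s, e - 1);
    const int B = rows.n_elem;
    blstm_forward_all(net, idx, rows, bc);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < T; ++t)
        imgs.slice(s + b).row(t) = bc.top.row(b + B * t);
  }
  return imgs;
}

double kernel_penalty(const Net& net) {
  double s = 0.0;
  for (size_t i = 0; i < net.names.size(); ++i)
    if (is_conv_kernel(net.names[i])) s += accu(square(net.P[i]));
  return s;
}

cube load_pssm(const Rcpp::NumericVector& pssm_arr, const Config& c, int n) {
  Rcpp::RObject dims = pssm_arr.attr("dim");
  Rcpp::IntegerVector d(dims);
  if (d.size() != 3 || d[0] != c.T || d[1] != 43 || d[2] != n)
    Rcpp::stop("PSSM array must be l_max x 43 x n");
  return cube(const_cast<double*>(pssm_arr.begin()), d[0], d[1], d[2],
              false, true);
}

}  // namespace

// ---- exported entry points ----------------------------------------------

// [[Rcpp::export(name = "net_predict")]]
arma::mat net_predict(Rcpp::List params, Rcpp::List cfg,
                      Rcpp::IntegerMatrix idx, Rcpp::NumericVector pssm_arr,
                      int batch_size) {
  Config c = parse_config(cfg);
  Net net = load_net(params, c);
  const int n = idx.nrow();
  cube pssm;
  if (c.use_conv2) pssm = load_pssm(pssm_arr, c, n);
  mat scores(n, c.L);
  mat Ydummy(n, c.L, fill::zeros);
  Workspaces wk;
  for (int s = 0; s < n; s += batch_size) {
    int e = std::min(n, s + batch_size);
    uvec rows = regspace<uvec>(s, e - 1);
    BatchResult br = run_batch(net, idx, pssm, Ydummy, rows, wk, nullptr);
    scores.rows(s, e - 1) = br.scores;
  }
  return scores;
}

// [[Rcpp::export(name = "net_blstm_forward")]]
arma::mat net_blstm_forward(Rcpp::List params, Rcpp::List cfg,
                            Rcpp::IntegerMatrix idx) {
  Config c = parse_config(cfg);
  Net net = load_net(params, c);
  uvec rows = {0};
  BlstmCache bc;
  blstm_forward_all(net, idx, rows, bc);
  mat out(c.T, 2 * c.h);
  for (int t = 0; t < c.T; ++t) out.row(t) = bc.top.row(t);  // B = 1
  return out;
}

// [[Rcpp::export(name = "net_loss_grads")]]
Rcpp::List net_loss_grads(Rcpp::List params, Rcpp::List cfg,
                          Rcpp::IntegerMatrix idx,
                          Rcpp::NumericVector pssm_arr,
                          Rcpp::NumericMatrix Ymat) {
  Config c = parse_config(cfg);
  Net net = load_net(params, c);
  const int n = idx.nrow();
  mat Y(Ymat.begin(), Ymat.nrow(), Ymat.ncol());
  cube pssm;
  if (c.use_conv2) pssm = load_pssm(pssm_arr, c, n);
  std::vector<mat> G;
  for (auto& p : net.P) G.push_back(mat(p.n_rows, p.n_cols, fill::zeros));
  uvec rows = regspace<uvec>(0, n - 1);
  Workspaces wk;
  BatchResult br = run_batch(net, idx, pssm, Y, rows, wk, &G);
  double loss = br.loss_sum / n + c.lambda * kernel_penalty(net);
  Rcpp::List gout;
  for (size_t i = 0; i < net.names.size(); ++i) {
    mat g = G[i] / (double)n;
    if (is_conv_kernel(net.names[i])) g += 2.0 * c.lambda * net.P[i];
    Rcpp::NumericMatrix rm(g.n_rows, g.n_cols);
    std::copy(g.begin(), g.end(), rm.begin());
    gout[net.names[i]] = rm;
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = gout);
}

// [[Rcpp::export(name = "net_train")]]
Rcpp::List net_train(Rcpp::List params, Rcpp::List cfg,
                     Rcpp::IntegerMatrix idx, Rcpp::NumericVector pssm_arr,
                     Rcpp::NumericMatrix Ymat, Rcpp::List tcfg,
                     Rcpp::IntegerMatrix orders) {
  Config c = parse_config(cfg);
  Net net = load_net(params, c);
  const int n = idx.nrow();
  mat Y(Ymat.begin(), Ymat.nrow(), Ymat.ncol());
  cube pssm;
  if (c.use_conv2) pssm = load_pssm(pssm_arr, c, n);
  const int epochs = Rcpp::as<int>(tcfg["epochs"]);
  const int batch = Rcpp::as<int>(tcfg["batch_size"]);
  const double lr = Rcpp::as<double>(tcfg["learning_rate"]);
  const double beta1 = Rcpp::as<double>(tcfg["beta1"]);
  const double beta2 = Rcpp::as<double>(tcfg["beta2"]);
  const double adam_eps = Rcpp::as<double>(tcfg["adam_eps"]);
  const double clip = Rcpp::as<double>(tcfg["clip_norm"]);
  const int patience = Rcpp::as<int>(tcfg["patience"]);  // 0 = off

  // frozen parameters: excluded from updates; if every LSTM parameter is
  // frozen the encoder's images are computed once and cached
  std::vector<bool> frozen(net.P.size(), false);
  std::vector<std::string> freeze_names =
    Rcpp::as<std::vector<std::string>>(tcfg["freeze"]);
  for (const auto& nm : freeze_names) frozen[net.idx(nm)] = true;
  bool freeze_lstm = c.use_lstm;
  for (size_t i = 0; i < net.names.size(); ++i)
    if (net.names[i].rfind("lstm", 0) == 0 && !frozen[i]) freeze_lstm = false;
  cube img_store;
  if (freeze_lstm && c.use_lstm) img_store = build_image_store(net, idx);
  const cube* imgp = (freeze_lstm && c.use_lstm) ? &img_store : nullptr;

  std::vector<mat> M, V, G;
  for (auto& p : net.P) {
    M.push_back(mat(p.n_rows, p.n_cols, fill::zeros));
    V.push_back(mat(p.n_rows, p.n_cols, fill::zeros));
    G.push_back(mat(p.n_rows, p.n_cols, fill::zeros));
  }
  Workspaces wk;
  vec history(epochs);
  long step = 0;
  int done = 0;
  double best = datum::inf;
  int best_e = -1;
  for (int e = 0; e < epochs; ++e) {
    double epoch_bce = 0.0;
    double penalty_acc = 0.0;
    int nb = 0;
    for (int s = 0; s < n; s += batch) {
      int en = std::min(n, s + batch);
      uvec rows(en - s);
      for (int q = s; q < en; ++q) rows(q - s) = orders(e, q) - 1;
      for (auto& g : G) g.zeros();
      BatchResult br = run_batch(net, idx, pssm, Y, rows, wk, &G, imgp);
      epoch_bce += br.loss_sum;
      penalty_acc += kernel_penalty(net);
      ++nb;
      const double bsz = (double)rows.n_elem;
      double norm2 = 0.0;
      for (size_t i = 0; i < G.size(); ++i) {
        if (frozen[i]) { G[i].zeros(); continue; }
        G[i] /= bsz;
        if (is_conv_kernel(net.names[i])) G[i] += 2.0 * c.lambda * net.P[i];
        norm2 += accu(square(G[i]));
      }
      if (clip > 0.0) {
        double norm = std::sqrt(norm2);
        if (norm > clip)
          for (auto& g : G) g *= clip / norm;
      }
      ++step;
      const double bc1 = 1.0 - std::pow(beta1, (double)step);
      const double bc2 = 1.0 - std::pow(beta2, (double)step);
      for (size_t i = 0; i < G.size(); ++i) {
        if (frozen[i]) continue;
        M[i] = beta1 * M[i] + (1.0 - beta1) * G[i];
        V[i] = beta2 * V[i] + (1.0 - beta2) * square(G[i]);
        net.P[i] -= lr * (M[i] / bc1) / (sqrt(V[i] / bc2) + adam_eps);
      }
    }
    history(e) = epoch_bce / n + c.lambda * penalty_acc / std::max(nb, 1);
    if (!std::isfinite(history(e)))
      Rcpp::stop("training loss diverged (non-finite) at epoch %d", e + 1);
    done = e + 1;
    if (patience > 0) {
      if (history(e) < best - 1e-12) { best = history(e); best_e = e; }
      else if (e - best_e >= patience) break;
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("params") = dump_params(net),
    Rcpp::Named("history") = Rcpp::NumericVector(history.begin(),
                                                 history.begin() + done));
}
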