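// Compact 2D U-Net: encoder-decoder with skip connections, trained with
// RMSprop on weighted binary cross-entropy. Activations are stored
// channels-first as (channels x H*W) matrices (pixels in R's column-major
// plane order), so im2col gathers and their backward scatters move
// contiguous channel blocks and each convolution is a single GEMM.
#include <RcppArmadillo.h>
#include <random>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct ConvLayer {
  int k = 3, cin = 0, cout = 0;
  fmat W;      // cout x (k*k*cin), column blocks by kernel offset
  fvec b;
  fmat gW; fvec gb;   // gradient accumulators
  fmat mW; fvec mb;   // RMSprop second-moment caches
};

struct UpLayer {
  int cin = 0, cout = 0;
  fmat W;      // (4*cout) x cin, row blocks by 2x2 offset
  fvec b;
  fmat gW; fvec gb;
  fmat mW; fvec mb;
};

// Precomputed index maps for a batch of B planes of one (H, W) size,
// laid out consecutively along the pixel axis.
struct Grid {
  int H = 0, W = 0, B = 1;
  umat im2col;                  // npix x 9; value npix flags zero padding
  std::vector<uvec> pool_child; // 4 vectors, each npix/4 (H, W even only)
  std::vector<uvec> up_out;     // 4 vectors, each npix, targets in 2H x 2W
};

inline void relu_inplace(fmat& Z) {
  for (auto& z : Z) if (z < 0.0f) z = 0.0f;
}

class Unet2D {
public:
  int cin, f0, levels, fmax;
  double rho = 0.9, eps = 1e-7;
  std::vector<ConvLayer> enc;   // 2 per level then 2 bottleneck convs
  std::vector<UpLayer> ups;     // decoder, deepest level first
  std::vector<ConvLayer> dec;   // 2 per decoder level, same order as ups
  ConvLayer fin;                // 1x1 conv to a single logit map

  Unet2D(int cin_, int f0_, int levels_, int fmax_, int seed) :
    cin(cin_), f0(f0_), levels(levels_), fmax(fmax_) {
    std::mt19937 rng(static_cast<uint32_t>(seed));
    int c_prev = cin;
    for (int l = 0; l < levels; ++l) {
      int f = filters(l);
      enc.push_back(make_conv(3, c_prev, f, rng));
      enc.push_back(make_conv(3, f, f, rng));
      c_prev = f;
    }
    int fb = filters(levels);
    enc.push_back(make_conv(3, c_prev, fb, rng));
    enc.push_back(make_conv(3, fb, fb, rng));
    c_prev = fb;
    for (int l = levels - 1; l >= 0; --l) {
      int f = filters(l);
      ups.push_back(make_up(c_prev, f, rng));
      dec.push_back(make_conv(3, 2 * f, f, rng));
      dec.push_back(make_conv(3, f, f, rng));
      c_prev = f;
    }
    fin = make_conv(1, c_prev, 1, rng);
  }

  int filters(int level) const {
    double f = f0 * std::pow(2.0, level);
    return static_cast<int>(std::min(f, static_cast<double>(fmax)));
  }

  long n_params() const {
    long n = 0;
    for (const auto& L : enc) n += L.W.n_elem + L.b.n_elem;
    for (const auto& L : ups) n += L.W.n_elem + L.b.n_elem;
    for (const auto& L : dec) n += L.W.n_elem + L.b.n_elem;
    n += fin.W.n_elem + fin.b.n_elem;
    return n;
  }

  const Grid& grid(int H, int W, int B) {
    long key = (static_cast<long>(H) * 100000L + W) * 1024L + B;
    auto it = grids_.find(key);
    if (it != grids_.end()) return it->second;
    Grid g; g.H = H; g.W = W; g.B = B;
    int npix = H * W;
    uword npixB = static_cast<uword>(npix) * B;
    g.im2col.set_size(npixB, 9);
    for (int b = 0; b < B; ++b)
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r) {
          uword p = static_cast<uword>(b) * npix + r + c * H;
          int o = 0;
          for (int dr = -1; dr <= 1; ++dr)
            for (int dc = -1; dc <= 1; ++dc) {
              int rr = r + dr, cc = c + dc;
              g.im2col(p, o++) = (rr < 0 || rr >= H || cc < 0 || cc >= W)
                ? npixB
                : static_cast<uword>(b) * npix + rr + cc * H;
            }
        }
    if (H % 2 == 0 && W % 2 == 0) {
      int Ho = H / 2, Wo = W / 2, npo = Ho * Wo;
      for (int a = 0; a < 2; ++a)
        for (int bq = 0; bq < 2; ++bq) {
          uvec v(static_cast<uword>(npo) * B);
          for (int b = 0; b < B; ++b)
            for (int c = 0; c < Wo; ++c)
              for (int r = 0; r < Ho; ++r)
                v(static_cast<uword>(b) * npo + r + c * Ho) =
                  static_cast<uword>(b) * npix + (2 * r + a) + (2 * c + bq) * H;
          g.pool_child.push_back(v);
        }
    }
    for (int a = 0; a < 2; ++a)
      for (int bq = 0; bq < 2; ++bq) {
        uvec v(npixB);
        for (int b = 0; b < B; ++b)
          for (int c = 0; c < W; ++c)
            for (int r = 0; r < H; ++r)
              v(static_cast<uword>(b) * npix + r + c * H) =
                static_cast<uword>(b) * 4 * npix +
                (2 * r + a) + (2 * c + bq) * (2 * H);
        g.up_out.push_back(v);
      }
    return grids_.emplace(key, std::move(g)).first->second;
  }

  // ---- per-sample forward state ----------------------------------------
  struct WS {
    std::vector<fmat> enc_col, enc_Y;
    std::vector<umat> pool_arg;          // chosen input pixel per (ch, outpix)
    std::vector<int> pool_npix_in;
    std::vector<fmat> up_A, up_Y;
    std::vector<fmat> dec_col, dec_Y;
    std::vector<fmat> skips;
    std::vector<std::pair<int, int>> dims_enc;  // (H, W) entering each level
    fmat fin_in;
    frowvec logits, probs;
    int H0 = 0, W0 = 0, B = 1;
  };

  frowvec forward(const fmat& X, int H, int W, int B, WS& ws) {
    ws.H0 = H; ws.W0 = W; ws.B = B;
    fmat A = X;                 // cin x (B * npix)
    int h = H, w = W;
    for (int l = 0; l < levels; ++l) {
      const Grid& g = grid(h, w, B);
      ws.dims_enc.push_back({h, w});
      A = conv_fwd(enc[2 * l], A, g, ws.enc_col, ws.enc_Y, true);
      A = conv_fwd(enc[2 * l + 1], A, g, ws.enc_col, ws.enc_Y, true);
      ws.skips.push_back(A);
      A = pool_fwd(A, g, ws);
      h /= 2; w /= 2;
    }
    const Grid& gb = grid(h, w, B);
    A = conv_fwd(enc[2 * levels], A, gb, ws.enc_col, ws.enc_Y, true);
    A = conv_fwd(enc[2 * levels + 1], A, gb, ws.enc_col, ws.enc_Y, true);
    for (int i = 0; i < levels; ++i) {
      const Grid& gin = grid(h, w, B);
      A = up_fwd(ups[i], A, gin, ws);
      h *= 2; w *= 2;
      const Grid& gout = grid(h, w, B);
      int l = levels - 1 - i;
      A = join_cols(A, ws.skips[l]);   // stack channels: [up; skip]
      A = conv_fwd(dec[2 * i], A, gout, ws.dec_col, ws.dec_Y, true);
      A = conv_fwd(dec[2 * i + 1], A, gout, ws.dec_col, ws.dec_Y, true);
    }
    ws.fin_in = A;
    ws.logits = fin.W * A + fin.b(0);
    ws.probs = 1.0 / (1.0 + exp(-ws.logits));
    return ws.probs;
  }

  // dlogit: gradient of the batch loss w.r.t. the logits of this sample.
  void backward(const frowvec& dlogit, WS& ws) {
    fin.gW += dlogit * ws.fin_in.t();
    fin.gb(0) += accu(dlogit);
    fmat dA = fin.W.t() * dlogit;       // f0 x (B * npix)
    int h = ws.H0, w = ws.W0;
    int B = ws.B;
    std::vector<fmat> dskip(levels);
    for (int i = levels - 1; i >= 0; --i) {
      const Grid& gout = grid(h, w, B);
      dA = conv_bwd(dec[2 * i + 1], ws.dec_col[2 * i + 1], ws.dec_Y[2 * i + 1],
                    dA, gout, true);
      dA = conv_bwd(dec[2 * i], ws.dec_col[2 * i], ws.dec_Y[2 * i],
                    dA, gout, true);
      int l = levels - 1 - i;
      int f = ups[i].cout;
      fmat dUp = dA.rows(0, f - 1);
      dskip[l] = dA.rows(f, dA.n_rows - 1);
      h /= 2; w /= 2;
      const Grid& gin = grid(h, w, B);
      dA = up_bwd(ups[i], ws.up_A[i], ws.up_Y[i], dUp, gin);
    }
    const Grid& gb = grid(h, w, B);
    dA = conv_bwd(enc[2 * levels + 1], ws.enc_col[2 * levels + 1],
                  ws.enc_Y[2 * levels + 1], dA, gb, true);
    dA = conv_bwd(enc[2 * levels], ws.enc_col[2 * levels],
                  ws.enc_Y[2 * levels], dA, gb, true);
    for (int l = levels - 1; l >= 0; --l) {
      int H = ws.dims_enc[l].first, W = ws.dims_enc[l].second;
      const Grid& g = grid(H, W, B);
      fmat dPool = pool_bwd(dA, ws.pool_arg[l], ws.pool_npix_in[l]);
      dPool += dskip[l];
      dA = conv_bwd(enc[2 * l + 1], ws.enc_col[2 * l + 1],
                    ws.enc_Y[2 * l + 1], dPool, g, true);
      dA = conv_bwd(enc[2 * l], ws.enc_col[2 * l], ws.enc_Y[2 * l],
                    dA, g, l > 0);
    }
  }

  void zero_grads() {
    auto zc = [](ConvLayer& L) { L.gW.zeros(); L.gb.zeros(); };
    for (auto& L : enc) zc(L);
    for (auto& L : dec) zc(L);
    for (auto& L : ups) { L.gW.zeros(); L.gb.zeros(); }
    zc(fin);
  }

  void rmsprop_step(double lr) {
    float r = static_cast<float>(rho), e = static_cast<float>(eps);
    float lrf = static_cast<float>(lr);
    auto upd = [&](fmat& W, fmat& g, fmat& m) {
      m = r * m + (1.0f - r) * square(g);
      W -= lrf * g / (sqrt(m) + e);
    };
    auto updb = [&](fvec& b, fvec& g, fvec& m) {
      m = r * m + (1.0f - r) * square(g);
      b -= lrf * g / (sqrt(m) + e);
    };
    for (auto& L : enc) { upd(L.W, L.gW, L.mW); updb(L.b, L.gb, L.mb); }
    for (auto& L : ups) { upd(L.W, L.gW, L.mW); updb(L.b, L.gb, L.mb); }
    for (auto& L : dec) { upd(L.W, L.gW, L.mW); updb(L.b, L.gb, L.mb); }
    upd(fin.W, fin.gW, fin.mW); updb(fin.b, fin.gb, fin.mb);
  }

  Rcpp::List export_weights() const {
    Rcpp::List out;
    auto push = [&](const fmat& W, const fvec& b) {
      out.push_back(Rcpp::NumericVector(W.begin(), W.end()));
      out.push_back(Rcpp::NumericVector(b.begin(), b.end()));
    };
    for (const auto& L : enc) push(L.W, L.b);
    for (size_t i = 0; i < ups.size(); ++i) {
      push(ups[i].W, ups[i].b);
      push(dec[2 * i].W, dec[2 * i].b);
      push(dec[2 * i + 1].W, dec[2 * i + 1].b);
    }
    push(fin.W, fin.b);
    return out;
  }

  Rcpp::List export_grads() const {
    Rcpp::List out;
    auto push = [&](const fmat& W, const fvec& b) {
      out.push_back(Rcpp::NumericVector(W.begin(), W.end()));
      out.push_back(Rcpp::NumericVector(b.begin(), b.end()));
    };
    for (const auto& L : enc) push(L.gW, L.gb);
    for (size_t i = 0; i < ups.size(); ++i) {
      push(ups[i].gW, ups[i].gb);
      push(dec[2 * i].gW, dec[2 * i].gb);
      push(dec[2 * i + 1].gW, dec[2 * i + 1].gb);
    }
    push(fin.gW, fin.gb);
    return out;
  }

  void import_weights(const Rcpp::List& wl) {
    size_t j = 0;
    auto pull = [&](fmat& W, fvec& b) {
      Rcpp::NumericVector vw = wl[j++], vb = wl[j++];
      if (static_cast<uword>(vw.size()) != W.n_elem ||
          static_cast<uword>(vb.size()) != b.n_elem)
        Rcpp::stop("weight vector length mismatch");
      std::copy(vw.begin(), vw.end(), W.begin());
      std::copy(vb.begin(), vb.end(), b.begin());
    };
    for (auto& L : enc) pull(L.W, L.b);
    for (size_t i = 0; i < ups.size(); ++i) {
      pull(ups[i].W, ups[i].b);
      pull(dec[2 * i].W, dec[2 * i].b);
      pull(dec[2 * i + 1].W, dec[2 * i + 1].b);
    }
    pull(fin.W, fin.b);
  }

private:
  std::unordered_map<long, Grid> grids_;

  static double glorot_limit(int fan_in, int fan_out) {
    return std::sqrt(6.0 / (fan_in + fan_out));
  }

  ConvLayer make_conv(int k, int ci, int co, std::mt19937& rng) {
    ConvLayer L; L.k = k; L.cin = ci; L.cout = co;
    L.W.set_size(co, k * k * ci);
    double lim = glorot_limit(k * k * ci, k * k * co);
    std::uniform_real_distribution<double> u(-lim, lim);
    for (auto& w : L.W) w = static_cast<float>(u(rng));
    L.b.zeros(co);
    L.gW.zeros(size(L.W)); L.gb.zeros(co);
    L.mW.zeros(size(L.W)); L.mb.zeros(co);
    return L;
  }

  UpLayer make_up(int ci, int co, std::mt19937& rng) {
    UpLayer L; L.cin = ci; L.cout = co;
    L.W.set_size(4 * co, ci);
    double lim = glorot_limit(4 * ci, 4 * co);
    std::uniform_real_distribution<double> u(-lim, lim);
    for (auto& w : L.W) w = static_cast<float>(u(rng));
    L.b.zeros(co);
    L.gW.zeros(size(L.W)); L.gb.zeros(co);
    L.mW.zeros(size(L.W)); L.mb.zeros(co);
    return L;
  }

  fmat conv_fwd(ConvLayer& L, const fmat& A, const Grid& g,
               std::vector<fmat>& cols, std::vector<fmat>& Ys, bool relu) {
    uword npix = A.n_cols;
    fmat col;
    if (L.k == 1) {
      col = A;
    } else {
      fmat Aext(L.cin, npix + 1);
      Aext.head_cols(npix) = A;
      Aext.col(npix).zeros();
      col.set_size(9 * L.cin, npix);
      for (int o = 0; o < 9; ++o) {
        const float* src = Aext.memptr();
        float* dst = col.memptr() + o * L.cin;
        const uword* idx = g.im2col.colptr(o);
        for (uword p = 0; p < npix; ++p)
          std::memcpy(dst + p * 9 * L.cin, src + idx[p] * L.cin,
                      L.cin * sizeof(float));
      }
    }
    fmat Z = L.W * col;
    Z.each_col() += L.b;
    if (relu) relu_inplace(Z);
    cols.push_back(std::move(col));
    Ys.push_back(Z);
    return Z;
  }

  fmat conv_bwd(ConvLayer& L, const fmat& col, const fmat& Y, const fmat& dYin,
               const Grid& g, bool need_dA) {
    fmat dZ = dYin;
    {
      const float* y = Y.memptr();
      float* z = dZ.memptr();
      for (uword i = 0; i < dZ.n_elem; ++i) if (y[i] <= 0.0f) z[i] = 0.0f;
    }
    L.gW += dZ * col.t();
    L.gb += sum(dZ, 1);
    if (!need_dA) return fmat();
    fmat dcol = L.W.t() * dZ;           // (k*k*cin) x npix
    if (L.k == 1) return dcol;
    uword npix = dZ.n_cols;
    fmat dAext(L.cin, npix + 1, fill::zeros);
    for (int o = 0; o < 9; ++o) {
      float* dst = dAext.memptr();
      const float* src = dcol.memptr() + o * L.cin;
      const uword* idx = g.im2col.colptr(o);
      for (uword p = 0; p < npix; ++p) {
        float* d = dst + idx[p] * L.cin;
        const float* s = src + p * 9 * L.cin;
        for (int c = 0; c < L.cin; ++c) d[c] += s[c];
      }
    }
    return dAext.head_cols(npix);
  }

  fmat pool_fwd(const fmat& A, const Grid& g, WS& ws) {
    uword npo = A.n_cols / 4;
    uword ch = A.n_rows;
    fmat Y(ch, npo);
    umat arg(ch, npo);
    for (uword p = 0; p < npo; ++p) {
      uword q0 = g.pool_child[0](p);
      float* y = Y.colptr(p);
      uword* a = arg.colptr(p);
      const float* c0 = A.colptr(q0);
      for (uword c = 0; c < ch; ++c) { y[c] = c0[c]; a[c] = q0; }
      for (int j = 1; j < 4; ++j) {
        uword qj = g.pool_child[j](p);
        const float* cj = A.colptr(qj);
        for (uword c = 0; c < ch; ++c)
          if (cj[c] > y[c]) { y[c] = cj[c]; a[c] = qj; }
      }
    }
    ws.pool_arg.push_back(std::move(arg));
    ws.pool_npix_in.push_back(A.n_cols);
    return Y;
  }

  static fmat pool_bwd(const fmat& dY, const umat& arg, int npix_in) {
    uword ch = dY.n_rows;
    fmat dA(ch, npix_in, fill::zeros);
    for (uword p = 0; p < dY.n_cols; ++p) {
      const float* dy = dY.colptr(p);
      const uword* a = arg.colptr(p);
      for (uword c = 0; c < ch; ++c) dA(c, a[c]) += dy[c];
    }
    return dA;
  }

  fmat up_fwd(UpLayer& L, const fmat& A, const Grid& gin, WS& ws) {
    uword npix = A.n_cols;
    fmat M = L.W * A;                        // (4*cout) x npix
    fmat Y(L.cout, 4 * npix);
    for (int o = 0; o < 4; ++o)
      Y.cols(gin.up_out[o]) = M.rows(o * L.cout, (o + 1) * L.cout - 1);
    Y.each_col() += L.b;
    relu_inplace(Y);
    ws.up_A.push_back(A);
    ws.up_Y.push_back(Y);
    return Y;
  }

  fmat up_bwd(UpLayer& L, const fmat& A, const fmat& Y, const fmat& dYin,
             const Grid& gin) {
    fmat dZ = dYin;
    {
      const float* y = Y.memptr();
      float* z = dZ.memptr();
      for (uword i = 0; i < dZ.n_elem; ++i) if (y[i] <= 0.0f) z[i] = 0.0f;
    }
    L.gb += sum(dZ, 1);
    uword npix = A.n_cols;
    fmat dM(4 * L.cout, npix);
    for (int o = 0; o < 4; ++o)
      dM.rows(o * L.cout, (o + 1) * L.cout - 1) = dZ.cols(gin.up_out[o]);
    L.gW += dM * A.t();
    return L.W.t() * dM;
  }
};

const float FCLIP = 1e-7f;

} // namespace

// [[Rcpp::export(name = ".unet2d_create")]]
SEXP unet2d_create(int in_channels, int base_filters, int levels,
                   int max_filters, int seed) {
  Rcpp::XPtr<Unet2D> p(new Unet2D(in_channels, base_filters, levels,
                                  max_filters, seed), true);
  return p;
}

// [[Rcpp::export(name = ".unet2d_n_params")]]
double unet2d_n_params(SEXP ptr) {
  Rcpp::XPtr<Unet2D> m(ptr);
  return static_cast<double>(m->n_params());
}

namespace {

// All slices of a batch must share one geometry; they are then laid out
// side by side along the pixel axis so the whole batch is one forward pass.
void batch_dims(const Rcpp::List& xs, int cin, int& H, int& W, int& C) {
  for (int i = 0; i < xs.size(); ++i) {
    Rcpp::NumericVector x = xs[i];
    Rcpp::IntegerVector d = x.attr("dim");
    int h = d[0], w = d[1], c = d.size() == 3 ? d[2] : 1;
    if (i == 0) { H = h; W = w; C = c; }
    else if (h != H || w != W || c != C)
      Rcpp::stop("all slices in a batch must share the same (y, x, c) shape");
  }
  if (C != cin)
    Rcpp::stop("slices have %d channels, model expects %d", C, cin);
}

// Chunk [i0, i1) of the slice list, channels-first single precision.
fmat concat_chunk(const Rcpp::List& xs, int i0, int i1, int H, int W, int C) {
  int npix = H * W;
  fmat X(C, static_cast<uword>(npix) * (i1 - i0));
  for (int i = i0; i < i1; ++i) {
    Rcpp::NumericVector x = xs[i];
    const double* src = x.begin();
    float* dst = X.memptr() + static_cast<size_t>(i - i0) * npix * C;
    for (int p = 0; p < npix; ++p)
      for (int c = 0; c < C; ++c)
        dst[static_cast<size_t>(p) * C + c] =
          static_cast<float>(src[static_cast<size_t>(c) * npix + p]);
  }
  return X;
}

// Samples per forward pass. One sample at a time keeps every layer's
// activations and im2col buffers cache-resident, which benchmarks faster
// here than wider fused batches; gradients still accumulate over the whole
// mini-batch before the optimiser step.
const int CHUNK = 1;

} // namespace

// [[Rcpp::export(name = ".unet2d_predict")]]
Rcpp::List unet2d_predict(SEXP ptr, Rcpp::List xs) {
  Rcpp::XPtr<Unet2D> m(ptr);
  int n = xs.size();
  if (n == 0) return Rcpp::List();
  int H, W, C;
  batch_dims(xs, m->cin, H, W, C);
  int npix = H * W;
  Rcpp::List out(n);
  for (int i0 = 0; i0 < n; i0 += CHUNK) {
    int i1 = std::min(n, i0 + CHUNK);
    fmat X = concat_chunk(xs, i0, i1, H, W, C);
    Unet2D::WS ws;
    frowvec p = m->forward(X, H, W, i1 - i0, ws);
    for (int i = i0; i < i1; ++i) {
      Rcpp::NumericMatrix pm(H, W);
      const float* pp = p.memptr() + static_cast<size_t>(i - i0) * npix;
      for (int q = 0; q < npix; ++q) pm[q] = pp[q];
      out[i] = pm;
    }
  }
  return out;
}

// Forward + backward over one mini-batch, then one RMSprop update.
// Returns the weight-normalised BCE of the batch (before the update).
// [[Rcpp::export(name = ".unet2d_train_batch")]]
double unet2d_train_batch(SEXP ptr, Rcpp::List xs, Rcpp::List ys,
                          Rcpp::NumericVector w, double lr) {
  Rcpp::XPtr<Unet2D> m(ptr);
  int n = xs.size();
  if (ys.size() != n || w.size() != n)
    Rcpp::stop("batch images, masks and weights must have equal length");
  int H, W, C;
  batch_dims(xs, m->cin, H, W, C);
  int npix = H * W;
  double den = 0.0;
  for (int i = 0; i < n; ++i) den += w[i] * npix;
  if (den <= 0) Rcpp::stop("batch has zero total weight");
  m->zero_grads();
  double num = 0.0;
  for (int i0 = 0; i0 < n; i0 += CHUNK) {
    int i1 = std::min(n, i0 + CHUNK);
    int nc = i1 - i0;
    fmat X = concat_chunk(xs, i0, i1, H, W, C);
    frowvec y(static_cast<uword>(npix) * nc), wpix(static_cast<uword>(npix) * nc);
    for (int i = i0; i < i1; ++i) {
      Rcpp::NumericVector yv = ys[i];
      if (yv.size() != npix) Rcpp::stop("mask size does not match image size");
      float* yd = y.memptr() + static_cast<size_t>(i - i0) * npix;
      for (int q = 0; q < npix; ++q) yd[q] = static_cast<float>(yv[q]);
      wpix.subvec(static_cast<uword>(i - i0) * npix,
                  static_cast<uword>(i - i0 + 1) * npix - 1)
          .fill(static_cast<float>(w[i]));
    }
    Unet2D::WS ws;
    frowvec p = m->forward(X, H, W, nc, ws);
    frowvec pc = clamp(p, FCLIP, 1.0f - FCLIP);
    num += accu(wpix % -(y % log(pc) + (1.0f - y) % log(1.0f - pc)));
    frowvec dlogit = (wpix / static_cast<float>(den)) % (p - y);
    m->backward(dlogit, ws);
  }
  double loss = num / den;
  if (!std::isfinite(loss)) Rcpp::stop("training loss is not finite");
  m->rmsprop_step(lr);
  return loss;
}

// [[Rcpp::export(name = ".unet2d_eval_batch")]]
double unet2d_eval_batch(SEXP ptr, Rcpp::List xs, Rcpp::List ys,
                         Rcpp::NumericVector w) {
  Rcpp::XPtr<Unet2D> m(ptr);
  int n = xs.size();
  if (n == 0) Rcpp::stop("evaluation pool is empty");
  int H, W, C;
  batch_dims(xs, m->cin, H, W, C);
  int npix = H * W;
  double num = 0.0, den = 0.0;
  for (int i0 = 0; i0 < n; i0 += CHUNK) {
    int i1 = std::min(n, i0 + CHUNK);
    int nc = i1 - i0;
    fmat X = concat_chunk(xs, i0, i1, H, W, C);
    frowvec y(static_cast<uword>(npix) * nc), wpix(static_cast<uword>(npix) * nc);
    for (int i = i0; i < i1; ++i) {
      Rcpp::NumericVector yv = ys[i];
      if (yv.size() != npix) Rcpp::stop("mask size does not match image size");
      float* yd = y.memptr() + static_cast<size_t>(i - i0) * npix;
      for (int q = 0; q < npix; ++q) yd[q] = static_cast<float>(yv[q]);
      wpix.subvec(static_cast<uword>(i - i0) * npix,
                  static_cast<uword>(i - i0 + 1) * npix - 1)
          .fill(static_cast<float>(w[i]));
      den += w[i] * npix;
    }
    Unet2D::WS ws;
    frowvec p = m->forward(X, H, W, nc, ws);
    frowvec pc = clamp(p, FCLIP, 1.0f - FCLIP);
    num += accu(wpix % -(y % log(pc) + (1.0f - y) % log(1.0f - pc)));
  }
  if (den <= 0) Rcpp::stop("evaluation pool has zero total weight");
  return num / den;
}

// Accumulated mini-batch gradients without an optimiser step (testing aid:
// lets the analytic gradients be checked against finite differences).
// [[Rcpp::export(name = ".unet2d_gradients")]]
Rcpp::List unet2d_gradients(SEXP ptr, Rcpp::List xs, Rcpp::List ys,
                            Rcpp::NumericVector w) {
  Rcpp::XPtr<Unet2D> m(ptr);
  int n = xs.size();
  int H, W, C;
  batch_dims(xs, m->cin, H, W, C);
  int npix = H * W;
  double den = 0.0;
  for (int i = 0; i < n; ++i) den += w[i] * npix;
  m->zero_grads();
  for (int i = 0; i < n; ++i) {
    fmat X = concat_chunk(xs, i, i + 1, H, W, C);
    Rcpp::NumericVector yv = ys[i];
    frowvec y(npix);
    for (int q = 0; q < npix; ++q) y(q) = static_cast<float>(yv[q]);
    Unet2D::WS ws;
    frowvec p = m->forward(X, H, W, 1, ws);
    frowvec dlogit = (static_cast<float>(w[i] / den)) * (p - y);
    m->backward(dlogit, ws);
  }
  return m->export_grads();
}

// [[Rcpp::export(name = ".unet2d_get_weights")]]
Rcpp::List unet2d_get_weights(SEXP ptr) {
  Rcpp::XPtr<Unet2D> m(ptr);
  return m->export_weights();
}

// [[Rcpp::export(name = ".unet2d_set_weights")]]
void unet2d_set_weights(SEXP ptr, Rcpp::List weights) {
  Rcpp::XPtr<Unet2D> m(ptr);
  m->import_weights(weights);
}
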