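// U-Net style encoder-decoder with 3x3 "same" convolutions, 2x2 average
// pooling, nearest-neighbour upsampling with skip concatenation, a 1x1
// sigmoid head, and Adam optimisation of the binary focal loss.
//
// The network is parameterised by a widths vector w[0..L] (L encoder levels
// plus the bottleneck) and trains whole images (no patching). Everything is
// deterministic given the seed: initialisation, shuffling and flip
// augmentation all draw from one std::mt19937.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;

static const double PROB_EPS = 1e-7;
static const double RELU_SLOPE = 0.1;  // leaky ReLU

// ---------------------------------------------------------------------------
// im2col / col2im for 3x3 kernels with zero padding 1
// ---------------------------------------------------------------------------

static mat im2col3(const cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  mat M(H * W, C * 9, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& S = X.slice(c);
    int k = 0;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int col = c * 9 + k;
        ++k;
        double* Mcol = M.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          const double* Scol = S.colptr(js);
          const int i0 = std::max(0, -di);
          const int i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i) Mcol[i + j * H] = Scol[i + di];
        }
      }
    }
  }
  return M;
}

static cube col2im3(const mat& dM, int H, int W, int C) {
  cube dX(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& S = dX.slice(c);
    int k = 0;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int col = c * 9 + k;
        ++k;
        const double* Mcol = dM.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          double* Scol = S.colptr(js);
          const int i0 = std::max(0, -di);
          const int i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i) Scol[i + di] += Mcol[i + j * H];
        }
      }
    }
  }
  return dX;
}

static cube mat2cube(const mat& Y, int H, int W, int C) {
  cube out(H, W, C);
  for (int c = 0; c < C; ++c)
    out.slice(c) = reshape(Y.col(c), H, W);
  return out;
}

static mat cube2mat(const cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  mat M(H * W, C);
  for (int c = 0; c < C; ++c) M.col(c) = vectorise(X.slice(c));
  return M;
}

// ---------------------------------------------------------------------------
// pooling / upsampling
// ---------------------------------------------------------------------------

static cube avgpool2(const cube& X) {
  const int H = X.n_rows / 2, W = X.n_cols / 2, C = X.n_slices;
  cube P(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        P(i, j, c) = 0.25 * (X(2 * i, 2 * j, c) + X(2 * i + 1, 2 * j, c) +
                             X(2 * i, 2 * j + 1, c) + X(2 * i + 1, 2 * j + 1, c));
  return P;
}

static cube avgpool2_back(const cube& dP) {
  const int H = dP.n_rows * 2, W = dP.n_cols * 2, C = dP.n_slices;
  cube dX(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < (int)dP.n_cols; ++j)
      for (int i = 0; i < (int)dP.n_rows; ++i) {
        const double g = 0.25 * dP(i, j, c);
        dX(2 * i, 2 * j, c) = g;
        dX(2 * i + 1, 2 * j, c) = g;
        dX(2 * i, 2 * j + 1, c) = g;
        dX(2 * i + 1, 2 * j + 1, c) = g;
      }
  return dX;
}

static cube upsample2(const cube& X) {
  const int H = X.n_rows * 2, W = X.n_cols * 2, C = X.n_slices;
  cube U(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        U(i, j, c) = X(i / 2, j / 2, c);
  return U;
}

static cube upsample2_back(const cube& dU) {
  const int H = dU.n_rows / 2, W = dU.n_cols / 2, C = dU.n_slices;
  cube dX(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < (int)dU.n_cols; ++j)
      for (int i = 0; i < (int)dU.n_rows; ++i)
        dX(i / 2, j / 2, c) += dU(i, j, c);
  return dX;
}

static cube concat_ch(const cube& A, const cube& B) {
  cube C(A.n_rows, A.n_cols, A.n_slices + B.n_slices);
  C.slices(0, A.n_slices - 1) = A;
  C.slices(A.n_slices, C.n_slices - 1) = B;
  return C;
}

// ---------------------------------------------------------------------------
// network plumbing
// ---------------------------------------------------------------------------

struct NetDef {
  int L;                      // encoder levels
  std::vector<int> w;         // widths, length L+1 (w[L] = bottleneck)
  std::vector<int> cin, cout; // per conv layer, 2L+2 layers
};

static NetDef make_def(const Rcpp::IntegerVector& widths, int in_ch) {
  NetDef d;
  d.L = widths.size() - 1;
  d.w.assign(widths.begin(), widths.end());
  const int n_layers = 2 * d.L + 2;
  d.cin.resize(n_layers);
  d.cout.resize(n_layers);
  for (int l = 0; l < d.L; ++l) {           // encoder convs
    d.cin[l] = (l == 0) ? in_ch : d.w[l - 1];
    d.cout[l] = d.w[l];
  }
  d.cin[d.L] = d.w[d.L - 1];                // bottleneck
  d.cout[d.L] = d.w[d.L];
  for (int v = d.L; v >= 1; --v) {          // decoder convs, level L..1
    const int li = d.L + 1 + (d.L - v);
    d.cin[li] = d.w[v] + d.w[v - 1];        // upsampled + skip
    d.cout[li] = d.w[v - 1];
  }
  d.cin[2 * d.L + 1] = d.w[0];              // 1x1 head
  d.cout[2 * d.L + 1] = 1;
  return d;
}

struct Params {
  std::vector<mat> K;
  std::vector<vec> b;
};

static Params params_from_list(const List& weights, const NetDef& d) {
  Params p;
  const int n = 2 * d.L + 2;
  p.K.resize(n);
  p.b.resize(n);
  for (int i = 0; i < n; ++i) {
    p.K[i] = Rcpp::as<mat>(weights[2 * i]);
    p.b[i] = Rcpp::as<vec>(weights[2 * i + 1]);
  }
  return p;
}

static List params_to_list(const Params& p) {
  const int n = p.K.size();
  List out(2 * n);
  Rcpp::CharacterVector nm(2 * n);
  for (int i = 0; i < n; ++i) {
    out[2 * i] = p.K[i];
    out[2 * i + 1] = p.b[i];
    nm[2 * i] = "K" + std::to_string(i);
    nm[2 * i + 1] = "b" + std::to_string(i);
  }
  out.attr("names") = nm;
  return out;
}

struct FwdCache {
  std::vector<mat> M;      // im2col input per conv layer
  std::vector<cube> enc;   // post-relu encoder activations per level
  std::vector<cube> dec;   // post-relu decoder activations, index 0 = level L
  cube bott;
  mat prob;                // H x W
};

static mat forward(const Params& p, const NetDef& d, const cube& X,
                   FwdCache* cache) {
  const int n_layers = 2 * d.L + 2;
  std::vector<mat> M(n_layers);
  std::vector<cube> enc(d.L);
  cube A = X;
  for (int l = 0; l < d.L; ++l) {
    M[l] = im2col3(A);
    mat Y = M[l] * p.K[l];
    Y.each_row() += p.b[l].t();
    Y.transform([](double x) { return x > 0 ? x : RELU_SLOPE * x; });
    enc[l] = mat2cube(Y, A.n_rows, A.n_cols, d.cout[l]);
    A = avgpool2(enc[l]);
  }
  M[d.L] = im2col3(A);
  mat Yb = M[d.L] * p.K[d.L];
  Yb.each_row() += p.b[d.L].t();
  Yb.transform([](double x) { return x > 0 ? x : RELU_SLOPE * x; });
  cube B = mat2cube(Yb, A.n_rows, A.n_cols, d.cout[d.L]);

  std::vector<cube> dec(d.L);
  cube D = B;
  for (int v = d.L; v >= 1; --v) {
    const int li = d.L + 1 + (d.L - v);
    cube C = concat_ch(upsample2(D), enc[v - 1]);
    M[li] = im2col3(C);
    mat Y = M[li] * p.K[li];
    Y.each_row() += p.b[li].t();
    Y.transform([](double x) { return x > 0 ? x : RELU_SLOPE * x; });
    D = mat2cube(Y, C.n_rows, C.n_cols, d.cout[li]);
    dec[d.L - v] = D;
  }
  const int lo = 2 * d.L + 1;
  M[lo] = cube2mat(D);
  vec z = M[lo] * p.K[lo] + p.b[lo](0);
  mat prob = reshape(1.0 / (1.0 + exp(-z)), D.n_rows, D.n_cols);
  if (cache) {
    cache->M = std::move(M);
    cache->enc = std::move(enc);
    cache->dec = std::move(dec);
    cache->bott = std::move(B);
    cache->prob = prob;
  }
  return prob;
}

// ---------------------------------------------------------------------------
// binary focal loss (mean over pixels)
// ---------------------------------------------------------------------------

static double focal_loss(const mat& prob, const mat& y, double alpha,
                         double gamma) {
  mat p = clamp(prob, PROB_EPS, 1.0 - PROB_EPS);
  double s = 0.0;
  for (uword i = 0; i < p.n_elem; ++i) {
    const double pi = p(i);
    if (y(i) > 0.5)
      s += -alpha * std::pow(1.0 - pi, gamma) * std::log(pi);
    else
      s += -(1.0 - alpha) * std::pow(pi, gamma) * std::log(1.0 - pi);
  }
  return s / p.n_elem;
}

// d(mean focal loss)/d(logit)
static mat focal_grad_logit(const mat& prob, const mat& y, double alpha,
                            double gamma) {
  mat g(prob.n_rows, prob.n_cols);
  const double n = prob.n_elem;
  for (uword i = 0; i < prob.n_elem; ++i) {
    double p = std::min(std::max((double)prob(i), PROB_EPS), 1.0 - PROB_EPS);
    double dLdp;
    if (y(i) > 0.5) {
      const double t = (gamma > 0)
        ? gamma * std::pow(1.0 - p, gamma - 1.0) * std::log(p) : 0.0;
      dLdp = alpha * (t - std::pow(1.0 - p, gamma) / p);
    } else {
      const double t = (gamma > 0)
        ? gamma * std::pow(p, gamma - 1.0) * std::log(1.0 - p) : 0.0;
      dLdp = -(1.0 - alpha) * (t - std::pow(p, gamma) / (1.0 - p));
    }
    g(i) = dLdp * p * (1.0 - p) / n;
  }
  return g;
}

// ---------------------------------------------------------------------------
// backward pass: accumulates parameter gradients into gK / gb
// ---------------------------------------------------------------------------

static void backward(const Params& p, const NetDef& d, const FwdCache& f,
                     const mat& y, double alpha, double gamma,
                     std::vector<mat>& gK, std::vector<vec>& gb) {
  const int lo = 2 * d.L + 1;
  const int H = f.prob.n_rows, W = f.prob.n_cols;
  vec dz = vectorise(focal_grad_logit(f.prob, y, alpha, gamma));

  gK[lo] += f.M[lo].t() * dz;
  gb[lo](0) += accu(dz);
  mat dD1 = dz * p.K[lo].t();                       // (H*W) x w0
  cube dD = mat2cube(dD1, H, W, d.w[0]);

  std::vector<cube> skip_grad(d.L);                 // grads flowing into enc acts
  // decoder levels 1..L (reverse of forward)
  for (int v = 1; v <= d.L; ++v) {
    const int li = d.L + 1 + (d.L - v);
    const cube& act = f.dec[d.L - v];               // post-relu output of layer li
    cube dY = dD;
    for (uword i = 0; i < dY.n_elem; ++i)
      if (act(i) <= 0) dY(i) *= RELU_SLOPE;
    mat dYm = cube2mat(dY);
    gK[li] += f.M[li].t() * dYm;
    gb[li] += sum(dYm, 0).t();
    mat dCm = dYm * p.K[li].t();
    cube dC = col2im3(dCm, dY.n_rows, dY.n_cols, d.cin[li]);
    cube dU = dC.slices(0, d.w[v] - 1);
    skip_grad[v - 1] = dC.slices(d.w[v], d.cin[li] - 1);
    dD = upsample2_back(dU);                        // grad w.r.t. D_{v+1} or bott
  }

  // bottleneck
  {
    cube dY = dD;
    for (uword i = 0; i < dY.n_elem; ++i)
      if (f.bott(i) <= 0) dY(i) *= RELU_SLOPE;
    mat dYm = cube2mat(dY);
    gK[d.L] += f.M[d.L].t() * dYm;
    gb[d.L] += sum(dYm, 0).t();
    mat dAm = dYm * p.K[d.L].t();
    cube dA = col2im3(dAm, dY.n_rows, dY.n_cols, d.cin[d.L]);
    dD = dA;                                        // grad w.r.t. pooled enc[L-1]
  }

  // encoder levels L..1
  for (int l = d.L - 1; l >= 0; --l) {
    cube dE = skip_grad[l] + avgpool2_back(dD);
    const cube& act = f.enc[l];
    for (uword i = 0; i < dE.n_elem; ++i)
      if (act(i) <= 0) dE(i) *= RELU_SLOPE;
    mat dYm = cube2mat(dE);
    gK[l] += f.M[l].t() * dYm;
    gb[l] += sum(dYm, 0).t();
    if (l > 0) {
      mat dAm = dYm * p.K[l].t();
      dD = col2im3(dAm, dE.n_rows, dE.n_cols, d.cin[l]);
    }
  }
}

// ---------------------------------------------------------------------------
// flips
// ---------------------------------------------------------------------------

static cube flip_cube(const cube& X, bool fh, bool fv) {
  cube out = X;
  for (uword c = 0; c < X.n_slices; ++c) {
    mat s = X.slice(c);
    if (fv) s = flipud(s);  // vertical flip: reverse rows
    if (fh) s = fliplr(s);  // horizontal flip: reverse columns
    out.slice(c) = s;
  }
  return out;
}

static mat flip_mat(const mat& X, bool fh, bool fv) {
  mat s = X;
  if (fv) s = flipud(s);
  if (fh) s = fliplr(s);
  return s;
}

// ---------------------------------------------------------------------------
// exported API
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_unet_init(Rcpp::IntegerVector widths, int in_channels, int seed) {
  NetDef d = make_def(widths, in_channels);
  std::mt19937 rng(static_cast<uint32_t>(seed));
  Params p;
  const int n = 2 * d.L + 2;
  p.K.resize(n);
  p.b.resize(n);
  for (int i = 0; i < n; ++i) {
    const bool head = (i == n - 1);
    const int kh = head ? 1 : 9;
    const int rows = d.cin[i] * kh;
    const double sd = std::sqrt(2.0 / rows);  // He initialisation
    std::normal_distribution<double> nd(0.0, sd);
    mat K(rows, d.cout[i]);
    for (uword jj = 0; jj < K.n_elem; ++jj) K(jj) = nd(rng);
    p.K[i] = K;
    p.b[i] = vec(d.cout[i], fill::zeros);
  }
  return params_to_list(p);
}

// [[Rcpp::export]]
arma::mat cpp_unet_predict(List weights, Rcpp::IntegerVector widths,
                           int in_channels, arma::cube image) {
  NetDef d = make_def(widths, in_channels);
  Params p = params_from_list(weights, d);
  return forward(p, d, image, nullptr);
}

// [[Rcpp::export]]
double cpp_unet_loss(List weights, Rcpp::IntegerVector widths, int in_channels,
                     List images, List masks, double alpha, double gamma) {
  NetDef d = make_def(widths, in_channels);
  Params p = params_from_list(weights, d);
  double s = 0.0;
  for (int i = 0; i < images.size(); ++i) {
    cube X = Rcpp::as<cube>(images[i]);
    mat y = Rcpp::as<mat>(masks[i]);
    s += focal_loss(forward(p, d, X, nullptr), y, alpha, gamma);
  }
  return s / images.size();
}

// loss and parameter gradients for one image/mask pair (gradient checking)
// [[Rcpp::export]]
List cpp_unet_grad(List weights, Rcpp::IntegerVector widths, int in_channels,
                   arma::cube image, arma::mat mask, double alpha,
                   double gamma) {
  NetDef d = make_def(widths, in_channels);
  Params p = params_from_list(weights, d);
  const int n_layers = 2 * d.L + 2;
  std::vector<mat> gK(n_layers);
  std::vector<vec> gb(n_layers);
  for (int i = 0; i < n_layers; ++i) {
    gK[i] = zeros<mat>(p.K[i].n_rows, p.K[i].n_cols);
    gb[i] = zeros<vec>(p.b[i].n_elem);
  }
  FwdCache f;
  forward(p, d, image, &f);
  const double loss = focal_loss(f.prob, mask, alpha, gamma);
  backward(p, d, f, mask, alpha, gamma, gK, gb);
  Params g;
  g.K = gK;
  g.b = gb;
  return List::create(Rcpp::Named("loss") = loss,
                      Rcpp::Named("grads") = params_to_list(g));
}

// [[Rcpp::export]]
List cpp_unet_train(List weights, Rcpp::IntegerVector widths, int in_channels,
                    List images, List masks, List val_images, List val_masks,
                    int epochs, double lr, int batch_size, double alpha,
                    double gamma, bool hflip, bool vflip, int seed) {
  NetDef d = make_def(widths, in_channels);
  Params p = params_from_list(weights, d);
  const int n_layers = 2 * d.L + 2;
  const int n = images.size();

  std::vector<cube> X(n);
  std::vector<mat> Y(n);
  for (int i = 0; i < n; ++i) {
    X[i] = Rcpp::as<cube>(images[i]);
    Y[i] = Rcpp::as<mat>(masks[i]);
  }
  const int nv = val_images.size();
  std::vector<cube> Xv(nv);
  std::vector<mat> Yv(nv);
  for (int i = 0; i < nv; ++i) {
    Xv[i] = Rcpp::as<cube>(val_images[i]);
    Yv[i] = Rcpp::as<mat>(val_masks[i]);
  }

  // Adam state
  std::vector<mat> mK(n_layers), vK(n_layers), gK(n_layers);
  std::vector<vec> mb(n_layers), vb(n_layers), gb(n_layers);
  for (int i = 0; i < n_layers; ++i) {
    mK[i] = zeros<mat>(p.K[i].n_rows, p.K[i].n_cols);
    vK[i] = mK[i];
    mb[i] = zeros<vec>(p.b[i].n_elem);
    vb[i] = mb[i];
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;

  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  vec train_hist(epochs), val_hist(epochs);
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0;
    int seen = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int stop = std::min(n, start + batch_size);
      const int bs = stop - start;
      for (int i = 0; i < n_layers; ++i) {
        gK[i].zeros(p.K[i].n_rows, p.K[i].n_cols);
        gb[i].zeros(p.b[i].n_elem);
      }
      double batch_loss = 0.0;
      for (int k = start; k < stop; ++k) {
        const int s = idx[k];
        bool fh = false, fv = false;
        if (hflip) fh = (rng() & 1u) != 0;
        if (vflip) fv = (rng() & 1u) != 0;
        cube Xi = (fh || fv) ? flip_cube(X[s], fh, fv) : X[s];
        mat Yi = (fh || fv) ? flip_mat(Y[s], fh, fv) : Y[s];
        FwdCache f;
        forward(p, d, Xi, &f);
        batch_loss += focal_loss(f.prob, Yi, alpha, gamma);
        backward(p, d, f, Yi, alpha, gamma, gK, gb);
      }
      ep_loss += batch_loss;
      seen += bs;
      ++t;
      const double bc1 = 1.0 - std::pow(b1, (double)t);
      const double bc2 = 1.0 - std::pow(b2, (double)t);
      for (int i = 0; i < n_layers; ++i) {
        mat g = gK[i] / bs;
        mK[i] = b1 * mK[i] + (1 - b1) * g;
        vK[i] = b2 * vK[i] + (1 - b2) * square(g);
        p.K[i] -= lr * (mK[i] / bc1) / (sqrt(vK[i] / bc2) + eps);
        vec gbv = gb[i] / bs;
        mb[i] = b1 * mb[i] + (1 - b1) * gbv;
        vb[i] = b2 * vb[i] + (1 - b2) * square(gbv);
        p.b[i] -= lr * (mb[i] / bc1) / (sqrt(vb[i] / bc2) + eps);
      }
    }
    train_hist(ep) = ep_loss / seen;
    if (nv > 0) {
      double vl = 0.0;
      for (int i = 0; i < nv; ++i)
        vl += focal_loss(forward(p, d, Xv[i], nullptr), Yv[i], alpha, gamma);
      val_hist(ep) = vl / nv;
    } else {
      val_hist(ep) = datum::nan;
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(
    Rcpp::Named("weights") = params_to_list(p),
    Rcpp::Named("train_loss") = train_hist,
    Rcpp::Named("val_loss") = val_hist);
}
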