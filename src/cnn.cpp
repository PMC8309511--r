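// Minimal CNN engine for stare/move window classification.
//
// Single-precision feed-forward networks built from conv (3x3/5x5, stride 1,
// same padding), ReLU/sigmoid, k x k max-pooling (stride k), and fully
// connected layers, trained with Adam on softmax cross-entropy. Convolutions
// are evaluated as im2col + GEMM so the heavy lifting runs through BLAS.
// Activations are laid out channel-major: index = c*H*W + y*W + x, one
// column per sample.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::uword;

struct Layer {
  std::string type;        // conv | relu | sigmoid | pool | fc
  int in_c = 0, out_c = 0, k = 0;  // conv
  int pk = 0;                      // pool
  int in_n = 0, out_n = 0;         // fc
  int C = 0, H = 0, W = 0;         // input shape (conv/pool)
  fmat Wm;
  fvec b;
  fmat mW, vW;                     // Adam first/second moments
  fvec mb, vb;
  // caches (per forward pass)
  fmat in, out;
  fmat col;                        // conv: im2col of the whole batch
  arma::umat poolidx;
};

static void im2col(const float* x, int C, int H, int W, int k, float* col) {
  // col is (C*k*k) x (H*W), column-major (arma); pad = k/2
  const int pad = k / 2;
  const int HW = H * W;
  const int KK = k * k;
  for (int o = 0; o < HW; ++o) {
    const int oy = o / W, ox = o % W;
    float* cptr = col + (size_t)o * C * KK;
    for (int c = 0; c < C; ++c) {
      const float* xc = x + (size_t)c * HW;
      for (int dy = 0; dy < k; ++dy) {
        const int iy = oy + dy - pad;
        for (int dx = 0; dx < k; ++dx) {
          const int ix = ox + dx - pad;
          float v = 0.0f;
          if (iy >= 0 && iy < H && ix >= 0 && ix < W) v = xc[iy * W + ix];
          cptr[c * KK + dy * k + dx] = v;
        }
      }
    }
  }
}

static void col2im_add(const float* col, int C, int H, int W, int k,
                       float* x) {
  const int pad = k / 2;
  const int HW = H * W;
  const int KK = k * k;
  for (int o = 0; o < HW; ++o) {
    const int oy = o / W, ox = o % W;
    const float* cptr = col + (size_t)o * C * KK;
    for (int c = 0; c < C; ++c) {
      float* xc = x + (size_t)c * HW;
      for (int dy = 0; dy < k; ++dy) {
        const int iy = oy + dy - pad;
        if (iy < 0 || iy >= H) continue;
        for (int dx = 0; dx < k; ++dx) {
          const int ix = ox + dx - pad;
          if (ix < 0 || ix >= W) continue;
          xc[iy * W + ix] += cptr[c * KK + dy * k + dx];
        }
      }
    }
  }
}

static std::vector<Layer> parse_arch(const List& arch, int H0, int W0) {
  std::vector<Layer> net;
  int C = 1, H = H0, W = W0;
  bool flat = false;
  int flat_n = H0 * W0;
  for (int i = 0; i < arch.size(); ++i) {
    List sp = arch[i];
    Layer L;
    L.type = as<std::string>(sp["type"]);
    if (L.type == "conv") {
      L.in_c = as<int>(sp["in_c"]);
      L.out_c = as<int>(sp["out_c"]);
      L.k = as<int>(sp["k"]);
      if (L.in_c != C) stop("conv layer %d: channel mismatch", i + 1);
      L.C = C; L.H = H; L.W = W;
      C = L.out_c;
      flat_n = C * H * W;
    } else if (L.type == "pool") {
      L.pk = as<int>(sp["k"]);
      if (H % L.pk != 0 || W % L.pk != 0)
        stop("pool layer %d: size not divisible", i + 1);
      L.C = C; L.H = H; L.W = W;
      H /= L.pk; W /= L.pk;
      flat_n = C * H * W;
    } else if (L.type == "fc") {
      L.in_n = as<int>(sp["in_n"]);
      L.out_n = as<int>(sp["out_n"]);
      if (L.in_n != flat_n) stop("fc layer %d: input size mismatch", i + 1);
      flat_n = L.out_n;
      flat = true;
    } else if (L.type != "relu" && L.type != "sigmoid") {
      stop("unknown layer type: %s", L.type.c_str());
    }
    net.push_back(L);
  }
  (void)flat;
  return net;
}

static void init_params(std::vector<Layer>& net, int seed, bool sigmoid_net) {
  std::mt19937 rng(seed);
  std::normal_distribution<float> N(0.0f, 1.0f);
  for (auto& L : net) {
    if (L.type == "conv") {
      const int fan_in = L.in_c * L.k * L.k;
      const float sd = sigmoid_net ? std::sqrt(1.0f / fan_in)
                                   : std::sqrt(2.0f / fan_in);
      L.Wm.set_size(L.out_c, fan_in);
      for (uword j = 0; j < L.Wm.n_elem; ++j) L.Wm(j) = sd * N(rng);
      L.b.zeros(L.out_c);
    } else if (L.type == "fc") {
      const float sd = sigmoid_net ? std::sqrt(1.0f / L.in_n)
                                   : std::sqrt(2.0f / L.in_n);
      L.Wm.set_size(L.out_n, L.in_n);
      for (uword j = 0; j < L.Wm.n_elem; ++j) L.Wm(j) = sd * N(rng);
      L.b.zeros(L.out_n);
    }
    if (L.Wm.n_elem) {
      L.mW.zeros(L.Wm.n_rows, L.Wm.n_cols);
      L.vW.zeros(L.Wm.n_rows, L.Wm.n_cols);
      L.mb.zeros(L.b.n_elem);
      L.vb.zeros(L.b.n_elem);
    }
  }
}

// forward one batch; X is D x B (column per sample)
static fmat forward(std::vector<Layer>& net, const fmat& X, bool train) {
  fmat a = X;
  for (auto& L : net) {
    if (train) L.in = a;
    if (L.type == "conv") {
      const int HW = L.H * L.W;
      const int B = a.n_cols;
      const int CKK = L.in_c * L.k * L.k;
      // one im2col block per sample, one GEMM for the whole batch
      fmat col(CKK, (size_t)HW * B);
      for (int i = 0; i < B; ++i) {
        im2col(a.colptr(i), L.C, L.H, L.W, L.k,
               col.colptr((size_t)i * HW));
      }
      fmat y = L.Wm * col;            // OC x (HW*B)
      y.each_col() += L.b;
      if (train) L.col = std::move(col);
      fmat out(L.out_c * HW, B);
      for (int i = 0; i < B; ++i) {
        // (oc*HW + o) ordering within each sample column
        out.col(i) =
            arma::vectorise(fmat(y.cols((size_t)i * HW,
                                        (size_t)(i + 1) * HW - 1)).t());
      }
      a = std::move(out);
    } else if (L.type == "relu") {
      a.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    } else if (L.type == "sigmoid") {
      a.transform([](float v) { return 1.0f / (1.0f + std::exp(-v)); });
    } else if (L.type == "pool") {
      const int H2 = L.H / L.pk, W2 = L.W / L.pk;
      const int B = a.n_cols;
      fmat out(L.C * H2 * W2, B);
      if (train) L.poolidx.set_size(L.C * H2 * W2, B);
      for (int i = 0; i < B; ++i) {
        const float* x = a.colptr(i);
        float* y = out.colptr(i);
        for (int c = 0; c < L.C; ++c) {
          const float* xc = x + (size_t)c * L.H * L.W;
          for (int oy = 0; oy < H2; ++oy) {
            for (int ox = 0; ox < W2; ++ox) {
              float best = -std::numeric_limits<float>::infinity();
              int besti = 0;
              for (int dy = 0; dy < L.pk; ++dy) {
                for (int dx = 0; dx < L.pk; ++dx) {
                  const int iy = oy * L.pk + dy, ix = ox * L.pk + dx;
                  const float v = xc[iy * L.W + ix];
                  if (v > best) { best = v; besti = iy * L.W + ix; }
                }
              }
              const size_t oidx = (size_t)c * H2 * W2 + oy * W2 + ox;
              y[oidx] = best;
              if (train)
                L.poolidx(oidx, i) = (uword)c * L.H * L.W + besti;
            }
          }
        }
      }
      a = std::move(out);
    } else if (L.type == "fc") {
      fmat out = L.Wm * a;
      out.each_col() += L.b;
      a = std::move(out);
    }
    if (train) L.out = a;
  }
  return a;
}

// backward one batch; returns nothing, fills gradients in gW/gb per layer
static void backward(std::vector<Layer>& net, const fmat& dscores,
                     std::vector<fmat>& gW, std::vector<fvec>& gb) {
  fmat d = dscores;
  for (int li = (int)net.size() - 1; li >= 0; --li) {
    Layer& L = net[li];
    if (L.type == "fc") {
      gW[li] = d * L.in.t();
      gb[li] = arma::sum(d, 1);
      d = L.Wm.t() * d;
    } else if (L.type == "relu") {
      d %= arma::conv_to<fmat>::from(L.in > 0.0f);
    } else if (L.type == "sigmoid") {
      d %= L.out % (1.0f - L.out);
    } else if (L.type == "pool") {
      const int B = d.n_cols;
      fmat dx(L.C * L.H * L.W, B, arma::fill::zeros);
      for (int i = 0; i < B; ++i) {
        for (uword o = 0; o < L.poolidx.n_rows; ++o) {
          dx(L.poolidx(o, i), i) += d(o, i);
        }
      }
      d = std::move(dx);
    } else if (L.type == "conv") {
      const int HW = L.H * L.W;
      const int B = d.n_cols;
      // rebuild dY in batch layout: OC x (HW*B)
      fmat dyall(L.out_c, (size_t)HW * B);
      for (int i = 0; i < B; ++i) {
        dyall.cols((size_t)i * HW, (size_t)(i + 1) * HW - 1) =
            arma::reshape(fmat(d.col(i)), HW, L.out_c).t();
      }
      gW[li] = dyall * L.col.t();        // OC x CKK
      gb[li] = arma::sum(dyall, 1);
      fmat dcolall = L.Wm.t() * dyall;   // CKK x (HW*B)
      fmat dx(L.C * HW, B, arma::fill::zeros);
      for (int i = 0; i < B; ++i) {
        col2im_add(dcolall.colptr((size_t)i * HW), L.C, L.H, L.W, L.k,
                   dx.colptr(i));
      }
      L.col.reset();
      d = std::move(dx);
    }
  }
}

// softmax probabilities (2 x B) from scores
static fmat softmax(const fmat& s) {
  fmat z = s;
  z.each_row() -= arma::max(z, 0);
  z = arma::exp(z);
  fmat sums = arma::sum(z, 0);
  z.each_row() /= sums;
  return z;
}

static void adam_step(std::vector<Layer>& net, const std::vector<fmat>& gW,
                      const std::vector<fvec>& gb, float lr, int t) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  const float c1 = 1.0f - std::pow(b1, (float)t);
  const float c2 = 1.0f - std::pow(b2, (float)t);
  for (size_t li = 0; li < net.size(); ++li) {
    Layer& L = net[li];
    if (!L.Wm.n_elem) continue;
    L.mW = b1 * L.mW + (1.0f - b1) * gW[li];
    L.vW = b2 * L.vW + (1.0f - b2) * arma::square(gW[li]);
    L.Wm -= lr * (L.mW / c1) / (arma::sqrt(L.vW / c2) + eps);
    L.mb = b1 * L.mb + (1.0f - b1) * gb[li];
    L.vb = b2 * L.vb + (1.0f - b2) * arma::square(gb[li]);
    L.b -= lr * (L.mb / c1) / (arma::sqrt(L.vb / c2) + eps);
  }
}

// evaluate accuracy and mean cross-entropy on a dataset, in chunks
static void evaluate(std::vector<Layer>& net, const fmat& X,
                     const arma::ivec& y, double* acc, double* loss) {
  const int n = X.n_cols;
  const int chunk = 256;
  double correct = 0, ll = 0;
  for (int s = 0; s < n; s += chunk) {
    const int e = std::min(s + chunk, n) - 1;
    fmat scores = forward(net, X.cols(s, e), false);
    fmat p = softmax(scores);
    for (int i = 0; i <= e - s; ++i) {
      const int yi = y(s + i);
      const uword pred = p(1, i) > p(0, i) ? 1 : 0;
      if ((int)pred == yi) correct += 1.0;
      ll += -std::log(std::max(p(yi, i), 1e-12f));
    }
  }
  *acc = correct / n;
  *loss = ll / n;
}

static List export_weights(const std::vector<Layer>& net) {
  List out;
  for (const auto& L : net) {
    if (L.Wm.n_elem) {
      out.push_back(List::create(
          _["W"] = wrap(arma::conv_to<arma::mat>::from(L.Wm)),
          _["b"] = wrap(arma::conv_to<arma::vec>::from(L.b))));
    } else {
      out.push_back(R_NilValue);
    }
  }
  return out;
}

static void import_weights(std::vector<Layer>& net, const List& weights) {
  if ((int)net.size() != weights.size()) stop("weight/arch length mismatch");
  for (size_t i = 0; i < net.size(); ++i) {
    if (!net[i].Wm.is_empty() || net[i].type == "conv" ||
        net[i].type == "fc") {
      List w = weights[i];
      net[i].Wm = arma::conv_to<fmat>::from(as<arma::mat>(w["W"]));
      net[i].b = arma::conv_to<fvec>::from(as<arma::vec>(w["b"]));
    }
  }
}

// [[Rcpp::export]]
List cnn_train_cpp(List arch, const arma::mat& Xtr, const arma::ivec& ytr,
                   const arma::mat& Xval, const arma::ivec& yval,
                   int img_px, int epochs, int batch, double lr, int seed,
                   bool sigmoid_net) {
  std::vector<Layer> net = parse_arch(arch, img_px, img_px);
  init_params(net, seed, sigmoid_net);
  // transpose to column-per-sample, single precision
  fmat Xt = arma::conv_to<fmat>::from(Xtr.t());
  fmat Xv = arma::conv_to<fmat>::from(Xval.t());
  const int n = Xt.n_cols;
  if (n == 0) stop("empty training set");
  std::vector<fmat> gW(net.size());
  std::vector<fvec> gb(net.size());
  std::mt19937 rng(seed + 1);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  NumericVector ep_tr_acc(epochs), ep_tr_loss(epochs);
  NumericVector ep_val_acc(epochs), ep_val_loss(epochs);
  int t = 0;
  double ep_correct = 0.0, ep_ll = 0.0;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    for (int s = 0; s < n; s += batch) {
      const int e = std::min(s + batch, n);
      const int B = e - s;
      fmat xb(Xt.n_rows, B);
      arma::ivec yb(B);
      for (int i = 0; i < B; ++i) {
        xb.col(i) = Xt.col(idx[s + i]);
        yb(i) = ytr(idx[s + i]);
      }
      fmat scores = forward(net, xb, true);
      fmat p = softmax(scores);
      // train metrics accumulated from the minibatch forward passes
      for (int i = 0; i < B; ++i) {
        const int yi = yb(i);
        if ((p(1, i) > p(0, i) ? 1 : 0) == yi) ep_correct += 1.0;
        ep_ll += -std::log(std::max(p(yi, i), 1e-12f));
      }
      fmat dscores = p;
      for (int i = 0; i < B; ++i) dscores(yb(i), i) -= 1.0f;
      dscores /= (float)B;
      backward(net, dscores, gW, gb);
      adam_step(net, gW, gb, (float)lr, ++t);
    }
    ep_tr_acc[ep] = ep_correct / n;
    ep_tr_loss[ep] = ep_ll / n;
    ep_correct = 0.0; ep_ll = 0.0;
    double a, l;
    evaluate(net, Xv, yval, &a, &l);
    ep_val_acc[ep] = a; ep_val_loss[ep] = l;
    Rcpp::checkUserInterrupt();
  }
  DataFrame hist = DataFrame::create(
      _["epoch"] = seq_len(epochs),
      _["train_acc"] = ep_tr_acc, _["train_loss"] = ep_tr_loss,
      _["val_acc"] = ep_val_acc, _["val_loss"] = ep_val_loss);
  return List::create(_["weights"] = export_weights(net),
                      _["history"] = hist);
}

// [[Rcpp::export]]
arma::mat cnn_predict_cpp(List arch, List weights, const arma::mat& X,
                          int img_px) {
  std::vector<Layer> net = parse_arch(arch, img_px, img_px);
  import_weights(net, weights);
  fmat Xt = arma::conv_to<fmat>::from(X.t());
  const int n = Xt.n_cols;
  arma::mat out(n, 2);
  const int chunk = 256;
  for (int s = 0; s < n; s += chunk) {
    const int e = std::min(s + chunk, n) - 1;
    fmat p = softmax(forward(net, Xt.cols(s, e), false));
    for (int i = 0; i <= e - s; ++i) {
      out(s + i, 0) = p(0, i);
      out(s + i, 1) = p(1, i);
    }
  }
  return out;
}
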