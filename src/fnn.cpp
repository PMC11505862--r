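#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Feedforward binary classifier: n_hidden dense layers of `width` units with
// ReLU and inverted dropout, sigmoid output, binary cross-entropy loss,
// Adam updates. Single-threaded and fully determined by `seed`.
// Training is done in single precision (the usual deep-learning dtype);
// weights are returned as doubles.

static arma::fvec sigmoidf(const arma::fvec& z) {
  return 1.0f / (1.0f + arma::exp(-z));
}

// [[Rcpp::export(name = ".fnn_train_cpp")]]
List fnn_train_cpp(const arma::mat& Xtr_in, const arma::vec& ytr_in,
                   const arma::mat& Xval_in, const arma::vec& yval_in,
                   int n_hidden, int width, double dropout,
                   int epochs, int batch_size, double lr, int seed) {
  const arma::fmat Xtr = arma::conv_to<arma::fmat>::from(Xtr_in.t()); // p x n
  const arma::fvec ytr = arma::conv_to<arma::fvec>::from(ytr_in);
  const arma::fmat Xval = arma::conv_to<arma::fmat>::from(Xval_in.t());
  const int p = Xtr.n_rows, n = Xtr.n_cols;
  const int L = n_hidden + 1;
  const float keep = 1.0f - (float)dropout;

  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<float> gauss(0.0f, 1.0f);
  std::uniform_real_distribution<float> unif(0.0f, 1.0f);

  std::vector<arma::fmat> W(L);
  std::vector<arma::fvec> b(L);
  for (int l = 0; l < L; ++l) {
    int fan_in = (l == 0) ? p : width;
    int fan_out = (l == L - 1) ? 1 : width;
    float sd = (l == L - 1) ? std::sqrt(1.0f / fan_in)   // Xavier-ish output
                            : std::sqrt(2.0f / fan_in);  // He for ReLU
    W[l].set_size(fan_out, fan_in);
    for (arma::uword k = 0; k < W[l].n_elem; ++k) W[l](k) = sd * gauss(rng);
    b[l].zeros(fan_out);
  }

  // Adam state
  std::vector<arma::fmat> mW(L), vW(L);
  std::vector<arma::fvec> mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    mW[l].zeros(arma::size(W[l])); vW[l].zeros(arma::size(W[l]));
    mb[l].zeros(b[l].n_elem);      vb[l].zeros(b[l].n_elem);
  }
  const float beta1 = 0.9f, beta2 = 0.999f, eps = 1e-8f;
  long tstep = 0;

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  std::vector<arma::fmat> A(L);      // post-activation per hidden layer
  std::vector<arma::fmat> mask(L);   // dropout masks

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    for (int start = 0; start < n; start += batch_size) {
      int stop = std::min(start + batch_size, n);
      int bs = stop - start;
      arma::uvec sel(bs);
      for (int i = 0; i < bs; ++i) sel[i] = idx[start + i];
      arma::fmat Xb = Xtr.cols(sel);
      arma::fvec yb = ytr.elem(sel);

      // forward
      arma::fmat cur = Xb;
      for (int l = 0; l < n_hidden; ++l) {
        arma::fmat Z = W[l] * cur;
        Z.each_col() += b[l];
        A[l] = arma::clamp(Z, 0.0f, std::numeric_limits<float>::max());
        mask[l].set_size(arma::size(A[l]));
        for (arma::uword k = 0; k < mask[l].n_elem; ++k)
          mask[l](k) = (unif(rng) < keep) ? 1.0f / keep : 0.0f;
        A[l] %= mask[l];
        cur = A[l];
      }
      arma::fvec zout = arma::vectorise(W[L - 1] * cur) + b[L - 1](0);
      arma::fvec prob = sigmoidf(zout);

      // backward (BCE + sigmoid): dZ = (prob - y)/bs
      arma::frowvec dZ = (prob - yb).t() / (float)bs;
      std::vector<arma::fmat> gW(L);
      std::vector<arma::fvec> gb(L);
      const arma::fmat& Aprev = (n_hidden > 0) ? A[n_hidden - 1] : Xb;
      gW[L - 1] = dZ * Aprev.t();
      gb[L - 1] = arma::fvec(1);
      gb[L - 1](0) = arma::accu(dZ);
      arma::fmat dA = W[L - 1].t() * dZ;  // width x bs
      for (int l = n_hidden - 1; l >= 0; --l) {
        arma::fmat dZl = dA % mask[l];           // dropout backprop
        dZl.elem(arma::find(A[l] == 0.0f)).zeros();  // ReLU gate
        const arma::fmat& Ain = (l == 0) ? Xb : A[l - 1];
        gW[l] = dZl * Ain.t();
        gb[l] = arma::sum(dZl, 1);
        if (l > 0) dA = W[l].t() * dZl;
      }

      // Adam step
      ++tstep;
      float bc1 = 1.0f - std::pow(beta1, (float)tstep);
      float bc2 = 1.0f - std::pow(beta2, (float)tstep);
      for (int l = 0; l < L; ++l) {
        mW[l] = beta1 * mW[l] + (1.0f - beta1) * gW[l];
        vW[l] = beta2 * vW[l] + (1.0f - beta2) * arma::square(gW[l]);
        W[l] -= (float)lr * (mW[l] / bc1) / (arma::sqrt(vW[l] / bc2) + eps);
        mb[l] = beta1 * mb[l] + (1.0f - beta1) * gb[l];
        vb[l] = beta2 * vb[l] + (1.0f - beta2) * arma::square(gb[l]);
        b[l] -= (float)lr * (mb[l] / bc1) / (arma::sqrt(vb[l] / bc2) + eps);
      }
    }
  }

  // inference helper (no dropout)
  auto predict = [&](const arma::fmat& X) {
    arma::fmat cur = X;
    for (int l = 0; l < n_hidden; ++l) {
      arma::fmat Z = W[l] * cur;
      Z.each_col() += b[l];
      cur = arma::clamp(Z, 0.0f, std::numeric_limits<float>::max());
    }
    arma::fvec z = arma::vectorise(W[L - 1] * cur) + b[L - 1](0);
    return sigmoidf(z);
  };

  arma::fvec ptr = predict(Xtr);
  double train_acc = arma::mean(arma::conv_to<arma::vec>::from(
      (ptr >= 0.5f) == (ytr >= 0.5f)));
  double val_acc = NA_REAL;
  if (Xval.n_cols > 0) {
    arma::fvec pv = predict(Xval);
    arma::fvec yv = arma::conv_to<arma::fvec>::from(yval_in);
    val_acc = arma::mean(arma::conv_to<arma::vec>::from(
        (pv >= 0.5f) == (yv >= 0.5f)));
  }

  List Wl(L), bl(L);
  for (int l = 0; l < L; ++l) {
    Wl[l] = wrap(arma::conv_to<arma::mat>::from(W[l]));
    bl[l] = wrap(arma::conv_to<arma::vec>::from(b[l]));
  }
  return List::create(_["W"] = Wl, _["b"] = bl,
                      _["train_acc"] = train_acc, _["val_acc"] = val_acc);
}

// [[Rcpp::export(name = ".fnn_predict_cpp")]]
arma::vec fnn_predict_cpp(List Wl, List bl, const arma::mat& X_in) {
  int L = Wl.size();
  arma::fmat cur = arma::conv_to<arma::fmat>::from(X_in.t());
  for (int l = 0; l < L - 1; ++l) {
    arma::fmat W = arma::conv_to<arma::fmat>::from(as<arma::mat>(Wl[l]));
    arma::fvec b = arma::conv_to<arma::fvec>::from(as<arma::vec>(bl[l]));
    arma::fmat Z = W * cur;
    Z.each_col() += b;
    cur = arma::clamp(Z, 0.0f, std::numeric_limits<float>::max());
  }
  arma::fmat W = arma::conv_to<arma::fmat>::from(as<arma::mat>(Wl[L - 1]));
  arma::fvec b = arma::conv_to<arma::fvec>::from(as<arma::vec>(bl[L - 1]));
  arma::fvec z = arma::vectorise(W * cur) + b(0);
  return arma::conv_to<arma::vec>::from(1.0f / (1.0f + arma::exp(-z)));
}
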