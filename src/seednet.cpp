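// Minibatch forward/backward engine for small residual convolutional
// networks.  Feature maps are stored one arma::mat per image with one row
// per channel and one column per spatial position (column-major spatial
// index s = h + H*w, matching R's array layout).  Convolutions are
// evaluated as im2col followed by a GEMM so the heavy lifting stays in
// BLAS; batch normalisation statistics are taken over the whole minibatch.
//
// The layer grammar mirrors the R-side network spec: conv / bn / relu /
// maxpool / block_start / block_add / gap / fc.  Residual blocks are
// delimited by block_start (which caches the block input and evaluates the
// optional 1x1 projection shortcut) and block_add (which adds the shortcut
// and applies the closing ReLU).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct ConvCache {
  std::vector<arma::mat> in;  // input feature maps per image
  int H = 0, W = 0, oH = 0, oW = 0;
};

struct BNCache {
  std::vector<arma::mat> xhat;  // normalised activations per image
  arma::vec invstd;
};

struct LayerCache {
  ConvCache conv;
  BNCache bn;
  std::vector<arma::mat> reluOut;      // post-ReLU activations (mask)
  std::vector<arma::umat> poolIdx;     // argmax source index per output px
  // block_start: cached block input + projection shortcut caches
  std::vector<arma::mat> blockIn;
  std::vector<arma::mat> shortcutOut;
  ConvCache projConv;
  BNCache projBn;
  int inH = 0, inW = 0;
};

int convOut(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

arma::mat im2col(const arma::mat& X, int H, int W, int k, int stride,
                 int pad, int oH, int oW) {
  const int inC = X.n_rows;
  arma::mat cols(inC * k * k, (arma::uword)oH * oW, arma::fill::zeros);
  for (int ow = 0; ow < oW; ++ow) {
    for (int oh = 0; oh < oH; ++oh) {
      const arma::uword t = (arma::uword)oh + (arma::uword)oH * ow;
      for (int kw = 0; kw < k; ++kw) {
        const int w = ow * stride - pad + kw;
        if (w < 0 || w >= W) continue;
        for (int kh = 0; kh < k; ++kh) {
          const int h = oh * stride - pad + kh;
          if (h < 0 || h >= H) continue;
          const arma::uword s = (arma::uword)h + (arma::uword)H * w;
          for (int c = 0; c < inC; ++c)
            cols(c * k * k + kh * k + kw, t) = X(c, s);
        }
      }
    }
  }
  return cols;
}

void col2imAdd(const arma::mat& dcols, arma::mat& dX, int H, int W, int k,
               int stride, int pad, int oH, int oW) {
  const int inC = dX.n_rows;
  for (int ow = 0; ow < oW; ++ow) {
    for (int oh = 0; oh < oH; ++oh) {
      const arma::uword t = (arma::uword)oh + (arma::uword)oH * ow;
      for (int kw = 0; kw < k; ++kw) {
        const int w = ow * stride - pad + kw;
        if (w < 0 || w >= W) continue;
        for (int kh = 0; kh < k; ++kh) {
          const int h = oh * stride - pad + kh;
          if (h < 0 || h >= H) continue;
          const arma::uword s = (arma::uword)h + (arma::uword)H * w;
          for (int c = 0; c < inC; ++c)
            dX(c, s) += dcols(c * k * k + kh * k + kw, t);
        }
      }
    }
  }
}

std::vector<arma::mat> convForward(const arma::mat& Wm,
                                   const std::vector<arma::mat>& batch,
                                   int H, int W, int k, int stride, int pad,
                                   bool keepCache, ConvCache& cache) {
  const int oH = convOut(H, k, stride, pad);
  const int oW = convOut(W, k, stride, pad);
  std::vector<arma::mat> out(batch.size());
  for (size_t i = 0; i < batch.size(); ++i)
    out[i] = Wm * im2col(batch[i], H, W, k, stride, pad, oH, oW);
  if (keepCache) {
    cache.in = batch;
    cache.H = H; cache.W = W; cache.oH = oH; cache.oW = oW;
  }
  return out;
}

std::vector<arma::mat> convBackward(const arma::mat& Wm,
                                    const ConvCache& cache,
                                    const std::vector<arma::mat>& dOut,
                                    int k, int stride, int pad,
                                    arma::mat& dW) {
  dW.zeros(Wm.n_rows, Wm.n_cols);
  std::vector<arma::mat> dIn(dOut.size());
  for (size_t i = 0; i < dOut.size(); ++i) {
    arma::mat cols = im2col(cache.in[i], cache.H, cache.W, k, stride, pad,
                            cache.oH, cache.oW);
    dW += dOut[i] * cols.t();
    arma::mat dcols = Wm.t() * dOut[i];
    dIn[i].zeros(cache.in[i].n_rows, cache.in[i].n_cols);
    col2imAdd(dcols, dIn[i], cache.H, cache.W, k, stride, pad,
              cache.oH, cache.oW);
  }
  return dIn;
}

// momentum > 0: exponential moving average of batch statistics;
// momentum <= 0: cumulative moving average over `cnt` updates (better
// calibrated inference statistics when training runs are short).
std::vector<arma::mat> bnForward(const arma::vec& gamma, const arma::vec& beta,
                                 const std::vector<arma::mat>& batch,
                                 bool training, arma::vec& runMean,
                                 arma::vec& runVar, double momentum,
                                 double& cnt, bool keepCache,
                                 BNCache& cache) {
  const int C = batch[0].n_rows;
  const double eps = 1e-5;
  arma::vec mu(C), var(C);
  if (training) {
    const double m = (double)batch.size() * batch[0].n_cols;
    mu.zeros(); var.zeros();
    for (const arma::mat& X : batch) mu += arma::sum(X, 1);
    mu /= m;
    for (const arma::mat& X : batch) {
      arma::mat d = X.each_col() - mu;
      var += arma::sum(arma::square(d), 1);
    }
    var /= m;
    double mom = momentum;
    if (momentum <= 0) {
      cnt += 1.0;
      mom = 1.0 / cnt;
    }
    runMean = (1.0 - mom) * runMean + mom * mu;
    runVar = (1.0 - mom) * runVar + mom * var;
  } else {
    mu = runMean;
    var = runVar;
  }
  arma::vec invstd = 1.0 / arma::sqrt(var + eps);
  std::vector<arma::mat> out(batch.size());
  if (keepCache) cache.xhat.resize(batch.size());
  for (size_t i = 0; i < batch.size(); ++i) {
    arma::mat xhat = (batch[i].each_col() - mu).each_col() % invstd;
    out[i] = (xhat.each_col() % gamma).each_col() + beta;
    if (keepCache) cache.xhat[i] = std::move(xhat);
  }
  if (keepCache) cache.invstd = invstd;
  return out;
}

std::vector<arma::mat> bnBackward(const arma::vec& gamma, const BNCache& cache,
                                  const std::vector<arma::mat>& dOut,
                                  arma::vec& dgamma, arma::vec& dbeta) {
  const int C = dOut[0].n_rows;
  const double m = (double)dOut.size() * dOut[0].n_cols;
  dgamma.zeros(C);
  dbeta.zeros(C);
  for (size_t i = 0; i < dOut.size(); ++i) {
    dgamma += arma::sum(dOut[i] % cache.xhat[i], 1);
    dbeta += arma::sum(dOut[i], 1);
  }
  std::vector<arma::mat> dIn(dOut.size());
  arma::vec scale = gamma % cache.invstd / m;
  for (size_t i = 0; i < dOut.size(); ++i) {
    arma::mat t = m * dOut[i];
    t.each_col() -= dbeta;
    t -= cache.xhat[i].each_col() % dgamma;
    dIn[i] = t.each_col() % scale;
  }
  return dIn;
}

}  // namespace

// Runs the network forward (and, when y is supplied with computeGrad, the
// full backward pass).  x is an (H, W, C, N) array scaled by the caller;
// y holds 1-based class labels.  Returns logits, the softmax cross-entropy
// loss, per-parameter gradients and updated batch-norm running statistics.
// [[Rcpp::export]]
List seednetRun(List spec, List params, List state, NumericVector x,
                IntegerVector y, bool training, bool computeGrad,
                double bnMomentum) {
  IntegerVector inputDim = spec["input"];
  const int H0 = inputDim[0], W0 = inputDim[1], C0 = inputDim[2];
  IntegerVector xdim = x.attr("dim");
  if (xdim.size() != 4 || xdim[0] != H0 || xdim[1] != W0 || xdim[2] != C0)
    stop("input array does not match the network's expected input size");
  const int N = xdim[3];
  List layers = spec["layers"];
  const int L = layers.size();

  // load input into per-image (C, H*W) matrices
  const arma::uword HW = (arma::uword)H0 * W0;
  std::vector<arma::mat> cur(N);
  for (int n = 0; n < N; ++n) {
    arma::mat M(C0, HW);
    const double* base = x.begin() + (arma::uword)n * C0 * HW;
    for (int c = 0; c < C0; ++c)
      for (arma::uword s = 0; s < HW; ++s) M(c, s) = base[c * HW + s];
    cur[n] = std::move(M);
  }

  const bool keep = computeGrad;
  std::vector<LayerCache> caches(L);
  std::vector<int> blockStack;
  // updated running stats (copied so the caller's state stays untouched)
  List newState = clone(state);

  int curH = H0, curW = W0;
  std::vector<std::pair<int, int>> dimsAt(L + 1);
  arma::mat logits;  // (nClass, N)

  for (int li = 0; li < L; ++li) {
    dimsAt[li] = {curH, curW};
    List ly = layers[li];
    std::string type = as<std::string>(ly["type"]);
    if (type == "conv") {
      const int k = ly["k"], stride = ly["stride"], pad = ly["pad"];
      const int pidx = as<int>(ly["pidx"]) - 1;
      arma::mat Wm = as<arma::mat>(params[pidx]);
      cur = convForward(Wm, cur, curH, curW, k, stride, pad, keep,
                        caches[li].conv);
      curH = convOut(curH, k, stride, pad);
      curW = convOut(curW, k, stride, pad);
    } else if (type == "bn") {
      const int pidx = as<int>(ly["pidx"]) - 1;
      List p = params[pidx];
      arma::vec gamma = as<arma::vec>(p["gamma"]);
      arma::vec beta = as<arma::vec>(p["beta"]);
      List st = newState[pidx];
      arma::vec rm = as<arma::vec>(st["mean"]);
      arma::vec rv = as<arma::vec>(st["var"]);
      double cnt = st.containsElementNamed("n") ? as<double>(st["n"]) : 0.0;
      cur = bnForward(gamma, beta, cur, training, rm, rv, bnMomentum, cnt,
                      keep, caches[li].bn);
      if (training)
        newState[pidx] = List::create(_["mean"] = rm, _["var"] = rv,
                                      _["n"] = cnt);
    } else if (type == "relu") {
      for (auto& M : cur) M.transform([](double v) { return v > 0 ? v : 0.0; });
      if (keep) caches[li].reluOut = cur;
    } else if (type == "maxpool") {
      const int k = ly["k"], stride = ly["stride"], pad = ly["pad"];
      const int oH = convOut(curH, k, stride, pad);
      const int oW = convOut(curW, k, stride, pad);
      const int C = cur[0].n_rows;
      if (keep) caches[li].poolIdx.resize(N);
      std::vector<arma::mat> out(N);
      for (int n = 0; n < N; ++n) {
        out[n].set_size(C, (arma::uword)oH * oW);
        arma::umat idx;
        if (keep) idx.set_size(C, (arma::uword)oH * oW);
        for (int ow = 0; ow < oW; ++ow)
          for (int oh = 0; oh < oH; ++oh) {
            const arma::uword t = (arma::uword)oh + (arma::uword)oH * ow;
            for (int c = 0; c < C; ++c) {
              double best = -arma::datum::inf;
              arma::uword bestS = 0;
              for (int kw = 0; kw < k; ++kw) {
                const int w = ow * stride - pad + kw;
                if (w < 0 || w >= curW) continue;
                for (int kh = 0; kh < k; ++kh) {
                  const int h = oh * stride - pad + kh;
                  if (h < 0 || h >= curH) continue;
                  const arma::uword s = (arma::uword)h + (arma::uword)curH * w;
                  if (cur[n](c, s) > best) { best = cur[n](c, s); bestS = s; }
                }
              }
              out[n](c, t) = best;
              if (keep) idx(c, t) = bestS;
            }
          }
        if (keep) caches[li].poolIdx[n] = std::move(idx);
      }
      cur = std::move(out);
      caches[li].inH = curH; caches[li].inW = curW;
      curH = oH; curW = oW;
    } else if (type == "block_start") {
      blockStack.push_back(li);
      caches[li].blockIn = cur;
      caches[li].inH = curH; caches[li].inW = curW;
      const bool proj = as<bool>(ly["proj"]);
      if (proj) {
        const int stride = ly["stride"];
        const int cpidx = as<int>(ly["convPidx"]) - 1;
        const int bpidx = as<int>(ly["bnPidx"]) - 1;
        arma::mat Wm = as<arma::mat>(params[cpidx]);
        std::vector<arma::mat> sc = convForward(Wm, cur, curH, curW, 1,
                                                stride, 0, keep,
                                                caches[li].projConv);
        List p = params[bpidx];
        arma::vec gamma = as<arma::vec>(p["gamma"]);
        arma::vec beta = as<arma::vec>(p["beta"]);
        List st = newState[bpidx];
        arma::vec rm = as<arma::vec>(st["mean"]);
        arma::vec rv = as<arma::vec>(st["var"]);
        double cnt = st.containsElementNamed("n") ? as<double>(st["n"]) : 0.0;
        sc = bnForward(gamma, beta, sc, training, rm, rv, bnMomentum, cnt,
                       keep, caches[li].projBn);
        if (training)
          newState[bpidx] = List::create(_["mean"] = rm, _["var"] = rv,
                                         _["n"] = cnt);
        caches[li].shortcutOut = std::move(sc);
      } else {
        caches[li].shortcutOut = cur;
      }
    } else if (type == "block_add") {
      const int bs = blockStack.back();
      blockStack.pop_back();
      for (int n = 0; n < N; ++n) {
        cur[n] += caches[bs].shortcutOut[n];
        cur[n].transform([](double v) { return v > 0 ? v : 0.0; });
      }
      if (keep) caches[li].reluOut = cur;
      caches[li].inH = bs;  // remember the matching block_start
    } else if (type == "gap") {
      caches[li].inH = curH; caches[li].inW = curW;
      std::vector<arma::mat> out(N);
      for (int n = 0; n < N; ++n) out[n] = arma::mean(cur[n], 1);
      if (keep) caches[li].blockIn = cur;  // reuse slot for input dims
      cur = std::move(out);
      curH = 1; curW = 1;
    } else if (type == "fc") {
      const int pidx = as<int>(ly["pidx"]) - 1;
      List p = params[pidx];
      arma::mat Wm = as<arma::mat>(p["W"]);
      arma::vec b = as<arma::vec>(p["b"]);
      if (keep) caches[li].blockIn = cur;
      std::vector<arma::mat> out(N);
      for (int n = 0; n < N; ++n) out[n] = Wm * cur[n] + b;
      cur = std::move(out);
    } else {
      stop("unknown layer type: " + type);
    }
  }

  const int nClass = cur[0].n_rows;
  logits.set_size(nClass, N);
  for (int n = 0; n < N; ++n) logits.col(n) = cur[n].col(0);

  double loss = NA_REAL;
  arma::mat probs(nClass, N);
  for (int n = 0; n < N; ++n) {
    arma::vec z = logits.col(n);
    z -= z.max();
    arma::vec e = arma::exp(z);
    probs.col(n) = e / arma::accu(e);
  }
  if (y.size() == N) {
    loss = 0.0;
    for (int n = 0; n < N; ++n)
      loss -= std::log(std::max(probs(y[n] - 1, n), 1e-12));
    loss /= N;
  }

  List grads(params.size());
  if (computeGrad) {
    if (y.size() != N) stop("labels required for gradient computation");
    // dlogits
    std::vector<arma::mat> d(N);
    for (int n = 0; n < N; ++n) {
      arma::vec g = probs.col(n);
      g(y[n] - 1) -= 1.0;
      d[n] = g / (double)N;
    }
    // stash for shortcut gradients, keyed by block_start layer index
    std::map<int, std::vector<arma::mat>> shortGrad;
    for (int li = L - 1; li >= 0; --li) {
      List ly = layers[li];
      std::string type = as<std::string>(ly["type"]);
      if (type == "conv") {
        const int k = ly["k"], stride = ly["stride"], pad = ly["pad"];
        const int pidx = as<int>(ly["pidx"]) - 1;
        arma::mat Wm = as<arma::mat>(params[pidx]);
        arma::mat dW;
        d = convBackward(Wm, caches[li].conv, d, k, stride, pad, dW);
        grads[pidx] = wrap(dW);
      } else if (type == "bn") {
        const int pidx = as<int>(ly["pidx"]) - 1;
        List p = params[pidx];
        arma::vec gamma = as<arma::vec>(p["gamma"]);
        arma::vec dgamma, dbeta;
        d = bnBackward(gamma, caches[li].bn, d, dgamma, dbeta);
        grads[pidx] = List::create(_["gamma"] = wrap(dgamma),
                                   _["beta"] = wrap(dbeta));
      } else if (type == "relu") {
        for (int n = 0; n < N; ++n)
          d[n] %= arma::conv_to<arma::mat>::from(caches[li].reluOut[n] > 0);
      } else if (type == "maxpool") {
        const int C = d[0].n_rows;
        const arma::uword inHW =
            (arma::uword)caches[li].inH * caches[li].inW;
        std::vector<arma::mat> dIn(N);
        for (int n = 0; n < N; ++n) {
          dIn[n].zeros(C, inHW);
          const arma::umat& idx = caches[li].poolIdx[n];
          for (arma::uword t = 0; t < d[n].n_cols; ++t)
            for (int c = 0; c < C; ++c)
              dIn[n](c, idx(c, t)) += d[n](c, t);
        }
        d = std::move(dIn);
      } else if (type == "block_add") {
        const int bs = caches[li].inH;
        for (int n = 0; n < N; ++n)
          d[n] %= arma::conv_to<arma::mat>::from(caches[li].reluOut[n] > 0);
        shortGrad[bs] = d;  // shortcut branch receives the same gradient
      } else if (type == "block_start") {
        std::vector<arma::mat>& ds = shortGrad[li];
        const bool proj = as<bool>(ly["proj"]);
        if (proj) {
          const int stride = ly["stride"];
          const int cpidx = as<int>(ly["convPidx"]) - 1;
          const int bpidx = as<int>(ly["bnPidx"]) - 1;
          List p = params[bpidx];
          arma::vec gamma = as<arma::vec>(p["gamma"]);
          arma::vec dgamma, dbeta;
          std::vector<arma::mat> dsc =
              bnBackward(gamma, caches[li].projBn, ds, dgamma, dbeta);
          grads[bpidx] = List::create(_["gamma"] = wrap(dgamma),
                                      _["beta"] = wrap(dbeta));
          arma::mat Wm = as<arma::mat>(params[cpidx]);
          arma::mat dW;
          dsc = convBackward(Wm, caches[li].projConv, dsc, 1, stride, 0, dW);
          grads[cpidx] = wrap(dW);
          for (int n = 0; n < N; ++n) d[n] += dsc[n];
        } else {
          for (int n = 0; n < N; ++n) d[n] += ds[n];
        }
        shortGrad.erase(li);
      } else if (type == "gap") {
        const arma::uword inHW =
            (arma::uword)caches[li].inH * caches[li].inW;
        std::vector<arma::mat> dIn(N);
        for (int n = 0; n < N; ++n)
          dIn[n] = arma::repmat(d[n] / (double)inHW, 1, inHW);
        d = std::move(dIn);
      } else if (type == "fc") {
        const int pidx = as<int>(ly["pidx"]) - 1;
        List p = params[pidx];
        arma::mat Wm = as<arma::mat>(p["W"]);
        arma::mat dW(Wm.n_rows, Wm.n_cols, arma::fill::zeros);
        arma::vec db(Wm.n_rows, arma::fill::zeros);
        std::vector<arma::mat> dIn(N);
        for (int n = 0; n < N; ++n) {
          dW += d[n] * caches[li].blockIn[n].t();
          db += d[n].col(0);
          dIn[n] = Wm.t() * d[n];
        }
        grads[pidx] = List::create(_["W"] = wrap(dW), _["b"] = wrap(db));
        d = std::move(dIn);
      }
    }
  }

  return List::create(_["logits"] = wrap(logits), _["probs"] = wrap(probs),
                      _["loss"] = loss, _["grads"] = grads,
                      _["state"] = newState);
}
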