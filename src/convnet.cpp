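// Fast path for the 3-layer convolutional feature extractor.
// Layout conventions match the R reference implementation:
//  - activations: (H, W, B, C) column-major, flattened index
//      h + H*w + H*W*b + H*W*B*c
//  - patch matrices: rows ordered (h, w, b) with h fastest; columns
//      offset*C + c with offset = dy*k + dx (dy fastest loop variable)
//  - conv weights: (k*k*Cin) x Cout, rows ordered like patch columns
//  - flattened features for sample b: element (h, w, c) at
//      h + Ho*w + Ho*Wo*c
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

inline arma::uword aidx(arma::uword h, arma::uword w, arma::uword b,
                        arma::uword c, arma::uword H, arma::uword W,
                        arma::uword B) {
  return h + H * (w + W * (b + B * c));
}

// im2col with zero padding p = (k-1)/2
arma::mat im2col(const arma::vec& A, arma::uword H, arma::uword W,
                 arma::uword B, arma::uword C, arma::uword k) {
  const long p = (k - 1) / 2;
  arma::mat P(H * W * B, k * k * C);
  for (arma::uword dy = 0; dy < k; ++dy) {
    for (arma::uword dx = 0; dx < k; ++dx) {
      const arma::uword off = dy * k + dx;
      const long oy = (long)dy - p, ox = (long)dx - p;
      for (arma::uword c = 0; c < C; ++c) {
        double* dst = P.colptr(off * C + c);
        for (arma::uword b = 0; b < B; ++b) {
          for (arma::uword w = 0; w < W; ++w) {
            const long sw = (long)w + ox;
            const arma::uword row0 = H * (w + W * b);
            if (sw < 0 || sw >= (long)W) {
              for (arma::uword h = 0; h < H; ++h) dst[row0 + h] = 0.0;
              continue;
            }
            const double* src = A.memptr() + aidx(0, (arma::uword)sw, b, c, H, W, B);
            for (arma::uword h = 0; h < H; ++h) {
              const long sh = (long)h + oy;
              dst[row0 + h] = (sh < 0 || sh >= (long)H) ? 0.0 : src[sh];
            }
          }
        }
      }
    }
  }
  return P;
}

// scatter-add transpose of im2col
arma::vec col2im(const arma::mat& dP, arma::uword H, arma::uword W,
                 arma::uword B, arma::uword C, arma::uword k) {
  const long p = (k - 1) / 2;
  arma::vec dA(H * W * B * C, arma::fill::zeros);
  for (arma::uword dy = 0; dy < k; ++dy) {
    for (arma::uword dx = 0; dx < k; ++dx) {
      const arma::uword off = dy * k + dx;
      const long oy = (long)dy - p, ox = (long)dx - p;
      for (arma::uword c = 0; c < C; ++c) {
        const double* src = dP.colptr(off * C + c);
        for (arma::uword b = 0; b < B; ++b) {
          for (arma::uword w = 0; w < W; ++w) {
            const long sw = (long)w + ox;
            if (sw < 0 || sw >= (long)W) continue;
            const arma::uword row0 = H * (w + W * b);
            double* dst = dA.memptr() + aidx(0, (arma::uword)sw, b, c, H, W, B);
            for (arma::uword h = 0; h < H; ++h) {
              const long sh = (long)h + oy;
              if (sh >= 0 && sh < (long)H) dst[sh] += src[row0 + h];
            }
          }
        }
      }
    }
  }
  return dA;
}

struct PoolOut {
  arma::vec out;
  arma::uvec argmax;   // flat index into the input array per output element
};

PoolOut maxpool(const arma::vec& A, arma::uword H, arma::uword W,
                arma::uword B, arma::uword C, arma::uword s) {
  const arma::uword Ho = H / s, Wo = W / s;
  PoolOut r;
  r.out.set_size(Ho * Wo * B * C);
  r.argmax.set_size(Ho * Wo * B * C);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword b = 0; b < B; ++b)
      for (arma::uword w = 0; w < Wo; ++w)
        for (arma::uword h = 0; h < Ho; ++h) {
          double best = -arma::datum::inf;
          arma::uword bi = 0;
          for (arma::uword dx = 0; dx < s; ++dx)
            for (arma::uword dy = 0; dy < s; ++dy) {
              const arma::uword ii =
                  aidx(h * s + dy, w * s + dx, b, c, H, W, B);
              if (A[ii] > best) { best = A[ii]; bi = ii; }
            }
          const arma::uword oi = aidx(h, w, b, c, Ho, Wo, B);
          r.out[oi] = best;
          r.argmax[oi] = bi;
        }
  return r;
}

struct LayerCache {
  arma::mat P, relu_mask, xhat;
  arma::rowvec inv;
  arma::uvec argmax;
  arma::uword in_dim[4];
};

struct NetCache {
  LayerCache layer[3];
  arma::mat feats;
  arma::uword feat_dim[4];
};

}  // namespace

// Forward pass. X: B x (H*W) row-major images. Returns features (B x D),
// optional logits and, in training mode, updated running statistics plus
// an external pointer to the layer caches consumed by the backward pass
// (kept C++-side to avoid copying patch matrices into R).
// [[Rcpp::export]]
List cpp_net_forward(const arma::mat& X, List params, List running,
                     IntegerVector input_shape, IntegerVector n_filters,
                     int kernel_size, int pool_size, bool train,
                     bool with_head, double bn_eps, double bn_momentum) {
  const arma::uword B = X.n_rows;
  arma::uword H = input_shape[0], W = input_shape[1];
  const arma::uword k = kernel_size, s = pool_size;

  // input (row-major pixels) -> (H, W, B, 1) layout
  arma::vec A(H * W * B);
  for (arma::uword b = 0; b < B; ++b)
    for (arma::uword w = 0; w < W; ++w)
      for (arma::uword h = 0; h < H; ++h)
        A[aidx(h, w, b, 0, H, W, B)] = X(b, h * W + w);

  arma::uword C = 1;
  XPtr<NetCache> cache(new NetCache(), true);
  List new_running;
  if (train) new_running = clone(running);
  for (int l = 0; l < 3; ++l) {
    const arma::mat Wl = params[std::string("W") + std::to_string(l + 1)];
    const arma::vec bl = params[std::string("b") + std::to_string(l + 1)];
    const arma::vec gamma = params[std::string("gamma") + std::to_string(l + 1)];
    const arma::vec beta = params[std::string("beta") + std::to_string(l + 1)];
    const arma::uword Cout = n_filters[l];

    arma::mat P = im2col(A, H, W, B, C, k);
    arma::mat Z = P * Wl;                     // (H*W*B) x Cout
    Z.each_row() += bl.t();
    arma::mat relu_mask = arma::conv_to<arma::mat>::from(Z > 0);
    arma::mat R = Z % relu_mask;

    // batch norm over all positions per channel
    arma::rowvec mu, v;
    if (train) {
      mu = arma::mean(R, 0);
      arma::mat xc = R.each_row() - mu;
      v = arma::mean(arma::square(xc), 0);
      arma::vec rm = new_running[std::string("mean") + std::to_string(l + 1)];
      arma::vec rv = new_running[std::string("var") + std::to_string(l + 1)];
      rm = (1 - bn_momentum) * rm + bn_momentum * mu.t();
      rv = (1 - bn_momentum) * rv + bn_momentum * v.t();
      new_running[std::string("mean") + std::to_string(l + 1)] = rm;
      new_running[std::string("var") + std::to_string(l + 1)] = rv;
    } else {
      const arma::vec rm = running[std::string("mean") + std::to_string(l + 1)];
      const arma::vec rv = running[std::string("var") + std::to_string(l + 1)];
      mu = rm.t();
      v = rv.t();
    }
    arma::rowvec inv = 1.0 / arma::sqrt(v + bn_eps);
    arma::mat xhat = (R.each_row() - mu).each_row() % inv;
    arma::mat bn_out = (xhat.each_row() % gamma.t()).each_row() + beta.t();

    arma::vec bnv = arma::vectorise(bn_out);
    PoolOut po = maxpool(bnv, H, W, B, Cout, s);

    if (train) {
      LayerCache& lc = cache->layer[l];
      lc.P = std::move(P);
      lc.relu_mask = std::move(relu_mask);
      lc.xhat = std::move(xhat);
      lc.inv = inv;
      lc.argmax = std::move(po.argmax);
      lc.in_dim[0] = H; lc.in_dim[1] = W; lc.in_dim[2] = B; lc.in_dim[3] = C;
    }
    A = po.out;
    H /= s; W /= s; C = Cout;
  }

  // flatten (H, W, B, C) -> B x (H*W*C), feature index h + H*w + H*W*c
  arma::mat feats(B, H * W * C);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword w = 0; w < W; ++w)
      for (arma::uword h = 0; h < H; ++h) {
        const arma::uword j = h + H * (w + W * c);
        for (arma::uword b = 0; b < B; ++b)
          feats(b, j) = A[aidx(h, w, b, c, H, W, B)];
      }

  List out = List::create(_["features"] = feats);
  if (train) {
    cache->feats = feats;
    cache->feat_dim[0] = H; cache->feat_dim[1] = W;
    cache->feat_dim[2] = B; cache->feat_dim[3] = C;
    out["cache_ptr"] = cache;
    out["running"] = new_running;
  }
  if (with_head) {
    const arma::mat Wfc = params["Wfc"];
    const arma::vec bfc = params["bfc"];
    arma::mat logits = feats * Wfc;
    logits.each_row() += bfc.t();
    out["logits"] = logits;
  }
  return out;
}

// Backward pass mirroring cpp_net_forward (training-mode caches required).
// [[Rcpp::export]]
List cpp_net_backward(SEXP cache_ptr, List params,
                      Nullable<arma::mat> dLogits_,
                      Nullable<arma::mat> dFeatures_, int kernel_size,
                      int pool_size) {
  const arma::uword k = kernel_size;
  XPtr<NetCache> cache(cache_ptr);
  const arma::mat& feats = cache->feats;
  const arma::uword B = feats.n_rows;
  List grads;

  arma::mat dF(B, feats.n_cols, arma::fill::zeros);
  if (dFeatures_.isNotNull()) dF += as<arma::mat>(dFeatures_);
  if (dLogits_.isNotNull()) {
    const arma::mat dLogits = as<arma::mat>(dLogits_);
    const arma::mat Wfc = params["Wfc"];
    grads["Wfc"] = feats.t() * dLogits;
    grads["bfc"] = arma::vec(arma::sum(dLogits, 0).t());
    dF += dLogits * Wfc.t();
  }

  // un-flatten to (H, W, B, C)
  arma::uword H = cache->feat_dim[0], W = cache->feat_dim[1],
              C = cache->feat_dim[3];
  arma::vec dA(H * W * B * C);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword w = 0; w < W; ++w)
      for (arma::uword h = 0; h < H; ++h) {
        const arma::uword j = h + H * (w + W * c);
        for (arma::uword b = 0; b < B; ++b)
          dA[aidx(h, w, b, c, H, W, B)] = dF(b, j);
      }

  for (int l = 2; l >= 0; --l) {
    const LayerCache& cl = cache->layer[l];
    const arma::uword Hi = cl.in_dim[0], Wi = cl.in_dim[1], Ci = cl.in_dim[3];
    const arma::mat Wl = params[std::string("W") + std::to_string(l + 1)];
    const arma::vec gamma = params[std::string("gamma") + std::to_string(l + 1)];
    const arma::uword Cout = Wl.n_cols;

    // max pool backward
    arma::vec dBN(Hi * Wi * B * Cout, arma::fill::zeros);
    for (arma::uword i = 0; i < cl.argmax.n_elem; ++i)
      dBN[cl.argmax[i]] += dA[i];

    // batch norm backward (batch statistics)
    arma::mat dM(dBN.memptr(), Hi * Wi * B, Cout, false, true);
    grads[std::string("gamma") + std::to_string(l + 1)] =
        arma::vec(arma::sum(dM % cl.xhat, 0).t());
    grads[std::string("beta") + std::to_string(l + 1)] =
        arma::vec(arma::sum(dM, 0).t());
    arma::mat dxhat = dM.each_row() % gamma.t();
    arma::rowvec m1 = arma::mean(dxhat, 0);
    arma::rowvec m2 = arma::mean(dxhat % cl.xhat, 0);
    arma::mat dR = dxhat;
    dR.each_row() -= m1;
    dR -= cl.xhat.each_row() % m2;
    dR.each_row() %= cl.inv;

    // ReLU backward, then conv backward
    arma::mat dZ = dR % cl.relu_mask;
    grads[std::string("W") + std::to_string(l + 1)] = cl.P.t() * dZ;
    grads[std::string("b") + std::to_string(l + 1)] =
        arma::vec(arma::sum(dZ, 0).t());
    if (l > 0) {
      arma::mat dP = dZ * Wl.t();
      dA = col2im(dP, Hi, Wi, B, Ci, k);
    }
  }
  return grads;
}
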