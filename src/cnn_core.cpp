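// Convolutional network engine for ice-ring plot classification.
//
// Architecture (fixed block structure, sizes configurable):
//   4 x [conv(k x k, same padding) -> BN -> ReLU -> conv -> BN -> ReLU -> maxpool]
//   flatten -> dense -> ReLU -> dropout -> dense -> ReLU -> dropout -> dense(1) -> sigmoid
//
// Convolutions run as im2col + GEMM; an activation cube (H,W,C) aliases the
// (H*W, C) GEMM output, so no transposes or copies are made. All stochastic
// operations (weight init, epoch shuffling, dropout masks) draw from a single
// std::mt19937_64 seeded explicitly, so runs are bit-reproducible on a given
// platform. Single-threaded by design.

#include <RcppArmadillo.h>
#include <random>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Arch {
  int nb;              // number of conv blocks (2 convs each)
  ivec filters;        // output channels per block, length nb
  int k;               // conv kernel size (odd)
  int pool;            // pooling window / stride
  ivec dense;          // two hidden dense sizes
  double dropout;
  bool batch_norm;
  int H0;              // square input side
  int n_conv() const { return 2 * nb; }
  int side(int b) const {        // spatial side entering block b (0-based)
    int s = H0;
    for (int i = 0; i < b; ++i) s /= pool;
    return s;
  }
  int flat_dim() const { return side(nb) * side(nb) * (int)filters(nb - 1); }
  int cin(int j) const {         // input channels of conv layer j (0-based)
    int b = j / 2;
    if (j % 2 == 1) return (int)filters(b);
    return b == 0 ? 1 : (int)filters(b - 1);
  }
  int cout(int j) const { return (int)filters(j / 2); }
};

Arch parse_arch(const Rcpp::List& a) {
  Arch ar;
  ar.nb = Rcpp::as<int>(a["n_blocks"]);
  ar.filters = Rcpp::as<ivec>(a["filters"]);
  ar.k = Rcpp::as<int>(a["kernel"]);
  ar.pool = Rcpp::as<int>(a["pool"]);
  ar.dense = Rcpp::as<ivec>(a["dense"]);
  ar.dropout = Rcpp::as<double>(a["dropout"]);
  ar.batch_norm = Rcpp::as<bool>(a["batch_norm"]);
  ar.H0 = Rcpp::as<int>(a["input_dim"]);
  if (ar.nb < 1 || (int)ar.filters.n_elem != ar.nb)
    Rcpp::stop("filters must have one entry per block");
  if (ar.k % 2 != 1 || ar.k < 1) Rcpp::stop("kernel size must be odd");
  int s = ar.H0;
  for (int b = 0; b < ar.nb; ++b) {
    if (s % ar.pool != 0) Rcpp::stop("input side not divisible by pool at block %d", b + 1);
    s /= ar.pool;
  }
  return ar;
}

struct Params {
  std::vector<mat> convW;  // (Cout, Cin*k*k)
  std::vector<vec> convb;
  std::vector<vec> bn_gamma, bn_beta, bn_rm, bn_rv;
  std::vector<mat> fcW;    // 3 dense layers (last is the sigmoid unit)
  std::vector<vec> fcb;
};

const double BN_EPS = 1e-5;
const double BN_MOM = 0.9;

Params load_params(const Rcpp::List& w, const Arch& ar) {
  Params p;
  char nm[64];
  for (int j = 0; j < ar.n_conv(); ++j) {
    snprintf(nm, sizeof(nm), "conv%d_W", j + 1);
    p.convW.push_back(Rcpp::as<mat>(w[nm]));
    snprintf(nm, sizeof(nm), "conv%d_b", j + 1);
    p.convb.push_back(Rcpp::as<vec>(w[nm]));
    if (ar.batch_norm) {
      snprintf(nm, sizeof(nm), "bn%d_gamma", j + 1);
      p.bn_gamma.push_back(Rcpp::as<vec>(w[nm]));
      snprintf(nm, sizeof(nm), "bn%d_beta", j + 1);
      p.bn_beta.push_back(Rcpp::as<vec>(w[nm]));
      snprintf(nm, sizeof(nm), "bn%d_rm", j + 1);
      p.bn_rm.push_back(Rcpp::as<vec>(w[nm]));
      snprintf(nm, sizeof(nm), "bn%d_rv", j + 1);
      p.bn_rv.push_back(Rcpp::as<vec>(w[nm]));
    }
  }
  for (int j = 0; j < 3; ++j) {
    snprintf(nm, sizeof(nm), "fc%d_W", j + 1);
    p.fcW.push_back(Rcpp::as<mat>(w[nm]));
    snprintf(nm, sizeof(nm), "fc%d_b", j + 1);
    p.fcb.push_back(Rcpp::as<vec>(w[nm]));
  }
  return p;
}

Rcpp::List dump_params(const Params& p, const Arch& ar) {
  Rcpp::List w;
  char nm[64];
  for (int j = 0; j < ar.n_conv(); ++j) {
    snprintf(nm, sizeof(nm), "conv%d_W", j + 1); w[nm] = p.convW[j];
    snprintf(nm, sizeof(nm), "conv%d_b", j + 1); w[nm] = p.convb[j];
    if (ar.batch_norm) {
      snprintf(nm, sizeof(nm), "bn%d_gamma", j + 1); w[nm] = p.bn_gamma[j];
      snprintf(nm, sizeof(nm), "bn%d_beta", j + 1); w[nm] = p.bn_beta[j];
      snprintf(nm, sizeof(nm), "bn%d_rm", j + 1); w[nm] = p.bn_rm[j];
      snprintf(nm, sizeof(nm), "bn%d_rv", j + 1); w[nm] = p.bn_rv[j];
    }
  }
  for (int j = 0; j < 3; ++j) {
    snprintf(nm, sizeof(nm), "fc%d_W", j + 1); w[nm] = p.fcW[j];
    snprintf(nm, sizeof(nm), "fc%d_b", j + 1); w[nm] = p.fcb[j];
  }
  return w;
}

// im2col, transposed layout: (H*W, Cin*k*k), zero padding (k-1)/2, stride 1.
// Column r = c*k*k + dj*k + di holds, at pixel index i + j*H, the input value
// at (i + di - pad, j + dj - pad, c). Runs over i are contiguous in both the
// source slice column and the destination column, so rows copy with memcpy.
void im2colT(const cube& X, int k, mat& Pt) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices, pad = (k - 1) / 2;
  Pt.zeros(H * W, C * k * k);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        double* dst = Pt.colptr(c * k * k + dj * k + di);
        const int i0 = std::max(0, pad - di), i1 = std::min(H, H + pad - di);
        if (i1 <= i0) continue;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          std::memcpy(dst + i0 + j * H,
                      X.slice_colptr(c, sj) + i0 + di - pad,
                      (i1 - i0) * sizeof(double));
        }
      }
    }
  }
}

// Adjoint of im2colT: scatter-add (H*W, C*k*k) patch gradients into a cube.
void col2imT(const mat& Qt, int k, cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices, pad = (k - 1) / 2;
  X.zeros();
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const double* src = Qt.colptr(c * k * k + dj * k + di);
        const int i0 = std::max(0, pad - di), i1 = std::min(H, H + pad - di);
        if (i1 <= i0) continue;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          double* dst = X.slice_colptr(c, sj) + di - pad;
          const double* s = src + j * H;
          for (int i = i0; i < i1; ++i) dst[i] += s[i];
        }
      }
    }
  }
}

struct Caches {
  std::vector<std::vector<cube>> conv_z;   // pre-BN conv outputs, per layer/sample
  std::vector<std::vector<cube>> act;      // post-ReLU activations
  std::vector<vec> bn_mu, bn_istd;
  std::vector<std::vector<ucube>> pool_arg;
  std::vector<std::vector<cube>> pool_out;
  mat X0, h1, h1a, h2, h2a, m1, m2;
  rowvec z3, score;
};

// Forward pass over a batch; fills cc. training=true uses batch BN statistics
// (updating running stats) and applies dropout via rng.
rowvec forward_batch(Params& p, const Arch& ar, const std::vector<cube>& xs,
                     bool training, std::mt19937_64* rng, Caches& cc) {
  const int B = xs.size();
  cc.conv_z.assign(ar.n_conv(), {});
  cc.act.assign(ar.n_conv(), {});
  cc.bn_mu.assign(ar.n_conv(), vec());
  cc.bn_istd.assign(ar.n_conv(), vec());
  cc.pool_arg.assign(ar.nb, {});
  cc.pool_out.assign(ar.nb, {});
  mat Pt;
  for (int b = 0; b < ar.nb; ++b) {
    for (int half = 0; half < 2; ++half) {
      const int j = 2 * b + half;
      const std::vector<cube>& ain =
          (j == 0) ? xs : (half == 1 ? cc.act[j - 1] : cc.pool_out[b - 1]);
      const int H = ain[0].n_rows, W = ain[0].n_cols, C = ar.cout(j);
      cc.conv_z[j].resize(B);
      cc.act[j].resize(B);
      for (int s = 0; s < B; ++s) {
        im2colT(ain[s], ar.k, Pt);
        cube& z = cc.conv_z[j][s];
        z.set_size(H, W, C);
        mat zm(z.memptr(), H * W, C, false, true);
        zm = Pt * p.convW[j].t();
        zm.each_row() += p.convb[j].t();
      }
      vec mu(C, fill::zeros), istd(C, fill::ones);
      if (ar.batch_norm) {
        if (training) {
          const double n = (double)B * H * W;
          for (int c = 0; c < C; ++c) {
            double sm = 0, sq = 0;
            for (int s = 0; s < B; ++s) {
              const double* z = cc.conv_z[j][s].slice_memptr(c);
              for (int i = 0; i < H * W; ++i) { sm += z[i]; sq += z[i] * z[i]; }
            }
            const double m = sm / n, v = std::max(sq / n - m * m, 0.0);
            mu(c) = m; istd(c) = 1.0 / std::sqrt(v + BN_EPS);
            p.bn_rm[j](c) = BN_MOM * p.bn_rm[j](c) + (1 - BN_MOM) * m;
            p.bn_rv[j](c) = BN_MOM * p.bn_rv[j](c) + (1 - BN_MOM) * v;
          }
        } else {
          mu = p.bn_rm[j];
          istd = 1.0 / sqrt(p.bn_rv[j] + BN_EPS);
        }
      }
      cc.bn_mu[j] = mu; cc.bn_istd[j] = istd;
      for (int s = 0; s < B; ++s) {
        cube& a = cc.act[j][s];
        a.set_size(H, W, C);
        for (int c = 0; c < C; ++c) {
          const double g = ar.batch_norm ? p.bn_gamma[j](c) : 1.0;
          const double bt = ar.batch_norm ? p.bn_beta[j](c) : 0.0;
          const double m = mu(c), is = istd(c);
          const double* z = cc.conv_z[j][s].slice_memptr(c);
          double* o = a.slice_memptr(c);
          for (int i = 0; i < H * W; ++i) {
            const double v = g * (z[i] - m) * is + bt;
            o[i] = v > 0 ? v : 0.0;
          }
        }
      }
    }
    // max pool
    const std::vector<cube>& ain = cc.act[2 * b + 1];
    const int H = ain[0].n_rows, C = ain[0].n_slices, P = ar.pool;
    const int Ho = H / P;
    cc.pool_out[b].resize(B);
    cc.pool_arg[b].resize(B);
    for (int s = 0; s < B; ++s) {
      cube& po = cc.pool_out[b][s];
      ucube& am = cc.pool_arg[b][s];
      po.set_size(Ho, Ho, C);
      am.set_size(Ho, Ho, C);
      for (int c = 0; c < C; ++c) {
        const double* S = ain[s].slice_memptr(c);
        for (int jo = 0; jo < Ho; ++jo)
          for (int io = 0; io < Ho; ++io) {
            double best = -datum::inf; uword bi = 0;
            for (int dj = 0; dj < P; ++dj)
              for (int di = 0; di < P; ++di) {
                const uword idx = (io * P + di) + (jo * P + dj) * H;
                if (S[idx] > best) { best = S[idx]; bi = idx; }
              }
            po(io, jo, c) = best;
            am(io, jo, c) = bi;
          }
      }
    }
  }
  // dense part
  const int flat = ar.flat_dim();
  cc.X0.set_size(flat, B);
  for (int s = 0; s < B; ++s)
    std::memcpy(cc.X0.colptr(s), cc.pool_out[ar.nb - 1][s].memptr(), flat * sizeof(double));
  cc.h1 = p.fcW[0] * cc.X0; cc.h1.each_col() += p.fcb[0];
  cc.h1a = clamp(cc.h1, 0.0, datum::inf);
  if (training && ar.dropout > 0) {
    std::uniform_real_distribution<double> U(0.0, 1.0);
    cc.m1.set_size(cc.h1a.n_rows, B);
    for (uword i = 0; i < cc.m1.n_elem; ++i)
      cc.m1(i) = U(*rng) < ar.dropout ? 0.0 : 1.0 / (1.0 - ar.dropout);
    cc.h1a %= cc.m1;
  }
  cc.h2 = p.fcW[1] * cc.h1a; cc.h2.each_col() += p.fcb[1];
  cc.h2a = clamp(cc.h2, 0.0, datum::inf);
  if (training && ar.dropout > 0) {
    std::uniform_real_distribution<double> U(0.0, 1.0);
    cc.m2.set_size(cc.h2a.n_rows, B);
    for (uword i = 0; i < cc.m2.n_elem; ++i)
      cc.m2(i) = U(*rng) < ar.dropout ? 0.0 : 1.0 / (1.0 - ar.dropout);
    cc.h2a %= cc.m2;
  }
  cc.z3 = p.fcW[2] * cc.h2a + p.fcb[2](0);
  cc.score = 1.0 / (1.0 + exp(-cc.z3));
  return cc.score;
}

struct Grads {
  std::vector<mat> convW;
  std::vector<vec> convb, bn_gamma, bn_beta;
  std::vector<mat> fcW;
  std::vector<vec> fcb;
};

Grads zero_grads(const Params& p) {
  Grads g;
  for (auto& W : p.convW) g.convW.push_back(mat(size(W), fill::zeros));
  for (auto& b : p.convb) g.convb.push_back(vec(size(b), fill::zeros));
  for (auto& v : p.bn_gamma) g.bn_gamma.push_back(vec(size(v), fill::zeros));
  for (auto& v : p.bn_beta) g.bn_beta.push_back(vec(size(v), fill::zeros));
  for (auto& W : p.fcW) g.fcW.push_back(mat(size(W), fill::zeros));
  for (auto& b : p.fcb) g.fcb.push_back(vec(size(b), fill::zeros));
  return g;
}

// Backward pass from logit gradients dz3. Fills parameter gradients when g is
// non-null; returns input gradients when want_dx. training selects the
// batch-statistics BN backward; otherwise BN is a fixed per-channel scaling.
std::vector<cube> backward_batch(const Params& p, const Arch& ar,
                                 const std::vector<cube>& xs, const Caches& cc,
                                 rowvec dz3, bool training, bool want_dx, Grads* g) {
  const int B = dz3.n_elem;
  if (g) {
    g->fcW[2] += dz3 * cc.h2a.t();
    g->fcb[2](0) += accu(dz3);
  }
  mat dh2a = p.fcW[2].t() * dz3;
  if (training && ar.dropout > 0) dh2a %= cc.m2;
  mat dh2 = dh2a % conv_to<mat>::from(cc.h2 > 0);
  if (g) { g->fcW[1] += dh2 * cc.h1a.t(); g->fcb[1] += sum(dh2, 1); }
  mat dh1a = p.fcW[1].t() * dh2;
  if (training && ar.dropout > 0) dh1a %= cc.m1;
  mat dh1 = dh1a % conv_to<mat>::from(cc.h1 > 0);
  if (g) { g->fcW[0] += dh1 * cc.X0.t(); g->fcb[0] += sum(dh1, 1); }
  mat dX0 = p.fcW[0].t() * dh1;

  const int sideN = ar.side(ar.nb);
  const int Cn = (int)ar.filters(ar.nb - 1);
  std::vector<cube> da(B);
  for (int s = 0; s < B; ++s)
    da[s] = cube(dX0.colptr(s), sideN, sideN, Cn);

  mat Pt, Qt;
  for (int b = ar.nb - 1; b >= 0; --b) {
    // pool backward
    const int Ho = da[0].n_rows, C = da[0].n_slices;
    const int H = Ho * ar.pool;
    std::vector<cube> dp(B);
    for (int s = 0; s < B; ++s) {
      dp[s].zeros(H, H, C);
      const ucube& am = cc.pool_arg[b][s];
      for (int c = 0; c < C; ++c) {
        double* S = dp[s].slice_memptr(c);
        for (int jo = 0; jo < Ho; ++jo)
          for (int io = 0; io < Ho; ++io)
            S[am(io, jo, c)] += da[s](io, jo, c);
      }
    }
    da = std::move(dp);
    for (int half = 1; half >= 0; --half) {
      const int j = 2 * b + half;
      const int Cj = (int)p.convb[j].n_elem;
      const int Hj = da[0].n_rows, Wj = da[0].n_cols;
      const int npx = Hj * Wj;
      // ReLU backward using cached post-activation
      for (int s = 0; s < B; ++s) {
        double* d = da[s].memptr();
        const double* a = cc.act[j][s].memptr();
        for (uword i = 0; i < da[s].n_elem; ++i)
          if (a[i] <= 0) d[i] = 0;
      }
      if (ar.batch_norm) {
        const vec& mu = cc.bn_mu[j];
        const vec& istd = cc.bn_istd[j];
        for (int c = 0; c < Cj; ++c) {
          double s_dy = 0, s_dyx = 0;
          if (training || g) {
            for (int s = 0; s < B; ++s) {
              const double* d = da[s].slice_memptr(c);
              const double* z = cc.conv_z[j][s].slice_memptr(c);
              for (int i = 0; i < npx; ++i) {
                s_dy += d[i];
                s_dyx += d[i] * (z[i] - mu(c)) * istd(c);
              }
            }
            if (g) { g->bn_beta[j](c) += s_dy; g->bn_gamma[j](c) += s_dyx; }
          }
          const double gi = p.bn_gamma[j](c) * istd(c);
          if (training) {
            const double n = (double)B * npx;
            const double mdy = s_dy / n, mdyx = s_dyx / n;
            for (int s = 0; s < B; ++s) {
              double* d = da[s].slice_memptr(c);
              const double* z = cc.conv_z[j][s].slice_memptr(c);
              for (int i = 0; i < npx; ++i)
                d[i] = gi * (d[i] - mdy - (z[i] - mu(c)) * istd(c) * mdyx);
            }
          } else {
            for (int s = 0; s < B; ++s) {
              double* d = da[s].slice_memptr(c);
              for (int i = 0; i < npx; ++i) d[i] *= gi;
            }
          }
        }
      }
      // conv backward
      const std::vector<cube>& ain =
          (j == 0) ? xs : (half == 1 ? cc.act[j - 1] : cc.pool_out[b - 1]);
      const bool need_dx = (j > 0) || want_dx;
      std::vector<cube> dxs(B);
      for (int s = 0; s < B; ++s) {
        // dZt aliases the gradient cube memory: (H*W, Cout)
        const mat dZt(const_cast<double*>(da[s].memptr()), npx, Cj, false, true);
        if (g) {
          im2colT(ain[s], ar.k, Pt);
          g->convW[j] += dZt.t() * Pt;
          g->convb[j] += sum(dZt, 0).t();
        }
        if (need_dx) {
          Qt = dZt * p.convW[j];   // (H*W, Cin*k*k)
          dxs[s].set_size(ain[s].n_rows, ain[s].n_cols, ain[s].n_slices);
          col2imT(Qt, ar.k, dxs[s]);
        }
      }
      if (need_dx) da = std::move(dxs); else da.clear();
    }
  }
  return da;
}

struct AdamState {
  Grads m, v;
  long t = 0;
};

void adam_step(Params& p, const Grads& g, AdamState& st, double lr, const Arch& ar) {
  st.t += 1;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  const double c1 = 1.0 - std::pow(b1, (double)st.t);
  const double c2 = 1.0 - std::pow(b2, (double)st.t);
  auto upd = [&](mat& w, const mat& gr, mat& m, mat& v) {
    m = b1 * m + (1 - b1) * gr;
    v = b2 * v + (1 - b2) * square(gr);
    w -= lr * (m / c1) / (sqrt(v / c2) + eps);
  };
  auto updv = [&](vec& w, const vec& gr, vec& m, vec& v) {
    m = b1 * m + (1 - b1) * gr;
    v = b2 * v + (1 - b2) * square(gr);
    w -= lr * (m / c1) / (sqrt(v / c2) + eps);
  };
  for (size_t j = 0; j < p.convW.size(); ++j) {
    upd(p.convW[j], g.convW[j], st.m.convW[j], st.v.convW[j]);
    updv(p.convb[j], g.convb[j], st.m.convb[j], st.v.convb[j]);
    if (ar.batch_norm) {
      updv(p.bn_gamma[j], g.bn_gamma[j], st.m.bn_gamma[j], st.v.bn_gamma[j]);
      updv(p.bn_beta[j], g.bn_beta[j], st.m.bn_beta[j], st.v.bn_beta[j]);
    }
  }
  for (int j = 0; j < 3; ++j) {
    upd(p.fcW[j], g.fcW[j], st.m.fcW[j], st.v.fcW[j]);
    updv(p.fcb[j], g.fcb[j], st.m.fcb[j], st.v.fcb[j]);
  }
}

std::vector<cube> slice_batch(const cube& X, const uvec& idx) {
  std::vector<cube> out;
  out.reserve(idx.n_elem);
  for (uword i = 0; i < idx.n_elem; ++i) {
    cube c(X.n_rows, X.n_cols, 1);
    c.slice(0) = X.slice(idx(i));
    out.push_back(c);
  }
  return out;
}

double bce(double p, double y) {
  const double q = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
  return -(y * std::log(q) + (1.0 - y) * std::log(1.0 - q));
}

// weighted mean loss + accuracy over a set, inference mode, batched
void eval_set(Params& p, const Arch& ar, const cube& X, const vec& y, const vec& w,
              double* loss, double* acc) {
  const int N = X.n_slices;
  double L = 0, W = 0; int ok = 0;
  Caches cc;
  for (int s0 = 0; s0 < N; s0 += 64) {
    const int s1 = std::min(N, s0 + 64);
    uvec idx = regspace<uvec>(s0, s1 - 1);
    std::vector<cube> xs = slice_batch(X, idx);
    rowvec sc = forward_batch(p, ar, xs, false, nullptr, cc);
    for (int i = 0; i < (int)sc.n_elem; ++i) {
      L += w(s0 + i) * bce(sc(i), y(s0 + i));
      W += w(s0 + i);
      if ((sc(i) >= 0.5) == (y(s0 + i) >= 0.5)) ++ok;
    }
  }
  *loss = W > 0 ? L / W : 0.0;
  *acc = N > 0 ? (double)ok / N : 0.0;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cnn_init_core(Rcpp::List arch, int seed) {
  Arch ar = parse_arch(arch);
  std::mt19937_64 rng(seed);
  std::normal_distribution<double> N01(0.0, 1.0);
  Params p;
  auto he_mat = [&](int rows, int cols, int fan_in) {
    mat W(rows, cols);
    const double sd = std::sqrt(2.0 / fan_in);
    for (uword i = 0; i < W.n_elem; ++i) W(i) = sd * N01(rng);
    return W;
  };
  for (int j = 0; j < ar.n_conv(); ++j) {
    const int cin = ar.cin(j), cout = ar.cout(j);
    p.convW.push_back(he_mat(cout, cin * ar.k * ar.k, cin * ar.k * ar.k));
    p.convb.push_back(vec(cout, fill::zeros));
    if (ar.batch_norm) {
      p.bn_gamma.push_back(vec(cout, fill::ones));
      p.bn_beta.push_back(vec(cout, fill::zeros));
      p.bn_rm.push_back(vec(cout, fill::zeros));
      p.bn_rv.push_back(vec(cout, fill::ones));
    }
  }
  const int flat = ar.flat_dim();
  p.fcW.push_back(he_mat(ar.dense(0), flat, flat));
  p.fcb.push_back(vec(ar.dense(0), fill::zeros));
  p.fcW.push_back(he_mat(ar.dense(1), ar.dense(0), ar.dense(0)));
  p.fcb.push_back(vec(ar.dense(1), fill::zeros));
  p.fcW.push_back(he_mat(1, ar.dense(1), ar.dense(1)));
  p.fcb.push_back(vec(1, fill::zeros));
  return dump_params(p, ar);
}

// [[Rcpp::export]]
arma::vec cnn_predict_core(Rcpp::List weights, Rcpp::List arch, const arma::cube& X) {
  Arch ar = parse_arch(arch);
  Params p = load_params(weights, ar);
  const int N = X.n_slices;
  vec out(N);
  Caches cc;
  for (int s0 = 0; s0 < N; s0 += 64) {
    const int s1 = std::min(N, s0 + 64);
    std::vector<cube> xs = slice_batch(X, regspace<uvec>(s0, s1 - 1));
    rowvec sc = forward_batch(p, ar, xs, false, nullptr, cc);
    for (int i = 0; i < (int)sc.n_elem; ++i) out(s0 + i) = sc(i);
  }
  return out;
}

// Gradient of the sigmoid score with respect to each input pixel (inference
// mode: running BN statistics, no dropout). Returns one slice per sample.
// [[Rcpp::export]]
arma::cube cnn_input_grad_core(Rcpp::List weights, Rcpp::List arch, const arma::cube& X) {
  Arch ar = parse_arch(arch);
  Params p = load_params(weights, ar);
  const int N = X.n_slices;
  cube out(X.n_rows, X.n_cols, N);
  for (int s0 = 0; s0 < N; s0 += 32) {
    const int s1 = std::min(N, s0 + 32);
    std::vector<cube> xs = slice_batch(X, regspace<uvec>(s0, s1 - 1));
    Caches cc;
    rowvec sc = forward_batch(p, ar, xs, false, nullptr, cc);
    rowvec dz3 = sc % (1.0 - sc);   // d score / d logit
    std::vector<cube> dx = backward_batch(p, ar, xs, cc, dz3, false, true, nullptr);
    for (int i = 0; i < (int)dx.size(); ++i) out.slice(s0 + i) = dx[i].slice(0);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cnn_train_core(Rcpp::List weights, Rcpp::List arch,
                          const arma::cube& Xtr, const arma::vec& ytr, const arma::vec& wtr,
                          const arma::cube& Xval, const arma::vec& yval, const arma::vec& wval,
                          int epochs, int batch, double lr, int seed, bool verbose) {
  Arch ar = parse_arch(arch);
  Params p = load_params(weights, ar);
  const int N = Xtr.n_slices;
  const bool has_val = Xval.n_slices > 0;
  std::mt19937_64 rng(seed);
  AdamState st;
  st.m = zero_grads(p); st.v = zero_grads(p);

  std::vector<double> h_loss, h_acc, h_vloss, h_vacc;
  Params best = p;
  double best_vloss = datum::inf;
  std::vector<uword> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  Caches cc;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double epL = 0, epW = 0; int ok = 0;
    for (int s0 = 0; s0 < N; s0 += batch) {
      const int s1 = std::min(N, s0 + batch);
      uvec idx(s1 - s0);
      for (int i = s0; i < s1; ++i) idx(i - s0) = order[i];
      std::vector<cube> xs = slice_batch(Xtr, idx);
      rowvec sc = forward_batch(p, ar, xs, true, &rng, cc);
      const int B = sc.n_elem;
      rowvec dz3(B);
      double sw = 0;
      for (int i = 0; i < B; ++i) sw += wtr(idx(i));
      for (int i = 0; i < B; ++i) {
        const double y = ytr(idx(i)), w = wtr(idx(i));
        dz3(i) = w * (sc(i) - y) / sw;
        epL += w * bce(sc(i), y); epW += w;
        if ((sc(i) >= 0.5) == (y >= 0.5)) ++ok;
      }
      Grads g = zero_grads(p);
      backward_batch(p, ar, xs, cc, dz3, true, false, &g);
      adam_step(p, g, st, lr, ar);
    }
    h_loss.push_back(epW > 0 ? epL / epW : 0.0);
    h_acc.push_back((double)ok / N);
    if (has_val) {
      double vl, va;
      eval_set(p, ar, Xval, yval, wval, &vl, &va);
      h_vloss.push_back(vl); h_vacc.push_back(va);
      if (vl < best_vloss) { best_vloss = vl; best = p; }
    } else {
      h_vloss.push_back(NA_REAL); h_vacc.push_back(NA_REAL);
      best = p;
    }
    if (verbose)
      Rcpp::Rcout << "epoch " << (ep + 1) << "/" << epochs
                  << "  loss " << h_loss.back() << "  acc " << h_acc.back()
                  << (has_val ? "  val_loss " + std::to_string(h_vloss.back()) : "")
                  << std::endl;
    Rcpp::checkUserInterrupt();
  }
  if (epochs == 0) best = p;
  return Rcpp::List::create(
      Rcpp::Named("weights") = dump_params(best, ar),
      Rcpp::Named("final_weights") = dump_params(p, ar),
      Rcpp::Named("history") = Rcpp::DataFrame::create(
          Rcpp::Named("epoch") = Rcpp::seq_len(epochs),
          Rcpp::Named("loss") = h_loss,
          Rcpp::Named("accuracy") = h_acc,
          Rcpp::Named("val_loss") = h_vloss,
          Rcpp::Named("val_accuracy") = h_vacc));
}
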