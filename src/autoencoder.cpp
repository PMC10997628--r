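// Compact 3D convolutional autoencoder engine.
//
// Layout conventions (must match the R side):
//  - volumes are flattened column-major, x fastest: idx = x + nx*(y + ny*z)
//  - a batch activation is an fmat of shape (B*nvox) x C, sample-major row blocks
//  - conv k=3 weights: (27*cin) x cout, row index c*27 + o,
//    offset o = (dz+1)*9 + (dy+1)*3 + (dx+1)
//  - transposed-conv k=2 s=2 weights: (8*cin) x cout, row index o*cin + c,
//    offset o = oz*4 + oy*2 + ox
//  - fully connected flatten stacks channels: [c0 voxels, c1 voxels, ...]
// All heavy lifting is float32 GEMM through BLAS.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <cstring>

using namespace Rcpp;
using namespace arma;

struct D3 {
  int x, y, z;
  long n() const { return (long)x * y * z; }
};

struct Cfg {
  D3 orig, pad;
  int nb, latent;
  std::vector<int> w;
  float slope;
  bool sum_loss;
  float bn_eps, bn_mom;
};

enum UType { CONV3, CONV1, BN, LRELU, POOL, TCONV, FCENC, FCDEC };

struct Unit {
  UType t;
  D3 din, dout;
  int cin, cout;
  int p;  // first parameter index
};

struct Plan {
  std::vector<Unit> units;
  std::vector<std::string> pnames;
  std::vector<std::pair<long, long>> pshapes;
  std::vector<bool> trainable;
  int enc_end;  // unit index of FCENC; encoder = units[0..enc_end]
};

static Cfg parse_cfg(const List& cfg) {
  Cfg c;
  IntegerVector d = cfg["input_shape"], p = cfg["padded_shape"];
  c.orig = {d[0], d[1], d[2]};
  c.pad = {p[0], p[1], p[2]};
  c.nb = as<int>(cfg["n_blocks"]);
  c.latent = as<int>(cfg["latent_dim"]);
  IntegerVector wv = cfg["channel_widths"];
  c.w.assign(wv.begin(), wv.end());
  c.slope = as<double>(cfg["negative_slope"]);
  c.sum_loss = as<std::string>(cfg["loss_reduction"]) == "sum";
  c.bn_eps = 1e-5f;
  c.bn_mom = 0.1f;
  return c;
}

static void add_param(Plan& pl, const std::string& nm, long r, long co, bool tr) {
  pl.pnames.push_back(nm);
  pl.pshapes.push_back({r, co});
  pl.trainable.push_back(tr);
}

// conv(k3) -> BN -> LeakyReLU
static void add_conv_unit(Plan& pl, const std::string& nm, int cin, int cout, D3 d) {
  int p = (int)pl.pnames.size();
  add_param(pl, nm + "_W", 27L * cin, cout, true);
  add_param(pl, nm + "_b", 1, cout, true);
  pl.units.push_back({CONV3, d, d, cin, cout, p});
  p = (int)pl.pnames.size();
  add_param(pl, nm + "_bn_gamma", 1, cout, true);
  add_param(pl, nm + "_bn_beta", 1, cout, true);
  add_param(pl, nm + "_bn_rm", 1, cout, false);
  add_param(pl, nm + "_bn_rv", 1, cout, false);
  pl.units.push_back({BN, d, d, cout, cout, p});
  pl.units.push_back({LRELU, d, d, cout, cout, -1});
}

static Plan build_plan(const Cfg& c) {
  Plan pl;
  D3 d = c.pad;
  add_conv_unit(pl, "enc0a", 1, c.w[0], d);
  add_conv_unit(pl, "enc0b", c.w[0], c.w[0], d);
  for (int e = 1; e <= c.nb; ++e) {
    D3 h = {d.x / 2, d.y / 2, d.z / 2};
    pl.units.push_back({POOL, d, h, c.w[e - 1], c.w[e - 1], -1});
    d = h;
    char nm[32];
    snprintf(nm, sizeof(nm), "enc%da", e);
    add_conv_unit(pl, nm, c.w[e - 1], c.w[e], d);
    snprintf(nm, sizeof(nm), "enc%db", e);
    add_conv_unit(pl, nm, c.w[e], c.w[e], d);
  }
  long flat = d.n() * c.w[c.nb];
  int p = (int)pl.pnames.size();
  add_param(pl, "fc_enc_W", flat, c.latent, true);
  add_param(pl, "fc_enc_b", 1, c.latent, true);
  pl.units.push_back({FCENC, d, {1, 1, 1}, c.w[c.nb], c.latent, p});
  pl.enc_end = (int)pl.units.size() - 1;

  p = (int)pl.pnames.size();
  add_param(pl, "fc_dec_W", c.latent, flat, true);
  add_param(pl, "fc_dec_b", 1, flat, true);
  pl.units.push_back({FCDEC, {1, 1, 1}, d, c.latent, c.w[c.nb], p});
  for (int e = c.nb; e >= 1; --e) {
    char nm[32];
    snprintf(nm, sizeof(nm), "dec%da", e);
    add_conv_unit(pl, nm, c.w[e], c.w[e], d);
    snprintf(nm, sizeof(nm), "dec%db", e);
    add_conv_unit(pl, nm, c.w[e], c.w[e], d);
    D3 u = {d.x * 2, d.y * 2, d.z * 2};
    p = (int)pl.pnames.size();
    snprintf(nm, sizeof(nm), "tconv%d", e);
    add_param(pl, std::string(nm) + "_W", 8L * c.w[e], c.w[e - 1], true);
    add_param(pl, std::string(nm) + "_b", 1, c.w[e - 1], true);
    pl.units.push_back({TCONV, d, u, c.w[e], c.w[e - 1], p});
    d = u;
  }
  add_conv_unit(pl, "fina", c.w[0], c.w[0], d);
  add_conv_unit(pl, "finb", c.w[0], c.w[0], d);
  p = (int)pl.pnames.size();
  add_param(pl, "out_W", c.w[0], 1, true);
  add_param(pl, "out_b", 1, 1, true);
  pl.units.push_back({CONV1, d, d, c.w[0], 1, p});
  return pl;
}

// ---- primitive ops -------------------------------------------------------

#if defined(__GNUC__) && defined(__x86_64__)
#define UDIP_HOT __attribute__((target_clones("default", "arch=haswell")))
#else
#define UDIP_HOT
#endif


// Direct 3x3x3 convolution kernels. Each sample's channels are copied into
// a zero-bordered buffer so the inner loops carry no bounds checks; with the
// small channel counts used here the working set stays in cache, which is
// far cheaper than materialising an im2col matrix.

// Pc: (dx+2)(dy+2)(dz+2) x C zero-bordered copy of sample s of A
static void pad_sample(const fmat& A, D3 d, int s, fmat& Pc) {
  int px = d.x + 2, py = d.y + 2, pz = d.z + 2;
  Pc.zeros((long)px * py * pz, A.n_cols);
  long nv = d.n();
  for (uword c = 0; c < A.n_cols; ++c) {
    const float* src = A.colptr(c) + (long)s * nv;
    float* dst = Pc.colptr(c);
    for (int z = 0; z < d.z; ++z)
      for (int y = 0; y < d.y; ++y)
        std::memcpy(dst + 1 + (long)px * ((y + 1) + (long)py * (z + 1)),
                    src + (long)d.x * (y + (long)d.y * z), sizeof(float) * d.x);
  }
}

// out(t, co) = bias(co) + sum_{c,o} W(c*27+o, co) * A(t + offset(o), c)
UDIP_HOT static void conv3_fwd(const fmat& A, D3 d, int B, const fmat& W,
                      const fmat& bias, fmat& out, fmat& Pc) {
  int cin = (int)A.n_cols, cout = (int)W.n_cols;
  long nv = d.n();
  out.set_size((long)B * nv, cout);
  int px = d.x + 2, py = d.y + 2;
  for (int s = 0; s < B; ++s) {
    pad_sample(A, d, s, Pc);
    for (int co = 0; co < cout; ++co) {
      float* ocol = out.colptr(co) + (long)s * nv;
      const float b = bias(0, co);
      const float* wcol = W.colptr(co);
      for (int z = 0; z < d.z; ++z)
        for (int y = 0; y < d.y; ++y) {
          float* orow = ocol + (long)d.x * (y + (long)d.y * z);
          for (int x = 0; x < d.x; ++x) orow[x] = b;
          for (int c = 0; c < cin; ++c) {
            const float* base = Pc.colptr(c);
            const float* wc = wcol + (long)c * 27;
            for (int dz = 0; dz < 3; ++dz)
              for (int dy = 0; dy < 3; ++dy) {
                const float* srow =
                    base + (long)px * ((y + dy) + (long)py * (z + dz));
                const float w0 = wc[dz * 9 + dy * 3 + 0];
                const float w1 = wc[dz * 9 + dy * 3 + 1];
                const float w2 = wc[dz * 9 + dy * 3 + 2];
                for (int x = 0; x < d.x; ++x)
                  orow[x] += w0 * srow[x] + w1 * srow[x + 1] + w2 * srow[x + 2];
              }
          }
        }
    }
  }
}

// dW(c*27+o, co) += sum_t A(t + offset(o), c) * dOut(t, co); db += col sums
UDIP_HOT static void conv3_dw(const fmat& A, const fmat& dOut, D3 d, int B, fmat& gW,
                     fmat& gb, fmat& Pc) {
  int cin = (int)A.n_cols, cout = (int)dOut.n_cols;
  long nv = d.n();
  int px = d.x + 2, py = d.y + 2;
  for (int s = 0; s < B; ++s) {
    pad_sample(A, d, s, Pc);
    for (int co = 0; co < cout; ++co) {
      const float* docol = dOut.colptr(co) + (long)s * nv;
      for (int c = 0; c < cin; ++c) {
        const float* base = Pc.colptr(c);
        float* gw = gW.colptr(co) + (long)c * 27;
        for (int dz = 0; dz < 3; ++dz)
          for (int dy = 0; dy < 3; ++dy) {
            double a0 = 0, a1 = 0, a2 = 0;
            for (int z = 0; z < d.z; ++z)
              for (int y = 0; y < d.y; ++y) {
                const float* srow =
                    base + (long)px * ((y + dy) + (long)py * (z + dz));
                const float* dorow = docol + (long)d.x * (y + (long)d.y * z);
                float r0 = 0, r1 = 0, r2 = 0;
                for (int x = 0; x < d.x; ++x) {
                  r0 += srow[x] * dorow[x];
                  r1 += srow[x + 1] * dorow[x];
                  r2 += srow[x + 2] * dorow[x];
                }
                a0 += r0; a1 += r1; a2 += r2;
              }
            gw[dz * 9 + dy * 3 + 0] += (float)a0;
            gw[dz * 9 + dy * 3 + 1] += (float)a1;
            gw[dz * 9 + dy * 3 + 2] += (float)a2;
          }
      }
    }
  }
  gb.row(0) += sum(dOut, 0);
}

// gradient w.r.t. the input: a convolution of dOut with the flipped,
// transposed kernel. flip(o) = 26 - o.
static fmat conv3_weight_flip(const fmat& W, int cin, int cout) {
  fmat W2(27L * cout, cin);
  for (int c = 0; c < cin; ++c)
    for (int o = 0; o < 27; ++o)
      for (int co = 0; co < cout; ++co)
        W2((long)co * 27 + (26 - o), c) = W((long)c * 27 + o, co);
  return W2;
}

static void pool_fwd(const fmat& A, D3 d, int B, fmat& out, umat& amax) {
  D3 h = {d.x / 2, d.y / 2, d.z / 2};
  long nvi = d.n(), nvo = h.n();
  int C = (int)A.n_cols;
  out.set_size((long)B * nvo, C);
  amax.set_size((long)B * nvo, C);
  for (int c = 0; c < C; ++c) {
    const float* src = A.colptr(c);
    float* dst = out.colptr(c);
    uword* am = amax.colptr(c);
    for (int s = 0; s < B; ++s)
      for (int z = 0; z < h.z; ++z)
        for (int y = 0; y < h.y; ++y)
          for (int x = 0; x < h.x; ++x) {
            long oi = (long)s * nvo + x + (long)h.x * (y + (long)h.y * z);
            float best = -std::numeric_limits<float>::infinity();
            long bi = 0;
            for (int oz = 0; oz < 2; ++oz)
              for (int oy = 0; oy < 2; ++oy)
                for (int ox = 0; ox < 2; ++ox) {
                  long ii = (long)s * nvi + (2 * x + ox) +
                            (long)d.x * ((2 * y + oy) + (long)d.y * (2 * z + oz));
                  if (src[ii] > best) { best = src[ii]; bi = ii; }
                }
            dst[oi] = best;
            am[oi] = (uword)bi;
          }
  }
}

// scatter rows of P (B*nvi x cout) into out at 2x+ox etc. for offset o
static void tconv_scatter(const fmat& P, D3 din, int B, int o, fmat& out) {
  D3 u = {din.x * 2, din.y * 2, din.z * 2};
  int ox = o % 2, oy = (o / 2) % 2, oz = o / 4;
  long nvi = din.n(), nvo = u.n();
  for (uword c = 0; c < P.n_cols; ++c) {
    const float* src = P.colptr(c);
    float* dst = out.colptr(c);
    for (int s = 0; s < B; ++s)
      for (int z = 0; z < din.z; ++z)
        for (int y = 0; y < din.y; ++y) {
          const float* srow = src + (long)s * nvi + (long)din.x * (y + (long)din.y * z);
          float* drow = dst + (long)s * nvo + ox +
                        (long)u.x * ((2 * y + oy) + (long)u.y * (2 * z + oz));
          for (int x = 0; x < din.x; ++x) drow[2 * x] += srow[x];
        }
  }
}

static void tconv_gather(const fmat& dOut, D3 din, int B, int o, fmat& G) {
  D3 u = {din.x * 2, din.y * 2, din.z * 2};
  int ox = o % 2, oy = (o / 2) % 2, oz = o / 4;
  long nvi = din.n(), nvo = u.n();
  G.set_size((long)B * nvi, dOut.n_cols);
  for (uword c = 0; c < dOut.n_cols; ++c) {
    const float* src = dOut.colptr(c);
    float* dst = G.colptr(c);
    for (int s = 0; s < B; ++s)
      for (int z = 0; z < din.z; ++z)
        for (int y = 0; y < din.y; ++y) {
          float* drow = dst + (long)s * nvi + (long)din.x * (y + (long)din.y * z);
          const float* srow = src + (long)s * nvo + ox +
                              (long)u.x * ((2 * y + oy) + (long)u.y * (2 * z + oz));
          for (int x = 0; x < din.x; ++x) drow[x] = srow[2 * x];
        }
  }
}

// ---- forward / backward --------------------------------------------------

struct Caches {
  std::vector<frowvec> mu;    // BN batch mean
  std::vector<frowvec> istd;  // BN inverse std
  std::vector<umat> amax;     // POOL
  std::vector<fmat> flat;     // FCENC flattened input
  void resize(size_t n) { mu.resize(n); istd.resize(n); amax.resize(n); flat.resize(n); }
};

static void run_forward(const Plan& pl, int from, int to, std::vector<fmat>& P,
                        std::vector<fmat>& buf, Caches& ca, int B, bool training,
                        const Cfg& cfg, fmat& col) {
  for (int k = from; k <= to; ++k) {
    const Unit& u = pl.units[k];
    const fmat& A = buf[k - from];
    fmat out;
    switch (u.t) {
      case CONV3: {
        conv3_fwd(A, u.din, B, P[u.p], P[u.p + 1], out, col);
        break;
      }
      case CONV1: {
        out = A * P[u.p];
        out.each_row() += P[u.p + 1].row(0);
        break;
      }
      case BN: {
        frowvec mu, sig2;
        if (training) {
          mu = mean(A, 0);
          sig2 = mean(square(A), 0) - square(mu);
          P[u.p + 2].row(0) = (1.f - cfg.bn_mom) * P[u.p + 2].row(0) + cfg.bn_mom * mu;
          P[u.p + 3].row(0) = (1.f - cfg.bn_mom) * P[u.p + 3].row(0) + cfg.bn_mom * sig2;
        } else {
          mu = P[u.p + 2].row(0);
          sig2 = P[u.p + 3].row(0);
        }
        frowvec istd = 1.f / sqrt(sig2 + cfg.bn_eps);
        out.set_size(A.n_rows, A.n_cols);
        for (uword c = 0; c < A.n_cols; ++c) {
          const float a = P[u.p](0, c) * istd(c);  // gamma * istd
          const float b2 = P[u.p + 1](0, c) - a * mu(c);
          const float* src = A.colptr(c);
          float* dst = out.colptr(c);
          for (uword r = 0; r < A.n_rows; ++r) dst[r] = a * src[r] + b2;
        }
        if (training) { ca.mu[k] = std::move(mu); ca.istd[k] = std::move(istd); }
        break;
      }
      case LRELU: {
        out = arma::max(A, cfg.slope * A);
        break;
      }
      case POOL: {
        umat am;
        pool_fwd(A, u.din, B, out, am);
        if (training) ca.amax[k] = std::move(am);
        break;
      }
      case TCONV: {
        out.zeros((long)B * u.dout.n(), u.cout);
        for (int o = 0; o < 8; ++o) {
          fmat Pm = A * P[u.p].rows((long)o * u.cin, (long)o * u.cin + u.cin - 1);
          tconv_scatter(Pm, u.din, B, o, out);
        }
        out.each_row() += P[u.p + 1].row(0);
        break;
      }
      case FCENC: {
        long nv = u.din.n();
        fmat F(B, nv * u.cin);
        for (int s = 0; s < B; ++s)
          F.row(s) = vectorise(A.rows((long)s * nv, (long)s * nv + nv - 1)).t();
        out = F * P[u.p];
        out.each_row() += P[u.p + 1].row(0);
        ca.flat[k] = std::move(F);
        break;
      }
      case FCDEC: {
        long nv = u.dout.n();
        fmat F = A * P[u.p];
        F.each_row() += P[u.p + 1].row(0);
        out.set_size((long)B * nv, u.cout);
        for (int s = 0; s < B; ++s)
          out.rows((long)s * nv, (long)s * nv + nv - 1) =
              reshape(F.row(s).t(), nv, u.cout);
        break;
      }
    }
    buf.push_back(std::move(out));
  }
}

static void run_backward(const Plan& pl, int from, int to, std::vector<fmat>& P,
                         std::vector<fmat>& buf, Caches& ca, std::vector<fmat>& G,
                         fmat& dOut, int B, const Cfg& cfg, fmat& col) {
  for (int k = to; k >= from; --k) {
    const Unit& u = pl.units[k];
    const fmat& A = buf[k - from];
    fmat dIn;
    switch (u.t) {
      case CONV3: {
        conv3_dw(A, dOut, u.din, B, G[u.p], G[u.p + 1], col);
        fmat W2 = conv3_weight_flip(P[u.p], u.cin, u.cout);
        fmat zb(1, u.cin, fill::zeros);
        conv3_fwd(dOut, u.din, B, W2, zb, dIn, col);
        break;
      }
      case CONV1: {
        G[u.p] += A.t() * dOut;
        G[u.p + 1].row(0) += sum(dOut, 0);
        dIn = dOut * P[u.p].t();
        break;
      }
      case BN: {
        const frowvec& mu = ca.mu[k];
        const frowvec& istd = ca.istd[k];
        const long n = (long)A.n_rows;
        dIn.set_size(A.n_rows, A.n_cols);
        for (uword c = 0; c < A.n_cols; ++c) {
          const float g = P[u.p](0, c), is = istd(c), m = mu(c);
          const float* a = A.colptr(c);
          const float* dy = dOut.colptr(c);
          float* di = dIn.colptr(c);
          double sdy = 0, sdyx = 0;
          for (long r = 0; r < n; ++r) {
            const float xh = (a[r] - m) * is;
            sdy += dy[r];
            sdyx += dy[r] * xh;
          }
          G[u.p](0, c) += (float)sdyx;
          G[u.p + 1](0, c) += (float)sdy;
          const float m1 = (float)(g * sdy / n), m2 = (float)(g * sdyx / n);
          for (long r = 0; r < n; ++r) {
            const float xh = (a[r] - m) * is;
            di[r] = is * (g * dy[r] - m1 - xh * m2);
          }
        }
        break;
      }
      case LRELU: {
        const fmat& out = buf[k - from + 1];
        dIn.set_size(dOut.n_rows, dOut.n_cols);
        const float* o = out.memptr();
        const float* dy = dOut.memptr();
        float* di = dIn.memptr();
        const long nel = (long)dOut.n_elem;
        // derivative 1 where the pre-activation (equivalently the output)
        // is positive, `slope` otherwise
        for (long i = 0; i < nel; ++i) di[i] = o[i] > 0 ? dy[i] : cfg.slope * dy[i];
        break;
      }
      case POOL: {
        const umat& am = ca.amax[k];
        dIn.zeros((long)B * u.din.n(), u.cin);
        for (uword c = 0; c < dOut.n_cols; ++c) {
          float* dst = dIn.colptr(c);
          const float* src = dOut.colptr(c);
          const uword* amc = am.colptr(c);
          for (uword r = 0; r < dOut.n_rows; ++r) dst[amc[r]] += src[r];
        }
        break;
      }
      case TCONV: {
        dIn.zeros((long)B * u.din.n(), u.cin);
        fmat Gm;
        for (int o = 0; o < 8; ++o) {
          tconv_gather(dOut, u.din, B, o, Gm);
          G[u.p].rows((long)o * u.cin, (long)o * u.cin + u.cin - 1) += A.t() * Gm;
          dIn += Gm * P[u.p].rows((long)o * u.cin, (long)o * u.cin + u.cin - 1).t();
        }
        G[u.p + 1].row(0) += sum(dOut, 0);
        break;
      }
      case FCENC: {
        const fmat& F = ca.flat[k];
        G[u.p] += F.t() * dOut;
        G[u.p + 1].row(0) += sum(dOut, 0);
        fmat dF = dOut * P[u.p].t();
        long nv = u.din.n();
        dIn.set_size((long)B * nv, u.cin);
        for (int s = 0; s < B; ++s)
          dIn.rows((long)s * nv, (long)s * nv + nv - 1) =
              reshape(dF.row(s).t(), nv, u.cin);
        break;
      }
      case FCDEC: {
        long nv = u.dout.n();
        fmat dF(B, nv * u.cout);
        for (int s = 0; s < B; ++s)
          dF.row(s) = vectorise(dOut.rows((long)s * nv, (long)s * nv + nv - 1)).t();
        G[u.p] += A.t() * dF;
        G[u.p + 1].row(0) += sum(dF, 0);
        dIn = dF * P[u.p].t();
        break;
      }
    }
    dOut = std::move(dIn);
  }
}

// ---- padding helpers -----------------------------------------------------

static void pad_column(const double* src, float* dst, const Cfg& c) {
  int ox = (c.pad.x - c.orig.x) / 2, oy = (c.pad.y - c.orig.y) / 2,
      oz = (c.pad.z - c.orig.z) / 2;
  std::memset(dst, 0, sizeof(float) * c.pad.n());
  for (int z = 0; z < c.orig.z; ++z)
    for (int y = 0; y < c.orig.y; ++y) {
      const double* s = src + (long)c.orig.x * (y + (long)c.orig.y * z);
      float* d = dst + ox + (long)c.pad.x * ((y + oy) + (long)c.pad.y * (z + oz));
      for (int x = 0; x < c.orig.x; ++x) d[x] = (float)s[x];
    }
}

static void crop_column(const float* src, double* dst, const Cfg& c) {
  int ox = (c.pad.x - c.orig.x) / 2, oy = (c.pad.y - c.orig.y) / 2,
      oz = (c.pad.z - c.orig.z) / 2;
  for (int z = 0; z < c.orig.z; ++z)
    for (int y = 0; y < c.orig.y; ++y) {
      const float* s = src + ox + (long)c.pad.x * ((y + oy) + (long)c.pad.y * (z + oz));
      double* d = dst + (long)c.orig.x * (y + (long)c.orig.y * z);
      for (int x = 0; x < c.orig.x; ++x) d[x] = s[x];
    }
}

static std::vector<fmat> params_in(const List& params) {
  std::vector<fmat> P(params.size());
  for (int i = 0; i < params.size(); ++i) {
    NumericMatrix m = params[i];
    P[i] = conv_to<fmat>::from(mat(m.begin(), m.nrow(), m.ncol(), false));
  }
  return P;
}

static List params_out(const std::vector<fmat>& P, const CharacterVector& nms) {
  List out(P.size());
  for (size_t i = 0; i < P.size(); ++i) {
    mat m = conv_to<mat>::from(P[i]);
    out[i] = wrap(m);
  }
  out.attr("names") = nms;
  return out;
}

// ---- exported API --------------------------------------------------------

// [[Rcpp::export]]
List cpp_ae_param_shapes(List cfg) {
  Cfg c = parse_cfg(cfg);
  Plan pl = build_plan(c);
  List shapes(pl.pshapes.size());
  for (size_t i = 0; i < pl.pshapes.size(); ++i)
    shapes[i] = IntegerVector::create((int)pl.pshapes[i].first,
                                      (int)pl.pshapes[i].second);
  shapes.attr("names") = wrap(pl.pnames);
  return List::create(_["shapes"] = shapes, _["trainable"] = wrap(pl.trainable));
}

// [[Rcpp::export]]
List cpp_ae_train(List params, NumericMatrix X, NumericMatrix M, List cfg,
                  IntegerVector train_idx, IntegerVector val_idx, int epochs,
                  int batch_size, double lr, int seed, bool verbose = false) {
  Cfg c = parse_cfg(cfg);
  Plan pl = build_plan(c);
  std::vector<fmat> P = params_in(params);
  int N = X.ncol();
  long nvp = c.pad.n();

  fmat Xp(nvp, N), Mp(nvp, N);
  fvec mcount(N);
  for (int i = 0; i < N; ++i) {
    pad_column(&X(0, i), Xp.colptr(i), c);
    pad_column(&M(0, i), Mp.colptr(i), c);
    mcount(i) = accu(Mp.col(i));
    if (mcount(i) <= 0) stop("volume %d has an empty mask", i + 1);
  }

  std::vector<fmat> Gr(P.size()), Am(P.size()), Av(P.size());
  for (size_t i = 0; i < P.size(); ++i) {
    Gr[i].zeros(P[i].n_rows, P[i].n_cols);
    if (pl.trainable[i]) {
      Am[i].zeros(P[i].n_rows, P[i].n_cols);
      Av[i].zeros(P[i].n_rows, P[i].n_cols);
    }
  }
  const float b1 = 0.9f, b2 = 0.999f, aeps = 1e-8f;
  long step = 0;

  std::vector<int> tr(train_idx.begin(), train_idx.end());
  std::vector<int> va(val_idx.begin(), val_idx.end());
  std::mt19937 rng((unsigned)seed);

  std::vector<double> hist_tr, hist_va;
  std::vector<fmat> bestP;
  double best_val = datum::inf;
  int best_epoch = -1;
  fmat col;
  int nunits = (int)pl.units.size();

  auto eval_loss = [&](const std::vector<int>& idx) {
    double tot = 0;
    long nv = 0;
    int eb = std::max(batch_size, 2);
    for (size_t s0 = 0; s0 < idx.size(); s0 += eb) {
      int B = (int)std::min((size_t)eb, idx.size() - s0);
      fmat Xb(nvp * B, 1);
      for (int s = 0; s < B; ++s)
        Xb.rows((long)s * nvp, (long)(s + 1) * nvp - 1) = Xp.col(idx[s0 + s]);
      std::vector<fmat> buf;
      buf.reserve(nunits + 1);
      buf.push_back(std::move(Xb));
      Caches ca;
      ca.resize(nunits);
      run_forward(pl, 0, nunits - 1, P, buf, ca, B, false, c, col);
      const fmat& R = buf.back();
      for (int s = 0; s < B; ++s) {
        int i = idx[s0 + s];
        double l = 0;
        const float* r = R.colptr(0) + (long)s * nvp;
        const float* o = Xp.colptr(i);
        const float* f = Mp.colptr(i);
        for (long v = 0; v < nvp; ++v) {
          double d = (r[v] - o[v]) * f[v];
          l += d * d;
        }
        tot += c.sum_loss ? l : l / mcount(i);
        ++nv;
      }
    }
    return tot / nv;
  };

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(tr.begin(), tr.end(), rng);
    double ep_loss = 0;
    long nb = 0;
    for (size_t s0 = 0; s0 < tr.size(); s0 += batch_size) {
      int B = (int)std::min((size_t)batch_size, tr.size() - s0);
      if (B < 2) continue;  // batch norm needs > 1 sample
      fmat Xb(nvp * B, 1);
      for (int s = 0; s < B; ++s)
        Xb.rows((long)s * nvp, (long)(s + 1) * nvp - 1) = Xp.col(tr[s0 + s]);
      std::vector<fmat> buf;
      buf.reserve(nunits + 1);
      buf.push_back(std::move(Xb));
      Caches ca;
      ca.resize(nunits);
      run_forward(pl, 0, nunits - 1, P, buf, ca, B, true, c, col);
      const fmat& R = buf.back();

      double loss = 0;
      fmat dR(R.n_rows, 1);
      for (int s = 0; s < B; ++s) {
        int i = tr[s0 + s];
        const float* o = Xp.colptr(i);
        const float* f = Mp.colptr(i);
        const float* r = R.colptr(0) + (long)s * nvp;
        float* g = dR.colptr(0) + (long)s * nvp;
        double l = 0;
        float scale = c.sum_loss ? 2.0f / B : 2.0f / (mcount(i) * B);
        for (long v = 0; v < nvp; ++v) {
          float d = (r[v] - o[v]) * f[v];
          l += (double)d * d;
          g[v] = scale * d;
        }
        loss += c.sum_loss ? l : l / mcount(i);
      }
      loss /= B;
      if (!std::isfinite(loss))
        stop("training diverged (non-finite loss) at epoch %d", ep + 1);
      ep_loss += loss;
      ++nb;

      for (size_t i = 0; i < P.size(); ++i) Gr[i].zeros();
      run_backward(pl, 0, nunits - 1, P, buf, ca, Gr, dR, B, c, col);

      ++step;
      float bc1 = 1.f - std::pow(b1, (float)step);
      float bc2 = 1.f - std::pow(b2, (float)step);
      for (size_t i = 0; i < P.size(); ++i) {
        if (!pl.trainable[i]) continue;
        Am[i] = b1 * Am[i] + (1.f - b1) * Gr[i];
        Av[i] = b2 * Av[i] + (1.f - b2) * square(Gr[i]);
        P[i] -= (float)lr * (Am[i] / bc1) / (sqrt(Av[i] / bc2) + aeps);
      }
    }
    if (nb == 0) stop("no usable training batches");
    double vl = eval_loss(va);
    hist_tr.push_back(ep_loss / nb);
    hist_va.push_back(vl);
    if (vl < best_val) {
      best_val = vl;
      best_epoch = ep + 1;
      bestP = P;
    }
    if (verbose)
      Rprintf("epoch %3d/%d  train %.5f  val %.5f%s\n", ep + 1, epochs,
              ep_loss / nb, vl, (best_epoch == ep + 1) ? "  *" : "");
    Rcpp::checkUserInterrupt();
  }

  CharacterVector nms = params.attr("names");
  return List::create(_["params"] = params_out(bestP, nms),
                      _["final_params"] = params_out(P, nms),
                      _["train_loss"] = wrap(hist_tr), _["val_loss"] = wrap(hist_va),
                      _["best_epoch"] = best_epoch, _["best_val_loss"] = best_val);
}

// [[Rcpp::export]]
NumericMatrix cpp_ae_encode(List params, NumericMatrix X, List cfg, int batch_size) {
  Cfg c = parse_cfg(cfg);
  Plan pl = build_plan(c);
  std::vector<fmat> P = params_in(params);
  int N = X.ncol();
  long nvp = c.pad.n();
  NumericMatrix Z(N, c.latent);
  fmat col;
  for (int s0 = 0; s0 < N; s0 += batch_size) {
    int B = std::min(batch_size, N - s0);
    fmat Xb(nvp * B, 1);
    for (int s = 0; s < B; ++s) pad_column(&X(0, s0 + s), Xb.colptr(0) + (long)s * nvp, c);
    std::vector<fmat> buf;
    buf.push_back(std::move(Xb));
    Caches ca;
    ca.resize(pl.units.size());
    run_forward(pl, 0, pl.enc_end, P, buf, ca, B, false, c, col);
    const fmat& L = buf.back();  // B x latent
    for (int s = 0; s < B; ++s)
      for (int j = 0; j < c.latent; ++j) Z(s0 + s, j) = L(s, j);
  }
  return Z;
}

// [[Rcpp::export]]
NumericMatrix cpp_ae_decode(List params, NumericMatrix Z, List cfg, int batch_size) {
  Cfg c = parse_cfg(cfg);
  Plan pl = build_plan(c);
  std::vector<fmat> P = params_in(params);
  int N = Z.nrow();
  if (Z.ncol() != c.latent) stop("latent width %d does not match model (%d)",
                                 Z.ncol(), c.latent);
  long nvo = c.orig.n();
  NumericMatrix R(nvo, N);
  fmat col;
  int nunits = (int)pl.units.size();
  for (int s0 = 0; s0 < N; s0 += batch_size) {
    int B = std::min(batch_size, N - s0);
    fmat Zb(B, c.latent);
    for (int s = 0; s < B; ++s)
      for (int j = 0; j < c.latent; ++j) Zb(s, j) = (float)Z(s0 + s, j);
    std::vector<fmat> buf;
    buf.push_back(std::move(Zb));
    Caches ca;
    ca.resize(nunits);
    run_forward(pl, pl.enc_end + 1, nunits - 1, P, buf, ca, B, false, c, col);
    const fmat& out = buf.back();
    for (int s = 0; s < B; ++s)
      crop_column(out.colptr(0) + (long)s * c.pad.n(), &R(0, s0 + s), c);
  }
  return R;
}
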