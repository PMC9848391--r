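// Plug-in transfer entropy between binarized spike trains.
//
// The estimator is order-1 in both histories: TE(X->Y) over the
// empirical joint of (Y_t, Y_{t-1}, X_{t-1}) on 10 ms bins. Trains are
// held as n-bit fields (one bit per bin); for each surrogate the input
// train is circularly rotated as a whole bit field and every joint count
// is an AND + popcount pass, so the cost per pair-shuffle is ~n/64 word
// operations. Shuffle shifts are drawn per input cell and reused across
// that cell's pairs.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

typedef std::vector<uint64_t> bits;

static inline int nwords(int n) { return (n + 63) / 64; }

static void set_bit(bits& b, int i) { b[i >> 6] |= (uint64_t(1) << (i & 63)); }

static inline uint64_t popcnt(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  x = x - ((x >> 1) & 0x5555555555555555ULL);
  x = (x & 0x3333333333333333ULL) + ((x >> 2) & 0x3333333333333333ULL);
  x = (x + (x >> 4)) & 0x0f0f0f0f0f0f0f0fULL;
  return (x * 0x0101010101010101ULL) >> 56;
#endif
}

static double pop_and(const bits& a, const bits& b) {
  double s = 0;
  for (size_t i = 0; i < a.size(); ++i) s += popcnt(a[i] & b[i]);
  return s;
}

static double pop1(const bits& a) {
  double s = 0;
  for (size_t i = 0; i < a.size(); ++i) s += popcnt(a[i]);
  return s;
}

// circular left-rotation of an n-bit field by k bits (0 <= k < n);
// fast word path when n is a multiple of 64, generic bit path otherwise
static void rotate_bits(const bits& in, bits& out, int k, int n) {
  int W = nwords(n);
  std::fill(out.begin(), out.end(), 0);
  if (n % 64 == 0) {
    int wk = k >> 6, bk = k & 63;
    if (bk == 0) {
      for (int i = 0; i < W; ++i) out[(i + wk) % W] = in[i];
    } else {
      for (int i = 0; i < W; ++i) {
        uint64_t v = in[i];
        int j = (i + wk) % W;
        out[j] |= v << bk;
        out[(j + 1) % W] |= v >> (64 - bk);
      }
    }
  } else {
    for (int i = 0; i < n; ++i)
      if (in[i >> 6] & (uint64_t(1) << (i & 63))) set_bit(out, (i + k) % n);
  }
}

static double te_from_counts(const double m[4], const double nyy[4],
                             double N) {
  double c[8]; // index 4*Yt + 2*Ylag + Xlag
  for (int k = 0; k < 4; ++k) {
    c[2 * k + 1] = m[k];
    c[2 * k + 0] = nyy[k] - m[k];
  }
  if (N <= 0) return 0.0;
  double n_ylxl[4]; // index 2*Ylag + Xlag
  for (int yl = 0; yl < 2; ++yl)
    for (int xl = 0; xl < 2; ++xl)
      n_ylxl[2 * yl + xl] = c[0 + 2 * yl + xl] + c[4 + 2 * yl + xl];
  double n_yl[2] = { nyy[0] + nyy[2], nyy[1] + nyy[3] };
  double te = 0.0;
  for (int yt = 0; yt < 2; ++yt)
    for (int yl = 0; yl < 2; ++yl)
      for (int xl = 0; xl < 2; ++xl) {
        double cc = c[4 * yt + 2 * yl + xl];
        if (cc <= 0) continue;
        double cond_joint = cc / n_ylxl[2 * yl + xl];    // p(Yt|Ylag,Xlag)
        double cond_self  = nyy[2 * yt + yl] / n_yl[yl]; // p(Yt|Ylag)
        te += (cc / N) * std::log2(cond_joint / cond_self);
      }
  return te;
}

// [[Rcpp::export(name = ".te_pairs_cpp")]]
NumericMatrix te_pairs_cpp(List xbins, int n, IntegerMatrix pairs,
                           IntegerMatrix shifts,
                           Nullable<LogicalVector> mask = R_NilValue) {
  const int P = pairs.nrow();
  const int S = shifts.nrow();
  const int ncell = xbins.size();
  if (shifts.ncol() != ncell && P > 0)
    stop("shifts must have one column per cell");
  const int W = nwords(n);
  NumericMatrix out(P, 2); // raw, null_mean

  // valid-triplet field V: bit t set iff triplet (t, t-1) is counted
  bits V(W, ~uint64_t(0));
  if (n % 64) V[W - 1] = (uint64_t(1) << (n % 64)) - 1; // trim tail bits
  if (mask.isNotNull()) {
    LogicalVector mv(mask);
    if ((int)mv.size() != n) stop("mask length must equal n bins");
    bits M(W, 0);
    for (int t = 0; t < n; ++t) if (mv[t]) set_bit(M, t);
    bits M1(W, 0);
    rotate_bits(M, M1, 1, n);           // bit t = mask[t-1]
    for (int i = 0; i < W; ++i) V[i] = M[i] & M1[i];
  }
  V[0] &= ~uint64_t(1);                  // t = 0 has no predecessor

  // per-cell spike bit fields
  std::vector<bits> spk(ncell, bits(W, 0));
  for (int c = 0; c < ncell; ++c) {
    IntegerVector b = xbins[c];
    for (int i = 0; i < b.size(); ++i) {
      if (b[i] < 0 || b[i] >= n) stop("spike bin out of range");
      set_bit(spk[c], b[i]);
    }
  }

  // per-recipient caches: Y1V (y_t), Y0V (y_{t-1}), Y10V, and nyy counts
  std::vector<bool> is_rec(ncell, false);
  for (int p = 0; p < P; ++p) {
    int r = pairs(p, 1);
    if (r < 1 || r > ncell) stop("recipient index out of range");
    is_rec[r - 1] = true;
  }
  double Ntot = pop1(V);
  std::vector<bits> Y1V(ncell), Y0V(ncell), Y10V(ncell);
  std::vector<std::array<double, 4> > nyy(ncell);
  bits tmp(W, 0);
  for (int c = 0; c < ncell; ++c) {
    if (!is_rec[c]) continue;
    Y1V[c].assign(W, 0); Y0V[c].assign(W, 0); Y10V[c].assign(W, 0);
    rotate_bits(spk[c], tmp, 1, n);      // bit t = y[t-1]
    for (int i = 0; i < W; ++i) {
      Y1V[c][i] = spk[c][i] & V[i];
      Y0V[c][i] = tmp[i] & V[i];
      Y10V[c][i] = Y1V[c][i] & Y0V[c][i];
    }
    double n3 = pop1(Y10V[c]);
    double ny1 = pop1(Y1V[c]);
    double ny0 = pop1(Y0V[c]);
    nyy[c][3] = n3;          // (yt=1, yl=1)
    nyy[c][2] = ny1 - n3;    // (yt=1, yl=0)
    nyy[c][1] = ny0 - n3;    // (yt=0, yl=1)
    nyy[c][0] = Ntot - ny1 - ny0 + n3;
  }

  // group pairs by input so rotated surrogates are shared
  std::vector<std::vector<int> > by_input(ncell);
  for (int p = 0; p < P; ++p) {
    int in = pairs(p, 0);
    if (in < 1 || in > ncell) stop("input index out of range");
    by_input[in - 1].push_back(p);
  }

  std::vector<bits> xrot(S + 1, bits(W, 0)); // slot 0 = raw (shift 1 bin fwd)
  std::vector<double> xtot(S + 1);
  for (int in = 0; in < ncell; ++in) {
    if (by_input[in].empty()) continue;
    // X_{t-1} at triplet position t: rotate the spike field by s + 1
    for (int s = 0; s <= S; ++s) {
      int k = (s == 0) ? 1 : (int)((1LL + shifts(s - 1, in)) % n);
      rotate_bits(spk[in], xrot[s], k, n);
      for (int i = 0; i < W; ++i) xrot[s][i] &= V[i];
      xtot[s] = pop1(xrot[s]);
    }
    for (size_t q = 0; q < by_input[in].size(); ++q) {
      int p = by_input[in][q];
      int rec = pairs(p, 1) - 1;
      double m[4], te_raw = 0, acc = 0;
      const uint64_t* y10 = Y10V[rec].data();
      const uint64_t* y1 = Y1V[rec].data();
      const uint64_t* y0 = Y0V[rec].data();
      for (int s = 0; s <= S; ++s) {
        const uint64_t* xr = xrot[s].data();
        double m3 = 0, my1 = 0, my0 = 0;
        for (int i = 0; i < W; ++i) {
          uint64_t x = xr[i];
          m3 += popcnt(x & y10[i]);
          my1 += popcnt(x & y1[i]);
          my0 += popcnt(x & y0[i]);
        }
        m[3] = m3; m[2] = my1 - m3; m[1] = my0 - m3;
        m[0] = xtot[s] - my1 - my0 + m3;
        double te = te_from_counts(m, nyy[rec].data(), Ntot);
        if (s == 0) te_raw = te; else acc += te;
      }
      out(p, 0) = te_raw;
      out(p, 1) = S > 0 ? acc / S : 0.0;
    }
  }
  return out;
}

// Dense reference path used by transfer_entropy() on raw 0/1 sequences.
// [[Rcpp::export(name = ".te_dense_cpp")]]
double te_dense_cpp(IntegerVector x, IntegerVector y) {
  int n = x.size();
  double c[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  for (int t = 1; t < n; ++t)
    c[4 * (y[t] != 0) + 2 * (y[t - 1] != 0) + (x[t - 1] != 0)] += 1.0;
  double m[4], nyy[4];
  for (int k = 0; k < 4; ++k) {
    m[k] = c[2 * k + 1];
    nyy[k] = c[2 * k] + c[2 * k + 1];
  }
  return te_from_counts(m, nyy, (double)(n - 1));
}
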