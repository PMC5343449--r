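// Vectorized giving-game engine for one generation.
//
// Draw order per round (shared with the pure-R reference engine so the two
// are bit-identical on the same RNG stream):
//   1. N uniforms  -> each donor's recipient (uniform over the other N-1)
//   2. N uniforms  -> implementation-error flips of the intended actions
//   3. geometric-skip uniforms -> perception-error flips over the
//      off-diagonal image entries in column-major order (exact i.i.d.
//      Bernoulli(p) process; no draws when p == 0)
// In lagged timing a synthetic round-0 record is drawn at generation start:
// N recipient uniforms, then N action uniforms (u < 0.5 -> C).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int draw_recipient(int j, int N) {
  int k = (int)(unif_rand() * (N - 1));
  if (k > N - 2) k = N - 2;  // guard against unif_rand() returning 1
  if (k >= j) ++k;
  return k;
}

// norms: integer codes 0..15 (locus 1 = MSB, G = 1), one per agent.
// Returns accumulated payoffs U = b*W - c*V, donation counts W (received)
// and V (given), realized cooperations per round, and the final image
// matrix (entry (i, j) = agent i's image of agent j, 1 = Good).
// [[Rcpp::export(name = ".engine_run_generation")]]
List engine_run_generation(IntegerVector norms, int R, double b, double c,
                           double p, double q, bool lagged) {
  const int N = norms.size();
  const size_t NN = (size_t)N * N;
  std::vector<signed char> img(NN, 1), nxt(NN, 1);
  NumericVector U(N);
  IntegerVector W(N), V(N), coop(R);
  std::vector<int> recip(N), act(N), ev_recip(N), ev_act(N);

  // per-agent assessment bit for each (action, image-of-recipient) pair;
  // slot a*2+g, a = 1 cooperation, g = 1 Good recipient image
  std::vector<signed char> look(4 * (size_t)N);
  for (int i = 0; i < N; ++i) {
    const int nm = norms[i];
    for (int s = 0; s < 4; ++s) look[(size_t)s * N + i] = (nm >> s) & 1;
  }

  if (lagged) {
    for (int j = 0; j < N; ++j) ev_recip[j] = draw_recipient(j, N);
    for (int j = 0; j < N; ++j) ev_act[j] = (unif_rand() < 0.5) ? 1 : 0;
  }

  const double n_offdiag = (double)N * (N - 1);

  for (int r = 0; r < R; ++r) {
    // phase A: pairings, actions, payoffs
    for (int j = 0; j < N; ++j) recip[j] = draw_recipient(j, N);
    for (int j = 0; j < N; ++j) {
      const int intended = img[(size_t)recip[j] * N + j];
      const double u = unif_rand();
      act[j] = (u < q) ? 1 - intended : intended;
    }
    int cc = 0;
    for (int j = 0; j < N; ++j) {
      if (act[j]) {
        U[j] -= c;
        ++V[j];
        U[recip[j]] += b;
        ++W[recip[j]];
        ++cc;
      }
    }
    coop[r] = cc;

    const std::vector<int>& er = lagged ? ev_recip : recip;
    const std::vector<int>& ea = lagged ? ev_act : act;

    // phase B: synchronous update, every observer i evaluates every donor j
    // from the pre-update matrix
    for (int j = 0; j < N; ++j) {
      const signed char* colk = &img[(size_t)er[j] * N];
      const signed char* lg = &look[(size_t)(ea[j] * 2 + 1) * N];
      const signed char* lb = &look[(size_t)(ea[j] * 2) * N];
      signed char* out = &nxt[(size_t)j * N];
      for (int i = 0; i < N; ++i) out[i] = colk[i] ? lg[i] : lb[i];
      out[j] = 1;  // self-image stays Good
    }

    // perception error over off-diagonal entries, column-major order
    if (p >= 1.0) {
      for (int j = 0; j < N; ++j)
        for (int i = 0; i < N; ++i)
          if (i != j) nxt[(size_t)j * N + i] ^= 1;
    } else if (p > 0.0) {
      const double denom = std::log(1.0 - p);
      double t = -1.0;
      for (;;) {
        const double u = unif_rand();
        t += 1.0 + std::floor(std::log(u) / denom);
        if (t >= n_offdiag) break;
        const long long tt = (long long)t;
        const int j = (int)(tt / (N - 1));
        int i = (int)(tt % (N - 1));
        if (i >= j) ++i;
        nxt[(size_t)j * N + i] ^= 1;
      }
    }

    img.swap(nxt);
    if (lagged) {
      ev_recip = recip;
      ev_act = act;
    }
  }

  IntegerMatrix final_img(N, N);
  for (size_t idx = 0; idx < NN; ++idx) final_img[idx] = img[idx];
  return List::create(_["U"] = U, _["W"] = W, _["V"] = V,
                      _["coop_counts"] = coop, _["images"] = final_img);
}
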