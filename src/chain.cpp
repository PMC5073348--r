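// Compiled chain drivers for the group-structured Moran / Wright-Fisher
// processes. Uses R's own RNG (unif_rand) so that set.seed() in R makes
// every trajectory bit-reproducible.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

// draw from a small discrete distribution given cumulative weights
inline int draw_cumulative(const std::vector<double> &cum) {
  double r = unif_rand() * cum.back();
  // linear scan is fine: these vectors are tiny (M) or moderate (N)
  for (size_t i = 0; i < cum.size(); ++i)
    if (r < cum[i]) return static_cast<int>(i);
  return static_cast<int>(cum.size()) - 1;
}

struct OffspringDrawer {
  int S, M;
  double u, v;
  std::vector<double> cum_kernel; // cumulative kernel weights
  OffspringDrawer(int S_, int M_, double u_, double v_, const NumericVector &f)
      : S(S_), M(M_), u(u_), v(v_), cum_kernel(M_) {
    double acc = 0.0;
    for (int d = 0; d < M; ++d) { acc += f[d]; cum_kernel[d] = acc; }
  }
  // strategy and 0-based group of the offspring of (s, g0)
  inline void operator()(int s_par, int g0_par, int &s_child, int &g0_child) {
    s_child = (u > 0.0 && unif_rand() < u)
                  ? static_cast<int>(unif_rand() * S) + 1
                  : s_par;
    if (s_child > S) s_child = S; // guard against unif_rand() == 1
    g0_child = g0_par;
    if (v > 0.0 && unif_rand() < v) {
      double r = unif_rand();
      int d = M - 1;
      for (int k = 0; k < M; ++k)
        if (r < cum_kernel[k]) { d = k; break; }
      g0_child = (g0_par + d) % M;
    }
  }
};

// Incrementally maintained occupancy n[s][g] and pair sums Q[a][b] =
// sum_g n_a(g) n_b(g); I_ab = Q_ab for a != b, I_aa = Q_aa - N_a.
struct CountState {
  int S, M;
  std::vector<int> n;      // S x M, column-major by group: n[s + S*g]
  std::vector<double> Q;   // S x S
  std::vector<int> ns;     // strategy totals
  CountState(int S_, int M_) : S(S_), M(M_), n(S_ * M_, 0), Q(S_ * S_, 0.0), ns(S_, 0) {}
  void rebuild(const std::vector<int> &s, const std::vector<int> &g0) {
    std::fill(n.begin(), n.end(), 0);
    std::fill(ns.begin(), ns.end(), 0);
    for (size_t i = 0; i < s.size(); ++i) {
      ++n[(s[i] - 1) + S * g0[i]];
      ++ns[s[i] - 1];
    }
    std::fill(Q.begin(), Q.end(), 0.0);
    for (int g = 0; g < M; ++g)
      for (int a = 0; a < S; ++a) {
        int na = n[a + S * g];
        if (!na) continue;
        for (int b = 0; b < S; ++b) Q[a + S * b] += double(na) * n[b + S * g];
      }
  }
  inline void remove(int s, int g0) {
    int a = s - 1;
    for (int b = 0; b < S; ++b) {
      double c = n[b + S * g0];
      Q[a + S * b] -= c;
      Q[b + S * a] -= c;
    }
    Q[a + S * a] += 1.0;
    --n[a + S * g0];
    --ns[a];
  }
  inline void insert(int s, int g0) {
    int a = s - 1;
    ++n[a + S * g0];
    ++ns[a];
    for (int b = 0; b < S; ++b) {
      double c = n[b + S * g0];
      Q[a + S * b] += c;
      Q[b + S * a] += c;
    }
    Q[a + S * a] -= 1.0;
  }
  inline double I(int a, int b) const { // 1-based strategy labels
    double q = Q[(a - 1) + S * (b - 1)];
    return (a == b) ? q - ns[a - 1] : q;
  }
};

} // namespace

// Neutral chain, accumulating the three sigma statistics
// t1 = x1 (I22 - I23), t2 = S x1 I23, td = x1 (I21 - I23)
// (optionally averaged over all ordered triples of distinct labels).
// [[Rcpp::export]]
List cpp_sigma_chain(IntegerVector s0, IntegerVector g0, int S, int M,
                     double u, double v, NumericVector fkern, int process,
                     double n_steps, double burn_in, int record_every,
                     int n_batches, bool symmetrize) {
  const int N = s0.size();
  std::vector<int> s(N), g(N);
  for (int i = 0; i < N; ++i) { s[i] = s0[i]; g[i] = g0[i] - 1; }

  OffspringDrawer offspring(S, M, u, v, fkern);
  CountState cs(S, M);
  cs.rebuild(s, g);

  const long long steps = static_cast<long long>(n_steps);
  const long long burn = static_cast<long long>(burn_in);
  const double total_rec = std::ceil(double(steps - burn) / record_every);
  NumericMatrix batch_sums(3, n_batches);
  double sum1 = 0.0, sum2 = 0.0, sumd = 0.0;
  double n_rec = 0.0;

  std::vector<int> s_next(N), g_next(N);
  RNGScope scope;

  for (long long step = 1; step <= steps; ++step) {
    if (process == 0) { // Moran
      int parent = static_cast<int>(unif_rand() * N);
      if (parent == N) parent = N - 1;
      int sc, gc;
      offspring(s[parent], g[parent], sc, gc);
      int dead = static_cast<int>(unif_rand() * N);
      if (dead == N) dead = N - 1;
      cs.remove(s[dead], g[dead]);
      s[dead] = sc; g[dead] = gc;
      cs.insert(sc, gc);
    } else { // Wright-Fisher
      for (int k = 0; k < N; ++k) {
        int parent = static_cast<int>(unif_rand() * N);
        if (parent == N) parent = N - 1;
        offspring(s[parent], g[parent], s_next[k], g_next[k]);
      }
      s.swap(s_next); g.swap(g_next);
      cs.rebuild(s, g);
    }

    if (step > burn && (step - burn - 1) % record_every == 0) {
      double t1 = 0.0, t2 = 0.0, td = 0.0;
      if (!symmetrize) {
        double x1 = double(cs.ns[0]) / N;
        t1 = x1 * (cs.I(2, 2) - cs.I(2, 3));
        t2 = S * x1 * cs.I(2, 3);
        td = x1 * (cs.I(2, 1) - cs.I(2, 3));
      } else {
        int n_trip = 0;
        for (int a = 1; a <= S; ++a)
          for (int b = 1; b <= S; ++b) {
            if (b == a) continue;
            for (int c = 1; c <= S; ++c) {
              if (c == a || c == b) continue;
              double xa = double(cs.ns[a - 1]) / N;
              t1 += xa * (cs.I(b, b) - cs.I(b, c));
              t2 += S * xa * cs.I(b, c);
              td += xa * (cs.I(b, a) - cs.I(b, c));
              ++n_trip;
            }
          }
        t1 /= n_trip; t2 /= n_trip; td /= n_trip;
      }
      sum1 += t1; sum2 += t2; sumd += td;
      int batch = static_cast<int>(n_rec * n_batches / total_rec);
      if (batch >= n_batches) batch = n_batches - 1;
      batch_sums(0, batch) += t1;
      batch_sums(1, batch) += t2;
      batch_sums(2, batch) += td;
      n_rec += 1.0;
    }
  }

  IntegerVector s_fin(N), g_fin(N);
  for (int i = 0; i < N; ++i) { s_fin[i] = s[i]; g_fin[i] = g[i] + 1; }
  return List::create(_["sum1"] = sum1, _["sum2"] = sum2, _["sumd"] = sumd,
                      _["n_samples"] = n_rec, _["batch_sums"] = batch_sums,
                      _["s"] = s_fin, _["g"] = g_fin);
}

// Chain with selection: fitness 1 + delta * (accumulated payoff), recording
// per-strategy frequency means (overall and per batch).
// [[Rcpp::export]]
List cpp_game_chain(IntegerVector s0, IntegerVector g0, int S, int M,
                    double u, double v, NumericVector fkern, int process,
                    double delta, NumericMatrix A,
                    double n_steps, double burn_in, int record_every,
                    int n_batches) {
  const int N = s0.size();
  std::vector<int> s(N), g(N);
  for (int i = 0; i < N; ++i) { s[i] = s0[i]; g[i] = g0[i] - 1; }

  OffspringDrawer offspring(S, M, u, v, fkern);

  std::vector<double> pay(N, 0.0), cum(N, 0.0);
  std::vector<int> ns(S, 0);
  auto rebuild_payoffs = [&]() {
    std::fill(pay.begin(), pay.end(), 0.0);
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < N; ++j)
        if (j != i && g[j] == g[i]) pay[i] += A(s[i] - 1, s[j] - 1);
  };
  auto rebuild_ns = [&]() {
    std::fill(ns.begin(), ns.end(), 0);
    for (int i = 0; i < N; ++i) ++ns[s[i] - 1];
  };
  rebuild_payoffs();
  rebuild_ns();

  const long long steps = static_cast<long long>(n_steps);
  const long long burn = static_cast<long long>(burn_in);
  const double total_rec = std::ceil(double(steps - burn) / record_every);
  NumericMatrix batch_freq(S, n_batches);
  NumericVector batch_n(n_batches);
  NumericVector freq_sum(S);
  double n_rec = 0.0;

  std::vector<int> s_next(N), g_next(N);
  RNGScope scope;

  for (long long step = 1; step <= steps; ++step) {
    // fitness-proportional parent weights
    double acc = 0.0;
    for (int i = 0; i < N; ++i) {
      double w = 1.0 + delta * pay[i];
      if (w <= 0.0) stop("non-positive fitness at step %lld", step);
      acc += w;
      cum[i] = acc;
    }
    if (process == 0) { // Moran
      int parent = draw_cumulative(cum);
      int sc, gc;
      offspring(s[parent], g[parent], sc, gc);
      int dead = static_cast<int>(unif_rand() * N);
      if (dead == N) dead = N - 1;
      // payoff bookkeeping: remove dead, add newborn
      for (int j = 0; j < N; ++j) {
        if (j == dead) continue;
        if (g[j] == g[dead]) pay[j] -= A(s[j] - 1, s[dead] - 1);
      }
      --ns[s[dead] - 1];
      s[dead] = sc; g[dead] = gc;
      ++ns[sc - 1];
      double p_new = 0.0;
      for (int j = 0; j < N; ++j) {
        if (j == dead) continue;
        if (g[j] == gc) {
          pay[j] += A(s[j] - 1, sc - 1);
          p_new += A(sc - 1, s[j] - 1);
        }
      }
      pay[dead] = p_new;
    } else { // Wright-Fisher
      for (int k = 0; k < N; ++k) {
        int parent = draw_cumulative(cum);
        offspring(s[parent], g[parent], s_next[k], g_next[k]);
      }
      s.swap(s_next); g.swap(g_next);
      rebuild_payoffs();
      rebuild_ns();
    }

    if (step > burn && (step - burn - 1) % record_every == 0) {
      int batch = static_cast<int>(n_rec * n_batches / total_rec);
      if (batch >= n_batches) batch = n_batches - 1;
      for (int a = 0; a < S; ++a) {
        double x = double(ns[a]) / N;
        freq_sum[a] += x;
        batch_freq(a, batch) += x;
      }
      batch_n[batch] += 1.0;
      n_rec += 1.0;
    }
  }

  return List::create(_["freq_sum"] = freq_sum, _["n_samples"] = n_rec,
                      _["batch_freq"] = batch_freq, _["batch_n"] = batch_n);
}
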