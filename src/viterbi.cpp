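// HSMM Viterbi decoder over adjacent-breath alignment states.
//
// A state is a pair (i, j) of adjacent breath timesteps with gap
// g = j - i constrained to [F_max, F_min] frames (F_max = frames per breath
// at the fastest admissible rate, so F_max < F_min). Scores, in log space:
//   initial:    pi(i,j) = 1/N0 uniform over admissible first states
//               (i <= i_max, gap admissible, j <= T)
//   transition: a((i,j)->(j,k)) = N(k-j; mu = j-i, sigma2), renormalized
//               over the k admissible from j (gap in range, k <= T)
//   emission:   b(i,j) = BB(i) * BB(j)
// The recursion runs backward (max score-to-go with r transitions left), so
// the forward reconstruction can greedily pick the lexicographically
// smallest breath-time sequence among score-optimal paths.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".viterbi_cpp")]]
List viterbi_cpp(NumericVector logbb, int F_max, int F_min, double sigma2,
                 IntegerVector Q_candidates, int i_max, double tol) {
  const int T = logbb.size();
  const int G = F_min - F_max + 1;          // gap index g: gap = F_max + g
  if (G < 1) stop("F_min must be >= F_max");
  int Qmax = 0;
  for (int qc : Q_candidates) if (qc > Qmax) Qmax = qc;
  if (Qmax < 1) stop("need at least one positive Q candidate");

  // Gaussian log-density table over gap differences d = -(G-1)..(G-1)
  const double lognorm = -0.5 * std::log(2.0 * M_PI * sigma2);
  std::vector<double> gtab(2 * G - 1);
  for (int d = -(G - 1); d <= G - 1; ++d)
    gtab[d + G - 1] = lognorm - 0.5 * d * d / sigma2;

  // state index: (t, g) -> t * G + g, t = later breath time (1-based), valid
  // iff t - (F_max + g) >= 1 and t <= T
  auto valid = [&](int t, int g) {
    return t >= 1 && t <= T && (t - (F_max + g)) >= 1;
  };

  // log of the transition normalizer out of state with later time j and gap
  // index gi: sum over admissible next gaps (limited by T - j)
  std::vector<double> Zlog((T + 1) * G, NEG_INF);
  for (int j = 1; j <= T; ++j) {
    int gk_hi = std::min(F_min, T - j) - F_max;  // max admissible next gap idx
    if (gk_hi < 0) continue;
    for (int gi = 0; gi < G; ++gi) {
      double mx = NEG_INF;
      for (int gk = 0; gk <= gk_hi; ++gk) {
        double v = gtab[gk - gi + G - 1];
        if (v > mx) mx = v;
      }
      double s = 0.0;
      for (int gk = 0; gk <= gk_hi; ++gk)
        s += std::exp(gtab[gk - gi + G - 1] - mx);
      Zlog[j * G + gi] = mx + std::log(s);
    }
  }

  // W[r][(t,g)]: best log score-to-go with r transitions remaining
  std::vector<std::vector<double>> W(Qmax);
  W[0].assign((T + 1) * G, 0.0);
  for (int t = 1; t <= T; ++t)
    for (int g = 0; g < G; ++g)
      if (!valid(t, g)) W[0][t * G + g] = NEG_INF;

  for (int r = 1; r < Qmax; ++r) {
    W[r].assign((T + 1) * G, NEG_INF);
    const std::vector<double>& Wp = W[r - 1];
    for (int j = 1; j <= T; ++j) {
      int gk_hi = std::min(F_min, T - j) - F_max;
      if (gk_hi < 0) continue;
      for (int gi = 0; gi < G; ++gi) {
        if (!valid(j, gi)) continue;
        double mx = NEG_INF;
        for (int gk = 0; gk <= gk_hi; ++gk) {
          int k = j + F_max + gk;
          double v = gtab[gk - gi + G - 1] + logbb[k - 1] + Wp[k * G + gk];
          if (v > mx) mx = v;
        }
        if (mx > NEG_INF)
          W[r][j * G + gi] = logbb[j - 1] - Zlog[j * G + gi] + mx;
      }
    }
  }

  // count admissible initial states (i <= i_max), shared by every Q
  long n0 = 0;
  for (int i = 1; i <= std::min(i_max, T); ++i)
    for (int g = 0; g < G; ++g)
      if (i + F_max + g <= T) ++n0;
  if (n0 == 0) stop("no admissible initial state: series too short");
  const double logpi = -std::log((double)n0);

  // evaluate each Q candidate: opt(Q) = max over initial states of
  // logpi + b(i,j) + W[Q-1](i,j); keep the best per-transition score
  int bestQ = -1;
  double bestNorm = NEG_INF, bestOpt = NEG_INF;
  for (int qc : Q_candidates) {
    if (qc < 1 || qc > Qmax) continue;
    double opt = NEG_INF;
    for (int i = 1; i <= std::min(i_max, T); ++i)
      for (int g = 0; g < G; ++g) {
        int j = i + F_max + g;
        if (j > T) continue;
        double v = logpi + logbb[i - 1] + logbb[j - 1] + W[qc - 1][j * G + g];
        if (v > opt) opt = v;
      }
    if (opt == NEG_INF) continue;          // no admissible path at this depth
    double norm = opt / qc;
    if (norm > bestNorm + tol ||
        (bestQ < 0 && norm > NEG_INF)) {
      bestNorm = norm; bestQ = qc; bestOpt = opt;
    }
  }
  if (bestQ < 0) stop("no admissible breath sequence for any depth candidate");

  // forward reconstruction, lexicographically smallest among optimal
  std::vector<int> times;
  int cur_j = -1, cur_g = -1;
  for (int i = 1; i <= std::min(i_max, T) && cur_j < 0; ++i)
    for (int g = 0; g < G; ++g) {
      int j = i + F_max + g;
      if (j > T) continue;
      double v = logpi + logbb[i - 1] + logbb[j - 1] + W[bestQ - 1][j * G + g];
      if (v >= bestOpt - tol) { times.push_back(i); times.push_back(j);
                                cur_j = j; cur_g = g; break; }
    }
  for (int q = 2; q <= bestQ; ++q) {
    int r = bestQ - q + 1;                 // transitions remaining at current
    double target = W[r][cur_j * G + cur_g];
    int gk_hi = std::min(F_min, T - cur_j) - F_max;
    int nxt_g = -1;
    for (int gk = 0; gk <= gk_hi; ++gk) {
      int k = cur_j + F_max + gk;
      double v = logbb[cur_j - 1] - Zlog[cur_j * G + cur_g] +
                 gtab[gk - cur_g + G - 1] + logbb[k - 1] +
                 W[r - 1][k * G + gk];
      if (v >= target - tol) { nxt_g = gk; break; }
    }
    if (nxt_g < 0) stop("internal error: backtrack failed");
    cur_j = cur_j + F_max + nxt_g;
    cur_g = nxt_g;
    times.push_back(cur_j);
  }

  return List::create(_["breath_times"] = wrap(times),
                      _["score"] = bestOpt,
                      _["Q"] = bestQ,
                      _["log_n0"] = std::log((double)n0));
}
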