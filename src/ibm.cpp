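// Individual-based simulator core.
//
// All randomness comes from R's RNG (unif_rand), so set.seed() in R gives
// bit-identical trajectories. Each individual carries {q, c_A}; c_B is
// cached and refreshed only on mutation. Per generation: fitness
// accumulators reset, `groups` groups of N distinct individuals play the
// collective task, realised fitness = accumulated payoff / games played
// (0 for non-participants), then `bouts` tournament replacements.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// uniform integer on 0..n-1
static inline int ru(int n) {
  int r;
  do { r = (int)(unif_rand() * n); } while (r >= n);
  return r;
}

static void play_groups(int n, int N, int groups,
                        const double* q, const double* c, const double* cB,
                        const double* sA, const double* sB,
                        double* acc, int* games, int* idx,
                        int* members, int* chose,
                        bool check, const double* expected, double* maxdev) {
  for (int g = 0; g < groups; ++g) {
    // partial Fisher-Yates draw of N distinct indices; swaps persist across
    // groups, which keeps every draw uniform without a reset pass
    for (int j = 0; j < N; ++j) {
      int r = j + ru(n - j);
      int tmp = idx[j]; idx[j] = idx[r]; idx[r] = tmp;
      members[j] = idx[j];
    }
    int i = 0;
    for (int j = 0; j < N; ++j) {
      chose[j] = (unif_rand() < q[members[j]]) ? 1 : 0;
      i += chose[j];
    }
    double paid = 0.0;
    for (int j = 0; j < N; ++j) {
      int m = members[j];
      double pay = chose[j] ? (sA[i] - c[m]) : (sB[i] - cB[m]);
      acc[m] += pay;
      games[m] += 1;
      if (check) paid += chose[j] ? sA[i] : sB[i];
    }
    if (check) {
      double d = std::fabs(paid - expected[i]);
      if (d > *maxdev) *maxdev = d;
    }
  }
}

static void realise_fitness(int n, const double* acc, const int* games,
                            double* fit) {
  for (int i = 0; i < n; ++i)
    fit[i] = games[i] > 0 ? acc[i] / games[i] : 0.0;
}

static void reproduce(int n, int bouts, double mut_prob, double eps,
                      double k, double alpha,
                      double* q, double* c, double* cB,
                      double* fit, int* games) {
  const double ka = std::pow(k, alpha);
  for (int b = 0; b < bouts; ++b) {
    int a1 = ru(n);
    int a2 = ru(n - 1);
    if (a2 >= a1) a2 += 1;
    int win, lose;
    if (fit[a1] > fit[a2])      { win = a1; lose = a2; }
    else if (fit[a2] > fit[a1]) { win = a2; lose = a1; }
    else if (unif_rand() < 0.5) { win = a1; lose = a2; }
    else                        { win = a2; lose = a1; }
    double nq = q[win], nc = c[win], ncB = cB[win];
    if (mut_prob > 0.0 && eps > 0.0 && unif_rand() < mut_prob) {
      // both traits mutate in one event; the cost step is uniform in the
      // transformed coordinate u = c_A^alpha (symmetric bracket in u)
      nq += (2.0 * unif_rand() - 1.0) * eps;
      if (nq < 0.0) nq = 0.0;
      if (nq > 1.0) nq = 1.0;
      double u = std::pow(nc, alpha) + (2.0 * unif_rand() - 1.0) * eps;
      if (u < 0.0) u = 0.0;
      if (u > ka) u = ka;
      nc = std::pow(u, 1.0 / alpha);
      ncB = std::pow(ka - u, 1.0 / alpha);
    } else if (mut_prob > 0.0 && eps <= 0.0 && unif_rand() < mut_prob) {
      // zero step width: mutation event changes nothing, traits copied exactly
    }
    q[lose] = nq; c[lose] = nc; cB[lose] = ncB;
    fit[lose] = 0.0; games[lose] = 0;
  }
}

// trajectory record: gen, mean_q, var_q, mean_c, var_c, mean_fit,
// frac_low, mean_q_low, mean_q_high, mean_c_low, mean_c_high
static void record_row(double* row, int gen, int n,
                       const double* q, const double* c, double mean_fit) {
  double sq = 0, sqq = 0, sc = 0, scc = 0;
  int nlow = 0;
  double sql = 0, sqh = 0, scl = 0, sch = 0;
  for (int i = 0; i < n; ++i) {
    sq += q[i]; sqq += q[i] * q[i];
    sc += c[i]; scc += c[i] * c[i];
    if (q[i] < 0.5) { nlow++; sql += q[i]; scl += c[i]; }
    else            { sqh += q[i]; sch += c[i]; }
  }
  int nhigh = n - nlow;
  row[0] = gen;
  row[1] = sq / n;
  row[2] = sqq / n - (sq / n) * (sq / n);
  row[3] = sc / n;
  row[4] = scc / n - (sc / n) * (sc / n);
  row[5] = mean_fit;
  row[6] = (double)nlow / n;
  row[7] = nlow  ? sql / nlow  : NA_REAL;
  row[8] = nhigh ? sqh / nhigh : NA_REAL;
  row[9] = nlow  ? scl / nlow  : NA_REAL;
  row[10] = nhigh ? sch / nhigh : NA_REAL;
}

// [[Rcpp::export]]
List cpp_play_generation(NumericVector q, NumericVector c, NumericVector cB,
                         NumericVector sA, NumericVector sB,
                         int N, int groups,
                         bool check, NumericVector expected) {
  int n = q.size();
  if (N > n) stop("group size N exceeds population size");
  NumericVector acc(n);
  IntegerVector games(n);
  NumericVector fit(n);
  std::vector<int> idx(n), members(N), chose(N);
  for (int i = 0; i < n; ++i) idx[i] = i;
  double maxdev = 0.0;
  play_groups(n, N, groups, q.begin(), c.begin(), cB.begin(),
              sA.begin(), sB.begin(), acc.begin(), games.begin(),
              idx.data(), members.data(), chose.data(),
              check, expected.begin(), &maxdev);
  realise_fitness(n, acc.begin(), games.begin(), fit.begin());
  return List::create(_["fitness"] = fit, _["games"] = games,
                      _["max_conservation_dev"] = maxdev);
}

// [[Rcpp::export]]
List cpp_reproduce(NumericVector q, NumericVector c, NumericVector cB,
                   NumericVector fitness, IntegerVector games,
                   int bouts, double mut_prob, double eps,
                   double k, double alpha) {
  NumericVector q2 = clone(q), c2 = clone(c), cB2 = clone(cB),
                f2 = clone(fitness);
  IntegerVector g2 = clone(games);
  reproduce(q.size(), bouts, mut_prob, eps, k, alpha,
            q2.begin(), c2.begin(), cB2.begin(), f2.begin(), g2.begin());
  return List::create(_["q"] = q2, _["c_A"] = c2, _["c_B"] = cB2,
                      _["fitness"] = f2, _["games"] = g2);
}

// [[Rcpp::export]]
List cpp_run(NumericVector q0, NumericVector c0, NumericVector cB0,
             NumericVector sA, NumericVector sB,
             int N, int groups, int bouts,
             double mut_prob, double eps, double k, double alpha,
             int generations, int record_every,
             bool check, NumericVector expected) {
  int n = q0.size();
  if (N > n) stop("group size N exceeds population size");
  NumericVector q = clone(q0), c = clone(c0), cB = clone(cB0);
  NumericVector acc(n), fit(n);
  IntegerVector games(n);
  std::vector<int> idx(n), members(N), chose(N);
  for (int i = 0; i < n; ++i) idx[i] = i;

  // recorded generations: 0, every record_every-th, and the last
  std::vector<int> sched;
  sched.push_back(0);
  if (record_every < 1) record_every = 1;
  for (int g = record_every; g <= generations; g += record_every)
    sched.push_back(g);
  if (generations > 0 && sched.back() != generations)
    sched.push_back(generations);
  NumericMatrix rec(sched.size(), 11);
  size_t ri = 0;
  double maxdev = 0.0;
  double row[11];

  record_row(row, 0, n, q.begin(), c.begin(), 0.0);
  for (int j = 0; j < 11; ++j) rec(0, j) = row[j];
  ri = 1;
  for (int gen = 1; gen <= generations; ++gen) {
    std::fill(acc.begin(), acc.end(), 0.0);
    std::fill(games.begin(), games.end(), 0);
    play_groups(n, N, groups, q.begin(), c.begin(), cB.begin(),
                sA.begin(), sB.begin(), acc.begin(), games.begin(),
                idx.data(), members.data(), chose.data(),
                check, expected.begin(), &maxdev);
    realise_fitness(n, acc.begin(), games.begin(), fit.begin());
    double mean_fit = 0.0;
    for (int i = 0; i < n; ++i) mean_fit += fit[i];
    mean_fit /= n;
    reproduce(n, bouts, mut_prob, eps, k, alpha,
              q.begin(), c.begin(), cB.begin(), fit.begin(), games.begin());
    if (ri < sched.size() && gen == sched[ri]) {
      record_row(row, gen, n, q.begin(), c.begin(), mean_fit);
      for (int j = 0; j < 11; ++j) rec(ri, j) = row[j];
      ++ri;
    }
    if (gen % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["q"] = q, _["c_A"] = c, _["c_B"] = cB,
                      _["fitness"] = fit, _["games"] = games,
                      _["records"] = rec,
                      _["max_conservation_dev"] = maxdev);
}
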