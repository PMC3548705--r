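#include <Rcpp.h>
using namespace Rcpp;

static inline double sqdist(const NumericMatrix &X, int i,
                            const NumericMatrix &P, int c) {
  double s = 0.0;
  const int d = X.ncol();
  for (int j = 0; j < d; ++j) {
    const double v = X(i, j) - P(c, j);
    s += v * v;
  }
  return s;
}

static inline int nearest(const NumericMatrix &X, int i,
                          const NumericMatrix &P) {
  // ties broken by lowest prototype index (strict <)
  int best = 0;
  double bd = sqdist(X, i, P, 0);
  for (int c = 1; c < P.nrow(); ++c) {
    const double dd = sqdist(X, i, P, c);
    if (dd < bd) {
      bd = dd;
      best = c;
    }
  }
  return best;
}

static double total_wss(const NumericMatrix &X, const IntegerVector &lab,
                        const NumericMatrix &P) {
  double w = 0.0;
  for (int i = 0; i < X.nrow(); ++i) w += sqdist(X, i, P, lab[i] - 1);
  return w;
}

// Batch (Lloyd) iteration to label convergence, then on-line (per-point)
// refinement passes until a full pass makes no move. Empty clusters arising
// in the batch phase are re-seeded at the point farthest from the stale
// prototype. Labels returned are 1-based.
// [[Rcpp::export(name = ".kmeans_core")]]
List kmeans_core(NumericMatrix X, NumericMatrix init, int max_batch,
                 int max_online) {
  const int n = X.nrow(), d = X.ncol(), k = init.nrow();
  NumericMatrix P = clone(init);
  IntegerVector lab(n, 0);
  std::vector<double> batch_wss, online_wss;
  bool batch_converged = false;

  int iter = 0;
  while (iter < max_batch) {
    ++iter;
    bool changed = false;
    for (int i = 0; i < n; ++i) {
      const int best = nearest(X, i, P) + 1;
      if (lab[i] != best) {
        lab[i] = best;
        changed = true;
      }
    }
    // recompute prototypes as cluster means
    std::vector<int> cnt(k, 0);
    NumericMatrix S(k, d);
    for (int i = 0; i < n; ++i) {
      const int c = lab[i] - 1;
      ++cnt[c];
      for (int j = 0; j < d; ++j) S(c, j) += X(i, j);
    }
    std::vector<bool> taken(n, false);
    for (int c = 0; c < k; ++c) {
      if (cnt[c] > 0) {
        for (int j = 0; j < d; ++j) P(c, j) = S(c, j) / cnt[c];
      } else {
        // re-seed: farthest point from this cluster's stale prototype
        int far = -1;
        double fd = -1.0;
        for (int i = 0; i < n; ++i) {
          if (taken[i]) continue;
          const double dd = sqdist(X, i, P, c);
          if (dd > fd) {
            fd = dd;
            far = i;
          }
        }
        taken[far] = true;
        for (int j = 0; j < d; ++j) P(c, j) = X(far, j);
        changed = true;  // force another allocation round
      }
    }
    batch_wss.push_back(total_wss(X, lab, P));
    if (!changed) {
      batch_converged = true;
      break;
    }
  }

  // on-line refinement: move a point to its nearest prototype and update
  // both affected means incrementally; never empty a cluster
  std::vector<int> cnt(k, 0);
  for (int i = 0; i < n; ++i) ++cnt[lab[i] - 1];
  int passes = 0;
  while (passes < max_online) {
    ++passes;
    bool moved = false;
    for (int i = 0; i < n; ++i) {
      const int cur = lab[i] - 1;
      const int best = nearest(X, i, P);
      if (best != cur && cnt[cur] > 1) {
        const double a = cnt[cur], b = cnt[best];
        for (int j = 0; j < d; ++j) {
          P(cur, j) = (P(cur, j) * a - X(i, j)) / (a - 1.0);
          P(best, j) = (P(best, j) * b + X(i, j)) / (b + 1.0);
        }
        --cnt[cur];
        ++cnt[best];
        lab[i] = best + 1;
        moved = true;
      }
    }
    online_wss.push_back(total_wss(X, lab, P));
    if (!moved) break;
  }

  return List::create(
      _["labels"] = lab, _["prototypes"] = P,
      _["wss"] = total_wss(X, lab, P), _["batch_wss"] = wrap(batch_wss),
      _["online_wss"] = wrap(online_wss),
      _["n_batch"] = (int)batch_wss.size(),
      _["n_online"] = (int)online_wss.size(),
      _["batch_converged"] = batch_converged);
}

// nearest-prototype labels only (shared by label assignment and projection)
// [[Rcpp::export(name = ".assign_nearest")]]
IntegerVector assign_nearest(NumericMatrix X, NumericMatrix P) {
  const int n = X.nrow();
  IntegerVector lab(n);
  for (int i = 0; i < n; ++i) lab[i] = nearest(X, i, P) + 1;
  return lab;
}
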