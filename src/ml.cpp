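// K-nearest-neighbour prediction and CART tree growing. Both are hot paths:
// KNN sits inside the wrapper-selection fitness, trees inside bagging/boosting.
// Deterministic tie-breaking throughout (distance ties -> lower row index,
// vote ties -> smaller class label).
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export(name = ".knn_predict_cpp")]]
IntegerVector knn_predict_cpp(NumericMatrix Xtr, IntegerVector ytr,
                              NumericMatrix Xte, IntegerVector cols, int k,
                              int K) {
  int ntr = Xtr.nrow(), nte = Xte.nrow(), p = cols.size();
  if (k > ntr) k = ntr;
  IntegerVector out(nte);
  // gather the selected columns into row-major buffers once; the distance
  // loop then walks contiguous memory
  std::vector<double> tr((size_t)ntr * p), te((size_t)nte * p);
  for (int c = 0; c < p; ++c) {
    int col = cols[c];
    for (int j = 0; j < ntr; ++j) tr[(size_t)j * p + c] = Xtr(j, col);
    for (int i = 0; i < nte; ++i) te[(size_t)i * p + c] = Xte(i, col);
  }
  std::vector<std::pair<double, int>> dist(ntr);
  std::vector<int> votes(K);
  for (int i = 0; i < nte; ++i) {
    const double *ti = &te[(size_t)i * p];
    for (int j = 0; j < ntr; ++j) {
      const double *tj = &tr[(size_t)j * p];
      double s = 0.0;
      for (int c = 0; c < p; ++c) {
        double d = ti[c] - tj[c];
        s += d * d;
      }
      dist[j] = std::make_pair(s, j);
    }
    std::partial_sort(dist.begin(), dist.begin() + k, dist.end());
    std::fill(votes.begin(), votes.end(), 0);
    for (int q = 0; q < k; ++q) ++votes[ytr[dist[q].second]];
    int best = 0;
    for (int c = 1; c < K; ++c)
      if (votes[c] > votes[best]) best = c;
    out[i] = best;
  }
  return out;
}

namespace {

struct TreeBuilder {
  const NumericMatrix &X;
  const NumericVector &y; // class labels (as doubles) or regression targets
  bool classify;
  int K, max_depth, min_split, mtry;
  std::mt19937 rng;

  std::vector<int> feat, left, right;
  std::vector<double> thr;
  std::vector<std::vector<double>> value; // K probs (classification) or {mean}

  TreeBuilder(const NumericMatrix &X_, const NumericVector &y_, bool cl,
              int K_, int md, int ms, int mtry_, unsigned seed)
      : X(X_), y(y_), classify(cl), K(K_), max_depth(md), min_split(ms),
        mtry(mtry_), rng(seed) {}

  int new_node() {
    feat.push_back(-1); thr.push_back(0.0);
    left.push_back(-1); right.push_back(-1);
    value.push_back(std::vector<double>(classify ? K : 1, 0.0));
    return (int)feat.size() - 1;
  }

  void leaf_value(int id, const std::vector<int> &rows) {
    std::vector<double> &v = value[id];
    if (classify) {
      for (int r : rows) ++v[(int)y[r]];
      for (double &x : v) x /= rows.size();
    } else {
      double s = 0.0;
      for (int r : rows) s += y[r];
      v[0] = s / rows.size();
    }
  }

  int build(std::vector<int> &rows, int depth) {
    int id = new_node();
    leaf_value(id, rows);
    int n = (int)rows.size();
    if (depth >= max_depth || n < min_split) return id;

    // pure node?
    bool pure = true;
    for (int i = 1; i < n && pure; ++i)
      if (y[rows[i]] != y[rows[0]]) pure = false;
    if (pure) return id;

    int p = X.ncol();
    std::vector<int> cols(p);
    for (int j = 0; j < p; ++j) cols[j] = j;
    if (mtry < p)
      for (int j = 0; j < mtry; ++j) {
        std::uniform_int_distribution<int> u(j, p - 1);
        std::swap(cols[j], cols[u(rng)]);
      }
    int ncand = std::min(mtry, p);

    double best_score = -1.0; // maximize impurity decrease
    int best_f = -1;
    double best_t = 0.0;

    std::vector<std::pair<double, int>> fv(n);
    std::vector<double> cl(K), cr(K);
    for (int ci = 0; ci < ncand; ++ci) {
      int f = cols[ci];
      for (int i = 0; i < n; ++i) fv[i] = std::make_pair(X(rows[i], f), rows[i]);
      std::sort(fv.begin(), fv.end());
      if (fv[0].first == fv[n - 1].first) continue;
      if (classify) {
        std::fill(cl.begin(), cl.end(), 0.0);
        std::fill(cr.begin(), cr.end(), 0.0);
        for (int i = 0; i < n; ++i) ++cr[(int)y[fv[i].second]];
        for (int i = 0; i < n - 1; ++i) {
          int c = (int)y[fv[i].second];
          ++cl[c]; --cr[c];
          if (fv[i + 1].first == fv[i].first) continue;
          double nl = i + 1, nr = n - nl;
          double gl = 1.0, gr = 1.0;
          for (int q = 0; q < K; ++q) {
            gl -= (cl[q] / nl) * (cl[q] / nl);
            gr -= (cr[q] / nr) * (cr[q] / nr);
          }
          double score = -(nl * gl + nr * gr);
          if (best_f < 0 || score > best_score) {
            best_score = score;
            best_f = f;
            best_t = 0.5 * (fv[i].first + fv[i + 1].first);
          }
        }
      } else {
        double sl = 0.0, sr = 0.0, sql = 0.0, sqr = 0.0;
        for (int i = 0; i < n; ++i) {
          sr += y[fv[i].second];
          sqr += y[fv[i].second] * y[fv[i].second];
        }
        for (int i = 0; i < n - 1; ++i) {
          double v = y[fv[i].second];
          sl += v; sql += v * v; sr -= v; sqr -= v * v;
          if (fv[i + 1].first == fv[i].first) continue;
          double nl = i + 1, nr = n - nl;
          double ssel = sql - sl * sl / nl;
          double sser = sqr - sr * sr / nr;
          double score = -(ssel + sser);
          if (best_f < 0 || score > best_score) {
            best_score = score;
            best_f = f;
            best_t = 0.5 * (fv[i].first + fv[i + 1].first);
          }
        }
      }
    }
    if (best_f < 0) return id;

    std::vector<int> lrows, rrows;
    for (int r : rows) {
      if (X(r, best_f) <= best_t) lrows.push_back(r);
      else rrows.push_back(r);
    }
    if (lrows.empty() || rrows.empty()) return id;
    feat[id] = best_f;
    thr[id] = best_t;
    int lid = build(lrows, depth + 1);
    int rid = build(rrows, depth + 1);
    left[id] = lid;
    right[id] = rid;
    return id;
  }
};

} // namespace

// [[Rcpp::export(name = ".tree_grow_cpp")]]
List tree_grow_cpp(NumericMatrix X, NumericVector y, IntegerVector rows,
                   bool classify, int K, int max_depth, int min_split,
                   int mtry, int seed) {
  TreeBuilder tb(X, y, classify, K, max_depth, min_split, mtry,
                 (unsigned)seed);
  std::vector<int> rv(rows.begin(), rows.end());
  tb.build(rv, 0);
  int nn = (int)tb.feat.size();
  NumericMatrix val(nn, classify ? K : 1);
  for (int i = 0; i < nn; ++i)
    for (int j = 0; j < val.ncol(); ++j) val(i, j) = tb.value[i][j];
  return List::create(_["feat"] = wrap(tb.feat), _["thr"] = wrap(tb.thr),
                      _["left"] = wrap(tb.left), _["right"] = wrap(tb.right),
                      _["value"] = val);
}

// [[Rcpp::export(name = ".tree_leaf_cpp")]]
IntegerVector tree_leaf_cpp(List tree, NumericMatrix X) {
  IntegerVector feat = tree["feat"], left = tree["left"], right = tree["right"];
  NumericVector thr = tree["thr"];
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feat[node] >= 0) {
      node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
    }
    out[i] = node; // 0-based node index
  }
  return out;
}

// Cross-validated KNN error count over a fixed fold assignment, on a
// column subset. Gathers the masked columns once, then classifies every
// sample from the training rows outside its fold.
// [[Rcpp::export(name = ".knn_cv_errors_cpp")]]
int knn_cv_errors_cpp(NumericMatrix X, IntegerVector y, IntegerVector fold,
                      IntegerVector cols, int k, int K) {
  int n = X.nrow(), p = cols.size();
  std::vector<double> buf((size_t)n * p);
  for (int c = 0; c < p; ++c) {
    int col = cols[c];
    for (int i = 0; i < n; ++i) buf[(size_t)i * p + c] = X(i, col);
  }
  std::vector<std::pair<double, int>> dist;
  dist.reserve(n);
  std::vector<int> votes(K);
  int errors = 0;
  for (int i = 0; i < n; ++i) {
    dist.clear();
    const double *bi = &buf[(size_t)i * p];
    for (int j = 0; j < n; ++j) {
      if (fold[j] == fold[i]) continue;
      const double *bj = &buf[(size_t)j * p];
      double s = 0.0;
      for (int c = 0; c < p; ++c) {
        double d = bi[c] - bj[c];
        s += d * d;
      }
      dist.push_back(std::make_pair(s, j));
    }
    int kk = std::min<int>(k, dist.size());
    std::partial_sort(dist.begin(), dist.begin() + kk, dist.end());
    std::fill(votes.begin(), votes.end(), 0);
    for (int q = 0; q < kk; ++q) ++votes[y[dist[q].second]];
    int best = 0;
    for (int c = 1; c < K; ++c)
      if (votes[c] > votes[best]) best = c;
    if (best != y[i]) ++errors;
  }
  return errors;
}
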