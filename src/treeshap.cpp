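// Exact tree-path Shapley attributions for regression trees, plus node
// routing helpers. The attribution algorithm is the polynomial-time
// unique-path procedure for tree ensembles: it tracks, along the root-leaf
// path, the proportion of feature subsets that flow to the current node
// ("zero fraction" when the split feature is absent from the subset, "one
// fraction" when present) together with permutation weights, and reads off
// each feature's Shapley contribution at the leaves. Node "cover" is the
// number of reference samples reaching the node and defines the
// expectation used for absent features.
//
// Tree encoding (0-based): left[j] / right[j] child indices, -1 at a leaf;
// feature[j] split-variable index (-1 at a leaf); threshold[j] split
// point, routing rule x <= threshold -> left; value[j] node prediction.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct PathElem {
  int d;
  double z, o, w;
};

void extendPath(std::vector<PathElem> &m, double pz, double po, int pi) {
  PathElem e;
  e.d = pi;
  e.z = pz;
  e.o = po;
  e.w = m.empty() ? 1.0 : 0.0;
  m.push_back(e);
  int l = (int)m.size();
  for (int j = l - 2; j >= 0; --j) {
    m[j + 1].w += po * m[j].w * (j + 1) / (double)l;
    m[j].w = pz * m[j].w * (l - j - 1) / (double)l;
  }
}

// sum of the path weights after notionally removing element i
double unwoundSum(const std::vector<PathElem> &m, int i) {
  int l = (int)m.size();
  double n = m[l - 1].w, sum = 0.0;
  double oi = m[i].o, zi = m[i].z;
  for (int j = l - 2; j >= 0; --j) {
    if (oi != 0.0) {
      double t = n * l / ((j + 1) * oi);
      sum += t;
      n = m[j].w - t * zi * (l - j - 1) / (double)l;
    } else {
      sum += m[j].w * l / (zi * (l - j - 1));
    }
  }
  return sum;
}

void unwindPath(std::vector<PathElem> &m, int i) {
  int l = (int)m.size();
  double n = m[l - 1].w;
  double oi = m[i].o, zi = m[i].z;
  for (int j = l - 2; j >= 0; --j) {
    if (oi != 0.0) {
      double t = m[j].w;
      m[j].w = n * l / ((j + 1) * oi);
      n = t - m[j].w * zi * (l - j - 1) / (double)l;
    } else {
      m[j].w = m[j].w * l / (zi * (l - j - 1));
    }
  }
  for (int j = i; j < l - 1; ++j) {
    m[j].d = m[j + 1].d;
    m[j].z = m[j + 1].z;
    m[j].o = m[j + 1].o;
  }
  m.pop_back();
}

struct Tree {
  const int *left, *right, *feature;
  const double *threshold, *value, *cover;
};

void recurse(const Tree &tr, int j, std::vector<PathElem> m, double pz,
             double po, int pi, const double *x, double *phi) {
  extendPath(m, pz, po, pi);
  if (tr.left[j] < 0) {
    for (int i = 1; i < (int)m.size(); ++i) {
      double w = unwoundSum(m, i);
      phi[m[i].d] += w * (m[i].o - m[i].z) * tr.value[j];
    }
    return;
  }
  int dj = tr.feature[j];
  int h, c;
  if (x[dj] <= tr.threshold[j]) {
    h = tr.left[j];
    c = tr.right[j];
  } else {
    h = tr.right[j];
    c = tr.left[j];
  }
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int i = 1; i < (int)m.size(); ++i) {
    if (m[i].d == dj) {
      k = i;
      break;
    }
  }
  if (k >= 0) {
    iz = m[k].z;
    io = m[k].o;
    unwindPath(m, k);
  }
  recurse(tr, h, m, iz * tr.cover[h] / tr.cover[j], io, dj, x, phi);
  recurse(tr, c, m, iz * tr.cover[c] / tr.cover[j], 0.0, dj, x, phi);
}

} // namespace

// [[Rcpp::export]]
NumericMatrix tree_shap_cpp(IntegerVector left, IntegerVector right,
                            IntegerVector feature, NumericVector threshold,
                            NumericVector value, NumericVector cover,
                            NumericMatrix X) {
  int n = X.nrow(), M = X.ncol();
  NumericMatrix phi(n, M);
  Tree tr{left.begin(),      right.begin(), feature.begin(),
          threshold.begin(), value.begin(), cover.begin()};
  std::vector<double> x(M), row(M);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < M; ++k) {
      x[k] = X(i, k);
      row[k] = 0.0;
    }
    std::vector<PathElem> m;
    recurse(tr, 0, m, 1.0, 1.0, -1, x.data(), row.data());
    for (int k = 0; k < M; ++k) phi(i, k) = row[k];
  }
  return phi;
}

// [[Rcpp::export]]
NumericVector tree_node_counts_cpp(IntegerVector left, IntegerVector right,
                                   IntegerVector feature,
                                   NumericVector threshold, NumericMatrix X) {
  int n = X.nrow(), nn = left.size();
  NumericVector counts(nn);
  for (int i = 0; i < n; ++i) {
    int j = 0;
    for (;;) {
      counts[j] += 1.0;
      if (left[j] < 0) break;
      j = (X(i, feature[j]) <= threshold[j]) ? left[j] : right[j];
    }
  }
  return counts;
}

// [[Rcpp::export]]
NumericVector tree_predict_cpp(IntegerVector left, IntegerVector right,
                               IntegerVector feature, NumericVector threshold,
                               NumericVector value, NumericMatrix X) {
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int j = 0;
    while (left[j] >= 0) {
      j = (X(i, feature[j]) <= threshold[j]) ? left[j] : right[j];
    }
    out[i] = value[j];
  }
  return out;
}

// cover-weighted mean over the leaves: the expectation of the tree under
// the reference measure, i.e. the attribution base value
// [[Rcpp::export]]
double tree_expected_value_cpp(IntegerVector left, NumericVector value,
                               NumericVector cover) {
  double tot = 0.0, w = 0.0;
  for (int j = 0; j < left.size(); ++j) {
    if (left[j] < 0) {
      tot += cover[j] * value[j];
      w += cover[j];
    }
  }
  return tot / w;
}
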