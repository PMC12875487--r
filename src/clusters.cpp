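// Spatiotemporal clustering of suprathreshold statistics and the
// sign-flip permutation null. Points are (channel, time) pairs; adjacency
// couples a point to the same channel at adjacent timepoints and to
// spatially neighboring channels at the same timepoint. Clusters spanning
// fewer than `min_nb` distinct electrodes are discarded (in the observed
// data and in every permutation alike, which keeps the null exact).

#include <Rcpp.h>
using namespace Rcpp;

// flood fill over the mask; returns labels (0 = background), the summed
// statistic per cluster, and the count of distinct channels per cluster.
// Clusters below the channel-extent minimum are erased from the labels.
static void label_clusters(const std::vector<int>& mask,
                           const double* stat, int n_ch, int n_t,
                           const std::vector<std::vector<int>>& nb,
                           int min_nb,
                           std::vector<int>& labels,
                           std::vector<double>& masses) {
  labels.assign(n_ch * n_t, 0);
  masses.clear();
  std::vector<int> stack;
  std::vector<int> member;
  std::vector<char> seen_ch(n_ch);
  int next = 0;
  for (int start = 0; start < n_ch * n_t; ++start) {
    if (!mask[start] || labels[start]) continue;
    int cand = next + 1;
    double mass = 0.0;
    member.clear();
    std::fill(seen_ch.begin(), seen_ch.end(), 0);
    int n_chan = 0;
    stack.push_back(start);
    labels[start] = cand;
    while (!stack.empty()) {
      int idx = stack.back();
      stack.pop_back();
      member.push_back(idx);
      mass += stat[idx];
      int c = idx % n_ch, t = idx / n_ch;
      if (!seen_ch[c]) { seen_ch[c] = 1; ++n_chan; }
      if (t > 0) {
        int j = idx - n_ch;
        if (mask[j] && !labels[j]) { labels[j] = cand; stack.push_back(j); }
      }
      if (t + 1 < n_t) {
        int j = idx + n_ch;
        if (mask[j] && !labels[j]) { labels[j] = cand; stack.push_back(j); }
      }
      for (int k : nb[c]) {
        int j = t * n_ch + k;
        if (mask[j] && !labels[j]) { labels[j] = cand; stack.push_back(j); }
      }
    }
    if (n_chan < min_nb) {
      for (int idx : member) labels[idx] = 0; // too few electrodes
    } else {
      ++next;
      if (cand != next) for (int idx : member) labels[idx] = next;
      masses.push_back(mass);
    }
  }
}

static std::vector<std::vector<int>> adj_to_vec(const List& adj) {
  int n = adj.size();
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adj[i];
    for (int j = 0; j < v.size(); ++j) nb[i].push_back(v[j] - 1);
  }
  return nb;
}

// [[Rcpp::export]]
List find_clusters_cpp(NumericMatrix tmat, double t_crit, List adj,
                       int min_nb) {
  int n_ch = tmat.nrow(), n_t = tmat.ncol();
  auto nb = adj_to_vec(adj);
  IntegerMatrix labels_out(n_ch, n_t);
  std::vector<double> all_masses;
  std::vector<int> all_signs;
  int offset = 0;
  for (int sign = 0; sign < 2; ++sign) {
    std::vector<int> mask(n_ch * n_t, 0);
    for (int i = 0; i < n_ch * n_t; ++i) {
      double v = tmat[i];
      mask[i] = sign == 0 ? (v > t_crit) : (v < -t_crit);
    }
    std::vector<int> labels;
    std::vector<double> masses;
    label_clusters(mask, REAL(tmat), n_ch, n_t, nb, min_nb, labels, masses);
    for (int i = 0; i < n_ch * n_t; ++i) {
      if (labels[i]) labels_out[i] = labels[i] + offset;
    }
    for (double m : masses) {
      all_masses.push_back(m);
      all_signs.push_back(sign == 0 ? 1 : -1);
    }
    offset += masses.size();
  }
  return List::create(_["labels"] = labels_out,
                      _["mass"] = wrap(all_masses),
                      _["polarity"] = wrap(all_signs));
}

// Sign-flip permutation null of the maximum absolute cluster mass.
// D: subjects x points matrix of condition differences (points ordered
// channel-fastest); signs: n_perm x subjects of +-1.
// [[Rcpp::export]]
NumericVector perm_null_max_mass_cpp(NumericMatrix D, IntegerMatrix signs,
                                     double t_crit, List adj, int n_ch,
                                     int n_t, int min_nb) {
  int n_sub = D.nrow(), P = D.ncol(), n_perm = signs.nrow();
  auto nb = adj_to_vec(adj);
  std::vector<double> ss(P, 0.0);
  for (int p = 0; p < P; ++p) {
    for (int s = 0; s < n_sub; ++s) ss[p] += D(s, p) * D(s, p);
  }
  NumericVector out(n_perm);
  std::vector<double> tvec(P);
  std::vector<int> mask(P);
  std::vector<int> labels;
  std::vector<double> masses;
  for (int r = 0; r < n_perm; ++r) {
    for (int p = 0; p < P; ++p) {
      double m = 0.0;
      for (int s = 0; s < n_sub; ++s) m += signs(r, s) * D(s, p);
      m /= n_sub;
      double var = (ss[p] - n_sub * m * m) / (n_sub - 1);
      tvec[p] = var > 0 ? m / std::sqrt(var / n_sub) : 0.0;
    }
    double best = 0.0;
    for (int sign = 0; sign < 2; ++sign) {
      for (int p = 0; p < P; ++p) {
        mask[p] = sign == 0 ? (tvec[p] > t_crit) : (tvec[p] < -t_crit);
      }
      label_clusters(mask, tvec.data(), n_ch, n_t, nb, min_nb, labels, masses);
      for (double m : masses) best = std::max(best, std::fabs(m));
    }
    out[r] = best;
  }
  return out;
}
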