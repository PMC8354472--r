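#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 2x2 transition probabilities of the two-state gain/loss chain.
// States: 0 = absent, 1 = present.  gain g: 0->1, loss l: 1->0.
static inline void tmat(double g, double l, double t, double P[2][2]) {
  double tot = g + l;
  if (tot <= 0.0 || t <= 0.0) {
    P[0][0] = 1.0; P[0][1] = 0.0; P[1][0] = 0.0; P[1][1] = 1.0;
    return;
  }
  double e = std::exp(-tot * t);
  P[0][1] = g / tot * (1.0 - e);
  P[0][0] = 1.0 - P[0][1];
  P[1][0] = l / tot * (1.0 - e);
  P[1][1] = 1.0 - P[1][0];
}

// Felsenstein pruning over all loci at once.
// child1/child2: 0-based child indices per node, -1 for tips.
// brlen: branch length above each node (ignored for root).
// postorder: 0-based node visit order, children before parents.
// tipstate: loci x nnode matrix; tips coded 0 absent / 1 present /
//           2 uncertain; internal columns ignored (-1 conventionally).
// rootp: nloci x 2 matrix of per-locus priors over (absent, present) at
// the root; a single-row matrix is recycled over loci.
// [[Rcpp::export]]
NumericVector pruning_loglik_cpp(IntegerVector child1, IntegerVector child2,
                                 NumericVector brlen, IntegerVector postorder,
                                 int root, IntegerMatrix tipstate,
                                 double g, double l, NumericMatrix rootp) {
  int nnode = child1.size();
  int nloci = tipstate.nrow();
  // partial likelihoods, nloci x 2 per node
  std::vector<double> up(2.0 * nnode * nloci);
  std::vector<double> scale(nloci, 0.0); // log scaling accumulators
  double P1[2][2], P2[2][2];
  for (int oi = 0; oi < postorder.size(); ++oi) {
    int v = postorder[oi];
    double *Lv = &up[(size_t)v * 2 * nloci];
    if (child1[v] < 0) { // tip
      for (int c = 0; c < nloci; ++c) {
        int s = tipstate(c, v);
        if (s == 2) { Lv[c] = 1.0; Lv[nloci + c] = 1.0; }
        else if (s == 1) { Lv[c] = 0.0; Lv[nloci + c] = 1.0; }
        else { Lv[c] = 1.0; Lv[nloci + c] = 0.0; }
      }
    } else {
      int a = child1[v], b = child2[v];
      double *La = &up[(size_t)a * 2 * nloci];
      double *Lb = &up[(size_t)b * 2 * nloci];
      tmat(g, l, brlen[a], P1);
      tmat(g, l, brlen[b], P2);
      for (int c = 0; c < nloci; ++c) {
        double a0 = P1[0][0] * La[c] + P1[0][1] * La[nloci + c];
        double a1 = P1[1][0] * La[c] + P1[1][1] * La[nloci + c];
        double b0 = P2[0][0] * Lb[c] + P2[0][1] * Lb[nloci + c];
        double b1 = P2[1][0] * Lb[c] + P2[1][1] * Lb[nloci + c];
        double v0 = a0 * b0, v1 = a1 * b1;
        double m = (v0 > v1) ? v0 : v1;
        if (m > 0 && m < 1e-200) { v0 /= m; v1 /= m; scale[c] += std::log(m); }
        Lv[c] = v0; Lv[nloci + c] = v1;
      }
    }
  }
  NumericVector out(nloci);
  double *Lr = &up[(size_t)root * 2 * nloci];
  bool rec = rootp.nrow() == 1;
  for (int c = 0; c < nloci; ++c) {
    int rc = rec ? 0 : c;
    double lik = rootp(rc, 0) * Lr[c] + rootp(rc, 1) * Lr[nloci + c];
    out[c] = std::log(lik) + scale[c];
  }
  return out;
}

// Marginal posterior probability of presence at every node, by the
// standard up (pruning) / down (outside message) two-pass algorithm.
// Returns an nloci x nnode matrix of P(present).
// [[Rcpp::export]]
NumericMatrix marginal_posteriors_cpp(IntegerVector child1, IntegerVector child2,
                                      NumericVector brlen, IntegerVector postorder,
                                      int root, IntegerMatrix tipstate,
                                      double g, double l, NumericMatrix rootp) {
  int nnode = child1.size();
  int nloci = tipstate.nrow();
  std::vector<double> up(2.0 * nnode * nloci);
  double P1[2][2], P2[2][2];
  for (int oi = 0; oi < postorder.size(); ++oi) {
    int v = postorder[oi];
    double *Lv = &up[(size_t)v * 2 * nloci];
    if (child1[v] < 0) {
      for (int c = 0; c < nloci; ++c) {
        int s = tipstate(c, v);
        if (s == 2) { Lv[c] = 1.0; Lv[nloci + c] = 1.0; }
        else if (s == 1) { Lv[c] = 0.0; Lv[nloci + c] = 1.0; }
        else { Lv[c] = 1.0; Lv[nloci + c] = 0.0; }
      }
    } else {
      int a = child1[v], b = child2[v];
      double *La = &up[(size_t)a * 2 * nloci];
      double *Lb = &up[(size_t)b * 2 * nloci];
      tmat(g, l, brlen[a], P1);
      tmat(g, l, brlen[b], P2);
      for (int c = 0; c < nloci; ++c) {
        double a0 = P1[0][0] * La[c] + P1[0][1] * La[nloci + c];
        double a1 = P1[1][0] * La[c] + P1[1][1] * La[nloci + c];
        double b0 = P2[0][0] * Lb[c] + P2[0][1] * Lb[nloci + c];
        double b1 = P2[1][0] * Lb[c] + P2[1][1] * Lb[nloci + c];
        double v0 = a0 * b0, v1 = a1 * b1;
        double m = (v0 > v1) ? v0 : v1;
        if (m > 0) { v0 /= m; v1 /= m; } // rescale; marginals are ratios
        Lv[c] = v0; Lv[nloci + c] = v1;
      }
    }
  }
  // down pass (preorder = reverse postorder)
  std::vector<double> down(2.0 * nnode * nloci);
  double *Dr = &down[(size_t)root * 2 * nloci];
  bool rec = rootp.nrow() == 1;
  for (int c = 0; c < nloci; ++c) {
    int rc = rec ? 0 : c;
    Dr[c] = rootp(rc, 0); Dr[nloci + c] = rootp(rc, 1);
  }
  for (int oi = postorder.size() - 1; oi >= 0; --oi) {
    int u = postorder[oi];
    if (child1[u] < 0) continue;
    int a = child1[u], b = child2[u];
    double *Du = &down[(size_t)u * 2 * nloci];
    double *Da = &down[(size_t)a * 2 * nloci];
    double *Db = &down[(size_t)b * 2 * nloci];
    double *La = &up[(size_t)a * 2 * nloci];
    double *Lb = &up[(size_t)b * 2 * nloci];
    tmat(g, l, brlen[a], P1);
    tmat(g, l, brlen[b], P2);
    for (int c = 0; c < nloci; ++c) {
      // message into a excludes a's subtree: down[u] * (P_b %*% up[b])
      double sb0 = P2[0][0] * Lb[c] + P2[0][1] * Lb[nloci + c];
      double sb1 = P2[1][0] * Lb[c] + P2[1][1] * Lb[nloci + c];
      double ha0 = Du[c] * sb0, ha1 = Du[nloci + c] * sb1;
      Da[c] = ha0 * P1[0][0] + ha1 * P1[1][0];
      Da[nloci + c] = ha0 * P1[0][1] + ha1 * P1[1][1];
      double sa0 = P1[0][0] * La[c] + P1[0][1] * La[nloci + c];
      double sa1 = P1[1][0] * La[c] + P1[1][1] * La[nloci + c];
      double hb0 = Du[c] * sa0, hb1 = Du[nloci + c] * sa1;
      Db[c] = hb0 * P2[0][0] + hb1 * P2[1][0];
      Db[nloci + c] = hb0 * P2[0][1] + hb1 * P2[1][1];
      double m;
      m = (Da[c] > Da[nloci + c]) ? Da[c] : Da[nloci + c];
      if (m > 0) { Da[c] /= m; Da[nloci + c] /= m; }
      m = (Db[c] > Db[nloci + c]) ? Db[c] : Db[nloci + c];
      if (m > 0) { Db[c] /= m; Db[nloci + c] /= m; }
    }
  }
  NumericMatrix out(nloci, nnode);
  for (int v = 0; v < nnode; ++v) {
    double *Lv = &up[(size_t)v * 2 * nloci];
    double *Dv = &down[(size_t)v * 2 * nloci];
    for (int c = 0; c < nloci; ++c) {
      double p0 = Lv[c] * Dv[c];
      double p1 = Lv[nloci + c] * Dv[nloci + c];
      out(c, v) = p1 / (p0 + p1);
    }
  }
  return out;
}
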