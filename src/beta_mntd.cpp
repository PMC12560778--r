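#include <Rcpp.h>
using namespace Rcpp;

// beta-MNTD over all sample pairs.
// D: taxa x taxa patristic distance matrix
// W: samples x taxa abundances (any scale; weights are renormalised)
// perm: 0-based permutation mapping matrix taxa to tree positions
//       (identity for the observed statistic, shuffled for nulls)
static void bmntd_fill(const NumericMatrix& D,
                       const std::vector<std::vector<int> >& pres,
                       const std::vector<std::vector<double> >& wts,
                       const std::vector<int>& perm,
                       NumericMatrix& out) {
  int S = pres.size();
  for (int i = 0; i < S - 1; ++i) {
    for (int j = i + 1; j < S; ++j) {
      double part_i = 0.0, part_j = 0.0;
      for (size_t a = 0; a < pres[i].size(); ++a) {
        int ta = perm[pres[i][a]];
        double mn = R_PosInf;
        for (size_t b = 0; b < pres[j].size(); ++b) {
          double d = D(ta, perm[pres[j][b]]);
          if (d < mn) mn = d;
        }
        part_i += wts[i][a] * mn;
      }
      for (size_t b = 0; b < pres[j].size(); ++b) {
        int tb = perm[pres[j][b]];
        double mn = R_PosInf;
        for (size_t a = 0; a < pres[i].size(); ++a) {
          double d = D(perm[pres[i][a]], tb);
          if (d < mn) mn = d;
        }
        part_j += wts[j][b] * mn;
      }
      out(i, j) = out(j, i) = 0.5 * (part_i + part_j);
    }
  }
}

static void build_lists(const NumericMatrix& W, bool weighted,
                        std::vector<std::vector<int> >& pres,
                        std::vector<std::vector<double> >& wts) {
  int S = W.nrow(), T = W.ncol();
  pres.assign(S, std::vector<int>());
  wts.assign(S, std::vector<double>());
  for (int s = 0; s < S; ++s) {
    double tot = 0.0;
    for (int t = 0; t < T; ++t) {
      if (W(s, t) > 0) { pres[s].push_back(t); tot += W(s, t); }
    }
    if (pres[s].empty()) stop("sample %d has no taxa", s + 1);
    for (size_t k = 0; k < pres[s].size(); ++k) {
      wts[s].push_back(weighted ? W(s, pres[s][k]) / tot
                                : 1.0 / pres[s].size());
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_beta_mntd(NumericMatrix D, NumericMatrix W, bool weighted) {
  std::vector<std::vector<int> > pres;
  std::vector<std::vector<double> > wts;
  build_lists(W, weighted, pres, wts);
  std::vector<int> ident(W.ncol());
  for (int t = 0; t < W.ncol(); ++t) ident[t] = t;
  NumericMatrix out(W.nrow(), W.nrow());
  bmntd_fill(D, pres, wts, ident, out);
  return out;
}

// One pass computing the observed beta-MNTD and the per-pair mean and sd
// of the tip-shuffle null. perms: n_null x n_taxa, 1-based permutations.
// [[Rcpp::export]]
List cpp_beta_nti(NumericMatrix D, NumericMatrix W, bool weighted,
                  IntegerMatrix perms) {
  int S = W.nrow(), T = W.ncol(), R = perms.nrow();
  std::vector<std::vector<int> > pres;
  std::vector<std::vector<double> > wts;
  build_lists(W, weighted, pres, wts);

  std::vector<int> ident(T);
  for (int t = 0; t < T; ++t) ident[t] = t;
  NumericMatrix obs(S, S);
  bmntd_fill(D, pres, wts, ident, obs);

  NumericMatrix sum(S, S), sumsq(S, S), nullmat(S, S);
  std::vector<int> perm(T);
  for (int r = 0; r < R; ++r) {
    for (int t = 0; t < T; ++t) perm[t] = perms(r, t) - 1;
    bmntd_fill(D, pres, wts, perm, nullmat);
    for (int i = 0; i < S; ++i) {
      for (int j = 0; j < S; ++j) {
        sum(i, j) += nullmat(i, j);
        sumsq(i, j) += nullmat(i, j) * nullmat(i, j);
      }
    }
    if (r % 16 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix mean(S, S), sd(S, S);
  for (int i = 0; i < S; ++i) {
    for (int j = 0; j < S; ++j) {
      mean(i, j) = sum(i, j) / R;
      double v = (sumsq(i, j) - sum(i, j) * sum(i, j) / R) / (R - 1);
      sd(i, j) = v > 0 ? std::sqrt(v) : 0.0;
    }
  }
  return List::create(_["obs"] = obs, _["null_mean"] = mean,
                      _["null_sd"] = sd);
}
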