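// Support search for truncated-L1 (L0-surrogate) constrained least squares.
// Works entirely on the Gram matrix G = X'X and c = X'y, so a single fit and
// the many refits on perturbed responses share the same O(K^3) inner solves.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// RSS of least squares restricted to columns `idx`; yty if idx is empty or
// the restricted system is singular (treated as an invalid move).
static double support_rss(const arma::mat& G, const arma::vec& c, double yty,
                          const arma::uvec& idx) {
  if (idx.n_elem == 0) return yty;
  arma::vec b;
  bool ok = arma::solve(b, G.submat(idx, idx), c.elem(idx),
                        arma::solve_opts::no_approx);
  if (!ok) return R_PosInf;
  return yty - arma::dot(b, c.elem(idx));
}

static arma::uvec full_index(const std::vector<unsigned int>& S, int l) {
  arma::uvec idx(S.size() + (l >= 0 ? 1 : 0));
  unsigned int k = 0;
  if (l >= 0) idx(k++) = (unsigned int)l;
  for (unsigned int j : S) idx(k++) = j;
  return idx;
}

// Greedy steepest-descent search over supports of size <= K among the
// penalized coordinates (coordinate l, if >= 0, is always in the model and
// never penalized). Moves are single additions and single swaps; each move
// strictly decreases the residual sum of squares, so the objective
// trajectory is monotone. Multiple starts guard against local optima.
// [[Rcpp::export]]
List tlp_search_cpp(const arma::mat& G, const arma::vec& c, double yty,
                    int K, int l, List starts, int max_moves) {
  const unsigned int p = G.n_rows;
  double best_rss = R_PosInf;
  std::vector<unsigned int> best_S;
  std::vector<double> best_traj;

  for (int s = 0; s < starts.size(); ++s) {
    IntegerVector st = starts[s];
    std::vector<unsigned int> S;
    std::vector<bool> inS(p, false);
    for (int k = 0; k < st.size() && (int)S.size() < K; ++k) {
      int j = st[k];
      if (j < 0 || j >= (int)p || j == l || inS[j]) continue;
      S.push_back((unsigned int)j);
      inS[j] = true;
    }
    double rss = support_rss(G, c, yty, full_index(S, l));
    std::vector<double> traj;
    traj.push_back(rss);

    int moves = 0;
    while (moves < max_moves) {
      double cand_rss = rss;
      int cand_add = -1, cand_out = -1;
      // additions
      if ((int)S.size() < K) {
        for (unsigned int j = 0; j < p; ++j) {
          if ((int)j == l || inS[j]) continue;
          std::vector<unsigned int> Sx = S;
          Sx.push_back(j);
          double r = support_rss(G, c, yty, full_index(Sx, l));
          if (r < cand_rss - 1e-12) { cand_rss = r; cand_add = j; cand_out = -1; }
        }
      }
      // swaps
      for (size_t o = 0; o < S.size(); ++o) {
        std::vector<unsigned int> Sx = S;
        for (unsigned int j = 0; j < p; ++j) {
          if ((int)j == l || inS[j]) continue;
          Sx[o] = j;
          double r = support_rss(G, c, yty, full_index(Sx, l));
          if (r < cand_rss - 1e-12) { cand_rss = r; cand_add = j; cand_out = o; }
        }
      }
      if (cand_add < 0) break;
      if (cand_out < 0) {
        S.push_back((unsigned int)cand_add);
      } else {
        inS[S[cand_out]] = false;
        S[cand_out] = (unsigned int)cand_add;
      }
      inS[cand_add] = true;
      rss = cand_rss;
      traj.push_back(rss);
      ++moves;
    }
    if (rss < best_rss - 1e-12) {
      best_rss = rss;
      best_S = S;
      best_traj = traj;
    }
  }

  arma::uvec idx = full_index(best_S, l);
  arma::vec beta(p, arma::fill::zeros);
  if (idx.n_elem > 0) {
    arma::vec b;
    arma::solve(b, G.submat(idx, idx), c.elem(idx), arma::solve_opts::no_approx);
    for (unsigned int k = 0; k < idx.n_elem; ++k) beta(idx(k)) = b(k);
  }
  return List::create(
    _["support"] = IntegerVector(best_S.begin(), best_S.end()),
    _["beta"] = beta,
    _["rss"] = best_rss,
    _["trajectory"] = NumericVector(best_traj.begin(), best_traj.end()));
}
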