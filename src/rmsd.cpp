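#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Kabsch superposition of P onto Q (both n x 3, rows are points).
// Returns the proper rotation R (det +1), translation t and the minimized
// RMSD of R p + t against Q. Reflection-optimal alignments are resolved by
// flipping the sign of the singular vector with the smallest singular value.
static double kabsch_core(const arma::mat &P, const arma::mat &Q,
                          arma::mat &R, arma::vec &t) {
  const arma::uword n = P.n_rows;
  arma::rowvec cp = arma::mean(P, 0), cq = arma::mean(Q, 0);
  R.eye(3, 3);
  if (n == 1) {
    t = (cq - cp).t();
    return 0.0;
  }
  arma::mat Pc = P.each_row() - cp;
  arma::mat Qc = Q.each_row() - cq;
  arma::mat H = Pc.t() * Qc;   // 3 x 3 covariance
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) Rcpp::stop("SVD failed in Kabsch superposition");
  double d = arma::det(V * U.t());
  arma::mat D = arma::eye(3, 3);
  if (d < 0) D(2, 2) = -1.0;   // smallest singular value is last
  R = V * D * U.t();
  t = cq.t() - R * cp.t();
  arma::mat diff = Pc * R.t() - Qc;
  double msd = arma::accu(diff % diff) / double(n);
  return std::sqrt(std::max(msd, 0.0));
}

static double plain_rmsd(const arma::mat &A, const arma::mat &B) {
  arma::mat diff = A - B;
  double msd = arma::accu(diff % diff) / double(A.n_rows);
  return std::sqrt(std::max(msd, 0.0));
}

// [[Rcpp::export]]
List cpp_kabsch(const arma::mat &P, const arma::mat &Q) {
  if (P.n_rows != Q.n_rows)
    Rcpp::stop("point counts differ (%d vs %d)", P.n_rows, Q.n_rows);
  if (P.n_rows < 1) Rcpp::stop("need at least one point");
  arma::mat R;
  arma::vec t;
  double r = kabsch_core(P, Q, R, t);
  return List::create(_["rotation"] = R, _["translation"] = t, _["rmsd"] = r);
}

// Minimum RMSD of A against B over a set of atom permutations applied to the
// rows of B (perms: m x n, 1-based). align toggles Kabsch minimization inside
// the search. Returns c(min_rmsd, argmin_perm_index).
// [[Rcpp::export]]
NumericVector cpp_rmsd_perms(const arma::mat &A, const arma::mat &B,
                             const IntegerMatrix &perms, bool align) {
  const int n = A.n_rows;
  if ((int)B.n_rows != n) Rcpp::stop("atom counts differ");
  if (perms.ncol() != n) Rcpp::stop("permutation length mismatch");
  double best = R_PosInf;
  int best_i = 0;
  arma::mat Bp(n, 3), R;
  arma::vec t;
  for (int m = 0; m < perms.nrow(); ++m) {
    for (int k = 0; k < n; ++k) {
      int src = perms(m, k) - 1;
      Bp.row(k) = B.row(src);
    }
    double r = align ? kabsch_core(A, Bp, R, t) : plain_rmsd(A, Bp);
    if (r < best) {
      best = r;
      best_i = m + 1;
      if (best <= 0.0) break;
    }
  }
  return NumericVector::create(best, (double)best_i);
}

// Greedy energy-sorted RMSD-diversity filter. ord: candidate conformer
// indices in ascending-energy order (1-based into the coords list); coords:
// list of k x 3 matrices (heavy-atom coordinates, shared atom order); perms:
// automorphism permutations of the heavy atoms. A candidate is kept iff its
// (optionally aligned) symmetry-corrected RMSD to every already kept
// conformer exceeds the threshold. Stops after max_n selections.
// [[Rcpp::export]]
IntegerVector cpp_greedy_filter(const List &coords, const IntegerVector &ord,
                                const IntegerMatrix &perms, double threshold,
                                int max_n, bool align) {
  std::vector<arma::mat> C;
  C.reserve(coords.size());
  for (int i = 0; i < coords.size(); ++i)
    C.push_back(as<arma::mat>(coords[i]));
  std::vector<int> kept;
  const int n = C.empty() ? 0 : C[0].n_rows;
  arma::mat Bp(n, 3), R;
  arma::vec t;
  for (int oi = 0; oi < ord.size(); ++oi) {
    if ((int)kept.size() >= max_n) break;
    int cand = ord[oi] - 1;
    bool ok = true;
    for (size_t s = 0; s < kept.size() && ok; ++s) {
      // min over automorphisms of rmsd(kept, perm(cand))
      double best = R_PosInf;
      for (int m = 0; m < perms.nrow() && best > threshold; ++m) {
        for (int k = 0; k < n; ++k)
          Bp.row(k) = C[cand].row(perms(m, k) - 1);
        double r = align ? kabsch_core(C[kept[s]], Bp, R, t)
                         : plain_rmsd(C[kept[s]], Bp);
        if (r < best) best = r;
      }
      if (best <= threshold) ok = false;
    }
    if (ok) kept.push_back(cand);
  }
  IntegerVector out(kept.size());
  for (size_t i = 0; i < kept.size(); ++i) out[i] = kept[i] + 1;
  return out;
}
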