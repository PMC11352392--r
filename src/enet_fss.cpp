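#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Feature-sign search for
//   min_w ||x - P w||^2 + lambda1 ||w||_1 + lambda2 ||w||_2^2
// in Gram form (G = P'P, q = P'x), along a warm-started lambda1 path.
//
// The deviation profiles this solver sees are almost collinear, which makes
// first-order coordinate descent crawl; an active-set method with exact
// restricted solves converges in a handful of small linear systems instead.
// The Cholesky factor of G_AA + lambda2 I is maintained incrementally
// (rank-1 extension per activation; full refactorization only after the
// rare sign-crossing drops). Off-support coefficients are exact zeros.
// Termination requires the full KKT conditions: |2(q_j - (Gw)_j)| <=
// lambda1 for inactive j; restricted stationarity is exact by construction.

static double obj_active(const arma::mat& GA, const arma::vec& qA,
                         const arma::vec& wA, double lam1, double lam2) {
  return arma::as_scalar(wA.t() * GA * wA) - 2.0 * arma::dot(qA, wA) +
         lam2 * arma::dot(wA, wA) + lam1 * arma::accu(arma::abs(wA));
}

// triangular solves against the maintained upper factor R ('R'R = M_AA)
static arma::vec chol_solve(const arma::mat& R, const arma::vec& rhs) {
  arma::vec y = arma::solve(arma::trimatl(R.t()), rhs);
  return arma::solve(arma::trimatu(R), y);
}

// [[Rcpp::export(name = ".enet_fss_path")]]
List enet_fss_path(const arma::mat& G, const arma::vec& q,
                   const arma::vec& lambda1, double lambda2, int maxit,
                   double tol) {
  const int p = (int)q.n_elem;
  const int L = (int)lambda1.n_elem;
  arma::mat W(p, L, arma::fill::zeros);
  IntegerVector iters(L);
  LogicalVector converged(L);
  NumericVector final_kkt(L);

  const double scale = std::max(1.0, 2.0 * arma::abs(q).max());
  const double ktol = tol * scale;

  std::vector<arma::uword> A;      // active indices, warm-started along path
  arma::vec w(p, arma::fill::zeros);
  arma::vec theta(p, arma::fill::zeros);   // sign state of active coords
  arma::mat R;                      // chol factor for current A (in order)

  auto refactor = [&]() {
    const arma::uvec Ai(A);
    arma::mat M = G.submat(Ai, Ai);
    M.diag() += lambda2;
    if (!arma::chol(R, M)) {
      M.diag() += 1e-10;            // numerically semidefinite corner case
      arma::chol(R, M);
    }
  };

  for (int l = 0; l < L; ++l) {
    const double lam1 = lambda1[l];
    int it = 0;
    bool ok = false;
    double kkt = R_PosInf;

    if (lam1 <= 0.0) {             // pure ridge: dense exact solve
      arma::mat M = G + lambda2 * arma::eye(p, p);
      w = arma::solve(M, q, arma::solve_opts::likely_sympd);
      A.clear();
      for (int j = 0; j < p; ++j) {
        if (w[j] != 0.0) { A.push_back(j); theta[j] = (w[j] > 0) ? 1 : -1; }
      }
      refactor();
      W.col(l) = w;
      iters[l] = 1;
      converged[l] = true;
      final_kkt[l] = 0.0;
      continue;
    }

    while (it++ < maxit) {
      // ---- restricted optimization over the current support ----
      int inner_guard = 0;
      while (!A.empty() && inner_guard++ < maxit) {
        const arma::uvec Ai(A);
        arma::vec wA = w.elem(Ai);
        const arma::vec thA = theta.elem(Ai);
        const arma::vec qA = q.elem(Ai);
        arma::vec wNew = chol_solve(R, qA - 0.5 * lam1 * thA);
        bool consistent = true;
        for (arma::uword a = 0; a < wNew.n_elem; ++a) {
          if (wNew[a] * thA[a] <= 0.0) { consistent = false; break; }
        }
        if (consistent) {
          w.elem(Ai) = wNew;
          break;
        }
        // line search from wA toward wNew over sign-crossing points
        arma::mat GA = G.submat(Ai, Ai);
        GA.diag() += lambda2;
        const arma::vec d = wNew - wA;
        std::vector<double> ts;
        ts.push_back(1.0);
        for (arma::uword a = 0; a < wA.n_elem; ++a) {
          if (d[a] != 0.0) {
            const double t = -wA[a] / d[a];
            if (t > 0.0 && t < 1.0) ts.push_back(t);
          }
        }
        double best_f = obj_active(GA, qA, wA, lam1, lambda2) - ktol * 1e-3;
        arma::vec best_w = wA;
        bool improved = false;
        for (double t : ts) {
          arma::vec wt = wA + t * d;
          if (t < 1.0) {             // zero the crossing coordinate exactly
            arma::uword amin = arma::index_min(arma::abs(wt));
            wt[amin] = 0.0;
          } else {
            // full step: coordinates that crossed flip sign legitimately
            for (arma::uword a = 0; a < wt.n_elem; ++a) {
              if (std::fabs(wt[a]) < 1e-300) wt[a] = 0.0;
            }
          }
          const double f = obj_active(GA, qA, wt, lam1, lambda2);
          if (f < best_f) { best_f = f; best_w = wt; improved = true; }
        }
        if (!improved) {             // numerically stalled; keep wA
          w.elem(Ai) = wA;
          break;
        }
        w.elem(Ai) = best_w;
        bool dropped = false;
        std::vector<arma::uword> keep;
        for (arma::uword a = 0; a < Ai.n_elem; ++a) {
          if (w[Ai[a]] != 0.0) {
            keep.push_back(Ai[a]);
            theta[Ai[a]] = (w[Ai[a]] > 0) ? 1 : -1;
          } else {
            theta[Ai[a]] = 0;
            dropped = true;
          }
        }
        if (dropped) { A = keep; if (!A.empty()) refactor(); }
      }
      // ---- global KKT check / activation ----
      arma::vec Gw(p, arma::fill::zeros);
      if (!A.empty()) {
        const arma::uvec Ai(A);
        Gw = G.cols(Ai) * w.elem(Ai);
      }
      arma::vec viol = 2.0 * arma::abs(q - Gw);
      for (arma::uword j : A) viol[j] = 0.0;
      const arma::uword jmax = viol.index_max();
      kkt = viol[jmax] - lam1;
      if (kkt <= ktol) { ok = true; break; }
      // extend the Cholesky factor by the entering index
      const arma::uword na = A.size();
      if (na == 0) {
        R.set_size(1, 1);
        R(0, 0) = std::sqrt(G(jmax, jmax) + lambda2);
      } else {
        const arma::uvec Ai(A);
        arma::vec colG = G.submat(Ai, arma::uvec{jmax});
        arma::vec r = arma::solve(arma::trimatl(R.t()), colG);
        double rho2 = G(jmax, jmax) + lambda2 - arma::dot(r, r);
        if (rho2 < 1e-12) rho2 = 1e-12;
        arma::mat R2(na + 1, na + 1, arma::fill::zeros);
        R2.submat(0, 0, na - 1, na - 1) = R;
        R2.submat(0, na, na - 1, na) = r;
        R2(na, na) = std::sqrt(rho2);
        R = std::move(R2);
      }
      A.push_back(jmax);
      w[jmax] = 0.0;
      theta[jmax] = (q[jmax] - Gw[jmax] > 0) ? 1.0 : -1.0;
    }
    W.col(l) = w;
    iters[l] = it;
    converged[l] = ok;
    final_kkt[l] = kkt;
  }
  return List::create(_["W"] = Rcpp::wrap(W), _["iters"] = iters,
                      _["converged"] = converged, _["final_kkt"] = final_kkt);
}
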