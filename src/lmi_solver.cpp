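// Dense-block interior-point solver for systems of affine linear matrix
// inequalities  F_k(x) = F_k0 + sum_j x_{v_kj} A_kj  <  0,  k = 1..m,
// optionally minimizing a linear objective c'x.
//
// Classic log-barrier path following: at barrier weight tau, minimize
//   tau * c'x - sum_k log det(-F_k(x))
// by damped Newton with a positive-definiteness-preserving line search,
// then increase tau geometrically.  Feasibility ("phase I") is obtained on
// the R side by appending a slack variable t with identity basis to every
// block and minimizing t.  Problem sizes here are small (a few hundred
// scalar variables, a few thousand blocks of order <= 16), so dense
// Hessians are adequate.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct Block {
  arma::mat F0;
  arma::uvec vidx;   // 0-based global variable indices
  arma::cube bases;  // n x n x nv
};

static std::vector<Block> unpack_blocks(const List& blocks) {
  std::vector<Block> out;
  out.reserve(blocks.size());
  for (int k = 0; k < blocks.size(); ++k) {
    List bl = blocks[k];
    Block b;
    b.F0 = as<arma::mat>(bl["F0"]);
    arma::ivec vi = as<arma::ivec>(bl["vidx"]);
    b.vidx = arma::conv_to<arma::uvec>::from(vi - 1);
    b.bases = as<arma::cube>(bl["bases"]);
    out.push_back(std::move(b));
  }
  return out;
}

static arma::mat block_value(const Block& b, const arma::vec& x) {
  arma::mat F = b.F0;
  for (arma::uword j = 0; j < b.vidx.n_elem; ++j)
    F += x(b.vidx(j)) * b.bases.slice(j);
  return F;
}

// true if -F_k(x) is positive definite for all k
static bool strictly_feasible(const std::vector<Block>& blocks,
                              const arma::vec& x) {
  arma::mat L;
  for (const Block& b : blocks) {
    arma::mat S = -block_value(b, x);
    if (!arma::chol(L, S, "lower")) return false;
  }
  return true;
}

// barrier value phi(x) = -sum_k log det(-F_k(x)); +Inf if infeasible
static double barrier_value(const std::vector<Block>& blocks,
                            const arma::vec& x) {
  double phi = 0.0;
  arma::mat L;
  for (const Block& b : blocks) {
    arma::mat S = -block_value(b, x);
    if (!arma::chol(L, S, "lower")) return arma::datum::inf;
    phi -= 2.0 * arma::accu(arma::log(L.diag()));
  }
  return phi;
}

// gradient and Hessian of phi at strictly feasible x
static void barrier_derivs(const std::vector<Block>& blocks, const arma::vec& x,
                           arma::vec& g, arma::mat& H) {
  g.zeros();
  H.zeros();
  for (const Block& b : blocks) {
    arma::mat S = -block_value(b, x);
    arma::mat Sinv = arma::inv_sympd(S);
    arma::uword nv = b.vidx.n_elem;
    std::vector<arma::mat> W(nv);
    for (arma::uword j = 0; j < nv; ++j) {
      W[j] = Sinv * b.bases.slice(j);
      g(b.vidx(j)) += arma::trace(W[j]);
    }
    for (arma::uword j = 0; j < nv; ++j) {
      arma::mat WjT = W[j].t();
      for (arma::uword l = j; l < nv; ++l) {
        double hjl = arma::accu(WjT % W[l]);
        H(b.vidx(j), b.vidx(l)) += hjl;
        if (l != j) H(b.vidx(l), b.vidx(j)) += hjl;
      }
    }
  }
}

//' @noRd
// [[Rcpp::export(name = ".lmi_barrier_cpp")]]
List lmi_barrier_cpp(List blocks_in, int nvar, arma::vec c, arma::vec x0,
                     double tau0 = 1.0, double mu = 10.0,
                     double tol_gap = 1e-7, int max_outer = 60,
                     int max_newton = 80,
                     double early_stop_obj = NA_REAL,
                     double ridge = 1e-12) {
  std::vector<Block> blocks = unpack_blocks(blocks_in);
  arma::vec x = x0;
  if (!strictly_feasible(blocks, x))
    return List::create(_["x"] = x, _["status"] = "start_infeasible",
                        _["obj"] = NA_REAL, _["gap"] = NA_REAL,
                        _["newton_iters"] = 0);

  double Ntot = 0.0;
  for (const Block& b : blocks) Ntot += (double)b.F0.n_rows;

  double tau = tau0;
  int total_newton = 0;
  std::string status = "max_outer";
  bool early = !ISNA(early_stop_obj);
  bool centered = false;  // did the last centering reach its tolerance?

  arma::vec g(nvar), gtot(nvar), dx(nvar);
  arma::mat H(nvar, nvar);

  for (int outer = 0; outer < max_outer; ++outer) {
    // center at current tau
    centered = false;
    for (int it = 0; it < max_newton; ++it) {
      barrier_derivs(blocks, x, g, H);
      gtot = tau * c + g;
      // Jacobi-scaled Newton solve: the decision variables live on wildly
      // different scales (Lyapunov blocks vs gains vs slack), so solve
      // D H D y = -D g with D = diag(H)^{-1/2} and adaptively ridge
      arma::vec d = H.diag();
      d.transform([](double v) { return v > 1e-300 ? 1.0 / std::sqrt(v) : 1.0; });
      arma::mat Hs = H;
      Hs.each_col() %= d;
      Hs.each_row() %= d.t();
      arma::vec gs = gtot % d;
      double lambda2 = -1.0;
      double rg = ridge;
      for (int attempt = 0; attempt < 8; ++attempt) {
        arma::mat Hr = Hs;
        Hr.diag() += rg;
        arma::vec y;
        bool ok = arma::solve(y, Hr, -gs, arma::solve_opts::likely_sympd);
        if (ok) {
          dx = y % d;
          lambda2 = arma::dot(gtot, -dx);
          if (lambda2 > 0) break;
        }
        rg = (rg > 0 ? rg * 100 : 1e-12);
      }
      if (!(lambda2 > 0)) break;
      // line search: keep strict feasibility, then sufficient decrease
      double f0 = tau * arma::dot(c, x) + barrier_value(blocks, x);
      double s = 1.0;
      int ls = 0;
      arma::vec xn;
      while (ls < 60) {
        xn = x + s * dx;
        double fn = tau * arma::dot(c, xn) + barrier_value(blocks, xn);
        if (std::isfinite(fn) && fn <= f0 - 0.25 * s * lambda2) break;
        s *= 0.5;
        ++ls;
      }
      if (ls >= 60) { break; }  // no progress possible at this centering
      x = xn;
      ++total_newton;
      if (early && arma::dot(c, x) <= early_stop_obj) {
        return List::create(_["x"] = x, _["status"] = "early_stop",
                            _["obj"] = arma::dot(c, x),
                            _["gap"] = Ntot / tau,
                            _["newton_iters"] = total_newton,
                            _["tau"] = tau);
      }
      if (lambda2 / 2.0 < 1e-9) { centered = true; break; }
    }
    if (status == "linalg_failure") break;
    if (Ntot / tau < tol_gap) {
      // only a converged final centering certifies (approximate) optimality
      status = centered ? "optimal" : "stalled";
      break;
    }
    tau *= mu;
  }
  return List::create(_["x"] = x, _["status"] = status,
                      _["obj"] = arma::dot(c, x),
                      _["gap"] = Ntot / tau,
                      _["newton_iters"] = total_newton,
                      _["tau"] = tau);
}

//' @noRd
// [[Rcpp::export(name = ".lmi_maxeig_cpp")]]
arma::vec lmi_maxeig_cpp(List blocks_in, arma::vec x) {
  std::vector<Block> blocks = unpack_blocks(blocks_in);
  arma::vec out(blocks.size());
  for (size_t k = 0; k < blocks.size(); ++k) {
    arma::mat F = block_value(blocks[k], x);
    arma::vec ev;
    arma::eig_sym(ev, arma::symmatu(0.5 * (F + F.t())));
    out(k) = ev.max();
  }
  return out;
}
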