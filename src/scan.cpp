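// Exhaustive grid scan over growth/transition rates.
//
// The objective for one candidate parameter vector needs the fractions of
// the linear system dN/dt = T N at a handful of timepoints for a handful of
// sorted-start conditions; grids run into millions of points, so the loop
// lives here.  Evaluation order is lexicographic in the free-parameter
// tuple and ties keep the first (lexicographically smallest) point, which
// makes the result independent of chunking and worker count.

// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_WARN_LEVEL 1  // ill-conditioned eigenbases fall back silently
#include <RcppArmadillo.h>

using namespace Rcpp;

// exp(T t) * x0 by eigendecomposition with expmat fallback
static arma::vec propagate(const arma::mat& T, const arma::vec& x0, double t,
                           const arma::cx_mat& V, const arma::cx_vec& lam,
                           bool eig_ok) {
  if (eig_ok) {
    arma::cx_vec a;
    if (arma::solve(a, V, arma::cx_vec(x0, arma::zeros(x0.n_elem)))) {
      arma::cx_vec y = V * (a % arma::exp(lam * t));
      return arma::real(y);
    }
  }
  return arma::expmat(T * t) * x0;
}

// [[Rcpp::export(name = ".scan_core")]]
List scan_core(const arma::vec& base_g,
               const arma::mat& base_k,
               const IntegerVector& free_type,   // 0 = growth, 1 = transition
               const IntegerVector& free_i,      // 0-based phenotype indices
               const IntegerVector& free_j,
               const List& grids,                // one value vector per free param
               const arma::mat& x0,              // m x ncond initial compositions
               const List& obs_times,            // per condition: positive times
               const List& obs_frac,             // per condition: m x ntimes observed
               int feas_sign,                    // +1 all-positive, -1 all-negative, 0 off
               bool feas_surv,
               int objective_kind,               // 0 = squared error, 1 = absolute
               int shortlist_n) {
  const int m = base_g.n_elem;
  const int npar = free_type.size();
  const int ncond = x0.n_cols;

  std::vector<arma::vec> gridv(npar);
  std::vector<int> radix(npar);
  long long total = 1;
  for (int p = 0; p < npar; ++p) {
    gridv[p] = as<arma::vec>(grids[p]);
    radix[p] = gridv[p].n_elem;
    total *= radix[p];
  }
  std::vector<arma::vec> tvec(ncond);
  std::vector<arma::mat> ovec(ncond);
  for (int c = 0; c < ncond; ++c) {
    tvec[c] = as<arma::vec>(obs_times[c]);
    ovec[c] = as<arma::mat>(obs_frac[c]);
  }

  std::vector<int> idx(npar, 0);
  arma::vec g = base_g;
  arma::mat k = base_k;

  double best_val = R_PosInf;
  std::vector<int> best_idx(npar, -1);
  // shortlist kept sorted by (value, insertion order)
  std::vector<double> sl_val;
  std::vector<std::vector<int>> sl_idx;
  long long n_feasible = 0, n_sign_fail = 0, n_surv_fail = 0;

  arma::mat T(m, m);
  for (long long it = 0; it < total; ++it) {
    // apply free parameters
    for (int p = 0; p < npar; ++p) {
      double v = gridv[p][idx[p]];
      if (free_type[p] == 0) g[free_i[p]] = v;
      else k(free_i[p], free_j[p]) = v;
    }
    // T = G + K, column i carries outflow of phenotype i
    T.zeros();
    for (int i = 0; i < m; ++i) {
      double out = 0.0;
      for (int j = 0; j < m; ++j) {
        if (j != i) { T(j, i) = k(i, j); out += k(i, j); }
      }
      T(i, i) = g[i] - out;
    }

    bool feasible = true;
    if (feas_surv) {
      for (int i = 0; i < m && feasible; ++i) {
        double out = 0.0;
        for (int j = 0; j < m; ++j) if (j != i) out += k(i, j);
        if (g[i] <= out) feasible = false;
      }
      if (!feasible) ++n_surv_fail;
    }

    arma::cx_vec lam;
    arma::cx_mat V;
    bool eig_ok = arma::eig_gen(lam, V, T);
    if (feasible && feas_sign != 0) {
      if (!eig_ok) {
        feasible = false;
        ++n_sign_fail;
      } else {
        for (arma::uword e = 0; e < lam.n_elem; ++e) {
          double re = lam[e].real();
          if ((feas_sign > 0 && re <= 0.0) || (feas_sign < 0 && re >= 0.0)) {
            feasible = false;
            break;
          }
        }
        if (!feasible) ++n_sign_fail;
      }
    }

    if (feasible) {
      ++n_feasible;
      double acc = 0.0;
      for (int c = 0; c < ncond; ++c) {
        for (arma::uword ti = 0; ti < tvec[c].n_elem; ++ti) {
          arma::vec y = propagate(T, x0.col(c), tvec[c][ti], V, lam, eig_ok);
          double s = arma::accu(y);
          if (!(s > 0.0) || !y.is_finite()) { acc = R_PosInf; break; }
          y /= s;
          for (int i = 0; i < m; ++i) {
            double d = y[i] - ovec[c](i, ti);
            acc += (objective_kind == 0) ? d * d : std::fabs(d);
          }
        }
        if (!std::isfinite(acc)) break;
      }

      if (std::isfinite(acc)) {
        if (acc < best_val) {  // strict: earlier (smaller tuple) wins ties
          best_val = acc;
          for (int p = 0; p < npar; ++p) best_idx[p] = idx[p];
        }
        if (shortlist_n > 0) {
          // insert keeping ascending order; stable for equal values
          size_t pos = sl_val.size();
          while (pos > 0 && sl_val[pos - 1] > acc) --pos;
          if ((int)sl_val.size() < shortlist_n || pos < (size_t)shortlist_n) {
            sl_val.insert(sl_val.begin() + pos, acc);
            sl_idx.insert(sl_idx.begin() + pos,
                          std::vector<int>(idx.begin(), idx.end()));
            if ((int)sl_val.size() > shortlist_n) {
              sl_val.pop_back();
              sl_idx.pop_back();
            }
          }
        }
      }
    }

    // increment mixed-radix counter, last parameter fastest
    for (int p = npar - 1; p >= 0; --p) {
      if (++idx[p] < radix[p]) break;
      idx[p] = 0;
    }
  }

  IntegerMatrix sl(sl_val.size(), npar);
  for (size_t r = 0; r < sl_val.size(); ++r)
    for (int p = 0; p < npar; ++p) sl(r, p) = sl_idx[r][p] + 1;

  IntegerVector best_idx1(npar);
  for (int p = 0; p < npar; ++p) best_idx1[p] = best_idx[p] + 1;  // 1-based for R

  return List::create(
    _["best_value"] = best_val,
    _["best_idx"] = best_idx1,
    _["shortlist_idx"] = sl,
    _["shortlist_value"] = NumericVector(sl_val.begin(), sl_val.end()),
    _["n_grid"] = (double)total,
    _["n_feasible"] = (double)n_feasible,
    _["n_sign_fail"] = (double)n_sign_fail,
    _["n_surv_fail"] = (double)n_surv_fail);
}
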