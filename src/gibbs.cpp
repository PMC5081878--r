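// Gibbs sampler core for the multi-trait fixed-regression test-day
// animal model. Single-level blocked updates: for each level of each
// term the 4-trait subvector is drawn from its multivariate-normal
// full conditional; (co)variance matrices from inverted-Wishart full
// conditionals. All randomness goes through R's RNG so chains are
// reproducible from set.seed() and resumable across segment calls.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat rwishart(double df, const arma::mat& S) {
  const arma::uword p = S.n_cols;
  arma::mat L = arma::chol(S, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (arma::uword i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - (double)i));
    for (arma::uword j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

// X ~ IW(df, Scale): draw W ~ Wishart(df, Scale^{-1}), return W^{-1}
static arma::mat riwishart(double df, const arma::mat& Scale) {
  arma::mat W = rwishart(df, arma::inv_sympd(arma::symmatu(Scale)));
  return arma::symmatu(arma::inv_sympd(W));
}

// draw u ~ N(P^{-1} b, P^{-1}) for a small precision matrix P
static arma::vec draw_mvn_precision(const arma::mat& P, const arma::vec& b) {
  arma::mat U = arma::chol(arma::symmatu(P));   // upper
  arma::vec mu = arma::solve(arma::symmatu(P), b, arma::solve_opts::likely_sympd);
  arma::vec z(b.n_elem);
  for (arma::uword t = 0; t < b.n_elem; ++t) z(t) = R::norm_rand();
  return mu + arma::solve(arma::trimatu(U), z);
}

struct Term {
  arma::uvec level;     // 0-based level per record
  arma::vec cov;        // covariate per record (1 for indicators)
  int nlev;
  int prior;            // 0 flat, 1 pedigree (G0, A-inverse), 2 iid (P0)
  // CSR by level
  arma::uvec ptr;       // nlev + 1
  arma::uvec rec;       // record indices sorted by level
  arma::vec sumc2;      // per-level sum of squared covariates
};

// [[Rcpp::export(name = ".gibbs_segment")]]
List gibbs_segment(const arma::mat& y,
                   const List& term_level,
                   const List& term_cov,
                   const IntegerVector& term_nlev,
                   const IntegerVector& term_prior,
                   const arma::sp_mat& Ainv,
                   List state,
                   const List& priors,
                   int cycle_start,      // cycles already completed
                   int n_cycles,         // cycles to run in this segment
                   int burn_in,
                   int thin,
                   bool update_cov,
                   int loc_mode,         // 0 none, 1 all terms, 2 fixed only
                   int trace_term,       // -1 = none (1-based otherwise)
                   int trace_level,      // 1-based
                   const IntegerVector& pe_animal) { // per PE level: 0-based
                                         // animal level, or -1 (single-site)
  const int n = y.n_rows;
  const int K = term_level.size();

  std::vector<Term> terms(K);
  for (int k = 0; k < K; ++k) {
    Term& tm = terms[k];
    tm.level = as<arma::uvec>(term_level[k]);        // 0-based
    tm.cov = as<arma::vec>(term_cov[k]);
    tm.nlev = term_nlev[k];
    tm.prior = term_prior[k];
    arma::uvec ord = arma::stable_sort_index(tm.level);
    tm.rec = ord;
    tm.ptr.zeros(tm.nlev + 1);
    tm.sumc2.zeros(tm.nlev);
    for (int r = 0; r < n; ++r) {
      tm.ptr(tm.level(r) + 1) += 1;
      tm.sumc2(tm.level(r)) += tm.cov(r) * tm.cov(r);
    }
    for (int l = 0; l < tm.nlev; ++l) tm.ptr(l + 1) += tm.ptr(l);
  }

  // effect matrices (nlev x 4), copied from state
  std::vector<arma::mat> U(K);
  List eff = state["effects"];
  for (int k = 0; k < K; ++k) U[k] = as<arma::mat>(eff[k]);
  arma::mat G0 = as<arma::mat>(state["G0"]);
  arma::mat P0 = as<arma::mat>(state["P0"]);
  arma::mat R0 = as<arma::mat>(state["R0"]);

  const double nu_G = as<double>(priors["nu_G"]);
  const double nu_P = as<double>(priors["nu_P"]);
  const double nu_R = as<double>(priors["nu_R"]);
  const arma::mat S_G = as<arma::mat>(priors["S_G"]);
  const arma::mat S_P = as<arma::mat>(priors["S_P"]);
  const arma::mat S_R = as<arma::mat>(priors["S_R"]);

  int anim_k = -1, pe_k = -1;
  for (int k = 0; k < K; ++k) {
    if (terms[k].prior == 1) anim_k = k;
    if (terms[k].prior == 2) pe_k = k;
  }
  const int n_animals = (anim_k >= 0) ? terms[anim_k].nlev : 0;
  const int n_pe = (pe_k >= 0) ? terms[pe_k].nlev : 0;
  if (update_cov) {
    if (anim_k >= 0 && n_animals + nu_G <= 3.0)
      stop("Wishart degrees of freedom <= dimension - 1 for G0");
    if (pe_k >= 0 && n_pe + nu_P <= 3.0)
      stop("Wishart degrees of freedom <= dimension - 1 for P0");
    if (n + nu_R <= 3.0)
      stop("Wishart degrees of freedom <= dimension - 1 for R0");
  }

  // residuals E = y - sum of fitted contributions
  arma::mat E = y;
  for (int k = 0; k < K; ++k) {
    const Term& tm = terms[k];
    for (int r = 0; r < n; ++r) E.row(r) -= tm.cov(r) * U[k].row(tm.level(r));
  }

  arma::mat G0inv = arma::inv_sympd(arma::symmatu(G0));
  arma::mat P0inv = arma::inv_sympd(arma::symmatu(P0));
  arma::mat R0inv = arma::inv_sympd(arma::symmatu(R0));

  const int n_store = [&]() {
    int c = 0;
    for (int cyc = cycle_start + 1; cyc <= cycle_start + n_cycles; ++cyc)
      if (cyc > burn_in && (cyc - burn_in) % thin == 0) ++c;
    return c;
  }();
  arma::mat samples(n_store, 31);
  arma::mat trace(trace_term > 0 ? n_store : 0, 4);
  int stored = 0;

  // animal levels paired with a PE level (recorded cows) are drawn as a
  // joint 8-dimensional (additive, permanent-environment) block: the two
  // effects are confounded within cow, and separate single-site draws
  // mix along that ridge arbitrarily slowly
  arma::ivec paired;
  const bool joint = (anim_k >= 0 && pe_k >= 0 && pe_animal.size() == n_pe);
  if (joint) {
    paired.set_size(n_animals);
    paired.fill(-1);
    for (int l = 0; l < n_pe; ++l) {
      if (pe_animal[l] >= 0) paired(pe_animal[l]) = l;
    }
  }

  for (int cyc = cycle_start + 1; cyc <= cycle_start + n_cycles; ++cyc) {
    for (int k = 0; loc_mode > 0 && k < K; ++k) {
      Term& tm = terms[k];
      arma::mat& Uk = U[k];
      if (loc_mode == 2 && tm.prior != 0) continue;  // random terms drawn outside
      if (joint && k == pe_k) continue;   // handled with its animal partner
      for (int l = 0; l < tm.nlev; ++l) {
        if (joint && k == anim_k && paired(l) >= 0) {
          // joint (additive, PE) draw for a recorded cow
          const int lp = paired(l);
          Term& tp = terms[pe_k];
          arma::mat& Up = U[pe_k];
          const arma::uword q0 = tp.ptr(lp), q1 = tp.ptr(lp + 1);
          arma::rowvec aold = Uk.row(l);
          arma::rowvec pold = Up.row(lp);
          arma::vec rhs(4, arma::fill::zeros);
          for (arma::uword p = q0; p < q1; ++p) {
            const arma::uword r = tp.rec(p);
            E.row(r) += aold + pold;
            rhs += E.row(r).t();
          }
          double adiag = 0.0;
          arma::vec s(4, arma::fill::zeros);
          for (arma::sp_mat::const_col_iterator it = Ainv.begin_col(l);
               it != Ainv.end_col(l); ++it) {
            const arma::uword j = it.row();
            if ((int)j == l) adiag = *it;
            else s += (*it) * Uk.row(j).t();
          }
          const double S = (double)(q1 - q0);
          arma::mat P8(8, 8);
          P8.submat(0, 0, 3, 3) = S * R0inv + adiag * G0inv;
          P8.submat(0, 4, 3, 7) = S * R0inv;
          P8.submat(4, 0, 7, 3) = S * R0inv;
          P8.submat(4, 4, 7, 7) = S * R0inv + P0inv;
          arma::vec b8(8);
          arma::vec bd = R0inv * rhs;
          b8.subvec(0, 3) = bd - G0inv * s;
          b8.subvec(4, 7) = bd;
          arma::vec u8 = draw_mvn_precision(P8, b8);
          Uk.row(l) = u8.subvec(0, 3).t();
          Up.row(lp) = u8.subvec(4, 7).t();
          for (arma::uword p = q0; p < q1; ++p) {
            const arma::uword r = tp.rec(p);
            E.row(r) -= Uk.row(l) + Up.row(lp);
          }
          continue;
        }
        const arma::uword p0 = tm.ptr(l), p1 = tm.ptr(l + 1);
        // flat prior with no data (or all-zero covariates): improper
        // conditional, leave the level untouched
        if (tm.prior == 0 && (p0 == p1 || tm.sumc2(l) <= 0.0)) continue;
        arma::rowvec uold = Uk.row(l);
        arma::vec rhs(4, arma::fill::zeros);
        for (arma::uword p = p0; p < p1; ++p) {
          const arma::uword r = tm.rec(p);
          const double c = tm.cov(r);
          E.row(r) += c * uold;                    // remove this level's fit
          rhs += c * E.row(r).t();
        }
        arma::mat P = tm.sumc2(l) * R0inv;
        arma::vec b = R0inv * rhs;
        if (tm.prior == 1) {
          // A-inverse x G0-inverse prior; column l of symmetric Ainv = row l
          double adiag = 0.0;
          arma::vec s(4, arma::fill::zeros);
          for (arma::sp_mat::const_col_iterator it = Ainv.begin_col(l);
               it != Ainv.end_col(l); ++it) {
            const arma::uword j = it.row();
            if ((int)j == l) adiag = *it;
            else s += (*it) * Uk.row(j).t();
          }
          P += adiag * G0inv;
          b -= G0inv * s;
        } else if (tm.prior == 2) {
          P += P0inv;
        }
        arma::vec unew = draw_mvn_precision(P, b);
        Uk.row(l) = unew.t();
        for (arma::uword p = p0; p < p1; ++p) {
          const arma::uword r = tm.rec(p);
          E.row(r) -= tm.cov(r) * Uk.row(l);
        }
      }
    }

    if (update_cov) {
      arma::mat Se = E.t() * E;
      R0 = riwishart((double)n + nu_R, Se + S_R);
      R0inv = arma::inv_sympd(arma::symmatu(R0));
      if (anim_k >= 0) {
        arma::mat Sa = U[anim_k].t() * (Ainv * U[anim_k]);
        G0 = riwishart((double)n_animals + nu_G, arma::symmatu(Sa) + S_G);
        G0inv = arma::inv_sympd(arma::symmatu(G0));
      }
      if (pe_k >= 0) {
        arma::mat Sp = U[pe_k].t() * U[pe_k];
        P0 = riwishart((double)n_pe + nu_P, Sp + S_P);
        P0inv = arma::inv_sympd(arma::symmatu(P0));
      }
    }

    if (cyc > burn_in && (cyc - burn_in) % thin == 0) {
      samples(stored, 0) = cyc;
      int c = 1;
      const arma::mat* mats[3] = { &G0, &P0, &R0 };
      for (int m = 0; m < 3; ++m)
        for (int i = 0; i < 4; ++i)
          for (int j = i; j < 4; ++j) samples(stored, c++) = (*mats[m])(i, j);
      if (trace_term > 0) trace.row(stored) = U[trace_term - 1].row(trace_level - 1);
      ++stored;
    }
    if (cyc % 200 == 0) Rcpp::checkUserInterrupt();
  }

  List eff_out(K);
  for (int k = 0; k < K; ++k) eff_out[k] = U[k];
  return List::create(
    _["samples"] = samples,
    _["trace"] = trace,
    _["state"] = List::create(_["effects"] = eff_out, _["G0"] = G0,
                              _["P0"] = P0, _["R0"] = R0),
    _["residuals"] = E,
    _["cycle_end"] = cycle_start + n_cycles);
}
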