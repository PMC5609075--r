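// Core of the Bayes R hybrid engine: a variational EM warm start and a
// Gibbs sampler for the four-component mixture model
//   y = Xb + Za + Wv + e,  v_i ~ sum_k P_k N(0, gamma_k * sigma_g2),
//   a ~ N(0, A * sigma_a2),  e ~ N(0, E * sigma_e2), E = diag(1/w_j),
// with scheduled dropping of low-PIP variants and Dirichlet prior
// compensation. All randomness goes through R's RNG so runs are
// bit-reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int NCLASS = 4;

// log f_k for classes 1..3 (0-based k), the marginal-likelihood weight of
// assigning the current variant to class k given rhs, ww; class 0 has f=1.
static inline void class_logf(double rhs, double ww, double se2,
                              const arma::vec& tau, const arma::vec& logP,
                              double* logf, double* mu, double* s) {
  logf[0] = logP[0];
  mu[0] = 0.0; s[0] = 0.0;
  for (int k = 1; k < NCLASS; ++k) {
    if (!std::isfinite(logP[k]) && logP[k] < 0) {  // P_k == 0
      logf[k] = -arma::datum::inf; mu[k] = 0; s[k] = 0; continue;
    }
    double lam = se2 / tau[k];
    double C = ww + lam;
    mu[k] = rhs / C;
    s[k] = se2 / C;
    logf[k] = logP[k] + 0.5 * (std::log(lam) - std::log(C)) +
              rhs * rhs / (2.0 * se2 * C);
  }
}

// polygenic single-site helpers ------------------------------------------

struct PedRecs {
  // CSR: records (0-based) belonging to each pedigree individual
  std::vector<int> ptr, idx;
  arma::vec sw;  // sum of weights over each individual's records
};

static PedRecs build_recs(const IntegerVector& rec_ptr,
                          const IntegerVector& rec_idx,
                          const arma::vec& w) {
  PedRecs pr;
  pr.ptr.assign(rec_ptr.begin(), rec_ptr.end());
  pr.idx.assign(rec_idx.begin(), rec_idx.end());
  int q = pr.ptr.size() - 1;
  pr.sw.set_size(q);
  for (int i = 0; i < q; ++i) {
    double s = 0;
    for (int t = pr.ptr[i]; t < pr.ptr[i + 1]; ++t) s += w[pr.idx[t]];
    pr.sw[i] = s;
  }
  return pr;
}

// Ainv column i dot a, minus the diagonal term (symmetric matrix)
static inline void ainv_col(const arma::sp_mat& Ainv, int i,
                            const arma::vec& a, double& diag, double& off) {
  diag = 0; off = 0;
  for (arma::sp_mat::const_col_iterator it = Ainv.begin_col(i);
       it != Ainv.end_col(i); ++it) {
    if ((int)it.row() == i) diag = *it;
    else off += (*it) * a[it.row()];
  }
}

// ------------------------------------------------------------------------
// Variational EM warm start.
//
// q(c_i, v_i) has a point mass at v = 0 for class 1 and normals for classes
// 2-4; parameters are (b, a, P, sigma_e2, sigma_a2). Every update is an
// exact coordinate maximization of the evidence lower bound, so the ELBO
// trace is non-decreasing up to round-off.
// [[Rcpp::export]]
List em_fit_cpp(const arma::mat& W, const arma::mat& Ww, const arma::vec& ww,
                const arma::mat& X, const arma::mat& XtEX,
                const arma::vec& y, const arma::vec& w,
                const IntegerVector& rec_ptr, const IntegerVector& rec_idx,
                const arma::sp_mat& Ainv, bool use_poly,
                const arma::vec& tau, const arma::vec& alpha,
                Nullable<NumericVector> fix_P,
                double fix_se2, double fix_sa2, double sa2_init,
                int max_iter, double tol) {
  const int n = y.n_elem, p = W.n_cols, f = X.n_cols;
  const int qped = use_poly ? Ainv.n_rows : 0;

  bool P_fixed = fix_P.isNotNull();
  arma::vec P(NCLASS);
  if (P_fixed) P = as<arma::vec>(fix_P.get());
  else P = alpha / arma::accu(alpha);

  bool se2_free = !std::isfinite(fix_se2);
  double se2 = se2_free ? arma::var(y) * 0.5 : fix_se2;
  if (se2 <= 0) se2 = 1e-8;
  // sigma_a2 is NOT an EM target (the warm start estimates a, P, b, v and
  // sigma_e2 only); it stays at its initial / fixed value throughout,
  // which also avoids the degenerate MAP mode at 0
  double sa2 = std::isfinite(fix_sa2) ? fix_sa2 : sa2_init;
  if (sa2 <= 0) sa2 = 1e-8;

  arma::vec b(f, arma::fill::zeros), a(qped, arma::fill::zeros);
  arma::vec m(p, arma::fill::zeros), Vv(p, arma::fill::zeros);
  arma::mat resp(p, NCLASS, arma::fill::zeros);
  resp.col(0).ones();
  arma::vec quadv(p, arma::fill::zeros), logdetv(p, arma::fill::zeros),
            entv(p, arma::fill::zeros);
  arma::vec r = y;  // residual mean: y - Xb - Za - W m

  PedRecs pr;
  if (use_poly) pr = build_recs(rec_ptr, rec_idx, w);

  arma::mat Lx;
  if (f > 0) Lx = arma::chol(XtEX, "lower");

  double logf[NCLASS], mu[NCLASS], s[NCLASS], qv[NCLASS];
  std::vector<double> elbo_tr;
  double elbo_prev = -arma::datum::inf;
  bool converged = false;
  int it = 0;
  const double sumlogw = arma::accu(arma::log(w));

  for (it = 1; it <= max_iter; ++it) {
    arma::vec logP = arma::log(P);

    // ---- variant sweep: exact update of each q(c_i, v_i)
    double* rp = r.memptr();
    for (int i = 0; i < p; ++i) {
      const double* wc = W.colptr(i);
      const double* gc = Ww.colptr(i);
      double mi = m[i];
      if (mi != 0.0) for (int j = 0; j < n; ++j) rp[j] += wc[j] * mi;
      double rhs = 0;
      for (int j = 0; j < n; ++j) rhs += gc[j] * rp[j];
      class_logf(rhs, ww[i], se2, tau, logP, logf, mu, s);
      double mx = logf[0];
      for (int k = 1; k < NCLASS; ++k) if (logf[k] > mx) mx = logf[k];
      double tot = 0;
      for (int k = 0; k < NCLASS; ++k) {
        qv[k] = std::isfinite(logf[k]) ? std::exp(logf[k] - mx) : 0.0;
        tot += qv[k];
      }
      double mnew = 0, ev2 = 0, quad = 0, logdet = 0, ent = 0;
      for (int k = 0; k < NCLASS; ++k) {
        qv[k] /= tot;
        resp(i, k) = qv[k];
        if (qv[k] > 0) ent -= qv[k] * std::log(qv[k]);
        if (k > 0 && qv[k] > 0) {
          mnew += qv[k] * mu[k];
          double m2 = mu[k] * mu[k] + s[k];
          ev2 += qv[k] * m2;
          quad += qv[k] * m2 / (2.0 * tau[k]);
          logdet += qv[k] * 0.5 * std::log(2.0 * M_PI * tau[k]);
          ent += qv[k] * 0.5 * std::log(2.0 * M_PI * M_E * s[k]);
        }
      }
      m[i] = mnew;
      Vv[i] = ev2 - mnew * mnew;
      quadv[i] = quad; logdetv[i] = logdet; entv[i] = ent;
      if (mnew != 0.0) for (int j = 0; j < n; ++j) rp[j] -= wc[j] * mnew;
    }

    // ---- fixed effects: exact GLS
    if (f > 0) {
      arma::vec radd = r + X * b;
      arma::vec rhsb = X.t() * (w % radd);
      arma::vec bnew = arma::solve(arma::trimatu(Lx.t()),
                                   arma::solve(arma::trimatl(Lx), rhsb));
      r = radd - X * bnew;
      b = bnew;
    }

    // ---- polygenic values: one exact coordinate sweep
    if (use_poly) {
      for (int i = 0; i < qped; ++i) {
        double ai = a[i];
        for (int t = pr.ptr[i]; t < pr.ptr[i + 1]; ++t)
          r[pr.idx[t]] += ai;
        double diag, off;
        ainv_col(Ainv, i, a, diag, off);
        double num = -off / sa2, prec = diag / sa2;
        for (int t = pr.ptr[i]; t < pr.ptr[i + 1]; ++t) {
          int j = pr.idx[t];
          num += w[j] * r[j] / se2;
        }
        prec += pr.sw[i] / se2;
        a[i] = num / prec;
        for (int t = pr.ptr[i]; t < pr.ptr[i + 1]; ++t)
          r[pr.idx[t]] -= a[i];
      }
    }

    // ---- mixing proportions (MAP under Dirichlet prior)
    arma::vec csq = arma::sum(resp, 0).t();
    if (!P_fixed) {
      arma::vec num = csq + alpha - 1.0;
      num.elem(arma::find(num < 0)).zeros();
      double tot = arma::accu(num);
      if (tot > 0) P = num / tot;
    }

    // ---- variances
    double ewrss = arma::dot(w, r % r) + arma::dot(Vv, ww);
    if (se2_free) se2 = std::max(ewrss / n, 1e-12);
    double aquad = 0;
    if (use_poly) aquad = arma::as_scalar(a.t() * (Ainv * a));

    // ---- evidence lower bound
    ewrss = arma::dot(w, r % r) + arma::dot(Vv, ww);
    double elbo = -0.5 * ewrss / se2 - 0.5 * n * std::log(2.0 * M_PI * se2) +
                  0.5 * sumlogw;
    arma::vec logP2 = arma::log(P);
    for (int k = 0; k < NCLASS; ++k)
      if (csq[k] > 0) elbo += csq[k] * logP2[k];
    elbo += -arma::accu(logdetv) - arma::accu(quadv) + arma::accu(entv);
    if (use_poly)
      elbo += -0.5 * aquad / sa2 - 0.5 * qped * std::log(2.0 * M_PI * sa2);
    if (!P_fixed)
      for (int k = 0; k < NCLASS; ++k)
        if (alpha[k] != 1.0 && logP2[k] > -arma::datum::inf)
          elbo += (alpha[k] - 1.0) * logP2[k];
    elbo_tr.push_back(elbo);

    if (it > 1 && std::abs(elbo - elbo_prev) <
                    tol * (1.0 + std::abs(elbo))) {
      converged = true;
      break;
    }
    elbo_prev = elbo;
  }

  return List::create(
      _["b"] = b, _["a"] = a, _["v"] = m, _["resp"] = resp, _["P"] = P,
      _["sigma_e2"] = se2, _["sigma_a2"] = sa2,
      _["elbo"] = elbo_tr, _["iterations"] = std::min(it, max_iter),
      _["converged"] = converged);
}

// ------------------------------------------------------------------------
// Gibbs sampler with optional in-chain drop event.
//
// total_iter iterations are run; when drop_prop > 0 and drop_iter >= 1 the
// drop happens after completing iteration drop_iter, based on the running
// inclusion frequencies from iteration 1..drop_iter, and posterior
// summaries are accumulated over the post-drop window only. With
// drop_prop == 0 no drop branch executes and no extra RNG is consumed, so
// the chain is bit-identical to an unscheduled run.
// [[Rcpp::export]]
List gibbs_cpp(const arma::mat& W, const arma::mat& Ww, const arma::vec& ww,
               const arma::mat& X, const arma::mat& XtEX,
               const arma::vec& y, const arma::vec& w,
               const IntegerVector& rec_ptr, const IntegerVector& rec_idx,
               const arma::sp_mat& Ainv, bool use_poly,
               const arma::vec& tau, const arma::vec& alpha0,
               Nullable<NumericVector> fix_P,
               double fix_se2, double fix_sa2,
               arma::vec b, arma::vec a, arma::vec v, arma::vec P,
               double se2, double sa2,
               LogicalVector active0,
               int total_iter, int drop_iter, double drop_prop,
               double min_sa2) {
  const int n = y.n_elem, p = W.n_cols, f = X.n_cols;
  const int qped = use_poly ? Ainv.n_rows : 0;

  bool P_fixed = fix_P.isNotNull();
  if (P_fixed) P = as<arma::vec>(fix_P.get());
  bool se2_free = !std::isfinite(fix_se2);
  bool sa2_free = !std::isfinite(fix_sa2);
  if (!se2_free) se2 = fix_se2;
  if (!sa2_free) sa2 = fix_sa2;

  arma::vec alpha = alpha0;
  std::vector<char> active(p);
  for (int i = 0; i < p; ++i) active[i] = active0[i] ? 1 : 0;

  PedRecs pr;
  if (use_poly) pr = build_recs(rec_ptr, rec_idx, w);
  arma::mat Lx;
  if (f > 0) Lx = arma::chol(XtEX, "lower");

  // residual from initial state
  arma::vec r = y - W * v;
  if (f > 0) r -= X * b;
  if (use_poly)
    for (int i = 0; i < qped; ++i)
      for (int t = pr.ptr[i]; t < pr.ptr[i + 1]; ++t) r[pr.idx[t]] -= a[i];

  // accumulators
  const int win_start = (drop_prop > 0 && drop_iter >= 1) ? drop_iter : 0;
  const int n_win = total_iter - win_start;
  arma::vec v_sum(p, arma::fill::zeros);
  arma::vec incl_win(p, arma::fill::zeros), incl_full(p, arma::fill::zeros);
  arma::mat class_cnt(p, NCLASS, arma::fill::zeros);
  arma::vec b_sum(f, arma::fill::zeros), a_sum(qped, arma::fill::zeros);
  arma::vec P_sum(NCLASS, arma::fill::zeros);
  double se2_sum = 0, sa2_sum = 0;
  arma::mat occ_trace(total_iter, NCLASS, arma::fill::zeros);
  arma::mat P_trace(total_iter, NCLASS, arma::fill::zeros);
  arma::vec se2_trace(total_iter), sa2_trace(total_iter,
                                             arma::fill::zeros);
  arma::vec pip_at_drop(p); pip_at_drop.fill(NA_REAL);
  std::vector<int> cls(p, 0);
  int dropped_n = 0;

  double logf[NCLASS], mu[NCLASS], s[NCLASS];
  double* rp = r.memptr();

  for (int t = 1; t <= total_iter; ++t) {
    arma::vec logP = arma::log(P);
    arma::vec cnt(NCLASS, arma::fill::zeros);

    // ---- variant effects, ascending genome order
    for (int i = 0; i < p; ++i) {
      if (!active[i]) continue;
      const double* wc = W.colptr(i);
      const double* gc = Ww.colptr(i);
      double vi = v[i];
      if (vi != 0.0) for (int j = 0; j < n; ++j) rp[j] += wc[j] * vi;
      double rhs = 0;
      for (int j = 0; j < n; ++j) rhs += gc[j] * rp[j];
      class_logf(rhs, ww[i], se2, tau, logP, logf, mu, s);
      double mx = logf[0];
      for (int k = 1; k < NCLASS; ++k) if (logf[k] > mx) mx = logf[k];
      double cum[NCLASS], tot = 0;
      for (int k = 0; k < NCLASS; ++k) {
        tot += std::isfinite(logf[k]) ? std::exp(logf[k] - mx) : 0.0;
        cum[k] = tot;
      }
      double u = R::unif_rand() * tot;
      int k = 0;
      while (k < NCLASS - 1 && u > cum[k]) ++k;
      cls[i] = k;
      cnt[k] += 1;
      if (k == 0) v[i] = 0.0;
      else {
        v[i] = mu[k] + std::sqrt(s[k]) * R::norm_rand();
        for (int j = 0; j < n; ++j) rp[j] -= wc[j] * v[i];
      }
    }

    // ---- mixing proportions
    if (!P_fixed) {
      double tot = 0;
      for (int k = 0; k < NCLASS; ++k) {
        P[k] = R::rgamma(alpha[k] + cnt[k], 1.0);
        tot += P[k];
      }
      P /= tot;
    }

    // ---- fixed effects
    if (f > 0) {
      arma::vec radd = r + X * b;
      arma::vec rhsb = X.t() * (w % radd);
      arma::vec mub = arma::solve(arma::trimatu(Lx.t()),
                                  arma::solve(arma::trimatl(Lx), rhsb));
      arma::vec z(f);
      for (int k = 0; k < f; ++k) z[k] = R::norm_rand();
      b = mub + std::sqrt(se2) * arma::solve(arma::trimatu(Lx.t()), z);
      r = radd - X * b;
      rp = r.memptr();
    }

    // ---- polygenic values, single-site
    if (use_poly) {
      for (int i = 0; i < qped; ++i) {
        double ai = a[i];
        for (int tt = pr.ptr[i]; tt < pr.ptr[i + 1]; ++tt)
          r[pr.idx[tt]] += ai;
        double diag, off;
        ainv_col(Ainv, i, a, diag, off);
        double num = -off / sa2, prec = diag / sa2;
        for (int tt = pr.ptr[i]; tt < pr.ptr[i + 1]; ++tt) {
          int j = pr.idx[tt];
          num += w[j] * r[j] / se2;
        }
        prec += pr.sw[i] / se2;
        double mn = num / prec;
        a[i] = mn + R::norm_rand() / std::sqrt(prec);
        for (int tt = pr.ptr[i]; tt < pr.ptr[i + 1]; ++tt)
          r[pr.idx[tt]] -= a[i];
      }
    }

    // ---- variances
    if (se2_free) {
      double ss = arma::dot(w, r % r);
      se2 = ss / R::rchisq(std::max(n - 2, 1));
    }
    if (use_poly && sa2_free) {
      double aq = arma::as_scalar(a.t() * (Ainv * a));
      sa2 = std::max(aq / R::rchisq(std::max(qped - 2, 1)), min_sa2);
    }

    // ---- traces and window accumulation; variants outside the model
    // (inactive/dropped) sit in the zero class by construction, so the
    // occupancy trace always counts the full panel (Table-style counts)
    int n_inact = 0;
    for (int i = 0; i < p; ++i) if (!active[i]) ++n_inact;
    cnt[0] += n_inact;
    occ_trace.row(t - 1) = cnt.t();
    P_trace.row(t - 1) = P.t();
    se2_trace[t - 1] = se2;
    if (use_poly) sa2_trace[t - 1] = sa2;
    for (int i = 0; i < p; ++i)
      if (active[i] && cls[i] > 0) incl_full[i] += 1;
    if (t > win_start) {
      for (int i = 0; i < p; ++i) {
        if (!active[i]) continue;
        v_sum[i] += v[i];
        class_cnt(i, cls[i]) += 1;
        if (cls[i] > 0) incl_win[i] += 1;
      }
      b_sum += b; if (use_poly) a_sum += a;
      P_sum += P; se2_sum += se2; sa2_sum += sa2;
    }

    // ---- scheduled drop
    if (drop_prop > 0 && t == drop_iter) {
      std::vector<int> act_idx;
      for (int i = 0; i < p; ++i) if (active[i]) act_idx.push_back(i);
      int n_act = act_idx.size();
      int n_drop = (int)std::lround(drop_prop * n_act);
      if (n_drop > 0) {
        arma::vec pipv(n_act);
        for (int k = 0; k < n_act; ++k)
          pipv[k] = incl_full[act_idx[k]] / (double)t;
        arma::uvec ord = arma::stable_sort_index(pipv, "ascend");
        for (int k = 0; k < n_drop; ++k) {
          int i = act_idx[ord[k]];
          active[i] = 0;
          pip_at_drop[i] = pipv[ord[k]];
          if (v[i] != 0.0) {
            const double* wc = W.colptr(i);
            for (int j = 0; j < n; ++j) rp[j] += wc[j] * v[i];
            v[i] = 0.0;
          }
        }
        alpha += (double)n_drop * P;  // pseudo-count compensation
        dropped_n += n_drop;
      }
    }
  }

  const double dn = n_win > 0 ? (double)n_win : 1.0;
  LogicalVector act_out(p);
  for (int i = 0; i < p; ++i) act_out[i] = active[i] != 0;

  return List::create(
      _["v_mean"] = v_sum / dn, _["pip"] = incl_win / dn,
      _["pip_full"] = incl_full / (double)total_iter,
      _["class_prob"] = class_cnt / dn,
      _["active"] = act_out, _["pip_at_drop"] = pip_at_drop,
      _["n_dropped"] = dropped_n,
      _["b_mean"] = b_sum / dn, _["a_mean"] = a_sum / dn,
      _["P_mean"] = P_sum / dn,
      _["sigma_e2_mean"] = se2_sum / dn, _["sigma_a2_mean"] = sa2_sum / dn,
      _["alpha_final"] = alpha,
      _["occ_trace"] = occ_trace, _["P_trace"] = P_trace,
      _["se2_trace"] = se2_trace, _["sa2_trace"] = sa2_trace,
      _["n_window"] = n_win, _["total_iter"] = total_iter,
      _["state"] = List::create(_["b"] = b, _["a"] = a, _["v"] = v,
                                _["P"] = P, _["sigma_e2"] = se2,
                                _["sigma_a2"] = sa2));
}
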