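// Penalized multigroup Bayesian Weighted Quantile Sum regression:
// log posterior, analytic gradient, and a No-U-Turn sampler
// (slice variant, dual-averaging step size, diagonal mass adaptation).
//
// Mean structure: mu_i = alpha + sum_g beta_g sum_{j in g} w_gj q_igj
//                        + z_i' gamma (+ sigma_u * u_raw[subj_i])
// Priors: w_g ~ Dirichlet(a0) via stick-breaking; beta_g elastic-net
//   p(beta|tau) ~ exp(-lambda|beta|/tau - (1-lambda) beta^2/(2 tau^2))
//   (normalizing constant is proportional to tau: a scale family);
//   tau ~ half-Cauchy(0,1); alpha, gamma ~ N(0, 10^2);
//   sigma ~ half-N(0,5); sigma_u ~ half-N(0,1); u_raw ~ N(0,1)
//   (non-centered random intercept).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Deterministic RNG independent of the C++ standard library's
// distribution implementations: xoshiro-free, plain mt19937_64 bits
// with explicit uniform/Box-Muller transforms.
struct Rng {
  std::mt19937_64 eng;
  explicit Rng(uint64_t seed) : eng(seed) {}
  double unif() {
    // 53-bit mantissa uniform in (0, 1)
    return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double normal() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

struct Model {
  vec y; mat Q; mat Z; ivec gsize; ivec subj;
  int n, J, G, K, S, V;
  bool enet, fixw, ranef;
  double lambda, a0;
  vec wfix;
  double sd_alpha, sd_gamma, sigma_scale, sigma_u_scale;
  // parameter offsets in the unconstrained vector
  int o_beta, o_gamma, o_v, o_ltau, o_lsig, o_lsigu, o_u, dim;

  void index() {
    V = 0;
    for (int g = 0; g < G; ++g) V += gsize[g] - 1;
    if (fixw) V = 0;
    o_beta = 1;
    o_gamma = o_beta + G;
    o_v = o_gamma + K;
    o_ltau = o_v + V;
    o_lsig = o_ltau + (enet ? 1 : 0);
    o_lsigu = o_lsig + 1;
    o_u = o_lsigu + (ranef ? 1 : 0);
    dim = o_u + (ranef ? S : 0);
  }

  // stick-breaking: v (length Jg-1) -> w (length Jg); returns log
  // Jacobian; z and rem buffers are filled for the reverse pass
  static double sticks(const double* v, int Jg, double* w,
                       double* z, double* rem) {
    double lj = 0.0, r = 1.0;
    for (int k = 0; k < Jg - 1; ++k) {
      double lk = v[k] - std::log((double)(Jg - 1 - k));
      double zk = 1.0 / (1.0 + std::exp(-lk));
      rem[k] = r;              // stick remaining before break k
      z[k] = zk;
      w[k] = r * zk;
      lj += std::log(zk) + std::log1p(-zk) + std::log(r);
      r *= (1.0 - zk);
    }
    w[Jg - 1] = r;
    return lj;
  }

  // log posterior density (unconstrained scale, Jacobians included)
  // and its gradient
  double lp_grad(const vec& th, vec& grad) const {
    grad.zeros(dim);
    double lp = 0.0;
    const double alpha = th[0];
    vec beta = th.subvec(o_beta, o_beta + G - 1);
    vec gamma = K ? th.subvec(o_gamma, o_gamma + K - 1) : vec();
    double tau = enet ? std::exp(th[o_ltau]) : 1.0;
    double sigma = std::exp(th[o_lsig]);
    double sig2 = sigma * sigma;

    // weights
    vec w(J), zbuf(J), rembuf(J);
    if (fixw) {
      w = wfix;
    } else {
      int vp = o_v, jp = 0;
      for (int g = 0; g < G; ++g) {
        int Jg = gsize[g];
        if (Jg == 1) { w[jp] = 1.0; }
        else {
          lp += sticks(th.memptr() + vp, Jg, w.memptr() + jp,
                       zbuf.memptr() + jp, rembuf.memptr() + jp);
          vp += Jg - 1;
        }
        jp += Jg;
      }
      if (a0 != 1.0)
        for (int j = 0; j < J; ++j) lp += (a0 - 1.0) * std::log(w[j]);
    }

    // linear predictor
    ivec grp(J);
    { int jp = 0;
      for (int g = 0; g < G; ++g)
        for (int k = 0; k < gsize[g]; ++k) grp[jp++] = g; }
    vec wb(J);
    for (int j = 0; j < J; ++j) wb[j] = beta[grp[j]] * w[j];
    vec mu = alpha + Q * wb;
    if (K) mu += Z * gamma;
    double sigma_u = 0.0;
    if (ranef) {
      sigma_u = std::exp(th[o_lsigu]);
      for (int i = 0; i < n; ++i) mu[i] += sigma_u * th[o_u + subj[i]];
    }

    // Gaussian likelihood
    vec r = y - mu;
    double ssr = dot(r, r);
    lp += -n * th[o_lsig] - 0.5 * ssr / sig2;
    vec rs = r / sig2;

    // likelihood gradients
    grad[0] += accu(rs);
    vec t = Q.t() * rs;                   // d lp / d wb
    vec gw(J, fill::zeros);
    for (int j = 0; j < J; ++j) {
      grad[o_beta + grp[j]] += w[j] * t[j];
      gw[j] = beta[grp[j]] * t[j];
    }
    if (K) {
      vec gz = Z.t() * rs;
      for (int k = 0; k < K; ++k) grad[o_gamma + k] += gz[k];
    }
    grad[o_lsig] += -n + ssr / sig2;
    if (ranef) {
      double gsu = 0.0;
      for (int i = 0; i < n; ++i) {
        grad[o_u + subj[i]] += sigma_u * rs[i];
        gsu += rs[i] * th[o_u + subj[i]];
      }
      grad[o_lsigu] += sigma_u * gsu;
    }

    // weight gradients: Dirichlet + reverse stick-breaking
    if (!fixw) {
      if (a0 != 1.0)
        for (int j = 0; j < J; ++j) gw[j] += (a0 - 1.0) / w[j];
      int vp = o_v, jp = 0;
      for (int g = 0; g < G; ++g) {
        int Jg = gsize[g];
        if (Jg > 1) {
          // adjoint of w wrt z, then z wrt v
          double gr = gw[jp + Jg - 1];    // d/d rem_{Jg-1}
          for (int k = Jg - 2; k >= 0; --k) {
            double zk = zbuf[jp + k], rk = rembuf[jp + k];
            double gzk = (gw[jp + k] - gr) * rk;
            gr = gw[jp + k] * zk + gr * (1.0 - zk);
            // Jacobian term d logJac / d z_k = 1/z - (Jg-1-k)/(1-z)
            gzk += 1.0 / zk - (double)(Jg - 1 - k) / (1.0 - zk);
            grad[vp + k] += gzk * zk * (1.0 - zk);
          }
          vp += Jg - 1;
        }
        jp += Jg;
      }
    }

    // priors
    lp += -0.5 * alpha * alpha / (sd_alpha * sd_alpha);
    grad[0] += -alpha / (sd_alpha * sd_alpha);
    for (int k = 0; k < K; ++k) {
      lp += -0.5 * gamma[k] * gamma[k] / (sd_gamma * sd_gamma);
      grad[o_gamma + k] += -gamma[k] / (sd_gamma * sd_gamma);
    }
    if (enet) {
      double tau2 = tau * tau, gt = 0.0;
      for (int g = 0; g < G; ++g) {
        double b = beta[g], ab = std::fabs(b);
        lp += -lambda * ab / tau - (1.0 - lambda) * b * b / (2.0 * tau2);
        double sg = (b > 0) - (b < 0);
        grad[o_beta + g] += -lambda * sg / tau - (1.0 - lambda) * b / tau2;
        gt += lambda * ab / tau + (1.0 - lambda) * b * b / tau2;
      }
      lp += -G * th[o_ltau];              // scale-family normalizer
      gt -= G;
      // half-Cauchy(0,1) on tau, with log-Jacobian
      lp += -std::log1p(tau2) + th[o_ltau];
      gt += -2.0 * tau2 / (1.0 + tau2) + 1.0;
      grad[o_ltau] += gt;
    }
    // sigma ~ half-N(0, sigma_scale)
    lp += -0.5 * sig2 / (sigma_scale * sigma_scale) + th[o_lsig];
    grad[o_lsig] += -sig2 / (sigma_scale * sigma_scale) + 1.0;
    if (ranef) {
      double su2 = sigma_u * sigma_u;
      lp += -0.5 * su2 / (sigma_u_scale * sigma_u_scale) + th[o_lsigu];
      grad[o_lsigu] += -su2 / (sigma_u_scale * sigma_u_scale) + 1.0;
      for (int s = 0; s < S; ++s) {
        lp += -0.5 * th[o_u + s] * th[o_u + s];
        grad[o_u + s] += -th[o_u + s];
      }
    }
    return lp;
  }

  // constrained parameter vector for reporting:
  // alpha, beta[G], gamma[K], w[J], tau?, sigma, sigma_u?
  int n_out() const { return 1 + G + K + J + (enet ? 1 : 0) + 1 +
                             (ranef ? 1 : 0) + 1; }
  void constrain(const vec& th, double lp, double* out) const {
    int p = 0;
    out[p++] = th[0];
    for (int g = 0; g < G; ++g) out[p++] = th[o_beta + g];
    for (int k = 0; k < K; ++k) out[p++] = th[o_gamma + k];
    vec w(J), zb(J), rb(J);
    if (fixw) w = wfix;
    else {
      int vp = o_v, jp = 0;
      for (int g = 0; g < G; ++g) {
        int Jg = gsize[g];
        if (Jg == 1) w[jp] = 1.0;
        else { sticks(th.memptr() + vp, Jg, w.memptr() + jp,
                      zb.memptr() + jp, rb.memptr() + jp);
               vp += Jg - 1; }
        jp += Jg;
      }
    }
    for (int j = 0; j < J; ++j) out[p++] = w[j];
    if (enet) out[p++] = std::exp(th[o_ltau]);
    out[p++] = std::exp(th[o_lsig]);
    if (ranef) out[p++] = std::exp(th[o_lsigu]);
    out[p++] = lp;
  }
};

struct Hamiltonian {
  const Model& m;
  vec minv;  // diagonal inverse mass = posterior variance estimate
  explicit Hamiltonian(const Model& mod) : m(mod) {
    minv.ones(mod.dim);
  }
  double H(const vec& th, const vec& p, double& lp, vec& grad) const {
    lp = m.lp_grad(th, grad);
    return -lp + 0.5 * dot(square(p), minv);
  }
  void leapfrog(vec& th, vec& p, vec& grad, double eps, double& lp) const {
    p += 0.5 * eps * grad;
    th += eps * (minv % p);
    lp = m.lp_grad(th, grad);
    p += 0.5 * eps * grad;
  }
  void sample_p(vec& p, Rng& rng) const {
    for (uword i = 0; i < p.n_elem; ++i)
      p[i] = rng.normal() / std::sqrt(minv[i]);
  }
};

struct NutsState {
  vec th_m, p_m, g_m, th_p, p_p, g_p, th_pr;
  double lp_pr;
  int n_pr;
  bool s_pr, div;
  double asum; int acnt;
};

static bool no_uturn(const Hamiltonian& ham, const vec& th_m, const vec& p_m,
                     const vec& th_p, const vec& p_p) {
  vec d = th_p - th_m;
  return dot(d, ham.minv % p_m) >= 0 && dot(d, ham.minv % p_p) >= 0;
}

// Recursive doubling (slice-sampling NUTS)
static void build_tree(const Hamiltonian& ham, vec th, vec p, vec grad,
                       double logu, int dir, int depth, double eps,
                       double H0, Rng& rng, NutsState& st) {
  if (depth == 0) {
    double lp;
    ham.leapfrog(th, p, grad, dir * eps, lp);
    double Hn = std::isfinite(lp)
      ? -lp + 0.5 * dot(square(p), ham.minv) : INFINITY;
    st.th_m = th; st.p_m = p; st.g_m = grad;
    st.th_p = th; st.p_p = p; st.g_p = grad;
    st.th_pr = th; st.lp_pr = lp;
    st.n_pr = (logu <= -Hn) ? 1 : 0;
    st.div = (logu - 1000.0 > -Hn) || !std::isfinite(Hn);
    st.s_pr = !st.div;
    double a = std::exp(std::min(0.0, H0 - Hn));
    st.asum = std::isfinite(a) ? a : 0.0;
    st.acnt = 1;
    return;
  }
  build_tree(ham, th, p, grad, logu, dir, depth - 1, eps, H0, rng, st);
  if (!st.s_pr) return;
  NutsState st2;
  if (dir == -1)
    build_tree(ham, st.th_m, st.p_m, st.g_m, logu, dir, depth - 1, eps,
               H0, rng, st2);
  else
    build_tree(ham, st.th_p, st.p_p, st.g_p, logu, dir, depth - 1, eps,
               H0, rng, st2);
  if (dir == -1) { st.th_m = st2.th_m; st.p_m = st2.p_m; st.g_m = st2.g_m; }
  else { st.th_p = st2.th_p; st.p_p = st2.p_p; st.g_p = st2.g_p; }
  int ntot = st.n_pr + st2.n_pr;
  if (st2.n_pr > 0 && rng.unif() < (double)st2.n_pr / std::max(ntot, 1)) {
    st.th_pr = st2.th_pr; st.lp_pr = st2.lp_pr;
  }
  st.n_pr = ntot;
  st.div = st.div || st2.div;
  st.s_pr = st2.s_pr && !st.div &&
    no_uturn(ham, st.th_m, st.p_m, st.th_p, st.p_p);
  st.asum += st2.asum;
  st.acnt += st2.acnt;
}

static double find_epsilon(const Hamiltonian& ham, const vec& th0, Rng& rng) {
  double eps = 0.1;
  vec p(th0.n_elem);
  ham.sample_p(p, rng);
  vec th = th0, grad(th0.n_elem);
  double lp0 = ham.m.lp_grad(th, grad);
  double H0 = -lp0 + 0.5 * dot(square(p), ham.minv);
  vec thn = th, pn = p, gn = grad;
  double lpn;
  ham.leapfrog(thn, pn, gn, eps, lpn);
  double Hn = std::isfinite(lpn)
    ? -lpn + 0.5 * dot(square(pn), ham.minv) : INFINITY;
  double dH = H0 - Hn;
  int dir = (dH > std::log(0.5)) ? 1 : -1;
  for (int it = 0; it < 50; ++it) {
    eps = (dir == 1) ? 2.0 * eps : 0.5 * eps;
    thn = th; pn = p; gn = grad;
    ham.leapfrog(thn, pn, gn, eps, lpn);
    Hn = std::isfinite(lpn)
      ? -lpn + 0.5 * dot(square(pn), ham.minv) : INFINITY;
    dH = H0 - Hn;
    if ((dir == 1 && dH <= std::log(0.5)) ||
        (dir == -1 && dH >= std::log(0.5))) break;
  }
  return eps;
}

static Model make_model(const vec& y, const mat& Q, const mat& Z,
                        const ivec& gsize, const ivec& subj, int S,
                        int prior_type, double lambda, double a0,
                        bool fix_w, const vec& w_fixed,
                        const Rcpp::List& hyper) {
  Model m;
  m.y = y; m.Q = Q; m.Z = Z; m.gsize = gsize; m.subj = subj;
  m.n = y.n_elem; m.J = Q.n_cols; m.G = gsize.n_elem; m.K = Z.n_cols;
  m.S = S; m.ranef = S > 0;
  m.enet = prior_type == 0;
  m.fixw = fix_w; m.wfix = w_fixed;
  m.lambda = lambda; m.a0 = a0;
  m.sd_alpha = Rcpp::as<double>(hyper["sd_alpha"]);
  m.sd_gamma = Rcpp::as<double>(hyper["sd_gamma"]);
  m.sigma_scale = Rcpp::as<double>(hyper["sigma_scale"]);
  m.sigma_u_scale = Rcpp::as<double>(hyper["sigma_u_scale"]);
  m.index();
  return m;
}

// [[Rcpp::export(name = ".lbwqsrLpGrad")]]
Rcpp::List lbwqsr_lp_grad(arma::vec theta, arma::vec y, arma::mat Q,
                          arma::mat Z, arma::ivec gsize, arma::ivec subj,
                          int S, int prior_type, double lambda, double a0,
                          bool fix_w, arma::vec w_fixed, Rcpp::List hyper) {
  Model m = make_model(y, Q, Z, gsize, subj, S, prior_type, lambda, a0,
                       fix_w, w_fixed, hyper);
  if ((int)theta.n_elem != m.dim)
    Rcpp::stop("theta has length %d, expected %d", theta.n_elem, m.dim);
  vec grad;
  double lp = m.lp_grad(theta, grad);
  return Rcpp::List::create(Rcpp::Named("lp") = lp,
                            Rcpp::Named("grad") = grad,
                            Rcpp::Named("dim") = m.dim);
}

// [[Rcpp::export(name = ".lbwqsrNuts")]]
Rcpp::List lbwqsr_nuts(arma::vec y, arma::mat Q, arma::mat Z,
                       arma::ivec gsize, arma::ivec subj, int S,
                       int prior_type, double lambda, double a0,
                       bool fix_w, arma::vec w_fixed, Rcpp::List hyper,
                       arma::vec init, int n_warmup, int n_iter,
                       double target_accept, int max_treedepth,
                       double seed) {
  Model m = make_model(y, Q, Z, gsize, subj, S, prior_type, lambda, a0,
                       fix_w, w_fixed, hyper);
  if ((int)init.n_elem != m.dim)
    Rcpp::stop("init has length %d, expected %d", init.n_elem, m.dim);
  Hamiltonian ham(m);
  Rng rng((uint64_t)seed);

  vec th = init;
  double eps = find_epsilon(ham, th, rng);

  // dual averaging state
  const double da_gamma = 0.05, da_t0 = 10.0, da_kappa = 0.75;
  double mu = std::log(10.0 * eps), log_eps_bar = 0.0, Hbar = 0.0;
  int da_count = 0;
  auto da_restart = [&]() {
    mu = std::log(10.0 * eps); log_eps_bar = std::log(eps);
    Hbar = 0.0; da_count = 0;
  };
  da_restart();

  // mass-adaptation windows (Stan-like: init buffer, doubling windows,
  // terminal buffer); degenerate schedules collapse gracefully
  int winit = 75, wterm = 50;
  if (n_warmup < 200) { winit = n_warmup / 4; wterm = n_warmup / 5; }
  std::vector<int> win_ends;
  {
    int start = winit, wsize = 25;
    while (start < n_warmup - wterm) {
      int end = std::min(start + wsize, n_warmup - wterm);
      if (n_warmup - wterm - end < wsize) end = n_warmup - wterm;
      win_ends.push_back(end);
      start = end;
      wsize *= 2;
    }
  }
  size_t win_idx = 0;
  running_stat_vec<vec> acc;

  int n_div = 0, n_maxdepth = 0;
  double accept_sum = 0.0; int accept_n = 0;
  mat draws(n_iter, m.n_out());
  vec grad(m.dim);
  std::vector<double> outbuf(m.n_out());

  for (int it = 0; it < n_warmup + n_iter; ++it) {
    bool warm = it < n_warmup;
    vec p(m.dim);
    ham.sample_p(p, rng);
    double lp0;
    double H0 = ham.H(th, p, lp0, grad);
    double logu = std::log(rng.unif()) - H0;

    NutsState st;
    st.th_m = th; st.p_m = p; st.g_m = grad;
    st.th_p = th; st.p_p = p; st.g_p = grad;
    st.th_pr = th; st.lp_pr = lp0;
    int ntot = 1; bool s = true; int depth = 0;
    double asum = 0.0; int acnt = 0;
    vec th_new = th; double lp_new = lp0;
    bool diverged = false;
    while (s && depth < max_treedepth) {
      int dir = (rng.unif() < 0.5) ? -1 : 1;
      NutsState sub;
      if (dir == -1)
        build_tree(ham, st.th_m, st.p_m, st.g_m, logu, dir, depth, eps,
                   H0, rng, sub);
      else
        build_tree(ham, st.th_p, st.p_p, st.g_p, logu, dir, depth, eps,
                   H0, rng, sub);
      if (dir == -1) { st.th_m = sub.th_m; st.p_m = sub.p_m; st.g_m = sub.g_m; }
      else { st.th_p = sub.th_p; st.p_p = sub.p_p; st.g_p = sub.g_p; }
      if (sub.s_pr && sub.n_pr > 0 &&
          rng.unif() < (double)sub.n_pr / std::max(ntot, 1)) {
        th_new = sub.th_pr; lp_new = sub.lp_pr;
      }
      ntot += sub.n_pr;
      diverged = diverged || sub.div;
      asum += sub.asum; acnt += sub.acnt;
      s = sub.s_pr && no_uturn(ham, st.th_m, st.p_m, st.th_p, st.p_p);
      ++depth;
    }
    if (depth == max_treedepth && !warm) ++n_maxdepth;
    if (diverged && !warm) ++n_div;
    th = th_new;
    double astat = (acnt > 0) ? asum / acnt : 0.0;

    if (warm) {
      // dual averaging
      ++da_count;
      double frac = 1.0 / (da_count + da_t0);
      Hbar = (1.0 - frac) * Hbar + frac * (target_accept - astat);
      double log_eps = mu - std::sqrt((double)da_count) / da_gamma * Hbar;
      double w = std::pow((double)da_count, -da_kappa);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
      eps = std::exp(log_eps);
      // mass windows
      if (win_idx < win_ends.size()) {
        if (it + 1 > winit) acc(th);
        if (it + 1 == win_ends[win_idx]) {
          if (acc.count() > 4) {
            vec v = acc.var();
            double nW = (double)acc.count();
            ham.minv = (nW / (nW + 5.0)) * v +
              1e-3 * (5.0 / (nW + 5.0)) * ones<vec>(m.dim);
            ham.minv = clamp(ham.minv, 1e-10, 1e10);
          }
          acc.reset();
          ++win_idx;
          eps = find_epsilon(ham, th, rng);
          da_restart();
        }
      }
      if (it + 1 == n_warmup) eps = std::exp(log_eps_bar);
    } else {
      accept_sum += astat; ++accept_n;
      m.constrain(th, lp_new, outbuf.data());
      for (int c = 0; c < m.n_out(); ++c)
        draws(it - n_warmup, c) = outbuf[c];
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("draws") = draws,
    Rcpp::Named("divergent") = n_div,
    Rcpp::Named("max_treedepth_hits") = n_maxdepth,
    Rcpp::Named("stepsize") = eps,
    Rcpp::Named("accept") = accept_n ? accept_sum / accept_n : NA_REAL,
    Rcpp::Named("dim") = m.dim);
}
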