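// Adaptive NUTS sampler for the hierarchical dummy-point logistic model.
//
// Parameter vector (non-centered; hierarchical mode):
//   [ psi_raw (G*Q) | gamma_raw (N*Q) | delta_raw (M*Q) | beta (M*J) | log_sigma (3) ]
// with
//   psi(g)   = sigma_cohort  * psi_raw(g)
//   gamma(n) = psi(coh(n))   + sigma_patient * gamma_raw(n)
//   delta(m) = gamma(pat(m)) + sigma_image   * delta_raw(m)
// Flat mode:
//   [ delta (M*Q) | beta (M*J) ],  delta ~ N(0, sd_delta^2) independently.
//
// Likelihood (all rows, logit link):
//   eta_i = z_i' beta(img_i) + x_i' delta(img_i) - offset_i
//   ll   += y_i * eta_i - log(1 + exp(eta_i))
//
// The non-centered parameterization leaves the posterior unchanged but removes
// the funnel geometry between coefficients and variance components.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct ModelData {
  mat X;            // n x Q interaction features
  mat Z;            // n x J covariates
  vec y;            // labels 0/1
  vec offset;       // log lambda_dummy per row
  uvec img;         // row -> image (0-based)
  uvec pat;         // image -> patient
  uvec coh;         // patient -> cohort
  int M, N, G, J, Q;
  bool hierarchical;
  double sd_beta;
  vec sd_sigma;     // half-normal scales (cohort, patient, image)
  double sd_delta_flat;

  int dim() const {
    return hierarchical ? (G + N + M) * Q + M * J + 3 : M * Q + M * J;
  }
};

inline double log1pexp(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// log posterior and gradient; returns lp, fills grad (same length as theta)
double lp_grad(const ModelData& d, const vec& theta, vec& grad) {
  const int M = d.M, N = d.N, G = d.G, J = d.J, Q = d.Q;
  grad.zeros(theta.n_elem);
  double lp = 0.0;

  // recover image-level coefficients delta (M x Q) and beta (M x J)
  mat delta(M, Q), beta(M, J);
  mat psi, gam;
  double sig_c = 0, sig_p = 0, sig_i = 0;
  int off_gamma = G * Q, off_delta = (G + N) * Q, off_beta = (G + N + M) * Q;
  if (d.hierarchical) {
    sig_c = std::exp(theta((G + N + M) * Q + M * J + 0));
    sig_p = std::exp(theta((G + N + M) * Q + M * J + 1));
    sig_i = std::exp(theta((G + N + M) * Q + M * J + 2));
    psi.set_size(G, Q);
    gam.set_size(N, Q);
    for (int g = 0; g < G; ++g)
      for (int q = 0; q < Q; ++q) psi(g, q) = sig_c * theta(g * Q + q);
    for (int n = 0; n < N; ++n)
      for (int q = 0; q < Q; ++q)
        gam(n, q) = psi(d.coh(n), q) + sig_p * theta(off_gamma + n * Q + q);
    for (int m = 0; m < M; ++m)
      for (int q = 0; q < Q; ++q)
        delta(m, q) = gam(d.pat(m), q) + sig_i * theta(off_delta + m * Q + q);
    for (int m = 0; m < M; ++m)
      for (int j = 0; j < J; ++j) beta(m, j) = theta(off_beta + m * J + j);
  } else {
    off_beta = M * Q;
    for (int m = 0; m < M; ++m)
      for (int q = 0; q < Q; ++q) delta(m, q) = theta(m * Q + q);
    for (int m = 0; m < M; ++m)
      for (int j = 0; j < J; ++j) beta(m, j) = theta(off_beta + m * J + j);
  }

  // likelihood and accumulation of d lp / d delta(m,.), d lp / d beta(m,.)
  mat u(M, Q, fill::zeros);   // X_m' e_m  per image
  mat ub(M, J, fill::zeros);  // Z_m' e_m
  const int n = d.X.n_rows;
  for (int i = 0; i < n; ++i) {
    const int m = d.img(i);
    double eta = -d.offset(i);
    for (int j = 0; j < J; ++j) eta += d.Z(i, j) * beta(m, j);
    for (int q = 0; q < Q; ++q) eta += d.X(i, q) * delta(m, q);
    lp += d.y(i) * eta - log1pexp(eta);
    const double e = d.y(i) - 1.0 / (1.0 + std::exp(-eta));
    for (int j = 0; j < J; ++j) ub(m, j) += d.Z(i, j) * e;
    for (int q = 0; q < Q; ++q) u(m, q) += d.X(i, q) * e;
  }

  // beta prior
  const double vb = d.sd_beta * d.sd_beta;
  for (int m = 0; m < M; ++m)
    for (int j = 0; j < J; ++j) {
      lp += -0.5 * beta(m, j) * beta(m, j) / vb;
      grad(off_beta + m * J + j) = ub(m, j) - beta(m, j) / vb;
    }

  if (!d.hierarchical) {
    const double vd = d.sd_delta_flat * d.sd_delta_flat;
    for (int m = 0; m < M; ++m)
      for (int q = 0; q < Q; ++q) {
        lp += -0.5 * delta(m, q) * delta(m, q) / vd;
        grad(m * Q + q) = u(m, q) - delta(m, q) / vd;
      }
    return lp;
  }

  // back-propagate through the non-centered cascade
  mat v(N, Q, fill::zeros);  // d lp / d gamma(n,.)
  mat w(G, Q, fill::zeros);  // d lp / d psi(g,.)
  double g_sig_i = 0, g_sig_p = 0, g_sig_c = 0;
  for (int m = 0; m < M; ++m)
    for (int q = 0; q < Q; ++q) {
      const double dr = theta(off_delta + m * Q + q);
      grad(off_delta + m * Q + q) = sig_i * u(m, q) - dr;  // + std normal prior
      lp += -0.5 * dr * dr;
      g_sig_i += dr * u(m, q);
      v(d.pat(m), q) += u(m, q);
    }
  for (int n2 = 0; n2 < N; ++n2)
    for (int q = 0; q < Q; ++q) {
      const double gr = theta(off_gamma + n2 * Q + q);
      grad(off_gamma + n2 * Q + q) = sig_p * v(n2, q) - gr;
      lp += -0.5 * gr * gr;
      g_sig_p += gr * v(n2, q);
      w(d.coh(n2), q) += v(n2, q);
    }
  for (int g = 0; g < G; ++g)
    for (int q = 0; q < Q; ++q) {
      const double pr = theta(g * Q + q);
      grad(g * Q + q) = sig_c * w(g, q) - pr;
      lp += -0.5 * pr * pr;
      g_sig_c += pr * w(g, q);
    }

  // half-normal hyperpriors on sigma, sampled on the log scale (+ Jacobian)
  const double sc = d.sd_sigma(0), sp = d.sd_sigma(1), si = d.sd_sigma(2);
  lp += -0.5 * sig_c * sig_c / (sc * sc) + std::log(sig_c);
  lp += -0.5 * sig_p * sig_p / (sp * sp) + std::log(sig_p);
  lp += -0.5 * sig_i * sig_i / (si * si) + std::log(sig_i);
  const int ls = (G + N + M) * Q + M * J;
  grad(ls + 0) = sig_c * g_sig_c - sig_c * sig_c / (sc * sc) + 1.0;
  grad(ls + 1) = sig_p * g_sig_p - sig_p * sig_p / (sp * sp) + 1.0;
  grad(ls + 2) = sig_i * g_sig_i - sig_i * sig_i / (si * si) + 1.0;
  return lp;
}

ModelData unpack(const Rcpp::List& data) {
  ModelData d;
  d.X = Rcpp::as<mat>(data["X"]);
  d.Z = Rcpp::as<mat>(data["Z"]);
  d.y = Rcpp::as<vec>(data["y"]);
  d.offset = Rcpp::as<vec>(data["offset"]);
  d.img = Rcpp::as<uvec>(data["img"]);
  d.pat = Rcpp::as<uvec>(data["pat"]);
  d.coh = Rcpp::as<uvec>(data["coh"]);
  d.M = Rcpp::as<int>(data["M"]);
  d.N = Rcpp::as<int>(data["N"]);
  d.G = Rcpp::as<int>(data["G"]);
  d.J = Rcpp::as<int>(data["J"]);
  d.Q = Rcpp::as<int>(data["Q"]);
  d.hierarchical = Rcpp::as<bool>(data["hierarchical"]);
  d.sd_beta = Rcpp::as<double>(data["sd_beta"]);
  d.sd_sigma = Rcpp::as<vec>(data["sd_sigma"]);
  d.sd_delta_flat = Rcpp::as<double>(data["sd_delta_flat"]);
  return d;
}

struct Rng {
  std::mt19937_64 gen;
  std::normal_distribution<double> norm;
  std::uniform_real_distribution<double> unif;
  explicit Rng(uint64_t seed) : gen(seed), norm(0, 1), unif(0, 1) {}
  double rnorm() { return norm(gen); }
  double runif() { return unif(gen); }
  double rexp() { return -std::log(1.0 - unif(gen)); }
};

struct Leaf {
  vec q, r, grad;
  double lp;
};

struct Hamiltonian {
  const ModelData* d;
  vec Minv;  // diagonal inverse mass

  double H(const Leaf& s) const { return s.lp - 0.5 * dot(s.r, Minv % s.r); }

  void leapfrog(Leaf& s, double eps) const {
    s.r += 0.5 * eps * s.grad;
    s.q += eps * (Minv % s.r);
    s.lp = lp_grad(*d, s.q, s.grad);
    s.r += 0.5 * eps * s.grad;
  }
};

struct Tree {
  Leaf minus, plus, prop;
  double n;      // number of valid leaves
  bool s;        // no U-turn / divergence
  double alpha;  // sum of accept probs
  int nalpha;
  bool divergent;
};

bool no_uturn(const Leaf& minus, const Leaf& plus, const vec& Minv) {
  const vec dq = plus.q - minus.q;
  return dot(dq, Minv % minus.r) >= 0 && dot(dq, Minv % plus.r) >= 0;
}

// recursive doubling (slice variant)
Tree build_tree(const Hamiltonian& ham, const Leaf& leaf, double log_u, int v,
                int j, double eps, double H0, Rng& rng) {
  Tree t;
  if (j == 0) {
    Leaf s = leaf;
    ham.leapfrog(s, v * eps);
    double H = std::isfinite(s.lp) ? ham.H(s) : -datum::inf;
    t.minus = s;
    t.plus = s;
    t.prop = s;
    t.n = (log_u <= H) ? 1.0 : 0.0;
    t.divergent = !(log_u < H + 1000.0);
    t.s = !t.divergent;
    double a = std::exp(std::min(0.0, H - H0));
    if (!std::isfinite(a)) a = 0.0;
    t.alpha = a;
    t.nalpha = 1;
    return t;
  }
  Tree t1 = build_tree(ham, leaf, log_u, v, j - 1, eps, H0, rng);
  if (!t1.s) return t1;
  const Leaf& edge = (v == -1) ? t1.minus : t1.plus;
  Tree t2 = build_tree(ham, edge, log_u, v, j - 1, eps, H0, rng);
  t.minus = (v == -1) ? t2.minus : t1.minus;
  t.plus = (v == -1) ? t1.plus : t2.plus;
  t.n = t1.n + t2.n;
  t.prop = t1.prop;
  if (t.n > 0 && rng.runif() < t2.n / t.n) t.prop = t2.prop;
  t.alpha = t1.alpha + t2.alpha;
  t.nalpha = t1.nalpha + t2.nalpha;
  t.divergent = t1.divergent || t2.divergent;
  t.s = t2.s && no_uturn(t.minus, t.plus, ham.Minv);
  return t;
}

double init_stepsize(const Hamiltonian& ham, const vec& q0, Rng& rng) {
  double eps = 0.1;
  Leaf s;
  s.q = q0;
  s.r.set_size(q0.n_elem);
  for (uword i = 0; i < q0.n_elem; ++i)
    s.r(i) = rng.rnorm() / std::sqrt(ham.Minv(i));
  s.lp = lp_grad(*ham.d, s.q, s.grad);
  const double H0 = ham.H(s);
  Leaf s1 = s;
  ham.leapfrog(s1, eps);
  double H1 = std::isfinite(s1.lp) ? ham.H(s1) : -datum::inf;
  double a = (H1 - H0 > std::log(0.5)) ? 1.0 : -1.0;
  for (int it = 0; it < 50; ++it) {
    eps *= std::pow(2.0, a);
    s1 = s;
    ham.leapfrog(s1, eps);
    H1 = std::isfinite(s1.lp) ? ham.H(s1) : -datum::inf;
    if (a * (H1 - H0) <= a * std::log(0.5)) break;
  }
  return eps;
}

}  // namespace

// [[Rcpp::export(name = ".shade_lp_grad")]]
Rcpp::List shade_lp_grad(const arma::vec& theta, const Rcpp::List& data) {
  ModelData d = unpack(data);
  vec grad;
  double lp = lp_grad(d, theta, grad);
  return Rcpp::List::create(Rcpp::Named("lp") = lp, Rcpp::Named("grad") = grad);
}

// Runs one chain; returns draws (unconstrained scale) and sampler statistics.
// [[Rcpp::export(name = ".shade_nuts_chain")]]
Rcpp::List shade_nuts_chain(const Rcpp::List& data, const arma::vec& init,
                            int n_warmup, int n_draws, double target_accept,
                            int max_treedepth, double seed,
                            const arma::vec& minv0) {
  ModelData d = unpack(data);
  const int dim = d.dim();
  if ((int)init.n_elem != dim) Rcpp::stop("init has wrong length");
  Rng rng(static_cast<uint64_t>(seed));

  Hamiltonian ham;
  ham.d = &d;
  ham.Minv = vec(dim, fill::ones);
  if ((int)minv0.n_elem == dim) ham.Minv = minv0;

  Leaf cur;
  cur.q = init;
  cur.lp = lp_grad(d, cur.q, cur.grad);
  if (!std::isfinite(cur.lp)) Rcpp::stop("non-finite log posterior at init");

  // dual averaging state
  double eps = init_stepsize(ham, cur.q, rng);
  double mu = std::log(10.0 * eps), log_eps_bar = 0.0, Hbar = 0.0;
  const double da_gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int da_count = 0;

  // metric adaptation window (Welford)
  const int win_lo = std::max(1, (int)(0.25 * n_warmup));
  const int win_hi = std::max(win_lo + 2, (int)(0.75 * n_warmup));
  vec wm(dim, fill::zeros), ws(dim, fill::zeros);
  int wn = 0;

  mat draws(n_draws, dim);
  vec lp_out(n_draws);
  Rcpp::IntegerVector treedepth(n_draws);
  int divergences = 0;
  double accept_sum = 0.0;
  int accept_n = 0;

  const int total = n_warmup + n_draws;
  for (int it = 0; it < total; ++it) {
    // momentum refresh
    Leaf s = cur;
    s.r.set_size(dim);
    for (int i = 0; i < dim; ++i) s.r(i) = rng.rnorm() / std::sqrt(ham.Minv(i));
    const double H0 = ham.H(s);
    const double log_u = H0 - rng.rexp();

    Leaf minus = s, plus = s, prop = s;
    double n_valid = 1.0;
    bool keep = true;
    int depth = 0;
    double alpha = 0.0;
    int nalpha = 0;
    bool div_this = false;
    while (keep && depth < max_treedepth) {
      const int v = (rng.runif() < 0.5) ? -1 : 1;
      Tree t = build_tree(ham, (v == -1) ? minus : plus, log_u, v, depth, eps,
                          H0, rng);
      if (v == -1) minus = t.minus; else plus = t.plus;
      if (t.s && t.n > 0 && rng.runif() < t.n / n_valid) prop = t.prop;
      n_valid += t.n;
      alpha = t.alpha;
      nalpha = t.nalpha;
      div_this = div_this || t.divergent;
      keep = t.s && no_uturn(minus, plus, ham.Minv);
      ++depth;
    }
    cur.q = prop.q;
    cur.lp = prop.lp;
    cur.grad = prop.grad;
    const double astat = (nalpha > 0) ? alpha / nalpha : 0.0;

    if (it < n_warmup) {
      // dual averaging
      ++da_count;
      const double frac = 1.0 / (da_count + t0);
      Hbar = (1 - frac) * Hbar + frac * (target_accept - astat);
      const double log_eps = mu - std::sqrt((double)da_count) / da_gamma * Hbar;
      const double w = std::pow((double)da_count, -kappa);
      log_eps_bar = w * log_eps + (1 - w) * log_eps_bar;
      eps = std::exp(log_eps);
      // metric window
      if (it >= win_lo && it < win_hi) {
        ++wn;
        const vec delta = cur.q - wm;
        wm += delta / wn;
        ws += delta % (cur.q - wm);
      }
      if (it == win_hi - 1 && wn > 4) {
        vec var = ws / (wn - 1);
        ham.Minv = ((double)wn / (wn + 5.0)) * var + (5.0 / (wn + 5.0)) * 1e-3;
        // restart step-size adaptation around the current value
        eps = init_stepsize(ham, cur.q, rng);
        mu = std::log(10.0 * eps);
        log_eps_bar = 0.0;
        Hbar = 0.0;
        da_count = 0;
      }
      if (it == n_warmup - 1) eps = std::exp(log_eps_bar);
    } else {
      const int k = it - n_warmup;
      draws.row(k) = cur.q.t();
      lp_out(k) = cur.lp;
      treedepth[k] = depth;
      if (div_this) ++divergences;
      accept_sum += astat;
      ++accept_n;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("draws") = draws, Rcpp::Named("lp") = lp_out,
      Rcpp::Named("divergences") = divergences,
      Rcpp::Named("treedepth") = treedepth,
      Rcpp::Named("accept_stat") = accept_sum / std::max(1, accept_n),
      Rcpp::Named("step_size") = eps);
}
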