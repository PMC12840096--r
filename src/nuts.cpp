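// Gradient-based MCMC core: the hierarchical CNV model's log density with
// analytic gradients, a conjugate normal-normal test model, and a No-U-Turn
// sampler with dual-averaging step-size adaptation and diagonal mass-matrix
// adaptation. All randomness comes from a std::mt19937_64 seeded explicitly,
// so runs are reproducible independent of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
#include <memory>
#include <string>

using namespace Rcpp;

static const double LOG_2_OVER_PI = std::log(2.0 / M_PI);
static const double LOG_2PI = std::log(2.0 * M_PI);

// log sech((x-loc)/s) / (pi s), computed without overflow for large |z|
static inline double sech_logpdf(double x, double loc, double s) {
  double z = (x - loc) / s;
  double az = std::fabs(z);
  return LOG_2_OVER_PI - std::log(s) - az - std::log1p(std::exp(-2.0 * az));
}

// log InvGamma(v; a, b) evaluated at v = exp(w), plus the log-Jacobian w
static inline double invgamma_logpdf_log(double w, double a, double b) {
  return a * std::log(b) - std::lgamma(a) - a * w - b * std::exp(-w);
}

struct Model {
  virtual int dim() const = 0;
  // tempered log density: log p(u) + beta * log p(x | u), unconstrained
  // space (Jacobians included in the prior part). Fills grad (length dim)
  // and the untempered log-likelihood.
  virtual double logp_grad(const std::vector<double>& u, double beta,
                           std::vector<double>& grad, double& loglik) const = 0;
  virtual std::vector<double> draw_init(std::mt19937_64& rng) const = 0;
  virtual ~Model() {}
};

// Hierarchical amplicon model. Unconstrained parameter layout:
//   u[0] = mu0, u[1] = log sigma2, u[2] = log tau0_sq,
//   u[3 .. 2+G] = eta_g (non-centered gene means),
//   u[3+G .. 2+2G] = log z_g.
// mu_g = mu0 + sqrt(sigma2) * eta_g; observation scale s_g = sqrt(tau0_sq) * z_g.
struct CnvModel : Model {
  std::vector<double> x;
  std::vector<int> gene;  // 0-based
  int G;
  double nu, a_s, b_s, a_t0, b_t0, a_z, b_z;

  int dim() const override { return 3 + 2 * G; }

  double logp_grad(const std::vector<double>& u, double beta,
                   std::vector<double>& grad, double& loglik) const override {
    const int D = dim();
    grad.assign(D, 0.0);
    const double mu0 = u[0], ls = u[1], lt = u[2];
    const double sigma = std::exp(0.5 * ls);

    double lp = -0.5 * std::log(2.0 * M_PI * nu) - 0.5 * mu0 * mu0 / nu;
    grad[0] += -mu0 / nu;

    lp += invgamma_logpdf_log(ls, a_s, b_s);
    grad[1] += -a_s + b_s * std::exp(-ls);
    lp += invgamma_logpdf_log(lt, a_t0, b_t0);
    grad[2] += -a_t0 + b_t0 * std::exp(-lt);

    std::vector<double> mu_g(G), s_g(G);
    for (int g = 0; g < G; ++g) {
      const double eta = u[3 + g];
      const double lz = u[3 + G + g];
      lp += -0.5 * LOG_2PI - 0.5 * eta * eta;
      grad[3 + g] += -eta;
      lp += invgamma_logpdf_log(lz, a_z, b_z);
      grad[3 + G + g] += -a_z + b_z * std::exp(-lz);
      mu_g[g] = mu0 + sigma * eta;
      s_g[g] = std::exp(0.5 * lt + lz);
    }

    double ll = 0.0;
    for (size_t j = 0; j < x.size(); ++j) {
      const int g = gene[j];
      const double s = s_g[g];
      const double z = (x[j] - mu_g[g]) / s;
      const double az = std::fabs(z);
      ll += LOG_2_OVER_PI - std::log(s) - az - std::log1p(std::exp(-2.0 * az));
      const double t = std::tanh(z);
      const double dmu = t / s;          // d loglik / d mu_g
      const double dlogs = -1.0 + z * t; // d loglik / d log s_g
      grad[0] += beta * dmu;
      grad[3 + g] += beta * dmu * sigma;
      grad[1] += beta * dmu * 0.5 * sigma * u[3 + g];
      grad[2] += beta * 0.5 * dlogs;
      grad[3 + G + g] += beta * dlogs;
    }
    loglik = ll;
    return lp + beta * ll;
  }

  std::vector<double> draw_init(std::mt19937_64& rng) const override {
    std::normal_distribution<double> rnorm(0.0, 1.0);
    std::vector<double> u(dim());
    u[0] = 0.25 * std::sqrt(nu) * rnorm(rng);
    // jittered prior-typical values for the variance parameters: start the
    // log-scale parameters near the prior median rather than in the IG tail
    auto lg_init = [&](double a, double b) {
      return std::log(b / (a + 1.0)) + 0.25 * rnorm(rng);
    };
    u[1] = lg_init(a_s, b_s);
    u[2] = lg_init(a_t0, b_t0);
    for (int g = 0; g < G; ++g) {
      u[3 + g] = 0.25 * rnorm(rng);
      u[3 + G + g] = lg_init(a_z, b_z);
    }
    return u;
  }
};

// Conjugate normal-normal model used as an analytic oracle for evidence
// estimation: theta ~ N(0, prior_var), x_j | theta ~ N(theta, lik_var).
struct NormalModel : Model {
  std::vector<double> x;
  double prior_var, lik_var;

  int dim() const override { return 1; }

  double logp_grad(const std::vector<double>& u, double beta,
                   std::vector<double>& grad, double& loglik) const override {
    grad.assign(1, 0.0);
    const double th = u[0];
    double lp = -0.5 * std::log(2.0 * M_PI * prior_var) - 0.5 * th * th / prior_var;
    grad[0] += -th / prior_var;
    double ll = 0.0, dth = 0.0;
    for (size_t j = 0; j < x.size(); ++j) {
      const double r = x[j] - th;
      ll += -0.5 * std::log(2.0 * M_PI * lik_var) - 0.5 * r * r / lik_var;
      dth += r / lik_var;
    }
    grad[0] += beta * dth;
    loglik = ll;
    return lp + beta * ll;
  }

  std::vector<double> draw_init(std::mt19937_64& rng) const override {
    std::normal_distribution<double> rnorm(0.0, std::sqrt(prior_var));
    return std::vector<double>(1, rnorm(rng));
  }
};

static std::unique_ptr<Model> make_model(const std::string& name, const List& data) {
  if (name == "cnv") {
    auto m = std::unique_ptr<CnvModel>(new CnvModel());
    NumericVector x = data["x"];
    IntegerVector g = data["gene"];
    m->x.assign(x.begin(), x.end());
    m->gene.resize(g.size());
    for (int i = 0; i < g.size(); ++i) m->gene[i] = g[i] - 1;
    m->G = as<int>(data["G"]);
    List hp = data["hp"];
    m->nu = as<double>(hp["nu"]);
    m->a_s = as<double>(hp["alpha_sigma"]);
    m->b_s = as<double>(hp["beta_sigma"]);
    m->a_t0 = as<double>(hp["alpha_tau0"]);
    m->b_t0 = as<double>(hp["beta_tau0"]);
    m->a_z = as<double>(hp["alpha_tau"]);
    m->b_z = as<double>(hp["beta_tau"]);
    return std::unique_ptr<Model>(m.release());
  } else if (name == "normal") {
    auto m = std::unique_ptr<NormalModel>(new NormalModel());
    NumericVector x = data["x"];
    m->x.assign(x.begin(), x.end());
    m->prior_var = as<double>(data["prior_var"]);
    m->lik_var = as<double>(data["lik_var"]);
    return std::unique_ptr<Model>(m.release());
  }
  stop("unknown model '%s'", name.c_str());
}

// ---------------------------------------------------------------------------
// NUTS

struct Sampler {
  const Model& model;
  double beta;
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> runif{0.0, 1.0};
  std::normal_distribution<double> rnorm{0.0, 1.0};
  std::exponential_distribution<double> rexp{1.0};
  int D;
  std::vector<double> inv_metric;  // diagonal of M^-1
  int max_treedepth;
  long n_divergent = 0;
  long n_grad = 0;

  Sampler(const Model& m, double beta_, uint64_t seed, int max_td)
      : model(m), beta(beta_), rng(seed), D(m.dim()),
        inv_metric(m.dim(), 1.0), max_treedepth(max_td) {}

  double logp(const std::vector<double>& u, std::vector<double>& grad, double& ll) {
    ++n_grad;
    return model.logp_grad(u, beta, grad, ll);
  }

  double kinetic(const std::vector<double>& p) const {
    double k = 0.0;
    for (int i = 0; i < D; ++i) k += inv_metric[i] * p[i] * p[i];
    return 0.5 * k;
  }

  void sample_momentum(std::vector<double>& p) {
    for (int i = 0; i < D; ++i) p[i] = rnorm(rng) / std::sqrt(inv_metric[i]);
  }

  // one leapfrog step; updates u, p, grad (grad must hold grad at u on entry)
  double leapfrog(std::vector<double>& u, std::vector<double>& p,
                  std::vector<double>& grad, double eps, double& ll) {
    for (int i = 0; i < D; ++i) p[i] += 0.5 * eps * grad[i];
    for (int i = 0; i < D; ++i) u[i] += eps * inv_metric[i] * p[i];
    double lp = logp(u, grad, ll);
    for (int i = 0; i < D; ++i) p[i] += 0.5 * eps * grad[i];
    return lp;
  }

  bool no_uturn(const std::vector<double>& um, const std::vector<double>& pm,
                const std::vector<double>& up, const std::vector<double>& pp) const {
    double dm = 0.0, dp = 0.0;
    for (int i = 0; i < D; ++i) {
      const double du = up[i] - um[i];
      dm += du * inv_metric[i] * pm[i];
      dp += du * inv_metric[i] * pp[i];
    }
    return dm >= 0.0 && dp >= 0.0;
  }

  struct Tree {
    std::vector<double> um, pm, gm, up, pp, gp;  // minus / plus edges
    std::vector<double> u_prop;
    double ll_prop = 0.0;
    double n = 0.0;
    bool ok = true;
    double alpha = 0.0;
    int n_alpha = 0;
    bool divergent = false;
  };

  void build_tree(Tree& t, std::vector<double> u, std::vector<double> p,
                  std::vector<double> grad, double log_su, int v, int depth,
                  double eps, double joint0) {
    if (depth == 0) {
      double ll;
      double lp = leapfrog(u, p, grad, v * eps, ll);
      double joint = lp - kinetic(p);
      if (!std::isfinite(joint)) joint = -std::numeric_limits<double>::infinity();
      t.um = u; t.pm = p; t.gm = grad;
      t.up = u; t.pp = p; t.gp = grad;
      t.u_prop = u;
      t.ll_prop = ll;
      t.n = (log_su <= joint) ? 1.0 : 0.0;
      t.ok = (log_su < joint + 1000.0);
      if (!t.ok) t.divergent = true;
      double a = joint - joint0;
      t.alpha = (a > 0.0) ? 1.0 : std::exp(a);
      t.n_alpha = 1;
      return;
    }
    build_tree(t, u, p, grad, log_su, v, depth - 1, eps, joint0);
    if (!t.ok) return;
    Tree t2;
    if (v == -1) {
      build_tree(t2, t.um, t.pm, t.gm, log_su, v, depth - 1, eps, joint0);
      t.um = t2.um; t.pm = t2.pm; t.gm = t2.gm;
    } else {
      build_tree(t2, t.up, t.pp, t.gp, log_su, v, depth - 1, eps, joint0);
      t.up = t2.up; t.pp = t2.pp; t.gp = t2.gp;
    }
    if (t2.divergent) t.divergent = true;
    if (t2.ok && t2.n > 0.0 && runif(rng) < t2.n / std::max(1.0, t.n + t2.n)) {
      t.u_prop = t2.u_prop;
      t.ll_prop = t2.ll_prop;
    }
    t.n += t2.n;
    t.alpha += t2.alpha;
    t.n_alpha += t2.n_alpha;
    t.ok = t.ok && t2.ok && no_uturn(t.um, t.pm, t.up, t.pp);
  }

  // one NUTS transition; returns accept-stat, updates u/ll in place
  double transition(std::vector<double>& u, double eps, double& ll, bool count_div) {
    std::vector<double> p(D), grad(D);
    sample_momentum(p);
    double ll0;
    double lp0 = logp(u, grad, ll0);
    double joint0 = lp0 - kinetic(p);
    double log_su = joint0 - rexp(rng);

    Tree t;
    t.um = u; t.pm = p; t.gm = grad;
    t.up = u; t.pp = p; t.gp = grad;
    t.u_prop = u; t.ll_prop = ll0;
    t.n = 1.0;
    t.ok = true;
    double alpha_sum = 0.0;
    int n_alpha = 0;
    bool divergent = false;

    for (int depth = 0; depth < max_treedepth && t.ok; ++depth) {
      int v = (runif(rng) < 0.5) ? -1 : 1;
      Tree t2;
      if (v == -1)
        build_tree(t2, t.um, t.pm, t.gm, log_su, v, depth, eps, joint0);
      else
        build_tree(t2, t.up, t.pp, t.gp, log_su, v, depth, eps, joint0);
      if (v == -1) { t.um = t2.um; t.pm = t2.pm; t.gm = t2.gm; }
      else { t.up = t2.up; t.pp = t2.pp; t.gp = t2.gp; }
      alpha_sum += t2.alpha;
      n_alpha += t2.n_alpha;
      if (t2.divergent) divergent = true;
      if (t2.ok && runif(rng) < t2.n / std::max(1.0, t.n)) {
        t.u_prop = t2.u_prop;
        t.ll_prop = t2.ll_prop;
      }
      t.n += t2.n;
      t.ok = t2.ok && no_uturn(t.um, t.pm, t.up, t.pp);
    }
    if (divergent && count_div) ++n_divergent;
    u = t.u_prop;
    ll = t.ll_prop;
    return n_alpha > 0 ? alpha_sum / n_alpha : 0.0;
  }

  double find_initial_stepsize(std::vector<double> u) {
    double eps = 1.0;
    std::vector<double> p(D), grad(D);
    sample_momentum(p);
    double ll;
    double lp0 = logp(u, grad, ll);
    double h0 = lp0 - kinetic(p);
    std::vector<double> u1 = u, p1 = p, g1 = grad;
    double lp1 = leapfrog(u1, p1, g1, eps, ll);
    double h1 = lp1 - kinetic(p1);
    if (!std::isfinite(h1)) h1 = -std::numeric_limits<double>::infinity();
    double dH = h1 - h0;
    double a = (dH > std::log(0.5)) ? 1.0 : -1.0;
    for (int iter = 0; iter < 50; ++iter) {
      eps *= std::pow(2.0, a);
      u1 = u; p1 = p; g1 = grad;
      lp1 = leapfrog(u1, p1, g1, eps, ll);
      h1 = lp1 - kinetic(p1);
      if (!std::isfinite(h1)) h1 = -std::numeric_limits<double>::infinity();
      if (a * (h1 - h0) <= a * std::log(0.5)) break;
    }
    return eps;
  }
};

// Welford accumulator for the diagonal metric
struct Welford {
  int n = 0;
  std::vector<double> mean, m2;
  void init(int D) { n = 0; mean.assign(D, 0.0); m2.assign(D, 0.0); }
  void add(const std::vector<double>& u) {
    ++n;
    for (size_t i = 0; i < u.size(); ++i) {
      double d = u[i] - mean[i];
      mean[i] += d / n;
      m2[i] += d * (u[i] - mean[i]);
    }
  }
};

struct DualAverage {
  double mu, log_eps, log_eps_bar = 0.0, h_bar = 0.0;
  double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int m = 0;
  void init(double eps0) {
    mu = std::log(10.0 * eps0);
    log_eps = std::log(eps0);
    log_eps_bar = 0.0;
    h_bar = 0.0;
    m = 0;
  }
  void update(double accept, double target) {
    ++m;
    h_bar = (1.0 - 1.0 / (m + t0)) * h_bar + (target - accept) / (m + t0);
    log_eps = mu - std::sqrt((double)m) / gamma * h_bar;
    double w = std::pow((double)m, -kappa);
    log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
  }
};

// [[Rcpp::export(name = ".nuts_run")]]
List nuts_run(std::string model_name, List data, double beta,
              int num_warmup, int num_samples, double target_accept,
              int max_treedepth, double seed,
              Nullable<NumericVector> init = R_NilValue) {
  std::unique_ptr<Model> model = make_model(model_name, data);
  const int D = model->dim();
  Sampler s(*model, beta, (uint64_t)seed, max_treedepth);

  std::vector<double> u;
  if (init.isNotNull()) {
    NumericVector iv(init);
    if (iv.size() != D) stop("init has length %d, expected %d", (int)iv.size(), D);
    u.assign(iv.begin(), iv.end());
  } else {
    u = model->draw_init(s.rng);
  }
  {
    std::vector<double> grad(D);
    double ll;
    double lp = s.logp(u, grad, ll);
    if (!std::isfinite(lp))
      stop("log density is not finite at the initial state (logp = %f)", lp);
    for (int i = 0; i < D; ++i)
      if (!std::isfinite(grad[i]))
        stop("gradient is not finite at the initial state (component %d)", i + 1);
  }

  // Warmup schedule: step-size-only buffers around doubling variance windows
  int init_buf = 75, term_buf = 50, base_win = 25;
  bool adapt_metric = num_warmup >= init_buf + term_buf + base_win;
  if (!adapt_metric) { init_buf = num_warmup; term_buf = 0; }
  std::vector<int> window_ends;
  if (adapt_metric) {
    int pos = init_buf, win = base_win;
    while (true) {
      int end = pos + win;
      if (end + 2 * win > num_warmup - term_buf) end = num_warmup - term_buf;
      window_ends.push_back(end);
      if (end >= num_warmup - term_buf) break;
      pos = end;
      win *= 2;
    }
  }

  DualAverage da;
  da.init(s.find_initial_stepsize(u));
  double eps = std::exp(da.log_eps);
  Welford wf;
  wf.init(D);
  size_t next_window = 0;
  double ll = 0.0;

  for (int m = 0; m < num_warmup; ++m) {
    double accept = s.transition(u, eps, ll, false);
    da.update(accept, target_accept);
    eps = std::exp(da.log_eps);
    if (adapt_metric && m >= init_buf && next_window < window_ends.size()) {
      wf.add(u);
      if (m + 1 == window_ends[next_window]) {
        if (wf.n >= 10) {
          for (int i = 0; i < D; ++i) {
            double v = wf.m2[i] / std::max(1, wf.n - 1);
            s.inv_metric[i] = (wf.n / (wf.n + 5.0)) * v + 1e-3 * (5.0 / (wf.n + 5.0));
          }
        }
        wf.init(D);
        ++next_window;
        da.init(s.find_initial_stepsize(u));
        eps = std::exp(da.log_eps);
      }
    }
  }
  if (num_warmup > 0) eps = std::exp(da.log_eps_bar);

  NumericMatrix draws(num_samples, D);
  NumericVector logliks(num_samples);
  double accept_sum = 0.0;
  s.n_divergent = 0;
  for (int m = 0; m < num_samples; ++m) {
    accept_sum += s.transition(u, eps, ll, true);
    for (int i = 0; i < D; ++i) draws(m, i) = u[i];
    logliks[m] = ll;
  }

  return List::create(
      _["draws"] = draws,
      _["loglik"] = logliks,
      _["accept_mean"] = num_samples > 0 ? accept_sum / num_samples : NA_REAL,
      _["divergences"] = (double)s.n_divergent,
      _["step_size"] = eps,
      _["inv_metric"] = NumericVector(s.inv_metric.begin(), s.inv_metric.end()),
      _["last_state"] = NumericVector(u.begin(), u.end()),
      _["n_gradient_evals"] = (double)s.n_grad);
}

// [[Rcpp::export(name = ".model_logp")]]
List model_logp(std::string model_name, List data, NumericVector u, double beta) {
  std::unique_ptr<Model> model = make_model(model_name, data);
  const int D = model->dim();
  if (u.size() != D) stop("u has length %d, expected %d", (int)u.size(), D);
  std::vector<double> uv(u.begin(), u.end()), grad(D);
  double ll;
  double lp = model->logp_grad(uv, beta, grad, ll);
  return List::create(_["logp"] = lp,
                      _["grad"] = NumericVector(grad.begin(), grad.end()),
                      _["loglik"] = ll);
}
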