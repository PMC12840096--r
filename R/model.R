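#' SoftLaplace (hyperbolic secant) distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the SoftLaplace distribution with density
#' \deqn{p(x \mid \mu, s) = \frac{\mathrm{sech}((x-\mu)/s)}{\pi s},}
#' a heavy-tailed alternative to the Gaussian used as the observation model
#' for per-amplicon log copy-number ratios. Its tails decay like the Laplace
#' distribution's (\eqn{\propto e^{-|x|/s}}) but the density is smooth and
#' differentiable everywhere, including the origin, which keeps gradient-based
#' samplers stable. The variance is \eqn{(\pi^2/4)\, s^2}.
#'
#' @param x,q vector of quantiles.
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param location location parameter \eqn{\mu}.
#' @param scale scale parameter \eqn{s > 0}.
#' @param log logical; return the log density?
#' @return `dsoftlaplace` the (log) density, `psoftlaplace` the CDF,
#'   `qsoftlaplace` the quantile function, `rsoftlaplace` random draws.
#' @examples
#' dsoftlaplace(0) # 1/pi
#' integrate(dsoftlaplace, -40, 40)$value # 1
#' @export
dsoftlaplace <- function(x, location = 0, scale = 1, log = FALSE) {
  if (any(scale <= 0)) stop_input("`scale` must be strictly positive")
  z <- (x - location) / scale
  az <- abs(z)
  # log(2/pi) - log(scale) - logaddexp(z, -z), overflow-safe
  out <- log(2 / pi) - base::log(scale) - az - log1p(exp(-2 * az))
  if (log) out else exp(out)
}

#' @rdname dsoftlaplace
#' @export
psoftlaplace <- function(q, location = 0, scale = 1) {
  if (any(scale <= 0)) stop_input("`scale` must be strictly positive")
  0.5 + atan(tanh((q - location) / (2 * scale))) * (2 / pi)
}

#' @rdname dsoftlaplace
#' @export
qsoftlaplace <- function(p, location = 0, scale = 1) {
  if (any(scale <= 0)) stop_input("`scale` must be strictly positive")
  if (any(p < 0 | p > 1)) stop_input("`p` must lie in [0, 1]")
  location + scale * 2 * atanh(tan(pi * (p - 0.5) / 2))
}

#' @rdname dsoftlaplace
#' @export
rsoftlaplace <- function(n, location = 0, scale = 1) {
  qsoftlaplace(runif(n), location = location, scale = scale)
}

#' Inverse-gamma density
#'
#' Shape/scale convention: \eqn{p(x) \propto x^{-\alpha-1} e^{-\beta/x}}.
#'
#' @param x vector of positive quantiles.
#' @param shape shape \eqn{\alpha > 0}.
#' @param scale scale \eqn{\beta > 0}.
#' @param log logical; return the log density?
#' @export
dinvgamma <- function(x, shape, scale, log = FALSE) {
  if (any(shape <= 0) || any(scale <= 0))
    stop_input("`shape` and `scale` must be strictly positive")
  out <- ifelse(x > 0,
                shape * base::log(scale) - lgamma(shape) -
                  (shape + 1) * base::log(x) - scale / x,
                -Inf)
  if (log) out else exp(out)
}

#' Hyperparameters of the hierarchical copy-number model
#'
#' The generative model is
#' \deqn{\mu_0 \sim N(0, \nu), \quad \sigma^2 \sim IG(\alpha_\sigma, \beta_\sigma),
#'   \quad \tau_0^2 \sim IG(\alpha_{\tau_0}, \beta_{\tau_0}),}
#' \deqn{\mu_g \mid \mu_0, \sigma^2 \sim N(\mu_0, \sigma^2), \quad
#'   z_g \sim IG(\alpha_\tau, \beta_\tau),}
#' \deqn{x_{ig} \mid \mu_g, \tau_0^2, z_g \sim
#'   \mathrm{SoftLaplace}(\mu_g, \tau_g^2 = \tau_0^2 z_g^2),}
#' where \eqn{x_{ig}} is the centered log copy-number ratio of amplicon
#' \eqn{i} in gene \eqn{g}, \eqn{\mu_g} the gene-level lCNR, and
#' \eqn{\tau_g^2} is the squared SoftLaplace scale of gene \eqn{g}.
#'
#' Defaults are weakly informative: prior mass on lCNR dispersions of order
#' 0.01–1, with the gene-level noise multipliers \eqn{z_g} concentrated near
#' 1 so that \eqn{\tau_g \approx \tau_0} absent evidence to the contrary.
#'
#' @param nu prior variance of the global mean lCNR \eqn{\mu_0}.
#' @param alpha_sigma,beta_sigma inverse-gamma shape/scale for the
#'   across-gene variance \eqn{\sigma^2}.
#' @param alpha_tau0,beta_tau0 inverse-gamma shape/scale for the global
#'   squared noise scale \eqn{\tau_0^2}.
#' @param alpha_tau,beta_tau inverse-gamma shape/scale for each gene's
#'   noise multiplier \eqn{z_g}.
#' @return An object of class `cnv_hyperparameters`.
#' @export
hyperparameters <- function(nu = 1,
                            alpha_sigma = 3, beta_sigma = 0.5,
                            alpha_tau0 = 3, beta_tau0 = 0.5,
                            alpha_tau = 3, beta_tau = 2) {
  hp <- list(nu = nu,
             alpha_sigma = alpha_sigma, beta_sigma = beta_sigma,
             alpha_tau0 = alpha_tau0, beta_tau0 = beta_tau0,
             alpha_tau = alpha_tau, beta_tau = beta_tau)
  if (!all(vapply(hp, function(v) is.numeric(v) && length(v) == 1 && v > 0,
                  logical(1))))
    stop_input("all hyperparameters must be single strictly positive numbers")
  structure(hp, class = c("cnv_hyperparameters", "list"))
}

#' @export
print.cnv_hyperparameters <- function(x, ...) {
  cat("Hierarchical CNV model hyperparameters\n")
  cat(sprintf("  mu0      ~ N(0, nu = %g)\n", x$nu))
  cat(sprintf("  sigma2   ~ InvGamma(%g, %g)\n", x$alpha_sigma, x$beta_sigma))
  cat(sprintf("  tau0_sq  ~ InvGamma(%g, %g)\n", x$alpha_tau0, x$beta_tau0))
  cat(sprintf("  z_g      ~ InvGamma(%g, %g)\n", x$alpha_tau, x$beta_tau))
  invisible(x)
}

#' Construct a model parameter state
#'
#' Bundles one full set of model parameters
#' \eqn{\theta = \{\mu_0, \sigma^2, \tau_0^2, \{\mu_g\}, \{z_g\}\}} with
#' validation of the positivity constraints.
#'
#' @param mu0 global mean lCNR.
#' @param sigma2 across-gene variance (> 0).
#' @param tau0_sq global squared noise scale (> 0).
#' @param mu numeric vector of gene-level lCNRs, length G.
#' @param z numeric vector of positive gene noise multipliers, length G.
#' @return An object of class `cnv_parameter_state`.
#' @export
parameter_state <- function(mu0, sigma2, tau0_sq, mu = numeric(), z = numeric()) {
  if (length(mu) != length(z))
    stop_input("`mu` and `z` must have the same length (one entry per gene)")
  if (!is.finite(mu0) || sigma2 <= 0 || tau0_sq <= 0 || any(z <= 0))
    stop_input("invalid parameter state: sigma2, tau0_sq and every z must be > 0")
  structure(list(mu0 = mu0, sigma2 = sigma2, tau0_sq = tau0_sq,
                 mu = as.numeric(mu), z = as.numeric(z)),
            class = c("cnv_parameter_state", "list"))
}

#' Log prior density of the hierarchical model
#'
#' Sum of the log densities of all prior terms of the generative model at a
#' parameter state (on the constrained scale, no change-of-variable terms).
#'
#' @param state a [parameter_state()].
#' @param hp a [hyperparameters()] object.
#' @return A single finite log density.
#' @export
log_prior <- function(state, hp = hyperparameters()) {
  stopifnot(inherits(state, "cnv_parameter_state"))
  lp <- dnorm(state$mu0, 0, sqrt(hp$nu), log = TRUE) +
    dinvgamma(state$sigma2, hp$alpha_sigma, hp$beta_sigma, log = TRUE) +
    dinvgamma(state$tau0_sq, hp$alpha_tau0, hp$beta_tau0, log = TRUE)
  if (length(state$mu) > 0) {
    lp <- lp +
      sum(dnorm(state$mu, state$mu0, sqrt(state$sigma2), log = TRUE)) +
      sum(dinvgamma(state$z, hp$alpha_tau, hp$beta_tau, log = TRUE))
  }
  lp
}

#' Log likelihood of centered lCNR data under the hierarchical model
#'
#' \eqn{\sum_g \sum_i \log \mathrm{SoftLaplace}(x_{ig}; \mu_g,
#' s_g = \sqrt{\tau_0^2}\, z_g)}. The model's \eqn{\tau_g^2} is interpreted
#' as the squared SoftLaplace scale.
#'
#' @param data an [prepare_dataset()] result, or a data frame with columns
#'   `gene_index` and `lcnr`.
#' @param state a [parameter_state()] whose gene dimension matches the data.
#' @return A single log density; `0` for an empty dataset.
#' @export
log_likelihood <- function(data, state) {
  stopifnot(inherits(state, "cnv_parameter_state"))
  df <- if (inherits(data, "lcnr_dataset")) data$data else data
  if (is.null(df$gene_index) || is.null(df$lcnr))
    stop_input("`data` must carry `gene_index` and `lcnr` columns")
  if (nrow(df) == 0) return(0)
  G <- length(state$mu)
  if (max(df$gene_index) > G)
    stop_input(sprintf("data refer to gene index %d but the state has G = %d",
                       max(df$gene_index), G))
  s <- sqrt(state$tau0_sq) * state$z
  sum(dsoftlaplace(df$lcnr, location = state$mu[df$gene_index],
                   scale = s[df$gene_index], log = TRUE))
}

#' Log joint density (unnormalized posterior)
#'
#' @inheritParams log_likelihood
#' @inheritParams log_prior
#' @return `log_prior(state, hp) + log_likelihood(data, state)`.
#' @export
log_joint <- function(data, state, hp = hyperparameters()) {
  log_prior(state, hp) + log_likelihood(data, state)
}
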