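#' Sampler configuration
#'
#' Settings for the No-U-Turn Sampler. "Iterations" means post-warmup draws;
#' warmup (step-size and mass-matrix adaptation) is separate and discarded.
#'
#' @param num_warmup warmup iterations (default 1000).
#' @param num_samples post-warmup draws per chain (default 10000).
#' @param num_chains number of chains (default 1). Multi-chain runs enable
#'   the split-R-hat diagnostic and are recommended for production use.
#' @param target_accept dual-averaging target acceptance probability,
#'   default 0.8 (midpoint of the acceptable 0.6–0.9 band).
#' @param max_treedepth maximum NUTS doubling depth (default 10).
#' @param seed integer seed; a fixed seed gives bit-reproducible draws.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(num_warmup = 1000, num_samples = 10000,
                           num_chains = 1, target_accept = 0.8,
                           max_treedepth = 10, seed = 1) {
  if (num_samples < 1 || num_chains < 1)
    stop_input("`num_samples` and `num_chains` must be >= 1")
  if (target_accept <= 0 || target_accept >= 1)
    stop_input("`target_accept` must lie strictly between 0 and 1")
  if (num_warmup < 0) stop_input("`num_warmup` must be >= 0")
  structure(list(num_warmup = as.integer(num_warmup),
                 num_samples = as.integer(num_samples),
                 num_chains = as.integer(num_chains),
                 target_accept = target_accept,
                 max_treedepth = as.integer(max_treedepth),
                 seed = as.integer(seed)),
            class = c("sampler_config", "list"))
}

# model-data list handed to the C++ core
as_model_data <- function(data, hp) {
  list(x = data$data$lcnr,
       gene = as.integer(data$data$gene_index),
       G = as.integer(data$G),
       hp = unclass(hp))
}

# unconstrained draw matrix -> named constrained draw matrix
constrain_draws <- function(mat, genes) {
  G <- length(genes)
  mu0 <- mat[, 1]
  sigma2 <- exp(mat[, 2])
  tau0_sq <- exp(mat[, 3])
  eta <- mat[, 3 + seq_len(G), drop = FALSE]
  z <- exp(mat[, 3 + G + seq_len(G), drop = FALSE])
  mu <- mu0 + sqrt(sigma2) * eta
  out <- cbind(mu0, sigma2, tau0_sq, mu, z)
  colnames(out) <- c("mu0", "sigma2", "tau0_sq",
                     paste0("mu[", genes, "]"), paste0("z[", genes, "]"))
  out
}

#' Draw posterior samples of the hierarchical copy-number model
#'
#' Runs the No-U-Turn Sampler (self-tuning Hamiltonian Monte Carlo) on the
#' hierarchical model. Gene means use the non-centered parameterization
#' \eqn{\mu_g = \mu_0 + \sqrt{\sigma^2}\,\eta_g} with standard-normal
#' \eqn{\eta_g}, and all positive parameters are sampled on the log scale;
#' both choices flatten the posterior geometry for gradient-based sampling.
#' Chains are initialized from jittered prior-typical values, seeded by
#' `config$seed` (chain `c` uses `seed + c - 1`), so a fixed seed gives
#' bit-reproducible draws.
#'
#' @param data an `lcnr_dataset` from [prepare_dataset()]; must contain at
#'   least one modeled gene.
#' @param hp model [hyperparameters()].
#' @param config a [sampler_config()].
#' @param likelihood_weight power-posterior exponent \eqn{\beta \in [0, 1]}
#'   applied to the likelihood; 1 (default) targets the posterior, 0 the
#'   prior. Used by the evidence module.
#' @return An object of class `cnv_posterior`: draws (tibble with `.chain`,
#'   `.draw` and one column per parameter), per-draw log likelihood,
#'   diagnostics, and the configuration used.
#' @examples
#' sim <- simulate_sample(simulation_config(seed = 1))
#' ds <- prepare_dataset(sim$counts)
#' post <- sample_posterior(ds, config = sampler_config(
#'   num_warmup = 200, num_samples = 200, seed = 1))
#' post$diagnostics$mean_accept_prob
#' @export
sample_posterior <- function(data, hp = hyperparameters(),
                             config = sampler_config(),
                             likelihood_weight = 1) {
  if (!inherits(data, "lcnr_dataset"))
    stop_input("`data` must be an `lcnr_dataset` from prepare_dataset()")
  if (data$G < 1 || data$J < 1)
    stop_input("dataset has no modeled genes; nothing to sample")
  if (any(data$genes$n_amplicons < 1))
    stop_input("a modeled gene has zero amplicons; preprocessing is inconsistent")
  if (likelihood_weight < 0 || likelihood_weight > 1)
    stop_input("`likelihood_weight` must lie in [0, 1]")

  md <- as_model_data(data, hp)
  chains <- vector("list", config$num_chains)
  logliks <- vector("list", config$num_chains)
  accept <- divergences <- numeric(config$num_chains)
  for (ch in seq_len(config$num_chains)) {
    res <- .nuts_run("cnv", md, likelihood_weight,
                     config$num_warmup, config$num_samples,
                     config$target_accept, config$max_treedepth,
                     config$seed + ch - 1, NULL)
    chains[[ch]] <- constrain_draws(res$draws, data$genes$gene)
    logliks[[ch]] <- res$loglik
    accept[ch] <- res$accept_mean
    divergences[ch] <- res$divergences
  }

  params <- colnames(chains[[1]])
  ess <- vapply(seq_along(params), function(j) {
    mcmc_ess(vapply(chains, function(m) m[, j], numeric(config$num_samples)))
  }, numeric(1))
  rhat_max <- NA_real_
  if (config$num_chains > 1) {
    rhat <- vapply(seq_along(params), function(j) {
      mcmc_rhat(vapply(chains, function(m) m[, j], numeric(config$num_samples)))
    }, numeric(1))
    rhat_max <- max(rhat, na.rm = TRUE)
  }

  draws <- purrr::map2(chains, seq_along(chains), function(m, ch) {
    dplyr::bind_cols(tibble(.chain = ch, .draw = seq_len(nrow(m))),
                     as_tibble(as.data.frame(m, check.names = FALSE)))
  }) |> purrr::list_rbind()

  diagnostics <- structure(
    list(mean_accept_prob = mean(accept),
         num_divergences = sum(divergences),
         min_ess = min(ess, na.rm = TRUE),
         rhat_max = rhat_max,
         ess = stats::setNames(ess, params)),
    class = c("cnv_diagnostics", "list"))

  structure(list(draws = draws,
                 params = params,
                 gene = data$genes$gene,
                 loglik = unlist(logliks),
                 diagnostics = diagnostics,
                 config = config,
                 hp = hp,
                 likelihood_weight = likelihood_weight,
                 dataset = list(G = data$G, J = data$J, genes = data$genes,
                                excluded_genes = data$excluded_genes)),
            class = "cnv_posterior")
}

#' @export
print.cnv_posterior <- function(x, ...) {
  cat(sprintf("<cnv_posterior> %d draws x %d chains, %d genes\n",
              x$config$num_samples, x$config$num_chains, length(x$gene)))
  cat(sprintf("  accept %.2f | divergences %d | min ESS %.0f\n",
              x$diagnostics$mean_accept_prob, x$diagnostics$num_divergences,
              x$diagnostics$min_ess))
  invisible(x)
}

#' Convergence verdict for a sampler run
#'
#' Applies the standard HMC health checks: mean acceptance probability in a
#' reasonable band (0.6–0.9 by default), no divergent transitions (large
#' energy error between the start and end of a trajectory), a minimum
#' effective sample size, and, for multi-chain runs, split-R-hat below a
#' limit. The verdict annotates output but never blocks it.
#'
#' @param diag diagnostics from a [sample_posterior()] run
#'   (`$diagnostics`), or the `cnv_posterior` itself.
#' @param accept_range acceptable range of the mean acceptance probability.
#' @param ess_floor minimum acceptable effective sample size (default 400).
#' @param rhat_limit maximum acceptable split-R-hat (default 1.01).
#' @return A list with `verdict` (`"pass"` or `"warn"`) and `reasons`
#'   (character vector, empty on pass).
#' @export
check_convergence <- function(diag, accept_range = c(0.6, 0.9),
                              ess_floor = 400, rhat_limit = 1.01) {
  if (inherits(diag, "cnv_posterior")) diag <- diag$diagnostics
  reasons <- character()
  if (diag$mean_accept_prob < accept_range[1] ||
      diag$mean_accept_prob > accept_range[2])
    reasons <- c(reasons, sprintf(
      "mean acceptance probability %.3f outside [%g, %g]",
      diag$mean_accept_prob, accept_range[1], accept_range[2]))
  if (diag$num_divergences > 0)
    reasons <- c(reasons, sprintf("%d divergent transition(s)",
                                  diag$num_divergences))
  if (diag$min_ess < ess_floor)
    reasons <- c(reasons, sprintf("minimum ESS %.0f below floor %g",
                                  diag$min_ess, ess_floor))
  if (!is.na(diag$rhat_max) && diag$rhat_max > rhat_limit)
    reasons <- c(reasons, sprintf("max split-R-hat %.3f above %g",
                                  diag$rhat_max, rhat_limit))
  list(verdict = if (length(reasons) > 0) "warn" else "pass",
       reasons = reasons)
}

# circular autocovariance of one chain via FFT, lags 0..n-1 (biased)
autocov_fft <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  npad <- 2^ceiling(log2(2 * n))
  f <- fft(c(x, rep(0, npad - n)))
  Re(fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (npad * n)
}

#' Effective sample size of MCMC draws
#'
#' Multi-chain effective sample size for the mean, using the standard
#' between/within variance decomposition with Geyer's initial
#' monotone-positive-sequence truncation of the autocorrelation sum. For
#' independent draws the estimate is close to the number of draws.
#'
#' @param x numeric vector (one chain) or an iterations-by-chains matrix.
#' @return Estimated effective sample size (`NA` for constant input).
#' @export
mcmc_ess <- function(x) {
  mat <- as.matrix(x)
  N <- nrow(mat); M <- ncol(mat)
  if (N < 4) return(NA_real_)
  if (max(mat) - min(mat) < .Machine$double.xmin) return(NA_real_)
  acovs <- vapply(seq_len(M), function(j) autocov_fft(mat[, j]), numeric(N))
  acovs <- matrix(acovs, nrow = N)
  chain_mean_var <- mean(acovs[1, ]) * N / (N - 1)
  var_plus <- chain_mean_var * (N - 1) / N
  if (M > 1) var_plus <- var_plus + var(colMeans(mat))
  rho <- 1 - (chain_mean_var - rowMeans(acovs)) / var_plus
  # paired sums P_t = rho_{2t} + rho_{2t+1}; keep while positive, enforce
  # monotone non-increase (Geyer 1992)
  pair_sums <- numeric(0)
  t <- 1
  while (t + 1 <= N) {
    p <- rho[t] + rho[t + 1]
    if (!is.finite(p) || p <= 0) break
    pair_sums <- c(pair_sums, p)
    t <- t + 2
  }
  if (length(pair_sums) == 0) return(N * M)
  tau <- -1 + 2 * sum(cummin(pair_sums))
  tau <- max(tau, 1 / log10(N))
  N * M / tau
}

#' Split-R-hat of MCMC draws
#'
#' Classic potential-scale-reduction statistic computed on split chains
#' (each chain halved), so it detects non-stationarity even for a single
#' chain.
#'
#' @param x numeric vector (one chain) or an iterations-by-chains matrix.
#' @return Split-R-hat estimate.
#' @export
mcmc_rhat <- function(x) {
  mat <- as.matrix(x)
  half <- floor(nrow(mat) / 2)
  if (half < 2) return(NA_real_)
  sm <- cbind(mat[seq_len(half), , drop = FALSE],
              mat[(nrow(mat) - half + 1):nrow(mat), , drop = FALSE])
  n <- nrow(sm)
  s2 <- apply(sm, 2, var)
  W <- mean(s2)
  B_over_n <- var(colMeans(sm))
  if (W < .Machine$double.xmin) return(NA_real_)
  sqrt((n - 1) / n + B_over_n / W)
}

#' @export
tidy.cnv_posterior <- function(x, ...) {
  draws <- x$draws
  purrr::map(x$params, function(p) {
    v <- draws[[p]]
    tibble(parameter = p,
           mean = mean(v), sd = sd(v),
           q5 = unname(quantile(v, 0.05)),
           q95 = unname(quantile(v, 0.95)),
           ess = unname(x$diagnostics$ess[p]))
  }) |> purrr::list_rbind()
}

#' @export
glance.cnv_posterior <- function(x, ...) {
  tibble(num_samples = x$config$num_samples,
         num_chains = x$config$num_chains,
         mean_accept_prob = x$diagnostics$mean_accept_prob,
         num_divergences = x$diagnostics$num_divergences,
         min_ess = x$diagnostics$min_ess,
         rhat_max = x$diagnostics$rhat_max)
}
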