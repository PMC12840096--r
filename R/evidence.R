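#' Inverse-temperature ladder for thermodynamic integration
#'
#' \eqn{\beta_k = ((k-1)/(K-1))^{a}} for \eqn{k = 1, \dots, K}. The default
#' exponent 5 concentrates rungs near \eqn{\beta = 0}, where the expected
#' log likelihood varies fastest along the prior-to-posterior path.
#'
#' @param K number of rungs (default 20; must be >= 2).
#' @param exponent power-law spacing exponent (> 0; 1 gives a uniform grid).
#' @return Strictly increasing numeric vector from exactly 0 to exactly 1.
#' @examples
#' make_ladder(5, exponent = 5)
#' @export
make_ladder <- function(K = 20, exponent = 5) {
  if (K < 2) stop_input("`K` must be at least 2")
  if (exponent <= 0) stop_input("`exponent` must be > 0")
  ((seq_len(K) - 1) / (K - 1))^exponent
}

# run one power-posterior chain per rung (warm-started from the previous
# rung's final state) and summarize the log-likelihood draws
run_rungs <- function(model_name, model_data, ladder, config) {
  init <- NULL
  out <- vector("list", length(ladder))
  for (k in seq_along(ladder)) {
    res <- .nuts_run(model_name, model_data, ladder[k],
                     config$num_warmup, config$num_samples,
                     config$target_accept, config$max_treedepth,
                     config$seed + k, init)
    init <- res$last_state
    ll <- res$loglik
    s <- sd(ll)
    if (s < .Machine$double.xmin) {
      ess <- length(ll); se <- 0
    } else {
      ess <- mcmc_ess(ll)
      if (!is.finite(ess) || ess < 1) ess <- 1
      se <- s / sqrt(ess)
    }
    warn_msg <- character()
    if (res$divergences > 0)
      warn_msg <- c(warn_msg, sprintf("rung %d (beta=%.4g): %d divergence(s)",
                                      k, ladder[k], res$divergences))
    if (res$accept_mean < 0.5)
      warn_msg <- c(warn_msg, sprintf("rung %d (beta=%.4g): low acceptance %.2f",
                                      k, ladder[k], res$accept_mean))
    out[[k]] <- list(row = tibble(beta = ladder[k],
                                  mean_loglik = mean(ll),
                                  se = se, ess = ess,
                                  accept = res$accept_mean,
                                  divergences = res$divergences),
                     warnings = warn_msg)
  }
  list(rungs = purrr::list_rbind(purrr::map(out, "row")),
       warnings = unlist(purrr::map(out, "warnings")))
}

#' Per-temperature expected log likelihood along the power-posterior path
#'
#' For each rung \eqn{\beta_k}, samples the power posterior
#' \eqn{p_\beta(\theta \mid x) \propto p(x \mid \theta)^\beta p(\theta)} and
#' averages the (untempered) log likelihood over the draws,
#' \eqn{\hat\mu_{\beta_k} = N^{-1} \sum_i \log p(x \mid \theta^{(i)})}. At
#' \eqn{\beta = 0} this is the prior expectation of the log likelihood.
#' Rungs with sampler pathologies carry a warning but are never silently
#' dropped.
#'
#' @param data an `lcnr_dataset`.
#' @param hp model [hyperparameters()].
#' @param ladder a [make_ladder()] result.
#' @param config a [sampler_config()]; defaults to 500 warmup and 1000 kept
#'   draws per rung.
#' @return Tibble with one row per rung: `beta`, `mean_loglik`, `se` (MC
#'   standard error), `ess`, `accept`, `divergences`; rung warnings in
#'   attribute `"warnings"`.
#' @export
power_posterior_means <- function(data, hp = hyperparameters(),
                                  ladder = make_ladder(),
                                  config = NULL) {
  if (!inherits(data, "lcnr_dataset"))
    stop_input("`data` must be an `lcnr_dataset`")
  if (is.null(config))
    config <- sampler_config(num_warmup = 500, num_samples = 1000)
  if (is.unsorted(ladder, strictly = TRUE) ||
      ladder[1] != 0 || ladder[length(ladder)] != 1)
    stop_input("`ladder` must increase strictly from 0 to 1")
  res <- run_rungs("cnv", as_model_data(data, hp), ladder, config)
  structure(res$rungs, warnings = res$warnings)
}

#' Trapezoidal log-evidence estimate from per-temperature means
#'
#' Applies the trapezoidal rule to the thermodynamic-integration identity
#' \eqn{\log Z = \int_0^1 E_{\beta}[\log p(x \mid \theta)]\, d\beta}:
#' \deqn{\widehat{\log Z} = \sum_{k=1}^{K-1}
#'   \frac{\beta_{k+1} - \beta_k}{2}\,(\hat\mu_{\beta_k} +
#'   \hat\mu_{\beta_{k+1}}).}
#' The sum of adjacent means is the standard trapezoidal rule; it is the
#' form that satisfies the constant-integrand identity (a constant
#' \eqn{\hat\mu = c} yields \eqn{\log Z = c}).
#'
#' @param means per-rung expected log likelihoods \eqn{\hat\mu_{\beta_k}}.
#' @param ladder the matching inverse-temperature ladder.
#' @return The log-evidence estimate.
#' @examples
#' trapezoid_log_evidence(c(0, 0.5, 1), c(0, 0.5, 1)) # 0.5
#' @export
trapezoid_log_evidence <- function(means, ladder) {
  if (length(means) != length(ladder))
    stop_input("`means` and `ladder` must have one value per rung")
  if (length(ladder) < 2) stop_input("need at least 2 rungs")
  K <- length(ladder)
  sum(diff(ladder) / 2 * (means[-K] + means[-1]))
}

# trapezoid weights w_k such that logZ = sum_k w_k * mu_k
trapezoid_weights <- function(ladder) {
  K <- length(ladder)
  d <- diff(ladder)
  w <- numeric(K)
  w[1] <- d[1] / 2
  w[K] <- d[K - 1] / 2
  if (K > 2) w[2:(K - 1)] <- (d[-1] + d[-(K - 1)]) / 2
  w
}

finish_evidence <- function(rungs, ladder, warnings, qc_threshold, model) {
  log_z <- trapezoid_log_evidence(rungs$mean_loglik, ladder)
  w <- trapezoid_weights(ladder)
  se <- sqrt(sum(w^2 * rungs$se^2))
  # the TI integrand is d/dbeta E_beta[log p] = Var_beta[log p] >= 0, so the
  # rung means must be non-decreasing up to Monte-Carlo error
  dmu <- diff(rungs$mean_loglik)
  dse <- sqrt(rungs$se[-nrow(rungs)]^2 + rungs$se[-1]^2)
  monotone_ok <- all(dmu >= -3 * dse - 1e-9)
  if (!monotone_ok)
    warnings <- c(warnings,
                  "per-temperature means decrease beyond 3 SE; estimate suspect")
  qc <- qc_evaluate(log_z, qc_threshold)
  structure(list(log_evidence = log_z, se = se,
                 rungs = rungs, ladder = ladder, K = length(ladder),
                 qc_threshold = qc_threshold, qc_verdict = qc$verdict,
                 monotone_ok = monotone_ok,
                 warnings = warnings, model = model),
            class = "evidence_estimate")
}

#' Marginal likelihood by thermodynamic integration
#'
#' Estimates the log evidence \eqn{\log Z = \log \int p(x \mid \theta)
#' p(\theta)\, d\theta} of a sample under the hierarchical model by
#' integrating the expected log likelihood over the power-posterior path
#' (see [power_posterior_means()] and [trapezoid_log_evidence()]).
#' Dramatically low evidence flags model–data mismatch: degraded input
#' material, a mismatched reference, or assay artifacts.
#'
#' @inheritParams power_posterior_means
#' @param K number of ladder rungs (default 20).
#' @param exponent ladder spacing exponent (default 5).
#' @param qc_threshold optional panel-specific QC threshold on the log
#'   evidence; there is no universal default, so `NULL` leaves the verdict
#'   `"not evaluated"`.
#' @return An object of class `evidence_estimate`: `log_evidence`, combined
#'   MC standard error `se`, per-rung table `rungs`, the ladder, QC verdict,
#'   and any rung warnings.
#' @export
ti_log_evidence <- function(data, hp = hyperparameters(), config = NULL,
                            K = 20, exponent = 5, qc_threshold = NULL) {
  ladder <- make_ladder(K, exponent)
  rungs <- power_posterior_means(data, hp, ladder, config)
  finish_evidence(rungs, ladder, attr(rungs, "warnings"), qc_threshold, "cnv")
}

#' Thermodynamic integration on the conjugate normal-normal model
#'
#' Runs the identical TI machinery on a model with an analytic answer:
#' \eqn{\theta \sim N(0, v_0)}, \eqn{x_j \mid \theta \sim N(\theta, v)},
#' whose evidence is available in closed form. Used to validate the
#' estimator (the whole sampling and integration path) against an exact
#' value.
#'
#' @param x numeric vector of observations.
#' @param prior_var prior variance \eqn{v_0}.
#' @param lik_var likelihood variance \eqn{v}.
#' @inheritParams ti_log_evidence
#' @return An `evidence_estimate` (with `model = "normal"`).
#' @export
ti_log_evidence_normal <- function(x, prior_var = 1, lik_var = 1,
                                   config = NULL, K = 20, exponent = 5) {
  if (is.null(config))
    config <- sampler_config(num_warmup = 500, num_samples = 1000)
  ladder <- make_ladder(K, exponent)
  md <- list(x = as.numeric(x), prior_var = prior_var, lik_var = lik_var)
  res <- run_rungs("normal", md, ladder, config)
  finish_evidence(res$rungs, ladder, res$warnings, NULL, "normal")
}

#' Harmonic-mean log-evidence estimate (unreliable; comparison only)
#'
#' \eqn{\hat Z_{HME} = (N^{-1} \sum_i p(x \mid \theta^{(i)})^{-1})^{-1}}
#' over posterior draws, computed stably via log-sum-exp. The harmonic-mean
#' estimator is dominated by rare low-likelihood draws and can have infinite
#' variance; it is provided only as a baseline to compare against
#' thermodynamic integration and should not be used for QC decisions.
#'
#' @param samples a `cnv_posterior` (per-draw log likelihoods are stored),
#'   or a numeric vector of per-draw log likelihoods.
#' @return A list of class `hme_estimate` with `log_evidence`, `n_draws`,
#'   and a `note` flagging the estimator as unreliable.
#' @export
harmonic_mean_log_evidence <- function(samples) {
  ll <- if (inherits(samples, "cnv_posterior")) samples$loglik
        else as.numeric(samples)
  if (length(ll) == 0) stop_input("no log-likelihood draws supplied")
  log_z <- -(logsumexp(-ll) - log(length(ll)))
  structure(list(log_evidence = log_z, n_draws = length(ll),
                 note = "unreliable estimator, for comparison only"),
            class = "hme_estimate")
}

#' @export
print.hme_estimate <- function(x, ...) {
  cat(sprintf("Harmonic-mean log evidence: %.3f (%d draws)\n  [%s]\n",
              x$log_evidence, x$n_draws, x$note))
  invisible(x)
}

#' Evidence-based sample quality control
#'
#' A sample fails QC iff its log evidence falls strictly below the
#' threshold (a value exactly at the threshold passes). The threshold is
#' panel-specific configuration — it depends on panel size and data scale —
#' so no universal default is shipped; with `threshold = NULL` the verdict
#' is `"not evaluated"`.
#'
#' @param estimate an `evidence_estimate` or a numeric log evidence.
#' @param threshold numeric QC threshold, or `NULL`.
#' @return A list with `verdict` (`"pass"`, `"fail"`, or
#'   `"not evaluated"`), `threshold`, and `log_evidence`.
#' @export
qc_evaluate <- function(estimate, threshold = NULL) {
  log_z <- if (inherits(estimate, "evidence_estimate")) estimate$log_evidence
           else as.numeric(estimate)
  verdict <- if (is.null(threshold)) "not evaluated"
             else if (log_z < threshold) "fail" else "pass"
  list(verdict = verdict, threshold = threshold, log_evidence = log_z)
}

#' @export
print.evidence_estimate <- function(x, ...) {
  cat(sprintf("<evidence_estimate> log Z = %.3f (MC se %.3f), K = %d rungs\n",
              x$log_evidence, x$se, x$K))
  cat(sprintf("  QC: %s%s\n", x$qc_verdict,
              if (is.null(x$qc_threshold)) ""
              else sprintf(" (threshold %g)", x$qc_threshold)))
  if (length(x$warnings) > 0)
    cat("  warnings:\n", paste0("   - ", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
tidy.evidence_estimate <- function(x, ...) x$rungs

#' @export
glance.evidence_estimate <- function(x, ...) {
  tibble(log_evidence = x$log_evidence, se = x$se, K = x$K,
         monotone_ok = x$monotone_ok,
         qc_verdict = x$qc_verdict,
         qc_threshold = if (is.null(x$qc_threshold)) NA_real_ else x$qc_threshold)
}
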