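#' Calling configuration
#'
#' Two criteria turn posterior samples into a CNV call for gene \eqn{g}:
#' \describe{
#'   \item{Effect size}{the posterior mean of \eqn{\mu_g} must exceed
#'     \eqn{\log T} (gains) or fall below \eqn{-\log T} (losses), where
#'     \eqn{T} is the copy ratio to be detected.}
#'   \item{Confidence}{the posterior probability of the neutral band,
#'     \eqn{\Pr(|\mu_g| < \delta)}, must be below \eqn{\epsilon}.}
#' }
#'
#' @param ratio_threshold copy-ratio call threshold \eqn{T > 1}
#'   (default 1.5, i.e. three copies against a diploid baseline).
#' @param neutral_band half-width \eqn{\delta \ge 0} of the neutral lCNR
#'   band (default 0.1, roughly a ±10% copy-ratio band).
#' @param confidence_epsilon tolerated neutral-band probability
#'   \eqn{\epsilon > 0} (default 0.05). Values below 1 are meaningful;
#'   \eqn{\epsilon > 1} disables the confidence criterion.
#' @param call_losses also call deletions, using the symmetric threshold
#'   \eqn{-\log T} (default TRUE). Loss calling is less validated than gain
#'   calling in amplicon liquid-biopsy assays.
#' @param ci_level credible-interval level for reporting (default 0.9).
#' @return An object of class `call_config`.
#' @export
call_config <- function(ratio_threshold = 1.5, neutral_band = 0.1,
                        confidence_epsilon = 0.05, call_losses = TRUE,
                        ci_level = 0.9) {
  if (ratio_threshold <= 1) stop_input("`ratio_threshold` must be > 1")
  if (neutral_band < 0) stop_input("`neutral_band` must be >= 0")
  if (confidence_epsilon <= 0) stop_input("`confidence_epsilon` must be > 0")
  if (ci_level <= 0 || ci_level >= 1) stop_input("`ci_level` must be in (0, 1)")
  structure(list(ratio_threshold = ratio_threshold,
                 neutral_band = neutral_band,
                 confidence_epsilon = confidence_epsilon,
                 call_losses = isTRUE(call_losses),
                 ci_level = ci_level),
            class = c("call_config", "list"))
}

#' Posterior summary of one gene's lCNR draws
#'
#' @param draws numeric vector of posterior draws of \eqn{\mu_g}
#'   (at least 100).
#' @param delta neutral-band half-width \eqn{\delta}.
#' @param ci_level central credible-interval level (default 0.9).
#' @return One-row tibble: `mean`, `ci_low`, `ci_high`, `p_neutral`
#'   (fraction of draws with \eqn{|\mu_g| < \delta}).
#' @export
summarize_gene <- function(draws, delta = 0.1, ci_level = 0.9) {
  if (length(draws) < 100)
    stop_input("at least 100 posterior draws are required to summarize a gene")
  a <- (1 - ci_level) / 2
  qs <- quantile(draws, c(a, 1 - a), names = FALSE)
  tibble(mean = mean(draws), ci_low = qs[1], ci_high = qs[2],
         p_neutral = mean(abs(draws) < delta))
}

#' Call copy-number variants from posterior samples
#'
#' Applies the effect-size and confidence criteria (see [call_config()]) to
#' the marginal posterior of each gene-level lCNR. Genes excluded during
#' preprocessing appear as `"no-call"` rows with the exclusion reason.
#' Copy ratio is `exp(mean)`; absolute copies assume a diploid baseline
#' (`2 * exp(mean)`).
#'
#' @param samples a `cnv_posterior` from [sample_posterior()].
#' @param config a [call_config()].
#' @return A tibble of class `cnv_calls` with columns `gene`,
#'   `n_amplicons`, `mean_lcnr`, `ci_low`, `ci_high`, `p_neutral`,
#'   `copy_ratio`, `est_copies`, `call`, `note`. The configuration and
#'   sampler diagnostics travel along as attributes.
#' @examples
#' sim <- simulate_sample(simulation_config(seed = 1))
#' post <- sample_posterior(prepare_dataset(sim$counts),
#'   config = sampler_config(num_warmup = 200, num_samples = 300, seed = 1))
#' call_genes(post)
#' @export
call_genes <- function(samples, config = call_config()) {
  if (!inherits(samples, "cnv_posterior"))
    stop_input("`samples` must be a `cnv_posterior` from sample_posterior()")
  log_T <- log(config$ratio_threshold)

  rows <- purrr::map(seq_along(samples$gene), function(i) {
    g <- samples$gene[i]
    d <- samples$draws[[paste0("mu[", g, "]")]]
    s <- summarize_gene(d, delta = config$neutral_band,
                        ci_level = config$ci_level)
    confident <- s$p_neutral < config$confidence_epsilon
    call <- if (s$mean > log_T && confident) {
      "amplification"
    } else if (config$call_losses && s$mean < -log_T && confident) {
      "deletion"
    } else {
      "neutral"
    }
    tibble(gene = g,
           n_amplicons = samples$dataset$genes$n_amplicons[
             samples$dataset$genes$gene == g],
           mean_lcnr = s$mean, ci_low = s$ci_low, ci_high = s$ci_high,
           p_neutral = s$p_neutral,
           copy_ratio = exp(s$mean), est_copies = 2 * exp(s$mean),
           call = call, note = NA_character_)
  }) |> purrr::list_rbind()

  excl <- samples$dataset$excluded_genes
  if (!is.null(excl) && nrow(excl) > 0) {
    rows <- dplyr::bind_rows(
      rows,
      tibble(gene = excl$gene, n_amplicons = excl$n_amplicons,
             mean_lcnr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             p_neutral = NA_real_, copy_ratio = NA_real_,
             est_copies = NA_real_, call = "no-call",
             note = excl$reason))
  }
  rows <- dplyr::arrange(rows, .data$gene)
  structure(rows,
            class = c("cnv_calls", class(tibble())),
            call_config = config,
            diagnostics = samples$diagnostics)
}

#' @export
tidy.cnv_calls <- function(x, ...) as_tibble(x)

#' @export
glance.cnv_calls <- function(x, ...) {
  cfg <- attr(x, "call_config")
  tibble(n_genes = nrow(x),
         n_amplifications = sum(x$call == "amplification"),
         n_deletions = sum(x$call == "deletion"),
         n_no_call = sum(x$call == "no-call"),
         ratio_threshold = cfg$ratio_threshold,
         neutral_band = cfg$neutral_band,
         confidence_epsilon = cfg$confidence_epsilon)
}
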