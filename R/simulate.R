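#' Gene layout for a simulated amplicon panel
#'
#' Convenience constructor for the `genes` table of a
#' [simulation_config()]: `n_genes` genes with `amplicons_per_gene`
#' amplicons each, all copy-neutral except the optional `cnv_genes`, set to
#' `cnv_ratio`. The default layout (10 genes, 40 amplicons each) mirrors the
#' scale of a targeted liquid-biopsy panel with a few hundred amplicons
#' across ten CNV genes.
#'
#' @param n_genes number of genes.
#' @param amplicons_per_gene amplicons targeting each gene.
#' @param cnv_genes character vector (or indices) of genes carrying a CNV.
#' @param cnv_ratio true copy ratio of the CNV genes.
#' @return Tibble `gene`, `n_amplicons`, `copy_ratio`.
#' @export
panel_genes <- function(n_genes = 10, amplicons_per_gene = 40,
                        cnv_genes = NULL, cnv_ratio = 2) {
  genes <- tibble(gene = sprintf("GENE%02d", seq_len(n_genes)),
                  n_amplicons = as.integer(amplicons_per_gene),
                  copy_ratio = 1)
  if (!is.null(cnv_genes)) {
    if (is.numeric(cnv_genes)) cnv_genes <- genes$gene[cnv_genes]
    genes$copy_ratio[genes$gene %in% cnv_genes] <- cnv_ratio
  }
  genes
}

#' Configuration of the synthetic amplicon-panel simulator
#'
#' The simulator emulates the generative structure of a targeted amplicon
#' assay: amplicon-specific amplification efficiencies (stable between the
#' case and its process-matched normal), overall sequencing depth, gene-level
#' copy-ratio shifts that scale expected counts linearly, heavy-tailed
#' per-amplicon noise on the log scale, and amplicon dropout.
#'
#' @param genes tibble `gene`, `n_amplicons`, `copy_ratio` (see
#'   [panel_genes()]).
#' @param depth expected reads per amplicon at unit efficiency
#'   (default 2000).
#' @param efficiency_sd log-scale standard deviation of the lognormal
#'   amplicon efficiencies (default 0.5, a typical several-fold spread
#'   across a panel).
#' @param noise_scale SoftLaplace scale of the per-amplicon lCNR noise in
#'   the case sample (default 0.1).
#' @param dropout_prob probability that an amplicon independently fails to
#'   amplify in the case sample (count set to 0; default 0).
#' @param count_model `"poisson"` (counts Poisson around the scaled
#'   expectation, default) or `"deterministic"` (rounded expectation, for
#'   exact unit tests).
#' @param seed integer seed; fixed seed gives identical tables.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(genes = panel_genes(), depth = 2000,
                              efficiency_sd = 0.5, noise_scale = 0.1,
                              dropout_prob = 0,
                              count_model = c("poisson", "deterministic"),
                              seed = 1) {
  count_model <- match.arg(count_model)
  if (any(genes$copy_ratio <= 0)) stop_input("copy ratios must be > 0")
  if (depth <= 0) stop_input("`depth` must be > 0")
  if (efficiency_sd < 0 || noise_scale < 0)
    stop_input("`efficiency_sd` and `noise_scale` must be >= 0")
  if (dropout_prob < 0 || dropout_prob > 1)
    stop_input("`dropout_prob` must lie in [0, 1]")
  structure(list(genes = as_tibble(genes), depth = depth,
                 efficiency_sd = efficiency_sd, noise_scale = noise_scale,
                 dropout_prob = dropout_prob, count_model = count_model,
                 seed = as.integer(seed)),
            class = c("simulation_config", "list"))
}

#' Simulate one case/normal amplicon count pair with known truth
#'
#' For amplicon \eqn{j} with lognormal efficiency \eqn{e_j}
#' (\eqn{\log e_j \sim N(0, \text{efficiency\_sd}^2)}):
#' normal expectation \eqn{d\, e_j}, case expectation
#' \eqn{d\, e_j\, r_{g(j)}\, e^{\eta_j}} with copy ratio \eqn{r_g} and
#' heavy-tailed log-scale noise \eqn{\eta_j \sim
#' \mathrm{SoftLaplace}(0, \text{noise\_scale})}. Counts are Poisson draws
#' around (or rounds of) the expectation; dropout independently zeroes each
#' amplicon's case count with probability `dropout_prob` (the amplicon fails
#' to amplify in the sample). Reproducible under a fixed seed; the caller's
#' RNG state is left untouched.
#'
#' @param config a [simulation_config()].
#' @param efficiencies optional numeric vector of amplicon efficiencies to
#'   reuse across samples (e.g. within a dilution-series replicate); drawn
#'   fresh when `NULL`.
#' @return An object of class `simulated_sample`: `counts` (tibble
#'   `amplicon_id`, `gene`, `case_count`, `normal_count`), `truth` (tibble
#'   `gene`, `copy_ratio`), and the `config`.
#' @examples
#' sim <- simulate_sample(simulation_config(
#'   genes = panel_genes(cnv_genes = "GENE01", cnv_ratio = 2), seed = 7))
#' head(sim$counts)
#' @export
simulate_sample <- function(config, efficiencies = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  g <- config$genes
  gene <- rep(g$gene, g$n_amplicons)
  ratio <- rep(g$copy_ratio, g$n_amplicons)
  J <- length(gene)
  amp <- paste0(gene, "_amp",
                unlist(lapply(g$n_amplicons, function(n)
                  sprintf("%03d", seq_len(n)))))

  with_seed(config$seed, {
    e <- if (is.null(efficiencies)) {
      exp(rnorm(J, 0, config$efficiency_sd))
    } else {
      if (length(efficiencies) != J)
        stop_input("`efficiencies` must have one value per amplicon")
      efficiencies
    }
    eta <- if (config$noise_scale > 0) {
      rsoftlaplace(J, 0, config$noise_scale)
    } else {
      numeric(J)
    }
    lam_normal <- config$depth * e
    if (config$count_model == "poisson") {
      normal_count <- rpois(J, lam_normal)
      case_count <- rpois(J, lam_normal * ratio * exp(eta))
    } else {
      # deterministic mode scales the realized normal counts so that, e.g.,
      # a ratio-2 gene has exactly doubled counts
      normal_count <- round(lam_normal)
      case_count <- round(normal_count * ratio * exp(eta))
    }
    if (config$dropout_prob > 0) {
      case_count[runif(J) < config$dropout_prob] <- 0L
    }
    structure(list(counts = tibble(amplicon_id = amp, gene = gene,
                                   case_count = as.integer(case_count),
                                   normal_count = as.integer(normal_count)),
                   truth = tibble(gene = g$gene, copy_ratio = g$copy_ratio),
                   config = config),
              class = "simulated_sample")
  })
}

#' @export
print.simulated_sample <- function(x, ...) {
  cat(sprintf("<simulated_sample> %d amplicons, %d genes (%d with CNV), depth %g\n",
              nrow(x$counts), nrow(x$truth), sum(x$truth$copy_ratio != 1),
              x$config$depth))
  invisible(x)
}

#' In-silico dilution series for limit-of-detection studies
#'
#' Re-creates a dilution experiment on fully synthetic data: for each target
#' copy ratio and replicate, one sample is generated with the designated CNV
#' genes set to the target ratio and all other genes neutral. Within a
#' replicate, all ratios share one amplicon efficiency profile, emulating
#' in-silico scaling of the same underlying sample.
#'
#' @param base_config a [simulation_config()]; its gene table defines the
#'   panel layout.
#' @param target_ratios copy ratios to titrate (all >= 1).
#' @param replicates samples per ratio (default 1).
#' @param cnv_genes genes carrying the titrated CNV; defaults to the genes
#'   with `copy_ratio > 1` in `base_config`, or the first gene if none.
#' @return List of `simulated_sample` objects, each with added fields
#'   `target_ratio` and `replicate`.
#' @export
dilution_series <- function(base_config, target_ratios, replicates = 1,
                            cnv_genes = NULL) {
  stopifnot(inherits(base_config, "simulation_config"))
  if (any(target_ratios < 1))
    stop_input("`target_ratios` must all be >= 1")
  g <- base_config$genes
  if (is.null(cnv_genes)) {
    cnv_genes <- g$gene[g$copy_ratio > 1]
    if (length(cnv_genes) == 0) cnv_genes <- g$gene[1]
  }
  J <- sum(g$n_amplicons)
  out <- list()
  for (rep_i in seq_len(replicates)) {
    e <- with_seed(base_config$seed + 1000L * rep_i,
                   exp(rnorm(J, 0, base_config$efficiency_sd)))
    for (ri in seq_along(target_ratios)) {
      cfg <- base_config
      cfg$genes$copy_ratio <- ifelse(cfg$genes$gene %in% cnv_genes,
                                     target_ratios[ri], 1)
      cfg$seed <- base_config$seed + 1000L * rep_i + ri
      sim <- simulate_sample(cfg, efficiencies = e)
      sim$target_ratio <- target_ratios[ri]
      sim$replicate <- rep_i
      out[[length(out) + 1]] <- sim
    }
  }
  out
}

#' Simulate a degraded (high-noise, high-dropout) sample
#'
#' Emulates poor-quality input material such as heavily damaged FFPE
#' templates, which amplify poorly and erratically: per-amplicon lCNR noise
#' is inflated by `noise_multiplier` and amplicons drop out with probability
#' `dropout_prob`.
#'
#' @param config a [simulation_config()] describing the clean regime.
#' @param noise_multiplier factor (>= 1) applied to `noise_scale`.
#' @param dropout_prob per-amplicon case-channel dropout probability.
#' @return A `simulated_sample`.
#' @export
degraded_sample <- function(config, noise_multiplier = 10,
                            dropout_prob = 0.2) {
  stopifnot(inherits(config, "simulation_config"))
  if (noise_multiplier < 1) stop_input("`noise_multiplier` must be >= 1")
  cfg <- config
  cfg$noise_scale <- cfg$noise_scale * noise_multiplier
  cfg$dropout_prob <- dropout_prob
  simulate_sample(cfg)
}

#' End-to-end limit-of-detection study
#'
#' Runs the full pipeline (preprocess, posterior sampling, calling) over a
#' [dilution_series()] and reports, per sample and titrated gene, the
#' posterior summary and whether the CNV was detected. The realized noise
#' level is echoed per sample as `neutral_scale_hat`, a SoftLaplace-scale
#' estimate from the CNV-neutral genes' centered lCNR spread
#' (\eqn{\hat s = \mathrm{sd}/(\pi/2)}), mirroring calibration against
#' empirically neutral genes.
#'
#' @inheritParams dilution_series
#' @param hp model [hyperparameters()].
#' @param sampler a [sampler_config()]; the default uses a reduced draw
#'   budget suited to running many samples.
#' @param call_cfg a [call_config()].
#' @return Tibble with one row per (ratio, replicate, CNV gene):
#'   `target_ratio`, `replicate`, `gene`, `mean_lcnr`, `copy_ratio`,
#'   `ci_low`, `ci_high`, `call`, `detected`, `neutral_scale_hat`, plus
#'   `n_false_calls` (non-titrated genes called in that sample).
#' @export
lod_study <- function(base_config, target_ratios, replicates = 1,
                      cnv_genes = NULL, hp = hyperparameters(),
                      sampler = sampler_config(num_warmup = 300,
                                               num_samples = 600),
                      call_cfg = call_config()) {
  sims <- dilution_series(base_config, target_ratios, replicates, cnv_genes)
  if (is.null(cnv_genes)) {
    g <- base_config$genes
    cnv_genes <- g$gene[g$copy_ratio > 1]
    if (length(cnv_genes) == 0) cnv_genes <- g$gene[1]
  }
  purrr::map(sims, function(sim) {
    ds <- prepare_dataset(sim$counts)
    scfg <- sampler
    scfg$seed <- sampler$seed + 13L * (sim$replicate * 101L) +
      match(sim$target_ratio, target_ratios)
    post <- sample_posterior(ds, hp = hp, config = scfg)
    calls <- call_genes(post, call_cfg)
    neutral <- ds$data |> dplyr::filter(!(.data$gene %in% cnv_genes))
    scale_hat <- sd(neutral$lcnr) / (pi / 2)
    calls |>
      dplyr::filter(.data$gene %in% cnv_genes) |>
      dplyr::transmute(target_ratio = sim$target_ratio,
                       replicate = sim$replicate,
                       gene = .data$gene,
                       mean_lcnr = .data$mean_lcnr,
                       copy_ratio = .data$copy_ratio,
                       ci_low = .data$ci_low, ci_high = .data$ci_high,
                       call = .data$call,
                       detected = .data$call == "amplification",
                       neutral_scale_hat = scale_hat,
                       n_false_calls = sum(calls$call != "neutral" &
                                             !(calls$gene %in% cnv_genes)))
  }) |> purrr::list_rbind()
}
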