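# fixtures built in code; no data files

# small deterministic count table
tiny_counts <- function() {
  tibble::tibble(
    amplicon_id = sprintf("amp%02d", 1:9),
    gene = rep(c("A", "B", "C"), each = 3),
    case_count = c(100L, 110L, 90L, 200L, 220L, 180L, 100L, 100L, 100L),
    normal_count = c(100L, 100L, 100L, 100L, 100L, 100L, 100L, 100L, 100L)
  )
}

# assemble an lcnr_dataset directly from centered values, bypassing the
# count pipeline, for tests that specify x_ig on the lCNR scale
make_lcnr_dataset <- function(x, gene) {
  stopifnot(length(x) == length(gene))
  genes <- tibble::tibble(gene = sort(unique(gene))) |>
    dplyr::mutate(gene_index = dplyr::row_number())
  data <- tibble::tibble(
    amplicon_id = sprintf("amp%04d", seq_along(x)),
    gene = gene, lcnr = x) |>
    dplyr::left_join(genes, by = "gene") |>
    dplyr::select(amplicon_id, gene, gene_index, lcnr)
  counts <- genes |>
    dplyr::left_join(dplyr::count(data, gene, name = "n_amplicons"), by = "gene")
  structure(list(
    data = data,
    genes = tibble::tibble(gene_index = genes$gene_index, gene = genes$gene,
                           n_amplicons = counts$n_amplicons),
    excluded_genes = tibble::tibble(gene = character(), n_amplicons = integer(),
                                    reason = character()),
    filtered = tibble::tibble(amplicon_id = character(), gene = character(),
                              reason = character()),
    G = nrow(genes), J = length(x),
    reference = "explicit-normal", min_count = 1),
    class = "lcnr_dataset")
}

# minimal cnv_posterior carrying prescribed mu_g draws, for calling-rule tests
fake_posterior <- function(mu_draws, excluded = NULL) {
  genes <- names(mu_draws)
  n <- length(mu_draws[[1]])
  draws <- tibble::as_tibble(
    stats::setNames(as.data.frame(mu_draws, check.names = FALSE),
                    paste0("mu[", genes, "]")))
  draws <- dplyr::bind_cols(tibble::tibble(.chain = 1L, .draw = seq_len(n)), draws)
  gene_tab <- tibble::tibble(gene_index = seq_along(genes), gene = genes,
                             n_amplicons = 10L)
  excl <- excluded %||%
    tibble::tibble(gene = character(), n_amplicons = integer(),
                   reason = character())
  structure(list(
    draws = draws, params = paste0("mu[", genes, "]"), gene = genes,
    loglik = rep(0, n),
    diagnostics = structure(list(mean_accept_prob = 0.8, num_divergences = 0L,
                                 min_ess = n, rhat_max = NA_real_,
                                 ess = stats::setNames(rep(n, length(genes)),
                                                       paste0("mu[", genes, "]"))),
                            class = c("cnv_diagnostics", "list")),
    config = sampler_config(num_warmup = 0, num_samples = n, seed = 1),
    hp = hyperparameters(), likelihood_weight = 1,
    dataset = list(G = length(genes), J = 10L * length(genes),
                   genes = gene_tab, excluded_genes = excl)),
    class = "cnv_posterior")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# study-condition panel: 10 genes x 40 amplicons, one gene at copy ratio 2,
# depth 2000, SoftLaplace lCNR noise 0.1
study_panel_config <- function(seed, cnv_gene = "GENE03", cnv_ratio = 2,
                               noise_scale = 0.1) {
  simulation_config(
    genes = panel_genes(10, 40, cnv_genes = cnv_gene, cnv_ratio = cnv_ratio),
    depth = 2000, noise_scale = noise_scale, seed = seed)
}

# shared 20-replicate recovery/calling study, computed once per test session
recovery_study_cache <- new.env(parent = emptyenv())
recovery_study <- function() {
  if (!is.null(recovery_study_cache$result)) return(recovery_study_cache$result)
  out <- purrr::map(1:20, function(r) {
    sim <- simulate_sample(study_panel_config(seed = 5000 + r))
    ds <- prepare_dataset(sim$counts)
    # the model estimates lCNR relative to the panel median (the centering
    # convention), so the simulation truth on the estimand scale is
    # log r_g minus the realized median of the raw log ratios
    med_off <- median(log(sim$counts$case_count / sim$counts$normal_count))
    post <- sample_posterior(ds, config = sampler_config(
      num_warmup = 500, num_samples = 2500, seed = r))
    calls <- call_genes(post)
    calls$nominal_lcnr <- ifelse(calls$gene == "GENE03", log(2), 0)
    calls$true_lcnr <- calls$nominal_lcnr - med_off
    calls$replicate <- r
    calls
  }) |> purrr::list_rbind()
  recovery_study_cache$result <- out
  out
}

# shared clean-vs-degraded evidence study (10 + 10 samples), cached;
# reduced per-rung budget keeps many-sample studies tractable
evidence_study_cache <- new.env(parent = emptyenv())
evidence_study <- function() {
  if (!is.null(evidence_study_cache$result)) return(evidence_study_cache$result)
  ev_cfg <- function(seed) sampler_config(num_warmup = 250, num_samples = 500,
                                          seed = seed)
  run_one <- function(sim, seed) {
    ds <- suppressWarnings(prepare_dataset(sim$counts))
    ti_log_evidence(ds, config = ev_cfg(seed), K = 12)
  }
  clean <- purrr::map(1:10, function(i) {
    run_one(simulate_sample(simulation_config(genes = panel_genes(10, 40),
                                              seed = 7000 + i)), 100 + i)
  })
  degraded <- purrr::map(1:10, function(i) {
    cfg <- simulation_config(genes = panel_genes(10, 40), seed = 7100 + i)
    run_one(degraded_sample(cfg, noise_multiplier = 10, dropout_prob = 0.2),
            200 + i)
  })
  evidence_study_cache$result <- list(clean = clean, degraded = degraded)
  evidence_study_cache$result
}
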