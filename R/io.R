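#' Read a per-amplicon count table
#'
#' Expects a TSV with a header and columns `amplicon_id`, `gene` (optional
#' when a manifest supplies gene assignments), `case_count` and, for
#' explicit-normal mode, `normal_count`; batch-mode tables may carry a
#' single `count` column instead.
#'
#' @param path TSV file path.
#' @return Tibble of counts.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop_input(paste0("count file not found: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(tab)
  if (nrow(probs) > 0)
    stop_input(sprintf("malformed count TSV %s (first problem at line %d: %s)",
                       path, probs$row[1], probs$expected[1]))
  if (!"amplicon_id" %in% names(tab))
    stop_input(sprintf("%s: missing required column `amplicon_id`", path))
  if (!any(c("case_count", "count") %in% names(tab)))
    stop_input(sprintf("%s: missing count column (`case_count` or `count`)", path))
  tab
}

#' Read an amplicon manifest (BED or TSV)
#'
#' Two formats are accepted. A headered TSV with columns `amplicon_id` and
#' `gene`; or a BED-derived file (no header, 0-based half-open coordinates)
#' with columns chrom, start, end, name, gene — the `name` field is the
#' amplicon identifier. Strand, if present, is ignored (counts are
#' strand-collapsed).
#'
#' @param path manifest file path.
#' @return Tibble with at least `amplicon_id` and `gene` (plus coordinate
#'   columns for BED input).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_input(paste0("manifest not found: ", path))
  first <- readLines(path, n = 1)
  if (grepl("amplicon_id", first, fixed = TRUE)) {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("amplicon_id", "gene") %in% names(tab)))
      stop_input(sprintf("%s: manifest TSV needs `amplicon_id` and `gene`", path))
    return(tab)
  }
  tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(tab) < 5)
    stop_input(sprintf(
      "%s: BED manifest needs 5+ columns (chrom, start, end, name, gene)", path))
  tibble(chrom = as.character(tab[[1]]), start = as.integer(tab[[2]]),
         end = as.integer(tab[[3]]), amplicon_id = as.character(tab[[4]]),
         gene = as.character(tab[[5]]))
}

#' @rdname read_count_table
#' @param counts count tibble to write.
#' @export
write_count_table <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

# fixed-format numeric rendering so reruns produce byte-identical files
format_fixed <- function(df, digits = 6) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      df[[nm]] <- ifelse(is.na(df[[nm]]), NA_character_,
                         sprintf(paste0("%.", digits, "f"), df[[nm]]))
    }
  }
  df
}

write_atomic_tsv <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  readr::write_tsv(df, tmp, na = "NA")
  file.rename(tmp, path)
  invisible(path)
}

#' Write the gene-level call report as TSV
#'
#' Numeric columns are written with fixed 6-decimal formatting so that
#' reruns with identical inputs and seed produce byte-identical files.
#'
#' @param calls a `cnv_calls` tibble.
#' @param path output TSV path.
#' @export
write_gene_calls <- function(calls, path) {
  write_atomic_tsv(format_fixed(as_tibble(calls)), path)
}

#' Write the filtered-amplicon log as TSV
#'
#' @param filtered tibble `amplicon_id`, `gene`, `reason`.
#' @param path output TSV path.
#' @export
write_filtered_amplicons <- function(filtered, path) {
  write_atomic_tsv(filtered, path)
}

#' Write a JSON run report
#'
#' @param report a named list (see [run_call()]).
#' @param path output JSON path.
#' @export
write_run_report <- function(report, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Validate a run report against the shipped schema
#'
#' Structural validation of the JSON run report: every property the shipped
#' schema (`inst/schema/run_report.schema.json`) marks as required must be
#' present with the declared JSON type.
#'
#' @param report a report list, or a path to a report JSON file.
#' @param schema_path alternative schema file.
#' @return `TRUE` invisibly; aborts with the offending property otherwise.
#' @export
validate_run_report <- function(report,
                                schema_path = system.file(
                                  "schema", "run_report.schema.json",
                                  package = "ampcnv")) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(schema_path)
  check_node <- function(node, sch, where) {
    req <- unlist(sch$required)
    for (p in req) {
      if (is.null(node[[p]]))
        stop_input(sprintf("run report is missing required field `%s%s`",
                           where, p))
      decl <- sch$properties[[p]]$type
      if (!is.null(decl)) {
        ok <- switch(decl,
                     string = is.character(node[[p]]) ||
                       (is.list(node[[p]]) && all(vapply(node[[p]], is.character, logical(1)))),
                     number = is.numeric(node[[p]]),
                     integer = is.numeric(node[[p]]) &&
                       all(node[[p]] == round(unlist(node[[p]]))),
                     boolean = is.logical(node[[p]]),
                     object = is.list(node[[p]]),
                     array = is.list(node[[p]]) || is.vector(node[[p]]),
                     TRUE)
        if (!isTRUE(ok))
          stop_input(sprintf("run report field `%s%s` has wrong type (need %s)",
                             where, p, decl))
        if (decl == "object" && !is.null(sch$properties[[p]]$required))
          check_node(node[[p]], sch$properties[[p]], paste0(where, p, "."))
      }
    }
    invisible(TRUE)
  }
  check_node(report, schema, "")
  invisible(TRUE)
}

config_echo <- function(hp, sampler = NULL, call_cfg = NULL) {
  out <- list(hyperparameters = unclass(hp))
  if (!is.null(sampler)) out$sampler <- unclass(sampler)
  if (!is.null(call_cfg)) out$calling <- unclass(call_cfg)
  out
}

resolve_counts <- function(counts, manifest = NULL) {
  if (is.character(counts)) counts <- read_count_table(counts)
  counts <- as_tibble(counts)
  if (!is.null(manifest)) {
    if (is.character(manifest)) manifest <- read_manifest(manifest)
    if (!"gene" %in% names(counts)) {
      counts <- dplyr::left_join(counts,
                                 manifest[, c("amplicon_id", "gene")],
                                 by = "amplicon_id")
    }
    unknown <- is.na(counts$gene)
    if (any(unknown))
      stop_input(paste0("amplicon(s) missing from manifest: ",
                        paste(utils::head(counts$amplicon_id[unknown], 5),
                              collapse = ", ")))
  }
  counts
}

#' Run the full calling pipeline
#'
#' Preprocess, posterior sampling, gene calling, and optionally evidence QC,
#' in one call. All thresholds, seeds and configurations are echoed into the
#' JSON run report for reproducibility. A QC failure never suppresses the
#' calls; the verdict is flagged in the report.
#'
#' @param counts count table (tibble) or path to a count TSV.
#' @param manifest optional manifest (tibble or path) supplying gene
#'   assignments when the count table lacks a `gene` column.
#' @param reference optional reference profile for normal-free calling
#'   (from [build_batch_reference()]); `NULL` uses the `normal_count`
#'   column.
#' @param hp model [hyperparameters()].
#' @param sampler a [sampler_config()].
#' @param call_cfg a [call_config()].
#' @param evidence also estimate the marginal likelihood (default FALSE).
#' @param evidence_K,evidence_config,qc_threshold evidence settings, see
#'   [ti_log_evidence()].
#' @param min_count preprocessing count filter, see [prepare_dataset()].
#' @param output_dir if non-NULL, `gene_calls.tsv`,
#'   `filtered_amplicons.tsv` and `run_report.json` are written there
#'   (atomically).
#' @return A list of class `cnv_run`: `calls`, `posterior`, `convergence`,
#'   `evidence` (or NULL), and the `report` list.
#' @export
run_call <- function(counts, manifest = NULL, reference = NULL,
                     hp = hyperparameters(), sampler = sampler_config(),
                     call_cfg = call_config(), evidence = FALSE,
                     evidence_K = 20, evidence_config = NULL,
                     qc_threshold = NULL, min_count = 1,
                     output_dir = NULL) {
  counts <- resolve_counts(counts, manifest)
  ds <- prepare_dataset(counts, reference = reference, min_count = min_count)
  post <- sample_posterior(ds, hp = hp, config = sampler)
  calls <- call_genes(post, call_cfg)
  conv <- check_convergence(post)
  ev <- NULL
  if (isTRUE(evidence))
    ev <- ti_log_evidence(ds, hp = hp, config = evidence_config,
                          K = evidence_K, qc_threshold = qc_threshold)

  report <- list(
    tool = "ampcnv",
    version = as.character(packageVersion("ampcnv")),
    seed = sampler$seed,
    configs = config_echo(hp, sampler, call_cfg),
    data = list(n_genes = ds$G, n_amplicons = ds$J,
                n_filtered = nrow(ds$filtered),
                n_excluded_genes = nrow(ds$excluded_genes),
                reference = ds$reference),
    diagnostics = list(mean_accept_prob = post$diagnostics$mean_accept_prob,
                       num_divergences = post$diagnostics$num_divergences,
                       min_ess = post$diagnostics$min_ess,
                       rhat_max = post$diagnostics$rhat_max),
    convergence = conv,
    calls = as.data.frame(as_tibble(calls))
  )
  if (!is.null(ev)) {
    report$evidence <- list(log_evidence = ev$log_evidence, se = ev$se,
                            K = ev$K, ladder = ev$ladder,
                            per_rung = as.data.frame(ev$rungs),
                            qc_threshold = qc_threshold,
                            qc_verdict = ev$qc_verdict,
                            hme_note = "use TI, not the harmonic mean, for QC")
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_gene_calls(calls, file.path(output_dir, "gene_calls.tsv"))
    write_filtered_amplicons(ds$filtered,
                             file.path(output_dir, "filtered_amplicons.tsv"))
    write_run_report(report, file.path(output_dir, "run_report.json"))
  }
  structure(list(calls = calls, posterior = post, convergence = conv,
                 evidence = ev, report = report, dataset = ds),
            class = "cnv_run")
}

#' @export
print.cnv_run <- function(x, ...) {
  cat(sprintf("<cnv_run> %d genes, %d amplification(s), %d deletion(s); convergence: %s\n",
              nrow(x$calls), sum(x$calls$call == "amplification"),
              sum(x$calls$call == "deletion"), x$convergence$verdict))
  if (!is.null(x$evidence))
    cat(sprintf("  log evidence %.2f (QC: %s)\n",
                x$evidence$log_evidence, x$evidence$qc_verdict))
  invisible(x)
}

#' Run evidence-based sample QC
#'
#' Preprocesses a sample and estimates its marginal log likelihood by
#' thermodynamic integration; the QC verdict follows [qc_evaluate()]. With
#' `qc_threshold = NULL` the verdict is `"not evaluated"`.
#'
#' @inheritParams run_call
#' @param config per-rung [sampler_config()]; defaults to 500 warmup and
#'   1000 kept draws.
#' @param K,exponent ladder settings, see [make_ladder()].
#' @return A list of class `evidence_run`: `evidence` (an
#'   `evidence_estimate`) and the `report` list.
#' @export
run_evidence <- function(counts, manifest = NULL, reference = NULL,
                         hp = hyperparameters(), config = NULL,
                         K = 20, exponent = 5, qc_threshold = NULL,
                         min_count = 1, output_dir = NULL) {
  counts <- resolve_counts(counts, manifest)
  ds <- prepare_dataset(counts, reference = reference, min_count = min_count)
  ev <- ti_log_evidence(ds, hp = hp, config = config, K = K,
                        exponent = exponent, qc_threshold = qc_threshold)
  report <- list(
    tool = "ampcnv",
    version = as.character(packageVersion("ampcnv")),
    seed = if (is.null(config)) 1L else config$seed,
    configs = config_echo(hp),
    data = list(n_genes = ds$G, n_amplicons = ds$J,
                n_filtered = nrow(ds$filtered),
                n_excluded_genes = nrow(ds$excluded_genes),
                reference = ds$reference),
    evidence = list(log_evidence = ev$log_evidence, se = ev$se, K = ev$K,
                    ladder = ev$ladder, per_rung = as.data.frame(ev$rungs),
                    qc_threshold = qc_threshold, qc_verdict = ev$qc_verdict,
                    warnings = ev$warnings)
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_run_report(report, file.path(output_dir, "evidence_report.json"))
  }
  structure(list(evidence = ev, report = report, dataset = ds),
            class = "evidence_run")
}

#' Write a simulated sample to the pipeline's input formats
#'
#' Emits the count TSV, a manifest TSV, and the truth table, so simulated
#' data can exercise the same readers the real pipeline uses.
#'
#' @param sim a `simulated_sample`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_simulated_sample <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_sample"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             manifest = file.path(dir, "manifest.tsv"),
             truth = file.path(dir, "truth.tsv"))
  readr::write_tsv(sim$counts, paths["counts"])
  readr::write_tsv(sim$counts[, c("amplicon_id", "gene")], paths["manifest"])
  readr::write_tsv(sim$truth, paths["truth"])
  paths
}
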