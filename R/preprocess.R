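#' Validate an amplicon count table
#'
#' Checks the invariants of a per-amplicon count table: required columns,
#' unique amplicon identifiers, a single gene per amplicon, and non-negative
#' integer counts.
#'
#' @param counts data frame with columns `amplicon_id`, `gene` and the count
#'   columns named in `count_cols`.
#' @param count_cols character vector of count column names to validate.
#' @return The input, invisibly, after validation.
#' @export
validate_count_table <- function(counts,
                                 count_cols = c("case_count", "normal_count")) {
  need <- c("amplicon_id", "gene", count_cols)
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols) > 0)
    stop_input(paste0("count table is missing column(s): ",
                      paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(counts$amplicon_id))
    stop_input("`amplicon_id` values must be unique")
  for (cc in count_cols) {
    v <- counts[[cc]]
    # a batch-mean `reference` may carry NA for amplicons missing in every
    # batch sample; those are removed by filter_amplicons()
    if (cc != "reference" && any(!is.finite(v)))
      stop_input(sprintf("column `%s` must contain finite counts", cc))
    if (any(!is.na(v) & (is.infinite(v) | v < 0)))
      stop_input(sprintf("column `%s` must contain non-negative finite counts", cc))
    if (cc %in% c("case_count", "normal_count") && any(abs(v - round(v)) > 1e-8))
      stop_input(sprintf("column `%s` must contain integer read counts", cc))
  }
  invisible(counts)
}

#' Per-amplicon log copy-number ratio
#'
#' Computes the raw log copy ratio \eqn{\tilde x_j = \log(s_j / n_j)} of case
#' over reference counts (natural logarithm). Both inputs must already have
#' been filtered to strictly positive values; a non-positive count reaching
#' this function indicates an upstream filtering bug and is an error.
#'
#' @param case_counts case-sample read counts \eqn{s_j}.
#' @param normal_counts process-matched reference counts \eqn{n_j} (raw
#'   counts for an explicit normal, or a batch-mean reference profile).
#' @return Numeric vector of raw log copy ratios.
#' @examples
#' compute_lcnr(c(200, 100), c(100, 100)) # log(2), 0
#' @export
compute_lcnr <- function(case_counts, normal_counts) {
  if (length(case_counts) != length(normal_counts))
    stop_input("case and reference count vectors must have equal length")
  if (any(case_counts <= 0) || any(normal_counts <= 0))
    stop_input(paste0("non-positive count passed to compute_lcnr(); ",
                      "amplicons must be filtered with filter_amplicons() first"))
  log(case_counts / normal_counts)
}

#' Median-center log ratios
#'
#' Subtracts the sample-wide median, \eqn{x_j = \tilde x_j -
#' \mathrm{median}(\{\tilde x_j\})}, absorbing sample-level depth and input
#' effects under the assumption that most amplicons are copy-neutral. For an
#' odd number of values the centered median is exactly zero.
#'
#' @param raw_lcnrs numeric vector of raw log copy ratios; at least one
#'   finite value is required.
#' @return Centered lCNR vector of the same length.
#' @export
median_center <- function(raw_lcnrs) {
  if (length(raw_lcnrs) == 0 || !any(is.finite(raw_lcnrs)))
    stop_data_quality("no finite log ratios to center: all amplicons were filtered")
  raw_lcnrs - median(raw_lcnrs)
}

#' Filter amplicons that failed to amplify
#'
#' An amplicon is removed iff its case count or its reference count falls
#' below `min_count`. The default `min_count = 1` removes exactly the
#' zero-count amplicons (those that failed to amplify in either the sample
#' or the reference). Removal reasons are recorded per amplicon.
#'
#' @param counts amplicon count table (see [validate_count_table()]); the
#'   reference column may be `normal_count` or `reference`.
#' @param min_count minimum acceptable read count (default 1).
#' @return A list with elements `retained` (tibble of surviving rows) and
#'   `filtered` (tibble `amplicon_id`, `gene`, `reason`).
#' @export
filter_amplicons <- function(counts, min_count = 1) {
  ref_col <- if ("normal_count" %in% names(counts)) "normal_count" else "reference"
  validate_count_table(counts, count_cols = c("case_count", ref_col))
  counts <- as_tibble(counts)
  low_case <- counts$case_count < min_count
  low_ref <- counts[[ref_col]] < min_count | !is.finite(counts[[ref_col]])
  reason <- dplyr::case_when(
    low_case & low_ref ~ "low_case_and_reference_count",
    low_case ~ "low_case_count",
    low_ref ~ "low_reference_count",
    TRUE ~ NA_character_
  )
  drop <- !is.na(reason)
  filtered <- tibble(amplicon_id = counts$amplicon_id[drop],
                     gene = counts$gene[drop],
                     reason = reason[drop])
  retained <- counts[!drop, , drop = FALSE]
  if (nrow(retained) == 0)
    stop_data_quality("all amplicons were filtered out; sample is unusable")
  list(retained = retained, filtered = filtered)
}

#' Batch-mean reference profile for normal-free calling
#'
#' When no process-matched normal is available, the reference is
#' approximated by the mean count profile across samples within a batch.
#' The per-amplicon reference is the geometric mean of the counts
#' (arithmetic mean in log space, consistent with all downstream modeling
#' being on the log scale), computed over the batch samples in which the
#' amplicon passed filtering. Amplicons failing in every batch sample are
#' marked missing and excluded downstream.
#'
#' @param batch list (length >= 2) of count tables sharing an amplicon
#'   manifest; each needs columns `amplicon_id`, `gene` and a count column
#'   named `count` or `case_count`.
#' @param min_count per-sample minimum count for an amplicon to contribute.
#' @return A tibble `amplicon_id`, `gene`, `reference`, `n_samples`,
#'   `missing`, with attribute `provenance = "batch-mean"`. Missing
#'   amplicons carry `reference = NA`.
#' @export
build_batch_reference <- function(batch, min_count = 1) {
  if (!is.list(batch) || length(batch) < 2)
    stop_input("`batch` must be a list of at least 2 count tables")
  tabs <- purrr::map(batch, function(tab) {
    cc <- if ("count" %in% names(tab)) "count" else "case_count"
    validate_count_table(tab, count_cols = cc)
    tibble(amplicon_id = tab$amplicon_id, gene = tab$gene, count = tab[[cc]])
  })
  ids <- tabs[[1]][, c("amplicon_id", "gene")]
  for (tab in tabs[-1]) {
    if (!identical(sort(tab$amplicon_id), sort(ids$amplicon_id)))
      stop_input("batch samples must share one amplicon manifest")
  }
  all_counts <- purrr::list_rbind(tabs)
  ref <- all_counts |>
    dplyr::filter(.data$count >= min_count) |>
    dplyr::group_by(.data$amplicon_id) |>
    dplyr::summarise(reference = exp(mean(log(.data$count))),
                     n_samples = dplyr::n(), .groups = "drop")
  out <- ids |>
    dplyr::left_join(ref, by = "amplicon_id") |>
    dplyr::mutate(n_samples = dplyr::coalesce(.data$n_samples, 0L),
                  missing = is.na(.data$reference))
  structure(as_tibble(out), provenance = "batch-mean")
}

#' Prepare a modeling-ready lCNR dataset
#'
#' End-to-end preprocessing: filter amplicons with counts below `min_count`
#' in either channel, compute raw log copy ratios against the reference,
#' exclude genes left with fewer than `min_gene_amplicons` amplicons (their
#' gene-level noise scale would be unidentifiable; they are reported
#' downstream as no-calls), median-center the remaining log ratios, and
#' group by gene.
#'
#' @param case amplicon count table for the case sample. With
#'   `reference = NULL` it must carry a `normal_count` column
#'   (explicit process-matched normal); otherwise only `case_count` is used.
#' @param reference optional reference profile from
#'   [build_batch_reference()], or any data frame with columns
#'   `amplicon_id` and `reference`.
#' @param min_count minimum read count in each channel (default 1).
#' @param min_gene_amplicons minimum retained amplicons for a gene to be
#'   modeled (default 2).
#' @return An object of class `lcnr_dataset`: a list with
#'   \describe{
#'     \item{data}{tibble `amplicon_id`, `gene`, `gene_index`, `lcnr`}
#'     \item{genes}{tibble `gene_index`, `gene`, `n_amplicons`}
#'     \item{excluded_genes}{tibble `gene`, `n_amplicons`, `reason`}
#'     \item{filtered}{tibble `amplicon_id`, `gene`, `reason`}
#'     \item{G, J}{modeled gene count and retained amplicon count}
#'     \item{reference}{provenance: `"explicit-normal"` or `"batch-mean"`}
#'   }
#' @examples
#' sim <- simulate_sample(simulation_config(seed = 1))
#' ds <- prepare_dataset(sim$counts)
#' ds$G; ds$J
#' @export
prepare_dataset <- function(case, reference = NULL, min_count = 1,
                            min_gene_amplicons = 2) {
  case <- as_tibble(case)
  if (is.null(reference)) {
    validate_count_table(case, count_cols = c("case_count", "normal_count"))
    provenance <- "explicit-normal"
    tab <- case[, c("amplicon_id", "gene", "case_count", "normal_count")]
    names(tab)[4] <- "reference"
  } else {
    validate_count_table(case, count_cols = "case_count")
    provenance <- attr(reference, "provenance") %||% "explicit-reference"
    tab <- case[, c("amplicon_id", "gene", "case_count")] |>
      dplyr::left_join(reference[, c("amplicon_id", "reference")],
                       by = "amplicon_id")
  }

  fl <- filter_amplicons(tab, min_count = min_count)
  retained <- fl$retained
  filtered <- fl$filtered

  # genes too thin to support a gene-level noise scale are set aside
  gene_sizes <- retained |> dplyr::count(.data$gene, name = "n_amplicons")
  thin <- gene_sizes |> dplyr::filter(.data$n_amplicons < min_gene_amplicons)
  excluded_genes <- tibble(gene = thin$gene, n_amplicons = thin$n_amplicons,
                           reason = "insufficient_amplicons")
  if (nrow(thin) > 0) {
    rlang::warn(paste0("gene(s) excluded from modeling (fewer than ",
                       min_gene_amplicons, " retained amplicons): ",
                       paste(thin$gene, collapse = ", ")),
                class = "ampcnv_gene_excluded")
    drop_rows <- retained$gene %in% thin$gene
    filtered <- dplyr::bind_rows(
      filtered,
      tibble(amplicon_id = retained$amplicon_id[drop_rows],
             gene = retained$gene[drop_rows],
             reason = "insufficient_amplicons_in_gene"))
    retained <- retained[!drop_rows, , drop = FALSE]
  }
  # genes whose amplicons all failed count filtering are excluded too
  all_genes <- unique(tab$gene)
  gone <- setdiff(all_genes, c(retained$gene, excluded_genes$gene))
  if (length(gone) > 0) {
    rlang::warn(paste0("gene(s) lost all amplicons to filtering: ",
                       paste(gone, collapse = ", ")),
                class = "ampcnv_gene_excluded")
    excluded_genes <- dplyr::bind_rows(
      excluded_genes,
      tibble(gene = gone, n_amplicons = 0L, reason = "all_amplicons_filtered"))
  }
  if (nrow(retained) == 0)
    stop_data_quality("no amplicons left after gene-level exclusion")

  lcnr <- median_center(compute_lcnr(retained$case_count, retained$reference))

  genes <- retained |>
    dplyr::count(.data$gene, name = "n_amplicons") |>
    dplyr::arrange(.data$gene) |>
    dplyr::mutate(gene_index = dplyr::row_number()) |>
    dplyr::select("gene_index", "gene", "n_amplicons")

  data <- tibble(amplicon_id = retained$amplicon_id,
                 gene = retained$gene,
                 lcnr = lcnr) |>
    dplyr::left_join(genes[, c("gene", "gene_index")], by = "gene") |>
    dplyr::select("amplicon_id", "gene", "gene_index", "lcnr")

  structure(list(data = data,
                 genes = genes,
                 excluded_genes = excluded_genes,
                 filtered = filtered,
                 G = nrow(genes),
                 J = nrow(data),
                 reference = provenance,
                 min_count = min_count),
            class = "lcnr_dataset")
}

#' @export
print.lcnr_dataset <- function(x, ...) {
  cat(sprintf("<lcnr_dataset> %d amplicons across %d genes (reference: %s)\n",
              x$J, x$G, x$reference))
  cat(sprintf("  filtered amplicons: %d; excluded genes: %d\n",
              nrow(x$filtered), nrow(x$excluded_genes)))
  invisible(x)
}

#' @export
tidy.lcnr_dataset <- function(x, ...) x$data

#' @export
glance.lcnr_dataset <- function(x, ...) {
  tibble(n_genes = x$G, n_amplicons = x$J,
         n_filtered = nrow(x$filtered),
         n_excluded_genes = nrow(x$excluded_genes),
         reference = x$reference)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
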