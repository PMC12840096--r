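test_that("log copy ratio is log(case/reference), natural log", {
  expect_equal(compute_lcnr(c(100, 100), c(100, 100)), c(0, 0))
  expect_equal(compute_lcnr(c(200, 100), c(100, 100)), c(log(2), 0))
  expect_equal(compute_lcnr(c(150, 75, 300), c(100, 100, 100)),
               c(log(1.5), log(0.75), log(3)))
  expect_error(compute_lcnr(c(0, 100), c(100, 100)), "filter")
  expect_error(compute_lcnr(100, c(100, 100)), "equal length")
})

test_that("median centering subtracts the sample median", {
  expect_equal(median_center(c(0.7, 0.0, 0.1)), c(0.6, -0.1, 0.0))
  expect_equal(median_center(rep(3.2, 4)), rep(0, 4))
  # a single outlier over a neutral majority is untouched
  expect_equal(median_center(c(log(2), 0, 0, 0, 0)), c(log(2), 0, 0, 0, 0))
  expect_error(median_center(numeric()), class = "ampcnv_data_quality_error")
})

test_that("amplicon filtering removes counts below min_count with reasons", {
  tab <- tibble::tibble(amplicon_id = c("a", "b", "c"),
                        gene = c("G1", "G1", "G2"),
                        case_count = c(10L, 0L, 10L),
                        normal_count = c(10L, 10L, 0L))
  fl <- filter_amplicons(tab, min_count = 1)
  expect_equal(nrow(fl$retained), 1)
  expect_equal(sort(fl$filtered$amplicon_id), c("b", "c"))
  expect_setequal(fl$filtered$reason,
                  c("low_case_count", "low_reference_count"))

  ok <- tibble::tibble(amplicon_id = c("a", "b"), gene = "G1",
                       case_count = c(10L, 10L), normal_count = c(10L, 10L))
  fl2 <- filter_amplicons(ok)
  expect_equal(nrow(fl2$retained), 2)
  expect_equal(nrow(fl2$filtered), 0)

  bad <- tibble::tibble(amplicon_id = "a", gene = "G1",
                        case_count = 0L, normal_count = 0L)
  expect_error(filter_amplicons(bad), class = "ampcnv_data_quality_error")
})

test_that("filtering conserves rows and matches a direct scan", {
  set.seed(42)
  for (i in 1:5) {
    n <- 100
    tab <- tibble::tibble(
      amplicon_id = sprintf("a%03d", 1:n),
      gene = sample(sprintf("G%d", 1:8), n, replace = TRUE),
      case_count = as.integer(ifelse(runif(n) < 0.07, 0, rpois(n, 500))),
      normal_count = as.integer(rpois(n, 500) + 1L))
    fl <- filter_amplicons(tab, min_count = 1)
    expect_equal(nrow(fl$retained) + nrow(fl$filtered), n)
    expect_equal(nrow(fl$retained),
                 sum(tab$case_count >= 1 & tab$normal_count >= 1))
  }
})

test_that("batch reference is the geometric mean over passing samples", {
  mk <- function(counts) tibble::tibble(amplicon_id = c("a1", "a2"),
                                        gene = "G1",
                                        count = as.integer(counts))
  ref <- build_batch_reference(list(mk(c(100, 100)), mk(c(400, 100)),
                                    mk(c(200, 100))))
  expect_equal(ref$reference[ref$amplicon_id == "a2"], 100)
  expect_equal(ref$reference[ref$amplicon_id == "a1"],
               exp(mean(log(c(100, 400, 200)))))
  expect_identical(attr(ref, "provenance"), "batch-mean")

  # two-sample geometric mean, by hand
  ref2 <- build_batch_reference(list(mk(c(100, 10)), mk(c(400, 10))))
  expect_equal(ref2$reference[1], 200)

  # identical tables: reference equals any member's counts
  ref3 <- build_batch_reference(list(mk(c(123, 77)), mk(c(123, 77))))
  expect_equal(ref3$reference, c(123, 77))

  # amplicon failing everywhere is marked missing
  ref4 <- build_batch_reference(list(mk(c(0, 50)), mk(c(0, 60))))
  expect_true(ref4$missing[ref4$amplicon_id == "a1"])
  expect_true(is.na(ref4$reference[ref4$amplicon_id == "a1"]))

  expect_error(build_batch_reference(list(mk(c(1, 1)))), "at least 2")
})

test_that("prepare_dataset composes filter, lCNR and centering by gene", {
  tab <- tiny_counts()
  neutral <- tab
  neutral$case_count <- neutral$normal_count
  ds <- prepare_dataset(neutral)
  expect_equal(ds$data$lcnr, rep(0, 9))
  expect_equal(ds$G, 3)
  expect_equal(ds$J, 9)
  expect_equal(sum(ds$genes$n_amplicons), ds$J)

  # one gene doubled on a majority-neutral panel keeps its log-2 shift
  g <- panel_genes(10, 11, cnv_genes = "GENE05", cnv_ratio = 2)
  sim <- simulate_sample(simulation_config(genes = g, noise_scale = 0,
                                           count_model = "deterministic",
                                           seed = 3))
  ds2 <- prepare_dataset(sim$counts)
  shifted <- ds2$data$lcnr[ds2$data$gene == "GENE05"]
  expect_equal(shifted, rep(log(2), 11), tolerance = 1e-6)
  expect_equal(median(ds2$data$lcnr), 0) # odd J: exact
})

test_that("prepare_dataset is depth-invariant and permutation-invariant", {
  sim <- simulate_sample(study_panel_config(seed = 11))
  ds <- prepare_dataset(sim$counts)
  scaled <- sim$counts
  scaled$case_count <- scaled$case_count * 10L
  ds10 <- prepare_dataset(scaled)
  expect_equal(ds10$data$lcnr, ds$data$lcnr, tolerance = 1e-12)

  shuf <- sim$counts[sample.int(nrow(sim$counts)), ]
  dss <- prepare_dataset(shuf)
  for (g in ds$genes$gene) {
    expect_equal(sort(dss$data$lcnr[dss$data$gene == g]),
                 sort(ds$data$lcnr[ds$data$gene == g]))
  }
})

test_that("genes with too few amplicons are excluded and reported", {
  tab <- tiny_counts()
  tab$case_count[tab$amplicon_id %in% c("amp07", "amp08")] <- 0L # gene C -> 1 left
  expect_warning(ds <- prepare_dataset(tab), class = "ampcnv_gene_excluded")
  expect_equal(ds$G, 2)
  expect_equal(ds$excluded_genes$gene, "C")
  expect_equal(ds$excluded_genes$reason, "insufficient_amplicons")
  expect_true("insufficient_amplicons_in_gene" %in% ds$filtered$reason)
  # retained + filtered covers all input amplicons
  expect_equal(ds$J + nrow(ds$filtered), nrow(tab))
})

test_that("count table invariants are enforced", {
  tab <- tiny_counts()
  dup <- tab; dup$amplicon_id[2] <- dup$amplicon_id[1]
  expect_error(validate_count_table(dup), "unique")
  neg <- tab; neg$case_count[1] <- -1L
  expect_error(validate_count_table(neg), "non-negative")
  frac <- tab; frac$case_count <- frac$case_count + 0.5
  expect_error(validate_count_table(frac), "integer")
  expect_error(validate_count_table(tab[, -2]), "missing column")
})
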