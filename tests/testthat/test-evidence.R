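test_that("temperature ladder follows the power-law schedule", {
  expect_equal(make_ladder(2, 5), c(0, 1))
  expect_equal(make_ladder(3, 1), c(0, 0.5, 1))
  expect_equal(make_ladder(5, 5), ((0:4) / 4)^5)
  expect_equal(make_ladder(5, 5)[2], 0.25^5) # 0.0009765625
  l <- make_ladder(20, 5)
  expect_equal(l[1], 0)
  expect_equal(l[20], 1)
  expect_true(all(diff(l) > 0))
  expect_error(make_ladder(1), "at least 2")
  expect_error(make_ladder(10, 0), "> 0")
})

test_that("trapezoid estimator satisfies the exactness identities", {
  # constant integrand returns the constant, on any ladder
  expect_equal(trapezoid_log_evidence(rep(-12.34, 7), make_ladder(7, 5)),
               -12.34, tolerance = 1e-12)
  # linear integrand on a uniform grid is integrated exactly
  l <- make_ladder(11, 1)
  expect_equal(trapezoid_log_evidence(l, l), 0.5, tolerance = 1e-12)
  # single panel
  expect_equal(trapezoid_log_evidence(c(3, 5), c(0, 1)), 4)
  expect_error(trapezoid_log_evidence(1:3, c(0, 1)), "per rung")
})

test_that("harmonic-mean estimator is exact on degenerate draws and stable", {
  expect_equal(harmonic_mean_log_evidence(rep(-7.5, 100))$log_evidence, -7.5)
  # log-sum-exp keeps extreme log likelihoods finite
  h <- harmonic_mean_log_evidence(c(-1e6, -5, 0))
  expect_true(is.finite(h$log_evidence))
  expect_match(h$note, "unreliable")
  expect_error(harmonic_mean_log_evidence(numeric()), "no log-likelihood")
})

test_that("QC verdict is a strict-inequality threshold rule", {
  expect_equal(qc_evaluate(-232, -100)$verdict, "fail")
  expect_equal(qc_evaluate(-15, -100)$verdict, "pass")
  expect_equal(qc_evaluate(-100, -100)$verdict, "pass") # boundary passes
  expect_equal(qc_evaluate(-15, NULL)$verdict, "not evaluated")
})

test_that("TI recovers the conjugate normal-normal evidence", {
  ev <- ti_log_evidence_normal(
    0, prior_var = 1, lik_var = 1,
    config = sampler_config(num_warmup = 400, num_samples = 1000, seed = 42),
    K = 20)
  exact <- dnorm(0, 0, sqrt(2), log = TRUE) # log N(0; 0, 2)
  expect_equal(exact, -1.2655, tolerance = 1e-4)
  expect_lt(abs(ev$log_evidence - exact), 3 * ev$se)
  expect_true(ev$monotone_ok)
  # multi-observation case against the closed form
  x <- c(0.4, -0.3, 1.1)
  ev2 <- ti_log_evidence_normal(
    x, prior_var = 2, lik_var = 0.5,
    config = sampler_config(num_warmup = 400, num_samples = 1000, seed = 43),
    K = 20)
  A <- 1 / 2 + length(x) / 0.5
  b <- sum(x) / 0.5
  exact2 <- -length(x) / 2 * log(2 * pi * 0.5) - 0.5 * log(2 * A) -
    sum(x^2) / (2 * 0.5) + b^2 / (2 * A)
  expect_lt(abs(ev2$log_evidence - exact2), 3 * ev2$se)
})

test_that("TI is more stable than the harmonic mean at a matched budget", {
  exact <- dnorm(0, 0, sqrt(2), log = TRUE)
  ti <- hme <- numeric(6)
  for (r in 1:6) {
    cfg <- sampler_config(num_warmup = 300, num_samples = 1000, seed = 200 + r)
    ti[r] <- ti_log_evidence_normal(0, config = cfg, K = 20)$log_evidence
    post <- ampcnv:::.nuts_run("normal",
                               list(x = 0, prior_var = 1, lik_var = 1),
                               1.0, 300, 1000, 0.8, 10, 900 + r, NULL)
    hme[r] <- harmonic_mean_log_evidence(post$loglik)$log_evidence
  }
  expect_lt(sqrt(mean((ti - exact)^2)), sqrt(mean((hme - exact)^2)))
})

test_that("ladder refinement changes the estimate by less than its error", {
  e20 <- ti_log_evidence_normal(0, config = sampler_config(
    num_warmup = 300, num_samples = 1000, seed = 11), K = 20)
  e40 <- ti_log_evidence_normal(0, config = sampler_config(
    num_warmup = 300, num_samples = 1000, seed = 12), K = 40)
  expect_lt(abs(e20$log_evidence - e40$log_evidence), e20$se + e40$se)
})

test_that("power-posterior means rise from prior to posterior expectations", {
  sim <- simulate_sample(simulation_config(
    genes = panel_genes(3, 12, cnv_genes = "GENE01"), seed = 15))
  ds <- prepare_dataset(sim$counts)
  ladder <- make_ladder(6, 5)
  rungs <- power_posterior_means(ds, ladder = ladder,
                                 config = sampler_config(
                                   num_warmup = 250, num_samples = 500,
                                   seed = 3))
  expect_equal(nrow(rungs), 6)
  expect_equal(rungs$beta, ladder)
  # non-decreasing within 3 combined SE
  dmu <- diff(rungs$mean_loglik)
  dse <- sqrt(rungs$se[-6]^2 + rungs$se[-1]^2)
  expect_true(all(dmu >= -3 * dse))
  # the beta=1 rung matches an independent posterior run's mean log likelihood
  post <- sample_posterior(ds, config = sampler_config(
    num_warmup = 400, num_samples = 1000, seed = 77))
  se_post <- sd(post$loglik) / sqrt(mcmc_ess(post$loglik))
  tol <- 4 * sqrt(rungs$se[6]^2 + se_post^2)
  expect_lt(abs(rungs$mean_loglik[6] - mean(post$loglik)), tol)
})

test_that("evidence estimate objects carry rungs, QC and warnings", {
  sim <- simulate_sample(simulation_config(
    genes = panel_genes(3, 10), seed = 25))
  ds <- prepare_dataset(sim$counts)
  ev <- ti_log_evidence(ds, config = sampler_config(
    num_warmup = 200, num_samples = 300, seed = 6), K = 5,
    qc_threshold = -1e6)
  expect_s3_class(ev, "evidence_estimate")
  expect_true(is.finite(ev$log_evidence))
  expect_equal(ev$qc_verdict, "pass")
  expect_equal(nrow(ev$rungs), 5)
  expect_equal(glance(ev)$log_evidence, ev$log_evidence)
  # halving draws roughly doubles the per-rung variance (MC scaling): check
  # the combined SE moves in the right direction
  ev_small <- ti_log_evidence(ds, config = sampler_config(
    num_warmup = 200, num_samples = 75, seed = 6), K = 5)
  expect_gt(ev_small$se, ev$se)
})
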