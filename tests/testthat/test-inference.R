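test_that("fixed seed gives bit-identical draws; config is validated", {
  sim <- simulate_sample(simulation_config(
    genes = panel_genes(3, 8, cnv_genes = "GENE01"), seed = 7))
  ds <- prepare_dataset(sim$counts)
  cfg <- sampler_config(num_warmup = 150, num_samples = 150, seed = 99)
  p1 <- sample_posterior(ds, config = cfg)
  p2 <- sample_posterior(ds, config = cfg)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$loglik, p2$loglik)
  # a different seed moves the draws
  p3 <- sample_posterior(ds, config = sampler_config(
    num_warmup = 150, num_samples = 150, seed = 100))
  expect_false(identical(p1$draws$mu0, p3$draws$mu0))

  expect_error(sampler_config(num_samples = 0), ">= 1")
  expect_error(sampler_config(target_accept = 1.2), "between 0 and 1")
  expect_error(sample_posterior(data.frame()), "lcnr_dataset")
})

test_that("posterior draws satisfy positivity and dimension invariants", {
  sim <- simulate_sample(simulation_config(
    genes = panel_genes(3, 10), seed = 12))
  ds <- prepare_dataset(sim$counts)
  post <- sample_posterior(ds, config = sampler_config(
    num_warmup = 150, num_samples = 200, num_chains = 2, seed = 5))
  expect_equal(nrow(post$draws), 200 * 2)
  expect_true(all(post$draws$sigma2 > 0))
  expect_true(all(post$draws$tau0_sq > 0))
  for (g in post$gene) expect_true(all(post$draws[[paste0("z[", g, "]")]] > 0))
  expect_true(is.finite(post$diagnostics$rhat_max))
})

test_that("gene-level lCNR is recovered on self-simulated data (G = 1)", {
  set.seed(1)
  x <- 0.7 + rsoftlaplace(200, 0, 0.05)
  ds <- make_lcnr_dataset(x, rep("ERBB2", 200))
  post <- sample_posterior(ds, config = sampler_config(
    num_warmup = 400, num_samples = 800, seed = 2))
  m <- mean(post$draws[["mu[ERBB2]"]])
  expect_lt(abs(m - 0.7), 0.05)
  expect_equal(post$diagnostics$num_divergences, 0)
})

test_that("with zero likelihood weight the sampler reproduces the prior", {
  ds <- make_lcnr_dataset(rnorm(8, 0, 0.1), rep(c("A", "B"), each = 4))
  hp <- hyperparameters()
  post <- sample_posterior(ds, hp = hp, config = sampler_config(
    num_warmup = 500, num_samples = 4000, seed = 8), likelihood_weight = 0)
  # mu0 ~ N(0, nu): check both moments within 3 MC standard errors
  mu0 <- post$draws$mu0
  ess <- mcmc_ess(mu0)
  expect_lt(abs(mean(mu0)), 3 * sd(mu0) / sqrt(ess))
  expect_equal(var(mu0), hp$nu, tolerance = 0.15)
  # sigma2 ~ InvGamma(3, 0.5): mean beta/(alpha-1) = 0.25
  s2 <- post$draws$sigma2
  expect_equal(mean(s2), 0.25, tolerance = 3 * sd(s2) / sqrt(mcmc_ess(s2)) + 0.02)
  # mu_g marginally ~ N(0, nu + E[sigma2]) is heavy; just check centering
  expect_lt(abs(mean(post$draws[["mu[A]"]])), 0.1)
})

test_that("ESS and split-R-hat behave on draws of known dependence", {
  set.seed(77)
  x <- rnorm(4000)
  expect_equal(mcmc_ess(x), 4000, tolerance = 0.2)
  # strongly autocorrelated AR(1) draws have much lower ESS
  rho <- 0.9
  ar <- as.numeric(stats::arima.sim(list(ar = rho), 4000))
  expect_lt(mcmc_ess(ar), 1000)
  # two iid chains: rhat near 1; shifted chains: rhat far above 1
  m <- cbind(rnorm(1000), rnorm(1000))
  expect_lt(mcmc_rhat(m), 1.02)
  expect_gt(mcmc_rhat(cbind(rnorm(1000), rnorm(1000) + 3)), 1.5)
  expect_true(is.na(mcmc_ess(rep(1, 50))))
})

test_that("convergence checks warn on the documented pathologies", {
  ok <- list(mean_accept_prob = 0.8, num_divergences = 0L, min_ess = 5000,
             rhat_max = NA_real_)
  expect_equal(check_convergence(ok)$verdict, "pass")

  div <- ok; div$num_divergences <- 3L
  v <- check_convergence(div)
  expect_equal(v$verdict, "warn")
  expect_match(v$reasons, "divergent", all = FALSE)

  low <- ok; low$mean_accept_prob <- 0.35
  v2 <- check_convergence(low)
  expect_equal(v2$verdict, "warn")
  expect_match(v2$reasons, "acceptance", all = FALSE)

  thin <- ok; thin$min_ess <- 120
  expect_match(check_convergence(thin)$reasons, "ESS", all = FALSE)

  bad_mix <- ok; bad_mix$rhat_max <- 1.2
  expect_match(check_convergence(bad_mix)$reasons, "R-hat", all = FALSE)
})
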