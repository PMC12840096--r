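test_that("SoftLaplace density has the sech closed form and is normalized", {
  expect_equal(dsoftlaplace(0), 1 / pi)
  expect_equal(dsoftlaplace(0, log = TRUE), log(1 / pi))
  # closed form at an off-center point
  expect_equal(dsoftlaplace(1.3, 0.2, 0.7),
               (1 / cosh((1.3 - 0.2) / 0.7)) / (pi * 0.7))
  # quadrature normalization across four scales
  for (s in c(0.01, 0.1, 1, 10)) {
    q <- stats::integrate(dsoftlaplace, -40 * s, 40 * s, scale = s,
                          rel.tol = 1e-10)
    expect_equal(q$value, 1, tolerance = 1e-8)
  }
  expect_error(dsoftlaplace(0, scale = 0), "positive")
})

test_that("SoftLaplace is symmetric, heavy-tailed, and stable far out", {
  a <- seq(0.1, 30, length.out = 40)
  expect_equal(dsoftlaplace(2 + a, 2, 1.4, log = TRUE),
               dsoftlaplace(2 - a, 2, 1.4, log = TRUE))
  # heavier than the variance-matched Gaussian beyond some finite point
  s <- 0.8
  gauss_sd <- pi * s / 2 # matches SoftLaplace variance (pi^2/4) s^2
  x_far <- seq(4, 12, by = 0.5) * gauss_sd
  expect_true(all(dsoftlaplace(x_far, 0, s, log = TRUE) >
                    dnorm(x_far, 0, gauss_sd, log = TRUE)))
  # no overflow at extreme arguments
  expect_true(is.finite(dsoftlaplace(1e6, 0, 1, log = TRUE)))
})

test_that("SoftLaplace quantile/CDF invert each other and drive rng", {
  p <- c(0.01, 0.2, 0.5, 0.9, 0.999)
  expect_equal(psoftlaplace(qsoftlaplace(p, 1, 2), 1, 2), p)
  set.seed(9)
  x <- rsoftlaplace(20000, 0, 1)
  expect_equal(mean(x), 0, tolerance = 0.05)
  expect_equal(var(x), pi^2 / 4, tolerance = 0.15)
})

test_that("inverse-gamma density matches the transformed gamma oracle", {
  x <- c(0.05, 0.3, 1, 4)
  expect_equal(dinvgamma(x, 3, 0.5, log = TRUE),
               dgamma(1 / x, shape = 3, rate = 0.5, log = TRUE) - 2 * log(x))
  expect_equal(dinvgamma(-1, 3, 0.5), 0)
})

test_that("log prior sums the component densities term by term", {
  hp <- hyperparameters()
  st <- parameter_state(0.3, 0.2, 0.04, mu = c(0.1, 0.7), z = c(0.9, 1.4))
  manual <- dnorm(0.3, 0, sqrt(hp$nu), log = TRUE) +
    dinvgamma(0.2, hp$alpha_sigma, hp$beta_sigma, log = TRUE) +
    dinvgamma(0.04, hp$alpha_tau0, hp$beta_tau0, log = TRUE) +
    sum(dnorm(c(0.1, 0.7), 0.3, sqrt(0.2), log = TRUE)) +
    sum(dinvgamma(c(0.9, 1.4), hp$alpha_tau, hp$beta_tau, log = TRUE))
  expect_equal(log_prior(st, hp), manual)

  # G = 0 reduces to the three global terms
  st0 <- parameter_state(0.3, 0.2, 0.04)
  expect_equal(log_prior(st0, hp),
               dnorm(0.3, 0, 1, log = TRUE) +
                 dinvgamma(0.2, 3, 0.5, log = TRUE) +
                 dinvgamma(0.04, 3, 0.5, log = TRUE))

  # duplicating a gene adds exactly its two terms again
  st3 <- parameter_state(0.3, 0.2, 0.04, mu = c(0.1, 0.7, 0.7),
                         z = c(0.9, 1.4, 1.4))
  expect_equal(log_prior(st3, hp) - log_prior(st, hp),
               dnorm(0.7, 0.3, sqrt(0.2), log = TRUE) +
                 dinvgamma(1.4, hp$alpha_tau, hp$beta_tau, log = TRUE))

  expect_error(parameter_state(0, -1, 1, 0.1, 1), "invalid")
  expect_error(parameter_state(0, 1, 1, c(0.1, 0.2), 1), "same length")
})

test_that("log likelihood is the SoftLaplace sum with scale tau0*z", {
  # all x at the gene means, unit scales: J * log(1/pi)
  ds <- make_lcnr_dataset(c(rep(0.5, 3), rep(-0.2, 4)),
                          c(rep("A", 3), rep("B", 4)))
  st <- parameter_state(0, 1, 1, mu = c(0.5, -0.2), z = c(1, 1))
  expect_equal(log_likelihood(ds, st), 7 * log(1 / pi))

  # empty data
  empty <- tibble::tibble(gene_index = integer(), lcnr = numeric())
  expect_equal(log_likelihood(empty, st), 0)
  expect_equal(log_joint(empty, st), log_prior(st))

  # permutation within a gene leaves the sum unchanged
  set.seed(4)
  x <- rnorm(12, 0, 0.3)
  ds1 <- make_lcnr_dataset(x, rep(c("A", "B"), each = 6))
  ds2 <- make_lcnr_dataset(c(sample(x[1:6]), sample(x[7:12])),
                           rep(c("A", "B"), each = 6))
  st2 <- parameter_state(0.1, 0.3, 0.02, mu = c(0.2, -0.1), z = c(1.2, 0.8))
  expect_equal(log_likelihood(ds1, st2), log_likelihood(ds2, st2))

  # general case against direct summation with explicit scales
  manual <- sum(dsoftlaplace(x, location = rep(c(0.2, -0.1), each = 6),
                             scale = sqrt(0.02) * rep(c(1.2, 0.8), each = 6),
                             log = TRUE))
  expect_equal(log_likelihood(ds1, st2), manual)
  expect_equal(log_joint(ds1, st2), log_prior(st2) + log_likelihood(ds1, st2))

  # dimension mismatch is a contract error
  st1 <- parameter_state(0, 1, 1, mu = 0.5, z = 1)
  expect_error(log_likelihood(ds1, st1), "gene index")
})

test_that("compiled log density agrees with the R reference and its gradient", {
  sim <- simulate_sample(simulation_config(
    genes = panel_genes(4, 8, cnv_genes = "GENE02"), seed = 21))
  ds <- prepare_dataset(sim$counts)
  hp <- hyperparameters()
  md <- ampcnv:::as_model_data(ds, hp)
  set.seed(31)
  for (rep in 1:3) {
    G <- ds$G
    u <- c(rnorm(1, 0, 0.5), log(runif(1, 0.05, 0.5)),
           log(runif(1, 0.01, 0.2)), rnorm(G, 0, 0.5),
           log(runif(G, 0.5, 2)))
    cpp <- ampcnv:::.model_logp("cnv", md, u, 1.0)
    sigma <- exp(0.5 * u[2])
    st <- parameter_state(u[1], exp(u[2]), exp(u[3]),
                          mu = u[1] + sigma * u[4:(3 + G)],
                          z = exp(u[(4 + G):(3 + 2 * G)]))
    # unconstrained density = constrained joint + log Jacobians of the
    # log transforms + the non-centered change of variables for mu_g
    jac <- u[2] + u[3] + sum(u[(4 + G):(3 + 2 * G)]) + G * 0.5 * u[2]
    expect_equal(cpp$logp, log_joint(ds, st, hp) + jac, tolerance = 1e-10)
    expect_equal(cpp$loglik, log_likelihood(ds, st), tolerance = 1e-10)
    # finite-difference gradient check
    fd <- vapply(seq_along(u), function(i) {
      h <- 1e-6
      up <- u; up[i] <- u[i] + h
      um <- u; um[i] <- u[i] - h
      (ampcnv:::.model_logp("cnv", md, up, 1)$logp -
         ampcnv:::.model_logp("cnv", md, um, 1)$logp) / (2 * h)
    }, numeric(1))
    expect_equal(cpp$grad, fd, tolerance = 1e-5)
  }
})
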