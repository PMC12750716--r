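# A fitted_model can be constructed directly for degenerate test cases.
manual_model <- function(coefs, family, residual_sd = NULL, terms = NULL) {
  terms <- terms %||% setdiff(names(coefs), "(Intercept)")
  structure(list(
    coefficients = coefs, residual_sd = residual_sd,
    vcov = diag(length(coefs)), converged = TRUE, n_obs = 100L,
    loglik = NA_real_, family = family,
    design = design_spec("..y..", terms, family = family),
    coding = list()), class = "fitted_model")
}

test_that("mediator simulation is degenerate without residual noise and
           null under a zero exposure coefficient", {
  mm <- manual_model(c(`(Intercept)` = 2, x_helpful = 1, c1 = 0.5),
                     "gaussian_identity", residual_sd = 0)
  recs <- data.frame(x_helpful = c(0, 1), c1 = c(2, -2))
  draws <- simulate_mediator(mm, recs, x_set = 1, draws = 50, rng_seed = 1)
  expect_identical(dim(draws), c(2L, 50L))
  expect_true(all(draws[1, ] == 2 + 1 + 0.5 * 2))
  expect_true(all(draws[2, ] == 2 + 1 - 0.5 * 2))

  mm0 <- manual_model(c(`(Intercept)` = 5, x_helpful = 0, c1 = 1),
                      "gaussian_identity", residual_sd = 2)
  recs2 <- data.frame(x_helpful = rep(0, 200), c1 = rnorm(200))
  d0 <- simulate_mediator(mm0, recs2, 0, draws = 500, rng_seed = 2)
  d1 <- simulate_mediator(mm0, recs2, 1, draws = 500, rng_seed = 2)
  mc_se <- 2 / sqrt(length(d0))
  expect_lt(abs(mean(d0) - mean(d1)), 4 * sqrt(2) * mc_se)
})

test_that("mediator draw means obey the CLT bound around the linear
           predictor", {
  mm <- manual_model(c(`(Intercept)` = 10, x_helpful = 3),
                     "gaussian_identity", residual_sd = 4)
  recs <- data.frame(x_helpful = 0)
  n_draws <- 1e5
  draws <- simulate_mediator(mm, recs, x_set = 1, draws = n_draws,
                             rng_seed = 33)
  expect_lt(abs(mean(draws) - 13), 3 * 4 / sqrt(n_draws))
})

test_that("linear-probability draws clip out-of-range predictors and
           count them", {
  mm <- manual_model(c(`(Intercept)` = 0.9, x_helpful = 0.4),
                     "gaussian_identity", residual_sd = 0.1)
  recs <- data.frame(x_helpful = rep(1, 10))
  draws <- simulate_mediator(mm, recs, x_set = 1, draws = 20, rng_seed = 1,
                             kind = "linear_probability")
  expect_identical(attr(draws, "n_clipped"), 10L) # 1.3 clipped for all rows
  expect_true(all(draws %in% c(0L, 1L)))
})

test_that("counterfactual means hit closed-form values in degenerate
           models", {
  # Y-model: everything zero except intercept 0 -> every mean expit(0)
  ym <- manual_model(c(`(Intercept)` = 0, x_helpful = 0, m = 0),
                     "binomial_logit")
  mm <- manual_model(c(`(Intercept)` = 1, x_helpful = 1),
                     "gaussian_identity", residual_sd = 1)
  recs <- data.frame(x_helpful = rep(0, 50), m = 0)
  mu <- counterfactual_means(ym, mm, recs, draws = 10, rng_seed = 1,
                             mediator = "m")
  expect_equal(unname(mu[c("mu_11", "mu_00", "mu_10")]), rep(0.5, 3))

  # Y-model ignoring the mediator: mu_11 equals mu_10 exactly
  ym2 <- manual_model(c(`(Intercept)` = 0.2, x_helpful = 0.7, m = 0),
                      "binomial_logit")
  mu2 <- counterfactual_means(ym2, mm, recs, draws = 200, rng_seed = 5,
                              mediator = "m")
  expect_equal(mu2[["mu_11"]], mu2[["mu_10"]], tolerance = 1e-12)
  expect_true(all(mu2 >= 0 & mu2 <= 1))
})

test_that("counterfactual means match a large-sample oracle on a known
           DGP", {
  # truth by direct large-n simulation from the true models
  set.seed(600)
  n_oracle <- 4e5
  c1 <- rnorm(n_oracle)
  m_of <- function(x) 1 + 1 * x + 0.5 * c1 + rnorm(n_oracle)
  p_of <- function(x, m) stats::plogis(-0.5 + 1 * x + 1 * m + 0.4 * c1)
  truth <- c(mu_11 = mean(p_of(1, m_of(1))),
             mu_00 = mean(p_of(0, m_of(0))),
             mu_10 = mean(p_of(1, m_of(0))))

  # average the plug-in means over datasets so sampling noise in the
  # fitted coefficients shrinks below the comparison tolerance
  mus <- vapply(1:30, function(i) {
    d <- tiny_mediation_data(4000, seed = 600 + i)
    mm <- med_fit(design_spec("bses_total", c("x_helpful", "c1"),
                              family = "gaussian_identity"), d)
    ym <- med_fit(design_spec("y_exclusive",
                              c("x_helpful", "bses_total", "c1"),
                              family = "binomial_logit"), d)
    mu_i <- counterfactual_means(ym, mm, d, draws = 150, rng_seed = 11 + i)
    mu_i[c("mu_11", "mu_00", "mu_10")]
  }, numeric(3L))
  expect_equal(unname(rowMeans(mus)[names(truth)]), unname(truth),
               tolerance = 0.01)
})

test_that("decomposition reproduces the published arithmetic and flags
           null totals", {
  # construct means with the published total and direct effects
  est <- decompose_effects(c(mu_11 = 0.84, mu_00 = 0.70, mu_10 = 0.83))
  expect_equal(est$tce, 0.14, tolerance = 1e-12)
  expect_equal(est$nde, 0.13, tolerance = 1e-12)
  expect_equal(est$nie, 0.01, tolerance = 1e-12)
  expect_equal(round(100 * est$prop_mediated), 7)

  est2 <- decompose_effects(c(mu_11 = 0.78, mu_00 = 0.60, mu_10 = 0.74))
  expect_equal(est2$tce, 0.18, tolerance = 1e-12)
  expect_equal(est2$nie, 0.04, tolerance = 1e-12)

  null <- decompose_effects(c(mu_11 = 0.5, mu_00 = 0.5, mu_10 = 0.5))
  expect_identical(null$prop_defined, FALSE)
  expect_true(is.na(null$prop_mediated))
  expect_identical(null$tce, 0)
})

test_that("nie + nde = tce holds exactly for random means", {
  set.seed(321)
  for (i in 1:1000) {
    mu <- runif(3)
    est <- decompose_effects(c(mu_11 = mu[1], mu_00 = mu[2],
                               mu_10 = mu[3]))
    expect_identical(est$nie + est$nde, est$tce)
    expect_true(abs(est$tce) <= 1 && abs(est$nie) <= 1)
  }
})

test_that("estimate() is deterministic and respects null paths by
           construction", {
  d <- tiny_mediation_data(800, seed = 17, g_m = 0)
  adj <- list(mediator = "c1", outcome = "c1")
  e1 <- gcomp_estimate(d, adjustment = adj, mediator_scale = "raw",
                       rng_seed = 42)
  e2 <- gcomp_estimate(d, adjustment = adj, mediator_scale = "raw",
                       rng_seed = 42)
  expect_identical(e1$estimates, e2$estimates) # bit-identical same seed
  expect_identical(e1$means, e2$means)

  # severed M -> Y path: nie should be near zero
  expect_lt(abs(e1$estimates$nie), 0.02)

  # no exposure effect anywhere: tce near zero
  d0 <- tiny_mediation_data(800, seed = 18, b_xm = 0, g_x = 0)
  e0 <- gcomp_estimate(d0, adjustment = adj, mediator_scale = "raw",
                       rng_seed = 43)
  expect_lt(abs(e0$estimates$tce), 0.05)
})

test_that("draw-Y mode agrees with probability averaging within MC error", {
  d <- tiny_mediation_data(1500, seed = 55)
  adj <- list(mediator = "c1", outcome = "c1")
  e_avg <- gcomp_estimate(d, adjustment = adj, mediator_scale = "raw",
                          mc_draws = 300, rng_seed = 9)
  e_draw <- gcomp_estimate(d, adjustment = adj, mediator_scale = "raw",
                           mc_draws = 300, rng_seed = 9, draw_y = TRUE)
  # Bernoulli sampling adds sd ~ sqrt(0.25 / (n * draws)) per mean
  expect_equal(e_draw$estimates$tce, e_avg$estimates$tce, tolerance = 0.01)
})

test_that("nie approximates the product-of-coefficients rule for a rare
           outcome with gaussian mediator", {
  set.seed(808)
  n <- 100000
  c1 <- rnorm(n)
  x <- rbinom(n, 1, 0.5)
  b_xm <- 0.3; g_m <- 0.4
  m <- 1 + b_xm * x + 0.3 * c1 + rnorm(n)
  y <- rbinom(n, 1, stats::plogis(-4.3 + 0.3 * x + g_m * m + 0.1 * c1))
  expect_lt(mean(y), 0.05) # rare-outcome regime
  d <- data.frame(x_helpful = x, bses_total = m, c1 = c1, y_exclusive = y)
  adj <- list(mediator = "c1", outcome = "c1")
  est <- gcomp_estimate(d, adjustment = adj, mediator_scale = "raw",
                        mc_draws = 150, rng_seed = 77)
  # product of the fitted exposure->mediator and mediator->outcome
  # coefficients, scaled by the bernoulli variance at mu_10
  a_hat <- est$model_m$coefficients[["x_helpful"]]
  b_hat <- est$model_y$coefficients[["bses_total"]]
  mu10 <- est$means[["mu_10"]]
  approx_nie <- a_hat * b_hat * mu10 * (1 - mu10)
  expect_lt(abs(est$estimates$nie - approx_nie) / abs(approx_nie), 0.10)
})
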