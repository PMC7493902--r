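test_that("marginal log-likelihood matches a Simpson quadrature oracle", {
  toy <- toy_records(seed = 2, n_per_cluster = 5, n_clusters = 2)
  spec <- anc_model_spec("y_any", "intention")
  des <- ancbayes:::build_design(spec, toy)
  for (case in list(list(beta = c(0.3, -0.2, 0.1), sigma = 0.7),
                    list(beta = c(-0.5, 0.4, 0.0), sigma = 1.5),
                    list(beta = c(0, 0, 0), sigma = 0.2))) {
    agq <- marginal_loglik(case$beta, case$sigma, design = des)
    orc <- simpson_marginal_ll(des, case$beta, case$sigma)
    expect_lt(abs(agq - orc), 1e-4)
  }
  # sigma = 0 collapses to the weighted Bernoulli log-likelihood
  beta <- c(0.2, 0.1, -0.1)
  eta <- as.numeric(des$X %*% beta)
  plain <- sum(des$w * (des$y * eta - log1p(exp(eta))))
  expect_equal(marginal_loglik(beta, 0, design = des), plain,
               tolerance = 1e-12)
  expect_error(marginal_loglik(beta, -1, design = des), "non-negative")
})

test_that("ML fit reduces to ordinary logistic regression when sigma_u = 0", {
  # direct check of the pseudo-likelihood surface: optimizing it at
  # sigma_u = 0 with equal weights reproduces glm() coefficients
  withr::with_seed(41, {
    n <- 400
    toy <- data.frame(cluster_id = rep(1:40, each = 10), weight = 1,
                      xc = rnorm(n), birth_within_3y = TRUE)
    toy$y_any <- rbinom(n, 1, plogis(-0.3 + 0.8 * toy$xc))
  })
  spec <- anc_model_spec("y_any", "xc")
  des <- ancbayes:::build_design(spec, toy)
  opt <- optim(c(0, 0), function(b) -marginal_loglik(b, 0, design = des),
               method = "BFGS",
               control = list(reltol = 1e-14, maxit = 2000))
  ref <- glm(y_any ~ xc, binomial(), toy)
  expect_equal(opt$par, unname(coef(ref)), tolerance = 1e-6)

  # the full ML route lands near the same answer (sigma_u^2 near 0)
  ml <- fit_ml(spec, toy)
  expect_lt(ml$sigma_u2_hat, 0.05)
  expect_equal(unname(ml$beta_hat), unname(coef(ref)), tolerance = 0.02)
})

test_that("ML fit agrees with the quadrature oracle at its own estimates", {
  withr::with_seed(21, {
    toy <- data.frame(cluster_id = rep(1:2, each = 5), weight = 1,
                      y_any = c(1, 0, 1, 1, 0, 0, 0, 1, 0, 0),
                      xc = rnorm(10), birth_within_3y = TRUE)
  })
  spec <- anc_model_spec("y_any", "xc")
  ml <- fit_ml(spec, toy)
  des <- ancbayes:::build_design(spec, toy)
  orc <- simpson_marginal_ll(des, ml$beta_hat, sqrt(ml$sigma_u2_hat))
  expect_lt(abs(ml$log_likelihood - orc), 1e-4)
  expect_equal(ml$k, 3L)
  expect_equal(ml$aic, -2 * ml$log_likelihood + 6, tolerance = 1e-12)
  expect_equal(ml$bic, -2 * ml$log_likelihood + 3 * log(10),
               tolerance = 1e-12)
})

test_that("intercept-only fit recovers a 50% prevalence intercept", {
  withr::with_seed(51, {
    toy <- data.frame(cluster_id = rep(1:50, each = 10), weight = 1,
                      y_any = rbinom(500, 1, 0.5), birth_within_3y = TRUE)
  })
  ml <- fit_ml(anc_model_spec("y_any", character(0)), toy)
  se <- sqrt(ml$vcov_beta[1, 1])
  expect_lt(abs(ml$beta_hat[["(Intercept)"]]), 3 * se)
})

test_that("single-run parameter recovery at survey scale", {
  w <- generate_wave(recovery_config(n_clusters = 150, seed = 611))
  d <- derive_variables(w$women)
  spec <- anc_model_spec("y_any", "intention")
  ml <- fit_ml(spec, d, nAGQ = 7)
  se_m <- sqrt(ml$vcov_beta["intention_mistimed", "intention_mistimed"])
  se_u <- sqrt(ml$vcov_beta["intention_unwanted", "intention_unwanted"])
  expect_lt(abs(ml$beta_hat[["intention_mistimed"]] + 0.3), 3 * se_m)
  expect_lt(abs(ml$beta_hat[["intention_unwanted"]] + 0.37), 3 * se_u)
  expect_lt(abs(ml$sigma_u2_hat - 0.64), 0.25)
})

test_that("fit errors are reported, not silently repaired", {
  toy <- toy_records()
  toy$y_any <- 1
  expect_error(fit_ml(anc_model_spec("y_any", "intention"), toy),
               "single class")
  toy2 <- toy_records()
  toy2$cluster_id <- 1
  expect_error(fit_ml(anc_model_spec("y_any", "intention"), toy2),
               "2 clusters")
  # perfectly separating covariate flagged
  withr::with_seed(8, {
    sep <- data.frame(cluster_id = rep(1:10, each = 10), weight = 1,
                      xc = rep(c(-1, 1), 50), birth_within_3y = TRUE)
    sep$y_any <- as.integer(sep$xc > 0)
  })
  expect_warning(fit_ml(anc_model_spec("y_any", "xc"), sep),
                 "separation")
})

test_that("estimates are invariant to cluster relabeling and weight rescaling", {
  toy <- toy_records(seed = 4, n_per_cluster = 20, n_clusters = 8)
  spec <- anc_model_spec("y_any", "intention")
  ml <- fit_ml(spec, toy)
  relab <- toy
  relab$cluster_id <- match(relab$cluster_id, sample(unique(relab$cluster_id))) + 100
  ml2 <- fit_ml(spec, relab)
  expect_equal(ml$beta_hat, ml2$beta_hat, tolerance = 1e-6)
  expect_equal(ml$sigma_u2_hat, ml2$sigma_u2_hat, tolerance = 1e-6)
  scaled <- toy
  scaled$weight <- scaled$weight * 37.5
  ml3 <- fit_ml(spec, scaled)
  expect_equal(ml$beta_hat, ml3$beta_hat, tolerance = 1e-10)
  expect_equal(ml$log_likelihood, ml3$log_likelihood, tolerance = 1e-8)
})

test_that("MCMC is reproducible and respects chain settings", {
  toy <- toy_records(seed = 4, n_per_cluster = 20, n_clusters = 8)
  spec <- anc_model_spec("y_any", "intention")
  ml <- fit_ml(spec, toy)
  pr <- noninformative_prior(ml)
  mc1 <- run_mcmc(spec, toy, pr, n_chains = 2, n_burnin = 100, n_kept = 200,
                  seed = 77, ml_fit = ml)
  mc2 <- run_mcmc(spec, toy, pr, n_chains = 2, n_burnin = 100, n_kept = 200,
                  seed = 77, ml_fit = ml)
  expect_identical(mc1$chains, mc2$chains)
  mc3 <- run_mcmc(spec, toy, pr, n_chains = 2, n_burnin = 100, n_kept = 200,
                  seed = 78, ml_fit = ml)
  expect_false(identical(mc1$chains, mc3$chains))
  expect_equal(dim(mc1$chains[[1]]), c(200L, 4L))  # 3 coefs + sigma_u
  expect_true(all(do.call(rbind, mc1$chains)[, "sigma_u"] >= 0))
  expect_error(run_mcmc(spec, toy, pr, n_chains = 0, n_burnin = 10,
                        n_kept = 10), "positive")
})

test_that("a near-degenerate prior pins the posterior at its mean", {
  toy <- toy_records(seed = 9, n_per_cluster = 10, n_clusters = 2)
  spec <- anc_model_spec("y_any", character(0))
  target <- 0.8
  pr <- make_prior(c("(Intercept)" = target), c("(Intercept)" = 1e-8))
  mc <- run_mcmc(spec, toy, pr, n_chains = 2, n_burnin = 500, n_kept = 2000,
                 seed = 5, sample_sigma = FALSE)
  post_mean <- mean(do.call(rbind, mc$chains)[, "(Intercept)"])
  expect_lt(abs(post_mean - target), 1e-2)
})

test_that("flat-prior posterior means match ML estimates on large data", {
  w <- generate_wave(sim_config(n_clusters = 100, households_per_cluster = 20,
                                eligible_fraction = 1, seed = 303))
  d <- derive_variables(w$women)
  spec <- anc_model_spec("y_any", "intention")
  ml <- fit_ml(spec, d, nAGQ = 7)
  pr <- noninformative_prior(ml)
  mc <- run_mcmc(spec, d, pr, n_chains = 2, n_burnin = 600, n_kept = 1500,
                 seed = 6, ml_fit = ml, n_gh = 7)
  draws <- do.call(rbind, mc$chains)
  for (nm in names(ml$beta_hat)) {
    mcse <- sd(draws[, nm]) / sqrt(100)  # conservative effective size
    expect_lt(abs(mean(draws[, nm]) - ml$beta_hat[[nm]]),
              max(3 * mcse, 0.05))
  }
})

test_that("posterior summaries transform draws correctly", {
  chains <- list(matrix(log(2), 100, 1, dimnames = list(NULL, "b")),
                 matrix(log(2), 100, 1, dimnames = list(NULL, "b")))
  mc <- structure(list(chains = chains, n_chains = 2, n_kept = 100,
                       sample_sigma = FALSE, coef_names = "b"),
                  class = "mcmc_result")
  ps <- posterior_summary(mc)
  expect_equal(ps$table$or, 2, tolerance = 1e-12)
  expect_equal(ps$table$or_lower, 2, tolerance = 1e-12)
  expect_equal(ps$table$or_upper, 2, tolerance = 1e-12)

  withr::with_seed(12, {
    z <- matrix(rnorm(1e5), ncol = 1, dimnames = list(NULL, "b"))
  })
  mc2 <- structure(list(chains = list(z[1:50000, , drop = FALSE],
                                      z[50001:1e5, , drop = FALSE]),
                        n_chains = 2, n_kept = 50000, sample_sigma = FALSE,
                        coef_names = "b"),
                   class = "mcmc_result")
  ps2 <- posterior_summary(mc2)
  expect_equal(ps2$table$or_lower, exp(-1.96), tolerance = 0.03)
  expect_equal(ps2$table$or_upper, exp(1.96), tolerance = 0.03)

  # pooling chains with different means widens the interval
  c1 <- matrix(rnorm(5000, -1, 0.2), ncol = 1, dimnames = list(NULL, "b"))
  c2 <- matrix(rnorm(5000, 1, 0.2), ncol = 1, dimnames = list(NULL, "b"))
  width <- function(ch) {
    q <- quantile(exp(ch[, 1]), c(0.025, 0.975))
    q[2] - q[1]
  }
  mc3 <- structure(list(chains = list(c1, c2), n_chains = 2, n_kept = 5000,
                        sample_sigma = FALSE, coef_names = "b"),
                   class = "mcmc_result")
  ps3 <- posterior_summary(mc3)
  expect_gt(ps3$table$or_upper - ps3$table$or_lower,
            max(width(c1), width(c2)))
  expect_error(posterior_summary(structure(list(chains = list()),
                                           class = "mcmc_result")),
               "empty")
})

test_that("grid posterior honours symmetry, flat-prior mode and conjugacy", {
  # symmetric data + symmetric prior: mean 0
  y <- rep(c(0, 1), 10)
  g <- exact_grid_posterior(y, matrix(1, 20, 1), prior_var = 4)
  expect_lt(abs(g$mean), 1e-10)

  # flat prior: mode/mean near the ML estimate
  y2 <- rep(c(1, 0), c(18, 42))
  g2 <- exact_grid_posterior(y2, matrix(1, 60, 1))
  mle <- qlogis(mean(y2))
  expect_lt(abs(g2$mean - mle), 0.1)  # flat-prior posterior mean ~ MLE

  # tight prior: conjugate normal-normal limit with the Fisher information
  m0 <- 0.3; v0 <- 0.01
  y3 <- rep(c(1, 0), c(14, 6))
  g3 <- exact_grid_posterior(y3, matrix(1, 20, 1), prior_mean = m0,
                             prior_var = v0, lower = -2, upper = 2)
  p0 <- plogis(m0)
  info <- 20 * p0 * (1 - p0)
  score <- sum(y3) - 20 * p0
  post_var <- 1 / (1 / v0 + info)
  post_mean <- m0 + post_var * score
  expect_lt(abs(g3$mean - post_mean), 1e-3)
  expect_lt(abs(g3$sd - sqrt(post_var)), 1e-3)

  expect_error(exact_grid_posterior(y, matrix(1, 20, 3)), "at most 2")
  expect_error(exact_grid_posterior(rep(y, 20), matrix(1, 400, 1)),
               "at most 200")
})
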