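test_that("non-informative priors are Normal(0, 10000) per coefficient", {
  pr <- noninformative_prior(c("(Intercept)", "intention_mistimed",
                               "intention_unwanted"))
  expect_length(pr$mean, 3)
  expect_true(all(pr$mean == 0))
  expect_true(all(pr$var == 10000))
  expect_equal(pr$provenance, "noninformative")

  pr1 <- noninformative_prior("(Intercept)")
  expect_length(pr1$mean, 1)
  expect_error(noninformative_prior(character(0)), "no coefficients")

  # resolution from a model spec + data
  toy <- toy_records()
  pr2 <- noninformative_prior(anc_model_spec("y_any", "intention"), toy)
  expect_setequal(names(pr2$mean),
                  c("(Intercept)", "intention_mistimed",
                    "intention_unwanted"))
})

test_that("prior/model coefficient mismatch is caught at fit time", {
  toy <- toy_records()
  pr <- noninformative_prior(c("(Intercept)", "wrong_name"))
  expect_error(run_mcmc(anc_model_spec("y_any", "intention"), toy, pr,
                        n_chains = 1, n_burnin = 10, n_kept = 10),
               "prior covers")
})

test_that("combine_priors implements the across-wave moment rule", {
  mk <- function(means, sds, year) list(mean = means, sd = sds,
                                        year_label = year)
  cn <- c("(Intercept)", "b")
  waves <- list(mk(setNames(c(0, 0), cn), setNames(c(1e-6, 1e-6), cn), 2004),
                mk(setNames(c(1, 1), cn), setNames(c(1e-6, 1e-6), cn), 2007),
                mk(setNames(c(2, 2), cn), setNames(c(1e-6, 1e-6), cn), 2011))
  pr <- combine_priors(waves)
  expect_equal(unname(pr$mean), c(1, 1))
  expect_equal(unname(pr$var), c(1, 1), tolerance = 1e-9)
  expect_equal(pr$provenance, "elicited")
  expect_equal(pr$source_waves, c(2004L, 2007L, 2011L))

  # floor rule engages when waves agree exactly
  same <- list(mk(c(b = 0.5), c(b = 0.1), 1),
               mk(c(b = 0.5), c(b = 0.1), 2),
               mk(c(b = 0.5), c(b = 0.1), 3))
  prf <- combine_priors(same)
  expect_equal(unname(prf$mean), 0.5)
  expect_equal(unname(prf$var), 0.01)

  # two waves, hand arithmetic: mean -0.3, var = sd(c(-.2,-.4))^2 = 0.02
  two <- list(mk(c(b = -0.2), c(b = 0.01), 1),
              mk(c(b = -0.4), c(b = 0.01), 2))
  pr2 <- combine_priors(two)
  expect_equal(unname(pr2$mean), -0.3)
  expect_equal(unname(pr2$var), 0.02, tolerance = 1e-9)

  # drifting coefficient across the three historical waves
  drift <- list(mk(c(b = -0.30), c(b = 0.001), 2004),
                mk(c(b = -0.32), c(b = 0.001), 2007),
                mk(c(b = -0.34), c(b = 0.001), 2011))
  expect_equal(unname(combine_priors(drift)$mean), -0.32)

  # order invariance of the elicited mean/variance
  expect_equal(combine_priors(waves[c(3, 1, 2)])$mean, pr$mean)
  expect_equal(combine_priors(waves[c(3, 1, 2)])$var, pr$var)

  expect_error(combine_priors(waves[1]), "at least 2")
  bad <- list(mk(c(b = 0), c(b = 1), 1), mk(c(c = 0), c(c = 1), 2))
  expect_error(combine_priors(bad), "mismatched")
})

test_that("historical fits recover the truth and elicited priors are informative", {
  cfgs <- lapply(1:3, function(i)
    sim_config(n_clusters = 60, households_per_cluster = 10,
               eligible_fraction = 1, year_label = 2000L + 3 * i,
               seed = 300 + i,
               beta = c(intention_mistimed = -0.3,
                        intention_unwanted = -0.37),
               sigma_u = 0.5, offset_any = 0, offset_four = -1.2))
  waves <- generate_panel(cfgs)
  spec <- anc_model_spec("y_any", "intention")
  posts <- lapply(seq_along(waves), function(i)
    fit_historical_wave(waves[[i]], spec, n_chains = 2, n_burnin = 400,
                        n_kept = 800, seed = 400 + i))
  for (p in posts) {
    se <- p$sd["intention_mistimed"]
    expect_lt(abs(p$mean["intention_mistimed"] + 0.3), 3 * se)
  }
  pr <- combine_priors(posts)
  expect_true(all(pr$var <= 10000))
  expect_true(all(pr$var < 10000))
  expect_lt(abs(pr$mean["intention_mistimed"] + 0.3), 0.35)

  # a wave lacking a model variable errors cleanly
  broken <- waves[[1]]
  broken$women$intention <- NULL
  expect_error(fit_historical_wave(broken, spec, n_chains = 1,
                                   n_burnin = 10, n_kept = 10),
               "model variables|required columns")
})

test_that("priors round-trip through JSON", {
  pr <- noninformative_prior(c("(Intercept)", "b"))
  pr$mean[] <- c(0.25, -0.5)
  pr$var[] <- c(0.5, 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_prior(pr, path)
  pr2 <- read_prior(path)
  expect_equal(pr2$mean, pr$mean)
  expect_equal(pr2$var, pr$var)
  expect_equal(pr2$provenance, pr$provenance)
})
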