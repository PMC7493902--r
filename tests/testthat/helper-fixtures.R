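# Shared fixtures and independent oracles used across the suite.

# prior_spec built by hand (bypasses the constructor on purpose, so prior
# machinery can be exercised independently of model fitting)
make_prior <- function(mean, var) {
  structure(list(mean = mean, var = var[names(mean)] %||% var,
                 provenance = "noninformative", source_waves = integer(0)),
            class = "prior_spec")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Simpson's-rule marginal likelihood oracle for the random-intercept logit:
# integrates exp(sum_i w_i * bernoulli_ll_i(u)) * dnorm(u, 0, sigma) over
# u in [-10 sigma, 10 sigma]. Brute force, independent of the AGQ code path.
simpson_marginal_ll <- function(design, beta, sigma, n_points = 10000) {
  eta <- as.numeric(design$X %*% beta)
  simpson <- function(f, a, b, n) {
    xs <- seq(a, b, length.out = n + 1)
    h <- (b - a) / n
    wts <- c(1, rep(c(4, 2), (n - 2) / 2), 4, 1)
    sum(wts * vapply(xs, f, 0)) * h / 3
  }
  ll <- 0
  for (j in unique(design$cluster)) {
    idx <- design$cluster == j
    f <- function(u) {
      e <- eta[idx] + u
      exp(sum(design$w[idx] * (design$y[idx] * e - log1p(exp(e))))) *
        dnorm(u, 0, sigma)
    }
    ll <- ll + log(simpson(f, -10 * sigma, 10 * sigma, n_points))
  }
  ll
}

# small two-cluster toy used by several oracle checks
toy_records <- function(seed = 2, n_per_cluster = 5, n_clusters = 2) {
  withr::with_seed(seed, {
    n <- n_per_cluster * n_clusters
    data.frame(cluster_id = rep(seq_len(n_clusters), each = n_per_cluster),
               weight = runif(n, 0.5, 1.5),
               y_any = rbinom(n, 1, 0.5),
               intention = sample(c("wanted", "mistimed", "unwanted"), n,
                                  replace = TRUE),
               xc = rnorm(n),
               birth_within_3y = TRUE)
  })
}

# intention-only recovery configuration (the simulation-study truth:
# beta_mistimed = -0.3, beta_unwanted = -0.37, sigma_u = 0.8)
recovery_config <- function(n_clusters, seed) {
  sim_config(n_clusters = n_clusters, households_per_cluster = 30,
             seed = seed, eligible_fraction = 1,
             beta = c(intention_mistimed = -0.3, intention_unwanted = -0.37),
             sigma_u = 0.8, offset_any = 0, offset_four = -1.2)
}
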