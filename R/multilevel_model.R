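#' Specify a survey-weighted random-intercept logistic model
#'
#' Fixes the outcome coding, the fixed-effect terms and the bookkeeping
#' columns (weights, cluster) for downstream fitting. Categorical terms use
#' the package's reference-first level conventions (wanted pregnancy,
#' illiterate, age <= 19, <= 2 children, agricultural worker, not exposed,
#' poorest, urban, Barishal, low community literacy, high community poverty,
#' high community four-visit uptake).
#'
#' @param outcome `"y_any"` (at least one skilled visit) or `"y_four"`
#'   (at least four skilled visits).
#' @param terms character vector of fixed-effect variable names (the
#'   intercept is always included).
#' @param weight_col,cluster_col column names holding the survey weight and
#'   cluster id.
#' @return object of class `anc_model_spec`.
#' @export
anc_model_spec <- function(outcome = c("y_any", "y_four"),
                           terms = c("intention"),
                           weight_col = "weight",
                           cluster_col = "cluster_id") {
  outcome <- match.arg(outcome)
  structure(list(outcome = outcome, terms = terms,
                 weight_col = weight_col, cluster_col = cluster_col),
            class = "anc_model_spec")
}

# Build the fixed-effect design matrix with columns "(Intercept)" and
# "<variable>_<level>" for each non-reference level, ordered by cluster.
build_design <- function(spec, data) {
  miss <- setdiff(c(spec$terms, spec$outcome, spec$weight_col,
                    spec$cluster_col), names(data))
  if (length(miss))
    stop("data lack model variables: ", paste(miss, collapse = ", "))
  ord <- order(data[[spec$cluster_col]])
  data <- data[ord, , drop = FALSE]
  n <- nrow(data)
  cols <- list("(Intercept)" = rep(1, n))
  for (v in spec$terms) {
    x <- data[[v]]
    if (is.numeric(x)) {
      cols[[v]] <- x
    } else {
      f <- if (is.factor(x)) x else as_anc_factor(x, v)
      if (v %in% names(anc_levels)) f <- as_anc_factor(as.character(f), v)
      for (lev in levels(f)[-1]) {
        if (any(f == lev, na.rm = TRUE))
          cols[[paste0(v, "_", lev)]] <- as.numeric(f == lev)
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  y <- data[[spec$outcome]]
  w <- data[[spec$weight_col]]
  cluster <- data[[spec$cluster_col]]
  keep <- stats::complete.cases(X) & !is.na(y) & !is.na(w)
  X <- X[keep, , drop = FALSE]
  list(X = X, y = as.numeric(y[keep]), w = as.numeric(w[keep]),
       cluster = cluster[keep], n_dropped = sum(!keep))
}

cluster_index <- function(cluster) {
  r <- rle(as.character(cluster))
  len <- r$lengths
  list(start = as.integer(cumsum(c(0L, len[-length(len)]))),
       len = as.integer(len))
}

#' Weighted marginal log-likelihood of the random-intercept logit model
#'
#' Integrates the cluster intercept out by adaptive Gauss-Hermite quadrature
#' (mode-centred, curvature-scaled), with each woman's Bernoulli
#' log-likelihood contribution multiplied by her survey weight
#' (pseudo-likelihood). Weights are used as passed (not renormalized).
#'
#' @param beta coefficient vector in design-column order.
#' @param sigma_u random-intercept standard deviation (>= 0).
#' @param design list from the internal design builder, or pass `spec` and
#'   `data` instead.
#' @param spec,data alternative input: an [anc_model_spec()] plus derived
#'   records.
#' @param n_gh number of quadrature nodes (default 11).
#' @return log pseudo-likelihood (scalar).
#' @export
marginal_loglik <- function(beta, sigma_u, design = NULL, spec = NULL,
                            data = NULL, n_gh = 11) {
  if (is.null(design)) design <- build_design(spec, data)
  if (sigma_u < 0) stop("'sigma_u' must be non-negative")
  ci <- cluster_index(design$cluster)
  gh <- gh_rule(n_gh)
  eta <- as.numeric(design$X %*% beta)
  agq_loglik_cpp(eta, design$y, design$w, ci$start, ci$len, sigma_u,
                 gh$x, gh$logw)
}

#' Maximum-likelihood fit of the survey-weighted multilevel logit model
#'
#' Fits the random-intercept logistic regression by adaptive Gauss-Hermite
#' maximum likelihood (via [lme4::glmer()]), with survey weights normalized
#' to sum to the sample size entering as pseudo-likelihood case weights.
#' Supplies the maximum-likelihood estimators used as starting values for
#' the MCMC stage, plus AIC/BIC inputs.
#'
#' @param spec an [anc_model_spec()].
#' @param data derived records.
#' @param nAGQ adaptive quadrature nodes (default 11, at least 7 advised).
#' @return object of class `ml_fit`: `beta_hat`, `sigma_u2_hat`,
#'   `log_likelihood`, `k` (fixed effects + 1 variance parameter), `n_obs`,
#'   `aic`, `bic`, `vcov_beta`, `separation` flag.
#' @export
fit_ml <- function(spec, data, nAGQ = 11) {
  design <- build_design(spec, data)
  if (length(unique(design$cluster)) < 2)
    stop("need at least 2 clusters")
  if (length(unique(design$y)) < 2)
    stop("outcome has a single class")
  n <- nrow(design$X)
  p <- ncol(design$X)
  w_norm <- design$w * n / sum(design$w)
  safe <- paste0("x", seq_len(p))
  dd <- as.data.frame(design$X)
  names(dd) <- safe
  dd$.y <- design$y
  dd$.cl <- design$cluster
  dd$.w <- w_norm
  f <- as.formula(paste(".y ~ 0 +", paste(safe, collapse = " + "),
                        "+ (1 | .cl)"))
  fit <- withCallingHandlers(
    lme4::glmer(f, data = dd, family = stats::binomial(), weights = .w,
                nAGQ = nAGQ,
                control = lme4::glmerControl(calc.derivs = FALSE,
                                             check.nlev.gtr.1 = "ignore")),
    warning = function(w) {
      if (grepl("non-integer", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- lme4::fixef(fit)
  names(beta) <- colnames(design$X)
  sigma_u2 <- as.numeric(lme4::VarCorr(fit)$.cl[1, 1])
  ll <- as.numeric(stats::logLik(fit))
  k <- p + 1L
  vc <- tryCatch(as.matrix(stats::vcov(fit)), error = function(e) diag(0.1, p))
  dimnames(vc) <- list(colnames(design$X), colnames(design$X))
  separation <- any(abs(beta) > 10)
  if (separation)
    warning("very large coefficient estimates: possible complete separation")
  structure(list(beta_hat = beta, sigma_u2_hat = sigma_u2,
                 log_likelihood = ll, k = k, n_obs = n,
                 aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(n),
                 vcov_beta = vc, separation = separation,
                 spec = spec),
            class = "ml_fit")
}

#' @export
print.ml_fit <- function(x, ...) {
  cat("<ml_fit>", x$n_obs, "obs; logLik", round(x$log_likelihood, 2),
      "; sigma_u^2 =", signif(x$sigma_u2_hat, 4), "\n")
  print(round(x$beta_hat, 4))
  invisible(x)
}

#' MCMC for the survey-weighted multilevel logit model under normal priors
#'
#' Samples the fixed effects and the cluster-intercept standard deviation
#' from the posterior proportional to the weighted marginal pseudo-likelihood
#' (cluster intercepts integrated out by adaptive Gauss-Hermite quadrature)
#' times independent normal priors on the coefficients and a Half-Normal
#' prior on `sigma_u`. The kernel is an adaptive random-walk Metropolis
#' whose proposal shape comes from the maximum-likelihood covariance and
#' whose global step scale is tuned during burn-in only; chains start from
#' jittered maximum-likelihood estimates.
#'
#' @param spec an [anc_model_spec()].
#' @param data derived records.
#' @param prior a [prior_spec][noninformative_prior()] covering exactly the
#'   model's coefficients.
#' @param n_chains,n_burnin,n_kept,thin chain settings (defaults 3 chains,
#'   5000 burn-in, 10000 kept, no thinning).
#' @param seed integer seed; the full run is reproducible from it.
#' @param ml_fit optional pre-computed [fit_ml()] result.
#' @param sample_sigma if `FALSE`, `sigma_u` is fixed at 0 and only the
#'   fixed effects are sampled (used by the oracle fixtures).
#' @param sigma_prior_scale Half-Normal scale for the `sigma_u` prior
#'   (default 5).
#' @param n_gh quadrature nodes (default 11).
#' @return object of class `mcmc_result`: list of per-chain draw matrices
#'   (columns: coefficients, then `sigma_u` when sampled), settings, prior,
#'   acceptance rates.
#' @export
run_mcmc <- function(spec, data, prior, n_chains = 3, n_burnin = 5000,
                     n_kept = 10000, thin = 1, seed = 1L, ml_fit = NULL,
                     sample_sigma = TRUE, sigma_prior_scale = 5, n_gh = 11) {
  if (n_chains < 1 || n_burnin < 0 || n_kept < 1 || thin < 1)
    stop("chain settings must be positive")
  design <- build_design(spec, data)
  cn <- colnames(design$X)
  if (!setequal(names(prior$mean), cn))
    stop("prior covers coefficients {",
         paste(names(prior$mean), collapse = ", "),
         "} but the model has {", paste(cn, collapse = ", "), "}")
  pm <- prior$mean[cn]
  pv <- prior$var[cn]
  if (any(pv <= 0)) stop("prior variances must be positive")
  n <- nrow(design$X)
  w_norm <- design$w * n / sum(design$w)
  ci <- cluster_index(design$cluster)
  gh <- gh_rule(n_gh)
  if (is.null(ml_fit)) ml_fit <- fit_ml(spec, data)
  if (!identical(names(ml_fit$beta_hat), cn))
    stop("'ml_fit' does not match the model specification")
  p <- length(cn)
  d <- p + as.integer(sample_sigma)
  theta0 <- ml_fit$beta_hat
  Sig <- matrix(0, d, d)
  Sig[seq_len(p), seq_len(p)] <- ml_fit$vcov_beta
  if (sample_sigma) {
    theta0 <- c(theta0, log(max(sqrt(ml_fit$sigma_u2_hat), 0.05)))
    Sig[d, d] <- 0.05
  }
  Sig <- Sig + diag(1e-8, d)
  L <- t(chol(Sig))
  chains <- vector("list", n_chains)
  accept <- numeric(n_chains)
  with_seed(seed, {
    for (ch in seq_len(n_chains)) {
      init <- theta0 + as.numeric(L %*% rnorm(d))
      res <- rwm_sample_cpp(design$X, design$y, w_norm, ci$start, ci$len,
                            pm, pv, sigma_prior_scale, init, L,
                            as.integer(n_burnin), as.integer(n_kept),
                            as.integer(thin), sample_sigma, gh$x, gh$logw)
      draws <- res$draws
      colnames(draws) <- if (sample_sigma) c(cn, "sigma_u") else cn
      chains[[ch]] <- draws
      accept[ch] <- res$accept_rate
    }
  })
  structure(list(chains = chains, n_chains = n_chains, n_burnin = n_burnin,
                 n_kept = n_kept, thin = thin, seed = seed, prior = prior,
                 sample_sigma = sample_sigma, accept_rate = accept,
                 coef_names = cn, spec = spec),
            class = "mcmc_result")
}

#' @export
print.mcmc_result <- function(x, ...) {
  cat("<mcmc_result>", x$n_chains, "chains x", x$n_kept, "kept draws;",
      "mean acceptance", round(mean(x$accept_rate), 3), "\n")
  invisible(x)
}

#' Posterior summary: odds ratios with 95% credible intervals
#'
#' Pools kept draws across chains. The odds-ratio point estimate is the
#' posterior mean of `exp(beta)`; the credible interval is the equal-tailed
#' 2.5th/97.5th percentile of the `exp(beta)` draws. Log-odds summaries and
#' the posterior mean of the cluster variance (with its latent-scale ICC)
#' are reported alongside.
#'
#' @param mcmc an `mcmc_result` (at least one chain of kept draws).
#' @param prob interval mass (default 0.95).
#' @return object of class `posterior_summary`: `table` (one row per
#'   coefficient: `term`, `beta_mean`, `beta_sd`, `or`, `or_lower`,
#'   `or_upper`), `sigma_u2_mean`, `icc`, `n_draws`.
#' @export
posterior_summary <- function(mcmc, prob = 0.95) {
  if (length(mcmc$chains) == 0 || nrow(mcmc$chains[[1]]) == 0)
    stop("empty chains")
  draws <- do.call(rbind, mcmc$chains)
  a <- (1 - prob) / 2
  cn <- mcmc$coef_names
  tab <- do.call(rbind, lapply(cn, function(nm) {
    b <- draws[, nm]
    e <- exp(b)
    data.frame(term = nm, beta_mean = mean(b), beta_sd = sd(b),
               or = mean(e),
               or_lower = as.numeric(quantile(e, a)),
               or_upper = as.numeric(quantile(e, 1 - a)),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  s2 <- if (mcmc$sample_sigma) mean(draws[, "sigma_u"]^2) else 0
  structure(list(table = tab, sigma_u2_mean = s2, icc = icc_latent(s2),
                 n_draws = nrow(draws), prob = prob),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, digits = 3, ...) {
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("sigma_u^2 posterior mean %.4f (latent ICC %.4f), %d draws\n",
              x$sigma_u2_mean, x$icc, x$n_draws))
  invisible(x)
}

#' Deterministic grid posterior for tiny logistic models (test oracle)
#'
#' Computes posterior moments of at most two logistic-regression
#' coefficients (cluster variance fixed at zero) by trapezoidal quadrature
#' on a regular grid, under independent normal priors. Intended as an
#' exact, sampler-free reference for MCMC correctness checks on small
#' fixtures.
#'
#' @param y 0/1 outcomes (at most 200).
#' @param X design matrix with 1 or 2 columns.
#' @param weights optional case weights (default 1).
#' @param prior_mean,prior_var normal prior moments per coefficient.
#' @param lower,upper grid range per coefficient (default -10, 10).
#' @param grid_points points per dimension (default 1e5 in 1D, 401 in 2D).
#' @return list with `mean`, `sd` per coefficient and the grid step
#'   (`resolution`).
#' @export
exact_grid_posterior <- function(y, X, weights = NULL,
                                 prior_mean = 0, prior_var = 10000,
                                 lower = -10, upper = 10,
                                 grid_points = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p > 2) stop("at most 2 free parameters are supported")
  n <- length(y)
  if (n > 200) stop("oracle restricted to at most 200 observations")
  if (is.null(weights)) weights <- rep(1, n)
  prior_mean <- rep_len(prior_mean, p)
  prior_var <- rep_len(prior_var, p)
  lower <- rep_len(lower, p)
  upper <- rep_len(upper, p)
  if (is.null(grid_points)) grid_points <- if (p == 1) 1e5 else 401
  grids <- lapply(seq_len(p), function(k)
    seq(lower[k], upper[k], length.out = grid_points))
  l1pe <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
  logpost <- function(bmat) {
    eta <- X %*% t(bmat)                       # n x G
    ll <- colSums(weights * (y * eta - l1pe(eta)))
    lp <- colSums(dnorm(t(bmat), prior_mean, sqrt(prior_var), log = TRUE))
    ll + lp
  }
  if (p == 1) {
    g <- grids[[1]]
    lp <- numeric(length(g))
    for (blk in split(seq_along(g), ceiling(seq_along(g) / 5000)))
      lp[blk] <- logpost(matrix(g[blk], ncol = 1))
    wts <- exp(lp - max(lp))
    Z <- sum(wts)
    m1 <- sum(wts * g) / Z
    m2 <- sum(wts * g^2) / Z
    list(mean = m1, sd = sqrt(max(m2 - m1^2, 0)),
         resolution = g[2] - g[1])
  } else {
    g1 <- grids[[1]]; g2 <- grids[[2]]
    grid <- as.matrix(expand.grid(g1, g2))
    lp <- numeric(nrow(grid))
    for (blk in split(seq_len(nrow(grid)), ceiling(seq_len(nrow(grid)) / 5000)))
      lp[blk] <- logpost(grid[blk, , drop = FALSE])
    wts <- exp(lp - max(lp))
    Z <- sum(wts)
    m <- colSums(wts * grid) / Z
    v <- colSums(wts * grid^2) / Z - m^2
    list(mean = m, sd = sqrt(pmax(v, 0)),
         resolution = c(g1[2] - g1[1], g2[2] - g2[1]))
  }
}
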