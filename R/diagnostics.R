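#' Latent-scale intra-class correlation for the multilevel logit model
#'
#' Under the latent-response formulation of the logistic model the
#' individual-level residual has variance pi^2/3, so the share of latent
#' variance attributable to clusters is
#' `sigma_u2 / (sigma_u2 + pi^2/3)`.
#'
#' @param sigma_u2 cluster-intercept variance (>= 0), scalar or vector.
#' @return ICC in \[0, 1).
#' @export
icc_latent <- function(sigma_u2) {
  if (any(sigma_u2 < 0)) stop("'sigma_u2' must be non-negative")
  sigma_u2 / (sigma_u2 + pi^2 / 3)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes the classic between/within-chain variance ratio with the
#' finite-sample correction: with m chains of length n,
#' `Rc = sqrt(((n-1)/n * W + B/n) / W)` where `W` is the mean within-chain
#' variance and `B/n` the variance of the chain means.
#'
#' @param chains a list of numeric vectors (one parameter), or a matrix with
#'   one column per chain.
#' @return `Rc` (scalar).
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  m <- length(chains)
  if (m < 2) stop("need at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("chains must have equal length")
  if (n < 10) stop("chains must have length >= 10")
  W <- mean(vapply(chains, var, 0))
  if (W == 0) stop("zero within-chain variance in all chains")
  B_over_n <- var(vapply(chains, mean, 0))
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Convergence check across all parameters of an MCMC result
#'
#' @param mcmc an `mcmc_result` with >= 2 chains.
#' @param threshold convergence cut-off on Rc (default 1.1).
#' @return list with `rc` (named per parameter), `max_rc`, `converged`.
#' @export
convergence_check <- function(mcmc, threshold = 1.1) {
  if (mcmc$n_chains < 2) stop("need at least 2 chains")
  pars <- colnames(mcmc$chains[[1]])
  rc <- vapply(pars, function(p)
    gelman_rubin(lapply(mcmc$chains, function(ch) ch[, p])), 0)
  list(rc = rc, max_rc = max(rc), converged = all(rc < threshold),
       threshold = threshold)
}

#' Fit the null/M1/M2/M3 model sequence and tabulate fit indices
#'
#' Fits four nested specifications for one outcome: M0 (intercept plus
#' cluster effect only), M1 (individual- and household-level factors), M2
#' (community-level factors only), and M3 (all factors). For each model it
#' reports AIC and BIC from the maximum-likelihood fit (`-2l + 2k` and
#' `-2l + k log n`), the latent-scale ICC at the posterior mean of the
#' cluster variance, and the maximum Gelman-Rubin Rc over parameters. The
#' preferred model is the converged fit with the smallest AIC, ties broken
#' by BIC.
#'
#' @param data derived records.
#' @param outcome `"y_any"` or `"y_four"`.
#' @param groups list with `individual`, `household`, `community` term
#'   vectors (defaults to the package conventions, restricted to columns
#'   present in `data`).
#' @param prior optional `prior_spec` applied to M3's coefficients;
#'   coefficients of the smaller models reuse its entries where present and
#'   Normal(0, 10000) otherwise. `NULL` gives flat priors everywhere.
#' @param n_chains,n_burnin,n_kept,seed MCMC settings.
#' @return data frame of class `comparison_table`: one row per model with
#'   `model`, `terms`, `k`, `aic`, `bic`, `sigma_u2`, `icc`, `max_rc`,
#'   `converged`, `preferred`.
#' @export
model_sequence <- function(data, outcome = "y_any", groups = NULL,
                           prior = NULL, n_chains = 3, n_burnin = 1000,
                           n_kept = 2000, seed = 1L) {
  if (is.null(groups)) {
    groups <- lapply(anc_term_groups, intersect, names(data))
  }
  specs <- list(
    M0 = character(0),
    M1 = c(groups$individual, groups$household),
    M2 = groups$community,
    M3 = c(groups$individual, groups$household, groups$community))
  rows <- lapply(names(specs), function(mn) {
    terms <- specs[[mn]]
    spec <- anc_model_spec(outcome, terms)
    row <- data.frame(model = mn, terms = paste(terms, collapse = "+"),
                      k = NA_integer_, aic = NA_real_, bic = NA_real_,
                      sigma_u2 = NA_real_, icc = NA_real_,
                      max_rc = NA_real_, converged = NA,
                      stringsAsFactors = FALSE)
    tryCatch({
      ml <- fit_ml(spec, data)
      pr <- noninformative_prior(ml)
      if (!is.null(prior)) {
        hit <- intersect(names(pr$mean), names(prior$mean))
        pr$mean[hit] <- prior$mean[hit]
        pr$var[hit] <- prior$var[hit]
        pr$provenance <- prior$provenance
      }
      mc <- run_mcmc(spec, data, pr, n_chains = n_chains,
                     n_burnin = n_burnin, n_kept = n_kept, seed = seed,
                     ml_fit = ml)
      ps <- posterior_summary(mc)
      cc <- convergence_check(mc)
      row$k <- ml$k
      row$aic <- ml$aic
      row$bic <- ml$bic
      row$sigma_u2 <- ps$sigma_u2_mean
      row$icc <- ps$icc
      row$max_rc <- cc$max_rc
      row$converged <- cc$converged
      row
    }, error = function(e) {
      warning("model ", mn, " failed: ", conditionMessage(e))
      row
    })
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$aic) & tab$converged %in% TRUE)
  tab$preferred <- FALSE
  if (length(ok)) {
    best <- ok[order(tab$aic[ok], tab$bic[ok])][1]
    tab$preferred[best] <- TRUE
  }
  class(tab) <- c("comparison_table", "data.frame")
  tab
}
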