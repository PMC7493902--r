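#' Non-informative normal priors for a model's coefficients
#'
#' Every coefficient receives an independent Normal(0, 10000) prior.
#'
#' @param coefs coefficient names: a character vector, an
#'   [anc_model_spec()] plus `data` (to resolve the design columns), or an
#'   `ml_fit`.
#' @param data derived records, required when `coefs` is a model spec.
#' @return object of class `prior_spec` with `mean`, `var`, `provenance`
#'   (`"noninformative"`), `source_waves`.
#' @export
noninformative_prior <- function(coefs, data = NULL) {
  if (inherits(coefs, "anc_model_spec")) {
    if (is.null(data)) stop("'data' is required to resolve coefficients")
    coefs <- colnames(build_design(coefs, data)$X)
  } else if (inherits(coefs, "ml_fit")) {
    coefs <- names(coefs$beta_hat)
  }
  if (length(coefs) == 0) stop("model has no coefficients")
  structure(list(mean = setNames(rep(0, length(coefs)), coefs),
                 var = setNames(rep(10000, length(coefs)), coefs),
                 provenance = "noninformative",
                 source_waves = integer(0)),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec>", x$provenance,
      if (length(x$source_waves)) paste0("(waves ",
        paste(x$source_waves, collapse = ", "), ")") else "", "\n")
  print(data.frame(mean = round(x$mean, 4), var = signif(x$var, 4)))
  invisible(x)
}

#' Flat-prior Bayesian fit to one historical survey wave
#'
#' Derives the analysis variables, applies the eligibility filter, and fits
#' the multilevel model under the non-informative Normal(0, 10000) priors by
#' MCMC (initialized at the maximum-likelihood estimators), returning the
#' per-coefficient posterior means and standard deviations that feed the
#' prior-elicitation rule.
#'
#' @param wave a `survey_wave` (see [generate_wave()] / [read_wave()]).
#' @param spec an [anc_model_spec()].
#' @param ... chain settings passed to [run_mcmc()] (`n_chains`, `n_burnin`,
#'   `n_kept`, `seed`, ...).
#' @return list with `mean`, `sd` (named per coefficient),
#'   `sigma_u2_mean`, `year_label`, `summary`.
#' @export
fit_historical_wave <- function(wave, spec, ...) {
  derived <- derive_variables(eligibility_filter(wave$women)$records)
  prior <- noninformative_prior(spec, derived)
  mc <- run_mcmc(spec, derived, prior, ...)
  ps <- posterior_summary(mc)
  list(mean = setNames(ps$table$beta_mean, ps$table$term),
       sd = setNames(ps$table$beta_sd, ps$table$term),
       sigma_u2_mean = ps$sigma_u2_mean,
       year_label = wave$year_label,
       summary = ps)
}

#' Combine historical-wave posteriors into an informative prior
#'
#' Per coefficient, the elicited prior mean is the arithmetic mean of the
#' wave posterior means; the prior standard deviation is the across-wave
#' sample standard deviation (n-1 denominator) of those means, floored at
#' the mean of the wave posterior standard deviations so the prior can
#' never collapse to a point when waves agree exactly. The prior variance
#' is the square of that standard deviation.
#'
#' @param wave_posteriors list (>= 2) of [fit_historical_wave()] results,
#'   all with identical coefficient sets.
#' @return object of class `prior_spec` with provenance `"elicited"`.
#' @export
combine_priors <- function(wave_posteriors) {
  if (length(wave_posteriors) < 2)
    stop("need at least 2 wave posteriors")
  cn <- names(wave_posteriors[[1]]$mean)
  for (wp in wave_posteriors)
    if (!setequal(names(wp$mean), cn))
      stop("wave posteriors have mismatched coefficient sets")
  M <- vapply(wave_posteriors, function(wp) wp$mean[cn],
              numeric(length(cn)))                          # p x waves
  S <- vapply(wave_posteriors, function(wp) wp$sd[cn],
              numeric(length(cn)))
  if (!is.matrix(M)) {
    M <- matrix(M, nrow = 1, dimnames = list(cn, NULL))
    S <- matrix(S, nrow = 1, dimnames = list(cn, NULL))
  }
  prior_mean <- rowMeans(M)
  across_sd <- apply(M, 1, sd)
  floor_sd <- rowMeans(S)
  prior_sd <- pmax(across_sd, floor_sd)
  years <- vapply(wave_posteriors,
                  function(wp) as.integer(wp$year_label %||% NA_integer_),
                  integer(1))
  structure(list(mean = setNames(prior_mean, cn),
                 var = setNames(prior_sd^2, cn),
                 provenance = "elicited",
                 source_waves = years),
            class = "prior_spec")
}

#' Elicit an informative prior from a set of historical waves
#'
#' Convenience wrapper: fits each historical wave with flat priors
#' ([fit_historical_wave()]) and combines the posteriors
#' ([combine_priors()]). Coefficients required by `spec` but unobserved in
#' every historical wave fall back to Normal(0, 10000) with a warning.
#'
#' @param waves list of `survey_wave` objects (the historical rounds).
#' @param spec an [anc_model_spec()].
#' @param target_coefs optional character vector of coefficients the final
#'   model needs (defaults to those present in the historical fits).
#' @param seed integer seed; wave `i` uses `seed + i`.
#' @param ... chain settings passed to [run_mcmc()].
#' @return a `prior_spec` with provenance `"elicited"`.
#' @export
elicit_prior <- function(waves, spec, target_coefs = NULL, seed = 1L, ...) {
  posts <- lapply(seq_along(waves), function(i)
    fit_historical_wave(waves[[i]], spec, seed = seed + i, ...))
  prior <- combine_priors(posts)
  if (!is.null(target_coefs)) {
    extra <- setdiff(target_coefs, names(prior$mean))
    if (length(extra)) {
      warning("no historical information for: ",
              paste(extra, collapse = ", "),
              "; using Normal(0, 10000) for those coefficients")
      prior$mean <- c(prior$mean, setNames(rep(0, length(extra)), extra))
      prior$var <- c(prior$var, setNames(rep(10000, length(extra)), extra))
    }
    prior$mean <- prior$mean[target_coefs]
    prior$var <- prior$var[target_coefs]
  }
  prior
}

#' Read / write a prior specification as JSON
#' @param prior a `prior_spec`.
#' @param path JSON file path.
#' @return `write_prior` returns the path invisibly; `read_prior` returns a
#'   `prior_spec`.
#' @export
write_prior <- function(prior, path) {
  jsonlite::write_json(list(mean = as.list(prior$mean),
                            var = as.list(prior$var),
                            provenance = prior$provenance,
                            source_waves = prior$source_waves),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_prior
#' @export
read_prior <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = unlist(x$mean), var = unlist(x$var),
                 provenance = x$provenance,
                 source_waves = as.integer(x$source_waves)),
            class = "prior_spec")
}
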