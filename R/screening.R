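#' Survey-weighted prevalence with 95% confidence interval
#'
#' Point estimate is the weighted proportion. The interval is computed on the
#' logit scale using a design-effect-adjusted effective sample size (Kish:
#' `n_eff = (sum w)^2 / sum w^2`) and back-transformed, which keeps bounds
#' inside \[0, 100\]. Degenerate proportions (0 or 1) get a one-sided
#' Clopper-Pearson-style bound at the effective sample size.
#'
#' @param values logical/0-1 vector, or a factor (one row per level).
#' @param weights positive survey weights, same length as `values`.
#' @param conf confidence level (default 0.95).
#' @return data frame with columns `category`, `n`, `prevalence_pct`,
#'   `ci_lower_pct`, `ci_upper_pct`.
#' @export
weighted_prevalence <- function(values, weights, conf = 0.95) {
  if (length(values) != length(weights))
    stop("'values' and 'weights' must have the same length")
  if (all(weights == 0)) stop("all weights are zero")
  if (any(weights < 0, na.rm = TRUE)) stop("weights must be positive")
  keep <- !is.na(values) & !is.na(weights)
  values <- values[keep]; weights <- weights[keep]
  n_eff <- sum(weights)^2 / sum(weights^2)
  z <- qnorm(1 - (1 - conf) / 2)
  alpha <- 1 - conf
  one <- function(ind, lab) {
    p <- weighted.mean(ind, weights)
    if (p <= 0) {
      lo <- 0; hi <- 1 - (alpha / 2)^(1 / n_eff)
    } else if (p >= 1) {
      lo <- (alpha / 2)^(1 / n_eff); hi <- 1
    } else {
      se <- 1 / sqrt(n_eff * p * (1 - p))
      lo <- plogis(qlogis(p) - z * se)
      hi <- plogis(qlogis(p) + z * se)
    }
    data.frame(category = lab, n = sum(ind),
               prevalence_pct = 100 * p,
               ci_lower_pct = 100 * lo, ci_upper_pct = 100 * hi,
               stringsAsFactors = FALSE)
  }
  if (is.factor(values) || is.character(values)) {
    f <- if (is.factor(values)) droplevels(values) else factor(values)
    out <- do.call(rbind, lapply(levels(f), function(l) one(f == l, l)))
  } else {
    out <- one(as.numeric(values) != 0, "positive")
  }
  rownames(out) <- NULL
  out
}

#' Design-corrected (Rao-Scott) chi-square test of association
#'
#' Tests independence between a categorical variable and an outcome from
#' weighted, cluster-sampled data. The Pearson statistic computed from the
#' weighted table is referred to a Satterthwaite-adjusted chi-square using
#' the eigenvalues of the generalized design-effect matrix (second-order
#' Rao-Scott correction), with the design covariance estimated by
#' with-replacement cluster linearization. With equal weights and one cluster
#' per observation the procedure reduces exactly to the Pearson chi-square
#' test (no continuity correction).
#'
#' @param variable categorical vector (>= 2 observed categories).
#' @param outcome categorical/binary vector.
#' @param weights survey weights (default equal).
#' @param cluster_ids first-stage cluster identifiers (default: each row its
#'   own cluster).
#' @return list of class `ancbayes_chisq` with `statistic` (uncorrected
#'   Pearson X2), `df`, `p_value`, `design_effects` (eigenvalues), and the
#'   corrected statistic/df.
#' @export
chisq_screen <- function(variable, outcome, weights = NULL,
                         cluster_ids = NULL) {
  keep <- !is.na(variable) & !is.na(outcome)
  variable <- variable[keep]; outcome <- outcome[keep]
  n <- length(variable)
  if (is.null(weights)) weights <- rep(1, n) else weights <- weights[keep]
  if (is.null(cluster_ids)) cluster_ids <- seq_len(n)
  else cluster_ids <- cluster_ids[keep]
  x <- droplevels(factor(variable))
  y <- droplevels(factor(outcome))
  R <- nlevels(x); C <- nlevels(y)
  if (R < 2) stop("'variable' has a single observed category")
  if (C < 2) stop("'outcome' has a single observed category")

  cell <- (as.integer(x) - 1L) * C + as.integer(y)  # RC cells, row-major
  K <- R * C
  W <- sum(weights)
  phat <- as.numeric(rowsum(weights, factor(cell, levels = seq_len(K)))) / W
  phat[is.na(phat)] <- 0
  prow <- rowSums(matrix(phat, R, C, byrow = TRUE))
  pcol <- colSums(matrix(phat, R, C, byrow = TRUE))
  p0 <- as.numeric(t(outer(prow, pcol)))  # row-major to match `cell`
  X2 <- n * sum((phat - p0)^2 / p0)
  df <- (R - 1) * (C - 1)

  # design covariance of phat: with-replacement cluster linearization
  Z <- matrix(0, n, K)
  Z[cbind(seq_len(n), cell)] <- 1
  Dmat <- (weights / W) * sweep(Z, 2, phat)  # n x K linearized contributions
  Dc <- rowsum(Dmat, cluster_ids)
  Vhat <- crossprod(Dc)

  # derivative of p -> p - prow*pcol, then the Pearson metric
  rindex <- rep(seq_len(R), each = C)
  cindex <- rep(seq_len(C), R)
  Jac <- outer(seq_len(K), seq_len(K), function(a, b)
    (rindex[a] == rindex[b]) * pcol[cindex[a]] +
    (cindex[a] == cindex[b]) * prow[rindex[a]])
  A <- diag(K) - Jac
  B <- A / sqrt(p0)
  # generalized design effects: eigenvalues of the design covariance
  # relative to the multinomial covariance, both at phat, restricted to the
  # (R-1)(C-1)-dimensional interaction space
  V0 <- (diag(phat) - tcrossprod(phat)) / n
  S0 <- B %*% V0 %*% t(B)
  S1 <- B %*% Vhat %*% t(B)
  e0 <- eigen((S0 + t(S0)) / 2, symmetric = TRUE)
  U <- e0$vectors[, seq_len(df), drop = FALSE]
  d0 <- pmax(e0$values[seq_len(df)], 1e-300)
  Tm <- t(U) %*% S1 %*% U / sqrt(tcrossprod(d0))
  lambda <- sort(eigen((Tm + t(Tm)) / 2, symmetric = TRUE,
                       only.values = TRUE)$values, decreasing = TRUE)
  lambda <- pmax(lambda, 0)
  lbar <- mean(lambda)
  if (lbar <= 0) {
    p_value <- 1; X2_adj <- 0; df_adj <- df
  } else {
    cv2 <- sum((lambda - lbar)^2) / (df * lbar^2)
    X2_adj <- X2 / (lbar * (1 + cv2))
    df_adj <- df / (1 + cv2)
    p_value <- pchisq(X2_adj, df_adj, lower.tail = FALSE)
  }
  structure(list(statistic = X2, df = df, p_value = p_value,
                 statistic_adj = X2_adj, df_adj = df_adj,
                 design_effects = lambda),
            class = "ancbayes_chisq")
}

#' @export
print.ancbayes_chisq <- function(x, ...) {
  cat(sprintf("Rao-Scott chi-square: X2 = %.3f (df %d), corrected %.3f (df %.2f), p = %.4g\n",
              x$statistic, x$df, x$statistic_adj, x$df_adj, x$p_value))
  invisible(x)
}

#' Screen candidate confounders against both outcomes
#'
#' Runs [chisq_screen()] for each candidate variable against the any-visit
#' and four-visit outcomes on derived records.
#'
#' @param derived derived records (see [derive_variables()]).
#' @param candidates character vector of column names to screen.
#' @return data frame with `variable`, `p_any`, `p_four`.
#' @export
screen_confounders <- function(derived,
                               candidates = setdiff(unlist(anc_term_groups),
                                                    c("intention",
                                                      "anc_quality"))) {
  rows <- lapply(candidates, function(v) {
    p1 <- chisq_screen(derived[[v]], derived$y_any, derived$weight,
                       derived$cluster_id)$p_value
    p4 <- chisq_screen(derived[[v]], derived$y_four, derived$weight,
                       derived$cluster_id)$p_value
    data.frame(variable = v, p_any = p1, p_four = p4,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select confounders by the p <= 0.20 screening rule
#'
#' A variable is retained if its screening p-value is at or below the
#' threshold for at least one of the two outcomes. The exposure (pregnancy
#' intention) is always retained regardless of its p-value.
#'
#' @param screening data frame from [screen_confounders()] (columns
#'   `variable`, `p_any`, `p_four`).
#' @param threshold retention threshold (default 0.20).
#' @param exposure name of the exposure variable, always kept.
#' @return data frame `screening` with a logical `selected` column; the
#'   exposure row is appended if absent.
#' @export
select_confounders <- function(screening, threshold = 0.20,
                               exposure = "intention") {
  sel <- screening$p_any <= threshold | screening$p_four <= threshold
  screening$selected <- sel
  if (!exposure %in% screening$variable) {
    screening <- rbind(screening,
                       data.frame(variable = exposure, p_any = NA_real_,
                                  p_four = NA_real_, selected = TRUE,
                                  stringsAsFactors = FALSE))
  } else {
    screening$selected[screening$variable == exposure] <- TRUE
  }
  screening
}
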