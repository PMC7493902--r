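#' Simulation configuration for a DHS-like survey wave
#'
#' Describes the generative truth for one synthetic two-stage cluster survey
#' wave: 600 enumeration areas (clusters) with 30 households each by default,
#' one eligible woman per selected household, a random-intercept logistic
#' model on the latent logit scale, and unequal selection emulated by
#' lognormal survey weights normalized to mean one.
#'
#' Both antenatal-care outcomes are driven by one shared linear predictor
#' `eta = x'beta + u_j` with outcome-specific intercept offsets: the
#' "at least one skilled visit" coding uses `eta + offset_any` and the
#' "at least four skilled visits" coding uses `eta + offset_four`. A single
#' uniform draw per woman thresholds both probabilities (comonotone
#' coupling), so each outcome has exactly its logistic marginal while the
#' four-visit outcome never exceeds the any-visit outcome. The default
#' offsets are calibrated so the marginal weighted prevalences sit near the
#' 64% (any skilled visit) and 32% (four or more) levels typical of the 2014
#' Bangladesh survey round.
#'
#' @param n_clusters number of first-stage clusters (default 600).
#' @param households_per_cluster households selected per cluster (default 30);
#'   one woman is generated per household.
#' @param year_label integer survey-year stamp.
#' @param beta named numeric vector of true log-odds coefficients. Names are
#'   `"(Intercept)"`, `"<variable>_<category>"` for categorical effects (e.g.
#'   `intention_mistimed`), or `anc_quality` for the continuous covariate.
#'   Unnamed variables have effect zero.
#' @param sigma_u cluster random-intercept standard deviation (latent logit
#'   scale); default 0.8.
#' @param offset_any,offset_four outcome-specific intercept offsets added to
#'   the shared linear predictor.
#' @param covariate_marginals named list of per-covariate category
#'   probabilities; defaults give realistic national-survey marginals.
#' @param intention_probs length-3 simplex (wanted, mistimed, unwanted);
#'   default `c(0.740, 0.151, 0.109)`.
#' @param eligible_fraction probability a household's woman reports a live
#'   birth in the 3 years before the survey (default 0.25, matching roughly
#'   4,500 analysis rows out of 18,000 interviewed women).
#' @param weight_dispersion lognormal sdlog of the raw survey weights
#'   (default 0.2); weights are normalized to mean 1.
#' @param community_sd standard deviation of a cluster-level tilt applied to
#'   the education and wealth marginals so community aggregates are
#'   non-degenerate; 0 switches the tilt off.
#' @param urban_prob probability a cluster is urban.
#' @param region_probs length-7 simplex over administrative regions.
#' @param p_missing_intention,p_missing_anc probability that an eligible
#'   woman's intention / ANC response is missing (default 0).
#' @param seed integer RNG seed; every realization is reproducible from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 600L,
                       households_per_cluster = 30L,
                       year_label = 2014L,
                       beta = default_truth_beta(),
                       sigma_u = 0.8,
                       offset_any = 0.367,
                       offset_four = -1.205,
                       covariate_marginals = default_covariate_marginals(),
                       intention_probs = c(wanted = 0.740, mistimed = 0.151,
                                           unwanted = 0.109),
                       eligible_fraction = 0.25,
                       weight_dispersion = 0.2,
                       community_sd = 0.6,
                       urban_prob = 0.30,
                       region_probs = c(barishal = 0.09, chattogram = 0.17,
                                        dhaka = 0.25, khulna = 0.12,
                                        rajshahi = 0.13, rangpur = 0.13,
                                        sylhet = 0.11),
                       p_missing_intention = 0,
                       p_missing_anc = 0,
                       seed = 1L) {
  stopifnot(n_clusters >= 1, households_per_cluster >= 1,
            sigma_u >= 0, weight_dispersion >= 0, community_sd >= 0,
            eligible_fraction > 0, eligible_fraction <= 1,
            offset_four <= offset_any)
  if (is.null(names(intention_probs)))
    names(intention_probs) <- c("wanted", "mistimed", "unwanted")
  stopifnot_simplex(intention_probs, "intention_probs")
  stopifnot_simplex(region_probs, "region_probs")
  for (nm in names(covariate_marginals)) {
    stopifnot_simplex(covariate_marginals[[nm]],
                      paste0("covariate_marginals$", nm))
  }
  if (is.null(names(beta)) && length(beta) > 0)
    stop("'beta' must be a named vector of coefficients")
  cfg <- list(n_clusters = as.integer(n_clusters),
              households_per_cluster = as.integer(households_per_cluster),
              year_label = as.integer(year_label),
              beta = beta, sigma_u = sigma_u,
              offset_any = offset_any, offset_four = offset_four,
              covariate_marginals = covariate_marginals,
              intention_probs = intention_probs,
              eligible_fraction = eligible_fraction,
              weight_dispersion = weight_dispersion,
              community_sd = community_sd,
              urban_prob = urban_prob, region_probs = region_probs,
              p_missing_intention = p_missing_intention,
              p_missing_anc = p_missing_anc,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Default true coefficient vector for simulation
#'
#' Mistimed and unwanted pregnancy lower the log-odds of skilled care by 0.30
#' and 0.37 (odds ratios 0.74 and 0.69); education, wealth, media exposure and
#' urban residence raise it by conventional amounts.
#' @return named numeric vector on the log-odds scale.
#' @export
default_truth_beta <- function() {
  c("intention_mistimed" = -0.30,
    "intention_unwanted" = -0.37,
    "education_primary" = 0.20,
    "education_secondary" = 0.40,
    "education_higher" = 0.50,
    "wealth_quintile_poorer" = 0.15,
    "wealth_quintile_middle" = 0.25,
    "wealth_quintile_richer" = 0.35,
    "wealth_quintile_richest" = 0.50,
    "residence_rural" = -0.40,
    "media_index_moderate" = 0.10,
    "media_index_high" = 0.20,
    "age_cat_20to34" = 0.15,
    "age_cat_ge35" = 0.20,
    "children_cat_gt2" = -0.15)
}

#' @rdname default_truth_beta
#' @export
default_covariate_marginals <- function() {
  list(education = c(none = 0.14, primary = 0.30, secondary = 0.42,
                     higher = 0.14),
       husband_education = c(none = 0.25, primary = 0.28, secondary = 0.30,
                             higher = 0.17),
       age_cat = c(le19 = 0.28, "20to34" = 0.66, ge35 = 0.06),
       children_cat = c(le2 = 0.72, gt2 = 0.28),
       husband_occupation = c(agriculture = 0.25, physical_labour = 0.35,
                              service = 0.10, business = 0.22, other = 0.08),
       wealth_quintile = c(poorest = 0.2, poorer = 0.2, middle = 0.2,
                           richer = 0.2, richest = 0.2),
       newspaper_weekly = c(yes = 0.15, no = 0.85),
       radio_weekly = c(yes = 0.20, no = 0.80),
       tv_weekly = c(yes = 0.55, no = 0.45))
}

# Linear predictor x'beta from raw woman-level records under the naming
# convention "<variable>_<category>" (plus "(Intercept)" and "anc_quality").
truth_linear_predictor <- function(df, beta) {
  eta <- numeric(nrow(df))
  cat_vars <- names(anc_levels)
  for (nm in names(beta)) {
    b <- beta[[nm]]
    if (nm == "(Intercept)") { eta <- eta + b; next }
    if (nm == "anc_quality") { eta <- eta + b * df$anc_quality; next }
    hit <- FALSE
    for (v in cat_vars) {
      pre <- paste0(v, "_")
      if (startsWith(nm, pre) && v %in% names(df)) {
        lev <- substring(nm, nchar(pre) + 1)
        if (!lev %in% anc_levels[[v]])
          stop("unknown category in coefficient name '", nm, "'")
        eta <- eta + b * (as.character(df[[v]]) == lev)
        hit <- TRUE
        break
      }
    }
    if (!hit) stop("coefficient '", nm, "' matches no generated variable")
  }
  eta
}

# Sample a categorical variable with per-cluster tilted probabilities:
# category k (scored k - (K+1)/2) gets weight base_k * exp(shift_j * score_k).
sample_cat_tilted <- function(base, shift, cluster_of) {
  K <- length(base)
  score <- seq_len(K) - (K + 1) / 2
  out <- character(length(cluster_of))
  for (j in unique(cluster_of)) {
    idx <- which(cluster_of == j)
    pr <- base * exp(shift[j] * score / 2)
    pr <- pr / sum(pr)
    out[idx] <- sample(names(base), length(idx), replace = TRUE, prob = pr)
  }
  out
}

#' Generate one synthetic survey wave
#'
#' Draws clusters, households, covariates, survey weights and both
#' antenatal-care outcomes from the multilevel logistic truth held in a
#' [sim_config()]. The realization is fully reproducible from `config$seed`
#' and the caller's RNG stream is left untouched.
#'
#' @param config a [sim_config()].
#' @return an object of class `survey_wave`: a list with `year_label`,
#'   `women` (one row per woman, raw analysis fields), `clusters` (cluster
#'   metadata including the latent intercept `u`), and `truth` (the config).
#' @export
generate_wave <- function(config) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  with_seed(config$seed, {
    J <- config$n_clusters
    H <- config$households_per_cluster
    n <- J * H
    clusters <- data.frame(
      cluster_id = seq_len(J),
      region = sample(names(config$region_probs), J, replace = TRUE,
                      prob = config$region_probs),
      residence = ifelse(runif(J) < config$urban_prob, "urban", "rural"),
      u = rnorm(J, 0, config$sigma_u),
      comm_shift = rnorm(J, 0, config$community_sd))
    cl <- rep(clusters$cluster_id, each = H)
    m <- config$covariate_marginals
    draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)
    women <- data.frame(
      woman_id = seq_len(n),
      cluster_id = cl,
      education = sample_cat_tilted(m$education, clusters$comm_shift, cl),
      husband_education = draw(m$husband_education),
      age_cat_true = draw(m$age_cat),
      children_cat_true = draw(m$children_cat),
      husband_occupation = draw(m$husband_occupation),
      wealth_quintile = sample_cat_tilted(m$wealth_quintile,
                                          clusters$comm_shift, cl),
      newspaper_weekly = draw(m$newspaper_weekly) == "yes",
      radio_weekly = draw(m$radio_weekly) == "yes",
      tv_weekly = draw(m$tv_weekly) == "yes",
      intention = sample(names(config$intention_probs), n, replace = TRUE,
                         prob = config$intention_probs),
      anc_quality = rnorm(n),
      residence = clusters$residence[cl],
      region = clusters$region[cl])
    # integer age consistent with the sampled age band
    women$age_at_delivery_years <- ifelse(
      women$age_cat_true == "le19", sample(15:19, n, replace = TRUE),
      ifelse(women$age_cat_true == "20to34", sample(20:34, n, replace = TRUE),
             sample(35:45, n, replace = TRUE)))
    women$children_ever_born <- ifelse(women$children_cat_true == "le2",
                                       sample(1:2, n, replace = TRUE),
                                       sample(3:7, n, replace = TRUE))
    media_n <- women$newspaper_weekly + women$radio_weekly + women$tv_weekly
    women$media_index <- ifelse(media_n == 0, "not_exposed",
                                ifelse(media_n == 3, "high", "moderate"))
    women$age_cat <- women$age_cat_true
    women$children_cat <- women$children_cat_true

    eta <- truth_linear_predictor(women, config$beta) +
      clusters$u[women$cluster_id]
    uu <- runif(n)
    y_any <- as.integer(uu < plogis(eta + config$offset_any))
    y_four <- as.integer(uu < plogis(eta + config$offset_four))

    women$anc_provider_skilled <- y_any == 1L
    women$anc_visits <- integer(n)
    women$anc_visits[y_four == 1L] <- 4L + rpois(sum(y_four), 1)
    idx13 <- y_any == 1L & y_four == 0L
    women$anc_visits[idx13] <- sample(1:3, sum(idx13), replace = TRUE)
    none <- y_any == 0L
    unsk <- none & runif(n) < 0.3
    women$anc_visits[unsk] <- sample(1:4, sum(unsk), replace = TRUE)

    women$birth_within_3y <- runif(n) < config$eligible_fraction
    not_asked <- !women$birth_within_3y
    women$intention[not_asked] <- NA_character_
    women$anc_visits[not_asked] <- NA_integer_
    women$anc_provider_skilled[not_asked] <- NA
    if (config$p_missing_intention > 0) {
      miss <- women$birth_within_3y & runif(n) < config$p_missing_intention
      women$intention[miss] <- NA_character_
    }
    if (config$p_missing_anc > 0) {
      miss <- women$birth_within_3y & runif(n) < config$p_missing_anc
      women$anc_visits[miss] <- NA_integer_
      women$anc_provider_skilled[miss] <- NA
    }

    w <- rlnorm(n, meanlog = -config$weight_dispersion^2 / 2,
                sdlog = config$weight_dispersion)
    women$weight <- w / mean(w)
    women$age_cat_true <- NULL
    women$children_cat_true <- NULL
    women$media_index <- NULL
    women$age_cat <- NULL
    women$children_cat <- NULL

    wave <- list(year_label = config$year_label, women = women,
                 clusters = clusters, truth = config)
    class(wave) <- "survey_wave"
    wave
  })
}

#' Generate a panel of survey waves
#'
#' @param configs list of [sim_config()] objects with distinct `year_label`s
#'   (at least two), e.g. analogues of the 2004/2007/2011/2014 survey rounds.
#'   Coefficient drift across waves is taken verbatim from the configs.
#' @return list of `survey_wave` objects, named by year label.
#' @export
generate_panel <- function(configs) {
  if (length(configs) == 0) stop("'configs' must contain at least one config")
  if (length(configs) < 2) stop("a panel needs at least two waves")
  years <- vapply(configs, function(c) c$year_label, integer(1))
  if (anyDuplicated(years)) stop("duplicate year_labels in panel configs")
  waves <- lapply(configs, generate_wave)
  names(waves) <- years
  waves
}

#' @export
print.survey_wave <- function(x, ...) {
  cat("<survey_wave> year", x$year_label, "-", nrow(x$women), "women in",
      nrow(x$clusters), "clusters\n")
  if (!is.null(x$truth))
    cat("  simulated truth: sigma_u =", x$truth$sigma_u, "\n")
  invisible(x)
}

#' Write / read a survey wave as CSV plus a JSON truth sidecar
#'
#' Writes `wave_<year>.csv` (one row per woman) and, for simulated waves,
#' `wave_<year>_truth.json` holding the generating configuration and cluster
#' latent effects.
#'
#' @param wave a `survey_wave`.
#' @param dir output directory (created if needed).
#' @return (invisibly) the CSV path.
#' @export
write_wave <- function(wave, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, sprintf("wave_%d.csv", wave$year_label))
  write.csv(wave$women, csv, row.names = FALSE)
  if (!is.null(wave$truth)) {
    side <- file.path(dir, sprintf("wave_%d_truth.json", wave$year_label))
    truth <- unclass(wave$truth)
    truth$clusters <- wave$clusters
    jsonlite::write_json(truth, side, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(csv)
}

#' @rdname write_wave
#' @param path path to a `wave_<year>.csv` file.
#' @export
read_wave <- function(path) {
  women <- read.csv(path, stringsAsFactors = FALSE)
  year <- as.integer(sub(".*wave_(\\d+)\\.csv$", "\\1", path))
  side <- sub("\\.csv$", "_truth.json", path)
  truth <- NULL
  clusters <- unique(women[, intersect(c("cluster_id", "region", "residence"),
                                       names(women)), drop = FALSE])
  clusters <- clusters[order(clusters$cluster_id), , drop = FALSE]
  if (file.exists(side)) {
    truth <- jsonlite::read_json(side, simplifyVector = TRUE)
    clusters <- as.data.frame(truth$clusters)
    truth$clusters <- NULL
    truth$beta <- unlist(truth$beta)
    truth$intention_probs <- unlist(truth$intention_probs)
    truth$region_probs <- unlist(truth$region_probs)
    truth$covariate_marginals <- lapply(truth$covariate_marginals, unlist)
    class(truth) <- "sim_config"
  }
  wave <- list(year_label = year, women = women, clusters = clusters,
               truth = truth)
  class(wave) <- "survey_wave"
  wave
}
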