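#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or a YAML file holding one) with:
#' \describe{
#'   \item{out_dir}{output directory for all artifacts.}
#'   \item{seed}{integer root seed; every stage derives its seed from it.}
#'   \item{simulate}{list of [sim_config()] overrides plus `years`, an
#'     ordered integer vector of wave labels (last = analysis wave), used
#'     when `waves` is absent.}
#'   \item{waves}{optional character vector of existing `wave_<year>.csv`
#'     paths (ordered, last = analysis wave); all must exist at run start.}
#'   \item{screening_threshold}{confounder retention threshold
#'     (default 0.20).}
#'   \item{terms}{optional fixed-effect terms for the final model; default
#'     is the screened selection plus the exposure.}
#'   \item{mcmc}{list with `n_chains`, `n_burnin`, `n_kept`.}
#' }
#'
#' @param config named list or path to a YAML file.
#' @return the validated config (invisibly usable), with defaults filled in.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  if (is.null(config$seed)) stop("config$seed is required")
  config$seed <- as.integer(config$seed)
  config$screening_threshold <- config$screening_threshold %||% 0.20
  if (config$screening_threshold <= 0 || config$screening_threshold > 1)
    stop("screening_threshold must be in (0, 1]")
  config$mcmc <- modifyList(list(n_chains = 3, n_burnin = 1000,
                                 n_kept = 2000), config$mcmc %||% list())
  if (any(unlist(config$mcmc) < 1)) stop("mcmc settings must be positive")
  if (!is.null(config$waves)) {
    missing <- config$waves[!file.exists(config$waves)]
    if (length(missing))
      stop("wave file(s) not found: ", paste(missing, collapse = ", "))
    if (length(config$waves) < 2)
      stop("need at least 2 waves (historical + analysis)")
  } else {
    config$simulate <- config$simulate %||% list()
    config$simulate$years <- as.integer(config$simulate$years %||%
                                          c(2004L, 2007L, 2011L, 2014L))
    if (length(config$simulate$years) < 2)
      stop("simulate$years needs at least 2 waves")
    if (anyDuplicated(config$simulate$years))
      stop("simulate$years must be distinct")
  }
  config
}

stage_log <- function(con, stage, ...) {
  line <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> derive -> screen -> elicit -> fit ->
#' diagnose -> report as one reproducible run. Every intermediate artifact
#' is written under `config$out_dir`; rerunning with the same configuration
#' and seed reproduces all numeric outputs exactly.
#'
#' @param config run configuration (see [validate_run_config()]).
#' @return object of class `model_report`: posterior tables for both
#'   outcomes, ICC, AIC/BIC, convergence summary, screening and exclusion
#'   audits, and a provenance block (config hash, seed, package version).
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(config$out_dir, "pipeline.log"), open = "wt")
  on.exit(close(logf))
  seed <- config$seed

  # -- simulate / load ------------------------------------------------------
  if (is.null(config$waves)) {
    years <- config$simulate$years
    overrides <- config$simulate
    overrides$years <- NULL
    configs <- lapply(seq_along(years), function(i) {
      args <- modifyList(overrides,
                         list(year_label = years[i], seed = seed + i))
      do.call(sim_config, args)
    })
    waves <- generate_panel(configs)
    for (wv in waves) write_wave(wv, file.path(config$out_dir, "waves"))
    stage_log(logf, "simulate", length(waves), " waves (",
              paste(years, collapse = ", "), "), ",
              nrow(waves[[1]]$women), " women each")
  } else {
    waves <- lapply(config$waves, read_wave)
    stage_log(logf, "simulate", "loaded ", length(waves), " wave files")
  }
  n_w <- length(waves)
  current <- waves[[n_w]]
  historical <- waves[-n_w]

  # -- derive ---------------------------------------------------------------
  elig <- eligibility_filter(current$women)
  derived <- derive_variables(elig$records)
  write.csv(derived, file.path(config$out_dir, "derived.csv"),
            row.names = FALSE)
  jsonlite::write_json(as.list(elig$exclusions),
                       file.path(config$out_dir, "exclusions.json"),
                       auto_unbox = TRUE)
  stage_log(logf, "derive", nrow(derived), " rows kept; exclusions ",
            paste(names(elig$exclusions), elig$exclusions,
                  sep = "=", collapse = ", "))

  # -- screen ---------------------------------------------------------------
  prev <- rbind(
    cbind(variable = "intention",
          weighted_prevalence(derived$intention, derived$weight)),
    cbind(variable = "y_any",
          weighted_prevalence(derived$y_any, derived$weight)),
    cbind(variable = "y_four",
          weighted_prevalence(derived$y_four, derived$weight)))
  write.csv(prev, file.path(config$out_dir, "table1_prevalence.csv"),
            row.names = FALSE)
  screening <- select_confounders(screen_confounders(derived),
                                  threshold = config$screening_threshold)
  write.csv(screening, file.path(config$out_dir, "table2_screening.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(threshold = config$screening_threshold,
         selected = screening$variable[screening$selected]),
    file.path(config$out_dir, "selection.json"), auto_unbox = TRUE)
  terms <- config$terms %||%
    unique(c("intention", screening$variable[screening$selected]))
  stage_log(logf, "screen", sum(screening$selected), " of ",
            nrow(screening), " variables selected; model terms: ",
            paste(terms, collapse = ", "))

  # -- elicit ---------------------------------------------------------------
  specs <- list(y_any = anc_model_spec("y_any", terms),
                y_four = anc_model_spec("y_four", terms))
  target <- colnames(build_design(specs$y_any, derived)$X)
  priors <- lapply(names(specs), function(oc) {
    pr <- elicit_prior(historical, specs[[oc]],
                       target_coefs = target, seed = seed + 10,
                       n_chains = config$mcmc$n_chains,
                       n_burnin = config$mcmc$n_burnin,
                       n_kept = config$mcmc$n_kept)
    write_prior(pr, file.path(config$out_dir,
                              paste0("prior_", oc, ".json")))
    pr
  })
  names(priors) <- names(specs)
  stage_log(logf, "elicit", "informative priors from ",
            length(historical), " historical waves")

  # -- fit + diagnose -------------------------------------------------------
  fits <- lapply(names(specs), function(oc) {
    ml <- fit_ml(specs[[oc]], derived)
    mc <- run_mcmc(specs[[oc]], derived, priors[[oc]],
                   n_chains = config$mcmc$n_chains,
                   n_burnin = config$mcmc$n_burnin,
                   n_kept = config$mcmc$n_kept,
                   seed = seed + 20 + match(oc, names(specs)),
                   ml_fit = ml)
    ps <- posterior_summary(mc)
    cc <- convergence_check(mc)
    jsonlite::write_json(
      list(outcome = oc, seed = seed,
           table = ps$table, sigma_u2_mean = ps$sigma_u2_mean,
           icc = ps$icc, aic = ml$aic, bic = ml$bic,
           rc = as.list(cc$rc), converged = cc$converged),
      file.path(config$out_dir, paste0("posterior_", oc, ".json")),
      auto_unbox = TRUE, digits = NA)
    stage_log(logf, "fit", oc, ": ", config$mcmc$n_chains, " chains, max Rc ",
              round(cc$max_rc, 4), ", ICC ", signif(ps$icc, 4))
    list(ml = ml, mcmc = mc, summary = ps, convergence = cc)
  })
  names(fits) <- names(specs)

  cfg_json <- file.path(config$out_dir, "config.json")
  cfg_clean <- config
  jsonlite::write_json(cfg_clean, cfg_json, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  report <- structure(list(
    outcomes = lapply(fits, function(f)
      list(summary = f$summary, aic = f$ml$aic, bic = f$ml$bic,
           icc = f$summary$icc, max_rc = f$convergence$max_rc,
           converged = f$convergence$converged)),
    terms = terms,
    screening = screening,
    exclusions = elig$exclusions,
    prevalence = prev,
    provenance = list(seed = seed,
                      config_hash = unname(tools::md5sum(cfg_json)),
                      package_version =
                        as.character(utils::packageVersion("ancbayes")))),
    class = "model_report")
  render_tables(report, config$out_dir)
  stage_log(logf, "report", "artifacts written to ", config$out_dir)
  report
}

# coefficient table in Table-3 shape: one row per category with "(ref)" rows
report_rows <- function(terms, summary_table) {
  tab <- summary_table
  rows <- list(data.frame(variable = "(Intercept)", category = "",
                          or = tab$or[tab$term == "(Intercept)"],
                          interval = sprintf("%.2f–%.2f",
                            tab$or_lower[tab$term == "(Intercept)"],
                            tab$or_upper[tab$term == "(Intercept)"]),
                          reference = FALSE, stringsAsFactors = FALSE))
  for (v in terms) {
    if (v %in% names(anc_levels)) {
      levs <- anc_levels[[v]]
      for (i in seq_along(levs)) {
        nm <- paste0(v, "_", levs[i])
        if (i == 1) {
          rows[[length(rows) + 1]] <-
            data.frame(variable = v, category = paste(levs[i], "(ref)"),
                       or = NA_real_, interval = "", reference = TRUE,
                       stringsAsFactors = FALSE)
        } else if (nm %in% tab$term) {
          k <- which(tab$term == nm)
          rows[[length(rows) + 1]] <-
            data.frame(variable = v, category = levs[i], or = tab$or[k],
                       interval = sprintf("%.2f–%.2f",
                                          tab$or_lower[k], tab$or_upper[k]),
                       reference = FALSE, stringsAsFactors = FALSE)
        }
      }
    } else if (v %in% tab$term) {
      k <- which(tab$term == v)
      rows[[length(rows) + 1]] <-
        data.frame(variable = v, category = "", or = tab$or[k],
                   interval = sprintf("%.2f–%.2f",
                                      tab$or_lower[k], tab$or_upper[k]),
                   reference = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$or_txt <- ifelse(out$reference, "(ref)", sprintf("%.2f", out$or))
  out
}

#' Render report tables as CSV and markdown
#'
#' Writes Table-3-shaped adjusted odds-ratio tables (ORs to 2 decimals,
#' equal-tailed 95% credible intervals as "lower-upper", reference rows
#' labelled "(ref)") and a Table-1-shaped prevalence block (percentages to
#' 1 decimal) for both outcomes.
#'
#' @param report a `model_report` from [run_pipeline()].
#' @param dir output directory.
#' @return (invisibly) named list of the rendered data frames.
#' @export
render_tables <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  md <- c("# Model report", "",
          sprintf("Seed %d; package ancbayes %s", report$provenance$seed,
                  report$provenance$package_version), "")
  for (oc in names(report$outcomes)) {
    rr <- report_rows(report$terms, report$outcomes[[oc]]$summary$table)
    out[[oc]] <- rr
    write.csv(rr[, c("variable", "category", "or_txt", "interval")],
              file.path(dir, paste0("table3_", oc, ".csv")),
              row.names = FALSE)
    md <- c(md, paste0("## Outcome ", oc), "",
            "| variable | category | aOR | 95% Cred. I |",
            "|---|---|---|---|",
            sprintf("| %s | %s | %s | %s |", rr$variable, rr$category,
                    rr$or_txt, rr$interval),
            "",
            sprintf("ICC %.4g; AIC %.2f; BIC %.2f; max Rc %.4f",
                    report$outcomes[[oc]]$icc, report$outcomes[[oc]]$aic,
                    report$outcomes[[oc]]$bic, report$outcomes[[oc]]$max_rc),
            "")
  }
  if (!is.null(report$prevalence)) {
    pv <- report$prevalence
    pv$prevalence_pct <- sprintf("%.1f", pv$prevalence_pct)
    pv$ci <- sprintf("%.1f–%.1f", report$prevalence$ci_lower_pct,
                     report$prevalence$ci_upper_pct)
    write.csv(pv[, c("variable", "category", "n", "prevalence_pct", "ci")],
              file.path(dir, "table1_rendered.csv"), row.names = FALSE)
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(out)
}

#' Percent reduction in odds implied by an odds ratio
#'
#' The narrative "X% lower odds" companion of an adjusted odds ratio:
#' `100 * (1 - or)`. Negative values mean higher odds.
#'
#' @param or odds ratio(s).
#' @return percentage reduction(s) in odds.
#' @export
odds_reduction_pct <- function(or) 100 * (1 - or)

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report> terms:", paste(x$terms, collapse = ", "), "\n")
  for (oc in names(x$outcomes)) {
    o <- x$outcomes[[oc]]
    cat(sprintf("  %s: ICC %.4g, AIC %.2f, BIC %.2f, max Rc %.4f (%s)\n",
                oc, o$icc, o$aic, o$bic, o$max_rc,
                if (isTRUE(o$converged)) "converged" else "NOT converged"))
  }
  invisible(x)
}
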