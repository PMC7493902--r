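#' Eligibility filter with exclusion audit
#'
#' Keeps women who gave birth within the 3 years preceding the survey and
#' have non-missing pregnancy-intention and antenatal-care responses.
#' Exclusions are tallied by the first applicable reason, in the order: no
#' recent birth, missing intention, missing ANC response.
#'
#' @param records data frame with columns `birth_within_3y`, `intention`,
#'   `anc_visits` (and optionally `anc_provider_skilled`).
#' @return list with `records` (kept rows) and `exclusions` (named integer
#'   tally: `no_recent_birth`, `missing_intention`, `missing_anc`).
#' @export
eligibility_filter <- function(records) {
  need <- c("birth_within_3y", "intention", "anc_visits")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack required columns: ", paste(miss, collapse = ", "))
  no_birth <- !records$birth_within_3y | is.na(records$birth_within_3y)
  no_int <- !no_birth & is.na(records$intention)
  no_anc <- !no_birth & !no_int & is.na(records$anc_visits)
  keep <- !(no_birth | no_int | no_anc)
  list(records = records[keep, , drop = FALSE],
       exclusions = c(no_recent_birth = sum(no_birth),
                      missing_intention = sum(no_int),
                      missing_anc = sum(no_anc)))
}

#' Code the two skilled antenatal-care outcomes
#'
#' `y_any` is 1 if the woman had at least one visit from skilled health
#' personnel, else 0; `y_four` is 1 if she had at least four such visits.
#' Visits to unskilled providers count as zero skilled visits, so both
#' outcomes are 0 whenever the provider was not skilled.
#'
#' @param anc_visits non-negative integer visit counts.
#' @param anc_provider_skilled logical, whether the visits were from skilled
#'   personnel (doctor, nurse/midwife/paramedic, family welfare visitor,
#'   community skilled birth attendant, sub-assistant community medical
#'   officer).
#' @return data frame with integer columns `y_any` and `y_four`.
#' @export
code_outcomes <- function(anc_visits, anc_provider_skilled) {
  if (any(anc_visits < 0, na.rm = TRUE))
    stop("'anc_visits' must be non-negative")
  skilled_visits <- ifelse(anc_provider_skilled, anc_visits, 0L)
  data.frame(y_any = as.integer(skilled_visits >= 1),
             y_four = as.integer(skilled_visits >= 4))
}

#' Mass-media exposure index
#'
#' Combines weekly newspaper, radio and television access into a 3-level
#' index: `not_exposed` if none of the three is accessed at least weekly,
#' `high` if all three are, `moderate` otherwise.
#'
#' @param newspaper_weekly,radio_weekly,tv_weekly logical vectors.
#' @return factor with levels `not_exposed`, `moderate`, `high`.
#' @export
media_exposure_index <- function(newspaper_weekly, radio_weekly, tv_weekly) {
  k <- newspaper_weekly + radio_weekly + tv_weekly
  as_anc_factor(ifelse(k == 0, "not_exposed",
                       ifelse(k == 3, "high", "moderate")), "media_index")
}

#' Community-level poverty category for one cluster
#'
#' A cluster whose households all sit in the top three wealth quintiles is
#' `middle_to_richest`; otherwise the share `p` of households in the bottom
#' two quintiles maps to `low` (p <= 25%), `moderate` (25% < p <= 50%) or
#' `high` (p > 50%).
#'
#' @param cluster_wealth_quintiles character/factor vector of quintile labels
#'   (`poorest` ... `richest`) for all households of one cluster.
#' @return length-1 factor with levels `high`, `moderate`, `low`,
#'   `middle_to_richest`.
#' @export
community_poverty <- function(cluster_wealth_quintiles) {
  q <- as.character(cluster_wealth_quintiles)
  q <- q[!is.na(q)]
  if (length(q) == 0) stop("empty cluster")
  p <- mean(q %in% c("poorest", "poorer"))
  lab <- if (p == 0) "middle_to_richest"
         else if (p <= 0.25) "low"
         else if (p <= 0.50) "moderate"
         else "high"
  as_anc_factor(lab, "community_poverty")
}

#' Community-level literacy category for one cluster
#'
#' The cluster share of literate women maps to `low` (<= 25%), `moderate`
#' (25% < share <= 50%) or `high` (> 50%).
#'
#' @param cluster_literacy_flags logical vector for one cluster.
#' @return length-1 factor with levels `low`, `moderate`, `high`.
#' @export
community_literacy <- function(cluster_literacy_flags) {
  f <- cluster_literacy_flags[!is.na(cluster_literacy_flags)]
  if (length(f) == 0) stop("empty cluster")
  share <- mean(f)
  lab <- if (share <= 0.25) "low" else if (share <= 0.50) "moderate" else "high"
  as_anc_factor(lab, "community_literacy")
}

#' Community-level uptake of four or more skilled visits
#'
#' `high` if more than 50% of the cluster's women attained four or more
#' skilled visits, else `low` (a share of exactly 50% is `low`).
#'
#' @param cluster_y_four_values 0/1 vector for one cluster.
#' @return length-1 factor with levels `high`, `low`.
#' @export
community_anc4 <- function(cluster_y_four_values) {
  y <- cluster_y_four_values[!is.na(cluster_y_four_values)]
  if (length(y) == 0) stop("empty cluster")
  as_anc_factor(if (mean(y) > 0.5) "high" else "low", "community_anc4")
}

#' Derive all analysis variables from raw woman-level records
#'
#' Adds the two outcome codings, the 3-level age-at-delivery category
#' (<=19, 20-34, >=35 years), the parity category (<=2, >2 children ever
#' born), the media-exposure index, a literacy flag (any formal education),
#' and the three community-level aggregates (literacy, poverty, four-visit
#' uptake), computed per cluster with the woman's own record included
#' (leave-self-in aggregation). All categoricals are returned as factors
#' with the package's reference-first level order.
#'
#' @param records raw woman-level data frame (as produced by
#'   [generate_wave()] or read from CSV per the data dictionary).
#' @return data frame of class `derived_records` with all raw fields plus
#'   the derived columns.
#' @export
derive_variables <- function(records) {
  d <- records
  oc <- code_outcomes(d$anc_visits, d$anc_provider_skilled)
  d$y_any <- oc$y_any
  d$y_four <- oc$y_four
  d$age_cat <- as_anc_factor(
    ifelse(d$age_at_delivery_years <= 19, "le19",
           ifelse(d$age_at_delivery_years <= 34, "20to34", "ge35")),
    "age_cat")
  d$children_cat <- as_anc_factor(
    ifelse(d$children_ever_born <= 2, "le2", "gt2"), "children_cat")
  d$media_index <- media_exposure_index(d$newspaper_weekly, d$radio_weekly,
                                        d$tv_weekly)
  d$literate <- as.character(d$education) != "none"

  split_idx <- split(seq_len(nrow(d)), d$cluster_id)
  comm <- lapply(split_idx, function(idx) {
    list(lit = as.character(community_literacy(d$literate[idx])),
         pov = as.character(community_poverty(d$wealth_quintile[idx])),
         anc = as.character(community_anc4(d$y_four[idx])))
  })
  key <- as.character(d$cluster_id)
  d$community_literacy <- as_anc_factor(
    vapply(comm, `[[`, "", "lit")[key], "community_literacy")
  d$community_poverty <- as_anc_factor(
    vapply(comm, `[[`, "", "pov")[key], "community_poverty")
  d$community_anc4 <- as_anc_factor(
    vapply(comm, `[[`, "", "anc")[key], "community_anc4")

  for (v in c("intention", "education", "husband_education",
              "husband_occupation", "wealth_quintile", "residence", "region"))
    if (v %in% names(d)) d[[v]] <- as_anc_factor(d[[v]], v)
  class(d) <- c("derived_records", "data.frame")
  d
}
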