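# Shared factor-level conventions. The first level of each variable is the
# reference category used throughout modelling (wanted pregnancy; illiterate;
# age <= 19; <= 2 children; agricultural worker; not media-exposed; poorest;
# urban; Barishal; low community literacy; high community poverty; high
# community ANC uptake).
anc_levels <- list(
  intention          = c("wanted", "mistimed", "unwanted"),
  education          = c("none", "primary", "secondary", "higher"),
  husband_education  = c("none", "primary", "secondary", "higher"),
  age_cat            = c("le19", "20to34", "ge35"),
  children_cat       = c("le2", "gt2"),
  husband_occupation = c("agriculture", "physical_labour", "service",
                         "business", "other"),
  media_index        = c("not_exposed", "moderate", "high"),
  wealth_quintile    = c("poorest", "poorer", "middle", "richer", "richest"),
  residence          = c("urban", "rural"),
  region             = c("barishal", "chattogram", "dhaka", "khulna",
                         "rajshahi", "rangpur", "sylhet"),
  community_literacy = c("low", "moderate", "high"),
  community_poverty  = c("high", "moderate", "low", "middle_to_richest"),
  community_anc4     = c("high", "low")
)

# Variable groups for the nested model sequence: M1 = individual + household,
# M2 = community, M3 = all.
anc_term_groups <- list(
  individual = c("intention", "age_cat", "education", "anc_quality"),
  household  = c("children_cat", "husband_education", "husband_occupation",
                 "media_index", "wealth_quintile"),
  community  = c("residence", "region", "community_literacy",
                 "community_poverty", "community_anc4")
)

as_anc_factor <- function(x, var) {
  lv <- anc_levels[[var]]
  if (is.null(lv)) stop("no level convention for variable '", var, "'")
  f <- factor(as.character(x), levels = lv)
  if (anyNA(f) && !anyNA(x)) {
    bad <- setdiff(unique(as.character(x)), lv)
    stop("invalid categories for '", var, "': ", paste(bad, collapse = ", "))
  }
  f
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never disturbs user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Gauss-Hermite nodes/log-weights for the physicists' weight exp(-x^2).
gh_rule <- function(n) {
  gh <- pracma::gaussHermite(n)
  list(x = gh$x, logw = log(gh$w))
}

logit <- function(p) qlogis(p)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_simplex <- function(p, tol = 1e-12) {
  is.numeric(p) && all(p >= 0) && abs(sum(p) - 1) <= tol
}

stopifnot_simplex <- function(p, what) {
  if (!is_simplex(p)) stop("'", what, "' must be a probability simplex summing to 1")
}
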