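test_that("eligibility filter keeps complete recent births and tallies exclusions", {
  toy <- data.frame(
    birth_within_3y = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    intention = c("wanted", "mistimed", "unwanted", "wanted", "wanted", NA),
    anc_visits = c(1L, 0L, 4L, 2L, NA, 3L))
  out <- eligibility_filter(toy)
  expect_equal(nrow(out$records), 3)
  expect_equal(out$exclusions,
               c(no_recent_birth = 2L, missing_intention = 1L,
                 missing_anc = 0L))

  all_ok <- toy[1:3, ]
  expect_identical(eligibility_filter(all_ok)$records, all_ok)
  empty <- toy[0, ]
  expect_equal(nrow(eligibility_filter(empty)$records), 0)
  expect_equal(sum(eligibility_filter(empty)$exclusions), 0)
  expect_error(eligibility_filter(data.frame(x = 1)), "required columns")
})

test_that("outcome coding follows the skilled-visit rules", {
  expect_equal(code_outcomes(4, TRUE), data.frame(y_any = 1L, y_four = 1L))
  expect_equal(code_outcomes(3, TRUE), data.frame(y_any = 1L, y_four = 0L))
  expect_equal(code_outcomes(2, FALSE), data.frame(y_any = 0L, y_four = 0L))
  expect_equal(code_outcomes(0, TRUE)$y_any, 0L)
  expect_error(code_outcomes(-1, TRUE), "non-negative")
  # monotonicity: one extra skilled visit never decreases either coding
  for (v in 0:6) {
    a <- code_outcomes(v, TRUE)
    b <- code_outcomes(v + 1, TRUE)
    expect_gte(b$y_any, a$y_any)
    expect_gte(b$y_four, a$y_four)
  }
  # y_four = 1 implies y_any = 1 on all visit/provider combinations
  grid <- expand.grid(visits = 0:8, skilled = c(TRUE, FALSE))
  oc <- code_outcomes(grid$visits, grid$skilled)
  expect_true(all(oc$y_any[oc$y_four == 1] == 1))
})

test_that("media index partitions the three weekly-access flags", {
  expect_equal(as.character(media_exposure_index(TRUE, TRUE, TRUE)), "high")
  expect_equal(as.character(media_exposure_index(FALSE, FALSE, FALSE)),
               "not_exposed")
  expect_equal(as.character(media_exposure_index(TRUE, FALSE, FALSE)),
               "moderate")
  grid <- expand.grid(n = c(TRUE, FALSE), r = c(TRUE, FALSE),
                      t = c(TRUE, FALSE))
  idx <- media_exposure_index(grid$n, grid$r, grid$t)
  expect_false(anyNA(idx))
  expect_equal(sum(idx == "high"), 1)
  expect_equal(sum(idx == "not_exposed"), 1)
  expect_equal(sum(idx == "moderate"), 6)
})

test_that("community poverty follows the bottom-two-quintile share rules", {
  expect_equal(as.character(community_poverty(
    c("middle", "richer", "richest", "middle"))), "middle_to_richest")
  q30 <- c(rep("poorest", 3), rep("richer", 7))
  expect_equal(as.character(community_poverty(q30)), "moderate")
  q60 <- c(rep("poorer", 6), rep("middle", 4))
  expect_equal(as.character(community_poverty(q60)), "high")
  q25 <- c("poorest", rep("richest", 3))
  expect_equal(as.character(community_poverty(q25)), "low")
  expect_error(community_poverty(character(0)), "empty")
})

test_that("community literacy uses the half-open 25/50% convention", {
  expect_equal(as.character(community_literacy(rep(c(TRUE, FALSE), c(1, 3)))),
               "low")      # share exactly 0.25
  expect_equal(as.character(community_literacy(rep(c(TRUE, FALSE), c(2, 3)))),
               "moderate") # share 0.40
  expect_equal(as.character(community_literacy(rep(c(TRUE, FALSE), c(51, 49)))),
               "high")     # share 0.51
  expect_equal(as.character(community_literacy(rep(c(TRUE, FALSE), c(1, 1)))),
               "moderate") # share exactly 0.50
  expect_error(community_literacy(logical(0)), "empty")
})

test_that("community four-visit uptake splits at a strict 50% majority", {
  expect_equal(as.character(community_anc4(c(1, 1, 1, 0))), "high")
  expect_equal(as.character(community_anc4(c(0, 0, 1, 1))), "low")
  expect_equal(as.character(community_anc4(c(0, 0, 0))), "low")
  expect_error(community_anc4(numeric(0)), "empty")
})

test_that("derived records partition every variable and aggregate per cluster", {
  w <- generate_wave(sim_config(n_clusters = 40, households_per_cluster = 15,
                                eligible_fraction = 1, seed = 17))
  d <- derive_variables(w$women)
  for (v in c("age_cat", "children_cat", "media_index", "community_literacy",
              "community_poverty", "community_anc4", "intention",
              "wealth_quintile")) {
    expect_false(anyNA(d[[v]]), info = v)
    expect_s3_class(d[[v]], "factor")
  }
  expect_true(all(d$y_any[d$y_four == 1] == 1))
  # community categories are constant within cluster (leave-self-in)
  for (v in c("community_literacy", "community_poverty", "community_anc4")) {
    per_cluster <- tapply(as.character(d[[v]]), d$cluster_id,
                          function(x) length(unique(x)))
    expect_true(all(per_cluster == 1), info = v)
  }
  # age categorization uses age at delivery
  expect_true(all(d$age_cat[d$age_at_delivery_years <= 19] == "le19"))
  expect_true(all(d$age_cat[d$age_at_delivery_years >= 35] == "ge35"))
})
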