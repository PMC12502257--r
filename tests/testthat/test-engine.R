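flex_row <- function(profile, tier) {
  th <- if (profile == "who-gbt") who_flexible_thresholds() else vmra_flexible_thresholds()
  th[th$tier == tier, , drop = FALSE]
}

mk_tally <- function(catalog, ratings_by_tier) {
  tally(mk_assessment(catalog, ratings_by_tier), catalog, "F1")
}

test_that("check_tier applies the flexible floors and caps exactly", {
  cat_g <- mk_catalog(c(PRE_BRONZE = 2, BRONZE = 2, SILVER = 2, GOLD = 100))
  # Gold: 85% implemented floor, 15% partial cap, 5% not-implemented cap
  tl <- mk_tally(cat_g, list(GOLD = c(IMPLEMENTED = 85, PARTIALLY_IMPLEMENTED = 10,
                                      NOT_IMPLEMENTED = 5)))
  expect_true(check_tier(tl, "GOLD", flex_row("vmra", "GOLD"))$pass)

  tl2 <- mk_tally(cat_g, list(GOLD = c(IMPLEMENTED = 84, PARTIALLY_IMPLEMENTED = 16)))
  ck2 <- check_tier(tl2, "GOLD", flex_row("vmra", "GOLD"))
  expect_false(ck2$pass)
  miss <- ck2$shortfalls[ck2$shortfalls$constraint == "min_implemented", ]
  expect_equal(miss$required, "85/100")
  expect_equal(miss$observed, "84/100")

  # Bronze admits no not-implemented items at all (cap 0)
  cat_b <- mk_catalog(c(PRE_BRONZE = 2, BRONZE = 20))
  tl3 <- mk_tally(cat_b, list(BRONZE = c(IMPLEMENTED = 19, NOT_IMPLEMENTED = 1)))
  ck3 <- check_tier(tl3, "BRONZE", flex_row("vmra", "BRONZE"))
  expect_false(ck3$pass)
  expect_true("max_not_implemented" %in% ck3$shortfalls$constraint)

  # an empty tier passes vacuously
  tl4 <- mk_tally(cat_b, list(BRONZE = c(NOT_APPLICABLE = 20)))
  expect_true(check_tier(tl4, "BRONZE", flex_row("vmra", "BRONZE"))$pass)

  # unmet lower tiers are reported through lower_tiers_full
  tl5 <- mk_tally(cat_b, list(PRE_BRONZE = c(IMPLEMENTED = 1, PARTIALLY_IMPLEMENTED = 1)))
  ck5 <- check_tier(tl5, "BRONZE", flex_row("vmra", "BRONZE"))
  expect_false(ck5$pass)
  expect_equal(ck5$shortfalls$constraint, "lower_tier_full")
  expect_equal(ck5$shortfalls$tier, "PRE_BRONZE")
})

test_that("flexible classification respects each tier's own pool and the 100% lower-tier rule", {
  cat_full <- mk_catalog(c(PRE_BRONZE = 6, BRONZE = 20, SILVER = 10, GOLD = 20,
                           GOLD_PLUS = 10))
  # 19/20 Bronze implemented: Bronze passes at exactly 95%, but Silver
  # requires Bronze at 100%, so the function stops at Bronze
  a <- mk_assessment(cat_full, list(BRONZE = c(IMPLEMENTED = 19, PARTIALLY_IMPLEMENTED = 1)))
  res <- classify_function(a, cat_full, "F1", "flexible")
  expect_equal(res$achieved_tier, "BRONZE")
  expect_equal(res$qualifier, "Bronze (flexible)")
  expect_equal(res$shortfalls$constraint[1], "lower_tier_full")

  # a failing entry level floors the function
  a2 <- mk_assessment(cat_full, list(PRE_BRONZE = c(IMPLEMENTED = 5, NOT_IMPLEMENTED = 1)))
  expect_equal(classify_function(a2, cat_full, "F1", "flexible")$achieved_tier, "L0")
  expect_equal(classify_function(a2, cat_full, "F1", "strict")$achieved_tier, "L0")

  # everything implemented reaches the top under every algorithm, and the
  # strict qualifier is preferred when strict also passes
  a3 <- mk_assessment(cat_full)
  for (alg in c("strict", "flexible")) {
    r3 <- classify_function(a3, cat_full, "F1", alg)
    expect_equal(r3$achieved_tier, "GOLD_PLUS")
    expect_equal(nrow(r3$shortfalls), 0L)
    expect_equal(r3$qualifier, "Gold-plus (strict)")
  }
})

test_that("restricted flexibility additionally pins critical sub-indicators", {
  cat_c <- mk_catalog(c(PRE_BRONZE = 6, BRONZE = 20, SILVER = 5),
                      critical_fraction = c(BRONZE = 0.05), seed = 7)
  crit_id <- cat_c$sub_indicators$sub_id[cat_c$sub_indicators$critical]
  expect_length(crit_id, 1L)
  a_full <- mk_assessment(cat_c)
  a_crit <- set_ratings(a_full, cat_c, crit_id, "PARTIALLY_IMPLEMENTED")

  # one partial of 20 passes flexible Bronze but fails restricted when the
  # partial item is critical
  expect_equal(classify_function(a_crit, cat_c, "F1", "flexible")$achieved_tier, "BRONZE")
  res <- classify_function(a_crit, cat_c, "F1", "restricted")
  expect_equal(res$achieved_tier, "PRE_BRONZE")
  expect_true("critical_implemented" %in% res$shortfalls$constraint)

  # requesting restricted on a catalog without critical flags is an error
  cat_plain <- reference_catalog("who-gbt")
  a_w <- gen_assessment(cat_plain, mix = c(IMPLEMENTED = 1), seed = 1)
  expect_error(classify_function(a_w, cat_plain, "RS", "restricted"),
               "unknown algorithm")
})

test_that("who-gbt flexible thresholds follow the published ML rules", {
  # ML3: lower levels full, 90% of ML3 implemented, remainder in process
  cat3 <- mk_catalog(c(ML1 = 5, ML2 = 5, ML3 = 100), profile = "who-gbt")
  a3 <- mk_assessment(cat3, list(ML3 = c(IMPLEMENTED = 90, PARTIALLY_IMPLEMENTED = 5,
                                         ONGOING_IMPLEMENTATION = 5)))
  expect_true(tier_rank(classify_function(a3, cat3, "F1", "flexible")$achieved_tier,
                        "who-gbt") >= tier_rank("ML3", "who-gbt"))
  a3f <- mk_assessment(cat3, list(ML3 = c(IMPLEMENTED = 89, ONGOING_IMPLEMENTATION = 11)))
  expect_equal(classify_function(a3f, cat3, "F1", "flexible")$achieved_tier, "ML2")

  # ML2 pools ML1+ML2: 38 of 40 implemented passes at exactly 95%, 37 fails
  cat2 <- mk_catalog(c(ML1 = 20, ML2 = 20), profile = "who-gbt")
  a_38 <- mk_assessment(cat2, list(ML2 = c(IMPLEMENTED = 18, ONGOING_IMPLEMENTATION = 2)))
  expect_true(tier_rank(classify_function(a_38, cat2, "F1", "flexible")$achieved_tier,
                        "who-gbt") >= tier_rank("ML2", "who-gbt"))
  a_37 <- mk_assessment(cat2, list(ML2 = c(IMPLEMENTED = 17, ONGOING_IMPLEMENTATION = 3)))
  expect_equal(classify_function(a_37, cat2, "F1", "flexible")$achieved_tier, "ML1")

  # ML4: 80% implemented with 20% in process passes
  cat4 <- mk_catalog(c(ML1 = 5, ML2 = 5, ML3 = 5, ML4 = 100), profile = "who-gbt")
  a4 <- mk_assessment(cat4, list(ML4 = c(IMPLEMENTED = 80, ONGOING_IMPLEMENTATION = 20)))
  expect_equal(classify_function(a4, cat4, "F1", "flexible")$achieved_tier, "ML4")
  # but not-implemented items are not tolerated in process-of-implementation remainders
  a4x <- mk_assessment(cat4, list(ML4 = c(IMPLEMENTED = 80, ONGOING_IMPLEMENTATION = 19,
                                          NOT_IMPLEMENTED = 1)))
  expect_equal(classify_function(a4x, cat4, "F1", "flexible")$achieved_tier, "ML3")
})

test_that("institution classification takes the minimum function tier and the mandatory cap", {
  cat_i <- mk_catalog(c(PRE_BRONZE = 8, BRONZE = 8, SILVER = 8, GOLD = 8, GOLD_PLUS = 8),
                      n_functions = 2L)
  a_all <- mk_assessment(cat_i)
  inst <- classify_institution(a_all, cat_i, "flexible")
  expect_equal(inst$institution_tier, "GOLD_PLUS")
  expect_length(inst$mandatory_failures, 0L)

  # one function dragged to Bronze drags the institution with it
  f2_silver <- cat_i$sub_indicators$sub_id[
    cat_i$sub_indicators$function_code == "F2" & cat_i$sub_indicators$tier == "SILVER"]
  a_min <- set_ratings(a_all, cat_i, f2_silver, "NOT_IMPLEMENTED")
  expect_equal(classify_institution(a_min, cat_i, "flexible")$institution_tier, "BRONZE")

  # a partially-implemented mandatory Silver item caps an all-Silver institution at Bronze
  cat_m <- mk_catalog(c(PRE_BRONZE = 4, BRONZE = 4, SILVER = 10, GOLD = 4))
  cat_m$sub_indicators$institution_mandatory[
    which(cat_m$sub_indicators$tier == "SILVER")[1]] <- TRUE
  mand_id <- cat_m$sub_indicators$sub_id[cat_m$sub_indicators$institution_mandatory]
  gold_ids <- cat_m$sub_indicators$sub_id[cat_m$sub_indicators$tier == "GOLD"]
  a_s <- set_ratings(mk_assessment(cat_m), cat_m, gold_ids, "NOT_IMPLEMENTED")
  expect_equal(classify_institution(a_s, cat_m, "flexible")$institution_tier, "SILVER")
  a_cap <- set_ratings(a_s, cat_m, mand_id, "PARTIALLY_IMPLEMENTED")
  inst_cap <- classify_institution(a_cap, cat_m, "flexible")
  expect_equal(inst_cap$institution_tier, "BRONZE")
  expect_equal(inst_cap$mandatory_failures, mand_id)
})

test_that("strict classification equals the one-line full-implementation oracle", {
  cat_s <- mk_catalog(c(PRE_BRONZE = 3, BRONZE = 4, SILVER = 4, GOLD = 6, GOLD_PLUS = 3))
  dt <- designation_tiers("vmra")
  for (seed in 1:40) {
    a <- gen_assessment(cat_s, mix = c(IMPLEMENTED = 0.8, PARTIALLY_IMPLEMENTED = 0.1,
                                       NOT_IMPLEMENTED = 0.05, NOT_APPLICABLE = 0.05),
                        seed = seed)
    merged <- merge(cat_s$sub_indicators, a$responses, by = "sub_id")
    merged <- merged[merged$rating != "NOT_APPLICABLE", ]
    # highest tier T with every applicable sub-indicator at tiers <= T IMPLEMENTED
    full <- vapply(seq_along(dt), function(k)
      all(merged$rating[merged$tier %in% dt[seq_len(k)]] == "IMPLEMENTED"), logical(1))
    expected <- if (all(!full)) "L0" else dt[max(which(cumprod(full) == 1))]
    expect_equal(classify_function(a, cat_s, "F1", "strict")$achieved_tier, expected)
  }
})
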