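test_that("rating scores match each profile's sliding scale", {
  vmra <- reference_catalog("vmra")
  who <- reference_catalog("who-gbt")
  expect_identical(score_rating("IMPLEMENTED", vmra), 1)
  expect_identical(score_rating("PARTIALLY_IMPLEMENTED", vmra), 0.5)
  expect_identical(score_rating("NOT_IMPLEMENTED", vmra), 0)
  expect_identical(score_rating("PARTIALLY_IMPLEMENTED", who), 0.75)
  expect_identical(score_rating("ONGOING_IMPLEMENTATION", who), 0.25)
  # the vmra profile dropped the ongoing category
  expect_error(score_rating("ONGOING_IMPLEMENTATION", vmra), "not in this profile's scale")
  # not-applicable is excluded, never a number
  expect_true(is_excluded(score_rating("NOT_APPLICABLE", vmra)))
  expect_false(is.numeric(score_rating("NOT_APPLICABLE", who)))
})

test_that("score_rating is monotone along the implementation ladder", {
  for (profile in c("vmra", "who-gbt")) {
    cat1 <- mk_catalog(stats::setNames(1L, designation_tiers(profile)[1]),
                       profile = profile)
    scores <- vapply(rating_ladder(profile), score_rating, numeric(1),
                     scale = cat1)
    expect_true(all(diff(scores) > 0))
  }
})

test_that("function_score is the exact rational mean over applicable responses", {
  cat2 <- mk_catalog(c(BRONZE = 2))
  a <- mk_assessment(cat2, list(BRONZE = c(IMPLEMENTED = 1, PARTIALLY_IMPLEMENTED = 1)))
  s <- function_score(a, cat2, "F1")
  expect_equal(c(s$num, s$den), c(3, 4))
  expect_equal(s$score, 0.75)

  cat3 <- mk_catalog(c(BRONZE = 3))
  a3 <- mk_assessment(cat3, list(BRONZE = c(IMPLEMENTED = 2, NOT_APPLICABLE = 1)))
  s3 <- function_score(a3, cat3, "F1")
  expect_equal(s3$score, 1)
  expect_equal(s3$applicable_count, 2L)

  cat6 <- mk_catalog(c(PRE_BRONZE = 6))
  s6 <- function_score(mk_assessment(cat6), cat6, "F1")
  expect_equal(s6$score, 1)

  a_na <- mk_assessment(cat3, list(BRONZE = c(NOT_APPLICABLE = 3)))
  s_na <- function_score(a_na, cat3, "F1")
  expect_true(is_excluded(s_na$score))
  expect_equal(s_na$applicable_count, 0L)
})

test_that("function_score ignores response order and added NA responses", {
  cat5 <- mk_catalog(c(BRONZE = 4, SILVER = 2))
  a <- mk_assessment(cat5, list(
    BRONZE = c(IMPLEMENTED = 2, PARTIALLY_IMPLEMENTED = 1, NOT_IMPLEMENTED = 1),
    SILVER = c(IMPLEMENTED = 2)))
  s1 <- function_score(a, cat5, "F1")
  shuffled <- a
  set.seed(99)
  shuffled$responses <- shuffled$responses[sample(nrow(shuffled$responses)), ]
  s2 <- function_score(shuffled, cat5, "F1")
  expect_equal(s1[c("num", "den", "score")], s2[c("num", "den", "score")])

  # flipping an IMPLEMENTED response to NOT_APPLICABLE re-weights exactly
  a_na <- set_ratings(a, cat5, a$responses$sub_id[a$responses$rating == "IMPLEMENTED"][1],
                      "NOT_APPLICABLE")
  s3 <- function_score(a_na, cat5, "F1")
  expect_equal(s3$applicable_count, s1$applicable_count - 1L)
})

test_that("missing responses are scored as NOT_IMPLEMENTED with a warning", {
  cat2 <- mk_catalog(c(BRONZE = 2))
  partial <- new_assessment(cat2, data.frame(
    sub_id = cat2$sub_indicators$sub_id[1], rating = "IMPLEMENTED"))
  expect_warning(s <- function_score(partial, cat2, "F1"), "no recorded rating")
  expect_equal(c(s$num, s$den), c(1, 2))
})

test_that("tally counts every tier correctly and sums to applicable_n", {
  cat26 <- mk_catalog(c(PRE_BRONZE = 6, BRONZE = 20))
  a <- mk_assessment(cat26, list(BRONZE = c(IMPLEMENTED = 19, PARTIALLY_IMPLEMENTED = 1)))
  tl <- tally(a, cat26, "F1")
  pb <- tl[tl$tier == "PRE_BRONZE", ]
  b <- tl[tl$tier == "BRONZE", ]
  expect_equal(c(pb$implemented_n, pb$partial_n, pb$not_implemented_n, pb$applicable_n),
               c(6L, 0L, 0L, 6L))
  expect_equal(c(b$implemented_n, b$partial_n, b$not_implemented_n, b$applicable_n),
               c(19L, 1L, 0L, 20L))

  # a tier whose responses are all NOT_APPLICABLE has applicable_n 0
  a_na <- mk_assessment(cat26, list(BRONZE = c(NOT_APPLICABLE = 20)))
  expect_equal(tally(a_na, cat26, "F1")$applicable_n[2], 0L)
})

test_that("tally matches a brute-force recount on random assessments", {
  cat_mix <- mk_catalog(c(PRE_BRONZE = 4, BRONZE = 8, SILVER = 6, GOLD = 10, GOLD_PLUS = 4))
  for (seed in 1:20) {
    a <- gen_assessment(cat_mix, mix = c(IMPLEMENTED = 0.4, PARTIALLY_IMPLEMENTED = 0.3,
                                         NOT_IMPLEMENTED = 0.2, NOT_APPLICABLE = 0.1),
                        seed = seed)
    tl <- tally(a, cat_mix, "F1")
    merged <- merge(cat_mix$sub_indicators, a$responses, by = "sub_id")
    for (i in seq_len(nrow(tl))) {
      rows <- merged[merged$tier == tl$tier[i], ]
      expect_equal(tl$implemented_n[i], sum(rows$rating == "IMPLEMENTED"))
      expect_equal(tl$partial_n[i], sum(rows$rating == "PARTIALLY_IMPLEMENTED"))
      expect_equal(tl$not_implemented_n[i], sum(rows$rating == "NOT_IMPLEMENTED"))
      expect_equal(tl$applicable_n[i], sum(rows$rating != "NOT_APPLICABLE"))
      expect_equal(tl$implemented_n[i] + tl$partial_n[i] + tl$ongoing_n[i] +
                     tl$not_implemented_n[i], tl$applicable_n[i])
    }
  }
})

test_that("response files round-trip and rating tokens are case-insensitive", {
  cat2 <- mk_catalog(c(BRONZE = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sub_indicator_id,rating,evidence,assessed_on",
               paste0(cat2$sub_indicators$sub_id[1], ",implemented,ok,2026-01-01"),
               paste0(cat2$sub_indicators$sub_id[2], ",Partially Implemented,,")),
             path)
  a <- read_assessment(path, cat2)
  expect_equal(sort(a$responses$rating), c("IMPLEMENTED", "PARTIALLY_IMPLEMENTED"))

  out <- withr::local_tempfile(fileext = ".csv")
  write_assessment(a, out)
  back <- read_assessment(out, cat2)
  expect_equal(back$responses$rating, a$responses$rating)
  expect_error(
    new_assessment(cat2, data.frame(sub_id = cat2$sub_indicators$sub_id[1],
                                    rating = "ONGOING_IMPLEMENTATION")),
    "not in the 'vmra' scale")
  expect_error(
    new_assessment(cat2, data.frame(sub_id = "GHOST", rating = "IMPLEMENTED")),
    "unknown sub-indicator")
})
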