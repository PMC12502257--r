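# Shared builders for engine tests: single-function catalogs with exact
# per-tier counts, and assessments assembled from per-tier rating counts.

mk_catalog <- function(tier_counts, profile = "vmra", critical_fraction = 0,
                       mandatory_fraction = 0, n_functions = 1L, seed = 1L) {
  gen_catalog(synth_spec(profile = profile, tier_counts = tier_counts,
                         critical_fraction = critical_fraction,
                         mandatory_fraction = mandatory_fraction,
                         n_functions = n_functions, seed = seed))
}

# ratings_by_tier: named list tier -> named counts,
# e.g. list(BRONZE = c(IMPLEMENTED = 19, PARTIALLY_IMPLEMENTED = 1));
# unlisted tiers default to IMPLEMENTED. Ratings are assigned in sub_id order.
mk_assessment <- function(catalog, ratings_by_tier = list()) {
  si <- catalog$sub_indicators[order(catalog$sub_indicators$sub_id), ]
  rating <- rep("IMPLEMENTED", nrow(si))
  for (tier in names(ratings_by_tier)) {
    idx <- which(si$tier == tier)
    counts <- ratings_by_tier[[tier]]
    stopifnot(sum(counts) == length(idx))
    rating[idx] <- rep(names(counts), times = counts)
  }
  new_assessment(catalog, data.frame(sub_id = si$sub_id, rating = rating,
                                     stringsAsFactors = FALSE))
}

# replace the rating of specific sub-indicators
set_ratings <- function(assessment, catalog, ids, rating) {
  r <- assessment$responses
  r$rating[r$sub_id %in% ids] <- rating
  new_assessment(catalog, r)
}

rating_ladder <- function(profile) {
  if (profile == "who-gbt")
    c("NOT_IMPLEMENTED", "ONGOING_IMPLEMENTATION", "PARTIALLY_IMPLEMENTED", "IMPLEMENTED")
  else c("NOT_IMPLEMENTED", "PARTIALLY_IMPLEMENTED", "IMPLEMENTED")
}
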