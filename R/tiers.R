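#' Maturity tier ladders
#'
#' Each assessment profile carries an ordered ladder of maturity tiers. The
#' lowest rung is a floor ("below entry level") that is never used to
#' designate a sub-indicator; the remaining rungs are designation tiers.
#' The `vmra` profile uses Pre-bronze through Gold-plus; the `who-gbt`
#' profile uses maturity levels ML1 through ML4.
#'
#' @param profile Profile id, `"vmra"` or `"who-gbt"`. Custom catalogs may
#'   declare their own profile id but must reuse one of these ladders.
#' @return `tier_levels()`: character vector of tier ids in ascending order,
#'   floor first. `designation_tiers()`: the same ladder without the floor.
#' @examples
#' tier_levels("vmra")
#' designation_tiers("who-gbt")
#' @export
tier_levels <- function(profile) {
  switch(tier_family(profile),
    vmra = c("L0", "PRE_BRONZE", "BRONZE", "SILVER", "GOLD", "GOLD_PLUS"),
    `who-gbt` = c("ML0", "ML1", "ML2", "ML3", "ML4")
  )
}

#' @rdname tier_levels
#' @export
designation_tiers <- function(profile) tier_levels(profile)[-1L]

# custom profiles default to the vmra ladder unless named who-gbt
tier_family <- function(profile) {
  if (identical(profile, "who-gbt")) "who-gbt" else "vmra"
}

#' @rdname tier_levels
#' @param tier Tier id (one of `tier_levels(profile)`).
#' @return `tier_label()`: human-readable tier name.
#' @export
tier_label <- function(tier, profile = "vmra") {
  labels <- switch(tier_family(profile),
    vmra = c(L0 = "Below Pre-bronze", PRE_BRONZE = "Pre-bronze", BRONZE = "Bronze",
             SILVER = "Silver", GOLD = "Gold", GOLD_PLUS = "Gold-plus"),
    `who-gbt` = c(ML0 = "ML0", ML1 = "ML1", ML2 = "ML2", ML3 = "ML3", ML4 = "ML4")
  )
  unname(labels[tier])
}

# integer rank on the ladder (floor = 1)
tier_rank <- function(tier, profile) {
  m <- match(tier, tier_levels(profile))
  if (anyNA(m)) stop("unknown tier(s) for profile '", profile, "': ",
                     paste(tier[is.na(m)], collapse = ", "), call. = FALSE)
  m
}

tier_floor <- function(profile) tier_levels(profile)[1L]
tier_top <- function(profile) utils::tail(tier_levels(profile), 1L)

# designation tiers strictly below `tier`
tiers_below <- function(tier, profile) {
  lv <- tier_levels(profile)
  lv[seq_len(tier_rank(tier, profile) - 1L)][-1L]
}
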