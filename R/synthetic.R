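#' Synthetic catalogs, assessments and classification oracles
#'
#' Tools for generating controlled test inputs: catalogs with prescribed
#' per-tier sub-indicator counts, random assessments drawn from a rating
#' mix, assessments constructed to classify at an exact target tier, and an
#' independent brute-force classification oracle. All generation is
#' deterministic given a seed (R's default Mersenne-Twister generator,
#' isolated from the caller's RNG state), and the seed is recorded in the
#' generated object's metadata.
#'
#' @name synthetic
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic catalog
#'
#' @param profile Profile id; determines the tier ladder and rating scale.
#' @param tier_counts Named integer vector, designation tier -> number of
#'   sub-indicators.
#' @param critical_fraction Fraction of sub-indicators flagged critical,
#'   either a scalar or named per tier (only meaningful for profiles with a
#'   restricted-flexibility algorithm).
#' @param mandatory_fraction Fraction flagged institution-mandatory.
#' @param n_functions Number of functions the sub-indicators are spread
#'   over (round-robin).
#' @param seed Integer seed recorded in, and governing, the generation.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(profile = "vmra", tier_counts, critical_fraction = 0,
                       mandatory_fraction = 0, n_functions = 1L, seed = 1L) {
  dt <- designation_tiers(profile)
  bad <- setdiff(names(tier_counts), dt)
  if (length(bad))
    stop("tier_counts names must be designation tiers of '", profile, "'; bad: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(tier_counts < 0)) stop("tier_counts must be non-negative", call. = FALSE)
  structure(list(profile = profile, tier_counts = tier_counts,
                 critical_fraction = critical_fraction,
                 mandatory_fraction = mandatory_fraction,
                 n_functions = as.integer(n_functions), seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic catalog
#'
#' @param spec A [synth_spec()].
#' @return A `vmra_catalog` with exactly `spec$tier_counts` sub-indicators
#'   per tier, placeholder texts, and the profile's shipped algorithm
#'   tables (strict/flexible, plus restricted when `critical_fraction > 0`
#'   under the vmra ladder).
#' @examples
#' gen_catalog(synth_spec(tier_counts = c(BRONZE = 3, SILVER = 2), seed = 1))
#' @export
gen_catalog <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  profile <- spec$profile
  dt <- designation_tiers(profile)
  counts <- stats::setNames(integer(length(dt)), dt)
  counts[names(spec$tier_counts)] <- as.integer(spec$tier_counts)

  fcodes <- paste0("F", seq_len(spec$n_functions))
  rows <- list()
  for (t in dt) {
    n <- counts[[t]]
    if (n == 0L) next
    fn <- fcodes[((seq_len(n) - 1L) %% spec$n_functions) + 1L]
    within_fn <- stats::ave(seq_len(n), fn, FUN = seq_along)
    rows[[t]] <- data.frame(
      sub_id = sprintf("%s-%s-%02d", fn, abbreviate_tier(t), within_fn),
      function_code = fn, indicator_code = "GEN",
      text = sprintf("Synthetic sub-indicator %s #%d (tier %s)", t, seq_len(n), t),
      tier = t, critical = FALSE, institution_mandatory = FALSE,
      stringsAsFactors = FALSE)
  }
  si <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sub_id = character(), function_code = character(),
               indicator_code = character(), text = character(), tier = character(),
               critical = logical(), institution_mandatory = logical(),
               stringsAsFactors = FALSE)
  rownames(si) <- NULL

  crit_frac <- spec$critical_fraction
  with_seed(spec$seed, {
    for (t in dt) {
      cf <- if (!is.null(names(crit_frac))) {
        if (t %in% names(crit_frac)) crit_frac[[t]] else 0
      } else crit_frac
      if (is.na(cf) || cf <= 0) next
      idx <- which(si$tier == t)
      k <- round(cf * length(idx))
      if (k > 0L) si$critical[sample(idx, k)] <- TRUE
    }
    mf <- spec$mandatory_fraction
    if (mf > 0 && nrow(si)) {
      k <- round(mf * nrow(si))
      if (k > 0L) si$institution_mandatory[sample(nrow(si), k)] <- TRUE
    }
  })

  scale <- if (tier_family(profile) == "who-gbt") who_scale() else vmra_scale()
  algorithms <- list(
    strict = list(requires_critical = FALSE, tiers = strict_thresholds(profile)),
    flexible = list(requires_critical = FALSE,
                    tiers = if (tier_family(profile) == "who-gbt")
                      who_flexible_thresholds() else vmra_flexible_thresholds()))
  if (any(si$critical))
    algorithms$restricted <- list(requires_critical = TRUE,
                                  tiers = algorithms$flexible$tiers)

  new_catalog(
    profile = profile,
    title = sprintf("Synthetic catalog (seed %d)", spec$seed),
    version = "synthetic",
    scale = scale, algorithms = algorithms,
    indicators = data.frame(indicator_code = "GEN", name = "Generated placeholder",
                            stringsAsFactors = FALSE),
    functions = data.frame(function_code = fcodes,
                           name = paste("Synthetic function", fcodes),
                           stringsAsFactors = FALSE),
    sub_indicators = si)
}

abbreviate_tier <- function(t) {
  c(PRE_BRONZE = "PB", BRONZE = "B", SILVER = "S", GOLD = "G", GOLD_PLUS = "GP",
    ML1 = "ML1", ML2 = "ML2", ML3 = "ML3", ML4 = "ML4")[[t]]
}

vmra_scale <- function() {
  data.frame(rating = c("IMPLEMENTED", "PARTIALLY_IMPLEMENTED", "NOT_IMPLEMENTED"),
             score = c(1, 0.5, 0), stringsAsFactors = FALSE)
}

who_scale <- function() {
  data.frame(rating = c("IMPLEMENTED", "PARTIALLY_IMPLEMENTED",
                        "ONGOING_IMPLEMENTATION", "NOT_IMPLEMENTED"),
             score = c(1, 0.75, 0.25, 0), stringsAsFactors = FALSE)
}

#' Generate a random assessment
#'
#' One rating per catalog sub-indicator, drawn independently from `mix`.
#'
#' @param catalog A `vmra_catalog`.
#' @param mix Named probability vector over rating tokens (may include
#'   `NOT_APPLICABLE`); must sum to 1.
#' @param seed Integer seed.
#' @return A `vmra_assessment`; the seed is recorded in
#'   `attr(x, "seed")`.
#' @export
gen_assessment <- function(catalog, mix, seed = 1L) {
  stopifnot(inherits(catalog, "vmra_catalog"))
  if (abs(sum(mix) - 1) > 1e-9) stop("mix probabilities must sum to 1", call. = FALSE)
  allowed <- c(catalog$scale$rating, "NOT_APPLICABLE")
  bad <- setdiff(names(mix), allowed)
  if (length(bad))
    stop("mix names not in the catalog scale: ", paste(bad, collapse = ", "),
         call. = FALSE)
  n <- nrow(catalog$sub_indicators)
  ratings <- with_seed(seed,
    sample(names(mix), n, replace = TRUE, prob = as.numeric(mix)))
  a <- new_assessment(catalog, data.frame(
    sub_id = catalog$sub_indicators$sub_id, rating = ratings,
    evidence = sprintf("synthetic (seed %d)", seed),
    assessed_on = NA_character_, stringsAsFactors = FALSE))
  attr(a, "seed") <- as.integer(seed)
  a
}

#' Construct an assessment that classifies to an exact tier
#'
#' Builds a response set whose function classification is exactly `target`
#' under `algorithm`: every tier at or below the target is satisfied (with
#' a seeded sprinkling of partially-implemented ratings inside the target
#' tier's allowance under the flexible algorithms, avoiding critical items
#' under restricted flexibility), and every sub-indicator above the target
#' is NOT_IMPLEMENTED, which defeats the next tier under any shipped
#' algorithm. The construction is verified by reclassification.
#'
#' @param catalog A `vmra_catalog`.
#' @param target A designation tier, or the ladder floor to violate even
#'   the entry tier.
#' @param algorithm Algorithm name defined in the catalog.
#' @param seed Integer seed.
#' @return A `vmra_assessment`.
#' @export
gen_assessment_at_tier <- function(catalog, target, algorithm = "flexible", seed = 1L) {
  alg <- get_algorithm(catalog, algorithm)
  profile <- catalog$profile
  lv <- tier_levels(profile)
  trank <- tier_rank(target, profile)
  si <- catalog$sub_indicators
  ranks <- tier_rank(si$tier, profile)
  rating <- ifelse(ranks <= trank, "IMPLEMENTED", "NOT_IMPLEMENTED")

  if (target %in% designation_tiers(profile)) {
    th <- alg$tiers[alg$tiers$tier == target, , drop = FALSE]
    in_process <- if (tier_family(profile) == "who-gbt")
      c("PARTIALLY_IMPLEMENTED", "ONGOING_IMPLEMENTATION") else "PARTIALLY_IMPLEMENTED"
    with_seed(seed, {
      for (fc in unique(si$function_code)) {
        fsel <- si$function_code == fc
        # lower tiers must still pass their own rules and the allowance is
        # applied per function, so demotions stay inside this function's
        # target-tier items; mandatory and (under restricted flexibility)
        # critical items are never demoted
        n_pool <- if (isTRUE(th$pooled_with_lower)) sum(fsel & ranks <= trank)
          else sum(fsel & ranks == trank)
        allow <- frac_floor_count(n_pool, th$max_partial)
        eligible <- which(fsel & ranks == trank & !si$institution_mandatory)
        if (alg$requires_critical) eligible <- eligible[!si$critical[eligible]]
        k <- min(allow, length(eligible))
        if (k > 0L) {
          pick <- if (length(eligible) == 1L) eligible else sample(eligible, k)
          rating[pick] <- sample(in_process, k, replace = TRUE)
        }
      }
    })
  }

  a <- new_assessment(catalog, data.frame(
    sub_id = si$sub_id, rating = rating,
    evidence = sprintf("constructed for %s under %s (seed %d)", target, algorithm, seed),
    assessed_on = NA_character_, stringsAsFactors = FALSE))
  attr(a, "seed") <- as.integer(seed)

  got <- suppressWarnings(classify_institution(a, catalog, algorithm))$institution_tier
  if (!identical(got, target))
    stop("target tier ", target, " is not achievable as an exact classification ",
         "for this catalog under '", algorithm, "' (constructed assessment reaches ",
         got, ")", call. = FALSE)
  a
}

#' Brute-force classification oracle
#'
#' An independent re-implementation of the maturity classification used to
#' cross-check the engine: it recounts every tier directly from the raw
#' responses, evaluates each tier's constraints in isolation with its own
#' arithmetic, and returns the top of the maximal consecutive run of
#' passing tiers from the bottom of the ladder. Intended for small
#' catalogs (hundreds of items).
#'
#' @inheritParams classify_function
#' @return A tier id.
#' @export
oracle_classify <- function(assessment, catalog, function_code, algorithm = "flexible") {
  alg <- catalog$algorithms[[algorithm]]
  if (is.null(alg)) stop("unknown algorithm: ", algorithm, call. = FALSE)
  profile <- catalog$profile
  si <- catalog$sub_indicators
  si <- si[si$function_code == function_code, , drop = FALSE]
  m <- match(si$sub_id, assessment$responses$sub_id)
  rating <- assessment$responses$rating[m]
  rating[is.na(rating)] <- "NOT_IMPLEMENTED"
  keep <- rating != "NOT_APPLICABLE"
  si <- si[keep, , drop = FALSE]
  rating <- rating[keep]

  dt <- designation_tiers(profile)
  tier_pass <- logical(length(dt))
  for (k in seq_along(dt)) {
    t <- dt[k]
    th <- alg$tiers[alg$tiers$tier == t, ]
    sel <- if (isTRUE(th$pooled_with_lower)) si$tier %in% dt[seq_len(k)] else si$tier == t
    n <- sum(sel)
    if (n == 0L) { tier_pass[k] <- TRUE; next }
    i <- sum(rating[sel] == "IMPLEMENTED")
    p <- sum(rating[sel] %in% c("PARTIALLY_IMPLEMENTED", "ONGOING_IMPLEMENTATION"))
    x <- sum(rating[sel] == "NOT_IMPLEMENTED")
    fr <- function(s) { v <- as.integer(strsplit(s, "/")[[1]]); v[1] / v[2] }
    ok <- i / n >= fr(th$min_implemented) - 1e-12 &&
      p / n <= fr(th$max_partial) + 1e-12 &&
      x / n <= fr(th$max_not_implemented) + 1e-12
    if (ok && isTRUE(th$lower_tiers_full) && k > 1L) {
      for (lt in dt[seq_len(k - 1L)]) {
        lsel <- si$tier == lt
        if (sum(lsel) && any(rating[lsel] != "IMPLEMENTED")) { ok <- FALSE; break }
      }
    }
    if (ok && alg$requires_critical) {
      csel <- si$critical & si$tier %in% dt[seq_len(k)]
      if (any(rating[csel] != "IMPLEMENTED")) ok <- FALSE
    }
    tier_pass[k] <- ok
  }
  run <- which(!cumprod(tier_pass))
  if (length(run) == 0L) return(dt[length(dt)])
  first_fail <- run[1]
  if (first_fail == 1L) tier_floor(profile) else dt[first_fail - 1L]
}
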