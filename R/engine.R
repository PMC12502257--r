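#' Maturity-classification engine
#'
#' A function's maturity tier is the highest designation tier whose
#' threshold constraints — and those of every tier below it — are met by
#' the function's rating tally. Three algorithms are defined for the vmra
#' profile:
#'
#' * **strict**: every applicable sub-indicator designated at or below the
#'   candidate tier must be IMPLEMENTED.
#' * **flexible**: per-tier thresholds; all lower tiers fully implemented,
#'   a minimum implemented fraction at the candidate tier, and caps on the
#'   partially-implemented and not-implemented fractions (Pre-bronze 100%;
#'   Bronze 95%/5%/0; Silver 90%/10%/0; Gold 85%/15%/5%;
#'   Gold-plus 80%/20%/10%).
#' * **restricted** (restricted flexibility): the flexible thresholds plus
#'   the requirement that every critical sub-indicator designated at or
#'   below the candidate tier is IMPLEMENTED.
#'
#' The who-gbt profile defines strict and flexible; its flexible ML2 rule
#' pools the ML1 and ML2 sub-indicators (95% of ML1+ML2 implemented, the
#' remainder in process of implementation), ML3 requires 90% and ML4 80% of
#' their own pools with all lower levels fully implemented.
#'
#' All fraction comparisons are exact (integer cross-multiplication), so
#' 19 implemented out of 20 meets a 95% floor exactly.
#'
#' @name maturity_engine
NULL

#' Check one tier's thresholds against a tally
#'
#' @param tally A [tally()] data frame covering all designation tiers.
#' @param tier The candidate tier to check.
#' @param thresholds One-row threshold data frame for `tier` (columns as in
#'   the catalog's algorithm tables), or a full table from which the row
#'   for `tier` is taken.
#' @return List with `pass` (logical) and `shortfalls`, a data frame with
#'   columns `tier`, `constraint`, `required`, `observed`. A tier with no
#'   applicable sub-indicators passes vacuously.
#' @export
check_tier <- function(tally, tier, thresholds) {
  profile <- attr(tally, "profile")
  if (nrow(thresholds) > 1L) thresholds <- thresholds[thresholds$tier == tier, , drop = FALSE]
  stopifnot(nrow(thresholds) == 1L, identical(thresholds$tier, tier))
  sf <- list()
  add <- function(tr, constraint, required, observed)
    sf[[length(sf) + 1L]] <<- data.frame(tier = tr, constraint = constraint,
                                         required = required, observed = observed,
                                         stringsAsFactors = FALSE)
  row_of <- function(tr) tally[tally$tier == tr, , drop = FALSE]
  this <- row_of(tier)
  stopifnot(nrow(this) == 1L)

  pool <- this
  if (isTRUE(thresholds$pooled_with_lower)) {
    lower <- tiers_below(tier, profile)
    pooled_rows <- tally[tally$tier %in% c(lower, tier), , drop = FALSE]
    pool <- data.frame(tier = tier,
                       implemented_n = sum(pooled_rows$implemented_n),
                       partial_n = sum(pooled_rows$partial_n),
                       ongoing_n = sum(pooled_rows$ongoing_n),
                       not_implemented_n = sum(pooled_rows$not_implemented_n),
                       applicable_n = sum(pooled_rows$applicable_n))
  }

  # vacuous pass when nothing is applicable at (or pooled into) this tier
  if (pool$applicable_n == 0L)
    return(list(pass = TRUE, shortfalls = empty_shortfalls()))

  if (isTRUE(thresholds$lower_tiers_full)) {
    for (lt in tiers_below(tier, profile)) {
      lr <- row_of(lt)
      if (lr$implemented_n < lr$applicable_n)
        add(lt, "lower_tier_full",
            frac_str(lr$applicable_n, lr$applicable_n),
            frac_str(lr$implemented_n, lr$applicable_n))
    }
  }

  n <- pool$applicable_n
  i <- pool$implemented_n
  p <- pool$partial_n + pool$ongoing_n
  x <- pool$not_implemented_n
  if (!frac_ge(i, n, thresholds$min_implemented))
    add(tier, "min_implemented",
        frac_str(frac_ceil_count(n, thresholds$min_implemented), n), frac_str(i, n))
  if (!frac_le(p, n, thresholds$max_partial))
    add(tier, "max_partial",
        frac_str(frac_floor_count(n, thresholds$max_partial), n), frac_str(p, n))
  if (!frac_le(x, n, thresholds$max_not_implemented))
    add(tier, "max_not_implemented",
        frac_str(frac_floor_count(n, thresholds$max_not_implemented), n), frac_str(x, n))

  shortfalls <- if (length(sf)) do.call(rbind, sf) else empty_shortfalls()
  list(pass = nrow(shortfalls) == 0L, shortfalls = shortfalls)
}

empty_shortfalls <- function() {
  data.frame(tier = character(), constraint = character(), required = character(),
             observed = character(), stringsAsFactors = FALSE)
}

get_algorithm <- function(catalog, algorithm) {
  if (!algorithm %in% names(catalog$algorithms))
    stop("unknown algorithm '", algorithm, "' for profile '", catalog$profile,
         "' (available: ", paste(names(catalog$algorithms), collapse = ", "), ")",
         call. = FALSE)
  alg <- catalog$algorithms[[algorithm]]
  if (alg$requires_critical && !any(catalog$sub_indicators$critical))
    stop("algorithm '", algorithm, "' requires critical sub-indicator flags, ",
         "but this catalog defines none", call. = FALSE)
  alg
}

# critical shortfall rows for candidate tier `upto` (restricted flexibility)
critical_shortfalls <- function(rows, upto, profile) {
  ranks <- tier_rank(rows$tier, profile)
  sel <- rows$critical & ranks <= tier_rank(upto, profile) &
    rows$rating != "NOT_APPLICABLE" & rows$rating != "IMPLEMENTED"
  if (!any(sel)) return(empty_shortfalls())
  data.frame(tier = rows$tier[sel], constraint = "critical_implemented",
             required = "IMPLEMENTED", observed = paste0(rows$sub_id[sel], "=", rows$rating[sel]),
             stringsAsFactors = FALSE)
}

#' Classify a function to a maturity tier
#'
#' @param assessment A `vmra_assessment`.
#' @param catalog The catalog.
#' @param function_code Function to classify.
#' @param algorithm Algorithm name defined in the catalog (vmra: `strict`,
#'   `flexible`, `restricted`; who-gbt: `strict`, `flexible`).
#' @return An object of class `vmra_maturity`: `function_code`,
#'   `algorithm`, `achieved_tier` (the ladder floor when even the entry
#'   tier fails), `qualifier` (e.g. `"Bronze (flexible)"`; when the strict
#'   algorithm reaches the same tier the strict qualifier is preferred) and
#'   `shortfalls` for the first tier above the achieved one.
#' @examples
#' vmra <- reference_catalog("vmra")
#' a <- gen_assessment(vmra, mix = c(IMPLEMENTED = 1), seed = 1)
#' classify_function(a, vmra, "VRS", "flexible")
#' @export
classify_function <- function(assessment, catalog, function_code, algorithm = "flexible") {
  alg <- get_algorithm(catalog, algorithm)
  rows <- function_rows(assessment, catalog, function_code)
  res <- classify_rows(rows, catalog, alg, algorithm, function_code)
  if (algorithm != "strict" && "strict" %in% names(catalog$algorithms)) {
    strict_res <- classify_rows(rows, catalog, catalog$algorithms[["strict"]],
                                "strict", function_code)
    if (identical(strict_res$achieved_tier, res$achieved_tier))
      res$qualifier <- paste0(tier_label(res$achieved_tier, catalog$profile), " (strict)")
  }
  res
}

classify_rows <- function(rows, catalog, alg, algorithm, function_code) {
  profile <- catalog$profile
  tl <- tally_from_rows(rows, profile, function_code)
  dt <- designation_tiers(profile)

  tier_ok <- vapply(dt, function(t) check_tier(tl, t, alg$tiers)$pass, logical(1))
  candidate_ok <- vapply(seq_along(dt), function(k) {
    ok <- all(tier_ok[seq_len(k)])
    if (ok && alg$requires_critical)
      ok <- nrow(critical_shortfalls(rows, dt[k], profile)) == 0L
    ok
  }, logical(1))

  achieved <- if (any(candidate_ok)) dt[max(which(candidate_ok))] else tier_floor(profile)

  shortfalls <- empty_shortfalls()
  achieved_rank <- tier_rank(achieved, profile)
  if (achieved_rank < tier_rank(tier_top(profile), profile)) {
    next_tier <- tier_levels(profile)[achieved_rank + 1L]
    # first failing tier at the next candidate: lowest tier <= next with findings
    for (t in dt[seq_len(match(next_tier, dt))]) {
      ck <- check_tier(tl, t, alg$tiers)
      if (!ck$pass) { shortfalls <- ck$shortfalls; break }
    }
    if (nrow(shortfalls) == 0L && alg$requires_critical)
      shortfalls <- critical_shortfalls(rows, next_tier, profile)
  }

  structure(list(function_code = function_code, algorithm = algorithm,
                 achieved_tier = achieved,
                 qualifier = paste0(tier_label(achieved, profile), " (", algorithm, ")"),
                 shortfalls = shortfalls),
            class = "vmra_maturity")
}

#' @export
print.vmra_maturity <- function(x, ...) {
  cat(sprintf("<vmra_maturity> %s: %s\n", x$function_code, x$qualifier))
  if (nrow(x$shortfalls)) {
    cat("  shortfalls blocking the next tier:\n")
    for (i in seq_len(nrow(x$shortfalls)))
      cat(sprintf("    %s %s: required %s, observed %s\n",
                  x$shortfalls$tier[i], x$shortfalls$constraint[i],
                  x$shortfalls$required[i], x$shortfalls$observed[i]))
  }
  invisible(x)
}

#' Classify the whole institution
#'
#' The institution's tier is the minimum of the per-function tiers, further
#' capped by the highest tier T for which every applicable
#' institution-mandatory sub-indicator designated at or below T is
#' IMPLEMENTED.
#'
#' @inheritParams classify_function
#' @return An object of class `vmra_institution`: `functions` (named list
#'   of per-function `vmra_maturity` results), `institution_tier`,
#'   `qualifier`, and `mandatory_failures` (sub-indicator ids of
#'   non-implemented mandatory items at or below the per-function minimum).
#' @export
classify_institution <- function(assessment, catalog, algorithm = "flexible") {
  get_algorithm(catalog, algorithm)  # fail fast on bad algorithm
  er <- effective_responses(assessment, catalog)
  fcodes <- catalog$functions$function_code
  results <- lapply(fcodes, function(fc) {
    rows <- er[er$function_code == fc, , drop = FALSE]
    res <- classify_rows(rows, catalog, catalog$algorithms[[algorithm]], algorithm, fc)
    if (algorithm != "strict" && "strict" %in% names(catalog$algorithms)) {
      sres <- classify_rows(rows, catalog, catalog$algorithms[["strict"]], "strict", fc)
      if (identical(sres$achieved_tier, res$achieved_tier))
        res$qualifier <- paste0(tier_label(res$achieved_tier, catalog$profile), " (strict)")
    }
    res
  })
  names(results) <- fcodes
  profile <- catalog$profile
  fn_ranks <- vapply(results, function(r) tier_rank(r$achieved_tier, profile), integer(1))
  min_fn_rank <- if (length(fn_ranks)) min(fn_ranks) else 1L

  mand <- er[er$institution_mandatory & er$rating != "NOT_APPLICABLE", , drop = FALSE]
  lv <- tier_levels(profile)
  cap_rank <- length(lv)
  if (nrow(mand)) {
    bad_ranks <- tier_rank(mand$tier[mand$rating != "IMPLEMENTED"], profile)
    if (length(bad_ranks)) cap_rank <- min(bad_ranks) - 1L
  }
  inst_rank <- min(min_fn_rank, cap_rank)
  inst_tier <- lv[inst_rank]
  qualifier_alg <- algorithm
  if (algorithm != "strict" && "strict" %in% names(catalog$algorithms)) {
    strict_inst <- suppressWarnings(classify_institution(assessment, catalog, "strict"))
    if (identical(strict_inst$institution_tier, inst_tier)) qualifier_alg <- "strict"
  }
  failures <- character()
  if (nrow(mand)) {
    sel <- mand$rating != "IMPLEMENTED" & tier_rank(mand$tier, profile) <= min_fn_rank
    failures <- sort(mand$sub_id[sel])
  }
  structure(list(functions = results, institution_tier = inst_tier,
                 qualifier = paste0(tier_label(inst_tier, profile), " (", qualifier_alg, ")"),
                 algorithm = algorithm, mandatory_failures = failures),
            class = "vmra_institution")
}

#' @export
print.vmra_institution <- function(x, ...) {
  cat("<vmra_institution>", x$qualifier, "\n")
  for (r in x$functions) cat(sprintf("  %s: %s\n", r$function_code, r$qualifier))
  if (length(x$mandatory_failures))
    cat("  mandatory failures:", paste(x$mandatory_failures, collapse = ", "), "\n")
  invisible(x)
}

# ---- shipped threshold tables (catalog data, not engine constants) ------

#' Threshold tables for the shipped profiles
#'
#' These construct the algorithm threshold tables embedded in the bundled
#' catalogs. They are data: a custom catalog may define its own tables.
#' `strict_thresholds()` requires 100% implementation at every tier;
#' `vmra_flexible_thresholds()` encodes the vmra flexible scheme
#' (Bronze 95%/5%/0, Silver 90%/10%/0, Gold 85%/15%/5%,
#' Gold-plus 80%/20%/10%, Pre-bronze 100%); `who_flexible_thresholds()`
#' encodes the who-gbt flexible scheme (ML2 95% of the pooled ML1+ML2,
#' ML3 90%, ML4 80%, remainders in process of implementation, i.e. ongoing
#' or partially implemented; ML1 has no printed flexible relaxation and is
#' kept at 100%).
#'
#' @param profile Profile id for `strict_thresholds()`.
#' @return Data frame with one row per designation tier and columns `tier`,
#'   `min_implemented`, `max_partial`, `max_not_implemented` (fraction
#'   strings), `lower_tiers_full`, `pooled_with_lower`.
#' @export
strict_thresholds <- function(profile) {
  dt <- designation_tiers(profile)
  data.frame(tier = dt, min_implemented = "1/1", max_partial = "0/1",
             max_not_implemented = "0/1", lower_tiers_full = TRUE,
             pooled_with_lower = FALSE, stringsAsFactors = FALSE)
}

#' @rdname strict_thresholds
#' @export
vmra_flexible_thresholds <- function() {
  data.frame(
    tier = c("PRE_BRONZE", "BRONZE", "SILVER", "GOLD", "GOLD_PLUS"),
    min_implemented = c("1/1", "19/20", "9/10", "17/20", "4/5"),
    max_partial = c("0/1", "1/20", "1/10", "3/20", "1/5"),
    max_not_implemented = c("0/1", "0/1", "0/1", "1/20", "1/10"),
    lower_tiers_full = TRUE,
    pooled_with_lower = FALSE,
    stringsAsFactors = FALSE)
}

#' @rdname strict_thresholds
#' @export
who_flexible_thresholds <- function() {
  data.frame(
    tier = c("ML1", "ML2", "ML3", "ML4"),
    min_implemented = c("1/1", "19/20", "9/10", "4/5"),
    max_partial = c("0/1", "1/20", "1/10", "1/5"),
    max_not_implemented = c("0/1", "0/1", "0/1", "0/1"),
    lower_tiers_full = c(TRUE, FALSE, TRUE, TRUE),
    pooled_with_lower = c(FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}
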