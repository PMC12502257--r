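#' Rating scale and scoring
#'
#' Responses use a sliding rating scale. Under the `vmra` profile the scale
#' is IMPLEMENTED (1), PARTIALLY_IMPLEMENTED (0.5), NOT_IMPLEMENTED (0);
#' the `who-gbt` profile keeps the four-step ladder IMPLEMENTED (1),
#' PARTIALLY_IMPLEMENTED (0.75), ONGOING_IMPLEMENTATION (0.25),
#' NOT_IMPLEMENTED (0). NOT_APPLICABLE is accepted everywhere and is
#' excluded from numerator and denominator alike — it never scores.
#'
#' All score arithmetic is exact: scores are quarter units (multiples of
#' 0.25) held as integers, and aggregates are reduced rationals.
#'
#' @name ratings
NULL

#' Sentinel for excluded (not-applicable) scores
#'
#' Returned by [score_rating()] for `NOT_APPLICABLE`; test with
#' [is_excluded()]. It is deliberately not a number.
#' @export
EXCLUDED <- structure("EXCLUDED", class = "vmra_excluded")

#' @rdname EXCLUDED
#' @param x Object to test.
#' @export
is_excluded <- function(x) inherits(x, "vmra_excluded")

# quarter-unit lookup for a scale data frame
scale_quarters <- function(scale) {
  stats::setNames(as.integer(round(scale$score * 4)), scale$rating)
}

resolve_scale <- function(scale) {
  if (inherits(scale, "vmra_catalog")) scale$scale else as_scale_df(scale)
}

#' Score a single rating
#'
#' @param rating Rating token (e.g. `"PARTIALLY_IMPLEMENTED"`).
#' @param scale A scale data frame (columns `rating`, `score`) or a
#'   `vmra_catalog` whose scale is used.
#' @return Numeric score in `[0, 1]`, or [EXCLUDED] for `NOT_APPLICABLE`.
#'   A rating outside the scale (e.g. `ONGOING_IMPLEMENTATION` under the
#'   vmra profile) is an error.
#' @examples
#' score_rating("PARTIALLY_IMPLEMENTED", reference_catalog("vmra"))
#' @export
score_rating <- function(rating, scale) {
  sc <- resolve_scale(scale)
  if (identical(rating, "NOT_APPLICABLE")) return(EXCLUDED)
  if (!rating %in% sc$rating)
    stop("rating '", rating, "' is not in this profile's scale (allowed: ",
         paste(c(sc$rating, "NOT_APPLICABLE"), collapse = ", "), ")", call. = FALSE)
  sc$score[sc$rating == rating]
}

# ---- assessments --------------------------------------------------------

#' Create an assessment
#'
#' An assessment maps sub-indicator ids to ratings plus free-text evidence
#' notes. Every response must refer to a sub-indicator in the catalog and
#' use a rating the catalog's scale allows (or `NOT_APPLICABLE`).
#'
#' @param catalog The catalog the responses refer to.
#' @param responses Data frame with columns `sub_id`, `rating`, and
#'   optionally `evidence` and `assessed_on`.
#' @return An object of class `vmra_assessment`.
#' @export
new_assessment <- function(catalog, responses) {
  stopifnot(inherits(catalog, "vmra_catalog"))
  responses <- as.data.frame(responses, stringsAsFactors = FALSE)
  stopifnot(all(c("sub_id", "rating") %in% names(responses)))
  if (is.null(responses$evidence)) responses$evidence <- ""
  if (is.null(responses$assessed_on)) responses$assessed_on <- NA_character_
  responses <- responses[c("sub_id", "rating", "evidence", "assessed_on")]
  responses$sub_id <- as.character(responses$sub_id)
  responses$rating <- normalise_rating(responses$rating)
  responses$evidence <- as.character(responses$evidence)
  responses$assessed_on <- as.character(responses$assessed_on)

  unknown <- setdiff(responses$sub_id, catalog$sub_indicators$sub_id)
  if (length(unknown))
    stop("responses refer to unknown sub-indicator id(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  if (anyDuplicated(responses$sub_id))
    stop("duplicate response for sub-indicator id(s): ",
         paste(unique(responses$sub_id[duplicated(responses$sub_id)]), collapse = ", "),
         call. = FALSE)
  allowed <- c(catalog$scale$rating, "NOT_APPLICABLE")
  bad <- setdiff(unique(responses$rating), allowed)
  if (length(bad))
    stop("rating(s) not in the '", catalog$profile, "' scale: ",
         paste(bad, collapse = ", "), call. = FALSE)

  structure(list(profile = catalog$profile, catalog_version = catalog$version,
                 responses = responses),
            class = "vmra_assessment")
}

# rating tokens are case-insensitive; spaces and hyphens map to underscores
normalise_rating <- function(x) {
  x <- toupper(trimws(as.character(x)))
  gsub("[ -]+", "_", x)
}

#' @export
print.vmra_assessment <- function(x, ...) {
  cat("<vmra_assessment> profile:", x$profile,
      " catalog version:", x$catalog_version, "\n")
  print(table(x$responses$rating))
  invisible(x)
}

#' Read and write assessment response files
#'
#' The response file is a comma-separated table (UTF-8, header row) with
#' columns `sub_indicator_id`, `rating`, `evidence`, `assessed_on`. Rating
#' tokens are case-insensitive.
#'
#' @param path CSV file path.
#' @param catalog Catalog the responses belong to.
#' @return `read_assessment()`: a `vmra_assessment`; `write_assessment()`:
#'   `path`, invisibly.
#' @export
read_assessment <- function(path, catalog) {
  if (!file.exists(path)) stop("response file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("sub_indicator_id", "rating") %in% names(df)))
    stop("response file must have columns sub_indicator_id and rating", call. = FALSE)
  new_assessment(catalog, data.frame(
    sub_id = df$sub_indicator_id, rating = df$rating,
    evidence = df$evidence %||% "", assessed_on = df$assessed_on %||% NA_character_,
    stringsAsFactors = FALSE))
}

#' @rdname read_assessment
#' @param assessment A `vmra_assessment`.
#' @export
write_assessment <- function(assessment, path) {
  r <- assessment$responses
  utils::write.csv(
    data.frame(sub_indicator_id = r$sub_id, rating = r$rating,
               evidence = r$evidence, assessed_on = r$assessed_on,
               stringsAsFactors = FALSE),
    path, row.names = FALSE, na = "")
  invisible(path)
}

# One row per catalog sub-indicator with its effective rating. Missing
# responses are conservatively treated as NOT_IMPLEMENTED (warned once).
effective_responses <- function(assessment, catalog, warn_missing = TRUE) {
  si <- catalog$sub_indicators
  m <- match(si$sub_id, assessment$responses$sub_id)
  rating <- assessment$responses$rating[m]
  n_missing <- sum(is.na(m))
  if (n_missing && warn_missing)
    warning(n_missing, " sub-indicator(s) have no recorded rating; treated as NOT_IMPLEMENTED",
            call. = FALSE)
  rating[is.na(m)] <- "NOT_IMPLEMENTED"
  data.frame(sub_id = si$sub_id, function_code = si$function_code,
             indicator_code = si$indicator_code, tier = si$tier,
             critical = si$critical, institution_mandatory = si$institution_mandatory,
             rating = rating, stringsAsFactors = FALSE)
}

#' Mean implementation score of a function
#'
#' Arithmetic mean of the rating scores over the function's applicable
#' (non-NOT_APPLICABLE) sub-indicators, kept as an exact reduced rational.
#'
#' @param assessment A `vmra_assessment`.
#' @param catalog The catalog.
#' @param function_code Function code to score.
#' @return A list of class `vmra_score` with `score` (numeric), `num`,
#'   `den` (reduced rational) and `applicable_count`. When every response
#'   in the function is NOT_APPLICABLE, `score` is [EXCLUDED] and
#'   `applicable_count` is 0.
#' @examples
#' cat10 <- gen_catalog(synth_spec(tier_counts = c(PRE_BRONZE = 2), seed = 1))
#' a <- gen_assessment(cat10, mix = c(IMPLEMENTED = 1), seed = 1)
#' function_score(a, cat10, "F1")
#' @export
function_score <- function(assessment, catalog, function_code) {
  er <- function_rows(assessment, catalog, function_code)
  q <- scale_quarters(catalog$scale)
  applicable <- er$rating != "NOT_APPLICABLE"
  n <- sum(applicable)
  if (n == 0L) {
    out <- list(score = EXCLUDED, num = NA_integer_, den = NA_integer_,
                applicable_count = 0L)
    class(out) <- "vmra_score"
    return(out)
  }
  total_quarters <- sum(q[er$rating[applicable]])
  r <- frac_reduce(total_quarters, 4L * n)
  out <- list(score = unname(r[["num"]] / r[["den"]]), num = unname(r[["num"]]),
              den = unname(r[["den"]]), applicable_count = as.integer(n))
  class(out) <- "vmra_score"
  out
}

#' @export
print.vmra_score <- function(x, ...) {
  if (is_excluded(x$score)) {
    cat("function score: EXCLUDED (no applicable responses)\n")
  } else {
    cat(sprintf("function score: %s/%s = %.4f over %d applicable sub-indicator(s)\n",
                x$num, x$den, x$score, x$applicable_count))
  }
  invisible(x)
}

function_rows <- function(assessment, catalog, function_code, warn_missing = TRUE) {
  if (!function_code %in% catalog$functions$function_code)
    stop("unknown function_code: ", function_code, call. = FALSE)
  er <- effective_responses(assessment, catalog, warn_missing = warn_missing)
  er[er$function_code == function_code, , drop = FALSE]
}

#' Per-tier rating tally of a function
#'
#' Counts, for each designation tier of the profile, how many of the
#' function's applicable sub-indicators are IMPLEMENTED, PARTIALLY
#' implemented, in ONGOING implementation, and NOT implemented. These
#' tallies are the direct input of the tier-threshold checks.
#'
#' @inheritParams function_score
#' @return A data frame of class `vmra_tally` with one row per designation
#'   tier and columns `tier`, `implemented_n`, `partial_n`, `ongoing_n`,
#'   `not_implemented_n`, `applicable_n`.
#' @export
tally <- function(assessment, catalog, function_code) {
  er <- function_rows(assessment, catalog, function_code)
  tally_from_rows(er, catalog$profile, function_code)
}

tally_from_rows <- function(rows, profile, function_code = NA_character_) {
  dt <- designation_tiers(profile)
  count <- function(tier, rating) sum(rows$tier == tier & rows$rating == rating)
  out <- data.frame(
    tier = dt,
    implemented_n = vapply(dt, count, integer(1), rating = "IMPLEMENTED"),
    partial_n = vapply(dt, count, integer(1), rating = "PARTIALLY_IMPLEMENTED"),
    ongoing_n = vapply(dt, count, integer(1), rating = "ONGOING_IMPLEMENTATION"),
    not_implemented_n = vapply(dt, count, integer(1), rating = "NOT_IMPLEMENTED"),
    stringsAsFactors = FALSE)
  out$applicable_n <- out$implemented_n + out$partial_n + out$ongoing_n +
    out$not_implemented_n
  rownames(out) <- NULL
  attr(out, "profile") <- profile
  attr(out, "function_code") <- function_code
  class(out) <- c("vmra_tally", class(out))
  out
}
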