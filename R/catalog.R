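#' Assessment-framework catalogs
#'
#' A catalog defines everything an assessment is scored against: the
#' regulatory functions, the thematic indicators, the tier-designated
#' sub-indicators, the rating scale with its numeric scores, and the
#' threshold tables of each maturity-classification algorithm. Catalogs are
#' plain YAML files with a versioned schema (see
#' `system.file("schema", "catalog-schema.json", package = "vmrasat")`);
#' unknown fields are rejected so that files round-trip bit-stably.
#'
#' @param profile Profile id (`"vmra"`, `"who-gbt"`, or a custom id using
#'   the vmra tier ladder).
#' @param title,version Free-text catalog metadata.
#' @param scale Data frame with columns `rating`, `score`. `NOT_APPLICABLE`
#'   is always accepted in responses and is never scored, so it does not
#'   appear here.
#' @param algorithms Named list; each element has `requires_critical`
#'   (logical: must every critical sub-indicator at or below the candidate
#'   tier be IMPLEMENTED?) and `tiers`, a data frame with columns `tier`,
#'   `min_implemented`, `max_partial`, `max_not_implemented` (fractions as
#'   `"num/den"` strings), `lower_tiers_full`, `pooled_with_lower`.
#' @param indicators Data frame with columns `indicator_code`, `name`.
#' @param functions Data frame with columns `function_code`, `name`.
#' @param sub_indicators Data frame with columns `sub_id`, `function_code`,
#'   `indicator_code`, `text`, `tier`, `critical`, `institution_mandatory`.
#' @param declared_totals Optional list with elements `total` and `tiers`
#'   (named counts); validation reports a "count mismatch" finding when the
#'   actual sub-indicator counts disagree.
#' @return An object of class `vmra_catalog`.
#' @seealso [load_catalog()], [write_catalog()], [validate_catalog()],
#'   [tier_counts()], [reference_catalog()]
#' @export
new_catalog <- function(profile, title = "", version = "1.0", scale, algorithms,
                        indicators, functions, sub_indicators,
                        declared_totals = NULL) {
  cat_obj <- structure(list(
    schema_version = 1L,
    profile = as.character(profile),
    title = as.character(title),
    version = as.character(version),
    scale = as_scale_df(scale),
    algorithms = lapply(algorithms, as_algorithm),
    indicators = as_plain_df(indicators, c("indicator_code", "name")),
    functions = as_plain_df(functions, c("function_code", "name")),
    sub_indicators = as_subind_df(sub_indicators),
    declared_totals = declared_totals
  ), class = "vmra_catalog")
  cat_obj
}

as_scale_df <- function(scale) {
  df <- as.data.frame(scale, stringsAsFactors = FALSE)
  stopifnot(all(c("rating", "score") %in% names(df)))
  data.frame(rating = as.character(df$rating), score = as.numeric(df$score),
             stringsAsFactors = FALSE)
}

as_algorithm <- function(a) {
  stopifnot(is.list(a), all(c("requires_critical", "tiers") %in% names(a)))
  tiers <- as.data.frame(a$tiers, stringsAsFactors = FALSE)
  need <- c("tier", "min_implemented", "max_partial", "max_not_implemented",
            "lower_tiers_full", "pooled_with_lower")
  stopifnot(all(need %in% names(tiers)))
  tiers <- tiers[need]
  tiers$tier <- as.character(tiers$tier)
  for (col in c("min_implemented", "max_partial", "max_not_implemented"))
    tiers[[col]] <- as.character(tiers[[col]])
  tiers$lower_tiers_full <- as.logical(tiers$lower_tiers_full)
  tiers$pooled_with_lower <- as.logical(tiers$pooled_with_lower)
  list(requires_critical = isTRUE(a$requires_critical), tiers = tiers)
}

as_plain_df <- function(df, cols) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(cols %in% names(df)))
  df <- df[cols]
  df[] <- lapply(df, as.character)
  rownames(df) <- NULL
  df
}

as_subind_df <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sub_id", "function_code", "indicator_code", "text", "tier",
            "critical", "institution_mandatory")
  stopifnot(all(need %in% names(df)))
  df <- df[need]
  for (col in c("sub_id", "function_code", "indicator_code", "text", "tier"))
    df[[col]] <- as.character(df[[col]])
  df$critical <- as.logical(df$critical)
  df$institution_mandatory <- as.logical(df$institution_mandatory)
  rownames(df) <- NULL
  df
}

#' @export
print.vmra_catalog <- function(x, ...) {
  cat("<vmra_catalog> profile:", x$profile, " version:", x$version, "\n")
  if (nzchar(x$title)) cat(" ", x$title, "\n")
  cat("  functions:", nrow(x$functions),
      " indicators:", nrow(x$indicators),
      " sub-indicators:", nrow(x$sub_indicators), "\n")
  tc <- tier_counts(x)
  cat("  tiers:", paste(sprintf("%s=%d", names(tc), tc), collapse = ", "), "\n")
  cat("  algorithms:", paste(names(x$algorithms), collapse = ", "), "\n")
  invisible(x)
}

#' Count sub-indicators per designation tier
#'
#' @param catalog A [new_catalog()] object.
#' @param function_code Optional function code; when given, counts are
#'   restricted to that function's sub-indicators.
#' @return Named integer vector over the profile's designation tiers, in
#'   ladder order. Values sum to the number of counted sub-indicators.
#' @examples
#' tier_counts(reference_catalog("vmra"))
#' @export
tier_counts <- function(catalog, function_code = NULL) {
  stopifnot(inherits(catalog, "vmra_catalog"))
  si <- catalog$sub_indicators
  if (!is.null(function_code)) {
    if (!function_code %in% catalog$functions$function_code)
      stop("unknown function_code: ", function_code, call. = FALSE)
    si <- si[si$function_code == function_code, , drop = FALSE]
  }
  dt <- designation_tiers(catalog$profile)
  counts <- table(factor(si$tier, levels = dt))
  stats::setNames(as.integer(counts), dt)
}

# ---- validation ---------------------------------------------------------

finding <- function(severity, location, message) {
  data.frame(severity = severity, location = location, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a catalog
#'
#' Checks every structural invariant of the catalog model: unique
#' sub-indicator ids, declared function and indicator codes, designation
#' tiers belonging to the profile's ladder, parseable threshold fractions,
#' score anchoring (IMPLEMENTED = 1, NOT_IMPLEMENTED = 0), critical flags
#' only in profiles that define a restricted-flexibility algorithm, and
#' agreement with any declared totals. Findings are returned, never thrown.
#'
#' @param catalog A [new_catalog()] object.
#' @return A `vmra_validation` data frame with columns `severity`
#'   (`"error"` or `"warning"`), `location`, `message`; zero rows iff all
#'   invariants hold.
#' @export
validate_catalog <- function(catalog) {
  f <- list()
  add <- function(...) f[[length(f) + 1L]] <<- finding(...)
  si <- catalog$sub_indicators
  dt <- designation_tiers(catalog$profile)

  if (!identical(catalog$schema_version, 1L))
    add("error", "schema_version", paste0("unsupported schema_version: ", catalog$schema_version))

  ## rating scale
  sc <- catalog$scale
  anchor <- function(rating, val) {
    if (rating %in% sc$rating && sc$score[sc$rating == rating] != val)
      add("error", "scale", paste0(rating, " must score ", val))
  }
  anchor("IMPLEMENTED", 1); anchor("NOT_IMPLEMENTED", 0)
  if (!all(c("IMPLEMENTED", "NOT_IMPLEMENTED") %in% sc$rating))
    add("error", "scale", "scale must include IMPLEMENTED and NOT_IMPLEMENTED")
  if (any(sc$score < 0 | sc$score > 1))
    add("error", "scale", "scores must lie in [0, 1]")
  if (any(abs(sc$score * 4 - round(sc$score * 4)) > 0))
    add("error", "scale", "scores must be multiples of 0.25 (exact quarter units)")
  if ("NOT_APPLICABLE" %in% sc$rating)
    add("error", "scale", "NOT_APPLICABLE is excluded from scoring and must not carry a score")
  if (anyDuplicated(sc$rating))
    add("error", "scale", "duplicate rating in scale")

  ## algorithms
  if (!length(catalog$algorithms))
    add("error", "algorithms", "at least one algorithm required")
  for (alg in names(catalog$algorithms)) {
    tiers <- catalog$algorithms[[alg]]$tiers
    loc <- paste0("algorithms/", alg)
    if (!setequal(tiers$tier, dt))
      add("error", loc, "threshold table must cover each designation tier exactly once")
    for (col in c("min_implemented", "max_partial", "max_not_implemented")) {
      ok <- vapply(tiers[[col]], function(x) !inherits(try(frac_parse(x), silent = TRUE), "try-error"), logical(1))
      if (!all(ok)) add("error", loc, paste0("malformed fraction in ", col))
    }
  }
  restricted_defined <- any(vapply(catalog$algorithms, `[[`, logical(1), "requires_critical"))

  ## indicators / functions
  if (anyDuplicated(catalog$indicators$indicator_code))
    add("error", "indicators", "duplicate indicator_code")
  if (nrow(catalog$indicators) > 13L)
    add("error", "indicators", paste0("profile declares at most 13 indicators, found ",
                                      nrow(catalog$indicators)))
  if (anyDuplicated(catalog$functions$function_code))
    add("error", "functions", "duplicate function_code")
  for (fc in catalog$functions$function_code) {
    if (!any(si$function_code == fc))
      add("warning", paste0("functions/", fc), "function has no sub-indicators")
  }

  ## sub-indicators
  dup <- unique(si$sub_id[duplicated(si$sub_id)])
  for (id in dup)
    add("error", paste0("sub_indicators/", id), paste0("duplicate sub_id: ", id))
  bad_fn <- unique(si$function_code[!si$function_code %in% catalog$functions$function_code])
  for (fc in bad_fn)
    add("error", "sub_indicators", paste0("unknown function_code: ", fc))
  bad_ind <- unique(si$indicator_code[!si$indicator_code %in% catalog$indicators$indicator_code])
  for (ic in bad_ind)
    add("error", "sub_indicators", paste0("unknown indicator_code: ", ic))
  bad_tier <- unique(si$tier[!si$tier %in% dt])
  for (tt in bad_tier)
    add("error", "sub_indicators", paste0("unknown or non-designation tier: ", tt))
  if (!restricted_defined && any(si$critical))
    add("error", "sub_indicators",
        "critical flags require an algorithm with requires_critical (restricted flexibility)")

  ## declared totals
  if (!is.null(catalog$declared_totals)) {
    decl <- catalog$declared_totals
    if (!is.null(decl$total) && decl$total != nrow(si))
      add("error", "declared_totals",
          paste0("count mismatch: declared total ", decl$total, " but found ", nrow(si)))
    if (!is.null(decl$tiers)) {
      actual <- tier_counts(catalog)
      for (tt in names(decl$tiers)) {
        if (!tt %in% names(actual)) {
          add("error", "declared_totals", paste0("count mismatch: unknown tier ", tt))
        } else if (decl$tiers[[tt]] != actual[[tt]]) {
          add("error", "declared_totals",
              paste0("count mismatch: tier ", tt, " declared ", decl$tiers[[tt]],
                     " but found ", actual[[tt]]))
        }
      }
    }
  }

  out <- if (length(f)) do.call(rbind, f) else
    data.frame(severity = character(), location = character(), message = character(),
               stringsAsFactors = FALSE)
  class(out) <- c("vmra_validation", class(out))
  out
}

#' @export
print.vmra_validation <- function(x, ...) {
  if (!nrow(x)) {
    cat("Catalog valid: no findings.\n")
  } else {
    cat(nrow(x), "finding(s):\n")
    for (i in seq_len(nrow(x)))
      cat(sprintf("  [%s] %s: %s\n", x$severity[i], x$location[i], x$message[i]))
  }
  invisible(x)
}

#' Export validation findings as JSON lines
#'
#' One finding per line, fields `severity`, `path`, `message`.
#'
#' @param report A [validate_catalog()] result.
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Invisibly (or visibly when `path` is `NULL`), a character vector
#'   of JSON lines.
#' @export
validation_jsonl <- function(report, path = NULL) {
  lines <- vapply(seq_len(nrow(report)), function(i) {
    jsonlite::toJSON(list(severity = report$severity[i], path = report$location[i],
                          message = report$message[i]), auto_unbox = TRUE)
  }, character(1))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# ---- file I/O -----------------------------------------------------------

catalog_top_keys <- c("schema_version", "profile", "title", "version", "scale",
                      "algorithms", "indicators", "functions", "declared_totals")
subind_keys <- c("sub_id", "indicator_code", "tier", "critical",
                 "institution_mandatory", "text")

#' Read a catalog file
#'
#' Parses the YAML catalog format, rejects unknown fields, assembles a
#' [new_catalog()] object and validates it. Any error-severity finding
#' aborts with a message listing every violated invariant.
#'
#' @param path Path to a catalog YAML file.
#' @return A validated `vmra_catalog`.
#' @examples
#' cat_path <- system.file("extdata", "vmra_reference.yaml", package = "vmrasat")
#' vmra <- load_catalog(cat_path)
#' nrow(vmra$sub_indicators)
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("catalog parse error: ", conditionMessage(e), call. = FALSE))
  catalog <- catalog_from_list(raw)
  rep <- validate_catalog(catalog)
  errs <- rep[rep$severity == "error", , drop = FALSE]
  if (nrow(errs)) {
    stop("catalog validation failed:\n",
         paste(sprintf("  %s: %s", errs$location, errs$message), collapse = "\n"),
         call. = FALSE)
  }
  catalog
}

catalog_from_list <- function(raw) {
  if (!is.list(raw)) stop("catalog parse error: top level must be a mapping", call. = FALSE)
  unknown <- setdiff(names(raw), catalog_top_keys)
  if (length(unknown))
    stop("catalog validation failed: unknown top-level field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(setdiff(catalog_top_keys, c("declared_totals", "title", "version")), names(raw))
  if (length(missing))
    stop("catalog validation failed: missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  scale <- do.call(rbind, lapply(raw$scale, function(s)
    data.frame(rating = s$rating, score = s$score, stringsAsFactors = FALSE)))

  algorithms <- lapply(raw$algorithms, function(a) {
    tiers <- do.call(rbind, lapply(a$tiers, function(t) {
      unknown <- setdiff(names(t), c("tier", "min_implemented", "max_partial",
                                     "max_not_implemented", "lower_tiers_full",
                                     "pooled_with_lower"))
      if (length(unknown))
        stop("catalog validation failed: unknown threshold field(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      data.frame(tier = t$tier, min_implemented = as.character(t$min_implemented),
                 max_partial = as.character(t$max_partial),
                 max_not_implemented = as.character(t$max_not_implemented),
                 lower_tiers_full = isTRUE(t$lower_tiers_full),
                 pooled_with_lower = isTRUE(t$pooled_with_lower),
                 stringsAsFactors = FALSE)
    }))
    list(requires_critical = isTRUE(a$requires_critical), tiers = tiers)
  })

  indicators <- do.call(rbind, lapply(raw$indicators, function(i)
    data.frame(indicator_code = i$indicator_code, name = i$name, stringsAsFactors = FALSE)))

  fn_meta <- do.call(rbind, lapply(raw$functions, function(fn)
    data.frame(function_code = fn$function_code, name = fn$name, stringsAsFactors = FALSE)))
  sub_rows <- lapply(raw$functions, function(fn) {
    if (is.null(fn$sub_indicators)) return(NULL)
    do.call(rbind, lapply(fn$sub_indicators, function(s) {
      unknown <- setdiff(names(s), subind_keys)
      if (length(unknown))
        stop("catalog validation failed: unknown sub-indicator field(s) on ",
             s$sub_id %||% "<missing id>", ": ", paste(unknown, collapse = ", "),
             call. = FALSE)
      data.frame(sub_id = s$sub_id, function_code = fn$function_code,
                 indicator_code = s$indicator_code, text = s$text %||% "",
                 tier = s$tier, critical = isTRUE(s$critical),
                 institution_mandatory = isTRUE(s$institution_mandatory),
                 stringsAsFactors = FALSE)
    }))
  })
  sub_indicators <- do.call(rbind, sub_rows)
  if (is.null(sub_indicators))
    sub_indicators <- data.frame(sub_id = character(), function_code = character(),
                                 indicator_code = character(), text = character(),
                                 tier = character(), critical = logical(),
                                 institution_mandatory = logical(),
                                 stringsAsFactors = FALSE)

  declared <- raw$declared_totals
  if (!is.null(declared) && !is.null(declared$tiers))
    declared$tiers <- lapply(declared$tiers, as.integer)
  if (!is.null(declared) && !is.null(declared$total))
    declared$total <- as.integer(declared$total)

  new_catalog(profile = raw$profile, title = raw$title %||% "",
              version = as.character(raw$version %||% "1.0"),
              scale = scale, algorithms = algorithms, indicators = indicators,
              functions = fn_meta, sub_indicators = sub_indicators,
              declared_totals = declared)
}

#' Write a catalog file
#'
#' Serialises a catalog to the YAML format read by [load_catalog()];
#' `load_catalog(write_catalog(x, p))` reproduces `x` field by field.
#'
#' @param catalog A `vmra_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "vmra_catalog"))
  si <- catalog$sub_indicators
  fns <- lapply(seq_len(nrow(catalog$functions)), function(i) {
    fc <- catalog$functions$function_code[i]
    rows <- si[si$function_code == fc, , drop = FALSE]
    list(function_code = fc, name = catalog$functions$name[i],
         sub_indicators = lapply(seq_len(nrow(rows)), function(j)
           list(sub_id = rows$sub_id[j], indicator_code = rows$indicator_code[j],
                tier = rows$tier[j], critical = rows$critical[j],
                institution_mandatory = rows$institution_mandatory[j],
                text = rows$text[j])))
  })
  out <- list(
    schema_version = catalog$schema_version,
    profile = catalog$profile,
    title = catalog$title,
    version = catalog$version,
    scale = lapply(seq_len(nrow(catalog$scale)), function(i)
      list(rating = catalog$scale$rating[i], score = catalog$scale$score[i])),
    algorithms = lapply(catalog$algorithms, function(a)
      list(requires_critical = a$requires_critical,
           tiers = lapply(seq_len(nrow(a$tiers)), function(i) as.list(a$tiers[i, ])))),
    indicators = lapply(seq_len(nrow(catalog$indicators)), function(i)
      as.list(catalog$indicators[i, ])),
    functions = fns
  )
  if (!is.null(catalog$declared_totals)) out$declared_totals <- catalog$declared_totals
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Bundled reference catalogs
#'
#' Loads one of the catalogs shipped with the package: the full VMRA-SAT
#' reference catalog (8 functions, 13 indicators, 235 tier-designated
#' sub-indicators with placeholder texts) or the WHO-GBT profile skeleton
#' (9 functions, 268 sub-indicators; its per-tier distribution is a
#' documented synthetic one, the published material giving only the total).
#'
#' @param profile `"vmra"` or `"who-gbt"`.
#' @return A validated `vmra_catalog`.
#' @examples
#' tier_counts(reference_catalog("vmra"))
#' @export
reference_catalog <- function(profile = c("vmra", "who-gbt")) {
  profile <- match.arg(profile)
  file <- if (profile == "vmra") "vmra_reference.yaml" else "who_gbt_skeleton.yaml"
  load_catalog(system.file("extdata", file, package = "vmrasat", mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
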