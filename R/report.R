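#' Assessment reports
#'
#' A report bundles the engine outputs for one assessment: per-function
#' scores (kept as exact rationals), tier tallies, maturity results with
#' their algorithm qualifiers, the institution summary, and IDP summary
#' counts. Rendering never recomputes anything — every number in a
#' rendered report is taken verbatim from the engine output. Percentages
#' are shown to one decimal place; the JSON rendering keeps the underlying
#' numerator/denominator pairs.
#'
#' @name reporting
NULL

#' Build a report
#'
#' @param assessment A `vmra_assessment`.
#' @param catalog The catalog.
#' @param algorithm Algorithm name.
#' @param agency Agency name recorded in the metadata.
#' @param date Assessment date recorded in the metadata; defaults to the
#'   latest `assessed_on` among the responses (or `NA`), so identical
#'   inputs always render byte-identical reports.
#' @return An object of class `vmra_report`.
#' @export
build_report <- function(assessment, catalog, algorithm = "flexible",
                         agency = "Unnamed agency", date = NULL) {
  inst <- classify_institution(assessment, catalog, algorithm)
  idp <- extract_gaps(assessment, catalog, algorithm)
  if (is.null(date)) {
    dates <- assessment$responses$assessed_on
    dates <- dates[!is.na(dates) & nzchar(dates)]
    date <- if (length(dates)) max(dates) else NA_character_
  }
  fcodes <- catalog$functions$function_code
  fn_rows <- lapply(fcodes, function(fc) {
    sc <- suppressWarnings(function_score(assessment, catalog, fc))
    res <- inst$functions[[fc]]
    list(function_code = fc,
         name = catalog$functions$name[catalog$functions$function_code == fc],
         score = if (is_excluded(sc$score)) NA_real_ else sc$score,
         score_num = sc$num, score_den = sc$den,
         applicable_count = sc$applicable_count,
         achieved_tier = res$achieved_tier, qualifier = res$qualifier,
         shortfalls = res$shortfalls,
         tally = suppressWarnings(tally(assessment, catalog, fc)))
  })
  names(fn_rows) <- fcodes

  idp_counts <- table(factor(idp$tier, levels = designation_tiers(catalog$profile)))
  structure(list(
    metadata = list(agency = agency, date = date, profile = catalog$profile,
                    catalog_version = catalog$version, algorithm = algorithm),
    functions = fn_rows,
    institution = list(tier = inst$institution_tier, qualifier = inst$qualifier,
                       mandatory_failures = inst$mandatory_failures),
    idp_summary = list(total = nrow(idp),
                       by_tier = stats::setNames(as.integer(idp_counts), names(idp_counts)))
  ), class = "vmra_report")
}

#' @export
print.vmra_report <- function(x, ...) {
  cat("<vmra_report>", x$metadata$agency, "—", x$metadata$profile,
      "profile,", x$metadata$algorithm, "algorithm\n")
  for (f in x$functions)
    cat(sprintf("  %-6s %-12s score %s\n", f$function_code, f$qualifier,
                ifelse(is.na(f$score), "n/a", sprintf("%.3f", f$score))))
  cat("  institution:", x$institution$qualifier, "\n")
  cat("  IDP entries:", x$idp_summary$total, "\n")
  invisible(x)
}

report_to_list <- function(report) {
  list(
    metadata = report$metadata,
    functions = lapply(unname(report$functions), function(f) {
      list(function_code = f$function_code, name = f$name,
           score = f$score,
           score_rational = list(num = f$score_num, den = f$score_den),
           applicable_count = f$applicable_count,
           achieved_tier = f$achieved_tier, qualifier = f$qualifier,
           shortfalls = df_records(f$shortfalls),
           tally = df_records(as.data.frame(f$tally)))
    }),
    institution = list(tier = report$institution$tier,
                       qualifier = report$institution$qualifier,
                       mandatory_failures = as.list(report$institution$mandatory_failures)),
    idp_summary = list(total = report$idp_summary$total,
                       by_tier = as.list(report$idp_summary$by_tier))
  )
}

df_records <- function(df) {
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' Render a report
#'
#' @param report A [build_report()] result.
#' @param format `"json"` (full structure, schema in
#'   `system.file("schema", "report-schema.json", package = "vmrasat")`),
#'   `"csv"` (one row per function) or `"markdown"`.
#' @param path Optional output file.
#' @return Character vector of document lines (a single JSON string for
#'   `"json"`); invisible when written to `path`.
#' @export
render_report <- function(report, format = c("json", "csv", "markdown"), path = NULL) {
  format <- match.arg(format)
  out <- switch(format,
    json = as.character(jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                                         digits = NA, null = "null", na = "null",
                                         pretty = TRUE)),
    csv = render_report_csv(report),
    markdown = render_report_md(report))
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

render_report_csv <- function(report) {
  rows <- do.call(rbind, lapply(report$functions, function(f)
    data.frame(function_code = f$function_code, name = f$name,
               achieved_tier = f$achieved_tier, qualifier = f$qualifier,
               score = ifelse(is.na(f$score), "", sprintf("%.1f", 100 * f$score)),
               score_num = ifelse(is.na(f$score_num), "", f$score_num),
               score_den = ifelse(is.na(f$score_den), "", f$score_den),
               applicable_count = f$applicable_count,
               stringsAsFactors = FALSE)))
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(rows, con, row.names = FALSE)
  close(con)
  out
}

render_report_md <- function(report) {
  md <- report$metadata
  profile <- md$profile
  out <- c(paste0("# Maturity assessment report: ", md$agency), "",
           paste0("- Profile: ", md$profile, " (catalog version ", md$catalog_version, ")"),
           paste0("- Algorithm: ", md$algorithm),
           paste0("- Date: ", ifelse(is.na(md$date), "not recorded", md$date)), "",
           paste0("Maturity ladder: ",
                  paste(tier_label(designation_tiers(profile), profile), collapse = " < ")),
           "", "## Functions", "",
           "| Function | Result | Mean score (%) | Applicable |",
           "|---|---|---|---|")
  for (f in report$functions)
    out <- c(out, sprintf("| %s (%s) | %s | %s | %d |", f$function_code, f$name,
                          f$qualifier,
                          ifelse(is.na(f$score), "n/a", sprintf("%.1f", 100 * f$score)),
                          f$applicable_count))
  out <- c(out, "", "## Institution", "",
           paste0("Overall maturity: **", report$institution$qualifier, "**"))
  if (length(report$institution$mandatory_failures))
    out <- c(out, paste0("Mandatory sub-indicators not implemented: ",
                         paste(report$institution$mandatory_failures, collapse = ", ")))
  out <- c(out, "", "## Institutional Development Plan", "",
           paste0("Open gaps: ", report$idp_summary$total))
  bt <- report$idp_summary$by_tier
  out <- c(out, sprintf("- %s: %d", tier_label(names(bt), profile), as.integer(bt)))
  out
}

#' Re-parse a JSON report rendering
#'
#' Inverse of `render_report(format = "json")` for round-trip checks.
#'
#' @param json JSON string or path to a JSON file.
#' @return A `vmra_report`.
#' @export
report_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  fns <- lapply(x$functions, function(f) {
    list(function_code = f$function_code, name = f$name,
         score = if (is.null(f$score)) NA_real_ else as.numeric(f$score),
         score_num = if (is.null(f$score_rational$num)) NA_integer_ else as.integer(f$score_rational$num),
         score_den = if (is.null(f$score_rational$den)) NA_integer_ else as.integer(f$score_rational$den),
         applicable_count = as.integer(f$applicable_count),
         achieved_tier = f$achieved_tier, qualifier = f$qualifier,
         shortfalls = records_df(f$shortfalls, c("tier", "constraint", "required", "observed")),
         tally = records_df(f$tally, c("tier", "implemented_n", "partial_n", "ongoing_n",
                                       "not_implemented_n", "applicable_n")))
  })
  names(fns) <- vapply(fns, `[[`, character(1), "function_code")
  bt <- unlist(x$idp_summary$by_tier)
  structure(list(
    metadata = list(agency = x$metadata$agency,
                    date = if (is.null(x$metadata$date)) NA_character_ else x$metadata$date,
                    profile = x$metadata$profile,
                    catalog_version = x$metadata$catalog_version,
                    algorithm = x$metadata$algorithm),
    functions = fns,
    institution = list(tier = x$institution$tier, qualifier = x$institution$qualifier,
                       mandatory_failures = as.character(unlist(x$institution$mandatory_failures))),
    idp_summary = list(total = as.integer(x$idp_summary$total),
                       by_tier = stats::setNames(as.integer(bt), names(bt)))
  ), class = "vmra_report")
}

records_df <- function(recs, cols) {
  if (!length(recs)) {
    df <- as.data.frame(stats::setNames(rep(list(character()), length(cols)), cols),
                        stringsAsFactors = FALSE)
    int_cols <- grep("_n$", cols, value = TRUE)
    for (cc in int_cols) df[[cc]] <- integer()
    return(df)
  }
  df <- do.call(rbind, lapply(recs, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  int_cols <- grep("_n$", names(df), value = TRUE)
  for (cc in int_cols) df[[cc]] <- as.integer(df[[cc]])
  rownames(df) <- NULL
  df
}
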