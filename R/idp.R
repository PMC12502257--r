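#' Institutional Development Plan (IDP) generation
#'
#' The IDP is the gap analysis attached to an assessment: one entry per
#' applicable sub-indicator that is not fully met, prioritised by
#' designated tier (ascending), critical flags first, then id. Each entry
#' records whether it blocks the next achievable tier under the chosen
#' algorithm, and carries a templated suggested action. `upgrade_path()`
#' complements it with a smallest set of rating upgrades that reaches a
#' requested target tier.
#'
#' @name idp_planner
NULL

#' Extract the gap list
#'
#' @param assessment A `vmra_assessment`.
#' @param catalog The catalog.
#' @param algorithm Algorithm used to decide which gaps block the next
#'   achievable tier of their function.
#' @return Data frame of class `vmra_idp`: `sub_id`, `function_code`,
#'   `indicator_code`, `tier`, `rating`, `critical`, `blocking`,
#'   `suggested_action`. Entries exist exactly for applicable
#'   sub-indicators whose rating is not IMPLEMENTED.
#' @examples
#' vmra <- reference_catalog("vmra")
#' a <- gen_assessment(vmra, mix = c(IMPLEMENTED = 0.9, NOT_IMPLEMENTED = 0.1), seed = 7)
#' head(extract_gaps(a, vmra))
#' @export
extract_gaps <- function(assessment, catalog, algorithm = "flexible") {
  get_algorithm(catalog, algorithm)
  er <- effective_responses(assessment, catalog)
  profile <- catalog$profile
  gaps <- er[er$rating != "IMPLEMENTED" & er$rating != "NOT_APPLICABLE", , drop = FALSE]

  gaps$blocking <- logical(nrow(gaps))
  top <- tier_top(profile)
  for (fc in unique(gaps$function_code)) {
    rows <- er[er$function_code == fc, , drop = FALSE]
    achieved <- classify_rows(rows, catalog, catalog$algorithms[[algorithm]],
                              algorithm, fc)$achieved_tier
    if (identical(achieved, top)) next
    next_tier <- tier_levels(profile)[tier_rank(achieved, profile) + 1L]
    fgaps <- which(gaps$function_code == fc &
                     tier_rank(gaps$tier, profile) <= tier_rank(next_tier, profile))
    for (g in fgaps) {
      # blocking iff the function still misses next_tier when this is the
      # only remaining gap
      solo <- rows
      solo$rating[solo$rating != "NOT_APPLICABLE"] <- "IMPLEMENTED"
      solo$rating[solo$sub_id == gaps$sub_id[g]] <- gaps$rating[g]
      res <- classify_rows(solo, catalog, catalog$algorithms[[algorithm]], algorithm, fc)
      gaps$blocking[g] <- tier_rank(res$achieved_tier, profile) < tier_rank(next_tier, profile)
    }
  }

  ind_names <- stats::setNames(catalog$indicators$name, catalog$indicators$indicator_code)
  gaps$suggested_action <- sprintf(
    "Advance %s (%s, %s) from %s to IMPLEMENTED; collect and attach supporting evidence.",
    gaps$sub_id, ind_names[gaps$indicator_code], tier_label(gaps$tier, profile), gaps$rating)

  ord <- order(tier_rank(gaps$tier, profile), !gaps$critical, gaps$sub_id)
  gaps <- gaps[ord, c("sub_id", "function_code", "indicator_code", "tier", "rating",
                      "critical", "blocking", "suggested_action")]
  rownames(gaps) <- NULL
  class(gaps) <- c("vmra_idp", class(gaps))
  gaps
}

#' Minimal upgrade path to a target tier
#'
#' Computes a smallest-cardinality set of single-sub-indicator rating
#' upgrades (all to IMPLEMENTED — raising the implemented count can never
#' violate a cap, so intermediate ratings are never needed for a minimal
#' path) after which the function (or, when `function_code` is `NULL`, the
#' institution) classifies at or above `target_tier` under `algorithm`.
#' Per tier, the not-implemented items above the caps are raised first,
#' then further items are promoted to meet the implemented floor; ties are
#' broken critical-first, then by sub-indicator id. The result is verified
#' by reclassification before it is returned.
#'
#' @inheritParams extract_gaps
#' @param target_tier Designation tier to reach.
#' @param function_code Function to upgrade, or `NULL` for the institution
#'   (per-function paths plus institution-mandatory items).
#' @return Data frame with columns `sub_id`, `function_code`, `tier`,
#'   `from_rating`, `to_rating`; zero rows when the target is already met.
#' @export
upgrade_path <- function(assessment, catalog, algorithm = "flexible",
                         target_tier, function_code = NULL) {
  alg <- get_algorithm(catalog, algorithm)
  profile <- catalog$profile
  if (!target_tier %in% designation_tiers(profile))
    stop("target_tier must be a designation tier of profile '", profile, "'",
         call. = FALSE)
  er <- effective_responses(assessment, catalog)

  if (is.null(function_code)) {
    # institution-mandatory items at or below the target must be implemented;
    # feed them into each function's deficit computation so they count
    # toward the floors there
    mand <- er$institution_mandatory & er$rating != "NOT_APPLICABLE" &
      er$rating != "IMPLEMENTED" &
      tier_rank(er$tier, profile) <= tier_rank(target_tier, profile)
    mand_ids <- er$sub_id[mand]
    ids <- unlist(lapply(catalog$functions$function_code, function(fc)
      path_ids_for_function(er[er$function_code == fc, , drop = FALSE],
                            catalog, alg, target_tier, forced_ids = mand_ids)))
    ids <- unique(c(ids, mand_ids))
  } else {
    ids <- path_ids_for_function(er[er$function_code == function_code, , drop = FALSE],
                                 catalog, alg, target_tier)
  }

  out <- er[match(ids, er$sub_id), c("sub_id", "function_code", "tier", "rating")]
  names(out)[names(out) == "rating"] <- "from_rating"
  out$to_rating <- rep("IMPLEMENTED", nrow(out))
  rownames(out) <- NULL

  # self-consistency: applying the path must reach the target
  upgraded <- assessment
  resp <- effective_to_responses(er, ids)
  upgraded$responses <- resp
  reached <- if (is.null(function_code)) {
    suppressWarnings(classify_institution(upgraded, catalog, algorithm))$institution_tier
  } else {
    suppressWarnings(classify_function(upgraded, catalog, function_code, algorithm))$achieved_tier
  }
  if (tier_rank(reached, profile) < tier_rank(target_tier, profile))
    stop("internal error: upgrade path fails to reach ", target_tier, call. = FALSE)
  out
}

effective_to_responses <- function(er, upgraded_ids) {
  rating <- er$rating
  rating[er$sub_id %in% upgraded_ids] <- "IMPLEMENTED"
  data.frame(sub_id = er$sub_id, rating = rating, evidence = "",
             assessed_on = NA_character_, stringsAsFactors = FALSE)
}

# minimal set of sub_ids to promote to IMPLEMENTED so that one function
# reaches target_tier under algorithm `alg`
path_ids_for_function <- function(rows, catalog, alg, target_tier,
                                  forced_ids = character()) {
  profile <- catalog$profile
  rows <- rows[rows$rating != "NOT_APPLICABLE", , drop = FALSE]
  target_rank <- tier_rank(target_tier, profile)
  ranks <- tier_rank(rows$tier, profile)

  chosen <- character()
  promote <- function(ids) chosen <<- union(chosen, ids)
  is_gap <- function(sel) sel & rows$rating != "IMPLEMENTED" & !(rows$sub_id %in% chosen)

  # upgrades imposed from outside (institution-mandatory items)
  promote(intersect(forced_ids, rows$sub_id[rows$rating != "IMPLEMENTED"]))
  # forced: critical items at or below the target (restricted flexibility)
  if (alg$requires_critical)
    promote(rows$sub_id[is_gap(ranks <= target_rank & rows$critical)])

  dt <- designation_tiers(profile)
  for (t in dt[seq_len(match(target_tier, dt))]) {
    th <- alg$tiers[alg$tiers$tier == t, , drop = FALSE]
    trank <- tier_rank(t, profile)
    # every tier strictly below the target must end up fully implemented:
    # either its own floor is 100% or a higher tier's lower_tiers_full (or
    # the target's) demands it
    if (trank < target_rank) {
      promote(rows$sub_id[is_gap(ranks == trank)])
      next
    }
    pool_sel <- if (isTRUE(th$pooled_with_lower)) ranks <= trank else ranks == trank
    eff_rating <- ifelse(rows$sub_id %in% chosen, "IMPLEMENTED", rows$rating)
    n <- sum(pool_sel)
    if (n == 0L) next
    i <- sum(pool_sel & eff_rating == "IMPLEMENTED")
    p_sel <- pool_sel & eff_rating %in% c("PARTIALLY_IMPLEMENTED", "ONGOING_IMPLEMENTATION")
    x_sel <- pool_sel & eff_rating == "NOT_IMPLEMENTED"
    need_i <- max(0L, frac_ceil_count(n, th$min_implemented) - i)
    over_x <- max(0L, sum(x_sel) - frac_floor_count(n, th$max_not_implemented))
    over_p <- max(0L, sum(p_sel) - frac_floor_count(n, th$max_partial))

    take <- function(sel, k) {
      cand <- rows[sel, , drop = FALSE]
      cand <- cand[order(!cand$critical, cand$sub_id), , drop = FALSE]
      utils::head(cand$sub_id, k)
    }
    # raise the over-cap counts first; promoting to IMPLEMENTED also feeds
    # the floor, so total upgrades = max(over_x + over_p, need_i)
    ux <- take(x_sel, over_x)
    up <- take(p_sel, over_p)
    promote(c(ux, up))
    extra <- need_i - length(ux) - length(up)
    if (extra > 0L) {
      rest_x <- take(x_sel & !(rows$sub_id %in% chosen), extra)
      promote(rest_x)
      extra <- extra - length(rest_x)
      if (extra > 0L) promote(take(p_sel & !(rows$sub_id %in% chosen), extra))
    }
  }
  chosen
}

#' Render an IDP
#'
#' @param idp An [extract_gaps()] result.
#' @param format `"csv"` or `"markdown"` (sections per tier).
#' @param path Optional output file.
#' @return The rendered document as a character vector of lines (invisibly
#'   when written to `path`).
#' @export
render_idp <- function(idp, format = c("csv", "markdown"), path = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(as.data.frame(idp), con, row.names = FALSE)
    close(con)
  } else {
    out <- c("# Institutional Development Plan", "")
    for (t in unique(idp$tier)) {
      rows <- idp[idp$tier == t, , drop = FALSE]
      out <- c(out, paste0("## ", t, " (", nrow(rows), " gap(s))"), "")
      out <- c(out, sprintf("- **%s**%s%s [%s]: %s", rows$sub_id,
                            ifelse(rows$critical, " (critical)", ""),
                            ifelse(rows$blocking, " (blocking)", ""),
                            rows$rating, rows$suggested_action))
      out <- c(out, "")
    }
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
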