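# Programmatic construction of the bundled catalogs. The YAML files under
# inst/extdata are generated from these builders (see data-raw/); texts of
# the individual sub-indicators are structured placeholders — the published
# framework defines their codes, tier designations and counts, not their
# wording.

vmra_functions <- function() {
  data.frame(
    function_code = c("VRS", "VMA", "VPV", "VMC", "VLI", "VRI", "VLT", "VBR"),
    name = c("Veterinary Medicines Regulatory Systems",
             "Veterinary Medicines Registration and Marketing Authorisation",
             "Veterinary Medicines Pharmacovigilance",
             "Veterinary Medicines Market Surveillance and Control",
             "Veterinary Medicines Licensing Establishments",
             "Veterinary Medicines Regulatory Inspection",
             "Veterinary Medicines Laboratory Testing",
             "Veterinary Medicines Batch Release"),
    stringsAsFactors = FALSE)
}

framework_indicators <- function() {
  data.frame(
    indicator_code = c("LP", "OG", "PS", "LC", "TC", "FR", "MO", "QM", "RP",
                       "HR", "MP", "LS", "IE"),
    name = c("Legal provisions, regulations and guidelines",
             "Organisation and governance",
             "Policy and strategic planning",
             "Leadership and crisis management",
             "Transparency, accountability and communication",
             "Financial resources",
             "Management of outsourced activities",
             "Quality and risk management system",
             "Regulatory process",
             "Human resources",
             "Monitoring progress and assessing impact",
             "Laboratory services",
             "Infrastructure and equipment"),
    stringsAsFactors = FALSE)
}

# per-function sub-indicator counts for each vmra designation tier;
# rows sum to the published per-tier totals 6 / 21 / 28 / 154 / 26
vmra_tier_layout <- function() {
  fn <- c("VRS", "VMA", "VPV", "VMC", "VLI", "VRI", "VLT", "VBR")
  m <- rbind(
    PRE_BRONZE = c(5, 1, 0, 0, 0, 0, 0, 0),
    BRONZE     = c(4, 4, 2, 2, 3, 2, 2, 2),
    SILVER     = c(4, 5, 3, 4, 3, 4, 3, 2),
    GOLD       = c(20, 26, 20, 20, 16, 20, 20, 12),
    GOLD_PLUS  = c(4, 4, 4, 3, 3, 3, 3, 2))
  colnames(m) <- fn
  m
}

build_vmra_reference <- function() {
  fns <- vmra_functions()
  layout <- vmra_tier_layout()
  inds <- framework_indicators()
  ind_cycle <- inds$indicator_code

  pre_bronze <- data.frame(
    sub_id = c("VRS-PB-01", "VRS-PB-02", "VRS-PB-03", "VRS-PB-04", "VRS-PB-05",
               "VMA-PB-01"),
    function_code = c(rep("VRS", 5), "VMA"),
    indicator_code = c("LP", "LP", "LP", "FR", "TC", "TC"),
    text = c(
      "Legal foundation: primary legislation establishing the veterinary medicines regulatory agency.",
      "Legal foundation: the legislation confers a mandate and enforcement powers over veterinary medicines.",
      "Legal foundation: implementing regulations for the core regulatory activities are in force.",
      "An established source of funding for the agency's regulatory activities.",
      "Published agency contact information for regulatory services.",
      "An up-to-date published list of veterinary medicines permitted on the national market."),
    tier = "PRE_BRONZE", critical = TRUE, institution_mandatory = TRUE,
    stringsAsFactors = FALSE)

  rows <- list(pre_bronze)
  for (tier in c("BRONZE", "SILVER", "GOLD", "GOLD_PLUS")) {
    ab <- abbreviate_tier(tier)
    for (fc in fns$function_code) {
      n <- layout[tier, fc]
      if (n == 0) next
      idx <- seq_len(n)
      rows[[paste(tier, fc)]] <- data.frame(
        sub_id = sprintf("%s-%s-%02d", fc, ab, idx),
        function_code = fc,
        indicator_code = ind_cycle[((idx - 1L) %% length(ind_cycle)) + 1L],
        text = sprintf("Placeholder requirement %s-%s-%02d (%s expectation for %s).",
                       fc, ab, idx, tier_label(tier), fc),
        tier = tier, critical = FALSE, institution_mandatory = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  si <- do.call(rbind, rows)
  rownames(si) <- NULL

  # critical set (user-editable catalog data): the six Pre-bronze items, the
  # clinical-field-trials requirement that replaces a dedicated clinical
  # trials function, and the first Bronze item of each function
  si$text[si$sub_id == "VMA-G-01"] <-
    "Legal provisions for veterinary clinical field trials (critical requirement standing in for a dedicated clinical-trials function)."
  si$critical[si$sub_id == "VMA-G-01"] <- TRUE
  si$critical[si$sub_id %in% sprintf("%s-B-01", fns$function_code)] <- TRUE
  # institution-mandatory placeholders at the higher tiers
  si$institution_mandatory[si$sub_id %in% c("VRS-B-01", "VRS-S-01", "VRS-G-01")] <- TRUE

  new_catalog(
    profile = "vmra",
    title = "VMRA-SAT reference catalog (placeholder sub-indicator texts)",
    version = "1.0",
    scale = vmra_scale(),
    algorithms = list(
      strict = list(requires_critical = FALSE, tiers = strict_thresholds("vmra")),
      flexible = list(requires_critical = FALSE, tiers = vmra_flexible_thresholds()),
      restricted = list(requires_critical = TRUE, tiers = vmra_flexible_thresholds())),
    indicators = framework_indicators(),
    functions = fns,
    sub_indicators = si,
    declared_totals = list(total = 235L,
                           tiers = list(PRE_BRONZE = 6L, BRONZE = 21L, SILVER = 28L,
                                        GOLD = 154L, GOLD_PLUS = 26L)))
}

who_functions <- function() {
  data.frame(
    function_code = c("RS", "MA", "VL", "MC", "LI", "RI", "LT", "CT", "LR"),
    name = c("National regulatory system", "Registration and marketing authorisation",
             "Vigilance", "Market surveillance and control", "Licensing establishments",
             "Regulatory inspection", "Laboratory testing", "Clinical trials oversight",
             "NRA lot release"),
    stringsAsFactors = FALSE)
}

# per-function counts per ML tier; the published material gives only the
# 268 total, so this distribution is synthetic (non-normative)
who_tier_layout <- function() {
  m <- rbind(
    ML1 = c(4, 4, 4, 3, 3, 3, 3, 3, 3),
    ML2 = c(6, 6, 6, 6, 6, 6, 6, 6, 6),
    ML3 = c(15, 15, 15, 15, 14, 14, 14, 14, 14),
    ML4 = c(6, 6, 6, 6, 6, 6, 6, 6, 6))
  colnames(m) <- who_functions()$function_code
  m
}

build_who_skeleton <- function() {
  fns <- who_functions()
  layout <- who_tier_layout()
  inds <- framework_indicators()
  ind_cycle <- inds$indicator_code
  rows <- list()
  for (tier in rownames(layout)) {
    for (fc in fns$function_code) {
      n <- layout[tier, fc]
      if (n == 0) next
      idx <- seq_len(n)
      rows[[paste(tier, fc)]] <- data.frame(
        sub_id = sprintf("%s-%s-%02d", fc, tier, idx),
        function_code = fc,
        indicator_code = ind_cycle[((idx - 1L) %% length(ind_cycle)) + 1L],
        text = sprintf("Placeholder requirement %s-%s-%02d (%s expectation for %s).",
                       fc, tier, idx, tier, fc),
        tier = tier, critical = FALSE, institution_mandatory = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  si <- do.call(rbind, rows)
  rownames(si) <- NULL
  si$institution_mandatory[si$sub_id %in% c("RS-ML1-01", "RS-ML2-01", "RS-ML3-01")] <- TRUE

  new_catalog(
    profile = "who-gbt",
    title = "WHO-GBT profile skeleton (synthetic, non-normative tier distribution)",
    version = "1.0",
    scale = who_scale(),
    algorithms = list(
      strict = list(requires_critical = FALSE, tiers = strict_thresholds("who-gbt")),
      flexible = list(requires_critical = FALSE, tiers = who_flexible_thresholds())),
    indicators = framework_indicators(),
    functions = fns,
    sub_indicators = si,
    declared_totals = list(total = 268L,
                           tiers = list(ML1 = 30L, ML2 = 54L, ML3 = 130L, ML4 = 54L)))
}
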