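---
title: "Maturity classification for veterinary medicines regulators: model, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maturity classification: model, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmrasat)
```

## The assessment model

The package implements a tiered capability-maturity assessment for
regulators of veterinary medicinal products, structured the way the WHO
Global Benchmarking Tool structures assessments of human-medicines
regulators. The unit of assessment is the **sub-indicator**: a single
verifiable requirement (a legal provision, a documented procedure, a
resourced activity), designated in advance to one maturity tier and
grouped under a thematic **indicator** within a regulatory **function**.

The vmra profile ships with 8 functions, 13 indicators and 235
sub-indicators designated Pre-bronze (6), Bronze (21), Silver (28), Gold
(154) and Gold-plus (26). Pre-bronze is the minimum operating capability:
a three-part legal foundation, an established funding source, published
agency contacts, and an up-to-date national list of permitted veterinary
medicines. The who-gbt profile skeleton has 9 functions and 268
sub-indicators over ML1–ML4.

Two modelling assumptions run through the engine:

* **Equal weighting.** Whether the live assessment software weights
  sub-indicators when displaying function scores is not documented; the
  package weights them equally, and records function scores as exact
  rational means so no information is lost before presentation.
* **Not-applicable exclusion.** A `NOT_APPLICABLE` response is removed
  from numerator and denominator everywhere — scores, tier tallies and
  threshold checks alike. Consequently a tier with no applicable
  sub-indicators passes its checks vacuously, and an assessment that is
  entirely not-applicable classifies to the top tier (the engine and the
  brute-force oracle agree on this by construction, and `validate`-level
  warnings surface empty functions). Real assessments always contain
  applicable items, so this boundary behaviour matters only for synthetic
  edge cases.

Missing responses are the opposite edge: a sub-indicator with no recorded
rating is scored `NOT_IMPLEMENTED` and a warning is raised, a deliberately
conservative choice that cannot inflate an agency's tier.

## Rating scales

The vmra scale is Implemented = 1, Partially implemented = 0.5, Not
implemented = 0; the who-gbt scale keeps Ongoing implementation = 0.25 and
scores Partially implemented 0.75. The vmra profile's two changes relative
to who-gbt — dropping the Ongoing category and halving the Partial score —
simplify scoring and avoid rewarding half-finished implementation. The
engine stores all scores internally in quarter units (integers 0–4), so
every aggregate is exact; catalog validation rejects scales that are not
quarter-multiples anchored at Implemented = 1 and Not implemented = 0.

## The three algorithms

A function's achieved tier is the highest designation tier `T` such that
the checks of `T` *and of every tier below it* pass:

* **strict** — thresholds (100%, 0, 0) at every tier: all applicable
  sub-indicators designated ≤ T must be Implemented.
* **flexible** — per-tier thresholds read from the catalog (they are data,
  not code constants): a floor on the implemented fraction, caps on the
  partially-implemented and not-implemented fractions, and full
  implementation of all lower tiers. The shipped vmra table is
  Bronze 95%/5%/0, Silver 90%/10%/0, Gold 85%/15%/5%, Gold-plus
  80%/20%/10%, with Pre-bronze admitting no relaxation at all.
* **restricted flexibility** (vmra only) — the flexible thresholds plus
  mandatory implementation of every sub-indicator flagged *critical* and
  designated ≤ T. It exists to stop an agency from parking essential
  requirements inside the flexible allowances.

Results carry a qualifier such as `"Silver (flexible)"`; when the strict
algorithm reaches the same tier, the strict qualifier is preferred as the
stronger statement.

The institution-level result is the minimum over function tiers, capped by
the highest tier for which every applicable institution-mandatory
sub-indicator designated at or below it is Implemented. The mandatory
mechanism is only sketched in the published description of the scheme;
this cap rule is the package's interpretation, and the offending
sub-indicator ids are always reported alongside the result.

### Numerical choices

Threshold fractions are stored as `"num/den"` strings and every comparison
is an integer cross-multiplication, so boundary cases are exact: 19 of 20
meets a 95% floor, 18 does not, with no floating-point tolerance anywhere
in the decision path. Floors are inclusive (`>=`) and caps are inclusive
(`<=`); the Gold row's columns (85 + 15 + 5 = 105%) are therefore treated
as an independent floor and two caps, not a partition — the "up to"
phrasing of the caps supports this reading. The "N/A" entries in the
not-implemented column for Bronze and Silver are caps of zero.

### The who-gbt flexible rules

ML2 is special: its 95% floor applies to the pooled ML1+ML2
sub-indicators, with the remainder *in process of implementation*
(Ongoing or Partially implemented — a not-implemented item is never
tolerated in a remainder). ML3 requires all lower levels full and 90% of
ML3; ML4 requires 80% of ML4. Two points were genuinely open and are
resolved as follows:

* No flexible relaxation for ML1 is published; ML1 under flexible is kept
  at 100%, identical to strict.
* Classification composes per tier: achieving ML2 requires ML1's own check
  to pass as well as the pooled ML2 check. A purely pooled reading (ML2
  achievable with ML1 below 100%) is arguable from the prose; the
  compositional rule was chosen because it preserves the ladder invariant
  that a higher tier never certifies less about lower tiers, and the two
  readings coincide whenever lower tiers are filled first.

## Gap analysis and upgrade paths

`extract_gaps()` lists every applicable sub-indicator not fully met,
ordered tier-ascending, critical first, then by id — the prioritisation is
an interpretation (the scheme's published description prescribes
prioritised, context-specific actions but no ordering rule), chosen so
that foundational gaps always precede aspirational ones. An entry is
*blocking* when the function still misses its next achievable tier with
every other gap hypothetically closed.

`upgrade_path()` returns a smallest set of single-sub-indicator upgrades
reaching a target tier. All upgrades go straight to Implemented: raising
the implemented count can never violate a floor, and the caps bind only on
partial/ongoing/not-implemented counts, so an upgrade to an intermediate
rating is dominated by the same upgrade taken to Implemented. Given that,
the minimum decomposes per tier — every tier below the target must be
fully implemented, and at the target tier the number of promotions is
`max(over-cap count, floor deficit)`, resolved not-implemented-first with
critical-first tie-breaks. Minimality is verified in the test suite
against exhaustive subset search on ≤ 10-item catalogs, and every returned
path is re-classified before being returned.

## The synthetic generator and the oracle

`gen_catalog()`/`gen_assessment()` produce catalogs with exact per-tier
counts and assessments drawn from an explicit rating mix; all randomness
flows through a caller-supplied seed (recorded in the output) and the
caller's RNG state is left untouched. `gen_assessment_at_tier()`
constructs an assessment that classifies exactly to a requested tier by
satisfying every tier up to the target — sprinkling in-process ratings
within the target tier's own allowance, per function, avoiding critical
and mandatory items — and setting everything above it to Not implemented.

The generator emulates structure, not behaviour: tier counts, criticality
and response mixes are controlled, but responses are independent across
sub-indicators, whereas real agencies' gaps cluster by indicator and
function (a missing quality-management system depresses many
sub-indicators at once). Passing tests therefore certify the engine's
arithmetic and ordering properties, not distributional realism of
simulated agencies.

`oracle_classify()` is an independent re-implementation used only in
tests: it recounts tiers directly from raw responses, evaluates each
tier's constraints in isolation (floating-point with an epsilon, a
deliberately different arithmetic route), and takes the maximal
consecutive passing run from the bottom. The test suites check
engine/oracle agreement on 200 seeded random assessments per profile and
algorithm, algorithm ordering (strict ≤ restricted ≤ flexible),
monotonicity under single-rating upgrades, invariance to marking items
not-applicable versus deleting them, and exact 95% boundary behaviour.
Problem sizes were chosen to keep the default test run fast while covering
every constraint: property catalogs of 30–36 items, sweep catalogs of
20–126 items, brute-force minimality on 10-item catalogs.

## Catalog files

Catalogs are YAML with a versioned schema (`inst/schema/`); unknown fields
are rejected at load so files round-trip exactly, and validation reports
findings (duplicate ids, undeclared codes, count mismatches against
declared totals) rather than failing fast. The bundled vmra catalog
carries placeholder sub-indicator texts: the published framework specifies
codes, tier designations and counts, but not the full requirement texts,
and the list of critical sub-indicators is likewise not public — the
bundled critical set (the six Pre-bronze items, the clinical-field-trials
requirement, and the first Bronze item of each function) is documented,
synthetic and user-editable. The who-gbt skeleton's per-tier distribution
(30/54/130/54) is synthetic too, summing to the published 268; its catalog
title flags it as non-normative.

## Known limitations

* Sub-indicator texts and fact sheets are placeholders; the package is an
  engine, not a source of regulatory guidance.
* The institution-mandatory and critical sets ship as documented
  placeholders and must be replaced with an authority's own lists for real
  use.
* Evidence handling is a free-text note per response; document management
  is out of scope, as are the peer-review mechanics of schemes built
  around external assessors.
* Percentages in rendered reports are shown to one decimal; consumers
  needing exactness should read the numerator/denominator pairs preserved
  in the JSON rendering.
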