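# vmrasat

A maturity self-assessment and benchmarking engine for national regulators
of veterinary medicines (the VMRA-SAT scheme), with the WHO Global
Benchmarking Tool (GBT) four-level scheme available as a second profile.

Regulatory capability is assessed bottom-up: the framework decomposes
regulation into **functions** (marketing authorisation, pharmacovigilance,
inspection, …), each function into thematic **indicators**, and each
indicator into atomic **sub-indicators**, every one pre-designated to a
maturity tier. The vmra profile uses five tiers — Pre-bronze (6
sub-indicators), Bronze (21), Silver (28), Gold (154) and Gold-plus (26),
235 in all across 8 functions and 13 indicators; the WHO-GBT profile uses
ML1–ML4 over 9 functions and 268 sub-indicators. An agency rates each
sub-indicator on a sliding scale — under vmra: Implemented (score 1),
Partially implemented (0.5), Not implemented (0), Not applicable
(excluded); under who-gbt the ladder keeps Ongoing implementation (0.25)
and scores Partially implemented 0.75.

A function's maturity tier is the highest tier T whose constraints, and
those of every tier below it, are met:

* **strict** — every applicable sub-indicator designated ≤ T is Implemented;
* **flexible** — per-tier thresholds on the implemented fraction and caps
  on the partial / not-implemented fractions:

  | Tier | % Implemented | % Partially implemented | % Not implemented |
  |---|---|---|---|
  | Pre-bronze | 100% | — | — |
  | Bronze | 100% PB & 95% B | up to 5% B | — |
  | Silver | 100% PB+B & 90% S | up to 10% S | — |
  | Gold | 100% PB+B+S & 85% G | up to 15% G | up to 5% G |
  | Gold-plus | 100% PB+B+S+G & 80% GP | up to 20% GP | up to 10% GP |

* **restricted flexibility** — the flexible thresholds plus mandatory
  implementation of every *critical* sub-indicator designated ≤ T.

The who-gbt flexible rules pool ML1+ML2 for ML2 (95% implemented, the
remainder in process of implementation), and require 90% of ML3 and 80% of
ML4 with all lower levels fully implemented. All threshold comparisons are
exact rational arithmetic (integer cross-multiplication), so 19 of 20 at a
95% floor passes unambiguously. The institution's tier is the minimum over
its functions, further capped by any non-implemented institution-mandatory
sub-indicators. Sub-indicators not fully met feed an Institutional
Development Plan (IDP): a prioritised gap list plus a provably minimal set
of rating upgrades that reaches a chosen target tier.

## Worked example

```r
library(vmrasat)

catalog    <- reference_catalog("vmra")
assessment <- read_assessment(
  system.file("extdata", "example_responses.csv", package = "vmrasat"),
  catalog)

classify_institution(assessment, catalog, "flexible")
#> <vmra_institution> Silver (flexible)
#>   VRS: Silver (strict)
#>   VMA: Silver (strict)
#>   VPV: Silver (strict)
#>   VMC: Gold (flexible)
#>   VLI: Silver (strict)
#>   VRI: Gold (flexible)
#>   VLT: Silver (strict)
#>   VBR: Silver (strict)
```

Every function has Pre-bronze through Silver satisfied; VMC and VRI also
meet the Gold thresholds under the flexible algorithm (at least 85% of
their Gold items implemented, no more than 15% partial and 5% not
implemented), while the remaining functions miss a Gold constraint, so the
institution overall is Silver. The `(strict)` qualifier marks functions
where the strict algorithm reaches the same tier as the flexible one.

```r
gaps <- extract_gaps(assessment, catalog, "flexible")
nrow(gaps)                  # open IDP entries (not fully met, applicable)
head(upgrade_path(assessment, catalog, "flexible",
                  target_tier = "GOLD", function_code = "VRS"))
```

The same operations are available from the shell via the bundled script
(`system.file("exec", "vmra-sat", package = "vmrasat")`) with subcommands
`validate`, `score`, `classify`, `idp`, `report` and `simulate`.

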