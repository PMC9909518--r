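# atcmapr

Measure and improve the **structuredness** of hospital drug-prescription
tables: the fraction of records carrying a WHO ATC level-5 code (the
active ingredient) instead of raw free text. Ingredient-level ATC codes
are the minimum usable unit for drug-utilisation research and
observational studies, so unstructured free-text prescriptions are lost
data until they are mapped back to the catalog.

`atcmapr` is aimed at medical-informatics and data-integration teams
working with EHR prescription extracts. It implements a four-step
pipeline:

1. **Assess** — split records on the catalog-pick flag, exclude
   non-medication orders ("BGA", "BB", ... lab/measurement requests) with
   a configurable rule engine, and group free texts into unique entries
   with frequencies.
2. **Map** — run three matching algorithms against the drug product
   catalog: whole-token ingredient-name containment, whole-token
   product-name containment, and token-set similarity ranking (top-3
   candidates with scores).
3. **Validate** — export the most frequent entries as a review workbook,
   re-import the expert-filled version, and classify reliability from
   inter-algorithm concordance and score patterns.
4. **Report** — structuredness summaries overall, per ATC level-1 group
   and per level-5 ingredient.

## The core model

Fuzzy matching is built on the insertion/deletion edit distance
`d(a,b) = |a| + |b| − 2·LCS(a,b)` (substitution = 2), normalised to a
0–100 score `round(100·(|a|+|b|−d)/(|a|+|b|))`. The ranking score is the
**token-set ratio**: normalise (lower-case, strip punctuation), split the
two token sets into sorted intersection `t0` and remainders `ra`, `rb`,
and take the maximum plain ratio among `(t0, t0+ra)`, `(t0, t0+rb)`,
`(t0+ra, t0+rb)`. It is 100 exactly when one token set is contained in
the other — the right semantics for terse prescriptions against decorated
catalog names. Reliability tiers encode the validated gradient:
agreement of the exact matchers (or all three algorithms) >
exact-plus-similarity agreement > similarity-only with score > 84.28 >
needs review.

## Worked example

```r
library(atcmapr)

score_pair("Stada paracetamol", "paracetamol Stada 400 mg")
#> # A tibble: 1 × 6
#>   a                 b                        simple partial token_sort token_set
#> 1 Stada paracetamol paracetamol Stada 400 mg     54      65         83       100
```

Simple ratio 54: barely half the characters align in order. Partial 65:
the best same-length window helps a little. Token-sort 83: word order was
most of the problem. Token-set 100: every word of the free text occurs in
the catalog name — a match.

```r
rx      <- read_prescriptions(system.file("extdata", "demo_prescriptions.csv",
                                          package = "atcmapr"))
catalog <- read_catalog(system.file("extdata", "demo_catalog.csv",
                                    package = "atcmapr"))
res <- run_pipeline(rx, catalog, n_validate = 10)
res$partition
#> 17 prescriptions: 4 structured (23.53%), 13 unstructured (76.47%)

dplyr::select(res$matched, medication, frequency, step1, step3_atc,
              step3_score, tier)
#> # A tibble: 9 × 6
#>   medication                                frequency step1   step3_atc step3_score tier
#> 1 Ibuprofen 600                                     2 M01AE01 M01AE01           100 consensus_high
#> 2 ARILIN 500 Filmtabletten | (Metronidazol)         1 P01AB01 P01AB01           100 consensus_exact
#> 3 Ibuprofen                                         1 M01AE01 M01AE01           100 consensus_high
#> 4 NaCL 0.9%                                         1 NA      B05BB11            55 needs_review
#> 5 NaCl 0.9%                                         1 NA      B05BB11            55 needs_review
#> 6 Pantoprazol                                       1 A02BC02 A02BC02           100 consensus_high
#> 7 Paracetamol 500                                   1 N02BE01 N02BE01           100 consensus_high
#> 8 Stada paracetamol                                 1 N02BE01 N02BE01           100 consensus_high
#> 9 Telmisartan 80                                    1 NA      C09DA07           100 score_based
```

Three "BGA"/"BE" order texts were rule-excluded before grouping. Note the
two instructive rows: the salt-solution texts score too low to trust
automatically, and `Telmisartan 80` is answered only by the similarity
matcher at score 100 with the *combination* product's code ranked first —
the classic failure mode the validation workbook exists to catch
(`res$workbook`, `export_validation_workbook()`,
`import_validation_workbook()`). With validation records in hand,
`final_assessment()` produces the summary, per-ATC-group and
per-ingredient reports (`glance()`, `tidy()`, `autoplot()`).

A seeded synthetic generator (`generate_fixture()`) produces catalogs and
prescription tables with known ground truth for testing the whole
pipeline without any hospital data; `inst/cli/atcmapr.R` is a thin
command-line front end (`score`, `simulate`, `assess`, `map`, `workbook`,
`report`).

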