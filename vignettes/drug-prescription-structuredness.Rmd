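---
title: "Assessing and improving the structuredness of free-text drug prescriptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing and improving the structuredness of free-text drug prescriptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(atcmapr)
library(dplyr)
```

## The problem

Hospital prescribing systems usually let clinicians either pick a drug from
the institutional product catalog — in which case the record carries a WHO
ATC (Anatomical Therapeutic Chemical) level-5 code identifying the active
ingredient — or type free text. For drug-utilisation research and
observational studies on common data models, the ingredient-level ATC code
is the minimum usable unit, so the *structuredness* of a prescription table
(the fraction of records with a valid ATC level-5 code) directly limits its
research value.

`atcmapr` implements a four-step procedure for measuring and improving
structuredness:

1. **Initial assessment** — partition records on the catalog-pick flag and
   group the free texts into unique entries with frequencies, after
   removing non-medication orders (lab requests and the like) with a
   configurable rule set.
2. **Improvement** — map each unique free text to candidate ATC codes with
   a cascade of three algorithms (exact ingredient containment, exact
   product containment, token-set similarity ranking).
3. **Validation** — export the most frequent entries as a review workbook,
   let experts mark each algorithm result correct or wrong, and read the
   filled workbook back; inter-algorithm concordance and similarity-score
   patterns then classify how trustworthy unreviewed results are.
4. **Final assessment** — merge structured records, validated free-text
   results and exclusion labels into structuredness reports by ATC level-1
   group and by level-5 ingredient.

## The similarity model

All fuzzy matching rests on the insertion/deletion (indel) edit distance:
the minimum number of single-character insertions and deletions turning
one string into the other, equivalently

$$d(a,b) \;=\; |a| + |b| - 2\,\mathrm{LCS}(a,b),$$

where LCS is the longest common subsequence. A substitution costs 2 (one
deletion plus one insertion). The normalised similarity on the 0–100 scale
is

$$\mathrm{ratio}(a,b) \;=\; \Big\lfloor 100\,\frac{|a|+|b|-d(a,b)}{|a|+|b|} + \tfrac12 \Big\rfloor ,$$

rounded half away from zero; two empty strings score 100 and exactly one
empty string scores 0. Distances count Unicode codepoints, not bytes, so
umlauts in German product names are one edit, not two.

Three derived scores handle the phenomena of prescription text:

* **partial ratio** — the best plain ratio of the shorter string against
  same-length windows of the longer one, with windows anchored at the
  start positions of longest-matching-block alignments (ties go to the
  leftmost window). It rewards texts that contain a catalog name plus
  decoration.
* **token-sort ratio** — the plain ratio after lower-casing, replacing
  every non-alphanumeric character by a space, splitting into tokens,
  sorting them alphabetically and rejoining. Word order stops mattering.
* **token-set ratio** — tokens are deduplicated and split into the sorted
  intersection $t_0$ and the two remainders; the score is the maximum
  plain ratio among $(t_0, t_0{+}r_a)$, $(t_0, t_0{+}r_b)$ and
  $(t_0{+}r_a, t_0{+}r_b)$. Its key property: whenever every token of one
  string occurs in the other, the score is exactly 100. That is precisely
  the requirement for matching a terse free text ("Stada paracetamol")
  against a fully decorated catalog name ("paracetamol Stada 400 mg"):

```{r}
score_pair("Stada paracetamol", "paracetamol Stada 400 mg")
```

The token-set score is the one used for candidate ranking (algorithm 3);
the others are exposed for diagnostics. Note one subtlety we verified
rather than assumed: the token-set ratio dominates the token-sort ratio
only for duplicate-free token lists. When a token repeats, the set
construction collapses duplicates the sort construction counts, and the
inequality can reverse; the test suite asserts dominance on duplicate-free
inputs only.

## The matching cascade

**Algorithms 1 and 2** interpret "string comparison" as *whole-token
containment after normalisation*: a catalog ingredient (or product) name
matches when every one of its tokens occurs among the text's tokens. Raw
substring search would hit short names inside longer words and could not
deliver the near-perfect precision exact matching is valued for, so the
token interpretation is deliberate. The longest matching name wins; if
equally good survivors map to more than one distinct ATC code (a
combination product sharing its ingredient name with a mono-product), the
algorithm returns nothing rather than guessing — precision first.

**Algorithm 3** scores the text against every ingredient and product name
with the token-set ratio, keeps each distinct ATC code's best score, and
returns the top *k* (default 3) candidates. Ties break by longer matched
name, then lexicographic ATC code, making reruns bit-identical. It always
answers, which is why its results need a reliability layer.

## Reliability: concordance and the score threshold

Expert validation of this cascade showed a clean gradient: results where
algorithms 1 and 2 (or all three) agreed were always correct; agreement of
algorithm 3 with one exact matcher was almost always correct; and for
entries only algorithm 3 answered, higher scores meant fewer errors, with
the mean score of validated-correct results (84.28) serving as a practical
cutoff. `assign_confidence()` encodes this as ordered tiers
(`consensus_exact` > `consensus_high` > `score_based` > `needs_review`);
the threshold default is 84.28 with a strict inequality and is explicitly
configurable, because it is an empirical indication, not a law. Wrong
results *at score 100* exist by construction — combination products,
dosage-form ambiguity, very short texts — which is also why score-based
accuracy need not be monotone in the threshold, and why the tier layer
never overrides the consensus evidence with a score.

`score_separation_test()` provides the supporting statistic: Welch's
two-sided t-test (unequal variances — the two groups' spreads differ and
nothing justifies assuming otherwise) on correct-vs-wrong scores, plus the
descriptive panel (count, mean, SD, range, quartiles) per group.

## The validation round trip

`export_validation_workbook()` writes the top-*n* most frequent entries
(default 1000, mirroring the scale at which a review team's effort covers
most of the unstructured mass) with algorithm results and concordance
flags prefilled and reviewer columns blank. On import, `FINAL` is resolved
with the precedence: explicit `CORRECT` code > first algorithm result
marked correct (`Eval1` > `Eval2` > `Eval3`) > reviewer label
(`nomed` for non-medication, `unspec` for unresolvable texts, or an ATC
code truncated to level 3/4 when only a coarser class is determinable) >
`no_eval`. Truncated codes aggregate upward into their level-1 group but
never into the level-5 ingredient report — a coarse code is never imputed
to an ingredient.

## Numerical and I/O choices

* Percentages print at two decimals, rounded half away from zero.
* Grouping keys are the exact raw strings (case-sensitive): "NaCl 0.9%"
  and "NaCL 0.9%" are distinct review units.
* The top-*n* coverage denominator is the *pre-exclusion* unstructured
  count, so exclusion-rule hits still count toward the mass that
  validation effort is budgeted against.
* Files are delimited text with the canonical DS1–DS4 headers; readers
  never silently drop rows — malformed rows land in a `rejects()` table
  with a reason, and accepted + rejected always equals input.
* Files are read as UTF-8 with a Latin-1 fallback when the bytes are not
  valid UTF-8 (German ERP exports predate consistent UTF-8).
* Exclusion rules evaluate in listed order, first match wins; `prefix`
  and `exact` rules act on normalised text (so "BGA" fires on
  "BGA arteriell" but not on "BGAx"), `regex` rules on the raw text.

## The synthetic fixture generator

No real prescription table can ship with the package, so
`generate_fixture()` builds one with known ground truth. Its defaults
encode the study conditions the package is tested under: 47.73%
structured records, 9.1% non-medication orders, and free texts produced
by rendering a Zipf-popularity-weighted catalog row through one of six
corruption classes — verbatim product name, ingredient + dose, shuffled
token order, truncation, typos at a controlled indel distance, and
unrecognisable text. Renderings are deterministic per (row, class), so
repeated draws produce repeated texts and the grouped frequencies inherit
the popularity skew (a Zipf exponent of 1.1 gives a realistically
heavy-tailed unique-text distribution). Catalog names are pronounceable
syllable constructions, never real drug lists. A configurable fraction of
catalog rows are combination products (same ingredient name, distinct
ATC), reproducing the cascade's principal real-world failure mode.

What the generator does *not* emulate: multi-drug texts in one field,
German morphological variation beyond dose/form/pipe decoration,
reviewer disagreement, and drifting catalogs. Passing fixture tests
therefore demonstrates the machinery's correctness and calibration under
controlled corruption, not clinical-grade accuracy on any particular
hospital's data — cohort-level numbers are intrinsically data-dependent.

Problem sizes used in the test suite were chosen to exercise every code
path at comfortable margins: catalogs of 20–250 entries, corpora of
300–100,000 prescriptions (the largest for the end-to-end conservation
and fraction-recovery check), and 10,000 random string pairs plus an
exhaustive length-≤6 sweep for the metric-oracle equivalence.

## Worked end-to-end example

```{r}
fx <- generate_fixture(fixture_spec(n_catalog = 60, n_prescriptions = 5000,
                                    seed = 42))
res <- run_pipeline(fx$prescriptions, fx$catalog, n_validate = 200)
res$partition
table(res$matched$tier)
```

With a (here simulated) expert validation round:

```{r}
val <- simulate_validation(res$workbook, fx$truth)
assess <- final_assessment(res$partition$structured, val, res$groups)
assess
glance(assess)
head(tidy(assess))
```

```{r, fig.width = 6, fig.height = 3.5}
autoplot(assess)
```

## Known limitations

* Algorithms 1/2 use token containment; a hospital whose legacy pipeline
  used raw case-sensitive substring search will match slightly different
  entries (the original behaviour is not documented, so the
  higher-precision reading was chosen and is recorded here as a design
  choice).
* Each free text is treated as one prescription; fields concatenating
  several drugs are matched on a first-come basis by the cascade and must
  be caught in review.
* The partial ratio's tie behaviour between equal-scoring windows follows
  the leftmost-window rule; other implementations may differ on contrived
  inputs.
* The exclusion-rule engine ships only the three canonical order codes as
  defaults; production use requires a site-specific rule config.
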