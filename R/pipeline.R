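# percentages printed half-away-from-zero at `digits` decimals
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.pct <- function(num, den, digits = 2) {
  ifelse(den > 0, round_half_up(100 * num / den, digits), 0)
}

#' Partition prescriptions into structured and unstructured
#'
#' Splits a DS1 prescription tibble on the `structured` flag and computes
#' the initial structuredness summary (counts and percentages at two
#' decimals).
#'
#' @param data A prescriptions tibble (see [read_prescriptions()] or
#'   [generate_prescriptions()]).
#' @return A list of class `rx_partition` with elements `structured`,
#'   `unstructured` (tibbles) and `summary` (one-row tibble with
#'   `n_total`, `n_structured`, `n_unstructured`, `pct_structured`,
#'   `pct_unstructured`).
#' @export
partition_prescriptions <- function(data) {
  s <- data[data$structured, ]
  u <- data[!data$structured, ]
  n <- nrow(data)
  summary <- tibble::tibble(
    n_total = n,
    n_structured = nrow(s),
    n_unstructured = nrow(u),
    pct_structured = .pct(nrow(s), n),
    pct_unstructured = .pct(nrow(u), n)
  )
  structure(list(structured = s, unstructured = u, summary = summary),
            class = "rx_partition")
}

#' @export
print.rx_partition <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "%d prescriptions: %d structured (%.2f%%), %d unstructured (%.2f%%)\n",
    s$n_total, s$n_structured, s$pct_structured,
    s$n_unstructured, s$pct_unstructured))
  invisible(x)
}

#' Group unstructured prescriptions into unique free texts (DS3)
#'
#' Entries matching an exclusion rule (non-medication orders) are removed
#' first and kept in the `excluded` attribute with their rule id. The
#' remaining entries are grouped by the exact raw `medication` string
#' (case-sensitive: "NaCl 0.9%" and "NaCL 0.9%" are distinct entries) and
#' sorted by frequency descending, then key ascending.
#'
#' @param data Unstructured prescriptions tibble (the `unstructured`
#'   element of [partition_prescriptions()]).
#' @param rules Exclusion rules tibble, or `NULL` to skip exclusion.
#' @return A tibble with columns `medication`, `frequency`, carrying
#'   attributes `excluded` (grouped excluded entries with `rule_id`) and
#'   `n_excluded` (total excluded prescriptions) and
#'   `n_unstructured_total` (pre-exclusion count, the coverage
#'   denominator).
#' @export
group_unstructured <- function(data, rules = default_exclusion_rules()) {
  texts <- data$medication
  n_total <- length(texts)
  rule_id <- if (is.null(rules) || nrow(rules) == 0) {
    rep(NA_character_, n_total)
  } else {
    classify_non_medication(texts, rules)
  }
  excluded <- tibble::tibble(medication = texts[!is.na(rule_id)],
                             rule_id = rule_id[!is.na(rule_id)]) |>
    dplyr::count(.data$medication, .data$rule_id, name = "frequency") |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$medication)
  kept <- texts[is.na(rule_id)]
  groups <- tibble::tibble(medication = kept) |>
    dplyr::count(.data$medication, name = "frequency") |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$medication)
  attr(groups, "excluded") <- excluded
  attr(groups, "n_excluded") <- n_total - length(kept)
  attr(groups, "n_unstructured_total") <- n_total
  groups
}

#' Coverage of the top-n most frequent free texts
#'
#' Percentage of all unstructured prescriptions covered by the `n` most
#' frequent unique free texts. The denominator is the pre-exclusion
#' unstructured count (exclusion-rule hits still count toward the mass
#' that validation effort is budgeted against). When `n` exceeds the
#' number of groups, all groups are used.
#'
#' @param groups A grouped tibble from [group_unstructured()].
#' @param n Number of top groups.
#' @param n_unstructured_total Coverage denominator; defaults to the
#'   `n_unstructured_total` attribute of `groups`, falling back to the
#'   sum of group frequencies.
#' @return A single percentage (two decimals).
#' @export
top_n_coverage <- function(groups, n,
                           n_unstructured_total =
                             attr(groups, "n_unstructured_total")) {
  stopifnot(n >= 1)
  if (is.null(n_unstructured_total)) {
    n_unstructured_total <- sum(groups$frequency)
  }
  g <- dplyr::arrange(groups, dplyr::desc(.data$frequency), .data$medication)
  covered <- sum(head(g$frequency, n))
  .pct(covered, n_unstructured_total)
}

.ds4_cols <- c("MEDICATION", "FREQUENCY", "Step1", "Step2", "Step3",
               "Eval1", "Eval2", "Eval3", "True12", "True13", "True23",
               "True123", "CORRECT", "COMMENTS", "FINAL")

#' Export the manual-validation workbook (DS4)
#'
#' Writes the top-`n` most frequent matched entries as a delimited
#' workbook for expert review. Algorithm results (`Step1`-`Step3`, with
#' `Step3` as the top-1 ATC code) and the concordance flags are
#' prefilled; the reviewer columns `Eval1`-`Eval3`, `CORRECT`, `COMMENTS`
#' and `FINAL` are left blank.
#'
#' @param data A matched tibble ([match_all()]) with `medication`,
#'   `frequency`, steps and concordance flags.
#' @param path Output path.
#' @param n Number of most frequent entries to export (default 1000).
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
export_validation_workbook <- function(data, path, n = 1000, delim = ",") {
  d <- dplyr::arrange(data, dplyr::desc(.data$frequency), .data$medication)
  d <- head(d, n)
  fmt_bool <- function(x) ifelse(is.na(x), "", ifelse(x, "TRUE", "FALSE"))
  out <- tibble::tibble(
    MEDICATION = d$medication,
    FREQUENCY = d$frequency,
    Step1 = dplyr::coalesce(d$step1, ""),
    Step2 = dplyr::coalesce(d$step2, ""),
    Step3 = dplyr::coalesce(d$step3_atc, ""),
    Eval1 = "", Eval2 = "", Eval3 = "",
    True12 = fmt_bool(d$true12), True13 = fmt_bool(d$true13),
    True23 = fmt_bool(d$true23), True123 = fmt_bool(d$true123),
    CORRECT = "", COMMENTS = "", FINAL = ""
  )
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

.final_labels <- c("nomed", "unspec", "no_eval")

#' Import a filled validation workbook
#'
#' Reads a DS4 workbook back and resolves the `final` result for every
#' row with the precedence: an explicit `CORRECT` code, else the first
#' algorithm result marked correct (`Eval1` > `Eval2` > `Eval3`), else a
#' label or code the reviewer wrote into `FINAL`, else `"no_eval"`.
#' `FINAL`/`CORRECT` accept ATC codes at level 3, 4 or 5 (a reviewer may
#' only be able to pin down a truncated code) and the labels `nomed`,
#' `unspec`, `no_eval`. Rows whose `CORRECT` or `FINAL` entry is neither
#' a valid code nor a label are quarantined into [rejects()].
#'
#' @param path Path to the workbook file.
#' @param delim Field delimiter.
#' @return A tibble with columns `medication`, `frequency`, `step1`,
#'   `step2`, `step3_atc`, `eval1`-`eval3`, `true12`-`true123`,
#'   `correct`, `comments`, `final`; attribute `rejects` holds malformed
#'   rows.
#' @export
import_validation_workbook <- function(path, delim = ",") {
  df <- .read_delim_enc(path, delim)
  .require_columns(df, as.list(.ds4_cols), path)
  blank_na <- function(x) dplyr::if_else(nzchar(trimws(x)), trimws(x),
                                         NA_character_)
  to_bool <- function(x) {
    x <- toupper(trimws(x))
    dplyr::case_when(x %in% c("TRUE", "T", "1", "YES") ~ TRUE,
                     x %in% c("FALSE", "F", "0", "NO") ~ FALSE,
                     TRUE ~ NA)
  }
  out <- tibble::tibble(
    medication = df$MEDICATION,
    frequency = as.integer(df$FREQUENCY),
    step1 = blank_na(df$Step1),
    step2 = blank_na(df$Step2),
    step3_atc = blank_na(df$Step3),
    eval1 = to_bool(df$Eval1), eval2 = to_bool(df$Eval2),
    eval3 = to_bool(df$Eval3),
    true12 = to_bool(df$True12) %in% TRUE,
    true13 = to_bool(df$True13) %in% TRUE,
    true23 = to_bool(df$True23) %in% TRUE,
    true123 = to_bool(df$True123) %in% TRUE,
    correct = blank_na(df$CORRECT),
    comments = dplyr::coalesce(blank_na(df$COMMENTS), ""),
    final_raw = blank_na(df$FINAL)
  )
  code_ok <- function(x) {
    !is.na(x) & is_valid_atc(x) & atc_level(toupper(x)) >= 3L
  }
  label_ok <- function(x) !is.na(x) & tolower(x) %in% .final_labels
  reason <- rep(NA_character_, nrow(out))
  bad_correct <- !is.na(out$correct) & !code_ok(out$correct)
  reason[bad_correct] <- sprintf(
    "CORRECT is not a valid ATC code at level 3-5: \"%s\"",
    out$correct[bad_correct])
  bad_final <- is.na(reason) & !is.na(out$final_raw) &
    !code_ok(out$final_raw) & !label_ok(out$final_raw)
  reason[bad_final] <- sprintf(
    "FINAL is neither a valid ATC code (level 3-5) nor a label: \"%s\"",
    out$final_raw[bad_final])
  out$final <- dplyr::case_when(
    !is.na(out$correct) ~ toupper(out$correct),
    out$eval1 %in% TRUE & !is.na(out$step1) ~ toupper(out$step1),
    out$eval2 %in% TRUE & !is.na(out$step2) ~ toupper(out$step2),
    out$eval3 %in% TRUE & !is.na(out$step3_atc) ~ toupper(out$step3_atc),
    !is.na(out$final_raw) & label_ok(out$final_raw) ~ tolower(out$final_raw),
    !is.na(out$final_raw) ~ toupper(out$final_raw),
    TRUE ~ "no_eval"
  )
  out$final_raw <- NULL
  bad <- !is.na(reason)
  rej <- dplyr::mutate(out[bad, ], reason = reason[bad])
  out <- out[!bad, ]
  attr(out, "rejects") <- rej
  out
}

#' Final structuredness assessment
#'
#' Merges the structured prescriptions (ATC from the source table), the
#' validated unstructured entries (resolved `final` results, weighted by
#' group frequency), the rule-excluded non-medication entries and the
#' never-validated remainder into the three final reports: an overall
#' structuredness summary, a per-ATC-level-1-group breakdown and a
#' per-level-5-ingredient breakdown. Every prescription lands in exactly
#' one bucket, so counts are conserved:
#' `n_total = n_structured + n_unstructured_atc + n_nomed + n_unspec +
#' n_not_validated`.
#'
#' A `final` code truncated to level 3 or 4 contributes to its level-1
#' group but never to the level-5 ingredient report (truncated codes
#' aggregate upward only).
#'
#' @param structured Tibble of structured prescriptions (with `atc_l5`).
#' @param validation Validation records from
#'   [import_validation_workbook()] (may have zero rows).
#' @param groups The full grouped tibble from [group_unstructured()]
#'   (its attributes supply the excluded-entry counts).
#' @param n_excluded Number of rule-excluded prescriptions; defaults to
#'   the `n_excluded` attribute of `groups`.
#' @return An object of class `structuredness_assessment`: a list with
#'   `summary` (one-row tibble), `by_atc_group` and `by_ingredient`
#'   tibbles. [tidy()] returns the group report, [glance()] the summary,
#'   [autoplot()] the per-group structuredness barplot.
#' @export
final_assessment <- function(structured, validation, groups,
                             n_excluded = attr(groups, "n_excluded")) {
  if (is.null(n_excluded)) n_excluded <- 0L
  n_structured <- nrow(structured)
  n_unstructured <- n_excluded + sum(groups$frequency)
  n_total <- n_structured + n_unstructured

  if (is.null(validation) || nrow(validation) == 0) {
    validation <- tibble::tibble(medication = character(),
                                 frequency = integer(),
                                 final = character())
  }
  v <- tibble::tibble(medication = validation$medication,
                      frequency = validation$frequency,
                      final = validation$final)
  v$kind <- dplyr::case_when(
    v$final %in% c("nomed", "unspec", "no_eval") ~ v$final,
    atc_level(v$final) == 5L ~ "atc5",
    TRUE ~ "atc_truncated"
  )
  w <- function(kind) sum(v$frequency[v$kind %in% kind])
  # groups never exported to (or returned from) the workbook are unvalidated
  in_wb <- groups$medication %in% v$medication
  n_not_in_wb <- sum(groups$frequency[!in_wb])
  n_nomed <- n_excluded + w("nomed")
  n_unspec <- w("unspec")
  n_unstr_atc <- w(c("atc5", "atc_truncated"))
  n_not_validated <- n_not_in_wb + w("no_eval")
  n_validated <- n_structured + n_unstr_atc + n_nomed + n_unspec

  summary <- tibble::tibble(
    n_total = n_total,
    n_structured = n_structured,
    n_unstructured = n_unstructured,
    n_unstructured_atc = n_unstr_atc,
    n_excluded_nomed = n_nomed,
    n_unspec = n_unspec,
    n_validated = n_validated,
    n_not_validated = n_not_validated,
    pct_structured = .pct(n_structured, n_total),
    pct_unstructured = .pct(n_unstructured, n_total),
    pct_validated = .pct(n_validated, n_total),
    pct_not_validated = .pct(n_not_validated, n_total)
  )

  # level-1 group report over ATC-classified prescriptions
  s_grp <- tibble::tibble(group = substr(structured$atc_l5, 1, 1),
                          frequency = 1L)
  u_atc <- v[v$kind %in% c("atc5", "atc_truncated"), ]
  u_grp <- tibble::tibble(group = substr(u_atc$final, 1, 1),
                          frequency = u_atc$frequency)
  grp <- dplyr::full_join(
    s_grp |> dplyr::count(.data$group, wt = .data$frequency,
                          name = "structured_n"),
    u_grp |> dplyr::count(.data$group, wt = .data$frequency,
                          name = "unstructured_n"),
    by = "group")
  grp$structured_n <- dplyr::coalesce(grp$structured_n, 0L)
  grp$unstructured_n <- dplyr::coalesce(grp$unstructured_n, 0L)
  grp$total_n <- grp$structured_n + grp$unstructured_n
  n_classified <- sum(grp$total_n)
  grp <- grp |>
    dplyr::arrange(dplyr::desc(.data$total_n), .data$group) |>
    dplyr::mutate(
      pct_structured = .pct(.data$structured_n, .data$total_n),
      pct_unstructured = .pct(.data$unstructured_n, .data$total_n),
      pct_of_total = .pct(.data$total_n, n_classified))
  label_rows <- tibble::tibble(
    group = c("nomed", "unspec", "not_validated"),
    structured_n = 0L,
    unstructured_n = c(n_nomed, n_unspec, n_not_validated),
    total_n = c(n_nomed, n_unspec, n_not_validated),
    pct_structured = 0,
    pct_unstructured = .pct(c(n_nomed, n_unspec, n_not_validated), n_total),
    pct_of_total = .pct(c(n_nomed, n_unspec, n_not_validated), n_total))
  by_atc_group <- dplyr::bind_rows(grp, label_rows)

  # level-5 ingredient report (level-5 codes only)
  s_ing <- tibble::tibble(atc = structured$atc_l5, frequency = 1L)
  u5 <- v[v$kind == "atc5", ]
  u_ing <- tibble::tibble(atc = u5$final, frequency = u5$frequency)
  by_ingredient <- dplyr::full_join(
    s_ing |> dplyr::count(.data$atc, wt = .data$frequency,
                          name = "structured_n"),
    u_ing |> dplyr::count(.data$atc, wt = .data$frequency,
                          name = "unstructured_n"),
    by = "atc") |>
    dplyr::mutate(
      structured_n = dplyr::coalesce(.data$structured_n, 0L),
      unstructured_n = dplyr::coalesce(.data$unstructured_n, 0L),
      total_n = .data$structured_n + .data$unstructured_n,
      pct_structured = .pct(.data$structured_n, .data$total_n)) |>
    dplyr::arrange(dplyr::desc(.data$total_n), .data$atc)

  structure(list(summary = summary, by_atc_group = by_atc_group,
                 by_ingredient = by_ingredient),
            class = "structuredness_assessment")
}

#' @export
print.structuredness_assessment <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("Structuredness assessment of %d prescriptions\n",
           "  structured:            %9d (%.2f%%)\n",
           "  unstructured w/ ATC:   %9d\n",
           "  no medication (nomed): %9d\n",
           "  unspecific (unspec):   %9d\n",
           "  validated total:       %9d (%.2f%%)\n",
           "  not validated:         %9d (%.2f%%)\n"),
    s$n_total, s$n_structured, s$pct_structured, s$n_unstructured_atc,
    s$n_excluded_nomed, s$n_unspec, s$n_validated, s$pct_validated,
    s$n_not_validated, s$pct_not_validated))
  cat(sprintf("  %d ATC level-5 codes (ingredients) identified\n",
              nrow(x$by_ingredient)))
  invisible(x)
}

#' @export
tidy.structuredness_assessment <- function(x, ...) {
  x$by_atc_group
}

#' @export
glance.structuredness_assessment <- function(x, ...) {
  x$summary
}

#' @export
autoplot.structuredness_assessment <- function(object, ...) {
  d <- object$by_atc_group
  d <- d[!d$group %in% c("nomed", "unspec", "not_validated"), ]
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$group, -.data$pct_structured),
    y = .data$pct_structured)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "ATC level-1 group", y = "% structured",
                  title = "Structuredness by ATC group") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Structuredness of individual ingredients
#'
#' Scatter of the structured percentage against prescription frequency,
#' one point per ATC level-5 code, showing the spread of structuredness
#' across ingredients.
#'
#' @param assessment A `structuredness_assessment` object.
#' @return A ggplot object.
#' @export
plot_ingredient_structuredness <- function(assessment) {
  d <- assessment$by_ingredient
  ggplot2::ggplot(d, ggplot2::aes(x = .data$total_n,
                                  y = .data$pct_structured)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "prescriptions per ATC level-5 code (log scale)",
                  y = "% structured",
                  title = "Structuredness by ingredient") +
    ggplot2::theme_minimal()
}

#' Run the full structuredness pipeline
#'
#' Orchestrates the four steps end to end: partition on the `structured`
#' flag, exclusion rules + grouping, the three matching algorithms with
#' concordance and confidence tiers, workbook export/import (when a
#' filled workbook is supplied) and the final assessment. Without a
#' filled workbook all matched groups remain unvalidated (`no_eval`), so
#' the assessment reflects only structured data plus rule exclusions.
#'
#' @param prescriptions DS1 prescriptions tibble.
#' @param catalog Drug catalog tibble.
#' @param rules Exclusion rules tibble.
#' @param n_validate Number of most frequent groups taken into the
#'   validation workbook (default 1000).
#' @param k Number of similarity candidates per entry.
#' @param score_threshold Confidence-tier score cutoff.
#' @param validation Optional validation records tibble (from
#'   [import_validation_workbook()] or [simulate_validation()]).
#' @return A list with `partition`, `groups`, `matched` (tiered DS3),
#'   `workbook` (top-`n_validate` slice), `coverage` (top-n coverage
#'   percentage) and `assessment`.
#' @export
run_pipeline <- function(prescriptions, catalog,
                         rules = default_exclusion_rules(),
                         n_validate = 1000, k = 3L,
                         score_threshold = 84.28,
                         validation = NULL) {
  part <- partition_prescriptions(prescriptions)
  groups <- group_unstructured(part$unstructured, rules)
  matched <- groups |>
    match_all(catalog, k = k) |>
    assign_confidence(score_threshold = score_threshold)
  wb <- head(dplyr::arrange(matched, dplyr::desc(.data$frequency),
                            .data$medication), n_validate)
  coverage <- if (nrow(groups)) {
    top_n_coverage(groups, n_validate)
  } else 0
  assessment <- final_assessment(part$structured, validation, groups)
  list(partition = part, groups = groups, matched = matched,
       workbook = wb, coverage = coverage, assessment = assessment)
}
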