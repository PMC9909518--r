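#' Inter-algorithm concordance flags
#'
#' For each entry, records whether the ATC codes returned by the three
#' matching algorithms agree pairwise and three-way (DS4 columns
#' `True12`, `True13`, `True23`, `True123`). A pair flag is `TRUE` only
#' when both results are present and equal at ATC level 5; a missing
#' result makes all of its pairs `FALSE`. By construction
#' `true123` implies all three pairwise flags.
#'
#' `concordance()` is the vector form; `add_concordance()` applies it to
#' a matched tibble using the `step1`, `step2`, `step3_atc` columns.
#'
#' @param step1,step2,step3 Character vectors of ATC codes (`NA` for no
#'   result), recycled to the common length.
#' @return A tibble with logical columns `true12`, `true13`, `true23`,
#'   `true123`.
#' @examples
#' concordance("N02BB02", "N02BB02", "N02BB02")
#' concordance("N02BB02", NA, "N02BB02")
#' @export
concordance <- function(step1, step2, step3) {
  n <- max(length(step1), length(step2), length(step3))
  s1 <- rep_len(as.character(step1), n)
  s2 <- rep_len(as.character(step2), n)
  s3 <- rep_len(as.character(step3), n)
  eq <- function(a, b) !is.na(a) & !is.na(b) & a == b
  t12 <- eq(s1, s2)
  t13 <- eq(s1, s3)
  t23 <- eq(s2, s3)
  tibble::tibble(true12 = t12, true13 = t13, true23 = t23,
                 true123 = t12 & t13 & t23)
}

#' @rdname concordance
#' @param data A data frame with columns `step1`, `step2`, `step3_atc`.
#' @export
add_concordance <- function(data) {
  fl <- concordance(data$step1, data$step2, data$step3_atc)
  data$true12 <- fl$true12
  data$true13 <- fl$true13
  data$true23 <- fl$true23
  data$true123 <- fl$true123
  data
}

.tier_levels <- c("excluded_nomed", "needs_review", "score_based",
                  "consensus_high", "consensus_exact")

#' Confidence tiers for automatically identified ATC codes
#'
#' Manual validation of the matcher cascade showed a reliability gradient:
#' results on which all three algorithms, or algorithms 1 and 2, agreed
#' were always correct; agreement of the similarity matcher with one exact
#' matcher was almost always correct; and for entries answered only by the
#' similarity matcher, a high token-set score (above the mean score of
#' validated-correct results, 84.28) indicates a low error rate. The tiers
#' encode that gradient:
#'
#' * `consensus_exact`: `true123` or `true12`;
#' * `consensus_high`: `true13` or `true23`;
#' * `score_based`: only algorithm 3 answered and its top score is
#'   strictly above `score_threshold`;
#' * `needs_review`: everything else.
#'
#' The ordering `excluded_nomed < needs_review < score_based <
#' consensus_high < consensus_exact` is total; raising the threshold never
#' moves an entry up a tier.
#'
#' @param data A matched tibble with columns `step1`, `step2`,
#'   `step3_atc`, `step3_score` and the concordance flags (see
#'   [add_concordance()]).
#' @param score_threshold Numeric score cutoff for the `score_based` tier
#'   (default 84.28, strict inequality).
#' @return `data` with added columns `tier` (ordered factor) and
#'   `tier_rationale`.
#' @export
assign_confidence <- function(data, score_threshold = 84.28) {
  need <- c("step1", "step2", "step3_atc", "step3_score",
            "true12", "true13", "true23", "true123")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("assign_confidence needs columns: ",
                 paste(miss, collapse = ", "),
                 " (run match_all() or add_concordance() first)"))
  }
  alg3_only <- is.na(data$step1) & is.na(data$step2) & !is.na(data$step3_atc)
  tier <- dplyr::case_when(
    data$true123 | data$true12 ~ "consensus_exact",
    data$true13 | data$true23 ~ "consensus_high",
    alg3_only & !is.na(data$step3_score) &
      data$step3_score > score_threshold ~ "score_based",
    TRUE ~ "needs_review"
  )
  data$tier <- factor(tier, levels = .tier_levels, ordered = TRUE)
  data$tier_rationale <- dplyr::case_when(
    data$true123 ~ "all three algorithms agree",
    data$true12 ~ "algorithms 1 and 2 agree",
    data$true13 ~ "algorithms 1 and 3 agree",
    data$true23 ~ "algorithms 2 and 3 agree",
    tier == "score_based" ~ sprintf("similarity score %d > %.2f",
                                    data$step3_score, score_threshold),
    TRUE ~ "no agreement and score not above threshold"
  )
  data
}

#' Score separation between correct and wrong similarity results
#'
#' Welch's two-sided t-test on the token-set similarity scores of
#' validated-correct versus validated-wrong algorithm-3 results, together
#' with the descriptive panel (count, mean, SD, range, quartiles) used to
#' justify a score-based confidence threshold. A clear separation of the
#' two means indicates that higher scores carry a higher probability of
#' correctness.
#'
#' @param data A data frame; one row per validated entry.
#' @param score Name of the numeric score column.
#' @param correct Name of the logical column marking validated-correct
#'   results.
#' @return An object of class `score_separation` with components `test`
#'   (the `htest`) and `descriptives` (a tibble with one row per group).
#'   [tidy()] returns the test as a one-row tibble, [glance()] adds the
#'   group means and sizes, [autoplot()] shows the two score
#'   distributions.
#' @examples
#' d <- data.frame(score = c(90, 85, 96, 60, 55, 71),
#'                 ok = rep(c(TRUE, FALSE), each = 3))
#' score_separation_test(d, "score", "ok")
#' @export
score_separation_test <- function(data, score = "step3_score",
                                  correct = "correct") {
  x <- data[[score]]
  g <- data[[correct]]
  keep <- !is.na(x) & !is.na(g)
  x <- as.numeric(x[keep])
  g <- as.logical(g[keep])
  cs <- x[g]
  ws <- x[!g]
  if (length(cs) < 2 || length(ws) < 2) {
    abort("each group needs at least 2 scores for the separation test")
  }
  tt <- t.test(cs, ws, alternative = "two.sided", var.equal = FALSE)
  desc <- function(v, lab) {
    q <- quantile(v, c(.25, .5, .75), names = FALSE)
    tibble::tibble(group = lab, n = length(v), mean = mean(v), sd = sd(v),
                   min = min(v), q25 = q[1], median = q[2], q75 = q[3],
                   max = max(v))
  }
  structure(
    list(test = tt,
         descriptives = dplyr::bind_rows(desc(cs, "correct"),
                                         desc(ws, "wrong"))),
    class = "score_separation")
}

#' @export
print.score_separation <- function(x, ...) {
  cat("Score separation (Welch two-sided t-test)\n")
  cat(sprintf("  t = %.3f, df = %.1f, p = %.3g\n",
              x$test$statistic, x$test$parameter, x$test$p.value))
  print(x$descriptives)
  invisible(x)
}

#' @export
tidy.score_separation <- function(x, ...) {
  tt <- x$test
  tibble::tibble(
    estimate = unname(tt$estimate[1] - tt$estimate[2]),
    estimate_correct = unname(tt$estimate[1]),
    estimate_wrong = unname(tt$estimate[2]),
    statistic = unname(tt$statistic),
    p.value = tt$p.value,
    parameter = unname(tt$parameter),
    conf.low = tt$conf.int[1],
    conf.high = tt$conf.int[2],
    method = tt$method,
    alternative = tt$alternative
  )
}

#' @export
glance.score_separation <- function(x, ...) {
  d <- x$descriptives
  tibble::tibble(
    n_correct = d$n[d$group == "correct"],
    n_wrong = d$n[d$group == "wrong"],
    mean_correct = d$mean[d$group == "correct"],
    mean_wrong = d$mean[d$group == "wrong"],
    sd_correct = d$sd[d$group == "correct"],
    sd_wrong = d$sd[d$group == "wrong"],
    statistic = unname(x$test$statistic),
    p.value = x$test$p.value
  )
}

#' @export
autoplot.score_separation <- function(object, ...) {
  d <- object$descriptives
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$min, lower = .data$q25,
                   middle = .data$median, upper = .data$q75,
                   ymax = .data$max),
      stat = "identity", width = 0.5, fill = "grey85") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean), shape = 18, size = 3) +
    ggplot2::labs(x = NULL, y = "token-set similarity score",
                  title = "Similarity scores of correct vs wrong results") +
    ggplot2::theme_minimal()
}
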