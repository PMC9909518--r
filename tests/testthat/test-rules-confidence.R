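test_that("default rules exclude order texts but not drug texts", {
  expect_equal(classify_non_medication("BGA"), "bga")
  expect_equal(classify_non_medication("bga arteriell"), "bga")
  expect_equal(classify_non_medication("BE abnehmen"), "be")
  expect_true(is.na(classify_non_medication("Ibuprofen 600")))
  # prefix rules are whole-token: "BEloc" is a drug name, not an order
  expect_true(is.na(classify_non_medication("BEloc 50")))
  # empty rule set excludes nothing
  expect_true(all(is.na(classify_non_medication(
    c("BGA", "BB"), default_exclusion_rules()[0, ]))))
})

test_that("rules fire in listed order with first match winning", {
  rules <- tibble::tibble(
    rule_id = c("r1", "r2"),
    kind = c("prefix", "exact"),
    pattern = c("BGA", "BGA"),
    description = "")
  expect_equal(classify_non_medication("BGA", rules), "r1")
  expect_equal(classify_non_medication("BGA", rules[2:1, ]), "r2")
})

test_that("regex rules act on raw text and must compile", {
  rules <- tibble::tibble(rule_id = "lab", kind = "regex",
                          pattern = "^Labor:", description = "")
  expect_equal(classify_non_medication("Labor: BB", rules), "lab")
  expect_true(is.na(classify_non_medication("kein labor", rules)))
  bad <- tibble::tibble(rule_id = "x", kind = "regex", pattern = "(",
                        description = "")
  expect_error(classify_non_medication("a", bad), "does not compile")
})

test_that("rule configs round-trip through YAML", {
  rules <- dplyr::bind_rows(
    default_exclusion_rules(),
    tibble::tibble(rule_id = "lab", kind = "regex", pattern = "^Labor",
                   description = "lab order"))
  f <- tempfile(fileext = ".yml")
  write_exclusion_rules(rules, f)
  back <- read_exclusion_rules(f)
  expect_equal(as.data.frame(back), as.data.frame(rules))
})

test_that("concordance matches brute-force enumeration over {A, B, none}^3", {
  vals <- c("A01AA01", "B01AA01", NA)
  grid <- expand.grid(s1 = vals, s2 = vals, s3 = vals,
                      stringsAsFactors = FALSE)
  got <- concordance(grid$s1, grid$s2, grid$s3)
  eq <- function(a, b) !is.na(a) & !is.na(b) & a == b
  for (i in seq_len(nrow(grid))) {   # independent scalar re-derivation
    expect_equal(got$true12[i], eq(grid$s1[i], grid$s2[i]))
    expect_equal(got$true13[i], eq(grid$s1[i], grid$s3[i]))
    expect_equal(got$true23[i], eq(grid$s2[i], grid$s3[i]))
    expect_equal(got$true123[i],
                 eq(grid$s1[i], grid$s2[i]) && eq(grid$s1[i], grid$s3[i]) &&
                   eq(grid$s2[i], grid$s3[i]))
  }
  # invariant: three-way agreement implies every pairwise flag
  expect_true(all(!got$true123 | (got$true12 & got$true13 & got$true23)))
})

mk_entry <- function(step1 = NA_character_, step2 = NA_character_,
                     step3_atc = NA_character_, step3_score = NA_integer_) {
  add_concordance(tibble::tibble(step1 = step1, step2 = step2,
                                 step3_atc = step3_atc,
                                 step3_score = step3_score))
}

test_that("confidence tiers encode the validated reliability gradient", {
  a <- "N02BB02"; b <- "B05BB11"
  expect_equal(as.character(assign_confidence(mk_entry(a, a, a, 100L))$tier),
               "consensus_exact")
  expect_equal(as.character(assign_confidence(mk_entry(a, a, b, 90L))$tier),
               "consensus_exact")   # algorithms 1+2 agreeing suffice
  expect_equal(as.character(assign_confidence(mk_entry(a, NA, a, 95L))$tier),
               "consensus_high")
  expect_equal(as.character(assign_confidence(mk_entry(NA, a, a, 95L))$tier),
               "consensus_high")
  expect_equal(as.character(
    assign_confidence(mk_entry(NA, NA, a, 90L))$tier), "score_based")
  expect_equal(as.character(
    assign_confidence(mk_entry(NA, NA, a, 60L))$tier), "needs_review")
  # threshold is strict: a score exactly at the cutoff is not enough
  expect_equal(as.character(
    assign_confidence(mk_entry(NA, NA, a, 84L),
                      score_threshold = 84)$tier), "needs_review")
  expect_equal(as.character(assign_confidence(mk_entry(a, b, b, 99L))$tier),
               "consensus_high")
  expect_equal(as.character(assign_confidence(mk_entry())$tier),
               "needs_review")
})

test_that("raising the threshold never moves an entry up a tier", {
  fx <- generate_fixture(fixture_spec(n_catalog = 40, n_prescriptions = 1200,
                                      seed = 31))
  part <- partition_prescriptions(fx$prescriptions)
  matched <- match_all(group_unstructured(part$unstructured), fx$catalog)
  thresholds <- c(0, 50, 84.28, 95, 100)
  tiers <- lapply(thresholds, function(th)
    assign_confidence(matched, score_threshold = th)$tier)
  for (i in seq_len(length(thresholds) - 1)) {
    expect_true(all(tiers[[i + 1]] <= tiers[[i]]))
  }
})

test_that("tier assignment is a pure per-row function (permutation safe)", {
  fx <- generate_fixture(fixture_spec(n_catalog = 30, n_prescriptions = 600,
                                      seed = 32))
  part <- partition_prescriptions(fx$prescriptions)
  matched <- match_all(group_unstructured(part$unstructured), fx$catalog)
  tiered <- assign_confidence(matched)
  perm <- sample(nrow(matched))
  tiered_perm <- assign_confidence(matched[perm, ])
  expect_equal(tiered_perm$tier, tiered$tier[perm])
})

test_that("Welch t-test matches a hand-computed 3-vs-3 example", {
  # correct = (90, 85, 96), wrong = (60, 55, 71)
  d <- tibble::tibble(score = c(90, 85, 96, 60, 55, 71),
                      ok = rep(c(TRUE, FALSE), each = 3))
  res <- score_separation_test(d, "score", "ok")
  m1 <- mean(c(90, 85, 96)); m2 <- mean(c(60, 55, 71))
  v1 <- var(c(90, 85, 96)); v2 <- var(c(60, 55, 71))
  se <- sqrt(v1 / 3 + v2 / 3)
  t_hand <- (m1 - m2) / se
  df_hand <- se^4 / ((v1 / 3)^2 / 2 + (v2 / 3)^2 / 2)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(unname(res$test$statistic), t_hand, tolerance = 1e-12)
  expect_equal(unname(res$test$parameter), df_hand, tolerance = 1e-12)
  expect_equal(res$test$p.value, p_hand, tolerance = 1e-12)
  expect_equal(res$descriptives$mean, c(m1, m2))
  expect_equal(res$descriptives$n, c(3L, 3L))
})

test_that("identical groups give t = 0 and p = 1; tiny groups error", {
  d <- tibble::tibble(score = rep(c(80, 90, 70), 2),
                      ok = rep(c(TRUE, FALSE), each = 3))
  res <- score_separation_test(d, "score", "ok")
  expect_equal(unname(res$test$statistic), 0)
  expect_equal(res$test$p.value, 1)
  d2 <- tibble::tibble(score = c(80, 90, 70), ok = c(TRUE, FALSE, FALSE))
  expect_error(score_separation_test(d2, "score", "ok"), "at least 2")
})

test_that("tidy and glance expose the separation test in broom style", {
  d <- tibble::tibble(score = c(90, 85, 96, 60, 55, 71),
                      ok = rep(c(TRUE, FALSE), each = 3))
  res <- score_separation_test(d, "score", "ok")
  td <- tidy(res)
  expect_equal(nrow(td), 1)
  expect_equal(td$estimate, mean(c(90, 85, 96)) - mean(c(60, 55, 71)))
  gl <- glance(res)
  expect_equal(gl$n_correct, 3L)
  expect_equal(gl$n_wrong, 3L)
  expect_s3_class(autoplot(res), "ggplot")
})
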