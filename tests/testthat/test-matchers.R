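groups_of <- function(...) {
  texts <- c(...)
  tibble::tibble(medication = texts, frequency = rep(1L, length(texts)))
}

test_that("ingredient matching recognises whole-token containment only", {
  cat0 <- toy_catalog()
  m <- match_ingredient(
    groups_of("Ibuprofen 600", "keine medikation", "Paracetamol",
              "ibuprofen  retard"), cat0)
  expect_equal(m$step1, c("M01AE01", NA, "N02BE01", "M01AE01"))
  # token must survive whole: a name hidden inside a longer word is no hit
  m2 <- match_ingredient(groups_of("Ibuprofenol 600"), cat0)
  expect_true(is.na(m2$step1))
})

test_that("ambiguous ingredient names (combination products) yield no result", {
  cat0 <- toy_catalog()
  # Telmisartan maps to both C09DA07 (comp) and C09CA07 -> ambiguous
  m <- match_ingredient(groups_of("Telmisartan 80"), cat0)
  expect_true(is.na(m$step1))
})

test_that("product matching handles decorated texts and shuffled tokens", {
  cat0 <- toy_catalog()
  m <- match_product(
    groups_of("ARILIN 500 Filmtabletten | (Metronidazol)",
              "",
              "Filmtabletten ARILIN 500",
              "irgendwas anderes"), cat0)
  expect_equal(m$step2, c("P01AB01", NA, "P01AB01", NA))
})

test_that("matched names' tokens are always contained in the query text", {
  fx <- generate_fixture(fixture_spec(n_catalog = 60, n_prescriptions = 1500,
                                      seed = 21))
  part <- partition_prescriptions(fx$prescriptions)
  groups <- group_unstructured(part$unstructured)
  m <- match_ingredient(match_product(groups, fx$catalog), fx$catalog)
  check <- function(names, texts) {
    ok <- mapply(function(nm, tx) {
      if (is.na(nm)) return(TRUE)
      all(tokenize_text(nm)[[1]] %in% tokenize_text(tx)[[1]])
    }, names, texts)
    all(ok)
  }
  expect_true(check(m$step1_name, m$medication))
  expect_true(check(m$step2_name, m$medication))
})

test_that("similarity matching returns ranked, deterministic top-k", {
  cat0 <- toy_catalog()
  g <- groups_of("Ibuprofen 600", "Telmisartan", "xyz unbekannt")
  m1 <- match_similarity(g, cat0, k = 3)
  m2 <- match_similarity(g, cat0, k = 3)
  expect_identical(m1$step3, m2$step3)  # bit-identical rerun
  for (cand in m1$step3) {
    expect_lte(nrow(cand), 3)
    expect_true(all(diff(cand$score) <= 0))        # non-increasing
    expect_equal(anyDuplicated(cand$atc), 0)       # unique ATCs
  }
  # text tokens a subset of a product name's tokens -> that ATC at 100
  m3 <- match_similarity(groups_of("Ibuprofen 600 STADA"), cat0)
  expect_equal(m3$step3_atc[1], "M01AE01")
  expect_equal(m3$step3_score[1], 100L)
})

test_that("similarity matching answers every entry; k and catalog validated", {
  cat0 <- toy_catalog()
  g <- groups_of("a", "zzz qqq", "NaCl 0.9%")
  m <- match_similarity(g, cat0)
  expect_false(any(is.na(m$step3_atc)))
  expect_error(match_similarity(g, cat0[0, ]), "non-empty catalog")
  expect_error(match_similarity(g, cat0, k = 0))
})

test_that("short ambiguous texts can rank a wrong combination product first", {
  # a truncated text matches both the combination and the plain product at
  # 100; the ranked list stays within k and contains the true code too
  cat0 <- toy_catalog()
  m <- match_similarity(groups_of("Telmisartan"), cat0, k = 3)
  cand <- m$step3[[1]]
  expect_lte(nrow(cand), 3)
  expect_true(all(c("C09DA07", "C09CA07") %in% cand$atc))
  expect_equal(cand$score[1], 100L)
})

test_that("verbatim product texts make all answering algorithms agree", {
  fx <- generate_fixture(fixture_spec(n_catalog = 40, n_prescriptions = 400,
                                      combination_fraction = 0, seed = 22))
  g <- groups_of(fx$catalog$product_name[1:20])
  m <- match_all(g, fx$catalog)
  agree <- function(a, b) is.na(a) | is.na(b) | a == b
  expect_true(all(agree(m$step1, m$step2)))
  expect_true(all(agree(m$step1, m$step3_atc)))
  expect_true(all(agree(m$step2, m$step3_atc)))
  expect_true(all(m$step2 == fx$catalog$atc_code[1:20]))
})

test_that("ingredient matching recovers ground truth on unambiguous fixtures", {
  fx <- generate_fixture(fixture_spec(n_catalog = 80, n_prescriptions = 4000,
                                      seed = 23))
  dose_ids <- fx$truth$class == "ingredient_plus_dose"
  comb_ing <- fx$catalog$ingredient_name[fx$catalog$combination]
  texts <- unique(fx$truth$medication[dose_ids])
  g <- tibble::tibble(medication = texts, frequency = 1L)
  m <- match_ingredient(g, fx$catalog)
  truth_map <- fx$truth[dose_ids, c("medication", "true_atc")]
  truth_map <- truth_map[!duplicated(truth_map$medication), ]
  tr <- truth_map$true_atc[match(m$medication, truth_map$medication)]
  ambiguous <- vapply(m$medication, function(tx) {
    any(tolower(comb_ing) %in% tokenize_text(tx)[[1]])
  }, logical(1))
  expect_true(all(m$step1[!ambiguous] == tr[!ambiguous]))
  expect_true(all(is.na(m$step1[ambiguous])))
  # sanity: alg3 top-1 on the same unambiguous subset is at least as accurate
  m3 <- match_similarity(g, fx$catalog)
  acc1 <- mean(m$step1[!ambiguous] == tr[!ambiguous])
  acc3 <- mean(m3$step3_atc[!ambiguous] == tr[!ambiguous])
  expect_gte(acc3, 0.9)
  expect_equal(acc1, 1)
})

test_that("token-shuffled product names are recovered at score 100", {
  fx <- generate_fixture(fixture_spec(n_catalog = 30, n_prescriptions = 500,
                                      combination_fraction = 0, seed = 24))
  sh <- fx$truth[fx$truth$class == "token_shuffle", ]
  sh <- sh[!duplicated(sh$medication), ]
  g <- tibble::tibble(medication = sh$medication, frequency = 1L)
  m <- match_similarity(g, fx$catalog)
  expect_true(all(m$step3_score == 100L))
  expect_true(all(m$step3_atc == sh$true_atc))
})
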