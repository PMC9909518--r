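test_that("normalisation lower-cases, maps punctuation to spaces, trims", {
  expect_equal(tokenize_text("NaCl 0.9%")[[1]], c("nacl", "0", "9"))
  expect_equal(tokenize_text("Stada paracetamol")[[1]],
               c("stada", "paracetamol"))
  expect_equal(tokenize_text("")[[1]], character(0))
  expect_equal(tokenize_text("||(%)__")[[1]], character(0))
  expect_equal(normalize_text("  A |b_ C  "), "a b c")
  # idempotence
  x <- c("NaCl 0.9%", "ARILIN 500 Filmtabletten | (Metronidazol)", "Zäpfchen")
  expect_equal(normalize_text(normalize_text(x)), normalize_text(x))
})

test_that("indel distance matches its defining LCS formula and oracles", {
  expect_equal(indel_distance("abc", "abc"), 0L)
  expect_equal(indel_distance("abc", ""), 3L)
  expect_equal(indel_distance("", ""), 0L)
  # exhaustive brute-force subsequence enumeration on tiny strings
  tiny <- all_strings(4)
  set.seed(11)
  pick <- sample(length(tiny), 30)
  for (i in pick) for (j in sample(length(tiny), 8)) {
    expect_equal(indel_distance(tiny[i], tiny[j]),
                 brute_indel(tiny[i], tiny[j]))
  }
  # independent generalized-edit-distance oracle on random longer strings
  set.seed(12)
  a <- rand_strings(300, 25)
  b <- rand_strings(300, 25)
  expect_equal(indel_distance(a, b), adist_indel(a, b))
})

test_that("indel distance is a metric (symmetry, identity, triangle)", {
  set.seed(13)
  a <- rand_strings(80, 12)
  b <- rand_strings(80, 12)
  c <- rand_strings(80, 12)
  expect_equal(indel_distance(a, b), indel_distance(b, a))
  expect_true(all(indel_distance(a, a) == 0L))
  expect_true(all((indel_distance(a, b) == 0L) == (a == b)))
  expect_true(all(indel_distance(a, c) <=
                    indel_distance(a, b) + indel_distance(b, c)))
})

test_that("distances count characters, not bytes, for non-ASCII names", {
  expect_equal(indel_distance("zäpfchen", "zapfchen"), 2L)
  expect_equal(ratio_simple("zäpfchen", "zäpfchen"), 100L)
})

test_that("the worked four-ratio example scores exactly as published", {
  d1 <- tolower("Stada paracetamol")
  d2 <- tolower("paracetamol Stada 400 mg")
  expect_identical(ratio_simple(d1, d2), 54L)
  expect_identical(ratio_partial(d1, d2), 65L)
  expect_identical(ratio_token_sort(d1, d2), 83L)
  expect_identical(ratio_token_set(d1, d2), 100L)
})

test_that("simple ratio is the rounded normalized indel similarity", {
  set.seed(14)
  a <- rand_strings(200, 15)
  b <- rand_strings(200, 15)
  d <- adist_indel(a, b)
  tot <- nchar(a) + nchar(b)
  expected <- ifelse(tot == 0, 100L,
                     as.integer(floor(100 * (tot - d) / tot + 0.5)))
  expect_equal(ratio_simple(a, b), expected)
  expect_identical(ratio_simple("", ""), 100L)
  expect_identical(ratio_simple("", "abc"), 0L)
  expect_true(all(ratio_simple(a, a) == 100L))
})

test_that("all four ratios are symmetric and bounded in [0, 100]", {
  set.seed(15)
  a <- rand_strings(60, 12, alphabet = c(letters[1:5], " "))
  b <- rand_strings(60, 12, alphabet = c(letters[1:5], " "))
  for (f in list(ratio_simple, ratio_partial, ratio_token_sort,
                 ratio_token_set)) {
    sab <- f(a, b)
    expect_equal(sab, f(b, a))
    expect_true(all(sab >= 0 & sab <= 100))
    expect_true(all(f(a, a) == 100L))
  }
})

test_that("partial ratio finds perfect windows for verbatim substrings", {
  expect_identical(ratio_partial("paracetamol", "xx paracetamol yy"), 100L)
  expect_identical(ratio_partial("abc", "abc"), 100L)
  set.seed(16)
  # embedded non-empty substring at a random offset always yields 100
  for (i in 1:20) {
    s <- paste(sample(letters[1:6], sample(1:8, 1), replace = TRUE),
               collapse = "")
    pre <- rand_strings(1, 5)
    post <- rand_strings(1, 5)
    expect_identical(ratio_partial(s, paste0(pre, s, post)), 100L)
  }
  # equal-length inputs have a single window: partial equals simple
  a <- rand_strings(50, 8)
  b <- vapply(seq_along(a), function(i)
    paste(sample(letters[1:6], nchar(a)[i], replace = TRUE), collapse = ""),
    character(1))
  expect_identical(ratio_partial(a, b), ratio_simple(a, b))
})

test_that("token-sort ratio equals the simple ratio of sorted-token forms", {
  expect_identical(ratio_token_sort("a b", "b a c"),
                   ratio_simple("a b", "a b c"))
  # permutations of the same token multiset always score 100
  set.seed(17)
  for (i in 1:20) {
    toks <- sample(c("alpha", "beta", "gamma", "delta", "400", "mg"),
                   sample(2:5, 1))
    expect_identical(
      ratio_token_sort(paste(toks, collapse = " "),
                       paste(sample(toks), collapse = " ")),
      100L)
  }
})

test_that("token-set ratio is 100 whenever one token set contains the other", {
  vocab <- c("para", "ibu", "hexal", "stada", "400", "600", "mg", "ml",
             "forte", "akut", "tabletten", "saft")
  set.seed(18)
  for (i in 1:200) {
    sub <- sample(vocab, sample(1:5, 1))
    sup <- unique(c(sub, sample(vocab, sample(0:6, 1))))
    a <- paste(sample(sub, length(sub), replace = TRUE), collapse = " ")
    b <- paste(sample(sup), collapse = " ")
    expect_identical(ratio_token_set(a, b), 100L)
  }
})

test_that("token-set ratio dominates token-sort ratio on duplicate-free
           token lists", {
  # with repeated tokens the set construction collapses duplicates that
  # the sort construction counts, so dominance only holds duplicate-free
  set.seed(19)
  vocab <- c("aa", "ab", "ba", "cc", "dd", "x", "y", "123", "mg", "ml")
  for (i in 1:300) {
    a <- paste(sample(vocab, sample(1:6, 1)), collapse = " ")
    b <- paste(sample(vocab, sample(1:6, 1)), collapse = " ")
    expect_gte(ratio_token_set(a, b), ratio_token_sort(a, b))
  }
})

test_that("disjoint token sets score as the simple ratio of the remainders", {
  # empty intersection: the construction reduces to remainder vs remainder
  expect_identical(ratio_token_set("aaa", "zzz"),
                   ratio_simple("aaa", "zzz"))
  expect_identical(ratio_token_set("abc def", "xyz uvw"),
                   ratio_simple("abc def", "uvw xyz"))
})

test_that("score_pair reports all four ratios in one row", {
  sp <- score_pair("Stada paracetamol", "paracetamol Stada 400 mg")
  expect_equal(sp$simple, 54L)
  expect_equal(sp$partial, 65L)
  expect_equal(sp$token_sort, 83L)
  expect_equal(sp$token_set, 100L)
})
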