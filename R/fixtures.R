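# run code under a temporary RNG state so generators are seeded and
# reproducible without disturbing the caller's stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.makers <- c("Stada", "Hexal", "Ratiopharm", "Verla", "Jenapharm",
             "Acis", "Puren")
.forms <- c("Filmtabletten", "Tabletten", "Kapseln", "Z\u00e4pfchen",
            "Injektionsl\u00f6sung", "Granulat", "Brausetabletten")
.doses <- c(5, 10, 20, 25, 40, 50, 75, 100, 150, 200, 250, 300, 400,
            500, 600, 750, 850, 1000)
.nomed_vocab <- c("BGA", "BB", "BE", "BGA kontrolle", "BB morgen",
                  "BE abnehmen", "BGA arteriell")

.syllables <- c("ba", "be", "bi", "bo", "bu", "ca", "ce", "ci", "co",
                "da", "de", "di", "do", "du", "fa", "fe", "fi", "fo",
                "ga", "ge", "gi", "go", "la", "le", "li", "lo", "lu",
                "ma", "me", "mi", "mo", "mu", "na", "ne", "ni", "no",
                "pa", "pe", "pi", "po", "ra", "re", "ri", "ro", "ru",
                "sa", "se", "si", "so", "ta", "te", "ti", "to", "tu",
                "va", "ve", "vi", "vo", "xa", "xe", "xi", "zo", "zu")
.name_suffixes <- c("zol", "fen", "pril", "statin", "micin", "dipin",
                    "olol", "mab", "tan", "ran", "xin", "cain")

.pseudo_name <- function(n_syll = sample(2:3, 1)) {
  base <- paste(sample(.syllables, n_syll, replace = TRUE), collapse = "")
  paste0(toupper(substr(base, 1, 1)), substr(base, 2, nchar(base)),
         sample(.name_suffixes, 1))
}

.random_atc5 <- function(n) {
  paste0(sample(.atc_groups, n, replace = TRUE),
         sprintf("%02d", sample(0:99, n, replace = TRUE)),
         sample(LETTERS, n, replace = TRUE),
         sample(LETTERS, n, replace = TRUE),
         sprintf("%02d", sample(0:99, n, replace = TRUE)))
}

#' Specification for a synthetic prescription fixture
#'
#' Bundles all generator parameters. The defaults encode the study
#' conditions the package is tested under: a structured fraction of
#' 0.4773 and a non-medication fraction of 0.091 (the proportions observed
#' in the motivating hospital cohort), a Zipf-skewed frequency
#' distribution over free texts (so a small top list covers most of the
#' unstructured mass), and a corruption mix spanning the free-text
#' phenomena the matchers must face: verbatim product names, ingredient
#' plus dose, shuffled token order, truncation, typos at a controlled
#' indel distance, and texts with no recognisable catalog rendering.
#'
#' @param n_catalog Number of catalog rows.
#' @param n_prescriptions Number of prescription records.
#' @param structured_fraction Probability a record is a structured catalog
#'   pick.
#' @param nomed_fraction Probability a record is a non-medication order
#'   text.
#' @param combination_fraction Fraction of catalog rows that are
#'   combination products: they reuse an existing ingredient name under a
#'   distinct ATC code, the main error source for similarity matching.
#' @param corruption_mix Named probabilities over the six free-text
#'   corruption classes (must sum to 1).
#' @param zipf_exponent Exponent of the rank-frequency law for drug
#'   popularity.
#' @param typo_k Indel distance of injected typos.
#' @param seed Integer seed governing all draws.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_catalog = 250,
                         n_prescriptions = 10000,
                         structured_fraction = 0.4773,
                         nomed_fraction = 0.091,
                         combination_fraction = 0.1,
                         corruption_mix = c(verbatim_product = 0.25,
                                            ingredient_plus_dose = 0.30,
                                            token_shuffle = 0.15,
                                            truncation = 0.10,
                                            typo = 0.10,
                                            non_catalog_text = 0.10),
                         zipf_exponent = 1.1,
                         typo_k = 2,
                         seed = 1) {
  stopifnot(n_catalog >= 1, n_prescriptions >= 1,
            structured_fraction >= 0, structured_fraction <= 1,
            nomed_fraction >= 0, nomed_fraction <= 1,
            structured_fraction + nomed_fraction <= 1,
            combination_fraction >= 0, combination_fraction < 1,
            all(corruption_mix >= 0),
            abs(sum(corruption_mix) - 1) < 1e-8,
            zipf_exponent > 0, typo_k >= 1)
  need <- c("verbatim_product", "ingredient_plus_dose", "token_shuffle",
            "truncation", "typo", "non_catalog_text")
  stopifnot(setequal(names(corruption_mix), need))
  structure(list(n_catalog = n_catalog,
                 n_prescriptions = n_prescriptions,
                 structured_fraction = structured_fraction,
                 nomed_fraction = nomed_fraction,
                 combination_fraction = combination_fraction,
                 corruption_mix = corruption_mix[need],
                 zipf_exponent = zipf_exponent,
                 typo_k = typo_k,
                 seed = seed),
            class = "fixture_spec")
}

#' Generate a synthetic drug catalog (DS2 shape)
#'
#' Pronounceable pseudo-ingredients built from syllable templates (never
#' real drug lists), decorated into product names with maker, dose and
#' form words. A configurable fraction of rows are combination products:
#' the same ingredient name under a second, distinct ATC level-5 code.
#' Deterministic for a given spec seed.
#'
#' @param spec A [fixture_spec()].
#' @return A `drug_catalog` tibble (`product_name`, `ingredient_name`,
#'   `atc_code`) with a logical `combination` column.
#' @export
generate_catalog <- function(spec = fixture_spec()) {
  .with_seed(spec$seed, {
    n <- spec$n_catalog
    n_comb <- floor(spec$combination_fraction * n)
    n_base <- n - n_comb
    banned <- tolower(c(.makers, .forms, .nomed_vocab))
    ingredients <- character(0)
    while (length(ingredients) < n_base) {
      cand <- vapply(seq_len(n_base - length(ingredients)), function(i)
        .pseudo_name(), character(1))
      cand <- setdiff(unique(cand), c(ingredients, banned))
      ingredients <- c(ingredients, cand)
    }
    atc <- unique(.random_atc5(3 * n))
    while (length(atc) < n) atc <- unique(c(atc, .random_atc5(n)))
    atc <- atc[seq_len(n)]
    mk_product <- function(ing, comp = FALSE) {
      paste(toupper(ing), if (comp) "comp" else sample(.makers, 1),
            sample(.doses, 1), "mg", sample(.forms, 1))
    }
    base <- tibble::tibble(
      product_name = vapply(ingredients, mk_product, character(1),
                            USE.NAMES = FALSE),
      ingredient_name = ingredients,
      atc_code = atc[seq_len(n_base)],
      combination = FALSE
    )
    comb <- if (n_comb > 0) {
      host <- sample(ingredients, n_comb,
                     replace = n_comb > length(ingredients))
      tibble::tibble(
        product_name = vapply(host, function(i) mk_product(i, comp = TRUE),
                              character(1), USE.NAMES = FALSE),
        ingredient_name = host,
        atc_code = atc[n_base + seq_len(n_comb)],
        combination = TRUE
      )
    } else NULL
    out <- dplyr::bind_rows(base, comb)
    # dose/form draws can collide for combination hosts; disambiguate
    dup <- duplicated(out$product_name)
    while (any(dup)) {
      out$product_name[dup] <- vapply(
        out$ingredient_name[dup],
        function(i) mk_product(i, comp = TRUE), character(1),
        USE.NAMES = FALSE)
      dup <- duplicated(out$product_name)
    }
    class(out) <- c("drug_catalog", class(out))
    out
  })
}

.inject_typo <- function(x, k) {
  ch <- strsplit(x, "")[[1]]
  for (i in seq_len(k)) {
    if (length(ch) > 3 && runif(1) < 0.5) {
      ch <- ch[-sample(length(ch), 1)]        # deletion
    } else {
      pos <- sample(length(ch) + 1, 1)        # insertion
      ch <- append(ch, sample(letters, 1), after = pos - 1)
    }
  }
  paste(ch, collapse = "")
}

# one deterministic free-text rendering per (catalog row, corruption class),
# so repeated draws of the same drug produce repeated texts and the grouped
# frequencies inherit the popularity skew
.renderings <- function(catalog, spec) {
  n <- nrow(catalog)
  shuffle <- function(x) {
    t <- strsplit(x, " ", fixed = TRUE)[[1]]
    paste(sample(t), collapse = " ")
  }
  truncate1 <- function(x) substr(x, 1, max(3, ceiling(nchar(x) / 2)))
  tibble::tibble(
    row = rep(seq_len(n), 6L),
    class = rep(c("verbatim_product", "ingredient_plus_dose",
                  "token_shuffle", "truncation", "typo",
                  "non_catalog_text"), each = n),
    text = c(
      catalog$product_name,
      paste(catalog$ingredient_name, sample(.doses, n, replace = TRUE)),
      vapply(catalog$product_name, shuffle, character(1),
             USE.NAMES = FALSE),
      vapply(catalog$ingredient_name, truncate1, character(1),
             USE.NAMES = FALSE),
      vapply(catalog$ingredient_name, .inject_typo, character(1),
             k = spec$typo_k, USE.NAMES = FALSE),
      vapply(seq_len(n), function(i)
        paste(.pseudo_name(), sample(.doses, 1), "ml"), character(1))
    )
  )
}

#' Generate synthetic prescriptions with ground truth (DS1 shape)
#'
#' Structured records are verbatim catalog picks carrying their ATC
#' level-5 code. Unstructured records render a Zipf-popularity-weighted
#' catalog row through one of six corruption classes (see
#' [fixture_spec()]); renderings are deterministic per (row, class) so
#' texts repeat and group frequencies follow the popularity skew.
#' Non-medication records are drawn from an order-text vocabulary
#' ("BGA", "BB", "BE", ...). Every non-nomed record's true ATC code
#' exists in the catalog.
#'
#' @param catalog A catalog from [generate_catalog()].
#' @param spec The same [fixture_spec()].
#' @return A list with `prescriptions` (tibble: `medication`, `year`,
#'   `structured`, `atc_l5`) and `truth` (tibble: `id`, `medication`,
#'   `true_atc` (`NA` for nomed), `class`).
#' @export
generate_prescriptions <- function(catalog, spec = fixture_spec()) {
  stopifnot(nrow(catalog) >= 1)
  .with_seed(spec$seed + 1L, {
    n <- spec$n_prescriptions
    nc <- nrow(catalog)
    status <- sample(c("structured", "nomed", "unstructured"), n,
                     replace = TRUE,
                     prob = c(spec$structured_fraction, spec$nomed_fraction,
                              1 - spec$structured_fraction -
                                spec$nomed_fraction))
    zipf <- (seq_len(nc))^(-spec$zipf_exponent)
    row <- sample(seq_len(nc), n, replace = TRUE, prob = zipf / sum(zipf))
    cls <- rep(NA_character_, n)
    uns <- status == "unstructured"
    cls[uns] <- sample(names(spec$corruption_mix), sum(uns), replace = TRUE,
                       prob = spec$corruption_mix)
    rend <- .renderings(catalog, spec)
    key <- paste(rend$row, rend$class)
    medication <- character(n)
    str_i <- status == "structured"
    medication[str_i] <- paste0(catalog$product_name[row[str_i]], " | (",
                                catalog$ingredient_name[row[str_i]], ")")
    nom_i <- status == "nomed"
    medication[nom_i] <- sample(.nomed_vocab, sum(nom_i), replace = TRUE)
    medication[uns] <- rend$text[match(paste(row[uns], cls[uns]), key)]
    prescriptions <- tibble::tibble(
      medication = medication,
      year = sample(2016:2020, n, replace = TRUE),
      structured = str_i,
      atc_l5 = dplyr::if_else(str_i, catalog$atc_code[row], NA_character_)
    )
    truth <- tibble::tibble(
      id = seq_len(n),
      medication = medication,
      true_atc = dplyr::if_else(nom_i, NA_character_,
                                catalog$atc_code[row]),
      class = dplyr::case_when(str_i ~ "structured",
                               nom_i ~ "nomed",
                               TRUE ~ cls)
    )
    list(prescriptions = prescriptions, truth = truth)
  })
}

#' Generate a complete fixture
#'
#' @param spec A [fixture_spec()].
#' @return A list with `catalog`, `prescriptions`, `truth` and `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  catalog <- generate_catalog(spec)
  gp <- generate_prescriptions(catalog, spec)
  list(catalog = catalog, prescriptions = gp$prescriptions,
       truth = gp$truth, spec = spec)
}

#' Write a fixture to disk (DS1 + DS2 + ground-truth sidecar)
#'
#' Writes `prescriptions.csv` (DS1 headers), `catalog.csv` (DS2 headers),
#' `truth.csv` and a `fixture_provenance.yml` sidecar recording every
#' generator parameter, into `dir`.
#'
#' @param fixture A fixture from [generate_fixture()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_prescriptions(fixture$prescriptions,
                      file.path(dir, "prescriptions.csv"))
  write_catalog(fixture$catalog, file.path(dir, "catalog.csv"))
  readr::write_delim(
    tibble::tibble(ID = fixture$truth$id,
                   MEDICATION = fixture$truth$medication,
                   TRUE_ATC = dplyr::coalesce(fixture$truth$true_atc, ""),
                   CLASS = fixture$truth$class),
    file.path(dir, "truth.csv"), delim = ",")
  spec <- fixture$spec
  yaml::write_yaml(
    list(generator = "atcmapr::generate_fixture",
         parameters = lapply(unclass(spec), function(x)
           if (is.numeric(x) && !is.null(names(x))) as.list(x) else x)),
    file.path(dir, "fixture_provenance.yml"))
  invisible(dir)
}

#' Simulate the expert validation round
#'
#' Fills the reviewer columns of an exported workbook slice the way an
#' oracle expert with access to the generator's ground truth would:
#' each algorithm result is marked correct/incorrect against the true
#' ATC code, nomed texts get `FINAL = "nomed"`, and when no algorithm
#' found the true code it is entered into `CORRECT`. The resolved
#' records mirror [import_validation_workbook()] output.
#'
#' @param workbook A matched workbook slice (the `workbook` element of
#'   [run_pipeline()], or any tibble with `medication`, `frequency`,
#'   `step1`, `step2`, `step3_atc` and concordance flags).
#' @param truth The fixture `truth` tibble.
#' @return A validation-records tibble with resolved `final`.
#' @export
simulate_validation <- function(workbook, truth) {
  # majority truth per unique text (truncation renderings may collide)
  tt <- truth |>
    dplyr::count(.data$medication, .data$true_atc, sort = TRUE) |>
    dplyr::distinct(.data$medication, .keep_all = TRUE)
  idx <- match(workbook$medication, tt$medication)
  true_atc <- tt$true_atc[idx]
  known <- !is.na(idx)
  is_nomed <- known & is.na(true_atc)
  eq <- function(s) known & !is.na(s) & !is.na(true_atc) & s == true_atc
  out <- tibble::tibble(
    medication = workbook$medication,
    frequency = workbook$frequency,
    step1 = workbook$step1,
    step2 = workbook$step2,
    step3_atc = workbook$step3_atc,
    eval1 = dplyr::if_else(is.na(workbook$step1), NA, eq(workbook$step1)),
    eval2 = dplyr::if_else(is.na(workbook$step2), NA, eq(workbook$step2)),
    eval3 = dplyr::if_else(is.na(workbook$step3_atc), NA,
                           eq(workbook$step3_atc)),
    true12 = workbook$true12, true13 = workbook$true13,
    true23 = workbook$true23, true123 = workbook$true123,
    correct = NA_character_,
    comments = ""
  )
  none_right <- known & !is_nomed & !(out$eval1 %in% TRUE) &
    !(out$eval2 %in% TRUE) & !(out$eval3 %in% TRUE)
  out$correct[none_right] <- true_atc[none_right]
  out$final <- dplyr::case_when(
    is_nomed ~ "nomed",
    !is.na(out$correct) ~ out$correct,
    out$eval1 %in% TRUE ~ out$step1,
    out$eval2 %in% TRUE ~ out$step2,
    out$eval3 %in% TRUE ~ out$step3_atc,
    TRUE ~ "no_eval"
  )
  out
}
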