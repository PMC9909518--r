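# Catalog name index shared by the three algorithms: one row per
# (name, atc, source) with the normalised form and token list.
.catalog_names <- function(catalog, sources = c("ingredient", "product")) {
  stopifnot(nrow(catalog) >= 1)
  parts <- list()
  if ("ingredient" %in% sources) {
    parts$ingredient <- tibble::tibble(
      name = catalog$ingredient_name, atc = catalog$atc_code,
      source = "ingredient")
  }
  if ("product" %in% sources) {
    parts$product <- tibble::tibble(
      name = catalog$product_name, atc = catalog$atc_code,
      source = "product")
  }
  idx <- dplyr::bind_rows(parts)
  idx$name[is.na(idx$name)] <- ""
  idx <- idx[nzchar(trimws(idx$name)), ]
  idx$norm <- normalize_text(idx$name)
  idx <- idx[nzchar(idx$norm), ]
  idx <- dplyr::distinct(idx, .data$norm, .data$atc, .data$source,
                         .keep_all = TRUE)
  idx$tokens <- lapply(tokenize_text(idx$norm), unique)
  idx$n_tok <- lengths(idx$tokens)
  idx$nchar_norm <- nchar(idx$norm)
  idx
}

# Whole-token containment matcher behind algorithms 1 and 2: a catalog
# name matches a text when every one of its tokens occurs among the
# text's tokens (order-free). Longest normalised name wins; if the
# surviving best names map to more than one distinct ATC the result is
# ambiguous and empty.
.match_containment <- function(texts, idx) {
  n <- length(texts)
  res <- tibble::tibble(atc = rep(NA_character_, n),
                        matched_name = rep(NA_character_, n),
                        score = rep(NA_integer_, n))
  if (nrow(idx) == 0 || n == 0) return(res)
  text_tokens <- lapply(tokenize_text(texts), unique)
  tok_tbl <- tibble::tibble(
    tid = rep(seq_len(n), lengths(text_tokens)),
    token = unlist(text_tokens)
  )
  name_tok <- tibble::tibble(
    nid = rep(seq_len(nrow(idx)), idx$n_tok),
    token = unlist(idx$tokens)
  )
  hits <- dplyr::inner_join(tok_tbl, name_tok, by = "token",
                            relationship = "many-to-many")
  if (nrow(hits) == 0) return(res)
  hits <- dplyr::count(dplyr::distinct(hits), .data$tid, .data$nid,
                       name = "n_hit")
  hits$n_tok <- idx$n_tok[hits$nid]
  full <- hits[hits$n_hit == hits$n_tok, c("tid", "nid")]
  if (nrow(full) == 0) return(res)
  full$nchar_norm <- idx$nchar_norm[full$nid]
  full$atc <- idx$atc[full$nid]
  full$name <- idx$name[full$nid]
  best <- full |>
    dplyr::group_by(.data$tid) |>
    dplyr::filter(.data$nchar_norm == max(.data$nchar_norm)) |>
    dplyr::summarise(
      n_atc = dplyr::n_distinct(.data$atc),
      atc = .data$atc[1],
      matched_name = sort(.data$name)[1],
      .groups = "drop")
  unambig <- best[best$n_atc == 1L, ]
  res$atc[unambig$tid] <- unambig$atc
  res$matched_name[unambig$tid] <- unambig$matched_name
  res$score[unambig$tid] <- 100L
  res
}

#' Algorithm 1: ingredient-name matching
#'
#' Matches each free text against catalog ingredient names by whole-token
#' containment: an ingredient matches when all of its (normalised) tokens
#' occur among the text's tokens. The longest matching ingredient name
#' wins; if equally long survivors map to more than one distinct ATC code
#' the entry is ambiguous and no result is returned. Exact matches carry
#' score 100.
#'
#' @param data A data frame with the free-text column (typically a grouped
#'   DS3 tibble from [group_unstructured()]).
#' @param catalog A `drug_catalog` tibble ([read_catalog()] or
#'   [generate_catalog()]).
#' @param text Name of the text column (default `medication`).
#' @return `data` with an added `step1` column (ATC level-5 code or `NA`)
#'   and `step1_name` (the matched ingredient name).
#' @export
match_ingredient <- function(data, catalog, text = "medication") {
  idx <- .catalog_names(catalog, "ingredient")
  m <- .match_containment(data[[text]], idx)
  data$step1 <- m$atc
  data$step1_name <- m$matched_name
  data
}

#' Algorithm 2: product-name matching
#'
#' As [match_ingredient()], but against catalog product names. Adds
#' `step2` and `step2_name`.
#'
#' @inheritParams match_ingredient
#' @return `data` with added `step2` and `step2_name` columns.
#' @export
match_product <- function(data, catalog, text = "medication") {
  idx <- .catalog_names(catalog, "product")
  m <- .match_containment(data[[text]], idx)
  data$step2 <- m$atc
  data$step2_name <- m$matched_name
  data
}

#' Algorithm 3: token-set similarity matching
#'
#' Scores each free text against every catalog ingredient name and product
#' name with [ratio_token_set()], keeps each distinct ATC code's best
#' score, and returns the top `k` candidates sorted by score (descending).
#' Ties are broken by longer matched name, then lexicographic ATC code, so
#' reruns are bit-identical. Unlike algorithms 1 and 2, this always
#' produces at least one candidate for a non-empty catalog.
#'
#' @inheritParams match_ingredient
#' @param k Maximum number of ranked candidates to keep (default 3).
#' @return `data` with added columns `step3` (list column of candidate
#'   tibbles with `atc`, `score`, `matched_name`, `source`), `step3_atc`
#'   and `step3_score` (the top-1 candidate).
#' @export
match_similarity <- function(data, catalog, text = "medication", k = 3L) {
  stopifnot(k >= 1)
  if (nrow(catalog) == 0) {
    abort("similarity matching requires a non-empty catalog")
  }
  idx <- .catalog_names(catalog, c("ingredient", "product"))
  texts <- data[[text]]
  qtok <- tokenize_text(texts)
  # order once so per-ATC dedup and top-k are a single slice
  cand1 <- vector("list", length(texts))
  for (i in seq_along(texts)) {
    scores <- .token_set_scores_cpp(qtok[[i]], idx$tokens)
    ord <- order(-scores, -idx$nchar_norm, idx$atc, method = "radix")
    atc_o <- idx$atc[ord]
    keep <- ord[!duplicated(atc_o)][seq_len(min(k, dplyr::n_distinct(atc_o)))]
    cand1[[i]] <- tibble::tibble(
      atc = idx$atc[keep],
      score = scores[keep],
      matched_name = idx$name[keep],
      source = idx$source[keep]
    )
  }
  data$step3 <- cand1
  data$step3_atc <- vapply(cand1, function(s) s$atc[1], character(1))
  data$step3_score <- vapply(cand1, function(s) s$score[1], integer(1))
  data
}

#' Run all three matching algorithms
#'
#' Convenience wrapper applying [match_ingredient()], [match_product()]
#' and [match_similarity()], then adding the pairwise/three-way
#' concordance flags with [add_concordance()].
#'
#' @inheritParams match_similarity
#' @return `data` with `step1`, `step2`, `step3*` and `true12`, `true13`,
#'   `true23`, `true123` columns.
#' @export
match_all <- function(data, catalog, text = "medication", k = 3L) {
  data |>
    match_ingredient(catalog, text = text) |>
    match_product(catalog, text = text) |>
    match_similarity(catalog, text = text, k = k) |>
    add_concordance()
}
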