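#' Exclusion rules for non-medication entries
#'
#' Prescription free-text fields also collect entries that are not drug
#' prescriptions at all: laboratory and measurement orders such as "BGA"
#' (blood gas analysis), "BE" (request to take a blood sample) or "BB"
#' (blood count). A small, configurable rule set identifies these before
#' any matching is attempted. Three rule kinds are supported:
#'
#' * `prefix`: the normalised text begins with the rule pattern as whole
#'   token(s);
#' * `exact`: the normalised text equals the normalised pattern;
#' * `regex`: the raw text matches the pattern as a regular expression.
#'
#' Rules are evaluated in listed order and the first match wins.
#' `default_exclusion_rules()` ships the three in-text order codes as
#' whole-token prefixes; real deployments extend it via a YAML config
#' ([read_exclusion_rules()]).
#'
#' @return A tibble with columns `rule_id`, `kind`, `pattern`,
#'   `description`.
#' @examples
#' default_exclusion_rules()
#' @export
default_exclusion_rules <- function() {
  tibble::tibble(
    rule_id = c("bga", "be", "bb"),
    kind = "prefix",
    pattern = c("BGA", "BE", "BB"),
    description = c("laboratory request for blood gas analysis",
                    "request to nurses for taking a blood sample",
                    "laboratory request for blood count")
  )
}

.validate_rules <- function(rules) {
  need <- c("rule_id", "kind", "pattern")
  if (!all(need %in% names(rules))) {
    abort("rules need columns rule_id, kind, pattern")
  }
  if (!all(rules$kind %in% c("prefix", "exact", "regex"))) {
    abort("rule kind must be one of prefix, exact, regex")
  }
  if (any(is.na(rules$pattern) | !nzchar(rules$pattern))) {
    abort("rule patterns must be non-empty")
  }
  for (p in rules$pattern[rules$kind == "regex"]) {
    ok <- tryCatch({grepl(p, ""); TRUE}, error = function(e) FALSE,
                   warning = function(w) FALSE)
    if (!ok) abort(sprintf("regex rule pattern does not compile: \"%s\"", p))
  }
  if (!"description" %in% names(rules)) rules$description <- ""
  rules
}

#' Read / write an exclusion-rule config (YAML)
#'
#' The YAML schema is a top-level `rules:` list whose elements have keys
#' `id`, `kind` (`prefix`/`exact`/`regex`), `pattern` and optional
#' `description`.
#'
#' @param path Path to a YAML file.
#' @return `read_exclusion_rules()` a rules tibble;
#'   `write_exclusion_rules()` returns `path` invisibly.
#' @export
read_exclusion_rules <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$rules)) abort("rule config must have a top-level `rules:` list")
  rules <- dplyr::bind_rows(lapply(y$rules, function(r) {
    tibble::tibble(rule_id = as.character(r$id %||% r$rule_id),
                   kind = as.character(r$kind),
                   pattern = as.character(r$pattern),
                   description = as.character(r$description %||% ""))
  }))
  .validate_rules(rules)
}

#' @rdname read_exclusion_rules
#' @param rules A rules tibble.
#' @export
write_exclusion_rules <- function(rules, path) {
  rules <- .validate_rules(rules)
  y <- list(rules = lapply(seq_len(nrow(rules)), function(i) {
    list(id = rules$rule_id[i], kind = rules$kind[i],
         pattern = rules$pattern[i], description = rules$description[i])
  }))
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify non-medication entries
#'
#' Applies the exclusion rules to a character vector of free texts and
#' returns, for each, the id of the first matching rule or `NA` when no
#' rule fires. `prefix` and `exact` rules act on the normalised text
#' ([normalize_text()]); `regex` rules act on the raw text.
#'
#' @param texts Character vector of medication free texts.
#' @param rules A rules tibble (default [default_exclusion_rules()]).
#' @return Character vector of rule ids (`NA` where no rule matched).
#' @examples
#' classify_non_medication(c("BGA", "Ibuprofen 600"))
#' @export
classify_non_medication <- function(texts, rules = default_exclusion_rules()) {
  out <- rep(NA_character_, length(texts))
  if (nrow(rules) == 0 || length(texts) == 0) return(out)
  rules <- .validate_rules(rules)
  norm <- normalize_text(texts)
  for (i in seq_len(nrow(rules))) {
    undecided <- is.na(out)
    if (!any(undecided)) break
    hit <- switch(
      rules$kind[i],
      prefix = {
        p <- normalize_text(rules$pattern[i])
        norm == p | startsWith(norm, paste0(p, " "))
      },
      exact = norm == normalize_text(rules$pattern[i]),
      regex = grepl(rules$pattern[i], texts)
    )
    out[undecided & hit] <- rules$rule_id[i]
  }
  out
}
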