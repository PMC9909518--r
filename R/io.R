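#' @keywords internal
#' Read a delimited file as UTF-8, falling back to Latin-1 when the bytes
#' are not valid UTF-8 (German exports often carry umlauts in Latin-1).
.read_delim_enc <- function(path, delim) {
  raw <- readBin(path, "raw", file.size(path))
  txt <- rawToChar(raw)
  enc <- if (validUTF8(txt)) "UTF-8" else "latin1"
  out <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = "c"),
    locale = readr::locale(encoding = enc), na = character(),
    progress = FALSE, show_col_types = FALSE)
  attr(out, "encoding") <- enc
  out
}

.require_columns <- function(df, cols, path) {
  missing <- setdiff(unname(unlist(cols)), names(df))
  if (length(missing)) {
    abort(sprintf("file \"%s\" is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "atcmapr_config_error")
  }
}

#' Accessor for rows quarantined by a reader
#'
#' Readers never silently drop malformed rows: rows failing validation are
#' kept in a rejects table (with a `reason` column) attached to the
#' returned tibble.
#'
#' @param x A tibble returned by [read_catalog()], [read_prescriptions()]
#'   or [import_validation_workbook()].
#' @return A tibble of rejected rows (zero rows when everything passed).
#' @export
rejects <- function(x) {
  r <- attr(x, "rejects")
  if (is.null(r)) tibble::tibble() else r
}

#' Read a drug product catalog (DS2)
#'
#' The catalog pairs product names and ingredient names with ATC level-5
#' codes, as exported from a hospital ERP system. Rows with an invalid or
#' non-level-5 ATC code, or an empty product name, are quarantined into
#' [rejects()] with a reason; exact duplicate rows are dropped once and
#' the count is reported. ATC codes are stored upper-cased.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter (default comma).
#' @param col_names Named list mapping the internal fields `product`,
#'   `ingredient`, `atc` to the file's header names. Defaults follow the
#'   DS2 schema: `Product_name`, `Ingredient_name`, `Atc_code`.
#' @param keep_legacy Logical; catalogs may contain legacy (discontinued)
#'   products. They are kept by default; set to `FALSE` to drop rows whose
#'   optional `Legacy` column is true.
#' @return A tibble of class `drug_catalog` with columns `product_name`,
#'   `ingredient_name`, `atc_code`, plus attributes `rejects`,
#'   `n_duplicates` and `encoding`.
#' @export
read_catalog <- function(path,
                         delim = ",",
                         col_names = list(product = "Product_name",
                                          ingredient = "Ingredient_name",
                                          atc = "Atc_code"),
                         keep_legacy = TRUE) {
  df <- .read_delim_enc(path, delim)
  .require_columns(df, col_names, path)
  out <- tibble::tibble(
    product_name = df[[col_names$product]],
    ingredient_name = df[[col_names$ingredient]],
    atc_code = toupper(df[[col_names$atc]])
  )
  if (!keep_legacy && "Legacy" %in% names(df)) {
    out <- out[!(toupper(df$Legacy) %in% c("TRUE", "1", "YES")), ]
  }
  n0 <- nrow(out)
  out <- dplyr::distinct(out)
  n_dup <- n0 - nrow(out)
  if (n_dup > 0) {
    message(sprintf("read_catalog: dropped %d exact duplicate row(s)", n_dup))
  }
  reason <- .atc_check(out$atc_code)
  not_l5 <- is.na(reason) & atc_level(out$atc_code) != 5L
  reason[not_l5] <- "ATC code is not level 5"
  empty_prod <- !nzchar(trimws(out$product_name))
  reason[is.na(reason) & empty_prod] <- "empty product name"
  bad <- !is.na(reason)
  rej <- dplyr::mutate(out[bad, ], reason = reason[bad])
  out <- out[!bad, ]
  class(out) <- c("drug_catalog", class(out))
  attr(out, "rejects") <- rej
  attr(out, "n_duplicates") <- n_dup
  attr(out, "encoding") <- attr(df, "encoding")
  out
}

#' Write a drug catalog with DS2 headers
#' @param x A `drug_catalog` tibble.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(x, path, delim = ",") {
  out <- tibble::tibble(Product_name = x$product_name,
                        Ingredient_name = x$ingredient_name,
                        Atc_code = x$atc_code)
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Read a prescription table (DS1)
#'
#' Each row is one drug prescription with a `MEDICATION` entry (free text
#' or a catalog pick), the prescription `YEAR`, a boolean `STRUCTURE` flag
#' and, for structured rows only, the ATC level-5 code. Rows violating the
#' schema invariant (structured without a valid level-5 code, or
#' unstructured with a code) are quarantined into [rejects()].
#'
#' @inheritParams read_catalog
#' @param col_names Named list mapping `medication`, `year`, `structure`,
#'   `atc` to the file's headers (defaults: `MEDICATION`, `YEAR`,
#'   `STRUCTURE`, `ATC_L5`).
#' @return A tibble with columns `medication`, `year` (integer),
#'   `structured` (logical), `atc_l5` (character, `NA` when unstructured),
#'   plus attributes `rejects` and `encoding`.
#' @export
read_prescriptions <- function(path,
                               delim = ",",
                               col_names = list(medication = "MEDICATION",
                                                year = "YEAR",
                                                structure = "STRUCTURE",
                                                atc = "ATC_L5")) {
  df <- .read_delim_enc(path, delim)
  .require_columns(df, col_names, path)
  atc_raw <- toupper(trimws(df[[col_names$atc]]))
  out <- tibble::tibble(
    medication = df[[col_names$medication]],
    year = suppressWarnings(as.integer(df[[col_names$year]])),
    structured = toupper(trimws(df[[col_names$structure]])) %in%
      c("TRUE", "T", "1", "YES"),
    atc_l5 = dplyr::if_else(nzchar(atc_raw), atc_raw, NA_character_)
  )
  reason <- rep(NA_character_, nrow(out))
  has_atc <- !is.na(out$atc_l5)
  atc_ok <- has_atc & is_valid_atc(out$atc_l5) & atc_level(out$atc_l5) == 5L
  reason[out$structured & !has_atc] <-
    "STRUCTURE is TRUE but ATC_L5 is empty"
  reason[out$structured & has_atc & !atc_ok] <-
    "STRUCTURE is TRUE but ATC_L5 is not a valid level-5 code"
  reason[!out$structured & has_atc] <-
    "STRUCTURE is FALSE but ATC_L5 is present"
  bad <- !is.na(reason)
  rej <- dplyr::mutate(out[bad, ], reason = reason[bad])
  out <- out[!bad, ]
  attr(out, "rejects") <- rej
  attr(out, "encoding") <- attr(df, "encoding")
  out
}

#' Write a prescription table with DS1 headers
#' @param x A prescriptions tibble (`medication`, `year`, `structured`,
#'   `atc_l5`).
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_prescriptions <- function(x, path, delim = ",") {
  out <- tibble::tibble(
    MEDICATION = x$medication,
    YEAR = x$year,
    STRUCTURE = ifelse(x$structured, "TRUE", "FALSE"),
    ATC_L5 = dplyr::coalesce(x$atc_l5, "")
  )
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

# serialize an alg3 candidate list to "ATC:score;ATC:score;..."
.format_step3 <- function(step3) {
  vapply(step3, function(cand) {
    if (is.null(cand) || nrow(cand) == 0) return("")
    paste(sprintf("%s:%d", cand$atc, cand$score), collapse = ";")
  }, character(1))
}

.parse_step3 <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(tibble::tibble(atc = character(), score = integer()))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    tibble::tibble(atc = vapply(parts, `[`, "", 1),
                   score = as.integer(vapply(parts, `[`, "", 2)))
  })
}

#' Write grouped free-text entries with algorithm results (DS3)
#'
#' @param x A grouped tibble as produced by [group_unstructured()] and the
#'   matchers (columns `medication`, `frequency`, optionally `step1`,
#'   `step2`, `step3` as a list column of candidate tibbles).
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_grouped <- function(x, path, delim = ",") {
  out <- tibble::tibble(
    MEDICATION = x$medication,
    FREQUENCY = x$frequency,
    Step1 = if ("step1" %in% names(x)) dplyr::coalesce(x$step1, "") else "",
    Step2 = if ("step2" %in% names(x)) dplyr::coalesce(x$step2, "") else "",
    Step3 = if ("step3" %in% names(x)) .format_step3(x$step3) else ""
  )
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Read a DS3 file back into a grouped tibble
#' @param path Path to a DS3 delimited file.
#' @param delim Field delimiter.
#' @return A tibble with columns `medication`, `frequency`, `step1`,
#'   `step2`, `step3` (list column), `step3_atc`, `step3_score`.
#' @export
read_grouped <- function(path, delim = ",") {
  df <- .read_delim_enc(path, delim)
  .require_columns(df, list("MEDICATION", "FREQUENCY"), path)
  step3 <- .parse_step3(if ("Step3" %in% names(df)) df$Step3 else
                          rep("", nrow(df)))
  blank_na <- function(x) dplyr::if_else(nzchar(x), x, NA_character_)
  tibble::tibble(
    medication = df$MEDICATION,
    frequency = as.integer(df$FREQUENCY),
    step1 = if ("Step1" %in% names(df)) blank_na(df$Step1) else NA_character_,
    step2 = if ("Step2" %in% names(df)) blank_na(df$Step2) else NA_character_,
    step3 = step3,
    step3_atc = vapply(step3, function(s)
      if (nrow(s)) s$atc[1] else NA_character_, character(1)),
    step3_score = vapply(step3, function(s)
      if (nrow(s)) s$score[1] else NA_integer_, integer(1))
  )
}
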