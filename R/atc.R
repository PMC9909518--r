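#' ATC code semantics
#'
#' The WHO Anatomical Therapeutic Chemical (ATC) classification arranges
#' drugs in a five-level hierarchy encoded as a positional string: one
#' letter for the anatomical main group (level 1), two digits (level 2),
#' one letter (level 3), one letter (level 4) and two digits identifying
#' the chemical substance (level 5). A code of level k is therefore 1, 3,
#' 4, 5 or 7 characters long, and the code of any ancestor level is a
#' string prefix.
#'
#' `parse_atc()` validates and upper-cases codes, `atc_level()` maps code
#' length to hierarchy level, `truncate_atc()` cuts a code down to an
#' ancestor level, and `is_valid_atc()` is the vectorised predicate behind
#' them.
#'
#' @param x Character vector of candidate ATC codes.
#' @param level Integer hierarchy level (1 to 5).
#' @return `parse_atc()` and `truncate_atc()` return a character vector of
#'   validated upper-case codes; `atc_level()` an integer vector;
#'   `is_valid_atc()` a logical vector.
#' @examples
#' parse_atc("n02bb02")
#' atc_level(c("N02BB02", "B05", "A"))
#' truncate_atc("B05BB11", 4)
#' @name atc
NULL

# code length for each hierarchy level
.atc_len <- c(1L, 3L, 4L, 5L, 7L)

# the 14 anatomical main groups
.atc_groups <- c("A", "B", "C", "D", "G", "H", "J", "L",
                 "M", "N", "P", "R", "S", "V")

.atc_check <- function(x) {
  # returns NA_character_ for valid codes, else a reason string
  x <- toupper(x)
  reason <- rep(NA_character_, length(x))
  miss <- is.na(x)
  len <- nchar(x)
  bad_len <- !miss & !(len %in% .atc_len)
  reason[bad_len] <- sprintf("invalid length %d (must be 1, 3, 4, 5 or 7)",
                             len[bad_len])
  ok <- !miss & is.na(reason)
  # per-position character classes, checked up to the code's length
  chk <- function(idx, pos, pattern, what) {
    sel <- idx & nchar(x) >= pos
    ch <- substr(x[sel], pos, pos)
    bad <- !grepl(pattern, ch)
    out <- rep(FALSE, length(x))
    out[which(sel)[bad]] <- TRUE
    reason[out] <<- sprintf("position %d must be %s (got \"%s\")",
                            pos, what, substr(x[out], pos, pos))
    invisible(NULL)
  }
  sel1 <- ok
  ch1 <- substr(x[sel1], 1, 1)
  bad1 <- !(ch1 %in% .atc_groups)
  bad1_idx <- which(sel1)[bad1]
  reason[bad1_idx] <- sprintf(
    "position 1 must be an anatomical main-group letter (got \"%s\")",
    substr(x[bad1_idx], 1, 1))
  ok <- !miss & is.na(reason)
  chk(ok, 2, "[0-9]", "a digit"); ok <- !miss & is.na(reason)
  chk(ok, 3, "[0-9]", "a digit"); ok <- !miss & is.na(reason)
  chk(ok, 4, "[A-Z]", "a letter"); ok <- !miss & is.na(reason)
  chk(ok, 5, "[A-Z]", "a letter"); ok <- !miss & is.na(reason)
  chk(ok, 6, "[0-9]", "a digit"); ok <- !miss & is.na(reason)
  chk(ok, 7, "[0-9]", "a digit")
  reason
}

#' @rdname atc
#' @export
is_valid_atc <- function(x) {
  !is.na(x) & is.na(.atc_check(x))
}

#' @rdname atc
#' @export
parse_atc <- function(x) {
  x_up <- toupper(x)
  reason <- .atc_check(x_up)
  bad <- !is.na(reason)
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("invalid ATC code \"%s\": %s", x[i], reason[i]),
          class = "atcmapr_invalid_atc")
  }
  x_up
}

#' @rdname atc
#' @export
atc_level <- function(x) {
  lvl <- match(nchar(x), .atc_len)
  lvl[is.na(x)] <- NA_integer_
  lvl
}

#' @rdname atc
#' @export
truncate_atc <- function(x, level) {
  stopifnot(length(level) == 1 || length(level) == length(x))
  if (any(level < 1 | level > 5, na.rm = TRUE)) {
    abort("`level` must be between 1 and 5")
  }
  x <- parse_atc(x)
  own <- atc_level(x)
  if (any(level > own, na.rm = TRUE)) {
    abort(sprintf(
      "cannot truncate \"%s\" (level %d) to level %d",
      x[which(level > own)[1]],
      own[which(level > own)[1]],
      if (length(level) == 1) level else level[which(level > own)[1]]))
  }
  substr(x, 1, .atc_len[level])
}
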