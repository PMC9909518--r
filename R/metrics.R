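#' Text normalisation and tokenisation
#'
#' Free-text prescriptions and catalog names are compared only after
#' normalisation: the string is lower-cased, every character that is not a
#' Unicode letter or digit (punctuation, pipes, parentheses, the percent
#' sign, underscores, ...) is replaced by a space, runs of whitespace are
#' collapsed and the result is trimmed. Tokens are the space-separated
#' pieces of the normalised string. Normalisation is idempotent.
#'
#' @param x Character vector.
#' @return `normalize_text()` a character vector; `tokenize_text()` a list
#'   of character vectors (zero-length for empty or all-punctuation input).
#' @examples
#' normalize_text("NaCl 0.9%")
#' tokenize_text("ARILIN 500 Filmtabletten | (Metronidazol)")
#' @name textnorm
NULL

#' @rdname textnorm
#' @export
normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[^\\p{L}\\p{N}]+", " ", x, perl = TRUE)
  trimws(x)
}

#' @rdname textnorm
#' @export
tokenize_text <- function(x) {
  out <- strsplit(normalize_text(x), " ", fixed = TRUE)
  lapply(out, function(t) t[nzchar(t)])
}

# byte-order token sort, locale-independent (matches the C++ side)
.sort_tokens <- function(tokens) sort(tokens, method = "radix")

#' Insertion/deletion edit distance
#'
#' Edit distance permitting only insertions and deletions (a substitution
#' costs 2). Equivalently `nchar(a) + nchar(b) - 2 * LCS(a, b)` where LCS
#' is the longest common subsequence. This is the distance underlying all
#' similarity ratios in the package. Vectorised with recycling; distances
#' count characters (codepoints), not bytes.
#'
#' @param a,b Character vectors (recycled to the common length).
#' @return Integer vector of distances.
#' @examples
#' indel_distance("abc", "abd")  # 2: one deletion + one insertion
#' @export
indel_distance <- function(a, b) {
  a <- enc2utf8(as.character(a))
  b <- enc2utf8(as.character(b))
  if (length(a) == 0 || length(b) == 0) return(integer(0))
  .indel_cpp(a, b)
}

#' Similarity ratios for drug-name matching
#'
#' Four similarity scores on the 0-100 scale, all built on the
#' insertion/deletion distance ([indel_distance()]):
#'
#' * `ratio_simple()`: `100 * (|a| + |b| - d(a, b)) / (|a| + |b|)`,
#'   rounded half away from zero; 100 when both strings are empty.
#' * `ratio_partial()`: the best `ratio_simple()` of the shorter string
#'   against same-length windows of the longer one, with candidate windows
#'   anchored at the start positions of longest-matching-block alignments.
#' * `ratio_token_sort()`: `ratio_simple()` after rebuilding each string
#'   from its alphabetically sorted tokens.
#' * `ratio_token_set()`: the two token sets are split into the sorted
#'   intersection `t0` and the remainders; the score is the maximum
#'   `ratio_simple()` among `(t0, t0+rest_a)`, `(t0, t0+rest_b)` and
#'   `(t0+rest_a, t0+rest_b)`. It is 100 whenever one token set is
#'   contained in the other, which is exactly the behaviour wanted for a
#'   free text whose words must all occur in a catalog name.
#'
#' The token-based ratios normalise their inputs first
#' ([normalize_text()]); `ratio_simple()` and `ratio_partial()` compare
#' the strings as given. All four are symmetric and vectorised with
#' recycling.
#'
#' @param a,b Character vectors (recycled to the common length).
#' @return Integer vector of scores in `[0, 100]`.
#' @examples
#' ratio_simple("stada paracetamol", "paracetamol stada 400 mg")     # 54
#' ratio_partial("stada paracetamol", "paracetamol stada 400 mg")    # 65
#' ratio_token_sort("stada paracetamol", "paracetamol stada 400 mg") # 83
#' ratio_token_set("Stada paracetamol", "paracetamol Stada 400 mg")  # 100
#' @name ratios
NULL

#' @rdname ratios
#' @export
ratio_simple <- function(a, b) {
  a <- enc2utf8(as.character(a))
  b <- enc2utf8(as.character(b))
  if (length(a) == 0 || length(b) == 0) return(integer(0))
  .ratio_cpp(a, b)
}

# Longest matching block between character vectors `ac[alo:ahi]` and
# `bc[blo:bhi]`: returns c(i, j, size) with 1-based starts, preferring
# smaller i then smaller j among equal-size blocks.
.longest_match <- function(ac, bc, alo, ahi, blo, bhi) {
  best <- c(alo, blo, 0L)
  if (alo > ahi || blo > bhi) return(best)
  bseg <- bc[blo:bhi]
  nb <- length(bseg)
  prev <- integer(nb)
  for (i in alo:ahi) {
    cur <- ifelse(ac[i] == bseg, c(0L, prev[-nb]) + 1L, 0L)
    mx <- max(cur)
    if (mx > best[3]) {
      jend <- which(cur == mx)[1]
      best <- c(i - mx + 1L, blo + jend - mx, as.integer(mx))
    }
    prev <- cur
  }
  best
}

# difflib-style non-overlapping matching blocks plus the zero-length
# terminal block at (la+1, lb+1).
.matching_blocks <- function(ac, bc) {
  blocks <- list()
  queue <- list(c(1L, length(ac), 1L, length(bc)))
  while (length(queue)) {
    r <- queue[[1]]
    queue <- queue[-1]
    m <- .longest_match(ac, bc, r[1], r[2], r[3], r[4])
    if (m[3] > 0) {
      blocks[[length(blocks) + 1]] <- m
      if (r[1] < m[1] && r[3] < m[2]) {
        queue[[length(queue) + 1]] <- c(r[1], m[1] - 1L, r[3], m[2] - 1L)
      }
      if (m[1] + m[3] <= r[2] && m[2] + m[3] <= r[4]) {
        queue[[length(queue) + 1]] <- c(m[1] + m[3], r[2], m[2] + m[3], r[4])
      }
    }
  }
  blocks[[length(blocks) + 1]] <- c(length(ac) + 1L, length(bc) + 1L, 0L)
  blocks
}

.partial_ratio_1 <- function(a, b) {
  if (is.na(a) || is.na(b)) return(NA_integer_)
  if (nchar(a) > nchar(b)) {
    tmp <- a; a <- b; b <- tmp
  }
  m <- nchar(a)
  n <- nchar(b)
  if (m == 0) return(if (n == 0) 100L else 0L)
  if (m == n) return(ratio_simple(a, b))
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  best <- 0L
  for (blk in .matching_blocks(ac, bc)) {
    start <- blk[2] - blk[1] + 1L      # align block start positions
    start <- max(1L, min(start, n - m + 1L))
    w <- substr(b, start, start + m - 1L)
    best <- max(best, ratio_simple(a, w))
    if (best == 100L) break
  }
  min(best, 100L)
}

#' @rdname ratios
#' @export
ratio_partial <- function(a, b) {
  a <- enc2utf8(as.character(a))
  b <- enc2utf8(as.character(b))
  if (length(a) == 0 || length(b) == 0) return(integer(0))
  n <- max(length(a), length(b))
  vapply(seq_len(n) - 1L,
         function(i) .partial_ratio_1(a[i %% length(a) + 1L],
                                      b[i %% length(b) + 1L]),
         integer(1))
}

#' @rdname ratios
#' @export
ratio_token_sort <- function(a, b) {
  rebuild <- function(x) {
    out <- vapply(tokenize_text(x),
                  function(t) paste(.sort_tokens(t), collapse = " "),
                  character(1))
    out[is.na(x)] <- NA_character_
    out
  }
  ratio_simple(rebuild(a), rebuild(b))
}

#' @rdname ratios
#' @export
ratio_token_set <- function(a, b) {
  ta <- tokenize_text(a)
  tb <- tokenize_text(b)
  if (length(ta) == 0 || length(tb) == 0) return(integer(0))
  n <- max(length(ta), length(tb))
  na_a <- is.na(a)
  na_b <- is.na(b)
  vapply(seq_len(n) - 1L, function(i) {
    ia <- i %% length(ta) + 1L
    ib <- i %% length(tb) + 1L
    if (na_a[ia] || na_b[ib]) return(NA_integer_)
    .token_set_pair_cpp(ta[[ia]], tb[[ib]])
  }, integer(1))
}

#' Score a string pair with all four ratios
#'
#' Convenience wrapper returning the simple, partial, token-sort and
#' token-set ratios of one or more string pairs as a tibble, in the layout
#' used for ad-hoc inspection of borderline matches.
#'
#' @param a,b Character vectors (recycled to the common length).
#' @return A tibble with columns `a`, `b`, `simple`, `partial`,
#'   `token_sort`, `token_set`.
#' @examples
#' score_pair("Stada paracetamol", "paracetamol Stada 400 mg")
#' @export
score_pair <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  tibble::tibble(
    a = a,
    b = b,
    simple = ratio_simple(tolower(a), tolower(b)),
    partial = ratio_partial(tolower(a), tolower(b)),
    token_sort = ratio_token_sort(a, b),
    token_set = ratio_token_set(a, b)
  )
}
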