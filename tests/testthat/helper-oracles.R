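# Independent oracles used across the suite.

withr_tempfile <- function() tempfile(fileext = ".csv")

# indel distance via base R's generalized edit distance with substitution
# cost 2 (a separate implementation from the package's LCS-based C++ core)
adist_indel <- function(a, b) {
  mapply(function(x, y) {
    as.integer(utils::adist(x, y, costs = list(ins = 1, del = 1, sub = 2)))
  }, a, b, USE.NAMES = FALSE)
}

# brute-force LCS by enumerating every subsequence of the shorter string
# and testing it against the longer one; only usable for tiny strings
brute_lcs <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (length(ca) > length(cb)) {
    tmp <- ca; ca <- cb; cb <- tmp
  }
  n <- length(ca)
  if (n == 0) return(0L)
  is_subseq <- function(s, t) {
    j <- 1
    for (ch in t) {
      if (j <= length(s) && s[j] == ch) j <- j + 1
    }
    j > length(s)
  }
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(idx) > best && is_subseq(ca[idx], cb)) {
      best <- length(idx)
    }
  }
  best
}

brute_indel <- function(a, b) {
  nchar(a) + nchar(b) - 2L * brute_lcs(a, b)
}

# random strings over a small alphabet
rand_strings <- function(n, max_len, alphabet = letters[1:6]) {
  vapply(seq_len(n), function(i) {
    len <- sample(0:max_len, 1)
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

# every string over `alphabet` with length 0..max_len
all_strings <- function(max_len, alphabet = c("a", "b", "c")) {
  out <- ""
  layer <- ""
  for (len in seq_len(max_len)) {
    layer <- as.vector(outer(layer, alphabet, paste0))
    out <- c(out, layer)
  }
  out
}

# hand-built six-entry catalog covering the phenomena the matchers face:
# plain ingredients, a combination product sharing an ingredient name,
# and umlaut-bearing product decorations
toy_catalog <- function() {
  tibble::tibble(
    product_name = c("IBUPROFEN STADA 600 mg Zäpfchen",
                     "PARACETAMOL HEXAL 500 mg Tabletten",
                     "ARILIN 500 Filmtabletten",
                     "TELMISARTAN PLUS comp 80 mg Tabletten",
                     "TELMISARTAN AL 80 mg Tabletten",
                     "NATRIUMCHLORID BRAUN 0.9% Infusionslösung"),
    ingredient_name = c("Ibuprofen", "Paracetamol", "Metronidazol",
                        "Telmisartan", "Telmisartan", "Natriumchlorid"),
    atc_code = c("M01AE01", "N02BE01", "P01AB01",
                 "C09DA07", "C09CA07", "B05BB11")
  )
}
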