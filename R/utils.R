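`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random DNA sequences with a given A+T content
#'
#' @param n number of sequences
#' @param len length (recycled)
#' @param at total A+T fraction (A and T equifrequent, as are C and G)
#' @return character vector of sequences
#' @export
random_dna <- function(n, len, at = 0.8) {
  len <- rep_len(len, n)
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  vapply(len, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
}

#' Reverse complement of DNA strings
#'
#' @param x character vector (ACGT alphabet)
#' @return character vector
#' @export
revcomp <- function(x) {
  stri_reverse(chartr("ACGTacgt", "TGCAtgca", x))
}

## fraction of A+T symbols per sequence
at_content <- function(x) {
  (stri_count_fixed(x, "A") + stri_count_fixed(x, "T")) / stri_length(x)
}

## deterministic integer sub-seed derived from a master seed and a tag,
## kept below 2^31; tags map to distinct seeds (polynomial rolling hash)
sub_seed <- function(seed, tag) {
  h <- 0
  for (code in utf8ToInt(as.character(tag))) h <- (h * 31 + code) %% 1000003
  as.integer(((as.integer(seed) %% 1009L) * 1000003 + h) %% 2147483647)
}
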