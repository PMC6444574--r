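# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "AANT"))
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Vectorised Hamming distance for equal-length string vectors (pairwise).
hamming_vec <- function(a, b) {
  mapply(function(x, y) sum(utf8ToInt(x) != utf8ToInt(y)), a, b, USE.NAMES = FALSE)
}

# Deterministic per-sample seed derived from a master seed; kept below 2^31.
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

# Draw n sequences of the given widths over {A,C,G,T}.
random_dna <- function(widths) {
  vapply(widths, function(w) {
    paste(sample(DNA_BASES, w, replace = TRUE), collapse = "")
  }, character(1))
}

# Stop with a formatted message.
abort_msg <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
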