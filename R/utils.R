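#' Sequence alphabet helpers
#'
#' Tags are stored internally in the DNA alphabet (`U` mapped to `T`); RNA
#' is used in user-facing reports and for folding. `revcomp()` is the DNA
#' reverse complement.
#'
#' @param x character vector of sequences.
#' @return character vector of the same length.
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' @rdname rna_to_dna
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname rna_to_dna
#' @export
revcomp <- function(x) {
  stri_reverse(chartr("ACGTacgt", "TGCAtgca", x))
}

#' @importFrom stringi stri_reverse
NULL

# derive a 32-bit sub-seed from the master seed, stream index k
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 7919 + k * 104729) %% 2147483647
}

# deterministic random DNA sequences (uses the current RNG stream)
random_dna <- function(n, lens) {
  if (n == 0) return(character(0))
  lens <- rep_len(lens, n)
  all <- sample(c("A", "C", "G", "T"), sum(lens), replace = TRUE)
  ends <- cumsum(lens)
  starts <- c(1, head(ends, -1) + 1)
  big <- paste(all, collapse = "")
  stringi::stri_sub(big, starts, ends)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
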