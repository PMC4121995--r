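#' Minimum-free-energy folding of a single RNA sequence
#'
#' Computes the minimum-energy pseudoknot-free secondary structure of an
#' RNA sequence under the bundled nearest-neighbour model (Watson-Crick
#' plus G:U wobble pairs, stacking energies, linear hairpin/bulge/interior
#' loop penalties, a linear multibranch-loop term, minimum hairpin loop of
#' 3 nt). Ties are broken toward fewer base pairs, then by a fixed
#' deterministic traceback order, so results are platform independent.
#'
#' This is the stability filter behind novel miRNA precursor calling: a
#' candidate hairpin must fold below -20 kcal/mol to count as stable.
#'
#' @param sequence a single RNA (or DNA; `T` is read as `U`) string,
#'   10-300 nt, alphabet ACGU.
#' @return an object of class `fold_result`: a list with `sequence` (RNA),
#'   `structure` (dot-bracket string of the same length), `mfe` (kcal/mol,
#'   <= 0; 0 with an all-dot structure when no pair is possible) and
#'   `npairs`.
#' @examples
#' fold_mfe(paste0(strrep("G", 10), "AAAA", strrep("C", 10)))
#' @export
fold_mfe <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  rna <- toupper(dna_to_rna(sequence))
  n <- nchar(rna)
  if (n < 10 || n > 300) {
    stop("sequence length must be within [10, 300], got ", n)
  }
  par <- energy_params()
  res <- c_fold_mfe(encode_rna(rna), stack_deci(par), par$loop)
  structure(list(sequence = rna, structure = res$structure,
                 mfe = res$mfe, npairs = res$npairs),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "\n",
      sprintf("MFE %.1f kcal/mol, %d pairs\n", x$mfe, x$npairs), sep = "")
  invisible(x)
}

# partner array (1-based; NA = unpaired) from a dot-bracket string
pair_table <- function(structure) {
  v <- strsplit(structure, "", fixed = TRUE)[[1]]
  partner <- rep(NA_integer_, length(v))
  stack <- integer(0)
  for (i in seq_along(v)) {
    if (v[i] == "(") {
      stack <- c(stack, i)
    } else if (v[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  partner
}
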