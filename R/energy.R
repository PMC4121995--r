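#' Nearest-neighbour energy parameters
#'
#' The folding and duplex modules share one simplified nearest-neighbour
#' parameter set: a 6x6 stacking table over the pairs AU, CG, GC, GU, UA,
#' UG (orientation: the row pair is closer to the 5' end of the strand
#' carrying its first base) and linear loop penalties. The table ships as
#' plain data under `inst/extdata/` so the parameter set can be audited or
#' swapped without touching code. All values are kcal/mol.
#'
#' @return a list with elements `stack` (6x6 numeric matrix, kcal/mol,
#'   dimnames are the pair labels) and `loop` (named list of loop-penalty
#'   coefficients plus the interior-loop size bound `max_loop` and the
#'   minimum hairpin loop `min_hairpin`).
#' @export
energy_params <- function() {
  if (!is.null(.srna_env$energy)) return(.srna_env$energy)
  pairs <- c("AU", "CG", "GC", "GU", "UA", "UG")
  st <- read.delim(system.file("extdata", "stack_energies.tsv",
                               package = "srnapipe"),
                   stringsAsFactors = FALSE)
  m <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  m[cbind(st$pair5, st$pair3)] <- st$dG
  if (anyNA(m)) stop("stack energy table is incomplete")
  lp <- read.delim(system.file("extdata", "loop_params.tsv",
                               package = "srnapipe"),
                   stringsAsFactors = FALSE)
  loop <- as.list(setNames(lp$value, lp$param))
  out <- list(stack = m, loop = loop)
  .srna_env$energy <- out
  out
}

# integer decikcal stack matrix for the C++ kernels
stack_deci <- function(par = energy_params()) {
  matrix(as.integer(round(par$stack * 10)), 6, 6,
         dimnames = dimnames(par$stack))
}

# encode an RNA string as integer codes A=0 C=1 G=2 U=3 (0-based for C++)
encode_rna <- function(sequence) {
  v <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  code <- match(v, c("A", "C", "G", "U")) - 1L
  if (anyNA(code)) {
    bad <- unique(v[is.na(code)])
    stop("invalid RNA alphabet character(s): ", paste(bad, collapse = ", "))
  }
  code
}
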