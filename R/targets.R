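#' miRNA:target duplex minimum free energy
#'
#' Intermolecular hybridisation energy of a miRNA against a target
#' window under the shared nearest-neighbour table: antiparallel pairing
#' only (no intramolecular structure), Watson-Crick plus G:U, stacking
#' between consecutive pairs, bulge/interior penalties for gaps bounded
#' by `max_gap` unpaired nt per side, free helix ends. The reported
#' energy is the global minimum over all alignments and target start
#' positions; ties prefer the leftmost target site. A duplex with no
#' stabilising stack (energy >= 0) is reported as a no-hit.
#'
#' @param mirna miRNA sequence (RNA or DNA), 15-30 nt.
#' @param target_window target sequence, at least as long as the miRNA.
#' @param max_gap maximum unpaired stretch per side inside the duplex,
#'   default 15.
#' @return list with `energy` (kcal/mol), `npairs`, `target_start` /
#'   `target_end` (0-based half-open on the target), `mirna_start` /
#'   `mirna_end`, and `no_hit` (TRUE when nothing stabilising exists).
#' @export
duplex_mfe <- function(mirna, target_window, max_gap = 15) {
  mr <- toupper(dna_to_rna(mirna))
  tw <- toupper(dna_to_rna(target_window))
  if (nchar(mr) < 15 || nchar(mr) > 30) {
    stop("miRNA length must be within [15, 30]")
  }
  if (nchar(tw) < nchar(mr)) {
    stop("target window shorter than the miRNA")
  }
  par <- energy_params()
  res <- c_duplex_mfe(encode_rna(mr), encode_rna(tw), stack_deci(par),
                      par$loop, as.integer(max_gap))
  res$no_hit <- res$npairs == 0L || res$energy >= 0
  res
}

# unbounded-length variant used internally by tests/oracles
duplex_mfe_raw <- function(mirna, target_window, max_gap = 15) {
  par <- energy_params()
  res <- c_duplex_mfe(encode_rna(toupper(dna_to_rna(mirna))),
                      encode_rna(toupper(dna_to_rna(target_window))),
                      stack_deci(par), par$loop, as.integer(max_gap))
  res$no_hit <- res$npairs == 0L || res$energy >= 0
  res
}

#' Extreme-value p-value for a duplex energy
#'
#' Significance of a best-over-positions duplex energy via an extreme
#' value distribution whose location and scale grow with the log target
#' length. The normalised score is `s = -energy / log10(mirna_len *
#' target_len)`; then `p = 1 - exp(-exp(-(s - loc)/scale))` with `loc =
#' location_slope * log10(target_len)` and `scale = scale_slope *
#' log10(target_len)`. The default slopes are 1.9 and 0.28; base-10
#' logarithms are used because under natural logarithms these slopes
#' would make every attainable energy insignificant.
#'
#' @param energy duplex energy in kcal/mol (<= 0).
#' @param mirna_len,target_len sequence lengths (> 1).
#' @param location_slope,scale_slope EVD growth parameters.
#' @return p-value in (0, 1).
#' @export
evd_pvalue <- function(energy, mirna_len, target_len,
                       location_slope = 1.9, scale_slope = 0.28) {
  if (any(mirna_len <= 1) || any(target_len <= 1)) {
    stop("lengths must exceed 1")
  }
  stopifnot(scale_slope > 0, all(energy <= 0))
  s <- -energy / log10(mirna_len * target_len)
  loc <- location_slope * log10(target_len)
  sc <- scale_slope * log10(target_len)
  p <- 1 - exp(-exp(-(s - loc) / sc))
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
}

#' Scan miRNAs against target sequences
#'
#' Computes the best duplex per (miRNA, gene) pair over the supplied
#' target sequences (typically 3' UTRs) and attaches EVD p-values. Only
#' the single best-energy site per pair is kept.
#'
#' @param matures named character vector or `DNAStringSet` of mature
#'   miRNA sequences.
#' @param targets named character vector or `DNAStringSet` of target
#'   sequences (gene ids as names).
#' @param location_slope,scale_slope EVD parameters (see
#'   [evd_pvalue()]).
#' @param max_p keep hits with p <= `max_p` (set to 1 to keep all),
#'   default 0.05.
#' @param max_energy optional energy ceiling (kcal/mol); when given,
#'   hits must also have energy <= `max_energy`.
#' @return data.frame: mirna_id, gene_id, position (0-based), energy,
#'   pvalue.
#' @export
predict_targets <- function(matures, targets, location_slope = 1.9,
                            scale_slope = 0.28, max_p = 0.05,
                            max_energy = NULL) {
  if (inherits(matures, "DNAStringSet")) {
    matures <- setNames(as.character(matures), names(matures))
  }
  if (inherits(targets, "DNAStringSet")) {
    targets <- setNames(as.character(targets), names(targets))
  }
  rows <- list()
  k <- 0L
  for (mi in names(matures)) {
    for (gi in names(targets)) {
      d <- duplex_mfe(matures[[mi]], targets[[gi]])
      if (d$no_hit) next
      p <- evd_pvalue(d$energy, nchar(matures[[mi]]),
                      nchar(targets[[gi]]), location_slope, scale_slope)
      if (p > max_p) next
      if (!is.null(max_energy) && d$energy > max_energy) next
      k <- k + 1L
      rows[[k]] <- data.frame(mirna_id = mi, gene_id = gi,
                              position = d$target_start,
                              energy = d$energy, pvalue = p,
                              stringsAsFactors = FALSE)
    }
  }
  if (!k) {
    return(data.frame(mirna_id = character(0), gene_id = character(0),
                      position = integer(0), energy = numeric(0),
                      pvalue = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Aggregate duplex hits over the DE groups
#'
#' Counts, per gene, the distinct up- and downregulated miRNAs with at
#' least one duplex hit; a gene is kept when mediated by strictly more
#' than `min_mirnas` miRNAs of either group. Each (miRNA, gene) pair is
#' counted once regardless of the number of sites.
#'
#' @param hits data.frame with `mirna_id`, `gene_id` (from
#'   [predict_targets()]).
#' @param de_status data.frame with `mirna_id`, `status` (up/down/ns).
#' @param min_mirnas strict threshold, default 3 ("more than 3").
#' @return data.frame: gene_id, n_up_mirnas, n_down_mirnas, kept;
#'   ordered by max(n_up, n_down) descending then gene_id.
#' @export
aggregate_targets <- function(hits, de_status, min_mirnas = 3) {
  miss <- setdiff(unique(hits$mirna_id), de_status$mirna_id)
  if (length(miss)) {
    stop("hits reference miRNAs without a DE status: ",
         paste(miss, collapse = ", "))
  }
  uh <- unique(hits[, c("mirna_id", "gene_id")])
  uh$status <- de_status$status[match(uh$mirna_id, de_status$mirna_id)]
  genes <- sort(unique(uh$gene_id))
  n_up <- vapply(genes, function(g) {
    length(unique(uh$mirna_id[uh$gene_id == g & uh$status == "up"]))
  }, integer(1))
  n_down <- vapply(genes, function(g) {
    length(unique(uh$mirna_id[uh$gene_id == g & uh$status == "down"]))
  }, integer(1))
  out <- data.frame(gene_id = genes, n_up_mirnas = n_up,
                    n_down_mirnas = n_down,
                    kept = n_up > min_mirnas | n_down > min_mirnas,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-pmax(out$n_up_mirnas, out$n_down_mirnas), out$gene_id), ,
      drop = FALSE]
}
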