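#' Excise candidate precursor windows around unannotated tags
#'
#' For every genome hit of an unannotated tag, a window of the tag plus
#' `flank` nt on each side is cut out of the genome (clipped at
#' chromosome ends). Minus-strand hits are reverse complemented so every
#' window reads in the sense orientation of the putative precursor, with
#' the tag at a recorded 0-based offset.
#'
#' @param hits data.frame of genome hits (tag, chrom, start, end, strand)
#'   restricted to unannotated tags.
#' @param genome named `DNAStringSet` or FASTA path.
#' @param flank flank size in nt, default 70.
#' @return data.frame: window_id, tag, chrom, start, end, strand,
#'   offset (0-based tag offset inside the oriented window), precursor
#'   (window sequence, DNA).
#' @export
excise_windows <- function(hits, genome, flank = 70) {
  genome <- as_dss(genome)
  if (!nrow(hits)) {
    return(data.frame(window_id = character(0), tag = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      offset = integer(0), precursor = character(0),
                      stringsAsFactors = FALSE))
  }
  clen <- setNames(Biostrings::width(genome), names(genome))
  ws <- pmax(0L, hits$start - as.integer(flank))
  we <- pmin(clen[hits$chrom], hits$end + as.integer(flank))
  seqs <- character(nrow(hits))
  for (chrom in unique(hits$chrom)) {
    i <- which(hits$chrom == chrom)
    cs <- as.character(genome[[chrom]])
    seqs[i] <- substr(rep.int(cs, length(i)), ws[i] + 1L, we[i])
  }
  minus <- hits$strand == "-"
  seqs[minus] <- revcomp(seqs[minus])
  offset <- ifelse(minus, we - hits$end, hits$start - ws)
  data.frame(window_id = sprintf("win_%04d", seq_len(nrow(hits))),
             tag = hits$tag, chrom = hits$chrom,
             start = as.integer(ws), end = as.integer(we),
             strand = hits$strand, offset = as.integer(offset),
             precursor = seqs, stringsAsFactors = FALSE)
}

# arm-placement test for a mature tag inside a folded window.
# Requirements: no tag base inside a terminal (hairpin) loop; the
# partners of the tag's paired bases all lie outside the tag on one side
# (the other arm); and >= min_paired_frac of tag bases are paired.
arm_placement <- function(structure, offset, tag_len,
                          min_paired_frac = 0.75) {
  partner <- pair_table(structure)
  span <- seq.int(offset + 1L, offset + tag_len)
  if (max(span) > length(partner)) return(list(pass = FALSE, arm = NA))
  p <- partner[span]
  paired <- !is.na(p)
  if (sum(paired) / tag_len < min_paired_frac) {
    return(list(pass = FALSE, arm = NA))
  }
  # hairpin loops: maximal unpaired runs whose flanking bases pair with
  # each other
  unp <- which(is.na(partner))
  if (length(unp)) {
    runs <- split(unp, cumsum(c(1L, diff(unp) != 1L)))
    for (r in runs) {
      u <- r[1] - 1L
      v <- r[length(r)] + 1L
      if (u >= 1L && v <= length(partner) && !is.na(partner[u]) &&
          partner[u] == v && any(r %in% span)) {
        return(list(pass = FALSE, arm = NA))
      }
    }
  }
  pp <- p[paired]
  if (all(pp > max(span))) return(list(pass = TRUE, arm = "5p"))
  if (all(pp < min(span))) return(list(pass = TRUE, arm = "3p"))
  list(pass = FALSE, arm = NA)
}

#' Call novel miRNA candidates from excised windows
#'
#' Applies the three gates of novel miRNA discovery: a stable hairpin
#' (MFE strictly below `mfe_max`, default -20 kcal/mol), a Dicer-like arm
#' placement (the tag sits entirely on one arm of the stem, outside any
#' terminal loop, with at least 75% of its bases paired) and detectable
#' expression in both libraries (TPM of the tag >= `tpm_min`, default 1,
#' in each). Overlapping passing windows on the same strand are collapsed
#' to the lowest-MFE one.
#'
#' @param windows data.frame from [excise_windows()].
#' @param lib_control,lib_knockdown the two `tag_library` objects (used
#'   for the tag TPMs).
#' @param mfe_max MFE gate (kcal/mol), strict `<`, default -20.
#' @param tpm_min expression floor in TPM for each library, default 1.
#' @param min_paired_frac arm-placement pairing fraction, default 0.75.
#' @param folds optional pre-computed list of [fold_mfe()] results, one
#'   per window row.
#' @return list with `candidates` (passing windows with structure, MFE,
#'   arm, TPMs) and `rejections` (per failed window, the flag values).
#' @export
call_novel <- function(windows, lib_control, lib_knockdown,
                       mfe_max = -20, tpm_min = 1,
                       min_paired_frac = 0.75, folds = NULL) {
  n <- nrow(windows)
  if (is.null(folds)) {
    folds <- lapply(windows$precursor, fold_mfe)
  }
  stopifnot(length(folds) == n)
  getc <- function(lib, tag) {
    v <- lib$tags[tag]
    ifelse(is.na(v), 0L, v)
  }
  tpm_c <- tpm(getc(lib_control, windows$tag), lib_control$total_clean)
  tpm_k <- tpm(getc(lib_knockdown, windows$tag),
               lib_knockdown$total_clean)
  mfe <- vapply(folds, `[[`, numeric(1), "mfe")
  structure_db <- vapply(folds, `[[`, character(1), "structure")

  mfe_pass <- mfe < mfe_max
  expression_pass <- pmin(tpm_c, tpm_k) >= tpm_min
  arm <- rep.int(NA_character_, n)
  arm_pass <- logical(n)
  for (i in seq_len(n)) {
    ap <- arm_placement(structure_db[i], windows$offset[i],
                        nchar(windows$tag[i]), min_paired_frac)
    arm_pass[i] <- ap$pass
    if (ap$pass) arm[i] <- ap$arm
  }
  pass <- mfe_pass & arm_pass & expression_pass

  cand <- cbind(windows[pass, , drop = FALSE],
                data.frame(structure = structure_db[pass],
                           mfe = mfe[pass], arm = arm[pass],
                           tpm_control = tpm_c[pass],
                           tpm_knockdown = tpm_k[pass],
                           stringsAsFactors = FALSE))
  # collapse overlapping loci (same chrom, either strand: a hairpin and
  # its reverse complement describe the same locus) to the lowest MFE
  if (nrow(cand) > 1) {
    cand <- cand[order(cand$chrom, cand$start), ]
    keep <- rep.int(TRUE, nrow(cand))
    grp_end <- -1L
    grp_best <- NA_integer_
    grp_key <- ""
    for (i in seq_len(nrow(cand))) {
      key <- cand$chrom[i]
      if (key == grp_key && cand$start[i] < grp_end) {
        if (cand$mfe[i] < cand$mfe[grp_best]) {
          keep[grp_best] <- FALSE
          grp_best <- i
        } else {
          keep[i] <- FALSE
        }
        grp_end <- max(grp_end, cand$end[i])
      } else {
        grp_key <- key
        grp_end <- cand$end[i]
        grp_best <- i
      }
    }
    cand <- cand[keep, , drop = FALSE]
  }
  rownames(cand) <- NULL
  rej <- data.frame(window_id = windows$window_id[!pass],
                    tag = windows$tag[!pass],
                    mfe = mfe[!pass],
                    mfe_pass = mfe_pass[!pass],
                    arm_pass = arm_pass[!pass],
                    expression_pass = expression_pass[!pass],
                    stringsAsFactors = FALSE)
  list(candidates = cand, rejections = rej)
}
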