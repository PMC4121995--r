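#' Map tags to a reference genome
#'
#' Finds all occurrences of every tag on both strands of the genome
#' (minus-strand occurrences via the reverse complement, reported in plus
#' strand coordinates). With `max_mismatch = 0` matching is exact
#' substring search; with a small mismatch budget `Biostrings` inexact
#' matching is used. Coordinates are 0-based half-open.
#'
#' @param lib a `tag_library`.
#' @param genome named `DNAStringSet` or path to a genome FASTA.
#' @param max_mismatch integer 0-2, default 0.
#' @return list with `hits` (data.frame: tag, chrom, start, end, strand),
#'   `frac_unique` and `frac_total` (mapped fractions of unique and
#'   count-weighted tags).
#' @export
map_tags <- function(lib, genome, max_mismatch = 0) {
  stopifnot(max_mismatch >= 0, max_mismatch <= 2)
  genome <- as_dss(genome)
  tags <- names(lib$tags)
  if (!length(tags)) {
    return(list(hits = empty_hits(), frac_unique = 0, frac_total = 0))
  }
  res <- vector("list", 2L * length(genome))
  k <- 0L
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci]
    cs <- as.character(genome[[ci]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") tags else revcomp(tags)
      loc <- if (max_mismatch == 0) {
        stringi::stri_locate_all_fixed(
          cs, pat, overlap = TRUE, omit_no_match = TRUE)
      } else {
        lapply(pat, function(p) {
          m <- Biostrings::matchPattern(p, genome[[ci]],
                                        max.mismatch = max_mismatch)
          cbind(Biostrings::start(m), Biostrings::end(m))
        })
      }
      nhit <- vapply(loc, nrow, integer(1))
      if (sum(nhit) == 0) next
      starts <- unlist(lapply(loc, function(m) m[, 1]), use.names = FALSE)
      ends <- unlist(lapply(loc, function(m) m[, 2]), use.names = FALSE)
      k <- k + 1L
      res[[k]] <- data.frame(
        tag = rep.int(tags, nhit), chrom = chrom,
        start = as.integer(starts) - 1L, end = as.integer(ends),
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  hits <- if (k) do.call(rbind, res[seq_len(k)]) else empty_hits()
  mapped <- unique(hits$tag)
  list(hits = hits,
       frac_unique = length(mapped) / lib$n_unique,
       frac_total = sum(lib$tags[mapped]) / lib$total_clean)
}

empty_hits <- function() {
  data.frame(tag = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             stringsAsFactors = FALSE)
}

as_dss <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  Biostrings::readDNAStringSet(x)
}

# category precedence; ncRNA classes form one block ranked by source
# (genbank beats rfam) and then by class order
.ncrna_classes <- c("rRNA", "scRNA", "snRNA", "snoRNA", "tRNA")

#' Priority-rule annotation of tags
#'
#' Resolves every tag to exactly one category using the fixed precedence
#' ncRNA-block (within it, a GenBank-sourced match outranks an Rfam one)
#' > known miRNA > repeat > exon > intron > unannotated. ncRNA and miRNA
#' assignment is by exact substring match against the reference
#' sequences; repeat/exon/intron assignment is by genome-hit overlap with
#' the annotated intervals, with exon/intron split into sense/antisense
#' by strand agreement (sense wins if any same-strand overlap exists).
#'
#' @param lib a `tag_library`.
#' @param refs a reference bundle (see [load_references()]).
#' @param hits genome hits data.frame from [map_tags()].
#' @return list with `annotated` (data.frame: tag, count, category,
#'   source) and `summary` (data.frame: category, unique, total; the
#'   counts partition the library).
#' @export
annotate_tags <- function(lib, refs, hits) {
  tags <- names(lib$tags)
  n <- length(tags)
  category <- rep.int("unannotated", n)
  source <- rep.int("none", n)

  if (!all(refs$ncrna_info$class %in% .ncrna_classes)) {
    bad <- setdiff(unique(refs$ncrna_info$class), .ncrna_classes)
    stop("unknown ncRNA class label(s): ", paste(bad, collapse = ", "))
  }
  if (!all(refs$ncrna_info$source %in% c("genbank", "rfam"))) {
    stop("ncRNA source labels must be 'genbank' or 'rfam'")
  }

  # ncRNA block: rank = source first, then class order
  nc_rank <- rep.int(Inf, n)
  nc_class <- rep.int(NA_character_, n)
  nc_source <- rep.int(NA_character_, n)
  if (length(refs$ncrna)) {
    ord <- order(match(refs$ncrna_info$source, c("genbank", "rfam")),
                 match(refs$ncrna_info$class, .ncrna_classes))
    for (j in ord) {
      rank_j <- match(refs$ncrna_info$source[j], c("genbank", "rfam")) * 10 +
        match(refs$ncrna_info$class[j], .ncrna_classes)
      seq_j <- as.character(refs$ncrna[[j]])
      m <- stringi::stri_detect_fixed(seq_j, tags)
      upd <- m & rank_j < nc_rank
      nc_rank[upd] <- rank_j
      nc_class[upd] <- refs$ncrna_info$class[j]
      nc_source[upd] <- refs$ncrna_info$source[j]
    }
  }
  is_nc <- is.finite(nc_rank)
  category[is_nc] <- nc_class[is_nc]
  source[is_nc] <- nc_source[is_nc]

  # known miRNA: substring of a precursor or equal to a mature sequence
  is_mir <- rep.int(FALSE, n)
  for (j in seq_along(refs$precursors)) {
    is_mir <- is_mir |
      stringi::stri_detect_fixed(as.character(refs$precursors[[j]]), tags)
  }
  is_mir <- is_mir | tags %in% as.character(refs$matures)
  upd <- is_mir & !is_nc
  category[upd] <- "known_miRNA"
  source[upd] <- "mirbase"

  # interval categories via genome hits
  open <- !(is_nc | is_mir)
  if (nrow(hits) && length(refs$features) && any(open)) {
    h <- hits[hits$tag %in% tags[open], , drop = FALSE]
    if (nrow(h)) {
      hgr <- GenomicRanges::GRanges(
        h$chrom, IRanges::IRanges(h$start + 1L, h$end), strand = h$strand)
      ov <- GenomicRanges::findOverlaps(hgr, refs$features,
                                        ignore.strand = TRUE)
      if (length(ov)) {
        qi <- S4Vectors::queryHits(ov)
        si <- S4Vectors::subjectHits(ov)
        ftype <- refs$features$type[si]
        sense <- as.character(GenomicRanges::strand(refs$features))[si] ==
          h$strand[qi]
        df <- data.frame(tag = h$tag[qi], type = ftype, sense = sense,
                         stringsAsFactors = FALSE)
        for (ty in c("repeat", "exon", "intron")) {
          sub <- df[df$type == ty, , drop = FALSE]
          if (!nrow(sub)) next
          idx <- match(unique(sub$tag), tags)
          idx <- idx[open[idx]]
          if (!length(idx)) next
          if (ty == "repeat") {
            category[idx] <- "repeat"
          } else {
            has_sense <- tapply(sub$sense, sub$tag, any)
            category[idx] <- paste0(
              ty, ifelse(has_sense[tags[idx]], "_sense", "_antisense"))
          }
          source[idx] <- "interval"
          open[idx] <- FALSE
        }
      }
    }
  }

  annotated <- data.frame(tag = tags, count = as.integer(lib$tags),
                          category = category, source = source,
                          stringsAsFactors = FALSE)
  levels <- c(.ncrna_classes, "known_miRNA", "repeat", "exon_sense",
              "exon_antisense", "intron_sense", "intron_antisense",
              "unannotated")
  f <- factor(category, levels = levels)
  summary <- data.frame(
    category = levels,
    unique = as.integer(table(f)),
    total = as.integer(tapply(annotated$count, f, sum, default = 0L)),
    stringsAsFactors = FALSE)
  list(annotated = annotated, summary = summary)
}

#' rRNA quality-control mark
#'
#' A library passes when strictly less than 40% of its total clean tags
#' are rRNA.
#'
#' @param summary category summary from [annotate_tags()].
#' @param threshold strict upper bound on the rRNA total fraction (0.40).
#' @return list with `verdict` ("PASS"/"FAIL") and `ratio`.
#' @export
rrna_qc <- function(summary, threshold = 0.40) {
  total <- sum(summary$total)
  if (!isTRUE(total > 0)) stop("empty category summary")
  ratio <- summary$total[summary$category == "rRNA"] / total
  list(verdict = if (ratio < threshold) "PASS" else "FAIL", ratio = ratio)
}

#' Quantify known miRNAs from a tag library
#'
#' A tag counts toward a mature miRNA when it equals the mature sequence
#' exactly or lies within the precursor and overlaps the mature span by at
#' least `min_overlap` nt. Tags matching only the precursor loop or star
#' region count toward the precursor but not the mature. A miRNA is
#' "detected" when its mature count is >= 1; arm tallies count detected
#' names suffixed -5p / -3p.
#'
#' @param lib a `tag_library`.
#' @param refs reference bundle, or a list with elements `precursors`,
#'   `matures` (named `DNAStringSet`s) and `mature_info` (data.frame with
#'   mature_id, precursor_id).
#' @param min_overlap minimum tag/mature overlap in nt, default 16.
#' @return list with `mirna` (data.frame: mirna_id, precursor_id, count),
#'   `precursor` (data.frame: precursor_id, count), `arms` (named vector
#'   n_5p, n_3p over detected miRNAs) and `detected` (character vector).
#' @export
quantify_known_mirna <- function(lib, refs, min_overlap = 16) {
  pre <- refs$precursors
  mat <- refs$matures
  info <- refs$mature_info
  stopifnot(all(info$mature_id %in% names(mat)),
            all(info$precursor_id %in% names(pre)))
  tags <- names(lib$tags)
  counts <- lib$tags

  mir_count <- setNames(integer(nrow(info)), info$mature_id)
  pre_count <- setNames(integer(length(pre)), names(pre))

  for (j in seq_len(nrow(info))) {
    pid <- info$precursor_id[j]
    pseq <- as.character(pre[[pid]])
    mseq <- as.character(mat[[info$mature_id[j]]])
    mpos <- stringi::stri_locate_first_fixed(pseq, mseq)
    if (is.na(mpos[1])) {
      stop("mature ", info$mature_id[j],
           " is not a substring of its precursor ", pid)
    }
    if (!length(tags)) next
    loc <- stringi::stri_locate_all_fixed(pseq, tags, overlap = TRUE,
                                          omit_no_match = TRUE)
    nhit <- vapply(loc, nrow, integer(1))
    inpre <- nhit > 0
    if (!any(inpre)) next
    # best overlap of any occurrence with the mature span
    best_ov <- vapply(which(inpre), function(i) {
      m <- loc[[i]]
      max(pmin(m[, 2], mpos[2]) - pmax(m[, 1], mpos[1]) + 1L)
    }, integer(1))
    ok <- tags[which(inpre)][best_ov >= min_overlap]
    mir_count[j] <- mir_count[j] + sum(counts[ok])
  }
  for (pid in names(pre)) {
    if (!length(tags)) next
    hit <- stringi::stri_detect_fixed(as.character(pre[[pid]]), tags)
    pre_count[pid] <- sum(counts[hit])
  }
  detected <- names(mir_count)[mir_count >= 1]
  arms <- c(n_5p = sum(grepl("-5p$", detected)),
            n_3p = sum(grepl("-3p$", detected)))
  list(mirna = data.frame(mirna_id = info$mature_id,
                          precursor_id = info$precursor_id,
                          count = as.integer(mir_count),
                          stringsAsFactors = FALSE),
       precursor = data.frame(precursor_id = names(pre_count),
                              count = as.integer(pre_count),
                              stringsAsFactors = FALSE),
       arms = arms, detected = detected)
}

#' Chromosome and strand distribution of mapped tags
#'
#' Multi-hit tags contribute once per hit in this report (a documented
#' divergence from the one-category-per-tag annotation). When the
#' annotation result is supplied, exon sense:antisense unique/total
#' counts and their ratio are included.
#'
#' @param hits genome hits from [map_tags()].
#' @param lib the `tag_library` the hits came from.
#' @param annotated optional `annotated` data.frame from [annotate_tags()].
#' @return list with `by_chrom` (data.frame: chrom, strand, unique,
#'   total) and, if `annotated` is given, `exon_ratio`.
#' @export
chrom_distribution <- function(hits, lib, annotated = NULL) {
  if (!nrow(hits)) {
    return(list(by_chrom = data.frame(chrom = character(0),
                                      strand = character(0),
                                      unique = integer(0),
                                      total = integer(0))))
  }
  key <- paste(hits$chrom, hits$strand, sep = "\r")
  cnt <- as.integer(lib$tags[hits$tag])
  uq <- tapply(hits$tag, key, function(x) length(unique(x)))
  tt <- tapply(cnt, key, sum)
  parts <- do.call(rbind, strsplit(names(uq), "\r", fixed = TRUE))
  by_chrom <- data.frame(chrom = parts[, 1], strand = parts[, 2],
                         unique = as.integer(uq), total = as.integer(tt),
                         stringsAsFactors = FALSE, row.names = NULL)
  out <- list(by_chrom = by_chrom)
  if (!is.null(annotated)) {
    es <- annotated[annotated$category == "exon_sense", ]
    ea <- annotated[annotated$category == "exon_antisense", ]
    out$exon_ratio <- data.frame(
      scale = c("unique", "total"),
      sense = c(nrow(es), sum(es$count)),
      antisense = c(nrow(ea), sum(ea$count)))
    out$exon_ratio$ratio <- with(out$exon_ratio,
                                 ifelse(antisense > 0, sense / antisense, NA))
  }
  out
}
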