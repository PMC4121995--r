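#' Clean raw small-RNA reads
#'
#' Performs the standard small-RNA cleaning pass: drop low-mean-quality
#' reads, locate and trim the 3' adapter, drop adaptor-dimer reads (empty
#' insert after trimming) and retain inserts within the length window
#' (18-30 nt by default). The discard classes partition the input exactly:
#' `kept + low_quality + adaptor_dimer + length == input`.
#'
#' Adapter location: if the full adapter occurs in the read, the insert is
#' everything before its first occurrence; otherwise the longest exact
#' overlap (>= `min_overlap` nt) between the read's 3' end and the
#' adapter's 5' end is trimmed. Reads with no adapter match are kept
#' untrimmed (and then usually fail the length filter).
#'
#' @param fastq path to a FASTQ file (Phred+33) or a character vector of
#'   FASTQ lines.
#' @param adapter 3' adapter sequence (DNA, non-empty).
#' @param min_mean_q minimum mean Phred quality; reads below are discarded
#'   as `low_quality`. Default 20.
#' @param min_len,max_len insert length window, default 18-30 (must lie
#'   within [15, 35]).
#' @param min_overlap minimum 3'-overlap with the adapter, default 6.
#' @return a list with `reads` (character vector of kept inserts, DNA
#'   upper case) and `stats` (named integer vector: input, kept,
#'   low_quality, adaptor_dimer, length).
#' @export
clean_reads <- function(fastq, adapter, min_mean_q = 20,
                        min_len = 18, max_len = 30, min_overlap = 6) {
  stopifnot(nchar(adapter) >= 1, min_len >= 15, max_len <= 35,
            min_len <= max_len)
  lines <- if (length(fastq) == 1L && file.exists(fastq)) {
    readLines(fastq)
  } else {
    as.character(fastq)
  }
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: ", length(lines),
         " lines is not a multiple of 4 (truncated record ",
         length(lines) %/% 4L + 1L, ")")
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(list(reads = character(0),
                stats = c(input = 0L, kept = 0L, low_quality = 0L,
                          adaptor_dimer = 0L, length = 0L)))
  }
  hd <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  pl <- lines[seq(3L, by = 4L, length.out = n)]
  ql <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+") |
                 nchar(sq) != nchar(ql))
  if (length(bad)) {
    stop("malformed FASTQ record at index ", bad[1])
  }

  meanq <- mean_phred(ql)
  insert_len <- locate_adapter(sq, toupper(adapter), min_overlap)

  low_quality <- meanq < min_mean_q
  dimer <- !low_quality & insert_len == 0L
  lenfail <- !low_quality & !dimer &
    (insert_len < min_len | insert_len > max_len)
  keep <- !(low_quality | dimer | lenfail)

  list(reads = substr(sq[keep], 1L, insert_len[keep]),
       stats = c(input = n, kept = sum(keep),
                 low_quality = sum(low_quality),
                 adaptor_dimer = sum(dimer),
                 length = sum(lenfail)))
}

# mean Phred+33 quality per read, vectorised
mean_phred <- function(qual) {
  if (!length(qual)) return(numeric(0))
  widths <- nchar(qual)
  bytes <- utf8ToInt(paste(qual, collapse = "")) - 33L
  as.numeric(rowsum(bytes, rep.int(seq_along(qual), widths))) / widths
}

# insert length after adapter removal; 0 = adaptor dimer; full read length
# when no match >= min_overlap is found
locate_adapter <- function(seqs, adapter, min_overlap = 6) {
  ins <- rep.int(NA_integer_, length(seqs))
  pos <- stringi::stri_locate_first_fixed(seqs, adapter)[, 1]
  ins[!is.na(pos)] <- pos[!is.na(pos)] - 1L
  todo <- is.na(ins)
  na <- nchar(adapter)
  if (any(todo)) {
    nl <- nchar(seqs)
    hi <- min(na - 1L, max(nl[todo]))
    ks <- if (hi >= min_overlap) seq(hi, min_overlap) else integer(0)
    for (k in ks) {
      if (!any(todo)) break
      hit <- todo & nl >= k &
        stringi::stri_sub(seqs, -k) == substr(adapter, 1L, k)
      ins[hit] <- nl[hit] - k
      todo <- todo & !hit
    }
  }
  ins[is.na(ins)] <- nchar(seqs)[is.na(ins)]
  ins
}

#' Collapse cleaned reads into unique tags
#'
#' @param reads character vector of cleaned insert sequences (DNA; `U` is
#'   normalised to `T`).
#' @param name library label.
#' @return a `tag_library`: list with `name`, `tags` (named integer vector
#'   sequence -> count, sorted by sequence), `total_clean` and `n_unique`.
#' @export
collapse_reads <- function(reads, name = "library") {
  reads <- rna_to_dna(toupper(reads))
  if (!length(reads)) {
    return(structure(list(name = name, tags = setNames(integer(0),
                                                       character(0)),
                          total_clean = 0L, n_unique = 0L),
                     class = "tag_library"))
  }
  tab <- table(reads)
  tags <- setNames(as.integer(tab), names(tab))
  tags <- tags[order(names(tags))]
  structure(list(name = name, tags = tags,
                 total_clean = sum(tags), n_unique = length(tags)),
            class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("tag_library '%s': %d unique tags, %d total tags\n",
              x$name, x$n_unique, x$total_clean))
  invisible(x)
}

#' Expand a tag library back to a read vector (inverse of collapse)
#' @param lib a `tag_library`.
#' @return character vector with one element per original read.
#' @export
expand_tags <- function(lib) {
  rep.int(names(lib$tags), lib$tags)
}

#' Tag length distribution
#'
#' @param lib a `tag_library`.
#' @return data.frame with columns `length`, `unique`, `total`.
#' @export
length_distribution <- function(lib) {
  if (lib$n_unique == 0L) {
    return(data.frame(length = integer(0), unique = integer(0),
                      total = integer(0)))
  }
  len <- nchar(names(lib$tags))
  agg_u <- tapply(rep.int(1L, length(len)), len, sum)
  agg_t <- tapply(lib$tags, len, sum)
  data.frame(length = as.integer(names(agg_u)),
             unique = as.integer(agg_u), total = as.integer(agg_t),
             row.names = NULL)
}

#' First-base and per-position base composition
#'
#' Frequencies are weighted by tag counts (total tags). `first_base` has
#' one row per tag length; `by_position` has one row per position over all
#' tags long enough to cover it. Every row sums to 1. Reported in the RNA
#' alphabet.
#'
#' @param lib a `tag_library`.
#' @return list with matrices `first_base` (rows = lengths) and
#'   `by_position` (rows = positions), columns A, C, G, U.
#' @export
base_composition <- function(lib) {
  stopifnot(lib$n_unique > 0L)
  seqs <- names(lib$tags)
  counts <- lib$tags
  lens <- nchar(seqs)
  bases <- c("A", "C", "G", "U")

  fb <- dna_to_rna(substr(seqs, 1L, 1L))
  first <- tapply(counts, list(lens, fb), sum)
  first[is.na(first)] <- 0
  miss <- setdiff(bases, colnames(first))
  if (length(miss)) {
    first <- cbind(first, matrix(0, nrow(first), length(miss),
                                 dimnames = list(NULL, miss)))
  }
  first <- first[, bases, drop = FALSE]
  first <- first / rowSums(first)

  maxlen <- max(lens)
  pos <- matrix(0, maxlen, 4L, dimnames = list(seq_len(maxlen), bases))
  chars <- strsplit(dna_to_rna(seqs), "", fixed = TRUE)
  for (i in seq_along(chars)) {
    b <- match(chars[[i]], bases)
    pos[cbind(seq_along(b), b)] <- pos[cbind(seq_along(b), b)] + counts[i]
  }
  pos <- pos / rowSums(pos)
  list(first_base = first, by_position = pos)
}

#' Tag sharing between two libraries
#'
#' Percentages follow a documented convention: the unique denominators are
#' the union of sequences, the total denominators the grand sum of counts
#' over both libraries; common plus the two specific percentages add to
#' 100 on each scale.
#'
#' @param a,b `tag_library` objects.
#' @return list with `unique_common_pct`, `total_common_pct`,
#'   `unique_specific_pct` (named vector, one entry per library) and
#'   `total_specific_pct`.
#' @export
library_overlap <- function(a, b) {
  stopifnot(a$n_unique > 0L, b$n_unique > 0L)
  sa <- names(a$tags); sb <- names(b$tags)
  shared <- intersect(sa, sb)
  uni <- union(sa, sb)
  grand <- a$total_clean + b$total_clean
  tot_common <- sum(a$tags[shared]) + sum(b$tags[shared])
  out <- list(
    unique_common_pct = 100 * length(shared) / length(uni),
    total_common_pct = 100 * tot_common / grand,
    unique_specific_pct = c(100 * length(setdiff(sa, sb)) / length(uni),
                            100 * length(setdiff(sb, sa)) / length(uni)),
    total_specific_pct = c(100 * sum(a$tags[setdiff(sa, sb)]) / grand,
                           100 * sum(b$tags[setdiff(sb, sa)]) / grand))
  names(out$unique_specific_pct) <- c(a$name, b$name)
  names(out$total_specific_pct) <- c(a$name, b$name)
  out
}
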