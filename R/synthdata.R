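#' Simulation configuration
#'
#' The stated world of the synthetic two-library experiment: a compact
#' random genome carrying planted known miRNA precursors, novel hairpins,
#' ncRNAs and repeat/exon/intron intervals; two sequencing libraries of
#' 3'-adapter-ligated 18-30 nt inserts (length distribution peaked at
#' 22 nt, 22-mers biased to a 5' U) with adaptor-dimer and low-quality
#' contamination; `n_de` miRNAs planted differentially expressed with
#' |log2 fold change| = `planted_log2fc` (sign random), each expressed at
#' `de_base_tpm` in its lower library so both directions are equally
#' detectable.
#'
#' @param seed master seed (all sub-streams derive from it).
#' @param genome_length total genome length in nt, split over two
#'   chromosomes.
#' @param n_known_mirna,n_novel_hairpin,n_de planted feature counts.
#' @param planted_log2fc absolute log2 fold change of DE miRNAs.
#' @param library_depth raw reads per library.
#' @param fractions named proportions (summing to 1) of clean reads per
#'   category: miRNA, novel, rRNA, tRNA, snRNA, snoRNA, scRNA, repeat,
#'   exon, intron, random.
#' @param adapter 3' adapter sequence.
#' @param dimer_rate proportion of raw reads that are adaptor dimers.
#' @param low_quality_rate proportion of low-quality reads.
#' @param de_base_tpm expected TPM of a DE miRNA in its lower library.
#' @param n_genes number of 3'UTR target genes.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1, genome_length = 100000,
                       n_known_mirna = 50, n_novel_hairpin = 8,
                       n_de = 10, planted_log2fc = 2,
                       library_depth = 1e5,
                       fractions = c(miRNA = 0.35, novel = 0.05,
                                     rRNA = 0.15, tRNA = 0.05,
                                     snRNA = 0.03, snoRNA = 0.03,
                                     scRNA = 0.02, "repeat" = 0.08,
                                     exon = 0.10, intron = 0.06,
                                     random = 0.08),
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       dimer_rate = 0.02, low_quality_rate = 0.02,
                       de_base_tpm = 100, n_genes = 60) {
  need <- c("miRNA", "novel", "rRNA", "tRNA", "snRNA", "snoRNA", "scRNA",
            "repeat", "exon", "intron", "random")
  if (!setequal(names(fractions), need)) {
    stop("fractions must be named exactly: ", paste(need, collapse = ", "))
  }
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  stopifnot(library_depth > 0, dimer_rate >= 0, dimer_rate < 1,
            low_quality_rate >= 0, low_quality_rate < 1,
            n_de <= n_known_mirna, planted_log2fc > 0,
            nchar(adapter) >= 6)
  structure(list(seed = seed, genome_length = genome_length,
                 n_known_mirna = n_known_mirna,
                 n_novel_hairpin = n_novel_hairpin, n_de = n_de,
                 planted_log2fc = planted_log2fc,
                 library_depth = library_depth,
                 fractions = fractions[need],
                 adapter = toupper(adapter), dimer_rate = dimer_rate,
                 low_quality_rate = low_quality_rate,
                 de_base_tpm = de_base_tpm, n_genes = n_genes),
            class = "sim_config")
}

# insert length weights over 18..30 nt, mode at 22
insert_length_weights <- function() {
  w <- c(2, 4, 8, 14, 30, 14, 8, 5, 4, 3, 2, 2, 2)
  setNames(w / sum(w), 18:30)
}

draw_insert_len <- function(n) {
  w <- insert_length_weights()
  sample(as.integer(names(w)), n, replace = TRUE, prob = w)
}

#' Build the synthetic reference bundle
#'
#' Generates and writes a genome FASTA, known-miRNA precursor and mature
#' FASTAs, an ncRNA FASTA with class/source header labels, a
#' repeat/exon/intron GFF3, a 3'UTR FASTA (with planted complementary
#' miRNA sites) and a gene-to-term TSV. Every planted mature is an exact
#' substring of its precursor, every precursor an exact genome substring
#' at its recorded locus, all feature intervals are non-overlapping, and
#' every planted novel hairpin folds below -20 kcal/mol under the
#' package's own energy model (verified at generation time). All output
#' is synthetic; ids carry a `sim-` prefix.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return a reference bundle of class `srna_refs` (also reloadable with
#'   [load_references()]), including a `truth` element with planted loci
#'   and the DE assignment.
#' @export
build_references <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(derive_seed(config$seed, 1))

  # --- known miRNA hairpins ---------------------------------------------
  n <- config$n_known_mirna
  pre_id <- sprintf("sim-mir-%03d", seq_len(n))
  mat_seq <- character(n); arm <- character(n); pre_seq <- character(n)
  for (i in seq_len(n)) {
    mlen <- sample(21:23, 1, prob = c(.25, .5, .25))
    first <- if (runif(1) < 0.7) "T" else sample(c("A", "C", "G"), 1)
    mat_seq[i] <- paste0(first, random_dna(1, mlen - 1L))
    arm[i] <- sample(c("5p", "3p"), 1)
    loop <- random_dna(1, sample(10:14, 1))
    star <- revcomp(mat_seq[i])
    pre_seq[i] <- if (arm[i] == "5p") paste0(mat_seq[i], loop, star) else
      paste0(star, loop, mat_seq[i])
  }
  mat_id <- paste0(pre_id, "-", arm)

  # --- novel hairpins: must fold below -20 kcal/mol ---------------------
  nn <- config$n_novel_hairpin
  nov_id <- sprintf("sim-novel-%02d", seq_len(nn))
  nov_mat <- character(nn); nov_arm <- character(nn)
  nov_pre <- character(nn); nov_mfe <- numeric(nn)
  for (h in seq_len(nn)) {
    for (try in 1:50) {
      m <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE,
                        prob = c(.2, .3, .3, .2)), collapse = "")
      a <- sample(c("5p", "3p"), 1)
      loop <- random_dna(1, sample(8:12, 1))
      p <- if (a == "5p") paste0(m, loop, revcomp(m)) else
        paste0(revcomp(m), loop, m)
      f <- fold_mfe(p)
      if (f$mfe < -20) break
    }
    if (f$mfe >= -20) stop("failed to generate a stable novel hairpin")
    nov_mat[h] <- m; nov_arm[h] <- a; nov_pre[h] <- p; nov_mfe[h] <- f$mfe
  }

  # --- ncRNAs and interval features -------------------------------------
  nc_spec <- data.frame(
    class = rep(c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA"),
                times = c(2, 3, 2, 2, 1)),
    len = rep(c(120L, 75L, 100L, 90L, 100L), times = c(2, 3, 2, 2, 1)),
    stringsAsFactors = FALSE)
  nc_spec$id <- sprintf("sim-nc-%02d", seq_len(nrow(nc_spec)))
  nc_spec$source <- rep_len(c("genbank", "rfam"), nrow(nc_spec))
  nc_spec$seq <- random_dna(nrow(nc_spec), nc_spec$len)

  iv_spec <- data.frame(
    type = rep(c("repeat", "exon", "intron"), times = c(4, 6, 4)),
    len = rep(c(150L, 200L, 300L), times = c(4, 6, 4)),
    stringsAsFactors = FALSE)
  iv_spec$id <- paste0("sim-", iv_spec$type, "-",
                       unlist(lapply(c(4, 6, 4), seq_len)))
  iv_spec$strand <- sample(c("+", "-"), nrow(iv_spec), replace = TRUE)

  # --- pack everything into the genome ----------------------------------
  items <- data.frame(
    id = c(pre_id, nov_id, nc_spec$id, iv_spec$id),
    type = c(rep("mirna_precursor", n), rep("novel_precursor", nn),
             rep("ncRNA", nrow(nc_spec)), iv_spec$type),
    len = c(nchar(pre_seq), nchar(nov_pre), nc_spec$len, iv_spec$len),
    strand = c(sample(c("+", "-"), n, TRUE), sample(c("+", "-"), nn, TRUE),
               rep("+", nrow(nc_spec)), iv_spec$strand),
    payload = c(pre_seq, nov_pre, nc_spec$seq,
                rep(NA_character_, nrow(iv_spec))),
    stringsAsFactors = FALSE)
  if (config$genome_length < 10 * sum(items$len)) {
    stop("infeasible packing: genome_length ", config$genome_length,
         " < 10 x total planted feature length ", sum(items$len))
  }
  chroms <- c(chr1 = config$genome_length %/% 2L,
              chr2 = config$genome_length - config$genome_length %/% 2L)
  items <- items[sample(nrow(items)), , drop = FALSE]
  half <- which(cumsum(items$len) >= sum(items$len) / 2)[1]
  items$chrom <- c(rep("chr1", half), rep("chr2", nrow(items) - half))
  items$start <- NA_integer_
  for (ch in names(chroms)) {
    sel <- which(items$chrom == ch)
    slack <- chroms[[ch]] - sum(items$len[sel])
    gaps <- as.integer(rmultinom(1, slack, rep(1, length(sel) + 1L)))
    pos <- cumsum(gaps[seq_along(sel)] +
                    c(0L, items$len[sel][-length(sel)]))
    items$start[sel] <- pos  # 0-based
  }
  items$end <- items$start + items$len

  gseq <- lapply(names(chroms), function(ch) random_dna(1, chroms[[ch]]))
  names(gseq) <- names(chroms)
  for (i in seq_len(nrow(items))) {
    if (is.na(items$payload[i])) next
    ins <- if (items$strand[i] == "-") revcomp(items$payload[i]) else
      items$payload[i]
    substr(gseq[[items$chrom[i]]], items$start[i] + 1L, items$end[i]) <- ins
  }
  genome <- Biostrings::DNAStringSet(unlist(gseq))
  names(genome) <- names(chroms)

  # interval features take their sequence from the underlying genome
  iv <- items[items$type %in% c("repeat", "exon", "intron"), , drop = FALSE]

  # --- DE assignment -----------------------------------------------------
  de_idx <- sort(sample(n, config$n_de))
  de <- data.frame(mirna_id = mat_id[de_idx],
                   sign = sample(c(1, -1), config$n_de, replace = TRUE),
                   stringsAsFactors = FALSE)
  de$log2fc <- de$sign * config$planted_log2fc

  # --- 3' UTRs with planted complementary sites --------------------------
  ng <- config$n_genes
  gene_id <- sprintf("sim-gene-%03d", seq_len(ng))
  utr <- random_dna(ng, sample(200:350, ng, replace = TRUE))
  utr_sites <- list()
  for (g in seq_len(min(ng, 30))) {
    k <- sample(0:4, 1)
    if (k == 0) next
    for (mi in sample(n, k)) {
      site <- revcomp(mat_seq[mi])
      pos <- sample(nchar(utr[g]) - nchar(site), 1)
      substr(utr[g], pos, pos + nchar(site) - 1L) <- site
      utr_sites[[length(utr_sites) + 1L]] <-
        data.frame(gene = gene_id[g], mirna_id = mat_id[mi],
                   pos = pos - 1L, stringsAsFactors = FALSE)
    }
  }
  utr_sites <- do.call(rbind, utr_sites)

  terms <- data.frame(term_id = sprintf("sim-term-%02d", 1:10),
                      term_name = paste("synthetic process", 1:10),
                      stringsAsFactors = FALSE)
  tm <- do.call(rbind, lapply(seq_len(ng), function(g) {
    ti <- sample(10, sample(1:3, 1))
    data.frame(gene = gene_id[g], term_id = terms$term_id[ti],
               term_name = terms$term_name[ti], stringsAsFactors = FALSE)
  }))

  # --- write the bundle ---------------------------------------------------
  wfa <- function(seqs, ids, file, extra = NULL) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- if (is.null(extra)) ids else paste(ids, extra)
    Biostrings::writeXStringSet(x, file.path(outdir, file))
    x
  }
  Biostrings::writeXStringSet(genome, file.path(outdir, "genome.fa"))
  wfa(pre_seq, pre_id, "mirna_precursors.fa")
  wfa(mat_seq, mat_id, "mirna_matures.fa",
      extra = sprintf("precursor=%s arm=%s", pre_id, arm))
  wfa(nc_spec$seq, nc_spec$id, "ncrna.fa",
      extra = sprintf("class=%s source=%s", nc_spec$class, nc_spec$source))
  wfa(utr, gene_id, "utr.fa")
  gff <- c("##gff-version 3",
           sprintf("%s\tsrnapipe_sim\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                   iv$chrom, iv$type, iv$start + 1L, iv$end, iv$strand,
                   iv$id))
  writeLines(gff, file.path(outdir, "features.gff3"))
  write.table(tm, file.path(outdir, "gene_terms.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  truth <- list(
    loci = items[, c("id", "type", "chrom", "start", "end", "strand")],
    novel = data.frame(id = nov_id, mature = nov_mat, arm = nov_arm,
                       precursor = nov_pre, mfe = nov_mfe,
                       chrom = items$chrom[match(nov_id, items$id)],
                       start = items$start[match(nov_id, items$id)],
                       end = items$end[match(nov_id, items$id)],
                       strand = items$strand[match(nov_id, items$id)],
                       stringsAsFactors = FALSE),
    de = de, utr_sites = utr_sites)
  jsonlite::write_json(truth, file.path(outdir, "refs_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  load_references(outdir)
}

#' Load a reference bundle from disk
#'
#' Reads the file set produced by [build_references()] (or equivalently
#' laid-out real references): genome.fa, mirna_precursors.fa,
#' mirna_matures.fa (headers `precursor=` and `arm=`), ncrna.fa (headers
#' `class=` and `source=`), features.gff3, utr.fa, gene_terms.tsv and,
#' when present, refs_truth.json.
#'
#' @param dir bundle directory.
#' @return an `srna_refs` list.
#' @export
load_references <- function(dir) {
  fp <- function(f) file.path(dir, f)
  genome <- Biostrings::readDNAStringSet(fp("genome.fa"))
  precursors <- Biostrings::readDNAStringSet(fp("mirna_precursors.fa"))
  matures <- Biostrings::readDNAStringSet(fp("mirna_matures.fa"))
  hdr <- names(matures)
  mature_id <- sub(" .*", "", hdr)
  kv <- function(h, key) {
    m <- stringi::stri_match_first_regex(h, paste0(key, "=(\\S+)"))[, 2]
    m
  }
  mature_info <- data.frame(mature_id = mature_id,
                            precursor_id = kv(hdr, "precursor"),
                            arm = kv(hdr, "arm"), stringsAsFactors = FALSE)
  names(matures) <- mature_id
  ncrna <- Biostrings::readDNAStringSet(fp("ncrna.fa"))
  nh <- names(ncrna)
  ncrna_info <- data.frame(id = sub(" .*", "", nh),
                           class = kv(nh, "class"),
                           source = kv(nh, "source"),
                           stringsAsFactors = FALSE)
  names(ncrna) <- ncrna_info$id
  features <- rtracklayer::import(fp("features.gff3"))
  utr <- Biostrings::readDNAStringSet(fp("utr.fa"))
  names(utr) <- sub(" .*", "", names(utr))
  terms <- read.delim(fp("gene_terms.tsv"), stringsAsFactors = FALSE)
  truth <- NULL
  if (file.exists(fp("refs_truth.json"))) {
    truth <- jsonlite::read_json(fp("refs_truth.json"),
                                 simplifyVector = TRUE)
  }
  structure(list(dir = dir, genome = genome, precursors = precursors,
                 matures = matures, mature_info = mature_info,
                 ncrna = ncrna, ncrna_info = ncrna_info,
                 features = features, utr = utr, terms = terms,
                 truth = truth),
            class = "srna_refs")
}

# random substrings of a set of parent sequences, with antisense flips
category_reads <- function(m, parents, antisense_rate = 0) {
  if (m == 0) return(character(0))
  pick <- sample(length(parents), m, replace = TRUE)
  plen <- nchar(parents)[pick]
  len <- pmin(draw_insert_len(m), plen)
  start <- floor(runif(m) * (plen - len + 1)) + 1L
  out <- substr(parents[pick], start, start + len - 1L)
  if (antisense_rate > 0) {
    flip <- runif(m) < antisense_rate
    out[flip] <- revcomp(out[flip])
  }
  out
}

#' Simulate the two sequencing libraries
#'
#' Draws `library_depth` raw reads per library: adaptor dimers
#' (adapter-only reads), low-quality reads (random inserts with Phred 2
#' qualities) and clean reads whose per-source counts are one multinomial
#' draw over the expected proportions. Planted DE miRNAs differ in
#' expected proportion by exactly `2^log2fc` between libraries; each
#' library has its own RNG stream derived from the master seed, so a
#' fixed config yields byte-identical FASTQ files.
#'
#' @param config a [sim_config()].
#' @param refs bundle from [build_references()].
#' @param outdir output directory for `control.fastq`,
#'   `knockdown.fastq` and `manifest.json`.
#' @return the truth manifest (invisibly also written as JSON):
#'   per-miRNA and per-novel-hairpin counts/TPMs and true log2
#'   fold changes, per-library category composition and totals.
#' @export
simulate_libraries <- function(config, refs, outdir) {
  stopifnot(inherits(config, "sim_config"), inherits(refs, "srna_refs"))
  if (config$library_depth <= 0) stop("library depth must be > 0")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fr <- config$fractions
  info <- refs$mature_info
  n <- nrow(info)
  de <- refs$truth$de
  lfc <- config$planted_log2fc

  # shared expected TPMs (stream 4): identical non-DE profile in both
  set.seed(derive_seed(config$seed, 4))
  w <- stats::rlnorm(n, 0, 1)
  is_de <- info$mature_id %in% de$mirna_id
  tpm_ctrl <- tpm_kd <- numeric(n)
  if (any(is_de)) {
    sg <- de$sign[match(info$mature_id[is_de], de$mirna_id)]
    base <- config$de_base_tpm
    tpm_ctrl[is_de] <- ifelse(sg > 0, base, base * 2^lfc)
    tpm_kd[is_de] <- ifelse(sg > 0, base * 2^lfc, base)
  }
  budget <- fr[["miRNA"]] * 1e6
  nonde_budget <- budget - sum(tpm_ctrl[is_de])
  if (nonde_budget < 0) stop("miRNA fraction too small for DE planting")
  if (any(!is_de)) {
    shared <- w[!is_de] / sum(w[!is_de]) * nonde_budget
    tpm_ctrl[!is_de] <- shared
    tpm_kd[!is_de] <- shared
  }
  nov <- refs$truth$novel
  nov_tpm <- if (nrow(nov)) rep(fr[["novel"]] * 1e6 / nrow(nov),
                                nrow(nov)) else numeric(0)

  classes <- c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA")
  class_tpm <- vapply(classes, function(cl) fr[[cl]] * 1e6, numeric(1))
  iv_tpm <- c("repeat" = fr[["repeat"]] * 1e6, exon = fr[["exon"]] * 1e6,
              intron = fr[["intron"]] * 1e6)

  # genome substrings of the interval features (read source material)
  loci <- refs$truth$loci
  gchr <- lapply(seq_along(refs$genome),
                 function(i) as.character(refs$genome[[i]]))
  names(gchr) <- names(refs$genome)
  iv_seq <- list()
  for (ty in c("repeat", "exon", "intron")) {
    sel <- loci[loci$type == ty, , drop = FALSE]
    s <- mapply(function(ch, a, b) substr(gchr[[ch]], a + 1L, b),
                sel$chrom, sel$start, sel$end, USE.NAMES = FALSE)
    s[sel$strand == "-"] <- revcomp(s[sel$strand == "-"])
    iv_seq[[ty]] <- s
  }

  mat_dna <- as.character(refs$matures)[info$mature_id]
  nov_dna <- if (nrow(nov)) rna_to_dna(nov$mature) else character(0)
  nc_by_class <- split(as.character(refs$ncrna), refs$ncrna_info$class)

  units_tpm <- list(control = c(tpm_ctrl, nov_tpm, class_tpm, iv_tpm),
                    knockdown = c(tpm_kd, nov_tpm, class_tpm, iv_tpm))
  manifest_lib <- list()
  unit_counts <- list()
  for (li in c("control", "knockdown")) {
    set.seed(derive_seed(config$seed, if (li == "control") 2 else 3))
    utpm <- units_tpm[[li]]
    random_tpm <- 1e6 - sum(utpm)
    if (random_tpm < 0) stop("category fractions exceed the unit budget")
    prob <- c(utpm, random_tpm) / 1e6

    depth <- as.integer(config$library_depth)
    n_dimer <- rbinom(1, depth, config$dimer_rate)
    n_lowq <- rbinom(1, depth - n_dimer, config$low_quality_rate)
    n_good <- depth - n_dimer - n_lowq
    counts <- as.integer(rmultinom(1, n_good, prob))

    idx <- 0L
    take <- function(k) {
      v <- counts[idx + seq_len(k)]
      idx <<- idx + k
      v
    }
    c_mir <- take(n)
    c_nov <- take(nrow(nov))
    c_cls <- take(length(classes))
    c_iv <- take(3L)
    c_rnd <- take(1L)

    inserts <- c(
      rep.int(mat_dna, c_mir),
      rep.int(nov_dna, c_nov),
      unlist(lapply(seq_along(classes), function(ci) {
        category_reads(c_cls[ci], nc_by_class[[classes[ci]]] %||%
                         character(0))
      }), use.names = FALSE),
      category_reads(c_iv[1], iv_seq[["repeat"]]),
      category_reads(c_iv[2], iv_seq[["exon"]], antisense_rate = 0.2),
      category_reads(c_iv[3], iv_seq[["intron"]], antisense_rate = 0.2),
      random_dna(c_rnd, draw_insert_len(c_rnd)))
    src <- c(rep.int(info$mature_id, c_mir),
             rep.int(nov$id, c_nov),
             rep.int(classes, c_cls),
             rep.int(c("repeat", "exon", "intron"), c_iv),
             rep.int("random", c_rnd))

    lowq <- random_dna(n_lowq, draw_insert_len(n_lowq))
    seqs <- c(paste0(inserts, config$adapter),
              paste0(lowq, config$adapter),
              rep.int(config$adapter, n_dimer))
    quals <- c(strrep("I", nchar(seqs[seq_along(inserts)])),
               strrep("#", nchar(lowq) + nchar(config$adapter)),
               rep.int(strrep("I", nchar(config$adapter)), n_dimer))
    srcs <- c(src, rep.int("lowq", n_lowq), rep.int("dimer", n_dimer))
    ord <- sample(length(seqs))
    out <- file.path(outdir, paste0(li, ".fastq"))
    writeLines(rbind(sprintf("@%s_%06d src=%s", li, seq_along(ord),
                             srcs[ord]),
                     seqs[ord], "+", quals[ord]),
               out)
    unit_counts[[li]] <- list(mirna = c_mir, novel = c_nov,
                              classes = setNames(c_cls, classes),
                              intervals = setNames(c_iv,
                                                   c("repeat", "exon",
                                                     "intron")),
                              random = c_rnd, n_good = n_good)
    manifest_lib[[li]] <- list(
      fastq = basename(out), raw_reads = depth, adaptor_dimers = n_dimer,
      low_quality = n_lowq, clean_reads = n_good,
      category_counts = c(miRNA = sum(c_mir), novel = sum(c_nov),
                          setNames(c_cls, classes),
                          setNames(c_iv, c("repeat", "exon", "intron")),
                          random = c_rnd))
  }

  uc <- unit_counts$control; uk <- unit_counts$knockdown
  mirna_truth <- data.frame(
    mirna_id = info$mature_id,
    count_control = uc$mirna, count_knockdown = uk$mirna,
    tpm_control = uc$mirna / uc$n_good * 1e6,
    tpm_knockdown = uk$mirna / uk$n_good * 1e6,
    expected_tpm_control = tpm_ctrl, expected_tpm_knockdown = tpm_kd,
    true_log2fc = ifelse(is_de,
                         de$log2fc[match(info$mature_id, de$mirna_id)], 0),
    stringsAsFactors = FALSE)
  novel_truth <- cbind(nov, data.frame(
    count_control = uc$novel, count_knockdown = uk$novel,
    tpm_control = uc$novel / uc$n_good * 1e6,
    tpm_knockdown = uk$novel / uk$n_good * 1e6,
    stringsAsFactors = FALSE))
  manifest <- list(seed = config$seed, depth = config$library_depth,
                   libraries = manifest_lib, mirna = mirna_truth,
                   novel = novel_truth, de = de)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
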