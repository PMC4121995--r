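dss <- function(x) Biostrings::DNAStringSet(x)

test_that("map_tags finds all exact hits on both strands", {
  set.seed(5)
  gseq <- random_dna_test(5000)
  genome <- dss(c(chrA = gseq))
  tagp <- substr(gseq, 101, 122)
  tagm <- revcomp(substr(gseq, 51, 72))
  lib <- collapse_reads(c(tagp, tagm, strrep("ACTG", 5)))
  mp <- map_tags(lib, genome)
  hp <- mp$hits[mp$hits$tag == tagp, ]
  expect_true(any(hp$start == 100 & hp$end == 122 & hp$strand == "+"))
  hm <- mp$hits[mp$hits$tag == tagm, ]
  expect_true(any(hm$start == 50 & hm$end == 72 & hm$strand == "-"))
})

test_that("map_tags agrees with a naive all-positions scan", {
  set.seed(6)
  gseq <- random_dna_test(3000)
  genome <- dss(c(chrA = gseq))
  # mix of planted and random tags
  tags <- c(vapply(1:5, function(i) {
    s <- sample(2900, 1)
    substr(gseq, s, s + 19)
  }, character(1)), rna_to_dna(vapply(rep(20, 5), random_rna,
                                      character(1))))
  lib <- collapse_reads(tags)
  mp <- map_tags(lib, genome)
  for (tg in unique(tags)) {
    naive <- naive_hits(gseq, tg)
    got <- mp$hits[mp$hits$tag == tg, c("start", "strand")]
    expect_equal(nrow(got), nrow(naive), label = tg)
    expect_setequal(paste(got$start, got$strand),
                    paste(naive$start, naive$strand))
  }
})

test_that("priority rule resolves multi-matching tags", {
  tag <- strrep("AGCT", 6)  # 24 nt, present in several references
  refs <- list(
    ncrna = dss(c(nc_rfam = paste0("CCC", tag, "GGG"),
                  nc_genbank = paste0("TTT", tag, "AAA"))),
    ncrna_info = data.frame(id = c("nc_rfam", "nc_genbank"),
                            class = c("tRNA", "rRNA"),
                            source = c("rfam", "genbank")),
    precursors = dss(c(mirP = paste0(tag, strrep("A", 30)))),
    matures = dss(c(mirP_mat = tag)),
    features = GenomicRanges::GRanges())
  lib <- collapse_reads(tag)
  ann <- annotate_tags(lib, refs, empty_hits_test())
  # genbank rRNA outranks rfam tRNA and the miRNA match
  expect_equal(ann$annotated$category, "rRNA")
  expect_equal(ann$annotated$source, "genbank")

  # without the genbank record, rfam tRNA still outranks miRNA
  refs2 <- refs
  refs2$ncrna <- refs$ncrna["nc_rfam"]
  refs2$ncrna_info <- refs$ncrna_info[1, ]
  ann2 <- annotate_tags(lib, refs2, empty_hits_test())
  expect_equal(ann2$annotated$category, "tRNA")

  # without ncRNA matches at all, known miRNA wins
  refs3 <- refs
  refs3$ncrna <- dss(character(0))
  refs3$ncrna_info <- refs$ncrna_info[0, ]
  ann3 <- annotate_tags(lib, refs3, empty_hits_test())
  expect_equal(ann3$annotated$category, "known_miRNA")

  refs_bad <- refs
  refs_bad$ncrna_info$class[1] <- "mystRNA"
  expect_error(annotate_tags(lib, refs_bad, empty_hits_test()),
               "unknown ncRNA class")
})

test_that("interval categories split sense/antisense and respect priority", {
  tag <- strrep("GATC", 5)
  hits <- data.frame(tag = tag, chrom = "chrA", start = 100L,
                     end = 120L, strand = "+")
  base_refs <- list(ncrna = dss(character(0)),
                    ncrna_info = data.frame(id = character(0),
                                            class = character(0),
                                            source = character(0)),
                    precursors = dss(character(0)),
                    matures = dss(character(0)))
  mkrefs <- function(type, strand) {
    r <- base_refs
    gr <- GenomicRanges::GRanges("chrA",
                                 IRanges::IRanges(90, 130),
                                 strand = strand)
    gr$type <- type
    r$features <- gr
    r
  }
  lib <- collapse_reads(tag)
  expect_equal(annotate_tags(lib, mkrefs("exon", "-"),
                             hits)$annotated$category, "exon_antisense")
  expect_equal(annotate_tags(lib, mkrefs("exon", "+"),
                             hits)$annotated$category, "exon_sense")
  expect_equal(annotate_tags(lib, mkrefs("intron", "+"),
                             hits)$annotated$category, "intron_sense")
  # repeat outranks exon when both overlap
  r <- base_refs
  gr <- GenomicRanges::GRanges("chrA", IRanges::IRanges(c(90, 95),
                                                        c(130, 125)),
                               strand = "+")
  gr$type <- c("exon", "repeat")
  r$features <- gr
  expect_equal(annotate_tags(lib, r, hits)$annotated$category, "repeat")
})

test_that("annotation matches brute-force priority evaluation and partitions", {
  fix <- sim_fixture()
  lib <- fix$libs$control
  mp <- map_tags(lib, fix$refs$genome)
  ann <- annotate_tags(lib, fix$refs, mp$hits)
  expect_equal(sum(ann$summary$unique), lib$n_unique)
  expect_equal(sum(ann$summary$total), lib$total_clean)

  # literal rule list applied per tag, on a sample of tags
  set.seed(3)
  idx <- sample(lib$n_unique, 50)
  pre <- as.character(fix$refs$precursors)
  mat <- as.character(fix$refs$matures)
  nc <- as.character(fix$refs$ncrna)
  for (i in idx) {
    tg <- names(lib$tags)[i]
    expected <- "unannotated"
    ncm <- vapply(nc, function(s) grepl(tg, s, fixed = TRUE), logical(1))
    if (any(ncm)) {
      info <- fix$refs$ncrna_info[ncm, ]
      info <- info[order(match(info$source, c("genbank", "rfam")),
                         match(info$class, c("rRNA", "scRNA", "snRNA",
                                             "snoRNA", "tRNA"))), ]
      expected <- info$class[1]
    } else if (any(vapply(pre, function(s) grepl(tg, s, fixed = TRUE),
                          logical(1))) || tg %in% mat) {
      expected <- "known_miRNA"
    } else {
      h <- mp$hits[mp$hits$tag == tg, ]
      found <- character(0)
      if (nrow(h)) {
        hgr <- GenomicRanges::GRanges(h$chrom,
                                      IRanges::IRanges(h$start + 1,
                                                       h$end),
                                      strand = h$strand)
        ov <- GenomicRanges::findOverlaps(hgr, fix$refs$features,
                                          ignore.strand = TRUE)
        if (length(ov)) {
          ty <- fix$refs$features$type[S4Vectors::subjectHits(ov)]
          sn <- as.character(
            GenomicRanges::strand(fix$refs$features))[
              S4Vectors::subjectHits(ov)] ==
            h$strand[S4Vectors::queryHits(ov)]
          for (t2 in c("repeat", "exon", "intron")) {
            if (any(ty == t2)) {
              found <- if (t2 == "repeat") "repeat" else
                paste0(t2, if (any(sn[ty == t2])) "_sense"
                       else "_antisense")
              break
            }
          }
        }
      }
      if (length(found)) expected <- found
    }
    got <- ann$annotated$category[ann$annotated$tag == tg]
    expect_equal(got, expected, label = tg)
  }
})

test_that("rRNA QC verdict uses a strict 40% bound", {
  mk <- function(rrna, rest) {
    data.frame(category = c("rRNA", "unannotated"),
               unique = c(1L, 1L), total = c(rrna, rest))
  }
  expect_equal(rrna_qc(mk(399L, 601L))$verdict, "PASS")
  expect_equal(rrna_qc(mk(400L, 600L))$verdict, "FAIL")
  expect_equal(rrna_qc(mk(0L, 1000L))$verdict, "PASS")
  expect_error(rrna_qc(mk(0L, 0L)), "empty")
})

test_that("known miRNA quantification obeys the overlap rule", {
  mature <- strrep("TGCA", 6)                      # 24 nt
  loop <- strrep("A", 12)
  pre <- paste0(mature, loop, revcomp(mature))
  refs <- list(precursors = dss(c(preX = pre)),
               matures = dss(c("preX-5p" = mature)),
               mature_info = data.frame(mature_id = "preX-5p",
                                        precursor_id = "preX",
                                        arm = "5p"))
  # tag = mature; tag inside loop+star only; tag overlapping mature by 16
  in_loop <- substr(pre, 26, 48)
  over16 <- substr(pre, 9, 30)  # covers mature positions 9..24 = 16 nt
  lib <- collapse_reads(c(rep(mature, 5), rep(in_loop, 2), over16))
  q <- quantify_known_mirna(lib, refs)
  expect_equal(q$mirna$count, 5L + 1L)
  expect_equal(q$precursor$count, 8L)
  expect_equal(unname(q$arms["n_5p"]), 1L)
  # with a stricter overlap the 16 nt-overlap tag drops out
  q17 <- quantify_known_mirna(lib, refs, min_overlap = 17)
  expect_equal(q17$mirna$count, 5L)
  # broken reference: mature not inside precursor
  bad <- refs
  bad$matures <- dss(c("preX-5p" = strrep("C", 24)))
  expect_error(quantify_known_mirna(lib, bad), "not a substring")
})

test_that("detected miRNA set matches the planted truth", {
  fix <- sim_fixture()
  q <- quantify_known_mirna(fix$libs$control, fix$refs)
  planted <- fix$manifest$mirna
  expect_setequal(q$detected,
                  planted$mirna_id[planted$count_control > 0])
  expect_equal(q$mirna$count[match(planted$mirna_id, q$mirna$mirna_id)],
               planted$count_control)
})

test_that("chromosome distribution counts every hit once", {
  lib <- collapse_reads(c(strrep("ACGT", 5), strrep("ACGT", 5),
                          strrep("TTGA", 5)))
  hits <- data.frame(tag = c(strrep("ACGT", 5), strrep("TTGA", 5),
                             strrep("TTGA", 5)),
                     chrom = c("chr1", "chr1", "chr2"),
                     start = c(0L, 10L, 20L), end = c(20L, 30L, 40L),
                     strand = c("+", "+", "-"))
  cd <- chrom_distribution(hits, lib)
  t1 <- cd$by_chrom[cd$by_chrom$chrom == "chr1" &
                      cd$by_chrom$strand == "+", ]
  expect_equal(t1$unique, 2L)
  expect_equal(t1$total, 3L)  # ACGT... has count 2, TTGA... count 1
  t2 <- cd$by_chrom[cd$by_chrom$chrom == "chr2", ]
  expect_equal(t2$strand, "-")
  expect_equal(t2$unique, 1L)
})
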