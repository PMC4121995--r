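test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  fr <- sim_config()$fractions
  expect_equal(sum(fr), 1)
  fr_bad <- fr; fr_bad["random"] <- fr_bad["random"] + 0.1
  expect_error(sim_config(fractions = fr_bad), "sum to 1")
  expect_error(sim_config(library_depth = 0), "library_depth")
  expect_error(sim_config(dimer_rate = 1), "dimer_rate")
  expect_error(sim_config(fractions = fr[-1]), "named exactly")
})

test_that("infeasible packing fails explicitly", {
  cfg <- sim_config(genome_length = 5000)
  expect_error(build_references(cfg, tempfile()), "infeasible packing")
})

test_that("seeded generation is byte-identical", {
  cfg <- sim_config(seed = 13, library_depth = 3000, n_known_mirna = 10,
                    n_novel_hairpin = 2, n_de = 2, genome_length = 60000,
                    n_genes = 10)
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- build_references(cfg, file.path(d1, "refs"))
  r2 <- build_references(cfg, file.path(d2, "refs"))
  for (f in list.files(file.path(d1, "refs"))) {
    expect_identical(unname(tools::md5sum(file.path(d1, "refs", f))),
                     unname(tools::md5sum(file.path(d2, "refs", f))),
                     label = f)
  }
  simulate_libraries(cfg, r1, file.path(d1, "sim"))
  simulate_libraries(cfg, r2, file.path(d2, "sim"))
  for (f in c("control.fastq", "knockdown.fastq", "manifest.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, "sim", f))),
                     unname(tools::md5sum(file.path(d2, "sim", f))),
                     label = f)
  }
})

test_that("planted references satisfy their structural postconditions", {
  fix <- sim_fixture()
  refs <- fix$refs
  cfg <- fix$cfg
  expect_length(refs$precursors, cfg$n_known_mirna)
  expect_length(refs$matures, cfg$n_known_mirna)
  # every mature is a substring of its precursor
  for (i in seq_len(nrow(refs$mature_info))) {
    expect_true(grepl(
      as.character(refs$matures[[refs$mature_info$mature_id[i]]]),
      as.character(refs$precursors[[refs$mature_info$precursor_id[i]]]),
      fixed = TRUE))
  }
  # every planted payload is the genome substring at its locus/strand
  loci <- refs$truth$loci
  g <- lapply(seq_along(refs$genome),
              function(i) as.character(refs$genome[[i]]))
  names(g) <- names(refs$genome)
  pay <- c(as.list(setNames(as.character(refs$precursors),
                            names(refs$precursors))),
           as.list(setNames(refs$truth$novel$precursor,
                            refs$truth$novel$id)),
           as.list(setNames(as.character(refs$ncrna),
                            names(refs$ncrna))))
  for (id in names(pay)) {
    lo <- loci[loci$id == id, ]
    sub <- substr(g[[lo$chrom]], lo$start + 1, lo$end)
    if (lo$strand == "-") sub <- revcomp(sub)
    expect_identical(sub, rna_to_dna(pay[[id]]), label = id)
  }
  # intervals are pairwise non-overlapping per chromosome
  for (ch in unique(loci$chrom)) {
    l <- loci[loci$chrom == ch, ]
    l <- l[order(l$start), ]
    expect_true(all(l$start[-1] >= l$end[-nrow(l)]))
  }
  # planted novel hairpins fold below -20 under the package's model
  for (h in seq_len(nrow(refs$truth$novel))) {
    expect_lt(fold_mfe(refs$truth$novel$precursor[h])$mfe, -20)
  }
})

test_that("emitted counts follow the planted expectations", {
  fix <- sim_fixture()
  man <- fix$manifest
  # DE miRNAs differ in expected proportion by exactly 2^log2fc
  de <- man$de
  m <- man$mirna
  i <- match(de$mirna_id, m$mirna_id)
  expect_equal(log2(m$expected_tpm_knockdown[i] /
                      m$expected_tpm_control[i]),
               de$log2fc)
  # observed counts within 5 binomial SDs of expectation
  for (li in c("control", "knockdown")) {
    exp_tpm <- m[[paste0("expected_tpm_", li)]]
    n_good <- man$libraries[[li]]$clean_reads
    expected <- exp_tpm / 1e6 * n_good
    sd <- sqrt(pmax(expected, 1))
    obs <- m[[paste0("count_", li)]]
    expect_true(all(abs(obs - expected) <= 5 * sd),
                label = paste("count deviation", li))
  }
})

test_that("manifest TPMs agree with pipeline TPMs from the cleaned reads", {
  fix <- sim_fixture()
  man <- fix$manifest
  lib <- fix$libs$control
  expect_equal(lib$total_clean, man$libraries$control$clean_reads,
               tolerance = 0.001)
  q <- quantify_known_mirna(lib, fix$refs)
  got <- tpm(q$mirna$count[match(man$mirna$mirna_id, q$mirna$mirna_id)],
             lib$total_clean)
  expect_equal(got, man$mirna$tpm_control, tolerance = 0.01)
})

test_that("a category with proportion zero emits no reads", {
  fr <- c(miRNA = 0, novel = 0, rRNA = 0.3, tRNA = 0.1, snRNA = 0.1,
          snoRNA = 0.1, scRNA = 0.1, "repeat" = 0.1, exon = 0.1,
          intron = 0.05, random = 0.05)
  cfg <- sim_config(seed = 3, library_depth = 2000, n_known_mirna = 5,
                    n_novel_hairpin = 1, n_de = 0, genome_length = 60000,
                    fractions = fr, n_genes = 5)
  d <- tempfile()
  refs <- build_references(cfg, file.path(d, "refs"))
  man <- simulate_libraries(cfg, refs, file.path(d, "sim"))
  expect_true(all(man$mirna$count_control == 0))
  expect_true(all(man$mirna$count_knockdown == 0))
  expect_equal(man$libraries$control$category_counts[["miRNA"]], 0L)
})

test_that("an rRNA-dominated library fails the downstream QC mark", {
  fr <- c(miRNA = 0.2, novel = 0, rRNA = 0.5, tRNA = 0.05, snRNA = 0,
          snoRNA = 0, scRNA = 0, "repeat" = 0.05, exon = 0.1,
          intron = 0.05, random = 0.05)
  cfg <- sim_config(seed = 5, library_depth = 5000, n_known_mirna = 5,
                    n_novel_hairpin = 1, n_de = 1, genome_length = 60000,
                    fractions = fr, n_genes = 5)
  d <- tempfile()
  refs <- build_references(cfg, file.path(d, "refs"))
  simulate_libraries(cfg, refs, file.path(d, "sim"))
  cl <- clean_reads(file.path(d, "sim", "control.fastq"), cfg$adapter)
  lib <- collapse_reads(cl$reads, "control")
  mp <- map_tags(lib, refs$genome)
  ann <- annotate_tags(lib, refs, mp$hits)
  expect_equal(rrna_qc(ann$summary)$verdict, "FAIL")
  expect_gt(rrna_qc(ann$summary)$ratio, 0.40)
})
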