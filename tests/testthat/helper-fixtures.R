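# Shared simulated dataset, built once per test run (seed 7, reduced
# depth to keep the default suite fast) and cached for all test files.
.fix_env <- new.env(parent = emptyenv())

sim_fixture <- function() {
  if (!is.null(.fix_env$fix)) return(.fix_env$fix)
  dir <- file.path(tempdir(), "srnapipe-fixture")
  cfg <- sim_config(seed = 7, library_depth = 2e4)
  refs <- build_references(cfg, file.path(dir, "refs"))
  manifest <- simulate_libraries(cfg, refs, file.path(dir, "sim"))
  libs <- list()
  clean <- list()
  for (li in c("control", "knockdown")) {
    cl <- clean_reads(file.path(dir, "sim", paste0(li, ".fastq")),
                      cfg$adapter)
    clean[[li]] <- cl
    libs[[li]] <- collapse_reads(cl$reads, li)
  }
  .fix_env$fix <- list(dir = dir, cfg = cfg, refs = refs,
                       manifest = manifest, clean = clean, libs = libs)
  .fix_env$fix
}

# small deterministic FASTQ builder
make_fastq <- function(seqs, quals = NULL, ids = NULL) {
  n <- length(seqs)
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  if (is.null(ids)) ids <- sprintf("@read_%d", seq_len(n))
  as.vector(rbind(ids, seqs, "+", quals))
}
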