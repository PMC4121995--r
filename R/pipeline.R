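#' Run the full two-library analysis
#'
#' Orchestrates preprocess -> annotate -> novel -> differential
#' expression -> targets -> enrichment on a pair of FASTQ libraries
#' against a reference bundle, persisting every intermediate as TSV and
#' returning (and writing) a machine-readable report. Any stage failure
#' aborts with the stage name and cause.
#'
#' @param config named list or path to a YAML file with fields:
#'   `refs_dir`, `fastq_control`, `fastq_knockdown`, `outdir`, and
#'   optional parameters `adapter` (default the standard small-RNA 3'
#'   adapter), `min_mean_q` (20), `min_len` (18), `max_len` (30),
#'   `max_mismatch` (0), `flank` (70), `mfe_max` (-20), `tpm_min` (1),
#'   `alpha_known` (0.01), `alpha_novel` (0.05), `min_fold` (2),
#'   `floor_tpm` (0.01), `evd_location` (1.9), `evd_scale` (0.28),
#'   `max_p` (0.05), `min_mirnas` (3), `run_targets` (TRUE; the duplex
#'   scan over all miRNA x gene pairs is the slow stage).
#' @return the report list (also written to `outdir/report.json`).
#' @export
run_all <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(adapter = "TGGAATTCTCGGGTGCCAAGG", min_mean_q = 20,
                   min_len = 18, max_len = 30, max_mismatch = 0,
                   flank = 70, mfe_max = -20, tpm_min = 1,
                   alpha_known = 0.01, alpha_novel = 0.05, min_fold = 2,
                   floor_tpm = 0.01, evd_location = 1.9,
                   evd_scale = 0.28, max_p = 0.05, min_mirnas = 3,
                   run_targets = TRUE)
  cfg <- utils::modifyList(defaults, config)
  for (f in c("refs_dir", "fastq_control", "fastq_knockdown", "outdir")) {
    if (is.null(cfg[[f]])) stop("config is missing required field: ", f)
  }
  for (f in c("refs_dir", "fastq_control", "fastq_knockdown")) {
    if (!file.exists(cfg[[f]])) {
      stop("config validation: path does not exist: ", cfg[[f]])
    }
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  tsv <- function(x, f) {
    write.table(x, file.path(cfg$outdir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  refs <- stage("load_references", load_references(cfg$refs_dir))

  libs <- stage("preprocess", {
    out <- list()
    for (li in c("control", "knockdown")) {
      cl <- clean_reads(cfg[[paste0("fastq_", li)]], cfg$adapter,
                        cfg$min_mean_q, cfg$min_len, cfg$max_len)
      out[[li]] <- list(clean = cl, lib = collapse_reads(cl$reads, li))
    }
    out
  })
  lib_c <- libs$control$lib
  lib_k <- libs$knockdown$lib
  tsv(data.frame(tag = union(names(lib_c$tags), names(lib_k$tags))) |>
        (\(d) {
          d$count_control <- as.integer(lib_c$tags[d$tag])
          d$count_knockdown <- as.integer(lib_k$tags[d$tag])
          d$count_control[is.na(d$count_control)] <- 0L
          d$count_knockdown[is.na(d$count_knockdown)] <- 0L
          d
        })(), "tags.tsv")
  for (li in c("control", "knockdown")) {
    tsv(length_distribution(libs[[li]]$lib),
        paste0("length_distribution_", li, ".tsv"))
  }

  ann <- stage("annotate", {
    out <- list()
    for (li in c("control", "knockdown")) {
      lib <- libs[[li]]$lib
      mp <- map_tags(lib, refs$genome, cfg$max_mismatch)
      an <- annotate_tags(lib, refs, mp$hits)
      qc <- rrna_qc(an$summary)
      qm <- quantify_known_mirna(lib, refs)
      tsv(an$summary, paste0("category_summary_", li, ".tsv"))
      tsv(an$annotated, paste0("annotation_", li, ".tsv"))
      out[[li]] <- list(map = mp, ann = an, qc = qc, quant = qm)
    }
    out
  })

  denovo <- stage("novel", {
    out <- list(candidates = NULL)
    for (li in c("control", "knockdown")) {
      a <- ann[[li]]
      un <- a$ann$annotated$tag[a$ann$annotated$category == "unannotated"]
      hits <- a$map$hits[a$map$hits$tag %in% un, , drop = FALSE]
      win <- excise_windows(hits, refs$genome, cfg$flank)
      cn <- call_novel(win, lib_c, lib_k, cfg$mfe_max, cfg$tpm_min)
      out[[li]] <- cn
    }
    # union over the two libraries, collapsed by locus
    both <- rbind(out$control$candidates, out$knockdown$candidates)
    if (nrow(both)) {
      both <- both[!duplicated(paste(both$chrom, both$start, both$end)), ]
    }
    tsv(both, "novel_candidates.tsv")
    out$candidates <- both
    out
  })

  de <- stage("diffexpr", {
    qc_tab <- ann$control$quant$mirna
    qk_tab <- ann$knockdown$quant$mirna
    counts <- data.frame(mirna_id = qc_tab$mirna_id,
                         count_control = qc_tab$count,
                         count_knockdown =
                           qk_tab$count[match(qc_tab$mirna_id,
                                              qk_tab$mirna_id)],
                         stringsAsFactors = FALSE)
    counts <- counts[counts$count_control + counts$count_knockdown >= 1, ]
    res <- de_test(counts, lib_c$total_clean, lib_k$total_clean,
                   alpha = cfg$alpha_known, min_fold = cfg$min_fold,
                   floor_tpm = cfg$floor_tpm)
    tsv(res$results, "de_known.tsv")
    res
  })

  de_novelcand <- stage("diffexpr_novel", {
    cand <- denovo$candidates
    if (is.null(cand) || !nrow(cand)) {
      list(results = NULL, n_up = 0L, n_down = 0L)
    } else {
      getc <- function(lib, tag) {
        v <- lib$tags[tag]
        as.integer(ifelse(is.na(v), 0L, v))
      }
      counts <- data.frame(mirna_id = cand$tag,
                           count_control = getc(lib_c, cand$tag),
                           count_knockdown = getc(lib_k, cand$tag),
                           stringsAsFactors = FALSE)
      counts <- counts[!duplicated(counts$mirna_id), ]
      res <- de_test(counts, lib_c$total_clean, lib_k$total_clean,
                     alpha = cfg$alpha_novel, min_fold = cfg$min_fold,
                     floor_tpm = cfg$floor_tpm)
      tsv(res$results, "de_novel.tsv")
      res
    }
  })

  report <- list(
    cleaning = lapply(libs, function(l) as.list(l$clean$stats)),
    libraries = list(control = list(unique = lib_c$n_unique,
                                    total = lib_c$total_clean),
                     knockdown = list(unique = lib_k$n_unique,
                                      total = lib_k$total_clean)),
    mapped_fraction = lapply(ann, function(a)
      list(unique = a$map$frac_unique, total = a$map$frac_total)),
    rrna_qc = lapply(ann, function(a) a$qc),
    category_summary = lapply(ann, function(a) a$ann$summary),
    known_de = list(n_up = de$n_up, n_down = de$n_down),
    novel = list(n_candidates = nrow(denovo$candidates %||%
                                       data.frame()),
                 n_up = de_novelcand$n_up, n_down = de_novelcand$n_down))

  # targets + enrichment on the significant known miRNAs
  if (isTRUE(cfg$run_targets)) {
    tgt <- stage("targets", {
      res <- de$results
      sig <- res[res$status != "ns", , drop = FALSE]
      if (!nrow(sig)) {
        list(hits = NULL, agg = NULL)
      } else {
        mat <- as.character(refs$matures)[sig$mirna_id]
        mat <- mat[!is.na(mat)]
        hits <- predict_targets(mat, refs$utr,
                                location_slope = cfg$evd_location,
                                scale_slope = cfg$evd_scale,
                                max_p = cfg$max_p)
        agg <- if (nrow(hits)) {
          aggregate_targets(hits,
                            data.frame(mirna_id = sig$mirna_id,
                                       status = sig$status),
                            cfg$min_mirnas)
        } else NULL
        if (nrow(hits)) tsv(hits, "target_hits.tsv")
        if (!is.null(agg)) tsv(agg, "target_genes.tsv")
        list(hits = hits, agg = agg)
      }
    })
    enr <- stage("enrich", {
      if (is.null(tgt$agg) || !any(tgt$agg$kept)) {
        NULL
      } else {
        kept <- tgt$agg$gene_id[tgt$agg$kept]
        universe <- unique(refs$terms$gene)
        e <- hypergeom_enrich(intersect(kept, universe), refs$terms,
                              universe)
        tsv(e, "enrichment.tsv")
        e
      }
    })
    report$targets <- list(
      n_hits = if (is.null(tgt$hits)) 0L else nrow(tgt$hits),
      n_kept_genes = if (is.null(tgt$agg)) 0L else sum(tgt$agg$kept))
    report$enrichment_top <- if (is.null(enr)) NULL else
      utils::head(enr, 5)
  }

  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' Replay a printed differential-expression table
#'
#' Applies the up/down classification rules to already-printed
#' (log2 fold change, adjusted P) rows — e.g. a published DE table — and
#' returns the up/down counts. Useful both as a check of the
#' classification rules and to re-threshold a table at another fold
#' cutoff.
#'
#' @param rows data.frame with columns `log2fc` and `adj_p` (or
#'   `adj_pvalue`), or the name of a packaged table (see
#'   [load_de_table()]).
#' @param alpha adjusted-P threshold.
#' @param min_fold fold-change threshold (natural scale; 2 = two-fold,
#'   4 = four-fold).
#' @return list with `n_up`, `n_down` and the per-row `status`.
#' @export
table_replay <- function(rows, alpha = 0.01, min_fold = 2) {
  if (is.character(rows) && length(rows) == 1L) {
    rows <- load_de_table(rows)
  }
  if (is.null(rows$adj_pvalue)) rows$adj_pvalue <- rows$adj_p
  if (is.null(rows$log2fc) || is.null(rows$adj_pvalue)) {
    stop("malformed table: need columns log2fc and adj_p/adj_pvalue")
  }
  cl <- classify_de(rows, alpha = alpha, min_fold = min_fold)
  list(n_up = cl$n_up, n_down = cl$n_down,
       status = cl$results$status)
}

#' Packaged differentially-expressed miRNA tables
#'
#' Two published DE tables ship with the package as plain TSV: `"known"`
#' (47 known miRNAs: id, log2fc, direction, adjusted P, genomic
#' location) and `"novel"` (17 novel miRNA candidates: id, log2fc,
#' direction, adjusted P, mature sequence). They serve as replay
#' fixtures for the classification rules.
#'
#' @param name `"known"` or `"novel"`.
#' @return the table as a data.frame.
#' @export
load_de_table <- function(name = c("known", "novel")) {
  name <- match.arg(name)
  f <- system.file("extdata", paste0(name, "_mirna_de_table.tsv"),
                   package = "srnapipe")
  read.delim(f, stringsAsFactors = FALSE)
}
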