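#' Transcripts-per-million normalisation
#'
#' TPM here is the tag count scaled by the library's total clean tags,
#' times one million ("one transcript per million tags").
#'
#' @param count non-negative count(s).
#' @param total_clean library total clean tag count (> 0).
#' @return numeric TPM value(s).
#' @export
tpm <- function(count, total_clean) {
  if (!isTRUE(all(total_clean > 0))) stop("total_clean must be > 0")
  stopifnot(all(count >= 0), all(count <= total_clean))
  count / total_clean * 1e6
}

#' Exact two-library count test
#'
#' Exact conditional test for equal relative abundance of one feature in
#' two sequencing libraries without replicates (Audic-Claverie in
#' spirit). Conditional on the combined count `n = x + y`, the knockdown
#' count is Binomial(n, N2/(N1+N2)) under the null; the two-sided p-value
#' sums the probabilities of all outcomes no more likely than the
#' observed one (minimum-likelihood rule).
#'
#' @param x,y counts in library 1 (control) and library 2 (knockdown).
#' @param N1,N2 total clean tags of the two libraries.
#' @return two-sided p-value in (0, 1].
#' @export
two_library_test <- function(x, y, N1, N2) {
  stopifnot(N1 > 0, N2 > 0, x >= 0, y >= 0)
  if (x + y < 1) stop("untestable: x + y must be >= 1")
  n <- x + y
  pr <- dbinom(0:n, n, N2 / (N1 + N2))
  pobs <- pr[y + 1]
  min(1, sum(pr[pr <= pobs * (1 + 1e-9)]))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  m <- length(pvalues)
  if (m == 0) return(numeric(0))
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / seq(m, 1) * pvalues[o]))[ro]
  adj
}

#' Log2 fold change with a zero floor
#'
#' Zeros are replaced by `floor` TPM before forming the ratio, mirroring
#' the finite large fold changes printed for miRNAs absent from one
#' library.
#'
#' @param tpm_control,tpm_knockdown TPM values (>= 0, not both 0).
#' @param floor replacement for zero TPM, default 0.01.
#' @return log2(knockdown / control).
#' @export
fold_change <- function(tpm_control, tpm_knockdown, floor = 0.01) {
  stopifnot(all(tpm_control >= 0), all(tpm_knockdown >= 0))
  if (any(tpm_control == 0 & tpm_knockdown == 0)) {
    stop("fold change undefined when both TPMs are 0")
  }
  log2(pmax(tpm_knockdown, floor) / pmax(tpm_control, floor))
}

#' Classify differential expression calls
#'
#' A miRNA is `up` when log2fc >= log2(min_fold) and adjusted P < alpha,
#' `down` when log2fc <= -log2(min_fold) and adjusted P < alpha, `ns`
#' otherwise.
#'
#' @param results data.frame with columns `log2fc` and `adj_pvalue`.
#' @param alpha significance level (0.01 for known miRNAs, 0.05 for
#'   novel candidates by default elsewhere).
#' @param min_fold fold-change threshold on the natural scale, default 2.
#' @return the input with a `status` column plus attributes; see also the
#'   returned `n_up` / `n_down` in the list.
#' @export
classify_de <- function(results, alpha = 0.01, min_fold = 2) {
  lf <- log2(min_fold)
  status <- rep.int("ns", nrow(results))
  status[results$log2fc >= lf & results$adj_pvalue < alpha] <- "up"
  status[results$log2fc <= -lf & results$adj_pvalue < alpha] <- "down"
  results$status <- status
  list(results = results,
       n_up = sum(status == "up"), n_down = sum(status == "down"))
}

#' Two-library differential expression of miRNAs
#'
#' End-to-end DE for a two-library count table: TPM normalisation, the
#' exact conditional test, BH adjustment, fold change with zero floor and
#' up/down/ns classification. Rows with zero counts in both libraries are
#' dropped (untestable).
#'
#' @param counts data.frame with columns `mirna_id`, `count_control`,
#'   `count_knockdown`.
#' @param N1,N2 library totals (total clean tags).
#' @param alpha significance level, default 0.01.
#' @param min_fold fold threshold, default 2.
#' @param floor_tpm zero-replacement floor for fold change, default 0.01.
#' @return list with `results` (DE table: counts, TPMs, log2fc, pvalue,
#'   adj_pvalue, status), `n_up`, `n_down`.
#' @export
de_test <- function(counts, N1, N2, alpha = 0.01, min_fold = 2,
                    floor_tpm = 0.01) {
  keep <- counts$count_control + counts$count_knockdown >= 1
  d <- counts[keep, , drop = FALSE]
  if (!nrow(d)) stop("no testable rows (all zero in both libraries)")
  d$tpm_control <- tpm(d$count_control, N1)
  d$tpm_knockdown <- tpm(d$count_knockdown, N2)
  d$log2fc <- fold_change(d$tpm_control, d$tpm_knockdown, floor_tpm)
  d$pvalue <- mapply(two_library_test, d$count_control,
                     d$count_knockdown, MoreArgs = list(N1 = N1, N2 = N2))
  d$adj_pvalue <- bh_adjust(d$pvalue)
  cl <- classify_de(d, alpha = alpha, min_fold = min_fold)
  rownames(cl$results) <- NULL
  cl
}

#' Library-specific miRNAs
#'
#' miRNAs expressed (count >= 1) in exactly one of the two libraries.
#'
#' @param counts data.frame with `mirna_id`, `count_control`,
#'   `count_knockdown`.
#' @return list with `control_specific` and `knockdown_specific` id
#'   vectors.
#' @export
sample_specific <- function(counts) {
  list(control_specific =
         counts$mirna_id[counts$count_control >= 1 &
                           counts$count_knockdown == 0],
       knockdown_specific =
         counts$mirna_id[counts$count_knockdown >= 1 &
                           counts$count_control == 0])
}
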