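#' Cell-level quality control for scRNA-seq counts
#'
#' A cell fails when its exon-mapped (non-spike-in) read total is below
#' `min_reads`, or when the ERCC spike-in fraction of its reads exceeds
#' `max_ercc_frac`. If the matrix carries no ERCC rows the spike-in
#' criterion is skipped with a warning.
#'
#' @param counts integer gene x cell matrix including ERCC rows.
#' @param is_ercc logical per row.
#' @param min_reads minimum exon-mapped reads (default 10,000).
#' @param max_ercc_frac maximum spike-in read fraction (default 0.2).
#' @return list: `qc_pass` logical per cell, `report` data.frame with
#'   per-cell totals and ERCC fractions and the failure reason.
#' @export
qc_cells <- function(counts, is_ercc, min_reads = 1e4,
                     max_ercc_frac = 0.2) {
  stopifnot(nrow(counts) == length(is_ercc))
  gene_tot <- colSums(counts[!is_ercc, , drop = FALSE])
  if (!any(is_ercc)) {
    warning("no ERCC rows; spike-in fraction criterion skipped")
    ercc_frac <- rep(NA_real_, ncol(counts))
    fail_ercc <- rep(FALSE, ncol(counts))
  } else {
    ercc_tot <- colSums(counts[is_ercc, , drop = FALSE])
    ercc_frac <- ercc_tot / pmax(1, gene_tot + ercc_tot)
    fail_ercc <- ercc_frac > max_ercc_frac
  }
  fail_depth <- gene_tot < min_reads
  qc_pass <- !(fail_depth | fail_ercc)
  reason <- rep("pass", ncol(counts))
  reason[fail_ercc] <- "ercc_fraction"
  reason[fail_depth] <- "low_depth"
  reason[fail_depth & fail_ercc] <- "low_depth+ercc_fraction"
  cells <- if (is.null(colnames(counts))) as.character(seq_len(ncol(counts)))
           else colnames(counts)
  list(qc_pass = qc_pass,
       report = data.frame(cell = cells,
                           exon_reads = gene_tot, ercc_frac = ercc_frac,
                           qc_pass = qc_pass, reason = reason,
                           row.names = NULL))
}

#' RPM / RPKM normalization
#'
#' `RPKM = counts * 1e9 / (gene_length * exon-mapped reads of the cell)`;
#' RPM rescales counts to reads per million exon-mapped reads. ERCC rows
#' are normalized with the same denominators but flagged and excluded from
#' the per-cell totals.
#'
#' @param counts integer gene x cell matrix.
#' @param gene_length per-gene length in bases (named or in row order).
#' @param is_ercc logical per row; default all FALSE.
#' @param qc_pass optional logical per cell; failing cells are dropped.
#' @return list of class `expression_matrix`: `rpkm`, `rpm`, `counts`,
#'   `gene_length`, `is_ercc`, `qc_pass`.
#' @export
normalize_expression <- function(counts, gene_length,
                                 is_ercc = rep(FALSE, nrow(counts)),
                                 qc_pass = NULL) {
  stopifnot(nrow(counts) == length(gene_length),
            nrow(counts) == length(is_ercc))
  if (!is.null(qc_pass)) counts <- counts[, qc_pass, drop = FALSE]
  tot <- colSums(counts[!is_ercc, , drop = FALSE])
  if (any(tot == 0)) stop("kept cell with zero exon-mapped reads")
  rpm <- sweep(counts, 2, tot / 1e6, "/")
  rpkm <- sweep(rpm, 1, gene_length / 1e3, "/")
  structure(list(rpkm = rpkm, rpm = rpm, counts = counts,
                 gene_length = gene_length, is_ercc = is_ercc,
                 qc_pass = if (is.null(qc_pass)) rep(TRUE, ncol(counts))
                           else qc_pass),
            class = "expression_matrix")
}

#' Compare two library-preparation protocols on a common gene universe
#'
#' For two groups of cells profiled with different protocols, computes the
#' per-gene logarithmic mean expression (LME; mean of log2(RPKM + 1) over
#' cells) in each group, their ratio DE-prot = LME_A / LME_B, and the
#' product score pooled-LME x DE-prot; genes with score above
#' `diff_threshold` are flagged as differing between protocols. Only genes
#' whose pooled LME exceeds `detect_threshold` enter. Also reports the
#' Pearson correlation of per-gene log means between the groups.
#'
#' The pooled LME is the mean of log expression across all cells of both
#' groups. With `ratio_of_logs = FALSE`, DE-prot is computed as the
#' log2 ratio of (linear) mean RPKMs instead of the ratio of log-means.
#'
#' @param expr_a,expr_b RPKM gene x cell matrices with identical rownames.
#' @param detect_threshold minimum pooled log2 RPKM (default 1).
#' @param diff_threshold score flag level (default 8).
#' @param ratio_of_logs compute DE-prot as a ratio of log-means (default
#'   TRUE, the literal rule) or as a log-ratio of means.
#' @return list: `table` (gene, lme_a, lme_b, lme_pooled, de_prot, score,
#'   flag_different, excluded_reason), `pearson` of per-gene log means.
#' @export
protocol_comparison <- function(expr_a, expr_b, detect_threshold = 1,
                                diff_threshold = 8, ratio_of_logs = TRUE) {
  stopifnot(identical(rownames(expr_a), rownames(expr_b)))
  la <- log2(expr_a + 1); lb <- log2(expr_b + 1)
  lme_a <- rowMeans(la); lme_b <- rowMeans(lb)
  lme_pool <- rowMeans(cbind(la, lb))
  keep <- lme_pool > detect_threshold
  g <- rownames(expr_a)[keep]
  a <- lme_a[keep]; b <- lme_b[keep]; pool <- lme_pool[keep]
  excluded <- rep(NA_character_, length(g))
  if (ratio_of_logs) {
    bad <- b == 0
    de <- ifelse(bad, NA_real_, a / b)
    excluded[bad] <- "divide_by_zero"
  } else {
    ma <- rowMeans(expr_a)[keep]; mb <- rowMeans(expr_b)[keep]
    bad <- mb == 0
    de <- ifelse(bad, NA_real_, log2(ma / mb))
    excluded[bad] <- "divide_by_zero"
  }
  score <- pool * de
  list(table = data.frame(gene = g, lme_a = a, lme_b = b,
                          lme_pooled = pool, de_prot = de, score = score,
                          flag_different = !is.na(score) &
                            score > diff_threshold,
                          excluded_reason = excluded, row.names = NULL),
       pearson = stats::cor(a, b))
}
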