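#' Cell-cycle module scores and phase assignment
#'
#' Bin-matched module scoring: genes are binned (default 25 bins) on their
#' average expression across cells; for each marker gene, `n_ctrl` control
#' genes are sampled (seeded) from the same bin, and a cell's score for a
#' marker set is the mean scaled (per-gene z-scored) marker expression
#' minus the mean scaled control expression. A cell is assigned to S or
#' G2M by the larger of the two scores when that maximum is positive, and
#' to G1 otherwise. The bin count is capped so that each bin holds at
#' least ~8 genes; with panels far smaller than a transcriptome the
#' nominal 25 bins would leave too few control candidates per bin.
#'
#' @param expr log-scale gene x cell expression matrix (e.g.
#'   log2(RPKM + 1)).
#' @param s_genes,g2m_genes character vectors of S-phase and G2/M marker
#'   genes (must intersect rownames of `expr`).
#' @param n_bins number of average-expression bins (default 25).
#' @param n_ctrl control genes sampled per marker gene (default 50).
#' @param seed integer seed for control sampling.
#' @return data.frame (`cell_state`): cell, s_score, g2m_score, phase.
#' @export
phase_scores <- function(expr, s_genes, g2m_genes, n_bins = 25,
                         n_ctrl = 50, seed = 1L) {
  s_genes <- intersect(s_genes, rownames(expr))
  g2m_genes <- intersect(g2m_genes, rownames(expr))
  if (!length(s_genes) || !length(g2m_genes))
    stop("marker set absent from the expression matrix")
  avg <- rowMeans(expr)
  n_bins <- max(2L, min(n_bins, floor(nrow(expr) / 8)))
  bin <- cut(rank(avg, ties.method = "first"),
             breaks = n_bins, labels = FALSE)
  names(bin) <- rownames(expr)
  markers <- c(s_genes, g2m_genes)
  z <- expr - rowMeans(expr)
  rsd <- apply(expr, 1, stats::sd)
  z <- z / ifelse(rsd > 0, rsd, 1)

  score_set <- function(set, stream) {
    ctrl <- with_seed(derive_seed(seed, stream), {
      unlist(lapply(set, function(g) {
        pool <- setdiff(names(bin)[bin == bin[g]], markers)
        if (!length(pool)) pool <- setdiff(names(bin), markers)
        sample(pool, min(n_ctrl, length(pool)))
      }))
    })
    colMeans(z[set, , drop = FALSE]) -
      colMeans(z[unique(ctrl), , drop = FALSE])
  }
  s <- score_set(s_genes, "phase_s")
  g2m <- score_set(g2m_genes, "phase_g2m")
  phase <- ifelse(pmax(s, g2m) <= 0, "G1", ifelse(s >= g2m, "S", "G2M"))
  data.frame(cell = colnames(expr), s_score = s, g2m_score = g2m,
             phase = phase, row.names = NULL)
}

#' Regress technical/cell-state covariates out of expression
#'
#' Per gene, fits ordinary least squares of expression on the supplied
#' covariates (with intercept) and returns the residual matrix. Residuals
#' are uncorrelated with every retained covariate by construction.
#' Constant covariates are dropped with a warning.
#'
#' @param expr gene x cell matrix (log scale recommended).
#' @param covariates data.frame or matrix, one row per cell (e.g.
#'   n_detected_genes, s_score, g2m_score).
#' @return residual gene x cell matrix.
#' @export
regress_covariates <- function(expr, covariates) {
  cov <- as.data.frame(covariates)
  stopifnot(nrow(cov) == ncol(expr))
  keep <- vapply(cov, function(x) stats::var(as.numeric(x)) > 0, logical(1))
  if (any(!keep)) {
    warning("dropping constant covariate(s): ",
            paste(names(cov)[!keep], collapse = ", "))
    cov <- cov[, keep, drop = FALSE]
  }
  X <- stats::model.matrix(~ ., data = cov)
  qrX <- qr(X)
  res <- t(qr.resid(qrX, t(expr)))
  dimnames(res) <- dimnames(expr)
  res
}
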