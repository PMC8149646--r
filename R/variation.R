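#' Per-gene mean and squared coefficient of variation
#'
#' `CV2 = variance / mean^2` across cells (sample variance). Genes with
#' zero mean are excluded; CV2 is scale-free, so multiplying a gene's
#' expression by a constant leaves it unchanged.
#'
#' @param expr gene x cell matrix (RPKM for RNA, signal units for
#'   protein).
#' @param cells optional column subset (indices, names or logical), e.g.
#'   S-phase cells only.
#' @return data.frame: gene, mean_expr, cv2.
#' @export
cv2_table <- function(expr, cells = NULL) {
  if (!is.null(cells)) expr <- expr[, cells, drop = FALSE]
  if (ncol(expr) < 3) stop("need at least 3 cells for CV2")
  m <- rowMeans(expr)
  v <- apply(expr, 1, stats::var)
  keep <- m > 0
  data.frame(gene = rownames(expr)[keep], mean_expr = m[keep],
             cv2 = v[keep] / m[keep]^2, row.names = NULL)
}

#' Mean-dependence fit of expression variation
#'
#' Least-squares polynomial (default degree 2) of log CV2 on log mean
#' expression; the residual of each gene from the fitted trend is its
#' mean-independent ("normalized") variation, positive when the gene is
#' more variable than the trend predicts. Natural logs are used; residuals
#' are scale-free either way. Genes with CV2 = 0 cannot enter the log-space
#' fit and get NA residuals.
#'
#' @param mean_expr,cv2 numeric vectors per gene (as from [cv2_table()]).
#' @param degree polynomial degree (default 2).
#' @return list: `resid` per gene (NA outside the fit support),
#'   `fitted` per gene, `coefficients`.
#' @export
mean_variation_fit <- function(mean_expr, cv2, degree = 2) {
  ok <- is.finite(mean_expr) & is.finite(cv2) & mean_expr > 0 & cv2 > 0
  if (sum(ok) < degree + 2)
    stop("need at least degree + 2 genes with positive mean and CV2")
  lx <- log(mean_expr[ok]); ly <- log(cv2[ok])
  fit <- stats::lm(ly ~ poly(lx, degree, raw = TRUE))
  fitted <- resid <- rep(NA_real_, length(mean_expr))
  fitted[ok] <- stats::fitted(fit)
  resid[ok] <- ly - fitted[ok]
  names(fitted) <- names(resid) <- names(mean_expr)
  list(resid = resid, fitted = fitted,
       coefficients = stats::coef(fit))
}

#' Cross-level (RNA vs protein) variation comparison
#'
#' Spearman correlation of normalized variation between modalities over
#' shared genes, plus variable/stable labels from the residual sign.
#'
#' @param resid_rna,resid_prot named residual vectors from
#'   [mean_variation_fit()].
#' @return list: `rho`, `n`, `table` (gene, resid_rna, resid_prot,
#'   label_rna, label_prot).
#' @export
cross_level_variation <- function(resid_rna, resid_prot) {
  shared <- intersect(names(resid_rna)[is.finite(resid_rna)],
                      names(resid_prot)[is.finite(resid_prot)])
  if (length(shared) < 5) stop("fewer than 5 shared genes")
  r <- resid_rna[shared]; p <- resid_prot[shared]
  list(rho = spearman(r, p), n = length(shared),
       table = data.frame(gene = shared, resid_rna = r, resid_prot = p,
                          label_rna = ifelse(r > 0, "variable", "stable"),
                          label_prot = ifelse(p > 0, "variable", "stable"),
                          row.names = NULL))
}

#' Translation-rate estimate from bulk protein and RNA abundance
#'
#' `trans_rate = log2(protein_abundance / rpkm_mean)` per gene; genes with
#' a non-positive value in either input are skipped with a reason.
#'
#' @param protein_abundance named per-gene bulk protein abundances.
#' @param rpkm_mean named per-gene mean RPKM.
#' @return list: `trans_rate` named vector over usable shared genes,
#'   `skipped` data.frame (gene, reason).
#' @export
translation_rate <- function(protein_abundance, rpkm_mean) {
  shared <- intersect(names(protein_abundance), names(rpkm_mean))
  pa <- protein_abundance[shared]; rm <- rpkm_mean[shared]
  bad <- !is.finite(pa) | !is.finite(rm) | pa <= 0 | rm <= 0
  skipped <- data.frame(gene = shared[bad],
                        reason = rep("non_positive_input", sum(bad)),
                        row.names = NULL)
  list(trans_rate = log2(pa[!bad] / rm[!bad]), skipped = skipped)
}

#' Additive predictor of protein expression variability
#'
#' `combined = resid_rna + w * trans_rate` (default weight 0.75, a fixed
#' compromise between the different dynamic ranges of the two inputs).
#' Reports Spearman correlations of the combined predictor, the RNA
#' residuals alone, and the translation rate alone against the protein
#' residual variation, over genes where all quantities exist.
#'
#' @param resid_rna named RNA residual-variation vector.
#' @param trans_rate named translation-rate vector.
#' @param resid_prot named protein residual-variation vector.
#' @param w weight on the translation rate (default 0.75; must be >= 0).
#' @return list: `combined` named vector, `rho_combined`, `rho_rna`,
#'   `rho_trans`, `n`.
#' @export
combined_predictor <- function(resid_rna, trans_rate, resid_prot,
                               w = 0.75) {
  if (w < 0) stop("weight w must be non-negative")
  shared <- Reduce(intersect, list(
    names(resid_rna)[is.finite(resid_rna)],
    names(trans_rate)[is.finite(trans_rate)],
    names(resid_prot)[is.finite(resid_prot)]))
  if (length(shared) < 5) stop("fewer than 5 genes with all quantities")
  comb <- resid_rna[shared] + w * trans_rate[shared]
  list(combined = comb,
       rho_combined = spearman(comb, resid_prot[shared]),
       rho_rna = spearman(resid_rna[shared], resid_prot[shared]),
       rho_trans = spearman(trans_rate[shared], resid_prot[shared]),
       n = length(shared))
}
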