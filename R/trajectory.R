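#' Genes changing along the trajectory
#'
#' Per gene, tests association between expression and pseudotime with a
#' natural cubic spline fit (default 3 df) against an intercept-only model
#' (F-test), adjusts p-values by Benjamini-Hochberg, and clusters the
#' standardized fitted profiles of significant genes into expression
#' modules by k-means. Constant genes get p = 1 by convention.
#'
#' @param expr gene x cell matrix (log scale recommended).
#' @param pt pseudotime per cell (hours or [0, 1]).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param df spline degrees of freedom (default 3).
#' @param n_modules number of expression modules among significant genes
#'   (default 2).
#' @param seed seed for the module k-means.
#' @return data.frame: gene, p_value, p_adjusted, significant, module
#'   (NA for non-significant genes).
#' @export
trajectory_genes <- function(expr, pt, alpha = 0.05, df = 3,
                             n_modules = 2, seed = 1L) {
  stopifnot(ncol(expr) == length(pt))
  X <- splines::ns(pt, df = df)
  fit_p <- function(y) {
    if (stats::var(y) == 0) return(1)
    m1 <- stats::lm(y ~ X)
    m0 <- stats::lm(y ~ 1)
    stats::anova(m0, m1)$`Pr(>F)`[2]
  }
  p <- apply(expr, 1, fit_p)
  padj <- stats::p.adjust(p, method = "BH")
  sig <- padj < alpha
  module <- rep(NA_integer_, nrow(expr))
  if (sum(sig) >= n_modules) {
    fitted <- t(apply(expr[sig, , drop = FALSE], 1, function(y)
      stats::fitted(stats::lm(y ~ X))))
    prof <- t(scale(t(fitted)))
    prof[!is.finite(prof)] <- 0
    km <- with_seed(derive_seed(seed, "modules"),
                    stats::kmeans(prof, centers = n_modules, nstart = 5))
    module[sig] <- km$cluster
  }
  data.frame(gene = rownames(expr), p_value = p, p_adjusted = padj,
             significant = sig, module = module, row.names = NULL)
}

#' RNA-slope vs protein-slope concordance
#'
#' For each gene, fits ordinary least squares of log RPKM on pseudotime
#' (slope `k_lRPKM`) and of the protein measurement on pseudotime (slope
#' `k_prot`), using only cells where the modality is detected, then
#' regresses the protein slopes on the RNA slopes across genes:
#' `k_prot = x * k_lRPKM + z`, reporting the cross-fit slope `x`,
#' intercept `z`, R-squared and Pearson r.
#'
#' @param log_rpkm gene x cell matrix of log RPKM values.
#' @param protein gene x cell matrix of protein measurements over the same
#'   cells, rows named like `log_rpkm` (the gene pairs to use).
#' @param pt pseudotime in hours per cell.
#' @param min_cells minimum detected cells per gene and modality
#'   (default 3).
#' @return list of class `slope_fit`: `slopes` data.frame (gene, k_rna,
#'   i_rna, k_prot, i_prot), `x`, `z`, `r_squared`, `pearson`, `n_genes`.
#' @export
slope_concordance <- function(log_rpkm, protein, pt, min_cells = 3) {
  genes <- intersect(rownames(log_rpkm), rownames(protein))
  stopifnot(ncol(log_rpkm) == length(pt), ncol(protein) == length(pt))
  rows <- lapply(genes, function(g) {
    yr <- log_rpkm[g, ]
    yp <- protein[g, ]
    det_p <- is.finite(yp) & yp != 0
    if (sum(is.finite(yr)) < min_cells || sum(det_p) < min_cells)
      return(NULL)
    fr <- stats::lm.fit(cbind(1, pt), yr)$coefficients
    fp <- stats::lm.fit(cbind(1, pt[det_p]), yp[det_p])$coefficients
    data.frame(gene = g, k_rna = fr[2], i_rna = fr[1],
               k_prot = fp[2], i_prot = fp[1])
  })
  slopes <- do.call(rbind, rows)
  if (is.null(slopes) || nrow(slopes) < 3)
    stop("fewer than 3 genes with slopes in both modalities")
  if (stats::var(slopes$k_rna) == 0)
    stop("degenerate predictor: all RNA slopes identical")
  fit <- stats::lm(k_prot ~ k_rna, data = slopes)
  r <- stats::cor(slopes$k_rna, slopes$k_prot)
  structure(list(slopes = slopes,
                 x = unname(stats::coef(fit)[2]),
                 z = unname(stats::coef(fit)[1]),
                 r_squared = r^2,  # = summary(fit)$r.squared for simple OLS
                 pearson = r,
                 n_genes = nrow(slopes)),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf(
    "slope concordance over %d genes: k_prot = %.3f * k_rna + %.3f (R2 = %.3f, r = %.3f)\n",
    x$n_genes, x$x, x$z, x$r_squared, x$pearson))
  invisible(x)
}
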