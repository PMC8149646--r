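#' Expressed-gene filter
#'
#' Genes with mean RPKM of at least `min_mean_rpkm` across the analysis
#' group's cells (boundary inclusive).
#'
#' @param rpkm gene x cell RPKM matrix.
#' @param min_mean_rpkm threshold (default 2).
#' @return character vector of gene ids.
#' @export
expressed_genes <- function(rpkm, min_mean_rpkm = 2) {
  out <- rownames(rpkm)[rowMeans(rpkm) >= min_mean_rpkm]
  if (!length(out)) stop("no genes pass the expression filter")
  out
}

#' TF-to-gene regulatory link weights
#'
#' For each candidate target gene, scores the dependence of its expression
#' on a transcription-factor profile (RNA log-expression or protein
#' signal) over the same cells. Two methods:
#'
#' * `"trees"`: a reduced tree-ensemble importance. Per gene, a regression
#'   forest predicts the gene from the TF profile plus `n_decoys` seeded
#'   decoy predictors (permutations of the TF profile, which share its
#'   marginal but carry no signal); the link weight is the TF's share of
#'   total variable importance. Decoys calibrate the importance null in
#'   place of a full all-gene predictor matrix.
#' * `"pearson"`: the absolute Pearson correlation.
#'
#' The signed Pearson correlation and its p-value are computed in both
#' modes (the sign reports whether a target is up- or down-regulated), and
#' BH FDR is computed across genes.
#'
#' @param tf_profile numeric vector per cell (zero variance is an error).
#' @param expr gene x cell matrix of candidate target expression.
#' @param method `"trees"` or `"pearson"`.
#' @param n_trees trees per forest (default 100).
#' @param n_decoys decoy predictors (default 20).
#' @param seed integer seed (decoys and forests).
#' @return data.frame (`link_table`): gene, weight, pearson_r, p_value,
#'   fdr.
#' @export
link_weights <- function(tf_profile, expr,
                         method = c("trees", "pearson"),
                         n_trees = 100, n_decoys = 20, seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(tf_profile) == ncol(expr))
  if (stats::var(tf_profile) == 0)
    stop("zero-variance TF profile")
  ct <- apply(expr, 1, function(y) {
    if (stats::var(y) == 0) return(c(0, 1))
    h <- stats::cor.test(tf_profile, y)
    c(h$estimate, h$p.value)
  })
  r <- ct[1, ]; pv <- ct[2, ]
  if (method == "pearson") {
    w <- abs(r)
  } else {
    w <- with_seed(derive_seed(seed, "link_trees"), {
      X <- cbind(tf = tf_profile,
                 vapply(seq_len(n_decoys), function(i) sample(tf_profile),
                        numeric(length(tf_profile))))
      colnames(X) <- c("tf", paste0("decoy", seq_len(n_decoys)))
      apply(expr, 1, function(y) {
        if (stats::var(y) == 0) return(0)
        rf <- randomForest::randomForest(X, y, ntree = n_trees)
        imp <- pmax(randomForest::importance(rf)[, 1], 0)
        # the TF is the first predictor column
        if (sum(imp) == 0) 0 else unname(imp[1] / sum(imp))
      })
    })
  }
  data.frame(gene = rownames(expr), weight = unname(w),
             pearson_r = unname(r), p_value = unname(pv),
             fdr = stats::p.adjust(pv, method = "BH"), row.names = NULL)
}

#' Target vs background separation test
#'
#' One-sided Wilcoxon rank-sum test that the link statistic (absolute
#' Pearson correlation by default, or the ensemble weight) of the TF's
#' annotated targets exceeds that of non-target background genes. Also
#' returns the rank-biserial effect size.
#'
#' @param link a `link_table` from [link_weights()].
#' @param target_set,background_set disjoint character vectors of gene
#'   ids present in `link`.
#' @param stat `"pearson"` (|r|) or `"weight"`.
#' @return list: `p` one-sided p-value, `effect` rank-biserial
#'   correlation, `n_target`, `n_background`.
#' @export
target_separation <- function(link, target_set, background_set,
                              stat = c("pearson", "weight")) {
  stat <- match.arg(stat)
  if (length(intersect(target_set, background_set)))
    stop("target and background sets overlap")
  v <- if (stat == "pearson") abs(link$pearson_r) else link$weight
  names(v) <- link$gene
  x <- v[intersect(target_set, link$gene)]
  y <- v[intersect(background_set, link$gene)]
  if (!length(x) || !length(y)) stop("empty set after matching to link table")
  ht <- stats::wilcox.test(x, y, alternative = "greater", exact = FALSE,
                           correct = TRUE)
  u <- unname(ht$statistic)
  list(p = ht$p.value, effect = 2 * u / (length(x) * length(y)) - 1,
       n_target = length(x), n_background = length(y))
}

#' ROC curve and AUC of a gene ranking against known positives
#'
#' Ranks genes by decreasing weight and accumulates true/false positive
#' rates; tied weights are treated as blocks (curve vertices only at block
#' boundaries), so the trapezoidal AUC equals the tie-corrected
#' Mann-Whitney statistic U / (n_pos * n_neg). The Youden point maximizes
#' TPR - FPR.
#'
#' @param weights named numeric vector of link weights per gene.
#' @param positives character vector (gene names) or logical vector
#'   marking the true targets.
#' @return list of class `roc_result`: `fpr`, `tpr`, `thresholds`, `auc`,
#'   `youden` (list threshold/tpr/fpr/j), `n_pos`, `n_neg`, `degenerate`.
#' @export
roc_auc <- function(weights, positives) {
  if (is.character(positives)) positives <- names(weights) %in% positives
  stopifnot(length(positives) == length(weights))
  n_pos <- sum(positives); n_neg <- sum(!positives)
  if (n_pos < 1 || n_neg < 1) stop("need at least one positive and one negative")
  o <- order(weights, decreasing = TRUE)
  w <- weights[o]; lab <- positives[o]
  blocks <- !duplicated(w)
  idx <- c(which(blocks)[-1] - 1L, length(w))  # last index of each block
  tp <- cumsum(lab)[idx]; fp <- cumsum(!lab)[idx]
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  auc <- sum((fpr[-1] - fpr[-length(fpr)]) *
               (tpr[-1] + tpr[-length(tpr)]) / 2)
  j <- tpr - fpr
  jy <- which.max(j)
  thr <- c(Inf, w[blocks])
  degenerate <- length(unique(w)) == 1L
  structure(list(fpr = fpr, tpr = tpr, thresholds = thr, auc = auc,
                 youden = list(threshold = thr[jy], tpr = tpr[jy],
                               fpr = fpr[jy], j = j[jy]),
                 n_pos = n_pos, n_neg = n_neg, degenerate = degenerate),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC over %d positives / %d negatives: AUC = %.4f%s\n",
              x$n_pos, x$n_neg, x$auc,
              if (x$degenerate) " (degenerate: all weights tied)" else ""))
  invisible(x)
}

#' Permutation null of the ROC AUC
#'
#' Repeatedly re-draws which `n_pos` genes are labelled positives
#' (uniformly, without replacement) under a fixed ranking, computing the
#' AUC each time. By exchangeability the null mean tends to 0.5; the
#' sample SD estimates the chance spread of the AUC.
#'
#' @param weights named numeric vector (the fixed ranking).
#' @param n_pos number of positives per draw.
#' @param n_perm permutations (default 200).
#' @param seed integer seed.
#' @return list: `mean`, `sd`, `auc` (the n_perm values).
#' @export
permutation_null <- function(weights, n_pos, n_perm = 200, seed = 1L) {
  if (n_perm < 2) stop("n_perm must be >= 2")
  if (n_pos >= length(weights)) stop("n_pos must be below the gene count")
  aucs <- with_seed(derive_seed(seed, "perm_null"), {
    vapply(seq_len(n_perm), function(i) {
      pos <- logical(length(weights))
      pos[sample.int(length(weights), n_pos)] <- TRUE
      roc_auc(weights, pos)$auc
    }, numeric(1))
  })
  list(mean = mean(aucs), sd = stats::sd(aucs), auc = aucs)
}

#' Two-stage discovery of novel TF targets
#'
#' Across several analysis groups (e.g. steady-state vs dynamic cells,
#' TF measured as RNA vs protein), a gene is reported as a candidate
#' target if it (i) ranks in the top `top_frac` of link weights in at
#' least one group, (ii) has binding evidence near its TSS
#' (`binding_set`, a pre-curated list), and (iii) is significant
#' (FDR < `fdr_threshold`) in at least `min_groups` groups.
#'
#' @param link_tables named list of `link_table` data.frames (>= 2).
#' @param binding_set character vector of genes with TF-binding evidence.
#' @param top_frac top quantile of weights per group (default 0.05).
#' @param min_groups minimum significant groups (default 2).
#' @param fdr_threshold FDR level (default 0.05).
#' @return data.frame: gene, n_top, n_significant, in_binding, plus one
#'   logical top/significant column pair per group; rows are the
#'   candidates passing all three rules.
#' @export
discover_targets <- function(link_tables, binding_set, top_frac = 0.05,
                             min_groups = 2, fdr_threshold = 0.05) {
  if (length(link_tables) < 2) stop("need at least 2 analysis groups")
  if (!length(binding_set)) stop("binding_set is empty")
  if (is.null(names(link_tables)))
    names(link_tables) <- paste0("group", seq_along(link_tables))
  genes <- unique(unlist(lapply(link_tables, `[[`, "gene")))
  top <- sig <- matrix(FALSE, length(genes), length(link_tables),
                       dimnames = list(genes, names(link_tables)))
  for (g in names(link_tables)) {
    lt <- link_tables[[g]]
    k <- max(1L, floor(top_frac * nrow(lt)))
    top_genes <- lt$gene[order(lt$weight, decreasing = TRUE)][seq_len(k)]
    top[lt$gene[lt$gene %in% top_genes], g] <- TRUE
    sig[lt$gene[lt$fdr < fdr_threshold], g] <- TRUE
  }
  keep <- rowSums(top) >= 1 & genes %in% binding_set &
    rowSums(sig) >= min_groups
  out <- data.frame(gene = genes, n_top = rowSums(top),
                    n_significant = rowSums(sig),
                    in_binding = genes %in% binding_set,
                    row.names = NULL)
  out <- cbind(out, top = top, significant = sig)
  out[keep, , drop = FALSE]
}
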