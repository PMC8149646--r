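#' Reduce cells to a 3-D embedding
#'
#' tSNE (perplexity 30, seeded) when at least `min_tsne` cells are present
#' and the Rtsne package is installed; PCA otherwise. tSNE is unstable for
#' very small data sets, hence the fallback.
#'
#' @param x cell x feature matrix (e.g. the transposed residual matrix).
#' @param ndim output dimensions (default 3).
#' @param method `"auto"`, `"tsne"` or `"pca"`.
#' @param perplexity tSNE perplexity (default 30, reduced automatically if
#'   too large for the cell count).
#' @param min_tsne minimum cells for tSNE under `"auto"` (default 50).
#' @param scale_features z-score each feature before embedding (default
#'   TRUE, the usual scale-data step; constant features are dropped).
#' @param seed integer seed.
#' @return cell x ndim coordinate matrix.
#' @export
reduce_dims <- function(x, ndim = 3, method = c("auto", "tsne", "pca"),
                        perplexity = 30, min_tsne = 50,
                        scale_features = TRUE, seed = 1L) {
  method <- match.arg(method)
  if (scale_features) {
    v <- apply(x, 2, stats::var)
    x <- scale(x[, v > 0, drop = FALSE])
  }
  n <- nrow(x)
  use_tsne <- switch(method,
                     auto = n >= min_tsne &&
                       requireNamespace("Rtsne", quietly = TRUE),
                     tsne = TRUE, pca = FALSE)
  if (use_tsne) {
    perp <- min(perplexity, floor((n - 1) / 3))
    emb <- with_seed(derive_seed(seed, "tsne"),
                     Rtsne::Rtsne(x, dims = ndim, perplexity = perp,
                                  check_duplicates = FALSE)$Y)
  } else {
    emb <- stats::prcomp(x, rank. = ndim)$x
  }
  rownames(emb) <- rownames(x)
  emb
}

# Project points onto a polyline; returns arc-length position and the
# mean distance from each point to its projection.
project_polyline <- function(points, curve) {
  nseg <- nrow(curve) - 1L
  seg_len <- sqrt(rowSums((curve[-1, , drop = FALSE] -
                             curve[-nrow(curve), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg_len))
  n <- nrow(points)
  best_d2 <- rep(Inf, n)
  best_pos <- numeric(n)
  best_proj <- matrix(0, n, ncol(points))
  for (s in seq_len(nseg)) {
    a <- curve[s, ]; b <- curve[s + 1L, ]
    ab <- b - a
    ab2 <- sum(ab^2)
    if (ab2 == 0) next
    t <- pmin(1, pmax(0, (sweep(points, 2, a) %*% ab) / ab2))
    proj <- outer(as.vector(t), ab) + rep(a, each = n)
    d2 <- rowSums((points - proj)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_pos[upd] <- cum[s] + t[upd] * seg_len[s]
    best_proj[upd, ] <- proj[upd, , drop = FALSE]
  }
  list(pos = best_pos, dist = sqrt(best_d2), proj = best_proj,
       length = sum(seg_len))
}

#' Principal-trajectory pseudotime
#'
#' Infers a single linear trajectory through an embedding in the style of
#' cluster-based principal-curve methods: (1) k-means into `k_clusters`
#' clusters; (2) the shortest Hamiltonian path through the cluster centers
#' (exhaustive over orderings for small k) forms the initial curve;
#' (3) the curve is refined by alternately projecting cells onto it and
#' re-estimating each embedding coordinate as a smooth function of the
#' projected arc-length position, until the mean projection shift drops
#' below `tol` times the curve length or `max_iter` iterations. Each cell's
#' pseudotime is its arc-length position rescaled to [0, 1].
#'
#' @param embedding cell x dim coordinate matrix.
#' @param k_clusters number of k-means clusters (default 4).
#' @param seed integer seed for k-means.
#' @param max_iter maximum refinement iterations (default 10).
#' @param tol convergence tolerance as a fraction of curve length
#'   (default 1e-4).
#' @param n_nodes number of polyline nodes of the refined curve.
#' @return numeric pseudotime in [0, 1] per cell (named by rownames of
#'   `embedding`).
#' @export
infer_pseudotime <- function(embedding, k_clusters = 4, seed = 1L,
                             max_iter = 10, tol = 1e-4, n_nodes = 100) {
  embedding <- as.matrix(embedding)
  if (nrow(embedding) < 3 * k_clusters)
    stop("need at least 3 * k_clusters cells")
  if (all(apply(embedding, 2, stats::var) == 0))
    stop("degenerate embedding: all points identical")

  km <- with_seed(derive_seed(seed, "pt_kmeans"),
                  stats::kmeans(embedding, centers = k_clusters,
                                nstart = 10))
  centers <- km$centers
  # shortest Hamiltonian path through the centers (k is small)
  perms <- all_permutations(k_clusters)
  d <- as.matrix(stats::dist(centers))
  path_len <- apply(perms, 1, function(p)
    sum(d[cbind(p[-length(p)], p[-1])]))
  curve <- centers[perms[which.min(path_len), ], , drop = FALSE]

  pos <- project_polyline(embedding, curve)$pos
  for (it in seq_len(max_iter)) {
    o <- order(pos)
    lam <- seq(0, 1, length.out = n_nodes)
    r <- (rank(pos, ties.method = "first") - 1) / (nrow(embedding) - 1)
    curve <- vapply(seq_len(ncol(embedding)), function(j) {
      fit <- stats::lowess(r[o], embedding[o, j], f = 0.3)
      stats::approx(fit$x, fit$y, xout = lam, rule = 2)$y
    }, numeric(n_nodes))
    pr <- project_polyline(embedding, curve)
    shift <- mean(abs(pr$pos - pos))
    pos <- pr$pos
    if (shift < tol * pr$length) break
  }
  pt <- if (max(pos) > min(pos)) (pos - min(pos)) / (max(pos) - min(pos))
        else rep(0, length(pos))
  stats::setNames(pt, rownames(embedding))
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    block <- cbind(i, matrix(c(seq_len(k)[-i])[sub], nrow(sub)))
    out <- rbind(out, block)
  }
  out
}

#' Orient a pseudotime by harvest time and scale to hours
#'
#' If the mean pseudotime of the 0 h cells exceeds that of the 48 h cells,
#' the axis is flipped as `pt <- (pt - 1) * (-1)` (an isometry on [0, 1]
#' that preserves all pairwise distances), then multiplied by 48 to express
#' pseudotime in hours over the 48 h window.
#'
#' @param pt pseudotime in [0, 1] per cell.
#' @param time_labels per-cell harvest labels (hours; must include 0 and
#'   48).
#' @return list: `pt_hours` per cell, `flipped` logical.
#' @export
orient_and_scale <- function(pt, time_labels) {
  if (!any(time_labels == 0) || !any(time_labels == 48))
    stop("need both 0 h and 48 h anchor cells to orient the trajectory")
  flipped <- mean(pt[time_labels == 0]) > mean(pt[time_labels == 48])
  if (flipped) pt <- (pt - 1) * (-1)
  list(pt_hours = 48 * pt, flipped = flipped)
}

#' One-call trajectory pseudotime from an expression matrix
#'
#' Chains covariate regression (optional), 3-D embedding, principal-
#' trajectory inference and time-point orientation/scaling. Works for
#' either modality: log expression for RNA, background-corrected signal
#' for protein.
#'
#' @param x gene/assay x cell matrix.
#' @param time_labels per-cell harvest labels in hours (0/24/48).
#' @param covariates optional per-cell covariate data.frame to regress
#'   out first.
#' @param method embedding method passed to [reduce_dims()].
#' @param k_clusters passed to [infer_pseudotime()].
#' @param seed integer seed.
#' @return list: `pt_hours` named per cell, `pt_unit` in [0, 1],
#'   `flipped`, `embedding`.
#' @export
trajectory_pseudotime <- function(x, time_labels, covariates = NULL,
                                  method = "auto", k_clusters = 4,
                                  seed = 1L) {
  stopifnot(ncol(x) == length(time_labels))
  if (!is.null(covariates)) x <- regress_covariates(x, covariates)
  emb <- reduce_dims(t(x), method = method, seed = seed)
  pt <- infer_pseudotime(emb, k_clusters = k_clusters, seed = seed)
  os <- orient_and_scale(pt, time_labels)
  list(pt_hours = os$pt_hours, pt_unit = os$pt_hours / 48,
       flipped = os$flipped, embedding = emb)
}

#' Cross-modality ordering concordance
#'
#' Spearman rank correlation (ties mid-ranked) of two pseudotime vectors
#' over their shared cells.
#'
#' @param pt_rna,pt_prot named pseudotime vectors.
#' @return list: `rho`, `n` shared cells.
#' @export
ordering_concordance <- function(pt_rna, pt_prot) {
  shared <- intersect(names(pt_rna), names(pt_prot))
  if (length(shared) < 3) stop("fewer than 3 shared cells")
  list(rho = spearman(pt_rna[shared], pt_prot[shared]),
       n = length(shared))
}
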