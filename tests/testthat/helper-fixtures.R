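# Shared fixtures, built lazily and cached for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A full differentiation experiment at the default study design scale
# (~250 cells over 0/24/48 h), used by cell-state and pseudotime tests.
demo_experiment <- function() {
  cached("demo_experiment", function() {
    k <- default_kinetics(n_genes = 120, seed = 1)
    cfg <- sim_config(n_cells_per_timepoint = c(84, 83, 83), seed = 1)
    gt <- simulate_cells(k, cfg)
    sc <- render_rna_counts(gt, cfg)
    qc <- qc_cells(sc$counts, sc$is_ercc)
    ex <- normalize_expression(sc$counts, sc$gene_length, sc$is_ercc,
                               qc$qc_pass)
    lx <- log2(ex$rpkm[!sc$is_ercc, , drop = FALSE] + 1)
    list(kinetics = k, config = cfg, truth = gt, counts = sc, qc = qc,
         expr = ex, log_rpkm = lx,
         n_detected = colSums(ex$counts[!sc$is_ercc, , drop = FALSE] > 0))
  })
}

# A regulator-target discovery experiment: 500 genes, one strongly
# silenced regulator (stable protein, short-lived mRNA) with 12 targets
# coupled to its protein at effect_strength 0.8; four analysis groups
# (steady/dynamic x RNA/protein TF profile) with pearson link weights.
regnet_experiment <- function() {
  cached("regnet_experiment", function() {
    seed <- 101
    k <- default_kinetics(n_genes = 500, seed = seed, frac_dynamic = 0)
    ri <- which(k$tf_role == "none" & !k$s_marker & !k$g2m_marker)[1]
    k$burst_on_rate[ri] <- 2; k$burst_size[ri] <- 8
    k$mrna_halflife[ri] <- 1.5; k$translation_rate[ri] <- 4
    k$protein_halflife[ri] <- 22
    k$mod0[ri] <- 1; k$mod24[ri] <- 0.25; k$mod48[ri] <- 0.05
    reg <- k$gene_id[ri]
    cand <- k$gene_id[k$tf_role == "none" & !k$s_marker &
                        !k$g2m_marker & k$gene_id != reg]
    targets <- cand[seq(2, 24, 2)]
    k <- add_regulation(k, reg, targets, effect_sign = 1,
                        effect_strength = 0.8)
    cfg <- sim_config(n_cells_per_timepoint = c(84, 83, 83), seed = seed)
    gt <- simulate_cells(k, cfg)
    sc <- render_rna_counts(gt, cfg)
    qc <- qc_cells(sc$counts, sc$is_ercc)
    ex <- normalize_expression(sc$counts, sc$gene_length, sc$is_ercc,
                               qc$qc_pass)
    rpkm <- ex$rpkm[!sc$is_ercc, , drop = FALSE]
    lx <- log2(rpkm + 1)
    cq <- render_cq_plate(gt, config = cfg, assay_genes = reg)
    pp <- pea_pipeline(cq, apply_detectability = FALSE)
    cells <- intersect(colnames(lx), colnames(pp$cells))
    tl <- gt$time_label[match(cells, colnames(gt$mrna))]
    expr_ok <- expressed_genes(rpkm[, cells])
    groups <- list(
      steady_rna = list(profile = lx[reg, cells], use = tl == 0),
      steady_prot = list(profile = pp$cells[reg, cells], use = tl == 0),
      dynamic_rna = list(profile = lx[reg, cells],
                         use = rep(TRUE, length(cells))),
      dynamic_prot = list(profile = pp$cells[reg, cells],
                          use = rep(TRUE, length(cells))))
    link_tables <- lapply(groups, function(g) {
      e <- lx[setdiff(expr_ok, reg), cells[g$use], drop = FALSE]
      link_weights(g$profile[g$use], e, method = "pearson", seed = seed)
    })
    list(kinetics = k, truth = gt, regulator = reg, targets = targets,
         expressed = expr_ok, link_tables = link_tables, cells = cells)
  })
}

# A hand-built long-format Cq table: `wells` is a data.frame with well_id,
# well_role and one column per target assay holding that well's Cq; the
# three control assays are constant unless overridden.
build_cq <- function(wells, plate_id = "P1", ext = 20, inc = 22, det = 24,
                     time_point = 0) {
  assays <- setdiff(names(wells), c("well_id", "well_role"))
  rows <- list()
  for (i in seq_len(nrow(wells))) {
    rows[[i]] <- data.frame(
      plate_id = plate_id,
      well_id = wells$well_id[i],
      assay_id = c(assays, "extension_ctl", "incubation_ctl",
                   "detection_ctl"),
      assay_role = c(rep("target", length(assays)), "extension_ctl",
                     "incubation_ctl", "detection_ctl"),
      well_role = wells$well_role[i],
      time_point = time_point,
      cell_id = if (wells$well_role[i] == "single_cell")
        wells$well_id[i] else NA_character_,
      cq = c(as.numeric(wells[i, assays]), ext, inc, det),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# Brute-force AUC oracle: fraction of (positive, negative) pairs ranked
# concordantly, ties counting one half.
auc_bruteforce <- function(weights, positives) {
  if (is.character(positives)) positives <- names(weights) %in% positives
  wp <- weights[positives]
  wn <- weights[!positives]
  cmp <- outer(wp, wn, FUN = function(a, b)
    (a > b) + 0.5 * (a == b))
  mean(cmp)
}
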