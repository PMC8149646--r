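#' Render sequencing read counts from simulated cells
#'
#' Converts true mRNA copy numbers into a gene x cell read-count matrix with
#' ERCC spike-in rows, emulating a full-length (non-UMI) protocol: each
#' molecule is captured independently with probability
#' `capture_efficiency`, and a cell's reads are distributed multinomially
#' over its captured molecules at the configured sequencing depth. ERCC
#' spike-ins have fixed true copy numbers shared by all cells. A chosen
#' number of "failed" cells is rendered with low exonic depth and/or an
#' inflated spike-in fraction so downstream QC has something to catch.
#'
#' @param truth a `ground_truth` from [simulate_cells()].
#' @param config the [sim_config()] used (capture/depth parameters).
#' @param n_ercc number of ERCC spike-in species.
#' @param n_fail_depth number of cells rendered with exonic depth below
#'   10,000 reads.
#' @param n_fail_ercc number of cells rendered with ERCC fraction above 20%.
#' @return list of class `sc_counts`: integer `counts`
#'   ((genes + ERCC) x cells), `gene_length` (bases), logical `is_ercc`,
#'   and the index vector `failed_cells`.
#' @export
render_rna_counts <- function(truth, config = truth$config,
                              n_ercc = 30, n_fail_depth = 0,
                              n_fail_ercc = 0) {
  stopifnot(inherits(truth, "ground_truth"))
  if (config$sequencing_depth <= 0) stop("sequencing_depth must be positive")
  ng <- nrow(truth$mrna); nc <- ncol(truth$mrna)
  with_seed(derive_seed(config$seed, "rna_render"), {
    gene_length <- round(stats::rlnorm(ng, log(1500), 0.4))
    ercc_length <- round(stats::runif(n_ercc, 300, 1500))
    # fixed ERCC input spanning a wide copy range, identical in every cell
    ercc_copies <- round(2^seq(1, 9, length.out = n_ercc))
    # spike dilution tuned so ERCC is a small fraction of a typical cell
    ercc_frac_target <- 0.03
    tot_m <- mean(colSums(truth$mrna))
    ercc_scale <- ercc_frac_target * tot_m / sum(ercc_copies)
    ercc_copies <- pmax(1L, round(ercc_copies * ercc_scale))

    fail_depth <- integer(0); fail_ercc <- integer(0)
    n_bad <- n_fail_depth + n_fail_ercc
    if (n_bad > 0) {
      bad <- sample.int(nc, n_bad)
      fail_depth <- bad[seq_len(n_fail_depth)]
      fail_ercc <- setdiff(bad, fail_depth)
    }

    # per-cell technical capture factor: the dominant source of detected-
    # gene-count variation between cells, as in real library preparations
    cap_sd <- if (is.null(config$capture_sd)) 0 else config$capture_sd
    eff_cell <- pmin(1, config$capture_efficiency *
                       stats::rlnorm(nc, -cap_sd^2 / 2, cap_sd))
    counts <- matrix(0L, ng + n_ercc, nc)
    for (c in seq_len(nc)) {
      cap_g <- stats::rbinom(ng, truth$mrna[, c], eff_cell[c])
      cap_e <- stats::rbinom(n_ercc, ercc_copies, eff_cell[c])
      if (c %in% fail_ercc) cap_e <- cap_e * 30L  # failed lysis: spike dominates
      depth <- stats::rpois(1, config$sequencing_depth)
      if (c %in% fail_depth) depth <- stats::rpois(1, 3000)
      pool <- c(cap_g, cap_e)
      # a cell whose lysate captured nothing yields an empty library
      if (sum(pool) > 0)
        counts[, c] <- stats::rmultinom(1, depth, pool)
    }
    rownames(counts) <- c(rownames(truth$mrna),
                          sprintf("ERCC-%05d", seq_len(n_ercc)))
    colnames(counts) <- colnames(truth$mrna)
    structure(list(counts = counts,
                   gene_length = stats::setNames(
                     c(gene_length, ercc_length), rownames(counts)),
                   is_ercc = c(rep(FALSE, ng), rep(TRUE, n_ercc)),
                   failed_cells = sort(c(fail_depth, fail_ercc))),
              class = "sc_counts")
  })
}

#' Build a default plate layout for simulated cells
#'
#' One 96-well plate per harvest time point, holding that time point's
#' single cells plus the control wells of the study design: duplicate
#' 100-cell population controls, triplicate lysis-buffer (no-cell) wells and
#' triplicate inter-plate control lysate wells.
#'
#' @param truth a `ground_truth`.
#' @return data.frame with columns `plate_id`, `well_id`, `well_role`,
#'   `time_point`, `cell_id`.
#' @export
make_plate_layout <- function(truth) {
  out <- list()
  for (tp in unique(truth$time_label)) {
    cells <- which(truth$time_label == tp)
    plate <- sprintf("plate_%02dh", tp)
    n_sc <- length(cells)
    if (n_sc > 88) stop("more than 88 single cells for one 96-well plate")
    roles <- c(rep("single_cell", n_sc), rep("pop100", 2),
               rep("buffer", 3), rep("interplate_lysate", 3))
    out[[plate]] <- data.frame(
      plate_id = plate,
      well_id = sprintf("%s%02d", rep(LETTERS[1:8], each = 12),
                        rep(1:12, 8))[seq_along(roles)],
      well_role = roles,
      time_point = tp,
      cell_id = c(colnames(truth$mrna)[cells], rep(NA, 8)),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Render a PEA qPCR Cq plate from simulated cells
#'
#' Emulates the protein measurement layer: for each target assay,
#' `Cq = cq_intercept - log2(protein units + background units) +
#' plate offset + Normal(0, cq_noise_sd)`, clipped at `cq_max` (reported
#' missing beyond it). Lower Cq means more protein, the qPCR convention.
#' The extension, incubation and detection control assays are drawn around
#' plate-level offsets shared by every well of a plate, so the downstream
#' extension normalization cancels the offset. Buffer wells contain
#' background units only; pop100 wells contain the summed protein of 100
#' cells resampled from the same time point; inter-plate wells contain a
#' fixed control lysate.
#'
#' @param truth a `ground_truth`.
#' @param layout plate layout as from [make_plate_layout()]; default built
#'   automatically.
#' @param config the [sim_config()].
#' @param assay_genes gene_ids measured by the protein panel; default the
#'   first `min(n_protein_assays, n_genes)` genes with nonzero translation.
#' @param background_units mean per-assay background level (units); actual
#'   per-assay backgrounds are log-normal around this.
#' @return data.frame of class `cq_plate` in long format: `plate_id`,
#'   `well_id`, `assay_id`, `assay_role`, `well_role`, `time_point`,
#'   `cell_id`, `cq` (NA where beyond `cq_max`).
#' @export
render_cq_plate <- function(truth, layout = make_plate_layout(truth),
                            config = truth$config, assay_genes = NULL,
                            background_units = 4) {
  stopifnot(inherits(truth, "ground_truth"))
  need <- c("pop100", "buffer", "interplate_lysate")
  for (p in unique(layout$plate_id)) {
    roles <- layout$well_role[layout$plate_id == p]
    if (sum(roles == "pop100") < 2 || sum(roles == "buffer") < 3 ||
        sum(roles == "interplate_lysate") < 3)
      stop("layout for ", p, " missing required control wells (",
           paste(need, collapse = "/"), ")")
  }
  if (is.null(assay_genes)) {
    # a real panel is designed for the model system: differentiation-
    # responsive proteins first, then cycle markers, then the rest
    k <- truth$kinetics
    cand <- k$gene_id[k$translation_rate > 0]
    pr <- order(-abs(log(k$mod48[match(cand, k$gene_id)])),
                !(k$s_marker | k$g2m_marker)[match(cand, k$gene_id)])
    assay_genes <- utils::head(cand[pr], min(config$n_protein_assays,
                                             length(cand)))
  }
  stopifnot(all(assay_genes %in% rownames(truth$protein)))
  ctrl <- c(extension_ctl = 20, incubation_ctl = 22, detection_ctl = 24)

  with_seed(derive_seed(config$seed, "cq_render"), {
    bg <- stats::rlnorm(length(assay_genes), log(background_units), 0.3)
    names(bg) <- assay_genes
    # fixed inter-plate lysate: one resampled 100-cell pool, shared
    ip_cells <- sample(which(truth$time_label == 0), 100, replace = TRUE)
    ip_units <- rowSums(truth$protein[assay_genes, ip_cells, drop = FALSE])

    rows <- list()
    for (p in unique(layout$plate_id)) {
      lay <- layout[layout$plate_id == p, ]
      offset <- stats::rnorm(1, 0, 0.3)
      for (w in seq_len(nrow(lay))) {
        role <- lay$well_role[w]
        units <- switch(
          role,
          single_cell = truth$protein[assay_genes, lay$cell_id[w]],
          pop100 = {
            src <- which(truth$time_label == lay$time_point[w])
            rs <- sample(src, 100, replace = TRUE)
            rowSums(truth$protein[assay_genes, rs, drop = FALSE])
          },
          buffer = stats::setNames(numeric(length(assay_genes)),
                                   assay_genes),
          interplate_lysate = ip_units
        )
        cq_t <- config$cq_intercept - log2(units + bg) + offset +
          stats::rnorm(length(units), 0, config$cq_noise_sd)
        cq_t[cq_t > config$cq_max] <- NA
        cq_c <- ctrl + offset + stats::rnorm(3, 0, 0.1)
        rows[[length(rows) + 1L]] <- data.frame(
          plate_id = p, well_id = lay$well_id[w],
          assay_id = c(assay_genes, names(ctrl)),
          assay_role = c(rep("target", length(assay_genes)), names(ctrl)),
          well_role = role, time_point = lay$time_point[w],
          cell_id = lay$cell_id[w],
          cq = c(cq_t, cq_c),
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("cq_plate", "data.frame")
    out
  })
}
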