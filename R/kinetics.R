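#' Per-gene kinetic parameter table for the bursting simulator
#'
#' Builds and validates the table of two-state (telegraph) bursting
#' parameters that drives [simulate_cells()]. Each gene is described by a
#' burst frequency, a mean (geometric) burst size, mRNA and protein
#' half-lives, a translation rate, an optional differentiation-response
#' schedule, optional cell-cycle marker behaviour, and an optional
#' regulatory role (a regulator, or a target coupled to a regulator's
#' protein level).
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param burst_on_rate bursts per hour (> 0).
#' @param burst_size mean mRNA molecules per burst (> 0); burst sizes are
#'   geometric with this mean.
#' @param mrna_halflife mRNA half-life in hours (> 0).
#' @param translation_rate proteins produced per mRNA per hour (>= 0; 0
#'   means the gene makes no protein).
#' @param protein_halflife protein half-life in hours (> 0).
#' @param mod0,mod24,mod48 multiplicative modulation of `burst_on_rate` at
#'   0, 24 and 48 h of differentiation; interpolated piecewise-linearly in
#'   log space between the anchors. All 1 for unresponsive genes.
#' @param tf_role one of `"none"`, `"regulator"`, `"target"` per gene.
#' @param regulator_id for targets, the `gene_id` of the regulating gene
#'   (must have `tf_role = "regulator"`); NA otherwise.
#' @param effect_sign +1 (activation) or -1 (repression) for targets.
#' @param effect_strength coupling strength in `[0, 1]` for targets; 0
#'   decouples the target from its regulator.
#' @param s_marker,g2m_marker logical; marker genes get their burst rate
#'   multiplied by `marker_mod` in the corresponding cell-cycle phase.
#' @param marker_mod phase modulation factor for marker genes (default 2.5).
#' @return a `data.frame` of class `gene_kinetics`.
#' @export
gene_kinetics <- function(gene_id,
                          burst_on_rate,
                          burst_size,
                          mrna_halflife,
                          translation_rate,
                          protein_halflife,
                          mod0 = 1, mod24 = 1, mod48 = 1,
                          tf_role = "none",
                          regulator_id = NA_character_,
                          effect_sign = 0,
                          effect_strength = 0,
                          s_marker = FALSE,
                          g2m_marker = FALSE,
                          marker_mod = 2.5) {
  n <- length(gene_id)
  k <- data.frame(
    gene_id = as.character(gene_id),
    burst_on_rate = rep_len(burst_on_rate, n),
    burst_size = rep_len(burst_size, n),
    mrna_halflife = rep_len(mrna_halflife, n),
    translation_rate = rep_len(translation_rate, n),
    protein_halflife = rep_len(protein_halflife, n),
    mod0 = rep_len(mod0, n), mod24 = rep_len(mod24, n),
    mod48 = rep_len(mod48, n),
    tf_role = rep_len(tf_role, n),
    regulator_id = rep_len(regulator_id, n),
    effect_sign = rep_len(effect_sign, n),
    effect_strength = rep_len(effect_strength, n),
    s_marker = rep_len(s_marker, n),
    g2m_marker = rep_len(g2m_marker, n),
    marker_mod = rep_len(marker_mod, n),
    stringsAsFactors = FALSE
  )
  validate_kinetics(k)
  class(k) <- c("gene_kinetics", "data.frame")
  k
}

validate_kinetics <- function(k) {
  if (nrow(k) == 0L) stop("kinetics table must be non-empty")
  if (anyDuplicated(k$gene_id)) stop("gene_id must be unique")
  pos <- c("burst_on_rate", "burst_size", "mrna_halflife", "protein_halflife")
  for (col in pos) {
    if (any(!is.finite(k[[col]]) | k[[col]] <= 0))
      stop("kinetic parameter '", col, "' must be strictly positive")
  }
  if (any(k$translation_rate < 0))
    stop("translation_rate must be non-negative")
  if (any(k$mod0 <= 0 | k$mod24 <= 0 | k$mod48 <= 0))
    stop("differentiation modulation factors must be strictly positive")
  if (!all(k$tf_role %in% c("none", "regulator", "target")))
    stop("tf_role must be none/regulator/target")
  tg <- k$tf_role == "target"
  if (any(tg)) {
    if (any(k$effect_strength[tg] < 0 | k$effect_strength[tg] > 1))
      stop("effect_strength must lie in [0, 1]")
    if (any(!k$effect_sign[tg] %in% c(-1, 1)))
      stop("target effect_sign must be -1 or +1")
    reg <- k$gene_id[k$tf_role == "regulator"]
    bad <- setdiff(k$regulator_id[tg], reg)
    if (length(bad))
      stop("regulator_id not a declared regulator: ",
           paste(bad, collapse = ", "))
    # regulators may not themselves be targets here, so a cycle can only
    # arise from a mislabeled role; check explicitly anyway
    if (any(k$regulator_id[tg] %in% k$gene_id[tg]))
      stop("regulatory cycle: a target gene is used as a regulator")
  }
  invisible(k)
}

#' Simulation configuration
#'
#' Collects the experiment-level parameters of the synthetic co-profiling
#' data set: cohort sizes, measurement-layer parameters for the sequencing
#' and qPCR readouts, and the master seed.
#'
#' Defaults mirror the structure of the study design the package targets:
#' three harvests at 0/24/48 h of directed differentiation (about 85/76/86
#' cells), a 92-protein PEA panel plus 4 control assays on 96-well plates
#' with duplicate 100-cell population controls and triplicate buffer and
#' inter-plate lysate controls, and a 40-cycle qPCR ceiling.
#'
#' @param n_cells_per_timepoint integer vector of length 3, cells at
#'   0/24/48 h.
#' @param n_genes number of simulated genes (used by generators that build
#'   kinetics tables; `simulate_cells` takes its gene list from `kinetics`).
#' @param n_protein_assays number of protein target assays on the panel.
#' @param capture_efficiency mean fraction of mRNA molecules captured into
#'   the sequencing library, in (0, 1].
#' @param capture_sd SD of the per-cell log-normal capture-efficiency
#'   factor (cell-to-cell technical variability of library conversion).
#' @param sequencing_depth mean mapped reads per cell.
#' @param cq_intercept Cq value corresponding to one captured protein unit.
#' @param cq_noise_sd per-measurement Cq noise SD (cycles).
#' @param cq_max qPCR cycle ceiling; Cq beyond it is reported as missing.
#' @param size_factor_sd SD of the log-normal cell-size factor.
#' @param time_jitter_sd SD (hours) of per-cell jitter around the nominal
#'   harvest time, truncated to `[0, 48]`.
#' @param dt tau-leap step (hours) of the kinetic simulation.
#' @param seed master seed; all stages derive their own streams from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_cells_per_timepoint = c(85, 76, 86),
                       n_genes = 120,
                       n_protein_assays = 92,
                       capture_efficiency = 0.2,
                       capture_sd = 0.35,
                       sequencing_depth = 1e5,
                       cq_intercept = 37,
                       cq_noise_sd = 0.25,
                       cq_max = 40,
                       size_factor_sd = 0.15,
                       time_jitter_sd = 2,
                       dt = 0.1,
                       seed = 1L) {
  cfg <- list(n_cells_per_timepoint = as.integer(n_cells_per_timepoint),
              n_genes = as.integer(n_genes),
              n_protein_assays = as.integer(n_protein_assays),
              capture_efficiency = capture_efficiency,
              capture_sd = capture_sd,
              sequencing_depth = sequencing_depth,
              cq_intercept = cq_intercept,
              cq_noise_sd = cq_noise_sd,
              cq_max = cq_max,
              size_factor_sd = size_factor_sd,
              time_jitter_sd = time_jitter_sd,
              dt = dt,
              seed = as.integer(seed))
  if (length(cfg$n_cells_per_timepoint) != 3L ||
      any(cfg$n_cells_per_timepoint < 1L))
    stop("n_cells_per_timepoint must be three counts >= 1")
  if (cfg$capture_efficiency <= 0 || cfg$capture_efficiency > 1)
    stop("capture_efficiency must lie in (0, 1]")
  if (cfg$sequencing_depth <= 0) stop("sequencing_depth must be positive")
  if (cfg$cq_max <= cfg$cq_intercept - 30)
    stop("cq_max too low relative to cq_intercept")
  if (cfg$n_genes < 1L || cfg$n_protein_assays < 1L)
    stop("counts must be >= 1")
  if (cfg$dt <= 0) stop("dt must be positive")
  class(cfg) <- "sim_config"
  cfg
}

#' Default kinetics table for a differentiation experiment
#'
#' Draws a heterogeneous gene panel: log-normal burst frequencies and sizes,
#' mRNA half-lives of a few hours, protein half-lives of tens of hours, and
#' log-normally distributed translation rates. A configurable fraction of
#' genes responds to differentiation (up or down), and small S-phase /
#' G2M-marker sets are included so cell-cycle scoring has signal.
#'
#' @param n_genes number of genes.
#' @param seed integer seed.
#' @param frac_dynamic fraction of genes with a differentiation response.
#' @param n_s_markers,n_g2m_markers counts of cycle marker genes.
#' @return a `gene_kinetics` table.
#' @export
default_kinetics <- function(n_genes = 120, seed = 1L,
                             frac_dynamic = 0.3,
                             n_s_markers = 12, n_g2m_markers = 12) {
  with_seed(derive_seed(seed, "kinetics"), {
    ids <- sprintf("G%03d", seq_len(n_genes))
    burst_rate <- stats::rlnorm(n_genes, log(1.0), 0.7)
    burst_size <- stats::rlnorm(n_genes, log(6), 0.5)
    hl_m <- stats::rlnorm(n_genes, log(3), 0.4)
    # regulatory and developmental proteins turn over within hours;
    # housekeeping proteins last longer — a 10 h median with broad spread
    hl_p <- stats::rlnorm(n_genes, log(10), 0.6)
    ktl <- stats::rlnorm(n_genes, log(2), 1.0)
    n_dyn <- round(frac_dynamic * n_genes)
    dyn <- sample.int(n_genes, n_dyn)
    up <- dyn[seq_len(floor(n_dyn / 2))]
    down <- setdiff(dyn, up)
    mod0 <- rep(1, n_genes); mod24 <- rep(1, n_genes); mod48 <- rep(1, n_genes)
    mod24[up] <- 4; mod48[up] <- 16
    mod24[down] <- 1 / 4; mod48[down] <- 1 / 16
    stat <- setdiff(seq_len(n_genes), dyn)
    sm <- sample(stat, min(n_s_markers, length(stat)))
    gm <- sample(setdiff(stat, sm), min(n_g2m_markers, length(stat) - length(sm)))
    s_marker <- seq_len(n_genes) %in% sm
    g2m_marker <- seq_len(n_genes) %in% gm
    # cycle markers are kept well expressed so the scoring op sees them
    burst_rate[s_marker | g2m_marker] <-
      pmax(burst_rate[s_marker | g2m_marker], 1.5)
    gene_kinetics(ids, burst_rate, burst_size, hl_m, ktl, hl_p,
                  mod0 = mod0, mod24 = mod24, mod48 = mod48,
                  s_marker = s_marker, g2m_marker = g2m_marker)
  })
}

#' Attach a regulator and its targets to a kinetics table
#'
#' Marks one gene as a regulator and couples a set of target genes to its
#' protein copy number. The regulator is usually made
#' differentiation-responsive (e.g. switched off) so that a dynamic analysis
#' group carries more signal than the steady-state group.
#'
#' @param kinetics a `gene_kinetics` table.
#' @param regulator gene_id of the regulator.
#' @param targets gene_ids of the targets.
#' @param effect_sign +1 or -1 (recycled).
#' @param effect_strength coupling in `[0, 1]` (recycled).
#' @return the modified `gene_kinetics` table.
#' @export
add_regulation <- function(kinetics, regulator, targets,
                           effect_sign = 1, effect_strength = 0.8) {
  stopifnot(regulator %in% kinetics$gene_id,
            all(targets %in% kinetics$gene_id),
            !regulator %in% targets)
  kinetics$tf_role[kinetics$gene_id == regulator] <- "regulator"
  i <- match(targets, kinetics$gene_id)
  kinetics$tf_role[i] <- "target"
  kinetics$regulator_id[i] <- regulator
  kinetics$effect_sign[i] <- rep_len(effect_sign, length(i))
  kinetics$effect_strength[i] <- rep_len(effect_strength, length(i))
  validate_kinetics(kinetics)
  kinetics
}
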