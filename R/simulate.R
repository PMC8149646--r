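#' Simulate coupled bursty mRNA/protein expression in single cells
#'
#' Stochastic simulation of a two-state (telegraph) bursting model in its
#' instantaneous-burst limit: transcriptional bursts arrive as a Poisson
#' process whose rate is modulated by differentiation time, cell size,
#' cell-cycle phase and (for target genes) the regulator's current protein
#' copy number; each burst deposits a geometric number of mRNAs; mRNA and
#' protein decay exponentially and protein is translated from mRNA at a
#' constant per-molecule rate. The system is advanced by tau-leaping
#' (Poisson burst arrivals, binomial decay with exact per-step survival
#' probabilities), which leaves the first moments unbiased; states are
#' initialized from the analytic stationary law of the bursty birth-death
#' process (negative-binomial mRNA, Poisson protein around its conditional
#' mean) so that a modest burn-in suffices.
#'
#' At stationarity the model obeys
#' `mean mRNA = burst_on_rate * burst_size * mrna_halflife / ln 2` (times
#' modulation and cell-size factor) and
#' `mean protein = mean mRNA * translation_rate * protein_halflife / ln 2`.
#'
#' @param kinetics a [gene_kinetics()] table.
#' @param config a [sim_config()].
#' @param burnin hours simulated before the first harvest; default
#'   `min(60, max(10, 2 * max(protein_halflife)))`.
#' @return an object of class `ground_truth`: list with integer matrices
#'   `mrna`, `protein` (gene x cell), vectors `size_factor`, `phase`,
#'   `time_label`, `true_time`, plus the `kinetics` and `config` used.
#' @export
simulate_cells <- function(kinetics, config = sim_config(), burnin = NULL) {
  validate_kinetics(kinetics)
  stopifnot(inherits(config, "sim_config"))
  ng <- nrow(kinetics)
  nc <- sum(config$n_cells_per_timepoint)
  dt <- config$dt

  if (is.null(burnin))
    burnin <- min(60, max(10, 2 * max(kinetics$protein_halflife)))

  with_seed(derive_seed(config$seed, "simulate"), {
    # --- cell-level latent variables -----------------------------------
    time_label <- rep(c(0, 24, 48), times = config$n_cells_per_timepoint)
    true_time <- pmin(48, pmax(0, time_label +
                                 stats::rnorm(nc, 0, config$time_jitter_sd)))
    sf <- stats::rlnorm(nc, -config$size_factor_sd^2 / 2,
                        config$size_factor_sd)
    u <- stats::runif(nc)
    phase <- ifelse(u < 0.5, "G1", ifelse(u < 0.8, "S", "G2M"))

    # --- time grid and recording schedule ------------------------------
    t0 <- -burnin
    n_steps <- ceiling((48 - t0) / dt)
    grid <- t0 + seq_len(n_steps) * dt
    rec_step <- pmin(n_steps, pmax(1L, ceiling((true_time - t0) / dt)))

    dm <- log(2) / kinetics$mrna_halflife      # mRNA decay /h
    dp <- log(2) / kinetics$protein_halflife   # protein decay /h
    pgeo <- 1 / (1 + kinetics$burst_size)      # geometric burst-size prob
    lmod <- log(cbind(kinetics$mod0, kinetics$mod24, kinetics$mod48))

    # burst-rate modulation from the differentiation schedule at time t
    sched <- function(t) {
      tt <- min(max(t, 0), 48)
      if (tt <= 24) w <- tt / 24 else w <- (tt - 24) / 24
      if (tt <= 24) exp(lmod[, 1] * (1 - w) + lmod[, 2] * w)
      else exp(lmod[, 2] * (1 - w) + lmod[, 3] * w)
    }

    # per-cell phase multiplier: marker genes are phase-specific, boosted
    # by marker_mod in their phase and suppressed by 1/marker_mod outside
    # it (as for cyclin-like genes, whose expression peaks in one phase)
    phase_mult <- matrix(1, ng, nc)
    phase_mult[kinetics$s_marker, ] <- 1 / kinetics$marker_mod[kinetics$s_marker]
    phase_mult[kinetics$s_marker, phase == "S"] <-
      kinetics$marker_mod[kinetics$s_marker]
    phase_mult[kinetics$g2m_marker, ] <- 1 / kinetics$marker_mod[kinetics$g2m_marker]
    phase_mult[kinetics$g2m_marker, phase == "G2M"] <-
      kinetics$marker_mod[kinetics$g2m_marker]

    out_m <- matrix(0L, ng, nc)
    out_p <- matrix(0L, ng, nc)
    is_target <- kinetics$tf_role == "target"
    regulators <- kinetics$gene_id[kinetics$tf_role == "regulator"]
    need_traj <- regulators[regulators %in%
                              kinetics$regulator_id[is_target]]

    # unregulated stationary protein mean of each needed regulator (used as
    # the reference level of the monotone coupling function)
    p_ref <- vapply(need_traj, function(g) {
      i <- match(g, kinetics$gene_id)
      mu_m <- kinetics$burst_on_rate[i] * kinetics$mod0[i] *
        kinetics$burst_size[i] / dm[i]
      mu_m * kinetics$translation_rate[i] / dp[i]
    }, numeric(1))

    run_pass <- function(rows, reg_traj = NULL, traj_rows = integer(0)) {
      g <- length(rows)
      if (g == 0L) return(NULL)
      traj_idx <- match(traj_rows, rows)
      kon0 <- kinetics$burst_on_rate[rows]
      bsz <- kinetics$burst_size[rows]
      pg <- pgeo[rows]
      dmr <- dm[rows]; dpr <- dp[rows]
      ktl <- kinetics$translation_rate[rows]
      surv_m <- 1 - exp(-dmr * dt)
      surv_p <- 1 - exp(-dpr * dt)
      # expected within-step survival of molecules born during the step
      # (birth times uniform over the step); thinning arrivals by this
      # factor makes the discrete update's stationary mean exactly
      # kon * b / d rather than inflated by dm*dt/(1-exp(-dm*dt))
      thin_m <- surv_m / (dmr * dt)
      thin_p <- surv_p / (dpr * dt)
      pmlt <- phase_mult[rows, , drop = FALSE]
      sf_row <- matrix(sf, g, nc, byrow = TRUE)

      mod_t0 <- sched(t0)[rows]
      base0 <- kon0 * mod_t0
      # base0 (length g) recycles down the columns of the g x nc matrices,
      # i.e. per-gene scaling of every cell
      kon_mat0 <- base0 * sf_row * pmlt
      rf0 <- reg_factor(rows, reg_traj, 0L)
      if (!is.null(rf0)) kon_mat0 <- kon_mat0 * rf0
      mu_m0 <- kon_mat0 * bsz / dmr
      M <- matrix(stats::rnbinom(g * nc,
                                 size = pmax(kon_mat0 / dmr, 1e-8),
                                 prob = pg), g, nc)
      P <- matrix(stats::rpois(g * nc, mu_m0 * ktl / dpr), g, nc)

      save_traj <- length(traj_idx) > 0L
      traj <- if (save_traj)
        array(0, dim = c(length(traj_idx), nc, n_steps)) else NULL

      for (s in seq_len(n_steps)) {
        kon <- (kon0 * sched(grid[s] - dt / 2)[rows]) * sf_row * pmlt
        rf <- reg_factor(rows, reg_traj, s)
        if (!is.null(rf)) kon <- kon * rf
        nb <- stats::rpois(g * nc, kon * dt)
        gain <- numeric(g * nc)
        idx <- which(nb > 0L)
        if (length(idx)) {
          raw <- stats::rnbinom(length(idx), size = nb[idx],
                                prob = rep(pg, nc)[idx])
          gain[idx] <- stats::rbinom(length(idx), raw, rep(thin_m, nc)[idx])
        }
        loss <- stats::rbinom(g * nc, as.vector(M), rep(surv_m, nc))
        pgain <- stats::rpois(g * nc,
                              as.vector(M) * rep(ktl * dt * thin_p, nc))
        M <- M + matrix(gain - loss, g, nc)
        ploss <- stats::rbinom(g * nc, as.vector(P), rep(surv_p, nc))
        P <- P + matrix(pgain - ploss, g, nc)
        if (save_traj) traj[, , s] <- P[traj_idx, ]
        hit <- which(rec_step == s)
        if (length(hit)) {
          out_m[rows, hit] <<- M[, hit]
          out_p[rows, hit] <<- P[, hit]
        }
      }
      traj
    }

    # coupling of a target's burst rate to its regulator's protein level:
    # ((p + 1) / (p_ref + 1)) ^ (2 * sign * strength), clamped to
    # [1/16, 16]; the factor 2 gives Hill-like cooperativity so that a
    # full-strength target responds steeply to regulator dose
    reg_factor <- function(rows, reg_traj, step) {
      if (is.null(reg_traj)) return(NULL)
      tg <- which(is_target[rows])
      if (!length(tg)) return(NULL)
      out <- matrix(1, length(rows), nc)
      for (j in tg) {
        gi <- rows[j]
        rid <- kinetics$regulator_id[gi]
        p_now <- if (step == 0L) reg_traj[[rid]][, 1L]
                 else reg_traj[[rid]][, step]
        e <- 2 * kinetics$effect_sign[gi] * kinetics$effect_strength[gi]
        f <- ((p_now + 1) / (p_ref[[rid]] + 1))^e
        out[j, ] <- pmin(16, pmax(1 / 16, f))
      }
      out
    }

    rows1 <- which(!is_target)
    traj1 <- run_pass(rows1,
                      traj_rows = match(need_traj, kinetics$gene_id))
    reg_traj <- NULL
    if (!is.null(traj1) && length(need_traj)) {
      reg_traj <- lapply(seq_along(need_traj), function(j)
        matrix(traj1[j, , ], nc, n_steps))
      names(reg_traj) <- need_traj
    }
    rows2 <- which(is_target)
    run_pass(rows2, reg_traj = reg_traj)

    dimnames(out_m) <- dimnames(out_p) <-
      list(kinetics$gene_id, sprintf("cell%03d", seq_len(nc)))
    structure(list(mrna = out_m, protein = out_p,
                   size_factor = sf, phase = phase,
                   time_label = time_label, true_time = true_time,
                   kinetics = kinetics, config = config),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", nrow(x$mrna), "genes x", ncol(x$mrna), "cells;",
      "harvests at", paste(unique(x$time_label), collapse = "/"), "h\n")
  invisible(x)
}
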