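# Bursting simulator and its two measurement layers.

test_that("stationary mRNA and protein moments match the bursting model", {
  k <- gene_kinetics("A", burst_on_rate = 2, burst_size = 5,
                     mrna_halflife = log(2), translation_rate = 1,
                     protein_halflife = 2)
  cfg <- sim_config(n_cells_per_timepoint = c(3334, 3333, 3333),
                    seed = 7, time_jitter_sd = 0, size_factor_sd = 1e-4)
  gt <- simulate_cells(k, cfg)
  # mean mRNA = burst_on_rate * burst_size / decay = 2 * 5 / 1 = 10
  expect_equal(mean(gt$mrna), 10, tolerance = 0.05)
  # geometric bursts: CV2 = (1 + burst_size) / mean
  cv2 <- stats::var(as.numeric(gt$mrna)) / mean(gt$mrna)^2
  expect_equal(cv2, 6 / 10, tolerance = 0.08)
  # protein mean = mRNA mean * translation_rate * protein_halflife / ln 2
  expect_equal(mean(gt$protein), 10 * 2 / log(2), tolerance = 0.05)
})

test_that("zero translation rate yields identically zero protein", {
  k <- gene_kinetics("B", 2, 5, 1, translation_rate = 0,
                     protein_halflife = 10)
  gt <- simulate_cells(k, sim_config(n_cells_per_timepoint = c(20, 20, 20),
                                     seed = 3))
  expect_true(all(gt$protein == 0))
})

test_that("stable protein outlives its mRNA after gene shutdown", {
  # POU5F1-like: gene switched off during differentiation, short-lived
  # mRNA, long-lived protein; at 48 h more cells retain protein than mRNA
  k <- gene_kinetics("off", burst_on_rate = 1.5, burst_size = 4,
                     mrna_halflife = 1, translation_rate = 2,
                     protein_halflife = 20,
                     mod0 = 1, mod24 = 0.25, mod48 = 0.05)
  cfg <- sim_config(n_cells_per_timepoint = c(50, 50, 200), seed = 11,
                    time_jitter_sd = 0)
  gt <- simulate_cells(k, cfg)
  late <- gt$time_label == 48
  expect_gt(mean(gt$protein[, late] > 0), mean(gt$mrna[, late] > 0))
})

test_that("same seed reproduces bit-identical output, different seed does not", {
  k <- default_kinetics(n_genes = 10, seed = 5)
  cfg <- sim_config(n_cells_per_timepoint = c(10, 10, 10), seed = 5)
  a <- simulate_cells(k, cfg)
  b <- simulate_cells(k, cfg)
  expect_identical(a$mrna, b$mrna)
  expect_identical(a$protein, b$protein)
  cfg2 <- sim_config(n_cells_per_timepoint = c(10, 10, 10), seed = 6)
  c <- simulate_cells(k, cfg2)
  expect_false(identical(a$mrna, c$mrna))
})

test_that("time averaging by a stable protein suppresses noise", {
  # protein CV2 < mRNA CV2 whenever the protein outlives the mRNA and
  # translation is moderate, across a small parameter grid
  for (hl_p in c(10, 30)) {
    for (b in c(4, 10)) {
      k <- gene_kinetics("g", burst_on_rate = 1, burst_size = b,
                         mrna_halflife = 1.5, translation_rate = 3,
                         protein_halflife = hl_p)
      cfg <- sim_config(n_cells_per_timepoint = c(400, 400, 400),
                        seed = 13 + b, time_jitter_sd = 0,
                        size_factor_sd = 1e-4)
      gt <- simulate_cells(k, cfg)
      cv2 <- function(x) stats::var(as.numeric(x)) / mean(x)^2
      expect_lt(cv2(gt$protein), cv2(gt$mrna))
    }
  }
})

test_that("in-silico knockdown removes regulator-target correlation", {
  # two plain genes (no size/phase confounding) so any correlation is due
  # to the regulatory coupling alone
  for (strength in c(0.8, 0)) {
    k <- gene_kinetics(c("reg", "tgt"),
                       burst_on_rate = c(1.5, 1.5), burst_size = 6,
                       mrna_halflife = 2, translation_rate = 2,
                       protein_halflife = c(15, 10))
    k <- add_regulation(k, "reg", "tgt", effect_sign = 1,
                        effect_strength = strength)
    cfg <- sim_config(n_cells_per_timepoint = c(84, 83, 83), seed = 9,
                      time_jitter_sd = 0, size_factor_sd = 1e-4)
    gt <- simulate_cells(k, cfg)
    r <- stats::cor(gt$protein["reg", ], gt$mrna["tgt", ])
    if (strength == 0) expect_lt(abs(r), 0.1) else expect_gt(r, 0.2)
  }
})

test_that("regulatory misconfiguration is rejected", {
  k <- default_kinetics(n_genes = 6, seed = 1)
  expect_error(gene_kinetics("X", -1, 5, 1, 1, 1), "positive")
  expect_error(add_regulation(k, "G001", "G001"))
  # a target may not serve as another target's regulator
  k2 <- add_regulation(k, "G001", "G002")
  k2$regulator_id[k2$gene_id == "G003"] <- "G002"
  k2$tf_role[k2$gene_id == "G003"] <- "target"
  k2$effect_sign[k2$gene_id == "G003"] <- 1
  expect_error(validate_kinetics(k2), "regulator")
})

test_that("read rendering preserves copy proportions at full capture and depth", {
  k <- default_kinetics(n_genes = 25, seed = 21, frac_dynamic = 0)
  cfg <- sim_config(n_cells_per_timepoint = c(4, 3, 3), seed = 21,
                    capture_efficiency = 1, capture_sd = 0,
                    sequencing_depth = 2e6)
  gt <- simulate_cells(k, cfg)
  sc <- render_rna_counts(gt, cfg, n_ercc = 5)
  gene_counts <- sc$counts[!sc$is_ercc, ]
  for (c in 1:3) {
    obs <- gene_counts[, c] / sum(gene_counts[, c])
    tru <- gt$mrna[, c] / sum(gt$mrna[, c])
    expect_equal(obs, tru, tolerance = 0.02, ignore_attr = TRUE)
  }
})

test_that("detection fraction under partial capture matches the thinning law", {
  # detection prob per cell = 1 - (1 - eff)^X for true copies X
  k <- gene_kinetics("low", burst_on_rate = 1.2, burst_size = 3,
                     mrna_halflife = 1, translation_rate = 1,
                     protein_halflife = 10)
  cfg <- sim_config(n_cells_per_timepoint = c(400, 400, 400), seed = 31,
                    capture_efficiency = 0.1, capture_sd = 0,
                    sequencing_depth = 5e4, time_jitter_sd = 0)
  gt <- simulate_cells(k, cfg)
  sc <- render_rna_counts(gt, cfg, n_ercc = 5)
  oracle <- mean(1 - (1 - 0.1)^gt$mrna["low", ])
  observed <- mean(sc$counts["low", ] > 0)
  expect_equal(observed, oracle, tolerance = 0.1)
})

test_that("configured failing cells violate QC thresholds exactly", {
  k <- default_kinetics(n_genes = 30, seed = 2)
  cfg <- sim_config(n_cells_per_timepoint = c(30, 30, 30), seed = 2)
  gt <- simulate_cells(k, cfg)
  sc <- render_rna_counts(gt, cfg, n_fail_depth = 2, n_fail_ercc = 1)
  qc <- qc_cells(sc$counts, sc$is_ercc)
  expect_identical(unname(which(!qc$qc_pass)), sc$failed_cells)
  expect_length(sc$failed_cells, 3L)
})

test_that("doubling protein lowers expected target Cq by one cycle", {
  # pre-noise log2 mapping: Cq = intercept - log2(units + background)
  cfg <- sim_config(seed = 1)
  units <- 500; bg <- 0
  cq1 <- cfg$cq_intercept - log2(units + bg)
  cq2 <- cfg$cq_intercept - log2(2 * units + bg)
  expect_equal(cq1 - cq2, 1.0)
})

test_that("cq rendering demands the control wells of the plate design", {
  k <- default_kinetics(n_genes = 10, seed = 4)
  cfg <- sim_config(n_cells_per_timepoint = c(5, 5, 5), seed = 4)
  gt <- simulate_cells(k, cfg)
  lay <- make_plate_layout(gt)
  broken <- lay[lay$well_role != "buffer", ]
  expect_error(render_cq_plate(gt, layout = broken, config = cfg),
               "control wells")
})
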