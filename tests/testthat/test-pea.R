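# PEA plate processing: well QC, dCq, background correction, detectability.

test_that("well QC keeps everything when controls are flat", {
  w <- data.frame(well_id = sprintf("W%d", 1:6),
                  well_role = "single_cell", A = 25)
  cq <- build_cq(w)
  qc <- qc_wells(cq)
  expect_equal(nrow(qc$kept), 6)
  expect_equal(nrow(qc$excluded), 0)
})

test_that("a missing control excludes the well with a reason", {
  w <- data.frame(well_id = sprintf("W%d", 1:5),
                  well_role = "single_cell", A = 25)
  cq <- build_cq(w)
  cq$cq[cq$well_id == "W2" & cq$assay_role == "detection_ctl"] <- NA
  qc <- qc_wells(cq)
  expect_false("W2" %in% qc$kept$well_id)
  expect_equal(qc$excluded$reason[qc$excluded$well_id == "W2"],
               "missing_control")
  # conservation: every well is either kept or excluded, never both
  expect_setequal(c(qc$kept$well_id, unique(qc$excluded$well_id)),
                  w$well_id)
  expect_length(intersect(qc$kept$well_id, qc$excluded$well_id), 0)
})

test_that("a control deviating more than 2 SD excludes the well", {
  # ext-ctl 20.0 in nine wells, 25.0 in one: mean 20.5, SD = sqrt(2.5),
  # |25 - 20.5| = 4.5 > 2 * 1.5811
  w <- data.frame(well_id = sprintf("W%02d", 1:10),
                  well_role = "single_cell", A = 25)
  cq <- build_cq(w)
  cq$cq[cq$assay_role == "extension_ctl"] <- c(rep(20, 9), 25)
  qc <- qc_wells(cq)
  expect_equal(unique(qc$excluded$well_id), "W10")
  expect_equal(qc$excluded$z, 4.5 / sqrt(2.5), tolerance = 1e-12)
  # the nine 20.0 wells deviate by 0.5 < 2 SD and stay
  expect_equal(nrow(qc$kept), 9)
})

test_that("well QC needs at least three evaluable wells", {
  w <- data.frame(well_id = c("W1", "W2"), well_role = "single_cell",
                  A = 25)
  expect_error(qc_wells(build_cq(w)), "fewer than 3")
})

test_that("extension normalization subtracts the well's extension control", {
  w <- data.frame(well_id = c("W1", "W2", "W3"),
                  well_role = "single_cell", A = c(24, 20, NA))
  dcq <- extension_normalize(build_cq(w))
  a <- dcq[dcq$assay_id == "A", ]
  expect_equal(a$dcq, c(4, 0, NA_real_))
})

test_that("background threshold is buffer mean + 2 SD, floored at zero", {
  w <- data.frame(
    well_id = c("B1", "B2", "B3", "C1", "C2", "C3"),
    well_role = rep(c("buffer", "single_cell"), each = 3),
    A = c(29, 30, 31, 27, 32, 30))  # dCq after ext 20: 9,10,11 / 7,12,10
  ps <- background_correct(extension_normalize(build_cq(w)))
  # buffer dCq {9,10,11}: T = 10 + 2*1 = 12
  expect_equal(unname(ps$signal["A", ]), c(12 - 7, 0, 12 - 10))
  expect_identical(unname(ps$detected["A", ]), c(TRUE, FALSE, TRUE))
})

test_that("degenerate buffer wells give the stated simple threshold", {
  w <- data.frame(
    well_id = c("B1", "B2", "B3", "C1"),
    well_role = c(rep("buffer", 3), "single_cell"),
    A = c(30, 30, 30, 27))
  ps <- background_correct(extension_normalize(build_cq(w)))
  # buffer dCq all 10: T = 10; sample dCq 7 -> signal 3, detected
  expect_equal(unname(ps$signal["A", "P1 C1"]), 3)
  expect_true(ps$detected["A", "P1 C1"])
})

test_that("missing sample dCq yields zero, undetected", {
  w <- data.frame(
    well_id = c("B1", "B2", "B3", "C1"),
    well_role = c(rep("buffer", 3), "single_cell"),
    A = c(30, 30, 30, NA))
  ps <- background_correct(extension_normalize(build_cq(w)))
  expect_equal(unname(ps$signal["A", "P1 C1"]), 0)
  expect_false(ps$detected["A", "P1 C1"])
})

test_that("an assay without enough buffer observations is dropped", {
  w <- data.frame(
    well_id = c("B1", "B2", "B3", "C1"),
    well_role = c(rep("buffer", 3), "single_cell"),
    A = c(30, 30, 30, 27), B = c(NA, NA, 28, 25))
  expect_warning(
    ps <- background_correct(extension_normalize(build_cq(w))),
    "buffer")
  expect_false("B" %in% rownames(ps$signal))
  expect_equal(ps$dropped_assays, "B")
})

test_that("plate-wide Cq offsets cancel end to end", {
  w <- data.frame(
    well_id = c("B1", "B2", "B3", "C1", "C2", "P1w", "P2w"),
    well_role = c(rep("buffer", 3), "single_cell", "single_cell",
                  "pop100", "pop100"),
    A = c(29, 30, 31, 26, 24, 22, 22.5))
  cq0 <- build_cq(w)
  cq1 <- cq0
  cq1$cq <- cq1$cq + 0.7  # every assay of the plate shifted
  p0 <- pea_pipeline(cq0, apply_detectability = FALSE)
  p1 <- pea_pipeline(cq1, apply_detectability = FALSE)
  expect_equal(p0$cells, p1$cells)
  expect_equal(p0$signal$protein_sum, p1$signal$protein_sum)
})

test_that("lower raw Cq never yields lower signal", {
  w <- data.frame(
    well_id = c("B1", "B2", "B3", sprintf("C%d", 1:8)),
    well_role = c(rep("buffer", 3), rep("single_cell", 8)),
    A = c(29, 30, 31, seq(34, 20, length.out = 8)))
  ps <- background_correct(extension_normalize(build_cq(w)))
  s <- ps$signal["A", ]
  expect_true(all(diff(s) >= 0))  # wells ordered by decreasing Cq
})

test_that("detectability keeps assays above 3 Cq over background, strictly", {
  w <- data.frame(
    well_id = c("B1", "B2", "B3", "P1w", "P2w"),
    well_role = c(rep("buffer", 3), "pop100", "pop100"),
    A = c(30, 30, 30, 26.5, 26.5),  # pop100 signal 3.5 -> kept
    B = c(30, 30, 30, 27.0, 27.0),  # exactly 3.0 -> dropped (strict >)
    C = c(30, 30, 30, 29.0, 29.0))  # 1.0 -> dropped
  ps <- background_correct(extension_normalize(build_cq(w)))
  expect_identical(detectability_filter(ps), "A")
  expect_error(detectability_filter(
    background_correct(extension_normalize(build_cq(
      w[w$well_role != "pop100", ])))), "pop100")
})

test_that("assays below the limit of detection are filtered as built", {
  # panel of 8 assays, 5 of them with protein far below background
  truth_sig <- c(a1 = 200, a2 = 500, a3 = 800, rep(0, 5))
  names(truth_sig)[4:8] <- paste0("lod", 1:5)
  cfg <- sim_config(seed = 2)
  wells <- c("B1", "B2", "B3", "P1w", "P2w")
  roles <- c(rep("buffer", 3), rep("pop100", 2))
  df <- data.frame(well_id = wells, well_role = roles)
  for (a in names(truth_sig)) {
    units <- ifelse(roles == "buffer", 0, truth_sig[[a]] * 100)
    df[[a]] <- cfg$cq_intercept - log2(units + 4)
  }
  ps <- background_correct(extension_normalize(build_cq(df)))
  expect_setequal(detectability_filter(ps), c("a1", "a2", "a3"))
})

test_that("true protein is recovered through the full Cq round trip", {
  # well-expressed panel far above background: Spearman >= 0.9 per assay
  # differentiation-responsive genes span a wide protein range across the
  # harvests, so ranks are informative relative to the 0.25-cycle noise
  k <- gene_kinetics(paste0("p", 1:4), burst_on_rate = c(1, 2, 1.5, 3),
                     burst_size = 6, mrna_halflife = 2,
                     translation_rate = c(4, 6, 8, 5),
                     protein_halflife = c(8, 10, 12, 10),
                     mod24 = c(0.2, 0.15, 6, 8),
                     mod48 = c(1 / 25, 1 / 30, 30, 40))
  cfg <- sim_config(n_cells_per_timepoint = c(67, 67, 66), seed = 17,
                    cq_noise_sd = 0.25)
  gt <- simulate_cells(k, cfg)
  cq <- render_cq_plate(gt, config = cfg)
  pp <- pea_pipeline(cq, apply_detectability = FALSE)
  for (a in rownames(pp$cells)) {
    tr <- gt$protein[a, colnames(pp$cells)]
    expect_gte(stats::cor(tr, pp$cells[a, ], method = "spearman"), 0.9)
  }
})

test_that("interplate wells give a finite reproducibility CV", {
  k <- default_kinetics(n_genes = 10, seed = 8)
  cfg <- sim_config(n_cells_per_timepoint = c(10, 10, 10), seed = 8)
  gt <- simulate_cells(k, cfg)
  cq <- render_cq_plate(gt, config = cfg)
  ps <- background_correct(extension_normalize(cq, qc_wells(cq)$kept))
  cvs <- interplate_cv(ps)
  expect_true(all(is.finite(cvs$cv) | is.na(cvs$cv)))
  expect_gt(sum(is.finite(cvs$cv)), 0)
})
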