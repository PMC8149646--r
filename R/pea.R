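#' Well-level quality control of a PEA Cq plate
#'
#' A well is excluded when any of its three spiked control assays
#' (extension, incubation, detection) is missing, or when a control's Cq
#' deviates from that control's mean across all wells of the same plate by
#' more than 2 standard deviations (sample SD, strict inequality). Controls
#' are assessed independently of each other, per plate. Amplification-curve
#' inspection is outside the scope of Cq-level processing; wells judged bad
#' upstream can be supplied through `blacklist`.
#'
#' @param cq long-format Cq table (as from [render_cq_plate()] or read from
#'   CSV) with columns `plate_id`, `well_id`, `assay_id`, `assay_role`,
#'   `cq`.
#' @param blacklist optional data.frame with `plate_id`, `well_id` of wells
#'   to drop regardless of controls.
#' @return list with `kept` (data.frame plate_id/well_id) and `excluded`
#'   (plate_id, well_id, control, cq, z, reason).
#' @export
qc_wells <- function(cq, blacklist = NULL) {
  ctrl_assays <- c("extension_ctl", "incubation_ctl", "detection_ctl")
  wells <- unique(cq[, c("plate_id", "well_id")])
  excl <- list()
  for (p in unique(wells$plate_id)) {
    sub <- cq[cq$plate_id == p & cq$assay_role %in% ctrl_assays, ]
    pw <- unique(sub$well_id)
    if (length(pw) < 3L)
      stop("plate ", p, " has fewer than 3 evaluable wells")
    for (ca in ctrl_assays) {
      v <- sub[sub$assay_role == ca, ]
      v <- v[match(pw, v$well_id), ]
      miss <- pw[is.na(v$cq)]
      if (length(miss))
        excl[[length(excl) + 1L]] <- data.frame(
          plate_id = p, well_id = miss, control = ca, cq = NA_real_,
          z = NA_real_, reason = "missing_control")
      ok <- !is.na(v$cq)
      if (sum(ok) >= 2L) {
        m <- mean(v$cq[ok]); s <- stats::sd(v$cq[ok])
        z <- (v$cq - m) / s
        out <- ok & s > 0 & abs(v$cq - m) > 2 * s
        if (any(out))
          excl[[length(excl) + 1L]] <- data.frame(
            plate_id = p, well_id = pw[out], control = ca,
            cq = v$cq[out], z = z[out], reason = "control_deviation")
      }
    }
  }
  if (!is.null(blacklist) && nrow(blacklist))
    excl[[length(excl) + 1L]] <- data.frame(
      plate_id = blacklist$plate_id, well_id = blacklist$well_id,
      control = NA_character_, cq = NA_real_, z = NA_real_,
      reason = "blacklist")
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(plate_id = character(), well_id = character(),
               control = character(), cq = numeric(), z = numeric(),
               reason = character())
  key <- paste(wells$plate_id, wells$well_id)
  bad <- key %in% paste(excluded$plate_id, excluded$well_id)
  list(kept = wells[!bad, , drop = FALSE], excluded = excluded)
}

#' Extension-control normalization (dCq)
#'
#' Normalizes for intra-plate variation by subtracting each well's
#' extension-control Cq from every assay of that well:
#' `dCq[assay, well] = Cq[assay, well] - Cq[extension_ctl, well]`.
#' Missing Cq propagates to missing dCq. Only wells passing [qc_wells()]
#' should be supplied.
#'
#' @param cq long-format Cq table.
#' @param kept optional data.frame plate_id/well_id of wells to keep (as
#'   returned by [qc_wells()]); default all wells.
#' @return the table restricted to kept wells with a `dcq` column added.
#' @export
extension_normalize <- function(cq, kept = NULL) {
  if (!is.null(kept)) {
    key <- paste(cq$plate_id, cq$well_id)
    cq <- cq[key %in% paste(kept$plate_id, kept$well_id), ]
  }
  wkey <- paste(cq$plate_id, cq$well_id)
  ext <- cq[cq$assay_role == "extension_ctl", ]
  ext_cq <- stats::setNames(ext$cq, paste(ext$plate_id, ext$well_id))
  if (anyNA(ext_cq[unique(wkey)]))
    stop("extension control missing in a kept well; run qc_wells first")
  cq$dcq <- cq$cq - ext_cq[wkey]
  cq
}

#' Background correction against lysis-buffer wells
#'
#' For each target assay, the detection threshold is
#' `T = mean(buffer dCq) + 2 * SD(buffer dCq)` over that plate set's
#' buffer wells, and the signal of a well is `T - dCq`, so larger signal
#' means more protein. Signals below zero are floored at zero and deemed
#' undetected; missing dCq also yields zero, undetected. Assays with fewer
#' than two buffer observations are dropped with a warning (SD undefined).
#'
#' @param dcq long-format table with a `dcq` column
#'   (from [extension_normalize()]).
#' @param per_plate logical; compute buffer thresholds within each plate
#'   (default) rather than across all plates.
#' @param sum_normalize logical; if TRUE, additionally divide each
#'   single-cell well's signals by that well's cumulative protein sum
#'   (off by default).
#' @return list of class `protein_signal`: `signal` and `detected`
#'   (assay x well matrices over non-buffer wells), `threshold` per
#'   assay (or assay x plate), `protein_sum` per well, `wells` (the well
#'   annotation), `dropped_assays`.
#' @export
background_correct <- function(dcq, per_plate = TRUE, sum_normalize = FALSE) {
  tg <- dcq[dcq$assay_role == "target", ]
  tg$wkey <- paste(tg$plate_id, tg$well_id)
  assays <- unique(tg$assay_id)
  wells <- unique(tg[tg$well_role != "buffer",
                     c("plate_id", "well_id", "well_role", "time_point",
                       "cell_id")])
  wells$wkey <- paste(wells$plate_id, wells$well_id)

  thr_for <- function(sub) {
    b <- sub$dcq[sub$well_role == "buffer" & !is.na(sub$dcq)]
    if (length(b) < 2L) return(NA_real_)
    mean(b) + 2 * stats::sd(b)
  }

  signal <- matrix(0, length(assays), nrow(wells),
                   dimnames = list(assays, wells$wkey))
  detected <- matrix(FALSE, length(assays), nrow(wells),
                     dimnames = list(assays, wells$wkey))
  dropped <- character(0)
  for (a in assays) {
    sa <- tg[tg$assay_id == a, ]
    if (per_plate) {
      ok_any <- FALSE
      for (p in unique(sa$plate_id)) {
        sp <- sa[sa$plate_id == p, ]
        thr <- thr_for(sp)
        if (is.na(thr)) next
        ok_any <- TRUE
        sp <- sp[sp$well_role != "buffer", ]
        s <- thr - sp$dcq
        s[is.na(s) | s < 0] <- 0
        signal[a, sp$wkey] <- s
        detected[a, sp$wkey] <- s > 0
      }
      if (!ok_any) dropped <- c(dropped, a)
    } else {
      thr <- thr_for(sa)
      if (is.na(thr)) { dropped <- c(dropped, a); next }
      sa2 <- sa[sa$well_role != "buffer", ]
      s <- thr - sa2$dcq
      s[is.na(s) | s < 0] <- 0
      signal[a, sa2$wkey] <- s
      detected[a, sa2$wkey] <- s > 0
    }
  }
  if (length(dropped)) {
    warning("dropping assays with < 2 buffer observations: ",
            paste(dropped, collapse = ", "))
    signal <- signal[!rownames(signal) %in% dropped, , drop = FALSE]
    detected <- detected[!rownames(detected) %in% dropped, , drop = FALSE]
  }
  protein_sum <- colSums(signal)
  if (sum_normalize) {
    sc <- wells$well_role == "single_cell" & protein_sum > 0
    signal[, sc] <- sweep(signal[, sc, drop = FALSE], 2, protein_sum[sc], "/")
  }
  structure(list(signal = signal, detected = detected,
                 protein_sum = protein_sum, wells = wells,
                 dropped_assays = dropped),
            class = "protein_signal")
}

#' Detectability filter on 100-cell population controls
#'
#' Keeps assays whose mean pop100 signal (over duplicate wells) exceeds
#' `min_over_bg` Cq units over background at at least one time point
#' (strict inequality).
#'
#' @param ps a `protein_signal` from [background_correct()].
#' @param min_over_bg threshold in Cq units over background (default 3).
#' @return character vector of retained assay ids.
#' @export
detectability_filter <- function(ps, min_over_bg = 3) {
  pop <- ps$wells$well_role == "pop100"
  if (!any(pop)) stop("no pop100 wells present")
  tps <- unique(ps$wells$time_point[pop])
  keep <- rep(FALSE, nrow(ps$signal))
  for (tp in tps) {
    cols <- pop & ps$wells$time_point == tp
    keep <- keep | rowMeans(ps$signal[, cols, drop = FALSE]) > min_over_bg
  }
  rownames(ps$signal)[keep]
}

#' Inter-plate reproducibility metric
#'
#' Coefficient of variation of the shared control-lysate wells per assay,
#' across all plates (a report-only metric; no correction is applied).
#'
#' @param ps a `protein_signal`.
#' @return data.frame assay_id / cv.
#' @export
interplate_cv <- function(ps) {
  ip <- ps$wells$well_role == "interplate_lysate"
  if (!any(ip)) stop("no interplate_lysate wells present")
  s <- ps$signal[, ip, drop = FALSE]
  data.frame(assay_id = rownames(s),
             cv = apply(s, 1, function(x)
               if (mean(x) > 0) stats::sd(x) / mean(x) else NA_real_),
             row.names = NULL)
}

#' Full PEA processing pipeline
#'
#' Convenience wrapper chaining [qc_wells()], [extension_normalize()],
#' [background_correct()] and [detectability_filter()]; returns the
#' processed signal restricted to single-cell wells of detectable assays.
#'
#' @inheritParams qc_wells
#' @inheritParams background_correct
#' @inheritParams detectability_filter
#' @param apply_detectability drop assays failing the pop100 filter
#'   (default TRUE).
#' @return list: `cells` (assay x cell signal matrix, columns named by
#'   cell_id), `detected` (matching mask), `signal` (full
#'   `protein_signal`), `qc` (well QC result), `kept_assays`.
#' @export
pea_pipeline <- function(cq, blacklist = NULL, min_over_bg = 3,
                         per_plate = TRUE, sum_normalize = FALSE,
                         apply_detectability = TRUE) {
  qc <- qc_wells(cq, blacklist = blacklist)
  dcq <- extension_normalize(cq, kept = qc$kept)
  ps <- background_correct(dcq, per_plate = per_plate,
                           sum_normalize = sum_normalize)
  kept_assays <- if (apply_detectability)
    detectability_filter(ps, min_over_bg) else rownames(ps$signal)
  sc <- ps$wells$well_role == "single_cell"
  cells <- ps$signal[kept_assays, sc, drop = FALSE]
  det <- ps$detected[kept_assays, sc, drop = FALSE]
  colnames(cells) <- colnames(det) <- ps$wells$cell_id[sc]
  list(cells = cells, detected = det, signal = ps, qc = qc,
       kept_assays = kept_assays)
}
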