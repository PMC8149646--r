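# coprofile

Analysis toolkit for single-cell experiments that measure **global mRNA
and multiplexed intracellular proteins in the same cells** — full-length
scRNA-seq (with ERCC spike-ins) combined with proximity extension assays
(PEA) read out as qPCR Cq values, across a short differentiation time
course (0/24/48 h).

Such co-profiling asks questions that neither modality answers alone: does
a transcript's level predict its protein's level in the same cell? Do the
two modalities order cells identically along differentiation? Does a
transcription factor's *protein* predict its regulatory targets better
than its mRNA? And how much of protein expression variability is explained
by RNA variability versus translation?

## What the package provides

* **PEA plate processing** — well QC against spiked control assays
  (exclusion beyond 2 SD of the per-plate control mean), extension-control
  normalization (`dCq = Cq − Cq_ext`), background correction against
  lysis-buffer wells (`signal = [buffer mean + 2 SD] − dCq`, floored at
  zero), and a detectability filter on 100-cell population controls
  (> 3 Cq over background).
* **scRNA-seq processing** — cell QC (≥ 10,000 exonic reads, ≤ 20% ERCC
  fraction), RPM/RPKM normalization, and a protocol-comparison statistic
  (logarithmic mean expression, DE ratio, product score).
* **Cell state & pseudotime** — bin-matched cell-cycle module scores with
  G1/S/G2M assignment, covariate regression, 3-D embedding (tSNE/PCA),
  cluster-based principal-trajectory pseudotime oriented by harvest time
  and scaled to hours, cross-modality ordering concordance (Spearman),
  trajectory-variable genes (spline F-test, BH), and the per-gene
  RNA-slope → protein-slope linear model `k_prot = x·k_RNA + z`.
* **Regulatory network evaluation** — TF→gene link weights (reduced
  GENIE3-style tree-ensemble importance with decoy calibration, or
  Pearson), target-vs-background rank-sum separation, exact tie-corrected
  ROC/AUC with Youden point (AUC ≡ Mann–Whitney U/(n₊·n₋)), a permutation
  null for the AUC, and two-stage novel-target discovery (top-5% weight +
  TSS-binding evidence + FDR < 0.05 in ≥ 2 analysis groups).
* **Expression variation** — per-gene CV² = var/mean², polynomial
  mean-dependence removal in log space ("normalized variation"),
  RNA-vs-protein residual comparison, translation-rate estimates
  (log2 protein/RPKM), and the additive predictor
  `resid_RNA + 0.75 × translation rate` of protein variability.
* **A ground-truth simulator** — telegraph bursting with geometric burst
  sizes, translation/decay kinetics, differentiation schedules,
  cell-cycle and cell-size modulation, protein-level regulatory coupling,
  and both measurement layers (binomial capture + multinomial reads;
  Cq plates with plate offsets, control assays, buffer/pop100/inter-plate
  wells). Used throughout the tests for parameter-recovery validation.

## Worked example

```r
library(coprofile)

# 1. Simulate a differentiation experiment (0/24/48 h) with ground truth
kin   <- default_kinetics(n_genes = 120, seed = 1)
cfg   <- sim_config(n_cells_per_timepoint = c(84, 83, 83), seed = 1)
truth <- simulate_cells(kin, cfg)

# 2. RNA layer: counts -> QC -> RPKM
sc   <- render_rna_counts(truth, cfg)
qc   <- qc_cells(sc$counts, sc$is_ercc)
expr <- normalize_expression(sc$counts, sc$gene_length, sc$is_ercc, qc$qc_pass)
log_rpkm <- log2(expr$rpkm[!sc$is_ercc, ] + 1)

# 3. Protein layer: Cq plates -> well QC -> dCq -> background -> signal
cq  <- render_cq_plate(truth, config = cfg)
pea <- pea_pipeline(cq)

# 4. Pseudotime per modality, then ordering concordance
ph <- phase_scores(log_rpkm, kin$gene_id[kin$s_marker],
                   kin$gene_id[kin$g2m_marker], seed = 1)
tl <- truth$time_label[match(colnames(log_rpkm), colnames(truth$mrna))]
tr_rna  <- trajectory_pseudotime(
  log_rpkm, tl,
  covariates = data.frame(ndet = colSums(expr$counts[!sc$is_ercc, ] > 0),
                          s = ph$s_score, g2m = ph$g2m_score),
  seed = 1)
tlp <- truth$time_label[match(colnames(pea$cells), colnames(truth$mrna))]
tr_prot <- trajectory_pseudotime(pea$cells, tlp, seed = 1)
ordering_concordance(tr_rna$pt_hours, tr_prot$pt_hours)

# 5. How much AUC does a random target assignment produce?
w  <- with_seed(1, setNames(runif(8610), paste0("g", 1:8610)))
permutation_null(w, n_pos = 8, n_perm = 200, seed = 1)
```

This prints (numbers from the run above):

```
ground_truth: 120 genes x 250 cells; harvests at 0/24/48 h
250 of 250 cells pass RNA QC
92 assays detectable; 217 single-cell wells kept
RNA-vs-protein ordering concordance: rho = 0.86 (n = 217)
permutation-null AUC: 0.49 +/- 0.102
```

Reading the output: all simulated cells pass RNA QC (none were rendered
as failing here); the PEA pipeline keeps 92 detectable assays and 217
single-cell wells after control-based well QC; ordering the same cells by
RNA or by protein gives closely agreeing pseudotimes (Spearman rho 0.86);
and a fixed gene ranking scored against 200 random 8-gene target sets
yields a mean AUC of ~0.5 — the chance baseline against which real
TF-target rankings are judged.

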