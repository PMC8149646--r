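---
title: "Co-profiling analysis methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-profiling analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(coprofile)
```

`coprofile` analyses single-cell experiments in which global mRNA
(full-length scRNA-seq with ERCC spike-ins) and a multiplexed panel of
intracellular proteins (proximity extension assays, PEA, read out as qPCR
Cq values) are measured in the *same* cells, typically across a short
differentiation time course (0/24/48 h). This vignette explains the models
behind each stage, the tunable parameters and their defaults, and the
design decisions taken where more than one reasonable construction exists.
It states no empirical results; all quantitative claims about the
package's behaviour live in the test suite, which computes them.

## The kinetic model behind the synthetic data

Validation rests on a generative simulator of coupled transcription and
translation. Each gene follows the instantaneous-burst limit of the
two-state (telegraph) model:

* transcriptional bursts arrive as a Poisson process with rate
  `burst_on_rate` (bursts/hour);
* each burst deposits a geometric number of mRNAs with mean `burst_size`;
* mRNA decays exponentially with half-life `mrna_halflife`;
* each mRNA produces protein at `translation_rate` proteins/(mRNA·hour);
* protein decays exponentially with half-life `protein_halflife`.

At stationarity the mRNA marginal is negative-binomial with mean
$\mu_m = k_{on} b\, t_{1/2,m}/\ln 2$ and $CV^2_m = (1+b)/\mu_m$; the
protein mean is $\mu_p = \mu_m\, k_{tl}\, t_{1/2,p}/\ln 2$. The
simulator initialises every cell from these stationary laws and advances
by tau-leaping: Poisson burst arrivals, binomial decay with the exact
per-step survival probability, and Poisson translation. Newly produced
molecules are binomially thinned by the expected within-step survival
$(1-e^{-d\,\Delta t})/(d\,\Delta t)$; without this correction the
discrete-time stationary mean is inflated by a factor
$d\,\Delta t/(1-e^{-d\,\Delta t})$ (about 5% at the default
`dt = 0.1` h for a one-hour mRNA lifetime). With it, the first moments
are exact for any step size; `dt` only affects higher-order temporal
correlation structure.

Three biological modulations multiply the burst rate:

* **Differentiation.** A per-gene schedule `(mod0, mod24, mod48)` is
  interpolated piecewise-linearly in log space over 0–48 h. Cells are
  sampled at their harvest label plus a small jitter
  (`time_jitter_sd = 2` h) so a continuous pseudotime is in principle
  recoverable. The default panel (`default_kinetics`) makes 30% of genes
  responsive with 16-fold swings by 48 h, mirroring the strong on/off
  switches (stemness factors, early neural genes) that dominate early
  directed differentiation.
* **Cell cycle.** A latent phase (G1/S/G2M at 50/30/20%) modulates
  designated marker genes: `marker_mod`-fold up in their own phase and
  `1/marker_mod` outside it (default 2.5), i.e. markers are
  phase-*specific*, as cyclins are. Without the out-of-phase suppression
  a marker is merely "sometimes higher", and phase scores in G1 cells are
  centred at zero rather than below it, which makes the G1 fallback rule
  uninformative.
* **Cell size.** A log-normal size factor (`size_factor_sd = 0.15`,
  mean 1) scales every gene's burst rate, creating the global
  covariation between totals and cell size that the covariate-regression
  stage is meant to remove.

**Regulation.** A target gene's burst rate is multiplied by
$\big((p+1)/(p_{ref}+1)\big)^{2 s\, e}$, where $p$ is the regulator's
current protein copy number, $p_{ref}$ its unregulated stationary mean,
$s = \pm 1$ the effect sign and $e \in [0,1]$ the effect strength,
clamped to $[1/16, 16]$. The exponent $2e$ gives Hill-like
cooperativity: a full-strength target responds steeply to regulator dose,
as TF dose–response curves with Hill coefficients of 2–4 do. Setting
$e = 0$ removes the coupling exactly (the in-silico knockdown used in the
tests). Regulators are simulated first and their protein trajectories
stored, so targets see the regulator's *protein*, not a proxy —
this is what makes protein-based link weights genuinely more informative
than mRNA-based ones when the regulator's mRNA is short-lived and noisy.

### The two measurement layers

*Sequencing*: each true mRNA molecule is captured independently with
probability `capture_efficiency` (default 0.2) times a per-cell
log-normal factor (`capture_sd = 0.35`); reads are multinomial over
captured molecules at `sequencing_depth` (default 1e5). The per-cell
capture factor matters: it makes the number of detected genes per cell a
*technical* covariate, as it predominantly is in real libraries. In a
small panel without it, detected-gene counts are driven by the genes that
differentiation switches off, and regressing them out (as the standard
pipeline does) removes biology instead of noise. ERCC spike-ins enter at
fixed copies (about 3% of a typical cell's mRNA); QC-failing cells can be
injected deliberately (low depth, or spike-dominated lysate).

*PEA/qPCR*: for target assays,
`Cq = cq_intercept − log2(protein units + background) + plate offset +
N(0, cq_noise_sd)`, clipped at `cq_max = 40` and reported missing beyond
it; lower Cq is more protein (qPCR convention). Extension, incubation and
detection control assays share each plate's offset, so dCq normalization
cancels it. Buffer wells contain background only; pop100 wells hold the
summed protein of 100 resampled cells; inter-plate wells a fixed shared
lysate. The default layout is one 96-well plate per harvest with
duplicate pop100, triplicate buffer and triplicate inter-plate wells.

What the generator does **not** emulate: transcript-level read placement
(no FASTQ, no GC or length bias within a gene), UMIs (the emulated
protocol is non-UMI full-length), antibody cross-reactivity, and
amplification-curve shapes. Passing recovery tests therefore demonstrates
that the analysis logic is correct under the stated noise model, not that
it is robust to every artefact of real data.

## PEA plate processing

Processing follows the standard single-cell PEA scheme:

1. **Well QC** — a well is dropped if any of its three control assays is
   missing, or deviates from that control's per-plate mean by more than
   2 sample SD (strict). Controls are assessed independently, per plate;
   we read the "across all samples measured on one chip" rule as
   per-plate because each plate is read on one chip. Amplification-curve
   inspection is upstream of Cq data; a pre-supplied blacklist is
   honoured instead.
2. **Extension normalization** — `dCq = Cq − Cq(extension control)`
   within each well; missing propagates.
3. **Background correction** — per assay, threshold
   `T = mean + 2 SD` of the buffer-well dCq; `signal = T − dCq`, so
   larger signal means more protein, negatives floored to zero and
   flagged undetected. Sample SD (n−1) is used throughout; with fewer
   than two buffer observations the SD is undefined and the assay is
   dropped with a warning.
4. **Detectability** — an assay is kept if its mean pop100 signal
   exceeds 3 Cq over background at one or more time points (strict).

Boundary conventions are uniformly strict (`> 2 SD` excludes, `> 3 Cq`
keeps), matching the wording "greater". The cumulative protein sum is the
column sum over target assays; per-cell sum-normalization is available
but off by default. Inter-plate lysate wells yield a per-assay CV as a
report-only reproducibility metric; no correction is derived from them.

## RNA processing and protocol comparison

Cells need at least 10,000 exon-mapped (non-spike-in) reads and at most
20% spike-in reads. RPKM is `counts · 1e9 / (length · exonic total)`;
RPM rescales to per-million; ERCC rows are normalized with the same
denominator but excluded from totals. "log RPKM" means `log2(RPKM + 1)`
throughout — base and pseudocount are configurable decisions, not data.

The protocol-comparison statistic works on per-gene logarithmic mean
expression (LME): genes with pooled LME > 1 enter; `DE-prot` is the ratio
of group LMEs (as literally defined; a log-ratio-of-means alternative is
available behind `ratio_of_logs = FALSE`); the flag score is pooled LME ×
DE-prot with threshold 8. Pooled LME is the mean over all cells of both
groups, which is how we read "for all samples irrespective of protocol".

## Cell state and pseudotime

Phase scores are bin-matched module scores: genes are binned on average
expression (nominally 25 bins, capped so each bin keeps ≥ ~8 genes —
with a panel far smaller than a transcriptome, 25 bins would leave
near-empty control pools), and a set's score is the mean z-scored marker
expression minus the mean of bin-matched, seeded control genes. Phase is
the argmax of (S, G2M) scores if positive, else G1.

Covariates (detected genes, S score, G2M score) are regressed out per
gene by OLS; residuals are exactly uncorrelated with each retained
covariate. We regress rather than rescale by scores because the variance
rescaling constants in the original tooling are unspecified; regression
has the same intent (removing cycle- and depth-driven axes) with a
defined estimator.

The embedding is tSNE into 3 dimensions (perplexity 30, seeded),
falling back to PCA below 50 cells where tSNE is unstable; features are
z-scored first (the standard scale-data step — without it high-mean genes
dominate the embedding). Trajectory inference is cluster-based principal
curves: k-means (k = 4), shortest Hamiltonian path through the centers
(exhaustive; k is small), then up to 10 rounds of project-and-smooth
(lowess, span 0.3, 100 nodes) until the mean projection shift falls
below 1e-4 of the curve length. Pseudotime is arc-length position
rescaled to [0, 1], oriented so 0 h cells precede 48 h cells — flipping
by `pt ← (pt − 1)(−1)`, an isometry — and multiplied by 48 to give
hours.

Trajectory-variable genes use a natural cubic spline (3 df) versus
intercept F-test with BH adjustment — a deliberate, documented
replacement for the original tool's internal test — and significant
genes are clustered into modules by k-means on standardized fitted
profiles. Constant genes get p = 1 by convention. The RNA-vs-protein
slope model fits per-gene OLS slopes of log RPKM and of protein signal
against pseudotime (protein slopes over detected cells only), then
regresses protein slopes on RNA slopes across genes.

## Regulatory network evaluation

Link weights come in two flavours. The tree method is a reduced
GENIE3: per candidate target, a 100-tree regression forest predicts the
gene from the TF profile plus 20 seeded decoy predictors (permutations of
the TF profile, sharing its marginal but carrying no signal), and the
weight is the TF's share of total importance. The decoys calibrate the
importance null in place of the full all-gene predictor matrix, which is
out of scope at this problem size. The Pearson method uses |r|; the
signed r and its p-value are always carried for up/down calls and FDR.

ROC curves rank genes by weight with tied blocks collapsed, so the
trapezoidal AUC equals the tie-corrected Mann–Whitney U statistic — the
test suite verifies exact agreement with a brute-force pair count. The
permutation null redraws which genes are positives (200 draws by
default); exchangeability centres it at AUC 0.5 with closed-form SD
$\sqrt{(n_+ + n_- + 1)/(12 n_+ n_-)}$ for tie-free rankings. Target
discovery requires membership in the top 5% of weights in ≥ 1 analysis
group, binding evidence near the TSS (a pre-curated input list), and
FDR < 0.05 in ≥ 2 groups. The mean-RPKM ≥ 2 expression filter is
boundary-inclusive.

In the discovery validation fixture, the 500-gene background is held
static and only the regulator responds to differentiation. This isolates
the discovery logic: with a background full of equally strong
differentiation switches, time acts as a confounder that inflates
correlations of unrelated genes with the regulator — a real phenomenon,
but one that the binding-evidence filter, not the correlation machinery,
is meant to address.

## Expression variation

Per-gene `CV² = var/mean²` over cells; a degree-2 polynomial of log CV²
on log mean (natural logs; residuals are scale-free) defines the trend,
and residuals from it are the mean-independent "normalized variation".
Genes with zero mean or zero CV² are excluded from the fit rather than
pseudocounted — a pseudocount would manufacture residual structure at
the low end. Translation rates are estimated as
`log2(bulk protein abundance / mean RPKM)`, and the combined predictor of
protein variability is `resid_RNA + 0.75 × translation rate`; the 0.75
weight is exposed as a parameter and reflects the different dynamic
ranges of its two inputs.

One finding from building the simulator deserves emphasis: the
translation-rate channel of protein noise is only visible for
short-lived, low-copy proteins. For very stable proteins
($t_{1/2,p} \gg t_{1/2,m}$), time-averaging attenuates propagated mRNA
fluctuations by $d_p/(d_m + d_p)$, and since the protein mean scales with
the translation rate, the translation-burst contribution to *residual*
(mean-corrected) variation cancels. The combined-predictor validation
therefore simulates a panel of short-lived proteins
($t_{1/2,p} \approx 2.5$ h, translation rates spanning two orders of
magnitude); for a panel of highly stable proteins, RNA residuals alone
are already near-optimal and the translation term adds nothing.

## Problem sizes, seeds and tolerances

Validation runs use the study-scale design: about 250 cells (85/76/86 per
harvest), panels of 60–500 genes, one 96-well plate per harvest with the
control-well complement described above. Every stochastic stage derives
its stream from a master seed via a stage-label hash (`derive_seed`), so
stages are reproducible in isolation and identical seeds give
bit-identical outputs. Numerical conventions: `dt = 0.1` h tau-leap;
burn-in twice the longest protein half-life (capped at 60 h) on top of
exact stationary initialisation; lowess span 0.3 and 100 curve nodes for
trajectory refinement; ties mid-ranked in all Spearman statistics.

Known limitations: no branching trajectories (the modelled process is a
single path); no UMI or transcript-isoform support; no technical-noise
deconvolution of CV² (deliberately, matching the analysed protocol); the
tree-ensemble variant calibrates against decoys rather than all genes;
and simulation-based directional claims (protein-vs-RNA AUC ordering,
combined-predictor gains) are statements about the stated generative
regimes, not about every parameter combination.
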