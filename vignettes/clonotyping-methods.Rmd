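---
title: "Methods: longitudinal subclone detection from expression-inferred copy number"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal subclone detection from expression-inferred copy number}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`clonotrace` detects minor therapy-resistant tumor subclones present at
diagnosis by clustering paired diagnosis/relapse single cells on copy-number
profiles inferred from expression alone. This vignette is the package's own
account of the model, the tunable parameters, the synthetic data the tests
rely on, and the numerical choices made where the design was genuinely open.

## The inference model

### From counts to copy-number residuals

Counts are library-size normalized and log-transformed,
$x_{ig} = \log(1 + c_{ig} \cdot 10^4 / C_i)$. Copy-number inference then
proceeds in the inferCNV style:

1. **Gene filter.** Genes with mean normalized expression below 0.1 across
   the analyzed cells are removed; too-sparse genes carry no usable dosage
   signal.
2. **Reference residuals.** The per-gene mean over *reference* cells — the
   non-malignant cells identified by marker-based typing — is subtracted,
   and residuals are clipped to ±3 to bound outlier leverage.
3. **Chromosome-ordered smoothing.** Residuals are averaged along genome
   order with a triangular (pyramidal) window of 101 genes, renormalized at
   chromosome edges and never mixing chromosomes. A constant signal is
   conserved exactly — this is tested against a brute-force oracle.
4. **Median centering.** Each cell's median smoothed residual is subtracted
   so its diploid baseline sits at zero.

The expected smoothed residual of a gene at copy number $c$ is then
approximately $\log(c/2)$ for well-expressed genes, shrinking toward zero
for shallow ones.

### Six-state HMM copy-state calling

Copy states $\{0, 1, 2, 3, 4, 5{+}\}$ are decoded per cell and chromosome
by Viterbi under Gaussian emissions
$\mathcal{N}(\mu_s, \sigma^2)$ with dosage-log means
$\mu_s = \log(\max(s, \varepsilon_0)/2)$, $\varepsilon_0 = 0.05$, and a
uniform-switch transition matrix (stay probability $1 - 5t$, switch $t$ to
each other state, default $t = 10^{-6}$). Ties are broken toward the
diploid state, then the lower state. The decoder is verified against
exhaustive enumeration of all $6^L$ paths for segments up to length 8.

Two calibrations are estimated from the data:

* **Emission sd.** $\sigma$ is the sd of the reference cells' smoothed
  centered residuals, floored at 0.05 and multiplied by an *sd amplifier*
  (default 3). Smoothing makes neighboring residuals strongly correlated,
  so an HMM calibrated to the marginal sd walks across state boundaries on
  noise excursions; the amplifier — the same lever inferCNV exposes —
  restores the intended persistence. With it, reference cells decode
  ≥ 99% diploid on clean data while planted events are still recovered.
* **Dosage attenuation.** At ~5000 UMIs per cell a copy ratio $r$ shifts
  $\log(1+x)$ expression by less than $\log r$; `dosage_attenuation()`
  predicts the average shortfall from the reference expression levels
  (typically 0.4–0.8 depending on depth). Per-cell decoding keeps the
  *unattenuated* means: single-cell profiles carry whole-chromosome
  sampling wobble, and the wide boundaries keep reference cells diploid.
  Clone-level decoding (`group_copy_segments()`, used for segment
  reporting, precursor matching and bulk validation) averages profiles
  over a subclone's cells — removing the wobble — and applies the
  attenuation-calibrated means, without which genuine events at realistic
  depth sit inside the diploid decision region. This mirrors inferCNV's
  default of reporting HMM calls at the subcluster level.

### Subclone clonotyping and longitudinal classification

Malignant cells from both timepoints are clustered **jointly** on their
smoothed residual profiles (PCA, shared-nearest-neighbor graph, Leiden
under the modularity objective; Ward.D2 with a fixed cut is available),
so subclone labels are shared across timepoints. Composition tables give
per-sample proportions; each subclone is classified with
$r = (p_\mathrm{rel} + \epsilon)/(p_\mathrm{dg} + \epsilon)$, resistant
iff $r \ge \theta_r = 0.8$ (a ≤ 20% relative drop still counts as
persistent), with $\epsilon$ = half a cell's worth at diagnosis as a
continuity correction; subclones absent at diagnosis are
`relapse_specific`. Multi-compartment relapse is classified per
compartment, combined as resistant-if-resistant-anywhere.

Precursor matching bins each subclone-by-timepoint segment table on a
100 kb grid and scores pairs by the directional Jaccard index: bins
non-diploid in both profiles with the same sign, over bins non-diploid in
either. The score is symmetric and equals 1 exactly when binned
non-diploid patterns coincide. **Full-coverage tables (diploid runs
included) must enter the binning**: events-only tables turn diploid
regions into missing bins and the score degenerates to agreement on the
jointly covered (typically truncal) regions.

### Concordance with bulk segments

Segment profiles are compared after uniform 100 kb binning over autosomes
(bins overlapping multiple segments take the *unweighted* mean of their
copy numbers; a bp-weighted mode is available behind a flag), subtraction
of the diploid baseline, and Spearman rank correlation over bins present
in both profiles (average ranks for ties; undefined below 3 shared bins or
for constant profiles). Binning is linear in clonal mixtures, which the
tests exploit. The pipeline's inferred pseudo-bulk profile is the
cell-proportion-weighted mixture of the subclone-level decoded integer
profiles — the same construction by which a bulk sample mixes its clones —
rather than a mean of noisy per-cell states. Inferred subclone events are
additionally intersected with the bulk table, retaining only gains and
losses whose direction a bulk segment confirms.

## Downstream statistics

* **Differential expression.** Wilcoxon rank-sum on normalized expression,
  pre-filtered to $|\log_2\mathrm{FC}| \ge 0.25$ (difference of group means
  of $\log_2(1+\text{expr})$) and expression in ≥ 10% of either group.
  Groups of ≤ 25 cells are tested by *exact permutation enumeration* — a
  dynamic program over doubled average ranks, so ties are handled exactly,
  with the symmetric two-sided definition
  $p = P(|W - \mu_W| \ge |w - \mu_W|)$; larger groups use the
  tie-corrected, continuity-corrected normal approximation. Significance:
  adjusted p < 0.05, $|\log_2\mathrm{FC}| > 0.8$, expressed in > 25% of the
  higher group. The 0.25/0.8 thresholds are read on the log2 scale.
* **Preranked GSEA.** Weighted Kolmogorov–Smirnov running sum
  (hit increments $\propto |s|^w$, $w = 1$); null by gene-label
  permutation; NES = ES divided by the mean |null ES| of matching sign;
  $p = (1 + \#\{|ES_\mathrm{null}| \ge |ES|\})/(n_\mathrm{perm}+1)$. The
  two-sided form is deliberate: conditioning the count on the observed ES
  sign bounds p at ~0.5 under the null and breaks uniformity, which the
  null-calibration test checks by KS against the uniform.
* **Cell-cycle scoring.** Module scores subtract expression-bin-matched
  control genes (24 quantile bins, 100 controls per set gene). Phases:
  G1 when both S and G2/M scores are ≤ 0, otherwise the larger score's
  phase (exact positive ties go to S with a warning). Phase-composition
  shifts are tested per patient by Pearson chi-square on the 2×3 table
  with BH correction across patients; phases absent at both timepoints
  are collapsed with a df reduction.

## The synthetic-data generator

The generator emulates the structure of a paired diagnosis/relapse MCL
experiment. Counts are negative binomial (gamma-Poisson) with mean
$\lambda_{ig} = L_i \, \rho_g \, (c_{g,k(i)}/2)^\alpha$: log-normal library
sizes (median ≈ 5000 UMIs), gamma baseline relative expression
(shape 0.6), shared dispersion (size = 2), dosage exponent $\alpha = 1$
(configurable, since the true expression–copy-number response in tumors is
buffered to an unknown degree), and homozygous deletions floored at
$\varepsilon_0 = 0.05$ of baseline. Planted structure:

* clonal architectures as parent/child subclones whose private events
  override inherited ones on overlap, with exact per-subclone and
  mixture-expected bulk segment tables as ground truth;
* a CCND1-like malignancy marker (placed on chr11, echoing the t(11;14)
  biology) expressed in malignant cells only, at 8× a high baseline;
* light-chain restriction: malignant cells express one immunoglobulin
  light chain at a 20:1 mean ratio over the other; normal B cells mix
  both — making the malignancy rule exercisable in both directions;
* per-cell-type marker sets for B/T/NK/monocyte-like normal populations;
* S and G2/M programs as 3× multipliers on 50-gene sets in a configurable
  fraction of malignant cells (defaults S = 0.15, G2M = 0.12, reflecting
  MCL's high proliferative index). Program genes get moderately high,
  *spread* baselines so they share control bins with background genes —
  giving them one shared baseline value concentrates them into a single
  expression bin and the control-matched score collapses;
* optional planted low-quality cells (high mitochondrial load, small
  libraries) for exercising the QC path.

The standard benchmark (`standard_experiment()`) is a 22-chromosome,
~6000-gene genome with 500 normal + 1500 malignant cells per timepoint;
subclones A/B/C at 0.90/0.09/0.01 (diagnosis) and 0.04/0.06/0.90
(relapse); every event spans ≥ 30 genes (most ~120, i.e. arm-scale, as is
typical of lymphoma CNVs) and clone C's profile equals the dominant
relapse profile. The full pipeline on this scenario runs in about a
minute on one core; module-level tests use a 6-chromosome, 480-gene
genome with 800 malignant cells.

**What passing tests do and do not show.** The generator draws genes
independently given the clone, has no ambient RNA, doublets, batch
effects, or gene-level dosage buffering, and its cell types differ only
through small marker sets. Recovery results on it demonstrate the
*internal correctness and calibration* of each stage (verified against
independent oracles), not performance on real tissue. Two limitations
observed even on synthetic data carry over to practice: (i) a
cell-type-mixed reference leaves marker-driven residual bumps that can be
called as small CNVs — the pipeline therefore excludes known
expression-program genes (cycle sets, light chains, the malignancy
marker) from CNV inference, and a type-matched reference is preferable
when available; (ii) per-cell copy-state calls at ~5000 UMIs are
conservative, which is why clone-level decoding backs the segment-level
conclusions.

## Design choices where the field's practice is open

* **Leiden resolution.** igraph's Leiden under modularity at resolution 1
  fragments homogeneous populations (two well-separated 100-cell blobs
  split into ~6 communities). Cell-level clustering defaults to
  resolution 0.3 — coarse enough for stable cluster-level QC and typing —
  and subclone clustering to 0.05, since clonal structure is coarse and
  CNV-profile blobs are large and dense. Both are config-exposed; the
  planted-partition tests document the recovery behavior.
* **SNN graph.** Euclidean kNN (k = 15) in PC space, Jaccard
  neighborhood weights pruned below 1/15 — the community standard.
* **HVG trend.** Degree-2 polynomial on log10 variance vs log10 mean of
  raw counts, standardized values clipped at $\sqrt{n}$; a smooth,
  deterministic stand-in for loess-based VST selection.
* **PCA dimensionality.** Components with individual explained-variance
  fraction ≥ 1.5%, floor of two; loadings sign-fixed (largest-magnitude
  loading positive) so embeddings are deterministic.
* **Light-chain rule.** "Ratio of kappa or lambda expression" is
  operationalized as the absolute difference of cluster-mean log1p
  expressions, threshold 1.0 (≈ an e-fold skew): monotone in the ratio,
  symmetric in the chains, robust to zeros.
* **Resistance threshold.** $\theta_r = 0.8$ encodes
  "expanded or persistent" vs "depleted or reduced" with a numeric rule;
  there is no canonical cutoff, so it is config-exposed.
* **Coordinates.** All segment tables are 1-based closed in files,
  converted internally where interval arithmetic requires it; bins tile
  each autosome from position 1.
* **Degenerate inputs.** All-zero cells are flagged and excluded before
  normalization (division by zero); zero-variance genes become zero
  columns under scaling; a fully diploid diagnostic profile makes the
  precursor score undefined and the match is declined with a warning;
  chi-square columns empty at both timepoints are collapsed with a
  warning.

## Known limitations

* Malignancy calls are cluster-level; a malignant cell inside a normal
  cluster inherits the normal call.
* The HMM assumes a shared emission sd across states and genes; strongly
  expression-dependent noise is only absorbed by smoothing.
* Precursor matching scores binned direction agreement, not event
  boundaries; two profiles with overlapping but differently sized events
  still score highly.
* The resistance classification is purely compositional; it does not ask
  *why* a clone survived therapy.
* Cytoband nomenclature, phylogeny reconstruction and SNV/VAF-based
  clonality are out of scope.
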