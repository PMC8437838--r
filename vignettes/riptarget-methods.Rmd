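---
title: "Calling RNA-binding-protein targets from 3'-end RIP-seq: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling RNA-binding-protein targets from 3'-end RIP-seq: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riptarget)
```

## The experiment and the question

RNA immunoprecipitation followed by sequencing (RIP-seq) asks which mRNAs
a given RNA-binding protein is physically associated with in a cell. The
design this package analyses splits each replicate lysate three ways: an
*Input* aliquot (total RNA), a specific-antibody IP (here labelled
`TIA1_IP` after the protein the package was built around), and an IgG
isotype-control IP that captures non-specific bead/antibody binding.
Libraries are 3'-end anchored (QuantSeq-style): reads pile up in a short
window around each polyadenylation site (PAS), so molecule counts — not
coverage — measure abundance, and unique molecular identifiers (UMIs)
collapse PCR duplicates.

Two quantities matter downstream:

* **Binding efficiency (BE)** of a gene: the log2 ratio of its abundance
  in the specific IP over the Input — the fraction of its transcripts the
  protein captures.
* **Target status**: a gene is called a target in a cell type when its
  specific-IP enrichment is at least 1.5-fold (log2 ≥ 0.58) with a
  Benjamini–Hochberg adjusted p ≤ 0.05 **both** over the IgG control
  (stage 1) and over the Input (stage 2).

## From reads to counts

Each PAS is captured by a fixed 30-nt window from 20 nt transcriptionally
upstream of the cleavage site to 10 nt downstream, absorbing random
priming and cleavage wobble. We realise coordinates 0-based and half-open:
on `+` the window is `[p - 20, p + 10)`; on `-` it is mirrored so that
"upstream" remains transcriptionally upstream. Note the inclusive reading
"−20 through +10" would span 31 nt; we honour the stated 30-nt length,
which costs at most one boundary base. Windows running below coordinate 0
are clipped with a warning.

Deduplication collapses exact `(sample, chrom, strand, position, UMI)`
keys only — no edit-distance clustering of UMIs, because 3'-end data with
short windows gains little from it and the simpler rule is auditable.
Assignment requires a strand match (3'-end protocols are stranded) and
membership `start ≤ position < end`. A read overlapping windows of more
than one gene is dropped and tallied as *ambiguous* by default —
conservative, and rare when PAS annotations separate genes — with an
optional fractional 1/k assignment. Counts of all PAS of a gene are summed
into the gene count.

## Normalisation

Size factors use the median-of-ratios estimator: per gene, the geometric
mean across samples is a pseudo-reference; a sample's factor is the median
of its ratios to that reference over genes with no zeros. For the
IP-vs-IgG stage only, the specific-IP factors are additionally multiplied
by 1.5 (`scale_ip_factors()`). This manual scaling conservatively encodes
the observation that the specific IP consistently yields several-fold
(≥ 4×) more RNA than the IgG control from the same number of cells:
without it, depth normalisation would erase the yield gap that is itself
evidence of specific binding. We deliberately do *not* apply the scaling
in the IP-vs-Input stage — the rationale for the factor is the IgG yield
gap, and the BE reported from stage 2 should remain an unbiased IP/Input
ratio; a flag (`apply_ip_scale_stage2`) restores global application for
users who read the procedure otherwise.

For QC we provide a sample-median normalisation (marker heatmaps), a
shifted-log transform `log2(count/sf + 1)` as a light-weight
variance-stabilising transform — exact parametric VST replication is out
of scope since the transform only feeds PCA — and a centred PCA on the
500 highest-variance genes (the usual plotPCA convention; configurable).

## The NB model and Wald testing

Counts are modelled per gene as negative binomial with log link,
`log mu = log(sf) + X beta`, with design `~ replicate + assay`. The
replicate factor pairs the three libraries made from one lysate and
absorbs gene-level batch effects; with a library missing (e.g. an IgG
replicate that yielded too little RNA), rank-deficient design columns are
dropped by QR pivoting and the fit proceeds.

Fitting is iteratively reweighted least squares, vectorised across genes
(all genes share the design matrix, so each IRLS step is two matrix
products plus small per-gene solves), run to a relative deviance change
below 1e-8 or 100 iterations. Dispersion estimation is in three steps:

1. **Gene-wise**: maximise the Cox–Reid adjusted profile likelihood
   (penalty −½ log det X'WX) on a 40-point log-spaced grid over
   `[1e-8, 10]` with parabolic refinement, holding fitted means from an
   initial moderate-dispersion fit. The grid is deterministic and robust;
   its ~±2% log-resolution is far below the sampling noise of a
   small-replicate estimate.
2. **Trend**: the parametric form `alpha(mu) = a0 + a1/mu`, fit by a
   gamma GLM with identity link on the informative genes with one
   outlier-exclusion pass. The gamma GLM operates on the natural scale,
   where the CR-adjusted gene-wise estimates are approximately
   mean-unbiased; fitting the trend on the log scale instead
   systematically underestimates dispersion (the mean of the log of a
   right-skewed estimator), which we measured as an inflated null
   rejection rate before settling on this estimator.
3. **Shrinkage**: each gene's final dispersion is a log-scale weighted
   average of gene-wise and trend values, weighting the gene-wise
   estimate by its residual df/2 against a prior weight of 8. Gene-wise
   estimates more than two robust SDs above the trend are kept unshrunk
   (dispersion outliers should not be pulled into false positives).

Wald tests report the contrast on the log2 scale with its standard error
from the inverse Fisher information and a two-sided standard-normal
p-value — the convention of NB differential-expression tools; no
likelihood-ratio test, no fold-change shrinkage, and no independent
filtering, because the calling thresholds act on the raw Wald log2 fold
change. All-zero genes are flagged untestable and propagate `NA` through
the BH adjustment, which is computed genome-wide within each contrast.
Stage 2 p-values are adjusted over all testable genes and then intersected
with the stage-1 passes (rather than re-adjusted within the stage-1
subset): this matches producing two results tables and filtering, and
keeps each stage's FDR interpretable on its own.

## What the simulator emulates — and what it does not

`simulation_config()` defaults encode the study conditions the package
was developed against: 3 cell types × 3 replicate lysates × 3 assays;
IgG yield at one quarter of Input (`igg_yield_ratio = 0.25`); bound
fractions of 18%/7%/3% per cell type; an option
(`igg_replicates = c(hESC = 3, NPC = 2, neuron = 2)`) for control
libraries lost to low yield; and NB counts with mean
`baseline × assay_factor × 2^(BE · [specific IP]) × lysate_effect × depth`.
Values the source experiment does not report were fixed once at realistic
levels: global dispersion 0.1 (typical of well-replicated bulk libraries),
log-normal baselines with `meanlog = log(1000), sdlog = 1` (consistent
with ~20 million 3'-end reads per library spread over an expressed
transcriptome of order 10⁴ genes — per-gene depth is kept at that level
regardless of how many genes a desk-scale simulation carries), gene-wise
lysate effects with `sdlog = 0.1`, depth factors uniform in
`[0.7, 1.3]`, and planted BE ~ N(2, 0.5²) truncated weakly positive.
Baselines are drawn independently per cell type, which produces the
strong cell-type separation a QC PCA should find.

The read-level path scatters molecule 3' ends uniformly inside their PAS
window, plants PCR duplicates at a Poisson rate per molecule, adds a
configurable off-window background, and guarantees distinct molecules
carry distinct `(position, UMI)` keys so that rate-zero deduplication is
lossless. It does **not** model sequencing errors, UMI errors,
internal-priming artefacts, alternative-PAS switching between conditions,
or mappability — so passing recovery tests demonstrate the statistical
pipeline, not robustness to those upstream artefacts. Likewise the NB
generator matches the inference model by construction; real-data
misspecification (outliers, composition shifts beyond the planted ones)
is only partially represented.

Problem sizes in the shipped tests were chosen to keep a full run
comfortable on one CPU: recovery and specificity fixtures use 5,000 genes
(three cell types, ~45 s each), calibration nulls 2,000 genes, unit
fixtures a few hundred. At these sizes the planted-truth benchmark gives
sensitivity ≈ 0.86 at empirical FDR 0 under the default thresholds.

## Downstream comparisons

* `compare_groups()` wraps the t-test: paired for the same transcripts
  across cell types (BE shifts along differentiation), unpaired for
  distinct gene groups within a sample. Unpaired comparisons default to
  Welch's correction — the safer choice when group variances differ —
  with classical pooled variance available via `var_equal = TRUE` for
  strict fidelity to "Student's t-test" wording.
* `compare_re()` contrasts ribosomal-engagement values of targets
  against all other detected genes (Welch); a negative mean difference
  is the translational-repression signature.
* `ddct()` implements relative qPCR quantification: fold change
  `2^−ΔΔCt` against a reference gene (18S rRNA by convention), plus
  percent-of-input with the Input Ct corrected by `log2(1/f)` for an
  input fraction `f` (default 0.1, i.e. a 10% aliquot). Both outputs are
  invariant to constant Ct shifts. The exact percent-of-input dilution
  arithmetic is a standard reconstruction — bench protocols rarely print
  it — and `f` is configurable for other splits.

Cell-type specificity uses the bottom-percentile rule: a gene is specific
to cell type X when it passes the expression filter in X and sits at or
below the 20th percentile (midrank ties) of the expressed genes of every
other cell type. The expression filter itself — undefined in most
write-ups — is: normalised Input count ≥ 5 in at least half of the cell
type's Input replicates; both the threshold and the percentile are
configurable.

## Degenerate inputs and numerical corners

* Size factors require at least one gene with positive counts in every
  sample; otherwise the error suggests filtering or a pseudocount.
* Fitted means are floored at 1e-8 and linear predictors capped at ±30,
  so groups with all-zero counts yield large-but-finite effect estimates
  with correspondingly large standard errors instead of overflow.
* `se = 0` with a non-zero estimate yields p = 0 with a warning; a zero
  contrast yields p = 1 exactly.
* Ambiguous-read and clipped-window counts are surfaced in run logs and
  assignment tallies rather than silently dropped.

## Reproducibility

Every generator derives its RNG stream deterministically from the config
seed plus a per-generator offset, so individual artefacts are
reproducible in isolation and a full `run_pipeline()` writes a manifest
of MD5 content hashes that is identical across runs with the same seed.
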