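# riptarget

Target calling for RIP-seq experiments quantified by 3'-end
(QuantSeq-style) sequencing.

RNA immunoprecipitation sequencing (RIP-seq) identifies the mRNAs bound
by an RNA-binding protein: each replicate lysate is split into an Input
aliquot, a specific-antibody IP, and an IgG isotype-control IP, and the
co-eluted RNAs are sequenced. With 3'-end libraries, reads stack in a
30-nt window around each polyadenylation site (PAS), UMIs collapse PCR
duplicates, and molecule counts per gene follow a negative-binomial
model. `riptarget` implements the full analysis:

1. **Quantification** — UMI deduplication, strand-aware assignment of
   read 3' ends to PAS windows (`[p − 20, p + 10)` on `+`, mirrored on
   `−`), aggregation to gene counts.
2. **Normalisation** — median-of-ratios size factors
   `sf_j = median_i (K_ij / (∏_j K_ij)^{1/m})`, with the specific-IP
   factors scaled ×1.5 for the IP-vs-IgG comparison to conservatively
   account for the ≥ 4× higher RNA yield of the specific IP over IgG.
3. **Testing** — per-gene NB GLM `log μ = log(sf) + Xβ` with design
   `~ replicate + assay` (replicate pairs the libraries from one
   lysate), Cox–Reid adjusted dispersion estimation shrunk toward a
   parametric `α(μ) = a₀ + a₁/μ` trend, Wald contrasts on the log2
   scale, Benjamini–Hochberg adjustment.
4. **Two-stage target calling** — a gene is a target in a cell type
   when `log2FC ≥ 0.58` (1.5-fold) and `padj ≤ 0.05` both for IP vs IgG
   (stage 1, scaled factors) and IP vs Input (stage 2, unscaled; its
   log2FC is the reported **binding efficiency**, BE).
5. **Downstream** — target-set overlaps, paired/unpaired t-tests of BE
   shifts across cell types, ribosomal-engagement comparisons
   (targets vs background), and qPCR ΔΔCt validation
   (`fold = 2^−ΔΔCt`, percent-of-input).

A synthetic-data module generates complete in-silico experiments with
planted ground truth (bound genes with known BE, IgG depletion,
replicate effects, PCR duplicates, off-window background, RE tables, Ct
tables), so every stage is testable against known answers.

## Worked example

```r
library(riptarget)

# a planted-truth experiment: 3 cell types x 3 replicates x 3 assays,
# 10% of 800 genes bound at log2 binding efficiency 2
fx <- make_fixtures("strong", n_genes = 800, seed = 42)
calls <- call_targets(fx$counts, fx$samples)
summarize_targets(calls)$n_targets
#>   hESC    NPC neuron
#>     67     52     65

# how well were the planted targets recovered?
key  <- paste(calls$gene_id, calls$cell_type)
tkey <- paste(fx$truth$gene_id, fx$truth$cell_type)
bound <- fx$truth$bound[match(key, tkey)]
c(sensitivity = sum(calls$is_target & bound) / sum(bound),
  fdr = sum(calls$is_target & !bound) / sum(calls$is_target))
#> sensitivity         fdr
#>   0.8761905   0.0000000
```

Each row of `calls` carries the stage-1 (IP vs IgG) and stage-2
(IP vs Input) log2 fold changes and adjusted p-values; `be_log2` is the
binding efficiency of the gene in that cell type, and `is_target`
applies the two-stage rule above. At this deliberately small fixture
size the caller recovers ~88% of planted targets with no false calls;
the 5,000-gene benchmark in the test suite gives sensitivity 0.86 at
empirical FDR 0.

A full run — simulate, normalise, call, downstream statistics, manifest
with content hashes — is one call:

```r
run_pipeline("my_run", simulation_config(n_genes = 2000, seed = 1))
```

`inst/scripts/riptarget` exposes the same stages as shell subcommands
(`riptarget run-all --out DIR --seed 1`).

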