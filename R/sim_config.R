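#' Configuration for a synthetic RIP-seq experiment
#'
#' Describes an in-silico experiment with the same shape as the bench
#' design the package analyses: several cell types, each with matched
#' Input, specific-antibody IP ("TIA1_IP") and IgG-control IP libraries
#' per replicate lysate, NB-distributed PAS counts, and a planted set of
#' bound genes whose IP libraries are enriched by a known log2 binding
#' efficiency.
#'
#' Defaults emulate the neurodevelopmental study design the package was
#' built around: three cell types (hESC, NPC, neuron) with three replicate
#' lysates each, an IgG RNA yield of one quarter of the Input-scale
#' libraries, bound fractions of 18%/7%/3% of genes, and per-gene depth
#' consistent with ~20 million 3'-end reads per library spread over an
#' expressed transcriptome. The situation where some IgG control
#' libraries yield too little RNA for library prep is available through
#' `igg_replicates` (e.g. `c(hESC = 3, NPC = 2, neuron = 2)`).
#'
#' @param n_genes number of simulated genes.
#' @param pas_per_gene integer range `c(min, max)`; each gene receives a
#'   uniform number of polyA sites in this range.
#' @param cell_types ordered character vector of cell-type labels.
#' @param n_replicates replicate lysates per cell type.
#' @param igg_replicates named integer vector (per cell type) of usable
#'   IgG-IP libraries; `NULL` (default) means all `n_replicates`. Set
#'   e.g. `c(hESC = 3, NPC = 2, neuron = 2)` to emulate control
#'   libraries whose RNA yield was too low for library prep.
#' @param fraction_bound scalar or per-cell-type vector in `[0, 1]`:
#'   fraction of genes bound by the protein.
#' @param be_log2_mean,be_log2_sd mean and spread of the planted log2
#'   binding efficiency of bound genes (log2 IP/Input enrichment).
#' @param igg_yield_ratio multiplicative depletion of IgG libraries
#'   relative to Input, in `(0, 1)`.
#' @param dispersion NB dispersion (alpha; `Var = mu + alpha mu^2`).
#' @param replicate_effect_sd sdlog of the gene-wise lognormal lysate
#'   (replicate) effect shared by the three assays of one lysate.
#' @param library_size_range uniform range of per-sample depth factors.
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of the
#'   per-(gene, cell type) baseline expression mean on the Input scale.
#' @param nested if `TRUE`, bound sets are nested along `cell_types`
#'   (each cell type's targets are a subset of the previous one's),
#'   mimicking a shrinking target repertoire along differentiation.
#' @param pas_min_separation minimum distance (nt) between polyA sites of
#'   different genes, so capture windows never straddle genes.
#' @param allow_overlapping_genes if `TRUE`, polyA sites are scattered
#'   without the separation guarantee (stress fixture).
#' @param reads_per_sample expected unique (deduplicated) reads per
#'   sample on the read-level simulation path.
#' @param pcr_duplicate_rate expected PCR duplicates per unique molecule
#'   (total reads = unique * (1 + rate) in expectation).
#' @param background_fraction fraction of reads falling outside any PAS
#'   window.
#' @param re_shift_targets downward shift of log-scale ribosomal
#'   engagement for bound genes.
#' @param re_sd spread of the ribosomal-engagement values.
#' @param qpcr_noise_sd technical noise (Ct units) of simulated qPCR.
#' @param seed integer seed; the same config (including seed) reproduces
#'   every generated object bit for bit.
#'
#' @return an object of class `rip_sim_config` (a validated list).
#' @export
simulation_config <- function(n_genes = 5000,
                              pas_per_gene = c(1L, 3L),
                              cell_types = c("hESC", "NPC", "neuron"),
                              n_replicates = 3L,
                              igg_replicates = NULL,
                              fraction_bound = c(hESC = 0.18, NPC = 0.07, neuron = 0.03),
                              be_log2_mean = 2,
                              be_log2_sd = 0.5,
                              igg_yield_ratio = 0.25,
                              dispersion = 0.1,
                              replicate_effect_sd = 0.1,
                              library_size_range = c(0.7, 1.3),
                              baseline_meanlog = log(1000),
                              baseline_sdlog = 1,
                              nested = FALSE,
                              pas_min_separation = 100L,
                              allow_overlapping_genes = FALSE,
                              reads_per_sample = 2e5,
                              pcr_duplicate_rate = 0.3,
                              background_fraction = 0.02,
                              re_shift_targets = 0.5,
                              re_sd = 1,
                              qpcr_noise_sd = 0.2,
                              seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), pas_per_gene = as.integer(pas_per_gene),
    cell_types = as.character(cell_types), n_replicates = as.integer(n_replicates),
    igg_replicates = igg_replicates, fraction_bound = fraction_bound,
    be_log2_mean = be_log2_mean, be_log2_sd = be_log2_sd,
    igg_yield_ratio = igg_yield_ratio, dispersion = dispersion,
    replicate_effect_sd = replicate_effect_sd,
    library_size_range = library_size_range,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    nested = isTRUE(nested), pas_min_separation = as.integer(pas_min_separation),
    allow_overlapping_genes = isTRUE(allow_overlapping_genes),
    reads_per_sample = reads_per_sample,
    pcr_duplicate_rate = pcr_duplicate_rate,
    background_fraction = background_fraction,
    re_shift_targets = re_shift_targets, re_sd = re_sd,
    qpcr_noise_sd = qpcr_noise_sd, seed = as.integer(seed)
  )

  fail <- function(field, msg) {
    stop("invalid simulation config field '", field, "': ", msg, call. = FALSE)
  }
  if (length(cfg$n_genes) != 1L || is.na(cfg$n_genes) || cfg$n_genes < 1L)
    fail("n_genes", "must be a positive integer")
  if (length(cfg$pas_per_gene) != 2L || any(cfg$pas_per_gene < 1L) ||
      cfg$pas_per_gene[1] > cfg$pas_per_gene[2])
    fail("pas_per_gene", "must be an increasing positive integer range c(min, max)")
  if (length(cfg$cell_types) < 1L || anyDuplicated(cfg$cell_types))
    fail("cell_types", "must be a non-empty vector of distinct labels")
  if (cfg$n_replicates < 1L) fail("n_replicates", "must be >= 1")

  nct <- length(cfg$cell_types)
  cfg$fraction_bound <- expand_per_cell_type(cfg$fraction_bound, cfg$cell_types,
                                             "fraction_bound", fail)
  if (any(cfg$fraction_bound < 0) || any(cfg$fraction_bound > 1))
    fail("fraction_bound", "must lie in [0, 1]")
  if (cfg$nested && nct > 1L && any(diff(cfg$fraction_bound) > 1e-12))
    fail("fraction_bound", "must be non-increasing along cell_types when nested = TRUE")

  if (is.null(cfg$igg_replicates)) {
    cfg$igg_replicates <- setNames(rep(cfg$n_replicates, nct), cfg$cell_types)
  } else {
    cfg$igg_replicates <- expand_per_cell_type(cfg$igg_replicates, cfg$cell_types,
                                               "igg_replicates", fail)
    cfg$igg_replicates <- as.integer(cfg$igg_replicates)
    names(cfg$igg_replicates) <- cfg$cell_types
  }
  if (any(cfg$igg_replicates < 1L) || any(cfg$igg_replicates > cfg$n_replicates))
    fail("igg_replicates", "must lie in [1, n_replicates]")

  if (!(cfg$igg_yield_ratio > 0 && cfg$igg_yield_ratio < 1))
    fail("igg_yield_ratio", "must lie in (0, 1)")
  if (!(cfg$dispersion > 0)) fail("dispersion", "must be > 0")
  if (cfg$be_log2_sd < 0) fail("be_log2_sd", "must be >= 0")
  if (cfg$replicate_effect_sd < 0) fail("replicate_effect_sd", "must be >= 0")
  if (length(cfg$library_size_range) != 2L || any(cfg$library_size_range <= 0) ||
      cfg$library_size_range[1] > cfg$library_size_range[2])
    fail("library_size_range", "must be a positive increasing range")
  if (cfg$pcr_duplicate_rate < 0) fail("pcr_duplicate_rate", "must be >= 0")
  if (cfg$background_fraction < 0 || cfg$background_fraction >= 1)
    fail("background_fraction", "must lie in [0, 1)")
  if (cfg$re_sd <= 0) fail("re_sd", "must be > 0")
  if (cfg$qpcr_noise_sd < 0) fail("qpcr_noise_sd", "must be >= 0")
  if (is.na(cfg$seed)) fail("seed", "must be an integer")

  structure(cfg, class = "rip_sim_config")
}

# recycle a scalar or match a (possibly named) per-cell-type vector;
# names that do not cover the cell types fall back to positional matching
expand_per_cell_type <- function(x, cell_types, field, fail) {
  if (length(x) == 1L)
    return(setNames(rep(as.numeric(x), length(cell_types)), cell_types))
  if (!is.null(names(x)) && all(cell_types %in% names(x)))
    return(setNames(as.numeric(x[cell_types]), cell_types))
  setNames(rep_len(as.numeric(unname(x)), length(cell_types)), cell_types)
}

#' @export
print.rip_sim_config <- function(x, ...) {
  cat("RIP-seq simulation config:", x$n_genes, "genes;",
      length(x$cell_types), "cell types (", paste(x$cell_types, collapse = ", "),
      ");", x$n_replicates, "replicates; seed", x$seed, "\n")
  cat("  bound fractions:", paste(sprintf("%s=%.3g", names(x$fraction_bound),
                                          x$fraction_bound), collapse = ", "), "\n")
  cat("  be_log2 ~ N(", x$be_log2_mean, ",", x$be_log2_sd,
      "); IgG yield ratio", x$igg_yield_ratio,
      "; dispersion", x$dispersion, "\n")
  invisible(x)
}

# deterministic sub-seeds so each generator is reproducible on its own,
# independent of call order; kept well below .Machine$integer.max
sim_seed <- function(config, offset) {
  (config$seed %% 1000000L) * 1000L + offset
}
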