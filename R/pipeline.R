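#' Run the simulate-to-statistics pipeline into a directory
#'
#' Orchestrates the stages as one reproducible run. Every stage reads
#' its inputs from, and writes its outputs to, `out_dir`, so a partial
#' rerun (`resume = TRUE`, the default) skips stages whose outputs are
#' already present. The run ends by writing `manifest.tsv` listing
#' every output with its MD5 content hash; two runs with the same
#' configuration and seed produce identical manifests.
#'
#' Stages:
#' * `simulate` — ground truth, PAS annotation (BED6), sample sheet,
#'   count matrix, ribosomal-engagement table and qPCR Ct table.
#' * `quantify` — read-level path: simulated read 3' ends per sample
#'   (BED6, UMI in the name column), deduplicated, assigned to PAS
#'   windows and aggregated to a second gene count matrix with
#'   assignment tallies.
#' * `normalize` — size factors per sample, shifted-log transform, PCA
#'   coordinates.
#' * `call` — two-stage target calls per cell type plus a JSON summary
#'   with per-cell-type counts and overlap regions.
#' * `stats` — ribosomal-engagement comparison per cell type and
#'   delta-delta-Ct quantification of the simulated qPCR table.
#'
#' @param out_dir run directory (created if needed).
#' @param config a [simulation_config()]; its `seed` drives every
#'   random draw.
#' @param calling a [calling_config()].
#' @param stages subset of
#'   `c("simulate", "quantify", "normalize", "call", "stats")`.
#' @param resume skip stages whose outputs already exist.
#' @return invisibly, a list with the manifest data frame and the
#'   output paths.
#' @export
run_pipeline <- function(out_dir,
                         config = simulation_config(),
                         calling = calling_config(),
                         stages = c("simulate", "normalize", "call", "stats"),
                         resume = TRUE) {
  stages <- match.arg(stages, c("simulate", "quantify", "normalize",
                                "call", "stats"), several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path <- function(...) file.path(out_dir, ...)
  log_path <- path("run_log.txt")
  log_lines <- c(sprintf("riptarget run; seed %d; stages: %s",
                         config$seed, paste(stages, collapse = ", ")))
  done <- function(files) resume && all(file.exists(files))

  if ("simulate" %in% stages) {
    outs <- path(c("truth.tsv", "pas.bed", "samples.tsv", "counts.tsv",
                   "re_table.tsv", "qpcr.tsv"))
    if (!done(outs)) {
      truth <- generate_truth(config)
      pas <- generate_pas_annotation(config)
      sim <- simulate_counts(config, truth)
      write_tsv(truth, path("truth.tsv"))
      write_pas_bed(pas, path("pas.bed"))
      write_tsv(sim$samples, path("samples.tsv"))
      write_counts(sim$counts, path("counts.tsv"))
      write_tsv(simulate_re_table(config, truth), path("re_table.tsv"))
      write_tsv(simulate_qpcr(config), path("qpcr.tsv"))
      log_lines <- c(log_lines, sprintf(
        "simulate: %d genes x %d samples; %d bound (gene, cell type) pairs",
        config$n_genes, nrow(sim$samples), sum(truth$bound)))
    } else log_lines <- c(log_lines, "simulate: outputs present, skipped")
  }

  if ("quantify" %in% stages) {
    outs <- path(c("counts_from_reads.tsv", "assignment_stats.tsv"))
    if (!done(outs)) {
      truth <- read_tsv(path("truth.tsv"))
      pas <- read_pas_bed(path("pas.bed"))
      all_counts <- NULL
      all_stats <- NULL
      for (ct in config$cell_types) {
        sim <- simulate_read_ends(config, truth, pas, cell_type = ct)
        write_reads_bed(sim$reads, path("reads"))
        q <- quantify_pas(sim$reads, pas)
        all_counts <- if (is.null(all_counts)) q$gene_counts else
          cbind(all_counts, q$gene_counts)
        all_stats <- rbind(all_stats, q$stats)
      }
      write_counts(all_counts, path("counts_from_reads.tsv"))
      write_tsv(all_stats, path("assignment_stats.tsv"))
      log_lines <- c(log_lines, sprintf(
        "quantify: %d reads assigned, %d unassigned, %d ambiguous",
        sum(all_stats$assigned), sum(all_stats$unassigned),
        sum(all_stats$ambiguous)))
    } else log_lines <- c(log_lines, "quantify: outputs present, skipped")
  }

  if ("normalize" %in% stages) {
    outs <- path(c("size_factors.tsv", "pca.tsv"))
    if (!done(outs)) {
      counts <- read_counts(path("counts.tsv"))
      samples <- read_tsv(path("samples.tsv"))
      sf <- size_factors(counts)
      write_tsv(data.frame(sample_id = names(sf), size_factor = sf,
                           stringsAsFactors = FALSE),
                path("size_factors.tsv"))
      pc <- pca_qc(vst_like(counts, sf))
      pc$coords$cell_type <- samples$cell_type[
        match(pc$coords$sample_id, samples$sample_id)]
      pc$coords$assay <- samples$assay[
        match(pc$coords$sample_id, samples$sample_id)]
      write_tsv(pc$coords, path("pca.tsv"))
      log_lines <- c(log_lines, sprintf(
        "normalize: PC1/PC2 explain %.1f%% / %.1f%% of variance",
        100 * pc$var_explained[1], 100 * pc$var_explained[2]))
    } else log_lines <- c(log_lines, "normalize: outputs present, skipped")
  }

  if ("call" %in% stages) {
    outs <- path(c("targets.tsv", "target_summary.json"))
    if (!done(outs)) {
      counts <- read_counts(path("counts.tsv"))
      samples <- read_tsv(path("samples.tsv"))
      calls <- call_targets(counts, samples, calling)
      write_tsv(as.data.frame(calls), path("targets.tsv"))
      summ <- summarize_targets(calls)
      jsonlite::write_json(summ, path("target_summary.json"),
                           auto_unbox = FALSE, digits = NA, pretty = TRUE)
      log_lines <- c(log_lines, sprintf(
        "call: targets per cell type: %s",
        paste(sprintf("%s=%d", names(summ$n_targets), summ$n_targets),
              collapse = ", ")))
    } else log_lines <- c(log_lines, "call: outputs present, skipped")
  }

  if ("stats" %in% stages) {
    outs <- path(c("stats.json", "qpcr_ddct.tsv"))
    if (!done(outs)) {
      calls <- read_tsv(path("targets.tsv"))
      re_table <- read_tsv(path("re_table.tsv"))
      qpcr <- read_tsv(path("qpcr.tsv"))
      re_stats <- list()
      for (ct in unique(calls$cell_type)) {
        targets <- calls$gene_id[calls$cell_type == ct & calls$is_target]
        re_stats[[ct]] <- if (length(targets) > 0) {
          cmp <- compare_re(re_table, targets, ct)
          list(n_targets = length(targets), t = cmp$statistic,
               p = cmp$p, mean_diff = cmp$mean_diff)
        } else list(n_targets = 0L)
      }
      dd <- ddct(qpcr)
      write_tsv(dd, path("qpcr_ddct.tsv"))
      jsonlite::write_json(list(ribosomal_engagement = re_stats),
                           path("stats.json"), auto_unbox = TRUE,
                           digits = 10, pretty = TRUE)
      log_lines <- c(log_lines, "stats: RE comparisons and ddCt written")
    } else log_lines <- c(log_lines, "stats: outputs present, skipped")
  }

  writeLines(log_lines, log_path)
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        c("manifest.tsv", "run_log.txt")))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE
  )
  write_tsv(manifest, path("manifest.tsv"))
  invisible(list(manifest = manifest, out_dir = out_dir,
                 files = file.path(out_dir, files)))
}

#' Canned simulation presets for tests and documentation
#'
#' * `"null"` — no bound genes and an IgG control yielding at the
#'   Input level: everything a target caller reports is a false call.
#' * `"strong"` — 10% of genes bound at a fixed log2 binding
#'   efficiency of 2, IgG at one quarter of the Input yield: the
#'   recovery benchmark.
#' * `"nested"` — bound sets shrinking along the cell-type order
#'   (each cell type's targets nest inside the previous one's).
#'
#' @param preset one of `"null"`, `"strong"`, `"nested"`.
#' @param n_genes number of genes.
#' @param seed simulation seed.
#' @return list with `config`, `truth`, `counts`, `samples`.
#' @export
make_fixtures <- function(preset = c("null", "strong", "nested"),
                          n_genes = 5000, seed = 1L) {
  preset <- match.arg(preset)
  config <- switch(preset,
    null = simulation_config(n_genes = n_genes, fraction_bound = 0,
                             igg_yield_ratio = 0.95, seed = seed),
    strong = simulation_config(n_genes = n_genes, fraction_bound = 0.1,
                               be_log2_mean = 2, be_log2_sd = 0,
                               igg_yield_ratio = 0.25, seed = seed),
    nested = simulation_config(n_genes = n_genes, nested = TRUE, seed = seed)
  )
  truth <- generate_truth(config)
  sim <- simulate_counts(config, truth)
  list(config = config, truth = truth, counts = sim$counts,
       samples = sim$samples)
}
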