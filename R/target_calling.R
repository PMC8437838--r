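#' Configuration of the two-stage target calling
#'
#' Thresholds of the target definition: a gene is a target in a cell
#' type when its specific-IP enrichment is at least `fold_min`
#' (`log2fc_min` in log2) with BH-adjusted p at most `padj_max`, both
#' over the IgG control (stage 1, with specific-IP size factors scaled
#' by `ip_igg_sf_scale`) and over the Input (stage 2, unscaled; its
#' log2 fold change is the reported binding efficiency).
#'
#' @param log2fc_min minimum log2 enrichment (default 0.58).
#' @param fold_min the same threshold on the fold scale (default 1.5);
#'   `round(log2(fold_min), 2)` must equal `log2fc_min`.
#' @param padj_max maximum BH-adjusted p-value.
#' @param ip_igg_sf_scale manual scaling of specific-IP size factors in
#'   the IP-vs-IgG stage.
#' @param apply_ip_scale_stage2 also scale the IP factors in the
#'   IP-vs-Input stage (off by default; the scaling is motivated by the
#'   IgG yield gap).
#' @param expression_min_norm_count a gene counts as expressed in a
#'   cell type when its normalised Input count reaches this value in at
#'   least half of the Input replicates.
#' @param specificity_percentile a gene is cell-type specific when it
#'   sits at or below this percentile of expression in every other
#'   cell type.
#' @return an object of class `rip_calling_config`.
#' @export
calling_config <- function(log2fc_min = 0.58, fold_min = 1.5,
                           padj_max = 0.05, ip_igg_sf_scale = 1.5,
                           apply_ip_scale_stage2 = FALSE,
                           expression_min_norm_count = 5,
                           specificity_percentile = 20) {
  if (round(log2(fold_min), 2) != round(log2fc_min, 2))
    stop("log2fc_min (", log2fc_min, ") must equal log2(fold_min) = ",
         round(log2(fold_min), 2), " to 2 decimals")
  if (!(padj_max > 0 && padj_max < 1)) stop("padj_max must lie in (0, 1)")
  if (ip_igg_sf_scale <= 0) stop("ip_igg_sf_scale must be positive")
  if (specificity_percentile <= 0 || specificity_percentile >= 100)
    stop("specificity_percentile must lie in (0, 100)")
  structure(list(log2fc_min = log2fc_min, fold_min = fold_min,
                 padj_max = padj_max, ip_igg_sf_scale = ip_igg_sf_scale,
                 apply_ip_scale_stage2 = isTRUE(apply_ip_scale_stage2),
                 expression_min_norm_count = expression_min_norm_count,
                 specificity_percentile = specificity_percentile),
            class = "rip_calling_config")
}

#' Flag expressed genes per cell type
#'
#' A gene is expressed in a cell type when its Input count, divided by
#' the Input-derived size factor of its sample, reaches
#' `config$expression_min_norm_count` in at least half of that cell
#' type's Input replicates.
#'
#' @param counts count matrix, genes x samples.
#' @param samples sample sheet.
#' @param config a [calling_config()].
#' @return logical matrix, genes x cell types.
#' @export
expressed_genes <- function(counts, samples, config = calling_config()) {
  counts <- as.matrix(counts)
  cts <- unique(samples$cell_type)
  out <- matrix(FALSE, nrow(counts), length(cts),
                dimnames = list(rownames(counts), cts))
  thr <- config$expression_min_norm_count
  for (ct in cts) {
    ids <- samples$sample_id[samples$cell_type == ct & samples$assay == "Input"]
    if (length(ids) == 0L) stop("no Input samples for cell type ", ct)
    sub <- counts[, ids, drop = FALSE]
    sf <- size_factors(sub)
    norm <- sweep(sub, 2L, sf, "/")
    out[, ct] <- rowSums(norm >= thr) >= length(ids) / 2
  }
  out
}

#' Call protein-bound target genes per cell type
#'
#' Runs the two-stage enrichment filter independently per cell type:
#'
#' * stage 1: specific IP vs IgG control, NB Wald test with design
#'   `~ replicate + assay` and specific-IP size factors scaled by
#'   `config$ip_igg_sf_scale`;
#' * stage 2: specific IP vs Input with unscaled factors; its log2
#'   fold change is the gene's binding efficiency (BE).
#'
#' BH adjustment is genome-wide within each contrast. A gene is a
#' target when it is expressed and passes
#' `log2fc >= config$log2fc_min & padj <= config$padj_max` in both
#' stages.
#'
#' @param counts count matrix, genes x samples (all cell types).
#' @param samples sample sheet covering Input, `TIA1_IP` and `IgG_IP`
#'   assays per cell type.
#' @param config a [calling_config()].
#' @param design model formula for both stages.
#' @return data frame of class `rip_target_calls`: one row per
#'   (gene, cell type) with `stage1_log2fc`, `stage1_padj`, `be_log2`,
#'   `stage2_padj`, `expressed`, `is_target`.
#' @export
call_targets <- function(counts, samples, config = calling_config(),
                         design = ~ replicate + assay) {
  counts <- as.matrix(counts)
  cts <- unique(samples$cell_type)
  expressed <- expressed_genes(counts, samples, config)
  out <- vector("list", length(cts))

  for (i in seq_along(cts)) {
    ct <- cts[i]
    sub_samples <- samples[samples$cell_type == ct, , drop = FALSE]
    missing <- setdiff(c("Input", "TIA1_IP", "IgG_IP"), unique(sub_samples$assay))
    if (length(missing) > 0)
      stop("cell type ", ct, " is missing assay(s): ",
           paste(missing, collapse = ", "))
    sub <- counts[, sub_samples$sample_id, drop = FALSE]
    sf <- size_factors(sub)

    stage1 <- nb_test(sub, sub_samples, contrast = c("assay", "TIA1_IP", "IgG_IP"),
                      design = design,
                      sf = scale_ip_factors(sf, sub_samples,
                                            scale = config$ip_igg_sf_scale))
    sf2 <- if (config$apply_ip_scale_stage2) {
      scale_ip_factors(sf, sub_samples, scale = config$ip_igg_sf_scale)
    } else sf
    stage2 <- nb_test(sub, sub_samples, contrast = c("assay", "TIA1_IP", "Input"),
                      design = design, sf = sf2)

    pass1 <- !is.na(stage1$padj) & stage1$log2fc >= config$log2fc_min &
      stage1$padj <= config$padj_max
    pass2 <- !is.na(stage2$padj) & stage2$log2fc >= config$log2fc_min &
      stage2$padj <= config$padj_max
    out[[i]] <- data.frame(
      gene_id = stage1$gene_id, cell_type = ct,
      base_mean = stage2$base_mean,
      stage1_log2fc = stage1$log2fc, stage1_padj = stage1$padj,
      be_log2 = stage2$log2fc, stage2_padj = stage2$padj,
      expressed = expressed[stage1$gene_id, ct],
      is_target = expressed[stage1$gene_id, ct] & pass1 & pass2,
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("rip_target_calls", class(res))
  res
}

#' Classify cell-type-specific genes
#'
#' A gene is specific to cell type `X` when it passes the expression
#' filter in `X` and its expression falls at or below the
#' `config$specificity_percentile`-th percentile (midrank ties) of the
#' expressed genes of *every* other cell type.
#'
#' @param expr_summary numeric matrix, genes x cell types, of mean
#'   normalised Input counts.
#' @param expressed logical matrix from [expressed_genes()] (same
#'   shape).
#' @param config a [calling_config()].
#' @return logical matrix, genes x cell types; `[g, X]` is `TRUE` when
#'   gene `g` is specific to `X`.
#' @export
cell_type_specific <- function(expr_summary, expressed,
                               config = calling_config()) {
  expr_summary <- as.matrix(expr_summary)
  stopifnot(identical(dim(expr_summary), dim(expressed)))
  cts <- colnames(expr_summary)
  pctl <- config$specificity_percentile
  # midrank percentile of every gene against the expressed genes of ct
  pct_mat <- matrix(NA_real_, nrow(expr_summary), length(cts),
                    dimnames = dimnames(expr_summary))
  for (j in seq_along(cts)) {
    ref <- expr_summary[expressed[, j], j]
    if (length(ref) == 0L) next
    x <- expr_summary[, j]
    below <- findInterval(x, sort(ref)) # counts ref <= x
    ties <- vapply(x, function(v) sum(ref == v), numeric(1))
    pct_mat[, j] <- 100 * (below - ties / 2) / length(ref)
  }
  out <- matrix(FALSE, nrow(expr_summary), length(cts),
                dimnames = dimnames(expr_summary))
  for (j in seq_along(cts)) {
    others <- setdiff(seq_along(cts), j)
    low_elsewhere <- rep(TRUE, nrow(expr_summary))
    for (k in others)
      low_elsewhere <- low_elsewhere & !is.na(pct_mat[, k]) & pct_mat[, k] <= pctl
    out[, j] <- expressed[, j] & low_elsewhere
  }
  out
}

#' Disjoint overlap regions of target sets
#'
#' For `k` named sets, returns the `2^k - 1` exclusive region counts
#' (e.g. genes in sets A and B but not C), summing to the size of the
#' union — the numbers behind a Venn diagram.
#'
#' @param sets named list of character vectors.
#' @return named integer vector; names join the member sets with `&`.
#' @export
overlap_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
  universe <- unique(unlist(sets))
  k <- length(sets)
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  names(combos) <- names(sets)
  out <- integer(nrow(combos))
  labels <- character(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    inc <- as.logical(combos[i, ])
    match_row <- rep(TRUE, length(universe))
    for (j in seq_len(k)) match_row <- match_row & (member[, j] == inc[j])
    out[i] <- sum(match_row)
    labels[i] <- paste(names(sets)[inc], collapse = "&")
  }
  setNames(out, labels)
}

#' Summarise target calls
#'
#' @param calls a [call_targets()] result.
#' @return list with per-cell-type target counts and the disjoint
#'   overlap regions of the target sets.
#' @export
summarize_targets <- function(calls) {
  cts <- unique(calls$cell_type)
  sets <- lapply(cts, function(ct)
    calls$gene_id[calls$cell_type == ct & calls$is_target])
  names(sets) <- cts
  list(n_targets = vapply(sets, length, integer(1)),
       venn = overlap_sets(sets))
}
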