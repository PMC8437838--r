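#' Two-group comparison by t-test
#'
#' Thin, structured wrapper around the classical t-test used for the
#' package's comparative questions: unpaired (Welch by default, pooled
#' variance via `var_equal = TRUE`) for distinct gene groups within a
#' sample (e.g. ribosomal-protein binding efficiencies vs all genes),
#' paired for the same transcripts measured in two cell types.
#'
#' @param a,b numeric vectors; aligned element-wise when `paired`.
#' @param paired paired comparison?
#' @param var_equal pooled-variance (classical Student) instead of
#'   Welch for the unpaired case.
#' @param two_sided two-sided alternative (default).
#' @return list of class `rip_group_comparison`: `statistic`, `df`,
#'   `p`, `n_a`, `n_b`, `paired`, `mean_diff` (`mean(a - b)` when
#'   paired, `mean(a) - mean(b)` otherwise), `flag` (`"ok"` or
#'   `"zero_variance"`).
#' @export
compare_groups <- function(a, b, paired = FALSE, var_equal = FALSE,
                           two_sided = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (paired && length(a) != length(b))
    stop("paired comparison needs equal-length, aligned vectors")
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 observations per group")
  alternative <- if (two_sided) "two.sided" else "greater"
  mean_diff <- if (paired) mean(a - b) else mean(a) - mean(b)
  if (paired && sd(a - b) == 0) {
    # identical paired vectors are a well-defined no-difference result;
    # constant non-zero differences have no finite t and are flagged
    if (mean_diff == 0) {
      return(structure(list(statistic = 0, df = length(a) - 1, p = 1,
                            n_a = length(a), n_b = length(b), paired = TRUE,
                            mean_diff = 0, flag = "ok"),
                       class = "rip_group_comparison"))
    }
    return(structure(list(statistic = NA_real_, df = NA_real_, p = NA_real_,
                          n_a = length(a), n_b = length(b), paired = TRUE,
                          mean_diff = mean_diff, flag = "zero_variance"),
                     class = "rip_group_comparison"))
  }
  tt <- tryCatch(
    t.test(a, b, paired = paired, var.equal = var_equal,
           alternative = alternative),
    error = function(e) NULL
  )
  if (is.null(tt)) {
    res <- list(statistic = NA_real_, df = NA_real_, p = NA_real_,
                n_a = length(a), n_b = length(b), paired = paired,
                mean_diff = mean_diff, flag = "zero_variance")
  } else {
    res <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, n_a = length(a), n_b = length(b),
                paired = paired, mean_diff = mean_diff, flag = "ok")
  }
  structure(res, class = "rip_group_comparison")
}

#' @export
print.rip_group_comparison <- function(x, ...) {
  cat(if (x$paired) "paired" else "unpaired", "t-test: t =",
      signif(x$statistic, 4), ", df =", signif(x$df, 4),
      ", p =", signif(x$p, 4), "\n")
  cat("  n =", x$n_a, "vs", x$n_b, "; mean difference =",
      signif(x$mean_diff, 4), if (x$flag != "ok") paste0(" [", x$flag, "]"), "\n")
  invisible(x)
}

#' Compare ribosomal engagement of targets against the background
#'
#' Welch t-test of the ribosomal-engagement (RE) values of the target
#' genes against all other detected genes in one cell type. A negative
#' mean difference means targets are less ribosome-engaged — the
#' signature of translational repression by the binding protein.
#'
#' @param re_table data frame `gene_id`, `cell_type`, `re`.
#' @param target_set character vector of target gene ids.
#' @param cell_type cell type to compare within.
#' @return a [compare_groups()] result (`mean_diff` = targets minus
#'   background).
#' @export
compare_re <- function(re_table, target_set, cell_type) {
  sub <- re_table[re_table$cell_type == cell_type, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no RE values for cell type ", cell_type)
  is_t <- sub$gene_id %in% target_set
  if (!any(is_t)) stop("empty target set for cell type ", cell_type)
  if (all(is_t))
    stop("target set covers every detected gene; no background to compare against")
  compare_groups(sub$re[is_t], sub$re[!is_t], paired = FALSE)
}

#' Relative qPCR quantification (delta-delta-Ct) of IP enrichment
#'
#' For each gene, computes `dCt = Ct_gene - Ct_reference` within the
#' Input and IP assays, `ddCt = dCt_IP - dCt_Input`, and the fold
#' change `2^-ddCt`. Also reports the percent-of-input recovery,
#' adjusting the Input Ct for the fraction of lysate it represents:
#' `percent_input = 100 * 2^(Ct_input_adj - Ct_IP)` with
#' `Ct_input_adj = Ct_input - log2(1 / input_fraction)`. Ct values are
#' averaged over replicates first. Both quantities are invariant to a
#' constant shift of all Ct values.
#'
#' @param ct_table data frame `gene`, `assay`, `replicate`, `ct`.
#' @param reference_gene normalising control (e.g. 18S rRNA).
#' @param input_fraction fraction of the lysate used as Input
#'   (default 0.1, i.e. a 10% input aliquot).
#' @param ip_assay,input_assay assay labels to contrast.
#' @return data frame `gene`, `ddct`, `fold_change`, `percent_input`.
#' @export
ddct <- function(ct_table, reference_gene = "rRNA_18S",
                 input_fraction = 0.1,
                 ip_assay = "TIA1_IP", input_assay = "Input") {
  stopifnot(all(c("gene", "assay", "ct") %in% names(ct_table)))
  if (!(input_fraction > 0 && input_fraction <= 1))
    stop("input_fraction must lie in (0, 1]")
  mean_ct <- function(gene, assay) {
    v <- ct_table$ct[ct_table$gene == gene & ct_table$assay == assay]
    if (length(v) == 0L) return(NA_real_)
    mean(v)
  }
  genes <- setdiff(unique(ct_table$gene), reference_gene)
  if (!(reference_gene %in% ct_table$gene))
    stop("reference gene '", reference_gene, "' absent from the Ct table")
  ref_ip <- mean_ct(reference_gene, ip_assay)
  ref_in <- mean_ct(reference_gene, input_assay)
  if (is.na(ref_ip) || is.na(ref_in))
    stop("reference gene '", reference_gene,
         "' lacks Ct values in the contrasted assays")
  out <- lapply(genes, function(g) {
    ct_ip <- mean_ct(g, ip_assay)
    ct_in <- mean_ct(g, input_assay)
    if (is.na(ct_ip) || is.na(ct_in))
      stop("gene '", g, "' lacks Ct values in the contrasted assays")
    ddct <- (ct_ip - ref_ip) - (ct_in - ref_in)
    ct_in_adj <- ct_in - log2(1 / input_fraction)
    data.frame(gene = g, ddct = ddct, fold_change = 2^-ddct,
               percent_input = 100 * 2^(ct_in_adj - ct_ip),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
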