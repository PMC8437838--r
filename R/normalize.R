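#' Median-of-ratios size factors
#'
#' The classical size-factor estimator for count matrices: per gene, the
#' geometric mean across samples is the reference; a sample's factor is
#' the median over genes of its count divided by that reference. Genes
#' with a zero in any sample drop out of the reference (their log
#' geometric mean is -Inf), and zero counts never enter a median.
#'
#' @param counts non-negative count matrix, genes x samples.
#' @return named positive numeric vector of size factors, one per
#'   sample (column).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  loggeo <- rowMeans(log(counts))
  if (!any(is.finite(loggeo)))
    stop("no gene has positive counts in every sample; filter low genes ",
         "or add a pseudocount before estimating size factors")
  sf <- apply(counts, 2L, function(cnts) {
    use <- is.finite(loggeo) & cnts > 0
    exp(median(log(cnts[use]) - loggeo[use]))
  })
  if (is.null(names(sf))) names(sf) <- colnames(counts)
  sf
}

#' Scale the size factors of the specific-IP libraries
#'
#' Multiplies the size factors of the specific-antibody IP samples by
#' `scale` (default 1.5), leaving Input and IgG factors untouched. This
#' manual scaling conservatively accounts for the consistently higher
#' RNA yield of the specific IP over the IgG control (on the order of
#' 4x from the same number of cells), and is applied for the IP-vs-IgG
#' contrast of the two-stage target calling.
#'
#' @param sf named size-factor vector from [size_factors()].
#' @param samples sample sheet with `sample_id` and `assay` columns;
#'   assays must be among `Input`, `TIA1_IP`, `IgG_IP`.
#' @param scale multiplier for the specific-IP factors.
#' @param ip_assay label of the specific-IP assay.
#' @return the scaled size-factor vector, with attribute
#'   `scaled_by_ip_rule = TRUE`.
#' @export
scale_ip_factors <- function(sf, samples, scale = 1.5, ip_assay = "TIA1_IP") {
  known <- c("Input", "TIA1_IP", "IgG_IP")
  bad <- setdiff(unique(samples$assay), known)
  if (length(bad) > 0)
    stop("unknown assay label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(known, collapse = ", "), ")")
  if (is.null(names(sf)) || !all(names(sf) %in% samples$sample_id))
    stop("size factors must be named by sample_id present in the sample sheet")
  assay <- samples$assay[match(names(sf), samples$sample_id)]
  sf[assay == ip_assay] <- sf[assay == ip_assay] * scale
  attr(sf, "scaled_by_ip_rule") <- TRUE
  sf
}

#' Median normalization for marker display
#'
#' Divides each sample's counts by that sample's median over its
#' expressed genes (counts > 0). Used for log10 marker heatmaps; not a
#' substitute for size factors in testing.
#'
#' @param counts count matrix, genes x samples.
#' @return numeric matrix of the same shape.
#' @export
median_normalize <- function(counts) {
  counts <- as.matrix(counts)
  med <- apply(counts, 2L, function(x) median(x[x > 0]))
  if (any(!is.finite(med)))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[!is.finite(med)], collapse = ", "))
  sweep(counts, 2L, med, "/")
}

#' Shifted-log variance-stabilising transform
#'
#' `log2(count / size_factor + 1)`: monotone in counts, finite
#' everywhere, and invariant to jointly rescaling counts and factors.
#' A light-weight stand-in for a parametric VST, sufficient for QC
#' (PCA, clustering) purposes.
#'
#' @param counts count matrix, genes x samples.
#' @param sf per-sample size factors (default: all 1).
#' @return numeric matrix of transformed values.
#' @export
vst_like <- function(counts, sf = rep(1, ncol(counts))) {
  counts <- as.matrix(counts)
  if (length(sf) != ncol(counts)) stop("one size factor per sample required")
  if (any(sf <= 0)) stop("size factors must be positive")
  log2(sweep(counts, 2L, sf, "/") + 1)
}

#' PCA of transformed counts for sample QC
#'
#' Centred PCA of the samples on the `ntop` highest-variance genes (the
#' usual QC convention), used to check that samples cluster by cell
#' type and assay.
#'
#' @param x transformed matrix (e.g. [vst_like()] output), genes x
#'   samples.
#' @param ntop number of top-variance genes to use.
#' @param ncomp number of components to return.
#' @return list with `coords` (data frame: `sample_id` plus `PC1..PCk`)
#'   and `var_explained` (fractions, non-increasing, summing to <= 1).
#' @export
pca_qc <- function(x, ntop = 500L, ncomp = 2L) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("PCA needs at least 2 samples")
  if (ncomp > ncol(x))
    stop("requested ", ncomp, " components but only ", ncol(x), " samples")
  rv <- matrixStats_rowVars(x)
  keep <- head(order(rv, decreasing = TRUE), min(ntop, nrow(x)))
  pc <- prcomp(t(x[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(ncomp, ncol(pc$x))
  coords <- data.frame(sample_id = colnames(x), pc$x[, seq_len(k), drop = FALSE],
                       row.names = NULL, stringsAsFactors = FALSE)
  list(coords = coords, var_explained = ve[seq_len(k)])
}

# row variances without extra dependencies
matrixStats_rowVars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1L)
}
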