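#' Remove PCR duplicates from a read 3'-end stream
#'
#' Collapses exact duplicates: at most one read is retained per
#' `(sample_id, chrom, strand, position, umi)` key, keeping the first
#' occurrence in input order. UMI matching is exact (no edit-distance
#' clustering), matching the usual QuantSeq dedup step.
#'
#' @param reads data frame with columns `chrom`, `strand`, `position`,
#'   `umi`, `sample_id`.
#' @return the deduplicated data frame, input order preserved.
#' @export
deduplicate_reads <- function(reads) {
  req <- c("chrom", "strand", "position", "umi", "sample_id")
  miss <- setdiff(req, names(reads))
  if (length(miss) > 0)
    stop("reads are missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(is.na(reads$umi) | reads$umi == "")
  if (length(bad) > 0)
    stop("reads without a UMI at row(s): ",
         paste(head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "")
  key <- paste(reads$sample_id, reads$chrom, reads$strand,
               reads$position, reads$umi, sep = "\r")
  out <- reads[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build polyA-site capture windows
#'
#' Each polyA site is captured by a fixed window around its cleavage
#' position: `upstream` nt transcriptionally upstream through
#' `downstream` nt downstream (default 20/10, a 30-nt window), to absorb
#' random priming and cleavage-site wobble. Coordinates are 0-based
#' half-open: on `+` the window is `[p - upstream, p + downstream)`; on
#' `-` it is mirrored to `[p - downstream + 1, p + upstream + 1)` so
#' "upstream" stays transcriptionally upstream. Windows running below
#' coordinate 0 are clipped with a warning.
#'
#' @param pas data frame with `gene_id`, `pas_id`, `chrom`, `strand`,
#'   `cleavage_position` (0-based).
#' @param upstream,downstream window extent in nt.
#' @return data frame `chrom`, `strand`, `start`, `end` (0-based
#'   half-open), `gene_id`, `pas_id`.
#' @export
build_pas_windows <- function(pas, upstream = 20L, downstream = 10L) {
  stopifnot(all(c("gene_id", "pas_id", "chrom", "strand",
                  "cleavage_position") %in% names(pas)))
  if (!all(pas$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  p <- as.integer(pas$cleavage_position)
  if (any(p < 0)) stop("cleavage positions must be >= 0")
  plus <- pas$strand == "+"
  start <- ifelse(plus, p - upstream, p - downstream + 1L)
  end <- ifelse(plus, p + downstream, p + upstream + 1L)
  clipped <- start < 0L
  if (any(clipped)) {
    warning(sum(clipped), " window(s) extended below coordinate 0 and were clipped")
    start[clipped] <- 0L
  }
  data.frame(chrom = pas$chrom, strand = pas$strand,
             start = as.integer(start), end = as.integer(end),
             gene_id = pas$gene_id, pas_id = pas$pas_id,
             stringsAsFactors = FALSE)
}

#' Assign deduplicated read 3' ends to polyA-site windows
#'
#' A read counts toward a window iff it lies on the same chromosome and
#' strand and `start <= position < end`. Reads overlapping no window are
#' tallied as unassigned. Reads overlapping windows of more than one
#' gene are, by default, assigned to none and tallied as ambiguous;
#' `ambiguous = "fraction"` instead splits them `1/k` across the `k`
#' windows. Multiple overlapping windows of the *same* gene resolve to
#' the first window (counts are summed per gene downstream anyway).
#'
#' @param reads deduplicated read data frame (see [deduplicate_reads()]).
#' @param windows output of [build_pas_windows()].
#' @param ambiguous `"drop"` (default) or `"fraction"`.
#' @return list with `pas_counts` (matrix, PAS x samples; numeric if
#'   fractional assignment is on), `pas_map` (pas_id -> gene_id), and
#'   `stats` (per sample: `assigned`, `unassigned`, `ambiguous`).
#' @export
assign_read_ends <- function(reads, windows, ambiguous = c("drop", "fraction")) {
  ambiguous <- match.arg(ambiguous)
  samples <- unique(reads$sample_id)
  pas_ids <- windows$pas_id
  counts <- matrix(0, nrow(windows), length(samples),
                   dimnames = list(pas_ids, samples))
  stats <- data.frame(sample_id = samples, assigned = 0, unassigned = 0,
                      ambiguous = 0, stringsAsFactors = FALSE)
  if (nrow(reads) == 0L)
    return(list(pas_counts = counts, pas_map = setNames(windows$gene_id, pas_ids),
                stats = stats))

  rgr <- GenomicRanges::GRanges(reads$chrom,
                                IRanges::IRanges(reads$position + 1L, width = 1L),
                                strand = reads$strand)
  wgr <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start + 1L, windows$end),
                                strand = windows$strand)
  ov <- GenomicRanges::findOverlaps(rgr, wgr, ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)

  n_genes_hit <- rep(0L, nrow(reads))
  if (length(qh) > 0) {
    genes_hit <- windows$gene_id[sh]
    # distinct genes per read
    gkey <- paste(qh, genes_hit, sep = "\r")
    first_gene <- !duplicated(gkey)
    n_genes_hit <- tabulate(qh[first_gene], nbins = nrow(reads))
  }

  si <- match(reads$sample_id, samples)
  unassigned <- n_genes_hit == 0L
  ambig <- n_genes_hit > 1L
  clean <- n_genes_hit == 1L

  # vectorized accumulation into the counts matrix by linear index
  add_counts <- function(counts, win_idx, samp_idx, val) {
    key <- (samp_idx - 1L) * nrow(counts) + win_idx
    agg <- rowsum(val, key)
    at <- as.integer(rownames(agg))
    counts[at] <- counts[at] + agg[, 1L]
    counts
  }
  if (any(clean) && length(qh) > 0) {
    keep <- clean[qh] & !duplicated(qh)   # first window of the single gene
    if (any(keep))
      counts <- add_counts(counts, sh[keep], si[qh[keep]], rep(1, sum(keep)))
  }
  if (ambiguous == "fraction" && any(ambig) && length(qh) > 0) {
    amb_hits <- ambig[qh]
    if (any(amb_hits)) {
      k_per_read <- tabulate(qh, nbins = nrow(reads)) # windows hit per read
      counts <- add_counts(counts, sh[amb_hits], si[qh[amb_hits]],
                           1 / k_per_read[qh[amb_hits]])
    }
  }

  for (s in seq_along(samples)) {
    stats$assigned[s] <- sum(clean & si == s)
    stats$unassigned[s] <- sum(unassigned & si == s)
    stats$ambiguous[s] <- sum(ambig & si == s)
  }
  if (ambiguous == "drop" && all(counts == round(counts)))
    storage.mode(counts) <- "integer"
  list(pas_counts = counts,
       pas_map = setNames(windows$gene_id, pas_ids),
       stats = stats)
}

#' Aggregate polyA-site counts to gene counts
#'
#' Gene abundance is the sum of its polyA-site counts per sample. Genes
#' present in the map but with zero counts everywhere are retained as
#' zero rows.
#'
#' @param pas_counts matrix of counts, PAS x samples (rownames are
#'   pas_ids).
#' @param pas_map named character vector mapping pas_id -> gene_id.
#' @return count matrix, genes x samples.
#' @export
aggregate_gene_counts <- function(pas_counts, pas_map) {
  unknown <- setdiff(rownames(pas_counts), names(pas_map))
  if (length(unknown) > 0)
    stop("pas_id(s) with no gene mapping: ",
         paste(head(unknown, 10L), collapse = ", "),
         if (length(unknown) > 10L) " ..." else "")
  genes <- unique(unname(pas_map))
  g <- factor(pas_map[rownames(pas_counts)], levels = genes)
  out <- rowsum(pas_counts, group = g)
  # rowsum drops levels with no rows; reinstate all-zero genes
  missing <- setdiff(genes, rownames(out))
  if (length(missing) > 0) {
    zero <- matrix(0, length(missing), ncol(pas_counts),
                   dimnames = list(missing, colnames(pas_counts)))
    out <- rbind(out, zero)
  }
  out[genes, , drop = FALSE]
}

#' Quantify gene abundance from read 3' ends in one call
#'
#' Convenience wrapper: deduplicate, build windows, assign, aggregate.
#'
#' @inheritParams deduplicate_reads
#' @inheritParams build_pas_windows
#' @inheritParams assign_read_ends
#' @return list with `gene_counts`, `pas_counts`, `stats` (assignment
#'   tallies per sample), and `windows`.
#' @export
quantify_pas <- function(reads, pas, upstream = 20L, downstream = 10L,
                         ambiguous = c("drop", "fraction")) {
  dedup <- deduplicate_reads(reads)
  windows <- build_pas_windows(pas, upstream = upstream, downstream = downstream)
  asg <- assign_read_ends(dedup, windows, ambiguous = ambiguous)
  gene_counts <- aggregate_gene_counts(asg$pas_counts, asg$pas_map)
  list(gene_counts = gene_counts, pas_counts = asg$pas_counts,
       stats = asg$stats, windows = windows)
}
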