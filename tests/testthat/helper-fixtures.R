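# Shared fixtures and independent brute-force oracles used across tests.
# Everything is generated in code at test time; nothing is stored.

.fixture_cache <- new.env(parent = emptyenv())

# memoised small planted-truth experiment used by several test files
small_strong_fixture <- function() {
  if (is.null(.fixture_cache$strong_small)) {
    .fixture_cache$strong_small <- make_fixtures("strong", n_genes = 800, seed = 42)
  }
  .fixture_cache$strong_small
}

# a minimal two-assay sample sheet (3 vs 3, one cell type)
two_group_samples <- function(n_per_group = 3L) {
  data.frame(
    sample_id = paste0("s", seq_len(2L * n_per_group)),
    assay = rep(c("Input", "TIA1_IP"), each = n_per_group),
    replicate = rep(seq_len(n_per_group), 2L),
    cell_type = "x",
    stringsAsFactors = FALSE
  )
}

# brute-force all-pairs overlap oracle: O(reads x windows)
oracle_assign <- function(reads, windows) {
  samples <- unique(reads$sample_id)
  counts <- matrix(0L, nrow(windows), length(samples),
                   dimnames = list(windows$pas_id, samples))
  for (w in seq_len(nrow(windows))) {
    hit <- reads$chrom == windows$chrom[w] &
      reads$strand == windows$strand[w] &
      reads$position >= windows$start[w] &
      reads$position < windows$end[w]
    if (!any(hit)) next
    # a read hitting windows of >1 gene is dropped by the default policy
    for (s in samples) {
      idx <- which(hit & reads$sample_id == s)
      for (i in idx) {
        genes_hit <- unique(windows$gene_id[
          windows$chrom == reads$chrom[i] &
            windows$strand == reads$strand[i] &
            windows$start <= reads$position[i] &
            windows$end > reads$position[i]])
        if (length(genes_hit) == 1L) {
          first_w <- which(windows$chrom == reads$chrom[i] &
                             windows$strand == reads$strand[i] &
                             windows$start <= reads$position[i] &
                             windows$end > reads$position[i])[1L]
          if (first_w == w) counts[w, s] <- counts[w, s] + 1L
        }
      }
    }
  }
  counts
}

# faster oracle for the big acceptance comparison: per-read enumeration
oracle_assign_fast <- function(reads, windows) {
  samples <- unique(reads$sample_id)
  counts <- matrix(0L, nrow(windows), length(samples),
                   dimnames = list(windows$pas_id, samples))
  si <- match(reads$sample_id, samples)
  for (i in seq_len(nrow(reads))) {
    hits <- which(windows$chrom == reads$chrom[i] &
                    windows$strand == reads$strand[i] &
                    windows$start <= reads$position[i] &
                    windows$end > reads$position[i])
    if (length(hits) == 0L) next
    if (length(unique(windows$gene_id[hits])) > 1L) next
    counts[hits[1L], si[i]] <- counts[hits[1L], si[i]] + 1L
  }
  counts
}

# independent step-up BH oracle
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# random read table generator for dedup / assignment oracles
random_reads <- function(n, chroms = c("c1", "c2"), max_pos = 2000L,
                         n_samples = 2L, umis = 50L) {
  data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    position = sample.int(max_pos, n, replace = TRUE) - 1L,
    umi = sprintf("UMI%03d", sample.int(umis, n, replace = TRUE)),
    sample_id = paste0("s", sample.int(n_samples, n, replace = TRUE)),
    stringsAsFactors = FALSE
  )
}
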