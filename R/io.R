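# Plain-text interchange: BED6 for genomic records, TSV for tables.

#' Write / read a polyA-site annotation as BED6
#'
#' Each cleavage site is one 1-nt BED feature (0-based half-open),
#' `name = pas_id` (which embeds the gene as `gene|pasN`), score 0,
#' strand in column 6.
#'
#' @param pas annotation data frame from [generate_pas_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pas_bed <- function(pas, path) {
  gr <- GenomicRanges::GRanges(
    pas$chrom,
    IRanges::IRanges(pas$cleavage_position + 1L, width = 1L),
    strand = pas$strand
  )
  S4Vectors::mcols(gr)$name <- pas$pas_id
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_pas_bed
#' @export
read_pas_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  name <- as.character(gr$name)
  data.frame(
    gene_id = sub("\\|.*$", "", name),
    pas_id = name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    cleavage_position = GenomicRanges::start(gr) - 1L,
    stringsAsFactors = FALSE
  )
}

#' Write / read read 3'-end records as BED6 (one file per sample)
#'
#' Each read 3' end is a 1-nt feature with `name = UMI`.
#'
#' @param reads read data frame (`chrom`, `strand`, `position`, `umi`,
#'   `sample_id`).
#' @param dir output directory; one `<sample_id>.bed` per sample.
#' @return character vector of written paths, invisibly.
#' @export
write_reads_bed <- function(reads, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (s in unique(reads$sample_id)) {
    sub <- reads[reads$sample_id == s, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      sub$chrom, IRanges::IRanges(sub$position + 1L, width = 1L),
      strand = sub$strand
    )
    S4Vectors::mcols(gr)$name <- sub$umi
    S4Vectors::mcols(gr)$score <- 0L
    p <- file.path(dir, paste0(s, ".bed"))
    rtracklayer::export(gr, p, format = "BED")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_reads_bed
#' @param path a single per-sample BED file.
#' @param sample_id sample id to stamp on the records (default: file
#'   name without extension).
#' @export
read_reads_bed <- function(path, sample_id = sub("\\.bed$", "", basename(path))) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    position = GenomicRanges::start(gr) - 1L,
    umi = as.character(gr$name),
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
}

#' Write / read a gene count matrix as TSV (genes in rows)
#'
#' @param counts count matrix with gene rownames and sample colnames.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), as.data.frame(counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write / read a plain data frame as TSV
#'
#' @param df data frame.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE)
}
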